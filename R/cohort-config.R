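#' Default clinical distribution parameters
#'
#' Group-wise age, fatigue-severity (FSS), disability (EDSS) and lesion-load
#' distributions for the synthetic cohort. Age and FSS are truncated normals
#' (`mean`, `sd`, `min`, `max`); EDSS is drawn uniformly on the 0.5-step
#' grid between `min` and `max`; lesion load is a range-truncated log-normal
#' (`meanlog`, `sdlog`, `min`, `max`) in cm^3. Controls carry no EDSS or
#' lesion load.
#'
#' @return Named list with elements `control`, `low_fatigue`, `high_fatigue`.
#' @export
default_clinical_params <- function() {
  list(
    control = list(
      age = c(mean = 38, sd = 7, min = 26, max = 49),
      fss = c(mean = 18, sd = 4, min = 13, max = 26),
      edss = NULL,
      lesion = NULL
    ),
    low_fatigue = list(
      age = c(mean = 38, sd = 5, min = 29, max = 43),
      fss = c(mean = 22, sd = 9, min = 11, max = 34),
      edss = c(min = 1.0, max = 1.5),
      lesion = c(meanlog = log(2), sdlog = 1.0, min = 0.15, max = 16.25)
    ),
    high_fatigue = list(
      age = c(mean = 42, sd = 8, min = 29, max = 56),
      fss = c(mean = 52, sd = 6, min = 42, max = 59),
      edss = c(min = 1.0, max = 2.5),
      lesion = c(meanlog = log(4), sdlog = 1.0, min = 0.44, max = 37.17)
    )
  )
}

group_levels <- function() c("control", "low_fatigue", "high_fatigue")

#' Build a group/voxel/metabolite effect map
#'
#' Convenience constructor for the multiplicative effects injected by
#' [simulate_cohort()]. The default reproduces the headline mechanism under
#' study: a 1.25-fold elevation of total creatine in the WM-rich target
#' voxels of the high-fatigue group.
#'
#' @param group Group label(s) receiving the effect.
#' @param voxel Voxel label(s) affected.
#' @param metabolite `"naa"` or `"tcr"`.
#' @param effect Multiplicative effect (> 0) applied to the voxel's true
#'   tissue concentration.
#' @return Tibble with columns `group`, `voxel`, `metabolite`, `effect`.
#' @export
effect_map <- function(group = "high_fatigue", voxel = c("L4", "R6"),
                       metabolite = "tcr", effect = 1.25) {
  tidyr::expand_grid(
    group = group, voxel = voxel, metabolite = metabolite, effect = effect
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the generative model used by
#' [simulate_cohort()]. Defaults encode the study conditions of the pontine
#' CSI cohort: group sizes 15/7/10, a per-voxel %GM profile spanning ~12%
#' (WM-rich pons) to ~90% (cerebellum), pure-tissue metabolite pools
#' calibrated so that NAA/tCr runs from ~2.75 in pure WM to ~1.1 in pure GM,
#' and measurement/biological noise calibrated to the observed voxel-ratio
#' spreads.
#'
#' @param n_control,n_low_fatigue,n_high_fatigue Subjects per group (>= 1).
#' @param tissue_profile Per-voxel %GM mean/SD table; see
#'   [default_tissue_profile()].
#' @param gm_conc,wm_conc Named numeric vectors (`naa`, `tcr`) of true
#'   metabolite concentrations (arbitrary units) in pure gray and pure white
#'   matter.
#' @param effects Effect map (see [effect_map()]) of multiplicative
#'   group/voxel/metabolite effects, or `NULL` for none.
#' @param csf_fraction_range Named list (`pons`, `cerebellum`) of
#'   `c(min, max)` CSF volume-fraction bounds; fractions are drawn uniformly.
#' @param noise_sd SD of the additive Gaussian measurement noise on fitted
#'   amplitudes (amplitude units).
#' @param conc_cv Coefficient of variation of the multiplicative
#'   (log-normal, median 1) biological variation of each voxel's metabolite
#'   concentration.
#' @param subject_scale_cv CV of the per-subject global signal scale
#'   (coil-loading); cancels in all within-subject ratios.
#' @param crlb_model List with `k` (reported CRLB = 100 * noise_sd * k /
#'   amplitude), `inflate_prob` (probability a value's CRLB is inflated,
#'   emulating occasional poor fits) and `inflate_range` (`c(min, max)`
#'   uniform inflation factor).
#' @param clinical_params Per-group clinical distributions; see
#'   [default_clinical_params()].
#' @param seed Integer seed; fans out to per-subject substreams.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 15,
                          n_low_fatigue = 7,
                          n_high_fatigue = 10,
                          tissue_profile = default_tissue_profile(),
                          gm_conc = c(naa = 1.1, tcr = 1.0),
                          wm_conc = c(naa = 2.2, tcr = 0.8),
                          effects = NULL,
                          csf_fraction_range = list(
                            pons = c(0.02, 0.18),
                            cerebellum = c(0.02, 0.12)
                          ),
                          noise_sd = 0.05,
                          conc_cv = 0.15,
                          subject_scale_cv = 0.05,
                          crlb_model = list(
                            k = 2,
                            inflate_prob = 0.03,
                            inflate_range = c(1.5, 3)
                          ),
                          clinical_params = default_clinical_params(),
                          seed = 1L) {
  cfg <- list(
    n_control = n_control,
    n_low_fatigue = n_low_fatigue,
    n_high_fatigue = n_high_fatigue,
    tissue_profile = tibble::as_tibble(tissue_profile),
    gm_conc = gm_conc,
    wm_conc = wm_conc,
    effects = if (is.null(effects)) effect_map()[0, ] else tibble::as_tibble(effects),
    csf_fraction_range = csf_fraction_range,
    noise_sd = noise_sd,
    conc_cv = conc_cv,
    subject_scale_cv = subject_scale_cv,
    crlb_model = crlb_model,
    clinical_params = clinical_params,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  p <- list()
  is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
  for (f in c("n_control", "n_low_fatigue", "n_high_fatigue")) {
    if (!is_count(cfg[[f]])) p[[f]] <- paste0("`", f, "` must be an integer count >= 1")
  }

  tp <- cfg$tissue_profile
  need <- c("voxel", "pct_gm_mean", "pct_gm_sd")
  if (!all(need %in% names(tp))) {
    p$tissue_profile <- "`tissue_profile` must have columns voxel, pct_gm_mean, pct_gm_sd"
  } else {
    if (!setequal(tp$voxel, voxel_labels())) {
      p$tissue_profile_voxels <- "`tissue_profile` must cover exactly the 16 voxels R1-R6, L1-L6, C1-C4"
    }
    if (any(tp$pct_gm_mean < 0 | tp$pct_gm_mean > 100)) {
      p$tissue_profile_mean <- "`tissue_profile$pct_gm_mean` must lie in [0, 100]"
    }
    if (any(tp$pct_gm_sd < 0)) {
      p$tissue_profile_sd <- "`tissue_profile$pct_gm_sd` must be >= 0"
    }
  }

  for (f in c("gm_conc", "wm_conc")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || !all(c("naa", "tcr") %in% names(v)) || any(v <= 0)) {
      p[[f]] <- paste0("`", f, "` must be a positive numeric vector with names naa, tcr")
    }
  }

  em <- cfg$effects
  if (nrow(em) > 0) {
    if (!all(c("group", "voxel", "metabolite", "effect") %in% names(em))) {
      p$effects <- "`effects` must have columns group, voxel, metabolite, effect"
    } else {
      if (!all(em$group %in% group_levels())) p$effects_group <- "`effects$group` has unknown group labels"
      if (!all(em$voxel %in% voxel_labels())) p$effects_voxel <- "`effects$voxel` has unknown voxel labels"
      if (!all(em$metabolite %in% c("naa", "tcr"))) p$effects_met <- "`effects$metabolite` must be naa or tcr"
      if (!all(em$effect > 0)) p$effects_effect <- "`effects$effect` must be > 0"
    }
  }

  for (rg in c("pons", "cerebellum")) {
    r <- cfg$csf_fraction_range[[rg]]
    if (is.null(r) || length(r) != 2 || any(r < 0) || any(r >= 1) || r[1] > r[2]) {
      p[[paste0("csf_", rg)]] <- paste0("`csf_fraction_range$", rg, "` must be c(min, max) within [0, 1)")
    }
  }

  for (f in c("noise_sd", "conc_cv", "subject_scale_cv")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      p[[f]] <- paste0("`", f, "` must be a single number >= 0")
    }
  }

  cm <- cfg$crlb_model
  if (!is.list(cm) || is.null(cm$k) || cm$k <= 0) p$crlb_k <- "`crlb_model$k` must be > 0"
  if (is.null(cm$inflate_prob) || cm$inflate_prob < 0 || cm$inflate_prob > 1) {
    p$crlb_prob <- "`crlb_model$inflate_prob` must be in [0, 1]"
  }
  if (is.null(cm$inflate_range) || length(cm$inflate_range) != 2 ||
    any(cm$inflate_range < 1) || cm$inflate_range[1] > cm$inflate_range[2]) {
    p$crlb_range <- "`crlb_model$inflate_range` must be c(min, max) with min >= 1"
  }

  if (!all(group_levels() %in% names(cfg$clinical_params))) {
    p$clinical <- "`clinical_params` must have entries control, low_fatigue, high_fatigue"
  }

  if (!is_count(abs(cfg$seed) + 1)) p$seed <- "`seed` must be a single integer"

  abort_invalid(p, "cohort configuration", class = "ponsmrsi_config_error")
}
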