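#' Simulate a synthetic CSI cohort
#'
#' Generates per-subject voxel tables with the statistical structure assumed
#' by the downstream pipeline. Each subject carries the 16 CSI voxels
#' (R1--R6, L1--L6, C1--C4). For each voxel, the percent gray matter of
#' brain tissue is drawn from the voxel's truncated-normal profile, the CSF
#' volume fraction uniformly from the region's range, and the true
#' (noiseless) fitted amplitude of each metabolite follows the
#' tissue-mixture dilution model
#'
#'   S0 = (fGM * C_GM + fWM * C_WM) * (1 - fCSF)
#'
#' (fGM, fWM the gray/white fractions of brain tissue, fGM + fWM = 1), so
#' that CSF partial-volume correction is its exact inverse in expectation.
#' Multiplicative group/voxel effects, median-1 log-normal biological
#' variation, a per-subject global scale, and additive Gaussian measurement
#' noise complete the observation model. Reported relative CRLBs follow
#' 100 * noise_sd * k / |amplitude|, occasionally inflated to exercise the
#' quality-control filter.
#'
#' Identical `(config, seed)` give byte-identical output; each subject draws
#' from an independently derived substream, so a subject's data do not
#' depend on the rest of the cohort.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort`, a tibble of one row per subject x voxel in
#'   the tidy interchange schema (`subject_id`, `group`, `age`, `fss`,
#'   `edss`, `lesion_volume_cm3`, `voxel`, `region`, `f_gm`, `f_wm`,
#'   `f_csf`, `naa`, `naa_crlb_pct`, `tcr`, `tcr_crlb_pct`), and `truth`,
#'   the recorded ground truth (per-voxel true fractions and noiseless
#'   amplitudes, pure-tissue ratios, the effect map, and the seed).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  groups <- rep(group_levels(),
    times = c(config$n_control, config$n_low_fatigue, config$n_high_fatigue)
  )
  n_sub <- length(groups)
  ids <- sprintf("S%03d", seq_len(n_sub))

  subj <- purrr::map2(seq_len(n_sub), groups, function(i, grp) {
    with_seed(
      fan_seed(config$seed, i),
      simulate_subject(ids[i], grp, config)
    )
  })

  cohort <- dplyr::bind_rows(purrr::map(subj, "data"))
  truth_voxels <- dplyr::bind_rows(purrr::map(subj, "truth"))

  truth <- list(
    voxels = truth_voxels,
    pure_gm_ratio = unname(config$gm_conc["naa"] / config$gm_conc["tcr"]),
    pure_wm_ratio = unname(config$wm_conc["naa"] / config$wm_conc["tcr"]),
    gm_conc = config$gm_conc,
    wm_conc = config$wm_conc,
    effects = config$effects,
    seed = config$seed
  )
  list(cohort = cohort, truth = truth)
}

# One subject's clinical fields plus 16 voxel measurements; assumes the RNG
# substream has already been seeded by the caller.
simulate_subject <- function(id, group, config) {
  cp <- config$clinical_params[[group]]
  age <- unname(rtruncnorm(1, cp$age["mean"], cp$age["sd"], cp$age["min"], cp$age["max"]))
  fss <- draw_fss(group, cp$fss)
  edss <- if (is.null(cp$edss)) NA_real_ else {
    grid <- seq(cp$edss["min"], cp$edss["max"], by = 0.5)
    grid[sample.int(length(grid), 1)]
  }
  lesion <- if (is.null(cp$lesion)) NA_real_ else draw_trunc_lnorm(cp$lesion)
  scale <- draw_lognorm_factor(1, config$subject_scale_cv)

  tp <- config$tissue_profile
  nv <- nrow(tp)
  pct_gm <- vapply(seq_len(nv), function(v) {
    rtruncnorm(1, tp$pct_gm_mean[v], tp$pct_gm_sd[v], 0, 100)
  }, numeric(1))
  region <- voxel_region(tp$voxel)
  csf_rng <- config$csf_fraction_range
  f_csf <- vapply(region, function(r) {
    stats::runif(1, csf_rng[[r]][1], csf_rng[[r]][2])
  }, numeric(1), USE.NAMES = FALSE)

  g <- pct_gm / 100 # GM fraction of brain tissue
  f_gm <- g * (1 - f_csf)
  f_wm <- (1 - g) * (1 - f_csf)

  eff_naa <- effect_multiplier(config$effects, group, tp$voxel, "naa")
  eff_tcr <- effect_multiplier(config$effects, group, tp$voxel, "tcr")

  bio_naa <- draw_lognorm_factor(nv, config$conc_cv)
  bio_tcr <- draw_lognorm_factor(nv, config$conc_cv)

  conc_naa <- (g * config$gm_conc["naa"] + (1 - g) * config$wm_conc["naa"]) * eff_naa * bio_naa
  conc_tcr <- (g * config$gm_conc["tcr"] + (1 - g) * config$wm_conc["tcr"]) * eff_tcr * bio_tcr

  s0_naa <- conc_naa * (1 - f_csf) * scale
  s0_tcr <- conc_tcr * (1 - f_csf) * scale

  naa <- s0_naa + stats::rnorm(nv, 0, config$noise_sd)
  tcr <- s0_tcr + stats::rnorm(nv, 0, config$noise_sd)

  cm <- config$crlb_model
  inflate <- function(n) {
    hit <- stats::runif(n) < cm$inflate_prob
    fac <- stats::runif(n, cm$inflate_range[1], cm$inflate_range[2])
    ifelse(hit, fac, 1)
  }
  crlb <- function(amp, infl) 100 * config$noise_sd * cm$k / pmax(abs(amp), 1e-12) * infl
  naa_crlb <- crlb(naa, inflate(nv))
  tcr_crlb <- crlb(tcr, inflate(nv))

  data <- tibble::tibble(
    subject_id = id, group = group, age = age, fss = fss, edss = edss,
    lesion_volume_cm3 = lesion,
    voxel = tp$voxel, region = region,
    f_gm = f_gm, f_wm = f_wm, f_csf = f_csf,
    naa = naa, naa_crlb_pct = naa_crlb,
    tcr = tcr, tcr_crlb_pct = tcr_crlb
  )
  truth <- tibble::tibble(
    subject_id = id, group = group, voxel = tp$voxel,
    f_gm = f_gm, f_wm = f_wm, f_csf = f_csf,
    conc_naa = unname(conc_naa), conc_tcr = unname(conc_tcr),
    s0_naa = unname(s0_naa), s0_tcr = unname(s0_tcr),
    subject_scale = scale
  )
  list(data = data, truth = truth)
}

effect_multiplier <- function(effects, group, voxels, metabolite) {
  out <- rep(1, length(voxels))
  if (nrow(effects) == 0) {
    return(out)
  }
  em <- effects[effects$group == group & effects$metabolite == metabolite, ]
  if (nrow(em) == 0) {
    return(out)
  }
  for (j in seq_len(nrow(em))) {
    out[voxels == em$voxel[j]] <- out[voxels == em$voxel[j]] * em$effect[j]
  }
  out
}

# Median-1 log-normal factor with coefficient of variation cv; log-symmetric
# so that log-scale fits of ratios are unbiased under biological noise.
draw_lognorm_factor <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog))
}

draw_trunc_lnorm <- function(par) {
  plo <- stats::plnorm(par["min"], par["meanlog"], par["sdlog"])
  phi <- stats::plnorm(par["max"], par["meanlog"], par["sdlog"])
  unname(stats::qlnorm(stats::runif(1, plo, phi), par["meanlog"], par["sdlog"]))
}

# FSS draw with the >36 fatigue cutoff enforced: high-fatigue scores are
# always above 36, low-fatigue and control scores never exceed it.
draw_fss <- function(group, par) {
  lo <- unname(par["min"])
  hi <- unname(par["max"])
  if (group == "high_fatigue") {
    lo <- max(lo, 36 + 1e-9)
  } else {
    hi <- min(hi, 36)
  }
  lo <- max(lo, 9)
  hi <- min(hi, 63)
  rtruncnorm(1, unname(par["mean"]), unname(par["sd"]), lo, hi)
}

#' Simulate Fatigue Severity Scale scores for a group
#'
#' Draws FSS scores from the group's truncated-normal distribution
#' (defaults: controls 18 +/- 4 on 13--26, low fatigue 22 +/- 9 on 11--34,
#' high fatigue 52 +/- 6 on 42--59). Draws are forced to respect the
#' fatigue cutoff: high-fatigue scores are always > 36, the other groups'
#' are always <= 36.
#'
#' @param group One of `"control"`, `"low_fatigue"`, `"high_fatigue"` (the
#'   shorthand `"low"`/`"high"` is accepted).
#' @param config A [cohort_config()] supplying the distribution parameters.
#' @param n Number of scores to draw.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return Numeric vector of FSS scores in \[9, 63\].
#' @export
simulate_fss <- function(group, config = cohort_config(), n = 1, seed = NULL) {
  group <- switch(group,
    low = "low_fatigue",
    high = "high_fatigue",
    group
  )
  if (!group %in% group_levels()) {
    rlang::abort(paste0("Unknown group label: '", group, "'"),
      class = "ponsmrsi_validation_error"
    )
  }
  par <- config$clinical_params[[group]]$fss
  with_seed(seed, vapply(seq_len(n), function(i) draw_fss(group, par), numeric(1)))
}

#' Simulate a lesion intensity image with known lesion volume
#'
#' Builds a 3D intensity image whose supra-threshold volume at the default
#' threshold equals the requested lesion volume to within one voxel. The
#' background is Gaussian, clipped strictly below the threshold; lesion
#' voxels are placed uniformly at random with intensities above it. The
#' threshold and voxel volume are stored as attributes so
#' [measure_lesion_volume()] can invert the construction.
#'
#' @param volume_cm3 Target lesion volume in cm^3 (>= 0).
#' @param shape Integer grid dimensions, default `c(40, 40, 40)`.
#' @param voxel_volume_mm3 Volume of one voxel in mm^3.
#' @param seed Optional seed.
#' @param background_mean,background_sd Background intensity distribution.
#' @return 3D numeric array with attributes `threshold` and
#'   `voxel_volume_mm3`.
#' @export
simulate_lesion_map <- function(volume_cm3, shape = c(40, 40, 40),
                                voxel_volume_mm3 = 1, seed = NULL,
                                background_mean = 30, background_sd = 5) {
  if (!is.numeric(volume_cm3) || length(volume_cm3) != 1 || volume_cm3 < 0) {
    rlang::abort("`volume_cm3` must be a single number >= 0",
      class = "ponsmrsi_validation_error"
    )
  }
  threshold <- background_mean + 3 * background_sd
  n_total <- prod(shape)
  n_lesion <- round(volume_cm3 * 1000 / voxel_volume_mm3)
  if (n_lesion > n_total) {
    rlang::abort(
      sprintf(
        "Target volume %.2f cm^3 (%d voxels) exceeds grid capacity (%d voxels)",
        volume_cm3, n_lesion, n_total
      ),
      class = "ponsmrsi_validation_error"
    )
  }
  img <- with_seed(seed, {
    bg <- stats::rnorm(n_total, background_mean, background_sd)
    bg <- pmin(bg, threshold - 0.5) # background strictly below threshold
    if (n_lesion > 0) {
      idx <- sample.int(n_total, n_lesion)
      bg[idx] <- threshold + abs(stats::rnorm(n_lesion, 10, 3))
    }
    array(bg, dim = shape)
  })
  attr(img, "threshold") <- threshold
  attr(img, "voxel_volume_mm3") <- voxel_volume_mm3
  img
}
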