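#' NAA / total-creatine ratio
#'
#' Elementwise ratio of the two amplitudes; non-positive or QC-missing
#' denominators yield a missing value rather than an error, matching the
#' available-case policy of the group statistics.
#'
#' @param naa,tcr Amplitudes (corrected or uncorrected; the CSF correction
#'   cancels in the ratio).
#' @return `naa / tcr`, `NA` where `tcr` is missing or `<= 0`.
#' @export
naa_tcr_ratio <- function(naa, tcr) {
  out <- naa / tcr
  out[is.na(tcr) | tcr <= 0] <- NA_real_
  out
}

#' Normalise pons metabolites to the subject's cerebellar reference
#'
#' For each subject and metabolite, divides every pons voxel's corrected
#' amplitude by the mean of that subject's surviving cerebellar voxels
#' (C1--C4), yielding NAA/NAA_Cb and tCr/tCr_Cb. The reference is strictly
#' within-subject, so any global per-subject signal scale (e.g. coil
#' loading) cancels. Subjects whose four cerebellar voxels all failed QC
#' for a metabolite get missing normalised ratios for that metabolite, with
#' a warning naming them.
#'
#' @param data Metrics-stage table with columns `subject_id`, `region`,
#'   `naa_corr`, `tcr_corr`.
#' @return `data` with `naa_over_naa_cb` and `tcr_over_tcr_cb` added
#'   (defined for pons rows; `NA` on cerebellar rows).
#' @export
cerebellar_normalize <- function(data) {
  cb_means <- data |>
    dplyr::filter(.data$region == "cerebellum") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      cb_naa = mean(.data$naa_corr, na.rm = TRUE),
      cb_tcr = mean(.data$tcr_corr, na.rm = TRUE),
      .groups = "drop"
    )
  lost_naa <- cb_means$subject_id[is.nan(cb_means$cb_naa)]
  lost_tcr <- cb_means$subject_id[is.nan(cb_means$cb_tcr)]
  if (length(lost_naa) > 0 || length(lost_tcr) > 0) {
    rlang::warn(paste0(
      "All cerebellar reference voxels rejected for: ",
      paste(unique(c(lost_naa, lost_tcr)), collapse = ", "),
      "; their normalised ratios are missing"
    ))
  }
  cb_means$cb_naa[is.nan(cb_means$cb_naa)] <- NA_real_
  cb_means$cb_tcr[is.nan(cb_means$cb_tcr)] <- NA_real_

  data |>
    dplyr::left_join(cb_means, by = "subject_id") |>
    dplyr::mutate(
      naa_over_naa_cb = ifelse(.data$region == "pons",
        .data$naa_corr / .data$cb_naa, NA_real_
      ),
      tcr_over_tcr_cb = ifelse(.data$region == "pons",
        .data$tcr_corr / .data$cb_tcr, NA_real_
      )
    ) |>
    dplyr::select(-"cb_naa", -"cb_tcr")
}

#' Ratio table for the statistical stages
#'
#' Adds the within-voxel NAA/tCr ratio, the cerebellar-normalised
#' metabolite ratios, and the white-matter composition (`pct_wm`, and
#' `f_wm_tissue` as a fraction in \[0, 1\] for the projection fit).
#'
#' @param corrected Output `data` of [apply_metrics()].
#' @return Tibble with `naa_tcr`, `naa_over_naa_cb`, `tcr_over_tcr_cb` and
#'   `f_wm_tissue` (white-matter fraction of brain tissue, `pct_wm / 100`,
#'   the composition coordinate of [composition_fit()]) columns added.
#' @export
compute_ratios <- function(corrected) {
  corrected |>
    dplyr::mutate(
      naa_tcr = naa_tcr_ratio(.data$naa_corr, .data$tcr_corr),
      f_wm_tissue = .data$pct_wm / 100
    ) |>
    cerebellar_normalize()
}

#' Percent change of a case group mean relative to control
#'
#' @param mean_case,mean_control Group means of a ratio.
#' @param round_to Optional number of digits for reporting (e.g. 0 for the
#'   integer percentages used in summaries); `NULL` returns the raw value.
#' @return `100 * (mean_case - mean_control) / mean_control`.
#' @export
percent_change <- function(mean_case, mean_control, round_to = NULL) {
  if (any(mean_control <= 0)) {
    rlang::abort("`mean_control` must be > 0", class = "ponsmrsi_validation_error")
  }
  out <- 100 * (mean_case - mean_control) / mean_control
  if (!is.null(round_to)) out <- round(out, round_to)
  out
}

#' Fit ratio vs white-matter composition and project to pure tissue
#'
#' Per group, fits the dependence of a metabolite ratio on the
#' white-matter fraction of brain tissue, `f` in \[0, 1\], and extrapolates
#' to the pure-GM (`f = 0`) and pure-WM (`f = 1`) endpoints. The default
#' model is the rational (linear/linear) curve implied by a ratio of two
#' quantities each linear in composition,
#'
#'   r(f) = (a + (b - a) f) / (1 + (g - 1) f),
#'
#' whose endpoints are `r(0) = a` and `r(1) = b / g`; it reproduces the
#' curvature and between-group convergence toward GM-rich compositions
#' that a straight line cannot. Residuals are minimised on the log scale,
#' which symmetrises the predominantly multiplicative voxel-level
#' variation of positive ratios and removes the denominator-noise bias of
#' a linear-scale fit. A plain linear fit (`method = "linear"`) is
#' available as a fallback.
#'
#' Endpoint differences between groups are tested by a nonparametric
#' bootstrap over subjects (resampling subjects within group, refitting,
#' and forming the two-sided percentile p-value).
#'
#' @param ratios Ratio table from [compute_ratios()] (needs `subject_id`,
#'   `group`, `f_wm_tissue` and the outcome column).
#' @param outcome Name of the ratio column to model (default `"naa_tcr"`).
#' @param method `"rational"` (default) or `"linear"`.
#' @param boot Number of bootstrap resamples for endpoint contrasts
#'   (0 disables testing).
#' @param seed Seed for the bootstrap.
#' @return Object of class `composition_fit`: list with `fits` (per group:
#'   coefficients, endpoint estimates and SEs, n), `contrasts` (pairwise
#'   endpoint differences with bootstrap p-values; empty when `boot = 0`),
#'   `outcome`, `method`.
#' @export
composition_fit <- function(ratios, outcome = "naa_tcr",
                            method = c("rational", "linear"),
                            boot = 0, seed = NULL) {
  method <- match.arg(method)
  df <- ratios |>
    dplyr::select("subject_id", "group", f_wm = "f_wm_tissue", value = dplyr::all_of(outcome)) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$f_wm), .data$value > 0)

  groups <- intersect(group_levels(), unique(df$group))
  fits <- purrr::map(groups, function(g) {
    d <- df[df$group == g, ]
    check_composition_spread(d, g)
    fit_one_composition(d, method)
  })
  names(fits) <- groups

  fit_tbl <- purrr::imap_dfr(fits, function(f, g) {
    tibble::tibble(
      group = g, n_points = f$n,
      gm_est = f$gm_est, gm_se = f$gm_se,
      wm_est = f$wm_est, wm_se = f$wm_se,
      coef = list(f$coef)
    )
  })

  contrasts <- tibble::tibble(
    contrast = character(), endpoint = character(),
    diff = numeric(), p_boot = numeric()
  )
  if (boot > 0 && length(groups) >= 2) {
    contrasts <- bootstrap_endpoint_contrasts(df, groups, method, boot, seed)
  }

  structure(
    list(fits = fit_tbl, contrasts = contrasts, outcome = outcome, method = method),
    class = "composition_fit"
  )
}

check_composition_spread <- function(d, group) {
  fvals <- unique(round(d$f_wm, 6))
  if (length(fvals) < 3 || diff(range(d$f_wm)) < 0.3) {
    rlang::abort(
      sprintf(
        "Insufficient composition spread in group '%s': need >= 3 distinct f_wm values spanning the pons-cerebellum range",
        group
      ),
      class = "ponsmrsi_fit_error"
    )
  }
}

fit_one_composition <- function(d, method) {
  if (method == "linear") {
    lf <- stats::lm(value ~ f_wm, data = d)
    co <- stats::coef(lf)
    vc <- stats::vcov(lf)
    gm <- unname(co[1])
    wm <- unname(co[1] + co[2])
    return(list(
      n = nrow(d), coef = co,
      gm_est = gm, gm_se = sqrt(vc[1, 1]),
      wm_est = wm, wm_se = sqrt(vc[1, 1] + vc[2, 2] + 2 * vc[1, 2])
    ))
  }
  # starting values from a linear fit of the raw ratio
  lf <- stats::lm(value ~ f_wm, data = d)
  a0 <- max(unname(stats::coef(lf)[1]), 0.05)
  b0 <- max(unname(sum(stats::coef(lf))), 0.05)
  nf <- minpack.lm::nlsLM(
    log(value) ~ log(a + (b - a) * f_wm) - log(1 + (g - 1) * f_wm),
    data = d,
    start = list(a = a0, b = b0, g = 1),
    lower = c(a = 1e-6, b = 1e-6, g = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  )
  co <- stats::coef(nf)
  vc <- stats::vcov(nf)
  gm <- unname(co["a"])
  wm <- unname(co["b"] / co["g"])
  # delta method for the pure-WM endpoint b/g
  gr <- c(0, 1 / co["g"], -co["b"] / co["g"]^2)
  wm_se <- sqrt(drop(t(gr) %*% vc %*% gr))
  list(
    n = nrow(d), coef = co,
    gm_est = gm, gm_se = sqrt(vc["a", "a"]),
    wm_est = wm, wm_se = wm_se
  )
}

bootstrap_endpoint_contrasts <- function(df, groups, method, boot, seed) {
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  subj_by_group <- split(unique(df[, c("subject_id", "group")])$subject_id,
    unique(df[, c("subject_id", "group")])$group
  )
  rows_by_subj <- split(df, df$subject_id)

  with_seed(seed, {
    boot_endpoints <- replicate(boot, {
      ep <- purrr::map(groups, function(g) {
        subj <- subj_by_group[[g]]
        pick <- sample(subj, length(subj), replace = TRUE)
        d <- dplyr::bind_rows(rows_by_subj[pick])
        f <- tryCatch(fit_one_composition(d, method), error = function(e) NULL)
        if (is.null(f)) c(gm = NA_real_, wm = NA_real_) else c(gm = f$gm_est, wm = f$wm_est)
      })
      names(ep) <- groups
      ep
    }, simplify = FALSE)

    purrr::map_dfr(pairs, function(pr) {
      obs <- purrr::map(pr, function(g) {
        f <- fit_one_composition(df[df$group == g, ], method)
        c(gm = f$gm_est, wm = f$wm_est)
      })
      purrr::map_dfr(c("gm", "wm"), function(end) {
        diffs <- vapply(boot_endpoints, function(b) b[[pr[2]]][end] - b[[pr[1]]][end], numeric(1))
        diffs <- diffs[is.finite(diffs)]
        p <- 2 * min(
          (sum(diffs <= 0) + 1) / (length(diffs) + 1),
          (sum(diffs >= 0) + 1) / (length(diffs) + 1)
        )
        tibble::tibble(
          contrast = paste(pr[2], "-", pr[1]),
          endpoint = paste0("pure_", end),
          diff = unname(obs[[2]][end] - obs[[1]][end]),
          p_boot = min(p, 1)
        )
      })
    })
  })
}

#' @export
print.composition_fit <- function(x, ...) {
  cat("Composition projection fit (", x$method, ") of ", x$outcome, "\n", sep = "")
  df <- x$fits
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-13s pure GM %.3f (SE %.3f)   pure WM %.3f (SE %.3f)   n=%d\n",
      df$group[i], df$gm_est[i], df$gm_se[i], df$wm_est[i], df$wm_se[i], df$n_points[i]
    ))
  }
  if (nrow(x$contrasts) > 0) {
    cat("Endpoint contrasts (bootstrap):\n")
    print(as.data.frame(x$contrasts), row.names = FALSE)
  }
  invisible(x)
}
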