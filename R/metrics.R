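#' Percent gray matter of the brain tissue in a voxel
#'
#' `%GM = 100 * GM / (GM + WM)`; the complementary percent white matter is
#' `100 - %GM`. CSF does not enter: the quantity describes the composition
#' of the brain-tissue (non-CSF) content only.
#'
#' @param gm,wm Gray and white matter volumes (or fractions; same units).
#' @return Percent gray matter in \[0, 100\]. Vectorised.
#' @export
pct_gm <- function(gm, wm) {
  if (any(gm < 0) || any(wm < 0)) {
    rlang::abort("Tissue volumes must be >= 0", class = "ponsmrsi_validation_error")
  }
  if (any(gm + wm == 0)) {
    rlang::abort("No brain tissue in voxel: GM + WM must be > 0",
      class = "ponsmrsi_validation_error"
    )
  }
  100 * gm / (gm + wm)
}

#' Percent CSF of the whole voxel
#'
#' `%CSF = 100 * CSF / (GM + WM + CSF)`.
#'
#' @param gm,wm,csf Tissue and CSF volumes (same units).
#' @return Percent CSF in \[0, 100\]. Vectorised.
#' @export
pct_csf <- function(gm, wm, csf) {
  if (any(gm < 0) || any(wm < 0) || any(csf < 0)) {
    rlang::abort("Volumes must be >= 0", class = "ponsmrsi_validation_error")
  }
  if (any(gm + wm + csf == 0)) {
    rlang::abort("All-zero volumes in voxel", class = "ponsmrsi_validation_error")
  }
  100 * csf / (gm + wm + csf)
}

#' CSF partial-volume correction of a metabolite amplitude
#'
#' CSF contributes no metabolite signal, so the measured amplitude of a
#' voxel is diluted by its CSF fraction. The correction rescales to the
#' brain-tissue compartment: `S = S0 / (1 - %CSF / 100)`. Any global scale
#' constant is irrelevant downstream because only ratios of corrected
#' amplitudes are analysed, and the correction cancels exactly in
#' within-voxel ratios such as NAA/tCr.
#'
#' @param s0 Uncorrected amplitude(s).
#' @param pct_csf Percent CSF of the voxel, in \[0, 100).
#' @return Corrected amplitude(s), `>= s0` for `s0 >= 0`. Vectorised.
#' @export
csf_correct <- function(s0, pct_csf) {
  if (any(pct_csf < 0 | pct_csf >= 100, na.rm = TRUE)) {
    rlang::abort("`pct_csf` must lie in [0, 100): a pure-CSF voxel cannot be corrected",
      class = "ponsmrsi_validation_error"
    )
  }
  s0 / (1 - pct_csf / 100)
}

#' Quality-control filter on reported CRLBs
#'
#' Marks metabolite amplitudes whose relative Cramer-Rao lower bound is
#' strictly greater than the threshold as missing (the default 20% is the
#' conventional rejection limit; a CRLB of exactly 20% is retained). Only
#' the offending metabolite value is voided -- the voxel's other metabolite
#' and the subject's other voxels are kept, and group statistics later use
#' available cases per voxel.
#'
#' @param data Tidy cohort table with columns `naa`, `naa_crlb_pct`, `tcr`,
#'   `tcr_crlb_pct` (and `group` for the report).
#' @param crlb_max_pct Rejection threshold in percent (default 20).
#' @return List with `data` (values failing QC set to `NA`, plus logical
#'   columns `naa_ok`, `tcr_ok`) and `report` (per group x metabolite:
#'   number and percentage of rejected values).
#' @export
qc_filter <- function(data, crlb_max_pct = 20) {
  if (nrow(data) == 0) {
    return(list(data = data, report = tibble::tibble(
      group = character(), metabolite = character(),
      n_total = integer(), n_rejected = integer(), pct_rejected = numeric()
    )))
  }
  out <- data
  out$naa_ok <- !is.na(out$naa) & out$naa_crlb_pct <= crlb_max_pct
  out$tcr_ok <- !is.na(out$tcr) & out$tcr_crlb_pct <= crlb_max_pct
  out$naa[!out$naa_ok] <- NA_real_
  out$tcr[!out$tcr_ok] <- NA_real_

  grp <- if ("group" %in% names(data)) data$group else "all"
  report <- tibble::tibble(
    group = rep(grp, 2),
    metabolite = rep(c("naa", "tcr"), each = nrow(data)),
    rejected = c(!out$naa_ok, !out$tcr_ok)
  ) |>
    dplyr::group_by(.data$group, .data$metabolite) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_rejected = sum(.data$rejected),
      pct_rejected = 100 * mean(.data$rejected),
      .groups = "drop"
    )
  list(data = out, report = report)
}

#' Measure lesion volume by intensity thresholding
#'
#' Counts voxels at or above an intensity threshold and converts the count
#' to cm^3. When no threshold is given it is taken from the image's
#' `threshold` attribute if present, otherwise estimated robustly as
#' `median + 3 * MAD` of the intensities (a simple stand-in for a
#' semi-automated threshold choice).
#'
#' @param image Numeric array of intensities.
#' @param threshold Intensity threshold; voxels with intensity
#'   `>= threshold` count as lesion.
#' @param voxel_volume_mm3 Volume of one voxel in mm^3 (taken from the
#'   image attribute if absent).
#' @return Lesion volume in cm^3.
#' @export
measure_lesion_volume <- function(image, threshold = NULL, voxel_volume_mm3 = NULL) {
  if (length(image) == 0) {
    rlang::abort("Empty image", class = "ponsmrsi_validation_error")
  }
  threshold <- threshold %||% attr(image, "threshold") %||%
    (stats::median(image) + 3 * stats::mad(image))
  voxel_volume_mm3 <- voxel_volume_mm3 %||% attr(image, "voxel_volume_mm3") %||% 1
  if (!is.finite(threshold)) {
    rlang::abort("`threshold` must be finite", class = "ponsmrsi_validation_error")
  }
  if (voxel_volume_mm3 <= 0) {
    rlang::abort("`voxel_volume_mm3` must be > 0", class = "ponsmrsi_validation_error")
  }
  sum(image >= threshold) * voxel_volume_mm3 / 1000
}

#' Compute per-voxel composition metrics and corrected amplitudes
#'
#' The metrics stage of the pipeline: derives `pct_gm`, `pct_wm` and
#' `pct_csf` from tissue volumes or fractions, applies CRLB quality
#' control, and CSF-corrects the surviving amplitudes into `naa_corr` and
#' `tcr_corr`.
#'
#' Tissue composition is accepted either as volume columns `gm`, `wm`,
#' `csf` (arbitrary common unit) or as whole-voxel fraction columns
#' `f_gm`, `f_wm`, `f_csf`; fractions must sum to 1 within 0.01 per voxel
#' and are renormalised.
#'
#' @param cohort Tidy cohort table (see [simulate_cohort()] /
#'   [read_cohort()]).
#' @param crlb_max_pct CRLB rejection threshold in percent.
#' @return List with `data` (input plus `pct_gm`, `pct_wm`, `pct_csf`,
#'   `naa_ok`, `tcr_ok`, `naa_corr`, `tcr_corr`) and `qc_report`.
#' @export
apply_metrics <- function(cohort, crlb_max_pct = 20) {
  has_vol <- all(c("gm", "wm", "csf") %in% names(cohort))
  has_frac <- all(c("f_gm", "f_wm", "f_csf") %in% names(cohort))
  if (!has_vol && !has_frac) {
    rlang::abort(
      "Cohort needs tissue volumes (gm, wm, csf) or fractions (f_gm, f_wm, f_csf)",
      class = "ponsmrsi_validation_error"
    )
  }
  if (has_frac && !has_vol) {
    tot <- cohort$f_gm + cohort$f_wm + cohort$f_csf
    bad <- abs(tot - 1) > 0.01
    if (any(bad)) {
      rlang::abort(
        sprintf(
          "Tissue fractions must sum to 1 +/- 0.01; %d row(s) violate this (first: row %d, sum %.3f)",
          sum(bad), which(bad)[1], tot[which(bad)[1]]
        ),
        class = "ponsmrsi_validation_error"
      )
    }
    gm <- cohort$f_gm / tot
    wm <- cohort$f_wm / tot
    csf <- cohort$f_csf / tot
  } else {
    gm <- cohort$gm
    wm <- cohort$wm
    csf <- cohort$csf
  }

  out <- cohort
  out$pct_gm <- pct_gm(gm, wm)
  out$pct_wm <- 100 - out$pct_gm
  out$pct_csf <- pct_csf(gm, wm, csf)

  qc <- qc_filter(out, crlb_max_pct = crlb_max_pct)
  out <- qc$data
  out$naa_corr <- csf_correct(out$naa, out$pct_csf)
  out$tcr_corr <- csf_correct(out$tcr, out$pct_csf)
  list(data = out, qc_report = qc$report)
}
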