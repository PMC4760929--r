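# Fixed voxel vocabulary of the 16-voxel CSI selection: six voxels in the
# right pons (R1-R6), six in the left pons (L1-L6) and four cerebellar
# reference voxels (C1-C4). Row semantics follow the %GM gradient: row 6 is
# the most WM-rich pons row (~12% GM), row 1 the most GM-rich (~63% GM),
# and the cerebellar row is predominantly GM (~90%).

pons_voxels <- function() {
  c(paste0("R", 6:1), paste0("L", 6:1))
}

cerebellar_voxels <- function() {
  paste0("C", 1:4)
}

#' Voxel vocabulary of the pontine CSI grid
#'
#' @return Character vector of the 16 valid voxel labels
#'   (`R1`--`R6`, `L1`--`L6`, `C1`--`C4`).
#' @export
voxel_labels <- function() {
  c(paste0("R", 1:6), paste0("L", 1:6), paste0("C", 1:4))
}

voxel_region <- function(voxel) {
  ifelse(substr(voxel, 1, 1) == "C", "cerebellum", "pons")
}

# Layout row of each voxel in the CSI grid figure: rows 6/5, 4/3, 2/1 in the
# pons plus the cerebellar row ("Cb"). Used for gradient checks and reports.
voxel_row <- function(voxel) {
  num <- suppressWarnings(as.integer(substr(voxel, 2, 2)))
  ifelse(substr(voxel, 1, 1) == "C", "Cb",
    ifelse(num >= 5, "row56", ifelse(num >= 3, "row34", "row12"))
  )
}

#' Default per-voxel gray-matter profile
#'
#' Mean and SD of percent gray matter (of brain tissue, GM/(GM+WM)) for each
#' of the 16 voxels, taken from the control-group tissue composition of the
#' pontine CSI layout: ~12% GM in the rostral WM-rich pons rows, ~33% and
#' ~63% in the middle and caudal rows, ~90% in the cerebellum.
#'
#' @return A tibble with columns `voxel`, `region`, `pct_gm_mean`,
#'   `pct_gm_sd`.
#' @export
default_tissue_profile <- function() {
  tibble::tibble(
    voxel = c(
      "R6", "R5", "L5", "L6",
      "R4", "R3", "L3", "L4",
      "R2", "R1", "L1", "L2",
      "C1", "C2", "C3", "C4"
    ),
    pct_gm_mean = c(
      12.3, 14.3, 13.1, 12.4,
      31.3, 34.9, 34.3, 36.5,
      62.6, 63.6, 60.3, 67.2,
      90.0, 94.3, 93.9, 90.7
    ),
    pct_gm_sd = c(
      5.7, 6.6, 6.8, 4.9,
      7.8, 7.0, 9.1, 10.3,
      8.9, 9.1, 8.7, 11.2,
      8.3, 4.0, 5.2, 7.8
    )
  ) |>
    dplyr::mutate(region = voxel_region(.data$voxel), .after = "voxel")
}
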