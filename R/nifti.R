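# Optional NIfTI entry points: tissue-probability maps and lesion images
# are converted into the tabular quantities the statistical core consumes.
# RNifti is only needed when these readers are used.

require_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    rlang::abort("The RNifti package is required for NIfTI input",
      class = "ponsmrsi_validation_error"
    )
  }
}

#' Tissue volumes per CSI voxel from segmentation probability maps
#'
#' Sums gray/white/CSF probability over the image block covered by each
#' CSI voxel, yielding the tissue volumes that enter the %GM and %CSF
#' computations. Blocks are axis-aligned index ranges (inclusive, 1-based)
#' in the maps' voxel grid — the CSI grid is assumed to have been aligned
#' to the structural image upstream. Volumes are reported in mm^3 using
#' the voxel dimensions from the NIfTI header.
#'
#' @param gm_map,wm_map,csf_map Paths to NIfTI probability maps (or arrays
#'   already read with `RNifti::readNifti()`), identical dimensions.
#' @param blocks Data frame with columns `voxel` and inclusive index
#'   bounds `i0`, `i1`, `j0`, `j1`, `k0`, `k1`.
#' @return Tibble with columns `voxel`, `region`, `gm`, `wm`, `csf`
#'   (mm^3), ready for [apply_metrics()] after joining amplitudes.
#' @export
nifti_tissue_volumes <- function(gm_map, wm_map, csf_map, blocks) {
  require_rnifti()
  read1 <- function(x) if (is.character(x)) RNifti::readNifti(x) else x
  gm <- read1(gm_map)
  wm <- read1(wm_map)
  csf <- read1(csf_map)
  if (!all(dim(gm) == dim(wm)) || !all(dim(gm) == dim(csf))) {
    rlang::abort("Probability maps must share dimensions",
      class = "ponsmrsi_validation_error"
    )
  }
  need <- c("voxel", "i0", "i1", "j0", "j1", "k0", "k1")
  if (!all(need %in% names(blocks))) {
    rlang::abort(paste("`blocks` must have columns", paste(need, collapse = ", ")),
      class = "ponsmrsi_validation_error"
    )
  }
  pd <- tryCatch(RNifti::pixdim(gm)[1:3], error = function(e) c(1, 1, 1))
  vox_mm3 <- prod(abs(pd))
  sum_block <- function(img, b) {
    sum(img[b$i0:b$i1, b$j0:b$j1, b$k0:b$k1])
  }
  purrr::map_dfr(seq_len(nrow(blocks)), function(r) {
    b <- blocks[r, ]
    tibble::tibble(
      voxel = b$voxel,
      region = voxel_region(b$voxel),
      gm = sum_block(gm, b) * vox_mm3,
      wm = sum_block(wm, b) * vox_mm3,
      csf = sum_block(csf, b) * vox_mm3
    )
  })
}

#' Read a lesion intensity image from NIfTI
#'
#' Loads the image and attaches the voxel volume from the header so that
#' [measure_lesion_volume()] reports cm^3 directly.
#'
#' @param path NIfTI file path.
#' @return Numeric array with a `voxel_volume_mm3` attribute.
#' @export
read_lesion_image <- function(path) {
  require_rnifti()
  img <- RNifti::readNifti(path)
  pd <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_volume_mm3") <- prod(abs(pd))
  out
}
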