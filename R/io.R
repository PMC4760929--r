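# Tidy interchange CSV: one row per subject x voxel. All pipeline stages
# read and write this schema; NIfTI maps or simulated spectra are converted
# into it upstream of the statistical core.

cohort_schema <- function() {
  c(
    "subject_id", "group", "age", "fss", "edss", "lesion_volume_cm3",
    "voxel", "region", "f_gm", "f_wm", "f_csf",
    "naa", "naa_crlb_pct", "tcr", "tcr_crlb_pct"
  )
}

provenance_header <- function(seed = NULL, config = NULL) {
  c(
    paste0("# ponsmrsi ", pkg_version()),
    paste0("# generated ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(seed)) paste0("# seed ", seed),
    if (!is.null(config)) paste0("# config_hash ", rlang::hash(config))
  )
}

#' Write a cohort table (or any pipeline table) as CSV
#'
#' Prepends a provenance header (`#`-prefixed: package version, timestamp,
#' seed, configuration hash) that [read_cohort()] and standard CSV readers
#' skip as comments.
#'
#' @param data Tibble to write.
#' @param path Output path.
#' @param seed,config Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, seed = NULL, config = NULL) {
  writeLines(provenance_header(seed, config), path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and validate a tidy cohort CSV
#'
#' Parses the interchange schema and aggregates every validation problem
#' (missing columns, unknown voxel labels, non-numeric fields, duplicate
#' subject x voxel rows, region/label mismatches) into a single error that
#' reports row numbers.
#'
#' @param path CSV path (UTF-8, `.` decimal; `#` lines are comments).
#' @return Validated tibble in the cohort schema.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      voxel = readr::col_character(),
      region = readr::col_character(),
      .default = readr::col_double()
    )
  )
  p <- list()
  missing_cols <- setdiff(cohort_schema(), names(raw))
  if (length(missing_cols) > 0) {
    p$cols <- paste("Missing columns:", paste(missing_cols, collapse = ", "))
    abort_invalid(p, paste0("cohort file '", path, "'"), class = "ponsmrsi_schema_error")
  }

  bad_voxel <- which(!raw$voxel %in% voxel_labels())
  if (length(bad_voxel) > 0) {
    p$voxel <- paste0(
      "Invalid voxel label(s) ",
      paste(unique(raw$voxel[bad_voxel]), collapse = ", "),
      " at row(s) ", paste(utils::head(bad_voxel, 10), collapse = ", ")
    )
  }
  bad_group <- which(!raw$group %in% group_levels())
  if (length(bad_group) > 0) {
    p$group <- paste0(
      "Invalid group label(s) ",
      paste(unique(raw$group[bad_group]), collapse = ", "),
      " at row(s) ", paste(utils::head(bad_group, 10), collapse = ", ")
    )
  }
  key <- paste(raw$subject_id, raw$voxel)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    p$dup <- paste0(
      "Duplicate subject x voxel rows at row(s) ",
      paste(utils::head(dup, 10), collapse = ", ")
    )
  }
  num_cols <- setdiff(cohort_schema(), c("subject_id", "group", "voxel", "region"))
  for (cl in num_cols) {
    if (!is.numeric(raw[[cl]])) {
      p[[cl]] <- paste0("Column '", cl, "' is not numeric")
    }
  }
  exp_region <- voxel_region(raw$voxel)
  bad_region <- which(!is.na(raw$region) & raw$region != exp_region & raw$voxel %in% voxel_labels())
  if (length(bad_region) > 0) {
    p$region <- paste0(
      "Region does not match voxel label at row(s) ",
      paste(utils::head(bad_region, 10), collapse = ", ")
    )
  }
  abort_invalid(p, paste0("cohort file '", path, "'"), class = "ponsmrsi_schema_error")
  raw[, cohort_schema()]
}
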