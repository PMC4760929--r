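#' Classify fatigue status from an FSS score
#'
#' The Fatigue Severity Scale total ranges from 9 to 63; scores strictly
#' greater than 36 indicate clinically relevant fatigue.
#'
#' @param fss Numeric score(s) in \[9, 63\].
#' @return `"high"` where `fss > 36`, else `"low"`.
#' @export
classify_fatigue <- function(fss) {
  if (any(is.na(fss)) || any(fss < 9 | fss > 63)) {
    rlang::abort("FSS scores must lie in [9, 63]", class = "ponsmrsi_validation_error")
  }
  ifelse(fss > 36, "high", "low")
}

#' Covariate-adjusted group comparison for one voxel
#'
#' Fits `outcome ~ group + covariates` by ordinary least squares (an
#' ANCOVA with percent gray matter -- and optionally age -- as covariate)
#' on available cases, and reports the omnibus group F-test plus pairwise
#' contrasts of each patient group against control and between the two
#' patient groups, all sharing the single covariate-adjusted error term of
#' the full three-group model. Adjusted group means are evaluated at the
#' covariate sample means. A covariate with no variation is dropped with a
#' warning, falling back to a plain one-way comparison.
#'
#' @param data One voxel's rows: columns `group`, the outcome, and the
#'   covariates.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate columns (default
#'   `"pct_gm"`).
#' @return List with `omnibus_p`, `contrasts` (tibble: contrast, estimate,
#'   se, df, p), `adjusted_means` (tibble: group, mean, n) and the fitted
#'   `model`.
#' @export
ancova_voxel <- function(data, outcome, covariates = "pct_gm") {
  df <- data[stats::complete.cases(data[, c("group", outcome, covariates)]), , drop = FALSE]
  df$group <- factor(df$group, levels = intersect(group_levels(), unique(df$group)))
  counts <- table(df$group)
  if (length(counts) < 2 || any(counts < 3)) {
    rlang::abort("Need >= 2 groups with >= 3 subjects each",
      class = "ponsmrsi_validation_error"
    )
  }
  keep <- covariates[vapply(covariates, function(v) stats::var(df[[v]]) > 0, logical(1))]
  if (length(keep) < length(covariates)) {
    rlang::warn(paste(
      "Dropping constant covariate(s):",
      paste(setdiff(covariates, keep), collapse = ", ")
    ))
  }
  rhs <- paste(c("group", keep), collapse = " + ")
  full <- stats::lm(stats::reformulate(c("group", keep), response = outcome), data = df)
  reduced <- stats::lm(stats::reformulate(if (length(keep)) keep else "1", response = outcome), data = df)
  omnibus_p <- stats::anova(reduced, full)[2, "Pr(>F)"]

  beta <- stats::coef(full)
  vc <- stats::vcov(full)
  rdf <- full$df.residual
  lv <- levels(df$group)

  contrast_row <- function(label, cvec) {
    est <- drop(cvec %*% beta)
    se <- sqrt(drop(t(cvec) %*% vc %*% cvec))
    tval <- est / se
    tibble::tibble(
      contrast = label, estimate = est, se = se, df = rdf,
      p = 2 * stats::pt(-abs(tval), rdf)
    )
  }
  cname <- function(g) paste0("group", g)
  unit <- function(g) {
    v <- rep(0, length(beta))
    names(v) <- names(beta)
    if (g != lv[1]) v[cname(g)] <- 1
    v
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  contrasts <- dplyr::bind_rows(purrr::map(pairs, function(pr) {
    contrast_row(paste(pr[2], "-", pr[1]), unit(pr[2]) - unit(pr[1]))
  }))

  cov_means <- vapply(keep, function(v) mean(df[[v]]), numeric(1))
  adj_mean <- function(g) {
    v <- unit(g)
    v["(Intercept)"] <- 1
    if (length(keep)) v[keep] <- cov_means
    drop(v %*% beta)
  }
  adjusted_means <- tibble::tibble(
    group = lv,
    mean = unname(vapply(lv, adj_mean, numeric(1))),
    n = as.integer(counts[lv])
  )
  list(
    omnibus_p = omnibus_p, contrasts = contrasts,
    adjusted_means = adjusted_means, model = full
  )
}

#' Per-voxel group comparisons across the pons with FDR control
#'
#' Runs [ancova_voxel()] for every pons voxel and outcome, then adjusts
#' the pairwise contrast p-values by Benjamini-Hochberg within each
#' outcome x contrast family of the 12 pons voxels (cerebellar voxels are
#' reference-only and excluded from the family). Significance flags derive
#' from the adjusted p-values only.
#'
#' @param ratios Ratio table from [compute_ratios()].
#' @param outcomes Outcome columns to compare.
#' @param covariates Covariates for the ANCOVA (default `"pct_gm"`; add
#'   `"age"` to reproduce the age-adjusted sensitivity analysis).
#' @param fdr_level Significance level applied to FDR-adjusted p-values.
#' @return Tibble: one row per voxel x outcome x contrast with `estimate`,
#'   `raw_p`, `fdr_p`, `significant`, plus the omnibus p and adjusted
#'   group means (list column).
#' @export
compare_groups <- function(ratios,
                           outcomes = c("naa_tcr", "naa_over_naa_cb", "tcr_over_tcr_cb"),
                           covariates = "pct_gm",
                           fdr_level = 0.05) {
  pons <- ratios[ratios$region == "pons", , drop = FALSE]
  res <- purrr::map_dfr(outcomes, function(oc) {
    purrr::map_dfr(unique(pons$voxel), function(vx) {
      d <- pons[pons$voxel == vx, , drop = FALSE]
      av <- tryCatch(ancova_voxel(d, oc, covariates), error = function(e) NULL)
      if (is.null(av)) {
        return(tibble::tibble())
      }
      av$contrasts |>
        dplyr::transmute(
          voxel = vx, outcome = oc, contrast = .data$contrast,
          estimate = .data$estimate, raw_p = .data$p,
          omnibus_p = av$omnibus_p,
          adjusted_means = list(av$adjusted_means)
        )
    })
  })
  if (nrow(res) == 0) {
    return(res)
  }
  res |>
    dplyr::group_by(.data$outcome, .data$contrast) |>
    dplyr::mutate(fdr_p = fdr_adjust(.data$raw_p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$fdr_p < fdr_level)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1; invariant to the
#' order of the input vector.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    rlang::abort("p-values must lie in [0, 1]", class = "ponsmrsi_validation_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When both samples have at most 8 observations
#' the null distribution of U is obtained by full enumeration of all
#' group assignments of the pooled mid-ranks (exact even under ties);
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric samples (nonempty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   chooses by sample size.
#' @return List with `U` (statistic for sample `a`), `p` (two-sided) and
#'   `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) {
    rlang::abort("Both samples must be nonempty", class = "ponsmrsi_validation_error")
  }
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- exact %||% (max(n1, n2) <= 8)

  if (exact) {
    idx <- utils::combn(n1 + n2, n1)
    r1 <- colSums(matrix(r[idx], nrow = n1))
    u_all <- r1 - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
    return(list(U = u_obs, p = min(p, 1), method = "exact enumeration"))
  }

  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) { # all observations tied: no evidence either way
    return(list(U = u_obs, p = 1, method = "normal approximation with tie correction"))
  }
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  list(
    U = u_obs, p = min(2 * stats::pnorm(-abs(z)), 1),
    method = "normal approximation with tie correction"
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-transform p-value; used to
#' relate MRS ratios to age and fatigue scores to disability and lesion
#' load.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs, nonzero
#'   variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    rlang::abort("Need >= 3 paired observations", class = "ponsmrsi_validation_error")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::abort("Zero variance in input", class = "ponsmrsi_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
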