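test_that("fatigue classification uses the strict >36 cutoff", {
  expect_equal(classify_fatigue(36), "low")
  expect_equal(classify_fatigue(36.01), "high")
  expect_equal(classify_fatigue(c(11, 52)), c("low", "high"))
  expect_error(classify_fatigue(8), class = "ponsmrsi_validation_error")
  expect_error(classify_fatigue(64), class = "ponsmrsi_validation_error")
})

# Fixed three-group fixture (n = 6 per group) for the ANCOVA oracle.
ancova_fixture <- function() {
  tibble::tibble(
    group = rep(c("control", "low_fatigue", "high_fatigue"), each = 6),
    pct_gm = c(
      12, 18, 25, 33, 41, 52,
      14, 20, 27, 35, 44, 50,
      11, 19, 24, 36, 42, 55
    ),
    y = c(
      2.61, 2.43, 2.30, 2.11, 1.95, 1.74,
      2.52, 2.38, 2.24, 2.06, 1.88, 1.79,
      2.30, 2.15, 2.08, 1.85, 1.72, 1.48
    )
  )
}

test_that("ANCOVA contrasts match a from-scratch normal-equations computation", {
  d <- ancova_fixture()
  res <- ancova_voxel(d, "y", covariates = "pct_gm")

  # independent oracle: explicit design matrix and projection computations
  g <- factor(d$group, levels = c("control", "low_fatigue", "high_fatigue"))
  X <- cbind(1, g == "low_fatigue", g == "high_fatigue", d$pct_gm)
  storage.mode(X) <- "double"
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% d$y
  resid <- d$y - X %*% beta
  rdf <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / rdf
  cvec <- c(0, 0, 1, 0) # high_fatigue - control
  tval <- (t(cvec) %*% beta) / sqrt(s2 * t(cvec) %*% XtXi %*% cvec)
  p_oracle <- 2 * pt(-abs(drop(tval)), rdf)

  got <- res$contrasts[res$contrasts$contrast == "high_fatigue - control", ]
  expect_equal(got$p, p_oracle, tolerance = 1e-10)
  expect_equal(got$estimate, drop(t(cvec) %*% beta), tolerance = 1e-10)
})

test_that("identical groups give null contrasts and a perfect covariate zero effect", {
  d <- ancova_fixture()
  d2 <- d
  d2$y[d2$group == "low_fatigue"] <- d2$y[d2$group == "control"]
  d2$pct_gm[d2$group == "low_fatigue"] <- d2$pct_gm[d2$group == "control"]
  res <- ancova_voxel(d2[d2$group != "high_fatigue", ], "y", covariates = "pct_gm")
  ct <- res$contrasts[res$contrasts$contrast == "low_fatigue - control", ]
  expect_lt(abs(ct$estimate), 1e-12)
  expect_equal(diff(res$adjusted_means$mean), 0, tolerance = 1e-12)

  # outcome exactly linear in the covariate with equal intercepts
  d3 <- d
  d3$y <- 3 - 0.02 * d3$pct_gm
  res3 <- suppressWarnings(ancova_voxel(d3, "y", covariates = "pct_gm"))
  expect_lt(max(abs(res3$contrasts$estimate)), 1e-12)
})

test_that("a constant covariate falls back to a one-way comparison with a warning", {
  d <- ancova_fixture()
  d$pct_gm <- 30
  expect_warning(res <- ancova_voxel(d, "y", covariates = "pct_gm"), "constant covariate")
  oneway <- anova(lm(y ~ factor(group, levels = unique(group)), data = d))
  expect_equal(res$omnibus_p, oneway[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("BH adjustment matches the manual step-up computation", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))

  p <- c(0.003, 0.04, 0.2, 0.01, 0.8, 0.05)
  manual <- {
    o <- order(p)
    m <- length(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  expect_equal(fdr_adjust(p), manual, tolerance = 1e-12)
  # order invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(fdr_adjust(p[perm]), manual[perm], tolerance = 1e-12)
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "ponsmrsi_validation_error")
})

test_that("Mann-Whitney exact p matches enumeration and wilcox.test", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)

  mw_id <- mann_whitney(c(5, 5, 7), c(5, 5, 7))
  expect_equal(mw_id$p, 1)

  set.seed(4)
  a <- rnorm(6)
  b <- rnorm(8) + 0.8
  ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
  got <- mann_whitney(a, b)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  # large-sample path agrees with the normal approximation in wilcox.test
  set.seed(9)
  a2 <- rnorm(15)
  b2 <- rnorm(12) + 0.5
  ref2 <- wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
  got2 <- mann_whitney(a2, b2)
  expect_equal(got2$p, ref2$p.value, tolerance = 1e-10)
  expect_match(got2$method, "normal approximation")

  expect_error(mann_whitney(numeric(0), 1), class = "ponsmrsi_validation_error")
})

test_that("group ages from overlapping distributions are usually non-significant", {
  # At these group sizes the configured age overlap leaves the comparison
  # underpowered, so most simulated cohorts show no significant age
  # difference (the exact-Wilcoxon rate under these distributions is ~64%).
  hits <- vapply(1:40, function(s) {
    sim <- simulate_cohort(cohort_config(seed = 300 + s))
    subj <- unique(sim$cohort[, c("subject_id", "group", "age")])
    mw <- mann_whitney(
      subj$age[subj$group == "high_fatigue"],
      subj$age[subj$group == "low_fatigue"]
    )
    mw$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.5)
  y <- c(2.0, 2.9, 4.2, 5.1, 6.9)
  got <- pearson_corr(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_manual <- r_manual * sqrt(3 / (1 - r_manual^2))
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 3), tolerance = 1e-12)

  expect_equal(pearson_corr(1:10, 2 * (1:10))$r, 1)
  expect_error(pearson_corr(1:5, rep(1, 5)), class = "ponsmrsi_validation_error")
  expect_error(pearson_corr(1:2, 1:2), class = "ponsmrsi_validation_error")
})

test_that("compare_groups restricts the FDR family to the 12 pons voxels", {
  out <- simulate_ratios(cohort_config(seed = 121))
  cmp <- compare_groups(out$ratios)
  expect_setequal(unique(cmp$voxel), setdiff(voxel_labels(), paste0("C", 1:4)))
  fam <- cmp[cmp$outcome == "naa_tcr" & cmp$contrast == "high_fatigue - control", ]
  expect_equal(nrow(fam), 12)
  expect_equal(fam$fdr_p, fdr_adjust(fam$raw_p), tolerance = 1e-12)
  expect_true(all(fam$fdr_p >= fam$raw_p))
  expect_equal(cmp$significant, cmp$fdr_p < 0.05)
})
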