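test_that("NAA/tCr handles missing and non-positive denominators as missing", {
  expect_equal(naa_tcr_ratio(2, 2), 1)
  expect_equal(naa_tcr_ratio(c(2, 1, 3), c(1, NA, 0)), c(2, NA, NA))
})

test_that("cerebellar normalisation divides by the subject's mean C-voxel value", {
  d <- tibble::tibble(
    subject_id = "S1",
    voxel = c("L4", paste0("C", 1:4)),
    region = c("pons", rep("cerebellum", 4)),
    naa_corr = c(2.4, 1, 1, 1, 1),
    tcr_corr = c(1.2, 1.0, 1.0, 1.4, 1.4)
  )
  out <- cerebellar_normalize(d)
  expect_equal(out$naa_over_naa_cb[out$voxel == "L4"], 2.4)
  expect_equal(out$tcr_over_tcr_cb[out$voxel == "L4"], 1.0) # mean reference 1.2
  expect_true(all(is.na(out$naa_over_naa_cb[out$region == "cerebellum"])))
})

test_that("normalised ratios are invariant to a global per-subject scale", {
  sim <- simulate_cohort(small_config(seed = 51))
  m <- apply_metrics(sim$cohort)$data
  r1 <- cerebellar_normalize(m)
  m2 <- m
  m2$naa_corr <- m2$naa_corr * 3.7
  m2$tcr_corr <- m2$tcr_corr * 3.7
  r2 <- cerebellar_normalize(m2)
  expect_equal(r2$naa_over_naa_cb, r1$naa_over_naa_cb, tolerance = 1e-12)
  expect_equal(r2$tcr_over_tcr_cb, r1$tcr_over_tcr_cb, tolerance = 1e-12)
})

test_that("subjects with no surviving cerebellar reference get missing ratios", {
  d <- tibble::tibble(
    subject_id = rep(c("S1", "S2"), each = 5),
    voxel = rep(c("L4", paste0("C", 1:4)), 2),
    region = rep(c("pons", rep("cerebellum", 4)), 2),
    naa_corr = c(2.4, 1, 1, 1, 1, 2.0, NA, NA, NA, NA),
    tcr_corr = c(1.2, 1, 1, 1, 1, 1.0, NA, NA, NA, NA)
  )
  expect_warning(out <- cerebellar_normalize(d), "S2")
  expect_true(is.na(out$naa_over_naa_cb[out$subject_id == "S2" & out$voxel == "L4"]))
  expect_false(is.na(out$naa_over_naa_cb[out$subject_id == "S1" & out$voxel == "L4"]))
})

test_that("percent change matches its defining formula", {
  expect_equal(percent_change(0.75, 0.60), 25)
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(0.67, 0.53, round_to = 0), 26)
  expect_error(percent_change(1, 0), class = "ponsmrsi_validation_error")
})

test_that("noiseless composition fit recovers the pure-tissue ratios exactly", {
  cfg <- noiseless_config(seed = 61)
  out <- simulate_ratios(cfg)
  fit <- composition_fit(out$ratios)
  truth_gm <- out$truth$pure_gm_ratio
  truth_wm <- out$truth$pure_wm_ratio
  for (i in seq_len(nrow(fit$fits))) {
    expect_lt(abs(fit$fits$gm_est[i] - truth_gm) / truth_gm, 1e-6)
    expect_lt(abs(fit$fits$wm_est[i] - truth_wm) / truth_wm, 1e-6)
  }
})

test_that("ratio decreases with %GM on noiseless data (WM-dominant NAA/tCr)", {
  cfg <- noiseless_config(seed = 71)
  out <- simulate_ratios(cfg)
  d <- out$ratios[order(out$ratios$f_wm_tissue), ]
  expect_true(all(diff(d$naa_tcr) >= -1e-12))
})

test_that("group curves converge toward GM-rich compositions when GM pools are shared", {
  em <- effect_map(group = "high_fatigue", voxel = c("L4", "R6"), metabolite = "tcr", effect = 1.25)
  cfg <- noiseless_config(effects = em, seed = 81)
  out <- simulate_ratios(cfg)
  fit <- composition_fit(out$ratios)
  gm_ests <- fit$fits$gm_est
  expect_lt(max(gm_ests) - min(gm_ests), 0.02 * mean(gm_ests))
})

test_that("an injected WM-tCr effect depresses the HF pure-WM NAA/tCr endpoint", {
  # effect in every WM-rich voxel so the pure-WM projection sees it
  em <- effect_map(
    group = "high_fatigue", voxel = c("R6", "R5", "L5", "L6"),
    metabolite = "tcr", effect = 1.25
  )
  cfg <- noiseless_config(effects = em, seed = 91)
  out <- simulate_ratios(cfg)
  fit <- composition_fit(out$ratios)
  ctrl <- fit$fits$wm_est[fit$fits$group == "control"]
  hf <- fit$fits$wm_est[fit$fits$group == "high_fatigue"]
  expect_lt(abs(hf - ctrl / 1.25) / (ctrl / 1.25), 0.05)
})

test_that("composition fit refuses insufficient composition spread", {
  d <- tibble::tibble(
    subject_id = rep("S1", 4), group = "control",
    f_wm_tissue = c(0.50, 0.51, 0.52, 0.53), naa_tcr = c(2, 2.1, 2, 2.2)
  )
  expect_error(composition_fit(d), class = "ponsmrsi_fit_error")
})

test_that("bootstrap endpoint contrast flags a strong noiseless group difference", {
  em <- effect_map(
    group = "high_fatigue", voxel = paste0(rep(c("R", "L"), each = 6), 1:6),
    metabolite = "tcr", effect = 1.25
  )
  cfg <- cohort_config(
    effects = em, noise_sd = 0.02, conc_cv = 0.05,
    subject_scale_cv = 0, seed = 101
  )
  out <- simulate_ratios(cfg)
  fit <- composition_fit(out$ratios, boot = 200, seed = 5)
  wm <- fit$contrasts[fit$contrasts$endpoint == "pure_wm" &
    fit$contrasts$contrast == "high_fatigue - control", ]
  expect_lt(wm$diff, 0)
  expect_lt(wm$p_boot, 0.05)
})
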