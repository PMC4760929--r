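test_that("cohort has the 16-voxel structure and is reproducible", {
  cfg <- cohort_config(seed = 7)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$cohort), 32 * 16)
  expect_equal(length(unique(sim$cohort$subject_id)), 32)
  per_subject <- table(sim$cohort$subject_id)
  expect_true(all(per_subject == 16))
  expect_setequal(unique(sim$cohort$voxel), voxel_labels())

  sim2 <- simulate_cohort(cohort_config(seed = 7))
  expect_identical(sim, sim2)
  sim3 <- simulate_cohort(cohort_config(seed = 8))
  expect_false(identical(sim$cohort$naa, sim3$cohort$naa))
})

test_that("true tissue fractions sum to one and %GM tracks the profile", {
  cfg <- cohort_config(seed = 2)
  sim <- simulate_cohort(cfg)
  tot <- sim$truth$voxels$f_gm + sim$truth$voxels$f_wm + sim$truth$voxels$f_csf
  expect_true(all(abs(tot - 1) < 1e-9))

  tp <- default_tissue_profile()
  obs_gm <- 100 * sim$cohort$f_gm / (sim$cohort$f_gm + sim$cohort$f_wm)
  for (v in c("R6", "L4", "R1", "C2")) {
    mu <- tp$pct_gm_mean[tp$voxel == v]
    sd <- tp$pct_gm_sd[tp$voxel == v]
    got <- mean(obs_gm[sim$cohort$voxel == v])
    # truncation at [0, 100] shifts the mean slightly; allow 4 SEs + 1.5
    expect_lt(abs(got - mu), 4 * sd / sqrt(32) + 1.5)
  }
})

test_that("mean %GM increases along the row gradient toward the cerebellum", {
  sim <- simulate_cohort(cohort_config(seed = 3))
  gm <- 100 * sim$cohort$f_gm / (sim$cohort$f_gm + sim$cohort$f_wm)
  row_of <- function(v) {
    n <- suppressWarnings(as.integer(substr(v, 2, 2)))
    ifelse(substr(v, 1, 1) == "C", 0L, n)
  }
  rows <- row_of(sim$cohort$voxel)
  means <- c(
    mean(gm[rows %in% 5:6]), mean(gm[rows %in% 3:4]),
    mean(gm[rows %in% 1:2]), mean(gm[rows == 0])
  )
  expect_true(all(diff(means) > 0))
})

test_that("noiseless amplitudes follow the tissue-mixture dilution model exactly", {
  cfg <- noiseless_config(n_control = 3, n_low_fatigue = 1, n_high_fatigue = 1, seed = 5)
  sim <- simulate_cohort(cfg)
  g <- sim$cohort$f_gm / (sim$cohort$f_gm + sim$cohort$f_wm)
  expected_ratio <- (g * cfg$gm_conc["naa"] + (1 - g) * cfg$wm_conc["naa"]) /
    (g * cfg$gm_conc["tcr"] + (1 - g) * cfg$wm_conc["tcr"])
  expect_equal(sim$cohort$naa / sim$cohort$tcr, unname(expected_ratio), tolerance = 1e-12)
  # CSF dilution is exact: S0 = mixture * (1 - fCSF)
  mix_naa <- g * cfg$gm_conc["naa"] + (1 - g) * cfg$wm_conc["naa"]
  expect_equal(sim$cohort$naa, unname(mix_naa * (1 - sim$cohort$f_csf)), tolerance = 1e-12)
})

test_that("an injected multiplicative effect scales the targeted voxel exactly", {
  em <- effect_map(group = "high_fatigue", voxel = "L4", metabolite = "tcr", effect = 1.25)
  cfg <- noiseless_config(effects = em, seed = 11)
  sim <- simulate_cohort(cfg)
  d <- sim$cohort[sim$cohort$voxel == "L4", ]
  g <- d$f_gm / (d$f_gm + d$f_wm)
  base <- (g * cfg$gm_conc["tcr"] + (1 - g) * cfg$wm_conc["tcr"]) * (1 - d$f_csf)
  mult <- ifelse(d$group == "high_fatigue", 1.25, 1)
  expect_equal(d$tcr, unname(base * mult), tolerance = 1e-12)
  # untargeted metabolite and voxels untouched
  d2 <- sim$cohort[sim$cohort$voxel == "R6", ]
  g2 <- d2$f_gm / (d2$f_gm + d2$f_wm)
  base2 <- (g2 * cfg$gm_conc["tcr"] + (1 - g2) * cfg$wm_conc["tcr"]) * (1 - d2$f_csf)
  expect_equal(d2$tcr, unname(base2), tolerance = 1e-12)
})

test_that("invalid configurations are rejected with all offending fields named", {
  err <- tryCatch(
    cohort_config(n_control = 0, noise_sd = -1, wm_conc = c(naa = -2, tcr = 1)),
    error = function(e) e
  )
  expect_s3_class(err, "ponsmrsi_config_error")
  msg <- conditionMessage(err)
  expect_match(msg, "n_control")
  expect_match(msg, "noise_sd")
  expect_match(msg, "wm_conc")
  expect_error(
    cohort_config(effects = effect_map(effect = -1)),
    class = "ponsmrsi_config_error"
  )
})

test_that("FSS draws respect group ranges and the >36 fatigue cutoff", {
  cfg <- cohort_config()
  hi <- simulate_fss("high", cfg, n = 200, seed = 1)
  lo <- simulate_fss("low", cfg, n = 200, seed = 2)
  ct <- simulate_fss("control", cfg, n = 200, seed = 3)
  expect_true(all(hi >= 42 & hi <= 59))
  expect_true(all(lo >= 11 & lo <= 34))
  expect_true(all(ct >= 13 & ct <= 26))
  expect_true(all(hi > 36))
  expect_true(all(c(lo, ct) <= 36))
  expect_error(simulate_fss("severe", cfg), class = "ponsmrsi_validation_error")

  # degenerate distribution collapses to the mean
  cfg0 <- cohort_config(clinical_params = local({
    cp <- default_clinical_params()
    cp$high_fatigue$fss["sd"] <- 0
    cp
  }))
  expect_equal(simulate_fss("high", cfg0, n = 5, seed = 1), rep(52, 5))
})

test_that("cohort FSS is consistent with classify_fatigue group membership", {
  sim <- simulate_cohort(cohort_config(seed = 9))
  subj <- unique(sim$cohort[, c("subject_id", "group", "fss")])
  cls <- classify_fatigue(subj$fss)
  expect_true(all(cls[subj$group == "high_fatigue"] == "high"))
  expect_true(all(cls[subj$group != "high_fatigue"] == "low"))
})

test_that("lesion maps round-trip through measure_lesion_volume", {
  img0 <- simulate_lesion_map(0, seed = 1)
  expect_equal(measure_lesion_volume(img0), 0)

  img <- simulate_lesion_map(2.0, shape = c(20, 20, 20), voxel_volume_mm3 = 1, seed = 4)
  expect_equal(sum(img >= attr(img, "threshold")), 2000)
  expect_equal(measure_lesion_volume(img), 2.0)

  img2 <- simulate_lesion_map(1.37, shape = c(30, 30, 30), voxel_volume_mm3 = 2, seed = 5)
  expect_lt(abs(measure_lesion_volume(img2) - 1.37), 2 / 1000 + 1e-12)

  expect_error(
    simulate_lesion_map(10, shape = c(5, 5, 5)),
    class = "ponsmrsi_validation_error"
  )
})

test_that("simulated clinical fields stay inside their configured ranges", {
  sim <- simulate_cohort(cohort_config(seed = 13))
  subj <- unique(sim$cohort[, c("subject_id", "group", "age", "edss", "lesion_volume_cm3")])
  ms <- subj[subj$group != "control", ]
  ctrl <- subj[subj$group == "control", ]
  expect_true(all(is.na(ctrl$edss)) && all(is.na(ctrl$lesion_volume_cm3)))
  expect_true(all(ms$edss >= 0 & ms$edss <= 10))
  expect_true(all(ms$edss %% 0.5 == 0))
  lf <- ms[ms$group == "low_fatigue", ]
  hf <- ms[ms$group == "high_fatigue", ]
  expect_true(all(lf$lesion_volume_cm3 >= 0.15 & lf$lesion_volume_cm3 <= 16.25))
  expect_true(all(hf$lesion_volume_cm3 >= 0.44 & hf$lesion_volume_cm3 <= 37.17))
})
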