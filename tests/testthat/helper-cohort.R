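# Shared fixtures: configs and a compact analysis wrapper used across tests.

# Fully deterministic generator: no measurement, biological or scale noise,
# no CRLB inflation.
noiseless_config <- function(...) {
  cohort_config(
    noise_sd = 0, conc_cv = 0, subject_scale_cv = 0,
    crlb_model = list(k = 2, inflate_prob = 0, inflate_range = c(1.5, 3)),
    ...
  )
}

# Small cohort for fast structural tests.
small_config <- function(...) {
  cohort_config(n_control = 4, n_low_fatigue = 3, n_high_fatigue = 3, ...)
}

# simulate -> metrics -> ratios in one call.
simulate_ratios <- function(config) {
  sim <- simulate_cohort(config)
  m <- apply_metrics(sim$cohort)
  list(
    ratios = compute_ratios(m$data),
    qc_report = m$qc_report,
    truth = sim$truth
  )
}
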