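#' Spectral basis and acquisition model
#'
#' A small metabolite basis for 1.5 T long-TE proton CSI of the brainstem:
#' NAA (singlet at 2.01 ppm) plus creatine and phosphocreatine, which
#' co-resonate near 3.03 ppm and are distinguishable only through their
#' transverse relaxation (T2 of Cr ~ 309 ms, PCr ~ 117 ms). Because the two
#' creatine pools share a resonance, the fit estimates only their pooled
#' total-creatine (tCr) amplitude; the Cr:PCr split exists solely on the
#' simulation side. myo-inositol is omitted: at TE = 135 ms its J-coupled
#' multiplets yield too little signal to quantify.
#'
#' @param peaks Data frame with columns `name`, `ppm`, `lw_hz` (Lorentzian
#'   full width at half maximum, Hz), `protons`, `t2_ms`.
#' @param te_ms,tr_ms Echo and repetition time in ms (defaults 135 / 1750).
#' @param f0_mhz Spectrometer frequency in MHz (default 63.87, i.e. 1.5 T).
#' @param sw_hz Spectral width in Hz.
#' @param npts Number of spectral points.
#' @param center_ppm Carrier position of the ppm axis.
#' @return Object of class `spectral_model`. The stored ppm axis ascends;
#'   display conventions (ppm decreasing left to right) are left to plotting.
#' @export
spectral_model <- function(peaks = default_peaks(),
                           te_ms = 135, tr_ms = 1750,
                           f0_mhz = 63.87, sw_hz = 1000, npts = 2048,
                           center_ppm = 2.6) {
  p <- list()
  need <- c("name", "ppm", "lw_hz", "protons", "t2_ms")
  if (!all(need %in% names(peaks))) {
    p$peaks <- paste("`peaks` must have columns", paste(need, collapse = ", "))
  } else {
    if (any(peaks$lw_hz <= 0)) p$lw <- "`peaks$lw_hz` must be > 0"
    if (any(peaks$t2_ms <= 0)) p$t2 <- "`peaks$t2_ms` must be > 0"
  }
  if (te_ms < 0) p$te <- "`te_ms` must be >= 0"
  if (te_ms >= tr_ms) p$tr <- "`te_ms` must be < `tr_ms`"
  abort_invalid(p, "spectral model", class = "ponsmrsi_config_error")

  freq_hz <- seq(-sw_hz / 2, sw_hz / 2, length.out = npts)
  ppm <- center_ppm + freq_hz / f0_mhz
  structure(
    list(
      peaks = tibble::as_tibble(peaks),
      te_ms = te_ms, tr_ms = tr_ms, f0_mhz = f0_mhz,
      sw_hz = sw_hz, npts = npts, ppm = ppm
    ),
    class = "spectral_model"
  )
}

default_peaks <- function() {
  tibble::tibble(
    name = c("NAA", "Cr", "PCr"),
    ppm = c(2.01, 3.03, 3.03),
    lw_hz = c(3, 3, 3),
    protons = c(3, 3, 3),
    t2_ms = c(350, 309, 117)
  )
}

#' T2-weight a concentration for the acquisition echo time
#'
#' Transverse relaxation attenuates the observed amplitude of a resonance
#' by `exp(-TE / T2)`.
#'
#' @param concentration Concentration (or amplitude) to weight.
#' @param t2_ms Transverse relaxation time in ms (> 0).
#' @param te_ms Echo time in ms (>= 0).
#' @return `concentration * exp(-te_ms / t2_ms)`.
#' @export
t2_weight <- function(concentration, t2_ms, te_ms) {
  if (any(t2_ms <= 0)) {
    rlang::abort("`t2_ms` must be > 0", class = "ponsmrsi_validation_error")
  }
  if (any(te_ms < 0)) {
    rlang::abort("`te_ms` must be >= 0", class = "ponsmrsi_validation_error")
  }
  concentration * exp(-te_ms / t2_ms)
}

#' Observed total-creatine amplitude from the two creatine pools
#'
#' At the acquisition TE the measured tCr peak is the T2-weighted sum of
#' the creatine and phosphocreatine contributions. Because Cr relaxes much
#' more slowly than PCr, shifting the Cr:PCr equilibrium toward Cr at fixed
#' total increases the observed tCr signal for any TE > 0.
#'
#' @param cr,pcr Pool concentrations (>= 0).
#' @param model A [spectral_model()] supplying TE and the pool T2s.
#' @return Observed (T2-weighted) tCr amplitude per unit proton count.
#' @export
observed_tcr <- function(cr, pcr, model = spectral_model()) {
  if (any(cr < 0) || any(pcr < 0)) {
    rlang::abort("Creatine pool concentrations must be >= 0",
      class = "ponsmrsi_validation_error"
    )
  }
  pk <- model$peaks
  t2_cr <- pk$t2_ms[pk$name == "Cr"]
  t2_pcr <- pk$t2_ms[pk$name == "PCr"]
  t2_weight(cr, t2_cr, model$te_ms) + t2_weight(pcr, t2_pcr, model$te_ms)
}

# Complex Lorentzian lineshape with unit area in the absorption (real)
# part; hwhm_hz is the half width at half maximum.
lorentzian <- function(freq_hz, f0_hz, hwhm_hz) {
  (1 / pi) / complex(real = hwhm_hz, imaginary = freq_hz - f0_hz)
}

peak_freq_hz <- function(model, ppm) {
  (ppm - model$ppm[1]) / (model$ppm[model$npts] - model$ppm[1]) * model$sw_hz - model$sw_hz / 2
}

#' Simulate a frequency-domain voxel spectrum
#'
#' Sums complex Lorentzian peaks at their chemical-shift positions, with
#' observed amplitudes `concentration * protons * exp(-TE / T2)`, and adds
#' iid complex Gaussian noise. The noiseless spectrum is deterministic.
#'
#' @param concentrations Named vector of metabolite concentrations; names
#'   must match `model$peaks$name`.
#' @param model A [spectral_model()].
#' @param noise_sd SD of the complex Gaussian noise per point (applied to
#'   real and imaginary channels independently).
#' @param seed Optional seed.
#' @return List of class `voxel_spectrum` with `y` (complex spectrum),
#'   `ppm` (ascending axis) and the generating `model`.
#' @export
simulate_spectrum <- function(concentrations, model = spectral_model(),
                              noise_sd = 0, seed = NULL) {
  unknown <- setdiff(names(concentrations), model$peaks$name)
  if (length(unknown) > 0 || is.null(names(concentrations))) {
    rlang::abort(
      paste0(
        "Unknown metabolite name(s): ",
        paste(unknown, collapse = ", ")
      ),
      class = "ponsmrsi_validation_error"
    )
  }
  if (any(concentrations < 0)) {
    rlang::abort("Concentrations must be >= 0", class = "ponsmrsi_validation_error")
  }
  freq <- seq(-model$sw_hz / 2, model$sw_hz / 2, length.out = model$npts)
  y <- complex(real = numeric(model$npts), imaginary = numeric(model$npts))
  for (m in names(concentrations)) {
    pk <- model$peaks[model$peaks$name == m, ]
    amp <- t2_weight(concentrations[[m]] * pk$protons, pk$t2_ms, model$te_ms)
    f0 <- (pk$ppm - mean(range(model$ppm))) * model$f0_mhz # offset from carrier
    y <- y + amp * lorentzian(freq, f0, pk$lw_hz / 2)
  }
  y <- with_seed(seed, {
    y + complex(
      real = stats::rnorm(model$npts, 0, noise_sd),
      imaginary = stats::rnorm(model$npts, 0, noise_sd)
    )
  })
  structure(list(y = y, ppm = model$ppm, model = model), class = "voxel_spectrum")
}

# Real-part basis matrix for the requested fit species. "tCr" pools the Cr
# and PCr lineshapes into one unit-amplitude column (they share ppm and
# linewidth, so only the pooled amplitude is identifiable).
fit_basis <- function(model, species) {
  freq <- seq(-model$sw_hz / 2, model$sw_hz / 2, length.out = model$npts)
  col_for <- function(names) {
    pk <- model$peaks[model$peaks$name %in% names, , drop = FALSE]
    sh <- numeric(model$npts)
    for (j in seq_len(nrow(pk))) {
      f0 <- (pk$ppm[j] - mean(range(model$ppm))) * model$f0_mhz
      sh <- sh + Re(lorentzian(freq, f0, pk$lw_hz[j] / 2)) / nrow(pk)
    }
    sh
  }
  B <- vapply(species, function(s) {
    if (s == "tCr") col_for(c("Cr", "PCr")) else col_for(s)
  }, numeric(model$npts))
  colnames(B) <- species
  B
}

#' Fit a spectrum by linear combination of basis lineshapes
#'
#' Least-squares fit of the real part of a spectrum against noiseless
#' unit-amplitude basis lineshapes, with relative Cramer-Rao lower bounds
#' computed from the Fisher information of the linear model:
#' `CRLB% = 100 * sigma_hat * sqrt(diag((B'B)^-1)) / |amplitude|`,
#' capped at 999% for vanishing amplitudes. Fitted amplitudes are in
#' "observed amplitude" units (T2- and proton-weighted), so the tCr
#' amplitude estimates the pooled, relaxation-weighted creatine signal.
#'
#' @param spectrum A `voxel_spectrum` (or complex/numeric vector on the
#'   model's grid).
#' @param model A [spectral_model()] sharing the spectrum's ppm grid.
#' @param species Fit species; the default fits NAA and pooled tCr.
#' @param nonneg If `TRUE` (default), negative amplitude estimates are
#'   truncated at zero (and flagged with the 999% CRLB cap).
#' @return List of class `fit_result` with `amplitudes` (named vector),
#'   `crlb_pct` (named vector), `sigma` (residual SD), `success` flag.
#' @export
fit_spectrum <- function(spectrum, model = spectral_model(),
                         species = c("NAA", "tCr"), nonneg = TRUE) {
  y <- if (inherits(spectrum, "voxel_spectrum")) spectrum$y else spectrum
  if (length(y) != model$npts) {
    rlang::abort("Spectrum and model do not share the same grid",
      class = "ponsmrsi_validation_error"
    )
  }
  B <- fit_basis(model, species)

  # collinearity check (e.g. Cr vs PCr fitted separately: same lineshape)
  if (ncol(B) > 1) {
    cc <- stats::cor(B)
    diag(cc) <- 0
    if (any(abs(cc) > 0.9999)) {
      idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      rlang::abort(
        sprintf(
          "Rank-deficient basis: '%s' and '%s' are collinear",
          colnames(B)[idx[1]], colnames(B)[idx[2]]
        ),
        class = "ponsmrsi_fit_error"
      )
    }
  }

  yr <- Re(y)
  xtx_inv <- solve(crossprod(B))
  beta <- drop(xtx_inv %*% crossprod(B, yr))
  names(beta) <- colnames(B)
  res <- yr - drop(B %*% beta)
  sigma <- sqrt(sum(res^2) / (length(yr) - ncol(B)))
  if (nonneg) beta <- pmax(beta, 0)

  crlb <- 100 * sigma * sqrt(diag(xtx_inv)) / pmax(abs(beta), 1e-12)
  crlb <- pmin(crlb, 999)
  crlb[beta <= 1e-12 & sigma > 0] <- 999
  structure(
    list(amplitudes = beta, crlb_pct = crlb, sigma = sigma, success = TRUE),
    class = "fit_result"
  )
}
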