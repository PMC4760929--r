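# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb an enclosing simulation stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic per-subject substream derivation: a Lehmer-style mix keeps
# every derived seed in [1, 2^31 - 1] and exact in double arithmetic.
fan_seed <- function(seed, index) {
  base <- as.double(seed) %% 2147483647
  as.integer((base * 48271 + 7919 * as.double(index)) %% 2147483646 + 1)
}

# Inverse-CDF truncated normal. sd = 0 degenerates to the mean (clamped to
# the interval). Vectorised over n only; mean/sd/bounds are scalars.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(lower <= upper)
  if (sd <= 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  out <- stats::qnorm(u, mean, sd)
  pmin(pmax(out, lower), upper)
}

# Aggregate-and-abort validation: collects messages, raises once.
abort_invalid <- function(problems, what, class = "ponsmrsi_validation_error") {
  problems <- problems[!vapply(problems, is.null, logical(1))]
  if (length(problems) == 0) {
    return(invisible(TRUE))
  }
  rlang::abort(
    c(paste0("Invalid ", what, ":"), rlang::set_names(unlist(problems), "x")),
    class = class
  )
}

pkg_version <- function() {
  as.character(utils::packageVersion("ponsmrsi"))
}
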