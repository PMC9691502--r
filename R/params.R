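#' Deterministic encoder parameters
#'
#' Constructs the parameter set of the dynamic-threshold spike encoder: a
#' constant bias voltage `v` drives a spike generator whose firing barrier
#' `r(t)` jumps by `A` volts at every spike and relaxes exponentially with
#' time constant `tau` (never resetting). A spike is emitted when the coding
#' error `e(t) = v - r(t)` reaches the spike threshold `gamma`.
#'
#' In the linearized (high-rate) regime the threshold decays along a line of
#' slope `-m` with `m = (v - gamma + A)/tau`, and the deterministic interspike
#' interval is `A/m = A*tau/(v - gamma + A)`. The slope is a derived quantity;
#' it is exposed through [slope()] and never stored independently.
#'
#' @param v Bias voltage (volts), `> 0`.
#' @param A Threshold jump after each spike (volts), `> 0`.
#' @param tau Relaxation time constant of the dynamic threshold (ms), `> 0`.
#' @param gamma Mean spike threshold (volts). Defaults to `A/2`, the value
#'   that minimizes the mean-squared coding error; the ISI serial correlation
#'   structure does not depend on it. Requires `v - gamma > 0`, otherwise the
#'   exponential model never fires.
#' @return An object of class `"model_params"`.
#' @seealso [slope()], [deterministic_isi()], [simulate_deterministic()]
#' @examples
#' p <- model_params(v = 1.845, A = 0.15, tau = 30)
#' slope(p)
#' deterministic_isi(p)
#' @export
model_params <- function(v, A, tau, gamma = A / 2) {
  stopifnot(is.numeric(v), is.numeric(A), is.numeric(tau), is.numeric(gamma),
            length(v) == 1L, length(A) == 1L, length(tau) == 1L,
            length(gamma) == 1L)
  if (!is.finite(v) || v <= 0) stop("invalid parameter: 'v' must be > 0")
  if (!is.finite(A) || A <= 0) stop("invalid parameter: 'A' must be > 0")
  if (!is.finite(tau) || tau <= 0) stop("invalid parameter: 'tau' must be > 0")
  if (!is.finite(gamma) || v - gamma <= 0)
    stop("invalid parameter: 'v - gamma' must be > 0 (model never fires)")
  structure(list(v = v, A = A, tau = tau, gamma = gamma),
            class = "model_params")
}

#' Slope of the linearized dynamic threshold
#'
#' @param params A [model_params()] object.
#' @return `m = (v - gamma + A)/tau` in volts/ms.
#' @export
slope <- function(params) {
  stopifnot(inherits(params, "model_params"))
  (params$v - params$gamma + params$A) / params$tau
}

#' Deterministic interspike interval
#'
#' Closed-form interval of the noise-free encoder. Under the linearized rule
#' every ISI equals `A*tau/(v - gamma + A)`; under the exact exponential decay
#' it is `tau * log((v - gamma + A)/(v - gamma))`.
#'
#' @param params A [model_params()] object.
#' @param rule `"linearized"` (default) or `"exponential"`.
#' @return ISI in ms.
#' @export
deterministic_isi <- function(params, rule = c("linearized", "exponential")) {
  stopifnot(inherits(params, "model_params"))
  rule <- match.arg(rule)
  with(params, switch(rule,
    linearized  = A * tau / (v - gamma + A),
    exponential = tau * log((v - gamma + A) / (v - gamma))
  ))
}

#' @export
print.model_params <- function(x, ...) {
  cat("Dynamic-threshold encoder parameters\n")
  cat(sprintf("  v = %g V, A = %g V, tau = %g ms, gamma = %g V\n",
              x$v, x$A, x$tau, x$gamma))
  cat(sprintf("  slope m = %g V/ms, deterministic ISI = %g ms (linearized), %g ms (exponential)\n",
              slope(x), deterministic_isi(x), deterministic_isi(x, "exponential")))
  invisible(x)
}

#' EOD-cycle firing grid
#'
#' Time grid at the period of the electric organ discharge (EOD). P-type
#' electrosensory afferents fire at most once per EOD cycle; when a grid is
#' enabled, spikes are emitted only at integer multiples of the period and
#' successive spikes are at least one period apart.
#'
#' @param period EOD period in ms (`> 0`), or `NULL` for a disabled grid
#'   (continuous time base).
#' @return An object of class `"eod_grid"`.
#' @examples
#' eod_grid(1.06)  # 943 Hz discharge
#' eod_grid()      # continuous time base
#' @export
eod_grid <- function(period = NULL) {
  if (is.null(period)) {
    return(structure(list(enabled = FALSE, period = NA_real_),
                     class = "eod_grid"))
  }
  stopifnot(is.numeric(period), length(period) == 1L)
  if (!is.finite(period) || period <= 0)
    stop("invalid parameter: EOD grid 'period' must be > 0")
  structure(list(enabled = TRUE, period = period), class = "eod_grid")
}

#' @export
print.eod_grid <- function(x, ...) {
  if (x$enabled)
    cat(sprintf("EOD grid: period %g ms (%.0f Hz)\n", x$period, 1000 / x$period))
  else cat("EOD grid: disabled (continuous time base)\n")
  invisible(x)
}
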