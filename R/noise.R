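# Threshold-noise processes: first-order autoregressive (both signs), white,
# and stationary Gaussian sequences with an arbitrary prescribed ACF.

#' Specification of AR(1) threshold noise
#'
#' The spike-threshold noise is a discrete wide-sense stationary process
#' sampled once per interspike interval. Its simplest colored form is a
#' first-order autoregressive recursion `g_k = s*a*g_{k-1} + w_k` with
#' magnitude `a` in `[0, 1)` and sign `s`: `+1` produces slow noise and
#' Type I (monotone negative) ISI correlations, `-1` fast noise and Type II
#' (alternating) correlations, and `0` white noise, the degenerate Type III
#' case. The discrete process is the sampled version of an
#' Ornstein-Uhlenbeck process with relaxation time `tau_gamma`, related by
#' `a = exp(-T1/tau_gamma)` with `T1` the mean ISI.
#'
#' @param a Magnitude of the AR coefficient, `0 <= a < 1`. Ignored (forced
#'   to 0) when `sign = 0`.
#' @param sign `+1` (Type I), `-1` (Type II) or `0` (white / Type III).
#' @param R0 Target noise power (lag-0 autocorrelation, volts^2). May be
#'   given instead via `snr_db`.
#' @param snr_db Signal-to-noise ratio `10*log10(v^2/R0)` in dB; requires
#'   `v`. Ignored when `R0` is given.
#' @param v Bias voltage used to convert `snr_db` to `R0`.
#' @return Object of class `"ar_noise_spec"` with fields `a`, `sign`, `R0`.
#' @examples
#' ar_noise_spec(0.4, +1, snr_db = 35, v = 1.845)  # R0 = 1.076e-3 V^2
#' @export
ar_noise_spec <- function(a, sign = 1, R0 = NULL, snr_db = NULL, v = NULL) {
  stopifnot(length(a) == 1L, length(sign) == 1L)
  if (!sign %in% c(-1, 0, 1)) stop("'sign' must be +1, -1 or 0")
  if (sign == 0) a <- 0
  if (!is.finite(a) || a < 0 || a >= 1)
    stop("nonstationary noise: 'a' must satisfy 0 <= a < 1")
  if (is.null(R0)) {
    if (is.null(snr_db) || is.null(v))
      stop("give either 'R0' or both 'snr_db' and 'v'")
    R0 <- snr_to_power(snr_db, v)
  }
  if (!is.finite(R0) || R0 <= 0) stop("'R0' must be > 0")
  structure(list(a = a, sign = sign, R0 = R0), class = "ar_noise_spec")
}

#' @export
print.ar_noise_spec <- function(x, ...) {
  type <- switch(as.character(x$sign), "1" = "Type I (slow)",
                 "-1" = "Type II (fast)", "0" = "white (Type III)")
  cat(sprintf("AR(1) threshold-noise spec: a = %g, sign %+d [%s], R0 = %g V^2\n",
              x$a, x$sign, type, x$R0))
  invisible(x)
}

#' Convert between noise power and SNR
#'
#' `SNR = 10*log10(v^2/R0)` in dB.
#' @param snr_db SNR in dB.
#' @param v Bias voltage.
#' @return Noise power `R0` in volts^2.
#' @export
snr_to_power <- function(snr_db, v) v^2 * 10^(-snr_db / 10)

#' @rdname snr_to_power
#' @param R0 Noise power (volts^2).
#' @export
power_to_snr <- function(R0, v) 10 * log10(v^2 / R0)

#' Relaxation time of the discretized noise process
#'
#' @param spec An [ar_noise_spec()].
#' @param T1 Mean ISI (ms) defining the discrete time base.
#' @return `tau_gamma = -T1/log(a)` in ms (`0` for white noise).
#' @export
tau_gamma <- function(spec, T1) {
  stopifnot(inherits(spec, "ar_noise_spec"))
  if (spec$a == 0) return(0)
  -T1 / log(spec$a)
}

#' Theoretical autocorrelation of AR(1) threshold noise
#'
#' For magnitude `a` and sign `s` the stationary autocorrelation is
#' `R_k = R0 * (s*a)^k`; with `normalized = "unit-innovation"` the classical
#' unscaled form `(s*a)^k / (1 - a^2)` is returned instead. White noise
#' (`sign = 0`) has `R_0 = R0` and zero elsewhere.
#'
#' @param spec An [ar_noise_spec()].
#' @param K Maximum lag (`>= 0`).
#' @param scale `"power"` (lag 0 equals the spec's `R0`, default) or
#'   `"unit-innovation"` (unit white-noise input variance).
#' @return A [noise_acf()] with lags `0..K`.
#' @examples
#' acf_ar1(ar_noise_spec(0.5, +1, R0 = 1), 2, scale = "unit-innovation")$R
#' # 1.3333 0.6667 0.3333
#' @export
acf_ar1 <- function(spec, K, scale = c("power", "unit-innovation")) {
  stopifnot(inherits(spec, "ar_noise_spec"), K >= 0)
  scale <- match.arg(scale)
  r <- (spec$sign * spec$a)^(0:K)
  R <- switch(scale, power = spec$R0 * r, `unit-innovation` = r / (1 - spec$a^2))
  noise_acf(R, normalization = if (scale == "power") "raw" else "raw")
}

#' Discrete noise autocorrelation function
#'
#' Values `R_k`, `k = 0..K`, of a wide-sense stationary threshold-noise
#' process, with lags counted in units of the mean ISI. Wide-sense
#' stationarity requires `R0 > 0` and `|R_k| <= R0`; validity as an ACF is
#' checked (when `validate = TRUE`) by requiring the Toeplitz matrix built
#' from the values to be positive semidefinite up to a tolerance.
#'
#' @param R Numeric vector of autocorrelation values at lags `0..K`.
#' @param normalization `"raw"` (volts^2) or `"R0"` (unit lag-0).
#' @param validate Check positive semidefiniteness (default `FALSE`;
#'   [generate_from_acf()] always checks).
#' @return Object of class `"noise_acf"` with fields `R`, `lags`,
#'   `normalization`.
#' @export
noise_acf <- function(R, normalization = c("raw", "R0"), validate = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(R), length(R) >= 1L)
  if (R[1L] <= 0) stop("R0 (lag-0 power) must be > 0")
  if (any(abs(R[-1L]) > R[1L] * (1 + 1e-9)))
    stop("|R_k| <= R0 violated: not wide-sense stationary")
  obj <- structure(list(R = as.numeric(R), lags = seq_along(R) - 1L,
                        normalization = normalization),
                   class = "noise_acf")
  if (validate) check_psd(obj)
  obj
}

# Minimum eigenvalue of the Toeplitz matrix of the ACF, relative to R0.
check_psd <- function(acf, tol = 1e-8) {
  ev <- eigen(stats::toeplitz(acf$R), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * acf$R[1L])
    stop("ACF is not positive semidefinite (min eigenvalue ",
         signif(min(ev) / acf$R[1L], 3), " relative to R0)")
  invisible(min(ev))
}

#' @export
print.noise_acf <- function(x, ...) {
  cat(sprintf("Noise ACF (%s), lags 0..%d:\n", x$normalization, max(x$lags)))
  print(utils::head(round(x$R, 6), 10))
  invisible(x)
}

#' Generate an AR(1) threshold-noise sequence
#'
#' Runs the recursion `g_k = s*a*g_{k-1} + w_k` with Gaussian innovations of
#' variance `R0*(1 - a^2)`, starting from a draw from the stationary
#' distribution (variance `R0`) so the output is stationary from the first
#' sample. `sign = 0` gives i.i.d. Gaussian values of variance `R0`.
#'
#' @param spec An [ar_noise_spec()].
#' @param n Number of samples (`>= 1`).
#' @param seed Optional integer seed; recorded in the output.
#' @return Object of class `"noise_seq"`: `values`, `spec`, `seed`.
#' @export
generate_ar1 <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "ar_noise_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sd_w <- sqrt(spec$R0 * (1 - spec$a^2))
  x0 <- stats::rnorm(1L, 0, sqrt(spec$R0))
  vals <- if (spec$a == 0) {
    stats::rnorm(n, 0, sqrt(spec$R0))
  } else {
    w <- stats::rnorm(n, 0, sd_w)
    as.numeric(stats::filter(w, spec$sign * spec$a, method = "recursive",
                             init = x0))
  }
  structure(list(values = vals, spec = spec, seed = seed), class = "noise_seq")
}

#' @export
print.noise_seq <- function(x, ...) {
  cat(sprintf("Threshold-noise sequence: n = %d, sample power %.3g V^2\n",
              length(x$values), mean(x$values^2)))
  invisible(x)
}

#' Generate a stationary Gaussian sequence with a prescribed ACF
#'
#' Builds the unique Gaussian autoregressive process of order `K` whose
#' autocovariances at lags `0..K` equal the input exactly (Yule-Walker
#' coefficients computed from the Toeplitz system), i.e. the maximum-entropy
#' extension of the prescribed ACF; beyond lag `K` the population ACF decays
#' according to the AR recursion. The first `K` samples are drawn from the
#' exact stationary distribution (Cholesky factor of the Toeplitz
#' covariance), so the output is stationary from sample 1.
#'
#' A near-singular covariance is regularized by adding a small diagonal
#' jitter (multiples of `R0`); the jitter actually used is recorded in the
#' result. An indefinite ACF raises an error.
#'
#' @param acf A [noise_acf()] with lags `0..K`, positive semidefinite up to
#'   tolerance.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return A `"noise_seq"` with fields `values`, `acf`, `seed`, `jitter`.
#' @export
generate_from_acf <- function(acf, n, seed = NULL) {
  stopifnot(inherits(acf, "noise_acf"), n >= 1)
  check_psd(acf)
  if (!is.null(seed)) set.seed(seed)
  R <- acf$R
  p <- length(R) - 1L
  if (p == 0L || all(R[-1L] == 0)) {
    vals <- stats::rnorm(n, 0, sqrt(R[1L]))
    return(structure(list(values = vals, acf = acf, seed = seed, jitter = 0),
                     class = "noise_seq"))
  }
  # Yule-Walker AR(p) coefficients, with escalating jitter if near-singular
  jitter <- 0
  phi <- NULL
  for (j in c(0, 10^seq(-10, -4))) {
    Tm <- stats::toeplitz(R[1:p]) + diag(j * R[1L], p)
    phi <- tryCatch(solve(Tm, R[2:(p + 1L)]), error = function(e) NULL)
    if (!is.null(phi)) {
      sig2 <- R[1L] * (1 + j) - sum(phi * R[2:(p + 1L)])
      if (sig2 > 0) { jitter <- j; break }
      phi <- NULL
    }
  }
  if (is.null(phi))
    stop("could not factor the Toeplitz covariance; ACF too ill-conditioned")
  # stationary start: exact joint distribution of the first p samples
  C <- stats::toeplitz(R[1:p]) + diag(jitter * R[1L], p)
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) {
    jitter <- max(jitter, 1e-8)
    L <- chol(stats::toeplitz(R[1:p]) + diag(jitter * R[1L], p))
  }
  init <- as.numeric(t(L) %*% stats::rnorm(p))
  if (n <= p) {
    vals <- init[1:n]
  } else {
    w <- stats::rnorm(n - p, 0, sqrt(sig2))
    rest <- stats::filter(w, phi, method = "recursive", init = rev(init))
    vals <- c(init, as.numeric(rest))
  }
  structure(list(values = vals, acf = acf, seed = seed, jitter = jitter),
            class = "noise_seq")
}
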