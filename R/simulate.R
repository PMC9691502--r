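# Spike-train generators for the dynamic-threshold encoder.
#
# All simulators share the convention that the threshold noise value for the
# i-th interval is drawn immediately after spike i-1 and held constant until
# spike i. A noise vector of length n+1 therefore yields n intervals; element
# 1 sets the post-spike state at t0 = 0.

noise_values <- function(noise) {
  if (inherits(noise, "noise_seq")) noise$values else as.numeric(noise)
}

#' Simulate the deterministic encoder
#'
#' With a noise-free threshold the linearized firing rule gives identical
#' intervals `A*tau/(v - gamma + A)` for a constant bias input.
#'
#' @param params A [model_params()] object.
#' @param n_spikes Number of spikes (at least 2); the train starts at `t0 = 0`.
#' @return A [spike_train()] on the continuous time base.
#' @examples
#' st <- simulate_deterministic(model_params(1.845, 0.15, 30, gamma = 0.075), 10)
#' unique(round(diff(st$times), 10))  # 2.34375 ms
#' @export
simulate_deterministic <- function(params, n_spikes) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(n_spikes) || n_spikes < 2)
    stop("invalid parameter: 'n_spikes' must be at least 2")
  isi <- deterministic_isi(params)
  spike_train(seq(0, by = isi, length.out = n_spikes),
              metadata = list(params = unclass(params), rule = "deterministic"))
}

#' Simulate ISIs under the linearized firing rule
#'
#' Implements the stochastic linearized rule
#' `ISI_i = (g_i - g_{i-1} + A)/m`, where `g_i` are threshold-noise
#' deviations and `m = (v - gamma + A)/tau`. The mean ISI converges to `A/m`.
#' Intervals that come out nonpositive indicate noise too large for the
#' linearization and raise an error rather than being clipped.
#'
#' @param params A [model_params()] object.
#' @param noise Threshold-noise deviations about the mean threshold: a
#'   numeric vector or a `noise_seq` from [generate_ar1()] /
#'   [generate_from_acf()]. Length `n + 1` yields `n` intervals.
#' @param n Number of intervals; defaults to `length(noise) - 1`.
#' @return An [isi_seq()] in ms.
#' @export
simulate_linearized <- function(params, noise, n = NULL) {
  stopifnot(inherits(params, "model_params"))
  x <- noise_values(noise)
  if (is.null(n)) n <- length(x) - 1L
  if (length(x) < n + 1L)
    stop("noise sequence must have at least n + 1 values")
  m <- slope(params)
  isi <- (x[2:(n + 1L)] - x[1:n] + params$A) / m
  bad <- which(isi <= 0)
  if (length(bad))
    stop("nonpositive ISI at index ", bad[1L],
         ": threshold noise too large for the linearized rule")
  isi_seq(isi, unit = "ms",
          metadata = list(params = unclass(params), rule = "linearized"))
}

#' Simulate a spike train with exact exponential threshold decay
#'
#' Event-driven simulation of the exponential-decay encoder. Between spikes
#' the dynamic threshold is `r(t) = (v - g_{i-1} + A) * exp(-(t - t_{i-1})/tau)`
#' (with `g` the realized spike thresholds) and the next spike falls at the
#' exact crossing `ISI_i = tau * log((v - g_{i-1} + A)/(v - g_i))`; no
#' time-stepped integration is involved, so there is no step-size tolerance.
#'
#' With an enabled EOD grid the spike is emitted at the first grid point at
#' or after the continuous crossing, and never earlier than one period after
#' the previous spike; the threshold jump `A` is applied to the threshold
#' value at the actual (grid) emission time. This enforces at most one spike
#' per EOD cycle and quantizes spike times, as observed in P-type afferents.
#' When the realized threshold is already exceeded at the start of an
#' interval (strong, fast noise) the grid rule emits the spike one period
#' later - the mechanism that produces the burst peak at one EOD period in
#' strongly bursting trains. On the continuous base the same situation has
#' no positive crossing and raises a domain error.
#'
#' @inheritParams simulate_linearized
#' @param grid An [eod_grid()]; disabled (default) gives the continuous base.
#' @param burn_in Number of initial intervals to discard (default 0; the
#'   fixture generator and fitting routines discard 100 for statistics).
#' @return A [spike_train()] starting at `t0 = 0` (after burn-in, re-zeroed).
#' @examples
#' p <- model_params(1.845, 0.15, 30)
#' st <- simulate_exponential(p, numeric(11))  # zero noise
#' unique(round(diff(st$times), 4))            # 2.4404 ms
#' @export
simulate_exponential <- function(params, noise, grid = eod_grid(),
                                 burn_in = 0L) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "eod_grid"))
  x <- noise_values(noise)
  n <- length(x) - 1L
  if (n < 1L) stop("noise sequence must have at least 2 values")
  v <- params$v; A <- params$A; tau <- params$tau; gam <- params$gamma
  level <- v - gam - x[2:(n + 1L)]
  if (any(level <= 0))
    stop("no threshold crossing exists: v - gamma_i <= 0 at index ",
         which(level <= 0)[1L])

  if (!grid$enabled) {
    # closed form: at each emission r equals the spike level exactly
    peak <- v - gam - x[1:n] + A
    if (any(peak <= level))
      stop("nonpositive ISI at index ", which(peak <= level)[1L],
           ": threshold already crossed at interval onset (continuous base);",
           " reduce noise power or enable an EOD grid")
    times <- cumsum(c(0, tau * log(peak / level)))
  } else {
    P <- grid$period
    peak <- v - gam - x[1L] + A
    tprev <- 0
    times <- numeric(n + 1L)
    for (i in seq_len(n)) {
      tc <- if (peak > level[i]) tprev + tau * log(peak / level[i]) else tprev
      temit <- P * ceiling(tc / P - 1e-9)
      if (temit < tprev + P) temit <- tprev + P
      peak <- peak * exp(-(temit - tprev) / tau) + A
      tprev <- temit
      times[i + 1L] <- temit
    }
  }
  if (burn_in > 0) {
    if (burn_in >= n) stop("burn_in must be smaller than the number of intervals")
    times <- times[-seq_len(burn_in)]
    times <- times - times[1L]
  }
  spike_train(times, grid = grid,
              metadata = list(params = unclass(params), rule = "exponential",
                              eod_period = if (grid$enabled) grid$period else NA,
                              burn_in = burn_in))
}

#' Per-interval time constants equivalent to a noisy threshold
#'
#' Transforms a threshold-noise realization into the equivalent noisy
#' time-constant model: `tau_i = (tau/A) * (g_i - g_{i-1} + A)`. The spike
#' train generated with a fixed threshold and these per-interval time
#' constants is identical, interval for interval, to the linearized
#' noisy-threshold train, and the serial correlations of `tau_i` equal those
#' of the ISIs (the ISI is `A/m_i`, a fixed multiple of `tau_i`).
#'
#' @inheritParams simulate_linearized
#' @return A [tau_seq()] with time constants `tau_i` and slopes `m_i`.
#' @export
tau_sequence_from_threshold_noise <- function(params, noise, n = NULL) {
  stopifnot(inherits(params, "model_params"))
  x <- noise_values(noise)
  if (is.null(n)) n <- length(x) - 1L
  if (length(x) < n + 1L)
    stop("noise sequence must have at least n + 1 values")
  tau_i <- (params$tau / params$A) *
    (x[2:(n + 1L)] - x[1:n] + params$A)
  bad <- which(tau_i <= 0)
  if (length(bad))
    stop("nonpositive time constant at index ", bad[1L],
         ": threshold noise too large")
  tau_seq(tau_i, (params$v - params$gamma + params$A) / tau_i)
}
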