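#' Spike train container
#'
#' A sequence of spike times in ms, strictly increasing, on either a
#' continuous time base or an EOD-cycle grid.
#'
#' @param times Numeric vector of spike times (ms), strictly increasing,
#'   length at least 2.
#' @param grid An [eod_grid()]; disabled grid means a continuous time base.
#' @param metadata Optional named list (parameters, seed, ...) carried along
#'   and written to file headers by [write_spike_times()].
#' @return Object of class `"spike_train"`.
#' @export
spike_train <- function(times, grid = eod_grid(), metadata = list()) {
  stopifnot(is.numeric(times), inherits(grid, "eod_grid"))
  if (length(times) < 2L)
    stop("a spike train needs at least 2 spike times to yield ISIs")
  if (any(diff(times) <= 0))
    stop("spike times must be strictly increasing (first violation at index ",
         which(diff(times) <= 0)[1L] + 1L, ")")
  if (grid$enabled) {
    k <- times / grid$period
    if (any(abs(k - round(k)) > 1e-6))
      stop("on an EOD grid all spike times must be integer multiples of the period")
  }
  structure(list(times = as.numeric(times), grid = grid, metadata = metadata),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %.3f ms (%s time base)\n",
              length(x$times), diff(range(x$times)),
              if (x$grid$enabled) sprintf("EOD grid, %g ms", x$grid$period)
              else "continuous"))
  cat(sprintf("  mean ISI %.4f ms, rate %.1f spikes/s\n",
              mean(diff(x$times)), 1000 / mean(diff(x$times))))
  invisible(x)
}

#' Interspike-interval sequence
#'
#' @param intervals Positive numeric vector of ISIs. On the `"eod"` unit base
#'   the intervals must be positive integers (counts of EOD cycles).
#' @param unit `"ms"` or `"eod"`; mandatory unit tag.
#' @param eod_period EOD period in ms; required when `unit = "eod"` so the
#'   sequence can be mapped back to physical time.
#' @param metadata Optional named list carried to file headers.
#' @return Object of class `"isi_seq"`.
#' @export
isi_seq <- function(intervals, unit = c("ms", "eod"), eod_period = NULL,
                    metadata = list()) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(intervals))
  bad <- which(intervals <= 0)
  if (length(bad))
    stop("all ISIs must be > 0 (first violation at index ", bad[1L], ")")
  if (unit == "eod") {
    if (any(abs(intervals - round(intervals)) > 1e-9))
      stop("ISIs in EOD units must be positive integers")
    intervals <- round(intervals)
    if (is.null(eod_period))
      stop("'eod_period' is required when unit = \"eod\"")
  }
  structure(list(intervals = as.numeric(intervals), unit = unit,
                 eod_period = eod_period, metadata = metadata),
            class = "isi_seq")
}

#' @export
print.isi_seq <- function(x, ...) {
  s <- isi_stats(x)
  cat(sprintf("ISI sequence: %d intervals (%s)\n", length(x$intervals), x$unit))
  cat(sprintf("  mean %.4f, sd %.4f, CV %.3f\n", s$T1, sqrt(s$V1), s$cv))
  invisible(x)
}

#' ISIs of a spike train
#'
#' @param train A [spike_train()].
#' @return An [isi_seq()] in ms (continuous base) or integer EOD cycles.
#' @export
isis <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  d <- diff(train$times)
  if (train$grid$enabled)
    isi_seq(round(d / train$grid$period), unit = "eod",
            eod_period = train$grid$period, metadata = train$metadata)
  else isi_seq(d, unit = "ms", metadata = train$metadata)
}

#' First- and second-order ISI statistics
#'
#' Mean `T1`, variance `V1`, coefficient of variation `C = sqrt(V1)/T1` and
#' the k-th order interval mean `T_k = k*T1`.
#'
#' @param x An [isi_seq()] or numeric vector of intervals.
#' @return List with `T1`, `V1`, `cv`, `n`, `unit`.
#' @export
isi_stats <- function(x) {
  unit <- if (inherits(x, "isi_seq")) x$unit else "ms"
  v <- if (inherits(x, "isi_seq")) x$intervals else as.numeric(x)
  T1 <- mean(v)
  V1 <- stats::var(v)
  list(T1 = T1, V1 = V1, cv = sqrt(V1) / T1, n = length(v), unit = unit)
}

#' Per-interval random time constants
#'
#' Container for the noisy-time-constant formulation of the encoder, in which
#' the threshold relaxation time is redrawn every interval while the spike
#' threshold stays fixed. Holds the per-interval time constants `tau_i` and
#' the implied per-interval slopes `m_i = (v - gamma + A)/tau_i`.
#'
#' @param tau_i Positive per-interval time constants (ms).
#' @param m_i Per-interval slopes (volts/ms).
#' @return Object of class `"tau_seq"`.
#' @seealso [tau_sequence_from_threshold_noise()]
#' @export
tau_seq <- function(tau_i, m_i) {
  stopifnot(is.numeric(tau_i), is.numeric(m_i), length(tau_i) == length(m_i))
  bad <- which(tau_i <= 0)
  if (length(bad))
    stop("time constants must be > 0 (first violation at index ", bad[1L],
         "); threshold noise too large")
  structure(list(tau_i = tau_i, m_i = m_i), class = "tau_seq")
}

#' @export
print.tau_seq <- function(x, ...) {
  cat(sprintf("Random time-constant sequence: %d intervals, mean tau %.4f ms\n",
              length(x$tau_i), mean(x$tau_i)))
  invisible(x)
}
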