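# Estimators applied to spike trains and ISI sequences.

#' Blockwise SCC estimator configuration
#'
#' @param M Block size in spikes (non-overlapping blocks); 1000-3000 are
#'   sensible, default 2000.
#' @param K Maximum lag (default 15).
#' @param min_blocks Minimum number of complete blocks required (default 1).
#' @return Object of class `"scc_config"`.
#' @export
scc_config <- function(M = 2000L, K = 15L, min_blocks = 1L) {
  stopifnot(M > K, K >= 1L, min_blocks >= 1L)
  structure(list(M = as.integer(M), K = as.integer(K),
                 min_blocks = as.integer(min_blocks)), class = "scc_config")
}

#' Resample a spike train onto the EOD grid
#'
#' Maps each spike time to its nearest EOD-cycle index and returns the ISIs
#' as positive integers (counts of EOD cycles). Two spikes falling in the
#' same cycle violate the one-spike-per-cycle discipline and raise an error
#' naming the offending spike.
#'
#' @param train A [spike_train()].
#' @param eod_period EOD period in ms; defaults to the train's grid period
#'   when it fires on a grid.
#' @return An [isi_seq()] in integer EOD units.
#' @export
resample_to_eod <- function(train, eod_period = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(eod_period)) {
    if (!train$grid$enabled)
      stop("'eod_period' is required for a continuous-base train")
    eod_period <- train$grid$period
  }
  if (!is.numeric(eod_period) || eod_period <= 0)
    stop("invalid parameter: 'eod_period' must be > 0")
  idx <- round(train$times / eod_period)
  coll <- which(diff(idx) == 0)
  if (length(coll))
    stop("two spikes in one EOD cycle at spike index ", coll[1L] + 1L,
         " (violates at most one spike per cycle)")
  isi_seq(diff(idx), unit = "eod", eod_period = eod_period,
          metadata = train$metadata)
}

#' Blockwise estimation of ISI serial correlation coefficients
#'
#' Estimates SCCs in non-overlapping blocks of `M` intervals. Within each
#' block, for lag `k`,
#' \deqn{\hat\rho_k = \frac{\sum_{i=1}^{M-k} (X_i - T_1)(X_{i+k} - T_1)}
#'   {\big(\sum_{i=1}^{M-k} (X_i - T_1)^2 \sum_{i=1}^{M-k} (X_{i+k} - T_1)^2\big)^{1/2}},}
#' with deviations taken about the global mean ISI \eqn{T_1} (not the block
#' mean), and the two root sums in the denominator taken over the same index
#' ranges as the numerator. Block values are averaged with equal weights
#' over the `floor(N/M)` complete blocks; the standard error is the block
#' standard deviation over the square root of the number of blocks. The
#' lag-0 coefficient is 1 by construction and is not returned.
#'
#' @param x An [isi_seq()], [spike_train()] (its ISIs are used) or numeric
#'   vector of intervals.
#' @param cfg An [scc_config()].
#' @return An estimated [scc_seq()] with `se`, `sd`, per-block matrix
#'   `blocks` (lags x blocks) and `n_blocks`.
#' @export
estimate_sccs <- function(x, cfg = scc_config()) {
  stopifnot(inherits(cfg, "scc_config"))
  if (inherits(x, "spike_train")) x <- isis(x)
  v <- if (inherits(x, "isi_seq")) x$intervals else as.numeric(x)
  M <- cfg$M; K <- cfg$K
  nb <- length(v) %/% M
  if (nb < cfg$min_blocks)
    stop("insufficient data: ", length(v), " ISIs give ", nb,
         " complete blocks of ", M, " (need ", cfg$min_blocks, ")")
  v <- v[seq_len(nb * M)]
  T1 <- mean(v)
  X <- matrix(v, nrow = M, ncol = nb) - T1
  if (any(colSums(X^2) <= 1e-300))
    stop("degenerate block: zero ISI variance within a block")
  blocks <- matrix(NA_real_, nrow = K, ncol = nb)
  for (k in seq_len(K)) {
    head_ <- X[1:(M - k), , drop = FALSE]
    tail_ <- X[(1 + k):M, , drop = FALSE]
    num <- colSums(head_ * tail_)
    den <- sqrt(colSums(head_^2) * colSums(tail_^2))
    if (any(den <= 1e-300))
      stop("degenerate block: zero ISI variance within a block")
    blocks[k, ] <- num / den
  }
  rho <- rowMeans(blocks)
  sdv <- apply(blocks, 1L, stats::sd)
  scc_seq(rho, "estimated", se = sdv / sqrt(nb),
          extra = list(sd = sdv, blocks = blocks, n_blocks = nb,
                       T1 = T1, M = M))
}

#' Partial autocorrelations by Durbin's recursion
#'
#' Computes the partial autocorrelation function from an SCC
#' sequence via Durbin's recursion
#' \deqn{\phi_{k+1,k+1} = \frac{\rho_{k+1} - \sum_j \phi_{k,j}\rho_{k+1-j}}
#'   {1 - \sum_j \phi_{k,j}\rho_j}, \qquad
#'   \phi_{k+1,j} = \phi_{k,j} - \phi_{k+1,k+1}\,\phi_{k,k+1-j},}
#' starting from `phi_{1,1} = rho_1` exactly. The intermediate coefficients
#' and the denominators are retained for audit; a denominator within
#' tolerance of zero aborts with the order at which the singularity occurs.
#'
#' @param sccs An [scc_seq()] or numeric vector of SCCs at lags `1..K`.
#' @param K Maximum order (default: full length of the input).
#' @param tol Singularity tolerance on the denominator.
#' @return Object of class `"pacf_seq"`: `phi` (the `phi_{k,k}`), the full
#'   coefficient matrix `phi_kj` (row k = AR(k) coefficients), and
#'   `denominators`.
#' @export
pacf_durbin <- function(sccs, K = NULL, tol = 1e-12) {
  rho <- scc_values(sccs)
  if (is.null(K)) K <- length(rho)
  if (length(rho) < K) stop("SCCs for lags 1..K are required")
  phi_kj <- matrix(0, K, K)
  phi <- numeric(K)
  denom <- numeric(K)
  phi[1L] <- rho[1L]
  phi_kj[1L, 1L] <- rho[1L]
  denom[1L] <- 1
  if (K > 1L) for (k in 1:(K - 1L)) {
    prev <- phi_kj[k, 1:k]
    den <- 1 - sum(prev * rho[1:k])
    if (abs(den) < tol)
      stop("Durbin recursion singular at order ", k + 1L,
           " (denominator ", signif(den, 3), ")")
    nxt <- (rho[k + 1L] - sum(prev * rho[k:1])) / den
    phi[k + 1L] <- nxt
    phi_kj[k + 1L, 1:k] <- prev - nxt * prev[k:1]
    phi_kj[k + 1L, k + 1L] <- nxt
    denom[k + 1L] <- den
  }
  if (any(abs(phi) > 1 + 1e-9))
    warning("|phi_kk| > 1: input is not a valid autocorrelation sequence")
  structure(list(phi = phi, phi_kj = phi_kj, denominators = denom,
                 lags = seq_len(K)), class = "pacf_seq")
}

#' @export
print.pacf_seq <- function(x, ...) {
  cat(sprintf("PACF (Durbin recursion), orders 1..%d:\n", length(x$phi)))
  print(round(utils::head(x$phi, 10), 4))
  invisible(x)
}

#' ISI and joint-ISI histograms
#'
#' Normalized one-dimensional ISI histogram, the joint histogram of
#' successive interval pairs `(X_i, X_{i+1})`, and a modality diagnostic: a
#' bin counts as a mode when it is a strict local maximum carrying more than
#' `mode_threshold` of the total mass. Bursting spike trains show a bimodal
#' ISI histogram with a mode near one EOD period.
#'
#' @param x An [isi_seq()] or numeric vector of intervals.
#' @param bin_width Histogram bin width (same unit as the intervals; `> 0`).
#' @param mode_threshold Minimum mass fraction for a local maximum to count
#'   as a mode (default 0.01).
#' @return Object of class `"joint_isi_hist"`: `marginal` (data frame
#'   `bin_left`, `bin_right`, `mass`), `joint` (sparse data frame `bin_i`,
#'   `bin_j`, `mass` over successive pairs), `n_modes`, `bimodal`,
#'   `bin_width`.
#' @export
isi_distributions <- function(x, bin_width, mode_threshold = 0.01) {
  v <- if (inherits(x, "isi_seq")) x$intervals else as.numeric(x)
  if (length(v) < 2L) stop("at least 2 ISIs are required")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("invalid parameter: 'bin_width' must be > 0")
  idx <- floor(v / bin_width)
  rng <- range(idx)
  bins <- rng[1L]:rng[2L]
  counts <- tabulate(idx - rng[1L] + 1L, nbins = length(bins))
  mass <- counts / length(v)
  marginal <- data.frame(bin_left = bins * bin_width,
                         bin_right = (bins + 1) * bin_width,
                         mass = mass)
  # strict local maxima above the mass threshold
  padded <- c(-Inf, mass, -Inf)
  is_peak <- mass > padded[seq_along(mass)] &
    mass > padded[seq_along(mass) + 2L] & mass > mode_threshold
  # joint distribution of successive pairs
  i1 <- idx[-length(idx)]; i2 <- idx[-1L]
  key <- paste(i1, i2)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  joint <- data.frame(bin_i = as.integer(parts[, 1L]) * bin_width,
                      bin_j = as.integer(parts[, 2L]) * bin_width,
                      mass = as.numeric(tab) / (length(v) - 1L))
  structure(list(marginal = marginal, joint = joint,
                 n_modes = sum(is_peak), bimodal = sum(is_peak) >= 2L,
                 bin_width = bin_width),
            class = "joint_isi_hist")
}

#' @export
print.joint_isi_hist <- function(x, ...) {
  cat(sprintf("ISI histogram: %d bins of width %g, %d mode(s)%s\n",
              nrow(x$marginal), x$bin_width, x$n_modes,
              if (x$bimodal) " (bimodal)" else ""))
  invisible(x)
}

#' Low-frequency spike-train power versus the correlation-sum prediction
#'
#' Bins the spike train into counts (bin width = EOD period when available,
#' otherwise a quarter of the mean ISI), takes the periodogram of the
#' mean-subtracted counts, and averages it over the lowest `band_frac` of
#' frequencies (excluding the DC bin). The empirical band power is compared
#' with the analytic zero-frequency limit
#' `C^2/(2*pi*T1) * (1 + 2*sum(rho_k))` evaluated with estimated SCCs.
#' Negative serial correlations summing to -1/2 drive this limit - and the
#' measured band power - to zero: the DC block.
#'
#' @param x A [spike_train()] or [isi_seq()] (intervals are cumulated into
#'   times).
#' @param sccs Optional pre-estimated [scc_seq()]; estimated from `x` when
#'   missing.
#' @param band_frac Fraction of the frequency axis averaged (default 0.02).
#' @param bin_width Optional count bin width in ms.
#' @return List with `empirical`, `predicted`, `ratio`, `renewal_level`
#'   (`C^2/(2*pi*T1)`, the renewal-train baseline), `band_hz`, `n_spikes`.
#'   Units are per ms per radian. Warns below 1e4 spikes.
#' @export
spectrum_dc <- function(x, sccs = NULL, band_frac = 0.02, bin_width = NULL) {
  if (inherits(x, "spike_train")) {
    times <- x$times
    P <- if (x$grid$enabled) x$grid$period else NULL
    iv <- isis(x)
  } else {
    iv <- if (inherits(x, "isi_seq")) x else
      isi_seq(as.numeric(x), unit = "ms")
    sc <- if (iv$unit == "eod") iv$eod_period else 1
    times <- cumsum(c(0, iv$intervals * sc))
    P <- iv$eod_period
  }
  st <- isi_stats(iv)
  T1_ms <- st$T1 * (if (st$unit == "eod") iv$eod_period else 1)
  n_sp <- length(times)
  if (n_sp < 1e4)
    warning("short train (", n_sp, " spikes): low-frequency power estimate is noisy")
  if (is.null(bin_width)) bin_width <- if (!is.null(P)) P else T1_ms / 4
  nb <- floor(max(times) / bin_width)
  counts <- tabulate(pmin(floor(times / bin_width) + 1L, nb), nbins = nb)
  spec <- Mod(stats::fft(counts - mean(counts)))^2 / (nb * bin_width * 2 * pi)
  jmax <- max(1L, floor(band_frac * nb / 2))
  empirical <- mean(spec[1L + seq_len(jmax)])
  if (is.null(sccs)) {
    M <- min(2000L, max(16L, length(iv$intervals) %/% 4))
    sccs <- estimate_sccs(iv, scc_config(M = M, K = 15L))
  }
  renewal <- st$cv^2 / (2 * pi * T1_ms)
  predicted <- renewal * (1 + 2 * sum(sccs$rho))
  list(empirical = empirical, predicted = predicted,
       ratio = empirical / predicted, renewal_level = renewal,
       band_hz = 1000 * jmax / (nb * bin_width), n_spikes = n_sp)
}
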