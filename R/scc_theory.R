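# Closed-form theory linking the threshold-noise autocorrelation R_k to the
# ISI serial correlation coefficients rho_k, and its inverse.

#' Serial correlation coefficient sequence
#'
#' SCCs `rho_k` for `k = 1..K` (the lag-0 coefficient is 1 by definition and
#' is not stored). Theoretical sequences enforce `|rho_k| <= 1` strictly;
#' estimated sequences may exceed 1 marginally from finite-sample noise and
#' only warn.
#'
#' @param rho Numeric vector of SCCs at lags `1..K`.
#' @param provenance `"theoretical"` or `"estimated"`.
#' @param se Optional standard errors (estimated sequences).
#' @param extra Optional named list of auxiliary results (per-block values,
#'   block count, ...).
#' @return Object of class `"scc_seq"` with fields `rho`, `lags`,
#'   `provenance` and optionally `se` plus `extra` entries.
#' @export
scc_seq <- function(rho, provenance = c("theoretical", "estimated"),
                    se = NULL, extra = list()) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(rho))
  if (any(abs(rho) > 1 + 1e-12)) {
    if (provenance == "theoretical")
      stop("theoretical SCCs must satisfy |rho_k| <= 1")
    warning("estimated SCC magnitude exceeds 1 (finite-sample noise)")
  }
  structure(c(list(rho = as.numeric(rho), lags = seq_along(rho),
                   provenance = provenance, se = se), extra),
            class = "scc_seq")
}

#' @export
print.scc_seq <- function(x, ...) {
  cat(sprintf("SCC sequence (%s), lags 1..%d:\n", x$provenance, length(x$rho)))
  print(round(utils::head(x$rho, 10), 4))
  cat(sprintf("  sum over %d lags: %.4f\n", length(x$rho), sum(x$rho)))
  invisible(x)
}

scc_values <- function(x) if (inherits(x, "scc_seq")) x$rho else as.numeric(x)

#' Forward map: noise ACF to ISI serial correlations
#'
#' For an encoder whose threshold noise has discrete autocorrelation `R_k`,
#' the ISI SCCs are the normalized second difference
#' \deqn{\rho_k = -\frac{R_{k-1} - 2R_k + R_{k+1}}{2(R_0 - R_1)}, \quad k \ge 1,}
#' independent of the deterministic encoder parameters. The result is
#' invariant to rescaling of the ACF.
#'
#' @param acf A [noise_acf()] with lags `0..K+1`.
#' @param K Maximum SCC lag; defaults to the largest supported by `acf`.
#' @return A theoretical [scc_seq()] for lags `1..K`.
#' @examples
#' scc_from_acf(noise_acf(c(1, 0, 0, 0)))$rho  # -0.5 0 (white noise)
#' @export
scc_from_acf <- function(acf, K = NULL) {
  stopifnot(inherits(acf, "noise_acf"))
  R <- acf$R
  if (is.null(K)) K <- length(R) - 2L
  if (K < 1L || length(R) < K + 2L)
    stop("ACF must provide lags 0..K+1")
  D <- 2 * (R[1L] - R[2L])
  if (abs(D) <= 1e-14 * abs(R[1L]))
    stop("degenerate denominator R0 = R1: zero ISI variance")
  k <- 1:K
  rho <- -(R[k] - 2 * R[k + 1L] + R[k + 2L]) / D
  scc_seq(rho, "theoretical")
}

#' Closed-form SCC families of the AR(1)-noise encoder
#'
#' Slow (positive-coefficient) AR(1) threshold noise yields the Type I
#' geometric family `rho_k = -a^(k-1) * (1-a)/2`: all coefficients negative,
#' increasing monotonically toward zero. Fast (negative-coefficient) noise
#' yields the Type II family `rho_k = -(-a)^(k-1) * (1+a)/2`: alternating in
#' sign and damped. Both sum to exactly -1/2 over all lags. As `a -> 0` both
#' collapse to the degenerate Type III pattern (`rho_1 = -0.5`, rest zero).
#'
#' @param a AR magnitude, `0 < a < 1`.
#' @param K Maximum lag.
#' @return A theoretical [scc_seq()].
#' @examples
#' scc_type1(0.4, 3)$rho   # -0.300 -0.120 -0.048
#' scc_type2(0.69, 2)$rho  # -0.845  0.58305
#' @export
scc_type1 <- function(a, K) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
    stop("'a' must lie in (0, 1)")
  scc_seq(-a^(0:(K - 1L)) * (1 - a) / 2, "theoretical")
}

#' @rdname scc_type1
#' @export
scc_type2 <- function(a, K) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
    stop("'a' must lie in (0, 1)")
  scc_seq(-(-a)^(0:(K - 1L)) * (1 + a) / 2, "theoretical")
}

#' Inverse map: ISI serial correlations to noise ACF
#'
#' Recovers the R0-normalized threshold-noise ACF that reproduces a given
#' SCC sequence. The forward map is a second-difference recurrence,
#' `R_{k+1} = 2R_k - R_{k-1} - D*rho_k` with `D = 2(1 - R_1)`, so the
#' inverse is closed once two boundary values are fixed. The solver uses
#' `R_0 = 1` and `R_{K+1} = 0` (the noise decorrelates at the horizon);
#' summing the telescoped first differences gives `R_1` in closed form,
#' \deqn{R_1 = 1 - 1 / (K + 1 + 2\sum_{k=1}^K (K + 1 - k)\rho_k),}
#' after which the recurrence fills in the interior lags.
#'
#' Continuing the recurrence one step past the horizon (with
#' `rho_{K+1} = 0`) gives `R_{K+2} = -R_K`; its magnitude is reported as a
#' consistency diagnostic, and it vanishes exactly when the partial sum of
#' the input SCCs equals -1/2. Solutions violating wide-sense stationarity
#' (`|R_k| > 1`) are returned with a warning.
#'
#' @param sccs An [scc_seq()] (or numeric vector) with lags `1..K`.
#' @param K Horizon; defaults to the length of the input.
#' @return A [noise_acf()] with lags `0..K+1` (`R_{K+1} = 0`),
#'   normalization `"R0"`, carrying attributes `residual` (`|R_{K+2}|`) and
#'   `scc_sum` (the partial sum of the input).
#' @examples
#' acf_from_scc(c(-0.5, 0, 0))$R  # 1 0 0 0 0 (white noise)
#' @export
acf_from_scc <- function(sccs, K = NULL) {
  rho <- scc_values(sccs)
  if (is.null(K)) K <- length(rho)
  if (K < 1L || length(rho) < K) stop("SCCs for lags 1..K are required")
  rho <- rho[1:K]
  k <- 1:K
  denom <- K + 1 + 2 * sum((K + 1 - k) * rho)
  if (abs(denom) < 1e-12)
    stop("degenerate inverse problem: boundary system is singular (D = 0)")
  d0 <- -1 / denom                    # first difference R_1 - R_0
  D <- -2 * d0                        # = 2 * (1 - R_1)
  d <- c(d0, d0 - D * cumsum(rho))    # differences d_0 .. d_K
  R <- c(1, 1 + cumsum(d))            # lags 0 .. K+1
  residual <- abs(R[K + 1L])          # |R_{K+2}| = |2 R_{K+1} - R_K| at boundary
  R[K + 2L] <- 0                      # enforce the boundary exactly
  if (any(abs(R[-1L]) > 1 + 1e-9))
    warning("inverse solution violates |R_k| <= R0: non-physical ACF ",
            "(input SCCs are not realizable by a stationary threshold noise)")
  out <- structure(list(R = R, lags = 0:(K + 1L), normalization = "R0"),
                   class = "noise_acf")
  attr(out, "residual") <- residual
  attr(out, "scc_sum") <- sum(rho)
  out
}

#' Estimate the AR parameter from serial correlations
#'
#' Inverts the closed-form SCC families: for Type I patterns
#' `a = 1 + 2*rho_1` or, usually more robustly, `a = rho_2/rho_1`; for
#' Type II patterns the signs flip (`a = -(1 + 2*rho_1)` or
#' `a = -rho_2/rho_1`). The estimate is clipped to `[0, 1)`; a `clipped`
#' attribute records when this happened.
#'
#' @param sccs An [scc_seq()] or numeric vector (lags 1..).
#' @param method `"ratio"` (default) or `"rho1"`.
#' @param pattern Optional [classify_pattern()] label; classified from the
#'   input when missing.
#' @return Estimated magnitude `a` with attributes `pattern` and `clipped`.
#' @examples
#' estimate_a(c(-0.3, -0.12))            # 0.4
#' estimate_a(c(-0.845, 0.583), "rho1")  # 0.69
#' @export
estimate_a <- function(sccs, method = c("ratio", "rho1"), pattern = NULL) {
  method <- match.arg(method)
  rho <- scc_values(sccs)
  if (length(rho) < 2L) stop("SCCs at lags 1 and 2 are required")
  if (is.null(pattern)) pattern <- classify_pattern(sccs)
  if (pattern == "OTHER")
    stop("SCC pattern is not of Type I/II/III; no AR(1) parameter exists")
  if (pattern == "TYPE_III" && method == "ratio")
    stop("ratio estimator undefined for a Type III pattern (rho_2 = 0)")
  if (rho[1L] >= 0 || rho[1L] <= -1)
    stop("rho_1 must lie in (-1, 0)")
  s <- if (pattern == "TYPE_II") -1 else 1
  a <- switch(method,
              rho1  = s * (1 + 2 * rho[1L]),
              ratio = s * rho[2L] / rho[1L])
  clipped <- a < 0 || a >= 1
  a <- min(max(a, 0), 1 - 1e-9)
  structure(a, pattern = pattern, clipped = clipped)
}

#' Partial sums of serial correlations
#'
#' Cumulative sums `sum_{k=1}^{j} rho_k`. For any SCC sequence produced by
#' the forward map from a decorrelating noise ACF, the total telescopes to
#' exactly -1/2 up to the truncation tail - the limiting-sum property that
#' makes the spike train a perfect DC block.
#'
#' @param sccs An [scc_seq()] or numeric vector.
#' @return Numeric vector of partial sums by lag.
#' @export
limiting_sum <- function(sccs) cumsum(scc_values(sccs))

#' DC power of the spike train
#'
#' The power spectrum of a stationary spike train at zero frequency is
#' `P(0) = C^2/(2*pi*T1) * (1 + 2*sum(rho_k))` with `T1` the mean ISI and
#' `C` the ISI coefficient of variation. With the limiting sum -1/2 the DC
#' power vanishes identically (perfect DC block); for a renewal train
#' (all `rho = 0`) it equals `C^2/(2*pi*T1)`.
#'
#' @param stats Output of [isi_stats()] (or any list with `T1` and `cv`).
#' @param sccs An [scc_seq()], numeric vector, or a pre-computed sum given
#'   as a length-1 list `list(sum = s)`.
#' @return Power density at `omega -> 0` (per ms per radian when `T1` is ms).
#' @export
dc_power <- function(stats, sccs) {
  stopifnot(is.list(stats), !is.null(stats$T1), !is.null(stats$cv))
  if (stats$T1 <= 0) stop("'T1' must be > 0")
  s <- if (is.list(sccs) && !is.null(sccs$sum) && !inherits(sccs, "scc_seq"))
    sccs$sum else sum(scc_values(sccs))
  stats$cv^2 / (2 * pi * stats$T1) * (1 + 2 * s)
}

#' Classify the serial-correlation pattern
#'
#' Deterministic assignment of the observed SCC pattern:
#' * `TYPE_III` - `rho_1 = -0.5` and all later coefficients zero, within
#'   `tol` (white threshold noise; degenerate singleton).
#' * `TYPE_I` - `-0.5 < rho_1 < 0` with `rho_2` on the negative side of
#'   `tol` (monotone negative, non-bursting).
#' * `TYPE_II` - `rho_1 < -0.5` with `rho_2 > 0` (alternating, bursting).
#' * `OTHER` - anything else.
#'
#' @param sccs An [scc_seq()] or numeric vector with at least lags 1-2.
#' @param tol Classification tolerance; the default 0.02 is roughly the
#'   blockwise estimator noise at 2.5e5 spikes.
#' @return One of `"TYPE_I"`, `"TYPE_II"`, `"TYPE_III"`, `"OTHER"`.
#' @export
classify_pattern <- function(sccs, tol = 0.02) {
  rho <- scc_values(sccs)
  if (length(rho) < 2L) stop("at least lags 1 and 2 are required")
  if (abs(rho[1L] + 0.5) <= tol && all(abs(rho[-1L]) <= tol)) return("TYPE_III")
  if (rho[1L] > -0.5 && rho[1L] < 0 && rho[2L] < tol) return("TYPE_I")
  if (rho[1L] < -0.5 && rho[2L] > 0) return("TYPE_II")
  "OTHER"
}
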