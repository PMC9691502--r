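# Shared constructors and independent oracles used across the test files.

# Matched Type I configuration (non-bursting afferent)
fig_type1 <- function() {
  list(params = model_params(1.845, 0.15, 30),
       spec = ar_noise_spec(0.4, +1, R0 = 1.07e-3),
       grid = eod_grid(1.06))
}

# Matched Type II configuration, moderate bursting
fig_type2_moderate <- function() {
  list(params = model_params(1.845, 0.28, 26),
       spec = ar_noise_spec(0.29, -1, R0 = 9.22e-3),
       grid = eod_grid(1.31))
}

# Matched Type II configuration, strong bursting
fig_type2_strong <- function() {
  list(params = model_params(1.845, 0.19, 60),
       spec = ar_noise_spec(0.69, -1, R0 = 6.4e-3),
       grid = eod_grid(1.04))
}

# Brute-force PACF oracle: solve the full Yule-Walker system at each order
# and take the last coefficient. Independent of the Durbin recursion.
pacf_yule_walker <- function(rho, K) {
  vapply(seq_len(K), function(k) {
    if (k == 1L) return(rho[1L])
    Rm <- stats::toeplitz(c(1, rho[seq_len(k - 1L)]))
    solve(Rm, rho[seq_len(k)])[k]
  }, numeric(1))
}

# Random valid (positive semidefinite) normalized autocorrelation sequence:
# inverse DFT of a nonnegative random spectrum is always a valid ACF.
random_valid_scc <- function(K, m = 64L) {
  s <- stats::runif(m)
  R <- Re(stats::fft(s))
  (R[2:(K + 1L)] / R[1L])
}

# Sample autocorrelation at a single lag (plain, whole-sequence; used as an
# independent cross-check of the blockwise estimator where exactness is not
# at stake)
sample_acf_lag <- function(x, k) {
  x <- x - mean(x)
  n <- length(x)
  sum(x[1:(n - k)] * x[(1 + k):n]) / sum(x^2)
}
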