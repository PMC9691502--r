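test_that("parameter invariants are enforced with informative errors", {
  expect_error(model_params(-1, 0.1, 30), "'v'")
  expect_error(model_params(1, -0.1, 30), "'A'")
  expect_error(model_params(1, 0.1, 0), "'tau'")
  expect_error(model_params(1, 0.1, 30, gamma = 2), "v - gamma")
  expect_error(eod_grid(0), "period")
  # default spike threshold is half the jump
  expect_equal(model_params(1.845, 0.15, 30)$gamma, 0.075)
})

test_that("deterministic firing rule gives constant ISIs A*tau/(v-gamma+A)", {
  p <- model_params(1.845, 0.15, 30, gamma = 0.075)
  st <- simulate_deterministic(p, 50)
  expect_equal(st$times[1], 0)
  expect_equal(diff(st$times), rep(4.5 / 1.92, 49))  # = 2.34375 ms
  # v = gamma: the jump and threshold gap cancel, ISI = tau
  p2 <- model_params(1, 0.2, 17, gamma = 1 - 1e-12)
  expect_equal(deterministic_isi(p2), 17, tolerance = 1e-9)
  # A -> 0: ISI vanishes
  p3 <- model_params(1.845, 1e-12, 30, gamma = 0.075)
  expect_lt(deterministic_isi(p3), 1e-10)
  expect_error(simulate_deterministic(p, 1), "at least 2")
})

test_that("linearized stochastic rule: ISI_i = (g_i - g_{i-1} + A)/m", {
  p <- model_params(1.845, 0.15, 30, gamma = 0.075)
  m <- slope(p)
  # zero noise reduces to the deterministic rule
  iv0 <- simulate_linearized(p, numeric(11))
  expect_equal(iv0$intervals, rep(p$A / m, 10))
  # a single threshold excursion +delta produces equal and opposite
  # deviations in the two adjacent intervals
  d <- 0.02
  iv <- simulate_linearized(p, c(0, d, 0))
  expect_equal(iv$intervals, c((d + p$A) / m, (-d + p$A) / m))
  expect_equal(sum(iv$intervals - p$A / m), 0)
  # nonpositive interval is a hard error naming the index
  expect_error(simulate_linearized(p, c(0, -0.2, 0)), "index 1")
  expect_error(simulate_linearized(p, c(0, 0.01, -0.2)), "index 2")
})

test_that("linearized mean ISI converges to A/m and SCCs match theory", {
  p <- model_params(1.845, 0.15, 30)
  spec <- ar_noise_spec(0.4, +1, snr_db = 40, v = p$v)
  iv <- simulate_linearized(p, generate_ar1(spec, 2e5 + 1, seed = 42))
  expect_equal(mean(iv$intervals), p$A / slope(p), tolerance = 0.01)
  est <- estimate_sccs(iv)
  # closed form for slow AR(1) threshold noise: rho_1 = -(1 - a)/2
  expect_equal(est$rho[1], -0.3, tolerance = 3 * est$se[1] / 0.3 + 0.01)
})

test_that("exponential simulator solves the threshold crossing exactly", {
  p <- model_params(1.845, 0.15, 30)  # gamma = A/2 = 0.075
  st <- simulate_exponential(p, numeric(21))
  expect_equal(diff(st$times), rep(30 * log(1.92 / 1.77), 20))  # 2.440369 ms
  # deterministic ISIs of the exponential and linearized rules agree to
  # second order in A/(v - gamma)
  u <- p$A / (p$v - p$gamma)
  expect_lt(abs(deterministic_isi(p, "exponential") - deterministic_isi(p)),
            p$tau * u^2)
  expect_error(simulate_exponential(p, c(0, 1.8, 0)), "no threshold crossing")
})

test_that("EOD grid quantizes spike times and enforces one spike per cycle", {
  p <- model_params(1.845, 0.15, 30)
  # grid period larger than the continuous ISI: every ISI is one period
  g <- eod_grid(3.0)
  st <- simulate_exponential(p, numeric(11), grid = g)
  expect_equal(diff(st$times), rep(3.0, 10))
  # generic grid: times are exact multiples, ISIs at least one period
  g2 <- eod_grid(1.06)
  noise <- generate_ar1(ar_noise_spec(0.4, 1, R0 = 1.07e-3), 2001, seed = 5)
  st2 <- simulate_exponential(p, noise, grid = g2)
  k <- st2$times / 1.06
  expect_equal(k, round(k), tolerance = 1e-9)
  expect_true(all(diff(st2$times) >= 1.06 - 1e-9))
  # spikes are emitted at the first grid point at or after the crossing
  st3 <- simulate_exponential(p, numeric(4), grid = g2)
  cont <- 30 * log(1.92 / 1.77)
  expect_equal(st3$times[2], 1.06 * ceiling(cont / 1.06))
})

test_that("noisy time-constant formulation is equivalent to a noisy threshold", {
  p <- model_params(1.845, 0.15, 30)
  # zero noise: all tau_i equal tau
  ts0 <- tau_sequence_from_threshold_noise(p, numeric(6))
  expect_equal(ts0$tau_i, rep(30, 5))
  # direct substitution: excursion to A/2 and back
  ts1 <- tau_sequence_from_threshold_noise(p, c(0, p$A / 2, 0))
  expect_equal(ts1$tau_i, c(1.5, 0.5) * p$tau)
  # excursion to A hits the tau = 0 boundary
  expect_error(tau_sequence_from_threshold_noise(p, c(0, p$A, 0)), "index 2")
  # same noise realization: identical linearized spike times, and the tau_i
  # carry exactly the serial correlations of the ISIs
  noise <- generate_ar1(ar_noise_spec(0.4, 1, snr_db = 42, v = p$v),
                        5e4 + 1, seed = 11)
  iv <- simulate_linearized(p, noise)
  ts <- tau_sequence_from_threshold_noise(p, noise)
  expect_equal(p$A / ts$m_i, iv$intervals, tolerance = 1e-12)
  scc_isi <- estimate_sccs(iv, scc_config(M = 1000, K = 5))
  scc_tau <- estimate_sccs(ts$tau_i, scc_config(M = 1000, K = 5))
  expect_equal(scc_tau$rho, scc_isi$rho, tolerance = 1e-10)
})

test_that("serial correlations do not depend on the deterministic parameters", {
  # with the same noise realization the linearized ISIs are an affine map of
  # the noise differences, so the SCCs are identical across encoders
  spec <- ar_noise_spec(0.5, +1, R0 = 1e-5)
  noise <- generate_ar1(spec, 4e4 + 1, seed = 3)
  cfg <- scc_config(M = 1000, K = 8)
  base <- estimate_sccs(simulate_linearized(model_params(1.845, 0.15, 30),
                                            noise), cfg)
  for (p in list(model_params(1.845, 0.15, 30, gamma = 0),
                 model_params(0.9, 0.07, 12),
                 model_params(3.2, 0.4, 55))) {
    alt <- estimate_sccs(simulate_linearized(p, noise), cfg)
    expect_equal(alt$rho, base$rho, tolerance = 1e-10)
  }
})

test_that("burn-in discards initial intervals and re-zeroes the train", {
  p <- model_params(1.845, 0.15, 30)
  noise <- generate_ar1(ar_noise_spec(0.3, 1, R0 = 1e-4), 201, seed = 1)
  st <- simulate_exponential(p, noise, burn_in = 50)
  expect_equal(length(st$times), 151)
  expect_equal(st$times[1], 0)
})
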