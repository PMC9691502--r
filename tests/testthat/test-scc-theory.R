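test_that("forward map: white threshold noise gives the degenerate pattern", {
  sccs <- scc_from_acf(noise_acf(c(2, 0, 0, 0, 0, 0)))
  expect_equal(sccs$rho, c(-0.5, 0, 0, 0))
  expect_equal(classify_pattern(sccs, tol = 1e-6), "TYPE_III")
})

test_that("forward map reproduces the closed-form geometric families", {
  K <- 10
  a1 <- acf_ar1(ar_noise_spec(0.4, +1, R0 = 1), K + 1)
  expect_equal(scc_from_acf(a1)$rho, scc_type1(0.4, K)$rho)
  expect_equal(scc_type1(0.4, 3)$rho, c(-0.3, -0.12, -0.048))
  a2 <- acf_ar1(ar_noise_spec(0.69, -1, R0 = 1), K + 1)
  expect_equal(scc_from_acf(a2)$rho, scc_type2(0.69, K)$rho)
  expect_equal(scc_type2(0.69, 3)$rho, c(-0.845, 0.58305, -0.4023045))
  # Type I family structure: all negative, increasing toward zero
  r1 <- scc_type1(0.4, 20)$rho
  expect_true(all(r1 < 0) && all(diff(r1) > 0))
  # Type II: alternating and damped
  r2 <- scc_type2(0.69, 20)$rho
  expect_true(all(sign(r2) == rep(c(-1, 1), 10)))
  expect_true(all(diff(abs(r2)) < 0))
  # geometric progression with ratio +-a; a -> 0 limit collapses to Type III
  expect_equal(r1[-1] / r1[-20], rep(0.4, 19))
  expect_equal(r2[-1] / r2[-20], rep(-0.69, 19))
  expect_equal(scc_type1(1e-9, 2)$rho, c(-0.5, 0), tolerance = 1e-8)
  expect_error(scc_type1(1.2, 5), "in \\(0, 1\\)")
})

test_that("forward map is scale invariant and separable", {
  R <- Re(stats::fft(stats::runif(32, 0.5, 1.5)))  # random valid ACF
  acf1 <- noise_acf(R[1:12])
  acf2 <- noise_acf(7.3 * R[1:12])
  expect_equal(scc_from_acf(acf1)$rho, scc_from_acf(acf2)$rho)
  # separability: rho_1 = -1/2 + (R_1 - R_2)/(2 (R_0 - R_1))
  rho <- scc_from_acf(acf1)$rho
  expect_equal(rho[1], -0.5 + (R[2] - R[3]) / (2 * (R[1] - R[2])))
  expect_error(scc_from_acf(noise_acf(c(1, 1, 1))), "degenerate")
})

test_that("telescoping identity links partial SCC sums to the ACF tail", {
  set.seed(4)
  R <- Re(stats::fft(stats::runif(64, 0.2, 1)))
  acf <- noise_acf(R[1:22])
  sccs <- scc_from_acf(acf)   # lags 1..20
  for (K in c(1, 5, 10, 20)) {
    lhs <- sum(sccs$rho[1:K])
    rhs <- -(R[1] - R[2] - R[K + 1] + R[K + 2]) / (2 * (R[1] - R[2]))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("limiting sum of the closed-form families is exactly -1/2", {
  expect_equal(sum(scc_type1(0.4, 1000)$rho), -0.5, tolerance = 1e-12)
  expect_equal(sum(scc_type2(0.69, 1000)$rho), -0.5, tolerance = 1e-12)
  # Type III reaches -1/2 at the first lag and stays there
  ps <- limiting_sum(c(-0.5, 0, 0, 0))
  expect_equal(ps, rep(-0.5, 4))
  # partial sums are cumulative
  expect_equal(limiting_sum(scc_type1(0.5, 3)),
               cumsum(c(-0.25, -0.125, -0.0625)))
})

test_that("inverse map recovers AR(1) ACFs and flags inconsistency", {
  # round trip at machine-level accuracy for both signs and a range of a
  for (a in c(0.2, 0.4, 0.69)) for (sgn in c(1, -1)) {
    K <- 70
    target <- (sgn * a)^(0:K)
    fam <- if (sgn > 0) scc_type1(a, K) else scc_type2(a, K)
    sol <- acf_from_scc(fam)
    expect_lt(max(abs(sol$R[1:(K + 1)] - target)), 1e-8)
    expect_lt(attr(sol, "residual"), 1e-8)
  }
  # white-noise case
  sol <- acf_from_scc(c(-0.5, 0, 0))
  expect_equal(sol$R, c(1, 0, 0, 0, 0))
  expect_equal(attr(sol, "residual"), 0)
  # the residual diagnostic vanishes iff the partial sum reaches -1/2:
  # truncating a slowly decaying family leaves a visible residual
  short <- acf_from_scc(scc_type1(0.8, 6)$rho)
  expect_gt(attr(short, "residual"), 1e-3)
  expect_gt(abs(attr(short, "scc_sum") + 0.5), 1e-3)
  # non-realizable SCCs warn about a non-physical ACF
  expect_warning(acf_from_scc(c(-0.9, -0.4, 0.1)), "non-physical")
})

test_that("inverse map round-trips arbitrary decorrelating ACFs", {
  set.seed(12)
  for (rep in 1:5) {
    # smooth random PSD ACF with a decaying tail
    spec_w <- stats::runif(256, 0.2, 1)
    R <- Re(stats::fft(spec_w))[1:45]
    R <- R * exp(-(0:44) / 4)   # force decorrelation within the horizon
    acf <- noise_acf(R / R[1])
    sccs <- scc_from_acf(acf)   # lags 1..43
    sol <- acf_from_scc(sccs)
    # accurate up to the neglected tail beyond the horizon
    expect_lt(max(abs(sol$R[1:44] - acf$R[1:44])), 1e-6)
  }
})

test_that("AR parameter estimation inverts the closed forms", {
  expect_equal(as.numeric(estimate_a(c(-0.3, -0.12), "ratio")), 0.4)
  expect_equal(as.numeric(estimate_a(c(-0.3, -0.12), "rho1")), 0.4)
  expect_equal(as.numeric(estimate_a(c(-0.845, 0.58305), "ratio")), 0.69)
  expect_equal(as.numeric(estimate_a(c(-0.845, 0.58305), "rho1")), 0.69)
  expect_equal(attr(estimate_a(c(-0.3, -0.12)), "pattern"), "TYPE_I")
  # clipping is flagged
  a <- estimate_a(c(-0.2, -0.19), "ratio")  # ratio 0.95 < 1, fine
  expect_false(attr(a, "clipped"))
  a2 <- estimate_a(c(-0.45, -0.45), "ratio")  # ratio 1: clipped to < 1
  expect_true(attr(a2, "clipped"))
  expect_error(estimate_a(c(-0.5, 0), "ratio"), "Type III")
  expect_equal(as.numeric(estimate_a(c(-0.5, 0), "rho1")), 0)
})

test_that("DC power follows the correlation sum", {
  st <- list(T1 = 2.42, cv = 0.3)
  # perfect DC block at the limiting sum
  expect_equal(dc_power(st, list(sum = -0.5)), 0)
  # renewal level with no correlations
  expect_equal(dc_power(st, numeric(5)), 0.3^2 / (2 * pi * 2.42))
  # partial cancellation
  expect_equal(dc_power(st, list(sum = -0.475)),
               0.3^2 / (2 * pi * 2.42) * 0.05)
  expect_equal(dc_power(st, scc_type1(0.4, 2000)), 0, tolerance = 1e-10)
})

test_that("pattern classification follows the rho_1 / rho_2 rules", {
  expect_equal(classify_pattern(c(-0.3, -0.12, -0.05)), "TYPE_I")
  expect_equal(classify_pattern(c(-0.7, 0.4, -0.2)), "TYPE_II")
  expect_equal(classify_pattern(c(-0.5, 0, 0), tol = 1e-6), "TYPE_III")
  expect_equal(classify_pattern(c(0.3, 0.1)), "OTHER")
  expect_equal(classify_pattern(c(-0.7, -0.3)), "OTHER")
  # tolerance window around the degenerate pattern
  expect_equal(classify_pattern(c(-0.49, 0.01, -0.015)), "TYPE_III")
})
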