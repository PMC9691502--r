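# Matching model parameters to target spike-train statistics.

#' Fit the deterministic encoder to a mean ISI
#'
#' The deterministic parameters satisfy the linearized matching identity
#' `A*tau = v*T1`. Fixing one of `A` or `tau` determines the other; the
#' spike threshold is set to its default `gamma = A/2`. A consistency check
#' warns when the exact exponential-decay deterministic ISI deviates from
#' the target `T1` by more than 5% (the linearization degrades when the ISI
#' is not small against `tau`).
#'
#' @param T1 Target mean ISI (ms), `> 0`.
#' @param v Bias voltage (volts); the SCCs do not depend on it, the default
#'   1.845 V is kept for reproducibility of the printed configurations.
#' @param free_param Which parameter to solve for: `"A"` (with `tau` fixed
#'   at `fixed_value`) or `"tau"` (with `A` fixed).
#' @param fixed_value Value of the fixed parameter (`> 0`).
#' @return A [model_params()] object.
#' @examples
#' fit_deterministic(2.42, free_param = "A", fixed_value = 30)$A  # 0.14883
#' @export
fit_deterministic <- function(T1, v = 1.845, free_param = c("A", "tau"),
                              fixed_value) {
  free_param <- match.arg(free_param)
  if (!is.numeric(T1) || T1 <= 0) stop("invalid parameter: 'T1' must be > 0")
  if (!is.numeric(v) || v <= 0) stop("invalid parameter: 'v' must be > 0")
  if (!is.numeric(fixed_value) || fixed_value <= 0)
    stop("invalid parameter: 'fixed_value' must be > 0")
  if (free_param == "A") {
    tau <- fixed_value
    A <- v * T1 / tau
  } else {
    A <- fixed_value
    tau <- v * T1 / A
  }
  p <- model_params(v = v, A = A, tau = tau)
  isi_exp <- deterministic_isi(p, "exponential")
  if (abs(isi_exp - T1) / T1 > 0.05)
    warning(sprintf(paste0("exponential-model deterministic ISI (%.4f ms) ",
                           "deviates from target T1 (%.4f ms) by more than 5%%"),
                    isi_exp, T1))
  p
}

#' Fit AR(1) threshold noise to observed serial correlations
#'
#' Classifies the SCC pattern, chooses the AR sign accordingly, and
#' estimates the magnitude `a` by the ratio method (`rho_2/rho_1`, sign per
#' type) with the `1 + 2*rho_1` inversion as fallback when the ratio falls
#' outside `[0, 1)`. Type III patterns give white noise (`a = 0`). The
#' noise power comes from `R0` directly or from the SNR as
#' `R0 = v^2 * 10^(-SNR/10)`.
#'
#' @param sccs An [scc_seq()] or numeric vector with at least lags 1-2.
#' @param snr_db Signal-to-noise ratio in dB (alternative to `R0`).
#' @param R0 Noise power (volts^2).
#' @param v Bias voltage (volts).
#' @param tol Classification tolerance passed to [classify_pattern()].
#' @return An [ar_noise_spec()] with attribute `pattern`.
#' @examples
#' fit_noise(c(-0.3, -0.12), snr_db = 35)$a   # 0.4
#' fit_noise(c(-0.845, 0.583), snr_db = 27)$a # 0.69
#' @export
fit_noise <- function(sccs, snr_db = NULL, R0 = NULL, v = 1.845, tol = 0.02) {
  pattern <- classify_pattern(sccs, tol = tol)
  if (pattern == "OTHER")
    stop("unfittable SCC pattern: neither Type I, II nor III")
  if (pattern == "TYPE_III") {
    spec <- ar_noise_spec(0, 0, R0 = R0, snr_db = snr_db, v = v)
  } else {
    sgn <- if (pattern == "TYPE_I") 1 else -1
    a <- estimate_a(sccs, "ratio", pattern)
    if (attr(a, "clipped"))
      a <- estimate_a(sccs, "rho1", pattern)
    spec <- ar_noise_spec(as.numeric(a), sgn, R0 = R0, snr_db = snr_db, v = v)
  }
  attr(spec, "pattern") <- pattern
  spec
}

#' Match a full model configuration to target statistics and verify it
#'
#' Assembles a complete encoder configuration (deterministic parameters,
#' AR(1) threshold noise, EOD grid) reproducing target spike-train summary
#' statistics, then verifies it by simulation. Deterministic parameters come
#' from `A*tau = v*T1`; the initial noise magnitude from the target SCC
#' pattern and the initial power from the linearized ISI-variance relation
#' `V1 = 2*R0*(1 -+ a)/m^2`. Because EOD-grid quantization and the
#' exponential nonlinearity shift the achieved correlations away from the
#' linearized closed forms, the magnitude `a` is then re-tuned by a bounded
#' secant iteration on the achieved versus target `rho_1`, and `R0` (never
#' `a`) is rescaled to match the target coefficient of variation; at most
#' `max_iter` rounds. Verification simulates the exponential-decay model on
#' the EOD grid and re-estimates all statistics.
#'
#' @param target Named list with `T1` (ms), `cv`, `rho1`, `rho2`,
#'   `eod_period` (ms).
#' @param sim_length Number of intervals per verification run.
#' @param seed Integer seed for the verification simulations.
#' @param tau Fixed threshold relaxation time (ms) handed to
#'   [fit_deterministic()].
#' @param v Bias voltage (volts).
#' @param max_iter Iteration cap (default 20).
#' @param tol_rho Convergence tolerance on `rho_1` (default 0.02).
#' @param tol_cv Relative convergence tolerance on the CV (default 0.05).
#' @return Object of class `"matched_model"`: `params`, `noise`, `grid`,
#'   `target`, `achieved` (T1 ms, cv, rho1, rho2, scc_sum, pattern),
#'   `converged`, `iterations`, `seed`.
#' @export
match_and_verify <- function(target, sim_length = 2e5, seed = NULL,
                             tau = 30, v = 1.845, max_iter = 20L,
                             tol_rho = 0.02, tol_cv = 0.05) {
  need <- c("T1", "cv", "rho1", "rho2", "eod_period")
  miss <- setdiff(need, names(target))
  if (length(miss))
    stop("incomplete target statistics: missing ", paste(miss, collapse = ", "))
  params <- fit_deterministic(target$T1, v = v, free_param = "A",
                              fixed_value = tau)
  grid <- eod_grid(target$eod_period)
  m <- slope(params)
  pattern <- classify_pattern(c(target$rho1, target$rho2))
  spec0 <- fit_noise(c(target$rho1, target$rho2), R0 = 1, v = v)  # sign + a
  sgn <- spec0$sign
  a <- spec0$a
  # linearized variance relation as the starting noise power
  R0 <- (target$cv * target$T1 * m)^2 / (2 * (1 - sgn * a))
  achieved <- NULL; converged <- FALSE
  a_prev <- NA_real_; f_prev <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    run_seed <- if (is.null(seed)) NULL else seed + it
    noise <- generate_ar1(ar_noise_spec(a, sgn, R0 = R0),
                          sim_length + 101L, seed = run_seed)
    st <- simulate_exponential(params, noise, grid = grid, burn_in = 100L)
    iv <- resample_to_eod(st)
    est <- estimate_sccs(iv)
    s <- isi_stats(iv)
    achieved <- list(T1 = s$T1 * grid$period, cv = s$cv,
                     rho1 = est$rho[1L], rho2 = est$rho[2L],
                     scc_sum = sum(est$rho),
                     pattern = classify_pattern(est))
    f <- achieved$rho1 - target$rho1
    cv_ok <- abs(achieved$cv / target$cv - 1) <= tol_cv
    if (abs(f) <= tol_rho && cv_ok) { converged <- TRUE; break }
    # rescale noise power toward the target CV (never touches a)
    R0 <- R0 * (target$cv / achieved$cv)^2
    if (pattern != "TYPE_III" && abs(f) > tol_rho) {
      # bounded secant step on a; d(rho1)/da = +-1/2 in the linearized limit
      slope_f <- if (!is.na(a_prev) && abs(a - a_prev) > 1e-6 &&
                     abs(f - f_prev) > 1e-9)
        (f - f_prev) / (a - a_prev) else sgn * 0.5
      a_prev <- a; f_prev <- f
      step <- f / slope_f
      a <- min(max(a - step, 1e-3), 0.98)
    }
  }
  structure(list(params = params, noise = ar_noise_spec(a, sgn, R0 = R0),
                 grid = grid, target = target, achieved = achieved,
                 converged = converged, iterations = it, seed = seed),
            class = "matched_model")
}

#' @export
print.matched_model <- function(x, ...) {
  cat("Matched dynamic-threshold model",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$params)
  print(x$noise)
  tg <- x$target; ac <- x$achieved
  tab <- rbind(target = c(tg$T1, tg$cv, tg$rho1, tg$rho2, NA),
               achieved = c(ac$T1, ac$cv, ac$rho1, ac$rho2, ac$scc_sum))
  colnames(tab) <- c("T1_ms", "cv", "rho1", "rho2", "scc_sum")
  print(round(tab, 4))
  invisible(x)
}

#' Serialize or restore a matched model
#'
#' @param model A `"matched_model"`.
#' @param path JSON file path.
#' @return `read_matched_model()` returns the restored `"matched_model"`;
#'   `write_matched_model()` returns `path` invisibly.
#' @export
write_matched_model <- function(model, path) {
  stopifnot(inherits(model, "matched_model"))
  out <- list(params = unclass(model$params),
              noise = unclass(model$noise),
              eod_period = model$grid$period,
              target = model$target, achieved = model$achieved,
              converged = model$converged, iterations = model$iterations,
              seed = model$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_matched_model
#' @export
read_matched_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    params = model_params(x$params$v, x$params$A, x$params$tau, x$params$gamma),
    noise = ar_noise_spec(x$noise$a, x$noise$sign, R0 = x$noise$R0),
    grid = eod_grid(x$eod_period),
    target = x$target, achieved = x$achieved,
    converged = x$converged, iterations = x$iterations,
    seed = x$seed), class = "matched_model")
}
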