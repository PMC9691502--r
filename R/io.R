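# Plain-text input/output: spike times, ISI sequences, ACF and SCC tables,
# analysis reports, and the fixture generator.

header_lines <- function(meta) {
  if (!length(meta)) return(character())
  flat <- unlist(meta)
  sprintf("# %s: %s", names(flat), as.character(flat))
}

parse_header <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2L) out[[trimws(p[1L])]] <- trimws(p[2L])
  out
}

#' Read and write spike-time files
#'
#' Spike times are stored one per line in ms at fixed precision (6 decimal
#' places), preceded by `#`-prefixed header lines carrying metadata
#' (parameters, seed, time base, EOD period). Reading validates that the
#' entries are numeric and strictly increasing and reports the offending
#' line number otherwise.
#'
#' @param train A [spike_train()].
#' @param path File path.
#' @return `read_spike_times()` returns a [spike_train()];
#'   `write_spike_times()` returns `path` invisibly.
#' @export
write_spike_times <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  meta <- c(list(time_base = if (train$grid$enabled) "eod_grid" else "continuous"),
            if (train$grid$enabled) list(eod_period = train$grid$period),
            train$metadata)
  writeLines(c(header_lines(meta), sprintf("%.6f", train$times)), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("empty spike-time file: ", path)
  times <- suppressWarnings(as.numeric(trimws(lines[body_idx])))
  if (anyNA(times))
    stop("non-numeric spike time at line ", body_idx[which(is.na(times))[1L]])
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop("non-increasing spike time at line ", body_idx[bad[1L] + 1L])
  meta <- parse_header(lines[is_hdr])
  grid <- if (identical(meta$time_base, "eod_grid"))
    eod_grid(as.numeric(meta$eod_period)) else eod_grid()
  spike_train(times, grid = grid, metadata = meta)
}

#' Read and write ISI-sequence files
#'
#' Single-column text with the unit tag (`ms` or `eod`) and any further
#' metadata in `#`-prefixed header lines.
#'
#' @param x An [isi_seq()].
#' @param path File path.
#' @return `read_isis()` returns an [isi_seq()]; `write_isis()` returns
#'   `path` invisibly.
#' @export
write_isis <- function(x, path) {
  stopifnot(inherits(x, "isi_seq"))
  meta <- c(list(unit = x$unit),
            if (!is.null(x$eod_period)) list(eod_period = x$eod_period),
            x$metadata)
  vals <- if (x$unit == "eod") sprintf("%d", as.integer(x$intervals))
          else sprintf("%.6f", x$intervals)
  writeLines(c(header_lines(meta), vals), path)
  invisible(path)
}

#' @rdname write_isis
#' @export
read_isis <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("empty ISI file: ", path)
  vals <- suppressWarnings(as.numeric(trimws(lines[body_idx])))
  if (anyNA(vals))
    stop("non-numeric ISI at line ", body_idx[which(is.na(vals))[1L]])
  meta <- parse_header(lines[is_hdr])
  unit <- if (identical(meta$unit, "eod")) "eod" else "ms"
  isi_seq(vals, unit = unit,
          eod_period = if (!is.null(meta$eod_period))
            as.numeric(meta$eod_period) else NULL,
          metadata = meta)
}

#' Write an ACF or SCC table as two-column text
#'
#' Lag and value, tab-separated, headers in `#` lines (normalization flag
#' for ACFs, provenance for SCCs).
#'
#' @param x A [noise_acf()] or [scc_seq()].
#' @param path File path.
#' @return `path`, invisibly; readers return the corresponding object.
#' @export
write_acf <- function(x, path) {
  stopifnot(inherits(x, "noise_acf"))
  writeLines(c(sprintf("# normalization: %s", x$normalization),
               sprintf("%d\t%.12g", x$lags, x$R)), path)
  invisible(path)
}

#' @rdname write_acf
#' @export
read_acf <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines[grepl("^#", lines)])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  noise_acf(as.numeric(parts[, 2L]),
            normalization = if (identical(meta$normalization, "R0")) "R0" else "raw")
}

#' @rdname write_acf
#' @export
write_scc <- function(x, path) {
  stopifnot(inherits(x, "scc_seq"))
  writeLines(c(sprintf("# provenance: %s", x$provenance),
               sprintf("%d\t%.12g", x$lags, x$rho)), path)
  invisible(path)
}

#' @rdname write_acf
#' @export
read_scc <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines[grepl("^#", lines)])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  scc_seq(as.numeric(parts[, 2L]),
          provenance = if (identical(meta$provenance, "estimated"))
            "estimated" else "theoretical")
}

#' Full analysis report for an ISI sequence
#'
#' Convenience wrapper running the estimator battery: mean ISI and CV,
#' blockwise SCCs with standard errors, Durbin partial autocorrelations,
#' pattern classification, partial sums, and the AR-parameter estimate when
#' the pattern admits one.
#'
#' @param x An [isi_seq()], [spike_train()] or numeric vector.
#' @param cfg An [scc_config()].
#' @param path Optional path; when given the report is written as JSON.
#' @return A named list (invisibly when written to `path`).
#' @export
analyze_isis <- function(x, cfg = scc_config(), path = NULL) {
  if (inherits(x, "spike_train")) x <- isis(x)
  iv <- if (inherits(x, "isi_seq")) x else isi_seq(as.numeric(x), unit = "ms")
  st <- isi_stats(iv)
  est <- estimate_sccs(iv, cfg)
  pac <- pacf_durbin(est)
  pattern <- classify_pattern(est)
  a_hat <- if (pattern %in% c("TYPE_I", "TYPE_II"))
    tryCatch(as.numeric(estimate_a(est, "ratio", pattern)),
             error = function(e) NA_real_) else if (pattern == "TYPE_III") 0
    else NA_real_
  report <- list(n = st$n, unit = st$unit, T1 = st$T1, cv = st$cv,
                 rho = est$rho, se = est$se, pacf = pac$phi,
                 partial_sums = limiting_sum(est), scc_sum = sum(est$rho),
                 pattern = pattern, a_hat = a_hat, n_blocks = est$n_blocks)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Printed model configurations of the three matched afferents
#'
#' Returns the full parameter bundle (deterministic encoder, AR(1) noise,
#' EOD grid) of the matched Type I, moderately bursting Type II and strongly
#' bursting Type II models, plus white-noise (Type III) and renewal
#' variants based on the Type I deterministic parameters.
#'
#' @param kind One of `"type1"`, `"type2_moderate"`, `"type2_strong"`,
#'   `"type3"`, `"renewal"`.
#' @return List with `params`, `spec`, `grid`, `kind`.
#' @export
fixture_config <- function(kind = c("type1", "type2_moderate", "type2_strong",
                                    "type3", "renewal")) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    type1 = list(params = model_params(1.845, 0.15, 30),
                 spec = ar_noise_spec(0.4, +1, R0 = 1.07e-3),
                 grid = eod_grid(1.06)),
    type2_moderate = list(params = model_params(1.845, 0.28, 26),
                          spec = ar_noise_spec(0.29, -1, R0 = 9.22e-3),
                          grid = eod_grid(1.31)),
    type2_strong = list(params = model_params(1.845, 0.19, 60),
                        spec = ar_noise_spec(0.69, -1, R0 = 6.4e-3),
                        grid = eod_grid(1.04)),
    # white threshold noise on the continuous base; weak so the linearized
    # rule stays admissible over long runs
    type3 = ,
    renewal = list(params = model_params(1.845, 0.15, 30),
                   spec = ar_noise_spec(0, 0, snr_db = 40, v = 1.845),
                   grid = eod_grid()))
  c(cfg, list(kind = kind))
}

#' Generate a fixture bundle
#'
#' Simulates one of the canonical model configurations and writes spike
#' times, ISIs and a JSON manifest with the generating parameters into
#' `dir`. The grid-locked kinds (`type1`, `type2_*`) use the exponential
#' simulator on the EOD grid; `type3` uses the linearized rule with white
#' threshold noise on the continuous base; `renewal` randomly permutes the
#' `type3` intervals, which preserves the ISI histogram and destroys all
#' serial correlations. The first 100 intervals of each simulation are
#' discarded as burn-in. Identical `seed` and arguments give byte-identical
#' files.
#'
#' @param kind Fixture kind, see [fixture_config()].
#' @param n_spikes Number of spikes to keep after burn-in.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths (`spikes`, `isis`,
#'   `manifest`), invisibly.
#' @export
generate_fixtures <- function(kind, n_spikes = 1e5, seed = 1L,
                              dir = tempdir()) {
  cfg <- fixture_config(kind)
  kind <- cfg$kind
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n <- as.integer(n_spikes) + 100L
  noise <- generate_ar1(cfg$spec, n + 1L)
  if (kind %in% c("type3", "renewal")) {
    iv <- simulate_linearized(cfg$params, noise)
    ints <- iv$intervals[-seq_len(100L)]
    if (kind == "renewal") ints <- sample(ints)
    train <- spike_train(cumsum(c(0, ints)),
                         metadata = list(kind = kind, seed = seed))
    out_isis <- isi_seq(ints, unit = "ms",
                        metadata = list(kind = kind, seed = seed))
  } else {
    train <- simulate_exponential(cfg$params, noise, grid = cfg$grid,
                                  burn_in = 100L)
    train$metadata <- list(kind = kind, seed = seed)
    out_isis <- isis(train)
  }
  paths <- c(spikes = file.path(dir, paste0(kind, "_spikes.txt")),
             isis = file.path(dir, paste0(kind, "_isis.txt")),
             manifest = file.path(dir, paste0(kind, "_manifest.json")))
  write_spike_times(train, paths[["spikes"]])
  write_isis(out_isis, paths[["isis"]])
  jsonlite::write_json(
    list(kind = kind, seed = seed, n_spikes = n_spikes,
         params = unclass(cfg$params), noise = unclass(cfg$spec),
         eod_period = if (cfg$grid$enabled) cfg$grid$period else NULL),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
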