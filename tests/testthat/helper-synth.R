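# Shared fixtures: everything is generated in code at test time.

# Small, fast generator config; overrides as needed.
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(sample_rate = 2000, duration_s = 10, beating_rate_bpm = 60,
                   rate_jitter = 0, noise_sd_uv = 0, seed = 1L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# Build an fp_complexes tibble directly from a list of equal-length vectors.
as_complexes <- function(samples, sample_rate, starts = NULL) {
  n <- length(samples[[1]])
  starts <- starts %||% (seq_along(samples) - 1L) * n + 1L
  structure(
    tibble::tibble(beat = seq_along(samples), start = starts,
                   peak_local = floor(n / 2) + 1L, samples = samples),
    window_samples = n, n_dropped = 0L,
    trace_length = max(starts) + n, sample_rate = sample_rate,
    peak_frac = 0.5,
    class = c("fp_complexes", class(tibble::tibble())))
}

# A classification report accepting every complex at the given lags.
accept_all_report <- function(complexes, lags = 0L) {
  n <- nrow(complexes)
  lags <- rep_len(as.integer(lags), n)
  structure(
    tibble::tibble(beat = complexes$beat, start = complexes$start,
                   coefficient = 1, best_lag = lags,
                   accepted = TRUE, degenerate = FALSE),
    cf = 0.98, max_lag = max(abs(lags)), method = "pearson",
    n_accepted = n, n_rejected = 0L,
    sample_rate = attr(complexes, "sample_rate"),
    window_samples = attr(complexes, "window_samples"),
    class = c("fp_classification", class(tibble::tibble())))
}

`%||%` <- rlang::`%||%`

# Independent brute-force oracle for the trapezium-area offset: evaluates
# the area at every candidate moving-vertex position.
brute_tra <- function(x, start_mode = "repol-peak") {
  n <- length(x)
  med <- stats::median(x)
  peak <- which.max(abs(x - med))
  post <- x[(peak + 1):n]
  sgn <- sign(x[peak] - med)
  valley <- peak + if (sgn >= 0) which.min(post) else which.max(post)
  seg <- x[(valley + 1):n]
  ri <- valley + which.max(sgn * (seg - med))
  m0 <- if (start_mode == "repol-peak") ri else valley
  areas <- vapply(m0:n, function(m) 0.5 * abs(x[ri] - x[m]) * (2 * n - m - ri),
                  numeric(1))
  (m0:n)[which.max(areas)]
}
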