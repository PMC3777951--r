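#' Extract per-beat field-potential complexes
#'
#' Cuts one fixed-length window per detected beat. With `window_ms =
#' "auto"` the window length is the smallest beat-to-beat interval (the
#' correlation interval: long enough to hold one complex, short enough not
#' to reach into the neighbour). The depolarization peak sits at fraction
#' `peak_frac` of the window (0.5 = centred on the peak). Beats whose full
#' window does not lie inside the trace are dropped and counted.
#'
#' @param trace Numeric µV series.
#' @param peaks `fp_peaks` tibble from [detect_peaks()].
#' @param sample_rate Sampling rate in Hz; taken from `peaks` if absent.
#' @param window_ms `"auto"` or an explicit window length in ms.
#' @param peak_frac Position of the peak inside the window, in (0, 1).
#'
#' @return An `fp_complexes` tibble with one row per retained beat:
#'   `beat` (index into `peaks`), `start` (global sample index of the first
#'   window sample), `peak_local` (peak index inside the window) and
#'   `samples` (list-column of length-N µV vectors). Attributes:
#'   `window_samples`, `n_dropped`, `trace_length`, `sample_rate`,
#'   `peak_frac`.
#' @export
extract_complexes <- function(trace, peaks, sample_rate = NULL,
                              window_ms = "auto", peak_frac = 0.5) {
  sample_rate <- sample_rate %||% attr(peaks, "sample_rate")
  if (is.null(sample_rate)) stop_cardiofp("sample_rate is required", "parameter")
  if (peak_frac <= 0 || peak_frac >= 1) {
    stop_cardiofp("peak_frac must lie strictly between 0 and 1", "parameter")
  }
  if (identical(window_ms, "auto")) {
    if (nrow(peaks) < 2) {
      stop_cardiofp("auto window needs >= 2 beats (smallest beat-beat interval)",
                    "insufficient_data")
    }
    window_ms <- beat_statistics(peaks, sample_rate)$min_interval_ms
  }
  n_win <- round(window_ms / 1000 * sample_rate)
  if (n_win < 2) stop_cardiofp("window is shorter than 2 samples", "parameter")
  if (n_win > length(trace)) {
    stop_cardiofp("window is larger than the trace", "parameter")
  }
  pre <- floor(n_win * peak_frac)

  starts <- peaks$index - pre
  ends <- starts + n_win - 1L
  ok <- starts >= 1L & ends <= length(trace)
  rows <- which(ok)
  out <- tibble(
    beat = rows,
    start = starts[rows],
    peak_local = pre + 1L,
    samples = lapply(rows, function(r) trace[starts[r]:ends[r]])
  )
  structure(out,
            window_samples = n_win, n_dropped = sum(!ok),
            trace_length = length(trace), sample_rate = sample_rate,
            peak_frac = peak_frac,
            class = c("fp_complexes", class(tibble())))
}

#' Select the template complex
#'
#' The comparison standard for classification: the default choice is the
#' complex whose window start is nearest the midpoint of the recording
#' (ties go to the earlier complex); a manual 1-based index picks a
#' specific complex (e.g. an arrhythmogenic one, to search for arrhythmic
#' beats). `"dominant"` emulates an operator choosing a template that
#' reflects the prevailing morphology: among a handful of candidate
#' complexes spread over the recording, it picks the one with the highest
#' median correlation against a spread of reference complexes — useful when
#' the centre complex might itself be an ectopic beat.
#'
#' @param complexes `fp_complexes` tibble from [extract_complexes()].
#' @param mode `"default"`, `"dominant"`, or a 1-based row index into
#'   `complexes`.
#'
#' @return A one-row `fp_template` tibble (same columns as `complexes`)
#'   with `selection_mode` and `template_row` attributes.
#' @export
select_template <- function(complexes, mode = "default") {
  if (nrow(complexes) == 0) {
    stop_cardiofp("no complexes to select a template from", "insufficient_data")
  }
  if (identical(mode, "default")) {
    mid <- attr(complexes, "trace_length") / 2
    row <- which.min(abs(complexes$start - mid))   # which.min: earliest tie wins
    sel <- "default-centre"
  } else if (identical(mode, "dominant")) {
    n <- nrow(complexes)
    fs <- attr(complexes, "sample_rate")
    max_lag <- min(round(0.002 * fs), floor(lengths(complexes$samples)[1] / 4))
    cand <- unique(round(seq(1, n, length.out = min(n, 7))))
    refs <- unique(round(seq(1, n, length.out = min(n, 15))))
    med <- vapply(cand, function(ci) {
      cc <- vapply(refs, function(ri) {
        tryCatch(
          correlation_coefficient(complexes$samples[[ci]],
                                  complexes$samples[[ri]],
                                  max_lag = max_lag)$coefficient,
          cardiofp_undefined_correlation = function(e) NA_real_
        )
      }, numeric(1))
      median(cc, na.rm = TRUE)
    }, numeric(1))
    row <- cand[which.max(med)]
    sel <- "dominant"
  } else {
    row <- as.integer(mode)
    if (is.na(row) || row < 1 || row > nrow(complexes)) {
      stop_cardiofp(
        sprintf("template index %s out of range 1..%d", mode, nrow(complexes)),
        "lookup"
      )
    }
    sel <- "manual index"
  }
  out <- complexes[row, ]
  attr(out, "selection_mode") <- sel
  attr(out, "template_row") <- row
  class(out) <- c("fp_template", setdiff(class(out), "fp_template"))
  out
}

# Lag-n similarity between two equal-length vectors, computed on the
# overlapping segment: pairs (x1[i], x2[i - n]). method:
#   pearson - mean-removed, amplitude-normalised (default; c in [-1, 1])
#   cosine  - amplitude-normalised, not mean-removed
#   raw     - the plain 1/N product sum (scale-dependent)
lag_similarity <- function(x1, x2, n, method) {
  N <- length(x1)
  i1 <- (1 + max(0, n)):(N + min(0, n))
  a <- x1[i1]
  b <- x2[i1 - n]
  if (method == "raw") return(sum(a * b) / N)
  if (method == "pearson") {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Cross-correlation coefficient between two complexes
#'
#' Maximises the similarity between two equal-length complexes over integer
#' lags `|n| <= max_lag`. The default coefficient is the Pearson-type
#' normalisation (mean-removed, amplitude-normalised product sum), bounded
#' in \[-1, 1\] so that a correlation-factor threshold is portable across
#' amplitudes; `method = "raw"` gives the plain `1/N` product sum and
#' `"cosine"` the normalised-but-uncentred variant. Lags are scanned in the
#' order 0, -1, +1, -2, +2, ... so ties resolve to the smaller `|lag|`,
#' then to the negative lag.
#'
#' The lag convention: `best_lag = n` means the pairing `x1[i] ~ x2[i - n]`
#' scores highest, i.e. `x2` advanced by `n` samples aligns with `x1`.
#'
#' @param x1,x2 Numeric vectors of identical length (or one-row
#'   `fp_complexes`/`fp_template` tibbles).
#' @param max_lag Maximum |lag| in samples; must be `<= N/4`.
#' @param method `"pearson"`, `"cosine"` or `"raw"`.
#'
#' @return A list with `coefficient` and `best_lag`.
#' @export
#' @examples
#' x <- sin(seq(0, 2 * pi, length.out = 100))
#' correlation_coefficient(x, x, max_lag = 0)$coefficient
correlation_coefficient <- function(x1, x2, max_lag = 0,
                                    method = c("pearson", "cosine", "raw")) {
  method <- match.arg(method)
  if (is.data.frame(x1)) x1 <- x1$samples[[1]]
  if (is.data.frame(x2)) x2 <- x2$samples[[1]]
  if (length(x1) != length(x2)) {
    stop_cardiofp("complexes must have identical window length N", "parameter")
  }
  N <- length(x1)
  if (max_lag < 0 || max_lag > N / 4) {
    stop_cardiofp("max_lag must lie in [0, N/4] samples", "parameter")
  }
  if (method != "raw" && (stats::var(x1) == 0 || stats::var(x2) == 0)) {
    stop_cardiofp("undefined correlation: an operand has zero variance",
                  "undefined_correlation")
  }
  lags <- 0
  if (max_lag > 0) {
    seq_l <- seq_len(max_lag)
    lags <- c(0, as.vector(rbind(-seq_l, seq_l)))
  }
  best <- -Inf
  best_lag <- 0
  for (n in lags) {
    cn <- lag_similarity(x1, x2, n, method)
    if (!is.na(cn) && cn > best) {
      best <- cn
      best_lag <- n
    }
  }
  list(coefficient = best, best_lag = best_lag)
}

#' Classify complexes against a template by correlation factor
#'
#' Scores every complex against the template with
#' [correlation_coefficient()] and accepts those whose coefficient is equal
#' to or greater than the correlation factor CF. A complex with an
#' undefined coefficient (zero variance) is rejected and flagged rather
#' than aborting the run.
#'
#' @param complexes `fp_complexes` tibble.
#' @param template `fp_template` (or any one-row complexes tibble).
#' @param cf Correlation factor in (0, 1].
#' @param max_lag Maximum alignment lag in samples; default 2 ms worth.
#' @param method Coefficient variant, see [correlation_coefficient()].
#'
#' @return An `fp_classification` tibble, one row per complex in input
#'   order: `beat`, `start`, `coefficient`, `best_lag`, `accepted`,
#'   `degenerate`. Attributes: `cf`, `max_lag`, `method`, `n_accepted`,
#'   `n_rejected`, `sample_rate`, `window_samples`.
#' @export
classify_complexes <- function(complexes, template, cf = 0.98,
                               max_lag = NULL,
                               method = c("pearson", "cosine", "raw")) {
  method <- match.arg(method)
  if (!is.numeric(cf) || cf <= 0 || cf > 1) {
    stop_cardiofp("correlation factor CF must lie in (0, 1]", "parameter")
  }
  fs <- attr(complexes, "sample_rate")
  max_lag <- max_lag %||% round(2 / 1000 * fs)
  tmpl <- if (is.data.frame(template)) template$samples[[1]] else template

  scored <- map(complexes$samples, function(s) {
    tryCatch(correlation_coefficient(tmpl, s, max_lag = max_lag, method = method),
             cardiofp_undefined_correlation = function(e) {
               list(coefficient = NA_real_, best_lag = 0L)
             })
  })
  out <- tibble(
    beat = complexes$beat,
    start = complexes$start,
    coefficient = map_dbl(scored, "coefficient"),
    best_lag = map_int(scored, function(s) as.integer(s$best_lag)),
    degenerate = is.na(map_dbl(scored, "coefficient"))
  )
  out$accepted <- !out$degenerate & out$coefficient >= cf
  out <- out[, c("beat", "start", "coefficient", "best_lag", "accepted", "degenerate")]
  structure(out,
            cf = cf, max_lag = max_lag, method = method,
            n_accepted = sum(out$accepted), n_rejected = sum(!out$accepted),
            sample_rate = fs, window_samples = attr(complexes, "window_samples"),
            class = c("fp_classification", class(tibble())))
}

#' Ensemble-average the accepted complexes
#'
#' Pointwise mean of the accepted complexes after advancing each by its
#' best alignment lag (alignment on the depolarization peak, refined by the
#' correlation lag search). Lag-shifted edge samples are handled by
#' shrinking to the common overlap of all shifted windows; the resulting
#' length is recorded in the waveform source.
#'
#' @param report `fp_classification` tibble from [classify_complexes()].
#' @param complexes The `fp_complexes` tibble the report was computed from.
#' @param combine `"mean"` (ensemble average) or `"median"`.
#'
#' @return An [fp_waveform][new_fp_waveform] with `n_ensembles` equal to
#'   the number of accepted complexes.
#' @export
ensemble_average <- function(report, complexes, combine = c("mean", "median")) {
  combine <- match.arg(combine)
  acc <- which(report$accepted)
  if (length(acc) == 0) {
    stop_cardiofp(
      "no complexes were accepted for averaging; consider lowering the correlation factor CF",
      "insufficient_data"
    )
  }
  N <- attr(complexes, "window_samples")
  lags <- report$best_lag[acc]
  # aligned_k[i] = samples_k[i - lag_k]; common index range across members
  lo <- 1L + max(0L, max(lags))
  hi <- N + min(0L, min(lags))
  if (hi <= lo) stop_cardiofp("alignment lags leave no common overlap", "parameter")
  m <- vapply(seq_along(acc), function(j) {
    s <- complexes$samples[[acc[j]]]
    s[(lo - lags[j]):(hi - lags[j])]
  }, numeric(hi - lo + 1L))
  avg <- if (combine == "mean") rowMeans(m) else apply(m, 1, median)
  new_fp_waveform(
    avg,
    sample_rate = attr(complexes, "sample_rate"),
    n_ensembles = length(acc),
    source = list(
      cf = attr(report, "cf"),
      method = attr(report, "method"),
      max_lag = attr(report, "max_lag"),
      combine = combine,
      window_samples = N,
      overlap = c(lo, hi),
      peak_local = complexes$peak_local[1] - (lo - 1L)
    )
  )
}

#' Averaged field-potential waveform
#'
#' The representative complex produced by [ensemble_average()]: a µV series
#' with its sampling rate, the number of averaged ensembles and a
#' provenance record.
#'
#' @param samples Numeric µV series.
#' @param sample_rate Sampling rate in Hz.
#' @param n_ensembles Number of complexes averaged (>= 1).
#' @param source Optional provenance list (file, electrode, CF, ...).
#'
#' @return An `fp_waveform` object.
#' @export
new_fp_waveform <- function(samples, sample_rate, n_ensembles = 1L,
                            source = list()) {
  if (n_ensembles < 1) stop_cardiofp("n_ensembles must be >= 1", "format")
  if (sample_rate <= 0) stop_cardiofp("sample_rate must be positive", "format")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         n_ensembles = as.integer(n_ensembles), source = source),
    class = "fp_waveform"
  )
}

#' @export
print.fp_waveform <- function(x, ...) {
  cat(sprintf("<fp_waveform> %d samples at %.6g Hz, N = %d ensembles\n",
              length(x$samples), x$sample_rate, x$n_ensembles))
  invisible(x)
}

#' @export
#' @rdname new_fp_waveform
#' @param x,object An `fp_waveform`.
#' @param ... Unused.
tidy.fp_waveform <- function(x, ...) {
  tibble(time_ms = (seq_along(x$samples) - 1) / x$sample_rate * 1000,
         amplitude_uv = x$samples)
}

#' @export
#' @rdname new_fp_waveform
glance.fp_waveform <- function(x, ...) {
  tibble(n_samples = length(x$samples), sample_rate = x$sample_rate,
         duration_ms = length(x$samples) / x$sample_rate * 1000,
         n_ensembles = x$n_ensembles)
}

#' @export
#' @rdname new_fp_waveform
autoplot.fp_waveform <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time_ms, .data$amplitude_uv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (\u00b5V)",
                  title = sprintf("Ensemble average (N = %d)", object$n_ensembles))
}

#' @export
autoplot.fp_classification <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$beat, .data$coefficient,
                               colour = .data$accepted)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "cf"), linetype = 2) +
    ggplot2::labs(x = "beat", y = "correlation coefficient",
                  colour = "accepted")
}
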