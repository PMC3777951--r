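#' Phase I: correlation analysis and ensemble averaging of one electrode
#'
#' The full phase-I chain on one electrode of a recording: zero-phase
#' low-pass filtering, depolarization-peak detection, complex extraction on
#' peak-centred windows of the smallest beat-to-beat interval (the
#' correlation interval), template selection, correlation classification at
#' the correlation factor `cf`, and ensemble averaging of the accepted
#' complexes.
#'
#' Averaging and FPD measurement need the repolarisation wave, which at
#' physiological beating rates ends later than half a beat interval after
#' the spike; the accepted beats are therefore re-extracted on an
#' asymmetric measurement window (peak at fraction `measure_peak_frac`,
#' length = smallest interval between consecutive accepted beats) before
#' averaging. Accepted beats whose measurement window contains another
#' detected beat (e.g. a trailing premature complex) are excluded from the
#' average so they cannot contaminate it.
#'
#' @param rec An [fp_recording][new_fp_recording].
#' @param electrode Electrode identifier; default the first.
#' @param cf Correlation factor in (0, 1].
#' @param template `"default"` (complex nearest the recording midpoint),
#'   `"dominant"` (highest median correlation among spread candidates, see
#'   [select_template()]) or a 1-based complex index.
#' @param max_lag_ms Correlation lag search half-width, ms.
#' @param window_ms Correlation window: `"auto"` (smallest beat-to-beat
#'   interval) or ms.
#' @param cutoff,order [lowpass_filter()] settings.
#' @param threshold,refractory_ms,peak_k [detect_peaks()] settings
#'   (`peak_k` is its `k`).
#' @param measure_peak_frac Peak position inside the measurement window.
#' @param method Correlation variant, see [correlation_coefficient()].
#'
#' @return An `fp_phase1` list: `waveform` (the
#'   [fp_waveform][new_fp_waveform] ensemble
#'   average), `classification` (the per-beat `fp_classification` report),
#'   `peaks`, `beat_stats` (over accepted beats), and `params`.
#' @export
average_recording <- function(rec, electrode = NULL, cf = 0.98,
                              template = "default",
                              max_lag_ms = 2, window_ms = "auto",
                              cutoff = 200, order = 5,
                              threshold = "auto", refractory_ms = 200,
                              peak_k = 5,
                              measure_peak_frac = 0.15,
                              method = "pearson") {
  electrode <- electrode %||% rec_electrodes(rec)[1]
  fs <- rec_sample_rate(rec)
  trace <- rec_trace(rec, electrode)
  filtered <- lowpass_filter(trace, fs, order = order, cutoff = cutoff)
  peaks <- detect_peaks(filtered, fs, threshold = threshold,
                        refractory_ms = refractory_ms, k = peak_k)
  if (nrow(peaks) < 2) {
    stop_cardiofp("fewer than 2 beats detected; cannot run correlation analysis",
                  "insufficient_data")
  }
  complexes <- extract_complexes(filtered, peaks, fs, window_ms = window_ms,
                                 peak_frac = 0.5)
  tmpl <- select_template(complexes, mode = template)
  max_lag <- round(max_lag_ms / 1000 * fs)
  report <- classify_complexes(complexes, tmpl, cf = cf, max_lag = max_lag,
                               method = method)

  acc_idx <- peaks$index[complexes$beat[report$accepted]]
  if (length(acc_idx) < 2) {
    stop_cardiofp("fewer than 2 accepted beats; consider lowering CF",
                  "insufficient_data")
  }
  acc_peaks <- structure(tibble(index = acc_idx),
                         sample_rate = fs, class = class(peaks))
  bs <- beat_statistics(acc_peaks, fs)
  # median-based rate: intervals spanning a rejected (e.g. premature) beat
  # include its compensatory pause and would bias the mean
  bs$beating_rate_bpm <- 60000 / median(bs$intervals_ms)

  # Measurement windows over accepted beats only, free of foreign peaks.
  cm <- extract_complexes(filtered, acc_peaks, fs,
                          window_ms = bs$min_interval_ms,
                          peak_frac = measure_peak_frac)
  n_win <- attr(cm, "window_samples")
  clean <- vapply(seq_len(nrow(cm)), function(r) {
    own <- acc_idx[cm$beat[r]]
    inside <- peaks$index >= cm$start[r] & peaks$index <= cm$start[r] + n_win - 1L
    sum(inside) == 1 && peaks$index[which(inside)] == own
  }, logical(1))
  cm2 <- cm[clean, ]
  attributes(cm2)[c("window_samples", "n_dropped", "trace_length",
                    "sample_rate", "peak_frac")] <-
    attributes(cm)[c("window_samples", "n_dropped", "trace_length",
                     "sample_rate", "peak_frac")]
  if (nrow(cm2) == 0) {
    stop_cardiofp("no accepted beat has an uncontaminated measurement window",
                  "insufficient_data")
  }
  tmpl_beat <- complexes$beat[attr(tmpl, "template_row")]
  tmpl_acc_row <- match(match(peaks$index[tmpl_beat], acc_idx), cm2$beat)
  tmpl2 <- if (!is.na(tmpl_acc_row)) cm2[tmpl_acc_row, ] else
    select_template(cm2, "default")
  report2 <- classify_complexes(cm2, tmpl2, cf = cf, max_lag = max_lag,
                                method = method)
  avg <- ensemble_average(report2, cm2)
  avg$source <- c(avg$source, list(
    electrode = electrode,
    beating_rate_bpm = bs$beating_rate_bpm,
    correlation_window_ms = attr(complexes, "window_samples") / fs * 1000,
    measurement_window_ms = n_win / fs * 1000,
    template_beat = tmpl_beat,
    n_beats_detected = nrow(peaks),
    n_accepted = attr(report, "n_accepted")
  ))

  structure(
    list(waveform = avg, classification = report, peaks = peaks,
         beat_stats = bs,
         params = list(electrode = electrode, cf = cf, template = template,
                       max_lag_ms = max_lag_ms, window_ms = window_ms,
                       cutoff = cutoff, order = order, threshold = threshold,
                       refractory_ms = refractory_ms, peak_k = peak_k,
                       measure_peak_frac = measure_peak_frac,
                       method = method)),
    class = "fp_phase1"
  )
}

#' @export
print.fp_phase1 <- function(x, ...) {
  cat(sprintf("<fp_phase1> %d/%d complexes accepted at CF %.2f; BR %.1f bpm\n",
              attr(x$classification, "n_accepted"), nrow(x$classification),
              attr(x$classification, "cf"), x$beat_stats$beating_rate_bpm))
  print(x$waveform)
  invisible(x)
}

#' @export
tidy.fp_phase1 <- function(x, ...) as_tibble(x$classification)

#' @export
glance.fp_phase1 <- function(x, ...) {
  tibble(
    n_beats = nrow(x$classification),
    n_accepted = attr(x$classification, "n_accepted"),
    cf = attr(x$classification, "cf"),
    beating_rate_bpm = x$beat_stats$beating_rate_bpm,
    min_interval_ms = x$beat_stats$min_interval_ms,
    n_ensembles = x$waveform$n_ensembles
  )
}

#' Overlay comparison of averaged waveforms (drug series)
#'
#' Aligns up to ten averaged waveforms on their depolarization peaks for
#' visual overlay (e.g. one waveform per drug concentration) and tabulates
#' FPD, cFPD, AUC and beating rate per waveform together with the deltas
#' against the first (baseline) waveform.
#'
#' @param waveforms List of [fp_waveform][new_fp_waveform] objects (1-10),
#'   all at the same sampling rate (no resampling is performed).
#' @param labels Labels, e.g. drug concentrations; defaults to `"wf1"`,
#'   `"wf2"`, ...
#' @param beating_rates Optional bpm vector overriding the rates stored in
#'   the waveform sources.
#' @param ... Passed to [analyze_waveform()] (e.g. `onset`, `offset`,
#'   `tra_start`).
#'
#' @return An `fp_overlay` list: `overlay` (long tibble of peak-aligned
#'   traces: `label`, `time_ms`, `amplitude_uv`) and `measurements` (one
#'   row per waveform with `fpd_ms`, `cfpd_ms`, `auc_uv_ms`,
#'   `beating_rate_bpm` and `delta_*` columns vs the first label).
#' @export
compare_waveforms <- function(waveforms, labels = NULL, beating_rates = NULL,
                              ...) {
  if (inherits(waveforms, "fp_waveform")) waveforms <- list(waveforms)
  nw <- length(waveforms)
  if (nw < 1 || nw > 10) {
    stop_cardiofp("between 1 and 10 waveforms can be compared at once", "limit")
  }
  stopifnot(all(vapply(waveforms, inherits, logical(1), "fp_waveform")))
  rates <- vapply(waveforms, function(w) w$sample_rate, numeric(1))
  if (length(unique(rates)) != 1) {
    stop_cardiofp("waveforms have mixed sampling rates; no resampling is performed",
                  "rate")
  }
  labels <- labels %||% paste0("wf", seq_len(nw))
  if (length(labels) != nw) stop_cardiofp("one label per waveform is required", "input")

  fs <- rates[1]
  rows <- vector("list", nw)
  overlay <- vector("list", nw)
  for (i in seq_len(nw)) {
    w <- waveforms[[i]]
    br <- if (!is.null(beating_rates)) beating_rates[i] else NULL
    meas <- analyze_waveform(w, beating_rate = br, ...)
    peak <- depol_peak_index(w$samples)
    overlay[[i]] <- tibble(
      label = labels[i],
      time_ms = (seq_along(w$samples) - peak) / fs * 1000,
      amplitude_uv = w$samples
    )
    rows[[i]] <- dplyr::bind_cols(tibble(label = labels[i]), meas)
  }
  tab <- bind_rows(rows)
  tab$delta_fpd_ms <- tab$fpd_ms - tab$fpd_ms[1]
  tab$delta_cfpd_ms <- tab$cfpd_ms - tab$cfpd_ms[1]
  tab$delta_auc_uv_ms <- tab$auc_uv_ms - tab$auc_uv_ms[1]
  tab$delta_br_bpm <- tab$beating_rate_bpm - tab$beating_rate_bpm[1]

  structure(list(overlay = bind_rows(overlay), measurements = tab),
            class = "fp_overlay")
}

#' @export
print.fp_overlay <- function(x, ...) {
  cat(sprintf("<fp_overlay> %d waveform(s)\n",
              length(unique(x$overlay$label))))
  print(x$measurements, ...)
  invisible(x)
}

#' @export
tidy.fp_overlay <- function(x, ...) x$measurements

#' @export
autoplot.fp_overlay <- function(object, ...) {
  ggplot2::ggplot(object$overlay,
                  ggplot2::aes(.data$time_ms, .data$amplitude_uv,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from depolarization peak (ms)",
                  y = "amplitude (\u00b5V)", colour = NULL)
}
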