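#' Zero-phase low-pass Butterworth filter
#'
#' Attenuates high-frequency noise with an order-5 Butterworth low-pass
#' (cut-off 200 Hz by default), applied forward and backward so that no
#' landmark latency is introduced. The effective magnitude response is the
#' square of the single-pass prototype, i.e. -6.02 dB at the cut-off.
#' The trace is odd-reflection padded before filtering (pad length about six
#' filter time constants) so edge transients do not leak into the output and
#' a constant trace passes through unchanged.
#'
#' @param trace Numeric µV series.
#' @param sample_rate Sampling rate in Hz.
#' @param order Butterworth order of the single pass.
#' @param cutoff Cut-off frequency in Hz; must be below Nyquist.
#'
#' @return Filtered series, same length as the input.
#' @export
#' @examples
#' lowpass_filter(rep(7.3, 100), sample_rate = 2000)[1:3]
lowpass_filter <- function(trace, sample_rate, order = 5, cutoff = 200) {
  if (cutoff >= sample_rate / 2) {
    stop_cardiofp(
      sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
              cutoff, sample_rate / 2),
      "parameter"
    )
  }
  n <- length(trace)
  if (n <= 3 * (order + 1)) {
    stop_cardiofp("trace too short for the requested filter order", "parameter")
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # remove the DC offset before filtering (zero initial conditions would
  # otherwise see it as a step), and pad by odd reflection
  off <- median(trace)
  x <- trace - off
  pad <- min(n - 1, ceiling(6 * sample_rate / cutoff))
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(pad + 1):(pad + n)] + off
}

#' Detect depolarization peaks (beats)
#'
#' Window-threshold beat detector for a (filtered) single-electrode trace:
#' the trace is median-centred, the dominant depolarization polarity is the
#' sign whose extrema are larger in magnitude, candidate local extrema above
#' the threshold are found, and candidates closer than the refractory period
#' are resolved in favour of the larger amplitude. The `"auto"` threshold is
#' `k` times the robust noise scale (median absolute deviation scaled by
#' 1.4826).
#'
#' @param trace Numeric µV series (ideally after [lowpass_filter()]).
#' @param sample_rate Sampling rate in Hz.
#' @param threshold `"auto"` or an explicit positive µV threshold (applied
#'   to the median-centred trace in the detected polarity).
#' @param refractory_ms Minimum separation between detected beats, ms.
#' @param k Threshold multiplier for the `"auto"` noise scale.
#' @param min_peak_frac Floor of the `"auto"` threshold as a fraction of the
#'   largest centred deflection; keeps secondary waves (repolarisation
#'   peaks) below threshold.
#'
#' @return An `fp_peaks` tibble with columns `index` (strictly increasing
#'   sample indices), `time_ms` and `amplitude_uv` (centred amplitude in the
#'   detected polarity), carrying `polarity`, `threshold`, `refractory`
#'   (samples) and `sample_rate` attributes. A trace with no supra-threshold
#'   extremum yields zero rows (not an error).
#' @export
#' @examples
#' out <- synth_recording(synth_config(sample_rate = 2000, duration_s = 5,
#'                                     beating_rate_bpm = 60, rate_jitter = 0,
#'                                     noise_sd_uv = 0))
#' nrow(detect_peaks(rec_trace(out$recording), 2000))
detect_peaks <- function(trace, sample_rate, threshold = "auto",
                         refractory_ms = 200, k = 5, min_peak_frac = 0.35) {
  if (refractory_ms <= 0) stop_cardiofp("refractory_ms must be positive", "parameter")
  centred <- trace - median(trace)
  pos <- max(centred)
  neg <- max(-centred)
  polarity <- if (pos >= neg) 1 else -1
  v <- polarity * centred

  if (identical(threshold, "auto")) {
    # k x robust noise scale, floored at a fraction of the dominant
    # deflection so that secondary waves (e.g. the repolarisation peak)
    # and, on noiseless traces, a zero MAD cannot produce spurious beats
    thr <- max(k * mad(centred), min_peak_frac * max(abs(centred)))
  } else {
    if (!is.numeric(threshold) || threshold <= 0) {
      stop_cardiofp("explicit threshold must be a positive value in uV", "parameter")
    }
    thr <- threshold
  }

  refr <- max(1L, round(refractory_ms / 1000 * sample_rate))
  n <- length(v)
  idx <- integer(0)
  if (thr > 0 && n >= 3) {
    interior <- 2:(n - 1)
    cand <- interior[v[interior] >= thr &
                     v[interior] >= v[interior - 1] &
                     v[interior] >= v[interior + 1]]
    # flat-top plateaus: keep the first sample of each run
    if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) > 1 | diff(v[cand]) != 0)]
    # greedy refractory suppression, larger amplitude wins
    if (length(cand) > 0) {
      ord <- cand[order(-v[cand], cand)]
      keep <- logical(0)
      chosen <- integer(0)
      for (i in ord) {
        if (all(abs(i - chosen) >= refr)) chosen <- c(chosen, i)
      }
      idx <- sort(chosen)
    }
  }

  structure(
    tibble(index = idx,
           time_ms = (idx - 1) / sample_rate * 1000,
           amplitude_uv = v[idx]),
    polarity = polarity, threshold = thr, refractory = refr,
    sample_rate = sample_rate,
    class = c("fp_peaks", class(tibble())))
}

#' Beat-interval statistics
#'
#' Successive beat-to-beat intervals, the smallest interval (the default
#' correlation/alignment window length) and the mean beating rate.
#'
#' @param peaks An `fp_peaks` tibble from [detect_peaks()] (or any tibble
#'   with an `index` column).
#' @param sample_rate Sampling rate in Hz; taken from `peaks` if absent.
#'
#' @return A list with `intervals_ms`, `min_interval_ms` and
#'   `beating_rate_bpm` (`60000 / mean(intervals)`).
#' @export
#' @examples
#' pk <- tibble::tibble(index = c(1, 401, 901))
#' beat_statistics(pk, sample_rate = 1000)$beating_rate_bpm
beat_statistics <- function(peaks, sample_rate = NULL) {
  sample_rate <- sample_rate %||% attr(peaks, "sample_rate")
  if (is.null(sample_rate)) stop_cardiofp("sample_rate is required", "parameter")
  if (nrow(peaks) < 2) {
    stop_cardiofp("at least 2 detected beats are required for interval statistics",
                  "insufficient_data")
  }
  intervals <- diff(peaks$index) / sample_rate * 1000
  list(
    intervals_ms = intervals,
    min_interval_ms = min(intervals),
    beating_rate_bpm = 60000 / mean(intervals)
  )
}
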