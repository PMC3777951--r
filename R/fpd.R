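# Baseline and depolarization-peak helpers shared by the landmark detectors.
wf_samples <- function(waveform) {
  if (inherits(waveform, "fp_waveform")) waveform$samples else as.numeric(waveform)
}
wf_rate <- function(waveform, sample_rate) {
  if (inherits(waveform, "fp_waveform")) waveform$sample_rate
  else sample_rate %||% stop_cardiofp("sample_rate is required", "parameter")
}
depol_peak_index <- function(x) which.max(abs(x - median(x)))

#' Detect the FPD onset on an averaged waveform
#'
#' Onset detection from amplitude changes relative to subsequent samples
#' within a short time frame: scanning forward (before the depolarization
#' peak), the first frame whose amplitude excursion (max - min over
#' `frame_ms`) exceeds `k` times the baseline excursion triggers, and the
#' onset is refined to the first sample in that frame deviating from the
#' baseline median by more than `k` times the baseline noise scale. The
#' baseline is the leading `frame_ms` of the window, which must precede the
#' depolarization peak.
#'
#' On a heavily averaged waveform the baseline excursion can be arbitrarily
#' close to zero, which would make the criterion fire on numerically tiny
#' ripple (e.g. pre-ringing of the zero-phase filter); the excursion
#' threshold therefore has a floor of `min_excursion_frac` times the
#' waveform's peak-to-peak amplitude.
#'
#' @param waveform An [fp_waveform][new_fp_waveform] or numeric µV series.
#' @param sample_rate Sampling rate in Hz (ignored for `fp_waveform`).
#' @param frame_ms Frame length in ms.
#' @param k Excursion multiplier.
#' @param min_excursion_frac Threshold floor as a fraction of the waveform
#'   peak-to-peak amplitude.
#'
#' @return Onset sample index (always before the depolarization peak).
#' @export
detect_onset <- function(waveform, sample_rate = NULL, frame_ms = 10, k = 3,
                         min_excursion_frac = 0.01) {
  x <- wf_samples(waveform)
  fs <- wf_rate(waveform, sample_rate)
  f <- max(2L, round(frame_ms / 1000 * fs))
  peak <- depol_peak_index(x)
  if (peak <= f) {
    stop_cardiofp("no pre-peak baseline segment of at least frame_ms", "detection_failure")
  }
  base <- x[1:f]
  base_exc <- max(base) - min(base)
  base_med <- median(base)
  base_scale <- max(mad(base), base_exc / 6)   # noiseless baseline -> 0
  floor_exc <- min_excursion_frac * (max(x) - min(x))
  thr_exc <- max(k * base_exc, floor_exc)
  thr_dev <- max(k * base_scale, floor_exc)

  for (t in seq_len(peak - 1)) {
    fr <- x[t:min(t + f - 1L, peak)]
    if ((max(fr) - min(fr)) > thr_exc) {
      # refine: first sample from the triggering frame onwards that deviates
      # from the baseline median beyond the noise/floor threshold
      dev <- which(abs(x[t:(peak - 1L)] - base_med) > max(thr_dev, base_exc))
      onset <- if (length(dev) > 0) t + dev[1] - 1L else t
      return(min(onset, peak - 1L))
    }
  }
  stop_cardiofp(
    "onset detection failed: no frame exceeds the baseline excursion criterion (consider manual mode)",
    "detection_failure"
  )
}

#' Detect the FPD offset by the trapezium-area method
#'
#' Repolarisation end-point detection: a rectangular trapezium is spanned by
#' three fixed vertices - derived from the repolarisation-wave peak
#' `(x_i, y_i)` and the reference point `(x_r, y_r)` at the last sample of
#' the waveform - and one moving vertex `(x_m, y_m)` on the waveform. The
#' offset is the earliest `x_m` maximising
#' `A(x_m) = 0.5 * |y_i - y_m| * (2 * x_r - x_m - x_i)`.
#'
#' The moving vertex runs from `search_start` to the last sample. The
#' default start is the repolarisation-wave peak itself: for any moving
#' point near baseline before the peak, `|y_i - y_m|` is already the full
#' wave amplitude while the width term is strictly larger than at any
#' post-peak point, so a pre-peak search start would always win and the
#' detector would never mark the repolarisation end (see the methods
#' vignette). `search_start = "post-spike-valley"` starts at the valley
#' following the depolarization peak instead; an explicit sample index is
#' also accepted.
#'
#' @param waveform An [fp_waveform][new_fp_waveform] or numeric µV series.
#' @param sample_rate Sampling rate in Hz (ignored for `fp_waveform`).
#' @param search_start `"repol-peak"`, `"post-spike-valley"`, or a sample
#'   index.
#'
#' @return Offset sample index.
#' @export
detect_offset_tra <- function(waveform, sample_rate = NULL,
                              search_start = c("repol-peak", "post-spike-valley")) {
  x <- wf_samples(waveform)
  n <- length(x)
  base_med <- median(x)
  peak <- depol_peak_index(x)
  if (peak >= n - 1) {
    stop_cardiofp("no samples after the activation peak", "detection_failure")
  }
  # valley after the activation peak: extremum opposite the peak deflection
  peak_sign <- sign(x[peak] - base_med)
  post <- x[(peak + 1):n]
  valley <- peak + if (peak_sign >= 0) which.min(post) else which.max(post)
  if (n - valley < 2) {
    stop_cardiofp("fewer than 2 samples after the valley", "detection_failure")
  }
  # repolarisation-wave peak: largest post-valley deflection in the
  # direction of the dominant depolarization lobe (an absolute-value
  # criterion would land on the valley's own shoulder)
  seg <- x[(valley + 1):n]
  ri <- valley + which.max(peak_sign * (seg - base_med))
  yi <- x[ri]

  if (is.numeric(search_start)) {
    m0 <- as.integer(search_start)
    if (m0 < 1 || m0 > n) stop_cardiofp("search_start index out of range", "parameter")
  } else {
    search_start <- match.arg(search_start)
    m0 <- if (search_start == "repol-peak") ri else valley
  }
  mm <- m0:n
  area <- 0.5 * abs(yi - x[mm]) * (2 * n - mm - ri)
  mm[which.max(area)]    # earliest maximiser
}

#' Compute FPD, Bazett-corrected FPD, AUC and beating rate
#'
#' From onset and offset sample indices on an averaged waveform:
#' `FPD = (offset - onset) / sample_rate * 1000` ms; the Bazett correction
#' normalises to the beating rate, `cFPD = FPD / sqrt(RR)` with the beat
#' interval `RR = 60 / beating_rate` in seconds; AUC is the trapezoidal
#' integral of `|amplitude - baseline|` between onset and offset in µV·ms,
#' with the baseline taken as the median of the pre-onset samples.
#'
#' @param waveform An [fp_waveform][new_fp_waveform] or numeric µV series.
#' @param onset,offset Sample indices, `onset < offset`.
#' @param beating_rate Beating rate in bpm (> 0).
#' @param sample_rate Sampling rate in Hz (ignored for `fp_waveform`).
#' @param onset_mode,offset_mode Provenance flags (`"auto"` or `"manual"`).
#'
#' @return A one-row `fp_measurement` tibble: `onset`, `offset`, `fpd_ms`,
#'   `cfpd_ms`, `auc_uv_ms`, `beating_rate_bpm`, `onset_mode`,
#'   `offset_mode`.
#' @export
#' @examples
#' x <- c(rep(0, 10), rep(1, 101), rep(0, 10))
#' measure_fpd(x, onset = 11, offset = 111, beating_rate = 60,
#'             sample_rate = 1000)$auc_uv_ms
measure_fpd <- function(waveform, onset, offset, beating_rate,
                        sample_rate = NULL,
                        onset_mode = "auto", offset_mode = "auto") {
  x <- wf_samples(waveform)
  fs <- wf_rate(waveform, sample_rate)
  if (onset >= offset) {
    stop_cardiofp("onset must precede offset", "ordering")
  }
  if (onset < 1 || offset > length(x)) {
    stop_cardiofp("onset/offset outside the waveform", "range")
  }
  if (beating_rate <= 0) stop_cardiofp("beating_rate must be positive", "parameter")

  fpd_ms <- (offset - onset) / fs * 1000
  rr_s <- 60 / beating_rate
  cfpd_ms <- fpd_ms / sqrt(rr_s)

  baseline <- if (onset > 1) median(x[1:(onset - 1)]) else x[1]
  y <- abs(x[onset:offset] - baseline)
  dt_ms <- 1000 / fs
  auc <- sum((y[-length(y)] + y[-1]) / 2) * dt_ms

  structure(
    tibble(onset = as.integer(onset), offset = as.integer(offset),
           fpd_ms = fpd_ms, cfpd_ms = cfpd_ms, auc_uv_ms = auc,
           beating_rate_bpm = beating_rate,
           onset_mode = onset_mode, offset_mode = offset_mode),
    class = c("fp_measurement", class(tibble()))
  )
}

#' Measure FPD from manually supplied landmarks
#'
#' Same arithmetic as [measure_fpd()], with operator-fixed onset/offset
#' times in ms from the start of the waveform; the measurement is flagged
#' `"manual"` for both landmarks.
#'
#' @inheritParams measure_fpd
#' @param onset_ms,offset_ms Landmark times in ms,
#'   `0 <= onset_ms < offset_ms <= duration`.
#' @return A one-row `fp_measurement` tibble.
#' @export
manual_landmarks <- function(waveform, onset_ms, offset_ms, beating_rate,
                             sample_rate = NULL) {
  x <- wf_samples(waveform)
  fs <- wf_rate(waveform, sample_rate)
  dur_ms <- (length(x) - 1) / fs * 1000
  if (onset_ms < 0 || offset_ms > dur_ms || onset_ms >= offset_ms) {
    stop_cardiofp(
      sprintf("landmarks must satisfy 0 <= onset (%g) < offset (%g) <= %g ms",
              onset_ms, offset_ms, dur_ms),
      "range"
    )
  }
  measure_fpd(x, onset = round(onset_ms / 1000 * fs) + 1L,
              offset = round(offset_ms / 1000 * fs) + 1L,
              beating_rate = beating_rate, sample_rate = fs,
              onset_mode = "manual", offset_mode = "manual")
}

#' Locate landmarks and measure an averaged waveform
#'
#' Phase-II convenience wrapper: runs [detect_onset()] and/or
#' [detect_offset_tra()] (or takes manual landmark times in ms) and returns
#' the [measure_fpd()] row. Mixing one automatic and one manual landmark is
#' allowed; the mode flags record the choice per landmark.
#'
#' @inheritParams detect_onset
#' @param onset,offset `"auto"` or a manual landmark time in ms.
#' @param beating_rate Beating rate in bpm; for an
#'   [fp_waveform][new_fp_waveform] produced
#'   by the phase-I pipeline the rate stored in its source is the default.
#' @param tra_start Passed to [detect_offset_tra()] as `search_start`.
#' @return A one-row `fp_measurement` tibble.
#' @export
analyze_waveform <- function(waveform, onset = "auto", offset = "auto",
                             beating_rate = NULL, sample_rate = NULL,
                             frame_ms = 10, k = 3,
                             tra_start = "repol-peak") {
  x <- wf_samples(waveform)
  fs <- wf_rate(waveform, sample_rate)
  beating_rate <- beating_rate %||%
    (if (inherits(waveform, "fp_waveform")) waveform$source$beating_rate_bpm)
  if (is.null(beating_rate)) {
    stop_cardiofp("beating_rate is required (not recorded in the waveform source)",
                  "parameter")
  }
  if (identical(onset, "auto")) {
    on_i <- detect_onset(x, fs, frame_ms = frame_ms, k = k)
    on_mode <- "auto"
  } else {
    on_i <- round(onset / 1000 * fs) + 1L
    on_mode <- "manual"
  }
  if (identical(offset, "auto")) {
    off_i <- detect_offset_tra(x, fs, search_start = tra_start)
    off_mode <- "auto"
  } else {
    off_i <- round(offset / 1000 * fs) + 1L
    off_mode <- "manual"
  }
  measure_fpd(x, on_i, off_i, beating_rate, fs,
              onset_mode = on_mode, offset_mode = off_mode)
}
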