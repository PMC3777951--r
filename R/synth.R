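#' Configuration for the synthetic MEA recording generator
#'
#' Builds a validated parameter set for [synth_recording()] /
#' [synth_complex()]. Defaults emulate spontaneously beating human
#' cardiomyocyte aggregates on an MEA: 20 kHz sampling, beating rate around
#' 120 bpm, a large biphasic depolarization (sodium) spike followed by a
#' slow repolarisation wave whose end defines the field potential duration
#' (FPD).
#'
#' The waveform primitives have compact support so every landmark is exact:
#' the spike is a Hann-windowed full sine period (onset exactly at the beat
#' time `t0`, width `spike_width_ms`), and the repolarisation wave rises as a
#' raised cosine over `repol_rise_ms` and returns to baseline linearly over
#' `repol_fall_ms`, reaching zero exactly at `t0 + fpd_ms`. The linear
#' return makes the trapezium-area repolarisation endpoint (see
#' [detect_offset_tra()]) coincide exactly with the planted offset.
#'
#' Premature (arrhythmogenic) beats are planted with probability
#' `premature_prob` per beat: a shortened coupling interval
#' (`coupling_frac` of the base beat interval, with a compensatory pause
#' afterwards) and a morphology compressed in both amplitude and time by
#' `premature_shape_scale`, so that a correlation-based classifier can
#' reject them on shape, not only on timing. `drift_per_beat` linearly
#' scales the repolarisation amplitude per beat to emulate gradual
#' morphology change under drug wash-in.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param beating_rate_bpm Base spontaneous beating rate, beats per minute.
#' @param rate_jitter Fractional uniform jitter on each beat interval.
#' @param spike_amplitude_uv Depolarization spike peak amplitude, µV.
#' @param repol_amplitude_uv Repolarisation wave peak amplitude, µV.
#' @param fpd_ms Planted field potential duration, ms (onset to offset).
#' @param noise_sd_uv Additive i.i.d. Gaussian noise standard deviation, µV.
#' @param premature_prob Per-beat probability of a premature beat.
#' @param premature_shape_scale Amplitude and time compression factor for
#'   premature beats, in (0, 1].
#' @param drift_per_beat Fractional change of repolarisation amplitude per
#'   beat (0 = stable morphology).
#' @param coupling_frac Premature coupling interval as a fraction of the
#'   base beat interval.
#' @param spike_width_ms Depolarization spike support width, ms.
#' @param repol_rise_ms Raised-cosine rise time of the repolarisation wave, ms.
#' @param repol_fall_ms Linear fall time of the repolarisation wave, ms.
#' @param electrodes Character vector of electrode identifiers.
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(duration_s = 5, beating_rate_bpm = 60, seed = 7)
#' cfg$fpd_ms
synth_config <- function(sample_rate = 20000,
                         duration_s = 10,
                         beating_rate_bpm = 120,
                         rate_jitter = 0.02,
                         spike_amplitude_uv = 200,
                         repol_amplitude_uv = 50,
                         fpd_ms = 350,
                         noise_sd_uv = 2,
                         premature_prob = 0,
                         premature_shape_scale = 0.5,
                         drift_per_beat = 0,
                         coupling_frac = 0.6,
                         spike_width_ms = 10,
                         repol_rise_ms = 120,
                         repol_fall_ms = 80,
                         electrodes = "A1",
                         seed = 1L) {
  cfg <- list(
    sample_rate = sample_rate, duration_s = duration_s,
    beating_rate_bpm = beating_rate_bpm, rate_jitter = rate_jitter,
    spike_amplitude_uv = spike_amplitude_uv,
    repol_amplitude_uv = repol_amplitude_uv, fpd_ms = fpd_ms,
    noise_sd_uv = noise_sd_uv, premature_prob = premature_prob,
    premature_shape_scale = premature_shape_scale,
    drift_per_beat = drift_per_beat, coupling_frac = coupling_frac,
    spike_width_ms = spike_width_ms, repol_rise_ms = repol_rise_ms,
    repol_fall_ms = repol_fall_ms, electrodes = as.character(electrodes),
    seed = as.integer(seed)
  )
  rr_ms <- 60000 / cfg$beating_rate_bpm
  if (cfg$sample_rate <= 0) stop_cardiofp("sample rate must be positive", "config")
  if (cfg$fpd_ms >= rr_ms) {
    stop_cardiofp(
      sprintf("fpd_ms (%g) must be shorter than the beat interval (%g ms at %g bpm)",
              cfg$fpd_ms, rr_ms, cfg$beating_rate_bpm),
      "config"
    )
  }
  if (cfg$fpd_ms <= cfg$repol_rise_ms + cfg$repol_fall_ms) {
    stop_cardiofp("fpd_ms must exceed repol_rise_ms + repol_fall_ms", "config")
  }
  amps <- c(cfg$spike_amplitude_uv, cfg$repol_amplitude_uv, cfg$noise_sd_uv)
  if (any(amps < 0)) stop_cardiofp("amplitudes and noise SD must be >= 0", "config")
  probs <- c(cfg$rate_jitter, cfg$premature_prob)
  if (any(probs < 0 | probs > 1)) stop_cardiofp("probabilities must lie in [0, 1]", "config")
  if (cfg$premature_shape_scale <= 0 || cfg$premature_shape_scale > 1) {
    stop_cardiofp("premature_shape_scale must lie in (0, 1]", "config")
  }
  if (anyDuplicated(cfg$electrodes)) stop_cardiofp("electrode identifiers must be unique", "config")
  structure(cfg, class = "synth_config")
}

# Peak value and location of the unit spike shape sin(2*pi*u) * sin(pi*u)^2
# on u in [0, 1]; used to normalise the spike to its nominal amplitude.
spike_shape_peak <- function() {
  opt <- stats::optimize(function(u) sin(2 * pi * u) * sin(pi * u)^2,
                         interval = c(0, 0.5), maximum = TRUE, tol = 1e-12)
  list(u = opt$maximum, value = opt$objective)
}

#' Generate a single synthetic field-potential complex
#'
#' Evaluates one beat of the synthetic waveform on the sample grid, with
#' exact landmark annotations. Time zero is the depolarization onset.
#'
#' @param cfg A [synth_config()].
#' @param shape_scale Amplitude-and-time compression factor (1 = normal
#'   beat; premature beats use `cfg$premature_shape_scale`).
#' @param repol_gain Extra multiplier on the repolarisation amplitude
#'   (used for morphology drift).
#'
#' @return A list with `samples` (µV, compact support starting at onset),
#'   and landmark annotations in ms relative to onset: `onset_ms` (0),
#'   `offset_ms` (planted FPD), `depol_peak_ms`, `repol_peak_ms`, plus
#'   `fpd_ms` and `sample_rate`.
#' @export
#' @examples
#' cplx <- synth_complex(synth_config(sample_rate = 2000))
#' cplx$offset_ms
synth_complex <- function(cfg, shape_scale = 1, repol_gain = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sample_rate
  # the spike keeps its width under shape scaling (a compressed spike would
  # simply vanish under the 200 Hz low-pass rather than change morphology);
  # amplitudes and the repolarisation geometry scale
  w <- cfg$spike_width_ms
  fpd <- cfg$fpd_ms * shape_scale
  fall <- cfg$repol_fall_ms * shape_scale
  rise <- cfg$repol_rise_ms * shape_scale
  tp <- fpd - fall          # repolarisation peak
  trs <- tp - rise          # repolarisation rise start
  n <- floor(fpd / 1000 * fs) + 1L
  t <- (seq_len(n) - 1) / fs * 1000
  pk <- spike_shape_peak()

  spike <- numeric(n)
  in_spike <- t < w
  u <- t[in_spike] / w
  s <- cfg$spike_amplitude_uv * shape_scale *
    sin(2 * pi * u) * sin(pi * u)^2 / pk$value
  # dominant positive deflection: the trailing negative lobe is scaled to
  # 80%, as in typical biphasic extracellular field potentials
  spike[in_spike] <- pmax(s, 0) + 0.8 * pmin(s, 0)

  ra <- cfg$repol_amplitude_uv * shape_scale * repol_gain
  repol <- numeric(n)
  in_rise <- t >= trs & t < tp
  repol[in_rise] <- ra * 0.5 * (1 - cos(pi * (t[in_rise] - trs) / rise))
  in_fall <- t >= tp & t <= fpd
  repol[in_fall] <- ra * (1 - (t[in_fall] - tp) / fall)

  list(
    samples = spike + repol,
    onset_ms = 0,
    offset_ms = if (ra > 0) fpd else w,
    depol_peak_ms = pk$u * w,
    repol_peak_ms = tp,
    fpd_ms = fpd,
    sample_rate = fs
  )
}

# Evaluate an expression with a private, seeded RNG stream, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic MEA recording with ground-truth annotations
#'
#' Schedules beats at the configured rate (with optional interval jitter and
#' planted premature beats), stamps the synthetic complex at each beat time,
#' adds i.i.d. Gaussian noise per electrode, and returns both the recording
#' and an exact per-beat ground-truth table. Identical configuration and
#' seed give bit-identical output.
#'
#' @param cfg A [synth_config()].
#'
#' @return A list with two elements:
#' \describe{
#'   \item{recording}{An [fp_recording][new_fp_recording] tibble (`time_ms` + one µV column
#'     per electrode).}
#'   \item{truth}{A tibble with one row per beat: `beat`, `t0_sample`
#'     (depolarization onset), `label` (`"normal"`, `"premature"` or
#'     `"drifted"`), `onset_sample`, `offset_sample`, `depol_peak_sample`,
#'     `fpd_ms`.}
#' }
#' @export
#' @examples
#' out <- synth_recording(synth_config(sample_rate = 2000, duration_s = 5,
#'                                     beating_rate_bpm = 60, rate_jitter = 0,
#'                                     noise_sd_uv = 0))
#' nrow(out$truth)
synth_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sample_rate
  n <- round(cfg$duration_s * fs)
  dur_ms <- cfg$duration_s * 1000
  rr <- 60000 / cfg$beating_rate_bpm

  with_seed(cfg$seed, {
    # Beat schedule: first beat after half a beat interval of baseline;
    # premature beats use a shortened coupling interval and are followed by
    # a compensatory pause. No two consecutive premature beats.
    t0 <- rr / 2
    times <- numeric(0)
    premature <- logical(0)
    next_gap_factor <- 1
    repeat {
      k <- length(times)
      is_prem <- k > 0 && !premature[k] && next_gap_factor == 1 &&
        stats::runif(1) < cfg$premature_prob
      if (k > 0) {
        gap <- if (is_prem) cfg$coupling_frac * rr
               else rr * next_gap_factor * (1 + cfg$rate_jitter * stats::runif(1, -1, 1))
        t0 <- times[k] + gap
      }
      scale_k <- if (is_prem) cfg$premature_shape_scale else 1
      if (t0 + cfg$fpd_ms * scale_k > dur_ms - 1) break
      times <- c(times, t0)
      premature <- c(premature, is_prem)
      next_gap_factor <- if (is_prem) 2 - cfg$coupling_frac else 1
    }
    if (length(times) == 0) {
      stop_cardiofp("configured duration is too short for a single beat", "config")
    }

    clean <- numeric(n)
    truth <- vector("list", length(times))
    drift_base <- 0L   # drift indexes beats, prematures excluded
    for (k in seq_along(times)) {
      scale_k <- if (premature[k]) cfg$premature_shape_scale else 1
      gain_k <- 1
      if (!premature[k]) {
        gain_k <- 1 + cfg$drift_per_beat * drift_base
        drift_base <- drift_base + 1L
      }
      cx <- synth_complex(cfg, shape_scale = scale_k, repol_gain = gain_k)
      i0 <- round(times[k] / 1000 * fs) + 1L
      idx <- i0:(i0 + length(cx$samples) - 1L)
      clean[idx] <- clean[idx] + cx$samples
      label <- if (premature[k]) "premature"
               else if (abs(gain_k - 1) > 0.1) "drifted" else "normal"
      truth[[k]] <- tibble(
        beat = k,
        t0_sample = i0,
        label = label,
        onset_sample = i0,
        offset_sample = i0 + round(cx$offset_ms / 1000 * fs),
        depol_peak_sample = i0 + round(cx$depol_peak_ms / 1000 * fs),
        fpd_ms = cx$fpd_ms
      )
    }
    truth <- bind_rows(truth)

    traces <- lapply(cfg$electrodes, function(e) {
      clean + if (cfg$noise_sd_uv > 0) stats::rnorm(n, 0, cfg$noise_sd_uv) else 0
    })
    names(traces) <- cfg$electrodes
    rec <- new_fp_recording(traces, sample_rate = fs)
    list(recording = rec, truth = truth)
  })
}

#' Match detected beats to ground-truth annotations
#'
#' Maps each detected depolarization-peak index to the nearest ground-truth
#' beat (within `tol_ms`) and returns that beat's label, or `NA` where no
#' annotated beat is close enough. Used to score classifier output against
#' [synth_recording()] annotations.
#'
#' @param peak_indices Detected peak sample indices.
#' @param truth Ground-truth tibble from [synth_recording()].
#' @param sample_rate Sampling rate in Hz.
#' @param tol_ms Matching tolerance in ms.
#' @return Character vector of labels, one per detected peak.
#' @export
match_beat_labels <- function(peak_indices, truth, sample_rate, tol_ms = 5) {
  tol <- tol_ms / 1000 * sample_rate
  vapply(peak_indices, function(i) {
    d <- abs(truth$depol_peak_sample - i)
    j <- which.min(d)
    if (d[j] <= tol) truth$label[j] else NA_character_
  }, character(1))
}
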