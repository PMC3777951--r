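#' Multi-channel MEA field-potential recording
#'
#' An `fp_recording` is a tibble with a `time_ms` column followed by one
#' amplitude column (µV) per electrode, carrying the sampling rate as an
#' attribute. All traces share one sampling rate and length; electrode
#' identifiers are unique.
#'
#' @param traces Named list of equal-length numeric µV vectors; names are
#'   electrode identifiers (e.g. `"A1"`, `"21"`).
#' @param sample_rate Sampling rate in Hz (positive).
#' @param time_ms Optional time axis in ms; defaults to a zero-based grid at
#'   `sample_rate`.
#'
#' @return An `fp_recording` tibble.
#' @export
#' @examples
#' rec <- new_fp_recording(list(A1 = sin(1:100), A2 = cos(1:100)),
#'                         sample_rate = 1000)
#' rec_duration(rec)
new_fp_recording <- function(traces, sample_rate, time_ms = NULL) {
  if (!is.list(traces) || length(traces) == 0 || is.null(names(traces)) ||
      any(!nzchar(names(traces)))) {
    stop_cardiofp("traces must be a non-empty named list of numeric vectors", "format")
  }
  if (anyDuplicated(names(traces))) {
    stop_cardiofp("electrode identifiers must be unique", "format")
  }
  len <- unique(lengths(traces))
  if (length(len) != 1 || len < 2) {
    stop_cardiofp("all traces must have identical length >= 2", "format")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop_cardiofp("sample_rate must be positive", "format")
  }
  if (is.null(time_ms)) time_ms <- (seq_len(len) - 1) / sample_rate * 1000
  out <- tibble(time_ms = time_ms)
  for (e in names(traces)) out[[e]] <- as.numeric(traces[[e]])
  structure(out,
            sample_rate = as.numeric(sample_rate),
            class = c("fp_recording", class(out)))
}

#' @rdname new_fp_recording
#' @param rec An `fp_recording`.
#' @export
rec_sample_rate <- function(rec) attr(rec, "sample_rate")

#' @rdname new_fp_recording
#' @export
rec_electrodes <- function(rec) setdiff(names(rec), "time_ms")

#' @rdname new_fp_recording
#' @export
rec_duration <- function(rec) nrow(rec) / rec_sample_rate(rec)

#' @rdname new_fp_recording
#' @param electrode Electrode identifier; defaults to the first.
#' @export
rec_trace <- function(rec, electrode = NULL) {
  electrode <- electrode %||% rec_electrodes(rec)[1]
  if (!electrode %in% rec_electrodes(rec)) {
    stop_cardiofp(
      sprintf("electrode '%s' not present; available: %s", electrode,
              paste(rec_electrodes(rec), collapse = ", ")),
      "lookup"
    )
  }
  rec[[electrode]]
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> %d electrode(s), %.6g Hz, %.3f s\n",
              length(rec_electrodes(x)), rec_sample_rate(x), rec_duration(x)))
  NextMethod()
}

#' Plot an MEA recording
#'
#' One facet per electrode, amplitude in µV against time in seconds.
#'
#' @param object An [fp_recording][new_fp_recording].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_ms",
                              names_to = "electrode", values_to = "amplitude_uv")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms / 1000, .data$amplitude_uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~electrode, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "amplitude (\u00b5V)")
}
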