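#' Read an MC_DataTool-style ASCII MEA export
#'
#' Parses the ASCII dialect produced by MC_DataTool conversions of native
#' MEA recordings: one or more header lines, the last of which holds
#' tab-separated column names (column 1 = time, remaining columns one per
#' electrode, e.g. `A1[uV]`), followed by tab-delimited numeric rows.
#' Amplitudes are interpreted in µV. The time unit is auto-detected from the
#' median inter-sample step (ms if < 1, seconds otherwise) unless given, and
#' the sampling rate is inferred from the median step unless overridden.
#' Steps jittering by more than 1 ppm (text rounding) trigger a warning and
#' the median step is used.
#'
#' @param path Path to the ASCII file.
#' @param electrodes Optional character vector of electrode identifiers to
#'   keep (in the requested order); all electrodes if `NULL`.
#' @param time_unit `"auto"`, `"ms"` or `"s"`.
#' @param sample_rate Optional sampling-rate override in Hz.
#'
#' @return An [fp_recording][new_fp_recording].
#' @export
#' @examples
#' cfg <- synth_config(sample_rate = 1000, duration_s = 3,
#'                     beating_rate_bpm = 60, noise_sd_uv = 0)
#' f <- tempfile(fileext = ".txt")
#' write_mcd_ascii(synth_recording(cfg)$recording, f)
#' rec <- read_mcd_ascii(f)
#' rec_sample_rate(rec)
read_mcd_ascii <- function(path, electrodes = NULL,
                           time_unit = c("auto", "ms", "s"),
                           sample_rate = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop_cardiofp(sprintf("file not found: %s", path), "io")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_cardiofp("file is empty: no header present", "format")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_data <- vapply(fields, function(f) {
    length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f)))
  }, logical(1))
  first_data <- which(is_data)[1]
  if (is.na(first_data)) {
    stop_cardiofp("no numeric data rows found after the header", "parse")
  }
  if (first_data == 1) {
    stop_cardiofp("missing header: line 1 is already numeric data", "format")
  }
  header_cols <- fields[[first_data - 1]]
  if (length(header_cols) < 2) {
    stop_cardiofp(
      sprintf("unparseable header: line %d must hold >= 2 tab-separated column names",
              first_data - 1),
      "format"
    )
  }
  # "A1[uV]" -> "A1"; tolerate surrounding whitespace
  ids <- trimws(sub("\\[.*\\]\\s*$", "", header_cols))
  available <- ids[-1]
  if (anyDuplicated(available)) {
    stop_cardiofp("duplicate electrode identifiers in header", "format")
  }

  data_fields <- fields[first_data:length(fields)]
  nf <- lengths(data_fields)
  bad <- which(nf != length(header_cols))
  if (length(bad) > 0) {
    stop_cardiofp(
      sprintf("ragged row: data row %d (file line %d) has %d fields, expected %d",
              bad[1], first_data + bad[1] - 1, nf[bad[1]], length(header_cols)),
      "parse"
    )
  }
  vals <- suppressWarnings(as.numeric(unlist(data_fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / length(header_cols))
    stop_cardiofp(
      sprintf("non-numeric cell in data row %d (file line %d)",
              bad_row, first_data + bad_row - 1),
      "parse"
    )
  }
  m <- matrix(vals, ncol = length(header_cols), byrow = TRUE)
  if (nrow(m) < 2) stop_cardiofp("need at least 2 data rows", "parse")

  keep <- electrodes %||% available
  missing <- setdiff(keep, available)
  if (length(missing) > 0) {
    stop_cardiofp(
      sprintf("electrode(s) %s not in header; available: %s",
              paste(missing, collapse = ", "), paste(available, collapse = ", ")),
      "lookup"
    )
  }

  tvals <- m[, 1]
  steps <- diff(tvals)
  med <- median(steps)
  if (med <= 0) stop_cardiofp("time column is not strictly increasing", "parse")
  # Auto-detection: an ms-based export has a step of >= 0.02 ms for any
  # sampling rate up to 50 kHz, while a seconds-based export at >= 1 kHz has
  # a step of <= 0.001; 0.02 separates the two regimes.
  if (time_unit == "auto") time_unit <- if (med < 0.02) "s" else "ms"
  step_ms <- if (time_unit == "ms") med else med * 1000
  if (max(abs(steps - med)) / med > 1e-6) {
    warn(sprintf("time column jitter exceeds 1 ppm; using median step (%g %s)",
                 med, time_unit))
  }
  fs <- sample_rate %||% (1000 / step_ms)

  traces <- lapply(keep, function(e) m[, 1 + match(e, available)])
  names(traces) <- keep
  time_ms <- if (time_unit == "ms") tvals else tvals * 1000
  new_fp_recording(traces, sample_rate = fs, time_ms = time_ms)
}

#' Write a recording as an MC_DataTool-style ASCII export
#'
#' Fixture-writing companion of [read_mcd_ascii()]: a short header (last
#' header line = tab-separated column names), then tab-delimited rows of
#' time in ms and per-electrode amplitude in µV. Amplitudes are printed to
#' 3 decimals, so a read-back reproduces samples to 1e-3 µV.
#'
#' @param rec An [fp_recording][new_fp_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mcd_ascii <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  els <- rec_electrodes(rec)
  fs <- rec_sample_rate(rec)
  header <- c(
    "MC_DataTool ASCII conversion (synthetic)",
    sprintf("Sample rate [Hz] = %.10g", fs),
    paste(c("t[ms]", paste0(els, "[uV]")), collapse = "\t")
  )
  t_ms <- (seq_len(nrow(rec)) - 1) / fs * 1000
  cols <- c(list(sprintf("%.6f", t_ms)),
            lapply(els, function(e) sprintf("%.3f", rec[[e]])))
  rows <- do.call(paste, c(cols, sep = "\t"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_cardiofp(sprintf("cannot open '%s' for writing: %s", path,
                          conditionMessage(e)), "io")
  })
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Write and read FPD measurement tables
#'
#' Measurement tables (see [measure_fpd()]) are stored as plain CSV; a
#' written table reads back field-for-field. An empty table yields a valid
#' header-only file.
#'
#' @param measurements A tibble of FPD measurements.
#' @param path CSV file path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` returns the tibble.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_cardiofp(sprintf("file not found: %s", path), "io")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read averaged-waveform archives
#'
#' An averaged waveform is stored as a self-describing pair: `<prefix>.json`
#' holds the metadata (sampling rate, ensemble count, provenance) and
#' `<prefix>.csv` the samples at full double precision, so the round trip is
#' exact.
#'
#' @param waveform An [fp_waveform][new_fp_waveform].
#' @param prefix Path prefix (without extension) for the `.json`/`.csv` pair.
#' @return `write_waveform()` returns the JSON path invisibly;
#'   `read_waveform()` returns the [fp_waveform][new_fp_waveform].
#' @export
write_waveform <- function(waveform, prefix) {
  stopifnot(inherits(waveform, "fp_waveform"))
  prefix <- sub("\\.json$", "", prefix)
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  readr::write_csv(
    tibble(sample = seq_along(waveform$samples), amplitude_uv = waveform$samples),
    csv
  )
  meta <- list(
    format = "cardiofp_waveform",
    sample_rate = waveform$sample_rate,
    n_ensembles = waveform$n_ensembles,
    source = waveform$source,
    samples_file = basename(csv)
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(json)
}

#' @rdname write_waveform
#' @param path Path to the `.json` metadata file (or the prefix).
#' @export
read_waveform <- function(path) {
  json <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  if (!file.exists(json)) stop_cardiofp(sprintf("file not found: %s", json), "io")
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  if (!identical(meta$format, "cardiofp_waveform")) {
    stop_cardiofp(sprintf("%s is not a cardiofp waveform archive", json), "format")
  }
  csv <- file.path(dirname(json), meta$samples_file)
  samples <- readr::read_csv(csv, show_col_types = FALSE)$amplitude_uv
  new_fp_waveform(samples, sample_rate = meta$sample_rate,
                  n_ensembles = meta$n_ensembles,
                  source = meta$source)
}
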