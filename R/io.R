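# Readers and writers: OpenFace-dialect CSV, tidy marker and MADRS tables,
# results tables, amplitude traces (plain text or 16-bit PCM WAV), and
# structured run configuration.

#' Read an OpenFace-dialect frame CSV
#'
#' Accepts both plain and padded headers (OpenFace emits `", AU01_r"`-style
#' comma-space headers); column names are trimmed.  The mandatory columns
#' `frame`, `timestamp`, `confidence`, `success` plus at least one
#' `AUxx_r`/`AUxx_c` column must be present; unknown columns are preserved.
#'
#' @param path Path to the CSV file.
#' @return Frame tibble.
#' @export
read_openface_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  names(raw) <- trimws(names(raw))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("unparseable rows in %s (first at line %d: %s).",
                  path, probs$row[1], probs$expected[1]),
          class = "dbm_parse_error")
  }
  mandatory <- c("frame", "timestamp", "confidence", "success")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    abort(sprintf("%s lacks mandatory column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "dbm_schema_error")
  }
  if (!any(grepl("^AU\\d{2}_[rc]$", names(raw)))) {
    abort(sprintf("%s has no AU columns.", path), class = "dbm_schema_error")
  }
  tibble::as_tibble(raw)
}

#' Write a frame table as OpenFace-dialect CSV
#'
#' @param frames Frame tibble.
#' @param path Output path.
#' @export
write_openface_csv <- function(frames, path) {
  readr::write_csv(tibble::as_tibble(frames), path, progress = FALSE)
  invisible(path)
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(sprintf("%s lacks column(s): %s", what, paste(missing, collapse = ", ")),
          class = "dbm_schema_error")
  }
}

#' Read / write the tidy marker table
#'
#' @param path CSV path.
#' @return Marker tibble (`subject_id`, `study_day`, `stimulus_class`,
#'   `marker`, `value`).
#' @export
read_marker_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, c("subject_id", "study_day", "stimulus_class", "marker", "value"),
                path)
  d
}

#' @rdname read_marker_table
#' @param markers Marker tibble.
#' @export
write_marker_table <- function(markers, path) {
  check_columns(markers, c("subject_id", "study_day", "stimulus_class",
                           "marker", "value"), "marker table")
  readr::write_csv(markers, path, progress = FALSE)
  invisible(path)
}

#' Read / write the MADRS table
#'
#' @param path CSV path.
#' @return MADRS tibble (`subject_id`, `visit`, `study_day`, `madrs`).
#' @export
read_madrs_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, c("subject_id", "study_day", "madrs"), path)
  d
}

#' @rdname read_madrs_table
#' @param madrs MADRS tibble.
#' @export
write_madrs_table <- function(madrs, path) {
  check_columns(madrs, c("subject_id", "study_day", "madrs"), "MADRS table")
  readr::write_csv(madrs, path, progress = FALSE)
  invisible(path)
}

#' Write / read an analysis results table
#'
#' Rows are written in deterministic order — condition (neutral, positive,
#' negative), then marker in catalog order — and round-trip exactly through
#' [read_results_table()].
#'
#' @param results A `marker_results` tibble (see [analyze_markers()]).
#' @param path CSV path.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) {
    abort("refusing to write an empty results table.", class = "dbm_bad_argument")
  }
  out <- order_results(tibble::as_tibble(results))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @return `read_results_table()` returns the results tibble.
#' @export
read_results_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         condition = "c", marker = "c",
                         statistic_kind = "c", direction = "c"))
  check_columns(d, c("condition", "marker", "statistic_kind", "statistic",
                     "p_raw", "p_fdr", "direction"), path)
  d
}

# ---- audio -----------------------------------------------------------------

#' Read / write amplitude traces
#'
#' Plain one-column numeric text (default interchange format; one sample
#' per line) or canonical 16-bit PCM mono WAV.  The sample rate of a text
#' trace is stated by the caller; a WAV file carries its own.
#'
#' @param path File path.
#' @param sample_rate Samples per second for text traces.
#' @return An `amplitude_series`.
#' @export
read_amplitude_text <- function(path, sample_rate) {
  assert_scalar_number(sample_rate, "sample_rate", min = 1)
  x <- scan(path, what = double(), quiet = TRUE)
  structure(list(samples = x, sample_rate = sample_rate,
                 duration_s = length(x) / sample_rate,
                 speech_intervals = NULL),
            class = "amplitude_series")
}

#' @rdname read_amplitude_text
#' @param audio An `amplitude_series` or numeric vector.
#' @export
write_amplitude_text <- function(audio, path) {
  x <- if (inherits(audio, "amplitude_series")) audio$samples else audio
  writeLines(formatC(x, format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname read_amplitude_text
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, 4))
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("%s is not a RIFF/WAVE file.", path), class = "dbm_parse_error")
  }
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4)
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2)
      sample_rate <- readBin(con, "integer", 1, 4)
      invisible(readBin(con, "integer", 1, 4))
      invisible(readBin(con, "integer", 1, 2))
      bits <- readBin(con, "integer", 1, 2)
      if (fmt[1] != 1L || fmt[2] != 1L || bits != 16L) {
        abort("only 16-bit PCM mono WAV is supported.", class = "dbm_parse_error")
      }
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (id == "data") {
      samples <- readBin(con, "integer", size / 2L, 2, signed = TRUE)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(sample_rate) || is.null(samples)) {
    abort(sprintf("%s: missing fmt or data chunk.", path), class = "dbm_parse_error")
  }
  structure(list(samples = samples / 32767, sample_rate = sample_rate,
                 duration_s = length(samples) / sample_rate,
                 speech_intervals = NULL),
            class = "amplitude_series")
}

#' @rdname read_amplitude_text
#' @export
write_wav <- function(audio, path, sample_rate = NULL) {
  if (inherits(audio, "amplitude_series")) {
    sample_rate <- audio$sample_rate
    audio <- audio$samples
  }
  assert_scalar_number(sample_rate, "sample_rate", min = 1)
  pcm <- as.integer(round(clip(audio, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4)
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4)
  writeBin(c(1L, 1L), con, size = 2)                   # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4)
  writeBin(as.integer(sample_rate * 2L), con, size = 4) # byte rate
  writeBin(c(2L, 16L), con, size = 2)                   # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4)
  writeBin(pcm, con, size = 2)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

#' Write / read a run configuration
#'
#' Serialises a [cohort_config()] (or any named list of run constants) to
#' YAML; every run echoes its effective configuration into the output
#' directory so it can be re-executed.
#'
#' @param config Named list.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  if (all(c("n_subjects", "seed") %in% names(cfg))) {
    do.call(cohort_config, cfg[intersect(names(cfg), known)])
  } else {
    cfg
  }
}
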