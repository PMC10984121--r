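#' Write an electrome series to a text file
#'
#' The format is a plain-text column of voltage values (mV, one per line,
#' 12 significant digits) preceded by `#`-prefixed header lines carrying the
#' sampling rate, units and provenance metadata. It is diff-friendly and
#' round-trips through [read_series()].
#'
#' @param series An [electrome_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_series(electrome_series(c(0.1, -0.2, 0.3)), f)
#' readLines(f)
#' @export
write_series <- function(series, path) {
  stopifnot(is_electrome_series(series))
  m <- series$meta
  header <- c(
    "# electromer series v1",
    sprintf("# rate_hz: %.10g", series$rate),
    "# units: mV",
    sprintf("# experiment: %s", m$experiment),
    sprintf("# plant_id: %s", m$plant_id),
    sprintf("# phase: %s", m$phase),
    sprintf("# is_reference: %s", m$is_reference)
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing.", path), class = "electromer_io_error")
  })
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.12g", series$samples), con)
  invisible(path)
}

#' Read an electrome series from a text file
#'
#' Parses the format written by [write_series()]: `#`-prefixed `key: value`
#' header lines (`rate_hz` is mandatory) followed by one finite numeric
#' voltage per line. Malformed records are reported with their line number.
#'
#' @param path Input file path.
#' @return An [electrome_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path), class = "electromer_io_error")
  }
  lines <- readLines(path)
  if (length(lines) == 0L) {
    abort(sprintf("'%s' is empty.", path), class = "electromer_empty_input")
  }
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  body <- lines[!is_header]
  body_lineno <- which(!is_header)

  kv <- regmatches(header, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", header))
  keys <- vapply(kv, function(x) if (length(x) == 3L) x[2] else NA_character_, "")
  vals <- vapply(kv, function(x) if (length(x) == 3L) x[3] else NA_character_, "")
  meta <- setNames(as.list(vals[!is.na(keys)]), keys[!is.na(keys)])

  if (is.null(meta$rate_hz)) {
    abort(sprintf("'%s': header is missing the mandatory 'rate_hz' field.", path),
      class = "electromer_format_error"
    )
  }
  rate <- suppressWarnings(as.numeric(meta$rate_hz))
  if (!is.finite(rate) || rate <= 0) {
    abort(sprintf("'%s': invalid rate_hz '%s'.", path, meta$rate_hz),
      class = "electromer_format_error"
    )
  }
  body <- body[nzchar(trimws(body))]
  body_lineno <- body_lineno[nzchar(trimws(body))]
  if (length(body) == 0L) {
    abort(sprintf("'%s' contains no data records.", path),
      class = "electromer_empty_input"
    )
  }
  values <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "'%s': non-numeric or non-finite value '%s' at line %d.",
        path, body[bad[1]], body_lineno[bad[1]]
      ),
      class = "electromer_format_error"
    )
  }
  na_if_literal <- function(x) if (identical(x, "NA")) NA_character_ else x
  electrome_series(
    values,
    rate = rate,
    experiment = na_if_literal(meta$experiment %||% NA_character_),
    plant_id = suppressWarnings(as.integer(meta$plant_id %||% NA)),
    phase = na_if_literal(meta$phase %||% NA_character_),
    is_reference = identical(meta$is_reference, "TRUE")
  )
}

#' Apply the acquisition-filter emulation
#'
#' Zero-phase (forward-backward) second-order Butterworth high-pass,
#' emulating the recorder's high-pass setting. The DC component is removed;
#' passband amplitudes are preserved. The analog anti-alias low-pass of the
#' hardware has no digital counterpart at this sampling rate and is not
#' modeled.
#'
#' @param series An [electrome_series()] or numeric vector.
#' @param highpass_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency.
#' @param rate Sampling rate, required when `series` is a bare vector.
#' @return Filtered series of the same type as the input.
#' @examples
#' s <- electrome_series(rep(1, 500))
#' max(abs(apply_acquisition_filter(s)$samples)) # ~ 0
#' @export
apply_acquisition_filter <- function(series, highpass_hz = 0.5, rate = NULL) {
  rate <- series_rate(series, rate)
  if (highpass_hz <= 0 || highpass_hz >= rate / 2) {
    abort("`highpass_hz` must lie in (0, rate/2).",
      class = "electromer_invalid_parameter"
    )
  }
  x <- series_samples(series)
  bf <- signal::butter(2, W = highpass_hz / (rate / 2), type = "high")
  # remove the mean first: the high-pass kills DC anyway, and doing it
  # up front avoids a large edge transient in the uninitialized filter
  y <- signal::filtfilt(bf, x - mean(x))
  if (is_electrome_series(series)) {
    series$samples <- as.numeric(y)
    series
  } else {
    as.numeric(y)
  }
}
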