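#' Construct an electrome series
#'
#' An `electrome_series` bundles one electrophytogram — a voltage-variation
#' time series in millivolts — with its sampling rate and provenance
#' metadata (experiment, plant, recording phase, reference-electrode flag).
#'
#' @param samples Numeric vector of voltage variations (mV). All values must
#'   be finite.
#' @param rate Sampling frequency in Hz (default 62.5, the acquisition rate
#'   the package emulates).
#' @param experiment Treatment name (e.g. `"water"`, `"nutrient"`, `"peg"`,
#'   `"nacl"`), or `NA`.
#' @param plant_id Integer plant identifier, or `NA`.
#' @param phase `"before"` or `"after"` stimulation, or `NA` for reference
#'   electrodes.
#' @param is_reference Logical; `TRUE` for the dead-stem reference electrode
#'   that monitors cage noise.
#'
#' @return An object of class `electrome_series`: a list with elements
#'   `samples`, `rate`, `duration` (seconds) and `meta`.
#' @examples
#' s <- electrome_series(sin(2 * pi * 5 * seq(0, 1, by = 1 / 62.5)))
#' s
#' @export
electrome_series <- function(samples, rate = 62.5, experiment = NA_character_,
                             plant_id = NA_integer_, phase = NA_character_,
                             is_reference = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one value.", class = "electromer_empty_input")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite (no NA/NaN/Inf).", class = "electromer_invalid_parameter")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).", class = "electromer_invalid_parameter")
  }
  if (!is.na(phase) && !phase %in% c("before", "after")) {
    abort("`phase` must be 'before', 'after' or NA.", class = "electromer_config_error")
  }
  structure(
    list(
      samples = samples,
      rate = rate,
      duration = length(samples) / rate,
      meta = list(
        experiment = as.character(experiment),
        plant_id = as.integer(plant_id),
        phase = as.character(phase),
        is_reference = isTRUE(is_reference)
      )
    ),
    class = "electrome_series"
  )
}

#' @export
print.electrome_series <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<electrome_series> %d samples @ %g Hz (%.1f s)\n", length(x$samples),
    x$rate, x$duration
  ))
  cat(sprintf(
    "  experiment: %s | plant: %s | phase: %s%s\n",
    m$experiment %||% NA, m$plant_id %||% NA, m$phase %||% NA,
    if (isTRUE(m$is_reference)) " | reference electrode" else ""
  ))
  cat(sprintf(
    "  range [%.4g, %.4g] mV, sd %.4g mV\n",
    min(x$samples), max(x$samples), sd(x$samples)
  ))
  invisible(x)
}

#' @export
as_tibble.electrome_series <- function(x, ...) {
  tibble(
    time_s = (seq_along(x$samples) - 1) / x$rate,
    voltage_mv = x$samples
  )
}

is_electrome_series <- function(x) inherits(x, "electrome_series")

# Accept either an electrome_series or a bare numeric vector; returns the
# sample vector and (when needed) the rate.
series_samples <- function(x) {
  if (is_electrome_series(x)) x$samples else as.numeric(x)
}

series_rate <- function(x, rate = NULL) {
  if (!is.null(rate)) return(rate)
  if (is_electrome_series(x)) return(x$rate)
  abort("`rate` must be supplied when the input is a bare numeric vector.",
    class = "electromer_invalid_parameter"
  )
}

#' Plot an electrome series
#'
#' @param object An [electrome_series()].
#' @param ... Unused.
#' @return A ggplot showing voltage variation (mV) against time (s).
#' @export
autoplot.electrome_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$time_s, .data$voltage_mv)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(
      x = "Time (s)", y = expression(Delta * V ~ "(mV)"),
      title = sprintf(
        "%s / %s", object$meta$experiment %||% "series",
        object$meta$phase %||% ""
      )
    ) +
    ggplot2::theme_minimal()
}
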