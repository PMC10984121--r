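#' Describe an experimental design
#'
#' A session design lists, per experiment, how many plants were recorded
#' (each contributing a before and an after series) and how many sessions
#' were run (each contributing before/after reference-electrode series from
#' the dead stem segment that monitors cage noise). The default reproduces
#' the study design this package emulates: water 30 plants / 10 sessions,
#' nutrient solution 21 / 7, PEG 54 / 18, NaCl 39 / 13, two-hour recordings
#' at 62.5 Hz (450,000 samples per series).
#'
#' @param experiments Data frame with columns `experiment`, `n_plants`,
#'   `n_sessions`. Zero rows are allowed (empty design).
#' @param samples_per_series Samples per recording.
#' @param rate Sampling frequency in Hz.
#'
#' @return A list of class `session_design`.
#' @examples
#' session_design()
#' @export
session_design <- function(experiments = tibble(
                             experiment = c("water", "nutrient", "peg", "nacl"),
                             n_plants = c(30L, 21L, 54L, 39L),
                             n_sessions = c(10L, 7L, 18L, 13L)
                           ),
                           samples_per_series = 450000L,
                           rate = 62.5) {
  experiments <- as_tibble(experiments)
  stopifnot(all(c("experiment", "n_plants", "n_sessions") %in% names(experiments)))
  if (any(experiments$n_plants < 0) || any(experiments$n_sessions < 0)) {
    abort("plant and session counts must be >= 0.",
      class = "electromer_invalid_parameter"
    )
  }
  structure(
    list(
      experiments = experiments,
      samples_per_series = as.integer(samples_per_series),
      rate = rate
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf(
    "<session_design> %d experiment(s), %d samples/series @ %g Hz\n",
    nrow(x$experiments), x$samples_per_series, x$rate
  ))
  print(x$experiments)
  invisible(x)
}

#' Enumerate every series of a design
#'
#' Expands a [session_design()] into one row per series: each plant yields a
#' before and an after electrome series; each session yields a before and an
#' after reference-electrode series. Series are not synthesized here — use
#' [realize_series()] on any subset of rows.
#'
#' @param design A [session_design()].
#' @return A tibble (class `electrome_manifest`) with columns `series_id`,
#'   `experiment`, `plant_id`, `phase`, `is_reference`, and attributes
#'   `samples_per_series` and `rate`.
#' @examples
#' m <- generate_manifest(session_design())
#' manifest_totals(m)
#' @export
generate_manifest <- function(design = session_design()) {
  stopifnot(inherits(design, "session_design"))
  ex <- design$experiments
  rows <- purrr::pmap(ex, function(experiment, n_plants, n_sessions, ...) {
    plant <- if (n_plants > 0) {
      tidyr::expand_grid(
        experiment = experiment,
        plant_id = seq_len(n_plants),
        phase = c("before", "after")
      ) |> dplyr::mutate(is_reference = FALSE)
    }
    ref <- if (n_sessions > 0) {
      tidyr::expand_grid(
        experiment = experiment,
        plant_id = NA_integer_,
        phase = c("before", "after")
      ) |>
        dplyr::slice(rep(seq_len(2L), n_sessions)) |>
        dplyr::mutate(is_reference = TRUE)
    }
    dplyr::bind_rows(plant, ref)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      experiment = character(), plant_id = integer(),
      phase = character(), is_reference = logical()
    )
  }
  out <- dplyr::mutate(out, series_id = dplyr::row_number(), .before = 1L)
  attr(out, "samples_per_series") <- design$samples_per_series
  attr(out, "rate") <- design$rate
  class(out) <- c("electrome_manifest", class(out))
  out
}

#' Totals of a manifest
#'
#' @param manifest An [generate_manifest()] result.
#' @return One-row tibble with the number of electrome series, reference
#'   series, and the grand total of data points (all series times samples
#'   per series).
#' @export
manifest_totals <- function(manifest) {
  stopifnot(inherits(manifest, "electrome_manifest"))
  n_el <- sum(!manifest$is_reference)
  n_ref <- sum(manifest$is_reference)
  tibble(
    n_electrome_series = n_el,
    n_reference_series = n_ref,
    n_series = n_el + n_ref,
    samples_per_series = attr(manifest, "samples_per_series"),
    total_points = (n_el + n_ref) * as.numeric(attr(manifest, "samples_per_series"))
  )
}

#' Synthesize the series listed in a manifest
#'
#' Generates the electrophytograms for (a subset of) manifest rows. Each
#' series gets a seed derived from the master seed and its identity
#' (experiment, plant/reference, phase), so any single series can be
#' regenerated without generating the rest. Reference-electrode rows are
#' synthesized as low-amplitude instrument noise with the 2.5/5/7.5 Hz
#' pickup tones and no biological spikes.
#'
#' @param manifest An `electrome_manifest`.
#' @param rows Integer vector of row indices to realize (default: all).
#' @param profiles Named list of [treatment_profile()]s; defaults to
#'   [default_profiles()].
#' @param seed Master seed.
#' @param ... Passed to [synthesize_electrome()] (e.g. `highpass_hz`).
#' @return A list of [electrome_series()], one per requested row.
#' @examples
#' d <- session_design(
#'   tibble::tibble(experiment = "water", n_plants = 1L, n_sessions = 0L),
#'   samples_per_series = 1000L
#' )
#' series <- realize_series(generate_manifest(d), seed = 1)
#' @export
realize_series <- function(manifest, rows = seq_len(nrow(manifest)),
                           profiles = NULL, seed = 1L, ...) {
  stopifnot(inherits(manifest, "electrome_manifest"))
  profiles <- profiles %||% default_profiles()
  rate <- attr(manifest, "rate")
  duration_s <- attr(manifest, "samples_per_series") / rate
  purrr::map(rows, function(i) {
    row <- manifest[i, ]
    if (row$is_reference) {
      s <- derive_seed(seed, row$experiment, "reference", row$series_id)
      x <- generate_colored_noise(
        n = attr(manifest, "samples_per_series"), rate = rate,
        beta = 0.3, sigma = 0.005, seed = s
      )
      for (f0 in c(2.5, 5, 7.5)) {
        x <- x + 0.002 * sin(2 * pi * f0 * seq_along(x) / rate)
      }
      out <- electrome_series(x,
        rate = rate, experiment = row$experiment,
        phase = row$phase, is_reference = TRUE
      )
      return(out)
    }
    synthesize_electrome(
      treatment = row$experiment, phase = row$phase,
      plant_id = row$plant_id,
      seed = derive_seed(seed, row$experiment, row$plant_id, row$phase),
      duration_s = duration_s, rate = rate, profiles = profiles, ...
    )
  })
}
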