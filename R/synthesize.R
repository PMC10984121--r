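#' Synthesize one electrophytogram
#'
#' Builds a voltage-variation series for a given treatment and phase:
#' colored-noise baseline, a Poisson spike train (AP-/VP-like waveforms with
#' bounded power-law amplitudes), plus — for post-stimulus phases with a
#' configured profile — an onset burst of extra events and slow long-period
#' waves. Optional instrument tones (e.g. 2.5/5/7.5 Hz pickup) can be
#' injected, and the acquisition high-pass filter is applied last. The
#' result is fully deterministic given `seed`.
#'
#' Note that a faithful 0.5 Hz zero-phase high-pass strongly attenuates the
#' slow-wave component (period of minutes); pass `highpass_hz = NULL` to
#' inspect the unfiltered signal.
#'
#' @param treatment A [treatment_profile()] or the name of one of the
#'   [default_profiles()] (`"water"`, `"nutrient"`, `"peg"`, `"nacl"`).
#' @param phase `"before"` or `"after"` stimulation.
#' @param plant_id Integer identifier stored in the metadata.
#' @param seed Master seed for this series; component draws (baseline,
#'   spikes, burst, waves) use seeds derived from it.
#' @param duration_s Recording length in seconds (default 7200 s = 2 h).
#' @param rate Sampling frequency in Hz (default 62.5).
#' @param highpass_hz Acquisition high-pass cutoff in Hz; `NULL` disables
#'   filtering.
#' @param tones Numeric vector of interference frequencies (Hz) to inject,
#'   or `NULL`.
#' @param tone_amplitude Peak amplitude of each injected tone (mV).
#' @param profiles Profile list used to resolve `treatment` when it is a
#'   name.
#'
#' @return An [electrome_series()] with `round(rate * duration_s)` samples.
#'   Spike event times and amplitudes are attached as a tibble in
#'   `attr(x, "events")` (columns `time_s`, `amplitude`, `component`).
#' @examples
#' s <- synthesize_electrome("water", "before", seed = 1, duration_s = 60)
#' length(s$samples)
#' @export
synthesize_electrome <- function(treatment, phase = c("before", "after"),
                                 plant_id = 1L, seed = 1L,
                                 duration_s = 7200, rate = 62.5,
                                 highpass_hz = 0.5,
                                 tones = NULL, tone_amplitude = 0.002,
                                 profiles = NULL) {
  if (length(phase) == 1L && !phase %in% c("before", "after")) {
    abort(sprintf("unknown phase '%s'.", phase), class = "electromer_config_error")
  }
  phase <- match.arg(phase)
  prof <- resolve_profile(treatment, profiles)
  n <- round(duration_s * rate)

  x <- generate_colored_noise(
    n = n, rate = rate, beta = prof$baseline_beta,
    sigma = prof$baseline_sigma, seed = derive_seed(seed, "baseline")
  )

  spikes <- if (phase == "before") prof$pre_spikes else prof$post_spikes
  train <- generate_spike_train(duration_s, spikes,
    rate = rate,
    seed = derive_seed(seed, "spikes", phase)
  )
  events <- spike_events(train, rate, "spikes")
  x <- x + train

  if (phase == "after" && !is.null(prof$burst)) {
    extra <- generate_spike_train(duration_s, spikes,
      rate = rate,
      seed = derive_seed(seed, "burst"),
      window_s = c(prof$burst$start_s, prof$burst$end_s),
      rate_per_hour = spikes$events_per_hour * (prof$burst$rate_multiplier - 1)
    )
    events <- dplyr::bind_rows(events, spike_events(extra, rate, "burst"))
    x <- x + extra
  }

  if (phase == "after" && !is.null(prof$slow_waves)) {
    x <- x + slow_wave_component(
      n, rate, prof$slow_waves,
      seed = derive_seed(seed, "waves")
    )
  }

  for (f0 in tones) {
    x <- x + tone_amplitude * sin(2 * pi * f0 * seq_len(n) / rate)
  }

  out <- electrome_series(x,
    rate = rate, experiment = prof$name, plant_id = plant_id, phase = phase
  )
  if (!is.null(highpass_hz)) {
    out <- apply_acquisition_filter(out, highpass_hz = highpass_hz)
  }
  attr(out, "events") <- dplyr::arrange(events, .data$time_s)
  out
}

spike_events <- function(train, rate, component) {
  ev <- attr(train, "events")
  if (is.null(ev)) {
    return(tibble(
      time_s = numeric(), amplitude = numeric(),
      component = character()
    ))
  }
  dplyr::mutate(ev, component = component)
}

# `count` single-period sine waves, Hann-tapered so they start and end at
# zero, at uniform random onsets.
slow_wave_component <- function(n, rate, sw, seed) {
  out <- numeric(n)
  len <- max(2L, round(sw$period_s * rate))
  if (len >= n) len <- n - 1L
  t <- seq_len(len) / len
  wave <- sw$amplitude_mv * sin(2 * pi * t) * (0.5 - 0.5 * cos(2 * pi * t))
  set.seed(as.integer(seed))
  starts <- floor(runif(sw$count, 0, n - len)) + 1L
  for (s in starts) {
    idx <- s:(s + len - 1L)
    out[idx] <- out[idx] + wave
  }
  out
}
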