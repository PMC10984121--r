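#' Describe a population of electrical spikes
#'
#' A spike profile parameterizes the transient events superimposed on the
#' baseline electrome: how often they occur, how their absolute amplitudes
#' are distributed (bounded power law, matching the "larger the peak, the
#' less frequent" phenomenology of scale-free electromes), their waveform
#' class and polarity mix.
#'
#' Two waveform classes are provided. `"ap_like"` is a fast biphasic pulse
#' (depolarization lobe followed by a damped undershoot) lasting a few
#' seconds, reminiscent of action potentials. `"vp_like"` is a slow
#' monophasic gamma-shaped wave lasting tens of seconds, reminiscent of
#' variation potentials.
#'
#' @param events_per_hour Mean Poisson event rate (>= 0).
#' @param amplitude_exponent Power-law exponent \eqn{\mu} of the absolute
#'   amplitude distribution (must be > 1).
#' @param amplitude_min,amplitude_max Amplitude bounds in mV
#'   (0 < min < max).
#' @param waveform `"ap_like"` or `"vp_like"`.
#' @param waveform_duration_s Event duration in seconds; defaults to 4 s for
#'   AP-like and 60 s for VP-like events.
#' @param sign_probability Probability that a spike is positive-going.
#'
#' @return A list of class `spike_profile`.
#' @examples
#' spike_profile(events_per_hour = 30, amplitude_max = 0.5)
#' @export
spike_profile <- function(events_per_hour = 30,
                          amplitude_exponent = 2.5,
                          amplitude_min = 0.05,
                          amplitude_max = 10,
                          waveform = c("ap_like", "vp_like"),
                          waveform_duration_s = NULL,
                          sign_probability = 0.5) {
  waveform <- match.arg(waveform)
  if (events_per_hour < 0) {
    abort("`events_per_hour` must be >= 0.", class = "electromer_invalid_parameter")
  }
  if (amplitude_exponent <= 1) {
    abort("`amplitude_exponent` must be > 1.", class = "electromer_invalid_parameter")
  }
  if (!(amplitude_min > 0 && amplitude_min < amplitude_max)) {
    abort("need 0 < amplitude_min < amplitude_max.", class = "electromer_invalid_parameter")
  }
  if (sign_probability < 0 || sign_probability > 1) {
    abort("`sign_probability` must be in [0, 1].", class = "electromer_invalid_parameter")
  }
  waveform_duration_s <- waveform_duration_s %||%
    switch(waveform, ap_like = 4, vp_like = 60)
  structure(
    list(
      events_per_hour = events_per_hour,
      amplitude_exponent = amplitude_exponent,
      amplitude_min = amplitude_min,
      amplitude_max = amplitude_max,
      waveform = waveform,
      waveform_duration_s = waveform_duration_s,
      sign_probability = sign_probability
    ),
    class = "spike_profile"
  )
}

# Unit-peak waveform template sampled at `rate`.
spike_waveform <- function(waveform, duration_s, rate) {
  n <- max(2L, round(duration_s * rate))
  t <- seq_len(n) / n # (0, 1]
  w <- switch(waveform,
    ap_like = sin(2 * pi * t) * exp(-3 * t),
    vp_like = {
      tp <- 0.25 # peak at a quarter of the duration
      (t / tp) * exp(1 - t / tp)
    },
    abort(sprintf("unknown waveform '%s'.", waveform),
      class = "electromer_config_error"
    )
  )
  w / max(abs(w))
}

# Inverse-CDF sampler for a Pareto law p(x) ~ x^(-mu) truncated to [a, b].
rtrunc_pareto <- function(n, mu, a, b) {
  u <- runif(n)
  e <- 1 - mu
  (a^e + u * (b^e - a^e))^(1 / e)
}

#' Generate a spike train
#'
#' Places spike waveforms at homogeneous-Poisson event times; absolute
#' amplitudes are drawn from the profile's bounded power law and signs from
#' its polarity probability.
#'
#' @param duration_s Series duration in seconds (> 0).
#' @param profile A [spike_profile()].
#' @param rate Sampling frequency in Hz.
#' @param seed Integer seed.
#' @param window_s Optional `c(start, end)` in seconds: events are placed
#'   only inside this window (used for stimulus-onset bursts).
#' @param rate_per_hour Event rate override; defaults to
#'   `profile$events_per_hour`.
#'
#' @return Numeric vector of length `round(duration_s * rate)`; all zeros
#'   when the event rate is zero.
#' @examples
#' p <- spike_profile(events_per_hour = 60, amplitude_max = 0.5)
#' x <- generate_spike_train(600, p, rate = 62.5, seed = 1)
#' @export
generate_spike_train <- function(duration_s, profile, rate = 62.5, seed = 1L,
                                 window_s = NULL, rate_per_hour = NULL) {
  if (duration_s <= 0) {
    abort("`duration_s` must be > 0.", class = "electromer_invalid_parameter")
  }
  if (!inherits(profile, "spike_profile")) {
    abort("`profile` must be a spike_profile.", class = "electromer_invalid_parameter")
  }
  n <- round(duration_s * rate)
  template <- spike_waveform(profile$waveform, profile$waveform_duration_s, rate)
  if (length(template) > n) {
    abort("spike waveform is longer than the series.",
      class = "electromer_invalid_parameter"
    )
  }
  out <- numeric(n)
  no_events <- tibble(time_s = numeric(), amplitude = numeric())
  attr(out, "events") <- no_events
  window_s <- window_s %||% c(0, duration_s)
  window_s[2] <- min(window_s[2], duration_s)
  span <- diff(window_s)
  if (span <= 0) return(out)
  lambda <- (rate_per_hour %||% profile$events_per_hour) * span / 3600
  if (lambda <= 0) return(out)
  set.seed(as.integer(seed))
  k <- rpois(1L, lambda)
  if (k == 0L) return(out)
  onsets <- floor(runif(k, window_s[1], window_s[2]) * rate) + 1L
  amps <- rtrunc_pareto(k, profile$amplitude_exponent,
    profile$amplitude_min, profile$amplitude_max
  )
  signs <- ifelse(runif(k) < profile$sign_probability, 1, -1)
  len <- length(template)
  for (i in seq_len(k)) {
    idx <- onsets[i]:min(onsets[i] + len - 1L, n)
    out[idx] <- out[idx] + signs[i] * amps[i] * template[seq_along(idx)]
  }
  attr(out, "events") <- tibble(
    time_s = (onsets - 1L) / rate,
    amplitude = signs * amps
  )
  out
}
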