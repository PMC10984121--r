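#' Define a treatment profile
#'
#' A treatment profile collects everything needed to synthesize the
#' electrome of one experimental treatment: the colored-noise baseline
#' (spectral exponent and amplitude), spike populations before and after
#' stimulation, an optional stimulus-onset burst (a window with an elevated
#' event rate, as seen in the first 20-30 min after salt shock) and optional
#' slow long-period waves.
#'
#' @param name Treatment name.
#' @param baseline_beta Spectral exponent of the baseline noise.
#' @param baseline_sigma Baseline standard deviation in mV.
#' @param pre_spikes,post_spikes [spike_profile()]s for the before/after
#'   phases.
#' @param burst Optional list `list(start_s=, end_s=, rate_multiplier=)`;
#'   inside the window the post-stimulus event rate is multiplied by
#'   `rate_multiplier` (>= 1).
#' @param slow_waves Optional list `list(period_s=, amplitude_mv=, count=)`:
#'   `count` tapered single-period sine waves placed at random onsets.
#'
#' @return A list of class `treatment_profile`.
#' @examples
#' treatment_profile("demo", pre_spikes = spike_profile(6, amplitude_max = 0.3))
#' @export
treatment_profile <- function(name,
                              baseline_beta = 1.7,
                              baseline_sigma = 0.02,
                              pre_spikes = spike_profile(),
                              post_spikes = spike_profile(),
                              burst = NULL,
                              slow_waves = NULL) {
  if (baseline_beta < 0 || baseline_sigma <= 0) {
    abort("baseline_beta must be >= 0 and baseline_sigma > 0.",
      class = "electromer_invalid_parameter"
    )
  }
  if (!is.null(burst)) {
    stopifnot(all(c("start_s", "end_s", "rate_multiplier") %in% names(burst)))
    if (burst$start_s < 0 || burst$end_s <= burst$start_s) {
      abort("burst window must satisfy 0 <= start_s < end_s.",
        class = "electromer_invalid_parameter"
      )
    }
    if (burst$rate_multiplier < 1) {
      abort("burst rate_multiplier must be >= 1.",
        class = "electromer_invalid_parameter"
      )
    }
  }
  if (!is.null(slow_waves)) {
    stopifnot(all(c("period_s", "amplitude_mv", "count") %in% names(slow_waves)))
  }
  structure(
    list(
      name = name, baseline_beta = baseline_beta,
      baseline_sigma = baseline_sigma,
      pre_spikes = pre_spikes, post_spikes = post_spikes,
      burst = burst, slow_waves = slow_waves
    ),
    class = "treatment_profile"
  )
}

profile_from_list <- function(name, x) {
  mk_spikes <- function(s) {
    do.call(spike_profile, s[names(s) %in% names(formals(spike_profile))])
  }
  treatment_profile(
    name = name,
    baseline_beta = x$baseline_beta %||% 1.7,
    baseline_sigma = x$baseline_sigma %||% 0.02,
    pre_spikes = mk_spikes(x$pre_spikes %||% list()),
    post_spikes = mk_spikes(x$post_spikes %||% list()),
    burst = x$burst,
    slow_waves = if (!is.null(x$slow_waves)) {
      list(
        period_s = x$slow_waves$period_s,
        amplitude_mv = x$slow_waves$amplitude_mv,
        count = x$slow_waves$count
      )
    }
  )
}

#' Read treatment profiles from a YAML config
#'
#' The config is a mapping from treatment name to profile fields
#' (`baseline_beta`, `baseline_sigma`, `pre_spikes`, `post_spikes`,
#' optional `burst` and `slow_waves`); see the file shipped at
#' `system.file("extdata", "profiles.yaml", package = "electromer")`.
#'
#' @param path Path to a YAML file.
#' @return Named list of [treatment_profile()]s.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("profile config '%s' not found.", path), class = "electromer_io_error")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) profile_from_list(nm, raw[[nm]]))
  setNames(out, names(raw))
}

#' Default treatment profiles for the four water-availability stimuli
#'
#' Profiles for distilled water, half-strength nutrient solution, -2 MPa
#' PEG-6000 and -2 MPa NaCl. Pre-stimulus electromes oscillate within about
#' +/-0.05 mV with rare spikes below +/-0.5 mV; the osmotic treatments gain
#' frequent high-amplitude spikes (up to the 5-10 mV range), and NaCl
#' additionally gets an onset burst in the first 30 minutes plus slow
#' long-period waves. Event rates are order-of-magnitude choices documented
#' in the methods vignette; they are read from the packaged
#' `profiles.yaml`, so the config file is the single source of truth.
#'
#' @return Named list of [treatment_profile()]s
#'   (`water`, `nutrient`, `peg`, `nacl`).
#' @examples
#' names(default_profiles())
#' @export
default_profiles <- function() {
  read_profiles(system.file("extdata", "profiles.yaml", package = "electromer"))
}

resolve_profile <- function(treatment, profiles = NULL) {
  if (inherits(treatment, "treatment_profile")) return(treatment)
  profiles <- profiles %||% default_profiles()
  if (!is.character(treatment) || !treatment %in% names(profiles)) {
    abort(sprintf("unknown treatment '%s'.", as.character(treatment)[1]),
      class = "electromer_config_error"
    )
  }
  profiles[[treatment]]
}
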