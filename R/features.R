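#' Mean voltage variation
#'
#' Arithmetic average of the absolute voltage variations \eqn{|\Delta V_i|}.
#' High-pass-filtered recordings are near zero-mean, so the signed mean is
#' uninformative (approximately 0 for every series); the absolute mean is
#' therefore the default, with `signed = TRUE` available.
#'
#' @param series An [electrome_series()] or numeric vector.
#' @param signed If `TRUE`, return the signed arithmetic mean instead.
#' @return Mean voltage variation in mV.
#' @examples
#' mean_voltage_variation(c(0.001, -0.001, 0.002, -0.002)) # 0.0015
#' @export
mean_voltage_variation <- function(series, signed = FALSE) {
  x <- series_samples(series)
  if (length(x) == 0L) {
    abort("empty series.", class = "electromer_empty_input")
  }
  if (signed) mean(x) else mean(abs(x))
}

#' Skewness and excess kurtosis
#'
#' Classical moment estimators (e1071 type 1): standardized third moment and
#' excess kurtosis (0 for a normal distribution).
#'
#' @param series An [electrome_series()] or numeric vector of length >= 4
#'   with nonzero variance.
#' @return One-row tibble with columns `skew` and `kurt`.
#' @examples
#' signal_moments(rnorm(1000))
#' @export
signal_moments <- function(series) {
  x <- series_samples(series)
  if (length(x) < 4L) {
    abort("need at least 4 samples.", class = "electromer_invalid_parameter")
  }
  if (sd(x) == 0) {
    abort("zero-variance series: moments are undefined.",
      class = "electromer_degenerate_input"
    )
  }
  tibble(
    skew = e1071::skewness(x, type = 1),
    kurt = e1071::kurtosis(x, type = 1)
  )
}

#' One-sided amplitude spectrum
#'
#' Discrete Fourier amplitude spectrum up to the Nyquist frequency: a pure
#' sinusoid of amplitude A appears as a single bin of magnitude A. The
#' spectrum is linear in the input and satisfies the discrete Parseval
#' relation.
#'
#' @param series An [electrome_series()] or numeric vector.
#' @param rate Sampling rate in Hz (taken from the series when omitted).
#' @return Tibble with columns `frequency` (Hz) and `magnitude` (mV).
#' @examples
#' t <- seq(0, 8, by = 1 / 62.5)
#' sp <- fft_spectrum(sin(2 * pi * 5 * t), rate = 62.5)
#' sp$frequency[which.max(sp$magnitude)] # ~ 5 Hz
#' @export
fft_spectrum <- function(series, rate = NULL) {
  rate <- series_rate(series, rate)
  x <- series_samples(series)
  n <- length(x)
  if (n == 0L) {
    abort("empty series.", class = "electromer_empty_input")
  }
  X <- fft(x)
  half <- seq_len(n %/% 2 + 1L)
  mag <- Mod(X[half]) / n
  # double interior bins so magnitudes read as sinusoid amplitudes
  interior <- half > 1L & !(n %% 2L == 0L & half == n %/% 2 + 1L)
  mag[interior] <- 2 * mag[interior]
  tibble(
    frequency = (half - 1L) * rate / n,
    magnitude = mag
  )
}

#' Autocorrelation decay time
#'
#' The smallest lag at which the sample autocorrelation function first
#' falls below 1/e, reported in seconds. An AR(1) process with coefficient
#' \eqn{\phi} decorrelates at about \eqn{-1/\ln\phi} samples. If the ACF
#' never crosses the threshold within `max_lag`, the result is flagged as
#' right-censored at that lag.
#'
#' @param series An [electrome_series()] or numeric vector (length >= 100,
#'   nonzero variance).
#' @param rate Sampling rate in Hz.
#' @param threshold Decorrelation threshold (default `exp(-1)`).
#' @param max_lag Maximum lag in samples searched; defaults to
#'   `min(n - 1, round(60 * rate))` (one minute).
#' @return One-row tibble: `lag_samples`, `lag_s`, `censored`.
#' @examples
#' autocorrelation_summary(rnorm(1000), rate = 62.5)$lag_samples # 1
#' @export
autocorrelation_summary <- function(series, rate = NULL,
                                    threshold = exp(-1), max_lag = NULL) {
  rate <- series_rate(series, rate)
  x <- series_samples(series)
  if (length(x) < 100L) {
    abort("need at least 100 samples.", class = "electromer_invalid_parameter")
  }
  if (sd(x) == 0) {
    abort("zero-variance series: autocorrelation is undefined.",
      class = "electromer_degenerate_input"
    )
  }
  max_lag <- max_lag %||% min(length(x) - 1L, round(60 * rate))
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
  hit <- which(rho < threshold)
  if (length(hit) == 0L) {
    return(tibble(
      lag_samples = as.integer(max_lag),
      lag_s = max_lag / rate, censored = TRUE
    ))
  }
  tibble(
    lag_samples = as.integer(hit[1]),
    lag_s = hit[1] / rate, censored = FALSE
  )
}
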