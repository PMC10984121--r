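#' Averaged-periodogram power spectral density
#'
#' Welch's method: the series is split into `nseg` segments with the given
#' overlap, each segment is mean-detrended, Hann-windowed and
#' periodogram-transformed, and the periodograms are averaged. Power is
#' normalized as a density (mV^2/Hz).
#'
#' @param series An [electrome_series()] or numeric vector.
#' @param rate Sampling rate in Hz.
#' @param nseg Number of segments (default 8).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Tibble with columns `frequency` (Hz, zero excluded) and `power`.
#' @examples
#' welch_psd(rnorm(8192), rate = 62.5)
#' @export
welch_psd <- function(series, rate = NULL, nseg = 8, overlap = 0.5) {
  rate <- series_rate(series, rate)
  x <- series_samples(series)
  n <- length(x)
  L <- floor(n / (1 + (nseg - 1) * (1 - overlap)))
  if (L < 8L) {
    abort("series too short for the requested segmentation.",
      class = "electromer_invalid_parameter"
    )
  }
  step <- max(1L, floor(L * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  U <- sum(w^2)
  half <- seq_len(L %/% 2 + 1L)
  starts <- seq(1L, n - L + 1L, by = step)
  P <- rowMeans(vapply(starts, function(s) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    (Mod(fft(seg))^2 / (rate * U))[half]
  }, numeric(length(half))))
  tibble(
    frequency = (half - 1L) * rate / L,
    power = P
  )[-1L, ]
}

#' Fit the PSD spectral exponent
#'
#' Estimates the exponent \eqn{\beta} of the \eqn{1/f^\beta} power-spectrum
#' model as minus the slope of an ordinary least-squares fit of log power
#' against log frequency over the averaged periodogram, restricted to
#' `fit_band_hz`. The default band (0.05-10 Hz) avoids the high-pass
#' shoulder at the low end and instrument tones at the high end.
#' \eqn{\beta = 0} is white, 1 pink and 2 brown noise.
#'
#' @param series An [electrome_series()] or numeric vector of length >=
#'   4096.
#' @param rate Sampling rate in Hz.
#' @param fit_band_hz Two-element numeric, fit band in Hz.
#' @param nseg,overlap Passed to [welch_psd()].
#' @return One-row tibble: `beta`, `r_squared`, `n_freq`, `failed`. When
#'   fewer than 10 frequency points fall in the band the fit is flagged as
#'   failed (no error is raised).
#' @examples
#' x <- generate_colored_noise(16384, beta = 1, sigma = 1, seed = 1)
#' fit_psd_exponent(x, rate = 62.5)$beta # ~ 1
#' @export
fit_psd_exponent <- function(series, rate = NULL, fit_band_hz = c(0.05, 10),
                             nseg = 8, overlap = 0.5) {
  x <- series_samples(series)
  if (length(x) < 4096L) {
    abort("need at least 4096 samples to estimate the spectral exponent.",
      class = "electromer_invalid_parameter"
    )
  }
  ps <- welch_psd(series, rate = rate, nseg = nseg, overlap = overlap)
  keep <- ps$frequency >= fit_band_hz[1] & ps$frequency <= fit_band_hz[2] &
    ps$power > 0
  if (sum(keep) < 10L) {
    return(tibble(
      beta = NA_real_, r_squared = NA_real_,
      n_freq = sum(keep), failed = TRUE
    ))
  }
  fit <- lm(log(power) ~ log(frequency), data = ps[keep, ])
  tibble(
    beta = -unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_freq = sum(keep),
    failed = FALSE
  )
}
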