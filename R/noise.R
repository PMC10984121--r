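#' Generate colored noise by spectral synthesis
#'
#' Draws a Gaussian-phase random series whose power spectrum follows
#' \eqn{1/f^\beta}: Fourier amplitudes are shaped proportional to
#' \eqn{f^{-\beta/2}} with independent uniform phases and inverted back to
#' the time domain. \eqn{\beta = 0} gives white noise, \eqn{\beta = 1} pink
#' and \eqn{\beta = 2} brown noise. The output is zero-mean and rescaled to
#' the requested standard deviation exactly.
#'
#' @param n Number of samples (>= 2).
#' @param rate Sampling frequency in Hz (metadata only; the spectral shape is
#'   scale-free).
#' @param beta Spectral exponent (>= 0).
#' @param sigma Target sample standard deviation in mV (> 0).
#' @param seed Integer seed; the draw is fully deterministic given `seed`.
#'
#' @return Numeric vector of length `n` with `mean(x) == 0` and
#'   `sd(x) == sigma` (up to float rounding).
#' @examples
#' x <- generate_colored_noise(4096, beta = 1, sigma = 0.02, seed = 1)
#' sd(x)
#' @export
generate_colored_noise <- function(n, rate = 62.5, beta = 1, sigma = 0.02, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    abort("`n` must be a single integer >= 2.", class = "electromer_invalid_parameter")
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    abort("`sigma` must be > 0.", class = "electromer_invalid_parameter")
  }
  if (!is.numeric(beta) || beta < 0) {
    abort("`beta` must be >= 0.", class = "electromer_invalid_parameter")
  }
  n <- as.integer(n)
  set.seed(as.integer(seed))
  nf <- n %/% 2L
  f <- seq_len(nf) / n
  amp <- f^(-beta / 2)
  ph <- runif(nf, 0, 2 * pi)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- complex(modulus = amp, argument = ph)
  if (n %% 2L == 0L) {
    # Nyquist bin must be real for a real-valued inverse transform
    full[nf + 1L] <- complex(real = amp[nf] * cos(ph[nf]))
    if (nf > 1L) full[(nf + 2L):n] <- Conj(full[nf:2L])
  } else {
    full[(nf + 2L):n] <- Conj(full[(nf + 1L):2L])
  }
  x <- Re(fft(full, inverse = TRUE))
  x <- x - mean(x)
  x * (sigma / sd(x))
}
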