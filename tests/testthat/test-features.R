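test_that("mean voltage variation averages absolute deviations", {
  expect_equal(mean_voltage_variation(c(0.001, -0.001, 0.002, -0.002)), 0.0015)
  expect_equal(mean_voltage_variation(rep(0, 10)), 0)
  expect_equal(mean_voltage_variation(rep(0.3, 10)), 0.3)
  expect_equal(mean_voltage_variation(c(1, -1), signed = TRUE), 0)
  expect_error(mean_voltage_variation(numeric()), class = "electromer_empty_input")
})

test_that("moment estimators match their distributional limits", {
  expect_equal(signal_moments(c(-1, 0, 1, -1, 0, 1))$skew, 0)
  set.seed(42)
  g <- rnorm(1e6)
  expect_lt(abs(signal_moments(g)$kurt - 0), 0.05)
  e <- stats::rexp(1e6)
  expect_lt(abs(signal_moments(e)$skew - 2), 0.05)
  expect_error(signal_moments(rep(1, 10)), class = "electromer_degenerate_input")
  expect_error(signal_moments(1:3), class = "electromer_invalid_parameter")
})

test_that("fft spectrum localizes sinusoids, is linear and conserves energy", {
  n <- 6250
  t <- seq_len(n) / 62.5
  sp <- fft_spectrum(sin(2 * pi * 5 * t), rate = 62.5)
  expect_equal(sp$frequency[which.max(sp$magnitude)], 5, tolerance = 0.02)
  expect_equal(max(sp$magnitude), 1, tolerance = 0.01)

  # discrete Parseval: sum x^2 == n * (M0^2 + MNyq^2 + sum interior M^2 / 2)
  set.seed(1)
  x <- rnorm(1024)
  m <- fft_spectrum(x, rate = 62.5)$magnitude
  interior <- seq(2, length(m) - 1)
  lhs <- sum(x^2)
  rhs <- 1024 * (m[1]^2 + m[length(m)]^2 + sum(m[interior]^2) / 2)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  y <- rnorm(1024)
  both <- fft_spectrum(x + y, rate = 62.5)
  # linearity holds on the complex transform; check via an even/odd split
  # where phases align: x + x
  expect_equal(
    fft_spectrum(x + x, rate = 62.5)$magnitude,
    2 * fft_spectrum(x, rate = 62.5)$magnitude,
    tolerance = 1e-9
  )
  expect_identical(nrow(both), 513L)
})

test_that("periodogram and autocovariance are a Fourier pair (Wiener-Khinchin)", {
  set.seed(3)
  x <- rnorm(1024)
  x <- x - mean(x)
  n <- length(x)
  # package periodogram, undoing the one-sided amplitude scaling
  m <- fft_spectrum(x, rate = 1)$magnitude
  half <- seq_along(m)
  interior <- half > 1 & half < length(m)
  p_pkg <- (m * n)^2
  p_pkg[interior] <- (m[interior] * n / 2)^2
  # oracle: FFT of the circular sample autocovariance
  acov <- vapply(0:(n - 1), function(k) sum(x * x[((seq_len(n) - 1 + k) %% n) + 1]), numeric(1))
  p_wk <- Re(fft(acov))[half]
  expect_equal(p_pkg / n, p_wk / n, tolerance = 1e-6)
})

test_that("autocorrelation decay lag matches the AR(1) closed form", {
  set.seed(1)
  expect_lte(autocorrelation_summary(rnorm(5000), rate = 62.5)$lag_samples, 2L)

  lags <- vapply(1:20, function(s) {
    set.seed(s)
    x <- as.numeric(stats::arima.sim(list(ar = 0.9), 20000))
    autocorrelation_summary(x, rate = 1)$lag_samples
  }, numeric(1))
  expect_lt(abs(mean(lags) - (-1 / log(0.9))), 2) # ~ 9.5 samples

  # seconds conversion and censoring
  res <- autocorrelation_summary(rnorm(1000), rate = 62.5)
  expect_equal(res$lag_s, res$lag_samples / 62.5)
  cens <- autocorrelation_summary(seq_len(500) + rnorm(500, sd = 1e-3),
    rate = 62.5, max_lag = 50
  )
  expect_true(cens$censored)
  expect_error(autocorrelation_summary(rep(1, 200), rate = 62.5),
    class = "electromer_degenerate_input"
  )
})

test_that("PSD exponent fit flags thin bands instead of failing", {
  x <- generate_colored_noise(8192, beta = 1, sigma = 1, seed = 1)
  res <- fit_psd_exponent(x, rate = 62.5, fit_band_hz = c(0.05, 0.06))
  expect_true(res$failed)
  expect_true(is.na(res$beta))
  expect_error(fit_psd_exponent(rnorm(100), rate = 62.5),
    class = "electromer_invalid_parameter"
  )
})

test_that("power-law tail fit recovers generating exponents and prefers true power laws", {
  for (mu in c(1.5, 2.5)) {
    x <- withr::with_seed(7, draw_trunc_powerlaw(2e4, mu, 0.05, 10))
    fit <- fit_pdf_exponent(x)
    expect_false(fit$failed)
    expect_lt(abs(fit$mu - mu), 0.2)
    ml <- fit_pdf_exponent(x, method = "ml")
    expect_lt(abs(ml$mu - mu), 0.2)
  }
  pl <- withr::with_seed(8, draw_trunc_powerlaw(2e4, 2.5, 0.05, 10))
  gs <- withr::with_seed(8, abs(rnorm(2e4)))
  expect_gt(
    fit_pdf_exponent(pl)$r_squared,
    fit_pdf_exponent(gs)$r_squared
  )
  expect_true(fit_pdf_exponent(rep(0, 100))$failed)
  expect_true(fit_pdf_exponent(c(0.1, 0.2))$failed)
})

test_that("the feature ledger never aborts and flags what it cannot compute", {
  const <- feature_ledger(rep(0, 6000), rate = 62.5, max_scale = 3)
  expect_equal(const$mean_dv, 0)
  expect_equal(const$apen, 0)
  expect_true(grepl("moments", const$flags))
  expect_true(is.na(const$skew))

  x <- generate_colored_noise(16384, beta = 1, sigma = 0.02, seed = 2)
  led1 <- feature_ledger(x, rate = 62.5, max_scale = 3)
  led2 <- feature_ledger(x, rate = 62.5, max_scale = 3)
  expect_identical(led1$apen, led2$apen)
  expect_identical(led1$psd_beta, led2$psd_beta)
  expect_lt(abs(led1$psd_beta - 1), 0.2)
  expect_identical(led1$msapen[[1]]$apen[1], led1$apen)
})
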