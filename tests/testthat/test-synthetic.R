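test_that("colored noise hits the requested sd, mean and length exactly", {
  x <- generate_colored_noise(4096, beta = 1, sigma = 0.02, seed = 3)
  expect_length(x, 4096)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 0.02, tolerance = 1e-9)
  expect_identical(x, generate_colored_noise(4096, beta = 1, sigma = 0.02, seed = 3))
  expect_false(identical(x, generate_colored_noise(4096, beta = 1, sigma = 0.02, seed = 4)))
  expect_error(generate_colored_noise(1, sigma = 1), class = "electromer_invalid_parameter")
  expect_error(generate_colored_noise(100, sigma = 0), class = "electromer_invalid_parameter")
  expect_error(generate_colored_noise(100, beta = -1), class = "electromer_invalid_parameter")
})

test_that("spectral synthesis recovers the generating exponent for white, pink and brown noise", {
  for (beta in c(0, 1, 2)) {
    est <- vapply(1:10, function(s) {
      x <- generate_colored_noise(16384, beta = beta, sigma = 1, seed = s)
      fit_psd_exponent(x, rate = 62.5)$beta
    }, numeric(1))
    expect_lt(abs(mean(est) - beta), 0.15)
  }
})

test_that("spike trains follow the configured Poisson rate and power-law amplitudes", {
  prof <- spike_profile(events_per_hour = 0)
  expect_identical(
    as.numeric(generate_spike_train(600, prof, rate = 10, seed = 1)),
    numeric(6000)
  )

  # Poisson count oracle: rate 60/h over 2 h -> mean 120 events
  prof <- spike_profile(events_per_hour = 60, amplitude_max = 0.5)
  counts <- vapply(1:50, function(s) {
    nrow(attr(generate_spike_train(7200, prof, rate = 5, seed = s), "events"))
  }, numeric(1))
  se <- sqrt(120 / 50)
  expect_lt(abs(mean(counts) - 120), 3 * se)

  # amplitude power-law recovery on ~10,000 pooled events
  prof <- spike_profile(
    events_per_hour = 5000, amplitude_exponent = 2.5,
    amplitude_min = 0.05, amplitude_max = 10
  )
  ev <- attr(generate_spike_train(7200, prof, rate = 5, seed = 7), "events")
  expect_gt(nrow(ev), 5000)
  fit <- fit_pdf_exponent(abs(ev$amplitude), fit_range = c(0.1, 10))
  expect_lt(abs(fit$mu - 2.5), 0.2)

  expect_error(
    generate_spike_train(2, spike_profile(waveform = "vp_like"), rate = 62.5),
    class = "electromer_invalid_parameter"
  )
})

test_that("pre-stimulus electromes stay within the quiet-baseline voltage band", {
  s <- synthesize_electrome("water", "before", seed = 5, duration_s = 1200)
  expect_identical(length(s$samples), 75000L)
  expect_gt(mean(abs(s$samples) <= 0.05), 0.95)
  # determinism
  s2 <- synthesize_electrome("water", "before", seed = 5, duration_s = 1200)
  expect_identical(s$samples, s2$samples)
  expect_error(
    synthesize_electrome("water", "during", seed = 1, duration_s = 60),
    class = "electromer_config_error"
  )
  expect_error(
    synthesize_electrome("vinegar", "before", seed = 1, duration_s = 60),
    class = "electromer_config_error"
  )
})

test_that("the salt-shock burst elevates early spike density by the configured multiplier", {
  early <- 0
  late <- 0
  for (s in 1:10) {
    ev <- attr(
      synthesize_electrome("nacl", "after", seed = s, duration_s = 7200, rate = 5),
      "events"
    )
    early <- early + sum(ev$time_s < 1800)
    late <- late + sum(ev$time_s >= 3600)
  }
  mult <- default_profiles()$nacl$burst$rate_multiplier
  dens_ratio <- (early / 0.5) / (late / 1) # per-hour densities
  se <- mult * sqrt(1 / early + 1 / late)
  expect_lt(abs(dens_ratio - mult), 3 * se)
})

test_that("the study-design manifest reproduces the series and point totals", {
  m <- generate_manifest(session_design())
  tot <- manifest_totals(m)
  expect_identical(tot$n_electrome_series, 288L)
  expect_identical(tot$n_reference_series, 96L)
  expect_identical(tot$total_points, 172800000)
  # per-experiment electrome counts
  by_ex <- table(m$experiment[!m$is_reference])
  expect_identical(
    as.integer(by_ex[c("water", "nutrient", "peg", "nacl")]),
    c(60L, 42L, 108L, 78L)
  )

  empty <- generate_manifest(session_design(
    tibble::tibble(
      experiment = character(), n_plants = integer(),
      n_sessions = integer()
    )
  ))
  expect_identical(nrow(empty), 0L)
  expect_identical(manifest_totals(empty)$total_points, 0)
})

test_that("realized series honour the manifest metadata and seed lineage", {
  d <- session_design(
    tibble::tibble(experiment = "nacl", n_plants = 2L, n_sessions = 1L),
    samples_per_series = 1000L
  )
  m <- generate_manifest(d)
  sl <- realize_series(m, seed = 9)
  expect_length(sl, nrow(m))
  expect_true(all(vapply(sl, function(s) length(s$samples) == 1000L, logical(1))))
  i_ref <- which(m$is_reference)[1]
  expect_true(sl[[i_ref]]$meta$is_reference)
  # a single row can be regenerated identically in isolation
  one <- realize_series(m, rows = 2L, seed = 9)[[1]]
  expect_identical(one$samples, sl[[2]]$samples)
})
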