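test_that("series files round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  s <- electrome_series(c(0.001, -0.0021234567, 5),
    rate = 62.5,
    experiment = "water", plant_id = 3L, phase = "before"
  )
  write_series(s, f)
  r <- read_series(f)
  expect_identical(r$samples, s$samples)
  expect_identical(r$rate, s$rate)
  expect_identical(r$meta, s$meta)

  # longer series: length and values preserved
  big <- electrome_series(rnorm(20000, sd = 0.02), rate = 62.5)
  write_series(big, f)
  r2 <- read_series(f)
  expect_identical(length(r2$samples), 20000L)
  expect_equal(r2$samples, big$samples, tolerance = 1e-9)
})

test_that("malformed series files are rejected with diagnostics", {
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("# units: mV", "0.1", "0.2"), f)
  expect_error(read_series(f),
    regexp = "rate_hz",
    class = "electromer_format_error"
  )

  writeLines(c("# rate_hz: 62.5", "0.1", "oops", "0.2"), f)
  expect_error(read_series(f),
    regexp = "line 3",
    class = "electromer_format_error"
  )

  writeLines(character(), f)
  expect_error(read_series(f), class = "electromer_empty_input")

  writeLines("# rate_hz: 62.5", f)
  expect_error(read_series(f), class = "electromer_empty_input")

  expect_error(read_series(file.path(tempdir(), "nope.tsv")),
    class = "electromer_io_error"
  )
})

test_that("acquisition filter removes DC, keeps the passband and rejects infrasound", {
  # constant input -> ~ 0
  out <- apply_acquisition_filter(rep(3, 2000), rate = 62.5)
  expect_lt(max(abs(out)), 1e-6 * 3)

  t <- seq_len(31250) / 62.5 # 500 s
  pass <- apply_acquisition_filter(sin(2 * pi * 5 * t), rate = 62.5)
  mid <- 1000:30000 # ignore edge transients
  expect_lt(abs(max(abs(pass[mid])) - 1) / 1, 0.05)

  stop_band <- apply_acquisition_filter(sin(2 * pi * 0.01 * t), rate = 62.5)
  expect_lt(max(abs(stop_band[mid])), 0.1)

  expect_error(apply_acquisition_filter(rnorm(100), highpass_hz = 40, rate = 62.5),
    class = "electromer_invalid_parameter"
  )
})

test_that("the acquisition filter is linear", {
  set.seed(1)
  x <- rnorm(4000)
  y <- rnorm(4000)
  fx <- apply_acquisition_filter(x, rate = 62.5)
  fy <- apply_acquisition_filter(y, rate = 62.5)
  fxy <- apply_acquisition_filter(2 * x - 3 * y, rate = 62.5)
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)
})
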