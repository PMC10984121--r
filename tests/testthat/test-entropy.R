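test_that("ApEn equals the brute-force Pincus definition", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(50:300, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, m = 2, r = r),
      apen_bruteforce(x, m = 2, r = r),
      tolerance = 1e-9
    )
  }
  # and an independent third implementation agrees
  skip_if_not_installed("pracma")
  set.seed(99)
  x <- rnorm(200)
  expect_equal(
    approximate_entropy(x, m = 2, r = 0.2 * sd(x)),
    pracma::approx_entropy(x, edim = 2, r = 0.2 * sd(x)),
    tolerance = 1e-9
  )
})

test_that("ApEn degenerate and invalid inputs behave per the definition", {
  expect_identical(approximate_entropy(rep(5, 200)), 0)
  expect_error(approximate_entropy(rnorm(100), r = -1),
    class = "electromer_invalid_parameter"
  )
  expect_error(approximate_entropy(rnorm(3), m = 2),
    class = "electromer_invalid_parameter"
  )
})

test_that("regular signals score lower ApEn than their shuffles", {
  square <- rep(c(0, 0, 1, 1), 100)
  for (s in 1:20) {
    set.seed(s)
    shuffled <- sample(square)
    r <- 0.2 * sd(square)
    expect_lt(
      approximate_entropy(square, r = r),
      approximate_entropy(shuffled, r = r)
    )
  }
})

test_that("decimation keeps long-series ApEn consistent with the small-N oracle", {
  set.seed(11)
  x <- rnorm(3000)
  # decimated path (max_points < n) must equal brute force on the kept samples
  kept <- x[seq(1, 3000, by = 3)]
  expect_equal(
    approximate_entropy(x, max_points = 1000),
    apen_bruteforce(kept, r = 0.2 * sd(x)),
    tolerance = 1e-9
  )
})

test_that("multiscale ApEn: scale identity, coarse lengths, white-noise decay", {
  set.seed(2)
  x <- rnorm(10000)
  ms <- multiscale_apen(x, max_scale = 20)
  expect_identical(ms$apen[1], approximate_entropy(x))
  expect_identical(nrow(ms), 20L)

  # coarse-grained length at scale s is floor(n/s)
  for (s in c(2, 7, 20)) {
    expect_length(electromer:::coarse_grain(x, s), 10000 %/% s)
  }

  # fixed-r multiscale entropy of white noise decreases with scale
  # (at most one of the 19 steps may go up, and the trend must fall)
  expect_lte(sum(diff(ms$apen) > 0), 1L)
  expect_lt(ms$apen[20], ms$apen[1])

  expect_error(multiscale_apen(rnorm(50), max_scale = 20),
    regexp = "feasible",
    class = "electromer_invalid_parameter"
  )
})
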