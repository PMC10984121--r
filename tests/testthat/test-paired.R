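test_that("coefficient of variation is correct and scale-free", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_equal(coefficient_of_variation(c(10, 20, 30)), 50)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_warning(res <- coefficient_of_variation(c(-1, 1)), "undefined")
  expect_true(is.na(res))
  expect_error(coefficient_of_variation(numeric()), class = "electromer_empty_input")
})

test_that("paired comparison routes by normality and reports the routed test", {
  # identical phases: degenerate, no p-value
  x <- rnorm(10)
  res <- paired_compare(x, x)
  expect_identical(res$test_used, "none")
  expect_true(is.na(res$p_value))

  # strong normal shift: t-test, tiny p
  set.seed(4)
  before <- rnorm(30)
  res <- paired_compare(before, before + 1 + rnorm(30, sd = 0.1))
  expect_identical(res$test_used, "t")
  expect_lt(res$p_value, 0.001)
  expect_true(res$significant)

  # heavy-tailed differences route to Wilcoxon in >= 90% of cases
  routed <- vapply(1:100, function(s) {
    set.seed(s)
    b <- rnorm(30)
    paired_compare(b, b + rcauchy(30))$test_used
  }, character(1))
  expect_gte(mean(routed == "wilcoxon"), 0.9)

  expect_error(paired_compare(rnorm(5), rnorm(4)),
    class = "electromer_invalid_input"
  )
  expect_error(paired_compare(rnorm(2), rnorm(2)),
    class = "electromer_invalid_parameter"
  )
})

test_that("phase comparison table pairs plants and mirrors the ledger variables", {
  set.seed(2)
  led <- tibble::tibble(
    plant_id = rep(1:12, 2),
    phase = rep(c("before", "after"), each = 12),
    apen = c(rnorm(12, 0.8, 0.05), rnorm(12, 0.2, 0.05)),
    psd_beta = rnorm(24, 1.7, 0.1)
  )
  tab <- phase_comparison_table(led, variables = c("apen", "psd_beta"))
  expect_identical(tab$variable, c("apen", "psd_beta"))
  apen_row <- tab[tab$variable == "apen", ]
  expect_identical(apen_row$n, 12L)
  expect_lt(apen_row$p_value, 0.001)
  expect_lt(apen_row$mean_after, apen_row$mean_before)
})
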