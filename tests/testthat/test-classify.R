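test_that("confusion matrices are row-normalized with correct edge handling", {
  perfect <- confusion_matrix(c("a", "b", "a", "b"), c("a", "b", "a", "b"))
  expect_equal(as.matrix(perfect), diag(2),
    ignore_attr = TRUE
  )

  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  m <- as.matrix(cm)
  expect_equal(rowSums(m), c(a = 1, b = 1))
  expect_equal(m["a", "b"], 0.5)

  # zero-support class flagged, not fabricated
  z <- confusion_matrix(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  expect_identical(attr(z, "zero_support"), "b")
  expect_true(all(is.na(as.matrix(z)["b", ])))

  expect_error(confusion_matrix(c("a"), c("c"), classes = c("a", "b")),
    class = "electromer_invalid_input"
  )
  expect_error(confusion_matrix(c("a", "b"), c("a")),
    class = "electromer_invalid_input"
  )
})

test_that("uniformly random predictions fill every cell at the chance level", {
  for (k in c(2, 4)) {
    set.seed(k)
    n <- 4000
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    m <- as.matrix(confusion_matrix(truth, pred))
    se <- sqrt((1 / k) * (1 - 1 / k) / (n / k))
    expect_true(all(abs(m - 1 / k) < 4 * se))
  }
})

test_that("the harness is deterministic and its splits reconstructible", {
  ds <- null_dataset(60, 2, seed = 5)
  a <- run_learning_curve(ds, "knn", fractions = c(0.3, 0.7), repetitions = 4, seed = 42)
  b <- run_learning_curve(ds, "knn", fractions = c(0.3, 0.7), repetitions = 4, seed = 42)
  expect_identical(a$accuracy, b$accuracy)
  c_ <- run_learning_curve(ds, "knn", fractions = c(0.3, 0.7), repetitions = 4, seed = 43)
  expect_false(identical(a$accuracy, c_$accuracy))
  expect_error(run_learning_curve(ds, "knn", repetitions = 0),
    class = "electromer_invalid_parameter"
  )
  one_class <- ds[ds$label == "a", ]
  expect_error(run_learning_curve(one_class, "knn"),
    class = "electromer_invalid_parameter"
  )
})

test_that("every classifier reaches the ceiling on separable electromes", {
  sep <- separable_electromes(n_per_class = 8, n_samples = 3000, seed = 3)
  ds <- reduce_dataset(sep$series, sep$labels, window_size = 1000)
  lc <- run_learning_curve(ds,
    classifiers = classifier_roster(),
    fractions = c(0.5, 0.9), repetitions = 3, seed = 17
  )
  g <- glance(lc)
  expect_true(all(g$mean_accuracy == 1))
})

test_that("shuffled labels drive every classifier to chance accuracy", {
  ds <- null_dataset(120, 2, seed = 8)
  lc <- run_learning_curve(ds,
    classifiers = classifier_roster(),
    fractions = 0.5, repetitions = 5, seed = 21
  )
  g <- glance(lc)
  # 5 reps x 60 test samples per point
  se <- sqrt(0.25 / 300)
  expect_true(all(abs(g$mean_accuracy - 0.5) < 4 * se))
})

test_that("paired Wilcoxon comparison of accuracy samples", {
  expect_true(compare_classifiers(rep(0.8, 20), rep(0.8, 20))$no_difference)
  set.seed(1)
  a <- runif(20, 0.75, 0.85)
  res <- compare_classifiers(a + 0.2, a)
  expect_lt(res$p_value, 0.05)
  expect_error(compare_classifiers(runif(20), runif(19)),
    class = "electromer_invalid_input"
  )
})
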