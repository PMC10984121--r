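#' Classifier roster
#'
#' The six classifier families evaluated by the harness, with fixed
#' documented hyperparameters: `knn` (k = 5, Euclidean, standardized
#' features), `dt` (CART decision tree), `rf` (random forest, 100 trees),
#' `bayes` (Gaussian naive Bayes), `svm` (RBF kernel, standardized
#' features) and `ann` (single hidden layer of 32 units, standardized
#' features).
#'
#' @return Character vector of classifier names.
#' @export
classifier_roster <- function() {
  c("knn", "dt", "rf", "bayes", "svm", "ann")
}

standardize_xy <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sds <- apply(train_x, 2, sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(
    train = sweep(sweep(train_x, 2, mu), 2, sds, "/"),
    test = sweep(sweep(test_x, 2, mu), 2, sds, "/")
  )
}

# One train/predict round. `train_x`/`test_x` are numeric matrices,
# `train_y` a factor. Returns predicted factor levels for the test rows.
fit_predict_classifier <- function(classifier, train_x, train_y, test_x,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  lv <- levels(train_y)
  pred <- switch(classifier,
    knn = {
      z <- standardize_xy(train_x, test_x)
      as.character(class::knn(z$train, z$test, train_y,
        k = min(5, nrow(z$train))
      ))
    },
    dt = {
      df <- data.frame(.label = train_y, train_x, check.names = FALSE)
      fit <- rpart::rpart(.label ~ .,
        data = df, method = "class",
        control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0)
      )
      as.character(predict(fit,
        newdata = as.data.frame(test_x, check.names = FALSE),
        type = "class"
      ))
    },
    rf = {
      fit <- randomForest::randomForest(train_x, train_y, ntree = 100)
      as.character(predict(fit, test_x))
    },
    bayes = {
      fit <- e1071::naiveBayes(train_x, train_y)
      as.character(predict(fit, test_x))
    },
    svm = {
      z <- standardize_xy(train_x, test_x)
      fit <- e1071::svm(z$train, train_y, kernel = "radial", scale = FALSE)
      as.character(predict(fit, z$test))
    },
    ann = {
      z <- standardize_xy(train_x, test_x)
      df <- data.frame(.label = train_y, z$train, check.names = FALSE)
      fit <- nnet::nnet(.label ~ .,
        data = df, size = 32, decay = 1e-2,
        maxit = 300, MaxNWts = 1e5, trace = FALSE
      )
      p <- predict(fit,
        newdata = as.data.frame(z$test, check.names = FALSE),
        type = "class"
      )
      as.character(p)
    },
    abort(sprintf("unknown classifier '%s'.", classifier),
      class = "electromer_invalid_parameter"
    )
  )
  factor(pred, levels = lv)
}

# Stratified train/test split. Draws round(fraction * n_c) per class; a
# draw that leaves a class without training samples is logged and redrawn,
# falling back to a forced minimum of one sample per class.
stratified_split <- function(y, fraction, seed, max_redraws = 50L) {
  n <- length(y)
  for (attempt in seq_len(max_redraws)) {
    set.seed(as.integer(derive_seed(seed, "split", attempt)))
    idx_tr <- unlist(lapply(split(seq_len(n), y), function(idx) {
      k <- round(fraction * length(idx))
      if (k >= length(idx)) k <- length(idx) - 1L
      if (k <= 0L) return(integer())
      sample(idx, k)
    }), use.names = FALSE)
    if (length(idx_tr) > 0L && length(idx_tr) < n &&
      all(levels(y) %in% y[idx_tr])) {
      return(sort(idx_tr))
    }
    message(sprintf(
      "split at fraction %.2f left a class empty; redrawing (attempt %d)",
      fraction, attempt
    ))
  }
  # fallback: force at least one training sample per class
  idx_tr <- unlist(lapply(split(seq_len(n), y), function(idx) {
    k <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
    sample(idx, k)
  }), use.names = FALSE)
  sort(idx_tr)
}

check_dataset <- function(data) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  y <- factor(data$label)
  if (nlevels(y) < 2L) {
    abort("need at least 2 classes.", class = "electromer_invalid_parameter")
  }
  if (any(table(y) < 2L)) {
    abort("need at least 2 samples per class.",
      class = "electromer_invalid_parameter"
    )
  }
  x <- as.matrix(dplyr::select(data, -"label"))
  storage.mode(x) <- "double"
  list(x = x, y = y)
}

#' Learning curves by repeated stratified holdout
#'
#' For every classifier and training fraction, draws `repetitions`
#' stratified random train/test splits (each with its own seed derived from
#' the master seed, classifier, fraction and repetition index, so every
#' split is reconstructible), trains on the training part and records the
#' test-set accuracy per repetition.
#'
#' @param data Tibble with a `label` column (class per series) and numeric
#'   feature columns, e.g. from [reduce_dataset()].
#' @param classifiers Subset of [classifier_roster()].
#' @param fractions Training fractions in (0, 1) (default 0.1 to 0.9 by
#'   0.1).
#' @param repetitions Repetitions per classifier x fraction (default 20,
#'   feeding the paired Wilcoxon comparison).
#' @param seed Master seed.
#' @return Tibble (class `electrome_curve`) with columns `classifier`,
#'   `fraction`, `repetition`, `accuracy`; `glance()` summarizes to mean
#'   +/- sd per curve point and `autoplot()` draws the curves.
#' @examples
#' d <- data.frame(
#'   label = rep(c("a", "b"), each = 10),
#'   f1 = c(rnorm(10), rnorm(10, 5))
#' )
#' run_learning_curve(d, "knn", fractions = 0.5, repetitions = 3, seed = 1)
#' @export
run_learning_curve <- function(data, classifiers = classifier_roster(),
                               fractions = seq(0.1, 0.9, by = 0.1),
                               repetitions = 20, seed = 1L) {
  classifiers <- match.arg(classifiers, classifier_roster(),
    several.ok = TRUE
  )
  if (repetitions < 1L) {
    abort("`repetitions` must be >= 1.", class = "electromer_invalid_parameter")
  }
  ds <- check_dataset(data)
  grid <- tidyr::expand_grid(
    classifier = classifiers, fraction = fractions,
    repetition = seq_len(repetitions)
  )
  out <- purrr::pmap_dfr(grid, function(classifier, fraction, repetition) {
    rep_seed <- derive_seed(seed, classifier, round(fraction * 1000), repetition)
    idx_tr <- stratified_split(ds$y, fraction, rep_seed)
    pred <- fit_predict_classifier(
      classifier, ds$x[idx_tr, , drop = FALSE], ds$y[idx_tr],
      ds$x[-idx_tr, , drop = FALSE],
      seed = derive_seed(rep_seed, "fit")
    )
    tibble(
      classifier = classifier, fraction = fraction,
      repetition = repetition, seed = rep_seed,
      accuracy = mean(as.character(pred) == as.character(ds$y[-idx_tr]))
    )
  })
  attr(out, "master_seed") <- seed
  class(out) <- c("electrome_curve", class(out))
  out
}

#' @export
glance.electrome_curve <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$classifier, .data$fraction),
    n = dplyr::n(),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = sd(.data$accuracy),
    .groups = "drop"
  )
}

#' @export
autoplot.electrome_curve <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(.data$fraction, .data$mean_accuracy,
    colour = .data$classifier
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy
    ), linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Training fraction", y = "Accuracy",
      colour = "Classifier"
    ) +
    ggplot2::theme_minimal()
}

#' Row-normalized confusion matrix
#'
#' Entry (i, j) is the fraction of class-i items predicted as class j, so
#' each row with nonzero support sums to 1. Under chance-level prediction
#' with k balanced classes every cell converges to 1/k.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class set; defaults to the union of levels. Labels
#'   outside `classes` raise an error.
#' @return Tibble (class `electrome_confusion`) in long form: `truth`,
#'   `predicted`, `n`, `prop` (NA for zero-support rows, which are also
#'   listed in `attr(x, "zero_support")`). Use [as.matrix()] for the wide
#'   k x k matrix.
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length.",
      class = "electromer_invalid_input"
    )
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- classes %||% sort(unique(c(truth, predicted)))
  if (length(classes) == 0L) {
    abort("`classes` must be non-empty.", class = "electromer_invalid_input")
  }
  stray <- setdiff(unique(c(truth, predicted)), classes)
  if (length(stray) > 0L) {
    abort(sprintf("label(s) outside `classes`: %s.", toString(stray)),
      class = "electromer_invalid_input"
    )
  }
  counts <- table(
    factor(truth, levels = classes),
    factor(predicted, levels = classes)
  )
  support <- rowSums(counts)
  props <- counts / ifelse(support == 0, NA_real_, support)
  out <- as_tibble(as.data.frame(counts, stringsAsFactors = FALSE))
  names(out) <- c("truth", "predicted", "n")
  # as.data.frame(table) enumerates truth fastest, matching column-major
  # order of the props matrix (truth in rows)
  out$prop <- as.numeric(props)
  attr(out, "classes") <- classes
  attr(out, "zero_support") <- classes[support == 0]
  class(out) <- c("electrome_confusion", class(out))
  out
}

#' @export
as.matrix.electrome_confusion <- function(x, ...) {
  classes <- attr(x, "classes")
  m <- matrix(NA_real_, length(classes), length(classes),
    dimnames = list(truth = classes, predicted = classes)
  )
  m[cbind(
    match(x$truth, classes),
    match(x$predicted, classes)
  )] <- x$prop
  m
}

#' @export
autoplot.electrome_confusion <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$predicted, .data$truth,
    fill = .data$prop
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop))) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue",
      limits = c(0, 1)
    ) +
    ggplot2::labs(x = "Predicted", y = "True class", fill = "Fraction") +
    ggplot2::theme_minimal()
}

#' Pooled confusion matrix at one training fraction
#'
#' Runs the repeated-holdout harness for a single classifier and training
#' fraction and pools the test-set predictions of all repetitions into one
#' row-normalized confusion matrix (the per-figure validation step of the
#' evaluation protocol).
#'
#' @inheritParams run_learning_curve
#' @param classifier One of [classifier_roster()].
#' @param fraction Training fraction.
#' @return An `electrome_confusion` (see [confusion_matrix()]) with the
#'   pooled prediction counts in `n`.
#' @export
evaluate_confusion <- function(data, classifier = "knn", fraction = 0.7,
                               repetitions = 20, seed = 1L) {
  classifier <- match.arg(classifier, classifier_roster())
  ds <- check_dataset(data)
  truth_all <- character()
  pred_all <- character()
  for (repetition in seq_len(repetitions)) {
    rep_seed <- derive_seed(seed, classifier, round(fraction * 1000), repetition)
    idx_tr <- stratified_split(ds$y, fraction, rep_seed)
    pred <- fit_predict_classifier(
      classifier, ds$x[idx_tr, , drop = FALSE], ds$y[idx_tr],
      ds$x[-idx_tr, , drop = FALSE],
      seed = derive_seed(rep_seed, "fit")
    )
    truth_all <- c(truth_all, as.character(ds$y[-idx_tr]))
    pred_all <- c(pred_all, as.character(pred))
  }
  confusion_matrix(truth_all, pred_all, classes = levels(ds$y))
}

#' Paired Wilcoxon comparison of two classifiers
#'
#' Compares the per-repetition accuracies of two classifiers evaluated on
#' the same repeated splits with the two-sided Wilcoxon signed-rank test.
#' When every paired difference is zero no test statistic exists and the
#' result is flagged `no_difference` instead of reporting a p-value.
#'
#' @param accuracy_a,accuracy_b Equal-length numeric vectors of paired
#'   per-repetition accuracies (length 20 under the default harness).
#' @return One-row tibble: `n`, `statistic`, `p_value`, `no_difference`.
#' @examples
#' compare_classifiers(c(0.9, 0.8, 0.85, 0.9), c(0.6, 0.5, 0.55, 0.65))
#' @export
compare_classifiers <- function(accuracy_a, accuracy_b) {
  if (length(accuracy_a) != length(accuracy_b)) {
    abort("paired accuracy vectors must have the same length.",
      class = "electromer_invalid_input"
    )
  }
  d <- accuracy_a - accuracy_b
  if (all(d == 0)) {
    return(tibble(
      n = length(d), statistic = NA_real_, p_value = NA_real_,
      no_difference = TRUE
    ))
  }
  ht <- suppressWarnings(
    wilcox.test(accuracy_a, accuracy_b, paired = TRUE, exact = FALSE)
  )
  tibble(
    n = length(d),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    no_difference = FALSE
  )
}
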