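#' Interval-arithmetic reduction of a series
#'
#' Reduces a voltage-variation series to per-window triplets
#' \eqn{[min, mean, max]}: the series is cut into consecutive
#' non-overlapping windows of `window_size` samples (a trailing partial
#' window is dropped) and each window is summarized by its minimum, central
#' value and maximum. With the study defaults (450,000-sample series,
#' 30,000-sample windows) this yields 15 triplets, i.e. 45 scalars per
#' series. The central value is the arithmetic mean by default; the median
#' is available via `center`.
#'
#' @param series An [electrome_series()] or numeric vector at least one
#'   window long.
#' @param window_size Window length in samples (default 30000).
#' @param center `"mean"` (default) or `"median"`.
#' @return Tibble (class `interval_features`) with columns `window`, `min`,
#'   `mid`, `max`; attribute `window_size`. Every row satisfies
#'   `min <= mid <= max`.
#' @examples
#' interval_reduce(1:6, window_size = 3)
#' @export
interval_reduce <- function(series, window_size = 30000,
                            center = c("mean", "median")) {
  center <- match.arg(center)
  x <- series_samples(series)
  if (window_size < 1 || length(x) < window_size) {
    abort("series is shorter than one window.",
      class = "electromer_invalid_parameter"
    )
  }
  k <- length(x) %/% window_size
  mat <- matrix(x[seq_len(k * window_size)], nrow = window_size)
  mid <- if (center == "mean") colMeans(mat) else apply(mat, 2, median)
  out <- tibble(
    window = seq_len(k),
    min = apply(mat, 2, min),
    mid = mid,
    max = apply(mat, 2, max)
  )
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "center") <- center
  class(out) <- c("interval_features", class(out))
  out
}

#' Flatten interval triplets into one feature vector
#'
#' @param reduced An [interval_reduce()] result (or a series, which is
#'   reduced first).
#' @param ... Passed to [interval_reduce()] when `reduced` is a series.
#' @return Named numeric vector `min_1, mid_1, max_1, min_2, ...` of length
#'   3 x number of windows.
#' @export
interval_features <- function(reduced, ...) {
  if (!inherits(reduced, "interval_features")) {
    reduced <- interval_reduce(reduced, ...)
  }
  k <- nrow(reduced)
  vals <- as.numeric(t(as.matrix(reduced[, c("min", "mid", "max")])))
  names(vals) <- paste0(
    rep(c("min_", "mid_", "max_"), k),
    rep(seq_len(k), each = 3)
  )
  vals
}

#' Build a labeled interval-feature dataset
#'
#' Reduces every series to its flattened triplet vector and stacks them
#' into the samples-by-features table the classifier harness consumes.
#'
#' @param series_list List of [electrome_series()] (or numeric vectors).
#' @param labels Class label per series (factor or character).
#' @param window_size,center Passed to [interval_reduce()].
#' @return Tibble with a `label` factor column followed by the flattened
#'   triplet columns.
#' @export
reduce_dataset <- function(series_list, labels, window_size = 30000,
                           center = "mean") {
  stopifnot(length(series_list) == length(labels))
  feats <- purrr::map(series_list, function(s) {
    as_tibble(as.list(interval_features(s,
      window_size = window_size,
      center = center
    )))
  })
  dplyr::bind_cols(
    tibble(label = factor(labels)),
    dplyr::bind_rows(feats)
  )
}
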