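#' Coefficient of variation
#'
#' \eqn{CV\% = 100 \cdot s / |\bar x|}: sample standard deviation as a
#' percentage of the absolute mean. Scale-free: multiplying the data by a
#' constant leaves it unchanged.
#'
#' @param values Non-empty numeric vector.
#' @return CV in percent, or `NA` (with a warning) when the mean is zero.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 50
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) == 0L) {
    abort("empty input.", class = "electromer_empty_input")
  }
  m <- mean(values)
  if (m == 0) {
    warning("CV is undefined for zero-mean data; returning NA.",
      call. = FALSE
    )
    return(NA_real_)
  }
  100 * sd(values) / abs(m)
}

#' Paired before/after comparison with normality-based test routing
#'
#' Compares paired values measured before and after a stimulus. The
#' Shapiro-Wilk test (at `alpha`) is applied to the paired differences: if
#' normality is not rejected a paired two-sided t-test is used, otherwise
#' the two-sided Wilcoxon signed-rank test. Which test ran is reported.
#' When before and after are identical no difference is detectable and the
#' comparison is reported as degenerate (`test_used = "none"`) rather than
#' with a p-value.
#'
#' @param before,after Equal-length numeric vectors (n >= 3).
#' @param alpha Significance level for both the routing check and the
#'   `significant` flag (default 0.05).
#' @param variable Optional variable name carried into the output.
#' @return One-row tibble (class `paired_comparison`): `variable`, `n`,
#'   `test_used`, `statistic`, `p_value`, `significant`, means, medians and
#'   SDs per phase, and `cv_before`/`cv_after` (CV%).
#' @examples
#' paired_compare(rnorm(20), rnorm(20, 1))
#' @export
paired_compare <- function(before, after, alpha = 0.05, variable = NA_character_) {
  if (length(before) != length(after)) {
    abort("`before` and `after` must have the same length.",
      class = "electromer_invalid_input"
    )
  }
  if (length(before) < 3L) {
    abort("need at least 3 pairs.", class = "electromer_invalid_parameter")
  }
  d <- after - before
  base <- tibble(
    variable = variable,
    n = length(before),
    test_used = NA_character_,
    statistic = NA_real_,
    p_value = NA_real_,
    significant = NA,
    mean_before = mean(before), mean_after = mean(after),
    median_before = median(before), median_after = median(after),
    sd_before = sd(before), sd_after = sd(after),
    cv_before = suppressWarnings(coefficient_of_variation(before)),
    cv_after = suppressWarnings(coefficient_of_variation(after))
  )
  if (all(d == 0)) {
    base$test_used <- "none"
    base$significant <- FALSE
    class(base) <- c("paired_comparison", class(base))
    return(base)
  }
  normal <- sd(d) > 0 &&
    tryCatch(shapiro.test(d)$p.value > alpha, error = function(e) FALSE)
  ht <- if (normal) {
    t.test(after, before, paired = TRUE)
  } else {
    suppressWarnings(wilcox.test(after, before, paired = TRUE, exact = FALSE))
  }
  base$test_used <- if (normal) "t" else "wilcoxon"
  base$statistic <- unname(ht$statistic)
  base$p_value <- ht$p.value
  base$significant <- ht$p.value <= alpha
  class(base) <- c("paired_comparison", class(base))
  base
}

#' @export
tidy.paired_comparison <- function(x, ...) as_tibble(x)

#' Before/after comparison table from a feature ledger
#'
#' Pairs each plant's before and after values for the requested ledger
#' variables and runs [paired_compare()] per variable, producing a
#' comparison table in the style of a treatment summary: mean +/- SD (or
#' medians), the routed test, p-value and significance marker.
#'
#' @param ledger Tibble with columns `plant_id`, `phase` and the feature
#'   columns (e.g. from [ledger_table()]).
#' @param variables Character vector of feature columns to compare.
#' @param alpha Significance level.
#' @return Tibble with one row per variable.
#' @export
phase_comparison_table <- function(ledger,
                                   variables = c(
                                     "mean_dv", "skew", "kurt", "pdf_mu",
                                     "acf_lag_s", "psd_beta", "apen"
                                   ),
                                   alpha = 0.05) {
  stopifnot(all(c("plant_id", "phase") %in% names(ledger)))
  variables <- intersect(variables, names(ledger))
  purrr::map_dfr(variables, function(v) {
    wide <- tidyr::pivot_wider(
      ledger[, c("plant_id", "phase", v)],
      names_from = "phase", values_from = dplyr::all_of(v)
    )
    wide <- wide[stats::complete.cases(wide[, c("before", "after")]), ]
    if (nrow(wide) < 3L) {
      return(tibble(variable = v, n = nrow(wide), test_used = "none"))
    }
    paired_compare(wide$before, wide$after, alpha = alpha, variable = v)
  })
}
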