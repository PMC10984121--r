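#' Fit the power-law exponent of the voltage-variation distribution
#'
#' Fits \eqn{P(\Delta V) \propto |\Delta V|^{-\mu}} to the tail of the
#' absolute voltage-variation distribution. The default protocol bins
#' \eqn{|\Delta V|} into log-spaced bins, converts counts to a density and
#' regresses log density on log amplitude (OLS) over the fit range —
#' by default everything above the 90th percentile of \eqn{|\Delta V|}.
#' A truncated-Pareto maximum-likelihood fit over the same range is
#' available with `method = "ml"`. Exponents between 1 and 3 are read as a
#' scale-free regime.
#'
#' @param series An [electrome_series()] or numeric vector.
#' @param bins Number of log-spaced bins (default 50).
#' @param fit_range Two-element numeric range of \eqn{|\Delta V|} used for
#'   the fit; default `c(quantile(|x|, 0.9), max(|x|))`.
#' @param method `"ols"` (log-log regression on binned densities, the
#'   default) or `"ml"` (truncated-Pareto maximum likelihood).
#' @return One-row tibble: `mu`, `r_squared` (`NA` for ML), `n_points`
#'   (samples in the fit range), `n_bins`, `failed`. When fewer than 10
#'   samples (or fewer than 5 nonempty bins) fall in the fit range the fit
#'   is flagged as failed rather than raising an error.
#' @examples
#' set.seed(1)
#' u <- runif(2e4)
#' x <- (0.05^-1.5 + u * (10^-1.5 - 0.05^-1.5))^(1 / -1.5) # mu = 2.5
#' fit_pdf_exponent(x)$mu
#' @export
fit_pdf_exponent <- function(series, bins = 50, fit_range = NULL,
                             method = c("ols", "ml")) {
  method <- match.arg(method)
  a <- abs(series_samples(series))
  a <- a[a > 0]
  failed <- tibble(
    mu = NA_real_, r_squared = NA_real_, n_points = 0L,
    n_bins = 0L, failed = TRUE
  )
  if (length(a) < 10L) return(failed)
  fit_range <- fit_range %||% c(unname(quantile(a, 0.9)), max(a))
  tail_x <- a[a >= fit_range[1] & a <= fit_range[2]]
  failed$n_points <- length(tail_x)
  if (length(tail_x) < 10L || fit_range[1] <= 0 ||
    fit_range[2] <= fit_range[1]) {
    return(failed)
  }

  if (method == "ml") {
    mu <- fit_trunc_pareto_ml(tail_x, fit_range[1], fit_range[2])
    return(tibble(
      mu = mu, r_squared = NA_real_, n_points = length(tail_x),
      n_bins = NA_integer_, failed = FALSE
    ))
  }

  edges <- exp(seq(log(fit_range[1]), log(fit_range[2]), length.out = bins + 1))
  counts <- graphics::hist(tail_x, breaks = edges, plot = FALSE)$counts
  widths <- diff(edges)
  centers <- sqrt(edges[-1] * edges[-length(edges)]) # geometric mid
  nonzero <- counts > 0
  failed$n_bins <- sum(nonzero)
  if (sum(nonzero) < 5L) return(failed)
  dens <- counts[nonzero] / (length(a) * widths[nonzero])
  fit <- lm(log(dens) ~ log(centers[nonzero]))
  tibble(
    mu = -unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_points = length(tail_x),
    n_bins = sum(nonzero),
    failed = FALSE
  )
}

# MLE for a Pareto density ~ x^-mu truncated to [a, b].
fit_trunc_pareto_ml <- function(x, a, b) {
  sl <- sum(log(x))
  n <- length(x)
  nll <- function(mu) {
    e <- 1 - mu
    logc <- if (abs(e) < 1e-9) -log(log(b / a)) else log(e / (b^e - a^e))
    -(n * logc - mu * sl)
  }
  optimize(nll, c(1.0001, 25))$minimum
}
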