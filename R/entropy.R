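#' Approximate entropy
#'
#' ApEn(m, r) in the original Pincus formulation:
#' \eqn{\Phi^m(r) - \Phi^{m+1}(r)}, with Chebyshev distance between
#' embedded template vectors and self-matches included. Lower values mean a
#' more regular signal; a constant series has ApEn 0.
#'
#' Computing ApEn on a full two-hour recording (450,000 samples) is
#' quadratic and impractical, so series longer than `max_points` are first
#' decimated by keeping every k-th sample (k = `floor(n / max_points)`);
#' the tolerance `r` is taken from the standard deviation of the
#' *undecimated* series. Set `max_points = Inf` to disable.
#'
#' @param series An [electrome_series()] or numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; defaults to `r_factor * sd(series)`.
#' @param r_factor Tolerance as a fraction of the series SD (default 0.2).
#' @param max_points Decimation target length (default 10000).
#' @return ApEn value (scalar, >= 0 up to float noise).
#' @examples
#' approximate_entropy(rep(1, 100)) # 0
#' approximate_entropy(rnorm(500)) # high: white noise is irregular
#' @export
approximate_entropy <- function(series, m = 2, r = NULL, r_factor = 0.2,
                                max_points = 10000) {
  x <- series_samples(series)
  if (length(x) < m + 2L) {
    abort("series shorter than m + 2.", class = "electromer_invalid_parameter")
  }
  r_derived <- is.null(r)
  r <- r %||% (r_factor * sd(x))
  if (!is.finite(r) || r <= 0) {
    # constant series: every template matches within any tolerance, ApEn = 0
    if (r_derived && sd(x) == 0) return(0)
    abort("`r` must be > 0.", class = "electromer_invalid_parameter")
  }
  x <- decimate_series(x, max_points)
  apen_cpp(x, as.integer(m), r)
}

decimate_series <- function(x, max_points) {
  n <- length(x)
  if (!is.finite(max_points) || n <= max_points) return(x)
  step <- floor(n / max_points)
  x[seq(1L, n, by = step)]
}

#' Multiscale approximate entropy
#'
#' ApEn computed on coarse-grained versions of the series: at scale s the
#' series is replaced by the means of non-overlapping blocks of s
#' consecutive samples (length `floor(n / s)`). The tolerance r is fixed
#' from the standard deviation of the original (scale-1) series for all
#' scales, so entropy changes across scales reflect the coarse-graining,
#' not a moving tolerance. Scale 1 is exactly [approximate_entropy()].
#'
#' @inheritParams approximate_entropy
#' @param max_scale Largest coarse-graining scale (default 50);
#'   `floor(n / max_scale)` must be at least `m + 2`.
#' @return Tibble with columns `scale` and `apen`.
#' @examples
#' multiscale_apen(rnorm(2000), max_scale = 5)
#' @export
multiscale_apen <- function(series, max_scale = 50, m = 2, r = NULL,
                            r_factor = 0.2, max_points = 10000) {
  x <- series_samples(series)
  n <- length(x)
  feasible <- n %/% (m + 2L)
  if (max_scale < 1L || n %/% max_scale < m + 2L) {
    abort(
      sprintf(
        "series too short for max_scale = %d (maximal feasible scale: %d).",
        max_scale, feasible
      ),
      class = "electromer_invalid_parameter"
    )
  }
  r <- r %||% (r_factor * sd(x))
  if (r == 0) r <- NULL # constant series: let each scale resolve to ApEn 0
  purrr::map_dfr(seq_len(max_scale), function(s) {
    tibble(
      scale = s,
      apen = approximate_entropy(coarse_grain(x, s),
        m = m, r = r,
        max_points = max_points
      )
    )
  })
}

coarse_grain <- function(x, s) {
  if (s == 1L) return(x)
  k <- length(x) %/% s
  colMeans(matrix(x[seq_len(k * s)], nrow = s))
}
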