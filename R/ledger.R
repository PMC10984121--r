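#' Compute the nine-statistic feature ledger of a series
#'
#' Aggregates the characterization statistics computed per
#' electrophytogram: mean voltage variation, skewness, kurtosis, power-law
#' PDF exponent \eqn{\mu}, autocorrelation decay lag, PSD exponent
#' \eqn{\beta}, approximate entropy, the Fourier amplitude spectrum and
#' multiscale approximate entropy. Statistics that cannot be computed on a
#' given series (e.g. moments of a constant signal, a failed tail fit) are
#' returned as `NA` and named in the `flags` column — the ledger itself
#' never aborts.
#'
#' @param series An [electrome_series()] or numeric vector.
#' @param rate Sampling rate in Hz (taken from the series when omitted).
#' @param m,r_factor,max_points ApEn parameters, see
#'   [approximate_entropy()].
#' @param max_scale Number of multiscale-entropy scales (default 50); set to
#'   `NULL` to skip the multiscale curve.
#' @param fit_band_hz PSD fit band, see [fit_psd_exponent()].
#' @param pdf_bins,pdf_fit_range PDF fit protocol, see
#'   [fit_pdf_exponent()].
#' @param include_fft Attach the full amplitude spectrum as a list-column?
#' @return A one-row tibble with scalar columns `mean_dv`, `skew`, `kurt`,
#'   `pdf_mu`, `pdf_r2`, `acf_lag_s`, `acf_censored`, `psd_beta`, `psd_r2`,
#'   `apen`, a `flags` character column, metadata columns (`experiment`,
#'   `plant_id`, `phase`) and list-columns `fft` and `msapen` holding the
#'   spectra. Deterministic given the series and parameters.
#' @examples
#' s <- synthesize_electrome("water", "before", seed = 1, duration_s = 120)
#' feature_ledger(s, max_scale = 5)
#' @export
feature_ledger <- function(series, rate = NULL, m = 2, r_factor = 0.2,
                           max_points = 10000, max_scale = 50,
                           fit_band_hz = c(0.05, 10),
                           pdf_bins = 50, pdf_fit_range = NULL,
                           include_fft = TRUE) {
  rate <- series_rate(series, rate)
  x <- series_samples(series)
  flags <- character()
  grab <- function(label, expr, default = NA_real_) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, label)
      default
    })
  }

  mom <- grab("moments", signal_moments(x),
    default = tibble(skew = NA_real_, kurt = NA_real_)
  )
  pdf_fit <- grab(
    "pdf",
    {
      ft <- fit_pdf_exponent(x, bins = pdf_bins, fit_range = pdf_fit_range)
      if (ft$failed) flags <<- c(flags, "pdf")
      ft
    },
    default = tibble(mu = NA_real_, r_squared = NA_real_)
  )
  ac <- grab("acf", autocorrelation_summary(x, rate = rate),
    default = tibble(lag_s = NA_real_, censored = NA)
  )
  psd_fit <- grab(
    "psd",
    {
      ft <- fit_psd_exponent(x, rate = rate, fit_band_hz = fit_band_hz)
      if (ft$failed) flags <<- c(flags, "psd")
      ft
    },
    default = tibble(beta = NA_real_, r_squared = NA_real_)
  )
  apen <- grab("apen", approximate_entropy(x,
    m = m, r_factor = r_factor,
    max_points = max_points
  ))
  msapen <- if (!is.null(max_scale)) {
    grab("msapen", multiscale_apen(x,
      max_scale = max_scale, m = m,
      r_factor = r_factor, max_points = max_points
    ), default = NULL)
  }
  spec <- if (include_fft) {
    grab("fft", fft_spectrum(x, rate = rate), default = NULL)
  }

  meta <- if (is_electrome_series(series)) series$meta else list()
  tibble(
    experiment = meta$experiment %||% NA_character_,
    plant_id = meta$plant_id %||% NA_integer_,
    phase = meta$phase %||% NA_character_,
    mean_dv = grab("mean_dv", mean_voltage_variation(x)),
    skew = mom$skew,
    kurt = mom$kurt,
    pdf_mu = pdf_fit$mu,
    pdf_r2 = pdf_fit$r_squared,
    acf_lag_s = ac$lag_s,
    acf_censored = ac$censored,
    psd_beta = psd_fit$beta,
    psd_r2 = psd_fit$r_squared,
    apen = apen,
    flags = paste(unique(flags), collapse = ","),
    fft = list(spec),
    msapen = list(msapen)
  )
}

#' Feature ledgers for a set of series
#'
#' Maps [feature_ledger()] over a list of series and binds the rows; the
#' scalar columns give a Table-style per-series characterization suitable
#' for [phase_comparison_table()].
#'
#' @param series_list List of [electrome_series()].
#' @param ... Passed to [feature_ledger()].
#' @return Tibble with one row per series.
#' @export
ledger_table <- function(series_list, ...) {
  purrr::map_dfr(series_list, feature_ledger, ...)
}
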