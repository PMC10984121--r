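#' Plot a multiscale-entropy curve
#'
#' @param msapen Tibble with `scale` and `apen` columns, as returned by
#'   [multiscale_apen()], optionally with a grouping column `group`.
#' @return A ggplot of ApEn against coarse-graining scale.
#' @export
plot_msapen <- function(msapen) {
  p <- ggplot2::ggplot(msapen, ggplot2::aes(.data$scale, .data$apen))
  if ("group" %in% names(msapen)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$group))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "Scale s", y = "ApEn(s)") + ggplot2::theme_minimal()
}
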