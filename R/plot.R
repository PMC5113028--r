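# Convenience plot of transmissibility spectra (requires ggplot2).

#' Plot glove transmissibility spectra
#'
#' Line plot of per-band transmissibility versus band center (log axis), one
#' facet per direction, colored by glove.
#'
#' @param spectra Spectra table (`glove, location, direction, freq_hz, value`).
#' @param location Location to plot.
#' @param directions Directions to include.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, location = "full",
                         directions = c("y", "xz", "xyz")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_spectra() needs the ggplot2 package", call. = FALSE)
  }
  dat <- spectra[spectra$location == location &
    spectra$direction %in% directions, ]
  if (nrow(dat) == 0) stop("nothing to plot for that selection", call. = FALSE)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$freq_hz, y = .data$value, color = .data$glove
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~direction, ncol = 1) +
    ggplot2::labs(
      x = "One-third octave band center (Hz)",
      y = "Transmissibility",
      title = paste("Glove transmissibility,", location, "location")
    ) +
    ggplot2::theme_minimal()
}
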