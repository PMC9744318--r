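# ggplot2 display methods for simulations, LFP traces and spectra.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Spike raster of a simulation
#'
#' @param object A `"tc_sim"` object.
#' @param layers Layers to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tc_sim
#' @export
autoplot.tc_sim <- function(object, layers = NULL, ...) {
  sp <- object$spikes
  if (!is.null(layers)) sp <- sp[sp$layer %in% layers, ]
  sp$layer <- factor(sp$layer, levels = object$config$layers$layer)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$t_ms / 1000, y = .data$cell)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$layer), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "cell index") +
    ggplot2::theme_minimal()
}

#' Plot an LFP trace
#' @param object An `"lfp_trace"` tibble.
#' @param ... Unused.
#' @method autoplot lfp_trace
#' @export
autoplot.lfp_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms / 1000, y = .data$lfp)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "LFP (scaled units)") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum
#'
#' @param spec Output of [power_spectrum()].
#' @param band Frequency range to display (Hz).
#' @export
plot_spectrum <- function(spec, band = c(0, 25)) {
  s <- spec[spec$freq_hz >= band[1] & spec$freq_hz <= band[2], ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$freq_hz, y = .data$log_power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "log10 power") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' @param sg Output of [spectrogram()].
#' @export
plot_spectrogram <- function(sg) {
  ggplot2::ggplot(sg, ggplot2::aes(x = .data$t_ms / 1000, y = .data$freq_hz,
                                   fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
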