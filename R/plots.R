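#' Plot an image or projection
#'
#' Raster display of a simulated image, projection, or plain matrix, with a
#' symmetric gray scale.
#'
#' @param img A `simulated_image`, [projection_image()], or 2D array.
#' @return A ggplot object.
#' @export
plot_image <- function(img) {
  px <- if (inherits(img, "simulated_image")) img$pixels
        else if (inherits(img, "projection_image")) img$pixels
        else img
  d <- dim(px)
  df <- data.frame(x = rep(seq_len(d[2]), each = d[1]),
                   y = rep(seq_len(d[1]), times = d[2]),
                   value = as.vector(px))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a Fourier shell correlation curve
#'
#' @param fsc A tibble from [fourier_shell_correlation()], or a named list
#'   of such tibbles to overlay (names become the legend).
#' @return A ggplot object with the conventional 0.5 and 0.143 thresholds.
#' @export
plot_fsc <- function(fsc) {
  if (is.data.frame(fsc)) fsc <- list(fsc = fsc)
  df <- do.call(rbind, lapply(names(fsc), function(nm) {
    d <- fsc[[nm]]; d$curve <- nm; d
  }))
  ggplot2::ggplot(df[!is.na(df$fsc), ],
                  ggplot2::aes(x = .data$q, y = .data$fsc,
                               colour = .data$curve)) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.143), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC") +
    ggplot2::theme_minimal()
}

#' Plot a refinement loss trace
#'
#' @param trace A `refinement_trace` from [refine_centers()].
#' @return A ggplot object.
#' @export
plot_loss_trace <- function(trace) {
  stopifnot(inherits(trace, "refinement_trace"))
  ggplot2::ggplot(trace$loss, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gradient step", y = "stack loss (-NCC)") +
    ggplot2::theme_minimal()
}

#' Plot a radial power spectrum
#'
#' @param spec A tibble from [radial_power_spectrum()], or a named list of
#'   them to overlay.
#' @return A ggplot object on a log10 power scale.
#' @export
plot_power_spectrum <- function(spec) {
  if (is.data.frame(spec)) spec <- list(spectrum = spec)
  df <- do.call(rbind, lapply(names(spec), function(nm) {
    d <- spec[[nm]]; d$curve <- nm; d
  }))
  ggplot2::ggplot(df[df$q > 0, ],
                  ggplot2::aes(x = .data$q, y = .data$power,
                               colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "radial power") +
    ggplot2::theme_minimal()
}
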