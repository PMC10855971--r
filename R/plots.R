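#' Plot spectra of a sample table
#'
#' Absorbance log(1/R) against wavelength, one line per sample, coloured by
#' class.
#'
#' @param table A sample table.
#' @param colour Column used for the line colour.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_spectra <- function(table, colour = "class", alpha = 0.4) {
  long <- tidyr::pivot_longer(table,
                              cols = dplyr::starts_with("wl_"),
                              names_to = "wavelength",
                              names_prefix = "wl_",
                              names_transform = as.numeric,
                              values_to = "absorbance")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                     group = .data$id,
                                     colour = .data[[colour]])) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "wavelength (nm)", y = "log(1/R)") +
    ggplot2::theme_minimal()
}

#' Plot the beta-coefficient profile of a calibration
#'
#' @param x A `tea_calibration` or `mpls_model`.
#' @param n_peaks Number of top |beta| peaks to annotate.
#' @return A ggplot object.
#' @export
plot_beta <- function(x, n_peaks = 2L) {
  model <- if (inherits(x, "tea_calibration")) x$model else x
  bc <- beta_coefficients(model)
  pk <- beta_peaks(model, n_peaks)
  ggplot2::ggplot(bc, ggplot2::aes(.data$wavelength, .data$beta)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = pk$wavelength, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "wavelength (nm)", y = expression(beta)) +
    ggplot2::theme_minimal()
}

#' @method autoplot tea_pca
#' @export
autoplot.tea_pca <- function(object, ...) {
  vf <- 100 * object$variance_fraction
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data$class,
                               shape = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", vf[1]),
                  y = sprintf("PC2 (%.1f%%)", vf[2])) +
    ggplot2::theme_minimal()
}

#' @method autoplot tea_calibration
#' @export
autoplot.tea_calibration <- function(object, ...) {
  d <- tibble::tibble(reference = object$model$y,
                      predicted = object$model$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$reference, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(title = object$analyte,
                  x = "reference concentration",
                  y = "NIR-predicted concentration") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
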