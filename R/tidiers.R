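#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MPLS model into its beta-coefficient profile
#'
#' @param x An `mpls_model`.
#' @param ... Unused.
#' @return Tibble with `wavelength` and `beta` (see [beta_coefficients()]).
#' @method tidy mpls_model
#' @export
tidy.mpls_model <- function(x, ...) beta_coefficients(x)

#' @rdname tidy.mpls_model
#' @return `glance()`: one-row tibble with `n_factors`, `n`, `sec`-style
#'   residual SD of the fit, and `rsq`.
#' @method glance mpls_model
#' @export
glance.mpls_model <- function(x, ...) {
  e <- x$y - x$fitted
  tibble::tibble(
    n = length(x$y),
    n_factors = x$n_factors,
    sigma = sqrt(sum(e^2) / max(1L, length(e) - x$n_factors - 1L)),
    rsq = 1 - sum(e^2) / sum((x$y - mean(x$y))^2))
}

#' Tidy methods for calibration results
#'
#' `tidy()` returns the wavelength-domain beta coefficients of the final
#' equation; `glance()` the one-row calibration statistics (N, mean, SD,
#' estimated range, SEC, SECV, RSQ, RPD).
#'
#' @param x A `tea_calibration` from [calibrate_full_protocol()].
#' @param ... Unused.
#' @method tidy tea_calibration
#' @export
tidy.tea_calibration <- function(x, ...) beta_coefficients(x$model)

#' @rdname tidy.tea_calibration
#' @method glance tea_calibration
#' @export
glance.tea_calibration <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(analyte = x$analyte), x$stats,
                   tibble::tibble(n_factors = x$n_factors,
                                  n_outliers = nrow(x$outliers)))
}

#' Tidy methods for confusion reports
#'
#' @param x A `confusion_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-class metric tibble; `glance()`: one row with
#'   overall accuracy (%).
#' @method tidy confusion_report
#' @export
tidy.confusion_report <- function(x, ...) x$by_class

#' @rdname tidy.confusion_report
#' @method glance confusion_report
#' @export
glance.confusion_report <- function(x, ...) {
  tibble::tibble(accuracy = 100 * x$overall,
                 n = sum(x$by_class$n))
}

#' Tidy methods for the metal-composition PCA
#'
#' @param x A `tea_pca`.
#' @param ... Unused.
#' @return `tidy()`: the score tibble; `glance()`: variance fractions of
#'   the first two components.
#' @method tidy tea_pca
#' @export
tidy.tea_pca <- function(x, ...) x$scores

#' @rdname tidy.tea_pca
#' @method glance tea_pca
#' @export
glance.tea_pca <- function(x, ...) {
  tibble::tibble(
    pc1_variance = x$variance_fraction[1],
    pc2_variance = x$variance_fraction[2],
    pc12_variance = sum(x$variance_fraction[1:2]))
}
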