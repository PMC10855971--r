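#' Standard NIR wavelength grid
#'
#' The working grid of the instrument: reflectance recorded every 2 nm from
#' 1100 to 2498 nm, giving 700 spectral variables per sample.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm).
#' @param step_nm Grid spacing (nm).
#' @return Numeric vector of wavelengths (nm), strictly increasing and
#'   uniformly spaced.
#' @examples
#' length(wavelength_grid()) # 700
#' @export
wavelength_grid <- function(start_nm = 1100, end_nm = 2498, step_nm = 2) {
  if (step_nm <= 0 || end_nm <= start_nm) {
    stop("wavelength grid must be increasing with positive step", call. = FALSE)
  }
  seq(start_nm, end_nm, by = step_nm)
}

#' @rdname wavelength_grid
#' @param wavelengths Numeric vector of wavelengths.
#' @return `wl_colnames()`: column names of the form `"wl_<nm>"`.
#' @export
wl_colnames <- function(wavelengths) paste0("wl_", wavelengths)

#' Spectral columns of a sample table
#'
#' Sample tables store one spectrum per row in columns named `wl_<nm>`.
#' These helpers extract the spectra as a plain matrix (rows = samples,
#' columns = wavelengths) and recover the wavelength axis from the names.
#'
#' @param table A sample table (data frame with `wl_*` columns).
#' @return `spectra_matrix()`: numeric matrix; `table_wavelengths()`:
#'   numeric vector of wavelengths (nm).
#' @export
spectra_matrix <- function(table) {
  cols <- grep("^wl_", names(table), value = TRUE)
  if (length(cols) == 0L) stop("no spectral (wl_*) columns found", call. = FALSE)
  m <- as.matrix(table[, cols])
  storage.mode(m) <- "double"
  rownames(m) <- if ("id" %in% names(table)) table$id else NULL
  m
}

#' @rdname spectra_matrix
#' @export
table_wavelengths <- function(table) {
  cols <- grep("^wl_", names(table), value = TRUE)
  as.numeric(sub("^wl_", "", cols))
}

# Replace the wl_* block of a table with a new spectra matrix (possibly on a
# shorter effective grid); non-spectral columns are kept in place.
set_spectra <- function(table, mat, wavelengths) {
  stopifnot(nrow(mat) == nrow(table), ncol(mat) == length(wavelengths))
  meta <- table[, !grepl("^wl_", names(table)), drop = FALSE]
  spec <- tibble::as_tibble(as.data.frame(mat))
  names(spec) <- wl_colnames(wavelengths)
  dplyr::bind_cols(tibble::as_tibble(meta), spec)
}

# Gaussian absorption band on a wavelength axis (unit peak height).
gaussian_band <- function(wavelengths, center, sigma) {
  exp(-0.5 * ((wavelengths - center) / sigma)^2)
}
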