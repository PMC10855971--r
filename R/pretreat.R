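#' Parse a WinISI-style pretreatment code
#'
#' Pretreatments are written as a scatter-correction name followed by a
#' 4-digit math treatment, e.g. `"Detrend (2,4,4,1)"`: derivative order,
#' gap (points) over which each difference is taken, first smoothing
#' segment, second smoothing segment.  A bare code such as `"(0,0,1,1)"`
#' means no scatter correction.
#'
#' @param text Code string, e.g. `"SNV-DT (1,4,4,1)"`.
#' @return A list of class `pretreatment_code` with elements `scatter`
#'   (one of `"none"`, `"SNV"`, `"MSC"`, `"DT"`, `"SNV_DT"`),
#'   `derivative`, `gap`, `smooth1`, `smooth2`.
#' @examples
#' parse_treatment_code("Detrend (2,4,4,1)")
#' @export
parse_treatment_code <- function(text) {
  if (inherits(text, "pretreatment_code")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^\\s*([A-Za-z-]+)?\\s*\\(\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*\\)\\s*$",
    text))[[1]]
  if (length(m) == 0L) {
    stop("malformed pretreatment code: ", text, call. = FALSE)
  }
  scatter_raw <- toupper(m[2])
  if (is.na(scatter_raw) || scatter_raw == "") scatter_raw <- "NONE"
  scatter <- switch(scatter_raw,
    "NONE" = "none",
    "SNV" = "SNV",
    "MSC" = "MSC",
    "DT" = "DT", "DETREND" = "DT",
    "SNV-DT" = "SNV_DT", "SNVDT" = "SNV_DT", "SNV-DETREND" = "SNV_DT",
    stop("unknown scatter correction: ", m[2], call. = FALSE)
  )
  digits <- as.integer(m[3:6])
  if (!digits[1] %in% 0:3) {
    stop("derivative order must be 0-3", call. = FALSE)
  }
  if (digits[1] > 0 && digits[2] < 1) {
    stop("gap must be >= 1 when a derivative is taken", call. = FALSE)
  }
  if (digits[3] < 1 || digits[4] < 1) {
    stop("smoothing segments must be >= 1 point", call. = FALSE)
  }
  structure(list(scatter = scatter, derivative = digits[1], gap = digits[2],
                 smooth1 = digits[3], smooth2 = digits[4]),
            class = "pretreatment_code")
}

#' @export
format.pretreatment_code <- function(x, ...) {
  name <- switch(x$scatter, none = "none", SNV = "SNV", MSC = "MSC",
                 DT = "Detrend", SNV_DT = "SNV-DT")
  sprintf("%s (%d,%d,%d,%d)", name, x$derivative, x$gap, x$smooth1, x$smooth2)
}

#' @export
print.pretreatment_code <- function(x, ...) {
  cat("<pretreatment code> ", format(x), "\n", sep = "")
  invisible(x)
}

# ---- scatter corrections ---------------------------------------------------

.snv_mat <- function(M, ids = NULL) {
  mu <- rowMeans(M)
  sdv <- apply(M, 1L, stats::sd)
  bad <- which(sdv < 1e-12)
  if (length(bad) > 0L) {
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
      paste(bad, collapse = ", ")
    stop("SNV undefined for constant spectrum (sample ", lab, ")",
         call. = FALSE)
  }
  (M - mu) / sdv
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum to mean 0 and sample SD 1 (n - 1
#' denominator), removing additive and multiplicative scatter per spectrum.
#'
#' @param x A numeric spectrum or a sample table with `wl_*` columns.
#' @return Object of the same shape with SNV-corrected spectra.
#' @export
snv <- function(x) {
  if (is.numeric(x)) {
    return(drop(.snv_mat(matrix(x, nrow = 1L))))
  }
  M <- spectra_matrix(x)
  set_spectra(x, .snv_mat(M, ids = x$id), table_wavelengths(x))
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum is regressed on a reference spectrum, `x = a + b * ref`,
#' and corrected to `(x - a) / b`.  The reference defaults to the mean
#' spectrum of the table it is fitted on and is returned so validation
#' spectra can receive the identical transform.
#'
#' @param table A sample table.
#' @param reference `"mean"` (default) or a numeric reference spectrum.
#' @return A list with elements `table` (corrected sample table) and
#'   `reference` (the reference spectrum used).
#' @export
msc <- function(table, reference = "mean") {
  M <- spectra_matrix(table)
  if (identical(reference, "mean")) {
    if (nrow(M) < 2L) {
      stop("MSC with a mean reference needs at least 2 samples", call. = FALSE)
    }
    reference <- colMeans(M)
  }
  stopifnot(length(reference) == ncol(M))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  a <- numeric(nrow(M)); b <- numeric(nrow(M))
  for (i in seq_len(nrow(M))) {
    b[i] <- sum((M[i, ] - mean(M[i, ])) * rc) / denom
    a[i] <- mean(M[i, ]) - b[i] * mean(reference)
  }
  if (any(abs(b) < 1e-8)) {
    stop("MSC slope ~ 0 for sample ",
         paste(which(abs(b) < 1e-8), collapse = ", "), call. = FALSE)
  }
  corrected <- (M - a) / b
  list(table = set_spectra(table, corrected, table_wavelengths(table)),
       reference = reference)
}

.detrend_mat <- function(M, wavelengths, degree = 2L) {
  if (degree >= ncol(M) - 1L) {
    stop("detrend degree too high for the grid length", call. = FALSE)
  }
  X <- stats::poly(wavelengths, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  # residuals of least-squares polynomial fit, all spectra at once
  Q <- qr.Q(qr(X))
  t(t(M) - Q %*% (t(Q) %*% t(M)))
}

#' Polynomial detrend
#'
#' Fits a least-squares polynomial of the given degree in wavelength to each
#' spectrum and subtracts it (Barnes-style detrending; degree 2 by default).
#'
#' @param x A numeric spectrum or sample table; for a bare numeric vector
#'   supply `wavelengths`.
#' @param degree Polynomial degree.
#' @param wavelengths Wavelength axis (required for numeric input).
#' @return Detrended spectrum or sample table; each output spectrum has
#'   mean 0.
#' @export
detrend <- function(x, degree = 2L, wavelengths = NULL) {
  if (is.numeric(x)) {
    if (is.null(wavelengths)) wavelengths <- seq_along(x)
    return(drop(.detrend_mat(matrix(x, nrow = 1L), wavelengths, degree)))
  }
  M <- spectra_matrix(x)
  wl <- table_wavelengths(x)
  set_spectra(x, .detrend_mat(M, wl, degree), wl)
}

# ---- gap-segment derivative -------------------------------------------------

# Left-aligned running segment mean of width w across the columns of M.
.segment_mean <- function(M, w) {
  if (w <= 1L) return(M)
  p <- ncol(M)
  if (w > p) stop("smoothing segment wider than the spectrum", call. = FALSE)
  cs <- t(apply(M, 1L, cumsum))
  if (nrow(M) == 1L) cs <- matrix(cs, nrow = 1L)
  lower <- cbind(matrix(0, nrow(M), 1L), cs[, seq_len(p - w), drop = FALSE])
  (cs[, w:p, drop = FALSE] - lower) / w
}

.gap_diff <- function(M, g) {
  p <- ncol(M)
  if (g >= p) stop("gap wider than the spectrum", call. = FALSE)
  M[, (1L + g):p, drop = FALSE] - M[, seq_len(p - g), drop = FALSE]
}

.gap_segment_mat <- function(M, wavelengths, code) {
  trim <- (code$smooth1 - 1L) + code$derivative * code$gap + (code$smooth2 - 1L)
  if (trim >= ncol(M)) {
    stop("derivative/smoothing stencil wider than the spectrum", call. = FALSE)
  }
  out <- .segment_mean(M, code$smooth1)
  if (code$derivative > 0L) {
    for (k in seq_len(code$derivative)) out <- .gap_diff(out, code$gap)
  }
  out <- .segment_mean(out, code$smooth2)
  left <- floor(trim / 2)
  wl_eff <- wavelengths[(left + 1L):(left + ncol(out))]
  list(values = out, wavelengths = wl_eff)
}

#' Gap-segment derivative with running-mean smoothing
#'
#' Applies the 4-digit math treatment: a running segment mean of width
#' `smooth1`, then the gap difference `x(i + gap) - x(i)` taken
#' `derivative` times, then a second segment mean of width `smooth2`.
#' Each stage shortens the usable range; the trimmed edge points are
#' dropped and the output is re-registered on the interior of the grid.
#'
#' @param x Numeric spectrum or sample table.
#' @param code A pretreatment code (string or [parse_treatment_code()]
#'   result); only its 4 digits are used.
#' @param wavelengths Wavelength axis for numeric input.
#' @return For a numeric spectrum, a numeric vector with a `"wavelengths"`
#'   attribute; for a table, a sample table on the shortened grid.
#' @export
derivative_gap_segment <- function(x, code, wavelengths = NULL) {
  code <- parse_treatment_code(code)
  if (is.numeric(x)) {
    if (is.null(wavelengths)) wavelengths <- seq_along(x)
    r <- .gap_segment_mat(matrix(x, nrow = 1L), wavelengths, code)
    out <- drop(r$values)
    attr(out, "wavelengths") <- r$wavelengths
    return(out)
  }
  r <- .gap_segment_mat(spectra_matrix(x), table_wavelengths(x), code)
  set_spectra(x, r$values, r$wavelengths)
}

#' Apply a full pretreatment code to a sample table
#'
#' Scatter correction first (SNV, MSC, detrend, or SNV then detrend), then
#' the 4-digit derivative/smoothing treatment.  State estimated from the
#' data (the MSC reference) is returned so that validation spectra receive
#' the identical transform: pass the returned `state` back in.
#'
#' @param table A sample table.
#' @param code Pretreatment code (string or parsed).
#' @param state Optional fitted state from a previous call on the
#'   calibration set.
#' @return A list with elements `table` (pretreated, possibly on a
#'   shortened grid) and `state` (list with the parsed `code` and any
#'   `msc_reference`).
#' @export
apply_pretreatment <- function(table, code, state = NULL) {
  code <- parse_treatment_code(code)
  out <- table
  msc_reference <- if (!is.null(state)) state$msc_reference else NULL
  if (code$scatter == "SNV" || code$scatter == "SNV_DT") {
    out <- snv(out)
  }
  if (code$scatter == "DT" || code$scatter == "SNV_DT") {
    out <- detrend(out)
  }
  if (code$scatter == "MSC") {
    r <- msc(out, reference = if (is.null(msc_reference)) "mean" else
      msc_reference)
    out <- r$table
    msc_reference <- r$reference
  }
  if (code$derivative > 0L || code$smooth1 > 1L || code$smooth2 > 1L) {
    out <- derivative_gap_segment(out, code)
  }
  list(table = out,
       state = list(code = code, msc_reference = msc_reference))
}
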