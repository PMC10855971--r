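#' Modified partial least squares (MPLS) regression
#'
#' PLS1 variant in which, after each factor is extracted, the X-residual at
#' every wavelength is standardized (divided by the residual SD of that
#' wavelength) before the next factor is computed.  The final model is an
#' affine map of the pretreated spectrum: `y-hat = beta0 + x . beta`.
#'
#' @param X Numeric matrix of pretreated spectra (rows = samples); column
#'   names of the form `wl_<nm>` are used to label the beta profile.
#' @param y Numeric vector of reference concentrations.
#' @param n_factors Number of factors to extract.
#' @param compute_beta Accumulate the wavelength-domain beta coefficients
#'   (skippable to speed up cross-validation refits).
#' @return An object of class `mpls_model`: factor weights, loadings,
#'   score regression coefficients, residual-scale vectors, centers,
#'   `beta0`/`beta`, and the calibration fitted values.
#' @export
fit_mpls <- function(X, y, n_factors, compute_beta = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) < 1e-12) {
    stop("reference values have zero variance", call. = FALSE)
  }
  if (n_factors < 0 || n_factors > min(n - 1L, p)) {
    stop("n_factors out of range", call. = FALSE)
  }
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xr <- sweep(X, 2L, x_center)
  yr <- y - y_center
  W <- matrix(0, p, max(n_factors, 1L))
  P <- matrix(0, p, max(n_factors, 1L))
  S <- matrix(1, p, max(n_factors, 1L))
  q <- numeric(max(n_factors, 1L))
  fitted <- rep(y_center, n)
  if (n_factors >= 1L) {
    for (k in seq_len(n_factors)) {
      w <- drop(crossprod(Xr, yr))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t_k <- drop(Xr %*% w)
      tt <- sum(t_k^2)
      if (tt < 1e-14) break
      p_k <- drop(crossprod(Xr, t_k)) / tt
      q_k <- sum(yr * t_k) / tt
      Xr <- Xr - tcrossprod(t_k, p_k)
      yr <- yr - q_k * t_k
      # MPLS step: standardize the residual at each wavelength before the
      # next factor; (near-)exhausted columns keep unit scale.
      mu_k <- colMeans(Xr)
      s_k <- sqrt(pmax(colSums(Xr^2) - n * mu_k^2, 0) / (n - 1L))
      s_k[!is.finite(s_k) | s_k < 1e-10] <- 1
      Xr <- sweep(Xr, 2L, s_k, "/")
      W[, k] <- w; P[, k] <- p_k; S[, k] <- s_k; q[k] <- q_k
      fitted <- fitted + q_k * t_k
    }
  }
  wl <- if (!is.null(colnames(X))) {
    suppressWarnings(as.numeric(sub("^wl_", "", colnames(X))))
  } else NULL
  model <- structure(
    list(n_factors = n_factors, x_center = x_center, y_center = y_center,
         weights = W, loadings = P, scales = S, q = q,
         wavelengths = wl, fitted = fitted, y = y,
         beta0 = NULL, beta = NULL),
    class = "mpls_model")
  if (compute_beta) {
    probe <- rbind(0, diag(p))
    pred <- predict_mpls(model, probe)
    model$beta0 <- pred[1]
    model$beta <- pred[-1] - pred[1]
  }
  model
}

#' Predict from an MPLS model
#'
#' Replays the factor pipeline (score, deflate, rescale) on new pretreated
#' spectra; equivalently `beta0 + X . beta`.
#'
#' @param model An `mpls_model`.
#' @param X Matrix of pretreated spectra on the model's effective grid.
#' @param all_factors Return an `n x K` matrix of predictions using
#'   1..K factors instead of a vector (used by cross-validation).
#' @return Numeric vector of predictions (or a matrix when
#'   `all_factors = TRUE`).
#' @export
predict_mpls <- function(model, X, all_factors = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_center)) {
    stop("spectra are not on the model's effective grid", call. = FALSE)
  }
  Xr <- sweep(X, 2L, model$x_center)
  yhat <- rep(model$y_center, nrow(X))
  K <- model$n_factors
  out <- if (all_factors) matrix(0, nrow(X), K) else NULL
  if (K >= 1L) {
    for (k in seq_len(K)) {
      t_k <- drop(Xr %*% model$weights[, k])
      yhat <- yhat + model$q[k] * t_k
      if (all_factors) out[, k] <- yhat
      Xr <- Xr - tcrossprod(t_k, model$loadings[, k])
      Xr <- sweep(Xr, 2L, model$scales[, k], "/")
    }
  }
  if (all_factors) out else yhat
}

#' @export
predict.mpls_model <- function(object, newdata, ...) {
  predict_mpls(object, newdata)
}

#' Global H (Mahalanobis) spectral outliers
#'
#' Distance of each spectrum from the population centroid in principal
#' component score space: `GH = mean_j ((t_j - mean_j) / sd_j)^2` over the
#' first `n_components` scores.  Samples with `GH >= threshold` are flagged
#' as global H outliers.
#'
#' @param X Matrix of (pretreated) spectra.
#' @param n_components Number of principal components for the score space.
#' @param threshold Flagging threshold in standardized units (3.0 by
#'   convention).
#' @param ids Optional sample identifiers.
#' @return A tibble with columns `id`, `gh`, `flagged`; the fraction of
#'   spectral variance retained by the scores is attached as attribute
#'   `"variance_explained"`.
#' @export
global_h_outliers <- function(X, n_components = 10L, threshold = 3.0,
                              ids = NULL) {
  X <- as.matrix(X)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sdj <- apply(scores, 2L, stats::sd)
  sdj[sdj < 1e-12] <- 1
  gh <- rowMeans(sweep(scores, 2L, sdj, "/")^2)
  out <- tibble::tibble(
    id = if (is.null(ids)) as.character(seq_len(nrow(X))) else ids,
    gh = gh,
    flagged = gh >= threshold)
  attr(out, "variance_explained") <-
    sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  out
}

#' T-statistic chemical outliers
#'
#' Standardized absolute prediction residual `T = |y - y-hat| / scale`;
#' samples with `T >= threshold` (2.5 by convention) are flagged as
#' chemical outliers.
#'
#' @param y,y_hat Reference and predicted concentrations.
#' @param scale SEC-type error used as the denominator; must be positive.
#' @param threshold Flagging threshold.
#' @param ids Optional sample identifiers.
#' @return A tibble with columns `id`, `t`, `flagged`.
#' @export
t_outliers <- function(y, y_hat, scale, threshold = 2.5, ids = NULL) {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  t_val <- abs(y - y_hat) / scale
  tibble::tibble(
    id = if (is.null(ids)) as.character(seq_along(y)) else ids,
    t = t_val,
    flagged = t_val >= threshold)
}

#' Grouped cross-validation for factor selection
#'
#' Splits the calibration set into `n_groups` groups (contiguous blocks of
#' a seeded shuffle); each group is predicted from a model built on the
#' others, and held-out errors are pooled into
#' `SECV(k) = sqrt(sum(e^2) / n)` for every factor count up to
#' `max_factors`.  The chosen factor count minimizes SECV, ties going to
#' fewer factors.
#'
#' @param X,y Calibration spectra and reference values.
#' @param n_groups Number of cross-validation groups (4 by convention).
#' @param max_factors Largest factor count tried.
#' @param seed Seed for the group shuffle.
#' @return List with `secv` (tibble: `n_factors`, `secv`), `chosen`
#'   (selected factor count) and `cv_predictions` (held-out predictions at
#'   `chosen`, in input order).
#' @export
cross_validate <- function(X, y, n_groups = 4L, max_factors = 16L,
                           seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_groups < 2L) stop("n_groups must be >= 2", call. = FALSE)
  if (max_factors < 1L) stop("max_factors must be >= 1", call. = FALSE)
  if (floor(n / n_groups) < 2L) {
    stop("cross-validation groups would have fewer than 2 samples",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  # contiguous blocks of the shuffled order become the validation groups
  fold <- integer(n)
  fold[perm] <- rep(seq_len(n_groups), each = ceiling(n / n_groups),
                    length.out = n)
  K <- min(max_factors, n - floor(n / n_groups) - 1L, ncol(X))
  pred <- matrix(NA_real_, n, K)
  for (g in seq_len(n_groups)) {
    hold <- which(fold == g)
    fit <- fit_mpls(X[-hold, , drop = FALSE], y[-hold], K,
                    compute_beta = FALSE)
    pred[hold, ] <- predict_mpls(fit, X[hold, , drop = FALSE],
                                 all_factors = TRUE)
  }
  secv <- sqrt(colMeans((y - pred)^2))
  chosen <- which.min(secv)  # first minimum = fewest factors on ties
  list(secv = tibble::tibble(n_factors = seq_len(K), secv = secv),
       chosen = chosen,
       cv_predictions = pred[, chosen])
}

#' Calibration statistics
#'
#' The descriptors reported for a calibration equation: N, mean and SD of
#' the reference values, the estimated concentration range
#' `mean -/+ 3 SD` (clamped at 0), `SEC = sqrt(SSE / (N - k - 1))`,
#' SECV from the cross-validation residuals, RSQ, and `RPD = SD / SEC`.
#'
#' @param y Reference values (after outlier removal).
#' @param y_fit Calibration fitted values.
#' @param y_cv Cross-validation (held-out) predictions.
#' @param n_factors Number of MPLS factors in the equation.
#' @return One-row tibble: `n`, `mean`, `sd`, `min_est`, `max_est`, `sec`,
#'   `secv`, `rsq`, `rpd`.
#' @export
calibration_statistics <- function(y, y_fit, y_cv, n_factors) {
  n <- length(y)
  stopifnot(length(y_fit) == n, length(y_cv) == n, n > n_factors + 1L)
  e <- y - y_fit
  mu <- mean(y); sdv <- stats::sd(y)
  sec <- sqrt(sum(e^2) / (n - n_factors - 1L))
  rpd <- if (sec == 0) {
    warning("SEC is zero; RPD reported as Inf")
    Inf
  } else sdv / sec
  tibble::tibble(
    n = n, mean = mu, sd = sdv,
    min_est = max(0, mu - 3 * sdv),
    max_est = mu + 3 * sdv,
    sec = sec,
    secv = sqrt(mean((y - y_cv)^2)),
    rsq = 1 - sum(e^2) / sum((y - mu)^2),
    rpd = rpd)
}

#' External validation statistics
#'
#' Applies a calibration to an independent validation set and reports
#' `bias = mean(y-hat - y)`, `SEP = sqrt(mean((y-hat - y)^2))` (= RMSE),
#' the bias-corrected `SEP(C)`, RSQ of predicted vs reference, and the
#' two-sided paired Student t p-value comparing predictions with the
#' reference method.
#'
#' @param model An `mpls_model`.
#' @param X_val Validation spectra on the model's grid.
#' @param y_val Reference values for the validation set.
#' @return One-row tibble: `n`, `bias`, `sep`, `sep_c`, `rmse`, `rsq`,
#'   `p_paired_t`, `zero_variance` (flag: differences had no variance and
#'   p = 1 was reported by convention).
#' @export
external_validation <- function(model, X_val, y_val) {
  yhat <- predict_mpls(model, X_val)
  n <- length(y_val)
  if (n < 3L) stop("paired t-test needs at least 3 samples", call. = FALSE)
  d <- yhat - y_val
  bias <- mean(d)
  sep <- sqrt(mean(d^2))
  sep_c <- sqrt(sum((d - bias)^2) / (n - 1L))
  zero_var <- stats::sd(d) < 1e-12
  p <- if (zero_var) 1 else stats::t.test(yhat, y_val, paired = TRUE)$p.value
  tibble::tibble(
    n = n, bias = bias, sep = sep, sep_c = sep_c, rmse = sep,
    rsq = if (stats::sd(yhat) < 1e-12) NA_real_ else
      stats::cor(yhat, y_val)^2,
    p_paired_t = p,
    zero_variance = zero_var)
}

#' Wavelength-domain beta coefficients
#'
#' The calibration equation in the pretreated-spectrum domain,
#' `y = beta0 + sum_j beta_j x_(lambda_j)`; large |beta| wavelengths point
#' at the spectral regions carrying the metal information.
#'
#' @param model An `mpls_model` fitted with `compute_beta = TRUE`.
#' @return Tibble with columns `wavelength`, `beta`.
#' @export
beta_coefficients <- function(model) {
  stopifnot(inherits(model, "mpls_model"))
  if (is.null(model$beta)) stop("model was fitted without beta accumulation",
                                call. = FALSE)
  wl <- model$wavelengths
  if (is.null(wl) || anyNA(wl)) wl <- seq_along(model$beta)
  tibble::tibble(wavelength = wl, beta = model$beta)
}

#' @rdname beta_coefficients
#' @param n_peaks Number of top |beta| local peaks to return.
#' @return `beta_peaks()`: tibble of the ranked local |beta| maxima
#'   (`wavelength`, `beta`, `rank`).
#' @export
beta_peaks <- function(model, n_peaks = 2L) {
  bc <- beta_coefficients(model)
  b <- abs(bc$beta)
  p <- length(b)
  is_peak <- c(b[1] > b[2],
               b[2:(p - 1)] >= b[1:(p - 2)] & b[2:(p - 1)] >= b[3:p],
               b[p] > b[p - 1])
  peaks <- bc[is_peak, ]
  peaks <- peaks[order(-abs(peaks$beta)), ]
  peaks <- utils::head(peaks, n_peaks)
  peaks$rank <- seq_len(nrow(peaks))
  peaks
}

#' Full MPLS calibration protocol for one analyte
#'
#' The complete calibration pipeline: pretreat the spectra, remove global H
#' spectral outliers (Mahalanobis distance in 10-component score space,
#' threshold 3.0), then iterate (at most `t_passes` times) grouped
#' cross-validation for factor selection, MPLS fitting, and removal of
#' chemical outliers with standardized residual `T >= t_threshold`, and
#' report the final model with its calibration statistics and outlier log.
#'
#' @param table Calibration sample table with reference values.
#' @param analyte One of `"Al"`, `"Pb"`, `"As"`, `"Hg"`, `"Cu"`, or the
#'   name of any numeric column in `table`.
#' @param pretreatment Pretreatment code (string or parsed);
#'   `"Detrend (2,4,4,1)"` by default.
#' @param folds Number of cross-validation groups.
#' @param max_factors Largest factor count tried.
#' @param gh_components,gh_threshold Score-space dimension and threshold of
#'   the global H elimination.
#' @param t_threshold,t_passes T criterion threshold and maximum number of
#'   elimination passes.
#' @param seed Seed for the cross-validation group shuffle.
#' @return Object of class `tea_calibration`: `model` (`mpls_model`),
#'   `stats` (tibble, see [calibration_statistics()]), `outliers` (log of
#'   removed samples), `pretreat_state`, `analyte`, `n_factors`, `secv`
#'   profile.
#' @export
calibrate_full_protocol <- function(table, analyte,
                                    pretreatment = "Detrend (2,4,4,1)",
                                    folds = 4L, max_factors = 16L,
                                    gh_components = 10L, gh_threshold = 3.0,
                                    t_threshold = 2.5, t_passes = 2L,
                                    seed = 1L) {
  code <- parse_treatment_code(pretreatment)
  ycol <- if (analyte %in% names(metal_columns())) {
    metal_columns()[[analyte]]
  } else analyte
  if (!ycol %in% names(table)) {
    stop("no reference column for analyte ", analyte, call. = FALSE)
  }
  pre <- apply_pretreatment(table, code)
  X <- spectra_matrix(pre$table)
  y <- table[[ycol]]
  ids <- table$id
  n0 <- length(y)

  gh <- global_h_outliers(X, n_components = gh_components,
                          threshold = gh_threshold, ids = ids)
  keep <- !gh$flagged
  log <- tibble::tibble(id = gh$id[gh$flagged], stage = "global_H",
                        statistic = "GH", value = gh$gh[gh$flagged])
  X <- X[keep, , drop = FALSE]; y <- y[keep]; ids <- ids[keep]

  cv <- NULL
  fit <- NULL
  for (pass in seq_len(t_passes)) {
    cv <- cross_validate(X, y, n_groups = folds, max_factors = max_factors,
                         seed = seed)
    fit <- fit_mpls(X, y, cv$chosen, compute_beta = FALSE)
    sec <- sqrt(sum((y - fit$fitted)^2) /
                  (length(y) - cv$chosen - 1L))
    tt <- t_outliers(y, fit$fitted, sec, threshold = t_threshold, ids = ids)
    if (!any(tt$flagged)) break
    log <- dplyr::bind_rows(log, tibble::tibble(
      id = tt$id[tt$flagged], stage = paste0("T_pass_", pass),
      statistic = "T", value = tt$t[tt$flagged]))
    keep <- !tt$flagged
    X <- X[keep, , drop = FALSE]; y <- y[keep]; ids <- ids[keep]
    if (length(y) < n0 / 2) {
      stop("more than 50% of calibration samples removed as outliers",
           call. = FALSE)
    }
  }
  cv <- cross_validate(X, y, n_groups = folds, max_factors = max_factors,
                       seed = seed)
  fit <- fit_mpls(X, y, cv$chosen, compute_beta = TRUE)
  stats <- calibration_statistics(y, fit$fitted, cv$cv_predictions,
                                  cv$chosen)
  structure(
    list(model = fit, stats = stats, outliers = log,
         pretreat_state = pre$state, analyte = analyte,
         n_factors = cv$chosen, secv = cv$secv,
         calibration_ids = ids),
    class = "tea_calibration")
}

#' @export
print.tea_calibration <- function(x, ...) {
  cat("<MPLS calibration> analyte:", x$analyte,
      "| pretreatment:", format(x$pretreat_state$code),
      "| factors:", x$n_factors,
      "| outliers removed:", nrow(x$outliers), "\n")
  print(x$stats)
  invisible(x)
}

#' Serialize a calibration to JSON
#'
#' Writes the affine prediction model (effective grid, centers, beta
#' coefficients, factor scales) together with provenance (pretreatment
#' code, outlier log, statistics) to a JSON file.
#'
#' @param calibration A `tea_calibration`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(calibration, path) {
  m <- calibration$model
  payload <- list(
    analyte = calibration$analyte,
    pretreatment = format(calibration$pretreat_state$code),
    n_factors = m$n_factors,
    wavelengths = m$wavelengths,
    x_center = unname(m$x_center),
    y_center = m$y_center,
    beta0 = m$beta0,
    beta = unname(m$beta),
    stats = as.list(calibration$stats),
    outliers = calibration$outliers)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
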