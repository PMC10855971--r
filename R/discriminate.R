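#' Authentication grouping schemes
#'
#' Maps each sample to its class under one of the two authentication
#' designs: `"pure_vs_blends"` (6 groups: the three pure teas and the three
#' ">50 % blend" groups) or `"blend_percentage"` (12 groups: each tea at
#' purity >95 %, 95-85 %, 85-75 %, 75-50 %).  Bins are assigned on the
#' dominant fraction; an exact boundary value (95/85/75 %) goes to the
#' upper bin, and pure samples fall in the ">95 %" bin of the percentage
#' scheme.
#'
#' @param table A sample table with fraction columns.
#' @param scheme `"pure_vs_blends"` or `"blend_percentage"`.
#' @return `table` with an added factor column `group` whose levels are the
#'   scheme's ordered class labels.
#' @export
assign_groups <- function(table,
                          scheme = c("pure_vs_blends", "blend_percentage")) {
  scheme <- match.arg(scheme)
  fr <- as.matrix(table[, c("fraction_black", "fraction_red",
                            "fraction_green")])
  teas <- c("black", "red", "green")
  dom_i <- max.col(fr, ties.method = "first")
  dom <- teas[dom_i]
  pct <- 100 * fr[cbind(seq_len(nrow(fr)), dom_i)]
  if (any(pct < 50 - 1e-9)) {
    stop("dominant fraction below 50% is outside the blend design",
         call. = FALSE)
  }
  if (scheme == "pure_vs_blends") {
    levels <- c(paste(teas, "pure"), paste(teas, "blends"))
    lab <- ifelse(pct >= 100 - 1e-9, paste(dom, "pure"),
                  paste(dom, "blends"))
  } else {
    bins <- c(">95%", "95-85%", "85-75%", "75-50%")
    levels <- as.vector(t(outer(teas, bins, function(t, b) paste(b, t))))
    # ">95%" is strict; the interior boundaries 85/75 go to the upper bin
    bin <- ifelse(pct > 95 + 1e-9, bins[1],
                  ifelse(pct >= 85 - 1e-9, bins[2],
                         ifelse(pct >= 75 - 1e-9, bins[3], bins[4])))
    lab <- paste(bin, dom)
  }
  out <- table
  out$group <- factor(lab, levels = levels)
  out
}

# extract spectra + group factor, common entry of the classifiers
.class_data <- function(table, group_col = "group") {
  if (!group_col %in% names(table)) {
    stop("no '", group_col, "' column; run assign_groups() first",
         call. = FALSE)
  }
  g <- table[[group_col]]
  if (!is.factor(g)) g <- factor(g)
  list(X = spectra_matrix(table), group = droplevels(g),
       ids = if ("id" %in% names(table)) table$id else
         as.character(seq_len(nrow(table))))
}

#' Number of principal components retained by the eigenvalue-greater-
#' than-one rule
#'
#' Eigenvalues are normalized to mean 1 (the correlation-matrix scale when
#' variables are standardized); components with normalized eigenvalue > 1
#' are retained, with a floor of one component.
#'
#' @param eigenvalues Positive eigenvalues of a class covariance/
#'   correlation structure.
#' @param cap Optional upper bound on the retained count.
#' @return Integer count of retained components.
#' @export
retain_components <- function(eigenvalues, cap = Inf) {
  ev <- eigenvalues[eigenvalues > 1e-12]
  k <- sum(ev * length(ev) / sum(ev) > 1)
  max(1L, min(as.integer(k), cap))
}

#' SIMCA class modelling
#'
#' Soft independent modelling of class analogy on the full spectrum.  The
#' data are normalized (per-spectrum SNV), column-scaled, and mean-centered
#' using statistics of the training set; each class then gets its own PCA
#' subspace with components retained by the eigenvalue > 1 rule (capped so
#' a residual subspace remains) and an F-type critical limit (alpha = 0.05)
#' on the standardized residual distance.
#'
#' @param table Sample table with a `group` column (see [assign_groups()]).
#' @param group_col Name of the class column.
#' @param alpha Significance level of the residual-distance limit.
#' @return Object of class `simca_model`.
#' @export
fit_simca <- function(table, group_col = "group", alpha = 0.05) {
  d <- .class_data(table, group_col)
  counts <- base::table(d$group)
  if (any(counts < 3L)) {
    stop("SIMCA needs >= 3 samples per class; short: ",
         paste(names(counts)[counts < 3L], collapse = ", "), call. = FALSE)
  }
  Xn <- .snv_mat(d$X, ids = d$ids)
  col_center <- colMeans(Xn)
  col_scale <- apply(Xn, 2L, stats::sd)
  col_scale[col_scale < 1e-12] <- 1
  Z <- sweep(sweep(Xn, 2L, col_center), 2L, col_scale, "/")
  p <- ncol(Z)
  classes <- levels(d$group)
  per_class <- lapply(classes, function(cl) {
    Zi <- Z[d$group == cl, , drop = FALSE]
    ni <- nrow(Zi)
    ctr <- colMeans(Zi)
    R <- sweep(Zi, 2L, ctr)
    pc <- stats::prcomp(R, center = FALSE)
    ev <- pc$sdev^2
    k <- retain_components(ev, cap = max(1L, ni - 2L))
    V <- pc$rotation[, seq_len(k), drop = FALSE]
    resid <- R - (R %*% V) %*% t(V)
    rss <- rowSums(resid^2)
    df_i <- p - k
    df_0 <- (ni - k - 1L) * (p - k)
    s0_sq <- sum(rss) / df_0
    list(center = ctr, loadings = V, k = k, s0_sq = s0_sq,
         f_crit = stats::qf(1 - alpha, df_i, df_0), n = ni)
  })
  names(per_class) <- classes
  structure(list(classes = classes, per_class = per_class,
                 col_center = col_center, col_scale = col_scale,
                 alpha = alpha, p = p),
            class = "simca_model")
}

#' Classify spectra with a SIMCA model
#'
#' Assigns each sample to the class with the smallest standardized residual
#' distance; samples whose distance exceeds every class's critical limit
#' are flagged `"no class"`.
#'
#' @param model A `simca_model`.
#' @param table Sample table on the training grid.
#' @return Tibble with columns `id`, `predicted` (character; possibly
#'   `"no class"`), and one `dist_<class>` column per class (standardized
#'   residual distance ratios).
#' @export
classify_simca <- function(model, table) {
  X <- spectra_matrix(table)
  if (ncol(X) != model$p) {
    stop("spectra are not on the model's grid", call. = FALSE)
  }
  ids <- if ("id" %in% names(table)) table$id else
    as.character(seq_len(nrow(X)))
  Xn <- .snv_mat(X, ids = ids)
  Z <- sweep(sweep(Xn, 2L, model$col_center), 2L, model$col_scale, "/")
  C <- length(model$classes)
  dist <- matrix(NA_real_, nrow(Z), C,
                 dimnames = list(NULL, model$classes))
  inside <- matrix(FALSE, nrow(Z), C)
  for (j in seq_len(C)) {
    pc <- model$per_class[[j]]
    R <- sweep(Z, 2L, pc$center)
    resid <- R - (R %*% pc$loadings) %*% t(pc$loadings)
    s_sq <- rowSums(resid^2) / (model$p - pc$k)
    f_ratio <- s_sq / pc$s0_sq
    dist[, j] <- sqrt(f_ratio)
    inside[, j] <- f_ratio < pc$f_crit
  }
  predicted <- model$classes[max.col(-dist, ties.method = "first")]
  predicted[rowSums(inside) == 0L] <- "no class"
  out <- tibble::tibble(id = ids, predicted = predicted)
  dd <- tibble::as_tibble(as.data.frame(dist))
  names(dd) <- paste0("dist_", model$classes)
  dplyr::bind_cols(out, dd)
}

# first left singular vector of crossprod(X, Y)
.first_left_sv <- function(XtY) {
  sv <- svd(XtY, nu = 1L, nv = 0L)
  drop(sv$u)
}

# NIPALS PLS2 on centered X, Y
.pls2 <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); Tm <- matrix(0, n, ncomp)
  Xr <- X; Yr <- Y
  for (a in seq_len(ncomp)) {
    u <- Yr[, which.max(colSums(Yr^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xr, u)); w <- w / sqrt(sum(w^2))
      t_a <- drop(Xr %*% w)
      q <- drop(crossprod(Yr, t_a)) / sum(t_a^2)
      u <- drop(Yr %*% q) / sum(q^2)
      if (sqrt(sum((t_a - t_old)^2)) < tol * sqrt(sum(t_a^2))) break
      t_old <- t_a
    }
    p_a <- drop(crossprod(Xr, t_a)) / sum(t_a^2)
    Xr <- Xr - tcrossprod(t_a, p_a)
    Yr <- Yr - tcrossprod(t_a, q)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q; Tm[, a] <- t_a
  }
  list(W = W, P = P, Q = Q, T = Tm, X_res = Xr, Y_res = Yr)
}

# orthogonal-signal filter: removes ncomp_orth components of X variation
# uncorrelated with Y (Trygg-Wold O-PLS); returns filtered X and the
# orthogonal weights/loadings for reuse on new data
.opls_filter <- function(X, Y, ncomp_orth) {
  p <- ncol(X)
  W_o <- matrix(0, p, max(ncomp_orth, 1L))
  P_o <- matrix(0, p, max(ncomp_orth, 1L))
  T_o <- matrix(0, nrow(X), max(ncomp_orth, 1L))
  Xr <- X
  if (ncomp_orth >= 1L) {
    for (a in seq_len(ncomp_orth)) {
      w <- .first_left_sv(crossprod(Xr, Y))
      t_w <- drop(Xr %*% w)
      p_w <- drop(crossprod(Xr, t_w)) / sum(t_w^2)
      w_o <- p_w - sum(w * p_w) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-12) break
      w_o <- w_o / nw
      t_o <- drop(Xr %*% w_o)
      p_o <- drop(crossprod(Xr, t_o)) / sum(t_o^2)
      Xr <- Xr - tcrossprod(t_o, p_o)
      W_o[, a] <- w_o; P_o[, a] <- p_o; T_o[, a] <- t_o
    }
  }
  list(X_filtered = Xr, W_o = W_o, P_o = P_o, T_o = T_o)
}

.opls_filter_apply <- function(Xc, W_o, P_o, ncomp_orth) {
  if (ncomp_orth >= 1L) {
    for (a in seq_len(ncomp_orth)) {
      t_o <- drop(Xc %*% W_o[, a])
      Xc <- Xc - tcrossprod(t_o, P_o[, a])
    }
  }
  Xc
}

#' OPLS-DA class discrimination
#'
#' Orthogonal projections to latent structures discriminant analysis:
#' class-orthogonal spectral variation (uncorrelated with the one-hot class
#' encoding) is removed, then a PLS2 discriminant model is fitted on the
#' filtered spectra.  Reports R2X (fraction of spectral variance modelled),
#' R2 (class-encoding variance explained), and Q2 by grouped
#' cross-validation of the whole pipeline (7 folds by convention).
#'
#' @param table Sample table with a `group` column.
#' @param group_col Name of the class column.
#' @param n_predictive,n_orthogonal Numbers of predictive and orthogonal
#'   components (2 and 2 by convention).
#' @param q2_folds Folds of the Q2 cross-validation.
#' @param seed Seed for the Q2 fold shuffle.
#' @return Object of class `oplsda_model` with fit metrics `r2x`, `r2`,
#'   `q2`, scores, and the fitted projection.
#' @export
fit_oplsda <- function(table, group_col = "group", n_predictive = 2L,
                       n_orthogonal = 2L, q2_folds = 7L, seed = 1L) {
  d <- .class_data(table, group_col)
  classes <- levels(d$group)
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  Y <- stats::model.matrix(~ 0 + d$group)
  colnames(Y) <- classes
  n <- nrow(d$X)
  if (n_predictive + n_orthogonal > min(n - 1L, ncol(d$X))) {
    stop("component count exceeds the data rank", call. = FALSE)
  }
  x_center <- colMeans(d$X)
  y_center <- colMeans(Y)
  Xc <- sweep(d$X, 2L, x_center)
  Yc <- sweep(Y, 2L, y_center)
  of <- .opls_filter(Xc, Yc, n_orthogonal)
  pls <- .pls2(of$X_filtered, Yc, n_predictive)
  ssx <- sum(Xc^2)
  ssx_res <- sum(pls$X_res^2)
  ssy <- sum(Yc^2)
  Yhat <- Yc - pls$Y_res
  r2 <- 1 - sum(pls$Y_res^2) / ssy
  r2x <- 1 - ssx_res / ssx  # predictive + orthogonal components jointly

  # Q2: grouped CV of the full filter + PLS2 pipeline
  set.seed(as.integer(seed))
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(q2_folds), length.out = n)
  press <- 0
  for (g in seq_len(q2_folds)) {
    hold <- which(fold == g)
    if (length(hold) == 0L) next
    Xt <- d$X[-hold, , drop = FALSE]; Yt <- Y[-hold, , drop = FALSE]
    xc <- colMeans(Xt); yc <- colMeans(Yt)
    Xtc <- sweep(Xt, 2L, xc); Ytc <- sweep(Yt, 2L, yc)
    oft <- .opls_filter(Xtc, Ytc, n_orthogonal)
    plst <- .pls2(oft$X_filtered, Ytc, n_predictive)
    Xh <- sweep(d$X[hold, , drop = FALSE], 2L, xc)
    Xh <- .opls_filter_apply(Xh, oft$W_o, oft$P_o, n_orthogonal)
    # project through the PLS2 factors
    Yp <- matrix(rep(yc, each = length(hold)), ncol = ncol(Y))
    Xr <- Xh
    for (a in seq_len(n_predictive)) {
      t_a <- drop(Xr %*% plst$W[, a])
      Yp <- Yp + tcrossprod(t_a, plst$Q[, a])
      Xr <- Xr - tcrossprod(t_a, plst$P[, a])
    }
    press <- press + sum((Y[hold, , drop = FALSE] - Yp)^2)
  }
  q2 <- 1 - press / ssy

  structure(
    list(classes = classes, x_center = x_center, y_center = y_center,
         W_o = of$W_o, P_o = of$P_o, T_o = of$T_o,
         W = pls$W, P = pls$P, Q = pls$Q, T_pred = pls$T,
         n_predictive = n_predictive, n_orthogonal = n_orthogonal,
         r2x = r2x, r2 = r2, q2 = q2,
         Y_encoding = Yc),
    class = "oplsda_model")
}

#' Classify spectra with an OPLS-DA model
#'
#' @param model An `oplsda_model`.
#' @param table Sample table on the training grid.
#' @return Tibble with `id`, `predicted`, and one `score_<class>` column
#'   of predicted class-encoding values per class.
#' @export
classify_oplsda <- function(model, table) {
  X <- spectra_matrix(table)
  if (ncol(X) != length(model$x_center)) {
    stop("spectra are not on the model's grid", call. = FALSE)
  }
  ids <- if ("id" %in% names(table)) table$id else
    as.character(seq_len(nrow(X)))
  Xc <- sweep(X, 2L, model$x_center)
  Xc <- .opls_filter_apply(Xc, model$W_o, model$P_o, model$n_orthogonal)
  Yp <- matrix(rep(model$y_center, each = nrow(X)),
               ncol = length(model$classes))
  for (a in seq_len(model$n_predictive)) {
    t_a <- drop(Xc %*% model$W[, a])
    Yp <- Yp + tcrossprod(t_a, model$Q[, a])
    Xc <- Xc - tcrossprod(t_a, model$P[, a])
  }
  predicted <- model$classes[max.col(Yp, ties.method = "first")]
  out <- tibble::tibble(id = ids, predicted = predicted)
  sc <- tibble::as_tibble(as.data.frame(Yp))
  names(sc) <- paste0("score_", model$classes)
  dplyr::bind_cols(out, sc)
}

#' RMS-X residual class modelling
#'
#' Stores, per class, the mean pretreated spectrum and the within-class
#' distribution of the RMS-X residual — the quadratic mean
#' `RMS_c(x) = sqrt(mean_j (x_j - m_cj)^2)` of a sample's deviation from
#' the class mean over the effective wavelengths.
#'
#' @param table Sample table with a `group` column.
#' @param pretreatment Pretreatment code applied before modelling
#'   (`"Detrend (2,4,4,1)"` by default).
#' @param group_col Name of the class column.
#' @param limit_multiplier `k` of the per-class decision limit
#'   `mean + k * SD` of the training RMS values.
#' @return Object of class `rmsx_model` with the class means, per-class RMS
#'   statistics (`rms_mean`, `rms_sd`, `rms_scale` — the quadratic mean —
#'   and `limit`), and the pretreatment state.
#' @export
fit_rmsx <- function(table, pretreatment = "Detrend (2,4,4,1)",
                     group_col = "group", limit_multiplier = 4) {
  code <- parse_treatment_code(pretreatment)
  d0 <- .class_data(table, group_col)
  counts <- base::table(d0$group)
  if (any(counts < 2L)) {
    stop("RMS-X needs >= 2 samples per class; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  pre <- apply_pretreatment(table, code)
  X <- spectra_matrix(pre$table)
  classes <- levels(d0$group)
  means <- t(vapply(classes, function(cl)
    colMeans(X[d0$group == cl, , drop = FALSE]), numeric(ncol(X))))
  rms_train <- sqrt(rowMeans((X - means[as.integer(d0$group), ,
                                        drop = FALSE])^2))
  stats <- tibble::tibble(
    class = classes,
    n = as.integer(counts[classes]),
    rms_mean = vapply(classes, function(cl)
      mean(rms_train[d0$group == cl]), 0),
    rms_sd = vapply(classes, function(cl)
      stats::sd(rms_train[d0$group == cl]), 0),
    rms_scale = vapply(classes, function(cl)
      sqrt(mean(rms_train[d0$group == cl]^2)), 0))
  stats$limit <- stats$rms_mean + limit_multiplier * stats$rms_sd
  structure(
    list(classes = classes, class_means = means,
         wavelengths = table_wavelengths(pre$table),
         class_stats = stats, pretreat_state = pre$state,
         limit_multiplier = limit_multiplier),
    class = "rmsx_model")
}

#' Classify spectra by RMS-X residual distance
#'
#' Each sample is assigned to the class minimizing its RMS-X residual.
#' Under the default rule, a sample whose smallest RMS falls inside that
#' class's decision limit (the stored within-class `mean + k * SD`) is a
#' typical member and is assigned there directly; a sample outside the
#' limit of its raw-nearest class does not look like a replicate
#' measurement of it, and is instead assigned to the class minimizing the
#' RMS divided by the class's within-class quadratic-mean RMS, so that
#' tight classes — the pure teas — cannot claim samples more distant than
#' their own replicate spread.  `rule = "raw"` always takes the plain
#' argmin; `rule = "standardized"` always judges on class scales.  Ties
#' are broken by class order with a warning.
#'
#' @param model An `rmsx_model`.
#' @param table Sample table (raw spectra; the model's pretreatment is
#'   applied internally).
#' @param rule `"auto"` (default), `"raw"`, or `"standardized"`.
#' @return Tibble with `id`, `predicted`, and one `rms_<class>` column of
#'   raw RMS residuals per class.
#' @export
classify_rmsx <- function(model, table,
                          rule = c("auto", "raw", "standardized")) {
  rule <- match.arg(rule)
  pre <- apply_pretreatment(table, model$pretreat_state$code,
                            state = model$pretreat_state)
  X <- spectra_matrix(pre$table)
  if (ncol(X) != ncol(model$class_means)) {
    stop("spectra are not on the model's effective grid", call. = FALSE)
  }
  ids <- if ("id" %in% names(table)) table$id else
    as.character(seq_len(nrow(X)))
  C <- length(model$classes)
  rms <- matrix(0, nrow(X), C, dimnames = list(NULL, model$classes))
  for (j in seq_len(C)) {
    rms[, j] <- sqrt(rowMeans(sweep(X, 2L, model$class_means[j, ])^2))
  }
  # a new sample's expected squared distance to a class mean estimated from
  # n members is (n+1)/(n-1) times a member's in-sample one; judge new
  # spectra against the corrected scale so small classes are not spuriously
  # tight
  n_c <- model$class_stats$n
  infl <- sqrt((n_c + 1) / pmax(n_c - 1, 1))
  scale_new <- model$class_stats$rms_scale * infl
  limit_new <- model$class_stats$limit * infl
  z <- sweep(rms, 2L, scale_new, "/")
  mins <- apply(rms, 1L, min)
  n_min <- rowSums(abs(rms - mins) < 1e-12)
  if (any(n_min > 1L)) {
    warning(sum(n_min > 1L),
            " sample(s) equidistant from several classes; ",
            "assigned to the first class in order")
  }
  raw_pick <- max.col(-rms, ties.method = "first")
  std_pick <- max.col(-z, ties.method = "first")
  pick <- switch(rule,
    raw = raw_pick,
    standardized = std_pick,
    auto = {
      inside <- rms[cbind(seq_len(nrow(rms)), raw_pick)] <=
        limit_new[raw_pick]
      ifelse(inside, raw_pick, std_pick)
    })
  out <- tibble::tibble(id = ids, predicted = model$classes[pick])
  dd <- tibble::as_tibble(as.data.frame(rms))
  names(dd) <- paste0("rms_", model$classes)
  dplyr::bind_cols(out, dd)
}

#' Per-class classification metrics
#'
#' Sensitivity (proportion of a class's samples correctly identified),
#' specificity (proportion of foreign samples correctly not assigned to the
#' class), the per-class percentage correctly classified (sensitivity x
#' 100), and overall accuracy.  Predictions outside the class set (e.g.
#' SIMCA's `"no class"`) count as misclassifications.
#'
#' @param true,predicted Aligned label vectors.
#' @param classes Ordered class labels; defaults to the levels of `true`.
#' @return Object of class `confusion_report`: tibble `by_class` (`class`,
#'   `n`, `pct_correct`, `sensitivity`, `specificity`), `overall` accuracy
#'   (proportion), and the raw confusion `counts`.
#' @export
confusion_metrics <- function(true, predicted, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (is.factor(true)) levels(droplevels(true)) else
      sort(unique(as.character(true)))
  }
  true <- as.character(true)
  predicted <- as.character(predicted)
  stopifnot(length(true) == length(predicted))
  if (!all(true %in% classes)) {
    stop("true labels outside the class set", call. = FALSE)
  }
  by_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(true == cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    fp <- sum(true != cl & predicted == cl)
    tn <- sum(true != cl & predicted != cl)
    tibble::tibble(
      class = cl, n = tp + fn,
      pct_correct = if (tp + fn == 0L) NA_real_ else 100 * tp / (tp + fn),
      sensitivity = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0L) NA_real_ else tn / (tn + fp))
  })
  counts <- table(factor(true, levels = classes),
                  factor(predicted, levels = unique(c(classes,
                                                      predicted))))
  structure(list(by_class = by_class,
                 overall = mean(true == predicted),
                 counts = counts),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("<confusion report> overall accuracy %.2f%%\n",
              100 * x$overall))
  print(x$by_class)
  invisible(x)
}
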