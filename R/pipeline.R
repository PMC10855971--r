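#' One-way ANOVA with Tukey HSD letter codes
#'
#' Group comparison in the style of composition tables: per-group mean and
#' SD, the one-way ANOVA F test, Tukey honest significant difference
#' pairwise comparisons, and a compact letter display (groups sharing a
#' letter do not differ significantly at `alpha`), assembled greedily from
#' the non-significant pairs.
#'
#' @param data A data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param alpha Significance level.
#' @return A tibble (`group`, `n`, `mean`, `sd`, `letters`) with the ANOVA
#'   `F` statistic and `p` value as attributes `"F"` and `"p"`.
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(base::table(g) < 2L)) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (all(vapply(split(y, g), stats::sd, 0) < 1e-12)) {
    stop("zero within-group variance in every group", call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  a <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  sig <- tk[, "p adj"] < alpha

  # greedy insert-and-absorb compact letter display
  lv <- levels(g)
  cols <- list(lv)
  for (i in which(sig)) {
    pr <- pairs[i, ]
    for (ci in rev(seq_along(cols))) {
      if (all(pr %in% cols[[ci]])) {
        s <- cols[[ci]]
        cols[[ci]] <- setdiff(s, pr[1])
        cols <- append(cols, list(setdiff(s, pr[2])))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) {
      for (cj in seq_along(cols)) {
        if (ci != cj && keep[cj] &&
            all(cols[[ci]] %in% cols[[cj]]) &&
            !(all(cols[[cj]] %in% cols[[ci]]) && ci < cj)) {
          if (length(cols[[ci]]) < length(cols[[cj]]) ||
              (length(cols[[ci]]) == length(cols[[cj]]) && ci > cj)) {
            keep[ci] <- FALSE
          }
        }
      }
    }
    cols <- cols[keep]
  }
  means <- vapply(split(y, g), mean, 0)
  ord <- order(vapply(cols, function(s) min(means[s]), 0))
  cols <- cols[ord]
  letters_by_group <- vapply(lv, function(l) {
    paste0(letters[which(vapply(cols, function(s) l %in% s, TRUE))],
           collapse = "")
  }, "")
  out <- tibble::tibble(
    group = lv,
    n = as.integer(base::table(g)[lv]),
    mean = means[lv],
    sd = vapply(split(y, g), stats::sd, 0)[lv],
    letters = letters_by_group)
  attr(out, "F") <- a[["F value"]][1]
  attr(out, "p") <- a[["Pr(>F)"]][1]
  out
}

#' Table-1-style group comparison of the metal contents
#'
#' Runs [anova_tukey()] for each of the five analytes over the tea classes
#' of a pure-sample table.
#'
#' @param table A sample table of pure samples.
#' @param alpha Significance level.
#' @return Tibble with one row per class and metal: `metal`, `class`, `n`,
#'   `mean`, `sd`, `letters`, `p_anova`.
#' @export
compare_metals_by_class <- function(table, alpha = 0.05) {
  cols <- metal_columns()
  purrr::map_dfr(names(cols), function(m) {
    r <- anova_tukey(table, cols[[m]], "class", alpha = alpha)
    tibble::tibble(metal = m, class = r$group, n = r$n, mean = r$mean,
                   sd = r$sd, letters = r$letters,
                   p_anova = attr(r, "p"))
  })
}

#' Exploratory PCA of the metal composition
#'
#' Principal component analysis of the per-sample concentration table with
#' autoscaling (each analyte centered and scaled to unit SD), used to see
#' which metals separate the tea types.
#'
#' @param table A sample table (typically pure samples only).
#' @param autoscale Center and scale the columns before decomposition.
#' @return Object of class `tea_pca`: `scores` (tibble with `id`, `class`,
#'   `PC1`, ...), `loadings` (tibble with `metal`, `PC1`, ...), and
#'   `variance_fraction`.
#' @export
exploratory_pca <- function(table, autoscale = TRUE) {
  cols <- metal_columns()
  M <- as.matrix(table[, cols])
  colnames(M) <- names(cols)
  if (autoscale && any(apply(M, 2L, stats::sd) < 1e-12)) {
    stop("constant concentration column; cannot autoscale", call. = FALSE)
  }
  if (nrow(M) < 3L) stop("need at least 3 samples", call. = FALSE)
  pc <- stats::prcomp(M, center = TRUE, scale. = autoscale)
  scores <- tibble::as_tibble(as.data.frame(pc$x))
  scores <- dplyr::bind_cols(
    tibble::tibble(id = table$id, class = table$class), scores)
  loadings <- dplyr::bind_cols(
    tibble::tibble(metal = rownames(pc$rotation)),
    tibble::as_tibble(as.data.frame(pc$rotation)))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2)),
            class = "tea_pca")
}

#' @export
print.tea_pca <- function(x, ...) {
  vf <- 100 * x$variance_fraction
  cat(sprintf("<metal-composition PCA> PC1 %.1f%%, PC2 %.1f%% of variance\n",
              vf[1], vf[2]))
  invisible(x)
}

#' Experiment configuration
#'
#' Bundles every setting of an end-to-end run so that reports carry full
#' provenance and two runs with equal configs are identical.
#'
#' @param seed Master seed: drives the generator, the 80/20 split, and the
#'   cross-validation shuffles.
#' @param generator A [generator_config()]; defaults to one seeded by
#'   `seed`.
#' @param analytes Analytes to calibrate.
#' @param pretreatment Pretreatment code used throughout.
#' @param cal_fraction Calibration share of the split.
#' @param folds Cross-validation groups.
#' @param max_factors Largest MPLS factor count tried.
#' @param scheme Grouping scheme for discrimination.
#' @param methods Discrimination methods to run (`"rmsx"`, `"simca"`,
#'   `"oplsda"`).
#' @return A list of class `tea_experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              generator = generator_config(seed = seed),
                              analytes = c("Al", "Pb", "As", "Hg", "Cu"),
                              pretreatment = "Detrend (2,4,4,1)",
                              cal_fraction = 0.8,
                              folds = 4L,
                              max_factors = 16L,
                              scheme = "pure_vs_blends",
                              methods = "rmsx") {
  stopifnot(inherits(generator, "tea_generator_config"),
            cal_fraction > 0, cal_fraction < 1, folds >= 2L,
            all(analytes %in% names(metal_columns())),
            all(methods %in% c("rmsx", "simca", "oplsda")))
  structure(list(seed = as.integer(seed), generator = generator,
                 analytes = analytes,
                 pretreatment = format(parse_treatment_code(pretreatment)),
                 cal_fraction = cal_fraction, folds = as.integer(folds),
                 max_factors = as.integer(max_factors),
                 scheme = scheme, methods = methods),
            class = "tea_experiment_config")
}

#' Run the full quantification experiment
#'
#' Simulate the library (or use a supplied one), split into calibration and
#' validation sets, run the full calibration protocol per analyte, and
#' validate externally: the complete workflow behind a calibration/
#' validation report.
#'
#' @param config A [experiment_config()].
#' @param library_table Optional pre-generated sample table (defaults to
#'   `generate_tea_library(config$generator)`).
#' @return Object of class `quantification_report`: `calibration` (one row
#'   per analyte: N, mean, SD, estimated range, SEC, SECV, RSQ, RPD,
#'   factors, outliers removed), `validation` (per analyte: SEP, SEP(C),
#'   bias, RSQ, RMSE, paired-t p), `outliers`, `models`, and the resolved
#'   `config`.
#' @export
run_quantification_experiment <- function(config = experiment_config(),
                                          library_table = NULL) {
  stopifnot(inherits(config, "tea_experiment_config"))
  if (is.null(library_table)) {
    library_table <- generate_tea_library(config$generator)
  }
  sets <- split_sets(library_table, cal_fraction = config$cal_fraction,
                     seed = config$seed)
  cols <- metal_columns()
  models <- list()
  cal_rows <- list(); val_rows <- list(); out_rows <- list()
  for (a in config$analytes) {
    cal <- calibrate_full_protocol(
      sets$calibration, a, pretreatment = config$pretreatment,
      folds = config$folds, max_factors = config$max_factors,
      seed = config$seed)
    pre_val <- apply_pretreatment(sets$validation,
                                  cal$pretreat_state$code,
                                  state = cal$pretreat_state)
    val <- external_validation(cal$model, spectra_matrix(pre_val$table),
                               sets$validation[[cols[[a]]]])
    models[[a]] <- cal
    cal_rows[[a]] <- dplyr::bind_cols(
      tibble::tibble(analyte = a), cal$stats,
      tibble::tibble(n_factors = cal$n_factors,
                     n_outliers = nrow(cal$outliers)))
    val_rows[[a]] <- dplyr::bind_cols(tibble::tibble(analyte = a), val)
    if (nrow(cal$outliers) > 0) {
      out_rows[[a]] <- dplyr::bind_cols(tibble::tibble(analyte = a),
                                        cal$outliers)
    }
  }
  structure(list(calibration = dplyr::bind_rows(cal_rows),
                 validation = dplyr::bind_rows(val_rows),
                 outliers = dplyr::bind_rows(out_rows),
                 models = models, config = config),
            class = "quantification_report")
}

#' @export
print.quantification_report <- function(x, ...) {
  cat("<quantification report>\ncalibration:\n")
  print(x$calibration)
  cat("external validation:\n")
  print(x$validation)
  invisible(x)
}

#' Run the discrimination experiment
#'
#' Simulate (or use a supplied library), split 80/20, assign the grouping
#' scheme, fit each requested classifier on the training set, and report
#' per-class calibration and validation classification metrics.
#'
#' @inheritParams run_quantification_experiment
#' @return Object of class `discrimination_report`: `results` (one row per
#'   method and class with calibration/validation % correct, sensitivity,
#'   specificity), `overall` (per method), the fitted `models`, and the
#'   resolved `config`.
#' @export
run_discrimination_experiment <- function(config = experiment_config(),
                                          library_table = NULL) {
  stopifnot(inherits(config, "tea_experiment_config"))
  if (is.null(library_table)) {
    library_table <- generate_tea_library(config$generator)
  }
  sets <- split_sets(library_table, cal_fraction = config$cal_fraction,
                     seed = config$seed)
  cal <- assign_groups(sets$calibration, config$scheme)
  val <- assign_groups(sets$validation, config$scheme)
  results <- list(); overall <- list(); models <- list()
  for (m in config$methods) {
    if (m == "rmsx") {
      fit <- fit_rmsx(cal, pretreatment = config$pretreatment)
      pred_cal <- classify_rmsx(fit, cal)
      pred_val <- classify_rmsx(fit, val)
    } else if (m == "simca") {
      fit <- fit_simca(cal)
      pred_cal <- classify_simca(fit, cal)
      pred_val <- classify_simca(fit, val)
    } else {
      fit <- fit_oplsda(cal, seed = config$seed)
      pred_cal <- classify_oplsda(fit, cal)
      pred_val <- classify_oplsda(fit, val)
    }
    classes <- levels(cal$group)
    cm_cal <- confusion_metrics(cal$group, pred_cal$predicted, classes)
    cm_val <- confusion_metrics(val$group, pred_val$predicted, classes)
    merged <- dplyr::full_join(
      dplyr::rename(cm_cal$by_class, n_cal = "n",
                    pct_correct_cal = "pct_correct",
                    sensitivity_cal = "sensitivity",
                    specificity_cal = "specificity"),
      dplyr::rename(cm_val$by_class, n_val = "n",
                    pct_correct_val = "pct_correct",
                    sensitivity_val = "sensitivity",
                    specificity_val = "specificity"),
      by = "class")
    results[[m]] <- dplyr::bind_cols(tibble::tibble(method = m), merged)
    overall[[m]] <- tibble::tibble(
      method = m,
      accuracy_cal = 100 * cm_cal$overall,
      accuracy_val = 100 * cm_val$overall)
    models[[m]] <- fit
  }
  structure(list(results = dplyr::bind_rows(results),
                 overall = dplyr::bind_rows(overall),
                 models = models, config = config,
                 scheme = config$scheme),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("<discrimination report> scheme:", x$scheme, "\n")
  print(x$overall)
  print(x$results)
  invisible(x)
}
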