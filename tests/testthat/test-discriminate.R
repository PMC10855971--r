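make_group_table <- function(n_per_class = 8, delta = 5, p = 20, sd = 0.1,
                             seed = 31, classes = c("A", "B")) {
  set.seed(seed)
  # class means differ in shape (phase-shifted waves), not just offset, so
  # the separation survives per-spectrum normalization
  rows <- lapply(seq_along(classes), function(k) {
    mu <- delta * sin(2 * pi * seq_len(p) / p + k)
    matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p) +
      matrix(mu, n_per_class, p, byrow = TRUE)
  })
  tab <- toy_table(do.call(rbind, rows))
  tab$group <- factor(rep(classes, each = n_per_class), levels = classes)
  tab
}

test_that("grouping schemes bin samples by dominant fraction", {
  tab <- tibble::tibble(
    id = as.character(1:5),
    fraction_black = c(1, 0, 0.04, 0.15, 0.55),
    fraction_green = c(0, 0.96, 0, 0, 0.45),
    fraction_red = c(0, 0.04, 0.96, 0.85, 0))
  g6 <- assign_groups(tab, "pure_vs_blends")
  expect_equal(as.character(g6$group)[1], "black pure")
  expect_equal(as.character(g6$group)[2], "green blends")
  expect_equal(nlevels(g6$group), 6L)
  g12 <- assign_groups(tab, "blend_percentage")
  expect_equal(as.character(g12$group),
               c(">95% black", ">95% green", ">95% red",
                 "95-85% red",  # boundary 85 goes to the upper bin
                 "75-50% black"))
  expect_equal(nlevels(g12$group), 12L)
  # a pure sample lands in the >95% bin of the percentage scheme
  expect_equal(as.character(g12$group)[1], ">95% black")
  bad <- tibble::tibble(id = "x", fraction_black = 0.4,
                        fraction_green = 0.3, fraction_red = 0.3)
  expect_error(assign_groups(bad), "outside the blend design")
})

test_that("eigenvalue > 1 retention uses the correlation scale", {
  expect_equal(retain_components(c(2.1, 0.6, 0.3)), 1L)
  expect_equal(retain_components(c(3, 2, 0.5, 0.3, 0.2)), 2L)
  # floor of one component even when nothing passes
  expect_equal(retain_components(c(1, 1, 1)), 1L)
  expect_equal(retain_components(c(5, 4, 0.5, 0.5)), 2L)
  expect_equal(retain_components(c(6, 5, 4, 0.1), cap = 2L), 2L)
})

test_that("SIMCA separates far classes and flags alien spectra", {
  tab <- make_group_table(n_per_class = 10, delta = 10)
  fit <- fit_simca(tab)
  pred <- classify_simca(fit, tab)
  expect_equal(pred$predicted, as.character(tab$group))
  # spectrum unlike either class: far off in a random direction
  alien <- toy_table(matrix(seq(0, 40, length.out = 20) +
                              rnorm(20, sd = 4), 1))
  pa <- classify_simca(fit, alien)
  expect_equal(pa$predicted, "no class")
  expect_error(fit_simca(tab[c(1, 2, 11, 12), ]), ">= 3 samples")
})

test_that("OPLS-DA separates classes and reports orthogonal components", {
  tab <- make_group_table(n_per_class = 10, delta = 3, sd = 0.5, seed = 33)
  fit <- fit_oplsda(tab, n_predictive = 2, n_orthogonal = 2, seed = 1)
  pred <- classify_oplsda(fit, tab)
  expect_equal(pred$predicted, as.character(tab$group))
  # orthogonal scores are uncorrelated with every class-encoding column
  for (j in seq_len(ncol(fit$Y_encoding))) {
    for (a in seq_len(fit$n_orthogonal)) {
      expect_lt(abs(sum(fit$T_o[, a] * fit$Y_encoding[, j])), 1e-6)
    }
  }
  expect_true(fit$r2x >= 0 && fit$r2x <= 1)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  # with zero orthogonal components the model reduces to PLS-DA
  f0 <- fit_oplsda(tab, n_predictive = 2, n_orthogonal = 0, seed = 1)
  p0 <- classify_oplsda(f0, tab)
  expect_equal(p0$predicted, pred$predicted)
  expect_error(fit_oplsda(tab, n_predictive = 30, n_orthogonal = 2),
               "rank")
})

test_that("RMS-X residuals have the closed-form toy geometry", {
  # two classes whose means differ by delta at every wavelength
  p <- 16
  delta <- 2
  base <- matrix(rep(c(0, delta), each = 3), 6, p)
  tab <- toy_table(base + rnorm(6 * p, sd = 1e-4))
  tab$group <- factor(rep(c("lo", "hi"), each = 3), levels = c("lo", "hi"))
  fit <- fit_rmsx(tab, pretreatment = "none (0,0,1,1)")
  # a sample at the 'lo' mean: RMS to own class ~ 0, to the other ~ delta
  probe <- toy_table(matrix(colMeans(spectra_matrix(tab)[1:3, ]), 1))
  res <- classify_rmsx(fit, probe, rule = "raw")
  expect_lt(res$rms_lo, 1e-3)
  expect_equal(res$rms_hi, delta, tolerance = 1e-3)
  expect_equal(res$predicted, "lo")
  # RMS is invariant to a consistent wavelength reordering
  perm <- sample(p)
  tab_p <- tab
  wl_cols <- grep("^wl_", names(tab))
  tab_p[, wl_cols] <- tab[, wl_cols[perm]]
  names(tab_p)[wl_cols] <- paste0("wl_", seq_len(p))
  fit_p <- fit_rmsx(tab_p, pretreatment = "none (0,0,1,1)")
  probe_p <- probe
  probe_p[, wl_cols] <- probe[, wl_cols[perm]]
  names(probe_p)[wl_cols] <- paste0("wl_", seq_len(p))
  res_p <- classify_rmsx(fit_p, probe_p, rule = "raw")
  expect_equal(res_p$rms_lo, res$rms_lo, tolerance = 1e-12)
  expect_equal(res_p$rms_hi, res$rms_hi, tolerance = 1e-12)
})

test_that("equidistant samples go to the first class with a warning", {
  p <- 10
  base <- matrix(rep(c(0, 2), each = 4), 8, p)
  tab <- toy_table(base)
  tab$group <- factor(rep(c("a", "b"), each = 4), levels = c("a", "b"))
  fit <- suppressWarnings(fit_rmsx(tab, pretreatment = "none (0,0,1,1)"))
  mid <- toy_table(matrix(1, 1, p))
  expect_warning(res <- classify_rmsx(fit, mid, rule = "raw"),
                 "equidistant")
  expect_equal(res$predicted, "a")
})

test_that("confusion metrics reproduce hand-counted tables", {
  # perfect prediction
  y <- factor(rep(c("a", "b", "c"), times = c(3, 3, 4)))
  cm <- confusion_metrics(y, as.character(y))
  expect_true(all(cm$by_class$sensitivity == 1))
  expect_true(all(cm$by_class$specificity == 1))
  expect_equal(cm$overall, 1)
  # degenerate classifier: everything called 'a' in a balanced 2-class set
  y2 <- factor(rep(c("a", "b"), each = 5))
  cm2 <- confusion_metrics(y2, rep("a", 10))
  m2 <- cm2$by_class
  expect_equal(m2$sensitivity, c(1, 0))
  expect_equal(m2$specificity, c(0, 1))
  # hand-counted 3-class confusion [[2,1,0],[0,3,0],[1,0,3]]
  truth <- rep(c("a", "b", "c"), times = c(3, 3, 4))
  pred <- c("a", "a", "b", "b", "b", "b", "a", "c", "c", "c")
  cm3 <- confusion_metrics(truth, pred, classes = c("a", "b", "c"))
  m3 <- cm3$by_class
  expect_equal(m3$sensitivity, c(2 / 3, 1, 3 / 4))
  # specificity from complement counts: a: TN 6/7, b: 6/7, c: 6/6
  expect_equal(m3$specificity, c(6 / 7, 6 / 7, 1))
  expect_equal(cm3$overall, 8 / 10)
  expect_equal(m3$pct_correct, m3$sensitivity * 100)
  expect_error(confusion_metrics(c("a", "z"), c("a", "a"),
                                 classes = c("a", "b")), "outside")
  # no-class predictions count as misclassification without inflating FP
  cm4 <- confusion_metrics(y2, c(rep("a", 4), "no class", rep("b", 5)))
  expect_equal(cm4$by_class$sensitivity[1], 0.8)
  expect_equal(cm4$by_class$specificity[2], 1)
})

test_that("specificity is 1 whenever a class attracts no foreign samples", {
  set.seed(35)
  for (rep_i in 1:10) {
    truth <- sample(c("x", "y", "z"), 30, replace = TRUE)
    pred <- truth
    flip <- sample(30, 5)
    pred[flip] <- sample(c("x", "y"), 5, replace = TRUE)
    cm <- confusion_metrics(truth, pred, classes = c("x", "y", "z"))
    for (k in seq_len(3)) {
      cl <- cm$by_class$class[k]
      if (!any(pred == cl & truth != cl)) {
        expect_equal(cm$by_class$specificity[k], 1)
      }
    }
  }
})

test_that("RMS-X accuracy does not improve with added noise", {
  # monotone non-increasing accuracy over a 3-point noise grid (averaged
  # over seeds); small fluctuations are tolerated via the average
  noise <- c(0.001, 0.005, 0.02)
  acc <- sapply(noise, function(ns) {
    mean(sapply(1:4, function(sd) {
      lib <- generate_tea_library(
        generator_config(seed = sd, n_total = 160L, noise_sd = ns))
      sets <- split_sets(lib, 0.8, seed = sd)
      cal <- assign_groups(sets$calibration, "pure_vs_blends")
      val <- assign_groups(sets$validation, "pure_vs_blends")
      fit <- fit_rmsx(cal)
      pv <- classify_rmsx(fit, val)
      mean(pv$predicted == as.character(val$group))
    }))
  })
  expect_true(acc[1] >= acc[3])
  expect_true(acc[2] >= acc[3] - 0.02)
})

test_that("blend-percentage errors land in adjacent bins", {
  bins <- c(">95%", "95-85%", "85-75%", "75-50%")
  n_adj <- 0; n_err <- 0
  for (sd in 1:3) {
    lib <- generate_tea_library(generator_config(seed = sd))
    sets <- split_sets(lib, 0.8, seed = sd)
    cal <- assign_groups(sets$calibration, "blend_percentage")
    val <- assign_groups(sets$validation, "blend_percentage")
    fit <- fit_rmsx(cal)
    pv <- classify_rmsx(fit, val)
    truth <- as.character(val$group)
    err <- which(pv$predicted != truth)
    n_err <- n_err + length(err)
    for (i in err) {
      tb <- strsplit(truth[i], " ")[[1]]
      pb <- strsplit(pv$predicted[i], " ")[[1]]
      same_tea <- tb[2] == pb[2]
      adjacent <- abs(match(tb[1], bins) - match(pb[1], bins)) <= 1
      if (same_tea && adjacent) n_adj <- n_adj + 1
    }
  }
  expect_gte(n_adj / n_err, 0.9)
})
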