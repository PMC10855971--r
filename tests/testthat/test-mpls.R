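test_that("MPLS recovers an exact single-wavelength linear relation", {
  set.seed(10)
  X <- matrix(rnorm(40), 20, 2)
  colnames(X) <- c("wl_1", "wl_2")
  y <- 2 + 3 * X[, 1]
  # only wavelength 1 is informative; wavelength 2 is pure noise but the
  # single factor must align with the informative direction
  X[, 2] <- 0
  fit <- fit_mpls(X, y, n_factors = 1)
  expect_equal(fit$beta0, 2, tolerance = 1e-8)
  expect_equal(unname(fit$beta), c(3, 0), tolerance = 1e-8)
  expect_equal(predict_mpls(fit, X), y, tolerance = 1e-8)
})

test_that("full-rank MPLS fitted values equal least squares", {
  set.seed(11)
  X <- matrix(rnorm(40), 8, 5)
  colnames(X) <- paste0("wl_", 1:5)
  y <- rnorm(8)
  fit <- fit_mpls(X, y, n_factors = 5)
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(unname(fit$fitted), unname(ols$fitted.values),
               tolerance = 1e-6)
  # beta reproduces the fitted values as a plain affine map
  expect_equal(unname(drop(fit$beta0 + X %*% fit$beta)),
               unname(fit$fitted), tolerance = 1e-8)
})

test_that("MPLS factor-1 weights equal standard PLS1 weights", {
  # residual standardization only begins after the first factor
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  colnames(X) <- paste0("wl_", 1:10)
  y <- rnorm(20)
  fit <- fit_mpls(X, y, n_factors = 3)
  W_ref <- pls1_oracle(X, y, 3)
  expect_equal(abs(sum(fit$weights[, 1] * W_ref[, 1])), 1,
               tolerance = 1e-9)
})

test_that("prediction is linear and reproduces the calibration fit", {
  set.seed(13)
  X <- matrix(rnorm(300), 30, 10)
  colnames(X) <- paste0("wl_", 1:10)
  y <- drop(X %*% rnorm(10)) + rnorm(30, sd = 0.1)
  fit <- fit_mpls(X, y, n_factors = 4)
  expect_equal(predict_mpls(fit, X), unname(fit$fitted), tolerance = 1e-9)
  zero <- matrix(0, 1, 10)
  expect_equal(predict_mpls(fit, zero), fit$beta0, tolerance = 1e-9)
  # spectra differing only where beta = 0 predict identically
  b0 <- which.min(abs(fit$beta))
  x1 <- X[1, , drop = FALSE]
  x2 <- x1; x2[b0] <- x2[b0] + 5
  expect_equal(predict_mpls(fit, x1) + 5 * fit$beta[b0],
               predict_mpls(fit, x2), tolerance = 1e-9)
  expect_error(predict_mpls(fit, X[, 1:3]), "grid")
  # doubling y doubles beta
  fit2 <- fit_mpls(X, 2 * y, n_factors = 4)
  expect_equal(fit2$beta, 2 * fit$beta, tolerance = 1e-8)
  expect_error(fit_mpls(X, rep(1, 30), 2), "zero variance")
  expect_error(fit_mpls(X, y, 50), "out of range")
})

test_that("global H flags exactly the planted score-space outlier", {
  set.seed(14)
  n <- 20
  latent <- matrix(rnorm(n * 2), n, 2)
  load <- matrix(rnorm(2 * 30), 2, 30)
  X <- latent %*% load + matrix(rnorm(n * 30, sd = 0.01), n, 30)
  X <- rbind(X, c(10, 10) %*% load)  # far point at ~10 latent SDs
  rep <- global_h_outliers(X, n_components = 2, threshold = 3)
  expect_true(rep$flagged[21])
  expect_equal(sum(rep$flagged), 1L)
  # oracle: direct standardized Mahalanobis in score space
  pc <- prcomp(X)
  sc <- scale(pc$x[, 1:2])
  gh_direct <- rowMeans(sc^2) * (nrow(X) - 1) / nrow(X) /
    ((nrow(X) - 1) / nrow(X))
  expect_equal(rep$gh, rowMeans(scale(pc$x[, 1:2],
                                      center = FALSE,
                                      scale = apply(pc$x[, 1:2], 2, sd))^2),
               tolerance = 1e-9)
  # sample at the centroid has GH ~ 0
  Xc <- rbind(X, colMeans(X))
  repc <- global_h_outliers(Xc, n_components = 2)
  expect_lt(repc$gh[22], 0.05)
  # duplicates receive identical GH
  Xd <- rbind(X, X[3, ])
  repd <- global_h_outliers(Xd, n_components = 2)
  expect_equal(repd$gh[22], repd$gh[3], tolerance = 1e-9)
})

test_that("the T criterion standardizes residuals with inclusive boundary", {
  y <- c(1, 2, 3, 4)
  yh <- c(1, 2 + 0.5, 3 - 2.5 * 0.2, 4)
  rep <- t_outliers(y, yh, scale = 0.2)
  expect_equal(rep$t, c(0, 2.5, 2.5, 0))
  expect_equal(rep$flagged, c(FALSE, TRUE, TRUE, FALSE))
  # scale invariance
  rep2 <- t_outliers(10 * y, 10 * yh, scale = 2)
  expect_equal(rep2$flagged, rep$flagged)
  expect_error(t_outliers(y, yh, scale = 0), "positive")
})

test_that("cross-validation selects a parsimonious factor count", {
  set.seed(15)
  # one latent direction, no noise: a single factor is a perfect model
  t_lat <- rnorm(60)
  X <- outer(t_lat, rnorm(10))
  colnames(X) <- paste0("wl_", 1:10)
  y <- 2 * t_lat
  cv <- cross_validate(X, y, n_groups = 4, max_factors = 5, seed = 1)
  expect_equal(cv$chosen, 1L)
  expect_lt(cv$secv$secv[1], 1e-8)
  # SECV identity: recomputable from the held-out residuals directly
  expect_equal(cv$secv$secv[cv$chosen],
               sqrt(mean((y - cv$cv_predictions)^2)), tolerance = 1e-12)
  # same seed gives identical folds and results
  cv2 <- cross_validate(X, y, n_groups = 4, max_factors = 5, seed = 1)
  expect_identical(cv$secv, cv2$secv)
  expect_error(cross_validate(X, y, n_groups = 40), "fewer than 2")
})

test_that("calibration statistics reproduce the printed worked examples", {
  # estimated concentration ranges from printed means and SDs
  expect_equal(max(0, 2.3537 - 3 * 0.2565), 1.584, tolerance = 5e-4)
  expect_equal(2.3537 + 3 * 0.2565, 3.123, tolerance = 5e-4)
  cs <- calibration_statistics(
    y = c(2.3537 + 0.2565 * scale(rnorm(50, 0, 1))[, 1]),
    y_fit = rep(2.3537, 50), y_cv = rep(2.3537, 50), n_factors = 1)
  expect_equal(cs$min_est, max(0, cs$mean - 3 * cs$sd))
  expect_equal(cs$max_est, cs$mean + 3 * cs$sd)
  # clamping at zero (Pb row: mean 0.8784, SD 0.3285)
  expect_equal(max(0, 0.8784 - 3 * 0.3285), 0)
  expect_equal(0.8784 + 3 * 0.3285, 1.864, tolerance = 5e-4)
  # RPD identity on the Cu row: SD 3.6119, SEC 0.625
  expect_equal(round(3.6119 / 0.625, 2), 5.78)
  # computed stats satisfy the same identities on synthetic numbers
  set.seed(16)
  y <- rnorm(40, 10, 2); e <- rnorm(40, 0, 0.3)
  cs2 <- calibration_statistics(y, y - e, y - e * 1.1, n_factors = 3)
  expect_equal(cs2$sec, sqrt(sum(e^2) / (40 - 3 - 1)), tolerance = 1e-12)
  expect_equal(cs2$rpd, cs2$sd / cs2$sec, tolerance = 1e-12)
  expect_equal(cs2$rsq, 1 - sum(e^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
})

test_that("external validation decomposes SEP into bias and SEP(C)", {
  set.seed(17)
  X <- matrix(rnorm(300), 30, 10)
  colnames(X) <- paste0("wl_", 1:10)
  y <- drop(X %*% rnorm(10))
  fit <- fit_mpls(X, y, n_factors = 5)
  Xv <- matrix(rnorm(150), 15, 10)
  yv <- predict_mpls(fit, Xv)  # perfect predictions
  v <- external_validation(fit, Xv, yv)
  expect_equal(v$sep, 0)
  expect_equal(v$bias, 0)
  expect_equal(v$p_paired_t, 1)
  expect_true(v$zero_variance)
  # constant shift: bias = c, SEP(C) = 0, SEP = |c|
  v2 <- external_validation(fit, Xv, yv - 0.7)
  expect_equal(v2$bias, 0.7, tolerance = 1e-10)
  expect_equal(v2$sep, 0.7, tolerance = 1e-10)
  expect_lt(v2$sep_c, 1e-9)
  # SEP^2 = SEP(C)^2 (n-1)/n + bias^2
  yv3 <- yv + rnorm(15, 0.3, 0.5)
  v3 <- external_validation(fit, Xv, yv3)
  expect_equal(v3$sep^2,
               v3$sep_c^2 * (v3$n - 1) / v3$n + v3$bias^2,
               tolerance = 1e-10)
  expect_equal(v3$rmse, v3$sep)
  # paired t oracle on alternating differences
  d <- c(1, -1, 1, -1)
  tt <- t.test(d)
  yh4 <- predict_mpls(fit, Xv[1:4, ])
  v4 <- external_validation(fit, Xv[1:4, ], yh4 - d)
  expect_equal(v4$p_paired_t, tt$p.value, tolerance = 1e-9)
})

test_that("beta peaks recover the planted metal signature wavelengths", {
  # the Al calibration's largest |beta| peaks must sit at the generator's
  # planted Al signature bands (1282/1290 nm) within +/- 6 nm
  lib <- generate_tea_library(generator_config(seed = 21))
  sets <- split_sets(lib, 0.8, seed = 21)
  cal <- calibrate_full_protocol(sets$calibration, "Al", seed = 21)
  pk <- beta_peaks(cal$model, n_peaks = 2)
  sig <- metal_signature_bands()
  planted <- unlist(sig[sig$metal == "Al", c("center1", "center2")])
  expect_lte(min(abs(pk$wavelength[1] - planted)), 6)
  expect_lte(min(abs(pk$wavelength[2] - planted)), 20)
})

test_that("the full protocol is deterministic and logs removals", {
  lib <- generate_tea_library(generator_config(seed = 22, n_total = 140L))
  sets <- split_sets(lib, 0.8, seed = 22)
  a <- calibrate_full_protocol(sets$calibration, "Cu", seed = 3)
  b <- calibrate_full_protocol(sets$calibration, "Cu", seed = 3)
  expect_equal(a$stats, b$stats)
  expect_identical(a$outliers, b$outliers)
  expect_equal(glance(a)$rpd, a$stats$rpd)
  expect_s3_class(tidy(a), "tbl_df")
  # false positives stay rare on clean data
  expect_lte(nrow(a$outliers), ceiling(0.08 * nrow(sets$calibration)))
})

test_that("a planted spectral outlier is removed in the first pass", {
  lib <- generate_tea_library(generator_config(seed = 23, n_total = 120L))
  sets <- split_sets(lib, 0.8, seed = 23)
  cal_tab <- sets$calibration
  M <- spectra_matrix(cal_tab)
  # corrupt one sample far outside the spectral population
  M[5, ] <- M[5, ] + sin(seq_len(ncol(M)) / 3) * 2
  cal_tab <- set_spectra(cal_tab, M, table_wavelengths(cal_tab))
  out <- calibrate_full_protocol(cal_tab, "Cu", seed = 3)
  expect_true(cal_tab$id[5] %in%
                out$outliers$id[out$outliers$stage == "global_H"])
})
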