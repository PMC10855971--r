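#' Reference heavy-metal composition of pure teas
#'
#' Class-wise mean and standard deviation of the five analytes in pure
#' black, red (Pu-erh), and green teas, as determined by ICP-MS on the
#' commercial samples the study design is modelled on.  Al is expressed in
#' g/kg, all other metals in mg/kg.  Mercury occurs only in green tea.
#'
#' @return A tibble with columns `class`, `metal`, `mean`, `sd`, `unit`.
#' @export
tea_metal_reference <- function() {
  tibble::tribble(
    ~class, ~metal, ~mean, ~sd, ~unit,
    "black", "Al",  2.04, 0.23, "g/kg",
    "black", "Pb",  0.56, 0.28, "mg/kg",
    "black", "As",  0.04, 0.01, "mg/kg",
    "black", "Hg",  0.00, 0.00, "mg/kg",
    "black", "Cu", 17.31, 2.60, "mg/kg",
    "red",   "Al",  2.36, 0.25, "g/kg",
    "red",   "Pb",  1.21, 0.36, "mg/kg",
    "red",   "As",  0.19, 0.09, "mg/kg",
    "red",   "Hg",  0.00, 0.00, "mg/kg",
    "red",   "Cu", 19.87, 2.78, "mg/kg",
    "green", "Al",  2.52, 0.29, "g/kg",
    "green", "Pb",  0.98, 0.40, "mg/kg",
    "green", "As",  0.09, 0.02, "mg/kg",
    "green", "Hg",  0.01, 0.01, "mg/kg",
    "green", "Cu", 12.19, 2.40, "mg/kg"
  )
}

#' Metal signature bands
#'
#' Metals have no direct NIR absorption; they are predictable because they
#' associate with organic ligands (phenolics, proteins) whose bands shift
#' with complexation.  The generator encodes this association as a pair of
#' narrow Gaussian bands per metal whose height is proportional to the
#' concentration; the band centers are the wavelengths at which the
#' regression (beta) coefficients of the reference calibrations peak.
#'
#' @return A tibble with columns `metal`, `center1`, `center2` (nm),
#'   `amplitude` (absorbance per concentration unit), `sigma` (nm).
#' @export
metal_signature_bands <- function() {
  tibble::tribble(
    ~metal, ~center1, ~center2, ~amplitude, ~sigma,
    "Al", 1282, 1290, 0.008,  6,
    "Pb", 1164, 1984, 0.008,  6,
    "As", 1264, 1580, 0.030,  6,
    "Hg", 1244, 1252, 0.600,  6,
    "Cu", 1310, 1614, 0.0008, 6
  )
}

#' Sample-table column names for the five analytes
#'
#' @return Named character vector mapping analyte (`"Al"`, ...) to the
#'   concentration column in a sample table (`"Al_g_kg"`, ...).
#' @export
metal_columns <- function() {
  c(Al = "Al_g_kg", Pb = "Pb_mg_kg", As = "As_mg_kg",
    Hg = "Hg_mg_kg", Cu = "Cu_mg_kg")
}

# Shared band structure of tea spectra: organic absorption bands (nm) and
# widths chosen to reproduce the qualitative shape of log(1/R) tea spectra
# (dominant water bands at 1440/1950 nm, CH/NH overtone structure elsewhere).
tea_band_table <- function() {
  tibble::tibble(
    center = c(1220, 1330, 1400, 1440, 1670, 1740,
               1885, 1950, 2150, 2170, 2280, 2350),
    sigma  = c(12, 10, 12, 24, 10, 10, 10, 28, 10, 10, 12, 14)
  )
}

# Per-class absorption band amplitudes (absorbance units).  Fermentation
# chemistry gives each tea its own band pattern: fully fermented black tea
# absorbs strongly across all bands; green tea weakly; post-fermented red
# (Pu-erh) tea alternates — stronger than black at some bands, weaker than
# green at others — so the three endmember patterns span a proper simplex
# rather than a single scale axis.  The overall absorbance ordering
# black > red > green is carried by the class baselines below, whose gaps
# exceed the band-amplitude excursions.
class_band_amplitudes <- function() {
  rbind(
    black = c(0.80, 0.60, 0.64, 0.92, 0.84, 0.80,
              0.60, 1.10, 0.80, 0.76, 0.84, 0.76),
    red   = c(0.02, 0.78, 0.01, 1.10, 0.01, 0.01,
              0.78, 1.25, 0.03, 0.80, 0.02, 0.94),
    green = c(0.12, 0.13, 0.10, 0.51, 0.10, 0.08,
              0.11, 0.30, 0.18, 0.09, 0.13, 0.14)
  )
}

# Class baseline absorbance (offset + gentle rise with wavelength).
class_baselines <- function() c(black = 0.85, red = 0.62, green = 0.44)

#' Generator configuration
#'
#' Bundles every tunable of the synthetic tea library: sample counts per
#' pure class, total library size, measurement noise, sample-presentation
#' scatter, and the within-class variability of the pure endmembers.
#'
#' @param seed Integer seed; the generator is a deterministic function of it
#'   (exactly so when `noise_sd`, scatter and jitter are zero).
#' @param n_black,n_green,n_red Number of pure samples per class.
#' @param n_total Total library size (pures + binary blends).
#' @param noise_sd Standard deviation of the per-wavelength measurement
#'   noise (absorbance units).
#' @param scatter_offset_sd,scatter_slope_sd Per-sample additive baseline
#'   offset and linear tilt SDs (absorbance), emulating repack/particle-size
#'   scatter; removed by SNV/MSC/detrend-type corrections.
#' @param band_jitter_sd Relative SD of the per-sample, per-band amplitude
#'   multiplier for pure endmembers (within-class compositional spread).
#' @return A list of class `tea_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_black = 7L, n_green = 11L, n_red = 8L,
                             n_total = 322L,
                             noise_sd = 0.001,
                             scatter_offset_sd = 0.02,
                             scatter_slope_sd = 0.02,
                             band_jitter_sd = 0.003) {
  if (any(c(n_black, n_green, n_red) <= 0)) {
    stop("class counts must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (scatter_offset_sd < 0 || scatter_slope_sd < 0 || band_jitter_sd < 0) {
    stop("scatter and jitter SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         n_black = as.integer(n_black),
         n_green = as.integer(n_green),
         n_red = as.integer(n_red),
         n_total = as.integer(n_total),
         noise_sd = noise_sd,
         scatter_offset_sd = scatter_offset_sd,
         scatter_slope_sd = scatter_slope_sd,
         band_jitter_sd = band_jitter_sd),
    class = "tea_generator_config"
  )
}

# Draw one truncated-normal value (resample until >= 0); an sd of 0 returns
# the mean (clamped at 0) exactly.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < 0)
  }
  out
}

# Deterministic (noise-free, jitter-free) class mean spectrum including the
# expected metal signature contribution at the class-mean concentrations.
class_mean_spectrum <- function(class, wavelengths = wavelength_grid()) {
  bands <- tea_band_table()
  amps <- class_band_amplitudes()[class, ]
  u <- (wavelengths - min(wavelengths)) / diff(range(wavelengths))
  s <- class_baselines()[[class]] + 0.25 * u
  for (k in seq_len(nrow(bands))) {
    s <- s + amps[k] *
      gaussian_band(wavelengths, bands$center[k], bands$sigma[k])
  }
  ref <- tea_metal_reference()
  sig <- metal_signature_bands()
  for (m in sig$metal) {
    cm <- ref$mean[ref$class == class & ref$metal == m]
    row <- sig[sig$metal == m, ]
    s <- s + cm * row$amplitude *
      (gaussian_band(wavelengths, row$center1, row$sigma) +
         gaussian_band(wavelengths, row$center2, row$sigma))
  }
  s
}

# Build one pure-tea spectrum: class bands with per-sample amplitude jitter,
# metal signatures at the sample's own concentrations, scatter, and noise.
.pure_spectrum <- function(class, metals, config, wavelengths) {
  bands <- tea_band_table()
  amps <- class_band_amplitudes()[class, ]
  u <- (wavelengths - min(wavelengths)) / diff(range(wavelengths))
  s <- class_baselines()[[class]] + 0.25 * u
  # per-sample compositional jitter, expressed relative to the black-tea
  # amplitude so weak bands vary on the same absolute scale as strong ones
  jitter <- stats::rnorm(nrow(bands), 0, config$band_jitter_sd) *
    class_band_amplitudes()["black", ]
  for (k in seq_len(nrow(bands))) {
    s <- s + (amps[k] + jitter[k]) *
      gaussian_band(wavelengths, bands$center[k], bands$sigma[k])
  }
  sig <- metal_signature_bands()
  for (j in seq_len(nrow(sig))) {
    s <- s + metals[[sig$metal[j]]] * sig$amplitude[j] *
      (gaussian_band(wavelengths, sig$center1[j], sig$sigma[j]) +
         gaussian_band(wavelengths, sig$center2[j], sig$sigma[j]))
  }
  s <- s + stats::rnorm(1, 0, config$scatter_offset_sd) +
    stats::rnorm(1, 0, config$scatter_slope_sd) * (u - 0.5)
  if (config$noise_sd > 0) {
    s <- s + stats::rnorm(length(s), 0, config$noise_sd)
  }
  s
}

# assemble a sample table from metadata vectors and a spectra matrix
.assemble_table <- function(id, class, fractions, metals, spectra,
                            wavelengths) {
  meta <- tibble::tibble(
    id = id, class = class,
    fraction_black = fractions[, "black"],
    fraction_green = fractions[, "green"],
    fraction_red = fractions[, "red"],
    Al_g_kg = metals[, "Al"], Pb_mg_kg = metals[, "Pb"],
    As_mg_kg = metals[, "As"], Hg_mg_kg = metals[, "Hg"],
    Cu_mg_kg = metals[, "Cu"])
  spec <- tibble::as_tibble(as.data.frame(spectra))
  names(spec) <- wl_colnames(wavelengths)
  dplyr::bind_cols(meta, spec)
}

.gen_pures <- function(config, wavelengths) {
  ref <- tea_metal_reference()
  classes <- c(rep("black", config$n_black),
               rep("green", config$n_green),
               rep("red", config$n_red))
  n <- length(classes)
  metals <- matrix(0, n, 5L,
                   dimnames = list(NULL, names(metal_columns())))
  spectra <- matrix(0, n, length(wavelengths))
  fractions <- matrix(0, n, 3L,
                      dimnames = list(NULL, c("black", "green", "red")))
  counters <- c(black = 0L, green = 0L, red = 0L)
  id <- character(n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    counters[cl] <- counters[cl] + 1L
    for (m in names(metal_columns())) {
      r <- ref[ref$class == cl & ref$metal == m, ]
      metals[i, m] <- rtruncnorm_pos(1L, r$mean, r$sd)
    }
    spectra[i, ] <- .pure_spectrum(cl, as.list(metals[i, ]), config,
                                   wavelengths)
    fractions[i, cl] <- 1
    id[i] <- sprintf("%s_%02d", cl, counters[cl])
  }
  .assemble_table(id, classes, fractions, metals, spectra, wavelengths)
}

#' Generate pure-tea endmember samples
#'
#' Draws the pure black, green, and red tea samples of the design: metal
#' concentrations per class from truncated normal distributions with the
#' reference means and SDs (see [tea_metal_reference()]; Hg is nonzero only
#' in green tea), and spectra built from class-specific absorption bands,
#' per-metal signature bands, sample scatter, and measurement noise.
#'
#' @param config A [generator_config()].
#' @return A sample table (tibble): one row per sample with columns `id`,
#'   `class`, the three blend fractions, the five concentration columns,
#'   and 700 `wl_*` absorbance columns.
#' @export
generate_pure_samples <- function(config = generator_config()) {
  stopifnot(inherits(config, "tea_generator_config"))
  set.seed(config$seed)
  .gen_pures(config, wavelength_grid())
}

#' Mixture chemistry of a binary blend
#'
#' The metal content of a blend is the mixture-weighted (linear) combination
#' of the constituents' contents, exactly as blend chemistry is computed
#' from the analysed pure samples.
#'
#' @param fractions Named numeric vector of constituent proportions; must
#'   sum to 1.
#' @param pure_metals List (same names/order as `fractions`) of named metal
#'   concentration vectors, one per constituent.
#' @return Named numeric vector of blended concentrations, in the source
#'   units.
#' @examples
#' blend_chemistry(c(a = 0.5, b = 0.5),
#'                 list(a = c(Cu = 20), b = c(Cu = 10)))
#' @export
blend_chemistry <- function(fractions, pure_metals) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("blend fractions must sum to 1", call. = FALSE)
  }
  if (length(fractions) != length(pure_metals)) {
    stop("one metal map per constituent is required", call. = FALSE)
  }
  metals <- names(pure_metals[[1]])
  out <- stats::setNames(numeric(length(metals)), metals)
  for (i in seq_along(fractions)) {
    out <- out + fractions[[i]] * pure_metals[[i]][metals]
  }
  out
}

# One blend record from two pure-sample rows (1-row tibbles).
.blend_record <- function(rec_a, rec_b, fraction, noise_sd, id, wavelengths) {
  met_cols <- metal_columns()
  ma <- stats::setNames(as.numeric(rec_a[1, met_cols]), names(met_cols))
  mb <- stats::setNames(as.numeric(rec_b[1, met_cols]), names(met_cols))
  metals <- blend_chemistry(c(a = fraction, b = 1 - fraction),
                            list(a = ma, b = mb))
  sa <- as.numeric(rec_a[1, wl_colnames(wavelengths)])
  sb <- as.numeric(rec_b[1, wl_colnames(wavelengths)])
  spec <- fraction * sa + (1 - fraction) * sb
  if (noise_sd > 0) spec <- spec + stats::rnorm(length(spec), 0, noise_sd)
  fr <- c(black = 0, green = 0, red = 0)
  fr[rec_a$class] <- fr[rec_a$class] + fraction
  fr[rec_b$class] <- fr[rec_b$class] + 1 - fraction
  .assemble_table(id, "blend", matrix(fr, 1L, dimnames = list(NULL, names(fr))),
                  matrix(metals, 1L, dimnames = list(NULL, names(metals))),
                  matrix(spec, 1L), wavelengths)
}

#' Blend two pure samples at a given dominant fraction
#'
#' Spectra mix linearly in absorbance (`f * A + (1 - f) * B`) with fresh
#' measurement noise; chemistry mixes linearly via [blend_chemistry()].
#'
#' @param rec_a,rec_b One-row sample tables (the dominant and second tea).
#' @param fraction Proportion of `rec_a` in the blend.
#' @param noise_sd Measurement noise SD added to the mixed spectrum.
#' @param id Sample identifier for the new record.
#' @return A one-row sample table for the blend.
#' @export
blend_records <- function(rec_a, rec_b, fraction, noise_sd = 0,
                          id = "blend_01") {
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  .blend_record(rec_a, rec_b, fraction, noise_sd, id,
                table_wavelengths(rec_a))
}

.gen_blends <- function(pures, config, wavelengths) {
  n_blends <- config$n_total - nrow(pures)
  if (n_blends < 0) {
    stop("n_total is smaller than the number of pure samples", call. = FALSE)
  }
  # The three binary pairs, each appearing with both dominance orders so all
  # six ">50% blend" groups are populated; allocation is uniform round-robin.
  ordered_pairs <- list(c("black", "red"), c("black", "green"),
                        c("red", "black"), c("red", "green"),
                        c("green", "black"), c("green", "red"))
  fractions_grid <- seq(0.50, 0.99, by = 0.01)
  pure_spec <- spectra_matrix(pures)
  pure_met <- as.matrix(pures[, metal_columns()])
  colnames(pure_met) <- names(metal_columns())
  n <- n_blends
  metals <- matrix(0, n, 5L,
                   dimnames = list(NULL, names(metal_columns())))
  spectra <- matrix(0, n, length(wavelengths))
  fractions <- matrix(0, n, 3L,
                      dimnames = list(NULL, c("black", "green", "red")))
  for (i in seq_len(n)) {
    pair <- ordered_pairs[[(i - 1L) %% 6L + 1L]]
    f <- sample(fractions_grid, 1L)
    ia <- sample(which(pures$class == pair[1]), 1L)
    ib <- sample(which(pures$class == pair[2]), 1L)
    metals[i, ] <- blend_chemistry(
      c(a = f, b = 1 - f),
      list(a = pure_met[ia, ], b = pure_met[ib, ]))
    spec <- f * pure_spec[ia, ] + (1 - f) * pure_spec[ib, ]
    if (config$noise_sd > 0) {
      spec <- spec + stats::rnorm(length(spec), 0, config$noise_sd)
    }
    spectra[i, ] <- spec
    fractions[i, pair[1]] <- f
    fractions[i, pair[2]] <- 1 - f
  }
  .assemble_table(sprintf("blend_%03d", seq_len(n)), rep("blend", n),
                  fractions, metals, spectra, wavelengths)
}

#' Generate the binary blends of a pure-sample library
#'
#' Emits blends for the three binary tea pairs with dominant fractions drawn
#' uniformly from \{0.50, 0.51, ..., 0.99\}, until the library (pures plus
#' blends) reaches `config$n_total` samples.
#'
#' @inheritParams generate_pure_samples
#' @param pures A sample table of pure samples (from
#'   [generate_pure_samples()]).
#' @return A sample table of blend records.
#' @export
generate_blends <- function(pures, config = generator_config()) {
  stopifnot(inherits(config, "tea_generator_config"))
  set.seed(config$seed + 1L)
  .gen_blends(pures, config, table_wavelengths(pures))
}

#' Generate the full synthetic tea library
#'
#' Pure endmembers plus binary blends, 322 samples by default (7 black + 11
#' green + 8 red pures and 296 blends), as a single seeded draw.
#'
#' @inheritParams generate_pure_samples
#' @return A sample table with `config$n_total` rows.
#' @export
generate_tea_library <- function(config = generator_config()) {
  stopifnot(inherits(config, "tea_generator_config"))
  set.seed(config$seed)
  wl <- wavelength_grid()
  pures <- .gen_pures(config, wl)
  blends <- .gen_blends(pures, config, wl)
  dplyr::bind_rows(pures, blends)
}

#' Random calibration/validation split
#'
#' Partitions a sample table at random into a calibration set of size
#' `floor(cal_fraction * n)` and a validation set holding the remainder
#' (322 samples at 80 % split 257/65).
#'
#' @param table A sample table.
#' @param cal_fraction Proportion assigned to calibration (0 < f < 1).
#' @param seed Integer seed for the permutation.
#' @return A list with elements `calibration` and `validation` (disjoint,
#'   exhaustive sample tables).
#' @export
split_sets <- function(table, cal_fraction = 0.8, seed = 1L) {
  n <- nrow(table)
  if (n == 0L) stop("cannot split an empty sample table", call. = FALSE)
  if (cal_fraction <= 0 || cal_fraction >= 1) {
    stop("cal_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  n_cal <- floor(cal_fraction * n)
  list(calibration = table[sort(idx[seq_len(n_cal)]), ],
       validation = table[sort(idx[-seq_len(n_cal)]), ])
}

#' Read and write sample tables as CSV
#'
#' One row per sample: `id`, `class`, the three blend fractions, five
#' concentration columns, then the `wl_*` absorbance columns.
#'
#' @param table A sample table.
#' @param path File path.
#' @return `write_sample_table()` returns `table` invisibly;
#'   `read_sample_table()` returns a sample table tibble.
#' @export
write_sample_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(table)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    class = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
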