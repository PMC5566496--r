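make_doublet <- function(centre, ppm = seq(0, 3, by = 5e-4), hw = 0.004,
                         j = 0.0175) {
  y <- hw^2 / ((ppm - centre + j / 2)^2 + hw^2) +
       hw^2 / ((ppm - centre - j / 2)^2 + hw^2)
  spectrum(ppm, y, "s1")
}

test_that("alanine calibration shifts the apex to 1.47 ppm", {
  s <- make_doublet(1.49)
  cal <- calibrate_to_alanine(s)
  win <- which(cal$ppm >= 1.40 & cal$ppm <= 1.55)
  apex <- win[which.max(cal$intensity[win])]
  expect_equal(cal$ppm[apex], 1.47, tolerance = 1e-9)
  # unresolved doublet (linewidth > J): apex sits at the centre, shift -0.02
  su <- make_doublet(1.49, hw = 0.02)
  calu <- calibrate_to_alanine(su)
  expect_equal(calu$ppm, su$ppm - 0.02, tolerance = 1e-6)
  # already calibrated: identity
  s2 <- make_doublet(1.47 + 0.0175 / 2)  # apex of the taller line at 1.47
  expect_equal(calibrate_to_alanine(make_doublet(1.47))$ppm[1],
               calibrate_to_alanine(calibrate_to_alanine(make_doublet(1.47)))$ppm[1])
  # flat window: error
  flat <- spectrum(seq(0, 3, by = 1e-3), rep(1, 3001), "flat")
  expect_error(calibrate_to_alanine(flat), "flat|maximum")
})

test_that("binning produces the expected uniform grid", {
  ppm <- seq(-1, 10, by = 5e-4)
  s <- spectrum(ppm, rep(2.5, length(ppm)), "const")
  s$calibrated <- TRUE
  sm <- bin_spectra(list(s))
  expect_equal(ncol(sm$X), 20000)
  expect_true(all(abs(sm$X - 2.5) < 1e-12))
  expect_equal(diff(sm$bins)[1], 0.00055, tolerance = 1e-12)
  # one bin covering everything = global mean
  s2 <- spectrum(seq(0, 1, by = 0.01), seq(0, 1, by = 0.01), "ramp")
  sm2 <- bin_spectra(list(s2), lo = 0, hi = 1.0000001, resolution = 1.0000001)
  expect_equal(as.numeric(sm2$X), mean(seq(0, 1, by = 0.01)), tolerance = 1e-9)
  expect_error(bin_spectra(list()), "empty")
})

test_that("binning conserves mean intensity over covered regions", {
  set.seed(1)
  ppm <- seq(0, 2, by = 1e-4)
  y <- abs(rnorm(length(ppm)))
  s <- spectrum(ppm, y, "a")
  sm <- bin_spectra(list(s), lo = 0, hi = 2, resolution = 0.01)
  covered <- ppm >= 0 & ppm < 2
  expect_equal(mean(sm$X[1, ]), mean(y[covered]), tolerance = 1e-3)
})

test_that("exclusion windows drop exactly the covered bins, idempotently", {
  ppm <- seq(-1, 10, by = 5e-4)
  s <- spectrum(ppm, rep(1, length(ppm)), "x")
  sm <- bin_spectra(list(s))
  # region covering nothing: identity
  same <- apply_exclusions(sm, list(exclusion_region(-5, -4, "none")))
  expect_equal(ncol(same$X), ncol(sm$X))
  # defaults: removed = bins whose centre falls in any window
  excl <- apply_exclusions(sm)
  inside <- (sm$bins >= 4.50 & sm$bins <= 5.19) |
            (sm$bins >= 1.10 & sm$bins <= 1.20) |
            (sm$bins >= 3.60 & sm$bins <= 3.90)
  expect_equal(ncol(sm$X) - ncol(excl$X), sum(inside))
  # overlapping regions remove a column once (PEG nested in ethanol window)
  overlap <- apply_exclusions(sm, list(exclusion_region(3.60, 3.90, "e"),
                                       exclusion_region(3.70, 3.75, "p")))
  solo <- apply_exclusions(sm, list(exclusion_region(3.60, 3.90, "e")))
  expect_equal(ncol(overlap$X), ncol(solo$X))
  expect_error(apply_exclusions(sm, list(exclusion_region(-2, 11, "all"))),
               "every bin")
})

test_that("PQN normalization has the defining fixed-point properties", {
  X <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = 3 * c(1, 2, 3, 4))
  m <- spectral_matrix(X, 1:4, flags = list(calibrated = TRUE, excluded = TRUE,
                                            normalized = FALSE, scaled = FALSE))
  n1 <- pqn_normalize(m)
  # identical (up to scale) rows collapse onto the reference
  expect_equal(n1$X[1, ], n1$X[3, ], tolerance = 1e-12)
  # idempotence: second application returns unit factors
  n2 <- pqn_normalize(n1)
  expect_true(all(abs(n2$dilution_factors - 1) < 1e-9))
  expect_equal(n2$X, n1$X, tolerance = 1e-12)
  # zero-area row rejected
  X0 <- rbind(a = c(0, 0, 0, 0), b = 1:4)
  m0 <- spectral_matrix(X0, 1:4)
  expect_error(pqn_normalize(m0), "zero-area.*a")
})

test_that("PQN recovers planted dilution factors", {
  meta <- simulate_metadata(cohort_config(n_patients = 18, seed = 8))
  sim <- simulate_spectra(meta, neutral_templates(), noise_sd = 0,
                          dilution_log_sd = 0.4, conc_log_sd = 0, seed = 8)
  sm <- pqn_normalize(apply_exclusions(bin_spectra(sim$spectra)))
  r <- cor(sm$dilution_factors[sim$spectra$sample_ids],
           sim$truth$dilution_factors)
  expect_gt(r, 0.999)
})

test_that("unit-variance scaling standardizes columns and is scale invariant", {
  set.seed(2)
  X <- cbind(rnorm(20, 5, 2), rnorm(20, -1, 0.1), rep(7, 20))
  m <- spectral_matrix(X, 1:3)
  m$flags$normalized <- TRUE
  sc <- unit_variance_scale(m)
  expect_equal(apply(sc$X[, 1:2], 2, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(colMeans(sc$X), rep(0, 3), tolerance = 1e-12)
  # constant column: zeros, flagged
  expect_true(sc$zero_variance[3])
  expect_true(all(sc$X[, 3] == 0))
  # rescaling an input column leaves its scaled output unchanged
  X2 <- X; X2[, 1] <- 7 * X2[, 1]
  m2 <- spectral_matrix(X2, 1:3); m2$flags$normalized <- TRUE
  expect_equal(unit_variance_scale(m2)$X[, 1], sc$X[, 1], tolerance = 1e-12)
})

test_that("pipeline order is enforced", {
  X <- matrix(abs(rnorm(40)) + 0.1, 4, 10)
  m <- spectral_matrix(X, 1:10)
  expect_error(unit_variance_scale(m), "normalized")
  mn <- pqn_normalize(m)
  expect_error(apply_exclusions(mn), "before normalization")
  ms <- unit_variance_scale(mn)
  expect_error(stocsy(ms, 5), "not unit-variance scaled")
  expect_error(pqn_normalize(ms), "already scaled")
})

test_that("STOCSY separates peaks of the same molecule from independent ones", {
  meta <- simulate_metadata(cohort_config(n_patients = 10, sites = "tumour",
                                          seed = 3))
  two_peak <- metabolite_template("ab", rbind(
    data.frame(centre_ppm = 2.0, multiplicity = 1L, j_spacing_ppm = 0.01,
               rel_intensity = 1),
    data.frame(centre_ppm = 6.0, multiplicity = 1L, j_spacing_ppm = 0.01,
               rel_intensity = 0.5)))
  other <- singlet_template("c", centre = 8.0)
  third <- singlet_template("d", centre = 9.0)
  sim <- simulate_spectra(meta, list(two_peak, other, third), noise_sd = 0,
                          dilution_log_sd = 0, conc_log_sd = 0.5, seed = 6)
  m <- pqn_normalize(apply_exclusions(bin_spectra(sim$spectra)))
  st <- stocsy(m, 2.0)
  r_at <- function(p) st$r[which.min(abs(st$ppm - p))]
  expect_equal(r_at(2.0), 1, tolerance = 1e-9)        # driver vs itself
  expect_gt(r_at(6.0), 0.99)                           # same molecule
  expect_lt(abs(r_at(8.0)), 0.99)                      # independent molecule
  # r vector matches the direct Pearson formula per column
  j <- which.min(abs(m$bins - 2.0))
  ref <- apply(m$X, 2, function(col)
    suppressWarnings(cor(col, m$X[, j])))
  expect_equal(st$r, unname(ref), tolerance = 1e-10)
})
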