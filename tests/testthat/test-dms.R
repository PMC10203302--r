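test_that("two-Gaussian ionograms resolve the reference peak positions", {
  ig <- simulate_ionogram(c(8, 10.25), width_V = 0.4,
                          height = c(1000, 1000), noise_sd = 5, seed = 3)
  pk <- detect_peaks(ig)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$cv_V[1] - 8), 0.05)
  expect_lt(abs(pk$cv_V[2] - 10.25), 0.05)
  expect_true(all(pk$fwhm_V > 0))
  expect_true(all(diff(pk$cv_V) > 0))  # sorted by CV
})

test_that("a single noiseless Gaussian yields one peak at its centre", {
  ig <- simulate_ionogram(5, width_V = 0.6, height = 800, noise_sd = 0,
                          seed = 1)
  pk <- detect_peaks(ig)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$cv_V - 5), 0.051)
  # FWHM of a Gaussian, inflated slightly by the smoothing kernel
  expect_lt(abs(pk$fwhm_V - 2.3548 * 0.6) / (2.3548 * 0.6), 0.2)
  expect_gt(pk$area, 0)
})

test_that("pure noise below prominence yields no peaks", {
  set.seed(12)
  ig <- ionogram(seq(-20, 20, 0.1), pmax(rnorm(401, 10, 1), 0))
  pk <- detect_peaks(ig, min_prominence_fraction = 0.5)
  expect_equal(nrow(pk), 0)
  flat <- ionogram(seq(-5, 5, 0.1), rep(0, 101))
  expect_equal(nrow(detect_peaks(flat)), 0)
})

test_that("detection is equivariant to intensity scale and CV shift", {
  ig <- simulate_ionogram(c(2, 7), width_V = 0.5, height = c(900, 700),
                          noise_sd = 3, seed = 8)
  pk <- detect_peaks(ig)
  scaled <- ionogram(ig$cv_V, ig$intensity * 7.5)
  expect_equal(detect_peaks(scaled)$cv_V, pk$cv_V)
  shifted <- ionogram(ig$cv_V + 4, ig$intensity)
  expect_equal(detect_peaks(shifted)$cv_V, pk$cv_V + 4, tolerance = 1e-9)
})

test_that("CV-shift series recover the planted modifier response", {
  mk_series <- function(slope, label, noise = 10)
    lapply(c(0, 0.1, 0.2, 0.3, 0.4), function(conc)
      simulate_ionogram(6, slope, width_V = 0.5, height = 1000,
                        noise_sd = noise, concentration = conc,
                        seed = round(1000 * conc) + 7,
                        species_label = label))
  s12 <- cv_shift_series(mk_series(12, "strong"))
  expect_lt(abs(s12$slope_V_per_molpct - 12), 0.12)
  expect_equal(s12$shift_V[1], 0)
  # identical ionograms at all concentrations -> zero slope
  flat <- lapply(c(0, 0.2, 0.4), function(conc) {
    ig <- simulate_ionogram(6, 0, width_V = 0.5, height = 1000,
                            noise_sd = 0, seed = 1,
                            species_label = "flat")
    ig$modifier_mol_percent <- conc
    ig
  })
  expect_equal(cv_shift_series(flat)$slope_V_per_molpct, 0,
               tolerance = 1e-9)
  # ranking places the stronger clusterer first
  s6 <- cv_shift_series(mk_series(6, "weak"))
  rk <- rank_clustering_propensity(list(s6, s12))
  expect_identical(rk$species[1], "strong")
  expect_error(cv_shift_series(list(s12 = flat[[1]],
                                    other = mk_series(3, "x")[[1]])),
               "mixes species")
})

test_that("gaps in a series are reported and the fit continues", {
  good <- lapply(c(0, 0.2, 0.4), function(conc)
    simulate_ionogram(6, 10, width_V = 0.5, height = 1000,
                      concentration = conc, seed = 2,
                      species_label = "g"))
  # blank out the middle concentration
  good[[2]] <- ionogram(good[[2]]$cv_V, rep(0, length(good[[2]]$cv_V)),
                        modifier_mol_percent = 0.2, species_label = "g")
  s <- cv_shift_series(good)
  expect_equal(s$gaps, 0.2)
  expect_true(is.na(s$cv_V[2]))
  expect_lt(abs(s$slope_V_per_molpct - 10), 0.1)
})

test_that("simulated ionograms are deterministic and validated", {
  i1 <- simulate_ionogram(5, 3, noise_sd = 8, concentration = 0.2,
                          seed = 42)
  i2 <- simulate_ionogram(5, 3, noise_sd = 8, concentration = 0.2,
                          seed = 42)
  expect_identical(i1$intensity, i2$intensity)
  expect_equal(i1$cv_V[which.max(simulate_ionogram(5, 3, noise_sd = 0,
    concentration = 0.2, seed = 1)$intensity)], 5 + 3 * 0.2,
    tolerance = 0.051)
  expect_error(ionogram(c(1, 2, 150), c(1, 1, 1)), "within")
  expect_error(ionogram(c(3, 2, 1), c(1, 1, 1)), "increasing")
  expect_error(ionogram(1:3, c(-1, 1, 1)), "non-negative")
})

test_that("ionograms round-trip through CSV with metadata", {
  ig <- simulate_ionogram(4, 0, width_V = 0.5, height = 500, noise_sd = 2,
                          seed = 5, species_label = "speciesA")
  ig$modifier_mol_percent <- 0.3
  f <- tempfile(fileext = ".csv")
  writeLines(c("# modifier_mol_percent: 0.3",
               "# dispersion_voltage_kV: 4.5",
               "# species_label: speciesA",
               "cv_V,intensity",
               sprintf("%.4f,%.4f", ig$cv_V, ig$intensity)), f)
  back <- read_ionogram(f)
  expect_equal(back$intensity, ig$intensity, tolerance = 1e-4)
  expect_equal(back$modifier_mol_percent, 0.3)
  expect_identical(back$species_label, "speciesA")
})
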