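test_that("PA CCS reproduces the analytic single-disk limit", {
  cf <- conformer(data.frame(element = "C", name = "X", resid = 1,
                             x = 0, y = 0, z = 0, radius = 1.5,
                             charge = 0), label = "one")
  res <- pa_ccs(cf, probe_radius_A = 1.0, n_orientations = 50, seed = 3)
  # identical projections: only binomial hit-sampling error remains
  expect_lt(abs(res$ccs_A2 - pi * 2.5^2), max(3 * res$std_error_A2, 0.15))
  expect_lt(abs(res$ccs_A2 - pi * 2.5^2) / (pi * 2.5^2), 0.02)
})

test_that("two distant spheres project to twice the single-disk area", {
  atoms <- data.frame(element = "C", name = "X", resid = c(1, 2),
                      x = 0, y = 0, z = c(0, 100), radius = 1.5,
                      charge = 0)
  res <- pa_ccs(conformer(atoms, label = "two"), probe_radius_A = 1.0,
                n_orientations = 150, seed = 3)
  expect_lt(abs(res$ccs_A2 - 2 * pi * 2.5^2), 3 * res$std_error_A2 + 0.2)
})

test_that("PA CCS agrees with the grid-rasterisation oracle within 1%", {
  cf <- random_coil_conformer(50, seed = 7)
  n_or <- 40
  res <- pa_ccs(cf, probe_radius_A = 1.0, n_orientations = n_or,
                n_hits = 20000, seed = 11)
  rot <- quasi_rotations(n_or, 11)  # the same orientation set
  oracle <- mean(raster_areas(cf, 1.0, rot))
  expect_lt(abs(res$ccs_A2 - oracle) / oracle, 0.01)
})

test_that("inflating atomic radii strictly increases the PA CCS", {
  cf <- random_coil_conformer(30, seed = 5)
  base <- pa_ccs(cf, probe_radius_A = 1.0, n_orientations = 100, seed = 2)
  for (delta in c(0.3, 0.6)) {
    big <- cf
    big$atoms$radius <- cf$atoms$radius + delta
    res <- pa_ccs(big, probe_radius_A = 1.0, n_orientations = 100,
                  seed = 2)
    expect_gt(res$ccs_A2, base$ccs_A2)
  }
})

test_that("PA CCS is invariant under rigid motion within Monte-Carlo error", {
  cf <- random_coil_conformer(30, seed = 9)
  res1 <- pa_ccs(cf, n_orientations = 150, seed = 4)
  R <- conformerge:::axis_angle_matrix(c(1, 2, 3), 1.1)
  xyz <- conformer_coords(cf) %*% t(R)
  moved <- conformerge:::set_coords(cf, sweep(xyz, 2, c(10, -5, 3), "+"))
  res2 <- pa_ccs(moved, n_orientations = 150, seed = 8)
  expect_lt(abs(res1$ccs_A2 - res2$ccs_A2),
            3 * sqrt(res1$std_error_A2^2 + res2$std_error_A2^2))
})

test_that("a compact helix has a smaller CCS than the extended chain", {
  seq24 <- "CAAAHAAAHAAAAHAAAHAAACAK"
  hel <- pa_ccs(build_peptide(seq24, "helix"), n_orientations = 80,
                seed = 1)
  ext <- pa_ccs(build_peptide(seq24, "extended"), n_orientations = 80,
                seed = 1)
  expect_lt(hel$ccs_A2, ext$ccs_A2)
})

test_that("PA CCS rejects degenerate inputs", {
  cf <- random_coil_conformer(5, seed = 1)
  expect_error(pa_ccs(cf, n_orientations = 5), "at least 10")
  bad <- cf
  bad$atoms$radius[2] <- -2  # cancels the probe radius exactly at 0 < r
  bad$atoms$radius[3] <- -1.5
  expect_error(pa_ccs(bad, probe_radius_A = 1.0), "positive")
})

test_that("ccs_distribution preserves order and tolerates failures", {
  confs <- lapply(1:3, function(i) {
    cf <- random_coil_conformer(10, seed = 100)
    cf$label <- sprintf("c%d", i)
    cf
  })
  ens <- conformer_ensemble(confs)
  out <- ccs_distribution(ens, n_orientations = 60, seed = 1)
  ccs <- vapply(out$conformers, function(x) x$ccs$ccs_A2, numeric(1))
  # identical geometries: equal means within Monte-Carlo error
  se <- vapply(out$conformers, function(x) x$ccs$std_error_A2, numeric(1))
  expect_lt(max(ccs) - min(ccs), 6 * max(se))
  expect_identical(vapply(out$conformers, function(x) x$label,
                          character(1)), c("c1", "c2", "c3"))
  # a broken conformer is reported, not fatal
  confs[[2]]$atoms$radius[] <- -5
  expect_warning(out2 <- ccs_distribution(conformer_ensemble(confs),
                                          n_orientations = 20, seed = 1),
                 "failed")
  expect_named(attr(out2, "failures"), "c2")
  expect_error(ccs_distribution(structure(list(conformers = list()),
                                          class = "conformer_ensemble")),
               "empty")
})
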