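neutral_atom_conformer <- function() {
  conformer(data.frame(element = "C", name = "X", resid = 1, x = 0, y = 0,
                       z = 0, radius = 1.7, charge = 0), label = "n1")
}

test_that("the probe map decays to zero far from a neutral solute", {
  m <- energy_map(neutral_atom_conformer(), spacing_A = 1, margin_A = 10,
                  n_orient = 8, seed = 1)
  corner <- m$energy[1, 1, 1]  # ~17 A from the atom
  expect_lt(abs(corner), 0.01)
})

test_that("voxels inside the solute core are clamped", {
  m <- energy_map(neutral_atom_conformer(), spacing_A = 1, margin_A = 4,
                  n_orient = 8, seed = 1)
  centre <- vapply(1:3, function(d)
    which.min(abs(m$origin[d] + (seq_len(m$dims[d]) - 1) * m$spacing)),
    integer(1))
  expect_equal(m$energy[centre[1], centre[2], centre[3]], 50)
})

test_that("an ion-dipole probe approaches the aligned closed form", {
  ion <- conformer(data.frame(element = "C", name = "Q", resid = 1,
                              x = 0, y = 0, z = 0, radius = 1.0,
                              charge = 1), label = "ion")
  # two-site dipole, LJ disabled through zero well depths
  pr <- solvent_probe(rbind(c(-0.5, 0, 0), c(0.5, 0, 0)),
                      charge = c(0.25, -0.25), sigma = c(0.1, 0.1),
                      eps = c(0, 0), vdw = c(0.3, 0.3), name = "dipole")
  m <- energy_map(ion, pr, spacing_A = 1, margin_A = 5, n_orient = 64,
                  seed = 4)
  ix <- which.min(abs(m$origin[1] + (seq_len(m$dims[1]) - 1) - 5))
  iy <- which.min(abs(m$origin[2] + (seq_len(m$dims[2]) - 1)))
  iz <- which.min(abs(m$origin[3] + (seq_len(m$dims[3]) - 1)))
  vox <- m$energy[ix, iy, iz]
  exact <- 332.0636 * 0.25 * (1 / 5.5 - 1 / 4.5)  # aligned optimum at 5 A
  expect_lt(vox, 0)
  expect_gte(vox, exact)  # the sampled minimum cannot beat aligned
  expect_lt(abs(vox - exact) / abs(exact), 0.2)  # sampling tolerance
  # denser orientation sampling converges towards the closed form
  m2 <- energy_map(ion, pr, spacing_A = 1, margin_A = 5, n_orient = 512,
                   seed = 4)
  vox2 <- m2$energy[ix, iy, iz]
  expect_lt(abs(vox2 - exact), abs(vox - exact) + 1e-9)
  expect_lt(abs(vox2 - exact) / abs(exact), 0.05)
})

test_that("site extraction equals exhaustive enumeration on random maps", {
  for (seed in 1:3) {
    set.seed(seed)
    raw <- array(rnorm(10 * 9 * 8, mean = 0.5, sd = 1.5), c(10, 9, 8))
    m <- synthetic_map(raw)
    got <- find_sites(m, threshold_kcal = -1.5, min_separation_A = 3.5)
    want <- find_sites_oracle(m, -1.5, 3.5)
    expect_equal(nrow(got), nrow(want))
    expect_equal(cbind(got$ix, got$iy, got$iz),
                 unname(want[, 1:3, drop = FALSE]))
    expect_true(all(got$energy_kcal <= -1.5))
  }
})

test_that("site counts shrink with stricter thresholds and larger separations", {
  cf <- polar_chain_conformer("exposed", 1)
  m <- energy_map(cf, spacing_A = 1, margin_A = 5, n_orient = 16, seed = 5)
  n_thr <- vapply(c(-1.5, -2.5, -3.5), function(thr)
    nrow(find_sites(m, threshold_kcal = thr)), integer(1))
  expect_true(all(diff(n_thr) <= 0))
  n_sep <- vapply(c(2.5, 3.5, 5, 8), function(sep)
    nrow(find_sites(m, min_separation_A = sep)), integer(1))
  expect_true(all(diff(n_sep) <= 0))
  expect_identical(nrow(find_sites(m, threshold_kcal = -1e4)), 0L)
})

test_that("two well-separated wells give two sites at the well centres", {
  E <- array(0, c(15, 7, 7))
  for (i in 1:15) for (j in 1:7) for (k in 1:7) {
    E[i, j, k] <- -3 * exp(-((i - 3)^2 + (j - 4)^2 + (k - 4)^2) / 4) -
      3 * exp(-((i - 13)^2 + (j - 4)^2 + (k - 4)^2) / 4)
  }
  s <- find_sites(synthetic_map(E), threshold_kcal = -1.5)
  expect_equal(nrow(s), 2)
  expect_setequal(s$ix, c(3, 13))
  expect_true(all(s$iy == 4 & s$iz == 4))
})

test_that("probe placement respects sites, clashes and additivity", {
  cf <- polar_chain_conformer("exposed", 2)
  m <- energy_map(cf, spacing_A = 1, margin_A = 5, n_orient = 16, seed = 5)
  sites <- find_sites(m)
  cx <- suppressWarnings(place_probes(cf, sites, m))
  expect_lte(cx$n_sites, nrow(sites))
  expect_lt(cx$e_interaction_kcal, 0)
  # relaxation can only improve on the voxel energy (small slack allowed)
  for (k in seq_along(cx$probes))
    expect_lte(cx$probes[[k]]$energy_kcal,
               cx$probes[[k]]$site_energy_kcal + 0.5)
  # placed probes never overlap
  if (cx$n_sites > 1) {
    centres <- t(vapply(cx$probes, function(p) p$centre, numeric(3)))
    expect_gt(min(dist(centres)), 2.5)
  }
  # no sites -> empty complex
  none <- find_sites(m, threshold_kcal = -1e4)
  cx0 <- place_probes(cf, none, m)
  expect_identical(cx0$n_sites, 0L)
  expect_equal(cx0$e_interaction_kcal, 0)
  expect_equal(lie_energy(cx0), 0)
})

test_that("the total interaction energy is the sum of per-probe energies", {
  cf <- polar_chain_conformer("exposed", 3)
  m <- energy_map(cf, spacing_A = 1, margin_A = 5, n_orient = 16, seed = 5)
  cx <- suppressWarnings(place_probes(cf, find_sites(m), m))
  per <- vapply(cx$probes, function(p) p$energy_kcal, numeric(1))
  expect_equal(cx$e_interaction_kcal, sum(per), tolerance = 1e-9)
  expect_equal(lie_energy(cx), cx$e_interaction_kcal, tolerance = 1e-7)
})

test_that("lie_energy matches an independent double-loop reference", {
  cf <- polar_chain_conformer("buried", 4)
  m <- energy_map(cf, spacing_A = 1, margin_A = 5, n_orient = 16, seed = 5)
  cx <- suppressWarnings(place_probes(cf, find_sites(m), m))
  expect_gt(length(cx$probes), 0)
  expect_equal(lie_energy(cx), lie_oracle(cx), tolerance = 1e-8)
})

test_that("deepening a solute charge deepens the nearby map minimum", {
  mk <- function(q) conformer(
    data.frame(element = "N", name = "Q", resid = 1, x = 0, y = 0, z = 0,
               radius = 1.6, charge = q), label = sprintf("q%g", q))
  dmin <- vapply(c(0.3, 0.6, 1.0), function(q)
    min(energy_map(mk(q), spacing_A = 0.5, margin_A = 4, n_orient = 16,
                   seed = 2)$energy), numeric(1))
  expect_true(all(diff(dmin) < 0))
})

test_that("exposed polar chains out-solvate compact buried balls", {
  ex <- lapply(1:3, function(s)
    microsolvate(polar_chain_conformer("exposed", s)))
  bu <- lapply(1:3, function(s)
    microsolvate(polar_chain_conformer("buried", s + 10)))
  n_ex <- vapply(ex, function(x) x$n_sites, numeric(1))
  n_bu <- vapply(bu, function(x) x$n_sites, numeric(1))
  e_ex <- vapply(ex, function(x) x$e_interaction_kcal, numeric(1))
  e_bu <- vapply(bu, function(x) x$e_interaction_kcal, numeric(1))
  expect_true(all(n_ex >= n_bu))
  expect_lt(mean(e_ex), mean(e_bu))  # more favourable when exposed
  cmp <- compare_ensembles(ex, bu, labels = c("exposed", "buried"))
  expect_gt(cmp$difference$n_sites, 0)
  expect_lt(cmp$difference$e_interaction, 0)
  expect_identical(cmp$exposed$n, 3L)
  expect_identical(cmp$buried$n, 3L)
  expect_warning(compare_ensembles(ex[1], bu, labels = c("a", "b")),
                 "singleton")
})

test_that("probes are validated and maps exportable as OpenDX text", {
  expect_error(solvent_probe(rbind(c(0, 0, 0)), charge = 0.5, sigma = 3,
                             eps = 0.1, vdw = 1.5), "net charge")
  expect_error(energy_map(neutral_atom_conformer(), spacing_A = 0.1),
               "spacing")
  m <- energy_map(neutral_atom_conformer(), spacing_A = 1, margin_A = 3,
                  n_orient = 4, seed = 1)
  f <- tempfile(fileext = ".dx")
  write_dx(m, f)
  lines <- readLines(f)
  expect_match(lines[1], sprintf("counts %d %d %d", m$dims[1], m$dims[2],
                                 m$dims[3]))
  expect_match(lines[7], sprintf("items %d", prod(m$dims)))
  vals <- as.numeric(unlist(strsplit(paste(lines[-(1:7)], collapse = " "),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  expect_length(vals, prod(m$dims))
})
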