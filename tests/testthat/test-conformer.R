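seq24 <- "CAAAHAAAHAAAAHAAAHAAACAK"

test_that("the helix builder reproduces canonical alpha-helix geometry", {
  cf <- build_peptide(seq24, "helix")
  a <- cf$atoms
  ca <- as.matrix(a[a$name == "CA", c("x", "y", "z")])
  axis <- prcomp(ca)$rotation[, 1]
  rise <- mean(abs(diff(ca %*% axis)))
  expect_gt(rise, 1.4)   # ~1.5 A per residue
  expect_lt(rise, 1.65)
  span <- diff(range(ca %*% axis))
  expect_lt(abs(span - 1.5 * 23), 2.5)  # axial span ~ rise x 23
})

test_that("extended chains are longer than helices of the same sequence", {
  hel <- build_peptide(seq24, "helix")
  ext <- build_peptide(seq24, "extended")
  ee <- function(cf) {
    xyz <- conformer_coords(cf)
    b <- cf$atoms$name %in% c("N", "CA", "C")
    max(dist(xyz[b, ][c(1, sum(b)), ]))
  }
  expect_gt(ee(ext), ee(hel))
  expect_gt(marker_distance(ext), marker_distance(hel))
})

test_that("peptide construction is deterministic and validated", {
  c1 <- build_peptide("ACDEFGHIK", "coil", seed = 3)
  c2 <- build_peptide("ACDEFGHIK", "coil", seed = 3)
  expect_identical(conformer_coords(c1), conformer_coords(c2))
  c3 <- build_peptide("ACDEFGHIK", "coil", seed = 4)
  expect_false(identical(conformer_coords(c1), conformer_coords(c3)))
  expect_error(build_peptide("ACDXFG"), "unknown residue")
  expect_error(build_peptide("A"), "at least 2")
  expect_error(build_peptide("ACDEF", marker_sites = 2), "2 marker")
  expect_error(build_peptide("ACDEF", marker_sites = c(1, 9)),
               "out of range")
})

test_that("charge assignment puts protons and dye charges where asked", {
  cf <- build_peptide("ACAAKA", charge_sites = 5, marker_charges = c(1, 1))
  a <- cf$atoms
  expect_equal(a$charge[a$resid == 5 & a$name == "CB"], 1)
  expect_equal(a$charge[a$name == "DYE"], c(1, 1))
  # backbone amide dipoles cancel within each residue
  expect_equal(sum(a$charge), 3)
})

test_that("marker distance is Euclidean and rigid-motion invariant", {
  cf <- dummy_conformer("d", r_da = 10)
  expect_equal(marker_distance(cf), 10)
  R <- conformerge:::axis_angle_matrix(c(0, 1, 1), 0.7)
  xyz <- sweep(conformer_coords(cf) %*% t(R), 2, c(3, -2, 8), "+")
  expect_equal(marker_distance(conformerge:::set_coords(cf, xyz)), 10,
               tolerance = 1e-12)
  cf$donor_marker <- NA_integer_
  expect_error(marker_distance(cf), "unset")
})

test_that("conformers round-trip through PDB with annotations intact", {
  cf <- build_peptide("ACAAKA", "helix", charge_sites = 5)
  cf$energy <- -12.345678
  f <- tempfile(fileext = ".pdb")
  write_pdb(cf, f)
  back <- read_pdb(f)
  expect_equal(conformer_coords(back), conformer_coords(cf),
               tolerance = 1.1e-3)
  expect_equal(back$atoms$radius, cf$atoms$radius, tolerance = 6e-3)
  expect_equal(back$atoms$charge, cf$atoms$charge, tolerance = 6e-3)
  expect_identical(back$donor_marker, cf$donor_marker)
  expect_identical(back$acceptor_marker, cf$acceptor_marker)
  expect_equal(back$energy, cf$energy, tolerance = 1e-5)
  expect_identical(back$label, cf$label)
})

test_that("PDB reading rejects malformed input with line numbers", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK hello", "END"), f)
  expect_error(read_pdb(f), "no ATOM")
  writeLines(c("ATOM      1  CA  ALA A   1      bad coords here",
               "END"), f)
  expect_error(read_pdb(f), "line 1")
  writeLines("ATOM      1  CA", f)
  expect_error(read_pdb(f), "line 1")
})

test_that("missing element columns are inferred from atom names", {
  f <- tempfile(fileext = ".pdb")
  writeLines(sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    1:3, 1:3, c(0, 3, 6), 0, 0, 1.7, 0.0), f)
  expect_warning(cf <- read_pdb(f), "inferring")
  expect_identical(cf$atoms$element, rep("C", 3))
})

test_that("ensembles enforce unique labels", {
  expect_error(conformer_ensemble(list(dummy_conformer("a"),
                                       dummy_conformer("a"))), "unique")
  expect_error(conformer_ensemble(list()), "length")
})
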