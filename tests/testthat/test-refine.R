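test_that("the energy filter keeps the lowest-energy rank percentile", {
  set.seed(1)
  n <- 200
  df <- data.frame(label = sprintf("c%03d", 1:n),
                   energy = rnorm(n, 50, 20),
                   ccs = runif(n, 500, 700), r_da = runif(n, 40, 90))
  ens <- dummy_ensemble(df)
  out <- energy_filter(ens, 0.2)
  expect_length(out$conformers, 40)
  kept <- vapply(out$conformers, function(x) x$energy, numeric(1))
  dropped <- setdiff(df$energy, kept)
  expect_lte(max(kept), min(dropped))          # rank property
  expect_length(energy_filter(ens, 1.0)$conformers, n)  # identity at f=1
  expect_error(energy_filter(ens, 0), "fraction")
  ens$conformers[[3]]$energy <- NA_real_
  expect_error(energy_filter(ens, 0.5), "unscored")
})

test_that("CCS matching applies symmetric fractional windows", {
  df <- data.frame(label = c("a", "b", "c"), energy = 1,
                   ccs = c(612, 606, 700), r_da = 50)
  ens <- dummy_ensemble(df)
  peaks <- data.frame(label = "P", ccs_A2 = 600,
                      tolerance_fraction = 0.02)
  g <- ccs_match(ens, peaks)
  labs <- vapply(g$P$conformers, function(x) x$label, character(1))
  expect_identical(labs, "b")  # 612 sits on the edge and is excluded
  expect_setequal(attr(g, "unassigned"), c("a", "c"))
  # two disjoint windows share no conformer
  peaks2 <- data.frame(label = c("L", "H"), ccs_A2 = c(610, 700),
                       tolerance_fraction = 0.02)
  g2 <- ccs_match(ens, peaks2)
  expect_length(intersect(
    vapply(g2$L$conformers, function(x) x$label, character(1)),
    vapply(g2$H$conformers, function(x) x$label, character(1))), 0)
  # nothing matching anywhere is an error
  peaks3 <- data.frame(label = "X", ccs_A2 = 100,
                       tolerance_fraction = 0.01)
  expect_error(ccs_match(ens, peaks3), "inconsistent")
})

test_that("window membership is strict at the fractional edge", {
  df <- data.frame(label = c("edge", "inside"), energy = 1,
                   ccs = c(612, 611.9), r_da = 50)
  g <- ccs_match(dummy_ensemble(df),
                 data.frame(label = "P", ccs_A2 = 600,
                            tolerance_fraction = 0.02))
  expect_identical(vapply(g$P$conformers, function(x) x$label,
                          character(1)), "inside")
})

test_that("planted two-population CCS ensembles are assigned correctly", {
  set.seed(7)
  n <- 100
  truth <- rep(c("C1", "C2"), each = n)
  ccs <- c(rnorm(n, 560, 5), rnorm(n, 630, 5))
  df <- data.frame(label = sprintf("x%03d", seq_len(2 * n)), energy = 1,
                   ccs = ccs, r_da = 50)
  peaks <- data.frame(label = c("C1", "C2"), ccs_A2 = c(560, 630),
                      tolerance_fraction = 0.02)
  g <- ccs_match(dummy_ensemble(df), peaks)
  assigned <- rep(NA_character_, 2 * n)
  for (p in names(g))
    assigned[match(vapply(g[[p]]$conformers, function(x) x$label,
                          character(1)), df$label)] <- p
  expect_gte(mean(assigned == truth, na.rm = TRUE), 0.95)
  expect_gte(mean(!is.na(assigned)), 0.95)
})

test_that("distance selection implements both rules with deterministic ties", {
  df <- data.frame(label = c("a", "b", "c", "d", "e"), energy = 1,
                   ccs = 600, r_da = c(60, 66, 70, 75, 80))
  g <- dummy_ensemble(df)
  below <- distance_select(g, 71.5, "closest_below", k = 2)
  expect_identical(vapply(below$conformers, function(x) x$label,
                          character(1)), c("c", "b"))  # 70 then 66
  closest <- distance_select(g, 71.5, "closest", k = 2)
  expect_setequal(vapply(closest$conformers, function(x) x$label,
                         character(1)), c("c", "d"))   # 70 and 75
  expect_length(distance_select(g, 71.5, "closest", k = 99)$conformers, 5)
  # shortfall below r_exp falls back with a warning
  expect_warning(fb <- distance_select(g, 62, "closest_below", k = 3),
                 "filling by closest")
  expect_length(fb$conformers, 3)
  expect_error(distance_select(
    structure(list(conformers = list()), class = "conformer_ensemble"),
    50, "closest", 2), "empty")
})

test_that("overestimation is the signed percent gap to the mean", {
  expect_equal(overestimation_report(77.5, rep(71.7, 5)), 7.48,
               tolerance = 1e-2)
  expect_equal(overestimation_report(77.5, rep(66.5, 5)), 14.19,
               tolerance = 1e-2)
  expect_equal(overestimation_report(50, c(50, 50)), 0)
  expect_lt(overestimation_report(50, c(60, 60)), 0)  # underestimation
  expect_error(overestimation_report(-1, 5), "positive")
})

make_planted <- function(seed = 101) {
  set.seed(seed)
  n_decoy <- 500
  decoys <- data.frame(label = sprintf("d%03d", 1:n_decoy),
                       energy = runif(n_decoy, 5, 100),
                       ccs = runif(n_decoy, 450, 750),
                       r_da = runif(n_decoy, 30, 110))
  planted <- data.frame(
    label = sprintf("p%02d", 1:10),
    energy = runif(10, 0, 2),           # safely in the lowest 20 %
    ccs = c(560 + runif(5, -4, 4), 630 + runif(5, -4, 4)),
    r_da = 71.5 + runif(10, -0.5, 0.5)) # nearest the experimental value
  dummy_ensemble(rbind(decoys, planted))
}

test_that("the cascade recovers planted structures among 500 decoys", {
  ens <- make_planted()
  cons <- experimental_constraints(
    data.frame(label = c("C1", "C2"), ccs_A2 = c(560, 630),
               tolerance_fraction = 0.02),
    r_da_A = 71.5, selection_rule = "closest", k_select = 5)
  res <- run_cascade(ens, cons, 0.2)
  expect_gte(sum(grepl("^p0[1-5]$", res$peaks$C1$labels)), 4)
  expect_gte(sum(grepl("^p(0[6-9]|10)$", res$peaks$C2$labels)), 4)
  # stage counts monotone non-increasing
  expect_lte(res$counts$energy_filter, res$counts$input)
  expect_true(all(res$counts$ccs_match <= res$counts$energy_filter))
  expect_true(all(res$counts$selected <= res$counts$ccs_match))
})

test_that("cascade selection equals exhaustive enumeration of the predicates", {
  set.seed(55)
  n <- 150
  df <- data.frame(label = sprintf("c%03d", 1:n),
                   energy = runif(n, 0, 100),
                   ccs = runif(n, 520, 700),
                   r_da = runif(n, 40, 100))
  ens <- dummy_ensemble(df)
  cons <- experimental_constraints(
    data.frame(label = "P", ccs_A2 = 590, tolerance_fraction = 0.05),
    r_da_A = 70, selection_rule = "closest", k_select = 5)
  res <- run_cascade(ens, cons, 0.2)
  # independent brute-force re-derivation
  keep <- df[rank(df$energy, ties.method = "first") <=
               ceiling(0.2 * n), ]
  inwin <- keep[keep$ccs >= 590 * 0.95 & keep$ccs <= 590 * 1.05, ]
  want <- inwin$label[order(abs(inwin$r_da - 70), inwin$label)][1:5]
  expect_setequal(res$peaks$P$labels, want[!is.na(want)])
  # every selected conformer satisfies the stage predicates post hoc
  sel <- df[df$label %in% res$peaks$P$labels, ]
  expect_true(all(sel$energy <= max(keep$energy)))
  expect_true(all(sel$ccs >= 590 * 0.95 & sel$ccs <= 590 * 1.05))
})

test_that("shuffling the ensemble does not change the selection", {
  ens <- make_planted(202)
  cons <- experimental_constraints(
    data.frame(label = "C1", ccs_A2 = 560, tolerance_fraction = 0.02),
    r_da_A = 71.5, selection_rule = "closest_below", k_select = 5)
  r1 <- run_cascade(ens, cons, 0.2)
  set.seed(9)
  shuf <- ens
  shuf$conformers <- ens$conformers[sample(length(ens$conformers))]
  r2 <- run_cascade(shuf, cons, 0.2)
  expect_setequal(r1$peaks$C1$labels, r2$peaks$C1$labels)
  expect_equal(r1$peaks$C1$overestimation_percent,
               r2$peaks$C1$overestimation_percent)
})

test_that("full-ensemble composition identity holds at f = 1", {
  df <- data.frame(label = sprintf("c%d", 1:20), energy = runif(20),
                   ccs = runif(20, 590, 610), r_da = runif(20, 50, 70))
  ens <- dummy_ensemble(df)
  cons <- experimental_constraints(
    data.frame(label = "P", ccs_A2 = 600, tolerance_fraction = 0.2),
    r_da_A = 80, selection_rule = "closest", k_select = 20)
  res <- run_cascade(ens, cons, 1.0)
  expect_length(res$peaks$P$labels, 20)
  expect_equal(res$peaks$P$overestimation_percent,
               100 * (80 - mean(df$r_da)) / 80)
})

test_that("each peak can carry its own experimental distance", {
  ens <- make_planted(303)
  cons <- experimental_constraints(
    data.frame(label = c("C1", "C2"), ccs_A2 = c(560, 630),
               tolerance_fraction = 0.02),
    r_da_A = c(C1 = 60, C2 = 85), selection_rule = "closest",
    k_select = 3)
  res <- run_cascade(ens, cons, 0.5)
  expect_equal(res$peaks$C1$r_exp_A, 60)
  expect_equal(res$peaks$C2$r_exp_A, 85)
  r1 <- vapply(res$selections$C1$conformers, marker_distance, numeric(1))
  r2 <- vapply(res$selections$C2$conformers, marker_distance, numeric(1))
  expect_lt(mean(abs(r1 - 60)), mean(abs(r1 - 85)))
  expect_lt(mean(abs(r2 - 85)), mean(abs(r2 - 60)))
})

test_that("constraint construction enforces invariants", {
  pk <- data.frame(label = "P", ccs_A2 = 600, tolerance_fraction = 0.02)
  expect_error(experimental_constraints(pk, r_da_A = -1), "positive")
  expect_error(experimental_constraints(
    data.frame(label = "P", ccs_A2 = 600, tolerance_fraction = 0.5),
    r_da_A = 70), "tolerance")
  expect_error(experimental_constraints(pk, r_da_A = 70, k_select = 0),
               "k_select")
})
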