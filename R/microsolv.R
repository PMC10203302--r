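# Probe-grid microsolvation: minimum-energy interaction map of a rigid
# solvent probe around a conformer, site extraction below an energy
# threshold, explicit probe placement and linear-interaction-energy (LIE)
# totals. The map is a direct probe energetics stand-in for
# trajectory-averaged grid solvation analysis: it locates favourable sites
# and scores them on the model's own energy scale.

#' Construct a rigid solvent probe
#'
#' @param offsets k x 3 matrix of site offsets from the probe centre,
#'   Angstrom.
#' @param charge per-site partial charges, e (must sum to ~0).
#' @param sigma,eps per-site LJ parameters (Angstrom, kcal/mol).
#' @param vdw per-site van der Waals radii for clash clamping, Angstrom.
#' @param name probe name.
#' @param reference_self_energy_kcal bulk solvent-solvent interaction
#'   energy carried as metadata for judging whether a site out-competes
#'   bulk solvation.
#' @return an object of class `solvent_probe`.
#' @export
solvent_probe <- function(offsets, charge, sigma, eps, vdw,
                          name = "probe",
                          reference_self_energy_kcal = NA_real_) {
  offsets <- as.matrix(offsets)
  k <- nrow(offsets)
  stopifnot(k >= 1, ncol(offsets) == 3,
            length(charge) == k, length(sigma) == k, length(eps) == k,
            length(vdw) == k)
  if (abs(sum(charge)) > 1e-6) stop("probe net charge must be ~0")
  structure(list(offsets = offsets, charge = charge, sigma = sigma,
                 eps = eps, vdw = vdw, name = name,
                 reference_self_energy_kcal = reference_self_energy_kcal),
            class = "solvent_probe")
}

#' Three-site acetonitrile-like probe
#'
#' Rigid collinear methyl-C-N model with charges summing to zero, used as
#' the gas-modifier probe. The bulk solvent-solvent reference energy
#' default is -7.006 kcal/mol.
#'
#' @param reference_self_energy_kcal bulk reference energy, kcal/mol.
#' @return a [solvent_probe()].
#' @export
acetonitrile_probe <- function(reference_self_energy_kcal = -7.006) {
  solvent_probe(
    offsets = rbind(c(-1.46, 0, 0), c(0, 0, 0), c(1.157, 0, 0)),
    charge = c(0.269, 0.129, -0.398),
    sigma = c(3.775, 3.40, 3.25),
    eps = c(0.207, 0.099, 0.170),
    vdw = c(2.0, 1.7, 1.6),
    name = "acetonitrile",
    reference_self_energy_kcal = reference_self_energy_kcal)
}

#' Probe interaction-energy map
#'
#' Evaluates, at every voxel centre of a regular grid spanning the
#' conformer's bounding box plus `margin_A`, the minimum over `n_orient`
#' quasi-random probe orientations of the probe-solute LJ + Coulomb energy.
#' Orientations placing any probe site within 0.7 x (sum of van der Waals
#' radii) of a solute atom are clamped to +50 kcal/mol.
#'
#' @param conf a [conformer()] with radii and charges.
#' @param probe a [solvent_probe()].
#' @param spacing_A grid spacing in \[0.25, 1\] Angstrom.
#' @param margin_A margin beyond the bounding box, Angstrom.
#' @param n_orient probe orientations per voxel.
#' @param seed seed for the orientation set.
#' @return an object of class `solvation_map`: `origin`, `spacing`, `dims`,
#'   3-d arrays `energy` and `orientation` (argmin index), the rotation
#'   set, probe and parameters.
#' @export
energy_map <- function(conf, probe = acetonitrile_probe(), spacing_A = 0.5,
                       margin_A = 6, n_orient = 32, seed = 1) {
  stopifnot(inherits(conf, "conformer"), inherits(probe, "solvent_probe"))
  if (spacing_A < 0.25 || spacing_A > 1.0)
    stop("spacing_A must be in [0.25, 1.0]")
  xyz <- conformer_coords(conf)
  lo <- apply(xyz, 2, min) - margin_A
  hi <- apply(xyz, 2, max) + margin_A
  ax <- lapply(1:3, function(d) seq(lo[d], hi[d], by = spacing_A))
  dims <- vapply(ax, length, integer(1))
  if (prod(dims) > 1e7) stop("grid exceeds 1e7 voxels: reduce margin/spacing")
  vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  rot <- quasi_rotations(n_orient, seed)
  lj <- atom_lj_params(conf$atoms)
  res <- cpp_grid_map(vox, xyz, conf$atoms$charge, lj$sigma, lj$eps,
                      conf$atoms$radius, probe$offsets, probe$charge,
                      probe$sigma, probe$eps, probe$vdw, as.numeric(rot),
                      50.0)
  structure(list(origin = lo, spacing = spacing_A, dims = dims,
                 energy = array(res$energy, dims),
                 orientation = array(res$orientation, dims),
                 rotations = rot, probe = probe, n_orient = n_orient,
                 seed = seed, clamp = 50),
            class = "solvation_map")
}

#' @export
print.solvation_map <- function(x, ...) {
  cat(sprintf("Solvation map %d x %d x %d @ %.2f A (probe: %s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$probe$name))
  cat(sprintf("  energy range: %.2f .. %.2f kcal/mol\n",
              min(x$energy), max(x$energy)))
  invisible(x)
}

#' Extract microsolvation sites from a map
#'
#' Sites are local minima (26-neighbourhood) among voxels below
#' `threshold_kcal`, accepted greedily in order of ascending energy subject
#' to a pairwise separation of at least `min_separation_A`. Deterministic;
#' an empty site list is a valid result.
#'
#' @param map a [energy_map()] result.
#' @param threshold_kcal site threshold; default -1.5 kcal/mol.
#' @param min_separation_A minimum distance between accepted sites.
#' @return data frame of class `solvation_sites`: `x`, `y`, `z`,
#'   `energy_kcal`, grid indices and the map-minimising orientation index.
#' @export
find_sites <- function(map, threshold_kcal = -1.5, min_separation_A = 3.5) {
  stopifnot(inherits(map, "solvation_map"))
  E <- map$energy
  d <- map$dims
  cand <- which(E < threshold_kcal, arr.ind = TRUE)
  sites <- list()
  if (nrow(cand)) {
    is_min <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
      e0 <- E[i, j, k]
      nb <- E[max(1, i - 1):min(d[1], i + 1),
              max(1, j - 1):min(d[2], j + 1),
              max(1, k - 1):min(d[3], k + 1)]
      is_min[r] <- all(e0 <= nb)
    }
    cand <- cand[is_min, , drop = FALSE]
    if (nrow(cand)) {
      en <- E[cand]
      pos <- sweep((cand - 1) * map$spacing, 2, map$origin, "+")
      ord <- order(en)
      acc <- integer(0)
      for (r in ord) {
        if (!length(acc) ||
            all(sqrt(rowSums(sweep(pos[acc, , drop = FALSE], 2,
                                   pos[r, ])^2)) >= min_separation_A))
          acc <- c(acc, r)
      }
      sites <- data.frame(x = pos[acc, 1], y = pos[acc, 2], z = pos[acc, 3],
                          energy_kcal = en[acc],
                          ix = cand[acc, 1], iy = cand[acc, 2],
                          iz = cand[acc, 3],
                          orientation = map$orientation[cand[acc, ,
                                                             drop = FALSE]])
    }
  }
  if (!length(sites))
    sites <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        energy_kcal = numeric(0), ix = integer(0),
                        iy = integer(0), iz = integer(0),
                        orientation = integer(0))
  class(sites) <- c("solvation_sites", "data.frame")
  attr(sites, "threshold_kcal") <- threshold_kcal
  attr(sites, "min_separation_A") <- min_separation_A
  sites
}

#' @noRd
probe_site_coords <- function(probe, centre, R) {
  sweep(probe$offsets %*% t(R), 2, centre, "+")
}

#' @noRd
probe_solute_energy <- function(coords, probe, solute_xyz, solute_q,
                                solute_lj) {
  cpp_inter_energy(coords, probe$charge, probe$sigma, probe$eps,
                   solute_xyz, solute_q, solute_lj$sigma, solute_lj$eps)
}

#' Place explicit probes at microsolvation sites
#'
#' Puts one rigid probe per site, starting at the site's map-minimising
#' orientation, then relaxes each probe by a short rigid-body optimisation
#' (translation bounded by `max_shift_A`, free reorientation). Probes whose
#' relaxed energy still indicates a clash, or which come within 2.5 A of an
#' already placed probe, are skipped with a warning.
#'
#' @param conf the [conformer()].
#' @param sites a [find_sites()] result (carrying the map's orientation
#'   indices).
#' @param map the [energy_map()] the sites came from (for the rotation
#'   set).
#' @param probe a [solvent_probe()]; default the map's probe.
#' @param max_shift_A rigid-body translation bound, Angstrom.
#' @return an object of class `microsolv_complex`: the conformer, placed
#'   probes (site coordinates, centres, energies), `n_sites` and
#'   `e_interaction_kcal` (solute-probe LIE total, probe-probe excluded).
#' @export
place_probes <- function(conf, sites, map, probe = NULL,
                         max_shift_A = 1.0) {
  stopifnot(inherits(conf, "conformer"), inherits(sites, "solvation_sites"))
  probe <- probe %||% map$probe
  xyz <- conformer_coords(conf)
  q <- conf$atoms$charge
  lj <- atom_lj_params(conf$atoms)
  placed <- list()
  for (s in seq_len(nrow(sites))) {
    centre0 <- c(sites$x[s], sites$y[s], sites$z[s])
    oi <- sites$orientation[s]
    R0 <- if (oi >= 1) map$rotations[, , oi] else diag(3)
    obj <- function(p) {
      R <- R0 %*% axis_angle_matrix_safe(p[4:6])
      probe_solute_energy(probe_site_coords(probe, centre0 + p[1:3], R),
                          probe, xyz, q, lj)
    }
    opt <- optim(rep(0, 6), obj, method = "L-BFGS-B",
                 lower = c(rep(-max_shift_A, 3), rep(-pi, 3)),
                 upper = c(rep(max_shift_A, 3), rep(pi, 3)),
                 control = list(maxit = 60))
    if (opt$value > map$clamp / 2) {
      warning("site ", s, ": placement clash unresolvable, skipped")
      next
    }
    centre <- centre0 + opt$par[1:3]
    ok <- TRUE
    for (pp in placed)
      if (vnorm(pp$centre - centre) <= 2.5) { ok <- FALSE; break }
    if (!ok) {
      warning("site ", s, ": overlaps an already placed probe, skipped")
      next
    }
    R <- R0 %*% axis_angle_matrix_safe(opt$par[4:6])
    placed[[length(placed) + 1]] <-
      list(centre = centre, rotation = R,
           coords = probe_site_coords(probe, centre, R),
           energy_kcal = opt$value, site_energy_kcal = sites$energy_kcal[s])
  }
  e_int <- if (length(placed))
    sum(vapply(placed, function(p) p$energy_kcal, numeric(1))) else 0
  structure(list(conformer = conf, probes = placed, probe = probe,
                 n_sites = length(placed), e_interaction_kcal = e_int),
            class = "microsolv_complex")
}

# rotation from an axis-angle 3-vector (angle = |v|); identity at 0
#' @noRd
axis_angle_matrix_safe <- function(v) {
  th <- vnorm(v)
  if (th < 1e-12) return(diag(3))
  axis_angle_matrix(v / th, th)
}

#' Linear interaction energy of a microsolvated complex
#'
#' Direct sum of LJ + Coulomb terms over all probe sites x solute atoms;
#' probe-probe terms are excluded by construction. Deterministic.
#'
#' @param x a [place_probes()] result.
#' @return total solute-probe interaction energy, kcal/mol (0 when no
#'   probes are placed).
#' @export
lie_energy <- function(x) {
  stopifnot(inherits(x, "microsolv_complex"))
  if (!length(x$probes)) return(0)
  xyz <- conformer_coords(x$conformer)
  q <- x$conformer$atoms$charge
  lj <- atom_lj_params(x$conformer$atoms)
  sum(vapply(x$probes, function(p)
    probe_solute_energy(p$coords, x$probe, xyz, q, lj), numeric(1)))
}

#' Compare microsolvation between two groups of complexes
#'
#' Per-group mean +/- SEM of the number of solvation sites and of the
#' interaction energy, plus Wilcoxon rank-sum statistics. Singleton groups
#' get an undefined (NA) SEM with a warning.
#'
#' @param a,b lists of [place_probes()] results.
#' @param labels group names.
#' @return a list summary (JSON-serialisable).
#' @export
compare_ensembles <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  summ <- function(xs, lab) {
    ns <- vapply(xs, function(x) x$n_sites, numeric(1))
    es <- vapply(xs, function(x) x$e_interaction_kcal, numeric(1))
    if (length(xs) == 1)
      warning("group '", lab, "' is a singleton: SEM undefined")
    sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else
      NA_real_
    list(n = length(xs), n_sites_mean = mean(ns), n_sites_sem = sem(ns),
         e_interaction_mean = mean(es), e_interaction_sem = sem(es))
  }
  ga <- summ(a, labels[1]); gb <- summ(b, labels[2])
  na <- vapply(a, function(x) x$n_sites, numeric(1))
  nb <- vapply(b, function(x) x$n_sites, numeric(1))
  ea <- vapply(a, function(x) x$e_interaction_kcal, numeric(1))
  eb <- vapply(b, function(x) x$e_interaction_kcal, numeric(1))
  wt <- function(x, y) {
    if (length(x) > 1 || length(y) > 1) {
      w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
      list(W = unname(w$statistic), p_value = w$p.value)
    } else list(W = NA_real_, p_value = NA_real_)
  }
  out <- setNames(list(ga, gb), labels)
  out$rank_sum <- list(n_sites = wt(na, nb), e_interaction = wt(ea, eb))
  out$difference <- list(
    n_sites = ga$n_sites_mean - gb$n_sites_mean,
    e_interaction = ga$e_interaction_mean - gb$e_interaction_mean)
  out
}

#' Export a solvation map as OpenDX grid text
#'
#' @param map a [energy_map()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(map, path) {
  d <- map$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", map$origin[1], map$origin[2],
            map$origin[3]),
    sprintf("delta %.4f 0 0", map$spacing),
    sprintf("delta 0 %.4f 0", map$spacing),
    sprintf("delta 0 0 %.4f", map$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(d))), con)
  # OpenDX order: z fastest
  v <- as.vector(aperm(map$energy, c(3, 2, 1)))
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0)
    writeLines(sprintf("%.6g %.6g %.6g",
                       v[seq(1, n3, 3)], v[seq(2, n3, 3)],
                       v[seq(3, n3, 3)]), con)
  if (n3 < length(v))
    writeLines(paste(sprintf("%.6g", v[(n3 + 1):length(v)]),
                     collapse = " "), con)
  invisible(path)
}
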