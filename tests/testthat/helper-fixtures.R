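# Shared fixture builders. Everything is generated in code at test time.

# minimal two-atom conformer whose markers sit r_da apart; energy and CCS
# can be planted directly, which makes it the unit for cascade tests
dummy_conformer <- function(label, energy = NA_real_, ccs = NULL,
                            r_da = 10) {
  atoms <- data.frame(element = "C", name = "DYE", resid = c(1, 2),
                      x = c(0, 0), y = c(0, 0), z = c(0, r_da),
                      radius = 1.7, charge = 0)
  cf <- conformer(atoms, donor_marker = 1L, acceptor_marker = 2L,
                  energy = energy, label = label)
  if (!is.null(ccs)) cf$ccs <- list(ccs_A2 = ccs)
  cf
}

dummy_ensemble <- function(df) {
  conformer_ensemble(lapply(seq_len(nrow(df)), function(i)
    dummy_conformer(df$label[i], df$energy[i], df$ccs[i], df$r_da[i])))
}

# random-coil blob of n atoms (self-avoiding-ish random walk)
random_coil_conformer <- function(n_atoms = 50, seed = 1) {
  set.seed(seed)
  pos <- matrix(0, n_atoms, 3)
  for (i in 2:n_atoms)
    pos[i, ] <- pos[i - 1, ] + rnorm(3) * 1.5
  conformer(data.frame(element = "C", name = "X", resid = seq_len(n_atoms),
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       radius = runif(n_atoms, 1.2, 1.9), charge = 0),
            label = sprintf("coil%d", seed))
}

# independent projected-area oracle: rasterise each projection on a fine
# grid instead of rejection sampling (same orientations)
raster_areas <- function(conf, probe_radius, rot, cell = 0.05) {
  xyz <- conformer_coords(conf)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  radii <- conf$atoms$radius + probe_radius
  n_orient <- dim(rot)[3]
  vapply(seq_len(n_orient), function(o) {
    p <- xyz %*% t(rot[, , o])  # same convention as the sampler
    px <- p[, 1]; py <- p[, 2]
    x0 <- min(px - radii); y0 <- min(py - radii)
    nx <- ceiling((max(px + radii) - x0) / cell) + 1
    ny <- ceiling((max(py + radii) - y0) / cell) + 1
    hit <- matrix(FALSE, nx, ny)
    for (i in seq_along(px)) {
      ix <- floor((px[i] - radii[i] - x0) / cell):
        ceiling((px[i] + radii[i] - x0) / cell)
      iy <- floor((py[i] - radii[i] - y0) / cell):
        ceiling((py[i] + radii[i] - y0) / cell)
      ix <- ix[ix >= 0 & ix < nx]; iy <- iy[iy >= 0 & iy < ny]
      cx <- x0 + (ix + 0.5) * cell; cy <- y0 + (iy + 0.5) * cell
      d2 <- outer((cx - px[i])^2, (cy - py[i])^2, "+")
      hit[ix + 1, iy + 1] <- hit[ix + 1, iy + 1] | (d2 <= radii[i]^2)
    }
    sum(hit) * cell^2
  }, numeric(1))
}

# microsolvation fixtures: the same twelve polar atoms as an open chain
# (every atom solvent-accessible) or collapsed into a compact ball
# (interior inaccessible, charges mutually shielded)
polar_chain_conformer <- function(kind = c("exposed", "buried"), seed = 1) {
  kind <- match.arg(kind)
  n <- 12
  set.seed(seed)
  jit <- matrix(rnorm(n * 3, 0, 0.15), n, 3)
  pos <- if (kind == "exposed") {
    cbind(seq(0, by = 4, length.out = n), 0, 0) + jit
  } else {
    u <- seq(0, n - 1)
    ga <- pi * (3 - sqrt(5))
    z <- 1 - 2 * u / (n - 1)
    r <- sqrt(pmax(0, 1 - z^2))
    2.6 * cbind(r * cos(ga * u), r * sin(ga * u), z) + jit
  }
  conformer(data.frame(element = "N", name = "Q", resid = seq_len(n),
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       radius = 1.6, charge = rep(c(0.3, -0.3), n / 2)),
            label = sprintf("%s%d", kind, seed))
}

microsolvate <- function(cf, spacing = 1.0, margin = 5, n_orient = 16,
                         seed = 5, threshold = -1.5) {
  m <- energy_map(cf, spacing_A = spacing, margin_A = margin,
                  n_orient = n_orient, seed = seed)
  s <- find_sites(m, threshold_kcal = threshold)
  suppressWarnings(place_probes(cf, s, m))
}

# plain-R double-loop reference for probe-solute LJ + Coulomb sums
lie_oracle <- function(cx) {
  xyz <- conformer_coords(cx$conformer)
  lj <- conformerge:::atom_lj_params(cx$conformer$atoms)
  q <- cx$conformer$atoms$charge
  pr <- cx$probe
  tot <- 0
  for (p in cx$probes) {
    for (s in seq_len(nrow(p$coords))) {
      for (a in seq_len(nrow(xyz))) {
        r <- sqrt(sum((p$coords[s, ] - xyz[a, ])^2))
        sg <- (pr$sigma[s] + lj$sigma[a]) / 2
        ep <- sqrt(pr$eps[s] * lj$eps[a])
        tot <- tot + 4 * ep * ((sg / r)^12 - (sg / r)^6) +
          332.0636 * pr$charge[s] * q[a] / r
      }
    }
  }
  tot
}

# exhaustive reference for find_sites on small grids
find_sites_oracle <- function(map, threshold = -1.5, min_sep = 3.5) {
  E <- map$energy
  d <- map$dims
  idx <- which(E < threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- E[max(1, i - 1):min(d[1], i + 1),
            max(1, j - 1):min(d[2], j + 1),
            max(1, k - 1):min(d[3], k + 1)]
    keep[r] <- all(E[i, j, k] <= nb)
  }
  idx <- idx[keep, , drop = FALSE]
  pos <- sweep((idx - 1) * map$spacing, 2, map$origin, "+")
  en <- E[idx]
  acc <- integer(0)
  for (r in order(en)) {
    ok <- TRUE
    for (a in acc)
      if (sqrt(sum((pos[a, ] - pos[r, ])^2)) < min_sep) { ok <- FALSE; break }
    if (ok) acc <- c(acc, r)
  }
  cbind(idx[acc, , drop = FALSE], energy = en[acc])
}

# synthetic solvation_map object from a raw energy array
synthetic_map <- function(E, spacing = 1, origin = c(0, 0, 0)) {
  structure(list(origin = origin, spacing = spacing, dims = dim(E),
                 energy = E, orientation = array(1L, dim(E)),
                 rotations = array(diag(3), c(3, 3, 1)),
                 probe = acetonitrile_probe(), n_orient = 1, seed = 1,
                 clamp = 50),
            class = "solvation_map")
}
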