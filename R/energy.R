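# Stand-in nonbonded energy: Lennard-Jones 12-6 + Coulomb (dielectric 1,
# in vacuo) over pairs separated by >= 3 bonds, plus a backbone
# hydrogen-bond well (Gaussian in the N...O distance, modulated by the
# C=O...N angle, -1 kcal/mol depth). This replaces a full biomolecular
# force field: it is a reduced score whose role is to rank conformers, and
# it is validated by limit and ordering properties, not against any
# published energy scale.

# per-element LJ parameters; pseudo-atoms (CB, DYE) derive sigma from their
# assigned radius so the LJ minimum sits at van der Waals contact.
lj_sigma <- c(H = 2.5, C = 3.4, N = 3.25, O = 2.96, S = 3.5)
lj_eps <- c(H = 0.02, C = 0.09, N = 0.17, O = 0.21, S = 0.25)

#' @noRd
atom_lj_params <- function(atoms) {
  sig <- unname(lj_sigma[atoms$element])
  eps <- unname(lj_eps[atoms$element])
  pseudo <- atoms$name %in% c("CB", "DYE")
  sig[pseudo] <- 2 * atoms$radius[pseudo] * 2^(-1 / 6)
  eps[pseudo] <- 0.15
  sig[is.na(sig)] <- 3.4
  eps[is.na(eps)] <- 0.09
  list(sigma = sig, eps = eps)
}

#' Prepare the energy model for a conformer
#'
#' Precomputes the nonbonded pair list (bond separation >= 3), combined LJ
#' parameters, Coulomb charge products and the backbone hydrogen-bond
#' triplets. The topology does not change under torsion moves, so one model
#' serves a whole sampling run.
#'
#' @param conf a [conformer()].
#' @param hbond_depth hydrogen-bond well depth, kcal/mol.
#' @param hbond_r0,hbond_width well centre and width of the N...O Gaussian,
#'   Angstrom.
#' @return an opaque list consumed by [score_energy()] and the samplers.
#' @export
prepare_energy_model <- function(conf, hbond_depth = 1.0, hbond_r0 = 2.9,
                                 hbond_width = 0.4) {
  stopifnot(inherits(conf, "conformer"))
  a <- conf$atoms
  n <- nrow(a)
  bonds <- conformer_bonds(conf)
  pairs <- if (nrow(bonds)) bond_separation_pairs(bonds, n, min_sep = 3) else
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lj <- atom_lj_params(a)
  pi_ <- pairs[, 1]; pj_ <- pairs[, 2]
  kq <- 332.0636
  hbN <- integer(0); hbO <- integer(0); hbC <- integer(0)
  iN <- which(a$name == "N"); iO <- which(a$name == "O")
  iC <- which(a$name == "C")
  for (o in iO) {
    cc <- iC[a$resid[iC] == a$resid[o]]
    if (!length(cc)) next
    for (nn in iN[abs(a$resid[iN] - a$resid[o]) >= 2]) {
      hbN <- c(hbN, nn); hbO <- c(hbO, o); hbC <- c(hbC, cc[1])
    }
  }
  list(n = n,
       pi0 = as.integer(pi_ - 1L), pj0 = as.integer(pj_ - 1L),
       sig = (lj$sigma[pi_] + lj$sigma[pj_]) / 2,
       eps = sqrt(lj$eps[pi_] * lj$eps[pj_]),
       qq = kq * a$charge[pi_] * a$charge[pj_],
       hbN0 = as.integer(hbN - 1L), hbO0 = as.integer(hbO - 1L),
       hbC0 = as.integer(hbC - 1L),
       hb_depth = hbond_depth, hb_r0 = hbond_r0, hb_w = hbond_width)
}

#' @noRd
model_energy <- function(xyz, model, want_grad = FALSE) {
  pe <- cpp_pair_energy(xyz, model$pi0, model$pj0, model$sig, model$eps,
                        model$qq, want_grad)
  hb <- cpp_hbond_energy(xyz, model$hbN0, model$hbO0, model$hbC0,
                         model$hb_depth, model$hb_r0, model$hb_w, want_grad)
  out <- list(energy = pe$energy + hb$energy, n_clash = pe$n_clash)
  if (want_grad) out$grad <- pe$grad + hb$grad
  out
}

#' Stand-in total energy of a conformer
#'
#' Sum of Lennard-Jones 12-6 and Coulomb terms over nonbonded pairs
#' (separation >= 3 bonds, dielectric 1) plus the backbone hydrogen-bond
#' well. Deterministic. Overlapping atoms (r < 0.1 A) contribute a large
#' finite penalty and trigger a warning.
#'
#' @param conf a [conformer()].
#' @param model optional precomputed [prepare_energy_model()] result.
#' @return energy in kcal/mol.
#' @export
score_energy <- function(conf, model = NULL) {
  model <- model %||% prepare_energy_model(conf)
  r <- model_energy(conformer_coords(conf), model)
  if (r$n_clash > 0)
    warning(r$n_clash, " overlapping atom pair(s) (r < 0.1 A): ",
            "penalty applied")
  r$energy
}

#' Score every conformer of an ensemble
#' @param ensemble a [conformer_ensemble()].
#' @param model optional shared energy model (same topology).
#' @return the ensemble with `$energy` set on each conformer.
#' @export
score_ensemble <- function(ensemble, model = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  for (i in seq_along(ensemble$conformers)) {
    cf <- ensemble$conformers[[i]]
    m <- model %||% prepare_energy_model(cf)
    ensemble$conformers[[i]]$energy <-
      model_energy(conformer_coords(cf), m)$energy
  }
  ensemble
}

# ---- torsion-space machinery ------------------------------------------

#' @noRd
rotate_torsion <- function(xyz, tor, angle) {
  axis <- xyz[tor$b, ] - xyz[tor$a, ]
  R <- axis_angle_matrix(axis, angle)
  moved <- tor$moved
  xyz[moved, ] <- sweep(sweep(xyz[moved, , drop = FALSE], 2, xyz[tor$b, ]) %*%
                          t(R), 2, xyz[tor$b, ], "+")
  xyz
}

# gradient of the energy with respect to each torsion angle, chain-ruled
# from the Cartesian gradient: dE/dtheta = sum_m g_m . (u x (x_m - x_b))
#' @noRd
torsion_gradient <- function(xyz, grad, torsions) {
  vapply(torsions, function(tor) {
    u <- xyz[tor$b, ] - xyz[tor$a, ]
    u <- u / vnorm(u)
    rel <- sweep(xyz[tor$moved, , drop = FALSE], 2, xyz[tor$b, ])
    arm <- cbind(u[2] * rel[, 3] - u[3] * rel[, 2],
                 u[3] * rel[, 1] - u[1] * rel[, 3],
                 u[1] * rel[, 2] - u[2] * rel[, 1])
    sum(grad[tor$moved, , drop = FALSE] * arm)
  }, numeric(1))
}

#' @noRd
apply_torsion_step <- function(xyz, torsions, dtheta) {
  for (k in seq_along(torsions))
    if (dtheta[k] != 0) xyz <- rotate_torsion(xyz, torsions[[k]], dtheta[k])
  xyz
}

#' Minimise a conformer's energy in torsion space
#'
#' Steepest-descent with backtracking line search for the first
#' `sd_evals` energy evaluations, then Polak-Ribiere conjugate gradient,
#' over the rotatable torsions (phi/psi and marker linkers). Torsion space
#' keeps the rigid bond geometry of the reduced representation intact; the
#' energy never increases along the trajectory.
#'
#' @param conf a [conformer()] with torsion metadata (from
#'   [build_peptide()] or [derive_torsions()]).
#' @param model optional precomputed energy model.
#' @param max_evals maximum energy evaluations (default 5000).
#' @param sd_evals evaluations before switching from steepest descent to
#'   conjugate gradient (default 1000).
#' @param tol gradient-norm convergence tolerance, kcal/mol/rad.
#' @return the minimised conformer; attributes `n_evals`, `converged`,
#'   `grad_norm` record the termination state.
#' @export
minimize_conformer <- function(conf, model = NULL, max_evals = 5000,
                               sd_evals = 1000, tol = 1e-3) {
  torsions <- conf$torsions %||% derive_torsions(conf)
  if (!length(torsions)) stop("no rotatable torsions")
  model <- model %||% prepare_energy_model(conf)
  xyz <- conformer_coords(conf)
  cur <- model_energy(xyz, model, want_grad = TRUE)
  n_eval <- 1L
  g <- torsion_gradient(xyz, cur$grad, torsions)
  dir <- -g
  g_prev <- g
  alpha <- 0.1
  while (n_eval < max_evals && vnorm(g) > tol) {
    if (sum(dir * -g) <= 0) dir <- -g  # ensure descent
    # backtracking Armijo line search
    improved <- FALSE
    a <- alpha
    for (bt in 1:12) {
      trial <- apply_torsion_step(xyz, torsions, a * dir)
      et <- model_energy(trial, model)
      n_eval <- n_eval + 1L
      if (et$energy <= cur$energy - 1e-4 * a * sum(g * -dir) &&
          et$energy < cur$energy) {
        xyz <- trial
        cur <- model_energy(xyz, model, want_grad = TRUE)
        n_eval <- n_eval + 1L
        improved <- TRUE
        alpha <- min(a * 2, 0.5)
        break
      }
      a <- a / 2
      if (n_eval >= max_evals) break
    }
    if (!improved) {
      if (identical(dir, -g)) break  # stuck even along steepest descent
      dir <- -g
      next
    }
    g_new <- torsion_gradient(xyz, cur$grad, torsions)
    if (n_eval < sd_evals) {
      dir <- -g_new
    } else {
      beta <- max(0, sum(g_new * (g_new - g_prev)) / sum(g_prev * g_prev))
      dir <- -g_new + beta * dir
    }
    g_prev <- g
    g <- g_new
  }
  out <- set_coords(conf, xyz)
  out$energy <- cur$energy
  attr(out, "n_evals") <- n_eval
  attr(out, "converged") <- vnorm(g) <= tol
  attr(out, "grad_norm") <- vnorm(g)
  out
}

#' Derive rotatable torsions for a generic conformer
#'
#' Scans backbone atom names (N, CA, C) and marker linkers (CA-CB of
#' marker-bearing residues) and computes the moved-atom set of each
#' rotatable bond from the bond graph.
#'
#' @param conf a [conformer()].
#' @return list of torsion descriptors.
#' @export
derive_torsions <- function(conf) {
  a <- conf$atoms
  bonds <- conformer_bonds(conf)
  idx <- list()
  for (i in sort(unique(a$resid))) {
    sel <- function(nm) which(a$resid == i & a$name == nm)[1]
    ii <- c(N = sel("N"), CA = sel("CA"), C = sel("C"), O = sel("O"),
            CB = sel("CB"))
    if (anyNA(ii[c("N", "CA", "C")])) next
    idx[[length(idx) + 1]] <- ii
  }
  if (!length(idx)) stop("cannot derive torsions: no backbone atoms found")
  marker_res <- unique(a$resid[which(a$name == "DYE")])
  marker_sites <- which(vapply(idx, function(ii)
    a$resid[ii["CA"]] %in% marker_res, logical(1)))
  peptide_torsions(idx, marker_sites,
                   which(a$name == "DYE"), nrow(a), bonds)
}
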