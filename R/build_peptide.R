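# Reduced-representation peptide construction.
#
# Each residue contributes backbone heavy atoms (N, CA, C, O) plus one
# unified side-chain pseudo-atom (CB) whose radius reflects the side-chain
# size. Dye markers are pseudo-atoms placed 5 A from the flagged residues
# along the side-chain vector. Geometry is built with the natural extension
# reference frame (NeRF) from standard bond lengths/angles.

aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

# unified side-chain pseudo-atom radii (Angstrom), roughly volume-based
sidechain_radius <- c(A = 1.8, R = 2.9, N = 2.3, D = 2.2, C = 2.1, Q = 2.5,
                      E = 2.4, G = 1.0, H = 2.5, I = 2.4, L = 2.4, K = 2.8,
                      M = 2.5, F = 2.7, P = 2.2, S = 1.9, T = 2.1, V = 2.2,
                      W = 2.9, Y = 2.8)

# backbone partial charges (e): amide dipoles of +/- 0.4
backbone_charge <- c(N = -0.4, CA = 0.4, C = 0.4, O = -0.4, CB = 0)

# NeRF: place atom d given a-b-c, |cd|, angle(b,c,d), dihedral(a,b,c,d)
#' @noRd
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- (c - b) / vnorm(c - b)
  n <- pracma_cross(b - a, bc)
  n <- n / vnorm(n)
  m <- pracma_cross(n, bc)
  d_local <- bond * c(-cos(angle), sin(angle) * cos(dihedral),
                      sin(angle) * sin(dihedral))
  c + cbind(bc, m, n) %*% d_local
}

#' @noRd
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build a reduced-representation peptide conformer
#'
#' Constructs backbone heavy atoms and one side-chain pseudo-atom per
#' residue at ideal geometry, with backbone dihedrals set by conformation:
#' `helix` uses phi = -57, psi = -47 degrees; `extended` uses
#' phi = -139, psi = 135; `coil` draws seeded dihedrals from broad
#' backbone-like ranges. Dye markers (element C, name DYE, radius 3 A) are
#' placed 5 A from the two flagged residues along their side-chain vectors
#' and bonded to the pseudo-side chain.
#'
#' @param sequence one-letter amino-acid string (length >= 2).
#' @param conformation `"helix"`, `"extended"` or `"coil"`.
#' @param seed RNG seed (used by `"coil"`).
#' @param marker_sites two residue indices carrying the dye markers
#'   (donor first); default the termini.
#' @param charge_sites residue indices whose side-chain pseudo-atom gets a
#'   +1 e protonation charge.
#' @param marker_charges charges (e) of the donor and acceptor marker.
#' @param phi,psi optional explicit per-residue dihedral vectors (degrees)
#'   overriding `conformation`.
#' @param label conformer label.
#' @return a [conformer()] with markers, bonds and rotatable-torsion
#'   metadata set.
#' @export
build_peptide <- function(sequence,
                          conformation = c("helix", "extended", "coil"),
                          seed = 1, marker_sites = NULL,
                          charge_sites = integer(0),
                          marker_charges = c(0, 0),
                          phi = NULL, psi = NULL, label = NULL) {
  conformation <- match.arg(conformation)
  res <- strsplit(toupper(sequence), "")[[1]]
  nres <- length(res)
  if (nres < 2) stop("sequence must have at least 2 residues")
  if (!all(res %in% names(aa3)))
    stop("unknown residue(s): ",
         paste(unique(res[!res %in% names(aa3)]), collapse = ", "))
  marker_sites <- marker_sites %||% c(1L, nres)
  if (length(marker_sites) < 2) stop("need 2 marker attachment sites")
  if (any(marker_sites < 1 | marker_sites > nres))
    stop("marker site out of range")

  deg <- pi / 180
  if (is.null(phi)) {
    ang <- switch(conformation,
      helix = list(phi = rep(-57, nres), psi = rep(-47, nres)),
      extended = list(phi = rep(-139, nres), psi = rep(135, nres)),
      coil = with_seed(seed, list(phi = runif(nres, -160, -50),
                                  psi = runif(nres, -60, 160))))
    phi <- ang$phi; psi <- ang$psi
  }
  stopifnot(length(phi) == nres, length(psi) == nres)
  phi <- phi * deg; psi <- psi * deg
  omega <- pi  # trans peptide bond

  # ideal backbone geometry (Angstrom / degrees)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231; b_CACB <- 1.53
  a_NCAC <- 111.0 * deg; a_CACN <- 116.2 * deg; a_CNCA <- 121.7 * deg
  a_CACO <- 120.8 * deg; a_NCACB <- 110.5 * deg

  atoms <- list()
  pos <- list()  # named positions per residue
  add <- function(elem, name, r, p, q, resi) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      element = elem, name = name, resid = resi,
      resname = unname(aa3[res[resi]]),
      x = p[1], y = p[2], z = p[3], radius = r, charge = q)
    length(atoms)
  }
  idx <- vector("list", nres)
  for (i in seq_len(nres)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(b_NCA, 0, 0)
      # arbitrary reference fixes the overall orientation only
      C <- place_atom(c(0, 0, 1), N, CA, b_CAC, a_NCAC, phi[1])
    } else {
      pN <- pos[[i - 1]]
      N <- place_atom(pN$N, pN$CA, pN$C, b_CN, a_CACN, psi[i - 1])
      CA <- place_atom(pN$CA, pN$C, N, b_NCA, a_CNCA, omega)
      C <- place_atom(pN$C, N, CA, b_CAC, a_NCAC, phi[i])
    }
    # carbonyl O anti to the next amide N (dihedral psi + pi)
    O <- place_atom(N, CA, C, b_CO, a_CACO, psi[i] + pi)
    CB <- place_atom(C, N, CA, b_CACB, a_NCACB, -120 * deg)
    pos[[i]] <- list(N = N, CA = CA, C = C, O = O, CB = CB)
    qCB <- if (i %in% charge_sites) 1 else 0
    idx[[i]] <- c(
      N = add("N", "N", default_vdw_radii[["N"]], N, backbone_charge["N"], i),
      CA = add("C", "CA", default_vdw_radii[["C"]], CA,
               backbone_charge["CA"], i),
      C = add("C", "C", default_vdw_radii[["C"]], C, backbone_charge["C"], i),
      O = add("O", "O", default_vdw_radii[["O"]], O, backbone_charge["O"], i),
      CB = add("C", "CB", unname(sidechain_radius[res[i]]), CB, qCB, i))
  }
  # dye markers: 5 A from the flagged residue along the CA -> CB vector
  marker_idx <- integer(2)
  for (k in 1:2) {
    i <- marker_sites[k]
    v <- pos[[i]]$CB - pos[[i]]$CA
    p <- pos[[i]]$CA + 5 * v / vnorm(v)
    marker_idx[k] <- add("C", "DYE", 3.0, p, marker_charges[k], i)
  }
  atoms <- do.call(rbind, atoms)

  bonds <- list()
  for (i in seq_len(nres)) {
    ii <- idx[[i]]
    bonds[[length(bonds) + 1]] <- rbind(
      c(ii["N"], ii["CA"]), c(ii["CA"], ii["C"]), c(ii["C"], ii["O"]),
      c(ii["CA"], ii["CB"]))
    if (i > 1)
      bonds[[length(bonds) + 1]] <- rbind(c(idx[[i - 1]]["C"], ii["N"]))
  }
  for (k in 1:2)
    bonds[[length(bonds) + 1]] <-
      rbind(c(idx[[marker_sites[k]]]["CB"], marker_idx[k]))
  bonds <- do.call(rbind, bonds)
  storage.mode(bonds) <- "integer"

  cf <- conformer(atoms, donor_marker = marker_idx[1],
                  acceptor_marker = marker_idx[2],
                  label = label %||% sprintf("%s_%s", conformation,
                                             substr(sequence, 1, 6)),
                  bonds = bonds)
  cf$torsions <- peptide_torsions(idx, marker_sites, marker_idx,
                                  nrow(atoms), bonds)
  cf$sequence <- sequence
  cf
}

# rotatable torsions: phi (N-CA), psi (CA-C) per residue, plus the
# CA-CB linker torsion of marker-bearing residues.
#' @noRd
peptide_torsions <- function(idx, marker_sites, marker_idx, n, bonds) {
  tors <- list()
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    tors[[length(tors) + 1]] <-
      list(a = unname(ii["N"]), b = unname(ii["CA"]), kind = "phi", res = i)
    tors[[length(tors) + 1]] <-
      list(a = unname(ii["CA"]), b = unname(ii["C"]), kind = "psi", res = i)
  }
  for (k in seq_along(marker_sites)) {
    ii <- idx[[marker_sites[k]]]
    tors[[length(tors) + 1]] <-
      list(a = unname(ii["CA"]), b = unname(ii["CB"]), kind = "linker",
           res = marker_sites[k])
  }
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  keep <- list()
  for (tr in tors) {
    # moved set: atoms reachable from b without crossing the a-b bond
    seen <- rep(FALSE, n)
    seen[tr$b] <- TRUE
    frontier <- setdiff(adj[[tr$b]], tr$a)
    while (length(frontier)) {
      frontier <- frontier[!seen[frontier]]
      seen[frontier] <- TRUE
      frontier <- unique(unlist(adj[frontier]))
    }
    moved <- setdiff(which(seen), c(tr$a, tr$b))
    if (length(moved) && length(moved) < n - 2) {
      tr$moved <- moved
      keep[[length(keep) + 1]] <- tr
    }
  }
  keep
}
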