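# Conformer container, marker distances, topology and PDB I/O.
#
# PDB dialect: the occupancy column stores the per-atom van der Waals
# radius and the B-factor column the partial charge. Marker atoms, the
# total energy and the label travel in REMARK 250 lines:
#   REMARK 250 CONFORMERGE DONOR_MARKER <atom index>
#   REMARK 250 CONFORMERGE ACCEPTOR_MARKER <atom index>
#   REMARK 250 CONFORMERGE ENERGY <kcal/mol>
#   REMARK 250 CONFORMERGE LABEL <string>

#' Construct a conformer
#'
#' The atomic model that flows through CCS, refinement and microsolvation:
#' coordinates, elements, van der Waals radii and partial charges per atom,
#' plus donor/acceptor marker atoms (dye stand-ins) and a total energy.
#'
#' @param atoms data frame with columns `element`, `name`, `resid`,
#'   `resname` (optional), `x`, `y`, `z`, `radius` (Angstrom), `charge` (e).
#' @param donor_marker,acceptor_marker atom indices of the two dye markers
#'   (NA when unset).
#' @param energy total stand-in energy, kcal/mol (NA until scored).
#' @param label identifier string.
#' @param bonds optional 2-column integer matrix of bonded atom pairs; when
#'   omitted it is inferred from interatomic distances on demand.
#' @return an object of class `conformer`.
#' @export
conformer <- function(atoms, donor_marker = NA_integer_,
                      acceptor_marker = NA_integer_, energy = NA_real_,
                      label = "conf", bonds = NULL) {
  need <- c("element", "name", "resid", "x", "y", "z", "radius", "charge")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (!"resname" %in% names(atoms)) atoms$resname <- "UNK"
  rownames(atoms) <- NULL
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  n <- nrow(atoms)
  for (m in c(donor_marker, acceptor_marker))
    if (!is.na(m) && (m < 1 || m > n)) stop("marker index out of range")
  structure(list(atoms = atoms, donor_marker = donor_marker,
                 acceptor_marker = acceptor_marker, energy = energy,
                 label = label, bonds = bonds),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("Conformer '%s': %d atoms, %d residues\n", x$label,
              nrow(x$atoms), length(unique(x$atoms$resid))))
  if (!is.na(x$energy)) cat(sprintf("  energy: %.2f kcal/mol\n", x$energy))
  if (!is.na(x$donor_marker) && !is.na(x$acceptor_marker))
    cat(sprintf("  marker distance: %.2f A\n", marker_distance(x)))
  invisible(x)
}

#' Coordinate matrix of a conformer
#' @param conf a [conformer()].
#' @return n x 3 numeric matrix.
#' @export
conformer_coords <- function(conf) {
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

#' @noRd
set_coords <- function(conf, xyz) {
  conf$atoms$x <- xyz[, 1]; conf$atoms$y <- xyz[, 2]; conf$atoms$z <- xyz[, 3]
  conf
}

#' Donor-acceptor marker distance
#'
#' Euclidean distance between the two marker atoms (the calculated r_DA of
#' a model structure).
#'
#' @param conf a [conformer()] with both markers set.
#' @return distance in Angstrom.
#' @export
marker_distance <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  if (is.na(conf$donor_marker) || is.na(conf$acceptor_marker))
    stop("markers unset")
  xyz <- conformer_coords(conf)
  vnorm(xyz[conf$donor_marker, ] - xyz[conf$acceptor_marker, ])
}

#' Radius of gyration
#' @param conf a [conformer()].
#' @return Rg in Angstrom (mass-unweighted).
#' @export
radius_of_gyration <- function(conf) {
  xyz <- conformer_coords(conf)
  c0 <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
}

#' @noRd
conformer_bonds <- function(conf, max_bond = 2.0) {
  if (!is.null(conf$bonds)) return(conf$bonds)
  xyz <- conformer_coords(conf)
  d <- as.matrix(dist(xyz))
  # below 0.4 A two centres are overlapping atoms, not a bond
  idx <- which(d > 0.4 & d < max_bond & upper.tri(d), arr.ind = TRUE)
  unname(idx)
}

# Graph distances up to `cut` bonds; returns list(pairs_excluded) as a
# logical adjacency for separations 1..cut-1.
#' @noRd
bond_separation_pairs <- function(bonds, n, min_sep = 3) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excluded <- matrix(FALSE, n, n)
  for (s in seq_len(n)) {
    # BFS to depth min_sep - 1
    depth <- rep(-1L, n)
    depth[s] <- 0L
    frontier <- s
    for (d in seq_len(min_sep - 1)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[depth[nxt] < 0]
      if (!length(nxt)) break
      depth[nxt] <- d
      frontier <- nxt
    }
    excluded[s, depth > 0] <- TRUE
  }
  w <- which(upper.tri(excluded) & !excluded, arr.ind = TRUE)
  unname(w)
}

#' Write a conformer to a PDB file
#'
#' Fixed-width ATOM/HETATM records; the occupancy column carries the per-
#' atom van der Waals radius, the B-factor the partial charge, and marker /
#' energy / label annotations are serialised as `REMARK 250 CONFORMERGE`
#' lines (see the package vignette for the dialect).
#'
#' @param conf a [conformer()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conf, path) {
  stopifnot(inherits(conf, "conformer"))
  a <- conf$atoms
  lines <- character(0)
  if (!is.na(conf$donor_marker))
    lines <- c(lines, sprintf("REMARK 250 CONFORMERGE DONOR_MARKER %d",
                              conf$donor_marker))
  if (!is.na(conf$acceptor_marker))
    lines <- c(lines, sprintf("REMARK 250 CONFORMERGE ACCEPTOR_MARKER %d",
                              conf$acceptor_marker))
  if (!is.na(conf$energy))
    lines <- c(lines, sprintf("REMARK 250 CONFORMERGE ENERGY %.6f",
                              conf$energy))
  lines <- c(lines, sprintf("REMARK 250 CONFORMERGE LABEL %s", conf$label))
  rec <- ifelse(a$name %in% c("DYE", "DON", "ACC"), "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                  substr(a$name, 1, 4))
  lines <- c(lines, sprintf(
    "%s%5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), name4, substr(a$resname, 1, 3), a$resid,
    a$x, a$y, a$z, a$radius, a$charge, a$element))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a conformer from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) using the package's dialect:
#' occupancy = van der Waals radius, B-factor = partial charge. Missing
#' element columns are inferred from the atom name with a warning; marker,
#' energy and label annotations are recovered from
#' `REMARK 250 CONFORMERGE` lines when present.
#'
#' @param path PDB file path.
#' @return a [conformer()].
#' @export
read_pdb <- function(path) {
  raw <- readLines(path)
  atom_lines <- grep("^(ATOM  |HETATM)", raw)
  if (!length(atom_lines)) stop("no ATOM records in ", path)
  for (i in atom_lines) {
    ln <- raw[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop("malformed ATOM record at line ", i, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  if (any(elem == "" | is.na(elem))) {
    warning("missing element column; inferring from atom names")
    miss <- elem == "" | is.na(elem)
    elem[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  }
  atoms <- data.frame(element = elem, name = trimws(at$elety),
                      resid = at$resno, resname = at$resid,
                      x = at$x, y = at$y, z = at$z,
                      radius = at$o, charge = at$b)
  bad <- !is.finite(atoms$radius) | atoms$radius <= 0
  if (any(bad)) {
    atoms$radius[bad] <-
      unname(default_vdw_radii[atoms$element[bad]])
    atoms$radius[!is.finite(atoms$radius)] <- 1.7
  }
  atoms$charge[!is.finite(atoms$charge)] <- 0
  grab <- function(tag) {
    m <- grep(paste0("^REMARK 250 CONFORMERGE ", tag, " "), raw,
              value = TRUE)
    if (length(m)) sub(paste0("^REMARK 250 CONFORMERGE ", tag, " "), "",
                       m[1]) else NA
  }
  dm <- suppressWarnings(as.integer(grab("DONOR_MARKER")))
  am <- suppressWarnings(as.integer(grab("ACCEPTOR_MARKER")))
  en <- suppressWarnings(as.numeric(grab("ENERGY")))
  lb <- grab("LABEL")
  conformer(atoms, donor_marker = dm, acceptor_marker = am,
            energy = if (is.na(en)) NA_real_ else en,
            label = if (is.na(lb)) basename(path) else lb)
}

#' Construct an ensemble of conformers
#'
#' @param conformers list of [conformer()] objects with unique labels.
#' @param provenance named list recording generator parameters and seeds.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(conformers, provenance = list()) {
  stopifnot(is.list(conformers), length(conformers) > 0)
  labels <- vapply(conformers, function(x) x$label, character(1))
  if (anyDuplicated(labels)) stop("conformer labels must be unique")
  structure(list(conformers = conformers, provenance = provenance),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  e <- vapply(x$conformers, function(cf) cf$energy, numeric(1))
  cat(sprintf("Ensemble of %d conformers", length(x$conformers)))
  if (all(is.finite(e)))
    cat(sprintf(" (energy %.1f .. %.1f kcal/mol)", min(e), max(e)))
  cat("\n")
  invisible(x)
}

#' @noRd
ensemble_labels <- function(e)
  vapply(e$conformers, function(x) x$label, character(1))
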