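# Constraint cascade: energy percentile cutoff -> CCS peak matching ->
# FRET-distance selection -> overestimation report.

#' Experimental constraints for ensemble refinement
#'
#' @param ccs_peaks data frame (or list of lists) with columns `label`,
#'   `ccs_A2` and `tolerance_fraction` describing the ion-mobility peaks.
#' @param r_da_A experimental donor-acceptor distance, Angstrom.
#' @param r_da_sigma_A its uncertainty, Angstrom.
#' @param selection_rule `"closest"` (smallest |r_calc - r_exp|) or
#'   `"closest_below"` (closest from below; falls back to `"closest"` with
#'   a warning when fewer than `k_select` candidates lie below).
#' @param k_select number of structures to keep per peak (default 5).
#' @return an object of class `experimental_constraints`.
#' @export
experimental_constraints <- function(ccs_peaks, r_da_A, r_da_sigma_A = 0,
                                     selection_rule = c("closest",
                                                        "closest_below"),
                                     k_select = 5) {
  selection_rule <- match.arg(selection_rule)
  if (is.list(ccs_peaks) && !is.data.frame(ccs_peaks))
    ccs_peaks <- do.call(rbind, lapply(ccs_peaks, as.data.frame))
  stopifnot(all(c("label", "ccs_A2", "tolerance_fraction") %in%
                  names(ccs_peaks)))
  if (any(ccs_peaks$ccs_A2 <= 0)) stop("ccs values must be positive")
  if (any(ccs_peaks$tolerance_fraction <= 0 |
          ccs_peaks$tolerance_fraction > 0.2))
    stop("tolerance_fraction must be in (0, 0.2]")
  if (k_select < 1) stop("k_select must be >= 1")
  if (any(r_da_A <= 0)) stop("r_da_A must be positive")
  structure(list(ccs_peaks = ccs_peaks, r_da_A = r_da_A,
                 r_da_sigma_A = r_da_sigma_A,
                 selection_rule = selection_rule,
                 k_select = as.integer(k_select)),
            class = "experimental_constraints")
}

#' @noRd
ensemble_energies <- function(e) {
  en <- vapply(e$conformers, function(x) x$energy, numeric(1))
  if (any(!is.finite(en)))
    stop("unscored conformer(s): run score_ensemble() first")
  en
}

#' @noRd
ensemble_ccs <- function(e) {
  vapply(e$conformers, function(x) {
    v <- if (!is.null(x$ccs)) x$ccs$ccs_A2 else x$ccs_A2
    if (is.null(v) || !is.finite(v))
      stop("conformer '", x$label, "' carries no CCS value")
    v
  }, numeric(1))
}

#' Energy percentile filter
#'
#' Retains the `ceiling(fraction * N)` lowest-energy conformers (rank
#' percentile, not energy range), preserving ensemble order; ties at the
#' cut are broken by label.
#'
#' @param ensemble a scored [conformer_ensemble()].
#' @param fraction fraction of conformers to keep, in (0, 1].
#' @return the filtered ensemble.
#' @export
energy_filter <- function(ensemble, fraction = 0.2) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  en <- ensemble_energies(ensemble)
  n_keep <- ceiling(fraction * length(en))
  ord <- order(en, ensemble_labels(ensemble))
  keep <- sort(ord[seq_len(n_keep)])
  out <- ensemble
  out$conformers <- ensemble$conformers[keep]
  out$provenance$energy_filter <- list(fraction = fraction,
                                       n_in = length(en), n_out = n_keep)
  out
}

#' Assign conformers to experimental CCS peaks
#'
#' A conformer is assigned to every peak whose window
#' `ccs * (1 +/- tolerance_fraction)` contains its calculated CCS;
#' conformers matching no peak are reported unassigned, conformers matching
#' several overlapping windows are reported as multiply assigned.
#'
#' @param ensemble a [conformer_ensemble()] whose conformers carry CCS
#'   values (see [ccs_distribution()]).
#' @param peaks data frame with `label`, `ccs_A2`, `tolerance_fraction`.
#' @return named list of per-peak ensembles, with attributes `unassigned`
#'   (labels) and `multi_assigned` (labels).
#' @export
ccs_match <- function(ensemble, peaks) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  ccs <- ensemble_ccs(ensemble)
  labs <- ensemble_labels(ensemble)
  groups <- list()
  n_assigned <- integer(length(ccs))
  for (p in seq_len(nrow(peaks))) {
    # strict relative deviation: a conformer exactly at the window edge
    # is outside
    inw <- which(abs(ccs - peaks$ccs_A2[p]) / peaks$ccs_A2[p] <
                   peaks$tolerance_fraction[p])
    n_assigned[inw] <- n_assigned[inw] + 1L
    g <- ensemble
    g$conformers <- ensemble$conformers[inw]
    g$provenance$ccs_peak <- as.list(peaks[p, ])
    groups[[peaks$label[p]]] <- g
  }
  if (all(n_assigned == 0))
    stop("constraints inconsistent with ensemble: no conformer matches ",
         "any CCS peak")
  attr(groups, "unassigned") <- labs[n_assigned == 0]
  attr(groups, "multi_assigned") <- labs[n_assigned > 1]
  groups
}

#' Select conformers against the experimental FRET distance
#'
#' `rule = "closest"` keeps the `k` conformers with the smallest
#' |r_calc - r_exp|. `rule = "closest_below"` keeps, among conformers with
#' r_calc < r_exp, the `k` largest r_calc (closest from below); when fewer
#' than `k` qualify, the remainder is filled by the `"closest"` rule with a
#' warning. Ties are broken by label for determinism.
#'
#' @param group a [conformer_ensemble()] with marker distances available.
#' @param r_exp_A experimental donor-acceptor distance, Angstrom.
#' @param rule `"closest"` or `"closest_below"`.
#' @param k number of conformers to select.
#' @return ensemble of the selected conformers (order of selection).
#' @export
distance_select <- function(group, r_exp_A,
                            rule = c("closest", "closest_below"), k = 5) {
  rule <- match.arg(rule)
  stopifnot(inherits(group, "conformer_ensemble"))
  if (!length(group$conformers)) stop("empty group")
  r <- vapply(group$conformers, marker_distance, numeric(1))
  labs <- ensemble_labels(group)
  k <- min(k, length(r))
  if (rule == "closest") {
    sel <- order(abs(r - r_exp_A), labs)[seq_len(k)]
  } else {
    below <- which(r < r_exp_A)
    sel <- below[order(-r[below], labs[below])]
    sel <- sel[seq_len(min(k, length(sel)))]
    if (length(sel) < k) {
      warning("closest_below: only ", length(sel), " of ", k,
              " candidates below r_exp; filling by closest")
      rest <- setdiff(order(abs(r - r_exp_A), labs), sel)
      sel <- c(sel, rest[seq_len(k - length(sel))])
    }
  }
  out <- group
  out$conformers <- group$conformers[sel]
  out$provenance$distance_select <- list(r_exp_A = r_exp_A, rule = rule,
                                         k = k)
  out
}

#' FRET distance overestimation
#'
#' Signed percent by which the experimental distance exceeds the mean
#' calculated distance of the selected structures:
#' `100 * (r_exp - mean(r_calc)) / r_exp`. Positive means the experiment
#' overestimates the model; negative values (underestimation) are reported
#' as such.
#'
#' @param r_exp_A experimental distance, Angstrom (> 0).
#' @param selected ensemble of selected conformers, or a numeric vector of
#'   calculated distances.
#' @return overestimation in percent (signed).
#' @export
overestimation_report <- function(r_exp_A, selected) {
  if (r_exp_A <= 0) stop("r_exp_A must be positive")
  r <- if (is.numeric(selected)) selected else {
    if (!length(selected$conformers)) stop("empty selection")
    vapply(selected$conformers, marker_distance, numeric(1))
  }
  if (!length(r)) stop("empty selection")
  100 * (r_exp_A - mean(r)) / r_exp_A
}

#' Run the full refinement cascade
#'
#' Composition of [energy_filter()], [ccs_match()], [distance_select()] and
#' [overestimation_report()]; stage counts are recorded and every stage
#' error is re-raised with its stage name.
#'
#' @param ensemble a [conformer_ensemble()] carrying energies, CCS values
#'   and marker distances.
#' @param constraints an [experimental_constraints()]. `r_da_A` may also be
#'   a named vector (one distance per peak label).
#' @param fraction energy-filter fraction (default 0.2).
#' @return an object of class `refinement_result`: per-peak selections,
#'   mean calculated r_DA, overestimation percent and stage counts.
#' @export
run_cascade <- function(ensemble, constraints, fraction = 0.2) {
  stopifnot(inherits(constraints, "experimental_constraints"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("cascade stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list(input = length(ensemble$conformers))
  filtered <- stage("energy_filter", energy_filter(ensemble, fraction))
  counts$energy_filter <- length(filtered$conformers)
  groups <- stage("ccs_match", ccs_match(filtered, constraints$ccs_peaks))
  counts$ccs_match <- vapply(groups, function(g) length(g$conformers),
                             integer(1))
  r_exp <- constraints$r_da_A
  peaks <- names(groups)
  sel <- list()
  per_peak <- list()
  for (p in peaks) {
    rp <- if (length(r_exp) > 1) r_exp[[p]] else r_exp
    s <- stage(paste0("distance_select[", p, "]"),
               distance_select(groups[[p]], rp, constraints$selection_rule,
                               constraints$k_select))
    r_calc <- vapply(s$conformers, marker_distance, numeric(1))
    per_peak[[p]] <- list(
      labels = ensemble_labels(s),
      mean_r_calc_A = mean(r_calc),
      r_exp_A = rp,
      overestimation_percent = stage(
        paste0("overestimation[", p, "]"),
        overestimation_report(rp, r_calc)))
    sel[[p]] <- s
  }
  counts$selected <- vapply(sel, function(g) length(g$conformers),
                            integer(1))
  structure(list(peaks = per_peak, selections = sel, counts = counts,
                 unassigned = attr(groups, "unassigned"),
                 multi_assigned = attr(groups, "multi_assigned"),
                 constraints = constraints, fraction = fraction),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("Refinement cascade:", x$counts$input, "->",
      x$counts$energy_filter, "after energy filter\n")
  for (p in names(x$peaks)) {
    pk <- x$peaks[[p]]
    cat(sprintf(
      "  peak %s: %d matched, %d selected; mean r_DA = %.1f A vs %.1f A",
      p, x$counts$ccs_match[[p]], length(pk$labels), pk$mean_r_calc_A,
      pk$r_exp_A))
    cat(sprintf(" (overestimation %+.1f%%)\n", pk$overestimation_percent))
  }
  invisible(x)
}
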