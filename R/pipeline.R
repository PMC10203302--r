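# End-to-end driver: sample -> score -> CCS -> FRET distances -> cascade
# -> microsolvation -> DMS summary, with a JSON report and provenance.

#' Run the full structure-determination pipeline
#'
#' Executes the workflow described by a [validate_config()] result:
#' build or load the start conformer, sample an ensemble by simulated
#' annealing, score energies, compute per-conformer PA CCS, convert
#' lifetimes to experimental FRET distances, refine the ensemble through
#' the constraint cascade, score the microsolvation of the selected
#' structures, and (optionally) summarise simulated DMS CV-shift series.
#' One master seed fans out to per-module seeds (`seed + 1` sampling,
#' `+ 2` CCS, `+ 3` microsolvation, `+ 4` DMS) so partial reruns are
#' reproducible. Rerunning an identical config yields an identical report.
#'
#' @param cfg a `run_config` from [validate_config()], or a path to a YAML
#'   config file.
#' @return the report, invisibly; side effects under `cfg$output_dir`:
#'   `report.json`, `stage_flags.tsv`, selected-structure PDBs.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. start conformer
  pep <- cfg$peptide
  start <- stage("build", {
    if (!is.null(pep$pdb)) read_pdb(pep$pdb)
    else build_peptide(pep$sequence, pep$conformation, seed = seed,
                       marker_sites = pep$marker_sites,
                       charge_sites = pep$charge_sites %||% integer(0),
                       marker_charges = pep$marker_charges %||% c(0, 0))
  })

  # 2. sampling
  sm <- cfg$sampling
  schedule <- annealing_schedule(sm$heat_steps, sm$plateau_steps,
                                 sm$cool_steps, sm$hold_steps, sm$t_max_K,
                                 sm$n_roots, sm$n_children)
  ens <- stage("sample",
               anneal_sample(start, schedule, seed = seed + 1L,
                             step_sigma_deg = sm$step_sigma_deg,
                             minimize_evals = sm$minimize_evals))

  # 3. CCS per conformer
  cc <- cfg$ccs
  ens <- stage("ccs",
               ccs_distribution(ens, probe_radius_A = cc$probe_radius_A,
                                n_orientations = cc$n_orientations,
                                n_hits = cc$n_hits, seed = seed + 2L,
                                scale_factor = cc$scale_factor))

  # 4. FRET distances from lifetimes
  ph <- cfg$photophysics
  R0 <- if (!is.null(ph$J_nm4_M_cm))
    forster_radius(dye_photophysics(ph$J_nm4_M_cm, ph$phi_D, ph$kappa2,
                                    ph$n_medium)) else NA_real_
  peaks_raw <- cfg$constraints$peaks
  peak_df <- do.call(rbind, lapply(peaks_raw, function(p) data.frame(
    label = p$label, ccs_A2 = p$ccs_A2,
    tolerance_fraction = p$tolerance_fraction %||% 0.02)))
  r_da <- vapply(peaks_raw, function(p) {
    if (!is.null(p$r_da_A)) return(as.numeric(p$r_da_A))
    E <- fret_efficiency(p$tau_DA_ns, ph$tau_D_ns)
    distance_from_efficiency(E, R0)
  }, numeric(1))
  names(r_da) <- peak_df$label

  # 5. refinement cascade
  constraints <- experimental_constraints(
    peak_df, r_da_A = r_da, r_da_sigma_A = cfg$constraints$r_da_sigma_A,
    selection_rule = cfg$constraints$selection_rule,
    k_select = cfg$constraints$k_select)
  refined <- stage("cascade",
                   run_cascade(ens, constraints,
                               cfg$constraints$energy_fraction))

  # 6. microsolvation of the selected structures
  ms <- cfg$microsolvation
  micro <- NULL
  if (isTRUE(ms$enabled)) {
    micro <- stage("microsolvation", {
      probe <- acetonitrile_probe()
      per_peak <- lapply(refined$selections, function(sel) {
        lapply(sel$conformers, function(cf) {
          m <- energy_map(cf, probe, spacing_A = ms$spacing_A,
                          margin_A = ms$margin_A, n_orient = ms$n_orient,
                          seed = seed + 3L)
          st <- find_sites(m, ms$threshold_kcal, ms$min_separation_A)
          place_probes(cf, st, m)
        })
      })
      cmp <- if (length(per_peak) >= 2)
        compare_ensembles(per_peak[[1]], per_peak[[2]],
                          labels = names(per_peak)[1:2]) else NULL
      list(per_peak = per_peak, comparison = cmp)
    })
  }

  # 7. DMS summary
  dms <- NULL
  if (isTRUE(cfg$dms$enabled)) {
    dms <- stage("dms", {
      series_list <- lapply(cfg$dms$species, function(sp) {
        series <- lapply(cfg$dms$concentrations, function(cc)
          simulate_ionogram(sp$base_cv_V,
                            sp$shift_slope_V_per_molpct %||% 0,
                            sp$width_V %||% 0.5, sp$height %||% 1000,
                            sp$noise_sd %||% 0, concentration = cc,
                            seed = seed + 4L, species_label = sp$label))
        cv_shift_series(series)
      })
      list(series = series_list,
           ranking = rank_clustering_propensity(series_list))
    })
  }

  # 8. report + artefacts
  for (p in names(refined$selections))
    for (cf in refined$selections[[p]]$conformers)
      write_pdb(cf, file.path(out_dir,
                              sprintf("selected_%s_%s.pdb", p, cf$label)))
  flags <- ensemble_stage_flags(ens, refined)
  write.table(flags, file.path(out_dir, "stage_flags.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("conformerge")),
      master_seed = seed,
      module_seeds = list(sampling = seed + 1L, ccs = seed + 2L,
                          microsolvation = seed + 3L, dms = seed + 4L),
      schedule = unclass(schedule),
      R0_A = R0),
    ensemble = list(
      n_conformers = length(ens$conformers),
      energy_range_kcal = range(vapply(ens$conformers,
                                       function(x) x$energy, numeric(1))),
      ccs_range_A2 = range(ensemble_ccs(ens)),
      r_da_range_A = range(vapply(ens$conformers, marker_distance,
                                  numeric(1)))),
    experimental = list(r_da_A = as.list(r_da)),
    refinement = list(counts = refined$counts,
                      peaks = refined$peaks),
    microsolvation = if (!is.null(micro)) list(
      comparison = micro$comparison,
      per_peak = lapply(micro$per_peak, function(g) lapply(g, function(x)
        list(n_sites = x$n_sites,
             e_interaction_kcal = x$e_interaction_kcal)))),
    dms = if (!is.null(dms)) list(
      ranking = dms$ranking,
      slopes = lapply(dms$series, function(s)
        list(species = s$species_label,
             slope_V_per_molpct = s$slope_V_per_molpct))))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

#' @noRd
ensemble_stage_flags <- function(ens, refined) {
  labs <- ensemble_labels(ens)
  filt <- unlist(lapply(refined$selections, function(s)
    ensemble_labels(s)), use.names = FALSE)
  en <- vapply(ens$conformers, function(x) x$energy, numeric(1))
  data.frame(label = labs, energy_kcal = en,
             ccs_A2 = ensemble_ccs(ens),
             r_da_A = vapply(ens$conformers, marker_distance, numeric(1)),
             selected = labs %in% filt)
}
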