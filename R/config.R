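# YAML run configuration: schema validation with defaults, all problems
# reported at once.

config_schema <- list(
  seed = 1L,
  output_dir = "conformerge_out",
  peptide = list(sequence = NULL, conformation = "helix",
                 marker_sites = NULL, charge_sites = integer(0),
                 marker_charges = c(0, 0), pdb = NULL),
  sampling = list(n_roots = 10L, n_children = 5L, heat_steps = 50L,
                  plateau_steps = 3950L, cool_steps = 500L,
                  hold_steps = 500L, t_max_K = 1500, step_sigma_deg = 10,
                  minimize_evals = 5000L),
  ccs = list(probe_radius_A = 1.0, n_orientations = 300L, n_hits = 10000L,
             scale_factor = 1.0),
  photophysics = list(J_nm4_M_cm = NULL, phi_D = NULL, kappa2 = 2 / 3,
                      n_medium = 1.0, tau_D_ns = NULL),
  constraints = list(peaks = NULL, selection_rule = "closest",
                     k_select = 5L, energy_fraction = 0.2,
                     r_da_sigma_A = 0),
  microsolvation = list(enabled = TRUE, spacing_A = 0.75, margin_A = 4,
                        n_orient = 12L, threshold_kcal = -1.5,
                        min_separation_A = 3.5),
  dms = list(enabled = FALSE, species = NULL,
             concentrations = c(0, 0.2, 0.4)))

#' Validate a pipeline run configuration
#'
#' Reads a YAML file, checks it against the configuration schema (unknown
#' keys are rejected), applies defaults and validates invariants
#' (referenced files exist, seeds are non-negative integers, required
#' fields present). All problems are reported in a single error.
#'
#' @param path YAML file path.
#' @return a fully defaulted list of class `run_config`; attribute
#'   `defaults_applied` lists every default that was filled in.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  defaults <- character(0)
  merge_block <- function(schema, given, prefix) {
    out <- schema
    for (key in names(given)) {
      if (!key %in% names(schema)) {
        problems <<- c(problems,
                       paste0("unknown key '", prefix, key, "'"))
        next
      }
      if (is.list(schema[[key]]) && !is.null(names(schema[[key]])) &&
          !key %in% c("peaks", "species", "marker_charges")) {
        out[[key]] <- merge_block(schema[[key]],
                                  as.list(given[[key]] %||% list()),
                                  paste0(prefix, key, "."))
      } else {
        out[[key]] <- given[[key]]
      }
    }
    for (key in setdiff(names(schema), names(given))) {
      if (is.list(schema[[key]]) && !is.null(names(schema[[key]]))) {
        out[[key]] <- merge_block(schema[[key]], list(),
                                  paste0(prefix, key, "."))
      } else if (!is.null(schema[[key]])) {
        defaults <<- c(defaults, paste0(prefix, key))
      }
    }
    out
  }
  cfg <- merge_block(config_schema, raw, "")

  # YAML 1.1 reads exponents without a sign ("3.848e15") as strings;
  # coerce anything number-shaped back to numeric
  coerce_nums <- function(x) {
    if (is.list(x)) return(lapply(x, coerce_nums))
    if (is.character(x) && length(x) > 0 &&
        all(grepl("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", x)))
      return(as.numeric(x))
    x
  }
  cfg <- coerce_nums(cfg)

  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed) && cfg$seed >= 0,
      "seed must be a non-negative integer")
  if (is.null(cfg$peptide$pdb)) {
    chk(!is.null(cfg$peptide$sequence), "peptide.sequence is required")
  } else {
    chk(file.exists(cfg$peptide$pdb),
        paste0("peptide.pdb not found: ", cfg$peptide$pdb))
  }
  chk(cfg$constraints$energy_fraction > 0 &&
        cfg$constraints$energy_fraction <= 1,
      "constraints.energy_fraction must be in (0, 1]")
  chk(!is.null(cfg$photophysics$J_nm4_M_cm) || is.null(cfg$constraints$peaks)
      || all(vapply(cfg$constraints$peaks,
                    function(p) !is.null(p$r_da_A), logical(1))),
      "photophysics.J_nm4_M_cm required to convert lifetimes to distances")
  if (!is.null(cfg$constraints$peaks)) {
    for (i in seq_along(cfg$constraints$peaks)) {
      p <- cfg$constraints$peaks[[i]]
      chk(!is.null(p$label) && !is.null(p$ccs_A2),
          sprintf("constraints.peaks[%d] needs label and ccs_A2", i))
      chk(!is.null(p$r_da_A) || !is.null(p$tau_DA_ns),
          sprintf("constraints.peaks[%d] needs r_da_A or tau_DA_ns", i))
    }
  }
  if (isTRUE(cfg$dms$enabled))
    chk(!is.null(cfg$dms$species), "dms.species required when dms.enabled")
  ms <- cfg$microsolvation
  chk(ms$spacing_A >= 0.25 && ms$spacing_A <= 1,
      "microsolvation.spacing_A must be in [0.25, 1]")
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  attr(cfg, "defaults_applied") <- defaults
  class(cfg) <- "run_config"
  cfg
}
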