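# Simulated-annealing conformer sampling: Metropolis Monte Carlo over
# backbone (phi, psi) and marker-linker torsions with a heat / plateau /
# cool / hold temperature profile and a two-level branching tree
# (roots -> children), each leaf energy-minimised.

#' Construct an annealing schedule
#'
#' The temperature profile ramps linearly to `t_max_K` over `heat_steps`,
#' holds for `plateau_steps`, cools linearly to 0 K over `cool_steps` and
#' holds at 0 K for `hold_steps`. `n_roots` sequential annealing cycles
#' seed the tree; each root spawns `n_children` further cycles, so the
#' sampler returns exactly `n_roots * n_children` conformers. The default
#' step counts are the full protocol scaled by 1/100 to desk scale; pass
#' the full-scale counts explicitly for production runs.
#'
#' @param heat_steps,plateau_steps,cool_steps,hold_steps phase lengths in
#'   Monte-Carlo steps (all > 0).
#' @param t_max_K plateau temperature, K (default 1500).
#' @param n_roots,n_children branching factors.
#' @return an object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(heat_steps = 50, plateau_steps = 3950,
                               cool_steps = 500, hold_steps = 500,
                               t_max_K = 1500, n_roots = 10,
                               n_children = 5) {
  v <- c(heat_steps, plateau_steps, cool_steps, hold_steps, n_roots,
         n_children)
  if (any(v <= 0) || any(v != round(v)))
    stop("all step counts and branching factors must be positive integers")
  if (t_max_K <= 0) stop("t_max_K must be positive")
  structure(list(heat_steps = heat_steps, plateau_steps = plateau_steps,
                 cool_steps = cool_steps, hold_steps = hold_steps,
                 t_max_K = t_max_K, n_roots = n_roots,
                 n_children = n_children),
            class = "annealing_schedule")
}

#' @noRd
schedule_temperatures <- function(s) {
  c(seq(s$t_max_K / s$heat_steps, s$t_max_K, length.out = s$heat_steps),
    rep(s$t_max_K, s$plateau_steps),
    seq(s$t_max_K, 0, length.out = s$cool_steps),
    rep(0, s$hold_steps))
}

# One annealing cycle: Metropolis MC over torsions along the temperature
# profile, delegated to the compiled kernel. Returns coords, energy and the
# plateau acceptance rate.
#' @noRd
anneal_cycle <- function(xyz, model, torsions, schedule,
                         step_sigma_deg = 10) {
  temps <- schedule_temperatures(schedule)
  tor_a <- vapply(torsions, function(t) t$a - 1L, integer(1))
  tor_b <- vapply(torsions, function(t) t$b - 1L, integer(1))
  moved <- lapply(torsions, function(t) as.integer(t$moved - 1L))
  moved_ptr <- as.integer(c(0L, cumsum(lengths(moved))))
  res <- cpp_anneal_cycle(xyz, model$pi0, model$pj0, model$sig, model$eps,
                          model$qq, model$hbN0, model$hbO0, model$hbC0,
                          model$hb_depth, model$hb_r0, model$hb_w,
                          tor_a, tor_b, unlist(moved), moved_ptr,
                          temps, step_sigma_deg * pi / 180,
                          schedule$t_max_K, schedule$heat_steps,
                          schedule$plateau_steps)
  list(xyz = res$coords, energy = res$energy,
       plateau_acceptance = res$plateau_acceptance)
}

#' Sample a conformer ensemble by simulated annealing
#'
#' Runs the branching annealing protocol from a start conformer:
#' `n_roots` sequential heat/plateau/cool/hold cycles (each cycle restarts
#' from the previous cycle's end point), then `n_children` cycles from each
#' root. Every leaf is energy-minimised in torsion space
#' (steepest descent switching to conjugate gradient after 1000
#' evaluations, 5000 evaluations maximum). Per-branch seeds are drawn once
#' from the master seed, so the ensemble is bit-for-bit reproducible given
#' `(start, schedule, seed)`.
#'
#' @param start a [conformer()] with torsion metadata.
#' @param schedule an [annealing_schedule()].
#' @param seed master integer seed.
#' @param step_sigma_deg Gaussian torsion step at the plateau temperature,
#'   degrees; scaled with sqrt(T/t_max) elsewhere.
#' @param minimize_evals max energy evaluations per leaf minimisation.
#' @return a [conformer_ensemble()] of `n_roots * n_children` minimised
#'   conformers labelled `r<root>c<child>`.
#' @export
anneal_sample <- function(start, schedule, seed = 1, step_sigma_deg = 10,
                          minimize_evals = 5000) {
  stopifnot(inherits(start, "conformer"),
            inherits(schedule, "annealing_schedule"))
  torsions <- start$torsions %||% derive_torsions(start)
  model <- prepare_energy_model(start)
  n_branch <- schedule$n_roots * (1 + schedule$n_children)
  branch_seeds <- with_seed(seed,
                            sample.int(.Machine$integer.max - 1, n_branch))
  conformers <- vector("list", schedule$n_roots * schedule$n_children)
  xyz_root_start <- conformer_coords(start)
  b <- 0L
  k <- 0L
  for (r in seq_len(schedule$n_roots)) {
    b <- b + 1L
    root <- with_seed(branch_seeds[b],
                      anneal_cycle(xyz_root_start, model, torsions, schedule,
                                   step_sigma_deg))
    if (root$plateau_acceptance == 0)
      stop("zero acceptance at plateau: torsion step size pathological")
    xyz_root_start <- root$xyz  # next root continues from here
    for (ch in seq_len(schedule$n_children)) {
      b <- b + 1L
      leaf <- with_seed(branch_seeds[b],
                        anneal_cycle(root$xyz, model, torsions, schedule,
                                     step_sigma_deg))
      cf <- set_coords(start, leaf$xyz)
      cf$label <- sprintf("r%02dc%02d", r, ch)
      cf <- minimize_conformer(cf, model, max_evals = minimize_evals)
      k <- k + 1L
      conformers[[k]] <- cf
    }
  }
  conformer_ensemble(conformers,
                     provenance = list(schedule = unclass(schedule),
                                       seed = seed,
                                       step_sigma_deg = step_sigma_deg,
                                       start_label = start$label))
}
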