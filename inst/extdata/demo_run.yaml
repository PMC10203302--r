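# Demonstration pipeline configuration: a doubly labelled 24-mer
# alpha-helical peptide sampled at desk scale (10 roots x 5 children with
# the 1/100-scale annealing cycle), refined against two synthetic
# ion-mobility peaks and a lifetime-derived FRET distance, then scored
# for acetonitrile microsolvation and summarised against simulated DMS
# CV-shift series.
seed: 1
output_dir: demo_out
peptide:
  sequence: CAAAHAAAHAAAAHAAAHAAACAK
  conformation: helix
  marker_sites: [1, 22]
  charge_sites: [5, 9, 14, 19]
  marker_charges: [1, 1]
sampling:
  n_roots: 10
  n_children: 5
  heat_steps: 50
  plateau_steps: 3950
  cool_steps: 500
  hold_steps: 500
  t_max_K: 1500
  minimize_evals: 1000
ccs:
  probe_radius_A: 1.0
  n_orientations: 150
  n_hits: 5000
photophysics:
  J_nm4_M_cm: 3.848e+15
  phi_D: 0.63
  kappa2: 0.6667
  n_medium: 1.0
  tau_D_ns: 6.80
constraints:
  peaks:
    - label: C1
      ccs_A2: 550
      tolerance_fraction: 0.03
      tau_DA_ns: 2.2
    - label: C2
      ccs_A2: 575
      tolerance_fraction: 0.03
      tau_DA_ns: 2.5
  selection_rule: closest
  k_select: 5
  energy_fraction: 0.2
microsolvation:
  spacing_A: 1.0
  margin_A: 4
  n_orient: 8
dms:
  enabled: true
  concentrations: [0, 0.2, 0.4]
  species:
    - label: compact-helix
      base_cv_V: 6
      shift_slope_V_per_molpct: 12
      width_V: 0.5
      height: 1000
      noise_sd: 10
    - label: open-isomer
      base_cv_V: 8
      shift_slope_V_per_molpct: 6
      width_V: 0.5
      height: 900
      noise_sd: 10
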