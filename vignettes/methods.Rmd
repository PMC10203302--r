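---
title: "Models and methods behind conformerge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind conformerge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformerge)
```

conformerge determines gas-phase peptide structures by combining three
orthogonal experimental observables — fluorescence-lifetime FRET
distances, ion-mobility collision cross sections (CCS), and differential
ion mobility (DMS) behaviour — with a conformer-generation and refinement
engine, and then rationalises DMS behaviour through microsolvation
scoring. This vignette explains the models, their assumptions, the
tunable parameters and the deliberate simplifications.

## Photophysics: from decay curves to distances

The spectral overlap integral is computed by trapezoid quadrature on the
union grid of the donor emission and acceptor extinction tables restricted
to their common wavelength range,

$$J = \frac{\int F_D(\lambda)\,\epsilon_A(\lambda)\,\lambda^4\,d\lambda}
           {\int F_D(\lambda)\,d\lambda}
  \quad [\mathrm{nm^4\,M^{-1}\,cm^{-1}}],$$

with linear interpolation of both spectra onto that grid. Quadrature
accuracy is bounded by the input sampling; convergence with grid density
is the caller's responsibility (the unit tests verify agreement with a
0.02-nm reference quadrature at 1-nm input sampling to 0.1%).

The Förster radius uses the standard constant for these units,

$$R_0 = 0.211\,\bigl(\kappa^2\,n^{-4}\,\Phi_D\,J\bigr)^{1/6}\ \mathrm{\AA}.$$

The orientation factor defaults to $\kappa^2 = 2/3$ (isotropic dynamic
averaging); it is an explicit parameter because gas-phase dye mobility is
not guaranteed to average isotropically. The refractive index is 1.0 for
in-vacuo work and 1.33 for aqueous solution. FRET efficiencies come from
donor lifetimes, $E = 1 - \tau_{DA}/\tau_D$, and invert to distances
through $r_{DA} = R_0((1-E)/E)^{1/6}$. Measured $\tau_{DA} > \tau_D$
(negative apparent transfer) clamps to $E = 0$ with a warning rather than
erroring, because it is a common small-signal artifact. The donor-only
reference lifetime may legitimately come from a different charge state
than the quenched species; that pairing is always explicit user input,
never inferred.

Lifetimes are fitted by weighted least squares (Levenberg–Marquardt via
minpack.lm) with Poisson weights, variance $\max(y_i, 1)$ so empty bins
carry weight one. All models are built from the exponentially modified
Gaussian — an exponential decay convolved with a Gaussian instrument
response, evaluated in closed form with the complementary error function
in log space for stability. `gaussmod` fits lifetime, amplitude and both
IRF parameters; `single_exp`/`double_exp` fix the IRF width to the
histogram's annotated value (zero when absent). With a zero-width IRF the
onset $\mu$ is exactly collinear with the amplitude, so it is fixed at
the histogram maximum; this keeps the Hessian invertible and the reported
parameter covariance meaningful. Initialisation is a deterministic
multi-start over log-spaced lifetimes; the converged fit with the lowest
$\chi^2$ wins, with ties broken towards the smaller short lifetime.
Model comparison uses the reduced $\chi^2$. A double-exponential fit
whose lifetimes differ by less than 20% warns as ill-conditioned.
Simulation checks at $10^5$ photons show recovery within 2% (gaussmod)
and 5% (double-exponential), estimator bias below 0.5% and approximately
nominal 95% interval coverage over 200 replicates; these tolerances are
what the test suite asserts.

## Collision cross sections

The projection approximation (PA) treats each atom as a disk of radius
(van der Waals + probe) and averages the area of the union of projected
disks over orientations. Orientations come from a Halton (2, 3, 5)
low-discrepancy sequence mapped through Shoemake's uniform-quaternion
construction, with a seeded Cranley–Patterson shift; per-orientation
areas are measured by uniform rejection sampling in the projection's
bounding box. Defaults: probe radius 1.0 Å (a nitrogen-like buffer gas),
300 orientations, $10^4$ sample points per orientation; the quoted
standard error is the between-orientation standard error of the mean.
The shipped van der Waals radii are Bondi-type (H 1.1, C 1.7, N 1.55,
O 1.52, S 1.8 Å) and can be overridden per atom through the PDB dialect
below. Scaled-PA conventions used by some published calculators are
available through an explicit `scale_factor` (default 1.0); no implicit
rescaling is performed because the exact scaling functions of external
tools are not public.

Travelling-wave calibration follows the standard power-law scheme: drift
times are dead-time corrected ($t' = t_D - c\sqrt{m/z}$, with $c$ an
instrument constant defaulting to 0), reference CCS values are reduced by
$\sqrt{\mu}/z$ (reduced mass $\mu$ against the buffer gas), and
$\ln CCS'$ is fitted linearly in $\ln t'$. Calibrations at different wave
heights are separate calibrations and are never pooled. A fit with
$r^2 < 0.98$ warns; extrapolation beyond the calibrated drift range
warns.

## The reduced conformer model

Conformers use a reduced representation: backbone heavy atoms (N, CA, C,
O) with ideal bond geometry, one unified side-chain pseudo-atom per
residue with a size-dependent radius, and one pseudo-atom per dye marker
placed 5 Å along the side-chain vector of its attachment residue. The
calculated donor–acceptor distance of a model is the Euclidean distance
between the two marker atoms. This representation replaces all-atom
force-field models: it keeps sampling, CCS and microsolvation testable at
desk scale while preserving the geometric observables the workflow
consumes (marker distance, projected area, solvent-accessible sites). It
is a stand-in by design, not a reimplementation of a biomolecular force
field, and nothing in the package compares its energies to published
force-field energies.

The stand-in energy is a Lennard-Jones 12-6 plus Coulomb sum (dielectric
1, in vacuo) over pairs at bond separation ≥ 3, plus a backbone
hydrogen-bond term: a Gaussian well in the N···O distance (centre 2.9 Å,
width 0.4 Å, depth 1 kcal/mol) gated by the C=O···N angle through a
$\cos^2$ factor active beyond 90°. Backbone amide dipoles carry ±0.4 e;
protonation sites (+1 e) are placed per user configuration to emulate
charge states, and dye markers can carry their own charge. Overlapping
atoms (r < 0.1 Å) contribute a large finite penalty and a warning instead
of an infinity, which keeps Monte-Carlo moves and minimisation
well-defined.

Sampling is Metropolis Monte Carlo over backbone ($\phi$, $\psi$) and
marker-linker torsions. The temperature profile ramps linearly to 1500 K,
holds, cools linearly to 0 K and holds again; the default step counts
(50 / 3950 / 500 / 500) are the full protocol scaled by 1/100 to desk
scale, and full-scale counts are available through configuration. Torsion
steps are Gaussian with σ = 10° at the plateau, scaled by
$\sqrt{T/T_{max}}$. The branching tree runs `n_roots` sequential cycles
(each continuing from the previous root's end point) and `n_children`
cycles per root, so the requested ensemble size is exactly their product;
per-branch seeds are drawn once from the master seed, which makes
ensembles bit-for-bit reproducible. Each leaf is energy-minimised with
steepest descent switching to Polak–Ribière conjugate gradient after 1000
energy evaluations (5000 maximum). Minimisation operates in torsion
space, not Cartesian space: the reduced energy has no bonded terms, so
Cartesian descent would be ill-posed (bonds would collapse), whereas
torsion moves preserve the rigid ideal geometry exactly. Gradients are
chain-ruled from the Cartesian nonbonded gradient.

## Refinement cascade

Refinement composes four stages. (1) The energy cutoff keeps the lowest
20% **by rank** (percentile), not 20% of the energy range — rank is
scale-free, which matters for a stand-in energy; the fraction is a
parameter. (2) CCS matching assigns a conformer to every experimental
peak whose fractional window contains it; the default window is ±2%
(peak-specific overrides allowed), membership is strict at the window
edge, and conformers matching no peak or several peaks are reported.
(3) Distance selection keeps the k = 5 structures per peak either closest
to the experimental distance (`closest`) or closest from below
(`closest_below`, for the case where the Förster radius is suspected to
be overestimated); a shortfall under `closest_below` falls back to
`closest` with a warning so batch runs survive. Signed differences are
used throughout — the code never assumes all candidates lie below the
experimental value. (4) The overestimation report is the signed percent
gap $100(r_{exp} - \overline{r_{calc}})/r_{exp}$, positive when the
experiment exceeds the model. All ties break by conformer label, making
the cascade deterministic and permutation-invariant, and tests verify the
selection against exhaustive enumeration on small ensembles.

## Microsolvation

The microsolvation module locates favourable solvent-modifier binding
sites and scores them, standing in for trajectory-averaged grid solvation
analysis. A rigid three-site acetonitrile-like probe (collinear
methyl–C–N, net charge zero) is swept over a regular grid (default
spacing 0.5 Å within 0.25–1 Å, margin 6 Å); each voxel stores the minimum
probe–solute LJ + Coulomb energy over 32 seeded quasi-random
orientations, with orientations clashing into the solute core (any
site–atom distance below 0.7× the van der Waals sum) clamped to +50
kcal/mol. Sites are local minima below −1.5 kcal/mol, accepted greedily
by ascending energy subject to a 3.5 Å pairwise separation; the grid
spacing and separation radius are engineering defaults, exposed in the
configuration. Explicit probes are then placed at each site in its
map-minimising orientation and relaxed by a short rigid-body optimisation
(translation bounded at 1 Å); unresolvable clashes and probe–probe
overlaps are skipped with warnings. The linear-interaction-energy total
is the plain double sum of probe-site × solute-atom nonbonded terms,
excluding probe–probe contributions. The bulk acetonitrile self-energy
(−7.006 kcal/mol) is carried as metadata for judging whether a site
out-competes bulk solvation. Because the probe map is a minimum-energy
surface rather than a trajectory average, absolute interaction energies
live on the package's own scale; only orderings (more exposed polar
surface → more sites → more favourable totals) and analytic limits are
asserted, and the tests construct exposed-chain versus compact-ball
fixtures to pin that ordering.

## DMS ionograms

DMS data enter the workflow qualitatively, as clustering-propensity
rankings, mirroring how compensation-voltage shifts with gas-modifier
concentration are used in practice. Peak detection smooths with a
Gaussian kernel (default FWHM 0.5 V), takes local maxima with prominence
at least 5% of the global maximum, and measures widths by interpolated
half-height crossings — deliberately model-agnostic so asymmetric peaks
are handled without assuming a Gaussian shape. The CV-shift series tracks
the dominant peak across concentrations, reports gaps, and fits the shift
slope by least squares; no attempt is made to compute differential
mobility from first principles or to predict CV from structure.

## What the synthetic generators emulate — and what they do not

The generators produce TCSPC histograms (IRF ⊗ exponential mixtures with
Poisson statistics), exact power-law calibrant tables, Gaussian ionograms
with linear concentration shifts, and annealed conformer ensembles. They
emulate the statistical structure of the real measurements — shot noise,
finite windows, multi-component decays, conformer heterogeneity — but not
detector afterpulsing or background, space-charge effects, real
calibrant chemistry, non-linear CV responses, or all-atom energetics.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and behave with the right limits, orderings and statistical
calibration; they do not certify accuracy on any particular instrument's
data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty site lists are valid,
flat ionograms give empty peak sets, singleton groups report undefined
SEMs, and every cascade stage failure carries its stage name. The test
suite and the demo configuration run at reduced problem sizes chosen as
the package's own desk-scale defaults: 1/100-scale annealing cycles,
ensembles of 4–200 conformers, 25–150 PA orientations, 1 Å solvation
grids with 8–16 orientations, and $10^5$-photon decay simulations. The
full-scale protocol (5000 conformers from 100 × 50 cycles, 300+
orientations, 0.5 Å grids) is available through configuration unchanged.

## Known limitations

The stand-in energy cannot reproduce published force-field energy scales,
only orderings; PA CCS systematically underestimates trajectory-method
CCS for large ions (the explicit `scale_factor` exists for that reason);
the microsolvation map has no entropic component; and automated
cross-charge-state peak assignment in DMS is out of scope. The
closest-below selection's fallback changes selection semantics when fewer
than k candidates lie below the experimental distance — it warns
precisely because that changes the interpretation of the overestimation
statistic.
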