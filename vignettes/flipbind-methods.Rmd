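---
title: "Methods: toy-scale thermodynamics, kinetics and NMR observables of type-II inhibitor binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: toy-scale thermodynamics, kinetics and NMR observables of type-II inhibitor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipbind)
```

## The problem this package models

Type-II kinase inhibitors such as Imatinib bind an inactive conformation
of the catalytic domain in which the conserved DFG motif has flipped from
"in" to "out". Whether the kinase flips first and the drug selects the
rare DFG-out state (conformational selection, "flip-bind") or the drug
binds first and drives the flip (induced fit, "bind-flip") is a classic
mechanistic question, usually attacked with a combination of enhanced-
sampling free-energy calculations, interface-sampling kinetics, and
solution NMR/SPR measurements.

`flipbind` implements that entire computational chain at desk scale. The
all-atom system is replaced by analytic toy free-energy landscapes whose
topography mirrors the kinase-inhibitor problem: a deep bound basin with
two near-degenerate poses A and B, a main unbinding transition state near
path coordinate `s = 12`, a metastable external ("deep pocket") pose C
about 4 kcal/mol above the main minimum near `s = 15`–`16`, and a flat
unbound plateau beyond `s = 22`. Every spectroscopic observable is
generated synthetically with known ground truth, so each fitter in the
package can be validated by parameter recovery rather than against
unavailable raw spectra.

## Landscapes and sampling

A `toy_landscape` is a sum of Gaussian wells and barriers plus soft
quadratic walls. Construction calibrates the Gaussian amplitudes by a
fixed-point iteration so that each *refined* critical point (located by
local optimization of the analytic form) sits exactly at its requested
free energy; declared minima are true local minima with gradient below
1e-6. Energies are kcal/mol throughout, with `kB = 0.0019872`
kcal/mol/K and a default temperature of 300 K (RT = 0.5961 kcal/mol).
H/D exchange uses 298 K (RT = 0.5922 kcal/mol), typical of exchange
experiments.

The default main barrier is **7 kcal/mol**, chosen so that brute-force
rate oracles (mean-first-passage-time runs) finish in minutes on one
CPU; `landscape_preset("default", barrier = 16.5)` gives the full-scale
variant used by the analytic worked examples. The binding ΔG of the toy
profile (plateau 4.5 kcal/mol above A) is a convenience choice — basin
thermodynamics is tested against quadrature, not against a target value.

Dynamics use the BAOAB splitting of Langevin dynamics (friction default
1 ps⁻¹, mass 1 in kcal/mol·ps²/u²), a stable, well-characterized
integrator for toy potentials. The time step is rejected up front if
`omega * dt >= 0.25` on the stiffest harmonic component, which keeps the
per-step energy drift far below 1e-3 kT. The flip axis `q_flip` of the
2D variant is an independent Gaussian double well (DFG-in deeper by
6 kcal/mol, the apo flip penalty) with an optional bilinear coupling to
`s`; it is evaluated analytically (quadrature) — the dynamics engine
integrates the 1D path coordinate, which is all the sampled estimators
need.

## Path collective variables

`compute_path_cv()` implements the standard progress/distance pair
\[
s = \frac{\sum_i i\, e^{-\lambda d_i^2}}{\sum_i e^{-\lambda d_i^2}},
\qquad
z = -\frac{1}{\lambda} \log \sum_i e^{-\lambda d_i^2} ,
\]
with 1-based frame indexing so that `s` spans `[1, N]` and the default
`N = 30` maps the landmark values (main TS near 12, external pose near
15–16, flip comparison near 25) directly onto the toy landscape scale.
Sums are evaluated with a max-shift (log-sum-exp); a configuration whose
nearest frame is beyond exponential range raises an explicit "off-path"
error instead of returning NaN. `build_reference_path()` reparametrizes
any ordered source polyline to near-uniform arc-length spacing, and
`choose_lambda()` applies the standard heuristic
`lambda = 2.3 / <d²_adjacent>`, which makes neighbouring frames
resolvable.

## Metadynamics and profile reconstruction

`run_metad()` deposits Gaussian hills every `pace` steps with the
well-tempered schedule `w_k = w0 exp(-V_b(s_k)/(kB ΔT))`,
`ΔT = (γ-1)T`; multiple walkers share one bias (accumulated on a grid
for O(1) force evaluation), and `γ = Inf` recovers standard
metadynamics. Defaults `w0 = 0.1` kcal/mol, `σ = 0.3` s-units,
`pace = 500` steps, `γ = 8` converge the 7 kcal/mol preset barrier in
about two minutes of CPU; they are toy-scale calibrations, not values
taken from any particular protein study. Hills logs use the PLUMED text
dialect (`#! FIELDS time s sigma_s height biasf walker`) and the reader
is strict about positive widths and heights.

The free energy is `F(s) = -γ/(γ-1) V_b(s)`, min-shifted. Because a
metadynamics profile is defined only up to a constant, uncertainties are
taken over **mean-aligned** profile snapshots reconstructed at evenly
spaced times in the final window (default: final 20% of deposition,
10 snapshots). For basin free-energy differences, `metad_dG()` evaluates
the difference at each snapshot and reports a 95% half-width from the
snapshot spread — this captures the correlated drift of the whole
profile, which per-bin standard deviations systematically miss.

## Basin thermodynamics

`basin_free_energy()` integrates `exp(-F/kT)` by trapezoidal quadrature
on the reconstruction grid (validated against a 10x refined grid) and
propagates per-bin errors by 200 seeded Gaussian resamples. Basin
boundaries default to the watershed of the separating saddle: each bin
is assigned to the minimum it drains to by steepest descent
(`watershed_basins()`); no published basin definition exists for this
kind of profile, so the watershed — the only parameter-free choice — is
used. The standard-state correction is `kT log(V_unbound / V0)` with
`V0 = 1660` Å³ (1 M); the identity `ΔG_std = ΔG_raw + correction` is
exact by construction.

`combine_cycle()` assembles the two routes: flip-bind (path association
ΔG plus the DFG-flip penalty) and bind-flip (a single path term). With
the printed components −14 and +6.0 kcal/mol the flip-bind total is
−8 kcal/mol, matching the bind-flip route — the cycle-closure check
`cycle_closure()` makes that comparison explicit with combined error
bars.

On populations of the external pose: a point-state Boltzmann factor for
ΔΔG = 4.0 kcal/mol at 300 K gives 0.12%, while integrating the (broad)
minor basin against the bound basin gives several-fold more, up to the
percent range depending on basin widths. The two conventions answer
slightly different questions, so the package reports both
(`boltzmann_population()` for point states, basin integrals for the
rest) and does not force agreement.

## Kinetics

The unbinding rate combines the barrier with an interface-shooting
transmission coefficient. `run_shooting()` launches unbiased
trajectories from interfaces spanning the barrier (default: 5 evenly
spaced over saddle ± 1 s-unit) with Maxwell-Boltzmann velocities and
records commitment to the bound or unbound watershed (shrunk by one
grid bin to avoid boundary flicker). The recrossing factor is the
positive-flux estimator at the saddle, `κ_rec = p⁺ − p⁻` (the
difference between the unbound-commitment probabilities of forward- and
backward-launched trajectories), with binomial confidence intervals.

Because the toy dynamics are diffusive, simple transition-state theory
overestimates the rate badly; the computed rate is
`k = κ_rec × k_TST_flux`, where `k_TST_flux` is the classical
positive-flux rate through the dividing surface
(`tst_rate_flux()`). Results are reported in the Eyring convention —
`k = (kB T/h) κ exp(-ΔG‡/RT)` with `κ` the effective transmission
coefficient implied by `k` — so the rate identity holds exactly and `κ`
absorbs both recrossing and the diffusive prefactor, mirroring how a
measured or computed rate is inverted against a known barrier. The
brute-force mean-first-passage oracle (`brute_force_mfpt()`) is the
correctness arbiter: on the 7 kcal/mol preset the shooting-based rate
agrees with it within a factor of 2. The reported sampling range on `k`
comes from the binomial interval on the recrossing factor.

SPR dissociation phases are fitted as `R(t) = R0 exp(-kd t) + c` by
Levenberg-Marquardt least squares with asymptotic confidence intervals;
the fit is invariant to response rescaling, and non-decaying or
zero-amplitude inputs raise explicit errors rather than returning
meaningless rates.

## NMR observables

**Model-free analysis.** Forward rates use the Lipari-Szabo spectral
density with the community-standard 15N constants (N-H 1.02 Å, CSA
−160 ppm, standard gyromagnetic ratios) — isotropic tumbling only. The
fit is two-stage: the global `τc` from the trimmed R2/R1 ratio
(S²-independent in the single-Lorentzian limit), refined by minimizing
the pooled misfit of a rigid subset; then per-residue selection among
(S²), (S², τe) and (S², Rex) by `χ² + 2k` with ties toward the simpler
model. Errors are floored at 0.1% of the observable so zero-noise data
remain well-posed. The default synthetic tumbling time is 18 ns — a
plausible value for a ~32 kDa kinase domain, chosen here as a package
default rather than taken from any measurement.

**R1R2 product.** Exchange-broadened residues are flagged when
`R1*R2` exceeds the 10%-trimmed mean by 1.5 trimmed standard deviations
(configurable); the product is used because it cancels the leading
τc dependence that makes R2 alone ambiguous.

**CSP.** Combined shifts use
`Δδ = sqrt(ΔδH² + (α ΔδN)²)` with `α = 0.15` (configurable — the common
community weighting). Signals are classed appearing/disappearing/
unchanged, and the bookkeeping block reports total, visible and assigned
counts with the assigned-of-visible percentage (268/196/179 → 91%).

**CSI.** Secondary shifts against a built-in simplified random-coil
HN/N table, three-level index with a configurable threshold (default
0.7 ppm for amide protons).

**Trajectory dynamics.** S² from the plateau of the P2 orientational
autocorrelation of unit bond vectors (mean over the final half of the
computed lag range); the uniform-cone closed form
`S² = [cosθ(1+cosθ)/2]²` is the analytic validation target across cone
angles, and `compare_s2()` reports the mean percentage deviation between
simulated and fitted order parameters.

**H/D exchange.** `hdx_fit()` fits single exponentials per residue,
forms `P = k_intr/k_exch` and `ΔG_unfold = RT log P` (exact identity;
P = 1000 at 298 K gives 4.09 kcal/mol). Residues fully exchanged before
the first timepoint become upper bounds on P, non-decaying curves lower
bounds — bounds are flagged, never silently converted to numbers.
Intrinsic rates are primarily a per-residue *input*; the shipped
sequence-based calculator (`intrinsic_rates()`, version
"BE93-simplified-1") is a simplified reference implementation with a
reduced coefficient table, adequate for synthetic work only.

## What the synthetic data do and do not show

The generators emulate the *statistical structure* of the real
measurements: mean order parameters of 0.85 (apo) and 0.87 (bound) with
flexible termini and loops, pocket-localized shift perturbations,
protection factors spanning 10–10⁶, single-exponential dissociation
with `kd` drawn in [0.024, 0.19] s⁻¹, and spectra with 268 amides of
which 196 are visible and 179 assigned. Noise defaults are Gaussian:
2% (relaxation), 3% absolute (HDX), 1 RU (SPR) — typical instrument
precision. What they deliberately do **not** model: anisotropic
tumbling, peak overlap and spectral processing artifacts, baseline
drift and mass-transport effects in SPR, EX1 exchange kinetics, or
correlated noise. Passing the recovery suites therefore demonstrates
estimator correctness under the stated noise model, not robustness to
every pathology of real data.

## Numerical choices and problem sizes

Tolerances and sizes used by the shipped tests, all chosen to keep the
full suite within a coffee break on one CPU: metadynamics convergence
runs use 2×10⁶ steps (dt 0.02 ps) on the asymmetric double well, whose
basin split is calibrated by quadrature to exactly 1.0 kcal/mol; the
kinetics cross-check uses 40 first-passage runs and 5×300 shooting
trajectories on the 7 kcal/mol preset at dt 0.04 ps and friction
0.7 ps⁻¹ (identical dynamics for estimator and oracle, so the
comparison is exact in distribution); model-free recovery uses 250
residues; coverage experiments use 100 seeded repeats. Quadratures use
`integrate()` at rel.tol 1e-10 or trapezoids on grids at least twice as
fine as the hill width. Degenerate inputs (flat profiles, empty hills
logs, single wells, zero-amplitude sensorgrams, non-decaying HDX
curves) raise warnings or errors by design and are covered by tests.

## Known limitations

1D dynamics along the path coordinate (the flip axis is analytic);
no reweighting of auxiliary observables from the metadynamics bias; no
full RETIS/forward-flux machinery (the shooting estimator is validated
only against its own brute-force oracle); isotropic diffusion only in
the model-free stage; the intrinsic-rate calculator is simplified. The
toy landscape is calibrated to landmark positions and energy gaps, not
to the shape of any particular computed surface.
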