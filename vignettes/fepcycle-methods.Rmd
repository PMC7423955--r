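---
title: "Methods: alchemical free energy cycle analysis with fepcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alchemical free energy cycle analysis with fepcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepcycle)
```

## The model

Relative binding free energies (ΔΔG) of protein mutations are obtained
from a thermodynamic cycle with two alchemical legs: the residue is
mutated in the apo protein (ΔG_apo) and in the holo, ligand-bound
protein (ΔG_holo), and ΔΔG = ΔG_holo − ΔG_apo. Each leg is a
λ-parameterized path between chemical end states, subdivided into
equally spaced windows (`make_windows()`; the conventional 40-window
grid makes the first window span λ = 0–0.025). In the dual-topology
scheme both end-state atom sets coexist without interacting with each
other; `coupling_at()` encodes the schedule by which their
environment interactions are scaled: van der Waals linearly across the
whole range, electrostatics split so the outgoing charges vanish by
λ = 0.5 before the incoming charges appear. Short-range repulsion of
partially coupled atoms is softened by a Beutler-style soft core
(`softcore_pair_energy()`), E = 4ελ(s² − s) with
s = σ⁶ / (α(1−λ)σ⁶ + r⁶), which reduces exactly to Lennard-Jones at
λ = 1 and stays finite at contact otherwise. The λ-shift is applied to
the r⁶ term only and the default α = 0.5; MD engines differ in the
precise soft-core form they implement, so the toy potential here is a
well-defined stand-in with the right limits, not a reproduction of any
engine's internal form. Likewise, the plain-linear vdW scale factor is
the simplest reading of "scaled across the full range"; engines may
fold the λ-dependence into the soft core instead, which changes
intermediate-state energies but not the end states.

## Estimators

Per window, `zwanzig()` implements exponential averaging,
ΔG = −k_B T ln⟨e^(−ΔU/k_B T)⟩, computed with a max-shift so the
exponentials never overflow; its standard error comes from the delta
method on the exponential mean. `bar()` implements the Bennett
acceptance ratio: the shift C solves
Σ_F f(β(w_F − C)) = Σ_R f(β(w_R + C)) with f(x) = 1/(1+eˣ), and
ΔG = C − k_B T ln(n_R/n_F). The left-hand side is increasing and the
right-hand side decreasing in C, so the root is unique; it is
bracketed by the two one-sided Zwanzig estimates ± 50 k_B T and
refined by `uniroot()` to a default tolerance of 1e-8 kcal/mol. The
uncertainty is Bennett's asymptotic variance evaluated at the
solution. Zero-variance inputs short-circuit to the exact
constant-work answer with zero error, avoiding degenerate root finds.

Correlated samples are thinned before estimation
(`statistical_inefficiency()`): g = 1 + 2Σρ_t with the autocorrelation
sum truncated at its first non-positive term, g clamped to
[1, n], and every ⌈g⌉-th observation retained. Subsampling is applied
per direction per window (the directions come from independent
simulations, so pooling their correlation structure would be wrong),
and a constant series — which carries no information about its own
correlation time — conservatively yields g = n with a warning.
Window estimates are summed by `accumulate()` with root-sum-square
errors, treating windows as independent, which is exact when each
window is sampled by its own simulation.

## Cycle assembly and comparison

`ddg()` forms ΔΔG = ΔG_holo − ΔG_apo with RSS errors;
`orient()` maps transformations run in the reversed direction
(mutant-to-wild-type) onto the canonical scale by negation, an
involution. Charge-changing mutations under periodic electrostatics
acquire an artefactual contribution from the neutralizing background
charge; `apply_corrections()` adds externally computed per-leg
constants (computing them — a Poisson–Boltzmann calculation — is out
of scope). Since the correction is nearly identical for apo and holo
legs of the same mutation, it largely cancels in ΔΔG: the packaged
R211S constants shift individual legs by ≈ −3.1 kcal/mol but the ΔΔG
by only +0.0012 (gbi1) and +0.0023 kcal/mol (gbi2).

`compare_to_experiment()` reports per-mutation deviations, flags
agreement within k_B T ln(fold) (default 10-fold at 300 K,
≈ 1.4 kcal/mol), and computes the mean absolute error at full
precision while also reporting it rounded to 0.1 kcal/mol — the
precision at which such tables are printed, and the form quoted in the
package's own outputs. On the packaged reference table this gives MAE
2.1 kcal/mol (gbi2, six mutations) and 1.1 kcal/mol excluding the
R211S outlier. For gbi1 the same arithmetic on the rounded table
entries gives 3.3 and 2.6 kcal/mol; values derived from unrounded
per-leg results would differ in the last digit, so the gbi1 figures
are reported as computed from the table, not asserted against any
external statement.

## Diagnostics

`work_overlap()` histograms forward and negated-reverse work on a
shared [min, max] grid (default 50 bins; the binning of published
overlap figures is rarely stated, and the coefficient is insensitive
to it at these sample sizes) and integrates the pointwise minimum of
the two densities. The coefficient is 1 for identical distributions, 0
for disjoint ones, and 2Φ(−δ/2) for unit Gaussians separated by δ — a
closed form the tests exploit. A default warning threshold of 0.03
marks windows with essentially no phase-space overlap; published work
reports such pathologies qualitatively (bimodal histograms), so the
numeric threshold is this package's choice. `hysteresis()` checks the
state-function property on independently computed opposite-direction
transformations, flagging |ΔG_fwd + ΔG_rev| > 2·RSS error.
`circular_mean()` and `angle_histogram()` (36 bins of 10°) support
dihedral-angle analysis of the floppy side chains that cause poor
overlap; a resultant length below 1e-9 leaves the mean direction
undefined and raises an error rather than returning noise.
`count_within()` counts probe points strictly closer than a cutoff to
a reference set — the primitive behind hydration counts (3 Å) and
overlapping-water pruning (2 Å). The strict-inequality boundary is a
stated convention; measure-zero ties make the choice immaterial for
real coordinates.

## Restraints

`restraint_energy()` implements a one-sided flat-bottom wall:
zero up to the wall, (k/2)(d − wall)² beyond, continuous and once
differentiable at the wall. The printed unit of the protocol's force
constant ("10 kcal/mol/Å") is dimensionally ambiguous for a harmonic
wall; it is interpreted as k = 10 kcal/mol/Å². The wall is one-sided
because its purpose is preventing excursions of decoupled charged side
chains, not compressions. `propose_upper_walls()` places walls at the
per-pair maximum of unrestrained equilibrium distances plus a margin
(default 0.5 Å), guaranteeing exactly zero restraint energy on the
calibration frames.

## Pose filtering

`rmsd()` computes plain coordinate RMSD by default — docked poses
share the receptor frame, so superposition would discard real
positional differences — with optional Kabsch superposition (via
bio3d) that can only lower the value. `reverse_cluster()` is greedy
leader clustering, visiting poses best-score-first (ties and missing
scores fall back to stable input order, making the result
deterministic and stated, where docking-tool plugins often leave the
order undocumented): a pose is retained iff its RMSD to every retained
representative strictly exceeds the cutoff (3.0 Å conventionally).
Retained representatives are therefore pairwise distinct, giving
diverse coverage of candidate binding modes. RMSD is computed over all
atoms with no symmetry equivalence handling; for ligands with
near-symmetric moieties this can overstate the distance between
mirror-equivalent poses (a documented limitation).

## The toy simulator

`sample_window()` runs Metropolis Monte Carlo (compiled, using R's
RNG for seed-reproducibility) at both window endpoints, recording
ΔU to the opposite endpoint at every step. Defaults: symmetric uniform
moves with a 3.0 Å half-width (≈ 40% acceptance on the default
harmonic spec), and a 20% burn-in mirroring a 1 ns equilibration /
4 ns production split. Per-window, per-direction seeds are derived
deterministically from the master seed, so windows are independent yet
bit-reproducible. The harmonic system (partition function ∝ k^(−1/2))
gives the analytic oracle ΔG = (k_B T/2) ln(k_final/k_initial) used
throughout the tests; the soft-core system exercises the
finite-at-contact end-point behaviour. The simulator emulates the
statistical structure of per-window FEP output — autocorrelated,
two-direction energy-difference time series with known exact answers —
but none of the physics of a solvated membrane protein: no
many-body effects, no slow conformational degrees of freedom, no
charge artefacts. Passing oracle tests therefore validates the
estimator and bookkeeping machinery, not the convergence of any real
molecular system.

## Problem sizes and numerical choices

The validation workflow uses 10-window transformations with 5·10⁴ MC
steps per direction per window over 20 seeds — enough for per-window
standard errors near 10⁻³ kcal/mol, so 3σ oracle checks are sharp —
and 4-window, 2·10⁴-step runs for the hysteresis and null-cycle
properties, where the question is consistency rather than precision.
Energies serialize at 6 decimals (the fepout round-trip contract);
k_B is fixed at 0.0019872041 kcal/mol/K and all quantities are
kcal/mol, Å, K. The statistical-inefficiency truncation (first
non-positive autocorrelation) slightly overestimates g on white noise
(≈ a 20% chance of retaining every 2nd sample) — a conservative bias
that costs efficiency, never correctness.

## Known limitations

- Pairwise BAR only; no multistate reweighting across all windows
  simultaneously.
- Analytic (asymptotic) uncertainties only; no bootstrap.
- The toy soft-core form is one specific choice among the several
  engines implement.
- Uniform λ spacing only; no adaptive window placement.
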