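---
title: "Least-action folding pathways: models, parameters, and numerical choices"
author: "admdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-action folding pathways: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The boundary-value formulation

admdr computes transition pathways as a boundary value problem.  Both
endpoint conformations are fixed; the interior of the discretized path
`q_0 … q_P` is adjusted to minimize the extended action

Φ = S + μ_E Σ_{j=0}^{P−1} (E_j − E)² + μ_K Σ_I (⟨K_I⟩ − 3k_BT/2)²,

where S is the classical action with the forward-difference Lagrangian
L_j = Σ_I m_I/(2Δ²)(q_{I,j} − q_{I,j+1})² − V(q_j), E_j is the frame total
energy built from the same forward difference, and ⟨K_I⟩ is atom I's
kinetic energy averaged over all P intervals.  The energy penalty is what
makes the problem well-posed: the discrete action alone is not bounded in
the direction of unbounded kinetic energy, and its unconstrained minimizers
need not conserve energy.  Pinning every E_j to one target E selects, among
all paths compatible with the boundary conditions, those that approximate
an energy-conserving Newtonian trajectory at that energy.  The kinetic
restraint distributes kinetic energy over atoms; its temperature T is a
path-quality knob, not a physical temperature, and is off by default
(`muK = 0`).

Assumptions worth keeping in mind: the dynamics is purely classical point
dynamics on a potential surface; the time grid is uniform; and the method
finds *local* minimizers of Φ — separate seeded runs (see
`foldingCampaign()`) stand in for global optimization, and only features
shared across runs should be interpreted.

## Path representation and multigrid refinement

Interior frames are represented in the sine basis
q_j = q_0 + (q_P − q_0)·j/P + Σ_k a_k sin(kπj/P).  Every basis function
vanishes at j = 0 and j = P, so endpoints are exact for any coefficient
vector — they are data, never variables.  The map between interior frames
and coefficients is the orthogonal type-I discrete sine transform, applied
to the residual after subtracting the straight-line interpolation; the
round trip is an identity to ~1e-12.

Optimization runs coarse-to-fine.  The default schedule doubles P from 20
and ends at 2000 (`multigridSchedule()`); refinement zero-pads the
coefficient vector, which reproduces the identical continuum curve on the
finer grid.  Two conventions are possible when P grows and the package
exposes both: holding the duration τ = PΔ fixed while Δ shrinks (default,
`fixTau = TRUE`), which makes refinement a pure basis extension, or holding
Δ fixed.  The L-BFGS relaxation at each level runs until the
projected-gradient max-norm drops below `gradTol` (default 1e-6) or
`maxIter` iterations; both are pinned in `ADMDConfig` because
reproducibility requires explicit stop conditions.

## Units and parameters

Toy surfaces use model units: masses 1, k_B = 1, so temperature carries
energy units.  For molecular systems in kcal/mol, Å, and amu, a single
documented conversion (1 kcal/mol = 418.4 amu·Å²/ps², `unitConstants()`)
keeps the kinetic prefactor m/(2Δ²) consistent with the potential.

The penalty weights are "arbitrary large constants" in principle; in
practice their scale matters and the package resolves `NA` weights at run
time so that each penalty term, evaluated on the initial trial path, weighs
about `factor` (default 100) times |S| (`resolvePenaltyWeights()`).  Two
regimes are worth knowing:

* **Bias at large μ_E.**  The forward-difference E_j sits half a step off
  the frame's potential, so E_j of an exact Newtonian path oscillates by
  O(Δ).  A dominant penalty therefore drags the path O(Δ) away from the
  true trajectory to flatten E_j.  On the harmonic-oscillator benchmark
  (P = 200) the deviation from the analytic orbit saturates near 1.4e-3
  for μ_E ≳ 1 but drops to 7.6e-4 at μ_E = 0.01 while still conserving
  energy to 0.03 % — when the target energy is exactly attainable, a light
  penalty is the better experiment, and that is what the package's
  Newtonian-recovery benchmark uses.
* **Floor at unattainable E.**  With E above the energy any Newtonian path
  can realize, the optimizer must hide the excess in grid-scale
  oscillations; the residual spread of E_j then floors at roughly 2 % of
  the excess regardless of μ_E.  In one dimension this is structural:
  flattening imposes P conditions on P−1 interior frames.

Energy conservation is accepted when sd(E_j) ≤ `conservationTol` ×
max(|E|, barrier), with a 1 % default — a quantitative proxy chosen because
"conserves energy" must be a decidable predicate.  The annealing protocol
(`annealTargetEnergy()`) lowers E stepwise (default decrement: 5 % of the
initial energy gap), warm-starts each run from the previous solution, and
returns the smallest conserving E.  Because of the floor just described,
the starting E must lie in the regime the grid can flatten; the package's
harmonic annealing benchmark starts 20 % above the analytic energy and
recovers it exactly, stopping one decrement below.  Likewise the
μ_E-tightening property (sd(E_j) non-increasing in μ_E) is measured at an
attainable target: at unattainable targets the small-μ_E limit drifts
toward the pure-action minimizer, whose *spread* is small even though its
mean energy is wrong, making the curve U-shaped and the comparison
meaningless.

## The contact, hydrogen-bond, and PCA definitions

A native contact joins residues with |i − j| ≥ 3 whose native Cα–Cα
distance is under 6.5 Å; the same cutoff decides formation in any frame,
and the Gō-chain potential uses the identical rule to pick its attractive
pairs, so "contact" means one thing everywhere.  A backbone hydrogen bond
requires O···H < 2.5 Å and a virtual angle above 135°.  The angle vertex
deserves a note: listing the atoms as oxygen–nitrogen–hydrogen suggests
measuring at N, but the N–H···O angle measured at H is the convention under
which a collinear arrangement scores 180° and physical hydrogen bonds pass
a 135° gate (angles at N are near 0° for linear bonds).  The package
defaults to the vertex-H convention and exposes `vertex = "N"` for the
literal alternative.

RMSD is the minimum over rigid motions (Kabsch superposition, via bio3d's
least-squares fit) on Cα atoms by default; backbone and all-atom
selections are options.  Rg is mass-weighted with an unweighted option.
PCA builds the 3N_α × 3N_α covariance of Cα coordinates over all frames.
Frames are superposed onto the final (native) frame by default: without
alignment the covariance mixes rigid-body and internal motion, which is
the literal definition and remains available as `alignment = "none"`.
Eigenvalues are sorted descending, variance fractions sum to one, and
per-residue contributions are the norms of each residue's three
eigenvector entries.

## The synthetic fixtures

`makeToyProtein()` builds a peptide-like chain (N, H, Cα, Cβ, C, O per
residue; the chain start lacks the amide H) twice from the same ideal bond
lengths and angles: helical dihedrals (φ = −57°, ψ = −47°) give the
compact native endpoint with i→i+4 hydrogen bonds at ~2.1 Å/165° and a
set of (i, i+3)/(i, i+4) native contacts; extended dihedrals (−135°/135°)
plus a seeded Gaussian perturbation (default 0.05 Å) give a disordered
endpoint with zero native contacts, zero hydrogen bonds, and a larger Rg.
Only dihedrals differ between the two builds, so the disordered state is
strained native topology, not a different molecule.  The Gō potential
built from the native structure makes that structure an *exact* stationary
point: bonds and 1–3 virtual bonds are harmonic at native lengths, native
Cα pairs sit in 12-6 wells with minima at native distances, and the
excluded-volume wall between non-native Cα pairs is force-shifted to zero
at 6 Å — below the 6.5 Å contact cutoff, so it is inactive at the native
state by construction.

What the fixture emulates: two-state folding between a disordered and a
compact helical endpoint, concurrent contact/H-bond formation, and chain
compaction.  What it does not: real force-field energetics, solvent,
side-chain packing beyond a single pseudo-atom, proline irregularities, or
any kinetic barrier structure beyond what the Gō bias induces.  Passing
tests on these fixtures validate the machinery — discretization, gradients,
optimization, observables — not biological conclusions about any real
protein.

## Problem sizes and study conditions

The benchmark battery (tests and `scripts/acceptance.R`) uses: P = 200 for
the 1-D Newtonian-recovery, annealing, and saddle-passage experiments;
a 12-residue, 71-atom Gō chain with P refined 16→32→64 and τ = 20 for the
five-run folding campaign (target energy 25 % of the endpoint gap above
the disordered endpoint, penalty factor 1000, trial-path amplitude 1 Å);
and N = 304, P = 2000 for the degrees-of-freedom accounting, where the
coefficient block has exactly 3·304·1999 = 1,823,088 entries.  These sizes
keep every experiment inside a few minutes on one core while leaving each
phenomenon measurable with wide margins.

## Degenerate inputs and edge behaviour

A path needs at least P = 2 (one interior frame); coefficient/endpoint
dimension mismatches, refinement to a smaller P, frame indices at j = P
(no forward neighbour), non-positive μ_E, zero-variance correlation input,
and unknown config keys are all rejected with named diagnostics.
Non-finite energies during optimization abort with the offending frame
index.  Residues without an amide hydrogen are skipped (and reported) by
the hydrogen-bond scan; glycine-like residues fall back to Cα in
side-chain distances.  `locateStationaryPoints()` warns and returns an
empty table when its scan window contains no stationary point.

## Known limitations

* Minimizers of Φ are local; different seeds can reach different pathways,
  which is why campaign-level agreement, not any single run, is the unit
  of evidence.
* The forward-difference discretization is first-order in the frame
  energies; conservation quality and Newtonian fidelity trade off through
  μ_E as described above, and both improve only linearly with P.
* The annealing window in low-dimensional systems is narrow (the E_j
  flattening floor); multi-dimensional systems hide excess energy in
  transverse modes and anneal more gracefully.
* No periodic boundaries, no constraints, no implicit solvent, no
  force-field import: potentials are the shipped analytic/coarse-grained
  surfaces or user-supplied energy/gradient closures.
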