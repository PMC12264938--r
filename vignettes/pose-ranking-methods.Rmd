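---
title: "Ranking binding poses with lambda-dynamics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking binding poses with lambda-dynamics: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambdapose)
```

## The problem

Docking can propose several geometrically plausible binding modes for one
ligand — typically a crystallographic-like pose and a "flipped" pose with
the scaffold core inverted — and scoring functions often cannot tell them
apart. A rigorous discriminator is the relative binding free energy of the
two poses, which `lambdapose` computes with dual-topology lambda-dynamics:
both poses exist simultaneously in one hybrid system, a dynamical
alchemical variable switches which pose interacts with the environment, and
the relative pose free energy follows from how often each pose dominates.

`lambdapose` implements this machinery at desk scale. Instead of an
all-atom protein, it ships a synthetic-system generator with *exactly
solvable* dual-pose toys, so every stochastic estimator in the package is
validated against a deterministic quadrature oracle rather than against
labels or folklore.

## The hybrid model

A `particle_system` has fixed environment anchors (the "protein") and, per
pose, up to three degrees of freedom of mobile particles (the "ligand" in
that pose) with:

* unscaled well potentials per particle (the bonded terms of the pose;
  bonds, angles and the like are conventionally excluded from alchemical
  scaling),
* soft-core pair interactions with the anchors, scaled by that pose's
  coupling `lambda_i` (Beutler-style separation-shifted form, softness
  `alpha = 0.5`; finite at contact for any `lambda < 1`, exactly
  Lennard-Jones at `lambda = 1`),
* no interaction term ever connecting the two poses — mirroring the
  exclusion of nonbonded terms between substituents in dual topology.

The couplings derive from unbounded angles via the FNEX form
`lambda_i = exp(c sin theta_i) / sum_j exp(c sin theta_j)` with `c = 5.5`,
so the pair `(lambda_xray, lambda_flip)` always sums to one. Restraints
(below) are *never* scaled by lambda: both poses feel them at the full
force constant in every alchemical state. That choice is what creates the
need for the end-point corrections in the thermodynamic cycle.

Units are kcal/mol, Å, ps, amu and K throughout, with
`kB = 0.0019872041 kcal/mol/K` and the default temperature 298.15 K
(`kBT = 0.59248 kcal/mol`).

## Restraining schemes

Weakly coupled poses drift without restraints. Two schemes are provided:

* **Inter-pose tethers** (`build_interpose_tethers()`): 2–4 atoms per pose
  tethered pairwise with stiff flat-bottom restraints
  (100–150 kcal/mol/Å² by convention). Applied symmetrically, their
  contribution cancels between the poses on a pose-symmetric system, which
  the test suite verifies against the exact dual-topology quadrature.
* **Multiple protein–ligand distance restraints**
  (`select_multiple_distance_restraints()`): candidate ligand–protein atom
  pairs with mean trajectory distance in a 10–15 Å band; per ligand atom
  the pair with the smallest distance fluctuation; global uniqueness so no
  atom appears twice (greedy in ascending fluctuation, ties broken by atom
  index — the order is this package's own determinization of the published
  rules); band edges `mean ± 4 Å`; force constant 40 kcal/mol/Å². For a
  flipped pose whose equilibrium trajectory drifts, statistics can come
  from a single minimized frame (`single_frame = TRUE`); every spread is
  then zero and the package breaks the degeneracy by preferring means
  closest to the band center — a convention, flagged as such.

Flat-bottom energies use `k * violation^2` with **no 1/2 factor**, matching
the NOE-style "force constant" reading; halve `k` for the other convention.
No force capping at large violations is implemented.

## The thermodynamic cycle

With protein–ligand restraints the lambda-dynamics core measures the
*restrained* pose free energy. The final answer assembles three legs
(`combine_cycle()`):

1. the cost of **adding** restraints to the xray pose,
2. the restrained core difference
   `-kBT ln(P[lambda_flip = 1] / P[lambda_xray = 1])`,
3. the cost of **removing** restraints from the flip pose.

Both corrections come from *one* reference ensemble at
`lambda = (0.5, 0.5)` with full restraints (`run_reference_state()`,
three independent replicas), re-scored at the four end-state definitions
and fed through Zwanzig's exponential average (one-step perturbation, OSP).
Signs are arranged so a never-violated restraint contributes exactly zero
and the three legs sum to the unrestrained pose difference — an identity
the tests verify exactly with the quadrature oracle.

The combined value is the exact sum of components; the combined uncertainty
is the root-sum-square of component uncertainties; rounding happens only at
presentation.

## Sampling and adaptive flattening

`run_lambda_dynamics()` propagates coordinates and theta with BAOAB
Langevin integration under independent thermostats. Defaults: `dt = 0.004`
ps for unit-scale work and `0.002` ps in the workflow (chosen so the
kinetic temperature stays within 2% of target against the steep soft-core
walls — the integrator aborts loudly on non-finite energies), friction
5 ps⁻¹, fictitious theta mass 1 amu·Å² (picked for nanosecond⁻¹-scale
endpoint transition rates on the toys), lambda saved every 10 steps.

Because intermediate lambda can carry a free-energy barrier, a tabulated
bias on lambda is optimized first (`flatten_alf()`). The stored profile
`b(lambda)` estimates the landscape; the applied Hamiltonian term is
`-b(lambda)`. Each iteration updates
`b <- b - gain * kBT * ln P_hat(lambda)` (gain 0.7, light 3-bin smoothing)
until the occupied-bin histogram ratio `max/min` is at most 10 *and* both
endpoints were visited. Exhausting the schedule returns the best bias
flagged "not flattened" — a warning, not an error, since estimates can
still be extracted and reweighted.

Two numerical choices deserve emphasis:

* **Equal-measure histogram bins.** The FNEX map concentrates sampling
  near the endpoints even on a flat landscape. Binning the histogram
  uniformly in lambda would force the bias to represent that measure
  correction — a profile with near-cliffs at the endpoint bins whose
  forces the integrator cannot resolve at the production time step, and a
  mis-integrated bias is mis-reweighted. The 50 bins are therefore
  quantiles of the exact FNEX sampling measure (computed once from a
  deterministic theta grid): a flat landscape now yields a flat histogram
  with *zero* bias, and the learned profile only ever represents the
  smooth landscape itself.
* **Bias only through lambda.** The bias is a function of lambda alone, so
  endpoint-conditional coordinate distributions are untouched; the tests
  check this with a Kolmogorov–Smirnov comparison against unbiased
  end-state sampling.

The ALF literature parameterizes biases with coefficient sets whose exact
functional forms live in supporting information we do not reproduce; the
`bias_model()` coefficient form (linear, quadratic and end-point-shaping
terms per pose) is this package's own documented convention, and all
flattening guarantees are stated against the model-free tabulated form.

Production runs use 5 replicas with derived seeds; the leading 1/6 of each
trace is discarded (the five-of-thirty-nanoseconds convention). Estimates
pool replicas; uncertainties are replica-level bootstrap standard
deviations (frames are autocorrelated; replicas are the independent unit).

## Estimators

* `endpoint_populations()` counts frames with `lambda > 0.99` (a pose
  "dominates"); `deltaG_from_populations()` applies the log-ratio formula
  and refuses zero populations rather than returning infinities.
* `wham_deltaG()` undoes the applied bias by weighting frames with
  `exp(+U_bias/kBT)` via log-sum-exp; with a zero bias it is *identical*
  to the population estimator; its uncertainty is a replica-level
  bootstrap floored by the binomial error over endpoint visits (the
  independent events of an autocorrelated trace).
* `zwanzig()` is the overflow-safe exponential average.
* `fep_mbar_path()` + `mbar_solve()` implement windowed multistate
  reweighting in log space with per-pair overlap diagnostics, so a
  vanishing-overlap failure between adjacent windows is flagged rather
  than silently converging to nonsense.
* `exact_deltaG_quadrature()` is the oracle: adaptive-order Gauss–Legendre
  quadrature on a box spanning each well ± 8 thermal widths, factorized
  over restraint-connectivity components, refusing anything beyond three
  degrees of freedom per component.

## What the toys emulate — and what they do not

The standard systems (`toy_spec_symmetric()`, `toy_spec_asymmetric()`,
`toy_spec_barrier()`) emulate: two mutually exclusive binding modes with
different environment couplings; distal anchors at restraint-selection
distances; thermal fluctuations (~1.1 Å) small against the ±4 Å
restraint band, as for heavy atoms in a real complex; and, in the barrier
toy, the overlap-repulsion mechanism (a pose forced onto its anchor) that
produces a multi-kBT alchemical barrier requiring flattening.

They do not emulate: explicit solvent, rotational/conformational ligand
entropy, multi-site alchemy, long-range electrostatics, or the
metastability of an unrestrained decoupled pose. The last point matters
for interpreting the one-step corrections: at toy equilibrium, removing a
*biting* restraint lets the decoupled pose genuinely wander, and the
restrained reference cannot see that region — the one-step estimate is
then systematically small, which is the same overlap pathology that makes
windowed approaches fail when the noninteracting pose wanders off. The
package therefore validates OSP in its convergent regime (restraints that
bite softly on a pose whose decoupled and coupled distributions coincide)
and relies on the default selection geometry — bands wide relative to
fluctuations — in the full pipeline, where the corrections are small and
exact. Passing tests certify the estimator algebra and its convergent
regimes, not OSP accuracy under hard overlap failure.

## Problem sizes

The shipped study conditions were chosen once as a realistic desk-scale
analog and are not tuned per run: production 5 × 240 ps at `dt = 0.002`
(12 000 lambda frames per replica), flattening up to 12 × 80 ps
iterations, reference state 3 × 180 ps, quadrature at 400/200/100 nodes
per dimension for 1/2/3-DOF components. A full pipeline closes the cycle
against the oracle in about a minute on one CPU.

## Known limitations

* Poses are distinct particle sets in mutually exclusive wells, not
  rotated copies of one molecule; geometric bookkeeping (alignment, RMSD)
  is deliberately out of scope.
* One alchemical site, exactly two poses.
* NVT only — a barostat is meaningless for non-periodic toys.
* The quadrature oracle's refusal above three DOF per coupled component is
  a hard boundary, not a fallback to approximation.
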