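# lambdapose

Rank two alternative binding poses of a ligand by relative binding free
energy, with dual-topology λ-dynamics — at desk scale, against exact
oracles.

## The problem

Docking frequently proposes both a crystallographic-like pose and a
"flipped" pose (scaffold core inverted) for the same ligand, and scoring
functions often rank them incorrectly. A physics-based discriminator is the
relative binding free energy ΔΔG between the poses. `lambdapose` implements
the alchemical machinery for this as an R package: both poses coexist in a
dual-topology hybrid Hamiltonian, a dynamical alchemical variable λ
switches which pose couples to its environment, and

```
ΔG(core) = −kB T ln ( P[λ_flip = 1] / P[λ_xray = 1] )
```

estimated from the endpoint populations of λ-dynamics trajectories. Because
restraints are required to keep the weakly coupled pose in place (either
inter-pose tethers or multiple protein–ligand flat-bottom distance
restraints selected from trajectory statistics), the final answer assembles
a three-leg thermodynamic cycle:

```
ΔΔG(xray→flip) = ΔG_add-restraints(xray)  +  ΔG(core, restrained)  +  ΔG_remove-restraints(flip)
```

with the two restraint corrections obtained by one-step perturbation from a
single reference ensemble sampled at λ = (0.5, 0.5), and the combined
uncertainty propagated in quadrature.

Everything runs on self-contained toy systems with at most three degrees of
freedom per pose, whose free energies are computed *exactly* by
deterministic Gauss–Legendre quadrature — so population counting, histogram
reweighting (WHAM-style), Zwanzig exponential averaging, and windowed
FEP/MBAR are all validated against a numerical oracle rather than against
each other.

## A worked example

```r
library(lambdapose)

spec <- toy_spec_asymmetric(seed = 1)   # two poses, different anchor couplings
sys  <- make_dual_pose_toy(spec)
sys
#> <particle_system> dim = 1 | 7 env anchors | 1 + 1 pose particles | T = 298.15 K

exact_deltaG_quadrature(sys)            # the exact answer, for comparison
#> <free_energy_estimate> -0.3957 +- 0.0000 kcal/mol  [quadrature-oracle]

fl <- flatten_alf(sys, NULL, simulation_config(seed = 101),
                  schedule = list(n_iterations = 10, steps_per_iteration = 15000))
traces <- run_replica_protocol(sys, fl$bias, NULL,
                               simulation_config(dt = 0.002, n_steps = 120000,
                                                 seed = 202), n_replicas = 5)
wham_deltaG(traces, fl$bias)
#> <free_energy_estimate> -0.3735 +- 0.0276 kcal/mol  [WHAM]

trace_diagnostics(traces)
#> # A tibble: 1 x 4
#>   transitions elapsed_ns transitions_per_ns physical_fraction
#> 1        1836      1.000              1836.             0.385
```

The reweighted estimate (−0.37 ± 0.03 kcal/mol) agrees with the exact pose
free-energy difference (−0.396 kcal/mol) within one combined standard
deviation: the flip pose of this toy binds more favorably. The diagnostics
say the alchemical variable alternated between the two physical end states
1836 times per ns and spent 38% of frames with one pose dominant (λ >
0.99) — a healthily sampled run. `autoplot()` methods draw λ traces, bias
profiles and cycle summaries; `tidy()`/`glance()` return the estimates as
tibbles.

The whole pipeline — equilibrium statistics, restraint selection, adaptive
flattening, 5-replica production, reference-state corrections, cycle
report — is also scripted behind one configuration:

```r
cfg <- default_workflow_config(outdir = "run1", seed = 7)
cmd_all(cfg)         # or: inst/cli/lambdapose all --outdir run1 --seed 7
```

which writes `system.json`, `restraints.txt`, `bias.json`, per-replica
λ-trace files and `cycle_report.json` under `run1/`.

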