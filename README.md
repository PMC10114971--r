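# boostmd

Gaussian-boosted Langevin dynamics on toy molecular systems, energetic
reweighting back to unbiased free-energy landscapes, and the conformational
ensemble analyses used to characterise state transitions in biomolecular
simulation: RMSF and flexibility differences, radius of gyration, solvent
accessible surface area, dynamic cross-correlation maps, Cartesian PCA,
2D free-energy landscapes with energy-valley detection, and geometric
interaction networks with per-contact occupancies.

## Who this is for

Enhanced-sampling simulations of the GaMD family add a smooth *boost
potential* below an energy threshold so that a system escapes local minima
orders of magnitude faster, then recover the unbiased thermodynamics by
reweighting.  Validating that machinery on real proteins is hard: the truth
is unknown and the trajectories are expensive.  `boostmd` implements the
complete method stack in testable form on toy systems whose free-energy
surfaces are known in closed form, so every stage — boost construction,
integration, reweighting, landscape analysis, contact classification — can
be checked against an exact answer.  It is aimed at method developers and
students of enhanced sampling, not at production protein simulation.

## The model

A system with potential \(V(\vec r)\) below a threshold \(E\) is simulated
on the modified surface

```
V*(r) = V(r) + dV(r),   dV(r) = 0                 if V >= E
                        dV(r) = k (E - V(r))^2/2  if V <  E
```

with the threshold and force constant set from running statistics of the
potential energy (`Vmax`, `Vmin`, `Vavg`, `sigma_V`) under the constraint
`Vmax <= E <= Vmin + 1/k` and `k = k0 / (Vmax - Vmin)`.  In lower-bound
mode `E = Vmax` and

```
k0 = min(1, (sigma_0 / sigma_V) * (Vmax - Vmin) / (Vmax - Vavg))
```

where `sigma_0` caps the boost fluctuation so that `dV` stays
near-Gaussian and the unbiased ensemble is recoverable.  Reweighting uses
per-bin estimators of `<exp(beta dV)>` — exact exponential averaging, a
Maclaurin expansion, or the second-order cumulant `exp(beta <dV> +
beta^2 var(dV)/2)` — and converts populations to free energies via
`G_i = -kB T ln(N_i / N_max)`.

Dynamics are integrated with BAOAB-discretised Langevin dynamics
(kcal/mol, Angstrom, amu, ps; `kB = 0.0019872041 kcal/mol/K`) in compiled
code; the staged protocol (unbiased statistics collection, boosted
equilibration with parameter refresh, production with frozen parameters)
mirrors standard practice.

## Worked example

A 1D double well with a 5 kcal/mol barrier (about 8.4 kT at 300 K) is
boosted, sampled, and reweighted back to the analytic profile:

```r
library(boostmd)

dw  <- toy_potential("double_well_1d", h = 5, b = 2)   # barrier 5 kcal/mol
cfg <- langevin_config(n_steps = 1, timestep = 0.002, seed = 42, stride = 5,
                       stages = list(cmd = 1e5, equil = 1e5, prod = 5e5))
run <- run_langevin(dw, cfg, boost = "lower_bound", sigma_0 = 6)
run$params
#> boost_params [lower_bound]: E = 6.3601 kcal/mol, k = 0.15723 (kcal/mol)^-1, k0 = 1.0000

cfg_u <- langevin_config(n_steps = 5e5, timestep = 0.002, seed = 42, stride = 5)
run_u <- run_langevin(dw, cfg_u)
c(boosted  = count_well_transitions(run$positions[, 1]),
  unbiased = count_well_transitions(run_u$positions[, 1]))
#>  boosted unbiased
#>       33        1

edges <- seq(-3, 3, length.out = 61)
bins  <- assign_bins(run$positions[, 1], edges, delta_v = run$records$dV)
pmf   <- reweight_pmf(bins, temperature = 300, method = "cumulant2")
g_ref <- sapply(pmf$centers[[1]], dw$analytic_pmf); g_ref <- g_ref - min(g_ref)
use   <- g_ref < 4 & pmf$counts > 0
round(mean(abs(pmf$G[use] - g_ref[use])), 3)
#> [1] 0.11
```

At matched step counts the boost turns 1 barrier crossing into 33, and the
cumulant-reweighted profile matches the analytic one to 0.11 kcal/mol
(mean absolute error over bins below 4 kcal/mol).

The same machinery scales up to the two-state "switch" bead chain
(`make_switch_chain()`), whose inter-bead reaction coordinate jumps
between compact (11.1 A) and incompact (26.9 A) states:
`run_pipeline(run_config(...))` simulates replicas, pools them, and writes
the landscape, valley table, RMSF, Rg, cross-correlation, PCA and contact
occupancy tables with a checksum manifest; `compare_conditions()` then
contrasts a wild-type run against a biased-well "mutant" run
(delta-RMSF, valley populations, occupancy join, contact diffs).

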