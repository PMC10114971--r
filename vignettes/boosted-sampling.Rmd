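---
title: "Boosted sampling, reweighting and ensemble analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted sampling, reweighting and ensemble analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boostmd)
```

This vignette is the package's own account of the science it implements:
the boost potential and its parameterisation, the Langevin integrator, the
reweighting estimators, the landscape and interaction analyses, what the
synthetic generators do and do not emulate, and the numerical choices made
where the design was genuinely open.

## The boost potential

A system with potential $V$ is simulated on $V^* = V + \Delta V$ with

$$\Delta V = \begin{cases} 0 & V \ge E \\ \tfrac12 k (E - V)^2 & V < E,\end{cases}$$

which fills basins below the threshold $E$ while leaving the surface
untouched above it.  $V^*$ is continuous with continuous forces at $V = E$
(the force on the boosted surface is $(1 - k(E - V))$ times the unbiased
force below threshold), and the constraint $E \le V_{min} + 1/k$ keeps the
force scale non-negative, so the landscape is flattened but never
inverted.

The threshold and force constant are set from running statistics of the
potential energy.  With $k = k_0/(V_{max}-V_{min})$, lower-bound mode uses
$E = V_{max}$ and

$$k_0 = \min\!\left(1,\ \frac{\sigma_0}{\sigma_V}\cdot
\frac{V_{max}-V_{min}}{V_{max}-V_{avg}}\right),$$

and upper-bound mode uses $E = V_{min} + 1/k$ with
$k_0 = (1 - \sigma_0/\sigma_V)\,(V_{max}-V_{min})/(V_{avg}-V_{min})$,
clamped to $(0, 1]$ and infeasible when $\sigma_0 \ge \sigma_V$.  The user
limit $\sigma_0$ (kcal/mol) caps the boost fluctuation; it is the single
most important tuning knob because reweighting accuracy degrades rapidly
once the per-bin boost distribution stops being near-Gaussian.  The
default $\sigma_0 = 6$ kcal/mol is appropriate for the 1-dof toys; for the
30-dof bead chain, whose potential-energy fluctuations are larger, a
gentler $\sigma_0 = 2$ is used in the examples.  `anharmonicity()`
quantifies the Gaussianity of a boost sample as the entropy gap
$\gamma = S_{gauss}(\hat\sigma) - \hat S$ between a Gaussian of the
sample's standard deviation and a histogram estimate of the sample's
differential entropy; `reweight_pmf()` warns when $\gamma > 0.1$ and the
cumulant estimator is requested.

## Integration and staging

Dynamics are BAOAB-discretised Langevin (compiled via Rcpp): velocity
half-kick, half-drift, Ornstein–Uhlenbeck velocity refresh, half-drift,
half-kick.  BAOAB was chosen for its configurational accuracy at large
timesteps; only the thermostat (friction, default 2 ps$^{-1}$, 300 K) is a
physical input.  Units are kcal/mol, Å, amu and ps, with
$k_B = 0.0019872041$ kcal mol$^{-1}$K$^{-1}$ and 1 kcal/mol =
418.4 amu Å$^2$ ps$^{-2}$.

Boosted runs use a three-stage protocol: (i) an unbiased
statistics-collection stage, (ii) a boosted equilibration stage whose
threshold and force constant are refreshed every 500 steps from the
running statistics, and (iii) production with frozen parameters, during
which $\Delta V$ is logged per stored frame.  Stage lengths default to
20/20/60 % of the step budget and can be given explicitly.  A burn-in
prefix (default 2000 steps, capped at half the collection stage) is
excluded from the statistics: without it a high-energy initial structure
(e.g. the fully extended chain pressed against its confinement wall)
inflates $V_{max}$, which drags the threshold far above the equilibrium
range and makes the boost both too strong and poorly reweightable.
Statistics update every integration step; update cadence during
equilibration (500 steps) is a convention, not a sensitive parameter.

## Reweighting

`assign_bins()` histograms a 1D or 2D reaction coordinate over half-open
bins (last bin closed) with a one-pass Welford accumulation of per-bin
boost mean and variance; out-of-range frames go to an overflow register
and are excluded with a warning.  `reweight_pmf()` multiplies bin
populations by a weight $W$:

* `none` — $W = 1$: the biased populations themselves;
* `exponential` — $W = \langle e^{\beta \Delta V}\rangle$ over retained
  samples: unbiased but exponentially noisy;
* `maclaurin` — $\sum_{j\le K} \beta^j \langle \Delta V^j\rangle / j!$
  (order 2 from accumulated moments; higher orders need retained samples);
* `cumulant2` (default) — $\ln W = \beta\langle\Delta V\rangle +
  \beta^2 \sigma^2_{\Delta V}/2$: exact for Gaussian $\Delta V$ and the
  standard practical choice.

All weights are handled in log space to avoid overflow.  Probabilities
are renormalised over populated bins and converted to
$G_i = -k_BT \ln(p_i/p_{max})$, so the modal bin sits at exactly zero.
Unpopulated bins are then assigned the energy of the least probable
populated bin and flagged `artificial` (`fill_empty_bins()`): this keeps
holes from reading as deep minima while making the imputation auditable.
The alternative of imputing a pseudo-count of one frame was rejected
because its height would depend on the total frame count.

## Landscapes, valleys, barriers

`build_fel()` composes reaction-coordinate extraction (named distances,
heavy-atom RMSD against a reference), binning, reweighting and the
empty-bin fill; grids default to 100 bins (1D) or 60×60 (2D) over the
observed range padded by 5 %, and the bead-chain examples use 24 bins per
axis, roughly 1 Å resolution on the distance axis, which is matched to
the frame counts used at desk scale (10^4–10^5 frames).

`find_valleys()` makes the visual notion of an "energy valley" explicit
and reproducible: local minima over 8-connected neighbourhoods among
populated, non-artificial bins; minima closer than `min_separation`
(default 2 bins, Chebyshev) merge into the deeper one; members are grown
over connected bins within `depth_cutoff` (default 1 kcal/mol) of the
valley floor, deeper valleys claiming first; and a bin must hold at least
`min_count` frames (default 5; 10 in the pipeline) to *seed* a valley —
a noise floor that stops single-frame bins, whose reweighted energies
carry the largest estimator variance, from nucleating spurious minima.
Valleys are labelled EV1, EV2, … by increasing floor energy.
`representative_frame()` returns the frame in the valley's minimum bin
nearest the bin centre, ties broken toward the lowest frame index.
`barrier_height()` reports the watershed (minimax-path) saddle between
two valley floors, computed by union-find over bins sorted by energy;
a minimax barrier was chosen because basin-to-basin comparisons should
not depend on an arbitrary transect.  Paths may not cross artificial
bins; disconnected valleys report `Inf`.

## Ensemble metrics and collective dynamics

Superposition is Kabsch via SVD with the reflection excluded; RMSF uses
an iterated mean reference (two iterations), not the first frame, and
the fit selection is separate from the measurement selection — fitting on
a stable core is the right way to measure a localised fluctuation, and
the rigid-body generator provides the null test (RMSF $< 10^{-8}$ Å).
Radius of gyration is mass-weighted by default.  Surface area is
Shrake–Rupley with Bondi radii, probe 1.4 Å and 960 deterministic
golden-spiral points; points exactly on a neighbour's sphere are assigned
to the lower-index atom so coincident spheres count once.  It stands in
for pairwise-overlap approximations at the level of the quantity itself,
not the algorithm.

The cross-correlation map uses full 3-vector displacement dot products,
$C_{ij} = \langle \Delta r_i\cdot\Delta r_j\rangle /
(\langle\Delta r_i^2\rangle\langle\Delta r_j^2\rangle)^{1/2}$, after
superposition onto the iterated mean; zero-variance atoms get `NA`
rows with a warning.  PCA eigendecomposes the $3n\times 3n$ coordinate
covariance with population (1/N) normalisation — the scalar choice does
not affect variance fractions — and fixes each eigenvector's sign by
making its largest-magnitude component positive so output is
reproducible.  Both analyses accept `fit = FALSE` for ensembles already
in a common frame: the prescribed-covariance oracle is analysed this way
because superposition would project out the very variance being
prescribed (for small atom counts, the 6 rigid-body degrees of freedom
are a large fraction of $3n$).

## Interaction networks

Hydrogen bonds: donor–acceptor distance $< 3.5$ Å and the angle at the
hydrogen between the H→donor and H→acceptor directions $> 120°$, both
strict, with donors/acceptors from built-in templates covering the 20
amino acids, GTP and water.  A distance-only fallback (off by default,
flagged `no_angle`) supports hydrogen-free coarse topologies.  Salt
bridges pair charged-group centroids (Lys/Arg/protonated His cations;
Asp/Glu carboxylates and the three GTP phosphate groups as anions) within
5.5 Å; π-stacking takes ring-centroid distance ≤ 5.5 Å with normals
≤ 30° (parallel) or 60–90° (T-shaped), skipping rings with RMS
out-of-plane deviation > 0.3 Å; metal coordination takes any O/N within
2.6 Å of the metal.  These cutoffs follow published geometric-profiler
conventions and are all overridable.  `occupancy()` reports
100 × (frames present)/(total frames) per interaction key; keys absent in
every frame are omitted rather than zero-filled, because without a
candidate universe a zero row is not well defined.

## The synthetic generators: what they emulate, and what they do not

* `toy_potential("double_well_1d")` (default $U = h((x^2-b^2)/b^2)^2$,
  $h = 5$ kcal/mol, $b = 2$ Å) has an 8.4 kT barrier at 300 K — high
  enough that unbiased Langevin rarely crosses within $10^5$ steps, so
  boosting demonstrably enhances sampling, and low enough that a boosted
  run converges at desk scale.
* `make_switch_chain()` builds a 10-bead chain (harmonic bonds
  100 kcal/mol/Å², equilibrium 3.8 Å; harmonic angles 0.5 kcal/mol/rad²
  about the extended geometry) with a two-state pair potential on the
  end beads: Gaussian wells at 11.1 and 26.9 Å (width 1.2 Å), a Gaussian
  barrier bump (1.5 kcal/mol) at the midpoint, and soft confining walls
  2.5 widths outside the wells.  A pure sum of Gaussians was used instead
  of wells on a quadratic backbone because a backbone slope would shift
  the stationary points off the stated well distances; with
  well-separated Gaussians the minima sit on them to numerical precision.
  Well depths default to (2, 2.8) kcal/mol: the incompact well is deeper
  by roughly $k_BT\ln 4$ to offset the chain's conformational-entropy
  preference for compact separations, so the two *states* (not the two
  pair-potential wells) are comparably populated at 300 K.
  `mutation_bias` adds energy to the compact well (negative = deeper) and
  is the package's stand-in for a point mutation that redistributes state
  populations.
* `sample_correlated_ensemble()` draws i.i.d. Gaussian frames with a
  prescribed $3n\times 3n$ covariance (eigendecomposition square root;
  eigenvalues below $-10^{-8}\,\lambda_{max}$ are an error, smaller
  negatives clamp to zero) — the exact oracle for DCCM/PCA.
* `make_hbond_fixture()` constructs a donor–H–acceptor triad whose
  qualifying-frame count is exact by construction (2.9 Å/180° vs 4.5 Å),
  shuffled by seed, with a manifest attribute for assertions.
* `make_rigid_body_trajectory()` applies uniform random rotations
  (quaternion draws) and translations to a base structure — the null
  model for every superposition-based fluctuation measure.

None of these emulate real force fields, solvent, or protein sequence;
passing tests demonstrate the correctness of the *machinery* (boost
algebra, integrator statistics, estimator consistency, geometric
classification), not fidelity to any particular protein's behaviour.
Two features of real data deliberately absent: multi-basin ruggedness on
top of the two states, and anisotropic, sequence-dependent flexibility.

Reproducibility is per-seed: generators and runs take explicit seeds and
are bitwise reproducible.  Seeding goes through R's global RNG (the R
idiom) rather than a passed generator object; the compiled integrator
draws from the same stream, so a single `seed` fixes an entire run.  One
practical consequence, found the hard way: two Langevin runs that share
a seed also share their noise sequence, and common noise synchronises
trajectories on similar force fields, hiding small energetic differences.
Condition comparisons (wild type vs biased mutant) therefore use disjoint
seed blocks per condition, four pooled replicas per condition — pooling
independent replicas before analysis, as combined-trajectory
post-processing does — and discard the first quarter of each replica as
equilibration.  With 6×10^5 steps per replica this resolves a 1 kcal/mol
well-depth change as a population shift with the correct sign across
seeds.

## Problem sizes and runtime

The shipped tests and the acceptance script run at desk scale by design:
$5\times10^5$ production steps for 1-dof profiles, $6\times10^5$-step
replicas for the 30-dof chain, $10^5$-frame oracle ensembles, 24–60-bin
grids.  The full test suite completes in a few minutes on one CPU; the
acceptance script in under two.

## Known limitations

* Total-potential boost only; dual (dihedral + total) boosting is
  meaningless for these toys and out of scope.
* Single-ensemble reweighting; no WHAM/MBAR multi-ensemble combination.
* The exponential estimator needs retained per-bin samples and is noisy;
  it is provided as the unbiased reference, not the default.
* Valley detection depends on bin resolution: grids much finer than the
  data support fragment basins (the `min_count` floor mitigates but does
  not remove this).
* PDB support covers fixed-width v3.3 ATOM/HETATM multi-model files
  (parsing is delegated to `bio3d` behind validating wrappers); no mmCIF
  and no binary trajectory formats.
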