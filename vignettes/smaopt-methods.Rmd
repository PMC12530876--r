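---
title: "Surrogate-assisted Lennard-Jones parameter optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted Lennard-Jones parameter optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smaopt)
```

This vignette is the package's account of the science it implements: the
models, the choices behind every tunable default, what the synthetic data
generator does and does not emulate, and the numerical decisions a
maintainer would otherwise have to reverse-engineer.

## The multiscale calibration problem

A classical force field's nonbonded term is the 12-6 pair potential
$V(r) = 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$, with per-element
parameters: here $\sigma_C, \sigma_H$ (nm) and
$\varepsilon_C, \varepsilon_H$ (kJ/mol) for an all-atom alkane.
$\sigma$ sets equilibrium distances and therefore the condensed-phase
density; $\varepsilon$ sets well depths and how easily thermal energy
perturbs the packing.  Calibration targets live on two scales:

* **macroscale** — the bulk-phase density of *n*-octane, 700 kg/m³ at
  293.15 K / 1 bar, normally estimated by an expensive MD simulation;
* **nanoscale** — 96 relative conformational energies (RCE) of an octane
  conformer ensemble, cheap molecular-mechanics evaluations.

The workflow's premise is that the expensive density evaluation can be
replaced inside the optimization loop by a regression surrogate trained on
a one-off library of (parameter set → density) records, while the RCE term
is always computed directly.

## Feasible space and sampling designs

The feasible box (`feasible_space()`) is $\sigma_C \in [0.05, 0.35]$,
$\sigma_H \in [0.045, 0.35]$ nm, $\varepsilon_C \in [0.15, 1.15]$,
$\varepsilon_H \in [0.01, 0.15]$ kJ/mol — wide enough to contain every
physically plausible alkane parameterization, narrow enough that
pseudo-simulations remain stable.

Two design families are implemented:

* `make_grid()` — inclusive arithmetic sequences per dimension, full
  Cartesian product, lexicographic ordering.  Endpoint inclusion uses a
  relative tolerance of 1e-9 so printed min/step/max triplets whose span
  is a floating-point multiple of the step reproduce their printed maxima
  (0.0750 + 5×0.0500 = 0.3250 exactly).
* `make_sobol()` — the first $2^m$ points of a base-2 Sobol sequence,
  scaled affinely into the box.  No installed R package provides a Sobol
  generator, so the package carries a small implementation using the
  standard Joe–Kuo primitive-polynomial/direction-number table (supports
  up to 8 dimensions; 30-bit precision; Gray-code order; first point at
  the origin).  The unscrambled sequence is the default so point sets are
  bit-for-bit reproducible across platforms; the optional `scramble_seed`
  applies a per-dimension digital (XOR) shift, which decorrelates repeated
  designs while provably preserving the net's one-dimensional
  stratification (each projection of $2^m$ points hits each of the $2^m$
  equal bins exactly once — a property the tests check exhaustively).
  Full Owen scrambling is deliberately out of scope: no contract in the
  package needs scrambled-sequence variance estimates.

Two grid sets and two Sobol sets with slightly different boxes make up the
canonical acquisition campaign; paired designs protect against a
coincidentally lucky or unlucky single sample set.  Whether the second
Sobol set differs by bounds, by scrambling, or both is a config choice
(`scramble_seed` per dataset); the shipped presets use different bounds
*and* a scrambled second sequence.

## The synthetic density oracle

Real MD is out of scope; the oracle is a documented closed form treated as
ground truth everywhere in the package:

$$v(p) = 8\sigma_C^3 + 18\sigma_H^3 \qquad \text{(molecular-volume proxy, nm}^3)$$
$$\mathrm{smooth}(p) = b + \frac{A}{1 + \exp\!\big(s\,(v - v_0)/v_0\big)}$$
$$\mathrm{rugged}(p) = a_r\,\frac{\varepsilon_C}{1.15}\,
  \sin\!\frac{2\pi\sigma_H}{\lambda_\sigma}\,
  \sin\!\frac{2\pi\varepsilon_C}{\lambda_\varepsilon}$$
$$\rho(p) = \mathrm{clamp}\big(\mathrm{smooth} + \mathrm{rugged} +
  \mathcal{N}(0, \sigma_n^2),\; 0,\; 2000\big)$$

Defaults: $b = 100$, $A = 1200$ (densities span roughly 100–1300 kg/m³,
so relative errors never blow up on near-zero denominators),
$v_0 = 0.6025$ (the smooth 700 kg/m³ level set then passes through
literature-like octane parameters, $\sigma_C \approx 0.329$,
$\sigma_H \approx 0.261$ nm), $s = 6$, $a_r = 60$,
$\lambda_\sigma = 0.037$ nm, $\lambda_\varepsilon = 0.25$ kJ/mol,
$\sigma_n = 5$ kg/m³, failure probability 0.05.  The design emulates the
two qualitative features of the simulated landscape: a smooth low-to-high
transition in the $(\sigma_C, \sigma_H)$ plane, and alternating
above/below-target bands in $(\sigma_H, \varepsilon_C)$ whose amplitude
grows with $\varepsilon_C$.  With the configured failure probability a
record is marked invalid and carries an implausible density (0 or
1.25 × cap), emulating crashed or unconverged runs; `preprocess_dataset()`
removes invalid records and anything outside the plausibility window
(0, 1500] kg/m³.

What the oracle does **not** emulate: thermostat/barostat artifacts,
correlated (non-Gaussian) sampling noise, equilibration drift, and any
coupling of failure probability to parameter extremity.  Passing tests
therefore demonstrate that the workflow machinery is correct and that the
method behaves as published on a landscape with the published features —
not that any particular MAPE will be attained on real MD data.

Per-point RNG streams derive from (master seed, point index), so datasets
are independent of evaluation order.

## Molecular-mechanics RCE engine and conformer fixture

`rce()` evaluates per-conformer energies as a fixed bonded-energy offset
plus a weighted sum of 12-6 pair energies over nonbonded intramolecular
pairs (pairs 1 or 2 bonds apart excluded; 1-4 pairs at weight
`scale_14`, default 1; Lorentz–Berthelot combining by default, geometric
available — the underlying GROMACS convention is not restated in the
source material, so both are supported).  Conformer geometries are fixed,
so pair distances are precomputed once; an objective evaluation is then a
closed-form function of the four parameters.

`make_conformer_fixture()` builds octane-like C₈H₁₈ chains: fixed bond
lengths (C–C 0.153, C–H 0.109 nm), tetrahedral angles, and seeded backbone
dihedrals drawn from trans/gauche± rotamer states with a ±8° twist.
Adjacent opposite-gauche (syn-pentane) states are rejected as steric
clashes, which caps the distinct rotamer states at 99; the default 97
conformers (96 non-reference RCE, matching the published target
cardinality) therefore all carry distinct backbone states.  Target RCE are
computed from a designated "true" parameter set — the previously published
octane optimum (0.3286, 0.2606, 0.6730, 0.1194) — so parameter recovery is
well-posed by construction.  Bonded offsets are 3.3 kJ/mol per gauche
state plus seeded jitter; offsets are then nudged so that every target has
magnitude at least 0.5 kJ/mol, because relative-deviation metrics are
ill-conditioned at near-zero targets (a single ±0.1 kJ/mol target would
otherwise dominate the whole objective).

## Surrogate families

One contract (`model_spec()` → `train_surrogate()` → `predict()`), five
families.  Inputs are standardized per dimension (training-split mean/sd)
for the polynomial, Gaussian-process and network families; forests and
plain linear fits consume raw values.  Training is deterministic given
`(spec, data)`; `train_seed` drives every stochastic ingredient.

* **linear / polynomial** — least squares; the polynomial basis is the
  full multivariate monomial set of total degree ≤ d (interaction terms
  included).  Training errors out when there are fewer points than basis
  functions.
* **random forest** — `randomForest` with the tree count as the
  benchmark's hyperparameter, remaining settings at the package defaults
  (bootstrap on, unrestricted depth).
* **Gaussian process** — written in-house (no installed package offers
  Matérn/rational-quadratic kernels with marginal-likelihood fitting).
  Kernels: RBF, Matérn 5/2, RQ; per-dimension ARD lengthscales; a linear
  mean function (universal-kriging trend) is subtracted before kernel
  fitting; hyperparameters (lengthscales, signal variance, RQ mixture
  parameter, observation-noise variance) maximize the log marginal
  likelihood with L-BFGS-B from 5 seeded restarts.  The noise variance is
  *estimated* by default: the pseudo-simulated densities carry 5 kg/m³
  noise, and an interpolating fit (tiny fixed jitter) reproduces that
  noise as spurious between-sample wiggles — observed as systematic
  4–7% verification errors in the optimization loop.  The interpolating
  behavior remains available (`gp_noise = 0`, stabilized by a 1e-6
  relative jitter, which bounds interpolation accuracy near 1e-4
  relative).  ARD matters here: the density responds strongly to the
  $\sigma$'s and barely to the $\varepsilon$'s, and an isotropic
  lengthscale fit showed several-percent bias exactly where the optimizer
  operates.
* **feed-forward network** — `nnet`: one hidden layer (default 16 units,
  logistic activations, linear output), BFGS training with weight decay
  1e-4.  The published architecture lives in unavailable supplementary
  material; this default is the package's own and is exposed as
  hyperparameters (`hidden`, `decay`, `maxit`).

Metrics: MAPE as a fraction, $R^2 = 1 - SS_{res}/SS_{tot}$, both guarded
against undefined inputs (zero reference values; constant references).

## Benchmark harness

`split_dataset()` partitions by seed (training share = round(ratio·n));
`run_ist_ost()` trains on the training part and scores twice — IST on the
held-out part, OST on the concatenation of all records of every *other*
dataset.  `experiment_plan()`/`plan_counts()` reproduce the full-scale
bookkeeping (19 ratios × 50 seeds × 4 datasets × per-family grids =
3 800 / 38 000 / 22 800 / 11 400 / 3 800 planned trainings).
`aggregate_metrics()` reports mean and n−1 sample sd (the published ±
convention is unstated; sample sd is the conventional reading).
`compare_means()` is a two-sided Welch t-test (the published p-values name
no test; no multiple-testing correction is applied, as none was there),
with p = 1 by convention for identical constant groups.  `select_top()`
unites the k lowest-MAPE and k highest-R² models; rows with identical
(MAPE, R²) pairs are treated as one model — that is how the published
24-row selection table marks its 7 duplicates, yielding the 17-model
union — and ties break by the secondary metric, then id.

## The optimization loop

`optimize_lj()` is box-constrained gradient descent in unit-box
coordinates (each parameter mapped to [0, 1], so the four differently
scaled parameters receive comparable steps):

* **objective** — $w_d (\mathrm{err}_{dens}/100)^2 + w_r\,
  \overline{((\mathrm{RCE}_i - t_i)/t_i)^2}$, defaults $w_d = w_r = 1$.
  The RCE term is a *smooth* least-squares mean of squared relative
  deviations; an earlier mean-absolute form produced a kinked surface on
  which plain descent reliably stalled.  The *reported* err_RCE stays the
  conventional mean absolute percentage.
* **gradient** — central differences, $h = 0.01$ per unit-box coordinate,
  one-sided at bounds (every stencil point stays feasible); components
  pushing into an active bound are projected out so iterates slide along
  box faces instead of being eaten by the clamp.
* **step length** — backtracking from $\alpha_0 = 0.1$ (up to 10
  halvings), with two accelerations that cost only surrogate evaluations:
  a Barzilai–Borwein initial step from the previous iterate, and greedy
  doubling (up to 3×) while a larger step keeps improving.  If no
  decreasing step exists the stencil is refined (h/4, twice) before the
  run is declared dead-ended — an apparent dead end at one stencil scale
  is often an artifact of surface curvature.
* **termination** — relative loss improvement below 1e-6 on 3 consecutive
  iterations, a dead-ended line search, or 1000 iterations.  These are
  deliberately generous: with a surrogate an objective evaluation costs
  milliseconds (that is the point of the workflow), and the combined
  objective descends a narrow curved valley — the density term constrains
  a 3-D level-set manifold and the RCE term is nearly degenerate along an
  $\varepsilon_C$–$\varepsilon_H$ tradeoff, exactly the wide-range
  behavior the published study reports for the $\varepsilon$'s.
* **multi-start** — `perturbed_starts()` perturbs a user-supplied initial
  force field (±15% of the box width per coordinate, reflected at the
  bounds so starts never sit exactly on a face).  Parameter refinement in
  practice begins from an existing plausible parameter set; much of the
  feasible box lies on the density sigmoid's plateaus where no useful
  gradient signal exists.  The presets use (0.34, 0.25, 0.45, 0.09), a
  literature-like all-atom alkane guess.

`verify_params()` re-evaluates optimized parameters against the oracle
with n replicate draws (failures disabled — a failed replicate would be
re-run in practice), reporting $\rho_{sim}$ mean ± sd, err_dens from the
mean, and err_RCE recomputed directly.

## Pipeline, presets and problem sizes

`run_pipeline()` chains sample → evaluate → preprocess → train/select →
optimize → verify, writing plain-text artifacts plus a manifest (stage,
outputs, md5, seed, wall time).  Stage seeds derive deterministically from
the global seed; unchanged configs reproduce CSVs byte-for-byte.

Two presets ship: `paper` (the full-scale plan: Table-sized sample sets,
19 ratios, 50 seeds, all five family grids — provided for bookkeeping and
full-scale reruns) and `desk`, the working default used throughout
development: four 256-point sample sets (two 4-level grids over the
published grid boxes, two Sobol sets), 5 ratios × 10 seeds, forest and
network families (cheap to fit 400 times and differentiable where it
matters — the selected surrogate feeds a gradient-based optimizer, which
is also why the forest, piecewise-constant in prediction, is never
selected for the optimization stage in practice), 25-conformer fixture,
3 optimization starts.  The desk pipeline completes in a few minutes on
one CPU.

The package's own heavier protocols use these sizes: the generalization
benchmark (Sobol- vs grid-trained degradation) runs the polynomial family
(degrees 3–4) over 4 × 256-point datasets, 5 ratios × 10 seeds; the
recovery protocol trains a GP-RQ surrogate on 256 Sobol points of a
mild-ruggedness oracle ($a_r = 20$, noise 5 kg/m³) and optimizes from 5
perturbed starts.

## Design choices where the ground was genuinely open

* **Generalization ordering at reduced scale.**  The published finding —
  Sobol-trained models degrade less from IST to OST than grid-trained —
  is asserted on the polynomial family.  At 256-point scale the linear
  and forest families' IST→OST contrast is dominated by a different
  mechanism (training-box extrapolation: full-box grids actually show
  *negative* degradation because their in-sample test is already hard),
  whereas the polynomial family cleanly isolates what the finding is
  about: a coarse lattice sees the rugged term only at fixed phases, so
  its in-sample score is flattered and its out-of-sample score collapses.
* **Welch test, sample sd, no correction** — the published analysis names
  none of the three; conventional readings adopted.
* **Objective weights** $w_d = w_r = 1$ — the true production objective
  lives in unavailable references; equal weighting of the two squared
  relative-error terms is the neutral stand-in and is isolated behind
  `lj_objective()`.
* **Recovery protocol surrogate** — the protocol admits a GP-RQ or a
  network surrogate; the ARD GP is used because on 256-point training
  libraries it is the more accurate of the two near the target level set.

## Known limitations

* The oracle's Gaussian, homoscedastic noise and parameter-independent
  failure rate are idealizations; real MD noise is correlated and
  failures cluster at extreme parameters.
* The optimizer is local by design.  Starts on the density plateaus (no
  gradient signal) or near the sparsely-sampled box faces (largest
  surrogate error) can dead-end; the multi-start + verification protocol
  is the intended mitigation, mirroring the published practice of running
  several optimizations and trusting the verified ones.
* Surrogate accuracy, not the optimizer, bounds the achievable
  verification error: with 256 training points the GP's corridor error is
  ~6 kg/m³ (≈0.9%), so individual runs occasionally verify outside ±2%
  even though the surrogate-internal loss is tiny.
* The Sobol generator covers d ≤ 8; higher-dimensional parameter spaces
  would need an extended direction-number table.
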