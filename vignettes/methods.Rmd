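---
title: "Methods: quantifying and modelling cranial asymmetry"
author: "cetasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and modelling cranial asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, the defaults, and the design decisions
behind `cetasym`, in the spirit of a methods supplement: what is computed,
under which assumptions, which knobs matter, and what a passing test does
and does not establish.

## 1. Asymmetry quantification

### Mirrored reference and superimposition

A specimen is an ordered set of 123 3D landmarks (57 bilateral pairs + 9
midline points; any scheme with the same structure is accepted).  The
symmetric reference *Rn* of a focal configuration *Fn* copies the left and
midline landmarks and replaces each right landmark with the reflection of
its left partner through the specimen's midsagittal plane.  The plane is
the total-least-squares plane through a set of anchors.

**Anchor choice (open design point).**  Two constructions are available
through `use_pair_midpoints`:

* midline landmarks only (the default whenever at least 3 non-collinear
  midline landmarks are observed), and
* midline landmarks plus midpoints of fully observed bilateral pairs
  (the fallback, and available as an explicit option).

Midpoints of *asymmetric* pairs are displaced by half the asymmetry
vector, so including them drags the fitted plane towards the very signal
being measured; with a planted single-landmark displacement the recovered
ρ is then biased by a few percent, while the midline-only plane recovers
it to about 0.02%.  Midline anchors are only reliable when they span the
plane well (the synthetic template therefore arcs its midline profile over
the cranial vertex, as real skull midlines do); when they are few or
near-collinear the midpoint fallback is used automatically.

GPA removes translation (centring), size (each configuration scaled to
unit centroid size) and orientation.  Rotations are constrained to
det = +1: an improper (reflecting) rotation would superimpose a skull onto
its mirror image and erase exactly the signal of interest; a regression
test compares against an unconstrained orthogonal-Procrustes oracle to
guarantee the constraint is active.  The consensus is the running mean
shape, initialised from the first configuration; iteration stops when the
consensus changes by less than 1e-10 (Frobenius norm) or after 100 sweeps.
Only focal configurations enter the consensus; each mirror is carried into
its focal specimen's frame by applying the focal translation/scale/
rotation verbatim, so ρ is measured with *Fn* and *Rn* in one frame.
Because ρ compares a specimen with its own mirror in a shared frame, it is
invariant to the rotation itself; the Procrustes step standardises units
(ρ is reported in dimensionless Procrustes units, displacement ÷ centroid
size).

### Missing landmarks

A landmark with any coordinate equal to the −9999 sentinel is treated as
wholly missing (partial sentinels warn).  Missing landmarks are estimated
by an interpolating 3D thin-plate spline, kernel `U(r) = r`, built on the
shared observed landmarks from a reference onto the incomplete specimen;
the reference is the Procrustes mean shape of all complete specimens,
rescaled to their median centroid size (recorded in the completion log).
TPS control points are centred and scaled before solving the bordered
system (with one step of iterative refinement), and pairwise distances are
computed from explicit coordinate differences: both choices are purely
numerical, and bring control-point interpolation error below 1e-8 even for
strongly nonlinear warps.  TPS reproduces affine maps exactly (zero
bending energy), which is the basis of the main correctness test.
Estimated landmarks are flagged and included in Σρ_spec by default
(`include_estimated = FALSE` gives the sensitivity variant); whether the
original study included them is not recorded, so both modes exist.

### Statistics

ρ is the per-landmark Euclidean distance between aligned *Fn* and *Rn*;
ϕ and θ are measured in the frame of the principal axes of the consensus
mean shape (the first two axes define the equatorial plane).  Only ρ feeds
the downstream statistics.  Σρ_spec sums ρ over all landmarks of a
specimen; x̄ρ is the group mean of Σρ_spec; x̄ρ_land the group mean of ρ at
one landmark; regional percentages divide the within-region ρ sum by
Σρ_spec.  Rankings break ties lexicographically by specimen id.  PCA is an
SVD of the centred, flattened aligned coordinates; Σρ_spec is point
metadata, not a PCA column.

## 2. Phylogenetic machinery

Trees are rooted with branch lengths in My; polytomies are resolved
deterministically with zero-length branches (patristic distances are
unchanged; an optional random mode exists).  Zero-length branches can make
the phylogenetic covariance singular, so every likelihood passes through a
Cholesky with a documented fallback ridge of 1e-8 × mean depth (logged via
a warning).  Regime paintings assign one state per branch from clade rules
(stem branch included by default; nested clades override; identical MRCAs
with different states are an error) or from tip states (maximal
single-state clades).  The painted covariance splits each entry by the
state of the contributing branch segments; components sum exactly to the
unpainted matrix.

### Mk models

ER/SYM/ARD rate matrices with uniform root prior by default (a
stationary-distribution option exists; the original analysis used ER
throughout, which the AIC study reproduces on simulated data).
Likelihoods use Felsenstein pruning with per-branch matrix exponentials;
when the eigendecomposition of Q is real and well-conditioned a compiled
kernel is used, otherwise an R path with a scaling-and-squaring fallback.
ML fits optimise log-rates in [1e-8, 1e3] per My by L-BFGS-B from 5 starts
spread around 1/tree-depth.

### BM/OU model family

All models are Gaussian on the tips.  Mean structures: root state (BM,
BMM), root + trend × tip depth (BMtr/BMMtr; on an ultrametric tree the
trend is unidentifiable and is fixed at 0 with a warning), one mean per
terminal state (BMsm/BMMsm), and OU weights (root weight `exp(-α d)` plus
per-state Butler–King occupancy weights integrated along each root-to-tip
lineage).  Covariances: σ²C, Σ_k σ²_k C_k, or the fixed-root OU covariance
`exp(-α(d_i+d_j-2t_ij))(1-exp(-2α t_ij))/(2α)`.

Mean coefficients and the overall σ² are profiled analytically by GLS;
α and the relative regime rates are optimised on the log scale (L-BFGS-B,
5 log-spaced starts, bounds 1e-9 to 1e6).  Two identifiability conventions
are built in rather than left to numerical pivoting:

* **OU/OUM on ultrametric trees**: the root state is not identifiable
  (its weight is constant across tips).  OU keeps only the stationary
  mean; OUM folds the root weight into the root state's optimum (the
  conventional "root at its regime's optimum").  On non-ultrametric trees
  (fossil tips) the root state is a free parameter.
* **Parameter counts**: k = 1 (σ²) + number of estimated mean
  coefficients + number of extra regime rates + 1 if α is free.  Aliased
  (dropped) mean columns are not counted.  AIC (not AICc) is used; a
  single α is shared across regimes in OUM, and per-regime optima are
  free — the plausible reading of the original model family where exact
  counts are not printed.

Ranking is ascending AIC with ΔAIC and a deterministic tie-break by model
name.

### Relaxed BM by reversible-jump MCMC

The state holds a set of branch shifts (each rescaling its branch and all
descendants until overridden deeper), per-branch jump counts (each jump
adds an independent normal displacement inherited below, entering the
likelihood as `jump_var × count` of extra branch variance, capped at 5 per
branch), a base rate σ², a measurement-error variance, and the root state.
The likelihood is the Brownian pruning likelihood with branch variances
`σ² × rate × length + jump_var × count` and the error variance on the tip
diagonal, implemented in C++ (a test pins it to the independent
multivariate-normal BMM route for a fixed shift configuration).

Priors: Poisson(log 2) on the shift count (50% prior mass on no shifts),
Half-Cauchy(25) on rate scalars, the base rate and the error variance,
Poisson(configurable mean, default log 2) on the tree-wide jump count,
Half-Cauchy(25) on the jump variance, improper flat on the root state.
With uniform placement among branches, birth proposals drawn from the
scalar prior, and death picking uniformly among existing shifts, the
reversible-jump acceptance ratios collapse to `λ/(k+1)` (birth) and `k/λ`
(death) times the likelihood ratio; the same algebra makes the jump
birth/death ratios `λ_J/(J+1)` and `J/λ_J`.  The move mix is rate updates
0.4 (base + scalars), shift birth/death 0.2, relocation 0.1, root/error
0.1, jump moves 0.2 (renormalised without jump moves for `rbm`); log-walk
proposals have SD 0.5, the root walk SD is sd(trait)/4.  Runs are pure
functions of the seed.  A likelihood-free mode samples the prior exactly;
the prior-predictive tests (χ² against Poisson(log 2), KS against
Half-Cauchy(25)) thin every 50 generations so retained samples are
effectively independent.

Summaries discard a 25% burn-in by default and report per-branch shift
probabilities, directions (sign of the log rate change relative to the
parent regime), posterior mean relative rates, jump probabilities and mean
counts, together with the retained-sample count (probabilities from few
retained samples are visibly granular, which that count makes
interpretable).  Diagnostics: ESS by Geyer's initial monotone sequence,
PSRF from ≥ 2 equal-length chains; ESS < 200 and PSRF > 1.1 are reporting
flags, never hard failures.

### Phylogenetic ANOVA

GLS with correlation `V(λ)`: off-diagonal phylogenetic covariance × λ,
λ ∈ [0, 1] profiled by a 21-point grid plus golden-section refinement
(tolerance 1e-6), boundary estimates reported as such.  The F statistic
compares whitened residual sums of squares of the scenario model and the
intercept-only null, both at the *alternative* model's λ̂ — the correlation
structure is fitted once per scenario, not refitted under the null.  The
scenario family for Benjamini–Hochberg is configurable; the pipeline
default is the six scenarios (regime, regime-split, echo-freq, age,
suborder, echo).  `bh_adjust` implements the step-up formula directly and
is tested against `stats::p.adjust` and a from-the-definition oracle.

## 3. The synthetic world

The generator emulates: a 123-landmark bilateral scheme; exact template
symmetry (left jittered, right exactly reflected, midline jittered within
the plane); graded directional nasofacial displacement for odontocetes
(right nasal + premaxilla + maxilla, 1.5–4.5 mm, with the monodontid /
physeteroid / platanistid analogues at 5.5–8.5 mm forming "regime4");
rostral displacement for archaeocetes (1.5–3 mm); digitising noise (0.5 mm
isotropic, 0.1% of the 500 mm centroid size, chosen so symmetric controls
score well below planted signals); missing landmarks hitting ~39% of
specimens, concentrated 4:1 in fragile regions (jugal, squamosal,
rostrum); non-ultrametric trees via truncated terminal branches; and
traits under BM/OU with planted regimes, shifts and jumps.  At these
defaults specimen sums span roughly 0.13–0.55 Procrustes units with group
means ordered odontocete > archaeocete > mysticete ≈ terrestrial, matching
the magnitudes the method is meant to resolve.

What it does **not** emulate: real suture-based landmark correlations,
taphonomic deformation (beyond isotropic noise), allometry, intraspecific
variation (one specimen per species), mesh-level artefacts, and any
realistic tree-to-trait coupling of the discrete scenarios (scenario
labels are assigned by group and family, not evolved).  A green end-to-end
test therefore establishes that the *pipeline arithmetic* recovers planted
signals of realistic size under realistic missingness and noise — not that
the biological conclusions would survive real data pathologies.

Test scale-downs (all documented in the test files): the ER-preference
study runs 20 replicates at 100 tips (stated design: 50 at 200), OUM
recovery 20 replicates at 120 tips (50 at 200), type-I calibration 600
replicates (1000), planted-jump recovery 10 replicates at 1.2e5
generations (20 full-length chains).  The planted-shift recovery runs at
its stated scale (20 runs, 100 tips, 2e5 generations).  Thresholds are
never loosened when scaling down.

## 4. Known limitations

* Angles ϕ/θ depend on the consensus principal-axis frame, which has sign
  ambiguities; only ρ feeds the statistics.
* The rjMCMC proposal mechanics are this package's own (the cited
  sampler's internals are unpublished); equivalence is asserted at the
  level of priors, likelihood, and summaries.
* Measurement-error variance in the continuous-ML module is only exact
  when σ² is fixed; the rjMCMC module estimates measurement error
  natively.
* `BMsm` without a painting has no way to form state means; it requires
  the scenario painting like the multi-regime classes.
* The λ-GLS route assumes a single correlation structure per scenario;
  simulation-based (Garland-style) phylogenetic ANOVA is out of scope.
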