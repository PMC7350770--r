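# cetasym

Quantification and macroevolutionary modelling of cranial asymmetry from
3D landmarks, built for the cetacean skull but applicable to any
bilaterally organised structure.

## The scientific problem

Toothed whales (odontocetes) are unusual among mammals in having markedly
asymmetric skulls, concentrated in the nasal and facial region and widely
linked to echolocation; baleen whales (mysticetes) and terrestrial
artiodactyls are nearly symmetric, and early stem whales (archaeocetes)
show asymmetry concentrated in the rostrum.  To put numbers on this, each
digitised skull (the focal configuration *Fn*, 123 landmarks: 57 bilateral
pairs plus 9 midline points) is compared against its own computer-mirrored
symmetric double (*Rn*), built by reflecting the left-side landmarks
through the fitted midsagittal plane.  After generalized Procrustes
superimposition (proper rotations only, so asymmetry is never absorbed by
a reflection), each landmark's displacement is decomposed in spherical
coordinates:

- **ρ** — the Euclidean distance between *Fn* and *Rn* at that landmark
  (Procrustes units),
- **ϕ**, **θ** — azimuth and polar angles of the displacement.

The per-specimen score **Σρ_spec = Σ_i ρ_i** summarises whole-skull
asymmetry; group means (x̄ρ), per-landmark group means (x̄ρ_land) and
regional percentages localise it.  Missing landmarks (broken jugals,
squamosals, rostrum tips — common in museum and fossil material) are first
estimated by a thin-plate spline (kernel `U(r) = r`) against the Procrustes
mean of the complete specimens.

The evolution of Σρ_spec on a time-calibrated phylogeny is then modelled
three ways:

1. **Relaxed Brownian motion by reversible-jump MCMC** — branch-specific
   rate *shifts* (Poisson(log 2) prior on the shift count, so no-shift has
   50% prior probability; Half-Cauchy(25) priors on rate scalars and
   measurement error) and trait *jumps* (the `jump-rbm` model), with
   per-branch posterior shift/jump probabilities, ESS and Gelman–Rubin
   diagnostics.
2. **Multi-regime BM/OU model selection** — `BM`, `BMtr` (trend), `BMsm`
   (per-state means), `BMM`/`BMMtr`/`BMMsm` (per-regime rates) and
   `OU`/`OUM` (per-regime optima, Butler–King lineage weighting) fitted by
   ML on regime paintings of the tree (ancestral / regime / regime-split /
   echo / echo-freq scenarios) and ranked by AIC = 2k − 2 logLik.
   Discrete scenario characters themselves are checked with Mk
   (ER/SYM/ARD) likelihood fits.
3. **Phylogenetic ANOVA** — GLS with a Pagel's λ correlation structure
   (off-diagonal covariance × λ ∈ [0,1], profiled by grid + golden
   section), F tests of each scenario against the intercept-only null, and
   Benjamini–Hochberg control across scenarios.

A synthetic-data module generates stylised skulls with planted, graded
nasofacial or rostral asymmetry, fragile-region missing data, digitising
noise, non-ultrametric trees with fossil tips, and traits with planted
regimes/shifts/jumps, so the whole pipeline is testable without the
museum-scan dataset.

## Worked example

```r
library(cetasym)

ds  <- make_synthetic_dataset(n_odontocete = 30, n_mysticete = 8,
                              n_archaeocete = 4, n_terrestrial = 3,
                              missing_fraction = 0.39, seed = 2)
res <- quantify_asymmetry(ds)
res
#> Asymmetry quantification: 45 specimens, 5535 radii values

group_summary(res)$group_means
#>         group  n mean_sum_rho
#> 1 archaeocete  4    0.1817921
#> 2   mysticete  8    0.1774466
#> 3  odontocete 30    0.3307512
#> 4 terrestrial  3    0.1650705

head(group_summary(res)$ranking, 5)
#>   rank specimen_id      group   sum_rho
#> 1    1     spec007 odontocete 0.5353795
#> 2    2     spec011 odontocete 0.4994503
#> 3    3     spec004 odontocete 0.4719915
#> 4    4     spec002 odontocete 0.4691807
#> 5    5     spec001 odontocete 0.4615564
```

The group means read like the empirical pattern this package is built
around: odontocetes carry roughly twice the total asymmetry of the
baseline groups (mean Σρ_spec 0.33 vs ~0.17), and the top-ranked specimens
all belong to the planted high-asymmetry odontocete families.  Downstream:

```r
tr    <- simulate_tree(45, seed = 10, fossil_tips = 12)
# ... map species to tips, then:
# run_rjmcmc(tr, trait, model = "jump-rbm", n_gen = 1e6, thin = 1e4)
# fit_model("OUM", tr, trait, painting = paint_regimes(...))
# run_phylo_anova(trait, scenarios, tr)
```

or run everything from one config with `run_pipeline(list(synthetic = TRUE,
n_specimens = 40, seed = 1, outdir = "out"))`, which writes `radii.csv`,
`asymmetry_summary.csv`, `model_ranking.csv`, `shifts.csv`, `jumps.csv`,
`anova.csv`, `diagnostics.json` and a checksummed `manifest.json`.
`sensitivity(config, "no-rostrum")` re-runs the model ranking without
rostral landmarks and reports whether the AIC ordering is preserved.

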