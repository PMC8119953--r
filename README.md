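# fluordom

Optical chemometrics for dissolved organic matter (DOM) degradation
experiments in R.

When river water meets the coastal ocean, sunlight and microbes compete to
transform its dissolved organic matter. Experiments that track this — bottles
of filtered water exposed to UV or incubated in the dark with size-fractionated
microbial inocula — are read out through optics: CDOM absorption spectra,
spectral slopes (S275:295, S350:400), SUVA254, and fluorescence
excitation–emission matrices (EEMs) decomposed by PARAFAC into humic- and
protein-like components. `fluordom` implements that entire analysis chain for
users of such incubation and field campaigns:

- **CDOM optics** — absorbance → Napierian absorption
  (a(λ) = 2.303·A(λ)/l), nonlinear spectral-slope fits
  a(λ) = a(λ₀)·e^(−S(λ−λ₀)) over 275–295 and 350–400 nm, SUVA254,
  robust replicate averaging.
- **EEM correction** — blank subtraction, absorbance-based inner-filter
  correction (10^((A_ex+A_em)/2)), Raman-unit normalisation, scatter masking;
  order-enforced and state-tracked.
- **Non-negative PARAFAC** — `parafac()` fits the trilinear model
  x_ijk ≈ Σ_f a_if·b_jf·c_kf (a, b, c ≥ 0) by masked, accelerated
  non-negative alternating least squares, with multi-start, split-half
  validation via Tucker congruence, leverage-based outlier screening, core
  consistency, library matching, and component-count selection. The fitted
  model is a classed S3 object with `print`, `summary`, `coef`, `fitted`,
  `residuals`, `predict` (project new EEMs) and `plot` methods.
- **Component metrics** — Fmax, percent contribution
  (100·Fmax_i/ΣFmax), percent change vs day 0 (100·(C_t−C_0)/C_0),
  iterative Grubbs outlier filtering, contributions ordered along the
  salinity gradient.
- **Photobleaching kinetics** — single vs double exponential decay
  (y = a·(f₁e^(−k₁t)+(1−f₁)e^(−k₂t))) with nested-model F-test selection
  and peak-absorption-loss localisation.
- **Campaign tables** — river/plume/ocean classification by salinity and
  day-0→24 change summaries (mean ± sd with the correct spread basis per
  class), DOC anomaly exclusion.
- **Synthetic campaigns** — a ground-truth-known generator
  (`simulate_campaign()`) emulating the full design: six fluorophore
  components, treatment-specific kinetics, exponential absorbance with
  photobleaching, seeded noise. Every stage of the package is tested
  against it.

## Worked example

Simulate a photobleaching campaign (10 stations across the salinity
gradient, 6 timepoints, 60 EEMs with 0.5% noise), fit and validate a
six-component model, and inspect recovery:

```r
library(fluordom)

cfg <- campaign_config(treatments = "PB", replicates = c(PB = 1),
                       ex_grid = seq(240, 650, 10), em_grid = seq(300, 600, 5),
                       seed = 7)
camp <- simulate_campaign(cfg)
ds <- assemble_dataset(camp$eems)

m <- parafac(ds, ncomp = 6, n_starts = 10, seed = 1)
summary(m)
#> Non-negative PARAFAC model: 6 components, 60 samples
#> Explained variation: 99.9960%  (converged: TRUE, 126 iterations)
#>  component peak_ex_nm peak_em_nm mean_score
#>         C1        390        510    0.28284
#>         C2        350        450    0.35192
#>         C3        250        430    0.38732
#>         C4        300        395    0.36587
#>         C5        280        340    0.13003
#>         C6        270        305    0.09302

split_half_validate(ds, 6, threshold = 0.95, seed = 11)
#> <parafac_validation> four quarters, three half-pairs
#>   min congruence 0.9988 (threshold 0.95): VALIDATED

match_components(m, camp$truth$component_spectra, threshold = 0.95)
```

The model explains 99.996% of the total variation; every fitted component
matches its generating fluorophore with Tucker congruence above 0.98 in both
spectral modes (components are labelled by descending emission peak, so the
long-wavelength humic appears first). Downstream,
`fmax()` → `component_changes()` → `summarize_changes()` turn the scores into
the familiar campaign change table, and `fit_decay()` models the
photobleaching decay of a_CDOM(300) per station.

A full end-to-end run (simulate → correct → fit → metrics → kinetics →
tables) is one call:

```r
run <- run_pipeline(pipeline_config(campaign = campaign_config(seed = 1),
                                    output_dir = "run1", seed = 42))
```

## Documentation

The methods vignette (`vignettes/fluordom-methods.Rmd`) describes the models
and their assumptions, all tunable parameters with units and defaults, what
the synthetic generator does and does not emulate, numerical choices, and
known limitations.
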