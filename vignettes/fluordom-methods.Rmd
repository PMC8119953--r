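---
title: "Optical chemometrics for DOM degradation experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical chemometrics for DOM degradation experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluordom)
```

# Scope

`fluordom` implements the optical-chemometric analysis chain used to study how
sunlight and microbes degrade dissolved organic matter (DOM) along a
river-to-ocean salinity gradient: absorbance conversion and spectral slopes,
excitation-emission matrix (EEM) correction, non-negative PARAFAC
decomposition with split-half validation, component change statistics,
photobleaching decay kinetics, and campaign summary tables. Because such
incubation datasets are rarely archived, the package ships a synthetic
campaign generator with full ground truth; every stage is tested against it.

# CDOM absorption and spectral slopes

Decadal absorbance $A(\lambda)$ measured over a cuvette of pathlength $l$
(metres) converts to Napierian absorption coefficients

$$a_{CDOM}(\lambda) = 2.303\, A(\lambda) / l \quad [\mathrm{m^{-1}}],$$

a linear, positivity-preserving map (`absorbance_to_absorption()`). Spectral
slopes $S$ (nm$^{-1}$) are obtained by unweighted nonlinear least squares of

$$a_{CDOM}(\lambda) = a_{CDOM}(\lambda_0)\, e^{-S (\lambda - \lambda_0)}$$

over the windows 275–295 nm and 350–400 nm, with $\lambda_0$ fixed at the
window midpoint (285 or 375 nm). The fit is started from, and on noiseless
exponentials coincides with, a log-linear regression
(`fit_spectral_slope_loglinear()` is retained as a cross-check). No additive
offset term is included: the exponential family above has none, and an offset
is not identifiable from the narrow windows. Values $\le 0$ inside a window
abort the fit rather than being masked, to avoid silent bias in low-CDOM,
high-salinity samples.

Replicate absorbance scans are screened before averaging: a scan is dropped
when its mean absolute deviation from the pointwise median spectrum
(250–500 nm) exceeds 5 times the median such deviation — a robust, scale-free
rule (`average_replicates()`). SUVA254 is absorbance at 254 nm per metre per
mg C L$^{-1}$ of DOC.

# EEM correction chain

Corrections are applied in a fixed, state-checked order (each step records
itself in the EEM's state and refuses re-application):

1. **Blank subtraction** of a same-day pure-water EEM. Negative residuals are
   kept; clipping would bias the noise statistics that PARAFAC sees.
2. **Inner-filter correction** by the absorbance-based (ABA) method for a
   1-cm cell: $F_{corr} = F_{obs}\,10^{(A(\lambda_{ex})+A(\lambda_{em}))/2}$
   with $A$ the decadal absorbance per cm. The method is reliable only up to
   total absorbance about 1.5; beyond that the sample is flagged.
3. **Raman normalisation**: division by the integrated water Raman peak of
   the same-day blank (emission scan at 350 nm excitation, trapezoidal
   integral over 371–428 nm — the community convention), converting
   intensities to Raman units (R.U.). Because sample and blank share the
   instrument gain, the gain cancels exactly; a property test simulates two
   instruments differing by a gain factor and requires identical R.U. EEMs.
4. **Scatter masking**: first/second-order Rayleigh and Raman bands are set
   to missing within configurable half-widths (defaults ±10, ±5, ±10,
   ±10 nm); the signal-free region below the Rayleigh diagonal
   (em ≤ ex + 5 nm) is set to zero. Masked cells are *missing*, not
   interpolated — the PARAFAC solver handles them explicitly, so no data are
   invented inside the bands.

# Non-negative PARAFAC

The corrected dataset is a sample × emission × excitation tensor $X$ with a
shared missing-cell mask. The trilinear model

$$x_{ijk} \approx \sum_{f=1}^{F} a_{if}\, b_{jf}\, c_{kf},
\qquad a,b,c \ge 0$$

is fitted by component-wise non-negative alternating least squares
(hierarchical ALS). Within each mode the component updates are iterated to
near-exactness (the Gram matrix is only $F\times F$, so inner sweeps are
cheap), and an extrapolation step along the last iterate accelerates the
slowly converging "swamps" caused by spectrally overlapping humic
components. Missing cells are handled by expectation-maximisation: they are
imputed from the current model each iteration and therefore contribute
nothing to the fitted loss (a test poisons masked cells and requires a
bit-identical model).

Conventions: all magnitude lives in the sample scores (R.U.); emission and
excitation loadings are unit Euclidean norm; components are ordered by
descending emission peak (ties by descending excitation peak), which together
with non-negativity absorbs PARAFAC's permutation and scale indeterminacy.

**Initialisation and stopping.** `n_starts` random non-negative starts plus
one SVD-based start are each run as 300-iteration pilots; the best pilot is
refined to full tolerance. Convergence is declared when the residual sum of
squares changes by less than `tol` (default $10^{-8}$) times the *total* sum
of squares per iteration — i.e. when the unexplained-variance fraction stops
moving at the eighth decimal, the convention of reference trilinear
implementations. An RSS-relative criterion at the same nominal value is
effectively unreachable inside swamps and would always exhaust `max_iter`
(default 2500). Fits are deterministic given the seed.

**Validation.** Samples are assigned round-robin to four quarters, combined
into the three canonical half-pairs; independent fits on each half are
matched by maximal Tucker congruence
($\phi(u,v) = \sum u v / \sqrt{\sum u^2 \sum v^2}$) and the model is
validated when every matched component exceeds the threshold (default 0.95)
in both spectral modes for all three pairs. Split-half congruence is the
validation gate; core consistency is computed as an auxiliary diagnostic
only, because with the strongly collinear humic loadings typical of DOM it
collapses (large negative values) even for the correct component count at
realistic noise — a known weakness of the diagnostic, observable directly on
the synthetic campaign. Sample outliers are screened by hat-matrix leverage
on the scores (flag above three times the mean leverage $F/n$ by default);
the leverages sum to $F$ and lie in $[0,1]$ by construction.

# Component metrics

Per sample and component, the fluorescence maximum is
$F_{max} = \text{score} \times \max(b_f) \times \max(c_f)$ (R.U.). Percent
contribution of component $i$ is $100\,F_{max,i} / \sum_f F_{max,f}$ and
percent change relative to day 0 is $100\,(C_t - C_0)/C_0$ — a pure ratio,
invariant to units. Change populations (per component × treatment ×
timepoint) are screened by iterative two-sided Grubbs tests at
$\alpha = 0.05$ (one removal per iteration, stopping at the first
non-rejection; identical values short-circuit via a zero-variance guard).
Changes are computed per bottle and then averaged, so replicate spread is
available where a station class needs it.

# Photobleaching kinetics

CDOM absorption (default $a_{CDOM}(300)$, normalised to day 0) and component
series are fitted with

- single: $y(t) = a\,e^{-kt}$,
- double: $y(t) = a\,(f_1 e^{-k_1 t} + (1-f_1) e^{-k_2 t})$,
  $k_1 \ge k_2 \ge 0$, $f_1 \in [0,1]$,

by bounded Levenberg–Marquardt least squares, the double exponential
multi-started over a grid of rate decades and canonicalised to $k_1 \ge k_2$.
Fits with coincident rates or a boundary fraction are flagged degenerate
(collapsed to single). Model selection uses the nested extra-sum-of-squares
F test at $\alpha = 0.01$: with the photobleaching schedule's six timepoints,
the corrected-AIC penalty for the four-parameter model is ill-conditioned
($n - k - 1 = 1$), so AICc values are recorded for reference but the F test
is the gate. At 1% noise this selects the single model for monoexponential
truth and the double model for well-separated biexponential truth in ≥95% of
seeded replicates (tested). Decay can be fitted against days or cumulative
exposure; no plateau term is included by default (fully photobleachable pool).

`peak_loss_wavelength()` locates the wavelength of maximal absolute
absorption loss between two spectra (ties to the lowest wavelength; "no
loss" is an explicit `NA` result).

# Campaign summaries

Stations classify by salinity into river (< 1 psu), plume (1–30 psu) and
ocean (≥ 30 psu); the boundaries are configuration, since class membership,
not thresholds, is what such studies report. Day-0→24 changes summarise as
mean ± sd per parameter × class × treatment, with the spread computed
between stations for river/plume (bottles first averaged within station) and
between replicate bottles for the single-station ocean class. Spectral-slope
changes are reported as absolute differences in nm$^{-1}$, never percent —
the summariser enforces this unit audit. DOC pairs with more carbon at day
24 than day 0 are excluded by strict inequality (a tolerance knob exists for
noisy synthetic DOC).

# The synthetic campaign generator

The generator emulates the incubation design the analysis assumes, with
defaults chosen once as the study conditions:

- **Design**: 10 stations spanning 0.1–31.2 psu; treatments PB
  (photobleaching, duplicate bottles, days 0/1/3/7/14/24), dark microbial
  treatments with 0.2/0.7/3.0 µm inocula (days 0/3/10/24) and a 3.0 µm
  incubation of previously photoexposed water.
- **EEMs**: exact trilinear mixtures of six fixed components built as
  products of unimodal bell curves in canonical DOM fluorophore regions —
  visible humic (ex 350/em 450), long-wavelength humic (390/510), UV humic
  (250/430), degraded humic (300/395), tryptophan-like (280/340),
  tyrosine-like (270/305). The excitation peaks of the two protein-like
  components are deliberately separated by 10 nm: identical excitation
  loadings would reduce the k-rank of the excitation factor to 1 and destroy
  PARAFAC uniqueness for that pair. Pairwise congruence of combined spectra
  is checked to be < 0.9 at build time.
- **Kinetics**: under PB the humics decay single-exponentially (24-day
  losses of about 83/65/80/46% for C1–C4), the tryptophan-like component
  rises then falls (photoproduction then photodegradation), and the
  tyrosine-like component rises toward a saturating maximum (+171% at day
  24); dark-treatment changes are an order of magnitude smaller, and the
  after-photoexposure treatment shows mild humification with net consumption
  of the protein-like material.
- **Noise**: multiplicative relative error (sd 0.5%) plus an additive floor
  (10⁻⁴ R.U.), mimicking photomultiplier shot and baseline noise; negative
  values are clipped to zero. Station baselines are log-uniform to create
  the leverage spread outlier screening needs.
- **Absorbance**: exact exponential spectra with slopes drawn from
  0.0138–0.0358 nm$^{-1}$. Under PB, $a_{350}$ decays at 0.0365 d$^{-1}$
  (−58% by day 24) and the slope steepens, solved per station and timepoint
  so the peak absolute absorption loss sits at 297 nm, inside the observed
  290–305 nm UV window.
- **DOC**: day-0/day-24 pairs with treatment-dependent mean losses
  (≈ −20% PB, −13 to −18% dark) and 5% station-level spread — drawn, not
  mechanistically modelled.

What the generator does *not* emulate: instrument spectral correction
factors, scatter physics (raw mode adds a synthetic Raman band, not a full
scatter model), wavelength-dependent noise, non-trilinear matrix effects,
and a two-slope absorbance family (so the small observed *decrease* of
S350:400 under photobleaching is not reproduced — the one-slope family can
only steepen). Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not instrument-specific
robustness on real data.

# Numerical choices and problem sizes

- Slope and decay fits: Levenberg–Marquardt (`minpack.lm`), `ftol/ptol`
  10⁻¹⁵, multi-start for the double exponential.
- PARAFAC: tol 10⁻⁸ × TSS per iteration, `max_iter` 2500, 10 random + 1 SVD
  start (300-iteration pilots, best refined); component death is tolerated
  (dead components report congruence 0 internally and are never matched).
- The test suite runs campaigns on coarsened grids (excitation 240–650 nm at
  10 nm, emission 300–600 nm at 5 nm; 60 samples) so the full suite stays
  fast; the acceptance script uses the full default grids (5 nm excitation,
  2 nm emission).
- The noiseless forward/inverse identity is asserted at 10⁻⁶ relative
  unexplained variance: the fit approaches machine-level reconstruction only
  asymptotically inside the humic swamp, and reaching 10⁻⁸ takes thousands
  of iterations for no scientific gain.

# Known limitations

- Corcondia is reported but unreliable under the strong humic collinearity
  typical of DOM; split-half validation is the gate.
- The outlier criterion (leverage cut) is a default, not a calibrated rule;
  real analyses should inspect flagged samples.
- Dark-treatment kinetics in the generator are single-law per component;
  real microbial dynamics (succession, production/consumption reversals) are
  richer.
- Decay-model selection with six timepoints has limited power by
  construction; rates separated by less than ~5× will usually select the
  single model.

# A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  input = "synthetic",
  campaign = campaign_config(seed = 1),
  parafac = list(candidates = 6, n_starts = 10),
  output_dir = "run1", seed = 42)
manifest <- run_pipeline(cfg)
manifest$model          # the fitted six-component PARAFAC model
```

The run directory contains `fmax.csv`, `contributions.csv`, `changes.csv`,
`kinetics.csv`, `table1.csv` (long) and `table1_wide.csv` (one column per
treatment), the exported loadings, a JSON model report, and the full
configuration; every table carries the configuration hash, and re-running
with the same configuration and seed reproduces identical checksums.
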