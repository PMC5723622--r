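---
title: "Modelling invasive bamboo habitat and projecting it under warming levels"
author: "bambooclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling invasive bamboo habitat and projecting it under warming levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bambooclim)
```

## The problem

Moso and madake bamboos (*Phyllostachys edulis*, *P. bambusoides*) are
vigorous clonal invaders whose northern and upslope range limits in Japan
are set chiefly by temperature. `bambooclim` implements a complete
bioclimatic-envelope analysis for this setting: it relates bamboo
presence/absence recorded around weather stations to station
climatologies, selects and validates a binomial-logit niche model, and
projects the thresholded habitat onto climate grids under global warming
levels of 1.5–4.0 °C above the preindustrial state, with extrapolation
diagnostics. Everything runs on synthetic data with known ground truth, so
each stage is testable without the original field or climate-model data.

## Climatic predictors

From each station's twelve monthly mean temperatures $t_i$ (°C) and
precipitation totals $p_i$ (mm) we compute

* the **warmth index** $WI = \sum_i \max(t_i - 5, 0)$ and **coldness
  index** $CI = \sum_i \min(t_i - 5, 0)$ (°C·month), Kira's classical
  plant-growth heat measures. The two satisfy the exact partition
  $WI + CI = 12(\bar t - 5)$, which the tests exploit as an invariant.
  $CI$ is kept with its negative sign.
* growing-season precipitation, the total over months with $t_i \ge 5$ °C
  (the 5 °C boundary is inclusive), and its complement; their sum always
  equals annual precipitation.
* mean annual temperature, and pass-through annual extreme temperatures
  and sun radiation. Annual minima/maxima come from sub-daily records
  upstream and are consumed as provided columns; the synthetic generator
  simulates them as fixed offsets from the coldest/warmest monthly mean.

With multi-year station records, indices are computed per year and then
averaged over the climatological window, not computed on averaged months;
the two orders differ whenever a month straddles 5 °C in some years only,
and the per-year order is the meaningful climatology of a growth index.

## The niche model and its selection

The core model is an ordinary logistic regression,
$\operatorname{logit} P(\text{presence}) = \beta_0 + \beta^\top x$,
fitted by IRLS (relative log-likelihood tolerance $10^{-8}$, at most 100
iterations). Complete separation — easy to provoke with 29 absences — is
detected from fitted probabilities and raised as a typed error naming the
most implicated predictor rather than returning divergent coefficients.

Model selection follows the information-theoretic protocol standard in
distribution modelling: all subsets of a candidate term set are fitted and
ranked by the small-sample criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$. Because the five
temperature-related variables (mean, annual extremes, $WI$, $CI$) are
near-collinear, as are the precipitation totals, the two-stage recipe
`rankGlobalModels()` crosses each temperature variable with each
precipitation variable into ten global models (each also carrying
non-growing-season precipitation, radiation, and forest/farmland ratios),
dredges each, and pools the union. The pooling rule — deduplicate by term
set and re-rank the union by AICc — is this package's own choice; ties
break by fewer parameters, then lexicographic term order, so rankings are
reproducible.

## Validation under class imbalance

With roughly four presences per absence, raw accuracy is uninformative, so
validation uses leave-one-out cross-validation scores, an AUC computed as
the tie-corrected rank statistic, and a probability threshold chosen by
maximizing Youden's $J = \text{sensitivity} + \text{specificity} - 1$.
Conventions that the underlying definitions leave open are fixed and
documented:

* classification is **inclusive**, presence iff score $\ge \tau$;
* threshold candidates are midpoints between consecutive sorted unique
  scores plus $\mp\infty$ sentinels; ties in $J$ take the smallest
  $\tau$, favouring sensitivity;
* tied scores earn half credit in the AUC (Mann–Whitney convention);
* any metric with a zero denominator (e.g. MCC with an empty margin) is
  reported as `NA` with a warning — silent zeros would corrupt model
  ranking;
* LOOCV folds that separate are scored `NA` with a warning and excluded,
  rather than aborting a 145-point analysis.

Both pooled-LOOCV and resubstitution scoring are available;
pooled LOOCV is the default in the pipeline. `solveConfusion()` inverts
printed (accuracy, informedness) pairs to the unique integer confusion
matrix, which is how the package cross-checks published metric sets for
internal consistency.

## Warming-level scenarios by pattern scaling

Scenarios at a target warming $X$ °C above preindustrial are built in the
classical pattern-scaling way:

1. a **scaling pattern** is the 20-year-mean future-minus-present field of
   a driving simulation divided by its global-mean warming `globalDT`
   (ensemble members 3.49, 3.57, 3.50, 3.41 °C in the motivating setup);
2. the scenario field is `baseline + (X − 0.5) × pattern`. The 0.5 °C is
   the warming already realized at the 1980–2000 baseline relative to
   preindustrial, so `X = 0.5` returns the baseline bit-exactly and the
   construction is affine in `X`;
3. the **exceedance year** of level $X$ is the first year the 20-year
   running-mean global anomaly (zero at the 1990 reference) reaches
   $X - 0.5$; the comparison is inclusive ("exceeded" read as $\ge$), and
   a level never reached returns `NA` rather than an error.

Running means are labelled by the exact window centre (half-integer years
for even windows), so a linear series maps onto itself at the labels; the
generator writes already-smoothed anomaly series at integer years, so
exceedance years are integers. Bias correction of simulated baselines is a
deliberately simple per-cell mean match — additive for temperature,
multiplicative for radiation with a near-zero guard — isolated behind
`biasCorrect()` so a quantile-mapping recipe can replace it without
touching the rest of the chain.

## Projection, area accounting, and extrapolation

`predictGrid()` applies the fitted coefficients cellwise and
`thresholdMap()` cuts at $\tau$ (inclusive, matching the station-level
rule). Habitat area is the fraction of land cells in the focal region —
by default at or north of 35 °N and at or east of 136 °E, both bounds
inclusive — counted per cell; at mid-latitudes on a ~5-km grid cell
counting is near-equal-area, and a `cos(latitude)` weighting is available
behind a flag for wider domains. The northern limit is the maximum
habitat cell-centre latitude, and shifts are converted at a fixed mean
meridian arc of 111.2 km/degree; published kilometre figures are treated
as descriptive, not normative.

Extrapolation is quantified with the multivariate environmental
similarity surface (MESS): per variable, the percentage $f$ of reference
points strictly below the cell value maps to a percent-like similarity
(negative outside the reference range), and the cell keeps the minimum
across variables plus the identity of the most dissimilar variable. A
degenerate single-valued reference yields similarity 0 off-value (100 on
it) with a warning. The published MESS definition is implemented as-is;
variant "modified" forms can be swapped in behind the one internal
function that computes per-variable similarity.

## The synthetic world

`makeStations()` emulates the study conditions: 145 stations over
35.3–41.5 °N, altitudes skewed low (cubed-uniform over 0–1100 m), mean
annual temperature following a −0.9 °C/degree latitudinal gradient and a
−6.5 °C/km lapse rate around a 16.3 °C southern sea-level base, 0.4 °C
station noise, and a fixed-amplitude (11 °C) sinusoidal seasonal cycle —
mean-zero by construction, so the latent annual mean is exact. Presence is
Bernoulli with
$\operatorname{logit} p = \beta_0 + \beta_T T + \beta_R R$ and defaults
$(\beta_0, \beta_T, \beta_R) = (-12.0, 1.1, 0.15)$, chosen once so the
occurrence probability rises steeply across mean annual temperatures of
about 7–11 °C and the presence fraction sits near 116/145. True
probabilities and coefficients travel with the table, which is what makes
coefficient-recovery tests possible.

What the generator does **not** emulate: real geography and coastlines,
spatial autocorrelation of residuals, observation error in the presence
records, non-sinusoidal seasonal cycles, and any land-use signal
(land-use ratios are generated independently of presence). Passing tests
therefore demonstrate correctness of the machinery — index arithmetic,
likelihood fitting, selection, thresholding, scaling, area accounting —
not ecological validity on real data.

`makeGridWorld()` produces paired present/future temperature and
radiation grids with a known warming field, so the recovered scaling
pattern is exactly `warming / globalDT`; with its spatial noise set to
zero the temperature field is purely latitudinal and the habitat boundary
is an analytically computable isotherm, which the end-to-end tests compare
against the projected area fraction at one-grid-row tolerance (0.1°
resolution in those tests; coarser 0.5–1.0° fixtures keep the full
pipeline tests fast).

## Numerical and interface choices

* All randomness flows through explicit seeds (`withSeed()` restores the
  caller's RNG state); rerunning any generator or the pipeline with the
  same configuration is byte-identical.
* Grids are plain matrices with cell-centre WGS84 coordinates inside S4
  containers with validity checks; masked cells are `NA` and provably
  never acquire values through scaling, scenario building, prediction or
  MESS.
* Grid files use the plain-text ESRI ASCII raster dialect with a JSON
  sidecar for variable/period labels; tables are UTF-8 comma-separated
  CSV with `.` decimals, fixed to avoid locale drift.
* The station dialect and its validation report offending line numbers;
  a bad ratio or a negative precipitation value fails loudly at ingestion,
  not deep in a fit.
* Sun radiation is treated as a static per-station value rather than a
  period-specific one; at the scales involved its effect on the model is
  secondary, and the interface accepts any column the user prefers.
* The sample size is parameterized throughout; nothing assumes exactly
  145 records.

## Known limitations

The bias-correction stand-in matches means only; the habitat/area
accounting ignores coastline geometry beyond the mask; the scorer
interface accepts external probability columns (so GAM/tree-ensemble
scores can be validated with the same LOOCV/threshold/metrics machinery)
but the package fits only the binomial-logit model; and kilometre
conversions use a spherical meridian constant. Each is an explicit,
isolated choice rather than an implicit assumption.
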