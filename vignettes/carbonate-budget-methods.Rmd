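---
title: "Methods: census-based reef carbonate budgets, kriging, and cover thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census-based reef carbonate budgets, kriging, and cover thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `reefbudget`, the choices that
were genuinely open when the package was designed, and what the synthetic
tests do and do not demonstrate about real survey data.

## The budget model

Net carbonate production at a site (kg CaCO₃ m⁻² y⁻¹) is gross
calcification plus a sediment term minus three bioerosion components.
Budgets are solved **per transect** and then averaged per site; every
component is available separately via `transect_budgets()` and
`site_budgets()`, and the identity
`net = gross + sediment − (parrotfish + urchin + macroboring)` is enforced
exactly (it is a derived column, and a property test asserts it to 1e−12
relative).

### Gross calcification

`coral_calcification()` evaluates
`r · (Σⱼ mⱼ (xⱼ/100) dⱼ gⱼ · 10 + 0.018 · pca · 10)`. The assumptions worth
stating:

* **Rugosity as a ratio.** The survey protocol measures a
  contour-following tape and a straight horizontal line above it.
  `rugosity()` returns the ratio contour/horizontal rather than the raw
  length difference, because the budget multiplies planar cover by `r` as
  an area-correction factor, which must be a dimensionless index near 1.
  Measurement noise can push the raw ratio marginally below 1; ratios in
  `[0.95, 1)` are clamped to 1 and anything lower is rejected as an
  inconsistent measurement pair.
* **Cover conventions.** Coral cover `x` and CCA cover `pca` are
  percentages (0–100); macroborer cover `plamc` is a proportion (0–1).
  The asymmetry is deliberate: with typical macroborer cover around half a
  percent, `plamc × 10` yields the ~0.05 kg m⁻² y⁻¹ magnitudes that
  macroboring erosion should take, and `macroboring_erosion()` rejects
  values above 1 with a hint about percent/proportion confusion.
* **Traits.** Each coral taxon needs a morphological coefficient `m`, a
  skeletal density `d` (g cm⁻³, accepted range 0.5–3.0) and a vertical
  growth rate `g` (cm y⁻¹). Missing traits are a hard error naming the
  taxon; `permissive = TRUE` substitutes generic values (m = 1,
  d = 1.5 g cm⁻³, g = 0.5 cm y⁻¹) with a warning. The shipped
  `default_traits()` table is assembled from typical published ranges and
  is explicitly non-canonical — real analyses should supply measured
  values.

### Bioerosion

Parrotfish erosion chains three allometries in fork length: an exponential
bite volume, a logistic scar proportion, and a linear bite rate with a
species-specific constant `brc`. Two numerical choices matter:

* **Bite-rate clamp.** The linear bite-rate regression goes negative for
  large fishes with small `brc` — it is being used outside its fitted size
  range. Rates are clamped at zero: a fish cannot erode negatively. The
  practical consequence is that very large individuals (e.g. bumphead
  parrotfish classes in the generator) can contribute nothing under the
  printed equation; the daily grazing time (`reeftime_h`, default 9 h)
  sits inside the subtracted term and is exposed in `budget_constants()`
  because its unit role in the printed formula is ambiguous.
* **Area normalisation.** The erosion sums carry no explicit per-area
  divisor in their original statement, but the output units are
  kg m⁻² y⁻¹. Fish erosion is therefore divided by the surveyed video area
  (transects × 120 m²) and echinoid erosion by the belt area
  (transects × 6 m²).

The mean coral density `D` that scales fish erosion is the cover-weighted
mean of trait densities over the coral taxa present at the site, falling
back to a configurable 1.5 g cm⁻³ on coral-free sites.

Echinoid erosion uses genus-level power laws in test diameter (Diadema,
Echinometra, other urchins), each converted by 365 × 0.001 (g day⁻¹ →
kg y⁻¹) and scaled by 0.57; the 0.365 product is asserted at constant
construction. Sediment contributes a fixed +0.4 kg CaCO₃ m⁻² y⁻¹ by
default; the sign switch for high-sedimentation settings is exposed as
`sediment_sign` because the original switch condition is never defined
quantitatively.

### Vertical growth and keep-up

`vertical_growth()` evaluates the quadratic conversion `V = Cp + α Cp²`,
with `α` calibrated by `calibrate_alpha()` from pairs of production and
growth values (closed-form least squares; a single pair inverts exactly —
the island-wide pair 9.7 kg CaCO₃ m⁻² y⁻¹ ↔ 7.9 mm y⁻¹ gives
α ≈ −0.0191). For negative `α` the parabola peaks at `Cp = −1/(2α) ≈ 26`;
beyond the apex the conversion would decrease, which is outside the
calibrated domain, so values are clamped at the apex with a warning rather
than returned decreasing. `keep_up_assessment()` compares growth against
RCP sea-level-rise rates (2.6: 5.0, 4.5: 6.5, 6: 6.7, 8.5: 9.0 mm y⁻¹);
ties keep up.

## Spatial interpolation

Site coordinates are projected from WGS84 degrees to UTM meters (zone from
the mean longitude) before any distance is computed; degrees are never
used as Euclidean coordinates. The empirical semivariogram is the binned
Matheron estimator, with optional directional estimates at bearings
{0°, 45°, 90°, 135°} (±22.5°) for anisotropy checks; a geometric
correction is suggested only when directional ranges differ by more than
50%. Model fitting is weighted least squares with weights
`pairs / distance²` over nugget, partial sill and range, box-constrained
quasi-Newton from three starts (tight convergence, `factr = 1e3`;
refitting a model to its own curve reproduces its parameters to ~1e−3).
The default family is exponential; `krige_budgets(family = "auto")`
selects among exponential/spherical/gaussian by residual sum of squares.

Ordinary kriging solves the bordered semivariance system once per dataset
and applies it to all grid nodes; weights sum to 1 by construction (tested
to 1e−10) and the predictor interpolates exactly with zero variance at
data points when the nugget is 0. Coincident-point duplicates are averaged
on ingest because they make the system singular. The default grid is the
10%-padded bounding box at 100 × 100 nodes (40 × 40 in `run_pipeline()`,
which keeps a full two-island run in a few seconds); no land masking is
applied — cartography is out of scope.

A caveat established while validating the fitter: a single Gaussian-field
realization at 200 sites constrains the range parameter only loosely — in
repeated simulations the single-realization range estimate misses the
truth by more than 25% in roughly two fifths of realizations, regardless
of binning. The recovery test therefore checks the median of fits over 11
replicate fields (domain ≈ 10 range parameters wide), which is the
estimator property that actually matters for interpretation.

## The threshold model

Per-transect net production `G` is modelled as
`G = β₀ + f(LCC) + Habitat + a_country + ε` with a cubic O'Sullivan
spline `f` (5 interior knots at cover quantiles, boundary fixed at 0–100%
cover so fitted curves can be evaluated over the whole feasible range),
treatment-coded habitat effects, a normal random intercept per country,
and normal residuals. Priors are deliberately diffuse: Normal(0, sd 100)
on fixed effects and half-Normal(sd 10) on all standard deviations. The
model is fitted with JAGS (4 chains × 2000 kept draws after 1000 warm-up
by default, chain RNGs derived from one seed), with split R-hat ≤ 1.05 as
the acceptance bar and `strict = TRUE` turning a convergence failure into
an error.

Two computational details were load-bearing:

* The O'Sullivan basis is re-expressed in mixed-model form (spectral
  transform of the exact integrated-squared-second-derivative penalty; a
  cubic basis with K interior knots yields K + 2 penalized columns and a
  2-dimensional unpenalized nullspace). The penalized columns are
  additionally orthogonalized in sample space against the intercept and
  linear term — the span is unchanged, but without this the Gibbs sampler
  has to negotiate near-collinearity between the slope and the smoother
  and mixes an order of magnitude more slowly. The JAGS `glm` module is
  loaded for block updates of the linear nodes for the same reason.
* With only two countries, the global intercept and the country
  intercepts are only jointly identified. Draws are re-centred (the mean
  of the country effects is swept into the intercept) so that reported
  parameters, diagnostics and threshold curves live on the identified
  parameterization.

### Inverting for the cover threshold

`estimate_threshold()` evaluates, per posterior draw and habitat, the
expected production curve on a cover grid (0–100% in steps of 0.1; halving
the step moves medians by < 0.2 pp in tests) and records the smallest
cover at which the curve crosses from negative to non-negative, using
linear interpolation inside the bracketing step. Curves already
non-negative at 0% report a threshold of 0; draws that never cross are
counted, and a habitat where more than half the draws have no crossing is
flagged "no finite threshold". Extra sign changes (usually spline wiggle
in the extrapolated high-cover region) raise a multimodality flag without
changing the first-crossing value.

One design decision deviates from the obvious "typical country"
convention. Because habitat strata are nested within countries (Palau
habitats occur only in Palau), a curve with the country intercept held at
0 is **not an identified quantity**: its posterior width tracks the
prior-dominated country-effect standard deviation, and once the sampler
mixes properly the resulting intervals become arbitrarily wide. The
default (`country = "observed"`) therefore adds the observation-weighted
intercept of the country in which the habitat was surveyed — the
combination the data identify — while `"typical"` and explicit country
levels remain available.

## The synthetic generator

`generate_survey_dataset()` emulates the study design the package targets:
Palau with 8/10/6 outer/patch/inner sites (outer split 4 west / 4 east),
Yap with 10/14 outer/inner and no patch stratum, six transects per site,
line-intercept records, rugosity pairs, fish and urchin observations.
Habitat-level cover distributions are Beta with means ordered
outer-west > patch > outer-east > inner (high-cover outer reefs, sparse
inner reefs); fish lengths are log-normal truncated to 5–60 cm with an
optional large bumphead class; urchin sizes log-normal truncated to
1–15 cm; rugosity is 1 plus a Gamma excess (mean ≈ 1.4). All of these
parameters are package choices — qualitatively realistic, deliberately
documented as non-canonical.

Ground truth is computed by an **independent arithmetic path**: the budget
equations are written out inline in the generator, without calling the
budget engine, so a shared bug cannot confirm itself. On noise-free
realizations (`noise = FALSE`, transects equal to their site expectation)
the pipeline must reproduce ground truth to 1e−9 relative, and does so in
the acceptance suite.

`generate_threshold_dataset()` draws cover uniformly on (0, 60)% and
builds production as `s_h (LCC − LCC*_h) + p(LCC) − p(LCC*_h) + ε` with a
shared smooth perturbation `p(LCC) = 0.3 sin(2π LCC/60)` and slope
`s_h = 0.25`. Subtracting `p(LCC*_h)` re-anchors each habitat's curve so
its deterministic part vanishes exactly at the declared threshold while
the mean structure stays inside the additive-model family (shared smoother
plus habitat offsets); the slope bound `wiggle·2π/60 < slope` keeps the
curve strictly increasing, so the crossing is unique. An earlier
construction with a habitat-phase-shifted perturbation put the truth
outside the model family and visibly biased recovered thresholds — a
useful reminder that "recovery" tests are joint tests of generator and
model.

What passing these tests does **not** show about real data: real budgets
have taxon compositions, size structures and spatial patterns far richer
than Beta/log-normal summaries; transect tapes have unequal usable
lengths (the package averages simple per-transect percentages per site);
erosion allometries are applied outside their fitted ranges for large
fishes; and the threshold model assumes a shared smoother across habitats
with additive offsets. The recovery results bound estimation error under
the model, not model misspecification on a real reef.

## Problem sizes and runtimes

Defaults were chosen so a full check runs on a laptop core: threshold
recovery uses 288 transects per replicate with 2 chains × 1200 kept draws
across 50 seeded replicates; kriging recovery uses 200 sites per field and
11 fields; the end-to-end pipeline demo krigs 40 × 40 nodes and samples
2 × 1500 draws. All seeds flow from a single integer per run.

## Known limitations

* Chemical dissolution, microborers and storm export are outside the
  budget; the sediment term is a constant, not a model.
* The bite-rate regression's unit narrative is internally ambiguous; the
  formula is implemented exactly as printed with `reeftime_h`
  configurable.
* Habitat means can be weighted by site or by transect
  (`summarize_by_habitat()`); for unbalanced real designs the two differ
  and neither is canonical.
* Kriging assumes intrinsic stationarity after an optional geometric
  anisotropy correction; no universal kriging trend is fitted.
* With two countries the country-effect standard deviation is essentially
  prior-driven; it is reported but should not be interpreted.
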