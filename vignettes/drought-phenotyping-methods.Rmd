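---
title: "Methods: variance-component analysis of two-field drought trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance-component analysis of two-field drought trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trifield)
```

## The problem

Screening a large accession panel for drought tolerance in the field is
usually done by growing the same panel twice: once under an irrigated
control regime and once under mobile rain-out shelters that exclude
precipitation for several weeks in early summer. UAV flights provide
plot-level traits — canopy cover (CC, % of the plot polygon classified as
vegetation), canopy height (CH, the 90th percentile of per-pixel height
above soil) and, on warm clear days, the crop water stress index (CWSI)
from thermal imagery. The analytical task is to turn noisy plot
observations into per-accession genetic values per field, quantify how much
of the variation is genetic, and compare the two fields accession by
accession.

`trifield` implements this pipeline end to end and ships a synthetic trial
generator with known ground truth, so every stage can be validated by
parameter recovery rather than by eyeball.

## Experimental design

Each field is an incomplete block design: `blocks x columns x rows` plots
(the demo scale mirrors a real deployment: 3 blocks of 5 columns x 53 rows
= 795 plots holding 394 accessions twice and a control cultivar seven
times, the control filling what would otherwise be empty cells).
`build_design()` fills both fields with independent randomizations of the
identical scheme and `validate_design()` re-checks every invariant
exhaustively.

The randomization constraint is deliberately mild: the two replicates of an
accession are placed in *distinct* blocks whenever `reps <= blocks`
(disable with `distinct_blocks = FALSE`). Field practice distributes
replicates "over the blocks" without stating a rule; we chose the
distinct-block variant because it maximizes spatial separation, which is
the point of blocking, and implemented it by capacity balancing (each
accession takes the blocks with the most remaining space, ties randomized),
which provably never dead-ends when the grid fills exactly.

Maturity is classified from flowering dates (FLD, day of year; plots that
never flowered carry the ceiling code 222): an accession is *early* if it
flowered in at least one plot, *late* if it never did, *unknown* without
data. The any-plot rule is applied regardless of how few plots support it;
the evidence count is returned alongside the call.

## The synthetic trial generator

`simulate_trial()` draws, per variable, accession effects
$g_i \sim N(0, V_G)$, spatial effects for block, column (the
(block, column) pair) and row, and residual noise $V_R$. The drought field
applies a time-varying proportional reduction $\delta(t) \in [0, 1]$ with a
per-accession sensitivity multiplier $1 + s_i$, $s_i \sim N(0,
\sigma_{GxE}^2)$:

* **CH** (identity link): the positive signal is multiplied by
  $(1-\delta(t))^{1+s_i}$, so with no GxE the drought/control ratio is
  exactly $1-\delta$ and the relative performance index recovers
  $\delta(t)$ — the property the recovery tests exploit.
* **CC** (scaled logit link): effects act additively on
  $\mathrm{logit}(CC/100)$, keeping values in $[0, 100]$ and making the
  treatment effect multiplicative near the bounds, which reproduces the
  saturation of canopy cover near 100% before a cut. Because of the link,
  mean Yr for CC is an attenuated, not identical, image of $\delta$.
* **CWSI**: drought *raises* stress, so a proportional-reduction
  $\delta \in [0,1]$ cannot describe it; the generator instead adds a
  configurable upward shift (`cwsi_drought_shift`) in the drought field
  while $\delta(t) > 0$.

Early accessions receive a configurable CH boost inside flowering windows,
reproducing the bimodal height distribution of mixed-maturity panels.
Default trait baselines follow the mown-sward sawtooth: regrowth restarts
at each cut. Faults are injected at the plot-by-variable level —
`not_established` and `damaged` set the observation flag the way field
notes would, while `outlier` faults silently displace the value so the
statistical QC rule has something to find. One master seed derives named
substreams (effects, flowering, noise, faults, weather) so components can
be varied independently.

What the generator does *not* emulate: spatially autocorrelated (AR1-type)
field trends beyond the block/column/row decomposition, plant mortality and
within-plot competition, weather-driven growth mechanics, and measurement
error structure specific to photogrammetry. Passing recovery tests
therefore demonstrate correctness of the estimation machinery under the
assumed variance-component model, not robustness to every field pathology.

## Trait extraction

* `compute_canopy_cover()`: vegetation pixel fraction, errors on an empty
  polygon.
* `compute_canopy_height()`: quantile (default Q90) over vegetation pixels,
  using linear interpolation between order statistics (`quantile` type 7);
  an empty mask yields a flagged missing value.
* `compute_cwsi()`: $(T_c - T_{wet}) / (T_{dry} - T_{wet})$ with
  per-scene references. When no reference panels were measured,
  `scene_references()` uses the 1st/99th percentiles of the scene
  temperature distribution; values outside $[0,1]$ are clamped with a
  warning count. This is the canonical empirical CWSI and the only form
  consistent with reporting on a 0–1 scale.
* `compute_cwd()`: cumulative water deficit
  $\mathrm{CWD}(t) = \sum_{u \le t} (ET_0 - P_{eff} - I)$, deficit
  positive (larger = drier); effective precipitation is zeroed inside
  shelter windows. The accumulation origin is configurable (`start_doy`,
  default: start of the series).

## Quality control

Variables are named `VAR_DOY` (`CC_178` = canopy cover on day 178);
`parse_variable()` inverts the naming. `filter_observations()` drops
plot-level faults (`not_established` excludes the plot for *all*
variables), variable-local faults (`damaged`, `missing`), and statistical
outliers: values outside median ± 3·IQR within variable × field × year ×
DOY. The multiplier is deliberately conservative — genetic tails are real —
and configurable. The rule is iterated to a fixed point so that filtering
is idempotent by construction. The exclusion report gives retained counts
per variable, the bookkeeping a trial report needs.

`correlate_ground_uav()` pairs each rising-plate-meter date with the
nearest UAV date within 7 days (ties toward the earlier UAV date — the
field protocol gives no rule, so we fixed one) and reports Pearson r per
pair over common plots; pairs with fewer than 3 plots are undefined rather
than misleading.

## Variance components, BLUPs, heritability

For each `VAR_DOY` variable and each field separately, six
intercept-plus-random-effects structures are fitted by REML:

    {A}, {A,Block}, {A,Column}, {A,Row}, {A,Block,Row}, {A,Column,Row}

Accession (A) is always present; Block and Column never co-occur because
columns are nested in blocks and the full model would be overparameterized.
Column is coded as the (block, column) pair; Row by its index across
blocks, i.e. a positional effect. Fitting uses `lme4::lmer` — the standard
tool for exactly this model class — with optimizer tolerances tightened to
1e-10 so estimates agree with closed forms to ~1e-7; the package's own
tests verify the fits against the balanced one-way ANOVA identity and an
independent dense grid search of the restricted likelihood surface.

Candidates are compared by `AIC = -2\,\log L_{REML} + 2k` with k =
intercept + all variance components (residual included, also at a boundary
estimate of 0 — the simplest consistent convention). Comparing REML fits by
AIC is valid here because every candidate shares the identical
intercept-only fixed part; whether the original field analyses used
restricted or ordinary likelihood for the comparison is not documented, so
the restricted choice is ours. Exact ties break toward fewer components.

From the selected fit: per-accession values are
$\mathrm{BLUP}_i = \hat\mu + \hat u_i$, and broad-sense heritability is
$H^2 = V_G / (V_G + V_R)$ — spatial components are excluded from the
denominator because they are design nuisance, not phenotype. FLD can be fit
like any variable, but note its 222 ceiling code is then treated as
numeric; interpret such fits accordingly.

## Drought response and ranking

The relative performance index per accession and variable is
$Y_r = (C - D) / C$ with $C$, $D$ the accession's control- and
drought-field values. We use BLUPs as inputs (raw plot means are available
for diagnostics); whether the original analysis used BLUPs or means is
unstated, and BLUPs are the natural choice given the pipeline computes
them. $Y_r > 0$ means growth was reduced by drought; no clamping is applied
(strongly negative values are informative), but control values below 1% of
the median absolute control BLUP yield a missing $Y_r$ rather than an
explosive ratio. Two-sided Z-tests (`z = mean/(sd/sqrt(n))`, sample sd —
the large-n normal approximation over hundreds of accessions) test whether
the panel-mean $Y_r$ differs from zero per variable and date, starred at
p < 0.05 / 0.01 / 0.001. `yr_trajectory()` lays the results out one row per
(year, variable, DOY) with drought-window annotation.

For multivariate structure, `reduce_variables()` keeps one mid-period and
one end-of-period observation per growing period (list mode) or prunes by
a correlation threshold; `run_pca()` standardizes by default (the variables
mix %, cm and unitless indices) and drops incomplete rows with a count.
`top_quartile_counts()` counts, per accession, the variables where it
reaches the 75th percentile (linear interpolation, boundary ties included —
consistent with the tie-inclusive top-set rule); `select_top_set()` returns
the nominal-size top set enlarged by ties; `overlap_sets()` reports the
control/drought/both counts — the schema of a between-field consistency
table.

## Numerical and design choices in brief

* Quantile convention everywhere: type 7 (linear interpolation).
* Drought window duration: `end_doy - start_doy` (start day excluded,
  end day included), matching the printed 50- and 69-day seasons of the
  demo timeline.
* Boundary variance estimates are reported as 0 with a flag; AIC still
  counts the parameter.
* Degenerate inputs error loudly (capacity mismatch names required vs
  available plots; a single-level factor names itself) or return flagged
  missing values (empty vegetation mask, sd = 0 Z-test).
* The two seasons are analyzed as independent pipeline invocations sharing
  a design; sward age and stress intensity differ between years, so pooling
  them as replicates would be wrong, and no pooled-year model is offered.

## Validation scale

The test suite and the acceptance script size their simulations for a
single CPU: parameter recovery uses 200 accessions × 2 replicates over 20
seeds per setting (heritability recovered within ±0.01–0.03 of truth in
practice, asserted at ±0.08), Yr recovery uses the same panel with a
stepped drought effect (recovered within ~0.002, asserted at ±0.03),
Z-test calibration uses 10,000 null panels of n = 395, and the ranking null
uses 10,000 draws of independent top-50-of-395 sets (expected overlap
50²/395 ≈ 6.33). The demo pipeline (`run_pipeline(default_config())`) runs
a 60-accession, 3-block trial in a few seconds.

## Known limitations

* No spatial correlation structures (AR1 rows/columns), fixed covariates,
  or multi-trait models; no standard errors on H².
* The outlier rule is distributional, not image-based; a plot that is
  wrong for a physical reason the flags don't capture will only be caught
  if it is numerically extreme.
* CWSI references from scene percentiles are a stand-in for measured
  wet/dry panels; absolute CWSI levels depend on that choice even though
  ranking within a scene is stable.
* The generator's CC link makes CC-based Yr an attenuated image of the
  generating effect; quantitative recovery statements are made on CH.
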