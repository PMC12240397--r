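---
title: "Estimating undescribed species richness from discovery curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating undescribed species richness from discovery curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linnean)
library(dplyr)
```

## The estimation problem

A taxonomic catalogue grows by accumulation: each decade taxonomists
describe some of the species that remain unnamed, and as the undescribed
pool shrinks the cumulative count of described species should level off
toward an asymptote — the total (described + undescribed) richness. If the
curve is genuinely approaching that asymptote, the distance still to go is
an estimate of the Linnean shortfall. `linnean` implements this program for
a stratified flora: per phytogeographic domain, per large family, per
habit.

Two datasets are derived from the raw name table and deliberately kept
apart:

* **basionyms** — one earliest name per currently accepted species. This is
  the series that tracks genuine additions to the inventory, and the one
  the richness estimates are based on.
* **all names** — every accepted name, synonym and infraspecific name with
  its publication year. It measures total nomenclatural activity
  (including lumping, splitting and transfers) and always dominates the
  basionym curve pointwise.

Because the name a species is currently known by may be much younger than
its first description, the basionym year is resolved per species across
three nomenclatural sources by majority rule: if at least two sources
agree on the basionym year that year is used. When all three disagree we
take the **earliest** voted year and flag the row `conflict` — a basionym
is by definition the earliest validly published name, and flagged rows are
reported separately so the opposite convention can be audited. This
tie-break is our choice; the sources we model do not dictate one.

Years are resolved in a fixed order — the primary publication-year field,
then the reference-derived fallback field, then flagged missing — and the
analysis window is 1753–2020: the start of binomial nomenclature, with
recent years truncated at 2020 because names take several years to reach
the aggregating databases (right-censoring of the last decade would
otherwise masquerade as a slowdown).

## Decade series and the regression abscissa

Counts are binned into calendar decades 1751–1760, …, 2011–2020 (the first
bin absorbs 1753–1760), 27 bins in all. The nonlinear fits use the integer
decade index `t = 1..27` as abscissa rather than the calendar year: the
curves are translation-invariant in `t`, and a ~1800-unit abscissa offset
makes the `c` (inflection-location) parameter poorly conditioned for no
statistical benefit. The `decade_start` column keeps the calendar
correspondence.

## Growth models and information criteria

Four asymptotic curves are fitted by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`): Gompertz 3P, Gompertz 4P (a baseline-offset `d`
added to the 3P form, so `a` is still the asymptote), Logistic 3P, and
Weibull growth. The "3P/4P" parameterizations are the common
statistical-software forms, chosen so coefficients are directly
interpretable; the fourth Gompertz parameter is an ordinate offset, not an
abscissa shift (both conventions exist; the offset form keeps `a` the
asymptote under every model, which the averaging step relies on).

Initialization matters more than the optimizer here. Each fit multi-starts
from an asymptote grid `{1.05, 1.2, 1.5, 2, 4} × max(C)` with the shape
parameters linearized from the data at each candidate asymptote (e.g.
`−log(−log(C/a₀))` is regressed on `t` for the Gompertz forms).
Non-convergence is captured, never raised: a model that fails reports NA
asymptote and criteria (the blank cells of a summary table) and gets
Akaike weight 0.

Model support uses the Gaussian-error criteria `AIC = n·ln(RSS/n) + 2k`,
`AICc = AIC + 2k(k+1)/(n−k−1)` and `BIC`, with `k` = curve parameters + 1
for the residual variance. The weighting criterion defaults to **AICc**
(at n = 27 and k = 4–5 the small-sample correction is material) but AIC
and BIC are selectable. An exactly perfect fit (RSS = 0) is given a −∞
criterion — the limit of the Gaussian formula — and wins any weighting;
ties split the weight evenly.

Model averaging combines the converged fits: `θ̄ = Σ wᵢaᵢ` with the
unconditional standard error `se_u = √(Σ wᵢ(seᵢ² + (aᵢ − θ̄)²))`, which
charges both within-model variance and between-model disagreement to the
interval. When a converged fit has a singular covariance (no SE), its
`seᵢ²` term is replaced by the **largest** available `seᵢ²` among
positive-weight fits: dropping the term would understate uncertainty, and
a conservative inflation is the safer default. Completeness is
`100·S_obs/(S_obs + remaining)`; per-stratum estimates aggregate into exact
sums and a "media" column, the midpoint of the averaged remaining estimate
and its upper 95% bound. Negative remaining estimates (a fitted asymptote
below the observed count — a fit pathology on saturated series) are
reported and flagged, not clipped.

By default only the four growth models enter the average. The
taxonomic-effort estimate can be pooled as a fifth candidate
(`averaging_candidates = "growth+effort"`, its weight from its own AIC);
we left pooling off by default because the effort model's AIC is computed
on per-decade counts rather than the cumulative series, and mixing
likelihood scales inside one weight vector deserves an explicit opt-in.

## The taxonomic-effort model

Description is modelled as an encounter process between the workforce and
the undescribed pool:

`D̂ᵢ = (a_e + b_e·sᵢ) · Tᵢ · (N_T − Cᵢ₋₁)`,  `C₀ = 0`,

with `Tᵢ` the number of distinct describing authors in decade `i`
(tokenized from authorship strings: split on `&`, `,`, ` et `; the
pre-`ex` author is discarded per standard botanical citation semantics;
tokens case-folded and stripped of periods and whitespace), and `sᵢ` the
decade index rescaled to [0, 1] so that the efficiency drift `b_e` is
numerically decoupled from the intercept `a_e`. With `b_e = 0` and
constant effort the trajectory is the closed-form monomolecular curve
`Cᵢ = N_T(1 − (1 − a_e·T)^i)`, which the tests use as an exact oracle.
Note the intrinsic scale non-identifiability: doubling `Tᵢ` while halving
`a_e` changes nothing — only the product is identified, which is fine
because `N_T` (the quantity of interest) is identified by the curvature.

The objective is ordinary least squares on per-decade counts (a Poisson
deviance option exists behind `objective = "poisson"`), so the reported
AIC/BIC are on the same Gaussian footing as the growth models. For fixed
`N_T` the efficiency parameters enter linearly and are profiled out
exactly; `N_T` is then a 1-D search, run twice — a `coarse` tier around
the grid `{1.05, 1.2, 1.5, 2, 4} × C_final` and a `dense` tier scanning
200 points across the admissible range — with **both** tiers reported.
Reporting two rows mirrors the practice of publishing the best-supported
parameterizations side by side and documents multi-start sensitivity
instead of hiding it.

## Predictor regressions

Five trendline families (linear, logarithmic, exponential, power,
quadratic) relate described-species numbers to human population density
and taxonomist counts. "Potential"-type power laws and exponentials are
fitted on the log scale, and r² is reported **on the fitting scale** —
the spreadsheet-trendline convention these comparisons are usually made
with — with a back-transformed r² kept as a diagnostic column. A constant
response defines r² := 0. Two windows are analysed: the cumulative series
over the whole 1753–2020 window (27 points) and per-decade counts for the
six decades covering 1960–2020, which highlight recent dynamics. The
per-domain density series feeds the regressions; a per-species
within-range density can be supplied as an input column where available.

## Spatial priority mapping

Occurrences are counted into non-overlapping rectangular cells with a
half-open `[min, max)` convention on both axes (a point on a shared edge
belongs to exactly one cell). Supported resolutions are 0.1°, 0.5°, 1°,
2°, and `"geohash156"` — 1.40625° cells anchored to the global geohash
lattice, ≈156 km at the equator. Per-cell completeness uses a Chao-type
incidence estimator, `S_est = S_obs + f1²/(2f2)` (bias-corrected
`S_obs + f1(f1−1)/2` when `f2 = 0`), computed from how many species are
seen once/twice in the cell; cells with fewer than `min_records = 5`
records report missing completeness — below that the estimator is noise.
The estimator is isolated in one function (`cell_completeness()`) so a
different completeness definition can be substituted without touching the
rest of the stage.

Priority combines the two deficits with equal weights (configurable):
`priority = round_half_up(10 · mean(1 − density_class/10, 1 − completeness/100))`,
with missing completeness treated as a full deficit — an unsurveyed cell
is maximally attractive for collecting. The score is monotone (lower
density class or lower completeness never lowers it), bounded in [0, 10],
and scale-free in total collecting intensity because density enters
through decile classes only. Quantile classes are rank-based with ties
assigned to the lower class. Overlap statistics take the top `n_top = 30`
cells (ties broken toward lower completeness, then fewer records, then
cell id, so the set is deterministic) and call a cell overlapping iff its
rectangle has a positive-area intersection with at least one polygon of
the layer — computed by Sutherland–Hodgman clipping plus the shoelace
formula, so edge-touching polygons do not count and duplicated polygons
change nothing.

## The synthetic generator: what it emulates, what it does not

The generator is the package's ground-truth instrument. Description years
are drawn by inverse-CDF sampling of the configured growth curve, so the
generated cumulative curve has exactly the asymptotic shape the fitters
assume, right-censored at 2020; a species' `u ~ U(0,1)` above the curve's
2020 saturation simply remains undiscovered. Under the `effort_driven`
shape, each decade describes a Binomial(pool, a·Tᵢ) draw instead — zero
effort forces zero descriptions. Synonyms arrive Poisson per species with
years uniform between the basionym year and 2020 (no synonym-age model is
assumed); three per-source basionym-year columns agree except with the
configured discordance probability; authorship strings are assembled from
a per-decade active author pool with round-robin coverage, so
authorship-derived taxonomist counts recover the schedule whenever a
decade has at least as many names as authors. The toy landscape places one
rectangular domain band per stratum, protected-area and Indigenous-land
rectangles covering the configured area fractions exactly, clustered
species home ranges, and a latent point set per species from which the
observed records are subsampled.

Defaults (chosen once as plausible study conditions): 27 decades
(1753–2020), Gompertz shape `b = 0.35, c = 8` on the decade index (≈99%
saturated by 2020, matching the near-asymptote premise), N* = 500 species
per stratum, synonym rate 0.5, discordance rate 5%, 5% missing primary
years, an exponentially growing author schedule, monotone density series,
5,000 occurrence points on a 10°×10° landscape with 20% PA and 30% TI
coverage. What the generator does **not** emulate: real spatial
biogeography, database-specific field quirks beyond the two year fields,
author-identity ambiguity (initials collisions), or taxonomic churn
(resynonymization changing past counts). Passing tests therefore show the
estimators are correct *when the world follows the model*; they cannot
show that a real flora's curve is near its asymptote — that assumption
must be argued from the data, not from this package.

## Numerical choices and degenerate inputs

* Multi-start grids for both fitters are fixed (no randomness inside the
  optimizers); all stochastic components draw from one seed threaded
  explicitly through the configuration.
* Perfect fits: criteria −∞, weight 1 (split if several).
* Constant cumulative series: the Weibull/Gompertz fits either converge to
  a degenerate near-constant curve or are flagged non-converged; both are
  legal outcomes and neither raises.
* All-equal quantile inputs put every cell in class 1; priority rounding
  is half-up (9.5 → 10) rather than banker's rounding.
* Aggregation totals are exact sums; rounding happens only in printed
  reports.

## Problem sizes used in validation

The test-suite simulations use N* in the hundreds, 27-decade windows, and
10–200 replicates per property; the acceptance script runs 200 replicates
per growth model (1% noise), 100 for the effort model (2% multiplicative
per-decade noise, a pool of 800 described to ~600), and an end-to-end run
with 2 strata × 300 species and 5,000 occurrence points. These sizes make
every property measurable with comfortable margins while keeping a full
validation run in minutes on one core.

## Known limitations

* The effort model's functional form is one defensible reading of
  effort-based discovery models; it lives behind a single function so a
  different efficiency term can be swapped in.
* The unconditional-SE interval assumes the candidate set contains a
  well-specified model; all-misspecified candidate sets give intervals
  that are too narrow.
* Completeness per cell inherits Chao-estimator bias under strong
  detection heterogeneity.
* Domain strata overlap (a species in k domains counts in all k), so
  per-domain remaining-species estimates do not sum to a deduplicated
  national total; the aggregate report documents, not removes, this.
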