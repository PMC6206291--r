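---
title: "Predicting lime tolerance from occurrence records: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lime tolerance from occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciphile)
```

## The problem and the model

Calcifuge plants — rhododendrons are the textbook case — fail on lime
(calcareous, high-pH) soils, where iron and other micronutrients become
unavailable. Direct tolerance screening of hundreds of taxa is infeasible,
but herbarium collections record where each taxon actually grows. If the
locations are georeferenced and joined to a gridded soil database, each
taxon acquires a sample of the topsoil pH and CaCO₃ values it occurs on —
its *realized soil niche* — and the upper tail of that sample indicates how
far toward alkaline, carbonate-rich conditions the taxon extends.

The decision rule operates on per-taxon quartiles of topsoil values: a
taxon with at least `min_n = 10` specimens is predicted lime tolerant iff
the upper quartile of its specimens' topsoil pH exceeds 7.2 **and** the
upper quartile of topsoil CaCO₃ exceeds 2 % weight, strictly. The upper
quartile, rather than the median, is deliberate: tolerance is about the
extreme conditions a taxon persists in, not its typical site; requiring a
full quarter of records beyond the threshold also buffers against isolated
geocoding errors. The pH 7.2 / CaCO₃ 2 % cut-offs are the soil-database
class boundaries above which soils are carbonate rich.

Validation is a 2×2 contingency test: each specimen's topsoil is lime
(pH > 7.2 ∧ CaCO₃ > 2), non-lime (pH ≤ 7.2 ∧ CaCO₃ ≤ 2), or *mixed*
(neither conjunction — counted and excluded, since the two definitions are
not complementary), cross-tabulated against its taxon's predicted label and
tested with the Yates-corrected Pearson chi-square, df = 1.

### Assumptions

* Occurrence implies tolerance of the local topsoil; absence is
  uninformative (collection effort is uneven).
* The cell-level soil attribute (one record per mapping unit, ~1 km cells)
  represents the specimen's microsite. This is the coarsest assumption:
  shallow-rooted plants can exploit acidic pockets within calcareous
  cells.
* Specimens are treated as independent draws from the taxon's niche;
  within-taxon spatial clustering of collectors is not modelled.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ph_threshold` | 7.2 | pH (−log[H⁺], soil-water) | lower edge of the carbonate-rich class (7.2–8.5) |
| `caco3_threshold` | 2 | % weight | lower edge of the first calcareous class (2–5) |
| `min_n` | 10 | specimens | below this the UQ of a sample is dominated by single records |
| `quantile_type` | 7 | — | linear interpolation between order statistics, p(k) = (k−1)/(n−1); printed quartiles in reference tables are consistent with it but cannot uniquely pin the rule, so it is configurable |
| `correction` | `TRUE` | — | Yates continuity correction; the default 2×2 behaviour of the statistical environment this analysis idiom comes from |
| `bandwidth` (density) | user-set | decimal degrees | no defensible default exists; the quartic kernel needs a scale chosen per map |

Strictness at the thresholds is part of the rule: a UQ of exactly 7.2 or
exactly 2.0 is *not* tolerant.

## What the synthetic generator emulates

`generate_landscape()` builds the stand-in for a harmonized soil raster:

* **Mapping-unit structure.** `n_units` (default ≤ 936) units, each with
  exactly one attribute record; the grid is a Voronoi tessellation of
  random unit seeds, so units are contiguous patches as in the real
  polygon-derived raster. This matters: with independently drawn cells, a
  sub-kilometre geocoding displacement would land a specimen on a
  statistically unrelated pH value, which is not how soil maps behave.
* **Multimodal pH.** Topsoil pH is drawn per unit from a four-component
  Gaussian mixture with modes 4.8, 5.7, 6.5 and 8.0 and weights
  proportional to the observed hump heights (6.7 : 7.9 : 12.5 : 11),
  rounded to 0.1 pH. Component sd defaults to 0.1 because the emulated
  database's attribute values are strongly discretized (a handful of
  values carry most of the mass).
* **CaCO₃ coupled to pH.** Deterministic-in-distribution rule: 0 below pH
  6.5; above, 2–5 % with probability 0.4 and 5–15 % with probability 0.6
  (uniform within the range). The coupling is what makes the two-condition
  UQ rule recoverable; the reference data show the joint structure but no
  generative model, so a piecewise rule is the simplest faithful choice.
* **Cleaning structure.** Fractions of units get excluded surface symbols
  (`WR`/`RK`/`GG`/`UR`; default 0.013) or missing subsoil attributes
  (default 0.103) — the removal proportions of the reference cleaning run.
  Excluded cells still carry attributes; exclusion happens at cleaning,
  as in the real database.
* **Taxa and specimens.** Tolerant taxa centre near pH 8, non-tolerant
  near pH 5 (sd 0.5); specimens pick cells with probability ∝ a Gaussian
  kernel of cell pH around the niche centre, then scatter uniformly within
  the cell. Placement uses the cell-level environment on purpose,
  mirroring the cell-level lookup of the analysis.
* **Geocoding noise.** Each specimen's location text maps to one gazetteer
  label displaced by a half-normal distance (mean `noise_km`, uniform
  bearing). Decoy labels can be added; labels are never shared between
  specimens, because the displacement contract is per specimen.

What it does **not** emulate: collection bias, spatial autocorrelation of
collectors, taxonomic misidentification, climate covariates, and the fuzzy
"best match" behaviour of commercial geocoders (matching here is exact by
label). A green recovery test therefore establishes that the pipeline's
arithmetic and the quartile rule work on well-separated niches under
map-consistent noise — not that the rule is robust to biased sampling or to
tens-of-kilometres geocoding error on a fine-grained landscape.

## Numerical choices

* **Quantiles**: `stats::quantile(type = 7)`, checked in the tests against
  an independently coded order-statistic interpolation.
* **Chi-square**: hand-implemented Pearson statistic with the correction
  `Σ (max(0, |O−E|−0.5))²/E`; a zero margin raises an error rather than
  returning `NaN`. p-values below 2.2×10⁻¹⁶ display as `"< 2.2e-16"`
  while the numeric value is kept.
* **Vincenty inverse**: the standard iterative solution on WGS84;
  non-convergence (nearly antipodal pairs) raises an explicit error —
  reproducibility over coverage at regional scale. Oracles: the exact
  equatorial arc `a·λ`, a numerically integrated meridian arc, and a
  spherical bound (< 0.6 % under 1000 km).
* **Grid cells** are half-open; a point on an interior boundary belongs to
  the higher-index cell, so cell assignment is a total partition. Indices
  are 1-based as idiomatic in R.
* **Class bins** are lower-inclusive (pH 4.5 → "4.5–5.5", CaCO₃ 2.0 →
  "2–5"); the printed touching ranges do not state a side, so one
  convention is fixed, documented, and kept away from acceptance checks.
* **Cleaning order** is first-match: out-of-region, then excluded surface,
  then missing subsoil — making the ledger well defined for records that
  violate several rules.
* **Seeds**: every generator takes an explicit seed; the pipeline derives
  per-stage seeds from one top-level seed by fixed offsets (kept below
  2³¹).

## Open design points, as decided here

* Specimens of taxa below `min_n` enter the contingency table in the
  non-tolerant row by default (`below_min_n = "exclude"` is available);
  published marginals do not pin the treatment down, so both are exposed.
* The geocoding accuracy summary stores the standard error (sd/√n): for a
  long-tailed displacement distribution the reported mean ± value is far
  above the quartiles, which is consistent with a standard error, not an
  sd.
* The parameter-recovery check links specimens at their true coordinates:
  the scenario it encodes specifies niche separation, not geocoder error.
  The pipeline default (`noise_km = 0.5`) exercises the geocoder
  separately.

## Known limitations

* Exact-label geocoding only; no address parsing or fuzzy matching.
* Planar-degree kernel density (circular in degrees, so anisotropic in
  kilometres away from the equator) — adequate for regional heat maps,
  not for metric density values.
* One attribute record per mapping unit means within-unit soil
  heterogeneity is invisible, exactly as in the emulated database.
* The quartile rule's output is a *candidate list*: a taxon can appear
  lime tolerant because its range happens to overlap mis-mapped or
  heterogeneous units, and field validation remains the arbiter.
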