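---
title: "Methods: an integrated climate-vulnerability assessment for wine regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated climate-vulnerability assessment for wine regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitivuln)
```

## The assessment framework

`vitivuln` implements an IPCC-style vulnerability assessment for winegrowing
regions (geographical indications, GIs): vulnerability is the combination of

* **exposure (E)** — how strongly the region's viticultural climate is
  projected to change,
* **sensitivity (S)** — how close the region's current climate already sits
  to the upper tolerance of the grape varieties it is built around, and
* **adaptive capacity (AC)** — the socioeconomic and biophysical resources
  available to adapt.

All three are relative scores in [0, 1] across the region set under study;
the assessment is comparative by design and says nothing absolute about any
single region.

## Bioclimatic indices

The climate substrate is a monthly climatology (12 values per cell per
variable) of minimum / mean / maximum temperature and precipitation. Three
indices summarize a cell's viticultural climate:

* **Huglin heliothermal index (HI, °C·days)**. We use a monthly
  approximation of the daily definition:
  `HI = Σ_{Apr..Sep} max(0, ((tas − 10) + (tasmax − 10))/2) · N · K(lat)`,
  with `N` the days in the month and `K` the stepwise day-length
  coefficient (1.00 below 40° N rising to 1.06 at 48–60° N; latitudes at or
  above 60° N are outside the published table and raise an error). The
  month-level `max(0, ·)` clamp is the default; an unclamped variant is
  exposed because the daily definition never sums negative days, and the
  monthly approximation must choose.
* **Cool Night Index (CNI, °C)**: the September mean minimum temperature,
  exactly.
* **Dryness Index (DI, mm)**: a Riou-style potential soil-water balance
  over April–September. The reserve starts full (`Wo = 200` mm); each month
  removes vine transpiration `Tv = k·PET` (k = 0.1, 0.3, then 0.5 for
  June–September) and bare-soil evaporation `Es = (PET/N)(1−k)·JPm` with
  `JPm = min(N, pr/5)` effective evaporation days, adds precipitation, and
  caps the reserve at `Wo`. The reserve is deliberately *not* floored at
  zero: negative end-of-season values express a strong potential deficit,
  and the only hard invariant is `DI ≤ Wo`. All constants sit in
  `di_params()` and are configurable.

PET is estimated with the temperature-only Hargreaves formula
(`0.0023 · Ra · (tas + 17.8) · √(tasmax − tasmin)`, Ra from the FAO-56
extraterrestrial-radiation formulas for the 15th of each month) because the
input contract carries no humidity or wind; a user-supplied PET matrix
overrides it in `bioclim_grid()`.

Cell indices are aggregated to regions by weighted means over member cells
(`regional_bioclim()`); whole-cell membership is the generator's default
but fractional weights are honoured throughout.

## Exposure

Per region, the change of each index between the present and the future
period is taken in its *adverse* direction: `ΔHI = HI_fut − HI_pres`,
`ΔCNI = CNI_fut − CNI_pres`, and `ΔDI = DI_pres − DI_fut`, so that drying
scores positive. Signed deltas are the default — a region that gets wetter
should score low on the water axis, not high; an absolute-value mode is a
config switch because the choice is not dictated by the framework itself.
Each delta column is min-max scaled across regions (a degenerate column,
all regions equal, maps to all zeros: no differential change means no
differential exposure), and E is the mean of the three scaled components.
Aggregation happens cell → region mean → scale, in that order.

A model-agreement diagnostic (`ensemble_spread()`) reports the per-cell
range and SD across pseudo-GCM ensemble members for temperature and
precipitation.

## Sensitivity and the bioregional climate range

The *bioregional climate range* of a variety summarizes where it has
historically been grown. Regions are first binned into combined climate
groups by HI, CNI and DI class edges (defaults follow the Géoviticulture
multicriteria classes: HI at 1500/1800/2100/2400/3000, CNI at 12/14/18, DI
at −100/50/150; right-closed bins). The group inventory is the set of
observed class triples — a reconstruction, since the exact historical group
table is not part of the input contract. Within each (variety, group), the
cultivation-area-weighted mean and frequency-weighted SD of each index are
computed across cultivating regions; the upper range limit is
`mean + m·SD` with `m = 1` by default (the multiplier is a config key
because range width is a modelling choice).

Before any of this, cultivation records are canonicalized through
country-scoped synonym lists in two tiers (primary list first, then the
secondary list); unmatched names are kept verbatim, flagged, and carry zero
cultivation area downstream — they are counted, never silently dropped.
Macro-region cultivation rows are split among authorizing member regions
proportionally to vineyard area, conserving the macro total exactly.
Regions with an explicit primary/additional split keep it; regions without
one have all authorized varieties promoted to primary.

Regional sensitivity compares the region's current climate with the upper
limits of its primary varieties' ranges. The margin
`upper_limit − current value` is computed per (region, variety, index),
z-scored per index across all pairs so that °C·days, °C and mm are
commensurable, averaged over the three indices, negated (a small or
negative margin means high sensitivity), averaged over the region's primary
varieties weighted by cultivation area, and min-max scaled across regions.
The z-score chain is the default standardization; min-max and raw-unit
strategies are selectable because the functional form of the
margin-to-sensitivity relation is qualitative in the framework, not unique.

## Positive effects

A variety in a region can also *benefit* from change. The group-wise
weighted mean serves as the variety's reference; the variety benefits if
its mean absolute standardized deviation from the reference (per-index
deviations divided by the cross-region SD of present values, then averaged)
is strictly smaller under the future than under the present climate. Ties
count as not benefiting. The regional positive-effect share is the
area-weighted (default; plain count optional) fraction of benefiting
primary varieties. Computed over a ladder of increasingly severe scenarios,
the mean share declines — the package's scenario ladder (half, full, and
one-and-a-half times the configured warming and drying, labelled
ssp126/ssp370/ssp585) exists precisely to make that qualitative behaviour
testable. A per-index majority-vote rule is available as an alternative
benefit criterion.

## Adaptive capacity

Fifteen indicators across five dimensions (social, physical, natural,
human, financial) enter the composite. Each column is scaled as
`AC_i = (X − Q5)/(Q95 − Q5)`, with the 5th/95th percentiles (linear
interpolation between order statistics — stated because percentile
conventions differ) as winsorizing thresholds, clamped to [0, 1];
lower-is-better columns are inverted. The directionality of each indicator
is not part of the input contract and ships as an editable default:
aging index, dependency ratio, population density, research accessibility
(a distance), debt ratio and subsidy dependence count against capacity, the
rest for it. The overall AC is the equal-weighted mean of the scaled
indicators — the most neutral choice when region-specific weights cannot be
defended — followed by a cross-region min-max rescale. Dimension means are
reported for profiling only; they never enter the composite.

As an alternative weighting mode, expert pairwise-comparison matrices are
reduced to weights by the analytic hierarchy process: the principal
eigenvector via power iteration (tolerance 1e-10), the consistency ratio
`CR = ((λmax − n)/(n − 1))/RI(n)` with the Saaty random-index table through
n = 15, and a strict `CR < 0.10` acceptance gate. Rank concordance between
expert weight vectors (`weight_concordance()`) quantifies how transferable
any single weight set would be.

## Vulnerability classification

Each of E, S and AC is cut into tertiles at its 33rd and 66th percentiles
(ties resolve downward, matching the right-closed binning used elsewhere;
if all scores are equal every region is `low`). The level rules, checked in
order:

1. high E, high S, low AC → **very high**;
2. exactly two adverse conditions → **high**;
3. at least two favorable conditions (low E, low S, high AC) → **low**;
4. otherwise **moderate**.

The six groups refine the levels: group 6 = very high; within the high
level the adverse pair decides (E+S → 3, E+AC → 4, S+AC → 5); moderate = 2,
low = 1. The precedence (very-high before high, low before moderate)
resolves the overlap a prose rule set leaves implicit; the 27-triple truth
table is exhaustively tested, forms a partition, and worsening any single
class never lowers the level.

## The synthetic study system

The generator (`synth_config()`, `generate_climate()` and friends) emulates
every input with known ground truth:

* smooth monthly climate fields with a north–south temperature gradient, a
  pseudo-terrain anomaly, and seeded cell noise; the future period is an
  exact transform of the present (additive warming field, multiplicative
  drying) so that warming monotonicity of the indices is structural, with
  optional extra future noise (`future_noise_sd`, default 0);
* pseudo-GCM members built as scenario-plus-zero-sum perturbations, so the
  ensemble mean equals the scenario field exactly;
* contiguous region blobs grown from seeded cells, with coarse country
  blocks and within-country macro units;
* varieties whose true optimum is the present-day climate of an anchor
  region, with cultivation area placed by a Gaussian kernel in standardized
  index distance (bandwidth 0.7 z-units) — chosen because it makes the
  area-weighted range mean a consistent estimator of the optimum, the
  premise of the recovery tests;
* synonym aliasing at a configurable rate with a small orphan fraction that
  stays unmatched (each region's largest-area variety is protected from
  orphaning so the sensitivity stage always has at least one ranged primary
  per region);
* an equicorrelated 15-indicator table and near-consistent expert AHP
  matrices built from known weight vectors.

Default study conditions: a 40 × 50 grid spanning 36–52° N, 60 regions
(200 in the recovery analyses), 24–30 varieties, +3 °C mean warming and a
15% precipitation reduction for the central scenario, field noise 0.5 °C
(0.1 °C in recovery runs), synonym rate 0.2 with 10% orphans, 30%
macro-level rows. These sizes keep a full run in seconds while leaving
every mechanism (groups, macro splits, aliasing loss, tertile diversity)
active. What the generator does *not* emulate: real geography and
elevation, realistic national statistics, variety phenology, partial-cell
region coverage (memberships are whole-cell, though the aggregation layer
accepts fractional weights). Passing tests therefore demonstrate the
correctness and internal consistency of the method, not the reproduction
of any real-world result.

## Numerical choices and edge cases

* Degenerate min-max and percentile scales map to 0 (warned, counted).
* Weighted SDs are population-style (total-weight denominator): one
  cultivating region gives SD 0 and an upper limit equal to the mean.
* Values exactly on a class edge or tertile cut fall in the lower bin,
  everywhere.
* The water balance is capped at `Wo` but not floored.
* All randomness flows from one integer seed through per-stage derived
  seeds; the caller's RNG state is saved and restored, and reruns are
  byte-identical (hash-checked in the tests).

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_regions = 60, seed = 1)
res <- run_pipeline(cfg, out_dir = "vitivuln-out")
table(res$profiles$level)
head(res$profiles)
```

## Known limitations

The sensitivity functional form, indicator directions, climate-group
edges and group-3/4/5 partition are documented reconstructions with
switches, not uniquely determined rules; the assessment is relative to the
region set, so adding or removing regions changes every score; the
Hargreaves PET is a coarse stand-in where measured PET exists; and a single
future period per scenario is generated (additional periods are simply
additional scenario keys to `positive_effect_share()`).
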