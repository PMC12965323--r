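---
title: "Multiple-cropping expansion potential under irrigation water constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-cropping expansion potential under irrigation water constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(multicropr)
```

## The problem

Multiple cropping — several harvests per year on the same field — is how a
large share of tropical and subtropical agriculture raises land
productivity without clearing new land. Whether a second (or third) crop
cycle is feasible at a given location depends on year-round growing
conditions, and in seasonally dry climates on whether irrigation can bridge
the dry months. Global crop models, however, typically simulate a single
prescribed growing season per crop. This package implements a
post-processing pipeline that turns single-season crop-model output into an
estimate of the multiple-cropping production potential on existing
cropland, explicitly accounting for where irrigation enables the extra
season and whether local rivers can actually supply the required water.

The pipeline runs on gridded inputs of the kind a global vegetation–crop–
hydrology model produces: monthly grass gross primary productivity (GPP)
and evapotranspiration under rainfed and irrigated conditions, main-season
crop yields and evapotranspiration components, physical and harvested crop
areas split by water regime, irrigation-system shares, runoff on a river
network, and non-agricultural water demand. Because those data products are
large and external, the package also ships a synthetic-world generator
(`generate_world()`) that reproduces their statistical structure, so every
stage is exercised end to end by code and tests alone.

## Suitability from monthly grass GPP

Grass grows year-round in the model world and therefore integrates
temperature, radiation and water limitation in every month, which makes
monthly grass GPP a parsimonious indicator of season quality. A month is a
growing-period month when grass GPP strictly exceeds
`gpp_threshold = 100` g C m⁻² month⁻¹ — roughly
`gpp_threshold_in_dm(100, 0.45)` = `r round(gpp_threshold_in_dm(100), 2)`
t DM ha⁻¹ at a carbon fraction of 0.45 g C per g dry matter. A cell is
suitable for multiple cropping under a regime when at least
`min_growing_months = 9` months qualify. Irrigated suitability uses grass
GPP simulated with unlimited irrigation water; actual water limits enter
only later, through the allocation stage.

Two reading choices are deliberate. *Strict* inequality at the threshold:
a month at exactly 100 g C m⁻² does not count (a measure-zero event on
real data, but tests pin it down). And the nine months need not be
consecutive — the rule counts months, not runs. A consecutive-run variant
exists (`consecutive_months = TRUE` in the configuration, counting the
longest run with December wrapping into January) but is off by default.

## Off-season yields

For each crop, regime and cell, the off-season-to-main-season ratio of
grass GPP sums (`offseason_ratio()`) scales the explicitly simulated
main-season yield to an off-season yield estimate. Sums rather than means
are used: the ratio should represent the *total* productivity available
outside the main season, so a long mediocre off-season can rival a short
excellent one. The estimate is reduced by the dampening factor
`offseason_dampening = 0.25`, standing in for turnaround time between
harvest and sowing and related penalties; the same factor dampens
off-season irrigation water use, keeping yield and water accounting
consistent. The off-season is one aggregate — the method does not resolve
whether it holds one or two extra cycles, and correspondingly the
multiple-cropping area share derived from cropping intensity
(`ci_to_mc_share()`, CI − 1) is capped at 1.

Cells where the main-season grass GPP sum is zero but off-season GPP is
positive have no meaningful main crop; the ratio is set to 0 and a warning
identifies the degenerate cell.

Country-level calibration (`calibrate_yields()`) applies one
multiplicative factor per country × crop chosen so the area-weighted mean
main-season yield matches the reported yield. A multiplicative factor is
the only form that preserves within-country spatial patterns exactly; it
is applied to main- and off-season yields alike and is idempotent.
Factors are uncapped by default; a cap argument exists for data situations
where reported yields are unreliable.

## Irrigation water demand

Main-season consumptive irrigation water requirement is the clamped
difference of crop evapotranspiration (transpiration + evaporation +
interception summed uniformly) between irrigated and rainfed conditions
over the *irrigated* growing season. For the off-season no crop simulation
exists, so per-crop OLS regressions of crop consumptive water use on grass
consumptive water use, fitted across cells on the main season
(`fit_offseason_regression()`), are applied to off-season grass water use;
negative predictions are clamped to zero. The regressions are fitted
pooled per crop: consumptive use at the field is treated as independent of
the irrigation system, which only enters at the withdrawal conversion.
Fit diagnostics (R², n) are carried in the regression table.

Withdrawals follow from the cell's irrigation-system mix with field
efficiencies 0.60/0.75/0.90 and conveyance efficiencies 0.70/0.95/0.95
for surface/sprinkler/drip (configurable), values representative of
global irrigation parameterisations. Half of the conveyance losses are
counted as consumed (evaporated in transit); the remainder and all field
losses are return flow. These choices guarantee withdrawal ≥ consumption
for any efficiency table with entries in (0, 1].

## Water allocation on the river network

Runoff accumulates to natural discharge in topological order
(`route_discharge()`). Demands are then served strictly in priority
order: non-agricultural uses first, then committed demand of
already-irrigated areas under reference cropping patterns, then expansion
requests ranked by the total irrigation yield gain of the cell (area ×
(irrigated-MC yield − reference rainfed yield), summed over crops),
descending, ties by cell id.

Each request may draw on cells of its own basin within
`radius_km = 100` km great-circle distance, tapped nearest first (ties by
cell id). Withdrawing `w` at a source with consumptive fraction κ removes
`w` from the source's availability and `κ·w` from every strictly
downstream cell — the return flow `(1−κ)·w` re-enters at the source's
downstream neighbour. Withdrawals at a basin outlet return to the sea.
Three deliberate choices here: the neighbourhood does not cross basin
boundaries (a conservative reading of radius-based access combined with
basin-wise ranking); a source withdrawal is additionally capped so that no
downstream availability can turn negative (the sequential update rule
alone does not guarantee this once several users interleave); and
consumptive conveyance losses count as consumption in allocation because
they do not return to the river.

Non-agricultural and committed shortfalls are booked as non-renewable
groundwater, so those users are always fully served; expansion requests
receive a fulfilled fraction in [0, 1] and can tap no groundwater. The
fraction scales the cell's expansion area proportionally across crops.

## Scenarios

All scenarios share one physical cropland extent; fallow land is excluded
from expansion throughout (only actively cropped area is intensified).

* **REF** — reference management: MC shares from cropping intensity,
  water demand for existing irrigated areas.
* **NWL** — MC expanded to every suitable area with no water constraint:
  rainfed-suitable areas go fully to rainfed MC; irrigated areas in
  irrigated-suitable cells go fully to irrigated MC; rainfed areas in
  cells suitable *only* under irrigation convert entirely to irrigated MC
  and are flagged *irrigation-enabled*. Unsuitable areas keep their
  reference management (REF acts as a floor). Cells already suitable under
  rainfed conditions are not converted to irrigation: irrigating where it
  enables no extra season is outside this analysis.
* **POT** — the same expansion limited by the allocation: rainfed MC
  expansion needs no water and proceeds as in NWL; irrigated expansion is
  scaled by each cell's fulfilled fraction.

A numerical detail: when a cell's expansion is fully served the fraction
is exactly 1 and the area formulas switch to exact branches, so that with
unbounded runoff POT reproduces NWL bit for bit rather than to rounding
error.

`summarize_scenarios()` aggregates areas, production, mean yields by
system and water by purpose, and derives shares as unrounded percents
(`pct_share()`, `pct_change()`, `NA` where the denominator is zero —
undefined, not 0), with `round_pct()` for nearest-integer display.
Summaries re-read from their CSV forms aggregate to identical totals, and
two runs under the same seed and configuration produce byte-identical
files.

## The synthetic world

`generate_world(seed, n_cells, n_basins, world_config)` is a pure
function of its arguments. It emulates exactly the features the analysis
keys on:

* cells scattered around basin centres (default spread 1°, so 100 km
  neighbourhoods are partially populated), with 0.5°-style cell areas
  shrinking with cos(latitude);
* river basins as random spanning trees built by connecting each cell to
  its nearest already-connected member, one outlet per basin;
* monthly grass GPP built per cell from a warm window (values safely
  above the 100 g C m⁻² threshold) and cold months safely below it, with
  a dry-season mask applied to the rainfed regime only — irrigation
  removes the dry-month limitation, which is precisely the mechanism the
  suitability rule detects. Cells are assigned a priori to three strata
  (rainfed-suitable / irrigated-only / unsuitable, default fractions
  0.3/0.4/0.3) that the classifier provably recovers; a configurable
  share of basins receives near-zero runoff so water scarcity binds
  somewhere (the water-scarce stratum);
* grass and crop evapotranspiration constructed so irrigated ≥ rainfed,
  with the crop–grass water relation linear by construction (slope drawn
  per crop) so the off-season regression has signal;
* cropping intensity in [1, 2], drawn above 1 only where the generator's
  own GPP makes the regime suitable; spatially clustered irrigation
  shares around hotspot cells; Dirichlet-style irrigation-system mixes;
  sparse log-normal non-agricultural demand; and synthetic countries as
  latitude bands, independent of basins, to exercise calibration.

What it does **not** emulate: realistic climatology or geography, real
coastlines or borders, crop rotations, sub-annual hydrology. Spatial
covariance of crop areas is simple distance-based clustering and is an
arbitrary choice. Passing tests therefore demonstrate correctness of the
accounting and algorithms under the assumed statistical structure — not
agreement with any real-world data product. The default of 4 crop types
keeps tests fast; the pipeline is crop-agnostic.

## Numerical choices and degenerate inputs

* Strict `>` at the GPP threshold; suitability requires `≥` min months.
* Negative consumptive requirements (rainfed ET exceeding irrigated ET)
  and negative regression predictions are clamped to 0.
* Allocation order is fully deterministic: priority class, then
  descending rank key, then cell id; sources nearest first, ties by cell
  id. Unsorted request lists are rejected rather than silently reordered.
* Availability is asserted non-negative after every allocation step
  (tolerance 1e-9, then clamped), making mass-balance violations loud.
* Zero physical area yields an MC share of 0; zero-area or zero-demand
  requests are fulfilled trivially with fraction 1.
* Worlds round-trip through plain CSV (+ YAML metadata) at full double
  precision; missing files or columns fail naming the layer.

## Interfaces

The package is used from R: `generate_world()` →
`run_pipeline()`/the individual stage functions → `summarize_scenarios()`
and `write_summary()`, with `world_to_files()`/`load_world()` for run
directories and `validate_config()`/`read_config()` for YAML
configurations. `scripts/acceptance.R` is a thin command-line wrapper
that regenerates a world from a seed and writes the headline quantities
as JSON. An adapter for real crop-model output needs to supply the six
world layers documented in `?generate_world`; the schema in
`?world_to_files` is the contract.

## Problem sizes used by the test-suite

Unit tests run on worlds of 20–120 cells. Property suites sweep 30 seeds
for generator invariants, 100 random small basins (≤ 10 cells) against a
brute-force allocation simulator, and 100 random worlds of 50–500 cells
for scenario orderings and conservation; these sizes give each check many
independent configurations while keeping a full suite run around two
minutes on one CPU.

## Known limitations

Annual water budgets only — seasonal storage and timing constraints are
not represented, which overstates availability where storage is the
binding constraint. A single crop repeated in the off-season — rotations
and their agronomic benefits are absent, biasing yield gains low. The
off-season is an aggregate, so double and triple cropping are not
distinguished. Expansion never irrigates land where irrigation enables no
additional season. Environmental flow requirements are not reserved
before allocation. Calibration functional form is multiplicative by
design; alternative (e.g. additive) schemes would not preserve relative
spatial patterns and are not offered.
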