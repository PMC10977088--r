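---
title: "Mapping sea-turtle habitat and fishery-interaction risk from participatory data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sea-turtle habitat and fishery-interaction risk from participatory data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turtlerisk)
```

## The problem and the data model

Coastal gillnet fisheries in the tropical Southwest Atlantic overlap the
feeding and migration habitat of sea turtles (green, hawksbill, loggerhead,
leatherback, olive ridley), but neither vessel-monitoring systems nor
systematic turtle surveys exist at that scale. `turtlerisk` operationalizes
a participatory design: fishers' vessels carry GPS loggers recording a fix
every 5 minutes, captains note turtle sightings (date, clock time, folk
name, count, life stage, sex) in a logbook, and publicly available daily
ocean-reflectance imagery (a chlorophyll-α proxy, quantized at 1-km
resolution) plus a bathymetry surface supply the environmental context.

Everything is computed on one metric lattice: a 1-km² grid in a UTM zone
(default zone 25 south on the GRS80 ellipsoid, appropriate for the Paraíba
shelf; configurable). The grid origin snaps to multiples of the cell size so
independently constructed grids align cell-for-cell, and cells are half-open
intervals so every point belongs to exactly one cell. Because no compiled
GIS stack is required, rasters travel as plain-text ASCII grids and vector
layers as GeoJSON; the projection itself is the transverse-Mercator series
implemented in the package (round-trip error well under a metre, verified
against a geodesic oracle in the tests).

## Pipeline stages and their assumptions

**Trip segmentation.** Loggers run continuously for days, so one track file
holds several fishing trips. A new trip starts whenever the gap between
consecutive fixes exceeds 4 h — far above the 5-min cadence, far below an
overnight gap; daily trips leave in the early morning and return by late
afternoon, so the rule is insensitive to the exact threshold over a wide
range. Single-fix trips carry no route and are flagged rather than used.

**Sighting association.** A logbook record is matched to the same fisher's
temporally nearest fix of that day; the default tolerance of 150 s is half
the fix interval, the worst-case distance to a fix when the clocks agree.
Logbook clocks are local time (default UTC−3) while GPX is UTC. Exact ties
break to the earlier fix, making the output deterministic. Unmatched records
are kept: the ethnobiological tables need no position, the spatial layers do.

**Habitat by same-value matching.** The reflectance product is
integer-quantized, so "pixels with the same value as the sighting pixel" is
a well-defined set; the default tolerance is therefore 0 (exact equality),
with a configurable ±τ band for un-quantized inputs. Matching runs on the
raster's native grid — it is a pixel-level rule — and only the resulting
masks are aggregated to the analysis grid. Nodata pixels are never matched,
a sighting on nodata is skipped with a warning, and a day whose sightings
all fall on nodata is an error rather than an empty layer. Bathymetry then
removes cells deeper than 50 m (depth as a physical barrier to these
coastal foragers), with areas also reported inside the 20 m isobath, the
two depths relevant for management. Daily rasters missing from the archive
are skipped and listed in the run manifest, mirroring how gaps in daily
satellite coverage are handled in practice.

**Potential distribution.** Stacking counts, per cell, the number of daily
layers that intersect it; a layer contributes at most 1 to a cell however
many of its pixels fall inside (each day is one piece of evidence, applied
as centroids-of-value-1 before the spatial join). The index is bounded by
the number of stacked days; the package does not cap it at any other value.

**Fishing areas and intensity.** The community fishing area is the
classical minimum convex polygon over all of that community's fixes; the
study-level figure is the *sum* of per-community MCP areas, which may
overlap. Intensity counts distinct trips whose route polyline — straight
segments between consecutive 5-min fixes, the least-assumption
interpolation at that cadence — crosses a cell; a trip never increments a
cell twice. Segment–cell incidence uses Liang–Barsky clipping and is tested
against an exhaustive cross-product oracle.

**Bootstrap.** Intensity distributions are zero-inflated and right-skewed,
so normal-theory intervals are inappropriate; the package uses the
percentile bootstrap (1,000 replications, 95% by default) via the `boot`
package. Which summary the interval describes is an explicit, named
parameter (default: the mean of positive-intensity cells) because several
summaries are defensible and the choice materially changes the numbers. The
log scale used elsewhere is `log10(x + 1)`, the +1 making zero cells
representable.

**Risk and IDW.** Risk is `log10(PD + 1) × log10(FI + 1)`: the log
transforms put a 0–9 occurrence index and a 0–71 trip count on comparable
scales so neither factor dominates, and the product annihilates wherever
either is zero. The two layers must share the grid exactly — misalignment
is an error, never a silent resample. Scores are computed where fishing was
observed (cells with ≥ 1 trip) and spread over the habitat-area centroids
by inverse-distance weighting with power 2 and all samples as neighbours —
the common defaults at study-scale sample counts, both configurable. IDW is
exact at sample locations and bounded by the sample range, so the surface
maximum is always an observed overlap cell, and nothing is extrapolated
beyond the habitat polygons.

**Ethnobiological tables.** Per-fisher effort (sighting events, distinct
active days, landing port), species composition (unidentified fraction on
all records; species shares on identified records only; percentages to two
decimals, round-half-even), and the folk–scientific correspondence test: a
record matches when its folk name maps to its species under a configurable
dictionary seeded with tartaruga-verde → *Chelonia mydas*,
tartaruga-cabeçuda → *Caretta caretta*, tartaruga-de-pente →
*Eretmochelys imbricata*. Records noted only as "turtle" make no
species-level claim and are excluded. Communities are compared by one-way
ANOVA with Tukey HSD; because the unit of replication is genuinely open,
both per-fisher proportions (default — fishers are the independent
observers) and per-record indicators are available. The all-identical
degenerate case (0/0 F ratio) is reported explicitly as F = 0, p = 1.

## What the synthetic generator emulates — and what it does not

The generator produces every input with known ground truth under one seed:
three ports with three fishers each, trips as biased correlated random
walks from port to a fishing ground and back at 5-min cadence, daily
quantized reflectance with a planted habitat patch carrying signature
values that occur nowhere else, a linear shore-normal bathymetry gradient
spanning 0–100 m, and logbooks whose timestamps are fix times plus ±60 s
jitter, with half the records left as generic "turtle" and per-community
folk-misidentification rates of 0.25/0.25/0.55 so the correspondence
comparison has signal. The default extent is a 28 × 28 km coastal box
(a few hundred grid cells), sized so the full pipeline runs in seconds;
fishing grounds are drawn inside the planted patch so habitat and traffic
genuinely overlap.

Because signature and background supports are disjoint, exact matching
recovers the planted patch cell-for-cell — this separates algorithm
correctness from data ambiguity, and an overlap mode exists to study false
positives. Real reflectance is not like this: habitat values recur in
open water, clouds punch nodata holes, and the "same value" rule inherits
the product's quantization. Passing the recovery tests therefore
demonstrates that the machinery is faithful, not that the ecological signal
in real imagery is unambiguous. The generator also makes no attempt at
oceanographic realism (no currents, tides or true chlorophyll dynamics) and
places sightings only inside the planted patch, so false-negative behaviour
of the matching rule is not exercised by default.

## Numerical choices and degenerate inputs

- Half-open cells and snapped origins make cell membership a partition and
  grid alignment checkable by equality.
- Nearest-neighbour resampling everywhere: reflectance values are
  categories; interpolation would invent values.
- MCP requires ≥ 3 non-collinear points; collinear input is an error, not a
  zero-area polygon.
- Duplicate IDW sample points with conflicting values are an error;
  coincident targets take the sample value exactly.
- Bootstrap with constant data degenerates cleanly to a zero-width interval.
- All stage outputs are pure functions of (inputs, config); the test suite
  verifies byte-identical reruns, and run manifests record input/output
  hashes but no timestamps.

## Known limitations

- Same-value matching is a presence-only heuristic, not a distribution
  model: no background sampling, no covariate weighting, no species-specific
  layers (sighting counts at species level are usually too small).
- MCPs overestimate territory for non-convex coastlines, by construction.
- The intensity unit is the trip; soak time, gear length and speed-based
  behaviour (steaming vs. setting) are not modelled.
- Risk is a relative overlap index; it is not calibrated to bycatch or
  mortality rates.
- Published fishing-area totals can only be reproduced from the original
  deposited vessel tracks; the corresponding acceptance check requires those
  GPX files to be supplied locally.

## A complete run

```{r example, eval = FALSE}
sc <- synthetic_scenario(seed = 1)
dir <- tempfile()
write_scenario(sc, dir)
cfg <- pipeline_config(
  gpx_dir         = file.path(dir, "gpx"),
  logbook_path    = file.path(dir, "logbook.csv"),
  reflectance_dir = file.path(dir, "reflectance"),
  bathymetry_path = file.path(dir, "bathymetry.asc"),
  registry_path   = file.path(dir, "registry.csv"))
res <- run_all(cfg, file.path(dir, "out"))
res$habitat$area          # recovered habitat, total and per-stratum km2
res$fishing$mcps$total_km2
res$fishing$ci            # percentile bootstrap of mean positive intensity
max(res$risk$raster$values)
```
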