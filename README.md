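# turtlerisk

Participatory mapping of sea-turtle habitat and turtle–fishery interaction
risk for data-poor, small-scale coastal fisheries.

Small-scale gillnet fisheries overlap the coastal habitats of sea turtles in
places where neither systematic telemetry nor official fishery statistics
exist. A low-cost alternative is participatory monitoring: fishers carry GPS
loggers (fixes every 5 min) and record turtle sightings in a logbook; daily
satellite reflectance (a chlorophyll-α proxy) and bathymetry supply the
environmental context. `turtlerisk` implements that workflow end to end for
anyone with tracks, logbooks and rasters — conservation scientists,
ethnobiologists and marine spatial planners working in data-poor contexts.

## Method

On a shared 1-km² metric grid (UTM, configurable):

1. **Sighting georeferencing.** Each logbook record is associated with the
   GPS fix of the same fisher on the same day that minimizes the absolute
   clock difference (default tolerance 150 s, half the fix interval).
2. **Habitat by same-value matching.** For each sighting day *d*, the daily
   habitat layer is `H_d = { pixels p : |v_d(p) − v_d(s)| ≤ τ for some
   sighting pixel s }`, with exact matching (τ = 0) on the quantized
   reflectance by default. Layers are constrained to depth ≤ 50 m
   (bathymetry as a physical barrier), and their union is the habitat area
   (km² reported in total and within the 20 m and 50 m isobaths).
3. **Potential distribution.** `PD(c) = Σ_d 1[H_d ∩ c ≠ ∅]` — the number of
   daily layers covering cell *c*, each day counting at most once per cell.
4. **Fishing areas and intensity.** Per-community fishing areas are minimum
   convex polygons (MCP) over all vessel fixes; fishing intensity
   `FI(c)` counts the distinct trips whose route polyline crosses cell *c*.
   A percentile bootstrap (1,000 replications, 95%) gives confidence
   intervals for a configurable intensity summary.
5. **Risk of interaction.** `R(c) = log10(PD(c) + 1) × log10(FI(c) + 1)`,
   computed where fishing was observed and spread over the habitat area by
   inverse-distance weighting (power 2 by default).

Ethnobiological tables (per-fisher effort, species composition,
folk–scientific correspondence compared between communities by one-way
ANOVA + Tukey HSD) are produced from the same logbook. A synthetic-data
module generates all inputs with known ground truth — planted habitat
signatures, port-anchored trips, jittered logbooks — so the whole pipeline
is testable offline.

## Worked example

```r
library(turtlerisk)

sc <- synthetic_scenario(seed = 1)    # 9 fishers, 3 ports, 5 trips each
dir <- tempfile(); write_scenario(sc, dir)

cfg <- pipeline_config(
  gpx_dir         = file.path(dir, "gpx"),
  logbook_path    = file.path(dir, "logbook.csv"),
  reflectance_dir = file.path(dir, "reflectance"),
  bathymetry_path = file.path(dir, "bathymetry.asc"),
  registry_path   = file.path(dir, "registry.csv"))

res <- run_all(cfg, file.path(dir, "out"))
#> [tracks] 1937 fixes, 45 trips from 9 fishers
#> [sightings] 83 of 83 records matched to a fix
#> [habitat] 62.00 km2 over 5 daily layers; index 0-5
#> [fishing] MCP total 184.05 km2; intensity 0-16 trips
#> [risk] surface over 62 habitat cells

res$habitat$area
#> <habitat_area> 62.00 km2 within 50 m depth (within_20m: 20.00 km2; within_50m: 62.00 km2)
res$fishing$ci
#> <bootstrap_ci> mean_positive = 6.7054, 95% CI [5.9641, 7.4737] (1000 reps, n = 112, seed 1)
```

The habitat area (62 km²) is exactly the planted ground-truth patch of the
scenario: with disjoint signature/background values and exact matching the
method recovers the patch cell-for-cell. 20 km² of it lies inside the 20 m
isobath. Fishing intensity peaks at 16 of 45 trips in the corridor cells off
the ports; the bootstrap CI summarizes the mean intensity of fished cells.
The risk surface (written to `out/risk_surface.asc`) has its maximum inside
the planted habitat where vessel corridors converge.

A shell entry point for the same flow is installed at
`system.file("scripts", "run_pipeline.R", package = "turtlerisk")`.

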