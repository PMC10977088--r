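# Shared fixtures: a small scenario materialized once per test session, and
# an in-memory pipeline runner used by scenario-level tests.

.fixture_env <- new.env(parent = emptyenv())

# one small scenario written to disk, reused across test files
scenario_fixture <- function(seed = 11) {
  key <- paste0("sc", seed)
  if (is.null(.fixture_env[[key]])) {
    sc <- synthetic_scenario(seed = seed)
    dir <- file.path(tempdir(), paste0("turtlerisk_fixture_", seed))
    if (!dir.exists(dir)) write_scenario(sc, dir)
    .fixture_env[[key]] <- list(scenario = sc, dir = dir)
  }
  .fixture_env[[key]]
}

# run the analysis stages in memory from a scenario (no file I/O)
run_scenario_memory <- function(sc, tolerance = 0) {
  fixes <- gen_trips(sc)
  lb <- gen_logbook(sc, fixes)
  sightings <- match_sightings(lb$records, fixes,
                               tz_offset_hours = sc$tz_offset_hours)
  bathy <- gen_bathymetry(sc)
  dates <- sort(unique(as.character(sightings$date[sightings$matched])))
  layers <- lapply(dates, function(d)
    daily_layer(sightings[sightings$date == as.Date(d), , drop = FALSE],
                gen_reflectance(sc, as.Date(d)), tolerance = tolerance))
  ha <- habitat_area(layers, bathy)
  masked <- lapply(layers, apply_bathymetry, bathymetry = bathy)
  pd <- stack_layers(masked, ha$grid)
  fi <- intensity_grid(fixes, ha$grid)
  rs <- risk_surface(pd, fi, ha)
  list(fixes = fixes, logbook = lb, sightings = sightings, layers = layers,
       habitat = ha, pd = pd, fi = fi, risk = rs)
}

# a tiny grid for pure-planar geometry tests: origin 0/0, 1 km cells
tiny_grid <- function(n_rows = 5, n_cols = 5, cell = 1000) {
  grid_spec(0, 0, cell, n_rows, n_cols, crs = utm_crs(25, TRUE))
}

# a tiny grid placed at realistic UTM 25S coordinates (Paraiba shelf), for
# tests that round-trip through geographic coordinates
GX0 <- 290000
GY0 <- 9190000
geo_grid <- function(n_rows = 5, n_cols = 5, cell = 1000) {
  grid_spec(GX0, GY0, cell, n_rows, n_cols, crs = utm_crs(25, TRUE))
}

# GPX text for a sequence of fixes, written to a temp file
gpx_file <- function(lat, lon, times, dir = tempdir(), drop_time_at = NULL) {
  path <- tempfile(fileext = ".gpx", tmpdir = dir)
  pts <- vapply(seq_along(lat), function(i) {
    if (!is.null(drop_time_at) && i == drop_time_at)
      sprintf('<trkpt lat="%f" lon="%f"></trkpt>', lat[i], lon[i])
    else
      sprintf('<trkpt lat="%f" lon="%f"><time>%s</time></trkpt>', lat[i], lon[i],
              format(times[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  }, character(1))
  writeLines(c('<?xml version="1.0"?>',
               '<gpx version="1.1" creator="test" xmlns="http://www.topografix.com/GPX/1/1">',
               "<trk><trkseg>", pts, "</trkseg></trk></gpx>"), path)
  path
}
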