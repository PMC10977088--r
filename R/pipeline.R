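# End-to-end orchestration: read inputs, run every stage in order, write the
# declared artifacts and a reproducibility manifest. Outputs are pure
# functions of (inputs, config): rerunning with the same inputs gives
# byte-identical files.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the defaults declared by the
#' owning stage. A resolved copy is serialized alongside the outputs so a run
#' is self-describing. Configs can also be read from a YAML file whose keys
#' mirror the arguments.
#'
#' @param gpx_dir directory of per-fisher GPX files (fisher id = file name).
#' @param logbook_path sighting logbook CSV.
#' @param reflectance_dir directory of daily reflectance ASCII grids.
#' @param reflectance_pattern regex extracting the ISO date from a
#'   reflectance file name (first capture group).
#' @param bathymetry_path bathymetry ASCII grid (positive-down metres).
#' @param registry_path fisher/port registry CSV
#'   (\code{fisher_id,community,lon,lat}).
#' @param crs_id metric CRS id (default \code{"UTM:25S"}).
#' @param cell_size analysis cell size, metres.
#' @param gap_threshold trip segmentation gap, seconds.
#' @param match_tolerance sighting/fix association tolerance, seconds.
#' @param tz_offset_hours logbook local-clock offset from UTC.
#' @param reflectance_tolerance value-matching half-width (0 = exact).
#' @param depth_limit habitat depth limit, metres.
#' @param depth_strata isobaths at which habitat area is reported.
#' @param depth_sign 1 = positive-down bathymetry.
#' @param idw_power,idw_neighbors IDW parameters.
#' @param boot_statistic \code{"mean_positive"} (mean of positive-intensity
#'   cells) or \code{"mean"} (all cells).
#' @param boot_n_reps,boot_level,boot_seed bootstrap parameters.
#' @return A named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(gpx_dir, logbook_path, reflectance_dir,
                            bathymetry_path, registry_path,
                            reflectance_pattern = "refl_([0-9-]+)\\.asc$",
                            crs_id = "UTM:25S", cell_size = 1000,
                            gap_threshold = 4 * 3600, match_tolerance = 150,
                            tz_offset_hours = -3, reflectance_tolerance = 0,
                            depth_limit = 50, depth_strata = c(20, 50),
                            depth_sign = 1, idw_power = 2,
                            idw_neighbors = "all",
                            boot_statistic = "mean_positive",
                            boot_n_reps = 1000, boot_level = 0.95,
                            boot_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file of config keys.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.boot_stat <- function(name) {
  switch(name,
         mean = list(fn = mean, values = function(fi) as.numeric(fi$trips_per_cell)),
         mean_positive = list(
           fn = mean,
           values = function(fi) {
             v <- as.numeric(fi$trips_per_cell); v[v > 0]
           }),
         stop("unknown bootstrap statistic: ", name, call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes every stage in order -- tracks, sighting association, habitat,
#' fishing areas and intensity, risk, ethnobiological tables -- and writes
#' the output bundle to \code{out_dir}: habitat area (GeoJSON + ASCII grid of
#' the potential-distribution index), per-community MCP polygons (GeoJSON),
#' fishing-intensity grid, risk surface, bootstrap CI report, effort /
#' composition / correspondence CSVs, the resolved config (YAML) and a run
#' manifest (JSON with input hashes, package version and output hashes).
#' Stage failures are reported with the stage name. The analysis grid is the
#' grid of the daily reflectance rasters, so distribution, intensity and risk
#' share one lattice by construction; sighting dates without a reflectance
#' raster are skipped and listed in the manifest.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and
#'   \code{manifest}.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  crs <- as_crs(config$crs_id)

  # --- tracks ---------------------------------------------------------
  fixes <- stage("tracks", {
    files <- sort(list.files(config$gpx_dir, pattern = "\\.gpx$",
                             full.names = TRUE))
    if (!length(files)) stop("no GPX files in ", config$gpx_dir)
    registry <- utils::read.csv(config$registry_path,
                                stringsAsFactors = FALSE)
    comm <- stats::setNames(registry$community, registry$fisher_id)
    do.call(rbind, lapply(files, function(f) {
      fx <- read_gpx(f)
      segment_trips(fx, gap_threshold = config$gap_threshold,
                    community = unname(comm[fx$fisher_id[1]]))
    }))
  })
  trips <- trip_table(fixes)
  .log_stage("tracks", nrow(fixes), " fixes, ", nrow(trips), " trips from ",
             length(unique(fixes$fisher_id)), " fishers")

  # --- sightings ------------------------------------------------------
  sightings <- stage("sightings", {
    records <- read_logbook(config$logbook_path)
    match_sightings(records, fixes, tolerance = config$match_tolerance,
                    tz_offset_hours = config$tz_offset_hours)
  })
  .log_stage("sightings", sum(sightings$matched), " of ", nrow(sightings),
             " records matched to a fix")

  # --- habitat --------------------------------------------------------
  habitat <- stage("habitat", {
    if (!file.exists(config$bathymetry_path))
      stop("bathymetry raster not found: ", config$bathymetry_path)
    bathy <- read_asc(config$bathymetry_path, crs)
    rfiles <- list.files(config$reflectance_dir,
                         pattern = config$reflectance_pattern,
                         full.names = TRUE)
    rdates <- regmatches(basename(rfiles),
                         regexec(config$reflectance_pattern, basename(rfiles)))
    rdates <- vapply(rdates, `[`, character(1), 2)
    names(rfiles) <- rdates
    sdates <- sort(unique(as.character(
      sightings$date[sightings$matched %in% TRUE])))
    dropped <- setdiff(sdates, rdates)
    if (length(dropped))
      .log_stage("habitat", "no reflectance raster for ",
                 length(dropped), " date(s): ",
                 paste(dropped, collapse = ", "), "; skipped")
    used <- intersect(sdates, rdates)
    if (!length(used)) stop("no sighting date has a reflectance raster")
    layers <- lapply(used, function(d)
      daily_layer(sightings[sightings$date == as.Date(d), , drop = FALSE],
                  read_asc(rfiles[[d]], crs),
                  tolerance = config$reflectance_tolerance))
    ha <- habitat_area(layers, bathy, depth_limit = config$depth_limit,
                       strata = config$depth_strata,
                       depth_sign = config$depth_sign)
    masked <- lapply(layers, apply_bathymetry, bathymetry = bathy,
                     depth_limit = config$depth_limit,
                     depth_sign = config$depth_sign)
    list(layers = layers, area = ha, grid = ha$grid,
         pd = stack_layers(masked, ha$grid), dropped_dates = dropped)
  })
  .log_stage("habitat", sprintf("%.2f km2 over %d daily layers; index 0-%d",
                                habitat$area$total_km2,
                                habitat$pd$n_layers, max(habitat$pd$index)))

  # --- fishing --------------------------------------------------------
  fishing <- stage("fishing", {
    mcps <- mcp_by_community(fixes, crs)
    fi <- intensity_grid(fixes, habitat$grid)
    st <- .boot_stat(config$boot_statistic)
    ci <- bootstrap_ci(st$values(fi), statistic = st$fn,
                       n_reps = config$boot_n_reps,
                       level = config$boot_level, seed = config$boot_seed,
                       statistic_name = config$boot_statistic)
    list(mcps = mcps, intensity = fi, ci = ci)
  })
  .log_stage("fishing", sprintf("MCP total %.2f km2; intensity 0-%d trips",
                                fishing$mcps$total_km2,
                                fishing$intensity$max_trips))

  # --- risk -----------------------------------------------------------
  risk <- stage("risk", {
    risk_surface(habitat$pd, fishing$intensity, habitat$area,
                 power = config$idw_power, neighbors = config$idw_neighbors)
  })
  .log_stage("risk", sprintf("surface over %d habitat cells",
                             sum(habitat$area$mask)))

  # --- ethno ----------------------------------------------------------
  ethno <- stage("ethno", {
    eff <- effort_table(sightings, trips)
    comp <- species_composition(sightings)
    corr <- tryCatch(correspondence_anova(sightings),
                     error = function(e) {
                       .log_stage("ethno", "correspondence test skipped: ",
                                  conditionMessage(e))
                       NULL
                     })
    list(effort = eff, composition = comp, correspondence = corr)
  })

  # --- outputs --------------------------------------------------------
  paths <- stage("outputs", {
    p <- list(
      pd = file.path(out_dir, "potential_distribution.asc"),
      intensity = file.path(out_dir, "fishing_intensity.asc"),
      risk = file.path(out_dir, "risk_surface.asc"),
      habitat = file.path(out_dir, "habitat_area.geojson"),
      mcp = file.path(out_dir, "fishing_areas.geojson"),
      sightings = file.path(out_dir, "sightings.geojson"),
      boot = file.path(out_dir, "bootstrap_ci.csv"),
      effort = file.path(out_dir, "effort_table.csv"),
      composition = file.path(out_dir, "species_composition.csv"),
      config = file.path(out_dir, "config_resolved.yaml")
    )
    write_asc(raster_layer(habitat$grid, habitat$pd$index), p$pd)
    write_asc(raster_layer(habitat$grid, fishing$intensity$trips_per_cell),
              p$intensity)
    write_asc(risk$raster, p$risk)
    write_geojson_polygons(
      mask_polygons(habitat$grid, habitat$area$mask), p$habitat, crs,
      properties = rep(list(c(list(total_km2 = habitat$area$total_km2),
                              as.list(habitat$area$depth_strata_km2))),
                       sum(habitat$area$mask)))
    write_geojson_polygons(
      lapply(fishing$mcps$mcps, `[[`, "polygon"), p$mcp, crs,
      properties = lapply(fishing$mcps$mcps, function(m)
        list(community = m$community, area_km2 = m$area_km2,
             n_fixes = m$n_fixes)))
    ms <- sightings[sightings$matched %in% TRUE, , drop = FALSE]
    if (nrow(ms)) {
      xy <- project(cbind(ms$lon, ms$lat), crs)
      write_geojson_points(
        data.frame(x = xy[, 1], y = xy[, 2], fisher_id = ms$fisher_id,
                   date = as.character(ms$date), folk_name = ms$folk_name,
                   stringsAsFactors = FALSE),
        p$sightings, crs)
    }
    ci <- fishing$ci
    utils::write.csv(
      data.frame(statistic = ci$statistic, estimate = ci$estimate,
                 level = ci$level, n_reps = ci$n_reps, seed = ci$seed,
                 lower = ci$lower, upper = ci$upper),
      p$boot, row.names = FALSE)
    utils::write.csv(ethno$effort, p$effort, row.names = FALSE)
    utils::write.csv(ethno$composition$species, p$composition,
                     row.names = FALSE)
    yaml::write_yaml(unclass(config), p$config)
    p
  })

  inputs <- c(config$logbook_path, config$bathymetry_path,
              config$registry_path,
              sort(list.files(config$gpx_dir, pattern = "\\.gpx$",
                              full.names = TRUE)),
              sort(list.files(config$reflectance_dir, full.names = TRUE)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("turtlerisk")),
    crs = crs$id,
    config = unclass(config),
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                        basename(inputs))),
    dropped_dates = habitat$dropped_dates,
    n_trips = nrow(trips),
    n_sightings = nrow(sightings),
    n_matched = sum(sightings$matched),
    habitat_total_km2 = habitat$area$total_km2,
    mcp_total_km2 = fishing$mcps$total_km2,
    output_md5 = local({
      f <- sort(unlist(paths))
      as.list(stats::setNames(unname(tools::md5sum(f)), basename(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fixes = fixes, trips = trips, sightings = sightings,
                 habitat = habitat, fishing = fishing, risk = risk,
                 ethno = ethno, manifest = manifest, paths = paths))
}
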