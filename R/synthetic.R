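# Synthetic study generator: ports, multi-trip vessel tracks radiating from
# them, daily quantized reflectance rasters with a planted habitat signature
# at known cells, a smooth shore-normal bathymetry gradient, and sighting
# logbooks whose timestamps fall between GPS fixes. Every stage of the
# pipeline can be tested offline against this known ground truth.

#' Define a synthetic study scenario
#'
#' All pipeline inputs flow from one scenario object and one seed; identical
#' seeds give bit-identical artifacts. The defaults emulate the study design:
#' three landing ports with three fishers each, 5-min GPS fixes, daily trips
#' from early morning, a planted offshore habitat patch in water shallower
#' than 50 m carrying a reflectance signature value that occurs nowhere else
#' (background and signature supports are disjoint, so exact-match recovery
#' of the planted patch is provable), and about half of the sightings noted
#' only as "turtle".
#'
#' @param seed integer master seed.
#' @param extent geographic rectangle \code{c(lonmin, latmin, lonmax, latmax)}.
#' @param cell_size analysis/raster cell size in metres.
#' @param n_fishers number of fishers (allocated to ports round-robin).
#' @param trips_per_fisher daily trips per fisher (one per consecutive day).
#' @param fix_interval GPS fix cadence in seconds (default 300 = 5 min).
#' @param sighting_rate target sightings per trip while inside the planted
#'   habitat.
#' @param jitter logbook timing noise, seconds (uniform on +-jitter); keep
#'   below half the fix interval so every sighting matches its true fix.
#' @param signature_values integer reflectance value(s) planted inside the
#'   habitat patch; must be disjoint from \code{background_support}.
#' @param background_support integer values the background field is quantized
#'   to.
#' @param turtle_fraction fraction of records noted only as "turtle".
#' @param misid_rates per-community probability that a species-level record
#'   carries the wrong folk name (named by community); the defaults mirror
#'   the study's correspondence proportions (0.75, 0.75, 0.45 correct).
#' @param start_date first trip date.
#' @param tz_offset_hours local-time offset of logbook clocks from UTC.
#' @return Object of class \code{synthetic_scenario}.
#' @export
synthetic_scenario <- function(seed = 1L,
                               extent = c(-34.90, -7.30, -34.65, -7.05),
                               cell_size = 1000,
                               n_fishers = 9L,
                               trips_per_fisher = 5L,
                               fix_interval = 300,
                               sighting_rate = 2,
                               jitter = 60,
                               signature_values = 777L,
                               background_support = 100:120,
                               turtle_fraction = 0.5,
                               misid_rates = c("Ponta de Matos" = 0.25,
                                               "Penha" = 0.25,
                                               "Jacumã" = 0.55),
                               start_date = as.Date("2018-07-02"),
                               tz_offset_hours = -3) {
  if (length(intersect(signature_values, background_support)))
    stop("signature values must be disjoint from the background support ",
         "(set them apart, or use an overlap deliberately to study false ",
         "positives)", call. = FALSE)
  crs <- utm_crs(utm_zone_for(mean(extent[c(1, 3)])),
                 south = mean(extent[c(2, 4)]) < 0)
  grid <- make_grid(extent, cell_size = cell_size, crs = crs)
  # three ports on the western (coastal) edge of the extent
  port_lats <- extent[2] + c(0.75, 0.5, 0.25) * (extent[4] - extent[2])
  ports <- data.frame(
    community = c("Ponta de Matos", "Penha", "Jacumã"),
    lon = extent[1] + 0.03 * (extent[3] - extent[1]),
    lat = port_lats, stringsAsFactors = FALSE
  )
  # planted habitat: a blob centred ~25% offshore (depth ~25 m), spanning
  # the 20 m isobath but staying well inside the 50 m depth limit
  ctr <- project(c(extent[1] + 0.25 * (extent[3] - extent[1]),
                   mean(extent[c(2, 4)])), crs)
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  radius <- 4500 + 1200 * sin(3 * ang)
  planted <- cbind(x = ctr[1] + radius * cos(ang),
                   y = ctr[2] + radius * sin(ang))
  structure(list(
    seed = as.integer(seed), extent = extent, crs = crs, grid = grid,
    ports = ports, n_fishers = as.integer(n_fishers),
    trips_per_fisher = as.integer(trips_per_fisher),
    fix_interval = fix_interval, sighting_rate = sighting_rate,
    jitter = jitter, signature_values = as.integer(signature_values),
    background_support = as.integer(background_support),
    turtle_fraction = turtle_fraction, misid_rates = misid_rates,
    start_date = as.Date(start_date),
    tz_offset_hours = tz_offset_hours,
    planted_habitat = planted
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> seed %d: %d fishers x %d trips, %d x %d grid (%s)\n",
              x$seed, x$n_fishers, x$trips_per_fisher,
              x$grid$n_rows, x$grid$n_cols, x$crs$id))
  invisible(x)
}

#' Planted-habitat cell footprint
#'
#' The ground-truth mask: grid cells whose centroid lies inside the planted
#' habitat polygon.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @return Logical matrix on the scenario grid.
#' @export
planted_mask <- function(scenario) {
  cc <- cell_centroids(scenario$grid)
  inside <- point_in_polygon(cc$x, cc$y, scenario$planted_habitat)
  matrix(inside, scenario$grid$n_rows, scenario$grid$n_cols, byrow = TRUE)
}

#' Synthetic bathymetry
#'
#' Depth increases linearly with distance from the western (coastal) edge of
#' the extent, spanning 0-100 m, so the 20 m and 50 m isobaths both exist and
#' every shore-normal transect is monotone.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @return A \code{\link{raster_layer}} of depths in metres (positive down).
#' @export
gen_bathymetry <- function(scenario) {
  g <- scenario$grid
  cc <- cell_centroids(g)
  xmin <- g$origin_x; xmax <- grid_xmax(g)
  depth <- 100 * (cc$x - xmin) / (xmax - xmin)
  raster_layer(g, matrix(depth, g$n_rows, g$n_cols, byrow = TRUE))
}

#' Synthetic daily reflectance raster
#'
#' An integer-quantized, spatially autocorrelated background field (a coarse
#' Gaussian field bilinearly upsampled, then quantized to the configured
#' support), with pixels inside the planted habitat overwritten by values
#' from the signature set. Because the supports are disjoint, a signature
#' value occurs on no pixel outside the planted habitat. The field differs
#' between dates (the per-date seed is derived from the scenario seed) but
#' the planted mask is identical every day.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @param date the day to generate.
#' @return A \code{\link{raster_layer}} of integer reflectance values.
#' @export
gen_reflectance <- function(scenario, date) {
  g <- scenario$grid
  day_i <- as.integer(as.Date(date) - scenario$start_date)
  set.seed((scenario$seed %% 100000L) * 1000L + (day_i %% 1000L))
  # coarse field, bilinear upsample
  nc <- 6
  coarse <- matrix(stats::rnorm(nc * nc), nc, nc)
  ri <- seq(1, nc, length.out = g$n_rows)
  ci <- seq(1, nc, length.out = g$n_cols)
  r0 <- pmin(floor(ri), nc - 1); c0 <- pmin(floor(ci), nc - 1)
  fr <- ri - r0; fc <- ci - c0
  field <- outer(seq_len(g$n_rows), seq_len(g$n_cols), function(i, j) {
    a <- coarse[cbind(r0[i], c0[j])] * (1 - fr[i]) * (1 - fc[j])
    b <- coarse[cbind(r0[i] + 1, c0[j])] * fr[i] * (1 - fc[j])
    d <- coarse[cbind(r0[i], c0[j] + 1)] * (1 - fr[i]) * fc[j]
    e <- coarse[cbind(r0[i] + 1, c0[j] + 1)] * fr[i] * fc[j]
    a + b + d + e
  })
  sup <- scenario$background_support
  q <- (field - min(field)) / (diff(range(field)) + 1e-12)
  vals <- sup[pmin(length(sup), 1 + floor(q * length(sup)))]
  vals <- matrix(vals, g$n_rows, g$n_cols)
  pm <- planted_mask(scenario)
  sig <- scenario$signature_values
  vals[pm] <- sig[1 + (stats::rpois(sum(pm), 1) %% length(sig))]
  raster_layer(g, vals)
}

# biased correlated walk from `from` towards `to`, ~step metres per fix
.walk_to <- function(from, to, step, arrive = 500) {
  pos <- from; path <- list()
  for (i in 1:500) {
    d <- sqrt(sum((to - pos)^2))
    if (d < arrive) break
    heading <- atan2(to[2] - pos[2], to[1] - pos[1]) + stats::rnorm(1, 0, 0.3)
    pos <- pos + pmin(step, d) * c(cos(heading), sin(heading))
    path[[length(path) + 1]] <- pos
  }
  do.call(rbind, path)
}

#' Synthetic vessel trips
#'
#' Each trip departs its port in the early morning, performs a correlated
#' random walk to a fishing ground sampled inside the planted habitat patch,
#' dwells there for about an hour, and returns, with fixes at the configured
#' cadence. Trips of one fisher fall on consecutive days, so a fisher's GPX
#' file holds several trips separated by overnight gaps.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @param gpx_dir optional directory; when given, one GPX file per fisher is
#'   written there (deterministic bytes under a fixed seed).
#' @return data.frame of ground-truth fixes with \code{trip_id},
#'   \code{fisher_id}, \code{community}, \code{timestamp}, \code{lat},
#'   \code{lon}, \code{source_file}.
#' @export
gen_trips <- function(scenario, gpx_dir = NULL) {
  set.seed(scenario$seed)
  g <- scenario$grid
  crs <- scenario$crs
  step <- 2.2 * scenario$fix_interval           # ~2.2 m/s cruise
  ports_xy <- project(cbind(scenario$ports$lon, scenario$ports$lat), crs)
  bbox <- apply(scenario$planted_habitat, 2, range)
  sample_ground <- function() {
    repeat {
      p <- c(stats::runif(1, bbox[1, 1], bbox[2, 1]),
             stats::runif(1, bbox[1, 2], bbox[2, 2]))
      if (point_in_polygon(p[1], p[2], scenario$planted_habitat)) return(p)
    }
  }
  all <- list()
  for (f in seq_len(scenario$n_fishers)) {
    fid <- sprintf("F%d", f)
    port_i <- ((f - 1) %% nrow(scenario$ports)) + 1
    port <- ports_xy[port_i, ]
    community <- scenario$ports$community[port_i]
    for (tr in seq_len(scenario$trips_per_fisher)) {
      date <- scenario$start_date + (tr - 1)
      # departure ~06:00 local, staggered per fisher; logbook clocks are
      # local = UTC + tz_offset, so UTC start is local minus the offset
      t0 <- as.POSIXct(paste(date, "06:00:00"), tz = "UTC") -
        scenario$tz_offset_hours * 3600 + (f - 1) * 420
      ground <- sample_ground()
      out <- .walk_to(port, ground, step)
      dwell <- matrix(rep(ground, 13), ncol = 2, byrow = TRUE) +
        cbind(stats::rnorm(13, 0, 150), stats::rnorm(13, 0, 150))
      last <- if (!is.null(out) && nrow(out)) out[nrow(out), ] else ground
      back <- .walk_to(last, port, step, arrive = 150)
      xy <- rbind(matrix(port, 1), out, dwell, back, matrix(port, 1))
      ll <- unproject(xy, crs)
      n <- nrow(xy)
      all[[length(all) + 1]] <- data.frame(
        timestamp = t0 + (seq_len(n) - 1) * scenario$fix_interval,
        lat = ll[, 2], lon = ll[, 1],
        fisher_id = fid, community = community,
        trip_id = sprintf("%s_t%02d", fid, tr),
        source_file = paste0(fid, ".gpx"),
        stringsAsFactors = FALSE
      )
    }
  }
  fixes <- do.call(rbind, all)
  fixes <- fixes[order(fixes$fisher_id, fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  if (!is.null(gpx_dir)) {
    dir.create(gpx_dir, showWarnings = FALSE, recursive = TRUE)
    for (fid in unique(fixes$fisher_id))
      write_gpx(fixes[fixes$fisher_id == fid, , drop = FALSE],
                file.path(gpx_dir, paste0(fid, ".gpx")))
  }
  fixes
}

#' Synthetic sighting logbook
#'
#' Places sightings on trip fixes whose grid cell carries the planted
#' signature (up to \code{sighting_rate} per trip), with logbook clock times
#' equal to the fix time plus uniform jitter, converted to the local clock.
#' Folk names are drawn from the study's three folk terms, with a
#' configurable fraction noted only as "turtle" (no species) and a
#' per-community misidentification rate (wrong folk name for the recorded
#' species) so the folk/scientific correspondence comparison is exercised.
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @param fixes ground-truth fixes from \code{\link{gen_trips}}.
#' @return List with \code{records} (logbook data.frame) and \code{truth}
#'   (data.frame of the generating fix index, position and trip per record).
#' @export
gen_logbook <- function(scenario, fixes) {
  force(fixes)  # evaluate before seeding: generating fixes consumes the RNG
  set.seed(scenario$seed + 7919L)
  xy <- project(cbind(fixes$lon, fixes$lat), scenario$crs)
  pm <- planted_mask(scenario)
  rc <- cell_of(scenario$grid, xy[, 1], xy[, 2])
  inside <- !is.na(rc$row) & pm[cbind(rc$row, rc$col)]
  folk_for <- c("Chelonia mydas" = "tartaruga-verde",
                "Caretta caretta" = "tartaruga-cabeçuda",
                "Eretmochelys imbricata" = "tartaruga-de-pente")
  recs <- list(); truth <- list()
  for (tid in unique(fixes$trip_id)) {
    cand <- which(fixes$trip_id == tid & inside)
    if (!length(cand)) next
    k <- min(length(cand), stats::rpois(1, scenario$sighting_rate))
    if (k == 0) next
    pick <- sort(sample(cand, k))
    for (i in pick) {
      jit <- round(stats::runif(1, -scenario$jitter, scenario$jitter))
      local <- fixes$timestamp[i] + jit + scenario$tz_offset_hours * 3600
      generic <- stats::runif(1) < scenario$turtle_fraction
      sp <- if (generic) NA_character_ else
        sample(names(folk_for), 1, prob = c(0.83, 0.10, 0.07))
      folk <- if (generic) "turtle" else unname(folk_for[sp])
      if (!generic) {
        misid <- scenario$misid_rates[[fixes$community[i]]]
        if (!is.null(misid) && stats::runif(1) < misid)
          folk <- sample(setdiff(unname(folk_for), folk), 1)
      }
      recs[[length(recs) + 1]] <- data.frame(
        date = as.Date(local, tz = "UTC"),
        time = format(local, "%H:%M:%S", tz = "UTC"),
        fisher_id = fixes$fisher_id[i],
        community = fixes$community[i],
        folk_name = folk,
        species = sp,
        n_individuals = 1L + stats::rpois(1, 0.2),
        life_stage = sample(c("adult", "juvenile", "unknown"), 1,
                            prob = c(0.47, 0.13, 0.40)),
        sex = sample(c("unknown", "male"), 1, prob = c(0.98, 0.02)),
        stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1]] <- data.frame(
        fix_index = i, trip_id = tid, lat = fixes$lat[i], lon = fixes$lon[i],
        fix_time = fixes$timestamp[i], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(recs))
    return(list(records = study_effort_logbook()[0, ], truth = NULL))
  list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
}

#' Write all scenario inputs to disk
#'
#' Materializes a scenario as the on-disk inputs \code{\link{run_all}}
#' consumes: per-fisher GPX files, a logbook CSV, one reflectance ASCII grid
#' per sighting date, a bathymetry grid, a port/fisher registry CSV, and a
#' ground-truth manifest (JSON).
#'
#' @param scenario a \code{\link{synthetic_scenario}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list of the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fixes <- gen_trips(scenario, gpx_dir = file.path(dir, "gpx"))
  lb <- gen_logbook(scenario, fixes)
  write_logbook(lb$records, file.path(dir, "logbook.csv"))
  dir.create(file.path(dir, "reflectance"), showWarnings = FALSE)
  for (d in sort(unique(as.character(lb$records$date))))
    write_asc(gen_reflectance(scenario, as.Date(d)),
              file.path(dir, "reflectance", paste0("refl_", d, ".asc")))
  write_asc(gen_bathymetry(scenario), file.path(dir, "bathymetry.asc"))
  reg <- unique(data.frame(fisher_id = fixes$fisher_id,
                           community = fixes$community,
                           stringsAsFactors = FALSE))
  reg <- merge(reg, scenario$ports, by = "community", sort = TRUE)
  utils::write.csv(reg[order(reg$fisher_id),
                       c("fisher_id", "community", "lon", "lat")],
                   file.path(dir, "registry.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(
    seed = scenario$seed, extent = scenario$extent, crs = scenario$crs$id,
    cell_size = scenario$grid$cell_size,
    n_fishers = scenario$n_fishers,
    trips_per_fisher = scenario$trips_per_fisher,
    signature_values = scenario$signature_values,
    planted_habitat_xy = unname(apply(scenario$planted_habitat, 1, c,
                                      simplify = FALSE)),
    planted_cells = sum(planted_mask(scenario)),
    n_records = nrow(lb$records)
  )
  jsonlite::write_json(manifest, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir))
}
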