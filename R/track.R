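# Vessel tracks and sighting logbooks: GPX reading/writing, trip
# segmentation, logbook parsing, and sighting-to-fix association.

#' The five sea-turtle species of the Southwest Atlantic RMU
#'
#' Scientific names accepted in the logbook \code{species} column.
#' @return Character vector of five binomials.
#' @export
rmu_species <- function() {
  c("Chelonia mydas", "Eretmochelys imbricata", "Caretta caretta",
    "Dermochelys coriacea", "Lepidochelys olivacea")
}

#' Folk-to-scientific name dictionary
#'
#' The default folk taxonomy used in the correspondence analysis, seeded with
#' the three folk names the fishers used at species level. The generic
#' "turtle" records carry no species-level claim and are excluded from the
#' correspondence test.
#'
#' @return Named character vector mapping folk name to scientific name.
#' @export
default_folk_taxonomy <- function() {
  c("tartaruga-verde" = "Chelonia mydas",
    "tartaruga-cabeçuda" = "Caretta caretta",
    "tartaruga-de-pente" = "Eretmochelys imbricata")
}

.parse_gpx_time <- function(s) {
  as.POSIXct(sub("Z$", "", sub("\\.[0-9]+", "", s)),
             format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Read a GPX track file
#'
#' Parses GPX 1.0/1.1 track points into a fix table. Every track point must
#' carry a \code{<time>} element; files with untimed points are rejected
#' (the association of sightings with positions is time-based).
#'
#' @param path GPX file path.
#' @param fisher_id identifier for the fisher/vessel; defaults to the file
#'   name without extension.
#' @return data.frame of fixes in file order with columns \code{timestamp}
#'   (POSIXct, UTC), \code{lat}, \code{lon}, \code{fisher_id},
#'   \code{source_file}.
#' @export
read_gpx <- function(path, fisher_id = NULL) {
  if (is.null(fisher_id))
    fisher_id <- tools::file_path_sans_ext(basename(path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0)
    stop("no track points in GPX file: ", path, call. = FALSE)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  times <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  if (anyNA(times)) {
    bad <- which(is.na(times))[1]
    stop("GPX track point ", bad, " in ", basename(path),
         " has no <time> element; untimed fixes cannot be used", call. = FALSE)
  }
  ts <- .parse_gpx_time(times)
  if (anyNA(ts))
    stop("unparseable <time> value in ", basename(path), call. = FALSE)
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("GPX coordinates outside valid lat/lon ranges in ", basename(path),
         call. = FALSE)
  data.frame(timestamp = ts, lat = lat, lon = lon,
             fisher_id = fisher_id, source_file = basename(path),
             stringsAsFactors = FALSE)
}

#' @rdname read_gpx
#' @param fixes fix data.frame as returned by \code{read_gpx}; an optional
#'   \code{trip_id} column starts a new \code{<trkseg>} per trip.
#' @param creator creator string stored in the GPX header.
#' @export
write_gpx <- function(fixes, path, creator = "turtlerisk") {
  seg_ids <- if ("trip_id" %in% names(fixes)) fixes$trip_id else rep(1, nrow(fixes))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<gpx version=\"1.1\" creator=\"%s\" xmlns=\"http://www.topografix.com/GPX/1/1\">", creator),
    "<trk><name>track</name>"
  )
  for (sid in unique(seg_ids)) {
    idx <- which(seg_ids == sid)
    lines <- c(lines, "<trkseg>",
               sprintf("<trkpt lat=\"%.6f\" lon=\"%.6f\"><time>%s</time></trkpt>",
                       fixes$lat[idx], fixes$lon[idx],
                       format(fixes$timestamp[idx], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
               "</trkseg>")
  }
  writeLines(c(lines, "</trk>", "</gpx>"), path)
  invisible(path)
}

#' Segment a fix sequence into fishing trips
#'
#' Splits a time-sorted fix sequence wherever the gap between consecutive
#' fixes exceeds \code{gap_threshold}. The trackers logged continuously for
#' days, so one file typically holds several daily trips separated by
#' overnight gaps; the 4 h default is far above the 5-min fix cadence and far
#' below an overnight gap. Trips with fewer than 2 fixes are flagged with
#' \code{trip_id = NA} and a warning (a single fix carries no route).
#'
#' @param fixes fix data.frame (one fisher), time-sorted.
#' @param gap_threshold seconds; split when the inter-fix gap exceeds this.
#' @param community optional community (landing port) label for the trips.
#' @return The fix data.frame with added \code{trip_id} (\code{"<fisher>_t<k>"})
#'   and \code{community} columns.
#' @export
segment_trips <- function(fixes, gap_threshold = 4 * 3600, community = NA_character_) {
  if (nrow(fixes) == 0) {
    fixes$trip_id <- character(0); fixes$community <- character(0)
    return(fixes)
  }
  if (length(unique(fixes$fisher_id)) > 1)
    stop("segment_trips expects fixes of a single fisher; split first",
         call. = FALSE)
  dt <- diff(as.numeric(fixes$timestamp))
  if (any(dt < 0)) stop("fixes are not time-sorted", call. = FALSE)
  grp <- cumsum(c(1, as.integer(dt > gap_threshold)))
  sizes <- tabulate(grp)
  keep <- sizes[grp] >= 2
  if (any(!keep))
    warning(sum(!keep), " single-fix trip(s) discarded for fisher ",
            fixes$fisher_id[1], call. = FALSE)
  # renumber surviving trips consecutively
  ids <- rep(NA_character_, nrow(fixes))
  kept_grps <- unique(grp[keep])
  for (k in seq_along(kept_grps))
    ids[grp == kept_grps[k]] <- sprintf("%s_t%02d", fixes$fisher_id[1], k)
  fixes$trip_id <- ids
  fixes$community <- community
  fixes
}

#' Per-trip summary table
#'
#' @param fixes fix data.frame with a \code{trip_id} column (see
#'   \code{\link{segment_trips}}); rows with \code{NA} trip are ignored.
#' @return data.frame with one row per trip: \code{trip_id},
#'   \code{fisher_id}, \code{community}, \code{date} (UTC date of first fix),
#'   \code{n_fixes}, \code{start}, \code{end}.
#' @export
trip_table <- function(fixes) {
  f <- fixes[!is.na(fixes$trip_id), , drop = FALSE]
  if (nrow(f) == 0)
    return(data.frame(trip_id = character(0), fisher_id = character(0),
                      community = character(0), date = as.Date(character(0)),
                      n_fixes = integer(0)))
  sp <- split(f, f$trip_id)
  out <- do.call(rbind, lapply(sp, function(t) {
    data.frame(trip_id = t$trip_id[1], fisher_id = t$fisher_id[1],
               community = if ("community" %in% names(t)) t$community[1] else NA,
               date = as.Date(min(t$timestamp), tz = "UTC"),
               n_fixes = nrow(t),
               start = min(t$timestamp), end = max(t$timestamp),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$trip_id), , drop = FALSE]
}

LOGBOOK_COLUMNS <- c("date", "time", "fisher_id", "community", "folk_name",
                     "species", "n_individuals", "life_stage", "sex")

#' Read a sighting logbook
#'
#' Reads the CSV logbook kept by the captains (one row per sighting event)
#' and validates it: the header must contain all documented columns, each
#' sighting involves at least one individual, and species names, when given,
#' must belong to the five-species Southwest Atlantic registry. Folk names
#' are kept verbatim; rows identified only as "turtle" carry an empty
#' species.
#'
#' @param path CSV file with header columns \code{date,time,fisher_id,
#'   community,folk_name,species,n_individuals,life_stage,sex}.
#' @return data.frame of sighting records; \code{date} parsed as Date,
#'   \code{species} is \code{NA} where blank.
#' @export
read_logbook <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(LOGBOOK_COLUMNS, names(df))
  if (length(miss))
    stop("logbook schema error, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$date <- as.Date(df$date)
  df$n_individuals <- as.integer(df$n_individuals)
  df$species[!nzchar(trimws(df$species))] <- NA_character_
  if (anyNA(df$date)) stop("unparseable date in logbook", call. = FALSE)
  if (anyNA(df$n_individuals) || any(df$n_individuals < 1))
    stop("logbook validation error: n_individuals must be >= 1 on every row",
         call. = FALSE)
  bad_sp <- setdiff(stats::na.omit(unique(df$species)), rmu_species())
  if (length(bad_sp))
    stop("species outside the Southwest Atlantic RMU registry: ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  df$life_stage[!df$life_stage %in% c("adult", "juvenile")] <- "unknown"
  df$sex[!df$sex %in% c("male", "female")] <- "unknown"
  df
}

#' @rdname read_logbook
#' @param records sighting record data.frame to write.
#' @export
write_logbook <- function(records, path) {
  out <- records[, LOGBOOK_COLUMNS]
  out$species[is.na(out$species)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.logbook_utc <- function(records, tz_offset_hours) {
  tstr <- ifelse(grepl("^[0-9]{1,2}:[0-9]{2}$", records$time),
                 paste0(records$time, ":00"), records$time)
  local <- as.POSIXct(paste(records$date, tstr),
                      format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  if (anyNA(local)) stop("unparseable time in logbook records", call. = FALSE)
  local - tz_offset_hours * 3600
}

#' Associate sightings with GPS fixes
#'
#' For each logbook record, finds the fix from the same fisher on the same
#' (local) day that minimizes the absolute time difference. Records whose
#' nearest fix is farther than \code{tolerance} seconds away -- or whose
#' fisher has no fixes that day -- are returned unmatched (flagged, never
#' dropped: they still feed the ethnobiological tables, only the spatial
#' layers require a position). Logbook clock times are local; GPX is UTC.
#'
#' @param records sighting records (see \code{\link{read_logbook}}).
#' @param fixes fix data.frame across all fishers.
#' @param tolerance seconds; default 150 (half the 5-min fix interval). An
#'   exact tie between two equidistant fixes goes to the earlier fix.
#' @param tz_offset_hours logbook local-time offset from UTC (default -3).
#' @return \code{records} with added columns \code{matched} (logical),
#'   \code{lat}, \code{lon}, \code{fix_time}, \code{time_offset} (seconds,
#'   fix minus sighting).
#' @export
match_sightings <- function(records, fixes, tolerance = 150,
                            tz_offset_hours = -3) {
  rec_utc <- .logbook_utc(records, tz_offset_hours)
  fix_local_date <- as.Date(fixes$timestamp + tz_offset_hours * 3600, tz = "UTC")
  records$matched <- FALSE
  records$lat <- NA_real_; records$lon <- NA_real_
  records$fix_time <- as.POSIXct(NA, tz = "UTC")
  records$time_offset <- NA_real_
  for (i in seq_len(nrow(records))) {
    cand <- which(fixes$fisher_id == records$fisher_id[i] &
                    fix_local_date == records$date[i])
    if (!length(cand)) next
    dt <- as.numeric(fixes$timestamp[cand]) - as.numeric(rec_utc[i])
    best <- abs(dt)
    j <- which(best == min(best))
    if (length(j) > 1)  # tie: earlier fix
      j <- j[which.min(as.numeric(fixes$timestamp[cand][j]))]
    records$time_offset[i] <- dt[j]
    records$fix_time[i] <- fixes$timestamp[cand][j]
    if (abs(dt[j]) <= tolerance) {
      records$matched[i] <- TRUE
      records$lat[i] <- fixes$lat[cand][j]
      records$lon[i] <- fixes$lon[cand][j]
    }
  }
  records
}
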