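# Reading, cleaning and describing Argos location streams.
#
# A track is a tibble of time-ordered Doppler fixes (columns `date`, `lat`,
# `lon`, `lc`) carrying per-animal metadata (id, tagging location and date) as
# attributes. Location classes follow the Argos convention {3,2,1,0,A,B,Z} in
# decreasing accuracy; class Z marks a failed localization and is removed by
# `clean_track()` before any analysis.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")

#' Construct a whale track
#'
#' @param data data frame with columns `date` (POSIXct, UTC), `lat`, `lon`,
#'   `lc` (Argos location class as character).
#' @param animal_id animal identifier (coerced to character).
#' @param tagging_location optional `c(lat, lon)`; defaults to the first fix.
#' @param tagging_date optional `Date`; defaults to the date of the first fix.
#' @return a `whale_track`: a tibble with metadata attributes.
#' @export
whale_track <- function(data, animal_id,
                        tagging_location = NULL, tagging_date = NULL) {
  data <- as_tibble(data)[, c("date", "lat", "lon", "lc")]
  if (!inherits(data$date, "POSIXct"))
    abort("`date` must be POSIXct (UTC)")
  attr(data$date, "tzone") <- "UTC"
  data$lc <- as.character(data$lc)
  bad_lc <- setdiff(unique(data$lc), ARGOS_CLASSES)
  if (length(bad_lc))
    abort(paste0("unknown Argos location class: ",
                 paste(bad_lc, collapse = ", ")))
  if (any(!is.finite(data$lat)) || any(!is.finite(data$lon)))
    abort("non-finite coordinates in track")
  if (any(abs(data$lat) > 90) || any(abs(data$lon) > 180))
    abort("coordinates outside [-90,90] x [-180,180]")
  data <- data[order(data$date), ]
  structure(data,
            class = c("whale_track", class(data)),
            animal_id = as.character(animal_id),
            tagging_location =
              if (is.null(tagging_location))
                c(lat = data$lat[1], lon = data$lon[1])
              else c(lat = unname(tagging_location[1]),
                     lon = unname(tagging_location[2])),
            tagging_date =
              if (is.null(tagging_date)) as.Date(data$date[1]) else
                as.Date(tagging_date))
}

#' @export
print.whale_track <- function(x, ...) {
  cat(sprintf("<whale_track> animal %s: %d fixes, %s to %s\n",
              animal_id(x), nrow(x),
              format(min(x$date)), format(max(x$date))))
  NextMethod()
}

#' Track metadata accessors
#' @param t a `whale_track`.
#' @export
animal_id <- function(t) attr(t, "animal_id")

#' @rdname animal_id
#' @export
tagging_location <- function(t) attr(t, "tagging_location")

#' @rdname animal_id
#' @export
tagging_date <- function(t) attr(t, "tagging_date")

# keep_track_attrs: dplyr/`[` drop custom attributes; re-attach them.
restamp <- function(new, old) {
  whale_track(new, animal_id(old), tagging_location(old), tagging_date(old))
}

#' Input dialect for delimited location tables
#'
#' Column names may be given as character vectors of candidates; the first
#' one present in the file is used. Defaults accept both the
#' Wildlife-Computers "-Locations.csv" layout (`DeployID`/`Ptt`, `Date`,
#' `Quality`, `Latitude`, `Longitude`) and this package's canonical export
#' (`id`, `timestamp_iso8601`, `lat`, `lon`, `lc`).
#'
#' @param id,timestamp,lat,lon,lc candidate column names.
#' @param delim field delimiter.
#' @param time_formats formats tried in order by [strptime()]; timestamps are
#'   always interpreted as GMT/UTC (tags are programmed in GMT).
#' @export
locations_dialect <- function(id = c("id", "DeployID", "Ptt"),
                              timestamp = c("timestamp_iso8601", "timestamp",
                                            "Date"),
                              lat = c("lat", "Latitude"),
                              lon = c("lon", "Longitude"),
                              lc = c("lc", "Quality", "loc_class"),
                              delim = ",",
                              time_formats = c("%Y-%m-%dT%H:%M:%OSZ",
                                               "%Y-%m-%d %H:%M:%OS",
                                               "%H:%M:%S %d-%b-%Y")) {
  list(id = id, timestamp = timestamp, lat = lat, lon = lon, lc = lc,
       delim = delim, time_formats = time_formats)
}

pick_col <- function(nms, candidates, what) {
  hit <- candidates[candidates %in% nms]
  if (!length(hit))
    abort(paste0("required column for ", what, " not found; looked for: ",
                 paste(candidates, collapse = ", ")))
  hit[1]
}

parse_times <- function(x, formats) {
  out <- rep(as.POSIXct(NA), length(x))
  left <- !is.na(x)
  for (f in formats) {
    if (!any(left)) break
    p <- as.POSIXct(strptime(x[left], f, tz = "UTC"))
    ok <- !is.na(p)
    out[which(left)[ok]] <- p[ok]
    left[which(left)[ok]] <- FALSE
  }
  out
}

#' Read Argos location tables into tracks
#'
#' Reads a delimited table of Doppler fixes and splits it into one
#' [whale_track()] per animal, time-sorted. Rows whose timestamp or
#' coordinates cannot be parsed are reported via a warning and returned in the
#' `bad_rows` attribute of the result, never silently dropped. Class-Z fixes
#' are retained at this stage (they are removed by [clean_track()]).
#'
#' @param path delimited text file.
#' @param dialect a [locations_dialect()].
#' @return named list of `whale_track` (possibly empty, with a warning).
#' @export
read_locations <- function(path, dialect = locations_dialect()) {
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0) {
    warn(paste0("no rows in ", path))
    return(structure(list(), bad_rows = raw))
  }
  nms <- names(raw)
  cid <- pick_col(nms, dialect$id, "animal id")
  cts <- pick_col(nms, dialect$timestamp, "timestamp")
  cla <- pick_col(nms, dialect$lat, "latitude")
  clo <- pick_col(nms, dialect$lon, "longitude")
  clc <- pick_col(nms, dialect$lc, "location class")
  parsed <- tibble(
    id = raw[[cid]],
    date = parse_times(raw[[cts]], dialect$time_formats),
    lat = suppressWarnings(as.numeric(raw[[cla]])),
    lon = suppressWarnings(as.numeric(raw[[clo]])),
    lc = toupper(trimws(raw[[clc]])))
  ok <- !is.na(parsed$date) & is.finite(parsed$lat) & is.finite(parsed$lon) &
    parsed$lc %in% ARGOS_CLASSES
  if (any(!ok))
    warn(sprintf("%d unparseable row(s) in %s (rows %s); kept in `bad_rows`",
                 sum(!ok), path,
                 paste(utils::head(which(!ok), 10), collapse = ",")))
  good <- parsed[ok, ]
  tracks <- lapply(split(good, good$id), function(d)
    whale_track(d[, c("date", "lat", "lon", "lc")], animal_id = d$id[1]))
  structure(tracks[order(names(tracks))], bad_rows = raw[!ok, ])
}

#' Write tracks to the canonical location CSV
#'
#' Columns: `id`, `timestamp_iso8601`, `lat`, `lon`, `lc`.
#'
#' @param tracks a `whale_track` or list of them.
#' @param path output file.
#' @export
write_locations <- function(tracks, path) {
  if (inherits(tracks, "whale_track")) tracks <- list(tracks)
  rows <- dplyr::bind_rows(lapply(tracks, function(t)
    tibble(id = animal_id(t),
           timestamp_iso8601 = format(t$date, "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
           lat = t$lat, lon = t$lon, lc = t$lc)))
  readr::write_csv(rows, path)
  invisible(path)
}

#' Export a track as a GeoJSON LineString
#' @param t a `whale_track` (or regularized track with `lat`/`lon`).
#' @param path optional file; if `NULL`, the GeoJSON string is returned.
#' @export
track_geojson <- function(t, path = NULL) {
  gj <- list(type = "Feature",
             properties = list(animal_id = attr(t, "animal_id")),
             geometry = list(type = "LineString",
                             coordinates = unname(
                               Map(c, t$lon, t$lat))))
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Clean a track: drop class-Z fixes, enforce strictly increasing times
#'
#' Failed localizations (class Z) are removed first; any timestamp equal to
#' (or, after sorting, not later than) its predecessor is then shifted
#' forward by 1 s, repeatedly, until timestamps are strictly increasing.
#' Idempotent.
#'
#' @param t a `whale_track`.
#' @return cleaned `whale_track`.
#' @export
clean_track <- function(t) {
  kept <- t[t$lc != "Z", ]
  if (nrow(kept) == 0)
    abort(paste0("track ", animal_id(t), " empty after cleaning"),
          class = "whalemigrate_empty_track")
  kept <- kept[order(kept$date), ]
  d <- as.numeric(kept$date)
  if (nrow(kept) > 1)
    for (i in 2:length(d)) if (d[i] <= d[i - 1]) d[i] <- d[i - 1] + 1
  kept$date <- as.POSIXct(d, origin = "1970-01-01", tz = "UTC")
  restamp(kept, t)
}

#' Per-track deployment metadata
#'
#' Summaries of tag performance: duration, coverage, sampling interval, and
#' transmission gaps longer than a threshold (72 h by default, the gap length
#' beyond which tracks are split for behavioural analyses).
#'
#' @param t a cleaned `whale_track` with at least 2 fixes.
#' @param gap_threshold_h gap-counting threshold, hours.
#' @return one-row tibble: `animal_id`, `track_duration_d`,
#'   `n_days_with_locations`, `n_locations`, `mean_time_step_h`, `max_gap_d`,
#'   `n_gaps_gt_threshold`.
#' @export
track_meta <- function(t, gap_threshold_h = 72) {
  if (nrow(t) < 2)
    abort("track metadata undefined for < 2 locations",
          class = "whalemigrate_undefined_metrics")
  span_h <- as.numeric(difftime(max(t$date), min(t$date), units = "hours"))
  gaps_h <- as.numeric(diff(t$date), units = "secs") / 3600
  tibble(
    animal_id = animal_id(t),
    track_duration_d = span_h / 24,
    n_days_with_locations = length(unique(as.Date(t$date))),
    n_locations = nrow(t),
    mean_time_step_h = span_h / (nrow(t) - 1),
    max_gap_d = max(gaps_h) / 24,
    n_gaps_gt_threshold = sum(gaps_h > gap_threshold_h))
}
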