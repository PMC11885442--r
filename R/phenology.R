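# Migration phenology: classify migrants by maximum displacement from the
# tagging site, delineate the northern foraging polygon from the
# non-migrants' tracks (100% minimum convex polygon), and date the four
# migration events per animal:
#   departure       last exit from the foraging polygon not followed by a
#                   re-entry (a re-entry that happens after the whale has
#                   been to the breeding grounds is the northbound return,
#                   not a cancellation of departure);
#   arrival         first 2-h position south of 45 N where the
#                   loess-smoothed speed is decreasing;
#   breeding dep.   first post-arrival position north of the cohort mean
#                   arrival latitude;
#   return          first re-entry into the foraging polygon afterwards.
# Durations are whole-day differences of the event dates (GMT calendar).

#' Classify an animal as migrant or non-migrant
#'
#' Maximum great-circle displacement from the tagging location; animals whose
#' maximum reaches `threshold_km` (1,000 km by default, the antimode of the
#' strongly bimodal displacement distribution of tagged whales) are migrants.
#'
#' @param t cleaned `whale_track`.
#' @param threshold_km classification threshold; the boundary value itself
#'   classifies as migrant.
#' @return one-row tibble: `animal_id`, `max_displacement_km`, `is_migrant`.
#' @export
classify_migrant <- function(t, threshold_km = 1000) {
  tl <- tagging_location(t)
  d <- great_circle_km(tl["lat"], tl["lon"], t$lat, t$lon)
  tibble(animal_id = animal_id(t),
         max_displacement_km = max(d),
         is_migrant = max(d) >= threshold_km)
}

# ---- minimum convex polygons ------------------------------------------------

#' 100% minimum convex polygon of a point set
#'
#' Convex hull of the points, with its area computed in a local Lambert
#' azimuthal equal-area plane. Vertices are returned in counter-clockwise
#' order.
#'
#' @param lat,lon point coordinates, degrees.
#' @param origin optional projection origin `c(lat, lon)`; defaults to the
#'   point centroid.
#' @return a `whale_polygon`: list with `vertices` (tibble `lat`, `lon`,
#'   `x_km`, `y_km`), `area_km2`, `origin`, `n_points`.
#' @export
mcp_polygon <- function(lat, lon, origin = NULL) {
  keep <- is.finite(lat) & is.finite(lon)
  lat <- lat[keep]; lon <- lon[keep]
  pts <- unique(cbind(lat, lon))
  if (nrow(pts) < 3)
    abort("need at least 3 distinct points for a convex polygon",
          class = "whalemigrate_degenerate_polygon")
  if (is.null(origin)) origin <- c(mean(pts[, 1]), mean(pts[, 2]))
  xy <- proj_laea(pts[, 1], pts[, 2], origin)
  hull <- chull(xy[, 1], xy[, 2])
  if (length(hull) < 3)
    abort("points are collinear; polygon is degenerate",
          class = "whalemigrate_degenerate_polygon")
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (abs(area2) / 2 < 1e-9)
    abort("points are collinear; polygon is degenerate",
          class = "whalemigrate_degenerate_polygon")
  if (area2 < 0) { hull <- rev(hull); hx <- rev(hx); hy <- rev(hy) }
  structure(list(vertices = tibble(lat = pts[hull, 1], lon = pts[hull, 2],
                                   x_km = hx, y_km = hy),
                 area_km2 = abs(area2) / 2,
                 origin = origin,
                 n_points = nrow(pts)),
            class = "whale_polygon")
}

#' @export
print.whale_polygon <- function(x, ...) {
  cat(sprintf("<whale_polygon> %d vertices, area %.0f km2 (from %d points)\n",
              nrow(x$vertices), x$area_km2, x$n_points))
  invisible(x)
}

#' Point-in-polygon test (closed boundary)
#'
#' Tests whether points fall inside or on the boundary of a convex
#' `whale_polygon` (boundary and vertices count as inside).
#'
#' @param poly a `whale_polygon`.
#' @param lat,lon point coordinates.
#' @return logical vector.
#' @export
point_in_polygon <- function(poly, lat, lon) {
  xy <- proj_laea(lat, lon, poly$origin)
  vx <- poly$vertices$x_km; vy <- poly$vertices$y_km
  n <- length(vx)
  inside <- rep(TRUE, nrow(xy))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cross <- (vx[j] - vx[i]) * (xy[, 2] - vy[i]) -
      (vy[j] - vy[i]) * (xy[, 1] - vx[i])
    # tolerance ~ 1 mm * edge length: boundary points count as inside
    edge <- sqrt((vx[j] - vx[i])^2 + (vy[j] - vy[i])^2)
    inside <- inside & (cross >= -1e-6 * max(edge, 1))
  }
  inside
}

#' Delineate the foraging polygon from non-migrant tracks
#'
#' Subsamples each non-migrant track to one location per `subsample_every_d`
#' days (to reduce serial autocorrelation) and returns the 100% minimum
#' convex polygon over the pooled subsample.
#'
#' @param non_migrants list of cleaned `whale_track` for the non-migrating
#'   animals.
#' @param subsample_every_d subsampling period, days.
#' @return a `whale_polygon`.
#' @export
foraging_polygon <- function(non_migrants, subsample_every_d = 2) {
  pts <- dplyr::bind_rows(lapply(non_migrants, function(t) {
    bin <- floor(as.numeric(t$date - t$date[1], units = "days") /
                   subsample_every_d)
    first <- !duplicated(bin)
    tibble(lat = t$lat[first], lon = t$lon[first])
  }))
  mcp_polygon(pts$lat, pts$lon)
}

#' Export a polygon as GeoJSON
#' @param poly a `whale_polygon`.
#' @param path optional file; if `NULL` the GeoJSON string is returned.
#' @export
polygon_geojson <- function(poly, path = NULL) {
  ring <- Map(c, c(poly$vertices$lon, poly$vertices$lon[1]),
              c(poly$vertices$lat, poly$vertices$lat[1]))
  gj <- list(type = "Feature",
             properties = list(area_km2 = poly$area_km2),
             geometry = list(type = "Polygon",
                             coordinates = list(unname(ring))))
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

# ---- event detection --------------------------------------------------------

#' Smoothed speed curve and acceleration proxy
#'
#' Loess-smooths the 2-h segment speeds of a regularized track (tricube
#' weights, span `span`, degree 2) and differentiates the fitted curve by
#' central differences, giving the deceleration/acceleration signal used by
#' the arrival detector.
#'
#' @param rt a segments-only `whale_rtrack`.
#' @param span loess span (fraction of points in each local window).
#' @param degree loess polynomial degree.
#' @return tibble `date`, `lat`, `lon`, `speed_kmh`, `speed_smooth`,
#'   `accel_kmh_per_h`, restricted to steps where speed is defined.
#' @export
smooth_speed_curve <- function(rt, span = 0.2, degree = 2) {
  sm <- step_metrics(rt)
  ok <- !is.na(sm$speed_kmh)
  d <- tibble(date = sm$date[ok], lat = rt$lat[ok], lon = rt$lon[ok],
              speed_kmh = sm$speed_kmh[ok])
  if (nrow(d) < 10)
    abort("too few speed observations for loess smoothing")
  t_h <- as.numeric(d$date - d$date[1], units = "secs") / 3600
  fit <- loess(speed_kmh ~ t_h, data = cbind(d, t_h = t_h), span = span,
               degree = degree, family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  smv <- predict(fit, newdata = data.frame(t_h = t_h))
  n <- length(smv)
  accel <- rep(NA_real_, n)
  if (n >= 3)
    accel[2:(n - 1)] <- (smv[3:n] - smv[1:(n - 2)]) /
      (t_h[3:n] - t_h[1:(n - 2)])
  accel[1] <- accel[2]; accel[n] <- accel[n - 1]
  d$speed_smooth <- smv
  d$accel_kmh_per_h <- accel
  d
}

# exit/entry events of the inside-polygon indicator
crossing_events <- function(inside) {
  n <- length(inside)
  if (n < 2) return(list(exit = integer(0), entry = integer(0)))
  list(exit = which(inside[-n] & !inside[-1]) + 1,
       entry = which(!inside[-n] & inside[-1]) + 1)
}

#' Date the departure from the foraging grounds
#'
#' The migration is taken to start at the last exit from the foraging
#' polygon that is not followed by a re-entry — except that a re-entry
#' occurring after the animal has been south of `breeding_lat` is the
#' northbound return and does not cancel the departure.
#'
#' @param rt whole-track `whale_rtrack` (gap-spanning, so a transmission gap
#'   cannot hide the exit).
#' @param poly the foraging `whale_polygon`.
#' @param breeding_lat latitude delimiting the breeding grounds, degrees N.
#' @return the departure `Date`, or `NA` if the animal never permanently
#'   leaves the polygon.
#' @export
detect_departure <- function(rt, poly, breeding_lat = 45) {
  inside <- point_in_polygon(poly, rt$lat, rt$lon)
  if (!any(inside)) return(as.Date(NA))
  ev <- crossing_events(inside)
  for (e in ev$exit) {
    nxt <- ev$entry[ev$entry > e]
    if (!length(nxt)) return(as.Date(rt$date[e]))
    if (min(rt$lat[e:(nxt[1] - 1)]) < breeding_lat)
      return(as.Date(rt$date[e]))
  }
  as.Date(NA)
}

#' Date the arrival in the breeding area
#'
#' First 2-h position after departure that is both south of `lat_limit`
#' (the 45 N delineation of North Atlantic sperm whale breeding grounds) and
#' decelerating (negative first derivative of the loess-smoothed speed).
#'
#' @param rt segments-only `whale_rtrack` (speeds are only meaningful within
#'   segments).
#' @param departure_date the detected departure `Date`.
#' @param lat_limit breeding-ground latitude limit, degrees N.
#' @param curve optional precomputed [smooth_speed_curve()].
#' @param span loess span used when `curve` is `NULL`.
#' @return the arrival `Date`, or `NA` if the animal never satisfies both
#'   criteria (e.g. tag failure while still in transit).
#' @export
detect_arrival <- function(rt, departure_date, lat_limit = 45,
                           curve = NULL, span = 0.2) {
  if (is.na(departure_date)) return(as.Date(NA))
  if (is.null(curve)) curve <- smooth_speed_curve(rt, span = span)
  hit <- which(as.Date(curve$date) >= departure_date &
                 curve$lat < lat_limit &
                 curve$accel_kmh_per_h < 0)
  if (!length(hit)) return(as.Date(NA))
  structure(as.Date(curve$date[hit[1]]),
            arrival_lat = curve$lat[hit[1]],
            arrival_datetime = curve$date[hit[1]])
}

#' Date the departure from the breeding area
#'
#' First post-arrival position north of `threshold_lat` — by default the
#' cohort mean of the arrival latitudes, so "leaving the breeding area" is
#' judged against the same latitude band the cohort entered through.
#'
#' @param rt whole-track `whale_rtrack`.
#' @param arrival_date the detected arrival `Date`.
#' @param threshold_lat latitude threshold, degrees N (cohort mean arrival
#'   latitude, or the animal's own arrival latitude for a per-individual
#'   variant).
#' @return the breeding-departure `Date`, or `NA` (tag failed in the
#'   breeding area).
#' @export
detect_breeding_departure <- function(rt, arrival_date, threshold_lat) {
  if (is.na(arrival_date)) return(as.Date(NA))
  hit <- which(as.Date(rt$date) > arrival_date & rt$lat > threshold_lat)
  if (!length(hit)) return(as.Date(NA))
  as.Date(rt$date[hit[1]])
}

#' Date the return to the northern foraging grounds
#'
#' First re-entry into the foraging polygon after the breeding departure
#' (polygon boundary counts as inside).
#'
#' @param rt whole-track `whale_rtrack`.
#' @param poly the foraging `whale_polygon`.
#' @param breeding_departure_date the detected breeding-departure `Date`.
#' @return the return `Date`, or `NA` (tag failed during the northbound
#'   transit).
#' @export
detect_return_north <- function(rt, poly, breeding_departure_date) {
  if (is.na(breeding_departure_date)) return(as.Date(NA))
  after <- as.Date(rt$date) > breeding_departure_date
  inside <- point_in_polygon(poly, rt$lat, rt$lon)
  hit <- which(after & inside)
  if (!length(hit)) return(as.Date(NA))
  as.Date(rt$date[hit[1]])
}

#' Whole-day durations between migration event dates
#'
#' @param start,arrival,departure,return event `Date`s (may be `NA`).
#' @return one-row tibble `ns_d`, `breeding_d`, `sn_d`, `whole_cycle_d`
#'   (integer days; `NA` where an event is missing).
#' @export
migration_durations <- function(start, arrival, departure, return) {
  tibble(ns_d = as.integer(arrival - start),
         breeding_d = as.integer(departure - arrival),
         sn_d = as.integer(return - departure),
         whole_cycle_d = as.integer(return - start))
}

#' Per-animal phenology record
#'
#' Assembles the machine-readable migration summary for one animal: event
#' dates, whole-day durations, cumulative great-circle distance per leg
#' (from the whole-track 2-h path), and the maximum displacement from the
#' tagging location.
#'
#' @param animal_id animal identifier.
#' @param events list with `start`, `arrival`, `departure`, `return`
#'   (`Date`s, `NA` allowed).
#' @param rt whole-track `whale_rtrack`.
#' @param tagging_loc `c(lat, lon)` of the tagging site.
#' @param is_migrant logical flag.
#' @return one-row tibble (a PhenologyRecord).
#' @export
summarize_phenology <- function(animal_id, events, rt, tagging_loc,
                                is_migrant = TRUE) {
  ev <- c(events$start, events$arrival, events$departure, events$return)
  pres <- !is.na(ev)
  if (any(diff(ev[pres]) < 0))
    abort(paste0("event dates out of order for animal ", animal_id))
  dur <- migration_durations(events$start, events$arrival,
                             events$departure, events$return)
  if (any(!is.na(dur) & dur == 0))
    warn(paste0("zero-day leg for animal ", animal_id,
                "; identical event dates are suspicious"))
  leg_km <- function(from, to) {
    if (is.na(from) || is.na(to)) return(NA_real_)
    sel <- as.Date(rt$date) >= from & as.Date(rt$date) <= to
    if (sum(sel) < 2) return(NA_real_)
    sub <- rt[sel, ]
    sum(great_circle_km(sub$lat[-nrow(sub)], sub$lon[-nrow(sub)],
                        sub$lat[-1], sub$lon[-1]))
  }
  maxd <- max(great_circle_km(tagging_loc[1], tagging_loc[2],
                              rt$lat, rt$lon))
  tibble(animal_id = animal_id, is_migrant = is_migrant,
         start_migration_date = events$start,
         arrival_breeding_date = events$arrival,
         departure_breeding_date = events$departure,
         return_north_date = events$return,
         !!!dur,
         cum_km_ns = leg_km(events$start, events$arrival),
         cum_km_breeding = leg_km(events$arrival, events$departure),
         cum_km_sn = leg_km(events$departure, events$return),
         cum_km_whole = leg_km(events$start, events$return),
         max_distance_from_tagging_km = maxd)
}

#' Detect all phenology events for a cohort of migrants
#'
#' Two-pass detection: departures and arrivals first (per animal), then the
#' cohort mean arrival latitude defines the breeding-departure threshold,
#' after which breeding departures and returns are dated.
#'
#' @param regs named list (by animal id) of [regularize_track()] results for
#'   the migrating animals.
#' @param poly the foraging `whale_polygon`.
#' @param tracks named list of the cleaned `whale_track`s (for tagging
#'   locations).
#' @param lat_limit breeding latitude delineation, degrees N.
#' @param span loess span for the arrival detector.
#' @param breeding_departure_lat `"cohort"` (mean arrival latitude across
#'   animals) or `"individual"` (each animal's own arrival latitude).
#' @return list with `records` (tibble of PhenologyRecords), `events`,
#'   `mean_arrival_lat`.
#' @export
detect_phenology <- function(regs, poly, tracks, lat_limit = 45,
                             span = 0.2,
                             breeding_departure_lat = c("cohort",
                                                        "individual")) {
  breeding_departure_lat <- match.arg(breeding_departure_lat)
  ids <- names(regs)
  ev <- lapply(ids, function(id) {
    r <- regs[[id]]
    dep <- detect_departure(r$whole_track, poly, breeding_lat = lat_limit)
    arr <- if (!is.null(r$segments_only))
      detect_arrival(r$segments_only, dep, lat_limit = lat_limit,
                     span = span)
    else as.Date(NA)
    arr_lat <- if (!is.na(arr)) attr(arr, "arrival_lat") else NA_real_
    list(start = dep, arrival = as.Date(as.numeric(arr),
                                        origin = "1970-01-01"),
         arrival_lat = arr_lat)
  })
  names(ev) <- ids
  arr_lats <- vapply(ev, function(e) e$arrival_lat, 0)
  mean_arr_lat <- mean(arr_lats, na.rm = TRUE)
  records <- dplyr::bind_rows(lapply(ids, function(id) {
    r <- regs[[id]]
    thr <- if (breeding_departure_lat == "cohort") mean_arr_lat else
      ev[[id]]$arrival_lat
    bdep <- detect_breeding_departure(r$whole_track, ev[[id]]$arrival, thr)
    ret <- detect_return_north(r$whole_track, poly, bdep)
    ev[[id]]$departure <<- bdep
    ev[[id]]$return <<- ret
    summarize_phenology(id,
                        list(start = ev[[id]]$start,
                             arrival = ev[[id]]$arrival,
                             departure = bdep, return = ret),
                        r$whole_track,
                        tagging_location(tracks[[id]]))
  }))
  list(records = records, events = ev, mean_arrival_lat = mean_arr_lat)
}

#' Cohort phenology summary
#'
#' Mean, sample SD (n-1) and range of each leg duration, rounded to whole
#' days, plus the span of departure dates within the calendar year
#' (day-of-year range, since departures are compared across years).
#'
#' @param records tibble of PhenologyRecords.
#' @return list of one-row tibbles: `durations` and `departure_span_d`.
#' @export
cohort_phenology_summary <- function(records) {
  summ <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x))
      return(tibble(n = 0L, mean = NA_real_, sd = NA_real_,
                    min = NA_integer_, max = NA_integer_))
    tibble(n = length(x), mean = round(mean(x)),
           sd = if (length(x) > 1) round(sd(x)) else NA_real_,
           min = min(x), max = max(x))
  }
  durations <- dplyr::bind_rows(
    ns = summ(records$ns_d),
    breeding = summ(records$breeding_d),
    sn = summ(records$sn_d),
    whole_cycle = summ(records$whole_cycle_d),
    .id = "leg")
  doy <- as.integer(format(records$start_migration_date, "%j"))
  list(durations = durations,
       departure_span_d = if (any(!is.na(doy)))
         max(doy, na.rm = TRUE) - min(doy, na.rm = TRUE) else NA_integer_)
}
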