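# Spherical geometry on a sphere of radius 6371 km: great-circle distances,
# initial bearings, and the two local projections the pipeline works in
# (azimuthal equidistant for state-space fitting, Lambert azimuthal
# equal-area for polygon areas and the 50-km grid).

#' Mean Earth radius used throughout the package (km)
#' @export
EARTH_RADIUS_KM <- 6371.0

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle (haversine) distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over all
#' arguments.
#'
#' @param lat1,lon1 origin coordinates, decimal degrees.
#' @param lat2,lon2 destination coordinates, decimal degrees.
#' @return distance in km.
#' @examples
#' great_circle_km(69, 15, 68, 15) # one degree of meridian arc, ~111.19 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' Forward azimuth of the great circle from point 1 to point 2, in degrees
#' clockwise from north, in [0, 360).
#'
#' @inheritParams great_circle_km
#' @return bearing in degrees.
#' @export
initial_bearing_deg <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  th <- atan2(sin(dlam) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam))
  (rad2deg(th) + 360) %% 360
}

# ---- local projections (spherical, closed form) -----------------------------
# Both return/accept km. `origin` is c(lat0, lon0) in degrees.

#' Local azimuthal projections
#'
#' `proj_aeqd()` / `unproj_aeqd()` implement the spherical azimuthal
#' equidistant projection (distances from the origin are exact); it is the
#' working plane for the state-space model. `proj_laea()` / `unproj_laea()`
#' implement the spherical Lambert azimuthal equal-area projection (areas are
#' exact), used for polygon areas and the time-spent-in-area grid. All
#' coordinates in km on a sphere of radius 6371 km.
#'
#' @param lat,lon coordinates, decimal degrees.
#' @param x,y planar coordinates, km.
#' @param origin projection origin `c(lat0, lon0)` in degrees.
#' @return a two-column matrix (`x`,`y` in km, or `lat`,`lon` in degrees).
#' @name projections
NULL

#' @rdname projections
#' @export
proj_aeqd <- function(lat, lon, origin) {
  p0 <- deg2rad(origin[1]); l0 <- deg2rad(origin[2])
  p <- deg2rad(lat); dl <- deg2rad(lon) - l0
  cosc <- pmin(1, pmax(-1, sin(p0) * sin(p) + cos(p0) * cos(p) * cos(dl)))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(p) * sin(dl)
  y <- EARTH_RADIUS_KM * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(dl))
  cbind(x = x, y = y)
}

#' @rdname projections
#' @export
unproj_aeqd <- function(x, y, origin) {
  p0 <- deg2rad(origin[1]); l0 <- deg2rad(origin[2])
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_KM
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  lat <- ifelse(rho < 1e-12, origin[1],
                rad2deg(asin(pmin(1, pmax(-1, cosc * sin(p0) +
                                            y * sinc * cos(p0) / pmax(rho, 1e-300))))))
  lon <- ifelse(rho < 1e-12, origin[2],
                rad2deg(l0 + atan2(x * sinc,
                                   rho * cos(p0) * cosc - y * sin(p0) * sinc)))
  cbind(lat = lat, lon = ((lon + 180) %% 360) - 180)
}

#' @rdname projections
#' @export
proj_laea <- function(lat, lon, origin) {
  p0 <- deg2rad(origin[1]); l0 <- deg2rad(origin[2])
  p <- deg2rad(lat); dl <- deg2rad(lon) - l0
  denom <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(dl)
  if (any(denom < 1e-12))
    abort("point antipodal to projection origin: outside projection validity")
  kp <- sqrt(2 / denom)
  x <- EARTH_RADIUS_KM * kp * cos(p) * sin(dl)
  y <- EARTH_RADIUS_KM * kp * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(dl))
  cbind(x = x, y = y)
}

#' @rdname projections
#' @export
unproj_laea <- function(x, y, origin) {
  p0 <- deg2rad(origin[1]); l0 <- deg2rad(origin[2])
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * EARTH_RADIUS_KM)))
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  lat <- ifelse(rho < 1e-12, origin[1],
                rad2deg(asin(pmin(1, pmax(-1, cosc * sin(p0) +
                                            y * sinc * cos(p0) / pmax(rho, 1e-300))))))
  lon <- ifelse(rho < 1e-12, origin[2],
                rad2deg(l0 + atan2(x * sinc,
                                   rho * cos(p0) * cosc - y * sin(p0) * sinc)))
  cbind(lat = lat, lon = ((lon + 180) %% 360) - 180)
}

# Destination point given start, bearing (deg) and distance (km); used by the
# simulator to advance a path along the sphere.
destination_point <- function(lat, lon, bearing_deg, dist_km) {
  p1 <- deg2rad(lat); l1 <- deg2rad(lon)
  th <- deg2rad(bearing_deg); d <- dist_km / EARTH_RADIUS_KM
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  cbind(lat = rad2deg(p2), lon = ((rad2deg(l2) + 180) %% 360) - 180)
}
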