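# Speed/distance/angle (SDA) plausibility filter, applied to cleaned tracks
# before state-space modelling. Removes fixes implying impossible sustained
# speeds and sharp out-and-back "spikes" typical of poor-quality Argos
# classes. Iterates to a fixed point, removing the single worst violator per
# pass so the result is deterministic.

#' SDA filter configuration
#'
#' @param vmax maximum plausible sustained speed, m/s.
#' @param spike_angles internal angles (degrees) below which a fix is a spike
#'   candidate, paired with `spike_dist_limits`.
#' @param spike_dist_limits leg lengths (m) above which the corresponding
#'   angle test applies.
#' @param gap_exempt_h consecutive fixes separated by more than this many
#'   hours are exempt from the speed test (over such gaps the straight-line
#'   speed no longer bounds plausibility; aligned with the 72-h segmentation
#'   gap by default).
#' @export
filter_config <- function(vmax = 5,
                          spike_angles = c(15, 25),
                          spike_dist_limits = c(2500, 5000),
                          gap_exempt_h = 72) {
  stopifnot(vmax > 0, all(spike_angles > 0), all(spike_angles < 180),
            all(spike_dist_limits > 0),
            !is.unsorted(spike_dist_limits))
  list(vmax = vmax, spike_angles = spike_angles,
       spike_dist_limits = spike_dist_limits, gap_exempt_h = gap_exempt_h)
}

# speeds (m/s) between consecutive rows of a track subset
pair_speed_ms <- function(lat, lon, date) {
  d_km <- great_circle_km(lat[-length(lat)], lon[-length(lon)],
                          lat[-1], lon[-1])
  dt_s <- diff(as.numeric(date))
  d_km * 1000 / dt_s
}

# internal angle (deg) at point 2 of a 1-2-3 triple: 0 = perfect out-and-back,
# 180 = straight line. Computed from great-circle side lengths (spherical
# law of cosines on the triangle's chord angles is overkill at these scales;
# use the planar angle from the three distances).
triple_angle_deg <- function(lat, lon) {
  a <- great_circle_km(lat[2], lon[2], lat[3], lon[3]) # opposite vertex 1
  b <- great_circle_km(lat[1], lon[1], lat[3], lon[3]) # opposite vertex 2
  c <- great_circle_km(lat[1], lon[1], lat[2], lon[2]) # opposite vertex 3
  if (a < 1e-9 || c < 1e-9) return(180)
  arg <- (a^2 + c^2 - b^2) / (2 * a * c)
  rad2deg(acos(pmin(1, pmax(-1, arg))))
}

#' Speed/distance/angle filter
#'
#' Iteratively removes implausible fixes from a cleaned track: interior fixes
#' whose minimum implied great-circle speed to both retained neighbours
#' exceeds `vmax`, and spike fixes whose turning geometry (angle smaller than
#' `spike_angles[k]` with both legs longer than `spike_dist_limits[k]`)
#' marks an out-and-back artefact. The first and last fixes are always
#' retained. When several fixes violate simultaneously, the single worst
#' offender (highest implied speed, then smallest angle) is removed and the
#' test re-run, so the output is a fixed point of the filter.
#'
#' @param t cleaned `whale_track`.
#' @param cfg a [filter_config()].
#' @return list with elements `track` (filtered `whale_track`) and `removed`
#'   (tibble of removed fixes with a `reason` column, `speed` or `spike`).
#' @export
sda_filter <- function(t, cfg = filter_config()) {
  if (nrow(t) < 3) {
    warn("track has < 3 fixes; SDA filter not applied")
    return(list(track = t,
                removed = tibble(date = t$date[0], lat = numeric(0),
                                 lon = numeric(0), lc = character(0),
                                 reason = character(0))))
  }
  n_all <- nrow(t)
  lat <- t$lat; lon <- t$lon; tt <- as.numeric(t$date)
  # doubly-linked list over retained fixes for O(1) local recomputation
  prv <- c(NA_integer_, seq_len(n_all - 1))
  nxt <- c(2:n_all, NA_integer_)
  keep <- rep(TRUE, n_all)
  reason <- character(n_all)
  min_sp <- rep(-Inf, n_all)   # per-interior-fix min neighbour speed (m/s)
  ang <- rep(180, n_all)
  spike <- rep(FALSE, n_all)
  eval_fix <- function(i) {
    p <- prv[i]; q <- nxt[i]
    if (is.na(p) || is.na(q)) {           # endpoint: never removed
      min_sp[i] <<- -Inf; ang[i] <<- 180; spike[i] <<- FALSE
      return(invisible())
    }
    d1 <- great_circle_km(lat[p], lon[p], lat[i], lon[i])
    d2 <- great_circle_km(lat[i], lon[i], lat[q], lon[q])
    dt1 <- (tt[i] - tt[p]) / 3600; dt2 <- (tt[q] - tt[i]) / 3600
    s1 <- if (dt1 > cfg$gap_exempt_h) 0 else d1 * 1000 / (dt1 * 3600)
    s2 <- if (dt2 > cfg$gap_exempt_h) 0 else d2 * 1000 / (dt2 * 3600)
    min_sp[i] <<- min(s1, s2)
    b <- great_circle_km(lat[p], lon[p], lat[q], lon[q])
    a_deg <- if (d1 < 1e-9 || d2 < 1e-9) 180 else {
      arg <- (d1^2 + d2^2 - b^2) / (2 * d1 * d2)
      rad2deg(acos(min(1, max(-1, arg))))
    }
    ang[i] <<- a_deg
    sp <- FALSE
    for (k in seq_along(cfg$spike_angles))
      sp <- sp || (a_deg < cfg$spike_angles[k] &&
                     d1 * 1000 > cfg$spike_dist_limits[k] &&
                     d2 * 1000 > cfg$spike_dist_limits[k])
    spike[i] <<- sp
    invisible()
  }
  for (i in seq_len(n_all)) eval_fix(i)
  repeat {
    viol <- keep & (min_sp > cfg$vmax | spike)
    if (!any(viol)) break
    w <- which(viol)
    worst <- w[order(-min_sp[w], ang[w])][1]
    keep[worst] <- FALSE
    reason[worst] <- if (min_sp[worst] > cfg$vmax) "speed" else "spike"
    p <- prv[worst]; q <- nxt[worst]
    if (!is.na(p)) nxt[p] <- q
    if (!is.na(q)) prv[q] <- p
    min_sp[worst] <- -Inf; spike[worst] <- FALSE; ang[worst] <- 180
    if (!is.na(p)) eval_fix(p)
    if (!is.na(q)) eval_fix(q)
  }
  removed <- tibble(date = t$date[!keep], lat = t$lat[!keep],
                    lon = t$lon[!keep], lc = t$lc[!keep],
                    reason = reason[!keep])
  list(track = restamp(t[keep, ], t), removed = removed)
}
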