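# Synthetic tag data with known ground truth. The generator emulates the
# structure the analysis assumes: multi-phase movement (Ornstein-Uhlenbeck
# home-range behaviour on the northern foraging grounds, a fast biased
# south-westward transit, slower correlated roaming south of 45 N, a
# northbound return), irregular surfacing-driven Argos sampling with
# class-dependent position error and multi-day transmission gaps, and
# per-phase binned dive records. Every simulated animal carries its true
# continuous path and true event dates so detector accuracy can be measured.

#' Cohort simulation configuration
#'
#' Defaults emulate the study conditions of the tagged Arctic cohort:
#' tagging along the shelf edge between 69 N and 79 N, transit speeds of
#' 4.7 km/h southbound and 4.4 km/h northbound, breeding-area roaming at
#' 3.5 km/h south of 45 N with residencies of 51-102 d, foraging-phase
#' home-range SD of 50 km, and a B-heavy Argos class mix with occasional
#' multi-day transmission gaps.
#'
#' @param seed mandatory integer seed; the whole cohort is reproducible from
#'   it.
#' @param n_migrants,n_non_migrants cohort composition.
#' @param tagging_line two `c(lat, lon)` endpoints of the shelf-edge
#'   tagging line; foraging centres are drawn along it.
#' @param foraging_sd_km stationary SD of the foraging OU process, km.
#' @param foraging_speed_kmh target mean horizontal speed while foraging.
#' @param transit_speed_kmh,sn_speed_kmh,breeding_speed_kmh mean speeds of
#'   the southbound transit, northbound transit, breeding roaming.
#' @param speed_sd_kmh per-step SD around the phase mean speed.
#' @param departure_after_d range (days after tagging) of the migration
#'   departure.
#' @param breeding_duration_d range of the planned breeding residency, days.
#' @param breeding_target_lat,breeding_target_lon ranges from which each
#'   migrant's breeding destination is drawn.
#' @param end_after_return_d tag lifetime after the northern return, days.
#' @param resident_duration_d tracking-duration range for non-migrants.
#' @param step_h fine simulation step, hours.
#' @param argos list: `mean_step_h` (mean inter-fix interval),
#'   `class_probs`, `class_sd_km` (isotropic error SD per class, km),
#'   `gap_rate_per_d`, `gap_meanlog_h`, `gap_sdlog` (Poisson gap starts with
#'   log-normal durations; defaults produce occasional >72-h gaps).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_migrants = 12, n_non_migrants = 14,
                       tagging_line = list(start = c(69.3, 16.2),
                                           end = c(79.2, 8.0)),
                       foraging_sd_km = 50,
                       foraging_speed_kmh = 2.0,
                       transit_speed_kmh = 4.7,
                       sn_speed_kmh = 4.4,
                       breeding_speed_kmh = 3.5,
                       speed_sd_kmh = 1.0,
                       departure_after_d = c(30, 90),
                       breeding_duration_d = c(51, 102),
                       breeding_target_lat = c(26, 38),
                       breeding_target_lon = c(-55, -20),
                       end_after_return_d = 30,
                       resident_duration_d = c(40, 220),
                       step_h = 0.5,
                       argos = list()) {
  if (missing(seed) || !is.finite(seed)) abort("`seed` is mandatory")
  argos_def <- list(
    mean_step_h = 2.5,
    class_probs = c("3" = 0.03, "2" = 0.05, "1" = 0.08, "0" = 0.10,
                    "A" = 0.16, "B" = 0.53, "Z" = 0.05),
    class_sd_km = c("3" = 0.25, "2" = 0.5, "1" = 1.5, "0" = 5,
                    "A" = 5, "B" = 10, "Z" = 50),
    gap_rate_per_d = 1 / 45,
    gap_meanlog_h = log(60),
    gap_sdlog = 0.7)
  argos <- utils::modifyList(argos_def, argos)
  stopifnot(foraging_sd_km > 0, step_h > 0, transit_speed_kmh > 0)
  structure(list(seed = as.integer(seed),
                 n_migrants = n_migrants, n_non_migrants = n_non_migrants,
                 tagging_line = tagging_line,
                 foraging_sd_km = foraging_sd_km,
                 foraging_speed_kmh = foraging_speed_kmh,
                 transit_speed_kmh = transit_speed_kmh,
                 sn_speed_kmh = sn_speed_kmh,
                 breeding_speed_kmh = breeding_speed_kmh,
                 speed_sd_kmh = speed_sd_kmh,
                 departure_after_d = departure_after_d,
                 breeding_duration_d = breeding_duration_d,
                 breeding_target_lat = breeding_target_lat,
                 breeding_target_lon = breeding_target_lon,
                 end_after_return_d = end_after_return_d,
                 resident_duration_d = resident_duration_d,
                 step_h = step_h, argos = argos),
            class = "sim_config")
}

# OU relaxation time chosen so the foraging-phase 2-h displacement matches
# the target mean speed given the stationary SD (2-D Rayleigh mean).
ou_tau_h <- function(sd_km, speed_kmh) {
  disp_2h <- speed_kmh * 2
  per_axis <- disp_2h / sqrt(pi / 2)
  4 * sd_km^2 / per_axis^2   # tau from per-axis step SD ~ sd*sqrt(2*dt/tau)
}

#' Simulate one animal's true path and Argos observations
#'
#' @param plan per-animal plan, as built by [simulate_cohort()]; a list with
#'   the animal's id, type, tagging date, foraging centre, phase schedule
#'   and the shared configuration. See `sim_config()` for the movement
#'   parameters.
#' @return list with `track` (a `whale_track` of noisy Argos fixes),
#'   `truth` (list: `path` tibble of the fine true path with phase labels,
#'   `events` named `Date`s, `leg_km` true path length per leg,
#'   `center` the foraging centre).
#' @export
simulate_track <- function(plan) {
  cfg <- plan$cfg
  set.seed(plan$seed)
  step_h <- cfg$step_h
  tau <- ou_tau_h(cfg$foraging_sd_km, cfg$foraging_speed_kmh)
  a_ou <- exp(-step_h / tau)
  s_ou <- cfg$foraging_sd_km * sqrt(1 - a_ou^2)
  center <- plan$foraging_center

  max_steps <- ceiling(400 * 24 / step_h)
  lat <- lon <- phase_v <- numeric(0)
  # state
  cur <- center + c(rnorm(1) * cfg$foraging_sd_km / 111.19,
                    rnorm(1) * cfg$foraging_sd_km /
                      (111.19 * cos(deg2rad(center[1]))))
  ou_xy <- proj_aeqd(cur[1], cur[2], center)[1, ]
  state <- "foraging"
  t_h <- 0
  dep_h <- plan$departure_d * 24
  arr_h <- bdep_h <- bdep_cross_h <- ret_h <- NA_real_
  end_h <- if (plan$type == "resident") plan$duration_d * 24 else Inf
  head_dev <- 0
  pref_head <- NA_real_
  pref_left_h <- 0
  out_lat <- numeric(max_steps); out_lon <- numeric(max_steps)
  out_phase <- character(max_steps)
  i <- 0
  while (t_h <= end_h && i < max_steps) {
    i <- i + 1
    out_lat[i] <- cur[1]; out_lon[i] <- cur[2]
    out_phase[i] <- if (state %in% c("foraging", "foraging2")) "foraging"
      else if (state == "transit") "N-S"
      else if (state == "breeding") "breeding" else "S-N"
    # advance
    if (state %in% c("foraging", "foraging2")) {
      ou_xy <- ou_xy * a_ou + rnorm(2, 0, s_ou)
      cur <- unproj_aeqd(ou_xy[1], ou_xy[2], center)[1, ]
      if (state == "foraging" && plan$type == "migrant" &&
          t_h + step_h >= dep_h) {
        state <- "transit"
        head_dev <- 0
      }
    } else {
      sp <- switch(state,
                   transit = cfg$transit_speed_kmh,
                   breeding = cfg$breeding_speed_kmh,
                   sn = cfg$sn_speed_kmh)
      sp <- max(0.3, rnorm(1, sp, cfg$speed_sd_kmh))
      if (state == "transit") {
        base <- initial_bearing_deg(cur[1], cur[2],
                                    plan$breeding_target[1],
                                    plan$breeding_target[2])
        head_dev <- 0.9 * head_dev + rnorm(1, 0, 5)
        hd <- base + head_dev
      } else if (state == "breeding") {
        if (pref_left_h <= 0) {
          pref_head <- runif(1, 0, 360)
          pref_left_h <- runif(1, 2, 6) * 24
        }
        pref_left_h <- pref_left_h - step_h
        # keep the roaming inside the breeding band
        if (cur[1] > plan$breeding_lat_limit - 1) pref_head <- 180
        if (cur[1] < 18) pref_head <- 0
        if (cur[2] < cfg$breeding_target_lon[1] - 8) pref_head <- 90
        if (cur[2] > cfg$breeding_target_lon[2] + 8) pref_head <- 270
        dd <- ((pref_head - (pref_head + head_dev)) + 540) %% 360 - 180
        head_dev <- head_dev + 0.1 * dd + rnorm(1, 0, 10)
        hd <- pref_head + head_dev
      } else { # sn
        base <- initial_bearing_deg(cur[1], cur[2], center[1], center[2])
        head_dev <- 0.9 * head_dev + rnorm(1, 0, 5)
        hd <- base + head_dev
      }
      cur <- destination_point(cur[1], cur[2], hd, sp * step_h)[1, ]
      if (state == "transit") {
        done <- if (plan$transit_end == "latitude")
          cur[1] < plan$breeding_lat_limit
        else t_h + step_h - dep_h >= plan$transit_duration_d * 24
        if (is.na(arr_h) && cur[1] < plan$breeding_lat_limit)
          arr_h <- t_h + step_h
        if (done) {
          if (plan$transit_end == "duration") { end_h <- t_h }
          else {
            state <- "breeding"
            bdep_h <- arr_h + plan$breeding_duration_d * 24
            head_dev <- 0; pref_left_h <- 0
          }
        }
      } else if (state == "breeding") {
        if (t_h + step_h >= bdep_h) { state <- "sn"; head_dev <- 0 }
      } else if (state == "sn") {
        if (is.na(bdep_cross_h) && cur[1] > plan$breeding_lat_limit)
          bdep_cross_h <- t_h + step_h
        dist_home <- great_circle_km(cur[1], cur[2], center[1], center[2])
        if (is.na(ret_h) && dist_home < 2 * cfg$foraging_sd_km)
          ret_h <- t_h + step_h
        if (dist_home < 20) {
          state <- "foraging2"
          ou_xy <- proj_aeqd(cur[1], cur[2], center)[1, ]
          end_h <- t_h + step_h + cfg$end_after_return_d * 24
        }
      }
    }
    t_h <- t_h + step_h
  }
  n <- i
  path <- tibble(
    date = plan$tag_date + seq(0, by = step_h * 3600, length.out = n),
    lat = out_lat[seq_len(n)], lon = out_lon[seq_len(n)],
    phase = out_phase[seq_len(n)])
  # true per-leg path lengths
  stepd <- c(0, great_circle_km(path$lat[-n], path$lon[-n],
                                path$lat[-1], path$lon[-1]))
  cum <- cumsum(stepd)
  t_hours <- seq(0, by = step_h, length.out = n)
  cum_at <- function(h) if (is.na(h)) NA_real_ else
    cum[max(1, sum(t_hours <= h))]
  # truth events use the same geometric semantics the detector measures:
  # arrival = southbound 45 N crossing, breeding departure = northbound
  # re-crossing, return = coming back within 2 home-range SD of the
  # foraging centre
  leg_km <- c(ns = cum_at(arr_h) - cum_at(dep_h),
              breeding = cum_at(bdep_cross_h) - cum_at(arr_h),
              sn = cum_at(ret_h) - cum_at(bdep_cross_h),
              whole = cum_at(ret_h) - cum_at(dep_h))
  ev_date <- function(h) if (is.na(h) || plan$type == "resident")
    as.Date(NA) else as.Date(plan$tag_date + h * 3600)
  events <- list(departure = if (plan$type == "migrant")
                   as.Date(plan$tag_date + dep_h * 3600) else as.Date(NA),
                 arrival = ev_date(arr_h),
                 breeding_departure = ev_date(bdep_cross_h),
                 return_north = ev_date(ret_h))

  # ---- Argos observation process -------------------------------------------
  ar <- cfg$argos
  span_h <- t_hours[n]
  n_fix_max <- ceiling(span_h / ar$mean_step_h * 2) + 10
  fix_t <- cumsum(rgamma(n_fix_max, shape = 2, scale = ar$mean_step_h / 2))
  fix_t <- c(0, fix_t[fix_t < span_h])
  fix_t <- round(fix_t * 3600) / 3600  # tags stamp whole seconds
  if (ar$gap_rate_per_d > 0) {
    n_gap <- rpois(1, span_h / 24 * ar$gap_rate_per_d)
    if (n_gap > 0) {
      g_start <- sort(runif(n_gap, 0, span_h))
      g_dur <- rlnorm(n_gap, ar$gap_meanlog_h, ar$gap_sdlog)
      for (g in seq_len(n_gap))
        fix_t <- fix_t[fix_t < g_start[g] | fix_t > g_start[g] + g_dur[g]]
    }
  }
  true_lat <- approx(t_hours, path$lat, xout = fix_t)$y
  true_lon <- approx(t_hours, path$lon, xout = fix_t)$y
  lc <- sample(names(ar$class_probs), length(fix_t), replace = TRUE,
               prob = ar$class_probs)
  sdk <- unname(ar$class_sd_km[lc])
  obs_lat <- true_lat + rnorm(length(fix_t), 0, sdk) / 111.19
  obs_lon <- true_lon + rnorm(length(fix_t), 0, sdk) /
    (111.19 * cos(deg2rad(true_lat)))
  track <- whale_track(
    tibble(date = plan$tag_date + round(fix_t * 3600),
           lat = obs_lat, lon = obs_lon, lc = lc),
    animal_id = plan$animal_id,
    tagging_location = c(path$lat[1], path$lon[1]),
    tagging_date = as.Date(plan$tag_date))
  list(track = track,
       truth = list(path = path, events = events, leg_km = leg_km,
                    center = center, is_migrant = plan$type == "migrant"))
}

#' Simulate a tagged cohort
#'
#' Draws per-animal plans (tagging dates spread through the year, foraging
#' centres along the tagging line, asynchronous departures) and simulates
#' each animal. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `tracks` (named list of `whale_track`), `truth` (named
#'   list of per-animal truth), `truth_table` (tibble of true event dates
#'   and leg lengths), `plans`.
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  n_tot <- cfg$n_migrants + cfg$n_non_migrants
  types <- c(rep("migrant", cfg$n_migrants),
             rep("resident", cfg$n_non_migrants))
  p0 <- cfg$tagging_line$start; p1 <- cfg$tagging_line$end
  # residents cover the tagging line; migrants forage within the stretch the
  # residents delineate (the phenology method presumes the migrants' foraging
  # spots lie inside the residents' polygon)
  frac_res <- runif(cfg$n_non_migrants)
  frac_mig <- runif(cfg$n_migrants, min(frac_res), max(frac_res))
  frac <- c(frac_mig, frac_res)
  tag_dates <- as.POSIXct("2022-01-01 00:00:00", tz = "UTC") +
    round(runif(n_tot, 0, 364) * 86400)
  plans <- lapply(seq_len(n_tot), function(i) {
    list(animal_id = sprintf("SIM%03d", i),
         type = types[i],
         seed = cfg$seed + 1000L + i,
         cfg = cfg,
         tag_date = tag_dates[i],
         foraging_center = c(p0[1] + frac[i] * (p1[1] - p0[1]),
                             p0[2] + frac[i] * (p1[2] - p0[2])),
         departure_d = runif(1, cfg$departure_after_d[1],
                             cfg$departure_after_d[2]),
         breeding_target = c(runif(1, cfg$breeding_target_lat[1],
                                   cfg$breeding_target_lat[2]),
                             runif(1, cfg$breeding_target_lon[1],
                                   cfg$breeding_target_lon[2])),
         breeding_duration_d = runif(1, cfg$breeding_duration_d[1],
                                     cfg$breeding_duration_d[2]),
         duration_d = runif(1, cfg$resident_duration_d[1],
                            cfg$resident_duration_d[2]),
         breeding_lat_limit = 45,
         transit_end = "latitude",
         transit_duration_d = NA_real_)
  })
  sims <- lapply(plans, simulate_track)
  ids <- vapply(plans, `[[`, "", "animal_id")
  names(sims) <- ids
  truth_table <- dplyr::bind_rows(lapply(ids, function(id) {
    tr <- sims[[id]]$truth
    tibble(animal_id = id, is_migrant = tr$is_migrant,
           departure = tr$events$departure,
           arrival = tr$events$arrival,
           breeding_departure = tr$events$breeding_departure,
           return_north = tr$events$return_north,
           leg_km_ns = tr$leg_km["ns"],
           leg_km_breeding = tr$leg_km["breeding"],
           leg_km_sn = tr$leg_km["sn"])
  }))
  list(tracks = lapply(sims, `[[`, "track"),
       truth = lapply(sims, `[[`, "truth"),
       truth_table = truth_table,
       plans = stats::setNames(plans, ids))
}

# truncated-normal draws by rejection (simple; parameters keep the
# acceptance rate high)
rtnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  left <- seq_len(n)
  while (length(left)) {
    x <- rnorm(length(left), mean, sd)
    ok <- x >= lower & x <= upper
    out[left[ok]] <- x[ok]
    left <- left[!ok]
  }
  out
}

#' Per-phase dive parameters used by the simulator
#'
#' Mean and SD of maximum depth (m) and duration (min) per migration phase,
#' anchored to the per-phase summaries observed on the tagged whales.
#' @export
dive_phase_params <- function() {
  tibble(phase = c("foraging", "N-S", "breeding", "S-N"),
         depth_mean = c(343, 556, 849, 847),
         depth_sd = c(283, 296, 444, 149),
         dur_mean = c(30, 40, 51, 47),
         dur_sd = c(10, 10, 15, 4))
}

#' Simulate single dives and 6-h histograms for one animal
#'
#' Dive times are drawn along the animal's tracking period (about six dives
#' per day); depth and duration come from per-phase truncated normals.
#' Histograms are built by exact binning of the same dives, so
#' histogram/summary consistency is testable by construction.
#'
#' @param truth one animal's truth from [simulate_track()].
#' @param seed integer seed.
#' @param dives_per_day mean dive rate.
#' @param cfg a [dive_bin_config()].
#' @param params per-phase depth/duration parameters, see
#'   [dive_phase_params()].
#' @param animal_id id stamped on the records.
#' @return list with `dives` (tibble) and `histograms` (from
#'   [build_dive_histograms()]).
#' @export
simulate_dives <- function(truth, seed, dives_per_day = 6,
                           cfg = dive_bin_config("B"),
                           params = dive_phase_params(),
                           animal_id = "SIM") {
  set.seed(seed)
  path <- truth$path
  span_h <- as.numeric(max(path$date) - min(path$date), units = "secs") /
    3600
  n_max <- ceiling(span_h / 24 * dives_per_day * 2) + 10
  t_h <- cumsum(rexp(n_max, rate = dives_per_day / 24))
  t_h <- t_h[t_h < span_h]
  dates <- min(path$date) + round(t_h * 3600)
  # phase from the true path (not from detected events)
  ph <- path$phase[pmax(1, findInterval(as.numeric(dates),
                                        as.numeric(path$date)))]
  if (!length(ph))
    return(list(dives = tibble(animal_id = character(0),
                               date = dates[0], max_depth_m = numeric(0),
                               duration_min = numeric(0),
                               phase = character(0)),
                histograms = build_dive_histograms(
                  tibble(animal_id = character(0), date = dates[0],
                         max_depth_m = numeric(0),
                         duration_min = numeric(0)), cfg)))
  pr <- params[match(ph, params$phase), ]
  depth <- rtnorm(length(t_h), pr$depth_mean, pr$depth_sd,
                  lower = cfg$ignore_depth_m, upper = 2500)
  dur <- rtnorm(length(t_h), pr$dur_mean, pr$dur_sd,
                lower = cfg$ignore_duration_min, upper = 95)
  dives <- tibble(animal_id = animal_id, date = dates,
                  max_depth_m = depth, duration_min = dur, phase = ph)
  list(dives = dives,
       histograms = build_dive_histograms(dives, cfg))
}
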