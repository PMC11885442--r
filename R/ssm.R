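# Continuous-time random-walk state-space model over irregular, filtered
# Argos fixes. The latent 2-D position follows Brownian motion with process
# SD sigma (km per sqrt-hour); fixes are observed with isotropic Gaussian
# error whose SD depends on the Argos location class. Fitting and smoothing
# run in a local azimuthal equidistant plane centred on the track centroid
# (a random walk in raw lon/lat degrees distorts badly at 70-79 N), and the
# smoothed states are re-inverted to lat/lon. The two planar coordinates are
# conditionally independent given sigma, so the model reduces to two scalar
# Kalman filters/smoothers.

#' State-space model configuration
#'
#' @param dt_pred prediction interval, hours.
#' @param obs_sd_by_class named vector of isotropic Argos position error SDs
#'   (km) per location class. Defaults are literature-typical one-sigma
#'   errors for Kalman-filter-processed Argos data.
#' @param p0_sd_km SD of the Gaussian prior on the initial position, centred
#'   on the first fix. Large enough to be effectively diffuse; fixed so the
#'   likelihood is well defined.
#' @param sigma_bounds_kmh search interval for the process SD
#'   (km per sqrt-hour).
#' @param tol relative tolerance of the univariate likelihood optimisation.
#' @export
ssm_config <- function(dt_pred = 2,
                       obs_sd_by_class = c("3" = 0.25, "2" = 0.5, "1" = 1.5,
                                           "0" = 5, "A" = 5, "B" = 10),
                       p0_sd_km = 100,
                       sigma_bounds_kmh = c(1e-4, 1e3),
                       tol = 1e-9) {
  stopifnot(dt_pred > 0, all(obs_sd_by_class > 0), p0_sd_km > 0)
  list(dt_pred = dt_pred, obs_sd_by_class = obs_sd_by_class,
       p0_sd_km = p0_sd_km, sigma_bounds_kmh = sigma_bounds_kmh, tol = tol)
}

#' Track segmentation rules
#'
#' Tracks are split at transmission gaps longer than `max_gap_h`; the
#' resulting windows must last at least `min_segment_duration_d` days and
#' carry at least `min_locs_per_day` locations per day spanned (average
#' density; `per_date = TRUE` instead requires every calendar date spanned to
#' hold a fix).
#'
#' @param max_gap_h split threshold, hours.
#' @param min_segment_duration_d minimum window duration, days.
#' @param min_locs_per_day minimum location density, fixes per day.
#' @param per_date logical; strict calendar-date coverage instead of average
#'   density.
#' @export
segment_rules <- function(max_gap_h = 72, min_segment_duration_d = 4,
                          min_locs_per_day = 1, per_date = FALSE) {
  stopifnot(max_gap_h > 0, min_segment_duration_d > 0, min_locs_per_day > 0)
  list(max_gap_h = max_gap_h,
       min_segment_duration_d = min_segment_duration_d,
       min_locs_per_day = min_locs_per_day, per_date = per_date)
}

#' Split a track into analyzable segments
#'
#' @param t filtered `whale_track`.
#' @param rules a [segment_rules()].
#' @return tibble with columns `start`, `end` (POSIXct, at fix times),
#'   `n_locs`; zero rows if no window survives the rules.
#' @export
segment_track <- function(t, rules = segment_rules()) {
  if (nrow(t) == 0)
    return(tibble(start = t$date[0], end = t$date[0], n_locs = integer(0)))
  gaps_h <- as.numeric(diff(t$date), units = "secs") / 3600
  brk <- c(0, cumsum(gaps_h > rules$max_gap_h))
  out <- lapply(split(seq_len(nrow(t)), brk), function(ix) {
    d <- t$date[ix]
    dur_d <- as.numeric(difftime(max(d), min(d), units = "days"))
    if (dur_d < rules$min_segment_duration_d) return(NULL)
    days_spanned <- as.numeric(as.Date(max(d)) - as.Date(min(d))) + 1
    if (rules$per_date) {
      if (length(unique(as.Date(d))) < days_spanned) return(NULL)
    } else {
      if (length(ix) / days_spanned < rules$min_locs_per_day) return(NULL)
    }
    tibble(start = min(d), end = max(d), n_locs = length(ix))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0)
    tibble(start = t$date[0], end = t$date[0], n_locs = integer(0))
  else out[order(out$start), ]
}

# ---- scalar Kalman machinery ------------------------------------------------

# Log-likelihood of one coordinate under the RW model.
# times_h strictly nondecreasing; r_var observation variances.
kf_loglik_1d <- function(times_h, y, r_var, sigma2, m0, p0) {
  n <- length(y)
  m <- m0; P <- p0; ll <- 0
  t_prev <- times_h[1]
  for (i in seq_len(n)) {
    P <- P + sigma2 * (times_h[i] - t_prev)
    S <- P + r_var[i]
    v <- y[i] - m
    ll <- ll - 0.5 * (log(2 * pi * S) + v * v / S)
    K <- P / S
    m <- m + K * v
    P <- (1 - K) * P
    t_prev <- times_h[i]
  }
  ll
}

# Filter + RTS smoother over an augmented time axis. `has_obs` marks rows
# with an observation (y, r_var used there). Returns smoothed and filtered
# moments at every row.
kf_smooth_1d <- function(times_h, has_obs, y, r_var, sigma2, m0, p0) {
  n <- length(times_h)
  m_pred <- P_pred <- m_filt <- P_filt <- numeric(n)
  m <- m0; P <- p0
  t_prev <- times_h[1]
  for (i in seq_len(n)) {
    P <- P + sigma2 * (times_h[i] - t_prev)
    m_pred[i] <- m; P_pred[i] <- P
    if (has_obs[i]) {
      S <- P + r_var[i]
      K <- P / S
      m <- m + K * (y[i] - m)
      P <- (1 - K) * P
    }
    m_filt[i] <- m; P_filt[i] <- P
    t_prev <- times_h[i]
  }
  m_sm <- m_filt; P_sm <- P_filt
  if (n > 1) {
    for (i in (n - 1):1) {
      if (P_pred[i + 1] <= 0) next
      C <- P_filt[i] / P_pred[i + 1]
      m_sm[i] <- m_filt[i] + C * (m_sm[i + 1] - m_pred[i + 1])
      P_sm[i] <- P_filt[i] + C^2 * (P_sm[i + 1] - P_pred[i + 1])
    }
  }
  list(mean = m_sm, var = pmax(P_sm, 0),
       mean_filt = m_filt, var_filt = pmax(P_filt, 0))
}

ssm_obs_frame <- function(t, cfg) {
  origin <- c(mean(t$lat), mean(t$lon))
  xy <- proj_aeqd(t$lat, t$lon, origin)
  r_sd <- unname(cfg$obs_sd_by_class[t$lc])
  if (any(is.na(r_sd)))
    abort("location class without an observation SD in `obs_sd_by_class`")
  list(origin = origin,
       times_h = as.numeric(t$date - t$date[1], units = "secs") / 3600,
       t0 = t$date[1], x = xy[, 1], y = xy[, 2], r_var = r_sd^2)
}

#' Fit the continuous-time random-walk state-space model
#'
#' Maximum-likelihood estimate of the process SD (km per sqrt-hour) of a 2-D
#' Brownian position process observed with class-dependent isotropic Gaussian
#' error, by a Kalman filter over the irregular fix times in a local planar
#' frame.
#'
#' @param t cleaned, filtered `whale_track` with at least 5 fixes.
#' @param cfg an [ssm_config()].
#' @return object of class `whale_ssm`: list with `sigma_kmh` (process SD
#'   per sqrt-hour), `loglik`, `boundary` flag, the observation frame, and
#'   the configuration.
#' @export
fit_ssm <- function(t, cfg = ssm_config()) {
  if (nrow(t) < 5) abort("need >= 5 fixes to fit the SSM")
  ob <- ssm_obs_frame(t, cfg)
  p0 <- cfg$p0_sd_km^2
  nll <- function(log_sigma) {
    s2 <- exp(2 * log_sigma)
    -(kf_loglik_1d(ob$times_h, ob$x, ob$r_var, s2, ob$x[1], p0) +
        kf_loglik_1d(ob$times_h, ob$y, ob$r_var, s2, ob$y[1], p0))
  }
  lb <- log(cfg$sigma_bounds_kmh[1]); ub <- log(cfg$sigma_bounds_kmh[2])
  opt <- tryCatch(optimize(nll, c(lb, ub), tol = max(cfg$tol, 1e-10)),
                  error = function(e)
                    abort(paste0("SSM optimisation failed: ",
                                 conditionMessage(e)),
                          class = "whalemigrate_ssm_failure"))
  if (!is.finite(opt$objective))
    abort("SSM likelihood not finite at optimum",
          class = "whalemigrate_ssm_failure")
  sigma <- exp(opt$minimum)
  structure(list(sigma_kmh = sigma,
                 loglik = -opt$objective,
                 boundary = (opt$minimum - lb < 1e-6) ||
                   (ub - opt$minimum < 1e-6),
                 obs = ob, cfg = cfg, animal_id = animal_id(t)),
            class = "whale_ssm")
}

#' @export
print.whale_ssm <- function(x, ...) {
  cat(sprintf(
    "<whale_ssm> animal %s: sigma = %.3f km/sqrt(h), logLik = %.2f%s\n",
    x$animal_id, x$sigma_kmh, x$loglik,
    if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Predict regular positions from a fitted SSM
#'
#' Runs the Kalman filter and Rauch-Tung-Striebel smoother over the fix times
#' augmented with a regular grid (every `cfg$dt_pred` hours) and returns the
#' smoothed positions and their uncertainties at the grid points. With
#' `dataset_kind = "whole_track"` a single grid spans the full track,
#' predicting across transmission gaps with correspondingly inflated
#' uncertainty; with `"segments_only"` grids are laid only inside the given
#' (or computed) segment windows.
#'
#' @param t the filtered `whale_track` used to fit the model.
#' @param fit a `whale_ssm` from [fit_ssm()].
#' @param dataset_kind `"whole_track"` or `"segments_only"`.
#' @param windows tibble of segment windows (`start`, `end`) as returned by
#'   [segment_track()]; computed with default [segment_rules()] when `NULL`
#'   and `dataset_kind = "segments_only"`.
#' @param cfg an [ssm_config()]; defaults to the one used in `fit`.
#' @return a `whale_rtrack`: tibble with `date`, `lat`, `lon`, `x_km`,
#'   `y_km`, `sd_x_km`, `sd_y_km` (smoothed), `sd_x_filt_km`, `sd_y_filt_km`
#'   (one-sided), `segment_id`; attributes `animal_id`, `dataset_kind`,
#'   `origin`, `dt_h`.
#' @export
predict_regular <- function(t, fit, dataset_kind = c("whole_track",
                                                     "segments_only"),
                            windows = NULL, cfg = fit$cfg) {
  dataset_kind <- match.arg(dataset_kind)
  ob <- fit$obs
  if (dataset_kind == "whole_track") {
    windows <- tibble(start = min(t$date), end = max(t$date))
  } else if (is.null(windows)) {
    windows <- segment_track(t)
  }
  s2 <- fit$sigma_kmh^2
  p0 <- cfg$p0_sd_km^2
  out <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    n_in <- sum(t$date >= windows$start[w] & t$date <= windows$end[w])
    if (n_in < 2) {
      warn(sprintf("segment %d has < 2 fixes; skipped", w))
      next
    }
    grid <- seq(windows$start[w], windows$end[w], by = cfg$dt_pred * 3600)
    grid_h <- as.numeric(grid - ob$t0, units = "secs") / 3600
    aug <- c(ob$times_h, grid_h)
    is_obs <- c(rep(TRUE, length(ob$times_h)), rep(FALSE, length(grid_h)))
    ord <- order(aug, !is_obs)  # observation first at coincident times
    aug <- aug[ord]; is_obs_o <- is_obs[ord]
    yx <- c(ob$x, rep(NA_real_, length(grid_h)))[ord]
    yy <- c(ob$y, rep(NA_real_, length(grid_h)))[ord]
    rv <- c(ob$r_var, rep(NA_real_, length(grid_h)))[ord]
    sx <- kf_smooth_1d(aug, is_obs_o, yx, rv, s2, ob$x[1], p0)
    sy <- kf_smooth_1d(aug, is_obs_o, yy, rv, s2, ob$y[1], p0)
    gpos <- which(!is_obs_o)
    ll <- unproj_aeqd(sx$mean[gpos], sy$mean[gpos], ob$origin)
    out[[w]] <- tibble(
      date = as.POSIXct(aug[gpos] * 3600, origin = ob$t0, tz = "UTC"),
      lat = ll[, "lat"], lon = ll[, "lon"],
      x_km = sx$mean[gpos], y_km = sy$mean[gpos],
      sd_x_km = sqrt(sx$var[gpos]), sd_y_km = sqrt(sy$var[gpos]),
      sd_x_filt_km = sqrt(sx$var_filt[gpos]),
      sd_y_filt_km = sqrt(sy$var_filt[gpos]),
      segment_id = w)
  }
  res <- dplyr::bind_rows(out)
  structure(res,
            class = c("whale_rtrack", class(res)),
            animal_id = fit$animal_id,
            dataset_kind = dataset_kind,
            origin = ob$origin,
            dt_h = cfg$dt_pred)
}

#' Regularize one track end-to-end
#'
#' Convenience wrapper: [clean_track()], [sda_filter()], [fit_ssm()], then
#' [predict_regular()] for both dataset kinds.
#'
#' @param t raw `whale_track`.
#' @param filter_cfg a [filter_config()].
#' @param ssm_cfg an [ssm_config()].
#' @param rules a [segment_rules()].
#' @return list with `whole_track`, `segments_only` (both `whale_rtrack`),
#'   `fit`, `filtered` track, and `removed` fixes.
#' @export
regularize_track <- function(t, filter_cfg = filter_config(),
                             ssm_cfg = ssm_config(),
                             rules = segment_rules()) {
  tc <- clean_track(t)
  fl <- sda_filter(tc, filter_cfg)
  fit <- fit_ssm(fl$track, ssm_cfg)
  segs <- segment_track(fl$track, rules)
  list(whole_track = predict_regular(fl$track, fit, "whole_track"),
       segments_only = if (nrow(segs))
         predict_regular(fl$track, fit, "segments_only", windows = segs)
       else NULL,
       fit = fit, filtered = fl$track, removed = fl$removed,
       segments = segs)
}
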