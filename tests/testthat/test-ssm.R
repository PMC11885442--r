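# Continuous-time random-walk state-space model: segmentation, likelihood,
# smoothing, prediction.

test_that("segmentation splits at >72-h gaps and applies the duration rule", {
  # 10 d of 4-h fixes, no gaps: one segment of 10 d
  t1 <- make_track(lat = rep(70, 61), lon = 15 + 0:60 * 0.01,
                   times = T0 + 0:60 * 4 * 3600)
  s1 <- segment_track(t1)
  expect_equal(nrow(s1), 1)
  expect_equal(as.numeric(difftime(s1$end, s1$start, units = "days")), 10)

  # 10 d with an 80-h hole after day 5: the ~1.7-d remainder is discarded
  tt <- c(T0 + 0:30 * 4 * 3600,
          T0 + 5 * 86400 + 80 * 3600 + 0:10 * 4 * 3600)
  t2 <- make_track(lat = rep(70, length(tt)), lon = rep(15, length(tt)),
                   times = tt)
  s2 <- segment_track(t2)
  expect_equal(nrow(s2), 1)
  expect_equal(as.numeric(difftime(s2$end, s2$start, units = "days")), 5)

  # 3 d of dense fixes: fails the 4-d minimum
  t3 <- make_track(lat = rep(70, 37), lon = rep(15, 37),
                   times = T0 + 0:36 * 7200)
  expect_equal(nrow(segment_track(t3)), 0)
})

test_that("SSM log-likelihood matches the dense GLS oracle to 1e-6", {
  set.seed(21)
  cfg <- ssm_config()
  # 6-fix toy track near (70 N, 10 E)
  x <- cumsum(rnorm(6, 0, 3)); y <- cumsum(rnorm(6, 0, 3))
  ll <- unproj_aeqd(x, y, c(70, 10))
  times <- T0 + cumsum(c(0, runif(5, 1, 5))) * 3600
  t <- make_track(ll[, 1], ll[, 2], times = times,
                  lc = c("3", "1", "B", "0", "2", "A"))
  fit <- fit_ssm(t, cfg)
  ob <- fit$obs
  for (sigma in c(0.5, fit$sigma_kmh, 4)) {
    ours <- whalemigrate:::kf_loglik_1d(ob$times_h, ob$x, ob$r_var,
                                        sigma^2, ob$x[1], cfg$p0_sd_km^2) +
      whalemigrate:::kf_loglik_1d(ob$times_h, ob$y, ob$r_var,
                                  sigma^2, ob$y[1], cfg$p0_sd_km^2)
    oracle <- gls_oracle_1d(ob$times_h, ob$x, ob$r_var, sigma^2,
                            ob$x[1], cfg$p0_sd_km^2)$loglik +
      gls_oracle_1d(ob$times_h, ob$y, ob$r_var, sigma^2,
                    ob$y[1], cfg$p0_sd_km^2)$loglik
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("smoothed states match the dense GLS oracle on a 10-fix track", {
  set.seed(22)
  cfg <- ssm_config()
  x <- cumsum(rnorm(10, 0, 5)); y <- cumsum(rnorm(10, 0, 5))
  ll <- unproj_aeqd(x, y, c(65, -20))
  times <- T0 + cumsum(c(0, runif(9, 2, 6))) * 3600
  t <- make_track(ll[, 1], ll[, 2], times = times, lc = "B")
  fit <- fit_ssm(t, cfg)
  rt <- predict_regular(t, fit, "whole_track")
  ob <- fit$obs
  grid_h <- as.numeric(rt$date - ob$t0, units = "secs") / 3600
  or_x <- gls_oracle_1d(ob$times_h, ob$x, ob$r_var, fit$sigma_kmh^2,
                        ob$x[1], cfg$p0_sd_km^2, pred_times = grid_h)
  or_y <- gls_oracle_1d(ob$times_h, ob$y, ob$r_var, fit$sigma_kmh^2,
                        ob$y[1], cfg$p0_sd_km^2, pred_times = grid_h)
  expect_equal(rt$x_km, or_x$mean, tolerance = 1e-6)
  expect_equal(rt$y_km, or_y$mean, tolerance = 1e-6)
  expect_equal(rt$sd_x_km^2, or_x$var, tolerance = 1e-6)
})

test_that("process SD is recovered within 15% from a dense random walk", {
  set.seed(23)
  sigma_true <- 2.5 # km per sqrt-hour
  n <- 500
  dt <- rep(1, n) # hourly fixes
  x <- cumsum(rnorm(n, 0, sigma_true * sqrt(dt)))
  y <- cumsum(rnorm(n, 0, sigma_true * sqrt(dt)))
  ll <- unproj_aeqd(x, y, c(70, 10))
  t <- make_track(ll[, 1] + rnorm(n, 0, 0.25 / 111.19),
                  ll[, 2] + rnorm(n, 0, 0.25 / 40),
                  times = T0 + cumsum(dt) * 3600, lc = "3")
  fit <- fit_ssm(t)
  expect_lt(abs(fit$sigma_kmh - sigma_true) / sigma_true, 0.15)
  expect_false(fit$boundary)
})

test_that("identical fixes drive the process SD to the boundary, no crash", {
  t <- make_track(lat = rep(70, 8), lon = rep(15, 8), lc = "3")
  fit <- fit_ssm(t)
  expect_lt(fit$sigma_kmh, 0.01)
  expect_true(fit$boundary)
})

test_that("with near-zero observation noise predictions pass through fixes", {
  set.seed(24)
  cfg <- ssm_config(obs_sd_by_class = c("3" = 1e-6, "2" = 1e-6, "1" = 1e-6,
                                        "0" = 1e-6, "A" = 1e-6, "B" = 1e-6))
  x <- cumsum(rnorm(8, 0, 4)); y <- cumsum(rnorm(8, 0, 4))
  ll <- unproj_aeqd(x, y, c(70, 10))
  t <- make_track(ll[, 1], ll[, 2], times = T0 + 0:7 * 4 * 3600, lc = "3")
  fit <- fit_ssm(t, cfg)
  rt <- predict_regular(t, fit, "whole_track")
  at_fix <- rt[rt$date %in% t$date, ]
  expect_equal(at_fix$lat, t$lat[t$date %in% at_fix$date], tolerance = 1e-6)
  expect_equal(at_fix$lon, t$lon[t$date %in% at_fix$date], tolerance = 1e-6)
})

test_that("midpoint prediction between two fixes is the Brownian bridge", {
  # closed form: with negligible obs noise and prior variance, the smoothed
  # state at the midpoint of a 4-h span is the average of the endpoints with
  # variance sigma^2 * (2 * 2) / 4
  sigma <- 3
  res <- whalemigrate:::kf_smooth_1d(
    times_h = c(0, 2, 4), has_obs = c(TRUE, FALSE, TRUE),
    y = c(0, NA, 10), r_var = c(1e-12, NA, 1e-12),
    sigma2 = sigma^2, m0 = 0, p0 = 1e-10)
  expect_equal(res$mean[2], 5, tolerance = 1e-5)
  expect_equal(res$var[2], sigma^2 * 2 * 2 / 4, tolerance = 1e-4)
})

test_that("smoothing never inflates the one-sided (filtered) uncertainty", {
  set.seed(25)
  x <- cumsum(rnorm(40, 0, 5)); y <- cumsum(rnorm(40, 0, 5))
  ll <- unproj_aeqd(x, y, c(70, 10))
  t <- make_track(ll[, 1], ll[, 2],
                  times = T0 + cumsum(runif(40, 1, 6)) * 3600, lc = "B")
  fit <- fit_ssm(t)
  rt <- predict_regular(t, fit, "whole_track")
  expect_true(all(rt$sd_x_km <= rt$sd_x_filt_km + 1e-9))
  expect_true(all(rt$sd_y_km <= rt$sd_y_filt_km + 1e-9))
})

test_that("segments-only prediction stays inside windows, 2-h spacing", {
  set.seed(26)
  tt <- c(T0 + 0:40 * 4 * 3600, T0 + 250 * 3600 + 0:40 * 4 * 3600)
  n <- length(tt)
  x <- cumsum(rnorm(n, 0, 3)); y <- cumsum(rnorm(n, 0, 3))
  ll <- unproj_aeqd(x, y, c(70, 10))
  t <- make_track(ll[, 1], ll[, 2], times = tt, lc = "1")
  fit <- fit_ssm(t)
  segs <- segment_track(t)
  expect_equal(nrow(segs), 2)
  rt <- predict_regular(t, fit, "segments_only", windows = segs)
  for (s in 1:2) {
    seg <- rt[rt$segment_id == s, ]
    expect_true(all(seg$date >= segs$start[s] & seg$date <= segs$end[s]))
    expect_true(all(diff(as.numeric(seg$date)) == 7200))
  }
  # whole-track grid spans the gap with ~tracked-hours/2 points
  rtw <- predict_regular(t, fit, "whole_track")
  span_h <- as.numeric(max(tt) - min(tt), units = "secs") / 3600
  expect_equal(nrow(rtw), floor(span_h / 2) + 1)
})
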