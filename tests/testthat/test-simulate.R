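# Synthetic-data generator: determinism, truth consistency, anchoring of
# the movement phases, and end-to-end recovery on a small cohort.

test_that("the same seed reproduces the cohort exactly", {
  cfg <- sim_config(seed = 77, n_migrants = 1, n_non_migrants = 2)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$truth_table, s2$truth_table)
  for (id in names(s1$tracks)) {
    expect_identical(s1$tracks[[id]]$date, s2$tracks[[id]]$date)
    expect_identical(s1$tracks[[id]]$lat, s2$tracks[[id]]$lat)
    expect_identical(s1$tracks[[id]]$lc, s2$tracks[[id]]$lc)
  }
})

test_that("zero-noise, gap-free observations lie on the true path", {
  cfg <- sim_config(seed = 78, n_migrants = 0, n_non_migrants = 1,
                    resident_duration_d = c(30, 30),
                    argos = list(class_probs = c("3" = 1, "2" = 0, "1" = 0,
                                                 "0" = 0, "A" = 0, "B" = 0,
                                                 "Z" = 0),
                                 class_sd_km = c("3" = 0, "2" = 0, "1" = 0,
                                                 "0" = 0, "A" = 0, "B" = 0,
                                                 "Z" = 0),
                                 gap_rate_per_d = 0))
  sim <- simulate_cohort(cfg)
  tr <- sim$tracks[[1]]
  path <- sim$truth[[1]]$path
  t_h <- as.numeric(tr$date - path$date[1], units = "secs") / 3600
  p_h <- as.numeric(path$date - path$date[1], units = "secs") / 3600
  expect_equal(tr$lat, approx(p_h, path$lat, xout = t_h)$y,
               tolerance = 1e-9)
  expect_equal(tr$lon, approx(p_h, path$lon, xout = t_h)$y,
               tolerance = 1e-9)
})

test_that("truth events are ordered and internally consistent", {
  cfg <- sim_config(seed = 79, n_migrants = 3, n_non_migrants = 3)
  sim <- simulate_cohort(cfg)
  tt <- sim$truth_table
  mig <- tt[tt$is_migrant, ]
  expect_true(all(mig$departure < mig$arrival))
  expect_true(all(mig$arrival < mig$breeding_departure))
  expect_true(all(mig$breeding_departure < mig$return_north))
  expect_true(all(!is.na(mig$leg_km_ns) & mig$leg_km_ns > 0))
  res <- tt[!tt$is_migrant, ]
  expect_true(all(is.na(res$departure)))
  # phases on the true path appear in cycle order
  ph <- rle(sim$truth[[1]]$path$phase)$values
  expect_equal(ph, c("foraging", "N-S", "breeding", "S-N", "foraging"))
})

test_that("a fixed-duration straight transit has the expected leg length", {
  # 40 d at a constant 4.7 km/h: true leg length ~ 4.7 * 24 * 40 = 4512 km,
  # inside the observed southbound range of the tagged cohort
  cfg <- sim_config(seed = 80, speed_sd_kmh = 0)
  plan <- list(animal_id = "T1", type = "migrant", seed = 81, cfg = cfg,
               tag_date = as.POSIXct("2022-06-01", tz = "UTC"),
               foraging_center = c(74, 12),
               departure_d = 10,
               breeding_target = c(25, -45),
               breeding_duration_d = 60,
               duration_d = NA_real_,
               breeding_lat_limit = 45,
               transit_end = "duration", transit_duration_d = 40)
  out <- simulate_track(plan)
  path <- out$truth$path
  transit <- path[path$phase == "N-S", ]
  n <- nrow(transit)
  leg <- sum(great_circle_km(transit$lat[-n], transit$lon[-n],
                             transit$lat[-1], transit$lon[-1]))
  expect_equal(leg, 4.7 * 24 * 40, tolerance = 0.02)
  expect_true(leg > 3869 && leg < 5877)
})

test_that("default transit speeds put southbound legs in the observed range", {
  cfg <- sim_config(seed = 82, n_migrants = 4, n_non_migrants = 3)
  sim <- simulate_cohort(cfg)
  ns <- sim$truth_table$leg_km_ns[sim$truth_table$is_migrant]
  expect_true(all(ns > 2500 & ns < 6500))
})

test_that("simulated dives follow the per-phase parameters", {
  cfg <- sim_config(seed = 83, n_migrants = 1, n_non_migrants = 1)
  sim <- simulate_cohort(cfg)
  dv <- simulate_dives(sim$truth[[1]], seed = 84, animal_id = "SIM001")
  expect_true(all(c("foraging", "N-S", "breeding", "S-N") %in%
                    unique(dv$dives$phase)))
  pars <- dive_phase_params()
  # depths are truncated normals (a dive depth must clear the tag's ignore
  # threshold), so the expected sample mean is the truncated-normal mean
  etrunc <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  for (p in pars$phase) {
    sel <- dv$dives$phase == p
    n <- sum(sel)
    if (n < 50) next
    i <- which(pars$phase == p)
    expect_lt(abs(mean(dv$dives$max_depth_m[sel]) -
                    etrunc(pars$depth_mean[i], pars$depth_sd[i], 50, 2500)),
              4 * pars$depth_sd[i] / sqrt(n))
    expect_lt(abs(mean(dv$dives$duration_min[sel]) -
                    etrunc(pars$dur_mean[i], pars$dur_sd[i], 5, 95)),
              4 * pars$dur_sd[i] / sqrt(n))
  }
  # histograms are exactly the dive-by-dive binning
  reh <- build_dive_histograms(dv$dives, dive_bin_config("B"))
  expect_identical(reh, dv$histograms)
  bb <- bin_dive(dv$dives$max_depth_m, dv$dives$duration_min,
                 dive_bin_config("B"))
  expect_equal(sum(reh$n_dives), sum(!bb$ignored))
  # a resident has no transit-phase dives
  dv_res <- simulate_dives(sim$truth[[2]], seed = 85, animal_id = "SIM002")
  expect_true(all(dv_res$dives$phase == "foraging"))
})

test_that("the pipeline recovers truth on a small cohort", {
  cfg <- sim_config(seed = 86, n_migrants = 2, n_non_migrants = 5)
  sim <- simulate_cohort(cfg)
  cleaned <- lapply(sim$tracks, clean_track)
  cls <- dplyr::bind_rows(lapply(cleaned, classify_migrant))
  truth_m <- sim$truth_table$is_migrant[match(cls$animal_id,
                                              sim$truth_table$animal_id)]
  expect_equal(cls$is_migrant, truth_m)
  poly <- foraging_polygon(cleaned[cls$animal_id[!cls$is_migrant]])
  regs <- lapply(cleaned[cls$animal_id[cls$is_migrant]], regularize_track)
  phen <- detect_phenology(regs, poly, cleaned[cls$animal_id[cls$is_migrant]])
  merged <- dplyr::left_join(phen$records, sim$truth_table,
                             by = "animal_id")
  expect_true(all(abs(as.numeric(merged$start_migration_date -
                                   merged$departure)) <= 2))
  expect_true(all(abs(as.numeric(merged$arrival_breeding_date -
                                   merged$arrival)) <= 2))
  expect_true(all(abs(as.numeric(merged$return_north_date -
                                   merged$return_north)) <= 3))
  # reconstructed leg distance within 5% of the true path length over the
  # same interval
  for (i in seq_len(nrow(merged))) {
    id <- merged$animal_id[i]
    truth_km <- truth_path_km(
      sim$truth[[id]]$path,
      as.POSIXct(merged$start_migration_date[i], tz = "UTC"),
      as.POSIXct(merged$arrival_breeding_date[i], tz = "UTC"))
    expect_lt(abs(merged$cum_km_ns[i] - truth_km) / truth_km, 0.05)
  }
})
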