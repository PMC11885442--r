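# Migrant classification, foraging polygon, event detection, durations.

test_that("migrant classification is exact at the 1,000-km boundary", {
  mk_excursion <- function(km) {
    far <- whalemigrate:::destination_point(70, 10, 200, km)
    make_track(lat = c(70, 70.05, far[1], 70.02),
               lon = c(10, 10.05, far[2], 10.02))
  }
  expect_false(classify_migrant(mk_excursion(999))$is_migrant)
  expect_true(classify_migrant(mk_excursion(1001))$is_migrant)
  expect_true(classify_migrant(mk_excursion(1000))$is_migrant)   # >= rule
  expect_true(classify_migrant(mk_excursion(1010))$is_migrant)
  expect_equal(classify_migrant(mk_excursion(1010))$max_displacement_km,
               1010, tolerance = 1e-6)
  still <- make_track(lat = rep(70, 5), lon = rep(10, 5))
  cl <- classify_migrant(still)
  expect_false(cl$is_migrant)
  expect_equal(cl$max_displacement_km, 0)
})

test_that("a 100 x 100 km square has a ~10,000 km2 hull", {
  corners <- unproj_laea(c(-50, 50, 50, -50), c(-50, -50, 50, 50),
                         c(70, 10))
  t <- make_track(corners[, 1], corners[, 2],
                  times = T0 + 0:3 * 2 * 86400)
  poly <- foraging_polygon(list(t))
  expect_equal(poly$area_km2, 10000, tolerance = 0.01)
  expect_equal(nrow(poly$vertices), 4)
})

test_that("foraging polygon subsamples one location per two days", {
  set.seed(51)
  t <- make_track(lat = 70 + rnorm(8, 0, 0.5), lon = 10 + rnorm(8, 0, 1),
                  times = T0 + 0:7 * 86400)
  poly <- foraging_polygon(list(t))
  expect_equal(poly$n_points, 4) # days 0,2,4,6
})

test_that("hulls agree with the exhaustive oracle on up to 12 points", {
  set.seed(52)
  for (n in c(5, 8, 12)) {
    lat <- runif(n, 69, 72); lon <- runif(n, 8, 14)
    poly <- mcp_polygon(lat, lon)
    xy <- proj_laea(lat, lon, poly$origin)
    oracle <- hull_oracle(xy[, 1], xy[, 2])
    expect_setequal(
      paste(round(poly$vertices$x_km, 6), round(poly$vertices$y_km, 6)),
      paste(round(xy[oracle$idx, 1], 6), round(xy[oracle$idx, 2], 6)))
    expect_equal(poly$area_km2, oracle$area, tolerance = 1e-9)
  }
})

test_that("collinear or too-few points raise a degenerate-geometry error", {
  expect_error(mcp_polygon(c(70, 70.5, 71), c(10, 10, 10)),
               class = "whalemigrate_degenerate_polygon")
  expect_error(mcp_polygon(c(70, 71), c(10, 11)),
               class = "whalemigrate_degenerate_polygon")
})

square_poly <- function(half_km = 100, origin = c(70, 10)) {
  c4 <- unproj_laea(c(-half_km, half_km, half_km, -half_km),
                    c(-half_km, -half_km, half_km, half_km), origin)
  mcp_polygon(c4[, 1], c4[, 2], origin = origin)
}

test_that("points on the polygon boundary and vertices count as inside", {
  poly <- square_poly()
  v1 <- poly$vertices
  expect_true(all(point_in_polygon(poly, v1$lat, v1$lon)))
  edge_mid <- unproj_laea(0, -100, c(70, 10)) # on the southern edge
  expect_true(point_in_polygon(poly, edge_mid[1], edge_mid[2]))
  outside <- unproj_laea(0, -101, c(70, 10))
  expect_false(point_in_polygon(poly, outside[1], outside[2]))
})

test_that("departure is the last exit not followed by a (non-return) entry", {
  poly <- square_poly()
  # 40 d wiggling inside, then a permanent southbound exit
  n_in <- 40 * 12
  set.seed(53)
  x <- c(runif(n_in, -60, 60), rep(0, 60))
  y <- c(runif(n_in, -60, 60), seq(-30, by = -60, length.out = 60))
  rt <- make_rtrack(x, y, origin = c(70, 10), kind = "whole_track")
  dep <- detect_departure(rt, poly)
  first_out <- n_in + which(y[(n_in + 1):(n_in + 60)] < -100)[1]
  expect_equal(dep, as.Date(rt$date[first_out]))

  # a brief 1.5-d excursion (no breeding latitudes) is not a departure
  n1 <- 20 * 12
  exc <- c(seq(-110, -160, length.out = 9), seq(-160, -90, length.out = 9))
  n2 <- 20 * 12
  x2 <- c(runif(n1, -60, 60), rep(0, 18), runif(n2, -60, 60), rep(0, 60))
  y2 <- c(runif(n1, -60, 60), exc, runif(n2, -60, 60),
          seq(-30, by = -60, length.out = 60))
  rt2 <- make_rtrack(x2, y2, origin = c(70, 10), kind = "whole_track")
  dep2 <- detect_departure(rt2, poly)
  base <- n1 + 18 + n2
  first_out2 <- base + which(y2[(base + 1):(base + 60)] < -100)[1]
  expect_equal(dep2, as.Date(rt2$date[first_out2]))
  expect_gt(as.numeric(dep2 - as.Date(rt2$date[1])), 39)

  # a non-migrant that never exits has no departure
  rt3 <- make_rtrack(runif(100, -60, 60), runif(100, -60, 60),
                     origin = c(70, 10), kind = "whole_track")
  expect_true(is.na(detect_departure(rt3, poly)))
})

test_that("a foraging-polygon re-entry during the S-N return still departs", {
  poly <- square_poly()
  # exit, run far south (past 45 N), come back inside, stay
  n_in <- 15 * 12
  set.seed(54)
  south <- seq(-60, -3200, length.out = 280) # reaches ~ lat 41 N
  north <- rev(south)
  x <- c(runif(n_in, -50, 50), rep(10, 560), runif(60, -50, 50))
  y <- c(runif(n_in, -50, 50), south, north, runif(60, -50, 50))
  rt <- make_rtrack(x, y, origin = c(70, 10), kind = "whole_track")
  expect_lt(min(rt$lat), 45)
  dep <- detect_departure(rt, poly)
  first_out <- n_in + which(y[(n_in + 1):(n_in + 280)] < -100)[1]
  expect_equal(dep, as.Date(rt$date[first_out]))
})

decel_rtrack <- function() {
  # southbound from ~52 N: constant 10 km/h for 30 steps, then smooth
  # deceleration; the 45 N crossing happens while slowing down
  steps <- c(rep(20, 30), seq(20, 6, length.out = 150))
  y <- 400 - cumsum(steps)
  make_rtrack(rep(0, length(y)), y, origin = c(48.5, -20),
              t_start = T0)
}

test_that("arrival is the first decelerating point south of 45 N", {
  rt <- decel_rtrack()
  dep_date <- as.Date(rt$date[1])
  arr <- detect_arrival(rt, dep_date)
  expect_false(is.na(arr))
  crossing <- which(rt$lat < 45)[1]
  expect_lte(abs(as.numeric(arr - as.Date(rt$date[crossing]))), 1)
  expect_lt(attr(arr, "arrival_lat"), 45)

  # never south of 45: the latitude gate blocks detection
  rt_north <- make_rtrack(rep(0, 150), seq(0, -300, length.out = 150),
                          origin = c(60, -10))
  expect_true(all(rt_north$lat > 45))
  expect_true(is.na(detect_arrival(rt_north, as.Date(rt_north$date[1]))))

  # monotonically accelerating south of 45: the derivative gate blocks
  steps_acc <- seq(6, 24, length.out = 200)
  y_acc <- 100 - cumsum(steps_acc)
  rt_acc <- make_rtrack(rep(0, 200), y_acc, origin = c(45.5, -20))
  expect_lt(min(rt_acc$lat), 45)
  expect_true(is.na(detect_arrival(rt_acc, as.Date(rt_acc$date[1]))))
})

test_that("breeding departure crosses the arrival-latitude threshold", {
  # go south to ~ -1500 km, roam, then come back north
  y <- c(seq(0, -1500, length.out = 150), runif(200, -1600, -1400),
         seq(-1400, 100, length.out = 150))
  rt <- make_rtrack(rep(0, length(y)), y, origin = c(44, -30),
                    kind = "whole_track")
  arr_date <- as.Date(rt$date[5])
  thr <- 43.5
  bdep <- detect_breeding_departure(rt, arr_date, thr)
  # the detected date is the northbound re-crossing of the threshold
  # latitude (y = -55.6 km), not any point of the southbound descent
  cross <- 350 + which(y[351:500] > -55.6)[1]
  expect_lte(abs(as.numeric(bdep - as.Date(rt$date[cross]))), 1)
  expect_gt(as.numeric(bdep - arr_date), 30)
  # tag dies in the breeding area: no departure
  rt_dead <- make_rtrack(rep(0, 200), seq(0, -1500, length.out = 200),
                         origin = c(44, -30), kind = "whole_track")
  expect_true(is.na(detect_breeding_departure(rt_dead, arr_date, 43.5)))
})

test_that("return is the first polygon re-entry, vertices included", {
  poly <- square_poly()
  # approach from the south, ending exactly on the polygon's SW vertex
  sw <- poly$vertices[which.min(poly$vertices$x_km + poly$vertices$y_km), ]
  y_app <- seq(-800, sw$y_km, length.out = 100)
  x_app <- seq(-300, sw$x_km, length.out = 100)
  rt <- make_rtrack(x_app, y_app, origin = c(70, 10), kind = "whole_track")
  bdep <- as.Date(rt$date[1])
  ret <- detect_return_north(rt, poly, bdep - 1)
  inside <- point_in_polygon(poly, rt$lat, rt$lon)
  expect_equal(ret, as.Date(rt$date[which(inside)[1]]))
  # last position is the vertex itself and must count as inside
  expect_true(inside[100])
  # tag dying mid-transit: no re-entry
  rt2 <- make_rtrack(seq(-300, -150, length.out = 50),
                     seq(-800, -400, length.out = 50),
                     origin = c(70, 10), kind = "whole_track")
  expect_true(is.na(detect_return_north(rt2, poly, bdep - 1)))
})

test_that("durations are whole-day differences and additive", {
  d <- migration_durations(as.Date("2023-04-04"), as.Date("2023-05-13"),
                           as.Date("2023-08-23"), as.Date("2023-09-26"))
  expect_equal(unlist(d), c(ns_d = 39, breeding_d = 102, sn_d = 34,
                            whole_cycle_d = 175))
  expect_equal(d$ns_d + d$breeding_d + d$sn_d, d$whole_cycle_d)
  # missing legs stay absent, never zero
  d2 <- migration_durations(as.Date("2022-10-06"), as.Date("2022-12-08"),
                            as.Date(NA), as.Date(NA))
  expect_equal(d2$ns_d, 63)
  expect_true(is.na(d2$breeding_d) && is.na(d2$sn_d))
})

test_that("summarize_phenology validates order and flags zero-day legs", {
  rt <- make_rtrack(rep(0, 50), seq(0, -500, length.out = 50),
                    origin = c(60, -10), kind = "whole_track")
  ev_bad <- list(start = as.Date("2022-06-10"),
                 arrival = as.Date("2022-06-05"),
                 departure = as.Date(NA), return = as.Date(NA))
  expect_error(summarize_phenology("W9", ev_bad, rt, c(60, -10)), "W9")
  ev0 <- list(start = as.Date(rt$date[1]), arrival = as.Date(rt$date[1]),
              departure = as.Date(NA), return = as.Date(NA))
  expect_warning(rec <- summarize_phenology("W1", ev0, rt, c(60, -10)),
                 "suspicious")
  expect_equal(rec$ns_d, 0)
  # cumulative leg distance matches the step sum over the leg
  ev <- list(start = as.Date(rt$date[1]), arrival = as.Date(rt$date[49]),
             departure = as.Date(NA), return = as.Date(NA))
  rec2 <- summarize_phenology("W1", ev, rt, c(60, -10))
  expect_gt(rec2$cum_km_ns, 450)
  expect_true(is.na(rec2$cum_km_breeding))
})

test_that("cohort summary reproduces mean/SD/range and departure span", {
  recs <- tibble::tibble(
    animal_id = letters[1:4],
    start_migration_date = as.Date(c("2022-01-18", "2022-03-01",
                                     "2021-10-06", "2023-07-10")),
    ns_d = c(28, 63, 40, 35), breeding_d = c(51, 102, 84, NA),
    sn_d = c(34, 33, NA, NA), whole_cycle_d = c(175, 180, NA, NA))
  cs <- cohort_phenology_summary(recs)
  ns <- cs$durations[cs$durations$leg == "ns", ]
  expect_equal(ns$mean, round(mean(c(28, 63, 40, 35))))
  expect_equal(ns$sd, round(sd(c(28, 63, 40, 35))))
  expect_equal(c(ns$min, ns$max), c(28, 63))
  # day-of-year span: 06 Oct vs 18 Jan
  expect_equal(cs$departure_span_d, 279 - 18)
})
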