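# Shared builders and independent oracles for the test suite. Oracles here
# are deliberately naive (dense linear algebra, exhaustive search) and never
# share code with the implementation they check.

T0 <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")

make_track <- function(lat, lon, times = NULL, lc = "3", id = "W1",
                       tagging_location = NULL) {
  n <- length(lat)
  if (is.null(times)) times <- T0 + (seq_len(n) - 1) * 7200
  whale_track(tibble::tibble(date = times, lat = lat, lon = lon,
                             lc = rep_len(lc, n)),
              animal_id = id, tagging_location = tagging_location)
}

# regularized-track builder in a local plane (km) around `origin`
make_rtrack <- function(x, y, origin = c(70, 10),
                        seg = rep(1L, length(x)), dt_h = 2,
                        t_start = T0, id = "W1",
                        kind = "segments_only", proj = "aeqd") {
  ll <- if (proj == "laea") unproj_laea(x, y, origin) else
    unproj_aeqd(x, y, origin)
  structure(tibble::tibble(
    date = t_start + (seq_along(x) - 1) * dt_h * 3600,
    lat = ll[, 1], lon = ll[, 2], x_km = x, y_km = y,
    sd_x_km = 0, sd_y_km = 0, sd_x_filt_km = 0, sd_y_filt_km = 0,
    segment_id = seg),
    class = c("whale_rtrack", "tbl_df", "tbl", "data.frame"),
    animal_id = id, dataset_kind = kind, origin = origin, dt_h = dt_h)
}

# ---- dense GLS oracle for the 1-D random-walk smoother ----------------------
# Prior: x(t_1) ~ N(m0, p0); Brownian increments with variance sigma2*dt.
# Joint covariance of states at `times`: p0 + sigma2*min(t_i - t_1, t_j - t_1).
gls_oracle_1d <- function(times, y, r_var, sigma2, m0, p0,
                          pred_times = times) {
  tt <- times - times[1]
  C <- p0 + sigma2 * outer(tt, tt, pmin)
  S <- C + diag(r_var, length(y))
  Si <- solve(S)
  ll <- -0.5 * (length(y) * log(2 * pi) +
                  determinant(S, logarithm = TRUE)$modulus[1] +
                  t(y - m0) %*% Si %*% (y - m0))
  pt <- pred_times - times[1]
  K <- p0 + sigma2 * outer(pt, tt, pmin)
  mean_s <- as.numeric(m0 + K %*% Si %*% (y - m0))
  var_s <- (p0 + sigma2 * pt) - diag(K %*% Si %*% t(K))
  list(loglik = as.numeric(ll), mean = mean_s, var = as.numeric(var_s))
}

# ---- exhaustive convex-hull oracle (<= 12 points) ---------------------------
# An ordered pair (i, j) is a hull edge iff every other point lies on or to
# the left of the directed line i -> j. Chaining the edges yields the hull.
hull_oracle <- function(x, y) {
  n <- length(x)
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
    if (all(cr >= -1e-9)) edges[[length(edges) + 1]] <- c(i, j)
  }
  em <- do.call(rbind, edges)
  # chain counter-clockwise starting from the lowest point
  start <- which.min(y + 1e-9 * x)
  ord <- start
  repeat {
    nxts <- em[em[, 1] == ord[length(ord)], 2]
    nxts <- setdiff(nxts, ord)
    if (!length(nxts)) break
    # pick the strictly outermost continuation (longest edge among collinear)
    d <- (x[nxts] - x[ord[length(ord)]])^2 + (y[nxts] - y[ord[length(ord)]])^2
    ord <- c(ord, nxts[which.max(d)])
  }
  area <- abs(sum(x[ord] * c(y[ord][-1], y[ord][1]) -
                    c(x[ord][-1], x[ord][1]) * y[ord])) / 2
  list(idx = ord, area = area)
}

# shoelace area of an ordered polygon
shoelace <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# true path length (km) between two datetimes, from a fine truth path
truth_path_km <- function(path, from, to) {
  sel <- path$date >= from & path$date <= to
  p <- path[sel, ]
  sum(great_circle_km(p$lat[-nrow(p)], p$lon[-nrow(p)],
                      p$lat[-1], p$lon[-1]))
}
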