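# Time spent in area (TSA): hours of track time apportioned to 50 x 50 km
# cells of an equal-area grid. Each 2-h inter-position interval is split in
# proportion to the length of the straight projected sub-segment falling in
# each cell (exact line clipping against the grid), so the per-segment sum of
# cell-hours equals the segment duration by construction.

#' Accumulate time-spent-in-area on an equal-area grid
#'
#' @param rt a `whale_rtrack` (use the segments-only dataset so time is never
#'   apportioned across transmission gaps), or a list of them (cells are
#'   accumulated on a common grid).
#' @param phases optional phase labels: a function `f(date) -> character`, or
#'   a character vector per position (per track when `rt` is a list). `NULL`
#'   labels everything `"all"`.
#' @param cell_km cell size, km.
#' @param origin projection/grid origin `c(lat, lon)`; defaults to the
#'   centroid of all positions. The grid is anchored at the projected origin.
#' @param grid_offset `c(x, y)` km shift of the grid relative to the origin
#'   (cell k covers `[offset + k*cell, offset + (k+1)*cell)`).
#' @return a `whale_tsa`: tibble `cell_x`, `cell_y`, `phase`, `hours` with
#'   grid metadata attributes.
#' @export
accumulate_tsa <- function(rt, phases = NULL, cell_km = 50, origin = NULL,
                           grid_offset = c(0, 0)) {
  rts <- if (inherits(rt, "whale_rtrack")) list(rt) else rt
  if (is.null(origin)) {
    all_lat <- unlist(lapply(rts, `[[`, "lat"))
    all_lon <- unlist(lapply(rts, `[[`, "lon"))
    origin <- c(mean(all_lat), mean(all_lon))
  }
  acc <- new.env(parent = emptyenv())
  add_hours <- function(cx, cy, phase, h) {
    key <- paste(cx, cy, phase, sep = "|")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + h
  }
  for (ti in seq_along(rts)) {
    r <- rts[[ti]]
    if (nrow(r) < 1) next
    ph <- if (is.null(phases)) rep("all", nrow(r))
          else if (is.function(phases)) phases(r$date)
          else if (is.list(phases) && !is.character(phases)) phases[[ti]]
          else phases
    xy <- proj_laea(r$lat, r$lon, origin)
    x <- xy[, 1] - grid_offset[1]
    y <- xy[, 2] - grid_offset[2]
    n <- nrow(r)
    if (n == 1) next
    for (i in seq_len(n - 1)) {
      if (r$segment_id[i + 1] != r$segment_id[i]) next
      dt_h <- as.numeric(r$date[i + 1] - r$date[i], units = "secs") / 3600
      x0 <- x[i]; y0 <- y[i]; x1 <- x[i + 1]; y1 <- y[i + 1]
      dx <- x1 - x0; dy <- y1 - y0
      if (abs(dx) < 1e-12 && abs(dy) < 1e-12) {
        add_hours(floor(x0 / cell_km), floor(y0 / cell_km), ph[i], dt_h)
        next
      }
      ts <- c(0, 1)
      if (abs(dx) > 1e-12) {
        ks <- seq(ceiling(min(x0, x1) / cell_km),
                  floor(max(x0, x1) / cell_km))
        ts <- c(ts, (ks * cell_km - x0) / dx)
      }
      if (abs(dy) > 1e-12) {
        ks <- seq(ceiling(min(y0, y1) / cell_km),
                  floor(max(y0, y1) / cell_km))
        ts <- c(ts, (ks * cell_km - y0) / dy)
      }
      ts <- sort(unique(pmin(1, pmax(0, ts))))
      for (j in seq_len(length(ts) - 1)) {
        frac <- ts[j + 1] - ts[j]
        if (frac <= 0) next
        tm <- (ts[j] + ts[j + 1]) / 2
        add_hours(floor((x0 + tm * dx) / cell_km),
                  floor((y0 + tm * dy) / cell_km),
                  ph[i], dt_h * frac)
      }
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  res <- tibble(
    cell_x = as.integer(vapply(parts, `[[`, "", 1)),
    cell_y = as.integer(vapply(parts, `[[`, "", 2)),
    phase = vapply(parts, `[[`, "", 3),
    hours = vapply(keys, function(k) acc[[k]], 0, USE.NAMES = FALSE))
  res <- res[order(res$cell_x, res$cell_y, res$phase), ]
  structure(res, class = c("whale_tsa", class(res)),
            origin = origin, cell_km = cell_km, grid_offset = grid_offset)
}

#' Summarize time-spent-in-area per phase
#'
#' Mean, SD and maximum of per-cell hours by phase. The TSA distribution is
#' typically long-tailed (resident animals can sit in one cell for weeks),
#' so the maximum is reported alongside the moments.
#'
#' @param g a `whale_tsa`.
#' @return tibble `phase`, `n_cells`, `mean_h`, `sd_h`, `max_h`.
#' @export
tsa_summary <- function(g) {
  if (nrow(g) == 0)
    return(tibble(phase = character(0), n_cells = integer(0),
                  mean_h = numeric(0), sd_h = numeric(0),
                  max_h = numeric(0)))
  as_tibble(g) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean_h = mean(.data$hours),
                     sd_h = if (dplyr::n() > 1) sd(.data$hours) else
                       NA_real_,
                     max_h = max(.data$hours), .groups = "drop")
}

#' Export a TSA grid as plain CSV
#' @param g a `whale_tsa`.
#' @param path output file.
#' @export
write_tsa <- function(g, path) {
  readr::write_csv(as_tibble(g), path)
  invisible(path)
}
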