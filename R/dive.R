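# Tag-transmitted dive records: 6-h binned histograms of dive counts by
# depth and duration bin, time-at-depth percentages, and randomly sampled
# single dives. Two tag programming configurations are supported, matching
# the two bin layouts used on the study animals: a shallow fine-grained
# layout ("A") and a deep coarse layout ("B"). Bins are half-open,
# lower-edge inclusive; the final bin is open-ended.

#' Dive bin configurations
#'
#' Configuration `"A"`: 14 depth bins with upper limits 2, 4, 10, 20, 40,
#' 60, 80, 100, 150, 200, 250, 300, 350 m and an open `>350` m bin; 14
#' duration bins with limits 6..30 min (step 2) and an open `>30` min bin;
#' dives shallower than 2 m and shorter than 1 min are ignored.
#' Configuration `"B"`: 10 depth bins with limits 50, 100, 200, 300, 500,
#' 700, 1000, 1500, 2000 m and an open `>2000` m bin; 7 duration bins with
#' limits 10, 20, 30, 50, 60, 80 min and an open `>80` min bin; dives
#' shallower than 50 m and shorter than 5 min are ignored.
#'
#' @param label `"A"` or `"B"`.
#' @param ignore_rule `"and"` (a dive is ignored only when it is both too
#'   shallow and too short — the default reading of the programming) or
#'   `"or"` (either condition suffices).
#' @return a `dive_bin_config`: list with `depth_edges`, `duration_edges`
#'   (closed lower edges, starting at 0, final bin open), `ignore_depth_m`,
#'   `ignore_duration_min`, `ignore_rule`, `label`.
#' @export
dive_bin_config <- function(label = c("B", "A"),
                            ignore_rule = c("and", "or")) {
  label <- match.arg(label)
  ignore_rule <- match.arg(ignore_rule)
  cfg <- if (label == "A") {
    list(depth_edges = c(0, 2, 4, 10, 20, 40, 60, 80, 100, 150, 200, 250,
                         300, 350),
         duration_edges = c(0, seq(6, 30, by = 2)),
         ignore_depth_m = 2, ignore_duration_min = 1)
  } else {
    list(depth_edges = c(0, 50, 100, 200, 300, 500, 700, 1000, 1500, 2000),
         duration_edges = c(0, 10, 20, 30, 50, 60, 80),
         ignore_depth_m = 50, ignore_duration_min = 5)
  }
  cfg$label <- label
  cfg$ignore_rule <- ignore_rule
  structure(cfg, class = "dive_bin_config")
}

bin_labels <- function(edges, unit) {
  n <- length(edges)
  c(sprintf("[%g,%g) %s", edges[-n], edges[-1], unit),
    sprintf(">=%g %s", edges[n], unit))
}

#' Assign a dive to its depth and duration bin
#'
#' Half-open binning, lower edge inclusive: a dive of exactly 50 m under
#' configuration B falls in the 50-100 m bin. Returns `NA` bins for ignored
#' dives (too shallow and/or too short per the configuration's ignore rule).
#'
#' @param depth_m,duration_min dive maximum depth (m) and duration (min);
#'   vectorised.
#' @param cfg a [dive_bin_config()].
#' @return tibble `depth_bin`, `duration_bin` (integer indices, 1-based;
#'   `NA` = ignored), `ignored`.
#' @export
bin_dive <- function(depth_m, duration_min, cfg = dive_bin_config()) {
  if (any(depth_m < 0) || any(duration_min < 0))
    abort("negative dive depth or duration")
  ign <- if (cfg$ignore_rule == "and")
    depth_m < cfg$ignore_depth_m & duration_min < cfg$ignore_duration_min
  else
    depth_m < cfg$ignore_depth_m | duration_min < cfg$ignore_duration_min
  db <- findInterval(depth_m, cfg$depth_edges)      # 1..n_bins (last open)
  ub <- findInterval(duration_min, cfg$duration_edges)
  tibble(depth_bin = ifelse(ign, NA_integer_, db),
         duration_bin = ifelse(ign, NA_integer_, ub),
         ignored = ign)
}

#' Build 6-h dive histograms from single dives
#'
#' Rebuilds the tag's transmitted summary product: dives are grouped into
#' 6-h GMT-aligned periods (00, 06, 12, 18 h; at most four per day) and
#' counted per depth and duration bin. Time-at-depth percentages are
#' computed as the duration-weighted share of dive time per depth bin,
#' normalised to 100.
#'
#' @param dives tibble with `animal_id`, `date` (POSIXct), `max_depth_m`,
#'   `duration_min`.
#' @param cfg a [dive_bin_config()].
#' @return tibble: one row per animal x 6-h period, with `n_dives`,
#'   list-columns `depth_counts`, `duration_counts` (integer vectors over
#'   the bins), and `tad_percent`.
#' @export
build_dive_histograms <- function(dives, cfg = dive_bin_config()) {
  bb <- bin_dive(dives$max_depth_m, dives$duration_min, cfg)
  d <- dives[!bb$ignored, ]
  b <- bb[!bb$ignored, ]
  if (nrow(d) == 0)
    return(tibble(animal_id = character(0), period_start = d$date[0],
                  n_dives = integer(0), depth_counts = list(),
                  duration_counts = list(), tad_percent = list()))
  period <- as.POSIXct(floor(as.numeric(d$date) / 21600) * 21600,
                       origin = "1970-01-01", tz = "UTC")
  nd <- length(cfg$depth_edges); nu <- length(cfg$duration_edges)
  key <- paste(d$animal_id, format(period, "%Y-%m-%d %H:%M:%S"))
  out <- lapply(split(seq_len(nrow(d)), key), function(ix) {
    dc <- tabulate(b$depth_bin[ix], nbins = nd)
    uc <- tabulate(b$duration_bin[ix], nbins = nu)
    tad_raw <- vapply(seq_len(nd), function(k)
      sum(d$duration_min[ix][b$depth_bin[ix] == k]), 0)
    tad <- if (sum(tad_raw) > 0) round(100 * tad_raw / sum(tad_raw), 1)
           else tad_raw
    tibble(animal_id = d$animal_id[ix[1]], period_start = period[ix[1]],
           n_dives = length(ix), depth_counts = list(dc),
           duration_counts = list(uc), tad_percent = list(tad))
  })
  res <- dplyr::bind_rows(out)
  res[order(res$animal_id, res$period_start), ]
}

#' Assign migration phases by timestamp
#'
#' Labels each item by the migration phase its timestamp falls in, given the
#' animal's phenology record. Intervals are closed on the left: an item
#' timestamped exactly on the arrival date belongs to the breeding phase.
#' Items before the migration start (and after the northern return) are
#' `foraging`; items in a leg whose closing event was never observed stay in
#' that leg (an animal without a detected arrival has all post-departure
#' items labelled `N-S`). Items for animals with no resolved events are
#' `unknown`.
#'
#' @param dates POSIXct or Date timestamps.
#' @param record one-row PhenologyRecord (or a list with the four event
#'   dates).
#' @return character vector of phase labels: `foraging`, `N-S`, `breeding`,
#'   `S-N`, or `unknown`.
#' @export
assign_phase <- function(dates, record) {
  d <- as.Date(dates)
  start <- record$start_migration_date
  arr <- record$arrival_breeding_date
  dep <- record$departure_breeding_date
  ret <- record$return_north_date
  ph <- rep("unknown", length(d))
  if (is.na(start)) return(ph)
  ph[d < start] <- "foraging"
  ph[d >= start] <- "N-S"
  if (!is.na(arr)) ph[d >= arr] <- "breeding"
  if (!is.na(dep)) ph[d >= dep] <- "S-N"
  if (!is.na(ret)) ph[d >= ret] <- "foraging"
  ph
}

#' Per-phase summaries of single dives
#'
#' Descriptive statistics of maximum depth and duration by migration phase,
#' plus the deepest and longest dives on record with the phase they occurred
#' in. Phases without dives are omitted.
#'
#' @param dives tibble with `max_depth_m`, `duration_min`, `phase`.
#' @return list with `by_phase` (tibble `phase`, `n`, `mean_depth_m`,
#'   `sd_depth_m`, `mean_duration_min`, `sd_duration_min`) and `records`
#'   (deepest and longest dives).
#' @export
phase_dive_summary <- function(dives) {
  by_phase <- dives |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_depth_m = mean(.data$max_depth_m),
      sd_depth_m = if (dplyr::n() > 1) sd(.data$max_depth_m) else NA_real_,
      mean_duration_min = mean(.data$duration_min),
      sd_duration_min = if (dplyr::n() > 1) sd(.data$duration_min) else
        NA_real_,
      .groups = "drop")
  deepest <- dives[which.max(dives$max_depth_m), ]
  longest <- dives[which.max(dives$duration_min), ]
  list(by_phase = by_phase,
       records = tibble(
         record = c("deepest", "longest"),
         max_depth_m = c(deepest$max_depth_m, longest$max_depth_m),
         duration_min = c(deepest$duration_min, longest$duration_min),
         phase = c(deepest$phase, longest$phase)))
}

#' Read a delimited single-dive table
#'
#' Expected columns (canonical export of the simulator): `id`,
#' `timestamp_iso8601`, `max_depth_m`, `duration_min`.
#'
#' @param path delimited text file.
#' @return tibble `animal_id`, `date`, `max_depth_m`, `duration_min`.
#' @export
read_dives <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    id = "c", timestamp_iso8601 = "c", max_depth_m = "d",
    duration_min = "d"), progress = FALSE)
  tibble(animal_id = raw$id,
         date = as.POSIXct(strptime(raw$timestamp_iso8601,
                                    "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")),
         max_depth_m = raw$max_depth_m, duration_min = raw$duration_min)
}

#' Write single dives to the canonical CSV
#' @param dives tibble with `animal_id`, `date`, `max_depth_m`,
#'   `duration_min`.
#' @param path output file.
#' @export
write_dives <- function(dives, path) {
  readr::write_csv(tibble(
    id = dives$animal_id,
    timestamp_iso8601 = format(dives$date, "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC"),
    max_depth_m = dives$max_depth_m,
    duration_min = dives$duration_min), path)
  invisible(path)
}
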