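# End-to-end orchestration: cleaning, SDA filtering, state-space
# regularization, phenology detection, movement metrics, TSA grids and dive
# summaries, with every stage's output written as plain CSV/GeoJSON so any
# stage can be re-run and inspected in isolation.

#' Run the full migration-analysis pipeline
#'
#' @param tracks named list of raw `whale_track` (e.g. from
#'   [read_locations()] or [simulate_cohort()]).
#' @param out_dir output directory (created if needed).
#' @param dives optional tibble of single dives (`animal_id`, `date`,
#'   `max_depth_m`, `duration_min`) to summarise by phase.
#' @param filter_cfg a [filter_config()].
#' @param ssm_cfg an [ssm_config()].
#' @param rules a [segment_rules()].
#' @param migrant_threshold_km migrant classification threshold.
#' @param lat_limit breeding-ground latitude delineation, degrees N.
#' @param loess_span loess span for the arrival detector; when `NULL` the
#'   documented default 0.2 is used and a warning is logged.
#' @param cell_km TSA cell size, km.
#' @param tsa_exclude animal ids excluded from the TSA stage (analyst
#'   outlier decisions are configuration, never hard-coded).
#' @param fit_mpm logical; also fit the pooled move-persistence model
#'   (slower).
#' @return invisibly, a list with all stage outputs; files are written under
#'   `out_dir` and listed (with content hashes) in `MANIFEST.csv`.
#' @export
run_pipeline <- function(tracks, out_dir,
                         dives = NULL,
                         filter_cfg = filter_config(),
                         ssm_cfg = ssm_config(),
                         rules = segment_rules(),
                         migrant_threshold_km = 1000,
                         lat_limit = 45,
                         loess_span = NULL,
                         cell_km = 50,
                         tsa_exclude = character(0),
                         fit_mpm = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("whalemigrate pipeline, package version %s",
       as.character(utils::packageVersion("whalemigrate")))
  logf("started %s UTC", format(Sys.time(), tz = "UTC"))
  logf("n tracks: %d", length(tracks))
  if (is.null(loess_span)) {
    loess_span <- 0.2
    warn("loess span not set; falling back to default 0.2")
    logf("WARNING: loess span not set; falling back to default 0.2")
  }
  logf("parameters: vmax=%g m/s, dt_pred=%g h, gap=%g h, min seg=%g d, migrant threshold=%g km, lat limit=%g N, loess span=%g, cell=%g km",
       filter_cfg$vmax, ssm_cfg$dt_pred, rules$max_gap_h,
       rules$min_segment_duration_d, migrant_threshold_km, lat_limit,
       loess_span, cell_km)

  status <- "incomplete"
  on.exit({
    files <- setdiff(list.files(out_dir), "MANIFEST.csv")
    readr::write_csv(tibble(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      status = status), file.path(out_dir, "MANIFEST.csv"))
  }, add = TRUE)

  cleaned <- lapply(tracks, clean_track)
  meta <- dplyr::bind_rows(lapply(cleaned, track_meta,
                                  gap_threshold_h = rules$max_gap_h))
  readr::write_csv(meta, file.path(out_dir, "track_meta.csv"))

  cls <- dplyr::bind_rows(lapply(cleaned, classify_migrant,
                                 threshold_km = migrant_threshold_km))
  readr::write_csv(cls, file.path(out_dir, "classification.csv"))
  migrants <- cls$animal_id[cls$is_migrant]
  residents <- cls$animal_id[!cls$is_migrant]
  logf("migrants: %d of %d", length(migrants), length(cleaned))

  poly <- foraging_polygon(cleaned[residents])
  polygon_geojson(poly, file.path(out_dir, "foraging_polygon.geojson"))
  logf("foraging polygon: %d vertices, %.0f km2",
       nrow(poly$vertices), poly$area_km2)

  regs <- lapply(cleaned[migrants], regularize_track,
                 filter_cfg = filter_cfg, ssm_cfg = ssm_cfg, rules = rules)
  for (id in migrants) {
    rt <- regs[[id]]$whole_track
    readr::write_csv(
      tibble(id = id, timestamp = format(rt$date, "%Y-%m-%dT%H:%M:%SZ"),
             lat = rt$lat, lon = rt$lon,
             sd_km = sqrt((rt$sd_x_km^2 + rt$sd_y_km^2) / 2),
             segment_id = rt$segment_id),
      file.path(out_dir, paste0("rtrack_whole_", id, ".csv")))
  }

  phen <- detect_phenology(regs, poly, cleaned[migrants],
                           lat_limit = lat_limit, span = loess_span)
  readr::write_csv(phen$records, file.path(out_dir, "phenology.csv"))

  # cohort breeding-area MCP over all positions between arrival and
  # breeding departure (whole-track positions, all migrants pooled)
  bpts <- dplyr::bind_rows(lapply(migrants, function(id) {
    rec <- phen$records[phen$records$animal_id == id, ]
    if (is.na(rec$arrival_breeding_date)) return(NULL)
    rt <- regs[[id]]$whole_track
    to <- if (!is.na(rec$departure_breeding_date))
      rec$departure_breeding_date else as.Date(max(rt$date))
    sel <- as.Date(rt$date) >= rec$arrival_breeding_date &
      as.Date(rt$date) <= to
    tibble(lat = rt$lat[sel], lon = rt$lon[sel])
  }))
  breeding_mcp <- if (nrow(bpts) >= 3)
    tryCatch(mcp_polygon(bpts$lat, bpts$lon), error = function(e) NULL)
  else NULL
  if (!is.null(breeding_mcp)) {
    polygon_geojson(breeding_mcp,
                    file.path(out_dir, "breeding_polygon.geojson"))
    logf("breeding-area MCP: %.0f km2", breeding_mcp$area_km2)
  }

  # per-phase speeds on segments
  speed_tbl <- dplyr::bind_rows(lapply(migrants, function(id) {
    seg <- regs[[id]]$segments_only
    if (is.null(seg)) return(NULL)
    sm <- step_metrics(seg)
    rec <- phen$records[phen$records$animal_id == id, ]
    tibble(animal_id = id, date = sm$date, speed_kmh = sm$speed_kmh,
           phase = assign_phase(sm$date, rec))
  }))
  speed_summary <- speed_tbl |>
    dplyr::filter(!is.na(.data$speed_kmh)) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(n = dplyr::n(), mean_kmh = mean(.data$speed_kmh),
                     sd_kmh = sd(.data$speed_kmh), .groups = "drop")
  readr::write_csv(speed_summary,
                   file.path(out_dir, "speed_by_phase.csv"))

  mpm <- NULL
  if (fit_mpm) {
    segs <- Filter(Negate(is.null), lapply(regs, `[[`, "segments_only"))
    mpm <- tryCatch(fit_move_persistence(segs), error = function(e) {
      logf("move-persistence fit failed: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(mpm))
      readr::write_csv(mpm$series,
                       file.path(out_dir, "move_persistence.csv"))
  }

  tsa_ids <- setdiff(migrants, tsa_exclude)
  tsa_rts <- Filter(Negate(is.null),
                    lapply(regs[tsa_ids], `[[`, "segments_only"))
  tsa_phases <- lapply(names(tsa_rts), function(id) {
    rec <- phen$records[phen$records$animal_id == id, ]
    assign_phase(tsa_rts[[id]]$date, rec)
  })
  tsa <- accumulate_tsa(unname(tsa_rts), phases = tsa_phases,
                        cell_km = cell_km)
  write_tsa(tsa, file.path(out_dir, "tsa.csv"))
  readr::write_csv(tsa_summary(tsa), file.path(out_dir, "tsa_summary.csv"))

  dive_sum <- NULL
  if (!is.null(dives) && nrow(dives)) {
    labelled <- dplyr::bind_rows(lapply(split(dives, dives$animal_id),
                                        function(d) {
      rec <- phen$records[phen$records$animal_id == d$animal_id[1], ]
      d$phase <- if (nrow(rec)) assign_phase(d$date, rec) else "unknown"
      d
    }))
    dive_sum <- phase_dive_summary(labelled)
    readr::write_csv(dive_sum$by_phase,
                     file.path(out_dir, "dive_phase_summary.csv"))
    readr::write_csv(dive_sum$records,
                     file.path(out_dir, "dive_records.csv"))
  }

  status <- "complete"
  logf("finished %s UTC", format(Sys.time(), tz = "UTC"))
  invisible(list(meta = meta, classification = cls, polygon = poly,
                 regs = regs, phenology = phen,
                 breeding_mcp = breeding_mcp,
                 speed_summary = speed_summary, tsa = tsa, mpm = mpm,
                 dive_summary = dive_sum, out_dir = out_dir))
}
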