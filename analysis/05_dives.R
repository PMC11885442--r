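#!/usr/bin/env Rscript
# Dive summaries for the SPLASH-style animals: per-phase depth/duration
# statistics of the transmitted single dives, the record dives, and a
# consistency check that the 6-h histograms equal dive-by-dive binning.

library(whalemigrate)

dives <- read_dives("scratch/sim/dives.csv")
phen <- readr::read_csv("results/pipeline/phenology.csv",
                        show_col_types = FALSE)
phen$start_migration_date <- as.Date(phen$start_migration_date)
phen$arrival_breeding_date <- as.Date(phen$arrival_breeding_date)
phen$departure_breeding_date <- as.Date(phen$departure_breeding_date)
phen$return_north_date <- as.Date(phen$return_north_date)

labelled <- dplyr::bind_rows(lapply(split(dives, dives$animal_id),
                                    function(d) {
  rec <- phen[phen$animal_id == d$animal_id[1], ]
  d$phase <- if (nrow(rec)) assign_phase(d$date, rec) else "unknown"
  d
}))

s <- phase_dive_summary(labelled)
readr::write_csv(s$by_phase, "results/dive_by_phase.csv")
readr::write_csv(s$records, "results/dive_records.csv")
cat("single dives by phase (means +/- SD):\n")
print(s$by_phase)
cat("\nrecord dives:\n")
print(s$records)

cfg_b <- dive_bin_config("B")
h <- build_dive_histograms(labelled, cfg_b)
bb <- bin_dive(labelled$max_depth_m, labelled$duration_min, cfg_b)
cat(sprintf("\n6-h histograms: %d periods, %d binned dives (%d ignored)\n",
            nrow(h), sum(h$n_dives), sum(bb$ignored)))
stopifnot(sum(h$n_dives) == sum(!bb$ignored))
deep <- sum(unlist(lapply(h$depth_counts, function(x) sum(x[8:10]))))
cat(sprintf("dives deeper than 1,000 m: %d (%.0f%%)\n",
            deep, 100 * deep / sum(h$n_dives)))
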