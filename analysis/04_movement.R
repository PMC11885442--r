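#!/usr/bin/env Rscript
# Behavioural movement metrics on the regularized segments: the pooled
# move-persistence model (single shared variance pair across animals, so
# gamma is comparable between individuals) and the per-phase distributions
# of speed, persistence and time-in-area.

library(whalemigrate)

tracks <- read_locations("scratch/sim/locations.csv")
cleaned <- lapply(tracks, clean_track)
cls <- dplyr::bind_rows(lapply(cleaned, classify_migrant))
mig_ids <- cls$animal_id[cls$is_migrant]
poly <- foraging_polygon(cleaned[cls$animal_id[!cls$is_migrant]])
regs <- lapply(cleaned[mig_ids], regularize_track)
phen <- detect_phenology(regs, poly, cleaned[mig_ids])

segs <- Filter(Negate(is.null), lapply(regs, `[[`, "segments_only"))
mpm <- fit_move_persistence(segs)
cat(sprintf("pooled move-persistence fit: sigma_p = %.2f km, sigma_g = %.3f\n",
            mpm$sigma_p_km, mpm$sigma_g))

series <- mpm$series
series$phase <- NA_character_
for (id in unique(series$animal_id)) {
  rec <- phen$records[phen$records$animal_id == id, ]
  series$phase[series$animal_id == id] <-
    assign_phase(series$date[series$animal_id == id], rec)
}
gamma_by_phase <- series |>
  dplyr::group_by(phase) |>
  dplyr::summarise(n = dplyr::n(), mean_gamma = mean(gamma),
                   sd_gamma = sd(gamma), .groups = "drop")
readr::write_csv(gamma_by_phase, "results/gamma_by_phase.csv")
cat("\nmove persistence by phase (directed transit ~ 1, resident ~ 0):\n")
print(gamma_by_phase)

tsa <- readr::read_csv("results/pipeline/tsa_summary.csv",
                       show_col_types = FALSE)
cat("\ntime-in-area per 50-km cell by phase (hours):\n")
print(tsa)
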