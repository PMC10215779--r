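#!/usr/bin/env Rscript
# Stage 7 — score predictions against the independent legacy dataset.
#
# A legacy record counts as correctly predicted when its grid cell is
# suitable; per-genus accuracy is the percentage of such records. The
# suitable-ocean-area fraction is reported alongside, flagging genera
# whose near-global envelopes would inflate the percentage.

library(rhizoniche)

cfg <- readRDS("scratch/cache/01_env.rds")$cfg
maps <- readRDS("scratch/cache/06_maps.rds")$maps
legacy <- readRDS("scratch/cache/02_reports.rds")$legacy

rows <- list()
for (g in names(maps)) {
  leg <- legacy[legacy$genus == g, ]
  if (nrow(leg) == 0) next
  rows[[g]] <- legacy_accuracy(maps[[g]], leg, tolerance = cfg$tolerance)
}
acc <- accuracy_report(dplyr::bind_rows(rows), maps,
                       area_flag_threshold = cfg$area_flag_threshold)
readr::write_csv(acc, "results/tables/accuracy.csv")
print(as.data.frame(acc))
message(sprintf("Legacy accuracies span %.1f%% - %.1f%% across %d genera (%d flagged inflation-prone).",
                attr(acc, "accuracy_min"), attr(acc, "accuracy_max"),
                nrow(acc), sum(acc$flag)))
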