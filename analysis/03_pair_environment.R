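#!/usr/bin/env Rscript
# Stage 3 — pair reports with the climatology.
#
# Each report is paired with every grid cell within +/-2 degrees in the
# report's month; matches are averaged into a 28-value environmental
# profile. Reports are then snapped to 2-degree cells and accumulated into
# the curated multivariate abundance and environmental dataframe.

library(rhizoniche)

env <- readRDS("scratch/cache/01_env.rds")$env
cache <- readRDS("scratch/cache/02_reports.rds")
cfg <- readRDS("scratch/cache/01_env.rds")$cfg

frame <- build_frame(cache$reports, env, map_step = cfg$map_step,
                     window = cfg$window)
message(sprintf("Curated frame: %d cell-month rows from %d reports (%d unpairable).",
                nrow(frame), nrow(cache$reports), attr(frame, "n_unpairable")))
frame <- impute_frame(frame)
message(sprintf("Imputed %d rows across %d predictors.",
                sum(frame$.imputed), length(attr(frame, "imputation"))))

readr::write_csv(frame, "results/tables/curated_frame.csv")
saveRDS(frame, "scratch/cache/03_frame.rds")
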