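#!/usr/bin/env Rscript
# Stage 5 — per-genus random forests and predictor selection.
#
# Presence/absence labels follow the co-report pseudo-absence rule; one
# shared 80/20 split feeds every genus' 500-tree forest. The most
# informative predictors are cut at the largest mean-decrease-Gini gap
# (extended to the second-largest gap when only one predictor would
# remain).

library(rhizoniche)

cfg <- readRDS("scratch/cache/01_env.rds")$cfg
frame <- readRDS("scratch/cache/03_frame.rds")

lt <- build_labels(frame)
rf <- rfm_all(lt, split_seed = cfg$seeds$split, rf_seed = cfg$seeds$rf,
              n_trees = cfg$n_trees, train_fraction = cfg$train_fraction)

readr::write_csv(rf$summary, "results/tables/rf_summary.csv")
readr::write_csv(rf$importance, "results/tables/rf_importance.csv")
jsonlite::write_json(rf$selected, "results/tables/rf_selected.json",
                     auto_unbox = TRUE, pretty = TRUE)

print(as.data.frame(rf$summary))
ok <- !is.na(rf$summary$accuracy)
message(sprintf("Test accuracies span %.1f%% - %.1f%%.",
                min(rf$summary$accuracy[ok]), max(rf$summary$accuracy[ok])))
for (g in names(rf$selected)) {
  message(sprintf("  %-12s -> %s", g, paste(rf$selected[[g]], collapse = ", ")))
}
saveRDS(rf, "scratch/cache/05_rf.rds")
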