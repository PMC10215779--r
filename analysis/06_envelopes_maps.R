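#!/usr/bin/env Rscript
# Stage 6 — envelope habitat prediction and distribution maps.
#
# For each genus, the suitable habitat is the region where every selected
# predictor lies within the central 90% interval of the genus' positive
# profiles, in at least one month. Maps overlay report points on the
# predicted suitability mask.

library(rhizoniche)

cfg <- readRDS("scratch/cache/01_env.rds")$cfg
env <- readRDS("scratch/cache/01_env.rds")$env
frame <- readRDS("scratch/cache/03_frame.rds")
rf <- readRDS("scratch/cache/05_rf.rds")
rep_cache <- readRDS("scratch/cache/02_reports.rds")

envelopes <- list(); maps <- list()
for (g in names(rf$selected)) {
  sel <- rf$selected[[g]]
  if (length(sel) == 0) next
  pos <- frame[frame[[g]] > 0, , drop = FALSE]
  envelopes[[g]] <- build_envelope(pos, sel, central_fraction = cfg$central_fraction,
                                   genus = g)
  maps[[g]] <- predict_suitable(env, envelopes[[g]], month_mode = cfg$month_mode)
}

env_tab <- dplyr::bind_rows(lapply(envelopes, function(e) {
  dplyr::mutate(e$bounds, genus = e$genus, .before = 1)
}))
readr::write_csv(env_tab, "results/tables/envelopes.csv")
print(as.data.frame(env_tab))

for (g in names(maps)) {
  p <- plot_suitability_map(maps[[g]],
                            rep_cache$reports[rep_cache$reports$genus == g, ],
                            rep_cache$legacy[rep_cache$legacy$genus == g, ])
  ggplot2::ggsave(sprintf("results/figures/distribution_%s.png", g), p,
                  width = 8, height = 4.5, dpi = 150)
}
message(sprintf("Wrote %d distribution maps to results/figures/.", length(maps)))
saveRDS(list(envelopes = envelopes, maps = maps), "scratch/cache/06_maps.rds")
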