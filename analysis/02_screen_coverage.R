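#!/usr/bin/env Rscript
# Stage 2 — ingest, curate, and screen by sample coverage.
#
# Reads the report CSVs back through the validating ingest path, truncates
# taxa to genus rank, rounds coordinates to tenths, collapses reports to
# coordinate-level abundance, and retains genera whose estimated sample
# coverage exceeds 0.95 (saturated report data).

library(rhizoniche)

stopifnot(file.exists("scratch/cache/01_env.rds"))
cache <- readRDS("scratch/cache/01_env.rds")
cfg <- cache$cfg
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

ing <- read_reports("results/data/reports.csv", "inaturalist")
message(sprintf("Read %d rows; rejected %d (reasons: %s)",
                nrow(ing$reports) + nrow(ing$rejected), nrow(ing$rejected),
                paste(unique(ing$rejected$reason), collapse = ", ")))
reports <- round_reports(filter_taxonomy(ing$reports, cfg$genera))

leg <- read_reports("results/data/legacy.csv", "legacy")
legacy <- round_reports(filter_taxonomy(leg$reports, cfg$genera))

coverage <- retain_genera(reports, threshold = cfg$sc_threshold)
readr::write_csv(coverage, "results/tables/coverage.csv")
print(as.data.frame(coverage))
message(sprintf("%d of %d genera have saturated report data (SC > %.2f).",
                sum(coverage$retained), nrow(coverage), cfg$sc_threshold))

reports <- reports[reports$genus %in% coverage$genus[coverage$retained], ]
saveRDS(list(reports = reports, legacy = legacy, coverage = coverage),
        "scratch/cache/02_reports.rds")
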