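#!/usr/bin/env Rscript
# Extract the per-cell feature table from the simulated corpus
# (run 01_simulate_cohort.R first): access-resistance QC, passive
# properties, then rheobase/single-AP/train features for spiking cells or
# spikelet features with response classification for the rest.

suppressMessages(library(icephys))

corpus_dir <- "scratch/corpus"
if (!dir.exists(corpus_dir)) stop("corpus missing; run analysis/01_simulate_cohort.R")

cfg <- pipeline_config()
files <- list.files(corpus_dir, pattern = "\\.csv$", full.names = TRUE)
rows <- NULL
for (f in files) {
  s <- read_sweepset(f, "csv")
  qc <- qc_access_resistance(s, cfg$qc_threshold)
  if (!qc$passed) { cat("QC fail:", s$cell_id, "\n"); next }
  row <- tryCatch(extract_cell_features(s, cfg), error = function(e) {
    cat("feature failure:", s$cell_id, conditionMessage(e), "\n"); NULL
  })
  if (!is.null(row)) rows <- rbind(rows, as.data.frame(row))
}
write.csv(rows, "results/feature_table.csv", row.names = FALSE)
cat("features extracted for", nrow(rows), "cells\n")
cat("response classes:\n")
print(table(rows$response_class))
cat(sprintf("median Rin: spiking %.0f MOhm, immature %.0f MOhm\n",
            median(rows$rin_Mohm[rows$response_class == "mature_AP"]),
            median(rows$rin_Mohm[rows$response_class != "mature_AP"])))
cat(sprintf("median capacitance: spiking %.0f pF, immature %.0f pF\n",
            median(rows$cap_pF[rows$response_class == "mature_AP"]),
            median(rows$cap_pF[rows$response_class != "mature_AP"])))
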