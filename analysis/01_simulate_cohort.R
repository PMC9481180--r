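#!/usr/bin/env Rscript
# Build the synthetic study corpus: a cortical-plate-like cohort of spiking
# cells (two genotypes drawn from one parameter distribution) plus an
# immature cohort in which some cells produce small TTX-sensitive spikelets
# and the rest respond passively. Sweeps are written in the package's CSV
# dialect under scratch/corpus/ (bulk data; regenerated on demand) and the
# metadata table under results/.
#
# Sampling is at 10 kHz here to keep the corpus light; the estimators are
# rate-agnostic and the validation suite exercises the full 40 kHz
# protocol.

suppressMessages(library(icephys))

seed <- 20260924
corpus_dir <- "scratch/corpus"
dir.create(corpus_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

proto_spiking <- step_protocol(
  step_amplitudes = c(-25, -25, -25, seq(25, 300, 25)),
  sample_rate = 10000)
proto_spikelet <- step_protocol(step_amplitudes = 125, sample_rate = 10000)

set.seed(seed)
metadata <- NULL
n_cp <- 20    # cortical-plate-like spiking cells, 10 per genotype
n_mass <- 10  # immature sub-cortical-plate-like cells: 6 spikelet, 4 silent

for (i in seq_len(n_cp)) {
  id <- sprintf("cp%02d", i)
  geno <- if (i <= n_cp / 2) "control" else "cKO"
  p <- membrane_params(spike_mode = "adex",
                       leak_conductance = runif(1, 4, 6),
                       capacitance_true = runif(1, 120, 180),
                       adaptation_increment = runif(1, 40, 80))
  s <- simulate_spiking_cell(p, proto_spiking, seed = seed + i,
                             cell_id = id)$sweeps
  s$access_resistance <- c(10, runif(1, 9, 11))
  write_sweepset(s, file.path(corpus_dir, paste0(id, ".csv")), "csv")
  metadata <- rbind(metadata, data.frame(
    cell_id = id, genotype = geno, age_days = sample(5:10, 1),
    region = "S1_L5"))
}

for (i in seq_len(n_mass)) {
  id <- sprintf("mass%02d", i)
  p <- membrane_params(spike_mode = "spikelet",
                       leak_conductance = runif(1, 1.5, 3),   # high Rin
                       capacitance_true = runif(1, 15, 40),   # small soma
                       na_scale = if (i <= 6) runif(1, 0.7, 1.3) else 0)
  s <- simulate_spikelet_series(p, proto_spikelet, n_sweeps = 8,
                                seed = seed + 100 + i, cell_id = id)$sweeps
  # prepend hyperpolarizing sweeps for the passive measurements
  hyp <- simulate_passive_sweeps(
    membrane_params(leak_conductance = p$leak_conductance,
                    capacitance_true = p$capacitance_true),
    step_protocol(step_amplitudes = -25, sample_rate = 10000),
    noise_sd = 0.3, n_sweeps = 3, seed = seed + 200 + i)$sweeps
  proto <- s$protocol
  proto$step_amplitudes <- c(hyp$protocol$step_amplitudes,
                             s$protocol$step_amplitudes)
  all_sweeps <- c(hyp$sweeps, s$sweeps)
  for (j in seq_along(all_sweeps)) all_sweeps[[j]]$sweep_id <- sprintf("s%02d", j)
  s2 <- sweep_set(id, proto, all_sweeps,
                  access_resistance = c(10, runif(1, 9.5, 10.5)))
  write_sweepset(s2, file.path(corpus_dir, paste0(id, ".csv")), "csv")
  metadata <- rbind(metadata, data.frame(
    cell_id = id, genotype = "cKO", age_days = sample(3:10, 1),
    region = "subCP_mass"))
}

write.csv(metadata, "results/cohort_metadata.csv", row.names = FALSE)
cat("wrote", n_cp + n_mass, "cells to", corpus_dir, "\n")
cat("genotype x region counts:\n")
print(table(metadata$genotype, metadata$region))
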