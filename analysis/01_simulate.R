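#!/usr/bin/env Rscript
# Stage 1: simulate a synthetic world of haemoglobin distributions and the
# heterogeneous surveys observing it (2 regions x 5 countries, 1990-2012,
# ~2 surveys per country-decade with summary-only, combined-women,
# subnational, and unadjusted-altitude sources), and write the survey CSVs
# plus the ground-truth table under results/sim/.
suppressMessages(library(hbtrends))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

out <- "results/sim"
res <- run_simulate(out, world_config(seed = seed), survey_design(),
                    seed = seed + 1L, force = TRUE)
obs <- res$surveys$observations
cat("Simulated", length(unique(obs$source_id)), "surveys over",
    length(res$world$countries), "countries:",
    sum(obs$data_form == "summary"), "summary cells,",
    sum(obs$data_form == "individual"), "individual-level cells,",
    nrow(res$surveys$individuals), "individual records.\n")
cat("Outputs in", out, "(see manifest.json for content hashes).\n")
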