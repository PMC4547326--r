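#!/usr/bin/env Rscript
# Stage 3: turn posterior draws into the reported quantities: mean
# haemoglobin, total and severe anaemia prevalence and counts for every
# country, region, and the world in 1995 and 2011 with 2.5th-97.5th centile
# credibility intervals; change per decade with posterior trend
# probabilities; the probability of halving anaemia prevalence by 2025; and
# the share of anaemia amenable to iron supplementation.
suppressMessages(library(hbtrends))

fits <- readRDS("results/fit/fits.rds")
tabs <- run_summarize(fits, "results/summaries",
                      years = c(1995, 2011), y1 = 1995, y2 = 2011,
                      target_year = 2025, seed = 1)
cat("Wrote", nrow(tabs$estimates), "estimate cells,",
    nrow(tabs$trends), "trend rows,",
    nrow(tabs$halving), "halving probabilities, and",
    nrow(tabs$iron_share), "iron-amenable shares to results/summaries/.\n")
glob <- tabs$estimates[tabs$estimates$scope == "globe" &
                         tabs$estimates$metric == "prev_total" &
                         tabs$estimates$year == 2011, ]
cat("Global total-anaemia prevalence, 2011 (posterior mean and 95% CrI):\n")
print(glob[, c("group", "point", "lo", "hi")], row.names = FALSE)
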