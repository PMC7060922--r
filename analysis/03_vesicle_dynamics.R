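#!/usr/bin/env Rscript
# Mobile/static vesicle counting: decompose each 1-min bin against its
# average projection, detect foci by the three-criterion rule, count per
# 100 um^2 ROI, and check the post-insulin plateau against the configured
# truth (2 mobile visits per 100 um^2 per min) over 10 seeds.

suppressPackageStartupMessages(library(tirfdyn))
dir.create("results", showWarnings = FALSE)

counts_all <- list()
plateaus <- numeric(10)
for (s in 1:10) {
  counts <- run_dynamics_study(seed = s)
  counts$seed <- s
  counts_all[[s]] <- counts
  plateaus[s] <- plateau_mobile_count(counts)
  cat(sprintf("seed %2d: plateau mobile %.2f per ROI\n", s, plateaus[s]))
}
counts_all <- do.call(rbind, counts_all)
write.csv(counts_all, "results/roi_counts.csv", row.names = FALSE)

tab <- aggregate(cbind(mobile_count, static_count) ~ bin_index + t_min,
                 counts_all, mean)
write.csv(tab, "results/counts_by_bin.csv", row.names = FALSE)
cat("\nmean counts per ROI by time bin (10 seeds x 10 ROIs):\n")
print(tab, digits = 3)
cat(sprintf(
  "\npost-insulin plateau: %.2f mobile per 100 um^2 (truth 2.0; %+.0f%%)\n",
  mean(plateaus), 100 * (mean(plateaus) / 2 - 1)))
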