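#!/usr/bin/env Rscript
# Stage 2: translational efficiencies and Kasugamycin effect values.
#
# Reads the simulated intensity table, computes per-replicate TEs
# (polysomal/free), applies the CV-triggered outlier rule and the
# 3-of-5-replicates filter, median-normalizes the log2 treated/untreated TE
# ratios into KEVs, classifies genes at the twofold thresholds and attaches
# per-gene Welch p-values. Compares the estimates against the generator's
# ground truth.

suppressPackageStartupMessages(library(ksgtome))

measurements <- read_measurements("scratch/simulated/measurements.tsv")
truth <- readr::read_tsv("scratch/simulated/truth.tsv",
                         show_col_types = FALSE)

res <- kev_analysis(measurements)
dir.create("results", showWarnings = FALSE)
write_kev_results(res, "results/kev_results.tsv")
readr::write_tsv(kev_distribution(res$log2_kev[res$pass]),
                 "results/kev_histogram.tsv")

n_pass <- sum(res$pass)
cat(sprintf("%d of %d genes passed the >=3-replicates filter (%.1f%%)\n",
            n_pass, nrow(res), 100 * n_pass / nrow(res)))
cat(sprintf("classified: %s\n",
            paste(sprintf("%s=%d", names(table(res$class[res$pass])),
                          table(res$class[res$pass])), collapse = ", ")))
cat(sprintf("median log2 KEV after normalization: %.3g\n",
            median(res$log2_kev[res$pass])))
span <- range(res$kev[res$pass])
cat(sprintf("most resistant / most sensitive KEV ratio: %.0f-fold\n",
            span[2] / span[1]))

m <- merge(res[res$pass, ], truth, by = "gene_id")
rmse <- sqrt(mean((m$log2_kev - m$true_log2_kev)^2))
recall <- sapply(c("sensitive", "resistant"), function(g)
  mean(m$class.x[m$class.y == g] == g))
cat(sprintf("log2 KEV RMSE vs truth: %.3f; recall sensitive %.2f, resistant %.2f\n",
            rmse, recall[1], recall[2]))
cat("tables written: results/kev_results.tsv, results/kev_histogram.tsv\n")
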