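#!/usr/bin/env Rscript
# Step 1 — simulate the screening cohorts.
#
# Generates a synthetic annotated cohort shaped like the primary study
# cohort (395 individuals, 177 couples of which 21 consanguineous, ~287x
# coverage, ~9.3 calls/individual) and a larger confirmation cohort (999
# individuals, ~57x, ~7.4 calls/individual), and writes the annotated
# call tables, pedigree, per-sample metrics and hidden truth labels under
# results/sim/.

suppressMessages(library(cilioscreen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(sub("--seed=", "", args[1])) else 1L

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

local <- generate_cohort(cohort_sim_params(seed = seed))
write_variant_table(local$calls, "results/sim/local_calls.tsv")
write_pedigree(local$pedigree, "results/sim/local.ped")
write.table(local$metrics, "results/sim/local_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(local$truth, "results/sim/local_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(local$child_genotypes, "results/sim/local_child_genotypes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

uk <- generate_cohort(uk_cohort_params(seed = seed + 1L))
write_variant_table(uk$calls, "results/sim/uk_calls.tsv")
write.table(uk$metrics, "results/sim/uk_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(uk$truth, "results/sim/uk_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("local cohort: %d individuals, %d calls (%.2f/individual)\n",
            nrow(local$metrics), nrow(local$calls),
            nrow(local$calls) / nrow(local$metrics)))
cat(sprintf("UK-like cohort: %d individuals, %d calls (%.2f/individual)\n",
            nrow(uk$metrics), nrow(uk$calls),
            nrow(uk$calls) / nrow(uk$metrics)))
cat("pairwise predictor-score correlations:",
    sprintf("%.2f..%.2f\n",
            min(cor(as.matrix(local$scores))[upper.tri(diag(9))]),
            max(cor(as.matrix(local$scores))[upper.tri(diag(9))])))
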