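#!/usr/bin/env Rscript
# Step 4 — strong-VUS prioritization.
#
# Ranks the strong VUS for future functional testing: per-gene missense
# score (share of missense P/LP disease alleles) combined with the
# structural deleteriousness category; first priority = ms-score > 0.1
# and structural score > 0.7. Also contrasts the cohort's per-gene
# variant-type spectrum with the patient-cohort spectrum.

suppressMessages(library(cilioscreen))

tiered <- read_variant_table("results/tiered_calls.tsv", "tsv")
assign <- read.delim("results/tier_assignments.tsv")
tiered$tier <- assign$tier[match(tiered$variant_key, assign$variant_key)]

panel <- ciliopathy_panel()
gs <- missense_score(panel)
vus <- tiered[tiered$tier == "STRONG_VUS", ]
pr <- prioritize(vus, gs)
cat(sprintf("%d unique strong VUS, %d first priority\n",
            nrow(pr), sum(pr$first_priority)))
write.table(pr, "results/vus_priorities.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sp <- spectrum_comparison(tiered, panel)
sp <- sp[order(-sp$divergence), ]
cat("largest cohort-vs-patient spectrum divergences:\n")
print(head(sp[, c("gene", "n_cohort", "cohort_missense_prop",
                  "patient_missense_prop", "divergence")], 5),
      row.names = FALSE)
write.table(sp, "results/spectrum_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
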