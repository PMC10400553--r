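#!/usr/bin/env Rscript
# Step 3 — tier classification.
#
# Assigns each high-confidence call to PATHOGENIC / NOVEL_LOF /
# STRONG_VUS / EXCLUDED with the ordered rule set (whitelist, benign
# override, MAF <= 0.1%, PVS1+PM2 with database support, ClinVar+HGMD
# concordance, LP-limited, HGMD-only, CADD/M-CAP/4-of-7 ensemble) and
# writes the tiered table plus tier counts.

suppressMessages(library(cilioscreen))

calls <- read_variant_table("results/high_confidence.tsv", "tsv")
cc <- classify_cohort(calls, recurring_allele_whitelist(),
                      default_thresholds())
print(cc$counts)
write_variant_table(cc$calls, "results/tiered_calls.tsv")
extra <- cc$calls[, c("variant_key", "tier", "fired_criteria", "reportable")]
write.table(extra, "results/tier_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cc$counts, "results/tier_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
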