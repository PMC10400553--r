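#!/usr/bin/env Rscript
# Step 2 — call-quality filtering.
#
# Applies the sample-level coverage gate and the rule-based per-call
# cut-offs (16% alternate reads, 20x depth), then trains the linear SVM
# on the labeled simulated calls and scores the cohort, writing the
# high-confidence call set and the serialized model.

suppressMessages(library(cilioscreen))

calls <- read_variant_table("results/sim/local_calls.tsv", "tsv")
metrics <- read.delim("results/sim/local_metrics.tsv")
truth <- read.delim("results/sim/local_truth.tsv")

gate <- sample_quality_gate(metrics)
passing <- gate$sample_id[gate$gate == "PASS"]
cat(sprintf("sample gate: %d/%d samples pass (>=85%% of exome at >=20x)\n",
            length(passing), nrow(metrics)))
calls <- calls[calls$sample_id %in% passing, ]
truth <- truth[truth$sample_id %in% passing, ]

flt <- preprocess_filter(calls)
cat(sprintf("rule-based filter: %d retained, %d excluded (%s)\n",
            nrow(flt$retained), nrow(flt$excluded),
            paste(names(table(flt$excluded$reason)),
                  table(flt$excluded$reason), collapse = ", ")))

# the simulator's QC feature columns were dropped by the TSV schema;
# train on depth + alternate fraction, the features the cut-offs name
train <- calls
train$label <- ifelse(truth$artifact, "FALSE_CALL", "TRUE_CALL")
model <- train_call_classifier(train)
scored <- score_calls(model, flt$retained)
cat(sprintf("SVM: %d high-confidence, %d rejected\n",
            nrow(scored$high_confidence), nrow(scored$rejected)))

dir.create("results", showWarnings = FALSE)
write_variant_table(scored$high_confidence, "results/high_confidence.tsv")
write_call_model(model, "results/call_model.json")
writeLines(passing, "results/passing_samples.txt")
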