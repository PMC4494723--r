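#!/usr/bin/env Rscript
# Step 1 — simulate the study corpus.
#
# Generates a ground-truth-labeled synthetic tweet corpus under the default
# event regime (11-day span, event spike, homonym confounders) at the
# 3,000-user scale used throughout the analysis, and writes the JSON-lines
# corpus plus truth sidecars for the later steps.

library(crisistri)

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_profile("scaled_regime", seed = 20130210)
g <- generate_corpus(cfg)

write_corpus_jsonl(g$records, "scratch/corpus.jsonl")
write.csv(as.data.frame(g$truth$users), "scratch/truth_users.csv", row.names = FALSE)
write.csv(as.data.frame(g$truth$tallies), "results/01_simulated_window_tallies.csv",
          row.names = FALSE)

n_reg <- sum(g$truth$users$is_regional)
cat(sprintf("Simulated %d tweets from %d active users (%d regional, %d homonym confounders).\n",
            nrow(g$records), nrow(g$truth$users), n_reg,
            sum(g$truth$users$confounder)))
cat("Planted per-window tallies (default -50h/+46h window):\n")
print(as.data.frame(g$truth$tallies))
cat("Corpus written to scratch/corpus.jsonl; truth labels to scratch/truth_users.csv\n")
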