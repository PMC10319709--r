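#!/usr/bin/env Rscript
# Build patient representations (mean-aggregated text vectors + the
# 15-feature tabular block) and train the three logistic risk models with
# Adam on binary cross-entropy, early-stopped on validation loss.

suppressPackageStartupMessages(library(crcnotes))

cohort <- read_cohort("results/cohort.jsonl")
windows <- build_windows(cohort)
split <- data.table::fread("results/split.csv")
embedding <- read_embedding("results/embedding.txt")
phrases <- jsonlite::fromJSON("results/phrases.json")

features <- build_features(windows, split, embedding, phrases)
write_features(features, "results/features.csv")

te <- features$part == "test"
scores <- data.frame(patient_id = features$ids[te], label = features$label[te])
for (kind in c("Tab", "Txt", "TabTxt")) {
  m <- fit_risk_model(kind, features, seed = 20260104,
                      max_epochs = 300L, batch_size = 64L,
                      patience = 30L, lr = 1e-2)
  print(m)
  write_risk_model(m, sprintf("results/model_%s.json", kind))
  scores[[kind]] <- predict(m, assemble_inputs(kind, features,
                                               features$ids[te]))
}
write.csv(scores, "results/scores.csv", row.names = FALSE)
cat(sprintf("wrote test scores for %d patients (%d cases)\n",
            nrow(scores), sum(scores$label)))
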