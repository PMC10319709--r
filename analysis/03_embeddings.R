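#!/usr/bin/env Rscript
# Train skip-gram negative-sampling word embeddings offline on the
# training-split window notes plus under-30 patients' notes, after one
# bigram-merging pass. Persists the embedding matrix as plain text.

suppressPackageStartupMessages(library(crcnotes))

cohort <- read_cohort("results/cohort.jsonl")
windows <- build_windows(cohort)
split <- data.table::fread("results/split.csv")

corpus <- build_training_corpus(windows, split)
cat(sprintf("corpus: %d notes, %d tokens\n", length(corpus),
            length(unlist(corpus))))

corpus <- detect_bigrams(corpus, delta = 5, threshold = 10)
phrases <- attr(corpus, "phrases")
cat(sprintf("bigram pass merged %d phrase types\n", length(phrases$keys)))

embedding <- train_sgns(corpus, dim = 50, window = 5, negative = 5,
                        subsample = 1e-5, min_count = 3, epochs = 5,
                        seed = 20260103)
print(embedding)
cat("per-epoch mean SGNS loss:",
    paste(round(embedding$epoch_loss, 4), collapse = " "), "\n")
write_embedding(embedding, "results/embedding.txt")
jsonlite::write_json(phrases, "results/phrases.json", auto_unbox = TRUE)
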