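#!/usr/bin/env Rscript
# Simulate the study cohort: consultation-level EMR records with a 0.89%
# CRC prevalence, short noisy notes (mode 7 words), elevated symptom-code
# rates and planted signal tokens in cases' pre-diagnosis windows.
# Writes the cohort as JSON Lines plus a Table-1-style summary.

suppressPackageStartupMessages(library(crcnotes))
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(seed = 20260101, n_patients = 20000)
cohort <- generate_cohort(cfg)
print(cohort)
write_cohort(cohort, "results/cohort.jsonl")

# cohort characteristics alongside the reference population percentages
w <- build_windows(cohort)
p <- w$patients[w$patients$included]
bracket <- cut(p$age_at_anchor, c(30, 60, 70, 80, Inf), right = FALSE,
               labels = c("age_30_60", "age_60_70", "age_70_80", "age_80_plus"))
char <- data.frame(
  group = c("total", "female", levels(bracket)),
  crc_pct = round(100 * c(mean(p$label),
                          mean(p$gender[p$label == 1] == "female"),
                          as.numeric(table(bracket[p$label == 1])) / sum(p$label)), 2),
  non_crc_pct = round(100 * c(1 - mean(p$label),
                              mean(p$gender[p$label == 0] == "female"),
                              as.numeric(table(bracket[p$label == 0])) / sum(1 - p$label)), 2))
write.csv(char, "results/cohort_characteristics.csv", row.names = FALSE)
cat(sprintf("included %d of %d patients; %d cases (%.2f%%)\n",
            nrow(p), nrow(cohort$patients), sum(p$label),
            100 * mean(p$label)))
print(char)
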