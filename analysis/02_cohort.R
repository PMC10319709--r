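#!/usr/bin/env Rscript
# Label patients (first D75 code = case anchor; controls anchored at the
# last visit), extract the two-year observation windows ending five months
# before the anchor, apply the inclusion rule and write the stratified
# 60/20/20 split.

suppressPackageStartupMessages(library(crcnotes))

cohort <- read_cohort("results/cohort.jsonl")
windows <- build_windows(cohort)
print(windows)

split <- split_data(windows, seed = 20260102)
data.table::fwrite(split, "results/split.csv")
print(table(split$part, split$label))

# window-level note profile: length distribution of retained cleaned notes
lens <- lengths(tokenize_note(windows$consultations$note_clean))
lens <- lens[lens > 0 & lens <= 15]
profile <- data.frame(words = 1:15,
                      fraction = round(tabulate(lens, 15) / length(lens), 4))
write.csv(profile, "results/note_length_profile.csv", row.names = FALSE)
cat(sprintf("mode of window note lengths: %d words (fraction %.3f)\n",
            which.max(profile$fraction), max(profile$fraction)))
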