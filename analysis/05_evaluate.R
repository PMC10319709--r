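#!/usr/bin/env Rscript
# The full evaluation protocol on the held-out test set: 1000 paired
# bootstrap resamples; per model the median and 2.5th/97.5th percentiles
# of AUROC, AUPRC, specificity at sensitivity >= 0.95 and Brier score;
# pairwise AUROC-difference intervals with the 0-exclusion significance
# rule; PR curves with decision-threshold dots and LOWESS calibration
# curves with the 99th-percentile marker.

suppressPackageStartupMessages(library(crcnotes))

sc <- read.csv("results/scores.csv")
scores <- list(Tab = sc$Tab, Txt = sc$Txt, TabTxt = sc$TabTxt)
report <- bootstrap_evaluate(scores, sc$label, n_boot = 1000,
                             seed = 20260105)
print(report)

data.table::fwrite(report$metrics, "results/metrics.csv")
data.table::fwrite(report$comparisons, "results/comparisons.csv")
jsonlite::write_json(list(metrics = report$metrics,
                          comparisons = report$comparisons,
                          n = report$n, n_boot = report$n_boot,
                          seed = report$seed),
                     "results/report.json", auto_unbox = TRUE, digits = NA)

dir.create("results/figures", showWarnings = FALSE)
gg <- plot_pr_curves(scores, sc$label, annotate_at = c(0.02, 0.05, 0.1))
ggplot2::ggsave("results/figures/pr_curves.svg", gg, width = 7, height = 5,
                device = grDevices::svg)
for (m in names(scores)) {
  gg <- plot_calibration(scores[[m]], sc$label)
  ggplot2::ggsave(sprintf("results/figures/calibration_%s.svg", m), gg,
                  width = 6, height = 5, device = grDevices::svg)
}
cat("figures written to results/figures\n")
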