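# Independent brute-force oracles used to pin down the evaluation
# operations. These deliberately use naive loops over all pairs /
# thresholds, not the package's vectorized code paths.

auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

pr_points_brute <- function(scores, labels, min_sens = NULL) {
  taus <- sort(unique(scores), decreasing = TRUE)
  out <- data.frame(threshold = taus, precision = NA_real_, recall = NA_real_,
                    specificity = NA_real_)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  for (i in seq_along(taus)) {
    pred <- scores >= taus[i]
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    out$precision[i] <- tp / (tp + fp)
    out$recall[i] <- tp / n1
    out$specificity[i] <- if (n0 > 0) sum(!pred & labels == 0) / n0 else NA
  }
  out
}

auprc_brute <- function(scores, labels) {
  pts <- pr_points_brute(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

spec_at_sens_brute <- function(scores, labels, min_sens = 0.95) {
  if (min_sens <= 0) return(list(threshold = Inf, specificity = 1))
  pts <- pr_points_brute(scores, labels)
  ok <- pts$recall >= min_sens
  tau <- max(pts$threshold[ok])
  list(threshold = tau, specificity = pts$specificity[pts$threshold == tau])
}

# small deterministic cohort for structural tests
tiny_cohort <- function(seed = 42, n = 400, prevalence = 0.05, ...) {
  generate_cohort(synth_config(seed = seed, n_patients = n,
                               prevalence = prevalence, ...))
}

# fast SGNS settings for tests
fast_sgns <- function(corpus, ...) {
  train_sgns(corpus, dim = 16L, epochs = 3L, subsample = 1e-3,
             min_count = 1L, seed = 7L, ...)
}
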