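#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly drawn
#' positive outscores a uniformly drawn negative, ties counted one half
#' (midranks).
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels 0/1 outcomes.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC requires both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall curve and its area
#'
#' Precision and recall at every distinct score threshold (predict
#' positive iff score >= threshold). The area uses the step-wise
#' precision-at-recall rule `sum((R_i - R_{i-1}) * P_i)` (average
#' precision), avoiding the bias of linear interpolation in PR space.
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcomes (at least one positive).
#' @param annotate_at optional decision thresholds to annotate; each is
#'   mapped to the closest achieved threshold point.
#' @return a `pr_curve`: list(curve = data.table(threshold, precision,
#'   recall), auprc, annotations).
#' @export
pr_curve <- function(scores, labels, annotate_at = NULL) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("PR analysis requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # collapse tied scores: threshold blocks end at the last index of a tie
  last <- which(diff(s) != 0)
  last <- c(last, length(s))
  thr <- s[last]
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / n1
  auprc <- sum(diff(c(0, recall)) * precision)
  ann <- NULL
  if (!is.null(annotate_at)) {
    j <- vapply(annotate_at, function(t0) which.min(abs(thr - t0)), integer(1))
    ann <- data.table::data.table(requested = annotate_at, threshold = thr[j],
                                  precision = precision[j], recall = recall[j])
  }
  out <- list(curve = data.table::data.table(threshold = thr,
                                             precision = precision,
                                             recall = recall),
              auprc = auprc, annotations = ann)
  class(out) <- "pr_curve"
  out
}

#' Area under the precision-recall curve
#'
#' @inheritParams pr_curve
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) pr_curve(scores, labels)$auprc

#' Decision threshold for a sensitivity floor
#'
#' The largest threshold tau (predict positive iff score >= tau) whose
#' sensitivity is at least `min_sens`; being the largest such threshold it
#' maximises specificity subject to the constraint. With `min_sens = 0`
#' the constraint is vacuous and `tau = Inf` (specificity 1).
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcomes (at least one positive).
#' @param min_sens sensitivity floor (default 0.95).
#' @return list(threshold, sensitivity, specificity).
#' @export
threshold_for_sensitivity <- function(scores, labels, min_sens = 0.95) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L)
    stop("requires at least one positive", call. = FALSE)
  if (min_sens <= 0)
    return(list(threshold = Inf, sensitivity = 0,
                specificity = if (n0 == 0L) NA_real_ else 1))
  # sensitivity is non-increasing in the threshold: walk distinct
  # thresholds downward and stop at the first (i.e. largest) meeting the
  # floor
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  sens <- tp / n1
  j <- which(sens >= min_sens)[1L]  # exists: sensitivity reaches 1
  list(threshold = s[last][j], sensitivity = sens[j],
       specificity = if (n0 == 0L) NA_real_ else 1 - fp[j] / n0)
}

#' Brier score
#'
#' Mean squared error of predicted probabilities:
#' `mean((p_i - y_i)^2)`.
#'
#' @param probabilities predictions in [0, 1].
#' @param labels 0/1 outcomes.
#' @return Brier score in [0, 1].
#' @export
brier <- function(probabilities, labels) {
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mean((probabilities - as.numeric(labels))^2)
}

#' Brier skill score against a reference predictor
#'
#' `1 - model / reference`: 1 is maximal improvement, 0 none, negative is
#' worse than the reference. Typical references are the constant-prevalence
#' predictor and the constant-zero ("no cancer") predictor.
#'
#' @param model_brier Brier score of the model.
#' @param reference_brier Brier score of the reference (> 0).
#' @return skill score (<= 1).
#' @export
brier_skill <- function(model_brier, reference_brier) {
  if (reference_brier <= 0)
    stop("reference Brier score must be positive", call. = FALSE)
  1 - model_brier / reference_brier
}

#' LOWESS calibration curve
#'
#' Locally weighted linear smoothing of the observed outcome against the
#' predicted probability, clipped to [0, 1], with the empirical 99th
#' percentile of the predictions recorded as a display cutoff (predictions
#' above it are too sparse to calibrate meaningfully at low prevalence).
#'
#' @param probabilities predictions in [0, 1] (n >= 50).
#' @param labels 0/1 outcomes.
#' @param fraction LOWESS span (default 0.6).
#' @return a `calibration_curve`: list(curve = data.table(predicted,
#'   observed), percentile_99).
#' @export
calibration_curve <- function(probabilities, labels, fraction = 0.6) {
  if (length(probabilities) < 50L)
    stop("calibration smoothing needs n >= 50", call. = FALSE)
  if (diff(range(probabilities)) < 1e-8) {
    # constant predictor: the curve collapses to one point
    sm <- list(x = rep(mean(probabilities), 2L),
               y = rep(mean(as.numeric(labels)), 2L))
  } else {
    # iter = 0: robustness reweighting would treat the rare 1s of a binary
    # outcome as outliers and bias the curve toward 0
    sm <- stats::lowess(probabilities, as.numeric(labels), f = fraction,
                        iter = 0)
  }
  out <- list(
    curve = data.table::data.table(predicted = sm$x,
                                   observed = pmin(pmax(sm$y, 0), 1)),
    percentile_99 = as.numeric(stats::quantile(probabilities, 0.99)),
    fraction = fraction
  )
  class(out) <- "calibration_curve"
  out
}

eval_metrics_once <- function(scores, labels, min_sens, ref_prevalence) {
  th <- threshold_for_sensitivity(scores, labels, min_sens)
  # Brier analysis applies only to probability-scale scores
  is_prob <- all(scores >= 0 & scores <= 1)
  b <- if (is_prob) brier(scores, labels) else NA_real_
  b_prev <- brier(rep(ref_prevalence, length(labels)), labels)
  b_zero <- brier(rep(0, length(labels)), labels)
  c(auroc = auroc(scores, labels),
    auprc = auprc(scores, labels),
    specificity = th$specificity,
    sensitivity = th$sensitivity,
    brier = b,
    bss_prevalence = if (is_prob) brier_skill(b, b_prev) else NA_real_,
    bss_zero = if (is_prob && b_zero > 0) brier_skill(b, b_zero) else NA_real_)
}

#' Paired percentile-bootstrap evaluation of one or more models
#'
#' Draws `n_boot` resamples (with replacement, size = test n) of patient
#' indices; the same index vector is applied to every model within a
#' replicate, so model differences are paired. Per model and metric the
#' bootstrap median and 2.5th/97.5th percentiles are reported; per model
#' pair, the percentile interval of the per-replicate AUROC differences
#' with the 0-exclusion significance rule. The sensitivity-floor threshold
#' is recomputed inside every replicate. Replicates containing a single
#' class are redrawn so exactly `n_boot` valid replicates are used.
#'
#' @param scores named list of score vectors (one per model), all over the
#'   same patients.
#' @param labels 0/1 outcomes.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param min_sens sensitivity floor for the specificity metric.
#' @param ref_prevalence reference prevalence for the Brier-skill baseline;
#'   default is the observed test-set prevalence.
#' @return an `eval_report`: list(metrics, comparisons, auroc_boot,
#'   n_boot, seed, n, redraws).
#' @export
bootstrap_evaluate <- function(scores, labels, n_boot = 1000L, seed = 1L,
                               min_sens = 0.95, ref_prevalence = NULL) {
  if (!is.list(scores)) scores <- list(model = scores)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    names(scores) <- paste0("model", seq_along(scores))
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(all(vapply(scores, length, integer(1)) == n))
  ref_prevalence <- ref_prevalence %||% mean(labels)
  models <- names(scores)
  metric_names <- c("auroc", "auprc", "specificity", "sensitivity", "brier",
                    "bss_prevalence", "bss_zero")

  point <- vapply(scores, eval_metrics_once, numeric(7), labels = labels,
                  min_sens = min_sens, ref_prevalence = ref_prevalence)

  boot <- array(NA_real_, dim = c(n_boot, length(models), 7L),
                dimnames = list(NULL, models, metric_names))
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        redraws <- redraws + 1L
      }
      yb <- labels[idx]
      for (m in models)
        boot[r, m, ] <- eval_metrics_once(scores[[m]][idx], yb,
                                          min_sens, ref_prevalence)
    }
  })
  if (redraws > 0L)
    message(sprintf("bootstrap_evaluate: %d single-class replicate(s) redrawn",
                    redraws))

  qs <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), na.rm = TRUE,
                                    names = FALSE)
  metrics <- data.table::rbindlist(lapply(models, function(m) {
    data.table::rbindlist(lapply(metric_names, function(mm) {
      q <- qs(boot[, m, mm])
      data.table::data.table(model = m, metric = mm,
                             point = point[mm, m], median = q[1],
                             ci_low = q[2], ci_high = q[3])
    }))
  }))

  comparisons <- NULL
  if (length(models) >= 2L) {
    pairs <- utils::combn(models, 2L)
    comparisons <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      d <- boot[, a, "auroc"] - boot[, b, "auroc"]
      q <- qs(d)
      data.table::data.table(
        model_a = a, model_b = b, metric = "auroc",
        diff_median = q[1], ci_low = q[2], ci_high = q[3],
        significant = q[2] > 0 || q[3] < 0)
    }))
  }

  out <- list(metrics = metrics, comparisons = comparisons,
              auroc_boot = boot[, , "auroc", drop = TRUE],
              boot = boot, n_boot = as.integer(n_boot),
              seed = as.integer(seed), n = n, redraws = redraws,
              ref_prevalence = ref_prevalence, min_sens = min_sens)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, %d bootstrap replicates (seed %d)\n",
              x$n, x$n_boot, x$seed))
  show <- x$metrics[x$metrics$metric %in%
                      c("auroc", "auprc", "specificity", "brier")]
  for (m in unique(show$model)) {
    rows <- show[show$model == m]
    cat(sprintf("  %-8s %s\n", m,
                paste(sprintf("%s %.4f (%.4f-%.4f)", rows$metric,
                              rows$median, rows$ci_low, rows$ci_high),
                      collapse = "  ")))
  }
  if (!is.null(x$comparisons)) {
    for (i in seq_len(nrow(x$comparisons))) {
      r <- x$comparisons[i]
      cat(sprintf("  dAUROC %s - %s: %.4f (%.4f-%.4f)%s\n", r$model_a,
                  r$model_b, r$diff_median, r$ci_low, r$ci_high,
                  if (r$significant) " *" else ""))
    }
  }
  invisible(x)
}
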