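#' Build a full run configuration
#'
#' One nested config drives the whole pipeline. Every randomized stage —
#' cohort synthesis, the three-way split, embedding training, model
#' fitting, the bootstrap — carries its own explicit seed so each is
#' independently reproducible.
#'
#' @param synth a [synth_config()] (its seed is the cohort seed).
#' @param seeds named list with integer seeds `split`, `embedding`,
#'   `model`, `bootstrap`.
#' @param embedding list of [train_sgns()] hyperparameters (`dim`,
#'   `window`, `negative`, `subsample`, `min_count`, `epochs`, `alpha`,
#'   `min_alpha`).
#' @param bigrams list(`delta`, `threshold`) for phrase detection, or
#'   `NULL` to skip bigrams.
#' @param aggregator text aggregation rule.
#' @param model list of [train_lr()] hyperparameters (`max_epochs`,
#'   `batch_size`, `patience`, `lr`, `l2`).
#' @param kinds model kinds to run.
#' @param n_boot bootstrap replicates.
#' @param min_sens sensitivity floor for the specificity metric.
#' @param out_dir optional directory for persisted artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       seeds = list(split = 2L, embedding = 3L, model = 4L,
                                    bootstrap = 5L),
                       embedding = list(dim = 300L, window = 5L,
                                        negative = 5L, subsample = 1e-5,
                                        min_count = 3L, epochs = 5L,
                                        alpha = 0.025, min_alpha = 1e-4),
                       bigrams = list(delta = 5, threshold = 10),
                       aggregator = "mean",
                       model = list(max_epochs = 300L, batch_size = 64L,
                                    patience = 30L, lr = 1e-2, l2 = 0),
                       kinds = c("Tab", "Txt", "TabTxt"),
                       n_boot = 1000L,
                       min_sens = 0.95,
                       out_dir = NULL) {
  stopifnot(all(c("split", "embedding", "model", "bootstrap") %in% names(seeds)))
  cfg <- list(synth = synth, seeds = seeds, embedding = embedding,
              bigrams = bigrams, aggregator = aggregator, model = model,
              kinds = kinds, n_boot = n_boot, min_sens = min_sens,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  x$synth$date_range <- format(x$synth$date_range)
  x$synth$age_mixture <- list(
    control = unname(x$synth$age_mixture["control", ]),
    case = unname(x$synth$age_mixture["case", ]))
  x$synth$consults_per_patient_mean <- as.list(x$synth$consults_per_patient_mean)
  x$synth$consults_per_patient_sd <- as.list(x$synth$consults_per_patient_sd)
  x$synth$gender_female <- as.list(x$synth$gender_female)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Inverse of [write_run_config()]: the read-back configuration is
#' identical to the one written.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sy <- x$synth
  sy$date_range <- as.Date(sy$date_range)
  sy$age_mixture <- rbind(control = unlist(sy$age_mixture$control),
                          case = unlist(sy$age_mixture$case))
  colnames(sy$age_mixture) <- c("30_60", "60_70", "70_80", "80_plus")
  for (f in c("consults_per_patient_mean", "consults_per_patient_sd",
              "gender_female"))
    sy[[f]] <- unlist(sy[[f]])
  synth <- do.call(synth_config, sy)
  run_config(synth = synth, seeds = x$seeds, embedding = x$embedding,
             bigrams = x$bigrams, aggregator = x$aggregator,
             model = x$model, kinds = x$kinds, n_boot = x$n_boot,
             min_sens = x$min_sens, out_dir = x$out_dir)
}

config_hash <- function(cfg) {
  content_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE))
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Synthesize (or read) a cohort, label and window it, split, train
#' embeddings on the training corpus, build features, fit the requested
#' risk models and evaluate them with the paired bootstrap. Stages log to
#' stderr with timers; artifacts are persisted under `config$out_dir` when
#' set.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built `emr_cohort` (otherwise generated from
#'   `config$synth`).
#' @return a `pipeline_report`: list(report = `eval_report`, scores,
#'   labels, models, embedding summary, provenance).
#' @export
run_all <- function(config, cohort = NULL) {
  t0 <- as.numeric(Sys.time())
  stage <- function(s) stage_msg(s, t0)

  if (is.null(cohort)) cohort <- generate_cohort(config$synth)
  stage(sprintf("cohort: %d patients", nrow(cohort$patients)))

  windows <- build_windows(cohort)
  stage(sprintf("windows: %d included, %d cases",
                sum(windows$patients$included),
                sum(windows$patients$label[windows$patients$included])))

  split <- split_data(windows, config$seeds$split)
  stage("split: 60/20/20 stratified")

  corpus <- build_training_corpus(windows, split)
  phrases <- NULL
  if (!is.null(config$bigrams)) {
    corpus <- detect_bigrams(corpus, config$bigrams$delta,
                             config$bigrams$threshold)
    phrases <- attr(corpus, "phrases")
    stage(sprintf("bigrams: %d phrases merged", length(phrases$keys)))
  }
  emb_args <- config$embedding
  embedding <- train_sgns(corpus,
                          dim = emb_args$dim, window = emb_args$window,
                          negative = emb_args$negative,
                          subsample = emb_args$subsample,
                          min_count = emb_args$min_count,
                          epochs = emb_args$epochs, alpha = emb_args$alpha,
                          min_alpha = emb_args$min_alpha,
                          seed = config$seeds$embedding)
  stage(sprintf("embeddings: %d x %d, final loss %.4f",
                nrow(embedding$W), embedding$dim,
                embedding$epoch_loss[length(embedding$epoch_loss)]))

  features <- build_features(windows, split, embedding, phrases,
                             config$aggregator)
  stage("features: tabular + text blocks")

  te <- features$part == "test"
  labels_test <- features$label[te]
  models <- list()
  scores <- list()
  for (i in seq_along(config$kinds)) {
    kind <- config$kinds[i]
    m <- fit_risk_model(kind, features,
                        seed = config$seeds$model + i - 1L,
                        max_epochs = config$model$max_epochs,
                        batch_size = config$model$batch_size,
                        patience = config$model$patience,
                        lr = config$model$lr, l2 = config$model$l2)
    models[[kind]] <- m
    scores[[kind]] <- predict(m, assemble_inputs(kind, features,
                                                 features$ids[te]))
    stage(sprintf("model %s: best epoch %d, val BCE %.5f", kind,
                  m$best_epoch, m$val_loss))
  }

  report <- bootstrap_evaluate(scores, labels_test,
                               n_boot = config$n_boot,
                               seed = config$seeds$bootstrap,
                               min_sens = config$min_sens)
  stage("bootstrap evaluation done")

  out <- list(
    report = report,
    scores = scores,
    labels = labels_test,
    test_ids = features$ids[te],
    models = models,
    embedding = list(vocab_size = nrow(embedding$W), dim = embedding$dim,
                     epoch_loss = embedding$epoch_loss,
                     n_phrases = if (is.null(phrases)) 0L
                     else length(phrases$keys)),
    provenance = list(
      config_hash = config_hash(config),
      seeds = c(list(cohort = config$synth$seed), config$seeds),
      n_patients = nrow(cohort$patients),
      n_included = sum(windows$patients$included),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  class(out) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(split, file.path(config$out_dir, "split.csv"))
    write_features(features, file.path(config$out_dir, "features.csv"))
    for (kind in names(models))
      write_risk_model(models[[kind]],
                       file.path(config$out_dir,
                                 sprintf("model_%s.json", kind)))
    sc <- data.frame(patient_id = out$test_ids, label = labels_test,
                     do.call(cbind, scores))
    data.table::fwrite(sc, file.path(config$out_dir, "scores.csv"))
    write_report_json(out, file.path(config$out_dir, "report.json"))
    stage(sprintf("artifacts written to %s", config$out_dir))
  }
  out
}

#' Serialize a pipeline report as JSON
#'
#' @param x a `pipeline_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  r <- x$report
  jsonlite::write_json(list(
    metrics = r$metrics,
    comparisons = r$comparisons,
    n = r$n, n_boot = r$n_boot, seed = r$seed,
    embedding = x$embedding[c("vocab_size", "dim", "n_phrases")],
    provenance = x$provenance
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> config %s, %d test patients\n",
              x$provenance$config_hash, length(x$labels)))
  print(x$report)
  invisible(x)
}
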