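#' Embed one patient by aggregating word vectors
#'
#' Pools the tokens of all cleaned notes in a patient's window into one
#' sequence, drops out-of-vocabulary tokens and reduces the remaining
#' tokens' target vectors elementwise. Patients with zero in-vocabulary
#' tokens get a zero vector.
#'
#' @param tokens character vector: all (bigram-merged) window tokens.
#' @param embedding an `embedding_matrix`.
#' @param aggregator one of "mean", "sum", "max", "min".
#' @return numeric vector of length `embedding$dim`, with attribute
#'   `n_tokens_in_vocab`.
#' @export
embed_patient <- function(tokens, embedding,
                          aggregator = c("mean", "sum", "max", "min")) {
  aggregator <- match.arg(aggregator)
  idx <- match(tokens, rownames(embedding$W))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    v <- numeric(embedding$dim)
    attr(v, "n_tokens_in_vocab") <- 0L
    return(v)
  }
  m <- embedding$W[idx, , drop = FALSE]
  v <- switch(aggregator,
              mean = colMeans(m),
              sum = colSums(m),
              max = apply(m, 2L, max),
              min = apply(m, 2L, min))
  v <- as.numeric(v)
  attr(v, "n_tokens_in_vocab") <- length(idx)
  v
}

# All window tokens per patient, cleaned and bigram-merged, pooled in
# consultation order.
patient_tokens <- function(windows, phrases = NULL, ids = NULL) {
  cons <- windows$consultations
  if (!is.null(ids)) cons <- cons[cons$patient_id %in% ids]
  cons <- cons[nzchar(cons$note_clean)]
  toks <- tokenize_note(cons$note_clean)
  if (!is.null(phrases)) toks <- apply_bigrams(toks, phrases)
  dt <- data.table::data.table(
    patient_id = rep(cons$patient_id, lengths(toks)),
    token = unlist(toks, use.names = FALSE))
  split(dt$token, dt$patient_id)
}

#' Text vectors for many patients
#'
#' @param windows a `labelled_windows` object.
#' @param embedding an `embedding_matrix`.
#' @param phrases optional bigram model from [detect_bigrams()]; applied to
#'   each patient's token sequence so phrase tokens match the vocabulary.
#' @param ids patients to embed (default: all included patients).
#' @param aggregator see [embed_patient()].
#' @return numeric matrix (patients x dim) with rownames = patient ids;
#'   attribute `n_tokens_in_vocab` holds the per-patient token counts.
#' @export
patient_text_matrix <- function(windows, embedding, phrases = NULL,
                                ids = NULL,
                                aggregator = c("mean", "sum", "max", "min")) {
  aggregator <- match.arg(aggregator)
  if (is.null(ids))
    ids <- windows$patients$patient_id[windows$patients$included]
  tok <- patient_tokens(windows, phrases, ids)
  out <- matrix(0, nrow = length(ids), ncol = embedding$dim,
                dimnames = list(ids, NULL))
  n_vocab <- integer(length(ids))
  names(n_vocab) <- ids

  vocab_tokens <- rownames(embedding$W)
  if (aggregator %in% c("mean", "sum")) {
    # grouped rowsum is much faster than per-patient loops
    pid <- rep(names(tok), lengths(tok))
    tv <- unlist(tok, use.names = FALSE)
    idx <- match(tv, vocab_tokens)
    ok <- !is.na(idx)
    pid <- pid[ok]; idx <- idx[ok]
    if (length(idx) > 0) {
      sums <- rowsum(embedding$W[idx, , drop = FALSE], group = pid)
      cnt <- table(pid)
      n_vocab[names(cnt)] <- as.integer(cnt)
      if (aggregator == "mean") sums <- sums / as.numeric(cnt[rownames(sums)])
      out[rownames(sums), ] <- sums
    }
  } else {
    for (id in names(tok)) {
      v <- embed_patient(tok[[id]], embedding, aggregator)
      out[id, ] <- v
      n_vocab[id] <- attr(v, "n_tokens_in_vocab")
    }
  }
  attr(out, "n_tokens_in_vocab") <- n_vocab
  out
}

#' Raw tabular features for many patients
#'
#' Per included patient: age at anchor, gender one-hot (female, male,
#' other) and the occurrence counts of the 11 tracked ICPC codes over the
#' window consultations (prefix match on the first three characters;
#' duplicate codes count multiply).
#'
#' @param windows a `labelled_windows` object.
#' @param ids patients to featurize (default: all included).
#' @return numeric matrix (patients x 15) with named columns.
#' @export
raw_tabular_features <- function(windows, ids = NULL) {
  p <- windows$patients
  if (is.null(ids)) ids <- p$patient_id[p$included]
  p <- p[match(ids, p$patient_id)]
  codes <- icpc_feature_codes()
  out <- matrix(0, nrow = length(ids), ncol = 15L,
                dimnames = list(ids, c("age", "gender_female", "gender_male",
                                       "gender_other", codes)))
  out[, "age"] <- p$age_at_anchor
  g <- factor(p$gender, levels = c("female", "male", "other"))
  out[cbind(seq_along(ids), 1L + as.integer(g))] <- 1

  cons <- windows$consultations
  cons <- cons[cons$patient_id %in% ids & nzchar(cons$icpc)]
  if (nrow(cons) > 0) {
    cl <- strsplit(cons$icpc, " ", fixed = TRUE)
    dt <- data.table::data.table(
      patient_id = rep(cons$patient_id, lengths(cl)),
      code = substr(unlist(cl, use.names = FALSE), 1L, 3L))
    dt <- dt[code %in% codes, list(n = .N), by = c("patient_id", "code")]
    if (nrow(dt) > 0)
      out[cbind(match(dt$patient_id, ids), 4L + match(dt$code, codes))] <- dt$n
  }
  out
}

#' Normalisation statistics from the training split
#'
#' Mean and standard deviation of age and the 11 code counts, computed on
#' training-split patients only (a leakage guard: validation and test rows
#' never inform the scaling).
#'
#' @param windows a `labelled_windows` object.
#' @param split assignment from [split_data()].
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return a `tab_stats` list used by [patient_tab_matrix()].
#' @export
tabular_stats <- function(windows, split, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  train_ids <- split$patient_id[split$part == "train"]
  raw <- raw_tabular_features(windows, train_ids)
  scaled_cols <- c("age", icpc_feature_codes())
  out <- list(
    method = method,
    center = apply(raw[, scaled_cols, drop = FALSE], 2L,
                   if (method == "zscore") mean else min),
    scale = apply(raw[, scaled_cols, drop = FALSE], 2L,
                  if (method == "zscore") stats::sd
                  else function(x) diff(range(x)))
  )
  class(out) <- "tab_stats"
  out
}

#' Normalised tabular feature matrix
#'
#' Age and the 11 ICPC counts are scaled with training-split statistics;
#' the gender one-hot block is untouched. A feature with zero spread in the
#' training split is mapped to 0 (with a warning) rather than dividing by
#' zero.
#'
#' @param windows a `labelled_windows` object.
#' @param stats a [tabular_stats()] result.
#' @param ids patients to featurize (default: all included).
#' @return numeric matrix (patients x 15).
#' @export
patient_tab_matrix <- function(windows, stats, ids = NULL) {
  raw <- raw_tabular_features(windows, ids)
  cols <- names(stats$center)
  zero <- stats$scale == 0 | !is.finite(stats$scale)
  if (any(zero)) {
    warning("feature(s) with zero training-split spread mapped to 0: ",
            paste(cols[zero], collapse = ", "), call. = FALSE)
  }
  for (j in seq_along(cols)) {
    raw[, cols[j]] <- if (zero[j]) 0
    else (raw[, cols[j]] - stats$center[j]) / stats$scale[j]
  }
  raw
}

#' Tabular feature vector for a single patient window
#'
#' @param windows a `labelled_windows` object.
#' @param patient_id one id.
#' @param stats a [tabular_stats()] result.
#' @return numeric length-15 vector.
#' @export
tabular_features <- function(windows, patient_id, stats) {
  drop(patient_tab_matrix(windows, stats, ids = patient_id))
}

#' Assemble the full feature set for modelling
#'
#' @param windows a `labelled_windows` object.
#' @param split assignment from [split_data()].
#' @param embedding an `embedding_matrix`.
#' @param phrases optional bigram model.
#' @param aggregator text aggregation rule (see [embed_patient()]).
#' @param standardize_text centre and scale each text dimension with
#'   training-split statistics (default `TRUE`). This is numerical
#'   preconditioning only: logistic regression on an affinely transformed
#'   input spans the same model class, but gradient optimisation converges
#'   far faster once the large component shared by all word vectors is
#'   removed.
#' @return a `patient_features` object: list with `ids`, `label`, matrices
#'   `tab` (n x 15) and `txt` (n x dim), `split` part per patient and the
#'   normalisation `stats`.
#' @export
build_features <- function(windows, split, embedding, phrases = NULL,
                           aggregator = "mean", standardize_text = TRUE) {
  ids <- split$patient_id
  stats <- tabular_stats(windows, split)
  tab <- patient_tab_matrix(windows, stats, ids)
  txt <- patient_text_matrix(windows, embedding, phrases, ids, aggregator)
  if (standardize_text) {
    tr <- ids %in% split$patient_id[split$part == "train"]
    mu <- colMeans(txt[tr, , drop = FALSE])
    sg <- apply(txt[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    txt <- sweep(sweep(txt, 2L, mu), 2L, sg, "/")
    attr(txt, "center") <- mu
    attr(txt, "scale") <- sg
  }
  p <- windows$patients
  out <- list(ids = ids,
              label = p$label[match(ids, p$patient_id)],
              tab = tab, txt = txt,
              part = split$part[match(ids, split$patient_id)],
              stats = stats, aggregator = aggregator)
  class(out) <- "patient_features"
  out
}

#' Persist a feature set as CSV
#'
#' Columns: patient_id, label, part, tab_1..tab_15, txt_1..txt_d.
#'
#' @param features a `patient_features` object.
#' @param path output csv.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  tab <- features$tab
  colnames(tab) <- paste0("tab_", seq_len(ncol(tab)))
  txt <- features$txt
  colnames(txt) <- paste0("txt_", seq_len(ncol(txt)))
  df <- data.frame(patient_id = features$ids, label = features$label,
                   part = features$part, tab, txt,
                   check.names = FALSE, row.names = NULL)
  data.table::fwrite(df, path)
  invisible(path)
}
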