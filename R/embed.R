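#' Build a min-count-filtered vocabulary
#'
#' Counts tokens over the corpus and drops types seen fewer than
#' `min_count` times. Counts and the total token count `N` are taken
#' before filtering, so corpus frequencies `f(w) = count(w) / N` refer to
#' the raw corpus. The low default keeps rare misspelling variants.
#'
#' @param corpus list of character vectors (tokenized cleaned notes).
#' @param min_count minimum raw count for a token to be retained.
#' @return an `sgns_vocab`: list(token, count, N, min_count); `token` and
#'   `count` are aligned, tokens in decreasing count order.
#' @export
build_vocabulary <- function(corpus, min_count = 3L) {
  toks <- unlist(corpus, use.names = FALSE)
  if (length(toks) == 0) stop("empty corpus", call. = FALSE)
  tab <- sort(table(toks), decreasing = TRUE)
  n_total <- sum(tab)
  tab <- tab[tab >= min_count]
  out <- list(token = names(tab), count = as.numeric(tab),
              N = as.numeric(n_total), min_count = as.integer(min_count))
  class(out) <- "sgns_vocab"
  out
}

#' @export
print.sgns_vocab <- function(x, ...) {
  cat(sprintf("<sgns_vocab> %d types (min_count %d) over %s tokens\n",
              length(x$token), x$min_count, format(x$N, big.mark = ",")))
  invisible(x)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

# Greedy, boundary-aware, non-overlapping selection of mergeable adjacent
# positions: within each run of consecutive mergeable positions, every
# other one (starting with the first) is merged — a single left-to-right
# pass in vectorized form.
merge_pass <- function(corpus, merge_keys) {
  lens <- lengths(corpus)
  toks <- unlist(corpus, use.names = FALSE)
  note_id <- rep(seq_along(corpus), lens)
  total <- length(toks)
  if (total < 2 || length(merge_keys) == 0) return(corpus)
  m <- logical(total)
  idx <- seq_len(total - 1L)
  same <- note_id[idx] == note_id[idx + 1L]
  keys <- pair_key(toks[idx], toks[idx + 1L])
  m[idx] <- same & (keys %in% merge_keys)
  hit <- which(m)
  if (length(hit) == 0) return(corpus)
  run_id <- cumsum(c(1L, diff(hit) > 1L))
  offset <- stats::ave(hit, run_id, FUN = seq_along) - 1L
  sel <- hit[offset %% 2L == 0L]
  toks[sel] <- paste(toks[sel], toks[sel + 1L], sep = "_")
  keep <- rep(TRUE, total)
  keep[sel + 1L] <- FALSE
  out <- split(toks[keep], note_id[keep])
  # restore notes that became empty or were empty to begin with
  res <- rep(list(character(0)), length(corpus))
  res[as.integer(names(out))] <- out
  res
}

#' Detect and merge frequent bigrams
#'
#' One pass of collocation scoring: an adjacent pair (a, b) is merged into
#' the single token `a_b` wherever
#' `score(a, b) = (count(ab) - delta) * N / (count(a) * count(b))`
#' exceeds `threshold`. The discount `delta` suppresses rare
#' co-occurrences.
#'
#' @param corpus list of token vectors.
#' @param delta discount count (default 5).
#' @param threshold score cutoff (default 10).
#' @return the merged corpus, with attribute `phrases`: a list holding the
#'   merged pair keys and the parameters, reusable via [apply_bigrams()]
#'   on unseen token sequences.
#' @export
detect_bigrams <- function(corpus, delta = 5, threshold = 10) {
  lens <- lengths(corpus)
  toks <- unlist(corpus, use.names = FALSE)
  if (length(toks) < 2) {
    attr(corpus, "phrases") <- list(keys = character(0), delta = delta,
                                    threshold = threshold)
    return(corpus)
  }
  note_id <- rep(seq_along(corpus), lens)
  n_total <- length(toks)
  uni <- table(toks)
  idx <- seq_len(n_total - 1L)
  same <- note_id[idx] == note_id[idx + 1L]
  a <- toks[idx][same]
  b <- toks[idx + 1L][same]
  pairs <- table(pair_key(a, b))
  ab <- as.numeric(pairs)
  parts <- strsplit(names(pairs), "\r", fixed = TRUE)
  ca <- as.numeric(uni[vapply(parts, `[[`, character(1), 1L)])
  cb <- as.numeric(uni[vapply(parts, `[[`, character(1), 2L)])
  score <- (ab - delta) * n_total / (ca * cb)
  keys <- names(pairs)[score > threshold]
  out <- merge_pass(corpus, keys)
  attr(out, "phrases") <- list(keys = keys, delta = delta,
                               threshold = threshold)
  out
}

#' Apply a learned bigram merge to new token sequences
#'
#' @param corpus list of token vectors.
#' @param phrases the `phrases` attribute of a [detect_bigrams()] result.
#' @return merged corpus.
#' @export
apply_bigrams <- function(corpus, phrases) {
  merge_pass(corpus, phrases$keys)
}

#' Subsampling keep probability for a frequent token
#'
#' `min(1, sqrt(t / f))`: tokens with corpus frequency `f <= t` are always
#' kept; more frequent tokens are discarded with probability
#' `1 - sqrt(t / f)`, which preserves the frequency ranking.
#'
#' @param f corpus frequency of the token, in (0, 1].
#' @param t subsampling threshold (> 0).
#' @return keep probability in (0, 1].
#' @export
keep_probability <- function(f, t) {
  if (any(f <= 0)) stop("`f` must be positive", call. = FALSE)
  if (t <= 0) stop("`t` must be positive", call. = FALSE)
  pmin(1, sqrt(t / f))
}

#' Assemble the embedding training corpus
#'
#' The corpus is the union of (a) the cleaned window notes of
#' training-split patients and (b) the cleaned window notes of under-30
#' patients, who are excluded from prediction. Validation- and test-split
#' notes never enter embedding training.
#'
#' @param windows a `labelled_windows` object.
#' @param split a split assignment from [split_data()].
#' @return list of token vectors (empty notes dropped), with attribute
#'   `sources` giving the contributing patient count.
#' @export
build_training_corpus <- function(windows, split) {
  train_ids <- split$patient_id[split$part == "train"]
  under30_ids <- windows$patients$patient_id[windows$patients$age_at_anchor <= 30]
  ids <- union(train_ids, under30_ids)
  cons <- windows$consultations
  cons <- cons[cons$patient_id %in% ids & nzchar(cons$note_clean)]
  corpus <- tokenize_note(cons$note_clean)
  attr(corpus, "sources") <- list(n_train = length(train_ids),
                                  n_under30 = length(under30_ids))
  corpus
}

#' Train skip-gram negative-sampling word embeddings
#'
#' A from-scratch Word2Vec skip-gram trainer. For each retained (after
#' frequency subsampling) center token `w` and each context token `c`
#' within a dynamic window (radius uniform on 1..`window`), one stochastic
#' gradient step is taken on
#' `L = -log sigma(W_w . C_c) - sum_i log sigma(-W_w . C_ni)`
#' with `negative` negatives drawn from the unigram^(3/4) distribution.
#' Subsampling removes tokens before windowing, shrinking effective
#' distances. Training is deterministic given `seed`.
#'
#' @param corpus list of token vectors (already bigram-merged if desired).
#' @param vocab optional [build_vocabulary()] result; built from the corpus
#'   with `min_count` otherwise.
#' @param dim embedding dimension (default 300).
#' @param window maximum context window radius (default 5).
#' @param negative number of negative samples per positive pair (default 5).
#' @param subsample frequency threshold t for subsampling (default 1e-5).
#' @param min_count vocabulary cutoff when `vocab` is NULL (default 3).
#' @param epochs training epochs (default 5).
#' @param alpha,min_alpha initial and floor learning rate (linear decay).
#' @param seed integer seed.
#' @return an `embedding_matrix`: list with target matrix `W` (V x dim,
#'   rownames = tokens), context matrix `C`, `vocab`, `dim`, training
#'   `params` and per-epoch mean loss `epoch_loss`.
#' @export
train_sgns <- function(corpus, vocab = NULL, dim = 300L, window = 5L,
                       negative = 5L, subsample = 1e-5, min_count = 3L,
                       epochs = 5L, alpha = 0.025, min_alpha = 1e-4,
                       seed = 1L) {
  if (is.null(vocab)) vocab <- build_vocabulary(corpus, min_count)
  if (length(vocab$token) < 2L)
    stop("vocabulary must contain at least 2 tokens", call. = FALSE)
  enc <- lapply(corpus, function(tk) {
    i <- match(tk, vocab$token)
    as.integer(i[!is.na(i)] - 1L)
  })
  enc <- enc[lengths(enc) >= 2L]
  if (length(enc) == 0) stop("no sentence with >= 2 in-vocabulary tokens",
                             call. = FALSE)
  fit <- sgns_train_cpp(enc, vocab$count, vocab$N, as.integer(dim),
                        as.integer(window), as.integer(negative), subsample,
                        as.integer(epochs), alpha, min_alpha,
                        as.integer(seed))
  rownames(fit$W) <- vocab$token
  rownames(fit$C) <- vocab$token
  out <- list(W = fit$W, C = fit$C, vocab = vocab, dim = as.integer(dim),
              params = list(dim = as.integer(dim), window = as.integer(window),
                            negative = as.integer(negative),
                            subsample = subsample,
                            min_count = vocab$min_count,
                            epochs = as.integer(epochs), alpha = alpha,
                            min_alpha = min_alpha, seed = as.integer(seed)),
              epoch_loss = fit$epoch_loss)
  class(out) <- "embedding_matrix"
  out
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d x %d", nrow(x$W), x$dim))
  if (!is.null(x$epoch_loss))
    cat(sprintf("; final-epoch SGNS loss %.4f",
                x$epoch_loss[length(x$epoch_loss)]))
  cat("\n")
  invisible(x)
}

#' Skip-gram negative-sampling loss for one training pair
#'
#' The objective one gradient step minimises:
#' `-log sigma(w . c) - sum_i log sigma(-w . n_i)`.
#'
#' @param w target vector.
#' @param c_pos context vector.
#' @param c_neg matrix of negative context vectors (rows).
#' @return scalar loss.
#' @export
sgns_pair_loss <- function(w, c_pos, c_neg) {
  z <- sum(w * c_pos)
  l <- -log(stats::plogis(z))
  if (NROW(c_neg) > 0) {
    zn <- as.numeric(c_neg %*% w)
    l <- l - sum(log(stats::plogis(-zn)))
  }
  l
}

#' Analytic gradient of [sgns_pair_loss()] with respect to the target vector
#'
#' `dL/dw = (sigma(w . c) - 1) c + sum_i sigma(w . n_i) n_i`.
#'
#' @inheritParams sgns_pair_loss
#' @return gradient vector of `length(w)`.
#' @export
sgns_pair_grad <- function(w, c_pos, c_neg) {
  g <- (stats::plogis(sum(w * c_pos)) - 1) * c_pos
  if (NROW(c_neg) > 0) {
    zn <- as.numeric(c_neg %*% w)
    g <- g + as.numeric(t(c_neg) %*% stats::plogis(zn))
  }
  g
}

#' Cosine similarity between embedding rows
#'
#' @param embedding an `embedding_matrix`.
#' @param a,b token names or indices.
#' @return cosine of the angle between the two target vectors.
#' @export
embedding_cosine <- function(embedding, a, b) {
  va <- embedding$W[a, ]
  vb <- embedding$W[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}
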