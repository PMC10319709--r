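test_that("vocabulary counts and min-count filtering follow the corpus", {
  voc <- build_vocabulary(list(c("a", "a", "a"), c("b", "b")), min_count = 3)
  expect_equal(voc$token, "a")
  expect_equal(voc$N, 5)          # N counted before dropping
  expect_equal(voc$count, 3)
  # count exactly at the cutoff is retained (keeps rare misspellings)
  voc2 <- build_vocabulary(list(rep("x", 3), rep("y", 2)), min_count = 3)
  expect_true("x" %in% voc2$token)
  expect_false("y" %in% voc2$token)
  # min_count 1 retains everything
  voc3 <- build_vocabulary(list(c("p", "q"), "r"), min_count = 1)
  expect_setequal(voc3$token, c("p", "q", "r"))
  expect_error(build_vocabulary(list()), "empty")
})

test_that("bigram scoring matches hand arithmetic on a toy corpus", {
  # corpus of 20 tokens; "colorectal cancer" adjacent 5 times
  corpus <- c(rep(list(c("colorectal", "cancer")), 5),
              rep(list(c("filler", "word")), 5))
  n_total <- 20
  score <- (5 - 2) * n_total / (5 * 5)  # delta 2 -> 2.4
  merged <- detect_bigrams(corpus, delta = 2, threshold = score - 1e-9)
  expect_true("colorectal_cancer" %in% unlist(merged))
  # threshold just above the score: no merge
  merged2 <- detect_bigrams(corpus, delta = 2, threshold = score + 1e-9)
  expect_false("colorectal_cancer" %in% unlist(merged2))
  # delta at least the max pair count kills every merge
  merged3 <- detect_bigrams(corpus, delta = 5, threshold = 0)
  expect_false(any(grepl("_", unlist(merged3))))
})

test_that("bigram merging is a greedy single left-to-right pass", {
  corpus <- rep(list(c("a", "b", "b", "c")), 30)
  out <- detect_bigrams(corpus, delta = 1, threshold = 0.1)
  phrases <- attr(out, "phrases")
  # overlapping merges cannot both fire inside one note
  expect_equal(out[[1]][1], "a_b")
  expect_false(any(vapply(out, function(x) "b_b" %in% x, logical(1))))
  # learned phrases apply identically to unseen sequences
  expect_equal(apply_bigrams(list(c("a", "b", "x")), phrases)[[1]],
               c("a_b", "x"))
})

test_that("subsampling keep probability follows min(1, sqrt(t/f))", {
  t0 <- 1e-4
  expect_equal(keep_probability(t0, t0), 1)
  expect_equal(keep_probability(4 * t0, t0), 0.5)
  expect_equal(keep_probability(t0 / 2, t0), 1)  # below threshold: always kept
  f <- seq(1e-5, 1, length.out = 200)
  expect_true(all(diff(keep_probability(f, t0)) <= 1e-12))  # non-increasing
  expect_error(keep_probability(0, t0), "positive")
  expect_error(keep_probability(0.1, 0), "positive")
})

test_that("analytic SGNS gradient matches central finite differences", {
  set.seed(5)
  d <- 12
  w <- rnorm(d, sd = 0.5)
  c_pos <- rnorm(d, sd = 0.5)
  c_neg <- matrix(rnorm(3 * d, sd = 0.5), nrow = 3)
  g <- sgns_pair_grad(w, c_pos, c_neg)
  h <- 1e-6
  g_num <- vapply(seq_len(d), function(i) {
    e <- rep(0, d); e[i] <- h
    (sgns_pair_loss(w + e, c_pos, c_neg) -
       sgns_pair_loss(w - e, c_pos, c_neg)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - g_num)) / max(abs(g)), 1e-5)
  # k = 1 case from first principles: dL/dw = (sigma(wc)-1)c + sigma(wn)n
  n1 <- c_neg[1, , drop = FALSE]
  g1 <- (plogis(sum(w * c_pos)) - 1) * c_pos + plogis(sum(w * n1)) * n1[1, ]
  expect_equal(sgns_pair_grad(w, c_pos, n1), g1, tolerance = 1e-12)
})

test_that("SGNS training loss decreases and is reproducible", {
  set.seed(42)
  vocab <- sprintf("t%02d", 1:30)
  corpus <- replicate(150, sample(vocab, 8, replace = TRUE), simplify = FALSE)
  e1 <- train_sgns(corpus, dim = 16, epochs = 5, subsample = 1e-2,
                   min_count = 1, seed = 9)
  e2 <- train_sgns(corpus, dim = 16, epochs = 5, subsample = 1e-2,
                   min_count = 1, seed = 9)
  expect_identical(e1$W, e2$W)
  expect_false(identical(
    e1$W, train_sgns(corpus, dim = 16, epochs = 5, subsample = 1e-2,
                     min_count = 1, seed = 10)$W))
  expect_lt(e1$epoch_loss[5], e1$epoch_loss[1])
  expect_true(all(is.finite(e1$W)) && all(is.finite(e1$C)))
  expect_error(train_sgns(list(c("a", "a", "a"))), "at least 2")
})

test_that("always-co-occurring tokens end up closer than disjoint ones", {
  # A and B always share a sentence; C lives in disjoint contexts
  set.seed(7)
  fill1 <- sprintf("f%02d", 1:10)
  fill2 <- sprintf("g%02d", 1:10)
  corpus <- c(
    replicate(120, c("A", "B", sample(fill1, 4, replace = TRUE)),
              simplify = FALSE),
    replicate(120, c("C", sample(fill2, 5, replace = TRUE)),
              simplify = FALSE))
  emb <- train_sgns(corpus, dim = 16, epochs = 10, subsample = 1,
                    min_count = 1, seed = 3)
  expect_gt(embedding_cosine(emb, "A", "B"), embedding_cosine(emb, "A", "C"))
})

test_that("two-block co-occurrence structure is recovered in cosine space", {
  set.seed(31)
  block1 <- sprintf("a%02d", 1:8)
  block2 <- sprintf("b%02d", 1:8)
  corpus <- c(
    replicate(250, sample(block1, 6, replace = TRUE), simplify = FALSE),
    replicate(250, sample(block2, 6, replace = TRUE), simplify = FALSE))
  emb <- train_sgns(corpus, dim = 16, epochs = 10, subsample = 1,
                    min_count = 1, seed = 5)
  nrm <- emb$W / sqrt(rowSums(emb$W^2))
  cs <- nrm %*% t(nrm)
  i1 <- match(block1, rownames(emb$W))
  i2 <- match(block2, rownames(emb$W))
  within <- mean(c(cs[i1, i1][upper.tri(cs[i1, i1])],
                   cs[i2, i2][upper.tri(cs[i2, i2])]))
  between <- mean(cs[i1, i2])
  expect_gt(within, between)
})

test_that("the embedding corpus never contains validation or test notes", {
  co <- tiny_cohort(seed = 23, n = 600, prevalence = 0.05)
  w <- build_windows(co)
  s <- split_data(w, seed = 6)
  # plant a unique token in a test patient's window note
  te_id <- s$patient_id[s$part == "test"][1]
  rows <- which(w$consultations$patient_id == te_id &
                  nzchar(w$consultations$note_clean))
  w$consultations$note_clean[rows[1]] <-
    paste(w$consultations$note_clean[rows[1]], "zzleaktokenzz")
  corpus <- build_training_corpus(w, s)
  expect_false("zzleaktokenzz" %in% unlist(corpus))
  # the same token planted in a training patient's window is present
  tr_id <- s$patient_id[s$part == "train"][1]
  rows <- which(w$consultations$patient_id == tr_id &
                  nzchar(w$consultations$note_clean))
  w$consultations$note_clean[rows[1]] <-
    paste(w$consultations$note_clean[rows[1]], "zztrainonlyzz")
  corpus <- build_training_corpus(w, s)
  expect_true("zztrainonlyzz" %in% unlist(corpus))
  # token counting identity
  expect_equal(length(unlist(corpus)),
               sum(lengths(tokenize_note(
                 w$consultations$note_clean[
                   w$consultations$patient_id %in%
                     union(s$patient_id[s$part == "train"],
                           w$patients$patient_id[w$patients$age_at_anchor <= 30]) &
                     nzchar(w$consultations$note_clean)]))))
})

test_that("under-30 patients contribute notes to the corpus", {
  co <- tiny_cohort(seed = 29, n = 800, prevalence = 0.05, under30_frac = 0.3)
  w <- build_windows(co)
  s <- split_data(w, seed = 6)
  with_u30 <- length(unlist(build_training_corpus(w, s)))
  # drop under-30 windows: corpus shrinks to training notes only
  keep <- w$patients$age_at_anchor > 30
  w2 <- w
  w2$patients <- w$patients[keep]
  w2$consultations <- w$consultations[
    w$consultations$patient_id %in% w$patients$patient_id[keep]]
  without_u30 <- length(unlist(build_training_corpus(w2, s)))
  expect_gt(with_u30, without_u30)
})

test_that("embedding persistence round-trips", {
  set.seed(2)
  corpus <- replicate(40, sample(letters[1:12], 6, replace = TRUE),
                      simplify = FALSE)
  emb <- fast_sgns(corpus)
  f <- tempfile(fileext = ".txt")
  write_embedding(emb, f)
  back <- read_embedding(f)
  expect_equal(rownames(back$W), rownames(emb$W))
  expect_equal(back$W, emb$W, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$params$dim, emb$params$dim)
})
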