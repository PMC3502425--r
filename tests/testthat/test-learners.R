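## small hand-built training set whose sentences cover all 13 labels
full_label_training <- function() {
  sents <- list(); labs <- list()
  for (fc in field_codes()) {
    sents[[length(sents) + 1L]] <-
      toy_sentence(c(paste0(fc, "head"), paste0(fc, "tail"), "filler"))
    labs[[length(labs) + 1L]] <- c(paste0("B-", fc), paste0("I-", fc), "O")
  }
  list(sentences = sents, labels = labs)
}

test_that("the SVM tagger realizes K(K-1)/2 pairwise classifiers", {
  tr <- full_label_training()
  fit <- svm_tagger(tr$sentences, tr$labels,
                    fcfg = feature_config(semantic = FALSE))
  expect_equal(length(fit$present), 13)
  expect_equal(fit$n_classifiers, 78)

  fit2 <- svm_tagger(list(toy_sentence(c("lasix", "stable"))),
                     list(c("B-m", "O")),
                     fcfg = feature_config(semantic = FALSE))
  expect_equal(fit2$n_classifiers, 1)
  expect_error(svm_tagger(list(), list()), "empty")
})

test_that("the SVM tagger labels separable held-out data and is deterministic", {
  set.seed(21)
  drugs <- c("lasix", "plavix", "zocor")
  fillers <- c("continue", "stable", "daily", "exam")
  mk <- function(n) {
    sents <- list(); labs <- list()
    for (i in seq_len(n)) {
      toks <- c(sample(fillers, 2), sample(drugs, 1), sample(fillers, 1))
      sents[[i]] <- toy_sentence(toks)
      labs[[i]] <- ifelse(toks %in% drugs, "B-m", "O")
    }
    list(s = sents, l = labs)
  }
  tr <- mk(40); te <- mk(10)
  fit <- svm_tagger(tr$s, tr$l, fcfg = feature_config(semantic = FALSE))
  pred <- predict(fit, te$s)
  expect_equal(pred, te$l)
  expect_identical(predict(fit, te$s), pred)
  ## contract: one in-alphabet label per token
  expect_true(all(lengths(pred) == vapply(te$s, nrow, 0L)))
  expect_true(all(unlist(pred) %in% bio_labels()))
})

test_that("SVM max-vote decisions equal explicit pairwise vote counting", {
  set.seed(22)
  words <- c("aa", "bb", "cc", "dd", "ee")
  sents <- list(); labs <- list()
  for (i in 1:30) {
    toks <- sample(words, 4, replace = TRUE)
    sents[[i]] <- toy_sentence(toks)
    labs[[i]] <- c(aa = "B-m", bb = "I-m", cc = "B-do", dd = "O",
                   ee = "O")[toks]
  }
  fcfg <- feature_config(semantic = FALSE, history = FALSE, window = 1)
  fit <- svm_tagger(sents, labs, fcfg = fcfg)
  te <- toy_sentence(sample(words, 6, replace = TRUE))
  got <- predict(fit, te)

  ## independent tally: fetch raw pairwise decision values and loop
  fstr <- medner:::svm_base_features(te, NULL, fit$fcfg)
  X <- medner:::feature_matrix(fstr, fit$vocab)
  dv <- attr(predict(fit$fit, X, decision.values = TRUE),
             "decision.values")
  for (row in seq_len(nrow(dv))) {
    tally <- stats::setNames(rep(0L, length(fit$labels)), fit$labels)
    for (cn in colnames(dv)) {
      pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
      winner <- if (dv[row, cn] > 0) pair[1] else pair[2]
      tally[winner] <- tally[winner] + 1L
    }
    best <- names(tally)[which.max(tally)]  # first max = canonical order
    expect_equal(got[row], best)
  }
})

test_that("CRF sequence probabilities normalize and match exhaustive enumeration", {
  set.seed(23)
  for (rep in 1:40) {
    nlab <- sample(2:5, 1)
    labels <- c(bio_labels()[seq_len(nlab - 1L)], "O")
    words <- paste0("w", 1:4)
    W <- matrix(rnorm(length(words) * nlab), length(words), nlab)
    Trans <- if (runif(1) < 0.7) matrix(rnorm(nlab * nlab), nlab) else NULL
    model <- build_toy_crf(words, labels, W, Trans)
    L <- sample(1:3, 1)
    toks <- sample(words, L, replace = TRUE)
    sent <- toy_sentence(toks)
    scores <- enum_scores(match(toks, words), W, Trans)
    probs <- exp(scores - max(scores))
    probs <- probs / sum(probs)
    seqs <- enum_sequences(nlab, L)
    total <- 0
    for (k in seq_len(nrow(seqs))) {
      p <- sequence_probability(model, sent, labels[seqs[k, ]])
      expect_equal(p, probs[k], tolerance = 1e-10)
      total <- total + p
    }
    expect_equal(total, 1, tolerance = 1e-8)
    ## Viterbi equals the enumeration argmax
    expect_equal(predict(model, sent), labels[seqs[which.max(scores), ]])
  }
})

test_that("an all-zero-weight CRF is uniform over label sequences", {
  labels <- c("B-m", "I-m", "O")
  model <- build_toy_crf(c("w1", "w2"), labels,
                         matrix(0, 2, 3), matrix(0, 3, 3))
  sent <- toy_sentence(c("w1", "w2", "w1"))
  expect_equal(sequence_probability(model, sent, c("B-m", "I-m", "O")),
               3^-3, tolerance = 1e-12)
  expect_error(sequence_probability(model, sent, c("O", "O")), "match")
})

test_that("the CRF recovers gold labels on a separable toy corpus", {
  set.seed(24)
  drugs <- c("lasix", "plavix")
  fillers <- c("continue", "stable", "exam")
  sents <- list(); labs <- list()
  for (i in 1:30) {
    toks <- c(sample(fillers, 2), sample(drugs, 1), sample(fillers, 1))
    sents[[i]] <- toy_sentence(toks)
    labs[[i]] <- ifelse(toks %in% drugs, "B-m", "O")
  }
  fit <- crf_tagger(sents, labs, fcfg = feature_config(semantic = FALSE),
                    maxit = 100)
  te <- toy_sentence(c("stable", "lasix", "exam"))
  expect_equal(predict(fit, te), c("O", "B-m", "O"))
  expect_true(all(unlist(predict(fit, sents)) %in% bio_labels()))
  expect_error(crf_tagger(list(), list()), "empty")
})
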