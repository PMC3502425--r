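table3_gold <- function() {
  mentions("doc", c("m", "do", "mo", "f"), 1, c(0, 1, 3, 4), 1, c(0, 2, 3, 6),
           c("Percocet", "1-2 Tablets", "p.o.", "Q 4 prn,"), 1:4)
}

test_that("chunk counts implement exact-match semantics", {
  g <- table3_gold()
  same <- chunk_counts(g, g)
  expect_equal(sum(same$tp), 4)
  expect_equal(sum(same$fp) + sum(same$fn), 0)

  miss <- chunk_counts(g, g[-2, ])
  expect_equal(sum(miss$tp), 3)
  expect_equal(sum(miss$fp), 0)
  expect_equal(sum(miss$fn), 1)
  expect_equal(miss$fn[miss$field == "do"], 1)

  ## boundary error: "Q 4" instead of "Q 4 prn," is both fp and fn for f
  pred <- g
  pred$end_offset[4] <- 5L
  pred$text[4] <- "Q 4"
  bnd <- chunk_counts(g, pred)
  expect_equal(bnd$fp[bnd$field == "f"], 1)
  expect_equal(bnd$fn[bnd$field == "f"], 1)
  expect_equal(bnd$tp[bnd$field == "f"], 0)

  expect_error(chunk_counts(g, rbind(g, g[1, ])), "duplicate")
})

test_that("scores compute percentages with the harmonic mean and safe zeros", {
  cnt <- chunk_counts(table3_gold(), table3_gold()[-2, ])
  sc <- ner_scores(cnt)
  expect_equal(sc$precision[sc$field == "ALL"], 100)
  expect_equal(sc$recall[sc$field == "ALL"], 75)
  expect_equal(sc$f[sc$field == "ALL"], 2 * 100 * 75 / 175,
               tolerance = 1e-12)
  empty <- ner_scores(chunk_counts(table3_gold()[0, ], table3_gold()[0, ]))
  expect_true(all(empty[, c("precision", "recall", "f")] == 0))
  expect_true(all(sc$precision >= 0 & sc$precision <= 100))
  ## micro identity: overall counts are the per-field sums
  expect_equal(sc$tp[1], sum(sc$tp[-1]))
  expect_equal(sc$fp[1], sum(sc$fp[-1]))
  expect_equal(sc$fn[1], sum(sc$fn[-1]))
})

test_that("mention scoring equals the conlleval-style column oracle", {
  set.seed(41)
  for (rep in 1:25) {
    nsent <- sample(3:6, 1)
    sents <- lapply(seq_len(nsent), function(s) {
      n <- sample(4:9, 1)
      sent <- data.frame(text = sample(RAND_VOCAB, n, replace = TRUE),
                         line = s, offset = seq_len(n) - 1L,
                         stringsAsFactors = FALSE)
      attr(sent, "doc_id") <- "d"
      sent
    })
    gold_lab <- lapply(sents, function(s) rand_bio(nrow(s)))
    pred_lab <- lapply(sents, function(s) rand_bio(nrow(s)))
    gold <- do.call(rbind, mapply(decode_bio, sents, gold_lab,
                                  SIMPLIFY = FALSE))
    pred <- do.call(rbind, mapply(decode_bio, sents, pred_lab,
                                  SIMPLIFY = FALSE))
    gold$event <- seq_len(nrow(gold)); pred$event <- seq_len(nrow(pred))
    sc <- ner_scores(chunk_counts(gold, pred))
    want <- oracle_prf(gold_lab, pred_lab)
    expect_equal(sc$precision[1], want[["precision"]], tolerance = 1e-10)
    expect_equal(sc$recall[1], want[["recall"]], tolerance = 1e-10)
    expect_equal(sc$f[1], want[["f"]], tolerance = 1e-10)
  }
})

test_that("folds partition documents into nearly equal seeded subsets", {
  ids <- sprintf("doc%03d", 1:268)
  folds <- make_folds(ids, k = 10, seed = 5)
  sizes <- vapply(folds, function(f) length(f$test), 0L)
  expect_equal(sort(unique(sizes)), c(26L, 27L))
  expect_equal(sum(sizes == 27L), 8)
  expect_equal(sum(sizes == 26L), 2)
  expect_setequal(unlist(lapply(folds, `[[`, "test")), ids)
  expect_equal(sum(sizes), 268)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(make_folds(ids, 10, seed = 5), folds)
  expect_false(identical(make_folds(ids, 10, seed = 6), folds))

  two <- make_folds(c("a", "b"), k = 2, seed = 1)
  expect_equal(sort(vapply(two, function(f) f$test, "")), c("a", "b"))
  expect_error(make_folds(c("a"), k = 2), "smaller")
  expect_error(make_folds(ids, k = 1), "k must be")
})

test_that("randomization test is symmetric, seeded, and null-safe", {
  set.seed(42)
  corp <- generate_corpus(synth_config(n_notes = 12, seed = 42))
  mk <- function(seed) {
    lab <- corrupt_labels(corp$labels,
                          corruption_config(deletion = 0.25, seed = seed))
    decode_all(corp$documents, lab)
  }
  a <- mk(1); b <- mk(2)

  ## identical outputs: f = 0 and p >= 0.5
  same <- approximate_randomization(a, a, corp$gold, n = 100, seed = 9)
  expect_equal(same$f_observed, 0)
  expect_gte(same$p_value, 0.5)

  r1 <- approximate_randomization(a, b, corp$gold, n = 200, seed = 9)
  expect_identical(r1,
                   approximate_randomization(a, b, corp$gold, n = 200,
                                             seed = 9))
  ## swapping the labeling flips the statistic; the reversed p of one
  ## ordering is the primary p of the other under the same draws
  r2 <- approximate_randomization(b, a, corp$gold, n = 200, seed = 9)
  expect_equal(r2$f_observed, -r1$f_observed)
  ## both estimate the same exchangeable quantity, from independent draws
  expect_lt(abs(r1$p_value_reversed - r2$p_value), 0.15)

  rs <- approximate_randomization(a, b, corp$gold, n = 200, seed = 9,
                                  variant = "swap")
  expect_true(rs$p_value >= 0 && rs$p_value <= 1)
  expect_error(approximate_randomization(a, b, corp$gold, n = 0), "n must")
})
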