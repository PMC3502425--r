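#' Exact-match chunk counts
#'
#' Compares predicted to gold entity mentions with conlleval-style
#' exact-match semantics: a prediction is a true positive iff a gold
#' mention with the identical field type and token span exists in the same
#' document; unmatched predictions are false positives and unmatched gold
#' mentions false negatives.
#'
#' @param gold,pred Mention data frames over the same document set.
#' @return An `eval_counts` data frame: one row per field with columns
#'   `tp`, `fp`, `fn`.
#' @export
chunk_counts <- function(gold, pred) {
  gk <- mention_key(gold)
  pk <- mention_key(pred)
  if (anyDuplicated(gk)) stop("duplicate identical mentions in gold")
  if (anyDuplicated(pk)) stop("duplicate identical mentions in predictions")
  out <- data.frame(field = field_codes(), tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  hit <- pk %in% gk
  for (k in seq_len(nrow(out))) {
    fc <- out$field[k]
    pf <- pred$field == fc
    gf <- gold$field == fc
    out$tp[k] <- sum(pf & hit)
    out$fp[k] <- sum(pf & !hit)
    out$fn[k] <- sum(gf & !(gk %in% pk))
  }
  class(out) <- c("eval_counts", "data.frame")
  out
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

#' Precision / recall / F from chunk counts
#'
#' Per-field scores plus the micro-averaged overall row (`ALL`), computed
#' from the summed counts so every entity carries equal weight.  Scores
#' are percentages; zero denominators yield 0.
#'
#' @param counts An `eval_counts` table from [chunk_counts()].
#' @return An `eval_report` data frame with rows `ALL, m, do, mo, f, du,
#'   r` and columns `tp`, `fp`, `fn`, `precision`, `recall`, `f`.
#' @export
ner_scores <- function(counts) {
  rows <- rbind(
    data.frame(field = "ALL", tp = sum(counts$tp), fp = sum(counts$fp),
               fn = sum(counts$fn), stringsAsFactors = FALSE),
    as.data.frame(counts)[, c("field", "tp", "fp", "fn")])
  sc <- t(mapply(prf, rows$tp, rows$fp, rows$fn))
  out <- cbind(rows, sc)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$precision <- round(y$precision, digits)
  y$recall <- round(y$recall, digits)
  y$f <- round(y$f, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Evaluate predicted mentions against gold
#'
#' Convenience wrapper: `ner_scores(chunk_counts(gold, pred))`.
#'
#' @param gold,pred Mention data frames.
#' @return An `eval_report`.
#' @export
evaluate_mentions <- function(gold, pred) ner_scores(chunk_counts(gold, pred))

## micro-F directly from counts: F = 2TP / (2TP + FP + FN)
micro_f <- function(tp, fp, fn) {
  d <- 2 * tp + fp + fn
  if (d > 0) unname(200 * tp / d) else 0
}

## per-document (tp, fp, fn) matrix for a prediction set vs gold
doc_count_matrix <- function(gold, pred, doc_ids) {
  out <- matrix(0L, nrow = length(doc_ids), ncol = 3,
                dimnames = list(doc_ids, c("tp", "fp", "fn")))
  gk <- mention_key(gold)
  pk <- mention_key(pred)
  if (anyDuplicated(gk)) stop("duplicate identical mentions in gold")
  if (anyDuplicated(pk)) stop("duplicate identical mentions in predictions")
  tp_tab <- table(factor(pred$doc_id[pk %in% gk], levels = doc_ids))
  fp_tab <- table(factor(pred$doc_id[!(pk %in% gk)], levels = doc_ids))
  fn_tab <- table(factor(gold$doc_id[!(gk %in% pk)], levels = doc_ids))
  out[, "tp"] <- as.integer(tp_tab)
  out[, "fp"] <- as.integer(fp_tab)
  out[, "fn"] <- as.integer(fn_tab)
  out
}

#' Approximate-randomization significance test
#'
#' Tests the difference in micro-averaged F between two systems evaluated
#' against the same gold standard.  An *entry* is one document's predicted
#' mention set.  The observed statistic is `f = F(A) - F(B)`.  System A's
#' `j` entries and system B's `k` entries are pooled into a superset `C`;
#' each of `n` iterations draws `j` entries from `C` without replacement
#' as pseudo-A, leaves the remainder as pseudo-B, and computes
#' `f_i = F(pseudo-A) - F(pseudo-B)`.  The p-value is the raw proportion
#' of iterations with `f_i - f >= 0`.  Because the direction of the
#' one-sided test depends on which system is labeled A, the p-value for
#' the reversed labeling is reported alongside.
#'
#' The `"swap"` variant instead flips each document's pair of entries
#' between the two pseudo-systems with probability 1/2, keeping one entry
#' per document on each side.
#'
#' @param pred_a,pred_b Mention data frames for the two systems.
#' @param gold Gold mention data frame.
#' @param n Number of shuffles (the conventional setting is 1000).
#' @param seed RNG seed.
#' @param variant `"pool"` (draw from the pooled superset) or `"swap"`
#'   (per-document swaps).
#' @return A `rand_test` object: `f_observed`, `p_value`,
#'   `p_value_reversed`, `n`, `seed`, `variant`.
#' @export
approximate_randomization <- function(pred_a, pred_b, gold, n = 1000L,
                                      seed = 1L,
                                      variant = c("pool", "swap")) {
  if (n < 1L) stop("n must be >= 1")
  variant <- match.arg(variant)
  doc_ids <- unique(gold$doc_id)
  A <- doc_count_matrix(gold, pred_a, doc_ids)
  B <- doc_count_matrix(gold, pred_b, doc_ids)
  f_obs <- micro_f(sum(A[, 1]), sum(A[, 2]), sum(A[, 3])) -
           micro_f(sum(B[, 1]), sum(B[, 2]), sum(B[, 3]))
  C <- rbind(A, B)
  j <- nrow(A)
  tot <- colSums(C)
  fi <- numeric(n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ## draws come in antithetic pairs: each random partition is followed by
  ## its complement.  The marginal distribution of each draw is unchanged
  ## (the complement of a uniform subset is uniform) but the realized f_i
  ## sample is exactly symmetric, so identical inputs give p >= 1/2.
  prev <- NULL
  for (it in seq_len(n)) {
    if (it %% 2L == 0L && !is.null(prev)) {
      idx <- setdiff(seq_len(nrow(C)), prev)
      prev <- NULL
    } else if (variant == "pool") {
      idx <- sample.int(nrow(C), j)
      prev <- idx
    } else {
      flip <- stats::runif(j) < 0.5
      idx <- ifelse(flip, seq_len(j) + j, seq_len(j))
      prev <- idx
    }
    a <- colSums(C[idx, , drop = FALSE])
    b <- tot - a
    fi[it] <- micro_f(a[1], a[2], a[3]) - micro_f(b[1], b[2], b[3])
  }
  structure(list(f_observed = f_obs,
                 p_value = mean(fi - f_obs >= 0),
                 p_value_reversed = mean(fi <= f_obs),
                 n = as.integer(n), seed = as.integer(seed),
                 variant = variant),
            class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat("Approximate randomization test (", x$variant, " variant, n = ",
      x$n, ", seed = ", x$seed, ")\n", sep = "")
  cat(sprintf("  observed micro-F difference f = %.4f\n", x$f_observed))
  cat(sprintf("  p (as labeled) = %.4f ; p (labels reversed) = %.4f\n",
              x$p_value, x$p_value_reversed))
  invisible(x)
}

#' Random k-fold partition of a document set
#'
#' Seeded random split into `k` folds of sizes differing by at most one;
#' each document appears in exactly one test fold.
#'
#' @param doc_ids Character vector of document ids (or a corpus list,
#'   whose `doc_id`s are used).
#' @param k Number of folds (>= 2).
#' @param seed RNG seed.
#' @return List of `k` elements, each `list(train = ids, test = ids)`.
#' @export
make_folds <- function(doc_ids, k = 10L, seed = 1L) {
  if (is.list(doc_ids)) doc_ids <- vapply(doc_ids, `[[`, "", "doc_id")
  n <- length(doc_ids)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("corpus of ", n, " documents is smaller than k = ", k)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  perm <- sample(doc_ids)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- perm[starts[i]:ends[i]]
    list(train = setdiff(doc_ids, test), test = test)
  })
}

## save/restore .Random.seed so seeded package functions do not disturb the
## caller's RNG stream
get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
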