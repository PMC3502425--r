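#' SVM tagger configuration
#'
#' One-vs-one multiclass SVM with a polynomial kernel
#' \eqn{(u \cdot v + 1)^d}.  Defaults: degree 2, cost 1.0, context window
#' \eqn{\pm 2} — the setting selected in the source experiments by a grid
#' over degrees 1–5 and costs 0.5–5.0.
#'
#' @param degree Polynomial kernel degree (\eqn{\ge 1}).
#' @param cost Soft-margin cost `C` (> 0).
#' @param window Context window half-width used for feature extraction.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(degree = 2L, cost = 1.0, window = 2L) {
  stopifnot(degree >= 1L, cost > 0)
  structure(list(degree = as.integer(degree), cost = cost,
                 window = as.integer(window), strategy = "one-vs-one"),
            class = "svm_config")
}

## sparse binary design matrix from per-token feature-string lists
## tok_feats: list (one per token) of character vectors; vocab: id map
feature_matrix <- function(tok_feats, vocab) {
  idx <- lapply(tok_feats, function(fs) {
    j <- match(fs, vocab)
    unique(j[!is.na(j)])
  })
  ni <- lengths(idx)
  Matrix::sparseMatrix(
    i = rep(seq_along(idx), ni),
    j = unlist(idx, use.names = FALSE),
    x = 1,
    dims = c(length(idx), length(vocab)))
}

## per-token SVM feature strings for one sentence; history appended
## separately so decoding can re-use the base features.
svm_base_features <- function(sentence, semantic_tags, fcfg) {
  cfg <- fcfg
  cfg$history <- FALSE
  lapply(sentence_features(sentence, semantic_tags, cfg), feature_strings)
}

hist_feature <- function(label) paste0("hist=", label)

#' Fit a one-vs-one SVM sequence tagger
#'
#' Trains a multiclass SVM over the 13 BIO labels on windowed token
#' features.  With `K` labels present in the training data the model
#' holds `K(K-1)/2` pairwise classifiers; prediction takes the label with
#' the most pairwise votes.  Training vectors use the gold previous label
#' as the history feature; decoding is greedy left-to-right on the
#' tagger's own previous predictions.
#'
#' The quadratic-programming backend is libsvm (via e1071), whose
#' multiclass strategy is natively one-against-one; vote counting and the
#' fixed-label-order tie-break are applied in-package from the pairwise
#' decision values.
#'
#' @param sentences List of sentence token data frames.
#' @param labels List of gold BIO label vectors aligned to `sentences`.
#' @param semantic_tags List of per-sentence semantic tag vectors, or
#'   `NULL`.
#' @param cfg An [svm_config()].
#' @param fcfg A [feature_config()]; its window is overridden by
#'   `cfg$window`.
#' @param labelset Label alphabet (default [bio_labels()]); also the
#'   tie-break order.
#' @return A fitted `svm_tagger` with a [predict][predict.svm_tagger]
#'   method; element `n_classifiers` holds the realized number of pairwise
#'   classifiers.
#' @export
svm_tagger <- function(sentences, labels, semantic_tags = NULL,
                       cfg = svm_config(), fcfg = feature_config(),
                       labelset = bio_labels()) {
  if (length(sentences) == 0L) stop("empty training set")
  stopifnot(length(labels) == length(sentences))
  fcfg$window <- cfg$window
  if (is.null(semantic_tags)) semantic_tags <- vector("list",
                                                      length(sentences))
  base <- mapply(svm_base_features, sentences, semantic_tags,
                 MoreArgs = list(fcfg = fcfg), SIMPLIFY = FALSE)
  tok_feats <- list()
  y <- character(0)
  for (s in seq_along(base)) {
    labs <- labels[[s]]
    for (i in seq_along(base[[s]])) {
      f <- base[[s]][[i]]
      if (isTRUE(fcfg$history)) {
        f <- c(f, hist_feature(if (i == 1L) "__BOS__" else labs[i - 1L]))
      }
      tok_feats[[length(tok_feats) + 1L]] <- f
    }
    y <- c(y, labs)
  }
  if (anyNA(match(y, labelset))) {
    stop("label outside the label set: ",
         paste(setdiff(y, labelset), collapse = ", "))
  }
  vocab <- unique(unlist(tok_feats, use.names = FALSE))
  present <- labelset[labelset %in% unique(y)]
  K <- length(present)
  fit <- NULL
  if (K > 1L) {
    X <- feature_matrix(tok_feats, vocab)
    fit <- e1071::svm(X, factor(y, levels = present), scale = FALSE,
                      kernel = "polynomial", degree = cfg$degree,
                      gamma = 1, coef0 = 1, cost = cfg$cost,
                      fitted = FALSE)
  }
  structure(list(fit = fit, vocab = vocab, labels = labelset,
                 present = present, n_classifiers = (K * (K - 1L)) %/% 2L,
                 cfg = cfg, fcfg = fcfg, n_tokens = length(y)),
            class = "svm_tagger")
}

#' @export
print.svm_tagger <- function(x, ...) {
  cat("<svm_tagger> one-vs-one, polynomial degree ", x$cfg$degree,
      ", cost ", x$cfg$cost, "\n  ", length(x$present), " labels -> ",
      x$n_classifiers, " pairwise classifiers; ",
      length(x$vocab), " features; ", x$n_tokens, " training tokens\n",
      sep = "")
  invisible(x)
}

## max-vote label per row of a pairwise decision-value matrix,
## ties broken by the fixed label order of `labelset`
vote_from_decisions <- function(dv, labelset) {
  votes <- matrix(0L, nrow = nrow(dv), ncol = length(labelset))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (k in seq_along(pairs)) {
    a <- match(pairs[[k]][1], labelset)
    b <- match(pairs[[k]][2], labelset)
    pos <- dv[, k] > 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
  }
  labelset[max.col(votes, ties.method = "first")]
}

#' Predict BIO labels with a fitted SVM tagger
#'
#' Greedy left-to-right decoding: at each position the history feature is
#' the label the tagger just predicted at the previous position; the label
#' is the pairwise-vote winner (ties broken by the fixed label order).
#' Sentences are decoded in lock-step so each within-sentence position is
#' a single batched classifier call.
#'
#' @param object A fitted [svm_tagger()].
#' @param sentences List of sentence token data frames (or a single one).
#' @param semantic_tags Matching semantic tag list, or `NULL`.
#' @param ... Unused.
#' @return List of label vectors (or a single vector for a single
#'   sentence).
#' @export
predict.svm_tagger <- function(object, sentences, semantic_tags = NULL, ...) {
  single <- is.data.frame(sentences)
  if (single) {
    sentences <- list(sentences)
    if (!is.null(semantic_tags) && !is.list(semantic_tags)) {
      semantic_tags <- list(semantic_tags)
    }
  }
  if (is.null(semantic_tags)) semantic_tags <- vector("list",
                                                      length(sentences))
  ns <- length(sentences)
  lens <- vapply(sentences, nrow, 0L)
  out <- lapply(lens, function(n) character(n))
  if (ns == 0L || max(lens) == 0L) return(if (single) out[[1]] else out)
  if (is.null(object$fit)) {  # degenerate single-class training set
    only <- object$present
    out <- lapply(lens, function(n) rep(only, n))
    return(if (single) out[[1]] else out)
  }
  base <- mapply(svm_base_features, sentences, semantic_tags,
                 MoreArgs = list(fcfg = object$fcfg), SIMPLIFY = FALSE)
  for (step in seq_len(max(lens))) {
    live <- which(lens >= step)
    feats <- lapply(live, function(s) {
      f <- base[[s]][[step]]
      if (isTRUE(object$fcfg$history)) {
        f <- c(f, hist_feature(if (step == 1L) "__BOS__"
                               else out[[s]][step - 1L]))
      }
      f
    })
    X <- feature_matrix(feats, object$vocab)
    p <- stats::predict(object$fit, X, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    lab <- vote_from_decisions(dv, object$labels)
    for (k in seq_along(live)) out[[live[k]]][step] <- lab[k]
  }
  if (single) out[[1]] else out
}
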