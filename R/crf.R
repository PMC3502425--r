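## Linear-chain CRF sequence labeler.
##
## The model assigns P(y|x) proportional to
##   exp( sum_t sum_k w_k f_k(y_{t-1}, y_t, t, x) )
## with indicator feature functions of two kinds: token features paired
## with the label at t (state features), and label-bigram transitions
## (y_{t-1}, y_t).  The normalizer is computed by the forward algorithm;
## decoding is Viterbi.  Training maximizes the L2-penalized conditional
## log-likelihood with L-BFGS.

## internal constructor; w_state nfeat x nlab, w_trans nlab x nlab or NULL
new_crf_model <- function(vocab, labelset, w_state,
                          w_trans = NULL, fcfg = feature_config()) {
  nfeat <- length(vocab); nlab <- length(labelset)
  stopifnot(length(w_state) == nfeat * nlab)
  use_trans <- !is.null(w_trans)
  w <- c(as.numeric(t(matrix(w_state, nrow = nfeat))), # -> f*nlab+y layout
         if (use_trans) as.numeric(t(w_trans)))
  ## NOTE: w_state supplied as [nfeat x nlab] matrix (row f, col y);
  ## internal layout is w[f*nlab + y], i.e. row-major.
  structure(list(w = w, vocab = vocab, labels = labelset,
                 use_trans = use_trans, fcfg = fcfg,
                 nfeat = nfeat, nlab = nlab),
            class = "crf_tagger")
}

## map one sentence's feature-string lists to 0-based id vectors
feat_ids <- function(fstr_list, vocab) {
  lapply(fstr_list, function(fs) {
    ids <- match(fs, vocab)
    as.integer(ids[!is.na(ids)] - 1L)
  })
}

## token feature strings for a sentence under the CRF's config (history off)
crf_feature_strings <- function(sentence, semantic_tags, fcfg) {
  cfg <- fcfg
  cfg$history <- FALSE
  lapply(sentence_features(sentence, semantic_tags, cfg), feature_strings)
}

#' Fit a conditional random field sequence labeler
#'
#' Trains a linear-chain CRF over the 13-label BIO set: state features are
#' the windowed token features crossed with the label at each position;
#' label-bigram transition features are included when
#' `fcfg$bigram` is `TRUE`.  Training maximizes the conditional
#' log-likelihood with an L2 penalty (strength `lambda`) by L-BFGS.
#'
#' @param sentences List of sentence token data frames (pooled across
#'   documents).
#' @param labels List of gold BIO label vectors aligned to `sentences`.
#' @param semantic_tags List of per-sentence semantic tag vectors (from
#'   [rule_tag()]), or `NULL`.
#' @param fcfg A [feature_config()]; the history switch is ignored (the
#'   CRF models label dependence through transitions, not a history
#'   feature).
#' @param lambda L2 regularization strength (default 1.0).
#' @param maxit Maximum L-BFGS iterations (default 200).
#' @param labelset Label alphabet (default [bio_labels()]).
#' @return A fitted `crf_tagger` with a [predict][predict.crf_tagger]
#'   method.
#' @export
crf_tagger <- function(sentences, labels, semantic_tags = NULL,
                       fcfg = feature_config(), lambda = 1.0, maxit = 200L,
                       labelset = bio_labels()) {
  if (length(sentences) == 0L) stop("empty training set")
  stopifnot(length(labels) == length(sentences))
  if (is.null(semantic_tags)) semantic_tags <- vector("list",
                                                      length(sentences))
  fstr <- mapply(crf_feature_strings, sentences, semantic_tags,
                 MoreArgs = list(fcfg = fcfg), SIMPLIFY = FALSE)
  vocab <- unique(unlist(fstr, use.names = FALSE))
  feats <- lapply(fstr, feat_ids, vocab = vocab)
  y <- lapply(labels, function(l) {
    ids <- match(l, labelset)
    if (anyNA(ids)) stop("label outside the label set: ",
                         paste(l[is.na(ids)], collapse = ", "))
    ids - 1L
  })
  nfeat <- length(vocab); nlab <- length(labelset)
  use_trans <- isTRUE(fcfg$bigram)
  nw <- nfeat * nlab + if (use_trans) nlab * nlab else 0L

  ## optim calls fn and gr separately; cache the joint evaluation
  cache <- new.env(parent = emptyenv())
  evalboth <- function(w) {
    if (!is.null(cache$w) && identical(cache$w, w)) return(cache$res)
    res <- crf_nll_grad_cpp(w, feats, y, nfeat, nlab, use_trans, lambda)
    cache$w <- w; cache$res <- res
    res
  }
  opt <- stats::optim(rep(0, nw),
                      fn = function(w) evalboth(w)$nll,
                      gr = function(w) evalboth(w)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit))
  structure(list(w = opt$par, vocab = vocab, labels = labelset,
                 use_trans = use_trans, fcfg = fcfg, nfeat = nfeat,
                 nlab = nlab, lambda = lambda,
                 value = opt$value, convergence = opt$convergence,
                 n_sentences = length(sentences)),
            class = "crf_tagger")
}

#' @export
print.crf_tagger <- function(x, ...) {
  cat("<crf_tagger> ", x$nfeat, " token features x ", x$nlab, " labels",
      if (x$use_trans) " + label-bigram transitions", "\n", sep = "")
  if (!is.null(x$n_sentences)) {
    cat("  trained on ", x$n_sentences, " sentences; penalized NLL ",
        format(x$value, digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' Predict BIO labels with a fitted CRF
#'
#' Viterbi decoding of the most probable label sequence.
#'
#' @param object A fitted [crf_tagger()].
#' @param sentences List of sentence token data frames (or a single one).
#' @param semantic_tags Matching semantic tag list, or `NULL`.
#' @param ... Unused.
#' @return List of label vectors (or a single vector if a single sentence
#'   was given).
#' @export
predict.crf_tagger <- function(object, sentences, semantic_tags = NULL, ...) {
  single <- is.data.frame(sentences)
  if (single) {
    sentences <- list(sentences)
    if (!is.null(semantic_tags) && !is.list(semantic_tags)) {
      semantic_tags <- list(semantic_tags)
    }
  }
  if (is.null(semantic_tags)) semantic_tags <- vector("list",
                                                      length(sentences))
  out <- vector("list", length(sentences))
  for (i in seq_along(sentences)) {
    fstr <- crf_feature_strings(sentences[[i]], semantic_tags[[i]],
                                object$fcfg)
    ids <- feat_ids(fstr, object$vocab)
    path <- crf_viterbi_cpp(object$w, ids, object$nfeat, object$nlab,
                            object$use_trans)
    out[[i]] <- object$labels[path + 1L]
  }
  if (single) out[[1]] else out
}

#' Conditional probability of a label sequence
#'
#' Evaluates \eqn{P(\mathbf{y}\mid\mathbf{x})} under a fitted CRF: the
#' exponentiated path score normalized by the forward-algorithm partition
#' function.
#'
#' @param model A `crf_tagger`.
#' @param sentence Sentence token data frame.
#' @param labels Label vector aligned to the sentence.
#' @param semantic_tags Optional semantic tag vector.
#' @return A probability in `[0, 1]`.
#' @export
sequence_probability <- function(model, sentence, labels,
                                 semantic_tags = NULL) {
  if (length(labels) != nrow(sentence)) {
    stop("labels length ", length(labels), " does not match token count ",
         nrow(sentence))
  }
  fstr <- crf_feature_strings(sentence, semantic_tags, model$fcfg)
  ids <- feat_ids(fstr, model$vocab)
  y <- match(labels, model$labels) - 1L
  if (anyNA(y)) stop("label outside the model's label set")
  s <- crf_path_score_cpp(model$w, ids, as.integer(y), model$nfeat,
                          model$nlab, model$use_trans)
  z <- crf_logZ_cpp(model$w, ids, model$nfeat, model$nlab, model$use_trans)
  exp(s - z)
}
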