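#' The feature-ablation grid
#'
#' The ten feature combinations of the standard ablation design for the
#' SVM tagger: words alone; words plus each single family; then the
#' cumulative combinations up to all six families.
#'
#' @param window,affix_len Passed to [feature_config()].
#' @return Named list of ten `feature_config`s.
#' @export
ablation_grid <- function(window = 2L, affix_len = 3L) {
  mk <- function(history = FALSE, morph = FALSE, pos = FALSE,
                 ortho = FALSE, semantic = FALSE) {
    feature_config(word = TRUE, history = history, morph = morph, pos = pos,
                   ortho = ortho, semantic = semantic, bigram = FALSE,
                   window = window, affix_len = affix_len)
  }
  list(
    words                  = mk(),
    `words+history`        = mk(history = TRUE),
    `words+morph`          = mk(morph = TRUE),
    `words+pos`            = mk(pos = TRUE),
    `words+ortho`          = mk(ortho = TRUE),
    `words+semantic`       = mk(semantic = TRUE),
    `words+hist+morph`     = mk(history = TRUE, morph = TRUE),
    `words+hist+morph+pos` = mk(history = TRUE, morph = TRUE, pos = TRUE),
    `words+hist+morph+pos+ortho` = mk(history = TRUE, morph = TRUE,
                                      pos = TRUE, ortho = TRUE),
    all                    = mk(history = TRUE, morph = TRUE, pos = TRUE,
                                ortho = TRUE, semantic = TRUE))
}

## flatten selected documents to aligned sentence/label/semantic-tag lists
flatten_docs <- function(documents, labels_by_doc, sem_by_doc, ids) {
  sents <- list(); labs <- list(); sems <- list()
  for (id in ids) {
    sents <- c(sents, documents[[id]]$sentences)
    labs <- c(labs, labels_by_doc[[id]])
    sems <- c(sems, sem_by_doc[[id]])
  }
  list(sentences = sents, labels = labs, sem = sems)
}

## regroup a flat per-sentence list back into per-document shape
regroup <- function(flat, documents, ids) {
  out <- list()
  k <- 0L
  for (id in ids) {
    ns <- length(documents[[id]]$sentences)
    out[[id]] <- flat[k + seq_len(ns)]
    k <- k + ns
  }
  out
}

decode_docs <- function(documents, labels_by_doc, ids) {
  res <- lapply(ids, function(id)
    decode_bio_document(documents[[id]], labels_by_doc[[id]]))
  out <- do.call(rbind, c(res, list(empty_mentions())))
  if (nrow(out)) out$event <- seq_len(nrow(out))
  out
}

#' Run an end-to-end labeling experiment
#'
#' Fits the rule-based, SVM and CRF systems, applies the requested voting
#' strategies, and evaluates everything with pooled (micro) chunk counts —
#' either by k-fold cross-validation over documents or on one fixed
#' train/test split.  Pairwise approximate-randomization significance
#' tests between all evaluated systems are run on the pooled predictions.
#'
#' @param documents Named list of `ner_document`s, or the result of
#'   [generate_corpus()] (whose gold and lexicon are then used).
#' @param gold Gold mention data frame (ignored when `documents` is a
#'   generated corpus).
#' @param lex,rules Rule-system resources.
#' @param mode `"crossval"` or `"split"`.
#' @param k Folds for cross-validation.
#' @param split For `mode = "split"`: either a fraction of documents used
#'   for training, or `list(train = ids, test = ids)`.
#' @param fcfg Feature configuration for both learners.
#' @param svm_cfg An [svm_config()].
#' @param crf_lambda,crf_maxit CRF training controls.
#' @param voting Character vector of voting strategies to evaluate.
#' @param ranking Majority-vote tie-break ranking, or `NULL` to rank
#'   systems by training-set micro-F within each fold.
#' @param sigtest_n Shuffles for the significance tests (0 disables).
#' @param seed Seed controlling fold assignment and the significance
#'   tests.
#' @return An `ner_experiment` object: `report` (wide table, one row per
#'   system), `scores` (named list of `eval_report`s), `predictions`
#'   (pooled mention sets per system), `sigtests` (data frame), `folds`,
#'   and the configuration.
#' @export
run_experiment <- function(documents, gold = NULL, lex = default_lexicon(),
                           rules = default_patterns(),
                           mode = c("crossval", "split"), k = 10L,
                           split = 0.7, fcfg = feature_config(),
                           svm_cfg = svm_config(), crf_lambda = 1.0,
                           crf_maxit = 200L,
                           voting = c("majority", "local_crf", "local_svm"),
                           ranking = NULL, sigtest_n = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.null(documents$documents)) {
    gold <- documents$gold
    if (!is.null(documents$lexicon)) lex <- documents$lexicon
    documents <- documents$documents
  }
  if (is.null(gold)) stop("gold mentions are required")
  ids <- names(documents)
  stopifnot(!is.null(ids), all(nzchar(ids)))

  ## rule system + semantic tags, once for the whole corpus
  rule_out <- lapply(documents, rule_tag, lex = lex, rules = rules)
  sem_by_doc <- lapply(rule_out, `[[`, "semantic_tags")
  labels_by_doc <- lapply(documents, function(d)
    encode_bio_document(d, gold[gold$doc_id == d$doc_id, , drop = FALSE]))

  folds <- if (mode == "crossval") {
    make_folds(ids, k = k, seed = seed)
  } else if (is.list(split)) {
    list(split)
  } else {
    sp <- make_folds(ids, k = 2L, seed = seed)  # seeded shuffle
    ntr <- max(1L, min(length(ids) - 1L, round(split * length(ids))))
    perm <- c(sp[[1]]$test, sp[[2]]$test)
    list(list(train = perm[seq_len(ntr)], test = perm[-seq_len(ntr)]))
  }

  systems <- c("rule", "svm", "crf", voting)
  pred_labels <- stats::setNames(
    rep(list(stats::setNames(vector("list", length(ids)), ids)),
        length(systems)), systems)

  for (fold in folds) {
    tr <- flatten_docs(documents, labels_by_doc, sem_by_doc, fold$train)
    svm_fit <- svm_tagger(tr$sentences, tr$labels, tr$sem,
                          cfg = svm_cfg, fcfg = fcfg)
    crf_fit <- crf_tagger(tr$sentences, tr$labels, tr$sem, fcfg = fcfg,
                          lambda = crf_lambda, maxit = crf_maxit)
    te <- flatten_docs(documents, labels_by_doc, sem_by_doc, fold$test)
    out <- list(
      rule = lapply(fold$test, function(id)
        encode_labels_from_sem(sem_by_doc[[id]])),
      svm = regroup(predict(svm_fit, te$sentences, te$sem),
                    documents, fold$test),
      crf = regroup(predict(crf_fit, te$sentences, te$sem),
                    documents, fold$test))
    names(out$rule) <- fold$test
    rank_use <- ranking
    if (is.null(rank_use) && "majority" %in% voting) {
      rank_use <- rank_systems(documents, gold, labels_by_doc, sem_by_doc,
                               fold$train, svm_fit, crf_fit)
    }
    for (v in voting) {
      cfg_v <- voting_config(v, ranking = if (is.null(rank_use))
        c("crf", "svm", "rule") else rank_use)
      flat <- ensemble_predict(
        lapply(out, function(o) do.call(c, unname(o))), cfg_v)
      out[[v]] <- regroup(flat$labels, documents, fold$test)
    }
    for (sys in systems) {
      for (id in fold$test) pred_labels[[sys]][[id]] <- out[[sys]][[id]]
    }
  }

  covered <- unique(unlist(lapply(folds, `[[`, "test")))
  covered <- ids[ids %in% covered]
  gold_eval <- gold[gold$doc_id %in% covered, , drop = FALSE]
  predictions <- lapply(pred_labels, function(pl)
    decode_docs(documents, pl, covered))
  scores <- lapply(predictions, function(p) evaluate_mentions(gold_eval, p))
  report <- do.call(rbind, lapply(systems, function(sys) {
    sc <- scores[[sys]]
    wide <- data.frame(system = sys, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sc))) {
      wide[[paste0(sc$field[i], "_P")]] <- sc$precision[i]
      wide[[paste0(sc$field[i], "_R")]] <- sc$recall[i]
      wide[[paste0(sc$field[i], "_F")]] <- sc$f[i]
    }
    wide
  }))

  sig <- NULL
  if (sigtest_n > 0L && length(systems) > 1L) {
    combs <- utils::combn(systems, 2)
    sig <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      rt <- approximate_randomization(predictions[[a]], predictions[[b]],
                                      gold_eval, n = sigtest_n, seed = seed)
      data.frame(system_a = a, system_b = b, f_diff = rt$f_observed,
                 p = rt$p_value, p_reversed = rt$p_value_reversed,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(report = report, scores = scores,
                 predictions = predictions, pred_labels = pred_labels,
                 sigtests = sig, folds = folds, mode = mode, seed = seed,
                 systems = systems),
            class = "ner_experiment")
}

## rule-system labels are the semantic tags themselves (already BIO-shaped)
encode_labels_from_sem <- function(sem) lapply(sem, repair_bio)

## rank systems by micro-F on (a sample of) the training documents
rank_systems <- function(documents, gold, labels_by_doc, sem_by_doc,
                         train_ids, svm_fit, crf_fit, max_docs = 10L) {
  use <- train_ids[seq_len(min(length(train_ids), max_docs))]
  g <- gold[gold$doc_id %in% use, , drop = FALSE]
  fl <- flatten_docs(documents, labels_by_doc, sem_by_doc, use)
  preds <- list(
    rule = stats::setNames(lapply(use, function(id)
      encode_labels_from_sem(sem_by_doc[[id]])), use),
    svm = regroup(predict(svm_fit, fl$sentences, fl$sem), documents, use),
    crf = regroup(predict(crf_fit, fl$sentences, fl$sem), documents, use))
  fs <- vapply(names(preds), function(sys) {
    p <- decode_docs(documents, preds[[sys]], use)
    ner_scores(chunk_counts(g, p))$f[1]
  }, 0)
  names(sort(fs, decreasing = TRUE))
}

#' @export
print.ner_experiment <- function(x, digits = 2, ...) {
  cat("<ner_experiment> ", x$mode, ", ", length(x$folds),
      " fold(s), seed ", x$seed, "\n\n", sep = "")
  tab <- x$report[, c("system", "ALL_P", "ALL_R", "ALL_F")]
  tab[-1] <- round(tab[-1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the SVM feature-ablation design
#'
#' Fits one SVM tagger per feature configuration of the grid on a fixed
#' train/test split and reports each configuration's scores.
#'
#' @param documents Corpus (as in [run_experiment()]).
#' @param gold Gold mentions.
#' @param lex,rules Rule-system resources for semantic tags.
#' @param grid Named list of [feature_config()]s (default
#'   [ablation_grid()]).
#' @param split Training fraction or `list(train=, test=)`.
#' @param svm_cfg An [svm_config()].
#' @param seed Seed for the split.
#' @return Named list of `eval_report`s, one per grid entry.
#' @export
run_ablation <- function(documents, gold = NULL, lex = default_lexicon(),
                         rules = default_patterns(), grid = ablation_grid(),
                         split = 0.7, svm_cfg = svm_config(), seed = 1L) {
  if (!is.null(documents$documents)) {
    gold <- documents$gold
    if (!is.null(documents$lexicon)) lex <- documents$lexicon
    documents <- documents$documents
  }
  ids <- names(documents)
  rule_out <- lapply(documents, rule_tag, lex = lex, rules = rules)
  sem_by_doc <- lapply(rule_out, `[[`, "semantic_tags")
  labels_by_doc <- lapply(documents, function(d)
    encode_bio_document(d, gold[gold$doc_id == d$doc_id, , drop = FALSE]))
  if (is.list(split)) {
    tr_ids <- split$train; te_ids <- split$test
  } else {
    sp <- make_folds(ids, k = 2L, seed = seed)
    perm <- c(sp[[1]]$test, sp[[2]]$test)
    ntr <- max(1L, min(length(ids) - 1L, round(split * length(ids))))
    tr_ids <- perm[seq_len(ntr)]; te_ids <- perm[-seq_len(ntr)]
  }
  tr <- flatten_docs(documents, labels_by_doc, sem_by_doc, tr_ids)
  te <- flatten_docs(documents, labels_by_doc, sem_by_doc, te_ids)
  g <- gold[gold$doc_id %in% te_ids, , drop = FALSE]
  out <- lapply(grid, function(fcfg) {
    fit <- svm_tagger(tr$sentences, tr$labels, tr$sem,
                      cfg = svm_cfg, fcfg = fcfg)
    pl <- regroup(predict(fit, te$sentences, te$sem), documents, te_ids)
    evaluate_mentions(g, decode_docs(documents, pl, te_ids))
  })
  names(out) <- names(grid)
  out
}
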