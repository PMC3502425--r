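## Independent oracles and random-input builders shared across tests.
## Everything here is deliberately written as naive brute force, separate
## from the package's code paths.

## brute-force whitespace splitter for one line
bf_tokens <- function(line) {
  t <- strsplit(line, "[ \t]+")[[1]]
  t[nzchar(t)]
}

## small vocabulary for random notes (no sentence-final-period shapes)
RAND_VOCAB <- c("alpha", "beta", "Gamma", "delta-2", "x10", "p.o.", "40",
                "mg", "prn,", "tabs", "0.5%", "(qd)", "epsilon", "zeta")

## a random multi-line note; returns the raw lines
rand_note_lines <- function(n_lines = 4, max_tok = 6) {
  vapply(seq_len(n_lines), function(i) {
    if (stats::runif(1) < 0.2) return("")
    paste(sample(RAND_VOCAB, sample.int(max_tok, 1), replace = TRUE),
          collapse = " ")
  }, "")
}

## plant random non-overlapping mentions on a document's sentences
rand_mentions_for_doc <- function(doc, p_mention = 0.5) {
  out <- list()
  ev <- 0L
  for (sent in doc$sentences) {
    n <- nrow(sent)
    i <- 1L
    while (i <= n) {
      if (stats::runif(1) < p_mention) {
        len <- min(sample.int(3L, 1), n - i + 1L)
        ev <- ev + 1L
        fld <- sample(medner::field_codes(), 1)
        out[[ev]] <- data.frame(
          doc_id = doc$doc_id, field = fld,
          start_line = sent$line[i], start_offset = sent$offset[i],
          end_line = sent$line[i + len - 1L],
          end_offset = sent$offset[i + len - 1L],
          text = paste(sent$text[i:(i + len - 1L)], collapse = " "),
          event = ev, stringsAsFactors = FALSE)
        i <- i + len + 1L  # gap so mentions never touch ambiguously
      } else i <- i + 1L
    }
  }
  if (!length(out)) {
    return(medner::mentions(character(0), character(0), integer(0),
                            integer(0), integer(0), integer(0),
                            character(0), integer(0)))
  }
  do.call(rbind, out)
}

## ---------------------------------------------------------------------
## conlleval-style chunk oracle over BIO label columns (independent of the
## package's mention data frames): a chunk starts at B-x, or at I-x whose
## predecessor is not of type x; equality is (sentence, start, end, type).
## ---------------------------------------------------------------------
oracle_chunks <- function(labels_by_sentence) {
  res <- list()
  for (s in seq_along(labels_by_sentence)) {
    lab <- labels_by_sentence[[s]]
    i <- 1L
    while (i <= length(lab)) {
      if (lab[i] == "O") { i <- i + 1L; next }
      typ <- sub("^[BI]-", "", lab[i])
      j <- i
      while (j < length(lab) && lab[j + 1L] == paste0("I-", typ)) j <- j + 1L
      res[[length(res) + 1L]] <- c(s, i, j, typ)
      i <- j + 1L
    }
  }
  if (!length(res)) return(character(0))
  vapply(res, paste, "", collapse = "|")
}

## micro P/R/F (percent) from two label-column corpora, conlleval-style
oracle_prf <- function(gold_by_sentence, pred_by_sentence) {
  g <- oracle_chunks(gold_by_sentence)
  p <- oracle_chunks(pred_by_sentence)
  tp <- sum(p %in% g)
  prec <- if (length(p)) 100 * tp / length(p) else 0
  rec <- if (length(g)) 100 * tp / length(g) else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f = f)
}

## random valid BIO label sequence of length n
rand_bio <- function(n, fields = medner::field_codes()) {
  lab <- character(n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < 0.5) { lab[i] <- "O"; i <- i + 1L; next }
    fld <- sample(fields, 1)
    len <- min(sample.int(3L, 1), n - i + 1L)
    lab[i:(i + len - 1L)] <- paste0("I-", fld)
    lab[i] <- paste0("B-", fld)
    i <- i + len
  }
  lab
}

## ---------------------------------------------------------------------
## CRF enumeration oracle: score every label sequence explicitly from a
## word-score matrix and transition matrix, mirroring the model definition
## score(y) = sum_t state(tok_t, y_t) + sum_{t>1} trans(y_{t-1}, y_t).
## ---------------------------------------------------------------------
enum_sequences <- function(nlab, L) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(nlab)), L)))
}

enum_scores <- function(word_ids, W, Trans) {
  ## word_ids: token -> row of W; W: nwords x nlab; Trans: nlab x nlab
  L <- length(word_ids)
  seqs <- enum_sequences(ncol(W), L)
  apply(seqs, 1, function(y) {
    s <- sum(W[cbind(word_ids, y)])
    if (L > 1L && !is.null(Trans)) {
      s <- s + sum(Trans[cbind(y[-L], y[-1])])
    }
    s
  })
}

## build a word-only window-0 CRF model around the package's internals so
## sequence_probability / predict see exactly the W, Trans used here
build_toy_crf <- function(words, labels, W, Trans) {
  fcfg <- medner::feature_config(word = TRUE, pos = FALSE, morph = FALSE,
                                 ortho = FALSE, semantic = FALSE,
                                 history = FALSE,
                                 bigram = !is.null(Trans), window = 0L)
  vocab <- paste0("word[0]=", words)
  medner:::new_crf_model(vocab, labels, W, Trans, fcfg)
}

toy_sentence <- function(tokens) {
  data.frame(text = tokens, line = 1L, offset = seq_along(tokens) - 1L,
             stringsAsFactors = FALSE)
}

## decode corpus predictions (list per doc of per-sentence labels)
decode_all <- function(documents, labels_by_doc) {
  out <- do.call(rbind, lapply(names(documents), function(id)
    medner::decode_bio_document(documents[[id]], labels_by_doc[[id]])))
  if (is.null(out)) return(medner:::empty_mentions())
  out$event <- seq_len(nrow(out))
  out
}

## micro-F of corrupted labels vs gold, via the package evaluator
micro_f_of <- function(corpus, pred_labels) {
  pred <- decode_all(corpus$documents, pred_labels)
  medner::ner_scores(medner::chunk_counts(corpus$gold, pred))$f[1]
}
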