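#' Write labeled documents in CoNLL column format
#'
#' One token per line with its label, tab-separated (additional label
#' columns may be supplied), a blank line between sentences, and a
#' `# doc <id>` marker before each document.
#'
#' @param documents Named list of `ner_document`s.
#' @param labels Per-document list of per-sentence label vectors (the
#'   first label column).
#' @param path Output path.
#' @param extra_labels Optional list of further label columns, each shaped
#'   like `labels` (e.g. gold next to predictions).
#' @return `path`, invisibly.
#' @export
write_conll <- function(documents, labels, path, extra_labels = NULL) {
  cols <- c(list(labels), extra_labels)
  con <- file(path, "w")
  on.exit(close(con))
  for (d in seq_along(documents)) {
    doc <- documents[[d]]
    writeLines(paste("# doc", doc$doc_id), con)
    for (s in seq_along(doc$sentences)) {
      toks <- doc$sentences[[s]]$text
      lab <- lapply(cols, function(cc) cc[[d]][[s]])
      writeLines(do.call(paste, c(list(toks), lab, list(sep = "\t"))), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read a CoNLL column file
#'
#' @param path File written by [write_conll()] (or any token-per-line
#'   file with blank-line sentence separators and `# doc` markers).
#' @return Named list per document with `sentences` (token data frames;
#'   line numbers are synthesized as one sentence per line) and `labels`
#'   (list of per-sentence character-vector columns).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  docs <- list()
  cur_doc <- NULL
  cur_tokens <- NULL
  cur_labels <- NULL
  sent_no <- 0L
  flush_sentence <- function() {
    if (is.null(cur_tokens) || !length(cur_tokens)) return()
    sent_no <<- sent_no + 1L
    sent <- data.frame(text = cur_tokens, line = sent_no,
                       offset = seq_along(cur_tokens) - 1L,
                       stringsAsFactors = FALSE)
    attr(sent, "doc_id") <- cur_doc
    docs[[cur_doc]]$sentences[[length(docs[[cur_doc]]$sentences) + 1L]] <<-
      sent
    docs[[cur_doc]]$labels[[length(docs[[cur_doc]]$labels) + 1L]] <<-
      do.call(rbind, cur_labels)
    cur_tokens <<- NULL
    cur_labels <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, "# doc ")) {
      flush_sentence()
      cur_doc <- sub("^# doc ", "", ln)
      docs[[cur_doc]] <- list(sentences = list(), labels = list())
      next
    }
    if (!nzchar(ln)) { flush_sentence(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cur_tokens <- c(cur_tokens, parts[1])
    cur_labels <- c(cur_labels, list(parts[-1]))
  }
  flush_sentence()
  lapply(docs, function(d) {
    ncol_lab <- if (length(d$labels)) ncol(d$labels[[1]]) else 0L
    list(sentences = d$sentences,
         labels = lapply(seq_len(ncol_lab), function(k)
           lapply(d$labels, function(m) unname(m[, k]))))
  })
}
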