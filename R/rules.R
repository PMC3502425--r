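#' Build a lexicon
#'
#' A lexicon maps lower-cased (possibly multi-token) phrases to field
#' types; lookups are case-insensitive, greedy, longest-match.
#'
#' @param entries Named character vector: names are phrases, values field
#'   codes.
#' @return Object of class `ner_lexicon` with components `entries` and
#'   `max_phrase_len`.
#' @export
#' @examples
#' lexicon(c("caltrate plus d" = "m", lasix = "m", dizziness = "r"))
lexicon <- function(entries) {
  if (length(entries) == 0L) {
    return(structure(list(entries = character(0), max_phrase_len = 0L),
                     class = "ner_lexicon"))
  }
  stopifnot(!is.null(names(entries)), all(nzchar(names(entries))),
            all(entries %in% field_codes()))
  names(entries) <- tolower(names(entries))
  lens <- lengths(strsplit(names(entries), " ", fixed = TRUE))
  structure(list(entries = entries, max_phrase_len = max(lens)),
            class = "ner_lexicon")
}

#' @export
print.ner_lexicon <- function(x, ...) {
  cat("<ner_lexicon> ", length(x$entries), " phrases (longest ",
      x$max_phrase_len, " tokens)\n", sep = "")
  invisible(x)
}

#' Read / write a lexicon file
#'
#' Tab-delimited, two columns: `phrase<TAB>field_code`.
#'
#' @param path File path.
#' @param lex A `ner_lexicon`.
#' @return `read_lexicon` returns a `ner_lexicon`.
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("phrase", "field"))
  lexicon(stats::setNames(tab$field, tab$phrase))
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lex, path) {
  writeLines(paste(names(lex$entries), lex$entries, sep = "\t"), path)
  invisible(path)
}

#' The shipped default drug/term lexicon
#'
#' About 200 entries: common medication names (single- and multi-token)
#' plus indication terms used as reason entries.  User-replaceable.
#'
#' @return A `ner_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "default_lexicon.tsv",
                           package = "medner", mustWork = TRUE))
}

#' Build pattern rules
#'
#' A pattern rule matches a fixed-length token sequence: its pattern is a
#' space-separated list of per-token regular expressions, each matched
#' case-insensitively against the whole token.  `priority` total-orders
#' rules; numerically smaller is stronger, and stronger matches shadow
#' overlapping weaker ones.
#'
#' @param name Rule names.
#' @param field Field codes.
#' @param priority Integer priorities.
#' @param pattern Space-separated token regexes.
#' @return A `pattern_rules` data frame.
#' @export
#' @examples
#' pattern_rules("du_xdays", "du", 10, "x[0-9]+ (days?|weeks?)[.,]?")
pattern_rules <- function(name, field, priority, pattern) {
  stopifnot(all(field %in% field_codes()))
  structure(data.frame(name = name, field = field,
                       priority = as.integer(priority), pattern = pattern,
                       stringsAsFactors = FALSE),
            class = c("pattern_rules", "data.frame"))
}

#' Read / write pattern rule files
#'
#' Tab-delimited, one rule per line: `name<TAB>field<TAB>priority<TAB>pattern`.
#'
#' @param path File path.
#' @param rules A `pattern_rules` table.
#' @return `read_patterns` returns a `pattern_rules` table.
#' @export
read_patterns <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("name", "field", "priority",
                                         "pattern"))
  pattern_rules(tab$name, tab$field, tab$priority, tab$pattern)
}

#' @rdname read_patterns
#' @export
write_patterns <- function(rules, path) {
  writeLines(paste(rules$name, rules$field, rules$priority, rules$pattern,
                   sep = "\t"), path)
  invisible(path)
}

#' The shipped default pattern rules
#'
#' About 25 rules covering dosage, mode, frequency and duration surface
#' patterns (`"x10 days"`, `"p.o."`, `"as needed"`, `"for ten days"`,
#' ...).  User-replaceable.
#'
#' @return A `pattern_rules` table.
#' @export
default_patterns <- function() {
  read_patterns(system.file("extdata", "default_patterns.tsv",
                            package = "medner", mustWork = TRUE))
}

## greedy non-overlapping selection from candidate spans ordered by rank
select_spans <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  taken <- rep(FALSE, max(cand$end))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Dictionary lookup over a sentence
#'
#' Greedy longest-match, left-to-right, case-insensitive phrase lookup.
#' Matched spans never overlap.
#'
#' @param sentence Sentence token data frame.
#' @param lex A [lexicon()].
#' @return Data frame with columns `start`, `end` (1-based token indices,
#'   inclusive) and `field`.
#' @export
lexicon_lookup <- function(sentence, lex) {
  n <- nrow(sentence)
  out <- data.frame(start = integer(0), end = integer(0),
                    field = character(0), stringsAsFactors = FALSE)
  if (n == 0L || length(lex$entries) == 0L) return(out)
  low <- tolower(sentence$text)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in rev(seq_len(min(lex$max_phrase_len, n - i + 1L)))) {
      phrase <- paste(low[i:(i + len - 1L)], collapse = " ")
      if (!is.na(lex$entries[phrase])) { hit <- len; break }
    }
    if (hit > 0L) {
      out <- rbind(out, data.frame(
        start = i, end = i + hit - 1L,
        field = unname(lex$entries[paste(low[i:(i + hit - 1L)],
                                         collapse = " ")]),
        stringsAsFactors = FALSE))
      i <- i + hit
    } else i <- i + 1L
  }
  out
}

## all raw matches of the rule set against a token vector
pattern_matches <- function(tokens, rules) {
  out <- list()
  n <- length(tokens)
  for (ri in seq_len(nrow(rules))) {
    parts <- strsplit(rules$pattern[ri], " ", fixed = TRUE)[[1]]
    L <- length(parts)
    if (L == 0L || n < L) next
    ## per-token regexes, anchored, case-insensitive
    ok <- vapply(parts, function(p)
      grepl(paste0("^(?:", p, ")$"), tokens, ignore.case = TRUE, perl = TRUE),
      logical(n))
    ok <- matrix(ok, nrow = n)
    for (s in seq_len(n - L + 1L)) {
      if (all(ok[cbind(s:(s + L - 1L), seq_len(L))])) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = s + L - 1L, field = rules$field[ri],
          priority = rules$priority[ri], rule = rules$name[ri],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(start = integer(0), end = integer(0),
                                        field = character(0),
                                        priority = integer(0),
                                        rule = character(0),
                                        stringsAsFactors = FALSE))))
}

#' Apply pattern rules to a sentence
#'
#' Each rule scans left-to-right; matches of stronger (numerically
#' smaller) priority shadow overlapping weaker ones; at equal priority the
#' leftmost-then-longest match wins.
#'
#' @param sentence Sentence token data frame.
#' @param rules A [pattern_rules()] table.
#' @return Data frame with columns `start`, `end`, `field`, `priority`,
#'   `rule`.
#' @export
apply_patterns <- function(sentence, rules) {
  cand <- pattern_matches(sentence$text, rules)
  if (nrow(cand)) {
    cand <- cand[order(cand$priority, cand$start, -(cand$end - cand$start)), ,
                 drop = FALSE]
    cand <- select_spans(cand)
    cand <- cand[order(cand$start), , drop = FALSE]
    rownames(cand) <- NULL
  }
  cand
}

#' Rule-based semantic tagging of a document
#'
#' The standalone rule-based system: merges lexicon matches and pattern
#' matches into non-overlapping field spans.  Lexicon matches win
#' conflicts for the medication field (closed drug vocabulary); pattern
#' matches win for the five other, pattern-like fields.  Returns both a
#' per-token semantic-tag sequence (position-qualified, `B-x`/`I-x`/`O`,
#' consumed as the semantic feature family by the learners) and the
#' decoded entity mentions.
#'
#' @param document A `ner_document`.
#' @param lex A [lexicon()] (default [default_lexicon()]).
#' @param rules A [pattern_rules()] table (default [default_patterns()]).
#' @return List with `semantic_tags` (list of per-sentence character
#'   vectors) and `mentions` (mention data frame).
#' @export
rule_tag <- function(document, lex = default_lexicon(),
                     rules = default_patterns()) {
  tags <- vector("list", length(document$sentences))
  ments <- list()
  for (si in seq_along(document$sentences)) {
    sent <- document$sentences[[si]]
    n <- nrow(sent)
    lab <- rep("O", n)
    lexm <- lexicon_lookup(sent, lex)
    patm <- apply_patterns(sent, rules)
    cand <- rbind(
      if (nrow(lexm)) cbind(lexm, rank1 = ifelse(lexm$field == "m", 0L, 2L),
                            rank2 = 0L),
      if (nrow(patm)) data.frame(start = patm$start, end = patm$end,
                                 field = patm$field, rank1 = 1L,
                                 rank2 = patm$priority,
                                 stringsAsFactors = FALSE))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$rank1, cand$rank2, cand$start,
                         -(cand$end - cand$start)), , drop = FALSE]
      cand <- select_spans(cand)
      cand <- cand[order(cand$start), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        span <- cand$start[k]:cand$end[k]
        lab[span] <- paste0("I-", cand$field[k])
        lab[span[1]] <- paste0("B-", cand$field[k])
      }
    }
    tags[[si]] <- lab
    ments[[si]] <- decode_bio(sent, lab, doc_id = document$doc_id)
  }
  res <- do.call(rbind, c(ments, list(empty_mentions())))
  if (nrow(res)) res$event <- seq_len(nrow(res))
  list(semantic_tags = tags, mentions = res)
}

#' Rule-based tagging of a corpus
#'
#' @param corpus List of `ner_document`s.
#' @param lex,rules See [rule_tag()].
#' @return List with `semantic_tags` (named list per document) and pooled
#'   `mentions`.
#' @export
rule_tag_corpus <- function(corpus, lex = default_lexicon(),
                            rules = default_patterns()) {
  per_doc <- lapply(corpus, rule_tag, lex = lex, rules = rules)
  names(per_doc) <- vapply(corpus, `[[`, "", "doc_id")
  list(semantic_tags = lapply(per_doc, `[[`, "semantic_tags"),
       mentions = do.call(rbind, c(lapply(per_doc, `[[`, "mentions"),
                                   list(empty_mentions()))))
}
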