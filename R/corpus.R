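#' Medication field codes
#'
#' The six medication-related field types, in their fixed canonical order:
#' medication (`m`), dosage (`do`), mode (`mo`), frequency (`f`),
#' duration (`du`), reason (`r`).
#'
#' @return Character vector of the six field codes.
#' @export
field_codes <- function() c("m", "do", "mo", "f", "du", "r")

#' The 13-label BIO tag set
#'
#' Per-token labels for the sequence-labeling formulation: for each of the
#' six field types a begin tag `B-x` and an inside tag `I-x`, plus the
#' outside tag `O`.  The order is the package's canonical tie-break order:
#' fields in [field_codes()] order with `B` before `I`, and `O` last.
#'
#' @return Character vector of 13 BIO labels.
#' @export
#' @examples
#' bio_labels()
bio_labels <- function() {
  f <- field_codes()
  c(as.vector(rbind(paste0("B-", f), paste0("I-", f))), "O")
}

## Field type of a BIO label ("B-do" -> "do", "O" -> NA)
label_field <- function(labels) {
  out <- rep(NA_character_, length(labels))
  idx <- labels != "O" & !is.na(labels)
  out[idx] <- substr(labels[idx], 3L, nchar(labels[idx]))
  out
}

## True where token text would end a sentence: bare word of >= 2 letters
## followed by a single terminal period (so "p.o.", "4." and "A." never split).
sentence_final <- function(tok) {
  grepl("^[A-Za-z]{2,}\\.$", tok)
}

#' Tokenize a clinical note
#'
#' Whitespace tokenization within each line; punctuation stays attached to
#' its word (so `"prn,"` is a single token).  Tokens are addressed by
#' 1-based line number and 0-based within-line offset.  Sentences break at
#' blank lines, and after a period-terminated word (at least two letters
#' followed by a single `.`; dotted abbreviations such as `"p.o."` are
#' exempt) when the next token starts a new line or begins with an
#' uppercase letter.
#'
#' @param raw_note Note text (single string, possibly multi-line), or a
#'   character vector of lines.
#' @param doc_id Note identifier (defaults to `"doc"`).
#' @return A `ner_document`: list with elements `doc_id`, `lines`
#'   (raw text lines) and `sentences` (list of data frames with columns
#'   `text`, `line`, `offset`).
#' @export
#' @examples
#' doc <- tokenize("Percocet 1-2 Tablets p.o. Q 4 prn,")
#' doc$sentences[[1]]$text
tokenize <- function(raw_note, doc_id = "doc") {
  if (length(raw_note) == 1L && grepl("\n", raw_note, fixed = TRUE)) {
    lines <- strsplit(raw_note, "\n", fixed = TRUE)[[1]]
  } else if (length(raw_note) == 1L && !nzchar(raw_note)) {
    lines <- character(0)
  } else {
    lines <- raw_note
  }

  toks <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    m <- regmatches(lines[[li]], gregexpr("\\S+", lines[[li]]))[[1]]
    if (length(m)) {
      toks[[li]] <- data.frame(text = m, line = li,
                               offset = seq_along(m) - 1L,
                               stringsAsFactors = FALSE)
    }
  }
  stream <- do.call(rbind, toks)
  sentences <- list()
  if (!is.null(stream) && nrow(stream)) {
    n <- nrow(stream)
    ## break after token i?
    brk <- logical(n)
    for (i in seq_len(n - 1L)) {
      nxt <- stream[i + 1L, ]
      if (nxt$line > stream$line[i] + 1L) brk[i] <- TRUE  # blank line between
      if (sentence_final(stream$text[i]) &&
          (nxt$line > stream$line[i] ||
           grepl("^[A-Z]", nxt$text))) brk[i] <- TRUE
    }
    brk[n] <- TRUE
    start <- 1L
    for (i in which(brk)) {
      s <- stream[start:i, , drop = FALSE]
      rownames(s) <- NULL
      attr(s, "doc_id") <- doc_id
      sentences[[length(sentences) + 1L]] <- s
      start <- i + 1L
    }
  }
  structure(list(doc_id = doc_id, lines = lines, sentences = sentences),
            class = "ner_document")
}

#' @export
print.ner_document <- function(x, ...) {
  cat("<ner_document> ", x$doc_id, ": ", length(x$lines), " lines, ",
      length(x$sentences), " sentences, ",
      sum(vapply(x$sentences, nrow, 0L)), " tokens\n", sep = "")
  invisible(x)
}

#' Read a note file into a document
#'
#' @param path Path to a plain-text note; the file stem becomes the
#'   document id.
#' @return A `ner_document` (see [tokenize()]).
#' @export
read_note <- function(path) {
  tokenize(readLines(path, warn = FALSE),
           doc_id = sub("\\.[^.]*$", "", basename(path)))
}

## Construct an empty mention data frame
empty_mentions <- function() {
  data.frame(doc_id = character(0), field = character(0),
             start_line = integer(0), start_offset = integer(0),
             end_line = integer(0), end_offset = integer(0),
             text = character(0), event = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct an entity-mention table
#'
#' Mentions are rows of a data frame: a field type, an inclusive token span
#' `(start_line:start_offset) .. (end_line:end_offset)` (1-based lines,
#' 0-based token offsets), the covered surface text, and an `event` group
#' id tying the fields of one medication event together.
#'
#' @param doc_id,field,start_line,start_offset,end_line,end_offset,text,event
#'   Vectors of equal length (recycled where length 1).
#' @return A mention data frame.
#' @export
mentions <- function(doc_id, field, start_line, start_offset,
                     end_line, end_offset, text, event = 1L) {
  stopifnot(all(field %in% field_codes()))
  data.frame(doc_id = doc_id, field = field,
             start_line = as.integer(start_line),
             start_offset = as.integer(start_offset),
             end_line = as.integer(end_line),
             end_offset = as.integer(end_offset),
             text = text, event = as.integer(event),
             stringsAsFactors = FALSE)
}

mention_key <- function(m) {
  paste(m$doc_id, m$field, m$start_line, m$start_offset,
        m$end_line, m$end_offset, sep = "\r")
}

## ---------------------------------------------------------------------------
## Annotation dialect:
##   m="percocet" 10:0 10:0||do="1-2 tablets" 10:1 10:2||mo="p.o." 10:3 10:3||
##   f="q 4 prn," 10:4 10:6||du="nm"||r="nm"||ln="list"
## One line per medication event; absent fields are x="nm"; ln carries the
## list/narrative flag and never produces a mention.
## ---------------------------------------------------------------------------

#' Parse one annotation line
#'
#' Parses a single line of the i2b2-2009-style annotation dialect into a
#' mention table.  Fields given as `x="nm"` are absent; the `ln`
#' (list/narrative) value is preserved as the `"ln"` attribute of the
#' result but produces no mention.
#'
#' @param line One annotation line.
#' @param doc_id Document id to stamp on the mentions.
#' @param event Event id to stamp on the mentions.
#' @return Mention data frame (possibly 0 rows) with attribute `ln`.
#' @export
#' @examples
#' parse_annotation_line(
#'   'm="percocet" 10:0 10:0||do="1-2 tablets" 10:1 10:2||mo="p.o." 10:3 10:3||f="q 4 prn," 10:4 10:6||du="nm"||r="nm"||ln="list"')
parse_annotation_line <- function(line, doc_id = "doc", event = 1L) {
  parts <- strsplit(line, "||", fixed = TRUE)[[1]]
  rx <- '^(m|do|mo|f|du|r|ln)="([^"]*)"(?: ([0-9]+):([0-9]+) ([0-9]+):([0-9]+))?$'
  out <- empty_mentions()
  ln_flag <- NA_character_
  for (ci in seq_along(parts)) {
    g <- regmatches(parts[[ci]], regexec(rx, parts[[ci]]))[[1]]
    if (!length(g)) {
      stop("malformed annotation field at column ", ci, ": ", parts[[ci]],
           "\n  in line: ", line)
    }
    code <- g[2]; txt <- g[3]
    if (code == "ln") { ln_flag <- txt; next }
    if (txt == "nm") next
    if (!nzchar(g[4])) {
      stop("missing offsets for field '", code, "' at column ", ci,
           "\n  in line: ", line)
    }
    out <- rbind(out, mentions(doc_id, code,
                               as.integer(g[4]), as.integer(g[5]),
                               as.integer(g[6]), as.integer(g[7]),
                               txt, event))
  }
  attr(out, "ln") <- ln_flag
  out
}

#' Write one annotation line
#'
#' Inverse of [parse_annotation_line()]: emits the fields of one medication
#' event in the fixed order m, do, mo, f, du, r followed by `ln`.  Field
#' text is lower-cased on output; absent fields are written as `x="nm"`.
#'
#' @param ments Mention data frame for one event (at most one mention per
#'   field).
#' @param narrative_flag The `ln` value, `"list"` or `"narrative"`.
#' @return A single annotation line.
#' @export
write_annotation_line <- function(ments, narrative_flag = "narrative") {
  pieces <- character(7)
  for (k in seq_along(field_codes())) {
    fc <- field_codes()[k]
    row <- ments[ments$field == fc, , drop = FALSE]
    if (nrow(row) == 0L) {
      pieces[k] <- sprintf('%s="nm"', fc)
    } else {
      if (nrow(row) > 1L) stop("more than one '", fc, "' mention in event")
      pieces[k] <- sprintf('%s="%s" %d:%d %d:%d', fc, tolower(row$text),
                           row$start_line, row$start_offset,
                           row$end_line, row$end_offset)
    }
  }
  pieces[7] <- sprintf('ln="%s"', narrative_flag)
  paste(pieces, collapse = "||")
}

#' Read an annotation file
#'
#' One annotation line per medication event.  If the matching document is
#' supplied, mention text is re-aligned (case-insensitively) to the
#' document's tokens so the case-preserving surface form is restored.
#'
#' @param path Path to a `.ann` file.
#' @param document Optional `ner_document` the annotations refer to.
#' @param doc_id Document id (defaults to the file stem).
#' @return Mention data frame with `event` and `ln` columns.
#' @export
read_annotations <- function(path, document = NULL, doc_id = NULL) {
  if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- parse_annotation_line(lines[[i]], doc_id = doc_id, event = i)
    if (nrow(m)) m$ln <- attr(m, "ln")
    out[[i]] <- m
  }
  res <- do.call(rbind, c(out, list(empty_mentions())))
  if (is.null(res$ln)) res$ln <- character(nrow(res))
  if (!is.null(document) && nrow(res)) {
    res$text <- vapply(seq_len(nrow(res)), function(i)
      span_text(document, res[i, ]), "")
  }
  res
}

#' Write an annotation file
#'
#' @param ments Mention data frame for one document; events are grouped by
#'   the `event` column, and each event's `ln` column (default
#'   `"narrative"`) supplies the list/narrative flag.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ments, path) {
  lines <- character(0)
  if (nrow(ments)) {
    if (is.null(ments$ln)) ments$ln <- "narrative"
    for (ev in unique(ments$event)) {
      grp <- ments[ments$event == ev, , drop = FALSE]
      lines <- c(lines, write_annotation_line(grp, grp$ln[1]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## Surface text of a mention span, read off the document tokens
## (case-preserving).  Errors if the span does not resolve.
span_text <- function(document, mention) {
  toks <- do.call(rbind, document$sentences)
  sel <- which(
    (toks$line > mention$start_line |
       (toks$line == mention$start_line & toks$offset >= mention$start_offset)) &
    (toks$line < mention$end_line |
       (toks$line == mention$end_line & toks$offset <= mention$end_offset)))
  if (!length(sel)) {
    stop("mention span ", mention$start_line, ":", mention$start_offset,
         " .. ", mention$end_line, ":", mention$end_offset,
         " does not resolve in document ", document$doc_id)
  }
  paste(toks$text[sel], collapse = " ")
}

## ---------------------------------------------------------------------------
## BIO encoding / decoding
## ---------------------------------------------------------------------------

## token indices (within sentence) covered by a mention, integer(0) if none
mention_token_idx <- function(sentence, mention) {
  which(
    (sentence$line > mention$start_line |
       (sentence$line == mention$start_line &
          sentence$offset >= mention$start_offset)) &
    (sentence$line < mention$end_line |
       (sentence$line == mention$end_line &
          sentence$offset <= mention$end_offset)))
}

#' Encode mentions as a BIO label sequence
#'
#' The first token of each mention of field `x` is labeled `B-x`,
#' subsequent tokens `I-x`, and all other tokens `O`.
#'
#' @param sentence Sentence token data frame (columns `text`, `line`,
#'   `offset`).
#' @param ments Mention data frame; mentions outside the sentence are
#'   ignored, overlapping mentions within it are an error.
#' @return Character vector of BIO labels, one per token.
#' @export
encode_bio <- function(sentence, ments) {
  labels <- rep("O", nrow(sentence))
  if (is.null(ments) || nrow(ments) == 0L) return(labels)
  for (i in seq_len(nrow(ments))) {
    idx <- mention_token_idx(sentence, ments[i, ])
    if (!length(idx)) next
    if (any(labels[idx] != "O")) {
      stop("overlapping mentions in sentence at line ", sentence$line[idx[1]])
    }
    labels[idx] <- paste0("I-", ments$field[i])
    labels[idx[1]] <- paste0("B-", ments$field[i])
  }
  labels
}

#' Decode a BIO label sequence into mentions
#'
#' Maximal runs `B-x (I-x)*` become one mention of field `x`.  An `I-x`
#' whose predecessor is neither `B-x` nor `I-x` starts a new mention of `x`
#' (conlleval-compatible repair), so any label sequence decodes.
#'
#' @param sentence Sentence token data frame.
#' @param labels BIO labels aligned to the sentence's tokens.
#' @param doc_id Document id for the mentions (defaults to the sentence's
#'   `doc_id` attribute).
#' @return Mention data frame.
#' @export
decode_bio <- function(sentence, labels, doc_id = NULL) {
  if (length(labels) != nrow(sentence)) {
    stop("label sequence length ", length(labels),
         " does not match token count ", nrow(sentence))
  }
  if (is.null(doc_id)) doc_id <- attr(sentence, "doc_id")
  if (is.null(doc_id)) doc_id <- "doc"
  out <- empty_mentions()
  n <- length(labels)
  i <- 1L
  ev <- 0L
  while (i <= n) {
    if (labels[i] == "O") { i <- i + 1L; next }
    fld <- label_field(labels[i])
    j <- i
    while (j < n && labels[j + 1L] == paste0("I-", fld)) j <- j + 1L
    ev <- ev + 1L
    out <- rbind(out, mentions(
      doc_id, fld, sentence$line[i], sentence$offset[i],
      sentence$line[j], sentence$offset[j],
      paste(sentence$text[i:j], collapse = " "), ev))
    i <- j + 1L
  }
  out
}

#' Decode BIO labels for a whole document
#'
#' @param document A `ner_document`.
#' @param labels List of label vectors, one per sentence.
#' @return Mention data frame for the document.
#' @export
decode_bio_document <- function(document, labels) {
  stopifnot(length(labels) == length(document$sentences))
  out <- mapply(decode_bio, document$sentences, labels,
                MoreArgs = list(doc_id = document$doc_id), SIMPLIFY = FALSE)
  res <- do.call(rbind, c(out, list(empty_mentions())))
  if (nrow(res)) res$event <- seq_len(nrow(res))
  res
}

#' Encode gold mentions for a whole document
#'
#' @param document A `ner_document`.
#' @param ments Mention data frame for the document.
#' @return List of BIO label vectors, one per sentence.
#' @export
encode_bio_document <- function(document, ments) {
  lapply(document$sentences, encode_bio, ments = ments)
}
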