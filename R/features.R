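#' Feature configuration
#'
#' Switches for the six token feature families plus the label-bigram
#' (transition) feature, the context window half-width, and the maximum
#' affix length.  The default configuration enables everything, with the
#' \eqn{\pm 2} window and 3-character affixes used throughout the package.
#'
#' @param word,pos,morph,ortho,semantic,history,bigram Logical switches.
#'   `history` (previous predicted label) is consumed by the SVM tagger;
#'   `bigram` (label-transition features) by the CRF.
#' @param window Context half-width \eqn{w \ge 0}; windowed features are
#'   emitted for relative positions \eqn{-w \dots +w}.
#' @param affix_len Maximum prefix/suffix length \eqn{\ge 1}.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(word = TRUE, pos = TRUE, morph = TRUE,
                           ortho = TRUE, semantic = TRUE, history = TRUE,
                           bigram = TRUE, window = 2L, affix_len = 3L) {
  window <- as.integer(window); affix_len <- as.integer(affix_len)
  stopifnot(window >= 0L, affix_len >= 1L)
  structure(list(word = word, pos = pos, morph = morph, ortho = ortho,
                 semantic = semantic, history = history, bigram = bigram,
                 window = window, affix_len = affix_len),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  fams <- c("word", "pos", "morph", "ortho", "semantic", "history", "bigram")
  on <- fams[vapply(fams, function(f) isTRUE(x[[f]]), TRUE)]
  cat("<feature_config> families: ", paste(on, collapse = ", "),
      "; window +/-", x$window, "; affix<=", x$affix_len, "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize a feature configuration
#'
#' Flat `key=value` text format, one key per line.
#'
#' @param cfg A `feature_config`.
#' @param path File path.
#' @return `read_feature_config` returns a `feature_config`.
#' @export
write_feature_config <- function(cfg, path) {
  vals <- unclass(cfg)
  writeLines(paste0(names(vals), "=", vapply(vals, as.character, "")), path)
  invisible(path)
}

#' @rdname write_feature_config
#' @export
read_feature_config <- function(path) {
  kv <- strsplit(readLines(path, warn = FALSE), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  feature_config(
    word = as.logical(vals[["word"]]), pos = as.logical(vals[["pos"]]),
    morph = as.logical(vals[["morph"]]), ortho = as.logical(vals[["ortho"]]),
    semantic = as.logical(vals[["semantic"]]),
    history = as.logical(vals[["history"]]),
    bigram = as.logical(vals[["bigram"]]),
    window = as.integer(vals[["window"]]),
    affix_len = as.integer(vals[["affix_len"]]))
}

#' Prefixes and suffixes of a word
#'
#' All prefixes and suffixes of length 1 up to `min(max_len, nchar(word))`.
#'
#' @param word A non-empty token.
#' @param max_len Maximum affix length (default 3).
#' @return List with components `prefixes` and `suffixes`.
#' @export
#' @examples
#' affixes("Percocet", 3)
affixes <- function(word, max_len = 3L) {
  if (!is.character(word) || length(word) != 1L || !nzchar(word)) {
    stop("'word' must be a single non-empty string")
  }
  k <- seq_len(min(max_len, nchar(word)))
  list(prefixes = substring(word, 1L, k),
       suffixes = substring(word, nchar(word) - k + 1L, nchar(word)))
}

## The 21 orthographic categories, first match wins.  This ordered table is
## the package's normative definition of the orthography feature.
ORTHO_TABLE <- c(
  ALL_DIGITS    = "^[0-9]{3,}$",
  SINGLE_DIGIT  = "^[0-9]$",
  DOUBLE_DIGIT  = "^[0-9]{2}$",
  REAL_NUMBER   = "^[0-9]*[.,][0-9]+$",
  PERCENT       = "^[0-9]+([.,][0-9]+)?%$",
  RANGE         = "^[0-9]+-[0-9]+$",
  DIGIT_SLASH   = "^[0-9]+/[0-9]+$",
  ALPHA_DIGIT   = "^[A-Za-z]+[0-9][0-9A-Za-z]*$",
  DIGIT_ALPHA   = "^[0-9]+[A-Za-z]+$",
  DOTTED_ABBREV = "^([A-Za-z][.])+[A-Za-z]?[.]?$",
  ALL_CAPS      = "^[A-Z]{2,}$",
  INIT_CAP      = "^[A-Z][a-z]+$",
  ALL_LOWER     = "^[a-z]+$",
  MIXED_CASE    = "^[A-Za-z]+$",
  HYPHENATED    = "^[0-9A-Za-z]+(-[0-9A-Za-z]+)+$",
  SLASH_WORD    = "^[0-9A-Za-z.]+(/[0-9A-Za-z.]+)+$",
  PUNCT_ONLY    = "^[^0-9A-Za-z]+$",
  HAS_PAREN     = "[()]",
  ENDS_COMMA    = ",$",
  ENDS_PERIOD   = "[.]$",
  OTHER         = ""
)

#' Orthographic category names
#'
#' @return The 21 orthographic class names in match order.
#' @export
ortho_classes <- function() names(ORTHO_TABLE)

#' Orthographic class of a token
#'
#' Assigns exactly one of 21 surface-shape categories (digits, real
#' numbers, percentages, ranges, dotted abbreviations, capitalization
#' shapes, trailing punctuation, ...) by first match in a fixed order.
#'
#' @param word Character vector of non-empty tokens.
#' @return Character vector of category names.
#' @export
#' @examples
#' orthographic_class(c("100", "0.5%", "p.o.", "Percocet", "prn,"))
orthographic_class <- function(word) {
  if (any(!nzchar(word))) stop("tokens must be non-empty")
  out <- rep("OTHER", length(word))
  undecided <- rep(TRUE, length(word))
  for (cls in names(ORTHO_TABLE)) {
    if (cls == "OTHER") break
    hit <- undecided & grepl(ORTHO_TABLE[[cls]], word)
    out[hit] <- cls
    undecided <- undecided & !hit
    if (!any(undecided)) break
  }
  out
}

## ---------------------------------------------------------------------------
## Deterministic rule-based POS fallback tagger (~20 rules).  A generic
## trained tagger can be plugged into pos_tag(); the fallback keeps the
## pipeline dependency-free and reproducible.
## ---------------------------------------------------------------------------

POS_CLOSED <- list(
  DT  = c("the", "a", "an", "this", "that", "these", "those"),
  IN  = c("of", "in", "on", "for", "with", "by", "at", "to", "from",
          "until", "during", "as", "per", "after", "before"),
  CC  = c("and", "or", "but"),
  PRP = c("he", "she", "it", "they", "patient's"),
  MD  = c("should", "may", "can", "will", "must"),
  VBZ = c("is", "has", "takes", "needs"),
  VBD = c("was", "were", "had", "took", "received", "given"),
  VB  = c("take", "continue", "start", "stop", "hold", "give")
)

fallback_pos <- function(tokens) {
  n <- length(tokens)
  out <- character(n)
  low <- tolower(tokens)
  for (i in seq_len(n)) {
    w <- tokens[i]
    tag <- NA_character_
    for (t in names(POS_CLOSED)) {
      if (low[i] %in% POS_CLOSED[[t]]) { tag <- t; break }
    }
    if (is.na(tag)) {
      body <- gsub("[[:punct:]]", "", w)
      if (grepl("[0-9]", w) && !grepl("[A-Za-z]", body)) tag <- "CD"
      else if (!grepl("[0-9A-Za-z]", w)) tag <- w          # bare punctuation
      else if (grepl("^([A-Za-z][.])+[A-Za-z]?[.]?$", w)) tag <- "NN"
      else if (grepl("ly[[:punct:]]*$", low[i])) tag <- "RB"
      else if (grepl("ing[[:punct:]]*$", low[i]) && nchar(body) > 4) tag <- "VBG"
      else if (grepl("ed[[:punct:]]*$", low[i]) && nchar(body) > 3) tag <- "VBN"
      else if (grepl("[a-z]s[[:punct:]]*$", w) &&
               !grepl("(ss|us|is)[[:punct:]]*$", low[i])) tag <- "NNS"
      else if (i > 1L && grepl("^[A-Z]", w)) tag <- "NNP"
      else tag <- "NN"
    }
    out[i] <- tag
  }
  out
}

#' Part-of-speech tags for a sentence
#'
#' One POS label per token.  The default backend is the package's
#' deterministic rule tagger (closed-class word lists, digit patterns,
#' suffix heuristics, capitalization away from sentence-initial position);
#' any function mapping a token vector to a tag vector can be plugged in.
#'
#' @param sentence Sentence token data frame, or a character vector of
#'   tokens.
#' @param backend `NULL` for the built-in fallback, or
#'   `function(tokens) -> tags`.
#' @return Character vector of POS tags, one per token.
#' @export
pos_tag <- function(sentence, backend = NULL) {
  tokens <- if (is.data.frame(sentence)) sentence$text else sentence
  if (length(tokens) == 0L) return(character(0))
  if (is.null(backend)) return(fallback_pos(tokens))
  out <- tryCatch(backend(tokens),
                  error = function(e) stop("POS backend '",
                                           deparse(substitute(backend)),
                                           "' failed: ", conditionMessage(e)))
  if (length(out) != length(tokens)) {
    stop("POS backend returned ", length(out), " tags for ",
         length(tokens), " tokens")
  }
  out
}

## ---------------------------------------------------------------------------
## Windowed token features
## ---------------------------------------------------------------------------

## Per-token feature atoms for a sentence: a named list of character
## vectors/matrices reused across window offsets.
sentence_atoms <- function(sentence, semantic_tags, cfg, backend = NULL) {
  toks <- sentence$text
  n <- length(toks)
  atoms <- list()
  if (isTRUE(cfg$word)) atoms$word <- toks
  if (isTRUE(cfg$pos)) atoms$pos <- pos_tag(sentence, backend)
  if (isTRUE(cfg$ortho)) atoms$ortho <- orthographic_class(toks)
  if (isTRUE(cfg$semantic)) {
    if (is.null(semantic_tags)) semantic_tags <- rep("O", n)
    if (length(semantic_tags) != n) {
      stop("semantic_tags length ", length(semantic_tags),
           " does not match token count ", n)
    }
    atoms$sem <- semantic_tags
  }
  if (isTRUE(cfg$morph)) {
    ## matrix [2*affix_len x n]; rows pre1..preK, suf1..sufK; NA when longer
    ## than the word
    K <- cfg$affix_len
    aff <- matrix(NA_character_, nrow = 2L * K, ncol = n)
    rownames(aff) <- c(paste0("pre", seq_len(K)), paste0("suf", seq_len(K)))
    for (i in seq_len(n)) {
      a <- affixes(toks[i], K)
      k <- length(a$prefixes)
      aff[seq_len(k), i] <- a$prefixes
      aff[K + seq_len(k), i] <- a$suffixes
    }
    atoms$morph <- aff
  }
  atoms
}

## Features for every position of a sentence; returns a list (one element
## per token) of named character vectors (feature name -> value).
## history_labels: labels for positions 1..n-1 shifted right, i.e. the label
## to use as the history feature at each position ("" = compute nothing).
sentence_features <- function(sentence, semantic_tags = NULL,
                              cfg = feature_config(), history_labels = NULL,
                              backend = NULL) {
  n <- nrow(sentence)
  if (n == 0L) return(list())
  atoms <- sentence_atoms(sentence, semantic_tags, cfg, backend)
  w <- cfg$window
  any_window <- length(atoms) > 0L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- character(0); val <- character(0)
    for (d in seq.int(-w, w)) {
      j <- i + d
      tag <- sprintf("[%+d]", d)
      if (d == 0L) tag <- "[0]"
      if (j < 1L || j > n) {
        if (any_window) {
          nm <- c(nm, paste0("bnd", tag))
          val <- c(val, if (j < 1L) "__BOS__" else "__EOS__")
        }
        next
      }
      for (fam in names(atoms)) {
        if (fam == "morph") {
          aff <- atoms$morph[, j]
          ok <- !is.na(aff)
          nm <- c(nm, paste0(rownames(atoms$morph)[ok], tag))
          val <- c(val, aff[ok])
        } else {
          nm <- c(nm, paste0(fam, tag))
          val <- c(val, atoms[[fam]][j])
        }
      }
    }
    if (isTRUE(cfg$history)) {
      nm <- c(nm, "hist")
      val <- c(val, if (is.null(history_labels)) {
        "__BOS__"
      } else if (i == 1L) "__BOS__" else history_labels[i - 1L])
    }
    out[[i]] <- stats::setNames(val, nm)
  }
  out
}

#' Features for one token position
#'
#' Emits the windowed word / POS / affix / orthography / semantic-tag
#' features for position `i` of a sentence, each feature name carrying its
#' relative window offset, plus boundary markers for out-of-sentence
#' window positions and (if enabled) the history feature — the label
#' assigned at position `i - 1`.
#'
#' @param sentence Sentence token data frame.
#' @param i Token position (1-based).
#' @param semantic_tags Per-token semantic tags (from [rule_tag()]), or
#'   `NULL`.
#' @param prev_labels Labels already assigned to positions `< i` (used for
#'   the history feature), or `NULL`.
#' @param cfg A [feature_config()].
#' @return Named character vector: feature names to values.
#' @export
#' @examples
#' s <- tokenize("Percocet 1-2 Tablets p.o. Q 4 prn,")$sentences[[1]]
#' token_features(s, 1, cfg = feature_config(history = FALSE))
token_features <- function(sentence, i, semantic_tags = NULL,
                           prev_labels = NULL, cfg = feature_config()) {
  n <- nrow(sentence)
  if (i < 1L || i > n) stop("position ", i, " out of range 1..", n)
  sentence_features(sentence, semantic_tags, cfg,
                    history_labels = prev_labels)[[i]]
}

## feature strings "name=value" for learner consumption
feature_strings <- function(fv) paste(names(fv), fv, sep = "=")
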