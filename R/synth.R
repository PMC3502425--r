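## ---------------------------------------------------------------------------
## Seeded synthetic discharge-summary-like corpora with gold annotations.
## Sentences are instantiated from list-style templates ("Drugname 40 mg
## p.o. daily x10 days") and narrative templates ("The patient was given
## ... as needed for dizziness"), with per-field phrase inventories modeled
## on the surface forms typical of medication lists.  All randomness comes
## from R's default Mersenne-Twister generator under the configured seed.
## ---------------------------------------------------------------------------

## phrase inventories; each entry is a space-separated token phrase whose
## first token is the B- position.  `pattern_safe` marks the subset fully
## recoverable by the shipped default pattern rules / lexicon, used by the
## separable profile.
SYNTH_PHRASES <- list(
  do = list(
    pattern_safe = c("1 tab", "40 mg", "0.4 mg", "100 mg", "1-2 tablets",
                     "2 tabs", "5 ml", "0.5 mg", "2 puffs", "10 meq",
                     "one tablet", "two tablets", "3 drops", "25 mg",
                     "one capsule", "650 mg", "81 mg", "20 meq"),
    extra = c("100 mg x 2 tablets", "half tablet")),
  mo = list(
    pattern_safe = c("p.o.", "orally", "iv", "intravenously", "topically",
                     "sublingual", "by mouth", "subcutaneously", "inhaled",
                     "i.v.", "im"),
    extra = character(0)),
  f = list(
    pattern_safe = c("prn", "daily", "b.i.d.", "t.i.d.", "qhs", "bid",
                     "twice a day", "three times a day", "as needed",
                     "every 6 hours", "q 8 hours", "at bedtime",
                     "q 4 prn", "once a day", "every other day", "nightly"),
    extra = c("three times a day as needed", "x3 before meal")),
  du = list(
    pattern_safe = c("x10 days", "for ten days", "for a month", "x3 weeks",
                     "for 5 days", "10-day course", "for two weeks",
                     "x7 days", "for 14 days"),
    extra = c("as long as needed", "during spring break")),
  r = list(
    pattern_safe = c("dizziness", "fever", "nausea", "hypertension",
                     "insomnia", "cough", "anxiety", "constipation",
                     "agitation", "wheezing"),
    extra = c("back pain", "chest pain", "rare angina", "frequent pvcs"))
)

SYNTH_FILLER <- c("no", "acute", "events", "overnight", "stable", "on",
                  "current", "regimen", "tolerated", "well", "plan", "to",
                  "follow", "up", "in", "clinic", "next", "week", "vital",
                  "signs", "remained", "within", "normal", "limits")

SYNTH_SYLLABLES <- c("lor", "va", "met", "dex", "cor", "tri", "zol", "pan",
                     "flu", "car", "ami", "oxa", "pred", "nef", "tam", "bex",
                     "dal", "rin", "quo", "sel", "ond", "miv", "tra", "gly")
SYNTH_SUFFIXES <- c("ol", "ide", "ine", "ate", "pril", "olol", "micin",
                    "zole", "statin", "mab", "oxin", "asone")

#' Synthetic corpus configuration
#'
#' Conditions for the corpus generator.  The default per-sentence field
#' rates follow the class balance of a real medication-annotation corpus
#' profile (medication 1.318, dosage 0.494, mode 0.367, frequency 0.448,
#' duration 0.0616, reason 0.158 expected mentions per sentence), so
#' duration and reason are scarce — the hard cases.  Non-medication
#' fields are attached to medication events by Poisson thinning, so
#' `field_rates` for them must not exceed the medication rate.
#'
#' @param n_notes Number of notes.
#' @param sentences_per_note Range `c(min, max)` of sentences per note.
#' @param list_fraction Probability a sentence is list-style rather than
#'   narrative.
#' @param field_rates Named vector of expected mentions per sentence, in
#'   [field_codes()] order.
#' @param lexicon_size Number of generated drug names.
#' @param seed RNG seed.
#' @param profile `"default"` uses the full phrase inventories;
#'   `"separable"` restricts every inventory to phrases fully recoverable
#'   by the shipped rules and lexicon (and forces list style), giving a
#'   corpus on which the rule system is exact by construction.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_notes = 50L, sentences_per_note = c(3L, 8L),
                         list_fraction = 0.7,
                         field_rates = c(m = 1.318, do = 0.494, mo = 0.367,
                                         f = 0.448, du = 0.0616, r = 0.158),
                         lexicon_size = 120L, seed = 1L,
                         profile = c("default", "separable")) {
  profile <- match.arg(profile)
  stopifnot(n_notes >= 1L, all(field_rates >= 0),
            length(sentences_per_note) == 2L,
            list_fraction >= 0, list_fraction <= 1)
  if (is.null(names(field_rates))) names(field_rates) <- field_codes()
  stopifnot(setequal(names(field_rates), field_codes()))
  if (field_rates[["m"]] == 0 && any(field_rates[setdiff(field_codes(),
                                                         "m")] > 0)) {
    stop("non-medication field rates require a positive medication rate")
  }
  if (profile == "separable") list_fraction <- 1
  structure(list(n_notes = as.integer(n_notes),
                 sentences_per_note = as.integer(sentences_per_note),
                 list_fraction = list_fraction,
                 field_rates = field_rates[field_codes()],
                 lexicon_size = as.integer(lexicon_size),
                 seed = as.integer(seed), profile = profile),
            class = "synth_config")
}

## deterministic synthetic drug name inventory; ~10% two/three-token names
synth_drug_names <- function(n) {
  names_out <- character(0)
  while (length(names_out) < n) {
    k <- sample(2:3, 1)
    nm <- paste0(paste(sample(SYNTH_SYLLABLES, k, replace = TRUE),
                       collapse = ""),
                 sample(SYNTH_SUFFIXES, 1))
    if (stats::runif(1) < 0.10) {
      nm <- paste(nm, sample(c("xr", "sr", "plus d", "forte"), 1))
    }
    names_out <- unique(c(names_out, nm))
  }
  names_out[seq_len(n)]
}

phrase_pool <- function(fc, profile) {
  inv <- SYNTH_PHRASES[[fc]]
  if (profile == "separable") inv$pattern_safe
  else c(inv$pattern_safe, inv$extra)
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

## build one sentence; returns list(tokens, spans = data.frame(start, end,
## field, event))
synth_sentence <- function(cfg, drugs, style) {
  rates <- cfg$field_rates
  n_events <- stats::rpois(1, rates[["m"]])
  spans <- data.frame(start = integer(0), end = integer(0),
                      field = character(0), event = integer(0),
                      stringsAsFactors = FALSE)
  tokens <- character(0)
  add <- function(toks) {
    s <- length(tokens) + 1L
    tokens <<- c(tokens, toks)
    c(s, length(tokens))
  }
  if (n_events == 0L) {
    tokens <- sample(SYNTH_FILLER, sample(3:7, 1), replace = TRUE)
    return(list(tokens = tokens, spans = spans, style = style))
  }
  if (style == "narrative") {
    add(c("The", "patient", "was", "given"))
  }
  for (ev in seq_len(n_events)) {
    if (ev > 1L) add(if (style == "list") ";" else "and")
    drug <- sample(drugs, 1)
    dtoks <- strsplit(drug, " ", fixed = TRUE)[[1]]
    dtoks[1] <- cap_first(dtoks[1])
    sp <- add(dtoks)
    spans <- rbind(spans, data.frame(start = sp[1], end = sp[2],
                                     field = "m", event = ev,
                                     stringsAsFactors = FALSE))
    for (fc in c("do", "mo", "f", "du", "r")) {
      p <- min(1, rates[[fc]] / rates[["m"]])
      if (stats::runif(1) >= p) next
      phrase <- sample(phrase_pool(fc, cfg$profile), 1)
      toks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
      if (fc == "r") add("for")
      sp <- add(toks)
      spans <- rbind(spans, data.frame(start = sp[1], end = sp[2],
                                       field = fc, event = ev,
                                       stringsAsFactors = FALSE))
    }
  }
  if (style == "narrative") add(".")
  list(tokens = tokens, spans = spans, style = style)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic per seed.  Emits tokenized notes (one sentence per line,
#' blank lines between sentences, so [tokenize()] reconstructs the gold
#' segmentation exactly), gold mentions grouped by medication event with
#' list/narrative flags, and the generating lexicon (drug names as
#' medication entries plus the single-token reason inventory).
#'
#' @param cfg A [synth_config()].
#' @return List with `documents` (list of `ner_document`), `gold` (mention
#'   data frame with `event` and `ln` columns), `labels` (gold BIO labels,
#'   named list per document), and `lexicon` (a [lexicon()]).
#' @export
generate_corpus <- function(cfg = synth_config()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  drugs <- synth_drug_names(cfg$lexicon_size)
  documents <- vector("list", cfg$n_notes)
  labels <- vector("list", cfg$n_notes)
  gold <- list()
  for (d in seq_len(cfg$n_notes)) {
    doc_id <- sprintf("note%03d", d)
    nsent <- sample(cfg$sentences_per_note[1]:cfg$sentences_per_note[2], 1)
    lines <- c("DISCHARGE NOTE", "")
    doc_ments <- list()
    ev_base <- 0L
    sent_info <- vector("list", nsent)
    for (s in seq_len(nsent)) {
      style <- if (stats::runif(1) < cfg$list_fraction) "list" else
        "narrative"
      sent_info[[s]] <- synth_sentence(cfg, drugs, style)
      lines <- c(lines, paste(sent_info[[s]]$tokens, collapse = " "), "")
    }
    doc <- tokenize(lines, doc_id = doc_id)
    ## map generated spans onto the tokenized document (sentence 1 is the
    ## note header)
    stopifnot(length(doc$sentences) == 1L + sum(vapply(sent_info,
      function(x) length(x$tokens) > 0, TRUE)))
    si <- 1L
    for (s in seq_len(nsent)) {
      info <- sent_info[[s]]
      if (!length(info$tokens)) next
      si <- si + 1L
      sent <- doc$sentences[[si]]
      stopifnot(nrow(sent) == length(info$tokens))
      if (nrow(info$spans)) {
        sp <- info$spans
        doc_ments[[length(doc_ments) + 1L]] <- data.frame(
          doc_id = doc_id, field = sp$field,
          start_line = sent$line[sp$start], start_offset = sent$offset[sp$start],
          end_line = sent$line[sp$end], end_offset = sent$offset[sp$end],
          text = vapply(seq_len(nrow(sp)), function(i)
            paste(info$tokens[sp$start[i]:sp$end[i]], collapse = " "), ""),
          event = sp$event + ev_base,
          ln = if (info$style == "list") "list" else "narrative",
          stringsAsFactors = FALSE)
        ev_base <- ev_base + max(sp$event)
      }
    }
    documents[[d]] <- doc
    gm <- do.call(rbind, doc_ments)
    if (is.null(gm)) {
      gm <- empty_mentions(); gm$ln <- character(0)
    }
    gold[[d]] <- gm
    labels[[d]] <- encode_bio_document(doc, gm)
  }
  names(documents) <- vapply(documents, `[[`, "", "doc_id")
  names(labels) <- names(documents)
  gold <- do.call(rbind, gold)
  rownames(gold) <- NULL
  lex_entries <- c(stats::setNames(rep("m", length(drugs)), drugs),
                   stats::setNames(rep("r", length(SYNTH_PHRASES$r$pattern_safe)),
                                   SYNTH_PHRASES$r$pattern_safe))
  list(documents = documents, gold = gold, labels = labels,
       lexicon = lexicon(lex_entries), config = cfg)
}

#' Write a generated corpus to disk
#'
#' One `.txt` note and one `.ann` gold file per document, the generating
#' lexicon, and a manifest recording the configuration and seed.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus$documents) {
    writeLines(doc$lines, file.path(dir, paste0(doc$doc_id, ".txt")))
    write_annotations(corpus$gold[corpus$gold$doc_id == doc$doc_id, ,
                                  drop = FALSE],
                      file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  write_lexicon(corpus$lexicon, file.path(dir, "lexicon.tsv"))
  cfg <- corpus$config
  manifest <- c(paste0("n_notes=", cfg$n_notes),
                paste0("sentences_per_note=",
                       paste(cfg$sentences_per_note, collapse = ",")),
                paste0("list_fraction=", cfg$list_fraction),
                paste0("field_rates=",
                       paste(names(cfg$field_rates), cfg$field_rates,
                             sep = ":", collapse = ",")),
                paste0("lexicon_size=", cfg$lexicon_size),
                paste0("seed=", cfg$seed),
                paste0("profile=", cfg$profile))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Corruption configuration
#'
#' Error process applied to gold labels to simulate an imperfect system:
#' per-field mention deletion, boundary shifts of one token, field-type
#' confusion, and spurious insertions.
#'
#' @param deletion Per-field deletion probability (scalar or named
#'   vector).
#' @param boundary Per-field probability of a one-token boundary error.
#' @param confusion Either a scalar (probability of relabeling to a
#'   uniformly random other field) or a 6x6 row-stochastic-or-less matrix
#'   of type-confusion probabilities (rows = true field).
#' @param spurious Expected number of spurious mentions inserted per
#'   sentence.
#' @param seed RNG seed.
#' @return An object of class `corruption_config`.
#' @export
corruption_config <- function(deletion = 0, boundary = 0, confusion = 0,
                              spurious = 0, seed = 1L) {
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, 6), field_codes())
    }
    stopifnot(setequal(names(x), field_codes()), all(x >= 0), all(x <= 1))
    x[field_codes()]
  }
  if (is.matrix(confusion)) {
    stopifnot(dim(confusion) == c(6, 6), all(confusion >= 0),
              all(rowSums(confusion) <= 1))
    dimnames(confusion) <- list(field_codes(), field_codes())
    diag(confusion) <- 0
  } else {
    p <- confusion
    stopifnot(p >= 0, p <= 1)
    confusion <- matrix(p / 5, 6, 6,
                        dimnames = list(field_codes(), field_codes()))
    diag(confusion) <- 0
  }
  structure(list(deletion = expand(deletion), boundary = expand(boundary),
                 confusion = confusion, spurious = spurious,
                 seed = as.integer(seed)),
            class = "corruption_config")
}

## runs of non-O labels: data.frame(start, end, field)
label_runs <- function(labels) {
  ments <- data.frame(start = integer(0), end = integer(0),
                      field = character(0), stringsAsFactors = FALSE)
  n <- length(labels)
  i <- 1L
  while (i <= n) {
    if (labels[i] == "O") { i <- i + 1L; next }
    fld <- label_field(labels[i])
    j <- i
    while (j < n && labels[j + 1L] == paste0("I-", fld)) j <- j + 1L
    ments <- rbind(ments, data.frame(start = i, end = j, field = fld,
                                     stringsAsFactors = FALSE))
    i <- j + 1L
  }
  ments
}

corrupt_sentence <- function(labels, cfg) {
  n <- length(labels)
  runs <- label_runs(labels)
  out_runs <- list()
  for (k in seq_len(nrow(runs))) {
    r <- runs[k, ]
    if (stats::runif(1) < cfg$deletion[[r$field]]) next
    u <- stats::runif(1)
    cum <- cumsum(cfg$confusion[r$field, ])
    hit <- which(u < cum)
    if (length(hit)) r$field <- field_codes()[hit[1]]
    if (stats::runif(1) < cfg$boundary[[r$field]]) {
      ops <- character(0)
      if (r$start > 1L) ops <- c(ops, "start-")
      if (r$end < n) ops <- c(ops, "end+")
      if (r$end > r$start) ops <- c(ops, "start+", "end-")
      if (length(ops)) {
        op <- sample(ops, 1)
        r[if (startsWith(op, "start")) "start" else "end"] <-
          switch(op, `start-` = r$start - 1L, `start+` = r$start + 1L,
                 `end+` = r$end + 1L, `end-` = r$end - 1L)
      }
    }
    out_runs[[length(out_runs) + 1L]] <- r
  }
  ## spurious insertions into free space
  n_spur <- stats::rpois(1, cfg$spurious)
  occupied <- rep(FALSE, n)
  for (r in out_runs) occupied[r$start:r$end] <- TRUE
  for (k in seq_len(n_spur)) {
    free <- which(!occupied)
    if (!length(free)) break
    s <- if (length(free) == 1L) free else sample(free, 1)
    e <- if (s + 1L <= n && !occupied[min(s + 1L, n)] &&
             stats::runif(1) < 0.5) s + 1L else s
    out_runs[[length(out_runs) + 1L]] <-
      data.frame(start = s, end = e,
                 field = sample(field_codes(), 1),
                 stringsAsFactors = FALSE)
    occupied[s:e] <- TRUE
  }
  ## re-emit labels; later runs never overwrite earlier ones (boundary
  ## shifts may collide with a neighbor, in which case the earlier run wins)
  out <- rep("O", n)
  for (r in out_runs) {
    span <- r$start:r$end
    if (any(out[span] != "O")) next
    out[span] <- paste0("I-", r$field)
    out[span[1]] <- paste0("B-", r$field)
  }
  out
}

#' Corrupt gold labels into a simulated system output
#'
#' Applies the configured error process to every sentence's gold labels.
#' Accepts either a flat list of per-sentence label vectors or a nested
#' per-document list (as produced by [generate_corpus()]), and returns the
#' same shape.  Seeded once per call.
#'
#' @param labels Gold BIO labels: list of character vectors, or list of
#'   such lists.
#' @param cfg A [corruption_config()].
#' @return Corrupted labels, same shape as the input.
#' @export
corrupt_labels <- function(labels, cfg = corruption_config()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  nested <- length(labels) > 0L && is.list(labels[[1]])
  if (nested) {
    lapply(labels, function(doc) lapply(doc, corrupt_sentence, cfg = cfg))
  } else {
    lapply(labels, corrupt_sentence, cfg = cfg)
  }
}
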