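#' Voting configuration
#'
#' Three strategies for combining the per-token outputs of the rule-based,
#' SVM and CRF systems:
#' \describe{
#'   \item{majority}{the label at least two of the three systems agree on;
#'     with three-way disagreement, the label of the highest-ranked
#'     system.}
#'   \item{local_crf}{the CRF label wherever the CRF predicts one of the
#'     `local_fields` (duration/reason by default); the SVM label
#'     everywhere else.}
#'   \item{local_svm}{the mirror image: SVM for the local fields, CRF
#'     elsewhere.}
#' }
#'
#' @param strategy One of `"majority"`, `"local_crf"`, `"local_svm"`.
#' @param ranking Tie-break order of system ids for majority voting,
#'   highest first.
#' @param local_fields Field codes routed to the local system (default
#'   duration and reason).
#' @return An object of class `voting_config`.
#' @export
voting_config <- function(strategy = c("majority", "local_crf", "local_svm"),
                          ranking = c("crf", "svm", "rule"),
                          local_fields = c("du", "r")) {
  strategy <- match.arg(strategy)
  stopifnot(all(local_fields %in% field_codes()))
  structure(list(strategy = strategy, ranking = ranking,
                 local_fields = local_fields),
            class = "voting_config")
}

#' Majority vote over one token's labels
#'
#' The modal label when a strict majority exists; otherwise the label of
#' the highest-ranked system.
#'
#' @param labels Named character vector: one BIO label per system (names
#'   are system ids).
#' @param ranking System ids in rank order (highest first); must cover the
#'   systems in `labels`.
#' @return The winning label.
#' @export
#' @examples
#' vote_majority(c(rule = "B-m", svm = "B-m", crf = "O"))
vote_majority <- function(labels, ranking = c("crf", "svm", "rule")) {
  if (length(labels) < 2L) stop("majority voting needs at least 2 systems")
  if (is.null(names(labels))) names(labels) <- ranking[seq_along(labels)]
  tab <- table(labels)
  top <- max(tab)
  if (top > length(labels) / 2) return(names(tab)[tab == top][1])
  ranking <- ranking[ranking %in% names(labels)]
  unname(labels[ranking[1]])
}

#' Local (field-routed) vote for one token
#'
#' The primary system's label if it predicts one of the local fields
#' (either `B-` or `I-` variant); otherwise the fallback label.
#'
#' @param primary_label,fallback_label BIO labels.
#' @param local_fields Field codes owned by the primary system.
#' @return The winning label.
#' @export
#' @examples
#' vote_local("B-du", "B-m")   # routed to the primary system
#' vote_local("O", "B-m")      # falls back
vote_local <- function(primary_label, fallback_label,
                       local_fields = c("du", "r")) {
  fld <- label_field(primary_label)
  ifelse(!is.na(fld) & fld %in% local_fields, primary_label, fallback_label)
}

#' Repair a BIO sequence
#'
#' Rewrites every orphan `I-x` (one whose predecessor is neither `B-x` nor
#' `I-x`) to `B-x`, leaving all other labels unchanged.  The output always
#' decodes.
#'
#' @param labels A BIO label vector.
#' @return Repaired label vector.
#' @export
#' @examples
#' repair_bio(c("O", "I-du", "I-du"))
repair_bio <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(labels)
  fld <- label_field(labels)
  prev_fld <- c(NA_character_, fld[-n])
  prev_fld[1] <- NA_character_
  is_i <- startsWith(labels, "I-")
  orphan <- is_i & (is.na(prev_fld) | prev_fld != fld)
  labels[orphan] <- paste0("B-", fld[orphan])
  labels
}

## vectorized majority over three aligned label vectors, in ranking order
majority3 <- function(l1, l2, l3) {
  ## l1 is the highest-ranked system; any pairwise agreement wins,
  ## otherwise l1
  out <- l1
  out[l2 == l3] <- l2[l2 == l3]
  ## (l1 agreement cases already equal l1)
  out
}

#' Combine system outputs with a voting strategy
#'
#' Applies the configured per-token vote across aligned system outputs,
#' repairs the resulting BIO sequences, and decodes them to entity
#' mentions.
#'
#' @param outputs Named list of system outputs.  Each output is a list of
#'   per-sentence label vectors (one flat list, aligned across systems).
#'   Majority voting requires `rule`, `svm` and `crf`; the local
#'   strategies require `svm` and `crf`.
#' @param cfg A [voting_config()].
#' @param sentences Optional list of sentence data frames aligned to the
#'   outputs; when given, decoded mentions are returned as well.
#' @return List with `labels` (per-sentence vectors) and, when `sentences`
#'   is supplied, `mentions`.
#' @export
ensemble_predict <- function(outputs, cfg = voting_config(),
                             sentences = NULL) {
  need <- switch(cfg$strategy,
                 majority = c("rule", "svm", "crf"),
                 local_crf = c("svm", "crf"),
                 local_svm = c("svm", "crf"))
  if (!all(need %in% names(outputs))) {
    stop("strategy '", cfg$strategy, "' needs systems: ",
         paste(need, collapse = ", "))
  }
  lens <- lapply(outputs[need], lengths)
  for (k in seq_along(lens)[-1]) {
    if (!identical(lens[[1]], lens[[k]])) {
      stop("system outputs are not aligned (sentence lengths differ)")
    }
  }
  nsent <- length(outputs[[need[1]]])
  voted <- vector("list", nsent)
  for (s in seq_len(nsent)) {
    lab <- switch(cfg$strategy,
      majority = {
        r <- cfg$ranking[cfg$ranking %in% need]
        majority3(outputs[[r[1]]][[s]], outputs[[r[2]]][[s]],
                  outputs[[r[3]]][[s]])
      },
      local_crf = vote_local(outputs$crf[[s]], outputs$svm[[s]],
                             cfg$local_fields),
      local_svm = vote_local(outputs$svm[[s]], outputs$crf[[s]],
                             cfg$local_fields))
    voted[[s]] <- repair_bio(lab)
  }
  res <- list(labels = voted)
  if (!is.null(sentences)) {
    stopifnot(length(sentences) == nsent)
    ments <- mapply(function(sent, lab) decode_bio(sent, lab),
                    sentences, voted, SIMPLIFY = FALSE)
    res$mentions <- do.call(rbind, c(ments, list(empty_mentions())))
    if (nrow(res$mentions)) res$mentions$event <- seq_len(nrow(res$mentions))
  }
  res
}
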