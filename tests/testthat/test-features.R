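test_that("affixes returns all prefixes/suffixes up to the cap", {
  a <- affixes("Percocet", 3)
  expect_equal(a$prefixes, c("P", "Pe", "Per"))
  expect_equal(a$suffixes, c("t", "et", "cet"))
  b <- affixes("at", 3)
  expect_equal(b$prefixes, c("a", "at"))
  expect_equal(b$suffixes, c("t", "at"))
  expect_error(affixes(""), "non-empty")

  set.seed(7)
  for (rep in 1:100) {
    w <- paste(sample(c(letters, LETTERS, 0:9), sample.int(8, 1),
                      replace = TRUE), collapse = "")
    a <- affixes(w, 3)
    k <- min(3, nchar(w))
    expect_length(a$prefixes, k)
    expect_length(a$suffixes, k)
    expect_true(all(startsWith(w, a$prefixes)))
    expect_true(all(endsWith(w, a$suffixes)))
  }
})

test_that("orthographic classes cover the shipped examples and are total", {
  expect_equal(orthographic_class("100"), "ALL_DIGITS")
  expect_equal(orthographic_class("0.5%"), "PERCENT")
  expect_equal(orthographic_class("p.o."), "DOTTED_ABBREV")
  expect_equal(
    orthographic_class(c("5", "42", "0.5", "1-2", "1/2", "B12", "10mg",
                         "TYLENOL", "Percocet", "lasix", "mgKg", "x10",
                         "10-day", "mg/kg", ":", "(qd)", "prn,", "daily.")),
    c("SINGLE_DIGIT", "DOUBLE_DIGIT", "REAL_NUMBER", "RANGE", "DIGIT_SLASH",
      "ALPHA_DIGIT", "DIGIT_ALPHA", "ALL_CAPS", "INIT_CAP", "ALL_LOWER",
      "MIXED_CASE", "ALPHA_DIGIT", "HYPHENATED", "SLASH_WORD", "PUNCT_ONLY",
      "HAS_PAREN", "ENDS_COMMA", "ENDS_PERIOD"))
  expect_length(ortho_classes(), 21)

  set.seed(8)
  for (rep in 1:200) {
    w <- paste(sample(c(letters, LETTERS, 0:9, ".", ",", "-", "%", "/",
                        "(", ")"), sample.int(6, 1), replace = TRUE),
               collapse = "")
    cls <- orthographic_class(w)
    expect_length(cls, 1)
    expect_true(cls %in% ortho_classes())
    ## deterministic, single-valued
    expect_identical(orthographic_class(w), cls)
  }
  expect_error(orthographic_class(""), "non-empty")
})

test_that("the fallback POS tagger applies its rules deterministically", {
  expect_equal(pos_tag(c("Percocet", "1-2", "Tablets")),
               c("NN", "CD", "NNS"))
  expect_equal(pos_tag(character(0)), character(0))
  set.seed(9)
  for (rep in 1:50) {
    toks <- sample(RAND_VOCAB, sample.int(8, 1), replace = TRUE)
    expect_length(pos_tag(toks), length(toks))
  }
  ## pluggable backend, and its failures are attributed
  expect_equal(pos_tag(c("a", "b"), backend = function(t) rep("X", length(t))),
               c("X", "X"))
  expect_error(pos_tag(c("a", "b"), backend = function(t) stop("boom")),
               "failed")
  expect_error(pos_tag(c("a", "b"), backend = function(t) "X"), "2 tokens")
})

test_that("token features carry window offsets and boundary markers", {
  s <- tokenize("Percocet 1-2 Tablets p.o. Q 4 prn,")$sentences[[1]]
  fv <- token_features(s, 1, cfg = feature_config(history = FALSE))
  expect_equal(unname(fv["word[0]"]), "Percocet")
  expect_equal(unname(fv["word[+1]"]), "1-2")
  expect_equal(unname(fv["word[+2]"]), "Tablets")
  expect_equal(unname(fv["bnd[-1]"]), "__BOS__")
  expect_equal(unname(fv["bnd[-2]"]), "__BOS__")
  expect_false(anyDuplicated(names(fv)) > 0)

  minimal <- feature_config(word = TRUE, pos = FALSE, morph = FALSE,
                            ortho = FALSE, semantic = FALSE,
                            history = FALSE, bigram = FALSE, window = 0)
  fv0 <- token_features(s, 2, cfg = minimal)
  expect_equal(fv0, c(`word[0]` = "1-2"))
  expect_error(token_features(s, 0), "out of range")
  expect_error(token_features(s, 99), "out of range")
})

test_that("feature counts match an independent combinatorial census", {
  ## expected count computed independently: per in-window position, one
  ## feature per scalar family plus 2*min(affix_len, nchar) morph features;
  ## one marker per out-of-window position; plus the history feature.
  census <- function(sent, i, cfg) {
    n <- nrow(sent)
    total <- 0L
    fams <- sum(cfg$word, cfg$pos, cfg$ortho, cfg$semantic)
    any_fam <- cfg$word || cfg$pos || cfg$ortho || cfg$semantic || cfg$morph
    for (j in (i - cfg$window):(i + cfg$window)) {
      if (j < 1 || j > n) {
        total <- total + as.integer(any_fam)
      } else {
        total <- total + fams +
          if (cfg$morph) 2L * min(cfg$affix_len, nchar(sent$text[j])) else 0L
      }
    }
    total + as.integer(cfg$history)
  }
  set.seed(10)
  for (rep in 1:60) {
    doc <- tokenize(rand_note_lines(2), doc_id = "d")
    if (!length(doc$sentences)) next
    sent <- doc$sentences[[1]]
    cfg <- feature_config(word = runif(1) < .7, pos = runif(1) < .5,
                          morph = runif(1) < .5, ortho = runif(1) < .5,
                          semantic = runif(1) < .5, history = runif(1) < .5,
                          bigram = FALSE, window = sample(0:3, 1))
    i <- sample.int(nrow(sent), 1)
    fv <- token_features(sent, i, semantic_tags = rep("O", nrow(sent)),
                         cfg = cfg)
    expect_length(fv, census(sent, i, cfg))
    ## determinism
    expect_identical(
      token_features(sent, i, semantic_tags = rep("O", nrow(sent)),
                     cfg = cfg), fv)
  }
})

test_that("feature sets grow monotonically with enabled families", {
  s <- tokenize("Caltrate plus D 600 mg p.o. daily")$sentences[[1]]
  sem <- rep("O", nrow(s))
  small <- feature_config(word = TRUE, pos = FALSE, morph = FALSE,
                          ortho = FALSE, semantic = FALSE, history = FALSE)
  mid <- feature_config(word = TRUE, pos = TRUE, morph = TRUE,
                        ortho = FALSE, semantic = FALSE, history = FALSE)
  full <- feature_config(history = FALSE)
  for (i in seq_len(nrow(s))) {
    f1 <- token_features(s, i, sem, cfg = small)
    f2 <- token_features(s, i, sem, cfg = mid)
    f3 <- token_features(s, i, sem, cfg = full)
    expect_true(all(names(f1) %in% names(f2)))
    expect_true(all(names(f2) %in% names(f3)))
  }
})

test_that("feature configurations serialize to flat key-value files", {
  cfg <- feature_config(pos = FALSE, history = FALSE, window = 3,
                        affix_len = 2)
  path <- file.path(tempdir(), "fcfg.txt")
  write_feature_config(cfg, path)
  expect_equal(read_feature_config(path), cfg)
})
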