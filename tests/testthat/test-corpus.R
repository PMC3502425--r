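test_that("tokenization keeps punctuation attached and addresses tokens by line:offset", {
  doc <- tokenize("Percocet 1-2 Tablets p.o. Q 4 prn,")
  expect_equal(doc$sentences[[1]]$text,
               c("Percocet", "1-2", "Tablets", "p.o.", "Q", "4", "prn,"))
  expect_equal(doc$sentences[[1]]$line, rep(1L, 7))
  expect_equal(doc$sentences[[1]]$offset, 0:6)

  expect_length(tokenize("")$sentences, 0)

  doc3 <- tokenize(c("alpha beta", "", "gamma delta epsilon"))
  expect_length(doc3$sentences, 2)
  ## brute-force per-line splitter oracle for (line, offset)
  stream <- do.call(rbind, doc3$sentences)
  k <- 0L
  for (li in c(1L, 3L)) {
    toks <- bf_tokens(c("alpha beta", "", "gamma delta epsilon")[li])
    for (o in seq_along(toks)) {
      k <- k + 1L
      expect_equal(stream$text[k], toks[o])
      expect_equal(stream$line[k], li)
      expect_equal(stream$offset[k], o - 1L)
    }
  }
})

test_that("sentences break after a sentence-final period but not after dotted abbreviations", {
  ## period-terminated word followed by an uppercase start
  doc <- tokenize("Take daily. Continue Lasix")
  expect_length(doc$sentences, 2)
  expect_equal(doc$sentences[[1]]$text, c("Take", "daily."))
  ## dotted abbreviation followed by uppercase must not break
  doc2 <- tokenize("Percocet p.o. Q 4")
  expect_length(doc2$sentences, 1)
  ## period-terminated word at end of line breaks
  doc3 <- tokenize(c("took meds overnight.", "stable on exam"))
  expect_length(doc3$sentences, 2)
})

test_that("annotation lines parse to the expected mentions and malformed input errors", {
  line <- paste0('m="percocet" 10:0 10:0||do="1-2 tablets" 10:1 10:2||',
                 'mo="p.o." 10:3 10:3||f="q 4 prn," 10:4 10:6||',
                 'du="nm"||r="nm"||ln="list"')
  m <- parse_annotation_line(line)
  expect_equal(nrow(m), 4)
  expect_equal(m$field, c("m", "do", "mo", "f"))
  expect_equal(m$start_offset, c(0L, 1L, 3L, 4L))
  expect_equal(m$end_offset, c(0L, 2L, 3L, 6L))
  expect_true(all(m$start_line == 10L & m$end_line == 10L))
  expect_equal(attr(m, "ln"), "list")

  all_nm <- 'm="nm"||do="nm"||mo="nm"||f="nm"||du="nm"||r="nm"||ln="narrative"'
  expect_equal(nrow(parse_annotation_line(all_nm)), 0)

  expect_error(parse_annotation_line('q="bad" 1:0 1:0||ln="list"'),
               "column 1")
  expect_error(parse_annotation_line('m="drug" 1:x 1:0||ln="list"'),
               "column 1")
})

test_that("writing an event emits the dialect exactly and inverts parsing", {
  line <- paste0('m="percocet" 10:0 10:0||do="1-2 tablets" 10:1 10:2||',
                 'mo="p.o." 10:3 10:3||f="q 4 prn," 10:4 10:6||',
                 'du="nm"||r="nm"||ln="list"')
  m <- parse_annotation_line(line)
  expect_identical(write_annotation_line(m, "list"), line)
  expect_identical(
    write_annotation_line(m[0, ], "narrative"),
    'm="nm"||do="nm"||mo="nm"||f="nm"||du="nm"||r="nm"||ln="narrative"')
})

test_that("annotation write/parse is the identity on random mention groups", {
  set.seed(401)
  for (rep in 1:200) {
    fields <- sample(field_codes(), sample.int(6, 1))
    k <- length(fields)
    start <- sort(sample.int(40, k)) * 2L
    m <- mentions("doc", fields, sample.int(30, k, replace = TRUE),
                  start, sample.int(30, k, replace = TRUE),
                  start + sample.int(3, k, replace = TRUE) - 1L,
                  text = vapply(seq_len(k), function(i)
                    paste(sample(letters, 3), collapse = ""), ""),
                  event = 1L)
    flag <- sample(c("list", "narrative"), 1)
    back <- parse_annotation_line(write_annotation_line(m, flag))
    expect_equal(attr(back, "ln"), flag)
    ## writer emits in canonical field order
    m_sorted <- m[order(match(m$field, field_codes())), ]
    rownames(m_sorted) <- NULL
    back$event <- 1L
    expect_equal(back[, names(back) != "text"],
                 m_sorted[, names(m_sorted) != "text"])
    expect_equal(back$text, tolower(m_sorted$text))
  }
})

test_that("BIO encoding matches the worked example and rejects overlaps", {
  doc <- tokenize("Percocet 1-2 Tablets p.o. Q 4 prn,")
  s <- doc$sentences[[1]]
  g <- mentions("doc", c("m", "do", "mo", "f"), 1, c(0, 1, 3, 4),
                1, c(0, 2, 3, 6),
                c("Percocet", "1-2 Tablets", "p.o.", "Q 4 prn,"), 1:4)
  expect_equal(encode_bio(s, g),
               c("B-m", "B-do", "I-do", "B-mo", "B-f", "I-f", "I-f"))
  expect_equal(encode_bio(s, g[0, ]), rep("O", 7))
  overlap <- rbind(g, mentions("doc", "du", 1, 2, 1, 4, "x", 5))
  expect_error(encode_bio(s, overlap), "overlap")
})

test_that("BIO decoding inverts encoding and repairs orphan I- labels", {
  doc <- tokenize("Percocet 1-2 Tablets p.o. Q 4 prn,")
  s <- doc$sentences[[1]]
  m <- decode_bio(s, c("B-m", "B-do", "I-do", "B-mo", "B-f", "I-f", "I-f"))
  expect_equal(m$text, c("Percocet", "1-2 Tablets", "p.o.", "Q 4 prn,"))
  expect_equal(m$field, c("m", "do", "mo", "f"))
  expect_equal(nrow(decode_bio(s, rep("O", 7))), 0)

  s3 <- toy_sentence(c("a", "b", "c"))
  orphan <- decode_bio(s3, c("O", "I-du", "I-du"))
  expect_equal(nrow(orphan), 1)
  expect_equal(orphan$field, "du")
  expect_equal(orphan$start_offset, 1L)
  expect_equal(orphan$end_offset, 2L)
  expect_error(decode_bio(s3, c("O", "O")), "length")
})

test_that("encode/decode round-trips random planted mentions", {
  set.seed(402)
  for (rep in 1:150) {
    doc <- tokenize(rand_note_lines(), doc_id = "d")
    if (!length(doc$sentences)) next
    g <- rand_mentions_for_doc(doc)
    labs <- encode_bio_document(doc, g)
    expect_true(all(lengths(labs) ==
                      vapply(doc$sentences, nrow, 0L)))
    expect_true(all(unlist(labs) %in% bio_labels()))
    back <- decode_bio_document(doc, labs)
    if (nrow(g)) {
      expect_setequal(medner:::mention_key(back), medner:::mention_key(g))
      expect_setequal(back$text, g$text)
    } else {
      expect_equal(nrow(back), 0)
    }
  }
})

test_that("annotation files round-trip through disk with case restored from the document", {
  doc <- tokenize(c("Percocet 1-2 Tablets p.o. Q 4 prn,"), doc_id = "n1")
  g <- mentions("n1", c("m", "do"), 1, c(0, 1), 1, c(0, 2),
                c("Percocet", "1-2 Tablets"), 1)
  g$ln <- "list"
  path <- file.path(tempdir(), "n1.ann")
  write_annotations(g, path)
  back <- read_annotations(path, document = doc)
  expect_equal(back$text, g$text)  # case re-aligned from the note
  back_nodoc <- read_annotations(path)
  expect_equal(back_nodoc$text, tolower(g$text))
})
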