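test_that("read_pubtator parses blocks, splits composite IDs and validates spans", {
  path <- withr::local_tempfile()
  writeLines(c(
    "1|t|T",
    "1|a|A",
    "",
    "2|t|Lithium tremor study.",
    "2|a|Lithium induced tremor.",
    paste("2", "0", "7", "Lithium", "Chemical", "D016651", sep = "\t"),
    paste("2", "38", "44", "tremor", "Disease", "D014202|D020820", sep = "\t"),
    paste("2", "CID", "D016651", "D014202", sep = "\t"),
    ""), path)
  docs <- read_pubtator(path)
  expect_length(docs, 2L)
  expect_equal(docs[[1]]$doc_id, "1")
  expect_equal(nrow(docs[[1]]$mentions), 0L)
  expect_equal(nrow(docs[[1]]$relations), 0L)

  d <- docs[[2]]
  full <- doc_text(d)
  # substring-extraction oracle: every span reproduces its text field
  for (i in seq_len(nrow(d$mentions)))
    expect_identical(substr(full, d$mentions$start[i] + 1L, d$mentions$end[i]),
                     d$mentions$text[i])
  expect_identical(d$mentions$concept_ids[[2]], c("D014202", "D020820"))
  expect_identical(d$relations$chemical_id, "D016651")
})

test_that("malformed annotation lines and bad offsets raise informative errors", {
  path <- withr::local_tempfile()
  writeLines(c("9|t|T", "9|a|A",
               paste("9", "5", "2", "x", "Chemical", "D1", sep = "\t")), path)
  expect_error(read_pubtator(path), "line 3")

  writeLines(c("9|t|T", "9|a|A", "garbage line"), path)
  expect_error(read_pubtator(path), "line 3")

  writeLines(c("9|t|Title here.", "9|a|Abstract.",
               paste("9", "0", "5", "WRONG", "Chemical", "D1", sep = "\t")), path)
  expect_error(read_pubtator(path), "9")
})

test_that("PubTator write/read round trip is the identity", {
  fx <- cached_fixture()
  path <- withr::local_tempfile()
  write_pubtator(fx$docs, path)
  expect_identical(read_pubtator(path), fx$docs)

  write_pubtator(list(), path)
  expect_length(read_pubtator(path), 0L)

  d <- plant_doc("5", list(list("A ", ment("xx", "Disease", "D1"), "."),
                           list("Body.")))
  d$mentions$concept_ids <- I(list(c("D1", "D2")))
  write_pubtator(list(d), path)
  line <- grep("\t", readLines(path), value = TRUE)
  expect_match(line, "D1\\|D2$")
  expect_identical(read_pubtator(path)[[1]]$mentions$concept_ids[[1]],
                   c("D1", "D2"))
})

test_that("segmentation is deterministic with stable offsets", {
  d <- cdr_document("1", "A.", "B.")
  s <- segment(d)
  expect_length(s, 2L)
  expect_equal(s[[1]]$start, 0L)

  t1 <- tokenize("Lithium-induced tremor.")
  t2 <- tokenize("Lithium-induced tremor.")
  expect_identical(t1, t2)
  # hyphen splitting rule
  expect_identical(t1$text[1:3], c("Lithium", "-", "induced"))
  expect_true(all(substr(rep("Lithium-induced tremor.", nrow(t1)),
                         t1$start + 1L, t1$end) == t1$text))
})

test_that("stemmer and PoS tagger apply their documented rules", {
  expect_identical(stem_word(c("Tremors", "studies", "induced", "walking")),
                   c("tremor", "study", "induc", "walk"))
  expect_identical(pos_tag(c("the", "42", ",", "rapidly")),
                   c("DT", "CD", "PUNCT", "RB"))
})

test_that("encode_bio applies the tag scheme, snapping and overlap rules", {
  d <- plant_doc("1", list(list(ment("Lithium", "Chemical", "D1"),
                                " induced ", ment("tremor", "Disease", "D2"),
                                ".")))
  s <- segment(d)[[1]]
  expect_identical(encode_bio(s, d$mentions), c("B-C", "O", "B-D", "O"))
  expect_identical(encode_bio(s, empty_mentions()), rep("O", 4L))

  d2 <- plant_doc("2", list(list("Severe ",
                                 ment("hepatic failure", "Disease", "D3"),
                                 " occurred.")))
  s2 <- segment(d2)[[1]]
  expect_identical(encode_bio(s2, d2$mentions),
                   c("O", "B-D", "I-D", "O", "O"))

  # overlap resolution: longer wins, tie -> earlier
  m <- rbind(mention_table(0L, 15L, "Lithium induced", "Chemical", "D1"),
             mention_table(8L, 22L, "induced tremor", "Disease", "D2"))
  m$text <- substr(rep(doc_text(d), 2), m$start + 1, m$end)
  r <- resolve_overlaps(m)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 0L)
})

test_that("decode_bio repairs malformed sequences and inverts encode_bio", {
  d <- plant_doc("1", list(list(ment("Lithium", "Chemical", "D1"),
                                " induced ", ment("tremor", "Disease", "D2"),
                                ".")))
  s <- segment(d)[[1]]
  out <- decode_bio(s, c("B-C", "O", "B-D", "O"), doc_text(d))
  expect_equal(nrow(out), 2L)
  expect_identical(out$type, c("Chemical", "Disease"))
  expect_identical(out$text, c("Lithium", "tremor"))

  # stray I-* after O is repaired to B-*
  rep1 <- decode_bio(s, c("I-D", "O", "O", "O"), doc_text(d))
  expect_equal(nrow(rep1), 1L)
  expect_identical(rep1$type, "Disease")
  # type switch I-C after I-D starts a new mention
  rep2 <- decode_bio(s, c("B-D", "I-C", "O", "O"), doc_text(d))
  expect_equal(nrow(rep2), 2L)
})

test_that("BIO encode/decode round trip is the identity on fixture sentences", {
  fx <- cached_fixture()
  for (doc in fx$docs) {
    full <- doc_text(doc)
    for (s in segment(doc)) {
      inside <- doc$mentions[doc$mentions$start < s$end &
                               doc$mentions$end > s$start, , drop = FALSE]
      gold <- resolve_overlaps(inside)
      dec <- decode_bio(s, encode_bio(s, doc$mentions), full)
      expect_identical(dec$start, gold$start)
      expect_identical(dec$end, gold$end)
      expect_identical(dec$type, gold$type)
      expect_identical(dec$text, gold$text)
    }
  }
})
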