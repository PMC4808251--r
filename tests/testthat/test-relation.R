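# crafted two-chemical / two-disease document:
#   title:  X in review.                       (X mention)
#   s1:     X induced Y in patients.           (co-sentence true pair)
#   s2:     Z was measured at baseline.        (Z alone)
#   s3:     W was monitored.                   (W alone, distance 2 from s1)
crafted_doc <- function() {
  plant_doc("77", list(
    list(ment("aspirin", "Chemical", "C1"), " in review."),
    list(ment("aspirin", "Chemical", "C1"), " induced ",
         ment("tremor", "Disease", "E1"), " in patients."),
    list(ment("zyrtec", "Chemical", "C2"), " was measured at baseline."),
    list(ment("anemia", "Disease", "E2"), " was monitored.")),
    relation_table("C1", "E1"))
}

test_that("core chemicals are title chemicals plus most-frequent chemicals", {
  d <- crafted_doc()
  expect_identical(detect_core_chemicals(d), "C1")

  # two chemicals tied on counts, neither in the title -> both core
  d2 <- plant_doc("78", list(
    list("A review."),
    list(ment("aaa", "Chemical", "C1"), " and ",
         ment("bbb", "Chemical", "C2"), " were given.")))
  expect_setequal(detect_core_chemicals(d2), c("C1", "C2"))

  d3 <- plant_doc("79", list(list("Nothing here."), list("Still nothing.")))
  expect_identical(detect_core_chemicals(d3), character())
})

test_that("candidate generation filters by level and drops -1", {
  d <- crafted_doc()
  doc_pairs <- generate_candidates(d, "document")
  expect_length(doc_pairs, 4L)   # {C1,C2} x {E1,E2}
  sent_pairs <- generate_candidates(d, "sentence")
  expect_length(sent_pairs, 1L)
  expect_identical(sent_pairs[[1]]$chemical_id, "C1")
  expect_identical(sent_pairs[[1]]$disease_id, "E1")
  expect_equal(sent_pairs[[1]]$min_sentence_distance, 0L)

  d_neg <- plant_doc("80", list(
    list(ment("mystery", "Chemical", "-1"), " and ",
         ment("tremor", "Disease", "E1"), " appeared.")))
  expect_length(generate_candidates(d_neg, "document"), 0L)

  # brute-force oracle on fixture documents
  fx <- cached_fixture()
  for (doc in fx$docs[1:6]) {
    ids <- function(t) unique(unlist(
      doc$mentions$concept_ids[doc$mentions$type == t]))
    chems <- setdiff(ids("Chemical"), "-1")
    diss <- setdiff(ids("Disease"), "-1")
    expect_length(generate_candidates(doc, "document"),
                  length(chems) * length(diss))
  }
})

test_that("sentence label projection equals co-sentence pairs intersected with gold", {
  fx <- cached_fixture()
  for (doc in fx$docs) {
    insts <- project_sentence_labels(doc)
    true_keys <- unique(vapply(
      Filter(function(i) isTRUE(i$label), insts),
      function(i) paste(i$chemical_id, i$disease_id), ""))
    co_keys <- vapply(generate_candidates(doc, "sentence"),
                      function(p) paste(p$chemical_id, p$disease_id), "")
    gold_keys <- paste(doc$relations$chemical_id, doc$relations$disease_id)
    expect_setequal(true_keys, intersect(co_keys, gold_keys))
  }
})

test_that("C_S features anchor the closest pair and read the between words", {
  d <- crafted_doc()
  p <- generate_candidates(d, "sentence")[[1]]
  f <- sentence_pair_features(p, d)
  expect_true("ctx:between=induced" %in% names(f))
  expect_true("ctx:terms_i" %in% names(f))
  expect_true("ent:chem_first" %in% names(f))
  expect_true("ctx:terms_h" %in% names(f))   # "patients" in the sentence
  expect_true("ent:core_chem" %in% names(f))
  expect_true(all(c("ent:cid=C1", "ent:did=E1") %in% names(f)))
  expect_identical(f, sentence_pair_features(p, d))  # byte-identical reruns

  doc_only <- generate_candidates(d, "document")
  far <- Filter(function(q) q$disease_id == "E2" && q$chemical_id == "C2",
                doc_only)[[1]]
  expect_error(sentence_pair_features(far, d), "co-sentence")
})

test_that("C_D positional one-hots partition and gate the holder feature", {
  d <- crafted_doc()
  pairs <- generate_candidates(d, "document")
  key <- vapply(pairs, function(p) paste(p$chemical_id, p$disease_id), "")
  f_adj <- document_pair_features(pairs[[match("C2 E2", key)]], d)  # s2 vs s3
  expect_true("ctx:adjacent" %in% names(f_adj))
  f_same <- document_pair_features(pairs[[match("C1 E1", key)]], d)
  expect_true("ctx:same_sentence" %in% names(f_same))
  expect_true("ctx:terms_i" %in% names(f_same))

  # distance >= 2: holder term never fires even when present
  d2 <- plant_doc("81", list(
    list("A study."),
    list(ment("aaa", "Chemical", "C1"), " was given."),
    list("Filler sentence one."),
    list("Filler sentence two."),
    list("The patients developed ", ment("anemia", "Disease", "E1"), ".")))
  p2 <- generate_candidates(d2, "document")[[1]]
  expect_gte(p2$min_sentence_distance, 2L)
  f2 <- document_pair_features(p2, d2)
  expect_true("ctx:distant" %in% names(f2))
  expect_false("ctx:terms_h" %in% names(f2))

  # exactly one positional feature per document-level pair, corpus-wide
  fx <- cached_fixture()
  for (doc in fx$docs[1:8]) {
    for (p in generate_candidates(doc, "document")) {
      f <- document_pair_features(p, doc, fx$kb)
      expect_equal(sum(c("ctx:same_sentence", "ctx:adjacent", "ctx:distant")
                       %in% names(f)), 1L)
    }
  }
})

test_that("relation models fit a separable corpus and are deterministic", {
  fx <- cached_fixture(seed = 7, n_docs = 30)
  m1 <- train_relation_models(fx$docs, fx$kb)
  pred <- lapply(fx$docs, function(d) {
    d2 <- d
    d2$relations <- predict_relations(m1, d, fx$kb)
    d2
  })
  expect_gte(eval_cid(fx$docs, pred)$f1, 0.95)

  m2 <- train_relation_models(fx$docs, fx$kb)
  expect_identical(m1$cs$svm$tot.nSV, m2$cs$svm$tot.nSV)
  expect_identical(m1$cd$svm$tot.nSV, m2$cd$svm$tot.nSV)

  no_rel <- lapply(fx$docs, function(d) {
    d$relations <- relation_table()
    d
  })
  expect_error(train_relation_models(no_rel, fx$kb), "zero positive")
})

test_that("union predictions contain both classifier outputs", {
  fx <- cached_fixture(seed = 7, n_docs = 30)
  m <- train_relation_models(fx$docs[1:25], fx$kb)
  for (doc in fx$docs[26:30]) {
    key <- function(r) paste(r$chemical_id, r$disease_id)
    cs <- key(predict_relations(m, doc, fx$kb, strategy = "cs"))
    cd <- key(predict_relations(m, doc, fx$kb, strategy = "cd"))
    un <- key(predict_relations(m, doc, fx$kb, strategy = "union"))
    expect_true(all(cs %in% un))
    expect_true(all(cd %in% un))
    expect_setequal(un, union(cs, cd))
  }
  # a document with no co-sentence pairs: CS is empty, union == CD
  d <- plant_doc("90", list(
    list("A study."),
    list(ment("aaa", "Chemical", "C1"), " was given."),
    list(ment("anemia", "Disease", "E1"), " was seen.")))
  expect_equal(nrow(predict_relations(m, d, fx$kb, strategy = "cs")), 0L)
  expect_identical(predict_relations(m, d, fx$kb, strategy = "union"),
                   predict_relations(m, d, fx$kb, strategy = "cd"))
})
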