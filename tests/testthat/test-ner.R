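sent_of <- function(text) segment(cdr_document("1", text))[[1]]

test_that("word features cover shape, affixes and character n-grams", {
  # shape mapping: upper -> A, lower -> a, digit -> 0, others kept
  expect_identical(case_shape("Ca2+"), "Aa0+")
  s <- sent_of("Severe pain x")
  f1 <- word_features(s, 1)
  expect_true("shape=Aaaaaa" %in% names(f1))
  expect_true("w=severe" %in% names(f1))
  f2 <- word_features(s, 2)
  sufs <- sub("^suf=", "", grep("^suf=", names(f2), value = TRUE))
  expect_setequal(sufs, c("n", "in", "ain", "pain"))
  f3 <- word_features(s, 3)
  expect_identical(grep("^pre=", names(f3), value = TRUE), "pre=x")
  expect_identical(grep("^suf=", names(f3), value = TRUE), "suf=x")
  # purity: identical call -> identical map
  expect_identical(word_features(s, 1), word_features(s, 1))
})

test_that("dictionary tagging is greedy longest-match", {
  lex <- ner_lexicon(c("blood pressure" = "disorder", "blood" = "substance"))
  s <- sent_of("blood pressure rose")
  expect_identical(dict_features(s, lex), c("B-disorder", "I-disorder", "NONE"))
  expect_identical(dict_features(s, ner_lexicon(character())),
                   rep("NONE", 3L))

  # planted-term recovery
  set.seed(9)
  vocab <- c("aa", "bb", "cc", "dd", "ee", "ff", "gg")
  for (k in 1:25) {
    term <- paste(sample(vocab, 2), collapse = " ")
    lex <- ner_lexicon(stats::setNames("disorder", term))
    filler <- paste(sample(c("xx", "yy", "zz"), 3, replace = TRUE), collapse = " ")
    s <- sent_of(paste(filler, term, "qq"))
    tags <- dict_features(s, lex)
    expect_identical(tags[4:5], c("B-disorder", "I-disorder"))
    expect_true(all(tags[-(4:5)] == "NONE"))
  }
})

test_that("context n-grams use boundary symbols and have closed-form counts", {
  s <- sent_of("alpha beta gamma")
  f <- context_features(s, 1)
  left <- grep("ctx:w:-2,-1=", names(f), value = TRUE)
  expect_identical(left, "ctx:w:-2,-1=<S>|<S>")
  f2 <- context_features(s, 2)
  expect_true(all(c("ctx:w:-1,0=alpha|beta", "ctx:w:0,1=beta|gamma") %in%
                    names(f2)))
  # count = streams * (bigrams + trigrams) as a function of window size
  set.seed(2)
  for (w in 1:3) {
    n_off <- 2 * w + 1
    expected <- 4 * ((n_off - 1) + (n_off - 2))
    txt <- paste(sample(letters, 8), collapse = " ")
    ss <- sent_of(txt)
    for (i in c(1, 4, 8))
      expect_length(context_features(ss, i, window = w), expected)
  }
})

test_that("domain affix and chemical-pattern flags fire as documented", {
  expect_true("has_disease_suffix" %in%
                names(domain_affix_features("hypokalemia")))
  expect_true("has_disease_prefix" %in%
                names(domain_affix_features("hemoglobin")))
  expect_length(domain_affix_features("table"), 0L)
  f <- domain_affix_features("CaCl2")
  expect_true("formula_like" %in% names(f))
  expect_equal(unname(f["n_digits"]), 1)
  expect_equal(unname(f["n_upper"]), 2)
})

test_that("embedding features are real-valued with zero OOV contribution", {
  path <- withr::local_tempfile()
  writeLines(c("2 2", "aspirin 0.5 -1.0", "tremor 0.5 -1.0"), path)
  tab <- read_embeddings(path)
  f <- embedding_features("Aspirin", tab)
  expect_equal(f, c(emb_0 = 0.5, emb_1 = -1.0))
  expect_identical(embedding_features("zzz", tab), numeric(0))
  expect_identical(embedding_features("aspirin", tab),
                   embedding_features("tremor", tab))
  writeLines(c("1 3", "aspirin 0.5 -1.0"), path)
  expect_error(read_embeddings(path), "dimension")
})

test_that("unified CRF fits its training corpus and is deterministic", {
  fx <- cached_fixture()
  cfg <- ner_config(mode = "unified", max_iter = 80)
  m <- train_ner(fx$docs, cfg, lexicon = fx$lexicon)
  pred <- lapply(fx$docs, function(d)
    cdr_document(d$doc_id, d$title, d$abstract, predict_mentions(m, d)))
  for (et in c("Chemical", "Disease")) {
    r <- eval_mention_level(fx$docs, pred, et)
    expect_gte(r$f1, 0.95)
  }
  # mention invariant on predictions
  for (d in pred)
    expect_silent(cdr_document(d$doc_id, d$title, d$abstract, d$mentions))

  m2 <- train_ner(fx$docs, cfg, lexicon = fx$lexicon)
  pred2 <- lapply(fx$docs, function(d)
    cdr_document(d$doc_id, d$title, d$abstract, predict_mentions(m2, d)))
  expect_identical(pred, pred2)
})

test_that("separate mode trains two type-pure models and merges overlaps", {
  fx <- cached_fixture()
  cfg <- ner_config(mode = "separate", max_iter = 60)
  m <- train_ner(fx$docs[1:6], cfg, lexicon = fx$lexicon)
  expect_named(m$models, c("chemical", "disease"))
  expect_setequal(m$models$chemical$labels, c("B-C", "I-C", "O"))
  expect_setequal(m$models$disease$labels, c("B-D", "I-D", "O"))
  p <- predict_mentions(m, fx$docs[[1]])
  # merged predictions contain no span overlap
  if (nrow(p) > 1L) {
    for (i in 2:nrow(p)) expect_gte(p$start[i], p$end[i - 1L])
  }
})

test_that("training runs with only bag-of-word features and errors on empty input", {
  fx <- cached_fixture()
  cfg <- ner_config(mode = "unified", use_word = FALSE, use_dict = FALSE,
                    use_context = FALSE, use_affix = FALSE,
                    use_embedding = FALSE, max_iter = 40)
  m <- train_ner(fx$docs[1:4], cfg)
  p <- predict_mentions(m, fx$docs[[1]])
  expect_s3_class(p, "data.frame")
  expect_error(train_ner(list(), cfg), "empty")

  d0 <- cdr_document("1", "Title only.")
  full_model <- train_ner(fx$docs[1:4], ner_config(mode = "unified",
                                                   max_iter = 40))
  expect_s3_class(predict_mentions(full_model, d0), "data.frame")
})
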