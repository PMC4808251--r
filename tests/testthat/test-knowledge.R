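retro_tree <- mesh_tree(list(
  D008569 = "C10.597.606.525.100",        # amnesia
  D000648 = "C10.597.606.525.100.150",    # retrograde amnesia
  D003072 = c("C10.1", "C20.2"),
  D999001 = "C10.597"))

test_that("hypernym_codes enumerates all proper prefixes, shortest first", {
  expect_identical(hypernym_codes("C10.597.606.525.100"),
                   c("C10", "C10.597", "C10.597.606", "C10.597.606.525"))
  expect_identical(hypernym_codes("C10"), character())
  expect_error(hypernym_codes("C10..597"), "malformed")

  set.seed(42)
  for (k in 1:20) {
    parts <- sprintf("%03d", sample(999, sample(2:6, 1)))
    tn <- paste(parts, collapse = ".")
    # brute-force split oracle
    oracle <- vapply(seq_len(length(parts) - 1L), function(j)
      paste(parts[1:j], collapse = "."), "")
    expect_identical(hypernym_codes(tn), oracle)
    expect_length(hypernym_codes(tn), length(parts) - 1L)
  }
})

test_that("concept_categories unions hypernyms over all tree numbers", {
  expect_identical(concept_categories("D008569", retro_tree),
                   hypernym_codes("C10.597.606.525.100"))
  expect_setequal(concept_categories("D003072", retro_tree), c("C10", "C20"))
  expect_warning(out <- concept_categories("D404", retro_tree), "unknown")
  expect_length(out, 0L)

  fx <- cached_fixture()
  tree <- fx$mesh$tree
  for (id in sample(names(tree), 10)) {
    oracle <- unique(unlist(lapply(tree[[id]], hypernym_codes)))
    expect_setequal(concept_categories(id, tree),
                    if (is.null(oracle)) character() else oracle)
  }
})

test_that("is_more_specific follows the proper-prefix rule", {
  expect_true(is_more_specific("D000648", "D008569", retro_tree))
  expect_false(is_more_specific("D008569", "D000648", retro_tree))
  expect_false(is_more_specific("D008569", "D008569", retro_tree))
  sib <- mesh_tree(list(a = "C10.1", b = "C10.2"))
  expect_false(is_more_specific("a", "b", sib))
  expect_false(is_more_specific("zz", "D008569", retro_tree))

  # antisymmetry + chain transitivity on the fixture hierarchy
  tree <- cached_fixture()$mesh$tree
  ids <- sample(names(tree), 12)
  for (a in ids) for (b in ids) {
    if (is_more_specific(a, b, tree)) expect_false(is_more_specific(b, a, tree))
  }
  chain <- names(tree)[vapply(tree, function(t)
    startsWith(t[1], "C01") && length(strsplit(t[1], ".", fixed = TRUE)[[1]]) <= 3, TRUE)]
  chain <- chain[order(nchar(unlist(tree[chain])))]
  if (length(chain) >= 3) {
    deep <- chain[length(chain)]
    expect_true(is_more_specific(deep, chain[1], tree) ||
                  !is_more_specific(deep, chain[2], tree))
  }
})

test_that("disease_specificity_flags match a pairwise brute-force check", {
  flags <- disease_specificity_flags("D008569", c("D008569", "D000648"), retro_tree)
  expect_true(flags[["has_more_specific"]])
  expect_false(flags[["has_more_general"]])
  flags2 <- disease_specificity_flags("D000648", c("D008569", "D000648"), retro_tree)
  expect_false(flags2[["has_more_specific"]])
  expect_true(flags2[["has_more_general"]])
  expect_identical(unname(disease_specificity_flags("D008569", "D008569", retro_tree)),
                   c(FALSE, FALSE))

  tree <- cached_fixture()$mesh$tree
  set.seed(3)
  for (k in 1:10) {
    ids <- sample(names(tree), 6)
    for (target in ids) {
      got <- disease_specificity_flags(target, ids, tree)
      oth <- setdiff(ids, target)
      expect_equal(got[["has_more_specific"]],
                   any(vapply(oth, is_more_specific, TRUE, target, tree)))
      expect_equal(got[["has_more_general"]],
                   any(vapply(oth, function(o) is_more_specific(target, o, tree), TRUE)))
    }
  }
})

test_that("KB lookups are exact, directed and label-checked", {
  ctd <- kb_table(data.frame(chemical_id = c("C1", "C2"),
                             disease_id = c("D1", "D2"),
                             label = c("marker/mechanism", "therapeutic")),
                  "CTD")
  expect_identical(kb_relation("C1", "D1", ctd), "marker/mechanism")
  expect_null(kb_relation("C1", "D2", ctd))
  expect_null(kb_relation("D1", "C1", ctd))   # reversed pair is absent
  expect_error(kb_table(data.frame(chemical_id = "C1", disease_id = "D1",
                                   label = "treatment"), "CTD"),
               "alphabet")

  sider <- kb_table(data.frame(chemical_id = c("C1", "C2", "C3"),
                               disease_id = c("D1", "D1", "D2"),
                               label = c("treatment", "adverse-drug-reaction",
                                         "treatment")),
                    "SIDER")
  expect_true(is_adr("D1", sider))
  expect_false(is_adr("D2", sider))
  expect_true(is_induced("D1", ctd))
  expect_false(is_induced("D2", ctd))

  # linear-scan oracle on the fixture tables
  fx <- cached_fixture()
  for (d in unique(fx$kb$sider$pairs$disease_id)) {
    oracle <- any(fx$kb$sider$pairs$label[fx$kb$sider$pairs$disease_id == d] ==
                    "adverse-drug-reaction")
    expect_equal(is_adr(d, fx$kb$sider), oracle)
  }
  for (d in unique(fx$kb$ctd$pairs$disease_id)) {
    oracle <- any(fx$kb$ctd$pairs$label[fx$kb$ctd$pairs$disease_id == d] ==
                    "marker/mechanism")
    expect_equal(is_induced(d, fx$kb$ctd), oracle)
  }
})

test_that("tree and trigger files round trip through their TSV dialects", {
  dir <- withr::local_tempdir()
  writeLines(c("D1\tC10.1|C20.2", "D2\tC10.1.100"),
             file.path(dir, "tree.tsv"))
  tr <- read_mesh_tree(file.path(dir, "tree.tsv"))
  expect_identical(tr[["D1"]], c("C10.1", "C20.2"))
  expect_true(is_more_specific("D2", "D1", tr))

  writeLines(c("caused", "induced"), file.path(dir, "ti.txt"))
  writeLines(c("patients"), file.path(dir, "th.txt"))
  tg <- read_triggers(file.path(dir, "ti.txt"), file.path(dir, "th.txt"))
  expect_identical(tg$terms_i, c("caused", "induced"))
  expect_identical(tg$terms_h, "patients")
})
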