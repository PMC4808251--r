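# Seeded synthetic fixtures: a toy MeSH-like concept dictionary and tree,
# knowledge-base tables consistent with the planted relations, trigger and
# semantic lexicons, a small embedding file, and PubTator corpora with
# planted, recoverable chemical-induced disease relations.
#
# Everything is a deterministic function of (spec, seed): generators save
# and restore the global RNG state and reseed from the spec, so the same
# spec always yields byte-identical artifacts.

#' Fixture specification
#'
#' @param seed integer master seed; together with the other fields it fully
#'   determines every generated artifact.
#' @param n_docs number of abstracts.
#' @param n_chemicals,n_diseases dictionary sizes (diseases are arranged in
#'   a rooted hierarchy of the given depth/branching; `n_diseases` must not
#'   exceed the node count of that tree).
#' @param tree_depth,tree_branching disease hierarchy shape.
#' @param cross_sentence_frac fraction of planted true relations rendered
#'   across sentence boundaries (mirroring the roughly 30% of relations
#'   that real abstracts express outside a single sentence).
#' @param distractor_rate probability of inserting an entity-free filler
#'   sentence between content blocks.
#' @param synonym_rate probability that a mention is rendered with a
#'   synonym rather than the preferred name.
#' @param unnorm_rate probability per document of injecting a mention whose
#'   surface form is absent from the dictionary (gold concept ID `"-1"`).
#' @param ctd_true_share share of planted true pairs recorded in the CTD
#'   table as `marker/mechanism`.
#' @param ctd_false_share share of planted false co-occurrence pairs
#'   recorded in CTD as `therapeutic`.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_docs = 20L, n_chemicals = 25L,
                         n_diseases = 30L, tree_depth = 3L,
                         tree_branching = 3L, cross_sentence_frac = 0.3,
                         distractor_rate = 0.3, synonym_rate = 0.3,
                         unnorm_rate = 0.05, ctd_true_share = 0.7,
                         ctd_false_share = 0.5) {
  stopifnot(n_docs >= 1L, n_chemicals >= 1L, n_diseases >= 1L,
            tree_depth >= 1L, tree_branching >= 1L,
            cross_sentence_frac >= 0, cross_sentence_frac <= 1,
            distractor_rate >= 0, distractor_rate <= 1,
            synonym_rate >= 0, synonym_rate <= 1,
            unnorm_rate >= 0, unnorm_rate <= 1)
  n_nodes <- sum(tree_branching^seq_len(tree_depth))
  if (n_diseases > n_nodes)
    stop("n_diseases exceeds the ", n_nodes, " nodes of the disease tree")
  structure(as.list(environment())[c(
    "seed", "n_docs", "n_chemicals", "n_diseases", "tree_depth",
    "tree_branching", "cross_sentence_frac", "distractor_rate",
    "synonym_rate", "unnorm_rate", "ctd_true_share", "ctd_false_share")],
    class = "fixture_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

.chem_names <- function() {
  g <- expand.grid(pre = c("flu", "chlor", "meth", "pro", "dex",
                           "zol", "tri", "oxa", "ver", "lam"),
                   mid = c("pro", "xi", "ral", "ben", "tol", "vir", "mi", "do"),
                   suf = c("ine", "ol", "ide", "ate", "pam", "stat"),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  unique(paste0(g$pre, g$mid, g$suf))
}

.dis_bases <- function() {
  g <- expand.grid(root = c("card", "neur", "hepat", "nephr", "gastr",
                            "arthr", "oste", "pulm", "derm", "cephal"),
                   suf = c("algia", "itis", "emia", "osis", "opathy", "oma"),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  unique(paste0(g$root, g$suf))
}

.dis_modifiers <- c("acute", "chronic", "severe", "juvenile", "recurrent",
                    "focal", "diffuse", "primary", "secondary")

#' Generate the MeSH-like dictionary and tree fixture
#'
#' Builds a consistent rooted disease hierarchy (child names are a modifier
#' prepended to the parent name, child tree numbers extend the parent's, so
#' parent/child pairs exist for the specificity features) plus a flat
#' two-level chemical branch. Every concept gets one synonym.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, writes `dictionary.tsv` and
#'   `mesh_tree.tsv` in the package's TSV dialects.
#' @return list with `dictionary` (data.frame as
#'   [read_concept_dictionary()] returns), `tree` (a `mesh_tree`),
#'   `reserved_chemicals`, `reserved_diseases` (names deliberately absent
#'   from the dictionary, for unnormalizable mentions).
#' @export
make_mesh_fixture <- function(spec, dir = NULL) {
  .with_seed(spec$seed + 101L, {
    chem_pool <- sample(.chem_names())
    chem <- chem_pool[seq_len(spec$n_chemicals)]
    reserved_chem <- chem_pool[spec$n_chemicals + seq_len(5L)]

    base_pool <- sample(.dis_bases())
    # BFS construction of the disease hierarchy
    nodes <- data.frame(name = character(), tn = character(), depth = integer(),
                        stringsAsFactors = FALSE)
    for (b in seq_len(spec$tree_branching)) {
      nodes <- rbind(nodes, data.frame(name = base_pool[b],
                                       tn = sprintf("C%02d", b), depth = 1L,
                                       stringsAsFactors = FALSE))
    }
    frontier <- seq_len(nrow(nodes))
    for (d in seq_len(spec$tree_depth - 1L)) {
      nxt <- integer()
      for (p in frontier) {
        mods <- sample(.dis_modifiers, spec$tree_branching)
        for (j in seq_len(spec$tree_branching)) {
          nodes <- rbind(nodes, data.frame(
            name = paste(mods[j], nodes$name[p]),
            tn = paste0(nodes$tn[p], ".", sprintf("%03d", j * 100L)),
            depth = d + 1L, stringsAsFactors = FALSE))
          nxt <- c(nxt, nrow(nodes))
        }
      }
      frontier <- nxt
    }
    nodes <- nodes[order(nodes$depth, nodes$tn), , drop = FALSE]
    nodes <- nodes[seq_len(spec$n_diseases), , drop = FALSE]
    reserved_dis <- base_pool[seq.int(spec$tree_branching + 1L,
                                      spec$tree_branching + 5L)]

    dict <- rbind(
      data.frame(mesh_id = sprintf("D%06d", 100000L + seq_along(chem)),
                 type = "Chemical", preferred_name = chem,
                 synonyms = I(lapply(chem, function(n) paste(n, "hydrochloride"))),
                 stringsAsFactors = FALSE),
      data.frame(mesh_id = sprintf("D%06d", 500000L + seq_len(nrow(nodes))),
                 type = "Disease", preferred_name = nodes$name,
                 synonyms = I(lapply(nodes$name, function(n) paste(n, "disorder"))),
                 stringsAsFactors = FALSE))

    tns <- c(lapply(seq_along(chem), function(i)
               paste0("D02.", sprintf("%03d", (i %% 9L + 1L) * 100L), ".",
                      sprintf("%03d", i))),
             as.list(nodes$tn))
    names(tns) <- dict$mesh_id
    tree <- mesh_tree(tns)

    out <- list(dictionary = dict, tree = tree,
                reserved_chemicals = reserved_chem,
                reserved_diseases = reserved_dis)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      syn <- vapply(dict$synonyms, paste, "", collapse = "|")
      writeLines(paste(dict$mesh_id, dict$type, dict$preferred_name, syn,
                       sep = "\t"), file.path(dir, "dictionary.tsv"))
      writeLines(paste(names(tns),
                       vapply(tns, paste, "", collapse = "|"), sep = "\t"),
                 file.path(dir, "mesh_tree.tsv"))
      out$paths <- c(dictionary = file.path(dir, "dictionary.tsv"),
                     tree = file.path(dir, "mesh_tree.tsv"))
    }
    out
  })
}

# ---- corpus templates -------------------------------------------------------

.ment <- function(name, type, id) list(text = name, type = type, id = id)

.true_same_templates <- function(C, D) list(
  list(C, " induced severe ", D, " in the patients."),
  list(C, " caused ", D, " in rats."),
  list("Treatment with ", C, " produced ", D, "."),
  list("Administration of ", C, " induced ", D, " in two patients."))

.true_cross_templates <- function(C, D) list(
  list(list(C, " was administered to the patients daily."),
       list("This treatment induced ", D, " in several subjects.")),
  list(list(C, " was given at high doses."),
       list("Prolonged exposure caused ", D, " in the group.")))

.false_same_templates <- function(C, D) list(
  list(C, " levels and ", D, " status were monitored."),
  list("Patients with ", D, " received ", C, " without complications."),
  list(C, " therapy was continued although ", D, " was present at baseline."))

.false_cross_templates <- function(C, D) list(
  list(list(C, " was given during the trial."),
       list(D, " was recorded at baseline in some participants."))
)

.distractor_sentences <- c(
  "The clinical study was conducted over several weeks.",
  "Baseline measurements were collected for all participants.",
  "Laboratory values remained within the normal range.",
  "The follow up period lasted six months.")

# assemble parts (strings or .ment lists) into text + mention rows
.render_sentence <- function(parts, base) {
  text <- ""
  ment <- empty_mentions()
  for (p in parts) {
    if (is.character(p)) {
      text <- paste0(text, p)
    } else {
      s <- base + nchar(text)
      text <- paste0(text, p$text)
      ment <- rbind(ment, mention_table(s, s + nchar(p$text), p$text,
                                        p$type, p$id))
    }
  }
  list(text = text, mentions = ment)
}

#' Generate a synthetic PubTator corpus with planted CID relations
#'
#' Each document names one core chemical in its title, renders every
#' planted true (chemical, disease) pair with an induced-relation trigger
#' template — within one sentence, or across adjacent/distant sentences for
#' the configured cross-sentence fraction — and renders false
#' co-occurrences with neutral templates. Gold mentions carry exact
#' offsets and dictionary IDs (or `"-1"` for injected out-of-dictionary
#' mentions); gold CID lines list exactly the planted true pairs.
#'
#' @param spec a [fixture_spec()].
#' @param mesh output of [make_mesh_fixture()] for the same spec.
#' @param path optional file path; when given, the corpus is also written
#'   with [write_pubtator()].
#' @return list with `docs` (list of `cdr_document`) and `planted`
#'   (data.frame `chemical_id`, `disease_id`, `truth` of every planted
#'   pair, corpus-wide unique).
#' @export
generate_corpus <- function(spec, mesh, path = NULL) {
  dict <- mesh$dictionary
  chems <- dict[dict$type == "Chemical", , drop = FALSE]
  diss <- dict[dict$type == "Disease", , drop = FALSE]
  tree <- mesh$tree

  parent_of <- function(did) {
    tn <- tree[[did]][1]
    anc <- hypernym_codes(tn)
    if (!length(anc)) return(NULL)
    ptn <- anc[length(anc)]
    hits <- names(tree)[vapply(tree, function(x) ptn %in% x, TRUE)]
    hits <- intersect(hits, diss$mesh_id)
    if (length(hits)) hits[1] else NULL
  }

  .with_seed(spec$seed + 202L, {
    docs <- list()
    # truth is a property of the (chemical, disease) pair, decided once and
    # reused wherever the pair co-occurs, so the KB tables stay consistent
    # with every document's gold annotations
    truth_table <- new.env(parent = emptyenv())
    pair_truth <- function(ci, di, p_true) {
      key <- paste(ci, di)
      if (is.null(truth_table[[key]]))
        truth_table[[key]] <- stats::runif(1) < p_true
      truth_table[[key]]
    }
    planted <- data.frame(chemical_id = character(), disease_id = character(),
                          truth = logical(), stringsAsFactors = FALSE)
    for (k in seq_len(spec$n_docs)) {
      n_chem <- 1L + stats::rbinom(1L, 1L, 0.4)
      crow <- sample(nrow(chems), min(n_chem, nrow(chems)))
      n_dis <- sample(2:3, 1L)
      drow <- sample(nrow(diss), min(n_dis, nrow(diss)))
      dids <- diss$mesh_id[drow]
      standalone <- character()
      if (stats::runif(1) < 0.3) {
        par <- parent_of(dids[1])
        if (!is.null(par) && !par %in% dids) {
          dids <- c(dids, par)
          standalone <- par
        }
      }
      cids <- chems$mesh_id[crow]
      core <- cids[1]

      surface <- function(id, type) {
        row <- dict[dict$mesh_id == id, ]
        nm <- if (stats::runif(1) < spec$synonym_rate) row$synonyms[[1]][1]
              else row$preferred_name
        .ment(nm, type, id)
      }

      blocks <- list()
      truths <- list()
      for (ci in cids) {
        for (di in dids) {
          if (di %in% standalone) next
          truth <- pair_truth(ci, di, if (ci == core) 0.6 else 0.3)
          truths[[paste(ci, di)]] <- truth
          C <- surface(ci, "Chemical"); D <- surface(di, "Disease")
          if (truth) {
            if (stats::runif(1) < spec$cross_sentence_frac) {
              tpl <- sample(.true_cross_templates(C, D), 1L)[[1]]
              if (stats::runif(1) < 1 / 3)  # distance 2
                tpl <- list(tpl[[1]], list(sample(.distractor_sentences, 1L)),
                            tpl[[2]])
              blocks[[length(blocks) + 1L]] <- tpl
            } else {
              blocks[[length(blocks) + 1L]] <-
                list(sample(.true_same_templates(C, D), 1L)[[1]])
            }
          } else {
            if (stats::runif(1) < 0.6) {
              blocks[[length(blocks) + 1L]] <-
                list(sample(.false_same_templates(C, D), 1L)[[1]])
            } else {
              tpl <- sample(.false_cross_templates(C, D), 1L)[[1]]
              blocks[[length(blocks) + 1L]] <- tpl
            }
          }
        }
      }
      for (di in standalone) {
        D <- surface(di, "Disease")
        blocks[[length(blocks) + 1L]] <-
          list(list("A history of ", D, " was noted."))
      }
      if (stats::runif(1) < spec$unnorm_rate) {
        nm <- sample(mesh$reserved_diseases, 1L)
        blocks[[length(blocks) + 1L]] <-
          list(list("Mild ", .ment(nm, "Disease", "-1"), " was also observed."))
      }
      if (stats::runif(1) < spec$unnorm_rate) {
        nm <- sample(mesh$reserved_chemicals, 1L)
        blocks[[length(blocks) + 1L]] <-
          list(list("Concomitant ", .ment(nm, "Chemical", "-1"),
                    " use was reported."))
      }

      blocks <- blocks[sample(length(blocks))]
      with_distractors <- list()
      for (b in blocks) {
        with_distractors <- c(with_distractors, b)
        if (stats::runif(1) < spec$distractor_rate)
          with_distractors <- c(with_distractors,
                                list(list(sample(.distractor_sentences, 1L))))
      }

      title_parts <- list("Effects of ", surface(core, "Chemical"),
                          " in clinical practice.")
      tr <- .render_sentence(title_parts, 0L)
      title <- tr$text
      mentions <- tr$mentions
      abstract <- ""
      base <- nchar(title) + 1L
      for (s in with_distractors) {
        if (nzchar(abstract)) abstract <- paste0(abstract, " ")
        r <- .render_sentence(s, base + nchar(abstract))
        abstract <- paste0(abstract, r$text)
        mentions <- rbind(mentions, r$mentions)
      }

      truth_keys <- names(truths)[unlist(truths)]
      rel <- if (length(truth_keys)) {
        parts <- strsplit(truth_keys, " ", fixed = TRUE)
        unique(relation_table(vapply(parts, `[`, "", 1L),
                              vapply(parts, `[`, "", 2L)))
      } else relation_table()
      all_keys <- strsplit(names(truths), " ", fixed = TRUE)
      planted <- rbind(planted, data.frame(
        chemical_id = vapply(all_keys, `[`, "", 1L),
        disease_id = vapply(all_keys, `[`, "", 2L),
        truth = unlist(truths), stringsAsFactors = FALSE))

      docs[[length(docs) + 1L]] <-
        cdr_document(as.character(k), title, abstract, mentions, rel)
    }
    planted <- planted[order(planted$chemical_id, planted$disease_id), ]
    planted <- planted[!duplicated(planted[, c("chemical_id", "disease_id")]), ]
    # a pair planted true anywhere is treated as true corpus-wide
    agg <- stats::aggregate(truth ~ chemical_id + disease_id, planted, any)
    if (!is.null(path)) write_pubtator(docs, path)
    list(docs = docs, planted = agg[order(agg$chemical_id, agg$disease_id), ])
  })
}

#' Generate knowledge-base tables consistent with the planted relations
#'
#' CTD records `marker/mechanism` for a configurable share of planted true
#' pairs and `therapeutic` for a share of planted false pairs; SIDER
#' records some true pairs as `adverse-drug-reaction` and some false pairs
#' as `treatment`; MEDI records `treatment` for false pairs. The
#' high-precision (MEDI) and FAERS-confirmed (SIDER) subsets are random
#' sub-samples of their parent tables.
#'
#' @param tree the fixture `mesh_tree` (unused for content, kept so callers
#'   hold the full knowledge bundle together).
#' @param planted data.frame from [generate_corpus()].
#' @param spec the same [fixture_spec()].
#' @param dir optional directory to write `kb_*.tsv` files into.
#' @return knowledge bundle: `list(tree, medi, medi_hp, sider, sider_faers,
#'   ctd)` of `kb_table`s.
#' @export
make_kb_fixture <- function(tree, planted, spec, dir = NULL) {
  .with_seed(spec$seed + 303L, {
    tp <- planted[planted$truth, , drop = FALSE]
    fp <- planted[!planted$truth, , drop = FALSE]
    pick <- function(df, share) df[stats::runif(nrow(df)) < share, , drop = FALSE]
    pairs_tab <- function(df, label) {
      if (!nrow(df)) return(data.frame(chemical_id = character(),
                                       disease_id = character(),
                                       label = character()))
      data.frame(chemical_id = df$chemical_id, disease_id = df$disease_id,
                 label = label, stringsAsFactors = FALSE)
    }
    ctd <- rbind(pairs_tab(pick(tp, spec$ctd_true_share), "marker/mechanism"),
                 pairs_tab(pick(fp, spec$ctd_false_share), "therapeutic"))
    medi <- pairs_tab(pick(fp, 0.4), "treatment")
    medi_hp <- pick(medi, 0.5)
    sider <- rbind(pairs_tab(pick(tp, 0.4), "adverse-drug-reaction"),
                   pairs_tab(pick(fp, 0.2), "treatment"))
    sider_faers <- pick(sider, 0.5)
    kb <- list(tree = tree,
               medi = kb_table(medi, "MEDI"),
               medi_hp = kb_table(medi_hp, "MEDI_HP"),
               sider = kb_table(sider, "SIDER"),
               sider_faers = kb_table(sider_faers, "SIDER_FAERS"),
               ctd = kb_table(ctd, "CTD"))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in c("medi", "medi_hp", "sider", "sider_faers", "ctd")) {
        p <- kb[[nm]]$pairs
        writeLines(if (nrow(p)) paste(p$chemical_id, p$disease_id, p$label,
                                      sep = "\t") else character(),
                   file.path(dir, paste0("kb_", nm, ".tsv")))
      }
    }
    kb
  })
}

#' Generate a semantic-tagger lexicon from the fixture dictionary
#'
#' Every name and synonym is entered with tag `drug` (chemicals) or
#' `disorder` (diseases).
#'
#' @param dictionary fixture dictionary data.frame.
#' @param path optional TSV output path (`term<TAB>tag`).
#' @return a `ner_lexicon`.
#' @export
make_lexicon_fixture <- function(dictionary, path = NULL) {
  terms <- character(); tags <- character()
  for (i in seq_len(nrow(dictionary))) {
    nm <- c(dictionary$preferred_name[i], dictionary$synonyms[[i]])
    terms <- c(terms, nm)
    tags <- c(tags, rep(if (dictionary$type[i] == "Chemical") "drug"
                        else "disorder", length(nm)))
  }
  if (!is.null(path)) writeLines(paste(tolower(terms), tags, sep = "\t"), path)
  ner_lexicon(stats::setNames(tags, terms))
}

#' Generate a word2vec-format embedding fixture
#'
#' Random unit-scale vectors for the whole fixture vocabulary (dictionary
#' tokens plus template words), written in the `n d` header text format.
#'
#' @param spec a [fixture_spec()].
#' @param words character vector of words to embed.
#' @param dim embedding dimension.
#' @param path optional output file.
#' @return an `embedding_table`.
#' @export
make_embedding_fixture <- function(spec, words, dim = 10L, path = NULL) {
  .with_seed(spec$seed + 404L, {
    words <- sort(unique(tolower(words)))
    vecs <- lapply(words, function(w) round(stats::runif(dim, -0.5, 0.5), 4))
    if (!is.null(path)) {
      writeLines(c(paste(length(words), dim),
                   vapply(seq_along(words), function(i)
                     paste(c(words[i], format(vecs[[i]], trim = TRUE)),
                           collapse = " "), "")), path)
    }
    names(vecs) <- words
    structure(list(vectors = vecs, dim = dim), class = "embedding_table")
  })
}

#' Generate the full fixture bundle
#'
#' Convenience wrapper running [make_mesh_fixture()], [generate_corpus()],
#' [make_kb_fixture()], [make_lexicon_fixture()] and
#' [make_embedding_fixture()] under one spec, optionally writing every
#' artifact (corpus, dictionary, tree, KB tables, lexicons, trigger lists,
#' embeddings) to a directory.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory.
#' @return list with `spec`, `mesh`, `docs`, `planted`, `kb`, `lexicon`,
#'   `embeddings`, `triggers`.
#' @export
make_fixture <- function(spec = fixture_spec(), dir = NULL) {
  mesh <- make_mesh_fixture(spec, dir)
  corp <- generate_corpus(spec, mesh,
                          path = if (!is.null(dir)) file.path(dir, "corpus.pubtator"))
  kb <- make_kb_fixture(mesh$tree, corp$planted, spec, dir)
  lexicon <- make_lexicon_fixture(mesh$dictionary,
                                  path = if (!is.null(dir)) file.path(dir, "lexicon.tsv"))
  vocab <- unique(tolower(unlist(c(
    lapply(mesh$dictionary$preferred_name, function(t) tokenize(t)$text),
    lapply(unlist(mesh$dictionary$synonyms), function(t) tokenize(t)$text),
    lapply(c(.distractor_sentences, "induced caused produced patients rats"),
           function(t) tokenize(t)$text)), use.names = FALSE)))
  emb <- make_embedding_fixture(spec, vocab,
                                path = if (!is.null(dir)) file.path(dir, "embeddings.txt"))
  triggers <- default_triggers()
  if (!is.null(dir)) {
    writeLines(triggers$terms_i, file.path(dir, "terms_i.txt"))
    writeLines(triggers$terms_h, file.path(dir, "terms_h.txt"))
  }
  list(spec = spec, mesh = mesh, docs = corp$docs, planted = corp$planted,
       kb = kb, lexicon = lexicon, embeddings = emb, triggers = triggers)
}
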