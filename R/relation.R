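# Chemical-induced disease relation extraction: candidate generation,
# sentence-level (C_S) and document-level (C_D) feature vectors, linear SVM
# training, and prediction with the CS / CD / union strategies.
#
# Candidates are unique (chemical_id, disease_id) pairs per document, built
# from normalized mentions; the "-1" pseudo ID never generates a pair.
# C_S is trained on distantly supervised sentence instances: a co-sentence
# pair instance is labeled true iff the pair is in the document-level gold.

# Per-document context shared by candidate generation and feature
# extraction: segmented sentences, a global token table, and the mention
# table expanded to one row per (mention, concept id) with sentence and
# token coordinates.
doc_context <- function(doc) {
  sents <- segment(doc)
  tok <- do.call(rbind, lapply(sents, function(s) {
    t <- s$tokens
    if (nrow(t)) t$sent <- s$index
    t
  }))
  if (is.null(tok)) tok <- cbind(tokenize(""), sent = integer())
  m <- doc$mentions
  rows <- list()
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      for (id in m$concept_ids[[i]]) {
        cover <- which(tok$start < m$end[i] & tok$end > m$start[i])
        si <- if (length(cover)) tok$sent[cover[1]] else
          max(0L, sum(vapply(sents, function(s) s$start <= m$start[i], TRUE)) - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          mention = i, id = id, type = m$type[i], start = m$start[i],
          end = m$end[i], text = m$text[i], sent = si,
          tok_first = if (length(cover)) cover[1] else NA_integer_,
          tok_last = if (length(cover)) cover[length(cover)] else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  me <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mention = integer(), id = character(), type = character(),
               start = integer(), end = integer(), text = character(),
               sent = integer(), tok_first = integer(), tok_last = integer(),
               stringsAsFactors = FALSE)
  list(doc = doc, sents = sents, tok = tok, me = me,
       title_end = nchar(doc$title))
}

#' Detect the core chemicals of a document
#'
#' A chemical concept is "core" when it has at least one mention inside the
#' title span, or when its mention count equals the document maximum (all
#' tied concepts are core).
#'
#' @param doc a `cdr_document` with normalized chemical mentions.
#' @param title_end end offset of the title span (defaults to the title
#'   length under the title-space-abstract convention).
#' @return character vector of core chemical IDs.
#' @export
detect_core_chemicals <- function(doc, title_end = nchar(doc$title)) {
  ctx <- doc_context(doc)
  .core_chemicals(ctx, title_end)
}

.core_chemicals <- function(ctx, title_end = ctx$title_end) {
  ch <- ctx$me[ctx$me$type == "Chemical" & ctx$me$id != "-1", , drop = FALSE]
  if (!nrow(ch)) return(character())
  in_title <- unique(ch$id[ch$start < title_end])
  counts <- table(ch$id)
  most <- names(counts)[counts == max(counts)]
  sort(unique(c(in_title, most)))
}

#' Generate candidate chemical-disease pairs
#'
#' One candidate per unique (chemical_id, disease_id) with both IDs
#' normalized (never `"-1"`); composite-ID mentions contribute every
#' constituent ID. Document level keeps all pairs; sentence level keeps
#' only pairs with some co-sentence mention pair.
#'
#' @param doc a `cdr_document` with normalized mentions.
#' @param level `"sentence"` or `"document"`.
#' @return list of `candidate_pair` objects (fields `doc_id`,
#'   `chemical_id`, `disease_id`, `chem_rows`, `dis_rows`,
#'   `min_sentence_distance`, `is_core_chemical`, `label`).
#' @export
generate_candidates <- function(doc, level = c("document", "sentence")) {
  level <- match.arg(level)
  ctx <- doc_context(doc)
  .candidates(ctx, level)
}

.candidates <- function(ctx, level) {
  me <- ctx$me
  chem <- me[me$type == "Chemical" & me$id != "-1", , drop = FALSE]
  dis <- me[me$type == "Disease" & me$id != "-1", , drop = FALSE]
  if (!nrow(chem) || !nrow(dis)) return(list())
  core <- .core_chemicals(ctx)
  out <- list()
  for (cid in sort(unique(chem$id))) {
    crows <- which(me$id == cid & me$type == "Chemical")
    for (did in sort(unique(dis$id))) {
      drows <- which(me$id == did & me$type == "Disease")
      dist <- min(abs(outer(me$sent[crows], me$sent[drows], "-")))
      if (level == "sentence" && dist != 0L) next
      out[[length(out) + 1L]] <- structure(
        list(doc_id = ctx$doc$doc_id, chemical_id = cid, disease_id = did,
             chem_rows = crows, dis_rows = drows,
             min_sentence_distance = as.integer(dist),
             is_core_chemical = cid %in% core, label = NA),
        class = "candidate_pair")
    }
  }
  out
}

.gold_has <- function(doc, cid, did) {
  any(doc$relations$chemical_id == cid & doc$relations$disease_id == did)
}

#' Project document-level gold relations onto sentence instances
#'
#' Every (pair, sentence) co-occurrence becomes one instance, labeled true
#' iff the (chemical_id, disease_id) pair appears in the document's gold
#' relations — the distant-supervision rule used to train the
#' sentence-level classifier.
#'
#' @param doc a `cdr_document` with normalized mentions and gold relations.
#' @return list of instances: each a `candidate_pair` with an extra
#'   `sentence` field and a logical `label`.
#' @export
project_sentence_labels <- function(doc) {
  ctx <- doc_context(doc)
  .sentence_instances(ctx, labeled = TRUE)
}

.sentence_instances <- function(ctx, labeled = FALSE) {
  pairs <- .candidates(ctx, "sentence")
  me <- ctx$me
  out <- list()
  for (p in pairs) {
    sents <- intersect(me$sent[p$chem_rows], me$sent[p$dis_rows])
    for (s in sort(sents)) {
      inst <- p
      inst$sentence <- s
      if (labeled)
        inst$label <- .gold_has(ctx$doc, p$chemical_id, p$disease_id)
      out[[length(out) + 1L]] <- inst
    }
  }
  out
}

# ---- feature helpers --------------------------------------------------------

.bow_feats <- function(prefix, words) {
  words <- tolower(words)
  f <- character()
  if (length(words)) f <- paste0(prefix, "=", unique(words))
  if (length(words) >= 2L)
    f <- c(f, unique(paste0(prefix, "2=", paste(words[-length(words)],
                                                words[-1], sep = "|"))))
  .flag(f)
}

# anchor mention pair: smallest token distance, ties -> earliest start
.anchor_pair <- function(ctx, crows, drows) {
  me <- ctx$me
  best <- NULL; best_key <- c(Inf, Inf)
  for (i in crows) for (j in drows) {
    ti <- me$tok_first[i]; tj <- me$tok_first[j]
    d <- if (is.na(ti) || is.na(tj)) Inf else abs(ti - tj)
    key <- c(d, min(me$start[i], me$start[j]))
    if (key[1] < best_key[1] || (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- c(i, j); best_key <- key
    }
  }
  best
}

.kb_features <- function(pair, ctx, kb, config) {
  f <- numeric(0)
  if (config$use_mesh && !is.null(kb$tree)) {
    dcat <- suppressWarnings(concept_categories(pair$disease_id, kb$tree))
    ccat <- suppressWarnings(concept_categories(pair$chemical_id, kb$tree))
    if (length(dcat)) f <- c(f, .flag(paste0("kb:dcat=", dcat)))
    if (length(ccat)) f <- c(f, .flag(paste0("kb:ccat=", ccat)))
    dids <- unique(ctx$me$id[ctx$me$type == "Disease" & ctx$me$id != "-1"])
    flags <- disease_specificity_flags(pair$disease_id, dids, kb$tree)
    if (flags[["has_more_specific"]]) f <- c(f, .flag("kb:has_more_specific"))
    if (flags[["has_more_general"]]) f <- c(f, .flag("kb:has_more_general"))
  }
  rel_feat <- function(name, table) {
    lab <- kb_relation(pair$chemical_id, pair$disease_id, table)
    .flag(paste0("kb:", name, "=", lab %||% "null"))
  }
  if (config$use_medi && !is.null(kb$medi)) {
    f <- c(f, rel_feat("medi", kb$medi))
    if (!is.null(kb$medi_hp)) f <- c(f, rel_feat("medi_hp", kb$medi_hp))
  }
  if (config$use_sider && !is.null(kb$sider)) {
    f <- c(f, rel_feat("sider", kb$sider))
    if (!is.null(kb$sider_faers)) f <- c(f, rel_feat("sider_faers", kb$sider_faers))
    if (is_adr(pair$disease_id, kb$sider)) f <- c(f, .flag("kb:is_adr"))
  }
  if (config$use_ctd && !is.null(kb$ctd)) {
    f <- c(f, rel_feat("ctd", kb$ctd))
    if (is_induced(pair$disease_id, kb$ctd)) f <- c(f, .flag("kb:is_induced"))
  }
  f
}

.entity_features <- function(pair, ctx, rows_scope, config, with_first = FALSE,
                             anchor = NULL) {
  me <- ctx$me
  f <- numeric(0)
  ctexts <- unique(me$text[intersect(pair$chem_rows, rows_scope)])
  dtexts <- unique(me$text[intersect(pair$dis_rows, rows_scope)])
  cw <- unlist(lapply(ctexts, function(t) tokenize(t)$text), use.names = FALSE)
  dw <- unlist(lapply(dtexts, function(t) tokenize(t)$text), use.names = FALSE)
  f <- c(f, .bow_feats("ent:cbow", cw), .bow_feats("ent:dbow", dw))
  f <- c(f, .flag(c(paste0("ent:cid=", pair$chemical_id),
                    paste0("ent:did=", pair$disease_id))))
  if (pair$is_core_chemical) f <- c(f, .flag("ent:core_chem"))
  if (with_first && !is.null(anchor) &&
      me$start[anchor[1]] < me$start[anchor[2]])
    f <- c(f, .flag("ent:chem_first"))
  f
}

#' Relation-classifier configuration
#'
#' @param cost SVM misclassification cost C (linear kernel).
#' @param use_entity,use_context feature-group switches (Table-style entity
#'   and context groups).
#' @param use_mesh,use_medi,use_sider,use_ctd knowledge-base feature
#'   switches, for ablation.
#' @param seed stored for provenance; SVM training is deterministic for
#'   fixed data.
#' @return object of class `relation_config`.
#' @export
relation_config <- function(cost = 1.0, use_entity = TRUE, use_context = TRUE,
                            use_mesh = TRUE, use_medi = TRUE,
                            use_sider = TRUE, use_ctd = TRUE, seed = 1L) {
  structure(list(cost = cost, use_entity = use_entity,
                 use_context = use_context, use_mesh = use_mesh,
                 use_medi = use_medi, use_sider = use_sider,
                 use_ctd = use_ctd, seed = as.integer(seed)),
            class = "relation_config")
}

#' Sentence-level (C_S) feature vector of a candidate pair
#'
#' Anchored at the closest co-sentence mention pair (smallest token
#' distance, ties earliest). Entity features: bag-of-words and bigrams of
#' the mention texts in the anchor sentence, the chemical-first flag, both
#' MeSH IDs and the core-chemical flag. Context features: bag-of-words and
#' bigrams before, between and after the anchored mentions, an
#' induced-trigger (`terms_i`) flag on the between words, and a holder-term
#' (`terms_h`) flag on the sentence containing the disease. Knowledge
#' features: MeSH categories and specificity flags, MEDI/SIDER/CTD relation
#' labels, `isADR`, `isInduced`.
#'
#' @param pair a `candidate_pair` (must be co-sentence).
#' @param doc its `cdr_document`.
#' @param kb knowledge bundle: `list(tree, medi, medi_hp, sider,
#'   sider_faers, ctd)` (elements may be `NULL`).
#' @param triggers trigger lexicons as from [default_triggers()].
#' @param config a [relation_config()].
#' @param sentence optional 0-based sentence index restricting the anchor.
#' @return named numeric feature vector.
#' @export
sentence_pair_features <- function(pair, doc, kb = list(),
                                   triggers = default_triggers(),
                                   config = relation_config(),
                                   sentence = NULL) {
  ctx <- doc_context(doc)
  .cs_features(pair, ctx, kb, triggers, config, sentence)
}

.cs_features <- function(pair, ctx, kb, triggers, config, sentence = NULL) {
  me <- ctx$me
  crows <- pair$chem_rows; drows <- pair$dis_rows
  if (!is.null(sentence)) {
    crows <- crows[me$sent[crows] == sentence]
    drows <- drows[me$sent[drows] == sentence]
  } else {
    co <- intersect(me$sent[crows], me$sent[drows])
    if (!length(co)) stop("pair is not co-sentence; C_S features undefined")
    crows <- crows[me$sent[crows] %in% co]
    drows <- drows[me$sent[drows] %in% co]
    keep <- intersect(me$sent[crows], me$sent[drows])
    crows <- crows[me$sent[crows] %in% keep]
    drows <- drows[me$sent[drows] %in% keep]
  }
  if (!length(crows) || !length(drows))
    stop("pair is not co-sentence; C_S features undefined")
  anchor <- .anchor_pair(ctx, crows, drows)
  s <- me$sent[anchor[1]]
  srows_scope <- which(me$sent == s)
  f <- numeric(0)
  if (config$use_entity)
    f <- c(f, .entity_features(pair, ctx, srows_scope, config,
                               with_first = TRUE, anchor = anchor))
  if (config$use_context) {
    tok <- ctx$tok
    stoks <- which(tok$sent == s)
    first <- min(me$tok_first[anchor]); last <- max(me$tok_last[anchor])
    before <- stoks[stoks < first]
    between <- stoks[stoks > min(me$tok_last[anchor]) &
                       stoks < max(me$tok_first[anchor])]
    after <- stoks[stoks > last]
    f <- c(f, .bow_feats("ctx:before", tok$text[before]),
           .bow_feats("ctx:between", tok$text[between]),
           .bow_feats("ctx:after", tok$text[after]))
    if (any(tolower(tok$text[between]) %in% triggers$terms_i))
      f <- c(f, .flag("ctx:terms_i"))
    dsent <- me$sent[anchor[2]]
    if (any(tolower(tok$text[tok$sent == dsent]) %in% triggers$terms_h))
      f <- c(f, .flag("ctx:terms_h"))
  }
  c(f, .kb_features(pair, ctx, kb, config))
}

#' Document-level (C_D) feature vector of a candidate pair
#'
#' Entity features as for C_S but pooled over the whole document and
#' without the chemical-first flag. Positional one-hots: exactly one of
#' same-sentence (distance 0), adjacent-sentences (1) or
#' crosses-more-than-two-sentences (>= 2) fires. The induced-trigger flag
#' is computed on the tokens between the closest anchored mentions (which
#' may cross sentence boundaries); the holder-term flag is emitted only
#' when the pair is same-sentence or adjacent. Knowledge features as for
#' C_S.
#'
#' @inheritParams sentence_pair_features
#' @return named numeric feature vector.
#' @export
document_pair_features <- function(pair, doc, kb = list(),
                                   triggers = default_triggers(),
                                   config = relation_config()) {
  ctx <- doc_context(doc)
  .cd_features(pair, ctx, kb, triggers, config)
}

.cd_features <- function(pair, ctx, kb, triggers, config) {
  me <- ctx$me
  anchor <- .anchor_pair(ctx, pair$chem_rows, pair$dis_rows)
  f <- numeric(0)
  if (config$use_entity)
    f <- c(f, .entity_features(pair, ctx, seq_len(nrow(me)), config,
                               with_first = FALSE))
  if (config$use_context) {
    d <- pair$min_sentence_distance
    f <- c(f, .flag(if (d == 0L) "ctx:same_sentence"
                    else if (d == 1L) "ctx:adjacent"
                    else "ctx:distant"))
    tok <- ctx$tok
    lo <- min(me$tok_last[anchor]); hi <- max(me$tok_first[anchor])
    between <- if (is.na(lo) || is.na(hi)) integer()
               else seq_len(nrow(tok))[seq_len(nrow(tok)) > lo &
                                         seq_len(nrow(tok)) < hi]
    if (any(tolower(tok$text[between]) %in% triggers$terms_i))
      f <- c(f, .flag("ctx:terms_i"))
    if (d <= 1L) {
      dsent <- me$sent[anchor[2]]
      if (any(tolower(tok$text[tok$sent == dsent]) %in% triggers$terms_h))
        f <- c(f, .flag("ctx:terms_h"))
    }
  }
  c(f, .kb_features(pair, ctx, kb, config))
}

# ---- SVM plumbing -----------------------------------------------------------

.feat_matrix <- function(feat_list, vocab) {
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_along(feat_list)) {
    f <- feat_list[[r]]
    j <- match(names(f), vocab)
    keep <- !is.na(j)
    ii <- c(ii, rep(r, sum(keep))); jj <- c(jj, j[keep])
    xx <- c(xx, as.numeric(f[keep]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(feat_list), length(vocab)))
}

.fit_svm <- function(feat_list, labels, config) {
  if (length(unique(labels)) < 2L)
    stop("single-class training data: need both positive and negative instances")
  vocab <- sort(unique(unlist(lapply(feat_list, names), use.names = FALSE)))
  x <- .feat_matrix(feat_list, vocab)
  y <- factor(labels, levels = c(FALSE, TRUE))
  cw <- length(y) / (2 * table(y))
  model <- e1071::svm(x, y, kernel = "linear", cost = config$cost,
                      class.weights = cw, scale = FALSE)
  list(svm = model, vocab = vocab)
}

.svm_predict <- function(fitted, feat_list) {
  if (!length(feat_list)) return(logical())
  x <- .feat_matrix(feat_list, fitted$vocab)
  as.logical(as.character(predict(fitted$svm, x)))
}

#' Train the sentence- and document-level relation classifiers
#'
#' C_S is trained on distantly supervised sentence instances (see
#' [project_sentence_labels()]); C_D on one instance per document-level
#' candidate pair labeled by the gold relations directly. Both are linear
#' SVMs with balanced class weights.
#'
#' @param docs training documents with normalized mentions and gold
#'   relations.
#' @param kb knowledge bundle (see [sentence_pair_features()]).
#' @param triggers trigger lexicons.
#' @param config a [relation_config()].
#' @return object of class `relation_models`.
#' @export
train_relation_models <- function(docs, kb = list(),
                                  triggers = default_triggers(),
                                  config = relation_config()) {
  if (!any(vapply(docs, function(d) nrow(d$relations) > 0L, TRUE)))
    stop("corpus has zero positive relations")
  cs_f <- list(); cs_y <- logical()
  cd_f <- list(); cd_y <- logical()
  for (doc in docs) {
    ctx <- doc_context(doc)
    for (inst in .sentence_instances(ctx, labeled = TRUE)) {
      cs_f[[length(cs_f) + 1L]] <- .cs_features(inst, ctx, kb, triggers,
                                                config, inst$sentence)
      cs_y <- c(cs_y, inst$label)
    }
    for (p in .candidates(ctx, "document")) {
      cd_f[[length(cd_f) + 1L]] <- .cd_features(p, ctx, kb, triggers, config)
      cd_y <- c(cd_y, .gold_has(doc, p$chemical_id, p$disease_id))
    }
  }
  structure(list(cs = .fit_svm(cs_f, cs_y, config),
                 cd = .fit_svm(cd_f, cd_y, config),
                 config = config),
            class = "relation_models")
}

#' @export
print.relation_models <- function(x, ...) {
  cat("<relation_models: C_S (", x$cs$svm$tot.nSV, " SV), C_D (",
      x$cd$svm$tot.nSV, " SV)>\n", sep = "")
  invisible(x)
}

#' Predict CID relations of a document
#'
#' `"cs"` classifies every co-sentence instance and marks a pair positive
#' if any of its instances is positive; `"cd"` classifies each
#' document-level pair once; `"union"` returns the union of the two
#' positive sets (the headline strategy).
#'
#' @param models a `relation_models`.
#' @param doc a `cdr_document` with normalized mentions.
#' @param kb knowledge bundle.
#' @param triggers trigger lexicons.
#' @param strategy `"cs"`, `"cd"` or `"union"`.
#' @return relation table of predicted (chemical_id, disease_id) pairs.
#' @export
predict_relations <- function(models, doc, kb = list(),
                              triggers = default_triggers(),
                              strategy = c("union", "cs", "cd")) {
  strategy <- match.arg(strategy)
  ctx <- doc_context(doc)
  config <- models$config
  pred_cs <- function() {
    insts <- .sentence_instances(ctx)
    if (!length(insts)) return(character())
    feats <- lapply(insts, function(i)
      .cs_features(i, ctx, kb, triggers, config, i$sentence))
    pos <- .svm_predict(models$cs, feats)
    unique(vapply(insts[pos], function(i)
      paste(i$chemical_id, i$disease_id, sep = "\r"), ""))
  }
  pred_cd <- function() {
    pairs <- .candidates(ctx, "document")
    if (!length(pairs)) return(character())
    feats <- lapply(pairs, function(p) .cd_features(p, ctx, kb, triggers, config))
    pos <- .svm_predict(models$cd, feats)
    vapply(pairs[pos], function(p)
      paste(p$chemical_id, p$disease_id, sep = "\r"), "")
  }
  keys <- switch(strategy,
                 cs = pred_cs(),
                 cd = pred_cd(),
                 union = union(pred_cs(), pred_cd()))
  if (!length(keys)) return(relation_table())
  parts <- strsplit(sort(keys), "\r", fixed = TRUE)
  relation_table(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}
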