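# CRF-based named entity recognition for chemicals and diseases.
#
# Two training regimes: NER-S ("separate") trains one CRF per entity type
# (labels B-C/I-C/O and B-D/I-D/O, optionally with extra type-specific
# corpora), NER-U ("unified") trains a single CRF over the five-label
# alphabet. Prediction decodes per sentence and, in separate mode, merges
# the two models' mentions with a fixed cross-type overlap rule.

#' NER configuration
#'
#' @param mode `"separate"` (one CRF per entity type) or `"unified"`.
#' @param use_word,use_dict,use_context,use_affix,use_embedding feature
#'   group switches.
#' @param window context window half-width (tokens).
#' @param l2 CRF L2 regularization strength.
#' @param max_iter CRF optimizer iteration cap.
#' @param disease_suffixes,disease_prefixes affix lists for the domain
#'   feature group.
#' @param seed stored with the model for provenance; training itself is
#'   deterministic.
#' @return object of class `ner_config`.
#' @export
ner_config <- function(mode = c("separate", "unified"),
                       use_word = TRUE, use_dict = TRUE, use_context = TRUE,
                       use_affix = TRUE, use_embedding = TRUE,
                       window = 2L, l2 = 1.0, max_iter = 200L,
                       disease_suffixes = .disease_suffixes,
                       disease_prefixes = .disease_prefixes,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(window >= 0L, l2 >= 0, max_iter >= 1L)
  structure(list(mode = mode, use_word = use_word, use_dict = use_dict,
                 use_context = use_context, use_affix = use_affix,
                 use_embedding = use_embedding, window = as.integer(window),
                 l2 = l2, max_iter = as.integer(max_iter),
                 disease_suffixes = disease_suffixes,
                 disease_prefixes = disease_prefixes,
                 seed = as.integer(seed)),
            class = "ner_config")
}

# feature sequences + BIO label sequences for a document collection,
# restricted to the given entity types
.doc_sequences <- function(docs, config, lexicon, embeddings, types) {
  seqs <- list(); labs <- list()
  for (doc in docs) {
    ments <- doc$mentions
    ments <- ments[ments$type %in% types, , drop = FALSE]
    for (sent in segment(doc)) {
      if (!nrow(sent$tokens)) next
      tags <- if (!is.null(lexicon)) dict_features(sent, lexicon) else NULL
      feats <- lapply(seq_len(nrow(sent$tokens)), function(i)
        token_features(sent, i, config, tags, embeddings))
      seqs[[length(seqs) + 1L]] <- feats
      labs[[length(labs) + 1L]] <- encode_bio(sent, ments)
    }
  }
  list(seqs = seqs, labs = labs)
}

#' Train NER model(s)
#'
#' @param docs list of `cdr_document` with gold mentions.
#' @param config a [ner_config()].
#' @param lexicon optional `ner_lexicon` for the dictionary feature group.
#' @param embeddings optional `embedding_table`.
#' @param extra_chemical,extra_disease optional additional document
#'   collections used only by the corresponding separate-mode model (the
#'   way external chemical- or disease-only corpora supplement training).
#' @return object of class `ner_model` holding one CRF (unified) or two
#'   (separate), the config, and the resources used.
#' @export
train_ner <- function(docs, config = ner_config(), lexicon = NULL,
                      embeddings = NULL, extra_chemical = NULL,
                      extra_disease = NULL) {
  if (!length(docs)) stop("empty training set")
  models <- if (config$mode == "unified") {
    d <- .doc_sequences(docs, config, lexicon, embeddings,
                        c("Chemical", "Disease"))
    list(unified = crf_fit(d$seqs, d$labs, config$l2, config$max_iter))
  } else {
    dc <- .doc_sequences(c(docs, extra_chemical), config, lexicon, embeddings,
                         "Chemical")
    dd <- .doc_sequences(c(docs, extra_disease), config, lexicon, embeddings,
                         "Disease")
    list(chemical = crf_fit(dc$seqs, dc$labs, config$l2, config$max_iter),
         disease = crf_fit(dd$seqs, dd$labs, config$l2, config$max_iter))
  }
  structure(list(mode = config$mode, config = config, models = models,
                 lexicon = lexicon, embeddings = embeddings),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model mode=", x$mode, " (", length(x$models), " CRF(s))>\n", sep = "")
  invisible(x)
}

# decode one document with one CRF
.predict_doc_crf <- function(crf, doc, config, lexicon, embeddings) {
  full <- doc_text(doc)
  out <- empty_mentions()
  for (sent in segment(doc)) {
    if (!nrow(sent$tokens)) next
    tags <- if (!is.null(lexicon)) dict_features(sent, lexicon) else NULL
    feats <- lapply(seq_len(nrow(sent$tokens)), function(i)
      token_features(sent, i, config, tags, embeddings))
    labels <- crf_decode(crf, feats)
    out <- rbind(out, decode_bio(sent, labels, full))
  }
  out
}

#' Predict chemical and disease mentions of a document
#'
#' Separate mode runs both per-type CRFs and merges their output; a
#' cross-type span overlap is resolved in favor of the longer mention, with
#' ties going to the chemical.
#'
#' @param model a trained `ner_model`.
#' @param doc a `cdr_document`.
#' @return mention table (concept IDs `"-1"`, i.e. not yet normalized).
#' @export
predict_mentions <- function(model, doc) {
  cfg <- model$config
  if (model$mode == "unified") {
    m <- .predict_doc_crf(model$models$unified, doc, cfg, model$lexicon,
                          model$embeddings)
    return(m[order(m$start, m$end), , drop = FALSE])
  }
  mc <- .predict_doc_crf(model$models$chemical, doc, cfg, model$lexicon,
                         model$embeddings)
  md <- .predict_doc_crf(model$models$disease, doc, cfg, model$lexicon,
                         model$embeddings)
  both <- rbind(mc, md)
  if (nrow(both) > 1L) {
    # longer span wins; tie -> Chemical (chemical rows come first in `both`)
    ord <- order(-(both$end - both$start),
                 as.integer(both$type != "Chemical"), both$start)
    kept <- integer()
    for (i in ord) {
      clash <- any(both$start[kept] < both$end[i] & both$end[kept] > both$start[i])
      if (!clash) kept <- c(kept, i)
    }
    both <- both[kept, , drop = FALSE]
  }
  both[order(both$start, both$end), , drop = FALSE]
}
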