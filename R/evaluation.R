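# Micro-averaged precision/recall/F over set comparisons: mention-level
# (exact span), concept-level (doc, MeSH ID) and relation-level
# (doc, chemical, disease) 3-tuples, plus the relation-coverage diagnostic.

#' Precision/recall/F1 from micro counts
#'
#' @param tp,fp,fn micro-averaged counts.
#' @param empty_convention value reported for all three metrics when both
#'   gold and prediction are empty (tp = fp = fn = 0); the conventional 1 by
#'   default, and the result is flagged via the `degenerate` field.
#' @return list of class `prf` with `precision`, `recall`, `f1`, `tp`,
#'   `fp`, `fn`, `degenerate`.
#' @export
prf <- function(tp, fp, fn, empty_convention = 1) {
  degenerate <- tp == 0 && fp == 0 && fn == 0
  if (degenerate) {
    p <- r <- f <- empty_convention
  } else {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  structure(list(precision = p, recall = r, f1 = f,
                 tp = tp, fp = fp, fn = fn, degenerate = degenerate),
            class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("P=%.4f R=%.4f F=%.4f (tp=%d fp=%d fn=%d)%s\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn,
              if (x$degenerate) " [empty gold and prediction]" else ""))
  invisible(x)
}

.check_aligned <- function(gold_docs, pred_docs) {
  gid <- vapply(gold_docs, `[[`, "", "doc_id")
  pid <- vapply(pred_docs, `[[`, "", "doc_id")
  if (!setequal(gid, pid) || anyDuplicated(gid) || anyDuplicated(pid))
    stop("gold and predicted collections must cover the same doc_ids exactly once")
  list(gold = gold_docs[order(gid)], pred = pred_docs[order(pid)])
}

.set_prf <- function(gold_items, pred_items, empty_convention = 1) {
  gold_items <- unique(gold_items); pred_items <- unique(pred_items)
  tp <- sum(pred_items %in% gold_items)
  prf(tp, length(pred_items) - tp, length(gold_items) - tp, empty_convention)
}

.mention_items <- function(doc, etype) {
  m <- doc$mentions[doc$mentions$type == etype, , drop = FALSE]
  if (!nrow(m)) return(character())
  paste(doc$doc_id, m$start, m$end, etype, sep = "\r")
}

.concept_items <- function(doc, etype) {
  m <- doc$mentions[doc$mentions$type == etype, , drop = FALSE]
  ids <- unique(unlist(m$concept_ids, use.names = FALSE))
  ids <- ids[!is.na(ids) & ids != "-1" & nzchar(ids)]
  if (!length(ids)) return(character())
  paste(doc$doc_id, ids, sep = "\r")
}

.cid_items <- function(doc) {
  r <- doc$relations
  if (!nrow(r)) return(character())
  unique(paste(doc$doc_id, r$chemical_id, r$disease_id, sep = "\r"))
}

#' Mention-level evaluation (exact span matching)
#'
#' Items are (doc_id, start, end, type) tuples; a predicted span off by one
#' character counts as both a false positive and a false negative.
#'
#' @param gold_docs,pred_docs lists of `cdr_document` covering the same
#'   doc_ids.
#' @param etype `"Chemical"` or `"Disease"`.
#' @param empty_convention see [prf()].
#' @return a `prf`.
#' @export
eval_mention_level <- function(gold_docs, pred_docs, etype,
                               empty_convention = 1) {
  a <- .check_aligned(gold_docs, pred_docs)
  .set_prf(unlist(lapply(a$gold, .mention_items, etype)),
           unlist(lapply(a$pred, .mention_items, etype)), empty_convention)
}

#' Concept-level evaluation
#'
#' Items are unique (doc_id, concept_id) tuples; the `"-1"` pseudo ID is
#' excluded on both sides; composite annotations contribute one item per
#' constituent ID.
#'
#' @inheritParams eval_mention_level
#' @return a `prf`.
#' @export
eval_concept_level <- function(gold_docs, pred_docs, etype,
                               empty_convention = 1) {
  a <- .check_aligned(gold_docs, pred_docs)
  .set_prf(unlist(lapply(a$gold, .concept_items, etype)),
           unlist(lapply(a$pred, .concept_items, etype)), empty_convention)
}

#' CID relation evaluation
#'
#' Items are unique (doc_id, chemical_id, disease_id) ordered 3-tuples.
#'
#' @inheritParams eval_mention_level
#' @return a `prf`.
#' @export
eval_cid <- function(gold_docs, pred_docs, empty_convention = 1) {
  a <- .check_aligned(gold_docs, pred_docs)
  .set_prf(unlist(lapply(a$gold, .cid_items)),
           unlist(lapply(a$pred, .cid_items)), empty_convention)
}

#' Relation coverage of predicted entities
#'
#' A gold relation is covered when both its chemical and its disease concept
#' ID appear among the predicted concept IDs of the same document — an upper
#' bound on what any downstream relation classifier can recover.
#'
#' @param gold_docs documents with gold relations.
#' @param predicted_entity_docs same doc_ids with predicted, normalized
#'   mentions.
#' @return list with `covered`, `total` and `fraction`.
#' @export
relation_coverage <- function(gold_docs, predicted_entity_docs) {
  a <- .check_aligned(gold_docs, predicted_entity_docs)
  covered <- 0L; total <- 0L
  for (i in seq_along(a$gold)) {
    g <- a$gold[[i]]; p <- a$pred[[i]]
    r <- unique(g$relations)
    if (!nrow(r)) next
    pm <- p$mentions
    cids <- unique(unlist(pm$concept_ids[pm$type == "Chemical"], use.names = FALSE))
    dids <- unique(unlist(pm$concept_ids[pm$type == "Disease"], use.names = FALSE))
    total <- total + nrow(r)
    covered <- covered + sum(r$chemical_id %in% cids & r$disease_id %in% dids)
  }
  list(covered = covered, total = total,
       fraction = if (total > 0) covered / total else NA_real_)
}
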