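# Vector-space normalization of entity mentions to MeSH IDs.
#
# Every name and synonym of every concept becomes a TF-IDF-weighted unit
# vector over lowercased stems; a mention is normalized to the concept whose
# best name vector has the highest cosine with the mention vector. A mention
# sharing no token with any name gets the pseudo ID "-1" with score 0.

.norm_tokens <- function(text) {
  toks <- tokenize(text)
  if (!nrow(toks)) return(character())
  toks$stem[toks$pos != "PUNCT"]
}

#' Read a concept dictionary
#'
#' @param path TSV with columns
#'   `mesh_id<TAB>type<TAB>preferred_name<TAB>synonym1|synonym2|...`
#'   (the synonym field may be empty).
#' @return data.frame with `mesh_id`, `type`, `preferred_name` and a
#'   `synonyms` list column.
#' @export
read_concept_dictionary <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("mesh_id", "type", "preferred_name", "synonyms"),
                           colClasses = "character", quote = "")
  syn <- strsplit(tab$synonyms, "|", fixed = TRUE)
  syn <- lapply(syn, function(s) s[nzchar(s)])
  data.frame(mesh_id = tab$mesh_id, type = tab$type,
             preferred_name = tab$preferred_name,
             synonyms = I(syn), stringsAsFactors = FALSE)
}

#' Build a concept index for one entity type
#'
#' Tokenizes, stems and lowercases every name and synonym of the entries of
#' the requested type, weights terms by smoothed TF-IDF
#' (`idf = 1 + log((N + 1) / (df + 1))`, so a term present in every name
#' still contributes with the floor weight 1) and stores unit-normalized
#' name vectors. Construction is insertion-order invariant; duplicate
#' (id, name) pairs are dropped with a warning.
#'
#' @param entries dictionary data.frame as from [read_concept_dictionary()].
#' @param etype `"Chemical"` or `"Disease"`.
#' @return object of class `concept_index`.
#' @export
build_concept_index <- function(entries, etype) {
  etype <- match.arg(etype, c("Chemical", "Disease"))
  entries <- entries[entries$type == etype, , drop = FALSE]
  if (!nrow(entries)) stop("no dictionary entries of type ", etype)
  ids <- rep(entries$mesh_id,
             1L + lengths(entries$synonyms))
  nms <- unlist(Map(c, entries$preferred_name, entries$synonyms),
                use.names = FALSE)
  keep <- !duplicated(paste(ids, nms, sep = "\r"))
  if (any(!keep)) warning(sum(!keep), " duplicate (id, name) pair(s) dropped")
  ids <- ids[keep]; nms <- nms[keep]
  ord <- order(ids, nms)
  ids <- ids[ord]; nms <- nms[ord]

  tok_lists <- lapply(nms, .norm_tokens)
  vocab <- sort(unique(unlist(tok_lists, use.names = FALSE)))
  n_names <- length(nms)
  df <- table(factor(unlist(lapply(tok_lists, unique), use.names = FALSE),
                     levels = vocab))
  idf <- 1 + log((n_names + 1) / (as.numeric(df) + 1))
  names(idf) <- vocab

  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_along(tok_lists)) {
    tl <- tok_lists[[r]]
    if (!length(tl)) next
    tf <- table(tl)
    j <- match(names(tf), vocab)
    w <- as.numeric(tf) * idf[j]
    w <- w / sqrt(sum(w^2))
    ii <- c(ii, rep(r, length(j))); jj <- c(jj, j); xx <- c(xx, w)
  }
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n_names, length(vocab)))
  structure(list(etype = etype, mesh_id = ids, name = nms,
                 vocab = vocab, idf = idf, vectors = mat),
            class = "concept_index")
}

#' @export
print.concept_index <- function(x, ...) {
  cat("<concept_index ", x$etype, ": ", length(unique(x$mesh_id)),
      " concept(s), ", length(x$name), " name vector(s), ",
      length(x$vocab), " term(s)>\n", sep = "")
  invisible(x)
}

#' Vectorize free text in the space of a concept index
#'
#' Applies the same tokenize/stem/lowercase pipeline and TF-IDF weights used
#' at index construction. Texts whose tokens are all unseen map to the zero
#' vector.
#'
#' @param text character scalar.
#' @param index a `concept_index`.
#' @return numeric vector over the index vocabulary (unit norm or all-zero).
#' @export
vectorize_term <- function(text, index) {
  v <- numeric(length(index$vocab))
  tl <- .norm_tokens(text)
  tl <- tl[tl %in% index$vocab]
  if (!length(tl)) return(v)
  tf <- table(tl)
  j <- match(names(tf), index$vocab)
  v[j] <- as.numeric(tf) * index$idf[j]
  v / sqrt(sum(v^2))
}

#' Normalize a mention to a MeSH ID
#'
#' Scores the mention text against every stored name vector by cosine; the
#' concept score is the maximum over its names. Ties on the top score are
#' broken by the lexicographically smallest MeSH ID (a deterministic stand-in
#' for arbitrary tie selection). A top score of 0 yields the pseudo ID
#' `"-1"`.
#'
#' @param text the mention surface string.
#' @param index `concept_index` of the mention's entity type.
#' @return list with `mesh_id`, `score` (cosine in \[0, 1\]) and
#'   `matched_name`.
#' @export
normalize_mention <- function(text, index) {
  q <- vectorize_term(text, index)
  if (!any(q != 0))
    return(list(mesh_id = "-1", score = 0, matched_name = NA_character_))
  scores <- as.numeric(index$vectors %*% q)
  best <- max(scores)
  if (best <= 1e-12)
    return(list(mesh_id = "-1", score = 0, matched_name = NA_character_))
  tied <- which(scores >= best - 1e-9)
  ids <- index$mesh_id[tied]
  pick <- tied[order(ids, index$name[tied])][1]
  list(mesh_id = index$mesh_id[pick], score = min(best, 1),
       matched_name = index$name[pick])
}

#' Normalize all mentions of a document
#'
#' Replaces each mention's concept IDs with the result of
#' [normalize_mention()] against the index matching its entity type.
#'
#' @param doc a `cdr_document`.
#' @param chem_index,dis_index `concept_index` objects.
#' @return the document with normalized `concept_ids`.
#' @export
normalize_document <- function(doc, chem_index, dis_index) {
  m <- doc$mentions
  if (nrow(m)) {
    ids <- character(nrow(m))
    for (i in seq_len(nrow(m))) {
      idx <- if (m$type[i] == "Chemical") chem_index else dis_index
      ids[i] <- normalize_mention(m$text[i], idx)$mesh_id
    }
    m$concept_ids <- I(as.list(ids))
    doc$mentions <- m
  }
  doc
}
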