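# PubTator-format corpus I/O and BIO sequence conversion.
#
# A document's full text is the title, a single space, then the abstract;
# all mention offsets are 0-based character offsets into that concatenation
# with exclusive ends (the CDR dialect).

#' Construct an empty mention table
#' @return zero-row mention data.frame.
#' @export
empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), text = character(),
             type = character(),
             concept_ids = I(list()), stringsAsFactors = FALSE)
}

#' Construct a mention table
#'
#' @param start,end 0-based character offsets (end exclusive) into the
#'   document full text.
#' @param text surface strings.
#' @param type entity types, `"Chemical"` or `"Disease"`.
#' @param concept_ids list of character vectors of MeSH IDs (may be `"-1"`).
#' @return data.frame with one row per mention; `concept_ids` is a list
#'   column so composite annotations like `"D1|D2"` keep both IDs.
#' @export
mention_table <- function(start, end, text, type, concept_ids) {
  stopifnot(all(start >= 0L), all(end > start),
            all(type %in% c("Chemical", "Disease")))
  if (is.character(concept_ids)) concept_ids <- strsplit(concept_ids, "|", fixed = TRUE)
  data.frame(start = as.integer(start), end = as.integer(end),
             text = as.character(text), type = as.character(type),
             concept_ids = I(concept_ids), stringsAsFactors = FALSE)
}

#' Construct a relation table
#' @param chemical_id,disease_id MeSH ID character vectors.
#' @return data.frame with `chemical_id`, `disease_id` columns.
#' @export
relation_table <- function(chemical_id = character(), disease_id = character()) {
  stopifnot(length(chemical_id) == length(disease_id))
  if (length(chemical_id)) {
    stopifnot(all(nzchar(chemical_id)), all(nzchar(disease_id)),
              all(chemical_id != "-1"), all(disease_id != "-1"))
  }
  data.frame(chemical_id = as.character(chemical_id),
             disease_id = as.character(disease_id), stringsAsFactors = FALSE)
}

#' Construct a document
#'
#' @param doc_id non-empty document identifier (a PMID in real corpora).
#' @param title,abstract character scalars.
#' @param mentions mention table (see [mention_table()]).
#' @param relations relation table (see [relation_table()]).
#' @param validate check that every mention span reproduces its text.
#' @return object of class `cdr_document`.
#' @export
cdr_document <- function(doc_id, title, abstract = "",
                         mentions = empty_mentions(),
                         relations = relation_table(), validate = TRUE) {
  stopifnot(is.character(doc_id), nzchar(doc_id))
  doc <- structure(list(doc_id = doc_id, title = title, abstract = abstract,
                        mentions = mentions, relations = relations),
                   class = "cdr_document")
  if (validate) validate_document(doc)
  doc
}

#' Full text of a document
#'
#' Title and abstract joined by a single space (the offset convention used
#' throughout; an empty abstract contributes nothing).
#' @param doc a `cdr_document`.
#' @return character scalar.
#' @export
doc_text <- function(doc) {
  if (is.na(doc$abstract) || !nzchar(doc$abstract)) doc$title
  else paste(doc$title, doc$abstract)
}

validate_document <- function(doc) {
  full <- doc_text(doc)
  m <- doc$mentions
  if (nrow(m)) {
    if (any(m$start < 0L) || any(m$end <= m$start) || any(m$end > nchar(full)))
      stop("document ", doc$doc_id, ": mention span out of bounds")
    got <- substr_off(rep(full, nrow(m)), m$start, m$end)
    bad <- which(got != m$text)
    if (length(bad))
      stop("document ", doc$doc_id, ": mention text/offset mismatch at row(s) ",
           paste(bad, collapse = ", "), " (span reads ",
           dQuote(got[bad[1]]), ", annotation says ", dQuote(m$text[bad[1]]), ")")
  }
  invisible(doc)
}

#' @export
print.cdr_document <- function(x, ...) {
  cat("<cdr_document ", x$doc_id, ": ", nrow(x$mentions), " mention(s), ",
      nrow(x$relations), " relation(s)>\n", sep = "")
  invisible(x)
}

#' Read a PubTator-format corpus
#'
#' Parses the CDR dialect: per document a `PMID|t|title` line, a
#' `PMID|a|abstract` line, then tab-separated annotation rows
#' (`PMID start end text type conceptID`) and relation rows
#' (`PMID CID chemicalID diseaseID`), documents separated by blank lines.
#' Composite concept fields (`"D1|D2"`) are split into multiple concept IDs.
#' Every mention is validated against the reconstructed full text.
#'
#' @param path file path (UTF-8).
#' @return list of `cdr_document`.
#' @export
read_pubtator <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur <- NULL
  flush_doc <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$title)) stop("document ", cur$doc_id, ": missing |t| line")
    m <- if (length(cur$ment)) do.call(rbind, cur$ment) else empty_mentions()
    r <- if (length(cur$rel)) do.call(rbind, cur$rel) else relation_table()
    cdr_document(cur$doc_id, cur$title, cur$abstract %||% "", m, r)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) {
      d <- flush_doc(cur)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      cur <- NULL
      next
    }
    tpos <- regexpr("|t|", line, fixed = TRUE)
    apos <- regexpr("|a|", line, fixed = TRUE)
    if (tpos > 0L || apos > 0L) {
      pos <- if (tpos > 0L) tpos else apos
      id <- substr(line, 1L, pos - 1L)
      txt <- substr(line, pos + 3L, nchar(line))
      if (!nzchar(id)) stop("line ", ln, ": empty document id")
      if (is.null(cur)) cur <- list(doc_id = id, ment = list(), rel = list())
      if (id != cur$doc_id) stop("line ", ln, ": document id changed within block")
      if (tpos > 0L) cur$title <- txt else cur$abstract <- txt
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (is.null(cur)) stop("line ", ln, ": annotation before any |t| line")
    if (length(f) >= 4L && f[2] == "CID") {
      if (length(f) < 4L) stop("line ", ln, ": malformed relation line")
      cur$rel[[length(cur$rel) + 1L]] <- relation_table(f[3], f[4])
    } else if (length(f) >= 6L) {
      s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e)) stop("line ", ln, ": non-numeric offsets")
      if (e <= s) stop("line ", ln, ": mention end <= start")
      if (!f[5] %in% c("Chemical", "Disease"))
        stop("line ", ln, ": unknown entity type ", dQuote(f[5]))
      cur$ment[[length(cur$ment) + 1L]] <- mention_table(s, e, f[4], f[5], f[6])
    } else {
      stop("line ", ln, ": malformed annotation line (", length(f), " fields)")
    }
  }
  d <- flush_doc(cur)
  if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  docs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write documents in PubTator format
#'
#' Inverse of [read_pubtator()]: round-tripping a valid document list
#' reproduces it field for field. Composite concept IDs are re-joined
#' with `"|"`.
#'
#' @param docs list of `cdr_document`.
#' @param path output file path.
#' @export
write_pubtator <- function(docs, path) {
  out <- character()
  for (doc in docs) {
    out <- c(out, paste0(doc$doc_id, "|t|", doc$title),
             paste0(doc$doc_id, "|a|", doc$abstract))
    m <- doc$mentions
    if (nrow(m)) {
      ids <- vapply(m$concept_ids, paste, "", collapse = "|")
      out <- c(out, paste(doc$doc_id, m$start, m$end, m$text, m$type, ids, sep = "\t"))
    }
    r <- doc$relations
    if (nrow(r)) {
      out <- c(out, paste(doc$doc_id, "CID", r$chemical_id, r$disease_id, sep = "\t"))
    }
    out <- c(out, "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = FALSE)
  invisible(NULL)
}

#' Segment a document into sentences and tokens
#'
#' Applies the package's deterministic sentence splitter and tokenizer to
#' the document full text; every token carries PoS tag and stem.
#'
#' @param doc a `cdr_document`.
#' @return list of sentences, each `list(index, start, end, tokens)` with
#'   0-based offsets into [doc_text()].
#' @export
segment <- function(doc) {
  full <- doc_text(doc)
  sent <- split_sentences(full)
  lapply(seq_len(nrow(sent)), function(i) {
    s <- sent$start[i]; e <- sent$end[i]
    toks <- tokenize(substr_off(full, s, e), base = s)
    list(index = i - 1L, start = s, end = e, tokens = toks)
  })
}

#' Resolve overlapping mention spans
#'
#' Keeps the longer of any two overlapping mentions; on equal length the
#' earlier one wins. BIO tagging cannot represent overlaps, so this rule is
#' applied before encoding.
#'
#' @param mentions mention table.
#' @return mention table without span overlaps, ordered by start.
#' @export
resolve_overlaps <- function(mentions) {
  if (nrow(mentions) <= 1L) return(mentions)
  ord <- order(-(mentions$end - mentions$start), mentions$start)
  kept <- integer()
  for (i in ord) {
    clash <- any(mentions$start[kept] < mentions$end[i] &
                 mentions$end[kept] > mentions$start[i])
    if (!clash) kept <- c(kept, i)
  }
  mentions[sort(kept), , drop = FALSE]
}

.bio_label <- function(type) c(Chemical = "C", Disease = "D")[[type]]

#' Encode sentence mentions as BIO labels
#'
#' Labels are `B-C`/`I-C` for chemicals, `B-D`/`I-D` for diseases and `O`
#' elsewhere. Mentions whose boundaries fall inside a token are snapped
#' outward to the covering tokens. Overlapping mentions are first resolved
#' by [resolve_overlaps()]; if survivors still collide on a token, an error
#' is raised.
#'
#' @param sentence one element of [segment()] output.
#' @param mentions mention table (document-wide; rows outside the sentence
#'   are ignored).
#' @return character vector of labels, one per token.
#' @export
encode_bio <- function(sentence, mentions) {
  toks <- sentence$tokens
  labels <- rep("O", nrow(toks))
  if (!nrow(toks) || !nrow(mentions)) return(labels)
  inside <- mentions$start < sentence$end & mentions$end > sentence$start
  mentions <- resolve_overlaps(mentions[inside, , drop = FALSE])
  for (i in seq_len(nrow(mentions))) {
    cover <- which(toks$start < mentions$end[i] & toks$end > mentions$start[i])
    if (!length(cover)) next
    if (any(labels[cover] != "O"))
      stop("overlapping mentions after resolution in sentence ", sentence$index)
    suf <- .bio_label(mentions$type[i])
    labels[cover] <- paste0("I-", suf)
    labels[cover[1]] <- paste0("B-", suf)
  }
  labels
}

#' Decode BIO labels into mentions
#'
#' Maximal `B-*`/`I-*` runs become mentions spanning the first to the last
#' covered token. Malformed sequences (`I-*` following `O` or a different
#' type) are repaired by treating the stray `I-*` as `B-*`, so the decoder
#' is total.
#'
#' @param sentence one element of [segment()] output.
#' @param labels character vector, one label per token.
#' @param full_text the document full text (for mention surface strings).
#' @return mention table (concept IDs all `"-1"`, i.e. not yet normalized).
#' @export
decode_bio <- function(sentence, labels, full_text) {
  toks <- sentence$tokens
  stopifnot(length(labels) == nrow(toks))
  out <- empty_mentions()
  cur_type <- NULL; cur_first <- NA_integer_; cur_last <- NA_integer_
  flush <- function() {
    if (is.null(cur_type)) return()
    type <- c(C = "Chemical", D = "Disease")[[cur_type]]
    s <- toks$start[cur_first]; e <- toks$end[cur_last]
    out <<- rbind(out, mention_table(s, e, substr_off(full_text, s, e), type, "-1"))
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") { flush(); cur_type <- NULL; next }
    tag <- substr(lab, 1L, 1L); typ <- substr(lab, 3L, 3L)
    continues <- tag == "I" && !is.null(cur_type) && identical(cur_type, typ)
    if (continues) {
      cur_last <- i
    } else {   # B-*, or repaired stray I-*
      flush()
      cur_type <- typ; cur_first <- i; cur_last <- i
    }
  }
  flush()
  out
}
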