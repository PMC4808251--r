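# Shared fixtures, built in code and memoized within one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 7, n_docs = 12, ...) {
  key <- paste(seed, n_docs, ..., sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture(fixture_spec(seed = seed,
                                                       n_docs = n_docs, ...))
  .fixture_cache[[key]]
}

# build a document from sentence part lists: parts are plain strings or
# ment("text", "Chemical", "D...") mention slots; first sentence is the title
ment <- function(text, type, id) list(text = text, type = type, id = id)

plant_doc <- function(doc_id, sentences, relations = relation_table()) {
  render <- function(parts, base) {
    text <- ""
    rows <- empty_mentions()
    for (p in parts) {
      if (is.character(p)) text <- paste0(text, p)
      else {
        s <- base + nchar(text)
        text <- paste0(text, p$text)
        rows <- rbind(rows, mention_table(s, s + nchar(p$text), p$text,
                                          p$type, p$id))
      }
    }
    list(text = text, mentions = rows)
  }
  t <- render(sentences[[1]], 0L)
  mentions <- t$mentions
  abstract <- ""
  base <- nchar(t$text) + 1L
  for (s in sentences[-1]) {
    if (nzchar(abstract)) abstract <- paste0(abstract, " ")
    r <- render(s, base + nchar(abstract))
    abstract <- paste0(abstract, r$text)
    mentions <- rbind(mentions, r$mentions)
  }
  cdr_document(doc_id, t$text, abstract, mentions, relations)
}

# quick micro P/R/F over two character vectors of item keys (oracle path)
oracle_prf <- function(gold, pred) {
  gold <- unique(gold); pred <- unique(pred)
  tp <- length(intersect(gold, pred))
  p <- if (length(pred)) tp / length(pred) else 0
  r <- if (length(gold)) tp / length(gold) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  if (!length(gold) && !length(pred)) p <- r <- f <- 1
  list(precision = p, recall = r, f1 = f)
}
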