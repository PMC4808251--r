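#' @useDynLib cidrex, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Deterministic rule-based text preprocessing. All offsets in this package are
# 0-based character offsets with exclusive ends, matching the PubTator
# convention; substr_off() converts to R's 1-based inclusive indexing.

substr_off <- function(x, start, end) substr(x, start + 1L, end)

#' Tokenize a string into offset-carrying tokens
#'
#' Splits on whitespace, then into maximal runs of letters, runs of digits,
#' and single punctuation characters, so hyphenated words like
#' `"Lithium-induced"` become three tokens (`"Lithium"`, `"-"`, `"induced"`).
#' The rule set is fixed; identical input always yields identical tokens.
#'
#' @param text character scalar.
#' @param base integer offset added to all token offsets (0-based).
#' @return data.frame with columns `start`, `end` (0-based, end exclusive),
#'   `text`, `pos`, `stem`.
#' @export
tokenize <- function(text, base = 0L) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      pos = character(), stem = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z]+|[0-9]+|[^A-Za-z0-9[:space:]]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      pos = character(), stem = character(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  start <- as.integer(m) - 1L + base
  end <- start + as.integer(len)
  tok <- substring(text, as.integer(m), as.integer(m) + len - 1L)
  data.frame(start = start, end = end, text = tok,
             pos = pos_tag(tok), stem = stem_word(tok),
             stringsAsFactors = FALSE)
}

#' Light suffix-stripping stemmer
#'
#' A small deterministic stemmer: lowercases, then strips plural and common
#' inflectional suffixes (`-sses`, `-ies`, `-s`, `-ing`, `-ed`) with minimal
#' stem-length guards. It is intentionally conservative: the normalization
#' index and the query side share the same stemmer, which is all that vector
#' space matching requires.
#'
#' @param w character vector of tokens.
#' @return character vector of stems.
#' @export
stem_word <- function(w) {
  s <- tolower(w)
  n <- nchar(s)
  out <- s
  i <- endsWith(s, "sses")
  out[i] <- substr(s[i], 1L, n[i] - 2L)
  j <- !i & endsWith(s, "ies") & n > 3L
  out[j] <- paste0(substr(s[j], 1L, n[j] - 3L), "y")
  k <- !i & !j & endsWith(s, "s") & !endsWith(s, "ss") & !endsWith(s, "us") & n > 3L
  out[k] <- substr(s[k], 1L, n[k] - 1L)
  n2 <- nchar(out)
  g <- endsWith(out, "ing") & n2 > 6L
  out[g] <- substr(out[g], 1L, n2[g] - 3L)
  n3 <- nchar(out)
  h <- endsWith(out, "ed") & n3 > 5L
  out[h] <- substr(out[h], 1L, n3[h] - 2L)
  out
}

.closed_class <- list(
  DT = c("the", "a", "an", "this", "that", "these", "those", "each", "no"),
  IN = c("in", "of", "on", "at", "by", "with", "for", "from", "to", "into",
         "during", "after", "before", "between", "while", "under", "over"),
  CC = c("and", "or", "but", "nor"),
  PRP = c("he", "she", "it", "they", "we", "i", "you"),
  MD = c("may", "can", "could", "should", "would", "must", "might"),
  VB = c("is", "are", "was", "were", "be", "been", "being", "has", "have",
         "had", "developed", "received", "showed", "remained")
)

#' Heuristic part-of-speech tagger
#'
#' Assigns coarse Penn-style tags from closed-class word lists and suffix
#' rules (`-ed` -> VBD, `-ing` -> VBG, `-ly` -> RB, adjectival suffixes -> JJ,
#' digits -> CD, punctuation -> PUNCT, plural nouns -> NNS, default NN). The
#' tagger is deterministic and context-free; tags feed the CRF as categorical
#' features, where self-consistency matters more than linguistic fidelity.
#'
#' @param w character vector of tokens.
#' @return character vector of tags.
#' @export
pos_tag <- function(w) {
  lw <- tolower(w)
  tags <- rep("NN", length(w))
  tags[grepl("^[0-9]+$", w)] <- "CD"
  tags[grepl("^[^A-Za-z0-9]+$", w)] <- "PUNCT"
  alpha <- grepl("^[A-Za-z]+$", w)
  for (tag in names(.closed_class)) {
    tags[alpha & lw %in% .closed_class[[tag]]] <- tag
  }
  open <- alpha & tags == "NN"
  tags[open & endsWith(lw, "ly")] <- "RB"
  tags[open & endsWith(lw, "ing") & nchar(lw) > 4L] <- "VBG"
  tags[open & endsWith(lw, "ed") & nchar(lw) > 3L] <- "VBD"
  open <- alpha & tags == "NN"
  adj <- endsWith(lw, "al") | endsWith(lw, "ous") | endsWith(lw, "ive") |
    endsWith(lw, "ic") | endsWith(lw, "able")
  tags[open & adj & nchar(lw) > 4L] <- "JJ"
  open <- alpha & tags == "NN"
  tags[open & endsWith(lw, "s") & !endsWith(lw, "ss") & nchar(lw) > 3L] <- "NNS"
  tags
}

#' Split text into sentences with character offsets
#'
#' Sentence boundaries are placed after `.`, `!` or `?` followed by
#' whitespace; trailing text forms the final sentence. Leading whitespace is
#' trimmed from each sentence span. Deterministic by construction.
#'
#' @param text character scalar.
#' @return data.frame with 0-based `start`, `end` offsets per sentence.
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer()))
  }
  n <- nchar(text)
  m <- gregexpr("[.!?](?=\\s)", text, perl = TRUE)[[1]]
  bounds <- if (m[1] == -1L) integer() else as.integer(m)  # 1-based pos of terminator
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(start = integer(), end = integer())
  for (i in seq_along(starts)) {
    seg <- substr(text, starts[i], ends[i])
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s0 <- starts[i] + lead - 1L        # 0-based
    e0 <- ends[i] - trail              # exclusive
    if (e0 > s0) out <- rbind(out, data.frame(start = s0, end = e0))
  }
  out
}
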