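# Per-token feature extraction for the NER CRFs: five feature groups —
# word-level, dictionary lookup, contextual n-grams, chemical/disease domain
# clues, and distributed word-representation (embedding) features.

.flag <- function(x) stats::setNames(rep(1, length(x)), x)

#' Case-shape pattern of a token
#'
#' Maps uppercase letters to `A`, lowercase to `a`, digits to `0` and keeps
#' any other character, so `"Ca2+"` becomes `"Aa0+"`.
#' @param w character vector.
#' @return character vector of shapes.
#' @export
case_shape <- function(w) {
  x <- gsub("[A-Z]", "A", w)
  x <- gsub("[a-z]", "a", x)
  gsub("[0-9]", "0", x)
}

.char_ngrams <- function(w, nmin = 2L, nmax = 4L) {
  n <- nchar(w)
  out <- character()
  for (k in nmin:nmax) {
    if (n < k) break
    out <- c(out, substring(w, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  unique(out)
}

#' Word-level features of one token
#'
#' Lowercased word, stem, PoS tag, case-shape pattern, character n-grams
#' (n = 2..4) and prefixes/suffixes of length 1..5, plus a constant bias
#' feature.
#'
#' @param sentence one element of [segment()] output.
#' @param i 1-based token index.
#' @return named numeric feature vector (all values 1).
#' @export
word_features <- function(sentence, i) {
  toks <- sentence$tokens
  stopifnot(i >= 1L, i <= nrow(toks))
  w <- toks$text[i]; lw <- tolower(w); n <- nchar(w)
  k <- seq_len(min(5L, n))
  .flag(c("bias",
          paste0("w=", lw),
          paste0("stem=", toks$stem[i]),
          paste0("pos=", toks$pos[i]),
          paste0("shape=", case_shape(w)),
          paste0("ng=", .char_ngrams(lw)),
          unique(paste0("pre=", substring(lw, 1L, k))),
          unique(paste0("suf=", substring(lw, n - k + 1L, n)))))
}

#' Read a semantic lexicon
#' @param path TSV `term<TAB>semantic_tag`, terms may be multi-word.
#' @return object of class `ner_lexicon` (also accepted: a named character
#'   vector term -> tag via [ner_lexicon()]).
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, col.names = c("term", "tag"),
                           colClasses = "character", quote = "")
  ner_lexicon(stats::setNames(tab$tag, tab$term))
}

#' Build a semantic lexicon object
#' @param entries named character vector: lowercased term -> semantic tag.
#' @return `ner_lexicon` with entries pre-tokenized for longest-match lookup.
#' @export
ner_lexicon <- function(entries) {
  terms <- tolower(names(entries))
  tokenized <- lapply(terms, function(t) tolower(tokenize(t)$text))
  keys <- vapply(tokenized, paste, "", collapse = " ")
  structure(list(map = stats::setNames(as.character(entries), keys),
                 max_len = if (length(tokenized)) max(lengths(tokenized)) else 0L),
            class = "ner_lexicon")
}

#' Dictionary-based semantic tags for a sentence
#'
#' Greedy longest-match left-to-right over the token sequence: each matched
#' span is tagged `B-<tag>`/`I-<tag>`, all other tokens `NONE`.
#'
#' @param sentence one element of [segment()] output.
#' @param lexicon a `ner_lexicon`.
#' @return character vector of semantic tags, one per token.
#' @export
dict_features <- function(sentence, lexicon) {
  toks <- tolower(sentence$tokens$text)
  n <- length(toks)
  tags <- rep("NONE", n)
  if (!n || !length(lexicon$map)) return(tags)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq.int(min(lexicon$max_len, n - i + 1L), 1L)) {
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      tag <- unname(lexicon$map[key])
      if (!is.na(tag)) {
        tags[i:(i + len - 1L)] <- paste0("I-", tag)
        tags[i] <- paste0("B-", tag)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  tags
}

#' Contextual n-gram features around one token
#'
#' Bi- and tri-grams of word, stem, PoS tag and semantic tag drawn from a
#' window of +/- `window` tokens around position `i`, with positional
#' prefixes; slots beyond the sentence boundary carry the symbol `"<S>"`.
#' For the default window of 2 this yields 7 n-grams per stream (4 bigrams,
#' 3 trigrams) and 28 features in total, independent of position.
#'
#' @param sentence one element of [segment()] output.
#' @param i 1-based token index.
#' @param tags per-token semantic tags from [dict_features()] (or `NULL`).
#' @param window window half-width (>= 0).
#' @return named numeric feature vector.
#' @export
context_features <- function(sentence, i, tags = NULL, window = 2L) {
  toks <- sentence$tokens
  n <- nrow(toks)
  stopifnot(i >= 1L, i <= n, window >= 0L)
  if (is.null(tags)) tags <- rep("NONE", n)
  at <- function(stream, j) {
    out <- rep("<S>", length(j))
    ok <- j >= 1L & j <= n
    out[ok] <- stream[j[ok]]
    out
  }
  streams <- list(w = tolower(toks$text), s = toks$stem, p = toks$pos, t = tags)
  feats <- character()
  offs <- seq.int(-window, window)
  for (nm in names(streams)) {
    st <- streams[[nm]]
    for (k in 2:3) {
      if (length(offs) < k) next
      for (a in seq_len(length(offs) - k + 1L)) {
        rel <- offs[a:(a + k - 1L)]
        vals <- at(st, i + rel)
        feats <- c(feats, paste0("ctx:", nm, ":", paste(rel, collapse = ","),
                                 "=", paste(vals, collapse = "|")))
      }
    }
  }
  .flag(feats)
}

.disease_suffixes <- c("algia", "emia", "itis", "osis", "pathy", "oma",
                       "uria", "penia")
.disease_prefixes <- c("ab", "hemo", "hyper", "hypo", "dys", "a")
.element_names <- c("hydrogen", "helium", "lithium", "carbon", "nitrogen",
                    "oxygen", "sodium", "magnesium", "phosphorus", "sulfur",
                    "chlorine", "potassium", "calcium", "iron", "copper",
                    "zinc", "selenium", "platinum", "gold", "mercury", "lead")
.amino_acids <- c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
                  "glutamine", "glutamate", "glycine", "histidine",
                  "isoleucine", "leucine", "lysine", "methionine",
                  "phenylalanine", "proline", "serine", "threonine",
                  "tryptophan", "tyrosine", "valine")
.greek <- c("alpha", "beta", "gamma", "delta", "epsilon", "kappa", "lambda",
            "omega", "α", "β", "γ", "δ")

#' Domain affix and chemical-pattern features of one token
#'
#' Binary flags: membership of the token's ending in a configurable disease
#' suffix list (defaults include `-algia`, `-emia`) and of its beginning in
#' a disease prefix list (defaults include `ab-`, `hemo-`), plus a set of
#' chemical-likeness clues (chemical element name, amino-acid name, a
#' chemical-formula-like shape, digit/uppercase/hyphen counts, Greek-letter
#' flag).
#'
#' @param token token surface string.
#' @param disease_suffixes,disease_prefixes character vectors (no dash).
#' @return named numeric feature vector.
#' @export
domain_affix_features <- function(token,
                                  disease_suffixes = .disease_suffixes,
                                  disease_prefixes = .disease_prefixes) {
  lw <- tolower(token)
  f <- numeric(0)
  if (any(vapply(disease_suffixes, function(s) endsWith(lw, s), TRUE)))
    f <- c(f, .flag("has_disease_suffix"))
  if (any(vapply(disease_prefixes, function(p)
      startsWith(lw, p) && nchar(lw) > nchar(p) + 2L, TRUE)))
    f <- c(f, .flag("has_disease_prefix"))
  if (lw %in% .element_names) f <- c(f, .flag("is_element"))
  if (lw %in% .amino_acids) f <- c(f, .flag("is_amino_acid"))
  if (grepl("^([A-Z][a-z]?[0-9]*)+[+-]?$", token) && grepl("[0-9]", token) &&
      nchar(token) >= 2L)
    f <- c(f, .flag("formula_like"))
  nd <- lengths(regmatches(token, gregexpr("[0-9]", token)))
  nu <- lengths(regmatches(token, gregexpr("[A-Z]", token)))
  nh <- lengths(regmatches(token, gregexpr("-", token, fixed = TRUE)))
  if (nd > 0) f <- c(f, stats::setNames(nd, "n_digits"))
  if (nu > 0) f <- c(f, stats::setNames(nu, "n_upper"))
  if (nh > 0) f <- c(f, stats::setNames(nh, "n_hyphens"))
  if (lw %in% .greek) f <- c(f, .flag("greek_letter"))
  f
}

#' Read a word2vec-format embedding table
#'
#' Text format: a header line `n d`, then one line per word,
#' `word v1 ... vd`. Lookup is case-folded; out-of-vocabulary words map to
#' the zero vector.
#'
#' @param path embedding file path.
#' @return object of class `embedding_table`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("malformed embedding header line")
  d <- hdr[2]
  body <- lines[-1][nzchar(lines[-1])]
  parts <- strsplit(trimws(body), "\\s+")
  words <- tolower(vapply(parts, `[`, "", 1L))
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  if (any(lengths(vecs) != d))
    stop("embedding dimension mismatch: expected ", d)
  names(vecs) <- words
  structure(list(vectors = vecs, dim = d), class = "embedding_table")
}

#' Embedding features of one token
#'
#' One real-valued feature per dimension, `emb_k -> v_k`, for the
#' case-folded token; out-of-vocabulary tokens (and a `NULL` table)
#' contribute nothing, equivalent to a zero vector.
#'
#' @param token token surface string.
#' @param table an `embedding_table` or `NULL`.
#' @return named numeric feature vector.
#' @export
embedding_features <- function(token, table) {
  if (is.null(table)) return(numeric(0))
  v <- table$vectors[[tolower(token)]]
  if (is.null(v)) return(numeric(0))
  stats::setNames(v, paste0("emb_", seq_along(v) - 1L))
}

#' Assemble the full per-token feature map for the CRF
#'
#' Concatenates the enabled feature groups of a [ner_config()].
#'
#' @param sentence one element of [segment()] output.
#' @param i 1-based token index.
#' @param config a `ner_config`.
#' @param tags semantic tags for the sentence (from [dict_features()]).
#' @param embeddings an `embedding_table` or `NULL`.
#' @return named numeric feature vector.
#' @export
token_features <- function(sentence, i, config, tags = NULL, embeddings = NULL) {
  f <- if (config$use_word) word_features(sentence, i)
       else .flag(c("bias", paste0("w=", tolower(sentence$tokens$text[i]))))
  if (config$use_dict && !is.null(tags))
    f <- c(f, .flag(paste0("sem=", tags[i])))
  if (config$use_context)
    f <- c(f, context_features(sentence, i, tags, config$window))
  if (config$use_affix)
    f <- c(f, domain_affix_features(sentence$tokens$text[i],
                                    config$disease_suffixes,
                                    config$disease_prefixes))
  if (config$use_embedding)
    f <- c(f, embedding_features(sentence$tokens$text[i], embeddings))
  f
}
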