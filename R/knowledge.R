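# MeSH tree-number algebra and knowledge-base relation lookups.
#
# Tree numbers are dot-separated hierarchical codes (e.g. "C10.597.606");
# every proper prefix is an ancestor (hypernym). Knowledge-base tables map a
# directed (chemical, disease) MeSH ID pair to a relation label; an absent
# pair means no known relation (NULL).

.kb_alphabets <- list(
  MEDI        = "treatment",
  MEDI_HP     = "treatment",
  SIDER       = c("treatment", "adverse-drug-reaction"),
  SIDER_FAERS = c("treatment", "adverse-drug-reaction"),
  CTD         = c("inferred-association", "therapeutic", "marker/mechanism")
)

#' Read a MeSH tree-number table
#'
#' @param path TSV with columns `mesh_id<TAB>tree_number1|tree_number2|...`.
#' @return object of class `mesh_tree`: a named list mapping MeSH ID to its
#'   character vector of tree numbers.
#' @export
read_mesh_tree <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, col.names = c("mesh_id", "tns"),
                           colClasses = "character", quote = "")
  tns <- strsplit(tab$tns, "|", fixed = TRUE)
  names(tns) <- tab$mesh_id
  mesh_tree(tns)
}

#' Build a MeSH tree object from an ID -> tree-number mapping
#' @param mapping named list: MeSH ID -> character vector of tree numbers.
#' @return `mesh_tree` object.
#' @export
mesh_tree <- function(mapping) {
  stopifnot(is.list(mapping), !is.null(names(mapping)))
  ok <- vapply(mapping, function(x) length(x) >= 1L &&
                 all(grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", x)), TRUE)
  if (!all(ok)) stop("malformed tree number(s) for: ",
                     paste(names(mapping)[!ok], collapse = ", "))
  structure(mapping, class = "mesh_tree")
}

#' Hypernym codes of a tree number
#'
#' All proper prefixes of a dot-separated tree number, shortest first; the
#' code itself is excluded. For example `"C10.597.606.525.100"` yields
#' `"C10"`, `"C10.597"`, `"C10.597.606"` and `"C10.597.606.525"` — the
#' direct and indirect hypernym categories of the concept.
#'
#' @param tn tree-number string.
#' @return character vector of ancestor codes (empty for a root code).
#' @export
hypernym_codes <- function(tn) {
  if (!grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", tn))
    stop("malformed tree number: ", dQuote(tn))
  parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) return(character())
  vapply(seq_len(length(parts) - 1L),
         function(k) paste(parts[seq_len(k)], collapse = "."), "")
}

#' Category codes of a concept
#'
#' Union of [hypernym_codes()] over all of the concept's tree numbers.
#' @param mesh_id concept ID.
#' @param tree a `mesh_tree`.
#' @return character vector of codes (empty, with a warning, for unknown IDs).
#' @export
concept_categories <- function(mesh_id, tree) {
  tns <- tree[[mesh_id]]
  if (is.null(tns)) {
    warning("unknown MeSH id: ", mesh_id)
    return(character())
  }
  unique(unlist(lapply(tns, hypernym_codes), use.names = FALSE)) %||% character()
}

#' Is concept a more specific than concept b?
#'
#' TRUE iff some tree number of `id_a` has a proper prefix equal to some
#' tree number of `id_b` — i.e. `id_a` sits strictly below `id_b` somewhere
#' in the hierarchy (as retrograde amnesia, C10.597.606.525.100.150, sits
#' below amnesia, C10.597.606.525.100).
#'
#' @param id_a,id_b MeSH IDs.
#' @param tree a `mesh_tree`.
#' @return logical scalar (FALSE if either ID is unknown).
#' @export
is_more_specific <- function(id_a, id_b, tree) {
  ta <- tree[[id_a]]; tb <- tree[[id_b]]
  if (is.null(ta) || is.null(tb)) return(FALSE)
  for (a in ta) {
    anc <- hypernym_codes(a)
    if (any(tb %in% anc)) return(TRUE)
  }
  FALSE
}

#' Disease specificity flags within a document
#'
#' For a target disease, reports whether any other disease mentioned in the
#' document is more specific (a hyponym) or more general (a hypernym) than
#' it. Unknown IDs yield `(FALSE, FALSE)`.
#'
#' @param disease_id target disease MeSH ID.
#' @param doc_disease_ids all disease IDs in the document.
#' @param tree a `mesh_tree`.
#' @return named logical vector `c(has_more_specific=, has_more_general=)`.
#' @export
disease_specificity_flags <- function(disease_id, doc_disease_ids, tree) {
  others <- setdiff(doc_disease_ids, disease_id)
  spec <- any(vapply(others, is_more_specific, TRUE, id_b = disease_id, tree = tree))
  gen <- any(vapply(others, function(o) is_more_specific(disease_id, o, tree), TRUE))
  c(has_more_specific = isTRUE(spec), has_more_general = isTRUE(gen))
}

#' Read a knowledge-base relation table
#'
#' @param path TSV with columns `chemical_id<TAB>disease_id<TAB>label`.
#' @param source one of `"MEDI"`, `"MEDI_HP"`, `"SIDER"`, `"SIDER_FAERS"`,
#'   `"CTD"`; fixes the admissible label alphabet.
#' @return object of class `kb_table`.
#' @export
read_kb_table <- function(path, source) {
  tab <- if (file.size(path) == 0) {
    data.frame(chemical_id = character(), disease_id = character(),
               label = character())
  } else {
    utils::read.delim(path, header = FALSE,
                      col.names = c("chemical_id", "disease_id", "label"),
                      colClasses = "character", quote = "")
  }
  kb_table(tab, source)
}

#' Build a knowledge-base table object
#' @param pairs data.frame with `chemical_id`, `disease_id`, `label`.
#' @param source KB source name (fixes the label alphabet).
#' @return `kb_table` object.
#' @export
kb_table <- function(pairs, source) {
  source <- match.arg(source, names(.kb_alphabets))
  bad <- setdiff(unique(pairs$label), .kb_alphabets[[source]])
  if (length(bad))
    stop("label(s) outside the ", source, " alphabet: ", paste(bad, collapse = ", "))
  lookup <- pairs$label
  names(lookup) <- paste(pairs$chemical_id, pairs$disease_id, sep = "\r")
  structure(list(source = source, pairs = pairs, lookup = lookup),
            class = "kb_table")
}

#' @export
print.kb_table <- function(x, ...) {
  cat("<kb_table ", x$source, ": ", nrow(x$pairs), " pair(s)>\n", sep = "")
  invisible(x)
}

#' Look up the KB relation of a (chemical, disease) pair
#'
#' Exact directed-pair lookup; an absent pair returns `NULL`.
#' @param chemical_id,disease_id MeSH IDs.
#' @param table a `kb_table`.
#' @return label string or `NULL`.
#' @export
kb_relation <- function(chemical_id, disease_id, table) {
  lab <- unname(table$lookup[paste(chemical_id, disease_id, sep = "\r")])
  if (length(lab) != 1L || is.na(lab)) NULL else lab
}

#' Is a disease a known adverse drug reaction in SIDER?
#'
#' TRUE iff any chemical pairs with the disease under the
#' `adverse-drug-reaction` label.
#' @param disease_id MeSH ID.
#' @param sider a SIDER `kb_table`.
#' @return logical scalar.
#' @export
is_adr <- function(disease_id, sider) {
  any(sider$pairs$disease_id == disease_id &
        sider$pairs$label == "adverse-drug-reaction")
}

#' Is a disease chemically induced according to CTD?
#'
#' TRUE iff any chemical pairs with the disease under the `marker/mechanism`
#' label.
#' @param disease_id MeSH ID.
#' @param ctd a CTD `kb_table`.
#' @return logical scalar.
#' @export
is_induced <- function(disease_id, ctd) {
  any(ctd$pairs$disease_id == disease_id & ctd$pairs$label == "marker/mechanism")
}

#' Default trigger-term lexicons
#'
#' `terms_i` are induced-relation triggers looked for between a chemical and
#' a disease mention; `terms_h` are holder terms (the bearer of the disease)
#' looked for in the sentence containing the disease. Both user-overridable.
#' @return list with lowercased character vectors `terms_i` and `terms_h`.
#' @export
default_triggers <- function() {
  list(terms_i = c("caused", "causes", "cause", "induced", "induces", "induce",
                   "produced", "resulted", "triggered"),
       terms_h = c("patient", "patients", "groups", "group", "rats", "subjects",
                   "mice"))
}

#' Read trigger lexicons from files
#'
#' @param terms_i_path,terms_h_path one lowercased term per line.
#' @return list as in [default_triggers()].
#' @export
read_triggers <- function(terms_i_path, terms_h_path) {
  rd <- function(p) tolower(trimws(readLines(p, warn = FALSE)))
  list(terms_i = Filter(nzchar, rd(terms_i_path)),
       terms_h = Filter(nzchar, rd(terms_h_path)))
}
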