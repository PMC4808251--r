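# Command-line pipeline: wires simulation, NER training/prediction,
# normalization, relation training and end-to-end extraction into
# subcommands. cidrex_main() is the testable entry point; the Rscript
# wrapper installed at inst/cli/cidrex.R just forwards to it.

.usage <- paste(
  "usage: cidrex <subcommand> [--flag value ...]",
  "",
  "subcommands:",
  "  simulate   --out DIR [--seed N] [--n-docs N] [--cross-sentence-frac X]",
  "  train-ner  --corpus FILE --out DIR [--mode separate|unified]",
  "             [--lexicon FILE] [--embeddings FILE] [--max-iter N] [--seed N]",
  "  ner        --model DIR --corpus FILE --out FILE",
  "  normalize  --corpus FILE --dictionary FILE --out FILE",
  "  train-rel  --corpus FILE --dictionary FILE --out DIR [--kb-dir DIR]",
  "             [--seed N]",
  "  extract    --model DIR --corpus FILE --dictionary FILE --out FILE",
  "             [--kb-dir DIR] [--strategy union|cs|cd]",
  "  eval       --gold FILE --pred FILE [--out FILE]",
  sep = "\n")

.parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    if (i + 1L > length(argv)) stop("missing value for ", a, call. = FALSE)
    flags[[substring(a, 3L)]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

.need <- function(flags, name) {
  v <- flags[[name]]
  if (is.null(v)) stop("missing required flag --", name, call. = FALSE)
  v
}

.need_file <- function(flags, name) {
  v <- .need(flags, name)
  if (!file.exists(v)) {
    message("error: no such file or directory: ", v)
    stop(structure(class = c("cidrex_missing_input", "error", "condition"),
                   list(message = v, call = NULL)))
  }
  v
}

.log <- function(...) message("[cidrex] ", ...)

#' Load a knowledge bundle from a fixture/KB directory
#'
#' Expects `mesh_tree.tsv` and any of `kb_medi.tsv`, `kb_medi_hp.tsv`,
#' `kb_sider.tsv`, `kb_sider_faers.tsv`, `kb_ctd.tsv`; missing tables
#' simply disable their features.
#'
#' @param dir directory path.
#' @return knowledge bundle list as used by the relation feature builders.
#' @export
load_kb_bundle <- function(dir) {
  pick <- function(f, source) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_kb_table(p, source) else NULL
  }
  tree_path <- file.path(dir, "mesh_tree.tsv")
  list(tree = if (file.exists(tree_path)) read_mesh_tree(tree_path) else NULL,
       medi = pick("kb_medi.tsv", "MEDI"),
       medi_hp = pick("kb_medi_hp.tsv", "MEDI_HP"),
       sider = pick("kb_sider.tsv", "SIDER"),
       sider_faers = pick("kb_sider_faers.tsv", "SIDER_FAERS"),
       ctd = pick("kb_ctd.tsv", "CTD"))
}

.load_indexes <- function(dict_path) {
  dict <- read_concept_dictionary(dict_path)
  list(chem = build_concept_index(dict, "Chemical"),
       dis = build_concept_index(dict, "Disease"))
}

.cmd_simulate <- function(flags) {
  out <- .need(flags, "out")
  spec <- fixture_spec(
    seed = as.integer(flags[["seed"]] %||% 1L),
    n_docs = as.integer(flags[["n-docs"]] %||% 20L),
    cross_sentence_frac = as.numeric(flags[["cross-sentence-frac"]] %||% 0.3))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fx <- make_fixture(spec, dir = out)
  .log("simulate: wrote ", length(fx$docs), " documents and fixtures to ", out)
  0L
}

.cmd_train_ner <- function(flags) {
  corpus <- .need_file(flags, "corpus")
  out <- .need(flags, "out")
  docs <- read_pubtator(corpus)
  cfg <- ner_config(mode = flags[["mode"]] %||% "separate",
                    max_iter = as.integer(flags[["max-iter"]] %||% 200L),
                    seed = as.integer(flags[["seed"]] %||% 1L))
  lex <- if (!is.null(flags[["lexicon"]])) read_lexicon(.need_file(flags, "lexicon"))
  emb <- if (!is.null(flags[["embeddings"]]))
    read_embeddings(.need_file(flags, "embeddings"))
  model <- train_ner(docs, cfg, lexicon = lex, embeddings = emb)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(out, "ner.rds"))
  .log("train-ner: mode=", cfg$mode, ", ", length(docs),
       " documents -> ", file.path(out, "ner.rds"))
  0L
}

.cmd_ner <- function(flags) {
  model_dir <- .need_file(flags, "model")
  corpus <- .need_file(flags, "corpus")
  out <- .need(flags, "out")
  model_path <- file.path(model_dir, "ner.rds")
  if (!file.exists(model_path)) {
    message("error: no trained NER model at ", model_path)
    return(1L)
  }
  model <- readRDS(model_path)
  docs <- read_pubtator(corpus)
  pred <- lapply(docs, function(d) {
    m <- predict_mentions(model, d)
    cdr_document(d$doc_id, d$title, d$abstract, m, relation_table())
  })
  write_pubtator(pred, out)
  .log("ner: ", sum(vapply(pred, function(d) nrow(d$mentions), 0L)),
       " mentions over ", length(docs), " documents -> ", out)
  0L
}

.cmd_normalize <- function(flags) {
  corpus <- .need_file(flags, "corpus")
  dict <- .need_file(flags, "dictionary")
  out <- .need(flags, "out")
  idx <- .load_indexes(dict)
  docs <- lapply(read_pubtator(corpus), normalize_document,
                 chem_index = idx$chem, dis_index = idx$dis)
  write_pubtator(docs, out)
  .log("normalize: ", length(docs), " documents -> ", out)
  0L
}

.cmd_train_rel <- function(flags) {
  corpus <- .need_file(flags, "corpus")
  dict <- .need_file(flags, "dictionary")
  out <- .need(flags, "out")
  kb <- if (!is.null(flags[["kb-dir"]])) load_kb_bundle(.need_file(flags, "kb-dir"))
        else list()
  docs <- read_pubtator(corpus)
  cfg <- relation_config(seed = as.integer(flags[["seed"]] %||% 1L))
  models <- train_relation_models(docs, kb, default_triggers(), cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  saveRDS(models, file.path(out, "relation.rds"))
  .log("train-rel: ", length(docs), " documents -> ",
       file.path(out, "relation.rds"))
  0L
}

.cmd_extract <- function(flags) {
  model_dir <- .need_file(flags, "model")
  corpus <- .need_file(flags, "corpus")
  dict <- .need_file(flags, "dictionary")
  out <- .need(flags, "out")
  strategy <- flags[["strategy"]] %||% "union"
  ner_path <- file.path(model_dir, "ner.rds")
  rel_path <- file.path(model_dir, "relation.rds")
  if (!file.exists(ner_path) || !file.exists(rel_path)) {
    message("error: need both ner.rds and relation.rds under ", model_dir)
    return(1L)
  }
  ner <- readRDS(ner_path)
  rel <- readRDS(rel_path)
  kb <- if (!is.null(flags[["kb-dir"]])) load_kb_bundle(.need_file(flags, "kb-dir"))
        else list()
  idx <- .load_indexes(dict)
  docs <- read_pubtator(corpus)
  preds <- lapply(docs, function(d) {
    m <- predict_mentions(ner, d)
    nd <- normalize_document(
      cdr_document(d$doc_id, d$title, d$abstract, m, relation_table()),
      idx$chem, idx$dis)
    nd$relations <- predict_relations(rel, nd, kb, default_triggers(), strategy)
    nd
  })
  write_pubtator(preds, out)
  .log("extract: strategy=", strategy, ", ",
       sum(vapply(preds, function(d) nrow(d$relations), 0L)),
       " relations over ", length(docs), " documents -> ", out)
  0L
}

.cmd_eval <- function(flags) {
  gold <- read_pubtator(.need_file(flags, "gold"))
  pred <- read_pubtator(.need_file(flags, "pred"))
  rows <- list()
  for (et in c("Chemical", "Disease")) {
    m <- eval_mention_level(gold, pred, et)
    c_ <- eval_concept_level(gold, pred, et)
    rows[[paste0("mention_", tolower(et))]] <- m
    rows[[paste0("concept_", tolower(et))]] <- c_
  }
  rows[["cid"]] <- eval_cid(gold, pred)
  cov <- relation_coverage(gold, pred)
  out_lines <- c("mode\tprecision\trecall\tf1\ttp\tfp\tfn",
                 vapply(names(rows), function(n) {
                   x <- rows[[n]]
                   sprintf("%s\t%.4f\t%.4f\t%.4f\t%d\t%d\t%d", n,
                           x$precision, x$recall, x$f1, x$tp, x$fp, x$fn)
                 }, ""),
                 sprintf("relation_coverage\t%d/%d\t%.4f", cov$covered,
                         cov$total,
                         if (is.na(cov$fraction)) NA_real_ else cov$fraction))
  cat(out_lines, sep = "\n")
  if (!is.null(flags[["out"]])) writeLines(out_lines, flags[["out"]])
  0L
}

#' Pipeline command-line entry point
#'
#' Dispatches `simulate`, `train-ner`, `ner`, `normalize`, `train-rel`,
#' `extract` and `eval` subcommands. Returns (rather than calls `quit()`
#' with) the exit code so it is directly testable: 0 on success, 1 on
#' missing inputs or runtime failure, 2 on usage errors.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code.
#' @export
cidrex_main <- function(argv) {
  if (!length(argv) || argv[1] %in% c("-h", "--help", "help")) {
    cat(.usage, "\n")
    return(if (length(argv)) 0L else 2L)
  }
  cmd <- argv[1]
  handler <- switch(cmd,
                    "simulate" = .cmd_simulate,
                    "train-ner" = .cmd_train_ner,
                    "ner" = .cmd_ner,
                    "normalize" = .cmd_normalize,
                    "train-rel" = .cmd_train_rel,
                    "extract" = .cmd_extract,
                    "eval" = .cmd_eval,
                    NULL)
  if (is.null(handler)) {
    message("error: unknown subcommand ", dQuote(cmd), "\n", .usage)
    return(2L)
  }
  flags <- tryCatch(.parse_flags(argv[-1]),
                    error = function(e) e)
  if (inherits(flags, "error")) {
    message("error: ", conditionMessage(flags), "\n", .usage)
    return(2L)
  }
  tryCatch(handler(flags),
           cidrex_missing_input = function(e) 1L,
           error = function(e) {
             message("error: ", conditionMessage(e))
             if (grepl("missing required flag", conditionMessage(e))) 2L else 1L
           })
}
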