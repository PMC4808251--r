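# R-side training/decoding wrapper around the C++ linear-chain CRF.
# Token features are sparse named numeric vectors; training builds a feature
# vocabulary, minimizes L2-regularized NLL with L-BFGS-B from a zero start
# (so training is deterministic for fixed data and config), and decoding
# runs Viterbi with unseen features dropped.

.seqs_to_cpp <- function(sequences, vocab, labels = NULL, label_set = NULL) {
  lapply(seq_along(sequences), function(s) {
    toks <- sequences[[s]]
    idx <- vector("list", length(toks))
    val <- vector("list", length(toks))
    for (t in seq_along(toks)) {
      f <- toks[[t]]
      j <- match(names(f), vocab)
      keep <- !is.na(j)
      idx[[t]] <- j[keep] - 1L
      val[[t]] <- as.numeric(f[keep])
    }
    y <- if (is.null(labels)) integer(length(toks))
         else match(labels[[s]], label_set) - 1L
    list(idx = idx, val = val, y = y)
  })
}

#' Train a linear-chain CRF
#'
#' @param sequences list of token sequences; each token is a named numeric
#'   feature vector (values may be real, e.g. embedding dimensions).
#' @param labels parallel list of character label vectors.
#' @param l2 L2 regularization strength (lambda).
#' @param max_iter maximum L-BFGS-B iterations.
#' @return object of class `crf_model`.
#' @export
crf_fit <- function(sequences, labels, l2 = 1.0, max_iter = 200L) {
  stopifnot(length(sequences) == length(labels), length(sequences) > 0)
  label_set <- sort(unique(unlist(labels, use.names = FALSE)))
  vocab <- sort(unique(unlist(lapply(sequences, function(s)
    unlist(lapply(s, names), use.names = FALSE)), use.names = FALSE)))
  cpp <- .seqs_to_cpp(sequences, vocab, labels, label_set)
  n_feat <- length(vocab); L <- length(label_set)
  n_par <- n_feat * L + L * L

  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return()
    r <- crf_nll_grad(par, cpp, n_feat, L)
    cache$par <- par
    cache$nll <- r$nll + 0.5 * l2 * sum(par^2)
    cache$grad <- r$grad + l2 * par
  }
  fn <- function(par) { eval_at(par); cache$nll }
  gr <- function(par) { eval_at(par); cache$grad }
  opt <- stats::optim(numeric(n_par), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e9))
  structure(list(theta = opt$par, vocab = vocab, labels = label_set,
                 l2 = l2, max_iter = max_iter, value = opt$value,
                 convergence = opt$convergence),
            class = "crf_model")
}

#' Decode the most likely label sequence
#'
#' @param model a `crf_model`.
#' @param sequence one token sequence (list of named numeric vectors).
#' @return character vector of predicted labels.
#' @export
crf_decode <- function(model, sequence) {
  if (!length(sequence)) return(character())
  cpp <- .seqs_to_cpp(list(sequence), model$vocab)[[1]]
  path <- crf_viterbi(model$theta, cpp$idx, cpp$val,
                      length(model$vocab), length(model$labels))
  model$labels[path + 1L]
}

#' @export
print.crf_model <- function(x, ...) {
  cat("<crf_model: ", length(x$labels), " labels, ", length(x$vocab),
      " features, final objective ", format(x$value, digits = 6), ">\n", sep = "")
  invisible(x)
}
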