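# Top-level interface: one fitting call running the full pipeline on an
# association matrix and a vocabulary, returning a classed object.

#' Fit the lncRNA functional-similarity / association-prediction model
#'
#' Runs the full pipeline: quality control of the association matrix
#' against the vocabulary, disease semantic similarity under the chosen
#' model, lncRNA functional similarity by best-match aggregation, WKNKN
#' score pre-completion, and extraction of the significant
#' potential-association network (threshold `mean + 2 sd` of the
#' potential scores).
#'
#' @param assoc binary lncRNA-disease association matrix (rows lncRNAs,
#'   columns diseases).
#' @param vocab a `mesh_vocab` disease vocabulary.
#' @param model semantic model: `"idssim"` (decay plus IC contribution
#'   factor), `"lncsim1"` (plain decay) or `"lncsim2"` (information
#'   content).
#' @param delta semantic contribution factor, default 0.5.
#' @param log_base IC logarithm base, default e.
#' @param p_on_child alternative IDSSIM recursion reading (default
#'   FALSE).
#' @param k,eta WKNKN parameters (defaults 5 and 0.9).
#' @param qc drop diseases absent from the vocabulary and lncRNAs left
#'   without associations before fitting (default TRUE); the QC report
#'   is kept in the result.
#' @return an object of class `idssim_fit` with components `assoc`,
#'   `dss`, `fs`, `pred`, `network`, `qc`, `params`.
#' @seealso [cross_validate()] for the evaluation protocol,
#'   [top_k()] for per-disease candidate ranking.
#' @examples
#' vocab <- synth_vocab(n_terms = 40, seed = 1)
#' assoc <- synth_assoc(vocab, n_lncrnas = 12, n_diseases = 10,
#'                      n_blocks = 2, seed = 1)
#' fit <- idssim(assoc, vocab)
#' fit
#' head(predict(fit, disease = colnames(assoc)[1], k = 3))
#' @export
idssim <- function(assoc, vocab, model = c("idssim", "lncsim1", "lncsim2"),
                   delta = 0.5, log_base = exp(1), p_on_child = FALSE,
                   k = 5L, eta = 0.9, qc = TRUE) {
  validate_assoc(assoc)
  stopifnot(inherits(vocab, "mesh_vocab"))
  params <- semantic_params(match.arg(model), delta, log_base, p_on_child)
  qcr <- NULL
  if (qc) {
    qcr <- qc_associations(assoc, vocab)
    if (length(qcr$report$dropped_diseases) ||
        length(qcr$report$dropped_lncrnas))
      message("QC dropped ", length(qcr$report$dropped_diseases),
              " disease(s) and ", length(qcr$report$dropped_lncrnas),
              " lncRNA(s); see $qc")
    assoc <- qcr$assoc
  }
  if (!length(assoc)) stop("no associations left after quality control")
  counts <- corpus_counts(vocab)
  dssm <- dss_matrix(vocab, colnames(assoc), params, counts)
  fsm <- fs_matrix(assoc, dssm, quiet = TRUE)
  pred <- wknkn(assoc, fsm, dssm, k = k, eta = eta)
  net <- significant_network(pred, assoc)
  structure(list(assoc = assoc, dss = dssm, fs = fsm, pred = pred,
                 network = net, qc = qcr,
                 params = list(model = params$model, delta = delta,
                               log_base = log_base, p_on_child = p_on_child,
                               k = as.integer(k), eta = eta)),
            class = "idssim_fit")
}

#' @export
print.idssim_fit <- function(x, ...) {
  cat("lncRNA-disease similarity fit (model: ", x$params$model, ")\n",
      "  ", nrow(x$assoc), " lncRNAs x ", ncol(x$assoc), " diseases, ",
      sum(x$assoc), " known associations\n",
      "  significant potential network: ", nrow(x$network$edges),
      " edge(s) above ", sprintf("%.4f", x$network$threshold), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.idssim_fit <- function(object, ...) {
  pot <- object$pred[object$assoc == 0]
  out <- list(
    model = object$params$model,
    dim = dim(object$assoc),
    n_known = sum(object$assoc),
    fs_mean_offdiag = mean(object$fs[upper.tri(object$fs)]),
    dss_mean_offdiag = mean(object$dss[upper.tri(object$dss)]),
    potential_score_summary = summary(pot),
    network_threshold = object$network$threshold,
    network_edges = nrow(object$network$edges))
  class(out) <- "summary.idssim_fit"
  out
}

#' @export
print.summary.idssim_fit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  cat("Matrix:", x$dim[1L], "lncRNAs x", x$dim[2L], "diseases;",
      x$n_known, "known associations\n")
  cat(sprintf("Mean off-diagonal similarity: DSS %.4f, FS %.4f\n",
              x$dss_mean_offdiag, x$fs_mean_offdiag))
  cat("Potential-association scores:\n")
  print(x$potential_score_summary)
  cat(sprintf("Significant network: %d edge(s) above %.4f\n",
              x$network_edges, x$network_threshold))
  invisible(x)
}

#' Predicted association scores or per-disease ranking
#'
#' Without `disease`, returns the full WKNKN score matrix. With a
#' disease name, returns the top-`k` candidate lncRNAs not yet known to
#' be associated with it.
#'
#' @param object an `idssim_fit`.
#' @param disease optional disease name.
#' @param k ranking depth when `disease` is given, default 20.
#' @param ... unused.
#' @return a score matrix, or a data frame `rank`/`lncrna`/`score`.
#' @export
predict.idssim_fit <- function(object, disease = NULL, k = 20L, ...) {
  if (is.null(disease)) return(object$pred)
  top_k(object$pred, object$assoc, disease, k)
}

#' Histogram of potential-association scores
#'
#' Plots the distribution of predicted scores over the cells with no
#' known association, with the significant-network threshold marked.
#'
#' @param x an `idssim_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.idssim_fit <- function(x, ...) {
  pot <- x$pred[x$assoc == 0]
  graphics::hist(pot, breaks = 40, col = "grey80",
                 main = "Potential-association scores",
                 xlab = "WKNKN score", ...)
  graphics::abline(v = x$network$threshold, col = "red3", lwd = 2)
  graphics::mtext(sprintf("threshold m + 2 sd = %.4f", x$network$threshold),
                  side = 3, line = 0, col = "red3", cex = 0.8)
  invisible(x)
}
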