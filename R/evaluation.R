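# Repeated five-fold masking cross-validation with threshold-swept
# ROC/AUC, significant-network extraction and per-disease ranking.

#' Assign every matrix cell to one of five folds
#'
#' All cells (positives and negatives alike) are partitioned uniformly at
#' random into five folds whose sizes differ by at most one; the
#' assignment is reproducible from `seed`.
#'
#' @param assoc association matrix (only its shape is used).
#' @param seed integer seed.
#' @return an object of class `fold_assignment`: `seed` plus an integer
#'   matrix `fold` of the same shape with values in `0:4`.
#' @export
make_folds <- function(assoc, seed) {
  if (!length(assoc)) stop("empty association matrix")
  n <- length(assoc)
  fold <- integer(n)
  fold[with_seed(seed, sample.int(n))] <- rep(0:4, length.out = n)
  fold <- matrix(fold, nrow(assoc), ncol(assoc), dimnames = dimnames(assoc))
  structure(list(seed = seed, fold = fold), class = "fold_assignment")
}

#' Mask one fold of an association matrix
#'
#' Cells of fold `f` that are 1 become 0; everything else is unchanged.
#'
#' @param assoc binary association matrix.
#' @param folds a `fold_assignment` for `assoc`.
#' @param f fold index in `0:4`.
#' @return the masked matrix.
#' @export
mask_fold <- function(assoc, folds, f) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (!f %in% 0:4) stop("fold index must be in 0..4")
  assoc[folds$fold == f & assoc == 1] <- 0
  assoc
}

#' ROC points of one fold by descending-threshold sweep
#'
#' Within the fold's cells only: positives are the cells that were 1 in
#' the *original* matrix, negatives those that were 0. The threshold runs
#' through the fold's predicted scores in descending order; at each
#' threshold a cell is a predicted positive iff its score is strictly
#' greater than the threshold. Endpoints (0,0) and (1,1) correspond to
#' thresholds above the maximum and below the minimum score.
#'
#' @param pred predicted score matrix aligned with `assoc`.
#' @param assoc the original (unmasked) binary association matrix.
#' @param folds a `fold_assignment`.
#' @param f fold index.
#' @return a list with `tpr`, `fpr`, `thresholds` and a logical
#'   `degenerate` (TRUE when the fold has no positives or no negatives;
#'   such folds carry no ROC information and are excluded from
#'   averaging).
#' @export
fold_roc <- function(pred, assoc, folds, f) {
  stopifnot(inherits(folds, "fold_assignment"),
            identical(dim(pred), dim(assoc)))
  cells <- folds$fold == f
  labels <- assoc[cells]
  scores <- pred[cells]
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    warning("fold ", f, " has no ", if (P == 0) "positives" else "negatives",
            "; flagged degenerate")
    return(list(tpr = numeric(0), fpr = numeric(0),
                thresholds = numeric(0), degenerate = TRUE))
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tp <- vapply(th, function(t) sum(scores > t & labels == 1), numeric(1L))
  fp <- vapply(th, function(t) sum(scores > t & labels == 0), numeric(1L))
  list(tpr = tp / P, fpr = fp / N, thresholds = th, degenerate = FALSE)
}

#' Seeded random-score predictor (calibration null)
#'
#' Returns a predictor function for [cross_validate()] that ignores the
#' similarity matrices and emits uniform random scores on the unknown
#' cells (known positives keep score 1). Used to verify that the
#' evaluation protocol is calibrated: its AUC must be ~0.5.
#'
#' @param seed integer seed; successive calls of the returned function
#'   advance an internal counter so folds get independent draws while the
#'   whole sequence stays reproducible.
#' @return a function `(assoc, fs, dss, k, eta) -> matrix`.
#' @export
null_predictor <- function(seed) {
  counter <- 0L
  function(assoc, fs, dss, k = 5L, eta = 0.9) {
    counter <<- counter + 1L
    r <- with_seed(seed + counter,
                   matrix(stats::runif(length(assoc)), nrow(assoc),
                          ncol(assoc), dimnames = dimnames(assoc)))
    pmax(assoc, r * (assoc == 0))
  }
}

#' Shuffle the labels of a similarity matrix
#'
#' Applies one random permutation jointly to rows and columns and then
#' restores the original dimnames, so every entity is assigned another
#' entity's similarity profile. Symmetry and the unit diagonal are
#' preserved, but the correspondence between labels and similarity
#' values — the only information the similarity contributes — is
#' destroyed.
#'
#' @param m symmetric similarity matrix with dimnames.
#' @param seed integer seed for the permutation.
#' @return the shuffled matrix.
#' @export
shuffle_similarity <- function(m, seed) {
  p <- with_seed(seed, sample.int(nrow(m)))
  s <- m[p, p]
  dimnames(s) <- dimnames(m)
  s
}

#' Shuffled-similarity control predictor
#'
#' Returns a predictor for [cross_validate()] that runs [wknkn()] on
#' label-shuffled copies of *both* similarity matrices (lncRNA and
#' disease side). Any AUC this control achieves comes from matrix
#' structure alone (e.g. disease popularity), not from the semantic
#' similarity; the margin of the real model over it measures the
#' similarity's contribution.
#'
#' @param seed integer seed; the two sides use `seed` and `seed + 1`.
#' @return a function `(assoc, fs, dss, k, eta) -> matrix`.
#' @export
shuffled_predictor <- function(seed) {
  function(assoc, fs, dss, k = 5L, eta = 0.9) {
    wknkn(assoc, shuffle_similarity(fs, seed),
          shuffle_similarity(dss, seed + 1L), k = k, eta = eta)
  }
}

#' Repeated five-fold cross-validation of the prediction pipeline
#'
#' For each of `repeats` repetitions (repeat `r` is seeded with
#' `base_seed + r`) the cells are split into five folds; each fold in
#' turn is masked, the lncRNA functional similarity recomputed (from the
#' masked matrix by default, leakage-free; set `fs_from_masked = FALSE`
#' to reuse the full-data FS), the predictor run, and the fold's ROC
#' computed against the original labels. Curves are interpolated onto a
#' fixed FPR grid and averaged pointwise over all folds and repeats; AUC
#' is the trapezoidal integral of the averaged curve. The disease
#' semantic similarity does not depend on the association matrix and is
#' computed once.
#'
#' @param assoc binary association matrix.
#' @param vocab a `mesh_vocab` covering the diseases of `assoc`.
#' @param params a `semantic_params`.
#' @param counts optional `corpus_counts` (computed from `vocab` when
#'   needed).
#' @param k,eta WKNKN parameters.
#' @param repeats number of five-fold repetitions, default 10.
#' @param base_seed integer; repeat `r` uses `base_seed + r`.
#' @param fs_from_masked recompute FS inside each fold (default TRUE).
#' @param predictor prediction function `(assoc, fs, dss, k, eta) ->
#'   score matrix`; defaults to [wknkn()].
#' @param grid_points FPR grid resolution, default 1001.
#' @param dssm optional precomputed disease similarity matrix (overrides
#'   `vocab`/`params` for similarity; used for control experiments).
#' @return an object of class `cv_result`: `model_tag`, `repeats`,
#'   `mean_fpr`, `mean_tpr`, `auc`, `n_curves`.
#' @export
cross_validate <- function(assoc, vocab = NULL, params = semantic_params(),
                           counts = NULL, k = 5L, eta = 0.9,
                           repeats = 10L, base_seed = 1L,
                           fs_from_masked = TRUE, predictor = NULL,
                           grid_points = 1001L, dssm = NULL) {
  validate_assoc(assoc)
  if (is.null(dssm)) {
    stopifnot(inherits(vocab, "mesh_vocab"))
    dssm <- dss_matrix(vocab, colnames(assoc), params, counts)
  }
  if (is.null(predictor)) predictor <- wknkn
  grid <- seq(0, 1, length.out = grid_points)
  acc <- matrix(0, 0, grid_points)
  fsm_full <- if (!fs_from_masked) fs_matrix(assoc, dssm, quiet = TRUE)
  for (r in seq_len(repeats)) {
    folds <- make_folds(assoc, base_seed + r)
    for (f in 0:4) {
      masked <- mask_fold(assoc, folds, f)
      fsm <- if (fs_from_masked) fs_matrix(masked, dssm, quiet = TRUE)
             else fsm_full
      pred <- predictor(masked, fsm, dssm, k = k, eta = eta)
      roc <- fold_roc(pred, assoc, folds, f)
      if (roc$degenerate) next
      tpr_g <- stats::approx(roc$fpr, roc$tpr, xout = grid, ties = max,
                             rule = 2)$y
      acc <- rbind(acc, tpr_g)
    }
  }
  if (!nrow(acc)) stop("all folds degenerate; cannot average a ROC curve")
  mean_tpr <- colMeans(acc)
  mean_tpr[1L] <- 0
  mean_tpr[grid_points] <- 1
  structure(list(model_tag = params$model, repeats = repeats,
                 mean_fpr = grid, mean_tpr = mean_tpr,
                 auc = trapezoid(grid, mean_tpr), n_curves = nrow(acc),
                 base_seed = base_seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation (", x$repeats, " x 5-fold, model ", x$model_tag,
      "): AUC = ", sprintf("%.4f", x$auc), " over ", x$n_curves,
      " fold curves\n", sep = "")
  invisible(x)
}

#' @export
plot.cv_result <- function(x, ...) {
  graphics::plot(x$mean_fpr, x$mean_tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (%s), AUC = %.4f", x$model_tag, x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Significant potential-association network
#'
#' The potential associations are the cells that are 0 in the known
#' matrix. With `LDA` their predicted scores, the network keeps those
#' scoring strictly above `m(LDA) + 2 * sd(LDA)`; `sd` uses the
#' population formula (divisor n).
#'
#' @param pred predicted score matrix aligned with `assoc`.
#' @param assoc binary association matrix.
#' @return an object of class `significant_network`: a data frame
#'   `edges` (lncrna, disease, score; descending score) and the
#'   `threshold`.
#' @export
significant_network <- function(pred, assoc) {
  validate_assoc(assoc)
  stopifnot(identical(dim(pred), dim(assoc)))
  pot <- assoc == 0
  if (!any(pot)) {
    warning("no potential associations (matrix has no zero cells)")
    return(structure(list(edges = data.frame(lncrna = character(0),
                                             disease = character(0),
                                             score = numeric(0)),
                          threshold = NA_real_),
                     class = "significant_network"))
  }
  lda <- pred[pot]
  m <- mean(lda)
  s <- sqrt(mean((lda - m)^2))
  threshold <- m + 2 * s
  sel <- which(pot & pred > threshold, arr.ind = TRUE)
  edges <- data.frame(lncrna = rownames(assoc)[sel[, 1L]],
                      disease = colnames(assoc)[sel[, 2L]],
                      score = pred[sel])
  edges <- edges[order(-edges$score, edges$lncrna, edges$disease), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, threshold = threshold),
            class = "significant_network")
}

#' @export
print.significant_network <- function(x, ...) {
  cat("Significant potential-association network: ", nrow(x$edges),
      " edge(s), threshold m + 2 sd = ",
      if (is.na(x$threshold)) "NA" else sprintf("%.6f", x$threshold),
      "\n", sep = "")
  print(utils::head(x$edges, 10L))
  invisible(x)
}

#' Top-k candidate lncRNAs for one disease
#'
#' Among lncRNAs with no known association to the disease, the k with the
#' highest predicted scores, in descending order; ties are broken
#' alphabetically for determinism.
#'
#' @param pred predicted score matrix.
#' @param assoc binary association matrix.
#' @param disease a column name.
#' @param k number of candidates, default 20. When fewer candidates
#'   exist, all are returned.
#' @return a data frame with columns `rank`, `lncrna`, `score`.
#' @export
top_k <- function(pred, assoc, disease, k = 20L) {
  validate_assoc(assoc)
  if (!disease %in% colnames(assoc))
    stop("unknown disease: ", disease)
  cand <- rownames(assoc)[assoc[, disease] == 0]
  sc <- pred[cand, disease]
  ord <- order(-sc, cand)
  take <- utils::head(ord, min(k, length(cand)))
  data.frame(rank = seq_along(take), lncrna = cand[take],
             score = unname(sc[take]))
}
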