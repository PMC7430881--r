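# WKNKN: weighted k nearest known neighbors pre-completion of a binary
# association matrix using the two similarity matrices.

#' WKNKN association prediction
#'
#' Replaces unknown entries of the binary lncRNA-disease matrix `Y` with
#' similarity-weighted averages over each side's k nearest *known*
#' neighbors (rows/columns with at least one known association, the query
#' excluded). On the lncRNA side,
#' `Y_l(u, .) = (1/Z_u) * sum_{i=1..k} eta^(i-1) * FS(u, u_i) * Y(u_i, .)`
#' with `Z_u = sum_i eta^(i-1) * FS(u, u_i)`, neighbors ordered by
#' descending similarity (ties broken by input index order); the disease
#' side is symmetric with DSS. The output is
#' `max(Y, (Y_l + Y_d)/2)` entrywise, clipped to `[0, 1]`, so known
#' positives are always preserved.
#'
#' @param assoc binary association matrix (rows lncRNAs, columns
#'   diseases).
#' @param fs lncRNA functional similarity matrix indexed by the rows of
#'   `assoc`.
#' @param dss disease semantic similarity matrix indexed by the columns
#'   of `assoc`.
#' @param k number of known nearest neighbors, default 5. When fewer
#'   known neighbors exist, all available are used.
#' @param eta per-rank geometric decay in (0, 1], default 0.9.
#' @return a numeric matrix of predicted association scores in `[0, 1]`
#'   with the layout of `assoc`.
#' @export
wknkn <- function(assoc, fs, dss, k = 5L, eta = 0.9) {
  validate_assoc(assoc)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be an integer >= 1")
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta > 1)
    stop("`eta` must satisfy 0 < eta <= 1")
  if (!all(rownames(assoc) %in% rownames(fs)) ||
      !setequal(rownames(fs), colnames(fs)))
    stop("`fs` must cover the lncRNAs of `assoc`")
  if (!all(colnames(assoc) %in% rownames(dss)) ||
      !setequal(rownames(dss), colnames(dss)))
    stop("`dss` must cover the diseases of `assoc`")
  fs <- fs[rownames(assoc), rownames(assoc), drop = FALSE]
  dss <- dss[colnames(assoc), colnames(assoc), drop = FALSE]
  yl <- side_estimate(assoc, fs, k, eta)
  yd <- t(side_estimate(t(assoc), dss, k, eta))
  out <- pmax(assoc, (yl + yd) / 2)
  out[out > 1] <- 1
  out[out < 0] <- 0
  out
}

# One-sided neighbor estimate over the rows of Y using similarity S.
side_estimate <- function(Y, S, k, eta) {
  n <- nrow(Y)
  known <- which(rowSums(Y) > 0)
  E <- matrix(0, n, ncol(Y), dimnames = dimnames(Y))
  for (u in seq_len(n)) {
    cand <- setdiff(known, u)
    if (!length(cand)) next
    ord <- order(-S[u, cand], cand)           # descending sim, tie by index
    idx <- cand[utils::head(ord, min(k, length(cand)))]
    w <- eta^(seq_along(idx) - 1L) * S[u, idx]
    Z <- sum(w)
    if (Z > 0)
      E[u, ] <- as.vector(w %*% Y[idx, , drop = FALSE]) / Z
  }
  E
}
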