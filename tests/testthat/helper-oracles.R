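# Independent naive re-implementations used as oracles. These are
# deliberately memo-free, loop-based and share no code with the package
# internals beyond the vocabulary data structure.

oracle_prefixes <- function(tn) {
  parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
  sapply(seq_along(parts), function(i) paste(parts[1:i], collapse = "."))
}

# every term owning any prefix of any tree number of `disease`
oracle_ancestors <- function(vocab, disease) {
  anc <- disease
  for (tn in vocab$tree_numbers[[disease]]) {
    for (p in oracle_prefixes(tn)) {
      owner <- names(which(vapply(vocab$tree_numbers,
                                  function(x) p %in% x, logical(1))))
      anc <- c(anc, owner)
    }
  }
  unique(anc)
}

# parent -> child edges between terms owning adjacent existing prefixes
oracle_dag_edges <- function(vocab, disease) {
  edges <- matrix(character(0), ncol = 2)
  for (tn in vocab$tree_numbers[[disease]]) {
    owners <- character(0)
    for (p in oracle_prefixes(tn)) {
      o <- names(which(vapply(vocab$tree_numbers,
                              function(x) p %in% x, logical(1))))
      owners <- c(owners, o)
    }
    if (length(owners) >= 2)
      for (i in 1:(length(owners) - 1))
        if (owners[i] != owners[i + 1])
          edges <- rbind(edges, c(owners[i], owners[i + 1]))
  }
  unique(edges)
}

oracle_counts <- function(vocab) {
  cnt <- sapply(vocab$terms, function(t)
    sum(vapply(vocab$terms, function(k) t %in% oracle_ancestors(vocab, k),
               logical(1))))
  list(D = length(vocab$terms), dags_count = cnt, max_dags = max(cnt))
}

# per-term semantic contributions, memo-free recursion on the printed
# formulas; returns a named vector over the ancestor set
oracle_sv <- function(vocab, disease, model, delta = 0.5,
                      counts = oracle_counts(vocab), log_base = exp(1)) {
  terms <- oracle_ancestors(vocab, disease)
  if (model == "lncsim2")
    return(setNames(-log(counts$dags_count[terms] / counts$D, log_base),
                    terms))
  edges <- oracle_dag_edges(vocab, disease)
  contrib_of <- function(t) {
    if (t == disease) return(1)
    ch <- edges[edges[, 1] == t, 2]
    w <- if (model == "lncsim1") delta
         else delta + (counts$max_dags - counts$dags_count[[t]]) / counts$D
    max(sapply(ch, function(c2) w * contrib_of(c2)))
  }
  setNames(sapply(terms, contrib_of), terms)
}

oracle_dss <- function(ca, cb) {
  shared <- intersect(names(ca), names(cb))
  if (!length(shared)) return(0)
  sum(ca[shared] + cb[shared]) / (sum(ca) + sum(cb))
}

oracle_fs <- function(gu, gv, dssm) {
  s_uv <- 0
  for (d in gu) {
    best <- -Inf
    for (d2 in gv) best <- max(best, dssm[d, d2])
    s_uv <- s_uv + best
  }
  s_vu <- 0
  for (d in gv) {
    best <- -Inf
    for (d2 in gu) best <- max(best, dssm[d2, d])
    s_vu <- s_vu + best
  }
  (s_uv + s_vu) / (length(gu) + length(gv))
}

oracle_fs_matrix <- function(assoc, dssm) {
  lnc <- rownames(assoc)
  m <- diag(1, length(lnc))
  dimnames(m) <- list(lnc, lnc)
  for (u in lnc) for (v in lnc) {
    if (u == v) next
    gu <- colnames(assoc)[assoc[u, ] == 1]
    gv <- colnames(assoc)[assoc[v, ] == 1]
    m[u, v] <- if (length(gu) && length(gv)) oracle_fs(gu, gv, dssm) else 0
  }
  m
}

oracle_wknkn <- function(Y, FS, DSS, k, eta) {
  n <- nrow(Y); m <- ncol(Y)
  Yl <- matrix(0, n, m); Yd <- matrix(0, n, m)
  for (u in seq_len(n)) {
    cand <- setdiff(which(rowSums(Y) > 0), u)
    if (!length(cand)) next
    nb <- cand[order(-FS[u, cand], cand)]
    nb <- nb[seq_len(min(k, length(nb)))]
    Z <- 0; acc <- rep(0, m)
    for (i in seq_along(nb)) {
      w <- eta^(i - 1) * FS[u, nb[i]]
      Z <- Z + w
      acc <- acc + w * Y[nb[i], ]
    }
    if (Z > 0) Yl[u, ] <- acc / Z
  }
  for (d in seq_len(m)) {
    cand <- setdiff(which(colSums(Y) > 0), d)
    if (!length(cand)) next
    nb <- cand[order(-DSS[d, cand], cand)]
    nb <- nb[seq_len(min(k, length(nb)))]
    Z <- 0; acc <- rep(0, n)
    for (i in seq_along(nb)) {
      w <- eta^(i - 1) * DSS[d, nb[i]]
      Z <- Z + w
      acc <- acc + w * Y[, nb[i]]
    }
    if (Z > 0) Yd[, d] <- acc / Z
  }
  out <- pmax(Y, (Yl + Yd) / 2)
  dimnames(out) <- dimnames(Y)
  pmin(pmax(out, 0), 1)
}

# exhaustive descending-threshold enumeration (strict >)
oracle_roc <- function(scores, labels) {
  P <- sum(labels == 1); N <- sum(labels == 0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- numeric(length(th)); fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    tp <- 0; fp <- 0
    for (j in seq_along(scores)) {
      if (scores[j] > th[i]) {
        if (labels[j] == 1) tp <- tp + 1 else fp <- fp + 1
      }
    }
    tpr[i] <- tp / P
    fpr[i] <- fp / N
  }
  list(tpr = tpr, fpr = fpr, thresholds = th)
}

oracle_network <- function(pred, assoc) {
  lda <- c()
  for (i in seq_len(nrow(assoc))) for (j in seq_len(ncol(assoc)))
    if (assoc[i, j] == 0) lda <- c(lda, pred[i, j])
  thr <- mean(lda) + 2 * sqrt(sum((lda - mean(lda))^2) / length(lda))
  edges <- NULL
  for (i in seq_len(nrow(assoc))) for (j in seq_len(ncol(assoc)))
    if (assoc[i, j] == 0 && pred[i, j] > thr)
      edges <- rbind(edges, data.frame(lncrna = rownames(assoc)[i],
                                       disease = colnames(assoc)[j],
                                       score = pred[i, j]))
  list(edges = edges, threshold = thr)
}
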