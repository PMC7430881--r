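# Synthetic fixtures: a random prefix-coded disease hierarchy and a
# binary association matrix with planted block structure.

#' Generate a random prefix-coded disease vocabulary
#'
#' Grows a forest of tree-numbered terms that stands in for a disease
#' vocabulary such as the MeSH disease category: roots are coded
#' `C01`, `C02`, ...; each child extends its parent's code with a
#' three-digit token. Every node is a term. Growth proceeds level by
#' level with a Poisson number of children per node (mean `branching`)
#' until `n_terms` terms exist or `depth` levels are reached; if the
#' frontier dies out early, children are attached to random non-maximal
#' nodes until the target size is met. Fully reproducible from `seed`.
#'
#' @param n_terms total number of terms, default 200.
#' @param n_roots number of root categories, default 4.
#' @param depth maximum number of levels, default 5.
#' @param branching mean children per node, default 3.
#' @param seed integer seed.
#' @return a `mesh_vocab`.
#' @export
synth_vocab <- function(n_terms = 200L, n_roots = 4L, depth = 5L,
                        branching = 3, seed = 1L) {
  if (n_terms < n_roots) stop("n_terms must be >= n_roots")
  if (n_roots < 1L || depth < 1L) stop("n_roots >= 1 and depth >= 1 required")
  with_seed(seed, {
    tn <- sprintf("C%02d", seq_len(n_roots))
    node_depth <- rep(1L, n_roots)
    n_children <- rep(0L, n_roots)
    level <- 1L
    frontier <- seq_len(n_roots)
    while (length(tn) < n_terms && level < depth && length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        nc <- stats::rpois(1L, branching)
        for (j in seq_len(nc)) {
          if (length(tn) >= n_terms) break
          n_children[p] <- n_children[p] + 1L
          tn <- c(tn, paste0(tn[p], sprintf(".%03d", n_children[p])))
          node_depth <- c(node_depth, node_depth[p] + 1L)
          n_children <- c(n_children, 0L)
          nxt <- c(nxt, length(tn))
        }
      }
      frontier <- nxt
      level <- level + 1L
    }
    while (length(tn) < n_terms) {
      p <- sample(which(node_depth < depth), 1L)
      n_children[p] <- n_children[p] + 1L
      tn <- c(tn, paste0(tn[p], sprintf(".%03d", n_children[p])))
      node_depth <- c(node_depth, node_depth[p] + 1L)
      n_children <- c(n_children, 0L)
    }
    terms <- sprintf("disease_%03d", seq_along(tn))
    mesh_vocab(stats::setNames(as.list(tn), terms))
  })
}

#' Generate an association matrix with planted block structure
#'
#' LncRNAs are split into `n_blocks` groups and each group is tied to a
#' set of diseases drawn preferentially from DAG siblings (terms sharing
#' a parent tree-number prefix), so the semantic similarity genuinely
#' carries signal about co-association. Cells inside a block are 1 with
#' probability `within_block_density`, everywhere else with
#' `background_density`. Reproducible from `seed`.
#'
#' @param vocab a `mesh_vocab` supplying the diseases.
#' @param n_lncrnas,n_diseases matrix dimensions, defaults 40 and 30.
#' @param n_blocks number of planted blocks, default 4.
#' @param within_block_density,background_density association
#'   probabilities inside/outside blocks, defaults 0.6 and 0.02; the
#'   background must be strictly sparser than the blocks.
#' @param seed integer seed.
#' @return a binary matrix with `lnc_block` and `disease_block`
#'   attributes recording the planted structure.
#' @export
synth_assoc <- function(vocab, n_lncrnas = 40L, n_diseases = 30L,
                        n_blocks = 4L, within_block_density = 0.6,
                        background_density = 0.02, seed = 1L) {
  stopifnot(inherits(vocab, "mesh_vocab"))
  if (!(background_density >= 0 && background_density < within_block_density &&
        within_block_density <= 1))
    stop("need 0 <= background_density < within_block_density <= 1")
  if (n_diseases > length(vocab$terms))
    stop("n_diseases exceeds the vocabulary size")
  if (n_blocks > n_lncrnas || n_blocks > n_diseases)
    stop("n_blocks exceeds a matrix dimension")
  with_seed(seed, {
    # sibling families: terms grouped by their parent tree-number prefix
    parent_of <- vapply(vocab$terms, function(t) {
      p <- tn_prefixes(vocab$tree_numbers[[t]][1L])
      if (length(p) > 1L) p[length(p) - 1L] else "<root>"
    }, character(1L))
    fams <- split(vocab$terms, parent_of)
    fams <- fams[sample.int(length(fams))]
    fams <- fams[order(-vapply(fams, length, 1L))]
    per_block <- diff(round(seq(0, n_diseases, length.out = n_blocks + 1L)))
    d_block <- vector("list", n_blocks)
    fi <- 1L
    pool <- fams
    for (b in seq_len(n_blocks)) {
      need <- per_block[b]
      got <- character(0)
      while (length(got) < need && length(pool)) {
        take <- utils::head(pool[[1L]], need - length(got))
        got <- c(got, take)
        pool[[1L]] <- setdiff(pool[[1L]], take)
        if (!length(pool[[1L]])) pool <- pool[-1L]
      }
      d_block[[b]] <- got
    }
    diseases <- unlist(d_block, use.names = FALSE)
    lnc <- sprintf("lnc_%03d", seq_len(n_lncrnas))
    l_block <- sort(rep_len(seq_len(n_blocks), n_lncrnas))
    p <- matrix(background_density, n_lncrnas, length(diseases),
                dimnames = list(lnc, diseases))
    for (b in seq_len(n_blocks))
      p[l_block == b, d_block[[b]]] <- within_block_density
    m <- matrix(as.numeric(stats::runif(length(p)) < p), nrow(p), ncol(p),
                dimnames = dimnames(p))
    attr(m, "lnc_block") <- stats::setNames(l_block, lnc)
    attr(m, "disease_block") <- stats::setNames(
      rep(seq_len(n_blocks), vapply(d_block, length, 1L)), diseases)
    m
  })
}
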