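# LncRNA functional similarity by best-match aggregation over disease
# groups, plus association-matrix quality control.

#' Validate a binary lncRNA-disease association matrix
#'
#' Rows are lncRNAs, columns are diseases; cells are 0/1 with unique row
#' and column names.
#'
#' @param assoc a matrix.
#' @return the matrix, invisibly, after validation.
#' @export
validate_assoc <- function(assoc) {
  if (!is.matrix(assoc) || !is.numeric(assoc))
    stop("association matrix must be a numeric matrix")
  if (is.null(rownames(assoc)) || is.null(colnames(assoc)))
    stop("association matrix needs lncRNA row names and disease column names")
  if (anyDuplicated(rownames(assoc)) || anyDuplicated(colnames(assoc)))
    stop("row/column names must be unique")
  if (!all(assoc %in% c(0, 1)))
    stop("association matrix cells must be 0 or 1")
  invisible(assoc)
}

#' Disease group of an lncRNA
#'
#' The set of diseases the lncRNA is known to be associated with (cells
#' equal to 1 in its row).
#'
#' @param assoc binary association matrix.
#' @param lncrna a row name of `assoc`.
#' @return character vector of disease names (possibly empty).
#' @export
disease_group <- function(assoc, lncrna) {
  if (!lncrna %in% rownames(assoc))
    stop("unknown lncRNA: ", lncrna)
  colnames(assoc)[assoc[lncrna, ] == 1]
}

#' Best-match similarity of a disease to a disease group
#'
#' `S(d, DG) = max over d' in DG of DSS(d, d')`.
#'
#' @param d disease name.
#' @param group non-empty character vector of disease names.
#' @param dssm disease semantic similarity matrix (named, symmetric).
#' @return a scalar in `[0, 1]`.
#' @export
best_match <- function(d, group, dssm) {
  if (!length(group)) stop("empty disease group")
  bad <- setdiff(c(d, group), rownames(dssm))
  if (length(bad))
    stop("disease(s) absent from similarity matrix: ",
         paste(bad, collapse = ", "))
  max(dssm[d, group])
}

#' Functional similarity of two lncRNAs
#'
#' Each disease in one lncRNA's group is matched to its most similar
#' disease in the other group; the two directed sums are normalised by
#' the group sizes:
#' `FS(u, v) = (S_{u->v} + S_{v->u}) / (|DG(u)| + |DG(v)|)`.
#'
#' @param u,v lncRNA names with non-empty disease groups.
#' @param assoc binary association matrix.
#' @param dssm disease semantic similarity matrix.
#' @return a scalar in `[0, 1]`.
#' @export
fs <- function(u, v, assoc, dssm) {
  gu <- disease_group(assoc, u)
  gv <- disease_group(assoc, v)
  if (!length(gu) || !length(gv))
    stop("lncRNA with empty disease group: ",
         paste(c(u, v)[c(!length(gu), !length(gv))], collapse = ", "))
  fs_pair(gu, gv, dssm)
}

fs_pair <- function(gu, gv, dssm) {
  sub <- dssm[gu, gv, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
    (length(gu) + length(gv))
}

#' Pairwise lncRNA functional similarity matrix
#'
#' Computed once per unordered pair. LncRNAs with empty disease groups
#' (which arise after cross-validation masking) receive 0 off-diagonal
#' and 1 on the diagonal rather than an error, so evaluation loops never
#' abort; this is reported once per matrix via a message.
#'
#' @param assoc binary association matrix.
#' @param dssm disease semantic similarity matrix covering every disease
#'   that carries a 1 in `assoc`.
#' @param quiet suppress the empty-group message.
#' @return a symmetric numeric matrix over the lncRNAs of `assoc` with
#'   unit diagonal and entries in `[0, 1]`.
#' @export
fs_matrix <- function(assoc, dssm, quiet = FALSE) {
  validate_assoc(assoc)
  used <- colnames(assoc)[colSums(assoc) > 0]
  bad <- setdiff(used, rownames(dssm))
  if (length(bad))
    stop("disease(s) in associations but absent from similarity matrix: ",
         paste(bad, collapse = ", "))
  lnc <- rownames(assoc)
  groups <- lapply(lnc, function(u) colnames(assoc)[assoc[u, ] == 1])
  names(groups) <- lnc
  empty <- vapply(groups, length, 1L) == 0L
  if (any(empty) && !quiet)
    message(sum(empty), " lncRNA(s) with empty disease group: ",
            "functional similarity set to 0 off-diagonal")
  n <- length(lnc)
  m <- diag(1, n)
  dimnames(m) <- list(lnc, lnc)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (empty[i] || empty[j]) next
      v <- fs_pair(groups[[i]], groups[[j]], dssm)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Quality control of an association matrix against a vocabulary
#'
#' Mirrors the curation step applied to lncRNA-disease databases: diseases
#' whose names do not match any vocabulary term (and therefore have no
#' tree numbers) are dropped, and lncRNAs left without any association
#' are dropped. Nothing is silent: the returned report lists every kept
#' and dropped name.
#'
#' @param assoc binary association matrix.
#' @param vocab a `mesh_vocab`.
#' @return an object of class `assoc_qc`: list with the filtered `assoc`
#'   and a `report` of kept/dropped diseases and lncRNAs.
#' @export
qc_associations <- function(assoc, vocab) {
  validate_assoc(assoc)
  stopifnot(inherits(vocab, "mesh_vocab"))
  keep_d <- colnames(assoc) %in% vocab$terms
  filtered <- assoc[, keep_d, drop = FALSE]
  keep_l <- rowSums(filtered) > 0
  report <- list(
    kept_diseases = colnames(filtered),
    dropped_diseases = colnames(assoc)[!keep_d],
    kept_lncrnas = rownames(filtered)[keep_l],
    dropped_lncrnas = rownames(filtered)[!keep_l],
    n_associations = sum(filtered[keep_l, , drop = FALSE]))
  structure(list(assoc = filtered[keep_l, , drop = FALSE], report = report),
            class = "assoc_qc")
}

#' @export
print.assoc_qc <- function(x, ...) {
  r <- x$report
  cat("Association QC:\n",
      "  diseases kept ", length(r$kept_diseases), ", dropped ",
      length(r$dropped_diseases), "\n",
      "  lncRNAs  kept ", length(r$kept_lncrnas), ", dropped ",
      length(r$dropped_lncrnas), "\n",
      "  associations retained: ", r$n_associations, "\n", sep = "")
  if (length(r$dropped_diseases))
    cat("  dropped diseases:",
        paste(utils::head(r$dropped_diseases, 10L), collapse = ", "), "\n")
  invisible(x)
}
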