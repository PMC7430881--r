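# Per-term semantic values on disease DAGs and pairwise disease semantic
# similarity under the three models.

#' Semantic model parameters
#'
#' @param model one of `"idssim"`, `"lncsim1"`, `"lncsim2"`.
#'   * `lncsim1`: recursive decay — the disease itself contributes 1, every
#'     other DAG term the maximum over its DAG children of
#'     `delta * contribution(child)`.
#'   * `lncsim2`: information content — each term contributes
#'     `-log(Dags(t)/D)`, independent of the disease.
#'   * `idssim`: the decay recursion with the per-term decay factor
#'     enlarged by the IC contribution factor `P_t`, so rarer (more
#'     specific) terms retain more contribution than common ones at the
#'     same layer.
#' @param delta semantic contribution factor in (0, 1], default 0.5.
#' @param log_base logarithm base for the IC model, default `exp(1)`.
#' @param p_on_child if `TRUE`, the IDSSIM recursion uses the child's
#'   `P` factor instead of the scored node's (an alternative reading of
#'   the recursion; default `FALSE`).
#' @return an object of class `semantic_params`.
#' @export
semantic_params <- function(model = c("idssim", "lncsim1", "lncsim2"),
                            delta = 0.5, log_base = exp(1),
                            p_on_child = FALSE) {
  model <- match.arg(model)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop("`delta` must satisfy 0 < delta <= 1")
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1)
    stop("`log_base` must be > 1")
  structure(list(model = model, delta = delta, log_base = log_base,
                 p_on_child = isTRUE(p_on_child)),
            class = "semantic_params")
}

#' Information-content value of a term
#'
#' `-log(Dags(t) / D)` in the configured base: the corpus surprisal of the
#' term. A term contained in every disease's DAG carries no information
#' (value 0); terms appearing in few DAGs are highly informative.
#'
#' @param t term identifier.
#' @param counts a `corpus_counts` object.
#' @param params a `semantic_params` (only `log_base` is used).
#' @return a non-negative scalar.
#' @export
ic_value <- function(t, counts, params = semantic_params("lncsim2")) {
  stopifnot(inherits(counts, "corpus_counts"))
  dt <- counts$dags_count[t]
  if (any(is.na(dt))) stop("term(s) absent from corpus: ",
                           paste(t[is.na(dt)], collapse = ", "))
  if (counts$D == 0 || any(dt == 0)) stop("zero corpus count")
  unname(-log(dt / counts$D, base = params$log_base))
}

#' Information-content contribution factor
#'
#' `P_t = (max_k Dags(k) - Dags(t)) / D`: the rarity bonus a term earns
#' relative to the most ubiquitous term in the corpus. The most frequent
#' term has `P_t = 0`; `P_t` grows as `Dags(t)` shrinks, so it lies in
#' `[0, 1)`. The IDSSIM recursion adds `P_t` to the decay factor.
#'
#' @inheritParams ic_value
#' @return a scalar in `[0, 1)` (vectorised over `t`).
#' @export
ic_contribution_factor <- function(t, counts) {
  stopifnot(inherits(counts, "corpus_counts"))
  dt <- counts$dags_count[t]
  if (any(is.na(dt))) stop("term(s) absent from corpus: ",
                           paste(t[is.na(dt)], collapse = ", "))
  unname((counts$max_dags - dt) / counts$D)
}

# Shared recursive evaluator: contribution of the disease is 1; any other
# term takes max over its DAG children of weight(t, child) * contrib(child).
# Memoised; a directed cycle in the DAG is a structural error.
sv_recursive <- function(dag, weight_fn) {
  A <- dag$disease
  kids <- split(dag$edges[, "child"], dag$edges[, "parent"])
  memo <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())   # cycle guard
  eval_t <- function(t) {
    key <- t
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (!is.null(state[[key]])) stop("cycle detected in DAG at term '", t, "'")
    state[[key]] <- TRUE
    v <- if (t == A) 1 else {
      ch <- kids[[t]]
      if (is.null(ch)) stop("term '", t, "' has no path to the disease")
      max(vapply(ch, function(cc) weight_fn(t, cc) * eval_t(cc), numeric(1L)))
    }
    memo[[key]] <- v
    v
  }
  contrib <- vapply(dag$terms, eval_t, numeric(1L))
  names(contrib) <- dag$terms
  contrib
}

new_profile <- function(disease, model, contrib) {
  structure(list(disease = disease, model = model, contrib = contrib,
                 total = sum(contrib)),
            class = "semantic_profile")
}

#' @export
print.semantic_profile <- function(x, ...) {
  cat("Semantic profile of '", x$disease, "' (", x$model, "): ",
      length(x$contrib), " terms, SV = ", format(x$total), "\n", sep = "")
  invisible(x)
}

#' Semantic profile under plain recursive decay (LNCSIM1)
#'
#' @param dag a `disease_dag`.
#' @param params a `semantic_params` with `model = "lncsim1"` (only
#'   `delta` is used).
#' @return a `semantic_profile`: per-term contributions and their sum
#'   `SV(A)`.
#' @export
sv_lncsim1 <- function(dag, params = semantic_params("lncsim1")) {
  stopifnot(inherits(dag, "disease_dag"))
  contrib <- sv_recursive(dag, function(t, child) params$delta)
  new_profile(dag$disease, "lncsim1", contrib)
}

#' Semantic profile under the information-content model (LNCSIM2)
#'
#' Per-term contributions are the corpus IC values; they do not depend on
#' which disease's DAG the term sits in.
#'
#' @param dag a `disease_dag`.
#' @param counts a `corpus_counts`.
#' @param params a `semantic_params` (only `log_base` is used).
#' @return a `semantic_profile`.
#' @export
sv_lncsim2 <- function(dag, counts, params = semantic_params("lncsim2")) {
  stopifnot(inherits(dag, "disease_dag"))
  contrib <- stats::setNames(ic_value(dag$terms, counts, params), dag$terms)
  new_profile(dag$disease, "lncsim2", contrib)
}

#' Semantic profile under decay with IC contribution factor (IDSSIM)
#'
#' The disease itself contributes 1; every other DAG term contributes the
#' maximum over its DAG children of `(delta + P_t) * contribution(child)`,
#' where `P_t` is the IC contribution factor of the term being scored.
#' Because `delta + P_t` may exceed 1, contributions can grow along a
#' path; no clipping is applied (the similarity normalisation keeps
#' pairwise scores in `[0, 1]` regardless).
#'
#' @param dag a `disease_dag`.
#' @param counts a `corpus_counts` covering every DAG term.
#' @param params a `semantic_params` (`delta` and `p_on_child` are used).
#' @return a `semantic_profile`.
#' @export
sv_idssim <- function(dag, counts, params = semantic_params("idssim")) {
  stopifnot(inherits(dag, "disease_dag"), inherits(counts, "corpus_counts"))
  missing <- setdiff(dag$terms, names(counts$dags_count))
  if (length(missing))
    stop("no corpus count for DAG term(s): ", paste(missing, collapse = ", "))
  wf <- if (params$p_on_child) {
    function(t, child) params$delta + ic_contribution_factor(child, counts)
  } else {
    function(t, child) params$delta + ic_contribution_factor(t, counts)
  }
  contrib <- sv_recursive(dag, wf)
  new_profile(dag$disease, "idssim", contrib)
}

#' Semantic profile dispatcher
#'
#' @param vocab a `mesh_vocab`.
#' @param disease a term of the vocabulary.
#' @param params a `semantic_params` selecting the model.
#' @param counts a `corpus_counts`; computed from `vocab` when `NULL` and
#'   the model needs it.
#' @return a `semantic_profile`.
#' @export
semantic_profile <- function(vocab, disease, params = semantic_params(),
                             counts = NULL) {
  dag <- build_dag(vocab, disease)
  if (params$model != "lncsim1" && is.null(counts))
    counts <- corpus_counts(vocab)
  switch(params$model,
         lncsim1 = sv_lncsim1(dag, params),
         lncsim2 = sv_lncsim2(dag, counts, params),
         idssim  = sv_idssim(dag, counts, params))
}

#' Disease semantic similarity of two profiles
#'
#' `DSS(A, B)` is the contribution mass the two DAGs place on their shared
#' terms, normalised by the two semantic values:
#' `sum over shared t of (SV_A(t) + SV_B(t)) / (SV(A) + SV(B))`. It is 0
#' when the DAGs share no term and 1 for a disease with itself.
#'
#' @param profile_a,profile_b `semantic_profile` objects computed under
#'   the same model and parameters.
#' @return a scalar in `[0, 1]`.
#' @export
dss <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "semantic_profile"),
            inherits(profile_b, "semantic_profile"))
  if (profile_a$model != profile_b$model)
    stop("profiles computed under different models: ",
         profile_a$model, " vs ", profile_b$model)
  shared <- intersect(names(profile_a$contrib), names(profile_b$contrib))
  if (!length(shared)) return(0)
  denom <- profile_a$total + profile_b$total
  if (denom <= 0) return(0)   # only possible for all-zero IC profiles
  sum(profile_a$contrib[shared] + profile_b$contrib[shared]) / denom
}

#' Pairwise disease semantic similarity matrix
#'
#' @param vocab a `mesh_vocab`.
#' @param diseases ordered character vector of terms (defaults to all
#'   vocabulary terms).
#' @param params a `semantic_params`.
#' @param counts optional `corpus_counts`; computed from `vocab` when
#'   needed. Supplying counts explicitly allows scoring against a larger
#'   reference corpus than the loaded subset.
#' @return a symmetric numeric matrix with `diseases` as both dimnames,
#'   unit diagonal, entries in `[0, 1]`.
#' @export
dss_matrix <- function(vocab, diseases = vocab$terms,
                       params = semantic_params(), counts = NULL) {
  stopifnot(inherits(vocab, "mesh_vocab"))
  bad <- setdiff(diseases, vocab$terms)
  if (length(bad))
    stop("disease(s) not in vocabulary: ", paste(bad, collapse = ", "))
  if (params$model != "lncsim1" && is.null(counts))
    counts <- corpus_counts(vocab)
  profiles <- lapply(diseases, function(d)
    semantic_profile(vocab, d, params, counts))
  n <- length(diseases)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- dss(profiles[[i]], profiles[[j]])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  # LNCSIM2 self-similarity is still 1 by the shared-term formula
  dimnames(m) <- list(diseases, diseases)
  m
}
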