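# Disease vocabulary: parsing, per-disease ancestor DAGs, corpus counts.

#' Construct a disease vocabulary
#'
#' A vocabulary maps each disease term (its canonical name, case-sensitive
#' after trimming) to one or more dot-delimited tree numbers, the prefix
#' codes that place the term in the hierarchy (as MeSH descriptors place
#' diseases in the MeSH trees). Every tree number belongs to exactly one
#' term; truncating a tree number at a dot yields the code of the parent
#' node where that parent exists in the vocabulary.
#'
#' @param tree_numbers named list; names are term identifiers, each element
#'   a non-empty character vector of tree numbers.
#' @param tree_number_prefixes optional character vector; when given, only
#'   tree numbers starting with one of these prefixes are kept (e.g. `"C"`
#'   restricts to the disease category), and terms left without any tree
#'   number are dropped.
#' @return an object of class `mesh_vocab` with components `terms`,
#'   `tree_numbers` and `node_index` (tree number -> owning term).
#' @export
mesh_vocab <- function(tree_numbers, tree_number_prefixes = NULL) {
  if (!is.list(tree_numbers) || is.null(names(tree_numbers)))
    stop("`tree_numbers` must be a named list of character vectors")
  names(tree_numbers) <- trimws(names(tree_numbers))
  tree_numbers <- lapply(tree_numbers, function(x) unique(trimws(x)))
  if (!is.null(tree_number_prefixes)) {
    keep_tn <- function(x) x[Reduce(`|`, lapply(tree_number_prefixes,
                                                function(p) startsWith(x, p)))]
    tree_numbers <- lapply(tree_numbers, keep_tn)
    tree_numbers <- tree_numbers[vapply(tree_numbers, length, 1L) > 0]
    if (!length(tree_numbers))
      stop("no terms left after applying tree_number_prefixes")
  }
  if (anyDuplicated(names(tree_numbers))) {
    # merge tree-number sets of repeated terms, keeping first-seen order
    ord <- unique(names(tree_numbers))
    tree_numbers <- lapply(split(tree_numbers, names(tree_numbers))[ord],
                           function(e) unique(unlist(e, use.names = FALSE)))
  }
  if (any(vapply(tree_numbers, length, 1L) == 0L))
    stop("every term needs at least one tree number")
  all_tn <- unlist(tree_numbers, use.names = FALSE)
  if (anyDuplicated(all_tn)) {
    dup <- unique(all_tn[duplicated(all_tn)])
    stop("tree number(s) assigned to more than one term: ",
         paste(dup, collapse = ", "))
  }
  node_index <- stats::setNames(
    rep(names(tree_numbers), vapply(tree_numbers, length, 1L)), all_tn)
  structure(list(terms = names(tree_numbers),
                 tree_numbers = tree_numbers,
                 node_index = node_index),
            class = "mesh_vocab")
}

#' @export
print.mesh_vocab <- function(x, ...) {
  cat("Disease vocabulary:", length(x$terms), "terms,",
      length(x$node_index), "tree numbers\n")
  show <- utils::head(x$terms, 5L)
  for (t in show)
    cat("  ", t, " [", paste(x$tree_numbers[[t]], collapse = "; "), "]\n",
        sep = "")
  if (length(x$terms) > 5L) cat("  ...\n")
  invisible(x)
}

#' Parse a MeSH descriptor ASCII file
#'
#' Reads the NLM descriptor ASCII dialect: records separated by a
#' `*NEWRECORD` line, with repeatable `MH = ` (heading, the term
#' identifier) and `MN = ` (tree number) fields. Records without any tree
#' number are dropped, mirroring the usual quality-control rule that
#' diseases lacking tree numbers cannot take part in semantic similarity.
#'
#' @param path file path.
#' @inheritParams mesh_vocab
#' @return a `mesh_vocab` object.
#' @export
parse_mesh_ascii <- function(path, tree_number_prefixes = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    warning("empty vocabulary file: ", path)
    return(empty_vocab())
  }
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))
  rec_start <- which(lines == "*NEWRECORD")
  if (!length(rec_start)) rec_start <- 1L
  bounds <- c(rec_start, length(lines) + 1L)
  tns <- list()
  for (i in seq_along(rec_start)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    mh <- sub("^MH = ", "", grep("^MH = ", block, value = TRUE))
    mn <- sub("^MN = ", "", grep("^MN = ", block, value = TRUE))
    if (!length(mn)) next                      # QC: no tree numbers
    if (!length(mh))
      stop("record with MN but no MH at byte offset ", offsets[bounds[i]])
    tns[[mh[1L]]] <- unique(c(tns[[mh[1L]]], mn))
  }
  if (!length(tns)) {
    warning("no usable records in ", path)
    return(empty_vocab())
  }
  mesh_vocab(tns, tree_number_prefixes)
}

#' Parse a two-column vocabulary TSV
#'
#' Portable vocabulary format: a header line `term<TAB>tree_numbers`, then
#' one term per line with its tree numbers joined by `";"`. A term listed
#' on several lines has its tree-number sets merged; a duplicated
#' (term, tree number) pair is deduplicated with a warning; the same tree
#' number under two different terms is an error.
#'
#' @inheritParams parse_mesh_ascii
#' @return a `mesh_vocab` object.
#' @export
parse_vocab_tsv <- function(path, tree_number_prefixes = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "")
  if (!all(c("term", "tree_numbers") %in% names(df)))
    stop("vocabulary TSV needs columns 'term' and 'tree_numbers'")
  if (!nrow(df)) {
    warning("empty vocabulary file: ", path)
    return(empty_vocab())
  }
  tns <- lapply(split(df$tree_numbers, df$term), function(x)
    unlist(strsplit(x, ";", fixed = TRUE)))
  ndup <- sum(vapply(tns, function(x) sum(duplicated(trimws(x))), 1L))
  if (ndup > 0)
    warning(ndup, " duplicate (term, tree number) pair(s) deduplicated")
  mesh_vocab(tns, tree_number_prefixes)
}

empty_vocab <- function() {
  structure(list(terms = character(0), tree_numbers = list(),
                 node_index = stats::setNames(character(0), character(0))),
            class = "mesh_vocab")
}

#' Write a vocabulary as TSV
#'
#' @param vocab a `mesh_vocab`.
#' @param path output path.
#' @param provenance optional character vector written as leading `#`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_vocab_tsv <- function(vocab, path, provenance = NULL) {
  stopifnot(inherits(vocab, "mesh_vocab"))
  lines <- c(if (length(provenance)) paste0("# ", provenance),
             "term\ttree_numbers",
             vapply(vocab$terms, function(t)
               paste0(t, "\t", paste(vocab$tree_numbers[[t]], collapse = ";")),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

# Ancestor term set of `disease`: every vocabulary term owning a prefix of
# any of its tree numbers, plus the disease itself.
ancestor_terms <- function(vocab, disease) {
  pre <- unlist(lapply(vocab$tree_numbers[[disease]], tn_prefixes),
                use.names = FALSE)
  owned <- vocab$node_index[unique(pre)]
  unique(c(disease, owned[!is.na(owned)]))
}

#' Build the ancestor DAG of one disease
#'
#' The DAG of disease `A` is the graph of its ancestor terms (including
#' `A` itself) induced by the prefix structure of its tree numbers: each
#' tree number's dot-truncation chain contributes the terms owning the
#' existing prefixes, with an edge from each term to the next more
#' specific one. Prefixes with no owning term in the vocabulary are
#' skipped and the chain continues (real vocabulary subsets are
#' incomplete). `layer` is the shortest ancestor-path distance from the
#' disease (0 at the disease itself); it is informational only.
#'
#' @param vocab a `mesh_vocab`.
#' @param disease a term in `vocab`.
#' @return an object of class `disease_dag` with components `disease`,
#'   `terms`, `edges` (two-column character matrix, parent then child) and
#'   `layer` (named integer vector).
#' @export
build_dag <- function(vocab, disease) {
  stopifnot(inherits(vocab, "mesh_vocab"))
  if (!disease %in% vocab$terms) {
    near <- agrep(disease, vocab$terms, max.distance = 0.3, value = TRUE)
    stop("unknown disease '", disease, "'",
         if (length(near)) paste0("; did you mean: ",
                                  paste(utils::head(near, 5L), collapse = ", ")))
  }
  terms <- disease
  edges <- matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  for (tn in vocab$tree_numbers[[disease]]) {
    chain <- tn_prefixes(tn)
    owner <- vocab$node_index[chain]
    owner[length(chain)] <- disease          # the full code is the disease's
    owner <- owner[!is.na(owner)]
    terms <- c(terms, owner)
    if (length(owner) >= 2L) {
      pc <- cbind(parent = owner[-length(owner)], child = owner[-1L])
      pc <- pc[pc[, 1L] != pc[, 2L], , drop = FALSE]  # a term owning two
      edges <- rbind(edges, pc)                        # chain levels: no loop
    }
  }
  terms <- unique(terms)
  edges <- unique(edges)
  rownames(edges) <- NULL
  # shortest-path layers from the disease, walking child -> parent
  layer <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  layer[disease] <- 0L
  frontier <- disease
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    parents <- unique(edges[edges[, "child"] %in% frontier, "parent"])
    frontier <- parents[is.na(layer[parents])]
    layer[frontier] <- d
  }
  structure(list(disease = disease, terms = terms, edges = edges,
                 layer = layer),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("Disease DAG of '", x$disease, "': ", length(x$terms), " terms, ",
      nrow(x$edges), " edges, ", max(x$layer) + 1L, " layer(s)\n", sep = "")
  invisible(x)
}

#' Corpus-level DAG frequencies
#'
#' For each term `t`, `Dags(t)` is the number of diseases in the
#' vocabulary whose ancestor DAG contains `t` (each term appears at least
#' in its own DAG). `D` is the number of diseases in the vocabulary and
#' `max_dags` the largest count; these feed the information-content
#' quantities of the semantic models.
#'
#' @param vocab a non-empty `mesh_vocab`.
#' @return an object of class `corpus_counts` with components `D`,
#'   `dags_count` (named integer vector over all terms) and `max_dags`.
#' @export
corpus_counts <- function(vocab) {
  stopifnot(inherits(vocab, "mesh_vocab"))
  if (!length(vocab$terms)) stop("empty vocabulary")
  anc <- unlist(lapply(vocab$terms, function(k) ancestor_terms(vocab, k)),
                use.names = FALSE)
  tab <- table(factor(anc, levels = vocab$terms))
  dags_count <- stats::setNames(as.integer(tab), vocab$terms)
  structure(list(D = length(vocab$terms), dags_count = dags_count,
                 max_dags = max(dags_count)),
            class = "corpus_counts")
}

#' @export
print.corpus_counts <- function(x, ...) {
  cat("Corpus counts: D =", x$D, ", max Dags(t) =", x$max_dags, "\n")
  invisible(x)
}
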