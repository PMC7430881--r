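# Labelled matrix I/O. All files are plain text; provenance lines start
# with '#' and are skipped on read. Matrices always carry row/column
# labels so misalignment is detected by name, never by position.

#' Read a binary association matrix from CSV/TSV
#'
#' Layout: header row of disease names, first column of lncRNA names,
#' cells 0/1. The separator is inferred from the file extension
#' (`.tsv` -> tab, otherwise comma) unless given.
#'
#' @param path file path.
#' @param sep field separator; inferred when `NULL`.
#' @return a validated binary matrix.
#' @export
read_assoc <- function(path, sep = NULL) {
  m <- read_labelled(path, sep)
  validate_assoc(m)
  m
}

#' Read a similarity (or prediction) matrix from CSV/TSV
#'
#' @inheritParams read_assoc
#' @return a numeric matrix with row and column names.
#' @export
read_matrix <- function(path, sep = NULL) {
  read_labelled(path, sep)
}

read_labelled <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          comment.char = "#", check.names = FALSE,
                          quote = "\"")
  as.matrix(df)
}

#' Write a labelled matrix as CSV/TSV
#'
#' Numeric cells are written with 10 significant digits; optional
#' provenance lines are prefixed with `#`.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @param provenance optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = NULL, provenance = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("", colnames(m)), collapse = sep), con)
  body <- apply(m, 1L, function(r)
    paste(format(signif(r, 10L), trim = TRUE, scientific = FALSE),
          collapse = sep))
  writeLines(paste(rownames(m), body, sep = sep), con)
  invisible(path)
}

# One-line provenance stamp for output files.
provenance_stamp <- function(...) {
  kv <- c(...)
  c(paste0("idssim ", as.character(utils::packageVersion("idssim"))),
    if (length(kv)) paste(names(kv), kv, sep = "="))
}
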