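# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomness in the package flows
# through explicit seeds; nothing perturbs the global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of y over x (x non-decreasing).
trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# All dot-truncation prefixes of a tree number, shortest first, the full
# code last. "C04.588.322" -> c("C04", "C04.588", "C04.588.322").
tn_prefixes <- function(tn) {
  parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
  vapply(seq_along(parts), function(i) paste(parts[seq_len(i)], collapse = "."),
         character(1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
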