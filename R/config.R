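# Run configuration: one validated object tying the module parameters
# together, loadable from a flat YAML file with flag overrides.

config_defaults <- function() {
  list(model = "idssim", delta = 0.5, log_base = exp(1),
       p_on_child = FALSE, fs_from_masked = TRUE,
       k = 5L, eta = 0.9, repeats = 10L, base_seed = 1L,
       tree_number_prefixes = NULL)
}

#' Assemble and validate a run configuration
#'
#' Fields and defaults: `model` ("idssim"), `delta` (0.5),
#' `log_base` (e), `p_on_child` (FALSE), `fs_from_masked` (TRUE),
#' `k` (5), `eta` (0.9), `repeats` (10), `base_seed` (1),
#' `tree_number_prefixes` (NULL = accept all). Every field is validated
#' against its module's invariants before any computation starts.
#'
#' @param ... named overrides of the defaults.
#' @return an object of class `idssim_config`.
#' @export
idssim_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(cfg), collapse = ", "))
  cfg[names(over)] <- over
  # reuse the module validators
  sp <- semantic_params(cfg$model, cfg$delta, cfg$log_base, cfg$p_on_child)
  cfg$model <- sp$model
  if (!is.numeric(cfg$k) || cfg$k < 1)
    stop("`k` must be an integer >= 1")
  if (!is.numeric(cfg$eta) || cfg$eta <= 0 || cfg$eta > 1)
    stop("`eta` must satisfy 0 < eta <= 1")
  if (!is.numeric(cfg$repeats) || cfg$repeats < 1)
    stop("`repeats` must be an integer >= 1")
  if (!is.numeric(cfg$base_seed))
    stop("`base_seed` must be an integer")
  if (!is.logical(cfg$fs_from_masked))
    stop("`fs_from_masked` must be TRUE or FALSE")
  cfg$k <- as.integer(cfg$k)
  cfg$repeats <- as.integer(cfg$repeats)
  cfg$base_seed <- as.integer(cfg$base_seed)
  structure(cfg, class = "idssim_config")
}

#' Load a configuration file with overrides
#'
#' The file is flat YAML (`key: value`); `overrides` (e.g. parsed
#' command-line flags) win over file values, which win over defaults.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides named list of overriding values.
#' @return an `idssim_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("cannot read config file: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  do.call(idssim_config, vals)
}

#' @export
print.idssim_config <- function(x, ...) {
  cat("idssim configuration:\n")
  for (k in names(unclass(x))) {
    v <- x[[k]]
    cat("  ", k, ": ", if (is.null(v)) "<all>" else paste(format(v),
        collapse = ","), "\n", sep = "")
  }
  invisible(x)
}

config_stamp <- function(cfg) {
  flat <- unclass(cfg)
  flat$tree_number_prefixes <- paste(flat$tree_number_prefixes %||% "all",
                                     collapse = ",")
  paste(names(flat), vapply(flat, function(v) paste(format(v), collapse = ","),
                            character(1L)), sep = "=", collapse = " ")
}
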