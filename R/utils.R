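# Internal helpers shared across modules.

#' @importFrom tools md5sum
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed recipekit condition
#'
#' All package errors carry a subclass of `recipekit_error` so callers can
#' distinguish validation, binding, evaluation, integrity, ... failures.
#' @noRd
rk_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "recipekit_error", "error")))
}

#' MD5 digest of a character string (via a temporary file)
#' @noRd
md5_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(charToRaw(x), tf)
  unname(tools::md5sum(tf))
}

#' Current time as ISO-8601 UTC with seconds precision
#' @noRd
iso8601_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

is_iso8601 <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(Z|[+-]\\d{2}:?\\d{2})?$", x)
}

#' Sanitize a value for use in a file-name token: runs of characters outside
#' [A-Za-z0-9._-] collapse to a single hyphen.
#' @noRd
sanitize_token <- function(x) {
  x <- gsub("[^A-Za-z0-9._-]+", "-", as.character(x))
  x <- gsub("^-+|-+$", "", x)
  if (!nzchar(x)) "x" else x
}

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

#' Canonical JSON for a parameter binding set: keys sorted, scalars unboxed.
#' Used as the exact-match lookup key in bucket manifests.
#' @noRd
canonical_params_json <- function(params) {
  params <- as.list(params)
  if (length(params)) params <- params[order(names(params))]
  as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA))
}

#' Deterministic lexicographic sort (C collation, independent of locale)
#' @noRd
sort_c <- function(x) sort(x, method = "radix")

#' Write a YAML document with stable scalar styles (logicals as true/false)
#' @noRd
write_yaml_stable <- function(x, path) {
  txt <- yaml::as.yaml(x, handlers = list(logical = yaml::verbatim_logical))
  writeLines(sub("\n$", "", txt), path, sep = "\n")
  invisible(path)
}
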