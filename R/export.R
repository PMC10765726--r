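# Prepare curated data for downstream tools (CWL/WDL-style job-input
# documents) and fetch pre-built curated files from a remote "bucket"
# described by a checksum manifest.

## ---- workflow job inputs ----------------------------------------------------

#' Build a workflow job-input document from curated data records
#'
#' Each record's primary data file becomes a CWL-convention File object
#' (`{class: "File", path: <absolute path>}`); recorded secondary files
#' populate its `secondaryFiles`. The document serializes to JSON or YAML
#' and can be fed to CWL/WDL engines as a job file.
#'
#' @param records List of `data_record`s (or a single record / `data_index`).
#' @param key_map Named character vector mapping record id to the workflow
#'   input name it should be exposed under. Must cover every record; input
#'   names must be unique.
#' @param format `"json"` or `"yaml"`.
#' @param allow_missing Permit referenced paths that do not exist (for
#'   assembling documents ahead of a transfer).
#' @return A `workflow_input_doc` with fields `format` and `entries`
#'   (ordered by input name).
#' @export
to_workflow_inputs <- function(records, key_map, format = c("json", "yaml"),
                               allow_missing = FALSE) {
  format <- match.arg(format)
  records <- as_record_list(records)
  ids <- vapply(records, `[[`, "", "id")
  if (!all(ids %in% names(key_map))) {
    rk_abort(sprintf("key_map does not cover record id(s): %s",
                     paste(setdiff(ids, names(key_map)), collapse = ", ")),
             "recipekit_validation_error")
  }
  keys <- unname(key_map[ids])
  if (anyDuplicated(keys)) {
    rk_abort(sprintf("duplicate workflow input name(s): %s",
                     paste(unique(keys[duplicated(keys)]), collapse = ", ")),
             "recipekit_validation_error")
  }
  entries <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    roles <- vapply(rec$meta$outputs, `[[`, "", "role")
    rels <- vapply(rec$meta$outputs, `[[`, "", "path")
    base <- dirname(rec$yml_path)
    paths <- file.path(base, rels)
    if (!allow_missing && any(!file.exists(paths))) {
      rk_abort(sprintf("exported path does not exist: %s",
                       paste(paths[!file.exists(paths)], collapse = ", ")),
               "recipekit_io_error")
    }
    primaries <- paths[roles == "primary"]
    secondaries <- paths[roles == "secondary"]
    file_obj <- function(p) {
      o <- list(class = "File", path = p)
      if (length(secondaries)) {
        o$secondaryFiles <- lapply(secondaries, function(s)
          list(class = "File", path = s))
      }
      o
    }
    entries[[keys[i]]] <- if (length(primaries) == 1L) {
      file_obj(primaries[1])
    } else {
      lapply(primaries, file_obj)
    }
  }
  entries <- entries[sort_c(names(entries))]
  structure(list(format = format, entries = entries),
            class = "workflow_input_doc")
}

#' Serialize a workflow job-input document
#'
#' @param doc A `workflow_input_doc`.
#' @return Document text in the doc's format (JSON or YAML).
#' @export
format_workflow_inputs <- function(doc) {
  stopifnot(inherits(doc, "workflow_input_doc"))
  if (doc$format == "json") {
    as.character(jsonlite::toJSON(doc$entries, auto_unbox = TRUE, pretty = TRUE))
  } else {
    yaml::as.yaml(doc$entries)
  }
}

#' @rdname format_workflow_inputs
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_workflow_inputs <- function(doc, path) {
  writeLines(format_workflow_inputs(doc), path)
  invisible(path)
}

## ---- bucket manifests and remote fetch --------------------------------------

#' Default transport: resolve a location to a local file path
#'
#' Handles plain paths and `file://` URLs. Other transports (HTTP, cloud
#' buckets) can be injected wherever a `transport` argument is accepted: a
#' transport is `function(location) -> local file path`.
#' @param location Path or file:// URL.
#' @return Local file path.
#' @export
local_transport <- function(location) {
  sub("^file://", "", location)
}

MD5_RE <- "^[0-9a-f]{32}$"

#' Read a bucket manifest
#'
#' A manifest is a TSV with header `recipe  params_json  path  md5  size`
#' listing pre-built curated files: the recipe that made each file, the
#' parameter bindings as canonical JSON (sorted keys), the file's location
#' relative to the bucket base, its MD5 and size.
#'
#' @param location Manifest path or URL (resolved through `transport`).
#' @param transport See [local_transport()].
#' @param base Base location the manifest's relative paths resolve against;
#'   defaults to the manifest's own directory.
#' @return A `bucket_manifest` with fields `base` and `entries` (data frame:
#'   recipe, params_json, path, md5, size).
#' @export
read_manifest <- function(location, transport = local_transport, base = NULL) {
  path <- transport(location)
  if (!file.exists(path)) {
    rk_abort(sprintf("manifest not readable: %s", location), "recipekit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    rk_abort("manifest is empty (missing header line)", "recipekit_parse_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("recipe", "params_json", "path", "md5", "size")
  if (!identical(header, expected)) {
    rk_abort(sprintf("manifest header must be '%s'",
                     paste(expected, collapse = "\\t")),
             "recipekit_parse_error")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) {
      rk_abort(sprintf("manifest line %d: expected 5 tab-separated fields, got %d",
                       i + 1L, length(f)),
               "recipekit_parse_error", line = i + 1L)
    }
    if (!grepl(MD5_RE, f[4])) {
      rk_abort(sprintf("manifest line %d: '%s' is not a 32-char hex MD5",
                       i + 1L, f[4]),
               "recipekit_parse_error", line = i + 1L)
    }
    rows[[i]] <- data.frame(recipe = f[1], params_json = f[2], path = f[3],
                            md5 = f[4], size = as.numeric(f[5]),
                            stringsAsFactors = FALSE)
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recipe = character(), params_json = character(),
               path = character(), md5 = character(), size = numeric(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(entries$path)) {
    rk_abort(sprintf("manifest: duplicate relative path(s): %s",
                     paste(unique(entries$path[duplicated(entries$path)]),
                           collapse = ", ")),
             "recipekit_validation_error")
  }
  structure(list(base = base %||% dirname(path), entries = entries),
            class = "bucket_manifest")
}

#' Write a bucket manifest
#'
#' @param manifest A `bucket_manifest`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "bucket_manifest"))
  e <- manifest$entries
  lines <- c(paste(c("recipe", "params_json", "path", "md5", "size"),
                   collapse = "\t"),
             if (nrow(e)) paste(e$recipe, e$params_json, e$path, e$md5,
                                format(e$size, scientific = FALSE, trim = TRUE),
                                sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Fetch a pre-built curated file from a bucket
#'
#' Looks up the (recipe, params) entry in the manifest, copies the file into
#' `dest` via the transport, checks its MD5 against the manifest, and writes
#' a synthetic `.yml` provenance sidecar (origin = bucket location, date =
#' fetch time) so the fetched file is indexable by [data_update()] and
#' verifiable by [verify()] exactly like locally curated data.
#'
#' @param manifest A [read_manifest()] result.
#' @param recipe_name Recipe name to look up.
#' @param params Parameter bindings; matched exactly against the manifest's
#'   canonical params JSON.
#' @param dest Destination directory (created if needed).
#' @param transport See [local_transport()].
#' @param recipe Optional [recipe()] used to name the sidecar with values in
#'   declaration order; without it, sorted parameter order is used.
#' @return The fetched `data_record`.
#' @export
fetch_remote <- function(manifest, recipe_name, params, dest,
                         transport = local_transport, recipe = NULL) {
  stopifnot(inherits(manifest, "bucket_manifest"))
  want <- canonical_params_json(params)
  e <- manifest$entries
  hit <- which(e$recipe == recipe_name & e$params_json == want)
  if (!length(hit)) {
    near <- e$params_json[e$recipe == recipe_name]
    rk_abort(sprintf(
      "no bucket entry for recipe '%s' with params %s%s",
      recipe_name, want,
      if (length(near))
        sprintf("; available param sets for this recipe: %s",
                paste(near, collapse = " | "))
      else "; no entries for this recipe at all"),
      "recipekit_notfound_error", near_misses = near)
  }
  row <- e[hit[1], ]
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  dest <- normalizePath(dest)
  src <- transport(file.path(manifest$base, row$path))
  if (!file.exists(src)) {
    rk_abort(sprintf("bucket object not readable: %s", row$path),
             "recipekit_io_error")
  }
  target <- file.path(dest, basename(row$path))
  file.copy(src, target, overwrite = TRUE)
  got <- compute_md5(target)
  if (!identical(got, row$md5)) {
    quarantine <- paste0(target, ".corrupt")
    file.rename(target, quarantine)
    rk_abort(sprintf(
      "integrity check failed for %s: manifest md5 %s, downloaded %s; file quarantined as %s",
      row$path, row$md5, got, basename(quarantine)),
      "recipekit_integrity_error", quarantined = quarantine)
  }

  vals <- as.list(params)
  if (!is.null(recipe)) {
    vals <- resolve_bindings(recipe, params)
    prefix <- evaluation_prefix(recipe, vals)
  } else {
    vals <- vals[order(names(vals))]
    toks <- vapply(vals, function(v) sanitize_token(as.character(v)), "")
    prefix <- paste(c(recipe_name, toks), collapse = "_")
  }
  meta <- list(
    recipe = recipe_name,
    version = if (!is.null(recipe)) recipe$version else "unknown",
    params = vals,
    date = iso8601_now(),
    origin = as.character(manifest$base),
    command_file = NULL,
    outputs = list(list(path = basename(row$path), role = "primary",
                        md5 = row$md5, size = as.integer(row$size))),
    software = list(),
    notes = list(),
    tags = list()
  )
  meta <- meta[!vapply(meta, is.null, TRUE)]
  yml_path <- file.path(dest, paste0(prefix, ".yml"))
  write_yaml_stable(meta, yml_path)
  data_record(yml_path)
}
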