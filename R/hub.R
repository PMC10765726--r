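# Persistent, keyword-searchable catalogs: a recipe index synced from
# directories of recipe definition files, and a data index built by scanning
# directory trees for `.yml` provenance sidecars.
#
# Each index persists itself as a single JSON file inside its cache
# directory. The files on disk stay authoritative: the recipe index stores
# source paths and re-parses the recipe definitions on load, and the data
# index stores sidecar paths and re-parses the sidecars, so tags edited into
# a sidecar survive a reload.

RECIPE_INDEX_FILE <- "recipe-index.json"
DATA_INDEX_FILE <- "data-index.json"

## ---- recipe index ----------------------------------------------------------

#' Open (or create) a recipe index
#'
#' @param cache_dir Directory holding the index file; created if needed. An
#'   existing persisted index is loaded.
#' @return A `recipe_index`.
#' @export
recipe_index <- function(cache_dir) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- normalizePath(cache_dir)
  idx_file <- file.path(cache_dir, RECIPE_INDEX_FILE)
  idx <- structure(
    list(cache_dir = cache_dir, entries = list(), sources = character()),
    class = "recipe_index"
  )
  if (file.exists(idx_file)) {
    st <- jsonlite::read_json(idx_file, simplifyVector = FALSE)
    idx$sources <- as.character(unlist(st$sources))
    for (e in st$entries) {
      rec <- tryCatch(read_recipe(e$source), error = function(err) NULL)
      if (is.null(rec)) {
        warning(sprintf("recipe index entry '%s' no longer parses from %s; dropped",
                        e$name, e$source))
        next
      }
      idx$entries[[rec$name]] <- list(recipe = rec, source = e$source,
                                      synced = e$synced)
    }
  }
  idx
}

save_recipe_index <- function(index) {
  st <- list(
    sources = as.list(index$sources),
    entries = lapply(unname(index$entries), function(e)
      list(name = e$recipe$name, source = e$source, synced = e$synced))
  )
  jsonlite::write_json(st, file.path(index$cache_dir, RECIPE_INDEX_FILE),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(index)
}

#' Sync recipe definitions from a source directory into an index
#'
#' All `*.yaml` files under `source` (recursively) are parsed and upserted by
#' recipe name; an index holds one version per name, latest sync winning
#' (with a warning when the version changes). Files that fail to parse are
#' reported in the returned index's `last_report`, not fatal.
#'
#' @param index A [recipe_index()].
#' @param source Directory containing recipe `*.yaml` files. Remote sources
#'   can be handled by materializing them to a local directory first (the
#'   transport is deliberately outside this function).
#' @return The updated (and persisted) index; `$last_report` lists files that
#'   failed to parse with their messages.
#' @export
recipe_update <- function(index, source) {
  stopifnot(inherits(index, "recipe_index"))
  if (!dir.exists(source)) {
    rk_abort(sprintf("recipe source not readable: %s", source),
             "recipekit_io_error")
  }
  source <- normalizePath(source)
  files <- sort_c(list.files(source, pattern = "\\.yaml$", recursive = TRUE,
                             full.names = TRUE))
  report <- list()
  stamp <- iso8601_now()
  for (f in files) {
    rec <- tryCatch(read_recipe(f), error = function(e) {
      report[[f]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(rec)) next
    old <- index$entries[[rec$name]]
    if (!is.null(old) && !identical(old$recipe$version, rec$version)) {
      warning(sprintf("recipe '%s': replacing version %s with %s",
                      rec$name, old$recipe$version, rec$version))
    }
    index$entries[[rec$name]] <- list(recipe = rec, source = f, synced = stamp)
  }
  index$sources <- union(index$sources, source)
  index$last_report <- report
  save_recipe_index(index)
  index
}

#' Search a recipe index by keywords
#'
#' Case-insensitive substring match over each recipe's name and description;
#' multiple keywords are ANDed. An empty keyword list returns every recipe.
#'
#' @param index A [recipe_index()].
#' @param keywords Character vector of keywords.
#' @return List of matching `recipe` objects, sorted by name.
#' @export
recipe_search <- function(index, keywords = character()) {
  stopifnot(inherits(index, "recipe_index"))
  hits <- Filter(function(e) {
    hay <- tolower(paste(e$recipe$name, e$recipe$description))
    all(vapply(tolower(keywords), function(k) grepl(k, hay, fixed = TRUE), TRUE))
  }, index$entries)
  hits <- hits[sort_c(names(hits))]
  lapply(unname(hits), `[[`, "recipe")
}

#' Load a recipe from an index by name
#'
#' @param index A [recipe_index()].
#' @param name Recipe name.
#' @return The `recipe`.
#' @export
recipe_load <- function(index, name) {
  stopifnot(inherits(index, "recipe_index"))
  e <- index$entries[[name]]
  if (is.null(e)) {
    rk_abort(sprintf("no recipe named '%s' in index (have: %s)", name,
                     paste(recipe_names(index), collapse = ", ")),
             "recipekit_notfound_error")
  }
  e$recipe
}

#' @export
print.recipe_index <- function(x, ...) {
  cat(sprintf("<recipe_index> %d recipe(s) @ %s\n", length(x$entries),
              x$cache_dir))
  invisible(x)
}

## ---- data records ----------------------------------------------------------

#' Build a data record from a provenance sidecar
#'
#' @param yml_path Path to a `.yml` sidecar written by [evaluate()] or
#'   [fetch_remote()].
#' @return A `data_record`: id (MD5 of the sidecar path), sidecar path, data
#'   paths, recipe name, params, notes, tags, date, origin, the full parsed
#'   meta, and a `missing_data` flag.
#' @export
data_record <- function(yml_path) {
  if (!file.exists(yml_path)) {
    rk_abort(sprintf("sidecar not found: %s", yml_path), "recipekit_io_error")
  }
  yml_path <- normalizePath(yml_path)
  meta <- tryCatch(yaml::read_yaml(yml_path), error = function(e) {
    rk_abort(sprintf("malformed sidecar %s: %s", yml_path, conditionMessage(e)),
             "recipekit_parse_error")
  })
  for (field in c("recipe", "date", "outputs")) {
    if (is.null(meta[[field]])) {
      rk_abort(sprintf("sidecar %s: missing field '%s'", yml_path, field),
               "recipekit_validation_error")
    }
  }
  base <- dirname(yml_path)
  rels <- vapply(meta$outputs, `[[`, "", "path")
  data_paths <- file.path(base, rels)
  structure(
    list(
      id = md5_string(yml_path),
      yml_path = yml_path,
      data_paths = data_paths,
      recipe_name = meta$recipe,
      params = meta$params %||% list(),
      notes = as.character(unlist(meta$notes)),
      tags = as.character(unlist(meta$tags)),
      date = meta$date,
      origin = meta$origin %||% "local",
      meta = meta,
      missing_data = any(!file.exists(data_paths))
    ),
    class = "data_record"
  )
}

#' @export
print.data_record <- function(x, ...) {
  cat(sprintf("<data_record> %s (%s)\n", paste(data_names(x), collapse = ", "),
              x$recipe_name))
  if (length(x$tags)) cat("  tags:", paste(x$tags, collapse = ", "), "\n")
  invisible(x)
}

as_record_list <- function(x) {
  if (inherits(x, "data_record")) return(list(x))
  if (inherits(x, "data_index")) return(unname(x$records))
  if (is.list(x)) return(x)
  rk_abort("expected a data_record, data_index, or list of records",
           "recipekit_validation_error")
}

#' Data record accessors
#'
#' Field accessors mirroring the usual curated-data hub interface:
#' `data_names()` returns data-file basenames, `data_paths()` full paths,
#' `data_notes()` evaluation-time keywords, `data_params()` the parameter
#' bindings used, `data_tags()` mutable labels, and `data_yml()` the sidecar
#' path. Each accepts a single record, a list of records, or a `data_index`.
#'
#' @param x A `data_record`, list of records, or `data_index`.
#' @return `data_params` returns a named list per record; the others return
#'   character vectors (lists when given several records).
#' @export
data_names <- function(x) {
  recs <- as_record_list(x)
  out <- lapply(recs, function(r) basename(r$data_paths))
  if (length(recs) == 1L) out[[1]] else out
}

#' @rdname data_names
#' @export
data_paths <- function(x) {
  recs <- as_record_list(x)
  out <- lapply(recs, `[[`, "data_paths")
  if (length(recs) == 1L) out[[1]] else out
}

#' @rdname data_names
#' @export
data_notes <- function(x) {
  recs <- as_record_list(x)
  out <- lapply(recs, `[[`, "notes")
  if (length(recs) == 1L) out[[1]] else out
}

#' @rdname data_names
#' @export
data_params <- function(x) {
  recs <- as_record_list(x)
  out <- lapply(recs, `[[`, "params")
  if (length(recs) == 1L) out[[1]] else out
}

#' @rdname data_names
#' @export
data_tags <- function(x) {
  recs <- as_record_list(x)
  out <- lapply(recs, `[[`, "tags")
  if (length(recs) == 1L) out[[1]] else out
}

#' @rdname data_names
#' @export
data_yml <- function(x) {
  recs <- as_record_list(x)
  out <- vapply(recs, `[[`, "", "yml_path")
  if (length(recs) == 1L) out[[1]] else out
}

## ---- data index ------------------------------------------------------------

#' Open (or create) a data index
#'
#' @param cache_dir Directory holding the index file; created if needed. An
#'   existing persisted index is loaded, records re-parsed from their
#'   sidecars (which stay authoritative, e.g. for tags).
#' @return A `data_index`.
#' @export
data_index <- function(cache_dir) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- normalizePath(cache_dir)
  idx_file <- file.path(cache_dir, DATA_INDEX_FILE)
  idx <- structure(
    list(cache_dir = cache_dir, records = list(), scanned_roots = character()),
    class = "data_index"
  )
  if (file.exists(idx_file)) {
    st <- jsonlite::read_json(idx_file, simplifyVector = FALSE)
    idx$scanned_roots <- as.character(unlist(st$scanned_roots))
    for (p in as.character(unlist(st$yml_paths))) {
      rec <- tryCatch(data_record(p), error = function(e) NULL)
      if (is.null(rec)) {
        warning(sprintf("indexed sidecar no longer loads: %s; dropped", p))
        next
      }
      idx$records[[rec$id]] <- rec
    }
  }
  idx
}

save_data_index <- function(index) {
  st <- list(
    scanned_roots = as.list(index$scanned_roots),
    yml_paths = lapply(unname(index$records), `[[`, "yml_path")
  )
  jsonlite::write_json(st, file.path(index$cache_dir, DATA_INDEX_FILE),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(index)
}

#' Scan a directory tree for curated data and update the index
#'
#' Every `*.yml` sidecar under `root` (any depth) is parsed into a
#' `data_record` and upserted, keyed by sidecar path. Records whose data
#' files are gone are still indexed but carry `missing_data = TRUE`.
#' Malformed sidecars are skipped and listed in `$last_report`. Re-running
#' over the same tree is idempotent.
#'
#' @param index A [data_index()].
#' @param root Directory to scan recursively.
#' @return The updated (and persisted) index.
#' @export
data_update <- function(index, root) {
  stopifnot(inherits(index, "data_index"))
  if (!dir.exists(root)) {
    rk_abort(sprintf("data root not readable: %s", root), "recipekit_io_error")
  }
  root <- normalizePath(root)
  ymls <- sort_c(list.files(root, pattern = "\\.yml$", recursive = TRUE,
                            full.names = TRUE))
  report <- list()
  for (y in ymls) {
    rec <- tryCatch(data_record(y), error = function(e) {
      report[[y]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(rec)) next
    index$records[[rec$id]] <- rec
  }
  index$scanned_roots <- union(index$scanned_roots, root)
  index$last_report <- report
  save_data_index(index)
  index
}

#' Text haystack a data record is matched against
#' @noRd
record_haystack <- function(rec) {
  params_txt <- if (length(rec$params)) {
    paste(names(rec$params),
          vapply(rec$params, function(v) paste(as.character(v), collapse = " "), ""),
          sep = "=", collapse = " ")
  } else ""
  tolower(paste(rec$recipe_name, paste(basename(rec$data_paths), collapse = " "),
                paste(rec$notes, collapse = " "), paste(rec$tags, collapse = " "),
                params_txt))
}

#' Search curated data by keywords
#'
#' Case-insensitive substring match over the concatenation of recipe name,
#' data-file basenames, notes, tags, and stringified parameters (as
#' `name=value`); multiple keywords are ANDed. An empty keyword list returns
#' every record.
#'
#' @param index A [data_index()].
#' @param keywords Character vector of keywords.
#' @return List of matching `data_record`s, sorted by sidecar path.
#' @export
data_search <- function(index, keywords = character()) {
  stopifnot(inherits(index, "data_index"))
  hits <- Filter(function(rec) {
    hay <- record_haystack(rec)
    all(vapply(tolower(keywords), function(k) grepl(k, hay, fixed = TRUE), TRUE))
  }, index$records)
  ord <- order(vapply(hits, `[[`, "", "yml_path"), method = "radix")
  unname(hits[ord])
}

#' Assign tags to data records
#'
#' Tags are mutable labels (typically the name of a downstream tool that
#' consumes the data) used to group records. They are written both into the
#' index and back into each record's `.yml` sidecar, so they survive a
#' rescan and travel with the data.
#'
#' @param index A [data_index()].
#' @param ids Record ids (see `data_record$id`).
#' @param tags Character vector of labels; replaces the records' tag list.
#' @return The updated (and persisted) index.
#' @export
set_tags <- function(index, ids, tags) {
  stopifnot(inherits(index, "data_index"))
  tags <- as.character(tags)
  if (any(!nzchar(tags))) {
    rk_abort("tags must not contain empty strings", "recipekit_validation_error")
  }
  unknown <- setdiff(ids, names(index$records))
  if (length(unknown)) {
    rk_abort(sprintf("unknown record id(s): %s", paste(unknown, collapse = ", ")),
             "recipekit_notfound_error")
  }
  for (id in ids) {
    rec <- index$records[[id]]
    meta <- yaml::read_yaml(rec$yml_path)
    meta$tags <- as.list(tags)
    write_yaml_stable(meta, rec$yml_path)
    index$records[[id]] <- data_record(rec$yml_path)
  }
  save_data_index(index)
  index
}

#' @export
print.data_index <- function(x, ...) {
  cat(sprintf("<data_index> %d record(s) @ %s\n", length(x$records),
              x$cache_dir))
  invisible(x)
}
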