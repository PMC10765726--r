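# Recipe evaluation: render the script, run it in a scratch directory,
# promote glob-matched outputs into the destination, and write the four
# provenance sidecars (<prefix>.yml / .sh / .cwl / .md5).
#
# Scratch-then-move keeps script litter out of the curated directory: only
# files matching the recipe's output patterns are promoted. A failed run
# writes nothing into the destination, so an index can never see
# half-curated data.

#' Describe how a recipe script should be executed
#'
#' Only `direct-shell` (run with `sh -e`) is implemented in-process;
#' `conda-wrapped` and `cwl-engine` are pluggable hooks that must honour the
#' same contract (run the script in the given directory, return an exit
#' code), supplied via `options$exec`.
#'
#' @param mode One of `"direct-shell"`, `"conda-wrapped"`, `"cwl-engine"`.
#' @param options Free-form list; for pluggable modes, `options$exec` must be
#'   `function(script_path, workdir, stderr_path) -> exit code`.
#' @return A `runner_spec`.
#' @export
runner_spec <- function(mode = "direct-shell", options = list()) {
  mode <- match.arg(mode, c("direct-shell", "cwl-engine", "conda-wrapped"))
  if (mode != "direct-shell" && !is.function(options$exec)) {
    rk_abort(sprintf("runner mode '%s' requires an options$exec hook", mode),
             "recipekit_validation_error")
  }
  structure(list(mode = mode, options = options), class = "runner_spec")
}

run_script <- function(runner, script_path, workdir, stderr_path) {
  if (runner$mode == "direct-shell") {
    withr_dir <- getwd()
    on.exit(setwd(withr_dir), add = TRUE)
    setwd(workdir)
    status <- suppressWarnings(
      system2("sh", c("-e", shQuote(script_path)),
              stdout = stderr_path, stderr = stderr_path)
    )
    return(status)
  }
  runner$options$exec(script_path, workdir, stderr_path)
}

#' Deterministic sidecar/file-name prefix for an evaluation
#'
#' The recipe name joined with the sanitized bound values in parameter
#' declaration order, e.g. `echo_out_Hello-World_hello`.
#' @noRd
evaluation_prefix <- function(recipe, values) {
  toks <- vapply(recipe$parameters, function(p)
    sanitize_token(value_to_text(values[[p$name]], p$type)), "")
  paste(c(recipe$name, toks), collapse = "_")
}

#' Collect output files from an evaluation directory
#'
#' @param scratch_dir Directory the script ran in.
#' @param outputs List of [output_spec()].
#' @return Data frame with columns `path`, `name` (the output spec) and
#'   `role`; files sorted lexicographically within each spec. A glob that
#'   matches nothing contributes no rows.
#' @export
collect_outputs <- function(scratch_dir, outputs) {
  stopifnot(dir.exists(scratch_dir))
  rows <- lapply(outputs, function(o) {
    hits <- Sys.glob(file.path(scratch_dir, o$glob))
    hits <- hits[file.exists(hits) & !dir.exists(hits)]
    hits <- sort_c(hits)
    if (!length(hits)) return(NULL)
    data.frame(path = hits, name = o$name, role = o$role,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(path = character(), name = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' MD5 digest of a file
#'
#' @param path Existing file.
#' @return 32-character lowercase hex digest.
#' @export
compute_md5 <- function(path) {
  if (!file.exists(path)) {
    rk_abort(sprintf("cannot hash missing file: %s", path), "recipekit_io_error")
  }
  unname(tools::md5sum(path))
}

#' Write a GNU md5sum-compatible checksum manifest
#'
#' One `<digest>  <name>` line per file (two spaces), verifiable with
#' `md5sum -c` from `relative_to`.
#'
#' @param files Paths of existing files to hash.
#' @param path Manifest destination.
#' @param relative_to Directory the recorded names are relative to; defaults
#'   to the manifest's own directory.
#' @return `path`, invisibly.
#' @export
write_md5_manifest <- function(files, path, relative_to = dirname(path)) {
  lines <- vapply(files, function(f) {
    rel <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1",
                                normalizePath(relative_to)), "/?"),
               "", normalizePath(f))
    sprintf("%s  %s", compute_md5(f), rel)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

sidecar_meta <- function(recipe, values, notes, output_rows, outdir, prefix) {
  rel <- basename(output_rows$path)
  outs <- lapply(seq_len(nrow(output_rows)), function(i) {
    f <- file.path(outdir, rel[i])
    list(path = rel[i], role = output_rows$role[i],
         md5 = compute_md5(f), size = as.integer(file.size(f)))
  })
  list(
    recipe = recipe$name,
    version = recipe$version,
    params = values,
    date = iso8601_now(),
    origin = recipe$origin %||% "local",
    command_file = paste0(prefix, ".sh"),
    outputs = outs,
    software = lapply(recipe$requirements, function(q)
      list(tool = q$tool, version = q$version, source = q$source, spec = q$spec)),
    notes = as.list(notes),
    tags = list()
  )
}

#' Evaluate a data recipe
#'
#' Renders the script with the given bindings, runs it in a scratch
#' directory, moves files matching the recipe's output globs into `outdir`,
#' and writes four provenance sidecars sharing a deterministic prefix:
#' `<prefix>.yml` (standardized annotations: recipe, version, parameters,
#' ISO-8601 UTC date, origin, per-file MD5 and size, software, notes, tags),
#' `<prefix>.sh` (the exact rendered script), `<prefix>.cwl` (CWL wrapper)
#' and `<prefix>.md5` (md5sum-compatible manifest).
#'
#' @inheritParams validate_bindings
#' @param outdir Destination directory (created if needed).
#' @param notes Character vector of free-text keywords stored in the sidecar
#'   to aid later retrieval.
#' @param runner A [runner_spec()]; the default runs the script directly with
#'   `sh -e`.
#' @return An `evaluation_result` with fields `outdir`, `prefix`,
#'   `data_files`, `sidecars` (yml/sh/cwl/md5 paths), `meta` and `exit_code`.
#' @export
#' @examples
#' r <- recipe("echo_out", 'echo "{{input}}" > {{outfile}}.txt',
#'             outputs = list(output_spec("txt", "*.txt")),
#'             parameters = list(param_spec("input"), param_spec("outfile")))
#' res <- evaluate(r, list(input = "Hello World", outfile = "hello"),
#'                 outdir = tempfile("curated-"), notes = c("toy", "demo"))
#' basename(res$data_files)
#' readLines(res$data_files)
evaluate <- function(recipe, bindings = list(), outdir,
                     notes = character(), runner = runner_spec()) {
  stopifnot(inherits(recipe, "recipe"))
  if (any(!nzchar(notes))) {
    rk_abort("notes must not contain empty strings", "recipekit_validation_error")
  }
  values <- resolve_bindings(recipe, bindings)
  script <- render_script(recipe, bindings)
  prefix <- evaluation_prefix(recipe, values)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outdir <- normalizePath(outdir)
  yml_path <- file.path(outdir, paste0(prefix, ".yml"))
  if (file.exists(yml_path)) {
    prev <- tryCatch(yaml::read_yaml(yml_path), error = function(e) NULL)
    prev_params <- canonical_params_json(prev$params %||% list())
    if (!identical(prev_params, canonical_params_json(values))) {
      rk_abort(sprintf(
        "evaluation prefix '%s' already exists in %s with different parameters",
        prefix, outdir),
        "recipekit_collision_error")
    }
  }

  scratch <- tempfile("recipekit-eval-")
  workdir <- file.path(scratch, "work")
  dir.create(workdir, recursive = TRUE)
  on.exit(unlink(scratch, recursive = TRUE), add = TRUE)
  script_path <- file.path(scratch, "cmd.sh")
  cat(script, file = script_path)
  stderr_path <- file.path(scratch, "stderr.log")

  status <- run_script(runner, script_path, workdir, stderr_path)
  if (!identical(as.integer(status), 0L)) {
    errlog <- if (file.exists(stderr_path))
      paste(readLines(stderr_path, warn = FALSE), collapse = "\n") else ""
    rk_abort(sprintf("recipe '%s' script exited with status %s\n%s",
                     recipe$name, status, errlog),
             "recipekit_evaluation_error",
             exit_code = as.integer(status), stderr = errlog)
  }

  rows <- collect_outputs(workdir, recipe$outputs)
  for (o in recipe$outputs) {
    if (o$role == "primary" && !any(rows$name == o$name)) {
      rk_abort(sprintf("recipe '%s': primary output glob '%s' matched no files",
                       recipe$name, o$glob),
               "recipekit_output_error", glob = o$glob)
    }
  }
  # a file matched by several globs is reported per spec but promoted once
  data_files <- file.path(outdir, unique(basename(rows$path)))
  for (src in unique(rows$path)) {
    file.copy(src, file.path(outdir, basename(src)), overwrite = TRUE)
  }

  sh_path <- file.path(outdir, paste0(prefix, ".sh"))
  cwl_path <- file.path(outdir, paste0(prefix, ".cwl"))
  md5_path <- file.path(outdir, paste0(prefix, ".md5"))
  cat(script, file = sh_path)  # exact rendered script, byte-for-byte
  write_cwl(to_cwl(recipe, script = script, script_name = paste0(prefix, ".sh")),
            cwl_path)
  write_md5_manifest(data_files, md5_path, relative_to = outdir)
  meta <- sidecar_meta(recipe, values, notes, rows[!duplicated(basename(rows$path)), ,
                                                   drop = FALSE],
                       outdir, prefix)
  write_yaml_stable(meta, yml_path)

  structure(
    list(outdir = outdir, prefix = prefix, data_files = data_files,
         sidecars = c(yml = yml_path, sh = sh_path, cwl = cwl_path,
                      md5 = md5_path),
         meta = meta, exit_code = 0L),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s\n", x$prefix))
  cat(sprintf("  outdir: %s\n", x$outdir))
  cat(sprintf("  data files: %s\n", paste(basename(x$data_files), collapse = ", ")))
  invisible(x)
}

#' Verify the integrity of a curated data record
#'
#' Recomputes the MD5 of every file listed in the record's sidecar and
#' compares it with the recorded digest. Missing files are reported as
#' failures with reason `"missing"`, not raised as errors.
#'
#' @param record A `data_record` (from [data_update()] or [fetch_remote()]),
#'   or an `evaluation_result`.
#' @return Data frame with columns `path`, `pass`, `reason` (`"ok"`,
#'   `"checksum-mismatch"` or `"missing"`), one row per recorded file.
#' @export
verify <- function(record) {
  if (inherits(record, "evaluation_result")) {
    base <- record$outdir
    outs <- record$meta$outputs
  } else if (inherits(record, "data_record")) {
    base <- dirname(record$yml_path)
    outs <- record$meta$outputs
  } else {
    rk_abort("verify() expects a data_record or evaluation_result",
             "recipekit_validation_error")
  }
  rows <- lapply(outs, function(o) {
    f <- file.path(base, o$path)
    if (!file.exists(f)) {
      return(data.frame(path = o$path, pass = FALSE, reason = "missing",
                        stringsAsFactors = FALSE))
    }
    ok <- identical(compute_md5(f), o$md5)
    data.frame(path = o$path, pass = ok,
               reason = if (ok) "ok" else "checksum-mismatch",
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(path = character(), pass = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
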