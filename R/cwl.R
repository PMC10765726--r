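# Compile recipes to CWL v1.2 CommandLineTool documents.
#
# The recipe's (possibly rendered) shell script is embedded through an
# InitialWorkDirRequirement file entry and executed with `sh -e`; recipe
# parameters are declared as typed CWL inputs but are substituted into the
# script at render time rather than bound to the command line, preserving
# the "one shell script drives multiple tools" model. Software requirements
# become hints, not hard requirements, because environment provisioning is
# owned by the evaluation runner.

CWL_TYPE_MAP <- c(string = "string", int = "int", float = "float",
                  boolean = "boolean", file = "File")

#' Compile a recipe to a CWL v1.2 CommandLineTool document
#'
#' Parameter types map string/int/float/boolean/file to the corresponding CWL
#' types (file becomes `File`). Each output pattern becomes a CWL output with
#' an `outputBinding.glob`; globs containing wildcard characters are typed
#' `File[]`, literal names `File`.
#'
#' @param recipe A [recipe()].
#' @param script Script text to embed; defaults to the recipe's template.
#'   [evaluate()] passes the rendered script so the `.cwl` sidecar is an
#'   executable record of the evaluation.
#' @param script_name File name for the embedded script entry.
#' @return A `cwl_document` (named list mirroring the YAML structure).
#' @export
#' @examples
#' r <- recipe("echo_out", 'echo "{{input}}" > {{outfile}}.txt',
#'             outputs = list(output_spec("txt", "*.txt")),
#'             parameters = list(param_spec("input"), param_spec("outfile")))
#' doc <- to_cwl(r)
#' doc$cwlVersion
to_cwl <- function(recipe, script = recipe$script, script_name = "script.sh") {
  stopifnot(inherits(recipe, "recipe"))
  inputs <- structure(list(), names = character(0))
  for (p in recipe$parameters) {
    inputs[[p$name]] <- unname(CWL_TYPE_MAP[[p$type]])
  }
  outputs <- list()
  for (o in recipe$outputs) {
    is_pattern <- grepl("[*?\\[]", o$glob)
    outputs[[o$name]] <- list(
      type = if (is_pattern) "File[]" else "File",
      outputBinding = list(glob = o$glob)
    )
  }
  doc <- list(
    cwlVersion = "v1.2",
    class = "CommandLineTool",
    doc = recipe$description,
    requirements = list(
      InitialWorkDirRequirement = list(
        listing = list(
          list(entryname = script_name, entry = script)
        )
      )
    )
  )
  hints <- cwl_hints(recipe$requirements)
  if (length(hints)) doc$hints <- hints
  doc$inputs <- inputs
  doc$outputs <- outputs
  doc$baseCommand <- list("sh", "-e", script_name)
  structure(doc, class = "cwl_document")
}

# Software requirements -> CWL hints. Container images become a
# DockerRequirement hint (first container wins; CWL allows only one);
# everything else is listed under a SoftwareRequirement hint.
cwl_hints <- function(requirements) {
  hints <- list()
  pkgs <- list()
  for (q in requirements) {
    if (q$source == "container-uri" && is.null(hints$DockerRequirement)) {
      hints$DockerRequirement <- list(dockerPull = q$spec)
      next
    }
    entry <- list(package = q$tool)
    if (!identical(q$version, "unversioned")) entry$version <- q$version
    if (nzchar(q$spec)) entry$specs <- q$spec
    pkgs[[length(pkgs) + 1L]] <- entry
  }
  if (length(pkgs)) hints$SoftwareRequirement <- list(packages = pkgs)
  hints
}

#' Write a CWL document to disk
#'
#' Emission is deterministic: key order is fixed (cwlVersion, class, doc,
#' requirements, hints, inputs, outputs, baseCommand) and repeated writes of
#' the same document are byte-identical.
#'
#' @param doc A `cwl_document` from [to_cwl()] or [read_cwl()].
#' @param path Destination path (conventionally `<prefix>.cwl`).
#' @return `path`, invisibly.
#' @export
write_cwl <- function(doc, path) {
  stopifnot(inherits(doc, "cwl_document") || is.list(doc))
  x <- unclass(doc)
  # empty inputs must serialize as an empty mapping, not an empty sequence
  if (!is.null(x$inputs) && length(x$inputs) == 0L) {
    x$inputs <- structure(list(), names = character(0))
  }
  write_yaml_stable(x, path)
  invisible(path)
}

#' Read a CWL document from disk
#'
#' @param path Path to a `.cwl` YAML file.
#' @return A `cwl_document`.
#' @export
read_cwl <- function(path) {
  if (!file.exists(path)) {
    rk_abort(sprintf("CWL file not found: %s", path), "recipekit_io_error")
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    rk_abort(sprintf("malformed CWL file %s: %s", path, conditionMessage(e)),
             "recipekit_parse_error")
  })
  structure(doc, class = "cwl_document")
}
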