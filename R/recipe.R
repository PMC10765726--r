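# Data recipes: parameterized, shell-script-backed procedures for curating
# data files. A recipe couples a script template with typed parameters,
# output glob patterns and software requirements; it is the unit that gets
# compiled to CWL, evaluated, indexed and shared.

PARAM_TYPES <- c("string", "int", "float", "boolean", "file")
OUTPUT_ROLES <- c("primary", "secondary")
REQ_SOURCES <- c("system", "conda-spec", "container-uri")

#' Declare a recipe parameter
#'
#' @param name Parameter identifier; must match `[A-Za-z_][A-Za-z0-9_]*` and
#'   corresponds to a `{{name}}` placeholder in the recipe script.
#' @param type One of `"string"`, `"int"`, `"float"`, `"boolean"`, `"file"`.
#' @param required Is a binding mandatory? Optional parameters must declare a
#'   `default`.
#' @param default Default value, conforming to `type`.
#' @param description Free-text description.
#' @return A `param_spec` object.
#' @export
#' @examples
#' param_spec("species", "string", description = "Genome species")
#' param_spec("threads", "int", required = FALSE, default = 4L)
param_spec <- function(name, type = "string", required = TRUE, default = NULL,
                       description = "") {
  type <- match.arg(type, PARAM_TYPES)
  if (!is_identifier(name)) {
    rk_abort(sprintf("parameter name '%s' is not a valid identifier", name),
             "recipekit_validation_error")
  }
  if (!isTRUE(required) && is.null(default)) {
    rk_abort(sprintf("optional parameter '%s' must declare a default", name),
             "recipekit_validation_error")
  }
  if (!is.null(default)) {
    co <- coerce_value(default, type)
    if (!co$ok) {
      rk_abort(sprintf("default for parameter '%s' does not conform to type %s",
                       name, type),
               "recipekit_validation_error")
    }
    default <- co$value
  }
  structure(
    list(name = name, type = type, required = isTRUE(required),
         default = default, description = description),
    class = "param_spec"
  )
}

#' Declare a recipe output pattern
#'
#' Output files are collected from the evaluation scratch directory by glob.
#' The `primary` role marks the main curated file(s); `secondary` marks
#' auxiliary files that travel with them (e.g. index files for a genome).
#'
#' @param name Output identifier.
#' @param glob Glob pattern, relative to the evaluation directory.
#' @param role `"primary"` or `"secondary"`.
#' @return An `output_spec` object.
#' @export
output_spec <- function(name, glob, role = "primary") {
  role <- match.arg(role, OUTPUT_ROLES)
  if (!is_identifier(name)) {
    rk_abort(sprintf("output name '%s' is not a valid identifier", name),
             "recipekit_validation_error")
  }
  if (!is.character(glob) || length(glob) != 1L || !nzchar(glob)) {
    rk_abort(sprintf("output '%s': glob must be a non-empty string", name),
             "recipekit_validation_error")
  }
  if (startsWith(glob, "/") || grepl("^[A-Za-z]:[/\\\\]", glob) ||
      grepl("(^|/)\\.\\.(/|$)", glob)) {
    rk_abort(sprintf("output '%s': glob must be relative (got '%s')", name, glob),
             "recipekit_validation_error")
  }
  structure(list(name = name, glob = glob, role = role), class = "output_spec")
}

#' Declare a software requirement of a recipe
#'
#' @param tool Tool name (non-empty).
#' @param version Version string, or `"unversioned"`.
#' @param source Where the tool comes from: `"system"` (assumed on PATH),
#'   `"conda-spec"` or `"container-uri"`.
#' @param spec Locator for non-system sources (conda package spec or image
#'   reference).
#' @return A `software_requirement` object.
#' @export
software_requirement <- function(tool, version = "unversioned",
                                 source = "system", spec = "") {
  source <- match.arg(source, REQ_SOURCES)
  if (!is.character(tool) || length(tool) != 1L || !nzchar(tool)) {
    rk_abort("software requirement: tool must be non-empty",
             "recipekit_validation_error")
  }
  if (source != "system" && !nzchar(spec)) {
    rk_abort(sprintf("software requirement '%s': source '%s' needs a non-empty spec",
                     tool, source),
             "recipekit_validation_error")
  }
  structure(list(tool = tool, version = version, source = source, spec = spec),
            class = "software_requirement")
}

# Placeholders are {{name}}; chosen over $var so recipe scripts can use
# ordinary shell variables without clashing with template substitution.
extract_placeholders <- function(script) {
  m <- gregexpr("\\{\\{([A-Za-z_][A-Za-z0-9_]*)\\}\\}", script)
  toks <- regmatches(script, m)[[1]]
  unique(gsub("^\\{\\{|\\}\\}$", "", toks))
}

#' Create a data recipe
#'
#' A recipe wraps a (possibly multi-tool) shell script as a reproducible,
#' parameterized data-curation procedure. Placeholders of the form
#' `{{name}}` in `script` must each name a declared parameter, and every
#' declared parameter must be used at least once.
#'
#' @param name Recipe identifier.
#' @param script Shell script text with `{{param}}` placeholders.
#' @param outputs List of [output_spec()] (at least one with role
#'   `"primary"`).
#' @param parameters List of [param_spec()].
#' @param requirements List of [software_requirement()].
#' @param version Version string (numeric dotted form, e.g. `"1.0.0"`).
#' @param description Free-text description (searchable).
#' @param origin Optional URL of the upstream data source.
#' @param executable_offline Set to `FALSE` for recipes whose scripts need
#'   network access or tools that may be absent; such recipes are still
#'   validated, rendered and compiled to CWL, but runners may refuse them.
#' @return A validated `recipe` object.
#' @export
#' @examples
#' r <- recipe(
#'   name = "echo_out",
#'   script = 'echo "{{input}}" > {{outfile}}.txt',
#'   parameters = list(param_spec("input"), param_spec("outfile")),
#'   outputs = list(output_spec("txt", "*.txt")),
#'   description = "Print a character string and output as a txt file"
#' )
#' recipe_names(r)
recipe <- function(name, script, outputs, parameters = list(),
                   requirements = list(), version = "0.1.0",
                   description = "", origin = NULL,
                   executable_offline = TRUE) {
  if (!is_identifier(name)) {
    rk_abort(sprintf("recipe name '%s' is not a valid identifier", name),
             "recipekit_validation_error")
  }
  if (!is.character(script) || length(script) != 1L || !nzchar(trimws(script))) {
    rk_abort("recipe script must be non-empty text", "recipekit_validation_error")
  }
  if (!grepl("^[0-9]+(\\.[0-9]+)*([.-][A-Za-z0-9]+)*$", version)) {
    rk_abort(sprintf("recipe '%s': version '%s' is not a dotted version string",
                     name, version),
             "recipekit_validation_error")
  }
  parameters <- lapply(parameters, as_param_spec)
  outputs <- lapply(outputs, as_output_spec)
  requirements <- lapply(requirements, as_software_requirement)

  pnames <- vapply(parameters, `[[`, "", "name")
  if (anyDuplicated(pnames)) {
    rk_abort(sprintf("recipe '%s': duplicate parameter names: %s", name,
                     paste(unique(pnames[duplicated(pnames)]), collapse = ", ")),
             "recipekit_validation_error")
  }
  problems <- character()
  ph <- extract_placeholders(script)
  undeclared <- setdiff(ph, pnames)
  unused <- setdiff(pnames, ph)
  if (length(undeclared)) {
    problems <- c(problems, sprintf("undeclared placeholder(s): %s",
                                    paste(undeclared, collapse = ", ")))
  }
  if (length(unused)) {
    problems <- c(problems, sprintf("unused parameter(s): %s",
                                    paste(unused, collapse = ", ")))
  }
  if (!length(outputs)) {
    problems <- c(problems, "at least one output_spec is required")
  } else if (!any(vapply(outputs, `[[`, "", "role") == "primary")) {
    problems <- c(problems, "at least one output must have role 'primary'")
  }
  if (length(problems)) {
    rk_abort(sprintf("invalid recipe '%s': %s", name,
                     paste(problems, collapse = "; ")),
             "recipekit_validation_error")
  }
  structure(
    list(name = name, version = version, description = description,
         origin = origin, script = script, parameters = parameters,
         outputs = outputs, requirements = requirements,
         executable_offline = isTRUE(executable_offline)),
    class = "recipe"
  )
}

as_param_spec <- function(x) {
  if (inherits(x, "param_spec")) return(x)
  if (!is.list(x) || is.null(x$name)) {
    rk_abort("parameters must be param_spec objects or equivalent lists",
             "recipekit_validation_error")
  }
  param_spec(x$name, x$type %||% "string", x$required %||% TRUE,
             x$default, x$description %||% "")
}

as_output_spec <- function(x) {
  if (inherits(x, "output_spec")) return(x)
  if (!is.list(x) || is.null(x$name) || is.null(x$glob)) {
    rk_abort("outputs must be output_spec objects or equivalent lists",
             "recipekit_validation_error")
  }
  output_spec(x$name, x$glob, x$role %||% "primary")
}

as_software_requirement <- function(x) {
  if (inherits(x, "software_requirement")) return(x)
  if (!is.list(x) || is.null(x$tool)) {
    rk_abort("requirements must be software_requirement objects or equivalent lists",
             "recipekit_validation_error")
  }
  software_requirement(x$tool, x$version %||% "unversioned",
                       x$source %||% "system", x$spec %||% "")
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("<recipe> %s (v%s)\n", x$name, x$version))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  cat(sprintf("  parameters: %s\n",
              if (length(x$parameters))
                paste(vapply(x$parameters, function(p)
                  sprintf("%s:%s", p$name, p$type), ""), collapse = ", ")
              else "(none)"))
  cat(sprintf("  outputs: %s\n",
              paste(vapply(x$outputs, function(o)
                sprintf("%s[%s]", o$glob, o$role), ""), collapse = ", ")))
  invisible(x)
}

#' Recipe name(s)
#'
#' Accessor returning the name of a recipe, or the (sorted) names held by a
#' recipe index.
#' @param x A `recipe` or `recipe_index`.
#' @return Character vector of names.
#' @export
recipe_names <- function(x) {
  if (inherits(x, "recipe")) return(x$name)
  if (inherits(x, "recipe_index")) return(sort_c(names(x$entries)))
  rk_abort("recipe_names() expects a recipe or recipe_index",
           "recipekit_validation_error")
}

## ---- bindings -------------------------------------------------------------

#' Coerce a bound value to a parameter type
#'
#' Bindings often arrive as text (CLI flags, job documents), so numeral text
#' is accepted for int/float and "true"/"false" for boolean.
#' @return list(ok = flag, value = coerced value)
#' @noRd
coerce_value <- function(value, type) {
  fail <- list(ok = FALSE, value = NULL)
  if (is.null(value) || length(value) != 1L || is.list(value)) return(fail)
  switch(type,
    string = ,
    file = {
      if (!is.character(value) && !is.numeric(value)) return(fail)
      list(ok = TRUE, value = as.character(value))
    },
    int = {
      if (is.numeric(value) && !is.na(value) && value == trunc(value)) {
        return(list(ok = TRUE, value = as.integer(value)))
      }
      if (is.character(value) && grepl("^[+-]?[0-9]+$", value)) {
        return(list(ok = TRUE, value = as.integer(value)))
      }
      fail
    },
    float = {
      if (is.numeric(value) && !is.na(value)) {
        return(list(ok = TRUE, value = as.numeric(value)))
      }
      if (is.character(value)) {
        v <- suppressWarnings(as.numeric(value))
        if (!is.na(v)) return(list(ok = TRUE, value = v))
      }
      fail
    },
    boolean = {
      if (is.logical(value) && !is.na(value)) {
        return(list(ok = TRUE, value = value))
      }
      if (is.character(value) && tolower(value) %in% c("true", "false")) {
        return(list(ok = TRUE, value = tolower(value) == "true"))
      }
      fail
    }
  )
}

#' Validate parameter bindings against a recipe
#'
#' @param recipe A [recipe()].
#' @param bindings Named list (or vector) mapping parameter names to values.
#' @return Character vector of violations, empty when the bindings are valid.
#'   Each violation is `"missing:<name>"`, `"undeclared:<name>"` or
#'   `"type:<name>:<type>"`.
#' @export
validate_bindings <- function(recipe, bindings) {
  stopifnot(inherits(recipe, "recipe"))
  bindings <- as.list(bindings)
  if (length(bindings) && (is.null(names(bindings)) || any(!nzchar(names(bindings))))) {
    return("unnamed:bindings must be a named list")
  }
  pnames <- vapply(recipe$parameters, `[[`, "", "name")
  violations <- character()
  for (p in recipe$parameters) {
    if (!p$name %in% names(bindings)) {
      if (p$required) violations <- c(violations, paste0("missing:", p$name))
      next
    }
    if (!coerce_value(bindings[[p$name]], p$type)$ok) {
      violations <- c(violations, sprintf("type:%s:%s", p$name, p$type))
    }
  }
  for (k in setdiff(names(bindings), pnames)) {
    violations <- c(violations, paste0("undeclared:", k))
  }
  violations
}

#' Resolve bindings: validate, apply defaults, coerce to declared types
#' @noRd
resolve_bindings <- function(recipe, bindings) {
  bindings <- as.list(bindings)
  violations <- validate_bindings(recipe, bindings)
  if (length(violations)) {
    rk_abort(sprintf("invalid bindings for recipe '%s': %s", recipe$name,
                     paste(violations, collapse = "; ")),
             "recipekit_binding_error", violations = violations)
  }
  out <- list()
  for (p in recipe$parameters) {
    v <- if (p$name %in% names(bindings)) bindings[[p$name]] else p$default
    out[[p$name]] <- coerce_value(v, p$type)$value
  }
  out
}

# Escape the characters that can break out of a double-quoted shell word
# (backslash, double quote, backtick, dollar). Values made only of ordinary
# text pass through verbatim, so templates read naturally; metacharacter-
# bearing values survive the shell intact when the template quotes the
# placeholder.
shell_escape_value <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("`", "\\`", x, fixed = TRUE)
  x <- gsub("$", "\\$", x, fixed = TRUE)
  x
}

value_to_text <- function(value, type) {
  switch(type,
    boolean = if (isTRUE(value)) "true" else "false",
    int = format(value, scientific = FALSE),
    float = format(value, scientific = FALSE, digits = 15),
    as.character(value)
  )
}

#' Render a recipe script with concrete parameter values
#'
#' Replaces every `{{param}}` placeholder with the bound value (after type
#' coercion and shell escaping) and returns the executable script text.
#' Rendering is pure: identical inputs produce identical text.
#'
#' @inheritParams validate_bindings
#' @return Rendered shell script (single string, no placeholders left).
#' @export
#' @examples
#' r <- recipe("echo_out", 'echo "{{input}}" > {{outfile}}.txt',
#'             outputs = list(output_spec("txt", "*.txt")),
#'             parameters = list(param_spec("input"), param_spec("outfile")))
#' render_script(r, list(input = "Hello World", outfile = "hello"))
render_script <- function(recipe, bindings = list()) {
  stopifnot(inherits(recipe, "recipe"))
  vals <- resolve_bindings(recipe, bindings)
  script <- recipe$script
  for (p in recipe$parameters) {
    txt <- shell_escape_value(value_to_text(vals[[p$name]], p$type))
    script <- gsub(paste0("{{", p$name, "}}"), txt, script, fixed = TRUE)
  }
  script
}

## ---- serialization ---------------------------------------------------------

recipe_to_list <- function(r) {
  out <- list(
    name = r$name,
    version = r$version,
    description = r$description,
    origin = r$origin,
    script = r$script,
    parameters = lapply(r$parameters, function(p) {
      e <- list(name = p$name, type = p$type, required = p$required)
      if (!is.null(p$default)) e$default <- p$default
      e$description <- p$description
      e
    }),
    outputs = lapply(r$outputs, function(o)
      list(name = o$name, glob = o$glob, role = o$role)),
    requirements = lapply(r$requirements, function(q)
      list(tool = q$tool, version = q$version, source = q$source, spec = q$spec))
  )
  if (!r$executable_offline) out$executable_offline <- FALSE
  if (is.null(out$origin)) out$origin <- NULL
  out[!vapply(out, is.null, TRUE)]
}

#' Write a recipe definition file
#'
#' Recipes are stored one per YAML document, conventionally named
#' `<name>.yaml`, so a directory of recipe files can be synced into a
#' [recipe_index()].
#'
#' @param recipe A [recipe()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_recipe <- function(recipe, path) {
  stopifnot(inherits(recipe, "recipe"))
  write_yaml_stable(recipe_to_list(recipe), path)
  invisible(path)
}

#' Read a recipe definition file
#'
#' Parses and fully validates a recipe YAML document; the roundtrip
#' `read_recipe(write_recipe(r))` reproduces `r` field-for-field.
#'
#' @param path Path to a recipe YAML file.
#' @return A validated `recipe`.
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) {
    rk_abort(sprintf("recipe file not found: %s", path), "recipekit_io_error")
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    rk_abort(sprintf("malformed recipe file %s: %s", path, conditionMessage(e)),
             "recipekit_parse_error")
  })
  if (!is.list(doc)) {
    rk_abort(sprintf("malformed recipe file %s: not a YAML mapping", path),
             "recipekit_parse_error")
  }
  for (field in c("name", "version", "script", "outputs")) {
    if (is.null(doc[[field]])) {
      rk_abort(sprintf("recipe file %s: missing required field '%s'", path, field),
               "recipekit_validation_error", field = field)
    }
  }
  recipe(
    name = doc$name,
    script = doc$script,
    outputs = doc$outputs,
    parameters = doc$parameters %||% list(),
    requirements = doc$requirements %||% list(),
    version = as.character(doc$version),
    description = doc$description %||% "",
    origin = doc$origin,
    executable_offline = doc$executable_offline %||% TRUE
  )
}
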