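# Shared fixtures and independent oracles for the test suite.

# Basic two-parameter echo recipe (the one offline-executable catalog entry).
toy_echo_recipe <- function() {
  recipe(
    name = "echo_out",
    script = 'echo "{{input}}" > {{outfile}}.txt\n',
    parameters = list(param_spec("input", description = "string to print"),
                      param_spec("outfile", description = "output basename")),
    outputs = list(output_spec("txt", "*.txt")),
    description = "Print a character string and output as a txt file"
  )
}

# Recipe emitting a primary file plus a secondary checksum file, exercising
# multi-output collection and secondaryFiles export.
toy_multi_recipe <- function() {
  recipe(
    name = "toy_indexed",
    script = paste0('printf "%s\\n" "{{body}}" > {{stem}}.dat\n',
                    "md5sum {{stem}}.dat > {{stem}}.dat.md5\n"),
    parameters = list(param_spec("body"), param_spec("stem")),
    outputs = list(output_spec("dat", "*.dat"),
                   output_spec("checksum", "*.dat.md5", role = "secondary")),
    requirements = list(software_requirement("md5sum")),
    description = "Write a text body and a checksum companion file"
  )
}

toy_failing_recipe <- function() {
  recipe(
    name = "toy_fail",
    script = "echo {{msg}} >&2\nexit 1\n",
    parameters = list(param_spec("msg")),
    outputs = list(output_spec("out", "*.txt")),
    description = "Always fails"
  )
}

# --- independent CWL v1.2 structural validator -------------------------------
# Written against the CWL v1.2 CommandLineTool specification, independently of
# the package's emitter: it re-reads the YAML itself and checks the schema
# rules (required fields, type names, output bindings, requirement shapes).
CWL_INPUT_TYPES <- c("string", "int", "long", "float", "double", "boolean",
                     "File", "Directory", "null")
KNOWN_CWL_REQUIREMENTS <- c(
  "InitialWorkDirRequirement", "ShellCommandRequirement", "DockerRequirement",
  "SoftwareRequirement", "EnvVarRequirement", "ResourceRequirement",
  "InlineJavascriptRequirement")

cwl_validate_file <- function(path) {
  problems <- character()
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) NULL)
  if (is.null(doc)) return("document does not parse as YAML")
  note <- function(msg) problems <<- c(problems, msg)

  if (!identical(doc$cwlVersion, "v1.2")) note("cwlVersion must be 'v1.2'")
  if (!identical(doc$class, "CommandLineTool")) {
    note("class must be 'CommandLineTool'")
  }
  id_re <- "^[A-Za-z_][A-Za-z0-9_-]*$"

  ins <- doc$inputs
  if (is.null(ins)) {
    note("inputs section is required")
  } else if (length(ins)) {
    if (is.null(names(ins)) || any(!nzchar(names(ins)))) {
      note("inputs must be a mapping of id -> type")
    } else {
      for (id in names(ins)) {
        if (!grepl(id_re, id)) note(sprintf("invalid input id '%s'", id))
        ty <- ins[[id]]
        if (is.list(ty)) ty <- ty$type
        if (!is.character(ty) ||
            !(ty %in% CWL_INPUT_TYPES ||
              ty %in% paste0(CWL_INPUT_TYPES, "[]") ||
              ty %in% paste0(CWL_INPUT_TYPES, "?"))) {
          note(sprintf("input '%s': unknown CWL type", id))
        }
      }
    }
  }

  outs <- doc$outputs
  if (is.null(outs)) {
    note("outputs section is required")
  } else {
    for (id in names(outs)) {
      if (!grepl(id_re, id)) note(sprintf("invalid output id '%s'", id))
      o <- outs[[id]]
      if (!is.list(o) || is.null(o$type)) {
        note(sprintf("output '%s': missing type", id))
        next
      }
      if (!o$type %in% c("File", "File[]", "Directory", "Directory[]")) {
        note(sprintf("output '%s': type must be File/File[]", id))
      }
      glob <- o$outputBinding$glob
      if (!is.character(glob) || !nzchar(glob)) {
        note(sprintf("output '%s': outputBinding.glob required", id))
      } else if (startsWith(glob, "/")) {
        note(sprintf("output '%s': glob must not be absolute", id))
      }
    }
  }

  if (is.null(doc$baseCommand) && is.null(doc$arguments)) {
    note("one of baseCommand/arguments is required")
  }

  reqs <- doc$requirements
  if (!is.null(reqs)) {
    req_names <- if (is.null(names(reqs)))
      vapply(reqs, function(r) r$class %||% "", "") else names(reqs)
    for (rn in req_names) {
      if (!rn %in% KNOWN_CWL_REQUIREMENTS) {
        note(sprintf("unknown requirement class '%s'", rn))
      }
    }
    iwdr <- if (is.null(names(reqs))) {
      Filter(function(r) identical(r$class, "InitialWorkDirRequirement"), reqs)
    } else reqs["InitialWorkDirRequirement"]
    for (r in iwdr) {
      if (is.null(r$listing)) {
        note("InitialWorkDirRequirement needs a listing")
        next
      }
      for (entry in r$listing) {
        if (is.null(entry$entryname) || is.null(entry$entry)) {
          note("InitialWorkDirRequirement listing entries need entryname+entry")
        }
      }
    }
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- brute-force keyword-search oracle ---------------------------------------
# Straight linear scan over records applying the documented match rule
# (case-insensitive substring, AND over keywords, haystack = recipe name +
# file basenames + notes + tags + name=value params), kept independent of
# data_search()'s implementation.
bf_data_search <- function(records, keywords) {
  match_one <- function(rec) {
    fields <- c(rec$recipe_name, basename(rec$data_paths), rec$notes, rec$tags)
    if (length(rec$params)) {
      for (nm in names(rec$params)) {
        fields <- c(fields,
                    paste0(nm, "=", paste(as.character(rec$params[[nm]]),
                                          collapse = " ")))
      }
    }
    hay <- tolower(paste(fields, collapse = " "))
    for (k in keywords) {
      if (!grepl(tolower(k), hay, fixed = TRUE)) return(FALSE)
    }
    TRUE
  }
  keep <- vapply(records, match_one, TRUE)
  out <- records[keep]
  out[order(vapply(out, `[[`, "", "yml_path"), method = "radix")]
}

record_ids <- function(records) vapply(records, `[[`, "", "id")

# Expected names and descriptions of the pre-built recipe catalog.
CATALOG_EXPECTED <- c(
  bowtie2_index = "Use \"bowtie2-build\" to index a specific reference genome",
  echo_out = "Print a character string and output as a txt file",
  ensembl_liftover = "Download and unzip genome liftover file from Ensembl",
  gcp_broad_gatk_hg19 = "Download file in GATK annotation bundle for hg19 from GCP",
  gcp_broad_gatk_hg38 = "Download file in GATK annotation bundle for hg38 from GCP",
  gcp_gatk_mutect2_b37 = "Download file in GATK mutect2 bundle for b37 from GCP",
  gcp_gatk_mutect2_hg38 = "Download file in GATK mutect2 bundle for hg38 from GCP",
  gencode_annotation = "Download and unzip annotation files from gencode",
  gencode_genome_grch38 = "Download human genome GRCh38 from GENCODE release 42",
  gencode_transcripts = "Download, unzip, and index transcripts files from gencode",
  hisat2_index = "Use \"hisat2-build\" to build the index files",
  reference_genome = "Download, format and index reference genome file with samtools, picard and bwa",
  salmon_index = "Use \"Salmon index\" command to build salmon index for your transcriptome",
  STAR_index = "Use STAR command to build genome index for STAR alignment",
  ucsc_database = "Download genome annotation file from UCSC database using the golden path"
)

# Two records expose the same searchable surface (everything data_search can
# see) when all compared fields agree; origin and date are deliberately not
# part of that surface.
record_haystacks_equal <- function(a, b) {
  identical(a$recipe_name, b$recipe_name) &&
    identical(basename(a$data_paths), basename(b$data_paths)) &&
    identical(a$notes, b$notes) &&
    identical(a$tags, b$tags) &&
    identical(lapply(a$params, as.character), lapply(b$params, as.character))
}

# Run `md5sum -c <manifest>` inside dir; returns the exit status (0 = all OK).
withr_like_md5check <- function(dir, manifest) {
  old <- setwd(dir)
  on.exit(setwd(old))
  suppressWarnings(
    as.integer(system2("md5sum", c("-c", manifest),
                       stdout = FALSE, stderr = FALSE))
  )
}

expect_rk_error <- function(expr, class) {
  expect_error(expr, class = class)
}
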