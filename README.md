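# recipekit

Reproducible, shareable curation of genomic data files through **data
recipes**, with standardized provenance sidecars and keyword-searchable
catalogs.

## The problem

Most genomics projects begin by re-deriving the same curated inputs —
reference genomes, annotation GTFs, liftover chain files, aligner indexes,
GATK bundles — from ad hoc shell scripts. Those scripts are rarely
reproducible, the resulting files carry no record of how they were made, and
every group member re-downloads and re-processes the same resources.
`recipekit` is for bioinformaticians (especially in core facilities) who
want those preprocessing scripts turned into versioned, parameterized,
portable procedures, and the resulting files indexed, verifiable and
reusable across projects and workflow systems.

## The model

A **data recipe** couples

* a shell-script *template* with `{{param}}` placeholders (one script may
  drive several tools, e.g. `wget` → `samtools faidx` → `bwa index`),
* typed **parameters** (`string | int | float | boolean | file`, with
  optional defaults),
* **output patterns** — globs that extract the files of interest from the
  run directory, each tagged `primary` or `secondary` (e.g. a genome FASTA
  and its index files), and
* **software requirements** (system tool, conda spec, or container URI).

Evaluating a recipe against parameter *bindings* renders the script, runs it
in a scratch directory, promotes only glob-matched files into the output
directory, and writes four provenance sidecars next to the data, sharing a
deterministic prefix `<recipe>_<value1>_<value2>`:

| sidecar | content |
|---|---|
| `.yml` | standardized annotations: recipe, version, parameters, ISO-8601 date, origin, per-file MD5 + size, software, user notes, mutable tags |
| `.sh`  | the exact rendered shell script |
| `.cwl` | a CWL v1.2 `CommandLineTool` wrapping the script |
| `.md5` | a GNU `md5sum`-compatible checksum manifest |

Directories of sidecar-annotated files are scanned into a persistent **data
index** (`data_update`), searched by ANDed case-insensitive keywords over
recipe name, file names, notes, tags and parameter values (`data_search`),
tagged (`set_tags`), integrity-checked against the recorded checksums
(`verify`), exported as CWL/WDL-style job-input documents
(`to_workflow_inputs`), or fetched pre-built from a remote bucket described
by a checksum manifest (`fetch_remote`). Recipe definition files are managed
symmetrically by a **recipe index** (`recipe_update` / `recipe_search` /
`recipe_load`). A catalog of 15 pre-built recipes ships with the package
(`shipped_catalog_dir()`); `echo_out` is runnable anywhere, the network-bound
ones are templates carrying their upstream origins.

## Worked example

```r
library(recipekit)

idx <- recipe_update(recipe_index(tempfile()), shipped_catalog_dir())
recipe_search(idx, "gencode")           # 3 recipes
r <- recipe_load(idx, "echo_out")

res <- evaluate(r, list(input = "Hello World", outfile = "hello"),
                outdir = "curated", notes = c("toy", "demo"))
print(res)
#> <evaluation_result> echo_out_Hello-World_hello
#>   outdir: /tmp/clidemo/curated
#>   data files: hello.txt
readLines(res$data_files)
#> [1] "Hello World"
list.files("curated")
#> [1] "echo_out_Hello-World_hello.cwl" "echo_out_Hello-World_hello.md5"
#> [3] "echo_out_Hello-World_hello.sh"  "echo_out_Hello-World_hello.yml"
#> [5] "hello.txt"

didx <- data_update(data_index(tempfile()), "curated")
rec <- data_search(didx, c("demo"))[[1]]
data_params(rec)
#> $input
#> [1] "Hello World"
#> $outfile
#> [1] "hello"
verify(rec)
#>        path pass reason
#> 1 hello.txt TRUE     ok

didx <- set_tags(didx, rec$id, "mytool")
doc <- to_workflow_inputs(list(rec), setNames("hello", rec$id), format = "json")
cat(format_workflow_inputs(doc))
#> {
#>   "hello": {
#>     "class": "File",
#>     "path": "/tmp/clidemo/curated/hello.txt"
#>   }
#> }
```

A thin command-line front end covering the same operations ships at
`system.file("cli", "recipekit", package = "recipekit")` (subcommands `run`,
`recipe sync|search`, `data update|search|tag`, `verify`, `export`, `fetch`,
`fixtures init`).

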