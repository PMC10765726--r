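---
title: "Data recipes, provenance sidecars, and curated-data management with recipekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data recipes, provenance sidecars, and curated-data management with recipekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recipekit)
```

## The procedure

`recipekit` treats the curation of a genomic data resource — downloading,
reformatting, indexing — as the evaluation of a *data recipe*: a shell-script
template with typed parameters, output-extraction globs, and declared
software requirements. The design assumption, common to real preprocessing
practice, is that one script may drive several tools in sequence, so the
script (not the individual tool invocation) is the unit of reproducibility.
Evaluation proceeds in five steps:

1. **Bind**: parameter bindings are validated against the declaration
   (missing, undeclared, type-mismatched values are each reported by name)
   and defaults fill optional parameters.
2. **Render**: every `{{param}}` placeholder is replaced by the bound value;
   rendering is a pure function of (recipe, bindings).
3. **Run**: the rendered script executes with `sh -e` in a throwaway scratch
   directory.
4. **Extract**: only files matching the recipe's output globs are promoted
   into the destination; script litter stays behind. A primary glob matching
   nothing aborts the evaluation.
5. **Annotate**: four sidecars are written next to the data, `.yml`
   (machine-readable provenance), `.sh` (the exact rendered script), `.cwl`
   (a CWL v1.2 `CommandLineTool` wrapper) and `.md5` (a `md5sum`-compatible
   manifest). The `.yml` is written last, so a failed evaluation can never
   leave a half-curated record that an index would pick up.

Everything downstream — indexing, search, tagging, verification, export,
remote fetch — operates on the `.yml` sidecars, which travel with the data
and remain the authoritative record.

## Tunable parameters

* `param_spec(type=)` — one of `string`, `int`, `float`, `boolean`, `file`;
  untyped use cases default to `string`. Optional parameters must carry a
  default of the declared type.
* `output_spec(role=)` — `primary` (the curated file of interest; at least
  one per recipe; must match at run time) or `secondary` (companions such as
  `.fai`/`.dict`/BWA index files that must travel with the primary).
* `evaluate(notes=)` — free-text keywords frozen into the sidecar at
  evaluation time; the complementary `set_tags()` labels are mutable
  afterwards. Both are searchable.
* `runner_spec(mode=)` — `direct-shell` (default, `sh -e`) is the only
  in-process runner; `conda-wrapped` and `cwl-engine` are injection points
  that accept an `options$exec` hook honouring the same contract. Environment
  provisioning (conda/Docker) is deliberately outside the package: it is
  platform plumbing, not part of the recipe semantics, and cannot be
  exercised offline.
* `data_search()/recipe_search()` keywords — case-insensitive substring
  match, ANDed. AND was chosen because narrowing is the common retrieval
  need; OR can be had by unioning searches.

## Design choices

**Placeholder syntax.** `{{name}}` rather than shell `$name`, so recipe
scripts can use ordinary shell variables without colliding with template
substitution, and so an unsubstituted placeholder is a loud, greppable
artifact.

**Shell escaping.** Bound values are substituted after backslash-escaping
the four characters that can break out of a double-quoted shell word
(`\`, `"`, `` ` ``, `$`). Ordinary values (`Hello World`, `GRCh38`) pass
through verbatim, so rendered scripts read exactly like the hand-written
originals; adversarial values (embedded quotes, `$VAR`, command
substitution) survive the shell intact when the template quotes the
placeholder, which the test suite checks by round-tripping rendered commands
through `sh` and comparing the captured output to the raw value. The known
limitation: a placeholder used *unquoted* in a template is only safe for
whitespace-free values — recipes should quote placeholders that may receive
arbitrary text. Wrapping every value in single quotes would have been
context-independent but makes the common rendered script diverge from the
script a practitioner would write, and mangles templates that already quote
their placeholders.

**Type coercion.** Bindings usually arrive as text (command-line flags, job
documents), so numeral text is accepted for `int`/`float` and
`"true"`/`"false"` for `boolean`; anything else is a named type violation,
not a silent cast.

**Sidecar naming.** The shared prefix is the recipe name plus the sanitized
bound values in declaration order (`echo_out_Hello-World_hello`):
deterministic, human-readable, and collision-avoidant across parameter sets.
If the prefix already exists in the destination with *different* recorded
parameters, evaluation refuses with a collision error; identical parameters
overwrite (a re-run of the same curation).

**Checksums.** MD5, matching the `.md5` manifest convention and the GNU
`md5sum -c` toolchain the manifests interoperate with; the integrity model
is corruption/drift detection, not cryptographic authentication.
Timestamps are ISO-8601 UTC at seconds precision.

**CWL mapping.** The recipe script is embedded via an
`InitialWorkDirRequirement` file entry and executed with `sh -e`; parameters
are declared as typed CWL inputs but are substituted into the script at
render time rather than bound to the command line. This preserves the
"one script drives multiple tools" model — per-argument `inputBinding`s
would force the script apart into single-tool calls. Software requirements
are emitted as *hints* (`SoftwareRequirement` packages, the first container
image as `DockerRequirement`), not hard requirements, because the evaluator
owns environment provisioning. Output globs with wildcard characters map to
`File[]`, literal names to `File`. Key order is fixed, so emission is
byte-deterministic and write→read→write is byte-identical.

**Index persistence.** Each index is a single JSON file in its cache
directory holding source/sidecar paths; records are re-parsed from disk on
load. This makes reload equivalence trivial by construction and keeps the
sidecars authoritative — a tag edited into a sidecar (or a sidecar shared
via a group folder) is never shadowed by stale index state. The trade-off,
accepted deliberately, is last-write-wins semantics with no multi-writer
locking.

**Remote buckets.** A bucket is "a manifest plus objects": the manifest is a
TSV (`recipe, params_json, path, md5, size`) with parameters serialized as
canonical sorted-key JSON so (recipe, params) lookup is exact string
equality. Transport is an injected `function(location) -> local path`; tests
and fixtures use local directories. A fetched file is checksum-verified
before a synthetic sidecar is written (`origin` = bucket location, `date` =
fetch time); on mismatch the file is quarantined with a `.corrupt` suffix so
a partial download can never masquerade as curated data. Compatibility with
any particular public bucket layout is not claimed.

**Search over parameter values** (`data_search` matches stringified
`name=value` pairs) is an extension beyond name/notes/tags matching: the
parameter values (species, assembly, release) are precisely what
distinguishes otherwise identical curations, so they belong in the
searchable surface.

## The fixture generators

The package must be fully exercisable offline, so `fixtures` are first-class
code, not stored data:

* `make_catalog()` writes the 15 pre-built recipe definitions. Only
  `echo_out` is executable offline; the network-bound recipes
  (GENCODE/Ensembl/UCSC downloads, GCP GATK bundles, aligner indexing) are
  schema-validated and CWL-rendered in tests but never run — they carry
  `executable_offline: false` and their real upstream origins.
* `make_toy_data_tree()` evaluates `echo_out` with seed-determined bindings
  and notes into a nested tree, emulating a shared curated-data folder
  (varying depth, varied notes/params vocabulary).
* `make_mock_bucket()` writes objects byte-identical to what the
  corresponding `echo_out` evaluation produces, plus a true-checksum
  manifest, so fetch-vs-local-evaluation equivalence is testable.

Generation is deterministic for a fixed seed (timestamps aside). What the
fixtures do **not** emulate: large files, binary formats, real network
latency/failure modes, concurrent writers, or the content of real reference
resources — passing tests demonstrate the management mechanics (templating,
extraction, provenance, indexing, integrity), not the correctness of any
particular genomic resource.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberately desk-scale
sizes: 15-recipe catalog, 20–22-record data trees, 100 random keyword sets
checked against a brute-force linear-scan oracle, byte flips at first/middle/
last positions per curated file, 2–3-object buckets. All pipeline logic is
deterministic; seeded pseudo-randomness is used only for fixture variety and
for choosing oracle probes. File ordering everywhere uses C-locale radix
sort so results do not depend on the session locale. Integer-valued
parameters render without scientific notation; floats render at full
precision.

## Known limitations

* `direct-shell` requires a POSIX `sh`; Windows is out of scope.
* No recipe DAGs: a recipe is a single (multi-tool) script by design;
  multi-recipe orchestration belongs to workflow engines consuming the
  exported job-input documents.
* The CWL documents are validated structurally in the test suite; engines
  with stricter schema-salad validation are the definitive arbiters, and the
  emitted documents keep to the plain CommandLineTool subset to stay inside
  what such validators accept.
* Index access is single-writer; concurrent `data_update` calls on one cache
  resolve last-write-wins.
* The on-disk recipe YAML schema is this package's own; no compatibility
  with other recipe systems' formats is claimed.
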