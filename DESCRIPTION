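Package: recipekit
Title: Reproducible Data Recipes with Provenance Sidecars for Genomic Data Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Author parameterized, shell-script-backed "data recipes" for
    curating genomic data files, compile them to Common Workflow Language
    (CWL v1.2) CommandLineTool documents, and evaluate them reproducibly to
    emit curated data together with standardized provenance sidecars
    (.yml annotations, .sh rendered script, .cwl wrapper, .md5 checksum
    manifest). Curated files and recipes are indexed into persistent,
    keyword-searchable catalogs; records can be tagged, integrity-verified
    against their checksum manifests, exported as CWL/WDL-style workflow
    job-input documents, and fetched from a remote bucket described by a
    checksum manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
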