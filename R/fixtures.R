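# Offline test assets: the pre-built recipe catalog as definition files,
# executable toy evaluations forming a curated-data tree, and a mock remote
# bucket with a checksum manifest. Everything is generated in code, uses
# only POSIX shell built-ins, and is byte-reproducible for a fixed seed
# (timestamps aside), so the whole package is exercisable with no network.

catalog_definitions <- function() {
  p <- param_spec
  o <- output_spec
  sr <- software_requirement
  list(
    recipe(
      name = "bowtie2_index",
      description = "Use \"bowtie2-build\" to index a specific reference genome",
      script = "bowtie2-build --threads {{threads}} {{fasta}} {{basename}}\n",
      parameters = list(
        p("fasta", "file", description = "Reference genome FASTA"),
        p("basename", "string", description = "Index basename"),
        p("threads", "int", required = FALSE, default = 4L)
      ),
      outputs = list(o("index_files", "*.bt2")),
      requirements = list(sr("bowtie2", "2.5.1", "conda-spec", "bowtie2=2.5.1")),
      executable_offline = FALSE
    ),
    recipe(
      name = "echo_out",
      description = "Print a character string and output as a txt file",
      script = "echo \"{{input}}\" > {{outfile}}.txt\n",
      parameters = list(
        p("input", "string", description = "Character string to print"),
        p("outfile", "string", description = "Output file basename")
      ),
      outputs = list(o("txt", "*.txt"))
    ),
    recipe(
      name = "ensembl_liftover",
      description = "Download and unzip genome liftover file from Ensembl",
      script = paste0(
        "wget https://ftp.ensembl.org/pub/assembly_mapping/{{species}}/",
        "{{from}}_to_{{to}}.chain.gz\n",
        "gunzip {{from}}_to_{{to}}.chain.gz\n"),
      parameters = list(
        p("species", "string", description = "Species directory name"),
        p("from", "string", description = "Source assembly"),
        p("to", "string", description = "Target assembly")
      ),
      outputs = list(o("chain", "*.chain")),
      requirements = list(sr("wget")),
      origin = "https://ftp.ensembl.org/pub/assembly_mapping/",
      executable_offline = FALSE
    ),
    gcp_bundle_recipe("gcp_broad_gatk_hg19",
      "Download file in GATK annotation bundle for hg19 from GCP",
      "gs://gcp-public-data--broad-references/hg19/v0"),
    gcp_bundle_recipe("gcp_broad_gatk_hg38",
      "Download file in GATK annotation bundle for hg38 from GCP",
      "gs://gcp-public-data--broad-references/hg38/v0"),
    gcp_bundle_recipe("gcp_gatk_mutect2_b37",
      "Download file in GATK mutect2 bundle for b37 from GCP",
      "gs://gatk-best-practices/somatic-b37"),
    gcp_bundle_recipe("gcp_gatk_mutect2_hg38",
      "Download file in GATK mutect2 bundle for hg38 from GCP",
      "gs://gatk-best-practices/somatic-hg38"),
    recipe(
      name = "gencode_annotation",
      description = "Download and unzip annotation files from gencode",
      script = paste0(
        "wget https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_{{species}}/",
        "release_{{version}}/gencode.v{{version}}.annotation.gtf.gz\n",
        "gunzip gencode.v{{version}}.annotation.gtf.gz\n"),
      parameters = list(
        p("species", "string", description = "human or mouse"),
        p("version", "string", description = "GENCODE release, e.g. 42")
      ),
      outputs = list(o("gtf", "*.gtf")),
      requirements = list(sr("wget")),
      origin = "https://ftp.ebi.ac.uk/pub/databases/gencode/",
      executable_offline = FALSE
    ),
    recipe(
      name = "gencode_genome_grch38",
      description = "Download human genome GRCh38 from GENCODE release 42",
      script = paste0(
        "wget https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_human/",
        "release_42/GRCh38.primary_assembly.genome.fa.gz\n",
        "gunzip GRCh38.primary_assembly.genome.fa.gz\n"),
      parameters = list(),
      outputs = list(o("genome", "*.fa")),
      requirements = list(sr("wget")),
      origin = paste0("https://ftp.ebi.ac.uk/pub/databases/gencode/",
                      "Gencode_human/release_42/"),
      executable_offline = FALSE
    ),
    recipe(
      name = "gencode_transcripts",
      description = "Download, unzip, and index transcripts files from gencode",
      script = paste0(
        "wget https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_{{species}}/",
        "release_{{version}}/gencode.v{{version}}.transcripts.fa.gz\n",
        "gunzip gencode.v{{version}}.transcripts.fa.gz\n",
        "samtools faidx gencode.v{{version}}.transcripts.fa\n"),
      parameters = list(
        p("species", "string", description = "human or mouse"),
        p("version", "string", description = "GENCODE release")
      ),
      outputs = list(o("fasta", "*.fa"), o("index", "*.fai", role = "secondary")),
      requirements = list(sr("wget"), sr("samtools", "1.17", "conda-spec",
                                         "samtools=1.17")),
      origin = "https://ftp.ebi.ac.uk/pub/databases/gencode/",
      executable_offline = FALSE
    ),
    recipe(
      name = "hisat2_index",
      description = "Use \"hisat2-build\" to build the index files",
      script = "hisat2-build -p {{threads}} {{fasta}} {{basename}}\n",
      parameters = list(
        p("fasta", "file", description = "Reference genome FASTA"),
        p("basename", "string", description = "Index basename"),
        p("threads", "int", required = FALSE, default = 4L)
      ),
      outputs = list(o("index_files", "*.ht2")),
      requirements = list(sr("hisat2", "2.2.1", "conda-spec", "hisat2=2.2.1")),
      executable_offline = FALSE
    ),
    recipe(
      name = "reference_genome",
      description = paste("Download, format and index reference genome file",
                          "with samtools, picard and bwa"),
      script = paste0(
        "wget -O genome.fa.gz {{fasta_url}}\n",
        "gunzip genome.fa.gz\n",
        "samtools faidx genome.fa\n",
        "picard CreateSequenceDictionary R=genome.fa O=genome.dict\n",
        "bwa index genome.fa\n"),
      parameters = list(
        p("fasta_url", "string", description = "URL of the genome FASTA (gzipped)")
      ),
      outputs = list(
        o("fasta", "genome.fa"),
        o("fai", "genome.fa.fai", role = "secondary"),
        o("dict", "genome.dict", role = "secondary"),
        o("bwa_index", "genome.fa.*", role = "secondary")
      ),
      requirements = list(
        sr("wget"),
        sr("samtools", "1.17", "conda-spec", "samtools=1.17"),
        sr("picard", "3.0.0", "conda-spec", "picard=3.0.0"),
        sr("bwa", "0.7.17", "conda-spec", "bwa=0.7.17")
      ),
      executable_offline = FALSE
    ),
    recipe(
      name = "salmon_index",
      description = paste("Use \"Salmon index\" command to build salmon index",
                          "for your transcriptome"),
      script = "salmon index -t {{transcriptome}} -i {{index_name}} -p {{threads}}\n",
      parameters = list(
        p("transcriptome", "file", description = "Transcriptome FASTA"),
        p("index_name", "string", description = "Index directory name"),
        p("threads", "int", required = FALSE, default = 4L)
      ),
      outputs = list(o("index_files", "*")),
      requirements = list(sr("salmon", "1.10.1", "conda-spec", "salmon=1.10.1")),
      executable_offline = FALSE
    ),
    recipe(
      name = "STAR_index",
      description = "Use STAR command to build genome index for STAR alignment",
      script = paste0(
        "STAR --runMode genomeGenerate --genomeDir STAR_index ",
        "--genomeFastaFiles {{fasta}} --sjdbGTFfile {{gtf}} ",
        "--sjdbOverhang {{sjdb_overhang}} --runThreadN {{threads}}\n"),
      parameters = list(
        p("fasta", "file", description = "Genome FASTA"),
        p("gtf", "file", description = "Gene annotation GTF"),
        p("sjdb_overhang", "int", required = FALSE, default = 100L),
        p("threads", "int", required = FALSE, default = 4L)
      ),
      outputs = list(o("index_files", "STAR_index/*")),
      requirements = list(sr("STAR", "2.7.10b", "conda-spec", "star=2.7.10b")),
      executable_offline = FALSE
    ),
    recipe(
      name = "ucsc_database",
      description = paste("Download genome annotation file from UCSC database",
                          "using the golden path"),
      script = paste0(
        "wget https://hgdownload.soe.ucsc.edu/goldenPath/{{genome}}/database/",
        "{{filename}}\n"),
      parameters = list(
        p("genome", "string", description = "UCSC genome build, e.g. hg38"),
        p("filename", "string", description = "Database file name")
      ),
      outputs = list(o("dbfile", "*")),
      requirements = list(sr("wget")),
      origin = "https://hgdownload.soe.ucsc.edu/goldenPath/",
      executable_offline = FALSE
    )
  )
}

gcp_bundle_recipe <- function(name, description, bucket) {
  recipe(
    name = name,
    description = description,
    script = sprintf("gsutil cp %s/{{filename}} .\n", bucket),
    parameters = list(
      param_spec("filename", "string", description = "Bundle file to download")
    ),
    outputs = list(output_spec("bundle_file", "*")),
    requirements = list(software_requirement("gsutil", "unversioned",
                                             "conda-spec", "gsutil")),
    origin = paste0(bucket, "/"),
    executable_offline = FALSE
  )
}

#' Write the pre-built recipe catalog
#'
#' Writes the 15 pre-built recipe definition files (one YAML per recipe) to
#' `dest`. Network-dependent recipes carry their upstream `origin` URLs and
#' are marked `executable_offline: false`; they are schema-valid and
#' CWL-renderable but their scripts need network access and external tools.
#' Only `echo_out` is runnable anywhere.
#'
#' @param dest Destination directory (created if needed).
#' @return Character vector of written file paths, sorted by name.
#' @export
#' @examples
#' paths <- make_catalog(tempfile("catalog-"))
#' basename(paths)
make_catalog <- function(dest) {
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  recs <- catalog_definitions()
  paths <- vapply(recs, function(r) {
    p <- file.path(dest, paste0(r$name, ".yaml"))
    write_recipe(r, p)
    p
  }, "")
  sort_c(paths)
}

#' Path to the shipped recipe catalog
#'
#' The same 15 definitions as [make_catalog()], shipped with the package.
#' @return Directory path.
#' @export
shipped_catalog_dir <- function() {
  system.file("extdata", "recipes", package = "recipekit", mustWork = TRUE)
}

# Deterministic word pools for fixture variety.
FIXTURE_WORDS <- c("human", "mouse", "genome", "liftover", "annotation",
                   "transcripts", "variants", "index", "coverage", "primer")
FIXTURE_NOTES <- list(c("human", "genome"), c("mouse", "genome"),
                      c("liftover"), c("annotation", "gtf"),
                      c("transcripts", "index"), c("toy", "demo"))

#' Generate a curated-data tree of toy evaluations
#'
#' Evaluates the offline `echo_out` recipe `n_records` times with distinct,
#' seed-determined bindings and notes, into a nested directory tree under
#' `root`, producing realistic data + sidecar layouts for index tests.
#' Regeneration with the same seed reproduces every file byte-for-byte
#' except the sidecar timestamps.
#'
#' @param root Destination directory (created if needed).
#' @param n_records Number of evaluations.
#' @param seed Integer seed driving binding/note choice.
#' @return Character vector of sidecar (`.yml`) paths.
#' @export
make_toy_data_tree <- function(root, n_records = 5L, seed = 1L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (n_records == 0L) return(character())
  defs <- catalog_definitions()
  r <- defs[[which(vapply(defs, `[[`, "", "name") == "echo_out")]]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  vapply(seq_len(n_records), function(i) {
    word <- sample(FIXTURE_WORDS, 1)
    notes <- FIXTURE_NOTES[[sample(length(FIXTURE_NOTES), 1)]]
    batch <- file.path(root, sprintf("batch%02d", (i - 1L) %% 3L + 1L))
    subdir <- if (i %% 2L == 0L) file.path(batch, sprintf("run%03d", i)) else batch
    res <- evaluate(
      r,
      list(input = sprintf("record %03d %s", i, word),
           outfile = sprintf("data%03d_%s", i, word)),
      outdir = subdir, notes = notes
    )
    unname(res$sidecars["yml"])
  }, "")
}

#' Generate a mock remote bucket with a checksum manifest
#'
#' Writes `entries` small text objects (exactly what an `echo_out`
#' evaluation would produce for the listed parameters) under
#' `<dir>/objects/echo_out/` and a valid manifest TSV with their true MD5s,
#' so [fetch_remote()] can be exercised end-to-end with the default local
#' transport.
#'
#' @param dir Bucket directory (created if needed).
#' @param entries Number of objects.
#' @param seed Integer seed driving object content.
#' @return Path of the written manifest (`<dir>/manifest.tsv`).
#' @export
make_mock_bucket <- function(dir, entries = 3L, seed = 1L) {
  objroot <- file.path(dir, "objects")
  dir.create(file.path(objroot, "echo_out"), recursive = TRUE,
             showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(entries), function(i) {
    word <- sample(FIXTURE_WORDS, 1)
    input <- sprintf("bucket object %03d %s", i, word)
    outfile <- sprintf("bucket%03d_%s", i, word)
    # paths are relative to the manifest's own directory (the bucket root)
    rel <- file.path("objects", "echo_out", paste0(outfile, ".txt"))
    f <- file.path(dir, rel)
    writeLines(input, f)  # echo adds the same trailing newline
    data.frame(
      recipe = "echo_out",
      params_json = canonical_params_json(list(input = input, outfile = outfile)),
      path = rel, md5 = compute_md5(f), size = as.numeric(file.size(f)),
      stringsAsFactors = FALSE
    )
  })
  entries_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recipe = character(), params_json = character(),
               path = character(), md5 = character(), size = numeric(),
               stringsAsFactors = FALSE)
  manifest <- structure(list(base = normalizePath(dir), entries = entries_df),
                        class = "bucket_manifest")
  mpath <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, mpath)
  mpath
}
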