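# Recipe and data indexes: sync, keyword search, tags, persistence.

test_that("recipe_update syncs a directory, idempotently, reporting bad files", {
  src <- tempfile("recipes-")
  dir.create(src)
  write_recipe(toy_echo_recipe(), file.path(src, "echo_out.yaml"))
  write_recipe(toy_multi_recipe(), file.path(src, "toy_indexed.yaml"))
  write_recipe(toy_failing_recipe(), file.path(src, "toy_fail.yaml"))

  idx <- recipe_index(tempfile("rcache-"))
  idx <- recipe_update(idx, src)
  expect_length(idx$entries, 3)
  expect_identical(recipe_names(idx), c("echo_out", "toy_fail", "toy_indexed"))

  # re-sync: unchanged
  idx <- recipe_update(idx, src)
  expect_length(idx$entries, 3)
  expect_length(idx$last_report, 0)

  # a malformed file is reported, not fatal
  writeLines("name: [unclosed", file.path(src, "broken.yaml"))
  idx <- recipe_update(idx, src)
  expect_length(idx$entries, 3)
  expect_length(idx$last_report, 1)
  expect_match(names(idx$last_report), "broken.yaml")

  # newer version of an existing name replaces it with a warning
  newer <- toy_echo_recipe()
  newer$version <- "0.2.0"
  write_recipe(newer, file.path(src, "echo_out.yaml"))
  expect_warning(idx <- recipe_update(idx, src), "0\\.2\\.0")
  expect_identical(recipe_load(idx, "echo_out")$version, "0.2.0")

  expect_rk_error(recipe_update(idx, tempfile("nosuch-")), "recipekit_io_error")
  expect_rk_error(recipe_load(idx, "nope"), "recipekit_notfound_error")
})

test_that("recipe_search ANDs case-insensitive substrings over name+description", {
  idx <- recipe_index(tempfile("rcache-"))
  idx <- recipe_update(idx, shipped_catalog_dir())
  expect_length(idx$entries, 15)

  hits <- vapply(recipe_search(idx, "gencode"), `[[`, "", "name")
  expect_identical(hits, c("gencode_annotation", "gencode_genome_grch38",
                           "gencode_transcripts"))
  hits <- vapply(recipe_search(idx, "gatk"), `[[`, "", "name")
  expect_identical(hits, c("gcp_broad_gatk_hg19", "gcp_broad_gatk_hg38",
                           "gcp_gatk_mutect2_b37", "gcp_gatk_mutect2_hg38"))
  # AND semantics across keywords
  hits <- vapply(recipe_search(idx, c("gatk", "hg38")), `[[`, "", "name")
  expect_identical(hits, c("gcp_broad_gatk_hg38", "gcp_gatk_mutect2_hg38"))
  expect_length(recipe_search(idx, "zzz-nonexistent"), 0)
  # empty keyword list returns everything
  expect_length(recipe_search(idx), 15)
})

test_that("recipe index persists and reloads to an equal index", {
  cache <- tempfile("rcache-")
  idx <- recipe_update(recipe_index(cache), shipped_catalog_dir())
  re <- recipe_index(cache)
  expect_identical(recipe_names(re), recipe_names(idx))
  for (nm in recipe_names(idx)) {
    expect_identical(recipe_load(re, nm), recipe_load(idx, nm))
  }
})

test_that("data_update scans recursively, idempotently, flagging missing data", {
  root <- tempfile("tree-")
  ymls <- make_toy_data_tree(root, n_records = 4L, seed = 7L)
  expect_length(ymls, 4)
  expect_true(any(lengths(strsplit(ymls, "/")) >
                    length(strsplit(root, "/")[[1]]) + 2))  # nested depths

  idx <- data_index(tempfile("dcache-"))
  idx <- data_update(idx, root)
  expect_length(idx$records, 4)
  idx <- data_update(idx, root)
  expect_length(idx$records, 4)

  # evaluate-then-update closure: one new record whose params equal the bindings
  b <- list(input = "closure check", outfile = "closure")
  evaluate(toy_echo_recipe(), b, outdir = file.path(root, "extra"))
  idx <- data_update(idx, root)
  expect_length(idx$records, 5)
  rec <- data_search(idx, "closure")[[1]]
  expect_identical(data_params(rec), b)

  # deleted data file: record indexed but flagged
  unlink(file.path(root, "extra", "closure.txt"))
  idx <- data_update(idx, root)
  expect_length(idx$records, 5)
  rec <- data_search(idx, "closure")[[1]]
  expect_true(rec$missing_data)

  # malformed sidecar skipped with a report
  writeLines("::not yaml::", file.path(root, "junk.yml"))
  idx <- data_update(idx, root)
  expect_length(idx$records, 5)
  expect_length(idx$last_report, 1)
})

test_that("data_search implements AND keyword matching over record text", {
  root <- tempfile("tree-")
  outdirs <- file.path(root, c("a", "b", "c"))
  r <- toy_echo_recipe()
  evaluate(r, list(input = "hg38 assembly", outfile = "human_set"),
           outdir = outdirs[1], notes = c("human", "genome"))
  evaluate(r, list(input = "mm39 assembly", outfile = "mouse_set"),
           outdir = outdirs[2], notes = c("mouse", "genome"))
  evaluate(r, list(input = "chain file", outfile = "lift_set"),
           outdir = outdirs[3], notes = "liftover")

  idx <- data_update(data_index(tempfile("dcache-")), root)
  expect_length(data_search(idx, "genome"), 2)
  expect_length(data_search(idx, c("genome", "human")), 1)
  expect_length(data_search(idx, "zzz"), 0)
  expect_length(data_search(idx), 3)
  # matches parameter values and file basenames too
  expect_length(data_search(idx, "hg38"), 1)
  expect_length(data_search(idx, "mouse_set"), 1)
})

test_that("data_search agrees with a brute-force oracle and is AND-monotone", {
  root <- tempfile("tree-")
  make_toy_data_tree(root, n_records = 12L, seed = 11L)
  idx <- data_update(data_index(tempfile("dcache-")), root)
  records <- unname(idx$records)

  pool <- c("human", "mouse", "genome", "liftover", "annotation", "toy",
            "record", "data", "echo", "zzz")
  set.seed(99)
  for (i in 1:40) {
    kws <- sample(pool, sample(1:3, 1))
    got <- data_search(idx, kws)
    want <- bf_data_search(records, kws)
    expect_identical(data_yml(got), data_yml(want))
    # adding a keyword never enlarges the result set
    wider <- data_search(idx, c(kws, sample(pool, 1)))
    expect_lte(length(wider), length(got))
    expect_true(all(record_ids(wider) %in% record_ids(got)))
  }
})

test_that("tags are durable: set in the index, written to sidecars, reloadable", {
  root <- tempfile("tree-")
  make_toy_data_tree(root, n_records = 3L, seed = 3L)
  cache <- tempfile("dcache-")
  idx <- data_update(data_index(cache), root)
  ids <- record_ids(unname(idx$records))[1:2]

  idx <- set_tags(idx, ids, "bwa")
  hits <- data_search(idx, "bwa")
  expect_setequal(record_ids(hits), ids)
  # re-tagging with the same tag is idempotent
  idx <- set_tags(idx, ids, "bwa")
  expect_setequal(record_ids(data_search(idx, "bwa")), ids)
  # the sidecar carries the tag (authoritative copy)
  expect_identical(yaml::read_yaml(idx$records[[ids[1]]]$yml_path)$tags, "bwa")

  # tags survive a fresh scan from disk and an index reload
  idx2 <- data_update(data_index(tempfile("dcache2-")), root)
  expect_setequal(record_ids(data_search(idx2, "bwa")), ids)
  idx3 <- data_index(cache)
  expect_setequal(record_ids(data_search(idx3, "bwa")), ids)

  expect_rk_error(set_tags(idx, "deadbeef", "x"), "recipekit_notfound_error")
  expect_rk_error(set_tags(idx, ids, c("ok", "")), "recipekit_validation_error")
})

test_that("a persisted data index reloads entry-for-entry equal", {
  root <- tempfile("tree-")
  make_toy_data_tree(root, n_records = 5L, seed = 21L)
  cache <- tempfile("dcache-")
  idx <- data_update(data_index(cache), root)
  re <- data_index(cache)
  expect_identical(sort(names(re$records)), sort(names(idx$records)))
  for (id in names(idx$records)) {
    expect_identical(re$records[[id]], idx$records[[id]])
  }
  expect_identical(re$scanned_roots, idx$scanned_roots)
})

test_that("record accessors expose the sidecar fields", {
  out <- tempfile("acc-")
  res <- evaluate(toy_multi_recipe(), list(body = "abc", stem = "acc"),
                  outdir = out, notes = c("note one", "note two"))
  rec <- data_record(res$sidecars[["yml"]])
  expect_identical(sort(data_names(rec)), c("acc.dat", "acc.dat.md5"))
  expect_identical(data_paths(rec), file.path(res$outdir, c("acc.dat", "acc.dat.md5")))
  expect_identical(data_notes(rec), c("note one", "note two"))
  expect_identical(data_params(rec), list(body = "abc", stem = "acc"))
  expect_identical(data_tags(rec), character(0))
  expect_identical(data_yml(rec), res$sidecars[["yml"]])
  expect_match(rec$id, "^[0-9a-f]{32}$")
})
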