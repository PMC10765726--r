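# Recipe evaluation: script execution, output collection, checksums,
# provenance sidecars, verification.

test_that("evaluation produces the data file and exactly four sidecars", {
  r <- toy_echo_recipe()
  outdir <- tempfile("eval-")
  res <- evaluate(r, list(input = "Hello World", outfile = "hello"),
                  outdir = outdir, notes = c("toy", "demo"))

  expect_identical(res$exit_code, 0L)
  expect_identical(res$prefix, "echo_out_Hello-World_hello")
  expect_identical(basename(res$data_files), "hello.txt")
  expect_identical(readLines(res$data_files), "Hello World")
  sidecars <- setdiff(list.files(res$outdir), "hello.txt")
  expect_setequal(sidecars, paste0(res$prefix, c(".yml", ".sh", ".cwl", ".md5")))

  meta <- yaml::read_yaml(res$sidecars[["yml"]])
  expect_identical(meta$recipe, "echo_out")
  expect_identical(meta$version, r$version)
  expect_identical(meta$params, list(input = "Hello World", outfile = "hello"))
  expect_match(meta$date, "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$")
  expect_identical(meta$origin, "local")
  expect_identical(meta$notes, c("toy", "demo"))
  expect_identical(meta$outputs[[1]]$path, "hello.txt")
  expect_match(meta$outputs[[1]]$md5, "^[0-9a-f]{32}$")

  # the .sh sidecar is the exact rendered script, byte-for-byte
  sh <- res$sidecars[["sh"]]
  expect_identical(rawToChar(readBin(sh, "raw", file.size(sh))),
                   render_script(r, list(input = "Hello World",
                                         outfile = "hello")))
  # the .cwl sidecar is independently schema-valid
  expect_identical(cwl_validate_file(res$sidecars[["cwl"]]), character(0))
  # the .md5 manifest passes the system checker
  status <- withr_like_md5check(res$outdir, basename(res$sidecars[["md5"]]))
  expect_identical(status, 0L)
  # verification passes immediately after evaluation
  rep <- verify(res)
  expect_true(all(rep$pass))
})

test_that("a failed script leaves no sidecars and carries exit code + stderr", {
  r <- toy_failing_recipe()
  outdir <- tempfile("evalfail-")
  err <- tryCatch(evaluate(r, list(msg = "boom"), outdir = outdir),
                  error = identity)
  expect_s3_class(err, "recipekit_evaluation_error")
  expect_identical(err$exit_code, 1L)
  expect_match(err$stderr, "boom")
  expect_false(any(grepl("\\.yml$", list.files(outdir))))

  # a primary glob matching nothing is an output-collection error
  r2 <- recipe("nomatch", "echo hi > hi.log\n",
               outputs = list(output_spec("vcf", "*.vcf")))
  err2 <- tryCatch(evaluate(r2, outdir = tempfile()), error = identity)
  expect_s3_class(err2, "recipekit_output_error")
  expect_match(conditionMessage(err2), "\\*\\.vcf")
})

test_that("collect_outputs globs, sorts, and handles overlap", {
  d <- tempfile("collect-")
  dir.create(d)
  for (f in c("b.txt", "a.txt", "c.log")) writeLines("x", file.path(d, f))

  got <- collect_outputs(d, list(output_spec("txt", "*.txt")))
  expect_identical(basename(got$path), c("a.txt", "b.txt"))

  expect_identical(nrow(collect_outputs(d, list(output_spec("vcf", "*.vcf")))),
                   0L)

  # overlapping globs: a.txt reported once per matching spec
  both <- collect_outputs(d, list(output_spec("txt", "*.txt"),
                                  output_spec("a_files", "a.*")))
  expect_identical(sum(basename(both$path) == "a.txt"), 2L)
  # ... but the evaluation result deduplicates promoted files (brute-force
  # set comparison against the union of matches)
  r <- recipe("overlap", 'echo "{{v}}" > a.txt\necho other > b.txt\n',
              parameters = list(param_spec("v")),
              outputs = list(output_spec("txt", "*.txt"),
                             output_spec("a_files", "a.*")))
  res <- evaluate(r, list(v = "dup"), outdir = tempfile())
  expect_identical(sort(basename(res$data_files)), c("a.txt", "b.txt"))
})

test_that("compute_md5 agrees with the system md5 utility", {
  empty <- tempfile(); file.create(empty)
  hello <- tempfile(); writeLines("Hello World", hello)  # content + newline
  for (f in c(empty, hello)) {
    sys <- strsplit(system2("md5sum", f, stdout = TRUE), " ")[[1]][1]
    expect_identical(compute_md5(f), sys)
    expect_identical(compute_md5(f), compute_md5(f))
  }
  expect_rk_error(compute_md5(tempfile()), "recipekit_io_error")
})

test_that("md5 manifests use the md5sum format and verify with md5sum -c", {
  d <- tempfile("manifest-")
  dir.create(d)
  f1 <- file.path(d, "one.txt"); writeLines("first", f1)
  f2 <- file.path(d, "two.txt"); writeLines("second", f2)
  mf <- file.path(d, "files.md5")

  write_md5_manifest(f1, mf)
  line <- readLines(mf)
  expect_length(line, 1)
  expect_match(line, "^[0-9a-f]{32}  one\\.txt$")  # two-space separator

  write_md5_manifest(c(f1, f2), mf)
  expect_identical(withr_like_md5check(d, "files.md5"), 0L)

  # empty file list -> empty manifest
  write_md5_manifest(character(), mf)
  expect_identical(readLines(mf), character(0))
})

test_that("verify detects tampering and missing files, per file", {
  r <- toy_multi_recipe()
  res <- evaluate(r, list(body = "payload", stem = "sample"),
                  outdir = tempfile("verify-"))
  expect_true(all(verify(res)$pass))

  # flip one byte of the primary file: exactly that file fails
  dat <- file.path(res$outdir, "sample.dat")
  bytes <- readBin(dat, "raw", file.size(dat))
  bytes[1] <- xor(bytes[1], as.raw(1))
  writeBin(bytes, dat)
  rep <- verify(res)
  expect_identical(rep$pass, c(FALSE, TRUE))
  expect_identical(rep$reason[1], "checksum-mismatch")

  # deleting a file reports reason "missing" without raising
  unlink(file.path(res$outdir, "sample.dat.md5"))
  rep2 <- verify(res)
  expect_identical(rep2$reason[rep2$path == "sample.dat.md5"], "missing")
})

test_that("repeated evaluation is deterministic; collisions are refused", {
  r <- toy_echo_recipe()
  b <- list(input = "same again", outfile = "stable")
  res1 <- evaluate(r, b, outdir = tempfile("det1-"))
  res2 <- evaluate(r, b, outdir = tempfile("det2-"))
  expect_identical(compute_md5(res1$data_files), compute_md5(res2$data_files))

  # re-running with identical parameters into the same outdir overwrites
  res3 <- evaluate(r, b, outdir = res1$outdir)
  expect_true(all(verify(res3)$pass))

  # same prefix, different recorded parameters -> collision error
  yml <- res1$sidecars[["yml"]]
  meta <- yaml::read_yaml(yml)
  meta$params$input <- "something else"
  yaml::write_yaml(meta, yml)
  expect_rk_error(evaluate(r, b, outdir = res1$outdir),
                  "recipekit_collision_error")
})

test_that("pluggable runners honour the evaluation contract", {
  r <- toy_echo_recipe()
  calls <- new.env()
  stub <- runner_spec("conda-wrapped", options = list(
    exec = function(script_path, workdir, stderr_path) {
      calls$seen <- TRUE
      old <- setwd(workdir); on.exit(setwd(old))
      system2("sh", c("-e", shQuote(script_path)),
              stdout = stderr_path, stderr = stderr_path)
    }))
  res <- evaluate(r, list(input = "via stub", outfile = "stubbed"),
                  outdir = tempfile(), runner = stub)
  expect_true(calls$seen)
  expect_identical(readLines(res$data_files), "via stub")

  expect_rk_error(runner_spec("cwl-engine"), "recipekit_validation_error")
})
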