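write_synth_fasta <- function(seed, n, range = c(30L, 80L)) {
  tmp <- tempfile(fileext = ".fasta")
  write_fasta(synth_proteins(seed, n, range), tmp)
  tmp
}

test_that("a small aac batch writes header plus one row per record", {
  fa <- withr::local_file(write_synth_fasta(38, 2))
  out <- withr::local_tempfile(fileext = ".csv")
  report <- run_batch(run_config(fa, "aac", out))
  expect_equal(report$records_read, 2L)
  expect_equal(report$rows_written, 2L)
  expect_equal(report$dim, 20L)
  res <- read_output(out, "csv")
  expect_equal(dim(res$matrix), c(2L, 20L))
  expect_equal(colnames(res$matrix), paste0("AAC_", ALPHA))
  expect_equal(res$ids, c("synth1", "synth2"))
  expect_equal(unname(rowSums(res$matrix)), c(1, 1), tolerance = 1e-9)
})

test_that("an empty FASTA yields a header-only file and a zero-record report", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  out <- withr::local_tempfile(fileext = ".csv")
  report <- run_batch(run_config(fa, "aac", out))
  expect_equal(report$records_read, 0L)
  lines <- readLines(out)
  expect_length(lines, 1L)
})

test_that("identical configs produce byte-identical outputs", {
  fa <- withr::local_file(write_synth_fasta(39, 25))
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  run_batch(run_config(fa, "pseaac1", out1, params = list(lambda = 10L)))
  run_batch(run_config(fa, "pseaac1", out2, params = list(lambda = 10L)))
  expect_identical(readLines(out1), readLines(out2))
})

test_that("row order follows FASTA order and skips are counted", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEACDE", ">b", "ACXE", ">c", "GGGG"), fa)
  out <- withr::local_tempfile(fileext = ".csv")
  expect_warning(
    report <- run_batch(run_config(fa, "aac", out,
                                   ambiguous_policy = "skip_record")),
    "skipped")
  expect_equal(report$records_read, 2L)
  expect_equal(report$records_skipped, 1L)
  expect_equal(read_output(out, "csv")$ids, c("a", "c"))
  # under policy=error the offending record aborts the run
  expect_error(run_batch(run_config(fa, "aac", out)), "'b'")
})

test_that("svmlight output omits zero features and round-trips values", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "AAACCC"), fa)
  out <- withr::local_tempfile(fileext = ".svm")
  run_batch(run_config(fa, "aac", out, format = "svmlight"))
  line <- readLines(out)
  expect_length(line, 1L)
  expect_match(line, "# p1$")
  toks <- strsplit(sub(" # p1$", "", line), " ")[[1]]
  expect_equal(toks[1], "0")
  pairs <- do.call(rbind, strsplit(toks[-1], ":"))
  expect_equal(as.integer(pairs[, 1]), c(1L, 2L))  # A and C only
  expect_equal(as.numeric(pairs[, 2]), c(0.5, 0.5))
})

test_that("csv round-trip preserves values to 12 significant digits", {
  fa <- withr::local_file(write_synth_fasta(40, 5))
  out <- withr::local_tempfile(fileext = ".tsv")
  run_batch(run_config(fa, "qso", out, format = "tsv"))
  res <- read_output(out, "tsv")
  direct <- t(sapply(read_fasta(fa), function(rec) {
    mats <- qso_matrices()
    unlist(lapply(mats, function(dm) as.numeric(qso_vector(rec, dm))))
  }))
  expect_equal(unname(res$matrix), unname(direct), tolerance = 1e-11)
})

test_that("annotation-backed modes run in batch with row alignment", {
  recs <- synth_proteins(41, 6, c(10L, 30L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  ids <- vapply(recs, `[[`, character(1), "id")
  amap <- synth_annotation_map(42, ids[1:5], n_terms = 9)
  atsv <- withr::local_tempfile(fileext = ".tsv")
  save_annotation_map(amap, atsv)
  out <- withr::local_tempfile(fileext = ".csv")
  expect_warning(
    report <- run_batch(run_config(fa, "go", out, annotations = atsv)),
    "absent")
  expect_equal(report$rows_written, 6L)
  res <- read_output(out, "csv")
  # the unannotated record keeps its (all-zero) row in input order
  expect_equal(res$ids, ids)
  expect_equal(sum(res$matrix[6, ]), 0)
})

test_that("streaming keeps at most one chunk of records in memory", {
  fa <- withr::local_file(write_synth_fasta(43, 120, c(10L, 25L)))
  out <- withr::local_tempfile(fileext = ".csv")
  chunk_sizes <- integer(0)
  report <- run_batch(run_config(fa, "aac", out, chunk_size = 16L),
                      chunk_hook = function(n) chunk_sizes <<- c(chunk_sizes, n))
  expect_equal(report$records_read, 120L)
  expect_true(all(chunk_sizes <= 16L))
  expect_equal(sum(chunk_sizes), 120L)
  expect_gt(length(chunk_sizes), 1L)
})

test_that("YAML configs mirror the flag set and reject unknown keys", {
  fa <- withr::local_file(write_synth_fasta(44, 3))
  out <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(paste0("input: ", fa),
               "mode: pseaac1",
               paste0("output: ", out),
               "params:",
               "  lambda: 4",
               "  w: 0.1"), yml)
  cfg <- load_run_config(yml)
  report <- run_batch(cfg)
  expect_equal(report$dim, 24L)
  writeLines(c(paste0("input: ", fa), "mode: aac",
               paste0("output: ", out), "bogus_key: 1"), yml)
  expect_error(load_run_config(yml), "bogus_key")
})

test_that("the CLI front end runs, lists modes and enumerates", {
  fa <- withr::local_file(write_synth_fasta(45, 3))
  out <- withr::local_tempfile(fileext = ".csv")
  expect_output(pseaac_main(c("run", "--mode", "aac", "--in", fa,
                              "--out", out, "--format", "csv")),
                "records read")
  expect_equal(nrow(read_output(out, "csv")$matrix), 3L)
  expect_output(pseaac_main("modes"), "pseaac1")
  expect_output(pseaac_main(c("enumerate", "--property-count", "544")),
                "total descriptor values: 57977")
  expect_error(pseaac_main(c("run", "--mode", "aac")), "--in|--out")
})
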