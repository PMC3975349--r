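test_that("FASTA records parse with ids, case folding and wrapped lines", {
  con <- textConnection(">p1\nACDE\n>p2 some description\nacde\nGHIK\n")
  recs <- read_fasta(con)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$seq, "ACDE")
  expect_equal(recs[[1]]$length, 4L)
  expect_equal(recs[[2]]$id, "p2")
  expect_equal(recs[[2]]$description, "some description")
  expect_equal(recs[[2]]$seq, "ACDEGHIK")
})

test_that("malformed FASTA reports the offending line number", {
  con <- textConnection("ACDE\n")
  expect_error(read_fasta(con), "line 1")
})

test_that("ambiguity policies behave as documented", {
  fa <- ">p1\nAXDE\n"
  expect_error(read_fasta(textConnection(fa), "error"), "p1.*X|X.*p1")
  expect_warning(
    recs <- read_fasta(textConnection(fa), "skip_record"), "skipped")
  expect_length(recs, 0L)
  # X is unresolvable even under mapping; B/Z/U/O/J map to D/E/C/K/L
  expect_warning(
    recs2 <- read_fasta(textConnection(fa), "map_to_nearest"), "skipped")
  expect_length(recs2, 0L)
  recs3 <- read_fasta(textConnection(">p1\nBZUOJ\n"), "map_to_nearest")
  expect_equal(recs3[[1]]$seq, "DECKL")
})

test_that("FASTA round-trips through write_fasta for canonical input", {
  recs <- synth_proteins(11, 20, c(5L, 120L))
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, tmp, width = 60L)
  back <- read_fasta(tmp)
  expect_equal(vapply(back, `[[`, character(1), "id"),
               vapply(recs, `[[`, character(1), "id"))
  expect_equal(vapply(back, `[[`, character(1), "seq"),
               vapply(recs, `[[`, character(1), "seq"))
})

test_that("package FASTA parsing agrees with Biostrings on canonical input", {
  skip_if_not_installed("Biostrings")
  recs <- synth_proteins(7, 10, c(10L, 80L))
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, tmp)
  ref <- Biostrings::readAAStringSet(tmp)
  expect_equal(unname(as.character(ref)),
               vapply(read_fasta(tmp), `[[`, character(1), "seq"))
})

test_that("TSV property tables load in canonical order", {
  tsv <- paste(c(paste(c("property", ALPHA), collapse = "\t"),
                 paste(c("P1", 1:20), collapse = "\t")), collapse = "\n")
  pt <- load_property_table(textConnection(tsv), "tsv")
  expect_equal(unname(pt$raw["P1", "A"]), 1)
  expect_equal(unname(pt$raw["P1", "Y"]), 20)
})

test_that("AAindex entries are re-mapped from ARNDCQEGHILKMFPSTWYV order", {
  vals <- sprintf("%.2f", 1:20)
  aaindex <- paste(c("H TEST0001", "D test entry",
                     "I   A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V",
                     paste(vals[1:10], collapse = "  "),
                     paste(vals[11:20], collapse = "  "),
                     "//"), collapse = "\n")
  pt <- load_property_table(textConnection(aaindex), "aaindex1")
  # first number of the block is A; fifth is C; last is V
  expect_equal(unname(pt$raw["TEST0001", "A"]), 1)
  expect_equal(unname(pt$raw["TEST0001", "C"]), 5)
  expect_equal(unname(pt$raw["TEST0001", "V"]), 20)
})

test_that("entries with NA values are dropped with a count; order is stable", {
  rows <- c(paste(c("property", ALPHA), collapse = "\t"),
            paste(c("P1", 1:20), collapse = "\t"),
            paste(c("BAD", c("NA", 2:20)), collapse = "\t"),
            paste(c("P2", 21:40), collapse = "\t"))
  expect_warning(
    pt <- load_property_table(textConnection(paste(rows, collapse = "\n"))),
    "dropped")
  expect_equal(rownames(pt$raw), c("P1", "P2"))
  expect_equal(attr(pt, "n_dropped"), 1L)
})

test_that("a property row with the wrong number of values names the accession", {
  rows <- c(paste(c("property", ALPHA), collapse = "\t"),
            paste(c("SHORT", 1:19), collapse = "\t"))
  expect_error(
    load_property_table(textConnection(paste(rows, collapse = "\n"))),
    "SHORT")
})

test_that("normalize_property standardizes with divisor-20 SD", {
  out <- normalize_property(1:20)
  expect_equal(out[1], (1 - 10.5) / sqrt(33.25))
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(out^2)), 1, tolerance = 1e-12)
  # already-standardized input is a fixed point
  alt <- rep(c(1, -1), 10)
  expect_equal(normalize_property(alt), alt, tolerance = 1e-12)
  set.seed(42)
  z <- normalize_property(rnorm(20))
  expect_equal(normalize_property(z), z, tolerance = 1e-12)
  expect_error(normalize_property(rep(3, 20)), "degenerate")
})

test_that("normalization is idempotent on every bundled property", {
  pt <- chou_classic_table()
  for (acc in rownames(pt$raw)) {
    z <- pt$normalized[acc, ]
    expect_equal(normalize_property(z), z, tolerance = 1e-12)
  }
})

test_that("synthetic fixtures are deterministic and validate", {
  f1 <- synth_fixtures(1, 2, c(10L, 20L))
  f2 <- synth_fixtures(1, 2, c(10L, 20L))
  expect_identical(f1$fasta, f2$fasta)
  expect_error(synth_proteins(1, 2, c(0L, 5L)), "lower bound")
  f0 <- synth_fixtures(1, 0, c(10L, 20L))
  expect_length(f0$records, 0L)
  big <- synth_proteins(1, 500, c(50L, 300L))
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(big, tmp)
  expect_length(read_fasta(tmp, "error"), 500L)
})
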