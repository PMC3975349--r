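# Seeded RNG scope: every generator here runs inside withr-style local seed
# handling so callers' RNG state is never disturbed.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate synthetic protein records
#'
#' Uniform i.i.d. sequences over the canonical alphabet with lengths drawn
#' uniformly from `length_range`. Deterministic for a given seed.
#'
#' @param seed integer seed
#' @param n number of proteins
#' @param length_range integer vector `c(min, max)`; `min >= 1`
#' @param prefix accession prefix
#' @return list of [protein_record]s with ids `<prefix>1..<prefix>n`
#' @export
synth_proteins <- function(seed, n, length_range = c(50L, 300L),
                           prefix = "synth") {
  if (length_range[1] < 1L)
    stop("length_range lower bound must be >= 1", call. = FALSE)
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      L <- sample(length_range[1]:length_range[2], 1L)
      protein_record(paste0(prefix, i),
                     paste(sample(AA_ALPHABET, L, replace = TRUE),
                           collapse = ""))
    })
  })
}

#' Generate a synthetic property table
#'
#' Standard-normal placeholder values; useful for dimensionality tests
#' (e.g. a 544-entry table mirroring the size of a full AAindex-derived
#' table) and for constructing adversarial properties in tests.
#'
#' @param seed integer seed
#' @param n_properties number of property rows
#' @param prefix accession prefix
#' @return a [property_table]
#' @export
synth_property_table <- function(seed, n_properties = 3L, prefix = "SYN") {
  .with_seed(seed, {
    raw <- matrix(stats::rnorm(20L * n_properties), nrow = n_properties)
    rownames(raw) <- sprintf("%s%04d", prefix, seq_len(n_properties))
    property_table(raw)
  })
}

#' Generate a synthetic annotation map
#'
#' @param seed integer seed
#' @param ids protein accessions to annotate
#' @param n_terms size of the term universe
#' @param mean_terms mean number of terms per protein (Poisson, capped at
#'   the universe size)
#' @return an [annotation_map()]
#' @export
synth_annotation_map <- function(seed, ids, n_terms = 50L, mean_terms = 4) {
  .with_seed(seed, {
    universe <- sprintf("GO:%07d", sort(sample.int(9999999L, n_terms)))
    assignments <- lapply(ids, function(id) {
      k <- min(stats::rpois(1L, mean_terms), n_terms)
      sample(universe, k)
    })
    names(assignments) <- ids
    annotation_map(assignments, universe)
  })
}

#' Generate a synthetic PSSM
#'
#' Integer log-odds scores uniform on `[-10, 10]`, the typical PSI-BLAST
#' score range.
#'
#' @param seed integer seed
#' @param L number of positions
#' @param accession accession label
#' @return a [pssm()]
#' @export
synth_pssm <- function(seed, L, accession = "synth") {
  .with_seed(seed,
    pssm(matrix(sample(-10:10, L * 20L, replace = TRUE), nrow = L),
         accession))
}

#' Generate a complete synthetic fixture set
#'
#' One call producing everything a batch run needs: FASTA text, a property
#' table, an annotation map over the generated accessions, and one PSSM per
#' protein. Byte-identical across runs with the same arguments.
#'
#' @param seed integer seed
#' @param n number of proteins
#' @param length_range protein length range `c(min, max)`
#' @param n_properties property rows in the table
#' @return list with `fasta` (character vector of FASTA lines), `records`,
#'   `ptable`, `amap`, `pssms` (list of [pssm()], one per record)
#' @export
synth_fixtures <- function(seed, n, length_range = c(50L, 300L),
                           n_properties = 3L) {
  records <- synth_proteins(seed, n, length_range)
  con <- textConnection("fasta_out", "w", local = TRUE)
  write_fasta(records, con)
  close(con)
  ids <- vapply(records, `[[`, character(1), "id")
  list(fasta = fasta_out,
       records = records,
       ptable = synth_property_table(seed + 1L, n_properties),
       amap = if (n > 0L) synth_annotation_map(seed + 2L, ids)
              else annotation_map(stats::setNames(list(), character(0)),
                                  character(0)),
       pssms = lapply(seq_len(n), function(i)
         synth_pssm(seed + 2L + i, records[[i]]$length, ids[i])))
}
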