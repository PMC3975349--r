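# k-mer feature names in row-major canonical order: first letter varies slowest
.kmer_names <- function(k, prefix) {
  grids <- rev(rep(list(AA_ALPHABET), k))
  g <- do.call(expand.grid, c(grids, list(stringsAsFactors = FALSE)))
  paste0(prefix, "_", do.call(paste0, rev(g)))
}

#' Amino-acid composition
#'
#' Frequencies of the 20 residues: `f_a = count(a) / L`. The 20 values sum
#' to one and are invariant under any permutation of the sequence.
#'
#' @param rec a [protein_record]
#' @return a 20-feature [descriptor_vector()] (`AAC_A` .. `AAC_Y`)
#' @export
aac <- function(rec) {
  idx <- aa_indices(rec$seq)
  f <- tabulate(idx, nbins = 20L) / rec$length
  descriptor_vector("aac", stats::setNames(f, paste0("AAC_", AA_ALPHABET)))
}

#' Di-peptide composition
#'
#' Frequencies of the 400 ordered residue pairs over the `L - 1`
#' overlapping windows: `f_ab = count(ab) / (L - 1)`.
#'
#' @param rec a [protein_record]; requires `L >= 2`
#' @return a 400-feature [descriptor_vector()] (`DPC_AA` .. `DPC_YY`,
#'   first letter varying slowest)
#' @export
dipeptide <- function(rec) {
  L <- rec$length
  if (L < 2L)
    stop("di-peptide composition needs L >= 2 (got L = ", L, ")", call. = FALSE)
  idx <- aa_indices(rec$seq)
  code <- (idx[-L] - 1L) * 20L + idx[-1L]
  f <- tabulate(code, nbins = 400L) / (L - 1L)
  descriptor_vector("dpc", stats::setNames(f, .kmer_names(2L, "DPC")))
}

#' Tri-peptide composition
#'
#' Frequencies of the 8000 ordered residue triples over the `L - 2`
#' overlapping windows: `f_abc = count(abc) / (L - 2)`. The emitted vector
#' is dense; at most `L - 2` entries are nonzero.
#'
#' @param rec a [protein_record]; requires `L >= 3`
#' @return an 8000-feature [descriptor_vector()] (`TPC_AAA` .. `TPC_YYY`)
#' @export
tripeptide <- function(rec) {
  L <- rec$length
  if (L < 3L)
    stop("tri-peptide composition needs L >= 3 (got L = ", L, ")", call. = FALSE)
  idx <- aa_indices(rec$seq)
  code <- (idx[1:(L - 2L)] - 1L) * 400L + (idx[2:(L - 1L)] - 1L) * 20L + idx[3:L]
  f <- tabulate(code, nbins = 8000L) / (L - 2L)
  descriptor_vector("tpc", stats::setNames(f, .kmer_names(3L, "TPC")))
}
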