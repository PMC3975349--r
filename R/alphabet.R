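#' Canonical amino-acid alphabet
#'
#' All descriptors in this package index amino acids in a single canonical
#' order: the alphabetical single-letter order `ACDEFGHIKLMNPQRSTVWY`.
#' External formats that use the AAindex residue order
#' (`ARNDCQEGHILKMFPSTWYV`) are re-mapped on load, so one internal order
#' holds everywhere.
#'
#' @format A character vector of the 20 canonical residues.
#' @export
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# residue order used by AAindex flat files and PSI-BLAST ASCII PSSMs
AAINDEX_ORDER <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

# letter -> 1..20 lookup in canonical order
.aa_code <- stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET)

#' Map residues to canonical indices
#'
#' @param seq a validated sequence string over the canonical alphabet
#' @return integer vector of positions in [AA_ALPHABET] (1..20)
#' @keywords internal
aa_indices <- function(seq) {
  idx <- .aa_code[strsplit(seq, "", fixed = TRUE)[[1]]]
  if (anyNA(idx)) {
    bad <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
    bad <- bad[!bad %in% AA_ALPHABET]
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(idx)
}
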