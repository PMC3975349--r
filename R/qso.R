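#' Amino-acid distance matrix
#'
#' @param mat 20x20 non-negative matrix with zero diagonal, rows/columns in
#'   canonical residue order
#' @param name matrix label used in feature names
#' @return a `distance_matrix`
#' @export
distance_matrix <- function(mat, name) {
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(20L, 20L)))
    stop("distance matrix must be 20x20", call. = FALSE)
  if (!all(is.finite(mat)) || any(mat < 0))
    stop("distance matrix entries must be finite and >= 0", call. = FALSE)
  if (any(diag(mat) != 0))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  dimnames(mat) <- list(AA_ALPHABET, AA_ALPHABET)
  structure(list(name = name, d = mat), class = "distance_matrix")
}

#' Load a distance matrix from TSV
#'
#' Layout: header `residue<TAB>A...Y`, then 20 rows each starting with the
#' residue letter, in canonical order.
#'
#' @param path path to the TSV
#' @param name label (default: file basename without extension)
#' @return a [distance_matrix()]
#' @export
load_distance_matrix <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(df[[1]], AA_ALPHABET))
    stop("distance matrix rows must be the 20 residues in canonical order",
         call. = FALSE)
  distance_matrix(as.matrix(df[, -1, drop = FALSE]), name)
}

#' Bundled distance matrices
#'
#' `grantham`: pairwise amino-acid distances recomputed from the published
#' composition / polarity / volume indices and formula, scaled so the mean
#' pairwise distance is 100 (kept at full precision, so values can differ
#' by up to 1 from the familiar rounded table). `physchem_synthetic`: a
#' synthetic matrix built in the style of physicochemical distance scales,
#' as the root-mean-square difference of the standardized classic
#' hydrophobicity / hydrophilicity / side-chain-mass indices; it stands in
#' for scales whose per-pair values are not redistributable and is labelled
#' synthetic accordingly.
#'
#' @return named list of two [distance_matrix()] objects
#' @export
qso_matrices <- function() {
  list(
    grantham = load_distance_matrix(
      system.file("extdata", "grantham.tsv", package = "pseaacg"),
      name = "grantham"),
    physchem_synthetic = load_distance_matrix(
      system.file("extdata", "physchem_distance_synthetic.tsv",
                  package = "pseaacg"),
      name = "physchem_synthetic"))
}

#' Sequence-order coupling number
#'
#' `tau_d = sum_{i=1}^{L-d} d(R_i, R_(i+d))^2` - the summed squared
#' physicochemical distance between residues `d` positions apart.
#'
#' @param rec a [protein_record]
#' @param dm a [distance_matrix()]
#' @param d lag, `1 <= d < L`
#' @return a scalar
#' @export
coupling_number <- function(rec, dm, d) {
  .check_lag(rec$length, d)
  idx <- aa_indices(rec$seq)
  L <- rec$length
  sum(dm$d[cbind(idx[1:(L - d)], idx[(1L + d):L])]^2)
}

#' Quasi-sequence-order descriptors
#'
#' The 20 residue frequencies plus `max_lag` coupling numbers, normalized
#' together: `X_a = f_a / (1 + w * sum(tau))` and
#' `X_(20+d) = w * tau_d / (1 + w * sum(tau))`. All components are
#' non-negative and sum to one.
#'
#' @param rec a [protein_record] with `L > max_lag`
#' @param dm a [distance_matrix()]
#' @param max_lag largest coupling rank `D`
#' @param w weight factor
#' @return a `(20 + max_lag)`-feature [descriptor_vector()] named
#'   `QSO_<matrix>_...`
#' @export
qso_vector <- function(rec, dm, max_lag = 30L, w = 0.1) {
  stopifnot(w > 0)
  .check_lambda(rec$length, max_lag, what = "max_lag")
  idx <- aa_indices(rec$seq)
  L <- rec$length
  tau <- vapply(seq_len(max_lag), function(d)
    sum(dm$d[cbind(idx[1:(L - d)], idx[(1L + d):L])]^2), numeric(1))
  f <- tabulate(idx, nbins = 20L) / L
  denom <- 1 + w * sum(tau)
  vals <- c(f, w * tau) / denom
  names(vals) <- c(paste0("QSO_", dm$name, "_", AA_ALPHABET),
                   paste0("QSO_", dm$name, "_lag", seq_len(max_lag)))
  descriptor_vector("qso", vals)
}
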