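#' Position-specific scoring matrix
#'
#' @param scores L x 20 numeric matrix of per-position log-odds scores,
#'   columns in canonical residue order
#' @param accession protein accession the matrix belongs to
#' @return a `pssm` object
#' @export
pssm <- function(scores, accession = "unknown") {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L || nrow(scores) < 1L)
    stop("PSSM must be an L x 20 matrix with L >= 1", call. = FALSE)
  if (!all(is.finite(scores))) stop("PSSM entries must be finite", call. = FALSE)
  colnames(scores) <- AA_ALPHABET
  structure(list(accession = accession, scores = scores), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm>", x$accession, " L =", nrow(x$scores), "\n")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the text produced by `psiblast -out_ascii_pssm`: after the header,
#' each row carries the position, the query residue, 20 log-odds scores and
#' 20 weighted-percentage columns (real PSI-BLAST output appends two more
#' statistics columns, which are accepted and ignored). Only the first
#' 20-score block is kept, re-mapped from the file's
#' `ARNDCQEGHILKMFPSTWYV` column order to canonical order.
#'
#' @param path file path or connection
#' @param accession accession to attach (default: file basename)
#' @return a [pssm()]
#' @export
parse_pssm <- function(path, accession = NULL) {
  if (is.null(accession))
    accession <- if (is.character(path)) sub("\\.[^.]*$", "", basename(path))
                 else "unknown"
  lines <- readLines(path)
  reorder <- match(AA_ALPHABET, AAINDEX_ORDER)
  rows <- list(); positions <- integer(0)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) < 2L) next
    if (!grepl("^[0-9]+$", toks[1]) || !toks[2] %in% c(AA_ALPHABET, "X", "B", "Z", "U", "O", "J", "*"))
      next
    nums <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (anyNA(nums) || !length(nums) %in% c(40L, 42L))
      stop("line ", i, ": PSSM row must carry 40 numeric fields ",
           "(20 scores + 20 percentages), got ", sum(!is.na(nums)),
           call. = FALSE)
    positions <- c(positions, as.integer(toks[1]))
    rows <- c(rows, list(nums[1:20][reorder]))
  }
  if (length(rows) == 0L)
    stop("no PSSM rows found (empty or malformed body)", call. = FALSE)
  if (!identical(positions, seq_along(positions)))
    stop("non-contiguous PSSM positions (expected 1..",
         length(positions), ")", call. = FALSE)
  pssm(do.call(rbind, rows), accession)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Mainly used to materialize synthetic PSSM fixtures that [parse_pssm()]
#' round-trips. Scores are written in the file-native
#' `ARNDCQEGHILKMFPSTWYV` column order with a zero percentage block.
#'
#' @param x a [pssm()]
#' @param path output path
#' @param seq optional residue column (defaults to `A` everywhere)
#' @export
write_pssm <- function(x, path, seq = NULL) {
  L <- nrow(x$scores)
  res <- if (is.null(seq)) rep("A", L) else strsplit(seq, "", fixed = TRUE)[[1]]
  reorder <- match(AAINDEX_ORDER, AA_ALPHABET)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("            ", paste(AAINDEX_ORDER, collapse = "   "))),
             con)
  for (i in seq_len(L)) {
    writeLines(paste(c(i, res[i], format(x$scores[i, reorder], trim = TRUE),
                       rep("0", 20L)), collapse = " "), con)
  }
  invisible(path)
}

#' Row-standardize a PSSM
#'
#' Each row is standardized over its 20 scores (divisor-20 SD). Constant
#' rows become all-zero rows with a warning. (A sigmoid squashing dialect
#' also circulates for this step; this package uses the z-score form.)
#'
#' @param x a [pssm()]
#' @return a [pssm()] with standardized scores
#' @export
normalize_pssm <- function(x) {
  E <- x$scores
  n_const <- 0L
  for (i in seq_len(nrow(E))) {
    m <- mean(E[i, ]); s <- sqrt(mean((E[i, ] - m)^2))
    if (s == 0) { E[i, ] <- 0; n_const <- n_const + 1L }
    else E[i, ] <- (E[i, ] - m) / s
  }
  if (n_const > 0L)
    warning(n_const, " constant PSSM row(s) set to zero for '",
            x$accession, "'", call. = FALSE)
  pssm(E, x$accession)
}

#' PsePSSM sequential-evolution descriptors
#'
#' From a row-standardized PSSM `E'`: the 20 column means
#' `abar_j = (1/L) * sum_i E'_ij`, followed for each lag `g = 1..xi` by the
#' 20 lagged squared-difference correlations
#' `theta_j(g) = (1/(L-g)) * sum_i (E'_ij - E'_(i+g),j)^2`. Feature order:
#' the 20 means, then lag-major blocks of 20.
#'
#' @param x a [pssm()] (standardize first with [normalize_pssm()]; the
#'   function does not re-standardize)
#' @param xi number of lags, `1 <= xi < L`
#' @return a `(20 + 20*xi)`-feature [descriptor_vector()]
#' @export
psepssm <- function(x, xi = 10L) {
  E <- x$scores
  L <- nrow(E)
  if (xi < 1L) stop("xi must be >= 1", call. = FALSE)
  if (L <= xi)
    stop("PSSM too short: L = ", L, " must exceed xi = ", xi, call. = FALSE)
  means <- colMeans(E)
  theta <- lapply(seq_len(xi), function(g)
    colMeans((E[1:(L - g), , drop = FALSE] - E[(1L + g):L, , drop = FALSE])^2))
  vals <- c(means, unlist(theta))
  names(vals) <- c(paste0("PsePSSM_mean_", AA_ALPHABET),
                   paste0("PsePSSM_g", rep(seq_len(xi), each = 20L), "_",
                          rep(AA_ALPHABET, xi)))
  descriptor_vector("psepssm", vals)
}

#' Load an accession-to-PSSM-path map
#'
#' TSV layout: `accession<TAB>path`; relative paths resolve against the
#' map file's directory.
#'
#' @param path map TSV
#' @return named character vector accession -> absolute path
#' @export
load_pssm_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  base <- dirname(path)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L || !nzchar(f[1]))
      stop("line ", i, ": PSSM map rows are accession<TAB>path", call. = FALSE)
    p <- if (grepl("^(/|[A-Za-z]:)", f[2])) f[2] else file.path(base, f[2])
    out[f[1]] <- p
  }
  out
}
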