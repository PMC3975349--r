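#' Standardize a 20-value amino-acid property
#'
#' Converts raw per-residue property values to zero mean and unit standard
#' deviation over the 20 residues, using the population SD (divisor 20).
#' This is the conversion the correlation-based modes (Type I/II PseAAC,
#' autocorrelation families) apply before use; tools that standardize with
#' divisor 19 will produce slightly different descriptor values.
#'
#' @param raw numeric vector of 20 finite values in canonical residue order
#' @return standardized vector (mean 0, SD 1, divisor 20)
#' @export
normalize_property <- function(raw) {
  if (length(raw) != 20L || !all(is.finite(raw)))
    stop("a property must have exactly 20 finite values", call. = FALSE)
  m <- mean(raw)
  s <- sqrt(mean((raw - m)^2))
  if (s == 0)
    stop("degenerate property: all 20 values equal; cannot standardize",
         call. = FALSE)
  (raw - m) / s
}

#' Build a property table
#'
#' @param raw numeric matrix, one row per property (rownames = property
#'   accessions), 20 columns in canonical residue order
#' @return a `property_table` with `$raw` and `$normalized` matrices.
#'   Constant properties keep their raw row but carry `NaN` in the
#'   normalized matrix; requesting them via [normalized_property()] errors.
#' @export
property_table <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20L) stop("property table must have 20 columns", call. = FALSE)
  if (is.null(rownames(raw)) || anyDuplicated(rownames(raw)))
    stop("property rows must have unique accession rownames", call. = FALSE)
  if (!all(is.finite(raw))) stop("property values must be finite", call. = FALSE)
  colnames(raw) <- AA_ALPHABET
  normalized <- t(apply(raw, 1L, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(NaN, 20L) else (x - mean(x)) / s
  }))
  dimnames(normalized) <- dimnames(raw)
  structure(list(raw = raw, normalized = normalized),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("<property_table>", nrow(x$raw), "properties:",
      paste(utils::head(rownames(x$raw), 5L), collapse = ", "),
      if (nrow(x$raw) > 5L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.property_table <- function(x) nrow(x$raw)

#' Fetch standardized rows of a property table
#'
#' @param ptable a [property_table]
#' @param accessions property accessions to fetch
#' @return matrix (|accessions| x 20) of standardized values
#' @export
normalized_property <- function(ptable, accessions) {
  missing <- setdiff(accessions, rownames(ptable$normalized))
  if (length(missing))
    stop("unknown propert", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- ptable$normalized[accessions, , drop = FALSE]
  if (!all(is.finite(out))) {
    bad <- accessions[!apply(is.finite(out), 1L, all)]
    stop("degenerate propert", if (length(bad) > 1) "ies" else "y",
         " (constant over residues): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Load a physicochemical property table
#'
#' Two dialects are supported. `tsv`: a header line
#' `property<TAB>A<TAB>C...Y` followed by one row per property, values
#' already in canonical alphabetical residue order. `aaindex1`: the AAindex
#' flat-file dialect (`H` accession line, `I` line introducing two rows of
#' ten values in `ARNDCQEGHILKMFPSTWYV` order, entries closed by `//`);
#' values are re-mapped to canonical order on load. Entries containing `NA`
#' values are dropped; the number dropped is recorded in the `n_dropped`
#' attribute and reported with a warning.
#'
#' @param path file path or connection
#' @param format `"tsv"` or `"aaindex1"`
#' @return a [property_table]; row order follows file order after NA drops
#' @export
load_property_table <- function(path, format = c("tsv", "aaindex1")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "tsv") .load_ptable_tsv(lines) else .load_ptable_aaindex(lines)
}

.load_ptable_tsv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty property table", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) != 21L || !identical(header[-1], AA_ALPHABET))
    stop("property TSV header must be: property\\tA\\tC...\\tY ",
         "(canonical residue order)", call. = FALSE)
  acc <- character(0); vals <- list(); dropped <- 0L
  for (ln in lines[-1]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      stop("property '", f[1], "': expected 20 values, got ",
           length(f) - 1L, call. = FALSE)
    v <- suppressWarnings(as.numeric(f[-1]))
    if (any(toupper(f[-1]) == "NA")) { dropped <- dropped + 1L; next }
    if (anyNA(v))
      stop("property '", f[1], "': unparseable value", call. = FALSE)
    acc <- c(acc, f[1]); vals <- c(vals, list(v))
  }
  .finish_ptable(acc, vals, dropped)
}

.load_ptable_aaindex <- function(lines) {
  # AAindex1 flat file: entries delimited by '//'; the I line is followed by
  # two lines of ten values each in ARNDCQEGHILKMFPSTWYV order
  reorder <- match(AA_ALPHABET, AAINDEX_ORDER)
  acc <- character(0); vals <- list(); dropped <- 0L
  cur_acc <- NA_character_; i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "H ")) {
      cur_acc <- trimws(sub("^H ", "", ln))
    } else if (startsWith(ln, "I ")) {
      if (is.na(cur_acc))
        stop("AAindex entry with I line but no H accession", call. = FALSE)
      if (i + 2L > length(lines))
        stop("property '", cur_acc, "': truncated value block", call. = FALSE)
      toks <- unlist(strsplit(trimws(c(lines[[i + 1L]], lines[[i + 2L]])), "\\s+"))
      if (length(toks) != 20L)
        stop("property '", cur_acc, "': expected 20 values, got ",
             length(toks), call. = FALSE)
      if (any(toupper(toks) == "NA")) {
        dropped <- dropped + 1L
      } else {
        v <- suppressWarnings(as.numeric(toks))
        if (anyNA(v))
          stop("property '", cur_acc, "': unparseable value", call. = FALSE)
        acc <- c(acc, cur_acc); vals <- c(vals, list(v[reorder]))
      }
      i <- i + 2L
    } else if (startsWith(ln, "//")) {
      cur_acc <- NA_character_
    }
    i <- i + 1L
  }
  .finish_ptable(acc, vals, dropped)
}

.finish_ptable <- function(acc, vals, dropped) {
  if (length(acc) == 0L)
    stop("no usable property entries found", call. = FALSE)
  if (anyDuplicated(acc))
    stop("duplicate property accession: ",
         acc[duplicated(acc)][1], call. = FALSE)
  raw <- do.call(rbind, vals)
  rownames(raw) <- acc
  if (dropped > 0L)
    warning(dropped, " propert", if (dropped > 1) "ies" else "y",
            " dropped (NA values)", call. = FALSE)
  pt <- property_table(raw)
  attr(pt, "n_dropped") <- dropped
  pt
}

#' The classic three-property table
#'
#' Hydrophobicity, hydrophilicity and side-chain mass - the property triple
#' that the original Type I PseAAC formulation is built on, bundled with the
#' package. Any other AAindex-style table can be substituted via
#' [load_property_table()].
#'
#' @return a [property_table] with rows `hydrophobicity`, `hydrophilicity`,
#'   `mass`
#' @export
chou_classic_table <- function() {
  load_property_table(system.file("extdata", "chou_classic.tsv",
                                  package = "pseaacg"),
                      format = "tsv")
}
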