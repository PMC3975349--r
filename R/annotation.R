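#' Build an annotation map
#'
#' An annotation map carries a deterministic (lexicographically sorted)
#' universe of term identifiers - GO accessions, domain identifiers, or any
#' other descriptive vocabulary - and per-protein term sets. It backs the
#' binary gene-ontology and functional-domain modes.
#'
#' @param assignments named list: accession -> character vector of terms
#' @param universe optional explicit term universe; defaults to the sorted
#'   union of assigned terms. Assigned terms outside an explicit universe
#'   are not scored; their count is kept in the `unknown_terms` field.
#' @return an `annotation_map` with fields `universe`, `assignments`,
#'   `unknown_terms`
#' @export
annotation_map <- function(assignments, universe = NULL) {
  if (length(assignments) > 0L &&
      (is.null(names(assignments)) || !all(nzchar(names(assignments)))))
    stop("assignments must be a named list (accession -> terms)", call. = FALSE)
  assignments <- lapply(assignments, function(x) sort(unique(as.character(x))))
  observed <- sort(unique(unlist(assignments, use.names = FALSE)))
  unknown <- 0L
  if (is.null(universe)) {
    universe <- observed
  } else {
    universe <- sort(unique(as.character(universe)))
    if (anyDuplicated(universe)) stop("duplicate universe terms", call. = FALSE)
    unknown <- sum(!observed %in% universe)
  }
  structure(list(universe = universe, assignments = assignments,
                 unknown_terms = unknown),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("<annotation_map>", length(x$assignments), "proteins,",
      length(x$universe), "terms",
      if (x$unknown_terms > 0) paste0("(", x$unknown_terms, " unknown)"), "\n")
  invisible(x)
}

#' Load an annotation map from TSV
#'
#' Layout: `accession<TAB>term1;term2;...`, one line per protein; repeated
#' accessions merge by set union. An optional universe file (one term per
#' line) fixes the column universe; otherwise the universe is the sorted
#' union of observed terms.
#'
#' @param path annotation TSV path
#' @param universe_path optional universe file
#' @return an [annotation_map()]
#' @export
load_annotation_map <- function(path, universe_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  assignments <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 1L || !nzchar(trimws(f[1])))
      stop("line ", i, ": empty accession field", call. = FALSE)
    acc <- trimws(f[1])
    terms <- if (length(f) >= 2L && nzchar(f[2]))
      strsplit(f[2], ";", fixed = TRUE)[[1]] else character(0)
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    assignments[[acc]] <- union(assignments[[acc]], terms)
  }
  universe <- if (!is.null(universe_path)) readLines(universe_path) else NULL
  if (!is.null(universe)) universe <- trimws(universe[nzchar(trimws(universe))])
  annotation_map(assignments, universe)
}

#' Save an annotation map as TSV
#'
#' @param amap an [annotation_map()]
#' @param path output TSV path
#' @param universe_path optional path to also write the universe file
#' @export
save_annotation_map <- function(amap, path, universe_path = NULL) {
  lines <- vapply(names(amap$assignments), function(acc)
    paste0(acc, "\t", paste(amap$assignments[[acc]], collapse = ";")),
    character(1))
  writeLines(lines, path)
  if (!is.null(universe_path)) writeLines(amap$universe, universe_path)
  invisible(path)
}

#' Binary annotation descriptor
#'
#' Value `j` is 1 iff term `j` of the universe is assigned to the protein.
#' Proteins absent from the map emit the all-zero vector with a warning, so
#' descriptor rows keep FASTA order.
#'
#' @param rec_id protein accession (or a [protein_record])
#' @param amap an [annotation_map()]
#' @param mode feature-name prefix / registry name (`"go"` or `"fdom"`)
#' @return a `|universe|`-feature 0/1 [descriptor_vector()]
#' @export
binary_vector <- function(rec_id, amap, mode = "go") {
  if (inherits(rec_id, "protein_record")) rec_id <- rec_id$id
  if (length(amap$universe) == 0L)
    stop("empty term universe", call. = FALSE)
  terms <- amap$assignments[[rec_id]]
  if (is.null(terms))
    warning("'", rec_id, "' absent from annotation map; all-zero vector",
            call. = FALSE)
  v <- as.numeric(amap$universe %in% terms)
  descriptor_vector(mode, stats::setNames(v, paste0(toupper(mode), "_",
                                                    amap$universe)))
}

# --- compact binary cache (versioned; magic "PSBEM1") --------------------
# Bitset rows over the sorted universe allow fast reload of large maps.

#' Save / load the compact annotation cache
#'
#' A versioned binary serialization of an annotation map (magic bytes
#' `PSBEM1`, term universe, then one bitset row per accession) for fast
#' reload of large universes. The TSV format remains the interchange
#' format; the cache is an optional local artifact.
#'
#' @param amap an [annotation_map()]
#' @param path cache file path
#' @return `load_annotation_cache` returns the reconstructed
#'   [annotation_map()]
#' @export
save_annotation_cache <- function(amap, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PSBEM1"), con)
  writeBin(1L, con, size = 4L, endian = "little")
  wr_str <- function(s) {
    b <- charToRaw(s)
    writeBin(length(b), con, size = 4L, endian = "little")
    writeBin(b, con)
  }
  writeBin(length(amap$universe), con, size = 4L, endian = "little")
  for (t in amap$universe) wr_str(t)
  writeBin(length(amap$assignments), con, size = 4L, endian = "little")
  nbytes <- ceiling(length(amap$universe) / 8)
  for (acc in names(amap$assignments)) {
    wr_str(acc)
    bits <- amap$universe %in% amap$assignments[[acc]]
    writeBin(packBits(c(bits, rep(FALSE, nbytes * 8 - length(bits)))), con)
  }
  invisible(path)
}

#' @rdname save_annotation_cache
#' @export
load_annotation_cache <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L))
  if (!identical(magic, "PSBEM1"))
    stop("not an annotation cache (bad magic bytes)", call. = FALSE)
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != 1L) stop("unsupported cache version ", version, call. = FALSE)
  rd_str <- function() {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rawToChar(readBin(con, "raw", n))
  }
  n_terms <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  universe <- vapply(seq_len(n_terms), function(i) rd_str(), character(1))
  n_acc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  nbytes <- ceiling(n_terms / 8)
  assignments <- vector("list", n_acc)
  accs <- character(n_acc)
  for (i in seq_len(n_acc)) {
    accs[i] <- rd_str()
    bits <- as.logical(rawToBits(readBin(con, "raw", nbytes)))[seq_len(n_terms)]
    assignments[[i]] <- universe[bits]
  }
  names(assignments) <- accs
  annotation_map(assignments, universe)
}
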