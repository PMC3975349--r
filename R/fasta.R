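#' Protein record
#'
#' @param id accession (non-empty)
#' @param seq validated uppercase sequence over the canonical alphabet
#' @param description free-text remainder of the FASTA header
#' @return a `protein_record` list with fields `id`, `description`, `seq`,
#'   `length`
#' @export
protein_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (nchar(seq) < 1L) stop("empty sequence for record '", id, "'", call. = FALSE)
  structure(list(id = id, description = description,
                 seq = seq, length = nchar(seq)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, " L =", x$length, "\n")
  invisible(x)
}

# substitutions applied under policy "map_to_nearest":
# ambiguity codes to their most common / closest canonical residue
.AMBIG_MAP <- c(B = "D", Z = "E", U = "C", O = "K", J = "L")

# Validate one raw sequence under an ambiguity policy.
# Returns the cleaned sequence, or NA_character_ when the record must be
# skipped (a warning is raised at the point of skipping).
.validate_seq <- function(seq, id, policy) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !chars %in% AA_ALPHABET
  if (!any(bad)) return(seq)
  if (policy == "error") {
    stop("record '", id, "': non-canonical residue '",
         chars[which(bad)[1]], "' at position ", which(bad)[1],
         " (policy = error)", call. = FALSE)
  }
  if (policy == "skip_record") {
    warning("record '", id, "' skipped: non-canonical residue '",
            chars[which(bad)[1]], "'", call. = FALSE)
    return(NA_character_)
  }
  # map_to_nearest: resolve ambiguity codes; X is unresolvable -> skip
  mappable <- bad & chars %in% names(.AMBIG_MAP)
  chars[mappable] <- .AMBIG_MAP[chars[mappable]]
  still_bad <- !chars %in% AA_ALPHABET
  if (any(still_bad)) {
    warning("record '", id, "' skipped: unresolvable residue '",
            chars[which(still_bad)[1]], "'", call. = FALSE)
    return(NA_character_)
  }
  paste(chars, collapse = "")
}

#' Stream a FASTA file record by record
#'
#' Applies `fun` to successive chunks of validated [protein_record]s without
#' ever holding more than `chunk_size` records in memory, so arbitrarily
#' large files process in constant memory. This is the primitive behind
#' [read_fasta()] and the batch engine.
#'
#' @param path path to a FASTA file, or a connection
#' @param fun function called as `fun(records)` on each chunk (a list of
#'   [protein_record]s, in file order)
#' @param ambiguous_policy what to do with non-canonical residues:
#'   `"error"` (default) stops; `"skip_record"` drops the record with a
#'   warning; `"map_to_nearest"` substitutes B>D, Z>E, U>C, O>K, J>L and
#'   skips records containing X (with a warning)
#' @param chunk_size records per callback invocation
#' @return invisibly, a list with `records_read` (validated records passed
#'   to `fun`) and `records_skipped`
#' @export
fasta_apply <- function(path, fun,
                        ambiguous_policy = c("error", "skip_record", "map_to_nearest"),
                        chunk_size = 500L) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  con <- if (inherits(path, "connection")) path else file(path, "rt")
  if (!inherits(path, "connection")) on.exit(close(con), add = TRUE)

  n_read <- 0L; n_skip <- 0L
  buf <- vector("list", chunk_size); nbuf <- 0L
  cur_id <- NULL; cur_desc <- ""; cur_seq <- character(); line_no <- 0L

  flush_buf <- function() {
    if (nbuf > 0L) fun(buf[seq_len(nbuf)])
  }
  emit <- function(rec) {
    nbuf <<- nbuf + 1L
    buf[[nbuf]] <<- rec
    if (nbuf == chunk_size) { fun(buf[seq_len(nbuf)]); nbuf <<- 0L }
  }
  finish_record <- function() {
    if (is.null(cur_id)) return(invisible())
    seq <- paste(cur_seq, collapse = "")
    if (!nzchar(seq))
      stop("record '", cur_id, "' has an empty sequence", call. = FALSE)
    cleaned <- .validate_seq(seq, cur_id, ambiguous_policy)
    if (is.na(cleaned)) {
      n_skip <<- n_skip + 1L
    } else {
      n_read <<- n_read + 1L
      emit(protein_record(cur_id, cleaned, cur_desc))
    }
  }

  repeat {
    lines <- readLines(con, n = 4096L)
    if (length(lines) == 0L) break
    for (ln in lines) {
      line_no <- line_no + 1L
      ln <- sub("\r$", "", ln)
      if (!nzchar(trimws(ln))) next
      if (startsWith(ln, ">")) {
        finish_record()
        header <- sub("^>\\s*", "", ln)
        toks <- regmatches(header, regexpr("^\\S+", header))
        if (length(toks) == 0L)
          stop("line ", line_no, ": FASTA header with empty id", call. = FALSE)
        cur_id <- toks
        cur_desc <- trimws(sub("^\\S+\\s*", "", header))
        cur_seq <- character()
      } else {
        if (is.null(cur_id))
          stop("line ", line_no,
               ": sequence data before any '>' header (malformed FASTA)",
               call. = FALSE)
        cur_seq <- c(cur_seq, gsub("\\s", "", ln))
      }
    }
  }
  finish_record()
  flush_buf()
  invisible(list(records_read = n_read, records_skipped = n_skip))
}

#' Read a FASTA file of protein sequences
#'
#' Convenience wrapper over [fasta_apply()] that accumulates all records.
#' For large files prefer [fasta_apply()] or [run_batch()], which stream.
#'
#' @inheritParams fasta_apply
#' @return list of [protein_record]s in file order (after policy skips)
#' @export
read_fasta <- function(path,
                       ambiguous_policy = c("error", "skip_record", "map_to_nearest")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  out <- list()
  fasta_apply(path, function(recs) out <<- c(out, recs),
              ambiguous_policy = ambiguous_policy)
  out
}

#' Write protein records as FASTA
#'
#' @param records list of [protein_record]s
#' @param path output path or connection
#' @param width line-wrap width for sequences
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- if (inherits(path, "connection")) path else file(path, "wt")
  if (!inherits(path, "connection")) on.exit(close(con), add = TRUE)
  for (rec in records) {
    header <- if (nzchar(rec$description))
      paste0(">", rec$id, " ", rec$description) else paste0(">", rec$id)
    writeLines(header, con)
    starts <- seq(1L, rec$length, by = width)
    writeLines(substring(rec$seq, starts, pmin(starts + width - 1L, rec$length)), con)
  }
  invisible(path)
}
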