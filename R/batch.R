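# deterministic float formatting: 12 significant digits, bit-stable
.fmt_num <- function(x) sprintf("%.12g", x)

#' Write a descriptor matrix
#'
#' `csv` / `tsv`: a header row of feature names with `id` first, then one
#' row per protein. `svmlight`: one line per protein with 1-based feature
#' indices, zero features omitted, and the accession carried as a trailing
#' `# id` comment. Floats are written with 12 significant digits, so
#' repeated runs produce byte-identical files.
#'
#' @param ids character vector of accessions
#' @param mat numeric matrix (rows = proteins) with feature colnames
#' @param path output path
#' @param format `"csv"`, `"tsv"` or `"svmlight"`
#' @export
write_output <- function(ids, mat, path, format = c("csv", "tsv", "svmlight")) {
  format <- match.arg(format)
  con <- file(path, "wt")
  on.exit(close(con))
  .write_header(con, colnames(mat), format)
  for (i in seq_len(nrow(mat)))
    .write_row(con, ids[i], mat[i, ], format)
  invisible(path)
}

.write_header <- function(con, feature_names, format) {
  if (format == "svmlight") return(invisible())
  sep <- if (format == "csv") "," else "\t"
  writeLines(paste(c("id", feature_names), collapse = sep), con)
}

.write_row <- function(con, id, values, format) {
  if (format == "svmlight") {
    nz <- which(values != 0)
    writeLines(paste(c("0", paste0(nz, ":", .fmt_num(values[nz])),
                       paste("#", id)), collapse = " "), con)
  } else {
    sep <- if (format == "csv") "," else "\t"
    writeLines(paste(c(id, .fmt_num(values)), collapse = sep), con)
  }
}

#' Read back a csv/tsv descriptor matrix
#'
#' @param path file written by [write_output()] or [run_batch()]
#' @param format `"csv"` or `"tsv"`
#' @return list with `ids` and numeric `matrix`
#' @export
read_output <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = TRUE,
                          sep = if (format == "csv") "," else "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- NULL
  list(ids = as.character(df[[1]]), matrix = mat)
}

#' Assemble a batch-run configuration
#'
#' @param input FASTA path
#' @param mode registered mode name
#' @param output output file path
#' @param params named list of mode parameter overrides
#' @param format output format (`csv`, `tsv`, `svmlight`)
#' @param ambiguous_policy residue policy passed to the FASTA reader
#' @param properties optional property-table path (TSV dialect); default:
#'   the bundled classic table
#' @param property_format `"tsv"` or `"aaindex1"`
#' @param annotations optional annotation TSV (backs `go` / `fdom`)
#' @param universe optional term-universe file
#' @param pssm_map optional accession-to-PSSM-path TSV (backs `psepssm`)
#' @param chunk_size records held in memory at once while streaming
#' @return a `run_config` list
#' @export
run_config <- function(input, mode, output, params = list(),
                       format = c("csv", "tsv", "svmlight"),
                       ambiguous_policy = c("error", "skip_record", "map_to_nearest"),
                       properties = NULL, property_format = "tsv",
                       annotations = NULL, universe = NULL,
                       pssm_map = NULL, chunk_size = 500L) {
  format <- match.arg(format)
  ambiguous_policy <- match.arg(ambiguous_policy)
  for (p in c(input, properties, annotations, universe, pssm_map))
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  structure(list(input = input, mode = mode, output = output,
                 params = params, format = format,
                 ambiguous_policy = ambiguous_policy,
                 properties = properties, property_format = property_format,
                 annotations = annotations, universe = universe,
                 pssm_map = pssm_map, chunk_size = as.integer(chunk_size)),
            class = "run_config")
}

#' Load a batch configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()] exactly.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(y), allowed)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(run_config, y)
}

# build the side-input context a config implies
.build_ctx <- function(config) {
  ctx <- list()
  ctx$ptable <- if (!is.null(config$properties))
    load_property_table(config$properties, config$property_format)
  else chou_classic_table()
  if (!is.null(config$annotations)) {
    amap <- load_annotation_map(config$annotations, config$universe)
    ctx$go_map <- amap
    ctx$fdom_map <- amap
  }
  if (!is.null(config$pssm_map)) {
    pmap <- load_pssm_map(config$pssm_map)
    cache <- new.env(parent = emptyenv())
    ctx$pssm_for <- function(id) {
      if (!exists(id, envir = cache, inherits = FALSE)) {
        if (is.na(pmap[id]))
          stop("no PSSM registered for '", id, "'", call. = FALSE)
        assign(id, parse_pssm(pmap[[id]], accession = id), envir = cache)
      }
      get(id, envir = cache, inherits = FALSE)
    }
  }
  ctx
}

#' Run a batch descriptor job
#'
#' Streams the FASTA input through the requested mode and writes one
#' descriptor row per record, in input order, to the output file. Records
#' are processed in chunks of `chunk_size`, so memory use is independent
#' of the number of sequences. Identical configuration and inputs produce
#' byte-identical output.
#'
#' @param config a [run_config()] (or plain list with the same fields)
#' @param registry mode registry (default: the built-ins)
#' @param chunk_hook optional `function(n_records)` called once per chunk
#'   with the chunk's record count - used by streaming tests and progress
#'   reporting
#' @return a `run_report`: records read/skipped, output dimensionality,
#'   elapsed seconds and the output path
#' @export
run_batch <- function(config, registry = builtin_registry(),
                      chunk_hook = NULL) {
  t0 <- proc.time()[["elapsed"]]
  spec <- get_mode(registry, config$mode)
  ctx <- .build_ctx(config)
  params <- utils::modifyList(spec$defaults, config$params %||% list())
  con <- file(config$output, "wt")
  on.exit(close(con))

  header_written <- FALSE
  n_rows <- 0L
  dim_out <- NA_integer_
  feature_names <- NULL

  counts <- fasta_apply(config$input, function(recs) {
    if (!is.null(chunk_hook)) chunk_hook(length(recs))
    for (rec in recs) {
      v <- compute_descriptor(registry, config$mode, rec, params, ctx)
      if (!header_written) {
        feature_names <<- names(v)
        dim_out <<- length(v)
        .write_header(con, feature_names, config$format)
        header_written <<- TRUE
      } else if (!identical(names(v), feature_names)) {
        stop("mode '", config$mode, "' emitted inconsistent feature names ",
             "at record '", rec$id, "'", call. = FALSE)
      }
      .write_row(con, rec$id, as.numeric(v), config$format)
      n_rows <<- n_rows + 1L
    }
  }, ambiguous_policy = config$ambiguous_policy,
     chunk_size = config$chunk_size)

  if (!header_written && config$format != "svmlight") {
    # empty input: emit a header from the mode's declared dimensionality
    .write_header(con, paste0(config$mode, "_", seq_len(
      max(0L, spec$dim(params, ctx)))), config$format)
  }

  structure(list(records_read = counts$records_read,
                 records_skipped = counts$records_skipped,
                 rows_written = n_rows,
                 dim = dim_out,
                 output = config$output,
                 format = config$format,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n",
      " records read:    ", x$records_read, "\n",
      " records skipped: ", x$records_skipped, "\n",
      " rows written:    ", x$rows_written, "\n",
      " dimensionality:  ", x$dim, "\n",
      " output:          ", x$output, " (", x$format, ")\n",
      " elapsed:         ", sprintf("%.2f s", x$elapsed), "\n", sep = "")
  invisible(x)
}
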