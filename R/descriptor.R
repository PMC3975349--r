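#' Construct a descriptor vector
#'
#' A descriptor vector is the unit every mode emits for one protein: an
#' ordered, named, finite numeric vector tagged with the mode that produced
#' it. Feature order is deterministic for a given mode and parameter set.
#'
#' @param mode name of the producing mode
#' @param values named numeric vector of features
#' @return a numeric vector of class `pseaac_descriptor` with a `mode`
#'   attribute
#' @export
descriptor_vector <- function(mode, values) {
  stopifnot(is.character(mode), length(mode) == 1L, nzchar(mode))
  if (is.null(names(values)) || anyNA(names(values)) || !all(nzchar(names(values))))
    stop("descriptor values must all be named", call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite value in descriptor for mode '", mode, "'", call. = FALSE)
  out <- as.numeric(values)
  names(out) <- names(values)
  structure(out, mode = mode, class = "pseaac_descriptor")
}

#' @export
print.pseaac_descriptor <- function(x, ...) {
  cat("<pseaac_descriptor> mode:", attr(x, "mode"),
      "features:", length(x), "\n")
  n <- min(6L, length(x))
  print(stats::setNames(as.numeric(x[seq_len(n)]), names(x)[seq_len(n)]))
  if (length(x) > n) cat("... and", length(x) - n, "more\n")
  invisible(x)
}

#' @export
mode_of <- function(x) attr(x, "mode")
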