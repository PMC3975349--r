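# per-position standardized property values for one sequence
.prop_profile <- function(rec, ptable, property) {
  p <- normalized_property(ptable, property)[1L, ]
  p[aa_indices(rec$seq)]
}

.check_lag <- function(L, d) {
  if (d < 1L) stop("lag must be >= 1", call. = FALSE)
  if (d >= L)
    stop("lag d = ", d, " must be smaller than sequence length L = ", L,
         call. = FALSE)
}

#' Normalized Moreau-Broto autocorrelation
#'
#' `AC(d) = (1/(L-d)) * sum_i P_i * P_(i+d)` where `P` is the standardized
#' (divisor-20 SD) property profile along the sequence.
#'
#' @param rec a [protein_record]
#' @param ptable a [property_table]
#' @param property a single property accession
#' @param d lag, `1 <= d < L`
#' @return a scalar
#' @export
moreau_broto <- function(rec, ptable, property, d) {
  .check_lag(rec$length, d)
  p <- .prop_profile(rec, ptable, property)
  L <- rec$length
  mean(p[1:(L - d)] * p[(1L + d):L])
}

#' Moran autocorrelation
#'
#' `I(d) = [(1/(L-d)) * sum (P_i - Pbar)(P_(i+d) - Pbar)] /
#'         [(1/L) * sum (P_i - Pbar)^2]`
#' with `Pbar` the mean property value over all `L` positions. A sequence
#' whose property profile has zero variance yields 0 with a warning (the
#' statistic is undefined there; 0 keeps batch matrices finite).
#'
#' @inheritParams moreau_broto
#' @return a scalar
#' @export
moran <- function(rec, ptable, property, d) {
  .check_lag(rec$length, d)
  p <- .prop_profile(rec, ptable, property)
  L <- rec$length
  pbar <- mean(p)
  denom <- mean((p - pbar)^2)
  if (denom == 0) {
    warning("zero property variance along '", rec$id,
            "'; Moran I(", d, ") reported as 0", call. = FALSE)
    return(0)
  }
  mean((p[1:(L - d)] - pbar) * (p[(1L + d):L] - pbar)) / denom
}

#' Geary autocorrelation
#'
#' `C(d) = [(1/(2(L-d))) * sum (P_i - P_(i+d))^2] /
#'         [(1/(L-1)) * sum (P_i - Pbar)^2]`.
#' Zero-variance profiles yield 0 with a warning, as for [moran()].
#'
#' @inheritParams moreau_broto
#' @return a scalar
#' @export
geary <- function(rec, ptable, property, d) {
  .check_lag(rec$length, d)
  p <- .prop_profile(rec, ptable, property)
  L <- rec$length
  pbar <- mean(p)
  denom <- sum((p - pbar)^2) / (L - 1L)
  if (denom == 0) {
    warning("zero property variance along '", rec$id,
            "'; Geary C(", d, ") reported as 0", call. = FALSE)
    return(0)
  }
  (sum((p[1:(L - d)] - p[(1L + d):L])^2) / (2 * (L - d))) / denom
}

#' Autocorrelation descriptor vector
#'
#' One value per (property, lag) pair for a single family, property-major
#' then by lag: `<FAMILY>_<prop>_d1 .. _d<max_lag>` for each property in
#' turn.
#'
#' @param rec a [protein_record] with `L > max_lag`
#' @param ptable a [property_table]
#' @param properties one or more property accessions
#' @param max_lag largest lag `D`
#' @param family `"nmbroto"`, `"moran"` or `"geary"`
#' @return a `(|properties| * max_lag)`-feature [descriptor_vector()]
#' @export
autocorr_vector <- function(rec, ptable, properties = rownames(ptable$raw),
                            max_lag = 30L,
                            family = c("nmbroto", "moran", "geary")) {
  family <- match.arg(family)
  if (length(properties) < 1L)
    stop("at least one property required", call. = FALSE)
  .check_lag(rec$length, max_lag)
  fn <- switch(family, nmbroto = moreau_broto, moran = moran, geary = geary)
  vals <- unlist(lapply(properties, function(pr) {
    vapply(seq_len(max_lag), function(d) fn(rec, ptable, pr, d), numeric(1))
  }))
  nm <- as.vector(t(outer(properties, seq_len(max_lag),
                          function(p, d) paste0(toupper(family), "_", p, "_d", d))))
  descriptor_vector(family, stats::setNames(vals, nm))
}
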