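#' Physicochemical correlation between two residues
#'
#' The Type I PseAAC coupling function: the mean squared difference of the
#' standardized property values,
#' `Theta(a, b) = (1/k) * sum_p (P_p(b) - P_p(a))^2`
#' over the `k` selected properties. Symmetric, non-negative, and zero for
#' identical residues.
#'
#' @param a,b single canonical residues
#' @param props matrix of standardized property rows
#'   (see [normalized_property()])
#' @return a scalar
#' @export
correlation_theta <- function(a, b, props) {
  if (nrow(props) < 1L) stop("at least one property required", call. = FALSE)
  ia <- aa_indices(a); ib <- aa_indices(b)
  mean((props[, ib, drop = TRUE] - props[, ia, drop = TRUE])^2)
}

# full 20x20 Theta lookup for a property set
.theta_matrix <- function(props) {
  k <- nrow(props)
  acc <- matrix(0, 20L, 20L)
  for (p in seq_len(k)) {
    r <- props[p, ]
    acc <- acc + outer(r, r, function(x, y) (y - x)^2)
  }
  acc / k
}

.check_lambda <- function(L, lam, what = "lambda") {
  if (lam < 1L) stop(what, " must be >= 1", call. = FALSE)
  if (L <= lam)
    stop("sequence too short: L = ", L, " must exceed ", what, " = ", lam,
         call. = FALSE)
}

#' Type I (parallel-correlation) pseudo-amino-acid composition
#'
#' Augments the 20 residue frequencies with `lambda` sequence-order
#' correlation factors
#' `tau_j = (1/(L-j)) * sum_i Theta(R_i, R_(i+j))`, `j = 1..lambda`,
#' where `Theta` averages squared standardized-property differences over the
#' selected properties (default: the classic hydrophobicity /
#' hydrophilicity / side-chain-mass triple). Components:
#' `x_u = f_u / (1 + w * sum(tau))` for the 20 frequencies and
#' `x_(20+j) = w * tau_j / (1 + w * sum(tau))`. All components are
#' non-negative and sum to one.
#'
#' @param rec a [protein_record] with `L > lambda`
#' @param lambda number of correlation tiers
#' @param w weight balancing composition against correlation terms
#' @param ptable a [property_table]
#' @param properties property accessions to use (one or more)
#' @return a `(20 + lambda)`-feature [descriptor_vector()]
#' @export
type1_pseaac <- function(rec, lambda = 30L, w = 0.05,
                         ptable = chou_classic_table(),
                         properties = rownames(ptable$raw)[1:3]) {
  stopifnot(w > 0)
  .check_lambda(rec$length, lambda)
  props <- normalized_property(ptable, properties)
  theta <- .theta_matrix(props)
  idx <- aa_indices(rec$seq)
  L <- rec$length
  tau <- vapply(seq_len(lambda), function(j) {
    mean(theta[cbind(idx[1:(L - j)], idx[(1L + j):L])])
  }, numeric(1))
  f <- tabulate(idx, nbins = 20L) / L
  denom <- 1 + w * sum(tau)
  vals <- c(f, w * tau) / denom
  names(vals) <- c(paste0("PseAAC1_", AA_ALPHABET),
                   paste0("PseAAC1_lam", seq_len(lambda)))
  descriptor_vector("pseaac1", vals)
}

#' Type II (amphiphilic, series-correlation) pseudo-amino-acid composition
#'
#' Uses exactly two standardized properties - by convention hydrophobicity
#' and hydrophilicity - and interleaves their lagged correlation factors:
#' `tau_(2j-1) = (1/(L-j)) * sum_i H1(R_i) * H1(R_(i+j))` and likewise
#' `tau_(2j)` for H2. Components are `x_u = f_u / (1 + w * sum(tau))` and
#' `x_(20+k) = w * tau_k / (1 + w * sum(tau))`. Unlike Type I the `tau`
#' here may be negative; a non-positive denominator is a degenerate
#' normalization and raises an error reporting the tau sum.
#'
#' @param rec a [protein_record] with `L > lambda`
#' @param lambda number of correlation tiers
#' @param w weight factor
#' @param ptable a [property_table]
#' @param properties exactly two property accessions (hydrophobicity,
#'   hydrophilicity by default)
#' @return a `(20 + 2*lambda)`-feature [descriptor_vector()]
#' @export
type2_pseaac <- function(rec, lambda = 30L, w = 0.05,
                         ptable = chou_classic_table(),
                         properties = c("hydrophobicity", "hydrophilicity")) {
  stopifnot(w > 0)
  if (length(properties) != 2L)
    stop("Type II PseAAC uses exactly two properties", call. = FALSE)
  .check_lambda(rec$length, lambda)
  props <- normalized_property(ptable, properties)
  idx <- aa_indices(rec$seq)
  L <- rec$length
  h1 <- props[1L, idx]; h2 <- props[2L, idx]
  tau <- numeric(2L * lambda)
  for (j in seq_len(lambda)) {
    tau[2L * j - 1L] <- mean(h1[1:(L - j)] * h1[(1L + j):L])
    tau[2L * j]      <- mean(h2[1:(L - j)] * h2[(1L + j):L])
  }
  denom <- 1 + w * sum(tau)
  if (denom <= 0)
    stop("degenerate normalization in Type II PseAAC: 1 + w * sum(tau) = ",
         format(denom), " (sum(tau) = ", format(sum(tau)), ")", call. = FALSE)
  f <- tabulate(idx, nbins = 20L) / L
  vals <- c(f, w * tau) / denom
  names(vals) <- c(paste0("PseAAC2_", AA_ALPHABET),
                   paste0("PseAAC2_tau", seq_len(2L * lambda)))
  descriptor_vector("pseaac2", vals)
}
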