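#' Size of the descriptor space
#'
#' Sums the output dimensionality of every built-in mode at its default
#' parameters, given a property table of `property_count` entries: the
#' composition modes (20 + 400 + 8000), Type I/II PseAAC (`20 + lambda`,
#' `20 + 2*lambda`), the three autocorrelation families
#' (`3 * property_count * max_lag` - the dominant term for large tables),
#' CTD (21 per grouping), QSO (`20 + max_lag` per distance matrix),
#' PsePSSM (`20 + 20*xi`), and the annotation modes (one feature per
#' universe term). With a full 544-property table and defaults the space
#' exceeds 20,000 descriptor values.
#'
#' @param property_count number of properties in the table
#' @param lambda Type I/II correlation tiers
#' @param max_lag autocorrelation and QSO lag depth
#' @param xi PsePSSM lag depth
#' @param n_groupings CTD groupings (7 bundled)
#' @param n_matrices QSO distance matrices (2 bundled)
#' @param go_universe,fdom_universe annotation universe sizes (0 when no
#'   map is loaded)
#' @return total descriptor count (integer) with a `breakdown` attribute
#'   giving the per-mode dimensionalities
#' @export
enumerate_descriptor_space <- function(property_count,
                                       lambda = 30L, max_lag = 30L,
                                       xi = 10L, n_groupings = 7L,
                                       n_matrices = 2L,
                                       go_universe = 0L, fdom_universe = 0L) {
  reg <- builtin_registry()
  ctx <- list(n_properties = as.integer(property_count),
              go_map = list(universe = character(go_universe)),
              fdom_map = list(universe = character(fdom_universe)),
              groupings = vector("list", n_groupings),
              matrices = vector("list", n_matrices))
  overrides <- list(pseaac1 = list(lambda = lambda),
                    pseaac2 = list(lambda = lambda),
                    nmbroto = list(max_lag = max_lag),
                    moran = list(max_lag = max_lag),
                    geary = list(max_lag = max_lag),
                    qso = list(max_lag = max_lag),
                    psepssm = list(xi = xi))
  breakdown <- vapply(list_modes(reg), function(m) {
    spec <- get_mode(reg, m)
    p <- utils::modifyList(spec$defaults, overrides[[m]] %||% list())
    as.integer(spec$dim(p, ctx))
  }, integer(1))
  structure(sum(breakdown), breakdown = breakdown)
}
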