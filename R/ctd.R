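#' Define a 3-class property grouping
#'
#' A grouping partitions the 20 residues into three disjoint, non-empty
#' classes of a physicochemical attribute (e.g. polar / neutral /
#' hydrophobic). The package bundles the seven standard attribute
#' groupings used by composition-transition-distribution descriptors; see
#' [ctd_groupings()].
#'
#' @param name attribute label
#' @param g1,g2,g3 strings of residues forming each class
#' @return a `ctd_grouping`
#' @export
ctd_grouping <- function(name, g1, g2, g3) {
  cls <- lapply(list(g1, g2, g3), function(s) strsplit(s, "", fixed = TRUE)[[1]])
  all_aa <- sort(unlist(cls))
  if (!identical(all_aa, sort(AA_ALPHABET)))
    stop("grouping '", name, "' must partition the 20 residues into ",
         "3 disjoint classes", call. = FALSE)
  if (any(lengths(cls) == 0L))
    stop("grouping '", name, "': empty class", call. = FALSE)
  # residue -> class 1..3
  cmap <- integer(20L)
  for (k in 1:3) cmap[match(cls[[k]], AA_ALPHABET)] <- k
  structure(list(name = name, classes = cls, class_of = cmap),
            class = "ctd_grouping")
}

#' Bundled CTD attribute groupings
#'
#' The seven standard 3-class groupings (hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary structure,
#' solvent accessibility), loaded from the package fixture file. Custom
#' groupings in the same TSV layout
#' (`attribute<TAB>g1<TAB>g2<TAB>g3`) load via [load_groupings()].
#'
#' @return named list of seven [ctd_grouping()]s
#' @export
ctd_groupings <- function() {
  load_groupings(system.file("extdata", "ctd_groupings.tsv",
                             package = "pseaacg"))
}

#' @rdname ctd_groupings
#' @param path path to a grouping TSV
#' @export
load_groupings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(colnames(df), c("attribute", "g1", "g2", "g3")))
    stop("grouping file header must be: attribute\\tg1\\tg2\\tg3", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    ctd_grouping(df$attribute[i], df$g1[i], df$g2[i], df$g3[i]))
  stats::setNames(out, df$attribute)
}

#' CTD composition
#'
#' Percentage of residues in each class: `C_k = 100 * n_k / L`. The three
#' values sum to 100.
#'
#' @param rec a [protein_record]
#' @param grouping a [ctd_grouping()]
#' @return numeric vector of 3 percentages
#' @export
ctd_composition <- function(rec, grouping) {
  cls <- grouping$class_of[aa_indices(rec$seq)]
  100 * tabulate(cls, nbins = 3L) / rec$length
}

#' CTD transition
#'
#' Percentage of adjacent residue pairs crossing between two classes, in
#' either direction, per unordered class pair (1,2), (1,3), (2,3):
#' `T_kl = 100 * n_kl / (L - 1)`.
#'
#' @param rec a [protein_record] with `L >= 2`
#' @param grouping a [ctd_grouping()]
#' @return numeric vector of 3 percentages (order: 1-2, 1-3, 2-3)
#' @export
ctd_transition <- function(rec, grouping) {
  L <- rec$length
  if (L < 2L)
    stop("CTD transition needs L >= 2 (got L = ", L, ")", call. = FALSE)
  cls <- grouping$class_of[aa_indices(rec$seq)]
  a <- pmin(cls[-L], cls[-1L]); b <- pmax(cls[-L], cls[-1L])
  c(sum(a == 1L & b == 2L), sum(a == 1L & b == 3L), sum(a == 2L & b == 3L)) *
    100 / (L - 1L)
}

#' CTD distribution
#'
#' For each class, the 1-based positions of its first, 25%, 50%, 75% and
#' last occurrence (occurrence index `ceiling(q * n_k)`, with the first
#' occurrence for `q -> 0`), each scaled to `100 * position / L`. Classes
#' absent from the sequence emit five zeros.
#'
#' @param rec a [protein_record]
#' @param grouping a [ctd_grouping()]
#' @return numeric vector of 15 values (class-major; fractions first, p25,
#'   p50, p75, p100 within each class)
#' @export
ctd_distribution <- function(rec, grouping) {
  cls <- grouping$class_of[aa_indices(rec$seq)]
  L <- rec$length
  unlist(lapply(1:3, function(k) {
    pos <- which(cls == k)
    n <- length(pos)
    if (n == 0L) return(rep(0, 5L))
    at <- c(1L, ceiling(c(0.25, 0.5, 0.75) * n), n)
    100 * pos[at] / L
  }))
}

#' CTD descriptor vector
#'
#' Concatenates composition (3), transition (3) and distribution (15)
#' values per grouping: 21 features per grouping, 147 with the seven
#' bundled groupings. Values are percentages (the `[0,100]` dialect); some
#' other tools emit the same quantities on `[0,1]`.
#'
#' @param rec a [protein_record] with `L >= 2`
#' @param groupings list of [ctd_grouping()]s (default: the bundled seven)
#' @return a `(21 * |groupings|)`-feature [descriptor_vector()]
#' @export
ctd_vector <- function(rec, groupings = ctd_groupings()) {
  if (length(groupings) < 1L)
    stop("at least one grouping required", call. = FALSE)
  parts <- lapply(groupings, function(g) {
    v <- c(ctd_composition(rec, g), ctd_transition(rec, g),
           ctd_distribution(rec, g))
    names(v) <- paste0("CTD_", g$name, "_",
                       c(paste0("C", 1:3),
                         c("T12", "T13", "T23"),
                         paste0("D", rep(1:3, each = 5L), "_",
                                rep(c("first", "p25", "p50", "p75", "p100"), 3L))))
    v
  })
  descriptor_vector("ctd", unlist(unname(parts)))
}
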