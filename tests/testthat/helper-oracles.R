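# Independent brute-force evaluators. Every function here is a direct,
# loop-based transliteration of the defining formulas, written separately
# from the package implementations so the two can disagree.

ALPHA <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

chars_of <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

rand_seq <- function(L, letters = ALPHA) {
  paste(sample(letters, L, replace = TRUE), collapse = "")
}

# standardize a 20-vector with divisor-20 SD (one-liner, no shared code)
oracle_standardize <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)

# props: matrix k x 20 of standardized values, columns named by residue
oracle_theta <- function(a, b, props) {
  total <- 0
  for (p in seq_len(nrow(props))) {
    total <- total + (props[p, b] - props[p, a])^2
  }
  total / nrow(props)
}

oracle_type1 <- function(seq, lambda, w, props) {
  ch <- chars_of(seq); L <- length(ch)
  tau <- numeric(lambda)
  for (j in seq_len(lambda)) {
    s <- 0
    for (i in seq_len(L - j)) s <- s + oracle_theta(ch[i], ch[i + j], props)
    tau[j] <- s / (L - j)
  }
  f <- sapply(ALPHA, function(a) sum(ch == a) / L)
  denom <- sum(f) + w * sum(tau)
  unname(c(f / denom, w * tau / denom))
}

oracle_type2 <- function(seq, lambda, w, props) {
  ch <- chars_of(seq); L <- length(ch)
  tau <- numeric(2 * lambda)
  for (j in seq_len(lambda)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(L - j)) {
      s1 <- s1 + props[1, ch[i]] * props[1, ch[i + j]]
      s2 <- s2 + props[2, ch[i]] * props[2, ch[i + j]]
    }
    tau[2 * j - 1] <- s1 / (L - j)
    tau[2 * j]     <- s2 / (L - j)
  }
  f <- sapply(ALPHA, function(a) sum(ch == a) / L)
  denom <- 1 + w * sum(tau)
  unname(c(f / denom, w * tau / denom))
}

# p: per-position property values
oracle_moreau <- function(p, d) {
  L <- length(p); s <- 0
  for (i in seq_len(L - d)) s <- s + p[i] * p[i + d]
  s / (L - d)
}

oracle_moran <- function(p, d) {
  L <- length(p); pbar <- mean(p)
  num <- 0
  for (i in seq_len(L - d)) num <- num + (p[i] - pbar) * (p[i + d] - pbar)
  num <- num / (L - d)
  den <- sum((p - pbar)^2) / L
  num / den
}

oracle_geary <- function(p, d) {
  L <- length(p); pbar <- mean(p)
  num <- 0
  for (i in seq_len(L - d)) num <- num + (p[i] - p[i + d])^2
  num <- num / (2 * (L - d))
  den <- sum((p - pbar)^2) / (L - 1)
  num / den
}

# grouping given as list of three residue-character vectors
oracle_ctd_C <- function(seq, groups) {
  ch <- chars_of(seq)
  unname(sapply(groups, function(g) 100 * sum(ch %in% g) / length(ch)))
}

oracle_ctd_T <- function(seq, groups) {
  ch <- chars_of(seq); L <- length(ch)
  cls <- sapply(ch, function(a) which(sapply(groups, function(g) a %in% g)))
  n12 <- 0; n13 <- 0; n23 <- 0
  for (i in seq_len(L - 1)) {
    pr <- sort(c(cls[i], cls[i + 1]))
    if (pr[1] == 1 && pr[2] == 2) n12 <- n12 + 1
    if (pr[1] == 1 && pr[2] == 3) n13 <- n13 + 1
    if (pr[1] == 2 && pr[2] == 3) n23 <- n23 + 1
  }
  100 * c(n12, n13, n23) / (L - 1)
}

oracle_ctd_D <- function(seq, groups) {
  ch <- chars_of(seq); L <- length(ch)
  out <- c()
  for (g in groups) {
    pos <- which(ch %in% g); n <- length(pos)
    if (n == 0) { out <- c(out, rep(0, 5)); next }
    picks <- c(1, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)
    out <- c(out, 100 * pos[picks] / L)
  }
  out
}

# dmat: 20x20 with residue dimnames
oracle_coupling <- function(seq, dmat, d) {
  ch <- chars_of(seq); L <- length(ch); s <- 0
  for (i in seq_len(L - d)) s <- s + dmat[ch[i], ch[i + d]]^2
  s
}

oracle_qso <- function(seq, dmat, D, w) {
  ch <- chars_of(seq); L <- length(ch)
  tau <- sapply(seq_len(D), function(d) oracle_coupling(seq, dmat, d))
  f <- sapply(ALPHA, function(a) sum(ch == a) / L)
  denom <- sum(f) + w * sum(tau)
  unname(c(f / denom, w * tau / denom))
}

# E: L x 20 already row-standardized
oracle_psepssm <- function(E, xi) {
  L <- nrow(E)
  means <- numeric(20)
  for (j in 1:20) means[j] <- sum(E[, j]) / L
  out <- means
  for (g in seq_len(xi)) {
    th <- numeric(20)
    for (j in 1:20) {
      s <- 0
      for (i in seq_len(L - g)) s <- s + (E[i, j] - E[i + g, j])^2
      th[j] <- s / (L - g)
    }
    out <- c(out, th)
  }
  out
}

# convenience: standardized classic property rows with residue colnames
classic_props <- function(which = c("hydrophobicity", "hydrophilicity", "mass")) {
  pt <- chou_classic_table()
  m <- pt$normalized[which, , drop = FALSE]
  colnames(m) <- ALPHA
  m
}

make_rec <- function(seq, id = "t") protein_record(id, seq)
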