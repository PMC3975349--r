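test_that("correlation theta is zero on the diagonal, symmetric, and exact", {
  props <- classic_props()
  for (a in c("A", "L", "W")) {
    expect_equal(correlation_theta(a, a, props), 0)
  }
  expect_equal(correlation_theta("A", "C", props),
               correlation_theta("C", "A", props))
  one <- matrix(c(1, -1, rep(0, 18)), nrow = 1,
                dimnames = list("x", ALPHA))
  expect_equal(correlation_theta("A", "C", one), 4)
  expect_equal(correlation_theta("A", "C", props),
               oracle_theta("A", "C", props), tolerance = 1e-12)
})

test_that("Type I PseAAC reduces to aac on homopolymers and sums to one", {
  rec <- make_rec(strrep("A", 50))
  v <- type1_pseaac(rec, lambda = 5)
  expect_equal(unname(v[["PseAAC1_A"]]), 1)
  expect_equal(sum(abs(as.numeric(v)[-1])), 0)
  set.seed(8)
  v2 <- type1_pseaac(make_rec(rand_seq(80)), lambda = 10)
  expect_equal(sum(v2), 1, tolerance = 1e-12)
  expect_true(all(v2 >= 0))
  expect_length(v2, 30L)
  expect_error(type1_pseaac(make_rec("ACDE"), lambda = 4), "exceed")
})

test_that("Type I PseAAC matches the brute-force oracle", {
  props <- classic_props()
  v <- type1_pseaac(make_rec("ACDEFGHIKL"), lambda = 2, w = 0.05)
  expect_equal(as.numeric(v), oracle_type1("ACDEFGHIKL", 2, 0.05, props),
               tolerance = 1e-12)
  # all sequences of length <= 8 over a 3-letter sub-alphabet
  set.seed(9)
  for (L in 3:8) {
    for (rep in 1:8) {
      seq <- rand_seq(L, letters = c("A", "G", "W"))
      lam <- sample(seq_len(L - 1), 1)
      w <- runif(1, 0.01, 0.9)
      expect_equal(as.numeric(type1_pseaac(make_rec(seq), lam, w)),
                   oracle_type1(seq, lam, w, props), tolerance = 1e-12)
    }
  }
})

test_that("Type II PseAAC matches the oracle and has 20 + 2*lambda features", {
  props <- classic_props(c("hydrophobicity", "hydrophilicity"))
  v <- type2_pseaac(make_rec("ACDEFGHIKL"), lambda = 2, w = 0.05)
  expect_equal(as.numeric(v), oracle_type2("ACDEFGHIKL", 2, 0.05, props),
               tolerance = 1e-12)
  expect_length(type2_pseaac(make_rec(rand_seq(30)), lambda = 4), 28L)
  set.seed(10)
  for (rep in 1:20) {
    seq <- rand_seq(sample(5:40, 1))
    lam <- sample(1:4, 1)
    expect_equal(as.numeric(type2_pseaac(make_rec(seq), lam, 0.1)),
                 oracle_type2(seq, lam, 0.1, props), tolerance = 1e-12)
  }
})

test_that("Type II reduces to aac when both property profiles are zero", {
  # property standardized values are 0 for residue A by construction:
  # give A the mean value of an otherwise symmetric pattern
  raw <- rbind(h1 = c(0, rep(c(1, -1), 9), 0),
               h2 = c(0, rep(c(2, -2), 9), 0))
  pt <- property_table(raw)
  expect_equal(unname(pt$normalized["h1", "A"]), 0)
  rec <- make_rec(strrep("A", 40))
  v <- type2_pseaac(rec, lambda = 3, ptable = pt, properties = c("h1", "h2"))
  expect_equal(unname(v[["PseAAC2_A"]]), 1, tolerance = 1e-12)
  expect_equal(sum(abs(as.numeric(v)[-1])), 0, tolerance = 1e-12)
})

test_that("Type II degenerate normalization is caught", {
  # anti-correlated profile with a large weight drives the denominator <= 0
  raw <- rbind(h1 = c(rep(c(10, -10), 10)), h2 = rep(c(1, -1), 10))
  pt <- property_table(raw)
  rec <- make_rec(strrep("AC", 30))  # alternating A/C
  expect_error(
    type2_pseaac(rec, lambda = 1, w = 50, ptable = pt,
                 properties = c("h1", "h2")),
    "degenerate normalization")
})

test_that("both PseAAC types converge to aac as w -> 0", {
  set.seed(11)
  for (rep in 1:5) {
    seq <- rand_seq(sample(40:120, 1))
    rec <- make_rec(seq)
    base <- as.numeric(aac(rec))
    t1 <- as.numeric(type1_pseaac(rec, lambda = 5, w = 1e-12))
    t2 <- as.numeric(type2_pseaac(rec, lambda = 5, w = 1e-12))
    expect_lt(max(abs(t1[1:20] - base)), 1e-9)
    expect_lt(max(abs(t1[21:25])), 1e-9)
    expect_lt(max(abs(t2[1:20] - base)), 1e-9)
    expect_lt(max(abs(t2[21:30])), 1e-9)
  }
})

test_that("tier means are lag-independent on i.i.d. sequences", {
  # for i.i.d. residues E[tau_j] does not depend on j; check the empirical
  # tier means across j agree within 3 standard errors
  set.seed(12)
  lambda <- 5L
  taus <- matrix(NA_real_, nrow = 200L, ncol = lambda)
  for (r in 1:200) {
    v <- type1_pseaac(make_rec(rand_seq(100)), lambda = lambda, w = 1)
    # recover tau (up to the common denominator) from the tail components
    tail_part <- as.numeric(v)[21:(20 + lambda)]
    taus[r, ] <- tail_part / sum(tail_part)
  }
  m <- colMeans(taus)
  se <- apply(taus, 2, stats::sd) / sqrt(nrow(taus))
  grand <- mean(m)
  expect_true(all(abs(m - grand) < 3 * se))
})
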