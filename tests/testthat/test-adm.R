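test_that("sequence probability follows the chain product", {
  a <- uniform_adm(5)
  expect_equal(seq_probability(a, "ACGTA"), 4^-5)

  # two-factor product: init(A) * P(C | A at h = 2)
  tr <- array(0.25, c(4, 4, 2))
  tr[1, , 2] <- c(0.4, 0.3, 0.2, 0.1)
  b <- adm(c(0.5, 0.2, 0.2, 0.1), tr)
  expect_equal(seq_probability(b, "AC"), 0.5 * 0.3)

  expect_error(seq_probability(a, "ACG"), "length")
  expect_error(seq_probability(a, "ACGTN"), "A,C,G,T")
})

test_that("probabilities of all sequences sum to one", {
  for (l in 2:5) {
    a <- random_adm(l, seed = l)
    g <- enum_grid(l)
    expect_equal(sum(seq_probability(a, g$seqs)), 1, tolerance = 1e-9)
  }
})

test_that("consensus equals the exhaustive argmax", {
  # deterministic single-path chain
  expect_equal(consensus(profile_adm(c("T", "A", "A", "T"), p = 1)), "TAAT")

  set.seed(42)
  for (rep in 1:100) {
    l <- sample(2:6, 1)
    a <- random_adm(l)
    g <- enum_grid(l)
    pr <- enum_probs(a$init, a$trans, g)
    best <- g$seqs[pr > max(pr) - 1e-12]
    expect_true(consensus(a) %in% best)
  }

  # ties resolve to the alphabetically smaller sequence
  tr <- array(0, c(4, 4, 2))
  for (h in 1:2) tr[, , h] <- matrix(c(0.4, 0.4, 0.1, 0.1), 4, 4, byrow = TRUE)
  expect_equal(consensus(adm(c(0.4, 0.4, 0.1, 0.1), tr)), "AA")
})

test_that("reverse complement reproduces revcomp probabilities exactly", {
  a <- random_adm(5, seed = 9)
  r <- reverse_complement_adm(a)
  g <- enum_grid(5)
  expect_equal(seq_probability(r, g$seqs), seq_probability(a, revcomp(g$seqs)),
               tolerance = 1e-12)
  # involution
  rr <- reverse_complement_adm(r)
  expect_equal(as_dinuc_matrix(rr), as_dinuc_matrix(a), tolerance = 1e-9)
})

test_that("reverse complement of a PPM-degenerate ADM reverses its columns", {
  a <- seed_to_adm("CYGA")
  r <- reverse_complement_adm(a)
  m <- marginals(a)
  mr <- marginals(r)
  expect_equal(mr, m[4:1, 4:1], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-marginal predecessors get a uniform row with a warning", {
  a <- profile_adm(c("A", "C", "G"), p = 1)
  expect_warning(r <- reverse_complement_adm(a), "zero-marginal")
  expect_valid_adm(r)
  expect_equal(consensus(r), "CGT")
})

test_that("marginals propagate the chain", {
  expect_true(all(abs(marginals(uniform_adm(4)) - 0.25) < 1e-12))

  a <- random_adm(3, seed = 5)
  g <- enum_grid(3)
  pr <- enum_probs(a$init, a$trans, g)
  m3 <- vapply(1:4, function(b) sum(pr[g$codes[, 3] == b]), 0)
  expect_equal(unname(marginals(a)[, 3]), m3, tolerance = 1e-12)

  det <- profile_adm(c("G", "T"), p = 1)
  expect_equal(unname(marginals(det)[, 1]), c(0, 0, 1, 0))
})

test_that("seed initialization spreads IUPAC weight as specified", {
  n <- seed_to_adm("NN")
  expect_true(all(abs(marginals(n) - 0.25) < 1e-12))

  a <- seed_to_adm("AA", match_weight = 0.8)
  expect_equal(unname(a$init), c(0.8, 0.2 / 3, 0.2 / 3, 0.2 / 3))

  hox <- seed_to_adm("CYMRTAAAA")
  m <- marginals(hox)
  expect_equal(unname(m[c("C", "T"), 2]), c(0.4, 0.4)) # Y splits C/T
  expect_equal(hox$length, 9)

  expect_error(seed_to_adm("ACXG"), "position 3")
})

test_that("estimation from counts recovers a sampled ADM", {
  a <- random_adm(4, seed = 21, min_entry = 0.15)
  set.seed(77)
  draws <- sample_adm(a, 1e6)
  initc <- tabulate(draws[, 1], 4)
  pairc <- array(0, c(4, 4, 4))
  for (h in 2:4) {
    pairc[, , h] <- table(factor(draws[, h - 1], 1:4),
                          factor(draws[, h], 1:4))
  }
  est <- adm_from_counts(initc, pairc, pseudocount = 0.01)
  expect_lt(max(abs(as_dinuc_matrix(est) - as_dinuc_matrix(a))), 0.01)
})

test_that("count estimation edge cases behave", {
  # single observation AC with no pseudocount: deterministic 2-mer
  pairc <- array(0, c(4, 4, 2))
  pairc[1, 2, 2] <- 1
  # rows other than A have no counts -> error without pseudocount
  expect_error(adm_from_counts(c(1, 0, 0, 0), pairc, pseudocount = 0),
               "all-zero")
  est <- adm_from_counts(c(1, 0, 0, 0), pairc, pseudocount = 1e-12)
  expect_equal(unname(est$init[1]), 1, tolerance = 1e-9)
  expect_equal(unname(est$trans[1, 2, 2]), 1, tolerance = 1e-9)

  # zero counts + pseudocount -> uniform
  u <- adm_from_counts(rep(0, 4), array(0, c(4, 4, 3)), pseudocount = 0.5)
  expect_true(all(abs(u$trans[, , 2:3] - 0.25) < 1e-12))
})

test_that("dinucleotide matrix layout round-trips", {
  a <- random_adm(5, seed = 3)
  m <- as_dinuc_matrix(a)
  expect_equal(dim(m), c(16, 5))
  expect_equal(rownames(m)[1:5], c("AA", "AC", "AG", "AT", "CA"))
  b <- from_dinuc_matrix(m)
  expect_equal(as_dinuc_matrix(b), m, tolerance = 1e-12)
})
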