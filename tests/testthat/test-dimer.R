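test_that("orientation composes reverse complements as documented", {
  t1 <- random_adm(4, seed = 1)
  t2 <- random_adm(3, seed = 2)

  ht <- orient_pair(t1, t2, "HT")
  expect_equal(as_dinuc_matrix(ht[[1]]), as_dinuc_matrix(t1))
  expect_equal(as_dinuc_matrix(ht[[2]]), as_dinuc_matrix(t2))

  tt <- orient_pair(t1, t2, "TT")
  expect_equal(as_dinuc_matrix(tt[[1]]),
               as_dinuc_matrix(reverse_complement_adm(t1)))
  expect_equal(as_dinuc_matrix(tt[[2]]), as_dinuc_matrix(t2))

  th <- orient_pair(t1, t2, "TH")
  expect_equal(as_dinuc_matrix(th[[2]]),
               as_dinuc_matrix(reverse_complement_adm(t2)))

  # HH with a palindromic second monomer equals HT
  pal <- seed_to_adm("ACGT") # order-zero palindrome
  hh <- orient_pair(t1, pal, "HH")
  expect_equal(as_dinuc_matrix(hh[[2]]), as_dinuc_matrix(pal),
               tolerance = 1e-12)
})

test_that("expected dimer factorizes into monomer x background x monomer", {
  t1 <- random_adm(2, seed = 11)
  t2 <- random_adm(2, seed = 12)
  bg <- background_model(c(0.3, 0.2, 0.2, 0.3))
  d <- 4
  tau <- expected_dimer(t1, t2, "HT", d, bg)
  expect_equal(tau$length, 8)
  g <- enum_grid(8)
  p_tau <- seq_probability(tau, g$seqs)
  p_fact <- seq_probability(t1, substr(g$seqs, 1, 2)) *
    bg$init[substring(g$seqs, 3, 3)] * bg$init[substring(g$seqs, 4, 4)] *
    bg$init[substring(g$seqs, 5, 5)] * bg$init[substring(g$seqs, 6, 6)] *
    seq_probability(t2, substr(g$seqs, 7, 8))
  expect_equal(p_tau, unname(p_fact), tolerance = 1e-12)
})

test_that("abutting dimers use the second monomer's initial at the junction", {
  t1 <- random_adm(3, seed = 4)
  t2 <- random_adm(3, seed = 5)
  tau <- expected_dimer(t1, t2, "HT", 0)
  expect_equal(tau$length, 6)
  for (a in 1:4) {
    expect_equal(unname(tau$trans[a, , 4]), unname(t2$init),
                 tolerance = 1e-12)
  }
})

test_that("overlapped columns take the renormalized marginal product", {
  t1 <- profile_adm(c("C", "A"), p = 1)          # marginal (1,0,0,0) at col 2
  tr <- array(0, c(4, 4, 2))
  tr[, , 1] <- matrix(c(0.5, 0.5, 0, 0), 4, 4, byrow = TRUE)
  tr[, , 2] <- matrix(c(0.25, 0.25, 0.25, 0.25), 4, 4, byrow = TRUE)
  t2 <- adm(c(0.5, 0.5, 0, 0), tr)               # marginal (.5,.5,0,0) at col 1
  tau <- expected_dimer(t1, t2, "HT", -1)
  expect_equal(tau$length, 3)
  # shared column: (1,0,0,0)*(0.5,0.5,0,0) renormalized -> (1,0,0,0)
  for (a in 1:4) {
    expect_equal(unname(tau$trans[a, , 2]), c(1, 0, 0, 0), tolerance = 1e-12)
  }
  expect_error(expected_dimer(t1, t2, "HT", -2), "shorter")
})

test_that("bridging replacement and deviation behave", {
  t1 <- random_adm(5, seed = 31, min_entry = 0.1)
  # independent spacing: expected model exactly
  tau <- build_dimer(t1, t1, "HT", 4, delta = 4)
  expect_equal(as_dinuc_matrix(tau),
               as_dinuc_matrix(expected_dimer(t1, t1, "HT", 4)))
  expect_error(build_dimer(t1, t1, "HT", 5, psi = array(0.25, c(4, 4, 7))),
               "d >= delta")

  # d = -2: bridging window has |d| + 2 = 4 columns
  em <- expected_bridge(t1, t1, "HH", -2)
  expect_equal(dim(em)[3], 4)
  tau2 <- build_dimer(t1, t1, "HH", -2, psi = em, delta = 4)
  expect_equal(as_dinuc_matrix(tau2),
               as_dinuc_matrix(expected_dimer(t1, t1, "HH", -2)),
               tolerance = 1e-12)

  # psi equal to the expected slice gives the zero deviation
  kd <- deviation(em, em)
  expect_true(all(kd == 0))
  expect_error(build_dimer(t1, t1, "HH", 2, psi = em[, , 1:3], delta = 4),
               "4 columns|\\|d\\| \\+ 2")
})

test_that("deviation blocks sum to zero and subtract entrywise", {
  psi <- expected_bridge(random_adm(4, seed = 7, min_entry = 0.1),
                         random_adm(4, seed = 8, min_entry = 0.1), "HT", 1)
  psi2 <- psi
  psi2[1, , 2] <- c(0.7, 0.1, 0.1, 0.1)
  kd <- deviation(psi2, psi)
  expect_equal(kd[1, , 2], c(0.7, 0.1, 0.1, 0.1) - psi[1, , 2])
  sums <- apply(unclass(kd), c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  expect_error(deviation(psi[, , 1:2], psi), "shape")
})

test_that("dimer length bookkeeping holds across the spacing grid", {
  t1 <- random_adm(5, seed = 41, min_entry = 0.1)
  t2 <- random_adm(4, seed = 42, min_entry = 0.1)
  for (o in c("HT", "HH", "TT", "TH")) {
    for (d in -2:6) {
      tau <- expected_dimer(t1, t2, o, d)
      expect_equal(tau$length, 5 + 4 + d)
    }
  }
})

test_that("minus-strand dimer scoring equals reverse complement scoring", {
  t1 <- random_adm(3, seed = 51, min_entry = 0.1)
  psi <- expected_bridge(t1, t1, "HT", 1)
  psi[1, , 2] <- c(0.55, 0.15, 0.15, 0.15)
  tau <- build_dimer(t1, t1, "HT", 1, psi = psi, delta = 4)
  rc <- reverse_complement_adm(tau)
  g <- enum_grid(7)
  expect_equal(seq_probability(rc, g$seqs),
               seq_probability(tau, revcomp(g$seqs)), tolerance = 1e-12)
})

test_that("COB tables round to milli-units and respect homodimer symmetry", {
  lam <- c("HT 2" = 0.0614, "HH 0" = 0.02, "TT -1" = 0.001)
  tb <- assemble_cob(lam, c(1, 1), dmin = -1, dmax = 3,
                     pruned = c("HT -1", "HT 0"))
  expect_s3_class(tb, "cob_table")
  expect_false("TH" %in% tb$orientation)
  expect_equal(tb$display[tb$orientation == "HT" & tb$d == 2], 61)
  expect_true(all(is.na(tb$lambda[tb$pruned])))
  expect_lte(sum(tb$lambda, na.rm = TRUE), 1)

  # heterodimer tables carry all four orientations
  tb2 <- assemble_cob(lam, c(1, 2), dmin = 0, dmax = 2)
  expect_setequal(unique(tb2$orientation), c("HT", "HH", "TT", "TH"))

  # fully pruned table has no live values
  tb3 <- assemble_cob(c("HT 0" = 0.1)[0], c(1, 1), 0, 2,
                      pruned = paste(rep(c("HT", "HH", "TT"), each = 3),
                                     rep(0:2, 3)))
  expect_true(all(is.na(tb3$lambda)))
})
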