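test_that("background-only generation matches the background composition", {
  bg <- background_model(c(0.4, 0.1, 0.1, 0.4))
  m <- mixture_model(bg, list(), numeric(0))
  sim <- generate_reads(m, 10000, 40, seed = 17)
  expect_true(all(sim$truth$component == "background"))
  freq <- table(factor(unlist(strsplit(sim$reads, "")), ALPH)) / (10000 * 40)
  n <- 10000 * 40
  for (b in seq_along(ALPH)) {
    p <- bg$init[b]
    expect_lt(abs(freq[b] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("the homodimer sanity profile builds the published mixture", {
  prof <- sanity_profile()
  expect_equal(prof$lambda, c(0.061, 0.055, 0.068, 0.034, 0.082))
  gen <- build_sanity_model(hoxb13_standin_adm(), prof, total_signal = 0.30)
  expect_equal(gen$lambda0, 0.70, tolerance = 1e-12)
  td <- tidy(gen)
  expect_equal(td$lambda[td$component == "1,1,HT,4"], 0.061)
  expect_equal(td$lambda[td$component == "1,1,HH,5"], 0.082)
  # rescaling to another total signal keeps proportions
  g9 <- build_sanity_model(hoxb13_standin_adm(), prof, total_signal = 0.90)
  expect_equal(g9$lambda0, 0.10, tolerance = 1e-12)
  expect_equal(g9$dimers$lambda / gen$dimers$lambda, rep(3, 5))
})

test_that("hand deviations perturb the bridge and round-trip", {
  mono <- hoxb13_standin_adm()
  kap <- test_kappa()
  g0 <- build_sanity_model(mono, sanity_profile(), total_signal = 0.30)
  g1 <- build_sanity_model(mono, sanity_profile(), total_signal = 0.30,
                           deviations = list("HH 2" = kap))
  i <- which(g1$dimers$orientation == "HH" & g1$dimers$d == 2)
  expect_equal(g1$dimers$psi[[i]] - g0$dimers$psi[[i]], kap,
               ignore_attr = TRUE)
  # all other bridging components are the expected slices (zero deviation)
  devs <- deviations(g0)
  expect_lt(max(abs(unlist(devs))), 1e-12)
  # deviations that leave the simplex are rejected
  bad <- kap * 10
  expect_error(
    build_sanity_model(mono, sanity_profile(), total_signal = 0.30,
                       deviations = list("HH 2" = bad)),
    "outside"
  )
})

test_that("deterministic components land exactly where logged", {
  mono <- profile_adm(c("T", "G", "A", "C", "A"), p = 1)
  m <- mixture_model(background_model(), list(mono), 1)
  sim <- generate_reads(m, 200, 15, seed = 21)
  for (i in 1:200) {
    w <- substr(sim$reads[i], sim$truth$start[i], sim$truth$start[i] + 4)
    expect_equal(w, if (sim$truth$strand[i] == "+") "TGACA" else
      revcomp("TGACA"))
  }
})

test_that("motif-bearing read fraction is binomially consistent", {
  gen <- two_motif_fixture(0.45)
  expect_equal(gen$lambda0, 0.1, tolerance = 1e-12)
  sim <- generate_reads(gen, 20000, 30, seed = 23)
  frac <- mean(sim$truth$component != "background")
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 20000))
})

test_that("dinucleotide frequencies at logged placements match the model", {
  mono <- random_adm(6, seed = 13, min_entry = 0.15)
  m <- mixture_model(background_model(), list(mono), 1)
  n <- 100000
  l <- mono$length
  sim <- generate_reads(m, n, 10, seed = 29)
  codes <- matrix(match(unlist(strsplit(sim$reads, "")), ALPH), n,
                  byrow = TRUE)
  inst <- t(vapply(seq_len(n), function(i) {
    v <- codes[i, sim$truth$start[i]:(sim$truth$start[i] + l - 1)]
    if (sim$truth$strand[i] == "-") rev(5L - v) else v
  }, integer(l)))
  initc <- tabulate(inst[, 1], 4)
  pairc <- array(0, c(4, 4, l))
  for (h in 2:l) {
    pairc[, , h] <- table(factor(inst[, h - 1], 1:4), factor(inst[, h], 1:4))
  }
  est <- adm_from_counts(initc, pairc, pseudocount = 0)
  expect_lt(max(abs(as_dinuc_matrix(est) - as_dinuc_matrix(mono))), 0.02)
})
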