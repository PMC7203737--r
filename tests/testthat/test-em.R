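# ZOOPS likelihood, E-step, Hamming restriction, M-step and the EM driver.

test_that("pure-background likelihood is n * L * log(1/4)", {
  m <- mixture_model(background_model(), list(), numeric(0))
  set.seed(1)
  reads <- apply(matrix(sample(ALPH, 30 * 12, TRUE), 30), 1, paste,
                 collapse = "")
  expect_equal(log_likelihood(m, reads), 30 * 12 * log(0.25),
               tolerance = 1e-9)
})

test_that("a full-length palindromic monomer at lambda = 1 scores its site", {
  pal <- seed_to_adm("AACGTT", 0.9) # palindromic profile: both strands equal
  m <- mixture_model(background_model(), list(pal), 1)
  s <- "AACGTT"
  expect_equal(log_likelihood(m, s), log(seq_probability(pal, s)),
               tolerance = 1e-9)
})

test_that("ZOOPS likelihood matches a hand-rolled placement sum", {
  mono <- seed_to_adm("TGA", 0.85)
  m <- mixture_model(background_model(), list(mono), 0.5)
  reads <- c("TGATGA", "ACGTAC", "TTTTTT")
  # independent oracle: explicit sum over placements and strands
  p_win <- function(w) {
    v <- match(strsplit(w, "")[[1]], ALPH)
    p <- mono$init[v[1]]
    for (h in 2:3) p <- p * mono$trans[v[h - 1], v[h], h]
    unname(p)
  }
  oracle <- sum(vapply(reads, function(r) {
    terms <- 0.5 * 0.25^6
    nplace <- 2 * 4
    for (j in 1:4) {
      w <- substr(r, j, j + 2)
      terms <- terms + 0.5 / nplace * 0.25^3 * (p_win(w) + p_win(revcomp(w)))
    }
    log(terms)
  }, 0))
  expect_equal(log_likelihood(m, reads), oracle, tolerance = 1e-9)
})

test_that("posteriors concentrate on a planted high-contrast site", {
  mono <- seed_to_adm("TGACTCAG", 0.95)
  m <- mixture_model(background_model(), list(mono), 0.5)
  read <- "AAAAATGACTCAGAAAAA" # site at start 6, plus strand
  post <- e_step(m, read)
  expect_gt(post$Wp[[1]][1, 6], 0.99)

  # lambda0 = 1: everything is background-only
  m0 <- mixture_model(background_model(), list(mono), 0)
  post0 <- e_step(m0, read)
  expect_equal(post0$w_bg, 1)

  # palindromic motifs load both strands equally
  pal <- seed_to_adm("AACGTT", 0.9)
  mp <- mixture_model(background_model(), list(pal), 0.5)
  pp <- e_step(mp, "GGAACGTTGG")
  expect_equal(pp$Wp[[1]], pp$Wm[[1]], tolerance = 1e-12)
})

test_that("the Hamming restriction drops far placements and renormalizes", {
  mono <- seed_to_adm("TGACTCAG", 0.9)
  m <- mixture_model(background_model(), list(mono), 0.5)
  reads <- c("AATGACTCAGAA", "AATGACTGGGAA") # exact site; 3-mismatch site
  post <- e_step(m, reads)

  expect_identical(hamming_filter(post, m, Inf), post)

  f0 <- hamming_filter(post, m, 0)
  expect_gt(f0$Wp[[1]][1, 3], 0.99)          # exact site survives
  expect_equal(sum(f0$Wp[[1]][2, ]) + sum(f0$Wm[[1]][2, ]), 0)
  expect_equal(f0$w_bg[2], 1)                 # read 2 is background-only
  tot <- f0$w_bg + rowSums(f0$Wp[[1]]) + rowSums(f0$Wm[[1]])
  expect_equal(tot, rep(1, 2), tolerance = 1e-9)
})

test_that("two close motifs are separated by the Hamming restriction", {
  gen <- two_motif_fixture(0.25)
  c1 <- consensus(gen$monomers[[1]])
  c2 <- consensus(gen$monomers[[2]])
  expect_lte(sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]), 4)
  reads <- c(paste0("AAAA", c1, "AAAA"), paste0("AAAA", c2, "AAAA"))
  post <- e_step(gen, reads)
  ham <- hamming_filter(post, gen, 1)
  # each motif keeps its own exact site but loses the other's exact site
  # (the two consensus sequences are 2 mismatches apart, radius is 1)
  expect_gt(sum(ham$Wp[[1]][1, ]) + sum(ham$Wm[[1]][1, ]), 0.9)
  expect_equal(ham$Wp[[2]][1, 5], 0)
  expect_equal(ham$Wm[[2]][1, 5], 0)
  expect_gt(sum(ham$Wp[[2]][2, ]) + sum(ham$Wm[[2]][2, ]), 0.9)
  expect_equal(ham$Wp[[1]][2, 5], 0)
  expect_equal(ham$Wm[[1]][2, 5], 0)
})

test_that("one E/M pass from the truth recovers a sharp monomer", {
  set.seed(99)
  l <- 8
  cols <- sapply(1:l, function(h) {
    v <- rep(0.1, 4); v[sample(4, 1)] <- 0.7; v
  })
  tr <- array(0, c(4, 4, l))
  for (h in 1:l) tr[, , h] <- matrix(cols[, h], 4, 4, byrow = TRUE)
  # inject first-order structure at column 4
  dom3 <- which.max(cols[, 3])
  tr[dom3, , 4] <- tr[dom3, , 4] + c(0.15, -0.05, -0.05, -0.05)
  mono <- adm(cols[, 1], tr)

  gen <- mixture_model(background_model(), list(mono), 1)
  sim <- generate_reads(gen, 50000, 16, seed = 11)
  post <- e_step(gen, sim$reads)
  m2 <- m_step(post, gen, em_config())
  expect_lt(max(abs(as_dinuc_matrix(m2$monomers[[1]]) -
                      as_dinuc_matrix(mono))), 0.02)
})

test_that("monomers learn nothing from close-dimer half-sites", {
  mono <- seed_to_adm("TGACTCAG", 0.9, name = "m1")
  psi <- expected_bridge(mono, mono, "HT", 2)
  dimers <- tibble::tibble(k1 = 1L, k2 = 1L, orientation = "HT", d = 2L,
                           lambda = 0.6, psi = list(psi))
  gen <- mixture_model(background_model(), list(mono), 0, dimers)
  sim <- generate_reads(gen, 300, 30, seed = 3)
  post <- e_step(gen, sim$reads)
  # all motif mass sits on the d = 2 (< delta) dimer; the monomer gets no
  # counts and is re-initialized with a warning
  expect_warning(m2 <- m_step(post, gen, em_config()), "no counts")
  expect_true(all(abs(m2$monomers[[1]]$trans[, , 2] - 0.25) < 1e-12))
  # the bridging component itself was re-estimated from those placements
  expect_false(isTRUE(all.equal(m2$dimers$psi[[1]], psi)))
})

test_that("all-background posteriors drive lambda0 to one", {
  mono <- seed_to_adm("ACGTAC", 0.9)
  m <- mixture_model(background_model(), list(mono), 0)
  set.seed(2)
  reads <- apply(matrix(sample(ALPH, 50 * 15, TRUE), 50), 1, paste,
                 collapse = "")
  post <- e_step(m, reads)
  suppressWarnings(m2 <- m_step(post, m, em_config()))
  expect_equal(m2$lambda0, 1)
})

test_that("weak dimers are pruned permanently and weights rebalance", {
  mono <- seed_to_adm("ACGTAC", 0.9)
  dimers <- tibble::tibble(
    k1 = 1L, k2 = 1L, orientation = c("HT", "HH"), d = c(5L, 6L),
    lambda = c(0.2, 5e-5), psi = list(NULL, NULL)
  )
  m <- mixture_model(background_model(), list(mono), 0.1, dimers)
  expect_identical(nrow(prune_weak_dimers(m, 0)$dimers), 2L)
  m2 <- prune_weak_dimers(m, 1e-4)
  expect_equal(nrow(m2$dimers), 1)
  expect_equal(m2$pruned$orientation, "HH")
  expect_equal(m2$lambda0, 1 - 0.1 - 0.2) # reassigned to background
  expect_error(prune_weak_dimers(m, -1), ">= 0")
})

test_that("EM started at the generating model stays there", {
  m0 <- mixture_model(background_model(), list(seed_to_adm("CYMRTAAAA", 0.8)),
                      0.5)
  sim <- generate_reads(m0, 20000, 30, seed = 5)
  fit <- run_em(sim$reads, "CYMRTAAAA", em_config(rho = Inf))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 20)
  expect_lt(model_distance(m0, fit$model, strict = FALSE), 0.05)
})

test_that("noise-only data neither crashes nor invents a strong motif", {
  set.seed(6)
  reads <- apply(matrix(sample(ALPH, 2000 * 20, TRUE), 2000), 1, paste,
                 collapse = "")
  fit <- run_em(reads, "ACGTACGT", em_config(maxiter = 30))
  expect_s3_class(fit, "adm_fit")
  expect_lt(fit$model$lambda_mono, 0.2)
  expect_true(all(is.finite(fit$trace$loglik)))
})

test_that("the EM is deterministic for identical inputs", {
  m0 <- two_motif_fixture(0.2)
  sim <- generate_reads(m0, 1500, 24, seed = 9)
  cfg <- em_config(maxiter = 8)
  f1 <- run_em(sim$reads, c("CACGTGAT", "CACGCGTT"), cfg)
  f2 <- run_em(sim$reads, c("CACGTGAT", "CACGCGTT"), cfg)
  expect_identical(f1$trace, f2$trace)
  expect_equal(model_distance(f1$model, f2$model), 0)
})

test_that("simulator determinism: one seed, one read set", {
  m0 <- two_motif_fixture(0.2)
  s1 <- generate_reads(m0, 500, 24, seed = 123)
  s2 <- generate_reads(m0, 500, 24, seed = 123)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("submodel selection is greedy on signal fraction", {
  mono <- lapply(c("ACGTAC", "TTTAAC", "GGGTAC"), seed_to_adm)
  m <- mixture_model(background_model(), mono, c(0.5, 0.3, 0.2))
  s1 <- select_submodel(m, 1)
  expect_equal(sum(s1$lambda_mono > 0), 3)

  # 0.5 + 0.3 = 0.8 < 0.85: all three components are needed
  expect_equal(sum(select_submodel(m, 0.85)$lambda_mono > 0), 3)

  m2 <- mixture_model(background_model(), mono, c(0.6, 0.3, 0.1))
  s2 <- select_submodel(m2, 0.85)
  expect_equal(unname(s2$lambda_mono), c(0.6, 0.3, 0)) # 0.9 >= 0.85
  expect_equal(attr(s2, "signal_covered"), 0.9)
  expect_error(select_submodel(m, 0), "fraction")
})
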