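# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately avoid the package's own chain-evaluation code paths: they
# enumerate sequences and multiply matrix entries directly.

ALPH <- c("A", "C", "G", "T")

# A random valid ADM (Dirichlet-ish rows via normalized uniforms).
random_adm <- function(l, seed = NULL, min_entry = 0) {
  if (!is.null(seed)) set.seed(seed)
  tr <- array(stats::runif(16 * l) + min_entry, c(4, 4, l))
  for (h in 2:l) tr[, , h] <- tr[, , h] / rowSums(tr[, , h])
  ini <- stats::runif(4) + min_entry
  adm(ini / sum(ini), tr)
}

# A sharp order-zero ADM whose column h puts `p` on cons[h].
profile_adm <- function(cons, p = 0.85) {
  l <- length(cons)
  tr <- array(0, c(4, 4, l))
  for (h in seq_len(l)) {
    v <- rep((1 - p) / 3, 4)
    v[match(cons[h], ALPH)] <- p
    tr[, , h] <- matrix(v, 4, 4, byrow = TRUE)
  }
  adm(tr[1, , 1], tr)
}

# All DNA l-mers with base 1 varying fastest, as a data frame of codes and
# as strings; used by the enumeration oracles.
enum_grid <- function(l) {
  g <- as.matrix(expand.grid(rep(list(1:4), l)))
  colnames(g) <- NULL
  list(codes = g,
       seqs = apply(g, 1, function(v) paste(ALPH[v], collapse = "")))
}

# Independent chain-probability oracle: direct product of matrix entries.
enum_probs <- function(init, trans, grid) {
  l <- dim(trans)[3]
  pr <- init[grid$codes[, 1]]
  if (l >= 2) {
    for (h in 2:l) {
      pr <- pr * trans[cbind(grid$codes[, h - 1], grid$codes[, h], h)]
    }
  }
  pr
}

# Column-shuffled decoy of an ADM: the marginal columns in permuted order,
# as an order-zero model (destroys both positional and dinucleotide
# structure while keeping the composition).
shuffle_columns_adm <- function(x, seed) {
  set.seed(seed)
  perm <- sample(x$length)
  m <- marginals(x)
  tr <- array(0, c(4, 4, x$length))
  for (h in seq_len(x$length)) {
    tr[, , h] <- matrix(m[, perm[h]], 4, 4, byrow = TRUE)
  }
  adm(m[, perm[1]], tr)
}

# Deviation array used by the co-operativity tests: +/- 0.18 in the two
# gap columns of a |d|+2 = 4 column bridging window.
test_kappa <- function() {
  kap <- array(0, c(4, 4, 4))
  kap[1, 2, 2] <- 0.18; kap[1, 3, 2] <- -0.18
  kap[2, 2, 2] <- 0.18; kap[2, 4, 2] <- -0.18
  kap[3, 1, 3] <- 0.18; kap[3, 4, 3] <- -0.18
  kap[4, 1, 3] <- 0.18; kap[4, 4, 3] <- -0.18
  kap
}

# Monomer for the co-operativity tests: six sharp core columns for precise
# localization plus two balanced boundary columns so every predecessor row
# of the bridging window is well populated.
kappa_test_monomer <- function() {
  cols <- matrix(0, 4, 8)
  cons <- c("T", "G", "A", "C", "T", "C")
  for (h in 1:6) {
    v <- rep(0.08 / 3, 4)
    v[match(cons[h], ALPH)] <- 0.92
    cols[, h] <- v
  }
  cols[, 7] <- c(0.40, 0.30, 0.20, 0.10)
  cols[, 8] <- c(0.30, 0.30, 0.20, 0.20)
  tr <- array(0, c(4, 4, 8))
  for (h in 1:8) tr[, , h] <- matrix(cols[, h], 4, 4, byrow = TRUE)
  adm(cols[, 1], tr, name = "m1")
}

expect_valid_adm <- function(x, tol = 1e-9) {
  expect_s3_class(x, "adm")
  expect_lt(abs(sum(x$init) - 1), tol)
  if (x$length >= 2) {
    rs <- apply(x$trans[, , 2:x$length, drop = FALSE], c(1, 3), sum)
    expect_lt(max(abs(rs - 1)), tol)
  }
}
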