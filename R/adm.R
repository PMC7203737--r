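#' Adjacent dinucleotide matrix (ADM) motif models
#'
#' An ADM represents a binding motif of length `l` as an inhomogeneous
#' first-order Markov chain over A, C, G, T: position 1 has an initial base
#' distribution, and every later position `h` has a 4 x 4 matrix of
#' conditionals `P(X_h = b | X_(h-1) = a)`. Serialized, this is the familiar
#' 16 x `l` dinucleotide layout (rows AA..TT), with column 1 holding the
#' initial distribution replicated across the four predecessor rows.
#'
#' @param init Numeric length-4 initial distribution over A, C, G, T.
#' @param trans 4 x 4 x `l` array of conditionals; slice `h` (h >= 2) has
#'   rows indexed by the predecessor base. Slice 1 is ignored and stored as
#'   the replicated initial distribution.
#' @param name Optional motif name.
#' @return An object of class `adm` with fields `length`, `init`, `trans`,
#'   `name`.
#' @export
#' @examples
#' a <- uniform_adm(4)
#' seq_probability(a, "ACGT")
adm <- function(init, trans, name = NULL) {
  if (length(init) != 4) stop("init must have length 4")
  if (length(dim(trans)) != 3 || any(dim(trans)[1:2] != 4)) {
    stop("trans must be a 4 x 4 x l array")
  }
  l <- dim(trans)[3]
  init <- as.numeric(init)
  trans[, , 1] <- matrix(init, 4, 4, byrow = TRUE)
  dimnames(trans) <- list(DNA_BASES, DNA_BASES, NULL)
  names(init) <- DNA_BASES
  x <- structure(
    list(length = l, init = init, trans = trans, name = name),
    class = "adm"
  )
  validate_adm(x)
  x
}

validate_adm <- function(x, tol = 1e-9) {
  if (abs(sum(x$init) - 1) > tol || any(x$init < -tol) || any(x$init > 1 + tol)) {
    stop("ADM initial distribution must be probabilities summing to 1")
  }
  if (x$length >= 2) {
    rs <- apply(x$trans[, , 2:x$length, drop = FALSE], c(1, 3), sum)
    if (any(abs(rs - 1) > tol)) {
      stop("every ADM conditional row must sum to 1 (worst deviation ",
           signif(max(abs(rs - 1)), 3), ")")
    }
    if (any(x$trans < -tol) || any(x$trans > 1 + tol)) {
      stop("ADM entries must lie in [0, 1]")
    }
  }
  invisible(x)
}

#' @export
print.adm <- function(x, ...) {
  cat("ADM", if (!is.null(x$name)) paste0("'", x$name, "'"), "of length",
      x$length, "- consensus", consensus(x), "\n")
  invisible(x)
}

#' @rdname adm
#' @param l Motif length.
#' @export
uniform_adm <- function(l, name = NULL) {
  adm(rep(0.25, 4), array(0.25, c(4, 4, l)), name = name)
}

#' Convert between ADM and 16 x l dinucleotide matrix layout
#'
#' @param x An `adm`.
#' @return `as_dinuc_matrix()`: a 16 x l numeric matrix with rows AA..TT
#'   (first letter = predecessor); column 1 is the initial distribution
#'   replicated across predecessor rows.
#' @export
as_dinuc_matrix <- function(x) {
  stopifnot(inherits(x, "adm"))
  m <- matrix(0, 16, x$length, dimnames = list(DINUC_LABELS, NULL))
  for (a in 1:4) for (b in 1:4) m[(a - 1) * 4 + b, ] <- x$trans[a, b, ]
  m[, 1] <- rep(x$init, 4)
  m
}

#' @rdname as_dinuc_matrix
#' @param m A 16 x l matrix in the layout written by [as_dinuc_matrix()].
#' @param name Optional name.
#' @export
from_dinuc_matrix <- function(m, name = NULL) {
  if (nrow(m) != 16) stop("expected 16 rows (dinucleotides AA..TT)")
  l <- ncol(m)
  trans <- array(0, c(4, 4, l))
  for (a in 1:4) for (b in 1:4) trans[a, b, ] <- m[(a - 1) * 4 + b, ]
  init <- colMeans(matrix(m[, 1], 4, 4, byrow = TRUE))
  # column 1 rows should be identical; average tolerates rounding
  init <- m[1:4, 1]
  adm(init / sum(init), trans, name = name)
}

#' Sequence probability under an ADM
#'
#' The chain probability `init(s1) * prod_h P(s_h | s_(h-1))`.
#'
#' @param x An `adm`.
#' @param s A DNA string over A,C,G,T of length `x$length`, or a character
#'   vector of such strings.
#' @return Numeric vector of probabilities.
#' @export
seq_probability <- function(x, s) {
  stopifnot(inherits(x, "adm"))
  s <- toupper(s)
  n <- nchar(s)
  if (any(n != x$length)) {
    stop("sequence length ", paste(unique(n[n != x$length]), collapse = "/"),
         " does not match ADM length ", x$length)
  }
  if (any(!grepl("^[ACGT]*$", s))) {
    stop("sequences must be over A,C,G,T (IUPAC ambiguity not allowed here)")
  }
  vapply(strsplit(s, "", fixed = TRUE), function(ch) {
    v <- match(ch, DNA_BASES)
    p <- x$init[v[1]]
    if (x$length >= 2) {
      for (h in 2:x$length) p <- p * x$trans[v[h - 1], v[h], h]
    }
    unname(p)
  }, numeric(1))
}

#' Per-position marginal base distributions of an ADM
#'
#' `m_1 = init`; `m_h(b) = sum_a m_(h-1)(a) P(b | a)`.
#'
#' @param x An `adm`.
#' @return A 4 x l matrix of marginals (rows A,C,G,T).
#' @export
marginals <- function(x) {
  stopifnot(inherits(x, "adm"))
  m <- matrix(0, 4, x$length, dimnames = list(DNA_BASES, NULL))
  m[, 1] <- x$init
  if (x$length >= 2) {
    for (h in 2:x$length) m[, h] <- as.numeric(m[, h - 1] %*% x$trans[, , h])
  }
  m
}

#' Consensus (highest-probability) sequence of an ADM
#'
#' Max-product dynamic programming over positions; ties are broken towards
#' the alphabetically smaller base at each backtracking decision, so the
#' result is deterministic.
#'
#' @param x An `adm`.
#' @return A DNA string of length `x$length`.
#' @export
consensus <- function(x) {
  stopifnot(inherits(x, "adm"))
  l <- x$length
  V <- matrix(0, 4, l)
  V[, 1] <- x$init
  if (l >= 2) {
    for (h in 2:l) {
      for (b in 1:4) V[b, h] <- max(V[, h - 1] * x$trans[, b, h])
    }
  }
  path <- integer(l)
  path[l] <- which.max(V[, l])
  if (l >= 2) {
    for (h in l:2) {
      path[h - 1] <- which.max(V[, h - 1] * x$trans[, path[h], h])
    }
  }
  paste(DNA_BASES[path], collapse = "")
}

#' Reverse complement of an ADM
#'
#' Returns the ADM of the reverse-complemented motif: for every sequence
#' `s`, `seq_probability(rc(x), s) == seq_probability(x, revcomp(s))`. The
#' reversal of a first-order chain is again first-order; the construction
#' forms position-wise joint dinucleotide distributions from the marginals,
#' reverses and complements them, and renormalizes to conditionals.
#' Predecessor states with zero marginal mass get a uniform conditional row
#' (with a warning); they are unreachable, so sequence probabilities are
#' unaffected.
#'
#' @param x An `adm`.
#' @return An `adm` of the same length.
#' @export
reverse_complement_adm <- function(x) {
  stopifnot(inherits(x, "adm"))
  l <- x$length
  m <- marginals(x)
  cc <- 4:1 # complement index: A<->T, C<->G
  init2 <- m[cc, l]
  trans2 <- array(0.25, c(4, 4, l))
  warned <- FALSE
  if (l >= 2) {
    for (j in 2:l) {
      hp <- l - j + 2 # original position whose pair (hp-1, hp) maps here
      # predecessor a at new pos j-1 is original base comp(a) at position hp
      for (a in 1:4) {
        denom <- m[cc[a], hp]
        if (denom <= 0) {
          trans2[a, , j] <- 0.25
          warned <- TRUE
        } else {
          # joint q_hp(u, v) = m_(hp-1)(u) * P(v | u); new cond(b | a) =
          # q_hp(comp(b), comp(a)) / m_hp(comp(a))
          trans2[a, , j] <- m[cc, hp - 1] * x$trans[cc, cc[a], hp] / denom
        }
      }
    }
  }
  if (warned) {
    warning("zero-marginal predecessor state(s); uniform rows substituted ",
            "(unreachable, sequence probabilities unaffected)")
  }
  adm(init2, trans2,
      name = if (!is.null(x$name)) paste0(x$name, "_rc"))
}

#' Build an order-zero ADM from an IUPAC seed
#'
#' Bases allowed by the IUPAC code at each position share `match_weight`
#' equally; the remaining bases share `1 - match_weight` equally. The
#' conditionals do not depend on the predecessor (an order-zero start: the
#' EM immediately introduces first-order structure).
#'
#' @param seed IUPAC string (15-letter DNA code), length >= 2.
#' @param match_weight Total probability assigned to the allowed bases
#'   (default 0.8). Positions allowing all four bases are uniform.
#' @param name Optional name (default: the seed).
#' @return An `adm`.
#' @export
#' @examples
#' seed_to_adm("CYMRTAAAA")
seed_to_adm <- function(seed, match_weight = 0.8, name = seed) {
  seed <- toupper(seed)
  ch <- strsplit(seed, "", fixed = TRUE)[[1]]
  l <- length(ch)
  if (l < 2) stop("seed must have length >= 2")
  cols <- matrix(0, 4, l, dimnames = list(DNA_BASES, NULL))
  for (h in seq_len(l)) {
    allowed <- IUPAC_CODES[[ch[h]]]
    if (is.null(allowed)) {
      stop("invalid IUPAC character '", ch[h], "' at position ", h)
    }
    k <- length(allowed)
    if (k == 4) {
      cols[, h] <- 0.25
    } else {
      cols[, h] <- (1 - match_weight) / (4 - k)
      cols[allowed, h] <- match_weight / k
    }
  }
  trans <- array(0, c(4, 4, l))
  for (h in seq_len(l)) trans[, , h] <- matrix(cols[, h], 4, 4, byrow = TRUE)
  adm(cols[, 1], trans, name = name)
}

#' Estimate an ADM from dinucleotide counts
#'
#' Row-normalizes `counts + pseudocount` per conditional row, and likewise
#' for the initial counts.
#'
#' @param init_counts Numeric length-4 nonnegative counts for position 1.
#' @param pair_counts 4 x 4 x l nonnegative array; slice `h` holds counts of
#'   (predecessor, base) pairs at positions (h-1, h). Slice 1 is ignored.
#' @param pseudocount Added to every cell before normalization
#'   (default 0.01).
#' @param name Optional name.
#' @return An `adm`.
#' @export
adm_from_counts <- function(init_counts, pair_counts, pseudocount = 0.01,
                            name = NULL) {
  if (any(init_counts < 0) || any(pair_counts < 0)) {
    stop("counts must be nonnegative")
  }
  l <- dim(pair_counts)[3]
  ic <- init_counts + pseudocount
  if (sum(ic) == 0) stop("all-zero initial counts with zero pseudocount")
  init <- ic / sum(ic)
  trans <- array(0, c(4, 4, l))
  if (l >= 2) {
    for (h in 2:l) {
      for (a in 1:4) {
        row <- pair_counts[a, , h] + pseudocount
        if (sum(row) == 0) {
          stop("all-zero count row (predecessor ", DNA_BASES[a],
               ", position ", h, ") with zero pseudocount")
        }
        trans[a, , h] <- row / sum(row)
      }
    }
  }
  adm(init, trans, name = name)
}

#' Sample sequences from an ADM
#'
#' Forward sampling of the chain; vectorized over draws.
#'
#' @param x An `adm`.
#' @param n Number of sequences.
#' @return Integer matrix n x l of base codes 1..4.
#' @export
sample_adm <- function(x, n) {
  stopifnot(inherits(x, "adm"))
  l <- x$length
  out <- matrix(0L, n, l)
  out[, 1] <- sample.int(4, n, replace = TRUE, prob = x$init)
  if (l >= 2) {
    for (h in 2:l) {
      cum <- t(apply(x$trans[, , h], 1, cumsum))
      u <- stats::runif(n)
      prev <- out[, h - 1]
      out[, h] <- 1L + (u > cum[cbind(prev, 1)]) + (u > cum[cbind(prev, 2)]) +
        (u > cum[cbind(prev, 3)])
    }
  }
  out
}

# Reverse complement a fragment of dinucleotide counts (init counts + 4x4xl
# pair counts + marginal counts of the last column). Counts of sequences
# transform exactly: rc pair at new position j is the old pair at position
# l-j+2 with bases complemented and swapped.
rc_counts <- function(init_counts, pair_counts, last_marginal) {
  l <- dim(pair_counts)[3]
  cc <- 4:1
  out <- array(0, c(4, 4, l))
  if (l >= 2) {
    for (j in 2:l) {
      hp <- l - j + 2
      out[, , j] <- t(pair_counts[cc, cc, hp])
    }
  }
  list(init = last_marginal[cc], pairs = out)
}
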