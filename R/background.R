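#' Background sequence model
#'
#' A homogeneous Markov chain for positions outside motif instances. The
#' default is order zero (independent bases from one marginal
#' distribution); an order-one background (4 x 4 transition matrix plus an
#' initial distribution) is supported as an option.
#'
#' @param probs Length-4 base distribution (order 0), default uniform.
#' @param trans Optional 4 x 4 transition matrix; supplying it makes the
#'   model order one, with `probs` as the initial distribution.
#' @return An object of class `bg_model` with fields `order`, `init`,
#'   `trans`.
#' @export
#' @examples
#' background_model()             # uniform order-0
#' background_model(c(.3, .2, .2, .3))
background_model <- function(probs = rep(0.25, 4), trans = NULL) {
  probs <- as.numeric(probs)
  if (length(probs) != 4 || abs(sum(probs) - 1) > 1e-9 || any(probs < 0)) {
    stop("background probs must be a length-4 distribution")
  }
  order <- if (is.null(trans)) 0L else 1L
  if (is.null(trans)) {
    trans <- matrix(probs, 4, 4, byrow = TRUE)
  } else {
    trans <- as.matrix(trans)
    if (any(dim(trans) != c(4, 4)) || any(abs(rowSums(trans) - 1) > 1e-9)) {
      stop("background transition rows must sum to 1")
    }
  }
  dimnames(trans) <- list(DNA_BASES, DNA_BASES)
  names(probs) <- DNA_BASES
  structure(list(order = order, init = probs, trans = trans),
            class = "bg_model")
}

#' @export
print.bg_model <- function(x, ...) {
  cat("Background model, order", x$order, "\n")
  print(round(x$init, 4))
  invisible(x)
}

#' Stationary distribution of a background model
#'
#' For order 0 this is the marginal itself; for order 1 it is the left
#' eigenvector of the transition matrix.
#'
#' @param bg A `bg_model`.
#' @return Length-4 distribution.
#' @export
bg_stationary <- function(bg) {
  if (bg$order == 0) return(bg$init)
  e <- eigen(t(bg$trans))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(v, DNA_BASES)
}

# Marginal column used when filling gaps / flanks: stationary distribution.
bg_column <- function(bg) bg_stationary(bg)

# Expand a bg_model to an ADM of length l (for sampling / composition).
bg_as_adm <- function(bg, l) {
  trans <- array(0, c(4, 4, l))
  for (h in seq_len(l)) trans[, , h] <- bg$trans
  adm(bg$init, trans, name = "background")
}

# Log-probability machinery over an encoded read set for ZOOPS flanks.
# Returns linit (n x L: log init at each position, 0 for N), ctr
# (n x L cumulative transition log-probs; transitions touching N or a read
# boundary contribute 0), and lp_full (n). Chain restarts after an N.
bg_read_tables <- function(bg, enc) {
  codes <- enc$codes
  n <- enc$n
  L <- enc$Lmax
  li <- log(bg$init)
  lt <- log(bg$trans)
  linit <- matrix(0, n, L)
  pos <- codes > 0
  linit[pos] <- li[codes[pos]]
  ctr <- matrix(0, n, L)
  if (L >= 2) {
    for (t in 2:L) {
      prev <- codes[, t - 1]
      cur <- codes[, t]
      ok <- prev > 0 & cur > 0 & t <= enc$lens
      add <- numeric(n)
      add[ok] <- lt[cbind(prev[ok], cur[ok])]
      # after an N the chain restarts with the initial distribution
      restart <- prev == 0 & cur > 0 & t <= enc$lens
      add[restart] <- li[cur[restart]]
      ctr[, t] <- ctr[, t - 1] + add
    }
  }
  lp_full <- linit[, 1] + ctr[cbind(seq_len(n), enc$lens)]
  list(linit = linit, ctr = ctr, lp_full = lp_full)
}

# Flank log-probability for a placement at start j with component length
# len: fresh chains over [1, j-1] and [j+len, L_i].
bg_flank_logprob <- function(bt, enc, j, len) {
  n <- enc$n
  left <- if (j >= 2) bt$linit[, 1] + bt$ctr[, j - 1] else numeric(n)
  t2 <- j + len
  right <- numeric(n)
  sel <- enc$lens >= t2
  if (any(sel)) {
    idx <- which(sel)
    right[idx] <- bt$linit[idx, t2] +
      (bt$ctr[cbind(idx, enc$lens[idx])] - bt$ctr[idx, t2])
  }
  left + right
}
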