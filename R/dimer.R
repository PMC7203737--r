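#' Dimeric motif structure
#'
#' A dimer combines two monomer motifs in a relative orientation (`HT`,
#' `HH`, `TT`, `TH`) at a signed spacing `d`: the distance from the right
#' end of the first (oriented) monomer to the left end of the second, with
#' negative values meaning an overlap of `|d|` bases. For homodimers only
#' `HT`, `HH`, `TT` are distinct (`TH` duplicates `HT` by strand symmetry).
#'
#' @name dimer
NULL

ORIENTATIONS <- c("HT", "HH", "TT", "TH")

#' Orient a pair of monomer ADMs
#'
#' `HT` leaves both unchanged; `TT` reverse-complements the first; `TH`
#' reverse-complements both; `HH` reverse-complements the second.
#'
#' @param theta1,theta2 Monomer `adm`s.
#' @param o Orientation, one of `"HT"`, `"HH"`, `"TT"`, `"TH"`.
#' @return List of the two oriented `adm`s, with attributes `rc1`, `rc2`
#'   saying which were reverse-complemented.
#' @export
orient_pair <- function(theta1, theta2, o) {
  o <- match.arg(o, ORIENTATIONS)
  rc1 <- o %in% c("TT", "TH")
  rc2 <- o %in% c("HH", "TH")
  out <- list(
    if (rc1) reverse_complement_adm(theta1) else theta1,
    if (rc2) reverse_complement_adm(theta2) else theta2
  )
  attr(out, "rc1") <- rc1
  attr(out, "rc2") <- rc2
  out
}

# Bridging window of a dimer of oriented lengths l1, l2 at spacing d:
# the gap/overlap columns plus one flanking column on each side, total
# |d| + 2 columns, starting at column l1 + min(d, 0).
bridge_window <- function(l1, d) {
  bs <- l1 + min(d, 0)
  c(start = bs, end = bs + abs(d) + 1)
}

#' Expected dimeric ADM under monomer independence
#'
#' Composes two oriented monomer ADMs at spacing `d` as if they bound
#' independently: for `d >= 0` the `d` gap columns carry background
#' conditionals and the second monomer re-enters with its initial
#' distribution (the independence junction); for `d < 0` the `|d|`
#' overlapped columns carry the renormalized elementwise product of the two
#' monomers' position marginals (order zero within the overlap), after
#' which the second monomer continues with its own conditionals.
#'
#' @param theta1,theta2 Monomer `adm`s (un-oriented).
#' @param o Orientation.
#' @param d Signed spacing; the overlap must be shorter than either
#'   monomer.
#' @param bg A `bg_model` used for gap columns.
#' @param name Optional name.
#' @return An `adm` of length `l1 + l2 + d`.
#' @export
expected_dimer <- function(theta1, theta2, o, d, bg = background_model(),
                           name = NULL) {
  op <- orient_pair(theta1, theta2, o)
  t1 <- op[[1]]; t2 <- op[[2]]
  l1 <- t1$length; l2 <- t2$length
  if (d <= -min(l1, l2)) {
    stop("overlap |d| = ", -d, " must be shorter than both monomers (",
         l1, ", ", l2, ")")
  }
  M <- l1 + l2 + d
  trans <- array(0, c(4, 4, M))
  trans[, , seq_len(l1)] <- t1$trans[, , seq_len(l1)]
  if (d >= 0) {
    if (d > 0) {
      bgcol <- matrix(bg_column(bg), 4, 4, byrow = TRUE)
      for (j in (l1 + 1):(l1 + d)) {
        trans[, , j] <- if (bg$order == 1) bg$trans else bgcol
      }
    }
    # independence junction: monomer 2 enters with its initial distribution
    trans[, , l1 + d + 1] <- matrix(t2$init, 4, 4, byrow = TRUE)
    if (l2 >= 2) {
      trans[, , (l1 + d + 2):M] <- t2$trans[, , 2:l2]
    }
  } else {
    v <- -d
    m1 <- marginals(t1)
    m2 <- marginals(t2)
    for (u in seq_len(v)) {
      p1 <- m1[, l1 + d + u]
      p2 <- m2[, u]
      col <- p1 * p2
      if (sum(col) <= 0) {
        stop("overlap column ", u, " has zero mass under the marginal product")
      }
      trans[, , l1 + d + u] <- matrix(col / sum(col), 4, 4, byrow = TRUE)
    }
    # monomer 2 re-enters with its own conditionals after the overlap
    trans[, , (l1 + 1):M] <- t2$trans[, , (v + 1):l2]
  }
  adm(t1$init, trans, name = name)
}

# Extract the conditional slices (4 x 4 x w) of an ADM over a column window.
adm_slice <- function(x, start, end) {
  x$trans[, , start:end, drop = FALSE]
}

#' Expected bridging slice of a dimer
#'
#' The `|d| + 2` middle conditional columns of [expected_dimer()], centred
#' on the gap/overlap; this is the initialization of the bridging component
#' and the reference against which its deviation is computed.
#'
#' @inheritParams expected_dimer
#' @return 4 x 4 x (`|d|`+2) array of conditionals.
#' @export
expected_bridge <- function(theta1, theta2, o, d, bg = background_model()) {
  ed <- expected_dimer(theta1, theta2, o, d, bg)
  # reverse complement preserves length, so the oriented l1 is theta1$length
  bw <- bridge_window(theta1$length, d)
  adm_slice(ed, bw["start"], bw["end"])
}

#' Compose a dimeric ADM, with an optional learned bridging component
#'
#' For `d >= delta` the dimer is exactly the expected (independent) model;
#' for `d < delta` the `|d| + 2` middle columns are replaced by the
#' bridging component `psi`.
#'
#' @inheritParams expected_dimer
#' @param psi 4 x 4 x (`|d|`+2) array of bridging conditionals (required
#'   iff `d < delta`).
#' @param delta Independence threshold (default 4).
#' @return An `adm` of length `l1 + l2 + d`.
#' @export
build_dimer <- function(theta1, theta2, o, d, psi = NULL, delta = 4,
                        bg = background_model(), name = NULL) {
  ed <- expected_dimer(theta1, theta2, o, d, bg, name = name)
  if (d >= delta) {
    if (!is.null(psi)) {
      stop("psi supplied for an independent dimer (d >= delta)")
    }
    return(ed)
  }
  if (is.null(psi)) stop("psi is required when d < delta")
  w <- abs(d) + 2
  if (length(dim(psi)) != 3 || any(dim(psi) != c(4, 4, w))) {
    stop("psi must be 4 x 4 x ", w, " (|d| + 2 columns)")
  }
  bw <- bridge_window(theta1$length, d)
  trans <- ed$trans
  trans[, , bw["start"]:bw["end"]] <- psi
  init <- if (bw["start"] == 1) psi[1, , 1] else ed$init
  adm(init, trans, name = name)
}

#' Deviation of a bridging component from independence
#'
#' The signed difference `psi - expected` over the bridging window; every
#' 4-entry conditional block sums to zero because both are conditional
#' distributions.
#'
#' @param psi 4 x 4 x w bridging conditionals.
#' @param expected_mid Matching 4 x 4 x w expected slice (see
#'   [expected_bridge()]).
#' @return 4 x 4 x w signed array of class `adm_deviation`.
#' @export
deviation <- function(psi, expected_mid) {
  if (length(dim(psi)) != length(dim(expected_mid)) ||
      !all(dim(psi) == dim(expected_mid))) {
    stop("psi (", paste(dim(psi), collapse = "x"), ") and expected slice (",
         paste(dim(expected_mid), collapse = "x"), ") differ in shape")
  }
  structure(psi - expected_mid, class = "adm_deviation")
}

#' Assemble a co-operative binding (COB) table
#'
#' The COB table of a monomer pair maps (orientation, spacing) to the
#' mixing weight of that dimer; pruned cells are `NA`. Display values are
#' the weights in integer multiples of 0.001 (round half up). Homodimer
#' tables omit the `TH` row (it duplicates `HT` by strand symmetry).
#'
#' @param lambda Named numeric vector of dimer weights; names `"o d"`, e.g.
#'   `"HT 2"`, `"TT -1"`.
#' @param pair Integer pair `c(k1, k2)` of monomer indices.
#' @param dmin,dmax Spacing range of the table.
#' @param pruned Character vector of pruned `"o d"` cells.
#' @param orientations Orientations to include; defaults to the homodimer
#'   set `HT, HH, TT` when `k1 == k2`, all four otherwise.
#' @return A tibble of class `cob_table` with columns `orientation`, `d`,
#'   `lambda`, `display`, `pruned`.
#' @export
assemble_cob <- function(lambda, pair, dmin, dmax, pruned = character(),
                         orientations = NULL) {
  if (any(lambda < 0)) stop("mixing weights must be nonnegative")
  if (is.null(orientations)) {
    orientations <- if (pair[1] == pair[2]) c("HT", "HH", "TT") else
      ORIENTATIONS
  }
  grid <- tidyr::expand_grid(orientation = orientations, d = dmin:dmax)
  key <- paste(grid$orientation, grid$d)
  lam <- unname(lambda[key])
  lam[key %in% pruned] <- NA_real_
  out <- tibble::tibble(
    k1 = pair[1], k2 = pair[2],
    orientation = grid$orientation, d = grid$d,
    lambda = lam,
    display = ifelse(is.na(lam), NA_real_, floor(lam / 0.001 + 0.5)),
    pruned = key %in% pruned
  )
  class(out) <- c("cob_table", class(out))
  out
}
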