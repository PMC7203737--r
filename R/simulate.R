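#' Simulate reads from an ADM mixture (ZOOPS generative process)
#'
#' Each read picks a mixture component by its weight (background-only with
#' probability `lambda0`). For a motif component an instance is sampled
#' from its (composed) ADM, reverse-complemented with probability 1/2
#' (fair-coin strand), placed at a uniformly random admissible start, and
#' the remaining positions are filled from the background model. The
#' ground-truth placement of every read is logged.
#'
#' @param model A `mixture_model`; every component must fit in `L`.
#' @param n Number of reads (>= 1).
#' @param L Read length.
#' @param seed Optional RNG seed; the same seed reproduces the identical
#'   read set.
#' @return A list with `reads` (character vector) and `truth` (tibble:
#'   `read`, `component`, `start`, `strand`; background-only reads have
#'   `component = "background"`).
#' @export
#' @examples
#' m <- mixture_model(background_model(), list(seed_to_adm("TAATGG")), 0.4)
#' sim <- generate_reads(m, 100, 20, seed = 1)
#' table(sim$truth$component)
generate_reads <- function(model, n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  comps <- flatten_model(model)
  lens <- vapply(comps, `[[`, 0, "len")
  if (any(lens > L)) {
    stop("component(s) longer than the read length L = ", L, ": ",
         paste(vapply(comps, `[[`, "", "key")[lens > L], collapse = ", "))
  }
  probs <- c(model$lambda0, vapply(comps, `[[`, 0, "lambda"))
  assignment <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  bg_adm <- bg_as_adm(model$background, L)
  codes <- sample_adm(bg_adm, n)
  truth <- tibble::tibble(
    read = seq_len(n), component = "background",
    start = NA_integer_, strand = NA_character_
  )
  for (ci in seq_along(comps)) {
    idx <- which(assignment == ci + 1)
    if (length(idx) == 0) next
    comp <- comps[[ci]]
    inst <- sample_adm(comp$tau, length(idx))
    minus <- stats::runif(length(idx)) < 0.5
    if (any(minus)) {
      inst[minus, ] <- comp_codes(inst[minus, rev(seq_len(comp$len)),
                                       drop = FALSE])
    }
    start <- sample.int(L - comp$len + 1, length(idx), replace = TRUE)
    for (t in seq_len(comp$len)) {
      codes[cbind(idx, start + t - 1)] <- inst[, t]
    }
    truth$component[idx] <- comp$key
    truth$start[idx] <- start
    truth$strand[idx] <- ifelse(minus, "-", "+")
  }
  reads <- apply(codes, 1, function(v) paste(DNA_BASES[v], collapse = ""))
  list(reads = reads, truth = truth)
}

#' Build the homodimer sanity-check mixture
#'
#' Constructs, around one monomer ADM, a mixture of homodimer components at
#' given orientations/spacings whose dimeric ADMs are the expected
#' (independence) models, optionally perturbed by hand-specified deviations
#' added to the bridging window. The weight profile is scaled so the total
#' signal fraction (1 - lambda0) matches `total_signal`.
#'
#' @param monomer A monomer `adm`.
#' @param specs Tibble/data frame with columns `orientation`, `d`,
#'   `lambda` (weights on the scale at which they are quoted; rescaled to
#'   `total_signal`).
#' @param total_signal Total non-background fraction; `NULL` keeps the
#'   quoted weights as is.
#' @param deviations Optional named list (`"o d"`, e.g. `"HH 2"`) of
#'   4 x 4 x (`|d|`+2) deviation arrays added to the expected bridging
#'   slice; an error is raised if any probability leaves the unit interval.
#' @param delta Independence threshold (default 4).
#' @param bg Background model (default uniform).
#' @return A `mixture_model` (monomer weight 0: all signal is dimeric,
#'   matching the sanity-check design).
#' @export
build_sanity_model <- function(monomer, specs, total_signal = NULL,
                               deviations = NULL, delta = 4,
                               bg = background_model()) {
  specs <- tibble::as_tibble(specs)
  lam <- specs$lambda
  if (!is.null(total_signal)) lam <- lam * total_signal / sum(lam)
  rows <- list()
  for (r in seq_len(nrow(specs))) {
    o <- specs$orientation[r]
    d <- specs$d[r]
    psi <- NULL
    if (d < delta) {
      psi <- expected_bridge(monomer, monomer, o, d, bg)
      key <- paste(o, d)
      if (!is.null(deviations) && key %in% names(deviations)) {
        kap <- deviations[[key]]
        if (length(dim(kap)) != 3 || !all(dim(kap) == dim(psi))) {
          stop("deviation for ", key, " has the wrong shape")
        }
        psi <- psi + kap
        if (any(psi < -1e-12) || any(psi > 1 + 1e-12)) {
          stop("deviation for ", key,
               " pushes probabilities outside [0, 1]")
        }
        rs <- apply(psi, c(1, 3), sum)
        if (any(abs(rs - 1) > 1e-9)) {
          stop("deviation conditional blocks for ", key,
               " must sum to zero")
        }
      }
    }
    rows[[r]] <- tibble::tibble(
      k1 = 1L, k2 = 1L, orientation = o, d = d, lambda = lam[r],
      psi = list(psi)
    )
  }
  mixture_model(bg, list(monomer), 0, dplyr::bind_rows(rows), delta = delta)
}

#' A synthetic HOXB13-like monomer ADM
#'
#' A deterministic, clearly synthetic stand-in for a HOXB13 monomer motif
#' built from the seed `CYMRTAAAA`: invariant positions carry the
#' consensus base at weight `sharp`; degenerate (Y/M/R) positions carry a
#' preference ordering (`primary` for the consensus-path base, `secondary`
#' for the alternative allowed base), as matrices learned from HT-SELEX
#' show in practice rather than an even split; and explicit first-order
#' couplings at the degenerate positions (e.g. a C at the Y position
#' favours A at the M position) give the model genuine dinucleotide
#' dependence. It is not a matrix estimated from SELEX data; use
#' [read_adm()] to load a real matrix where one is available.
#'
#' @param seed IUPAC seed (default `"CYMRTAAAA"`).
#' @param primary,secondary Weights of the preferred / alternative allowed
#'   base at two-fold degenerate positions (defaults 0.60, 0.26).
#' @param sharp Weight of the consensus base at invariant positions
#'   (default 0.94).
#' @return An `adm` of length `nchar(seed)`.
#' @export
hoxb13_standin_adm <- function(seed = "CYMRTAAAA", primary = 0.60,
                               secondary = 0.26, sharp = 0.94) {
  base <- seed_to_adm(seed, name = "HOXB13_standin_synthetic")
  trans <- base$trans
  l <- base$length
  ch <- strsplit(toupper(seed), "", fixed = TRUE)[[1]]
  rest2 <- (1 - primary - secondary) / 2
  deg_col <- function(h) {
    allowed <- match(IUPAC_CODES[[ch[h]]], DNA_BASES)
    v <- rep(rest2, 4)
    v[allowed] <- c(primary, secondary)
    v
  }
  for (h in seq_len(l)) {
    if (ch[h] %in% DNA_BASES) {
      v <- rep((1 - sharp) / 3, 4)
      v[match(ch[h], DNA_BASES)] <- sharp
      trans[, , h] <- matrix(v, 4, 4, byrow = TRUE)
    } else if (length(IUPAC_CODES[[ch[h]]]) == 2) {
      trans[, , h] <- matrix(deg_col(h), 4, 4, byrow = TRUE)
    }
  }
  couple <- function(h, prev_base, fav) {
    # after `prev_base`, the favoured allowed base takes the primary weight
    allowed <- match(IUPAC_CODES[[ch[h]]], DNA_BASES)
    v <- rep(rest2, 4)
    v[allowed] <- c(primary, secondary)[order(allowed != fav)]
    trans[prev_base, , h] <<- v
  }
  if (l >= 4 && ch[2] == "Y" && ch[3] == "M" && ch[4] == "R") {
    couple(3, prev_base = 2, fav = 1)  # C at Y -> favour A at M
    couple(3, prev_base = 4, fav = 2)  # T at Y -> favour C at M
    couple(4, prev_base = 1, fav = 3)  # A at M -> favour G at R
    couple(4, prev_base = 2, fav = 1)  # C at M -> favour A at R
  }
  adm(trans[1, , 1], trans, name = "HOXB13_standin_synthetic")
}

#' The published homodimer sanity-check weight profile
#'
#' The generating mixture of the sanity experiment: uniform background and
#' homodimers HT 4, HH 4, HH 2, TT 2, HH 5 with weights 0.061, 0.055,
#' 0.068, 0.034, 0.082 at total signal fraction 0.30 (rescalable to 0.03
#' or 0.90).
#'
#' @return Tibble with columns `orientation`, `d`, `lambda`.
#' @export
sanity_profile <- function() {
  tibble::tibble(
    orientation = c("HT", "HH", "HH", "TT", "HH"),
    d = c(4L, 4L, 2L, 2L, 5L),
    lambda = c(0.061, 0.055, 0.068, 0.034, 0.082)
  )
}

#' Two close monomer motifs at a given signal fraction
#'
#' A two-monomer mixture (no dimers) whose consensus sequences are a small
#' Hamming distance apart, each at monomer fraction `f`; used to study when
#' a small Hamming radius helps the EM separate similar motifs at low
#' signal.
#'
#' @param f Monomer fraction in (0, 0.5]; `lambda0 = 1 - 2 f`.
#' @param seeds Two seed strings (defaults 2 mismatches apart).
#' @param match_weight Sharpness of the generating profiles (default 0.9).
#' @return A `mixture_model` with two monomers.
#' @export
two_motif_fixture <- function(f, seeds = c("CACGTGAT", "CACGCGTT"),
                              match_weight = 0.9) {
  if (f <= 0 || f > 0.5) stop("f must be in (0, 0.5]")
  monomers <- lapply(seeds, seed_to_adm, match_weight = match_weight)
  mixture_model(background_model(), monomers, c(f, f))
}
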