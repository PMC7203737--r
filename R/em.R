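#' Training configuration for the ZOOPS mixture EM
#'
#' Defaults follow the method's published settings: spacing interval
#' `[-floor(min(l1, l2) / 2), 10]` per pair, independence threshold
#' `delta = 4`, `maxiter = 150`, convergence threshold `epsilon = 0.001`
#' on the weighted maximum norm between consecutive models, and Hamming
#' radius `rho = 3` for ADMs (2 is the order-zero default).
#'
#' @param pairs List of integer pairs `c(k1, k2)` of monomer indices whose
#'   dimers are learned (the set R); empty list = monomeric mode.
#' @param dmin,dmax Optional spacing bounds; a single value applies to all
#'   pairs, `NULL` uses the default interval per pair.
#' @param delta Minimum spacing at which monomers in a dimer are modeled as
#'   independent (default 4).
#' @param maxiter Maximum EM iterations (default 150).
#' @param epsilon Convergence threshold on consecutive-model distance
#'   (default 0.001).
#' @param rho Hamming radius restricting M-step counts to placements near
#'   the current consensus (default 3; `Inf` disables).
#' @param prune_threshold Dimers with mixing weight below this are removed
#'   permanently, starting at iteration `prune_start` (defaults 1e-4, 3).
#' @param prune_start First iteration at which weak dimers are pruned.
#' @param pseudocount Added per count cell in every re-estimation
#'   (default 0.01).
#' @param match_weight Seed initialization weight for allowed bases
#'   (default 0.8).
#' @param background Initial `bg_model` (default uniform order 0).
#' @param estimate_background Re-estimate the (order-0) background marginal
#'   from posterior-weighted non-motif positions each M-step
#'   (default TRUE). Order-1 backgrounds are kept fixed.
#' @param orientations_homo Orientations used for homodimers (default
#'   `HT, HH, TT`; `TH` duplicates `HT` by strand symmetry but can be
#'   forced here).
#' @param lambda0_init Initial background weight (default 0.5); the
#'   remainder is spread uniformly over live components.
#' @param flanks Character pair of constant flank sequences prepended /
#'   appended to every read (default none). Motif placements may extend
#'   into flanks; flank positions are excluded from background
#'   re-estimation.
#' @param seed Optional RNG seed recorded in the config (the EM itself is
#'   deterministic; the seed is for simulation helpers).
#' @return A list of class `em_config`.
#' @export
em_config <- function(pairs = list(), dmin = NULL, dmax = NULL, delta = 4,
                      maxiter = 150, epsilon = 0.001, rho = 3,
                      prune_threshold = 1e-4, prune_start = 3,
                      pseudocount = 0.01, match_weight = 0.8,
                      background = background_model(),
                      estimate_background = TRUE,
                      orientations_homo = c("HT", "HH", "TT"),
                      lambda0_init = 0.5, flanks = c("", ""), seed = NULL) {
  structure(as.list(environment()), class = "em_config")
}

# ---- scoring ---------------------------------------------------------------

# Score every live component against every read placement. Returns log
# posterior numerators (Tp/Tm per component), the background term, and the
# per-read admissible placement counts.
score_components <- function(model, enc, comps = flatten_model(model)) {
  bt <- bg_read_tables(model$background, enc)
  flank_cache <- new.env()
  flank_mat <- function(len) {
    key <- as.character(len)
    if (is.null(flank_cache[[key]])) {
      npos <- enc$Lmax - len + 1
      Fm <- matrix(-Inf, enc$n, npos)
      for (j in seq_len(npos)) Fm[, j] <- bg_flank_logprob(bt, enc, j, len)
      flank_cache[[key]] <- Fm
    }
    flank_cache[[key]]
  }
  Tp <- vector("list", length(comps))
  Tm <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    if (comp$len > max(enc$lens)) {
      stop("component ", comp$key, " (length ", comp$len,
           ") is longer than the longest read (", max(enc$lens), ")")
    }
    tau <- comp$tau
    rc <- suppressWarnings(reverse_complement_adm(tau))
    Sp <- cpp_window_logprob(enc$codes_t, enc$lens, log(tau$init),
                             log(tau$trans), comp$len)
    Sm <- cpp_window_logprob(enc$codes_t, enc$lens, log(rc$init),
                             log(rc$trans), comp$len)
    Ni <- rowSums(is.finite(Sp)) + rowSums(is.finite(Sm))
    Fm <- flank_mat(comp$len)
    lamterm <- ifelse(Ni > 0, log(comp$lambda) - log(Ni), -Inf)
    Tp[[ci]] <- Sp + Fm + lamterm
    Tm[[ci]] <- Sm + Fm + lamterm
  }
  list(Tp = Tp, Tm = Tm,
       bgterm = log(model$lambda0) + bt$lp_full,
       comps = comps)
}

rowmax_mat <- function(m) {
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' ZOOPS E-step: posterior placement table
#'
#' Computes, for every read, the posterior distribution over (component,
#' start, strand) placements and the background-only alternative under the
#' zero-or-one-occurrence-per-sequence model: a placement's mass is
#' proportional to `lambda_k / N_ik * P_bg(flanks) * P_k(window)`, the
#' background-only mass to `lambda0 * P_bg(read)`.
#'
#' @param model A `mixture_model`.
#' @param reads Character vector of reads, or the result of a previous
#'   `e_step()`'s `$enc` (re-used internally).
#' @return A `posterior_table`: per-component plus/minus posterior weight
#'   matrices, the background-only weights, the data log-likelihood of
#'   `model`, and the encoded reads.
#' @export
e_step <- function(model, reads) {
  enc <- if (is.list(reads) && !is.null(reads$codes)) reads else
    encode_reads(reads)
  comps <- flatten_model(model)
  sc <- score_components(model, enc, comps)
  M <- sc$bgterm
  for (ci in seq_along(comps)) {
    M <- pmax(M, rowmax_mat(sc$Tp[[ci]]), rowmax_mat(sc$Tm[[ci]]))
  }
  denom <- exp(sc$bgterm - M)
  Wp <- vector("list", length(comps))
  Wm <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    Wp[[ci]] <- exp(sc$Tp[[ci]] - M)
    Wm[[ci]] <- exp(sc$Tm[[ci]] - M)
    denom <- denom + rowSums(Wp[[ci]]) + rowSums(Wm[[ci]])
  }
  w_bg <- exp(sc$bgterm - M) / denom
  for (ci in seq_along(comps)) {
    Wp[[ci]] <- Wp[[ci]] / denom
    Wm[[ci]] <- Wm[[ci]] / denom
  }
  structure(list(
    keys = vapply(comps, `[[`, "", "key"),
    comps = comps, Wp = Wp, Wm = Wm, w_bg = w_bg,
    loglik = sum(M + log(denom)), enc = enc
  ), class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat("ZOOPS posterior table:", length(x$w_bg), "reads,",
      length(x$keys), "components; log-likelihood", round(x$loglik, 2), "\n")
  invisible(x)
}

#' Tidy a posterior table
#'
#' @param x A `posterior_table`.
#' @param min_mass Placements with posterior below this are dropped
#'   (default 0.01) to keep the tibble manageable.
#' @param ... Unused.
#' @return Tibble with columns `read`, `component`, `start`, `strand`,
#'   `posterior` (background-only rows have `component = "background"`).
#' @export
tidy.posterior_table <- function(x, min_mass = 0.01, ...) {
  out <- list(tibble::tibble(
    read = seq_along(x$w_bg), component = "background",
    start = NA_integer_, strand = NA_character_, posterior = x$w_bg
  ))
  for (ci in seq_along(x$keys)) {
    for (sgn in c("+", "-")) {
      W <- if (sgn == "+") x$Wp[[ci]] else x$Wm[[ci]]
      idx <- which(W >= min_mass, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          read = idx[, 1], component = x$keys[ci],
          start = idx[, 2], strand = sgn, posterior = W[idx]
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$read,
                 dplyr::desc(.data$posterior))
}

#' Data log-likelihood of a mixture model
#'
#' @param model A `mixture_model`.
#' @param reads Character vector of reads.
#' @return Scalar log-likelihood under the ZOOPS mixture.
#' @export
log_likelihood <- function(model, reads) {
  e_step(model, reads)$loglik
}

# ---- Hamming restriction ---------------------------------------------------

#' Restrict posteriors to the Hamming neighborhood of the consensus
#'
#' Placements whose window is more than `rho` mismatches from the current
#' consensus of their component lose their posterior mass before the
#' M-step; for dimers the rule applies per half-site (each half compared to
#' its oriented monomer's consensus with radius `rho`). The remaining mass
#' of each read is renormalized; reads with no surviving placement become
#' background-only. `rho = Inf` is a no-op.
#'
#' @param posteriors A `posterior_table` from [e_step()].
#' @param model The `mixture_model` that produced it.
#' @param rho Hamming radius (>= 0, or `Inf`).
#' @return A filtered `posterior_table`.
#' @export
hamming_filter <- function(posteriors, model, rho) {
  if (is.infinite(rho)) return(posteriors)
  if (rho < 0) stop("rho must be >= 0 or Inf")
  enc <- posteriors$enc
  cons_codes <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]],
                                  DNA_BASES)
  for (ci in seq_along(posteriors$comps)) {
    comp <- posteriors$comps[[ci]]
    if (comp$kind == "monomer") {
      cs <- consensus(comp$tau)
      dp <- cpp_window_hamming(enc$codes_t, enc$lens, cons_codes(cs), 0L,
                               comp$len)
      dm <- cpp_window_hamming(enc$codes_t, enc$lens,
                               cons_codes(revcomp(cs)), 0L, comp$len)
      keep_p <- !is.na(dp) & dp <= rho
      keep_m <- !is.na(dm) & dm <= rho
    } else {
      op <- orient_pair(model$monomers[[comp$k1]],
                        model$monomers[[comp$k2]], comp$o)
      c1 <- consensus(op[[1]])
      c2 <- consensus(op[[2]])
      M <- comp$len
      l1 <- comp$l1; l2 <- comp$l2
      d1p <- cpp_window_hamming(enc$codes_t, enc$lens, cons_codes(c1), 0L, M)
      d2p <- cpp_window_hamming(enc$codes_t, enc$lens, cons_codes(c2),
                                as.integer(M - l2), M)
      d1m <- cpp_window_hamming(enc$codes_t, enc$lens,
                                cons_codes(revcomp(c1)),
                                as.integer(M - l1), M)
      d2m <- cpp_window_hamming(enc$codes_t, enc$lens,
                                cons_codes(revcomp(c2)), 0L, M)
      keep_p <- !is.na(d1p) & d1p <= rho & d2p <= rho
      keep_m <- !is.na(d1m) & d1m <= rho & d2m <= rho
    }
    posteriors$Wp[[ci]][!keep_p] <- 0
    posteriors$Wm[[ci]][!keep_m] <- 0
  }
  tot <- posteriors$w_bg
  for (ci in seq_along(posteriors$comps)) {
    tot <- tot + rowSums(posteriors$Wp[[ci]]) + rowSums(posteriors$Wm[[ci]])
  }
  dead <- tot <= 0
  if (any(dead)) {
    posteriors$w_bg[dead] <- 1
    tot[dead] <- 1
  }
  posteriors$w_bg <- posteriors$w_bg / tot
  for (ci in seq_along(posteriors$comps)) {
    posteriors$Wp[[ci]] <- posteriors$Wp[[ci]] / tot
    posteriors$Wm[[ci]] <- posteriors$Wm[[ci]] / tot
  }
  posteriors
}

# ---- M-step ----------------------------------------------------------------

#' ZOOPS M-step: re-estimate all model parameters
#'
#' Mixing weights are posterior averages. Monomer ADMs are re-estimated
#' from monomeric placements and from half-sites of dimers whose spacing is
#' at least `delta` (isolated occurrences) - never from half-sites of
#' closer dimers, whose windows feed only the bridging components. In the
#' monomeric mode (no dimers) monomers use all their placements.
#' Minus-strand windows are reverse-complemented into motif coordinates
#' before counting. The (order-0) background marginal is re-estimated from
#' posterior-weighted non-motif positions plus the gap columns of
#' independent dimers.
#'
#' @param posteriors A (possibly Hamming-filtered) `posterior_table`; its
#'   weights drive the matrix re-estimation.
#' @param model The current `mixture_model`.
#' @param config An `em_config` (pseudocount, background options, flanks).
#' @param lambda_table Optional `posterior_table` whose weights drive the
#'   mixing-weight update instead; the Hamming restriction applies to the
#'   learning of the matrices, so [run_em()] passes the unfiltered
#'   posteriors here while the matrices use the filtered ones. Default:
#'   `posteriors`.
#' @return The updated `mixture_model`.
#' @export
m_step <- function(posteriors, model, config = em_config(),
                   lambda_table = NULL) {
  enc <- posteriors$enc
  n <- enc$n
  pc <- config$pseudocount
  comps <- posteriors$comps
  if (is.null(lambda_table)) lambda_table <- posteriors
  counts <- vector("list", length(comps))
  lam <- numeric(length(comps))
  for (ci in seq_along(comps)) {
    counts[[ci]] <- cpp_accumulate_counts(enc$codes_t, enc$lens,
                                          posteriors$Wp[[ci]],
                                          posteriors$Wm[[ci]],
                                          comps[[ci]]$len)
    lam[ci] <- sum(lambda_table$Wp[[ci]]) + sum(lambda_table$Wm[[ci]])
  }
  lam <- lam / n

  p <- length(model$monomers)
  mono_init <- lapply(seq_len(p), function(k) numeric(4))
  mono_pairs <- lapply(seq_len(p), function(k) {
    array(0, c(4, 4, model$monomers[[k]]$length))
  })
  add_fragment <- function(k, fi, fp) {
    mono_init[[k]] <<- mono_init[[k]] + fi
    mono_pairs[[k]] <<- mono_pairs[[k]] + fp
  }
  col_marginal <- function(cnt, col) {
    if (col == 1) cnt$init else colSums(cnt$pairs[, , col])
  }
  half_fragment <- function(cnt, start, l) {
    fp <- array(0, c(4, 4, l))
    if (l >= 2) fp[, , 2:l] <- cnt$pairs[, , (start + 1):(start + l - 1)]
    list(init = col_marginal(cnt, start), pairs = fp,
         last = col_marginal(cnt, start + l - 1))
  }
  new_dimers <- model$dimers
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    cnt <- counts[[ci]]
    if (comp$kind == "monomer") {
      add_fragment(comp$k, cnt$init, cnt$pairs)
    } else {
      ri <- which(new_dimers$k1 == comp$k1 & new_dimers$k2 == comp$k2 &
                    new_dimers$orientation == comp$o & new_dimers$d == comp$d)
      new_dimers$lambda[ri] <- lam[ci]
      if (comp$independent) {
        f1 <- half_fragment(cnt, 1, comp$l1)
        if (comp$rc1) {
          rcc <- rc_counts(f1$init, f1$pairs, f1$last)
          add_fragment(comp$k1, rcc$init, rcc$pairs)
        } else add_fragment(comp$k1, f1$init, f1$pairs)
        f2 <- half_fragment(cnt, comp$half2[1], comp$l2)
        if (comp$rc2) {
          rcc <- rc_counts(f2$init, f2$pairs, f2$last)
          add_fragment(comp$k2, rcc$init, rcc$pairs)
        } else add_fragment(comp$k2, f2$init, f2$pairs)
      } else {
        # close / overlapping dimer: update its bridging component only
        bw <- comp$bridge
        w <- unname(bw["end"] - bw["start"] + 1)
        psi <- array(0, c(4, 4, w))
        for (j in seq_len(w)) {
          col <- bw["start"] + j - 1
          if (col == 1) {
            v <- cnt$init + pc
            psi[, , j] <- matrix(v / sum(v), 4, 4, byrow = TRUE)
          } else {
            m <- cnt$pairs[, , col] + pc
            psi[, , j] <- m / rowSums(m)
          }
        }
        new_dimers$psi[[ri]] <- psi
      }
    }
  }

  new_monomers <- model$monomers
  mono_lambda <- lam[vapply(comps, function(c) c$kind == "monomer",
                            logical(1))]
  for (k in seq_len(p)) {
    tot <- sum(mono_init[[k]])
    if (tot <= 1e-12) {
      warning("monomer ", k, " received no counts; uniform re-initialization")
      new_monomers[[k]] <- uniform_adm(model$monomers[[k]]$length,
                                       name = model$monomers[[k]]$name)
    } else {
      new_monomers[[k]] <- adm_from_counts(mono_init[[k]], mono_pairs[[k]],
                                           pseudocount = pc,
                                           name = model$monomers[[k]]$name)
    }
  }

  bg <- model$background
  if (isTRUE(config$estimate_background) && bg$order == 0) {
    fl <- nchar(config$flanks[1])
    fr <- nchar(config$flanks[2])
    keep <- matrix(TRUE, n, enc$Lmax)
    if (fl > 0) keep[, seq_len(fl)] <- FALSE
    for (i in seq_len(n)) {
      if (enc$lens[i] < enc$Lmax) keep[i, (enc$lens[i] + 1):enc$Lmax] <- FALSE
      if (fr > 0) keep[i, (enc$lens[i] - fr + 1):enc$lens[i]] <- FALSE
    }
    cod <- enc$codes[keep]
    total <- tabulate(cod[cod > 0], nbins = 4)
    covered <- numeric(4)
    gapadd <- numeric(4)
    for (ci in seq_along(comps)) {
      covered <- covered + counts[[ci]]$base_read
      for (g in comps[[ci]]$gapcols) {
        gapadd <- gapadd + colSums(counts[[ci]]$pairs[, , g])
      }
    }
    bgc <- pmax(total - covered, 0) + gapadd + pc
    bg <- background_model(bgc / sum(bgc))
  }

  mixture_model(bg, new_monomers, mono_lambda, new_dimers,
                delta = model$delta, pruned = model$pruned)
}

# ---- pruning and the driver ------------------------------------------------

#' Remove weak dimers from a mixture
#'
#' Dimer components whose mixing weight fell below `threshold` are removed
#' permanently (recorded as pruned for COB reporting); their weight is
#' reassigned to the background. Monomers are never pruned.
#'
#' @param model A `mixture_model`.
#' @param threshold Nonnegative weight threshold.
#' @return The pruned `mixture_model`.
#' @export
prune_weak_dimers <- function(model, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (nrow(model$dimers) == 0) return(model)
  weak <- model$dimers$lambda < threshold
  if (!any(weak)) return(model)
  newly <- dplyr::select(model$dimers[weak, ], "k1", "k2", "orientation", "d")
  mixture_model(model$background, model$monomers, model$lambda_mono,
                model$dimers[!weak, ], delta = model$delta,
                pruned = dplyr::bind_rows(model$pruned, newly))
}

default_spacing <- function(l1, l2) c(-floor(min(l1, l2) / 2), 10)

# Candidate dimer grid for a config + monomer set, psi initialized to the
# expected slices (zero deviation).
init_dimer_grid <- function(monomers, config, bg) {
  rows <- list()
  for (pair in config$pairs) {
    k1 <- pair[1]; k2 <- pair[2]
    l1 <- monomers[[k1]]$length
    l2 <- monomers[[k2]]$length
    sp <- default_spacing(l1, l2)
    dmin <- if (is.null(config$dmin)) sp[1] else config$dmin
    dmax <- if (is.null(config$dmax)) sp[2] else config$dmax
    if (dmin <= -min(l1, l2)) {
      stop("dmin must exceed -min(l1, l2) for pair ", k1, ",", k2)
    }
    ors <- if (k1 == k2) config$orientations_homo else ORIENTATIONS
    for (o in ors) for (d in dmin:dmax) {
      psi <- if (d < config$delta) {
        expected_bridge(monomers[[k1]], monomers[[k2]], o, d, bg)
      } else NULL
      rows[[length(rows) + 1]] <- tibble::tibble(
        k1 = k1, k2 = k2, orientation = o, d = d, lambda = 0,
        psi = list(psi)
      )
    }
  }
  if (length(rows) == 0) NULL else dplyr::bind_rows(rows)
}

#' Learn an ADM mixture model by seed-initialized ZOOPS EM
#'
#' Initializes monomer ADMs from IUPAC seeds, builds the candidate dimer
#' grid from the configured monomer pairs, and iterates E-step, Hamming
#' restriction, M-step and weak-dimer pruning until the weighted maximum
#' norm between consecutive models drops below `epsilon` or `maxiter` is
#' reached.
#'
#' @param reads Character vector of DNA reads (see [read_sequences()]).
#' @param seeds Character vector of IUPAC seeds, one per monomer motif.
#' @param config An [em_config()].
#' @param verbose Print a per-iteration summary line (default FALSE).
#' @return An object of class `adm_fit`: the final `mixture_model`
#'   (`$model`), the per-iteration trace tibble (`$trace`: iteration,
#'   loglik, distance, n_components, lambda0), the config, convergence
#'   flag and iteration count.
#' @export
run_em <- function(reads, seeds, config = em_config(), verbose = FALSE) {
  if (nzchar(config$flanks[1]) || nzchar(config$flanks[2])) {
    reads <- paste0(toupper(config$flanks[1]), toupper(reads),
                    toupper(config$flanks[2]))
  }
  enc <- encode_reads(reads)
  monomers <- lapply(seeds, seed_to_adm, match_weight = config$match_weight)
  if (any(vapply(monomers, `[[`, 0, "length") > max(enc$lens))) {
    stop("every seed must be shorter than the read length")
  }
  bg <- config$background
  dimers <- init_dimer_grid(monomers, config, bg)
  ncomp <- length(monomers) + if (is.null(dimers)) 0 else nrow(dimers)
  lam_each <- (1 - config$lambda0_init) / ncomp
  if (!is.null(dimers)) dimers$lambda <- lam_each
  model <- mixture_model(bg, monomers, rep(lam_each, length(monomers)),
                         dimers, delta = config$delta)
  trace <- list()
  converged <- FALSE
  iter <- 0
  while (iter < config$maxiter) {
    iter <- iter + 1
    post <- e_step(model, enc)
    postf <- hamming_filter(post, model, config$rho)
    new_model <- m_step(postf, model, config, lambda_table = post)
    if (iter >= config$prune_start) {
      new_model <- prune_weak_dimers(new_model, config$prune_threshold)
    }
    dist <- model_distance(model, new_model, strict = FALSE)
    trace[[iter]] <- tibble::tibble(
      iteration = iter, loglik = post$loglik, distance = dist,
      n_components = length(new_model$monomers) + nrow(new_model$dimers),
      lambda0 = new_model$lambda0
    )
    if (verbose) {
      message(sprintf("iter %3d  loglik %.2f  distance %.5f  comps %d",
                      iter, post$loglik, dist, trace[[iter]]$n_components))
    }
    model <- new_model
    if (dist < config$epsilon) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    model = model, trace = dplyr::bind_rows(trace), config = config,
    seeds = seeds, converged = converged, iterations = iter
  ), class = "adm_fit")
}

#' @export
print.adm_fit <- function(x, ...) {
  cat("ADM mixture fit:", x$iterations, "iterations,",
      if (x$converged) "converged" else "not converged",
      "- final log-likelihood",
      round(utils::tail(x$trace$loglik, 1), 2), "\n")
  print(x$model)
  invisible(x)
}

#' Select the strongest submodel covering a signal fraction
#'
#' Components are added in decreasing order of mixing weight until the
#' selected weights cover at least `fraction` of the total non-background
#' signal (default 85%). Ties prefer monomers, then lexicographic order.
#' Selected weights keep their original values; the background absorbs the
#' remainder.
#'
#' @param model A `mixture_model`.
#' @param fraction Signal fraction threshold in (0, 1] (default 0.85).
#' @return The reduced `mixture_model`, with attribute `"selected"` (keys)
#'   and `"signal_covered"`.
#' @export
select_submodel <- function(model, fraction = 0.85) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  comp <- tibble::tibble(
    key = c(paste0("monomer", seq_along(model$monomers)),
            if (nrow(model$dimers) > 0)
              dimer_key(model$dimers$k1, model$dimers$k2,
                        model$dimers$orientation, model$dimers$d)),
    kind = c(rep("monomer", length(model$monomers)),
             rep("dimer", nrow(model$dimers))),
    lambda = c(model$lambda_mono, model$dimers$lambda)
  )
  total <- sum(comp$lambda)
  if (total <= 0) return(model)
  comp <- dplyr::arrange(comp, dplyr::desc(.data$lambda),
                         .data$kind != "monomer", .data$key)
  cum <- cumsum(comp$lambda) / total
  ntake <- which(cum >= fraction)[1]
  sel <- comp$key[seq_len(ntake)]
  mono_sel <- paste0("monomer", seq_along(model$monomers)) %in% sel
  dim_keep <- if (nrow(model$dimers) > 0) {
    dimer_key(model$dimers$k1, model$dimers$k2, model$dimers$orientation,
              model$dimers$d) %in% sel
  } else logical(0)
  out <- mixture_model(model$background, model$monomers,
                       ifelse(mono_sel, model$lambda_mono, 0),
                       model$dimers[dim_keep, ], delta = model$delta,
                       pruned = model$pruned)
  attr(out, "selected") <- sel
  attr(out, "signal_covered") <- cum[ntake]
  out
}
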