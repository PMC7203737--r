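#' Mixture model of monomeric and dimeric motifs
#'
#' The full motif model: a background model, `p` monomer ADMs, bridging
#' components for every close/overlapping dimer in the candidate set, and
#' mixing weights over monomers, dimers and background
#' (`lambda0 = 1 - sum(lambda)`).
#'
#' @param background A `bg_model`.
#' @param monomers List of monomer `adm`s.
#' @param lambda_mono Numeric vector of monomer mixing weights (one per
#'   monomer; may be zero).
#' @param dimers A tibble (or data frame) with columns `k1`, `k2`,
#'   `orientation`, `d`, `lambda`, and a list column `psi` holding the
#'   4 x 4 x (`|d|`+2) bridging conditionals for `d < delta` rows (`NULL`
#'   otherwise). May be `NULL`/empty for the monomeric mode.
#' @param delta Independence threshold for spacings (default 4).
#' @param pruned Tibble of pruned dimer specs (columns `k1, k2,
#'   orientation, d`), kept for COB reporting.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(background, monomers, lambda_mono,
                          dimers = NULL, delta = 4, pruned = NULL) {
  stopifnot(inherits(background, "bg_model"))
  if (length(monomers) != length(lambda_mono)) {
    stop("one mixing weight per monomer is required")
  }
  if (is.null(dimers) || nrow(dimers) == 0) {
    dimers <- tibble::tibble(
      k1 = integer(), k2 = integer(), orientation = character(),
      d = integer(), lambda = numeric(), psi = list()
    )
  } else {
    dimers <- tibble::as_tibble(dimers)
    if (!"psi" %in% names(dimers)) dimers$psi <- vector("list", nrow(dimers))
    p <- length(monomers)
    if (any(dimers$k1 > p | dimers$k2 > p)) {
      stop("dimer spec references a monomer index beyond ", p)
    }
    need <- dimers$d < delta
    if (any(need & vapply(dimers$psi, is.null, logical(1)))) {
      stop("bridging psi required for every dimer with d < delta")
    }
  }
  if (is.null(pruned)) {
    pruned <- tibble::tibble(k1 = integer(), k2 = integer(),
                             orientation = character(), d = integer())
  }
  lam_sum <- sum(lambda_mono) + sum(dimers$lambda)
  if (lam_sum > 1 + 1e-9 || any(lambda_mono < 0) || any(dimers$lambda < 0)) {
    stop("mixing weights must be nonnegative and sum to at most 1")
  }
  structure(list(
    background = background,
    monomers = monomers,
    lambda_mono = as.numeric(lambda_mono),
    dimers = dimers,
    delta = delta,
    lambda0 = 1 - lam_sum,
    pruned = pruned
  ), class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("ADM mixture model:", length(x$monomers), "monomer(s),",
      nrow(x$dimers), "dimer(s), lambda0 =", round(x$lambda0, 4), "\n")
  invisible(x)
}

dimer_key <- function(k1, k2, o, d) paste0(k1, ",", k2, ",", o, ",", d)

# Flatten a mixture into scannable components: for each live component its
# key, composed ADM tau, mixing weight, and bookkeeping used by the M-step
# (half-site windows, gap columns, bridging window, orientation flags).
flatten_model <- function(model) {
  comps <- list()
  for (k in seq_along(model$monomers)) {
    th <- model$monomers[[k]]
    comps[[length(comps) + 1]] <- list(
      key = paste0("monomer", k), kind = "monomer", k = k,
      lambda = model$lambda_mono[k], tau = th, len = th$length
    )
  }
  if (nrow(model$dimers) > 0) {
    for (r in seq_len(nrow(model$dimers))) {
      sp <- model$dimers[r, ]
      t1 <- model$monomers[[sp$k1]]
      t2 <- model$monomers[[sp$k2]]
      tau <- build_dimer(t1, t2, sp$orientation, sp$d,
                         psi = sp$psi[[1]], delta = model$delta,
                         bg = model$background)
      l1 <- t1$length; l2 <- t2$length
      M <- l1 + l2 + sp$d
      bw <- if (sp$d < model$delta) bridge_window(l1, sp$d) else NULL
      gapcols <- if (sp$d >= model$delta) (l1 + 1):(l1 + sp$d) else integer()
      comps[[length(comps) + 1]] <- list(
        key = dimer_key(sp$k1, sp$k2, sp$orientation, sp$d),
        kind = "dimer", k1 = sp$k1, k2 = sp$k2, o = sp$orientation,
        d = sp$d, lambda = sp$lambda, tau = tau, len = M,
        l1 = l1, l2 = l2,
        rc1 = sp$orientation %in% c("TT", "TH"),
        rc2 = sp$orientation %in% c("HH", "TH"),
        half1 = c(1, l1), half2 = c(M - l2 + 1, M),
        bridge = bw, gapcols = gapcols,
        independent = sp$d >= model$delta
      )
    }
  }
  comps
}

# 16 x l matrix representation of a component, used by model_distance.
component_matrix <- function(comp) as_dinuc_matrix(comp$tau)

#' Weighted maximum norm distance between two mixture models
#'
#' For each mixture component present in both models the contribution is
#' `max(|lambda1 - lambda2|, min(lambda1, lambda2) * max |M1 - M2|)` where
#' `M` is the component's 16 x l matrix (the composed dimer ADM for dimer
#' components); the background contributes its weight difference and
#' weighted matrix difference likewise. The distance is the maximum over
#' components: zero iff the parameters are identical.
#'
#' @param eta1,eta2 `mixture_model`s.
#' @param strict If `TRUE` (default) the two models must have identical
#'   component structure, else an error lists the differing components. If
#'   `FALSE`, models are aligned on the union of components and a component
#'   missing from one side counts with weight 0 (its matrix difference is
#'   then weighted by 0); used to compare models across pruning.
#' @return Nonnegative scalar.
#' @export
model_distance <- function(eta1, eta2, strict = TRUE) {
  f1 <- flatten_model(eta1)
  f2 <- flatten_model(eta2)
  k1 <- vapply(f1, `[[`, "", "key")
  k2 <- vapply(f2, `[[`, "", "key")
  if (strict && (!setequal(k1, k2))) {
    stop("models differ in components: ",
         paste(c(setdiff(k1, k2), setdiff(k2, k1)), collapse = ", "))
  }
  allk <- union(k1, k2)
  dmax <- abs(eta1$lambda0 - eta2$lambda0)
  b1 <- bg_as_adm(eta1$background, 1)
  b2 <- bg_as_adm(eta2$background, 1)
  dmax <- max(dmax, min(eta1$lambda0, eta2$lambda0) *
                max(abs(as_dinuc_matrix(b1) - as_dinuc_matrix(b2))))
  for (key in allk) {
    c1 <- f1[match(key, k1)][[1]]
    c2 <- f2[match(key, k2)][[1]]
    l1 <- if (is.null(c1)) 0 else c1$lambda
    l2 <- if (is.null(c2)) 0 else c2$lambda
    dmax <- max(dmax, abs(l1 - l2))
    if (!is.null(c1) && !is.null(c2)) {
      if (c1$tau$length != c2$tau$length) {
        stop("component ", key, " has different lengths in the two models")
      }
      md <- max(abs(component_matrix(c1) - component_matrix(c2)))
      dmax <- max(dmax, min(l1, l2) * md)
    }
  }
  dmax
}

#' COB tables of a mixture model
#'
#' One [assemble_cob()] table per monomer pair in the model's candidate
#' set, including pruned cells.
#'
#' @param model A `mixture_model`.
#' @param dmin,dmax Optional spacing range; defaults to the range present
#'   (live or pruned) per pair.
#' @return A list of `cob_table` tibbles named `"k1,k2"`.
#' @export
cob_tables <- function(model, dmin = NULL, dmax = NULL) {
  specs <- dplyr::bind_rows(
    dplyr::select(model$dimers, "k1", "k2", "orientation", "d",
                  "lambda"),
    dplyr::mutate(model$pruned, lambda = NA_real_)
  )
  if (nrow(specs) == 0) return(list())
  out <- list()
  for (pr in unique(paste(specs$k1, specs$k2))) {
    kk <- as.integer(strsplit(pr, " ")[[1]])
    sub <- specs[specs$k1 == kk[1] & specs$k2 == kk[2], ]
    lam <- stats::setNames(sub$lambda, paste(sub$orientation, sub$d))
    lam <- lam[!is.na(lam)]
    prn <- paste(sub$orientation, sub$d)[is.na(sub$lambda)]
    out[[paste0(kk[1], ",", kk[2])]] <- assemble_cob(
      lam, kk,
      dmin = if (is.null(dmin)) min(sub$d) else dmin,
      dmax = if (is.null(dmax)) max(sub$d) else dmax,
      pruned = prn
    )
  }
  out
}

#' Deviation matrices of a mixture model
#'
#' For every dimer with `d < delta`, the deviation of its learned bridging
#' component from the expected slice under the model's current monomers.
#'
#' @param model A `mixture_model`.
#' @return Named list (by `"k1,k2,o,d"`) of `adm_deviation` arrays.
#' @export
deviations <- function(model) {
  out <- list()
  if (nrow(model$dimers) == 0) return(out)
  for (r in seq_len(nrow(model$dimers))) {
    sp <- model$dimers[r, ]
    if (sp$d >= model$delta) next
    em <- expected_bridge(model$monomers[[sp$k1]], model$monomers[[sp$k2]],
                          sp$orientation, sp$d, model$background)
    out[[dimer_key(sp$k1, sp$k2, sp$orientation, sp$d)]] <-
      deviation(sp$psi[[1]], em)
  }
  out
}
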