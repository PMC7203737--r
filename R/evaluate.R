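#' Count canonical k-mers in a read set
#'
#' Sliding-window counts over the reads, collapsed to canonical k-mers: a
#' k-mer and its reverse complement share one entry (keyed by the
#' lexicographically smaller of the two); windows containing an ambiguous
#' base are skipped. With no ambiguous bases the counts sum to
#' `sum(L_i - k + 1)`.
#'
#' @param reads Character vector of DNA reads.
#' @param k K-mer length (<= shortest read).
#' @return Tibble of class `kmer_table` with columns `kmer` (canonical)
#'   and `count`, for every observed k-mer.
#' @export
#' @examples
#' count_kmers(c("ACGT", "AAAA"), 2)
count_kmers <- function(reads, k) {
  if (k > min(nchar(reads))) {
    stop("k = ", k, " exceeds the shortest read length (",
         min(nchar(reads)), ")")
  }
  x <- Biostrings::DNAStringSet(toupper(reads))
  cnt <- Biostrings::oligonucleotideFrequency(x, width = k,
                                              simplify.as = "collapsed")
  cnt <- cnt[cnt > 0]
  km <- names(cnt)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  canon <- ifelse(km <= rc, km, rc)
  out <- tibble::tibble(kmer = canon, count = as.numeric(cnt)) |>
    dplyr::summarise(count = sum(.data$count), .by = "kmer") |>
    dplyr::arrange(.data$kmer)
  class(out) <- c("kmer_table", class(out))
  out
}

# Effective length-k chain for a component placed at offset t relative to
# the k-mer (component occupies k-mer columns t .. t+l-1; full containment
# either way). Positions outside the component carry background columns;
# overhanging component positions enter through the component's marginals.
kmer_effective_adm <- function(tau, k, t, bg) {
  l <- tau$length
  marg <- marginals(tau)
  bgcol <- bg_column(bg)
  trans <- array(0, c(4, 4, k))
  init <- NULL
  for (j in seq_len(k)) {
    h <- j - t + 1
    if (h >= 1 && h <= l) {
      if (j == 1) {
        init <- if (h == 1) tau$init else marg[, h]
      } else if (h == 1) {
        trans[, , j] <- matrix(tau$init, 4, 4, byrow = TRUE)
      } else {
        trans[, , j] <- tau$trans[, , h]
      }
    } else {
      if (j == 1) init <- bgcol
      trans[, , j] <- matrix(bgcol, 4, 4, byrow = TRUE)
    }
  }
  adm(init, trans)
}

#' Model score of k-mers under an ADM mixture
#'
#' The mixture-weighted, placement-averaged probability of observing each
#' k-mer in a read window: for every component, every full-containment
#' alignment of the component against the k-mer window (the component may
#' extend past the k-mer; overhanging positions are marginalized), on both
#' strands, contributes `lambda_k P(window) / N_k` with `N_k` the number
#' of alignments; the background contributes `lambda0 P_bg(w)`.
#'
#' @param model A `mixture_model`.
#' @param kmers Character vector of equal-length k-mers.
#' @return Numeric vector of positive scores.
#' @export
score_kmers <- function(model, kmers) {
  k <- unique(nchar(kmers))
  if (length(k) != 1) stop("all k-mers must have the same length")
  enc <- encode_reads(kmers)
  comps <- flatten_model(model)
  bgk <- bg_as_adm(model$background, k)
  score <- model$lambda0 *
    exp(cpp_window_logprob(enc$codes_t, enc$lens, log(bgk$init),
                           log(bgk$trans), k)[, 1])
  for (comp in comps) {
    l <- comp$len
    offsets <- seq(min(1, k - l + 1), max(1, k - l + 1))
    acc <- numeric(length(kmers))
    for (tau in list(comp$tau,
                     suppressWarnings(reverse_complement_adm(comp$tau)))) {
      for (t in offsets) {
        eff <- kmer_effective_adm(tau, k, t, model$background)
        acc <- acc + exp(cpp_window_logprob(enc$codes_t, enc$lens,
                                            log(eff$init), log(eff$trans),
                                            k)[, 1])
      }
    }
    score <- score + comp$lambda * acc / length(offsets)
  }
  score
}

#' @rdname score_kmers
#' @param w A single k-mer.
#' @export
score_kmer <- function(model, w) score_kmers(model, w)

#' Squared correlation between k-mer counts and model scores
#'
#' The model-fit criterion: the squared Pearson correlation between
#' observed k-mer occurrence counts and the mixture's k-mer scores over
#' all observed canonical k-mers, on the raw scale by default (a log-log
#' option is provided). It is invariant to positive rescaling of scores.
#'
#' @param counts A `kmer_table` from [count_kmers()].
#' @param model A `mixture_model`.
#' @param log_scale Correlate `log10(count)` with `log10(score)` instead
#'   (k-mers with zero score are dropped).
#' @param min_count Drop k-mers with fewer occurrences (default 0: keep
#'   all).
#' @return Scalar between 0 and 1.
#' @export
r_squared <- function(counts, model, log_scale = FALSE, min_count = 0) {
  counts <- counts[counts$count >= min_count, ]
  if (nrow(counts) < 2) stop("need at least 2 distinct observed k-mers")
  sc <- score_kmers(model, counts$kmer)
  x <- counts$count
  y <- sc
  if (log_scale) {
    keep <- y > 0 & x > 0
    x <- log10(x[keep])
    y <- log10(y[keep])
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: counts or scores are constant")
  }
  unname(stats::cor(x, y)^2)
}
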