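#' @useDynLib admotif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import tibble
NULL

# Fixed DNA alphabet. The symbol order A,C,G,T pins down all matrix row and
# column indices; the complement map is the usual involution A<->T, C<->G.
DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# 15-letter IUPAC code -> allowed bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Row labels of the 16 x l serialized ADM layout: AA, AC, ..., TT, where the
# first letter is the predecessor base.
DINUC_LABELS <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))

#' Reverse complement of DNA strings
#'
#' Plain-character utility used throughout; `N` is self-complementary.
#'
#' @param x Character vector of DNA strings (A, C, G, T, N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", x) |>
    vapply(function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# Encode DNA strings to an integer matrix (n x Lmax): A,C,G,T -> 1..4,
# N -> 0. Rows padded with 0 beyond each read's length; lengths returned.
encode_reads <- function(reads) {
  reads <- toupper(reads)
  lens <- nchar(reads)
  Lmax <- max(lens)
  n <- length(reads)
  codes <- matrix(0L, n, Lmax)
  chars <- strsplit(reads, "", fixed = TRUE)
  for (i in seq_len(n)) {
    v <- match(chars[[i]], DNA_BASES)
    v[is.na(v)] <- 0L
    codes[i, seq_len(lens[i])] <- v
  }
  bad <- !grepl("^[ACGTN]*$", reads)
  if (any(bad)) {
    stop("non-nucleotide characters (other than N) in read(s): ",
         paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  # codes_t (position-major) feeds the compiled scanners
  list(codes = codes, codes_t = t(codes), lens = lens, n = n, Lmax = Lmax)
}

decode_seq <- function(codes) {
  paste(c("N", DNA_BASES)[codes + 1L], collapse = "")
}

# complement codes (1..4), keeping 0 as 0
comp_codes <- function(v) ifelse(v == 0L, 0L, 5L - v)
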