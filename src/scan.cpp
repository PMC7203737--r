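#include <Rcpp.h>
using namespace Rcpp;

// Reads are passed position-major: `codes_t` is Lmax x n (one read per
// column, so window loops walk contiguous memory), values 1..4 for
// A,C,G,T, 0 for ambiguous bases (N); positions beyond a read's length are
// unused (lens gives per-read lengths). A window containing an ambiguous
// base is inadmissible.

static inline int tr_idx(int a, int b, int h) {
  // trans[a, b, h] in a 4 x 4 x len array, all 1-based
  return (h - 1) * 16 + (b - 1) * 4 + (a - 1);
}

// Log-probability of every length-`len` window of every read under an
// inhomogeneous first-order chain (loginit: 4, logtrans: 4x4xlen with
// slice 1 unused). Returns n x (Lmax - len + 1); inadmissible windows are
// -Inf.
// [[Rcpp::export]]
NumericMatrix cpp_window_logprob(const IntegerMatrix& codes_t,
                                 const IntegerVector& lens,
                                 const NumericVector& loginit,
                                 const NumericVector& logtrans,
                                 int len) {
  const int n = codes_t.ncol();
  const int Lmax = codes_t.nrow();
  const int npos = Lmax - len + 1;
  if (npos < 1) stop("component length exceeds the longest read");
  NumericMatrix out(n, npos);
  std::fill(out.begin(), out.end(), R_NegInf);
  const int* cp = codes_t.begin();
  const double* lt = logtrans.begin();
  for (int i = 0; i < n; ++i) {
    const int* col = cp + (R_xlen_t)i * Lmax;
    const int ni = lens[i] - len + 1;
    for (int j = 0; j < ni; ++j) {
      int a = col[j];
      if (a == 0) continue;
      double s = loginit[a - 1];
      bool ok = true;
      for (int h = 2; h <= len; ++h) {
        const int b = col[j + h - 1];
        if (b == 0) { ok = false; break; }
        s += lt[tr_idx(a, b, h)];
        a = b;
      }
      if (ok) out(i, j) = s;
    }
  }
  return out;
}

// Posterior-weighted dinucleotide counts for one component. Wp/Wm are
// n x npos posterior weights for plus/minus placements (0 where
// inadmissible). Minus-strand windows are reverse complemented into motif
// coordinates before accumulation. Also returns the posterior-weighted
// base counts of covered window positions in read orientation (for
// background re-estimation).
// [[Rcpp::export]]
List cpp_accumulate_counts(const IntegerMatrix& codes_t,
                           const IntegerVector& lens,
                           const NumericMatrix& Wp,
                           const NumericMatrix& Wm,
                           int len) {
  const int n = codes_t.ncol();
  const int Lmax = codes_t.nrow();
  NumericVector initc(4);
  NumericVector pairc(16 * len); // 4 x 4 x len, slice 1 unused
  NumericVector base_read(4);
  const int* cp = codes_t.begin();
  for (int i = 0; i < n; ++i) {
    const int* col = cp + (R_xlen_t)i * Lmax;
    const int ni = lens[i] - len + 1;
    for (int j = 0; j < ni; ++j) {
      const double wp = Wp(i, j);
      const double wm = Wm(i, j);
      if (wp <= 0 && wm <= 0) continue;
      const double wtot = wp + wm;
      for (int t = 0; t < len; ++t) {
        const int c = col[j + t];
        if (c > 0) base_read[c - 1] += wtot;
      }
      if (wp > 0) {
        int a = col[j];
        if (a > 0) {
          initc[a - 1] += wp;
          for (int h = 2; h <= len; ++h) {
            const int b = col[j + h - 1];
            if (b == 0) break;
            pairc[tr_idx(a, b, h)] += wp;
            a = b;
          }
        }
      }
      if (wm > 0) {
        // instance = revcomp(window): instance[h] = 5 - window[len + 1 - h]
        int a = col[j + len - 1];
        if (a > 0) {
          a = 5 - a;
          initc[a - 1] += wm;
          for (int h = 2; h <= len; ++h) {
            int b = col[j + len - h];
            if (b == 0) break;
            b = 5 - b;
            pairc[tr_idx(a, b, h)] += wm;
            a = b;
          }
        }
      }
    }
  }
  pairc.attr("dim") = IntegerVector::create(4, 4, len);
  return List::create(_["init"] = initc, _["pairs"] = pairc,
                      _["base_read"] = base_read);
}

// Hamming distance of the sub-window codes[j+offset .. j+offset+cl-1] of
// read i against a consensus fragment (codes, length cl), for every
// admissible start j of a full component of length winlen. Ambiguous
// bases mismatch. Inadmissible starts are NA.
// [[Rcpp::export]]
IntegerMatrix cpp_window_hamming(const IntegerMatrix& codes_t,
                                 const IntegerVector& lens,
                                 const IntegerVector& cons,
                                 int offset,
                                 int winlen) {
  const int n = codes_t.ncol();
  const int Lmax = codes_t.nrow();
  const int npos = Lmax - winlen + 1;
  const int cl = cons.size();
  IntegerMatrix out(n, npos);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  const int* cp = codes_t.begin();
  const int* cs = cons.begin();
  for (int i = 0; i < n; ++i) {
    const int* col = cp + (R_xlen_t)i * Lmax + offset;
    const int ni = lens[i] - winlen + 1;
    for (int j = 0; j < ni; ++j) {
      int d = 0;
      const int* w = col + j;
      for (int t = 0; t < cl; ++t) {
        if (w[t] != cs[t]) ++d;
      }
      out(i, j) = d;
    }
  }
  return out;
}
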