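#include <Rcpp.h>
using namespace Rcpp;

// FNV-1a over the byte representation of a vector of ints; returns the
// 32-bit hash as a double (R has no native uint32).
// [[Rcpp::export]]
double fnv1a_hash(IntegerVector x) {
  uint32_t h = 2166136261u;
  for (int i = 0; i < x.size(); ++i) {
    uint32_t v = (uint32_t) x[i];
    for (int b = 0; b < 4; ++b) {
      h ^= (v >> (8 * b)) & 0xffu;
      h *= 16777619u;
    }
  }
  return (double) h;
}

// Vectorised variant: hash each row of an integer matrix.
// [[Rcpp::export]]
NumericVector fnv1a_hash_rows(IntegerMatrix m) {
  NumericVector out(m.nrow());
  for (int r = 0; r < m.nrow(); ++r) {
    uint32_t h = 2166136261u;
    for (int c = 0; c < m.ncol(); ++c) {
      uint32_t v = (uint32_t) m(r, c);
      for (int b = 0; b < 4; ++b) {
        h ^= (v >> (8 * b)) & 0xffu;
        h *= 16777619u;
      }
    }
    out[r] = (double) h;
  }
  return out;
}
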