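#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Continuous-bag-of-words word2vec with negative sampling, single-threaded
// and driven entirely by an internal xorshift RNG so that a fixed seed gives
// bit-identical embeddings. The context vector is the MEAN of the input
// vectors of the surrounding tokens; after training the input weight matrix
// holds one embedding per vocabulary token.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ull) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  uint64_t uniform(uint64_t n) { return next() % n; }
  // uniform double in [0, 1)
  double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;

} // namespace

// sentences: list of integer vectors (0-based vocabulary indices)
// counts: token frequency per vocabulary entry (for the negative table)
// [[Rcpp::export]]
NumericMatrix cbow_train(List sentences, IntegerVector counts, int dim,
                         int window, int negative, int epochs,
                         double alpha0, double alpha_min, int seed) {
  const int vocab = counts.size();
  XorShift rng((uint64_t) seed * 2654435761ull + 1ull);

  // sigmoid lookup, as in the reference implementation
  std::vector<double> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double e = std::exp((i / (double) EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    expTable[i] = e / (e + 1.0);
  }

  // unigram^0.75 negative-sampling table
  const int TABLE_SIZE = 1 << 17;
  std::vector<int> unitable(TABLE_SIZE);
  double norm = 0.0;
  for (int i = 0; i < vocab; ++i) norm += std::pow((double) counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow((double) counts[0], 0.75) / norm;
    for (int a = 0; a < TABLE_SIZE; ++a) {
      unitable[a] = i;
      if ((a + 1.0) / TABLE_SIZE > cum && i < vocab - 1) {
        ++i;
        cum += std::pow((double) counts[i], 0.75) / norm;
      }
    }
  }

  // weights: w_in (vocab x dim) uniform(-0.5, 0.5)/dim; w_out zero
  std::vector<double> w_in((size_t) vocab * dim), w_out((size_t) vocab * dim, 0.0);
  for (size_t i = 0; i < w_in.size(); ++i)
    w_in[i] = (rng.runif() - 0.5) / dim;

  // total training tokens for the learning-rate schedule
  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_tokens += ((IntegerVector) sentences[s]).size();
  total_tokens *= epochs;
  long long seen = 0;

  std::vector<double> neu1(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - (double) seen / (total_tokens + 1));
        if (alpha < alpha_min) alpha = alpha_min;
        ++seen;
        const int target = sent[pos];
        // dynamic window shrink, as in word2vec
        const int reduced = (int) rng.uniform((uint64_t) window) ; // 0..window-1
        const int cw_lo = pos - (window - reduced);
        const int cw_hi = pos + (window - reduced);
        std::fill(neu1.begin(), neu1.end(), 0.0);
        std::fill(neu1e.begin(), neu1e.end(), 0.0);
        int cw = 0;
        for (int p = cw_lo; p <= cw_hi; ++p) {
          if (p == pos || p < 0 || p >= len) continue;
          const double* v = &w_in[(size_t) sent[p] * dim];
          for (int d = 0; d < dim; ++d) neu1[d] += v[d];
          ++cw;
        }
        if (cw == 0) continue;
        for (int d = 0; d < dim; ++d) neu1[d] /= cw;
        // negative sampling updates on w_out
        for (int n = 0; n <= negative; ++n) {
          int label, tgt;
          if (n == 0) { tgt = target; label = 1; }
          else {
            tgt = unitable[rng.uniform(TABLE_SIZE)];
            if (tgt == target) continue;
            label = 0;
          }
          double* o = &w_out[(size_t) tgt * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += neu1[d] * o[d];
          double grad;
          if (f > MAX_EXP) grad = (label - 1) * alpha;
          else if (f < -MAX_EXP) grad = label * alpha;
          else {
            int idx = (int) ((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
            grad = (label - expTable[idx]) * alpha;
          }
          for (int d = 0; d < dim; ++d) neu1e[d] += grad * o[d];
          for (int d = 0; d < dim; ++d) o[d] += grad * neu1[d];
        }
        // propagate to the context tokens' input vectors
        for (int p = cw_lo; p <= cw_hi; ++p) {
          if (p == pos || p < 0 || p >= len) continue;
          double* v = &w_in[(size_t) sent[p] * dim];
          for (int d = 0; d < dim; ++d) v[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = w_in[(size_t) i * dim + d];
  return out;
}
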