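#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact (O(n^2)) t-SNE with the standard machinery: per-point precision
// calibrated to the target perplexity by bisection, symmetrised affinities,
// early exaggeration, momentum switch and adaptive gains. The initial 2D
// layout Y0 is supplied by the caller (seeded from R), and the gradient
// descent itself is deterministic, so a fixed seed gives identical maps.

// [[Rcpp::export]]
NumericMatrix tsne_exact(NumericMatrix X, NumericMatrix Y0, double perplexity,
                         int max_iter) {
  const int n = X.nrow(), d = X.ncol();
  if (Y0.nrow() != n || Y0.ncol() != 2) stop("Y0 must be n x 2");

  // pairwise squared distances in input space
  std::vector<double> D2((size_t) n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      D2[(size_t) i * n + j] = D2[(size_t) j * n + i] = s;
    }

  // conditional affinities with entropy = log(perplexity)
  const double logU = std::log(perplexity);
  std::vector<double> P((size_t) n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -1.0, betamax = -1.0;
    std::vector<double> row(n);
    for (int iter = 0; iter < 60; ++iter) {
      double sum = 0.0;
      for (int j = 0; j < n; ++j) {
        row[j] = (j == i) ? 0.0 : std::exp(-D2[(size_t) i * n + j] * beta);
        sum += row[j];
      }
      if (sum < 1e-300) sum = 1e-300;
      double H = 0.0;
      for (int j = 0; j < n; ++j)
        if (row[j] > 0) H += row[j] / sum * (D2[(size_t) i * n + j] * beta);
      H += std::log(sum);
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {
        betamin = beta;
        beta = (betamax < 0) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = (betamin < 0) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    double sum = 0.0;
    for (int j = 0; j < n; ++j) sum += row[j];
    if (sum < 1e-300) sum = 1e-300;
    for (int j = 0; j < n; ++j) P[(size_t) i * n + j] = row[j] / sum;
  }
  // symmetrise
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double p = (P[(size_t) i * n + j] + P[(size_t) j * n + i]) / (2.0 * n);
      if (p < 1e-12) p = 1e-12;
      P[(size_t) i * n + j] = P[(size_t) j * n + i] = p;
    }

  const int exag_iter = std::min(250, max_iter / 2);
  const double exaggeration = 12.0, eta = 200.0;
  for (size_t k = 0; k < P.size(); ++k) P[k] *= exaggeration;

  std::vector<double> Y((size_t) n * 2), dY((size_t) n * 2, 0.0),
      gains((size_t) n * 2, 1.0), grad((size_t) n * 2);
  for (int i = 0; i < n; ++i) {
    Y[i * 2] = Y0(i, 0);
    Y[i * 2 + 1] = Y0(i, 1);
  }

  std::vector<double> Qnum((size_t) n * n);
  for (int iter = 0; iter < max_iter; ++iter) {
    double Z = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = Y[i * 2] - Y[j * 2], dy = Y[i * 2 + 1] - Y[j * 2 + 1];
        double q = 1.0 / (1.0 + dx * dx + dy * dy);
        Qnum[(size_t) i * n + j] = Qnum[(size_t) j * n + i] = q;
        Z += 2.0 * q;
      }
    if (Z < 1e-300) Z = 1e-300;
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        double q = Qnum[(size_t) i * n + j];
        double mult = (P[(size_t) i * n + j] - q / Z) * q;
        grad[i * 2] += 4.0 * mult * (Y[i * 2] - Y[j * 2]);
        grad[i * 2 + 1] += 4.0 * mult * (Y[i * 2 + 1] - Y[j * 2 + 1]);
      }
    double momentum = (iter < 250) ? 0.5 : 0.8;
    for (size_t k = 0; k < Y.size(); ++k) {
      gains[k] = ((grad[k] > 0) != (dY[k] > 0)) ? gains[k] + 0.2 : gains[k] * 0.8;
      if (gains[k] < 0.01) gains[k] = 0.01;
      dY[k] = momentum * dY[k] - eta * gains[k] * grad[k];
      Y[k] += dY[k];
    }
    // re-centre
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < n; ++i) { mx += Y[i * 2]; my += Y[i * 2 + 1]; }
    mx /= n; my /= n;
    for (int i = 0; i < n; ++i) { Y[i * 2] -= mx; Y[i * 2 + 1] -= my; }
    if (iter + 1 == exag_iter)
      for (size_t k = 0; k < P.size(); ++k) P[k] /= exaggeration;
  }

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = Y[i * 2];
    out(i, 1) = Y[i * 2 + 1];
  }
  return out;
}
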