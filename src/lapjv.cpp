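#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Rectangular linear assignment by successive shortest augmenting paths with
// dual-variable updates (the Jonker-Volgenant family). Assigns each of the
// n rows of the cost matrix to a distinct one of the m >= n columns so that
// the total cost is minimal. Returns 1-based column indices per row.

// [[Rcpp::export]]
IntegerVector lap_solve(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (m < n) stop("cost matrix needs at least as many columns as rows");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n, 0.0), v(m, 0.0), shortest(m);
  std::vector<int> col4row(n, -1), row4col(m, -1), path(m);
  std::vector<bool> SR(n), SC(m);

  for (int cur_row = 0; cur_row < n; ++cur_row) {
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(SR.begin(), SR.end(), false);
    std::fill(SC.begin(), SC.end(), false);
    std::fill(path.begin(), path.end(), -1);

    int sink = -1, i = cur_row;
    double minVal = 0.0;
    while (sink == -1) {
      SR[i] = true;
      double lowest = INF;
      int index = -1;
      for (int j = 0; j < m; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { path[j] = i; shortest[j] = r; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          index = j;
        }
      }
      minVal = lowest;
      if (!std::isfinite(minVal)) stop("assignment problem is infeasible");
      int j = index;
      if (row4col[j] == -1) sink = j; else i = row4col[j];
      SC[j] = true;
    }

    u[cur_row] += minVal;
    for (int k = 0; k < n; ++k)
      if (SR[k] && k != cur_row) u[k] += minVal - shortest[col4row[k]];
    for (int j = 0; j < m; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];

    int j = sink;
    while (true) {
      int ii = path[j];
      row4col[j] = ii;
      int tmp = col4row[ii];
      col4row[ii] = j;
      if (ii == cur_row) break;
      j = tmp;
    }
  }

  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = col4row[k] + 1;
  return out;
}
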