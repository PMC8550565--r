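#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Neighbour counts for the KSG (type 1) mutual information estimator.
// For each point i, eps_i is the Chebyshev distance to its k-th nearest
// neighbour in the joint (x, y) space; nx_i / ny_i count points strictly
// inside eps_i in the x / y marginal. O(n^2 (px + py)); fine for the
// sample sizes the estimator is meant for (n up to ~1e4).
// [[Rcpp::export]]
List ksg_neighbor_counts(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow(), px = x.ncol(), py = y.ncol();
  IntegerVector nx(n), ny(n);
  std::vector<double> dx(n), dy(n), dj(n), tmp(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double mx = 0.0, my = 0.0;
      for (int c = 0; c < px; ++c) {
        double d = std::fabs(x(i, c) - x(j, c));
        if (d > mx) mx = d;
      }
      for (int c = 0; c < py; ++c) {
        double d = std::fabs(y(i, c) - y(j, c));
        if (d > my) my = d;
      }
      dx[j] = mx;
      dy[j] = my;
      dj[j] = mx > my ? mx : my;
    }
    // dj[i] == 0 (self), so the (k+1)-th order statistic of dj is the
    // distance to the k-th neighbour excluding the point itself.
    tmp = dj;
    std::nth_element(tmp.begin(), tmp.begin() + k, tmp.end());
    const double eps = tmp[k];
    int cx = 0, cy = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dx[j] < eps) ++cx;
      if (dy[j] < eps) ++cy;
    }
    nx[i] = cx;
    ny[i] = cy;
  }
  return List::create(_["nx"] = nx, _["ny"] = ny);
}
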