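#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information between
// two scalar series, in nats. Chebyshev (max) metric in the joint space;
// marginal counts strictly inside the k-th neighbour distance.
// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (n != y.size()) stop("length mismatch");
  if (k < 1 || k >= n) stop("k out of range");
  std::vector<double> jd(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::fabs(x[i] - x[j]);
      double dy = std::fabs(y[i] - y[j]);
      jd[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(jd.begin(), jd.begin() + (k - 1), jd.begin() + m);
    double eps = jd[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[i] - x[j]) < eps) ++nx;
      if (std::fabs(y[i] - y[j]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
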