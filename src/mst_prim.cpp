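#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Total Euclidean edge length of a minimum spanning tree over n points in
// R^3, by Prim's algorithm with an O(n^2) lazy distance array. The total
// length is unique even when the tree itself is not.
// [[Rcpp::export(name = ".mst_total_length_cpp")]]
double mst_total_length_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 2) stop("need at least 2 points");
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<bool> used(n, false);
  const double *x = &pts(0, 0), *y = &pts(0, 1), *z = &pts(0, 2);
  double total = 0.0;
  int cur = 0;
  used[0] = true;
  for (int added = 1; added < n; ++added) {
    const double cx = x[cur], cy = y[cur], cz = z[cur];
    double mind = std::numeric_limits<double>::infinity();
    int next = -1;
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      const double dx = x[j] - cx, dy = y[j] - cy, dz = z[j] - cz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best[j]) best[j] = d2;
      if (best[j] < mind) { mind = best[j]; next = j; }
    }
    used[next] = true;
    total += std::sqrt(mind);
    cur = next;
  }
  return total;
}
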