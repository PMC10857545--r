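#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact brute-force nearest neighbour from each query row to the reference
// rows. Returns 1-based indices and Euclidean distances. O(n_query * n_ref),
// which is fine for the cloud sizes this package works with (~1e4).
// [[Rcpp::export]]
List nn_search_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int besti = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; besti = j; }
    }
    idx[i] = besti + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Mean distance from each point to its k nearest neighbours (self excluded),
// the statistic behind statistical outlier removal.
// [[Rcpp::export]]
NumericVector knn_mean_dist_cpp(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  NumericVector out(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = px - pts(j, 0), dy = py - pts(j, 1), dz = pz - pts(j, 2);
      d2[j] = dx * dx + dy * dy + dz * dz;
    }
    d2[i] = R_PosInf; // exclude self
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    double acc = 0.0;
    for (int j = 0; j < k; ++j) acc += std::sqrt(d2[j]);
    out[i] = acc / k;
    for (int j = 0; j < n; ++j) d2[j] = 0.0;
  }
  return out;
}
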