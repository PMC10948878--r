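#include <Rcpp.h>
using namespace Rcpp;

// Exact k nearest neighbors of each query row among the reference rows
// (squared Euclidean), with early abandonment against the current k-th
// best distance. A reference row whose id equals the query's id is
// skipped (self-exclusion). Returns the ids of the neighbors, NA-padded
// when the reference holds fewer than k usable rows.
// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericMatrix query, NumericMatrix ref, int k,
                        IntegerVector query_ids, IntegerVector ref_ids) {
  int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  IntegerMatrix out(nq, k);
  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  for (int i = 0; i < nq; ++i) {
    for (int s = 0; s < k; ++s) {
      bestd[s] = R_PosInf;
      besti[s] = NA_INTEGER;
    }
    for (int j = 0; j < nr; ++j) {
      if (ref_ids[j] == query_ids[i]) continue;
      double acc = 0.0;
      double cut = bestd[k - 1];
      for (int t = 0; t < d; ++t) {
        double diff = query(i, t) - ref(j, t);
        acc += diff * diff;
        if (acc >= cut) break;
      }
      if (acc < cut) {
        int pos = k - 1;
        while (pos > 0 && acc < bestd[pos - 1]) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = acc;
        besti[pos] = ref_ids[j];
      }
    }
    for (int s = 0; s < k; ++s) out(i, s) = besti[s];
  }
  return out;
}
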