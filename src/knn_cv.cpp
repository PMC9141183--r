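#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <utility>
#include <vector>
using namespace Rcpp;

// Cross-validated KNN accuracy from an additive squared-distance matrix.
// D holds the distance contributions of the current feature subset; M is a
// candidate feature's contribution applied with sign `sgn` (+1 tentative add,
// -1 tentative removal, 0 to score D as-is). Scoring never materializes
// D + sgn*M: each test/train entry is combined on the fly. Neighbour ties at
// equal distance resolve to the smaller training index, votes at exactly 0.5
// resolve to class 0, so scores are deterministic.
// [[Rcpp::export(name = ".knn_cv_score_cpp")]]
double knn_cv_score_cpp(NumericMatrix D, NumericMatrix M, double sgn,
                        IntegerVector fold, IntegerVector y, int k) {
  const int n = D.nrow();
  int n_folds = 0;
  for (int i = 0; i < n; ++i) n_folds = std::max(n_folds, fold[i]);
  int correct = 0;
  std::vector<int> tr;
  std::vector<std::pair<double, int> > d;
  tr.reserve(n);
  d.reserve(n);
  for (int f = 1; f <= n_folds; ++f) {
    tr.clear();
    for (int j = 0; j < n; ++j) if (fold[j] != f) tr.push_back(j);
    if (tr.empty()) continue;
    const int kk = std::min<int>(k, tr.size());
    for (int i = 0; i < n; ++i) {
      if (fold[i] != f) continue;
      d.clear();
      for (size_t t = 0; t < tr.size(); ++t) {
        const int j = tr[t];
        double v = D(i, j);
        if (sgn != 0.0) v += sgn * M(i, j);
        d.push_back(std::make_pair(v, j));
      }
      std::partial_sort(d.begin(), d.begin() + kk, d.end());
      int votes1 = 0;
      for (int t = 0; t < kk; ++t) votes1 += (y[d[t].second] == 1);
      const int pred = (2 * votes1 > kk) ? 1 : 0;
      if (pred == y[i]) ++correct;
    }
  }
  return (double)correct / n;
}
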