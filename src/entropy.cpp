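#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template-match counts shared by sample and approximate entropy.
// Chebyshev distance; one O(n^2) pass over template pairs with early abandon
// as soon as a coordinate difference exceeds the tolerance.
//
// Returns:
//   A, B      : #pair matches at length m+1 / m over the N-m templates that
//               admit an (m+1)-extension, self-matches excluded (SampEn).
//   phi_m,
//   phi_m1    : mean log relative frequency of matches, self-matches included
//               (ApEn's Phi statistics).
// [[Rcpp::export(name = ".entropy_counts_cpp")]]
List entropy_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n <= m + 1) stop("series too short for template length m+1");
  const double* px = REAL(x);
  const int Nm = n - m + 1;  // # length-m templates
  const int Nm1 = n - m;     // # length-(m+1) templates
  std::vector<double> cm(Nm, 1.0);    // self-match included
  std::vector<double> cm1(Nm1, 1.0);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < Nm; ++i) {
    const double* xi = px + i;
    for (int j = i + 1; j < Nm; ++j) {
      const double* xj = px + j;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(xi[k] - xj[k]) > r) { match = false; break; }
      }
      if (match) {
        cm[i] += 1.0;
        cm[j] += 1.0;
        if (j < Nm1) {  // both templates extend to length m+1 (i < j)
          B += 1.0;
          if (std::fabs(xi[m] - xj[m]) <= r) {
            A += 1.0;
            cm1[i] += 1.0;
            cm1[j] += 1.0;
          }
        }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < Nm; ++i) phi_m += std::log(cm[i] / Nm);
  phi_m /= Nm;
  for (int i = 0; i < Nm1; ++i) phi_m1 += std::log(cm1[i] / Nm1);
  phi_m1 /= Nm1;
  return List::create(_["A"] = A, _["B"] = B,
                      _["phi_m"] = phi_m, _["phi_m1"] = phi_m1);
}
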