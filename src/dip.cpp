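#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Hartigan's dip statistic: the smallest sup-norm distance between the
// empirical distribution function and the class of unimodal distribution
// functions (convex below the mode, concave above, a jump allowed at the
// mode).
//
// Computation (modal-interval narrowing): ties are collapsed to distinct
// values y_1..y_m with cumulative counts c_j (c_0 = 0). On the current
// modal candidate interval [lo, hi]:
//   * the greatest convex minorant (gcm) of the ECDF staircase is the
//     lower convex hull of the lower corners (y_j, c_{j-1});
//   * the least concave majorant (lcm) is the upper hull of the upper
//     corners (y_j, c_j);
//   * d = max over hull vertices of (lcm - gcm) is the gap the unimodal
//     fit must bridge inside the interval.
// If d exceeds the largest outer-region fit error D found so far, the
// interval narrows to the hull vertices bracketing the gap maximizer, and
// the convex (concave) fit errors of the newly excluded outer regions --
// max_j (c_j - gcm(y_j)) on the left, max_j (lcm(y_j) - c_{j-1}) on the
// right -- are folded into D. When d <= D the two branches, shifted by
// D/2, can be joined monotonically through the modal interval, so the
// optimal sup distance is D/2 (in ECDF units, D / (2n)).

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs) {
  const int n = xs.size();
  if (n < 2) return 0.0;
  std::vector<double> y;
  std::vector<double> chi;  // upper-corner count c_j
  y.reserve(n);
  chi.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (i > 0 && xs[i] < xs[i - 1]) stop("input must be sorted");
    if (!y.empty() && xs[i] == y.back()) {
      chi.back() += 1.0;
    } else {
      y.push_back(xs[i]);
      chi.push_back(1.0);
    }
  }
  const int m = (int) y.size();
  if (m == 1) return 0.0;
  for (int j = 1; j < m; ++j) chi[j] += chi[j - 1];
  std::vector<double> clo(m);  // lower-corner count c_{j-1}
  clo[0] = 0.0;
  for (int j = 1; j < m; ++j) clo[j] = chi[j - 1];

  std::vector<int> gcm, lcm;  // hull vertex indices
  gcm.reserve(m);
  lcm.reserve(m);
  int lo = 0, hi = m - 1;
  double D = 0.0;

  while (true) {
    // lower hull of (y_j, clo_j) on [lo, hi]
    gcm.clear();
    for (int k = lo; k <= hi; ++k) {
      while (gcm.size() >= 2) {
        int a = gcm[gcm.size() - 2], b = gcm.back();
        if ((clo[b] - clo[a]) * (y[k] - y[a]) >=
            (clo[k] - clo[a]) * (y[b] - y[a])) {
          gcm.pop_back();
        } else {
          break;
        }
      }
      gcm.push_back(k);
    }
    // upper hull of (y_j, chi_j) on [lo, hi]
    lcm.clear();
    for (int k = lo; k <= hi; ++k) {
      while (lcm.size() >= 2) {
        int a = lcm[lcm.size() - 2], b = lcm.back();
        if ((chi[b] - chi[a]) * (y[k] - y[a]) <=
            (chi[k] - chi[a]) * (y[b] - y[a])) {
          lcm.pop_back();
        } else {
          break;
        }
      }
      lcm.push_back(k);
    }

    auto interp = [&](const std::vector<int> &h, const std::vector<double> &v,
                      double x0) -> double {
      // piecewise-linear hull value at x0 (x0 within [y[h.front()], y[h.back()]])
      int a = 0, b = (int) h.size() - 1;
      while (b - a > 1) {
        int c = (a + b) / 2;
        if (y[h[c]] <= x0) a = c; else b = c;
      }
      const int ia = h[a], ib = h[b];
      if (ib == ia || y[ib] == y[ia]) return v[ia];
      return v[ia] + (v[ib] - v[ia]) * (x0 - y[ia]) / (y[ib] - y[ia]);
    };

    if (lo == hi) break;  // residual jump at the mode is bridged freely

    // largest gap lcm - gcm over vertices of both hulls
    double d = -1.0;
    double tstar = y[lo];
    for (size_t t = 0; t < gcm.size(); ++t) {
      const double gap = interp(lcm, chi, y[gcm[t]]) - clo[gcm[t]];
      if (gap > d) { d = gap; tstar = y[gcm[t]]; }
    }
    for (size_t t = 0; t < lcm.size(); ++t) {
      const double gap = chi[lcm[t]] - interp(gcm, clo, y[lcm[t]]);
      if (gap > d) { d = gap; tstar = y[lcm[t]]; }
    }

    if (d <= D) break;

    // narrow to the hull vertices bracketing the gap maximizer
    int newlo = lo, newhi = hi;
    for (size_t t = 0; t < gcm.size(); ++t) {
      if (y[gcm[t]] <= tstar) newlo = gcm[t];
    }
    for (size_t t = lcm.size(); t-- > 0; ) {
      if (y[lcm[t]] >= tstar) newhi = lcm[t];
    }

    // convex fit error on the excluded left region [lo, newlo)
    for (int j = lo; j < newlo; ++j) {
      const double dev = chi[j] - interp(gcm, clo, y[j]);
      if (dev > D) D = dev;
    }
    // concave fit error on the excluded right region (newhi, hi]
    for (int j = newhi + 1; j <= hi; ++j) {
      const double dev = interp(lcm, chi, y[j]) - clo[j];
      if (dev > D) D = dev;
    }
    lo = newlo;
    hi = newhi;
  }
  return 0.5 * D / n;
}
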