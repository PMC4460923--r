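#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exhaustive threshold scan for one (precondition subset, attribute) pair
// of a confidence-rated boosting iteration.
//
// Candidate thresholds are the midpoints between consecutive distinct
// sorted attribute values. For the condition "value >= threshold" each
// candidate is scored with the split part of the Z-criterion,
//   z = 2 * ( sqrt(W+(r) W-(r)) + sqrt(W+(!r) W-(!r)) ),
// where W+/W- are class weight sums inside the subset; the caller adds
// the constant W(!precondition) term. Ties are broken toward the smallest
// threshold.
//
// x:   attribute values of the instances satisfying the precondition
// w:   boosting weights (positive)
// pos: TRUE where the instance label is positive
//
// Returns ok = FALSE when there is no candidate (fewer than two distinct
// values).
// [[Rcpp::export(name = ".cpp_best_cut")]]
List cpp_best_cut(NumericVector x, NumericVector w, LogicalVector pos) {
  int n = x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  double wp_tot = 0.0, wn_tot = 0.0;
  for (int i = 0; i < n; ++i) {
    if (pos[i]) wp_tot += w[i]; else wn_tot += w[i];
  }

  double best_z = R_PosInf, best_thr = NA_REAL;
  double best_wp_lo = NA_REAL, best_wn_lo = NA_REAL;
  bool ok = false;

  // prefix sums over the sorted order; a cut after position i (0-based)
  // sends x < threshold right (low side) and x >= threshold left
  double wp_lo = 0.0, wn_lo = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    int a = idx[i];
    if (pos[a]) wp_lo += w[a]; else wn_lo += w[a];
    double xi = x[idx[i]], xj = x[idx[i + 1]];
    if (xi == xj) continue;  // not a boundary between distinct values
    double thr = xi + (xj - xi) / 2.0;
    double wp_hi = wp_tot - wp_lo, wn_hi = wn_tot - wn_lo;
    double z = 2.0 * (std::sqrt(wp_hi * wn_hi) + std::sqrt(wp_lo * wn_lo));
    if (z < best_z) {  // strict: keeps the smallest tied threshold
      best_z = z;
      best_thr = thr;
      best_wp_lo = wp_lo;
      best_wn_lo = wn_lo;
      ok = true;
    }
  }

  if (!ok) return List::create(_["ok"] = false);
  return List::create(
      _["ok"] = true, _["threshold"] = best_thr, _["z_split"] = best_z,
      _["wp_true"] = wp_tot - best_wp_lo, _["wn_true"] = wn_tot - best_wn_lo,
      _["wp_false"] = best_wp_lo, _["wn_false"] = best_wn_lo);
}
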