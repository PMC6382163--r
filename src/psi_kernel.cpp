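#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Order-parameter kernel: for every query point, accumulate
// psi^(M) = (1/N) sum_l exp(i * M * phi_l) over reference points whose
// distance lies in [r_inner, r_outer]. exp(i * phi) is the unit complex
// (dx + i dy) / d, and its M-th powers are built by repeated
// multiplication, so no trigonometric calls are needed.
//
// exclude_self: skip reference j == query k (scoring a map against
// itself). min_dist: additionally skip reference points closer than this
// (coincident points when scoring against a separate reference map).
//
// Returns a list with the complex matrix `psi` (n_query x n_M, NA rows
// where a query has no neighbors) and the integer vector `n_neighbors`.
// [[Rcpp::export(name = ".psi_kernel")]]
List psi_kernel(NumericMatrix query, NumericMatrix ref,
                double r_inner, double r_outer, IntegerVector m_set,
                bool exclude_self, double min_dist) {
  const int nq = query.nrow(), nr = ref.nrow(), nm = m_set.size();
  int max_m = 0;
  for (int m = 0; m < nm; ++m) max_m = std::max(max_m, m_set[m]);
  // column index for each power 1..max_m (-1 if unused)
  std::vector<int> col_of(max_m + 1, -1);
  for (int m = 0; m < nm; ++m) col_of[m_set[m]] = m;

  ComplexMatrix psi(nq, nm);
  IntegerVector nn(nq);
  const double lo2 = r_inner * r_inner, hi2 = r_outer * r_outer;
  const double min2 = min_dist * min_dist;
  std::vector<double> sre(nm), sim(nm);

  for (int k = 0; k < nq; ++k) {
    const double xk = query(k, 0), yk = query(k, 1);
    std::fill(sre.begin(), sre.end(), 0.0);
    std::fill(sim.begin(), sim.end(), 0.0);
    int cnt = 0;
    for (int j = 0; j < nr; ++j) {
      if (exclude_self && j == k) continue;
      const double dx = ref(j, 0) - xk, dy = ref(j, 1) - yk;
      const double d2 = dx * dx + dy * dy;
      if (d2 < lo2 || d2 > hi2 || d2 <= min2) continue;
      const double inv = 1.0 / std::sqrt(d2);
      const double ur = dx * inv, ui = dy * inv;
      double pr = ur, pi = ui;
      if (col_of[1] >= 0) { sre[col_of[1]] += pr; sim[col_of[1]] += pi; }
      for (int M = 2; M <= max_m; ++M) {
        const double nr_ = pr * ur - pi * ui;
        pi = pr * ui + pi * ur;
        pr = nr_;
        const int c = col_of[M];
        if (c >= 0) { sre[c] += pr; sim[c] += pi; }
      }
      ++cnt;
    }
    nn[k] = cnt;
    for (int m = 0; m < nm; ++m) {
      Rcomplex z;
      if (cnt > 0) { z.r = sre[m] / cnt; z.i = sim[m] / cnt; }
      else { z.r = NA_REAL; z.i = NA_REAL; }
      psi(k, m) = z;
    }
  }
  return List::create(_["psi"] = psi, _["n_neighbors"] = nn);
}

// Squared pairwise distances are needed twice per map (histogram and
// scoring); the histogram only needs the counts per bin, so bin on the
// fly instead of materialising n*(n-1)/2 distances.
// [[Rcpp::export(name = ".pair_dist_counts")]]
List pair_dist_counts(NumericMatrix pos, double bin_width, int n_bins) {
  const int n = pos.nrow();
  IntegerVector counts(n_bins);
  double d_max = 0.0;
  for (int k = 1; k < n; ++k) {
    const double xk = pos(k, 0), yk = pos(k, 1);
    for (int j = 0; j < k; ++j) {
      const double dx = pos(j, 0) - xk, dy = pos(j, 1) - yk;
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > d_max) d_max = d;
      if (bin_width > 0.0) {
        int b = (int)std::ceil(d / bin_width - 1e-12) - 1;
        if (b >= 0 && b < n_bins) ++counts[b];
      }
    }
  }
  return List::create(_["counts"] = counts, _["d_max"] = d_max);
}
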