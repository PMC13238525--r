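#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simplex prediction for one query point from the library rows listed in
// libidx (0-based). self >= 0 excludes that library row (leave-one-out).
// Weights are exp(-d_i / d_1); if the nearest distance is 0, the exact
// matches get all the weight (uniform among them).
static double simplex_point(const NumericMatrix &lib, const NumericVector &liby,
                            const std::vector<int> &libidx,
                            const NumericMatrix &qpts, int qrow, int self) {
  const int E = lib.ncol();
  const int k = E + 1;
  std::vector<std::pair<double, int> > d;
  d.reserve(libidx.size());
  for (size_t j = 0; j < libidx.size(); ++j) {
    const int r = libidx[j];
    if (r == self) continue;
    double s = 0.0;
    for (int c = 0; c < E; ++c) {
      const double diff = lib(r, c) - qpts(qrow, c);
      s += diff * diff;
    }
    d.push_back(std::make_pair(std::sqrt(s), r));
  }
  if ((int)d.size() < k) return NA_REAL;
  std::partial_sort(d.begin(), d.begin() + k, d.end());
  const double d1 = d[0].first;
  double num = 0.0, den = 0.0;
  if (d1 <= 0.0) {
    int m = 0;
    for (int j = 0; j < k && d[j].first <= 0.0; ++j) {
      num += liby[d[j].second];
      ++m;
    }
    return num / m;
  }
  for (int j = 0; j < k; ++j) {
    const double w = std::exp(-d[j].first / d1);
    num += w * liby[d[j].second];
    den += w * 1.0;
  }
  return num / den;
}

static double pearson(const std::vector<double> &a, const std::vector<double> &b) {
  const size_t n = a.size();
  if (n < 2) return NA_REAL;
  double ma = 0, mb = 0;
  for (size_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, sa = 0, sb = 0;
  for (size_t i = 0; i < n; ++i) {
    sab += (a[i] - ma) * (b[i] - mb);
    sa += (a[i] - ma) * (a[i] - ma);
    sb += (b[i] - mb) * (b[i] - mb);
  }
  if (sa <= 0 || sb <= 0) return NA_REAL;
  return sab / std::sqrt(sa * sb);
}

// [[Rcpp::export]]
NumericVector cpp_simplex_predict(NumericMatrix lib_pts, NumericVector lib_y,
                                  NumericMatrix query_pts, IntegerVector exclude) {
  const int nq = query_pts.nrow();
  std::vector<int> all(lib_pts.nrow());
  for (int i = 0; i < lib_pts.nrow(); ++i) all[i] = i;
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const int self = exclude[q] - 1; // 1-based from R; 0 means none
    out[q] = simplex_point(lib_pts, lib_y, all, query_pts, q, self);
  }
  return out;
}

// Cross-map skill over random libraries: for each library size, draw
// n_samples libraries without replacement (R RNG, so set.seed applies),
// predict every point (leave-one-out when the point is in the library),
// and record the Pearson correlation between predictions and targets.
// [[Rcpp::export]]
NumericMatrix cpp_ccm_rhos(NumericMatrix pts, NumericVector y,
                           IntegerVector lib_sizes, int n_samples) {
  const int P = pts.nrow();
  const int ns = lib_sizes.size();
  NumericMatrix out(n_samples, ns);
  IntegerVector allr = seq(0, P - 1);
  for (int s = 0; s < ns; ++s) {
    const int L = lib_sizes[s];
    for (int rep = 0; rep < n_samples; ++rep) {
      IntegerVector drawn = (L >= P) ? allr : Rcpp::sample(allr, L, false);
      std::vector<int> lib(drawn.begin(), drawn.end());
      std::vector<char> inlib(P, 0);
      for (size_t j = 0; j < lib.size(); ++j) inlib[lib[j]] = 1;
      std::vector<double> pred, obs;
      pred.reserve(P); obs.reserve(P);
      for (int q = 0; q < P; ++q) {
        const int self = inlib[q] ? q : -1;
        const double p = simplex_point(pts, y, lib, pts, q, self);
        if (!ISNAN(p)) { pred.push_back(p); obs.push_back(y[q]); }
      }
      out(rep, s) = pearson(pred, obs);
    }
  }
  return out;
}

// Full-library cross-map (leave-one-out): the deterministic skill used as
// the test statistic in surrogate significance testing.
// [[Rcpp::export]]
double cpp_xmap_full(NumericMatrix pts, NumericVector y) {
  const int P = pts.nrow();
  std::vector<int> all(P);
  for (int i = 0; i < P; ++i) all[i] = i;
  std::vector<double> pred, obs;
  pred.reserve(P); obs.reserve(P);
  for (int q = 0; q < P; ++q) {
    const double p = simplex_point(pts, y, all, pts, q, q);
    if (!ISNAN(p)) { pred.push_back(p); obs.push_back(y[q]); }
  }
  return pearson(pred, obs);
}
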