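#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Euclidean distance between frame i of x and frame j of y.
// Signals are stored timepoints x channels.
static inline double frame_dist(const NumericMatrix& x, const NumericMatrix& y,
                                int i, int j) {
  double s = 0.0;
  int nc = x.ncol();
  for (int c = 0; c < nc; ++c) {
    double d = x(i, c) - y(j, c);
    s += d * d;
  }
  return std::sqrt(s);
}

// Dynamic-programming DTW with steps {(1,0),(0,1),(1,1)} and no slope
// constraint. band < 0 disables the Sakoe-Chiba band. The band is applied
// around the slope-adjusted diagonal so unequal lengths stay reachable.
// [[Rcpp::export(name = ".cpp_dtw")]]
List cpp_dtw(NumericMatrix x, NumericMatrix y, int band, bool want_path) {
  const int n = x.nrow(), m = y.nrow();
  const double inf = std::numeric_limits<double>::infinity();

  if (!want_path && band < 0) {
    // distance-only mode: two rolling rows
    std::vector<double> prev(m), cur(m);
    prev[0] = frame_dist(x, y, 0, 0);
    for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + frame_dist(x, y, 0, j);
    for (int i = 1; i < n; ++i) {
      cur[0] = prev[0] + frame_dist(x, y, i, 0);
      for (int j = 1; j < m; ++j) {
        double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
        cur[j] = best + frame_dist(x, y, i, j);
      }
      std::swap(prev, cur);
    }
    return List::create(_["distance"] = prev[m - 1], _["path"] = R_NilValue);
  }

  NumericMatrix D(n, m);
  std::fill(D.begin(), D.end(), inf);
  double slope = (n > 1) ? (double)(m - 1) / (double)(n - 1) : 0.0;
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      int center = (int)std::lround(slope * i);
      jlo = std::max(0, center - band);
      jhi = std::min(m - 1, center + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double fd = frame_dist(x, y, i, j);
      if (i == 0 && j == 0) { D(i, j) = fd; continue; }
      double best = inf;
      if (i > 0 && j > 0 && D(i - 1, j - 1) < best) best = D(i - 1, j - 1);
      if (i > 0 && D(i - 1, j) < best) best = D(i - 1, j);
      if (j > 0 && D(i, j - 1) < best) best = D(i, j - 1);
      if (best < inf) D(i, j) = best + fd;
    }
  }
  double dist = D(n - 1, m - 1);

  if (!want_path)
    return List::create(_["distance"] = dist, _["path"] = R_NilValue);

  // backtrack, preferring the diagonal step on ties
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double dd = D(i - 1, j - 1), du = D(i - 1, j), dl = D(i, j - 1);
      if (dd <= du && dd <= dl) { --i; --j; }
      else if (du <= dl) { --i; }
      else { --j; }
    } else if (i > 0) { --i; } else { --j; }
    pi.push_back(i); pj.push_back(j);
  }
  int len = (int)pi.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {         // reverse to start at (1,1)
    path(k, 0) = pi[len - 1 - k] + 1;
    path(k, 1) = pj[len - 1 - k] + 1;
  }
  return List::create(_["distance"] = dist, _["path"] = path);
}

// Pairwise DTW distance matrix over a list of timepoints-x-channels matrices.
// [[Rcpp::export(name = ".cpp_dtw_matrix")]]
NumericMatrix cpp_dtw_matrix(List signals, int band, bool normalize) {
  int n = signals.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix xi = signals[i];
    for (int j = i + 1; j < n; ++j) {
      NumericMatrix xj = signals[j];
      List r = cpp_dtw(xi, xj, band, normalize);
      double d = as<double>(r["distance"]);
      if (normalize) {
        IntegerMatrix p = r["path"];
        d /= (double)p.nrow();
      }
      out(i, j) = d;
      out(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Cross DTW distances: rows over `a`, columns over `b`.
// [[Rcpp::export(name = ".cpp_dtw_cross")]]
NumericMatrix cpp_dtw_cross(List a, List b, int band, bool normalize) {
  int n = a.size(), m = b.size();
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    NumericMatrix xi = a[i];
    for (int j = 0; j < m; ++j) {
      NumericMatrix xj = b[j];
      List r = cpp_dtw(xi, xj, band, normalize);
      double d = as<double>(r["distance"]);
      if (normalize) {
        IntegerMatrix p = r["path"];
        d /= (double)p.nrow();
      }
      out(i, j) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
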