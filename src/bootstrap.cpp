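#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Average ranks (midrank ties) of v into out.
static void rank_avg_cpp(const std::vector<double>& v, std::vector<double>& out,
                         std::vector<int>& ord) {
  const int m = (int)v.size();
  ord.resize(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  out.resize(m);
  int i = 0;
  while (i < m) {
    int j = i;
    while (j + 1 < m && v[ord[j + 1]] == v[ord[i]]) ++j;
    const double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) out[ord[k]] = r;
    i = j + 1;
  }
}

// Residualize y on the design [1, C] via normal equations (k <= 4 small).
static void residualize(const std::vector<std::vector<double>>& C,
                        const std::vector<double>& y, int m,
                        std::vector<double>& resid) {
  const int k = (int)C.size() + 1;
  std::vector<double> G((size_t)k * k, 0.0), b(k, 0.0), beta(k, 0.0);
  // G = X'X with X = [1, C...]; b = X'y
  G[0] = m;
  for (int a = 1; a < k; ++a) {
    double s = 0.0, sy = 0.0;
    for (int i = 0; i < m; ++i) s += C[a - 1][i];
    G[a] = G[(size_t)a * k] = s;
    for (int c = 1; c <= a; ++c) {
      double g = 0.0;
      for (int i = 0; i < m; ++i) g += C[a - 1][i] * C[c - 1][i];
      G[(size_t)a * k + c] = G[(size_t)c * k + a] = g;
    }
    for (int i = 0; i < m; ++i) sy += C[a - 1][i] * y[i];
    b[a] = sy;
  }
  for (int i = 0; i < m; ++i) b[0] += y[i];
  // Gaussian elimination with partial pivoting
  std::vector<int> piv(k);
  for (int i = 0; i < k; ++i) piv[i] = i;
  for (int col = 0; col < k; ++col) {
    int best = col;
    for (int r = col + 1; r < k; ++r) {
      if (std::fabs(G[(size_t)r * k + col]) > std::fabs(G[(size_t)best * k + col]))
        best = r;
    }
    if (best != col) {
      for (int c = 0; c < k; ++c)
        std::swap(G[(size_t)col * k + c], G[(size_t)best * k + c]);
      std::swap(b[col], b[best]);
    }
    const double d = G[(size_t)col * k + col];
    for (int r = col + 1; r < k; ++r) {
      const double f = G[(size_t)r * k + col] / d;
      if (f == 0.0) continue;
      for (int c = col; c < k; ++c) G[(size_t)r * k + c] -= f * G[(size_t)col * k + c];
      b[r] -= f * b[col];
    }
  }
  for (int r = k - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < k; ++c) s -= G[(size_t)r * k + c] * beta[c];
    beta[r] = s / G[(size_t)r * k + r];
  }
  resid.resize(m);
  for (int i = 0; i < m; ++i) {
    double f = beta[0];
    for (int a = 1; a < k; ++a) f += beta[a] * C[a - 1][i];
    resid[i] = y[i] - f;
  }
}

static double pearson(const std::vector<double>& x, const std::vector<double>& y) {
  const int m = (int)x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < m; ++i) { mx += x[i]; my += y[i]; }
  mx /= m; my /= m;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < m; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0.0 || syy <= 0.0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// One subject's bootstrap peak latencies.
//
// V: m x W matrix (neural vectors restricted to the search window)
// target: length-m target vector; controls: m x k matrix (k may be 0)
// idx: m x B matrix of 1-based resample indices (same indices applied to
//      neural, target and control vectors)
// Returns the 0-based argmax window column per bootstrap (earliest on ties).
// [[Rcpp::export]]
IntegerVector bootstrap_peaks_cpp(NumericMatrix V, NumericVector target,
                                  NumericMatrix controls, IntegerMatrix idx) {
  const int m = V.nrow(), W = V.ncol();
  const int k = controls.ncol();
  const int B = idx.ncol();
  IntegerVector peak(B);
  std::vector<double> buf(m), rt, ry, rx;
  std::vector<int> ord;
  std::vector<std::vector<double>> C((size_t)k);
  std::vector<double> rtarget;

  for (int b = 0; b < B; ++b) {
    // ranked resampled target and controls
    for (int i = 0; i < m; ++i) buf[i] = target[idx(i, b) - 1];
    rank_avg_cpp(buf, rt, ord);
    for (int c = 0; c < k; ++c) {
      for (int i = 0; i < m; ++i) buf[i] = controls(idx(i, b) - 1, c);
      rank_avg_cpp(buf, C[c], ord);
    }
    if (k > 0) {
      residualize(C, rt, m, rtarget);
    } else {
      rtarget = rt;
    }
    double best = -2.0;
    int best_t = 0;
    for (int t = 0; t < W; ++t) {
      for (int i = 0; i < m; ++i) buf[i] = V(idx(i, b) - 1, t);
      rank_avg_cpp(buf, ry, ord);
      double r;
      if (k > 0) {
        residualize(C, ry, m, rx);
        r = pearson(rx, rtarget);
      } else {
        r = pearson(ry, rtarget);
      }
      if (!ISNA(r) && r > best + 1e-15) { best = r; best_t = t; }
    }
    peak[b] = best_t;
  }
  return peak;
}
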