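#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM,
// solved in the dual with the bias handled as an augmented constant feature.
// X is row-major here: x[i*d + k] is feature k of sample i (d includes the
// bias column, which the caller appends implicitly via `aug`).
//
// Returns the primal weight vector (length d + 1, last entry the bias).
// Deterministic xorshift RNG for the per-epoch index shuffles, so solutions
// are reproducible and independent of R's RNG state.
static inline unsigned int xorshift(unsigned int& s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

static void dcd_train(const std::vector<double>& X, const std::vector<int>& y,
                      int n, int d, double C, int max_epochs, double tol,
                      std::vector<double>& w, std::vector<double>& alpha) {
  std::vector<double> qii(n);
  std::vector<int> index(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0;                  // bias feature contributes 1
    const double* xi = &X[(size_t)i * d];
    for (int k = 0; k < d; ++k) s += xi[k] * xi[k];
    qii[i] = s;
    index[i] = i;
  }
  // warm start: w is determined by the (feasible) incoming alphas
  std::fill(w.begin(), w.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    if (alpha[i] != 0.0) {
      const double ayi = alpha[i] * y[i];
      const double* xi = &X[(size_t)i * d];
      for (int k = 0; k < d; ++k) w[k] += ayi * xi[k];
      w[d] += ayi;
    }
  }
  unsigned int rng = 88172645u;
  int active = n;
  const double INF = std::numeric_limits<double>::infinity();
  double pgmax_old = INF, pgmin_old = -INF;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double pgmax_new = -INF, pgmin_new = INF;
    for (int s = active - 1; s > 0; --s) {       // Fisher-Yates over active set
      int j = (int)(xorshift(rng) % (unsigned int)(s + 1));
      std::swap(index[s], index[j]);
    }
    for (int s = 0; s < active; ++s) {
      const int i = index[s];
      const double* xi = &X[(size_t)i * d];
      double g = w[d];
      for (int k = 0; k < d; ++k) g += w[k] * xi[k];
      g = y[i] * g - 1.0;
      double pg = 0.0;
      if (alpha[i] == 0.0) {
        if (g > pgmax_old) {                      // shrink
          --active; std::swap(index[s], index[active]); --s; continue;
        }
        if (g < 0.0) pg = g;
      } else if (alpha[i] == C) {
        if (g < pgmin_old) {
          --active; std::swap(index[s], index[active]); --s; continue;
        }
        if (g > 0.0) pg = g;
      } else {
        pg = g;
      }
      if (pg > pgmax_new) pgmax_new = pg;
      if (pg < pgmin_new) pgmin_new = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int k = 0; k < d; ++k) w[k] += delta * xi[k];
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
    }
    if (pgmax_new - pgmin_new <= tol) {
      if (active == n) break;
      active = n; pgmax_old = INF; pgmin_old = -INF;  // unshrink and confirm
      continue;
    }
    pgmax_old = pgmax_new > 0.0 ? pgmax_new : INF;
    pgmin_old = pgmin_new < 0.0 ? pgmin_new : -INF;
  }
}

// Cross-validated pairwise decoding over timepoints.
//
// data: trials x channels x timepoints array (column-major, R layout)
// labels: 1-based condition index per trial
// folds: trials x n_repeats matrix of 1-based fold ids
// pairs: n_pairs x 2 matrix of 1-based condition indices
//
// For each pair, repeat and fold: train on out-of-fold trials of the two
// conditions (features = channel vector at timepoint t, z-scored with
// training-fold statistics only), test on the held-out fold; accuracy is the
// mean over n_repeats * n_folds held-out folds.
// [[Rcpp::export]]
NumericMatrix decode_pairs_cpp(NumericVector data, IntegerVector labels,
                               IntegerMatrix folds, IntegerMatrix pairs,
                               int n_folds, double cost,
                               int max_epochs, double tol) {
  IntegerVector dims = data.attr("dim");
  const int n_trials = dims[0], n_ch = dims[1], n_time = dims[2];
  const int n_repeats = folds.ncol();
  const int n_pairs = pairs.nrow();
  NumericMatrix acc(n_pairs, n_time);

  std::vector<double> Xall, Xtr, Xte, w((size_t)n_ch + 1), mu(n_ch), sd(n_ch);
  std::vector<int> ytr;

  for (int p = 0; p < n_pairs; ++p) {
    const int ca = pairs(p, 0), cb = pairs(p, 1);
    std::vector<int> idx, yy;
    for (int i = 0; i < n_trials; ++i) {
      if (labels[i] == ca) { idx.push_back(i); yy.push_back(+1); }
      else if (labels[i] == cb) { idx.push_back(i); yy.push_back(-1); }
    }
    const int n = (int)idx.size();
    Xall.assign((size_t)n * n_ch, 0.0);

    for (int t = 0; t < n_time; ++t) {
      // gather features for this timepoint, row-major per trial
      for (int i = 0; i < n; ++i) {
        const int tr = idx[i];
        for (int k = 0; k < n_ch; ++k) {
          Xall[(size_t)i * n_ch + k] =
            data[tr + (size_t)n_trials * (k + (size_t)n_ch * t)];
        }
      }
      double correct = 0.0, total = 0.0;
      // dual variables per pair-trial, carried across folds/repeats of this
      // (pair, timepoint) as a feasible warm start for the solver
      std::vector<double> alpha_trial(n, 0.0), alpha_local;
      for (int r = 0; r < n_repeats; ++r) {
        for (int f = 1; f <= n_folds; ++f) {
          // split
          Xtr.clear(); ytr.clear(); Xte.clear();
          std::vector<int> yte, tr_rows;
          for (int i = 0; i < n; ++i) {
            const bool test = folds(idx[i], r) == f;
            const double* xi = &Xall[(size_t)i * n_ch];
            if (test) {
              Xte.insert(Xte.end(), xi, xi + n_ch);
              yte.push_back(yy[i]);
            } else {
              Xtr.insert(Xtr.end(), xi, xi + n_ch);
              ytr.push_back(yy[i]);
              tr_rows.push_back(i);
            }
          }
          const int ntr = (int)ytr.size(), nte = (int)yte.size();
          if (nte == 0) continue;
          // z-score with training-fold statistics only
          for (int k = 0; k < n_ch; ++k) { mu[k] = 0.0; sd[k] = 0.0; }
          for (int i = 0; i < ntr; ++i)
            for (int k = 0; k < n_ch; ++k) mu[k] += Xtr[(size_t)i * n_ch + k];
          for (int k = 0; k < n_ch; ++k) mu[k] /= ntr;
          for (int i = 0; i < ntr; ++i)
            for (int k = 0; k < n_ch; ++k) {
              const double dkv = Xtr[(size_t)i * n_ch + k] - mu[k];
              sd[k] += dkv * dkv;
            }
          for (int k = 0; k < n_ch; ++k) {
            sd[k] = std::sqrt(sd[k] / (ntr > 1 ? ntr - 1 : 1));
            if (sd[k] < 1e-12) sd[k] = 1.0;
          }
          for (int i = 0; i < ntr; ++i)
            for (int k = 0; k < n_ch; ++k)
              Xtr[(size_t)i * n_ch + k] = (Xtr[(size_t)i * n_ch + k] - mu[k]) / sd[k];
          for (int i = 0; i < nte; ++i)
            for (int k = 0; k < n_ch; ++k)
              Xte[(size_t)i * n_ch + k] = (Xte[(size_t)i * n_ch + k] - mu[k]) / sd[k];

          alpha_local.resize(ntr);
          for (int i = 0; i < ntr; ++i) alpha_local[i] = alpha_trial[tr_rows[i]];
          dcd_train(Xtr, ytr, ntr, n_ch, cost, max_epochs, tol, w, alpha_local);
          for (int i = 0; i < ntr; ++i) alpha_trial[tr_rows[i]] = alpha_local[i];

          double fold_correct = 0.0;
          for (int i = 0; i < nte; ++i) {
            double s = w[n_ch];
            const double* xi = &Xte[(size_t)i * n_ch];
            for (int k = 0; k < n_ch; ++k) s += w[k] * xi[k];
            if ((s > 0.0 ? +1 : -1) == yte[i]) fold_correct += 1.0;
          }
          correct += fold_correct / nte;
          total += 1.0;
        }
      }
      acc(p, t) = correct / total;
    }
    Rcpp::checkUserInterrupt();
  }
  return acc;
}

// Standalone linear-SVM train/predict on pre-scaled data, exposed so tests
// can compare decisions against an external SVM implementation.
// [[Rcpp::export]]
IntegerVector linear_svm_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                     NumericMatrix Xte, double cost,
                                     int max_epochs, double tol) {
  const int ntr = Xtr.nrow(), d = Xtr.ncol(), nte = Xte.nrow();
  std::vector<double> X((size_t)ntr * d), w((size_t)d + 1), alpha(ntr, 0.0);
  std::vector<int> y(ytr.begin(), ytr.end());
  for (int i = 0; i < ntr; ++i)
    for (int k = 0; k < d; ++k) X[(size_t)i * d + k] = Xtr(i, k);
  dcd_train(X, y, ntr, d, cost, max_epochs, tol, w, alpha);
  IntegerVector pred(nte);
  for (int i = 0; i < nte; ++i) {
    double s = w[d];
    for (int k = 0; k < d; ++k) s += w[k] * Xte(i, k);
    pred[i] = s > 0.0 ? +1 : -1;
  }
  return pred;
}
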