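#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Linear max-margin classifier trained by dual coordinate descent on the
// L1-loss (hinge) SVM dual, liblinear-style, with the intercept handled as a
// regularized augmented feature. Problem sizes here are tiny (tens of trials,
// tens of features), so deterministic sweeps in index order converge quickly
// and keep results reproducible across platforms.

static void svm_train_cd(const std::vector<double>& X, int n, int p,
                         const std::vector<double>& y, double C,
                         std::vector<double>& w) {
  // X is row-major n x (p+1), last column the constant 1 bias feature.
  const int d = p + 1;
  std::vector<double> alpha(n, 0.0), Qii(n);
  w.assign(d, 0.0);
  for (int i = 0; i < n; ++i) {
    double q = 0.0;
    const double* xi = &X[(size_t)i * d];
    for (int j = 0; j < d; ++j) q += xi[j] * xi[j];
    Qii[i] = q > 1e-12 ? q : 1e-12;
  }
  const int max_epochs = 300;
  const double tol = 1e-4;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &X[(size_t)i * d];
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      double G = y[i] * wx - 1.0;
      double PG;
      if (alpha[i] <= 0.0)      PG = G < 0.0 ? G : 0.0;
      else if (alpha[i] >= C)   PG = G > 0.0 ? G : 0.0;
      else                      PG = G;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C)   a_new = C;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
}

// Stratified-CV accuracy of the linear classifier for one feature matrix and
// one fold assignment. Columns are standardized with moments fitted on the
// training rows of each fold. y01 in {0,1}; fold ids 1..K.
static void fold_accuracies(const NumericMatrix& X, const IntegerVector& y01,
                            const IntegerVector& fold, int K, double C,
                            std::vector<double>& acc) {
  const int n = X.nrow(), p = X.ncol(), d = p + 1;
  acc.assign(K, NA_REAL);
  std::vector<double> Xtr, ytr, w;
  std::vector<int> te_idx;
  std::vector<double> mu(p), sd(p);
  for (int k = 1; k <= K; ++k) {
    // training moments
    int ntr = 0;
    for (int j = 0; j < p; ++j) { mu[j] = 0.0; sd[j] = 0.0; }
    for (int i = 0; i < n; ++i) if (fold[i] != k) {
      ++ntr;
      for (int j = 0; j < p; ++j) mu[j] += X(i, j);
    }
    if (ntr < 2) continue;
    for (int j = 0; j < p; ++j) mu[j] /= ntr;
    for (int i = 0; i < n; ++i) if (fold[i] != k)
      for (int j = 0; j < p; ++j) {
        double v = X(i, j) - mu[j];
        sd[j] += v * v;
      }
    for (int j = 0; j < p; ++j) {
      sd[j] = std::sqrt(sd[j] / (ntr - 1));
      if (sd[j] < 1e-12) sd[j] = 1.0;
    }
    Xtr.assign((size_t)ntr * d, 0.0);
    ytr.assign(ntr, 0.0);
    te_idx.clear();
    int r = 0, n_pos = 0;
    for (int i = 0; i < n; ++i) {
      if (fold[i] != k) {
        for (int j = 0; j < p; ++j) Xtr[(size_t)r * d + j] = (X(i, j) - mu[j]) / sd[j];
        Xtr[(size_t)r * d + p] = 1.0;
        ytr[r] = y01[i] == 1 ? 1.0 : -1.0;
        if (y01[i] == 1) ++n_pos;
        ++r;
      } else {
        te_idx.push_back(i);
      }
    }
    if (te_idx.empty()) continue;
    int correct = 0;
    if (n_pos == 0 || n_pos == ntr) {
      // single-class training fold: predict the majority (only) class
      int cls = n_pos == ntr ? 1 : 0;
      for (size_t t = 0; t < te_idx.size(); ++t)
        if (y01[te_idx[t]] == cls) ++correct;
    } else {
      svm_train_cd(Xtr, ntr, p, ytr, C, w);
      for (size_t t = 0; t < te_idx.size(); ++t) {
        int i = te_idx[t];
        double s = w[p];
        for (int j = 0; j < p; ++j) s += w[j] * (X(i, j) - mu[j]) / sd[j];
        int pred = s >= 0.0 ? 1 : 0;
        if (pred == y01[i]) ++correct;
      }
    }
    acc[k - 1] = (double)correct / te_idx.size();
  }
}

// [[Rcpp::export]]
NumericVector cpp_cv_fold_acc(NumericMatrix X, IntegerVector y01,
                              IntegerVector fold, int n_folds, double cost) {
  std::vector<double> acc;
  fold_accuracies(X, y01, fold, n_folds, cost, acc);
  return wrap(acc);
}

// Per-window fold-accuracy matrix (n_windows x n_folds) for a list of
// feature matrices sharing rows and one fold assignment.
// [[Rcpp::export]]
NumericMatrix cpp_cv_curve(List Xs, IntegerVector y01, IntegerVector fold,
                           int n_folds, double cost) {
  const int W = Xs.size();
  NumericMatrix out(W, n_folds);
  std::vector<double> acc;
  for (int wdx = 0; wdx < W; ++wdx) {
    NumericMatrix X = Xs[wdx];
    fold_accuracies(X, y01, fold, n_folds, cost, acc);
    for (int k = 0; k < n_folds; ++k) out(wdx, k) = acc[k];
  }
  return out;
}

// Permutation engine: each column b of labels/folds is one null draw; the
// full fold/classifier procedure is re-run per draw and per window. Returns
// a B x n_windows matrix of fold-mean accuracies.
// [[Rcpp::export]]
NumericMatrix cpp_null_curves(List Xs, IntegerMatrix labels, IntegerMatrix folds,
                              int n_folds, double cost) {
  const int W = Xs.size(), B = labels.ncol(), n = labels.nrow();
  NumericMatrix out(B, W);
  std::vector<double> acc;
  IntegerVector y(n), f(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) { y[i] = labels(i, b); f[i] = folds(i, b); }
    for (int wdx = 0; wdx < W; ++wdx) {
      NumericMatrix X = Xs[wdx];
      fold_accuracies(X, y, f, n_folds, cost, acc);
      double m = 0.0; int cnt = 0;
      for (int k = 0; k < n_folds; ++k)
        if (!ISNAN(acc[k])) { m += acc[k]; ++cnt; }
      out(b, wdx) = cnt > 0 ? m / cnt : NA_REAL;
    }
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Train on all rows, return the (unstandardized-input) decision weights and
// test-set predictions; used for cross-checks against reference SVM fits.
// [[Rcpp::export]]
IntegerVector cpp_svm_predict(NumericMatrix Xtr, IntegerVector y01,
                              NumericMatrix Xte, double cost) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), d = p + 1;
  std::vector<double> mu(p, 0.0), sd(p, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) mu[j] += Xtr(i, j);
  for (int j = 0; j < p; ++j) mu[j] /= n;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) { double v = Xtr(i, j) - mu[j]; sd[j] += v * v; }
  for (int j = 0; j < p; ++j) {
    sd[j] = std::sqrt(sd[j] / (n - 1));
    if (sd[j] < 1e-12) sd[j] = 1.0;
  }
  std::vector<double> X((size_t)n * d), y(n), w;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) X[(size_t)i * d + j] = (Xtr(i, j) - mu[j]) / sd[j];
    X[(size_t)i * d + p] = 1.0;
    y[i] = y01[i] == 1 ? 1.0 : -1.0;
  }
  svm_train_cd(X, n, p, y, cost, w);
  IntegerVector pred(Xte.nrow());
  for (int i = 0; i < Xte.nrow(); ++i) {
    double s = w[p];
    for (int j = 0; j < p; ++j) s += w[j] * (Xte(i, j) - mu[j]) / sd[j];
    pred[i] = s >= 0.0 ? 1 : 0;
  }
  return pred;
}
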