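#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Base classifier: shrinkage-regularized linear discriminant analysis
// with empirical class priors. The discriminant is
//   w = (S + lambda tr(S)/p I)^-1 (mu1 - mu0),
// and a row is called positive iff
//   w . x - w . (mu1 + mu0)/2 + log(n1/n0) > 0.
// The log-prior term shifts the boundary toward the majority class, so a
// negatives-heavy training set yields a conservative (high-specificity)
// rule. The ridge (lambda = 0.05 of the mean eigenvalue) keeps the
// weights bounded when features are collinear — binding-site descriptors
// like composition, stem length and duplex energy are strongly coupled,
// and an unregularized inverse extrapolates wildly off the training
// manifold. Zero-variance features get weight exactly 0, so constant
// features cannot change the classifier. Everything is closed form and
// deterministic.
//
// Classifier representation: numeric vector c(b, w_1 ... w_p).

static bool solve_sym(std::vector<double>& A, std::vector<double>& b, int p) {
  // Gaussian elimination with partial pivoting on the p x p system A x = b
  for (int k = 0; k < p; ++k) {
    int piv = k;
    double best = std::fabs(A[(size_t)k * p + k]);
    for (int r = k + 1; r < p; ++r) {
      double v = std::fabs(A[(size_t)r * p + k]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) return false;
    if (piv != k) {
      for (int c = 0; c < p; ++c)
        std::swap(A[(size_t)k * p + c], A[(size_t)piv * p + c]);
      std::swap(b[k], b[piv]);
    }
    for (int r = k + 1; r < p; ++r) {
      double f = A[(size_t)r * p + k] / A[(size_t)k * p + k];
      if (f == 0.0) continue;
      for (int c = k; c < p; ++c) A[(size_t)r * p + c] -= f * A[(size_t)k * p + c];
      b[r] -= f * b[k];
    }
  }
  for (int k = p - 1; k >= 0; --k) {
    double s = b[k];
    for (int c = k + 1; c < p; ++c) s -= A[(size_t)k * p + c] * b[c];
    b[k] = s / A[(size_t)k * p + k];
  }
  return true;
}

// Fit on the rows flagged in `use`. `col` is X column-major. Returns c(b, w).
static std::vector<double> lda_fit_core(const std::vector<double>& col,
                                        int n, int p,
                                        const IntegerVector& y,
                                        const std::vector<char>& use) {
  std::vector<double> mu0(p, 0.0), mu1(p, 0.0);
  int n0 = 0, n1 = 0;
  for (int i = 0; i < n; ++i) {
    if (!use[i]) continue;
    if (y[i] == 1) { ++n1; for (int f = 0; f < p; ++f) mu1[f] += col[(size_t)f * n + i]; }
    else           { ++n0; for (int f = 0; f < p; ++f) mu0[f] += col[(size_t)f * n + i]; }
  }
  std::vector<double> out(p + 1, 0.0);
  if (n0 == 0 || n1 == 0) {             // degenerate: constant vote by prior
    out[0] = (n1 >= n0 && n1 > 0) ? 1.0 : -1.0;
    return out;
  }
  for (int f = 0; f < p; ++f) { mu0[f] /= n0; mu1[f] /= n1; }
  std::vector<double> S((size_t)p * p, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!use[i]) continue;
    const std::vector<double>& mu = (y[i] == 1) ? mu1 : mu0;
    for (int f = 0; f < p; ++f) {
      double df = col[(size_t)f * n + i] - mu[f];
      for (int g = f; g < p; ++g)
        S[(size_t)f * p + g] += df * (col[(size_t)g * n + i] - mu[g]);
    }
  }
  double denom = std::max(1, n0 + n1 - 2);
  double trace = 0.0;
  for (int f = 0; f < p; ++f) trace += S[(size_t)f * p + f] / denom;
  double ridge = 0.05 * std::max(trace / p, 1e-30);
  for (int f = 0; f < p; ++f) {
    for (int g = f; g < p; ++g) {
      double v = S[(size_t)f * p + g] / denom;
      S[(size_t)f * p + g] = v;
      S[(size_t)g * p + f] = v;
    }
    S[(size_t)f * p + f] += ridge;
  }
  std::vector<double> w(p);
  for (int f = 0; f < p; ++f) w[f] = mu1[f] - mu0[f];
  if (!solve_sym(S, w, p)) {
    out[0] = (n1 >= n0) ? 1.0 : -1.0;
    return out;
  }
  double b = std::log((double)n1 / n0);
  for (int f = 0; f < p; ++f) b -= w[f] * 0.5 * (mu0[f] + mu1[f]);
  out[0] = b;
  for (int f = 0; f < p; ++f) out[f + 1] = w[f];
  return out;
}

static std::vector<double> flatten(const NumericMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> col((size_t)n * p);
  for (int f = 0; f < p; ++f)
    for (int i = 0; i < n; ++i) col[(size_t)f * n + i] = X(i, f);
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_lda_fit(NumericMatrix X, IntegerVector y, IntegerVector rows) {
  std::vector<char> use(X.nrow(), rows.size() == 0 ? 1 : 0);
  for (int t = 0; t < rows.size(); ++t) use[rows[t] - 1] = 1;
  std::vector<double> col = flatten(X);
  std::vector<double> m = lda_fit_core(col, X.nrow(), X.ncol(), y, use);
  return wrap(m);
}

static inline int lda_predict_row(const std::vector<double>& m,
                                  const NumericMatrix& X, int row) {
  double s = m[0];
  for (int f = 0; f < (int)m.size() - 1; ++f) s += m[f + 1] * X(row, f);
  return s > 0.0 ? 1 : 0;
}

// [[Rcpp::export]]
IntegerVector cpp_lda_predict(NumericVector model, NumericMatrix X) {
  std::vector<double> m(model.begin(), model.end());
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = lda_predict_row(m, X, i);
  return out;
}

// Leave-one-out cross-validated accuracy of the LDA learner on (X, y).
// [[Rcpp::export]]
double cpp_lda_loocv(NumericMatrix X, IntegerVector y) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> col = flatten(X);
  std::vector<char> use(n, 1);
  int correct = 0;
  for (int i = 0; i < n; ++i) {
    use[i] = 0;
    std::vector<double> m = lda_fit_core(col, n, p, y, use);
    double sc = m[0];
    for (int f = 0; f < p; ++f) sc += m[f + 1] * col[(size_t)f * n + i];
    if ((sc > 0.0 ? 1 : 0) == y[i]) ++correct;
    use[i] = 1;
  }
  return (double)correct / n;
}
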