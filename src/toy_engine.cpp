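#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Toy nearest-neighbour model used by the offline engine: per-pair free
// energies G-C -3, A-U -2, G-U -1 kcal/mol, no loop terms, minimum hairpin
// loop of 3 nt. Base encoding: A=0 C=1 G=2 U=3, N=4 (never pairs).

static const double RT37 = 0.0019872041 * 310.15; // kcal/mol at 37 C

static inline double pscore(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.0;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.0;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0;
  return 0.0;
}

// Minimum free energy over structures with only inter-molecular pairs:
// maximum-weight non-crossing antiparallel matching, solved by aligning
// `a` 5'->3' against `b` reversed.
// [[Rcpp::export]]
List cpp_toy_duplex(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = std::max(M(i - 1, j), M(i, j - 1));
      double s = pscore(a[i - 1], b[m - j]);
      if (s > 0.0 && M(i - 1, j - 1) + s > best) best = M(i - 1, j - 1) + s;
      M(i, j) = best;
    }
  }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    double s = pscore(a[i - 1], b[m - j]);
    if (s > 0.0 && M(i, j) == M(i - 1, j - 1) + s) {
      pa.push_back(i); pb.push_back(m - j + 1); --i; --j;
    } else if (M(i, j) == M(i - 1, j)) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["energy"] = -M(n, m),
                      _["a_pos"] = wrap(pa), _["b_pos"] = wrap(pb));
}

// Ensemble free energy -RT ln Z over all intra-molecular secondary
// structures (min hairpin loop 3). Positions flagged in `blocked` may not
// pair (the single-strandedness constraint behind dG_open). Log-space DP
// so that both structure-rich and structure-free sequences stay in range.
// [[Rcpp::export]]
double cpp_toy_ensemble(IntegerVector s, LogicalVector blocked) {
  int n = s.size();
  if (n == 0) return 0.0;
  std::vector<double> L((size_t)(n + 2) * (n + 2), 0.0); // log Z(i,j); empty => log 1
  auto idx = [&](int i, int j) { return (size_t)i * (n + 2) + j; };
  for (int len = 5; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double acc = L[idx(i + 1, j)]; // i unpaired
      if (!blocked[i - 1]) {
        for (int k = i + 4; k <= j; ++k) {
          if (blocked[k - 1]) continue;
          double ps = pscore(s[i - 1], s[k - 1]);
          if (ps <= 0.0) continue;
          double t = ps / RT37 + L[idx(i + 1, k - 1)] + L[idx(k + 1, j)];
          if (t > acc) acc = t + std::log1p(std::exp(acc - t));
          else         acc = acc + std::log1p(std::exp(t - acc));
        }
      }
      L[idx(i, j)] = acc;
    }
  }
  return -RT37 * L[idx(1, n)];
}

// MFE joint structure of two concatenated molecules (positions 1..cut and
// cut+1..n) allowing intra- and inter-molecular pairs. Forced pairs (fi,fj)
// are driven into the optimum through a large bonus and their partners are
// locked; the minimum-hairpin-loop rule applies only within a molecule.
// [[Rcpp::export]]
List cpp_toy_cofold(IntegerVector s, int cut, IntegerVector fi, IntegerVector fj) {
  int n = s.size();
  std::vector<int> forced(n + 1, 0);
  for (int t = 0; t < fi.size(); ++t) { forced[fi[t]] = fj[t]; forced[fj[t]] = fi[t]; }
  const double BONUS = 1e6;
  auto W = [&](int i, int k) -> double { // weight of pair (i,k), i<k; <0 => forbidden
    if (forced[i] && forced[i] != k) return -1.0;
    if (forced[k] && forced[k] != i) return -1.0;
    bool same = (i <= cut) == (k <= cut);
    if (same && k - i < 4) return -1.0;
    double ps = pscore(s[i - 1], s[k - 1]);
    if (ps <= 0.0) return -1.0;
    return ps + (forced[i] == k ? BONUS : 0.0);
  };
  std::vector<double> D((size_t)(n + 2) * (n + 2), 0.0);
  auto idx = [&](int i, int j) { return (size_t)i * (n + 2) + j; };
  for (int len = 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double best = D[idx(i + 1, j)];
      for (int k = i + 1; k <= j; ++k) {
        double w = W(i, k);
        if (w < 0.0) continue;
        double t = w + D[idx(i + 1, k - 1)] + D[idx(k + 1, j)];
        if (t > best) best = t;
      }
      D[idx(i, j)] = best;
    }
  }
  IntegerVector partner(n, 0);
  std::function<void(int, int)> tb = [&](int i, int j) {
    while (i < j) {
      if (D[idx(i, j)] == D[idx(i + 1, j)]) { ++i; continue; }
      for (int k = i + 1; k <= j; ++k) {
        double w = W(i, k);
        if (w < 0.0) continue;
        if (D[idx(i, j)] == w + D[idx(i + 1, k - 1)] + D[idx(k + 1, j)]) {
          partner[i - 1] = k; partner[k - 1] = i;
          tb(i + 1, k - 1);
          i = k + 1;
          break;
        }
      }
    }
  };
  tb(1, n);
  double e = 0.0;
  for (int i = 1; i <= n; ++i)
    if (partner[i - 1] > i) e -= pscore(s[i - 1], s[partner[i - 1] - 1]);
  return List::create(_["partner"] = partner, _["energy"] = e);
}
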