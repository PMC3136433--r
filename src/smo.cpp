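// Sequential minimal optimization for the soft-margin SVM dual:
//   max W(a) = sum a_i - 1/2 sum a_i a_j y_i y_j K_ij
//   s.t. 0 <= a_i <= C, sum a_i y_i = 0
// Platt-style pair selection with a full error cache: first-violator outer
// loop, |E1-E2|-maximizing second choice, then randomized sweeps (seeded, so
// tie-breaks are reproducible and independent of R's global RNG).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Smo {
  const NumericMatrix &K;
  const NumericVector &y;
  double C, tol, eps;
  int n;
  std::vector<double> alpha, E; // E_i = f(x_i) - y_i
  double b;
  std::mt19937 rng;

  Smo(const NumericMatrix &K_, const NumericVector &y_, double C_,
      double tol_, double eps_, unsigned seed)
      : K(K_), y(y_), C(C_), tol(tol_), eps(eps_), n(K_.nrow()),
        alpha(n, 0.0), E(n), b(0.0), rng(seed) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];
  }

  bool nonBound(int i) const { return alpha[i] > eps && alpha[i] < C - eps; }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    const double a1 = alpha[i1], a2 = alpha[i2];
    const double y1 = y[i1], y2 = y[i2], s = y1 * y2;
    const double E1 = E[i1], E2 = E[i2];
    double L, H;
    if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C, C + a2 - a1); }
    else       { L = std::max(0.0, a1 + a2 - C); H = std::min(C, a1 + a2); }
    if (L >= H) return false;
    const double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    const double eta = k11 + k22 - 2.0 * k12; // >= 0 for a PSD kernel
    const double g = y2 * (E1 - E2);          // dW/da2 along the constraint
    double a2new;
    if (eta > 0) {
      a2new = a2 + g / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      const double dL = L - a2, dH = H - a2;
      const double WL = g * dL - 0.5 * eta * dL * dL;
      const double WH = g * dH - 0.5 * eta * dH * dH;
      if (WL > WH + eps) a2new = L;
      else if (WH > WL + eps) a2new = H;
      else return false;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0)      { a2new += s * a1new;       a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }
    const double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    const double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    if (a1new > eps && a1new < C - eps)      bnew = b1;
    else if (a2new > eps && a2new < C - eps) bnew = b2;
    else                                     bnew = 0.5 * (b1 + b2);
    const double db = bnew - b, d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K(i1, i) + d2 * K(i2, i) + db;
    alpha[i1] = a1new; alpha[i2] = a2new; b = bnew;
    return true;
  }

  bool examine(int i2) {
    const double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    const double r2 = E2 * y2;
    if (!((r2 < -tol && a2 < C - eps) || (r2 > tol && a2 > eps))) return false;
    // 1. second-choice heuristic: maximize |E1 - E2| over non-bound alphas
    int best = -1; double gap = 0.0;
    for (int i = 0; i < n; ++i)
      if (nonBound(i) && std::fabs(E[i] - E2) > gap) {
        gap = std::fabs(E[i] - E2); best = i;
      }
    if (best >= 0 && takeStep(best, i2)) return true;
    // 2. sweep non-bound alphas from a random start
    int start = static_cast<int>(rng() % n);
    for (int k = 0; k < n; ++k) {
      int i1 = (start + k) % n;
      if (nonBound(i1) && takeStep(i1, i2)) return true;
    }
    // 3. sweep everything from a random start
    start = static_cast<int>(rng() % n);
    for (int k = 0; k < n; ++k)
      if (takeStep((start + k) % n, i2)) return true;
    return false;
  }
};

} // namespace

// [[Rcpp::export]]
List smo_solve(const NumericMatrix &K, const NumericVector &y, double C,
               double tol, double eps, int max_epochs, int seed) {
  if (K.nrow() != K.ncol() || K.nrow() != y.size())
    stop("DimensionError: kernel matrix and labels are inconsistent");
  Smo smo(K, y, C, tol, eps, static_cast<unsigned>(seed));
  int changed = 0, epochs = 0;
  bool examineAll = true;
  while (changed > 0 || examineAll) {
    changed = 0;
    if (examineAll) {
      for (int i = 0; i < smo.n; ++i) changed += smo.examine(i);
    } else {
      for (int i = 0; i < smo.n; ++i)
        if (smo.nonBound(i)) changed += smo.examine(i);
    }
    if (examineAll) examineAll = false;
    else if (changed == 0) examineAll = true;
    if (++epochs >= max_epochs) break;
  }
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(), smo.alpha.end()),
                      _["b"] = smo.b, _["epochs"] = epochs,
                      _["converged"] = epochs < max_epochs);
}
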