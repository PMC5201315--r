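#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual:
//   max  sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j K_ij
//   s.t. 0 <= a_i <= C,  sum_i a_i y_i = 0
// Pairwise updates keep both constraints satisfied exactly at every step.
// Partner selection follows Platt: first the maximal |E_i - E_j|, then a
// deterministic scan over the remaining indices if that pair cannot move.

struct Smo {
  const NumericMatrix& K;
  const NumericVector& y;
  double C, b;
  std::vector<double> alpha, E;
  static constexpr double eps = 1e-12;

  Smo(const NumericMatrix& K_, const NumericVector& y_, double C_)
      : K(K_), y(y_), C(C_), b(0.0), alpha(K_.nrow(), 0.0), E(K_.nrow()) {
    for (int i = 0; i < K.nrow(); ++i) E[i] = -y[i];  // f == 0 initially
  }

  // attempt a joint update of (alpha_i, alpha_j); true if it moved
  bool take_step(int i, int j) {
    if (i == j) return false;
    const double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (H - L < eps) return false;
    const double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
    double aj;
    if (eta < -eps) {
      aj = aj_old - y[j] * (E[i] - E[j]) / eta;
      aj = std::min(H, std::max(L, aj));
    } else {
      // flat or concave-up direction: move to the better interval end
      const double s = y[j] * (E[j] - E[i]);
      aj = s > 0 ? H : L;
    }
    if (std::fabs(aj - aj_old) < 1e-8 * (aj + aj_old + 1e-8)) return false;
    const double ai = ai_old + y[i] * y[j] * (aj_old - aj);

    const double b1 = b - E[i] - y[i] * (ai - ai_old) * K(i, i)
                        - y[j] * (aj - aj_old) * K(i, j);
    const double b2 = b - E[j] - y[i] * (ai - ai_old) * K(i, j)
                        - y[j] * (aj - aj_old) * K(j, j);
    double b_new;
    if (ai > eps && ai < C - eps)      b_new = b1;
    else if (aj > eps && aj < C - eps) b_new = b2;
    else                               b_new = 0.5 * (b1 + b2);

    const double dai = (ai - ai_old) * y[i];
    const double daj = (aj - aj_old) * y[j];
    const double db = b_new - b;
    const int n = K.nrow();
    for (int k = 0; k < n; ++k)
      E[k] += dai * K(i, k) + daj * K(j, k) + db;
    alpha[i] = ai;
    alpha[j] = aj;
    b = b_new;
    return true;
  }

  bool examine(int i, double tol) {
    const double ri = E[i] * y[i];
    if (!((ri < -tol && alpha[i] < C - eps) ||
          (ri > tol && alpha[i] > eps)))
      return false;
    const int n = K.nrow();
    // heuristic partner: maximal |E_i - E_j|
    int j = -1;
    double best = -1.0;
    for (int k = 0; k < n; ++k) {
      if (k == i) continue;
      const double d = std::fabs(E[i] - E[k]);
      if (d > best) { best = d; j = k; }
    }
    if (j >= 0 && take_step(i, j)) return true;
    // fallback: non-bound alphas, then everything, in fixed order
    for (int k = 0; k < n; ++k)
      if (alpha[k] > eps && alpha[k] < C - eps && take_step(i, k))
        return true;
    for (int k = 0; k < n; ++k)
      if (take_step(i, k)) return true;
    return false;
  }
};

// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_sweeps = 5000) {
  Smo s(K, y, C);
  const int n = K.nrow();
  int sweeps = 0;
  bool examine_all = true;
  for (; sweeps < max_sweeps; ++sweeps) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      if (!examine_all &&
          !(s.alpha[i] > Smo::eps && s.alpha[i] < C - Smo::eps))
        continue;
      changed += s.examine(i, tol) ? 1 : 0;
    }
    if (examine_all) {
      if (changed == 0) break;      // full pass, no KKT violation movable
      examine_all = false;
    } else if (changed == 0) {
      examine_all = true;           // re-check the whole set before stopping
    }
  }
  return List::create(_["alpha"] = NumericVector(s.alpha.begin(), s.alpha.end()),
                      _["b"] = s.b,
                      _["sweeps"] = sweeps,
                      _["converged"] = sweeps < max_sweeps);
}

// RBF kernel matrix exp(-g * ||x_i - x_j||^2) between row sets A and B.
// [[Rcpp::export]]
NumericMatrix rbf_kernel(NumericMatrix A, NumericMatrix B, double g) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  NumericMatrix K(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-g * s);
    }
  return K;
}
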