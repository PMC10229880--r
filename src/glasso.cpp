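#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Graphical lasso by block coordinate descent (Friedman-style), with the
// diagonal of the precision matrix left unpenalized so that W_ii = S_ii at
// the optimum. Each column update solves
//   min_b  0.5 * b' W11 b - s12' b + lambda * ||b||_1
// by cyclic coordinate descent; Theta is recovered from the final regression
// coefficients and the stopping rule is the scaled duality gap
//   gap = tr(S Theta) + lambda * sum_{i != j} |Theta_ij| - p,
// which is zero at the optimum (and reduces to tr(S Theta) - p when
// lambda = 0, i.e. Theta = S^{-1}).

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One cyclic coordinate-descent solve of the column-j lasso subproblem.
// W is the current covariance estimate, Beta(k, j) holds the coefficient of
// node k in the regression for node j (Beta(j, j) == 0).
static void update_column(const NumericMatrix& S, NumericMatrix& W,
                          NumericMatrix& Beta, int j, double lambda,
                          double inner_tol, int inner_maxit) {
  const int p = S.nrow();
  for (int it = 0; it < inner_maxit; ++it) {
    double max_delta = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      // partial residual: s_kj - sum_{l != j, l != k} W_kl * beta_l
      double r = S(k, j);
      for (int l = 0; l < p; ++l) {
        if (l == j || l == k) continue;
        double b = Beta(l, j);
        if (b != 0.0) r -= W(k, l) * b;
      }
      double b_new = soft(r, lambda) / W(k, k);
      double d = b_new - Beta(k, j);
      if (std::abs(d) > max_delta) max_delta = std::abs(d);
      Beta(k, j) = b_new;
    }
    if (max_delta < inner_tol) break;
  }
  // w12 = W11 * beta
  for (int k = 0; k < p; ++k) {
    if (k == j) continue;
    double w = 0.0;
    for (int l = 0; l < p; ++l) {
      if (l == j) continue;
      double b = Beta(l, j);
      if (b != 0.0) w += W(k, l) * b;
    }
    W(k, j) = w;
    W(j, k) = w;
  }
}

// Recover Theta from W and the regression coefficients. Exact zeros in Theta
// come from the lasso soft threshold; an off-diagonal pair is declared zero
// only when both directed coefficients are zero, otherwise the two halves are
// averaged (they agree to within the convergence tolerance).
static NumericMatrix recover_theta(const NumericMatrix& W,
                                   const NumericMatrix& Beta) {
  const int p = W.nrow();
  NumericMatrix Theta(p, p);
  NumericVector theta_diag(p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      dot += W(k, j) * Beta(k, j);
    }
    theta_diag[j] = 1.0 / (W(j, j) - dot);
  }
  for (int j = 0; j < p; ++j) {
    Theta(j, j) = theta_diag[j];
    for (int k = j + 1; k < p; ++k) {
      double a = -Beta(k, j) * theta_diag[j];
      double b = -Beta(j, k) * theta_diag[k];
      double v;
      if (Beta(k, j) == 0.0 && Beta(j, k) == 0.0) {
        v = 0.0;
      } else {
        v = 0.5 * (a + b);
      }
      Theta(k, j) = v;
      Theta(j, k) = v;
    }
  }
  return Theta;
}

static double duality_gap(const NumericMatrix& S, const NumericMatrix& Theta,
                          double lambda) {
  const int p = S.nrow();
  double tr = 0.0, l1 = 0.0;
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) {
      tr += S(i, j) * Theta(j, i);
      if (i != j) l1 += std::abs(Theta(i, j));
    }
  }
  return tr + lambda * l1 - static_cast<double>(p);
}

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(NumericMatrix S, double lambda, double tol = 1e-6,
                int maxit = 1000, Nullable<NumericMatrix> beta_init = R_NilValue) {
  const int p = S.nrow();
  if (p == 1) {
    NumericMatrix Theta(1, 1);
    Theta(0, 0) = 1.0 / S(0, 0);
    return List::create(_["theta"] = Theta, _["beta"] = NumericMatrix(1, 1),
                        _["iterations"] = 0, _["converged"] = true,
                        _["gap"] = 0.0);
  }
  NumericMatrix W = clone(S);
  NumericMatrix Beta(p, p);
  if (beta_init.isNotNull()) {
    NumericMatrix b0(beta_init);
    Beta = clone(b0);
    // rebuild W from the warm-started coefficients
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          double b = Beta(l, j);
          if (b != 0.0) w += W(k, l) * b;
        }
        W(k, j) = w;
        W(j, k) = w;
      }
    }
  }
  const double inner_tol = tol * 1e-2;
  bool converged = false;
  int it = 0;
  double gap = R_PosInf;
  NumericMatrix Theta;
  for (it = 1; it <= maxit; ++it) {
    for (int j = 0; j < p; ++j) {
      update_column(S, W, Beta, j, lambda, inner_tol, 1000);
    }
    Theta = recover_theta(W, Beta);
    gap = duality_gap(S, Theta, lambda);
    if (std::abs(gap) / static_cast<double>(p) < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["theta"] = Theta, _["beta"] = Beta,
                      _["iterations"] = it, _["converged"] = converged,
                      _["gap"] = gap);
}

// Fit the whole decreasing-lambda path with warm starts. `lambdas` must be
// strictly decreasing; the sparsest model is fitted first and each fit seeds
// the next.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
List glasso_path_cpp(NumericMatrix S, NumericVector lambdas, double tol = 1e-6,
                     int maxit = 1000) {
  const int m = lambdas.size();
  List thetas(m);
  IntegerVector iterations(m);
  LogicalVector converged(m);
  NumericVector gaps(m);
  Nullable<NumericMatrix> warm = R_NilValue;
  for (int i = 0; i < m; ++i) {
    List fit = glasso_cpp(S, lambdas[i], tol, maxit, warm);
    thetas[i] = fit["theta"];
    iterations[i] = as<int>(fit["iterations"]);
    converged[i] = as<bool>(fit["converged"]);
    gaps[i] = as<double>(fit["gap"]);
    warm = Nullable<NumericMatrix>(fit["beta"]);
  }
  return List::create(_["thetas"] = thetas, _["iterations"] = iterations,
                      _["converged"] = converged, _["gaps"] = gaps);
}
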