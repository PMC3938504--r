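#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate descent for L1-penalised logistic regression, glmnet-style:
// outer IRLS quadratic approximation, inner cyclic coordinate descent with
// soft-thresholding.  Objective minimised for each lambda:
//   (1/n) * sum_i [ -y_i eta_i + log(1 + exp(eta_i)) ] + lambda * sum_j |beta_j|
// with eta = b0 + X beta; the intercept is never penalised.
//
// X must arrive standardised (mean 0, sd 1 per column); de-standardisation
// happens on the R side.  lambda must be non-increasing so warm starts carry.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List cd_logistic(const NumericMatrix& X, const NumericVector& y,
                 const NumericVector& lambda,
                 double tol = 1e-9, int maxit = 200, int max_inner = 1000) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  const double wmin = 1e-5;

  NumericMatrix B(p, nlam);
  NumericVector B0(nlam);
  IntegerVector iters(nlam);
  LogicalVector conv(nlam);

  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = std::log(std::max(ybar, 1e-10) / std::max(1.0 - ybar, 1e-10));

  std::vector<double> eta(n, b0), w(n), z(n);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    bool converged = false;
    int it = 0;
    for (; it < maxit && !converged; ++it) {
      // IRLS weights and working response around current eta
      for (int i = 0; i < n; ++i) {
        double pi = 1.0 / (1.0 + std::exp(-eta[i]));
        double wi = pi * (1.0 - pi);
        if (wi < wmin) wi = wmin;
        w[i] = wi;
        z[i] = eta[i] + (y[i] - pi) / wi;
      }
      // inner CD on the penalised weighted least squares problem
      double max_delta_outer = 0.0;
      for (int inner = 0; inner < max_inner; ++inner) {
        double max_delta = 0.0;
        for (int j = 0; j < p; ++j) {
          double num = 0.0, den = 0.0;
          for (int i = 0; i < n; ++i) {
            double xij = X(i, j);
            num += w[i] * xij * (z[i] - eta[i] + xij * beta[j]);
            den += w[i] * xij * xij;
          }
          if (den <= 0.0) continue;
          double bnew = soft(num / n, lam) / (den / n);
          double d = bnew - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) eta[i] += X(i, j) * d;
            beta[j] = bnew;
            double ad = std::fabs(d);
            if (ad > max_delta) max_delta = ad;
          }
        }
        // intercept update
        double sw = 0.0, swr = 0.0;
        for (int i = 0; i < n; ++i) {
          sw += w[i];
          swr += w[i] * (z[i] - eta[i]);
        }
        double d0 = swr / sw;
        if (d0 != 0.0) {
          b0 += d0;
          for (int i = 0; i < n; ++i) eta[i] += d0;
          if (std::fabs(d0) > max_delta) max_delta = std::fabs(d0);
        }
        if (max_delta > max_delta_outer) max_delta_outer = max_delta;
        if (max_delta < tol) break;
      }
      if (max_delta_outer < tol) converged = true;
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
    B0[l] = b0;
    iters[l] = it;
    conv[l] = converged || maxit == 0;
  }

  return List::create(_["beta"] = B, _["intercept"] = B0,
                      _["iterations"] = iters, _["converged"] = conv);
}
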