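// Coordinate-descent LASSO path with K-fold cross-validation and the
// one-standard-error rule, matching glmnet's objective
//   (1/2n) ||y - b0 - X b||^2 + lambda ||b||_1
// with columns standardised to unit population sd. Small dense problems
// only (pathway parent sets), so no sparsity tricks are needed.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Std {
  std::vector<double> mean, sd;
  double ymean;
};

// standardise columns of X (population sd) and centre y over rows in idx
Std standardise(const NumericMatrix& X, const NumericVector& y,
                const std::vector<int>& idx, std::vector<double>& Xs,
                std::vector<double>& ys) {
  int n = idx.size(), p = X.ncol();
  Std st;
  st.mean.assign(p, 0.0);
  st.sd.assign(p, 0.0);
  st.ymean = 0.0;
  for (int i = 0; i < n; ++i) st.ymean += y[idx[i]];
  st.ymean /= n;
  for (int j = 0; j < p; ++j) {
    double m = 0;
    for (int i = 0; i < n; ++i) m += X(idx[i], j);
    m /= n;
    double v = 0;
    for (int i = 0; i < n; ++i) {
      double d = X(idx[i], j) - m;
      v += d * d;
    }
    st.mean[j] = m;
    st.sd[j] = std::sqrt(v / n);
  }
  Xs.assign((size_t)n * p, 0.0);
  ys.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    ys[i] = y[idx[i]] - st.ymean;
    for (int j = 0; j < p; ++j) {
      Xs[(size_t)j * n + i] =
          st.sd[j] > 0 ? (X(idx[i], j) - st.mean[j]) / st.sd[j] : 0.0;
    }
  }
  return st;
}

inline double soft(double z, double l) {
  if (z > l) return z - l;
  if (z < -l) return z + l;
  return 0.0;
}

// CD over the whole lambda path (decreasing) with warm starts, in
// covariance form: G = X'X/n (p x p), c = X'y/n, so each coordinate update
// costs O(p) regardless of n.
void cd_path(const std::vector<double>& Xs, const std::vector<double>& ys,
             int n, int p, const std::vector<double>& lambda,
             std::vector<double>& beta_path) {
  std::vector<double> G((size_t)p * p, 0.0), c(p, 0.0);
  double yy = 0.0;
  for (int i = 0; i < n; ++i) yy += ys[i] * ys[i];
  yy /= n;
  for (int j = 0; j < p; ++j) {
    const double* xj = &Xs[(size_t)j * n];
    double cj = 0.0;
    for (int i = 0; i < n; ++i) cj += xj[i] * ys[i];
    c[j] = cj / n;
    for (int k = j; k < p; ++k) {
      const double* xk = &Xs[(size_t)k * n];
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += xj[i] * xk[i];
      G[(size_t)j * p + k] = G[(size_t)k * p + j] = g / n;
    }
  }

  std::vector<double> b(p, 0.0), gb(p, 0.0);  // gb = G b
  int L = lambda.size();
  beta_path.assign((size_t)p * L, 0.0);
  double tol = 1e-6 * std::max(1.0, std::sqrt(yy));

  auto objective = [&](double lam) {
    double quad = 0.0, lin = 0.0, l1 = 0.0;
    for (int j = 0; j < p; ++j) {
      quad += b[j] * gb[j];
      lin += b[j] * c[j];
      l1 += std::fabs(b[j]);
    }
    return (yy - 2.0 * lin + quad) / 2.0 + lam * l1;
  };

  for (int l = 0; l < L; ++l) {
    double lam = lambda[l];
    double obj = objective(lam);
    // near-collinear designs let coefficients slide along flat valleys with
    // large coordinate moves but little objective change: stop on both
    for (int it = 0; it < 60; ++it) {
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        double gjj = G[(size_t)j * p + j];
        if (gjj <= 0) continue;  // zero-variance column
        double rho = c[j] - gb[j] + gjj * b[j];
        double bn = soft(rho, lam) / gjj;
        double d = bn - b[j];
        if (d != 0.0) {
          const double* Gj = &G[(size_t)j * p];
          for (int k = 0; k < p; ++k) gb[k] += d * Gj[k];
          b[j] = bn;
          if (std::fabs(d) > maxd) maxd = std::fabs(d);
        }
      }
      if (maxd < tol) break;
      double obj2 = objective(lam);
      if (obj - obj2 < 1e-7 * std::max(1.0, obj)) break;
      obj = obj2;
    }
    for (int j = 0; j < p; ++j) beta_path[(size_t)j + (size_t)p * l] = b[j];
  }
}

}  // namespace

// K-fold cross-validated LASSO; returns coefficients (standardised scale) at
// the one-SE lambda, plus the path diagnostics. foldid: 1..nfolds per row.
// [[Rcpp::export]]
List cd_lasso_cv(NumericMatrix X, NumericVector y, IntegerVector foldid,
                 int nlambda, double lambda_min_ratio) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  std::vector<double> Xs, ys;
  standardise(X, y, all, Xs, ys);

  double lmax = 0.0;
  for (int j = 0; j < p; ++j) {
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += Xs[(size_t)j * n + i] * ys[i];
    rho = std::fabs(rho) / n;
    if (rho > lmax) lmax = rho;
  }
  if (lmax <= 0) {
    return List::create(_["coef"] = NumericVector(p),
                        _["lambda_1se"] = NA_REAL, _["lambda"] = NumericVector(0));
  }
  std::vector<double> lambda(nlambda);
  double lstep = std::log(lambda_min_ratio) / (nlambda - 1);
  for (int l = 0; l < nlambda; ++l) lambda[l] = lmax * std::exp(lstep * l);

  int nfolds = 0;
  for (int i = 0; i < n; ++i) nfolds = std::max(nfolds, foldid[i]);
  std::vector<std::vector<double>> fold_mse(nfolds,
                                            std::vector<double>(nlambda, 0.0));
  for (int k = 1; k <= nfolds; ++k) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (foldid[i] == k ? te : tr).push_back(i);
    if (te.empty() || tr.size() < 2) continue;
    std::vector<double> Xtr, ytr;
    Std st = standardise(X, y, tr, Xtr, ytr);
    std::vector<double> bp;
    cd_path(Xtr, ytr, tr.size(), p, lambda, bp);
    for (int l = 0; l < nlambda; ++l) {
      double mse = 0.0;
      for (size_t t = 0; t < te.size(); ++t) {
        double pred = st.ymean;
        for (int j = 0; j < p; ++j) {
          if (st.sd[j] > 0)
            pred += bp[(size_t)j + (size_t)p * l] *
                    (X(te[t], j) - st.mean[j]) / st.sd[j];
        }
        double d = y[te[t]] - pred;
        mse += d * d;
      }
      fold_mse[k - 1][l] = mse / te.size();
    }
  }
  NumericVector cvm(nlambda), cvse(nlambda);
  for (int l = 0; l < nlambda; ++l) {
    double m = 0;
    for (int k = 0; k < nfolds; ++k) m += fold_mse[k][l];
    m /= nfolds;
    double v = 0;
    for (int k = 0; k < nfolds; ++k) {
      double d = fold_mse[k][l] - m;
      v += d * d;
    }
    cvm[l] = m;
    cvse[l] = std::sqrt(v / (nfolds - 1)) / std::sqrt((double)nfolds);
  }
  int i_min = 0;
  for (int l = 1; l < nlambda; ++l)
    if (cvm[l] < cvm[i_min]) i_min = l;
  int i_1se = 0;
  for (int l = 0; l < nlambda; ++l) {
    if (cvm[l] <= cvm[i_min] + cvse[i_min]) { i_1se = l; break; }
  }

  std::vector<double> bp;
  cd_path(Xs, ys, n, p, lambda, bp);
  NumericVector coef(p);
  for (int j = 0; j < p; ++j) {
    double b = bp[(size_t)j + (size_t)p * i_1se];
    coef[j] = std::fabs(b) < 1e-10 ? 0.0 : b;  // round-off dust guard
  }
  return List::create(_["coef"] = coef, _["lambda_1se"] = lambda[i_1se],
                      _["lambda"] = NumericVector(lambda.begin(), lambda.end()),
                      _["cvm"] = cvm, _["cvse"] = cvse);
}
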