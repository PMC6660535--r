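// Single-site Gibbs samplers for Bayesian whole-genome regression.
// Families: 0 = per-marker scaled-t shrinkage ("bayes_a"),
//           1 = point-mass + common Gaussian slab mixture ("bayes_b"),
//           2 = point-mass + per-marker scaled-t slab mixture ("bayes_c"),
//           3 = Bayesian lasso (double-exponential via exponential mixing).
// Uses R's RNG throughout, so chains are reproducible via set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static inline double rinvgauss(double mu, double lambda) {
  // Michael, Schucany & Haas (1976)
  double z = R::norm_rand();
  double y = z * z;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static inline double rscaled_inv_chisq(double df, double scale_sum) {
  // draws sigma2 with sigma2 * df_eff ~ scale_sum / chisq(df)
  double chi = R::rchisq(df);
  if (chi < 1e-12) chi = 1e-12;
  return scale_sum / chi;
}

// [[Rcpp::export]]
List bayes_gibbs_cpp(NumericMatrix X, NumericVector y, int family,
                     int niter, int burn, int thin,
                     double df0, double R2, double pi_init,
                     double dfE, double min_var) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> x2(m);
  double msx = 0.0;                 // sum of column variances of X
  for (int j = 0; j < m; ++j) {
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) { s += X(i, j); ss += X(i, j) * X(i, j); }
    x2[j] = ss;
    double mean = s / n;
    msx += ss / n - mean * mean;
  }
  if (msx < 1e-8) msx = 1e-8;
  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);

  // hyperprior scales: prior R2 heuristic on the slab, remainder on noise
  double Sb = vy * R2 / msx * (df0 + 2.0);
  if (family == 1 || family == 2) Sb /= pi_init;   // mixture: mass on few markers
  const double SE = vy * (1.0 - R2) * (dfE + 2.0);

  double mu = my, varE = vy * (1.0 - R2);
  std::vector<double> b(m, 0.0), varB(m, Sb / (df0 + 2.0));
  std::vector<int> incl(m, 1);
  double varB_common = Sb / (df0 + 2.0);
  double pi = pi_init;
  double lambda2 = 2.0 * (1.0 - R2) / R2 * msx;    // BL regularization init
  std::vector<double> tau2(m, 1.0 / lambda2);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;    // b starts at 0

  std::vector<double> b_mean(m, 0.0), b_sq(m, 0.0);
  double mu_mean = 0.0, varE_mean = 0.0, pi_mean = 0.0;
  int nsave = 0;
  std::vector<double> varE_trace;
  varE_trace.reserve(niter);

  for (int it = 0; it < niter; ++it) {
    // intercept
    double se_sum = 0.0;
    for (int i = 0; i < n; ++i) se_sum += e[i];
    double mu_new = (se_sum / n + mu) + R::norm_rand() * std::sqrt(varE / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    int n_incl = 0;
    double ss_b = 0.0;          // included effects sum of squares (B)
    double ss_btau = 0.0;       // sum b^2 / tau2 (BL)

    for (int j = 0; j < m; ++j) {
      const double *xj = &X(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += x2[j] * b[j];

      double prior_var;
      switch (family) {
      case 0: prior_var = varB[j]; break;
      case 1: prior_var = varB_common; break;
      case 2: prior_var = varB[j]; break;
      default: prior_var = varE * tau2[j]; break;
      }
      if (prior_var < min_var) prior_var = min_var;

      double b_new = 0.0;
      bool included = true;
      if (family == 1 || family == 2) {
        // spike-and-slab: conditional Bayes factor for inclusion
        double v = varE + prior_var * x2[j];
        double logBF = 0.5 * (rhs * rhs * prior_var / (varE * v)) -
          0.5 * std::log(v / varE);
        double logodds = std::log(pi / (1.0 - pi)) + logBF;
        double p1 = 1.0 / (1.0 + std::exp(-logodds));
        included = (R::unif_rand() < p1);
      }
      if (included) {
        double C = x2[j] + varE / prior_var;
        b_new = rhs / C + R::norm_rand() * std::sqrt(varE / C);
      }
      double db = b_new - b[j];
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= xj[i] * db;
      b[j] = b_new;
      if (included) { ++n_incl; ss_b += b_new * b_new; }

      // per-marker variance updates
      if (family == 0) {
        varB[j] = rscaled_inv_chisq(df0 + 1.0, Sb + b[j] * b[j]);
      } else if (family == 2) {
        if (included) {
          varB[j] = rscaled_inv_chisq(df0 + 1.0, Sb + b[j] * b[j]);
        } else {
          varB[j] = rscaled_inv_chisq(df0, Sb);   // refresh from prior
        }
      } else if (family == 3) {
        double babs = std::fabs(b[j]);
        if (babs < 1e-10) babs = 1e-10;
        double itau = rinvgauss(std::sqrt(lambda2 * varE) / babs, lambda2);
        tau2[j] = 1.0 / itau;
        ss_btau += b[j] * b[j] / tau2[j];
      }
    }

    if (family == 1) {
      varB_common = rscaled_inv_chisq(df0 + n_incl, Sb + ss_b);
    }
    if (family == 1 || family == 2) {
      pi = R::rbeta(1.0 + n_incl, 1.0 + m - n_incl);
      if (pi < 1e-4) pi = 1e-4;
      if (pi > 1.0 - 1e-4) pi = 1.0 - 1e-4;
    }
    if (family == 3) {
      double sum_tau2 = 0.0;
      for (int j = 0; j < m; ++j) sum_tau2 += tau2[j];
      // Gamma hyperprior on lambda^2 (shape 1.1, prior mode at the init)
      double shape0 = 1.1;
      double rate0 = (shape0 - 1.0) / (2.0 * (1.0 - R2) / R2 * msx);
      lambda2 = R::rgamma(shape0 + m, 1.0 / (rate0 + sum_tau2 / 2.0));
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    if (family == 3) {
      varE = rscaled_inv_chisq(n + m + dfE, sse + ss_btau + SE);
    } else {
      varE = rscaled_inv_chisq(n + dfE, sse + SE);
    }
    if (!R_finite(varE) || !R_finite(mu)) {
      stop("divergent chain (non-finite draw) at iteration %d", it + 1);
    }
    varE_trace.push_back(varE);

    if (it >= burn && ((it - burn) % thin == 0)) {
      ++nsave;
      mu_mean += mu; varE_mean += varE; pi_mean += pi;
      for (int j = 0; j < m; ++j) {
        b_mean[j] += b[j];
        b_sq[j] += b[j] * b[j];
      }
    }
  }
  std::vector<double> b_sd(m);
  for (int j = 0; j < m; ++j) {
    b_mean[j] /= nsave;
    double v = b_sq[j] / nsave - b_mean[j] * b_mean[j];
    b_sd[j] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(
    _["mu"] = mu_mean / nsave,
    _["b"] = NumericVector(b_mean.begin(), b_mean.end()),
    _["b_sd"] = NumericVector(b_sd.begin(), b_sd.end()),
    _["varE"] = varE_mean / nsave,
    _["pi"] = pi_mean / nsave,
    _["varE_trace"] = NumericVector(varE_trace.begin(), varE_trace.end()),
    _["n_saved"] = nsave
  );
}
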