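// Blocked Gibbs sampler for the heteroscedastic global-local shrinkage model
//
//   y_ig ~ N(c_g + x_i * beta_g, sigma_g^2)
//   (c_g, beta_g) | sigma_g^2 ~ N((0, h_g), sigma_g^2 * diag(s0^2, lambda_g^2 tau^2))
//   sigma_g^2 ~ IG(xi1, xi2);  lambda_g, tau ~ Half-Cauchy(0, 1)
//
// Per sweep: beta_g drawn from its marginal conditional (c_g and sigma_g^2
// integrated out; scaled/shifted Student-t), then sigma_g^2 (IG, c_g
// integrated out), then c_g (normal), then lambda_g by slice sampling; one
// global tau slice step closes the iteration.  All per-gene updates reduce
// to O(1) work through the sufficient statistics (Sy, Syy, Sxy).
//
// Uses R's RNG throughout, so a set.seed() call on the R side makes every
// run bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SCALE_FLOOR = 1e-6;              // lower bound for lambda, tau
static const double LOG_SCALE_FLOOR = std::log(1e-6);

// log(1 + exp(z)) without overflow
static inline double log1p_exp(double z) {
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

// One slice-sampling transition (Neal 2003, stepping-out + shrinkage) on
// u = log(scale).  Target must be a proper log-density in u; values below
// LOG_SCALE_FLOOR are treated as having zero density, which regularises the
// improper spike at scale -> 0 when the Gaussian term vanishes.
template <class F>
static double slice_log_scale(double u0, F logf) {
  const double w = 1.0;
  const int m = 50;
  if (u0 < LOG_SCALE_FLOOR) u0 = LOG_SCALE_FLOOR;
  double f0 = logf(u0);
  if (!R_finite(f0)) Rcpp::stop("slice sampler: log-density not finite at current value");
  double yslice = f0 - R::exp_rand();

  double L = u0 - w * R::unif_rand();
  double Rr = L + w;
  int j = (int)std::floor(m * R::unif_rand());
  int k = m - 1 - j;
  while (j-- > 0 && L > LOG_SCALE_FLOOR && logf(L) > yslice) L -= w;
  while (k-- > 0 && logf(Rr) > yslice) Rr += w;
  if (L < LOG_SCALE_FLOOR) L = LOG_SCALE_FLOOR;

  for (;;) {
    double u1 = L + (Rr - L) * R::unif_rand();
    if (logf(u1) > yslice) return u1;
    if (u1 < u0) L = u1; else Rr = u1;
  }
}

// log-density (up to a constant), in u = log(lambda), of
//   (1 + lambda^2)^-1 * lambda^-1 * exp(-a / lambda^2)
// including the Jacobian lambda of the log transform.
struct HcScaleTarget {
  double a;  // (beta - h)^2 / (2 sigma^2 tau^2), or the tau analogue
  double km1; // (number of Gaussian terms) - 1
  double operator()(double u) const {
    return -log1p_exp(2.0 * u) - km1 * u - a * std::exp(-2.0 * u);
  }
};

// One conjugate sweep for a single gene given tau.  State passed by
// reference; suff stats: n total samples, n1 treated, Sy = sum y,
// Syy = sum y^2, Sxy = sum of y over treated samples.
static void gene_sweep(double Sy, double Syy, double Sxy, int n, int n1,
                       double h, double xi1, double xi2, double s0sq,
                       double tau, bool update_lambda,
                       double &c, double &beta, double &sig2, double &lam) {
  double lt2 = lam * lam * tau * tau;
  if (lt2 < 1e-300) lt2 = 1e-300;

  // (a) beta | lambda, tau, y  -- c and sigma^2 integrated out
  double A11 = n + 1.0 / s0sq;
  double A12 = (double)n1;
  double A22 = n1 + 1.0 / lt2;
  double b1 = Sy;
  double b2 = Sxy + h / lt2;
  double det = A11 * A22 - A12 * A12;
  double m1 = (A22 * b1 - A12 * b2) / det;
  double m2 = (-A12 * b1 + A11 * b2) / det;
  double xi1n = xi1 + 0.5 * n;
  double xi2n = xi2 + 0.5 * (Syy + h * h / lt2 - (m1 * b1 + m2 * b2));
  if (xi2n < 1e-12) xi2n = 1e-12;
  double bscale = std::sqrt(xi2n / xi1n * A11 / det);
  beta = m2 + bscale * R::rt(2.0 * xi1n);

  // (b) sigma^2 | beta (c integrated out), then c | beta, sigma^2
  double Sr = Sy - beta * n1;
  double Srr = Syy - 2.0 * beta * Sxy + beta * beta * n1;
  double Ac = n + 1.0 / s0sq;
  double mc = Sr / Ac;
  double dsq = (beta - h) * (beta - h);
  double sh = xi1 + 0.5 * n + 0.5;
  double rate = xi2 + 0.5 * (Srr - Sr * Sr / Ac) + 0.5 * dsq / lt2;
  if (rate < 1e-12) rate = 1e-12;
  sig2 = 1.0 / R::rgamma(sh, 1.0 / rate);
  c = mc + std::sqrt(sig2 / Ac) * R::norm_rand();

  // (c) lambda | beta, sigma^2, tau by slice sampling
  if (update_lambda) {
    HcScaleTarget tgt;
    tgt.a = dsq / (2.0 * sig2 * tau * tau);
    tgt.km1 = 0.0;
    double u = slice_log_scale(std::log(lam), tgt);
    lam = std::exp(u);
    if (lam < SCALE_FLOOR) lam = SCALE_FLOOR;
  }

  if (!R_finite(beta) || !R_finite(sig2) || !R_finite(c) || sig2 <= 0.0)
    Rcpp::stop("divergent gene state (non-finite draw)");
}

// One slice transition for the global tau aggregating nterms Gaussian terms
// with quadsum = sum_g (beta_g - h_g)^2 / (sigma_g^2 lambda_g^2).
static double tau_sweep(double tau, double quadsum, int nterms) {
  HcScaleTarget tgt;
  tgt.a = 0.5 * quadsum;
  tgt.km1 = (double)nterms - 1.0;
  double v = slice_log_scale(std::log(tau), tgt);
  double out = std::exp(v);
  return out < SCALE_FLOOR ? SCALE_FLOOR : out;
}

// [[Rcpp::export(name = ".gene_update_cpp")]]
List gene_update_cpp(NumericVector y, IntegerVector x, double h,
                     double c, double beta, double sig2, double lam,
                     double tau, double xi1, double xi2, double s0sq,
                     bool update_lambda) {
  int n = y.size();
  if (x.size() != n) stop("y and x lengths differ");
  double Sy = 0, Syy = 0, Sxy = 0; int n1 = 0;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(y[i])) stop("non-finite expression value");
    Sy += y[i]; Syy += y[i] * y[i];
    if (x[i] == 1) { Sxy += y[i]; ++n1; }
  }
  if (n1 == 0 || n1 == n) stop("degenerate design: all samples in one group");
  gene_sweep(Sy, Syy, Sxy, n, n1, h, xi1, xi2, s0sq, tau, update_lambda,
             c, beta, sig2, lam);
  return List::create(_["c"] = c, _["beta"] = beta, _["sigma2"] = sig2,
                      _["lambda"] = lam);
}

// [[Rcpp::export(name = ".sample_tau_cpp")]]
double sample_tau_cpp(NumericVector beta, NumericVector h,
                      NumericVector sigma2, NumericVector lambda,
                      double tau) {
  int G = beta.size();
  if (G == 0) stop("empty gene set");
  double quadsum = 0;
  for (int g = 0; g < G; ++g) {
    double d = beta[g] - h[g];
    quadsum += d * d / (sigma2[g] * lambda[g] * lambda[g]);
  }
  return tau_sweep(tau, quadsum, G);
}

// [[Rcpp::export(name = ".run_gibbs_cpp")]]
List run_gibbs_cpp(NumericMatrix Y, IntegerVector x, NumericVector h,
                   double xi1, double xi2, double s0sq,
                   int n_iter, int burn_in, int thin,
                   double tau_init, bool tau_is_fixed) {
  int G = Y.nrow(), n = Y.ncol();
  if (x.size() != n) stop("group length does not match sample count");
  if (h.size() != G) stop("prior center length does not match gene count");
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (x[i] == 1) ++n1;
  if (n1 < 2 || n - n1 < 2) stop("need at least 2 samples per group");

  std::vector<double> Sy(G), Syy(G), Sxy(G);
  for (int g = 0; g < G; ++g) {
    double sy = 0, syy = 0, sxy = 0;
    for (int i = 0; i < n; ++i) {
      double v = Y(g, i);
      if (!R_finite(v)) stop("non-finite expression value at gene " +
                             std::to_string(g + 1));
      sy += v; syy += v * v;
      if (x[i] == 1) sxy += v;
    }
    Sy[g] = sy; Syy[g] = syy; Sxy[g] = sxy;
  }

  // initialisation: intercept = gene mean, beta = group-mean difference,
  // sigma^2 = pooled residual variance, lambda = 1, tau = tau_init
  std::vector<double> c(G), beta(G), sig2(G), lam(G, 1.0);
  int n0 = n - n1;
  for (int g = 0; g < G; ++g) {
    double mu1 = Sxy[g] / n1, mu0 = (Sy[g] - Sxy[g]) / n0;
    c[g] = Sy[g] / n;
    beta[g] = mu1 - mu0;
    double ss = Syy[g] - n1 * mu1 * mu1 - n0 * mu0 * mu0;
    sig2[g] = ss > 0 ? ss / (n - 2) : 1e-3;
  }
  double tau = tau_init;

  int M = (n_iter - burn_in) / thin;
  NumericMatrix beta_out(G, M), lam_out(G, M), sig2_out(G, M), c_out(G, M);
  NumericVector tau_out(M);

  for (int t = 1; t <= n_iter; ++t) {
    for (int g = 0; g < G; ++g) {
      gene_sweep(Sy[g], Syy[g], Sxy[g], n, n1, h[g], xi1, xi2, s0sq,
                 tau, true, c[g], beta[g], sig2[g], lam[g]);
    }
    if (!tau_is_fixed) {
      double quadsum = 0;
      for (int g = 0; g < G; ++g) {
        double d = beta[g] - h[g];
        quadsum += d * d / (sig2[g] * lam[g] * lam[g]);
      }
      tau = tau_sweep(tau, quadsum, G);
    }
    if (t > burn_in && (t - burn_in) % thin == 0) {
      int m = (t - burn_in) / thin - 1;
      for (int g = 0; g < G; ++g) {
        beta_out(g, m) = beta[g]; lam_out(g, m) = lam[g];
        sig2_out(g, m) = sig2[g]; c_out(g, m) = c[g];
      }
      tau_out[m] = tau;
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["beta"] = beta_out, _["lambda"] = lam_out,
                      _["sigma2"] = sig2_out, _["c"] = c_out,
                      _["tau"] = tau_out);
}

// ---------------------------------------------------------------------------
// Two-component (dropout + continuous) sampler for single-cell data.
//
//   Pr(Z_ig = 1) = logistic(cD_g + x_i * betaD_g)        [dropout component]
//   Y_ig | Z_ig = 1 ~ N(cC_g + x_i * betaC_g, sigma_g^2) [continuous part]
//
// Continuous component: identical conjugate sweep restricted to nonzero
// cells, prior center mu_g.  Dropout component: adaptive random-walk
// Metropolis for (cD, betaD) with priors cD ~ N(0, s0D^2) and
// betaD ~ N(kappa mu_g, lambdaD^2 tau^2) (no sigma^2 factor: the logistic
// likelihood has no residual variance).  Shared global tau over both
// components' local scales.
// ---------------------------------------------------------------------------

static inline double logistic_ll(double cD, double bD, double m0, double k0,
                                 double m1, double k1) {
  return k0 * cD + k1 * (cD + bD)
       - m0 * log1p_exp(cD) - m1 * log1p_exp(cD + bD);
}

// [[Rcpp::export(name = ".run_gibbs_sc_cpp")]]
List run_gibbs_sc_cpp(NumericVector Sy, NumericVector Syy, NumericVector Sxy,
                      IntegerVector nz0, IntegerVector nz1,
                      double m0, double m1,
                      NumericVector mu, double kappa,
                      double xi1, double xi2, double s0sq,
                      int n_iter, int burn_in, int thin,
                      double tau_init, bool tau_is_fixed) {
  int G = Sy.size();
  if (G == 0) stop("empty gene set");

  std::vector<double> cC(G), bC(G), sig2(G), lamC(G, 1.0);
  std::vector<double> cD(G), bD(G), lamD(G, 1.0);
  std::vector<double> step_c(G, 0.5), step_b(G, 0.5); // adaptive RW scales (log units)
  double tau = tau_init;

  for (int g = 0; g < G; ++g) {
    int n = nz0[g] + nz1[g];
    double mu1 = Sxy[g] / nz1[g], mu0g = (Sy[g] - Sxy[g]) / nz0[g];
    cC[g] = Sy[g] / n;
    bC[g] = mu1 - mu0g;
    double ss = Syy[g] - nz1[g] * mu1 * mu1 - nz0[g] * mu0g * mu0g;
    sig2[g] = ss > 0 ? ss / std::max(n - 2, 1) : 1e-3;
    // logits of empirical detection rates, lightly clamped
    double p0 = std::min(std::max(nz0[g] / m0, 0.02), 0.98);
    double p1 = std::min(std::max(nz1[g] / m1, 0.02), 0.98);
    cD[g] = std::log(p0 / (1 - p0));
    bD[g] = std::log(p1 / (1 - p1)) - cD[g];
  }

  int M = (n_iter - burn_in) / thin;
  NumericMatrix bC_out(G, M), bD_out(G, M), lamC_out(G, M), lamD_out(G, M),
                sig2_out(G, M), cC_out(G, M), cD_out(G, M);
  NumericVector tau_out(M);

  for (int t = 1; t <= n_iter; ++t) {
    double adapt = t <= burn_in ? 1.0 / std::pow((double)t, 0.6) : 0.0;
    for (int g = 0; g < G; ++g) {
      int n = nz0[g] + nz1[g];
      // continuous component on nonzero cells
      gene_sweep(Sy[g], Syy[g], Sxy[g], n, nz1[g], mu[g], xi1, xi2, s0sq,
                 tau, false, cC[g], bC[g], sig2[g], lamC[g]);
      {
        HcScaleTarget tgt;
        double d = bC[g] - mu[g];
        tgt.a = d * d / (2.0 * sig2[g] * tau * tau);
        tgt.km1 = 0.0;
        lamC[g] = std::exp(slice_log_scale(std::log(lamC[g]), tgt));
        if (lamC[g] < SCALE_FLOOR) lamC[g] = SCALE_FLOOR;
      }

      // dropout component: RW-Metropolis on cD then betaD
      double ll = logistic_ll(cD[g], bD[g], m0, nz0[g], m1, nz1[g]);
      {
        double prop = cD[g] + std::exp(step_c[g]) * R::norm_rand();
        double llp = logistic_ll(prop, bD[g], m0, nz0[g], m1, nz1[g]);
        double lr = llp - ll
          + (cD[g] * cD[g] - prop * prop) / (2.0 * s0sq);
        double acc = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < acc) { cD[g] = prop; ll = llp; }
        step_c[g] += adapt * (acc - 0.44);
      }
      {
        double pv = lamD[g] * lamD[g] * tau * tau;
        double pm = kappa * mu[g];
        double prop = bD[g] + std::exp(step_b[g]) * R::norm_rand();
        double llp = logistic_ll(cD[g], prop, m0, nz0[g], m1, nz1[g]);
        double lr = llp - ll
          + ((bD[g] - pm) * (bD[g] - pm) - (prop - pm) * (prop - pm)) / (2.0 * pv);
        double acc = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < acc) { bD[g] = prop; ll = llp; }
        step_b[g] += adapt * (acc - 0.44);
      }
      {
        HcScaleTarget tgt;
        double d = bD[g] - kappa * mu[g];
        tgt.a = d * d / (2.0 * tau * tau);
        tgt.km1 = 0.0;
        lamD[g] = std::exp(slice_log_scale(std::log(lamD[g]), tgt));
        if (lamD[g] < SCALE_FLOOR) lamD[g] = SCALE_FLOOR;
      }
    }

    if (!tau_is_fixed) {
      double quadsum = 0;
      for (int g = 0; g < G; ++g) {
        double dC = bC[g] - mu[g];
        double dD = bD[g] - kappa * mu[g];
        quadsum += dC * dC / (sig2[g] * lamC[g] * lamC[g])
                 + dD * dD / (lamD[g] * lamD[g]);
      }
      tau = tau_sweep(tau, quadsum, 2 * G);
    }

    if (t > burn_in && (t - burn_in) % thin == 0) {
      int m = (t - burn_in) / thin - 1;
      for (int g = 0; g < G; ++g) {
        bC_out(g, m) = bC[g]; bD_out(g, m) = bD[g];
        lamC_out(g, m) = lamC[g]; lamD_out(g, m) = lamD[g];
        sig2_out(g, m) = sig2[g]; cC_out(g, m) = cC[g]; cD_out(g, m) = cD[g];
      }
      tau_out[m] = tau;
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["betaC"] = bC_out, _["betaD"] = bD_out,
                      _["lambdaC"] = lamC_out, _["lambdaD"] = lamD_out,
                      _["sigma2"] = sig2_out, _["cC"] = cC_out,
                      _["cD"] = cD_out, _["tau"] = tau_out);
}
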