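#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Numerical kernels for the marginal likelihood of Binomial-type mixed
// models with a single population random intercept, integrated out by
// Gauss-Hermite quadrature. All probability arithmetic is in log space;
// fitted probabilities are clamped away from {0,1} so that extreme linear
// predictors degrade gracefully instead of producing NaN.

static const double P_EPS = 1e-12;

static inline double plogis_clamped(double x) {
  double p = 1.0 / (1.0 + std::exp(-x));
  if (p < P_EPS) p = P_EPS;
  if (p > 1.0 - P_EPS) p = 1.0 - P_EPS;
  return p;
}

// log C(n,k) + k log p + (n-k) log(1-p); lch passed in precomputed
static inline double binom_logpmf_term(double h, double c, double lch, double p) {
  return lch + h * std::log(p) + (c - h) * std::log1p(-p);
}

static inline double logsumexp(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// Beta-Binomial log pmf in shape parameterization, vectorized.
// log pmf = log C(n,k) + lbeta(k+a, n-k+b) - lbeta(a, b)
// [[Rcpp::export]]
NumericVector bb_logpmf_cpp(NumericVector k, NumericVector n,
                            NumericVector a, NumericVector b) {
  R_xlen_t m = k.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    double ai = a[i], bi = b[i];
    out[i] = R::lchoose(n[i], k[i]) +
      (std::lgamma(k[i] + ai) + std::lgamma(n[i] - k[i] + bi) -
       std::lgamma(n[i] + ai + bi)) -
      (std::lgamma(ai) + std::lgamma(bi) - std::lgamma(ai + bi));
  }
  return out;
}

// Marginal log-likelihood with the population intercept integrated out by
// Gauss-Hermite quadrature (nodes/weights for weight function exp(-x^2)
// supplied from R). family: 0 = Binomial, 1 = Binomial + OLRE (disp is the
// SD sigma_eps of logit-scale noise, integrated by an inner quadrature),
// 2 = Beta-Binomial (disp is phi; shapes a = p/phi, b = (1-p)/phi).
// pop is 0-based, J the number of populations, eta0 the fixed-effect part
// (mu_pop + X beta) of the linear predictor.
// [[Rcpp::export]]
double marginal_loglik_cpp(NumericVector h, NumericVector c, NumericVector eta0,
                           IntegerVector pop, int J,
                           double sigma_pop, int family, double disp,
                           NumericVector ghx1, NumericVector ghw1,
                           NumericVector ghx2, NumericVector ghw2) {
  R_xlen_t n = h.size();
  const double lsqrtpi = 0.5 * std::log(M_PI);

  // outer quadrature over the population intercept deviation
  std::vector<double> xo, lwo;
  if (sigma_pop > 0.0) {
    for (R_xlen_t k = 0; k < ghx1.size(); ++k) {
      xo.push_back(M_SQRT2 * sigma_pop * ghx1[k]);
      lwo.push_back(std::log(ghw1[k]) - lsqrtpi);
    }
  } else {
    xo.push_back(0.0);
    lwo.push_back(0.0);
  }
  int Ko = (int) xo.size();

  // inner quadrature over the observation-level effect (OLRE only)
  std::vector<double> xi, lwi;
  bool olre = (family == 1 && disp > 0.0);
  if (olre) {
    for (R_xlen_t m2 = 0; m2 < ghx2.size(); ++m2) {
      xi.push_back(M_SQRT2 * disp * ghx2[m2]);
      lwi.push_back(std::log(ghw2[m2]) - lsqrtpi);
    }
  }
  int Ki = (int) xi.size();

  // below ~1e-8 the shape parameters are so large that lgamma differences
  // lose precision; the limit is the plain Binomial, so use it directly
  bool betabin = (family == 2 && disp > 1e-8);
  double inv_phi = betabin ? 1.0 / disp : 0.0;
  double lg_s = betabin ? std::lgamma(inv_phi) : 0.0;

  std::vector<double> lch(n);
  for (R_xlen_t i = 0; i < n; ++i) lch[i] = R::lchoose(c[i], h[i]);

  // per-population, per-outer-node log conditional likelihoods
  std::vector<double> lp((size_t) J * Ko, 0.0);
  std::vector<double> inner(Ki);

  for (int k = 0; k < Ko; ++k) {
    double off = xo[k];
    for (R_xlen_t i = 0; i < n; ++i) {
      double eta = eta0[i] + off;
      double term;
      if (olre) {
        for (int m2 = 0; m2 < Ki; ++m2) {
          double p = plogis_clamped(eta + xi[m2]);
          inner[m2] = lwi[m2] + binom_logpmf_term(h[i], c[i], lch[i], p);
        }
        term = logsumexp(inner);
      } else if (betabin) {
        double p = plogis_clamped(eta);
        double a = p * inv_phi, b = (1.0 - p) * inv_phi;
        term = lch[i] +
          (std::lgamma(h[i] + a) + std::lgamma(c[i] - h[i] + b) -
           std::lgamma(c[i] + inv_phi)) -
          (std::lgamma(a) + std::lgamma(b) - lg_s);
      } else {
        double p = plogis_clamped(eta);
        term = binom_logpmf_term(h[i], c[i], lch[i], p);
      }
      lp[(size_t) pop[i] * Ko + k] += term;
    }
  }

  double ll = 0.0;
  std::vector<double> buf(Ko);
  for (int j = 0; j < J; ++j) {
    for (int k = 0; k < Ko; ++k) buf[k] = lwo[k] + lp[(size_t) j * Ko + k];
    ll += logsumexp(buf);
  }
  return ll;
}
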