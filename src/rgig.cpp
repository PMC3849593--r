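#include <Rcpp.h>
using namespace Rcpp;

// Generalized inverse Gaussian sampler.
//
// Parameterization: density proportional to
//   x^(lambda - 1) * exp(-(chi / x + psi * x) / 2),  x > 0,
// with chi >= 0, psi >= 0 (both zero is improper).  The workhorse samples the
// two-parameter form x^(lambda-1) exp(-omega (x + 1/x) / 2) with lambda >= 0,
// omega > 0 by rejection on the log scale: the log density of
// X = log(G / m), with m the mode, is concave, and is dominated by a flat
// centre piece plus two exponential tails obtained from tangents at t and -s.

static inline double psi_fn(double x, double alpha, double lambda) {
  return -alpha * (cosh(x) - 1.0) - lambda * (exp(x) - x - 1.0);
}

static inline double dpsi_fn(double x, double alpha, double lambda) {
  return -alpha * sinh(x) - lambda * (exp(x) - 1.0);
}

// two-parameter GIG(lambda >= 0, omega > 0)
static double rgig_std(double lambda, double omega) {
  double alpha = sqrt(omega * omega + lambda * lambda) - lambda;
  if (alpha < 0.0) alpha = 0.0;  // guard against cancellation

  double x = -psi_fn(1.0, alpha, lambda);
  double t;
  if (x >= 0.5 && x <= 2.0) {
    t = 1.0;
  } else if (x > 2.0) {
    t = sqrt(2.0 / (alpha + lambda));
  } else {  // x < 0.5; alpha + 2 lambda < 4 here so the log is positive
    t = log(4.0 / (alpha + 2.0 * lambda));
  }

  x = -psi_fn(-1.0, alpha, lambda);
  double s;
  if (x >= 0.5 && x <= 2.0) {
    s = 1.0;
  } else if (x > 2.0) {
    s = sqrt(4.0 / (alpha * cosh(1.0) + lambda));
  } else {
    if (alpha == 0.0) {
      s = 1.0 / lambda;
    } else {
      double ia = 1.0 / alpha;
      double s1 = log(1.0 + ia + sqrt(ia * ia + 2.0 * ia));
      s = (lambda > 0.0) ? std::min(1.0 / lambda, s1) : s1;
    }
  }

  double eta = -psi_fn(t, alpha, lambda);
  double zeta = -dpsi_fn(t, alpha, lambda);
  double theta = -psi_fn(-s, alpha, lambda);
  double xi = dpsi_fn(-s, alpha, lambda);
  double p = 1.0 / xi;
  double r = 1.0 / zeta;
  double td = t - r * eta;
  double sd = s - p * theta;
  double q = td + sd;

  double X = 0.0;
  for (int iter = 0; iter < 100000; ++iter) {
    double U = unif_rand();
    double V = unif_rand();
    double W = unif_rand();
    if (U < q / (p + q + r)) {
      X = -sd + q * V;
    } else if (U < (q + r) / (p + q + r)) {
      X = td - r * log(V);
    } else {
      X = -sd + p * log(V);
    }
    double env;
    if (X > td) {
      env = exp(-eta - zeta * (X - t));
    } else if (X < -sd) {
      env = exp(-theta + xi * (X + s));
    } else {
      env = 1.0;
    }
    if (W * env <= exp(psi_fn(X, alpha, lambda))) break;
  }

  double m = (lambda + sqrt(lambda * lambda + omega * omega)) / omega;  // mode
  return m * exp(X);
}

// three-parameter draw, handling lambda < 0 by inversion and the gamma /
// inverse-gamma limits when one of chi, psi vanishes
static double rgig_one(double lambda, double chi, double psi) {
  if (chi < 0.0 || psi < 0.0) Rcpp::stop("rgig: chi and psi must be >= 0");
  if (chi == 0.0) {
    if (lambda <= 0.0) Rcpp::stop("rgig: chi = 0 requires lambda > 0");
    return R::rgamma(lambda, 2.0 / psi);  // shape, scale = 2/psi (rate psi/2)
  }
  if (psi == 0.0) {
    if (lambda >= 0.0) Rcpp::stop("rgig: psi = 0 requires lambda < 0");
    return chi / (2.0 * R::rgamma(-lambda, 1.0));  // inverse-gamma limit
  }
  if (lambda < 0.0) {
    // X ~ GIG(lambda, chi, psi)  <=>  1/X ~ GIG(-lambda, psi, chi)
    double z = rgig_std(-lambda, sqrt(chi * psi));
    return 1.0 / (sqrt(psi / chi) * z);
  }
  double z = rgig_std(lambda, sqrt(chi * psi));
  return sqrt(chi / psi) * z;
}

// [[Rcpp::export(name = ".rgig_cpp")]]
NumericVector rgig_cpp(int n, NumericVector lambda, NumericVector chi,
                       NumericVector psi) {
  NumericVector out(n);
  R_xlen_t nl = lambda.size(), nc = chi.size(), np = psi.size();
  for (int i = 0; i < n; ++i) {
    out[i] = rgig_one(lambda[i % nl], chi[i % nc], psi[i % np]);
  }
  return out;
}
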