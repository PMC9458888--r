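// Censored (skew-)normal two-level regression: joint log posterior and
// analytic gradient in the unconstrained parameterization used by the
// sampler, plus Owen's T function for the skew-normal CDF.
//
// Mean parameterization: (mu, sigma, alpha) are the residual
// distribution's mean, SD and shape. Internally
//   delta = alpha / sqrt(1 + alpha^2)
//   omega = sigma / sqrt(1 - 2 delta^2 / pi)      (scale)
//   xi    = mu - omega delta sqrt(2/pi)           (location)
// so regression coefficients act on the outcome mean for any alpha.

#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

static const double SQRT_2_PI = 0.7978845608028654; // sqrt(2/pi)

// ---- Gauss-Legendre nodes (computed once by Newton iteration) ----
static const int GLN = 32;
static double gl_x[GLN], gl_w[GLN];
static bool gl_ready = false;

static void gl_init() {
  if (gl_ready) return;
  int n = GLN;
  for (int i = 0; i < (n + 1) / 2; i++) {
    double x = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double p0, p1, p2, dp = 1.0;
    for (int it = 0; it < 100; it++) {
      p0 = 1.0; p1 = x;
      for (int k = 2; k <= n; k++) {
        p2 = ((2.0 * k - 1.0) * x * p1 - (k - 1.0) * p0) / k;
        p0 = p1; p1 = p2;
      }
      dp = n * (x * p1 - p0) / (x * x - 1.0);
      double x1 = x;
      x = x1 - p1 / dp;
      if (std::fabs(x - x1) < 1e-15) break;
    }
    gl_x[i] = -x;
    gl_x[n - 1 - i] = x;
    gl_w[i] = gl_w[n - 1 - i] = 2.0 / ((1.0 - x * x) * dp * dp);
  }
  gl_ready = true;
}

// core integral: T(h, a) for 0 <= a <= 1, any h
static double owen_core(double h, double a) {
  gl_init();
  double s = 0.0, hh = -0.5 * h * h;
  for (int i = 0; i < GLN; i++) {
    double x = 0.5 * a * (gl_x[i] + 1.0);
    s += gl_w[i] * std::exp(hh * (1.0 + x * x)) / (1.0 + x * x);
  }
  return s * 0.5 * a / (2.0 * M_PI);
}

double owen_t(double h, double a) {
  if (a == 0.0 || !R_finite(h)) return 0.0;
  double sign = 1.0;
  if (a < 0) { a = -a; sign = -1.0; }
  h = std::fabs(h); // T(-h, a) = T(h, a)
  double t;
  if (a <= 1.0) {
    t = owen_core(h, a);
  } else {
    // T(h,a) = (Phi(h) + Phi(ah))/2 - Phi(h) Phi(ah) - T(ah, 1/a), h >= 0
    double ph = R::pnorm(h, 0.0, 1.0, 1, 0);
    double pah = R::pnorm(a * h, 0.0, 1.0, 1, 0);
    t = 0.5 * (ph + pah) - ph * pah - owen_core(a * h, 1.0 / a);
  }
  return sign * t;
}

// [[Rcpp::export]]
NumericVector cpp_owen_t(NumericVector h, NumericVector a) {
  int n = std::max(h.size(), a.size());
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    out[i] = owen_t(h[i % h.size()], a[i % a.size()]);
  }
  return out;
}

// inverse Mills ratio phi(x)/Phi(x), stable in the left tail
static double mills(double x) {
  return std::exp(R::dnorm(x, 0.0, 1.0, 1) - R::pnorm(x, 0.0, 1.0, 1, 1));
}

// log density (truncated at 0) of half-t(df, scale) and d/dx log density
static double halft_lpdf(double x, double df, double s) {
  return M_LN2 + R::lgammafn((df + 1.0) / 2.0) - R::lgammafn(df / 2.0) -
         0.5 * std::log(df * M_PI * s * s) -
         (df + 1.0) / 2.0 * std::log1p(x * x / (df * s * s));
}
static double halft_dlpdf(double x, double df, double s) {
  return -(df + 1.0) * x / (df * s * s + x * x);
}

double model_lp_grad(const double* theta, double* grad, const ModelData& md) {
  const int n = md.n, p = md.p, J = md.J;
  const bool want_grad = grad != 0;
  const int ia = p + 2;                      // alpha position (if skew)
  const int ie = p + 2 + (md.skew ? 1 : 0);  // eta offset
  const int dim = ie + J;

  double log_sigma = theta[p], log_tau = theta[p + 1];
  double sigma = std::exp(log_sigma), tau = std::exp(log_tau);
  double alpha = md.skew ? theta[ia] : 0.0;
  double delta = alpha / std::sqrt(1.0 + alpha * alpha);
  double ddelta = std::pow(1.0 + alpha * alpha, -1.5);
  double cfac = 1.0 / std::sqrt(1.0 - 2.0 * delta * delta / M_PI);
  double omega = sigma * cfac;
  double bd = SQRT_2_PI * delta;
  double domega_dalpha = omega * cfac * cfac * (2.0 * delta / M_PI) * ddelta;

  if (want_grad) std::fill(grad, grad + dim, 0.0);
  double lp = 0.0;
  double S_omega = 0.0, S_alpha = 0.0, sum_gmu_eta = 0.0;

  for (int i = 0; i < n; i++) {
    double m = 0.0;
    for (int k = 0; k < p; k++) m += md.X[i + (size_t)k * n] * theta[k];
    double mu = m + tau * theta[ie + md.person[i]];
    int cc = md.censor[i];
    double gmu = 0.0, gom = 0.0, gal = 0.0;
    if (cc == 0) {
      double u = (md.y[i] - mu) / omega;
      double z = u + bd;
      lp += M_LN2 - std::log(omega) + R::dnorm(z, 0.0, 1.0, 1) +
            R::pnorm(alpha * z, 0.0, 1.0, 1, 1);
      if (want_grad) {
        double mz = md.skew ? mills(alpha * z) : M_SQRT2 / std::sqrt(M_PI);
        double A = -z + alpha * mz;   // d ll / d z
        gmu = -A / omega;
        gom = -A * u / omega - 1.0 / omega;
        if (md.skew) gal = mz * z + A * SQRT_2_PI * ddelta;
      }
    } else {
      double bound = (cc < 0) ? md.lo : md.hi;
      double u = (bound - mu) / omega;
      double z = u + bd;
      double llc, A = 0.0, gdir = 0.0;
      if (!md.skew || alpha == 0.0) {
        // stable normal tail handling
        if (cc < 0) {
          llc = R::pnorm(z, 0.0, 1.0, 1, 1);
          if (want_grad) A = mills(z);
        } else {
          llc = R::pnorm(z, 0.0, 1.0, 0, 1);
          if (want_grad) A = -mills(-z);
        }
      } else {
        double F = R::pnorm(z, 0.0, 1.0, 1, 0) - 2.0 * owen_t(z, alpha);
        if (F < 1e-300) F = 1e-300;
        if (F > 1.0 - 1e-16) F = 1.0 - 1e-16;
        double dFdz = 2.0 * R::dnorm(z, 0.0, 1.0, 0) *
                      R::pnorm(alpha * z, 0.0, 1.0, 1, 0);
        double dFda = -std::exp(-0.5 * z * z * (1.0 + alpha * alpha)) /
                      (M_PI * (1.0 + alpha * alpha));
        if (cc < 0) {
          llc = std::log(F);
          A = dFdz / F; gdir = dFda / F;
        } else {
          llc = std::log1p(-F);
          A = -dFdz / (1.0 - F); gdir = -dFda / (1.0 - F);
        }
      }
      lp += llc;
      if (want_grad) {
        gmu = -A / omega;
        gom = -A * u / omega;
        if (md.skew) gal = gdir + A * SQRT_2_PI * ddelta;
      }
    }
    if (want_grad) {
      for (int k = 0; k < p; k++) grad[k] += gmu * md.X[i + (size_t)k * n];
      grad[ie + md.person[i]] += tau * gmu;
      sum_gmu_eta += gmu * theta[ie + md.person[i]];
      S_omega += gom;
      S_alpha += gal;
    }
  }

  // priors
  for (int k = 0; k < p; k++) {
    lp += R::dnorm(theta[k], 0.0, md.beta_sd, 1);
    if (want_grad) grad[k] += -theta[k] / (md.beta_sd * md.beta_sd);
  }
  lp += halft_lpdf(sigma, md.sd_df, md.sd_scale) + log_sigma;  // + Jacobian
  lp += halft_lpdf(tau, md.sd_df, md.sd_scale) + log_tau;
  if (md.skew) lp += R::dnorm(alpha, 0.0, md.alpha_sd, 1);
  for (int j = 0; j < J; j++) {
    lp += R::dnorm(theta[ie + j], 0.0, 1.0, 1);
    if (want_grad) grad[ie + j] += -theta[ie + j];
  }

  if (want_grad) {
    grad[p] = S_omega * omega +
              halft_dlpdf(sigma, md.sd_df, md.sd_scale) * sigma + 1.0;
    grad[p + 1] = tau * sum_gmu_eta +
                  halft_dlpdf(tau, md.sd_df, md.sd_scale) * tau + 1.0;
    if (md.skew) {
      grad[ia] = S_alpha + S_omega * domega_dalpha -
                 alpha / (md.alpha_sd * md.alpha_sd);
    }
  }
  return lp;
}

// Joint log posterior and gradient (R interface; see model.h for the
// parameter layout).
// [[Rcpp::export]]
List cpp_lp_grad(NumericVector theta, NumericMatrix X, NumericVector y,
                 IntegerVector censor, IntegerVector person, int J,
                 double lo, double hi, bool skew,
                 double beta_sd, double sd_df, double sd_scale,
                 double alpha_sd, bool want_grad = true) {
  ModelData md{REAL(SEXP(X)), X.nrow(), X.ncol(), REAL(SEXP(y)),
               INTEGER(SEXP(censor)), INTEGER(SEXP(person)), J, lo, hi,
               skew, beta_sd, sd_df, sd_scale, alpha_sd};
  int ie = md.p + 2 + (skew ? 1 : 0);
  if (theta.size() != ie + J) stop("theta has wrong length");
  NumericVector grad(theta.size());
  double lp = model_lp_grad(REAL(SEXP(theta)),
                            want_grad ? REAL(SEXP(grad)) : 0, md);
  return List::create(Named("lp") = lp, Named("grad") = grad);
}
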