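// No-U-Turn sampler specialized to the censored (skew-)normal two-level
// model, so the whole trajectory loop runs compiled. The algorithm
// mirrors the classic recursive formulation: slice variable, doubling
// with the no-U-turn termination criterion, dual-averaging step-size
// adaptation, and a diagonal mass matrix re-estimated in warmup
// windows. Randomness comes from R's RNG so runs are reproducible from
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "model.h"
using namespace Rcpp;

namespace {

struct Model {
  ModelData md;

  double lp_grad(const std::vector<double>& th, std::vector<double>& grad) {
    return model_lp_grad(th.data(), grad.data(), md);
  }
};

struct State {
  std::vector<double> th, r, g;
  double lp;
};

struct Sampler {
  Model* m;
  int d;
  std::vector<double> inv_mass;
  int divergences = 0;

  double joint(const State& s) {
    double k = 0.0;
    for (int i = 0; i < d; i++) k += s.r[i] * s.r[i] * inv_mass[i];
    return s.lp - 0.5 * k;
  }

  void leapfrog(State& s, double eps) {
    for (int i = 0; i < d; i++) s.r[i] += 0.5 * eps * s.g[i];
    for (int i = 0; i < d; i++) s.th[i] += eps * inv_mass[i] * s.r[i];
    s.lp = m->lp_grad(s.th, s.g);
    for (int i = 0; i < d; i++) s.r[i] += 0.5 * eps * s.g[i];
  }

  bool no_uturn(const State& minus, const State& plus) {
    double a = 0.0, b = 0.0;
    for (int i = 0; i < d; i++) {
      double dth = plus.th[i] - minus.th[i];
      a += dth * inv_mass[i] * minus.r[i];
      b += dth * inv_mass[i] * plus.r[i];
    }
    return a >= 0.0 && b >= 0.0;
  }

  struct Tree {
    State minus, plus, prop;
    int n;
    bool s;
    double alpha;
    int nalpha;
  };

  Tree build_tree(const State& z, double logu, int v, int j, double eps,
                  double h0, bool count_div) {
    Tree t;
    if (j == 0) {
      State s = z;
      leapfrog(s, v * eps);
      double jt = std::isfinite(s.lp) ? joint(s) : -INFINITY;
      bool div = !(jt - h0 > -1000.0);
      if (div && count_div) divergences++;
      t.minus = s; t.plus = s; t.prop = s;
      t.n = (logu <= jt) ? 1 : 0;
      t.s = !div;
      double a = jt - h0;
      t.alpha = a > 0 ? 1.0 : std::exp(a);
      if (!std::isfinite(t.alpha)) t.alpha = 0.0;
      t.nalpha = 1;
      return t;
    }
    Tree t1 = build_tree(z, logu, v, j - 1, eps, h0, count_div);
    if (!t1.s) return t1;
    Tree t2 = (v == -1)
      ? build_tree(t1.minus, logu, v, j - 1, eps, h0, count_div)
      : build_tree(t1.plus, logu, v, j - 1, eps, h0, count_div);
    if (v == -1) t1.minus = t2.minus; else t1.plus = t2.plus;
    int ntot = t1.n + t2.n;
    if (t2.n > 0 && unif_rand() < (double)t2.n / std::max(ntot, 1)) {
      t1.prop = t2.prop;
    }
    t1.s = t2.s && no_uturn(t1.minus, t1.plus);
    t1.n = ntot;
    t1.alpha = t1.alpha + t2.alpha;
    t1.nalpha = t1.nalpha + t2.nalpha;
    return t1;
  }

  double find_eps(State& cur) {
    double eps = 0.1;
    State z = cur;
    for (int i = 0; i < d; i++) z.r[i] = norm_rand() / std::sqrt(inv_mass[i]);
    double h0 = joint(z);
    State s = z;
    leapfrog(s, eps);
    double dh = std::isfinite(s.lp) ? joint(s) - h0 : -INFINITY;
    int a = dh > std::log(0.5) ? 1 : -1;
    for (int k = 0; k < 50; k++) {
      eps *= std::pow(2.0, a);
      State s2 = z;
      leapfrog(s2, eps);
      dh = std::isfinite(s2.lp) ? joint(s2) - h0 : -INFINITY;
      if (a == 1 && !(dh > std::log(0.5))) break;
      if (a == -1 && (dh > std::log(0.5))) break;
    }
    return eps;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_nuts_chain(NumericVector init, int n_warmup, int n_iter,
                    double adapt_delta, int max_treedepth,
                    NumericMatrix X, NumericVector y, IntegerVector censor,
                    IntegerVector person, int J, double lo, double hi,
                    bool skew, double beta_sd, double sd_df,
                    double sd_scale, double alpha_sd) {
  Model model{ModelData{REAL(SEXP(X)), X.nrow(), X.ncol(), REAL(SEXP(y)),
                        INTEGER(SEXP(censor)), INTEGER(SEXP(person)), J,
                        lo, hi, skew, beta_sd, sd_df, sd_scale, alpha_sd}};
  int d = init.size();
  Sampler smp;
  smp.m = &model;
  smp.d = d;
  smp.inv_mass.assign(d, 1.0);

  State cur;
  cur.th.assign(init.begin(), init.end());
  cur.r.assign(d, 0.0);
  cur.g.assign(d, 0.0);
  cur.lp = model.lp_grad(cur.th, cur.g);
  if (!std::isfinite(cur.lp)) stop("non-finite log posterior at init");

  double eps = smp.find_eps(cur);
  // dual averaging
  double da_mu = std::log(10.0 * eps), da_bar = 1.0, da_h = 0.0;
  int da_count = 0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;

  int w1 = std::max(5, (int)std::floor(0.15 * n_warmup));
  int w3 = std::max(5, (int)std::floor(0.10 * n_warmup));
  std::vector<int> metric_ends;
  for (double f : {0.45, 0.75}) {
    int e = (int)std::floor(f * n_warmup);
    if (e > w1 + 5 && e < n_warmup - w3) metric_ends.push_back(e);
  }
  std::vector<double> acc_m(d, 0.0), acc_s(d, 0.0);
  int acc_k = 0;

  NumericMatrix draws(n_iter, d);
  int max_depth_hits = 0;
  int n_total = n_warmup + n_iter;

  for (int it = 1; it <= n_total; it++) {
    bool warm = it <= n_warmup;
    State z = cur;
    for (int i = 0; i < d; i++) {
      z.r[i] = norm_rand() / std::sqrt(smp.inv_mass[i]);
    }
    double h0 = smp.joint(z);
    double logu = h0 + std::log(unif_rand());
    State minus = z, plus = z, prop = z;
    int j = 0, n = 1;
    bool s = true;
    double alpha_stat = 1.0;
    int nalpha_stat = 1;
    while (s) {
      int v = unif_rand() < 0.5 ? -1 : 1;
      Sampler::Tree t = (v == -1)
        ? smp.build_tree(minus, logu, v, j, eps, h0, !warm)
        : smp.build_tree(plus, logu, v, j, eps, h0, !warm);
      if (v == -1) minus = t.minus; else plus = t.plus;
      if (t.s && t.n > 0 && unif_rand() < std::min(1.0, (double)t.n / n)) {
        prop = t.prop;
      }
      n += t.n;
      s = t.s && smp.no_uturn(minus, plus);
      alpha_stat = t.alpha;
      nalpha_stat = t.nalpha;
      j++;
      if (j >= max_treedepth) {
        if (!warm) max_depth_hits++;
        break;
      }
    }
    cur = prop;

    if (warm) {
      da_count++;
      double w = 1.0 / (da_count + t0);
      da_h = (1 - w) * da_h + w * (adapt_delta - alpha_stat / nalpha_stat);
      double log_eps = da_mu - std::sqrt((double)da_count) / gamma * da_h;
      double wb = std::pow((double)da_count, -kappa);
      da_bar = std::exp((1 - wb) * std::log(da_bar) + wb * log_eps);
      eps = std::exp(log_eps);
      bool in_window = it > w1 &&
        !metric_ends.empty() && it <= metric_ends.back();
      if (in_window) {
        acc_k++;
        for (int i = 0; i < d; i++) {
          double dlt = cur.th[i] - acc_m[i];
          acc_m[i] += dlt / acc_k;
          acc_s[i] += dlt * (cur.th[i] - acc_m[i]);
        }
      }
      for (int e : metric_ends) {
        if (it == e && acc_k > 4) {
          for (int i = 0; i < d; i++) {
            double v_est = acc_s[i] / (acc_k - 1);
            smp.inv_mass[i] = v_est * acc_k / (acc_k + 5.0) +
              1e-3 * 5.0 / (acc_k + 5.0);
          }
          std::fill(acc_m.begin(), acc_m.end(), 0.0);
          std::fill(acc_s.begin(), acc_s.end(), 0.0);
          acc_k = 0;
          eps = smp.find_eps(cur);
          da_mu = std::log(10.0 * eps);
          da_bar = 1.0; da_h = 0.0; da_count = 0;
        }
      }
      if (it == n_warmup) eps = da_bar;
    } else {
      for (int i = 0; i < d; i++) draws(it - n_warmup - 1, i) = cur.th[i];
    }
  }
  return List::create(Named("draws") = draws,
                      Named("eps") = eps,
                      Named("inv_mass") = NumericVector(smp.inv_mass.begin(),
                                                        smp.inv_mass.end()),
                      Named("divergences") = smp.divergences,
                      Named("max_depth_hits") = max_depth_hits);
}
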