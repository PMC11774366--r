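#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the BYM Poisson model.
//
//   y_i ~ Poisson(E_i * exp(mu_i)),  mu_i = alpha + x_i'beta + u_i + v_i
//   u  : intrinsic CAR (conditional N(mean of neighbours, sigma2_u/deg)),
//        proper N(0, sigma2_u) for isolated areas
//   v  : iid N(0, sigma2_v)
//   alpha, beta_j ~ N(0, large variance); sigma2_u, sigma2_v ~ IG(a, b)
//
// Random-walk Metropolis for alpha, beta, u_i, v_i with per-parameter
// proposal scales adapted during burn-in towards 40-50% acceptance, then
// frozen.  Conjugate Gibbs draws for the variances.  u is mean-centred in
// every multi-area connected component each iteration.  Uses R's RNG so
// a set.seed() call on the R side makes runs reproducible.

static inline double sq(double x) { return x * x; }

// [[Rcpp::export]]
List bym_mcmc_cpp(NumericVector y, NumericVector E, NumericMatrix X,
                  List nb, IntegerVector comp,
                  double prior_var_alpha, double prior_var_beta,
                  double a, double b,
                  int n_iter, int n_burnin, int thin,
                  bool keep_effects, bool fix_variances,
                  double sigma2_u_fix, double sigma2_v_fix,
                  bool update_u, bool update_v) {
  const int n = y.size();
  const int p = X.ncol();

  // neighbour structure
  std::vector<std::vector<int>> nbr(n);
  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nb[i];
    nbr[i].assign(v.begin(), v.end());
    for (auto &j : nbr[i]) j -= 1;          // to 0-based
    deg[i] = nbr[i].size();
  }

  // multi-area components (for centring) and IG shape for sigma2_u
  int n_comp = 0;
  for (int i = 0; i < n; ++i) n_comp = std::max(n_comp, comp[i]);
  std::vector<std::vector<int>> comps(n_comp);
  for (int i = 0; i < n; ++i) comps[comp[i] - 1].push_back(i);
  std::vector<std::vector<int>> multi;
  for (auto &c : comps) if (c.size() >= 2) multi.push_back(c);
  int n_iso = 0;
  for (int i = 0; i < n; ++i) if (deg[i] == 0) ++n_iso;
  double n_eff = n_iso;
  for (auto &c : multi) n_eff += c.size() - 1.0;
  const double shape_u = a + n_eff / 2.0;
  const double shape_v = a + n / 2.0;

  // covariate index sets (dummy coding: update touches its areas only)
  std::vector<std::vector<int>> xset(p);
  std::vector<double> sumY_x(p, 0.0);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      if (X(i, j) != 0.0) { xset[j].push_back(i); sumY_x[j] += y[i] * X(i, j); }

  double sumY = 0.0, sumE = 0.0;
  for (int i = 0; i < n; ++i) { sumY += y[i]; sumE += E[i]; }

  // state
  double alpha = std::log((sumY + 0.5) / sumE);
  std::vector<double> beta(p, 0.0), u(n, 0.0), v(n, 0.0);
  double sigma2_u = fix_variances ? sigma2_u_fix : 0.01;
  double sigma2_v = fix_variances ? sigma2_v_fix : 0.01;
  std::vector<double> mu(n), lambda(n);
  for (int i = 0; i < n; ++i) { mu[i] = alpha; lambda[i] = E[i] * std::exp(mu[i]); }
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += lambda[i];

  // proposal scales + adaptation counters
  double s_alpha = 0.1;
  std::vector<double> s_beta(p, 0.1), s_u(n, 0.1), s_v(n, 0.1);
  int att_a = 0, acc_a = 0;
  std::vector<int> att_b(p, 0), acc_b(p, 0), att_u(n, 0), acc_u(n, 0),
                   att_v(n, 0), acc_v(n, 0);
  long post_att_a = 0, post_acc_a = 0, post_att_b = 0, post_acc_b = 0,
       post_att_u = 0, post_acc_u = 0, post_att_v = 0, post_acc_v = 0;
  auto tune = [](double &s, int &acc, int &att) {
    if (att >= 50) {
      double r = (double)acc / att;
      if (r > 0.50) s *= 1.2; else if (r < 0.40) s /= 1.2;
      if (s < 1e-6) s = 1e-6; if (s > 5.0) s = 5.0;
      acc = 0; att = 0;
    }
  };

  const int n_keep = (n_iter - n_burnin + thin - 1) / thin;
  NumericVector out_alpha(n_keep), out_s2u(n_keep), out_s2v(n_keep),
                out_evu(n_keep), out_evv(n_keep);
  NumericMatrix out_beta(n_keep, p), out_mu(n, n_keep);
  NumericMatrix out_u(keep_effects ? n_keep : 0, keep_effects ? n : 0),
                out_v(keep_effects ? n_keep : 0, keep_effects ? n : 0);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < n_burnin;

    // ---- alpha (O(1) via cached S) ----
    {
      double d = R::rnorm(0.0, s_alpha);
      double dlik = d * sumY - (std::exp(d) - 1.0) * S;
      double dpri = (sq(alpha) - sq(alpha + d)) / (2.0 * prior_var_alpha);
      ++att_a; if (!adapting) ++post_att_a;
      if (std::log(R::runif(0.0, 1.0)) < dlik + dpri) {
        alpha += d;
        double ed = std::exp(d);
        for (int i = 0; i < n; ++i) { mu[i] += d; lambda[i] *= ed; }
        S *= ed;
        ++acc_a; if (!adapting) ++post_acc_a;
      }
      if (adapting) tune(s_alpha, acc_a, att_a);
    }

    // ---- beta_j, dummy covariates ----
    for (int j = 0; j < p; ++j) {
      double d = R::rnorm(0.0, s_beta[j]);
      double Sj = 0.0;
      for (int i : xset[j]) Sj += lambda[i];
      double dlik = d * sumY_x[j] - (std::exp(d) - 1.0) * Sj;
      double dpri = (sq(beta[j]) - sq(beta[j] + d)) / (2.0 * prior_var_beta);
      ++att_b[j]; if (!adapting) ++post_att_b;
      if (std::log(R::runif(0.0, 1.0)) < dlik + dpri) {
        beta[j] += d;
        double ed = std::exp(d);
        for (int i : xset[j]) {
          S -= lambda[i]; mu[i] += d; lambda[i] *= ed; S += lambda[i];
        }
        ++acc_b[j]; if (!adapting) ++post_acc_b;
      }
      if (adapting) tune(s_beta[j], acc_b[j], att_b[j]);
    }

    // ---- structured effects u ----
    if (update_u) {
      for (int i = 0; i < n; ++i) {
        double d = R::rnorm(0.0, s_u[i]);
        double dlik = y[i] * d - lambda[i] * (std::exp(d) - 1.0);
        double dpri;
        if (deg[i] == 0) {
          dpri = (sq(u[i]) - sq(u[i] + d)) / (2.0 * sigma2_u);
        } else {
          double m = 0.0;
          for (int jn : nbr[i]) m += u[jn];
          m /= deg[i];
          double cvar = sigma2_u / deg[i];
          dpri = (sq(u[i] - m) - sq(u[i] + d - m)) / (2.0 * cvar);
        }
        ++att_u[i]; if (!adapting) ++post_att_u;
        if (std::log(R::runif(0.0, 1.0)) < dlik + dpri) {
          u[i] += d;
          S -= lambda[i]; mu[i] += d; lambda[i] *= std::exp(d); S += lambda[i];
          ++acc_u[i]; if (!adapting) ++post_acc_u;
        }
        if (adapting) tune(s_u[i], acc_u[i], att_u[i]);
      }
      // sum-to-zero centring per multi-area component
      for (auto &c : multi) {
        double m = 0.0;
        for (int i : c) m += u[i];
        m /= c.size();
        if (m != 0.0) {
          double em = std::exp(-m);
          for (int i : c) {
            u[i] -= m; S -= lambda[i]; mu[i] -= m; lambda[i] *= em;
            S += lambda[i];
          }
        }
      }
    }

    // ---- unstructured effects v ----
    if (update_v) {
      for (int i = 0; i < n; ++i) {
        double d = R::rnorm(0.0, s_v[i]);
        double dlik = y[i] * d - lambda[i] * (std::exp(d) - 1.0);
        double dpri = (sq(v[i]) - sq(v[i] + d)) / (2.0 * sigma2_v);
        ++att_v[i]; if (!adapting) ++post_att_v;
        if (std::log(R::runif(0.0, 1.0)) < dlik + dpri) {
          v[i] += d;
          S -= lambda[i]; mu[i] += d; lambda[i] *= std::exp(d); S += lambda[i];
          ++acc_v[i]; if (!adapting) ++post_acc_v;
        }
        if (adapting) tune(s_v[i], acc_v[i], att_v[i]);
      }
    }

    // ---- conjugate variance draws ----
    if (!fix_variances) {
      if (update_u) {
        double pair = 0.0;
        for (int i = 0; i < n; ++i)
          for (int jn : nbr[i])
            if (jn > i) pair += sq(u[i] - u[jn]);
        double iso_sq = 0.0;
        for (int i = 0; i < n; ++i) if (deg[i] == 0) iso_sq += sq(u[i]);
        double rate = b + pair / 2.0 + iso_sq / 2.0;
        sigma2_u = 1.0 / R::rgamma(shape_u, 1.0 / rate);
      }
      if (update_v) {
        double ss = 0.0;
        for (int i = 0; i < n; ++i) ss += sq(v[i]);
        sigma2_v = 1.0 / R::rgamma(shape_v, 1.0 / (b + ss / 2.0));
      }
    }

    // refresh cached total occasionally to cap floating-point drift
    if ((it + 1) % 1000 == 0) {
      S = 0.0;
      for (int i = 0; i < n; ++i) S += lambda[i];
    }

    // ---- record ----
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      out_alpha[kept] = alpha;
      for (int j = 0; j < p; ++j) out_beta(kept, j) = beta[j];
      out_s2u[kept] = sigma2_u;
      out_s2v[kept] = sigma2_v;
      double mu_u = 0.0, mu_v = 0.0;
      for (int i = 0; i < n; ++i) { mu_u += u[i]; mu_v += v[i]; }
      mu_u /= n; mu_v /= n;
      double vu = 0.0, vv = 0.0;
      for (int i = 0; i < n; ++i) { vu += sq(u[i] - mu_u); vv += sq(v[i] - mu_v); }
      out_evu[kept] = vu / (n - 1);
      out_evv[kept] = vv / (n - 1);
      for (int i = 0; i < n; ++i) out_mu(i, kept) = mu[i];
      if (keep_effects)
        for (int i = 0; i < n; ++i) { out_u(kept, i) = u[i]; out_v(kept, i) = v[i]; }
      ++kept;
    }
  }

  auto rate = [](long acc, long att) {
    return att > 0 ? (double)acc / att : NA_REAL;
  };
  List out = List::create(
    _["alpha"] = out_alpha, _["beta"] = out_beta,
    _["sigma2_u"] = out_s2u, _["sigma2_v"] = out_s2v,
    _["empvar_u"] = out_evu, _["empvar_v"] = out_evv,
    _["mu"] = out_mu,
    _["accept_alpha"] = rate(post_acc_a, post_att_a),
    _["accept_beta"] = rate(post_acc_b, post_att_b),
    _["accept_u"] = rate(post_acc_u, post_att_u),
    _["accept_v"] = rate(post_acc_v, post_att_v));
  if (keep_effects) { out["u_draws"] = out_u; out["v_draws"] = out_v; }
  return out;
}
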