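#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a unit-diffusion Wiener process between two
// absorbing boundaries, evaluated with the classic dual series expansion:
// a small-time (image-sum) and a large-time (eigenfunction) form, switching
// to whichever needs fewer terms at truncation tolerance eps.
//
// Convention: boundaries at 0 (lower) and a (upper); the process starts at
// w * a with 0 < w < 1; drift v points toward the upper boundary. This
// function returns the LOG density of absorption at the LOWER boundary at
// decision time td (already excluding nondecision time).
static double wfpt_log_lower(double td, double v, double a, double w,
                             double eps) {
  if (!(td > 0.0)) return R_NegInf;
  const double u = td / (a * a); // time in boundary-normalized units

  // number of series terms required for error < eps in each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double p;
  if (ks < kl) { // small-time image sum
    const int K = (int)std::ceil(ks);
    const int klo = -(int)std::floor((K - 1) / 2.0);
    const int khi = (int)std::ceil((K - 1) / 2.0);
    p = 0.0;
    for (int k = klo; k <= khi; ++k) {
      const double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * u));
    }
    p /= std::sqrt(2.0 * M_PI * u * u * u);
  } else { // large-time eigenfunction series
    const int K = (int)std::ceil(kl);
    p = 0.0;
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  if (!(p > 0.0)) return R_NegInf; // truncation can leave tiny negatives
  return std::log(p) - v * a * w - v * v * td / 2.0 - 2.0 * std::log(a);
}

// Log FPT density at either boundary at observed time t (includes tau).
// upper boundary density is the lower-boundary form under the reflection
// (v, w) -> (-v, 1 - w).
static double wfpt_log_obs(double t, bool upper, double alpha, double z,
                           double tau, double v, double eps) {
  const double td = t - tau;
  if (!(td > 0.0)) return R_NegInf;
  if (upper) return wfpt_log_lower(td, -v, alpha, 1.0 - z, eps);
  return wfpt_log_lower(td, v, alpha, z, eps);
}

// [[Rcpp::export]]
NumericVector cpp_wfpt_logd(NumericVector t, IntegerVector upper, double alpha,
                            double z, double tau, NumericVector drift,
                            double eps) {
  const int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = wfpt_log_obs(t[i], upper[i] != 0, alpha, z, tau, drift[i], eps);
  }
  return out;
}

// log posterior kernel: Wiener likelihood + half-normal(alpha), uniform(z),
// truncated half-normal(tau on (0, tau_max)), uniform betas on (lo, hi).
struct DDMPost {
  const NumericMatrix &X;
  const NumericVector &rt;
  const IntegerVector &reject;
  double alpha_sigma, tau_sigma, beta_lo, beta_hi, tau_max, eps;

  // fills per-trial log-likelihood into ll; returns log posterior (or -Inf)
  double operator()(const std::vector<double> &th, std::vector<double> &ll) const {
    const int n = rt.size(), k = X.ncol();
    const double alpha = th[0], z = th[1], tau = th[2];
    if (!(alpha > 0.0) || !(z > 0.0) || !(z < 1.0) || !(tau > 0.0) ||
        !(tau < tau_max))
      return R_NegInf;
    for (int j = 0; j < k; ++j)
      if (!(th[3 + j] > beta_lo) || !(th[3 + j] < beta_hi)) return R_NegInf;
    double lp = -alpha * alpha / (2.0 * alpha_sigma * alpha_sigma) -
                tau * tau / (2.0 * tau_sigma * tau_sigma);
    for (int i = 0; i < n; ++i) {
      double v = 0.0;
      for (int j = 0; j < k; ++j) v += X(i, j) * th[3 + j];
      const double l = wfpt_log_obs(rt[i], reject[i] != 0, alpha, z, tau, v, eps);
      ll[i] = l;
      if (!R_FINITE(l)) return R_NegInf;
      lp += l;
    }
    return lp;
  }
};

// Adaptive Metropolis-within-Gibbs sampler over (alpha, z, tau, betas).
// Proposal scales adapt during burn-in only (Robbins-Monro toward 0.44
// acceptance) so retained draws come from a fixed-kernel Markov chain.
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List cpp_sample_ddm(NumericMatrix X, NumericVector rt, IntegerVector reject,
                    int chains, int burn, int ndraws, double alpha_sigma,
                    double tau_sigma, double beta_lo, double beta_hi,
                    double tau_max, double eps) {
  const int n = rt.size(), k = X.ncol(), npar = 3 + k;
  DDMPost post{X, rt, reject, alpha_sigma, tau_sigma, beta_lo, beta_hi,
               tau_max, eps};

  NumericVector draws(Dimension(chains, ndraws, npar));
  NumericVector ll_store(Dimension(chains, ndraws, n));
  NumericMatrix accept(chains, npar);
  IntegerVector reinit(chains);

  std::vector<double> th(npar), prop(npar), ll(n), ll_prop(n);

  for (int c = 0; c < chains; ++c) {
    // initialization: overdispersed draws until the posterior is finite
    double lp = R_NegInf;
    int tries = 0;
    while (!R_FINITE(lp) && tries < 200) {
      th[0] = 0.5 + 2.5 * unif_rand();
      th[1] = 0.3 + 0.4 * unif_rand();
      th[2] = tau_max * (0.05 + 0.85 * unif_rand());
      for (int j = 0; j < k; ++j) th[3 + j] = -1.0 + 2.0 * unif_rand();
      lp = post(th, ll);
      ++tries;
    }
    if (!R_FINITE(lp))
      stop("could not initialize chain %d at a finite posterior density",
           c + 1);
    reinit[c] = tries - 1;

    std::vector<double> lsd(npar);
    lsd[0] = std::log(0.4);
    lsd[1] = std::log(0.1);
    lsd[2] = std::log(std::max(0.05 * tau_max, 1e-4));
    for (int j = 0; j < k; ++j) lsd[3 + j] = std::log(0.4);

    for (int it = 0; it < burn + ndraws; ++it) {
      for (int j = 0; j < npar; ++j) {
        prop = th;
        prop[j] = th[j] + std::exp(lsd[j]) * norm_rand();
        const double lp_new = post(prop, ll_prop);
        const bool acc =
            R_FINITE(lp_new) && std::log(unif_rand()) < lp_new - lp;
        if (acc) {
          th = prop;
          lp = lp_new;
          ll.swap(ll_prop);
        }
        if (it < burn) {
          const double gamma = std::min(0.25, 3.0 / std::sqrt(it + 1.0));
          lsd[j] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
        } else if (acc) {
          accept(c, j) += 1.0;
        }
      }
      if (it >= burn) {
        const int d = it - burn;
        for (int j = 0; j < npar; ++j)
          draws[c + chains * (d + (R_xlen_t)ndraws * j)] = th[j];
        for (int i = 0; i < n; ++i)
          ll_store[c + chains * (d + (R_xlen_t)ndraws * i)] = ll[i];
      }
    }
    for (int j = 0; j < npar; ++j) accept(c, j) /= ndraws;
  }

  return List::create(_["draws"] = draws, _["loglik"] = ll_store,
                      _["accept"] = accept, _["reinit"] = reinit);
}

// Euler-Maruyama simulation of one Wiener trial per drift value.
// choice: 0 = accept (lower), 1 = reject (upper), 2 = timeout (censored at
// the deadline); rt includes nondecision time tau. Uses R's RNG.
// [[Rcpp::export]]
List cpp_simulate_ddm(NumericVector drift, double alpha, double z, double tau,
                      double dt, double deadline) {
  const int n = drift.size();
  IntegerVector choice(n);
  NumericVector rt(n);
  const double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = z * alpha, t = 0.0;
    int ch = 2;
    for (;;) {
      t += dt;
      if (tau + t > deadline) { ch = 2; break; } // censored at the deadline
      x += drift[i] * dt + sdt * norm_rand();
      if (x <= 0.0) { ch = 0; break; }
      if (x >= alpha) { ch = 1; break; }
    }
    choice[i] = ch;
    rt[i] = (ch == 2) ? NA_REAL : tau + t;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}
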