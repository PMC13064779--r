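#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Bernoulli log-likelihood y*eta - log(1 + exp(eta)), overflow-safe.
static inline double bll(int y, double eta) {
  if (eta > 0.0) return y * eta - eta - log1p(std::exp(-eta));
  return y * eta - log1p(std::exp(eta));
}

// Metropolis-within-Gibbs sampler for the 2PL testlet response model
//   P(y_ij = 1) = logistic(a_j * (theta_i - b_j - gamma_{i, d(j)}))
// with priors theta ~ N(0,1), gamma_{.d} ~ N(0, sig2_d),
// log a ~ N(0, prior_a_sd^2), b ~ N(0, prior_b_sd^2),
// sig2_d ~ Inverse-Gamma(ig_shape, ig_rate).
// Proposal scales adapt toward 0.44 acceptance during burn-in only.
// Uses R's RNG, so draws are reproducible given set.seed().
// [[Rcpp::export(name = ".testlet_sampler")]]
List testlet_sampler(IntegerMatrix Y, IntegerVector dom,
                     int n_iter, int burn_in, int thin,
                     NumericVector theta_init, NumericMatrix gamma_init,
                     NumericVector a_init, NumericVector b_init,
                     NumericVector sig2_init,
                     LogicalVector sigma_zero,
                     bool update_items, bool update_sigma,
                     double prior_a_sd, double prior_b_sd,
                     double ig_shape, double ig_rate,
                     double target_accept) {
  const int n = Y.nrow(), J = Y.ncol();
  int D = 0;
  for (int j = 0; j < J; ++j) D = std::max(D, dom[j] + 1);

  std::vector<std::vector<int>> items_of(D);
  for (int j = 0; j < J; ++j) items_of[dom[j]].push_back(j);

  NumericVector theta = clone(theta_init);
  NumericMatrix gamma = clone(gamma_init);
  NumericVector a = clone(a_init), b = clone(b_init);
  NumericVector sig2 = clone(sig2_init);

  bool all_free = true;
  for (int d = 0; d < D; ++d) if (sigma_zero[d]) all_free = false;

  // adaptive log proposal scales
  NumericVector ls_theta(n, std::log(0.5));
  NumericMatrix ls_gamma(n, D);
  std::fill(ls_gamma.begin(), ls_gamma.end(), std::log(0.5));
  NumericVector ls_item(J, std::log(0.15));

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix dr_theta(n_keep, n), dr_a(n_keep, J), dr_b(n_keep, J);
  NumericMatrix dr_sigma(n_keep, D);
  NumericMatrix dr_gamma(n_keep, n * D);
  NumericVector acc_theta(n), acc_item(J);
  int kept = 0;

  for (int t = 0; t < n_iter; ++t) {
    const bool adapting = t < burn_in;
    const double step = std::min(0.25, 4.0 / std::sqrt((double)(t + 1)));

    // -- theta block ---------------------------------------------------------
    for (int i = 0; i < n; ++i) {
      const double cur = theta[i];
      const double prop = cur + norm_rand() * std::exp(ls_theta[i]);
      double llc = 0.0, llp = 0.0;
      for (int j = 0; j < J; ++j) {
        const int y = Y(i, j);
        if (y == NA_INTEGER) continue;
        const double base = -b[j] - gamma(i, dom[j]);
        llc += bll(y, a[j] * (cur + base));
        llp += bll(y, a[j] * (prop + base));
      }
      const double lr = llp - llc - 0.5 * (prop * prop - cur * cur);
      const bool acc = std::log(unif_rand()) < lr;
      if (acc) theta[i] = prop;
      if (adapting)
        ls_theta[i] += step * ((acc ? 1.0 : 0.0) - target_accept);
      if (!adapting && acc) acc_theta[i] += 1.0;
    }

    // -- gamma block (domains have disjoint item sets) -----------------------
    for (int d = 0; d < D; ++d) {
      if (sigma_zero[d]) continue;
      const std::vector<int>& jj = items_of[d];
      for (int i = 0; i < n; ++i) {
        const double cur = gamma(i, d);
        const double prop = cur + norm_rand() * std::exp(ls_gamma(i, d));
        double llc = 0.0, llp = 0.0;
        for (size_t k = 0; k < jj.size(); ++k) {
          const int j = jj[k];
          const int y = Y(i, j);
          if (y == NA_INTEGER) continue;
          const double base = theta[i] - b[j];
          llc += bll(y, a[j] * (base - cur));
          llp += bll(y, a[j] * (base - prop));
        }
        const double lr = llp - llc -
          0.5 * (prop * prop - cur * cur) / sig2[d];
        const bool acc = std::log(unif_rand()) < lr;
        if (acc) gamma(i, d) = prop;
        if (adapting)
          ls_gamma(i, d) += step * ((acc ? 1.0 : 0.0) - target_accept);
      }
    }

    // -- likelihood-invariant recentering (theta_i, gamma_i.) ----------------
    // eta depends on theta_i - gamma_id, so a joint shift is a pure prior
    // draw; Gibbs-sample it to fix the slowest-mixing direction.
    if (all_free) {
      for (int i = 0; i < n; ++i) {
        double tau = 1.0, wsum = theta[i];
        for (int d = 0; d < D; ++d) {
          tau += 1.0 / sig2[d];
          wsum += gamma(i, d) / sig2[d];
        }
        const double delta = -wsum / tau + norm_rand() / std::sqrt(tau);
        theta[i] += delta;
        for (int d = 0; d < D; ++d) gamma(i, d) += delta;
      }
    }

    // -- item block: joint (log a, b) random walk ----------------------------
    if (update_items) {
      for (int j = 0; j < J; ++j) {
        const double la = std::log(a[j]);
        const double s = std::exp(ls_item[j]);
        const double lap = la + norm_rand() * s;
        const double bp = b[j] + norm_rand() * s;
        const double ap = std::exp(lap);
        double llc = 0.0, llp = 0.0;
        const int d = dom[j];
        for (int i = 0; i < n; ++i) {
          const int y = Y(i, j);
          if (y == NA_INTEGER) continue;
          const double z = theta[i] - gamma(i, d);
          llc += bll(y, a[j] * (z - b[j]));
          llp += bll(y, ap * (z - bp));
        }
        const double lr = llp - llc -
          0.5 * (lap * lap - la * la) / (prior_a_sd * prior_a_sd) -
          0.5 * (bp * bp - b[j] * b[j]) / (prior_b_sd * prior_b_sd);
        const bool acc = std::log(unif_rand()) < lr;
        if (acc) { a[j] = ap; b[j] = bp; }
        if (adapting)
          ls_item[j] += step * ((acc ? 1.0 : 0.0) - target_accept);
        if (!adapting && acc) acc_item[j] += 1.0;
      }
    }

    // -- testlet variance block (conjugate) ----------------------------------
    if (update_sigma) {
      for (int d = 0; d < D; ++d) {
        if (sigma_zero[d]) continue;
        double ss = 0.0;
        for (int i = 0; i < n; ++i) ss += gamma(i, d) * gamma(i, d);
        const double shape = ig_shape + 0.5 * n;
        const double rate = ig_rate + 0.5 * ss;
        sig2[d] = rate / R::rgamma(shape, 1.0);
      }
    }

    // -- storage -------------------------------------------------------------
    if (t >= burn_in && ((t - burn_in) % thin == 0) && kept < n_keep) {
      for (int i = 0; i < n; ++i) dr_theta(kept, i) = theta[i];
      for (int j = 0; j < J; ++j) { dr_a(kept, j) = a[j]; dr_b(kept, j) = b[j]; }
      for (int d = 0; d < D; ++d) dr_sigma(kept, d) = std::sqrt(sig2[d]);
      for (int d = 0; d < D; ++d)
        for (int i = 0; i < n; ++i)
          dr_gamma(kept, d * n + i) = gamma(i, d);
      ++kept;
    }
  }

  const double post_iter = (double)(n_iter - burn_in);
  return List::create(
    _["theta"] = dr_theta, _["a"] = dr_a, _["b"] = dr_b,
    _["sigma"] = dr_sigma, _["gamma"] = dr_gamma,
    _["accept_theta"] = acc_theta / post_iter,
    _["accept_item"] = acc_item / post_iter);
}
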