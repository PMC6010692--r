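// Metropolis-within-Gibbs samplers for the conjunctive cognitive diagnosis
// models. One function per model variant, each running a single chain; the R
// wrapper seeds R's RNG per chain, so everything here draws through the R API.
//
// Conventions shared by all samplers:
//  - Y is N x I with missing responses coded -1 (dropped from every
//    likelihood term).
//  - A latent-response cache w (rho for probabilistic models, eta for the
//    deterministic ones) is kept in sync with the person parameters; cache
//    entries are always recomputed as fresh products, never updated by
//    ratios, so no drift accumulates.
//  - Random-walk proposal scales adapt in batches during burn-in only, toward
//    the target acceptance band, and are frozen afterwards so the retained
//    draws come from a fixed kernel.
//  - Slip/guess proposals outside {s > 0, g > 0, g < 1 - s} are rejected,
//    which with the symmetric proposal is exactly the truncated-prior target.

#include <Rcpp.h>
using namespace Rcpp;

static const double P_EPS = 1e-10;

static inline double clampp(double p) {
  if (p < P_EPS) return P_EPS;
  if (p > 1.0 - P_EPS) return 1.0 - P_EPS;
  return p;
}

// Bernoulli log-likelihood of one observed cell
static inline double bern_ll(int y, double p) {
  p = clampp(p);
  return y == 1 ? std::log(p) : std::log1p(-p);
}

static inline double logistic(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

typedef std::vector< std::vector<int> > adjacency;

static void q_adjacency(const IntegerMatrix& Q, adjacency& attrs_of_item,
                        adjacency& items_of_attr) {
  int I = Q.nrow(), K = Q.ncol();
  attrs_of_item.assign(I, std::vector<int>());
  items_of_attr.assign(K, std::vector<int>());
  for (int i = 0; i < I; ++i)
    for (int k = 0; k < K; ++k)
      if (Q(i, k) == 1) {
        attrs_of_item[i].push_back(k);
        items_of_attr[k].push_back(i);
      }
}

// product of person n's parameter over the attributes item i requires,
// optionally substituting value dsub for attribute ksub
static inline double w_item(const NumericMatrix& person,
                            const std::vector<int>& attrs, int n,
                            int ksub = -1, double dsub = 1.0) {
  double r = 1.0;
  for (size_t j = 0; j < attrs.size(); ++j) {
    int k = attrs[j];
    r *= (k == ksub) ? dsub : person(n, k);
  }
  return r;
}

static double total_deviance(const IntegerMatrix& Y, const NumericMatrix& w,
                             const std::vector<double>& s,
                             const std::vector<double>& g) {
  double ll = 0.0;
  int N = Y.nrow(), I = Y.ncol();
  for (int i = 0; i < I; ++i) {
    double one_sg = 1.0 - s[i] - g[i];
    for (int n = 0; n < N; ++n) {
      int y = Y(n, i);
      if (y < 0) continue;
      ll += bern_ll(y, g[i] + one_sg * w(n, i));
    }
  }
  return -2.0 * ll;
}

// batch adaptation of log proposal scales toward the acceptance band
static void adapt_scales(std::vector<double>& ls, std::vector<int>& acc,
                         std::vector<int>& tot, int batch_index,
                         double lo, double hi) {
  double step = std::min(0.25, 1.0 / std::sqrt((double) batch_index));
  for (size_t j = 0; j < ls.size(); ++j) {
    if (tot[j] == 0) continue;
    double rate = (double) acc[j] / (double) tot[j];
    if (rate < lo) ls[j] -= step;
    else if (rate > hi) ls[j] += step;
    acc[j] = 0; tot[j] = 0;
  }
}

// one Metropolis sweep over all (s_i, g_i); w is the latent-response cache
static void update_item_params(const IntegerMatrix& Y, const NumericMatrix& w,
                               std::vector<double>& s, std::vector<double>& g,
                               double a_s, double b_s, double a_g, double b_g,
                               std::vector<double>& ls_s,
                               std::vector<double>& ls_g,
                               std::vector<int>& acc_s, std::vector<int>& tot_s,
                               std::vector<int>& acc_g, std::vector<int>& tot_g) {
  int N = Y.nrow(), I = Y.ncol();
  for (int i = 0; i < I; ++i) {
    // slip
    double sp = s[i] + std::exp(ls_s[i]) * norm_rand();
    ++tot_s[i];
    if (sp > 0.0 && sp < 1.0 && g[i] < 1.0 - sp) {
      double lr = (a_s - 1.0) * (std::log(sp) - std::log(s[i]))
                + (b_s - 1.0) * (std::log1p(-sp) - std::log1p(-s[i]));
      double d_old = 1.0 - s[i] - g[i], d_new = 1.0 - sp - g[i];
      for (int n = 0; n < N; ++n) {
        int y = Y(n, i);
        if (y < 0) continue;
        lr += bern_ll(y, g[i] + d_new * w(n, i))
            - bern_ll(y, g[i] + d_old * w(n, i));
      }
      if (std::log(unif_rand()) < lr) { s[i] = sp; ++acc_s[i]; }
    }
    // guess
    double gp = g[i] + std::exp(ls_g[i]) * norm_rand();
    ++tot_g[i];
    if (gp > 0.0 && gp < 1.0 - s[i]) {
      double lr = (a_g - 1.0) * (std::log(gp) - std::log(g[i]))
                + (b_g - 1.0) * (std::log1p(-gp) - std::log1p(-g[i]));
      double one_s = 1.0 - s[i];
      for (int n = 0; n < N; ++n) {
        int y = Y(n, i);
        if (y < 0) continue;
        lr += bern_ll(y, gp + (one_s - gp) * w(n, i))
            - bern_ll(y, g[i] + (one_s - g[i]) * w(n, i));
      }
      if (std::log(unif_rand()) < lr) { g[i] = gp; ++acc_g[i]; }
    }
  }
}

static void init_item_params(std::vector<double>& s, std::vector<double>& g,
                             double a_s, double b_s, double a_g, double b_g) {
  for (size_t i = 0; i < s.size(); ++i) {
    int tries = 0;
    do {
      s[i] = R::rbeta(a_s, b_s);
      g[i] = R::rbeta(a_g, b_g);
    } while (g[i] >= 1.0 - s[i] && ++tries < 1000);
    if (g[i] >= 1.0 - s[i]) g[i] = unif_rand() * (1.0 - s[i]);
    s[i] = std::min(std::max(s[i], 1e-4), 1.0 - 1e-4);
    g[i] = std::min(std::max(g[i], 1e-4), (1.0 - s[i]) * (1.0 - 1e-4));
  }
}

static inline double rate(const std::vector<int>& acc,
                          const std::vector<int>& tot) {
  long a = 0, t = 0;
  for (size_t j = 0; j < acc.size(); ++j) { a += acc[j]; t += tot[j]; }
  return t == 0 ? NA_REAL : (double) a / (double) t;
}

// ---------------------------------------------------------------- PINC -----

// [[Rcpp::export]]
List cpp_chain_pinc(IntegerMatrix Y, IntegerMatrix Q,
                    double a_delta, double b_delta,
                    double a_s, double b_s, double a_g, double b_g,
                    int n_iter, int n_burn, int n_thin,
                    int adapt_batch, double acc_lo, double acc_hi,
                    bool store_person) {
  int N = Y.nrow(), I = Y.ncol(), K = Q.ncol();
  adjacency attrs_of_item, items_of_attr;
  q_adjacency(Q, attrs_of_item, items_of_attr);
  RNGScope scope;

  // initial values drawn from the priors
  NumericMatrix delta(N, K);
  for (int k = 0; k < K; ++k)
    for (int n = 0; n < N; ++n)
      delta(n, k) = std::min(std::max(R::rbeta(a_delta, b_delta), 1e-6),
                             1.0 - 1e-6);
  std::vector<double> s(I), g(I);
  init_item_params(s, g, a_s, b_s, a_g, b_g);

  NumericMatrix rho(N, I);
  for (int i = 0; i < I; ++i)
    for (int n = 0; n < N; ++n)
      rho(n, i) = w_item(delta, attrs_of_item[i], n);

  std::vector<double> ls_d(N * K, std::log(1.0)),
                      ls_s(I, std::log(0.05)), ls_g(I, std::log(0.05));
  std::vector<int> acc_d(N * K, 0), tot_d(N * K, 0),
                   acc_s(I, 0), tot_s(I, 0), acc_g(I, 0), tot_g(I, 0);

  int n_keep = (n_iter - n_burn) / n_thin;
  NumericMatrix out_delta(store_person ? n_keep : 0,
                          store_person ? N * K : 0);
  NumericMatrix out_s(n_keep, I), out_g(n_keep, I);
  NumericVector out_dev(n_keep);
  int keep = 0, batch = 0;
  double post_acc_d = 0.0; long post_n_d = 0, post_a_d = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // mastery probabilities: random walk on the logit scale.
    // Beta(a, b) prior plus the logit Jacobian gives target terms
    // a*log(delta) + b*log(1 - delta).
    for (int k = 0; k < K; ++k) {
      const std::vector<int>& items = items_of_attr[k];
      for (int n = 0; n < N; ++n) {
        int idx = n + N * k;
        double d = delta(n, k);
        double x = std::log(d) - std::log1p(-d);
        double xp = x + std::exp(ls_d[idx]) * norm_rand();
        double dp = logistic(xp);
        if (dp < 1e-12) dp = 1e-12;
        if (dp > 1.0 - 1e-12) dp = 1.0 - 1e-12;
        double lr = a_delta * (std::log(dp) - std::log(d))
                  + b_delta * (std::log1p(-dp) - std::log1p(-d));
        for (size_t j = 0; j < items.size(); ++j) {
          int i = items[j];
          int y = Y(n, i);
          if (y < 0) continue;
          double one_sg = 1.0 - s[i] - g[i];
          double rp = w_item(delta, attrs_of_item[i], n, k, dp);
          lr += bern_ll(y, g[i] + one_sg * rp)
              - bern_ll(y, g[i] + one_sg * rho(n, i));
        }
        ++tot_d[idx]; if (it > n_burn) ++post_n_d;
        if (std::log(unif_rand()) < lr) {
          ++acc_d[idx]; if (it > n_burn) ++post_a_d;
          delta(n, k) = dp;
          for (size_t j = 0; j < items.size(); ++j) {
            int i = items[j];
            rho(n, i) = w_item(delta, attrs_of_item[i], n);
          }
        }
      }
    }

    update_item_params(Y, rho, s, g, a_s, b_s, a_g, b_g,
                       ls_s, ls_g, acc_s, tot_s, acc_g, tot_g);

    if (it <= n_burn && it % adapt_batch == 0) {
      ++batch;
      adapt_scales(ls_d, acc_d, tot_d, batch, acc_lo, acc_hi);
      adapt_scales(ls_s, acc_s, tot_s, batch, acc_lo, acc_hi);
      adapt_scales(ls_g, acc_g, tot_g, batch, acc_lo, acc_hi);
    }

    if (it > n_burn && (it - n_burn) % n_thin == 0) {
      out_dev[keep] = total_deviance(Y, rho, s, g);
      for (int i = 0; i < I; ++i) { out_s(keep, i) = s[i]; out_g(keep, i) = g[i]; }
      if (store_person)
        for (int k = 0; k < K; ++k)
          for (int n = 0; n < N; ++n)
            out_delta(keep, n + N * k) = delta(n, k);
      ++keep;
    }
  }
  post_acc_d = post_n_d == 0 ? NA_REAL : (double) post_a_d / (double) post_n_d;

  return List::create(
    _["delta"] = out_delta, _["s"] = out_s, _["g"] = out_g,
    _["deviance"] = out_dev,
    _["acceptance"] = NumericVector::create(
      _["delta"] = post_acc_d, _["s"] = rate(acc_s, tot_s),
      _["g"] = rate(acc_g, tot_g)));
}

// ------------------------------------------------------------- HO-PINC -----

// [[Rcpp::export]]
List cpp_chain_hopinc(IntegerMatrix Y, IntegerMatrix Q,
                      double lambda_sd, double beta_sd,
                      double a_s, double b_s, double a_g, double b_g,
                      int n_iter, int n_burn, int n_thin,
                      int adapt_batch, double acc_lo, double acc_hi,
                      bool store_person) {
  int N = Y.nrow(), I = Y.ncol(), K = Q.ncol();
  adjacency attrs_of_item, items_of_attr;
  q_adjacency(Q, attrs_of_item, items_of_attr);
  RNGScope scope;

  std::vector<double> theta(N), lambda(K), beta(K);
  for (int n = 0; n < N; ++n) theta[n] = norm_rand();
  for (int k = 0; k < K; ++k) {
    do { lambda[k] = R::rnorm(0.0, lambda_sd); } while (lambda[k] <= 0.0);
    beta[k] = R::rnorm(0.0, beta_sd);
  }
  std::vector<double> s(I), g(I);
  init_item_params(s, g, a_s, b_s, a_g, b_g);

  NumericMatrix delta(N, K);
  for (int k = 0; k < K; ++k)
    for (int n = 0; n < N; ++n)
      delta(n, k) = logistic(lambda[k] * theta[n] - beta[k]);
  NumericMatrix rho(N, I);
  for (int i = 0; i < I; ++i)
    for (int n = 0; n < N; ++n)
      rho(n, i) = w_item(delta, attrs_of_item[i], n);

  double lambda_var = lambda_sd * lambda_sd, beta_var = beta_sd * beta_sd;
  std::vector<double> ls_t(N, std::log(0.5)),
                      ls_l(K, std::log(0.3)), ls_b(K, std::log(0.3)),
                      ls_s(I, std::log(0.05)), ls_g(I, std::log(0.05));
  std::vector<int> acc_t(N, 0), tot_t(N, 0), acc_l(K, 0), tot_l(K, 0),
                   acc_b(K, 0), tot_b(K, 0),
                   acc_s(I, 0), tot_s(I, 0), acc_g(I, 0), tot_g(I, 0);

  int n_keep = (n_iter - n_burn) / n_thin;
  NumericMatrix out_theta(n_keep, N), out_lambda(n_keep, K),
                out_beta(n_keep, K), out_s(n_keep, I), out_g(n_keep, I);
  NumericMatrix out_delta(store_person ? n_keep : 0,
                          store_person ? N * K : 0);
  NumericVector out_dev(n_keep);
  int keep = 0, batch = 0;

  std::vector<double> dnew(K), dcol(N);

  for (int it = 1; it <= n_iter; ++it) {
    // higher-order trait, one random walk per person; a change in theta_n
    // moves the whole delta row, so the likelihood spans all items.
    for (int n = 0; n < N; ++n) {
      double tp = theta[n] + std::exp(ls_t[n]) * norm_rand();
      double lr = -0.5 * (tp * tp - theta[n] * theta[n]);
      for (int k = 0; k < K; ++k)
        dnew[k] = logistic(lambda[k] * tp - beta[k]);
      for (int i = 0; i < I; ++i) {
        int y = Y(n, i);
        if (y < 0) continue;
        const std::vector<int>& attrs = attrs_of_item[i];
        double rp = 1.0;
        for (size_t j = 0; j < attrs.size(); ++j) rp *= dnew[attrs[j]];
        double one_sg = 1.0 - s[i] - g[i];
        lr += bern_ll(y, g[i] + one_sg * rp)
            - bern_ll(y, g[i] + one_sg * rho(n, i));
      }
      ++tot_t[n];
      if (std::log(unif_rand()) < lr) {
        ++acc_t[n];
        theta[n] = tp;
        for (int k = 0; k < K; ++k) delta(n, k) = dnew[k];
        for (int i = 0; i < I; ++i)
          rho(n, i) = w_item(delta, attrs_of_item[i], n);
      }
    }

    // attribute slopes and intercepts; proposals with lambda <= 0 rejected
    // (truncated prior)
    for (int what = 0; what < 2; ++what) {
      for (int k = 0; k < K; ++k) {
        double lp, bp, lr;
        if (what == 0) {
          lp = lambda[k] + std::exp(ls_l[k]) * norm_rand();
          ++tot_l[k];
          if (lp <= 0.0) continue;
          bp = beta[k];
          lr = -0.5 * (lp * lp - lambda[k] * lambda[k]) / lambda_var;
        } else {
          lp = lambda[k];
          bp = beta[k] + std::exp(ls_b[k]) * norm_rand();
          ++tot_b[k];
          lr = -0.5 * (bp * bp - beta[k] * beta[k]) / beta_var;
        }
        const std::vector<int>& items = items_of_attr[k];
        for (int n = 0; n < N; ++n) {
          double dnp = logistic(lp * theta[n] - bp);
          dcol[n] = dnp;
          for (size_t j = 0; j < items.size(); ++j) {
            int i = items[j];
            int y = Y(n, i);
            if (y < 0) continue;
            double one_sg = 1.0 - s[i] - g[i];
            double rp = w_item(delta, attrs_of_item[i], n, k, dnp);
            lr += bern_ll(y, g[i] + one_sg * rp)
                - bern_ll(y, g[i] + one_sg * rho(n, i));
          }
        }
        if (std::log(unif_rand()) < lr) {
          if (what == 0) { lambda[k] = lp; ++acc_l[k]; }
          else { beta[k] = bp; ++acc_b[k]; }
          for (int n = 0; n < N; ++n) delta(n, k) = dcol[n];
          for (size_t j = 0; j < items.size(); ++j) {
            int i = items[j];
            for (int n = 0; n < N; ++n)
              rho(n, i) = w_item(delta, attrs_of_item[i], n);
          }
        }
      }
    }

    update_item_params(Y, rho, s, g, a_s, b_s, a_g, b_g,
                       ls_s, ls_g, acc_s, tot_s, acc_g, tot_g);

    if (it <= n_burn && it % adapt_batch == 0) {
      ++batch;
      adapt_scales(ls_t, acc_t, tot_t, batch, acc_lo, acc_hi);
      adapt_scales(ls_l, acc_l, tot_l, batch, acc_lo, acc_hi);
      adapt_scales(ls_b, acc_b, tot_b, batch, acc_lo, acc_hi);
      adapt_scales(ls_s, acc_s, tot_s, batch, acc_lo, acc_hi);
      adapt_scales(ls_g, acc_g, tot_g, batch, acc_lo, acc_hi);
    }

    if (it > n_burn && (it - n_burn) % n_thin == 0) {
      out_dev[keep] = total_deviance(Y, rho, s, g);
      for (int n = 0; n < N; ++n) out_theta(keep, n) = theta[n];
      for (int k = 0; k < K; ++k) {
        out_lambda(keep, k) = lambda[k];
        out_beta(keep, k) = beta[k];
      }
      for (int i = 0; i < I; ++i) { out_s(keep, i) = s[i]; out_g(keep, i) = g[i]; }
      if (store_person)
        for (int k = 0; k < K; ++k)
          for (int n = 0; n < N; ++n)
            out_delta(keep, n + N * k) = delta(n, k);
      ++keep;
    }
  }

  return List::create(
    _["theta"] = out_theta, _["lambda"] = out_lambda, _["beta"] = out_beta,
    _["delta"] = out_delta, _["s"] = out_s, _["g"] = out_g,
    _["deviance"] = out_dev,
    _["acceptance"] = NumericVector::create(
      _["theta"] = rate(acc_t, tot_t), _["lambda"] = rate(acc_l, tot_l),
      _["beta"] = rate(acc_b, tot_b), _["s"] = rate(acc_s, tot_s),
      _["g"] = rate(acc_g, tot_g)));
}

// ---------------------------------------------------------------- DINA -----

// draw alpha(n, k) from its exact two-point full conditional; prior_logit is
// the log-odds of mastery from the structural layer (base rate or logistic
// link)
static inline void update_alpha_cell(const IntegerMatrix& Y,
                                     NumericMatrix& alpha, NumericMatrix& eta,
                                     const adjacency& attrs_of_item,
                                     const std::vector<int>& items,
                                     const std::vector<double>& s,
                                     const std::vector<double>& g,
                                     int n, int k, double prior_logit) {
  double l1 = 0.0, l0 = 0.0;
  for (size_t j = 0; j < items.size(); ++j) {
    int i = items[j];
    int y = Y(n, i);
    if (y < 0) continue;
    double eta1 = w_item(alpha, attrs_of_item[i], n, k, 1.0);
    double one_sg = 1.0 - s[i] - g[i];
    l1 += bern_ll(y, g[i] + one_sg * eta1);
    l0 += bern_ll(y, g[i]); // with alpha_nk = 0 the conjunction fails: eta = 0
  }
  double pr = logistic(prior_logit + l1 - l0);
  alpha(n, k) = (unif_rand() < pr) ? 1.0 : 0.0;
  for (size_t j = 0; j < items.size(); ++j) {
    int i = items[j];
    eta(n, i) = w_item(alpha, attrs_of_item[i], n);
  }
}

// [[Rcpp::export]]
List cpp_chain_dina(IntegerMatrix Y, IntegerMatrix Q,
                    double a_pi, double b_pi,
                    double a_s, double b_s, double a_g, double b_g,
                    int n_iter, int n_burn, int n_thin,
                    int adapt_batch, double acc_lo, double acc_hi,
                    bool store_person) {
  int N = Y.nrow(), I = Y.ncol(), K = Q.ncol();
  adjacency attrs_of_item, items_of_attr;
  q_adjacency(Q, attrs_of_item, items_of_attr);
  RNGScope scope;

  std::vector<double> pi(K);
  NumericMatrix alpha(N, K);
  for (int k = 0; k < K; ++k) {
    pi[k] = R::rbeta(a_pi, b_pi);
    for (int n = 0; n < N; ++n)
      alpha(n, k) = (unif_rand() < pi[k]) ? 1.0 : 0.0;
  }
  std::vector<double> s(I), g(I);
  init_item_params(s, g, a_s, b_s, a_g, b_g);
  NumericMatrix eta(N, I);
  for (int i = 0; i < I; ++i)
    for (int n = 0; n < N; ++n)
      eta(n, i) = w_item(alpha, attrs_of_item[i], n);

  std::vector<double> ls_s(I, std::log(0.05)), ls_g(I, std::log(0.05));
  std::vector<int> acc_s(I, 0), tot_s(I, 0), acc_g(I, 0), tot_g(I, 0);

  int n_keep = (n_iter - n_burn) / n_thin;
  NumericMatrix out_pi(n_keep, K), out_s(n_keep, I), out_g(n_keep, I);
  NumericMatrix out_alpha(store_person ? n_keep : 0,
                          store_person ? N * K : 0);
  NumericVector out_dev(n_keep);
  int keep = 0, batch = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int k = 0; k < K; ++k) {
      double pl = std::log(clampp(pi[k])) - std::log1p(-clampp(pi[k]));
      for (int n = 0; n < N; ++n)
        update_alpha_cell(Y, alpha, eta, attrs_of_item, items_of_attr[k],
                          s, g, n, k, pl);
      // conjugate update of the mastery base rate
      double sum_k = 0.0;
      for (int n = 0; n < N; ++n) sum_k += alpha(n, k);
      pi[k] = R::rbeta(a_pi + sum_k, b_pi + N - sum_k);
    }

    update_item_params(Y, eta, s, g, a_s, b_s, a_g, b_g,
                       ls_s, ls_g, acc_s, tot_s, acc_g, tot_g);

    if (it <= n_burn && it % adapt_batch == 0) {
      ++batch;
      adapt_scales(ls_s, acc_s, tot_s, batch, acc_lo, acc_hi);
      adapt_scales(ls_g, acc_g, tot_g, batch, acc_lo, acc_hi);
    }

    if (it > n_burn && (it - n_burn) % n_thin == 0) {
      out_dev[keep] = total_deviance(Y, eta, s, g);
      for (int k = 0; k < K; ++k) out_pi(keep, k) = pi[k];
      for (int i = 0; i < I; ++i) { out_s(keep, i) = s[i]; out_g(keep, i) = g[i]; }
      if (store_person)
        for (int k = 0; k < K; ++k)
          for (int n = 0; n < N; ++n)
            out_alpha(keep, n + N * k) = alpha(n, k);
      ++keep;
    }
  }

  return List::create(
    _["pi"] = out_pi, _["alpha"] = out_alpha, _["s"] = out_s, _["g"] = out_g,
    _["deviance"] = out_dev,
    _["acceptance"] = NumericVector::create(
      _["s"] = rate(acc_s, tot_s), _["g"] = rate(acc_g, tot_g)));
}

// ------------------------------------------------------------- HO-DINA -----

// [[Rcpp::export]]
List cpp_chain_hodina(IntegerMatrix Y, IntegerMatrix Q,
                      double lambda_sd, double beta_sd,
                      double a_s, double b_s, double a_g, double b_g,
                      int n_iter, int n_burn, int n_thin,
                      int adapt_batch, double acc_lo, double acc_hi,
                      bool store_person) {
  int N = Y.nrow(), I = Y.ncol(), K = Q.ncol();
  adjacency attrs_of_item, items_of_attr;
  q_adjacency(Q, attrs_of_item, items_of_attr);
  RNGScope scope;

  std::vector<double> theta(N), lambda(K), beta(K);
  for (int n = 0; n < N; ++n) theta[n] = norm_rand();
  for (int k = 0; k < K; ++k) {
    do { lambda[k] = R::rnorm(0.0, lambda_sd); } while (lambda[k] <= 0.0);
    beta[k] = R::rnorm(0.0, beta_sd);
  }
  NumericMatrix dprob(N, K), alpha(N, K);
  for (int k = 0; k < K; ++k)
    for (int n = 0; n < N; ++n) {
      dprob(n, k) = logistic(lambda[k] * theta[n] - beta[k]);
      alpha(n, k) = (unif_rand() < dprob(n, k)) ? 1.0 : 0.0;
    }
  std::vector<double> s(I), g(I);
  init_item_params(s, g, a_s, b_s, a_g, b_g);
  NumericMatrix eta(N, I);
  for (int i = 0; i < I; ++i)
    for (int n = 0; n < N; ++n)
      eta(n, i) = w_item(alpha, attrs_of_item[i], n);

  double lambda_var = lambda_sd * lambda_sd, beta_var = beta_sd * beta_sd;
  std::vector<double> ls_t(N, std::log(0.8)),
                      ls_l(K, std::log(0.3)), ls_b(K, std::log(0.3)),
                      ls_s(I, std::log(0.05)), ls_g(I, std::log(0.05));
  std::vector<int> acc_t(N, 0), tot_t(N, 0), acc_l(K, 0), tot_l(K, 0),
                   acc_b(K, 0), tot_b(K, 0),
                   acc_s(I, 0), tot_s(I, 0), acc_g(I, 0), tot_g(I, 0);

  int n_keep = (n_iter - n_burn) / n_thin;
  NumericMatrix out_theta(n_keep, N), out_lambda(n_keep, K),
                out_beta(n_keep, K), out_s(n_keep, I), out_g(n_keep, I);
  NumericMatrix out_alpha(store_person ? n_keep : 0,
                          store_person ? N * K : 0);
  NumericVector out_dev(n_keep);
  int keep = 0, batch = 0;
  std::vector<double> dcol(N);

  for (int it = 1; it <= n_iter; ++it) {
    // attribute profiles: exact two-point conditionals given theta
    for (int k = 0; k < K; ++k)
      for (int n = 0; n < N; ++n) {
        double d = clampp(dprob(n, k));
        update_alpha_cell(Y, alpha, eta, attrs_of_item, items_of_attr[k],
                          s, g, n, k, std::log(d) - std::log1p(-d));
      }

    // theta given alpha: the items drop out; only the structural layer counts
    for (int n = 0; n < N; ++n) {
      double tp = theta[n] + std::exp(ls_t[n]) * norm_rand();
      double lr = -0.5 * (tp * tp - theta[n] * theta[n]);
      for (int k = 0; k < K; ++k) {
        double dn = logistic(lambda[k] * tp - beta[k]);
        lr += bern_ll((int) alpha(n, k), dn)
            - bern_ll((int) alpha(n, k), dprob(n, k));
      }
      ++tot_t[n];
      if (std::log(unif_rand()) < lr) {
        ++acc_t[n];
        theta[n] = tp;
        for (int k = 0; k < K; ++k)
          dprob(n, k) = logistic(lambda[k] * theta[n] - beta[k]);
      }
    }

    for (int what = 0; what < 2; ++what) {
      for (int k = 0; k < K; ++k) {
        double lp, bp, lr;
        if (what == 0) {
          lp = lambda[k] + std::exp(ls_l[k]) * norm_rand();
          ++tot_l[k];
          if (lp <= 0.0) continue;
          bp = beta[k];
          lr = -0.5 * (lp * lp - lambda[k] * lambda[k]) / lambda_var;
        } else {
          lp = lambda[k];
          bp = beta[k] + std::exp(ls_b[k]) * norm_rand();
          ++tot_b[k];
          lr = -0.5 * (bp * bp - beta[k] * beta[k]) / beta_var;
        }
        for (int n = 0; n < N; ++n) {
          double dn = logistic(lp * theta[n] - bp);
          dcol[n] = dn;
          lr += bern_ll((int) alpha(n, k), dn)
              - bern_ll((int) alpha(n, k), dprob(n, k));
        }
        if (std::log(unif_rand()) < lr) {
          if (what == 0) { lambda[k] = lp; ++acc_l[k]; }
          else { beta[k] = bp; ++acc_b[k]; }
          for (int n = 0; n < N; ++n) dprob(n, k) = dcol[n];
        }
      }
    }

    update_item_params(Y, eta, s, g, a_s, b_s, a_g, b_g,
                       ls_s, ls_g, acc_s, tot_s, acc_g, tot_g);

    if (it <= n_burn && it % adapt_batch == 0) {
      ++batch;
      adapt_scales(ls_t, acc_t, tot_t, batch, acc_lo, acc_hi);
      adapt_scales(ls_l, acc_l, tot_l, batch, acc_lo, acc_hi);
      adapt_scales(ls_b, acc_b, tot_b, batch, acc_lo, acc_hi);
      adapt_scales(ls_s, acc_s, tot_s, batch, acc_lo, acc_hi);
      adapt_scales(ls_g, acc_g, tot_g, batch, acc_lo, acc_hi);
    }

    if (it > n_burn && (it - n_burn) % n_thin == 0) {
      out_dev[keep] = total_deviance(Y, eta, s, g);
      for (int n = 0; n < N; ++n) out_theta(keep, n) = theta[n];
      for (int k = 0; k < K; ++k) {
        out_lambda(keep, k) = lambda[k];
        out_beta(keep, k) = beta[k];
      }
      for (int i = 0; i < I; ++i) { out_s(keep, i) = s[i]; out_g(keep, i) = g[i]; }
      if (store_person)
        for (int k = 0; k < K; ++k)
          for (int n = 0; n < N; ++n)
            out_alpha(keep, n + N * k) = alpha(n, k);
      ++keep;
    }
  }

  return List::create(
    _["theta"] = out_theta, _["lambda"] = out_lambda, _["beta"] = out_beta,
    _["alpha"] = out_alpha, _["s"] = out_s, _["g"] = out_g,
    _["deviance"] = out_dev,
    _["acceptance"] = NumericVector::create(
      _["theta"] = rate(acc_t, tot_t), _["lambda"] = rate(acc_l, tot_l),
      _["beta"] = rate(acc_b, tot_b), _["s"] = rate(acc_s, tot_s),
      _["g"] = rate(acc_g, tot_g)));
}
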