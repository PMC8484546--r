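// Metropolis-within-Gibbs core for the b2 dyadic network model.
//
// State: overall mean m, covariate coefficients beta, actor random effects
// A (one slot per actor per network), variance sigma2. The dyad linear
// predictors mu and their Bernoulli log-likelihood terms are cached and
// updated incrementally, so one sweep costs O(#dyads) for m/beta and
// O(sum of actor degrees) for the A updates.

#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// y*mu - log(1 + exp(mu)), stable for large |mu|
static inline double bll(double mu, double y) {
  if (mu > 0.0) return (y - 1.0) * mu - std::log1p(std::exp(-mu));
  return y * mu - std::log1p(std::exp(mu));
}

static inline double normal_lp_delta(double cur, double prop,
                                     double mean, double var) {
  if (!R_finite(var)) return 0.0;  // flat prior
  double dc = cur - mean, dp = prop - mean;
  return (dc * dc - dp * dp) / (2.0 * var);
}

// [[Rcpp::export]]
List b2_sampler(NumericVector y, NumericMatrix X,
                IntegerVector si, IntegerVector sj, List slot_dyads,
                double m_init, NumericVector beta_init, double sigma2_init,
                double m_mean, double m_var,
                double beta_mean, double beta_var,
                double nu0, double s02,
                bool fix_sigma2, bool re_active,
                int n_iter, int burn_in, int thin,
                double target_accept, bool save_A) {
  const int D = y.size();
  const int p = X.ncol();
  const int N = slot_dyads.size();

  // incident dyads per actor slot, flattened
  std::vector<std::vector<int>> inc(N);
  for (int a = 0; a < N; ++a) inc[a] = as<std::vector<int>>(slot_dyads[a]);

  double m = m_init;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> A(N, 0.0);
  double sigma2 = sigma2_init;

  std::vector<double> mu(D), cur_ll(D);
  for (int d = 0; d < D; ++d) {
    double v = m;
    for (int r = 0; r < p; ++r) v += X(d, r) * beta[r];
    v += A[si[d]] + A[sj[d]];
    mu[d] = v;
    cur_ll[d] = bll(v, y[d]);
  }

  // adaptive proposal scales (log scale), frozen after burn-in
  double ls_m = std::log(0.1);
  std::vector<double> ls_beta(p, std::log(0.1));
  std::vector<double> ls_A(N, std::log(0.5));
  double ls_c = std::log(0.2);
  const int batch = 50;
  int batch_no = 0;
  int acc_m_b = 0, acc_c_b = 0;
  std::vector<int> acc_beta_b(p, 0), acc_A_b(N, 0);
  long acc_m = 0, acc_c = 0, try_post = 0;
  std::vector<long> acc_beta(p, 0), acc_A(N, 0);

  const int n_keep = (n_iter - burn_in) / thin;
  const int n_par = 1 + p + 1 + (save_A ? N : 0);
  NumericMatrix draws(n_keep, n_par);
  std::vector<double> A_sum(N, 0.0);
  int kept = 0;

  std::vector<double> prop_ll(D);

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= burn_in;
    if (!adapting) ++try_post;

    // --- m: random-walk over all dyads
    {
      double eps = R::rnorm(0.0, std::exp(ls_m));
      double dll = 0.0;
      for (int d = 0; d < D; ++d) {
        prop_ll[d] = bll(mu[d] + eps, y[d]);
        dll += prop_ll[d] - cur_ll[d];
      }
      dll += normal_lp_delta(m, m + eps, m_mean, m_var);
      if (std::log(R::unif_rand()) < dll) {
        m += eps;
        for (int d = 0; d < D; ++d) { mu[d] += eps; cur_ll[d] = prop_ll[d]; }
        if (adapting) ++acc_m_b; else ++acc_m;
      }
    }

    // --- beta_r: random-walk, only dyads with nonzero covariate change
    for (int r = 0; r < p; ++r) {
      double eps = R::rnorm(0.0, std::exp(ls_beta[r]));
      double dll = 0.0;
      for (int d = 0; d < D; ++d) {
        double x = X(d, r);
        if (x != 0.0) {
          prop_ll[d] = bll(mu[d] + eps * x, y[d]);
          dll += prop_ll[d] - cur_ll[d];
        }
      }
      dll += normal_lp_delta(beta[r], beta[r] + eps, beta_mean, beta_var);
      if (std::log(R::unif_rand()) < dll) {
        beta[r] += eps;
        for (int d = 0; d < D; ++d) {
          double x = X(d, r);
          if (x != 0.0) { mu[d] += eps * x; cur_ll[d] = prop_ll[d]; }
        }
        if (adapting) ++acc_beta_b[r]; else ++acc_beta[r];
      }
    }

    if (re_active) {
      // --- actor effects: random-walk over incident dyads
      for (int a = 0; a < N; ++a) {
        double eps = R::rnorm(0.0, std::exp(ls_A[a]));
        double Anew = A[a] + eps;
        double dll = (A[a] * A[a] - Anew * Anew) / (2.0 * sigma2);
        const std::vector<int>& ds = inc[a];
        for (size_t q = 0; q < ds.size(); ++q) {
          int d = ds[q];
          prop_ll[d] = bll(mu[d] + eps, y[d]);
          dll += prop_ll[d] - cur_ll[d];
        }
        if (std::log(R::unif_rand()) < dll) {
          A[a] = Anew;
          for (size_t q = 0; q < ds.size(); ++q) {
            int d = ds[q];
            mu[d] += eps; cur_ll[d] = prop_ll[d];
          }
          if (adapting) ++acc_A_b[a]; else ++acc_A[a];
        }
      }

      // --- translation move: A -> A - c, m -> m + 2c leaves mu unchanged;
      //     accepted on the prior ratio alone
      {
        double c = R::rnorm(0.0, std::exp(ls_c));
        double sumA = 0.0;
        for (int a = 0; a < N; ++a) sumA += A[a];
        double dlp = -(N * c * c - 2.0 * c * sumA) / (2.0 * sigma2);
        dlp += normal_lp_delta(m, m + 2.0 * c, m_mean, m_var);
        if (std::log(R::unif_rand()) < dlp) {
          for (int a = 0; a < N; ++a) A[a] -= c;
          m += 2.0 * c;
          if (adapting) ++acc_c_b; else ++acc_c;
        }
      }

      // --- sigma2: conjugate scaled inverse-chi^2 Gibbs draw
      if (!fix_sigma2) {
        double ssq = 0.0;
        for (int a = 0; a < N; ++a) ssq += A[a] * A[a];
        sigma2 = (nu0 * s02 + ssq) / R::rchisq(nu0 + N);
      }
    }

    // --- adaptation (burn-in only)
    if (adapting && it % batch == 0) {
      ++batch_no;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
      ls_m += (acc_m_b > target_accept * batch) ? delta : -delta;
      acc_m_b = 0;
      for (int r = 0; r < p; ++r) {
        ls_beta[r] += (acc_beta_b[r] > target_accept * batch) ? delta : -delta;
        acc_beta_b[r] = 0;
      }
      if (re_active) {
        for (int a = 0; a < N; ++a) {
          ls_A[a] += (acc_A_b[a] > target_accept * batch) ? delta : -delta;
          acc_A_b[a] = 0;
        }
        ls_c += (acc_c_b > target_accept * batch) ? delta : -delta;
        acc_c_b = 0;
      }
    }

    // --- record
    if (it > burn_in && (it - burn_in) % thin == 0) {
      draws(kept, 0) = m;
      for (int r = 0; r < p; ++r) draws(kept, 1 + r) = beta[r];
      draws(kept, 1 + p) = sigma2;
      if (save_A) for (int a = 0; a < N; ++a) draws(kept, 2 + p + a) = A[a];
      for (int a = 0; a < N; ++a) A_sum[a] += A[a];
      ++kept;
    }
  }

  NumericVector A_mean(N);
  if (n_keep > 0) for (int a = 0; a < N; ++a) A_mean[a] = A_sum[a] / n_keep;

  double mean_acc_A = 0.0;
  if (re_active && N > 0 && try_post > 0) {
    for (int a = 0; a < N; ++a) mean_acc_A += (double)acc_A[a];
    mean_acc_A /= (double)N * try_post;
  }
  NumericVector acc_out = NumericVector::create(
    _["m"] = try_post > 0 ? (double)acc_m / try_post : NA_REAL,
    _["beta"] = (p > 0 && try_post > 0)
      ? (double)std::accumulate(acc_beta.begin(), acc_beta.end(), 0L) /
        (p * (double)try_post) : NA_REAL,
    _["A"] = re_active ? mean_acc_A : NA_REAL,
    _["translation"] = (re_active && try_post > 0)
      ? (double)acc_c / try_post : NA_REAL);

  return List::create(_["draws"] = draws, _["accept"] = acc_out,
                      _["A_mean"] = A_mean);
}
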