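#include <Rcpp.h>
using namespace Rcpp;

// Binomial-logit NMA sampler: adaptive random-walk Metropolis within Gibbs.
// Blocks: each study baseline mu_i, each basic (or per-comparison) parameter d,
// each trial-specific effect delta_ik (random effects), the heterogeneity sd
// sigma. Step sizes adapt toward ~0.44 acceptance during burn-in only and are
// frozen afterwards so the retained kernel is fixed.

// log Binomial(r | n, expit(theta)) kernel; the combinatorial term is constant
// per data point and cancels in Metropolis ratios, so it is omitted here. The
// R-level log_likelihood() adds it via the log-Gamma continuous extension.
static inline double log_binom_kernel(double r, double n, double theta) {
  double lp, lq; // log p, log(1-p), numerically stable in both tails
  if (theta > 0.0) {
    lq = -theta - log1p(std::exp(-theta));
    lp = -log1p(std::exp(-theta));
  } else {
    lp = theta - log1p(std::exp(theta));
    lq = -log1p(std::exp(theta));
  }
  double ll = r * lp + (n - r) * lq;
  if (!R_finite(ll)) ll = -1e10; // guard boundary states, keep posterior finite
  return ll;
}

struct Model {
  IntegerMatrix t;     // ns x maxa treatment index per arm (1-based), 0 = absent
  NumericMatrix r, n;  // events, sizes
  IntegerVector na;    // arms per study
  int ns, nt, nd;
  bool random, ume;
  IntegerMatrix cmap;  // ume: 1-based comparison-parameter index per non-baseline arm
  double mu_sd, d_sd;
  int het_type;        // 0 uniform on sigma, 1 lognormal on sigma^2
  double het_p1, het_p2;

  NumericVector mu, d;
  NumericMatrix delta; // trial-specific log odds ratios, col 0 unused (baseline)
  double sigma;

  // basic mean for arm k (0-based) of study i: d[t_ik] - d[t_i1] under
  // consistency (d of reference treatment = 0), independent parameter under UME
  double basic_mean(int i, int k) const {
    if (k == 0) return 0.0;
    if (ume) return d[cmap(i, k) - 1];
    int ti = t(i, k), tb = t(i, 0);
    double m = 0.0;
    if (ti > 1) m += d[ti - 2];
    if (tb > 1) m -= d[tb - 2];
    return m;
  }

  double theta_arm(int i, int k) const {
    double off = 0.0;
    if (k > 0) off = random ? delta(i, k) : basic_mean(i, k);
    return mu[i] + off;
  }

  double loglik_arm(int i, int k) const {
    return log_binom_kernel(r(i, k), n(i, k), theta_arm(i, k));
  }

  double loglik_study(int i) const {
    double s = 0.0;
    for (int k = 0; k < na[i]; ++k) s += loglik_arm(i, k);
    return s;
  }

  double loglik_total() const {
    double s = 0.0;
    for (int i = 0; i < ns; ++i) s += loglik_study(i);
    return s;
  }

  // joint log prior of a study's delta vector via the sequential conditional
  // decomposition of the exchangeable multivariate normal (var sigma^2,
  // pairwise cov sigma^2/2); UME deltas are independent N(mean, sigma^2)
  double logprior_delta_study(int i) const {
    if (!random) return 0.0;
    double s = 0.0, cum = 0.0;
    for (int k = 1; k < na[i]; ++k) {
      double m = basic_mean(i, k), v;
      if (ume) {
        v = sigma * sigma;
      } else {
        m += cum / k;                               // (1/(p-1)) sum of deviations
        v = sigma * sigma * (k + 1) / (2.0 * k);    // p/(2(p-1)) with p = k+1
      }
      s += R::dnorm(delta(i, k), m, std::sqrt(v), 1);
      if (!ume) cum += delta(i, k) - basic_mean(i, k);
    }
    return s;
  }

  double logprior_delta_total() const {
    double s = 0.0;
    for (int i = 0; i < ns; ++i) s += logprior_delta_study(i);
    return s;
  }

  double logprior_sigma(double sg) const {
    if (sg <= 0.0) return R_NegInf;
    if (het_type == 0) {
      return (sg <= het_p1) ? -std::log(het_p1) : R_NegInf;
    }
    // lognormal on the variance sigma^2, change of variables to sigma
    double v = sg * sg;
    return R::dlnorm(v, het_p1, het_p2, 1) + std::log(2.0 * sg);
  }
};

// [[Rcpp::export]]
List nma_chain_cpp(IntegerMatrix t, NumericMatrix r, NumericMatrix n,
                   IntegerVector na, int nt, bool random, bool ume,
                   IntegerMatrix cmap, int nd,
                   double mu_sd, double d_sd,
                   int het_type, double het_p1, double het_p2,
                   NumericVector mu0, NumericVector d0, double sigma0,
                   int n_burnin, int n_sample, int thin) {
  Model M;
  M.t = t; M.r = r; M.n = n; M.na = na;
  M.ns = t.nrow(); M.nt = nt; M.nd = nd;
  M.random = random; M.ume = ume; M.cmap = cmap;
  M.mu_sd = mu_sd; M.d_sd = d_sd;
  M.het_type = het_type; M.het_p1 = het_p1; M.het_p2 = het_p2;
  M.mu = clone(mu0); M.d = clone(d0); M.sigma = sigma0;
  int maxa = t.ncol();
  M.delta = NumericMatrix(M.ns, maxa);
  if (random)
    for (int i = 0; i < M.ns; ++i)
      for (int k = 1; k < na[i]; ++k) M.delta(i, k) = M.basic_mean(i, k);

  // scalar update blocks: mu (ns), d (nd), delta (flattened), sigma
  int ndelta = 0;
  std::vector<int> di, dk;
  if (random)
    for (int i = 0; i < M.ns; ++i)
      for (int k = 1; k < na[i]; ++k) { di.push_back(i); dk.push_back(k); ++ndelta; }
  int npar = M.ns + nd + ndelta + (random ? 1 : 0);
  std::vector<double> lstep(npar, std::log(0.5));
  std::vector<int> acc_win(npar, 0), acc_tot(npar, 0);
  std::vector<int> prop_win(npar, 0), prop_tot(npar, 0);

  int nobs = 0;
  for (int i = 0; i < M.ns; ++i) nobs += na[i];
  int n_ret = n_sample / thin;
  int ncol_out = M.ns + nd + (random ? 1 : 0) + nobs;
  NumericMatrix out(n_ret, ncol_out);

  int total_iter = n_burnin + n_sample, win = 0, row = 0;
  for (int it = 0; it < total_iter; ++it) {
    bool adapting = it < n_burnin;
    int b = 0;

    // mu blocks: likelihood of own study + normal prior
    for (int i = 0; i < M.ns; ++i, ++b) {
      double cur = M.mu[i];
      double l0 = M.loglik_study(i) + R::dnorm(cur, 0.0, mu_sd, 1);
      double prop = cur + std::exp(lstep[b]) * norm_rand();
      ++prop_win[b]; if (!adapting) ++prop_tot[b];
      M.mu[i] = prop;
      double l1 = M.loglik_study(i) + R::dnorm(prop, 0.0, mu_sd, 1);
      if (std::log(unif_rand()) < l1 - l0) { ++acc_win[b]; if (!adapting) ++acc_tot[b]; }
      else M.mu[i] = cur;
    }

    // d blocks: under FE they enter the likelihood; under RE only the delta prior
    for (int j = 0; j < nd; ++j, ++b) {
      double cur = M.d[j];
      double l0 = (random ? M.logprior_delta_total() : M.loglik_total()) +
                  R::dnorm(cur, 0.0, d_sd, 1);
      double prop = cur + std::exp(lstep[b]) * norm_rand();
      ++prop_win[b]; if (!adapting) ++prop_tot[b];
      M.d[j] = prop;
      double l1 = (random ? M.logprior_delta_total() : M.loglik_total()) +
                  R::dnorm(prop, 0.0, d_sd, 1);
      if (std::log(unif_rand()) < l1 - l0) { ++acc_win[b]; if (!adapting) ++acc_tot[b]; }
      else M.d[j] = cur;
    }

    if (random) {
      // delta blocks: own-arm likelihood + joint study delta prior
      for (int q = 0; q < ndelta; ++q, ++b) {
        int i = di[q], k = dk[q];
        double cur = M.delta(i, k);
        double l0 = M.loglik_arm(i, k) + M.logprior_delta_study(i);
        double prop = cur + std::exp(lstep[b]) * norm_rand();
        ++prop_win[b]; if (!adapting) ++prop_tot[b];
        M.delta(i, k) = prop;
        double l1 = M.loglik_arm(i, k) + M.logprior_delta_study(i);
        if (std::log(unif_rand()) < l1 - l0) { ++acc_win[b]; if (!adapting) ++acc_tot[b]; }
        else M.delta(i, k) = cur;
      }
      // sigma block, proposed several times per sweep: the heterogeneity sd
      // couples to every delta, so extra proposals cut its autocorrelation
      // at negligible cost
      for (int rep = 0; rep < 5; ++rep) {
        double cur = M.sigma;
        double p0 = M.logprior_sigma(cur);
        double l0 = M.logprior_delta_total() + p0;
        double prop = cur + std::exp(lstep[b]) * norm_rand();
        double p1 = M.logprior_sigma(prop);
        ++prop_win[b]; if (!adapting) ++prop_tot[b];
        if (R_finite(p1)) {
          M.sigma = prop;
          double l1 = M.logprior_delta_total() + p1;
          if (std::log(unif_rand()) < l1 - l0) { ++acc_win[b]; if (!adapting) ++acc_tot[b]; }
          else M.sigma = cur;
        }
      }
      ++b;
    }

    // Robbins-Monro style step adaptation toward 0.44, burn-in only
    if (adapting && ((it + 1) % 50 == 0)) {
      ++win;
      double gain = std::min(0.1, 1.0 / std::sqrt((double)win));
      for (int p = 0; p < npar; ++p) {
        double rate = prop_win[p] > 0 ? acc_win[p] / (double)prop_win[p] : 0.44;
        lstep[p] += (rate > 0.44 ? gain : -gain);
        acc_win[p] = 0; prop_win[p] = 0;
      }
    }
    if (it == n_burnin - 1)
      for (int p = 0; p < npar; ++p) { acc_win[p] = 0; prop_win[p] = 0; }

    if (!adapting && ((it - n_burnin + 1) % thin == 0)) {
      int c = 0;
      for (int i = 0; i < M.ns; ++i) out(row, c++) = M.mu[i];
      for (int j = 0; j < nd; ++j) out(row, c++) = M.d[j];
      if (random) out(row, c++) = M.sigma;
      for (int i = 0; i < M.ns; ++i)
        for (int k = 0; k < na[i]; ++k)
          out(row, c++) = 1.0 / (1.0 + std::exp(-M.theta_arm(i, k)));
      ++row;
    }
  }

  NumericVector acc(npar), steps(npar);
  for (int p = 0; p < npar; ++p) {
    acc[p] = prop_tot[p] > 0 ? acc_tot[p] / (double)prop_tot[p] : NA_REAL;
    steps[p] = std::exp(lstep[p]);
  }
  return List::create(_["draws"] = out, _["accept"] = acc, _["steps"] = steps,
                      _["n_delta"] = ndelta);
}
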