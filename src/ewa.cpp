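#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Forward EWA likelihood
//
// params: J x 9 natural-scale matrix, columns
//   0 lambda, 1 phi, 2 gamma, 3 fc, 4..8 beta pay/rank/kin/fem/sex
// Cue matrices are E x K; undefined cue means are stored as 0 and only
// multiply into techniques with n = 0, whose social weight is 0 anyway.
// ---------------------------------------------------------------------------

struct EwaData {
  IntegerVector actor;   // 1-based individual index, length E
  IntegerVector tech;    // 1-based technique index, length E
  NumericVector payoff;  // 0/1
  NumericMatrix N, pay, rank, kin, fem, sex;
  bool use_social;
  int E, K, J;
};

// log-probability of the observed technique at one event, given the actor's
// current attraction row; updates nothing
static inline double event_logprob(const EwaData &d, int e,
                                   const double *A_row,
                                   const double *p_row,
                                   double *I, double *logw) {
  const int K = d.K;
  const double lambda = p_row[0], gamma = p_row[2], fc = p_row[3];
  double zmax = -INFINITY;
  for (int k = 0; k < K; ++k) {
    I[k] = lambda * A_row[k];
    if (I[k] > zmax) zmax = I[k];
  }
  double s = 0.0;
  for (int k = 0; k < K; ++k) { I[k] = std::exp(I[k] - zmax); s += I[k]; }
  for (int k = 0; k < K; ++k) I[k] /= s;

  const int kc = d.tech[e] - 1;
  double p = I[kc];
  if (d.use_social) {
    bool any = false;
    double wmax = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double n = d.N(e, k);
      if (n > 0) {
        double B = p_row[4] * d.pay(e, k) + p_row[5] * d.rank(e, k) +
                   p_row[6] * d.kin(e, k) + p_row[7] * d.fem(e, k) +
                   p_row[8] * d.sex(e, k);
        logw[k] = fc * std::log(n) + B;
        if (logw[k] > wmax) wmax = logw[k];
        any = true;
      } else {
        logw[k] = -INFINITY;
      }
    }
    if (any) {
      double ws = 0.0;
      for (int k = 0; k < K; ++k) {
        logw[k] = (logw[k] == -INFINITY) ? 0.0 : std::exp(logw[k] - wmax);
        ws += logw[k];
      }
      double S = logw[kc] / ws;
      p = (1.0 - gamma) * I[kc] + gamma * S;
    }
  }
  return std::log(p);
}

// pointwise log-likelihood over all events; A is a J x K workspace reset to 0
static void pointwise_ll(const EwaData &d, const NumericMatrix &params,
                         std::vector<double> &A, double *out,
                         NumericMatrix *probs) {
  const int K = d.K;
  std::fill(A.begin(), A.end(), 0.0);
  std::vector<double> I(K), logw(K);
  for (int e = 0; e < d.E; ++e) {
    int j = d.actor[e] - 1;
    double *A_row = &A[(size_t)j * K];
    const double p_row[9] = {params(j, 0), params(j, 1), params(j, 2),
                             params(j, 3), params(j, 4), params(j, 5),
                             params(j, 6), params(j, 7), params(j, 8)};
    out[e] = event_logprob(d, e, A_row, p_row, I.data(), logw.data());
    if (probs) {
      // recompute the full probability vector for reporting
      double gamma = p_row[2];
      bool any = false;
      if (d.use_social)
        for (int k = 0; k < K; ++k) if (d.N(e, k) > 0) { any = true; break; }
      double zmax = -INFINITY;
      std::vector<double> Iv(K), wv(K);
      for (int k = 0; k < K; ++k) {
        Iv[k] = p_row[0] * A_row[k];
        if (Iv[k] > zmax) zmax = Iv[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) { Iv[k] = std::exp(Iv[k] - zmax); s += Iv[k]; }
      for (int k = 0; k < K; ++k) Iv[k] /= s;
      if (any) {
        double wmax = -INFINITY;
        for (int k = 0; k < K; ++k) {
          double n = d.N(e, k);
          if (n > 0) {
            double B = p_row[4] * d.pay(e, k) + p_row[5] * d.rank(e, k) +
                       p_row[6] * d.kin(e, k) + p_row[7] * d.fem(e, k) +
                       p_row[8] * d.sex(e, k);
            wv[k] = p_row[3] * std::log(n) + B;
            if (wv[k] > wmax) wmax = wv[k];
          } else wv[k] = -INFINITY;
        }
        double ws = 0.0;
        for (int k = 0; k < K; ++k) {
          wv[k] = (wv[k] == -INFINITY) ? 0.0 : std::exp(wv[k] - wmax);
          ws += wv[k];
        }
        for (int k = 0; k < K; ++k)
          (*probs)(e, k) = (1.0 - gamma) * Iv[k] + gamma * wv[k] / ws;
      } else {
        for (int k = 0; k < K; ++k) (*probs)(e, k) = Iv[k];
      }
    }
    int kc = d.tech[e] - 1;
    A_row[kc] = (1.0 - params(j, 1)) * A_row[kc] + params(j, 1) * d.payoff[e];
  }
}

// log-likelihood restricted to one individual's events (its attractions are
// self-contained); ev_idx holds that individual's event indices in order
static double individual_ll(const EwaData &d, const double *p_row,
                            const std::vector<int> &ev_idx,
                            std::vector<double> &A_row,
                            std::vector<double> &I, std::vector<double> &logw) {
  std::fill(A_row.begin(), A_row.end(), 0.0);
  double ll = 0.0;
  for (int e : ev_idx) {
    ll += event_logprob(d, e, A_row.data(), p_row, I.data(), logw.data());
    int kc = d.tech[e] - 1;
    A_row[kc] = (1.0 - p_row[1]) * A_row[kc] + p_row[1] * d.payoff[e];
  }
  return ll;
}

static EwaData make_data(IntegerVector actor, IntegerVector tech,
                         NumericVector payoff, NumericMatrix N,
                         NumericMatrix pay, NumericMatrix rank,
                         NumericMatrix kin, NumericMatrix fem,
                         NumericMatrix sex, bool use_social, int J) {
  EwaData d{actor, tech, payoff, N, pay, rank, kin, fem, sex, use_social,
            (int)actor.size(), N.ncol(), J};
  return d;
}

// [[Rcpp::export]]
List ewa_loglik_cpp(IntegerVector actor, IntegerVector tech,
                    NumericVector payoff, NumericMatrix N, NumericMatrix pay,
                    NumericMatrix rank, NumericMatrix kin, NumericMatrix fem,
                    NumericMatrix sex, NumericMatrix params, bool use_social,
                    bool return_probs) {
  EwaData d = make_data(actor, tech, payoff, N, pay, rank, kin, fem, sex,
                        use_social, params.nrow());
  std::vector<double> A((size_t)d.J * d.K);
  NumericVector ll(d.E);
  NumericMatrix probs;
  if (return_probs) probs = NumericMatrix(d.E, d.K);
  pointwise_ll(d, params, A, REAL(ll), return_probs ? &probs : nullptr);
  NumericVector prob(d.E);
  for (int e = 0; e < d.E; ++e) prob[e] = std::exp(ll[e]);
  List out = List::create(_["loglik"] = ll, _["prob"] = prob);
  if (return_probs) out["probs"] = probs;
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical sampler: adaptive Metropolis-within-Gibbs on a non-centred
// parameterisation.  Hyper vector layout (p hierarchical slots,
// q = p(p-1)/2, J individuals, G groups):
//   mu[p] | b_juv[p] | b_male[p] | log sigma_ind[p] | y_ind[q] |
//   log sigma_grp[p] | y_grp[q] | Z_ind[p*J] | Z_grp[p*G]
// Correlation Cholesky factors are built from unconstrained y via the
// tanh / partial-correlation transform with an LKJ prior.
// ---------------------------------------------------------------------------

struct Hier {
  int p, q, J, G, n;
  std::vector<int> slot;      // 0-based natural-param slot per hier param
  std::vector<int> link;      // 0 identity, 1 log, 2 logit
  IntegerVector juv, male, grp; // per individual (grp 1-based)
  double mean_sd, offset_sd, sigma_rate, lkj_eta;
  int i_mu, i_bj, i_bm, i_lsi, i_yi, i_lsg, i_yg, i_zi, i_zg;
};

static inline double invlink(double x, int link) {
  if (link == 1) return std::exp(x);
  if (link == 2) return 1.0 / (1.0 + std::exp(-x));
  return x;
}

// y (length q) -> lower Cholesky L (p x p); returns log prior (LKJ) +
// log |Jacobian| of the transform
static double build_chol(int p, const double *y, std::vector<double> &L,
                         double eta) {
  std::fill(L.begin(), L.end(), 0.0);
  double logj = 0.0, logprior = 0.0;
  L[0] = 1.0;
  int c = 0;
  for (int i = 1; i < p; ++i) {
    double sumsq = 0.0;
    for (int j = 0; j < i; ++j) {
      double z = std::tanh(y[c]);
      double scale = std::sqrt(1.0 - sumsq);
      L[(size_t)i * p + j] = z * scale;
      logj += std::log1p(-z * z) + 0.5 * std::log(1.0 - sumsq);
      sumsq += L[(size_t)i * p + j] * L[(size_t)i * p + j];
      ++c;
    }
    double Lii = std::sqrt(std::max(1.0 - sumsq, 1e-300));
    L[(size_t)i * p + i] = Lii;
    logprior += (p - (i + 1) + 2.0 * eta - 2.0) * std::log(Lii);
  }
  return logprior + logj;
}

// natural-scale J x 9 parameter matrix from the hyper vector
static void assemble(const Hier &h, const double *th, NumericMatrix &P) {
  const int p = h.p;
  std::vector<double> Li((size_t)p * p), Lg((size_t)p * p);
  build_chol(p, th + h.i_yi, Li, h.lkj_eta);
  build_chol(p, th + h.i_yg, Lg, h.lkj_eta);
  std::vector<double> si(p), sg(p);
  for (int r = 0; r < p; ++r) {
    si[r] = std::exp(th[h.i_lsi + r]);
    sg[r] = std::exp(th[h.i_lsg + r]);
  }
  // group effects: sg * Lg * z_g
  std::vector<double> ug((size_t)p * h.G);
  for (int g = 0; g < h.G; ++g)
    for (int r = 0; r < p; ++r) {
      double v = 0.0;
      for (int c = 0; c <= r; ++c)
        v += Lg[(size_t)r * p + c] * th[h.i_zg + (size_t)g * p + c];
      ug[(size_t)g * p + r] = sg[r] * v;
    }
  for (int j = 0; j < h.J; ++j) {
    // defaults: lambda 1, phi 0, gamma 0, fc 1, betas 0
    P(j, 0) = 1.0; P(j, 1) = 0.0; P(j, 2) = 0.0; P(j, 3) = 1.0;
    for (int k = 4; k < 9; ++k) P(j, k) = 0.0;
    int g = h.grp[j] - 1;
    for (int r = 0; r < p; ++r) {
      double v = 0.0;
      for (int c = 0; c <= r; ++c)
        v += Li[(size_t)r * p + c] * th[h.i_zi + (size_t)j * p + c];
      double eta = th[h.i_mu + r] + th[h.i_bj + r] * h.juv[j] +
                   th[h.i_bm + r] * h.male[j] + si[r] * v +
                   ug[(size_t)g * p + r];
      P(j, h.slot[r]) = invlink(eta, h.link[r]);
    }
  }
}

// full log prior of the hyper vector
static double log_prior(const Hier &h, const double *th) {
  double lp = 0.0;
  const int p = h.p;
  for (int r = 0; r < p; ++r) {
    double m = th[h.i_mu + r] / h.mean_sd;
    double a = th[h.i_bj + r] / h.offset_sd;
    double b = th[h.i_bm + r] / h.offset_sd;
    lp += -0.5 * (m * m + a * a + b * b);
    // exponential prior on sigma with log-scale Jacobian
    lp += -h.sigma_rate * std::exp(th[h.i_lsi + r]) + th[h.i_lsi + r];
    lp += -h.sigma_rate * std::exp(th[h.i_lsg + r]) + th[h.i_lsg + r];
  }
  std::vector<double> L((size_t)p * p);
  lp += build_chol(p, th + h.i_yi, L, h.lkj_eta);
  lp += build_chol(p, th + h.i_yg, L, h.lkj_eta);
  for (int j = 0; j < h.J * p; ++j) {
    double z = th[h.i_zi + j];
    lp += -0.5 * z * z;
  }
  for (int g = 0; g < h.G * p; ++g) {
    double z = th[h.i_zg + g];
    lp += -0.5 * z * z;
  }
  return lp;
}

struct Adapt {
  double ls;          // log proposal scale
  double target;
  long n_prop = 0, n_acc = 0;
  void tune(bool acc, int t) {
    double gain = std::pow((double)t + 1.0, -0.6);
    ls += gain * ((acc ? 1.0 : 0.0) - target);
  }
};

// [[Rcpp::export]]
List ewa_mcmc_cpp(IntegerVector actor, IntegerVector tech,
                  NumericVector payoff, NumericMatrix N, NumericMatrix pay,
                  NumericMatrix rank, NumericMatrix kin, NumericMatrix fem,
                  NumericMatrix sex, bool use_social,
                  IntegerVector juv, IntegerVector male, IntegerVector grp,
                  IntegerVector slot1, IntegerVector link_code,
                  double mean_sd, double offset_sd, double sigma_rate,
                  double lkj_eta,
                  NumericVector init, int n_warmup, int n_iter) {
  const int J = juv.size();
  const int G = Rcpp::max(grp);
  EwaData d = make_data(actor, tech, payoff, N, pay, rank, kin, fem, sex,
                        use_social, J);
  Hier h;
  h.p = slot1.size();
  h.q = h.p * (h.p - 1) / 2;
  h.J = J; h.G = G;
  h.slot.resize(h.p); h.link.resize(h.p);
  for (int r = 0; r < h.p; ++r) {
    h.slot[r] = slot1[r] - 1;
    h.link[r] = link_code[r];
  }
  h.juv = juv; h.male = male; h.grp = grp;
  h.mean_sd = mean_sd; h.offset_sd = offset_sd;
  h.sigma_rate = sigma_rate; h.lkj_eta = lkj_eta;
  const int p = h.p, q = h.q;
  h.i_mu = 0; h.i_bj = p; h.i_bm = 2 * p; h.i_lsi = 3 * p; h.i_yi = 4 * p;
  h.i_lsg = 4 * p + q; h.i_yg = 5 * p + q; h.i_zi = 5 * p + 2 * q;
  h.i_zg = 5 * p + 2 * q + p * J;
  h.n = h.i_zg + p * G;
  if ((int)init.size() != h.n) stop("init vector has wrong length");
  // with a single group the group level is confounded with the population
  // mean; its effects are frozen at zero (no updates, z = 0)
  const bool use_group = G > 1;

  std::vector<double> th(init.begin(), init.end());
  NumericMatrix P(J, 9), Pprop(J, 9);
  std::vector<double> A((size_t)J * d.K);
  std::vector<double> ll_ind(J, 0.0), ll_ind_prop(J);
  std::vector<double> Arow(d.K), Iws(d.K), Wws(d.K);

  // per-individual event index lists
  std::vector<std::vector<int>> ev_of(J);
  for (int e = 0; e < d.E; ++e) ev_of[actor[e] - 1].push_back(e);

  auto full_ll = [&](const NumericMatrix &Pm, std::vector<double> &out) {
    double tot = 0.0;
    for (int j = 0; j < J; ++j) {
      const double p_row[9] = {Pm(j, 0), Pm(j, 1), Pm(j, 2), Pm(j, 3),
                               Pm(j, 4), Pm(j, 5), Pm(j, 6), Pm(j, 7),
                               Pm(j, 8)};
      out[j] = individual_ll(d, p_row, ev_of[j], Arow, Iws, Wws);
      tot += out[j];
    }
    return tot;
  };

  assemble(h, th.data(), P);
  double cur_ll = full_ll(P, ll_ind);
  double cur_lp = log_prior(h, th.data());
  if (!std::isfinite(cur_ll + cur_lp)) stop("non-finite initial posterior");

  // adaptation state: one scale per scalar family member / block
  std::vector<Adapt> ad_sc(5 * p + 2 * q); // mu, bj, bm, lsi, lsg + yi,yg blocks handled below
  for (auto &a : ad_sc) { a.ls = std::log(0.2); a.target = 0.44; }
  Adapt ad_yi{std::log(0.1), 0.25}, ad_yg{std::log(0.1), 0.25};
  std::vector<Adapt> ad_zi(J), ad_zg(G);
  for (auto &a : ad_zi) { a.ls = std::log(0.3); a.target = 0.25; }
  for (auto &a : ad_zg) { a.ls = std::log(0.3); a.target = 0.25; }
  std::vector<Adapt> ad_shift_i(p), ad_shift_g(p), ad_scale_i(p), ad_scale_g(p);
  for (auto *v : {&ad_shift_i, &ad_shift_g, &ad_scale_i, &ad_scale_g})
    for (auto &a : *v) { a.ls = std::log(0.3); a.target = 0.44; }

  NumericMatrix draws(n_iter, h.n);
  NumericMatrix pw(n_iter, d.E);

  // generic global proposal over a set of indices; recomputes the full
  // likelihood (hierarchy-level parameters touch every individual)
  auto try_global = [&](const std::vector<int> &idx, double scale,
                        Adapt &a, int t, bool warm) {
    std::vector<double> old(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) {
      old[i] = th[idx[i]];
      th[idx[i]] += scale * norm_rand();
    }
    double lp_new = log_prior(h, th.data());
    bool acc = false;
    if (std::isfinite(lp_new)) {
      assemble(h, th.data(), Pprop);
      double ll_new = full_ll(Pprop, ll_ind_prop);
      double lr = (ll_new + lp_new) - (cur_ll + cur_lp);
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        acc = true;
        cur_ll = ll_new; cur_lp = lp_new;
        std::copy(ll_ind_prop.begin(), ll_ind_prop.end(), ll_ind.begin());
        for (int j = 0; j < J; ++j)
          for (int k = 0; k < 9; ++k) P(j, k) = Pprop(j, k);
      }
    }
    if (!acc) for (size_t i = 0; i < idx.size(); ++i) th[idx[i]] = old[i];
    a.n_prop++; if (acc) a.n_acc++;
    if (warm) a.tune(acc, t);
  };

  for (int t = 0; t < n_warmup + n_iter; ++t) {
    bool warm = t < n_warmup;
    // scalar hierarchy parameters
    for (int fam = 0; fam < (use_group ? 5 : 4); ++fam) {
      int base = (fam == 0) ? h.i_mu : (fam == 1) ? h.i_bj
               : (fam == 2) ? h.i_bm : (fam == 3) ? h.i_lsi : h.i_lsg;
      for (int r = 0; r < p; ++r) {
        Adapt &a = ad_sc[fam * p + r];
        std::vector<int> idx{base + r};
        try_global(idx, std::exp(a.ls), a, t, warm);
      }
    }
    // correlation blocks
    if (q > 0) {
      std::vector<int> idx(q);
      for (int i = 0; i < q; ++i) idx[i] = h.i_yi + i;
      try_global(idx, std::exp(ad_yi.ls), ad_yi, t, warm);
      if (use_group) {
        for (int i = 0; i < q; ++i) idx[i] = h.i_yg + i;
        try_global(idx, std::exp(ad_yg.ls), ad_yg, t, warm);
      }
    }
    // group varying-effect blocks
    if (use_group) for (int g = 0; g < G; ++g) {
      std::vector<int> idx(p);
      for (int r = 0; r < p; ++r) idx[r] = h.i_zg + g * p + r;
      try_global(idx, std::exp(ad_zg[g].ls), ad_zg[g], t, warm);
    }
    // interweaving moves: translate mass between a population mean (or a
    // log-scale) and the corresponding varying effects while keeping every
    // linear predictor fixed, so only the priors enter the ratio; these
    // traverse the mean/varying-effect ridge and the scale funnel cheaply
    {
      std::vector<double> Li((size_t)p * p), Lg((size_t)p * p);
      build_chol(p, th.data() + h.i_yi, Li, h.lkj_eta);
      build_chol(p, th.data() + h.i_yg, Lg, h.lkj_eta);
      // forward solve L x = e_r (x has support r..p-1)
      auto solve_er = [&](const std::vector<double> &L, int r,
                          std::vector<double> &x) {
        std::fill(x.begin(), x.end(), 0.0);
        x[r] = 1.0 / L[(size_t)r * p + r];
        for (int i = r + 1; i < p; ++i) {
          double sacc = 0.0;
          for (int c = r; c < i; ++c) sacc += L[(size_t)i * p + c] * x[c];
          x[i] = -sacc / L[(size_t)i * p + i];
        }
      };
      std::vector<double> x(p);
      for (int r = 0; r < p; ++r) {
        // (a) mu_r <-> individual effects
        {
          Adapt &a = ad_shift_i[r];
          double delta = std::exp(a.ls) * norm_rand();
          double si = std::exp(th[h.i_lsi + r]);
          solve_er(Li, r, x);
          double lr = 0.0;
          double mu_new = th[h.i_mu + r] + delta;
          lr += -0.5 * (mu_new * mu_new - th[h.i_mu + r] * th[h.i_mu + r]) /
                (h.mean_sd * h.mean_sd);
          for (int j = 0; j < J; ++j)
            for (int c = r; c < p; ++c) {
              double z0 = th[h.i_zi + (size_t)j * p + c];
              double z1 = z0 - delta / si * x[c];
              lr += -0.5 * (z1 * z1 - z0 * z0);
            }
          bool acc = std::log(unif_rand()) < lr;
          if (acc) {
            th[h.i_mu + r] = mu_new;
            for (int j = 0; j < J; ++j)
              for (int c = r; c < p; ++c)
                th[h.i_zi + (size_t)j * p + c] -= delta / si * x[c];
            cur_lp += lr;
          }
          a.n_prop++; if (acc) a.n_acc++;
          if (warm) a.tune(acc, t);
        }
        // (b) mu_r <-> group effects
        if (use_group) {
          Adapt &a = ad_shift_g[r];
          double delta = std::exp(a.ls) * norm_rand();
          double sg = std::exp(th[h.i_lsg + r]);
          solve_er(Lg, r, x);
          double lr = 0.0;
          double mu_new = th[h.i_mu + r] + delta;
          lr += -0.5 * (mu_new * mu_new - th[h.i_mu + r] * th[h.i_mu + r]) /
                (h.mean_sd * h.mean_sd);
          for (int g = 0; g < G; ++g)
            for (int c = r; c < p; ++c) {
              double z0 = th[h.i_zg + (size_t)g * p + c];
              double z1 = z0 - delta / sg * x[c];
              lr += -0.5 * (z1 * z1 - z0 * z0);
            }
          bool acc = std::log(unif_rand()) < lr;
          if (acc) {
            th[h.i_mu + r] = mu_new;
            for (int g = 0; g < G; ++g)
              for (int c = r; c < p; ++c)
                th[h.i_zg + (size_t)g * p + c] -= delta / sg * x[c];
            cur_lp += lr;
          }
          a.n_prop++; if (acc) a.n_acc++;
          if (warm) a.tune(acc, t);
        }
        // (c) log sigma_ind_r <-> individual effects (funnel move)
        {
          Adapt &a = ad_scale_i[r];
          double delta = std::exp(a.ls) * norm_rand();
          double ls0 = th[h.i_lsi + r], ls1 = ls0 + delta;
          double fac = std::exp(-delta) - 1.0;
          solve_er(Li, r, x);
          double lr = (-h.sigma_rate * (std::exp(ls1) - std::exp(ls0))) +
                      (ls1 - ls0);
          std::vector<double> w(J);
          for (int j = 0; j < J; ++j) {
            double wr = 0.0;
            for (int c = 0; c <= r; ++c)
              wr += Li[(size_t)r * p + c] * th[h.i_zi + (size_t)j * p + c];
            w[j] = wr;
            for (int c = r; c < p; ++c) {
              double z0 = th[h.i_zi + (size_t)j * p + c];
              double z1 = z0 + fac * wr * x[c];
              lr += -0.5 * (z1 * z1 - z0 * z0);
            }
          }
          // map Jacobian e^{-delta} per block enters the ratio, not the prior
          bool acc = std::log(unif_rand()) < lr - delta * J;
          if (acc) {
            th[h.i_lsi + r] = ls1;
            for (int j = 0; j < J; ++j)
              for (int c = r; c < p; ++c)
                th[h.i_zi + (size_t)j * p + c] += fac * w[j] * x[c];
            cur_lp += lr;
          }
          a.n_prop++; if (acc) a.n_acc++;
          if (warm) a.tune(acc, t);
        }
        // (d) log sigma_grp_r <-> group effects
        if (use_group) {
          Adapt &a = ad_scale_g[r];
          double delta = std::exp(a.ls) * norm_rand();
          double ls0 = th[h.i_lsg + r], ls1 = ls0 + delta;
          double fac = std::exp(-delta) - 1.0;
          solve_er(Lg, r, x);
          double lr = (-h.sigma_rate * (std::exp(ls1) - std::exp(ls0))) +
                      (ls1 - ls0);
          std::vector<double> w(G);
          for (int g = 0; g < G; ++g) {
            double wr = 0.0;
            for (int c = 0; c <= r; ++c)
              wr += Lg[(size_t)r * p + c] * th[h.i_zg + (size_t)g * p + c];
            w[g] = wr;
            for (int c = r; c < p; ++c) {
              double z0 = th[h.i_zg + (size_t)g * p + c];
              double z1 = z0 + fac * wr * x[c];
              lr += -0.5 * (z1 * z1 - z0 * z0);
            }
          }
          bool acc = std::log(unif_rand()) < lr - delta * G;
          if (acc) {
            th[h.i_lsg + r] = ls1;
            for (int g = 0; g < G; ++g)
              for (int c = r; c < p; ++c)
                th[h.i_zg + (size_t)g * p + c] += fac * w[g] * x[c];
            cur_lp += lr;
          }
          a.n_prop++; if (acc) a.n_acc++;
          if (warm) a.tune(acc, t);
        }
      }
    }

    // individual varying-effect blocks: only that individual's events move
    for (int j = 0; j < J; ++j) {
      Adapt &a = ad_zi[j];
      double scale = std::exp(a.ls);
      std::vector<double> old(p);
      double dz2 = 0.0; // change in the z-block's N(0,1) prior
      for (int r = 0; r < p; ++r) {
        int i = h.i_zi + j * p + r;
        old[r] = th[i];
        double nz = th[i] + scale * norm_rand();
        dz2 += -0.5 * (nz * nz - th[i] * th[i]);
        th[i] = nz;
      }
      // re-assemble this individual's row only
      std::vector<double> Li((size_t)p * p), Lg((size_t)p * p);
      build_chol(p, th.data() + h.i_yi, Li, h.lkj_eta);
      build_chol(p, th.data() + h.i_yg, Lg, h.lkj_eta);
      double p_row[9] = {1.0, 0.0, 0.0, 1.0, 0.0, 0.0, 0.0, 0.0, 0.0};
      int g = h.grp[j] - 1;
      for (int r = 0; r < p; ++r) {
        double v = 0.0, vg = 0.0;
        for (int c = 0; c <= r; ++c) {
          v += Li[(size_t)r * p + c] * th[h.i_zi + (size_t)j * p + c];
          vg += Lg[(size_t)r * p + c] * th[h.i_zg + (size_t)g * p + c];
        }
        double eta = th[h.i_mu + r] + th[h.i_bj + r] * h.juv[j] +
                     th[h.i_bm + r] * h.male[j] +
                     std::exp(th[h.i_lsi + r]) * v +
                     std::exp(th[h.i_lsg + r]) * vg;
        p_row[h.slot[r]] = invlink(eta, h.link[r]);
      }
      double ll_new = individual_ll(d, p_row, ev_of[j], Arow, Iws, Wws);
      double lr = (ll_new - ll_ind[j]) + dz2;
      bool acc = std::isfinite(lr) && std::log(unif_rand()) < lr;
      if (acc) {
        cur_ll += ll_new - ll_ind[j];
        cur_lp += dz2;
        ll_ind[j] = ll_new;
        for (int k = 0; k < 9; ++k) P(j, k) = p_row[k];
      } else {
        for (int r = 0; r < p; ++r) th[h.i_zi + j * p + r] = old[r];
      }
      a.n_prop++; if (acc) a.n_acc++;
      if (warm) a.tune(acc, t);
    }

    if (!warm) {
      int it = t - n_warmup;
      for (int i = 0; i < h.n; ++i) draws(it, i) = th[i];
      std::vector<double> pwe(d.E);
      pointwise_ll(d, P, A, pwe.data(), nullptr);
      for (int e = 0; e < d.E; ++e) pw(it, e) = pwe[e];
    }
  }

  // acceptance-rate report
  double acc_scalar = 0, acc_block = 0;
  long n_scalar = 0, n_block = 0;
  for (auto &a : ad_sc) { acc_scalar += a.n_acc; n_scalar += a.n_prop; }
  for (auto &a : ad_zi) { acc_block += a.n_acc; n_block += a.n_prop; }
  for (auto &a : ad_zg) { acc_block += a.n_acc; n_block += a.n_prop; }
  acc_block += ad_yi.n_acc + ad_yg.n_acc;
  n_block += ad_yi.n_prop + ad_yg.n_prop;

  return List::create(
    _["draws"] = draws,
    _["pointwise"] = pw,
    _["accept_scalar"] = n_scalar ? acc_scalar / n_scalar : NA_REAL,
    _["accept_block"] = n_block ? acc_block / n_block : NA_REAL,
    _["n_hyper"] = h.n
  );
}
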