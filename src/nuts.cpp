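// Hierarchical qAOP model: joint log-density, gradient, and a No-U-Turn
// sampler with dual-averaging step-size and diagonal metric adaptation.
//
// Unconstrained parameter vector layout (free scalars only):
//   [mu] [log_sigma] [beta_raw (p1+p2+p3)]
//   then, for each predictor block with missing cells:
//   [mu_xmiss] [log_sigma_xmiss] [x_raw per missing cell]
// Coefficients and imputed cells are non-centered:
//   beta = mu + sigma * beta_raw;  x = mu_xmiss + sigma_xmiss * x_raw.
// Missing outcome labels are marginalized out (they have no children in
// the theta chain), so the likelihood sums over observed labels only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ModelData {
  arma::mat X[3];        // n x p_k, missing cells hold 0 placeholders
  arma::umat miss[3];    // m_k x 2 zero-based (row, col) indices
  arma::mat y;           // n x 4, labels (0/1), junk where unobserved
  arma::umat yobs;       // n x 4, 1 = observed
  double s_mu, s_sig, s_mu_imp, s_sig_imp;
  bool fix_mu, fix_sigma;
  double mu_fixed, sigma_fixed;
  int n;
  arma::uvec p;          // block dims
  // layout
  int idx_mu, idx_ls;    // -1 when fixed
  int idx_beta[3];
  int idx_impmu[3], idx_impls[3], idx_impx[3]; // -1 / start indices
  int dim;
};

ModelData make_model(const List& d) {
  ModelData m;
  List Xl = d["x"], Ml = d["miss"];
  for (int k = 0; k < 3; ++k) {
    m.X[k] = as<arma::mat>(Xl[k]);
    m.miss[k] = as<arma::umat>(Ml[k]);
  }
  m.y = as<arma::mat>(d["y"]);
  m.yobs = as<arma::umat>(d["yobs"]);
  m.s_mu = as<double>(d["s_mu"]);
  m.s_sig = as<double>(d["s_sig"]);
  m.s_mu_imp = as<double>(d["s_mu_imp"]);
  m.s_sig_imp = as<double>(d["s_sig_imp"]);
  m.fix_mu = as<bool>(d["fix_mu"]);
  m.fix_sigma = as<bool>(d["fix_sigma"]);
  m.mu_fixed = as<double>(d["mu_value"]);
  m.sigma_fixed = as<double>(d["sigma_value"]);
  m.n = m.X[0].n_rows;
  m.p = arma::uvec(3);
  int pos = 0;
  m.idx_mu = m.fix_mu ? -1 : pos++;
  m.idx_ls = m.fix_sigma ? -1 : pos++;
  for (int k = 0; k < 3; ++k) {
    m.p[k] = m.X[k].n_cols;
    m.idx_beta[k] = pos;
    pos += m.p[k];
  }
  for (int k = 0; k < 3; ++k) {
    if (m.miss[k].n_rows > 0) {
      m.idx_impmu[k] = pos++;
      m.idx_impls[k] = pos++;
      m.idx_impx[k] = pos;
      pos += m.miss[k].n_rows;
    } else {
      m.idx_impmu[k] = m.idx_impls[k] = m.idx_impx[k] = -1;
    }
  }
  m.dim = pos;
  return m;
}

inline double inv_logit(double x) {
  return x > 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

// log(1 + exp(x)), stable
inline double log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Joint log-density (with log-scale Jacobians) and its gradient.
double logp_grad(const ModelData& m, const arma::vec& q, arma::vec& grad) {
  grad.zeros(m.dim);
  const double HALF_LOG_2PI = 0.9189385332046727;
  double lp = 0.0;

  double mu = m.fix_mu ? m.mu_fixed : q[m.idx_mu];
  double sigma, ls = 0.0;
  if (m.fix_sigma) {
    sigma = m.sigma_fixed;
  } else {
    ls = q[m.idx_ls];
    sigma = std::exp(ls);
  }

  // hyperpriors
  if (!m.fix_mu) {
    lp += -HALF_LOG_2PI - std::log(m.s_mu) - 0.5 * mu * mu / (m.s_mu * m.s_mu);
    grad[m.idx_mu] += -mu / (m.s_mu * m.s_mu);
  }
  if (!m.fix_sigma) {
    // HalfNormal(s_sig) on sigma, plus Jacobian log|d sigma / d ls| = ls
    lp += std::log(2.0) - HALF_LOG_2PI - std::log(m.s_sig)
        - 0.5 * sigma * sigma / (m.s_sig * m.s_sig) + ls;
    grad[m.idx_ls] += -sigma * sigma / (m.s_sig * m.s_sig) + 1.0;
  }

  // beta_raw standard-normal priors
  arma::vec beta_all(m.p[0] + m.p[1] + m.p[2]);
  {
    int off = 0;
    for (int k = 0; k < 3; ++k) {
      for (unsigned j = 0; j < m.p[k]; ++j) {
        double b = q[m.idx_beta[k] + j];
        lp += -HALF_LOG_2PI - 0.5 * b * b;
        grad[m.idx_beta[k] + j] += -b;
        beta_all[off + j] = mu + sigma * b;
      }
      off += m.p[k];
    }
  }

  // imputation blocks: hyperpriors, raw-cell priors, filled design matrices
  arma::mat Xf[3];
  double isg[3] = {1, 1, 1};
  for (int k = 0; k < 3; ++k) {
    Xf[k] = m.X[k];
    unsigned mk = m.miss[k].n_rows;
    if (mk == 0) continue;
    double mm = q[m.idx_impmu[k]];
    double lsm = q[m.idx_impls[k]];
    double sm = std::exp(lsm);
    isg[k] = sm;
    lp += -HALF_LOG_2PI - std::log(m.s_mu_imp)
        - 0.5 * mm * mm / (m.s_mu_imp * m.s_mu_imp);
    grad[m.idx_impmu[k]] += -mm / (m.s_mu_imp * m.s_mu_imp);
    lp += std::log(2.0) - HALF_LOG_2PI - std::log(m.s_sig_imp)
        - 0.5 * sm * sm / (m.s_sig_imp * m.s_sig_imp) + lsm;
    grad[m.idx_impls[k]] += -sm * sm / (m.s_sig_imp * m.s_sig_imp) + 1.0;
    for (unsigned c = 0; c < mk; ++c) {
      double xr = q[m.idx_impx[k] + c];
      lp += -HALF_LOG_2PI - 0.5 * xr * xr;
      grad[m.idx_impx[k] + c] += -xr;
      Xf[k](m.miss[k](c, 0), m.miss[k](c, 1)) = mm + sm * xr;
    }
  }

  if (m.n > 0) {
    // linear predictors and theta chain
    arma::vec c1 = m.p[0] > 0 ? arma::vec(Xf[0] * beta_all.subvec(0, m.p[0] - 1))
                              : arma::zeros(m.n);
    arma::vec c2 = m.p[1] > 0
        ? arma::vec(Xf[1] * beta_all.subvec(m.p[0], m.p[0] + m.p[1] - 1))
        : arma::zeros(m.n);
    arma::vec c3 = m.p[2] > 0
        ? arma::vec(Xf[2] * beta_all.subvec(m.p[0] + m.p[1],
                                            m.p[0] + m.p[1] + m.p[2] - 1))
        : arma::zeros(m.n);
    arma::mat theta(m.n, 4);
    theta.col(0) = c1;
    theta.col(1) = c2 + theta.col(0);
    theta.col(2) = c3 + theta.col(1);
    theta.col(3) = theta.col(0) + theta.col(1) + theta.col(2);

    // observed-label Bernoulli-logit likelihood and d lp / d theta
    arma::mat g(m.n, 4, arma::fill::zeros);
    for (int k = 0; k < 4; ++k) {
      for (int i = 0; i < m.n; ++i) {
        if (!m.yobs(i, k)) continue;
        double th = theta(i, k), yi = m.y(i, k);
        lp += yi * th - log1pexp(th);
        g(i, k) = yi - inv_logit(th);
      }
    }
    // chain rule back to block contributions
    arma::vec dc1 = g.col(0) + g.col(1) + g.col(2) + 3.0 * g.col(3);
    arma::vec dc2 = g.col(1) + g.col(2) + 2.0 * g.col(3);
    arma::vec dc3 = g.col(2) + g.col(3);
    arma::vec dc[3] = {dc1, dc2, dc3};

    int off = 0;
    double sum_gb = 0.0, sum_bgb = 0.0;
    for (int k = 0; k < 3; ++k) {
      if (m.p[k] > 0) {
        arma::vec gb = Xf[k].t() * dc[k];  // d lp / d beta (likelihood part)
        for (unsigned j = 0; j < m.p[k]; ++j) {
          double braw = q[m.idx_beta[k] + j];
          grad[m.idx_beta[k] + j] += sigma * gb[j];
          sum_gb += gb[j];
          sum_bgb += braw * gb[j];
        }
      }
      unsigned mk = m.miss[k].n_rows;
      if (mk > 0) {
        int jb = m.idx_beta[k];
        double gsum = 0.0, gxr = 0.0;
        for (unsigned c = 0; c < mk; ++c) {
          unsigned i = m.miss[k](c, 0), j = m.miss[k](c, 1);
          double gx = beta_all[off + j] * dc[k][i];  // d lp / d x_cell
          double xr = q[m.idx_impx[k] + c];
          grad[m.idx_impx[k] + c] += isg[k] * gx;
          gsum += gx;
          gxr += xr * gx;
        }
        grad[m.idx_impmu[k]] += gsum;
        grad[m.idx_impls[k]] += isg[k] * gxr;
        (void)jb;
      }
      off += m.p[k];
    }
    if (!m.fix_mu) grad[m.idx_mu] += sum_gb;
    if (!m.fix_sigma) grad[m.idx_ls] += sigma * sum_bgb;
  }

  return lp;
}

struct Hamiltonian {
  const ModelData& m;
  arma::vec inv_metric;  // diagonal of M^{-1}
  explicit Hamiltonian(const ModelData& mm)
      : m(mm), inv_metric(arma::ones(mm.dim)) {}

  double kinetic(const arma::vec& r) const {
    return 0.5 * arma::dot(r % inv_metric, r);
  }
  double H(const arma::vec& q, const arma::vec& r, arma::vec& grad) const {
    double lp = logp_grad(m, q, grad);
    return lp - kinetic(r);
  }
  // advances (q, r); returns log-density at the new q, grad updated in place
  double leapfrog(arma::vec& q, arma::vec& r, arma::vec& grad, double eps) const {
    r += 0.5 * eps * grad;
    q += eps * (inv_metric % r);
    double lp = logp_grad(m, q, grad);
    r += 0.5 * eps * grad;
    return lp;
  }
  arma::vec sample_momentum() const {
    arma::vec r(m.dim);
    for (int i = 0; i < m.dim; ++i) r[i] = R::norm_rand() / std::sqrt(inv_metric[i]);
    return r;
  }
};

struct Tree {
  arma::vec q_minus, r_minus, g_minus;
  arma::vec q_plus, r_plus, g_plus;
  arma::vec q_prop;
  double n;       // slice-acceptable states in subtree
  bool ok;        // no U-turn, no divergence
  bool divergent;
  double alpha;   // sum of acceptance probabilities
  int n_alpha;
};

const double DELTA_MAX = 1000.0;

bool no_uturn(const Hamiltonian& h, const arma::vec& qm, const arma::vec& rm,
              const arma::vec& qp, const arma::vec& rp) {
  arma::vec dq = qp - qm;
  return arma::dot(dq, h.inv_metric % rm) >= 0 &&
         arma::dot(dq, h.inv_metric % rp) >= 0;
}

// Hoffman & Gelman (2014) Algorithm 6 build_tree (slice variant).
Tree build_tree(const Hamiltonian& h, arma::vec q, arma::vec r, arma::vec g,
                double log_u, int dir, int depth, double eps, double H0) {
  Tree t;
  if (depth == 0) {
    double lp = h.leapfrog(q, r, g, dir * eps);
    double Hq = lp - h.kinetic(r);
    t.q_minus = t.q_plus = t.q_prop = q;
    t.r_minus = t.r_plus = r;
    t.g_minus = t.g_plus = g;
    double dH = Hq - H0;
    t.n = (log_u <= dH) ? 1 : 0;
    t.divergent = !(log_u < dH + DELTA_MAX) || !std::isfinite(Hq);
    t.ok = !t.divergent;
    double a = std::exp(std::min(0.0, dH));
    t.alpha = std::isfinite(a) ? a : 0.0;
    t.n_alpha = 1;
    return t;
  }
  Tree t1 = build_tree(h, q, r, g, log_u, dir, depth - 1, eps, H0);
  if (!t1.ok) return t1;
  Tree t2 = (dir == -1)
      ? build_tree(h, t1.q_minus, t1.r_minus, t1.g_minus, log_u, dir,
                   depth - 1, eps, H0)
      : build_tree(h, t1.q_plus, t1.r_plus, t1.g_plus, log_u, dir,
                   depth - 1, eps, H0);
  t.q_minus = (dir == -1) ? t2.q_minus : t1.q_minus;
  t.r_minus = (dir == -1) ? t2.r_minus : t1.r_minus;
  t.g_minus = (dir == -1) ? t2.g_minus : t1.g_minus;
  t.q_plus = (dir == -1) ? t1.q_plus : t2.q_plus;
  t.r_plus = (dir == -1) ? t1.r_plus : t2.r_plus;
  t.g_plus = (dir == -1) ? t1.g_plus : t2.g_plus;
  double ntot = t1.n + t2.n;
  t.q_prop = t1.q_prop;
  if (ntot > 0 && R::unif_rand() < t2.n / ntot) t.q_prop = t2.q_prop;
  t.n = ntot;
  t.divergent = t2.divergent;
  t.ok = t2.ok && no_uturn(h, t.q_minus, t.r_minus, t.q_plus, t.r_plus);
  t.alpha = t1.alpha + t2.alpha;
  t.n_alpha = t1.n_alpha + t2.n_alpha;
  return t;
}

// One NUTS transition; returns accept-prob statistic, sets divergent flag.
double nuts_transition(const Hamiltonian& h, arma::vec& q, double eps,
                       int max_depth, bool& divergent, int& depth_used) {
  arma::vec g(h.m.dim);
  arma::vec r = h.sample_momentum();
  double H0 = h.H(q, r, g);
  double log_u = -R::exp_rand();  // log Uniform(0,1)

  arma::vec q_minus = q, q_plus = q, r_minus = r, r_plus = r;
  arma::vec g_minus = g, g_plus = g;
  double n = 1;
  bool ok = true;
  divergent = false;
  double alpha_sum = 0;
  int n_alpha = 0;
  int depth = 0;
  while (ok && depth < max_depth) {
    int dir = (R::unif_rand() < 0.5) ? -1 : 1;
    Tree t = (dir == -1)
        ? build_tree(h, q_minus, r_minus, g_minus, log_u, dir, depth, eps, H0)
        : build_tree(h, q_plus, r_plus, g_plus, log_u, dir, depth, eps, H0);
    if (dir == -1) {
      q_minus = t.q_minus; r_minus = t.r_minus; g_minus = t.g_minus;
    } else {
      q_plus = t.q_plus; r_plus = t.r_plus; g_plus = t.g_plus;
    }
    if (t.divergent) divergent = true;
    if (t.ok && t.n > 0 && R::unif_rand() < std::min(1.0, t.n / n)) {
      q = t.q_prop;
    }
    n += t.n;
    ok = t.ok && no_uturn(h, q_minus, r_minus, q_plus, r_plus);
    alpha_sum += t.alpha;
    n_alpha += t.n_alpha;
    ++depth;
  }
  depth_used = depth;
  return n_alpha > 0 ? alpha_sum / n_alpha : 0.0;
}

double find_initial_eps(const Hamiltonian& h, const arma::vec& q0) {
  double eps = 0.1;
  arma::vec g(h.m.dim);
  arma::vec r = h.sample_momentum();
  double H0 = h.H(q0, r, g);
  arma::vec q = q0, rr = r;
  double lp1 = h.leapfrog(q, rr, g, eps);
  double dH = lp1 - h.kinetic(rr) - H0;
  if (!std::isfinite(dH)) dH = -1e10;
  double a = (dH > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= (a == 1.0) ? 2.0 : 0.5;
    q = q0;
    rr = r;
    logp_grad(h.m, q, g);
    lp1 = h.leapfrog(q, rr, g, eps);
    dH = lp1 - h.kinetic(rr) - H0;
    if (!std::isfinite(dH)) dH = -1e10;
    if (a * dH <= a * std::log(0.5)) break;
  }
  return std::max(1e-8, std::min(eps, 10.0));
}

}  // namespace

// [[Rcpp::export]]
double cpp_log_joint(List data, NumericVector q) {
  ModelData m = make_model(data);
  arma::vec grad;
  return logp_grad(m, as<arma::vec>(q), grad);
}

// [[Rcpp::export]]
List cpp_log_joint_grad(List data, NumericVector q) {
  ModelData m = make_model(data);
  arma::vec grad;
  double lp = logp_grad(m, as<arma::vec>(q), grad);
  return List::create(_["lp"] = lp, _["grad"] = wrap(grad));
}

// [[Rcpp::export]]
int cpp_model_dim(List data) {
  return make_model(data).dim;
}

// Runs one chain.  R-side code manages the RNG seed (set.seed) and loops
// over chains, so draws are reproducible through R's RNG.
// [[Rcpp::export]]
List cpp_nuts_chain(List data, int warmup, int iter, double target_accept,
                    int max_depth) {
  ModelData m = make_model(data);
  Hamiltonian h(m);
  RNGScope rng;

  arma::vec q(m.dim);
  for (int i = 0; i < m.dim; ++i) q[i] = 2.0 * R::unif_rand() - 1.0;

  double eps = find_initial_eps(h, q);
  // dual averaging state
  double mu_da = std::log(10.0 * eps), log_eps_bar = 0.0, Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // adaptation windows (Stan-like): init buffer, doubling metric windows,
  // terminal buffer
  int init_buf = std::min(75, std::max(1, warmup / 5));
  int term_buf = std::min(50, std::max(1, warmup / 10));
  int window = 25;
  int next_window_end = std::min(init_buf + window, warmup - term_buf);
  arma::running_stat_vec<arma::vec> acc;

  arma::mat draws(iter, m.dim);
  IntegerVector divergent(iter), treedepth(iter);
  int div_warmup = 0, div_sampling = 0;
  double accept_sum = 0.0;

  for (int s = 0; s < warmup + iter; ++s) {
    bool div;
    int depth;
    double alpha = nuts_transition(h, q, eps, max_depth, div, depth);
    bool in_warmup = s < warmup;
    if (in_warmup) {
      if (div) ++div_warmup;
      // dual averaging update
      ++da_count;
      double frac = 1.0 / (da_count + t0);
      Hbar = (1 - frac) * Hbar + frac * (target_accept - alpha);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma * Hbar;
      double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      // metric windows
      bool in_metric_phase = (s >= init_buf) && (s < warmup - term_buf);
      if (in_metric_phase) acc(q);
      if (in_metric_phase && (s + 1) == next_window_end) {
        if (acc.count() >= 10) {
          arma::vec v = acc.var();
          double nn = (double)acc.count();
          h.inv_metric = (nn / (nn + 5.0)) * v +
                         1e-3 * (5.0 / (nn + 5.0)) * arma::ones(m.dim);
          h.inv_metric.elem(arma::find(h.inv_metric <= 0)).fill(1e-3);
        }
        acc.reset();
        window *= 2;
        next_window_end = std::min((int)(s + 1 + window), warmup - term_buf);
        if (warmup - term_buf - next_window_end < 2 * window)
          next_window_end = warmup - term_buf;
        // restart step-size adaptation around current eps
        eps = find_initial_eps(h, q);
        mu_da = std::log(10.0 * eps);
        Hbar = 0.0;
        log_eps_bar = 0.0;
        da_count = 0;
      }
      if (s == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      int j = s - warmup;
      draws.row(j) = q.t();
      divergent[j] = div ? 1 : 0;
      treedepth[j] = depth;
      if (div) ++div_sampling;
      accept_sum += alpha;
    }
  }

  return List::create(
      _["draws"] = wrap(draws), _["divergent"] = divergent,
      _["treedepth"] = treedepth, _["stepsize"] = eps,
      _["inv_metric"] = wrap(h.inv_metric),
      _["divergences"] = div_sampling, _["divergences_warmup"] = div_warmup,
      _["mean_accept"] = iter > 0 ? accept_sum / iter : NA_REAL);
}
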