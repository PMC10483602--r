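// Metropolis-within-Gibbs sampler for the joint model of a longitudinal
// biomarker trajectory and time to progression.
//
// Longitudinal submodel: y_ij ~ N(x_ij'beta + o_ij'delta + z_ij'b_i, sigma^2)
// Survival submodel:     h_i(t) = lambda_{q(t)} exp(w_i'gamma + alpha f_i(t))
// where f_i(t) = xa(t)'beta + za(t)'b_i is the current value, slope or
// scaled area of the trajectory (the R side supplies the corresponding
// design matrices), and the baseline hazard is piecewise constant.
// The cumulative hazard is integrated by Gauss-Legendre quadrature with
// nodes placed per hazard-interval segment (weights supplied by R).
//
// Priors: N(0,100) on beta, delta, gamma, alpha; half-Cauchy(2.5) on sigma
// and the random-effect sds; uniform (LKJ eta=1) on the random-effect
// correlation matrix; Gamma(0.1, 0.1) on the hazard levels (Gibbs update).

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double SD_COEF = 10.0;   // normal prior sd for regression terms
static const double HC_SCALE = 2.5;   // half-Cauchy scale for sd parameters
static const double GAM_A = 0.1, GAM_B = 0.1;  // hazard level prior

inline double lp_normal(double x) { return -0.5 * x * x / (SD_COEF * SD_COEF); }
// half-Cauchy prior on s = exp(ls), including the log-scale jacobian
inline double lp_halfcauchy_log(double ls) {
  double s = std::exp(ls);
  return -std::log1p((s / HC_SCALE) * (s / HC_SCALE)) + ls;
}

struct Caches {
  vec eta;    // N: longitudinal linear predictor
  vec f_nd;   // M: association value at quadrature nodes
  vec f_T;    // n: association value at event/censoring time
  vec wg;     // n: covariate linear predictor W * gamma
};

// [[Rcpp::export]]
List jm_mcmc(List data, List init, List control) {
  // --- unpack ---
  vec y = as<vec>(data["y"]);
  uvec id = as<uvec>(data["id"]);           // 0-based, sorted
  mat Xt = as<mat>(data["Xt_obs"]);
  mat Xo = as<mat>(data["Xo_obs"]);         // may have 0 cols
  mat Z  = as<mat>(data["Z_obs"]);
  uvec obs_off = as<uvec>(data["obs_off"]); // n+1 offsets into rows
  LogicalVector cens_in = data["cens"];     // tobit left-censoring at 0

  vec d = as<vec>(data["d"]);
  mat W = as<mat>(data["W"]);               // may have 0 cols
  mat XaT = as<mat>(data["Xa_T"]);
  mat ZaT = as<mat>(data["Za_T"]);
  uvec intT = as<uvec>(data["int_T"]);

  uvec node_pat = as<uvec>(data["node_pat"]);
  vec node_w = as<vec>(data["node_w"]);
  uvec node_int = as<uvec>(data["node_int"]);
  mat Xa_nd = as<mat>(data["Xa_nd"]);
  mat Za_nd = as<mat>(data["Za_nd"]);
  uvec node_off = as<uvec>(data["node_off"]); // n+1 offsets into nodes

  int Q = as<int>(data["Q"]);
  bool tobit = as<bool>(data["tobit"]);

  const int N = y.n_elem, n = d.n_elem;
  const int p1 = Xt.n_cols, p0 = Xo.n_cols, pw = W.n_cols, q = Z.n_cols;
  const int M = node_w.n_elem;

  vec beta = as<vec>(init["beta"]);
  vec delta = p0 ? as<vec>(init["delta"]) : vec();
  vec gamma_ = pw ? as<vec>(init["gamma"]) : vec();
  double alpha = as<double>(init["alpha"]);
  double lsigma = std::log(as<double>(init["sigma"]));
  mat b = as<mat>(init["b"]);               // n x q
  vec lsd = arma::log(as<vec>(init["re_sd"]));
  int nrho = q * (q - 1) / 2;
  vec rho(nrho, fill::zeros);
  vec loglam = arma::log(as<vec>(init["lambda"]));

  int n_iter = as<int>(control["n_iter"]);
  int n_burn = as<int>(control["n_burn"]);
  int thin = as<int>(control["thin"]);
  bool fix_alpha = as<bool>(control["fix_alpha"]);

  uvec cens(N);
  for (int i = 0; i < N; ++i) cens[i] = (tobit && cens_in[i]) ? 1u : 0u;

  // --- caches ---
  Caches C;
  auto re_rows = [&](const mat& Zm, const uvec& pat) {
    vec out(Zm.n_rows);
    for (uword r = 0; r < Zm.n_rows; ++r)
      out[r] = dot(Zm.row(r), b.row(pat[r]));
    return out;
  };
  uvec id_nd = node_pat;
  C.eta = Xt * beta + (p0 ? vec(Xo * delta) : vec(N, fill::zeros)) +
          re_rows(Z, id);
  C.f_nd = Xa_nd * beta + re_rows(Za_nd, id_nd);
  C.f_T = XaT * beta + re_rows(ZaT, regspace<uvec>(0, n - 1));
  C.wg = pw ? vec(W * gamma_) : vec(n, fill::zeros);

  // longitudinal log-likelihood over a row range given eta values
  auto ll_long_range = [&](const vec& eta, uword lo, uword hi) {
    double sigma = std::exp(lsigma), ll = 0.0;
    const double c = -0.5 * std::log(2.0 * M_PI) - lsigma;
    for (uword r = lo; r < hi; ++r) {
      double z = (y[r] - eta[r]) / sigma;
      if (cens[r])
        ll += R::pnorm(-eta[r] / sigma, 0.0, 1.0, 1, 1);
      else
        ll += c - 0.5 * z * z;
    }
    return ll;
  };
  auto ll_long_all = [&](const vec& eta) { return ll_long_range(eta, 0, N); };

  // survival log-likelihood for one patient given association values
  auto ll_surv_pat = [&](int i, const vec& f_nd, double f_Ti,
                         double alpha_) {
    double ll = d[i] * (loglam[intT[i]] + C.wg[i] + alpha_ * f_Ti);
    double cum = 0.0;
    for (uword m = node_off[i]; m < node_off[i + 1]; ++m)
      cum += node_w[m] * std::exp(loglam[node_int[m]] + alpha_ * f_nd[m]);
    return ll - std::exp(C.wg[i]) * cum;
  };
  auto ll_surv_all = [&](const vec& f_nd, const vec& f_T, double alpha_) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += ll_surv_pat(i, f_nd, f_T[i], alpha_);
    return ll;
  };

  // random-effect prior: - n/2 log|D| - 0.5 sum b' Dinv b
  auto build_corr = [&](const vec& rho_) {
    mat R = eye(q, q);
    int k = 0;
    for (int i = 0; i < q; ++i)
      for (int j = i + 1; j < q; ++j) R(i, j) = R(j, i) = rho_[k++];
    return R;
  };
  auto lp_b_all = [&](const mat& bm, const vec& lsd_, const vec& rho_,
                      bool& ok) {
    mat R = build_corr(rho_);
    mat S = diagmat(arma::exp(lsd_));
    mat D = S * R * S;
    mat L;
    ok = chol(L, D, "lower");
    if (!ok) return -datum::inf;
    double logdet = 2.0 * accu(arma::log(L.diag()));
    mat sol = solve(trimatl(L), bm.t());
    return -0.5 * n * logdet - 0.5 * accu(square(sol));
  };
  auto lp_b_one = [&](const rowvec& bi, const mat& Dinv, double logdet) {
    return -0.5 * logdet - 0.5 * as_scalar(bi * Dinv * bi.t());
  };

  // adaptive step sizes (log scale)
  vec ls_beta(p1, fill::value(-2.0)), ls_delta(std::max(p0, 1), fill::value(-2.0)),
      ls_gamma(std::max(pw, 1), fill::value(-2.0));
  double ls_alpha = -3.0, ls_sigma = -3.0;
  vec ls_b(n, fill::value(-1.0));
  vec ls_lsd(q, fill::value(-2.0)), ls_rho(std::max(nrho, 1), fill::value(-2.0));
  auto adapt = [&](double& ls, bool acc, int it, double target) {
    if (it < n_burn) ls += (acc ? 1.0 - target : -target) *
      std::min(0.05, 5.0 / std::sqrt(it + 1.0));
  };

  // storage
  int n_keep = (n_iter - n_burn + thin - 1) / thin;
  mat S_beta(n_keep, p1), S_delta(n_keep, std::max(p0, 1)),
      S_gamma(n_keep, std::max(pw, 1)), S_lsd(n_keep, q),
      S_rho(n_keep, std::max(nrho, 1)), S_lam(n_keep, Q);
  vec S_alpha(n_keep), S_sigma(n_keep);
  cube S_b(n, q, n_keep);
  int keep = 0;
  double acc_alpha = 0.0; int n_alpha = 0;

  mat D_cur, Dinv_cur; double logdet_cur;
  auto refresh_D = [&]() {
    mat R = build_corr(rho);
    mat S = diagmat(arma::exp(lsd));
    D_cur = S * R * S;
    Dinv_cur = inv_sympd(D_cur);
    double sign;
    log_det(logdet_cur, sign, D_cur);
  };
  refresh_D();

  for (int it = 0; it < n_iter; ++it) {
    // -- beta (trajectory fixed effects): componentwise RW --
    for (int j = 0; j < p1; ++j) {
      double step = std::exp(ls_beta[j]);
      double db = R::rnorm(0.0, step);
      vec eta_p = C.eta + Xt.col(j) * db;
      vec fnd_p = C.f_nd + Xa_nd.col(j) * db;
      vec fT_p = C.f_T + XaT.col(j) * db;
      double lr = ll_long_all(eta_p) - ll_long_all(C.eta)
        + ll_surv_all(fnd_p, fT_p, alpha) - ll_surv_all(C.f_nd, C.f_T, alpha)
        + lp_normal(beta[j] + db) - lp_normal(beta[j]);
      bool acc = std::log(R::runif(0, 1)) < lr;
      if (acc) { beta[j] += db; C.eta = eta_p; C.f_nd = fnd_p; C.f_T = fT_p; }
      adapt(ls_beta[j], acc, it, 0.44);
    }
    // -- delta (infusion offsets): longitudinal only --
    for (int j = 0; j < p0; ++j) {
      double db = R::rnorm(0.0, std::exp(ls_delta[j]));
      vec eta_p = C.eta + Xo.col(j) * db;
      double lr = ll_long_all(eta_p) - ll_long_all(C.eta)
        + lp_normal(delta[j] + db) - lp_normal(delta[j]);
      bool acc = std::log(R::runif(0, 1)) < lr;
      if (acc) { delta[j] += db; C.eta = eta_p; }
      adapt(ls_delta[j], acc, it, 0.44);
    }
    // -- gamma (survival covariates) --
    for (int j = 0; j < pw; ++j) {
      double dg = R::rnorm(0.0, std::exp(ls_gamma[j]));
      vec wg_old = C.wg;
      double ll_old = ll_surv_all(C.f_nd, C.f_T, alpha);
      C.wg = wg_old + W.col(j) * dg;
      double ll_new = ll_surv_all(C.f_nd, C.f_T, alpha);
      double lr = ll_new - ll_old +
        lp_normal(gamma_[j] + dg) - lp_normal(gamma_[j]);
      bool acc = std::log(R::runif(0, 1)) < lr;
      if (acc) gamma_[j] += dg; else C.wg = wg_old;
      adapt(ls_gamma[j], acc, it, 0.44);
    }
    // -- alpha (association) --
    if (!fix_alpha) {
      double da = R::rnorm(0.0, std::exp(ls_alpha));
      double lr = ll_surv_all(C.f_nd, C.f_T, alpha + da)
        - ll_surv_all(C.f_nd, C.f_T, alpha)
        + lp_normal(alpha + da) - lp_normal(alpha);
      bool acc = std::log(R::runif(0, 1)) < lr;
      if (acc) alpha += da;
      adapt(ls_alpha, acc, it, 0.44);
      if (it >= n_burn) { acc_alpha += acc; ++n_alpha; }
    }
    // -- sigma --
    {
      double dls = R::rnorm(0.0, std::exp(ls_sigma));
      double ll_old = ll_long_all(C.eta) + lp_halfcauchy_log(lsigma);
      lsigma += dls;
      double ll_new = ll_long_all(C.eta) + lp_halfcauchy_log(lsigma);
      bool acc = std::log(R::runif(0, 1)) < (ll_new - ll_old);
      if (!acc) lsigma -= dls;
      adapt(ls_sigma, acc, it, 0.44);
    }
    // -- random effects b_i --
    for (int i = 0; i < n; ++i) {
      double step = std::exp(ls_b[i]);
      rowvec db(q);
      for (int k2 = 0; k2 < q; ++k2) db[k2] = R::rnorm(0.0, step);
      rowvec bi_new = b.row(i) + db;
      // longitudinal rows
      uword lo = obs_off[i], hi = obs_off[i + 1];
      vec eta_p = C.eta;
      for (uword r = lo; r < hi; ++r)
        eta_p[r] += dot(Z.row(r), db);
      // association values on this patient's nodes
      vec fnd_p = C.f_nd;
      for (uword m = node_off[i]; m < node_off[i + 1]; ++m)
        fnd_p[m] += dot(Za_nd.row(m), db);
      double fT_p = C.f_T[i] + dot(ZaT.row(i), db);
      double lr = ll_long_range(eta_p, lo, hi) - ll_long_range(C.eta, lo, hi)
        + ll_surv_pat(i, fnd_p, fT_p, alpha)
        - ll_surv_pat(i, C.f_nd, C.f_T[i], alpha)
        + lp_b_one(bi_new, Dinv_cur, logdet_cur)
        - lp_b_one(b.row(i), Dinv_cur, logdet_cur);
      bool acc = std::log(R::runif(0, 1)) < lr;
      if (acc) {
        b.row(i) = bi_new;
        for (uword r = lo; r < hi; ++r) C.eta[r] = eta_p[r];
        for (uword m = node_off[i]; m < node_off[i + 1]; ++m)
          C.f_nd[m] = fnd_p[m];
        C.f_T[i] = fT_p;
      }
      adapt(ls_b[i], acc, it, 0.25);
    }
    // -- D: log-sds and correlations --
    for (int k2 = 0; k2 < q; ++k2) {
      double dls = R::rnorm(0.0, std::exp(ls_lsd[k2]));
      vec lsd_p = lsd; lsd_p[k2] += dls;
      bool ok1, ok2;
      double lp_new = lp_b_all(b, lsd_p, rho, ok1) +
        lp_halfcauchy_log(lsd_p[k2]);
      double lp_old = lp_b_all(b, lsd, rho, ok2) +
        lp_halfcauchy_log(lsd[k2]);
      bool acc = ok1 && std::log(R::runif(0, 1)) < (lp_new - lp_old);
      if (acc) { lsd = lsd_p; refresh_D(); }
      adapt(ls_lsd[k2], acc, it, 0.44);
    }
    for (int k2 = 0; k2 < nrho; ++k2) {
      double dr = R::rnorm(0.0, std::exp(ls_rho[k2]));
      vec rho_p = rho; rho_p[k2] += dr;
      bool acc = false;
      if (std::abs(rho_p[k2]) < 0.999) {
        bool ok1, ok2;
        double lp_new = lp_b_all(b, lsd, rho_p, ok1);
        double lp_old = lp_b_all(b, lsd, rho, ok2);
        acc = ok1 && std::log(R::runif(0, 1)) < (lp_new - lp_old);
      }
      if (acc) { rho = rho_p; refresh_D(); }
      adapt(ls_rho[k2], acc, it, 0.44);
    }
    // -- hazard levels: conjugate Gibbs --
    {
      vec A(Q, fill::zeros), dq(Q, fill::zeros);
      for (int m = 0; m < M; ++m)
        A[node_int[m]] += node_w[m] *
          std::exp(C.wg[node_pat[m]] + alpha * C.f_nd[m]);
      for (int i = 0; i < n; ++i) if (d[i] > 0) dq[intT[i]] += 1.0;
      for (int q2 = 0; q2 < Q; ++q2)
        loglam[q2] = std::log(
          R::rgamma(GAM_A + dq[q2], 1.0 / (GAM_B + A[q2])));
    }

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      S_beta.row(keep) = beta.t();
      if (p0) S_delta.row(keep) = delta.t();
      if (pw) S_gamma.row(keep) = gamma_.t();
      S_alpha[keep] = alpha;
      S_sigma[keep] = std::exp(lsigma);
      S_lsd.row(keep) = arma::exp(lsd).t();
      if (nrho) S_rho.row(keep) = rho.t();
      S_lam.row(keep) = arma::exp(loglam).t();
      S_b.slice(keep) = b;
      ++keep;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  cube B_out = S_b.slices(0, keep - 1);
  return List::create(
    _["beta"] = S_beta.rows(0, keep - 1),
    _["delta"] = S_delta.rows(0, keep - 1),
    _["gamma"] = S_gamma.rows(0, keep - 1),
    _["alpha"] = S_alpha.head(keep),
    _["sigma"] = S_sigma.head(keep),
    _["re_sd"] = S_lsd.rows(0, keep - 1),
    _["re_corr"] = S_rho.rows(0, keep - 1),
    _["lambda"] = S_lam.rows(0, keep - 1),
    _["b"] = B_out,
    _["accept_alpha"] = n_alpha ? acc_alpha / n_alpha : NA_REAL);
}
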