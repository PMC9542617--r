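// Sampler for the negative-binomial spatially varying coefficient trend
// model:
//
//   y_o ~ NegBin(mu_o, Phi),   log mu_o = alpha_c + eps_c * logE_o
//                                        + tau_c * T_o + gamma_{c,t} + kappa_k
//
// Fields are parameterized through sum-to-zero bases: alpha/eps/tau via the
// spectral basis B of the scaled iCAR structure, gamma via a per-cell
// sum-to-zero basis over years, kappa via a global sum-to-zero basis over
// circles. The sampler alternates
//   1. HMC over all centers and whitened basis coefficients z ~ N(0, I)
//      (field deviation = sigma_f B z), conditional on the standard
//      deviations and Phi, with dual-averaging step-size and diagonal mass
//      adaptation during warmup — whitening removes the funnel between a
//      field and its scale;
//   2. interweaving slice-sampling updates of each log standard deviation:
//      first the ancillary conditional (whitened coefficients fixed, the
//      likelihood moves), then the sufficient conditional (centered
//      coefficients fixed, conjugate-like Gaussian statistic), so mixing
//      does not stall whether the field is strongly or weakly identified;
//   3. a slice-sampling update of log Phi.
// Field SDs carry exponential (PC) priors; Phi carries a PC prior on the
// Poisson-base distance 1/sqrt(Phi) or a gamma fallback.
//
// One chain per call; the R wrapper runs chains and assembles diagnostics.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct ModelData {
  vec y, logE, Tt;
  uvec cell, yearidx, circ;   // 0-based
  mat B;                      // ncell x m spatial basis
  mat Cg;                     // nyear x (nyear-1) gamma basis
  mat Dk;                     // ncirc x (ncirc-1) kappa basis
  int ncell, nyear, ncirc;
  bool est_alpha_field, est_eps, est_eps_field, est_tau_field;
  bool est_gamma, est_kappa, est_phi;
  double fix_eps, fix_phi;
  double lambda_sd, center_sd;
  double mlE, mT;   // means of log-effort and T over observations; the
                    // sampler works in a0' = a0 + e0*mlE + t0*mT coordinates
                    // so the three centers are decorrelated (exact affine
                    // reparameterization, unit Jacobian)
  bool phi_pc; double phi_l, phi_shape, phi_rate;

  // coefficient-vector offsets (sigma and phi live outside the HMC vector)
  int m, off_a0, off_e0, off_t0, off_za, off_ze, off_zt, off_g, off_w, npar;
  // indices of the five sigma slots that are active
  enum { SA = 0, SE = 1, ST = 2, SG = 3, SK = 4 };

  void layout() {
    m = B.n_cols;
    int p = 0;
    off_a0 = p; p += 1;
    off_e0 = est_eps ? p : -1; if (est_eps) p += 1;
    off_t0 = p; p += 1;
    off_za = est_alpha_field ? p : -1; if (est_alpha_field) p += m;
    off_ze = (est_eps && est_eps_field) ? p : -1; if (est_eps && est_eps_field) p += m;
    off_zt = est_tau_field ? p : -1; if (est_tau_field) p += m;
    off_g  = est_gamma ? p : -1; if (est_gamma) p += ncell * (nyear - 1);
    off_w  = est_kappa ? p : -1; if (est_kappa) p += (ncirc - 1);
    npar = p;
  }
};

struct FieldRef { int off, n; };  // coefficient block of one field

static FieldRef field_ref(const ModelData& md, int f) {
  switch (f) {
    case ModelData::SA: return {md.off_za, md.m};
    case ModelData::SE: return {md.off_ze, md.m};
    case ModelData::ST: return {md.off_zt, md.m};
    case ModelData::SG: return {md.off_g, md.ncell * (md.nyear - 1)};
    default:            return {md.off_w, md.ncirc - 1};
  }
}

// NB log likelihood given whitened coefficient vector and field scales
static double loglik(const ModelData& md, const vec& th, const vec& sig,
                     double phi) {
  double e0 = md.est_eps ? th(md.off_e0) : 0.0;
  double t0 = th(md.off_t0);
  double a0 = th(md.off_a0) - (md.est_eps ? e0 * md.mlE : 0.0) - t0 * md.mT;
  vec alpha(md.ncell, fill::value(a0)), epsv(md.ncell), tauv(md.ncell, fill::value(t0));
  epsv.fill(md.est_eps ? e0 : md.fix_eps);
  if (md.est_alpha_field)
    alpha += sig(ModelData::SA) *
             (md.B * th.subvec(md.off_za, md.off_za + md.m - 1));
  if (md.est_eps && md.est_eps_field)
    epsv += sig(ModelData::SE) *
            (md.B * th.subvec(md.off_ze, md.off_ze + md.m - 1));
  if (md.est_tau_field)
    tauv += sig(ModelData::ST) *
            (md.B * th.subvec(md.off_zt, md.off_zt + md.m - 1));
  mat gam(md.ncell, md.nyear, fill::zeros);
  if (md.est_gamma) {
    mat G = reshape(th.subvec(md.off_g, md.off_g + md.ncell * (md.nyear - 1) - 1),
                    md.ncell, md.nyear - 1);
    gam = sig(ModelData::SG) * (G * md.Cg.t());
  }
  vec kap(md.ncirc, fill::zeros);
  if (md.est_kappa)
    kap = sig(ModelData::SK) *
          (md.Dk * th.subvec(md.off_w, md.off_w + md.ncirc - 2));

  double lp = 0.0;
  const int n = md.y.n_elem;
  for (int o = 0; o < n; ++o) {
    int c = md.cell(o), t = md.yearidx(o), k = md.circ(o);
    double eta = alpha(c) + epsv(c) * md.logE(o) + tauv(c) * md.Tt(o)
               + gam(c, t) + kap(k);
    double mu = std::exp(eta);
    if (!std::isfinite(mu)) return -datum::inf;
    double yo = md.y(o);
    lp += std::lgamma(yo + phi) - std::lgamma(phi) - std::lgamma(yo + 1.0)
        + phi * std::log(phi) + yo * eta - (yo + phi) * std::log(mu + phi);
  }
  return lp;
}

// log posterior over coefficients (sigmas, phi fixed) and its gradient
static double logp_grad(const ModelData& md, const vec& th, const vec& sig,
                        double phi, vec& grad) {
  grad.zeros(md.npar);
  const int n = md.y.n_elem;
  double e0 = md.est_eps ? th(md.off_e0) : 0.0;
  double t0 = th(md.off_t0);
  double a0 = th(md.off_a0) - (md.est_eps ? e0 * md.mlE : 0.0) - t0 * md.mT;
  vec alpha(md.ncell, fill::value(a0)), epsv(md.ncell), tauv(md.ncell, fill::value(t0));
  epsv.fill(md.est_eps ? e0 : md.fix_eps);
  if (md.est_alpha_field)
    alpha += sig(ModelData::SA) *
             (md.B * th.subvec(md.off_za, md.off_za + md.m - 1));
  if (md.est_eps && md.est_eps_field)
    epsv += sig(ModelData::SE) *
            (md.B * th.subvec(md.off_ze, md.off_ze + md.m - 1));
  if (md.est_tau_field)
    tauv += sig(ModelData::ST) *
            (md.B * th.subvec(md.off_zt, md.off_zt + md.m - 1));
  mat gam(md.ncell, md.nyear, fill::zeros);
  if (md.est_gamma) {
    mat G = reshape(th.subvec(md.off_g, md.off_g + md.ncell * (md.nyear - 1) - 1),
                    md.ncell, md.nyear - 1);
    gam = sig(ModelData::SG) * (G * md.Cg.t());
  }
  vec kap(md.ncirc, fill::zeros);
  if (md.est_kappa)
    kap = sig(ModelData::SK) *
          (md.Dk * th.subvec(md.off_w, md.off_w + md.ncirc - 2));

  double lp = 0.0;
  vec s_a(md.ncell, fill::zeros), s_e(md.ncell, fill::zeros),
      s_t(md.ncell, fill::zeros);
  mat s_cy(md.ncell, md.nyear, fill::zeros);
  vec s_k(md.ncirc, fill::zeros);
  for (int o = 0; o < n; ++o) {
    int c = md.cell(o), t = md.yearidx(o), k = md.circ(o);
    double eta = alpha(c) + epsv(c) * md.logE(o) + tauv(c) * md.Tt(o)
               + gam(c, t) + kap(k);
    double mu = std::exp(eta);
    if (!std::isfinite(mu)) return -datum::inf;
    double yo = md.y(o);
    lp += std::lgamma(yo + phi) - std::lgamma(phi) - std::lgamma(yo + 1.0)
        + phi * std::log(phi) + yo * eta - (yo + phi) * std::log(mu + phi);
    double r = yo - (yo + phi) * mu / (mu + phi);
    s_a(c) += r;
    s_e(c) += r * md.logE(o);
    s_t(c) += r * md.Tt(o);
    s_cy(c, t) += r;
    s_k(k) += r;
  }
  if (!std::isfinite(lp)) return -datum::inf;

  double cs2 = md.center_sd * md.center_sd;
  lp += -0.5 * a0 * a0 / cs2 - 0.5 * t0 * t0 / cs2;
  double g_a0 = accu(s_a) - a0 / cs2;
  double g_t0 = accu(s_t) - t0 / cs2;
  grad(md.off_a0) = g_a0;
  grad(md.off_t0) = g_t0 - md.mT * g_a0;
  if (md.est_eps) {
    lp += -0.5 * e0 * e0 / cs2;
    grad(md.off_e0) = accu(s_e) - e0 / cs2 - md.mlE * g_a0;
  }
  auto prior_block = [&](int f, const vec& lik_grad) {
    FieldRef fr = field_ref(md, f);
    vec z = th.subvec(fr.off, fr.off + fr.n - 1);
    lp += -0.5 * dot(z, z);
    grad.subvec(fr.off, fr.off + fr.n - 1) = sig(f) * lik_grad - z;
  };
  if (md.est_alpha_field) prior_block(ModelData::SA, md.B.t() * s_a);
  if (md.est_eps && md.est_eps_field) prior_block(ModelData::SE, md.B.t() * s_e);
  if (md.est_tau_field) prior_block(ModelData::ST, md.B.t() * s_t);
  if (md.est_gamma) prior_block(ModelData::SG, vectorise(s_cy * md.Cg));
  if (md.est_kappa) prior_block(ModelData::SK, md.Dk.t() * s_k);
  return lp;
}

// generic univariate slice sampler on an unnormalized log density
template <typename F>
static double slice_sample(F logf, double x0, double w, int max_step,
                           std::mt19937_64& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double f0 = logf(x0);
  if (!std::isfinite(f0)) return x0;
  double logy = f0 + std::log(U(rng));
  double L = x0 - w * U(rng), R = L + w;
  for (int i = 0; i < max_step && logf(L) > logy; ++i) L -= w;
  for (int i = 0; i < max_step && logf(R) > logy; ++i) R += w;
  for (int i = 0; i < 100; ++i) {
    double x1 = L + U(rng) * (R - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// log prior of sigma in theta = log(sigma) coordinates (incl. Jacobian)
static double lprior_lsig(double ls, double lambda) {
  return -lambda * std::exp(ls) + ls;
}

static double lprior_lphi(const ModelData& md, double lphi) {
  if (md.phi_pc) return -0.5 * lphi - md.phi_l * std::exp(-0.5 * lphi);
  return md.phi_shape * lphi - md.phi_rate * std::exp(lphi);
}

// [[Rcpp::export]]
Rcpp::List nb_svc_hmc(
    const arma::vec& y, const arma::vec& logE, const arma::vec& Tt,
    const arma::uvec& cell, const arma::uvec& yearidx, const arma::uvec& circ,
    const arma::mat& B, const arma::mat& Cg, const arma::mat& Dk,
    int ncell, int nyear, int ncirc,
    bool est_alpha_field, bool est_eps, bool est_eps_field,
    bool est_tau_field, bool est_gamma, bool est_kappa,
    double fix_eps, double fix_phi,
    double lambda_sd, double center_sd, double mlE, double mT,
    bool phi_pc, double phi_l, double phi_shape, double phi_rate,
    int iter, int warmup, int max_leapfrog, double target_accept,
    double init_eps, int seed) {

  ModelData md;
  md.y = y; md.logE = logE; md.Tt = Tt;
  md.cell = cell; md.yearidx = yearidx; md.circ = circ;
  md.B = B; md.Cg = Cg; md.Dk = Dk;
  md.ncell = ncell; md.nyear = nyear; md.ncirc = ncirc;
  md.est_alpha_field = est_alpha_field; md.est_eps = est_eps;
  md.est_eps_field = est_eps_field; md.est_tau_field = est_tau_field;
  md.est_gamma = est_gamma; md.est_kappa = est_kappa;
  md.est_phi = fix_phi <= 0;
  md.fix_eps = fix_eps; md.fix_phi = fix_phi;
  md.lambda_sd = lambda_sd; md.center_sd = center_sd;
  md.mlE = mlE; md.mT = mT;
  md.phi_pc = phi_pc; md.phi_l = phi_l;
  md.phi_shape = phi_shape; md.phi_rate = phi_rate;
  md.layout();

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  bool active[5] = {est_alpha_field, est_eps && est_eps_field, est_tau_field,
                    est_gamma, est_kappa};
  vec sig(5);
  sig(0) = 0.3; sig(1) = 0.1; sig(2) = 0.05; sig(3) = 0.1; sig(4) = 0.2;
  double phi = md.est_phi ? 1.0 : md.fix_phi;

  vec th(md.npar, fill::zeros);
  for (int i = 0; i < md.npar; ++i) th(i) = 0.05 * rnorm01(rng);
  if (md.est_eps) th(md.off_e0) = 1.0 + 0.1 * rnorm01(rng);

  vec grad(md.npar), grad_prop(md.npar);
  double lp = logp_grad(md, th, sig, phi, grad);
  if (!std::isfinite(lp)) Rcpp::stop("non-finite log posterior at initial values");

  // dual averaging (Hoffman & Gelman)
  double eps = init_eps, log_eps_bar = std::log(eps), Hbar = 0.0;
  double mu_da = std::log(10.0 * eps);
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int da_count = 0;

  vec Minv(md.npar, fill::ones);
  vec msum(md.npar, fill::zeros), msum2(md.npar, fill::zeros);
  int mcount = 0;
  int w1 = static_cast<int>(0.30 * warmup), w2 = static_cast<int>(0.90 * warmup);

  int nkeep = md.npar + 5 + 1;   // coefficients + log sigmas + log phi
  mat draws(iter, nkeep);
  int divergences = 0, n_accept = 0;

  for (int it = 0; it < warmup + iter; ++it) {
    bool warm = it < warmup;

    // --- HMC update of coefficients given (sigma, phi)
    vec p(md.npar);
    for (int i = 0; i < md.npar; ++i) p(i) = rnorm01(rng) / std::sqrt(Minv(i));
    double H0 = -lp + 0.5 * dot(square(p), Minv);
    int Lmin = std::max(1, max_leapfrog / 2);
    int L = Lmin + static_cast<int>(runif01(rng) * (max_leapfrog - Lmin + 1));
    if (L > max_leapfrog) L = max_leapfrog;

    vec th_p = th;
    grad_prop = grad;
    double lp_p = lp;
    bool bad = false;
    p += 0.5 * eps * grad_prop;
    for (int l = 0; l < L; ++l) {
      th_p += eps * (Minv % p);
      lp_p = logp_grad(md, th_p, sig, phi, grad_prop);
      if (!std::isfinite(lp_p)) { bad = true; break; }
      p += (l == L - 1 ? 0.5 : 1.0) * eps * grad_prop;
    }
    double accept_prob = 0.0;
    if (!bad) {
      double H1 = -lp_p + 0.5 * dot(square(p), Minv);
      double dH = H0 - H1;
      if (std::isfinite(dH)) {
        accept_prob = dH > 0 ? 1.0 : std::exp(dH);
        if (dH < -1000.0) { bad = true; accept_prob = 0.0; }
      } else bad = true;
    }
    if (bad && !warm) ++divergences;
    if (!bad && runif01(rng) < accept_prob) {
      th = th_p; lp = lp_p; grad = grad_prop;
      if (!warm) ++n_accept;
    }

    // --- sigma updates: ancillary conditional, then sufficient conditional
    for (int f = 0; f < 5; ++f) {
      if (!active[f]) continue;
      FieldRef fr = field_ref(md, f);
      vec z = th.subvec(fr.off, fr.off + fr.n - 1);   // whitened
      // (a) sigma | whitened z, y: the likelihood moves with sigma
      auto lf_anc = [&](double ls) {
        vec sig_try = sig; sig_try(f) = std::exp(ls);
        return loglik(md, th, sig_try, phi) + lprior_lsig(ls, md.lambda_sd);
      };
      sig(f) = std::exp(slice_sample(lf_anc, std::log(sig(f)), 0.3, 15, rng));
      // (b) sigma | centered coefficients: Gaussian sufficient statistic;
      // the whitened coordinates rescale to keep the centered field fixed
      double ssq = sig(f) * sig(f) * dot(z, z);
      auto lf_suff = [&](double ls) {
        double s = std::exp(ls);
        return -fr.n * ls - 0.5 * ssq / (s * s) + lprior_lsig(ls, md.lambda_sd);
      };
      double ls2 = slice_sample(lf_suff, std::log(sig(f)), 0.5, 30, rng);
      th.subvec(fr.off, fr.off + fr.n - 1) = z * (sig(f) / std::exp(ls2));
      sig(f) = std::exp(ls2);
    }

    // --- phi update
    if (md.est_phi) {
      auto lf_phi = [&](double lphi) {
        return loglik(md, th, sig, std::exp(lphi)) + lprior_lphi(md, lphi);
      };
      double lphi = slice_sample(lf_phi, std::log(phi), 0.5, 20, rng);
      phi = std::exp(lphi);
    }
    lp = logp_grad(md, th, sig, phi, grad);

    if (warm) {
      ++da_count;
      double eta_h = 1.0 / (da_count + da_t0);
      Hbar = (1.0 - eta_h) * Hbar + eta_h * (target_accept - accept_prob);
      double log_eps = mu_da - std::sqrt(static_cast<double>(da_count)) /
                       da_gamma * Hbar;
      double w = std::pow(static_cast<double>(da_count), -da_kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (it >= w1 && it < w2) {
        msum += th; msum2 += square(th); ++mcount;
      }
      if (it == w2 - 1 && mcount > 10) {
        vec v = (msum2 - square(msum) / mcount) / (mcount - 1.0);
        double nreg = mcount;
        Minv = v * (nreg / (nreg + 5.0)) + 1e-3 * (5.0 / (nreg + 5.0));
        Minv = clamp(Minv, 1e-8, 1e8);
        mu_da = std::log(10.0 * std::exp(log_eps_bar));
        Hbar = 0.0; da_count = 0;
      }
      if (it == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      int r = it - warmup;
      draws.row(r).subvec(0, md.npar - 1) = th.t();
      for (int f = 0; f < 5; ++f)
        draws(r, md.npar + f) = active[f] ? std::log(sig(f)) : NA_REAL;
      draws(r, md.npar + 5) = md.est_phi ? std::log(phi) : NA_REAL;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("accept_rate") = iter > 0 ? double(n_accept) / iter : NA_REAL,
    Rcpp::Named("step_size") = eps,
    Rcpp::Named("divergences") = divergences,
    Rcpp::Named("npar") = md.npar,
    Rcpp::Named("offsets") = Rcpp::IntegerVector::create(
      Rcpp::Named("a0") = md.off_a0, Rcpp::Named("e0") = md.off_e0,
      Rcpp::Named("t0") = md.off_t0, Rcpp::Named("za") = md.off_za,
      Rcpp::Named("ze") = md.off_ze, Rcpp::Named("zt") = md.off_zt,
      Rcpp::Named("g") = md.off_g, Rcpp::Named("w") = md.off_w,
      Rcpp::Named("lsa") = est_alpha_field ? md.npar + 0 : -1,
      Rcpp::Named("lse") = (est_eps && est_eps_field) ? md.npar + 1 : -1,
      Rcpp::Named("lst") = est_tau_field ? md.npar + 2 : -1,
      Rcpp::Named("lsg") = est_gamma ? md.npar + 3 : -1,
      Rcpp::Named("lsk") = est_kappa ? md.npar + 4 : -1,
      Rcpp::Named("lphi") = md.est_phi ? md.npar + 5 : -1));
}
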