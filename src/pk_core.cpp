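// Three-compartment mammillary disposition with zero-order infusion input,
// solved by eigendecomposition of the rate matrix (distinct-eigenvalue case)
// with a matrix-exponential fallback for near-degenerate spectra, plus the
// per-subject Laplace inner step used by the population estimator.
//
// Units: amounts mg, volumes L, clearances L/h, time h. Concentrations are
// returned in mg/L; the R layer owns the single mg/L -> ng/mL conversion.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double EIG_GAP_REL = 1e-8;

struct Sys {
  unsigned int n;   // active compartments (central always first)
  mat A;
  double k10;
  double v1;
  bool use_eig;
  vec lam;          // eigenvalues, real
  mat W;            // eigenvectors
  vec q0;           // Winv * e1 (unit input into central)
};

static Sys build_sys(double cl, double v1, double v2, double v3,
                     double cld2, double cld3) {
  Sys S;
  S.k10 = cl / v1;
  S.v1 = v1;
  double k12 = cld2 / v1;
  double k21 = (v2 > 0.0) ? cld2 / v2 : 0.0;
  double k13 = cld3 / v1;
  double k31 = (v3 > 0.0) ? cld3 / v3 : 0.0;

  mat Afull(3, 3, fill::zeros);
  Afull(0, 0) = -(S.k10 + k12 + k13);
  Afull(0, 1) = k21;
  Afull(0, 2) = k31;
  Afull(1, 0) = k12;
  Afull(1, 1) = -k21;
  Afull(2, 0) = k13;
  Afull(2, 2) = -k31;

  uvec act;
  if (cld2 > 0.0 && cld3 > 0.0)      act = {0, 1, 2};
  else if (cld2 > 0.0)               act = {0, 1};
  else if (cld3 > 0.0)               act = {0, 2};
  else                               act = uvec{0};
  S.n = act.n_elem;
  S.A = Afull.submat(act, act);

  S.use_eig = false;
  cx_vec ev;
  cx_mat eW;
  if (eig_gen(ev, eW, S.A)) {
    double scale = max(abs(ev));
    if (scale <= 0.0) scale = 1.0;
    bool ok = max(abs(imag(ev))) <= EIG_GAP_REL * scale;
    if (ok) {
      for (unsigned int i = 0; ok && i + 1 < S.n; ++i)
        for (unsigned int j = i + 1; ok && j < S.n; ++j)
          if (std::abs(ev(i).real() - ev(j).real()) < EIG_GAP_REL * scale)
            ok = false;
    }
    if (ok) {
      S.lam = real(ev);
      S.W = real(eW);
      mat Winv;
      if (inv(Winv, S.W)) {
        S.q0 = Winv.col(0);
        S.use_eig = true;
      }
    }
  }
  return S;
}

// (exp(l t) - 1) / l, stable near l t = 0
static inline double phi1(double l, double t) {
  double x = l * t;
  if (std::abs(x) < 1e-10) return t;
  return std::expm1(x) / l;
}

// integral of phi1 from 0 to t: (phi1(l,t) - t) / l
static inline double phi2(double l, double t) {
  double x = l * t;
  if (std::abs(x) < 1e-8) return 0.5 * t * t;
  return (phi1(l, t) - t) / l;
}

// central amount a1 and its running integral z for ONE dose, tau >= 0 after
// dose start, infusion rate amt/dur over [0, dur]
static void single_dose(const Sys& S, double amt, double dur, double tau,
                        double& a1, double& z) {
  a1 = 0.0; z = 0.0;
  if (tau <= 0.0 || amt <= 0.0) return;
  double rate = amt / dur;

  if (S.use_eig) {
    double tin = std::min(tau, dur);
    for (unsigned int j = 0; j < S.n; ++j) {
      double c = S.W(0, j) * S.q0(j) * rate;
      double l = S.lam(j);
      if (tau <= dur) {
        a1 += c * phi1(l, tau);
        z  += c * phi2(l, tau);
      } else {
        double w = c * phi1(l, dur);          // post-infusion coefficient
        double s = tau - dur;
        a1 += w * std::exp(l * s);
        z  += c * phi2(l, tin) + w * phi1(l, s);
      }
    }
    return;
  }

  // fallback: augmented matrix exponential; states (a[n], u, z)
  try {
  unsigned int n = S.n;
  mat M(n + 2, n + 2, fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = S.A;
  M(0, n) = rate;       // u' = 0 drives the infusion
  M(n + 1, 0) = 1.0;    // z' = a1
  vec x0(n + 2, fill::zeros);
  x0(n) = 1.0;
  double tin = std::min(tau, dur);
  vec x = expmat(M * tin) * x0;
  if (tau <= dur) {
    a1 = x(0); z = x(n + 1);
    return;
  }
  // post-infusion: states (a[n], z), no input
  mat M2(n + 1, n + 1, fill::zeros);
  M2.submat(0, 0, n - 1, n - 1) = S.A;
  M2(n, 0) = 1.0;
  vec y0(n + 1);
  for (unsigned int i = 0; i < n; ++i) y0(i) = x(i);
  y0(n) = x(n + 1);
  vec y = expmat(M2 * (tau - dur)) * y0;
  a1 = y(0); z = y(n);
  } catch (const std::exception&) {
    a1 = datum::nan; z = datum::nan;
  }
}

static double conc_at(const Sys& S, const mat& doses, double t) {
  double tot = 0.0;
  for (unsigned int d = 0; d < doses.n_rows; ++d) {
    double tau = t - doses(d, 0);
    if (tau <= 0.0) continue;
    double a1, z;
    single_dose(S, doses(d, 1), doses(d, 2), tau, a1, z);
    tot += a1;
  }
  return tot / S.v1;
}

// [[Rcpp::export]]
arma::vec cpp_conc3(const arma::vec& pars, const arma::mat& doses,
                    const arma::vec& times) {
  Sys S = build_sys(pars(0), pars(1), pars(2), pars(3), pars(4), pars(5));
  vec out(times.n_elem, fill::zeros);
  if (doses.n_rows == 0) return out;
  for (unsigned int i = 0; i < times.n_elem; ++i)
    out(i) = conc_at(S, doses, times(i));
  return out;
}

static double cum_amt_int(const Sys& S, const mat& doses, double t) {
  double tot = 0.0;
  for (unsigned int d = 0; d < doses.n_rows; ++d) {
    double tau = t - doses(d, 0);
    if (tau <= 0.0) continue;
    double a1, z;
    single_dose(S, doses(d, 1), doses(d, 2), tau, a1, z);
    tot += z;
  }
  return tot;
}

// [[Rcpp::export]]
double cpp_auc3(const arma::vec& pars, const arma::mat& doses,
                double t0, double t1) {
  Sys S = build_sys(pars(0), pars(1), pars(2), pars(3), pars(4), pars(5));
  if (doses.n_rows == 0) return 0.0;
  double F1;
  if (std::isinf(t1)) {
    // elimination occurs only from the central compartment:
    // integral of a1 over (0, inf) per dose is amt / k10
    F1 = accu(doses.col(1)) / S.k10;
  } else {
    F1 = cum_amt_int(S, doses, t1);
  }
  double F0 = (t0 <= 0.0) ? 0.0 : cum_amt_int(S, doses, t0);
  return (F1 - F0) / S.v1;
}

// joint -2 log density contribution (2*pi constants dropped):
//   sum_j [ r_j^2/sigma^2 + log sigma^2 ] + eta' Oinv eta + logdet(Omega)
// typ = typical (cl, v1, v2, v3, cld2, cld3); eta acts on cl and v1
static double g_subject(const vec& eta, const vec& typ, const mat& doses,
                        const vec& obs_t, const vec& logdv_mgL,
                        double sigma, const mat& Oinv, double logdetO) {
  vec p = typ;
  p(0) = typ(0) * std::exp(eta(0));
  p(1) = typ(1) * std::exp(eta(1));
  Sys S = build_sys(p(0), p(1), p(2), p(3), p(4), p(5));
  double s2 = sigma * sigma;
  double g = dot(eta, Oinv * eta) + logdetO;
  for (unsigned int i = 0; i < obs_t.n_elem; ++i) {
    double c = conc_at(S, doses, obs_t(i));
    if (!(c > 0.0) || !std::isfinite(c)) return 1e100;
    double r = logdv_mgL(i) - std::log(c);
    g += r * r / s2 + std::log(s2);
  }
  return g;
}

// [[Rcpp::export]]
double cpp_g_subject(const arma::vec& eta, const arma::vec& typ,
                     const arma::mat& doses, const arma::vec& obs_t,
                     const arma::vec& logdv_mgL, double sigma,
                     const arma::mat& Oinv, double logdetO) {
  return g_subject(eta, typ, doses, obs_t, logdv_mgL, sigma, Oinv, logdetO);
}

// 2x2 central-difference Hessian and gradient of g at eta
static void grad_hess(const vec& eta, const vec& typ, const mat& doses,
                      const vec& obs_t, const vec& logdv, double sigma,
                      const mat& Oinv, double logdetO,
                      vec& gr, mat& H) {
  const double h = 1e-4;
  double g0 = g_subject(eta, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  vec e1 = {h, 0.0}, e2 = {0.0, h};
  double gp1 = g_subject(eta + e1, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  double gm1 = g_subject(eta - e1, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  double gp2 = g_subject(eta + e2, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  double gm2 = g_subject(eta - e2, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  double gpp = g_subject(eta + e1 + e2, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  double gpm = g_subject(eta + e1 - e2, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  double gmp = g_subject(eta - e1 + e2, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  double gmm = g_subject(eta - e1 - e2, typ, doses, obs_t, logdv, sigma, Oinv, logdetO);
  gr = {(gp1 - gm1) / (2 * h), (gp2 - gm2) / (2 * h)};
  H.set_size(2, 2);
  H(0, 0) = (gp1 - 2 * g0 + gm1) / (h * h);
  H(1, 1) = (gp2 - 2 * g0 + gm2) / (h * h);
  H(0, 1) = H(1, 0) = (gpp - gpm - gmp + gmm) / (4 * h * h);
}

// Newton minimization of g over eta with ridge damping and step halving;
// returns eta_hat, g(eta_hat) and logdet(H/2) for the Laplace correction
// [[Rcpp::export]]
Rcpp::List cpp_inner_laplace(const arma::vec& typ, const arma::mat& doses,
                             const arma::vec& obs_t, const arma::vec& logdv_mgL,
                             double sigma, const arma::mat& Omega,
                             const arma::vec& eta_start,
                             int maxit = 50, double tol = 1e-8) {
  mat Om = symmatu(Omega);
  mat Oinv;
  if (!inv_sympd(Oinv, Om)) {
    Om += 1e-10 * (1.0 + trace(Om)) * eye(2, 2);
    if (!inv_sympd(Oinv, Om)) Rcpp::stop("Omega is singular");
  }
  double ld_o, sgn_o;
  log_det(ld_o, sgn_o, Om);
  double logdetO = ld_o;
  vec eta = eta_start;
  double g0 = g_subject(eta, typ, doses, obs_t, logdv_mgL, sigma, Oinv, logdetO);
  if (g0 >= 1e99) { eta.zeros(); g0 = g_subject(eta, typ, doses, obs_t, logdv_mgL, sigma, Oinv, logdetO); }
  vec gr(2);
  mat H(2, 2);
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    grad_hess(eta, typ, doses, obs_t, logdv_mgL, sigma, Oinv, logdetO, gr, H);
    mat Hp = H;
    double ridge = 0.0;
    while (!Hp.is_sympd()) {
      ridge = (ridge == 0.0) ? 1e-6 * (1.0 + std::abs(Hp(0,0)) + std::abs(Hp(1,1))) : ridge * 10.0;
      Hp = H + ridge * eye(2, 2);
      if (ridge > 1e8) break;
    }
    vec step = -solve(Hp, gr);
    double alpha = 1.0, gnew = 0.0;
    bool improved = false;
    for (int ls = 0; ls < 20; ++ls) {
      gnew = g_subject(eta + alpha * step, typ, doses, obs_t, logdv_mgL,
                       sigma, Oinv, logdetO);
      if (gnew < g0) { improved = true; break; }
      alpha *= 0.5;
    }
    if (!improved) { conv = norm(gr) < 1e-3; break; }
    eta += alpha * step;
    double dg = g0 - gnew;
    g0 = gnew;
    if (dg < tol && norm(alpha * step) < 1e-6) { conv = true; break; }
  }
  grad_hess(eta, typ, doses, obs_t, logdv_mgL, sigma, Oinv, logdetO, gr, H);
  mat Hh = 0.5 * H;
  double ld, sign;
  log_det(ld, sign, Hh);
  if (sign <= 0.0) {
    // force PD for the correction term if curvature is numerically indefinite
    vec evs = eig_sym(Hh);
    double bump = std::max(1e-8, 1e-8 - evs.min());
    log_det(ld, sign, Hh + bump * eye(2, 2));
  }
  return Rcpp::List::create(Rcpp::Named("eta") = eta,
                            Rcpp::Named("g") = g0,
                            Rcpp::Named("logdet_half_hess") = ld,
                            Rcpp::Named("converged") = conv);
}

// population Laplace OFV: sum over subjects of g(eta_hat) + logdet(H/2).
// subjects: list of list(doses, obs_t, logdv) with logdv on log mg/L scale;
// typ: n x 6 matrix of per-subject typical parameters
// [[Rcpp::export]]
Rcpp::List cpp_pop_ofv(const Rcpp::List& subjects, const arma::mat& typ,
                       double sigma, const arma::mat& Omega,
                       const arma::mat& eta_start) {
  unsigned int n = subjects.size();
  vec ofv_i(n, fill::zeros);
  mat etas(n, 2, fill::zeros);
  for (unsigned int i = 0; i < n; ++i) {
    Rcpp::List s = subjects[i];
    mat doses = Rcpp::as<mat>(s["doses"]);
    vec obs_t = Rcpp::as<vec>(s["obs_t"]);
    vec logdv = Rcpp::as<vec>(s["logdv"]);
    vec typ_i = typ.row(i).t();
    vec e0 = eta_start.row(i).t();
    Rcpp::List r = cpp_inner_laplace(typ_i, doses, obs_t, logdv, sigma,
                                     Omega, e0);
    ofv_i(i) = Rcpp::as<double>(r["g"]) + Rcpp::as<double>(r["logdet_half_hess"]);
    vec eh = Rcpp::as<vec>(r["eta"]);
    etas.row(i) = eh.t();
  }
  return Rcpp::List::create(Rcpp::Named("ofv") = accu(ofv_i),
                            Rcpp::Named("ofv_i") = ofv_i,
                            Rcpp::Named("etas") = etas);
}
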