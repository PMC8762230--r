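// Compiled core: structural ODE model, Dormand-Prince 5(4) integrator with
// dose-event handling, and the Laplace/FOCE-I per-subject machinery.
//
// States: 0 A_gut (mg), 1 A1 parent central (mg), 2 A2 metabolite (mg),
//         3 cumAUC1 (mg*h/L), 4 cumAUC2 (mg*h/L).
#include <RcppArmadillo.h>

using namespace Rcpp;

static const int NSTATE = 5;

struct Pars {
  double F, ka, V1, CL1, V2, Vmax, Km, CL2, Imax, IC50, kn;
};

static inline Pars as_pars(const double* p) {
  Pars q;
  q.F = p[0]; q.ka = p[1]; q.V1 = p[2]; q.CL1 = p[3]; q.V2 = p[4];
  q.Vmax = p[5]; q.Km = p[6]; q.CL2 = p[7]; q.Imax = p[8]; q.IC50 = p[9];
  q.kn = p[10];
  return q;
}

static inline void rhs(const double* y, double* dy, const Pars& p) {
  const double C1 = y[1] / p.V1;
  const double C2 = y[2] / p.V2;
  const double clnl = p.Vmax / (C1 + p.Km) * (1.0 - p.Imax * C2 / (p.IC50 + C2));
  dy[0] = -p.ka * y[0];
  dy[1] = p.F * p.ka * y[0] - (p.CL1 + clnl) / p.V1 * y[1];
  dy[2] = clnl / p.V1 * y[1] * p.kn - p.CL2 / p.V2 * y[2];
  dy[3] = C1;
  dy[4] = C2;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate y over [t0, t1]; throws on step-size collapse or negative states.
static void integrate_seg(double* y, double t0, double t1, const Pars& p,
                          double rtol, double atol, double* hcarry,
                          double hfix) {
  if (t1 <= t0) return;
  double t = t0;
  // fixed-step mode: a parameter-independent step sequence keeps the
  // objective surface smooth for finite-difference outer gradients
  const bool fixed = hfix > 0.0;
  int nfix = 0, ifix = 0;
  double h;
  if (fixed) {
    nfix = (int)std::ceil((t1 - t0) / hfix);
    h = (t1 - t0) / nfix;
  } else {
    h = std::min(*hcarry, t1 - t0);
  }
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
      k6[NSTATE], k7[NSTATE], yt[NSTATE], y5[NSTATE];
  bool have_k1 = false;
  int nstep = 0;
  while (t < t1) {
    if (++nstep > 1000000)
      stop("ODE solver failed: step count exceeded at t=%g", t);
    if (!fixed && h > t1 - t) h = t1 - t;
    if (!have_k1) rhs(y, k1, p);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(yt, k2, p);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(yt, k3, p);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(yt, k4, p);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(yt, k5, p);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(yt, k6, p);
    for (int i = 0; i < NSTATE; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    rhs(y5, k7, p);
    double err = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      const double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                    e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      const double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / NSTATE);
    if (fixed) {
      if (!std::isfinite(err))
        stop("ODE solver failed: non-finite state at t=%g", t);
      ++ifix;
      t = t0 + ifix * h;
      if (ifix == nfix) t = t1;
      for (int i = 0; i < NSTATE; ++i) {
        y[i] = y5[i];
        k1[i] = k7[i];
      }
      have_k1 = true;
      continue;
    }
    if (!std::isfinite(err)) {
      h *= 0.2;
      if (h < 1e-12)
        stop("ODE solver failed: non-finite state at t=%g", t);
      have_k1 = true;
      continue;
    }
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NSTATE; ++i) {
        y[i] = y5[i];
        k1[i] = k7[i];  // FSAL
      }
      have_k1 = true;
    } else {
      have_k1 = true;  // k1 still valid at unchanged y
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12)
      stop("ODE solver failed: step size underflow at t=%g", t);
  }
  if (!fixed) *hcarry = h;
  for (int i = 0; i < NSTATE; ++i)
    if (y[i] < -1e-9)
      stop("ODE solver produced negative state %d (%g) at t=%g", i + 1, y[i],
           t1);
}

// Simulate one subject: instantaneous oral doses into A_gut, record the full
// state at each observation time. Observations at a dose time are pre-dose.
static void simulate_subject(const double* dose_t, const double* dose_a,
                             int ndose, const double* obs_t, int nobs,
                             const Pars& p, double rtol, double atol,
                             double hfix,
                             double* out /* nobs x NSTATE, col-major */) {
  double y[NSTATE] = {0, 0, 0, 0, 0};
  double t = 0.0;
  double hcarry = 1.0;
  int io = 0, id = 0;
  while (io < nobs || id < ndose) {
    double tn;
    if (io < nobs && id < ndose)
      tn = std::min(obs_t[io], dose_t[id]);
    else if (io < nobs)
      tn = obs_t[io];
    else
      tn = dose_t[id];
    if (tn < t) stop("event times must be nondecreasing (t=%g after %g)", tn, t);
    if (hfix > 0.0) {
      // the fixed grid is only a smoothness device; individual parameter
      // draws can make the system too stiff for it, in which case the
      // segment falls back to the adaptive stepper
      double ysave[NSTATE];
      for (int i = 0; i < NSTATE; ++i) ysave[i] = y[i];
      try {
        integrate_seg(y, t, tn, p, rtol, atol, &hcarry, hfix);
      } catch (...) {
        for (int i = 0; i < NSTATE; ++i) y[i] = ysave[i];
        double hc = std::min(hcarry, 0.25);
        integrate_seg(y, t, tn, p, rtol, atol, &hc, 0.0);
      }
    } else {
      integrate_seg(y, t, tn, p, rtol, atol, &hcarry, hfix);
    }
    t = tn;
    while (io < nobs && obs_t[io] == tn) {
      for (int s = 0; s < NSTATE; ++s) out[io + s * nobs] = y[s];
      ++io;
    }
    bool dosed = false;
    while (id < ndose && dose_t[id] == tn) {
      y[0] += dose_a[id];
      ++id;
      dosed = true;
    }
    if (dosed) hcarry = std::min(hcarry, 0.25);  // restart across the jump
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_solve_profile(NumericVector dose_t, NumericVector dose_a,
                                NumericVector obs_t, NumericVector pars,
                                double rtol, double atol, double hfix = 0.0) {
  if (pars.size() != 11) stop("pars must have 11 elements");
  const Pars p = as_pars(REAL(pars));
  const int nobs = obs_t.size();
  NumericMatrix out(nobs, NSTATE);
  simulate_subject(REAL(dose_t), REAL(dose_a), dose_t.size(), REAL(obs_t),
                   nobs, p, rtol, atol, hfix, REAL(out));
  colnames(out) = CharacterVector::create("A_gut", "A1", "A2", "cumAUC1",
                                          "cumAUC2");
  return out;
}

// Batch simulation: one row of `pars` per subject, shared dosing schedule and
// observation times. Returns concentration and cumulative-AUC matrices.
// [[Rcpp::export]]
List cpp_simulate_multi(NumericMatrix pars, NumericVector dose_t,
                        NumericVector dose_a, NumericVector obs_t, double rtol,
                        double atol, double hfix = 0.0) {
  if (pars.ncol() != 11) stop("pars must have 11 columns");
  const int n = pars.nrow(), m = obs_t.size();
  NumericMatrix C1(n, m), C2(n, m), AUC1(n, m), AUC2(n, m);
  std::vector<double> out(m * NSTATE);
  for (int i = 0; i < n; ++i) {
    double pv[11];
    for (int k = 0; k < 11; ++k) pv[k] = pars(i, k);
    const Pars p = as_pars(pv);
    simulate_subject(REAL(dose_t), REAL(dose_a), dose_t.size(), REAL(obs_t),
                     m, p, rtol, atol, hfix, out.data());
    for (int j = 0; j < m; ++j) {
      C1(i, j) = out[j + 1 * m] / p.V1;
      C2(i, j) = out[j + 2 * m] / p.V2;
      AUC1(i, j) = out[j + 3 * m];
      AUC2(i, j) = out[j + 4 * m];
    }
  }
  return List::create(_["C1"] = C1, _["C2"] = C2, _["cumAUC1"] = AUC1,
                      _["cumAUC2"] = AUC2);
}

// ---------------------------------------------------------------------------
// FOCE-I inner machinery
// ---------------------------------------------------------------------------

struct Subject {
  std::vector<double> dose_t, dose_a, obs_t, y;
  std::vector<int> analyte;  // 1 = parent, 2 = metabolite
};

// typical parameters (V1, CL1, CL2, Vmax) scaled by exp(eta)
static inline Pars subject_pars(const arma::rowvec& typ, const double* fixedp,
                                const arma::vec& eta) {
  Pars p;
  p.F = fixedp[0]; p.ka = fixedp[1]; p.V2 = fixedp[2]; p.Km = fixedp[3];
  p.Imax = fixedp[4]; p.IC50 = fixedp[5]; p.kn = fixedp[6];
  p.V1 = typ[0] * std::exp(eta[0]);
  p.CL1 = typ[1] * std::exp(eta[1]);
  p.CL2 = typ[2] * std::exp(eta[2]);
  p.Vmax = typ[3] * std::exp(eta[3]);
  return p;
}

static long g_predict_calls = 0;

// [[Rcpp::export]]
double cpp_predict_calls() { return (double)g_predict_calls; }

static void predict(const Subject& s, const Pars& p, double rtol, double atol,
                    double hfix, arma::vec& f) {
  ++g_predict_calls;
  const int m = (int)s.obs_t.size();
  std::vector<double> out(m * NSTATE);
  simulate_subject(s.dose_t.data(), s.dose_a.data(), (int)s.dose_t.size(),
                   s.obs_t.data(), m, p, rtol, atol, hfix, out.data());
  for (int j = 0; j < m; ++j)
    f[j] = (s.analyte[j] == 1) ? out[j + 1 * m] / p.V1 : out[j + 2 * m] / p.V2;
}

// residual variances; errmodel per analyte: 1 additive, 2 proportional,
// 3 combined. sig(analyte-1, 0) additive sd, sig(analyte-1, 1) proportional sd
static void res_var(const Subject& s, const arma::vec& f, const arma::mat& sig,
                    const arma::ivec& errmodel, arma::vec& v) {
  for (size_t j = 0; j < s.y.size(); ++j) {
    const int a = s.analyte[j] - 1;
    double vj = 0.0;
    if (errmodel[a] == 1)
      vj = sig(a, 0) * sig(a, 0);
    else if (errmodel[a] == 2)
      vj = sig(a, 1) * sig(a, 1) * f[j] * f[j];
    else
      vj = sig(a, 0) * sig(a, 0) + sig(a, 1) * sig(a, 1) * f[j] * f[j];
    v[j] = std::max(vj, 1e-12);
  }
}

// d v / d f per observation (0 for additive error)
static void res_var_df(const Subject& s, const arma::vec& f,
                       const arma::mat& sig, const arma::ivec& errmodel,
                       arma::vec& dv) {
  for (size_t j = 0; j < s.y.size(); ++j) {
    const int a = s.analyte[j] - 1;
    dv[j] = (errmodel[a] == 1) ? 0.0 : 2.0 * sig(a, 1) * sig(a, 1) * f[j];
  }
}

// -2 log joint density (observations + eta prior), diagonal Omega
static double m_obj(const Subject& s, const arma::vec& f, const arma::vec& v,
                    const arma::vec& eta, const arma::vec& omega2,
                    const arma::uvec& act) {
  double m = 0.0;
  for (size_t j = 0; j < s.y.size(); ++j) {
    const double r = s.y[j] - f[j];
    m += std::log(2.0 * M_PI * v[j]) + r * r / v[j];
  }
  for (size_t k = 0; k < act.n_elem; ++k) {
    const unsigned a = act[k];
    m += std::log(2.0 * M_PI * omega2[a]) + eta[a] * eta[a] / omega2[a];
  }
  return m;
}

// finite-difference sensitivities of f wrt active etas
static void sens(const Subject& s, const arma::rowvec& typ,
                 const double* fixedp, const arma::vec& eta,
                 const arma::vec& f0, const arma::uvec& act, double rtol,
                 double atol, double hfix, arma::mat& G) {
  const double del = 1e-4;
  const int m = (int)s.obs_t.size();
  arma::vec fp(m), fm(m);
  for (size_t k = 0; k < act.n_elem; ++k) {
    arma::vec ep = eta, em = eta;
    ep[act[k]] += del;
    em[act[k]] -= del;
    predict(s, subject_pars(typ, fixedp, ep), rtol, atol, hfix, fp);
    predict(s, subject_pars(typ, fixedp, em), rtol, atol, hfix, fm);
    G.col(k) = (fp - fm) / (2.0 * del);
  }
}

struct InnerResult {
  double ofv;
  arma::vec eta;
  bool converged;
  arma::vec f, v;
  arma::mat G;
};

// Gauss-Newton (Levenberg-damped) search for the conditional mode of eta,
// followed by the Laplace/FOCE-I objective contribution.
static InnerResult inner_fit(const Subject& s, const arma::rowvec& typ,
                             const double* fixedp, const arma::vec& omega2,
                             const arma::mat& sig, const arma::ivec& errmodel,
                             arma::vec eta, double rtol, double atol,
                             double hfix, int maxit, double tol_eta) {
  const int m = (int)s.obs_t.size();
  InnerResult res;
  arma::uvec act = arma::find(omega2 > 0.0);
  const int q = (int)act.n_elem;
  for (unsigned k = 0; k < 4; ++k)
    if (omega2[k] <= 0.0) eta[k] = 0.0;

  arma::vec f(m), v(m);
  if (m == 0) {
    res.ofv = 0.0;
    res.eta = arma::zeros(4);
    res.converged = true;
    return res;
  }
  predict(s, subject_pars(typ, fixedp, eta), rtol, atol, hfix, f);
  res_var(s, f, sig, errmodel, v);
  double mcur = m_obj(s, f, v, eta, omega2, act);

  bool converged = (q == 0);
  arma::mat G(m, std::max(q, 1));
  // the Gauss-Newton iteration converges linearly (the Hessian is only
  // approximate), so the Jacobian is frozen between refreshes: recomputing
  // it every iteration costs 2q simulations for no faster convergence
  arma::vec eta_at_G(4, arma::fill::zeros);
  bool haveG = false;
  if (q > 0) {
    double lambda = 0.0;
    for (int it = 0; it < maxit; ++it) {
      double drift = 0.0;
      for (int k = 0; k < 4; ++k)
        drift = std::max(drift, std::fabs(eta[k] - eta_at_G[k]));
      if (!haveG || drift > 0.05 || it % 5 == 4) {
        sens(s, typ, fixedp, eta, f, act, rtol, atol, hfix, G);
        eta_at_G = eta;
        haveG = true;
      }
      arma::vec r(m), dv(m);
      for (int j = 0; j < m; ++j) r[j] = s.y[j] - f[j];
      res_var_df(s, f, sig, errmodel, dv);
      // -(1/2) gradient of the full conditional objective, including the
      // eta-interaction of the residual variance (log v and 1/v terms)
      arma::vec wr(m);
      for (int j = 0; j < m; ++j)
        wr[j] = r[j] / v[j] -
                0.5 * dv[j] * (1.0 / v[j] - r[j] * r[j] / (v[j] * v[j]));
      arma::mat A = G.t() * (G.each_col() / v);
      arma::vec b = G.t() * wr;
      for (int k = 0; k < q; ++k) {
        A(k, k) += 1.0 / omega2[act[k]];
        b[k] -= eta[act[k]] / omega2[act[k]];
      }
      if (arma::abs(b).max() < 1e-7 * (1.0 + std::fabs(mcur))) {
        converged = true;
        break;
      }
      bool accepted = false;
      double stepmax = 0.0;
      for (int tries = 0; tries < 8 && !accepted; ++tries) {
        arma::mat Ad = A;
        if (lambda > 0.0) Ad.diag() += lambda * A.diag();
        arma::vec d;
        if (!arma::solve(d, Ad, b, arma::solve_opts::likely_sympd)) {
          lambda = std::max(1e-3, lambda * 10.0);
          continue;
        }
        // trust-region style clamp: huge eta excursions make the ODE
        // system arbitrarily stiff and are never accepted anyway
        const double dmax = arma::abs(d).max();
        if (dmax > 2.0) d *= 2.0 / dmax;
        if (dmax < tol_eta) {  // proposed step below tolerance: at the mode
          converged = true;
          break;
        }
        // backtracking line search along the damped descent direction
        double alpha = 1.0;
        for (int ls = 0; ls < 14; ++ls, alpha *= 0.5) {
          arma::vec etat = eta;
          for (int k = 0; k < q; ++k) etat[act[k]] += alpha * d[k];
          arma::vec ft(m), vt(m);
          bool sim_ok = true;
          try {
            predict(s, subject_pars(typ, fixedp, etat), rtol, atol, hfix, ft);
          } catch (...) {
            sim_ok = false;
          }
          if (!sim_ok) continue;
          res_var(s, ft, sig, errmodel, vt);
          const double mt = m_obj(s, ft, vt, etat, omega2, act);
          if (mt <= mcur + 1e-10) {
            eta = etat;
            f = ft;
            v = vt;
            mcur = mt;
            stepmax = alpha * arma::abs(d).max();
            accepted = true;
            if (alpha == 1.0) lambda = (lambda > 1e-8) ? lambda / 3.0 : 0.0;
            break;
          }
        }
        if (!accepted) lambda = std::max(1e-3, lambda * 10.0);
      }
      if (converged) break;
      if (!accepted) break;  // flat to machine precision: current eta is it
      if (stepmax < tol_eta) {
        converged = true;
        break;
      }
    }
  }

  // Laplace correction at the mode; refresh the Jacobian if the mode moved
  // appreciably since it was last evaluated
  double ofv = mcur;
  arma::mat Gfin(m, std::max(q, 1));
  if (q > 0) {
    double drift = 0.0;
    for (int k = 0; k < 4; ++k)
      drift = std::max(drift, std::fabs(eta[k] - eta_at_G[k]));
    if (!haveG || drift > 3e-4)
      sens(s, typ, fixedp, eta, f, act, rtol, atol, hfix, G);
    arma::mat A = G.t() * (G.each_col() / v);
    for (int k = 0; k < q; ++k) A(k, k) += 1.0 / omega2[act[k]];
    double ldet, sign;
    arma::log_det(ldet, sign, A);
    if (sign <= 0.0) stop("non-positive-definite conditional Hessian");
    ofv += ldet - q * std::log(2.0 * M_PI);
    Gfin = G;
  } else {
    Gfin.zeros(m, 1);
  }

  res.ofv = ofv;
  res.eta = eta;
  res.converged = converged;
  res.f = f;
  res.v = v;
  res.G = Gfin;
  return res;
}

static std::vector<Subject> unpack_subjects(const List& subj) {
  const int n = subj.size();
  std::vector<Subject> out(n);
  for (int i = 0; i < n; ++i) {
    List si = subj[i];
    out[i].dose_t = as<std::vector<double>>(si["dose_t"]);
    out[i].dose_a = as<std::vector<double>>(si["dose_a"]);
    out[i].obs_t = as<std::vector<double>>(si["obs_t"]);
    out[i].y = as<std::vector<double>>(si["y"]);
    out[i].analyte = as<std::vector<int>>(si["analyte"]);
  }
  return out;
}

// FOCE-I objective over all subjects.
//   typicals: n x 4 covariate-adjusted typical values (V1, CL1, CL2, Vmax)
//   fixedp:   F, ka, V2, Km, Imax, IC50, kn
//   omega2:   4 IIV variances (0 fixes the eta at 0)
//   sig:      2 x 2 (rows: parent, metabolite; cols: additive sd, prop sd)
//   errmodel: per analyte, 1 additive / 2 proportional / 3 combined
// [[Rcpp::export]]
List cpp_foce_ofv(List subjects, NumericMatrix typicals, NumericVector fixedp,
                  NumericVector omega2, NumericMatrix sig,
                  IntegerVector errmodel, NumericMatrix eta_init, double rtol,
                  double atol, int maxit, double tol_eta, bool return_cond,
                  double hfix = 0.0) {
  std::vector<Subject> subj = unpack_subjects(subjects);
  const int n = (int)subj.size();
  if (typicals.nrow() != n || eta_init.nrow() != n)
    stop("typicals/eta_init rows must match subject count");
  arma::mat typ(typicals.begin(), n, 4, false);
  arma::vec om2(omega2.begin(), 4);
  arma::mat sg(sig.begin(), 2, 2);
  arma::ivec em(2);
  em[0] = errmodel[0];
  em[1] = errmodel[1];

  NumericVector ofv_i(n);
  NumericMatrix eta_out(n, 4);
  LogicalVector conv(n);
  List cond(return_cond ? n : 0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    arma::vec e0(4);
    for (int k = 0; k < 4; ++k) e0[k] = eta_init(i, k);
    InnerResult r = inner_fit(subj[i], typ.row(i), REAL(fixedp), om2, sg, em,
                              e0, rtol, atol, hfix, maxit, tol_eta);
    ofv_i[i] = r.ofv;
    total += r.ofv;
    conv[i] = r.converged;
    for (int k = 0; k < 4; ++k) eta_out(i, k) = r.eta[k];
    if (return_cond)
      cond[i] = List::create(_["f"] = NumericVector(r.f.begin(), r.f.end()),
                             _["v"] = NumericVector(r.v.begin(), r.v.end()),
                             _["G"] = wrap(r.G));
  }
  List out = List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                          _["eta"] = eta_out, _["converged"] = conv);
  if (return_cond) out["cond"] = cond;
  return out;
}
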