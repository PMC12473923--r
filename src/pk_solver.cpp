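// Compiled kernels for the one-compartment SC model with parallel linear and
// Michaelis-Menten elimination, and the per-subject Laplace marginal likelihood.
//
// States: y[0] depot amount (mg), y[1] central amount (mg), y[2] cumulative
// amount eliminated (mg).  The system is autonomous; doses are bolus additions
// to the depot handled by integration restarts.  eta ordering everywhere is
// (CL, V, KA).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

struct PkPar {
  double ka, v, cl, km, vmax;
};

static inline void pk_rhs_c(const double* y, double* dy, const PkPar& p) {
  double C = y[1] > 0.0 ? y[1] / p.v : 0.0;
  double elim = p.cl * C;
  if (p.vmax > 0.0) elim += p.vmax * C / (p.km + C);
  dy[0] = -p.ka * y[0];
  dy[1] = p.ka * y[0] - elim;
  dy[2] = elim;
}

// Adaptive Dormand-Prince 5(4) from t to tend; h is the persisted trial step.
static void integrate_to(double& t, double tend, double* y, const PkPar& p,
                         double rtol, double atol, double& h) {
  if (!(tend > t)) return;
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], y5[3];
  if (!(h > 0.0) || !std::isfinite(h)) h = (tend - t) * 0.01;
  long nstep = 0;
  while (t < tend) {
    if (++nstep > 300000L)
      stop("ODE integration exceeded the maximum number of steps (invalid or stiff parameters?)");
    if (h > tend - t) h = tend - t;
    if (h < 1e-13 * (1.0 + std::fabs(t)))
      stop("ODE step size underflow (invalid parameters?)");
    pk_rhs_c(y, k1, p);
    for (int i = 0; i < 3; i++) yt[i] = y[i] + h * (0.2 * k1[i]);
    pk_rhs_c(yt, k2, p);
    for (int i = 0; i < 3; i++)
      yt[i] = y[i] + h * (3.0/40.0*k1[i] + 9.0/40.0*k2[i]);
    pk_rhs_c(yt, k3, p);
    for (int i = 0; i < 3; i++)
      yt[i] = y[i] + h * (44.0/45.0*k1[i] - 56.0/15.0*k2[i] + 32.0/9.0*k3[i]);
    pk_rhs_c(yt, k4, p);
    for (int i = 0; i < 3; i++)
      yt[i] = y[i] + h * (19372.0/6561.0*k1[i] - 25360.0/2187.0*k2[i]
                          + 64448.0/6561.0*k3[i] - 212.0/729.0*k4[i]);
    pk_rhs_c(yt, k5, p);
    for (int i = 0; i < 3; i++)
      yt[i] = y[i] + h * (9017.0/3168.0*k1[i] - 355.0/33.0*k2[i]
                          + 46732.0/5247.0*k3[i] + 49.0/176.0*k4[i]
                          - 5103.0/18656.0*k5[i]);
    pk_rhs_c(yt, k6, p);
    for (int i = 0; i < 3; i++)
      y5[i] = y[i] + h * (35.0/384.0*k1[i] + 500.0/1113.0*k3[i]
                          + 125.0/192.0*k4[i] - 2187.0/6784.0*k5[i]
                          + 11.0/84.0*k6[i]);
    pk_rhs_c(y5, k7, p);
    double errnorm = 0.0;
    for (int i = 0; i < 3; i++) {
      double e = h * ((35.0/384.0 - 5179.0/57600.0) * k1[i]
                      + (500.0/1113.0 - 7571.0/16695.0) * k3[i]
                      + (125.0/192.0 - 393.0/640.0) * k4[i]
                      + (-2187.0/6784.0 + 92097.0/339200.0) * k5[i]
                      + (11.0/84.0 - 187.0/2100.0) * k6[i]
                      - (1.0/40.0) * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double q = e / sc;
      errnorm += q * q;
    }
    errnorm = std::sqrt(errnorm / 3.0);
    if (errnorm <= 1.0) {
      t += h;
      y[0] = y5[0]; y[1] = y5[1]; y[2] = y5[2];
    }
    double fac = (errnorm > 1e-12) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
  }
}

// Integrate through the dose/observation schedule.  Observations at a dose
// time are recorded before the dose is applied (pre-dose sampling convention).
static void simulate_subject(const PkPar& p,
                             const double* dose_t, const double* dose_a, int nd,
                             const double* obs_t, int no,
                             double rtol, double atol,
                             double* conc, double* depot, double* central,
                             double* elim) {
  double y[3] = {0.0, 0.0, 0.0};
  double t = 0.0, h = 0.0;
  int di = 0, oi = 0;
  const double inf = std::numeric_limits<double>::infinity();
  while (oi < no) {
    double to = obs_t[oi];
    double td = (di < nd) ? dose_t[di] : inf;
    if (td < to) {
      integrate_to(t, td, y, p, rtol, atol, h);
      y[0] += dose_a[di];
      di++;
      h = 0.0;  // restart step-size control at the discontinuity
    } else {
      integrate_to(t, to, y, p, rtol, atol, h);
      conc[oi] = y[1] > 0.0 ? y[1] / p.v : 0.0;
      if (depot) depot[oi] = y[0];
      if (central) central[oi] = y[1] > 0.0 ? y[1] : 0.0;
      if (elim) elim[oi] = y[2];
      oi++;
    }
  }
}

// ---- augmented (variational) system: states + sensitivities wrt etas -----
//
// y = (A_d, A_c, S_d_ka, S_c_cl, S_c_v, S_c_ka, S_c_km, S_c_vm) where
// S_c_p = d(A_c)/d(log p) for the log-scale parameters (cl = cl0 e^{eta}
// and the MU-referenced typical values enter identically, so these
// sensitivities serve both the inner eta search and the outer fixed-effect
// gradient).  Concentration sensitivities at output times:
// dc/d(log cl) = S_c_cl / v, dc/d(log v) = S_c_v / v - C (product rule:
// C = A_c / v and v itself moves), dc/d(log ka) = S_c_ka / v,
// dc/d(log km) = S_c_km / v, dc/d(log vmax) = S_c_vm / v.
static inline void pk_rhs_sens(const double* y, double* dy, const PkPar& p) {
  double C = y[1] > 0.0 ? y[1] / p.v : 0.0;
  double denom = p.km + C;
  double mm = p.vmax > 0.0;
  double w = p.cl + (mm ? p.vmax * p.km / (denom * denom) : 0.0);
  double elim = p.cl * C + (mm ? p.vmax * C / denom : 0.0);
  dy[0] = -p.ka * y[0];
  dy[1] = p.ka * y[0] - elim;
  dy[2] = -p.ka * (y[2] + y[0]);                  // S_d_ka
  dy[3] = -w / p.v * y[3] - p.cl * C;             // S_c_cl
  dy[4] = -w / p.v * y[4] + w * C;                // S_c_v
  dy[5] = p.ka * (y[2] + y[0]) - w / p.v * y[5];  // S_c_ka
  dy[6] = -w / p.v * y[6] + (mm ? p.vmax * C * p.km / (denom * denom) : 0.0); // S_c_km
  dy[7] = -w / p.v * y[7] - (mm ? p.vmax * C / denom : 0.0);                  // S_c_vm
}

static void integrate_to_sens(double& t, double tend, double* y,
                              const PkPar& p, double rtol, double atol,
                              double& h) {
  if (!(tend > t)) return;
  const int N = 8;
  double k1[N], k2[N], k3[N], k4[N], k5[N], k6[N], k7[N], yt[N], y5[N];
  if (!(h > 0.0) || !std::isfinite(h)) h = (tend - t) * 0.01;
  long nstep = 0;
  while (t < tend) {
    if (++nstep > 300000L)
      stop("ODE integration exceeded the maximum number of steps (invalid or stiff parameters?)");
    if (h > tend - t) h = tend - t;
    if (h < 1e-13 * (1.0 + std::fabs(t)))
      stop("ODE step size underflow (invalid parameters?)");
    pk_rhs_sens(y, k1, p);
    for (int i = 0; i < N; i++) yt[i] = y[i] + h * (0.2 * k1[i]);
    pk_rhs_sens(yt, k2, p);
    for (int i = 0; i < N; i++)
      yt[i] = y[i] + h * (3.0/40.0*k1[i] + 9.0/40.0*k2[i]);
    pk_rhs_sens(yt, k3, p);
    for (int i = 0; i < N; i++)
      yt[i] = y[i] + h * (44.0/45.0*k1[i] - 56.0/15.0*k2[i] + 32.0/9.0*k3[i]);
    pk_rhs_sens(yt, k4, p);
    for (int i = 0; i < N; i++)
      yt[i] = y[i] + h * (19372.0/6561.0*k1[i] - 25360.0/2187.0*k2[i]
                          + 64448.0/6561.0*k3[i] - 212.0/729.0*k4[i]);
    pk_rhs_sens(yt, k5, p);
    for (int i = 0; i < N; i++)
      yt[i] = y[i] + h * (9017.0/3168.0*k1[i] - 355.0/33.0*k2[i]
                          + 46732.0/5247.0*k3[i] + 49.0/176.0*k4[i]
                          - 5103.0/18656.0*k5[i]);
    pk_rhs_sens(yt, k6, p);
    for (int i = 0; i < N; i++)
      y5[i] = y[i] + h * (35.0/384.0*k1[i] + 500.0/1113.0*k3[i]
                          + 125.0/192.0*k4[i] - 2187.0/6784.0*k5[i]
                          + 11.0/84.0*k6[i]);
    pk_rhs_sens(y5, k7, p);
    double errnorm = 0.0;
    for (int i = 0; i < N; i++) {
      double e = h * ((35.0/384.0 - 5179.0/57600.0) * k1[i]
                      + (500.0/1113.0 - 7571.0/16695.0) * k3[i]
                      + (125.0/192.0 - 393.0/640.0) * k4[i]
                      + (-2187.0/6784.0 + 92097.0/339200.0) * k5[i]
                      + (11.0/84.0 - 187.0/2100.0) * k6[i]
                      - (1.0/40.0) * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double q = e / sc;
      errnorm += q * q;
    }
    errnorm = std::sqrt(errnorm / N);
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < N; i++) y[i] = y5[i];
    }
    double fac = (errnorm > 1e-12) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
  }
}

// conc and d(conc)/d(log p) (columns: cl, v, ka, km, vmax) at the
// observation times
static void simulate_subject_sens(const PkPar& p,
                                  const double* dose_t, const double* dose_a,
                                  int nd, const double* obs_t, int no,
                                  double rtol, double atol,
                                  double* conc, double* Jfull /* no x 5 */) {
  double y[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double t = 0.0, h = 0.0;
  int di = 0, oi = 0;
  const double inf = std::numeric_limits<double>::infinity();
  while (oi < no) {
    double to = obs_t[oi];
    double td = (di < nd) ? dose_t[di] : inf;
    if (td < to) {
      integrate_to_sens(t, td, y, p, rtol, atol, h);
      y[0] += dose_a[di];
      di++;
      h = 0.0;
    } else {
      integrate_to_sens(t, to, y, p, rtol, atol, h);
      double C = y[1] > 0.0 ? y[1] / p.v : 0.0;
      conc[oi] = C;
      Jfull[oi * 5 + 0] = y[3] / p.v;
      Jfull[oi * 5 + 1] = y[4] / p.v - C;
      Jfull[oi * 5 + 2] = y[5] / p.v;
      Jfull[oi * 5 + 3] = y[6] / p.v;
      Jfull[oi * 5 + 4] = y[7] / p.v;
      oi++;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix solve_profile_cpp(double ka, double v, double cl, double km,
                                double vmax,
                                NumericVector dose_t, NumericVector dose_a,
                                NumericVector times,
                                double rtol, double atol) {
  int no = times.size();
  PkPar p = {ka, v, cl, km, vmax};
  NumericMatrix out(no, 4);
  std::vector<double> conc(no), dep(no), cen(no), eli(no);
  simulate_subject(p, dose_t.begin(), dose_a.begin(), dose_t.size(),
                   times.begin(), no, rtol, atol,
                   conc.data(), dep.data(), cen.data(), eli.data());
  for (int i = 0; i < no; i++) {
    out(i, 0) = dep[i];
    out(i, 1) = cen[i];
    out(i, 2) = eli[i];
    out(i, 3) = conc[i];
  }
  colnames(out) = CharacterVector::create("depot", "central", "eliminated", "conc");
  return out;
}

// [[Rcpp::export]]
NumericVector conc_subject_cpp(double lcl, double lv, double lka,
                               double km, double vmax, NumericVector eta,
                               NumericVector dose_t, NumericVector dose_a,
                               NumericVector obs_t,
                               double rtol, double atol) {
  PkPar p = {std::exp(lka + eta[2]), std::exp(lv + eta[1]),
             std::exp(lcl + eta[0]), km, vmax};
  int no = obs_t.size();
  NumericVector conc(no);
  simulate_subject(p, dose_t.begin(), dose_a.begin(), dose_t.size(),
                   obs_t.begin(), no, rtol, atol,
                   conc.begin(), nullptr, nullptr, nullptr);
  return conc;
}

// ---- small dense Cholesky helpers (m <= 3) --------------------------------

static bool chol_small(const double* A, int m, double* L) {
  for (int i = 0; i < m * m; i++) L[i] = 0.0;
  for (int j = 0; j < m; j++) {
    double d = A[j * m + j];
    for (int k = 0; k < j; k++) d -= L[j * m + k] * L[j * m + k];
    if (!(d > 0.0)) return false;
    L[j * m + j] = std::sqrt(d);
    for (int i = j + 1; i < m; i++) {
      double s = A[i * m + j];
      for (int k = 0; k < j; k++) s -= L[i * m + k] * L[j * m + k];
      L[i * m + j] = s / L[j * m + j];
    }
  }
  return true;
}

static void chol_solve_small(const double* L, int m, const double* b, double* x) {
  double z[3];
  for (int i = 0; i < m; i++) {
    double s = b[i];
    for (int k = 0; k < i; k++) s -= L[i * m + k] * z[k];
    z[i] = s / L[i * m + i];
  }
  for (int i = m - 1; i >= 0; i--) {
    double s = z[i];
    for (int k = i + 1; k < m; k++) s -= L[k * m + i] * x[k];
    x[i] = s / L[i * m + i];
  }
}

static double chol_logdet_small(const double* L, int m) {
  double s = 0.0;
  for (int i = 0; i < m; i++) s += std::log(L[i * m + i]);
  return 2.0 * s;
}

// ---- per-subject joint negative log density and its Laplace treatment -----

class SubjLik {
public:
  NumericVector dose_t, dose_a, obs_t, dv;
  double lcl, lv, lka, km, vmax;
  double omega2[3];
  double sigma2, vfloor, rtol, atol;
  int freeidx[3];
  int m;

  SubjLik(List subj, double lcl_, double lv_, double lka_,
          double km_, double vmax_, const NumericVector& om2,
          double sigma2_, double vfloor_, double rtol_, double atol_)
      : dose_t(as<NumericVector>(subj["dose_t"])),
        dose_a(as<NumericVector>(subj["dose_a"])),
        obs_t(as<NumericVector>(subj["obs_t"])),
        dv(as<NumericVector>(subj["dv"])),
        lcl(lcl_), lv(lv_), lka(lka_), km(km_), vmax(vmax_),
        sigma2(sigma2_), vfloor(vfloor_), rtol(rtol_), atol(atol_) {
    m = 0;
    for (int k = 0; k < 3; k++) {
      omega2[k] = om2[k];
      if (om2[k] > 0.0) freeidx[m++] = k;
    }
  }

  int nobs() const { return obs_t.size(); }

  void conc(const double* etaf, double* cout) {
    double e[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < m; k++) e[freeidx[k]] = etaf[k];
    PkPar p = {std::exp(lka + e[2]), std::exp(lv + e[1]),
               std::exp(lcl + e[0]), km, vmax};
    simulate_subject(p, dose_t.begin(), dose_a.begin(), dose_t.size(),
                     obs_t.begin(), obs_t.size(), rtol, atol,
                     cout, nullptr, nullptr, nullptr);
  }

  // conc + exact d(conc)/d(log parameter) (variational ODE); J5 is n x 5
  // over (cl, v, ka, km, vmax)
  void conc_sens5(const double* etaf, double* cout, double* J5) {
    double e[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < m; k++) e[freeidx[k]] = etaf[k];
    PkPar p = {std::exp(lka + e[2]), std::exp(lv + e[1]),
               std::exp(lcl + e[0]), km, vmax};
    simulate_subject_sens(p, dose_t.begin(), dose_a.begin(), dose_t.size(),
                          obs_t.begin(), obs_t.size(), rtol, atol, cout, J5);
  }

  // free-eta columns only
  void conc_sens(const double* etaf, double* cout, double* Jfree /* n x m */) {
    int n = obs_t.size();
    std::vector<double> J5(5 * std::max(1, n));
    conc_sens5(etaf, cout, J5.data());
    for (int j = 0; j < n; j++)
      for (int k = 0; k < m; k++)
        Jfree[j * m + k] = J5[j * 5 + freeidx[k]];
  }

  double g_from_conc(const double* etaf, const double* cbuf) {
    double sv = 0.0;
    for (int k = 0; k < m; k++)
      sv += 0.5 * etaf[k] * etaf[k] / omega2[freeidx[k]];
    int n = nobs();
    for (int j = 0; j < n; j++) {
      double c = cbuf[j];
      double vj = sigma2 * c * c + vfloor;
      double r = dv[j] - c;
      sv += 0.5 * (r * r / vj + std::log(2.0 * M_PI * vj));
    }
    return sv;
  }

  // g(eta) = -log[p(y | eta) p(eta)] up to the (2*pi)^{m/2} prior constant,
  // i.e. 0.5 eta' Om^-1 eta + 0.5 sum_j [r^2/v_j + log(2 pi v_j)],
  // with interaction: v_j = sigma2 * c_j(eta)^2 + vfloor.
  double g(const double* etaf, double* cbuf) {
    conc(etaf, cbuf);
    double s = 0.0;
    for (int k = 0; k < m; k++)
      s += 0.5 * etaf[k] * etaf[k] / omega2[freeidx[k]];
    int n = nobs();
    for (int j = 0; j < n; j++) {
      double c = cbuf[j];
      double vj = sigma2 * c * c + vfloor;
      double r = dv[j] - c;
      s += 0.5 * (r * r / vj + std::log(2.0 * M_PI * vj));
    }
    return s;
  }
};

// Gauss-Newton inner search for the conditional mode, then the Laplace
// -2 log marginal contribution with a central-difference Hessian of g.
// correction = 0: expected (Gauss-Newton) information at the mode (FOCE-I
// style); correction = 1: full central-difference Hessian of g (Laplace).
// grad_out (optional, length 9): analytic derivative of this subject's
// -2 log marginal contribution with respect to the log-scale population
// parameters, by the envelope theorem at the conditional mode:
// [0..4] d/d(log cl0, log v0, log ka0, log km, log vmax),
// [5]    d/d(log sigma^2),
// [6..8] d/d(log omega^2_{cl,v,ka}).
// The data terms are exact; the dependence of log|H| on the fixed effects
// through J and W is neglected (the classical first-order simplification),
// which the fitter compensates with a finite-difference polish.
// Only computed for correction == 0 (expected information).
static double laplace_one(SubjLik& S, double* eta, double inner_tol,
                          int max_inner, bool& conv,
                          double hfd, double hH, int correction,
                          double* grad_out) {
  const int m = S.m;
  const int n = S.nobs();
  std::vector<double> c0(n), ch(n), cn(n);
  double g0 = S.g(eta, c0.data());
  // a stale warm start can sit in a poor local basin of the conditional
  // posterior; fall back to the prior mode when that is better
  bool warm = false;
  for (int k = 0; k < m; k++) warm = warm || eta[k] != 0.0;
  if (warm) {
    double z[3] = {0.0, 0.0, 0.0};
    double gz = S.g(z, cn.data());
    if (gz < g0) {
      for (int k = 0; k < m; k++) eta[k] = 0.0;
      g0 = gz;
      c0 = cn;
    }
  }
  double sumlogw = 0.0;
  for (int k = 0; k < m; k++) sumlogw += std::log(S.omega2[S.freeidx[k]]);
  conv = true;
  // m == 0 (no random effects): g is exact, the inner loop below exits at
  // once and the correction block contributes nothing but the gradient
  std::vector<double> J(std::max(1, n * m));
  double grad[3], H[9], L[9], step[3], etan[3];

  if (n > 0) {
    conv = false;
    for (int iter = 0; iter < max_inner; ++iter) {
      S.conc_sens(eta, c0.data(), J.data());
      g0 = S.g_from_conc(eta, c0.data());
      for (int k = 0; k < m; k++)
        grad[k] = eta[k] / S.omega2[S.freeidx[k]];
      for (int k = 0; k < m * m; k++) H[k] = 0.0;
      for (int k = 0; k < m; k++) H[k * m + k] = 1.0 / S.omega2[S.freeidx[k]];
      for (int j = 0; j < n; j++) {
        double c = c0[j];
        double vj = S.sigma2 * c * c + S.vfloor;
        double r = S.dv[j] - c;
        double w1 = 1.0 / vj + 2.0 * S.sigma2 * S.sigma2 * c * c / (vj * vj);
        for (int k = 0; k < m; k++) {
          double Jk = J[j * m + k];
          grad[k] += -r * Jk / vj
                     + S.sigma2 * c * Jk * (1.0 / vj - r * r / (vj * vj));
          for (int l = k; l < m; l++) H[k * m + l] += Jk * J[j * m + l] * w1;
        }
      }
      for (int k = 0; k < m; k++)
        for (int l = k + 1; l < m; l++) H[l * m + k] = H[k * m + l];

      double gmax = 0.0;
      for (int k = 0; k < m; k++) gmax = std::max(gmax, std::fabs(grad[k]));
      if (gmax < inner_tol) { conv = true; break; }

      if (chol_small(H, m, L)) {
        double nb[3];
        for (int k = 0; k < m; k++) nb[k] = -grad[k];
        chol_solve_small(L, m, nb, step);
      } else {
        for (int k = 0; k < m; k++) step[k] = -grad[k] / H[k * m + k];
      }

      // trust-region style cap: no more than 2 log units per iteration,
      // and keep etas inside a generous box
      double smax = 0.0;
      for (int k = 0; k < m; k++) smax = std::max(smax, std::fabs(step[k]));
      if (smax > 2.0)
        for (int k = 0; k < m; k++) step[k] *= 2.0 / smax;

      double lam = 1.0;
      bool ok = false;
      double gn = g0;
      for (int ls = 0; ls < 12; ++ls) {
        for (int k = 0; k < m; k++) {
          etan[k] = eta[k] + lam * step[k];
          if (etan[k] > 8.0) etan[k] = 8.0;
          if (etan[k] < -8.0) etan[k] = -8.0;
        }
        gn = S.g(etan, cn.data());
        if (std::isfinite(gn) && gn <= g0 + 1e-12) { ok = true; break; }
        lam *= 0.5;
      }
      if (!ok) { conv = true; break; }  // no descent possible: at the mode
      bool tiny = (g0 - gn) < 1e-10 * (1.0 + std::fabs(g0));
      for (int k = 0; k < m; k++) eta[k] = etan[k];
      c0 = cn;
      g0 = gn;
      if (tiny) { conv = true; break; }
    }
  }

  // curvature correction at the mode
  double logdet = -sumlogw;  // value for n == 0 (H = Omega^-1)
  if (grad_out) for (int k = 0; k < 9; k++) grad_out[k] = 0.0;
  if (n > 0 && correction == 0) {
    // expected information: Omega^-1 + J' W J with the interaction weights
    std::vector<double> J5(5 * n);
    S.conc_sens5(eta, c0.data(), J5.data());
    for (int j = 0; j < n; j++)
      for (int k = 0; k < m; k++)
        J[j * m + k] = J5[j * 5 + S.freeidx[k]];
    double Hg[9], Lg[9];
    for (int k = 0; k < m * m; k++) Hg[k] = 0.0;
    for (int k = 0; k < m; k++) Hg[k * m + k] = 1.0 / S.omega2[S.freeidx[k]];
    for (int j = 0; j < n; j++) {
      double c = c0[j];
      double vj = S.sigma2 * c * c + S.vfloor;
      double w1 = 1.0 / vj + 2.0 * S.sigma2 * S.sigma2 * c * c / (vj * vj);
      for (int k = 0; k < m; k++)
        for (int l = k; l < m; l++)
          Hg[k * m + l] += J[j * m + k] * J[j * m + l] * w1;
    }
    for (int k = 0; k < m; k++)
      for (int l = k + 1; l < m; l++) Hg[l * m + k] = Hg[k * m + l];
    if (m > 0) {
      chol_small(Hg, m, Lg);  // PD by construction
      logdet = chol_logdet_small(Lg, m);
    }
    if (grad_out) {
      // H^-1 for the log|H| pieces (m <= 3)
      double Hinv[9];
      if (m > 0) {
        for (int k = 0; k < m; k++) {
          double ek[3] = {0.0, 0.0, 0.0};
          double xk[3];
          ek[k] = 1.0;
          chol_solve_small(Lg, m, ek, xk);
          for (int l = 0; l < m; l++) Hinv[l * m + k] = xk[l];
        }
      }
      for (int j = 0; j < n; j++) {
        double c = c0[j];
        double vj = S.sigma2 * c * c + S.vfloor;
        double r = S.dv[j] - c;
        double s2 = S.sigma2;
        double dgdc = -r / vj + s2 * c * (1.0 / vj - r * r / (vj * vj));
        // q_j = J_j' H^-1 J_j enters d log|H| = tr(H^-1 dH) through the
        // interaction weights W_j = 1/v_j + 2 sigma^4 c^2 / v_j^2
        double qj = 0.0;
        for (int k = 0; k < m; k++)
          for (int l = 0; l < m; l++)
            qj += J[j * m + k] * Hinv[k * m + l] * J[j * m + l];
        double a = s2 * c * c;  // d v_j / d log sigma^2
        // For log sigma^2 the log|H| correction through W is exact (J does
        // not depend on sigma).  For the location parameters the W-part and
        // the neglected dJ/dtheta part of d log|H| largely cancel, so the
        // plain envelope data term is the better approximation there.
        double dW_dlsig = -a / (vj * vj)
          + 4.0 * s2 * s2 * c * c / (vj * vj)
          - 4.0 * s2 * s2 * c * c * a / (vj * vj * vj);
        for (int p = 0; p < 5; p++)
          grad_out[p] += 2.0 * dgdc * J5[j * 5 + p];
        grad_out[5] += (1.0 / vj - r * r / (vj * vj)) * a + dW_dlsig * qj;
      }
      // d/d(log omega^2_k): + 1 (log|Omega|) - eta_k^2/omega^2_k (prior)
      //                     - [H^-1]_kk / omega^2_k (log|H| via Omega^-1)
      for (int k = 0; k < m; k++) {
        grad_out[6 + S.freeidx[k]] =
          1.0 - eta[k] * eta[k] / S.omega2[S.freeidx[k]]
          - Hinv[k * m + k] / S.omega2[S.freeidx[k]];
      }
    }
  } else if (m > 0 && n > 0) {
    double Hf[9];
    double ep[3], em[3];
    for (int k = 0; k < m; k++) {
      for (int q = 0; q < m; q++) { ep[q] = eta[q]; em[q] = eta[q]; }
      ep[k] += hH; em[k] -= hH;
      double gp = S.g(ep, ch.data());
      double gm = S.g(em, ch.data());
      Hf[k * m + k] = (gp - 2.0 * g0 + gm) / (hH * hH);
    }
    for (int k = 0; k < m; k++) {
      for (int l = k + 1; l < m; l++) {
        double e1[3], e2[3], e3[3], e4[3];
        for (int q = 0; q < m; q++) e1[q] = e2[q] = e3[q] = e4[q] = eta[q];
        e1[k] += hH; e1[l] += hH;
        e2[k] += hH; e2[l] -= hH;
        e3[k] -= hH; e3[l] += hH;
        e4[k] -= hH; e4[l] -= hH;
        double v = (S.g(e1, ch.data()) - S.g(e2, ch.data())
                    - S.g(e3, ch.data()) + S.g(e4, ch.data()))
                   / (4.0 * hH * hH);
        Hf[k * m + l] = v;
        Hf[l * m + k] = v;
      }
    }
    double Lf[9];
    if (chol_small(Hf, m, Lf)) {
      logdet = chol_logdet_small(Lf, m);
    } else {
      // fall back to the (positive-definite) Gauss-Newton curvature
      S.conc_sens(eta, c0.data(), J.data());
      double Hg[9];
      for (int k = 0; k < m * m; k++) Hg[k] = 0.0;
      for (int k = 0; k < m; k++) Hg[k * m + k] = 1.0 / S.omega2[S.freeidx[k]];
      for (int j = 0; j < n; j++) {
        double c = c0[j];
        double vj = S.sigma2 * c * c + S.vfloor;
        double w1 = 1.0 / vj + 2.0 * S.sigma2 * S.sigma2 * c * c / (vj * vj);
        for (int k = 0; k < m; k++)
          for (int l = k; l < m; l++)
            Hg[k * m + l] += J[j * m + k] * J[j * m + l] * w1;
      }
      for (int k = 0; k < m; k++)
        for (int l = k + 1; l < m; l++) Hg[l * m + k] = Hg[k * m + l];
      chol_small(Hg, m, Lf);
      logdet = chol_logdet_small(Lf, m);
    }
  }
  return 2.0 * g0 + sumlogw + logdet;
}

// [[Rcpp::export]]
List ofv_nlme_cpp(List subjects, NumericVector lcl, NumericVector lv,
                  NumericVector lka, double km, double vmax,
                  NumericVector omega2, double sigma2,
                  NumericMatrix eta_start,
                  double rtol, double atol,
                  double inner_tol, int max_inner, double vfloor,
                  double hfd, double hH, int correction, bool want_grad) {
  int ns = subjects.size();
  NumericVector ofv_i(ns);
  NumericMatrix etas(ns, 3);
  LogicalVector conv(ns);
  NumericMatrix grad_i(want_grad ? ns : 1, 9);
  double total = 0.0;
  double gbuf[9];
  for (int i = 0; i < ns; i++) {
    SubjLik S(subjects[i], lcl[i], lv[i], lka[i], km, vmax, omega2, sigma2,
              vfloor, rtol, atol);
    double eta[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < S.m; k++) eta[k] = eta_start(i, S.freeidx[k]);
    bool cv = true;
    double o = laplace_one(S, eta, inner_tol, max_inner, cv, hfd, hH,
                           correction, want_grad ? gbuf : nullptr);
    ofv_i[i] = o;
    conv[i] = cv;
    total += o;
    for (int k = 0; k < S.m; k++) etas(i, S.freeidx[k]) = eta[k];
    if (want_grad)
      for (int k = 0; k < 9; k++) grad_i(i, k) = gbuf[k];
  }
  List out = List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                          _["etas"] = etas, _["inner_converged"] = conv);
  if (want_grad) out["grad_i"] = grad_i;
  return out;
}
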