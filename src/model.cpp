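// Core numerics for the nasal-epithelium transport model.
//
// State vector y (internal units):
//   y[0] W    cell water volume per unit area        (cm^3 cm^-2)
//   y[1] N_Na intracellular Na+ moles per unit area  (mol cm^-2)
//   y[2] N_K  intracellular K+  moles per unit area  (mol cm^-2)
//   y[3] N_Cl intracellular Cl- moles per unit area  (mol cm^-2)
//   y[4] V_a  apical membrane potential, cell - lumen   (V)
//   y[5] V_b  basolateral membrane potential, cell - serosa (V)
//
// Parameter vector q: P_Na_ap, P_Cl_ap, P_K_bl, rho_NaK, rho_NKCC, P_Cl_bl,
//   P_pa  (permeabilities cm s^-1, densities mol cm^-2).
// Bath vector b: Na_l, K_l, Cl_l, imp_l, Na_s, K_s, Cl_s, imp_s (mol cm^-3).
// Model-constant vector m: see enum below.
//
// Sign conventions (fixed throughout): positive channel current = positive
// charge leaving the cell; positive paracellular current = positive charge
// moving serosa -> lumen; positive J_NKCC = ion flux into the cell; positive
// water flux = serosal -> mucosal direction.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum { M_F = 0, M_RGAS, M_T, M_CM, M_PWAP, M_PWBL, M_NIMP, M_ZIMP,
       M_KPUMP, M_KMNA, M_KMK, M_KNKCC, M_KN, M_KK, M_KC,
       M_SELNA, M_SELK, M_SELCL, M_LEN };

struct Model { const double *q, *b, *m; };

// characteristic scales used to nondimensionalise residuals
static const double SCL[6] = {1e-3, 1e-7, 1e-7, 1e-7, 2.5e-2, 2.5e-2};

// GHK flux equation; removable singularity handled by a second-order
// expansion for |zFV/RT| < 1e-6 (exact limit P z F (ci - co) at V = 0).
static inline double ghk_i(double P, double z, double V, double ci, double co,
                           double F, double RT) {
  double u = z * F * V / RT;
  if (std::fabs(u) < 1e-6)
    return P * z * F * ((ci - co) + 0.5 * u * (ci + co));
  double e = std::exp(-u);
  return P * z * F * u * (ci - co * e) / (1.0 - e);
}

// fl: 0 iNaAp 1 iClAp 2 iKBl 3 iClBl 4 ipNa 5 ipK 6 ipCl 7 Jpump 8 Jnkcc
//     9 JwAp 10 JwBl
static void compute_flux(const double* y, const Model& M, double* fl) {
  const double *q = M.q, *b = M.b, *m = M.m;
  double F = m[M_F], RT = m[M_RGAS] * m[M_T];
  double W = y[0];
  double cNa = y[1] / W, cK = y[2] / W, cCl = y[3] / W;
  double Va = y[4], Vb = y[5], Vpa = Va - Vb; // Vpa = -V_t, serosa as inside

  fl[0] = ghk_i(q[0],  1.0, Va, cNa, b[0], F, RT);
  fl[1] = ghk_i(q[1], -1.0, Va, cCl, b[2], F, RT);
  fl[2] = ghk_i(q[2],  1.0, Vb, cK,  b[5], F, RT);
  fl[3] = ghk_i(q[5], -1.0, Vb, cCl, b[6], F, RT);
  fl[4] = ghk_i(q[6] * m[M_SELNA],  1.0, Vpa, b[4], b[0], F, RT);
  fl[5] = ghk_i(q[6] * m[M_SELK],   1.0, Vpa, b[5], b[1], F, RT);
  fl[6] = ghk_i(q[6] * m[M_SELCL], -1.0, Vpa, b[6], b[2], F, RT);

  double sNa = cNa / (cNa + m[M_KMNA]);
  double sK  = b[5] / (b[5] + m[M_KMK]);
  fl[7] = q[3] * m[M_KPUMP] * sNa * sNa * sNa * sK * sK;

  double us = (b[4] / m[M_KN]) * (b[5] / m[M_KK]) *
              (b[6] / m[M_KC]) * (b[6] / m[M_KC]);
  double ui = (cNa / m[M_KN]) * (cK / m[M_KK]) *
              (cCl / m[M_KC]) * (cCl / m[M_KC]);
  fl[8] = q[4] * m[M_KNKCC] * (us - ui) / (1.0 + us + ui);

  double Si = cNa + cK + cCl + m[M_NIMP] / W;
  double Sl = b[0] + b[1] + b[2] + b[3];
  double Ss = b[4] + b[5] + b[6] + b[7];
  fl[9]  = m[M_PWAP] * (Sl - Si);  // cell -> lumen, serosal->mucosal positive
  fl[10] = m[M_PWBL] * (Si - Ss);  // serosa -> cell, serosal->mucosal positive
}

static void rhs_c(const double* y, const Model& M, double* dy) {
  double fl[11];
  compute_flux(y, M, fl);
  double F = M.m[M_F], Cm = M.m[M_CM];
  dy[0] = fl[10] - fl[9];
  dy[1] = -fl[0] / F - 3.0 * fl[7] + fl[8];
  dy[2] = -fl[2] / F + 2.0 * fl[7] + fl[8];
  dy[3] = (fl[1] + fl[3]) / F + 2.0 * fl[8];
  double Ia = fl[0] + fl[1];
  double Ib = fl[2] + fl[3] + F * fl[7];
  double Ip = fl[4] + fl[5] + fl[6];
  dy[4] = -(Ia + Ip) / Cm;
  dy[5] = (Ip - Ib) / Cm;
}

static double resnorm(const double* dy) {
  double r = 0.0;
  for (int k = 0; k < 6; ++k) {
    double v = std::fabs(dy[k]) / SCL[k];
    if (v > r) r = v;
  }
  return r;
}

static bool state_ok(const double* y) {
  if (!(y[0] > 1e-5 && y[0] < 1e-1)) return false;
  for (int k = 1; k < 4; ++k) {
    if (!(y[k] >= 0.0)) return false;
    if (y[k] / y[0] > 500e-6) return false;  // concentration cap 500 mM
  }
  if (!(std::fabs(y[4]) <= 0.2 && std::fabs(y[5]) <= 0.2)) return false;
  for (int k = 0; k < 6; ++k) if (!std::isfinite(y[k])) return false;
  return true;
}

static void jac_fd(const double* y, const Model& M, arma::mat& J) {
  double f1[6], f2[6], yy[6];
  for (int j = 0; j < 6; ++j) {
    double h = 1e-6 * SCL[j];
    std::memcpy(yy, y, sizeof(yy));
    yy[j] = y[j] + h; rhs_c(yy, M, f1);
    yy[j] = y[j] - h; rhs_c(yy, M, f2);
    for (int i = 0; i < 6; ++i) J(i, j) = (f1[i] - f2[i]) / (2.0 * h);
  }
}

static double intracellular_charge(const double* y, const Model& M) {
  // net charge per unit area minus charge stored on the two capacitors
  double F = M.m[M_F], Cm = M.m[M_CM];
  double Q = F * (y[1] + y[2] - y[3] + M.m[M_ZIMP] * M.m[M_NIMP]);
  return Q - Cm * (y[4] + y[5]);
}

// Pseudo-transient continuation: one Newton-like backward-Euler step
// (I/h - J) d = f(y) per iteration, with residual-based step control.
static int relax_ss(double* y, const Model& M, double rtol, int maxsteps,
                    double* res_out) {
  double dy[6], ytry[6], dytry[6];
  arma::mat J(6, 6), A(6, 6);
  arma::vec f(6), d(6);
  double h = 1e-4;
  const double hmax = 1e5;
  rhs_c(y, M, dy);
  double res = resnorm(dy);
  int step = 0;
  while (res > rtol && step < maxsteps) {
    ++step;
    jac_fd(y, M, J);
    A = -J;
    for (int k = 0; k < 6; ++k) A(k, k) += 1.0 / h;
    for (int k = 0; k < 6; ++k) f(k) = dy[k];
    bool solved = arma::solve(d, A, f, arma::solve_opts::no_approx +
                                       arma::solve_opts::fast);
    int shrink = 0;
    while (true) {
      if (solved) {
        for (int k = 0; k < 6; ++k) ytry[k] = y[k] + d(k);
        if (state_ok(ytry)) {
          rhs_c(ytry, M, dytry);
          double rtry = resnorm(dytry);
          if (std::isfinite(rtry) && rtry < 2.0 * res) {
            std::memcpy(y, ytry, sizeof(ytry));
            std::memcpy(dy, dytry, sizeof(dytry));
            h = std::min(hmax, h * (rtry < 0.5 * res ? 2.5 : 1.3));
            res = rtry;
            break;
          }
        }
      }
      // reject: shrink the pseudo-step and retry
      h *= 0.25;
      if (++shrink > 40 || h < 1e-14) return 1;
      A = -J;
      for (int k = 0; k < 6; ++k) A(k, k) += 1.0 / h;
      solved = arma::solve(d, A, f, arma::solve_opts::no_approx +
                                    arma::solve_opts::fast);
    }
  }
  *res_out = res;
  if (!state_ok(y)) return 2;
  return res <= rtol ? 0 : 1;
}

// Root residual: first five rhs components plus the charge-conservation
// constraint (the rhs has an exact linear conservation law, so the raw
// 6-equation Jacobian is singular at a steady state).
static void gfun(const double* y, const Model& M, double D0, double* g) {
  double dy[6];
  rhs_c(y, M, dy);
  for (int k = 0; k < 5; ++k) g[k] = dy[k] / SCL[k];
  g[5] = (intracellular_charge(y, M) - D0) / (M.m[M_F] * SCL[1]);
}

static int newton_root(double* y, const Model& M, double D0, double tol,
                       int maxit, double* res_out) {
  arma::mat J(6, 6);
  arma::vec g(6), d(6);
  double yy[6], y2[6], g1[6], g2[6];
  for (int it = 0; it < maxit; ++it) {
    gfun(y, M, D0, g.memptr());
    double gnorm = arma::norm(g, "inf");
    if (gnorm < tol) break;
    for (int j = 0; j < 6; ++j) {
      double h = 1e-6 * SCL[j];
      std::memcpy(yy, y, sizeof(yy));
      yy[j] = y[j] + h; gfun(yy, M, D0, g1);
      yy[j] = y[j] - h; gfun(yy, M, D0, g2);
      for (int i = 0; i < 6; ++i) J(i, j) = (g1[i] - g2[i]) / (2.0 * h);
    }
    if (!arma::solve(d, J, g, arma::solve_opts::no_approx)) return 2;
    double lam = 1.0;
    bool moved = false;
    for (int t = 0; t < 12; ++t) {
      for (int k = 0; k < 6; ++k) y2[k] = y[k] - lam * d(k);
      if (state_ok(y2)) {
        gfun(y2, M, D0, g1);
        double gt = 0.0;
        for (int k = 0; k < 6; ++k) gt = std::max(gt, std::fabs(g1[k]));
        if (std::isfinite(gt) && (gt < gnorm * (1.0 - 0.05 * lam) || gt < tol)) {
          std::memcpy(y, y2, sizeof(y2));
          moved = true;
          break;
        }
      }
      lam *= 0.5;
    }
    if (!moved) {
      // stagnated: accept if already essentially converged
      if (gnorm < 1e-9) break;
      return 3;
    }
  }
  double dy[6];
  rhs_c(y, M, dy);
  *res_out = resnorm(dy);
  gfun(y, M, D0, g.memptr());
  double gn = arma::norm(g, "inf");
  if (gn > std::max(tol, 1e-9)) return 1;
  return 0;
}

static double max_re_eig(const double* y, const Model& M) {
  arma::mat J(6, 6), Js(6, 6);
  jac_fd(y, M, J);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j)
      Js(i, j) = J(i, j) * SCL[j] / SCL[i];
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, Js)) return NA_REAL;
  return arma::real(ev).max();
}

struct SSOut { double y[6]; int status; double res; double maxre; };

// method: 0 hybrid (relax then root polish), 1 relaxation only, 2 root only
// status: 0 ok, 1 no convergence, 2 left physical region, 3 unstable
static SSOut solve_ss(const double* y0, const Model& M, int method,
                      double rtol_relax, double rtol_root, bool check_stab) {
  SSOut out;
  std::memcpy(out.y, y0, sizeof(out.y));
  out.res = NA_REAL;
  out.maxre = NA_REAL;
  double D0 = intracellular_charge(y0, M);
  int s = -1;
  if (method == 1) {
    s = relax_ss(out.y, M, rtol_relax, 4000, &out.res);
  } else if (method == 2) {
    s = newton_root(out.y, M, D0, rtol_root, 80, &out.res);
    if (s == 2 || s == 3) s = 1;
  } else {
    double res0;
    int s1 = relax_ss(out.y, M, 1e-5, 1500, &res0);
    int s2 = newton_root(out.y, M, D0, rtol_root, 80, &out.res);
    if (s2 == 0) {
      s = state_ok(out.y) ? 0 : 2;
    } else if (s1 == 0 || s1 == 1) {
      // fall back to a strict relaxation
      s = relax_ss(out.y, M, rtol_relax, 4000, &out.res);
    } else {
      s = s1;
    }
  }
  out.status = s;
  if (s == 0 && check_stab) {
    out.maxre = max_re_eig(out.y, M);
    if (!std::isfinite(out.maxre) || out.maxre > 1e-6) out.status = 3;
  }
  return out;
}

static Model make_model(const NumericVector& q, const NumericVector& b,
                        const NumericVector& m) {
  Model M;
  M.q = q.begin();
  M.b = b.begin();
  M.m = m.begin();
  return M;
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector y, NumericVector q, NumericVector b,
                      NumericVector m) {
  Model M = make_model(q, b, m);
  NumericVector dy(6);
  rhs_c(y.begin(), M, dy.begin());
  return dy;
}

// [[Rcpp::export(name = ".flux_cpp")]]
NumericVector flux_cpp(NumericVector y, NumericVector q, NumericVector b,
                       NumericVector m) {
  Model M = make_model(q, b, m);
  NumericVector fl(11);
  compute_flux(y.begin(), M, fl.begin());
  fl.attr("names") = CharacterVector::create(
      "I_Na_ap", "I_Cl_ap", "I_K_bl", "I_Cl_bl",
      "I_pa_Na", "I_pa_K", "I_pa_Cl",
      "J_NaK", "J_NKCC", "J_w_ap", "J_w_bl");
  return fl;
}

// [[Rcpp::export(name = ".steady_cpp")]]
List steady_cpp(NumericVector y0, NumericVector q, NumericVector b,
                NumericVector m, int method = 0, double rtol_relax = 1e-9,
                double rtol_root = 1e-12, bool check_stability = true) {
  Model M = make_model(q, b, m);
  SSOut out = solve_ss(y0.begin(), M, method, rtol_relax, rtol_root,
                       check_stability);
  NumericVector y(6);
  std::memcpy(y.begin(), out.y, sizeof(out.y));
  return List::create(
      _["y"] = y,
      _["status"] = out.status,
      _["converged"] = out.status == 0,
      _["residual"] = out.res,
      _["max_re_eig"] = out.maxre,
      _["charge_defect"] = intracellular_charge(out.y, M) -
                           intracellular_charge(y0.begin(), M));
}

// [[Rcpp::export(name = ".charge_defect_cpp")]]
double charge_defect_cpp(NumericVector y, NumericVector m) {
  Model M;
  M.q = NULL; M.b = NULL; M.m = m.begin();
  return intracellular_charge(y.begin(), M);
}

static void obs_from_state(const double* y, double* obs5) {
  obs5[0] = y[1] / y[0] * 1e6;          // [Na]_i mM
  obs5[1] = y[3] / y[0] * 1e6;          // [Cl]_i mM
  obs5[2] = y[4] * 1e3;                 // V_a mV
  obs5[3] = y[5] * 1e3;                 // V_b mV
  obs5[4] = (y[5] - y[4]) * 1e3;        // V_t mV
}

// Batched observable evaluation for the Monte Carlo filter.
// par: N x 6 free transport parameters (internal units).
// Returns N x 13: Na_i, Cl_i, V_a, V_b, V_t, dVa_amil, dVt_amil,
// dVa_lowCl, dVt_lowCl, status_basal, status_amil, status_lowcl, maxre.
// union_bounds: 5 x 2 box on the basal observables; rows failing it are not
// given perturbation solves when early_exit is true (status -1 = skipped).
// [[Rcpp::export(name = ".observables_batch_cpp")]]
NumericMatrix observables_batch_cpp(NumericMatrix par, double Ppa,
                                    NumericVector b, NumericVector blow,
                                    NumericVector m, NumericVector y0,
                                    NumericMatrix union_bounds,
                                    bool early_exit = true,
                                    double rtol_relax = 1e-9,
                                    double rtol_root = 1e-12) {
  int N = par.nrow();
  NumericMatrix out(N, 13);
  std::fill(out.begin(), out.end(), NA_REAL);
  double q[7];
  q[6] = Ppa;
  Model M; M.q = q; M.b = b.begin(); M.m = m.begin();
  Model Mlow; Mlow.q = q; Mlow.b = blow.begin(); Mlow.m = m.begin();
  double obs[5], obs2[5];
  for (int i = 0; i < N; ++i) {
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    for (int k = 0; k < 6; ++k) q[k] = par(i, k);
    SSOut basal = solve_ss(y0.begin(), M, 0, rtol_relax, rtol_root, true);
    out(i, 9) = basal.status;
    out(i, 12) = basal.maxre;
    if (basal.status != 0) continue;
    obs_from_state(basal.y, obs);
    for (int k = 0; k < 5; ++k) out(i, k) = obs[k];
    if (early_exit) {
      bool inside = true;
      for (int k = 0; k < 5; ++k)
        if (obs[k] < union_bounds(k, 0) || obs[k] > union_bounds(k, 1)) {
          inside = false; break;
        }
      if (!inside) {
        out(i, 10) = -1.0;
        out(i, 11) = -1.0;
        continue;
      }
    }
    // amiloride: complete ENaC block, re-solve from the basal steady state
    double pna = q[0];
    q[0] = 0.0;
    SSOut amil = solve_ss(basal.y, M, 0, rtol_relax, rtol_root, true);
    q[0] = pna;
    out(i, 10) = amil.status;
    if (amil.status == 0) {
      obs_from_state(amil.y, obs2);
      out(i, 5) = obs2[2] - obs[2];
      out(i, 6) = obs2[4] - obs[4];
    }
    // low luminal chloride, applied independently from the basal state
    SSOut lcl = solve_ss(basal.y, Mlow, 0, rtol_relax, rtol_root, true);
    out(i, 11) = lcl.status;
    if (lcl.status == 0) {
      obs_from_state(lcl.y, obs2);
      out(i, 7) = obs2[2] - obs[2];
      out(i, 8) = obs2[4] - obs[4];
    }
  }
  return out;
}

// CFTR knockout: dVt0 = V_t(P_Cl_ap = 0) - V_t(basal), batched.
// Returns N x 3: dVt0 (mV), status_basal, status_knockout.
// [[Rcpp::export(name = ".knockout_batch_cpp")]]
NumericMatrix knockout_batch_cpp(NumericMatrix par, double Ppa,
                                 NumericVector b, NumericVector m,
                                 NumericVector y0,
                                 double rtol_relax = 1e-9,
                                 double rtol_root = 1e-12) {
  int N = par.nrow();
  NumericMatrix out(N, 3);
  std::fill(out.begin(), out.end(), NA_REAL);
  double q[7];
  q[6] = Ppa;
  Model M; M.q = q; M.b = b.begin(); M.m = m.begin();
  for (int i = 0; i < N; ++i) {
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
    for (int k = 0; k < 6; ++k) q[k] = par(i, k);
    SSOut basal = solve_ss(y0.begin(), M, 0, rtol_relax, rtol_root, true);
    out(i, 1) = basal.status;
    if (basal.status != 0) continue;
    q[1] = 0.0;
    SSOut ko = solve_ss(basal.y, M, 0, rtol_relax, rtol_root, true);
    q[1] = par(i, 1);
    out(i, 2) = ko.status;
    if (ko.status != 0) continue;
    out(i, 0) = ((ko.y[5] - ko.y[4]) - (basal.y[5] - basal.y[4])) * 1e3;
  }
  return out;
}
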