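// Fixed-step RK4 core for the four-population thalamocortical model,
// with zero-order-hold exogenous inputs and an optional in-loop controller
// (feedback / RBF-adaptive / filtered sliding-mode / hybrid).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double he, hi, ht, hr;
  double te, ti, tt, tr;
  double cee, cei, cet, cie, cte, ctr, cre, crt, crr;
  double lneps, a, b, c1, c2;
};

static Pars unpack(const List& p) {
  Pars q;
  q.he = p["h_e"]; q.hi = p["h_i"]; q.ht = p["h_t"]; q.hr = p["h_r"];
  q.te = p["tau_e"]; q.ti = p["tau_i"]; q.tt = p["tau_t"]; q.tr = p["tau_r"];
  q.cee = p["c_ee"]; q.cei = p["c_ei"]; q.cet = p["c_et"]; q.cie = p["c_ie"];
  q.cte = p["c_te"]; q.ctr = p["c_tr"]; q.cre = p["c_re"]; q.crt = p["c_rt"];
  q.crr = p["c_rr"];
  double eps = p["epsilon"];
  q.lneps = std::log(eps);
  q.a = p["a"]; q.b = p["b"]; q.c1 = p["c1"]; q.c2 = p["c2"];
  return q;
}

// overflow-safe sigmoid 1/(1 + eps^-x) = 1/(1 + exp(-x*ln(eps)))
static inline double fsig(double x, double lneps) {
  double z = -x * lneps;
  if (z > 700.0) z = 700.0; else if (z < -700.0) z = -700.0;
  return 1.0 / (1.0 + std::exp(z));
}

static inline void vf(const double* x, const Pars& p, double* dx) {
  const double fPY = fsig(x[0], p.lneps);
  const double fIN = fsig(x[1], p.lneps);
  const double fTC = fsig(x[2], p.lneps);
  const double sTC = p.a * x[2] + p.b;
  const double sRE = p.a * x[3] + p.b;
  dx[0] = p.te * (p.he - x[0] + p.cee * fPY - p.cei * fIN + p.cet * fTC);
  dx[1] = p.ti * (p.hi - x[1] + p.cie * fPY);
  dx[2] = p.tt * (p.ht - x[2] + p.cte * fPY - p.ctr * sRE);
  dx[3] = p.tr * (p.hr - x[3] + p.cre * fPY + p.crt * sTC - p.crr * sRE);
}

// one classical RK4 step; exogenous additive input w (per population) is
// held constant over the step and enters the derivative directly
static inline void rk4(const double* x, const Pars& p, double dt,
                       const double* w, double* out) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  vf(x, p, k1);
  for (int i = 0; i < 4; ++i) { k1[i] += w[i]; tmp[i] = x[i] + 0.5 * dt * k1[i]; }
  vf(tmp, p, k2);
  for (int i = 0; i < 4; ++i) { k2[i] += w[i]; tmp[i] = x[i] + 0.5 * dt * k2[i]; }
  vf(tmp, p, k3);
  for (int i = 0; i < 4; ++i) { k3[i] += w[i]; tmp[i] = x[i] + dt * k3[i]; }
  vf(tmp, p, k4);
  for (int i = 0; i < 4; ++i) {
    k4[i] += w[i];
    out[i] = x[i] + dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
}

// [[Rcpp::export(name = ".model_rhs_cpp")]]
NumericVector model_rhs_cpp(NumericVector state, List params) {
  Pars p = unpack(params);
  double dx[4];
  vf(REAL(state), p, dx);
  return NumericVector::create(dx[0], dx[1], dx[2], dx[3]);
}

// [[Rcpp::export(name = ".rk4_step_cpp")]]
NumericVector rk4_step_cpp(NumericVector state, List params, double dt,
                           NumericVector exogenous) {
  Pars p = unpack(params);
  double out[4];
  rk4(REAL(state), p, dt, REAL(exogenous), out);
  return NumericVector::create(out[0], out[1], out[2], out[3]);
}

static const char* comp_names[4] = {"PY", "IN", "TC", "RE"};

// Unified open-/closed-loop runner.
// exo: 4 x nsteps matrix of disturbance inputs (ZOH per step).
// method: 0 none, 1 feedback, 2 feedback+rbf, 3 feedback+smc (filtered),
//         4 hybrid, 5 feedback+smc with raw sign (chattering variant).
// enabled: optional per-step 0/1 gate (length nsteps) used by the on-demand
//          trigger; if length 0 the controller is on for all t >= switch_on.
// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(List params, NumericVector init, double dt, int nsteps,
                  NumericMatrix exo, int method, NumericVector yd,
                  double lam, double rho, double kc, double gamma,
                  NumericVector centers, double width, double tau_filter,
                  int switch_on_step, IntegerVector enabled,
                  NumericVector target_mask, NumericVector theta0,
                  double z0) {
  Pars p = unpack(params);
  const int m = centers.size();
  const bool ctrl = method > 0;
  const bool gate = enabled.size() > 0;
  if (exo.nrow() != 4 || exo.ncol() < nsteps)
    stop("exogenous input matrix must be 4 x nsteps");
  if (m > 64) stop("at most 64 RBF nodes are supported");
  if (ctrl && yd.size() < nsteps + 1)
    stop("reference must cover the full grid");

  NumericMatrix states(nsteps + 1, 4);
  NumericVector y(nsteps + 1), u(nsteps + 1), svar(nsteps + 1), zout(nsteps + 1);
  NumericMatrix theta_hist;
  std::vector<double> theta(m, 0.0);
  if (ctrl && (method == 2 || method == 4)) {
    theta_hist = NumericMatrix(nsteps + 1, m);
    for (int j = 0; j < m; ++j) theta[j] = (theta0.size() == m) ? theta0[j] : 0.0;
  }
  double x[4] = {init[0], init[1], init[2], init[3]};
  double z = z0;
  const double decay = std::exp(-dt / tau_filter);

  for (int i = 0; i <= nsteps; ++i) {
    for (int j = 0; j < 4; ++j) states(i, j) = x[j];
    y[i] = p.c1 * x[0] + p.c2 * x[1];
    if (ctrl && (method == 2 || method == 4))
      for (int j = 0; j < m; ++j) theta_hist(i, j) = theta[j];
    zout[i] = z;
    svar[i] = ctrl ? (y[i] - yd[i]) : 0.0;
    if (i == nsteps) { if (i > 0) u[i] = u[i - 1]; break; }

    double ui = 0.0;
    double s = svar[i];
    bool on = ctrl && i >= switch_on_step && (!gate || enabled[i] != 0);
    if (on) {
      double sgn = (s >= 0.0) ? 1.0 : -1.0;   // sign(0) = +1
      z = sgn + (z - sgn) * decay;            // exact first-order LPF update
      double tphi = 0.0;
      if (method == 2 || method == 4) {
        // adaptive law theta-dot = gamma*s*phi - kc*gamma*|s|*theta (Euler)
        double phi[64];
        for (int j = 0; j < m; ++j) {
          double dcj = (s - centers[j]) / width;
          phi[j] = std::exp(-0.5 * dcj * dcj);
        }
        for (int j = 0; j < m; ++j)
          theta[j] += dt * (gamma * s * phi[j] - kc * gamma * std::fabs(s) * theta[j]);
        for (int j = 0; j < m; ++j) tphi += theta[j] * phi[j];
      }
      ui = -lam * s;
      if (method == 2 || method == 4) ui -= tphi;
      if (method == 3 || method == 4) ui -= rho * z;
      if (method == 5) ui -= rho * sgn;
    }
    u[i] = ui;

    double w[4];
    for (int j = 0; j < 4; ++j) w[j] = exo(j, i) + ui * target_mask[j];
    double xn[4];
    rk4(x, p, dt, w, xn);
    for (int j = 0; j < 4; ++j) {
      if (!std::isfinite(xn[j])) {
        stop("simulation diverged: %s became non-finite at t = %.4f s",
             comp_names[j], (i + 1) * dt);
      }
      x[j] = xn[j];
    }
    if (ctrl && (method == 2 || method == 4)) {
      for (int j = 0; j < m; ++j)
        if (!std::isfinite(theta[j]))
          stop("adaptive weight vector became non-finite at t = %.4f s", (i + 1) * dt);
    }
  }

  List out = List::create(_["states"] = states, _["y"] = y, _["u"] = u,
                          _["s"] = svar, _["z"] = zout);
  if (ctrl && (method == 2 || method == 4)) out["theta"] = theta_hist;
  return out;
}
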