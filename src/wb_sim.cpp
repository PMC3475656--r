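#include <Rcpp.h>
using namespace Rcpp;

// Wang-Buzsaki (1996) rate constants. alpha_m and alpha_n have removable
// singularities at V = -35 and V = -34 mV; evaluate the analytic limit there.
static inline double vtrap(double x) {
  // x / (exp(x) - 1), stable near x = 0 (limit 1 - x/2 + ...)
  if (std::fabs(x) < 1e-7) return 1.0 - x / 2.0;
  return x / (std::exp(x) - 1.0);
}

static inline double alpha_m(double V) { return 1.0 * vtrap(-0.1 * (V + 35.0)); }
static inline double beta_m(double V)  { return 4.0 * std::exp(-(V + 60.0) / 18.0); }
static inline double alpha_h(double V) { return 0.07 * std::exp(-(V + 58.0) / 20.0); }
static inline double beta_h(double V)  { return 1.0 / (std::exp(-0.1 * (V + 28.0)) + 1.0); }
static inline double alpha_n(double V) { return 0.1 * vtrap(-0.1 * (V + 34.0)); }
static inline double beta_n(double V)  { return 0.125 * std::exp(-(V + 44.0) / 80.0); }

// [[Rcpp::export(name = ".wb_rates_cpp")]]
NumericMatrix wb_rates_cpp(NumericVector V) {
  int n = V.size();
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    double v = V[i];
    out(i, 0) = alpha_m(v); out(i, 1) = beta_m(v);
    out(i, 2) = alpha_h(v); out(i, 3) = beta_h(v);
    out(i, 4) = alpha_n(v); out(i, 5) = beta_n(v);
  }
  colnames(out) = CharacterVector::create("alpha_m", "beta_m", "alpha_h",
                                          "beta_h", "alpha_n", "beta_n");
  return out;
}

// The per-step noise draw used by the integrator, exposed so the discrete
// variance contract (Var = half^2 / 3 = 2*lambda/dt under the default
// dialect) can be verified on the exact sampling path.
// [[Rcpp::export(name = ".noise_draws_cpp")]]
NumericVector noise_draws_cpp(int n, double noise_half) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = R::runif(-noise_half, noise_half);
  return out;
}

struct WBParams {
  double E_L, E_Na, E_K, g_L, g_Na, g_K, C_m, zeta;
  double g_slow, tau_z_fast, tau_z_slow, V_z;
};

struct WBState { double V, h, n, z; };

// Right-hand side of the WB model; m is slaved to m_inf(V).
static inline WBState wb_deriv(const WBState &s, double I_inj, double xi,
                               const WBParams &p) {
  double am = alpha_m(s.V), bm = beta_m(s.V);
  double m_inf = am / (am + bm);
  double I_L = p.g_L * (s.V - p.E_L);
  double I_Na = p.g_Na * m_inf * m_inf * m_inf * s.h * (s.V - p.E_Na);
  double I_K = p.g_K * std::pow(s.n, 4) * (s.V - p.E_K);
  double I_slow = p.g_slow * s.z * (s.V - p.E_K);
  WBState d;
  d.V = (-I_L - I_Na - I_K - I_slow + I_inj) / p.C_m + xi;
  d.h = p.zeta * (alpha_h(s.V) * (1.0 - s.h) - beta_h(s.V) * s.h);
  d.n = p.zeta * (alpha_n(s.V) * (1.0 - s.n) - beta_n(s.V) * s.n);
  // slow K gate: charges with tau_z_fast above V_z, decays with tau_z_slow
  double z_inf = (s.V >= p.V_z) ? 1.0 : 0.0;
  double tau_z = (s.V >= p.V_z) ? p.tau_z_fast : p.tau_z_slow;
  d.z = (z_inf - s.z) / tau_z;
  return d;
}

static WBParams unpack_params(List params) {
  WBParams p;
  p.E_L = params["E_L"]; p.E_Na = params["E_Na"]; p.E_K = params["E_K"];
  p.g_L = params["g_L"]; p.g_Na = params["g_Na"]; p.g_K = params["g_K"];
  p.C_m = params["C_m"]; p.zeta = params["zeta"];
  p.g_slow = params["g_slow"];
  p.tau_z_fast = params["tau_z_fast"]; p.tau_z_slow = params["tau_z_slow"];
  p.V_z = params["V_z"];
  return p;
}

// Second-order Runge-Kutta (midpoint) integration of the WB neuron.
// The noise current is drawn once per step from a uniform distribution and
// held constant through both RK stages. noise_half is the half-width of that
// uniform; the R wrapper sets it per the chosen dialect. Uses R's RNG so
// set.seed() upstream controls the draw.
// [[Rcpp::export(name = ".wb_simulate_cpp")]]
List wb_simulate_cpp(NumericVector I_inj, double dt, List params,
                     double noise_half, double V0, double z0,
                     bool record_gates) {
  WBParams p = unpack_params(params);
  int n_steps = I_inj.size();
  NumericVector V(n_steps);
  NumericVector hg, ng, zg;
  if (record_gates) { hg = NumericVector(n_steps); ng = NumericVector(n_steps);
                      zg = NumericVector(n_steps); }

  WBState s;
  s.V = V0;
  double am = alpha_m(V0), bm = beta_m(V0); (void)am; (void)bm;
  s.h = alpha_h(V0) / (alpha_h(V0) + beta_h(V0));
  s.n = alpha_n(V0) / (alpha_n(V0) + beta_n(V0));
  s.z = z0;

  RNGScope scope;
  for (int i = 0; i < n_steps; ++i) {
    V[i] = s.V;
    if (record_gates) { hg[i] = s.h; ng[i] = s.n; zg[i] = s.z; }
    double xi = 0.0;
    if (noise_half > 0.0) xi = R::runif(-noise_half, noise_half);
    WBState k1 = wb_deriv(s, I_inj[i], xi, p);
    WBState mid = { s.V + 0.5 * dt * k1.V, s.h + 0.5 * dt * k1.h,
                    s.n + 0.5 * dt * k1.n, s.z + 0.5 * dt * k1.z };
    WBState k2 = wb_deriv(mid, I_inj[i], xi, p);
    s.V += dt * k2.V; s.h += dt * k2.h; s.n += dt * k2.n; s.z += dt * k2.z;
    if (!std::isfinite(s.V)) {
      stop("non-finite membrane potential at step %d", i + 1);
    }
  }
  List out = List::create(_["V"] = V);
  if (record_gates) { out["h"] = hg; out["n"] = ng; out["z"] = zg; }
  return out;
}
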