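#include <Rcpp.h>
using namespace Rcpp;

// Conductance-based LIF network integrator.
//
// Membrane equation per unit:
//   C dV/dt = -g_L (V - E_L) - G_e (V - E_e) - G_i (V - E_i)
// integrated with exponential Euler (V relaxes towards the instantaneous
// equilibrium with the instantaneous total conductance held over the step).
//
// Each synaptic channel (e, i) is an alpha-function filter implemented as the
// exact propagation of the two-state linear system
//   g' = -g/tau + y,   y' = -y/tau  =>  over dt:
//   g <- exp(-dt/tau) * (g + dt * y),  y <- exp(-dt/tau) * y
// An event with peak conductance J adds J*e/tau to y, which yields the kernel
// g(t) = (J/tau) * t * exp(1 - t/tau) peaking at exactly J at t = tau.
//
// External drive: per-unit homogeneous Poisson rates, piecewise constant over
// segments; event counts per step are Poisson(rate * dt) draws from R's RNG,
// each event weighted by the mean peak conductance. Recurrent spikes take
// effect on the next step (zero synaptic delay) with their per-connection
// weight. While refractory, V is clamped at V_r and conductances evolve.

// [[Rcpp::export]]
List simulate_lif_cpp(NumericMatrix W, LogicalVector is_e, List np,
                      double dt, int n_steps,
                      NumericMatrix rate_e_ext, NumericMatrix rate_i_ext,
                      IntegerVector seg_end,
                      double amp_ext_e, double amp_ext_i,
                      NumericVector v0, int record_every) {
  const int n = W.nrow();
  const double C    = np["C"],   gL  = np["g_L"], EL = np["E_L"];
  const double Ee   = np["E_e"], Ei  = np["E_i"];
  const double ET   = np["E_T"], Vr  = np["V_r"];
  const double taue = np["tau_e"], taui = np["tau_i"];
  const double tref = np["t_ref"];

  const double dec_e = std::exp(-dt / taue), dec_i = std::exp(-dt / taui);
  const double ke = std::exp(1.0) / taue;  // y-increment per unit peak conductance
  const double ki = std::exp(1.0) / taui;
  const int ref_steps = (int)std::lround(tref / dt);

  std::vector<double> V(v0.begin(), v0.end()), ge(n, 0.0), gi(n, 0.0), ye(n, 0.0), yi(n, 0.0);
  std::vector<double> pe(n, 0.0), pi(n, 0.0);  // pending y-increments for this step
  std::vector<int> ref(n, 0);
  std::vector<int> spk_unit;
  std::vector<double> spk_time;
  std::vector<int> fired;
  fired.reserve(n);

  const int n_seg = seg_end.size();
  int seg = 0;

  const int n_rec = record_every > 0 ? n_steps / record_every : 0;
  NumericMatrix Vrec(n_rec > 0 ? n_rec : 1, n_rec > 0 ? n : 1);
  NumericMatrix GErec(n_rec > 0 ? n_rec : 1, n_rec > 0 ? n : 1);
  NumericMatrix GIrec(n_rec > 0 ? n_rec : 1, n_rec > 0 ? n : 1);
  NumericVector trec(n_rec > 0 ? n_rec : 1);
  int irec = 0;

  const double dt_s = dt / 1000.0;  // rates are in Hz, dt in ms

  for (int step = 0; step < n_steps; ++step) {
    while (seg < n_seg - 1 && step >= seg_end[seg]) ++seg;
    fired.clear();

    for (int u = 0; u < n; ++u) {
      // external Poisson events this step + pending recurrent input
      double re = rate_e_ext(u, seg), ri = rate_i_ext(u, seg);
      double add_e = pe[u], add_i = pi[u];
      if (re > 0) add_e += R::rpois(re * dt_s) * amp_ext_e * ke;
      if (ri > 0) add_i += R::rpois(ri * dt_s) * amp_ext_i * ki;
      pe[u] = 0.0; pi[u] = 0.0;
      ye[u] += add_e; yi[u] += add_i;

      // exact alpha-filter propagation
      ge[u] = dec_e * (ge[u] + dt * ye[u]);
      ye[u] *= dec_e;
      gi[u] = dec_i * (gi[u] + dt * yi[u]);
      yi[u] *= dec_i;

      if (ref[u] > 0) {
        --ref[u];
        V[u] = Vr;
      } else {
        const double gtot = gL + ge[u] + gi[u];
        const double vinf = (gL * EL + ge[u] * Ee + gi[u] * Ei) / gtot;
        V[u] = vinf + (V[u] - vinf) * std::exp(-gtot * dt / C);
        if (!std::isfinite(V[u])) stop("simulation diverged: non-finite membrane potential");
        if (V[u] >= ET) {
          spk_unit.push_back(u + 1);
          spk_time.push_back((step + 1) * dt);
          V[u] = Vr;
          ref[u] = ref_steps;
          fired.push_back(u);
        }
      }
    }

    // recurrent delivery: spikes take effect next step
    for (size_t s = 0; s < fired.size(); ++s) {
      const int src = fired[s];
      if (is_e[src]) {
        for (int tgt = 0; tgt < n; ++tgt) {
          const double w = W(src, tgt);
          if (w > 0) pe[tgt] += w * ke;
        }
      } else {
        for (int tgt = 0; tgt < n; ++tgt) {
          const double w = W(src, tgt);
          if (w > 0) pi[tgt] += w * ki;
        }
      }
    }

    if (record_every > 0 && ((step + 1) % record_every == 0) && irec < n_rec) {
      for (int u = 0; u < n; ++u) {
        Vrec(irec, u) = V[u];
        GErec(irec, u) = ge[u];
        GIrec(irec, u) = gi[u];
      }
      trec[irec] = (step + 1) * dt;
      ++irec;
    }
  }

  List out = List::create(
    _["unit"] = wrap(spk_unit),
    _["time"] = wrap(spk_time));
  if (n_rec > 0) {
    out["t_rec"] = trec;
    out["V"] = Vrec;
    out["G_e"] = GErec;
    out["G_i"] = GIrec;
  }
  return out;
}
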