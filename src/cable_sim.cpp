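#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama stepping kernel for the threshold-reset stochastic cable
// model on a star morphology: J neurites joined at x = 0 (sealed end when
// J == 1), optionally through a lumped soma with its own membrane ODE.
//
// Staggered grid: v and s live at half-integer nodes x = (k + 1/2) dx,
// k = 0..N-1; the spatial derivative dv lives at integer nodes x = k dx,
// k = 0..N. Per step and neurite j:
//   v_k   += (dt/tau_j) * (mu_j - v_k + (lambda_j^2/dx)(dv_{k+1} - dv_k) + s_k)
//   dv_k   = (v_k - v_{k-1})/dx              (interior)
//   s_k   += (dt/tau_s) * (-s_k + amp_j * psi),  psi ~ N(0,1) iid
// with amp_j = 2 sigma_s sqrt(lambda_j tau_s / (dx dt)) on driven neurites
// and 0 on the passive axon. Far ends are sealed (dv_N = 0). At the
// junction all neurites share one voltage v_J: for a nominal soma v_J is
// the flux-balance average with weights w_j = lambda_j G_j; for a lumped
// soma v_J = v_0 obeys tau_0 dv_0/dt = -v_0 + sum_j rho_j lambda_j dv_j(0),
// stepped with the same explicit scheme. The proximal derivative node uses
// the half spacing: dv_0 = (v_0 - v_J) / (dx/2).
//
// Noise is drawn from R's RNG in a fixed (neurite, site) order, so a run is
// exactly reproducible given the R seed, and resets never consume draws.

// [[Rcpp::export]]
List run_cable_cpp(List neurites, double dx, double dt, double tau_s,
                   int junction_type,        // 0 nominal, 1 lumped soma
                   NumericVector jweights,   // per-neurite junction weights
                   double tau_0,
                   int trig_neurite,         // 0-based; -1 = junction node
                   int trig_node, double v_th, double v_re,
                   int mode,                 // 0 free, 1 no-reset, 2 reset
                   int n_steps, int transient_steps,
                   Nullable<List> state_in, bool record_trace) {
  const int J = neurites.size();
  std::vector<int> N(J);
  std::vector<double> tau(J), lam2dx(J), mu(J), amp(J), w(J);
  std::vector<std::vector<double> > v(J), s(J), dv(J);
  double wsum = 0.0;
  for (int j = 0; j < J; ++j) {
    List nj = neurites[j];
    N[j] = as<int>(nj["n"]);
    tau[j] = as<double>(nj["tau"]);
    double lambda = as<double>(nj["lambda"]);
    lam2dx[j] = lambda * lambda / dx;
    mu[j] = as<double>(nj["mu"]);
    amp[j] = as<double>(nj["amp"]);
    w[j] = jweights[j];
    wsum += w[j];
    v[j].assign(N[j], 0.0);
    s[j].assign(N[j], 0.0);
    dv[j].assign(N[j] + 1, 0.0);
  }
  double v0 = 0.0;
  if (state_in.isNotNull()) {
    List st(state_in);
    List vin = st["v"], sin = st["s"];
    for (int j = 0; j < J; ++j) {
      NumericVector vj = vin[j], sj = sin[j];
      if ((int)vj.size() != N[j]) stop("state/lattice size mismatch");
      for (int k = 0; k < N[j]; ++k) { v[j][k] = vj[k]; s[j][k] = sj[k]; }
    }
    v0 = as<double>(st["v_junction"]);
  }

  const double half = 2.0 / dx;  // 1/(dx/2)
  // junction voltage for the nominal case (algebraic flux balance)
  if (junction_type == 0) {
    double num = 0.0;
    for (int j = 0; j < J; ++j) num += w[j] * v[j][0];
    v0 = num / wsum;
  }

  std::vector<double> spikes;
  long n_up = 0, n_samp = 0, n_dsamp = 0;
  double sum_v = 0.0, sum_v2 = 0.0, sum_d = 0.0, sum_d2 = 0.0;
  std::vector<std::vector<double> > node_sum(J), node_sum2(J);
  for (int j = 0; j < J; ++j) {
    node_sum[j].assign(N[j], 0.0);
    node_sum2[j].assign(N[j], 0.0);
  }
  NumericVector trace(record_trace ? n_steps : 0);

  double prev_trig = NA_REAL;
  bool prev_valid = false;
  RNGScope rngscope;

  for (int i = 0; i < n_steps; ++i) {
    // derivative field from current v and junction voltage
    for (int j = 0; j < J; ++j) {
      std::vector<double>& vj = v[j];
      std::vector<double>& dj = dv[j];
      dj[0] = (vj[0] - v0) * half;
      for (int k = 1; k < N[j]; ++k)
        dj[k] = (vj[k] - vj[k - 1]) / dx;
      dj[N[j]] = 0.0;  // sealed far end
    }
    // lumped soma advances with the derivative field at the current level
    if (junction_type == 1) {
      double flux = 0.0;
      for (int j = 0; j < J; ++j) flux += w[j] * dv[j][0];
      v0 += (dt / tau_0) * (-v0 + flux);
    }
    // voltage update
    for (int j = 0; j < J; ++j) {
      const double a = dt / tau[j], l2 = lam2dx[j], m = mu[j];
      std::vector<double>& vj = v[j];
      std::vector<double>& sj = s[j];
      std::vector<double>& dj = dv[j];
      for (int k = 0; k < N[j]; ++k)
        vj[k] += a * (m - vj[k] + l2 * (dj[k + 1] - dj[k]) + sj[k]);
    }
    // nominal junction: algebraic balance on the updated field
    if (junction_type == 0) {
      double num = 0.0;
      for (int j = 0; j < J; ++j) num += w[j] * v[j][0];
      v0 = num / wsum;
    }
    // synaptic field update (driven neurites only)
    for (int j = 0; j < J; ++j) {
      if (amp[j] == 0.0) continue;
      const double b = dt / tau_s, aj = amp[j];
      std::vector<double>& sj = s[j];
      for (int k = 0; k < N[j]; ++k)
        sj[k] += b * (-sj[k] + aj * norm_rand());
    }

    double vt = (trig_neurite < 0) ? v0 : v[trig_neurite][trig_node];
    if (!std::isfinite(vt) || std::fabs(vt) > 1e3)
      stop("numeric blow-up: |v| exceeded 1000 mV at step %d", i);
    if (record_trace) trace[i] = vt;

    bool crossed = prev_valid && prev_trig < v_th && vt >= v_th;
    bool after_transient = i >= transient_steps;

    if (after_transient) {
      sum_v += vt; sum_v2 += vt * vt; ++n_samp;
      if (prev_valid) {
        double d = (vt - prev_trig) / dt;
        sum_d += d; sum_d2 += d * d; ++n_dsamp;
      }
      for (int j = 0; j < J; ++j) {
        const std::vector<double>& vj = v[j];
        std::vector<double>& a1 = node_sum[j];
        std::vector<double>& a2 = node_sum2[j];
        for (int k = 0; k < N[j]; ++k) {
          a1[k] += vj[k];
          a2[k] += vj[k] * vj[k];
        }
      }
    }

    if (mode == 1) {            // no-reset: count upcrossings
      if (crossed && after_transient) ++n_up;
      prev_trig = vt; prev_valid = true;
    } else if (mode == 2) {     // integrate-and-fire reset
      if (vt >= v_th) {
        if (after_transient) spikes.push_back((i + 1) * dt);
        for (int j = 0; j < J; ++j)
          for (int k = 0; k < N[j]; ++k) v[j][k] = v_re;
        v0 = v_re;
        prev_valid = false;     // derivative across a reset is meaningless
      } else {
        prev_trig = vt; prev_valid = true;
      }
    } else {
      prev_trig = vt; prev_valid = true;
    }
  }

  List vout(J), sout(J), dvout(J), nsum(J), nsum2(J);
  for (int j = 0; j < J; ++j) {
    vout[j] = NumericVector(v[j].begin(), v[j].end());
    sout[j] = NumericVector(s[j].begin(), s[j].end());
    dvout[j] = NumericVector(dv[j].begin(), dv[j].end());
    nsum[j] = NumericVector(node_sum[j].begin(), node_sum[j].end());
    nsum2[j] = NumericVector(node_sum2[j].begin(), node_sum2[j].end());
  }
  List state = List::create(_["v"] = vout, _["s"] = sout, _["dv"] = dvout,
                            _["v_junction"] = v0);
  List out = List::create(
    _["state"] = state,
    _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
    _["n_upcross"] = (double)n_up,
    _["n_samples"] = (double)n_samp,
    _["sum_v"] = sum_v, _["sum_v2"] = sum_v2,
    _["n_dsamples"] = (double)n_dsamp,
    _["sum_vdot"] = sum_d, _["sum_vdot2"] = sum_d2,
    _["node_sum"] = nsum, _["node_sum2"] = nsum2);
  if (record_trace) out["trace"] = trace;
  return out;
}
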