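// Clock-driven integration core for adaptive exponential integrate-and-fire
// populations with exponential postsynaptic currents, one-step spike
// transmission delay, and calcium/voltage-gated bistable plasticity.
//
// Design notes:
//  - All randomness goes through R's RNG (RNGScope), so a set.seed() on the
//    R side makes runs bit-reproducible.
//  - The bistable drift (constant-rate, direction set by w vs theta_w, capped
//    at the rails) is advanced lazily: per synapse at presynaptic-spike
//    arrivals and once at the end of the run. Because the drift rate is
//    constant and its direction cannot flip between events, lazy advancement
//    is exact and equivalent to per-step application.
//  - Plastic weights are modified in place; the R wrapper passes a copy.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Column order of the per-neuron parameter matrix (kept in step with
// neuron_param_matrix() on the R side).
enum NP {
  P_TAU_M = 0, P_V_REST, P_V_THR, P_SLOPE, P_V_RESET, P_T_REF,
  P_ADAPT_INC, P_TAU_ADAPT, P_CA_INC, P_TAU_CA, NP_NCOL
};

static inline double drift_advance(double w, double elapsed,
                                   double theta_w, double c_drift,
                                   double w_min, double w_max) {
  if (elapsed <= 0.0) return w;
  if (w > theta_w) {
    w += c_drift * elapsed;
    if (w > w_max) w = w_max;
  } else if (w < theta_w) {
    w -= c_drift * elapsed;
    if (w < w_min) w = w_min;
  }
  return w;
}

// [[Rcpp::export]]
List sm_run_core(int n,
                 NumericMatrix nparams,      // n x NP_NCOL
                 NumericMatrix state0,       // n x 5: V, adapt, Ca, refr, Isyn
                 NumericMatrix static_w,     // n x n, row = pre
                 bool has_plastic,
                 NumericMatrix plastic_w,    // n x n (modified in place)
                 IntegerMatrix plastic_exists,
                 IntegerMatrix plastic_learn,
                 double plastic_gain,
                 NumericVector plast_par,
                 bool plasticity_enabled,
                 bool drift_enabled,
                 List epochs,                // list of (targets, rates, start, dur, weight)
                 NumericVector ev_time,      // external spike events (sorted)
                 IntegerVector ev_neuron,
                 NumericVector ev_weight,
                 NumericVector i_const,      // per-neuron constant current
                 double psc_tau,
                 double dt,
                 double duration,
                 bool record) {
  if (n == 0) {
    return List::create(_["times"] = NumericVector(0),
                        _["neurons"] = IntegerVector(0),
                        _["state"] = state0,
                        _["plastic_w"] = plastic_w);
  }
  if (nparams.ncol() != NP_NCOL) stop("neuron parameter matrix has wrong shape");
  if (static_w.nrow() != n || static_w.ncol() != n)
    stop("static weight matrix dimension mismatch: expected %d x %d", n, n);
  if (has_plastic && (plastic_w.nrow() != n || plastic_w.ncol() != n))
    stop("plastic weight matrix dimension mismatch");

  RNGScope rngscope;

  const int n_steps = (int) std::ceil(duration / dt - 1e-9);
  std::vector<double> V(n), adapt(n), Ca(n), refr(n), Isyn(n);
  for (int i = 0; i < n; ++i) {
    V[i] = state0(i, 0); adapt[i] = state0(i, 1); Ca[i] = state0(i, 2);
    refr[i] = state0(i, 3); Isyn[i] = state0(i, 4);
  }

  // Precompute per-neuron decay factors (dt is fixed for the whole run).
  std::vector<double> dec_adapt(n), dec_ca(n);
  const double dec_syn = std::exp(-dt / psc_tau);
  for (int i = 0; i < n; ++i) {
    dec_adapt[i] = std::exp(-dt / nparams(i, P_TAU_ADAPT));
    dec_ca[i]    = std::exp(-dt / nparams(i, P_TAU_CA));
  }

  // Plasticity parameters.
  double th_mem = 0, th1 = 0, th_max = 0, dwp = 0, dwm = 0,
         c_drift = 0, th_w = 0, w_min = 0, w_max = 0, th1_ltd = 0;
  if (has_plastic) {
    th_mem = plast_par[0]; th1 = plast_par[1]; th_max = plast_par[2];
    dwp = plast_par[3]; dwm = plast_par[4]; c_drift = plast_par[5];
    th_w = plast_par[6]; w_min = plast_par[7]; w_max = plast_par[8];
    th1_ltd = plast_par[9];
  }
  // Last drift-advance time per plastic synapse.
  std::vector<double> t_last;
  if (has_plastic) t_last.assign((size_t) n * n, 0.0);

  // Epochs: unpack once.
  const int n_ep = epochs.size();
  std::vector<IntegerVector> ep_targets(n_ep);
  std::vector<NumericVector> ep_lambda(n_ep);  // rate * dt / 1000 (per step)
  std::vector<double> ep_start(n_ep), ep_end(n_ep), ep_weight(n_ep);
  for (int e = 0; e < n_ep; ++e) {
    List ep = epochs[e];
    ep_targets[e] = as<IntegerVector>(ep["targets"]);
    NumericVector rates = as<NumericVector>(ep["rates"]);
    NumericVector lam(rates.size());
    for (int k = 0; k < rates.size(); ++k) lam[k] = rates[k] * dt / 1000.0;
    ep_lambda[e] = lam;
    ep_start[e] = as<double>(ep["start"]);
    ep_end[e] = ep_start[e] + as<double>(ep["duration"]);
    ep_weight[e] = as<double>(ep["weight"]);
    for (int k = 0; k < ep_targets[e].size(); ++k)
      if (ep_targets[e][k] < 0 || ep_targets[e][k] >= n)
        stop("stimulus epoch targets a neuron index out of range");
  }

  // External event stream cursor.
  int ev_cursor = 0;
  const int n_ev = ev_time.size();
  for (int k = 0; k < n_ev; ++k)
    if (ev_neuron[k] < 0 || ev_neuron[k] >= n)
      stop("external event targets a neuron index out of range");

  std::vector<int> spiked_prev;   // spikes emitted last step (deliver now)
  std::vector<int> spiked_now;
  std::vector<double> rec_t;
  std::vector<int> rec_i;
  if (record) { rec_t.reserve(1 << 16); rec_i.reserve(1 << 16); }

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // 1. Deliver last step's spikes (one-step transmission delay).
    for (size_t q = 0; q < spiked_prev.size(); ++q) {
      const int pre = spiked_prev[q];
      for (int post = 0; post < n; ++post) {
        const double w = static_w(pre, post);
        if (w != 0.0) Isyn[post] += w;
      }
      if (has_plastic) {
        for (int post = 0; post < n; ++post) {
          if (!plastic_exists(pre, post)) continue;
          double w = plastic_w(pre, post);
          if (plastic_learn(pre, post)) {
            const size_t idx = (size_t) pre + (size_t) post * n;
            if (drift_enabled) w = drift_advance(w, t - t_last[idx], th_w,
                                                 c_drift, w_min, w_max);
            t_last[idx] = t;
            Isyn[post] += plastic_gain * w;   // efficacy seen by this spike
            if (plasticity_enabled) {
              const double vp = V[post], cap = Ca[post];
              if (vp > th_mem && cap > th1 && cap < th_max) {
                w += dwp; if (w > w_max) w = w_max;
              } else if (vp < th_mem && cap >= th1_ltd && cap < th_max) {
                w -= dwm; if (w < w_min) w = w_min;
              }
            }
            plastic_w(pre, post) = w;
          } else {
            // Auxiliary potentiated synapse: transmits but is frozen.
            Isyn[post] += plastic_gain * w;
          }
        }
      }
    }
    spiked_prev.clear();

    // 2. External Poisson drive.
    for (int e = 0; e < n_ep; ++e) {
      if (t < ep_start[e] || t >= ep_end[e]) continue;
      const IntegerVector& tg = ep_targets[e];
      const NumericVector& lam = ep_lambda[e];
      const double w = ep_weight[e];
      for (int k = 0; k < tg.size(); ++k) {
        if (lam[k] <= 0.0) continue;
        const double nsp = R::rpois(lam[k]);
        if (nsp > 0.0) Isyn[tg[k]] += w * nsp;
      }
    }
    // 2b. Explicit external events falling in [t, t + dt).
    while (ev_cursor < n_ev && ev_time[ev_cursor] < t + dt) {
      if (ev_time[ev_cursor] >= t)
        Isyn[ev_neuron[ev_cursor]] += ev_weight[ev_cursor];
      ++ev_cursor;
    }

    // 3. Integrate membrane, adaptation, calcium; detect spikes.
    for (int i = 0; i < n; ++i) {
      const double tau_m = nparams(i, P_TAU_M);
      const double v_rest = nparams(i, P_V_REST);
      const double v_thr = nparams(i, P_V_THR);
      const double slope = nparams(i, P_SLOPE);

      if (refr[i] > 0.0) {
        refr[i] -= dt;
        V[i] = nparams(i, P_V_RESET);
      } else {
        const double I = Isyn[i] + i_const[i] - adapt[i];
        double v = V[i];
        if (slope > 0.0) {
          // forward Euler with a guarded exponential spike-initiation term
          double a = (v - v_thr) / slope;
          if (a > 20.0) a = 20.0;
          v += dt / tau_m * (-(v - v_rest) + slope * std::exp(a) + I);
        } else {
          // exponential Euler: exact for piecewise-constant input
          const double vinf = v_rest + I;
          v = vinf + (v - vinf) * std::exp(-dt / tau_m);
        }
        if (!R_finite(v))
          stop("membrane potential of neuron %d became non-finite at t = %g ms "
               "(numerical blow-up; reduce dt or input weights)", i + 1, t);
        const double cutoff = slope > 0.0 ? v_thr + 5.0 * slope : v_thr;
        if (v >= cutoff) {
          V[i] = nparams(i, P_V_RESET);
          refr[i] = nparams(i, P_T_REF);
          adapt[i] += nparams(i, P_ADAPT_INC);
          Ca[i] += nparams(i, P_CA_INC);
          spiked_now.push_back(i);
          if (record) { rec_t.push_back(t); rec_i.push_back(i); }
        } else {
          V[i] = v;
        }
      }
      adapt[i] *= dec_adapt[i];
      Ca[i] *= dec_ca[i];
      if (Ca[i] < 0.0) Ca[i] = 0.0;
      Isyn[i] *= dec_syn;
    }
    spiked_prev.swap(spiked_now);   // emitted this step, delivered next step
  }

  // Final lazy-drift advance to the end of the run.
  if (has_plastic && drift_enabled) {
    const double t_end = n_steps * dt;
    for (int pre = 0; pre < n; ++pre)
      for (int post = 0; post < n; ++post)
        if (plastic_exists(pre, post) && plastic_learn(pre, post)) {
          const size_t idx = (size_t) pre + (size_t) post * n;
          plastic_w(pre, post) = drift_advance(plastic_w(pre, post),
                                               t_end - t_last[idx], th_w,
                                               c_drift, w_min, w_max);
        }
  }

  NumericMatrix state(n, 5);
  for (int i = 0; i < n; ++i) {
    state(i, 0) = V[i]; state(i, 1) = adapt[i]; state(i, 2) = Ca[i];
    state(i, 3) = refr[i] > 0.0 ? refr[i] : 0.0; state(i, 4) = Isyn[i];
  }

  return List::create(_["times"] = wrap(rec_t),
                      _["neurons"] = wrap(rec_i),
                      _["state"] = state,
                      _["plastic_w"] = plastic_w);
}
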