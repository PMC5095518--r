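// Core 1-ms forward-Euler simulation loop for the E/I spiking network.
//
// Conventions (mirrored by the R reference functions in R/neuron.R and
// R/plasticity.R, which the tests cross-check against this engine):
//  * units: mV, ms, pA, pF, nS; fixed dt = 1 ms
//  * spike: detected when the Euler update reaches V_PEAK; the detection
//    step's voltage is clipped to V_PEAK and held for one further step
//    (the stereotyped crest), then reset to E_l
//  * traces are Euler low-pass filters x += dt/tau * (drive - x); the
//    presynaptic trace x_bar decays by (1 - dt/tau_x) and bumps by 1 per
//    arrival; lateral x_bar values are stored lazily per synapse with a
//    decay lookup table
//  * per step: deliver delayed spikes -> integrate membranes -> update
//    traces -> LTD (arrival-gated) -> LTP (voltage-gated), weights floored
//    at zero
// All randomness comes from the R RNG so runs are reproducible from set.seed.

#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct PoisTable {
  // inverse-CDF lookup for Poisson(mean) counts
  std::vector<double> cdf;
  void init(double mean) {
    cdf.clear();
    if (mean <= 0) return;
    double p = std::exp(-mean), c = p;
    cdf.push_back(c);
    for (int k = 1; k < 64 && c < 1.0 - 1e-14; ++k) {
      p *= mean / k;
      c += p;
      cdf.push_back(c);
    }
  }
  inline int draw() const {
    if (cdf.empty()) return 0;
    double u = unif_rand();
    size_t k = 0;
    while (k < cdf.size() && u > cdf[k]) ++k;
    return (int)k;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_run_network(arma::mat W_ff, arma::mat W_lat, arma::mat W_EI,
                     arma::mat W_IE, arma::mat W_II,
                     const IntegerMatrix delays,
                     const arma::mat& rates,      // n_in x n_pres (Hz)
                     int stim_ms, int blank_ms,
                     bool plastic,
                     List neuron, List plast, List netp,
                     bool silence_inh, int disable_lat, bool block_spikes,
                     bool record_spikes, bool record_potentials,
                     IntegerVector checkpoint_pres,
                     int verbose_every) {
  const int n_E = W_ff.n_rows, n_in = W_ff.n_cols, n_I = W_EI.n_rows;
  // internal feedforward layout: inputs x cells, so that per-cell passes
  // (input summation, LTD, LTP) all run down contiguous columns
  arma::mat Wff_t = W_ff.t();
  const int n_tot = n_E + n_I;
  const int n_pres = rates.n_cols;
  const int pres_ms = stim_ms + blank_ms;
  const double dt = 1.0;

  // neuron parameters
  const double C = neuron["C"], g_l = neuron["g_l"], E_l = neuron["E_l"],
    Delta_T = neuron["Delta_T"], V_Trest = neuron["V_Trest"],
    V_TMAX = neuron["V_TMAX"], tau_VT = neuron["tau_VT"],
    b_wad = neuron["b_wad"], tau_wad = neuron["tau_wad"],
    I_sp = neuron["I_sp"], tau_z = neuron["tau_z"],
    V_PEAK = neuron["V_PEAK"], exp_cap = neuron["exp_cap"];
  // plasticity parameters
  const double A_LTD = plast["A_LTD"], A_LTP = plast["A_LTP"],
    tau_uplus = plast["tau_uplus"], tau_uminus = plast["tau_uminus"],
    tau_long = plast["tau_long"], tau_x = plast["tau_x"],
    theta_minus = plast["theta_minus"], u_ref = plast["u_ref"],
    gamma_w = plast["gamma"], w_eps = plast["w_eps"];
  const double th_plus = (V_TMAX + V_Trest) / 2.0;
  // network parameters
  const double A_lat = netp["A_lat"], noise_rate = netp["noise_rate"],
    w_noise = netp["w_noise"];

  // state
  arma::vec u(n_tot), V_T(n_tot), w_ad(n_tot, arma::fill::zeros),
    z(n_tot, arma::fill::zeros);
  u.fill(E_l); V_T.fill(V_Trest);
  std::vector<uint8_t> clip(n_tot, 0);
  arma::vec u_plus(n_E), u_minus(n_E), u_long(n_E, arma::fill::zeros);
  u_plus.fill(E_l); u_minus.fill(E_l);
  arma::vec xbar_ff(n_in, arma::fill::zeros);

  // lazy lateral presynaptic traces (post i, pre s) -> index i + s*n_E
  std::vector<double> xlat_val((size_t)n_E * n_E, 0.0);
  std::vector<int64_t> xlat_t((size_t)n_E * n_E, -1);
  const double xdecay1 = 1.0 - dt / tau_x;
  const int XTAB = 2048;
  std::vector<double> xtab(XTAB);
  { double v = 1.0; for (int k = 0; k < XTAB; ++k) { xtab[k] = v; v *= xdecay1; } }
  auto xlat_get = [&](size_t idx, int64_t now) -> double {
    int64_t last = xlat_t[idx];
    if (last < 0) return 0.0;
    int64_t dk = now - last;
    if (dk >= XTAB) return 0.0;
    return xlat_val[idx] * xtab[dk];
  };

  // delay ring buffer of (pre, post) events
  int d_max = 1;
  for (int i = 0; i < n_tot; ++i)
    for (int j = 0; j < n_tot; ++j)
      if (i != j && delays(i, j) > d_max) d_max = delays(i, j);
  const int n_slots = d_max + 1;
  std::vector<std::vector<int32_t>> slots(n_slots);
  const int ENC = 4096;  // event = pre * ENC + post

  PoisTable noise_tab;
  noise_tab.init(noise_rate * 1e-3 * dt);

  // feedforward spike buckets for one presentation
  std::vector<std::vector<int16_t>> ff_at(std::max(stim_ms, 1));

  // outputs
  IntegerMatrix counts_stim(n_E, n_pres), counts_blank(n_E, n_pres);
  NumericMatrix potentials;
  IntegerMatrix pot_n;
  if (record_potentials) {
    potentials = NumericMatrix(n_E, n_pres);
    pot_n = IntegerMatrix(n_E, n_pres);
  }
  std::vector<int> sp_time, sp_id;
  std::vector<bool> is_cp(n_pres + 1, false);
  for (int k = 0; k < checkpoint_pres.size(); ++k) {
    int cp = checkpoint_pres[k];
    if (cp >= 1 && cp <= n_pres) is_cp[cp] = true;
  }
  List cp_lat, cp_ff;
  std::vector<int> cp_idx;

  arma::vec I_ff(n_E), lat_exc(n_E), inh_E(n_E), exc_I(n_I), inh_I(n_I);
  arma::vec ltd(n_E);
  std::vector<int32_t> ee_arrivals;   // encoded pre*ENC+post, this step
  std::vector<int16_t> ff_spiked;     // input channels spiking this step
  const double inv_uref2 = 1.0 / (u_ref * u_ref);

  int64_t now = 0;
  long long tot_spikes_E = 0, tot_spikes_I = 0;

  for (int pres = 0; pres < n_pres; ++pres) {
    // draw this presentation's feedforward spike times (Bernoulli process
    // per channel, sampled by geometric skips)
    for (int t = 0; t < stim_ms; ++t) ff_at[t].clear();
    for (int j = 0; j < n_in; ++j) {
      double p = rates(j, pres) * 1e-3 * dt;
      if (p <= 0) continue;
      if (p >= 1.0) {
        for (int t = 0; t < stim_ms; ++t) ff_at[t].push_back((int16_t)j);
        continue;
      }
      double lq = std::log1p(-p);
      int t = -1;
      for (;;) {
        double uu = unif_rand();
        t += 1 + (int)std::floor(std::log(uu) / lq);
        if (t >= stim_ms) break;
        ff_at[t].push_back((int16_t)j);
      }
    }

    for (int tt = 0; tt < pres_ms; ++tt, ++now) {
      const bool in_stim = tt < stim_ms;
      const int slot = (int)(now % n_slots);

      // 1. deliver delayed lateral spikes
      lat_exc.zeros(); inh_E.zeros(); exc_I.zeros(); inh_I.zeros();
      ee_arrivals.clear();
      for (int32_t ev : slots[slot]) {
        int s = ev / ENC, p2 = ev % ENC;
        if (s < n_E) {
          if (p2 < n_E) {
            lat_exc[p2] += W_lat(p2, s);
            if (plastic) ee_arrivals.push_back(ev);
          } else {
            exc_I[p2 - n_E] += W_EI(p2 - n_E, s);
          }
        } else {
          if (p2 < n_E) inh_E[p2] += W_IE(p2, s - n_E);
          else inh_I[p2 - n_E] += W_II(p2 - n_E, s - n_E);
        }
      }
      slots[slot].clear();

      // 2. feedforward input spikes (per-cell pass down contiguous columns)
      ff_spiked.clear();
      if (in_stim) ff_spiked = ff_at[tt];
      if (ff_spiked.empty()) {
        I_ff.zeros();
      } else {
        for (int i = 0; i < n_E; ++i) {
          const double* col = Wff_t.colptr(i);
          double acc = 0.0;
          for (int16_t j : ff_spiked) acc += col[j];
          I_ff[i] = acc;
        }
      }

      // 3. integrate membranes
      for (int i = 0; i < n_tot; ++i) {
        const bool isE = i < n_E;
        if (!isE && silence_inh) { u[i] = E_l; continue; }  // silenced: frozen
        if (clip[i]) {            // crest step: hold at V_PEAK, then reset
          clip[i] = 0;
          u[i] = V_PEAK;
          V_T[i] += dt / tau_VT * (V_Trest - V_T[i]);
          w_ad[i] *= 1.0 - dt / tau_wad;
          z[i] *= 1.0 - dt / tau_z;
          continue;
        }
        double ui = (u[i] >= V_PEAK) ? E_l : u[i];  // post-crest reset
        double noise_I = w_noise * noise_tab.draw();
        double I_tot;
        if (isE) {
          I_tot = I_ff[i] + A_lat * (lat_exc[i] + inh_E[i]) + noise_I;
        } else {
          I_tot = A_lat * (exc_I[i - n_E] + inh_I[i - n_E]) + noise_I;
        }
        double expo = 0.0;
        if (!block_spikes) {
          double arg = (ui - V_T[i]) / Delta_T;
          if (arg > exp_cap) arg = exp_cap;
          expo = g_l * Delta_T * std::exp(arg);
        }
        double un = ui + dt / C *
          (-g_l * (ui - E_l) + expo - w_ad[i] + z[i] + I_tot);
        V_T[i] += dt / tau_VT * (V_Trest - V_T[i]);
        w_ad[i] *= 1.0 - dt / tau_wad;
        z[i] *= 1.0 - dt / tau_z;
        if (!std::isfinite(un)) {
          stop("numerical blow-up in neuron %d at step %lld", i + 1,
               (long long)now);
        }
        if (un >= V_PEAK) {
          // spike: clip, stereotyped adjustments, enqueue delayed deliveries
          u[i] = V_PEAK;
          clip[i] = 1;
          V_T[i] = V_TMAX;
          w_ad[i] += b_wad;
          z[i] = I_sp;
          if (isE) { ++tot_spikes_E; } else { ++tot_spikes_I; }
          if (isE) {
            if (in_stim) counts_stim(i, pres)++;
            else counts_blank(i, pres)++;
          }
          if (record_spikes) {
            sp_time.push_back((int)now);
            sp_id.push_back(i + 1);
          }
          if (disable_lat != 2) {
            for (int p2 = 0; p2 < n_tot; ++p2) {
              if (p2 == i) continue;
              if (disable_lat == 1 && isE && p2 < n_E) continue;
              int d = delays(p2, i);
              if (d < 1) d = 1;
              slots[(int)((now + d) % n_slots)].push_back(i * ENC + p2);
            }
          }
        } else {
          u[i] = un;
        }
      }

      // 4. traces (observed, post-clipping voltages)
      for (int i = 0; i < n_E; ++i) {
        double ui = u[i];
        u_plus[i]  += dt / tau_uplus  * (ui - u_plus[i]);
        u_minus[i] += dt / tau_uminus * (ui - u_minus[i]);
        double drive = ui - th_plus;
        if (drive < 0) drive = 0;
        u_long[i] += dt / tau_long * (drive - u_long[i]);
      }
      if (plastic) {
        xbar_ff *= xdecay1;
        for (int16_t j : ff_spiked) xbar_ff[j] += 1.0;

        // 5. LTD at presynaptic spike arrival
        for (int i = 0; i < n_E; ++i) {
          double dep = u_minus[i] - theta_minus;
          double ul = u_long[i];
          ltd[i] = dep > 0 ? A_LTD * dep * ul * ul * inv_uref2 : 0.0;
        }
        if (!ff_spiked.empty()) {
          for (int i = 0; i < n_E; ++i) {
            double l = ltd[i];
            if (l <= 0) continue;
            double* col = Wff_t.colptr(i);
            for (int16_t j : ff_spiked) {
              double w = col[j] - l;
              col[j] = w > 0 ? w : 0.0;
            }
          }
        }
        for (int32_t ev : ee_arrivals) {
          int s = ev / ENC, p2 = ev % ENC;
          double w = W_lat(p2, s) - ltd[p2];
          W_lat(p2, s) = w > 0 ? w : 0.0;
          size_t idx = (size_t)p2 + (size_t)s * n_E;
          xlat_val[idx] = xlat_get(idx, now) + 1.0;
          xlat_t[idx] = now;
        }

        // 6. LTP where the voltage exceeds theta_plus (spike crests)
        for (int i = 0; i < n_E; ++i) {
          double over = u[i] - th_plus;
          if (over <= 0) continue;
          double dep = u_plus[i] - theta_minus;
          if (dep <= 0) continue;
          double gate = A_LTP * over * dep;
          double* col = Wff_t.colptr(i);
          for (int j = 0; j < n_in; ++j) {
            double xb = xbar_ff[j];
            if (xb < 1e-9) continue;
            double w = col[j];
            col[j] = w + gate * xb / (gamma_w * (w + w_eps));
          }
          double* lbase = W_lat.memptr() + i;
          for (int s = 0; s < n_E; ++s) {
            if (s == i) continue;
            double xb = xlat_get((size_t)i + (size_t)s * n_E, now);
            if (xb < 1e-9) continue;
            double w = lbase[(size_t)s * n_E];
            lbase[(size_t)s * n_E] = w + gate * xb / (gamma_w * (w + w_eps));
          }
        }
      }

      // 7. subthreshold potential recording (stimulus window, crest excluded)
      if (record_potentials && in_stim) {
        for (int i = 0; i < n_E; ++i) {
          if (u[i] < V_PEAK) {
            potentials(i, pres) += u[i];
            pot_n(i, pres)++;
          }
        }
      }
    }

    if (record_potentials) {
      for (int i = 0; i < n_E; ++i) {
        int denom = pot_n(i, pres);
        potentials(i, pres) /= denom > 0 ? denom : 1;
      }
    }
    if (is_cp[pres + 1]) {
      cp_lat.push_back(arma::vec(arma::vectorise(W_lat)));
      cp_ff.push_back(arma::vec(arma::vectorise(arma::mat(Wff_t.t()))));
      cp_idx.push_back(pres + 1);
    }
    if (verbose_every > 0 && (pres + 1) % verbose_every == 0) {
      Rprintf("presentation=%d mean_E_rate_Hz=%.3f wff_sum=%.1f wlat_sum=%.1f\n",
              pres + 1,
              1000.0 * (double)tot_spikes_E / ((double)n_E * (pres + 1) * pres_ms),
              arma::accu(Wff_t), arma::accu(W_lat));
    }
    if ((pres + 1) % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["counts_stim"] = counts_stim,
    _["counts_blank"] = counts_blank,
    _["potentials"] = potentials,
    _["spike_time"] = IntegerVector(sp_time.begin(), sp_time.end()),
    _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["W_ff"] = arma::mat(Wff_t.t()),
    _["W_lat"] = W_lat,
    _["checkpoints_lat"] = cp_lat,
    _["checkpoints_ff"] = cp_ff,
    _["checkpoint_at"] = IntegerVector(cp_idx.begin(), cp_idx.end()),
    _["total_spikes_E"] = (double)tot_spikes_E,
    _["total_spikes_I"] = (double)tot_spikes_I);
}
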