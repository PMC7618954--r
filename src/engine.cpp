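// Core simulation loop: conductance-based LIF network with co-dependent
// excitatory and inhibitory plasticity. One call advances the network by one
// protocol stage; all state is passed in and returned so stages chain
// continuously. Synaptic and AHP increments from spikes in step s are applied
// at step s+1 (one-step transmission delay); membrane and conductance decay
// use forward Euler; spike traces decay exactly (lazily, at read time).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SynGroup {
  int pre_type;    // 0 = E, 1 = I, 2 = input group
  int input_index; // which input group when pre_type == 2 (0-based)
  int post_type;   // 0 = E, 1 = I
  int n_pre;
  IntegerVector pre, post;     // 0-based synapse endpoints (sorted by pre)
  IntegerVector pre_ptr;       // length n_pre + 1
  IntegerVector post_order;    // synapse ids sorted by post
  IntegerVector post_ptr;      // length n_post + 1
  NumericVector w;             // cloned, mutated in place
  int plastic;                 // 0 static, 1 EE co-dependent, 2 IE ISP
};

inline double lazy_read(const std::vector<double>& tr,
                        const std::vector<int>& last,
                        int i, long step, double dt, double tau) {
  return tr[i] * std::exp(-(step - last[i]) * dt / tau);
}

} // namespace

// [[Rcpp::export]]
List sim_stage_cpp(List state, List groups, List inputs,
                   List np, List pp,
                   double duration_s, double dt,
                   bool plastic_on, bool record_spikes, bool record_inputs,
                   double rate_cap_hz, std::string stage_name) {
  // --- unpack neuron params ---
  const double tau_m = np["tau_m"], V_rest = np["V_rest"], V_th = np["V_th"];
  const double V_AMPA = np["V_AMPA"], V_NMDA = np["V_NMDA"];
  const double V_GABA = np["V_GABA"], V_AHP = np["V_AHP"];
  const double tref_E = np["tau_ref_E"], tref_I = np["tau_ref_I"];
  const double tau_AHP = np["tau_AHP"], A_AHP = np["A_AHP"];
  const double g_L = np["g_L"]; // leak conductance normalising Eq. 2 (nS)
  const bool nmda_spike = as<std::string>(np["nmda_mode"]) == "spike";
  const double f_nmda = np["nmda_fraction"]; // weight fraction entering NMDA
  const bool ahp_on_I = as<bool>(np["ahp_inhibitory"]);
  const double tau_AMPA = np["tau_AMPA"], tau_GABA = np["tau_GABA"],
               tau_NMDA = np["tau_NMDA"];
  // --- plasticity params ---
  const double A_LTP = pp["A_LTP"], A_LTD = pp["A_LTD"], A_het = pp["A_het"];
  const double I_star = pp["I_star"], gamma_ = pp["gamma"];
  const double tau_plus = pp["tau_plus"], tau_minus = pp["tau_minus"],
               tau_yE = pp["tau_yE"];
  const double A_ISP = pp["A_ISP"], alpha = pp["alpha"],
               tau_STDP = pp["tau_STDP"];
  const double tau_Ec = pp["tau_E_curr"], tau_Ic = pp["tau_I_curr"];
  const double sE = pp["current_scale_E"], sI = pp["current_scale_I"];
  const bool as_printed = pp["traces_as_printed"];

  // --- state (cloned: the caller's object is not mutated) ---
  NumericVector V_E = clone(as<NumericVector>(state["V_E"]));
  NumericVector V_I = clone(as<NumericVector>(state["V_I"]));
  NumericVector gA_E = clone(as<NumericVector>(state["g_AHP_E"]));
  NumericVector gM_E = clone(as<NumericVector>(state["g_AMPA_E"]));
  NumericVector gG_E = clone(as<NumericVector>(state["g_GABA_E"]));
  NumericVector gN_E = clone(as<NumericVector>(state["g_NMDA_E"]));
  NumericVector gA_I = clone(as<NumericVector>(state["g_AHP_I"]));
  NumericVector gM_I = clone(as<NumericVector>(state["g_AMPA_I"]));
  NumericVector gG_I = clone(as<NumericVector>(state["g_GABA_I"]));
  NumericVector gN_I = clone(as<NumericVector>(state["g_NMDA_I"]));
  NumericVector ref_E = clone(as<NumericVector>(state["ref_E"]));
  NumericVector ref_I = clone(as<NumericVector>(state["ref_I"]));
  NumericVector Etr = clone(as<NumericVector>(state["E_trace"]));
  NumericVector Itr = clone(as<NumericVector>(state["I_trace"]));
  const int n_E = V_E.size(), n_I = V_I.size();

  std::vector<double> trp(n_E), trm(n_E), trE(n_E), trsE(n_E), trsI(n_I);
  {
    NumericVector a = state["x_plus"], b = state["y_minus"], c = state["y_E"],
                  d = state["y_isp"], e = state["x_isp"];
    for (int i = 0; i < n_E; ++i) {
      trp[i] = a[i]; trm[i] = b[i]; trE[i] = c[i]; trsE[i] = d[i];
    }
    for (int i = 0; i < n_I; ++i) trsI[i] = e[i];
  }
  std::vector<int> last_E(n_E, 0), last_I(n_I, 0);

  // --- groups ---
  const int n_groups = groups.size();
  std::vector<SynGroup> G(n_groups);
  std::vector<std::vector<int> > by_pre_E, by_pre_I;
  std::vector<std::vector<int> > by_input;
  const int n_inputs = inputs.size();
  by_input.resize(n_inputs);
  std::vector<int> input_n(n_inputs);
  std::vector<double> input_p(n_inputs);
  std::vector<int> input_offset(n_inputs);
  int off = n_E + n_I;
  for (int g = 0; g < n_inputs; ++g) {
    List ig = inputs[g];
    input_n[g] = as<int>(ig["n"]);
    input_p[g] = as<double>(ig["rate_hz"]) * dt / 1000.0;
    if (input_p[g] >= 1.0) stop("input rate * dt must be < 1");
    input_offset[g] = off;
    off += input_n[g];
  }
  by_pre_E.resize(1); by_pre_I.resize(1);
  by_pre_E[0].clear(); by_pre_I[0].clear();
  std::vector<int> eplast, iplast; // plastic group ids
  for (int g = 0; g < n_groups; ++g) {
    List gl = groups[g];
    SynGroup& s = G[g];
    s.pre_type = as<int>(gl["pre_type"]);
    s.input_index = as<int>(gl["input_index"]);
    s.post_type = as<int>(gl["post_type"]);
    s.pre = gl["pre"]; s.post = gl["post"];
    s.pre_ptr = gl["pre_ptr"];
    s.post_order = gl["post_order"]; s.post_ptr = gl["post_ptr"];
    s.w = clone(as<NumericVector>(gl["w"]));
    s.plastic = as<int>(gl["plastic"]);
    s.n_pre = s.pre_ptr.size() - 1;
    if (s.pre_type == 0) by_pre_E[0].push_back(g);
    else if (s.pre_type == 1) by_pre_I[0].push_back(g);
    else by_input[s.input_index].push_back(g);
    if (s.plastic == 1) eplast.push_back(g);
    if (s.plastic == 2) iplast.push_back(g);
  }

  const long n_steps = (long)std::floor(duration_s * 1000.0 / dt + 0.5);
  const double dec_AHP = 1.0 - dt / tau_AHP, dec_AMPA = 1.0 - dt / tau_AMPA,
               dec_GABA = 1.0 - dt / tau_GABA, dec_NMDA = 1.0 - dt / tau_NMDA;
  const double k_NMDA = dt / tau_NMDA; // filtered mode: g_NMDA tracks g_AMPA

  std::vector<int> prev_E, prev_I, cur_E, cur_I;
  std::vector<std::vector<int> > prev_in(n_inputs), cur_in(n_inputs);

  std::vector<double> rec_t; std::vector<int> rec_id;
  double Esum = 0, Isum = 0, E2sum = 0, EIsum = 0; long n_monitor = 0;
  std::vector<double> EtrAvg(n_E, 0.0), ItrAvg(n_E, 0.0);
  long cap_count = 0; const long cap_window = (long)(1000.0 / dt); // 1 s
  double t0 = as<double>(state["t_s"]);

  for (long step = 0; step < n_steps; ++step) {
    // 1. decay conductances
    if (nmda_spike) {
      for (int i = 0; i < n_E; ++i) gN_E[i] *= dec_NMDA;
      for (int i = 0; i < n_I; ++i) gN_I[i] *= dec_NMDA;
    } else {
      for (int i = 0; i < n_E; ++i) gN_E[i] += k_NMDA * (gM_E[i] - gN_E[i]);
      for (int i = 0; i < n_I; ++i) gN_I[i] += k_NMDA * (gM_I[i] - gN_I[i]);
    }
    for (int i = 0; i < n_E; ++i) {
      gA_E[i] *= dec_AHP; gM_E[i] *= dec_AMPA; gG_E[i] *= dec_GABA;
    }
    for (int i = 0; i < n_I; ++i) {
      gA_I[i] *= dec_AHP; gM_I[i] *= dec_AMPA; gG_I[i] *= dec_GABA;
    }
    // 2. deliver previous-step spikes
    for (size_t k = 0; k < prev_E.size(); ++k) gA_E[prev_E[k]] += A_AHP;
    if (ahp_on_I)
      for (size_t k = 0; k < prev_I.size(); ++k) gA_I[prev_I[k]] += A_AHP;
    for (int which = 0; which < 2; ++which) {
      const std::vector<int>& sp = which == 0 ? prev_E : prev_I;
      const std::vector<int>& gs = which == 0 ? by_pre_E[0] : by_pre_I[0];
      for (size_t k = 0; k < sp.size(); ++k) {
        int pre = sp[k];
        for (size_t gi = 0; gi < gs.size(); ++gi) {
          SynGroup& s = G[gs[gi]];
          for (int sy = s.pre_ptr[pre]; sy < s.pre_ptr[pre + 1]; ++sy) {
            int tgt = s.post[sy]; double w = s.w[sy];
            if (s.pre_type == 0) { // excitatory
              if (s.post_type == 0) { gM_E[tgt] += w; if (nmda_spike) gN_E[tgt] += f_nmda * w; }
              else { gM_I[tgt] += w; if (nmda_spike) gN_I[tgt] += f_nmda * w; }
            } else {               // inhibitory: GABA
              if (s.post_type == 0) gG_E[tgt] += w;
              else gG_I[tgt] += w;
            }
          }
        }
      }
    }
    for (int g = 0; g < n_inputs; ++g) {
      const std::vector<int>& sp = prev_in[g];
      for (size_t k = 0; k < sp.size(); ++k) {
        int pre = sp[k];
        for (size_t gi = 0; gi < by_input[g].size(); ++gi) {
          SynGroup& s = G[by_input[g][gi]];
          for (int sy = s.pre_ptr[pre]; sy < s.pre_ptr[pre + 1]; ++sy) {
            int tgt = s.post[sy]; double w = s.w[sy];
            if (s.post_type == 0) { gM_E[tgt] += w; if (nmda_spike) gN_E[tgt] += f_nmda * w; }
            else { gM_I[tgt] += w; if (nmda_spike) gN_I[tgt] += f_nmda * w; }
          }
        }
      }
    }
    // 3. membrane update + threshold
    cur_E.clear(); cur_I.clear();
    for (int i = 0; i < n_E; ++i) {
      if (ref_E[i] > 0) { ref_E[i] -= dt; V_E[i] = V_rest; continue; }
      double V = V_E[i];
      V += dt / tau_m * ((V_rest - V) + (gA_E[i] * (V_AHP - V) +
                         gM_E[i] * (V_AMPA - V) + gG_E[i] * (V_GABA - V) +
                         gN_E[i] * (V_NMDA - V)) / g_L);
      if (!R_finite(V))
        stop("numerical instability in stage '%s': non-finite V, E neuron %d, step %ld",
             stage_name.c_str(), i + 1, step);
      if (V < V_GABA) V = V_GABA;          // reversal potentials bound V
      else if (V > V_AMPA) V = V_AMPA;
      if (V >= V_th) { cur_E.push_back(i); V = V_rest; ref_E[i] = tref_E; }
      V_E[i] = V;
    }
    for (int i = 0; i < n_I; ++i) {
      if (ref_I[i] > 0) { ref_I[i] -= dt; V_I[i] = V_rest; continue; }
      double V = V_I[i];
      V += dt / tau_m * ((V_rest - V) + (gA_I[i] * (V_AHP - V) +
                         gM_I[i] * (V_AMPA - V) + gG_I[i] * (V_GABA - V) +
                         gN_I[i] * (V_NMDA - V)) / g_L);
      if (!R_finite(V))
        stop("numerical instability in stage '%s': non-finite V, I neuron %d, step %ld",
             stage_name.c_str(), i + 1, step);
      if (V < V_GABA) V = V_GABA;          // reversal potentials bound V
      else if (V > V_AMPA) V = V_AMPA;
      if (V >= V_th) { cur_I.push_back(i); V = V_rest; ref_I[i] = tref_I; }
      V_I[i] = V;
    }
    // 4. plasticity (uses traces before this step's increments and the
    //    current traces from the end of the previous step)
    if (plastic_on) {
      // excitatory rule, presynaptic-spike (depression) side first: only this
      // term reads w, so the within-step event order is immaterial
      for (size_t ei = 0; ei < eplast.size(); ++ei) {
        SynGroup& s = G[eplast[ei]];
        for (size_t k = 0; k < cur_E.size(); ++k) {
          int pre = cur_E[k];
          for (int sy = s.pre_ptr[pre]; sy < s.pre_ptr[pre + 1]; ++sy) {
            int post = s.post[sy];
            double gate = std::exp(-std::pow(Itr[post] / I_star, gamma_));
            double ym = as_printed
              ? lazy_read(trm, last_E, pre, step, dt, tau_minus)
              : lazy_read(trm, last_E, post, step, dt, tau_minus);
            double w = s.w[sy] - A_LTD * ym * gate * s.w[sy];
            s.w[sy] = w > 0 ? w : 0;
          }
        }
      }
      for (size_t ei = 0; ei < eplast.size(); ++ei) {
        SynGroup& s = G[eplast[ei]];
        for (size_t k = 0; k < cur_E.size(); ++k) {
          int post = cur_E[k];
          double gate = std::exp(-std::pow(Itr[post] / I_star, gamma_));
          double Ep = Etr[post];
          double het = A_het * lazy_read(trE, last_E, post, step, dt, tau_yE) *
                       Ep * Ep * gate;
          double xp_post = as_printed
            ? lazy_read(trp, last_E, post, step, dt, tau_plus) : 0.0;
          for (int sy = s.post_ptr[post]; sy < s.post_ptr[post + 1]; ++sy) {
            int id = s.post_order[sy];
            int pre = s.pre[id];
            double xp = as_printed
              ? xp_post : lazy_read(trp, last_E, pre, step, dt, tau_plus);
            double w = s.w[id] + A_LTP * xp * Ep * gate - het;
            if (!R_finite(w))
              stop("non-finite excitatory weight in stage '%s' (gate %g, E %g, step %ld)",
                   stage_name.c_str(), gate, Ep, step);
            s.w[id] = w > 0 ? w : 0;
          }
        }
      }
      // inhibitory rule
      for (size_t ii = 0; ii < iplast.size(); ++ii) {
        SynGroup& s = G[iplast[ii]];
        for (size_t k = 0; k < cur_E.size(); ++k) { // postsynaptic spikes
          int post = cur_E[k];
          double drive = A_ISP * Etr[post] * (Etr[post] - alpha * Itr[post]);
          double x_post = as_printed
            ? lazy_read(trsE, last_E, post, step, dt, tau_STDP) : 0.0;
          for (int sy = s.post_ptr[post]; sy < s.post_ptr[post + 1]; ++sy) {
            int id = s.post_order[sy];
            double x = as_printed
              ? x_post
              : lazy_read(trsI, last_I, s.pre[id], step, dt, tau_STDP);
            double w = s.w[id] + drive * x;
            s.w[id] = w > 0 ? w : 0;
          }
        }
        for (size_t k = 0; k < cur_I.size(); ++k) { // presynaptic spikes
          int pre = cur_I[k];
          double x_pre = as_printed
            ? lazy_read(trsI, last_I, pre, step, dt, tau_STDP) : 0.0;
          for (int sy = s.pre_ptr[pre]; sy < s.pre_ptr[pre + 1]; ++sy) {
            int post = s.post[sy];
            double drive = A_ISP * Etr[post] * (Etr[post] - alpha * Itr[post]);
            double y = as_printed
              ? x_pre
              : lazy_read(trsE, last_E, post, step, dt, tau_STDP);
            double w = s.w[sy] + drive * y;
            if (!R_finite(w))
              stop("non-finite inhibitory weight in stage '%s' (step %ld)",
                   stage_name.c_str(), step);
            s.w[sy] = w > 0 ? w : 0;
          }
        }
      }
    }
    // 5. trace increments at this step's spikes (lazy exact decay)
    for (size_t k = 0; k < cur_E.size(); ++k) {
      int i = cur_E[k];
      double el = (step - last_E[i]) * dt;
      trp[i] = trp[i] * std::exp(-el / tau_plus) + 1.0;
      trm[i] = trm[i] * std::exp(-el / tau_minus) + 1.0;
      trE[i] = trE[i] * std::exp(-el / tau_yE) + 1.0;
      trsE[i] = trsE[i] * std::exp(-el / tau_STDP) + 1.0;
      last_E[i] = step;
    }
    for (size_t k = 0; k < cur_I.size(); ++k) {
      int i = cur_I[k];
      double el = (step - last_I[i]) * dt;
      trsI[i] = trsI[i] * std::exp(-el / tau_STDP) + 1.0;
      last_I[i] = step;
    }
    // 6. Poisson inputs for this step (delivered next step)
    for (int g = 0; g < n_inputs; ++g) {
      cur_in[g].clear();
      if (input_p[g] <= 0) continue;
      int K = (int)R::rbinom((double)input_n[g], input_p[g]);
      for (int k = 0; k < K; ++k) {
        int id;
        bool dup;
        do {
          id = (int)(unif_rand() * input_n[g]);
          if (id >= input_n[g]) id = input_n[g] - 1;
          dup = false;
          for (int m = 0; m < k; ++m)
            if (cur_in[g].size() > (size_t)m && cur_in[g][m] == id) dup = true;
        } while (dup);
        cur_in[g].push_back(id);
      }
    }
    // 7. filtered current traces (Euler, post-update V and conductances)
    for (int i = 0; i < n_E; ++i) {
      double InE = sE * gN_E[i] * (V_NMDA - V_E[i]);
      double InI = sI * gG_E[i] * (V_E[i] - V_GABA);
      if (InE < 0) InE = 0;
      if (InI < 0) InI = 0;
      Etr[i] += dt / tau_Ec * (-Etr[i] + InE);
      Itr[i] += dt / tau_Ic * (-Itr[i] + InI);
    }
    // 8. record
    double t_now = t0 + (step + 1) * dt / 1000.0;
    if (record_spikes) {
      for (size_t k = 0; k < cur_E.size(); ++k) {
        rec_t.push_back(t_now); rec_id.push_back(cur_E[k]);
      }
      for (size_t k = 0; k < cur_I.size(); ++k) {
        rec_t.push_back(t_now); rec_id.push_back(n_E + cur_I[k]);
      }
      if (record_inputs)
        for (int g = 0; g < n_inputs; ++g)
          for (size_t k = 0; k < cur_in[g].size(); ++k) {
            rec_t.push_back(t_now);
            rec_id.push_back(input_offset[g] + cur_in[g][k]);
          }
    }
    // 9. monitors
    if (step % 10 == 0) {
      double se = 0, si = 0, se2 = 0, sei = 0;
      for (int i = 0; i < n_E; ++i) {
        se += Etr[i]; si += Itr[i];
        se2 += Etr[i] * Etr[i]; sei += Etr[i] * Itr[i];
        EtrAvg[i] += Etr[i]; ItrAvg[i] += Itr[i];
      }
      Esum += se / n_E; Isum += si / n_E;
      E2sum += se2 / n_E; EIsum += sei / n_E; ++n_monitor;
    }
    cap_count += (long)cur_E.size();
    if (rate_cap_hz > 0 && (step + 1) % cap_window == 0) {
      double r = (double)cap_count / n_E; // Hz over the past second
      if (r > rate_cap_hz)
        stop("runaway excitation in stage '%s': mean E rate %.1f Hz exceeds cap %.1f Hz",
             stage_name.c_str(), r, rate_cap_hz);
      cap_count = 0;
    }
    prev_E.swap(cur_E); prev_I.swap(cur_I);
    for (int g = 0; g < n_inputs; ++g) prev_in[g].swap(cur_in[g]);
  }

  // fold lazy decay to the stage end so state chains cleanly
  NumericVector xp(n_E), ym(n_E), yE(n_E), yisp(n_E), xisp(n_I);
  for (int i = 0; i < n_E; ++i) {
    double el = (n_steps - last_E[i]) * dt;
    xp[i] = trp[i] * std::exp(-el / tau_plus);
    ym[i] = trm[i] * std::exp(-el / tau_minus);
    yE[i] = trE[i] * std::exp(-el / tau_yE);
    yisp[i] = trsE[i] * std::exp(-el / tau_STDP);
  }
  for (int i = 0; i < n_I; ++i)
    xisp[i] = trsI[i] * std::exp(-(n_steps - last_I[i]) * dt / tau_STDP);

  List new_state = List::create(
    _["V_E"] = V_E, _["V_I"] = V_I,
    _["g_AHP_E"] = gA_E, _["g_AMPA_E"] = gM_E, _["g_GABA_E"] = gG_E,
    _["g_NMDA_E"] = gN_E,
    _["g_AHP_I"] = gA_I, _["g_AMPA_I"] = gM_I, _["g_GABA_I"] = gG_I,
    _["g_NMDA_I"] = gN_I,
    _["ref_E"] = ref_E, _["ref_I"] = ref_I,
    _["E_trace"] = Etr, _["I_trace"] = Itr,
    _["x_plus"] = xp, _["y_minus"] = ym, _["y_E"] = yE,
    _["y_isp"] = yisp, _["x_isp"] = xisp,
    _["t_s"] = t0 + n_steps * dt / 1000.0);

  List wlist(n_groups);
  for (int g = 0; g < n_groups; ++g) wlist[g] = G[g].w;
  NumericVector avgE(n_E), avgI(n_E);
  for (int i = 0; i < n_E; ++i) {
    avgE[i] = n_monitor ? EtrAvg[i] / n_monitor : 0.0;
    avgI[i] = n_monitor ? ItrAvg[i] / n_monitor : 0.0;
  }

  return List::create(
    _["state"] = new_state,
    _["weights"] = wlist,
    _["spike_time"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["spike_id"] = IntegerVector(rec_id.begin(), rec_id.end()),
    _["mean_E_trace"] = n_monitor ? Esum / n_monitor : 0.0,
    _["mean_I_trace"] = n_monitor ? Isum / n_monitor : 0.0,
    _["mean_E2_trace"] = n_monitor ? E2sum / n_monitor : 0.0,
    _["mean_EI_trace"] = n_monitor ? EIsum / n_monitor : 0.0,
    _["avg_E_trace"] = avgE, _["avg_I_trace"] = avgI);
}
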