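// Simulation engine: map-based (Rulkov) neuron network in a particle
// foraging world, with rewarded STDP, homeostatic/heterosynaptic
// normalization and a REM-like sleep mode.  The R-level operation
// functions in R/ are the reference semantics; this engine exists so
// that multi-thousand-epoch protocols run in seconds.  All randomness
// flows through R's RNG (set.seed reproducible).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cfg {
  double alpha, mu, sigma, beta_e, sigma_e, dt;
  double gamma, Rv, vrp_exc, vrp_inh;
  double gain_ih, gain_ho, gain_inh, gain_noise;
  double pulse_amp; int pulse_steps;
  int epoch_steps, decision_steps;
  double tc_ms, k_max; int pair_window, trace_lifetime;
  double c_epochs, delta_avg, avg_floor;
  double d_tar, target_rate;
  double explore_base, explore_step;
  double ctrl_gain, ctrl_ema;
  double w_floor, wih_cap_frac;
};

Cfg read_cfg(const List& c) {
  Cfg f;
  f.alpha = c["alpha"]; f.mu = c["mu"]; f.sigma = c["sigma"];
  f.beta_e = c["beta_e"]; f.sigma_e = c["sigma_e"]; f.dt = c["dt"];
  f.gamma = c["gamma"]; f.Rv = c["release_var"];
  f.vrp_exc = c["vrp_exc"]; f.vrp_inh = c["vrp_inh"];
  f.gain_ih = c["gain_ih"]; f.gain_ho = c["gain_ho"];
  f.gain_inh = c["gain_inh"]; f.gain_noise = c["gain_noise"];
  f.pulse_amp = c["pulse_amp"]; f.pulse_steps = as<int>(c["pulse_steps"]);
  f.epoch_steps = as<int>(c["epoch_steps"]);
  f.decision_steps = as<int>(c["decision_steps"]);
  f.tc_ms = c["tc_ms"]; f.k_max = c["k_max"];
  f.pair_window = as<int>(c["pair_window"]);
  f.trace_lifetime = as<int>(c["trace_lifetime"]);
  f.c_epochs = c["c_epochs"]; f.delta_avg = c["delta_avg"];
  f.avg_floor = c["avg_floor"];
  f.d_tar = c["d_tar"]; f.target_rate = c["target_rate"];
  f.explore_base = c["explore_base"]; f.explore_step = c["explore_step"];
  f.ctrl_gain = c["ctrl_gain"]; f.ctrl_ema = c["ctrl_ema"];
  f.w_floor = c["w_floor"];
  f.wih_cap_frac = c["wih_cap_frac"];
  return f;
}

inline double release(double Rv) { return 1.0 - Rv + 2.0 * unif_rand() * Rv; }

inline int wrap(int x, int n) { int m = x % n; return m < 0 ? m + n : m; }

// particle pixel offsets by orientation code
// 0 horizontal, 1 vertical, 2 positive diagonal, 3 negative diagonal
inline void ori_offset(int ori, int& dr, int& dc) {
  switch (ori) {
  case 0: dr = 0; dc = 1; break;
  case 1: dr = 1; dc = 0; break;
  case 2: dr = -1; dc = 1; break;
  default: dr = 1; dc = 1; break;
  }
}

const int DIR_R[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
const int DIR_C[8] = {-1, 0, 1,-1, 1,-1, 0, 1};

struct World {
  int W, H;
  std::vector<int> cells;              // H x W, 0 or particle id (1-based)
  std::vector<int> ori, pr, pc;        // per particle (pr,pc 0-based anchor)
  int& at(int r, int c) { return cells[wrap(r, H) * W + wrap(c, W)]; }
  bool neigh_clear(int r, int c, int skip_id) {
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        int v = at(r + dr, c + dc);
        if (v != 0 && v != skip_id) return false;
      }
    return true;
  }
  bool admissible(int r, int c, int ori, int skip_id) {
    int dr, dc; ori_offset(ori, dr, dc);
    if (at(r, c) != 0 || at(r + dr, c + dc) != 0) return false;
    return neigh_clear(r, c, skip_id) && neigh_clear(r + dr, c + dc, skip_id);
  }
  void place(int id, int r, int c) {   // id 1-based, anchor (r,c)
    int dr, dc; ori_offset(ori[id - 1], dr, dc);
    pr[id - 1] = wrap(r, H); pc[id - 1] = wrap(c, W);
    at(r, c) = id; at(r + dr, c + dc) = id;
  }
  void remove(int id) {
    int dr, dc; ori_offset(ori[id - 1], dr, dc);
    at(pr[id - 1], pc[id - 1]) = 0;
    at(pr[id - 1] + dr, pc[id - 1] + dc) = 0;
  }
  bool respawn(int id) {
    for (int tries = 0; tries < 200000; ++tries) {
      int r = (int)std::floor(unif_rand() * H);
      int c = (int)std::floor(unif_rand() * W);
      if (r >= H) r = H - 1;
      if (c >= W) c = W - 1;
      if (admissible(r, c, ori[id - 1], id)) { place(id, r, c); return true; }
    }
    return false;
  }
};

struct Trace { int h, o; double tr, te; };

} // namespace

// One call runs n_epochs of a single phase.  Returns updated state plus
// per-epoch records.  Phase types: "unsupervised", "train", "test", "sleep".
// [[Rcpp::export]]
List engine_run(List net, List envl, List agentl, List phase, int n_epochs,
                List cfgl) {
  Cfg cfg = read_cfg(cfgl);

  // ---- unpack network ----
  int vfs = as<int>(net["vfs"]);
  int n_in = as<int>(net["n_in"]);
  int n_hid = as<int>(net["n_hid"]);
  const int n_dec = 8;                  // decision neurons (3x3 minus center)
  int n_neu = n_in + n_hid + 9;
  int off_h = n_in, off_o = n_in + n_hid;
  int half = (vfs - 1) / 2;

  NumericVector V = clone(as<NumericVector>(net["V"]));
  NumericVector Iv = clone(as<NumericVector>(net["I"]));
  NumericVector Vp = clone(as<NumericVector>(net["Vprev"]));
  NumericVector Ge = clone(as<NumericVector>(net["Gexc"]));
  NumericVector Gi = clone(as<NumericVector>(net["Ginh"]));
  NumericMatrix Wih = clone(as<NumericMatrix>(net["W_ih"]));
  IntegerMatrix src = as<IntegerMatrix>(net["src"]);   // 1-based input ids
  NumericVector row0 = clone(as<NumericVector>(net["row0"]));
  NumericMatrix Who = clone(as<NumericMatrix>(net["W_ho"]));
  NumericVector WI = clone(as<NumericVector>(net["WI"]));
  NumericVector Wj0 = clone(as<NumericVector>(net["Wj0"]));
  NumericVector Wj0ref = as<NumericVector>(net["Wj0_ref"]);
  NumericVector Wi0 = clone(as<NumericVector>(net["Wi0"]));
  IntegerMatrix frozen = clone(as<IntegerMatrix>(net["frozen"]));
  IntegerVector hact = clone(as<IntegerVector>(net["hidden_active"]));
  double avg_tr = as<double>(net["avg_tr"]);
  double epoch_now = as<double>(net["epoch_now"]);
  NumericVector lambda = clone(as<NumericVector>(net["sleep_lambda"]));
  NumericVector rate_ema = clone(as<NumericVector>(net["sleep_rate_ema"]));
  int n_aff = src.ncol();

  std::vector<Trace> traces;
  {
    List tl = net["traces"];
    IntegerVector th = tl["h"], to = tl["o"];
    NumericVector ttr = tl["tr"], tte = tl["te"];
    for (int k = 0; k < th.size(); ++k)
      traces.push_back({th[k] - 1, to[k] - 1, ttr[k], tte[k]});
  }

  // fan-out: input neuron -> (hidden, slot)
  std::vector<std::vector<std::pair<int,int> > > fan(n_in);
  for (int h = 0; h < n_hid; ++h)
    for (int a = 0; a < n_aff; ++a)
      fan[src(h, a) - 1].push_back(std::make_pair(h, a));

  // cached W_IH row sums (kept exact across in-epoch updates)
  std::vector<double> rsum(n_hid, 0.0);
  for (int h = 0; h < n_hid; ++h) {
    double s = 0; for (int a = 0; a < n_aff; ++a) s += Wih(h, a);
    rsum[h] = s;
  }

  // ---- unpack world + agent ----
  World wld;
  wld.W = as<int>(envl["width"]); wld.H = as<int>(envl["height"]);
  {
    IntegerMatrix cm = as<IntegerMatrix>(envl["cells"]); // H x W
    wld.cells.assign(wld.H * wld.W, 0);
    for (int r = 0; r < wld.H; ++r)
      for (int c = 0; c < wld.W; ++c) wld.cells[r * wld.W + c] = cm(r, c);
    IntegerVector o = envl["ori"], prr = envl["pr"], pcc = envl["pc"];
    for (int k = 0; k < o.size(); ++k) {
      wld.ori.push_back(o[k]);
      wld.pr.push_back(prr[k] - 1);
      wld.pc.push_back(pcc[k] - 1);
    }
  }
  int ar = as<int>(agentl["r"]) - 1, ac = as<int>(agentl["c"]) - 1;
  int last_dir = as<int>(agentl["last_dir"]);
  double explore = as<double>(agentl["explore"]);

  // ---- phase flags ----
  std::string ptype = as<std::string>(phase["type"]);
  int task = as<int>(phase["task"]);          // 0 none, 1, 2
  bool plastic_ih = as<bool>(phase["plastic_ih"]);
  bool plastic_ho = as<bool>(phase["plastic_ho"]);
  bool homeo = as<bool>(phase["homeostatic"]);
  bool motor = as<bool>(phase["motor"]);
  bool input_on = as<bool>(phase["input_on"]);
  bool is_sleep = (ptype == "sleep");
  double s_rp_sleep = as<double>(phase["s_rp_sleep"]);
  int snap_every = as<int>(phase["snapshot_every"]);
  bool fixed_vf_mode = phase.containsElementNamed("fixed_vf") &&
    !Rf_isNull(phase["fixed_vf"]);
  IntegerMatrix fixed_vf;
  if (fixed_vf_mode) fixed_vf = as<IntegerMatrix>(phase["fixed_vf"]);
  // reward mapping per task: rewarded / punished orientations
  int ori_rew = (task == 1) ? 0 : (task == 2 ? 1 : -1);
  int ori_pun = (task == 1) ? 3 : (task == 2 ? 2 : -1);

  // ---- records ----
  IntegerVector consumption(n_epochs);       // 0 none,1 rewarded,2 punished,3 other
  IntegerVector dirs(n_epochs);
  std::vector<double> hid_tot(n_hid, 0.0);
  std::vector<double> out_tot(n_dec, 0.0);
  double in_spk_total = 0.0; int n_moves = 0;
  double colsum_err = 0.0;
  double clamp_hits = 0.0, fac_events = 0.0, sum_tr_acc = 0.0,
    abs_sum_tr_acc = 0.0; int n_events = 0;
  std::vector< std::vector<double> > snaps;
  std::vector<double> snap_ep;

  // spike step buffers (absolute step times), current + previous epoch
  std::vector<std::vector<int> > in_cur(n_in), in_prev(n_in);
  std::vector<std::vector<int> > hid_cur(n_hid), hid_prev(n_hid);
  std::vector<std::vector<int> > out_cur(n_dec), out_prev(n_dec);

  const double tc_steps = cfg.tc_ms / cfg.dt;  // trace time constant in steps

  for (int e = 0; e < n_epochs; ++e) {
    // ---- visual field -> stimulated input neurons ----
    std::vector<char> stim(n_in, 0);
    if (input_on && !is_sleep) {
      if (fixed_vf_mode) {
        for (int a = 0; a < vfs; ++a)
          for (int b = 0; b < vfs; ++b)
            if (fixed_vf(a, b) != 0) stim[a * vfs + b] = 1;
      } else {
        for (int a = 0; a < vfs; ++a)
          for (int b = 0; b < vfs; ++b)
            if (wld.at(ar + a - half, ac + b - half) != 0) stim[a * vfs + b] = 1;
      }
    }

    // ---- sleep noise event schedule ----
    std::vector<std::pair<int,int> > noise; // (step, hidden)
    if (is_sleep) {
      for (int h = 0; h < n_hid; ++h) {
        if (!hact[h] || lambda[h] <= 0) continue;
        double p = lambda[h] / cfg.epoch_steps;
        if (p > 1) p = 1;
        int k = (int) R::rbinom(cfg.epoch_steps, p);
        for (int j = 0; j < k; ++j) {
          int s = (int)std::floor(unif_rand() * cfg.epoch_steps);
          if (s >= cfg.epoch_steps) s = cfg.epoch_steps - 1;
          noise.push_back(std::make_pair(s, h));
        }
      }
      std::sort(noise.begin(), noise.end());
    }
    size_t noise_ptr = 0;

    std::vector<int> out_count_dec(n_dec, 0);  // decision-window counts
    std::vector<int> out_count_full(n_dec, 0);
    std::vector<int> spk_in, spk_hid, spk_out; // ids spiking this step
    int abs0 = (int)((epoch_now + e) * (double)cfg.epoch_steps -
                     epoch_now * (double)cfg.epoch_steps);
    // absolute step within this call (windows never span calls)
    int abs_base = e * cfg.epoch_steps; (void)abs0;

    for (int s = 0; s < cfg.epoch_steps; ++s) {
      int t_abs = abs_base + s;
      // sleep noise increments arriving this step
      while (noise_ptr < noise.size() && noise[noise_ptr].first == s) {
        int h = noise[noise_ptr].second;
        Ge[off_h + h] += cfg.gain_noise * release(cfg.Rv);
        ++noise_ptr;
      }
      spk_in.clear(); spk_hid.clear(); spk_out.clear();
      // ---- neuron updates (conductance decay fused in) ----
      // tiny conductances are flushed to zero: geometric decay otherwise
      // walks them through the denormal range, which is pathologically slow
      double* pV = REAL(V); double* pI = REAL(Iv); double* pVp = REAL(Vp);
      double* pGe = REAL(Ge); double* pGi = REAL(Gi);
      bool in_pulse = (s < cfg.pulse_steps);
      for (int i = 0; i < n_neu; ++i) {
        if (i >= off_h && i < off_o && !hact[i - off_h]) continue; // dropped
        double v = pV[i];
        double ext = pGe[i] * (cfg.vrp_exc - v) + pGi[i] * (cfg.vrp_inh - v);
        if (in_pulse && i < n_in && stim[i]) ext += cfg.pulse_amp;
        double Istar = pI[i] + cfg.beta_e * ext;
        double nv; bool spk = false;
        if (v <= 0.0) nv = cfg.alpha / (1.0 - v) - 1.0 + Istar;
        else if (v < cfg.alpha + Istar && pVp[i] <= 0.0) { nv = cfg.alpha + Istar; spk = true; }
        else nv = -1.0;
        pI[i] = pI[i] - cfg.mu * (v + 1.0) + cfg.mu * cfg.sigma +
          cfg.mu * cfg.sigma_e * ext;
        pVp[i] = v; pV[i] = nv;
        pGe[i] = (pGe[i] > 1e-12) ? pGe[i] * cfg.gamma : 0.0;
        pGi[i] = (pGi[i] > 1e-12) ? pGi[i] * cfg.gamma : 0.0;
        if (spk) {
          if (i < n_in) { spk_in.push_back(i); in_spk_total += 1; }
          else if (i < off_o) { spk_hid.push_back(i - off_h); hid_tot[i - off_h] += 1; }
          else if (i != off_o + 4) {         // skip nonfunctional center
            int j9 = i - off_o;
            int k = j9 < 4 ? j9 : j9 - 1;
            spk_out.push_back(k);
            out_tot[k] += 1; out_count_full[k] += 1;
            if (s < cfg.decision_steps) out_count_dec[k] += 1;
          }
        }
      }
      for (size_t q = 0; q < spk_in.size(); ++q) {
        int i = spk_in[q];
        in_cur[i].push_back(t_abs);
        for (size_t f = 0; f < fan[i].size(); ++f) {
          int h = fan[i][f].first, a = fan[i][f].second;
          if (!hact[h] || rsum[h] <= 0) continue;
          Ge[off_h + h] += cfg.gain_ih * release(cfg.Rv) * Wih(h, a) / rsum[h];
        }
      }
      for (size_t q = 0; q < spk_hid.size(); ++q) {
        int h = spk_hid[q];
        hid_cur[h].push_back(t_abs);
        for (int k = 0; k < n_dec; ++k) {
          int j9 = k < 4 ? k : k + 1;
          int o_idx = off_o + j9;
          // excitation is normalized by the FIXED initial target sum so that
          // homeostatic rescaling of the weights feeds back on the drive;
          // inhibition is normalized by the CURRENT target so it tracks the
          // weight scale and homeostasis steers the E/I balance rather than
          // scaling both sides together
          Ge[o_idx] += cfg.gain_ho * release(cfg.Rv) * Who(h, k) / Wj0ref[k];
          Gi[o_idx] += cfg.gain_inh * release(cfg.Rv) * (-WI[h]) / Wj0[k];
        }
      }
      for (size_t q = 0; q < spk_out.size(); ++q) out_cur[spk_out[q]].push_back(t_abs);

      // ---- STDP pairing ----
      if (plastic_ih) {
        for (size_t q = 0; q < spk_hid.size(); ++q) { // pre(input) before post(hidden)
          int h = spk_hid[q];
          for (int a = 0; a < n_aff; ++a) {
            int i = src(h, a) - 1;
            double mult = 1.0;
            for (int side = 0; side < 2; ++side) {
              const std::vector<int>& ts = side ? in_prev[i] : in_cur[i];
              for (size_t u = 0; u < ts.size(); ++u) {
                int d = t_abs - ts[u];
                if (d >= 0 && d <= cfg.pair_window)
                  mult *= 1.0 + cfg.k_max * std::exp(-(double)d / tc_steps);
              }
            }
            if (mult != 1.0) {
              rsum[h] += Wih(h, a) * (mult - 1.0);
              Wih(h, a) *= mult;
            }
          }
        }
        for (size_t q = 0; q < spk_in.size(); ++q) {   // post(hidden) before pre(input)
          int i = spk_in[q];
          for (size_t f = 0; f < fan[i].size(); ++f) {
            int h = fan[i][f].first, a = fan[i][f].second;
            double mult = 1.0;
            for (int side = 0; side < 2; ++side) {
              const std::vector<int>& ts = side ? hid_prev[h] : hid_cur[h];
              for (size_t u = 0; u < ts.size(); ++u) {
                int d = t_abs - ts[u];
                if (d >= 1 && d <= cfg.pair_window)
                  mult *= 1.0 - cfg.k_max * std::exp(-(double)d / tc_steps);
              }
            }
            if (mult != 1.0) {
              rsum[h] += Wih(h, a) * (mult - 1.0);
              Wih(h, a) *= mult;
              if (Wih(h, a) < 0) { rsum[h] -= Wih(h, a); Wih(h, a) = 0; }
            }
          }
        }
      }
      if (plastic_ho) {
        double te = epoch_now + e;
        for (size_t q = 0; q < spk_out.size(); ++q) {  // pre(hidden) before post(out)
          int k = spk_out[q];
          for (int h = 0; h < n_hid; ++h) {
            for (int side = 0; side < 2; ++side) {
              const std::vector<int>& ts = side ? hid_prev[h] : hid_cur[h];
              for (size_t u = 0; u < ts.size(); ++u) {
                int d = t_abs - ts[u];
                if (d >= 0 && d <= cfg.pair_window)
                  traces.push_back({h, k, cfg.k_max * std::exp(-(double)d / tc_steps), te});
              }
            }
          }
        }
        for (size_t q = 0; q < spk_hid.size(); ++q) {  // post(out) before pre(hidden)
          int h = spk_hid[q];
          for (int k = 0; k < n_dec; ++k) {
            for (int side = 0; side < 2; ++side) {
              const std::vector<int>& ts = side ? out_prev[k] : out_cur[k];
              for (size_t u = 0; u < ts.size(); ++u) {
                int d = t_abs - ts[u];
                if (d >= 1 && d <= cfg.pair_window)
                  traces.push_back({h, k, -cfg.k_max * std::exp(-(double)d / tc_steps), te});
              }
            }
          }
        }
      }
    } // steps

    // ---- decision ----
    int choice = -1, best = -1, nb = 0;
    for (int k = 0; k < n_dec; ++k) {
      if (out_count_dec[k] > best) { best = out_count_dec[k]; nb = 1; choice = k; }
      else if (out_count_dec[k] == best) {
        ++nb;
        if (unif_rand() < 1.0 / nb) choice = k;  // reservoir pick among ties
      }
    }
    if (best <= 0) choice = last_dir;            // no output spikes
    dirs[e] = choice;

    // ---- movement + reward event ----
    int kind = 0; double s_rp = 0.0; bool have_event = false;
    if (is_sleep) { s_rp = s_rp_sleep; have_event = true; }
    else if (motor) {
      int dir = choice;
      if (unif_rand() < explore) dir = (int)std::floor(unif_rand() * 8.0);
      if (dir >= 8) dir = 7;
      if (dir >= 0) {
        ar = wrap(ar + DIR_R[dir], wld.H);
        ac = wrap(ac + DIR_C[dir], wld.W);
        last_dir = dir; ++n_moves;
        int id = wld.at(ar, ac);
        if (id > 0) {
          int po = wld.ori[id - 1];
          wld.remove(id);
          wld.respawn(id);
          kind = (po == ori_rew) ? 1 : (po == ori_pun ? 2 : 3);
        }
        s_rp = (kind == 1) ? 1.0 : (kind == 2 ? -0.001 : (kind == 0 ? -0.0001 : 0.0));
        have_event = true;
      }
      // every movement cycle without an acquisition raises the exploration
      // probability by one step; any acquisition resets it to the base
      if (kind == 0) explore = std::min(1.0, explore + cfg.explore_step);
      else explore = cfg.explore_base;
    }
    consumption[e] = kind;

    // ---- trace pruning (6-epoch lifetime) ----
    double t_now = epoch_now + e;
    {
      size_t w = 0;
      for (size_t k = 0; k < traces.size(); ++k)
        if (t_now - traces[k].te <= cfg.trace_lifetime) traces[w++] = traces[k];
      traces.resize(w);
    }

    // ---- rewarded update ----
    if (plastic_ho && have_event) {
      double sum_tr = 0.0;
      for (size_t k = 0; k < traces.size(); ++k)
        sum_tr += traces[k].tr / (t_now - traces[k].te + cfg.c_epochs);
      // cold start: the running average adopts the first realized scale so
      // the Sum/Avg ratio begins at +-1 rather than an arbitrary magnitude
      if (avg_tr < 0.0 && !traces.empty())
        avg_tr = std::max(std::fabs(sum_tr), cfg.avg_floor);
      if (!traces.empty() && s_rp != 0.0) {
        double ratio = sum_tr / std::max(avg_tr, cfg.avg_floor);
        std::vector<double> Wi(n_hid, 0.0);
        for (int h = 0; h < n_hid; ++h) {
          double sw = 0; for (int k = 0; k < n_dec; ++k) sw += Who(h, k);
          Wi[h] = sw;
        }
        for (size_t k = 0; k < traces.size(); ++k) {
          const Trace& t = traces[k];
          if (frozen(t.h, t.o)) continue;
          double dk = s_rp * (t.tr / (t_now - t.te + cfg.c_epochs)) * ratio;
          // the W_i0/W_i boost for weak neurons is capped, and each factor
          // is floored above zero: exact zero would be an absorbing state
          // under a purely multiplicative rule
          double boost = (Wi[t.h] > 0) ? Wi0[t.h] / Wi[t.h] : 10.0;
          if (boost > 10.0) boost = 10.0;
          double fac = 1.0 + boost * dk;
          fac_events += 1.0;
          if (fac < 0.05) { fac = 0.05; clamp_hits += 1.0; }
          if (fac > 20.0) { fac = 20.0; clamp_hits += 1.0; }
          Who(t.h, t.o) *= fac;
        }
        // weak synapses are floored at a small positive value before the
        // renormalization: purely multiplicative dynamics otherwise drive
        // the weak cluster to depths from which replay cannot recruit it
        for (int k = 0; k < n_dec; ++k)
          for (int h = 0; h < n_hid; ++h)
            if (!frozen(h, k) && Who(h, k) < cfg.w_floor) Who(h, k) = cfg.w_floor;
        // heterosynaptic rescale per output column, then inhibitory balance
        for (int k = 0; k < n_dec; ++k) {
          double fs = 0, us = 0;
          for (int h = 0; h < n_hid; ++h)
            (frozen(h, k) ? fs : us) += Who(h, k);
          double tgt = Wj0[k] - fs;
          if (us > 0 && tgt > 0) {
            double f = tgt / us;
            for (int h = 0; h < n_hid; ++h)
              if (!frozen(h, k)) Who(h, k) *= f;
          }
        }
        for (int h = 0; h < n_hid; ++h) {
          double sw = 0; for (int k = 0; k < n_dec; ++k) sw += Who(h, k);
          WI[h] = -sw / n_dec;
        }
      }
      if (avg_tr >= 0.0)
        avg_tr = (1.0 - cfg.delta_avg) * avg_tr + cfg.delta_avg * sum_tr;
      sum_tr_acc += sum_tr; abs_sum_tr_acc += std::fabs(sum_tr); ++n_events;
    }

    // ---- homeostatic scaling (every epoch while H->O plasticity is on) ----
    if (plastic_ho && homeo) {
      for (int k = 0; k < n_dec; ++k) {
        double rate = out_count_full[k];
        if (rate < cfg.target_rate) Wj0[k] *= (1.0 + cfg.d_tar);
        else if (rate > cfg.target_rate) Wj0[k] *= (1.0 - cfg.d_tar);
        double fs = 0, us = 0;
        for (int h = 0; h < n_hid; ++h)
          (frozen(h, k) ? fs : us) += Who(h, k);
        double tgt = Wj0[k] - fs;
        if (us > 0 && tgt > 0) {
          double f = tgt / us;
          for (int h = 0; h < n_hid; ++h)
            if (!frozen(h, k)) Who(h, k) *= f;
        }
      }
      for (int h = 0; h < n_hid; ++h) {
        double sw = 0; for (int k = 0; k < n_dec; ++k) sw += Who(h, k);
        WI[h] = -sw / n_dec;
      }
      // invariant diagnostic: column sums vs Wj0
      for (int k = 0; k < n_dec; ++k) {
        double cs = 0, fs = 0;
        for (int h = 0; h < n_hid; ++h) { cs += Who(h, k); if (frozen(h,k)) fs += Who(h,k); }
        double tgt = Wj0[k];
        if (tgt > fs) {
          double err = std::fabs(cs - tgt) / std::max(tgt, 1e-12);
          if (err > colsum_err) colsum_err = err;
        }
      }
    }

    // ---- W_IH row renormalization (scale hygiene; unsupervised phase) ----
    // each afferent is also capped at a fraction of the row sum: without a
    // saturation bound multiplicative STDP concentrates the whole row onto
    // one input and the neuron degenerates from a conjunction (orientation)
    // detector into a single-pixel detector
    if (plastic_ih) {
      for (int h = 0; h < n_hid; ++h) {
        if (rsum[h] <= 0) continue;
        double f = row0[h] / rsum[h];
        for (int a = 0; a < n_aff; ++a) Wih(h, a) *= f;
        double cap = cfg.wih_cap_frac * row0[h];
        double s = 0;
        for (int a = 0; a < n_aff; ++a) {
          if (Wih(h, a) > cap) Wih(h, a) = cap;
          s += Wih(h, a);
        }
        rsum[h] = s;
      }
    }

    // ---- sleep rate controller ----
    if (is_sleep) {
      for (int h = 0; h < n_hid; ++h) {
        double realized = 0;
        for (size_t u = 0; u < hid_cur[h].size(); ++u) realized += 1;
        rate_ema[h] = (1.0 - cfg.ctrl_ema) * rate_ema[h] + cfg.ctrl_ema * realized;
      }
      NumericVector tgt = as<NumericVector>(phase["target_rates"]);
      for (int h = 0; h < n_hid; ++h) {
        double err = tgt[h] - rate_ema[h];
        lambda[h] *= (1.0 + cfg.ctrl_gain * err / std::max(tgt[h], 0.25));
        if (lambda[h] < 0.01) lambda[h] = 0.01;
        if (lambda[h] > 60.0) lambda[h] = 60.0;
      }
    }

    // ---- snapshots ----
    if (snap_every > 0 && ((e + 1) % snap_every == 0 || e == n_epochs - 1)) {
      std::vector<double> v(n_hid * n_dec);
      for (int k = 0; k < n_dec; ++k)
        for (int h = 0; h < n_hid; ++h) v[k * n_hid + h] = Who(h, k);
      snaps.push_back(v);
      snap_ep.push_back(epoch_now + e);
    }

    // rotate spike buffers
    in_prev.swap(in_cur); hid_prev.swap(hid_cur); out_prev.swap(out_cur);
    for (int i = 0; i < n_in; ++i) in_cur[i].clear();
    for (int h = 0; h < n_hid; ++h) hid_cur[h].clear();
    for (int k = 0; k < n_dec; ++k) out_cur[k].clear();
  } // epochs

  epoch_now += n_epochs;

  // ---- repack ----
  int nt = traces.size();
  IntegerVector th(nt), to(nt); NumericVector ttr(nt), tte(nt);
  for (int k = 0; k < nt; ++k) {
    th[k] = traces[k].h + 1; to[k] = traces[k].o + 1;
    ttr[k] = traces[k].tr; tte[k] = traces[k].te;
  }
  List net2 = clone(net);
  net2["V"] = V; net2["I"] = Iv; net2["Vprev"] = Vp;
  net2["Gexc"] = Ge; net2["Ginh"] = Gi;
  net2["W_ih"] = Wih; net2["row0"] = row0;
  net2["W_ho"] = Who; net2["WI"] = WI; net2["Wj0"] = Wj0; net2["Wi0"] = Wi0;
  net2["frozen"] = frozen; net2["hidden_active"] = hact;
  net2["avg_tr"] = avg_tr; net2["epoch_now"] = epoch_now;
  net2["sleep_lambda"] = lambda; net2["sleep_rate_ema"] = rate_ema;
  net2["traces"] = List::create(_["h"] = th, _["o"] = to,
                                _["tr"] = ttr, _["te"] = tte);

  IntegerMatrix cells(wld.H, wld.W);
  for (int r = 0; r < wld.H; ++r)
    for (int c = 0; c < wld.W; ++c) cells(r, c) = wld.cells[r * wld.W + c];
  IntegerVector po(wld.ori.size()), ppr(wld.ori.size()), ppc(wld.ori.size());
  for (size_t k = 0; k < wld.ori.size(); ++k) {
    po[k] = wld.ori[k]; ppr[k] = wld.pr[k] + 1; ppc[k] = wld.pc[k] + 1;
  }
  List env2 = clone(envl);
  env2["cells"] = cells; env2["ori"] = po; env2["pr"] = ppr; env2["pc"] = ppc;

  List agent2 = List::create(_["r"] = ar + 1, _["c"] = ac + 1,
                             _["last_dir"] = last_dir, _["explore"] = explore);

  NumericMatrix sm(snaps.size(), n_hid * n_dec);
  for (size_t i = 0; i < snaps.size(); ++i)
    for (int j = 0; j < n_hid * n_dec; ++j) sm(i, j) = snaps[i][j];

  return List::create(
    _["net"] = net2, _["env"] = env2, _["agent"] = agent2,
    _["consumption"] = consumption, _["dirs"] = dirs,
    _["hid_spikes"] = NumericVector(hid_tot.begin(), hid_tot.end()),
    _["out_spikes"] = NumericVector(out_tot.begin(), out_tot.end()),
    _["in_spike_total"] = in_spk_total, _["n_moves"] = n_moves,
    _["snapshots"] = sm, _["snap_epochs"] = NumericVector(snap_ep.begin(), snap_ep.end()),
    _["colsum_err"] = colsum_err, _["n_traces"] = nt,
    _["clamp_frac"] = fac_events > 0 ? clamp_hits / fac_events : 0.0,
    _["mean_sum_tr"] = n_events > 0 ? sum_tr_acc / n_events : 0.0,
    _["mean_abs_sum_tr"] = n_events > 0 ? abs_sum_tr_acc / n_events : 0.0);
}

// Iterate a single map neuron under a supplied external-current sequence.
// Dual-route check target for the pure-R stepper.
// [[Rcpp::export]]
List simulate_neuron_cpp(double V0, double I0, double Vprev0,
                         NumericVector I_ext, double alpha, double mu,
                         double sigma, double beta_e, double sigma_e) {
  int n = I_ext.size();
  NumericVector V(n), Iv(n); LogicalVector spk(n);
  double v = V0, ii = I0, vp = Vprev0;
  for (int s = 0; s < n; ++s) {
    double Istar = ii + beta_e * I_ext[s];
    double nv; bool sp = false;
    if (v <= 0.0) nv = alpha / (1.0 - v) - 1.0 + Istar;
    else if (v < alpha + Istar && vp <= 0.0) { nv = alpha + Istar; sp = true; }
    else nv = -1.0;
    double ni = ii - mu * (v + 1.0) + mu * sigma + mu * sigma_e * I_ext[s];
    vp = v; v = nv; ii = ni;
    V[s] = v; Iv[s] = ii; spk[s] = sp;
  }
  return List::create(_["V"] = V, _["I"] = Iv, _["spiked"] = spk,
                      _["V_last"] = v, _["I_last"] = ii, _["Vprev_last"] = vp);
}
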