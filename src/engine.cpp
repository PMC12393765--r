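// Conductance-based network integrator.
//
// Units: time ms, voltage mV, conductance uS, current nA, capacitance nF.
// Membrane update: exponential Euler with an A-stable Pade factor
// (1 - x/2)/(1 + x/2) ~ exp(-x); gating via Rush-Larsen with voltage lookup
// tables built per call for the fixed dt. Synapses are lumped double
// exponential conductance slots (one pair of states per target/kind);
// delayed deliveries go through a ring buffer of (slot, weight) events.
//
// Kinetics: pyramidal compartments use Traub-Miles style transient Na /
// delayed-rectifier K plus a slow hyperpolarization-activated current;
// basket cells use Wang-Buzsaki fast-spiking kinetics (instantaneous m).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the singularity removed
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / y / 2.0);
  return x / (1.0 - std::exp(-x / y));
}

struct GateTab {
  double vmin, dv;
  std::vector<double> xinf, rel;  // rel = exp(-dt*(a+b))
  inline void at(double v, double &xi, double &rl) const {
    double u = (v - vmin) / dv;
    int i = (int)u;
    int n = (int)xinf.size();
    if (i < 0) { xi = xinf[0]; rl = rel[0]; return; }
    if (i >= n - 1) { xi = xinf[n - 1]; rl = rel[n - 1]; return; }
    double f = u - i;
    xi = xinf[i] + f * (xinf[i + 1] - xinf[i]);
    rl = rel[i] + f * (rel[i + 1] - rel[i]);
  }
};

void build_tab(GateTab &t, double dt,
               double (*alpha)(double), double (*beta)(double)) {
  t.vmin = -130.0; t.dv = 0.05;
  int n = (int)((60.0 - t.vmin) / t.dv) + 1;
  t.xinf.resize(n); t.rel.resize(n);
  for (int i = 0; i < n; ++i) {
    double v = t.vmin + i * t.dv;
    double a = alpha(v), b = beta(v);
    t.xinf[i] = a / (a + b);
    t.rel[i] = std::exp(-dt * (a + b));
  }
}

// Traub-Miles pyramidal kinetics (rates in 1/ms)
double pc_am(double v) { return 0.32 * vtrap(v + 54.0, 4.0); }
double pc_bm(double v) { return 0.28 * vtrap(-(v + 27.0), 5.0); }
double pc_ah(double v) { return 0.128 * std::exp(-(v + 50.0) / 18.0); }
double pc_bh(double v) { return 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0)); }
double pc_an(double v) { return 0.032 * vtrap(v + 52.0, 5.0); }
double pc_bn(double v) { return 0.5 * std::exp(-(v + 57.0) / 40.0); }
// hyperpolarization-activated current: slow, opens on hyperpolarization
double pc_ar(double v) { double ri = 1.0 / (1.0 + std::exp((v + 80.0) / 8.0));
                         return ri / 100.0; }
double pc_br(double v) { double ri = 1.0 / (1.0 + std::exp((v + 80.0) / 8.0));
                         return (1.0 - ri) / 100.0; }
// Wang-Buzsaki basket-cell kinetics, phi = 5 on h and n
double bc_am(double v) { return 0.1 * vtrap(v + 35.0, 10.0); }
double bc_bm(double v) { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
double bc_ah(double v) { return 5.0 * 0.07 * std::exp(-(v + 58.0) / 20.0); }
double bc_bh(double v) { return 5.0 / (1.0 + std::exp(-0.1 * (v + 28.0))); }
double bc_an(double v) { return 5.0 * 0.01 * vtrap(v + 34.0, 10.0); }
double bc_bn(double v) { return 5.0 * 0.125 * std::exp(-(v + 44.0) / 80.0); }

// small counter-based RNG (splitmix64) for per-source Poisson streams
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

} // namespace

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(List nodes, List edges, List slots, List net_syn,
                     List theta_in, List poisson_in, List extra_in,
                     List opts) {
  // --- nodes ---
  NumericVector cm = nodes["cm"], gl = nodes["gl"], el = nodes["el"],
                gna = nodes["gna"], gk = nodes["gk"], gh = nodes["gh"];
  const double ena_pc = as<double>(nodes["ena_pc"]),
               ek_pc = as<double>(nodes["ek_pc"]),
               eh = as<double>(nodes["eh"]),
               ena_bc = as<double>(nodes["ena_bc"]),
               ek_bc = as<double>(nodes["ek_bc"]);
  IntegerVector kin = nodes["kin"];             // 0 PC, 1 BC
  IntegerVector cell_of = nodes["cell"];        // 0-based cell index
  IntegerVector det_node = nodes["detect_node"];// per cell: node for spikes
  IntegerVector pcsoma = nodes["pc_soma_nodes"];// nodes entering V_PC/i_transm
  IntegerVector pcdend = nodes["pc_dend_nodes"];// nodes for dendritic i_transm
  const int n_pc = as<int>(nodes["n_pc"]);
  const int n_cells = det_node.size();
  const int nn = cm.size();

  // --- axial edges ---
  IntegerVector ea = edges["a"], eb = edges["b"];
  NumericVector eg = edges["g"];
  // adjacency in CSR
  std::vector<int> deg(nn, 0);
  for (int e = 0; e < ea.size(); ++e) { deg[ea[e]]++; deg[eb[e]]++; }
  std::vector<int> aptr(nn + 1, 0);
  for (int i = 0; i < nn; ++i) aptr[i + 1] = aptr[i] + deg[i];
  std::vector<int> anbr(aptr[nn]);
  std::vector<double> ag(aptr[nn]);
  { std::vector<int> pos(aptr.begin(), aptr.end() - 1);
    for (int e = 0; e < ea.size(); ++e) {
      anbr[pos[ea[e]]] = eb[e]; ag[pos[ea[e]]++] = eg[e];
      anbr[pos[eb[e]]] = ea[e]; ag[pos[eb[e]]++] = eg[e];
    } }

  // --- synapse slots ---
  IntegerVector s_node = slots["node"], s_kind = slots["kind"];
  NumericVector s_erev = slots["erev"], s_taur = slots["taur"],
                s_taud = slots["taud"];
  const int ns = s_node.size();
  std::vector<double> sA(ns, 0.0), sB(ns, 0.0), s_ra(ns), s_rd(ns), s_nrm(ns);
  const double dt = as<double>(opts["dt"]);
  for (int s = 0; s < ns; ++s) {
    s_ra[s] = std::exp(-dt / s_taur[s]);
    s_rd[s] = std::exp(-dt / s_taud[s]);
    double tr = s_taur[s], td = s_taud[s];
    double tp = tr * td / (td - tr) * std::log(td / tr);
    s_nrm[s] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  }

  // --- network synapses (CSR by presynaptic cell) ---
  IntegerVector syn_ptr = net_syn["ptr"], syn_slot = net_syn["slot"],
                syn_dstep = net_syn["delay_steps"];
  NumericVector syn_w = net_syn["w"];

  // --- theta drive ---
  NumericVector th_t = theta_in["t"];
  IntegerVector th_unit = theta_in["unit"];
  IntegerVector th_ptr = theta_in["ptr"], th_slot = theta_in["slot"],
                th_dstep = theta_in["delay_steps"];
  NumericVector th_w = theta_in["w"];

  // --- poisson sources ---
  IntegerVector po_slot = poisson_in["slot"];
  NumericVector po_w = poisson_in["w"], po_interval = poisson_in["interval"];
  IntegerVector po_stream = poisson_in["stream"]; // 0 noise, 1 parallel
  const double noise_seed = as<double>(opts["noise_seed"]);
  const double parallel_seed = as<double>(opts["parallel_seed"]);
  const int npo = po_slot.size();
  std::vector<SplitMix> po_rng;
  std::vector<double> po_next(npo);
  po_rng.reserve(npo);
  for (int p = 0; p < npo; ++p) {
    uint64_t base = (po_stream[p] == 0 ? (uint64_t)noise_seed
                                       : (uint64_t)parallel_seed);
    po_rng.emplace_back(base * 0x9E3779B97F4A7C15ULL + (uint64_t)(p + 1) * 0xD1B54A32D192ED03ULL);
    po_next[p] = -po_interval[p] * std::log(po_rng[p].unif());
  }

  // --- extra events ---
  NumericVector ev_t = extra_in["t"];
  IntegerVector ev_slot = extra_in["slot"];
  NumericVector ev_w = extra_in["w"];

  // --- options ---
  const int n_steps = as<int>(opts["n_steps"]);
  const int rec_every = as<int>(opts["rec_every"]);
  const double v_thresh = as<double>(opts["spike_threshold"]);
  const double refr = as<double>(opts["refractory_ms"]);
  const double mg = as<double>(opts["mg"]);
  IntegerVector rec_slots = opts["theta_current_slots"]; // 0-based slot ids

  // --- gating tables ---
  GateTab Tpm, Tph, Tpn, Tpr, Tbm, Tbh, Tbn;
  build_tab(Tpm, dt, pc_am, pc_bm);
  build_tab(Tph, dt, pc_ah, pc_bh);
  build_tab(Tpn, dt, pc_an, pc_bn);
  build_tab(Tpr, dt, pc_ar, pc_br);
  build_tab(Tbm, dt, bc_am, bc_bm);
  build_tab(Tbh, dt, bc_ah, bc_bh);
  build_tab(Tbn, dt, bc_an, bc_bn);

  // --- state ---
  const double v0 = as<double>(opts["v_init"]);
  std::vector<double> V(nn, v0), gm(nn), gh_(nn), gn(nn), gr(nn);
  for (int i = 0; i < nn; ++i) {
    double xi, rl;
    if (kin[i] == 0) {
      Tpm.at(V[i], xi, rl); gm[i] = xi;
      Tph.at(V[i], xi, rl); gh_[i] = xi;
      Tpn.at(V[i], xi, rl); gn[i] = xi;
      Tpr.at(V[i], xi, rl); gr[i] = xi;
    } else {
      Tbh.at(V[i], xi, rl); gh_[i] = xi;
      Tbn.at(V[i], xi, rl); gn[i] = xi;
    }
  }
  std::vector<double> gsyn(nn), gesyn(nn);
  std::vector<double> last_spike(n_cells, -1e9);
  std::vector<double> vprev_det(n_cells, v0);

  // delay ring
  int max_d = 2;
  for (int i = 0; i < syn_dstep.size(); ++i) max_d = std::max(max_d, syn_dstep[i]);
  for (int i = 0; i < th_dstep.size(); ++i) max_d = std::max(max_d, th_dstep[i]);
  const int ring_len = max_d + 2;
  std::vector<std::vector<std::pair<int, double> > > ring(ring_len);

  // recording buffers
  const int n_rec = n_steps / rec_every;
  NumericVector rec_vpc(n_rec), rec_itr(n_rec), rec_ith(n_rec), rec_vbc(n_rec),
                rec_itd(n_rec);
  double acc_v = 0, acc_i = 0, acc_th = 0, acc_vb = 0, acc_d = 0;
  int n_bc_nodes = 0;
  for (int i = 0; i < nn; ++i) if (kin[i] == 1) n_bc_nodes++;

  std::vector<int> sp_cell; std::vector<double> sp_t;
  std::vector<double> par_t;  // parallel-pathway event times (pooled)

  // cable chains: every edge connects consecutive nodes, so cells are
  // chains delimited by missing (i, i+1) edges
  std::vector<double> edge_g(nn, 0.0);
  for (int e = 0; e < ea.size(); ++e) {
    if (eb[e] != ea[e] + 1) stop("axial edges must connect consecutive nodes");
    edge_g[ea[e]] = eg[e];
  }
  std::vector<int> chain_start, chain_end;
  { int s0 = 0;
    for (int i = 0; i < nn; ++i) {
      if (edge_g[i] == 0.0) { chain_start.push_back(s0); chain_end.push_back(i + 1); s0 = i + 1; }
    } }
  int max_chain = 1;
  for (size_t c = 0; c < chain_start.size(); ++c)
    max_chain = std::max(max_chain, chain_end[c] - chain_start[c]);
  std::vector<double> gtot_n(nn), idrv_n(nn);
  std::vector<double> td_a(max_chain), td_b(max_chain), td_c(max_chain),
                      td_d(max_chain);
  int th_pos = 0, ev_pos = 0;
  bool blown = false; double blow_v = 0; int blow_step = 0;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // (a) decay synaptic states
    for (int s = 0; s < ns; ++s) { sA[s] *= s_ra[s]; sB[s] *= s_rd[s]; }

    // (b) enqueue external events due around this step
    while (th_pos < th_t.size() && th_t[th_pos] < t + dt) {
      int u = th_unit[th_pos];
      int base = (int)(th_t[th_pos] / dt + 0.5);
      for (int k = th_ptr[u]; k < th_ptr[u + 1]; ++k) {
        int tgt = base + th_dstep[k];
        if (tgt <= step) tgt = step + 1;
        if (tgt < n_steps + ring_len)
          ring[tgt % ring_len].push_back(std::make_pair(th_slot[k], th_w[k]));
      }
      ++th_pos;
    }
    for (int p = 0; p < npo; ++p) {
      while (po_next[p] < t + dt) {
        int tgt = (int)(po_next[p] / dt + 0.5);
        if (tgt <= step) tgt = step + 1;
        ring[tgt % ring_len].push_back(std::make_pair(po_slot[p], po_w[p]));
        if (po_stream[p] == 1) par_t.push_back(po_next[p]);
        po_next[p] += -po_interval[p] * std::log(po_rng[p].unif());
      }
    }
    while (ev_pos < ev_t.size() && ev_t[ev_pos] < t + dt) {
      int tgt = (int)(ev_t[ev_pos] / dt + 0.5);
      if (tgt <= step) tgt = step + 1;
      ring[tgt % ring_len].push_back(std::make_pair(ev_slot[ev_pos], ev_w[ev_pos]));
      ++ev_pos;
    }

    // (c) deliver events scheduled for this step
    {
      std::vector<std::pair<int, double> > &q = ring[step % ring_len];
      for (size_t k = 0; k < q.size(); ++k) {
        sA[q[k].first] += q[k].second;
        sB[q[k].first] += q[k].second;
      }
      q.clear();
    }

    // (d) synaptic conductances per node
    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    std::fill(gesyn.begin(), gesyn.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      double g = s_nrm[s] * (sB[s] - sA[s]);
      if (g <= 0) continue;
      if (s_kind[s] == 1) { // NMDA magnesium block
        double v = V[s_node[s]];
        g /= (1.0 + 0.28 * mg * std::exp(-0.062 * v));
      }
      gsyn[s_node[s]] += g;
      gesyn[s_node[s]] += g * s_erev[s];
    }

    // theta-input synaptic current recording (before V update)
    if (rec_slots.size() > 0) {
      double ith = 0;
      for (int k = 0; k < rec_slots.size(); ++k) {
        int s = rec_slots[k];
        double g = s_nrm[s] * (sB[s] - sA[s]);
        if (s_kind[s] == 1)
          g /= (1.0 + 0.28 * mg * std::exp(-0.062 * V[s_node[s]]));
        ith += g * (V[s_node[s]] - s_erev[s]);
      }
      acc_th += ith / n_pc;
    }

    // (e) gating update (Rush-Larsen at old V) and membrane coefficients
    double svpc = 0, sitr = 0, svbc = 0;
    for (int i = 0; i < nn; ++i) {
      double v = V[i];
      if (kin[i] == 0) {
        double m3h = gm[i] * gm[i] * gm[i] * gh_[i];
        double n4 = gn[i] * gn[i]; n4 *= n4;
        double gNa = gna[i] * m3h, gK = gk[i] * n4, gH = gh[i] * gr[i];
        gtot_n[i] = gl[i] + gNa + gK + gH + gsyn[i];
        idrv_n[i] = gl[i] * el[i] + gNa * ena_pc + gK * ek_pc + gH * eh +
                    gesyn[i];
        double xi, rl;
        Tpm.at(v, xi, rl); gm[i] = xi + (gm[i] - xi) * rl;
        Tph.at(v, xi, rl); gh_[i] = xi + (gh_[i] - xi) * rl;
        Tpn.at(v, xi, rl); gn[i] = xi + (gn[i] - xi) * rl;
        Tpr.at(v, xi, rl); gr[i] = xi + (gr[i] - xi) * rl;
      } else {
        double xi, rl;
        Tbm.at(v, xi, rl);
        double m = xi;                     // instantaneous activation
        double m3h = m * m * m * gh_[i];
        double n4 = gn[i] * gn[i]; n4 *= n4;
        double gNa = gna[i] * m3h, gK = gk[i] * n4;
        gtot_n[i] = gl[i] + gNa + gK + gsyn[i];
        idrv_n[i] = gl[i] * el[i] + gNa * ena_bc + gK * ek_bc + gesyn[i];
        Tbh.at(v, xi, rl); gh_[i] = xi + (gh_[i] - xi) * rl;
        Tbn.at(v, xi, rl); gn[i] = xi + (gn[i] - xi) * rl;
      }
    }

    // Crank-Nicolson membrane update with implicit axial coupling: every
    // cell is a chain of consecutively numbered nodes, so the linear system
    // is tridiagonal and solved per cell with the Thomas algorithm.
    for (int c0 = 0; c0 < (int)chain_start.size(); ++c0) {
      int s0 = chain_start[c0], s1 = chain_end[c0];   // [s0, s1)
      int len = s1 - s0;
      for (int i = s0; i < s1; ++i) {
        double ga_lo = (i > s0) ? edge_g[i - 1] : 0.0;   // edge to i-1
        double ga_hi = (i + 1 < s1) ? edge_g[i] : 0.0;   // edge to i+1
        double Ga = ga_lo + ga_hi;
        double a = cm[i] / dt;
        td_b[i - s0] = a + 0.5 * (gtot_n[i] + Ga);
        td_a[i - s0] = -0.5 * ga_lo;
        td_c[i - s0] = -0.5 * ga_hi;
        double ax_old = ga_lo * ((i > s0) ? V[i - 1] : 0.0) +
                        ga_hi * ((i + 1 < s1) ? V[i + 1] : 0.0) - Ga * V[i];
        td_d[i - s0] = (a - 0.5 * gtot_n[i]) * V[i] + 0.5 * ax_old +
                       idrv_n[i];
      }
      // forward sweep
      for (int k = 1; k < len; ++k) {
        double m = td_a[k] / td_b[k - 1];
        td_b[k] -= m * td_c[k - 1];
        td_d[k] -= m * td_d[k - 1];
      }
      double vk = td_d[len - 1] / td_b[len - 1];
      V[s1 - 1] = vk;
      for (int k = len - 2; k >= 0; --k) {
        vk = (td_d[k] - td_c[k] * vk) / td_b[k];
        V[s0 + k] = vk;
      }
      for (int i = s0; i < s1; ++i) {
        if (V[i] > 80.0 || V[i] < -150.0 || V[i] != V[i]) {
          blown = true; blow_v = V[i]; blow_step = step;
        }
      }
    }
    if (blown) break;

    // (f) spike detection & network propagation
    for (int c = 0; c < n_cells; ++c) {
      double v = V[det_node[c]];
      if (vprev_det[c] < v_thresh && v >= v_thresh &&
          t - last_spike[c] > refr) {
        last_spike[c] = t;
        sp_cell.push_back(c + 1);
        sp_t.push_back(t);
        for (int k = syn_ptr[c]; k < syn_ptr[c + 1]; ++k) {
          int tgt = step + syn_dstep[k];
          if (tgt < n_steps + ring_len)
            ring[tgt % ring_len].push_back(std::make_pair(syn_slot[k], syn_w[k]));
        }
      }
      vprev_det[c] = v;
    }

    // (g) record (mean somatic V and transmembrane current over PCs)
    for (int k = 0; k < pcsoma.size(); ++k) {
      int i = pcsoma[k];
      svpc += V[i];
      double ax = 0;
      for (int e = aptr[i]; e < aptr[i + 1]; ++e)
        ax += ag[e] * (V[anbr[e]] - V[i]);
      sitr += ax;   // axial inflow = outward transmembrane current
    }
    if (n_bc_nodes > 0) {
      for (int i = 0; i < nn; ++i) if (kin[i] == 1) svbc += V[i];
    }
    double sitd = 0;
    for (int k = 0; k < pcdend.size(); ++k) {
      int i = pcdend[k];
      for (int e = aptr[i]; e < aptr[i + 1]; ++e)
        sitd += ag[e] * (V[anbr[e]] - V[i]);
    }
    acc_d += (pcdend.size() > 0 ? sitd / n_pc : 0.0);
    acc_v += svpc / pcsoma.size();
    acc_i += sitr / n_pc;
    acc_vb += (n_bc_nodes > 0 ? svbc / n_bc_nodes : 0.0);

    if ((step + 1) % rec_every == 0) {
      int r = (step + 1) / rec_every - 1;
      rec_vpc[r] = acc_v / rec_every;
      rec_itr[r] = acc_i / rec_every;
      rec_ith[r] = acc_th / rec_every;
      rec_vbc[r] = acc_vb / rec_every;
      rec_itd[r] = acc_d / rec_every;
      acc_v = acc_i = acc_th = acc_vb = acc_d = 0;
    }
  }

  if (blown) {
    stop("numerical instability: V = %f mV at t = %f ms", blow_v,
         blow_step * dt);
  }
  return List::create(
    _["spike_cell"] = wrap(sp_cell), _["spike_t"] = wrap(sp_t),
    _["v_pc"] = rec_vpc, _["i_transm"] = rec_itr,
    _["i_theta"] = rec_ith, _["v_bc"] = rec_vbc,
    _["i_dend"] = rec_itd, _["parallel_t"] = wrap(par_t));
}
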