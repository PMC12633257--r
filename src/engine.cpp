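// Fixed-step linearly-implicit compartmental integrator.
//
// Scheme per step (backward Euler in v, exact exponential update for gating
// and synaptic states evaluated at the previous voltage):
//   1. deliver queued synaptic events, advance background Poisson streams
//   2. decay dual-exponential synaptic states analytically
//   3. gate update x <- x_inf(v) + (x - x_inf(v)) * exp(-dt/tau(v))
//   4. assemble and solve the per-cell linear system in v (channels and
//      synapses implicit through their conductances, gap junctions explicit)
//   5. update intracellular Ca2+, detect spikes, queue outgoing events
//
// Units: mV, ms, nA, uS, nF, mM. Current convention: outward positive.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
#include <chrono>

using namespace Rcpp;

// ---- channel kinetics (kept in sync with R/mechanisms.R) -------------------

enum MechId { M_NATA = 0, M_NAP, M_KV31, M_KPST, M_KTST, M_IM, M_IH,
              M_CAHVA, M_CALVA, M_SK, M_KVDET, N_MECH };

static const int MECH_NGATES[N_MECH] = {2, 2, 1, 2, 2, 1, 1, 2, 2, 1, 1};
static const int MECH_POWERS[N_MECH][2] = {
  {3, 1}, {3, 1}, {1, 0}, {2, 1}, {4, 1}, {1, 0}, {1, 0},
  {2, 1}, {2, 1}, {1, 0}, {1, 0}};

static const double QT_HAY = 2.952882641412121; // 2.3^1.3, 34 C vs 21 C

static inline double ipow(double x, int p) {
  switch (p) {
  case 1: return x;
  case 2: return x * x;
  case 3: return x * x * x;
  case 4: { double x2 = x * x; return x2 * x2; }
  default: {
    double r = 1.0;
    for (int i = 0; i < p; ++i) r *= x;
    return r;
  }
  }
}

static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}
static inline double efun(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

// inf and tau for gate g of mechanism m at voltage v (Ca-independent gates).
static void gate_inf_tau(int m, int g, double v, double &inf, double &tau) {
  double a, b;
  switch (m) {
  case M_NATA:
    if (g == 0) {
      a = 0.182 * vtrap(v + 38.0, 6.0); b = 0.124 * vtrap(-(v + 38.0), 6.0);
      inf = a / (a + b); tau = 1.0 / (a + b) / QT_HAY;
    } else {
      a = 0.015 * vtrap(-(v + 66.0), 6.0); b = 0.015 * vtrap(v + 66.0, 6.0);
      inf = a / (a + b); tau = 1.0 / (a + b) / QT_HAY;
    }
    break;
  case M_NAP:
    if (g == 0) {
      inf = 1.0 / (1.0 + std::exp(-(v + 52.6) / 4.6));
      a = 0.182 * vtrap(v + 38.0, 6.0); b = 0.124 * vtrap(-(v + 38.0), 6.0);
      tau = 6.0 / (a + b) / QT_HAY;
    } else {
      inf = 1.0 / (1.0 + std::exp((v + 48.8) / 10.0));
      a = 2.88e-6 * vtrap(-(v + 17.0), 4.63);
      b = 6.94e-6 * vtrap(v + 64.4, 2.63);
      tau = 1.0 / (a + b) / QT_HAY;
    }
    break;
  case M_KV31:
    inf = 1.0 / (1.0 + std::exp(-(v - 18.7) / 9.7));
    tau = 4.0 / (1.0 + std::exp(-(v + 46.56) / 44.14));
    break;
  case M_KPST:
    if (g == 0) {
      inf = 1.0 / (1.0 + std::exp(-(v + 11.0) / 12.0));
      tau = (v < -50.0) ? (1.25 + 175.03 * std::exp(0.026 * v)) / QT_HAY
                        : (1.25 + 13.0 * std::exp(-0.026 * v)) / QT_HAY;
    } else {
      inf = 1.0 / (1.0 + std::exp((v + 64.0) / 11.0));
      tau = (360.0 + (1010.0 + 24.0 * (v + 65.0)) *
             std::exp(-std::pow((v + 85.0) / 48.0, 2))) / QT_HAY;
    }
    break;
  case M_KTST:
    if (g == 0) {
      inf = 1.0 / (1.0 + std::exp(-(v + 10.0) / 19.0));
      tau = (0.34 + 0.92 * std::exp(-std::pow((v + 81.0) / 59.0, 2))) / QT_HAY;
    } else {
      inf = 1.0 / (1.0 + std::exp((v + 76.0) / 10.0));
      tau = (8.0 + 49.0 * std::exp(-std::pow((v + 83.0) / 23.0, 2))) / QT_HAY;
    }
    break;
  case M_IM:
    a = 3.3e-3 * std::exp(0.1 * (v + 35.0));
    b = 3.3e-3 * std::exp(-0.1 * (v + 35.0));
    inf = a / (a + b); tau = 1.0 / (a + b) / QT_HAY;
    break;
  case M_IH:
    a = 6.43e-3 * efun(v + 154.9, 11.9);
    b = 1.93e-3 * std::exp(v / 33.1);
    inf = a / (a + b); tau = 1.0 / (a + b);
    break;
  case M_CAHVA:
    if (g == 0) {
      a = 0.055 * efun(-27.0 - v, 3.8);
      b = 0.94 * std::exp((-75.0 - v) / 17.0);
      inf = a / (a + b); tau = 1.0 / (a + b);
    } else {
      a = 4.57e-4 * std::exp((-13.0 - v) / 50.0);
      b = 6.5e-3 / (std::exp((-15.0 - v) / 28.0) + 1.0);
      inf = a / (a + b); tau = 1.0 / (a + b);
    }
    break;
  case M_CALVA:
    if (g == 0) {
      inf = 1.0 / (1.0 + std::exp(-(v + 40.0) / 6.0));
      tau = (5.0 + 20.0 / (1.0 + std::exp((v + 35.0) / 5.0))) / QT_HAY;
    } else {
      inf = 1.0 / (1.0 + std::exp((v + 90.0) / 6.4));
      tau = (20.0 + 50.0 / (1.0 + std::exp((v + 50.0) / 7.0))) / QT_HAY;
    }
    break;
  case M_SK: // handled separately (Ca-dependent); placeholder
    inf = 0.0; tau = 1.0;
    break;
  case M_KVDET:
    inf = 1.0 / (1.0 + std::exp(-(v + 30.0) / 10.0));
    tau = 2.0 + 16.0 * std::exp(-std::pow((v + 40.0) / 30.0, 2));
    break;
  default:
    stop("unknown mechanism id");
  }
}

static inline double sk_inf(double cai) {
  double c = cai > 1e-10 ? cai : 1e-10;
  return 1.0 / (1.0 + std::pow(0.00043 / c, 4.8));
}

static inline double ca_rev(double cai) {
  // 1000 * R * T / (2 F) * log(cao/cai) at 307.15 K, cao = 2 mM
  const double coef = 1000.0 * 8.31446 * 307.15 / (2.0 * 96485.0);
  double c = cai > 1e-10 ? cai : 1e-10;
  return coef * std::log(2.0 / c);
}

static inline double mg_block(double v, double mg) {
  return 1.0 / (1.0 + mg / 3.57 * std::exp(-0.062 * v));
}

// ---- lookup tables ---------------------------------------------------------

static const double TAB_VMIN = -120.0, TAB_VMAX = 60.0, TAB_DV = 0.05;
static const int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;

// ---- engine ----------------------------------------------------------------

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List net, List ctl) {
  // --- unpack network ---
  const int ncomp = as<int>(net["ncomp"]);
  NumericVector c_nF = net["c_nF"], gpas_uS = net["gpas_uS"],
    epas = net["epas"], area_um2 = net["area_um2"];
  IntegerVector parent = net["parent"];      // 0-based, -1 for root
  NumericVector gax_uS = net["gax_uS"];      // conductance to parent
  IntegerVector comp_cell = net["comp_cell"]; // 0-based cell id per comp

  IntegerVector chan_comp = net["chan_comp"], chan_mech = net["chan_mech"];
  NumericVector chan_gbar = net["chan_gbar_uS"], chan_erev = net["chan_erev"];
  IntegerVector chan_is_ca = net["chan_is_ca"];
  const int nchan = chan_comp.size();

  NumericVector ca_k = net["ca_k"], ca_tau = net["ca_tau"], ca_inf = net["ca_inf"];
  IntegerVector ca_on = net["ca_on"];

  IntegerVector slot_comp = net["slot_comp"];
  NumericVector slot_tr = net["slot_tau_r"], slot_td = net["slot_tau_d"],
    slot_e = net["slot_e"];
  IntegerVector slot_mg = net["slot_mg"];
  NumericVector slot_mgc = net["slot_mg_conc"];
  const int nslot = slot_comp.size();

  IntegerVector con_pre = net["con_pre_cell"], con_slot = net["con_slot"];
  NumericVector con_dw = net["con_dw"], con_delay = net["con_delay"];
  const int ncon = con_pre.size();

  IntegerVector bg_slot = net["bg_slot"];
  NumericVector bg_rate = net["bg_rate_hz"], bg_dw = net["bg_dw"];
  const int nbg = bg_slot.size();

  IntegerVector gap_a = net["gap_a"], gap_b = net["gap_b"];
  NumericVector gap_g = net["gap_g_uS"];
  const int ngap = gap_a.size();

  IntegerVector ic_comp = net["ic_comp"];
  NumericVector ic_amp = net["ic_amp_nA"], ic_start = net["ic_start"],
    ic_end = net["ic_end"];
  const int nic = ic_comp.size();

  IntegerVector vc_comp = net["vc_comp"];
  NumericVector vc_hold = net["vc_hold"], vc_step = net["vc_step"],
    vc_tstep = net["vc_tstep"];
  const int nvc = vc_comp.size();

  const int ncell = as<int>(net["ncell"]);
  IntegerVector cell_spike_comp = net["cell_spike_comp"];
  const double spike_thresh = as<double>(net["spike_threshold"]);
  const double spike_refrac = as<double>(net["spike_refractory"]);
  IntegerVector cell_lif = net["cell_lif"];
  NumericVector lif_vth = net["lif_vth"], lif_vreset = net["lif_vreset"],
    lif_tref = net["lif_tref"];

  // --- unpack control ---
  const double dt = as<double>(ctl["dt"]);
  const double tstop = as<double>(ctl["tstop"]);
  const double v_init = as<double>(ctl["v_init"]);
  const uint64_t seed = (uint64_t)as<double>(ctl["seed"]);
  IntegerVector rec_comps = ctl["record_comps"];
  const double rec_dt = as<double>(ctl["rec_dt"]);
  const int states_comp = as<int>(ctl["record_states_comp"]); // -1 = off
  const bool use_tables = as<bool>(ctl["use_tables"]);

  const int nstep = (int)std::lround(tstop / dt);
  const int rec_every = rec_dt > 0 ? std::max(1, (int)std::lround(rec_dt / dt)) : 0;

  // --- per-cell compartment lists ---

  // --- per-cell outgoing connections ---
  std::vector<std::vector<int>> cell_out(ncell);
  for (int i = 0; i < ncon; ++i) cell_out[con_pre[i]].push_back(i);

  // --- gating tables (interleaved inf/fac, contiguous for cache locality) ---
  std::vector<double> tabs;
  if (use_tables) {
    tabs.assign((size_t)N_MECH * 2 * TAB_N * 2, 0.0);
    for (int m = 0; m < N_MECH; ++m) {
      if (m == M_SK) continue;
      for (int g = 0; g < MECH_NGATES[m]; ++g) {
        double *row = &tabs[((size_t)(m * 2 + g) * TAB_N) * 2];
        for (int k = 0; k < TAB_N; ++k) {
          double v = TAB_VMIN + k * TAB_DV, inf, tau;
          gate_inf_tau(m, g, v, inf, tau);
          row[2 * k] = inf;
          row[2 * k + 1] = std::exp(-dt / tau);
        }
      }
    }
  }

  // --- state ---
  std::vector<double> v(ncomp, v_init), v_old(ncomp);
  std::vector<double> cai(ncomp);
  for (int i = 0; i < ncomp; ++i) cai[i] = ca_inf[i];
  std::vector<double> gate(2 * nchan, 0.0);
  for (int ic = 0; ic < nchan; ++ic) {
    int m = chan_mech[ic];
    for (int g = 0; g < MECH_NGATES[m]; ++g) {
      double inf, tau;
      if (m == M_SK) { inf = sk_inf(cai[chan_comp[ic]]); tau = 1.0; }
      else gate_inf_tau(m, g, v_init, inf, tau);
      gate[2 * ic + g] = inf;
    }
  }
  std::vector<double> synA(nslot, 0.0), synB(nslot, 0.0);
  std::vector<double> syn_fr(nslot), syn_fd(nslot);
  for (int s = 0; s < nslot; ++s) {
    syn_fr[s] = std::exp(-dt / slot_tr[s]);
    syn_fd[s] = std::exp(-dt / slot_td[s]);
  }
  const double sk_fac = std::exp(-dt / 1.0);
  std::vector<double> ca_fac(ncomp);
  for (int i = 0; i < ncomp; ++i) ca_fac[i] = std::exp(-dt / ca_tau[i]);

  // event ring buffer
  double max_delay = 0.0;
  for (int i = 0; i < ncon; ++i) max_delay = std::max(max_delay, con_delay[i]);
  const int ring_len = (int)std::lround(max_delay / dt) + 2;
  std::vector<std::vector<std::pair<int,double>>> ring(ring_len);

  // background streams
  std::mt19937_64 rng(seed ^ 0x9e3779b97f4a7c15ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> bg_next(nbg);
  for (int i = 0; i < nbg; ++i) {
    if (bg_rate[i] > 0) {
      double u = unif(rng);
      bg_next[i] = -std::log(1.0 - u) * 1000.0 / bg_rate[i];
    } else bg_next[i] = 2.0 * tstop + 1.0;
  }

  // spike bookkeeping
  std::vector<double> last_spike(ncell, -1e9);
  std::vector<double> lif_until(ncell, -1e9);
  std::vector<int> spk_cell; std::vector<double> spk_t;

  // clamp map
  std::vector<int> vc_of(ncomp, -1);
  for (int i = 0; i < nvc; ++i) vc_of[vc_comp[i]] = i;

  // recording buffers
  const int nrec = rec_comps.size();
  int nrec_t = rec_every > 0 ? nstep / rec_every + 1 : 0;
  NumericMatrix rec_v(nrec > 0 ? nrec_t : 0, nrec);
  NumericVector rec_t(nrec > 0 ? nrec_t : 0);
  // state recording: gates of all channels on states_comp + cai + chan current
  std::vector<int> st_chans;
  int st_ngates = 0;
  if (states_comp >= 0) {
    for (int ic = 0; ic < nchan; ++ic)
      if (chan_comp[ic] == states_comp) st_chans.push_back(ic);
    for (size_t j = 0; j < st_chans.size(); ++j)
      st_ngates += MECH_NGATES[chan_mech[st_chans[j]]];
  }
  NumericMatrix rec_states(states_comp >= 0 ? nrec_t : 0,
                           states_comp >= 0 ? st_ngates + 2 : 0);

  // per-comp accumulators
  std::vector<double> Gsum(ncomp), GEsum(ncomp), Gca(ncomp), GcaE(ncomp),
    Iext(ncomp);

  // per-cell dense solver workspace
  const double NOCLAMP = -1e30;
  bool any_lif = false;
  for (int c = 0; c < ncell; ++c) if (cell_lif[c]) any_lif = true;
  const bool any_clamp = (nvc > 0) || any_lif;
  std::vector<double> dvec(ncomp), evec(ncomp), bb(ncomp), clampv(ncomp);
  std::vector<int> tab_k0(ncomp);
  std::vector<double> tab_w(ncomp);
  std::vector<double> cdt(ncomp);
  for (int i = 0; i < ncomp; ++i) cdt[i] = c_nF[i] / dt;
  // per-compartment Ca-derived quantities, refreshed when cai changes
  std::vector<double> eca_c(ncomp), skinf_c(ncomp);
  for (int i = 0; i < ncomp; ++i) {
    eca_c[i] = ca_rev(cai[i]);
    skinf_c[i] = sk_inf(cai[i]);
  }

  double prof[8] = {0,0,0,0,0,0,0,0};
  bool do_prof = ctl.containsElementNamed("profile") && as<bool>(ctl["profile"]);
  auto tick = [&](int which, auto &t0) {
    if (do_prof) {
      auto t1 = std::chrono::steady_clock::now();
      prof[which] += std::chrono::duration<double>(t1 - t0).count();
      t0 = t1;
    }
  };
  int rec_row = 0;
  auto record_row = [&](double tnow) {
    if (nrec > 0 && rec_row < nrec_t) {
      rec_t[rec_row] = tnow;
      for (int j = 0; j < nrec; ++j) rec_v(rec_row, j) = v[rec_comps[j]];
    }
    if (states_comp >= 0 && rec_row < nrec_t) {
      int col = 0;
      double itot = 0.0;
      for (size_t j = 0; j < st_chans.size(); ++j) {
        int ic = st_chans[j], m = chan_mech[ic];
        double open = 1.0;
        for (int g = 0; g < MECH_NGATES[m]; ++g) {
          rec_states(rec_row, col++) = gate[2 * ic + g];
          open *= ipow(gate[2 * ic + g], MECH_POWERS[m][g]);
        }
        double e = chan_is_ca[ic] ? ca_rev(cai[states_comp]) : chan_erev[ic];
        itot += chan_gbar[ic] * open * (v[states_comp] - e);
      }
      rec_states(rec_row, col++) = cai[states_comp];
      rec_states(rec_row, col) = itot; // nA, channels only
    }
    ++rec_row;
  };
  if (rec_every > 0) record_row(0.0);

  // ---- main loop ----
  for (int k = 0; k < nstep; ++k) {
    auto tp = std::chrono::steady_clock::now();
    double t = k * dt, tnext = (k + 1) * dt;
    for (int i = 0; i < ncomp; ++i) v_old[i] = v[i];

    // deliver queued events
    int bucket = k % ring_len;
    for (size_t j = 0; j < ring[bucket].size(); ++j) {
      int s = ring[bucket][j].first;
      double dw = ring[bucket][j].second;
      synA[s] += dw; synB[s] += dw;
    }
    ring[bucket].clear();

    // background events
    for (int i = 0; i < nbg; ++i) {
      while (bg_next[i] < tnext) {
        synA[bg_slot[i]] += bg_dw[i];
        synB[bg_slot[i]] += bg_dw[i];
        double u = unif(rng);
        bg_next[i] += -std::log(1.0 - u) * 1000.0 / bg_rate[i];
      }
    }

    tick(0, tp);

    tick(1, tp);
    // gating update + conductance accumulation
    for (int i = 0; i < ncomp; ++i) {
      Gsum[i] = 0.0; GEsum[i] = 0.0; Gca[i] = 0.0; GcaE[i] = 0.0; Iext[i] = 0.0;
    }
    if (use_tables) {
      for (int i = 0; i < ncomp; ++i) {
        double vv = v_old[i];
        double vc = vv < TAB_VMIN ? TAB_VMIN : (vv > TAB_VMAX ? TAB_VMAX : vv);
        double x = (vc - TAB_VMIN) / TAB_DV;
        int k0 = (int)x; if (k0 >= TAB_N - 1) k0 = TAB_N - 2;
        tab_k0[i] = k0; tab_w[i] = x - k0;
      }
    }
    for (int ic = 0; ic < nchan; ++ic) {
      int cp = chan_comp[ic], m = chan_mech[ic];
      double vv = v_old[cp];
      double open = 1.0;
      if (m == M_SK) {
        double inf = skinf_c[cp];
        gate[2 * ic] = inf + (gate[2 * ic] - inf) * sk_fac;
        open = gate[2 * ic];
      } else if (use_tables) {
        int k0 = tab_k0[cp];
        double w = tab_w[cp];
        for (int g = 0; g < MECH_NGATES[m]; ++g) {
          const double *row = &tabs[((size_t)(m * 2 + g) * TAB_N + k0) * 2];
          double inf = row[0] + w * (row[2] - row[0]);
          double fac = row[1] + w * (row[3] - row[1]);
          double &x0 = gate[2 * ic + g];
          x0 = inf + (x0 - inf) * fac;
          open *= ipow(x0, MECH_POWERS[m][g]);
        }
      } else {
        for (int g = 0; g < MECH_NGATES[m]; ++g) {
          double inf, tau;
          gate_inf_tau(m, g, vv, inf, tau);
          double &x0 = gate[2 * ic + g];
          x0 = inf + (x0 - inf) * std::exp(-dt / tau);
          open *= ipow(x0, MECH_POWERS[m][g]);
        }
      }
      double gg = chan_gbar[ic] * open;
      if (chan_is_ca[ic]) {
        double e = eca_c[cp];
        Gca[cp] += gg; GcaE[cp] += gg * e;
        Gsum[cp] += gg; GEsum[cp] += gg * e;
      } else {
        Gsum[cp] += gg; GEsum[cp] += gg * chan_erev[ic];
      }
    }

    tick(2, tp);
    // synaptic states: decay (flushing tiny values to zero as a denormal
    // guard) and conductance accumulation in one pass
    for (int s = 0; s < nslot; ++s) {
      double a = synA[s] * syn_fr[s], b = synB[s] * syn_fd[s];
      if (b < 1e-12) { a = 0.0; b = 0.0; }
      synA[s] = a; synB[s] = b;
      double gg = b - a;
      if (gg <= 0.0) continue;
      int cp = slot_comp[s];
      if (slot_mg[s]) gg *= mg_block(v_old[cp], slot_mgc[s]);
      Gsum[cp] += gg; GEsum[cp] += gg * slot_e[s];
    }

    tick(3, tp);
    // injected currents
    for (int i = 0; i < nic; ++i)
      if (t >= ic_start[i] && t < ic_end[i]) Iext[ic_comp[i]] += ic_amp[i];

    // gap junctions (explicit)
    for (int i = 0; i < ngap; ++i) {
      double ig = gap_g[i] * (v_old[gap_b[i]] - v_old[gap_a[i]]);
      Iext[gap_a[i]] += ig;
      Iext[gap_b[i]] -= ig;
    }

    tick(4, tp);
    // implicit solve: Hines-style tree elimination, O(ncomp) total.
    // Compartments are ordered parents-before-children within each cell, so
    // a single global backward/forward sweep solves every cell's system.
    // Clamped compartments (voltage clamp, LIF refractory hold) have their
    // row replaced by v = level and their axial couplings moved to the RHS.
    if (any_clamp) {
      for (int i = 0; i < ncomp; ++i) clampv[i] = NOCLAMP;
      for (int q = 0; q < nvc; ++q)
        clampv[vc_comp[q]] = (t >= vc_tstep[q]) ? vc_step[q] : vc_hold[q];
      for (int c = 0; c < ncell; ++c)
        if (cell_lif[c] && t < lif_until[c])
          clampv[cell_spike_comp[c]] = lif_vreset[c];
    }
    for (int i = 0; i < ncomp; ++i) {
      if (any_clamp && clampv[i] != NOCLAMP) {
        dvec[i] = 1.0; evec[i] = 0.0; bb[i] = clampv[i];
        continue;
      }
      dvec[i] = cdt[i] + gpas_uS[i] + Gsum[i];
      bb[i] = cdt[i] * v_old[i] + gpas_uS[i] * epas[i] +
        GEsum[i] + Iext[i];
      evec[i] = 0.0;
    }
    // axial couplings
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      double g = gax_uS[i];
      bool ci = any_clamp && clampv[i] != NOCLAMP,
        cp = any_clamp && clampv[p] != NOCLAMP;
      if (ci && cp) continue;
      if (ci) { // child clamped: parent sees a known boundary voltage
        dvec[p] += g; bb[p] += g * clampv[i];
      } else if (cp) { // parent clamped
        dvec[i] += g; bb[i] += g * clampv[p];
      } else {
        dvec[i] += g; dvec[p] += g; evec[i] = -g;
      }
    }
    // backward sweep (children into parents)
    for (int i = ncomp - 1; i >= 0; --i) {
      int p = parent[i];
      if (p < 0 || evec[i] == 0.0) continue;
      double f = evec[i] / dvec[i];
      dvec[p] -= f * evec[i];
      bb[p] -= f * bb[i];
    }
    // forward sweep (with divergence guard)
    bool diverged = false;
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      double vi = (p < 0 || evec[i] == 0.0) ? bb[i] / dvec[i]
        : (bb[i] - evec[i] * v[p]) / dvec[i];
      v[i] = vi;
      diverged |= !(vi > -200.0 && vi < 200.0);
    }
    if (diverged) {
      for (int i = 0; i < ncomp; ++i)
        if (!(v[i] > -200.0 && v[i] < 200.0))
          stop("integration-failure: |v| > 200 mV at compartment %d (cell %d) "
               "t = %.3f ms", i + 1, comp_cell[i] + 1, tnext);
    }

    tick(5, tp);
    // calcium update (using new v)
    for (int i = 0; i < ncomp; ++i) {
      if (!ca_on[i]) continue;
      double ica = Gca[i] * v[i] - GcaE[i]; // nA, outward positive (inward < 0)
      double a = -ca_k[i] * ica + ca_inf[i] / ca_tau[i];
      double tauc = ca_tau[i];
      cai[i] = a * tauc + (cai[i] - a * tauc) * ca_fac[i];
      if (cai[i] < 1e-10) cai[i] = 1e-10;
      eca_c[i] = ca_rev(cai[i]);
      skinf_c[i] = sk_inf(cai[i]);
    }

    tick(6, tp);
    // spikes
    for (int c = 0; c < ncell; ++c) {
      int sc = cell_spike_comp[c];
      if (sc < 0) continue;
      bool fired = false;
      if (cell_lif[c]) {
        if (tnext >= lif_until[c] && v[sc] >= lif_vth[c]) {
          fired = true;
          v[sc] = lif_vreset[c];
          lif_until[c] = tnext + lif_tref[c];
        }
      } else {
        if (v[sc] >= spike_thresh && v_old[sc] < spike_thresh &&
            tnext - last_spike[c] > spike_refrac)
          fired = true;
      }
      if (fired) {
        last_spike[c] = tnext;
        spk_cell.push_back(c + 1); // 1-based for R
        spk_t.push_back(tnext);
        for (size_t j = 0; j < cell_out[c].size(); ++j) {
          int e = cell_out[c][j];
          int dsteps = (int)std::lround(con_delay[e] / dt);
          if (dsteps < 1) dsteps = 1;
          ring[(k + dsteps) % ring_len].push_back(
            std::make_pair((int)con_slot[e], con_dw[e]));
        }
      }
    }

    if (rec_every > 0 && ((k + 1) % rec_every == 0)) record_row(tnext);
  }

  if (do_prof) {
    Rprintf("events/bg %.2f gating %.2f syn %.2f ext %.2f solve %.2f ca %.2f spk/rec %.2f\n",
            prof[0], prof[1], prof[2], prof[3], prof[4], prof[5], prof[6]);
  }
  List out = List::create(
    _["spike_cell"] = wrap(spk_cell),
    _["spike_time"] = wrap(spk_t),
    _["times"] = rec_t,
    _["v"] = rec_v);
  if (states_comp >= 0) out["states"] = rec_states;
  return out;
}
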