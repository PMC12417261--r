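// Time-driven simulation core: conductance-based LIF neurons with AMPA,
// GABA and NMDA receptor currents on a fixed dt grid, embedded RKF45 with
// adaptive substeps inside each grid interval, spike checks at grid points
// only, and per-connection delays handled by ring buffers.
//
// NMDA backends:
//   0 "approximate": one aggregated S_NMDA per neuron; each excitatory
//     source carries a local gating value updated by the jump map
//     dS = k0 + k1*S at its own spikes, and the weighted jump is delivered.
//   1 "exact shared": one (S, x) pair per excitatory source neuron
//     (valid for block-weighted all-to-all connectivity with one delay per
//     source); targets read weighted population sums.
//   2 "exact per-synapse": one (S, x) pair per excitatory edge; targets sum
//     their own incoming units. Same integration routine as backend 1, so
//     the two agree up to summation order.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---- Fehlberg 4(5) tableau -------------------------------------------------
static const double FC2 = 1.0 / 4, FC3 = 3.0 / 8, FC4 = 12.0 / 13,
                    FC5 = 1.0, FC6 = 1.0 / 2;
static const double NODES[6] = {0.0, FC2, FC3, FC4, FC5, FC6};
static const double A21 = 1.0 / 4;
static const double A31 = 3.0 / 32, A32 = 9.0 / 32;
static const double A41 = 1932.0 / 2197, A42 = -7200.0 / 2197,
                    A43 = 7296.0 / 2197;
static const double A51 = 439.0 / 216, A52 = -8.0, A53 = 3680.0 / 513,
                    A54 = -845.0 / 4104;
static const double A61 = -8.0 / 27, A62 = 2.0, A63 = -3544.0 / 2565,
                    A64 = 1859.0 / 4104, A65 = -11.0 / 40;
static const double B51 = 16.0 / 135, B53 = 6656.0 / 12825,
                    B54 = 28561.0 / 56430, B55 = -9.0 / 50, B56 = 2.0 / 55;
// 5th-minus-4th order error weights
static const double E1 = 16.0 / 135 - 25.0 / 216,
                    E3 = 6656.0 / 12825 - 1408.0 / 2565,
                    E4 = 28561.0 / 56430 - 2197.0 / 4104,
                    E5 = -9.0 / 50 + 1.0 / 5, E6 = 2.0 / 55;

// Adaptive RKF45 for a scalar ODE over one grid interval [0, dt]. hprop is
// the persisted step-size proposal (never above dt); substeps never leave
// the interval. Advances with the 5th-order solution.
template <class F>
static double rkf45_interval(double y, double dt, double &hprop, double atol,
                             double rtol, F f) {
  double s = 0.0;
  int guard = 0;
  while (s < dt * (1.0 - 1e-12)) {
    if (++guard > 100000)
      stop("RKF45 failed to reach tolerance within the substep budget");
    double h = hprop < dt - s ? hprop : dt - s;
    bool truncated = h < hprop;
    double k1 = f(s, y);
    double k2 = f(s + FC2 * h, y + h * A21 * k1);
    double k3 = f(s + FC3 * h, y + h * (A31 * k1 + A32 * k2));
    double k4 = f(s + FC4 * h, y + h * (A41 * k1 + A42 * k2 + A43 * k3));
    double k5 =
        f(s + FC5 * h, y + h * (A51 * k1 + A52 * k2 + A53 * k3 + A54 * k4));
    double k6 = f(s + FC6 * h, y + h * (A61 * k1 + A62 * k2 + A63 * k3 +
                                        A64 * k4 + A65 * k5));
    double y5 =
        y + h * (B51 * k1 + B53 * k3 + B54 * k4 + B55 * k5 + B56 * k6);
    double err =
        std::fabs(h * (E1 * k1 + E3 * k3 + E4 * k4 + E5 * k5 + E6 * k6));
    double tol = atol + rtol * std::fabs(y);
    bool accept = err <= tol;
    if (accept) {
      s += h;
      y = y5;
    }
    double fac = err > 0.0 ? 0.9 * std::pow(tol / err, 0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    double hnew = h * fac;
    // keep the larger proposal when an accepted step was only truncated to
    // fit the interval end
    if (!(truncated && accept && hnew < hprop)) hprop = hnew;
    if (hprop > dt) hprop = dt;
    if (hprop < 1e-8) hprop = 1e-8;
  }
  return y;
}

// ---- per-population parameter block ---------------------------------------
struct PopPar {
  double Cm, gL, EL, Vthr, Vreset, gA, gAe, gG, gN, VE, VI, Mg, tauA, tauG,
      tauD, alpha, tauR;
  int ref_steps;
  double k0, k1;               // jump-map constants
  double decA, decG, decN, decR;  // exp(-dt/tau)
  double facA[6], facG[6], facN[6], facR[6];  // node decay factors for h = dt
};

static PopPar make_pop_par(const double *p, double dt) {
  PopPar P;
  P.Cm = p[0]; P.gL = p[1]; P.EL = p[2]; P.Vthr = p[3]; P.Vreset = p[4];
  double tref = p[5];
  P.gA = p[6]; P.gAe = p[7]; P.gG = p[8]; P.gN = p[9];
  P.VE = p[10]; P.VI = p[11]; P.Mg = p[12];
  P.tauA = p[13]; P.tauG = p[14];
  P.alpha = p[15]; P.tauR = p[16]; P.tauD = p[17];
  P.ref_steps = (int)std::ceil(tref / dt - 1e-9);
  double a_tr = P.alpha * P.tauR;
  double sh = 1.0 - P.tauR / P.tauD;
  P.k0 = a_tr > 0.0
             ? std::pow(a_tr, P.tauR / P.tauD) *
                   R::pgamma(a_tr, sh, 1.0, 1, 0) * R::gammafn(sh)
             : 0.0;
  P.k1 = std::exp(-a_tr) - 1.0;
  P.decA = std::exp(-dt / P.tauA);
  P.decG = std::exp(-dt / P.tauG);
  P.decN = std::exp(-dt / P.tauD);
  P.decR = std::exp(-dt / P.tauR);
  for (int i = 0; i < 6; ++i) {
    P.facA[i] = std::exp(-NODES[i] * dt / P.tauA);
    P.facG[i] = std::exp(-NODES[i] * dt / P.tauG);
    P.facN[i] = std::exp(-NODES[i] * dt / P.tauD);
    P.facR[i] = std::exp(-NODES[i] * dt / P.tauR);
  }
  return P;
}

// exp(-0.062 V) on a fine grid: the magnesium-block factor is evaluated in
// every RHS call, and a linearly interpolated table at 0.01 mV spacing
// (relative error ~5e-8, far below the integrator tolerance) avoids a libm
// exp in the hot loop. Out-of-range V falls back to exp().
static const double MGV_LO = -200.0, MGV_HI = 100.0, MGV_STEP = 0.01;
static const int MGV_N = (int)((MGV_HI - MGV_LO) / MGV_STEP) + 2;
static std::vector<double> mg_exp_tab;
static void mg_tab_init() {
  if (!mg_exp_tab.empty()) return;
  mg_exp_tab.resize(MGV_N);
  for (int i = 0; i < MGV_N; ++i)
    mg_exp_tab[i] = std::exp(-0.062 * (MGV_LO + i * MGV_STEP));
}
static inline double mg_exp(double V) {
  if (V <= MGV_LO || V >= MGV_HI) return std::exp(-0.062 * V);
  double u = (V - MGV_LO) / MGV_STEP;
  int i = (int)u;
  double f = u - i;
  return mg_exp_tab[i] + f * (mg_exp_tab[i + 1] - mg_exp_tab[i]);
}

static inline double v_rhs(const PopPar &P, double V, double SA, double SAe,
                           double SG, double SN, double Iconst) {
  double mg = 1.0 / (1.0 + P.Mg * mg_exp(V) / 3.57);
  double I = P.gA * (V - P.VE) * SA + P.gAe * (V - P.VE) * SAe +
             P.gG * (V - P.VI) * SG + P.gN * (V - P.VE) * mg * SN + Iconst;
  return (-(P.gL * (V - P.EL)) - I) / P.Cm;
}

// Advance V over one grid interval. Gating enters the RHS in closed form:
// exponential decay from the interval-start values; the NMDA drive is
// either SNeff*e^{-s/tauD} + SNoff (approximate backend, SNoff = clamp
// drive * tauD) or linearly interpolated nm0 + nmslope*s (exact backends).
// A single full-interval step with precomputed node factors is tried first;
// on rejection (or a persisted substep below dt) control falls back to the
// generic adaptive routine.
static double lif_advance(const PopPar &P, double V, double dt, double &hprop,
                          double atol, double rtol, double SA, double SAe,
                          double SG, bool approx_nmda, double SNeff,
                          double SNoff, double nm0, double nmslope,
                          double Iconst) {
  auto f_generic = [&](double s, double y) {
    double fA = std::exp(-s / P.tauA);
    double sg = SG * std::exp(-s / P.tauG);
    double sn = approx_nmda ? SNeff * std::exp(-s / P.tauD) + SNoff
                            : nm0 + nmslope * s;
    return v_rhs(P, y, SA * fA, SAe * fA, sg, sn, Iconst);
  };
  if (hprop >= dt * (1.0 - 1e-12)) {
    auto feval = [&](int i, double yv) {
      double fA = P.facA[i];
      double sg = SG * P.facG[i];
      double sn = approx_nmda ? SNeff * P.facN[i] + SNoff
                              : nm0 + nmslope * NODES[i] * dt;
      return v_rhs(P, yv, SA * fA, SAe * fA, sg, sn, Iconst);
    };
    double k1 = feval(0, V);
    double k2 = feval(1, V + dt * A21 * k1);
    double k3 = feval(2, V + dt * (A31 * k1 + A32 * k2));
    double k4 = feval(3, V + dt * (A41 * k1 + A42 * k2 + A43 * k3));
    double k5 =
        feval(4, V + dt * (A51 * k1 + A52 * k2 + A53 * k3 + A54 * k4));
    double k6 = feval(5, V + dt * (A61 * k1 + A62 * k2 + A63 * k3 +
                                   A64 * k4 + A65 * k5));
    double y5 =
        V + dt * (B51 * k1 + B53 * k3 + B54 * k4 + B55 * k5 + B56 * k6);
    double err =
        std::fabs(dt * (E1 * k1 + E3 * k3 + E4 * k4 + E5 * k5 + E6 * k6));
    double tol = atol + rtol * std::fabs(V);
    if (err <= tol) {
      hprop = dt;
      return y5;
    }
    double fac = 0.9 * std::pow(tol / err, 0.2);
    if (fac < 0.2) fac = 0.2;
    hprop = dt * fac;
  }
  return rkf45_interval(V, dt, hprop, atol, rtol, f_generic);
}

// Advance one exact-model gating variable S over a grid interval; the rise
// variable has the closed form x0*exp(-s/tauR) and is substituted directly.
static double exact_unit_advance(const PopPar &P, double S, double x0,
                                 double dt, double atol, double rtol) {
  auto f_generic = [&](double s, double y) {
    return -y / P.tauD +
           P.alpha * x0 * std::exp(-s / P.tauR) * (1.0 - y);
  };
  auto feval = [&](int i, double yv) {
    return -yv / P.tauD + P.alpha * x0 * P.facR[i] * (1.0 - yv);
  };
  double k1 = feval(0, S);
  double k2 = feval(1, S + dt * A21 * k1);
  double k3 = feval(2, S + dt * (A31 * k1 + A32 * k2));
  double k4 = feval(3, S + dt * (A41 * k1 + A42 * k2 + A43 * k3));
  double k5 = feval(4, S + dt * (A51 * k1 + A52 * k2 + A53 * k3 + A54 * k4));
  double k6 = feval(5, S + dt * (A61 * k1 + A62 * k2 + A63 * k3 + A64 * k4 +
                                 A65 * k5));
  double y5 = S + dt * (B51 * k1 + B53 * k3 + B54 * k4 + B55 * k5 + B56 * k6);
  double err =
      std::fabs(dt * (E1 * k1 + E3 * k3 + E4 * k4 + E5 * k5 + E6 * k6));
  double tol = atol + rtol * std::fabs(S);
  if (err <= tol) return y5;
  double h = dt * 0.9 * std::pow(tol / err, 0.2);
  if (h < 1e-8) h = 1e-8;
  return rkf45_interval(S, dt, h, atol, rtol, f_generic);
}

static inline double mg_factor(double V, double Mg) {
  return 1.0 / (1.0 + Mg * std::exp(-0.062 * V) / 3.57);
}

// ---- single postsynaptic neuron driven by given spike trains ---------------
// src_bins: per source, 0-based grid-bin indices of spike arrivals (NMDA
// drive with weight w). Used by the error-characterization experiment and
// the single-neuron integrator.
// [[Rcpp::export]]
List cpp_single_neuron(List src_bins, double w, NumericVector par, double dt,
                       int n_steps, bool exact, double I_const, double V0,
                       double atol, double rtol) {
  mg_tab_init();
  PopPar P = make_pop_par(REAL(par), dt);
  int n_src = src_bins.size();

  // flatten arrivals sorted by (bin, source)
  std::vector<int> ev_bin, ev_src;
  for (int j = 0; j < n_src; ++j) {
    IntegerVector b = src_bins[j];
    for (int q = 0; q < b.size(); ++q) {
      if (b[q] < 0 || b[q] >= n_steps)
        stop("spike bin outside the simulation window");
      ev_bin.push_back(b[q]);
      ev_src.push_back(j);
    }
  }
  std::vector<size_t> ord(ev_bin.size());
  for (size_t q = 0; q < ord.size(); ++q) ord[q] = q;
  std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return ev_bin[a] < ev_bin[b];
  });

  std::vector<double> Su(exact ? n_src : 0, 0.0), xu(exact ? n_src : 0, 0.0);
  std::vector<double> S_loc(exact ? 0 : n_src, 0.0);
  std::vector<int> loc_last(exact ? 0 : n_src, 0);

  double V = V0, SN = 0.0, hprop = dt / 10.0;
  long long refr_until = 0;
  NumericVector Vtr(n_steps), SNtr(n_steps), Inm(n_steps), tgrid(n_steps);
  std::vector<double> spk;
  size_t ptr = 0;

  for (int k = 0; k < n_steps; ++k) {
    // deliver arrivals at the interval boundary
    while (ptr < ord.size() && ev_bin[ord[ptr]] == k) {
      int j = ev_src[ord[ptr]];
      if (exact) {
        xu[j] += 1.0;
      } else {
        S_loc[j] *= std::pow(P.decN, (double)(k - loc_last[j]));
        loc_last[j] = k;
        double dS = P.k0 + P.k1 * S_loc[j];
        S_loc[j] += dS;
        SN += w * dS;
      }
      ++ptr;
    }
    double nm0 = 0.0, nm1 = 0.0;
    if (exact) {
      for (int j = 0; j < n_src; ++j) nm0 += Su[j];
      for (int j = 0; j < n_src; ++j) {
        if (Su[j] > 1e-14 || xu[j] > 1e-14) {
          Su[j] = exact_unit_advance(P, Su[j], xu[j], dt, atol, rtol);
          xu[j] *= P.decR;
        }
      }
      for (int j = 0; j < n_src; ++j) nm1 += Su[j];
      nm0 *= w;
      nm1 *= w;
    }
    if (k >= refr_until) {
      if (exact)
        V = lif_advance(P, V, dt, hprop, atol, rtol, 0.0, 0.0, 0.0, false,
                        0.0, 0.0, nm0, (nm1 - nm0) / dt, I_const);
      else
        V = lif_advance(P, V, dt, hprop, atol, rtol, 0.0, 0.0, 0.0, true, SN,
                        0.0, 0.0, 0.0, I_const);
    } else {
      V = P.Vreset;
    }
    if (!exact) SN *= P.decN;
    double sn_now = exact ? nm1 : SN;
    if (k >= refr_until && V >= P.Vthr) {
      spk.push_back((k + 1) * dt);
      V = P.Vreset;
      refr_until = (long long)k + 1 + P.ref_steps;
    }
    tgrid[k] = (k + 1) * dt;
    Vtr[k] = V;
    SNtr[k] = sn_now;
    Inm[k] = P.gN * (V - P.VE) * mg_factor(V, P.Mg) * sn_now;
  }
  return List::create(_["time"] = tgrid, _["V"] = Vtr, _["S_NMDA"] = SNtr,
                      _["I_NMDA"] = Inm, _["spikes"] = wrap(spk));
}

// ---- full network simulator ------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_network(IntegerVector pop_of, NumericMatrix pop_par,
                          LogicalVector exc_pop, IntegerVector src_ptr,
                          IntegerVector adj_tgt, NumericVector adj_w,
                          IntegerVector adj_delay, double dt, int n_steps,
                          int backend, NumericVector p_ext,
                          NumericMatrix stim_p, NumericMatrix Wnmda,
                          NumericVector clamp_drive, int clamp_end_step,
                          LogicalVector clamp_pop, int rec_every,
                          IntegerVector rec_neurons, double atol,
                          double rtol) {
  mg_tab_init();
  const int n = pop_of.size();
  const int n_pops = pop_par.nrow();
  std::vector<PopPar> PP(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    std::vector<double> row(pop_par.ncol());
    for (int c = 0; c < pop_par.ncol(); ++c) row[c] = pop_par(p, c);
    PP[p] = make_pop_par(row.data(), dt);
  }
  const bool has_stim = stim_p.nrow() > 0;
  const bool has_clamp = clamp_drive.size() == n && clamp_end_step > 0;

  int max_delay = 1;
  for (int e = 0; e < adj_delay.size(); ++e) {
    if (adj_delay[e] < 1) stop("delays must be at least one grid step");
    if (adj_delay[e] > max_delay) max_delay = adj_delay[e];
  }
  const int slots = max_delay + 1;
  std::vector<double> ringA((size_t)slots * n, 0.0),
      ringN((size_t)slots * n, 0.0), ringG((size_t)slots * n, 0.0);

  // exact-mode gating units
  int n_units = 0;
  std::vector<int> unit_of(n, -1);       // backend 1: neuron -> unit
  std::vector<int> unit_pop, unit_tgt, unit_delay, unit_src;
  std::vector<double> unit_w;
  if (backend == 1) {
    for (int i = 0; i < n; ++i) {
      if (exc_pop[pop_of[i]]) {
        unit_of[i] = n_units++;
        unit_pop.push_back(pop_of[i]);
        int d = 1;
        if (src_ptr[i + 1] > src_ptr[i]) d = adj_delay[src_ptr[i]];
        for (int e = src_ptr[i]; e < src_ptr[i + 1]; ++e)
          if (adj_delay[e] != d)
            stop("exact shared backend requires one delay per source");
        unit_delay.push_back(d);
      }
    }
  } else if (backend == 2) {
    for (int i = 0; i < n; ++i) {
      if (!exc_pop[pop_of[i]]) continue;
      for (int e = src_ptr[i]; e < src_ptr[i + 1]; ++e) {
        unit_pop.push_back(pop_of[i]);
        unit_tgt.push_back(adj_tgt[e]);
        unit_delay.push_back(adj_delay[e]);
        unit_w.push_back(adj_w[e]);
        unit_src.push_back(i);
        ++n_units;
      }
    }
    if (n_units > 2000000)
      stop("per-synapse exact backend is limited to small networks");
  }
  std::vector<double> Su(n_units, 0.0), xu(n_units, 0.0);
  std::vector<double> ring_x((size_t)slots * std::max(n_units, 1), 0.0);
  // backend 2: first-unit index per source, for per-source spike queuing
  std::vector<std::pair<int, int> > syn_units_of;  // (start,end) in unit list
  if (backend == 2) {
    syn_units_of.assign(n, std::make_pair(0, 0));
    int u = 0;
    for (int i = 0; i < n; ++i) {
      int st = u;
      if (exc_pop[pop_of[i]]) u += src_ptr[i + 1] - src_ptr[i];
      syn_units_of[i] = std::make_pair(st, u);
    }
  }

  std::vector<double> V(n), SA(n, 0.0), SAe(n, 0.0), SG(n, 0.0), SN(n, 0.0),
      S_loc(n, 0.0), hprop(n, dt / 10.0);
  std::vector<long long> refr_until(n, 0);
  for (int i = 0; i < n; ++i) V[i] = PP[pop_of[i]].EL;

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  long long delivA = 0, delivN = 0, delivG = 0;

  const int n_rec = rec_every > 0 ? n_steps / rec_every : 0;
  NumericMatrix popS(n_rec, n_pops);
  NumericVector rec_times(n_rec);
  const int n_rn = rec_neurons.size();
  NumericMatrix traceV(rec_every > 0 ? n_rec : 0, n_rn),
      traceSN(rec_every > 0 ? n_rec : 0, n_rn);

  std::vector<double> psum0(n_pops), psum1(n_pops), nm0v, nm1v;
  if (backend == 2) {
    nm0v.assign(n, 0.0);
    nm1v.assign(n, 0.0);
  }
  std::vector<int> pop_count(n_pops, 0);
  for (int i = 0; i < n; ++i) pop_count[pop_of[i]]++;
  // unit counts per pop for exact popS means
  std::vector<int> unit_count(n_pops, 0);
  for (int u = 0; u < n_units; ++u) unit_count[unit_pop[u]]++;

  for (int k = 0; k < n_steps; ++k) {
    const int slot = k % slots;
    // 1. consume delayed deliveries arriving at t_k
    {
      double *rA = &ringA[(size_t)slot * n], *rN = &ringN[(size_t)slot * n],
             *rG = &ringG[(size_t)slot * n];
      for (int i = 0; i < n; ++i) {
        SA[i] += rA[i];
        SN[i] += rN[i];
        SG[i] += rG[i];
        rA[i] = rN[i] = rG[i] = 0.0;
      }
      if (backend != 0) {
        double *rx = &ring_x[(size_t)slot * std::max(n_units, 1)];
        for (int u = 0; u < n_units; ++u) {
          xu[u] += rx[u];
          rx[u] = 0.0;
        }
      }
    }
    // 2. external background and stimulus (Bernoulli per bin, weight 1)
    for (int i = 0; i < n; ++i) {
      int p = pop_of[i];
      if (p_ext[p] > 0.0 && unif_rand() < p_ext[p]) SAe[i] += 1.0;
      if (has_stim) {
        double ps = stim_p(k, p);
        if (ps > 0.0 && unif_rand() < ps) SAe[i] += 1.0;
      }
    }
    const bool clamp_now = has_clamp && k < clamp_end_step;
    // 3. exact backends: advance gating units, form NMDA sums
    if (backend == 1) {
      std::fill(psum0.begin(), psum0.end(), 0.0);
      std::fill(psum1.begin(), psum1.end(), 0.0);
      for (int u = 0; u < n_units; ++u) psum0[unit_pop[u]] += Su[u];
      for (int u = 0; u < n_units; ++u) {
        if (Su[u] > 1e-14 || xu[u] > 1e-14) {
          Su[u] = exact_unit_advance(PP[unit_pop[u]], Su[u], xu[u], dt, atol,
                                     rtol);
          xu[u] *= PP[unit_pop[u]].decR;
        }
      }
      for (int u = 0; u < n_units; ++u) psum1[unit_pop[u]] += Su[u];
    } else if (backend == 2) {
      std::fill(nm0v.begin(), nm0v.end(), 0.0);
      std::fill(nm1v.begin(), nm1v.end(), 0.0);
      for (int u = 0; u < n_units; ++u) nm0v[unit_tgt[u]] += unit_w[u] * Su[u];
      for (int u = 0; u < n_units; ++u) {
        if (Su[u] > 1e-14 || xu[u] > 1e-14) {
          Su[u] = exact_unit_advance(PP[unit_pop[u]], Su[u], xu[u], dt, atol,
                                     rtol);
          xu[u] *= PP[unit_pop[u]].decR;
        }
      }
      for (int u = 0; u < n_units; ++u) nm1v[unit_tgt[u]] += unit_w[u] * Su[u];
    }
    // 4. membrane integration over [t_k, t_k + dt]
    for (int i = 0; i < n; ++i) {
      const int p = pop_of[i];
      const PopPar &P = PP[p];
      double D = clamp_now ? clamp_drive[i] : 0.0;
      double SNoff = D * P.tauD;
      if (k >= refr_until[i]) {
        if (backend == 0) {
          V[i] = lif_advance(P, V[i], dt, hprop[i], atol, rtol, SA[i], SAe[i],
                             SG[i], true, SN[i] - SNoff, SNoff, 0.0, 0.0,
                             0.0);
        } else {
          double m0, m1;
          if (backend == 1) {
            m0 = m1 = 0.0;
            for (int sp = 0; sp < n_pops; ++sp) {
              m0 += Wnmda(sp, p) * psum0[sp];
              m1 += Wnmda(sp, p) * psum1[sp];
            }
          } else {
            m0 = nm0v[i];
            m1 = nm1v[i];
          }
          V[i] = lif_advance(P, V[i], dt, hprop[i], atol, rtol, SA[i], SAe[i],
                             SG[i], false, 0.0, 0.0, m0, (m1 - m0) / dt, 0.0);
        }
      } else {
        V[i] = P.Vreset;
      }
      // 5. end-of-interval gating decay (exact exponential propagators)
      SA[i] *= P.decA;
      SAe[i] *= P.decA;
      SG[i] *= P.decG;
      SN[i] = (SN[i] - SNoff) * P.decN + SNoff;
      S_loc[i] *= P.decN;
    }
    // 6. threshold checks at the grid point t_{k+1}, in neuron-id order
    for (int i = 0; i < n; ++i) {
      if (k < refr_until[i] || V[i] < PP[pop_of[i]].Vthr) continue;
      const int p = pop_of[i];
      const PopPar &P = PP[p];
      spk_id.push_back(i + 1);
      spk_t.push_back((k + 1) * dt);
      V[i] = P.Vreset;
      refr_until[i] = (long long)k + 1 + P.ref_steps;
      double dS = 0.0;
      bool exc = exc_pop[p];
      if (backend == 0 && exc) {
        dS = P.k0 + P.k1 * S_loc[i];
        S_loc[i] += dS;
      }
      for (int e = src_ptr[i]; e < src_ptr[i + 1]; ++e) {
        int arrive = k + 1 + adj_delay[e];
        int sl = arrive % slots;
        int tgt = adj_tgt[e];
        if (exc) {
          ringA[(size_t)sl * n + tgt] += adj_w[e];
          ++delivA;
          bool suppressed =
              has_clamp && clamp_pop[p] && arrive < clamp_end_step;
          if (backend == 0 && !suppressed) {
            ringN[(size_t)sl * n + tgt] += adj_w[e] * dS;
            ++delivN;
          }
        } else {
          ringG[(size_t)sl * n + tgt] += adj_w[e];
          ++delivG;
        }
      }
      if (backend == 1 && exc) {
        int u = unit_of[i];
        int sl = (k + 1 + unit_delay[u]) % slots;
        ring_x[(size_t)sl * n_units + u] += 1.0;
      } else if (backend == 2 && exc) {
        for (int u = syn_units_of[i].first; u < syn_units_of[i].second; ++u) {
          int sl = (k + 1 + unit_delay[u]) % slots;
          ring_x[(size_t)sl * n_units + u] += 1.0;
        }
      }
    }
    // 7. recording
    if (rec_every > 0 && (k + 1) % rec_every == 0) {
      int r = (k + 1) / rec_every - 1;
      rec_times[r] = (k + 1) * dt;
      for (int p = 0; p < n_pops; ++p) popS(r, p) = 0.0;
      if (backend == 0) {
        for (int i = 0; i < n; ++i) popS(r, pop_of[i]) += S_loc[i];
        for (int p = 0; p < n_pops; ++p)
          if (pop_count[p] > 0) popS(r, p) /= pop_count[p];
      } else {
        for (int u = 0; u < n_units; ++u) popS(r, unit_pop[u]) += Su[u];
        for (int p = 0; p < n_pops; ++p)
          if (unit_count[p] > 0) popS(r, p) /= unit_count[p];
      }
      for (int q = 0; q < n_rn; ++q) {
        int i = rec_neurons[q];
        traceV(r, q) = V[i];
        double sn = SN[i];
        if (backend == 1) {
          sn = 0.0;
          for (int sp = 0; sp < n_pops; ++sp)
            sn += Wnmda(sp, pop_of[i]) * psum1[sp];
        } else if (backend == 2) {
          sn = nm1v[i];
        }
        traceSN(r, q) = sn;
      }
    }
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["spike_id"] = wrap(spk_id), _["spike_time"] = wrap(spk_t),
      _["rec_times"] = rec_times, _["popS"] = popS, _["traceV"] = traceV,
      _["traceSN"] = traceSN, _["final_SN"] = wrap(SN),
      _["deliveries"] = NumericVector::create(_["AMPA"] = (double)delivA,
                                              _["NMDA"] = (double)delivN,
                                              _["GABA"] = (double)delivG));
}
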