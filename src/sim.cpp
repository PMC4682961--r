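#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "cell.h"
using namespace Rcpp;

static void fill_mult(const NumericVector &m, Mult &out) {
  if (m.size() != N_CURRENT) stop("multiplier vector must have length 14");
  for (int k = 0; k < N_CURRENT; k++) {
    if (!(m[k] > 0)) stop("all conductance multipliers must be > 0");
    out.m[k] = m[k];
  }
}

static CharacterVector state_names() {
  return CharacterVector::create(
      "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
      "m", "h", "j", "a", "iF", "iS", "ap", "iFp", "iSp",
      "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
      "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt");
}

// [[Rcpp::export]]
NumericVector ord_initial_state_cpp() {
  NumericVector s(N_STATE);
  cell_initial_state(REAL(s));
  s.attr("names") = state_names();
  return s;
}

// exact (no lookup table) right-hand side; diagnostic / oracle path
// [[Rcpp::export]]
List cell_rhs_cpp(NumericVector state, NumericVector mult, double istim = 0) {
  if (state.size() != N_STATE) stop("state must have length 35");
  Mult mm;
  fill_mult(mult, mm);
  double q[NQ], dS[N_STATE], cur[N_CURRENT];
  compute_vdep(state[0], q);
  double iion = cell_rhs(REAL(state), q, mm, istim, dS, cur);
  NumericVector d(dS, dS + N_STATE), cc(cur, cur + N_CURRENT);
  d.attr("names") = state_names();
  cc.attr("names") = CharacterVector::create(
      "I_Na", "I_to", "I_CaL", "I_CaNa", "I_CaK", "I_Kr", "I_Ks", "I_K1",
      "I_NaCa", "I_NaK", "I_Nab", "I_Cab", "I_pCa", "I_Kb");
  for (int k = 0; k < N_CURRENT; k++)
    if (!std::isfinite(cur[k]))
      stop("non-finite ionic current: %s",
           as<std::string>(as<CharacterVector>(cc.attr("names"))[k]).c_str());
  return List::create(_["i_ion"] = iion, _["dstate"] = d,
                      _["currents"] = cc);
}

struct StimSchedule {
  std::vector<double> times; // pulse onsets, sorted
  double dur, amp;
  size_t k;
  StimSchedule() : dur(0), amp(0), k(0) {}
  double current(double t) {
    while (k < times.size() && t >= times[k] + dur) k++;
    if (k < times.size() && t >= times[k]) return amp;
    return 0.0;
  }
};

// single myocyte, optionally coupled to one passive fibroblast
// [[Rcpp::export]]
List simulate_cell_cpp(NumericVector state0, NumericVector mult,
                       double dt, double duration_ms, double sample_ms,
                       NumericVector stim_times, double stim_dur,
                       double stim_amp, bool has_fib, double vf0, double cf,
                       double ef, double gf_lo, double gf_hi, double gf_vt,
                       double ggap, double cm, bool rush_larsen,
                       bool use_lut) {
  if (state0.size() != N_STATE) stop("state must have length 35");
  if (dt <= 0 || duration_ms <= 0) stop("dt and duration must be > 0");
  Mult mm;
  fill_mult(mult, mm);
  long nsteps = (long)std::floor(duration_ms / dt + 0.5);
  long se = (long)std::floor(sample_ms / dt + 0.5);
  if (se < 1) se = 1;
  long nsamp = nsteps / se + 1;
  NumericVector tout(nsamp), vout(nsamp);
  NumericVector vfout = has_fib ? NumericVector(nsamp) : NumericVector(0);
  double S[N_STATE], q[NQTOT];
  lut_ensure(dt);
  for (int k = 0; k < N_STATE; k++) S[k] = state0[k];
  double vf = vf0;
  StimSchedule st;
  st.times = as<std::vector<double> >(stim_times);
  st.dur = stim_dur;
  st.amp = stim_amp;
  long isamp = 0;
  for (long step = 0; step < nsteps; step++) {
    double t = step * dt;
    if (step % se == 0) {
      tout[isamp] = t;
      vout[isamp] = S[IX_V];
      if (has_fib) vfout[isamp] = vf;
      isamp++;
    }
    double istim = st.current(t);
    if (use_lut)
      lut_lookup(S[IX_V], q);
    else
      compute_vdep_full(S[IX_V], dt, q);
    double vm = S[IX_V];
    double igap = has_fib ? ggap * (vm - vf) : 0.0;
    double iion = cell_advance(S, q, mm, istim, dt, rush_larsen);
    double vnew = vm + dt * (-iion - istim - igap / cm);
    if (!std::isfinite(vnew) || vnew > 600.0 || vnew < -155.0)
      stop("numerical instability at t = %.3f ms (Vm = %g)", t, vnew);
    S[IX_V] = vnew;
    if (has_fib) {
      double gf = (vf < gf_vt) ? gf_lo : gf_hi;
      vf += dt * (igap - gf * (vf - ef)) / cf;
    }
  }
  if (nsteps % se == 0) {
    tout[isamp] = nsteps * dt;
    vout[isamp] = S[IX_V];
    if (has_fib) vfout[isamp] = vf;
  }
  NumericVector sfin(S, S + N_STATE);
  sfin.attr("names") = state_names();
  List out = List::create(_["time"] = tout, _["vm"] = vout,
                          _["state"] = sfin);
  if (has_fib) {
    out["vf"] = vfout;
    out["vf_final"] = vf;
  }
  return out;
}

// monodomain tissue on an nx x ny grid (column-major site index i + nx*j)
// [[Rcpp::export]]
List simulate_tissue_cpp(int nx, int ny, double dx, double d0, double dt,
                         double duration_ms, IntegerVector type,
                         LogicalVector obstacle, NumericVector dscale,
                         NumericMatrix mult, NumericMatrix init,
                         LogicalVector fib_attach, NumericVector fib_ef,
                         NumericVector fib_ggap, double gf_lo, double gf_hi,
                         double gf_vt, double cf, double cm,
                         List stim_sites, List stim_times,
                         NumericVector stim_amp, NumericVector stim_dur,
                         IntegerVector sensors, double sample_ms,
                         double snapshot_ms, bool rush_larsen,
                         bool record_vf, bool return_state,
                         Nullable<NumericMatrix> init_site = R_NilValue,
                         Nullable<NumericVector> init_vf = R_NilValue) {
  const int ns = nx * ny;
  if (type.size() != ns || obstacle.size() != ns || dscale.size() != ns ||
      fib_attach.size() != ns || fib_ef.size() != ns || fib_ggap.size() != ns)
    stop("per-site maps must all have length nx*ny");
  if (init.nrow() != N_STATE || init.ncol() != mult.nrow())
    stop("init must be 35 x n_types");
  const int ntypes = mult.nrow();
  std::vector<Mult> mm(ntypes);
  for (int r = 0; r < ntypes; r++) {
    NumericVector row = mult(r, _);
    fill_mult(row, mm[r]);
  }

  // states
  std::vector<double> S((size_t)ns * N_STATE);
  std::vector<double> va(ns), vb(ns), vf(ns, 0.0);
  std::vector<char> act(ns, 0);
  std::vector<double> act_time(ns, NA_REAL);
  bool per_site = init_site.isNotNull();
  NumericMatrix isite;
  if (per_site) {
    isite = NumericMatrix(init_site);
    if (isite.nrow() != N_STATE || isite.ncol() != ns)
      stop("init_site must be 35 x (nx*ny)");
  }
  for (int i = 0; i < ns; i++) {
    if (obstacle[i]) {
      va[i] = NA_REAL;
      continue;
    }
    int tp = type[i];
    if (tp < 0 || tp >= ntypes) stop("cell-type index out of range");
    for (int k = 0; k < N_STATE; k++)
      S[(size_t)i * N_STATE + k] = per_site ? isite(k, i) : init(k, tp);
    va[i] = S[(size_t)i * N_STATE + IX_V];
    if (fib_attach[i]) vf[i] = fib_ef[i];
  }
  if (init_vf.isNotNull()) {
    NumericVector iv(init_vf);
    if (iv.size() != ns) stop("init_vf must have length nx*ny");
    for (int i = 0; i < ns; i++) vf[i] = iv[i];
  }

  // face weights (conservative flux form, no-flux at boundaries/obstacles)
  const double rdx2 = 1.0 / (dx * dx);
  std::vector<double> wL(ns, 0.0), wR(ns, 0.0), wU(ns, 0.0), wD(ns, 0.0);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      int s = i + nx * j;
      if (obstacle[s]) continue;
      double Ds = d0 * dscale[s];
      if (i > 0 && !obstacle[s - 1])
        wL[s] = 0.5 * (Ds + d0 * dscale[s - 1]) * rdx2;
      if (i < nx - 1 && !obstacle[s + 1])
        wR[s] = 0.5 * (Ds + d0 * dscale[s + 1]) * rdx2;
      if (j > 0 && !obstacle[s - nx])
        wD[s] = 0.5 * (Ds + d0 * dscale[s - nx]) * rdx2;
      if (j < ny - 1 && !obstacle[s + nx])
        wU[s] = 0.5 * (Ds + d0 * dscale[s + nx]) * rdx2;
    }

  // stimuli
  const int nstim = stim_sites.size();
  std::vector<StimSchedule> stims(nstim);
  std::vector<std::vector<int> > ssites(nstim);
  for (int s = 0; s < nstim; s++) {
    IntegerVector ss = stim_sites[s];
    ssites[s].resize(ss.size());
    for (int k = 0; k < ss.size(); k++) {
      int site = ss[k] - 1;
      if (site < 0 || site >= ns) stop("stimulus site out of range");
      ssites[s][k] = site;
    }
    stims[s].times = as<std::vector<double> >(stim_times[s]);
    stims[s].amp = stim_amp[s];
    stims[s].dur = stim_dur[s];
  }
  std::vector<double> istim_site(ns, 0.0);
  unsigned prev_active = 0xffffffffu; // force initial build

  long nsteps = (long)std::floor(duration_ms / dt + 0.5);
  long se = (long)std::floor(sample_ms / dt + 0.5);
  if (se < 1) se = 1;
  long nsamp = nsteps / se + 1;
  const int nsen = sensors.size();
  NumericMatrix traces(nsamp, nsen);
  NumericMatrix vftraces(record_vf ? nsamp : 0, record_vf ? nsen : 0);
  NumericVector tout(nsamp);
  std::vector<int> sen(nsen);
  for (int k = 0; k < nsen; k++) {
    sen[k] = sensors[k] - 1;
    if (sen[k] < 0 || sen[k] >= ns) stop("sensor site out of range");
  }
  long snap_every = snapshot_ms > 0 ? (long)std::floor(snapshot_ms / dt + 0.5)
                                    : 0;
  List snaps;
  std::vector<double> snap_times;

  double q[NQTOT];
  lut_ensure(dt);
  const double thr = -40.0; // activation threshold, mV
  long isamp = 0;
  double *vcur = va.data(), *vnew = vb.data();

  for (long step = 0; step < nsteps; step++) {
    double t = step * dt;
    if (step % se == 0) {
      tout[isamp] = t;
      for (int k = 0; k < nsen; k++) traces(isamp, k) = vcur[sen[k]];
      if (record_vf)
        for (int k = 0; k < nsen; k++) vftraces(isamp, k) = vf[sen[k]];
      isamp++;
    }
    if (snap_every > 0 && step % snap_every == 0) {
      NumericVector f(vcur, vcur + ns);
      snaps.push_back(f);
      snap_times.push_back(t);
    }
    // stimulus field (rebuild only when an on/off transition occurs)
    unsigned active = 0;
    for (int s = 0; s < nstim; s++)
      if (stims[s].current(t) != 0.0) active |= (1u << s);
    if (active != prev_active) {
      std::fill(istim_site.begin(), istim_site.end(), 0.0);
      for (int s = 0; s < nstim; s++)
        if (active & (1u << s))
          for (size_t k = 0; k < ssites[s].size(); k++)
            istim_site[ssites[s][k]] += stims[s].amp;
      prev_active = active;
    }

    for (int i = 0; i < ns; i++) {
      if (obstacle[i]) {
        vnew[i] = NA_REAL;
        continue;
      }
      double v = vcur[i];
      double diff = 0.0;
      if (wL[i] != 0.0) diff += wL[i] * (vcur[i - 1] - v);
      if (wR[i] != 0.0) diff += wR[i] * (vcur[i + 1] - v);
      if (wD[i] != 0.0) diff += wD[i] * (vcur[i - nx] - v);
      if (wU[i] != 0.0) diff += wU[i] * (vcur[i + nx] - v);
      double istim = istim_site[i];
      double igap = 0.0;
      if (fib_attach[i]) igap = fib_ggap[i] * (v - vf[i]);
      double *Si = &S[(size_t)i * N_STATE];
      lut_lookup(v, q);
      double iion = cell_advance(Si, q, mm[type[i]], istim, dt, rush_larsen);
      double vn = v + dt * (-iion - istim - igap / cm + diff);
      if (!std::isfinite(vn) || vn > 600.0 || vn < -155.0)
        stop("numerical instability at site %d (x=%d, y=%d), t = %.3f ms",
             i + 1, i % nx + 1, i / nx + 1, t);
      vnew[i] = vn;
      Si[IX_V] = vn;
      if (fib_attach[i]) {
        double gf = (vf[i] < gf_vt) ? gf_lo : gf_hi;
        vf[i] += dt * (igap - gf * (vf[i] - fib_ef[i])) / cf;
      }
      if (!act[i] && vn > thr && v <= thr) {
        act[i] = 1;
        act_time[i] = t + dt * (thr - v) / (vn - v);
      }
    }
    std::swap(vcur, vnew);
  }
  if (nsteps % se == 0) {
    tout[isamp] = nsteps * dt;
    for (int k = 0; k < nsen; k++) traces(isamp, k) = vcur[sen[k]];
    if (record_vf)
      for (int k = 0; k < nsen; k++) vftraces(isamp, k) = vf[sen[k]];
  }

  NumericVector vfin(vcur, vcur + ns);
  NumericVector amap(act_time.begin(), act_time.end());
  List out = List::create(
      _["time"] = tout, _["traces"] = traces, _["activation_map"] = amap,
      _["v_final"] = vfin, _["snapshot_times"] = wrap(snap_times),
      _["snapshots"] = snaps);
  if (record_vf) out["vf_traces"] = vftraces;
  if (return_state) {
    NumericMatrix sf(N_STATE, ns);
    for (int i = 0; i < ns; i++)
      for (int k = 0; k < N_STATE; k++)
        sf(k, i) = obstacle[i] ? NA_REAL : S[(size_t)i * N_STATE + k];
    out["state_final"] = sf;
    NumericVector vff(vf.begin(), vf.end());
    out["vf_final"] = vff;
  }
  return out;
}
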