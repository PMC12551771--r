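// Step-by-step (SBS) stochastic diffusion-reaction kernel.
//
// Point-tracked radiolysis species perform Brownian motion in a reflective
// cubic phantom. Second-order reactions use the Green's-function
// diffusion-equation (GFDE) encounter probability for an isolated pair,
//   p(r) = 1                                   for r <= R
//   p(r) = (R/r) * erfc((r - R) / (2 sqrt(D' dt)))  otherwise,
// evaluated against candidate partners within R + 4 sqrt(2 D' dt).
// When that search radius exceeds the phantom edge the channel is fully
// mixed; the free-space probability averaged over uniformly distributed
// partners integrates exactly to the mass-action rate 4 pi R D' dt / V, so
// the kernel then samples reaction counts from the equivalent per-pair
// binomial law without enumerating pairs. Dissolved oxygen is a continuum
// scavenger: each eligible molecule reacts with 1 - exp(-k C dt).
//
// Positions are synchronised lazily: a molecule's pending Brownian
// displacement is accumulated and realised as a single Gaussian of variance
// 2 D (t - t_sync) when the position is actually needed (spatial pair
// search, snapshot, final state). Folding the summed increment samples the
// exact reflected-diffusion transition kernel, so deferral is statistically
// exact.
//
// All randomness draws from R's RNG, so runs are reproducible under
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double PAIR_CONV = 1.0 / (6.02214076e23 * 1e-15); // M per (molecule/um^3)

static inline double fold(double v, double L) {
  const double p = 2.0 * L;
  v -= std::floor(v / p) * p;    // into [0, 2L)
  if (v > L) v = p - v;
  return v;
}

struct Cand { int rid; int i; int j; };

// [[Rcpp::export]]
List cpp_run_chemistry(
    IntegerVector init_sp, NumericVector init_x, NumericVector init_y,
    NumericVector init_z, IntegerVector init_trk,
    NumericVector D_um2s, LogicalVector continuum,
    IntegerVector so_a, IntegerVector so_b, NumericVector so_R_um,
    NumericVector so_Dmut_um2s, NumericVector so_k, IntegerMatrix so_prod,
    IntegerVector pfo_sp, NumericVector pfo_k, IntegerMatrix pfo_prod,
    double o2_uM, double avg_volume_um3,
    NumericVector arr_time, List arr_sp, List arr_x, List arr_y, List arr_z,
    IntegerVector arr_trk, NumericVector arr_energy_eV,
    double t_start, double t_end,
    NumericVector sched_bp, NumericVector sched_dt_s,
    double box_L, double wm_frac,
    NumericVector pd_r, NumericVector pd_w,
    NumericVector out_times, NumericVector snap_times,
    bool log_events, double max_molecules) {

  const int n_sp = D_um2s.size();
  const int n_so = so_a.size();
  const int n_pfo = pfo_sp.size();
  const double Vbox = box_L * box_L * box_L;

  // --- state (struct of arrays) ---
  std::vector<double> x, y, z, tsync;
  std::vector<int> sp, trk;
  std::vector<char> alive;
  long n_alive = 0;

  auto add_molecule = [&](int s, double px, double py, double pz, int tr,
                          double ts) {
    sp.push_back(s);
    x.push_back(fold(px, box_L));
    y.push_back(fold(py, box_L));
    z.push_back(fold(pz, box_L));
    trk.push_back(tr);
    tsync.push_back(ts);
    alive.push_back(1);
    ++n_alive;
  };

  for (int i = 0; i < init_sp.size(); ++i)
    add_molecule(init_sp[i], init_x[i], init_y[i], init_z[i], init_trk[i],
                 t_start);

  // --- schedule lookup ---
  std::vector<double> bp(sched_bp.begin(), sched_bp.end());
  std::vector<double> dts(sched_dt_s.begin(), sched_dt_s.end());
  auto sched = [&](double elapsed) -> double {
    double dt = dts[0];
    for (size_t k = 1; k < bp.size(); ++k) {
      if (bp[k] <= elapsed) dt = dts[k]; else break;
    }
    return dt;
  };

  // --- outputs ---
  const int n_out = out_times.size();
  IntegerMatrix out_counts(n_out, n_sp);
  NumericVector out_o2(n_out), out_edep(n_out);
  int next_out = 0;
  const int n_snap = snap_times.size();
  List snapshots(n_snap);
  int next_snap = 0;

  std::vector<int> ev_rid, ev_ta, ev_tb;
  std::vector<double> ev_t;
  double o2_gen_total = 0, o2_cons_total = 0;
  double edep = 0;

  // --- helpers ---
  std::vector<std::vector<int>> by_sp(n_sp);
  std::vector<char> sp_synced(n_sp, 0);

  auto sync_molecule = [&](int i, double tnow) {
    double dtau = tnow - tsync[i];
    if (dtau <= 0) return;
    double sig = std::sqrt(2.0 * D_um2s[sp[i]] * dtau);
    if (sig > 0) {
      x[i] = fold(x[i] + norm_rand() * sig, box_L);
      y[i] = fold(y[i] + norm_rand() * sig, box_L);
      z[i] = fold(z[i] + norm_rand() * sig, box_L);
    }
    tsync[i] = tnow;
  };
  auto sync_species = [&](int s, double tnow) {
    for (int i : by_sp[s]) if (alive[i]) sync_molecule(i, tnow);
  };
  auto sync_all = [&](double tnow) {
    for (size_t i = 0; i < sp.size(); ++i) if (alive[i]) sync_molecule(i, tnow);
  };

  auto record_out = [&](int k) {
    for (size_t i = 0; i < sp.size(); ++i)
      if (alive[i]) out_counts(k, sp[i]) += 1;
    out_o2[k] = o2_uM;
    out_edep[k] = edep;
  };

  auto record_snap = [&](int k, double tnow) {
    sync_all(tnow);
    IntegerVector ssp(n_alive);
    NumericVector sx(n_alive), sy(n_alive), sz(n_alive);
    IntegerVector str(n_alive);
    int m = 0;
    for (size_t i = 0; i < sp.size(); ++i) if (alive[i]) {
      ssp[m] = sp[i]; sx[m] = x[i]; sy[m] = y[i]; sz[m] = z[i];
      str[m] = trk[i]; ++m;
    }
    snapshots[k] = List::create(_["time_s"] = tnow, _["sp"] = ssp,
                                _["x_um"] = sx, _["y_um"] = sy,
                                _["z_um"] = sz, _["track"] = str);
  };

  auto compact = [&]() {
    size_t m = 0;
    for (size_t i = 0; i < sp.size(); ++i) {
      if (alive[i]) {
        if (m != i) {
          sp[m] = sp[i]; x[m] = x[i]; y[m] = y[i]; z[m] = z[i];
          trk[m] = trk[i]; tsync[m] = tsync[i];
        }
        ++m;
      }
    }
    sp.resize(m); x.resize(m); y.resize(m); z.resize(m);
    trk.resize(m); tsync.resize(m);
    alive.assign(m, 1);
  };

  // --- main loop ---
  int next_arr = 0;
  const int n_arr = arr_time.size();
  auto inject_due = [&](double tnow) {
    while (next_arr < n_arr && arr_time[next_arr] <= tnow + 1e-300) {
      IntegerVector ms = arr_sp[next_arr];
      NumericVector mx = arr_x[next_arr], my = arr_y[next_arr],
                    mz = arr_z[next_arr];
      for (int i = 0; i < ms.size(); ++i)
        add_molecule(ms[i], mx[i], my[i], mz[i], arr_trk[next_arr],
                     arr_time[next_arr]);
      edep += arr_energy_eV[next_arr];
      ++next_arr;
      if ((double)sp.size() > max_molecules)
        stop("molecule capacity exceeded");
    }
  };

  double t = t_start;
  inject_due(t);
  double elapsed = 0;
  double last_arrival = t_start;
  while (next_out < n_out && out_times[next_out] <= t + 1e-300) {
    record_out(next_out); ++next_out;
  }
  while (next_snap < n_snap && snap_times[next_snap] <= t + 1e-300) {
    record_snap(next_snap, t); ++next_snap;
  }

  std::vector<Cand> cand;
  std::vector<int> cellhead, cellnext; // cell list storage

  while (t < t_end * (1 - 1e-15)) {
    double dt = sched(elapsed);
    double t_next = t + dt;
    if (next_arr < n_arr && arr_time[next_arr] < t_next)
      t_next = arr_time[next_arr];
    if (next_out < n_out && out_times[next_out] > t &&
        out_times[next_out] < t_next)
      t_next = out_times[next_out];
    if (next_snap < n_snap && snap_times[next_snap] > t &&
        snap_times[next_snap] < t_next)
      t_next = snap_times[next_snap];
    if (t_end < t_next) t_next = t_end;
    dt = t_next - t;

    if (dt > 0 && n_alive > 0) {
      // rebuild per-species index lists
      for (int s = 0; s < n_sp; ++s) by_sp[s].clear();
      for (size_t i = 0; i < sp.size(); ++i)
        if (alive[i]) by_sp[sp[i]].push_back((int)i);

      // ---- second-order reactions ----
      cand.clear();
      std::fill(sp_synced.begin(), sp_synced.end(), 0);
      long o2_gen = 0, o2_cons = 0;

      for (int r = 0; r < n_so; ++r) {
        int a = so_a[r], b = so_b[r];
        size_t na = by_sp[a].size(), nb = by_sp[b].size();
        if (a == b) { if (na < 2) continue; }
        else if (na == 0 || nb == 0) continue;
        double R = so_R_um[r], Dm = so_Dmut_um2s[r];
        double sdiff = std::sqrt(2.0 * Dm * dt);
        double cutoff = R + 4.0 * sdiff;

        if (cutoff >= wm_frac * box_L) {
          // mixed channel: free-space GFDE probability averaged over the
          // box's uniform pair-distance distribution. For short steps this
          // integrates to the mass-action rate 4 pi R D' dt / V; for steps
          // long compared with the box mixing time it saturates at the
          // geometric encounter probability <R/r>, as in free space.
          double inv2sm = 1.0 / (2.0 * std::sqrt(Dm * dt));
          double q = 0.0;
          for (int b2 = 0; b2 < pd_r.size(); ++b2) {
            double rr = pd_r[b2];
            double p = (rr <= R) ? 1.0
                                 : (R / rr) * std::erfc((rr - R) * inv2sm);
            q += pd_w[b2] * p;
          }
          if (q > 1) q = 1;
          double npairs = (a == b) ? 0.5 * (double)na * (double)(na - 1)
                                   : (double)na * (double)nb;
          double nev = R::rbinom(npairs, q);
          double cap = 3.0 * (a == b ? na / 2.0 : std::min(na, nb));
          if (nev > cap) nev = cap;
          for (int e = 0; e < (int)nev; ++e) {
            int i, j;
            if (a == b) {
              i = (int)(unif_rand() * na); if (i >= (int)na) i = na - 1;
              j = (int)(unif_rand() * (na - 1)); if (j >= (int)na - 1) j = na - 2;
              if (j >= i) ++j;
              i = by_sp[a][i]; j = by_sp[a][j];
            } else {
              i = by_sp[a][(int)(unif_rand() * na) % na];
              j = by_sp[b][(int)(unif_rand() * nb) % nb];
            }
            cand.push_back({r, i, j});
          }
          continue;
        }

        // spatial (GFDE) channel. The erfc expression is the capture
        // probability within dt GIVEN the separation at the step start, so
        // pairs are evaluated on positions synchronised to the start of the
        // step; survivors then carry the step's displacement lazily.
        if (!sp_synced[a]) { sync_species(a, t); sp_synced[a] = 1; }
        if (!sp_synced[b]) { sync_species(b, t); sp_synced[b] = 1; }
        double c2 = cutoff * cutoff;
        double inv2s = 1.0 / (2.0 * std::sqrt(Dm * dt));
        const std::vector<int>& A = by_sp[a];
        const std::vector<int>& B = by_sp[b];

        auto try_pair = [&](int i, int j) {
          double dxv = x[i] - x[j], dyv = y[i] - y[j], dzv = z[i] - z[j];
          double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
          if (r2 > c2) return;
          double rr = std::sqrt(r2);
          double p = (rr <= R) ? 1.0
                               : (R / rr) * std::erfc((rr - R) * inv2s);
          if (unif_rand() < p) cand.push_back({r, i, j});
        };

        if ((double)na * (double)nb <= 20000.0) {
          for (size_t ii = 0; ii < na; ++ii) {
            int i = A[ii];
            size_t j0 = (a == b) ? ii + 1 : 0;
            for (size_t jj = j0; jj < nb; ++jj) {
              int j = B[jj];
              try_pair(i, j);
            }
          }
        } else {
          // cell list over B
          int ncell = (int)std::floor(box_L / cutoff);
          if (ncell < 1) ncell = 1;
          if (ncell > 64) ncell = 64;
          double csz = box_L / ncell;
          int ncell3 = ncell * ncell * ncell;
          cellhead.assign(ncell3, -1);
          cellnext.resize(sp.size());
          auto cix = [&](double v) {
            int k = (int)(v / csz);
            if (k < 0) k = 0;
            if (k >= ncell) k = ncell - 1;
            return k;
          };
          for (int j : B) {
            int c = cix(x[j]) + ncell * (cix(y[j]) + ncell * cix(z[j]));
            cellnext[j] = cellhead[c];
            cellhead[c] = j;
          }
          for (int i : A) {
            int cxi = cix(x[i]), cyi = cix(y[i]), czi = cix(z[i]);
            for (int ddx = -1; ddx <= 1; ++ddx) {
              int gx = cxi + ddx; if (gx < 0 || gx >= ncell) continue;
              for (int ddy = -1; ddy <= 1; ++ddy) {
                int gy = cyi + ddy; if (gy < 0 || gy >= ncell) continue;
                for (int ddz = -1; ddz <= 1; ++ddz) {
                  int gz = czi + ddz; if (gz < 0 || gz >= ncell) continue;
                  int c = gx + ncell * (gy + ncell * gz);
                  for (int j = cellhead[c]; j >= 0; j = cellnext[j]) {
                    if (a == b && j <= i) continue;
                    try_pair(i, j);
                  }
                }
              }
            }
          }
        }
      }

      // random-order conflict resolution: shuffle candidates, apply
      for (size_t i = cand.size(); i > 1; --i) {
        size_t j = (size_t)(unif_rand() * i); if (j >= i) j = i - 1;
        std::swap(cand[i - 1], cand[j]);
      }
      for (const Cand& c : cand) {
        if (!alive[c.i] || !alive[c.j]) continue;
        int r = c.rid;
        alive[c.i] = 0; alive[c.j] = 0; n_alive -= 2;
        bool mixed = (so_R_um[r] + 4.0 * std::sqrt(2.0 * so_Dmut_um2s[r] * dt))
                       >= wm_frac * box_L;
        // product anchor: diffusion-weighted point between the reactants
        double px, py, pz, pts;
        if (mixed) {
          px = unif_rand() * box_L; py = unif_rand() * box_L;
          pz = unif_rand() * box_L; pts = t_next;
        } else {
          double wi = std::sqrt(D_um2s[sp[c.j]]);
          double wj = std::sqrt(D_um2s[sp[c.i]]);
          double ws = wi + wj;
          if (ws <= 0) { wi = wj = 1; ws = 2; }
          px = (wi * x[c.i] + wj * x[c.j]) / ws;
          py = (wi * y[c.i] + wj * y[c.j]) / ws;
          pz = (wi * z[c.i] + wj * z[c.j]) / ws;
          pts = t;  // products inherit the step's pending displacement
        }
        for (int pcol = 0; pcol < 3; ++pcol) {
          int pid = so_prod(r, pcol);
          if (pid < 0) continue;
          if (continuum[pid]) { ++o2_gen; continue; }
          if (pcol == 0) add_molecule(pid, px, py, pz, trk[c.i], pts);
          else if (pcol == 1)
            add_molecule(pid, mixed ? unif_rand() * box_L : x[c.i],
                         mixed ? unif_rand() * box_L : y[c.i],
                         mixed ? unif_rand() * box_L : z[c.i], trk[c.i], pts);
          else
            add_molecule(pid, mixed ? unif_rand() * box_L : x[c.j],
                         mixed ? unif_rand() * box_L : y[c.j],
                         mixed ? unif_rand() * box_L : z[c.j], trk[c.i], pts);
        }
        if (log_events) {
          ev_rid.push_back(r); ev_t.push_back(t_next);
          ev_ta.push_back(trk[c.i]); ev_tb.push_back(trk[c.j]);
        }
      }

      // ---- pseudo-first-order scavenging by the continuum field ----
      for (int r = 0; r < n_pfo; ++r) {
        double C_M = o2_uM * 1e-6;
        if (C_M <= 0) continue;
        double p = -std::expm1(-pfo_k[r] * C_M * dt);
        if (p <= 0) continue;
        int s = pfo_sp[r];
        for (int i : by_sp[s]) {
          if (!alive[i]) continue;
          if (unif_rand() >= p) continue;
          alive[i] = 0; --n_alive;
          ++o2_cons;
          for (int pcol = 0; pcol < 3; ++pcol) {
            int pid = pfo_prod(r, pcol);
            if (pid < 0) continue;
            if (continuum[pid]) { ++o2_gen; continue; }
            add_molecule(pid, x[i], y[i], z[i], trk[i], tsync[i]);
          }
          if (log_events) {
            ev_rid.push_back(n_so + r); ev_t.push_back(t_next);
            ev_ta.push_back(trk[i]); ev_tb.push_back(-1);
          }
        }
      }

      // ---- spatially averaged oxygen bookkeeping ----
      if (o2_gen != 0 || o2_cons != 0) {
        o2_gen_total += o2_gen; o2_cons_total += o2_cons;
        o2_uM += (double)(o2_gen - o2_cons) * PAIR_CONV * 1e6 / avg_volume_um3;
        if (o2_uM < 0) o2_uM = 0;
      }

      if ((double)sp.size() - (double)n_alive > 2000 &&
          (double)n_alive < 0.5 * (double)sp.size())
        compact();
      if ((double)sp.size() > max_molecules)
        stop("molecule capacity exceeded");
    }

    t = t_next;
    elapsed = t - last_arrival;
    if (next_arr < n_arr && arr_time[next_arr] <= t + 1e-300) {
      inject_due(t);
      last_arrival = t;
      elapsed = 0;
    }
    while (next_out < n_out && out_times[next_out] <= t + 1e-300) {
      record_out(next_out); ++next_out;
    }
    while (next_snap < n_snap && snap_times[next_snap] <= t + 1e-300) {
      record_snap(next_snap, t); ++next_snap;
    }
    checkUserInterrupt();
  }

  // record any outputs at/after the horizon
  while (next_out < n_out) { record_out(next_out); ++next_out; }
  while (next_snap < n_snap) { record_snap(next_snap, t); ++next_snap; }

  sync_all(t);
  compact();
  int nm = sp.size();
  IntegerVector fsp(nm), ftr(nm);
  NumericVector fx(nm), fy(nm), fz(nm);
  for (int i = 0; i < nm; ++i) {
    fsp[i] = sp[i]; ftr[i] = trk[i]; fx[i] = x[i]; fy[i] = y[i]; fz[i] = z[i];
  }

  return List::create(
    _["out_counts"] = out_counts,
    _["out_o2_uM"] = out_o2,
    _["out_edep_eV"] = out_edep,
    _["events"] = List::create(
      _["reaction"] = IntegerVector(ev_rid.begin(), ev_rid.end()),
      _["time_s"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["track_a"] = IntegerVector(ev_ta.begin(), ev_ta.end()),
      _["track_b"] = IntegerVector(ev_tb.begin(), ev_tb.end())),
    _["snapshots"] = snapshots,
    _["final"] = List::create(_["sp"] = fsp, _["x_um"] = fx, _["y_um"] = fy,
                              _["z_um"] = fz, _["track"] = ftr),
    _["o2_uM"] = o2_uM,
    _["o2_generated"] = o2_gen_total,
    _["o2_consumed"] = o2_cons_total,
    _["edep_eV"] = edep,
    _["n_injected_tracks"] = next_arr);
}
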