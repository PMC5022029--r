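// Lattice Gillespie engine for STIM1/Orai1 assembly on the plasma membrane.
//
// Species per subvolume (sv):
//   free dimers      -- individual-based (needed for O(1) diffusion hops)
//   trapped dimers   -- counts b0 (clean) / b1 (oxidized)
//   tetramers        -- counts T[k], k = number of oxidized constituent dimers (0..2)
//   hexamers         -- counts H[k], k = 0..3
// STIM1 sites are pooled per junction; a trapped dimer consumes `spd` sites.
// A channel is "locked" (non-conducting) iff k > 0.
//
// Reactions (propensities):
//   hop free dimer        4*D/h^2 * N_free          (blocked directions = null events)
//   hop trapped dimer     4*D_t/h^2 * N_b           (target must stay in same junction)
//   trap                  k_trap * sum_j stim_j * F_j   (F_j = free dimers over junction svs)
//   untrap                k_untrap * N_b
//   dimer+dimer -> tet    k_dd * sum_i bt_i*(bt_i-1)/2
//   tet+dimer  -> hex     k_td * sum_i Tt_i*bt_i
//   tet -> 2 dimers       k_dis_tet * N_T
//   hex -> tet + dimer    k_dis_hex * N_H
//
// Uses R's RNG: trajectories are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double pairs2(int n) { return 0.5 * n * (n - 1); }

struct Engine {
  int nx, ny, nsv;
  double h;
  std::vector<int> jof;                 // junction of sv, -1 if none
  std::vector<std::vector<int>> jsvs;   // member svs per junction
  std::vector<int> jsv_all;             // all junction svs (flat)
  int nj;

  // params
  double D, Dt, k_trap, k_untrap, k_dd, k_td, k_dis_tet, k_dis_hex;
  double P_hex, P_tet, P_dim, i_unit;
  int spd;
  double t_store;

  // free dimers, individual-based
  std::vector<int> d_sv, d_ox;          // indexed by id
  std::vector<int> pool, pool_pos;      // live free ids; position in pool
  std::vector<int> dead;                // reusable ids
  std::vector<std::vector<int>> svlist; // free ids per sv
  std::vector<int> sv_pos;              // position of id in its svlist
  std::vector<int> f0, f1;              // free counts per sv

  // trapped + channels, count-based
  std::vector<int> b0, b1, T0, T1, T2, H0, H1, H2, H3;
  std::vector<int> stim;                // free STIM1 sites per junction
  std::vector<int> Fj;                  // free dimers over junction svs

  // maintained aggregates
  long Nfree, Nb, NT, NH;
  long b0tot, b1tot, T0tot, H0tot, lockedtot;
  double Pdd, Ptd, Strap;
  bool stim_active;
  long M0; // conserved monomer count

  int bt(int i) const { return b0[i] + b1[i]; }
  int Tt(int i) const { return T0[i] + T1[i] + T2[i]; }
  int Ht(int i) const { return H0[i] + H1[i] + H2[i] + H3[i]; }

  void strap_update_j(int j, int old_stim, int old_F) {
    double oldw = (old_stim >= spd) ? (double)old_stim * old_F : 0.0;
    double neww = (stim[j] >= spd) ? (double)stim[j] * Fj[j] : 0.0;
    Strap += neww - oldw;
  }

  // --- free dimer plumbing -------------------------------------------------
  void free_insert(int id, int sv) {
    d_sv[id] = sv;
    pool_pos[id] = pool.size(); pool.push_back(id);
    sv_pos[id] = svlist[sv].size(); svlist[sv].push_back(id);
    if (d_ox[id]) f1[sv]++; else f0[sv]++;
    Nfree++;
    int j = jof[sv];
    if (j >= 0) { int oF = Fj[j]; Fj[j]++; strap_update_j(j, stim[j], oF); }
  }
  void free_remove(int id) {
    int sv = d_sv[id];
    // pool swap-remove
    int p = pool_pos[id], last = pool.back();
    pool[p] = last; pool_pos[last] = p; pool.pop_back();
    // svlist swap-remove
    int q = sv_pos[id], lst = svlist[sv].back();
    svlist[sv][q] = lst; sv_pos[lst] = q; svlist[sv].pop_back();
    if (d_ox[id]) f1[sv]--; else f0[sv]--;
    Nfree--;
    int j = jof[sv];
    if (j >= 0) { int oF = Fj[j]; Fj[j]--; strap_update_j(j, stim[j], oF); }
  }
  void free_move(int id, int to) {
    int from = d_sv[id];
    int q = sv_pos[id], lst = svlist[from].back();
    svlist[from][q] = lst; sv_pos[lst] = q; svlist[from].pop_back();
    sv_pos[id] = svlist[to].size(); svlist[to].push_back(id);
    if (d_ox[id]) { f1[from]--; f1[to]++; } else { f0[from]--; f0[to]++; }
    d_sv[id] = to;
    int jf = jof[from], jt = jof[to];
    if (jf != jt) {
      if (jf >= 0) { int oF = Fj[jf]; Fj[jf]--; strap_update_j(jf, stim[jf], oF); }
      if (jt >= 0) { int oF = Fj[jt]; Fj[jt]++; strap_update_j(jt, stim[jt], oF); }
    }
  }
  int new_free(int sv, int ox) {
    int id;
    if (!dead.empty()) { id = dead.back(); dead.pop_back(); }
    else {
      id = d_sv.size();
      d_sv.push_back(0); d_ox.push_back(0);
      pool_pos.push_back(-1); sv_pos.push_back(-1);
    }
    d_ox[id] = ox;
    free_insert(id, sv);
    return id;
  }

  // --- trapped-dimer count updates keeping Pdd/Ptd consistent --------------
  void b_change(int i, int dox0, int dox1) {
    int obt = bt(i), oT = Tt(i);
    b0[i] += dox0; b1[i] += dox1;
    b0tot += dox0; b1tot += dox1;
    Nb += dox0 + dox1;
    Pdd += pairs2(bt(i)) - pairs2(obt);
    Ptd += (double)oT * (bt(i) - obt);
  }
  void T_change(int i, int k, int d) {
    int oT = Tt(i);
    if (k == 0) T0[i] += d; else if (k == 1) T1[i] += d; else T2[i] += d;
    NT += d;
    if (k == 0) T0tot += d; else lockedtot += d;
    Ptd += (double)(Tt(i) - oT) * bt(i);
  }
  void H_change(int i, int k, int d) {
    if (k == 0) H0[i] += d; else if (k == 1) H1[i] += d;
    else if (k == 2) H2[i] += d; else H3[i] += d;
    NH += d;
    if (k == 0) H0tot += d; else lockedtot += d;
  }

  double current() const {
    return i_unit * (P_hex * H0tot + P_tet * T0tot + P_dim * b0tot);
  }
  long monomers() const { return 2 * (Nfree + Nb) + 4 * NT + 6 * NH; }

  // weighted pick over junction svs; w supplied by caller as lambda
  template <class W>
  int pick_jsv(double total, W w) {
    double u = unif_rand() * total, acc = 0.0;
    int last = -1;
    for (size_t q = 0; q < jsv_all.size(); ++q) {
      int i = jsv_all[q];
      double wi = w(i);
      if (wi <= 0) continue;
      last = i; acc += wi;
      if (u < acc) return i;
    }
    return last; // guard against fp round-off
  }
};

int d_svx(const Engine& E, int id, const int* dx, const int* dy, int dir);

// [[Rcpp::export(name = ".socm_engine")]]
List socm_engine_cpp(List geom, List par, List state, double t_end,
                     double record_dt, double max_events, double check_every) {
  Engine E;
  E.nx = as<int>(geom["nx"]); E.ny = as<int>(geom["ny"]);
  E.h  = as<double>(geom["h"]);
  E.nsv = E.nx * E.ny;
  IntegerVector jof_r = geom["junction_of"]; // 0 = none, 1-based junction ids
  E.jof.resize(E.nsv);
  for (int i = 0; i < E.nsv; ++i) E.jof[i] = jof_r[i] - 1;
  List jsvs_r = geom["junction_svs"];        // 1-based sv indices per junction
  E.nj = jsvs_r.size();
  E.jsvs.resize(E.nj);
  for (int j = 0; j < E.nj; ++j) {
    IntegerVector v = jsvs_r[j];
    for (int k = 0; k < v.size(); ++k) {
      E.jsvs[j].push_back(v[k] - 1);
      E.jsv_all.push_back(v[k] - 1);
    }
  }

  E.D = as<double>(par["D_O"]); E.Dt = as<double>(par["D_trapped"]);
  E.k_trap = as<double>(par["k_trap"]); E.k_untrap = as<double>(par["k_untrap"]);
  E.k_dd = as<double>(par["k_dd"]); E.k_td = as<double>(par["k_td"]);
  E.k_dis_tet = as<double>(par["k_dis_tet"]); E.k_dis_hex = as<double>(par["k_dis_hex"]);
  E.P_hex = as<double>(par["P_hex"]); E.P_tet = as<double>(par["P_tet"]);
  E.P_dim = as<double>(par["P_dim"]);
  E.i_unit = as<double>(par["i_unit"]);
  E.spd = as<int>(par["stim_per_dimer"]);
  E.t_store = as<double>(par["store_depletion_time"]);

  // state in
  IntegerVector fr_sv = state["free_sv"], fr_ox = state["free_ox"]; // 1-based sv
  IntegerVector b0_r = state["b0"], b1_r = state["b1"];
  IntegerVector T0_r = state["T0"], T1_r = state["T1"], T2_r = state["T2"];
  IntegerVector H0_r = state["H0"], H1_r = state["H1"], H2_r = state["H2"], H3_r = state["H3"];
  IntegerVector stim_r = state["stim_free"];
  double t = as<double>(state["t"]);

  E.f0.assign(E.nsv, 0); E.f1.assign(E.nsv, 0);
  E.svlist.assign(E.nsv, {});
  E.b0.assign(E.nsv, 0); E.b1.assign(E.nsv, 0);
  E.T0.assign(E.nsv, 0); E.T1.assign(E.nsv, 0); E.T2.assign(E.nsv, 0);
  E.H0.assign(E.nsv, 0); E.H1.assign(E.nsv, 0); E.H2.assign(E.nsv, 0); E.H3.assign(E.nsv, 0);
  E.stim.assign(E.nj, 0); E.Fj.assign(E.nj, 0);
  E.Nfree = E.Nb = E.NT = E.NH = 0;
  E.b0tot = E.b1tot = E.T0tot = E.H0tot = E.lockedtot = 0;
  E.Pdd = E.Ptd = E.Strap = 0.0;

  for (int j = 0; j < E.nj; ++j) E.stim[j] = stim_r[j];
  for (int i = 0; i < fr_sv.size(); ++i) E.new_free(fr_sv[i] - 1, fr_ox[i]);
  for (int i = 0; i < E.nsv; ++i) {
    if (b0_r[i] || b1_r[i]) E.b_change(i, b0_r[i], b1_r[i]);
    if (T0_r[i]) E.T_change(i, 0, T0_r[i]);
    if (T1_r[i]) E.T_change(i, 1, T1_r[i]);
    if (T2_r[i]) E.T_change(i, 2, T2_r[i]);
    if (H0_r[i]) E.H_change(i, 0, H0_r[i]);
    if (H1_r[i]) E.H_change(i, 1, H1_r[i]);
    if (H2_r[i]) E.H_change(i, 2, H2_r[i]);
    if (H3_r[i]) E.H_change(i, 3, H3_r[i]);
  }
  E.M0 = E.monomers();
  E.stim_active = (t >= E.t_store);

  // recording grid (t0 .. t_end)
  bool record = record_dt > 0;
  std::vector<double> rec_t, rec_I;
  std::vector<int> rec_free, rec_b, rec_T, rec_H, rec_lock;
  double next_rec = t;
  auto rec_point = [&](double tt) {
    rec_t.push_back(tt); rec_I.push_back(E.current());
    rec_free.push_back(E.Nfree); rec_b.push_back(E.Nb);
    rec_T.push_back(E.NT); rec_H.push_back(E.NH); rec_lock.push_back(E.lockedtot);
  };

  double hopf = 4.0 * E.D / (E.h * E.h), hopb = 4.0 * E.Dt / (E.h * E.h);
  const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
  double n_events = 0;
  long since_check = 0;
  bool limited = max_events > 0;

  while (t < t_end) {
    if (limited && n_events >= max_events) break;
    double a1 = hopf * E.Nfree;
    double a2 = hopb * E.Nb;
    double a3 = E.stim_active ? E.k_trap * E.Strap : 0.0;
    double a4 = E.k_untrap * E.Nb;
    double a5 = E.k_dd * E.Pdd;
    double a6 = E.k_td * E.Ptd;
    double a7 = E.k_dis_tet * E.NT;
    double a8 = E.k_dis_hex * E.NH;
    double atot = a1 + a2 + a3 + a4 + a5 + a6 + a7 + a8;

    if (atot <= 0.0) {
      if (!E.stim_active && E.t_store < t_end) {
        while (record && next_rec <= E.t_store + 1e-12 && next_rec <= t_end) {
          rec_point(next_rec); next_rec += record_dt;
        }
        t = E.t_store; E.stim_active = true; continue;
      }
      t = t_end; break;
    }

    double tnew = t + exp_rand() / atot;
    if (!E.stim_active && tnew >= E.t_store) {
      // propensities change at store depletion: redraw from t_store (memoryless)
      while (record && next_rec < E.t_store - 1e-12 && next_rec <= t_end) {
        rec_point(next_rec); next_rec += record_dt;
      }
      t = E.t_store; E.stim_active = true; continue;
    }
    while (record && next_rec <= std::min(tnew, t_end) + 1e-12) {
      rec_point(next_rec); next_rec += record_dt;
    }
    if (tnew >= t_end) { t = t_end; break; }
    t = tnew;
    n_events += 1;

    double u = unif_rand() * atot;
    if (u < a1) {
      // free hop
      int id = E.pool[(int)(unif_rand() * E.Nfree) % E.Nfree];
      int dir = (int)(unif_rand() * 4) % 4;
      int x = d_svx(E, id, dx, dy, dir);
      if (x >= 0) E.free_move(id, x);
    } else if (u < a1 + a2) {
      // trapped hop, restricted to same junction
      int i = E.pick_jsv(E.Nb, [&](int q) { return (double)E.bt(q); });
      int dir = (int)(unif_rand() * 4) % 4;
      int cx = i % E.nx + dx[dir], cy = i / E.nx + dy[dir];
      if (cx >= 0 && cx < E.nx && cy >= 0 && cy < E.ny) {
        int to = cx + E.nx * cy;
        if (E.jof[to] == E.jof[i]) {
          int ox = (unif_rand() * E.bt(i) < E.b1[i]) ? 1 : 0;
          E.b_change(i, ox ? 0 : -1, ox ? -1 : 0);
          E.b_change(to, ox ? 0 : 1, ox ? 1 : 0);
        }
      }
    } else if (u < a1 + a2 + a3) {
      // trap: junction ~ stim_j*F_j, sv ~ f, class ~ f0/f1
      double uu = unif_rand() * E.Strap, acc = 0.0;
      int j = -1;
      for (int q = 0; q < E.nj; ++q) {
        if (E.stim[q] < E.spd) continue;
        double w = (double)E.stim[q] * E.Fj[q];
        if (w <= 0) continue;
        j = q; acc += w; if (uu < acc) break;
      }
      if (j >= 0) {
        double u2 = unif_rand() * E.Fj[j], a2c = 0.0;
        int sv = -1;
        for (int q : E.jsvs[j]) {
          int f = E.f0[q] + E.f1[q];
          if (!f) continue;
          sv = q; a2c += f; if (u2 < a2c) break;
        }
        if (sv >= 0) {
          int ox = (unif_rand() * (E.f0[sv] + E.f1[sv]) < E.f1[sv]) ? 1 : 0;
          int id = -1;
          for (int cand : E.svlist[sv]) if (E.d_ox[cand] == ox) { id = cand; break; }
          if (id >= 0) {
            E.free_remove(id); E.dead.push_back(id);
            int oS = E.stim[j]; E.stim[j] -= E.spd; E.strap_update_j(j, oS, E.Fj[j]);
            E.b_change(sv, ox ? 0 : 1, ox ? 1 : 0);
          }
        }
      }
    } else if (u < a1 + a2 + a3 + a4) {
      // untrap
      int i = E.pick_jsv(E.Nb, [&](int q) { return (double)E.bt(q); });
      int ox = (unif_rand() * E.bt(i) < E.b1[i]) ? 1 : 0;
      E.b_change(i, ox ? 0 : -1, ox ? -1 : 0);
      int j = E.jof[i];
      int oS = E.stim[j]; E.stim[j] += E.spd; E.strap_update_j(j, oS, E.Fj[j]);
      E.new_free(i, ox);
    } else if (u < a1 + a2 + a3 + a4 + a5) {
      // dimer + dimer -> tetramer (hypergeometric oxidation draw)
      int i = E.pick_jsv(E.Pdd, [&](int q) { return pairs2(E.bt(q)); });
      int o1 = (unif_rand() * E.bt(i) < E.b1[i]) ? 1 : 0;
      int rem1 = E.b1[i] - o1;
      int o2 = (unif_rand() * (E.bt(i) - 1) < rem1) ? 1 : 0;
      int k = o1 + o2;
      E.b_change(i, -(2 - k), -k);
      E.T_change(i, k, +1);
    } else if (u < a1 + a2 + a3 + a4 + a5 + a6) {
      // tetramer + dimer -> hexamer
      int i = E.pick_jsv(E.Ptd, [&](int q) { return (double)E.Tt(q) * E.bt(q); });
      double uT = unif_rand() * E.Tt(i);
      int k = (uT < E.T0[i]) ? 0 : (uT < E.T0[i] + E.T1[i]) ? 1 : 2;
      int ox = (unif_rand() * E.bt(i) < E.b1[i]) ? 1 : 0;
      E.T_change(i, k, -1);
      E.b_change(i, ox ? 0 : -1, ox ? -1 : 0);
      E.H_change(i, k + ox, +1);
    } else if (u < a1 + a2 + a3 + a4 + a5 + a6 + a7) {
      // tetramer -> 2 trapped dimers (oxidation flags restored)
      int i = E.pick_jsv(E.NT, [&](int q) { return (double)E.Tt(q); });
      double uT = unif_rand() * E.Tt(i);
      int k = (uT < E.T0[i]) ? 0 : (uT < E.T0[i] + E.T1[i]) ? 1 : 2;
      E.T_change(i, k, -1);
      E.b_change(i, 2 - k, k);
    } else {
      // hexamer -> tetramer + trapped dimer
      int i = E.pick_jsv(E.NH, [&](int q) { return (double)E.Ht(q); });
      double uH = unif_rand() * E.Ht(i);
      int k = (uH < E.H0[i]) ? 0 : (uH < E.H0[i] + E.H1[i]) ? 1
              : (uH < E.H0[i] + E.H1[i] + E.H2[i]) ? 2 : 3;
      E.H_change(i, k, -1);
      int rel_ox = (unif_rand() * 3.0 < (double)k) ? 1 : 0;
      E.T_change(i, k - rel_ox, +1);
      E.b_change(i, rel_ox ? 0 : 1, rel_ox ? 1 : 0);
    }

    if (++since_check >= (long)check_every) {
      since_check = 0;
      if (E.monomers() != E.M0)
        stop("mass conservation violated: %ld monomers, expected %ld",
             E.monomers(), E.M0);
    }
  }
  while (record && next_rec <= t_end + 1e-12) { rec_point(next_rec); next_rec += record_dt; }

  if (E.monomers() != E.M0)
    stop("mass conservation violated at end of run");

  // state out
  int nf = E.Nfree;
  IntegerVector o_sv(nf), o_ox(nf);
  for (int q = 0; q < nf; ++q) {
    int id = E.pool[q];
    o_sv[q] = E.d_sv[id] + 1; o_ox[q] = E.d_ox[id];
  }
  List st = List::create(
    _["free_sv"] = o_sv, _["free_ox"] = o_ox,
    _["b0"] = IntegerVector(E.b0.begin(), E.b0.end()),
    _["b1"] = IntegerVector(E.b1.begin(), E.b1.end()),
    _["T0"] = IntegerVector(E.T0.begin(), E.T0.end()),
    _["T1"] = IntegerVector(E.T1.begin(), E.T1.end()),
    _["T2"] = IntegerVector(E.T2.begin(), E.T2.end()),
    _["H0"] = IntegerVector(E.H0.begin(), E.H0.end()),
    _["H1"] = IntegerVector(E.H1.begin(), E.H1.end()),
    _["H2"] = IntegerVector(E.H2.begin(), E.H2.end()),
    _["H3"] = IntegerVector(E.H3.begin(), E.H3.end()),
    _["stim_free"] = IntegerVector(E.stim.begin(), E.stim.end()),
    _["t"] = t);
  List trace = List::create(
    _["t"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["I"] = NumericVector(rec_I.begin(), rec_I.end()),
    _["N_dimer_free"] = IntegerVector(rec_free.begin(), rec_free.end()),
    _["N_dimer_trapped"] = IntegerVector(rec_b.begin(), rec_b.end()),
    _["N_tet"] = IntegerVector(rec_T.begin(), rec_T.end()),
    _["N_hex"] = IntegerVector(rec_H.begin(), rec_H.end()),
    _["N_locked"] = IntegerVector(rec_lock.begin(), rec_lock.end()));
  return List::create(_["state"] = st, _["trace"] = trace,
                      _["n_events"] = n_events);
}

// helper outside class: target sv of a free hop, -1 if blocked (reflective)
static int d_svx_impl(const Engine& E, int id, const int* dx, const int* dy, int dir) {
  int sv = E.d_sv[id];
  int cx = sv % E.nx + dx[dir], cy = sv / E.nx + dy[dir];
  if (cx < 0 || cx >= E.nx || cy < 0 || cy >= E.ny) return -1;
  return cx + E.nx * cy;
}
int d_svx(const Engine& E, int id, const int* dx, const int* dy, int dir) {
  return d_svx_impl(E, id, dx, dy, dir);
}
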