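// Core individual-based engine: zero-sum death--birth cycle on the genetic
// similarity matrix, with incremental maintenance of the compatibility
// graph, species labels and event records.
//
// The random-draw sequence per elementary step is, deliberately, exactly
// the one the pure-R reference engine uses (one uniform for the death, one
// per first-parent draw, acceptance draws for graded viability kinds in
// ascending candidate order, one for the mate), so that both engines
// produce bitwise-identical trajectories from the same R RNG state.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

namespace {

struct EventLog {
  std::vector<int> step, type, mode, label, other, new_size, mother_size;
  std::vector<int> died, p1, p2;
  void add(int st, int ty, int mo, int la, int ot, int ns, int ms,
           int di, int a, int b) {
    step.push_back(st); type.push_back(ty); mode.push_back(mo);
    label.push_back(la); other.push_back(ot);
    new_size.push_back(ns); mother_size.push_back(ms);
    died.push_back(di); p1.push_back(a); p2.push_back(b);
  }
};

inline bool support_ok(double q, double q_min, bool has_qmax, double q_max,
                       int vkind) {
  // vkind: 0 step, 1 range, 2 linear, 3 exponential
  if (vkind == 0) return q >= q_min;
  if (vkind == 1) return q >= q_min && q <= q_max;
  return q > q_min;
}

inline double viability_val(double q, double q_min, double q_max,
                            int vkind, double shape) {
  if (vkind == 0) return q >= q_min ? 1.0 : 0.0;
  if (vkind == 1) return (q >= q_min && q <= q_max) ? 1.0 : 0.0;
  if (vkind == 2) {
    double v = (q - q_min) / (1.0 - q_min);
    return std::max(0.0, std::min(1.0, v));
  }
  double v = 1.0 - std::exp(-shape * std::max(0.0, q - q_min));
  return v / (1.0 - std::exp(-shape * (1.0 - q_min)));
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int N, double mu, double q_min,
                double q_max, bool has_qmax,
                int regime,        // 0 neutral, 1 frequency-dependent
                int vkind,         // 0 step, 1 range, 2 linear, 3 exponential
                double shape,
                int fds_form,      // 0 inverse_degree, 1 linear_deficit
                int n_steps,
                int snapshot_steps,
                List neighbors) {  // R list of integer vectors, or empty
  const double lam = std::exp(-2.0 * mu);

  NumericMatrix Q(N, N);
  std::fill(Q.begin(), Q.end(), 1.0);
  std::vector<unsigned char> spat;
  bool spatial = neighbors.size() > 0;
  if (spatial) {
    spat.assign((size_t)N * N, 0);
    for (int i = 0; i < N; ++i) {
      IntegerVector nb = neighbors[i];
      for (int k = 0; k < nb.size(); ++k)
        spat[(size_t)i * N + nb[k] - 1] = 1;
    }
  }

  // adjacency (flat row-major) + degree, initially complete (all q = 1 >=
  // q_min) unless q_max or spatial restrictions apply
  std::vector<unsigned char> A((size_t)N * N, 0);
  std::vector<int> deg(N, 0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      bool e = support_ok(1.0, q_min, has_qmax, q_max, vkind);
      if (spatial) e = e && spat[(size_t)i * N + j];
      A[(size_t)i * N + j] = e ? 1 : 0;
      if (e) deg[i]++;
    }

  // initial species = connected components of the initial graph (one
  // species for the standard step kind; q_max or a disconnected lattice
  // can fragment the identical founding population)
  std::vector<int> labels(N, 0);
  int next_label = 1;
  std::vector<int> lin_parent(1, 0), lin_origin(1, 0), lin_end(1, NA_INTEGER),
      lin_type(1, 0), lin_into(1, 0);  // type: 0 extant 1 extinct 2 merged
  {
    for (int src = 0; src < N; ++src) {
      if (labels[src] != 0) continue;
      int lab = next_label++;
      lin_parent.push_back(0); lin_origin.push_back(0);
      lin_end.push_back(NA_INTEGER); lin_type.push_back(0);
      lin_into.push_back(0);
      labels[src] = lab;
      std::queue<int> bfs;
      bfs.push(src);
      while (!bfs.empty()) {
        int v = bfs.front(); bfs.pop();
        for (int j = 0; j < N; ++j)
          if (A[(size_t)v * N + j] && labels[j] == 0) {
            labels[j] = lab;
            bfs.push(j);
          }
      }
    }
  }

  EventLog ev;
  std::vector<int> snap_gen;
  std::vector<int> snap_label, snap_size, snap_off;  // flattened
  std::vector<double> snap_qbar;
  int halted = 0;

  std::vector<double> qn(N), w(N), wn(N);
  std::vector<int> members, compid(N), cand;
  std::vector<int> szcount;

  auto count_size = [&](int L) {
    int s = 0;
    for (int j = 0; j < N; ++j) if (labels[j] == L) ++s;
    return s;
  };

  auto new_lineage = [&](int parent, int origin) {
    lin_parent.push_back(parent); lin_origin.push_back(origin);
    lin_end.push_back(NA_INTEGER); lin_type.push_back(0);
    lin_into.push_back(0);
    return next_label++;
  };

  auto take_snapshot = [&](int gen) {
    snap_gen.push_back(gen);
    snap_off.push_back((int)snap_label.size());
    double qs = 0.0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) qs += Q(i, j);
    snap_qbar.push_back(qs / ((double)N * (N - 1) / 2.0));
    std::vector<int> seen;
    for (int j = 0; j < N; ++j) {
      int L = labels[j];
      bool found = false;
      for (size_t k = 0; k < seen.size(); ++k)
        if (seen[k] == L) { found = true; break; }
      if (!found) seen.push_back(L);
    }
    std::sort(seen.begin(), seen.end());
    for (size_t k = 0; k < seen.size(); ++k) {
      snap_label.push_back(seen[k]);
      snap_size.push_back(count_size(seen[k]));
    }
  };

  int step = 0;
  for (step = 1; step <= n_steps; ++step) {
    // --- death sub-step -------------------------------------------------
    double u = unif_rand();
    int die = (int)(u * N);
    if (die >= N) die = N - 1;
    int L = labels[die];
    labels[die] = -1;
    std::vector<int> dn;  // die's former neighbors within its species
    for (int j = 0; j < N; ++j) {
      if (A[(size_t)die * N + j]) {
        deg[j]--;
        A[(size_t)die * N + j] = 0;
        A[(size_t)j * N + die] = 0;
        if (labels[j] == L) dn.push_back(j);
      }
    }
    deg[die] = 0;

    // fission / extinction detection within the dead individual's species
    members.clear();
    for (int j = 0; j < N; ++j) if (labels[j] == L) members.push_back(j);
    if (members.empty()) {
      ev.add(step, 2, 0, L, NA_INTEGER, NA_INTEGER, NA_INTEGER,
             die + 1, NA_INTEGER, NA_INTEGER);
      lin_end[L] = step; lin_type[L] = 1;
    } else if (members.size() > 1 && dn.size() > 1) {
      // The component can only split if the dead node's former neighbors
      // fall apart: BFS from one of them, stopping early once all are
      // reconnected (the common case).
      std::fill(compid.begin(), compid.end(), -1);
      int found = 1;
      compid[dn[0]] = 0;
      {
        std::queue<int> bfs;
        bfs.push(dn[0]);
        while (!bfs.empty() && found < (int)dn.size()) {
          int v = bfs.front(); bfs.pop();
          const unsigned char *row = &A[(size_t)v * N];
          for (int j = 0; j < N; ++j)
            if (row[j] && compid[j] == -1 && labels[j] == L) {
              compid[j] = 0;
              bfs.push(j);
              bool isdn = false;
              for (size_t k2 = 1; k2 < dn.size(); ++k2)
                if (dn[k2] == j) { isdn = true; break; }
              if (isdn) ++found;
            }
        }
      }
      bool split = found < (int)dn.size();
      int ncomp = 0;
      if (split) {
        // full component assignment over the species' members
        std::fill(compid.begin(), compid.end(), -1);
        for (size_t s0 = 0; s0 < members.size(); ++s0) {
          int src = members[s0];
          if (compid[src] != -1) continue;
          compid[src] = ncomp;
          std::queue<int> bfs;
          bfs.push(src);
          while (!bfs.empty()) {
            int v = bfs.front(); bfs.pop();
            const unsigned char *row = &A[(size_t)v * N];
            for (int j = 0; j < N; ++j)
              if (row[j] && compid[j] == -1 && labels[j] == L) {
                compid[j] = ncomp;
                bfs.push(j);
              }
          }
          ++ncomp;
        }
      }
      if (split && ncomp > 1) {
        std::vector<int> sz(ncomp, 0), mn(ncomp, N);
        for (size_t k = 0; k < members.size(); ++k) {
          int c = compid[members[k]];
          sz[c]++;
          if (members[k] < mn[c]) mn[c] = members[k];
        }
        int mother = 0;
        for (int c = 1; c < ncomp; ++c)
          if (sz[c] > sz[mother] ||
              (sz[c] == sz[mother] && mn[c] < mn[mother]))
            mother = c;
        for (int c = 0; c < ncomp; ++c) {
          if (c == mother) continue;
          int nl = new_lineage(L, step);
          for (size_t k = 0; k < members.size(); ++k)
            if (compid[members[k]] == c) labels[members[k]] = nl;
          ev.add(step, 1, 1, nl, L, sz[c], sz[mother],
                 die + 1, NA_INTEGER, NA_INTEGER);
        }
      }
    }

    // --- parent selection ----------------------------------------------
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {
      double wj;
      if (j == die || deg[j] == 0) wj = 0.0;
      else if (regime == 0) wj = 1.0;
      else if (fds_form == 0) wj = 1.0 / (1.0 + deg[j]);
      else wj = (double)(N - deg[j]) / N;
      w[j] = wj;
      tot += wj;
    }
    if (tot == 0.0) { halted = step; break; }
    double S = 0.0;
    for (int j = 0; j < N; ++j) { wn[j] = w[j] / tot; S += wn[j]; }

    int p1 = -1, p2 = -1;
    long guard = 0;
    while (true) {
      if (++guard > 1000000) stop("parent redraw loop did not terminate");
      double u1 = unif_rand() * S;
      double cum = 0.0;
      p1 = N - 1;
      for (int j = 0; j < N; ++j) {
        cum += wn[j];
        if (u1 < cum) { p1 = j; break; }
      }
      cand.clear();
      for (int j = 0; j < N; ++j)
        if (A[(size_t)p1 * N + j]) cand.push_back(j);
      if (vkind >= 2 && !cand.empty()) {
        std::vector<int> kept;
        for (size_t k = 0; k < cand.size(); ++k) {
          double v = viability_val(Q(p1, cand[k]), q_min, q_max, vkind,
                                   shape);
          if (unif_rand() < v) kept.push_back(cand[k]);
        }
        cand.swap(kept);
      }
      if (!cand.empty()) break;
    }
    {
      double u2 = unif_rand();
      int idx = (int)(u2 * cand.size());
      if (idx >= (int)cand.size()) idx = (int)cand.size() - 1;
      p2 = cand[idx];
    }

    // --- birth sub-step -------------------------------------------------
    for (int j = 0; j < N; ++j)
      qn[j] = lam * (Q(p1, j) + Q(p2, j)) / 2.0;
    qn[die] = 1.0;
    for (int j = 0; j < N; ++j) { Q(die, j) = qn[j]; Q(j, die) = qn[j]; }
    Q(die, die) = 1.0;

    for (int j = 0; j < N; ++j) {
      if (j == die) continue;
      bool e = support_ok(qn[j], q_min, has_qmax, q_max, vkind);
      if (spatial) e = e && spat[(size_t)die * N + j];
      if (e) {
        A[(size_t)die * N + j] = 1; A[(size_t)j * N + die] = 1;
        deg[die]++; deg[j]++;
      }
    }

    // species membership of the newborn
    std::vector<int> joined;
    for (int j = 0; j < N; ++j)
      if (A[(size_t)die * N + j]) {
        int Lj = labels[j];
        bool found = false;
        for (size_t k = 0; k < joined.size(); ++k)
          if (joined[k] == Lj) { found = true; break; }
        if (!found) joined.push_back(Lj);
      }
    if (joined.empty()) {
      int mL = labels[p1];
      int msz = count_size(mL);
      int nl = new_lineage(mL, step);
      labels[die] = nl;
      ev.add(step, 1, 2, nl, mL, 1, msz, die + 1, p1 + 1, p2 + 1);
    } else if (joined.size() == 1) {
      labels[die] = joined[0];
    } else {
      // newborn bridges several species: keep the largest (tie: smallest
      // label), retire the rest as bookkeeping merges
      int keep = joined[0], keepsz = count_size(joined[0]);
      for (size_t k = 1; k < joined.size(); ++k) {
        int sz = count_size(joined[k]);
        if (sz > keepsz || (sz == keepsz && joined[k] < keep)) {
          keep = joined[k]; keepsz = sz;
        }
      }
      std::sort(joined.begin(), joined.end());
      for (size_t k = 0; k < joined.size(); ++k) {
        int L2 = joined[k];
        if (L2 == keep) continue;
        int sz = count_size(L2);
        ev.add(step, 3, 0, L2, keep, sz, keepsz,
               die + 1, p1 + 1, p2 + 1);
        for (int j = 0; j < N; ++j) if (labels[j] == L2) labels[j] = keep;
        lin_end[L2] = step; lin_type[L2] = 2; lin_into[L2] = keep;
      }
      labels[die] = keep;
    }

    if (snapshot_steps > 0 && step % snapshot_steps == 0)
      take_snapshot(step / snapshot_steps);
  }
  if (halted > 0) {
    // restore a consistent label for the empty slot: none — report as-is
  }

  int snaps = (int)snap_gen.size();
  snap_off.push_back((int)snap_label.size());

  int nlab = next_label - 1;
  IntegerVector lparent(nlab), lorigin(nlab), lend(nlab), ltype(nlab),
      linto(nlab);
  for (int k = 1; k <= nlab; ++k) {
    lparent[k - 1] = lin_parent[k];
    lorigin[k - 1] = lin_origin[k];
    lend[k - 1] = lin_end[k];
    ltype[k - 1] = lin_type[k];
    linto[k - 1] = lin_into[k];
  }

  return List::create(
    _["events"] = List::create(
      _["step"] = wrap(ev.step), _["type"] = wrap(ev.type),
      _["mode"] = wrap(ev.mode), _["label"] = wrap(ev.label),
      _["other"] = wrap(ev.other), _["new_size"] = wrap(ev.new_size),
      _["mother_size"] = wrap(ev.mother_size), _["died"] = wrap(ev.died),
      _["p1"] = wrap(ev.p1), _["p2"] = wrap(ev.p2)),
    _["labels"] = wrap(labels),
    _["q"] = Q,
    _["lineage"] = List::create(
      _["label"] = seq(1, nlab), _["parent"] = lparent,
      _["origin_step"] = lorigin, _["end_step"] = lend,
      _["end_type"] = ltype, _["merged_into"] = linto),
    _["snap_gen"] = wrap(snap_gen),
    _["snap_qbar"] = wrap(snap_qbar),
    _["snap_label"] = wrap(snap_label),
    _["snap_size"] = wrap(snap_size),
    _["snap_off"] = wrap(snap_off),
    _["halted"] = halted,
    _["steps_done"] = (halted > 0 ? halted : n_steps));
}
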