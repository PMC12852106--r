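#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structural controllability reduces to maximum matching on the bipartite
// "out-copy / in-copy" representation of a directed graph: edge u -> v becomes
// (u+, v-).  A matching here is an edge set in which no two edges share a
// source or share a target.  Kuhn's augmenting-path algorithm; deterministic
// for a fixed edge order.

namespace {

struct Matcher {
  int n;
  std::vector<int> esrc, etgt;              // 0-based endpoints per edge
  std::vector<std::vector<int>> adj, radj;  // edge ids by source / by target
  std::vector<int> ms, mt;                  // matched edge id per copy, -1 free
  std::vector<int> vis;
  int stamp;
  std::vector<char> edead;
  int src_dead, tgt_dead;                   // at most one deleted copy per side

  Matcher(int n_, const IntegerVector& s, const IntegerVector& t)
      : n(n_), stamp(0), src_dead(-1), tgt_dead(-1) {
    int L = s.size();
    esrc.resize(L);
    etgt.resize(L);
    adj.assign(n, {});
    radj.assign(n, {});
    for (int e = 0; e < L; ++e) {
      esrc[e] = s[e] - 1;
      etgt[e] = t[e] - 1;
      adj[esrc[e]].push_back(e);
      radj[etgt[e]].push_back(e);
    }
    ms.assign(n, -1);
    mt.assign(n, -1);
    vis.assign(n, -1);
    edead.assign(L, 0);
  }

  // alternating-path search from a free out-copy u+
  bool augment(int u) {
    vis[u] = stamp;
    for (int e : adj[u]) {
      if (edead[e]) continue;
      int v = etgt[e];
      if (v == tgt_dead) continue;
      if (mt[v] == -1) {
        mt[v] = e;
        ms[u] = e;
        return true;
      }
    }
    for (int e : adj[u]) {
      if (edead[e]) continue;
      int v = etgt[e];
      if (v == tgt_dead) continue;
      int u2 = esrc[mt[v]];
      if (u2 != src_dead && vis[u2] != stamp && augment(u2)) {
        mt[v] = e;
        ms[u] = e;
        return true;
      }
    }
    return false;
  }

  // mirror search from a free in-copy v-
  bool augment_from_target(int v) {
    vis[v] = stamp;
    for (int e : radj[v]) {
      if (edead[e]) continue;
      int u = esrc[e];
      if (u == src_dead) continue;
      if (ms[u] == -1) {
        ms[u] = e;
        mt[v] = e;
        return true;
      }
    }
    for (int e : radj[v]) {
      if (edead[e]) continue;
      int u = esrc[e];
      if (u == src_dead) continue;
      int v2 = etgt[ms[u]];
      if (v2 != tgt_dead && vis[v2] != stamp && augment_from_target(v2)) {
        ms[u] = e;
        mt[v] = e;
        return true;
      }
    }
    return false;
  }

  int max_matching() {
    int m = 0;
    for (int u = 0; u < n; ++u) {
      if (ms[u] == -1 && !adj[u].empty()) {
        ++stamp;
        if (augment(u)) ++m;
      }
    }
    return m;
  }
};

}  // namespace

// [[Rcpp::export]]
List max_matching_cpp(int n, IntegerVector src, IntegerVector tgt) {
  Matcher M(n, src, tgt);
  int m = M.max_matching();
  IntegerVector ms(n), mt(n);
  for (int i = 0; i < n; ++i) {
    ms[i] = M.ms[i] + 1;  // 1-based edge id, 0 = unmatched
    mt[i] = M.mt[i] + 1;
  }
  return List::create(_["size"] = m,
                      _["match_from_source"] = ms,
                      _["match_into_target"] = mt);
}

// Labels: 1 = critical (removal raises the driver count), 2 = redundant
// (member of no maximum matching), 3 = ordinary.  Tested per edge against a
// frozen maximum matching M*:
//   * e in M*: delete e and search for one augmenting path from the freed
//     source u+ and, failing that, from the freed target v- (a replacement
//     path may end at v- without touching u+); if neither exists |M| drops by
//     one, which raises N_D unless the matching was already perfect
//     (driver-count floor of 1).
//   * e = (u, v) not in M*: delete the copies u+ and v-.  The maximum matching
//     of the remainder is m - 1 when e lies in some maximum matching and m - 2
//     when it lies in none.  Starting from M* minus the (at most two) matched
//     edges incident to the deleted copies, every augmenting path must end at
//     one of the freed partner copies, so one search per freed copy restores
//     maximality.
// [[Rcpp::export]]
List classify_edges_cpp(int n, IntegerVector src, IntegerVector tgt) {
  Matcher M(n, src, tgt);
  int m = M.max_matching();
  int L = src.size();
  std::vector<int> ms0 = M.ms, mt0 = M.mt;
  IntegerVector label(L);

  for (int e = 0; e < L; ++e) {
    int u = M.esrc[e], v = M.etgt[e];
    if (ms0[u] == e) {
      M.edead[e] = 1;
      M.ms[u] = -1;
      M.mt[v] = -1;
      ++M.stamp;
      bool restored = M.augment(u);
      if (!restored) {
        ++M.stamp;
        restored = M.augment_from_target(v);
      }
      M.edead[e] = 0;
      M.ms = ms0;
      M.mt = mt0;
      label[e] = (!restored && n - m >= 1) ? 1 : 3;
    } else {
      M.src_dead = u;
      M.tgt_dead = v;
      int removed = 0;
      int eA = M.ms[u], eB = M.mt[v];
      int freed_tgt = -1, freed_src = -1;
      if (eA != -1) {
        freed_tgt = M.etgt[eA];
        M.ms[u] = -1;
        M.mt[freed_tgt] = -1;
        ++removed;
      }
      if (eB != -1) {
        freed_src = M.esrc[eB];
        M.ms[freed_src] = -1;
        M.mt[v] = -1;
        ++removed;
      }
      if (freed_src != -1 && M.ms[freed_src] == -1) {
        ++M.stamp;
        if (M.augment(freed_src)) --removed;
      }
      if (freed_tgt != -1 && M.mt[freed_tgt] == -1) {
        ++M.stamp;
        if (M.augment_from_target(freed_tgt)) --removed;
      }
      // maximum matching avoiding u+ and v- has size m - removed
      label[e] = (removed == 2) ? 2 : 3;
      M.src_dead = -1;
      M.tgt_dead = -1;
      M.ms = ms0;
      M.mt = mt0;
    }
  }
  return List::create(_["labels"] = label, _["matching_size"] = m);
}
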