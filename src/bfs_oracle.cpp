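// Bidirectional breadth-first search over restricted DCJ-indel scenarios.
//
// States are genomes over relabeled integer markers: matched pairs share an
// id, unmatched (singular) markers have unique ids. A shortest scenario
// A -> B of DCJs, deletions of singular segments and insertions of singular
// segments can be reordered so that every deletion precedes every insertion
// (no marker is both inserted and deleted in an optimal scenario, and a
// deletion commutes backwards past operations on disjoint material). Read
// backwards, the insertion suffix is a deletion prefix from B. The search
// therefore runs two deletion-plus-DCJ searches, one from each genome, and
// meets at genomes over matched markers only; insertions never have to be
// enumerated. States are canonicalized (linear chromosomes up to reversal,
// circular ones up to rotation and reversal, chromosome order ignored)
// before hashing.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <functional>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;
using std::string;
using std::vector;

struct Chrom {
  bool circ;
  vector<int> seq;  // signed marker ids
};
typedef vector<Chrom> State;

static vector<int> revneg(const vector<int>& v) {
  vector<int> r(v.rbegin(), v.rend());
  for (auto& x : r) x = -x;
  return r;
}

static vector<int> canon_linear(const vector<int>& v) {
  vector<int> r = revneg(v);
  return std::min(v, r);
}

static vector<int> canon_circular(const vector<int>& v) {
  int k = (int)v.size();
  vector<int> best;
  vector<int> cur(k);
  for (int dir = 0; dir < 2; dir++) {
    vector<int> base = dir ? revneg(v) : v;
    for (int r = 0; r < k; r++) {
      for (int i = 0; i < k; i++) cur[i] = base[(r + i) % k];
      if (best.empty() || cur < best) best = cur;
    }
  }
  return best;
}

static bool chrom_less(const Chrom& x, const Chrom& y) {
  if (x.circ != y.circ) return x.circ < y.circ;
  return x.seq < y.seq;
}

static State canon_state(const State& s) {
  State c;
  c.reserve(s.size());
  for (const auto& ch : s) {
    Chrom n;
    n.circ = ch.circ;
    n.seq = ch.circ ? canon_circular(ch.seq) : canon_linear(ch.seq);
    c.push_back(n);
  }
  std::sort(c.begin(), c.end(), chrom_less);
  return c;
}

static string state_key(const State& s) {
  string k;
  for (const auto& ch : s) {
    k += ch.circ ? 'C' : 'L';
    for (int x : ch.seq) {
      k += std::to_string(x);
      k += ',';
    }
    k += ';';
  }
  return k;
}

// extremity codes: tail of marker m -> 2m, head -> 2m+1
static void adj_of(const State& s, std::unordered_map<int, int>& adj,
                   vector<int>& tel, vector<int>& markers) {
  for (const auto& ch : s) {
    int k = (int)ch.seq.size();
    vector<int> L(k), R(k);
    for (int i = 0; i < k; i++) {
      int m = std::abs(ch.seq[i]);
      markers.push_back(m);
      L[i] = ch.seq[i] > 0 ? 2 * m : 2 * m + 1;
      R[i] = ch.seq[i] > 0 ? 2 * m + 1 : 2 * m;
    }
    for (int i = 0; i + 1 < k; i++) {
      adj[R[i]] = L[i + 1];
      adj[L[i + 1]] = R[i];
    }
    if (ch.circ) {
      adj[R[k - 1]] = L[0];
      adj[L[0]] = R[k - 1];
    } else {
      tel.push_back(L[0]);
      tel.push_back(R[k - 1]);
    }
  }
}

static State rebuild(const vector<int>& markers,
                     const std::unordered_map<int, int>& adj) {
  State out;
  std::unordered_set<int> seen;
  for (int m : markers) {
    for (int e : {2 * m, 2 * m + 1}) {
      if (seen.count(e) || adj.count(e)) continue;
      Chrom ch;
      ch.circ = false;
      int cur = e;
      while (true) {
        int mm = cur / 2;
        bool tail = (cur % 2 == 0);
        ch.seq.push_back(tail ? mm : -mm);
        seen.insert(cur);
        int other = tail ? cur + 1 : cur - 1;
        seen.insert(other);
        auto it = adj.find(other);
        if (it == adj.end()) break;
        cur = it->second;
      }
      out.push_back(ch);
    }
  }
  for (int m : markers) {
    int e = 2 * m;
    if (seen.count(e)) continue;
    Chrom ch;
    ch.circ = true;
    int cur = e;
    while (!seen.count(cur)) {
      int mm = cur / 2;
      bool tail = (cur % 2 == 0);
      ch.seq.push_back(tail ? mm : -mm);
      seen.insert(cur);
      int other = tail ? cur + 1 : cur - 1;
      seen.insert(other);
      cur = adj.at(other);
    }
    out.push_back(ch);
  }
  return out;
}

typedef std::function<void(const State&)> Emit;

// all DCJ results (Def. 3: two-adjacency recombinations, single cut,
// adjacency-telomere exchange, telomere join)
static void dcj_successors(const State& s, const Emit& emit) {
  std::unordered_map<int, int> adj;
  vector<int> tel, markers;
  adj_of(s, adj, tel, markers);
  vector<std::pair<int, int>> edges;
  for (const auto& kv : adj)
    if (kv.first < kv.second) edges.push_back({kv.first, kv.second});
  std::sort(edges.begin(), edges.end());
  std::sort(tel.begin(), tel.end());

  auto apply = [&](const vector<std::pair<int, int>>& rm,
                   const vector<std::pair<int, int>>& addv) {
    std::unordered_map<int, int> a2(adj);
    for (const auto& e : rm) {
      a2.erase(e.first);
      a2.erase(e.second);
    }
    for (const auto& e : addv) {
      a2[e.first] = e.second;
      a2[e.second] = e.first;
    }
    emit(rebuild(markers, a2));
  };

  int ne = (int)edges.size(), nt = (int)tel.size();
  for (int i = 0; i < ne; i++) {
    int a = edges[i].first, b = edges[i].second;
    for (int j = i + 1; j < ne; j++) {
      int c = edges[j].first, d = edges[j].second;
      apply({{a, b}, {c, d}}, {{a, c}, {b, d}});
      apply({{a, b}, {c, d}}, {{a, d}, {b, c}});
    }
    apply({{a, b}}, {});  // ab -> a, b
    for (int t = 0; t < nt; t++) {
      int sx = tel[t];
      apply({{a, b}}, {{a, sx}});  // ab,s -> as,b
      apply({{a, b}}, {{b, sx}});  // ab,s -> bs,a
    }
  }
  for (int i = 0; i < nt; i++)
    for (int j = i + 1; j < nt; j++)
      apply({}, {{tel[i], tel[j]}});  // s,t -> st
}

static bool is_singular(int signed_m, const std::unordered_set<int>& sing) {
  return sing.count(std::abs(signed_m)) > 0;
}

// deletions of contiguous all-singular segments: linear runs and their
// sub-segments, wrapped circular runs, and whole all-singular chromosomes
// (a circular or linear singleton removed in one indel)
static void deletion_successors(const State& s,
                                const std::unordered_set<int>& sing,
                                const Emit& emit) {
  for (size_t ci = 0; ci < s.size(); ci++) {
    const Chrom& ch = s[ci];
    int k = (int)ch.seq.size();
    auto emit_removed = [&](int start, int len) {
      State nxt;
      for (size_t cj = 0; cj < s.size(); cj++)
        if (cj != ci) nxt.push_back(s[cj]);
      if (len < k) {
        Chrom rem;
        rem.circ = ch.circ;
        if (!ch.circ) {
          for (int i = 0; i < k; i++)
            if (i < start || i >= start + len) rem.seq.push_back(ch.seq[i]);
        } else {
          for (int i = 0; i < k - len; i++)
            rem.seq.push_back(ch.seq[(start + len + i) % k]);
        }
        nxt.push_back(rem);
      }
      emit(nxt);
    };
    if (!ch.circ) {
      for (int i = 0; i < k; i++) {
        if (!is_singular(ch.seq[i], sing)) continue;
        for (int j = i; j < k && is_singular(ch.seq[j], sing); j++)
          emit_removed(i, j - i + 1);
      }
    } else {
      bool all_sing = true;
      for (int i = 0; i < k; i++)
        if (!is_singular(ch.seq[i], sing)) {
          all_sing = false;
          break;
        }
      if (all_sing) emit_removed(0, k);
      for (int i = 0; i < k; i++) {
        if (!is_singular(ch.seq[i], sing)) continue;
        for (int len = 1; len < k; len++) {
          if (!is_singular(ch.seq[(i + len - 1) % k], sing)) break;
          emit_removed(i, len);
        }
      }
    }
  }
}

static State states_from_r(List seqs, LogicalVector circ) {
  State st;
  for (int i = 0; i < seqs.size(); i++) {
    Chrom ch;
    ch.circ = circ[i];
    IntegerVector v = seqs[i];
    ch.seq.assign(v.begin(), v.end());
    st.push_back(ch);
  }
  return st;
}

// [[Rcpp::export(name = ".bfs_core")]]
int bfs_core(List a_seqs, LogicalVector a_circ, List b_seqs,
             LogicalVector b_circ, IntegerVector sing_a, IntegerVector sing_b,
             int max_states, int max_depth) {
  State A = canon_state(states_from_r(a_seqs, a_circ));
  State B = canon_state(states_from_r(b_seqs, b_circ));
  std::unordered_set<int> singA(sing_a.begin(), sing_a.end());
  std::unordered_set<int> singB(sing_b.begin(), sing_b.end());

  string keyA = state_key(A), keyB = state_key(B);
  if (keyA == keyB) return 0;

  // dist maps and frontiers for both directions
  std::unordered_map<string, int> dist[2];
  vector<State> frontier[2];
  const std::unordered_set<int>* sing[2] = {&singA, &singB};
  dist[0][keyA] = 0;
  dist[1][keyB] = 0;
  frontier[0].push_back(A);
  frontier[1].push_back(B);
  int depth[2] = {0, 0};
  int best = INT_MAX;
  bool capped = false;

  while (!frontier[0].empty() || !frontier[1].empty()) {
    int side;
    if (frontier[0].empty()) side = 1;
    else if (frontier[1].empty()) side = 0;
    else side = frontier[0].size() <= frontier[1].size() ? 0 : 1;
    // a state first reached from this side at depth+1 can only take part in
    // meetings of total cost >= depth+1, so once that reaches the incumbent
    // the side is done (the other side still probes this side's map)
    if (best != INT_MAX && depth[side] + 1 >= best) {
      frontier[side].clear();
      continue;
    }
    if (depth[side] >= max_depth) {
      capped = true;  // exploration truncated: only trust an early meeting
      frontier[side].clear();
      continue;
    }
    depth[side]++;
    int d_new = depth[side];
    vector<State> next;
    Emit emit = [&](const State& raw) {
      State cc = canon_state(raw);
      string key = state_key(cc);
      auto it = dist[side].find(key);
      if (it != dist[side].end()) return;
      if ((int)(dist[0].size() + dist[1].size()) >= max_states) {
        capped = true;
        return;
      }
      dist[side][key] = d_new;
      auto ot = dist[1 - side].find(key);
      if (ot != dist[1 - side].end())
        best = std::min(best, d_new + ot->second);
      next.push_back(cc);
    };
    for (const State& cur : frontier[side]) {
      dcj_successors(cur, emit);
      deletion_successors(cur, *sing[side], emit);
    }
    frontier[side] = std::move(next);
    if (capped) return -1;
    // everything still undiscovered on this side has distance > depth[side];
    // both searches are exhausted below, so best is exact on termination
  }
  if (best == INT_MAX) return capped ? -1 : -2;
  // under truncation, any undiscovered meeting is missing from at least one
  // map and so costs more than that side's completed depth
  if (capped && best > std::min(depth[0], depth[1])) return -1;
  return best;
}
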