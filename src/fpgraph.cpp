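// Graph primitives for fingerprinting: bridge detection, SSSR ring
// perception, linear-path enumeration (substructure fingerprint) and
// iterative circular-environment hashing (extended-connectivity
// fingerprint). Molecules are small (tens of atoms), so simple exact
// algorithms are used throughout.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// FNV-1a 32-bit: the documented stable hash used for all bit assignments.
static inline uint32_t fnv1a(const unsigned char* data, size_t n,
                             uint32_t h = 2166136261u) {
  for (size_t i = 0; i < n; ++i) {
    h ^= data[i];
    h *= 16777619u;
  }
  return h;
}

static inline uint32_t fnv1a_str(const std::string& s) {
  return fnv1a(reinterpret_cast<const unsigned char*>(s.data()), s.size());
}

static inline uint32_t fnv1a_ints(const std::vector<uint32_t>& v) {
  return fnv1a(reinterpret_cast<const unsigned char*>(v.data()),
               v.size() * sizeof(uint32_t));
}

// ---------------------------------------------------------------------------
// Adjacency helper
// ---------------------------------------------------------------------------
struct Graph {
  int n;
  std::vector<std::vector<int>> adj;       // neighbour atom (0-based)
  std::vector<std::vector<int>> adj_edge;  // parallel: edge index (0-based)
  Graph(int n_, const IntegerVector& from, const IntegerVector& to)
      : n(n_), adj(n_), adj_edge(n_) {
    for (int e = 0; e < from.size(); ++e) {
      int a = from[e] - 1, b = to[e] - 1;
      adj[a].push_back(b);
      adj_edge[a].push_back(e);
      adj[b].push_back(a);
      adj_edge[b].push_back(e);
    }
  }
};

// ---------------------------------------------------------------------------
// Bridges (an edge is cyclic iff it is not a bridge)
// ---------------------------------------------------------------------------
static void bridge_dfs(const Graph& g, int u, int parent_edge, int& timer,
                       std::vector<int>& tin, std::vector<int>& low,
                       std::vector<bool>& is_bridge) {
  tin[u] = low[u] = timer++;
  for (size_t i = 0; i < g.adj[u].size(); ++i) {
    int v = g.adj[u][i], e = g.adj_edge[u][i];
    if (e == parent_edge) continue;
    if (tin[v] != -1) {
      low[u] = std::min(low[u], tin[v]);
    } else {
      bridge_dfs(g, v, e, timer, tin, low, is_bridge);
      low[u] = std::min(low[u], low[v]);
      if (low[v] > tin[u]) is_bridge[e] = true;
    }
  }
}

// ---------------------------------------------------------------------------
// SSSR: candidate cycles are the shortest cycle through each non-bridge
// edge (BFS with that edge removed); a linearly independent subset over
// GF(2) of size E - V + C is retained, smallest rings first.
// ---------------------------------------------------------------------------
typedef std::vector<uint64_t> EdgeSet;

static inline void eset_flip(EdgeSet& s, int e) { s[e >> 6] ^= (1ull << (e & 63)); }
static inline bool eset_empty(const EdgeSet& s) {
  for (uint64_t w : s)
    if (w) return false;
  return true;
}
static inline int eset_low(const EdgeSet& s) {
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i]) {
      uint64_t w = s[i];
      int b = 0;
      while (!(w & 1)) { w >>= 1; ++b; }
      return static_cast<int>(i) * 64 + b;
    }
  return -1;
}

// [[Rcpp::export]]
List cpp_ring_info(int natoms, IntegerVector bond_from, IntegerVector bond_to) {
  int ne = bond_from.size();
  Graph g(natoms, bond_from, bond_to);

  std::vector<bool> is_bridge(ne, false);
  std::vector<int> tin(natoms, -1), low(natoms, -1), comp(natoms, -1);
  int timer = 0, ncomp = 0;
  for (int s = 0; s < natoms; ++s)
    if (tin[s] == -1) {
      bridge_dfs(g, s, -1, timer, tin, low, is_bridge);
      ++ncomp;
    }

  int rank = ne - natoms + ncomp;  // circuit rank = number of SSSR rings
  int words = (ne + 63) / 64;

  // candidate cycles: (size, edge set)
  std::vector<std::pair<int, EdgeSet>> cand;
  for (int e = 0; e < ne; ++e) {
    if (is_bridge[e]) continue;
    int u = bond_from[e] - 1, v = bond_to[e] - 1;
    // BFS u -> v avoiding edge e
    std::vector<int> prev_edge(natoms, -2), prev_node(natoms, -1);
    std::vector<int> queue_;
    queue_.push_back(u);
    prev_edge[u] = -1;
    for (size_t qi = 0; qi < queue_.size() && prev_edge[v] == -2; ++qi) {
      int x = queue_[qi];
      for (size_t i = 0; i < g.adj[x].size(); ++i) {
        int y = g.adj[x][i], ee = g.adj_edge[x][i];
        if (ee == e || prev_edge[y] != -2) continue;
        prev_edge[y] = ee;
        prev_node[y] = x;
        queue_.push_back(y);
      }
    }
    if (prev_edge[v] == -2) continue;  // parallel-edge safety
    EdgeSet es(words, 0);
    int size = 1;
    eset_flip(es, e);
    for (int x = v; x != u; x = prev_node[x]) {
      eset_flip(es, prev_edge[x]);
      ++size;
    }
    cand.push_back(std::make_pair(size, es));
  }
  std::stable_sort(cand.begin(), cand.end(),
                   [](const std::pair<int, EdgeSet>& a,
                      const std::pair<int, EdgeSet>& b) { return a.first < b.first; });

  // GF(2) elimination: keep independent cycles until the rank is reached
  std::vector<EdgeSet> basis;      // reduced rows
  std::vector<EdgeSet> kept_sets;  // original (unreduced) kept rings
  std::vector<int> kept_sizes;
  for (size_t c = 0; c < cand.size() && (int)kept_sets.size() < rank; ++c) {
    EdgeSet row = cand[c].second;
    for (const EdgeSet& b : basis) {
      int p = eset_low(b);
      if (p >= 0 && (row[p >> 6] >> (p & 63)) & 1)
        for (int w = 0; w < words; ++w) row[w] ^= b[w];
    }
    if (!eset_empty(row)) {
      basis.push_back(row);
      kept_sets.push_back(cand[c].second);
      kept_sizes.push_back(cand[c].first);
    }
  }

  IntegerVector ring_sizes(kept_sizes.begin(), kept_sizes.end());
  IntegerVector atom_rings(natoms, 0), bond_rings(ne, 0);
  for (const EdgeSet& es : kept_sets) {
    std::vector<bool> atom_hit(natoms, false);
    for (int e = 0; e < ne; ++e)
      if ((es[e >> 6] >> (e & 63)) & 1) {
        bond_rings[e]++;
        atom_hit[bond_from[e] - 1] = true;
        atom_hit[bond_to[e] - 1] = true;
      }
    for (int a = 0; a < natoms; ++a)
      if (atom_hit[a]) atom_rings[a]++;
  }

  LogicalVector bond_cyclic(ne);
  for (int e = 0; e < ne; ++e) bond_cyclic[e] = !is_bridge[e];

  return List::create(Named("ring_sizes") = ring_sizes,
                      Named("atom_rings") = atom_rings,
                      Named("bond_rings") = bond_rings,
                      Named("bond_cyclic") = bond_cyclic);
}

// ---------------------------------------------------------------------------
// Substructure path fingerprint: all simple linear atom-bond paths of
// 0..max_len bonds; each path token string (orientation-canonical) is
// hashed to one of nbits positions.
// ---------------------------------------------------------------------------
static void sfp_dfs(const Graph& g, const std::vector<std::string>& atok,
                    const std::vector<std::string>& btok,
                    std::vector<int>& path_atoms, std::vector<int>& path_edges,
                    std::vector<bool>& visited, int max_len,
                    std::vector<int>& bits, int nbits) {
  // emit current path
  std::string fwd, rev;
  int m = path_atoms.size();
  for (int i = 0; i < m; ++i) {
    fwd += atok[path_atoms[i]];
    if (i < m - 1) fwd += btok[path_edges[i]];
  }
  for (int i = m - 1; i >= 0; --i) {
    rev += atok[path_atoms[i]];
    if (i > 0) rev += btok[path_edges[i - 1]];
  }
  const std::string& canon = (fwd <= rev) ? fwd : rev;
  bits[fnv1a_str(canon) % nbits] = 1;

  if ((int)path_edges.size() >= max_len) return;
  int u = path_atoms.back();
  for (size_t i = 0; i < g.adj[u].size(); ++i) {
    int v = g.adj[u][i];
    if (visited[v]) continue;
    visited[v] = true;
    path_atoms.push_back(v);
    path_edges.push_back(g.adj_edge[u][i]);
    sfp_dfs(g, atok, btok, path_atoms, path_edges, visited, max_len, bits, nbits);
    path_atoms.pop_back();
    path_edges.pop_back();
    visited[v] = false;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_sfp(CharacterVector atom_tokens, IntegerVector bond_from,
                      IntegerVector bond_to, IntegerVector bond_order,
                      int max_len, int nbits) {
  int n = atom_tokens.size();
  Graph g(n, bond_from, bond_to);
  std::vector<std::string> atok(n);
  for (int i = 0; i < n; ++i) atok[i] = as<std::string>(atom_tokens[i]);
  std::vector<std::string> btok(bond_order.size());
  for (int e = 0; e < bond_order.size(); ++e) {
    switch (bond_order[e]) {
      case 2: btok[e] = "="; break;
      case 3: btok[e] = "#"; break;
      default: btok[e] = "-";
    }
  }
  std::vector<int> bits(nbits, 0);
  std::vector<bool> visited(n, false);
  std::vector<int> pa, pe;
  for (int s = 0; s < n; ++s) {
    visited[s] = true;
    pa.push_back(s);
    sfp_dfs(g, atok, btok, pa, pe, visited, max_len, bits, nbits);
    pa.pop_back();
    visited[s] = false;
  }
  return IntegerVector(bits.begin(), bits.end());
}

// ---------------------------------------------------------------------------
// Extended-connectivity fingerprint: invariant rows are hashed to the
// radius-0 identifiers, then updated radius by radius from sorted
// (bond code, neighbour identifier) pairs. An atom whose environment
// does not grow at a radius emits no new identifier (methane rule).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_ecfp(IntegerMatrix invariants, IntegerVector bond_from,
                       IntegerVector bond_to, IntegerVector bond_code,
                       int radius, int nbits) {
  int n = invariants.nrow();
  Graph g(n, bond_from, bond_to);
  std::vector<int> bits(nbits, 0);

  std::vector<uint32_t> id(n);
  for (int a = 0; a < n; ++a) {
    std::vector<uint32_t> row;
    row.push_back(0u);  // radius tag
    for (int j = 0; j < invariants.ncol(); ++j)
      row.push_back(static_cast<uint32_t>(invariants(a, j)));
    id[a] = fnv1a_ints(row);
    bits[id[a] % nbits] = 1;
  }

  int words = (n + 63) / 64;
  std::vector<std::vector<uint64_t>> env(n, std::vector<uint64_t>(words, 0));
  for (int a = 0; a < n; ++a) env[a][a >> 6] |= (1ull << (a & 63));

  for (int r = 1; r <= radius; ++r) {
    std::vector<uint32_t> new_id(n);
    std::vector<std::vector<uint64_t>> new_env(n);
    std::vector<bool> grew(n);
    for (int a = 0; a < n; ++a) {
      std::vector<std::pair<uint32_t, uint32_t>> nb;
      std::vector<uint64_t> e = env[a];
      for (size_t i = 0; i < g.adj[a].size(); ++i) {
        int v = g.adj[a][i];
        nb.push_back(std::make_pair(
            static_cast<uint32_t>(bond_code[g.adj_edge[a][i]]), id[v]));
        for (int w = 0; w < words; ++w) e[w] |= env[v][w];
      }
      std::sort(nb.begin(), nb.end());
      std::vector<uint32_t> row;
      row.push_back(static_cast<uint32_t>(r));
      row.push_back(id[a]);
      for (auto& p : nb) {
        row.push_back(p.first);
        row.push_back(p.second);
      }
      new_id[a] = fnv1a_ints(row);
      grew[a] = (e != env[a]);
      new_env[a] = e;
    }
    for (int a = 0; a < n; ++a) {
      if (grew[a]) {
        id[a] = new_id[a];
        bits[id[a] % nbits] = 1;
      }
      env[a] = new_env[a];
    }
  }
  return IntegerVector(bits.begin(), bits.end());
}
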