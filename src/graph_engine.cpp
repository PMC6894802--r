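// Core graph engine for binary (0/1, undirected, simple) networks.
//
// Everything here operates on plain edge lists (1-based, as handed over from
// R) so that the permutation loops never pay per-call graph-object
// construction costs. Adjacency is kept both as bitset rows (word-parallel
// BFS and triangle counting) and, where needed, as adjacency lists
// (Brandes, union-find resilience). All randomness is drawn through an
// xorshift128+ stream seeded from R's RNG, so set.seed() upstream fully
// determines results.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xorshift128+, seeded from R's RNG stream
// ---------------------------------------------------------------------------
struct XRng {
  uint64_t s0, s1;
  XRng() {
    uint64_t z = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                  (uint64_t)(unif_rand() * 4294967296.0);
    s0 = splitmix(z);
    s1 = splitmix(z);
    if (!(s0 | s1)) s0 = 0x9E3779B97F4A7C15ULL;
  }
  static uint64_t splitmix(uint64_t& z) {
    z += 0x9E3779B97F4A7C15ULL;
    uint64_t x = z;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in [0, n) by 32-bit multiply-shift (no division)
  static inline int reduce32(uint32_t x, int n) {
    return (int)(((uint64_t)x * (uint64_t)n) >> 32);
  }
  inline int below(int n) { return reduce32((uint32_t)(next() >> 32), n); }
};

// ---------------------------------------------------------------------------
// Bitset adjacency
// ---------------------------------------------------------------------------
struct Bits {
  int n, W;
  std::vector<uint64_t> b;
  Bits(int n_) : n(n_), W((n_ + 63) >> 6), b((size_t)n_ * ((n_ + 63) >> 6), 0) {}
  inline uint64_t* row(int i) { return &b[(size_t)i * W]; }
  inline const uint64_t* row(int i) const { return &b[(size_t)i * W]; }
  inline bool has(int i, int j) const { return (row(i)[j >> 6] >> (j & 63)) & 1ULL; }
  inline void set(int i, int j) {
    row(i)[j >> 6] |= 1ULL << (j & 63);
    row(j)[i >> 6] |= 1ULL << (i & 63);
  }
  inline void clear(int i, int j) {
    row(i)[j >> 6] &= ~(1ULL << (j & 63));
    row(j)[i >> 6] &= ~(1ULL << (i & 63));
  }
};

static void edges_from_matrix(const IntegerMatrix& e, int m,
                              std::vector<int>& eu, std::vector<int>& ev) {
  eu.resize(m); ev.resize(m);
  for (int k = 0; k < m; ++k) { eu[k] = e(k, 0) - 1; ev[k] = e(k, 1) - 1; }
}

static void fill_bits(Bits& g, const std::vector<int>& eu, const std::vector<int>& ev, int m) {
  for (int k = 0; k < m; ++k) g.set(eu[k], ev[k]);
}

// ---------------------------------------------------------------------------
// Bitset BFS from s restricted to `mask`; accumulates distance statistics.
// ---------------------------------------------------------------------------
static inline void bfs_stats(const Bits& g, int s, const uint64_t* mask,
                             uint64_t* visited, uint64_t* frontier, uint64_t* nxt,
                             double& sum_d, int& cnt, double& sum_inv) {
  const int W = g.W;
  for (int w = 0; w < W; ++w) { visited[w] = 0; frontier[w] = 0; }
  frontier[s >> 6] = 1ULL << (s & 63);
  visited[s >> 6] = frontier[s >> 6];
  sum_d = 0.0; cnt = 0; sum_inv = 0.0;
  int level = 0;
  bool any = true;
  while (any) {
    ++level;
    for (int w = 0; w < W; ++w) nxt[w] = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t f = frontier[w];
      while (f) {
        int bpos = __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t* r = g.row((w << 6) + bpos);
        for (int k = 0; k < W; ++k) nxt[k] |= r[k];
      }
    }
    any = false;
    int newc = 0;
    for (int w = 0; w < W; ++w) {
      nxt[w] &= mask[w] & ~visited[w];
      visited[w] |= nxt[w];
      newc += __builtin_popcountll(nxt[w]);
      frontier[w] = nxt[w];
      if (nxt[w]) any = true;
    }
    if (newc) {
      sum_d += (double)newc * level;
      cnt += newc;
      sum_inv += (double)newc / level;
    }
  }
}

// scratch workspace reused across calls within one exported entry point
struct Scratch {
  std::vector<uint64_t> mask, vis, fr, nx;
  void init(int W, int n) {
    mask.assign(W, 0); vis.resize(W); fr.resize(W); nx.resize(W);
    for (int i = 0; i < n; ++i) mask[i >> 6] |= 1ULL << (i & 63);
  }
};

static void path_stats(const Bits& g, Scratch& sc, double& L, double& eglob,
                       double& unreach) {
  const int n = g.n;
  double tot_d = 0.0, tot_inv = 0.0;
  long tot_cnt = 0;
  double sd; int c; double si;
  for (int s = 0; s < n; ++s) {
    bfs_stats(g, s, sc.mask.data(), sc.vis.data(), sc.fr.data(), sc.nx.data(),
              sd, c, si);
    tot_d += sd; tot_cnt += c; tot_inv += si;
  }
  L = (tot_cnt > 0) ? tot_d / (double)tot_cnt : NA_REAL;
  double pairs = (double)n * (n - 1);
  eglob = (n > 1) ? tot_inv / pairs : 0.0;
  unreach = (pairs - (double)tot_cnt) / 2.0;
}

// per-node Watts-Strogatz clustering; degree < 2 contributes 0
static void clustering_local(const Bits& g, std::vector<double>& c) {
  const int n = g.n, W = g.W;
  c.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const uint64_t* ri = g.row(i);
    int k = 0;
    for (int w = 0; w < W; ++w) k += __builtin_popcountll(ri[w]);
    if (k < 2) continue;
    long tri2 = 0; // counts each within-neighborhood edge twice
    for (int w = 0; w < W; ++w) {
      uint64_t f = ri[w];
      while (f) {
        int bpos = __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t* rj = g.row((w << 6) + bpos);
        for (int q = 0; q < W; ++q) tri2 += __builtin_popcountll(ri[q] & rj[q]);
      }
    }
    c[i] = (double)tri2 / ((double)k * (k - 1));
  }
}

static double clustering_mean(const Bits& g, std::vector<double>& buf) {
  clustering_local(g, buf);
  double s = 0.0;
  for (double x : buf) s += x;
  return s / g.n;
}

// mean clustering via per-edge common-neighbor counts (fast path when the
// edge list is at hand); identical value to clustering_local's mean
static double clustering_mean_edges(const Bits& g, const std::vector<int>& eu,
                                    const std::vector<int>& ev,
                                    std::vector<long>& tri2,
                                    std::vector<int>& deg) {
  const int n = g.n, W = g.W, m = (int)eu.size();
  tri2.assign(n, 0);
  deg.assign(n, 0);
  for (int k = 0; k < m; ++k) {
    const uint64_t* ru = g.row(eu[k]);
    const uint64_t* rv = g.row(ev[k]);
    int common = 0;
    for (int w = 0; w < W; ++w) common += __builtin_popcountll(ru[w] & rv[w]);
    tri2[eu[k]] += common;
    tri2[ev[k]] += common;
    ++deg[eu[k]];
    ++deg[ev[k]];
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    if (deg[i] >= 2) s += (double)tri2[i] / ((double)deg[i] * (deg[i] - 1));
  return s / n;
}

// per-node local efficiency (global efficiency of each neighborhood subgraph)
static void local_efficiency(const Bits& g, Scratch& sc, std::vector<double>& e) {
  const int n = g.n, W = g.W;
  e.assign(n, 0.0);
  double sd; int c; double si;
  for (int i = 0; i < n; ++i) {
    const uint64_t* mask = g.row(i);
    int k = 0;
    for (int w = 0; w < W; ++w) k += __builtin_popcountll(mask[w]);
    if (k < 2) continue;
    double tot_inv = 0.0;
    for (int w = 0; w < W; ++w) {
      uint64_t f = mask[w];
      while (f) {
        int bpos = __builtin_ctzll(f);
        f &= f - 1;
        bfs_stats(g, (w << 6) + bpos, mask, sc.vis.data(), sc.fr.data(),
                  sc.nx.data(), sd, c, si);
        tot_inv += si;
      }
    }
    e[i] = tot_inv / ((double)k * (k - 1));
  }
}

// ---------------------------------------------------------------------------
// Brandes betweenness, allocation-free (predecessors found by re-scanning
// neighbors on the dependency pass). Each unordered pair counted once.
// ---------------------------------------------------------------------------
struct BrandesWork {
  std::vector<int> dist, queue, stack;
  std::vector<double> sigma, delta;
  std::vector<int> head, nbr; // CSR adjacency
  void init(int n) {
    dist.resize(n); queue.resize(n); stack.resize(n);
    sigma.resize(n); delta.resize(n);
  }
  void build_csr(int n, const std::vector<int>& eu, const std::vector<int>& ev,
                 int m) {
    head.assign(n + 1, 0);
    nbr.resize(2 * (size_t)m);
    for (int k = 0; k < m; ++k) { ++head[eu[k] + 1]; ++head[ev[k] + 1]; }
    for (int i = 0; i < n; ++i) head[i + 1] += head[i];
    std::vector<int> pos(head.begin(), head.end() - 1);
    for (int k = 0; k < m; ++k) {
      nbr[pos[eu[k]]++] = ev[k];
      nbr[pos[ev[k]]++] = eu[k];
    }
  }
};

static void brandes_csr(int n, BrandesWork& w, std::vector<double>& bc) {
  bc.assign(n, 0.0);
  const int* head = w.head.data();
  const int* nbr = w.nbr.data();
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) { w.dist[i] = -1; w.sigma[i] = 0.0; w.delta[i] = 0.0; }
    int qh = 0, qt = 0, sp = 0;
    w.dist[s] = 0; w.sigma[s] = 1.0; w.queue[qt++] = s;
    while (qh < qt) {
      int v = w.queue[qh++];
      w.stack[sp++] = v;
      const int dv = w.dist[v];
      const double sv = w.sigma[v];
      for (int e = head[v]; e < head[v + 1]; ++e) {
        const int u = nbr[e];
        if (w.dist[u] < 0) { w.dist[u] = dv + 1; w.queue[qt++] = u; }
        if (w.dist[u] == dv + 1) w.sigma[u] += sv;
      }
    }
    while (sp > 0) {
      int v = w.stack[--sp];
      const double coef = (1.0 + w.delta[v]) / w.sigma[v];
      const int dvm = w.dist[v] - 1;
      for (int e = head[v]; e < head[v + 1]; ++e) {
        const int u = nbr[e];
        if (w.dist[u] == dvm) w.delta[u] += w.sigma[u] * coef;
      }
      if (v != s) bc[v] += w.delta[v];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] *= 0.5;
}

static void brandes(int n, const std::vector<int>& eu, const std::vector<int>& ev,
                    int m, BrandesWork& w, std::vector<double>& bc) {
  w.build_csr(n, eu, ev, m);
  brandes_csr(n, w, bc);
}

static void adj_from_edges(int n, const std::vector<int>& eu, const std::vector<int>& ev,
                           int m, std::vector<std::vector<int>>& adj) {
  adj.assign(n, {});
  for (int k = 0; k < m; ++k) { adj[eu[k]].push_back(ev[k]); adj[ev[k]].push_back(eu[k]); }
}

// ---------------------------------------------------------------------------
// Maslov-Sneppen degree-preserving rewiring (attempt-counted)
// ---------------------------------------------------------------------------
static void rewire_ms(std::vector<int>& eu, std::vector<int>& ev, Bits& g,
                      long attempts, XRng& rng) {
  const int m = (int)eu.size();
  if (m < 2) return;
  int* pu = eu.data();
  int* pv = ev.data();
  uint64_t* bb = g.b.data();
  const int W = g.W;
  for (long t = 0; t < attempts; ++t) {
    const uint64_t r = rng.next();
    const int i = XRng::reduce32((uint32_t)(r >> 32), m);
    const int j = XRng::reduce32((uint32_t)r, m);
    int a = pu[i], b = pv[i], c = pu[j], d = pv[j];
    // branchless orientation flip of the second edge
    const int flip = -(int)((r >> 20) & 1ULL);
    const int x = (c ^ d) & flip;
    c ^= x; d ^= x;
    // proposed swap: (a,b),(c,d) -> (a,d),(c,b); one fused rejection test
    const bool clash = (i == j) | (a == d) | (c == b) | (a == c) | (b == d);
    if (clash) continue;
    const uint64_t had = ((bb[(size_t)a * W + (d >> 6)] >> (d & 63)) |
                          (bb[(size_t)c * W + (b >> 6)] >> (b & 63))) & 1ULL;
    if (had) continue;
    g.clear(a, b); g.clear(c, d);
    g.set(a, d); g.set(c, b);
    pv[i] = d; pu[j] = c; pv[j] = b;
  }
}

// Erdos-Renyi G(n, m) null: m distinct edges uniformly
static void sample_gnm(int n, int m, Bits& g, std::vector<int>& eu,
                       std::vector<int>& ev, XRng& rng) {
  int placed = 0;
  while (placed < m) {
    int a = rng.below(n), b = rng.below(n);
    if (a == b || g.has(a, b)) continue;
    g.set(a, b);
    eu[placed] = a;
    ev[placed] = b;
    ++placed;
  }
}

// mean C and L over n_random degree-preserving null networks, sampled along
// one Maslov-Sneppen chain: `rewire_factor * m` swap attempts of burn-in from
// the observed network, then one sample every `spacing_factor * m` further
// attempts. er_null draws independent G(n, m) graphs instead.
static void sigma_nulls(int n, const std::vector<int>& eu0, const std::vector<int>& ev0,
                        int n_random, double rewire_factor, bool er_null, XRng& rng,
                        Scratch& sc, double& c_rand, double& l_rand,
                        double spacing_factor = 2.0) {
  const int m = (int)eu0.size();
  double csum = 0.0, lsum = 0.0;
  std::vector<long> tri2;
  std::vector<int> deg;
  std::vector<int> eu = eu0, ev = ev0;
  Bits g(n);
  if (!er_null) fill_bits(g, eu, ev, m);
  for (int t = 0; t < n_random; ++t) {
    if (er_null) {
      std::fill(g.b.begin(), g.b.end(), 0ULL);
      sample_gnm(n, m, g, eu, ev, rng);
    } else {
      long attempts = (long)((t == 0 ? rewire_factor : spacing_factor) * m);
      rewire_ms(eu, ev, g, attempts, rng);
    }
    csum += clustering_mean_edges(g, eu, ev, tri2, deg);
    double L, eg, un;
    path_stats(g, sc, L, eg, un);
    lsum += L; // NA propagates if a null is fully disconnected
  }
  c_rand = csum / n_random;
  l_rand = lsum / n_random;
}

// ---------------------------------------------------------------------------
// Union-find and resilience curves (reverse node addition)
// ---------------------------------------------------------------------------
struct UF {
  std::vector<int> p, sz;
  void init(int n) { p.resize(n); sz.assign(n, 1); for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  int unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return sz[a];
    if (sz[a] < sz[b]) std::swap(a, b);
    p[b] = a; sz[a] += sz[b];
    return sz[a];
  }
};

// s_k = (largest component after removing order[0..k-1]) / n, k = 0..n
static void lcc_curve(int n, const std::vector<std::vector<int>>& adj,
                      const std::vector<int>& order, UF& uf,
                      std::vector<char>& active, std::vector<double>& s) {
  uf.init(n);
  active.assign(n, 0);
  s.resize(n + 1);
  int maxsz = 0;
  for (int t = n - 1; t >= 0; --t) {
    int v = order[t];
    active[v] = 1;
    if (maxsz < 1) maxsz = 1;
    for (int w : adj[v])
      if (active[w]) {
        int ms = uf.unite(v, w);
        if (ms > maxsz) maxsz = ms;
      }
    s[t] = (double)maxsz / n;
  }
  s[n] = 0.0;
}

static double curve_auc(const std::vector<double>& s, int n) {
  double a = 0.0;
  for (int k = 0; k < n; ++k) a += 0.5 * (s[k] + s[k + 1]);
  return a / n;
}

// ---------------------------------------------------------------------------
// Multilevel (Louvain-style) modularity optimization, deterministic
// (sequential node sweep, first-best tie break).
// ---------------------------------------------------------------------------
struct WGraph {
  int n;
  std::vector<std::vector<std::pair<int, double>>> adj; // neighbor, weight
  std::vector<double> self;                             // self-loop weight (x2 in degree)
  double two_m;                                         // total degree incl self loops
};

static void louvain_one_level(WGraph& g, std::vector<int>& comm, bool& improved) {
  const int n = g.n;
  comm.resize(n);
  std::vector<double> tot(n); // total degree per community
  std::vector<double> kdeg(n);
  for (int i = 0; i < n; ++i) {
    double k = g.self[i];
    for (auto& pr : g.adj[i]) k += pr.second;
    kdeg[i] = k;
    comm[i] = i;
    tot[i] = k;
  }
  const double two_m = g.two_m;
  std::vector<double> wcomm(n, 0.0);
  std::vector<int> touched;
  improved = false;
  bool moved = true;
  int guard = 0;
  while (moved && guard++ < 100) {
    moved = false;
    for (int v = 0; v < n; ++v) {
      touched.clear();
      for (auto& pr : g.adj[v]) {
        int c = comm[pr.first];
        if (wcomm[c] == 0.0) touched.push_back(c);
        wcomm[c] += pr.second;
      }
      const int cv = comm[v];
      tot[cv] -= kdeg[v];
      double best_gain = wcomm[cv] - kdeg[v] * tot[cv] / two_m;
      int best_c = cv;
      for (int c : touched) {
        if (c == cv) continue;
        double gain = wcomm[c] - kdeg[v] * tot[c] / two_m;
        if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
      }
      comm[v] = best_c;
      tot[best_c] += kdeg[v];
      for (int c : touched) wcomm[c] = 0.0;
      if (wcomm[cv] != 0.0) wcomm[cv] = 0.0;
      if (best_c != cv) { moved = true; improved = true; }
    }
  }
}

static void louvain_aggregate(const WGraph& g, const std::vector<int>& comm,
                              std::vector<int>& relabel, WGraph& out) {
  const int n = g.n;
  relabel.assign(n, -1);
  int nc = 0;
  for (int i = 0; i < n; ++i) {
    int c = comm[i];
    if (relabel[c] < 0) relabel[c] = nc++;
  }
  out.n = nc;
  out.adj.assign(nc, {});
  out.self.assign(nc, 0.0);
  out.two_m = g.two_m;
  // accumulate with a dense scratch row per aggregated node
  std::vector<double> row(nc, 0.0);
  std::vector<std::vector<int>> members(nc);
  for (int i = 0; i < n; ++i) members[relabel[comm[i]]].push_back(i);
  for (int c = 0; c < nc; ++c) {
    double self_w = 0.0;
    std::vector<int> nz;
    for (int v : members[c]) {
      self_w += g.self[v];
      for (auto& pr : g.adj[v]) {
        int cu = relabel[comm[pr.first]];
        if (cu == c) { self_w += pr.second; continue; }
        if (row[cu] == 0.0) nz.push_back(cu);
        row[cu] += pr.second;
      }
    }
    out.self[c] = self_w;
    for (int cu : nz) { out.adj[c].push_back({cu, row[cu]}); row[cu] = 0.0; }
  }
}

// returns membership on the original nodes
static void louvain(int n, const std::vector<int>& eu, const std::vector<int>& ev,
                    std::vector<int>& memb) {
  WGraph g;
  g.n = n;
  g.adj.assign(n, {});
  g.self.assign(n, 0.0);
  const int m = (int)eu.size();
  for (int k = 0; k < m; ++k) {
    g.adj[eu[k]].push_back({ev[k], 1.0});
    g.adj[ev[k]].push_back({eu[k], 1.0});
  }
  g.two_m = 2.0 * m;
  memb.resize(n);
  for (int i = 0; i < n; ++i) memb[i] = i;
  if (m == 0) return;
  std::vector<int> comm, relabel;
  for (int level = 0; level < 50; ++level) {
    bool improved = false;
    louvain_one_level(g, comm, improved);
    if (!improved) break;
    WGraph g2;
    louvain_aggregate(g, comm, relabel, g2);
    for (int i = 0; i < n; ++i) memb[i] = relabel[comm[memb[i]]];
    if (g2.n == g.n) break;
    g = std::move(g2);
  }
}

// Newman Q of a membership vector on the unweighted graph
static double modularity_value(int n, const std::vector<int>& eu,
                               const std::vector<int>& ev,
                               const std::vector<int>& memb) {
  const int m = (int)eu.size();
  if (m == 0) return NA_REAL;
  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, memb[i] + 1);
  std::vector<double> e_in(nc, 0.0), dtot(nc, 0.0);
  for (int k = 0; k < m; ++k) {
    dtot[memb[eu[k]]] += 1.0;
    dtot[memb[ev[k]]] += 1.0;
    if (memb[eu[k]] == memb[ev[k]]) e_in[memb[eu[k]]] += 1.0;
  }
  double Q = 0.0;
  for (int c = 0; c < nc; ++c) {
    double frac = dtot[c] / (2.0 * m);
    Q += e_in[c] / m - frac * frac;
  }
  return Q;
}

// ===========================================================================
// Exported functions
// ===========================================================================

// [[Rcpp::export]]
NumericVector eng_path_stats(IntegerMatrix edges, int n) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  Bits g(n);
  fill_bits(g, eu, ev, (int)eu.size());
  Scratch sc;
  sc.init(g.W, n);
  double L, eg, un;
  path_stats(g, sc, L, eg, un);
  return NumericVector::create(_["L"] = L, _["eglob"] = eg,
                               _["unreachable_pairs"] = un);
}

// [[Rcpp::export]]
NumericVector eng_clustering(IntegerMatrix edges, int n) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  Bits g(n);
  fill_bits(g, eu, ev, (int)eu.size());
  std::vector<double> c;
  clustering_local(g, c);
  return NumericVector(c.begin(), c.end());
}

// [[Rcpp::export]]
NumericVector eng_local_efficiency(IntegerMatrix edges, int n) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  Bits g(n);
  fill_bits(g, eu, ev, (int)eu.size());
  Scratch sc;
  sc.init(g.W, n);
  std::vector<double> e;
  local_efficiency(g, sc, e);
  return NumericVector(e.begin(), e.end());
}

// [[Rcpp::export]]
NumericVector eng_betweenness(IntegerMatrix edges, int n) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  BrandesWork w;
  w.init(n);
  std::vector<double> bc;
  brandes(n, eu, ev, (int)eu.size(), w, bc);
  return NumericVector(bc.begin(), bc.end());
}

// [[Rcpp::export]]
NumericVector eng_sigma_nulls(IntegerMatrix edges, int n, int n_random,
                              double rewire_factor, bool er_null) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  XRng rng;
  Scratch sc;
  sc.init((n + 63) >> 6, n);
  double cr, lr;
  sigma_nulls(n, eu, ev, n_random, rewire_factor, er_null, rng, sc, cr, lr);
  return NumericVector::create(_["c_rand"] = cr, _["l_rand"] = lr);
}

// [[Rcpp::export]]
IntegerMatrix eng_rewire(IntegerMatrix edges, int n, double rewire_factor) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  const int m = (int)eu.size();
  Bits g(n);
  fill_bits(g, eu, ev, m);
  XRng rng;
  rewire_ms(eu, ev, g, (long)(rewire_factor * m), rng);
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) { out(k, 0) = eu[k] + 1; out(k, 1) = ev[k] + 1; }
  return out;
}

// [[Rcpp::export]]
List eng_louvain(IntegerMatrix edges, int n) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  std::vector<int> memb;
  louvain(n, eu, ev, memb);
  double Q = modularity_value(n, eu, ev, memb);
  IntegerVector mv(memb.begin(), memb.end());
  return List::create(_["membership"] = mv + 1, _["Q"] = Q);
}

// [[Rcpp::export]]
double eng_modularity_q(IntegerMatrix edges, int n, IntegerVector membership) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  std::vector<int> memb(n);
  // compact arbitrary labels
  std::vector<int> seen;
  for (int i = 0; i < n; ++i) {
    int lab = membership[i];
    int idx = -1;
    for (size_t k = 0; k < seen.size(); ++k)
      if (seen[k] == lab) { idx = (int)k; break; }
    if (idx < 0) { idx = (int)seen.size(); seen.push_back(lab); }
    memb[i] = idx;
  }
  return modularity_value(n, eu, ev, memb);
}

// [[Rcpp::export]]
NumericVector eng_lcc_curve(IntegerMatrix edges, int n, IntegerVector order) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  std::vector<std::vector<int>> adj;
  adj_from_edges(n, eu, ev, (int)eu.size(), adj);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = order[i] - 1;
  UF uf;
  std::vector<char> act;
  std::vector<double> s;
  lcc_curve(n, adj, ord, uf, act, s);
  return NumericVector(s.begin(), s.end());
}

// [[Rcpp::export]]
NumericMatrix eng_random_failure(IntegerMatrix edges, int n, int n_rep) {
  std::vector<int> eu, ev;
  edges_from_matrix(edges, edges.nrow(), eu, ev);
  std::vector<std::vector<int>> adj;
  adj_from_edges(n, eu, ev, (int)eu.size(), adj);
  XRng rng;
  NumericMatrix out(n_rep, n + 1);
  std::vector<int> ord(n);
  UF uf;
  std::vector<char> act;
  std::vector<double> s;
  for (int r = 0; r < n_rep; ++r) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(ord[i], ord[rng.below(i + 1)]);
    lcc_curve(n, adj, ord, uf, act, s);
    for (int k = 0; k <= n; ++k) out(r, k) = s[k];
  }
  return out;
}

// [[Rcpp::export]]
int eng_min_connected_k(IntegerMatrix ranked_edges, int n) {
  UF uf;
  uf.init(n);
  int ncomp = n;
  const int m = ranked_edges.nrow();
  for (int k = 0; k < m; ++k) {
    int a = ranked_edges(k, 0) - 1, b = ranked_edges(k, 1) - 1;
    if (uf.find(a) != uf.find(b)) {
      uf.unite(a, b);
      if (--ncomp == 1) return k + 1;
    }
  }
  return NA_INTEGER;
}

// Global metrics over a nested density grid.
// Columns: C, L, eglob, eloc, c_rand, l_rand, sigma, unreachable_pairs
// [[Rcpp::export]]
NumericMatrix eng_grid_global(IntegerMatrix ranked_edges, int n, IntegerVector ks,
                              int n_random, double rewire_factor, bool er_null,
                              bool do_sigma, bool do_eloc) {
  std::vector<int> eu, ev;
  edges_from_matrix(ranked_edges, ranked_edges.nrow(), eu, ev);
  const int K = ks.size();
  NumericMatrix out(K, 8);
  colnames(out) = CharacterVector::create("C", "L", "eglob", "eloc", "c_rand",
                                          "l_rand", "sigma", "unreachable_pairs");
  XRng rng;
  Bits g(n);
  Scratch sc;
  sc.init(g.W, n);
  int built = 0;
  std::vector<double> cl, le;
  for (int q = 0; q < K; ++q) {
    int k = ks[q];
    while (built < k) { g.set(eu[built], ev[built]); ++built; }
    double cm = clustering_mean(g, cl);
    double L, eg, un;
    path_stats(g, sc, L, eg, un);
    double el = NA_REAL;
    if (do_eloc) {
      local_efficiency(g, sc, le);
      el = 0.0;
      for (double x : le) el += x;
      el /= n;
    }
    double cr = NA_REAL, lr = NA_REAL, sg = NA_REAL;
    if (do_sigma) {
      std::vector<int> eu_k(eu.begin(), eu.begin() + k),
                       ev_k(ev.begin(), ev.begin() + k);
      sigma_nulls(n, eu_k, ev_k, n_random, rewire_factor, er_null, rng, sc, cr, lr);
      if (R_finite(cr) && cr > 0 && R_finite(lr) && lr > 0 && R_finite(L))
        sg = (cm / cr) / (L / lr);
    }
    out(q, 0) = cm; out(q, 1) = L; out(q, 2) = eg; out(q, 3) = el;
    out(q, 4) = cr; out(q, 5) = lr; out(q, 6) = sg; out(q, 7) = un;
  }
  return out;
}

// Modularity Q per density (native multilevel optimizer)
// [[Rcpp::export]]
NumericVector eng_grid_modularity(IntegerMatrix ranked_edges, int n,
                                  IntegerVector ks) {
  std::vector<int> eu, ev;
  edges_from_matrix(ranked_edges, ranked_edges.nrow(), eu, ev);
  const int K = ks.size();
  NumericVector out(K);
  std::vector<int> memb;
  for (int q = 0; q < K; ++q) {
    int k = ks[q];
    std::vector<int> eu_k(eu.begin(), eu.begin() + k),
                     ev_k(ev.begin(), ev.begin() + k);
    louvain(n, eu_k, ev_k, memb);
    out[q] = modularity_value(n, eu_k, ev_k, memb);
  }
  return out;
}

// Nodal metrics (betweenness, degree, clustering) over a nested density grid
// [[Rcpp::export]]
List eng_grid_nodal(IntegerMatrix ranked_edges, int n, IntegerVector ks) {
  std::vector<int> eu, ev;
  edges_from_matrix(ranked_edges, ranked_edges.nrow(), eu, ev);
  const int K = ks.size();
  NumericMatrix bcm(n, K), degm(n, K), clm(n, K);
  Bits g(n);
  std::vector<int> deg(n, 0);
  BrandesWork w;
  w.init(n);
  int built = 0;
  std::vector<double> bc, cl;
  for (int q = 0; q < K; ++q) {
    int k = ks[q];
    while (built < k) {
      g.set(eu[built], ev[built]);
      ++deg[eu[built]];
      ++deg[ev[built]];
      ++built;
    }
    brandes(n, eu, ev, k, w, bc);
    clustering_local(g, cl);
    for (int i = 0; i < n; ++i) {
      bcm(i, q) = bc[i];
      degm(i, q) = (double)deg[i];
      clm(i, q) = cl[i];
    }
  }
  return List::create(_["bc"] = bcm, _["degree"] = degm, _["clustering"] = clm);
}

// Per-density resilience AUC. mode 0 = targeted attack (static ranking by
// betweenness on the intact network at that density, ties by node index),
// mode 1 = random failure (mean AUC over n_rep random orders). If `bc` has
// K columns it supplies precomputed per-density betweenness for mode 0.
// [[Rcpp::export]]
NumericVector eng_grid_resilience_auc(IntegerMatrix ranked_edges, int n,
                                      IntegerVector ks, int mode, int n_rep,
                                      Nullable<NumericMatrix> bc_pre = R_NilValue) {
  std::vector<int> eu, ev;
  edges_from_matrix(ranked_edges, ranked_edges.nrow(), eu, ev);
  const int K = ks.size();
  NumericVector out(K);
  std::vector<std::vector<int>> adj(n);
  int built = 0;
  XRng rng;
  UF uf;
  BrandesWork w;
  if (mode == 0 && bc_pre.isNull()) w.init(n);
  NumericMatrix bcm;
  bool have_bc = false;
  if (bc_pre.isNotNull()) { bcm = NumericMatrix(bc_pre); have_bc = true; }
  std::vector<char> act;
  std::vector<double> s, bc(n);
  std::vector<int> ord(n);
  for (int q = 0; q < K; ++q) {
    int k = ks[q];
    while (built < k) {
      adj[eu[built]].push_back(ev[built]);
      adj[ev[built]].push_back(eu[built]);
      ++built;
    }
    if (mode == 0) {
      if (have_bc) for (int i = 0; i < n; ++i) bc[i] = bcm(i, q);
      else brandes(n, eu, ev, k, w, bc);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [&bc](int a, int b) { return bc[a] > bc[b]; });
      lcc_curve(n, adj, ord, uf, act, s);
      out[q] = curve_auc(s, n);
    } else {
      double acc = 0.0;
      for (int r = 0; r < n_rep; ++r) {
        for (int i = 0; i < n; ++i) ord[i] = i;
        for (int i = n - 1; i > 0; --i) std::swap(ord[i], ord[rng.below(i + 1)]);
        lcc_curve(n, adj, ord, uf, act, s);
        acc += curve_auc(s, n);
      }
      out[q] = acc / n_rep;
    }
  }
  return out;
}
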