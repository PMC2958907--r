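// Core motif machinery: ESU enumeration of connected k-node induced
// subgraphs, canonical labeling by permutation maximisation (k <= 6),
// degree-preserving edge switching, and the enrichment ensemble loop.
#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int MAXK = 6;

// ---- permutations -------------------------------------------------------

static std::vector<std::vector<std::array<int, MAXK> > > perm_tab(MAXK + 1);

static const std::vector<std::array<int, MAXK> >& perms_for(int k) {
  std::vector<std::array<int, MAXK> >& tab = perm_tab[k];
  if (tab.empty()) {
    std::array<int, MAXK> p;
    for (int i = 0; i < k; ++i) p[i] = i;
    do {
      tab.push_back(p);
    } while (std::next_permutation(p.begin(), p.begin() + k));
  }
  return tab;
}

// Row-major bit encoding, most significant bit first: cell (i,j) of a k x k
// adjacency matrix contributes 2^(k*k - 1 - (i*k + j)).
static inline uint64_t cell_bit(int k, int i, int j) {
  return uint64_t(1) << (k * k - 1 - (i * k + j));
}

// Canonical id = max over all simultaneous row/column permutations of the
// row-major bit integer. A[] is k x k row-major boolean.
static uint64_t canon_of(const unsigned char* A, int k) {
  const std::vector<std::array<int, MAXK> >& ps = perms_for(k);
  uint64_t best = 0;
  for (size_t t = 0; t < ps.size(); ++t) {
    const std::array<int, MAXK>& p = ps[t];
    uint64_t v = 0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (A[p[i] * k + p[j]]) v |= cell_bit(k, i, j);
    if (v > best) best = v;
  }
  return best;
}

// ---- graph --------------------------------------------------------------

struct Graph {
  int n;
  std::vector<std::pair<int, int> > edges;       // 0-based
  std::vector<std::vector<int> > und;            // undirected neighbours, sorted
  std::vector<unsigned char> adj;                // n*n membership matrix
  bool has(int a, int b) const { return adj[(size_t)a * n + b] != 0; }
};

static Graph build_graph(int n, const IntegerMatrix& edges) {
  if ((double)n * n > 6.4e7)
    stop("graph too large for dense motif analysis (n = %d)", n);
  Graph g;
  g.n = n;
  g.adj.assign((size_t)n * n, 0);
  std::vector<std::vector<int> > und(n);
  int m = edges.nrow();
  g.edges.reserve(m);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a < 0 || a >= n || b < 0 || b >= n) stop("edge endpoint out of range");
    if (a == b) stop("self-loop in edge list");
    if (g.adj[(size_t)a * n + b]) stop("parallel edge in edge list");
    g.adj[(size_t)a * n + b] = 1;
    g.edges.push_back(std::make_pair(a, b));
    und[a].push_back(b);
    und[b].push_back(a);
  }
  for (int v = 0; v < n; ++v) {
    std::sort(und[v].begin(), und[v].end());
    und[v].erase(std::unique(und[v].begin(), und[v].end()), und[v].end());
  }
  g.und = und;
  return g;
}

// ---- ESU ----------------------------------------------------------------

// Callback-style ESU (Wernicke): visits every k-node subset whose induced
// subgraph is weakly connected exactly once, in deterministic order.
template <typename F>
struct Esu {
  const Graph& g;
  int k;
  F& emit;
  std::vector<int> sub;
  std::vector<int> in_sub_or_ext;  // visit stamp per node
  int root;

  Esu(const Graph& g_, int k_, F& emit_) : g(g_), k(k_), emit(emit_) {
    in_sub_or_ext.assign(g.n, -1);
  }

  void extend(std::vector<int>& ext) {
    if ((int)sub.size() == (size_t)k) {
      emit(sub);
      return;
    }
    // iterate over a private copy; remove head each step (ESU discipline)
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> newly;
      const std::vector<int>& nb = g.und[w];
      for (size_t i = 0; i < nb.size(); ++i) {
        int u = nb[i];
        if (u > root && in_sub_or_ext[u] != root) {
          ext2.push_back(u);
          in_sub_or_ext[u] = root;
          newly.push_back(u);
        }
      }
      sub.push_back(w);
      extend(ext2);
      sub.pop_back();
      for (size_t i = 0; i < newly.size(); ++i) in_sub_or_ext[newly[i]] = -1;
    }
  }

  void run() {
    for (int v = 0; v < g.n; ++v) {
      root = v;
      in_sub_or_ext[v] = v;
      std::vector<int> ext;
      const std::vector<int>& nb = g.und[v];
      for (size_t i = 0; i < nb.size(); ++i)
        if (nb[i] > v) {
          ext.push_back(nb[i]);
          in_sub_or_ext[nb[i]] = v;
        }
      sub.assign(1, v);
      extend(ext);
      for (size_t i = 0; i < nb.size(); ++i)
        if (nb[i] > v) in_sub_or_ext[nb[i]] = -1;
      in_sub_or_ext[v] = -1;
    }
  }
};

// Induced adjacency bits of a subset, nodes taken in the subset's current
// order; raw (non-canonical) pattern used as cache key.
static inline uint64_t subset_bits(const Graph& g, const std::vector<int>& s,
                                   int k) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j && g.has(s[i], s[j])) v |= cell_bit(k, i, j);
  return v;
}

typedef std::unordered_map<uint64_t, uint64_t> U64Map;

// Census with a raw-pattern -> canonical-id cache shared across graphs.
static void census_into(const Graph& g, int k, U64Map& cache, U64Map& counts,
                        uint64_t& total) {
  unsigned char A[MAXK * MAXK];
  struct Emit {
    const Graph& g;
    int k;
    U64Map& cache;
    U64Map& counts;
    uint64_t& total;
    unsigned char* A;
    void operator()(const std::vector<int>& s) {
      uint64_t raw = subset_bits(g, s, k);
      U64Map::iterator it = cache.find(raw);
      uint64_t canon;
      if (it != cache.end()) {
        canon = it->second;
      } else {
        for (int i = 0; i < k * k; ++i)
          A[i] = (raw & (uint64_t(1) << (k * k - 1 - i))) ? 1 : 0;
        canon = canon_of(A, k);
        cache[raw] = canon;
      }
      ++counts[canon];
      ++total;
    }
  } emit = {g, k, cache, counts, total, A};
  Esu<Emit> esu(g, k, emit);
  esu.run();
}

// ---- RNG (splitmix64) ---------------------------------------------------

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // bounded draw; modulo bias is negligible for the sizes used here
  uint64_t bounded(uint64_t m) { return next() % m; }
};

static uint64_t stream_key(double seed, double stream) {
  uint64_t a = (uint64_t)(int64_t)seed;
  uint64_t b = (uint64_t)(int64_t)stream;
  uint64_t z = a * 0x9E3779B97F4A7C15ULL + b + 0x632BE59BD9B4E019ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  return z ^ (z >> 27);
}

// ---- degree-preserving switching ----------------------------------------

struct EdgeSet {
  int n;
  std::vector<std::pair<int, int> > edges;
  std::vector<unsigned char> adj;
  bool has(int a, int b) const { return adj[(size_t)a * n + b] != 0; }
  void set(int a, int b, unsigned char v) { adj[(size_t)a * n + b] = v; }
};

// Attempt q * m pair swaps (a->b, c->d) -> (a->d, c->b); reject self-loops
// and parallel edges. Returns number of accepted swaps.
static int switch_edges(EdgeSet& es, int q, Rng& rng) {
  int m = (int)es.edges.size();
  int accepted = 0;
  if (m < 2) return 0;
  long attempts = (long)q * m;
  for (long t = 0; t < attempts; ++t) {
    int e1 = (int)rng.bounded(m), e2 = (int)rng.bounded(m);
    if (e1 == e2) continue;
    int a = es.edges[e1].first, b = es.edges[e1].second;
    int c = es.edges[e2].first, d = es.edges[e2].second;
    if (a == d || c == b) continue;        // would create self-loop
    if (b == d || a == c) continue;        // swap is a no-op
    if (es.has(a, d) || es.has(c, b)) continue;  // parallel edge
    es.set(a, b, 0);
    es.set(c, d, 0);
    es.set(a, d, 1);
    es.set(c, b, 1);
    es.edges[e1].second = d;
    es.edges[e2].second = b;
    ++accepted;
  }
  return accepted;
}

static EdgeSet edgeset_from(int n, const IntegerMatrix& edges) {
  EdgeSet es;
  es.n = n;
  es.adj.assign((size_t)n * n, 0);
  int m = edges.nrow();
  es.edges.reserve(m);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    es.edges.push_back(std::make_pair(a, b));
    es.set(a, b, 1);
  }
  return es;
}

static Graph graph_from_edgeset(const EdgeSet& es) {
  Graph g;
  g.n = es.n;
  g.adj = es.adj;
  g.edges = es.edges;
  std::vector<std::vector<int> > und(es.n);
  for (size_t e = 0; e < es.edges.size(); ++e) {
    und[es.edges[e].first].push_back(es.edges[e].second);
    und[es.edges[e].second].push_back(es.edges[e].first);
  }
  for (int v = 0; v < es.n; ++v) {
    std::sort(und[v].begin(), und[v].end());
    und[v].erase(std::unique(und[v].begin(), und[v].end()), und[v].end());
  }
  g.und = und;
  return g;
}

// ---- exports ------------------------------------------------------------

// [[Rcpp::export]]
double cpp_canonical_id(IntegerMatrix mat) {
  int k = mat.nrow();
  if (mat.ncol() != k) stop("adjacency matrix must be square");
  if (k < 1 || k > MAXK) stop("order must be between 1 and %d", MAXK);
  unsigned char A[MAXK * MAXK];
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      int v = mat(i, j);
      if (i == j && v != 0) stop("nonzero diagonal: self-loops not allowed");
      A[i * k + j] = v ? 1 : 0;
    }
  return (double)canon_of(A, k);
}

// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_subgraphs(int n, IntegerMatrix edges, int k) {
  Graph g = build_graph(n, edges);
  std::vector<int> out;
  struct Emit {
    std::vector<int>& out;
    int k;
    void operator()(const std::vector<int>& s) {
      std::vector<int> srt(s);
      std::sort(srt.begin(), srt.end());
      for (int i = 0; i < k; ++i) out.push_back(srt[i]);
    }
  } emit = {out, k};
  Esu<Emit> esu(g, k, emit);
  esu.run();
  int rows = (int)(out.size() / k);
  IntegerMatrix res(rows, k);
  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < k; ++c) res(r, c) = out[(size_t)r * k + c] + 1;
  return res;
}

// [[Rcpp::export]]
List cpp_motif_census(int n, IntegerMatrix edges, int k) {
  Graph g = build_graph(n, edges);
  U64Map cache, counts;
  uint64_t total = 0;
  census_into(g, k, cache, counts, total);
  std::vector<uint64_t> ids;
  ids.reserve(counts.size());
  for (U64Map::const_iterator it = counts.begin(); it != counts.end(); ++it)
    ids.push_back(it->first);
  std::sort(ids.begin(), ids.end());
  NumericVector rid(ids.size()), rcount(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) {
    rid[i] = (double)ids[i];
    rcount[i] = (double)counts[ids[i]];
  }
  return List::create(_["canonical_id"] = rid, _["count"] = rcount,
                      _["total"] = (double)total);
}

// [[Rcpp::export]]
List cpp_switch_randomize(int n, IntegerMatrix edges, int q, double seed,
                          double stream) {
  if ((double)n * n > 6.4e7) stop("graph too large (n = %d)", n);
  EdgeSet es = edgeset_from(n, edges);
  Rng rng(stream_key(seed, stream));
  int accepted = switch_edges(es, q, rng);
  int m = (int)es.edges.size();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = es.edges[e].first + 1;
    out(e, 1) = es.edges[e].second + 1;
  }
  return List::create(_["edges"] = out, _["accepted"] = accepted);
}

// Ensemble loop: census the real graph at size k, then n_random switched
// replicates; report per-replicate counts of every class seen in the real
// graph. The canonicalisation cache is shared across the whole ensemble.
// [[Rcpp::export]]
List cpp_enrichment_counts(int n, IntegerMatrix edges, int k, int n_random,
                           int q, double seed) {
  Graph g = build_graph(n, edges);
  U64Map cache;
  U64Map real_counts;
  uint64_t real_total = 0;
  census_into(g, k, cache, real_counts, real_total);

  std::vector<uint64_t> ids;
  for (U64Map::const_iterator it = real_counts.begin();
       it != real_counts.end(); ++it)
    ids.push_back(it->first);
  std::sort(ids.begin(), ids.end());
  int nc = (int)ids.size();
  U64Map id_index;
  for (int i = 0; i < nc; ++i) id_index[ids[i]] = i;

  NumericVector rid(nc), rcount(nc);
  for (int i = 0; i < nc; ++i) {
    rid[i] = (double)ids[i];
    rcount[i] = (double)real_counts[ids[i]];
  }

  NumericMatrix ens(n_random, nc);
  IntegerVector accepted(n_random);
  for (int r = 0; r < n_random; ++r) {
    EdgeSet es = edgeset_from(n, edges);
    Rng rng(stream_key(seed, r + 1));
    accepted[r] = switch_edges(es, q, rng);
    Graph gr = graph_from_edgeset(es);
    U64Map counts;
    uint64_t total = 0;
    census_into(gr, k, cache, counts, total);
    for (U64Map::const_iterator it = counts.begin(); it != counts.end(); ++it) {
      U64Map::const_iterator ix = id_index.find(it->first);
      if (ix != id_index.end()) ens(r, (int)ix->second) = (double)it->second;
    }
    if ((r & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["canonical_id"] = rid, _["count_real"] = rcount,
                      _["total_real"] = (double)real_total,
                      _["ensemble"] = ens, _["accepted"] = accepted);
}
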