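#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Directed-pair key; n is the node count, ids are 0-based.
static inline long long pkey(int a, int b, long long n) {
  return (long long)a * n + b;
}

// Enumerate all weakly connected unordered node triples and return, per
// triple, the 6-bit adjacency code of the sorted triple (i < j < k).
// Bit layout (MSB..LSB): (i,j) (i,k) (j,i) (j,k) (k,i) (k,j).
// Edges must be self-loop free and deduplicated; ids 0-based.
// [[Rcpp::export]]
IntegerMatrix connected_triples_cpp(int n, IntegerVector from, IntegerVector to) {
  int m = from.size();
  std::unordered_set<long long> eset;
  eset.reserve(m * 2 + 1);
  std::vector<std::unordered_set<int>> nset(n);
  for (int e = 0; e < m; ++e) {
    eset.insert(pkey(from[e], to[e], n));
    nset[from[e]].insert(to[e]);
    nset[to[e]].insert(from[e]);
  }
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) nbr[i].assign(nset[i].begin(), nset[i].end());

  std::unordered_set<long long> seen;
  std::vector<int> ti, tj, tk, code;
  long long n2 = (long long)n * n;
  for (int u = 0; u < n; ++u) {
    for (size_t vi = 0; vi < nbr[u].size(); ++vi) {
      int v = nbr[u][vi];
      if (v <= u) continue;  // each adjacent pair once, u < v
      for (int pass = 0; pass < 2; ++pass) {
        const std::vector<int>& cand = (pass == 0) ? nbr[u] : nbr[v];
        for (size_t wi = 0; wi < cand.size(); ++wi) {
          int w = cand[wi];
          if (w == u || w == v) continue;
          int a = u, b = v, c = w;
          if (b < a) std::swap(a, b);
          if (c < b) { std::swap(b, c); if (b < a) std::swap(a, b); }
          long long key = (long long)a * n2 + (long long)b * n + c;
          if (seen.count(key)) continue;
          seen.insert(key);
          int cd = 0;
          if (eset.count(pkey(a, b, n))) cd |= 32;
          if (eset.count(pkey(a, c, n))) cd |= 16;
          if (eset.count(pkey(b, a, n))) cd |= 8;
          if (eset.count(pkey(b, c, n))) cd |= 4;
          if (eset.count(pkey(c, a, n))) cd |= 2;
          if (eset.count(pkey(c, b, n))) cd |= 1;
          ti.push_back(a + 1); tj.push_back(b + 1); tk.push_back(c + 1);
          code.push_back(cd);
        }
      }
    }
  }
  int nt = (int)ti.size();
  IntegerMatrix out(nt, 4);
  for (int r = 0; r < nt; ++r) {
    out(r, 0) = ti[r]; out(r, 1) = tj[r]; out(r, 2) = tk[r]; out(r, 3) = code[r];
  }
  colnames(out) = CharacterVector::create("i", "j", "k", "code");
  return out;
}

// Degree-preserving double edge swaps: pick two edges (a->b), (c->d) and
// rewire to (a->d), (c->b) unless that would create a self-loop or a
// duplicate edge. Uses R's RNG, so results are reproducible via set.seed().
// [[Rcpp::export]]
List rewire_edges_cpp(int n, IntegerVector from, IntegerVector to, int attempts) {
  int m = from.size();
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  std::unordered_set<long long> eset;
  eset.reserve(m * 2 + 1);
  for (int e = 0; e < m; ++e) eset.insert(pkey(f[e], t[e], n));
  int done = 0, failed = 0;
  for (int s = 0; s < attempts; ++s) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) { ++failed; continue; }
    int a = f[e1], b = t[e1], c = f[e2], d = t[e2];
    // no-op swaps, would-be self-loops, would-be duplicates
    if (a == c || b == d || a == d || c == b) { ++failed; continue; }
    if (eset.count(pkey(a, d, n)) || eset.count(pkey(c, b, n))) { ++failed; continue; }
    eset.erase(pkey(a, b, n));
    eset.erase(pkey(c, d, n));
    eset.insert(pkey(a, d, n));
    eset.insert(pkey(c, b, n));
    t[e1] = d; t[e2] = b;
    ++done;
  }
  return List::create(_["from"] = IntegerVector(f.begin(), f.end()),
                      _["to"] = IntegerVector(t.begin(), t.end()),
                      _["swaps_done"] = done,
                      _["swaps_failed"] = failed);
}
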