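#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact minimal addition chain search by iterative-deepening DFS over
// strictly increasing chains (minimal chains can always be rearranged to be
// strictly increasing). Pruning: the chain maximum can at most double per
// remaining step, so amax * 2^r must reach n and the next element must be at
// least ceil(n / 2^(r-1)). Candidates are tried in ascending order so the
// first chain found at the minimal depth is the lexicographically smallest.

struct Cand { long long v; long long a, b; };

static bool dfs(std::vector<long long> &chain, long long n, int remaining,
                std::vector<long long> &ai, std::vector<long long> &bi) {
  long long amax = chain.back();
  if (amax == n) return true;
  if (remaining <= 0) return false;
  // reachability: amax * 2^remaining >= n (shift with overflow guard)
  long long cap = amax;
  for (int k = 0; k < remaining && cap < n; ++k) cap <<= 1;
  if (cap < n) return false;
  // next element must satisfy next * 2^(remaining-1) >= n
  long long lo;
  if (remaining - 1 >= 62) lo = 2;
  else lo = (n + ((1LL << (remaining - 1)) - 1)) >> (remaining - 1);
  if (lo <= amax) lo = amax + 1;
  long long hi = std::min(n, amax * 2);
  if (lo > hi) return false;

  std::vector<Cand> cands;
  const int m = (int)chain.size();
  for (int i = m - 1; i >= 0; --i) {
    for (int j = i; j >= 0; --j) {
      long long s = chain[i] + chain[j];
      if (s < lo) break;  // chain sorted ascending: decreasing j lowers s
      if (s <= hi) cands.push_back({s, chain[j], chain[i]});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand &x, const Cand &y) {
    if (x.v != y.v) return x.v < y.v;
    if (x.a != y.a) return x.a < y.a;
    return x.b < y.b;
  });
  cands.erase(std::unique(cands.begin(), cands.end(),
                          [](const Cand &x, const Cand &y) { return x.v == y.v; }),
              cands.end());
  for (const Cand &c : cands) {
    chain.push_back(c.v);
    ai.push_back(c.a);
    bi.push_back(c.b);
    if (dfs(chain, n, remaining - 1, ai, bi)) return true;
    chain.pop_back();
    ai.pop_back();
    bi.pop_back();
  }
  return false;
}

// [[Rcpp::export(name = ".addition_chain_exact")]]
List addition_chain_exact(double n_in) {
  if (n_in < 1 || n_in != std::floor(n_in) || n_in > 9e15)
    stop("n must be a positive integer within exact-search range");
  long long n = (long long)n_in;
  std::vector<long long> chain{1}, ai, bi;
  if (n == 1)
    return List::create(_["index"] = 0, _["value"] = NumericVector(0),
                        _["i"] = NumericVector(0), _["j"] = NumericVector(0));
  int lb = 0;
  while ((1LL << lb) < n) ++lb;  // ceil(log2 n)
  for (int d = lb; ; ++d) {
    chain.assign(1, 1);
    ai.clear(); bi.clear();
    if (dfs(chain, n, d, ai, bi)) {
      int L = (int)chain.size() - 1;
      NumericVector v(L), a(L), b(L);
      for (int k = 0; k < L; ++k) {
        v[k] = (double)chain[k + 1];
        a[k] = (double)ai[k];
        b[k] = (double)bi[k];
      }
      return List::create(_["index"] = L, _["value"] = v, _["i"] = a, _["j"] = b);
    }
    if (d > 2 * lb + 10) stop("addition-chain search failed to terminate");
  }
}
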