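#include <Rcpp.h>
#include <climits>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-connected neighbourhood offsets, column-major indexing (idx = col * nrow + row)
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Maximum-bottleneck ("brightest") pixel path between two pixel sets.
//
// Phase 1: multi-source widest-path Dijkstra maximising the minimum
// intensity along the path (endpoints included).
// Phase 2: restricted to pixels at or above the bottleneck, a second
// Dijkstra minimises total darkness sum(max_intensity - I(p)) with path
// length and then pixel index as deterministic tie-breaks; this prefers
// bright and short among all bottleneck-optimal routes.
//
// img: intensity matrix; src, dst: 0-based column-major linear indices;
// allowed: logical vector over pixels restricting the search envelope.
// [[Rcpp::export]]
List cpp_brightest_path(NumericMatrix img, IntegerVector src, IntegerVector dst,
                        LogicalVector allowed) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<char> is_dst(n, 0), in_env(n, 0);
  for (int i = 0; i < n; ++i) in_env[i] = allowed[i] ? 1 : 0;
  for (int i = 0; i < dst.size(); ++i) is_dst[dst[i]] = 1;

  // ---- Phase 1: bottleneck value ----
  std::vector<double> best(n, -1.0);
  typedef std::pair<double, int> PDI;
  std::priority_queue<PDI> pq;
  for (int i = 0; i < src.size(); ++i) {
    int s = src[i];
    if (!in_env[s]) continue;
    double b = img[s];
    if (b > best[s]) { best[s] = b; pq.push(PDI(b, s)); }
  }
  double bottleneck = -1.0;
  while (!pq.empty()) {
    PDI top = pq.top(); pq.pop();
    double b = top.first; int u = top.second;
    if (b < best[u]) continue;
    if (is_dst[u]) { bottleneck = b; break; }
    int r = u % nr, c = u / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int v = cc * nr + rr;
      if (!in_env[v]) continue;
      double nb = std::min(b, img[v]);
      if (nb > best[v]) { best[v] = nb; pq.push(PDI(nb, v)); }
    }
  }
  if (bottleneck < 0.0)
    return List::create(_["path"] = IntegerVector(0), _["bottleneck"] = NA_REAL);

  // ---- Phase 2: min total darkness over pixels >= bottleneck ----
  double imax = bottleneck;
  for (int i = 0; i < n; ++i)
    if (in_env[i] && img[i] > imax) imax = img[i];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> cost(n, INF);
  std::vector<int> len(n, INT_MAX), par(n, -1);
  // ordering: (cost, len, idx) smallest first
  typedef std::tuple<double, int, int> T3;
  std::priority_queue<T3, std::vector<T3>, std::greater<T3> > q2;
  for (int i = 0; i < src.size(); ++i) {
    int s = src[i];
    if (!in_env[s] || img[s] < bottleneck) continue;
    double c0 = imax - img[s];
    if (c0 < cost[s] || (c0 == cost[s] && 1 < len[s])) {
      cost[s] = c0; len[s] = 1; par[s] = -1;
      q2.push(T3(c0, 1, s));
    }
  }
  int goal = -1;
  while (!q2.empty()) {
    T3 top = q2.top(); q2.pop();
    double cu = std::get<0>(top); int lu = std::get<1>(top), u = std::get<2>(top);
    if (cu > cost[u] || (cu == cost[u] && lu > len[u])) continue;
    if (is_dst[u]) { goal = u; break; }
    int r = u % nr, c = u / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int v = cc * nr + rr;
      if (!in_env[v] || img[v] < bottleneck) continue;
      double nc2 = cu + (imax - img[v]);
      int nl = lu + 1;
      bool better = (nc2 < cost[v]) ||
        (nc2 == cost[v] && nl < len[v]) ||
        (nc2 == cost[v] && nl == len[v] && par[v] >= 0 && u < par[v]);
      if (better) {
        cost[v] = nc2; len[v] = nl; par[v] = u;
        q2.push(T3(nc2, nl, v));
      }
    }
  }
  if (goal < 0)  // should not happen if phase 1 succeeded
    return List::create(_["path"] = IntegerVector(0), _["bottleneck"] = NA_REAL);

  std::vector<int> rev;
  for (int u = goal; u >= 0; u = par[u]) rev.push_back(u);
  IntegerVector path(rev.size());
  for (size_t i = 0; i < rev.size(); ++i) path[i] = rev[rev.size() - 1 - i];
  return List::create(_["path"] = path, _["bottleneck"] = bottleneck);
}
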