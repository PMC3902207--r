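#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Breadth-first search in the infinite translation-invariant connection
// graph, restricted to spatial offsets |x|, |y| <= bound. States are
// (feature, x, y); edges follow the connection templates
// (dx, dy, j -> k). Returns, for one source feature placed at the
// origin, the directed hop distance to every feature at the origin
// (-1 when unreachable within the bound / hop cap).
// [[Rcpp::export]]
IntegerVector cpp_bfs_column(IntegerVector dx, IntegerVector dy,
                             IntegerVector jf, IntegerVector kf,
                             int K, int bound, int source, int max_hops) {
  const int D = 2 * bound + 1;
  const size_t nstate = (size_t)K * D * D;
  const int n = dx.size();
  // group edge templates by afferent feature
  std::vector<std::vector<int>> by_j(K);
  for (int e = 0; e < n; ++e) by_j[jf[e] - 1].push_back(e);
  std::vector<int> dist(nstate, -1);
  IntegerVector out(K, -1);
  int found = 0;
  auto sid = [&](int f, int x, int y) {
    return ((size_t)f * D + (size_t)(y + bound)) * D + (size_t)(x + bound);
  };
  std::queue<std::array<int, 3>> q;
  dist[sid(source - 1, 0, 0)] = 0;
  out[source - 1] = 0;
  ++found;
  q.push({source - 1, 0, 0});
  while (!q.empty() && found < K) {
    auto s = q.front();
    q.pop();
    const int d0 = dist[sid(s[0], s[1], s[2])];
    if (d0 >= max_hops) continue;
    for (int e : by_j[s[0]]) {
      const int x = s[1] + dx[e], y = s[2] + dy[e];
      if (x < -bound || x > bound || y < -bound || y > bound) continue;
      const int k = kf[e] - 1;
      size_t id = sid(k, x, y);
      if (dist[id] >= 0) continue;
      dist[id] = d0 + 1;
      if (x == 0 && y == 0 && out[k] < 0) {
        out[k] = d0 + 1;
        ++found;
      }
      q.push({k, x, y});
    }
  }
  return out;
}
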