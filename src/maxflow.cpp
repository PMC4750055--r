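#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow / min-cut on the GrabCut graph: pixel nodes plus source and
// sink terminals. N-links are undirected (equal residual capacity in both
// directions); t-links are directed from the source and into the sink.
// Returns the source-side (foreground) indicator per pixel after the min cut.

struct DinicGraph {
  int n;
  std::vector<int> head;          // CSR-ish adjacency via linked lists
  std::vector<int> to, nxt;
  std::vector<double> cap;
  std::vector<int> level, iter;

  DinicGraph(int n_) : n(n_), head(n_, -1) {}

  void add_pair(int a, int b, double cab, double cba) {
    to.push_back(b); cap.push_back(cab); nxt.push_back(head[a]);
    head[a] = (int)to.size() - 1;
    to.push_back(a); cap.push_back(cba); nxt.push_back(head[b]);
    head[b] = (int)to.size() - 1;
  }

  bool bfs(int s, int t) {
    level.assign(n, -1);
    std::queue<int> q;
    level[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int e = head[v]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[v] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int v, int t, double f) {
    if (v == t) return f;
    for (int &e = iter[v]; e != -1; e = nxt[e]) {
      int u = to[e];
      if (cap[e] > 1e-12 && level[u] == level[v] + 1) {
        double d = dfs(u, t, std::min(f, cap[e]));
        if (d > 0) {
          cap[e] -= d;
          cap[e ^ 1] += d;  // paired arc is the reverse
          return d;
        }
      }
    }
    return 0;
  }

  double maxflow(int s, int t) {
    double flow = 0;
    while (bfs(s, t)) {
      iter = head;
      double f;
      while ((f = dfs(s, t, R_PosInf)) > 0) flow += f;
    }
    return flow;
  }
};

// pa, pb: 1-based pixel endpoints of undirected n-links with weights w;
// cap_src / cap_snk: terminal capacities per pixel.
// [[Rcpp::export]]
List grid_mincut_cpp(IntegerVector pa, IntegerVector pb, NumericVector w,
                     NumericVector cap_src, NumericVector cap_snk) {
  int n = cap_src.size();
  int S = n, T = n + 1;
  DinicGraph g(n + 2);
  for (R_xlen_t i = 0; i < pa.size(); ++i) {
    g.add_pair(pa[i] - 1, pb[i] - 1, w[i], w[i]);
  }
  for (int i = 0; i < n; ++i) {
    if (cap_src[i] > 0) g.add_pair(S, i, cap_src[i], 0.0);
    if (cap_snk[i] > 0) g.add_pair(i, T, cap_snk[i], 0.0);
  }
  double flow = g.maxflow(S, T);
  // source side of the residual graph = foreground
  std::vector<char> vis(n + 2, 0);
  std::queue<int> q;
  vis[S] = 1;
  q.push(S);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int e = g.head[v]; e != -1; e = g.nxt[e]) {
      if (g.cap[e] > 1e-12 && !vis[g.to[e]]) {
        vis[g.to[e]] = 1;
        q.push(g.to[e]);
      }
    }
  }
  LogicalVector fg(n);
  for (int i = 0; i < n; ++i) fg[i] = vis[i] != 0;
  return List::create(_["foreground"] = fg, _["flow"] = flow);
}
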