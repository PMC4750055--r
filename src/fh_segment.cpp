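#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Disjoint-set forest with union by rank, tracking component sizes.
struct Universe {
  std::vector<int> parent, rank_, size_;
  Universe(int n) : parent(n), rank_(n, 0), size_(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int root = x;
    while (parent[root] != root) root = parent[root];
    while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
    return root;
  }
  int join(int a, int b) {
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    size_[a] += size_[b];
    if (rank_[a] == rank_[b]) ++rank_[a];
    return a;
  }
};

struct Edge { float w; int a, b; };

static inline double px(const NumericVector &im, int H, int W, int r, int c, int ch) {
  return im[r + c * H + ch * H * W];
}

// Separable Gaussian blur per channel, reflecting boundaries.
static NumericVector gaussian_smooth(const NumericVector &im, int H, int W, double sigma) {
  if (sigma <= 0) return clone(im);
  int rad = std::max(1, (int)std::ceil(2.5 * sigma));
  std::vector<double> kern(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) { kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma)); s += kern[i + rad]; }
  for (double &k : kern) k /= s;
  NumericVector tmp(im.size()), out(im.size());
  for (int ch = 0; ch < 3; ++ch) {
    // horizontal pass
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        double acc = 0;
        for (int i = -rad; i <= rad; ++i) {
          int cc = c + i;
          if (cc < 0) cc = -cc - 1;
          if (cc >= W) cc = 2 * W - cc - 1;
          acc += kern[i + rad] * px(im, H, W, r, cc, ch);
        }
        tmp[r + c * H + ch * H * W] = acc;
      }
    // vertical pass
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        double acc = 0;
        for (int i = -rad; i <= rad; ++i) {
          int rr = r + i;
          if (rr < 0) rr = -rr - 1;
          if (rr >= H) rr = 2 * H - rr - 1;
          acc += kern[i + rad] * px(tmp, H, W, rr, c, ch);
        }
        out[r + c * H + ch * H * W] = acc;
      }
  }
  return out;
}

// Graph-based segmentation by greedy MST merging: components A, B merge when the
// connecting edge weight is no larger than min(Int(A)+k/|A|, Int(B)+k/|B|), with
// Int the largest internal edge weight. Afterwards components smaller than
// min_size are absorbed across their cheapest incident edges. image is an
// (H,W,3) array on the 0..255 scale; returns 0-based consecutive labels.
// [[Rcpp::export]]
List fh_segment_cpp(NumericVector image, int H, int W, double k, double sigma, int min_size) {
  NumericVector sm = gaussian_smooth(image, H, W, sigma);
  int n = H * W;
  std::vector<Edge> edges;
  edges.reserve((size_t)n * 4);
  // 8-neighbourhood: right, down, down-right, down-left (each undirected edge once)
  const int dr[4] = {0, 1, 1, 1};
  const int dc[4] = {1, 0, 1, -1};
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
        double dw = 0;
        for (int ch = 0; ch < 3; ++ch) {
          double diff = px(sm, H, W, r, c, ch) - px(sm, H, W, r2, c2, ch);
          dw += diff * diff;
        }
        Edge e;
        e.w = (float)std::sqrt(dw);
        e.a = r + c * H;
        e.b = r2 + c2 * H;
        edges.push_back(e);
      }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge &x, const Edge &y) { return x.w < y.w; });
  Universe u(n);
  std::vector<double> threshold(n, k); // Int(C) + k/|C| starts at k for singletons
  for (const Edge &e : edges) {
    int a = u.find(e.a), b = u.find(e.b);
    if (a == b) continue;
    if (e.w <= threshold[a] && e.w <= threshold[b]) {
      int m = u.join(a, b);
      threshold[m] = e.w + k / u.size_[m];
    }
  }
  // absorb small components (in edge-weight order, the usual post-process)
  for (const Edge &e : edges) {
    int a = u.find(e.a), b = u.find(e.b);
    if (a != b && (u.size_[a] < min_size || u.size_[b] < min_size)) u.join(a, b);
  }
  // relabel to consecutive 0-based ids in first-occurrence (column-major) order
  std::vector<int> remap(n, -1);
  int next = 0;
  IntegerMatrix labels(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int root = u.find(r + c * H);
      if (remap[root] < 0) remap[root] = next++;
      labels(r, c) = remap[root];
    }
  return List::create(_["labels"] = labels, _["n_regions"] = next);
}

// 8-connected components of a binary mask; labels 0 = background, 1..n = blobs,
// numbered in column-major order of first occurrence.
// [[Rcpp::export]]
List cc_label8_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> sizes;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      int sz = 0;
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        ++sz;
        int pr = p % H, pc = p / H;
        for (int d = 0; d < 8; ++d) {
          int rr = pr + dr[d], cc = pc + dc[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
      sizes.push_back(sz);
    }
  return List::create(_["labels"] = lab, _["n"] = next, _["sizes"] = wrap(sizes));
}
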