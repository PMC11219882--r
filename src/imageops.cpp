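#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// 4-connected components of a binary mask (non-zero = foreground).
// Labels are assigned in raster (column-major) order of first pixel,
// so the result is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(c * H + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nc * H + nr);
          }
        }
      }
    }
  }
  return lab;
}

static const double DT_INF = 1e20;

// 1D squared distance transform lower envelope (Felzenszwalb-Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -DT_INF; z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance of foreground pixels to the nearest
// background (zero) pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix g(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = mask(r, c) ? DT_INF : 0.0;
    dt1d(f, d, H);
    for (int r = 0; r < H; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = g(r, c);
    dt1d(f, d, W);
    for (int c = 0; c < W; ++c) out(r, c) = d[c];
  }
  return out;
}

struct WsNode {
  double prio;   // flood from high priority downwards
  long order;    // insertion counter: deterministic tie-break
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on prio
    return a.order > b.order;                      // FIFO among ties
  }
};

// Marker-controlled watershed by priority flooding: basins grow from the
// markers outwards in order of decreasing priority (e.g. the distance
// transform), restricted to mask pixels. 4-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& prio,
                            const IntegerMatrix& markers,
                            const IntegerMatrix& mask) {
  int H = prio.nrow(), W = prio.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long counter = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (markers(r, c) > 0 && mask(r, c) != 0) {
        lab(r, c) = markers(r, c);
        pq.push(WsNode{prio(r, c), counter++, c * H + r});
      }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int pr = nd.idx % H, pc = nd.idx / H;
    int l = lab(pr, pc);
    for (int k = 0; k < 4; ++k) {
      int nr = pr + dr[k], nc = pc + dc[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
        lab(nr, nc) = l;
        pq.push(WsNode{prio(nr, nc), counter++, nc * H + nr});
      }
    }
  }
  return lab;
}

// Optimal square linear assignment (min cost) via shortest augmenting
// paths with dual potentials, O(n^3). Forbidden entries should be a large
// finite cost. Returns, for each row, the assigned column (1-based).
// [[Rcpp::export]]
IntegerVector cpp_lap(const NumericMatrix& cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return IntegerVector(0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector rowsol(n);
  for (int j = 1; j <= n; ++j) rowsol[p[j] - 1] = j;
  return rowsol;
}
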