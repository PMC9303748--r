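#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8- or 4-connected component labeling of a logical mask.
// Labels are assigned in column-major scan order, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, const int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nk = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int k = 0; k < nk; ++k) {
          const int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher 2012).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, const int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance of each foreground pixel to the nearest background
// pixel (background outside the image is ignored: a blob cut by the border has
// large distances there, which keeps border blobs floodable).
// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix D(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      D(r, c) = mask(r, c) ? INF : 0.0;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int c = 0; c < W; ++c) {  // transform along rows (within each column)
    for (int r = 0; r < H; ++r) f[r] = D(r, c);
    dt1d(f, d, H);
    for (int r = 0; r < H; ++r) D(r, c) = d[r];
  }
  for (int r = 0; r < H; ++r) {  // then along columns
    for (int c = 0; c < W; ++c) f[c] = D(r, c);
    dt1d(f, d, W);
    for (int c = 0; c < W; ++c) D(r, c) = std::sqrt(d[c]);
  }
  return D;
}

// Separable Gaussian blur with reflected boundaries; kernel radius = ceil(3*sigma).
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, const double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += ker[i + rad];
  }
  for (double& k : ker) k /= ksum;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c) {  // vertical pass
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= H) rr = 2 * H - rr - 1;
        acc += ker[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  for (int r = 0; r < H; ++r) {  // horizontal pass
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= W) cc = 2 * W - cc - 1;
        acc += ker[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Chebyshev-window maximum filter (separable running max), used for peak finding.
// [[Rcpp::export]]
NumericMatrix cpp_max_filter(const NumericMatrix& img, const int radius) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double m = -INFINITY;
      for (int i = std::max(0, r - radius); i <= std::min(H - 1, r + radius); ++i)
        m = std::max(m, img(i, c));
      tmp(r, c) = m;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double m = -INFINITY;
      for (int i = std::max(0, c - radius); i <= std::min(W - 1, c + radius); ++i)
        m = std::max(m, tmp(r, i));
      out(r, c) = m;
    }
  return out;
}

struct QItem {
  double prio;
  long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO tie-break => deterministic
  }
};

// Seeded watershed by priority flooding: seeds grow into the masked region in
// increasing order of `priority` (pass the negated distance transform to flood
// basins from their deepest points). Every foreground pixel reachable from a
// seed gets that seed's label; no watershed-line pixels are left unlabeled.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& priority, const IntegerMatrix& seeds,
                            const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (seeds(r, c) != 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({priority(r, c), order++, r + c * H});
      }
  while (!pq.empty()) {
    const QItem it = pq.top();
    pq.pop();
    const int pr = it.idx % H, pc = it.idx / H;
    const int plab = lab(pr, pc);
    for (int k = 0; k < 8; ++k) {
      const int nr = pr + dr[k], nc = pc + dc[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (mask(nr, nc) && lab(nr, nc) == 0) {
        lab(nr, nc) = plab;
        pq.push({priority(nr, nc), order++, nr + nc * H});
      }
    }
  }
  return lab;
}
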