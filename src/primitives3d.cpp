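#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D volumes are stored as R arrays with dim = (nz, ny, nx), z fastest.
// All functions below assume that layout.

static inline int reflect_index(int i, int n) {
  // reflect-101 boundary (a b c | b a), robust for any i
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// separable convolution along one axis; axis: 0=z, 1=y, 2=x
static void conv_axis(std::vector<double> &v, int nz, int ny, int nx,
                      int axis, const std::vector<double> &k) {
  int r = ((int)k.size() - 1) / 2;
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::vector<double> line(n), out(n);
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)nz
                                                  : (R_xlen_t)nz * ny;
  int n1 = (axis == 0) ? ny : nz;
  int n2 = (axis == 2) ? ny : nx;
  R_xlen_t s1 = (axis == 0) ? (R_xlen_t)nz : 1;
  R_xlen_t s2 = (axis == 2) ? (R_xlen_t)nz : (R_xlen_t)nz * ny;
  for (int a = 0; a < n1; ++a) {
    for (int b = 0; b < n2; ++b) {
      R_xlen_t base = a * s1 + b * s2;
      for (int i = 0; i < n; ++i) line[i] = v[base + i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j)
          acc += k[j + r] * line[reflect_index(i + j, n)];
        out[i] = acc;
      }
      for (int i = 0; i < n; ++i) v[base + i * stride] = out[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis)
    if (sigma[axis] > 1e-12) conv_axis(v, nz, ny, nx, axis, gauss_kernel(sigma[axis]));
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// voxel is a local maximum if >= all 26 in-bounds neighbours
// [[Rcpp::export]]
LogicalVector cpp_local_maxima3d(NumericVector vol, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        double v = vol[idx];
        bool is_max = true;
        for (int dx = -1; dx <= 1 && is_max; ++dx)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dz = -1; dz <= 1 && is_max; ++dz) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              if (vol[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] > v)
                is_max = false;
            }
        out[idx] = is_max;
      }
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of a binary mask (BFS)
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    queue.clear();
    queue.push_back(start);
    lab[start] = next;
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t nb = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[nb] && !lab[nb]) {
              lab[nb] = next;
              queue.push_back(nb);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

struct WsNode {
  double value;
  unsigned long order;
  R_xlen_t idx;
};
struct WsCompare {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value < b.value; // max-heap on intensity
    return a.order > b.order;                         // FIFO on ties
  }
};

// seeded watershed: flood the masked region from labelled seeds in order of
// decreasing intensity; every masked voxel reachable from a seed gets a label
// [[Rcpp::export]]
IntegerVector cpp_watershed_seeded(NumericVector vol, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCompare> pq;
  unsigned long order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({vol[i], order++, i});
    }
  while (!pq.empty()) {
    WsNode cur = pq.top();
    pq.pop();
    int z = (int)(cur.idx % nz);
    int y = (int)((cur.idx / nz) % ny);
    int x = (int)(cur.idx / ((R_xlen_t)nz * ny));
    int curlab = lab[cur.idx];
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t nb = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (mask[nb] && !lab[nb]) {
            lab[nb] = curlab;
            pq.push({vol[nb], order++, nb});
          }
        }
  }
  lab.attr("dim") = dim;
  return lab;
}

// exact voxel-pair overlap counting between two label volumes
// [[Rcpp::export]]
DataFrame cpp_pair_overlaps(IntegerVector a, IntegerVector b) {
  std::map<std::pair<int, int>, int> counts;
  R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (a[i] > 0 && b[i] > 0) counts[{a[i], b[i]}]++;
  int m = (int)counts.size();
  IntegerVector la(m), lb(m), ov(m);
  int j = 0;
  for (auto &kv : counts) {
    la[j] = kv.first.first;
    lb[j] = kv.first.second;
    ov[j] = kv.second;
    ++j;
  }
  return DataFrame::create(_["label_a"] = la, _["label_b"] = lb,
                           _["overlap_voxels"] = ov);
}
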