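// Low-level voxel algorithms shared by the segmentation and spatial modules.
// All arrays are column-major (R layout); dims has length 2 or 3.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

struct Grid {
  std::vector<int> dims;
  std::vector<int> strides;
  int nd;
  R_xlen_t n;
  // neighbor offsets as coordinate deltas
  std::vector<std::vector<int>> offs;

  Grid(const IntegerVector &d, bool full) {
    nd = d.size();
    dims.assign(d.begin(), d.end());
    strides.resize(nd);
    n = 1;
    for (int a = 0; a < nd; ++a) { strides[a] = (int)n; n *= dims[a]; }
    // enumerate offsets
    std::vector<int> cur(nd, -1);
    while (true) {
      bool zero = true, face = false;
      int nz = 0;
      for (int a = 0; a < nd; ++a) { if (cur[a] != 0) { zero = false; ++nz; } }
      face = (nz == 1);
      if (!zero && (full || face)) offs.push_back(cur);
      int a = 0;
      for (; a < nd; ++a) { if (cur[a] < 1) { ++cur[a]; break; } cur[a] = -1; }
      if (a == nd) break;
    }
  }

  void coords(R_xlen_t idx, std::vector<int> &c) const {
    for (int a = 0; a < nd; ++a) { c[a] = idx % dims[a]; idx /= dims[a]; }
  }

  // neighbor linear index or -1 if outside
  R_xlen_t neighbor(const std::vector<int> &c, const std::vector<int> &off) const {
    R_xlen_t idx = 0;
    for (int a = 0; a < nd; ++a) {
      int v = c[a] + off[a];
      if (v < 0 || v >= dims[a]) return -1;
      idx += (R_xlen_t)v * strides[a];
    }
    return idx;
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, bool full_connectivity = true) {
  Grid g(dims, full_connectivity);
  IntegerVector lab(g.n, 0);
  std::vector<int> c(g.nd);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      g.coords(p, c);
      for (const auto &off : g.offs) {
        R_xlen_t q = g.neighbor(c, off);
        if (q >= 0 && mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Grayscale reconstruction by dilation of `marker` under `mask` (marker <= mask),
// Vincent (1993) hybrid raster/queue algorithm.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilate(NumericVector marker, NumericVector mask,
                                     IntegerVector dims, bool full_connectivity = true) {
  Grid g(dims, full_connectivity);
  NumericVector J = clone(marker);
  std::vector<int> c(g.nd);
  // split offsets into raster-backward (negative linear offset) and forward
  std::vector<std::vector<int>> back, fwd;
  for (const auto &off : g.offs) {
    R_xlen_t lin = 0;
    for (int a = 0; a < g.nd; ++a) lin += (R_xlen_t)off[a] * g.strides[a];
    if (lin < 0) back.push_back(off); else fwd.push_back(off);
  }
  // forward scan
  for (R_xlen_t i = 0; i < g.n; ++i) {
    g.coords(i, c);
    double m = J[i];
    for (const auto &off : back) {
      R_xlen_t q = g.neighbor(c, off);
      if (q >= 0 && J[q] > m) m = J[q];
    }
    J[i] = std::min(m, mask[i]);
  }
  // backward scan + queue init
  std::queue<R_xlen_t> fifo;
  for (R_xlen_t i = g.n - 1; i >= 0; --i) {
    g.coords(i, c);
    double m = J[i];
    for (const auto &off : fwd) {
      R_xlen_t q = g.neighbor(c, off);
      if (q >= 0 && J[q] > m) m = J[q];
    }
    J[i] = std::min(m, mask[i]);
    for (const auto &off : fwd) {
      R_xlen_t q = g.neighbor(c, off);
      if (q >= 0 && J[q] < J[i] && J[q] < mask[q]) { fifo.push(i); break; }
    }
    if (i == 0) break;
  }
  // propagation
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    g.coords(p, c);
    for (const auto &off : g.offs) {
      R_xlen_t q = g.neighbor(c, off);
      if (q >= 0 && J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dims;
  return J;
}

// Regional minima: plateaus with no strictly lower neighbor (within mask).
// [[Rcpp::export]]
LogicalVector cpp_regional_minima(NumericVector img, IntegerVector dims,
                                  LogicalVector mask, bool full_connectivity = true) {
  Grid g(dims, full_connectivity);
  LogicalVector out(g.n, false);
  std::vector<signed char> state(g.n, 0); // 0 unvisited, 1 visited
  std::vector<int> c(g.nd);
  std::vector<R_xlen_t> plateau, stack;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (state[i] || !mask[i]) continue;
    double v = img[i];
    bool is_min = true;
    plateau.clear(); stack.clear();
    stack.push_back(i); state[i] = 1;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      plateau.push_back(p);
      g.coords(p, c);
      for (const auto &off : g.offs) {
        R_xlen_t q = g.neighbor(c, off);
        if (q < 0 || !mask[q]) continue;
        if (img[q] < v) { is_min = false; continue; }
        if (img[q] == v && !state[q]) { state[q] = 1; stack.push_back(q); }
      }
    }
    if (is_min) for (R_xlen_t p : plateau) out[p] = true;
  }
  out.attr("dim") = dims;
  return out;
}

// Marker-controlled watershed by priority flooding (Meyer). Queue ordered by
// (intensity, insertion order); insertion order makes ties deterministic and
// lexicographic in voxel scan order.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector img, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims,
                            bool full_connectivity = true) {
  Grid g(dims, full_connectivity);
  IntegerVector lab = clone(markers);
  struct Item { double pri; unsigned long ord; R_xlen_t idx; int label; };
  struct Cmp {
    bool operator()(const Item &a, const Item &b) const {
      if (a.pri != b.pri) return a.pri > b.pri;
      return a.ord > b.ord;
    }
  };
  std::priority_queue<Item, std::vector<Item>, Cmp> pq;
  unsigned long ord = 0;
  std::vector<int> c(g.nd);
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (lab[i] <= 0) continue;
    g.coords(i, c);
    for (const auto &off : g.offs) {
      R_xlen_t q = g.neighbor(c, off);
      if (q >= 0 && mask[q] && lab[q] == 0)
        pq.push(Item{img[q], ord++, q, lab[i]});
    }
  }
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    if (lab[it.idx] != 0) continue;
    lab[it.idx] = it.label;
    g.coords(it.idx, c);
    for (const auto &off : g.offs) {
      R_xlen_t q = g.neighbor(c, off);
      if (q >= 0 && mask[q] && lab[q] == 0)
        pq.push(Item{img[q], ord++, q, it.label});
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Anisotropic squared Euclidean distance transform to the nearest `feature`
// voxel center (Felzenszwalb & Huttenlocher, separable lower-envelope passes).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dims, NumericVector spacing) {
  int nd = dims.size();
  R_xlen_t n = 1;
  std::vector<R_xlen_t> strides(nd);
  for (int a = 0; a < nd; ++a) { strides[a] = n; n *= dims[a]; }
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = feature[i] ? 0.0 : INF;

  std::vector<double> f, d, z;
  std::vector<int> v;
  for (int a = 0; a < nd; ++a) {
    int len = dims[a];
    if (len == 1) continue;
    double s2 = spacing[a] * spacing[a];
    f.assign(len, 0.0); d.assign(len, 0.0);
    v.assign(len + 1, 0); z.assign(len + 1, 0.0);
    R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // base index of this line
      R_xlen_t rem = line, base = 0;
      for (int b = 0; b < nd; ++b) {
        if (b == a) continue;
        R_xlen_t cb = rem % dims[b];
        rem /= dims[b];
        base += cb * strides[b];
      }
      for (int i = 0; i < len; ++i) f[i] = D[base + (R_xlen_t)i * strides[a]];
      // lower envelope of parabolas f[i] + s2*(q-i)^2
      int k = 0;
      v[0] = 0; z[0] = -INF; z[1] = INF;
      for (int q = 1; q < len; ++q) {
        if (f[q] == INF) continue;
        if (f[v[k]] == INF) { v[k] = q; continue; }
        double sct;
        while (true) {
          sct = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
                (2.0 * s2 * (q - v[k]));
          if (sct <= z[k]) { --k; } else break;
        }
        ++k; v[k] = q; z[k] = sct; z[k + 1] = INF;
      }
      if (f[v[0]] == INF) { // entire line infinite
        for (int q = 0; q < len; ++q) d[q] = INF;
      } else {
        int kk = 0;
        for (int q = 0; q < len; ++q) {
          while (z[kk + 1] < q) ++kk;
          d[q] = f[v[kk]] + s2 * (q - v[kk]) * (double)(q - v[kk]);
        }
      }
      for (int i = 0; i < len; ++i) D[base + (R_xlen_t)i * strides[a]] = d[i];
    }
  }
  D.attr("dim") = dims;
  return D;
}
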