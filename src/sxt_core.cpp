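#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D array helpers: R column-major layout, 0-based idx = i + j*d1 + k*d1*d2.

// Felzenszwalb & Huttenlocher 1D squared distance transform (lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary mask: per-voxel distance to
// the nearest zero (background) voxel centre. Foreground-free input gives 0s.
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  const double INF = 1e30;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f(std::max(d1, std::max(d2, d3)));
  std::vector<double> d(std::max(d1, std::max(d2, d3)));

  // pass along axis 1
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++) {
      R_xlen_t base = (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2;
      for (int i = 0; i < d1; i++) f[i] = g[base + i];
      dt1d(f, d, d1);
      for (int i = 0; i < d1; i++) g[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < d3; k++)
    for (int i = 0; i < d1; i++) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * d1 * d2;
      for (int j = 0; j < d2; j++) f[j] = g[base + (R_xlen_t)j * d1];
      dt1d(f, d, d2);
      for (int j = 0; j < d2; j++) g[base + (R_xlen_t)j * d1] = d[j];
    }
  // axis 3
  for (int j = 0; j < d2; j++)
    for (int i = 0; i < d1; i++) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * d1;
      for (int k = 0; k < d3; k++) f[k] = g[base + (R_xlen_t)k * d1 * d2];
      dt1d(f, d, d3);
      for (int k = 0; k < d3; k++) g[base + (R_xlen_t)k * d1 * d2] = d[k];
    }
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  return out;
}

// Local thickness by sphere painting (Hildebrand-style): every foreground
// voxel c with EDT radius r marks all voxels strictly inside its inscribed
// sphere with diameter 2r - 1 (voxel units); each voxel keeps the largest
// diameter of any inscribed sphere containing it.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector edt, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector th(n);

  std::vector<R_xlen_t> idx;
  idx.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; i++)
    if (edt[i] > 0) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (edt[a] != edt[b]) return edt[a] > edt[b];
    return a < b;
  });

  for (R_xlen_t c : idx) {
    const double r = edt[c];
    const double diam = 2.0 * r - 1.0;
    const int ci = c % d1, cj = (c / d1) % d2, ck = c / ((R_xlen_t)d1 * d2);
    const int rr = (int)std::ceil(r);
    const double r2 = r * r;
    for (int k = std::max(0, ck - rr); k <= std::min(d3 - 1, ck + rr); k++) {
      const double dk2 = (double)(k - ck) * (k - ck);
      for (int j = std::max(0, cj - rr); j <= std::min(d2 - 1, cj + rr); j++) {
        const double dj2 = (double)(j - cj) * (j - cj);
        if (dk2 + dj2 >= r2) continue;
        const int span = (int)std::floor(std::sqrt(r2 - dk2 - dj2 - 1e-12));
        R_xlen_t base = (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2;
        for (int i = std::max(0, ci - span); i <= std::min(d1 - 1, ci + span); i++) {
          const double dd = dk2 + dj2 + (double)(i - ci) * (i - ci);
          if (dd < r2 && th[base + i] < diam) th[base + i] = diam;
        }
      }
    }
  }
  return th;
}

// 26-connectivity connected-component labelling of a binary mask.
// Labels are assigned in scan order (deterministic), starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      const int ci = c % d1, cj = (c / d1) % d2, ck = c / ((R_xlen_t)d1 * d2);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            const int i = ci + di, j = cj + dj, k = ck + dk;
            if (i < 0 || i >= d1 || j < 0 || j >= d2 || k < 0 || k >= d3) continue;
            const R_xlen_t u = (R_xlen_t)i + (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2;
            if (mask[u] && !lab[u]) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
    }
  }
  return lab;
}

struct WsNode {
  double prio;      // EDT value: flood high EDT (basin cores) first
  long long order;  // insertion counter for deterministic tie-breaking
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on EDT
    return a.order > b.order;                      // FIFO among ties
  }
};

// Marker-based watershed on the Euclidean distance transform of a mask:
// seeds grow outward in order of decreasing EDT (equivalently, increasing
// -EDT relief), claiming 26-connected mask voxels.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector edt, IntegerVector mask,
                            IntegerVector seeds, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({edt[i], counter++, i});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    const R_xlen_t c = nd.idx;
    const int ci = c % d1, cj = (c / d1) % d2, ck = c / ((R_xlen_t)d1 * d2);
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (!di && !dj && !dk) continue;
          const int i = ci + di, j = cj + dj, k = ck + dk;
          if (i < 0 || i >= d1 || j < 0 || j >= d2 || k < 0 || k >= d3) continue;
          const R_xlen_t u = (R_xlen_t)i + (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2;
          if (mask[u] && !lab[u]) {
            lab[u] = lab[c];
            pq.push({edt[u], counter++, u});
          }
        }
  }
  return lab;
}
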