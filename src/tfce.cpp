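// Threshold-free cluster enhancement and max-statistic permutation null.
//
// TFCE(v) = sum over thresholds h = dh, 2dh, ... <= t_v of
//           e(h, v)^E * h^H * dh
// where e(h, v) is the size of the connected component containing v in
// the suprathreshold set {t >= h}.
//
// Thresholds are processed in descending order with a union-find over
// activating voxels; per-component increments are accumulated lazily via
// offset-carrying path compression, so one enhancement costs roughly
// O(V * alpha + sum_h #components) instead of O(V * #thresholds).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct OffsetUF {
  std::vector<int> parent, size;
  std::vector<double> delta;  // offset of node relative to its parent chain
  std::vector<double> acc;    // accumulated score of a root's component
  explicit OffsetUF(int n) : parent(n, -1), size(n, 0), delta(n, 0.0),
                             acc(n, 0.0) {}
  bool active(int v) const { return parent[v] >= 0; }
  void activate(int v) { parent[v] = v; size[v] = 1; }
  int find(int v) {
    int root = v;
    double sum = 0.0;
    while (parent[root] != root) { sum += delta[root]; root = parent[root]; }
    int cur = v;
    double s = sum;
    while (parent[cur] != root) {
      int nxt = parent[cur];
      double d = delta[cur];
      parent[cur] = root;
      delta[cur] = s;
      s -= d;
      cur = nxt;
    }
    return root;
  }
  // merge root b into root a (a, b distinct roots); returns surviving root
  int link(int a, int b) {
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    delta[b] = acc[b] - acc[a];
    size[a] += size[b];
    return a;
  }
  double resolve(int v) {
    int r = find(v);
    return (v == r) ? acc[v] : delta[v] + acc[r];
  }
};

struct Grid {
  int nx, ny, nz;
  std::vector<int> noff;  // linear neighbor offsets
  std::vector<int> dx, dy, dz;
  Grid(IntegerVector dims, int connectivity)
      : nx(dims[0]), ny(dims[1]), nz(dims[2]) {
    for (int k = -1; k <= 1; ++k)
      for (int j = -1; j <= 1; ++j)
        for (int i = -1; i <= 1; ++i) {
          if (i == 0 && j == 0 && k == 0) continue;
          if (connectivity == 6 && std::abs(i) + std::abs(j) + std::abs(k) != 1)
            continue;
          dx.push_back(i); dy.push_back(j); dz.push_back(k);
          noff.push_back(i + nx * (j + ny * k));
        }
  }
  int n() const { return nx * ny * nz; }
};

// TFCE of a non-negative map; adds results into out (caller zeroes it).
void tfce_nonneg(const double* x, const Grid& g, double E, double H,
                 double dh, int n_steps, double* out) {
  const int n = g.n();
  std::vector<int> order;
  order.reserve(n / 4);
  double hmax = 0.0;
  for (int v = 0; v < n; ++v)
    if (x[v] > 0.0) {
      order.push_back(v);
      if (x[v] > hmax) hmax = x[v];
    }
  if (order.empty()) return;
  if (dh <= 0.0) dh = hmax / n_steps;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return x[a] > x[b]; });
  int K = (int)std::floor(hmax / dh + 1e-9);
  if (K < 1) return;

  OffsetUF uf(n);
  std::vector<int> roots;
  size_t ptr = 0;
  for (int k = K; k >= 1; --k) {
    const double h = k * dh;
    while (ptr < order.size() && x[order[ptr]] >= h - 1e-12) {
      const int v = order[ptr++];
      uf.activate(v);
      roots.push_back(v);
      const int vx = v % g.nx, vy = (v / g.nx) % g.ny, vz = v / (g.nx * g.ny);
      for (size_t e = 0; e < g.noff.size(); ++e) {
        const int ux = vx + g.dx[e], uy = vy + g.dy[e], uz = vz + g.dz[e];
        if (ux < 0 || ux >= g.nx || uy < 0 || uy >= g.ny ||
            uz < 0 || uz >= g.nz)
          continue;
        const int u = v + g.noff[e];
        if (!uf.active(u)) continue;
        const int ra = uf.find(v), rb = uf.find(u);
        if (ra != rb) uf.link(ra, rb);
      }
    }
    // add this threshold's increment to every live component
    const double hterm = std::pow(h, H) * dh;
    size_t w = 0;
    for (size_t i = 0; i < roots.size(); ++i) {
      const int r = roots[i];
      if (uf.parent[r] == r) {
        uf.acc[r] += std::pow((double)uf.size[r], E) * hterm;
        roots[w++] = r;
      }
    }
    roots.resize(w);
  }
  for (size_t i = 0; i < order.size(); ++i) {
    const int v = order[i];
    if (uf.active(v)) out[v] += uf.resolve(v);
  }
}

double max_of(const std::vector<double>& v) {
  double m = 0.0;
  for (double x : v) if (x > m) m = x;
  return m;
}

}  // namespace

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims, double E,
                       double H, double dh, int n_steps, int connectivity) {
  Grid g(dims, connectivity);
  if (stat.size() != g.n()) stop("stat length does not match dims");
  const int n = g.n();
  std::vector<double> pos(n, 0.0), neg(n, 0.0), xp(n), xn(n);
  for (int v = 0; v < n; ++v) {
    xp[v] = stat[v] > 0 ? stat[v] : 0.0;
    xn[v] = stat[v] < 0 ? -stat[v] : 0.0;
  }
  tfce_nonneg(xp.data(), g, E, H, dh, n_steps, pos.data());
  tfce_nonneg(xn.data(), g, E, H, dh, n_steps, neg.data());
  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = pos[v] - neg[v];
  return out;
}

// Pooled-variance two-sample t per voxel for one labeling; zero pooled
// variance yields t = 0.
static void pooled_t(const double* data, int nvox, int nsub,
                     const int* labels, std::vector<double>& t) {
  int na = 0;
  for (int s = 0; s < nsub; ++s) na += labels[s];
  const int nb = nsub - na;
  std::vector<double> sa(nvox, 0.0), sa2(nvox, 0.0), sb(nvox, 0.0),
      sb2(nvox, 0.0);
  for (int s = 0; s < nsub; ++s) {
    const double* col = data + (size_t)s * nvox;
    if (labels[s]) {
      for (int v = 0; v < nvox; ++v) { sa[v] += col[v]; sa2[v] += col[v] * col[v]; }
    } else {
      for (int v = 0; v < nvox; ++v) { sb[v] += col[v]; sb2[v] += col[v] * col[v]; }
    }
  }
  const double inv = 1.0 / na + 1.0 / nb;
  const int df = na + nb - 2;
  for (int v = 0; v < nvox; ++v) {
    const double ma = sa[v] / na, mb = sb[v] / nb;
    const double ss = (sa2[v] - na * ma * ma) + (sb2[v] - nb * mb * mb);
    const double sp2 = ss / df;
    t[v] = (sp2 > 1e-24) ? (ma - mb) / std::sqrt(sp2 * inv) : 0.0;
  }
}

// Max TFCE (over both contrast signs) per permutation labeling.
// data: nvox x nsub column-major; perms: n_perm x nsub of 0/1 labels.
// [[Rcpp::export]]
NumericVector perm_max_tfce_cpp(NumericMatrix data, IntegerMatrix perms,
                                IntegerVector dims, double E, double H,
                                int n_steps, int connectivity) {
  Grid g(dims, connectivity);
  const int nvox = data.nrow(), nsub = data.ncol();
  if (nvox != g.n()) stop("data rows do not match dims");
  const int n_perm = perms.nrow();
  if (perms.ncol() != nsub) stop("perms columns must equal subject count");
  NumericVector out(n_perm);
  std::vector<double> t(nvox), xp(nvox), xn(nvox), enh(nvox);
  std::vector<int> labels(nsub);
  for (int p = 0; p < n_perm; ++p) {
    for (int s = 0; s < nsub; ++s) labels[s] = perms(p, s);
    pooled_t(REAL(data), nvox, nsub, labels.data(), t);
    for (int v = 0; v < nvox; ++v) {
      xp[v] = t[v] > 0 ? t[v] : 0.0;
      xn[v] = t[v] < 0 ? -t[v] : 0.0;
    }
    std::fill(enh.begin(), enh.end(), 0.0);
    tfce_nonneg(xp.data(), g, E, H, -1.0, n_steps, enh.data());
    const double mpos = max_of(enh);
    std::fill(enh.begin(), enh.end(), 0.0);
    tfce_nonneg(xn.data(), g, E, H, -1.0, n_steps, enh.data());
    out[p] = std::max(mpos, max_of(enh));
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Connected-component labeling of a logical mask (labels 1..K in scan
// order of the first voxel encountered).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Grid g(dims, connectivity);
  const int n = g.n();
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || lab[v0]) continue;
    ++next;
    lab[v0] = next;
    stack.push_back(v0);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int vx = v % g.nx, vy = (v / g.nx) % g.ny, vz = v / (g.nx * g.ny);
      for (size_t e = 0; e < g.noff.size(); ++e) {
        const int ux = vx + g.dx[e], uy = vy + g.dy[e], uz = vz + g.dz[e];
        if (ux < 0 || ux >= g.nx || uy < 0 || uy >= g.ny ||
            uz < 0 || uz >= g.nz)
          continue;
        const int u = v + g.noff[e];
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}
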