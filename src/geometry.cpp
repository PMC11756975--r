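#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Uniform-grid spatial index over an N x 3 coordinate matrix.
// Exact k-nearest-neighbour queries by expanding Chebyshev shells:
// after scanning all cells within shell radius s, any unscanned cell
// is at least s*h away, so the search stops once the running k-th
// best distance is <= s*h.
namespace {

struct Grid {
  int nx, ny, nz;
  double h;
  double ox, oy, oz;
  std::vector<int> cell_of;      // cell id per point
  std::vector<int> start;        // CSR offsets, length ncell+1
  std::vector<int> order;        // point ids grouped by cell
  const double* X;
  int n;

  int cx(double x) const {
    int i = (int)std::floor((x - ox) / h);
    return std::min(std::max(i, 0), nx - 1);
  }
  int cy(double y) const {
    int i = (int)std::floor((y - oy) / h);
    return std::min(std::max(i, 0), ny - 1);
  }
  int cz(double z) const {
    int i = (int)std::floor((z - oz) / h);
    return std::min(std::max(i, 0), nz - 1);
  }
  int cid(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }
};

// Choose a cell edge targeting ~`target` points per occupied cell.
// Falls back to a 2-D estimate when the cloud is a thin slab.
double pick_cell_size(double ex, double ey, double ez, int n, double target) {
  double h3 = std::cbrt(std::max(ex * ey * ez, 1e-300) * target / n);
  double h2 = std::sqrt(std::max(ex * ey, 1e-300) * target / n);
  double h = (ez < 0.5 * h3) ? h2 : h3;
  if (!std::isfinite(h) || h <= 0) h = std::max({ex, ey, ez, 1e-9}) / 16.0;
  return h;
}

Grid build_grid(const NumericMatrix& X, double target) {
  Grid g;
  g.n = X.nrow();
  g.X = REAL(X);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf;
    hi[d] = R_NegInf;
  }
  for (int i = 0; i < g.n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = g.X[i + d * g.n];
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double ex = hi[0] - lo[0], ey = hi[1] - lo[1], ez = hi[2] - lo[2];
  double h = pick_cell_size(std::max(ex, 1e-9), std::max(ey, 1e-9),
                            std::max(ez, 1e-12), g.n, target);
  // cap the grid at ~8n cells
  for (;;) {
    double ncell = std::ceil(std::max(ex, 1e-12) / h) *
                   std::ceil(std::max(ey, 1e-12) / h) *
                   std::ceil(std::max(ez, 1e-12) / h);
    if (ncell <= 8.0 * g.n + 64.0) break;
    h *= 1.26;
  }
  g.h = h;
  g.ox = lo[0];
  g.oy = lo[1];
  g.oz = lo[2];
  g.nx = std::max(1, (int)std::ceil(std::max(ex, 1e-12) / h));
  g.ny = std::max(1, (int)std::ceil(std::max(ey, 1e-12) / h));
  g.nz = std::max(1, (int)std::ceil(std::max(ez, 1e-12) / h));
  int ncell = g.nx * g.ny * g.nz;
  g.cell_of.resize(g.n);
  std::vector<int> cnt(ncell + 1, 0);
  for (int i = 0; i < g.n; ++i) {
    int c = g.cid(g.cx(g.X[i]), g.cy(g.X[i + g.n]), g.cz(g.X[i + 2 * g.n]));
    g.cell_of[i] = c;
    cnt[c + 1]++;
  }
  g.start.resize(ncell + 1);
  g.start[0] = 0;
  for (int c = 0; c < ncell; ++c) g.start[c + 1] = g.start[c] + cnt[c + 1];
  g.order.resize(g.n);
  std::vector<int> fill(g.start.begin(), g.start.end() - 1);
  for (int i = 0; i < g.n; ++i) g.order[fill[g.cell_of[i]]++] = i;
  return g;
}

// bounded max-heap of (dist2, index) keeping the k smallest
struct KBest {
  int k;
  std::vector<std::pair<double, int>> h;
  explicit KBest(int k_) : k(k_) { h.reserve(k_ + 1); }
  double worst() const {
    return (int)h.size() < k ? R_PosInf : h.front().first;
  }
  void push(double d2, int idx) {
    if ((int)h.size() < k) {
      h.emplace_back(d2, idx);
      std::push_heap(h.begin(), h.end());
    } else if (d2 < h.front().first) {
      std::pop_heap(h.begin(), h.end());
      h.back() = std::make_pair(d2, idx);
      std::push_heap(h.begin(), h.end());
    }
  }
};

// exact kNN of point i among all other points (self excluded)
void knn_query(const Grid& g, int i, KBest& best) {
  const double* X = g.X;
  const int n = g.n;
  double px = X[i], py = X[i + n], pz = X[i + 2 * n];
  int ix = g.cx(px), iy = g.cy(py), iz = g.cz(pz);
  int smax = std::max({g.nx, g.ny, g.nz});
  for (int s = 0; s <= smax; ++s) {
    // shells 0..s-1 are done: any unscanned cell is >= (s-1)*h away
    if (s >= 1 && (int)best.h.size() == best.k) {
      double bound = (double)(s - 1) * g.h;
      if (best.worst() <= bound * bound) break;
    }
    int xlo = std::max(ix - s, 0), xhi = std::min(ix + s, g.nx - 1);
    int ylo = std::max(iy - s, 0), yhi = std::min(iy + s, g.ny - 1);
    int zlo = std::max(iz - s, 0), zhi = std::min(iz + s, g.nz - 1);
    for (int cz2 = zlo; cz2 <= zhi; ++cz2)
      for (int cy2 = ylo; cy2 <= yhi; ++cy2)
        for (int cx2 = xlo; cx2 <= xhi; ++cx2) {
          // only the new shell (Chebyshev radius exactly s)
          int cheb = std::max({std::abs(cx2 - ix), std::abs(cy2 - iy),
                               std::abs(cz2 - iz)});
          if (cheb != s) continue;
          int c = g.cid(cx2, cy2, cz2);
          for (int t = g.start[c]; t < g.start[c + 1]; ++t) {
            int j = g.order[t];
            if (j == i) continue;
            double dx = X[j] - px, dy = X[j + n] - py, dz = X[j + 2 * n] - pz;
            best.push(dx * dx + dy * dy + dz * dz, j);
          }
        }
  }
}

// eigenvalues of a symmetric 3x3 matrix by cyclic Jacobi
void eig_sym3(double a[3][3], double ev[3]) {
  for (int sweep = 0; sweep < 32; ++sweep) {
    double off = a[0][1] * a[0][1] + a[0][2] * a[0][2] + a[1][2] * a[1][2];
    if (off < 1e-30) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        double app = a[p][p], aqq = a[q][q], apq = a[p][q];
        a[p][p] = c * c * app - 2 * s * c * apq + s * s * aqq;
        a[q][q] = s * s * app + 2 * s * c * apq + c * c * aqq;
        a[p][q] = a[q][p] = 0.0;
        for (int r = 0; r < 3; ++r) {
          if (r == p || r == q) continue;
          double arp = a[r][p], arq = a[r][q];
          a[r][p] = a[p][r] = c * arp - s * arq;
          a[r][q] = a[q][r] = s * arp + c * arq;
        }
      }
  }
  ev[0] = a[0][0];
  ev[1] = a[1][1];
  ev[2] = a[2][2];
  std::sort(ev, ev + 3);  // ascending
}

}  // namespace

// [[Rcpp::export(rng = false)]]
NumericVector cpp_knn_mean_dist(NumericMatrix X, int k) {
  int n = X.nrow();
  if (n <= k) stop("need more than k = %d points, got %d", k, n);
  Grid g = build_grid(X, 2.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    KBest best(k);
    knn_query(g, i, best);
    double s = 0;
    for (auto& p : best.h) s += std::sqrt(p.first);
    out[i] = s / k;
  }
  return out;
}

// Surface variation lambda_min / (l1+l2+l3) of the covariance of each
// point's neighbourhood (the point itself plus its k nearest neighbours).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_surface_variation(NumericMatrix X, int k) {
  int n = X.nrow();
  if (n <= k) stop("need more than k = %d points, got %d", k, n);
  Grid g = build_grid(X, std::min(8.0, std::max(2.0, k / 8.0)));
  const double* P = REAL(X);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    KBest best(k);
    knn_query(g, i, best);
    int m = (int)best.h.size() + 1;
    double mx = P[i], my = P[i + n], mz = P[i + 2 * n];
    for (auto& pr : best.h) {
      int j = pr.second;
      mx += P[j];
      my += P[j + n];
      mz += P[j + 2 * n];
    }
    mx /= m;
    my /= m;
    mz /= m;
    double c[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    auto acc = [&](int j) {
      double dx = P[j] - mx, dy = P[j + n] - my, dz = P[j + 2 * n] - mz;
      c[0][0] += dx * dx;
      c[0][1] += dx * dy;
      c[0][2] += dx * dz;
      c[1][1] += dy * dy;
      c[1][2] += dy * dz;
      c[2][2] += dz * dz;
    };
    acc(i);
    for (auto& pr : best.h) acc(pr.second);
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < p; ++q) c[p][q] = c[q][p];
    double ev[3];
    eig_sym3(c, ev);
    double tot = ev[0] + ev[1] + ev[2];
    out[i] = (tot > 0) ? std::max(0.0, ev[0]) / tot : 0.0;
  }
  return out;
}

// Greedy Poisson-disk thinning in input order: a point is kept iff no
// already-kept point lies within distance r. Deterministic.
// [[Rcpp::export(rng = false)]]
LogicalVector cpp_poisson_thin(NumericMatrix X, double r) {
  int n = X.nrow();
  LogicalVector keep(n);
  if (n == 0) return keep;
  if (r <= 0) {
    std::fill(keep.begin(), keep.end(), true);
    return keep;
  }
  const double* P = REAL(X);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) lo[d] = std::min(lo[d], P[i + d * n]);
  double h = r;
  double r2 = r * r;
  // open-addressing style: map cell triple -> kept point indices
  std::vector<std::array<int64_t, 3>> cell(n);
  struct H {
    size_t operator()(const std::array<int64_t, 3>& a) const {
      uint64_t h = 1469598103934665603ull;
      for (int d = 0; d < 3; ++d) {
        h ^= (uint64_t)a[d];
        h *= 1099511628211ull;
      }
      return (size_t)h;
    }
  };
  std::unordered_map<std::array<int64_t, 3>, std::vector<int>, H> buckets;
  buckets.reserve(n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      cell[i][d] = (int64_t)std::floor((P[i + d * n] - lo[d]) / h);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (int64_t dz = -1; dz <= 1 && ok; ++dz)
      for (int64_t dy = -1; dy <= 1 && ok; ++dy)
        for (int64_t dx = -1; dx <= 1 && ok; ++dx) {
          auto it = buckets.find({cell[i][0] + dx, cell[i][1] + dy, cell[i][2] + dz});
          if (it == buckets.end()) continue;
          for (int j : it->second) {
            double ddx = P[j] - P[i], ddy = P[j + n] - P[i + n],
                   ddz = P[j + 2 * n] - P[i + 2 * n];
            if (ddx * ddx + ddy * ddy + ddz * ddz < r2) {
              ok = false;
              break;
            }
          }
        }
    keep[i] = ok;
    if (ok) buckets[cell[i]].push_back(i);
  }
  return keep;
}

// Count distinct occupied voxels: index = floor((coord - origin)/edge),
// half-open cells. Exact (sort + unique on integer triples).
// [[Rcpp::export(rng = false)]]
double cpp_voxel_count(NumericMatrix X, double edge, NumericVector origin) {
  int n = X.nrow();
  if (n == 0) return 0;
  const double* P = REAL(X);
  std::vector<std::array<int64_t, 3>> v(n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      v[i][d] = (int64_t)std::floor((P[i + d * n] - origin[d]) / edge);
  std::sort(v.begin(), v.end());
  return (double)(std::unique(v.begin(), v.end()) - v.begin());
}
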