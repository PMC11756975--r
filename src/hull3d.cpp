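#include <Rcpp.h>
#include <array>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

// Quickhull in 3-D, volume only. Faces carry conflict lists (points that
// see them); the farthest conflict point is inserted, its visible region
// removed, and the horizon re-triangulated. Volume is the sum of signed
// tetrahedra from an interior point over the final facets.
namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int v[3];
  Vec3 nrm;      // outward, unit
  double off;    // plane offset: dot(nrm, p) = off
  bool alive = true;
  std::vector<int> conflict;
  int adj[3];    // neighbour across edge (v[e], v[(e+1)%3])
};

struct Hull {
  const std::vector<Vec3>& P;
  std::vector<Face> F;
  double eps;

  explicit Hull(const std::vector<Vec3>& pts, double eps_) : P(pts), eps(eps_) {}

  double dist(int f, int p) const { return dot(F[f].nrm, P[p]) - F[f].off; }

  int add_face(int a, int b, int c, const Vec3& inside) {
    Face f;
    f.v[0] = a;
    f.v[1] = b;
    f.v[2] = c;
    Vec3 n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    double L = norm(n);
    if (L > 0) {
      n.x /= L;
      n.y /= L;
      n.z /= L;
    }
    f.nrm = n;
    f.off = dot(n, P[a]);
    if (dot(n, inside) - f.off > 0) {  // flip to point away from interior
      std::swap(f.v[1], f.v[2]);
      f.nrm = {-n.x, -n.y, -n.z};
      f.off = -f.off;
    }
    f.adj[0] = f.adj[1] = f.adj[2] = -1;
    F.push_back(f);
    return (int)F.size() - 1;
  }
};

}  // namespace

// [[Rcpp::export(rng = false)]]
List cpp_convex_hull_volume(NumericMatrix X) {
  int n = X.nrow();
  auto degenerate = [](double vol) {
    return List::create(_["volume"] = vol, _["degenerate"] = true,
                        _["n_vertices"] = 0);
  };
  if (n < 4) return degenerate(0.0);

  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {X(i, 0), X(i, 1), X(i, 2)};

  // scale-aware tolerance
  Vec3 lo = P[0], hi = P[0];
  for (auto& p : P) {
    lo = {std::min(lo.x, p.x), std::min(lo.y, p.y), std::min(lo.z, p.z)};
    hi = {std::max(hi.x, p.x), std::max(hi.y, p.y), std::max(hi.z, p.z)};
  }
  double diag = norm(sub(hi, lo));
  if (diag <= 0) return degenerate(0.0);
  double eps = 1e-12 * diag;

  // initial simplex: extreme pair, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  {
    double best = -1;
    int ext[6];
    for (int d = 0; d < 6; ++d) ext[d] = 0;
    for (int i = 0; i < n; ++i) {
      if (P[i].x < P[ext[0]].x) ext[0] = i;
      if (P[i].x > P[ext[1]].x) ext[1] = i;
      if (P[i].y < P[ext[2]].y) ext[2] = i;
      if (P[i].y > P[ext[3]].y) ext[3] = i;
      if (P[i].z < P[ext[4]].z) ext[4] = i;
      if (P[i].z > P[ext[5]].z) ext[5] = i;
    }
    for (int a = 0; a < 6; ++a)
      for (int b = a + 1; b < 6; ++b) {
        double d = norm(sub(P[ext[a]], P[ext[b]]));
        if (d > best) {
          best = d;
          i0 = ext[a];
          i1 = ext[b];
        }
      }
    if (best <= eps) return degenerate(0.0);
  }
  int i2 = -1;
  {
    double best = eps;
    Vec3 d01 = sub(P[i1], P[i0]);
    double L = norm(d01);
    for (int i = 0; i < n; ++i) {
      double d = norm(cross(d01, sub(P[i], P[i0]))) / L;
      if (d > best) {
        best = d;
        i2 = i;
      }
    }
    if (i2 < 0) return degenerate(0.0);  // collinear
  }
  int i3 = -1;
  Vec3 nrm0 = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  {
    double L = norm(nrm0);
    double best = eps;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dot(nrm0, sub(P[i], P[i0]))) / L;
      if (d > best) {
        best = d;
        i3 = i;
      }
    }
    if (i3 < 0) return degenerate(0.0);  // coplanar
  }

  Vec3 inside = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4,
                 (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4,
                 (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4};
  Hull H(P, eps);
  H.add_face(i0, i1, i2, inside);
  H.add_face(i0, i1, i3, inside);
  H.add_face(i0, i2, i3, inside);
  H.add_face(i1, i2, i3, inside);

  auto link = [&](int fa, int fb) {
    for (int ea = 0; ea < 3; ++ea) {
      int a1 = H.F[fa].v[ea], a2 = H.F[fa].v[(ea + 1) % 3];
      for (int eb = 0; eb < 3; ++eb) {
        int b1 = H.F[fb].v[eb], b2 = H.F[fb].v[(eb + 1) % 3];
        if ((a1 == b1 && a2 == b2) || (a1 == b2 && a2 == b1)) {
          H.F[fa].adj[ea] = fb;
          H.F[fb].adj[eb] = fa;
        }
      }
    }
  };
  for (int a = 0; a < 4; ++a)
    for (int b = a + 1; b < 4; ++b) link(a, b);

  // initial conflict assignment
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    for (int f = 0; f < 4; ++f)
      if (H.dist(f, p) > H.eps) {
        H.F[f].conflict.push_back(p);
        break;
      }
  }

  std::vector<int> pending;
  for (int f = 0; f < 4; ++f)
    if (!H.F[f].conflict.empty()) pending.push_back(f);

  std::vector<char> in_visible;
  while (!pending.empty()) {
    int f = pending.back();
    if (!H.F[f].alive || H.F[f].conflict.empty()) {
      pending.pop_back();
      continue;
    }
    // farthest conflict point of face f
    int p = -1;
    double best = -1;
    for (int q : H.F[f].conflict) {
      double d = H.dist(f, q);
      if (d > best) {
        best = d;
        p = q;
      }
    }
    if (p < 0 || best <= H.eps) {
      H.F[f].conflict.clear();
      pending.pop_back();
      continue;
    }
    // BFS over faces visible from p
    std::vector<int> visible{f};
    in_visible.assign(H.F.size(), 0);
    in_visible[f] = 1;
    std::vector<std::pair<int, int>> horizon;  // (visible face, edge)
    for (size_t qi = 0; qi < visible.size(); ++qi) {
      int g = visible[qi];
      for (int e = 0; e < 3; ++e) {
        int nb = H.F[g].adj[e];
        if (nb < 0) continue;
        if (in_visible[nb]) continue;
        if (H.F[nb].alive && H.dist(nb, p) > H.eps) {
          in_visible[nb] = 1;
          visible.push_back(nb);
        } else {
          horizon.emplace_back(g, e);
        }
      }
    }
    // collect orphaned conflict points, kill visible faces
    std::vector<int> orphans;
    for (int g : visible) {
      for (int q : H.F[g].conflict)
        if (q != p) orphans.push_back(q);
      H.F[g].conflict.clear();
      H.F[g].alive = false;
    }
    // build the new cone of faces over the horizon
    std::vector<int> fresh;
    std::map<std::pair<int, int>, std::pair<int, int>> edge_owner;
    for (auto& he : horizon) {
      int g = he.first, e = he.second;
      int a = H.F[g].v[e], b = H.F[g].v[(e + 1) % 3];
      int nf = H.add_face(a, b, p, inside);
      in_visible.push_back(0);
      // link across the horizon edge
      int outside = H.F[g].adj[e];
      if (outside >= 0) link(nf, outside);
      fresh.push_back(nf);
      // register the two side edges for cone-internal linking
      for (int e2 = 0; e2 < 3; ++e2) {
        int u = H.F[nf].v[e2], v = H.F[nf].v[(e2 + 1) % 3];
        if (u != p && v != p) continue;
        auto key = std::make_pair(std::min(u, v), std::max(u, v));
        auto it = edge_owner.find(key);
        if (it == edge_owner.end()) {
          edge_owner[key] = {nf, e2};
        } else {
          H.F[nf].adj[e2] = it->second.first;
          H.F[it->second.first].adj[it->second.second] = nf;
        }
      }
    }
    // redistribute orphans
    for (int q : orphans) {
      for (int nf : fresh)
        if (H.dist(nf, q) > H.eps) {
          H.F[nf].conflict.push_back(q);
          break;
        }
    }
    for (int nf : fresh)
      if (!H.F[nf].conflict.empty()) pending.push_back(nf);
  }

  double vol = 0;
  std::vector<char> used(n, 0);
  for (auto& f : H.F) {
    if (!f.alive) continue;
    Vec3 a = sub(P[f.v[0]], inside), b = sub(P[f.v[1]], inside),
         c = sub(P[f.v[2]], inside);
    vol += dot(a, cross(b, c)) / 6.0;
    used[f.v[0]] = used[f.v[1]] = used[f.v[2]] = 1;
  }
  int nv = 0;
  for (int i = 0; i < n; ++i) nv += used[i];
  return List::create(_["volume"] = std::fabs(vol), _["degenerate"] = false,
                      _["n_vertices"] = nv);
}
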