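// Geometry kernels: ray casting against solid primitives, point-in-solid
// tests, voxelized volume, brute-force kNN, PCA normal estimation with
// BFS orientation propagation, trilinear splatting/sampling on a uniform
// grid, and marching-tetrahedra isosurface extraction.
//
// Primitive encoding (one row per solid, 10 doubles):
//   type 1 sphere    : cx cy cz r
//   type 2 ellipsoid : cx cy cz ax ay az            (axis-aligned semi-axes)
//   type 3 capsule   : x0 y0 z0 x1 y1 z1 r
//   type 4 cylinder  : x0 y0 z0 x1 y1 z1 r          (flat caps)
//   type 5 box       : xmin ymin zmin xmax ymax zmax
#include <RcppArmadillo.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static const double TMIN = 1e-9;
static const double INF = std::numeric_limits<double>::infinity();

struct V3 {
  double x, y, z;
  V3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  double dot(const V3& o) const { return x * o.x + y * o.y + z * o.z; }
  V3 cross(const V3& o) const {
    return V3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

// smallest positive root of A t^2 + B t + C = 0, or INF
static double quad_root(double A, double B, double C) {
  if (std::fabs(A) < 1e-300) {
    if (std::fabs(B) < 1e-300) return INF;
    double t = -C / B;
    return t > TMIN ? t : INF;
  }
  double disc = B * B - 4.0 * A * C;
  if (disc < 0) return INF;
  double s = std::sqrt(disc);
  double q = (B < 0) ? -0.5 * (B - s) : -0.5 * (B + s);
  double t0 = q / A, t1 = (std::fabs(q) < 1e-300) ? INF : C / q;
  if (t0 > t1) std::swap(t0, t1);
  if (t0 > TMIN) return t0;
  if (t1 > TMIN) return t1;
  return INF;
}

static double hit_sphere(const V3& o, const V3& d, const V3& c, double r) {
  V3 m = o - c;
  return quad_root(d.dot(d), 2.0 * m.dot(d), m.dot(m) - r * r);
}

static double hit_ellipsoid(const V3& o, const V3& d, const V3& c, const V3& s) {
  V3 q((o.x - c.x) / s.x, (o.y - c.y) / s.y, (o.z - c.z) / s.z);
  V3 w(d.x / s.x, d.y / s.y, d.z / s.z);
  return quad_root(w.dot(w), 2.0 * q.dot(w), q.dot(q) - 1.0);
}

// capsule: cylinder side within [0,L] plus spherical caps
static double hit_capsule(const V3& o, const V3& d, const V3& p0, const V3& p1,
                          double r) {
  V3 ax = p1 - p0;
  double L = ax.norm();
  double best = INF;
  if (L < 1e-300) return hit_sphere(o, d, p0, r);
  V3 a = ax * (1.0 / L);
  V3 m = o - p0;
  double md = m.dot(a), nd = d.dot(a);
  V3 mp = m - a * md, np = d - a * nd;
  double t = quad_root(np.dot(np), 2.0 * mp.dot(np), mp.dot(mp) - r * r);
  if (t < INF) {
    double s = md + t * nd;
    if (s >= 0 && s <= L) best = t;
  }
  double tc = hit_sphere(o, d, p0, r);
  if (tc < best && (md + tc * nd) < 0) best = tc;
  tc = hit_sphere(o, d, p1, r);
  if (tc < best && (md + tc * nd) > L) best = tc;
  return best;
}

static double hit_cylinder(const V3& o, const V3& d, const V3& p0, const V3& p1,
                           double r) {
  V3 ax = p1 - p0;
  double L = ax.norm();
  if (L < 1e-300) return INF;
  V3 a = ax * (1.0 / L);
  V3 m = o - p0;
  double md = m.dot(a), nd = d.dot(a);
  V3 mp = m - a * md, np = d - a * nd;
  double best = INF;
  double t = quad_root(np.dot(np), 2.0 * mp.dot(np), mp.dot(mp) - r * r);
  if (t < INF) {
    double s = md + t * nd;
    if (s >= 0 && s <= L) best = t;
  }
  if (std::fabs(nd) > 1e-300) {
    for (int cap = 0; cap < 2; ++cap) {
      double s = cap == 0 ? 0.0 : L;
      double tc = (s - md) / nd;
      if (tc > TMIN && tc < best) {
        V3 q = m + d * tc - a * s;
        if (q.dot(q) <= r * r) best = tc;
      }
    }
  }
  return best;
}

static double hit_box(const V3& o, const V3& d, const V3& lo, const V3& hi) {
  double t0 = -INF, t1 = INF;
  const double ov[3] = {o.x, o.y, o.z}, dv[3] = {d.x, d.y, d.z};
  const double lv[3] = {lo.x, lo.y, lo.z}, hv[3] = {hi.x, hi.y, hi.z};
  for (int i = 0; i < 3; ++i) {
    if (std::fabs(dv[i]) < 1e-300) {
      if (ov[i] < lv[i] || ov[i] > hv[i]) return INF;
    } else {
      double a = (lv[i] - ov[i]) / dv[i], b = (hv[i] - ov[i]) / dv[i];
      if (a > b) std::swap(a, b);
      t0 = std::max(t0, a);
      t1 = std::min(t1, b);
      if (t0 > t1) return INF;
    }
  }
  if (t0 > TMIN) return t0;
  if (t1 > TMIN) return t1;
  return INF;
}

static double hit_prim(const V3& o, const V3& d, const double* p) {
  int type = (int)p[0];
  switch (type) {
    case 1: return hit_sphere(o, d, V3(p[1], p[2], p[3]), p[4]);
    case 2: return hit_ellipsoid(o, d, V3(p[1], p[2], p[3]), V3(p[4], p[5], p[6]));
    case 3: return hit_capsule(o, d, V3(p[1], p[2], p[3]), V3(p[4], p[5], p[6]), p[7]);
    case 4: return hit_cylinder(o, d, V3(p[1], p[2], p[3]), V3(p[4], p[5], p[6]), p[7]);
    case 5: return hit_box(o, d, V3(p[1], p[2], p[3]), V3(p[4], p[5], p[6]));
    default: return INF;
  }
}

static bool inside_prim(const V3& q, const double* p) {
  int type = (int)p[0];
  switch (type) {
    case 1: {
      V3 m = q - V3(p[1], p[2], p[3]);
      return m.dot(m) <= p[4] * p[4];
    }
    case 2: {
      double a = (q.x - p[1]) / p[4], b = (q.y - p[2]) / p[5], c = (q.z - p[3]) / p[6];
      return a * a + b * b + c * c <= 1.0;
    }
    case 3: {
      V3 p0(p[1], p[2], p[3]), p1(p[4], p[5], p[6]);
      V3 ax = p1 - p0;
      double L2 = ax.dot(ax);
      double t = L2 < 1e-300 ? 0.0 : std::min(1.0, std::max(0.0, (q - p0).dot(ax) / L2));
      V3 c = p0 + ax * t;
      V3 m = q - c;
      return m.dot(m) <= p[7] * p[7];
    }
    case 4: {
      V3 p0(p[1], p[2], p[3]), p1(p[4], p[5], p[6]);
      V3 ax = p1 - p0;
      double L = ax.norm();
      if (L < 1e-300) return false;
      V3 a = ax * (1.0 / L);
      double s = (q - p0).dot(a);
      if (s < 0 || s > L) return false;
      V3 m = q - (p0 + a * s);
      return m.dot(m) <= p[7] * p[7];
    }
    case 5:
      return q.x >= p[1] && q.y >= p[2] && q.z >= p[3] && q.x <= p[4] &&
             q.y <= p[5] && q.z <= p[6];
    default: return false;
  }
}

// [[Rcpp::export]]
List cpp_ray_cast(NumericVector origin, NumericMatrix dirs, NumericMatrix prims) {
  int n = dirs.nrow(), k = prims.nrow();
  V3 o(origin[0], origin[1], origin[2]);
  NumericVector tout(n);
  IntegerVector hout(n);
  std::vector<std::array<double, 10>> P(k);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < 10; ++c) P[j][c] = prims(j, c);
  for (int i = 0; i < n; ++i) {
    V3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    double best = INF;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double t = hit_prim(o, d, P[j].data());
      if (t < best) { best = t; bj = j + 1; }
    }
    tout[i] = best;
    hout[i] = best < INF ? bj : 0;
  }
  return List::create(_["t"] = tout, _["hit"] = hout);
}

// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix pts, NumericMatrix prims) {
  int n = pts.nrow(), k = prims.nrow();
  std::vector<std::array<double, 10>> P(k);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < 10; ++c) P[j][c] = prims(j, c);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    V3 q(pts(i, 0), pts(i, 1), pts(i, 2));
    bool in = false;
    for (int j = 0; j < k && !in; ++j) in = inside_prim(q, P[j].data());
    out[i] = in;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_voxel_volume(NumericMatrix prims, NumericVector lo, NumericVector hi,
                        double h) {
  int k = prims.nrow();
  std::vector<std::array<double, 10>> P(k);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < 10; ++c) P[j][c] = prims(j, c);
  long nx = (long)std::ceil((hi[0] - lo[0]) / h);
  long ny = (long)std::ceil((hi[1] - lo[1]) / h);
  long nz = (long)std::ceil((hi[2] - lo[2]) / h);
  long long count = 0;
  for (long iz = 0; iz < nz; ++iz) {
    double z = lo[2] + (iz + 0.5) * h;
    for (long iy = 0; iy < ny; ++iy) {
      double y = lo[1] + (iy + 0.5) * h;
      for (long ix = 0; ix < nx; ++ix) {
        V3 q(lo[0] + (ix + 0.5) * h, y, z);
        for (int j = 0; j < k; ++j) {
          if (inside_prim(q, P[j].data())) { ++count; break; }
        }
      }
    }
  }
  return (double)count * h * h * h;
}

// k nearest neighbours of each query row among ref rows (brute force).
// Returns 1-based indices and distances, both n x k.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k) {
  int n = query.nrow(), m = ref.nrow();
  if (k > m) stop("k exceeds reference size");
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<std::pair<double, int>> d(m);
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      d[j] = {dx * dx + dy * dy + dz * dz, j};
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int c = 0; c < k; ++c) {
      idx(i, c) = d[c].second + 1;
      dst(i, c) = std::sqrt(d[c].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// kNN via a uniform spatial hash: points are bucketed into cells of edge
// `cell`; each query expands cube shells until the k-th best distance is
// provably reached. Orders of magnitude faster than brute force on the
// dense, locally uniform clouds produced by depth images.
// [[Rcpp::export]]
List cpp_knn_grid(NumericMatrix query, NumericMatrix ref, int k, double cell) {
  int n = query.nrow(), m = ref.nrow();
  if (k > m) stop("k exceeds reference size");
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < 3; ++c) lo[c] = std::min(lo[c], ref(j, c));
  auto cell_of = [&](double x, int c) {
    return (int64_t)std::floor((x - lo[c]) / cell);
  };
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  auto key_of = [](int64_t i, int64_t j, int64_t l) {
    return ((uint64_t)(i & 0x1FFFFF) << 42) | ((uint64_t)(j & 0x1FFFFF) << 21) |
           (uint64_t)(l & 0x1FFFFF);
  };
  buckets.reserve(m);
  for (int j = 0; j < m; ++j)
    buckets[key_of(cell_of(ref(j, 0), 0), cell_of(ref(j, 1), 1),
                   cell_of(ref(j, 2), 2))].push_back(j);
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<std::pair<double, int>> heap;  // max-heap of best k (d2, idx)
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int64_t ci = cell_of(qx, 0), cj = cell_of(qy, 1), ck = cell_of(qz, 2);
    heap.clear();
    for (int r = 0;; ++r) {
      // visit the shell of cube radius r
      for (int64_t di = -r; di <= r; ++di)
        for (int64_t dj = -r; dj <= r; ++dj)
          for (int64_t dk = -r; dk <= r; ++dk) {
            if (std::max({std::llabs(di), std::llabs(dj), std::llabs(dk)}) != r)
              continue;
            auto it = buckets.find(key_of(ci + di, cj + dj, ck + dk));
            if (it == buckets.end()) continue;
            for (int j : it->second) {
              double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy,
                     dz = ref(j, 2) - qz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if ((int)heap.size() < k) {
                heap.push_back({d2, j});
                std::push_heap(heap.begin(), heap.end());
              } else if (d2 < heap.front().first) {
                std::pop_heap(heap.begin(), heap.end());
                heap.back() = {d2, j};
                std::push_heap(heap.begin(), heap.end());
              }
            }
          }
      // shells beyond r cannot beat the current k-th distance once
      // r*cell exceeds it (query sits somewhere inside its own cell)
      if ((int)heap.size() == k) {
        double bound = (double)r * cell;
        if (bound * bound >= heap.front().first) break;
      }
      if (r > 0 && (double)r * cell > 1e9) stop("knn grid search diverged");
    }
    std::sort_heap(heap.begin(), heap.end());
    for (int c = 0; c < k; ++c) {
      idx(i, c) = heap[c].second + 1;
      dst(i, c) = std::sqrt(heap[c].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// PCA normals: smallest-eigenvector of the local covariance over the kNN
// neighbourhood given by idx (1-based, n x k, typically includes self).
// [[Rcpp::export]]
NumericMatrix cpp_pca_normals(NumericMatrix pts, IntegerMatrix idx) {
  int n = pts.nrow(), k = idx.ncol();
  NumericMatrix out(n, 3);
  arma::mat33 C;
  arma::vec3 eigval;
  arma::mat33 eigvec;
  for (int i = 0; i < n; ++i) {
    double mx = 0, my = 0, mz = 0;
    for (int c = 0; c < k; ++c) {
      int j = idx(i, c) - 1;
      mx += pts(j, 0); my += pts(j, 1); mz += pts(j, 2);
    }
    mx /= k; my /= k; mz /= k;
    C.zeros();
    for (int c = 0; c < k; ++c) {
      int j = idx(i, c) - 1;
      double dx = pts(j, 0) - mx, dy = pts(j, 1) - my, dz = pts(j, 2) - mz;
      C(0, 0) += dx * dx; C(0, 1) += dx * dy; C(0, 2) += dx * dz;
      C(1, 1) += dy * dy; C(1, 2) += dy * dz; C(2, 2) += dz * dz;
    }
    C(1, 0) = C(0, 1); C(2, 0) = C(0, 2); C(2, 1) = C(1, 2);
    arma::eig_sym(eigval, eigvec, C);
    out(i, 0) = eigvec(0, 0);
    out(i, 1) = eigvec(1, 0);
    out(i, 2) = eigvec(2, 0);
  }
  return out;
}

// Orient normals consistently: BFS over the kNN graph per connected
// component, flipping a neighbour when it disagrees with its parent; each
// component is seeded at its point farthest from the component centroid,
// with the seed normal pointing away from the centroid.
// [[Rcpp::export]]
NumericMatrix cpp_orient_normals(NumericMatrix pts, NumericMatrix normals,
                                 IntegerMatrix idx) {
  int n = pts.nrow(), k = idx.ncol();
  NumericMatrix out(clone(normals));
  std::vector<int> comp(n, -1);
  int nc = 0;
  // connected components over the (directed) kNN graph treated as undirected
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < k; ++c) {
      int j = idx(i, c) - 1;
      if (j != i) { adj[i].push_back(j); adj[j].push_back(i); }
    }
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    std::queue<int> q;
    q.push(s);
    comp[s] = nc;
    std::vector<int> members;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      members.push_back(u);
      for (int v : adj[u]) if (comp[v] < 0) { comp[v] = nc; q.push(v); }
    }
    // seed: farthest from centroid, oriented away from centroid
    double cx = 0, cy = 0, cz = 0;
    for (int u : members) { cx += pts(u, 0); cy += pts(u, 1); cz += pts(u, 2); }
    cx /= members.size(); cy /= members.size(); cz /= members.size();
    int seed = members[0];
    double best = -1;
    for (int u : members) {
      double dx = pts(u, 0) - cx, dy = pts(u, 1) - cy, dz = pts(u, 2) - cz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; seed = u; }
    }
    double dx = pts(seed, 0) - cx, dy = pts(seed, 1) - cy, dz = pts(seed, 2) - cz;
    if (out(seed, 0) * dx + out(seed, 1) * dy + out(seed, 2) * dz < 0) {
      out(seed, 0) = -out(seed, 0); out(seed, 1) = -out(seed, 1);
      out(seed, 2) = -out(seed, 2);
    }
    std::vector<char> done(n, 0);
    std::queue<int> q2;
    q2.push(seed);
    done[seed] = 1;
    while (!q2.empty()) {
      int u = q2.front(); q2.pop();
      for (int v : adj[u]) {
        if (done[v]) continue;
        done[v] = 1;
        if (out(u, 0) * out(v, 0) + out(u, 1) * out(v, 1) +
            out(u, 2) * out(v, 2) < 0) {
          out(v, 0) = -out(v, 0); out(v, 1) = -out(v, 1); out(v, 2) = -out(v, 2);
        }
        q2.push(v);
      }
    }
    ++nc;
  }
  return out;
}

// Trilinear splat of per-point vectors into a (nx, ny, nz) grid (x fastest).
// Returns list of 3 arrays plus a weight array.
// [[Rcpp::export]]
List cpp_splat_normals(NumericMatrix pts, NumericMatrix vec, IntegerVector dims,
                       NumericVector origin, double h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector Vx(N), Vy(N), Vz(N), W(N);
  int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    double fx = (pts(i, 0) - origin[0]) / h;
    double fy = (pts(i, 1) - origin[1]) / h;
    double fz = (pts(i, 2) - origin[2]) / h;
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= nx - 1 || j0 >= ny - 1 || k0 >= nz - 1)
      continue;
    double ax = fx - i0, ay = fy - j0, az = fz - k0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dxx = 0; dxx < 2; ++dxx) {
          double w = (dxx ? ax : 1 - ax) * (dy ? ay : 1 - ay) * (dz ? az : 1 - az);
          size_t id = (size_t)(i0 + dxx) + (size_t)nx * ((j0 + dy) + (size_t)ny * (k0 + dz));
          Vx[id] += w * vec(i, 0);
          Vy[id] += w * vec(i, 1);
          Vz[id] += w * vec(i, 2);
          W[id] += w;
        }
  }
  return List::create(_["Vx"] = Vx, _["Vy"] = Vy, _["Vz"] = Vz, _["W"] = W);
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dims,
                            NumericVector origin, double h, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double fx = (pts(i, 0) - origin[0]) / h;
    double fy = (pts(i, 1) - origin[1]) / h;
    double fz = (pts(i, 2) - origin[2]) / h;
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    if (i0 < 0) { i0 = 0; fx = 0; } if (j0 < 0) { j0 = 0; fy = 0; }
    if (k0 < 0) { k0 = 0; fz = 0; }
    if (i0 >= nx - 1) { i0 = nx - 2; fx = nx - 1; }
    if (j0 >= ny - 1) { j0 = ny - 2; fy = ny - 1; }
    if (k0 >= nz - 1) { k0 = nz - 2; fz = nz - 1; }
    double ax = fx - i0, ay = fy - j0, az = fz - k0;
    double acc = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dxx = 0; dxx < 2; ++dxx) {
          double w = (dxx ? ax : 1 - ax) * (dy ? ay : 1 - ay) * (dz ? az : 1 - az);
          size_t id = (size_t)(i0 + dxx) + (size_t)nx * ((j0 + dy) + (size_t)ny * (k0 + dz));
          acc += w * field[id];
        }
    out[i] = acc;
  }
  return out;
}

// Marching tetrahedra over a uniform grid. Each cube is split into the six
// tetrahedra around its main diagonal; the split is conforming across
// neighbouring cubes, and interpolated edge vertices are shared through a
// hash map, so the extracted surface is watertight and consistently
// oriented (triangle normals point towards field values above iso).
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector origin, double h, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int CO[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int TETS[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;
  uint64_t NTOT = (uint64_t)nx * ny * nz;

  auto gidx = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  auto edge_vertex = [&](uint64_t ga, uint64_t gb, double va, double vb,
                         const double pa[3], const double pb[3]) -> int {
    uint64_t key = ga < gb ? ga * NTOT + gb : gb * NTOT + ga;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 1e-6) t = 1e-6;
    if (t > 1 - 1e-6) t = 1 - 1e-6;
    VX.push_back(pa[0] + t * (pb[0] - pa[0]));
    VY.push_back(pa[1] + t * (pb[1] - pa[1]));
    VZ.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)VX.size();  // 1-based
    vmap[key] = id;
    return id;
  };
  // NOTE: for dedup correctness the interpolated position must not depend on
  // the direction the edge is visited; enforce canonical order:
  auto edge_vertex_canon = [&](uint64_t ga, uint64_t gb, double va, double vb,
                               const double pa[3], const double pb[3]) -> int {
    if (ga <= gb) return edge_vertex(ga, gb, va, vb, pa, pb);
    return edge_vertex(gb, ga, vb, va, pb, pa);
  };

  auto emit = [&](int a, int b, int c, const double w[3]) {
    // orient so normal has positive dot with w (inside -> outside direction)
    double ux = VX[b - 1] - VX[a - 1], uy = VY[b - 1] - VY[a - 1], uz = VZ[b - 1] - VZ[a - 1];
    double vx = VX[c - 1] - VX[a - 1], vy = VY[c - 1] - VY[a - 1], vz = VZ[c - 1] - VZ[a - 1];
    double nxv = uy * vz - uz * vy, nyv = uz * vx - ux * vz, nzv = ux * vy - uy * vx;
    if (nxv * w[0] + nyv * w[1] + nzv * w[2] < 0) std::swap(b, c);
    F.push_back(a); F.push_back(b); F.push_back(c);
  };

  double P[8][3];
  double V[8];
  uint64_t G[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CO[c][0], jj = j + CO[c][1], kk = k + CO[c][2];
          G[c] = gidx(ii, jj, kk);
          V[c] = field[G[c]];
          P[c][0] = origin[0] + ii * h;
          P[c][1] = origin[1] + jj * h;
          P[c][2] = origin[2] + kk * h;
          if (V[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4], nin = 0;
          const int* T = TETS[t];
          int ins[4], outs[4];
          int nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (V[T[c]] > iso) ins[nin++] = T[c]; else outs[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) ci[d] += P[ins[c]][d] / nin;
          for (int c = 0; c < nout; ++c)
            for (int d = 0; d < 3; ++d) co[d] += P[outs[c]][d] / nout;
          double w[3] = {co[0] - ci[0], co[1] - ci[1], co[2] - ci[2]};
          if (nin == 1) {
            int a = ins[0];
            int e0 = edge_vertex_canon(G[a], G[outs[0]], V[a], V[outs[0]], P[a], P[outs[0]]);
            int e1 = edge_vertex_canon(G[a], G[outs[1]], V[a], V[outs[1]], P[a], P[outs[1]]);
            int e2 = edge_vertex_canon(G[a], G[outs[2]], V[a], V[outs[2]], P[a], P[outs[2]]);
            emit(e0, e1, e2, w);
          } else if (nin == 3) {
            int a = outs[0];
            int e0 = edge_vertex_canon(G[ins[0]], G[a], V[ins[0]], V[a], P[ins[0]], P[a]);
            int e1 = edge_vertex_canon(G[ins[1]], G[a], V[ins[1]], V[a], P[ins[1]], P[a]);
            int e2 = edge_vertex_canon(G[ins[2]], G[a], V[ins[2]], V[a], P[ins[2]], P[a]);
            emit(e0, e1, e2, w);
          } else {
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int q0 = edge_vertex_canon(G[a], G[c], V[a], V[c], P[a], P[c]);
            int q1 = edge_vertex_canon(G[a], G[d], V[a], V[d], P[a], P[d]);
            int q2 = edge_vertex_canon(G[b], G[d], V[b], V[d], P[b], P[d]);
            int q3 = edge_vertex_canon(G[b], G[c], V[b], V[c], P[b], P[c]);
            emit(q0, q1, q2, w);
            emit(q0, q2, q3, w);
          }
          (void)vi;
        }
      }
  int nv = (int)VX.size(), nf = (int)F.size() / 3;
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) { Vm(i, 0) = VX[i]; Vm(i, 1) = VY[i]; Vm(i, 2) = VZ[i]; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = F[3 * i]; Fm(i, 1) = F[3 * i + 1]; Fm(i, 2) = F[3 * i + 2];
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// 8-connected component labelling of a logical matrix (row, col), labels
// assigned in row-major order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto [cr, cc] = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || c2 < 0 || rr >= nr || c2 >= nc) continue;
            if (mask(rr, c2) && !lab(rr, c2)) {
              lab(rr, c2) = next;
              stack.push_back({rr, c2});
            }
          }
      }
    }
  return lab;
}

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t tab[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      tab[i] = c;
    }
    init = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = tab[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}
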