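// Geometric kernels: KD-tree nearest neighbours, exact point-to-triangle-mesh
// distance, pinhole ray casting, scanline mesh voxelization, surface-net
// isosurface extraction and 3D connected components.
// All coordinates are in mm; meshes use 0-based vertex indices at this level.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <queue>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

typedef std::array<double,3> Vec3;

static inline Vec3 vsub(const Vec3&a, const Vec3&b){ return {a[0]-b[0],a[1]-b[1],a[2]-b[2]}; }
static inline Vec3 vadd(const Vec3&a, const Vec3&b){ return {a[0]+b[0],a[1]+b[1],a[2]+b[2]}; }
static inline Vec3 vscale(const Vec3&a, double s){ return {a[0]*s,a[1]*s,a[2]*s}; }
static inline double vdot(const Vec3&a, const Vec3&b){ return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
static inline Vec3 vcross(const Vec3&a, const Vec3&b){
  return {a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]};
}
static inline double vnorm2(const Vec3&a){ return vdot(a,a); }
static inline double vnorm(const Vec3&a){ return std::sqrt(vnorm2(a)); }

static std::vector<Vec3> mat_to_vec3(const NumericMatrix& m){
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = {m(i,0), m(i,1), m(i,2)};
  return v;
}

// ---------------------------------------------------------------- KD-tree

class KdTree {
public:
  explicit KdTree(const std::vector<Vec3>& pts) : pts_(pts) {
    idx_.resize(pts.size());
    for (size_t i = 0; i < pts.size(); ++i) idx_[i] = (int)i;
    if (!pts.empty()) build(0, (int)pts.size(), 0);
  }

  // nearest neighbour: returns index, writes squared distance
  int nearest(const Vec3& q, double& best_d2) const {
    best_d2 = std::numeric_limits<double>::infinity();
    int best = -1;
    nn_rec(q, 0, (int)pts_.size(), 0, best, best_d2);
    return best;
  }

  void within_radius(const Vec3& q, double r, std::vector<int>& out) const {
    rad_rec(q, r * r, 0, (int)pts_.size(), 0, out);
  }

  void knn(const Vec3& q, int k, std::vector<std::pair<double,int> >& heap) const {
    heap.clear();
    knn_rec(q, k, 0, (int)pts_.size(), 0, heap);
    std::sort_heap(heap.begin(), heap.end());
  }

private:
  const std::vector<Vec3>& pts_;
  std::vector<int> idx_;

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int axis = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [&](int a, int b){ return pts_[a][axis] < pts_[b][axis]; });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void nn_rec(const Vec3& q, int lo, int hi, int depth, int& best, double& best_d2) const {
    if (lo >= hi) return;
    int axis = depth % 3;
    int mid = (lo + hi) / 2;
    const Vec3& p = pts_[idx_[mid]];
    double d2 = vnorm2(vsub(q, p));
    if (d2 < best_d2) { best_d2 = d2; best = idx_[mid]; }
    double diff = q[axis] - p[axis];
    int first_lo = diff < 0 ? lo : mid + 1, first_hi = diff < 0 ? mid : hi;
    int sec_lo  = diff < 0 ? mid + 1 : lo, sec_hi  = diff < 0 ? hi : mid;
    nn_rec(q, first_lo, first_hi, depth + 1, best, best_d2);
    if (diff * diff < best_d2) nn_rec(q, sec_lo, sec_hi, depth + 1, best, best_d2);
  }

  void rad_rec(const Vec3& q, double r2, int lo, int hi, int depth, std::vector<int>& out) const {
    if (lo >= hi) return;
    int axis = depth % 3;
    int mid = (lo + hi) / 2;
    const Vec3& p = pts_[idx_[mid]];
    if (vnorm2(vsub(q, p)) <= r2) out.push_back(idx_[mid]);
    double diff = q[axis] - p[axis];
    if (diff < 0 || diff * diff <= r2) rad_rec(q, r2, lo, mid, depth + 1, out);
    if (diff > 0 || diff * diff <= r2) rad_rec(q, r2, mid + 1, hi, depth + 1, out);
  }

  void knn_rec(const Vec3& q, int k, int lo, int hi, int depth,
               std::vector<std::pair<double,int> >& heap) const {
    if (lo >= hi) return;
    int axis = depth % 3;
    int mid = (lo + hi) / 2;
    const Vec3& p = pts_[idx_[mid]];
    double d2 = vnorm2(vsub(q, p));
    if ((int)heap.size() < k) {
      heap.push_back(std::make_pair(d2, idx_[mid]));
      std::push_heap(heap.begin(), heap.end());
    } else if (d2 < heap.front().first) {
      std::pop_heap(heap.begin(), heap.end());
      heap.back() = std::make_pair(d2, idx_[mid]);
      std::push_heap(heap.begin(), heap.end());
    }
    double diff = q[axis] - p[axis];
    double worst = (int)heap.size() < k ? std::numeric_limits<double>::infinity()
                                        : heap.front().first;
    int first_lo = diff < 0 ? lo : mid + 1, first_hi = diff < 0 ? mid : hi;
    int sec_lo  = diff < 0 ? mid + 1 : lo, sec_hi  = diff < 0 ? hi : mid;
    knn_rec(q, k, first_lo, first_hi, depth + 1, heap);
    worst = (int)heap.size() < k ? std::numeric_limits<double>::infinity() : heap.front().first;
    if (diff * diff < worst) knn_rec(q, k, sec_lo, sec_hi, depth + 1, heap);
  }
};

// [[Rcpp::export]]
List cpp_knn(NumericMatrix target, NumericMatrix query, int k) {
  std::vector<Vec3> tp = mat_to_vec3(target);
  std::vector<Vec3> qp = mat_to_vec3(query);
  if (tp.empty()) stop("empty target cloud");
  if (k < 1 || k > (int)tp.size()) stop("k out of range");
  KdTree tree(tp);
  IntegerMatrix idx(qp.size(), k);
  NumericMatrix dist(qp.size(), k);
  std::vector<std::pair<double,int> > heap;
  for (size_t i = 0; i < qp.size(); ++i) {
    tree.knn(qp[i], k, heap);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = heap[j].second + 1;   // 1-based for R
      dist(i, j) = std::sqrt(heap[j].first);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// ------------------------------------------- closest point on a triangle
// Ericson, Real-Time Collision Detection, ch. 5.1.5
static Vec3 closest_point_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

// Exact point-to-mesh closest points. Candidate triangles are gathered with a
// KD-tree over centroids using the nearest-vertex distance as an upper bound;
// any triangle that could beat the bound has its centroid within
// bound + max triangle circumradius, so the search is exact.
// [[Rcpp::export]]
List cpp_mesh_closest(NumericMatrix vertices, IntegerMatrix faces, NumericMatrix query) {
  std::vector<Vec3> V = mat_to_vec3(vertices);
  std::vector<Vec3> Q = mat_to_vec3(query);
  int nf = faces.nrow();
  if (V.empty() || nf == 0) stop("empty mesh");
  std::vector<Vec3> cent(nf);
  std::vector<double> trad(nf);
  double rmax = 0.0;
  for (int f = 0; f < nf; ++f) {
    const Vec3 &a = V[faces(f,0)], &b = V[faces(f,1)], &c = V[faces(f,2)];
    cent[f] = vscale(vadd(a, vadd(b, c)), 1.0 / 3.0);
    double r = std::sqrt(std::max(std::max(vnorm2(vsub(a, cent[f])), vnorm2(vsub(b, cent[f]))),
                                  vnorm2(vsub(c, cent[f]))));
    trad[f] = r;
    if (r > rmax) rmax = r;
  }
  // one incident face per vertex so the query can always report a face
  std::vector<int> vface(V.size(), -1);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k)
      if (vface[faces(f,k)] < 0) vface[faces(f,k)] = f;
  KdTree vtree(V), ctree(cent);
  NumericVector dist(Q.size());
  NumericMatrix cpts(Q.size(), 3);
  IntegerVector cface(Q.size());
  std::vector<int> cand;
  for (size_t i = 0; i < Q.size(); ++i) {
    double d2;
    int vi = vtree.nearest(Q[i], d2);
    double best = std::sqrt(d2);
    Vec3 bp = V[vi];
    int bf = vface[vi];
    cand.clear();
    ctree.within_radius(Q[i], best + rmax + 1e-12, cand);
    for (int f : cand) {
      if (vnorm(vsub(Q[i], cent[f])) > best + trad[f] + 1e-12) continue;
      Vec3 cp = closest_point_triangle(Q[i], V[faces(f,0)], V[faces(f,1)], V[faces(f,2)]);
      double d = vnorm(vsub(Q[i], cp));
      if (d < best) { best = d; bp = cp; bf = f; }
    }
    dist[i] = best;
    cpts(i,0) = bp[0]; cpts(i,1) = bp[1]; cpts(i,2) = bp[2];
    cface[i] = bf + 1; // 1-based; a face containing the nearest vertex if no
                       // candidate triangle beat the vertex bound
  }
  return List::create(_["distance"] = dist, _["point"] = cpts, _["face"] = cface);
}

// ------------------------------------------------------------ ray casting
// Moller-Trumbore; returns t >= 0 or -1
static double ray_triangle(const Vec3& o, const Vec3& d,
                           const Vec3& a, const Vec3& b, const Vec3& c) {
  const double EPS = 1e-12;
  Vec3 e1 = vsub(b, a), e2 = vsub(c, a);
  Vec3 h = vcross(d, e2);
  double det = vdot(e1, h);
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  Vec3 s = vsub(o, a);
  double u = vdot(s, h) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return -1.0;
  Vec3 q = vcross(s, e1);
  double v = vdot(d, q) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return -1.0;
  double t = vdot(e2, q) * inv;
  return t > EPS ? t : -1.0;
}

// Pinhole camera ray casting with image-space triangle binning.
// basis rows: right, up, forward (orthonormal); tan_x/tan_y are tangents of
// the half field of view. Returns first-hit points and hit mask per pixel.
// [[Rcpp::export]]
List cpp_raycast(NumericMatrix vertices, IntegerMatrix faces,
                 NumericVector origin, NumericMatrix basis,
                 double tan_x, double tan_y, int nx, int ny) {
  std::vector<Vec3> V = mat_to_vec3(vertices);
  int nf = faces.nrow();
  Vec3 o = {origin[0], origin[1], origin[2]};
  Vec3 right = {basis(0,0), basis(0,1), basis(0,2)};
  Vec3 up    = {basis(1,0), basis(1,1), basis(1,2)};
  Vec3 fwd   = {basis(2,0), basis(2,1), basis(2,2)};

  // bin triangles by pixel-footprint bounding box
  std::vector<std::vector<int> > bins((size_t)nx * ny);
  std::vector<int> global; // triangles with a vertex at/behind the camera plane
  for (int f = 0; f < nf; ++f) {
    double pxmin = 1e30, pxmax = -1e30, pymin = 1e30, pymax = -1e30;
    int n_behind = 0;
    for (int k = 0; k < 3; ++k) {
      Vec3 w = vsub(V[faces(f,k)], o);
      double z = vdot(w, fwd);
      if (z < 1e-9) { ++n_behind; continue; }
      double u = vdot(w, right) / (z * tan_x);  // [-1, 1] inside fov
      double v = vdot(w, up)    / (z * tan_y);
      double px = (u + 1.0) * 0.5 * nx, py = (v + 1.0) * 0.5 * ny;
      pxmin = std::min(pxmin, px); pxmax = std::max(pxmax, px);
      pymin = std::min(pymin, py); pymax = std::max(pymax, py);
    }
    if (n_behind == 3) continue;               // fully behind: unreachable
    if (n_behind > 0) { global.push_back(f); continue; }  // straddles the plane
    int ix0 = std::max(0, (int)std::floor(pxmin) - 1), ix1 = std::min(nx - 1, (int)std::ceil(pxmax));
    int iy0 = std::max(0, (int)std::floor(pymin) - 1), iy1 = std::min(ny - 1, (int)std::ceil(pymax));
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix)
        bins[(size_t)iy * nx + ix].push_back(f);
  }

  NumericMatrix pts((size_t)nx * ny, 3);
  LogicalVector hit((size_t)nx * ny);
  NumericVector tvals((size_t)nx * ny);
  NumericMatrix dirs((size_t)nx * ny, 3);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      size_t pix = (size_t)iy * nx + ix;
      double u = ((ix + 0.5) / nx) * 2.0 - 1.0;
      double v = ((iy + 0.5) / ny) * 2.0 - 1.0;
      Vec3 d = vadd(fwd, vadd(vscale(right, u * tan_x), vscale(up, v * tan_y)));
      d = vscale(d, 1.0 / vnorm(d));
      double tbest = std::numeric_limits<double>::infinity();
      for (int f : bins[pix]) {
        double t = ray_triangle(o, d, V[faces(f,0)], V[faces(f,1)], V[faces(f,2)]);
        if (t > 0 && t < tbest) tbest = t;
      }
      for (int f : global) {
        double t = ray_triangle(o, d, V[faces(f,0)], V[faces(f,1)], V[faces(f,2)]);
        if (t > 0 && t < tbest) tbest = t;
      }
      bool h = std::isfinite(tbest);
      hit[pix] = h;
      tvals[pix] = h ? tbest : NA_REAL;
      dirs(pix,0) = d[0]; dirs(pix,1) = d[1]; dirs(pix,2) = d[2];
      if (h) {
        Vec3 p = vadd(o, vscale(d, tbest));
        pts(pix,0) = p[0]; pts(pix,1) = p[1]; pts(pix,2) = p[2];
      }
    }
  }
  return List::create(_["hit"] = hit, _["point"] = pts, _["t"] = tvals, _["dir"] = dirs);
}

// --------------------------------------------------- scanline voxelization
// Fills voxel centers inside a closed mesh by x-directed parity scanlines.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_mesh(NumericMatrix vertices, IntegerMatrix faces,
                                IntegerVector dims, NumericVector spacing,
                                NumericVector origin) {
  std::vector<Vec3> V = mat_to_vec3(vertices);
  int nf = faces.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  // tiny deterministic offset avoids rays through edges/vertices of
  // grid-aligned meshes
  const double jy = 0.37e-4 * sy, jz = 0.61e-4 * sz;

  // bin triangles into (y,z) rows they may cross
  std::vector<std::vector<int> > rows((size_t)ny * nz);
  for (int f = 0; f < nf; ++f) {
    double ymin = 1e30, ymax = -1e30, zmin = 1e30, zmax = -1e30;
    for (int k = 0; k < 3; ++k) {
      const Vec3& p = V[faces(f,k)];
      ymin = std::min(ymin, p[1]); ymax = std::max(ymax, p[1]);
      zmin = std::min(zmin, p[2]); zmax = std::max(zmax, p[2]);
    }
    int j0 = std::max(0, (int)std::ceil((ymin - oy - jy) / sy) - 1);
    int j1 = std::min(ny - 1, (int)std::floor((ymax - oy - jy) / sy) + 1);
    int k0 = std::max(0, (int)std::ceil((zmin - oz - jz) / sz) - 1);
    int k1 = std::min(nz - 1, (int)std::floor((zmax - oz - jz) / sz) + 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        rows[(size_t)k * ny + j].push_back(f);
  }

  LogicalVector out((size_t)nx * ny * nz, false);
  Vec3 dir = {1.0, 0.0, 0.0};
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const std::vector<int>& tl = rows[(size_t)k * ny + j];
      if (tl.empty()) continue;
      Vec3 o = {ox - 10.0 * sx, oy + j * sy + jy, oz + k * sz + jz};
      xs.clear();
      for (int f : tl) {
        double t = ray_triangle(o, dir, V[faces(f,0)], V[faces(f,1)], V[faces(f,2)]);
        if (t > 0) xs.push_back(o[0] + t);
      }
      if (xs.size() < 2) continue;
      std::sort(xs.begin(), xs.end());
      // parity fill between successive crossing pairs
      for (size_t c = 0; c + 1 < xs.size(); c += 2) {
        int i0 = std::max(0, (int)std::ceil((xs[c] - ox) / sx));
        int i1 = std::min(nx - 1, (int)std::floor((xs[c + 1] - ox) / sx));
        for (int i = i0; i <= i1; ++i)
          out[(size_t)k * nx * ny + (size_t)j * nx + i] = true;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ----------------------------------------------------------- surface nets
// Dual-contouring isosurface at the 0.5 level of a binary mask. Each dual
// cell (8 neighbouring voxels) with mixed occupancy yields one vertex at the
// mean of its sign-change edge midpoints; each sign-change voxel edge yields
// a quad over the 4 incident cells. The mask must have a false border (the R
// wrapper pads), so the surface is closed.
// [[Rcpp::export]]
List cpp_surface_nets(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  auto at = [&](int i, int j, int k) -> bool {
    return mask[(size_t)k * nx * ny + (size_t)j * nx + i] != 0;
  };
  int cnx = nx - 1, cny = ny - 1, cnz = nz - 1;
  if (cnx < 1 || cny < 1 || cnz < 1) stop("mask grid too small");
  std::vector<int> cellv((size_t)cnx * cny * cnz, -1);
  auto cellid = [&](int i, int j, int k) -> size_t {
    return (size_t)k * cnx * cny + (size_t)j * cnx + i;
  };
  static const int edges[12][2][3] = {
    {{0,0,0},{1,0,0}}, {{0,1,0},{1,1,0}}, {{0,0,1},{1,0,1}}, {{0,1,1},{1,1,1}},
    {{0,0,0},{0,1,0}}, {{1,0,0},{1,1,0}}, {{0,0,1},{0,1,1}}, {{1,0,1},{1,1,1}},
    {{0,0,0},{0,0,1}}, {{1,0,0},{1,0,1}}, {{0,1,0},{0,1,1}}, {{1,1,0},{1,1,1}}
  };
  std::vector<double> vx, vy, vz;
  for (int k = 0; k < cnz; ++k) {
    for (int j = 0; j < cny; ++j) {
      for (int i = 0; i < cnx; ++i) {
        int ntrue = 0;
        for (int c = 0; c < 8; ++c)
          if (at(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1))) ++ntrue;
        if (ntrue == 0 || ntrue == 8) continue;
        double mx = 0, my = 0, mz = 0; int ne = 0;
        for (int e = 0; e < 12; ++e) {
          bool a = at(i + edges[e][0][0], j + edges[e][0][1], k + edges[e][0][2]);
          bool b = at(i + edges[e][1][0], j + edges[e][1][1], k + edges[e][1][2]);
          if (a != b) {
            mx += i + 0.5 * (edges[e][0][0] + edges[e][1][0]);
            my += j + 0.5 * (edges[e][0][1] + edges[e][1][1]);
            mz += k + 0.5 * (edges[e][0][2] + edges[e][1][2]);
            ++ne;
          }
        }
        cellv[cellid(i,j,k)] = (int)vx.size();
        vx.push_back(ox + sx * (mx / ne));
        vy.push_back(oy + sy * (my / ne));
        vz.push_back(oz + sz * (mz / ne));
      }
    }
  }
  std::vector<int> tri; // 0-based, converted in R wrapper
  // quad for each sign-change voxel edge along axis a, wound so normals
  // point from true (inside) to false (outside)
  auto emit_quad = [&](int c0, int c1, int c2, int c3, bool flip) {
    if (c0 < 0 || c1 < 0 || c2 < 0 || c3 < 0) return; // cannot happen on padded masks
    if (flip) {
      tri.push_back(c0); tri.push_back(c2); tri.push_back(c1);
      tri.push_back(c0); tri.push_back(c3); tri.push_back(c2);
    } else {
      tri.push_back(c0); tri.push_back(c1); tri.push_back(c2);
      tri.push_back(c0); tri.push_back(c2); tri.push_back(c3);
    }
  };
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool a = at(i, j, k), b = at(i + 1, j, k);
        if (a == b) continue;
        int c0 = cellv[cellid(i, j - 1, k - 1)], c1 = cellv[cellid(i, j, k - 1)];
        int c2 = cellv[cellid(i, j, k)],         c3 = cellv[cellid(i, j - 1, k)];
        emit_quad(c0, c1, c2, c3, !a); // a true => outward normal +x
      }
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        bool a = at(i, j, k), b = at(i, j + 1, k);
        if (a == b) continue;
        int c0 = cellv[cellid(i - 1, j, k - 1)], c1 = cellv[cellid(i - 1, j, k)];
        int c2 = cellv[cellid(i, j, k)],         c3 = cellv[cellid(i, j, k - 1)];
        emit_quad(c0, c1, c2, c3, !a);
      }
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        bool a = at(i, j, k), b = at(i, j, k + 1);
        if (a == b) continue;
        int c0 = cellv[cellid(i - 1, j - 1, k)], c1 = cellv[cellid(i, j - 1, k)];
        int c2 = cellv[cellid(i, j, k)],         c3 = cellv[cellid(i - 1, j, k)];
        emit_quad(c0, c1, c2, c3, !a);
      }
  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) { Vout(i,0) = vx[i]; Vout(i,1) = vy[i]; Vout(i,2) = vz[i]; }
  IntegerMatrix Fout(nt, 3);
  for (int t = 0; t < nt; ++t) {
    Fout(t,0) = tri[3*t]; Fout(t,1) = tri[3*t+1]; Fout(t,2) = tri[3*t+2];
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ------------------------------------------------------ connected components
// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  std::vector<std::array<int,3> > nbrs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
        nbrs.push_back({dx, dy, dz});
      }
  size_t n = (size_t)nx * ny * nz;
  IntegerVector label(n, 0);
  std::vector<int> sizes;
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s] != 0) continue;
    ++cur;
    int count = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      ++count;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((size_t)nx * ny));
      for (const auto& d : nbrs) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t w = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
        if (mask[w] && label[w] == 0) { label[w] = cur; stack.push_back(w); }
      }
    }
    sizes.push_back(count);
  }
  label.attr("dim") = dims;
  return List::create(_["label"] = label, _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
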