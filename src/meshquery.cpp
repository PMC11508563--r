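// Mesh query primitives: ray casting (Moller-Trumbore), closest point on
// a triangle soup (uniform-grid accelerated), and solid voxelization by
// z-column parity counting.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
inline Vec3 operator-(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 operator+(const Vec3 &a, const Vec3 &b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
inline Vec3 operator*(double s, const Vec3 &a) {
  return {s * a.x, s * a.y, s * a.z};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}

inline Vec3 vrow(const NumericMatrix &V, int i) {
  return {V(i, 0), V(i, 1), V(i, 2)};
}

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p
Vec3 closest_on_tri(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                    const Vec3 &c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

}  // namespace

// Ray-mesh intersection.  Returns a matrix with columns (t, face, margin)
// sorted by t, where margin is the smallest barycentric coordinate of the
// hit (callers treat margin < tol as a degenerate edge/vertex graze and
// re-cast from a jittered origin).
// [[Rcpp::export]]
NumericMatrix ray_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, NumericVector dir) {
  const int nf = F.nrow();
  Vec3 o = v3(origin[0], origin[1], origin[2]);
  Vec3 d = v3(dir[0], dir[1], dir[2]);
  std::vector<double> ts, margins;
  std::vector<int> faces;
  const double eps = 1e-12;
  for (int i = 0; i < nf; ++i) {
    Vec3 a = vrow(V, F(i, 0) - 1);
    Vec3 b = vrow(V, F(i, 1) - 1);
    Vec3 c = vrow(V, F(i, 2) - 1);
    Vec3 e1 = b - a, e2 = c - a;
    Vec3 pv = cross(d, e2);
    double det = dot(e1, pv);
    if (std::fabs(det) < eps) continue;
    double inv = 1.0 / det;
    Vec3 tv = o - a;
    double u = dot(tv, pv) * inv;
    if (u < -1e-9 || u > 1.0 + 1e-9) continue;
    Vec3 qv = cross(tv, e1);
    double v = dot(d, qv) * inv;
    if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
    double t = dot(e2, qv) * inv;
    if (t < -1e-9) continue;
    double w = 1.0 - u - v;
    double margin = std::min(std::min(u, v), w);
    ts.push_back(t);
    faces.push_back(i + 1);
    margins.push_back(margin);
  }
  std::vector<int> idx(ts.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = static_cast<int>(i);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return ts[a] < ts[b]; });
  NumericMatrix out(static_cast<int>(ts.size()), 3);
  for (size_t i = 0; i < idx.size(); ++i) {
    out(static_cast<int>(i), 0) = ts[idx[i]];
    out(static_cast<int>(i), 1) = faces[idx[i]];
    out(static_cast<int>(i), 2) = margins[idx[i]];
  }
  return out;
}
// Uniform grid over triangle bounding boxes for closest-point queries;
// built once (optionally kept alive through an external pointer for
// repeated queries, e.g. ICP iterations) and searched in Chebyshev
// shells with exact cell AABB lower bounds.
namespace {

struct MeshGrid {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  double lo[3], hi[3], csz[3];
  int nc[3];
  std::vector<std::vector<int>> buckets;

  void build(const NumericMatrix &V, const IntegerMatrix &F) {
    const int nv = V.nrow(), nf = F.nrow();
    vx.resize(nv); vy.resize(nv); vz.resize(nv);
    for (int i = 0; i < nv; ++i) {
      vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
    }
    f0.resize(nf); f1.resize(nf); f2.resize(nf);
    for (int i = 0; i < nf; ++i) {
      f0[i] = F(i, 0) - 1; f1[i] = F(i, 1) - 1; f2[i] = F(i, 2) - 1;
    }
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < nv; ++i) {
      lo[0] = std::min(lo[0], vx[i]); hi[0] = std::max(hi[0], vx[i]);
      lo[1] = std::min(lo[1], vy[i]); hi[1] = std::max(hi[1], vy[i]);
      lo[2] = std::min(lo[2], vz[i]); hi[2] = std::max(hi[2], vz[i]);
    }
    double diag = 0;
    for (int d = 0; d < 3; ++d) diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
    diag = std::sqrt(diag);
    // keep the grid occupancy sensible for sparse meshes: no finer
    // than ~4 cells per triangle
    double cell = std::max(diag / 96.0,
                           diag / std::cbrt(4.0 * nf + 1.0));
    cell = std::max(cell, 1e-6);
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, static_cast<int>(std::ceil((hi[d] - lo[d]) / cell)));
      nc[d] = std::min(nc[d], 256);
      csz[d] = std::max((hi[d] - lo[d]) / nc[d], 1e-9);
    }
    buckets.assign(static_cast<size_t>(nc[0]) * nc[1] * nc[2], {});
    for (int i = 0; i < nf; ++i) {
      double tlo[3] = {
        std::min(vx[f0[i]], std::min(vx[f1[i]], vx[f2[i]])),
        std::min(vy[f0[i]], std::min(vy[f1[i]], vy[f2[i]])),
        std::min(vz[f0[i]], std::min(vz[f1[i]], vz[f2[i]]))};
      double thi[3] = {
        std::max(vx[f0[i]], std::max(vx[f1[i]], vx[f2[i]])),
        std::max(vy[f0[i]], std::max(vy[f1[i]], vy[f2[i]])),
        std::max(vz[f0[i]], std::max(vz[f1[i]], vz[f2[i]]))};
      int c0[3], c1[3];
      for (int d = 0; d < 3; ++d) {
        c0[d] = std::max(0, std::min(nc[d] - 1,
                 static_cast<int>((tlo[d] - lo[d]) / csz[d])));
        c1[d] = std::max(0, std::min(nc[d] - 1,
                 static_cast<int>((thi[d] - lo[d]) / csz[d])));
      }
      for (int iz = c0[2]; iz <= c1[2]; ++iz)
        for (int iy = c0[1]; iy <= c1[1]; ++iy)
          for (int ix = c0[0]; ix <= c1[0]; ++ix)
            buckets[cidx(ix, iy, iz)].push_back(i);
    }
  }

  size_t cidx(int ix, int iy, int iz) const {
    return static_cast<size_t>(ix) +
           static_cast<size_t>(nc[0]) *
               (iy + static_cast<size_t>(nc[1]) * iz);
  }

  Vec3 vert(int i) const { return {vx[i], vy[i], vz[i]}; }

  // max_dist caps the search: if no triangle lies within max_dist the
  // query returns best = max_dist with no face (enough for banded
  // level-set fields, and it bounds the shell expansion)
  void query(const Vec3 &p, double &best, Vec3 &bestp, int &bestf,
             double max_dist) const {
    double pq[3] = {p.x, p.y, p.z};
    int qc[3];
    for (int d = 0; d < 3; ++d) {
      qc[d] = std::max(0, std::min(nc[d] - 1,
               static_cast<int>((pq[d] - lo[d]) / csz[d])));
    }
    best = max_dist;
    bestp = p;
    bestf = -1;
    int settled = 0;
    auto visit_cell = [&](int ix, int iy, int iz, double &shell_min) {
      double blo[3] = {lo[0] + ix * csz[0], lo[1] + iy * csz[1],
                       lo[2] + iz * csz[2]};
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double c0 = blo[d], c1 = blo[d] + csz[d], dd = 0;
        if (pq[d] < c0) dd = c0 - pq[d];
        else if (pq[d] > c1) dd = pq[d] - c1;
        d2 += dd * dd;
      }
      double lb = std::sqrt(d2);
      shell_min = std::min(shell_min, lb);
      if (lb >= best) return;
      for (int ti : buckets[cidx(ix, iy, iz)]) {
        Vec3 cp = closest_on_tri(p, vert(f0[ti]), vert(f1[ti]),
                                 vert(f2[ti]));
        Vec3 dv = p - cp;
        double dd = std::sqrt(dot(dv, dv));
        if (dd < best) { best = dd; bestp = cp; bestf = ti; }
      }
    };
    const int max_r = std::max(std::max(nc[0], nc[1]), nc[2]);
    for (int r = 0; r <= max_r + 1; ++r) {
      double shell_min = R_PosInf;
      int x0 = qc[0] - r, x1 = qc[0] + r;
      int y0 = qc[1] - r, y1 = qc[1] + r;
      int z0 = qc[2] - r, z1 = qc[2] + r;
      int cx0 = std::max(0, x0), cx1 = std::min(nc[0] - 1, x1);
      int cy0 = std::max(0, y0), cy1 = std::min(nc[1] - 1, y1);
      int cz0 = std::max(0, z0), cz1 = std::min(nc[2] - 1, z1);
      if (r == 0) {
        visit_cell(qc[0], qc[1], qc[2], shell_min);
      } else {
        for (int fx : {x0, x1}) {
          if (fx < 0 || fx >= nc[0]) continue;
          for (int iy = cy0; iy <= cy1; ++iy)
            for (int iz = cz0; iz <= cz1; ++iz)
              visit_cell(fx, iy, iz, shell_min);
        }
        for (int fy : {y0, y1}) {
          if (fy < 0 || fy >= nc[1]) continue;
          int ix0 = std::max(cx0, x0 + 1), ix1 = std::min(cx1, x1 - 1);
          for (int ix = ix0; ix <= ix1; ++ix)
            for (int iz = cz0; iz <= cz1; ++iz)
              visit_cell(ix, fy, iz, shell_min);
        }
        for (int fz : {z0, z1}) {
          if (fz < 0 || fz >= nc[2]) continue;
          int ix0 = std::max(cx0, x0 + 1), ix1 = std::min(cx1, x1 - 1);
          int iy0 = std::max(cy0, y0 + 1), iy1 = std::min(cy1, y1 - 1);
          for (int ix = ix0; ix <= ix1; ++ix)
            for (int iy = iy0; iy <= iy1; ++iy)
              visit_cell(ix, iy, fz, shell_min);
        }
      }
      bool covers = x0 <= 0 && y0 <= 0 && z0 <= 0 && x1 >= nc[0] - 1 &&
                    y1 >= nc[1] - 1 && z1 >= nc[2] - 1;
      if (shell_min > best) {
        if (++settled >= 2) break;  // one slack shell for anisotropy
      } else {
        settled = 0;
      }
      if (covers) break;
    }
  }
};

List grid_query(const MeshGrid &G, const NumericMatrix &Q,
                double max_dist) {
  const int nq = Q.nrow();
  NumericVector dist(nq);
  NumericMatrix pts(nq, 3);
  IntegerVector face(nq);
  for (int q = 0; q < nq; ++q) {
    Vec3 p = {Q(q, 0), Q(q, 1), Q(q, 2)};
    double best;
    Vec3 bestp;
    int bestf;
    G.query(p, best, bestp, bestf, max_dist);
    dist[q] = best;
    pts(q, 0) = bestp.x; pts(q, 1) = bestp.y; pts(q, 2) = bestp.z;
    face[q] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = pts,
                      _["face"] = face);
}

}  // namespace

// [[Rcpp::export]]
List mesh_closest_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix Q,
                      double max_dist = 1e18) {
  MeshGrid G;
  G.build(V, F);
  return grid_query(G, Q, max_dist);
}

// [[Rcpp::export]]
SEXP mesh_grid_build_cpp(NumericMatrix V, IntegerMatrix F) {
  Rcpp::XPtr<MeshGrid> ptr(new MeshGrid(), true);
  ptr->build(V, F);
  return ptr;
}

// [[Rcpp::export]]
List mesh_grid_query_cpp(SEXP grid, NumericMatrix Q,
                         double max_dist = 1e18) {
  Rcpp::XPtr<MeshGrid> ptr(grid);
  return grid_query(*ptr, Q, max_dist);
}
// that edge-aligned meshes do not produce degenerate crossings.
// [[Rcpp::export]]
LogicalVector voxelize_cpp(NumericMatrix V, IntegerMatrix F,
                           IntegerVector dims, NumericVector spacing,
                           NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double jx = 2.0736e-4 * sx, jy = 1.4142e-4 * sy;
  const int nf = F.nrow();

  std::vector<std::vector<int>> cols(static_cast<size_t>(nx) * ny);
  for (int i = 0; i < nf; ++i) {
    double xlo = R_PosInf, xhi = R_NegInf, ylo = R_PosInf, yhi = R_NegInf;
    for (int m = 0; m < 3; ++m) {
      int vi = F(i, m) - 1;
      xlo = std::min(xlo, V(vi, 0)); xhi = std::max(xhi, V(vi, 0));
      ylo = std::min(ylo, V(vi, 1)); yhi = std::max(yhi, V(vi, 1));
    }
    int i0 = std::max(0, static_cast<int>(std::floor((xlo - ox - jx) / sx)));
    int i1 = std::min(nx - 1,
                      static_cast<int>(std::ceil((xhi - ox - jx) / sx)));
    int j0 = std::max(0, static_cast<int>(std::floor((ylo - oy - jy) / sy)));
    int j1 = std::min(ny - 1,
                      static_cast<int>(std::ceil((yhi - oy - jy) / sy)));
    for (int jj = j0; jj <= j1; ++jj)
      for (int ii = i0; ii <= i1; ++ii)
        cols[ii + static_cast<size_t>(nx) * jj].push_back(i);
  }

  LogicalVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  std::fill(out.begin(), out.end(), FALSE);
  std::vector<double> zs;
  for (int jj = 0; jj < ny; ++jj) {
    for (int ii = 0; ii < nx; ++ii) {
      const std::vector<int> &bk = cols[ii + static_cast<size_t>(nx) * jj];
      if (bk.empty()) continue;
      double px = ox + ii * sx + jx, py = oy + jj * sy + jy;
      zs.clear();
      for (int ti : bk) {
        Vec3 a = vrow(V, F(ti, 0) - 1);
        Vec3 b = vrow(V, F(ti, 1) - 1);
        Vec3 c = vrow(V, F(ti, 2) - 1);
        double d = (b.y - c.y) * (a.x - c.x) + (c.x - b.x) * (a.y - c.y);
        if (std::fabs(d) < 1e-14) continue;  // vertical triangle
        double l1 = ((b.y - c.y) * (px - c.x) + (c.x - b.x) * (py - c.y)) / d;
        double l2 = ((c.y - a.y) * (px - c.x) + (a.x - c.x) * (py - c.y)) / d;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        zs.push_back(l1 * a.z + l2 * b.z + l3 * c.z);
      }
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      // merge duplicate crossings from shared edges
      std::vector<double> zu;
      for (double z : zs) {
        if (zu.empty() || z - zu.back() > 1e-9) zu.push_back(z);
      }
      size_t npair = zu.size() / 2;
      for (size_t m = 0; m < npair; ++m) {
        double zin = zu[2 * m], zout = zu[2 * m + 1];
        int k0 = static_cast<int>(std::ceil((zin - oz) / sz));
        int k1 = static_cast<int>(std::floor((zout - oz) / sz));
        k0 = std::max(0, k0);
        k1 = std::min(nz - 1, k1);
        for (int kk = k0; kk <= k1; ++kk)
          out[ii + static_cast<R_xlen_t>(nx) *
                       (jj + static_cast<R_xlen_t>(ny) * kk)] = TRUE;
      }
    }
  }
  return out;
}

// Fractional occupancy per voxel: xy-subsampled columns with exact
// z-interval integration (partial-volume rasterization). `ss` columns
// per voxel per axis; fractions are continuous along z.
// [[Rcpp::export]]
NumericVector voxelize_frac_cpp(NumericMatrix V, IntegerMatrix F,
                                IntegerVector dims, NumericVector spacing,
                                NumericVector origin, int ss) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double jx = 2.0736e-4 * sx, jy = 1.4142e-4 * sy;
  const int nf = F.nrow();

  std::vector<std::vector<int>> cols(static_cast<size_t>(nx) * ny);
  for (int i = 0; i < nf; ++i) {
    double xlo = R_PosInf, xhi = R_NegInf, ylo = R_PosInf, yhi = R_NegInf;
    for (int m = 0; m < 3; ++m) {
      int vi = F(i, m) - 1;
      xlo = std::min(xlo, V(vi, 0)); xhi = std::max(xhi, V(vi, 0));
      ylo = std::min(ylo, V(vi, 1)); yhi = std::max(yhi, V(vi, 1));
    }
    int i0 = std::max(0, static_cast<int>(std::floor((xlo - ox) / sx)) - 1);
    int i1 = std::min(nx - 1, static_cast<int>(std::ceil((xhi - ox) / sx)) + 1);
    int j0 = std::max(0, static_cast<int>(std::floor((ylo - oy) / sy)) - 1);
    int j1 = std::min(ny - 1, static_cast<int>(std::ceil((yhi - oy) / sy)) + 1);
    for (int jj = j0; jj <= j1; ++jj)
      for (int ii = i0; ii <= i1; ++ii)
        cols[ii + static_cast<size_t>(nx) * jj].push_back(i);
  }

  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double w = 1.0 / (ss * ss);
  std::vector<double> zs;
  for (int jj = 0; jj < ny; ++jj) {
    for (int ii = 0; ii < nx; ++ii) {
      const std::vector<int> &bk = cols[ii + static_cast<size_t>(nx) * jj];
      if (bk.empty()) continue;
      for (int a = 0; a < ss; ++a) {
        for (int b = 0; b < ss; ++b) {
          double px = ox + ii * sx + (a - (ss - 1) * 0.5) * sx / ss + jx;
          double py = oy + jj * sy + (b - (ss - 1) * 0.5) * sy / ss + jy;
          zs.clear();
          for (int ti : bk) {
            Vec3 va = vrow(V, F(ti, 0) - 1);
            Vec3 vb = vrow(V, F(ti, 1) - 1);
            Vec3 vc = vrow(V, F(ti, 2) - 1);
            double d = (vb.y - vc.y) * (va.x - vc.x) +
                       (vc.x - vb.x) * (va.y - vc.y);
            if (std::fabs(d) < 1e-14) continue;
            double l1 = ((vb.y - vc.y) * (px - vc.x) +
                         (vc.x - vb.x) * (py - vc.y)) / d;
            double l2 = ((vc.y - va.y) * (px - vc.x) +
                         (va.x - vc.x) * (py - vc.y)) / d;
            double l3 = 1.0 - l1 - l2;
            if (l1 < 0 || l2 < 0 || l3 < 0) continue;
            zs.push_back(l1 * va.z + l2 * vb.z + l3 * vc.z);
          }
          if (zs.size() < 2) continue;
          std::sort(zs.begin(), zs.end());
          std::vector<double> zu;
          for (double z : zs)
            if (zu.empty() || z - zu.back() > 1e-9) zu.push_back(z);
          size_t npair = zu.size() / 2;
          for (size_t m = 0; m < npair; ++m) {
            // voxel k covers z in [oz + (k-0.5) sz, oz + (k+0.5) sz]
            double zin = zu[2 * m], zout = zu[2 * m + 1];
            int k0 = std::max(0, static_cast<int>(
                std::floor((zin - oz) / sz + 0.5)));
            int k1 = std::min(nz - 1, static_cast<int>(
                std::floor((zout - oz) / sz + 0.5)));
            for (int kk = k0; kk <= k1; ++kk) {
              double vlo = oz + (kk - 0.5) * sz;
              double vhi = vlo + sz;
              double ov = std::min(vhi, zout) - std::max(vlo, zin);
              if (ov > 0)
                out[ii + static_cast<R_xlen_t>(nx) *
                         (jj + static_cast<R_xlen_t>(ny) * kk)] +=
                    w * ov / sz;
            }
          }
        }
      }
    }
  }
  return out;
}
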