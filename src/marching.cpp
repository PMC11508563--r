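// Iso-surface extraction by marching tetrahedra on a rectilinear scalar
// field.  Each grid cell is split into the 6 Freudenthal tetrahedra sharing
// the 0-7 cube diagonal, which makes face diagonals agree between
// neighbouring cells and hence yields a watertight, consistently wound
// surface.  Vertices are welded through a global edge -> vertex map.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct MTState {
  std::unordered_map<uint64_t, int> edge_map;
  std::vector<double> verts;  // xyz triplets
  std::vector<int> tris;      // 0-based vertex ids
};

// interpolated vertex on grid edge (ga, gb); canonical order keeps the
// interpolation bit-identical no matter which tet visits the edge first
inline int edge_vertex(MTState &st, int64_t ga, int64_t gb,
                       double fa, double fb, double iso,
                       const double *pa, const double *pb) {
  if (ga > gb) {
    std::swap(ga, gb); std::swap(fa, fb);
    const double *tmp = pa; pa = pb; pb = tmp;
  }
  uint64_t key = (static_cast<uint64_t>(ga) << 32) | static_cast<uint64_t>(gb);
  auto it = st.edge_map.find(key);
  if (it != st.edge_map.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  int id = static_cast<int>(st.verts.size() / 3);
  st.verts.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.verts.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.verts.push_back(pa[2] + t * (pb[2] - pa[2]));
  st.edge_map.emplace(key, id);
  return id;
}

inline void emit_tri(MTState &st, int a, int b, int c,
                     const double *ref_in, const double *ref_out) {
  // orient the triangle so its normal points from the inside (f < iso)
  // corners towards the outside corners of the tetrahedron
  const double *va = &st.verts[3 * a];
  const double *vb = &st.verts[3 * b];
  const double *vc = &st.verts[3 * c];
  double e1[3] = {vb[0] - va[0], vb[1] - va[1], vb[2] - va[2]};
  double e2[3] = {vc[0] - va[0], vc[1] - va[1], vc[2] - va[2]};
  double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                 e1[2] * e2[0] - e1[0] * e2[2],
                 e1[0] * e2[1] - e1[1] * e2[0]};
  double d[3] = {ref_out[0] - ref_in[0], ref_out[1] - ref_in[1],
                 ref_out[2] - ref_in[2]};
  double dp = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
  if (dp < 0) std::swap(b, c);
  st.tris.push_back(a); st.tris.push_back(b); st.tris.push_back(c);
}

}  // namespace

// [[Rcpp::export]]
List mt_surface_cpp(NumericVector field, IntegerVector dims,
                    NumericVector spacing, NumericVector origin, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *f = REAL(field);
  MTState st;
  st.edge_map.reserve(1 << 16);

  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  int cdi[8], cdj[8], cdk[8];
  for (int c = 0; c < 8; ++c) {
    cdi[c] = c & 1; cdj[c] = (c >> 1) & 1; cdk[c] = (c >> 2) & 1;
  }

  int64_t gids[8];
  double fv[8], px[8], py[8], pz[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      const int64_t base_j0 = static_cast<int64_t>(nx) *
                              (j + static_cast<int64_t>(ny) * k);
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + cdi[c], jj = j + cdj[c], kk = k + cdk[c];
          int64_t g = ii + static_cast<int64_t>(nx) *
                               (jj + static_cast<int64_t>(ny) * kk);
          gids[c] = g;
          fv[c] = f[g];
          if (fv[c] < iso) any_in = true; else any_out = true;
        }
        (void)base_j0;
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) {
          px[c] = ox + (i + cdi[c]) * sx;
          py[c] = oy + (j + cdj[c]) * sy;
          pz[c] = oz + (k + cdk[c]) * sz;
        }
        for (int t = 0; t < 6; ++t) {
          int vin[4], vout[4];
          int nin = 0, nout = 0;
          for (int m = 0; m < 4; ++m) {
            int c = tets[t][m];
            if (fv[c] < iso) vin[nin++] = c; else vout[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          double rin[3] = {0, 0, 0}, rout[3] = {0, 0, 0};
          for (int m = 0; m < nin; ++m) {
            rin[0] += px[vin[m]]; rin[1] += py[vin[m]]; rin[2] += pz[vin[m]];
          }
          for (int m = 0; m < nout; ++m) {
            rout[0] += px[vout[m]]; rout[1] += py[vout[m]];
            rout[2] += pz[vout[m]];
          }
          for (int d = 0; d < 3; ++d) { rin[d] /= nin; rout[d] /= nout; }

          auto ev = [&](int a, int b) {
            double pa[3] = {px[a], py[a], pz[a]};
            double pb[3] = {px[b], py[b], pz[b]};
            return edge_vertex(st, gids[a], gids[b], fv[a], fv[b], iso, pa, pb);
          };

          if (nin == 1) {
            int a = vin[0];
            emit_tri(st, ev(a, vout[0]), ev(a, vout[1]), ev(a, vout[2]),
                     rin, rout);
          } else if (nin == 3) {
            int d = vout[0];
            emit_tri(st, ev(vin[0], d), ev(vin[1], d), ev(vin[2], d),
                     rin, rout);
          } else {  // 2 in, 2 out: quad on edges AC, AD, BD, BC
            int A = vin[0], B = vin[1], C = vout[0], D = vout[1];
            int q1 = ev(A, C), q2 = ev(A, D), q3 = ev(B, D), q4 = ev(B, C);
            emit_tri(st, q1, q2, q3, rin, rout);
            emit_tri(st, q1, q3, q4, rin, rout);
          }
        }
      }
    }
  }

  const int nv = static_cast<int>(st.verts.size() / 3);
  const int nf = static_cast<int>(st.tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = st.verts[3 * v];
    V(v, 1) = st.verts[3 * v + 1];
    V(v, 2) = st.verts[3 * v + 2];
  }
  IntegerMatrix Fm(nf, 3);
  for (int q = 0; q < nf; ++q) {
    Fm(q, 0) = st.tris[3 * q] + 1;
    Fm(q, 1) = st.tris[3 * q + 1] + 1;
    Fm(q, 2) = st.tris[3 * q + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
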