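// Binary 3D morphology on voxel masks: 26-connected flood fill, connected
// component labelling, and iterated erosion/dilation (one 26-neighbourhood
// step per iteration, i.e. an approximately spherical structuring element
// grown by repetition).
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

inline int64_t lidx(int i, int j, int k, int nx, int ny) {
  return i + static_cast<int64_t>(nx) * (j + static_cast<int64_t>(ny) * k);
}

void flood_from(const int *mask, int *out, int label, int64_t seed,
                int nx, int ny, int nz) {
  std::vector<int64_t> stack;
  stack.push_back(seed);
  out[seed] = label;
  while (!stack.empty()) {
    int64_t cur = stack.back();
    stack.pop_back();
    int i = static_cast<int>(cur % nx);
    int64_t rest = cur / nx;
    int j = static_cast<int>(rest % ny);
    int k = static_cast<int>(rest / ny);
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          int64_t n = lidx(ii, jj, kk, nx, ny);
          if (mask[n] && !out[n]) {
            out[n] = label;
            stack.push_back(n);
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector flood26_cpp(IntegerVector mask, IntegerVector dims,
                          IntegerVector seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(mask.size());
  int64_t s = lidx(seed[0], seed[1], seed[2], nx, ny);
  if (!mask[s]) stop("seed voxel is background");
  flood_from(INTEGER(mask), INTEGER(out), 1, s, nx, ny, nz);
  return out;
}

// [[Rcpp::export]]
IntegerVector cc26_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(mask.size());
  const int *m = INTEGER(mask);
  int *o = INTEGER(out);
  int label = 0;
  const int64_t n = static_cast<int64_t>(nx) * ny * nz;
  for (int64_t v = 0; v < n; ++v) {
    if (m[v] && !o[v]) flood_from(m, o, ++label, v, nx, ny, nz);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector erode26_cpp(IntegerVector mask, IntegerVector dims, int iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector cur = clone(mask);
  for (int it = 0; it < iter; ++it) {
    IntegerVector nxt(cur.size());
    const int *m = INTEGER(cur);
    int *o = INTEGER(nxt);
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int64_t v = lidx(i, j, k, nx, ny);
          if (!m[v]) continue;
          bool keep = true;
          for (int dk = -1; dk <= 1 && keep; ++dk) {
            int kk = k + dk;
            for (int dj = -1; dj <= 1 && keep; ++dj) {
              int jj = j + dj;
              for (int di = -1; di <= 1; ++di) {
                int ii = i + di;
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                    kk >= nz || !m[lidx(ii, jj, kk, nx, ny)]) {
                  keep = false;
                  break;
                }
              }
            }
          }
          if (keep) o[v] = 1;
        }
      }
    }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export]]
IntegerVector dilate26_cpp(IntegerVector mask, IntegerVector dims, int iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector cur = clone(mask);
  for (int it = 0; it < iter; ++it) {
    IntegerVector nxt = clone(cur);
    const int *m = INTEGER(cur);
    int *o = INTEGER(nxt);
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int64_t v = lidx(i, j, k, nx, ny);
          if (!m[v]) continue;
          for (int dk = -1; dk <= 1; ++dk) {
            int kk = k + dk;
            if (kk < 0 || kk >= nz) continue;
            for (int dj = -1; dj <= 1; ++dj) {
              int jj = j + dj;
              if (jj < 0 || jj >= ny) continue;
              for (int di = -1; di <= 1; ++di) {
                int ii = i + di;
                if (ii < 0 || ii >= nx) continue;
                o[lidx(ii, jj, kk, nx, ny)] = 1;
              }
            }
          }
        }
      }
    }
    cur = nxt;
  }
  return cur;
}

// Chamfer distance propagation: `init` carries exact distances near the
// surface (Inf elsewhere); two sweeps with 26-neighbourhood Euclidean
// steps fill the rest of the grid to within a few percent.
// [[Rcpp::export]]
NumericVector chamfer_cpp(NumericVector init, IntegerVector dims,
                          NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector d = clone(init);
  double *v = REAL(d);
  double step[3][3][3];
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c)
        step[a + 1][b + 1][c + 1] = std::sqrt(
            a * a * spacing[0] * spacing[0] +
            b * b * spacing[1] * spacing[1] +
            c * c * spacing[2] * spacing[2]);
  auto relax = [&](int i, int j, int k, bool forward) {
    int64_t at = lidx(i, j, k, nx, ny);
    double best = v[at];
    for (int c = -1; c <= 1; ++c) {
      int kk = k + c;
      if (kk < 0 || kk >= nz) continue;
      for (int b = -1; b <= 1; ++b) {
        int jj = j + b;
        if (jj < 0 || jj >= ny) continue;
        for (int a = -1; a <= 1; ++a) {
          if (!a && !b && !c) continue;
          // causal half-neighbourhood per sweep direction
          int ord = c * 9 + b * 3 + a;
          if (forward ? ord >= 0 : ord <= 0) continue;
          int ii = i + a;
          if (ii < 0 || ii >= nx) continue;
          double cand = v[lidx(ii, jj, kk, nx, ny)] +
                        step[a + 1][b + 1][c + 1];
          if (cand < best) best = cand;
        }
      }
    }
    v[at] = best;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) relax(i, j, k, true);
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) relax(i, j, k, false);
  return d;
}
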