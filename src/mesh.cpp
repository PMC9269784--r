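#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Isosurface extraction on the Kuhn subdivision: every grid cell is split
// into the six tetrahedra spanned by the monotone lattice paths from corner
// (0,0,0) to (1,1,1). The subdivision is translation-invariant, so faces
// shared by neighbouring cells are triangulated identically and the
// resulting surface is closed. Vertices are linearly interpolated at the
// iso-level crossing of tetrahedron edges and deduplicated by edge key.

namespace {

struct MeshBuilder {
  const double *v;          // field values, column-major (x fastest)
  int nx, ny, nz;
  double iso;
  const double *sp;         // spacing (sx, sy, sz)
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;   // flat x,y,z triples (physical mm)
  std::vector<int> tris;       // flat 0-based vertex index triples

  inline double val(int i, int j, int k) const {
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
  }
  inline uint64_t pid(int i, int j, int k) const {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  }

  // vertex on the edge between lattice points a and b (each packed id)
  int edge_point(int ai, int aj, int ak, int bi, int bj, int bk) {
    uint64_t a = pid(ai, aj, ak), b = pid(bi, bj, bk);
    uint64_t key = a < b ? (a << 32 | b) : (b << 32 | a);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = val(ai, aj, ak), vb = val(bi, bj, bk);
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double x = (ai + t * (bi - ai)) * sp[0];
    double y = (aj + t * (bj - aj)) * sp[1];
    double z = (ak + t * (bk - ak)) * sp[2];
    int id = (int)(verts.size() / 3);
    verts.push_back(x); verts.push_back(y); verts.push_back(z);
    edge_vertex.emplace(key, id);
    return id;
  }

  void emit(int a, int b, int c) {
    tris.push_back(a); tris.push_back(b); tris.push_back(c);
  }

  // corners: 4 lattice points (i,j,k each), values already looked up
  void do_tetra(const int c[4][3]) {
    double tv[4];
    int above = 0, mask = 0;
    for (int m = 0; m < 4; ++m) {
      tv[m] = val(c[m][0], c[m][1], c[m][2]);
      if (tv[m] >= iso) { mask |= 1 << m; ++above; }
    }
    if (above == 0 || above == 4) return;
    if (above == 1 || above == 3) {
      // one isolated corner: triangle on its three incident edges
      int lone = -1;
      for (int m = 0; m < 4; ++m) {
        bool isAbove = (mask >> m) & 1;
        if ((above == 1 && isAbove) || (above == 3 && !isAbove)) lone = m;
      }
      int e[3], q = 0;
      for (int m = 0; m < 4; ++m) {
        if (m == lone) continue;
        e[q++] = edge_point(c[lone][0], c[lone][1], c[lone][2],
                            c[m][0], c[m][1], c[m][2]);
      }
      emit(e[0], e[1], e[2]);
    } else {
      // two/two split: quad over the four crossing edges
      int a[2], b[2], qa = 0, qb = 0;
      for (int m = 0; m < 4; ++m) {
        if ((mask >> m) & 1) a[qa++] = m; else b[qb++] = m;
      }
      int e00 = edge_point(c[a[0]][0], c[a[0]][1], c[a[0]][2],
                           c[b[0]][0], c[b[0]][1], c[b[0]][2]);
      int e01 = edge_point(c[a[0]][0], c[a[0]][1], c[a[0]][2],
                           c[b[1]][0], c[b[1]][1], c[b[1]][2]);
      int e11 = edge_point(c[a[1]][0], c[a[1]][1], c[a[1]][2],
                           c[b[1]][0], c[b[1]][1], c[b[1]][2]);
      int e10 = edge_point(c[a[1]][0], c[a[1]][1], c[a[1]][2],
                           c[b[0]][0], c[b[0]][1], c[b[0]][2]);
      emit(e00, e01, e11);
      emit(e00, e11, e10);
    }
  }
};

const int kPerms[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

} // namespace

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims,
                   NumericVector spacing, double iso) {
  if (dims.size() != 3) stop("dims must have length 3");
  MeshBuilder mb;
  mb.v = REAL(field);
  mb.nx = dims[0]; mb.ny = dims[1]; mb.nz = dims[2];
  mb.iso = iso;
  mb.sp = REAL(spacing);

  for (int k = 0; k + 1 < mb.nz; ++k) {
    for (int j = 0; j + 1 < mb.ny; ++j) {
      for (int i = 0; i + 1 < mb.nx; ++i) {
        // skip cells entirely on one side of the iso level
        int nAbove = 0;
        for (int d = 0; d < 8; ++d) {
          if (mb.val(i + (d & 1), j + ((d >> 1) & 1), k + ((d >> 2) & 1)) >= iso)
            ++nAbove;
        }
        if (nAbove == 0 || nAbove == 8) continue;
        for (int p = 0; p < 6; ++p) {
          int c[4][3] = {{i, j, k}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
          int cur[3] = {i, j, k};
          for (int s = 0; s < 3; ++s) {
            cur[kPerms[p][s]] += 1;
            c[s + 1][0] = cur[0]; c[s + 1][1] = cur[1]; c[s + 1][2] = cur[2];
          }
          mb.do_tetra(c);
        }
      }
    }
  }

  int nv = (int)(mb.verts.size() / 3), nt = (int)(mb.tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int r = 0; r < nv; ++r)
    for (int d = 0; d < 3; ++d) V(r, d) = mb.verts[3 * (size_t)r + d];
  IntegerMatrix F(nt, 3);
  for (int r = 0; r < nt; ++r)
    for (int d = 0; d < 3; ++d) F(r, d) = mb.tris[3 * (size_t)r + d] + 1;
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// Separable Gaussian blur in index space; outside the array is treated as 0.
// [[Rcpp::export(name = ".gaussian_smooth3d")]]
NumericVector gaussian_smooth3d(NumericVector field, IntegerVector dims,
                                double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * (i * i) / (sigma * sigma));
    s += kern[i + radius];
  }
  for (double &w : kern) w /= s;

  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(REAL(field), REAL(field) + n), b(n, 0.0);
  const size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int ext[3] = {nx, ny, nz};

  for (int axis = 0; axis < 3; ++axis) {
    size_t stride = strides[axis];
    int len = ext[axis];
    for (size_t base = 0; base < n; ++base) {
      // walk positions whose coordinate along `axis` is 0
      int coord = (int)((base / stride) % (size_t)len);
      if (coord != 0) continue;
      for (int p = 0; p < len; ++p) {
        double acc = 0.0;
        int lo = std::max(0, p - radius), hi = std::min(len - 1, p + radius);
        for (int q = lo; q <= hi; ++q)
          acc += kern[q - p + radius] * a[base + (size_t)q * stride];
        b[base + (size_t)p * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), REAL(out));
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  const double *x = &pts(0, 0), *y = &pts(0, 1), *z = &pts(0, 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// 26-connected component labeling of a binary volume (BFS).
// [[Rcpp::export(name = ".label_components26")]]
IntegerVector label_components26(IntegerVector grid, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  const int *g = INTEGER(grid);
  int *lab = INTEGER(labels);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < n; ++start) {
    if (!g[start] || lab[start]) continue;
    ++next;
    stack.clear();
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((size_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t q = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
            if (g[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
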