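#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <limits>

using namespace Rcpp;

// 13 unique displacement vectors covering the 26-neighbourhood (one per
// antipodal pair), Chebyshev distance 1.
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_glcm_counts(IntegerVector levels, int nx, int ny, int nz,
                              int ng) {
  // ordered pair counts per direction; symmetrisation happens in R
  IntegerVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int l1 = levels[idx3(x, y, z, nx, ny)];
          if (l1 <= 0) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          const int l2 = levels[idx3(x2, y2, z2, nx, ny)];
          if (l2 <= 0) continue;
          out[(l1 - 1) + ng * (l2 - 1) + ng * ng * d] += 1;
        }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_glrlm_counts(IntegerVector levels, int nx, int ny, int nz,
                               int ng, int maxlen) {
  // run-length counts per direction: maximal runs of equal level, broken by
  // grid boundary and by out-of-mask voxels
  IntegerVector out(ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int l = levels[idx3(x, y, z, nx, ny)];
          if (l <= 0) continue;
          // run starts here iff the predecessor does not continue it
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[idx3(xp, yp, zp, nx, ny)] == l)
            continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 &&
                 zc < nz && levels[idx3(xc, yc, zc, nx, ny)] == l) {
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          if (len > maxlen) len = maxlen;  // cannot happen with sane maxlen
          out[(l - 1) + ng * (len - 1) + ng * maxlen * d] += 1;
        }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, int nx, int ny, int nz) {
  // 26-connected components of equal gray level; returns (level, size) rows
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] <= 0) continue;
    const int l = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      ++size;
      const int cz = cur / (nx * ny);
      const int cy = (cur - cz * nx * ny) / nx;
      const int cx = cur - nx * (cy + ny * cz);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                z2 >= nz)
              continue;
            const int j = idx3(x2, y2, z2, nx, ny);
            if (!seen[j] && levels[j] == l) {
              seen[j] = 1;
              stack.push_back(j);
            }
          }
    }
    zl.push_back(l);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_gldm_counts(IntegerVector levels, int nx, int ny, int nz,
                              int ng, int alpha) {
  // dependence = number of 26-neighbours in mask with |level diff| <= alpha;
  // column j corresponds to dependence j-1 (0..26)
  IntegerMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l = levels[idx3(x, y, z, nx, ny)];
        if (l <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              const int l2 = levels[idx3(x2, y2, z2, nx, ny)];
              if (l2 > 0 && std::abs(l2 - l) <= alpha) ++dep;
            }
        out(l - 1, dep) += 1;
      }
  return out;
}

// ---- Euclidean distance transform (squared), lower-envelope algorithm ----

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h, int n) {
  // squared distance transform of sampled function f on a grid with step h
  std::vector<int> v(n);
  std::vector<double> zpt(n + 1);
  int k = 0;
  v[0] = 0;
  zpt[0] = -std::numeric_limits<double>::infinity();
  zpt[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    if (f[q] == std::numeric_limits<double>::infinity()) continue;
    if (f[v[k]] == std::numeric_limits<double>::infinity()) {
      v[k] = q;
      continue;
    }
    double s = ((f[q] + q * q * h * h) - (f[v[k]] + v[k] * v[k] * h * h)) /
               (2.0 * h * (q - v[k]));
    while (k > 0 && s <= zpt[k]) {
      --k;
      s = ((f[q] + q * q * h * h) - (f[v[k]] + v[k] * v[k] * h * h)) /
          (2.0 * h * (q - v[k]));
    }
    ++k;
    v[k] = q;
    zpt[k] = s;
    zpt[k + 1] = std::numeric_limits<double>::infinity();
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == std::numeric_limits<double>::infinity()) {
      d[q] = std::numeric_limits<double>::infinity();
      continue;
    }
    while (zpt[j + 1] < q * h) ++j;
    d[q] = (q - v[j]) * (q - v[j]) * h * h + f[v[j]];
  }
}

static void edt3d(std::vector<double> &g, int nx, int ny, int nz, double sx,
                  double sy, double sz) {
  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, sx, nx);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = d[x];
    }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, sy, ny);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, sz, nz);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
    }
}

// [[Rcpp::export]]
NumericVector cpp_signed_edt(IntegerVector mask, int nx, int ny, int nz,
                             double sx, double sy, double sz) {
  // negative inside (distance to nearest background voxel centre),
  // positive outside (distance to nearest foreground voxel centre), in mm
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dout(n), din(n);
  for (int i = 0; i < n; ++i) {
    dout[i] = mask[i] ? 0.0 : INF;
    din[i] = mask[i] ? INF : 0.0;
  }
  edt3d(dout, nx, ny, nz, sx, sy, sz);
  edt3d(din, nx, ny, nz, sx, sy, sz);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (dout[i] == INF ? 0.0 : std::sqrt(dout[i])) -
             (din[i] == INF ? 0.0 : std::sqrt(din[i]));
  return out;
}

// ---- iso-surface mesh: marching tetrahedra on the Kuhn subdivision ----

// Kuhn subdivision of the unit cube into 6 tetrahedra sharing the main
// diagonal (0,0,0)-(1,1,1); face diagonals match across neighbouring cells,
// so the extracted surface is watertight.
static const int TET_PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

struct MeshAcc {
  std::vector<double> verts;  // x,y,z triples (triangle soup)
  double area = 0.0;
  double vol = 0.0;
};

static void emit_tri(MeshAcc &acc, const double *p0, const double *p1,
                     const double *p2, const double *outward) {
  // outward = point on the outside; orient normal toward it
  double u[3], v[3], c[3], cen[3];
  for (int i = 0; i < 3; ++i) {
    u[i] = p1[i] - p0[i];
    v[i] = p2[i] - p0[i];
    cen[i] = (p0[i] + p1[i] + p2[i]) / 3.0;
  }
  c[0] = u[1] * v[2] - u[2] * v[1];
  c[1] = u[2] * v[0] - u[0] * v[2];
  c[2] = u[0] * v[1] - u[1] * v[0];
  const double dot = c[0] * (outward[0] - cen[0]) +
                     c[1] * (outward[1] - cen[1]) +
                     c[2] * (outward[2] - cen[2]);
  const double *q1 = p1, *q2 = p2;
  if (dot < 0) { q1 = p2; q2 = p1; }
  acc.area += 0.5 * std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
  // signed tetra volume against the origin; with outward orientation the
  // signed volumes sum to the enclosed volume (divergence theorem)
  acc.vol += (p0[0] * (q1[1] * q2[2] - q1[2] * q2[1]) -
              p0[1] * (q1[0] * q2[2] - q1[2] * q2[0]) +
              p0[2] * (q1[0] * q2[1] - q1[1] * q2[0])) / 6.0;
  acc.verts.insert(acc.verts.end(), {p0[0], p0[1], p0[2], q1[0], q1[1],
                                     q1[2], q2[0], q2[1], q2[2]});
}

static void interp(const double *a, const double *b, double va, double vb,
                   double level, double *out) {
  double t = (level - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + t * (b[i] - a[i]);
}

// [[Rcpp::export]]
List cpp_isosurface(NumericVector field, int nx, int ny, int nz,
                    double level, double sx, double sy, double sz) {
  MeshAcc acc;
  double P[8][3];
  double V[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          V[c] = field[idx3(x + dx, y + dy, z + dz, nx, ny)];
          P[c][0] = (x + dx) * sx;
          P[c][1] = (y + dy) * sy;
          P[c][2] = (z + dz) * sz;
          if (V[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          // tetra corners: walk 0 -> 7 adding axes in permuted order
          int corner[4];
          corner[0] = 0;
          int cur = 0;
          for (int s = 0; s < 3; ++s) {
            cur |= 1 << TET_PERMS[t][s];
            corner[s + 1] = cur;
          }
          int in[4], nin = 0, out[4], nout = 0;
          for (int s = 0; s < 4; ++s) {
            if (V[corner[s]] > level) in[nin++] = corner[s];
            else out[nout++] = corner[s];
          }
          if (nin == 0 || nin == 4) continue;
          double e[4][3];
          if (nin == 1) {
            for (int s = 0; s < 3; ++s)
              interp(P[in[0]], P[out[s]], V[in[0]], V[out[s]], level, e[s]);
            // outward reference: mean of outside corners
            double ref[3] = {
              (P[out[0]][0] + P[out[1]][0] + P[out[2]][0]) / 3.0,
              (P[out[0]][1] + P[out[1]][1] + P[out[2]][1]) / 3.0,
              (P[out[0]][2] + P[out[1]][2] + P[out[2]][2]) / 3.0};
            emit_tri(acc, e[0], e[1], e[2], ref);
          } else if (nin == 3) {
            for (int s = 0; s < 3; ++s)
              interp(P[in[s]], P[out[0]], V[in[s]], V[out[0]], level, e[s]);
            emit_tri(acc, e[0], e[1], e[2], P[out[0]]);
          } else {  // nin == 2: quad split into two triangles
            interp(P[in[0]], P[out[0]], V[in[0]], V[out[0]], level, e[0]);
            interp(P[in[0]], P[out[1]], V[in[0]], V[out[1]], level, e[1]);
            interp(P[in[1]], P[out[1]], V[in[1]], V[out[1]], level, e[2]);
            interp(P[in[1]], P[out[0]], V[in[1]], V[out[0]], level, e[3]);
            double ref[3] = {(P[out[0]][0] + P[out[1]][0]) / 2.0,
                             (P[out[0]][1] + P[out[1]][1]) / 2.0,
                             (P[out[0]][2] + P[out[1]][2]) / 2.0};
            emit_tri(acc, e[0], e[1], e[2], ref);
            emit_tri(acc, e[0], e[2], e[3], ref);
          }
        }
      }
  const size_t ntri = acc.verts.size() / 9;
  NumericMatrix verts(acc.verts.size() / 3, 3);
  for (size_t i = 0; i < acc.verts.size() / 3; ++i) {
    verts(i, 0) = acc.verts[3 * i];
    verts(i, 1) = acc.verts[3 * i + 1];
    verts(i, 2) = acc.verts[3 * i + 2];
  }
  return List::create(_["area"] = acc.area, _["volume"] = std::fabs(acc.vol),
                      _["vertices"] = verts, _["n_triangles"] = (int)ntri);
}

// [[Rcpp::export]]
NumericVector cpp_max_diameters(NumericMatrix pts) {
  // max pairwise distance in 3D and in the three axis-aligned projections
  // (xy, yz, xz); points deduplicated first to keep the O(n^2) pass small
  std::unordered_map<int64_t, int> seen;
  std::vector<double> X, Y, Z;
  for (int i = 0; i < pts.nrow(); ++i) {
    const int64_t kx = (int64_t)std::llround(pts(i, 0) * 1e6);
    const int64_t ky = (int64_t)std::llround(pts(i, 1) * 1e6);
    const int64_t kz = (int64_t)std::llround(pts(i, 2) * 1e6);
    const int64_t key = ((kx * 1000003) ^ ky) * 1000033 ^ kz;
    if (seen.find(key) != seen.end()) continue;
    seen[key] = 1;
    X.push_back(pts(i, 0));
    Y.push_back(pts(i, 1));
    Z.push_back(pts(i, 2));
  }
  double d3 = 0, dxy = 0, dyz = 0, dxz = 0;
  const size_t n = X.size();
  for (size_t i = 0; i + 1 < n; ++i)
    for (size_t j = i + 1; j < n; ++j) {
      const double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
      const double qxy = dx * dx + dy * dy;
      const double qyz = dy * dy + dz * dz;
      const double qxz = dx * dx + dz * dz;
      const double q3 = qxy + dz * dz;
      if (q3 > d3) d3 = q3;
      if (qxy > dxy) dxy = qxy;
      if (qyz > dyz) dyz = qyz;
      if (qxz > dxz) dxz = qxz;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dxy),
                               std::sqrt(dyz), std::sqrt(dxz));
}
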