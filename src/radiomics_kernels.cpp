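// Counting kernels behind the texture matrices, plus surface helpers.
// Discretized ROIs arrive as integer arrays (column-major, dim c(X,Y,Z))
// with level 0 marking voxels outside the mask and 1..Ng inside.

#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline bool in_grid(int x, int y, int z, int X, int Y, int Z) {
  return x >= 0 && x < X && y >= 0 && y < Y && z >= 0 && z < Z;
}

// Directed co-occurrence counts for a set of offsets; result Ng x Ng x nOff.
// [[Rcpp::export]]
NumericVector rx_pair_counts(IntegerVector lev, IntegerVector dims, int Ng,
                             IntegerMatrix offsets) {
  const int X = dims[0], Y = dims[1], Z = dims[2], nd = offsets.nrow();
  NumericVector out(R_xlen_t(Ng) * Ng * nd);
  const int *pl = lev.begin();
  for (int d = 0; d < nd; ++d) {
    const int ox = offsets(d, 0), oy = offsets(d, 1), oz = offsets(d, 2);
    double *m = out.begin() + R_xlen_t(Ng) * Ng * d;
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int x = 0; x < X; ++x) {
          const int li = pl[x + R_xlen_t(X) * (y + R_xlen_t(Y) * z)];
          if (li == 0) continue;
          const int x2 = x + ox, y2 = y + oy, z2 = z + oz;
          if (!in_grid(x2, y2, z2, X, Y, Z)) continue;
          const int lj = pl[x2 + R_xlen_t(X) * (y2 + R_xlen_t(Y) * z2)];
          if (lj == 0) continue;
          m[(li - 1) + R_xlen_t(Ng) * (lj - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(Ng, Ng, nd);
  return out;
}

// Maximal same-level runs along one offset; counts matrix Ng x maxlen.
// [[Rcpp::export]]
NumericMatrix rx_run_counts(IntegerVector lev, IntegerVector dims, int Ng,
                            IntegerVector offset, int maxlen) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int ox = offset[0], oy = offset[1], oz = offset[2];
  NumericMatrix out(Ng, maxlen);
  const int *pl = lev.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const int li = pl[x + R_xlen_t(X) * (y + R_xlen_t(Y) * z)];
        if (li == 0) continue;
        // run starts here iff the previous voxel along -offset differs
        const int xp = x - ox, yp = y - oy, zp = z - oz;
        if (in_grid(xp, yp, zp, X, Y, Z) &&
            pl[xp + R_xlen_t(X) * (yp + R_xlen_t(Y) * zp)] == li)
          continue;
        int len = 1, xc = x + ox, yc = y + oy, zc = z + oz;
        while (in_grid(xc, yc, zc, X, Y, Z) &&
               pl[xc + R_xlen_t(X) * (yc + R_xlen_t(Y) * zc)] == li) {
          ++len; xc += ox; yc += oy; zc += oz;
        }
        if (len > maxlen) stop("rx_run_counts: run longer than maxlen");
        out(li - 1, len - 1) += 1.0;
      }
  return out;
}

// 26-connected zones of equal level; returns (level, size) per zone.
// [[Rcpp::export]]
IntegerMatrix rx_zone_sizes(IntegerVector lev, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = R_xlen_t(X) * Y * Z;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  const int *pl = lev.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (pl[i] == 0 || seen[i]) continue;
    const int level = pl[i];
    int size = 0;
    std::queue<R_xlen_t> q;
    q.push(i); seen[i] = 1;
    while (!q.empty()) {
      const R_xlen_t v = q.front(); q.pop();
      ++size;
      const int x = v % X, y = (v / X) % Y, z = v / (R_xlen_t(X) * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (!in_grid(x2, y2, z2, X, Y, Z)) continue;
            const R_xlen_t j = x2 + R_xlen_t(X) * (y2 + R_xlen_t(Y) * z2);
            if (!seen[j] && pl[j] == level) { seen[j] = 1; q.push(j); }
          }
    }
    zl.push_back(level); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) { out(k, 0) = zl[k]; out(k, 1) = zs[k]; }
  return out;
}

// Dependence counts: for each in-mask voxel the number of in-mask
// 26-neighbours with |level difference| <= alpha; matrix over
// (level, neighbours + 1).
// [[Rcpp::export]]
NumericMatrix rx_dependence_counts(IntegerVector lev, IntegerVector dims,
                                   int Ng, int alpha) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericMatrix out(Ng, 27);
  const int *pl = lev.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const int li = pl[x + R_xlen_t(X) * (y + R_xlen_t(Y) * z)];
        if (li == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!in_grid(x2, y2, z2, X, Y, Z)) continue;
              const int lj = pl[x2 + R_xlen_t(X) * (y2 + R_xlen_t(Y) * z2)];
              if (lj != 0 && std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep) += 1.0;
      }
  return out;
}

// Minimum Euclidean distance from each row of A to the rows of B (n x 3).
// [[Rcpp::export]]
NumericVector rx_min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Marching tetrahedra on a scalar field (iso-level 0.5, cell corners at
// voxel centres, one layer of zero padding so the surface closes). Crossing
// vertices are placed by linear interpolation between corner values.
// Returns a triangle soup: one row per triangle, 9 columns (three xyz
// vertices, voxel units, 0-based voxel-centre coordinates).
static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};

// [[Rcpp::export]]
NumericMatrix rx_surface_mesh(NumericVector field, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const double *pm = field.begin();
  // padded field value at voxel-centre grid point (x,y,z) in [-1, X] etc.
  auto fval = [&](int x, int y, int z) -> double {
    if (!in_grid(x, y, z, X, Y, Z)) return 0.0;
    return pm[x + R_xlen_t(X) * (y + R_xlen_t(Y) * z)];
  };
  std::vector<double> tri;
  const int corner[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                            {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  double vx[8], vy[8], vz[8], fv[8];
  for (int z = -1; z < Z; ++z)
    for (int y = -1; y < Y; ++y)
      for (int x = -1; x < X; ++x) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          const int cx = x + corner[c][0], cy = y + corner[c][1],
                    cz = z + corner[c][2];
          fv[c] = fval(cx, cy, cz);
          vx[c] = cx; vy[c] = cy; vz[c] = cz;
          if (fv[c] > 0.5) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int inside = 0, idxin[4], idxout[4];
          int nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (fv[T[k]] > 0.5) { idxin[nin++] = T[k]; ++inside; }
            else idxout[nout++] = T[k];
          }
          if (inside == 0 || inside == 4) continue;
          auto emitv = [&](int a, int b, double *p) {
            double t = (0.5 - fv[a]) / (fv[b] - fv[a]);
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
            p[0] = vx[a] + t * (vx[b] - vx[a]);
            p[1] = vy[a] + t * (vy[b] - vy[a]);
            p[2] = vz[a] + t * (vz[b] - vz[a]);
          };
          double P[4][3];
          // emit a triangle oriented so its normal points away from the
          // inside vertex `iv` (outward orientation; needed for the signed
          // divergence-theorem volume)
          auto emit_tri = [&](double *A, double *Bp, double *Cp, int iv) {
            const double ax = Bp[0]-A[0], ay = Bp[1]-A[1], az2 = Bp[2]-A[2];
            const double bx = Cp[0]-A[0], by = Cp[1]-A[1], bz = Cp[2]-A[2];
            const double nx = ay*bz - az2*by, ny = az2*bx - ax*bz,
                         nz = ax*by - ay*bx;
            const double dxp = A[0]-vx[iv], dyp = A[1]-vy[iv], dzp = A[2]-vz[iv];
            const bool flip = (nx*dxp + ny*dyp + nz*dzp) < 0;
            double *v1 = flip ? Cp : Bp, *v2 = flip ? Bp : Cp;
            for (int d = 0; d < 3; ++d) tri.push_back(A[d]);
            for (int d = 0; d < 3; ++d) tri.push_back(v1[d]);
            for (int d = 0; d < 3; ++d) tri.push_back(v2[d]);
          };
          if (inside == 1 || inside == 3) {
            const int apex = (inside == 1) ? idxin[0] : idxout[0];
            const int *base = (inside == 1) ? idxout : idxin;
            for (int k = 0; k < 3; ++k) emitv(apex, base[k], P[k]);
            emit_tri(P[0], P[1], P[2], idxin[0]);
          } else {  // 2 in, 2 out -> quad, split into two triangles
            emitv(idxin[0], idxout[0], P[0]);
            emitv(idxin[0], idxout[1], P[1]);
            emitv(idxin[1], idxout[1], P[2]);
            emitv(idxin[1], idxout[0], P[3]);
            emit_tri(P[0], P[1], P[2], idxin[0]);
            emit_tri(P[0], P[2], P[3], idxin[0]);
          }
        }
      }
  const int nt = tri.size() / 9;
  NumericMatrix out(nt, 9);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 9; ++j) out(i, j) = tri[i * 9 + j];
  return out;
}
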