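#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shortest travel time over the 26-neighbour voxel graph. Edge cost is the
// Euclidean edge length divided by the mean of the two node speeds, which
// reproduces expanding (ellipsoidal in anisotropic speed fields) wavefronts
// with modest grid anisotropy.
// [[Rcpp::export]]
NumericVector dijkstra_grid_cpp(IntegerMatrix ijk, IntegerVector dims,
                                IntegerVector row_of, NumericVector speed,
                                IntegerVector start_rows, NumericVector onsets,
                                double res) {
  const int n = ijk.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector time(n, R_PosInf);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < start_rows.size(); ++s) {
    int r = start_rows[s] - 1;
    if (onsets[s] < time[r]) { time[r] = onsets[s]; pq.push(QE(onsets[s], r)); }
  }
  // 26-neighbour offsets and lengths
  int offs[26][3]; double len[26]; int m = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs[m][0] = dx; offs[m][1] = dy; offs[m][2] = dz;
        len[m] = res * std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        ++m;
      }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double t = top.first; int u = top.second;
    if (t > time[u]) continue;
    int ui = ijk(u, 0), uj = ijk(u, 1), uk = ijk(u, 2);
    for (int e = 0; e < 26; ++e) {
      int vi = ui + offs[e][0], vj = uj + offs[e][1], vk = uk + offs[e][2];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      int v = row_of[vi + nx * (vj + (long)ny * vk)];
      if (v == 0) continue;
      --v;
      double w = len[e] / (0.5 * (speed[u] + speed[v]));
      double tv = t + w;
      if (tv < time[v]) { time[v] = tv; pq.push(QE(tv, v)); }
    }
  }
  return time;
}

static inline double curve_at(const NumericMatrix& curves, int g, double lag,
                              double dt, int nt) {
  if (lag <= 0.0) return curves(0, g);
  double x = lag / dt;
  int i0 = (int)std::floor(x);
  if (i0 >= nt - 1) return curves(nt - 1, g);
  double f = x - i0;
  return curves(i0, g) * (1.0 - f) + curves(i0 + 1, g) * f;
}

// Multiple-dipole equivalent generator, aggregated into spatial blocks.
// Each pair of face-adjacent myocardial voxels i,j (j = i + e_k) contributes
// a dipole moment gain * w_ij * (V_i - V_j) along +e_k, split equally
// between the blocks of i and j; faces against non-myocardium contribute
// nothing. The face weight w_ij = min(w_i, w_j) attenuates faces touching
// low-source-density tissue (the sparse Purkinje-like layer) while keeping
// spatially uniform potential fields exactly silent.
// Returns a (3 * nblocks) x length(tgrid) matrix in heart-local axes.
// [[Rcpp::export]]
NumericMatrix dipole_sequence_cpp(IntegerMatrix nbr_plus, NumericVector act,
                                  IntegerVector group, NumericMatrix curves,
                                  double dt_curve, IntegerVector block,
                                  int nblocks, NumericVector tgrid, double gain,
                                  NumericVector node_weight) {
  const int n = nbr_plus.nrow();
  const int nt = tgrid.size();
  const int nc = curves.nrow();
  NumericMatrix D(3 * nblocks, nt);
  std::vector<double> V(n);
  for (int it = 0; it < nt; ++it) {
    double t = tgrid[it];
    for (int u = 0; u < n; ++u)
      V[u] = curve_at(curves, group[u] - 1, t - act[u], dt_curve, nc);
    for (int u = 0; u < n; ++u) {
      int bu = block[u] - 1;
      for (int a = 0; a < 3; ++a) {
        int v = nbr_plus(u, a);
        if (v == 0) continue;
        double w = std::min(node_weight[u], node_weight[v - 1]);
        double dv = 0.5 * gain * w * (V[u] - V[v - 1]);
        D(3 * bu + a, it) += dv;
        D(3 * (block[v - 1] - 1) + a, it) += dv;
      }
    }
  }
  return D;
}

// Signed solid angle of triangle (r1,r2,r3) seen from the origin
// (van Oosterom & Strackee 1983). Positive when the vertex order appears
// counter-clockwise from the observation point.
static inline double tri_solid_angle(const double* a, const double* b,
                                     const double* c) {
  double la = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
  double lb = std::sqrt(b[0]*b[0] + b[1]*b[1] + b[2]*b[2]);
  double lc = std::sqrt(c[0]*c[0] + c[1]*c[1] + c[2]*c[2]);
  const double eps = 1e-12;
  if (la < eps || lb < eps || lc < eps) return 0.0; // observation at a vertex
  double num = a[0]*(b[1]*c[2] - b[2]*c[1])
             - a[1]*(b[0]*c[2] - b[2]*c[0])
             + a[2]*(b[0]*c[1] - b[1]*c[0]);
  double den = la*lb*lc + (a[0]*b[0] + a[1]*b[1] + a[2]*b[2]) * lc
                        + (a[0]*c[0] + a[1]*c[1] + a[2]*c[2]) * lb
                        + (b[0]*c[0] + b[1]*c[1] + b[2]*c[2]) * la;
  return 2.0 * std::atan2(num, den);
}

// Double-layer BEM matrix: for every observation point, the solid angle of
// each triangle is distributed in equal thirds to the triangle's vertices.
// Triangles having the observation point as one of their vertices contribute
// zero (planar principal value); the caller applies the auto-solid-angle
// correction per surface.
// [[Rcpp::export]]
NumericMatrix solid_angle_weights_cpp(NumericMatrix obs, NumericMatrix verts,
                                      IntegerMatrix tris) {
  const int P = obs.nrow(), V = verts.nrow(), T = tris.nrow();
  NumericMatrix W(P, V);
  std::vector<double> vx(V), vy(V), vz(V);
  for (int j = 0; j < V; ++j) { vx[j] = verts(j,0); vy[j] = verts(j,1); vz[j] = verts(j,2); }
  for (int i = 0; i < P; ++i) {
    double ox = obs(i, 0), oy = obs(i, 1), oz = obs(i, 2);
    for (int t = 0; t < T; ++t) {
      int i1 = tris(t, 0) - 1, i2 = tris(t, 1) - 1, i3 = tris(t, 2) - 1;
      double a[3] = { vx[i1] - ox, vy[i1] - oy, vz[i1] - oz };
      double b[3] = { vx[i2] - ox, vy[i2] - oy, vz[i2] - oz };
      double c[3] = { vx[i3] - ox, vy[i3] - oy, vz[i3] - oz };
      double om = tri_solid_angle(a, b, c);
      if (om == 0.0) continue;
      double third = om / 3.0;
      W(i, i1) += third; W(i, i2) += third; W(i, i3) += third;
    }
  }
  return W;
}

// Infinite-medium dipole kernel: G[i, 3*(m-1)+k] = (r_i - s_m)_k / (4 pi R^3)
// [[Rcpp::export]]
NumericMatrix dipole_kernel_cpp(NumericMatrix obs, NumericMatrix src) {
  const int P = obs.nrow(), M = src.nrow();
  NumericMatrix G(P, 3 * M);
  const double c4pi = 4.0 * M_PI;
  for (int i = 0; i < P; ++i) {
    for (int m = 0; m < M; ++m) {
      double rx = obs(i,0) - src(m,0);
      double ry = obs(i,1) - src(m,1);
      double rz = obs(i,2) - src(m,2);
      double r2 = rx*rx + ry*ry + rz*rz;
      double ir3 = 1.0 / (c4pi * r2 * std::sqrt(r2));
      G(i, 3*m)     = rx * ir3;
      G(i, 3*m + 1) = ry * ir3;
      G(i, 3*m + 2) = rz * ir3;
    }
  }
  return G;
}
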