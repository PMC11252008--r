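#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
using namespace Rcpp;

// Arrays arrive in R's column-major layout with dim = (z, y, x):
// index = z + nz*y + nz*ny*x.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// neighbour offsets for 6/18/26 connectivity
static std::vector<std::array<int,3>> conn_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int,3>> off = conn_offsets(connectivity);
  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!mask[i] || lab[i]) continue;
        lab[i] = ++next;
        q.push({z, y, x});
        while (!q.empty()) {
          std::array<int,3> p = q.front(); q.pop();
          for (size_t k = 0; k < off.size(); ++k) {
            int zz = p[0] + off[k][0], yy = p[1] + off[k][1],
                xx = p[2] + off[k][2];
            if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx)
              continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; q.push({zz, yy, xx}); }
          }
        }
      }
  lab.attr("n") = next;
  return lab;
}

// min/max filter over an arbitrary offset set (Euclidean ball given from R).
// op: 0 = min (erosion), 1 = max (dilation). Out-of-bounds neighbours are
// ignored (equivalent to padding with +Inf for min, -Inf for max).
// [[Rcpp::export(name = ".cpp_ball_filter")]]
NumericVector cpp_ball_filter(NumericVector vol, IntegerVector dims,
                              IntegerMatrix offsets, int op) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out(vol.size());
  int K = offsets.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = op == 0 ? R_PosInf : R_NegInf;
        for (int k = 0; k < K; ++k) {
          int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
              xx = x + offsets(k, 2);
          if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx)
            continue;
          double v = vol[lin(zz, yy, xx, nz, ny)];
          if (op == 0) { if (v < acc) acc = v; }
          else         { if (v > acc) acc = v; }
        }
        out[lin(z, y, x, nz, ny)] = acc;
      }
  return out;
}

// Marching cubes over a binary field using a 256-case triangle table built in
// R. Cube corners are numbered by bit i = z*1 + y*2 ... see R side; tri_table
// is a list of integer vectors (3 edge ids per triangle, 0-based, -1 none).
// Edge id e in 0..11 refers to the cube edge list passed as edge_corners
// (12 x 2, 0-based corner ids); corner coordinates passed as corner_zyx
// (8 x 3). Vertices land on edge midpoints (binary field, iso 0.5).
// Returns list(vertices = N x 3 (voxel coords), faces = M x 3 1-based).
// [[Rcpp::export(name = ".cpp_march_binary")]]
List cpp_march_binary(LogicalVector occ, IntegerVector dims, List tri_table,
                      IntegerMatrix edge_corners, IntegerMatrix corner_zyx) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  // global edge key: ((z * ny + y) * nx + x) * 3 + axis, anchored at the
  // lower voxel of the edge; axis 0=z,1=y,2=x
  std::map<long long, int> vid;
  std::vector<double> vz, vy, vx;
  std::vector<int> f1, f2, f3;
  // precompute per-edge: anchor corner and axis
  int eanchor[12], eaxis[12];
  for (int e = 0; e < 12; ++e) {
    int a = edge_corners(e, 0), b = edge_corners(e, 1);
    int az = corner_zyx(a, 0), ay = corner_zyx(a, 1), ax = corner_zyx(a, 2);
    int bz = corner_zyx(b, 0), by = corner_zyx(b, 1), bx = corner_zyx(b, 2);
    // anchor = min corner
    int anch = (az + ay + ax <= bz + by + bx) ? a : b;
    eanchor[e] = anch;
    if (az != bz) eaxis[e] = 0;
    else if (ay != by) eaxis[e] = 1;
    else eaxis[e] = 2;
  }
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        int cfg = 0;
        for (int c = 0; c < 8; ++c) {
          int zz = z + corner_zyx(c, 0), yy = y + corner_zyx(c, 1),
              xx = x + corner_zyx(c, 2);
          if (occ[lin(zz, yy, xx, nz, ny)]) cfg |= (1 << c);
        }
        if (cfg == 0 || cfg == 255) continue;
        IntegerVector tris = tri_table[cfg];
        for (int t = 0; t + 2 < tris.size(); t += 3) {
          int ids[3];
          for (int k = 0; k < 3; ++k) {
            int e = tris[t + k];
            int anch = eanchor[e];
            long long gz = z + corner_zyx(anch, 0);
            long long gy = y + corner_zyx(anch, 1);
            long long gx = x + corner_zyx(anch, 2);
            long long key = ((gz * ny + gy) * nx + gx) * 3 + eaxis[e];
            std::map<long long, int>::iterator it = vid.find(key);
            int id;
            if (it == vid.end()) {
              id = (int) vz.size();
              vid[key] = id;
              // midpoint of the edge
              double mz = gz + (eaxis[e] == 0 ? 0.5 : 0.0);
              double my = gy + (eaxis[e] == 1 ? 0.5 : 0.0);
              double mx = gx + (eaxis[e] == 2 ? 0.5 : 0.0);
              vz.push_back(mz); vy.push_back(my); vx.push_back(mx);
            } else id = it->second;
            ids[k] = id;
          }
          f1.push_back(ids[0] + 1); f2.push_back(ids[1] + 1);
          f3.push_back(ids[2] + 1);
        }
      }
  int nv = (int) vz.size(), nf = (int) f1.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vz[i]; V(i,1) = vy[i]; V(i,2) = vx[i]; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) { Fm(i,0) = f1[i]; Fm(i,1) = f2[i]; Fm(i,2) = f3[i]; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Taubin lambda/mu smoothing on a triangle mesh (uniform weights).
// [[Rcpp::export(name = ".cpp_taubin_smooth")]]
NumericMatrix cpp_taubin_smooth(NumericMatrix verts, IntegerMatrix faces,
                                double lambda, double mu, int iters) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::vector<int>> nb(nv);
  for (int i = 0; i < nf; ++i) {
    int a = faces(i, 0) - 1, b = faces(i, 1) - 1, c = faces(i, 2) - 1;
    nb[a].push_back(b); nb[a].push_back(c);
    nb[b].push_back(a); nb[b].push_back(c);
    nb[c].push_back(a); nb[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(nb[i].begin(), nb[i].end());
    nb[i].erase(std::unique(nb[i].begin(), nb[i].end()), nb[i].end());
  }
  NumericMatrix V = clone(verts);
  NumericMatrix W(nv, 3);
  for (int it = 0; it < iters; ++it) {
    double fac[2] = {lambda, mu};
    for (int s = 0; s < 2; ++s) {
      for (int i = 0; i < nv; ++i) {
        if (nb[i].empty()) { W(i,0)=V(i,0); W(i,1)=V(i,1); W(i,2)=V(i,2); continue; }
        double mz = 0, my = 0, mx = 0;
        for (size_t k = 0; k < nb[i].size(); ++k) {
          mz += V(nb[i][k], 0); my += V(nb[i][k], 1); mx += V(nb[i][k], 2);
        }
        double n = (double) nb[i].size();
        W(i,0) = V(i,0) + fac[s] * (mz / n - V(i,0));
        W(i,1) = V(i,1) + fac[s] * (my / n - V(i,1));
        W(i,2) = V(i,2) + fac[s] * (mx / n - V(i,2));
      }
      V = clone(W);
    }
  }
  return V;
}

// binary dilation by scattering offsets from foreground voxels only
// (much faster than the dense min/max filter when foreground is sparse)
// [[Rcpp::export(name = ".cpp_binary_dilate")]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dims,
                                IntegerMatrix offsets) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out(mask.size());
  int K = offsets.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!mask[i]) continue;
        for (int k = 0; k < K; ++k) {
          int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
              xx = x + offsets(k, 2);
          if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx)
            continue;
          out[lin(zz, yy, xx, nz, ny)] = true;
        }
      }
  return out;
}
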