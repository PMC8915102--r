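#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra over a scalar field on a regular grid. Each cell is
// split into six tetrahedra sharing the main diagonal; surface vertices are
// linearly interpolated on tetrahedron edges and welded by grid-edge
// identity, so the mesh is watertight by construction.

static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

// [[Rcpp::export]]
List mt_isosurface(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto lin = [&](int x, int y, int z) {
    return (long long)x + (long long)nx * (y + (long long)ny * z);
  };
  std::unordered_map<long long, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> t1, t2, t3;

  auto vertex_on_edge = [&](long long ga, long long gb,
                            double fa, double fb) {
    long long a = ga, b = gb;
    double f1 = fa, f2 = fb;
    if (a > b) { std::swap(a, b); std::swap(f1, f2); }
    long long key = a * (long long)(nx) * ny * nz + b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - f1) / (f2 - f1);
    int az = (int)(a / ((long long)nx * ny));
    int ay = (int)((a / nx) % ny), ax = (int)(a % nx);
    int bz = (int)(b / ((long long)nx * ny));
    int by = (int)((b / nx) % ny), bx = (int)(b % nx);
    vx.push_back(ax + 1 + t * (bx - ax));   // 1-based voxel coordinates
    vy.push_back(ay + 1 + t * (by - ay));
    vz.push_back(az + 1 + t * (bz - az));
    int id = (int)vx.size();                 // 1-based vertex index
    edge_vertex[key] = id;
    return id;
  };

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double f[8];
        long long g[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          g[c] = lin(x + CUBE[c][0], y + CUBE[c][1], z + CUBE[c][2]);
          f[c] = field[g[c]];
          (f[c] >= iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            id[c] = TETS[t][c];
            in[c] = f[id[c]] >= iso;
            nin += in[c];
          }
          if (nin == 0 || nin == 4) continue;
          int A[4], B[4], na = 0, nb = 0;      // inside / outside corners
          for (int c = 0; c < 4; ++c) (in[c] ? A[na++] : B[nb++]) = id[c];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? A[0] : B[0];
            int *oth = (nin == 1) ? B : A;
            int p = vertex_on_edge(g[apex], g[oth[0]], f[apex], f[oth[0]]);
            int q = vertex_on_edge(g[apex], g[oth[1]], f[apex], f[oth[1]]);
            int r = vertex_on_edge(g[apex], g[oth[2]], f[apex], f[oth[2]]);
            if (p != q && q != r && p != r) {
              t1.push_back(p); t2.push_back(q); t3.push_back(r);
            }
          } else {                              // 2 in, 2 out: quad
            int p = vertex_on_edge(g[A[0]], g[B[0]], f[A[0]], f[B[0]]);
            int q = vertex_on_edge(g[A[0]], g[B[1]], f[A[0]], f[B[1]]);
            int r = vertex_on_edge(g[A[1]], g[B[1]], f[A[1]], f[B[1]]);
            int s = vertex_on_edge(g[A[1]], g[B[0]], f[A[1]], f[B[0]]);
            if (p != q && q != r && p != r) {
              t1.push_back(p); t2.push_back(q); t3.push_back(r);
            }
            if (p != r && r != s && p != s) {
              t1.push_back(p); t2.push_back(r); t3.push_back(s);
            }
          }
        }
      }

  NumericMatrix V(vx.size(), 3);
  for (size_t i = 0; i < vx.size(); ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  IntegerMatrix T(t1.size(), 3);
  for (size_t i = 0; i < t1.size(); ++i) {
    T(i, 0) = t1[i]; T(i, 1) = t2[i]; T(i, 2) = t3[i];
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// Attraction-repulsion relaxation of mesh nodes on the unit sphere.
// Per cycle, from the cycle-start positions C: every node is pulled toward
// the mean of its mesh neighbours (attraction, weights ||d||^2 + CA2), pushed
// away from all other nodes with magnitude 1/||d|| (repulsion, factor
// CR/(2I)), then projected back onto the unit sphere. Stops when the mean
// per-node displacement over a cycle falls below tol.

// [[Rcpp::export]]
List ar_cycles(NumericMatrix coords, IntegerVector nb_idx, IntegerVector nb_ptr,
               double ca1, double ca2, double cr, int max_cycles, double tol) {
  const int I = coords.nrow();
  std::vector<double> X(I), Y(I), Z(I), NX(I), NY(I), NZ(I);
  for (int i = 0; i < I; ++i) {
    X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2);
  }
  double mean_disp = R_PosInf;
  int cyc = 0;
  const double rep = cr / (2.0 * I);
  while (cyc < max_cycles && mean_disp >= tol) {
    ++cyc;
    for (int i = 0; i < I; ++i) {
      double ax = 0, ay = 0, az = 0;
      for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; ++k) {
        int j = nb_idx[k];
        double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
        double d2 = dx * dx + dy * dy + dz * dz;
        double w = d2 + ca2;                  // d*||d||^2 + CA2*d
        ax += w * dx; ay += w * dy; az += w * dz;
      }
      double rx = 0, ry = 0, rz = 0;
      for (int j = 0; j < I; ++j) {
        if (j == i) continue;
        double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < 1e-24) continue;
        double w = 1.0 / d2;
        rx += w * dx; ry += w * dy; rz += w * dz;
      }
      double nxv = X[i] + ca1 * ax - rep * rx;   // repulsive sign
      double nyv = Y[i] + ca1 * ay - rep * ry;
      double nzv = Z[i] + ca1 * az - rep * rz;
      double nrm = std::sqrt(nxv * nxv + nyv * nyv + nzv * nzv);
      if (nrm < 1e-300 || !std::isfinite(nrm))
        stop("non-finite or vanishing node update in attraction-repulsion");
      NX[i] = nxv / nrm; NY[i] = nyv / nrm; NZ[i] = nzv / nrm;
    }
    double s = 0;
    for (int i = 0; i < I; ++i) {
      double dx = NX[i] - X[i], dy = NY[i] - Y[i], dz = NZ[i] - Z[i];
      s += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    mean_disp = s / I;
    X.swap(NX); Y.swap(NY); Z.swap(NZ);
  }
  NumericMatrix out(I, 3);
  for (int i = 0; i < I; ++i) {
    out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i];
  }
  return List::create(_["coords"] = out, _["cycles"] = cyc,
                      _["mean_disp"] = mean_disp);
}
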