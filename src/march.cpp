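// Iso-surface extraction of a binary volume at level 0.5 by marching
// tetrahedra on the uniform 6-tetrahedron (Kuhn) subdivision of each cell
// between voxel centers. All crossing vertices sit at edge midpoints (binary
// data), the subdivision is face-consistent across cells, and the resulting
// mesh is watertight whenever the foreground does not touch the grid border
// (capping pads the volume with one background layer so it never does).
// Triangles are oriented with normals pointing from bone into background.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// cube corner offsets in (x, y, z), standard marching-cubes numbering
static const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
// Kuhn subdivision: six tets sharing the 0-6 diagonal
static const int TETS[6][4] = {{0, 1, 2, 6}, {0, 1, 5, 6}, {0, 3, 2, 6},
                               {0, 3, 7, 6}, {0, 4, 5, 6}, {0, 4, 7, 6}};

struct MeshBuilder {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> t0, t1, t2;

  int vertex(uint64_t ia, uint64_t ib, const double* pa, const double* pb) {
    uint64_t key = ia < ib ? (ia << 32) | ib : (ib << 32) | ia;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    int id = (int)vx.size();
    vx.push_back(0.5 * (pa[0] + pb[0]));
    vy.push_back(0.5 * (pa[1] + pb[1]));
    vz.push_back(0.5 * (pa[2] + pb[2]));
    edge_vertex.emplace(key, id);
    return id;
  }

  void tri(int a, int b, int c, const double* w, const double* n0) {
    // orient so normal = (B-A)x(C-A) has positive dot with w (fg -> bg)
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy;
    double ny = uz * wx - ux * wz;
    double nz = ux * wy - uy * wx;
    (void)n0;
    double d = nx * w[0] + ny * w[1] + nz * w[2];
    if (d >= 0) {
      t0.push_back(a); t1.push_back(b); t2.push_back(c);
    } else {
      t0.push_back(a); t1.push_back(c); t2.push_back(b);
    }
  }
};

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(IntegerVector data, IntegerVector dim, double h,
                       bool cap) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* bin = INTEGER(data);
  int pad = cap ? 1 : 0;
  int gx = nx + 2 * pad, gy = ny + 2 * pad, gz = nz + 2 * pad;
  auto value = [&](int X, int Y, int Z) -> int {
    int x = X - pad, y = Y - pad, z = Z - pad;
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return bin[z + (long)nz * (y + (long)ny * x)];
  };
  MeshBuilder mb;
  double P[8][3];
  uint64_t gid[8];
  int val[8];
  for (int X = 0; X < gx - 1; ++X)
    for (int Y = 0; Y < gy - 1; ++Y)
      for (int Z = 0; Z < gz - 1; ++Z) {
        int s = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = X + CX[c], cy = Y + CY[c], cz = Z + CZ[c];
          val[c] = value(cx, cy, cz);
          s += val[c];
          P[c][0] = (cx - pad) * h;
          P[c][1] = (cy - pad) * h;
          P[c][2] = (cz - pad) * h;
          gid[c] = (uint64_t)cz + (uint64_t)gz * ((uint64_t)cy +
                   (uint64_t)gy * (uint64_t)cx);
        }
        if (s == 0 || s == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int cs[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int fg[4], bg[4], nfg = 0, nbg = 0;
          for (int j = 0; j < 4; ++j) {
            if (val[cs[j]]) fg[nfg++] = cs[j]; else bg[nbg++] = cs[j];
          }
          if (nfg == 0 || nfg == 4) continue;
          double w[3];
          if (nfg == 1) {
            int f = fg[0];
            int a = mb.vertex(gid[f], gid[bg[0]], P[f], P[bg[0]]);
            int b = mb.vertex(gid[f], gid[bg[1]], P[f], P[bg[1]]);
            int c = mb.vertex(gid[f], gid[bg[2]], P[f], P[bg[2]]);
            for (int k = 0; k < 3; ++k) w[k] = P[bg[0]][k] - P[f][k];
            mb.tri(a, b, c, w, nullptr);
          } else if (nfg == 3) {
            int b0 = bg[0];
            int a = mb.vertex(gid[b0], gid[fg[0]], P[b0], P[fg[0]]);
            int b = mb.vertex(gid[b0], gid[fg[1]], P[b0], P[fg[1]]);
            int c = mb.vertex(gid[b0], gid[fg[2]], P[b0], P[fg[2]]);
            for (int k = 0; k < 3; ++k) w[k] = P[b0][k] - P[fg[0]][k];
            mb.tri(a, b, c, w, nullptr);
          } else {
            int a0 = fg[0], a1 = fg[1], b0 = bg[0], b1 = bg[1];
            int q0 = mb.vertex(gid[a0], gid[b0], P[a0], P[b0]);
            int q1 = mb.vertex(gid[a0], gid[b1], P[a0], P[b1]);
            int q2 = mb.vertex(gid[a1], gid[b1], P[a1], P[b1]);
            int q3 = mb.vertex(gid[a1], gid[b0], P[a1], P[b0]);
            for (int k = 0; k < 3; ++k) w[k] = P[b0][k] - P[a0][k];
            mb.tri(q0, q1, q2, w, nullptr);
            mb.tri(q0, q2, q3, w, nullptr);
          }
        }
      }
  int nv = (int)mb.vx.size(), nt = (int)mb.t0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = mb.vx[i];
    V(i, 1) = mb.vy[i];
    V(i, 2) = mb.vz[i];
  }
  IntegerMatrix Tm(nt, 3);
  for (int i = 0; i < nt; ++i) {
    Tm(i, 0) = mb.t0[i] + 1;
    Tm(i, 1) = mb.t1[i] + 1;
    Tm(i, 2) = mb.t2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}

// Each undirected edge must appear in exactly two triangles for a closed
// (watertight) mesh. Returns the number of edges violating that.
// [[Rcpp::export(name = ".cpp_open_edge_count")]]
int cpp_open_edge_count(IntegerMatrix tri) {
  std::unordered_map<uint64_t, int> cnt;
  int nt = tri.nrow();
  cnt.reserve((size_t)nt * 2);
  for (int i = 0; i < nt; ++i) {
    int v[3] = {tri(i, 0), tri(i, 1), tri(i, 2)};
    for (int e = 0; e < 3; ++e) {
      uint64_t a = v[e], b = v[(e + 1) % 3];
      uint64_t key = a < b ? (a << 32) | b : (b << 32) | a;
      ++cnt[key];
    }
  }
  int bad = 0;
  for (auto& kv : cnt)
    if (kv.second != 2) ++bad;
  return bad;
}
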