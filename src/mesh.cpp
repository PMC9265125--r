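#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Iso-surface of a scalar field at a given level by marching tetrahedra:
// each cell of the voxel-center lattice (padded with background so the
// surface closes) is split into 6 tetrahedra sharing the main diagonal;
// iso-surface vertices are placed on tetrahedron edges by linear
// interpolation. On a raw binary mask the vertices sit at edge midpoints;
// meshing a lightly smoothed indicator field instead removes the staircase
// faceting and makes the area estimate converge (see morphology_features).
// Returns total triangle area (mm^2) and enclosed volume (mm^3, divergence
// theorem with outward-oriented triangles).

struct V3 { double x, y, z; };

static inline V3 sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 cross(const V3& a, const V3& b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// Point on the edge (a, va) -- (b, vb) where the field crosses `level`.
static inline V3 lerp(const V3& a, double va, const V3& b, double vb, double level) {
  double t = (level - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// Accumulate one triangle, oriented so its normal points away from `in_pt`
// (a point inside the surface near the triangle).
static void add_tri(const V3& a, const V3& b, const V3& c, const V3& in_pt,
                    double& area, double& vol6) {
  V3 n = cross(sub(b, a), sub(c, a));
  V3 centroid = {(a.x+b.x+c.x)/3 - in_pt.x, (a.y+b.y+c.y)/3 - in_pt.y,
                 (a.z+b.z+c.z)/3 - in_pt.z};
  const V3 *p1 = &b, *p2 = &c;
  if (dot(n, centroid) < 0) { p1 = &c; p2 = &b; }
  area += 0.5 * std::sqrt(dot(n, n));
  // signed volume of tetra (origin, a, p1, p2) with outward orientation
  vol6 += dot(a, cross(*p1, *p2));
}

static void march_tet(const V3 p[4], const double v[4], double level,
                      double& area, double& vol6) {
  int in_idx[4], out_idx[4], ni = 0, no = 0;
  for (int i = 0; i < 4; ++i) {
    if (v[i] > level) in_idx[ni++] = i; else out_idx[no++] = i;
  }
  if (ni == 0 || ni == 4) return;
  if (ni == 1) {
    const int A = in_idx[0];
    add_tri(lerp(p[A], v[A], p[out_idx[0]], v[out_idx[0]], level),
            lerp(p[A], v[A], p[out_idx[1]], v[out_idx[1]], level),
            lerp(p[A], v[A], p[out_idx[2]], v[out_idx[2]], level),
            p[A], area, vol6);
  } else if (ni == 3) {
    const int D = out_idx[0];
    V3 in_pt = {(p[in_idx[0]].x + p[in_idx[1]].x + p[in_idx[2]].x) / 3,
                (p[in_idx[0]].y + p[in_idx[1]].y + p[in_idx[2]].y) / 3,
                (p[in_idx[0]].z + p[in_idx[1]].z + p[in_idx[2]].z) / 3};
    add_tri(lerp(p[D], v[D], p[in_idx[0]], v[in_idx[0]], level),
            lerp(p[D], v[D], p[in_idx[1]], v[in_idx[1]], level),
            lerp(p[D], v[D], p[in_idx[2]], v[in_idx[2]], level),
            in_pt, area, vol6);
  } else { // ni == 2: quad split into two triangles
    const int A = in_idx[0], B = in_idx[1];
    V3 in_pt = {(p[A].x + p[B].x) / 2, (p[A].y + p[B].y) / 2, (p[A].z + p[B].z) / 2};
    V3 q1 = lerp(p[A], v[A], p[out_idx[0]], v[out_idx[0]], level);
    V3 q2 = lerp(p[A], v[A], p[out_idx[1]], v[out_idx[1]], level);
    V3 q3 = lerp(p[B], v[B], p[out_idx[1]], v[out_idx[1]], level);
    V3 q4 = lerp(p[B], v[B], p[out_idx[0]], v[out_idx[0]], level);
    add_tri(q1, q2, q3, in_pt, area, vol6);
    add_tri(q1, q3, q4, in_pt, area, vol6);
  }
}

// Corner offsets of the unit cube; tetrahedra share the v0-v6 diagonal.
static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};

// [[Rcpp::export]]
List cpp_mesh_field(const NumericVector& field,
                    const IntegerVector& dims,
                    const NumericVector& spacing,
                    double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto val = [&](int x, int y, int z) -> double {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0.0;
    return field[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
  };
  double area = 0.0, vol6 = 0.0;
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double cv[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          cv[c] = val(x + CUBE[c][0], y + CUBE[c][1], z + CUBE[c][2]);
          const bool in = cv[c] > level;
          any = any || in; all = all && in;
        }
        if (!any || all) continue;
        V3 cp[8];
        for (int c = 0; c < 8; ++c)
          cp[c] = {(x + CUBE[c][0]) * sx, (y + CUBE[c][1]) * sy, (z + CUBE[c][2]) * sz};
        for (int t = 0; t < 6; ++t) {
          V3 tp[4];
          double tv[4];
          for (int i = 0; i < 4; ++i) { tp[i] = cp[TETS[t][i]]; tv[i] = cv[TETS[t][i]]; }
          march_tet(tp, tv, level, area, vol6);
        }
      }
  return List::create(_["area"] = area, _["volume"] = vol6 / 6.0);
}

// Largest pairwise Euclidean distance (mm) between centers of surface
// voxels (foreground voxels with an exposed face, 6-neighborhood).
// [[Rcpp::export]]
double cpp_max_diameter(const LogicalVector& mask,
                        const IntegerVector& dims,
                        const NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto val = [&](int x, int y, int z) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return mask[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] ? 1 : 0;
  };
  std::vector<double> px, py, pz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!val(x, y, z)) continue;
        if (val(x-1,y,z) && val(x+1,y,z) && val(x,y-1,z) && val(x,y+1,z) &&
            val(x,y,z-1) && val(x,y,z+1)) continue;
        px.push_back(x * spacing[0]);
        py.push_back(y * spacing[1]);
        pz.push_back(z * spacing[2]);
      }
  double best = 0.0;
  const size_t m = px.size();
  for (size_t i = 0; i < m; ++i)
    for (size_t j = i + 1; j < m; ++j) {
      const double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
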