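#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull with half-space membership counting.
//
// Input coordinates are voxel indices (integers stored as doubles), for
// which every orientation determinant is computed exactly in double
// precision, or physical coordinates (indices scaled by voxel size), for
// which a small tolerance absorbs rounding. Visibility is strict
// (orient > eps): a point on a facet plane is never "beyond" it, which is
// the correct treatment for cohyperplanar lattice points — a point strictly
// outside the current polytope always violates some facet half-space
// strictly. Degenerate (zero-area) facets produced by collinear horizon
// edges impose no constraint and are skipped during membership tests.

struct Face {
  int a, b, c;
  bool alive;
};

static inline void face_normal(const std::vector<double> &P, int a, int b, int c,
                               double &nx, double &ny, double &nz) {
  double ux = P[3 * b] - P[3 * a], uy = P[3 * b + 1] - P[3 * a + 1], uz = P[3 * b + 2] - P[3 * a + 2];
  double vx = P[3 * c] - P[3 * a], vy = P[3 * c + 1] - P[3 * a + 1], vz = P[3 * c + 2] - P[3 * a + 2];
  nx = uy * vz - uz * vy;
  ny = uz * vx - ux * vz;
  nz = ux * vy - uy * vx;
}

static inline double orient_face(const std::vector<double> &P, const Face &f,
                                 double qx, double qy, double qz) {
  double nx, ny, nz;
  face_normal(P, f.a, f.b, f.c, nx, ny, nz);
  return nx * (qx - P[3 * f.a]) + ny * (qy - P[3 * f.a + 1]) + nz * (qz - P[3 * f.a + 2]);
}

// Count query points lying inside or on the convex hull of pts.
// Returns -1 when the points are affinely degenerate (rank < 3).
// [[Rcpp::export(name = ".hull_count_cpp")]]
int hull_count_cpp(NumericMatrix ptsM, NumericMatrix qryM, double tol) {
  const int n = ptsM.nrow();
  if (n == 0) stop("empty point set");
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = ptsM(i, 0);
    P[3 * i + 1] = ptsM(i, 1);
    P[3 * i + 2] = ptsM(i, 2);
  }
  const double eps = 1e-9;

  // initial affinely independent quadruple
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = eps;
  for (int i = 1; i < n; ++i) {
    double dx = P[3 * i] - P[0], dy = P[3 * i + 1] - P[1], dz = P[3 * i + 2] - P[2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0) return -1;
  best = eps;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ux = P[3 * i1] - P[0], uy = P[3 * i1 + 1] - P[1], uz = P[3 * i1 + 2] - P[2];
    double vx = P[3 * i] - P[0], vy = P[3 * i + 1] - P[1], vz = P[3 * i + 2] - P[2];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return -1;
  best = eps;
  {
    Face f0 = {i0, i1, i2, true};
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2) continue;
      double d = std::fabs(orient_face(P, f0, P[3 * i], P[3 * i + 1], P[3 * i + 2]));
      if (d > best) { best = d; i3 = i; }
    }
  }
  if (i3 < 0) return -1;

  std::vector<Face> faces;
  {
    int t[4] = {i0, i1, i2, i3};
    int opp[4][4] = {{0, 1, 2, 3}, {0, 2, 3, 1}, {0, 3, 1, 2}, {1, 3, 2, 0}};
    for (int k = 0; k < 4; ++k) {
      Face f = {t[opp[k][0]], t[opp[k][1]], t[opp[k][2]], true};
      int d = t[opp[k][3]];
      if (orient_face(P, f, P[3 * d], P[3 * d + 1], P[3 * d + 2]) > 0) std::swap(f.b, f.c);
      faces.push_back(f);
    }
  }

  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    double qx = P[3 * i], qy = P[3 * i + 1], qz = P[3 * i + 2];
    visible.clear();
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (!faces[fi].alive) continue;
      if (orient_face(P, faces[fi], qx, qy, qz) > eps) visible.push_back((int)fi);
    }
    if (visible.empty()) continue;
    // directed edges of visible facets; horizon = edges whose reverse is absent
    std::map<std::pair<int, int>, int> edges;
    for (size_t k = 0; k < visible.size(); ++k) {
      const Face &f = faces[visible[k]];
      edges[std::make_pair(f.a, f.b)] = 1;
      edges[std::make_pair(f.b, f.c)] = 1;
      edges[std::make_pair(f.c, f.a)] = 1;
    }
    for (size_t k = 0; k < visible.size(); ++k) faces[visible[k]].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = edges.begin(); it != edges.end(); ++it) {
      int u = it->first.first, v = it->first.second;
      if (edges.count(std::make_pair(v, u))) continue;
      Face nf = {u, v, i, true};
      faces.push_back(nf);
    }
  }

  // collect non-degenerate half-spaces
  std::vector<double> HN;  // nx, ny, nz, offset (n . x <= offset), scale
  for (size_t fi = 0; fi < faces.size(); ++fi) {
    if (!faces[fi].alive) continue;
    double nx, ny, nz;
    face_normal(P, faces[fi].a, faces[fi].b, faces[fi].c, nx, ny, nz);
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn <= eps) continue;
    double off = nx * P[3 * faces[fi].a] + ny * P[3 * faces[fi].a + 1] + nz * P[3 * faces[fi].a + 2];
    HN.push_back(nx); HN.push_back(ny); HN.push_back(nz); HN.push_back(off); HN.push_back(nn);
  }
  const size_t nh = HN.size() / 5;

  // sanity: every input point satisfies every half-space
  for (int i = 0; i < n; ++i) {
    for (size_t h = 0; h < nh; ++h) {
      double s = HN[5 * h] * P[3 * i] + HN[5 * h + 1] * P[3 * i + 1] + HN[5 * h + 2] * P[3 * i + 2];
      if (s > HN[5 * h + 3] + tol * HN[5 * h + 4] + 1e-7)
        stop("internal error: hull construction failed verification");
    }
  }

  int count = 0;
  const int m = qryM.nrow();
  for (int q = 0; q < m; ++q) {
    double qx = qryM(q, 0), qy = qryM(q, 1), qz = qryM(q, 2);
    bool inside = true;
    for (size_t h = 0; h < nh; ++h) {
      double s = HN[5 * h] * qx + HN[5 * h + 1] * qy + HN[5 * h + 2] * qz;
      if (s > HN[5 * h + 3] + tol * HN[5 * h + 4]) { inside = false; break; }
    }
    if (inside) ++count;
  }
  return count;
}
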