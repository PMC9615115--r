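// Periodic 3D Voronoi face-sharing neighbors by per-particle cell
// clipping (the voro++ strategy): each particle's cell starts as a large
// cube and is cut by the bisector half-space of every nearby particle
// image, nearest first, stopping once no remaining candidate can reach
// the cell.  A particle pair are neighbors iff a bisector plane survives
// as a cell face of positive area.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef std::array<double, 3> P3;

struct Face {
  std::vector<P3> v;
  int id;  // candidate index owning the plane, -1 for bounding cube
};

static inline double dot3(const P3 &a, const double n[3]) {
  return a[0] * n[0] + a[1] * n[1] + a[2] * n[2];
}

// cut cell by half-space x.n <= h; returns true if the cell changed
static bool cut_cell(std::vector<Face> &faces, const double n[3], double h,
                     int id, double eps) {
  std::vector<P3> newpts;
  std::vector<Face> out;
  out.reserve(faces.size() + 1);
  bool changed = false;
  for (const Face &f : faces) {
    const int m = (int)f.v.size();
    std::vector<double> s(m);
    bool anyout = false, anyin = false;
    for (int i = 0; i < m; ++i) {
      s[i] = dot3(f.v[i], n) - h;
      if (s[i] > eps) anyout = true; else anyin = true;
    }
    if (!anyout) { out.push_back(f); continue; }
    changed = true;
    if (!anyin) continue;
    Face nf; nf.id = f.id;
    for (int i = 0; i < m; ++i) {
      int j = (i + 1) % m;
      bool in_i = s[i] <= eps, in_j = s[j] <= eps;
      if (in_i) nf.v.push_back(f.v[i]);
      if (in_i != in_j) {
        double t = s[i] / (s[i] - s[j]);
        P3 p;
        for (int k = 0; k < 3; ++k) p[k] = f.v[i][k] + t * (f.v[j][k] - f.v[i][k]);
        nf.v.push_back(p);
        newpts.push_back(p);
      }
    }
    if (nf.v.size() >= 3) out.push_back(nf);
  }
  if (!changed) return false;
  // deduplicate the cut-section points and order them around the plane
  std::vector<P3> pts;
  for (const P3 &p : newpts) {
    bool dup = false;
    for (const P3 &q : pts) {
      double d2 = (p[0] - q[0]) * (p[0] - q[0]) + (p[1] - q[1]) * (p[1] - q[1]) +
                  (p[2] - q[2]) * (p[2] - q[2]);
      if (d2 < 1e-16) { dup = true; break; }
    }
    if (!dup) pts.push_back(p);
  }
  if (pts.size() >= 3) {
    P3 c = {0, 0, 0};
    for (const P3 &p : pts) { c[0] += p[0]; c[1] += p[1]; c[2] += p[2]; }
    for (int k = 0; k < 3; ++k) c[k] /= pts.size();
    // in-plane basis
    P3 t1;
    if (std::fabs(n[0]) < 0.9) t1 = {0.0, -n[2], n[1]};
    else t1 = {-n[1], n[0], 0.0};
    double nt = std::sqrt(t1[0] * t1[0] + t1[1] * t1[1] + t1[2] * t1[2]);
    for (int k = 0; k < 3; ++k) t1[k] /= nt;
    P3 t2 = {n[1] * t1[2] - n[2] * t1[1], n[2] * t1[0] - n[0] * t1[2],
             n[0] * t1[1] - n[1] * t1[0]};
    std::vector<std::pair<double, int>> ang(pts.size());
    for (size_t i = 0; i < pts.size(); ++i) {
      P3 d = {pts[i][0] - c[0], pts[i][1] - c[1], pts[i][2] - c[2]};
      ang[i] = {std::atan2(dot3(d, t2.data()), dot3(d, t1.data())), (int)i};
    }
    std::sort(ang.begin(), ang.end());
    Face nf; nf.id = id;
    for (auto &a : ang) nf.v.push_back(pts[a.second]);
    out.push_back(nf);
  }
  faces.swap(out);
  return true;
}

static double face_area(const Face &f) {
  if (f.v.size() < 3) return 0.0;
  P3 c = {0, 0, 0};
  for (const P3 &p : f.v) { c[0] += p[0]; c[1] += p[1]; c[2] += p[2]; }
  for (int k = 0; k < 3; ++k) c[k] /= f.v.size();
  double sx = 0, sy = 0, sz = 0;
  const int m = (int)f.v.size();
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    double ax = f.v[i][0] - c[0], ay = f.v[i][1] - c[1], az = f.v[i][2] - c[2];
    double bx = f.v[j][0] - c[0], by = f.v[j][1] - c[1], bz = f.v[j][2] - c[2];
    sx += ay * bz - az * by;
    sy += az * bx - ax * bz;
    sz += ax * by - ay * bx;
  }
  return 0.5 * std::sqrt(sx * sx + sy * sy + sz * sz);
}

struct Cand { double d2; int atom; P3 d; };

// [[Rcpp::export]]
IntegerMatrix voronoi_pairs_cpp(NumericMatrix pos, NumericMatrix box) {
  const int n = pos.nrow();
  if (n < 2) stop("need at least 2 atoms");
  double A[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) A[r][c] = box(r, c);
  double diag = 0;
  for (int r = 0; r < 3; ++r)
    diag += std::sqrt(A[r][0] * A[r][0] + A[r][1] * A[r][1] + A[r][2] * A[r][2]);
  const double R0 = diag;  // bounding cube half-size: sum of box vector norms
  const double eps = 1e-7;
  const double area_tol = 1e-7;

  std::set<std::pair<int, int>> pairs;
  std::vector<Cand> cands;
  cands.reserve((size_t)n * 27);

  for (int i = 0; i < n; ++i) {
    cands.clear();
    for (int j = 0; j < n; ++j) {
      for (int ia = -1; ia <= 1; ++ia)
        for (int ib = -1; ib <= 1; ++ib)
          for (int ic = -1; ic <= 1; ++ic) {
            if (j == i && ia == 0 && ib == 0 && ic == 0) continue;
            P3 d;
            for (int k = 0; k < 3; ++k)
              d[k] = pos(j, k) + ia * A[0][k] + ib * A[1][k] + ic * A[2][k] -
                     pos(i, k);
            double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
            if (d2 < 1e-12) {
              if (j != i)
                stop("coincident atoms %d and %d: degenerate tessellation",
                     i + 1, j + 1);
              continue;
            }
            cands.push_back({d2, j, d});
          }
    }
    std::sort(cands.begin(), cands.end(),
              [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });

    // initial cube
    std::vector<Face> faces;
    const int sgn[6][2] = {{0, 1}, {0, -1}, {1, 1}, {1, -1}, {2, 1}, {2, -1}};
    for (int fIdx = 0; fIdx < 6; ++fIdx) {
      int ax = sgn[fIdx][0], s = sgn[fIdx][1];
      Face f; f.id = -1;
      int a1 = (ax + 1) % 3, a2 = (ax + 2) % 3;
      const int cs[4][2] = {{1, 1}, {1, -1}, {-1, -1}, {-1, 1}};
      for (int k = 0; k < 4; ++k) {
        P3 p;
        p[ax] = s * R0;
        p[a1] = cs[k][0] * R0;
        p[a2] = cs[k][1] * R0;
        f.v.push_back(p);
      }
      faces.push_back(f);
    }
    double maxR2 = 3 * R0 * R0;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      double dist = std::sqrt(cands[ci].d2);
      if (0.25 * cands[ci].d2 > maxR2) break;
      double nrm[3] = {cands[ci].d[0] / dist, cands[ci].d[1] / dist,
                       cands[ci].d[2] / dist};
      if (cut_cell(faces, nrm, 0.5 * dist, (int)ci, eps)) {
        maxR2 = 0;
        for (const Face &f : faces)
          for (const P3 &p : f.v) {
            double r2 = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
            if (r2 > maxR2) maxR2 = r2;
          }
      }
    }
    for (const Face &f : faces) {
      if (f.id < 0) continue;
      int j = cands[f.id].atom;
      if (j == i) continue;  // own periodic image
      if (face_area(f) > area_tol) {
        pairs.insert({std::min(i, j), std::max(i, j)});
      }
    }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  int r = 0;
  for (auto &pr : pairs) {
    out(r, 0) = pr.first + 1;
    out(r, 1) = pr.second + 1;
    ++r;
  }
  return out;
}
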