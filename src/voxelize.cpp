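#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <set>
#include <vector>

using namespace Rcpp;

// Streamline-grid traversal.
//
// Coordinates arriving here are continuous 0-based voxel-CENTER coordinates
// ("v-space"): voxel i owns the half-open interval [i - 0.5, i + 0.5) on each
// axis, so a point exactly on a shared face belongs to the higher-index voxel.
// Internally we shift to corner coordinates u = v + 0.5, where voxel i owns
// [i, i + 1) and faces sit at integers; ownership is then floor(u), which
// implements the half-open rule directly.

namespace {

inline bool inside(const int *c, const int *dim) {
  return c[0] >= 0 && c[0] < dim[0] && c[1] >= 0 && c[1] < dim[1] &&
         c[2] >= 0 && c[2] < dim[2];
}

inline int linearIndex(const int *c, const int *dim) {
  // 1-based linear index, column-major like R arrays
  return 1 + c[0] + dim[0] * (c[1] + dim[1] * c[2]);
}

// Collect all voxels traversed by the segment p -> q (u-space corner coords).
// Exact method: gather the parameter values where the segment crosses any
// integer grid plane, then take the voxel under the midpoint of every
// resulting sub-interval. Midpoints are strictly interior to their voxel, so
// ties at faces cannot occur there; segment endpoints are added separately
// under the half-open ownership rule.
void traverseSegment(const double *p, const double *q, const int *dim,
                     std::set<int> &out) {
  std::vector<double> ts;
  ts.push_back(0.0);
  ts.push_back(1.0);
  for (int ax = 0; ax < 3; ++ax) {
    double a = p[ax], b = q[ax];
    double lo = std::min(a, b), hi = std::max(a, b);
    double d = b - a;
    if (d == 0.0) continue;
    for (double k = std::ceil(lo); k <= std::floor(hi); k += 1.0) {
      double t = (k - a) / d;
      if (t > 0.0 && t < 1.0) ts.push_back(t);
    }
  }
  std::sort(ts.begin(), ts.end());
  // endpoint voxels
  for (int e = 0; e < 2; ++e) {
    const double *pt = (e == 0) ? p : q;
    int c[3] = {(int)std::floor(pt[0]), (int)std::floor(pt[1]),
                (int)std::floor(pt[2])};
    if (inside(c, dim)) out.insert(linearIndex(c, dim));
  }
  for (size_t i = 0; i + 1 < ts.size(); ++i) {
    double tm = 0.5 * (ts[i] + ts[i + 1]);
    if (!(tm > 0.0 && tm < 1.0)) continue;
    int c[3];
    for (int ax = 0; ax < 3; ++ax)
      c[ax] = (int)std::floor(p[ax] + tm * (q[ax] - p[ax]));
    if (inside(c, dim)) out.insert(linearIndex(c, dim));
  }
}

std::set<int> traversePolyline(const NumericMatrix &v, const int *dim) {
  std::set<int> out;
  int n = v.nrow();
  for (int i = 0; i + 1 < n; ++i) {
    double p[3] = {v(i, 0) + 0.5, v(i, 1) + 0.5, v(i, 2) + 0.5};
    double q[3] = {v(i + 1, 0) + 0.5, v(i + 1, 1) + 0.5, v(i + 1, 2) + 0.5};
    traverseSegment(p, q, dim, out);
  }
  if (n == 1) {
    double p[3] = {v(0, 0) + 0.5, v(0, 1) + 0.5, v(0, 2) + 0.5};
    int c[3] = {(int)std::floor(p[0]), (int)std::floor(p[1]),
                (int)std::floor(p[2])};
    if (inside(c, dim)) out.insert(linearIndex(c, dim));
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cppVoxelizePolyline")]]
IntegerVector cppVoxelizePolyline(NumericMatrix vcoords, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  std::set<int> s = traversePolyline(vcoords, d);
  return IntegerVector(s.begin(), s.end());
}

// [[Rcpp::export(name = ".cppVoxelizeTractogram")]]
List cppVoxelizeTractogram(List vcoordList, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  int n = vcoordList.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix v = vcoordList[i];
    std::set<int> s = traversePolyline(v, d);
    out[i] = IntegerVector(s.begin(), s.end());
  }
  return out;
}
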