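#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Closest point on a single triangle (a,b,c) to point p.
// Ericson, "Real-Time Collision Detection", ch. 5.1.5.
static inline void closest_on_triangle(const double *p,
                                       const double *a, const double *b,
                                       const double *c,
                                       double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v*ab[k];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w*ac[k];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w*(c[k] - b[k]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

// Exact closest surface point for each query point. Every face is
// considered; a centroid-radius bound rejects faces that cannot beat the
// current best, so the result is identical to the exhaustive scan. Ties
// broken toward the lowest face index (strict < on squared distance).
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  int n = pts.nrow(), nf = F.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3), bary(n, 3);
  IntegerVector face(n);
  std::vector<double> vx(V.nrow()*3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) vx[3*i+k] = V(i, k);
  // per-face centroid and bounding radius
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    const double *a = &vx[3*(F(f,0)-1)];
    const double *b = &vx[3*(F(f,1)-1)];
    const double *c = &vx[3*(F(f,2)-1)];
    cx[f] = (a[0]+b[0]+c[0]) / 3.0;
    cy[f] = (a[1]+b[1]+c[1]) / 3.0;
    cz[f] = (a[2]+b[2]+c[2]) / 3.0;
    double r2 = 0.0;
    const double *vs[3] = {a, b, c};
    for (int v = 0; v < 3; ++v) {
      double dx = vs[v][0]-cx[f], dy = vs[v][1]-cy[f], dz = vs[v][2]-cz[f];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i,0), pts(i,1), pts(i,2) };
    // seed the bound with the closest face centroid (plus its radius)
    double cbest = R_PosInf;
    int seed = 0;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < cbest) { cbest = d2; seed = f; }
    }
    double best = R_PosInf, bq[3] = {0,0,0}, bb[3] = {0,0,0};
    int bf = 0;
    double bestd = R_PosInf;  // sqrt of best
    for (int step = 0; step < nf; ++step) {
      // visit the seed face first so the bound is tight immediately
      int f = (step == 0) ? seed : (step <= seed ? step - 1 : step);
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double cdist = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (cdist - rad[f] >= bestd) continue;  // cannot beat current best
      const double *a = &vx[3*(F(f,0)-1)];
      const double *b = &vx[3*(F(f,1)-1)];
      const double *c = &vx[3*(F(f,2)-1)];
      double q[3], bc[3];
      closest_on_triangle(p, a, b, c, q, bc);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) { double dd = p[k]-q[k]; d2 += dd*dd; }
      if (d2 < best) {
        best = d2; bf = f + 1;
        bestd = std::sqrt(best);
        for (int k = 0; k < 3; ++k) { bq[k] = q[k]; bb[k] = bc[k]; }
      }
    }
    dist[i] = bestd;
    face[i] = bf;
    for (int k = 0; k < 3; ++k) { closest(i,k) = bq[k]; bary(i,k) = bb[k]; }
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face, _["bary"] = bary);
}

// Voxel interior mask by x-ray parity. Rays pass through voxel centers in
// the (y,z) plane with a fixed sub-voxel offset so that exact edge hits
// have measure zero for generic meshes.
// [[Rcpp::export]]
LogicalVector cpp_inside_mask(NumericMatrix V, IntegerMatrix F,
                              NumericVector origin, double voxel,
                              IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nf = F.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const double jy = 2.5e-4 * voxel, jz = 4.1e-4 * voxel;
  // precompute triangle data
  std::vector<double> ay(nf), az(nf), by(nf), bz(nf), cy(nf), cz(nf),
    ax(nf), bx(nf), cx(nf), ylo(nf), yhi(nf), zlo(nf), zhi(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
    ax[f]=V(i0,0); ay[f]=V(i0,1); az[f]=V(i0,2);
    bx[f]=V(i1,0); by[f]=V(i1,1); bz[f]=V(i1,2);
    cx[f]=V(i2,0); cy[f]=V(i2,1); cz[f]=V(i2,2);
    ylo[f]=std::min(ay[f],std::min(by[f],cy[f]));
    yhi[f]=std::max(ay[f],std::max(by[f],cy[f]));
    zlo[f]=std::min(az[f],std::min(bz[f],cz[f]));
    zhi[f]=std::max(az[f],std::max(bz[f],cz[f]));
  }
  std::vector<double> xs;
  for (int j = 0; j < ny; ++j) {
    double y = origin[1] + (j + 0.5) * voxel + jy;
    for (int k = 0; k < nz; ++k) {
      double z = origin[2] + (k + 0.5) * voxel + jz;
      xs.clear();
      for (int f = 0; f < nf; ++f) {
        if (y < ylo[f] || y > yhi[f] || z < zlo[f] || z > zhi[f]) continue;
        // 2D barycentric in (y,z)
        double d11 = by[f]-ay[f], d12 = bz[f]-az[f];
        double d21 = cy[f]-ay[f], d22 = cz[f]-az[f];
        double det = d11*d22 - d12*d21;
        if (det == 0.0) continue; // triangle parallel to ray
        double py = y - ay[f], pz = z - az[f];
        double u = ( d22*py - d21*pz) / det;
        double v = (-d12*py + d11*pz) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        xs.push_back(ax[f] + u*(bx[f]-ax[f]) + v*(cx[f]-ax[f]));
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // parity fill along x voxel centers
      size_t m = xs.size();
      for (size_t s = 0; s + 1 < m; s += 2) {
        int i0 = (int)std::ceil((xs[s]   - origin[0]) / voxel - 0.5);
        int i1 = (int)std::floor((xs[s+1] - origin[0]) / voxel - 0.5);
        if (i0 < 0) i0 = 0;
        if (i1 > nx - 1) i1 = nx - 1;
        for (int i = i0; i <= i1; ++i)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}

// Edge-manifold / watertight check: every undirected edge is used by
// exactly two faces, once in each direction.
// [[Rcpp::export]]
List cpp_edge_check(IntegerMatrix F) {
  std::map<std::pair<int,int>, std::pair<int,int> > edges; // (fwd, bwd) counts
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int idx[3] = { F(f,0), F(f,1), F(f,2) };
    for (int e = 0; e < 3; ++e) {
      int u = idx[e], v = idx[(e+1)%3];
      std::pair<int,int> key = u < v ? std::make_pair(u,v) : std::make_pair(v,u);
      std::pair<int,int> &cnt = edges[key];
      if (u < v) cnt.first += 1; else cnt.second += 1;
    }
  }
  int bad = 0;
  for (std::map<std::pair<int,int>, std::pair<int,int> >::iterator it = edges.begin();
       it != edges.end(); ++it) {
    if (it->second.first != 1 || it->second.second != 1) ++bad;
  }
  return List::create(_["n_edges"] = (int)edges.size(),
                      _["n_bad_edges"] = bad,
                      _["watertight"] = (bad == 0));
}
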