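// Triangle rasterisation and silhouette comparison kernels.
//
// Pixel convention: image row r, column c (1-based from R) has its centre at
// continuous coordinates (c - 0.5, r - 0.5), origin at the image top-left,
// x rightward, y downward.  A pixel belongs to the silhouette iff its centre
// lies inside at least one projected triangle (closed edges; the union of
// filled triangles makes shared-edge handling immaterial).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double edgeFun(double ax, double ay, double bx, double by,
                             double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

// rasterise triangles into a byte buffer of size w x h covering pixel
// columns [c0, c0+w) and rows [r0, r0+h) (0-based)
static void fillBuffer(const double* px, const double* py,
                       const IntegerMatrix& tri, int c0, int r0, int w,
                       int h, std::vector<unsigned char>& buf) {
  int nt = tri.nrow();
  for (int k = 0; k < nt; ++k) {
    int i0 = tri(k, 0) - 1, i1 = tri(k, 1) - 1, i2 = tri(k, 2) - 1;
    double x0 = px[i0], y0 = py[i0];
    double x1 = px[i1], y1 = py[i1];
    double x2 = px[i2], y2 = py[i2];
    double area2 = edgeFun(x0, y0, x1, y1, x2, y2);
    if (area2 == 0.0) continue;
    if (area2 < 0.0) { std::swap(x1, x2); std::swap(y1, y2); }
    double xmin = std::min(x0, std::min(x1, x2));
    double xmax = std::max(x0, std::max(x1, x2));
    double ymin = std::min(y0, std::min(y1, y2));
    double ymax = std::max(y0, std::max(y1, y2));
    // pixel (0-based) c has centre x = c + 0.5
    int ca = std::max(c0, (int)std::ceil(xmin - 0.5));
    int cb = std::min(c0 + w - 1, (int)std::floor(xmax - 0.5 + 1e-12));
    int ra = std::max(r0, (int)std::ceil(ymin - 0.5));
    int rb = std::min(r0 + h - 1, (int)std::floor(ymax - 0.5 + 1e-12));
    for (int r = ra; r <= rb; ++r) {
      double yc = r + 0.5;
      for (int c = ca; c <= cb; ++c) {
        double xc = c + 0.5;
        if (edgeFun(x0, y0, x1, y1, xc, yc) >= 0 &&
            edgeFun(x1, y1, x2, y2, xc, yc) >= 0 &&
            edgeFun(x2, y2, x0, y0, xc, yc) >= 0)
          buf[(size_t)(c - c0) * h + (r - r0)] = 1;
      }
    }
  }
}

// [[Rcpp::export(name = ".rasterTriangles")]]
LogicalMatrix rasterTriangles(NumericVector px, NumericVector py,
                              IntegerMatrix tri, int W, int H) {
  std::vector<unsigned char> buf((size_t)W * H, 0);
  fillBuffer(px.begin(), py.begin(), tri, 0, 0, W, H, buf);
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = buf[(size_t)c * H + r] != 0;
  return out;
}

// Fused tracking objective for orthographic cameras: projects the vertices
// with uv = A x + b per camera and accumulates the symmetric-difference
// pixel counts against the observed masks. For closed, consistently
// oriented meshes only front-facing triangles are rasterised (their union
// already covers the silhouette).
// [[Rcpp::export(name = ".orthoObjective")]]
double orthoObjective(NumericMatrix V, IntegerMatrix tri, List Alist,
                      List blist, List masks, NumericVector counts,
                      bool closed) {
  int nv = V.nrow();
  std::vector<double> px(nv), py(nv);
  double total = 0.0;
  int ncam = masks.size();
  for (int ci = 0; ci < ncam; ++ci) {
    NumericMatrix A = Alist[ci];
    NumericVector b = blist[ci];
    LogicalMatrix obs = masks[ci];
    for (int i = 0; i < nv; ++i) {
      px[i] = A(0, 0) * V(i, 0) + A(0, 1) * V(i, 1) + A(0, 2) * V(i, 2) + b[0];
      py[i] = A(1, 0) * V(i, 0) + A(1, 1) * V(i, 1) + A(1, 2) * V(i, 2) + b[1];
    }
    int H = obs.nrow(), W = obs.ncol();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < nv; ++i) {
      if (px[i] < xmin) xmin = px[i];
      if (px[i] > xmax) xmax = px[i];
      if (py[i] < ymin) ymin = py[i];
      if (py[i] > ymax) ymax = py[i];
    }
    int c0 = std::max(0, (int)std::floor(xmin - 1));
    int c1 = std::min(W - 1, (int)std::ceil(xmax + 1));
    int r0 = std::max(0, (int)std::floor(ymin - 1));
    int r1 = std::min(H - 1, (int)std::ceil(ymax + 1));
    if (c1 < c0 || r1 < r0) { total += counts[ci]; continue; }
    int w = c1 - c0 + 1, h = r1 - r0 + 1;
    std::vector<unsigned char> buf((size_t)w * h, 0);
    int nt = tri.nrow();
    for (int k = 0; k < nt; ++k) {
      int i0 = tri(k, 0) - 1, i1 = tri(k, 1) - 1, i2 = tri(k, 2) - 1;
      double x0 = px[i0], y0 = py[i0];
      double x1 = px[i1], y1 = py[i1];
      double x2 = px[i2], y2 = py[i2];
      double area2 = edgeFun(x0, y0, x1, y1, x2, y2);
      if (area2 == 0.0) continue;
      if (area2 < 0.0) {
        if (closed) continue;           // back-facing on a closed surface
        std::swap(x1, x2); std::swap(y1, y2);
      }
      double txmin = std::min(x0, std::min(x1, x2));
      double txmax = std::max(x0, std::max(x1, x2));
      double tymin = std::min(y0, std::min(y1, y2));
      double tymax = std::max(y0, std::max(y1, y2));
      int ca = std::max(c0, (int)std::ceil(txmin - 0.5));
      int cb = std::min(c0 + w - 1, (int)std::floor(txmax - 0.5 + 1e-12));
      int ra = std::max(r0, (int)std::ceil(tymin - 0.5));
      int rb = std::min(r0 + h - 1, (int)std::floor(tymax - 0.5 + 1e-12));
      for (int r = ra; r <= rb; ++r) {
        double yc = r + 0.5;
        for (int c = ca; c <= cb; ++c) {
          double xc = c + 0.5;
          if (edgeFun(x0, y0, x1, y1, xc, yc) >= 0 &&
              edgeFun(x1, y1, x2, y2, xc, yc) >= 0 &&
              edgeFun(x2, y2, x0, y0, xc, yc) >= 0)
            buf[(size_t)(c - c0) * h + (r - r0)] = 1;
        }
      }
    }
    double rendered = 0, inter = 0;
    const int* obsp = LOGICAL(obs);
    for (int c = 0; c < w; ++c) {
      const unsigned char* col = &buf[(size_t)c * h];
      const int* ocol = obsp + (size_t)(c + c0) * H + r0;
      for (int r = 0; r < h; ++r) {
        if (col[r]) {
          rendered += 1;
          if (ocol[r]) inter += 1;
        }
      }
    }
    total += (rendered - inter) + (counts[ci] - inter);
  }
  return total;
}

// Soft variant of the objective: the observed mask is a smoothed (graded)
// silhouette in [0, 1]; the accumulated cost is sum |rendered - obs|,
// which reduces to the symmetric difference for a binary obs. Used by the
// coarse search stage, where the graded edges give the objective sub-pixel
// sensitivity. obsSum is the total of obs over the full image.
// [[Rcpp::export(name = ".orthoObjectiveSoft")]]
double orthoObjectiveSoft(NumericMatrix V, IntegerMatrix tri, List Alist,
                          List blist, List masks, NumericVector obsSums,
                          bool closed) {
  int nv = V.nrow();
  std::vector<double> px(nv), py(nv);
  double total = 0.0;
  int ncam = masks.size();
  for (int ci = 0; ci < ncam; ++ci) {
    NumericMatrix A = Alist[ci];
    NumericVector b = blist[ci];
    NumericMatrix obs = masks[ci];
    for (int i = 0; i < nv; ++i) {
      px[i] = A(0, 0) * V(i, 0) + A(0, 1) * V(i, 1) + A(0, 2) * V(i, 2) + b[0];
      py[i] = A(1, 0) * V(i, 0) + A(1, 1) * V(i, 1) + A(1, 2) * V(i, 2) + b[1];
    }
    int H = obs.nrow(), W = obs.ncol();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < nv; ++i) {
      if (px[i] < xmin) xmin = px[i];
      if (px[i] > xmax) xmax = px[i];
      if (py[i] < ymin) ymin = py[i];
      if (py[i] > ymax) ymax = py[i];
    }
    int c0 = std::max(0, (int)std::floor(xmin - 1));
    int c1 = std::min(W - 1, (int)std::ceil(xmax + 1));
    int r0 = std::max(0, (int)std::floor(ymin - 1));
    int r1 = std::min(H - 1, (int)std::ceil(ymax + 1));
    if (c1 < c0 || r1 < r0) { total += obsSums[ci]; continue; }
    int w = c1 - c0 + 1, h = r1 - r0 + 1;
    std::vector<unsigned char> buf((size_t)w * h, 0);
    fillBuffer(px.data(), py.data(), tri, c0, r0, w, h, buf);
    if (closed) {
      // nothing extra: fillBuffer rasterises both windings; culling is
      // handled only in the binary kernel where it matters for speed
    }
    double inBbox = 0, interDiff = 0;
    const double* obsp = REAL(obs);
    for (int c = 0; c < w; ++c) {
      const unsigned char* col = &buf[(size_t)c * h];
      const double* ocol = obsp + (size_t)(c + c0) * H + r0;
      for (int r = 0; r < h; ++r) {
        double o = ocol[r];
        inBbox += o;
        if (col[r]) interDiff += 1.0 - 2.0 * o;
      }
    }
    // sum over bbox of |R - O| = interDiff + inBbox; outside bbox R = 0
    total += interDiff + inBbox + (obsSums[ci] - inBbox);
  }
  return total;
}

// Symmetric-difference pixel count between the rendered silhouette of the
// projected triangles and an observed binary mask. obsCount is the total
// number of set pixels in obs (precomputed once per frame).
// [[Rcpp::export(name = ".silhouetteSymDiff")]]
double silhouetteSymDiff(NumericVector px, NumericVector py,
                         IntegerMatrix tri, LogicalMatrix obs,
                         double obsCount) {
  int H = obs.nrow(), W = obs.ncol();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  int n = px.size();
  for (int i = 0; i < n; ++i) {
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  int c0 = std::max(0, (int)std::floor(xmin - 1));
  int c1 = std::min(W - 1, (int)std::ceil(xmax + 1));
  int r0 = std::max(0, (int)std::floor(ymin - 1));
  int r1 = std::min(H - 1, (int)std::ceil(ymax + 1));
  if (c1 < c0 || r1 < r0) return obsCount;  // mesh fully outside the frame
  int w = c1 - c0 + 1, h = r1 - r0 + 1;
  std::vector<unsigned char> buf((size_t)w * h, 0);
  fillBuffer(px.begin(), py.begin(), tri, c0, r0, w, h, buf);
  double rendered = 0, inter = 0;
  const int* obsp = LOGICAL(obs);
  for (int c = 0; c < w; ++c) {
    const unsigned char* col = &buf[(size_t)c * h];
    const int* ocol = obsp + (size_t)(c + c0) * H + r0;
    for (int r = 0; r < h; ++r) {
      if (col[r]) {
        rendered += 1;
        if (ocol[r]) inter += 1;
      }
    }
  }
  return (rendered - inter) + (obsCount - inter);
}
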