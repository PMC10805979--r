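#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 0-based linear index in a column-major (d0,d1,d2) lattice
static inline R_xlen_t lin3(int i, int j, int k, const int* d) {
  return (R_xlen_t)i + (R_xlen_t)d[0] * ((R_xlen_t)j + (R_xlen_t)d[1] * k);
}

// Resample a 3D volume onto a new lattice sharing the position of voxel 0.
// Output voxel (i,j,k) samples input coordinate (i,j,k) * scale; trilinear
// interpolation when linear=true, nearest-neighbour otherwise. Coordinates
// are clamped to the input lattice.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector arr, IntegerVector newShape,
                             NumericVector scale, bool linear) {
  IntegerVector dv = arr.attr("dim");
  int d[3] = {dv[0], dv[1], dv[2]};
  int n[3] = {newShape[0], newShape[1], newShape[2]};
  NumericVector out((R_xlen_t)n[0] * n[1] * n[2]);
  out.attr("dim") = newShape;
  const double* src = arr.begin();
  double* dst = out.begin();
  R_xlen_t p = 0;
  for (int k = 0; k < n[2]; ++k) {
    double z = std::min(std::max(k * scale[2], 0.0), (double)(d[2] - 1));
    for (int j = 0; j < n[1]; ++j) {
      double y = std::min(std::max(j * scale[1], 0.0), (double)(d[1] - 1));
      for (int i = 0; i < n[0]; ++i, ++p) {
        double x = std::min(std::max(i * scale[0], 0.0), (double)(d[0] - 1));
        if (!linear) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y),
              zi = (int)std::lround(z);
          dst[p] = src[lin3(xi, yi, zi, d)];
        } else {
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          int x1 = std::min(x0 + 1, d[0] - 1);
          int y1 = std::min(y0 + 1, d[1] - 1);
          int z1 = std::min(z0 + 1, d[2] - 1);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          double c00 = src[lin3(x0, y0, z0, d)] * (1 - fx) +
                       src[lin3(x1, y0, z0, d)] * fx;
          double c10 = src[lin3(x0, y1, z0, d)] * (1 - fx) +
                       src[lin3(x1, y1, z0, d)] * fx;
          double c01 = src[lin3(x0, y0, z1, d)] * (1 - fx) +
                       src[lin3(x1, y0, z1, d)] * fx;
          double c11 = src[lin3(x0, y1, z1, d)] * (1 - fx) +
                       src[lin3(x1, y1, z1, d)] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          dst[p] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary 3D mask. connectivity is 6 or
// 26. Labels are 1..ncomp in first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector mask, int connectivity) {
  IntegerVector dv = mask.attr("dim");
  int d[3] = {dv[0], dv[1], dv[2]};
  R_xlen_t nvox = mask.size();
  IntegerVector labels(nvox, 0);
  labels.attr("dim") = dv;
  const double* m = mask.begin();
  int* lab = labels.begin();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < nvox; ++start) {
    if (m[start] == 0 || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % d[0]);
      int j = (int)((v / d[0]) % d[1]);
      int k = (int)(v / ((R_xlen_t)d[0] * d[1]));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && manh != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 ||
                ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
            R_xlen_t w = lin3(ii, jj, kk, d);
            if (m[w] != 0 && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  return labels;
}

// Fill enclosed holes: background voxels with no 6-connected path to the
// lattice boundary become foreground.
// [[Rcpp::export]]
NumericVector cpp_fill_holes(NumericVector mask) {
  IntegerVector dv = mask.attr("dim");
  int d[3] = {dv[0], dv[1], dv[2]};
  R_xlen_t nvox = mask.size();
  const double* m = mask.begin();
  std::vector<char> outside(nvox, 0);
  std::vector<R_xlen_t> stack;
  // seed the flood with all background voxels on the lattice faces
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        if (i > 0 && j > 0 && k > 0 &&
            i < d[0] - 1 && j < d[1] - 1 && k < d[2] - 1) continue;
        R_xlen_t v = lin3(i, j, k, d);
        if (m[v] == 0 && !outside[v]) {
          outside[v] = 1;
          stack.push_back(v);
        }
      }
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int i = (int)(v % d[0]);
    int j = (int)((v / d[0]) % d[1]);
    int k = (int)(v / ((R_xlen_t)d[0] * d[1]));
    for (int t = 0; t < 6; ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || jj < 0 || kk < 0 ||
          ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
      R_xlen_t w = lin3(ii, jj, kk, d);
      if (m[w] == 0 && !outside[w]) {
        outside[w] = 1;
        stack.push_back(w);
      }
    }
  }
  NumericVector out(nvox);
  out.attr("dim") = dv;
  for (R_xlen_t v = 0; v < nvox; ++v)
    out[v] = (m[v] != 0 || !outside[v]) ? 1.0 : 0.0;
  return out;
}

// Binary dilation by an odd-sized structuring element, repeated iter times.
// [[Rcpp::export]]
NumericVector cpp_dilate(NumericVector mask, NumericVector se, int iter) {
  IntegerVector dv = mask.attr("dim");
  IntegerVector sv = se.attr("dim");
  int d[3] = {dv[0], dv[1], dv[2]};
  int s[3] = {sv[0], sv[1], sv[2]};
  int r[3] = {s[0] / 2, s[1] / 2, s[2] / 2};
  R_xlen_t nvox = mask.size();
  NumericVector cur = clone(mask);
  for (int it = 0; it < iter; ++it) {
    NumericVector nxt(nvox);
    const double* m = cur.begin();
    double* o = nxt.begin();
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          R_xlen_t v = lin3(i, j, k, d);
          if (m[v] == 0) continue;
          for (int dk = -r[2]; dk <= r[2]; ++dk)
            for (int dj = -r[1]; dj <= r[1]; ++dj)
              for (int di = -r[0]; di <= r[0]; ++di) {
                if (se[lin3(di + r[0], dj + r[1], dk + r[2], s)] == 0)
                  continue;
                int ii = i + di, jj = j + dj, kk = k + dk;
                if (ii < 0 || jj < 0 || kk < 0 ||
                    ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
                o[lin3(ii, jj, kk, d)] = 1.0;
              }
        }
    cur = nxt;
  }
  cur.attr("dim") = dv;
  return cur;
}

// Coordinates (0-based, n x 3) of surface voxels: foreground voxels with at
// least one background 6-neighbour; voxels beyond the lattice count as
// background.
// [[Rcpp::export]]
IntegerMatrix cpp_surface_voxels(NumericVector mask) {
  IntegerVector dv = mask.attr("dim");
  int d[3] = {dv[0], dv[1], dv[2]};
  const double* m = mask.begin();
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  std::vector<int> coords;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        if (m[lin3(i, j, k, d)] == 0) continue;
        bool surf = false;
        for (int t = 0; t < 6 && !surf; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || jj < 0 || kk < 0 ||
              ii >= d[0] || jj >= d[1] || kk >= d[2] ||
              m[lin3(ii, jj, kk, d)] == 0)
            surf = true;
        }
        if (surf) {
          coords.push_back(i);
          coords.push_back(j);
          coords.push_back(k);
        }
      }
  int n = (int)(coords.size() / 3);
  IntegerMatrix out(n, 3);
  for (int t = 0; t < n; ++t) {
    out(t, 0) = coords[3 * t];
    out(t, 1) = coords[3 * t + 1];
    out(t, 2) = coords[3 * t + 2];
  }
  return out;
}

// For every point of A (n x 3 voxel coords), the Euclidean distance in mm
// to the nearest point of B, with anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_min_distances(IntegerMatrix A, IntegerMatrix B,
                                NumericVector spacing) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int a = 0; a < na; ++a) {
    double best = R_PosInf;
    double ax = A(a, 0) * sx, ay = A(a, 1) * sy, az = A(a, 2) * sz;
    for (int b = 0; b < nb; ++b) {
      double dx = ax - B(b, 0) * sx;
      double dy = ay - B(b, 1) * sy;
      double dz = az - B(b, 2) * sz;
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// Rotate (degrees, counter-clockwise) about the matrix centre and zoom in
// by factor >= 1, resampling on the original lattice. linear=false gives
// nearest-neighbour (for masks). Out-of-range samples take `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_warp2d(NumericMatrix img, double angleDeg, double zoom,
                         bool linear, double fill) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double cx = (H - 1) / 2.0, cy = (W - 1) / 2.0;
  double th = angleDeg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      // inverse map: undo zoom then rotation
      double u = (i - cx) / zoom, v = (j - cy) / zoom;
      double x = cx + ct * u + st * v;
      double y = cy - st * u + ct * v;
      if (x < 0 || y < 0 || x > H - 1 || y > W - 1) {
        out(i, j) = fill;
        continue;
      }
      if (!linear) {
        out(i, j) = img((int)std::lround(x), (int)std::lround(y));
      } else {
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        int x1 = std::min(x0 + 1, H - 1), y1 = std::min(y0 + 1, W - 1);
        double fx = x - x0, fy = y - y0;
        out(i, j) = img(x0, y0) * (1 - fx) * (1 - fy) +
                    img(x1, y0) * fx * (1 - fy) +
                    img(x0, y1) * (1 - fx) * fy +
                    img(x1, y1) * fx * fy;
      }
    }
  return out;
}
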