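#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected foreground voxels of a 3D logical array.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++current;
    stack.clear();
    stack.push_back(start);
    labels[start] = current;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[nb] && !labels[nb]) {
              labels[nb] = current;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  labels.attr("label_count") = current;
  return labels;
}

static inline int px(const std::vector<int> &img, int nx, int ny, int x, int y) {
  if (x < 0 || x >= nx || y < 0 || y >= ny) return 0;
  return img[x + nx * y];
}

// Zhang-Suen thinning of a 2D binary mask; returns the 1-pixel-wide skeleton.
// [[Rcpp::export(name = ".thin_2d")]]
LogicalMatrix thin_2d(LogicalMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  std::vector<int> img((size_t)nx * ny);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      img[x + nx * y] = mask(x, y) ? 1 : 0;

  bool changed = true;
  std::vector<R_xlen_t> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          if (!img[x + nx * y]) continue;
          // neighbours p2..p9 clockwise from north
          int p2 = px(img, nx, ny, x, y - 1);
          int p3 = px(img, nx, ny, x + 1, y - 1);
          int p4 = px(img, nx, ny, x + 1, y);
          int p5 = px(img, nx, ny, x + 1, y + 1);
          int p6 = px(img, nx, ny, x, y + 1);
          int p7 = px(img, nx, ny, x - 1, y + 1);
          int p8 = px(img, nx, ny, x - 1, y);
          int p9 = px(img, nx, ny, x - 1, y - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = 0;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(x + (R_xlen_t)nx * y);
        }
      }
      if (!kill.empty()) changed = true;
      for (R_xlen_t k : kill) img[k] = 0;
    }
  }

  LogicalMatrix out(nx, ny);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      out(x, y) = img[x + nx * y] != 0;
  return out;
}
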