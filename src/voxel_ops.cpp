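#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Linear index helpers for column-major (R) 3-D arrays: idx = i + nx*(j + ny*k)

// 26-connected component labelling of a binary mask.
// Components are relabelled 1..K in decreasing voxel-count order
// (ties broken by first raster-scan encounter).
// [[Rcpp::export(name = ".cc26_label")]]
IntegerVector cc26_label(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> sizes;  // sizes[provisional label - 1]
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    R_xlen_t sz = 0;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      ++sz;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
          }
    }
    sizes.push_back(sz);
  }
  // stable sort provisional labels by decreasing size
  std::vector<int> ord(next);
  for (int i = 0; i < next; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&sizes](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[ord[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (lab[s] != 0) lab[s] = remap[lab[s]];
  return lab;
}

static LogicalVector morph6(const LogicalVector& mask, const IntegerVector& dim,
                            int iter, bool erode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector cur = clone(mask);
  for (int it = 0; it < iter; ++it) {
    LogicalVector nxt(n);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          bool acc = cur[v];
          // 6-connected (face) neighbours; outside the grid counts as background
          const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
          if (erode) {
            if (acc) {
              for (int m = 0; m < 6 && acc; ++m) {
                int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) { acc = false; break; }
                R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                if (!cur[w]) acc = false;
              }
            }
          } else {
            if (!acc) {
              for (int m = 0; m < 6 && !acc; ++m) {
                int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
                R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                if (cur[w]) acc = true;
              }
            }
          }
          nxt[v] = acc;
        }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export(name = ".binary_erode6")]]
LogicalVector binary_erode6(LogicalVector mask, IntegerVector dim, int iter) {
  return morph6(mask, dim, iter, true);
}

// [[Rcpp::export(name = ".binary_dilate6")]]
LogicalVector binary_dilate6(LogicalVector mask, IntegerVector dim, int iter) {
  return morph6(mask, dim, iter, false);
}

// Nearest-source-voxel-centre label resampling in world coordinates.
// tgt_affine maps target 0-based voxel index -> world (first 3 rows, 4 cols,
// column-major as an R 3x4 slice of the 4x4); src_inv maps world -> source
// continuous 0-based index. For each target voxel the candidate source
// voxels within +/- radius of the rounded continuous index are scanned and
// the one whose centre is closest in world (mm) distance wins.
// [[Rcpp::export(name = ".nn_resample_labels")]]
IntegerVector nn_resample_labels(IntegerVector src, IntegerVector src_dim,
                                 NumericMatrix src_affine, NumericMatrix src_inv,
                                 IntegerVector tgt_dim, NumericMatrix tgt_affine,
                                 int radius) {
  const int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  const int tx = tgt_dim[0], ty = tgt_dim[1], tz = tgt_dim[2];
  const R_xlen_t nt = (R_xlen_t)tx * ty * tz;
  IntegerVector out(nt, 0);
  R_xlen_t v = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++v) {
        double wx = tgt_affine(0,0)*i + tgt_affine(0,1)*j + tgt_affine(0,2)*k + tgt_affine(0,3);
        double wy = tgt_affine(1,0)*i + tgt_affine(1,1)*j + tgt_affine(1,2)*k + tgt_affine(1,3);
        double wz = tgt_affine(2,0)*i + tgt_affine(2,1)*j + tgt_affine(2,2)*k + tgt_affine(2,3);
        double ci = src_inv(0,0)*wx + src_inv(0,1)*wy + src_inv(0,2)*wz + src_inv(0,3);
        double cj = src_inv(1,0)*wx + src_inv(1,1)*wy + src_inv(1,2)*wz + src_inv(1,3);
        double ck = src_inv(2,0)*wx + src_inv(2,1)*wy + src_inv(2,2)*wz + src_inv(2,3);
        int ri = (int)std::lround(ci), rj = (int)std::lround(cj), rk = (int)std::lround(ck);
        // nearest-centre semantics also outside the grid: clamp, then search
        ri = std::min(std::max(ri, 0), sx - 1);
        rj = std::min(std::max(rj, 0), sy - 1);
        rk = std::min(std::max(rk, 0), sz - 1);
        double best = R_PosInf;
        int bestlab = 0;
        for (int dk = -radius; dk <= radius; ++dk)
          for (int dj = -radius; dj <= radius; ++dj)
            for (int di = -radius; di <= radius; ++di) {
              int ii = ri + di, jj = rj + dj, kk = rk + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= sx || jj >= sy || kk >= sz) continue;
              double cx = src_affine(0,0)*ii + src_affine(0,1)*jj + src_affine(0,2)*kk + src_affine(0,3);
              double cy = src_affine(1,0)*ii + src_affine(1,1)*jj + src_affine(1,2)*kk + src_affine(1,3);
              double cz = src_affine(2,0)*ii + src_affine(2,1)*jj + src_affine(2,2)*kk + src_affine(2,3);
              double d2 = (cx-wx)*(cx-wx) + (cy-wy)*(cy-wy) + (cz-wz)*(cz-wz);
              if (d2 < best) {
                best = d2;
                bestlab = src[ii + (R_xlen_t)sx * (jj + (R_xlen_t)sy * kk)];
              }
            }
        if (R_finite(best)) out[v] = bestlab;
      }
  return out;
}
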