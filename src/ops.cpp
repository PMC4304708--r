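// Low-level morphological operators for the erythema detection pipeline.
//
// Conventions: matrices are R numeric/logical matrices (column-major,
// index r + c*H, 0-based here).  "Raster order" means row-major scanning
// (top row first, left to right), which is how lesion labels are ordered.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Grayscale erosion by a discrete Euclidean disc {(dx,dy): dx^2+dy^2 <= r^2}.
// Decomposed by row offset: for each dy the disc contributes a centred
// horizontal run of half-width floor(sqrt(r^2-dy^2)); a monotonic-deque
// sliding minimum makes each run O(W).  Pixels outside the image act as
// +Inf (window truncation), so the output never exceeds the input.
// [[Rcpp::export(name = ".erode_disc_cpp")]]
NumericMatrix erode_disc_cpp(NumericMatrix x, int radius) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), INF);

  std::vector<double> rowmin(W);
  std::deque<int> dq;

  for (int dy = -radius; dy <= radius; ++dy) {
    const int wx = (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));
    for (int i = 0; i < H; ++i) {
      const int src = i + dy;
      if (src < 0 || src >= H) continue;
      // sliding min over columns of row `src`, window [j-wx, j+wx]
      dq.clear();
      for (int j = 0; j < W + wx; ++j) {
        if (j < W) {
          const double v = x(src, j);
          while (!dq.empty() && x(src, dq.back()) >= v) dq.pop_back();
          dq.push_back(j);
        }
        const int outj = j - wx;
        if (outj >= 0 && outj < W) {
          while (!dq.empty() && dq.front() < outj - wx) dq.pop_front();
          rowmin[outj] = x(src, dq.front());
        }
      }
      for (int j = 0; j < W; ++j)
        if (rowmin[j] < out(i, j)) out(i, j) = rowmin[j];
    }
  }
  return out;
}

// Grayscale geodesic reconstruction by dilation (marker under mask),
// 4-connected, hybrid raster/anti-raster algorithm with a FIFO queue
// (Vincent-style).  Requires marker <= mask everywhere.
// [[Rcpp::export(name = ".reconstruct_dilate_cpp")]]
NumericMatrix reconstruct_dilate_cpp(NumericMatrix marker, NumericMatrix mask) {
  const int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W)
    stop("marker and mask dimensions differ");
  NumericMatrix J = clone(marker);
  for (int k = 0; k < H * W; ++k)
    if (J[k] > mask[k] + 1e-12) stop("marker must not exceed mask");

  // raster scan: neighbours already visited are up and left
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double v = J(i, j);
      if (i > 0 && J(i - 1, j) > v) v = J(i - 1, j);
      if (j > 0 && J(i, j - 1) > v) v = J(i, j - 1);
      const double m = mask(i, j);
      J(i, j) = v < m ? v : m;
    }
  }
  // anti-raster scan + queue seeding
  std::queue<int> fifo;
  for (int i = H - 1; i >= 0; --i) {
    for (int j = W - 1; j >= 0; --j) {
      double v = J(i, j);
      if (i < H - 1 && J(i + 1, j) > v) v = J(i + 1, j);
      if (j < W - 1 && J(i, j + 1) > v) v = J(i, j + 1);
      const double m = mask(i, j);
      J(i, j) = v < m ? v : m;
      const double cur = J(i, j);
      bool push = false;
      if (i < H - 1 && J(i + 1, j) < cur && J(i + 1, j) < mask(i + 1, j)) push = true;
      if (!push && j < W - 1 && J(i, j + 1) < cur && J(i, j + 1) < mask(i, j + 1)) push = true;
      if (push) fifo.push(i + j * H);
    }
  }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!fifo.empty()) {
    const int p = fifo.front(); fifo.pop();
    const int i = p % H, j = p / H;
    const double cur = J(i, j);
    for (int k = 0; k < 4; ++k) {
      const int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      const double nv = J(ni, nj), nm = mask(ni, nj);
      if (nv < cur && nv < nm) {
        J(ni, nj) = cur < nm ? cur : nm;
        fifo.push(ni + nj * H);
      }
    }
  }
  return J;
}

// Hysteresis thresholding: a pixel is kept iff its value >= t_low and it is
// 8-connected through >= t_low pixels to some pixel >= t_high.
// [[Rcpp::export(name = ".hysteresis_cpp")]]
LogicalMatrix hysteresis_cpp(NumericMatrix x, double t_low, double t_high) {
  const int H = x.nrow(), W = x.ncol();
  LogicalMatrix out(H, W);
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (x(i, j) >= t_high && !out(i, j)) {
        out(i, j) = true;
        stack.push_back(i + j * H);
        while (!stack.empty()) {
          const int p = stack.back(); stack.pop_back();
          const int pi = p % H, pj = p / H;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int ni = pi + di, nj = pj + dj;
              if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
              if (!out(ni, nj) && x(ni, nj) >= t_low) {
                out(ni, nj) = true;
                stack.push_back(ni + nj * H);
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// 8-connected component labelling.  Labels are assigned in the order the
// components are first met by a row-major (raster) scan, so label k's
// top-left-most pixel precedes label k+1's in raster order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W); // zero-initialized
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(i + j * H);
        while (!stack.empty()) {
          const int p = stack.back(); stack.pop_back();
          const int pi = p % H, pj = p / H;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int ni = pi + di, nj = pj + dj;
              if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
              if (mask(ni, nj) && lab(ni, nj) == 0) {
                lab(ni, nj) = next;
                stack.push_back(ni + nj * H);
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
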