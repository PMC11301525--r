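// Pixel-level image operations: 3x3 local entropy / standard-deviation
// filters (mirror padding), 4-connected component labelling, border-connected
// hole filling, 8-neighbour boundary extraction, and clockwise Moore contour
// tracing. All coordinates returned to R are 0-based (row, col).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

static inline int mirror_idx(int i, int n) {
  // symmetric (edge-repeating) reflection, valid for |overhang| < n
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// [[Rcpp::export]]
NumericMatrix entropy3_cpp(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  int bins[9];
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int n = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = mirror_idx(c + dc, W);
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = mirror_idx(r + dr, H);
          double v = img(rr, cc);
          if (v < 0) v = 0; else if (v > 1) v = 1;
          int b = (int)(v * 256.0);
          if (b > 255) b = 255;
          bins[n++] = b;
        }
      }
      // entropy over the 9-sample histogram (256 uniform bins on [0,1])
      double ent = 0.0;
      for (int i = 0; i < 9; ++i) {
        if (bins[i] < 0) continue;  // already counted
        int cnt = 1;
        for (int j = i + 1; j < 9; ++j)
          if (bins[j] == bins[i]) { ++cnt; bins[j] = -1; }
        const double p = cnt / 9.0;
        ent -= p * std::log2(p);
      }
      out(r, c) = ent;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix std3_cpp(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double s = 0.0, s2 = 0.0;
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = mirror_idx(c + dc, W);
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = mirror_idx(r + dr, H);
          const double v = img(rr, cc);
          s += v; s2 += v * v;
        }
      }
      double var = (s2 - s * s / 9.0) / 8.0;  // sample variance, n - 1 = 8
      if (var < 0) var = 0;
      out(r, c) = std::sqrt(var);
    }
  }
  return out;
}

// [[Rcpp::export]]
List label4_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix labels(H, W);
  std::vector<int> sizes;
  int next = 0;
  const int drs[4] = {-1, 1, 0, 0}, dcs[4] = {0, 0, -1, 1};
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || labels(r, c)) continue;
      ++next;
      int sz = 0;
      stack.clear();
      stack.push_back(r + c * H);
      labels(r, c) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % H, pc = p / H;
        ++sz;
        for (int k = 0; k < 4; ++k) {
          const int nr = pr + drs[k], nc = pc + dcs[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && !labels(nr, nc)) {
            labels(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  return List::create(Named("labels") = labels,
                      Named("sizes") = wrap(sizes));
}

// [[Rcpp::export]]
IntegerMatrix fill_holes_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // flood background 4-connected to the border; the rest becomes foreground
  std::vector<char> outside((size_t)H * W, 0);
  std::vector<int> stack;
  const int drs[4] = {-1, 1, 0, 0}, dcs[4] = {0, 0, -1, 1};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (r != 0 && r != H - 1 && c != 0 && c != W - 1) continue;
      if (mask(r, c) || outside[r + (size_t)c * H]) continue;
      outside[r + (size_t)c * H] = 1;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int k = 0; k < 4; ++k) {
          const int nr = pr + drs[k], nc = pc + dcs[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (!mask(nr, nc) && !outside[nr + (size_t)nc * H]) {
            outside[nr + (size_t)nc * H] = 1;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = mask(r, c) ? 1 : (outside[r + (size_t)c * H] ? 0 : 1);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix boundary8_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> rows, cols;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      bool bd = false;
      for (int dr = -1; dr <= 1 && !bd; ++dr)
        for (int dc = -1; dc <= 1 && !bd; ++dc) {
          if (!dr && !dc) continue;
          const int nr = r + dr, nc = c + dc;
          if (nr < 0 || nr >= H || nc < 0 || nc >= W || !mask(nr, nc)) bd = true;
        }
      if (bd) { rows.push_back(r); cols.push_back(c); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { out(i, 0) = rows[i]; out(i, 1) = cols[i]; }
  return out;
}

// Moore-neighbour tracing, clockwise, starting from the uppermost then
// leftmost foreground pixel, with Jacob's stopping criterion. The input is
// expected to be a single 4-connected component; repeated visits (1-pixel
// spurs) are deduplicated keeping first occurrence.
// [[Rcpp::export]]
IntegerMatrix trace_contour_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // clockwise from North
  const int drs[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dcs[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) stop("empty mask");
  auto fg = [&](int r, int c) {
    return r >= 0 && r < H && c >= 0 && c < W && mask(r, c) != 0;
  };
  std::vector<int> rows, cols;
  std::vector<char> seen((size_t)H * W, 0);
  auto emit = [&](int r, int c) {
    if (!seen[r + (size_t)c * H]) {
      seen[r + (size_t)c * H] = 1;
      rows.push_back(r); cols.push_back(c);
    }
  };
  emit(sr, sc);
  // backtrack starts West of the start pixel (guaranteed background)
  int cr = sr, cc = sc, bdir = 6;  // direction from current to backtrack
  // the walk is deterministic in (position, backtrack direction): stop as
  // soon as a state repeats, which closes the contour exactly once
  std::vector<char> state_seen((size_t)H * W * 8, 0);
  const long maxit = 8L * H * W + 16;
  for (long it = 0; it < maxit; ++it) {
    const size_t sid = ((size_t)cr + (size_t)cc * H) * 8 + bdir;
    if (state_seen[sid]) break;
    state_seen[sid] = 1;
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      const int d = (bdir + k) % 8;
      if (fg(cr + drs[d], cc + dcs[d])) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    // backtrack for the next step: the neighbour scanned just before `found`
    const int prev = (found + 7) % 8;
    const int nr = cr + drs[found], nc = cc + dcs[found];
    const int br = cr + drs[prev], bc = cc + dcs[prev];
    int nb = 0;
    for (int d = 0; d < 8; ++d)
      if (nr + drs[d] == br && nc + dcs[d] == bc) { nb = d; break; }
    cr = nr; cc = nc; bdir = nb;
    emit(cr, cc);
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { out(i, 0) = rows[i]; out(i, 1) = cols[i]; }
  return out;
}
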