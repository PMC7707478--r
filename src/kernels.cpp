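#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sliding-histogram median filter for 8-bit images, square window of
// half-width `radius`, replicate edge handling (out-of-bounds indices are
// clamped, so edge rows/columns are weighted as in ImageJ's replicated
// border). Input must already be quantized to integers in [0, 255].
// [[Rcpp::export]]
NumericMatrix cpp_window_median(const NumericMatrix img, const int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int w = 2 * radius + 1;
  const int ntot = w * w, half = (ntot + 1) / 2;
  NumericMatrix out(nr, nc);
  std::vector<int> hist(256);

  for (int i = 0; i < nr; ++i) {
    std::fill(hist.begin(), hist.end(), 0);
    // initial window centred on column 0
    for (int dj = -radius; dj <= radius; ++dj) {
      const int j = clampi(dj, 0, nc - 1);
      for (int di = -radius; di <= radius; ++di) {
        const int ii = clampi(i + di, 0, nr - 1);
        ++hist[(int)img(ii, j)];
      }
    }
    for (int j = 0; j < nc; ++j) {
      if (j > 0) {
        const int jout = clampi(j - 1 - radius, 0, nc - 1);
        const int jin  = clampi(j + radius,     0, nc - 1);
        for (int di = -radius; di <= radius; ++di) {
          const int ii = clampi(i + di, 0, nr - 1);
          --hist[(int)img(ii, jout)];
          ++hist[(int)img(ii, jin)];
        }
      }
      int acc = 0, g = 0;
      for (; g < 256; ++g) { acc += hist[g]; if (acc >= half) break; }
      out(i, j) = g;
    }
  }
  return out;
}

// Local mean and population SD over a circular window (dx^2+dy^2 <= r^2),
// replicate edges via index clamping. Returns a list(mean=, sd=).
// [[Rcpp::export]]
List cpp_local_stats_circle(const NumericMatrix img, const int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dxs, dys;
  for (int dx = -radius; dx <= radius; ++dx)
    for (int dy = -radius; dy <= radius; ++dy)
      if (dx * dx + dy * dy <= radius * radius) { dxs.push_back(dx); dys.push_back(dy); }
  const int nwin = (int)dxs.size();
  NumericMatrix mu(nr, nc), sd(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int k = 0; k < nwin; ++k) {
        const double v = img(clampi(i + dys[k], 0, nr - 1), clampi(j + dxs[k], 0, nc - 1));
        s += v; s2 += v * v;
      }
      const double m = s / nwin;
      double var = s2 / nwin - m * m;
      if (var < 0) var = 0;
      mu(i, j) = m;
      sd(i, j) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// Separable correlation with replicate edges: out(i,j) =
// sum_u sum_v kr[u] * kc[v] * img(clamp(i+u-cr), clamp(j+v-cc)).
// kr runs along rows (dim 1), kc along columns (dim 2); both lengths odd.
// [[Rcpp::export]]
NumericMatrix cpp_sep_convolve(const NumericMatrix img, const NumericVector kr,
                               const NumericVector kc) {
  const int nr = img.nrow(), nc = img.ncol();
  const int lr = kr.size(), lc = kc.size();
  const int cr = lr / 2, cc = lc / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // pass 1: along rows (dim 1)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int u = 0; u < lr; ++u) s += kr[u] * img(clampi(i + u - cr, 0, nr - 1), j);
      tmp(i, j) = s;
    }
  // pass 2: along columns (dim 2)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int v = 0; v < lc; ++v) s += kc[v] * tmp(i, clampi(j + v - cc, 0, nc - 1));
      out(i, j) = s;
    }
  return out;
}

static inline int nb(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen two-subiteration thinning to quasi-unit-width centerlines.
// Out-of-image neighbours count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_zhang_suen(const LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          // neighbours clockwise from north: P2..P9
          const int p2 = nb(m, i - 1, j),     p3 = nb(m, i - 1, j + 1);
          const int p4 = nb(m, i, j + 1),     p5 = nb(m, i + 1, j + 1);
          const int p6 = nb(m, i + 1, j),     p7 = nb(m, i + 1, j - 1);
          const int p8 = nb(m, i, j - 1),     p9 = nb(m, i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = false;
      }
    }
  }
  return m;
}

// 8-connected component labeling by BFS flood fill; labels 1..K in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(i + j * nr);
      while (!q.empty()) {
        const int idx = q.front(); q.pop();
        const int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              q.push(ni + nj * nr);
            }
          }
      }
    }
  }
  return lab;
}

// Render tubular structures: for each sample point (x=column, y=row, 1-based,
// fractional allowed) with tube radius rad, stamp an anti-aliased disk whose
// per-pixel coverage is clamp(rad + 0.5 - dist, 0, 1); the canvas keeps the
// pointwise maximum. Returns the updated canvas (input is not modified).
// [[Rcpp::export]]
NumericMatrix cpp_stamp_tubes(const NumericMatrix canvas, const NumericVector x,
                              const NumericVector y, const NumericVector rad) {
  const int nr = canvas.nrow(), nc = canvas.ncol();
  NumericMatrix out = clone(canvas);
  const int n = x.size();
  for (int k = 0; k < n; ++k) {
    const double cx = x[k] - 1.0, cy = y[k] - 1.0, r = rad[k];
    const int j0 = clampi((int)std::floor(cx - r - 1), 0, nc - 1);
    const int j1 = clampi((int)std::ceil(cx + r + 1), 0, nc - 1);
    const int i0 = clampi((int)std::floor(cy - r - 1), 0, nr - 1);
    const int i1 = clampi((int)std::ceil(cy + r + 1), 0, nr - 1);
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        const double d = std::sqrt((j - cx) * (j - cx) + (i - cy) * (i - cy));
        double cov = r + 0.5 - d;
        if (cov <= 0) continue;
        if (cov > 1) cov = 1;
        if (cov > out(i, j)) out(i, j) = cov;
      }
    }
  }
  return out;
}

// Grayscale white top-hat with a disk structuring element
// (dx^2 + dy^2 <= r^2): image minus opening (erosion then dilation), with
// out-of-bounds window positions ignored (equivalent to replicate padding
// for a symmetric flat element).
// [[Rcpp::export]]
NumericMatrix cpp_gray_tophat(const NumericMatrix img, const int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dxs, dys;
  for (int dx = -radius; dx <= radius; ++dx)
    for (int dy = -radius; dy <= radius; ++dy)
      if (dx * dx + dy * dy <= radius * radius) { dxs.push_back(dx); dys.push_back(dy); }
  const int nwin = (int)dxs.size();
  NumericMatrix ero(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < nwin; ++k) {
        const int ii = i + dys[k], jj = j + dxs[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (img(ii, jj) < m) m = img(ii, jj);
      }
      ero(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < nwin; ++k) {
        const int ii = i + dys[k], jj = j + dxs[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (ero(ii, jj) > m) m = ero(ii, jj);
      }
      out(i, j) = img(i, j) - m;
    }
  return out;
}
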