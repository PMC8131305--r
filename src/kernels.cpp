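#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Images are numeric matrices indexed [y, x] (row = y), intensities in [0, 1].
// All pixel coordinates are 0-based; the centre of pixel (x, y) is at (x, y).

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample with edge clamping.
static inline double sample_bilinear(const NumericMatrix &img, double x, double y) {
  const int w = img.ncol(), h = img.nrow();
  x = clampd(x, 0.0, w - 1.0);
  y = clampd(y, 0.0, h - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > w - 2) x0 = w - 2;
  if (y0 > h - 2) y0 = h - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  double fx = x - x0, fy = y - y0;
  double v00 = img(y0, x0),     v01 = img(y0, x0 + 1);
  double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Catmull-Rom bicubic sampling with edge clamping: used by the LK solvers,
// where the sub-pixel phase bias of bilinear sampling would imprint a
// nuisance-locked ripple on recovered positions.
static inline double cubic_w(double f, double m1, double p0, double p1, double p2) {
  return p0 + 0.5 * f * (p1 - m1 +
         f * (2.0 * m1 - 5.0 * p0 + 4.0 * p1 - p2 +
         f * (3.0 * (p0 - p1) + p2 - m1)));
}

static inline double sample_bicubic(const NumericMatrix &img, double x, double y) {
  const int w = img.ncol(), h = img.nrow();
  x = clampd(x, 0.0, w - 1.0);
  y = clampd(y, 0.0, h - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > w - 2) x0 = w - 2;
  if (y0 > h - 2) y0 = h - 2;
  double fx = x - x0, fy = y - y0;
  const double *I = img.begin();
  double rows[4];
  for (int j = -1; j <= 2; ++j) {
    int yj = y0 + j; yj = yj < 0 ? 0 : (yj > h - 1 ? h - 1 : yj);
    int xm = x0 - 1 < 0 ? 0 : x0 - 1;
    int xp = x0 + 1 > w - 1 ? w - 1 : x0 + 1;
    int xq = x0 + 2 > w - 1 ? w - 1 : x0 + 2;
    const double m1 = I[(size_t)xm * h + yj];
    const double p0 = I[(size_t)x0 * h + yj];
    const double p1 = I[(size_t)xp * h + yj];
    const double p2 = I[(size_t)xq * h + yj];
    rows[j + 1] = cubic_w(fx, m1, p0, p1, p2);
  }
  return cubic_w(fy, rows[0], rows[1], rows[2], rows[3]);
}

// clamped source index pairs + constant fraction for a constant-shift axis
static void axis_idx(int n, double d, std::vector<int> &i0,
                     std::vector<int> &i1, double &f) {
  double fl = std::floor(-d);
  f = (-d) - fl;
  i0.resize(n); i1.resize(n);
  for (int t = 0; t < n; ++t) {
    int a = t + (int)fl;
    i0[t] = a < 0 ? 0 : (a > n - 1 ? n - 1 : a);
    int b = a + 1;
    i1[t] = b < 0 ? 0 : (b > n - 1 ? n - 1 : b);
  }
}

// Translate image content by (dx, dy): out(y, x) = in(x - dx, y - dy),
// bilinear with edge padding. Constant shift -> constant weights.
// [[Rcpp::export]]
NumericMatrix cpp_translate(const NumericMatrix &img, double dx, double dy) {
  const int w = img.ncol(), h = img.nrow();
  NumericMatrix out(h, w);
  std::vector<int> x0, x1, y0, y1;
  double fx, fy;
  axis_idx(w, dx, x0, x1, fx);
  axis_idx(h, dy, y0, y1, fy);
  const double *I = img.begin();
  double *O = out.begin();
  for (int x = 0; x < w; ++x) {
    const double *c0 = I + (size_t)x0[x] * h;
    const double *c1 = I + (size_t)x1[x] * h;
    double *oc = O + (size_t)x * h;
    for (int y = 0; y < h; ++y) {
      double v0 = (1 - fx) * c0[y0[y]] + fx * c1[y0[y]];
      double v1 = (1 - fx) * c0[y1[y]] + fx * c1[y1[y]];
      oc[y] = (1 - fy) * v0 + fy * v1;
    }
  }
  return out;
}

// 2x2 mean downsampling (pyramid level builder); odd trailing row/col clamped.
// [[Rcpp::export]]
NumericMatrix cpp_downsample2(const NumericMatrix &img) {
  const int w = img.ncol(), h = img.nrow();
  const int w2 = (w + 1) / 2, h2 = (h + 1) / 2;
  NumericMatrix out(h2, w2);
  for (int y = 0; y < h2; ++y) {
    int y0 = 2 * y, y1 = std::min(2 * y + 1, h - 1);
    for (int x = 0; x < w2; ++x) {
      int x0 = 2 * x, x1 = std::min(2 * x + 1, w - 1);
      out(y, x) = 0.25 * (img(y0, x0) + img(y0, x1) + img(y1, x0) + img(y1, x1));
    }
  }
  return out;
}

// Composite one synthetic frame: background translated by the nuisance
// shift, tendon layer (texture + soft mask) additionally translated by the
// twitch, alpha-blended in a single pass.
// [[Rcpp::export]]
NumericMatrix cpp_render_frame(const NumericMatrix &bg,
                               const NumericMatrix &tendon,
                               const NumericMatrix &mask,
                               double ndx, double ndy,
                               double tdx, double tdy,
                               double noise_sd) {
  const int w = bg.ncol(), h = bg.nrow();
  NumericMatrix out(h, w);
  RNGScope rng; // use R's RNG so seeding stays reproducible from R
  std::vector<int> bx0, bx1, by0, by1, tx0, tx1, ty0, ty1;
  double bfx, bfy, tfx, tfy;
  axis_idx(w, ndx, bx0, bx1, bfx);
  axis_idx(h, ndy, by0, by1, bfy);
  axis_idx(w, ndx + tdx, tx0, tx1, tfx);
  axis_idx(h, ndy + tdy, ty0, ty1, tfy);
  const double *B = bg.begin(), *T = tendon.begin(), *M = mask.begin();
  double *O = out.begin();
  for (int x = 0; x < w; ++x) {
    const double *bc0 = B + (size_t)bx0[x] * h, *bc1 = B + (size_t)bx1[x] * h;
    const double *tc0 = T + (size_t)tx0[x] * h, *tc1 = T + (size_t)tx1[x] * h;
    const double *mc0 = M + (size_t)tx0[x] * h, *mc1 = M + (size_t)tx1[x] * h;
    double *oc = O + (size_t)x * h;
    for (int y = 0; y < h; ++y) {
      double b = (1 - bfy) * ((1 - bfx) * bc0[by0[y]] + bfx * bc1[by0[y]]) +
                 bfy * ((1 - bfx) * bc0[by1[y]] + bfx * bc1[by1[y]]);
      double t = (1 - tfy) * ((1 - tfx) * tc0[ty0[y]] + tfx * tc1[ty0[y]]) +
                 tfy * ((1 - tfx) * tc0[ty1[y]] + tfx * tc1[ty1[y]]);
      double m = (1 - tfy) * ((1 - tfx) * mc0[ty0[y]] + tfx * mc1[ty0[y]]) +
                 tfy * ((1 - tfx) * mc0[ty1[y]] + tfx * mc1[ty1[y]]);
      double v = b * (1 - m) + t * m;
      if (noise_sd > 0) v += R::rnorm(0.0, noise_sd);
      v = clampd(v, 0.0, 1.0);
      oc[y] = std::round(v * 65535.0) / 65535.0; // 16-bit grid
    }
  }
  return out;
}

// Normalized cross-correlation template match around a reference position.
// templ's reference top-left corner is (tx, ty); offsets searched in
// [-radius, radius]^2. Returns (dx, dy, quality): the content offset that
// maximizes NCC, refined to sub-pixel by 1-D quadratic fits through the peak.
// [[Rcpp::export]]
NumericVector cpp_ncc_match(const NumericMatrix &frame, const NumericMatrix &templ,
                            int tx, int ty, int radius) {
  const int fw = frame.ncol(), fh = frame.nrow();
  const int tw = templ.ncol(), th = templ.nrow();
  const int n = tw * th;
  double tmean = 0.0;
  for (int j = 0; j < th; ++j) for (int i = 0; i < tw; ++i) tmean += templ(j, i);
  tmean /= n;
  double tss = 0.0;
  std::vector<double> tc(n); // column-major, like the frame
  for (int i = 0; i < tw; ++i)
    for (int j = 0; j < th; ++j) {
      double v = templ(j, i) - tmean;
      tc[i * th + j] = v;
      tss += v * v;
    }
  if (tss <= 0.0) stop("degenerate template: zero intensity variance");
  const double tnorm = std::sqrt(tss);

  const int side = 2 * radius + 1;
  std::vector<double> score(side * side, -2.0);
  double best = -2.0;
  int bi = 0, bj = 0;
  for (int oy = -radius; oy <= radius; ++oy) {
    int ry = ty + oy;
    if (ry < 0 || ry + th > fh) continue;
    for (int ox = -radius; ox <= radius; ++ox) {
      int rx = tx + ox;
      if (rx < 0 || rx + tw > fw) continue;
      // single pass: NCC from raw sums (template is already mean-free)
      const double *F = frame.begin();
      double sf = 0.0, sff = 0.0, sft = 0.0;
      for (int i = 0; i < tw; ++i) {
        const double *fcol = F + (size_t)(rx + i) * fh + ry;
        const double *tcol = &tc[i * th];
        for (int j = 0; j < th; ++j) {
          double fv = fcol[j];
          sf += fv; sff += fv * fv; sft += fv * tcol[j];
        }
      }
      double fss = sff - sf * sf / n;
      double s = fss > 0.0 ? sft / (tnorm * std::sqrt(fss)) : 0.0;
      score[(oy + radius) * side + (ox + radius)] = s;
      if (s > best) { best = s; bi = ox; bj = oy; }
    }
  }
  // sub-pixel refinement: quadratic through the peak and its axis neighbours
  double dx = bi, dy = bj;
  int ci = bi + radius, cj = bj + radius;
  if (ci > 0 && ci < side - 1) {
    double sm = score[cj * side + ci - 1], s0 = score[cj * side + ci],
           sp = score[cj * side + ci + 1];
    double den = sm - 2 * s0 + sp;
    if (sm > -2 && sp > -2 && den < 0) dx += clampd(0.5 * (sm - sp) / den, -0.5, 0.5);
  }
  if (cj > 0 && cj < side - 1) {
    double sm = score[(cj - 1) * side + ci], s0 = score[cj * side + ci],
           sp = score[(cj + 1) * side + ci];
    double den = sm - 2 * s0 + sp;
    if (sm > -2 && sp > -2 && den < 0) dy += clampd(0.5 * (sm - sp) / den, -0.5, 0.5);
  }
  return NumericVector::create(dx, dy, best);
}

// Iterative Lucas-Kanade refinement of a global shift estimate: registers
// the template patch (top-left at (tx, ty) in the reference frame) to the
// frame, starting from (dx0, dy0). Gradients come from the template
// interior. Returns (dx, dy, ok).
// [[Rcpp::export]]
NumericVector cpp_refine_shift(const NumericMatrix &frame,
                               const NumericMatrix &templ,
                               int tx, int ty, double dx0, double dy0,
                               int max_iter, double eps) {
  const int tw = templ.ncol(), th = templ.nrow();
  const int fw = frame.ncol(), fh = frame.nrow();
  const int n = (tw - 2) * (th - 2);
  std::vector<double> Tv(n), Txg(n), Tyg(n);
  double gxx = 0, gxy = 0, gyy = 0;
  int k = 0;
  for (int j = 1; j < th - 1; ++j)
    for (int i = 1; i < tw - 1; ++i, ++k) {
      Tv[k] = templ(j, i);
      double ix = 0.5 * (templ(j, i + 1) - templ(j, i - 1));
      double iy = 0.5 * (templ(j + 1, i) - templ(j - 1, i));
      Txg[k] = ix; Tyg[k] = iy;
      gxx += ix * ix; gxy += ix * iy; gyy += iy * iy;
    }
  double det = gxx * gyy - gxy * gxy;
  double dx = dx0, dy = dy0;
  if (det < 1e-12) return NumericVector::create(dx, dy, 0.0);
  for (int it = 0; it < max_iter; ++it) {
    double ox = tx + dx, oy = ty + dy;
    if (ox + 1 < 0 || oy + 1 < 0 || ox + tw - 1 > fw - 1 || oy + th - 1 > fh - 1)
      return NumericVector::create(dx0, dy0, 0.0);
    double bx = 0, by = 0;
    k = 0;
    for (int j = 1; j < th - 1; ++j)
      for (int i = 1; i < tw - 1; ++i, ++k) {
        double dI = Tv[k] - sample_bicubic(frame, ox + i, oy + j);
        bx += dI * Txg[k];
        by += dI * Tyg[k];
      }
    double ux = (gyy * bx - gxy * by) / det;
    double uy = (gxx * by - gxy * bx) / det;
    dx += ux; dy += uy;
    if (std::sqrt(ux * ux + uy * uy) < eps) break;
  }
  return NumericVector::create(dx, dy, 1.0);
}

// One pyramid level of iterative Lucas-Kanade for a single point.
// Returns updated displacement (dx, dy) and ok flag.
static bool lk_level(const NumericMatrix &I, const NumericMatrix &J,
                     double x, double y, int hw, int max_iter, double eps,
                     double &dx, double &dy) {
  const int w = I.ncol(), h = I.nrow();
  const int win = 2 * hw + 1, n = win * win;
  // window (with 1 px gradient margin) must stay inside the source image
  if (x - hw - 1 < 0 || y - hw - 1 < 0 || x + hw + 1 > w - 1 || y + hw + 1 > h - 1)
    return false;
  // sample the (win+2)^2 source patch once; gradients from its interior
  const int wp = win + 2;
  std::vector<double> P(wp * wp);
  for (int j = 0; j < wp; ++j)
    for (int i = 0; i < wp; ++i)
      P[j * wp + i] = sample_bicubic(I, x + i - hw - 1, y + j - hw - 1);
  std::vector<double> Iv(n), Ix(n), Iy(n);
  double gxx = 0, gxy = 0, gyy = 0;
  int k = 0;
  for (int j = 1; j <= win; ++j)
    for (int i = 1; i <= win; ++i, ++k) {
      Iv[k] = P[j * wp + i];
      double ix = 0.5 * (P[j * wp + i + 1] - P[j * wp + i - 1]);
      double iy = 0.5 * (P[(j + 1) * wp + i] - P[(j - 1) * wp + i]);
      Ix[k] = ix; Iy[k] = iy;
      gxx += ix * ix; gxy += ix * iy; gyy += iy * iy;
    }
  double det = gxx * gyy - gxy * gxy;
  if (det < 1e-12) return false;
  for (int it = 0; it < max_iter; ++it) {
    double nx = x + dx, ny = y + dy;
    if (nx - hw < 0 || ny - hw < 0 || nx + hw > w - 1 || ny + hw > h - 1)
      return false;
    double bx = 0, by = 0;
    k = 0;
    for (int j = -hw; j <= hw; ++j)
      for (int i = -hw; i <= hw; ++i, ++k) {
        double dI = Iv[k] - sample_bicubic(J, nx + i, ny + j);
        bx += dI * Ix[k];
        by += dI * Iy[k];
      }
    double ux = (gyy * bx - gxy * by) / det;
    double uy = (gxx * by - gxy * bx) / det;
    dx += ux; dy += uy;
    if (std::sqrt(ux * ux + uy * uy) < eps) break;
  }
  double nx = x + dx, ny = y + dy;
  return !(nx < 0 || ny < 0 || nx > w - 1 || ny > h - 1);
}

// Pyramidal KLT for a set of points between two frames. pyrI/pyrJ are lists
// of matrices, finest level first. pts is n x 2 (x, y) at level 0; init is
// n x 2 with the starting displacement guess at level 0.
// Returns n x 3: new x, new y, ok flag.
// [[Rcpp::export]]
NumericMatrix cpp_klt_pair(const List &pyrI, const List &pyrJ,
                           const NumericMatrix &pts, int hw, int max_iter,
                           double eps, const NumericMatrix &init) {
  const int L = pyrI.size();
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  std::vector<NumericMatrix> Is, Js;
  for (int l = 0; l < L; ++l) {
    Is.push_back(as<NumericMatrix>(pyrI[l]));
    Js.push_back(as<NumericMatrix>(pyrJ[l]));
  }
  const double top = std::pow(2.0, L - 1);
  for (int p = 0; p < n; ++p) {
    double x0 = pts(p, 0), y0 = pts(p, 1);
    double dx = init(p, 0) / top, dy = init(p, 1) / top;
    bool ok = true;
    for (int l = L - 1; l >= 0; --l) {
      double s = std::pow(2.0, l);
      double xl = x0 / s, yl = y0 / s;
      double dxs = dx, dys = dy;
      ok = lk_level(Is[l], Js[l], xl, yl, hw, max_iter, eps, dx, dy);
      if (!ok) {
        if (l == 0) break;
        // window does not fit (or solve degenerated) at this coarse level:
        // skip it and let the finer levels do the work
        dx = dxs; dy = dys; ok = true;
      }
      if (l > 0) { dx *= 2.0; dy *= 2.0; }
    }
    out(p, 0) = x0 + dx;
    out(p, 1) = y0 + dy;
    out(p, 2) = ok ? 1.0 : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// MSER: maximally stable extremal regions, bright-on-dark polarity (call on
// the inverted image for the dark polarity). img holds integers in 0..255.
// Union-find over pixels added in descending intensity order; each surviving
// root records its (level, area) history; maximally stable levels are local
// minima of the relative area variation across +/- delta intensity steps.
// Returns a matrix with one row per candidate:
//   cx, cy, mxx, myy, mxy (central moments), area, level, variation
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_mser(const IntegerMatrix &img, int delta, int min_area,
                       int max_area, double max_variation) {
  const int w = img.ncol(), h = img.nrow(), npx = w * h;
  // counting sort of pixel ids by intensity, descending
  std::vector<int> cnt(257, 0);
  for (int p = 0; p < npx; ++p) {
    int v = img[p]; // column-major linear index
    if (v < 0 || v > 255) stop("pixel values must be in 0..255");
    cnt[255 - v + 1]++;
  }
  for (int i = 1; i <= 256; ++i) cnt[i] += cnt[i - 1];
  std::vector<int> order(npx);
  {
    std::vector<int> pos(cnt.begin(), cnt.end() - 1);
    // within a level, ascending pixel id for determinism
    for (int p = 0; p < npx; ++p) order[pos[255 - img[p]]++] = p;
  }
  std::vector<int> parent(npx, -1), sz(npx, 0);
  std::map<int, std::vector<std::pair<int, int> > > hist; // root -> (level, area)
  std::vector<int> stamp(npx, -1);

  // find with path compression
  std::vector<int> path;
  auto findroot = [&](int p) {
    path.clear();
    while (parent[p] != p) { path.push_back(p); p = parent[p]; }
    for (size_t i = 0; i < path.size(); ++i) parent[path[i]] = p;
    return p;
  };

  int idx = 0;
  for (int g = 255; g >= 0; --g) {
    // add all pixels of intensity g
    int start = idx;
    while (idx < npx && img[order[idx]] == g) {
      int p = order[idx++];
      parent[p] = p; sz[p] = 1;
      int py = p % h, px = p / h; // column-major
      const int nb[4][2] = { {px - 1, py}, {px + 1, py}, {px, py - 1}, {px, py + 1} };
      for (int q = 0; q < 4; ++q) {
        int nx = nb[q][0], ny = nb[q][1];
        if (nx < 0 || ny < 0 || nx >= w || ny >= h) continue;
        int np = nx * h + ny;
        if (parent[np] < 0) continue;
        int ra = findroot(p), rb = findroot(np);
        if (ra == rb) continue;
        // larger component's root survives; ties -> lower pixel id
        if (sz[ra] < sz[rb] || (sz[ra] == sz[rb] && rb < ra)) std::swap(ra, rb);
        parent[rb] = ra;
        sz[ra] += sz[rb];
      }
    }
    if (idx == start && g > 0) {
      // no new pixels; area histories unchanged at this level unless we must
      // still record the level for variation lookup -- record only when roots
      // exist (cheap: skip, variation lookup interpolates between records)
    }
    // record area of each active root at this level
    for (int k2 = 0; k2 < idx; ++k2) {
      int r = findroot(order[k2]);
      if (stamp[r] != g) {
        stamp[r] = g;
        hist[r].push_back(std::make_pair(g, sz[r]));
      }
    }
  }

  // area lookup in one history: levels recorded descending; area at level q =
  // area of the latest record with level >= q... histories are per-root with
  // monotone non-decreasing areas as the level drops.
  struct Cand { int seed, level, area; double variation; };
  std::vector<Cand> cands;
  for (std::map<int, std::vector<std::pair<int, int> > >::iterator it = hist.begin();
       it != hist.end(); ++it) {
    std::vector<std::pair<int, int> > &hv = it->second;
    int m = hv.size();
    if (m == 0) continue;
    int g_birth = hv[0].first, g_last = hv[m - 1].first;
    auto area_at = [&](int q) {
      // clamp above birth to birth area; below last record the root no longer
      // exists independently -> return -1
      if (q >= g_birth) return hv[0].second;
      if (q < g_last) return -1;
      // binary search: records descending in level
      int lo = 0, hi = m - 1;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (hv[mid].first >= q) lo = mid; else hi = mid - 1;
      }
      return hv[lo].second;
    };
    std::vector<double> var(m, -1.0);
    for (int i = 0; i < m; ++i) {
      int g = hv[i].first;
      int ahi = area_at(g + delta);
      int alo = area_at(g - delta);
      if (alo < 0) continue;
      var[i] = (double)(alo - ahi) / (double)hv[i].second;
    }
    for (int i = 0; i < m; ++i) {
      if (var[i] < 0 || var[i] > max_variation) continue;
      int a = hv[i].second;
      if (a < min_area || a > max_area) continue;
      double vprev = (i > 0 && var[i - 1] >= 0) ? var[i - 1] : 1e18;
      double vnext = (i < m - 1 && var[i + 1] >= 0) ? var[i + 1] : 1e18;
      if (var[i] <= vprev && var[i] <= vnext) {
        // collapse plateaus of identical area: keep highest level only
        if (i > 0 && hv[i - 1].second == a && var[i - 1] >= 0 &&
            var[i - 1] <= max_variation && var[i - 1] <= var[i])
          continue;
        Cand c; c.seed = it->first; c.level = hv[i].first; c.area = a;
        c.variation = var[i];
        cands.push_back(c);
      }
    }
  }

  // flood fill each candidate at its level to get pixel-set moments
  NumericMatrix out(cands.size(), 8);
  std::vector<int> mark(npx, -1);
  std::vector<int> stack;
  for (size_t c = 0; c < cands.size(); ++c) {
    int g = cands[c].level;
    stack.clear();
    stack.push_back(cands[c].seed);
    mark[cands[c].seed] = (int)c;
    double n = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int py = p % h, px = p / h;
      n += 1; sx += px; sy += py;
      sxx += (double)px * px; syy += (double)py * py; sxy += (double)px * py;
      const int nb[4][2] = { {px - 1, py}, {px + 1, py}, {px, py - 1}, {px, py + 1} };
      for (int q = 0; q < 4; ++q) {
        int nx = nb[q][0], ny = nb[q][1];
        if (nx < 0 || ny < 0 || nx >= w || ny >= h) continue;
        int np = nx * h + ny;
        if (mark[np] == (int)c || img[np] < g) continue;
        mark[np] = (int)c;
        stack.push_back(np);
      }
    }
    double cx = sx / n, cy = sy / n;
    out(c, 0) = cx;
    out(c, 1) = cy;
    out(c, 2) = sxx / n - cx * cx + 1.0 / 12.0; // pixel footprint correction
    out(c, 3) = syy / n - cy * cy + 1.0 / 12.0;
    out(c, 4) = sxy / n - cx * cy;
    out(c, 5) = n;
    out(c, 6) = g;
    out(c, 7) = cands[c].variation;
  }
  return out;
}
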