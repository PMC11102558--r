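#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Rolling-ball background: grayscale opening with a non-flat ball structuring
// element of the given pixel radius. Offsets falling outside the image are
// ignored, which keeps opening <= input everywhere (the identity offset is
// always in bounds).
// [[Rcpp::export]]
NumericMatrix cpp_ball_background(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> dr, dc;
  std::vector<double> se;
  double r2 = (double)radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= r2) {
        dr.push_back(a);
        dc.push_back(b);
        se.push_back(std::sqrt(r2 - d2));
      }
    }
  int K = (int)dr.size();
  NumericMatrix ero(H, W), bg(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int r = i + dr[k], c = j + dc[k];
        if (r < 0 || r >= H || c < 0 || c >= W) continue;
        double v = img(r, c) - se[k];
        if (v < m) m = v;
      }
      ero(i, j) = m;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int r = i + dr[k], c = j + dc[k];
        if (r < 0 || r >= H || c < 0 || c >= W) continue;
        double v = ero(r, c) + se[k];
        if (v > m) m = v;
      }
      bg(i, j) = m;
    }
  return bg;
}

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// One pass of separable Gaussian filtering with reflective boundary.
// Kernel radius is ceil(4*sigma), normalized to unit sum.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t)
        acc += k[t + rad] * img(reflect_idx(i + t, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t)
        acc += k[t + rad] * tmp(i, reflect_idx(j + t, W));
      out(i, j) = acc;
    }
  return out;
}

// 3x3 unsharp kernel: center 12, neighbors -1, divisor 4; replicate boundary;
// clipped to [0,255].
// [[Rcpp::export]]
NumericMatrix cpp_sharpen(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b) {
          int r = std::min(std::max(i + a, 0), H - 1);
          int c = std::min(std::max(j + b, 0), W - 1);
          double w = (a == 0 && b == 0) ? 12.0 : -1.0;
          acc += w * img(r, c);
        }
      acc /= 4.0;
      if (acc < 0.0) acc = 0.0;
      if (acc > 255.0) acc = 255.0;
      out(i, j) = acc;
    }
  return out;
}

// Binary dilation with the full 3x3 (8-connected) structuring element.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate3(LogicalMatrix mask, int iterations) {
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalMatrix nxt(H, W);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        bool v = false;
        for (int a = -1; a <= 1 && !v; ++a)
          for (int b = -1; b <= 1 && !v; ++b) {
            int r = i + a, c = j + b;
            if (r < 0 || r >= H || c < 0 || c >= W) continue;
            if (cur(r, c)) v = true;
          }
        nxt(i, j) = v;
      }
    cur = nxt;
  }
  return cur;
}

static inline bool at(const LogicalMatrix &m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return false;
  return m(i, j);
}

// Simple-point test for (8-connected foreground, 4-connected background),
// precomputed over all 256 neighborhood configurations. Deleting a simple
// pixel cannot change the topology of either phase.
// Ring order (dr, dc): N, NE, E, SE, S, SW, W, NW.
static const int ring_dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int ring_dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static bool simple_lut[256];
static bool simple_lut_ready = false;

static void init_simple_lut() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    bool fg[8];
    for (int k = 0; k < 8; ++k) fg[k] = (cfg >> k) & 1;
    // T8: components of foreground ring positions under plane 8-adjacency
    int comp[8];
    for (int k = 0; k < 8; ++k) comp[k] = fg[k] ? k : -1;
    bool merged = true;
    while (merged) {
      merged = false;
      for (int a = 0; a < 8; ++a) {
        if (!fg[a]) continue;
        for (int b = a + 1; b < 8; ++b) {
          if (!fg[b]) continue;
          int dr = ring_dr[a] - ring_dr[b], dc = ring_dc[a] - ring_dc[b];
          if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1 &&
              comp[a] != comp[b]) {
            int from = comp[b], to = comp[a];
            for (int t = 0; t < 8; ++t)
              if (comp[t] == from) comp[t] = to;
            merged = true;
          }
        }
      }
    }
    int t8 = 0;
    for (int k = 0; k < 8; ++k)
      if (fg[k] && comp[k] == k) ++t8;
    // T4bar: components of background 4-neighbors (ring 0,2,4,6), where
    // consecutive edge positions merge iff the corner between them is
    // also background (a 4-connected background path through the corner)
    int edges[4] = {0, 2, 4, 6};
    int bcomp[4];
    int nbg = 0;
    for (int e = 0; e < 4; ++e) {
      bcomp[e] = !fg[edges[e]] ? e : -1;
      if (!fg[edges[e]]) ++nbg;
    }
    merged = true;
    while (merged) {
      merged = false;
      for (int e = 0; e < 4; ++e) {
        int f = (e + 1) % 4;
        int corner = (edges[e] + 1) % 8;  // ring corner between edge e and f
        if (bcomp[e] >= 0 && bcomp[f] >= 0 && !fg[corner] &&
            bcomp[e] != bcomp[f]) {
          int from = bcomp[f], to = bcomp[e];
          for (int t = 0; t < 4; ++t)
            if (bcomp[t] == from) bcomp[t] = to;
          merged = true;
        }
      }
    }
    int t4 = 0;
    for (int e = 0; e < 4; ++e)
      if (bcomp[e] >= 0 && bcomp[e] == e) ++t4;
    simple_lut[cfg] = (t8 == 1 && t4 == 1);
  }
  simple_lut_ready = true;
}

static inline int neighborhood_code(const LogicalMatrix &m, int i, int j) {
  int cfg = 0;
  for (int k = 0; k < 8; ++k)
    if (at(m, i + ring_dr[k], j + ring_dc[k])) cfg |= (1 << k);
  return cfg;
}

// Distance-ordered homotopic thinning to a 1-pixel-wide skeleton:
// simple, non-endpoint pixels are deleted sequentially in increasing
// order of their chamfer (3-4) distance to the background, iterated to a
// fixed point. Sequential deletion with the simple-point criterion
// guarantees that foreground 8-topology and background 4-topology are
// preserved exactly, and the distance ordering keeps the skeleton on the
// medial axis (in particular, branch points of fused junctions stay near
// the true vertex).
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  if (!simple_lut_ready) init_simple_lut();
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix m = clone(mask);
  // chamfer 3-4 distance to background (two-pass)
  std::vector<int> D((size_t)H * W);
  const int BIG = 1 << 28;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      D[(size_t)j * H + i] = m(i, j) ? BIG : 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      size_t id = (size_t)j * H + i;
      if (D[id] == 0) continue;
      int v = D[id];
      if (i > 0) v = std::min(v, D[id - 1] + 3);
      if (j > 0) v = std::min(v, D[id - (size_t)H] + 3);
      if (i > 0 && j > 0) v = std::min(v, D[id - (size_t)H - 1] + 4);
      if (i < H - 1 && j > 0) v = std::min(v, D[id - (size_t)H + 1] + 4);
      // the frame has no outside neighbor; treat it as adjacent to
      // background so blobs on the frame thin inward too
      if (i == 0 || i == H - 1 || j == 0 || j == W - 1) v = std::min(v, 3);
      D[id] = v;
    }
  for (int j = W - 1; j >= 0; --j)
    for (int i = H - 1; i >= 0; --i) {
      size_t id = (size_t)j * H + i;
      if (D[id] == 0) continue;
      int v = D[id];
      if (i < H - 1) v = std::min(v, D[id + 1] + 3);
      if (j < W - 1) v = std::min(v, D[id + (size_t)H] + 3);
      if (i < H - 1 && j < W - 1) v = std::min(v, D[id + (size_t)H + 1] + 4);
      if (i > 0 && j < W - 1) v = std::min(v, D[id + (size_t)H - 1] + 4);
      D[id] = v;
    }
  // indices of foreground pixels sorted by distance (stable counting sort)
  std::vector<std::pair<int, size_t> > order;
  order.reserve((size_t)H * W / 4);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (m(i, j)) order.push_back(std::make_pair(D[(size_t)j * H + i],
                                                  (size_t)j * H + i));
  std::stable_sort(order.begin(), order.end());
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t t = 0; t < order.size(); ++t) {
      int i = (int)(order[t].second % H);
      int j = (int)(order[t].second / H);
      if (!m(i, j)) continue;
      int cfg = neighborhood_code(m, i, j);
      int B = __builtin_popcount((unsigned)cfg);
      if (B < 2) continue;  // keep curve endpoints
      if (!simple_lut[cfg]) continue;
      m(i, j) = false;
      changed = true;
    }
  }
  return m;
}

static int degree8(const LogicalMatrix &m, int i, int j) {
  int d = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b) {
      if (a == 0 && b == 0) continue;
      if (at(m, i + a, j + b)) ++d;
    }
  return d;
}

// Remove spur branches shorter than minlen (walked from an endpoint to the
// first branch point) and whole 8-connected components smaller than minlen.
// Iterated to a fixed point so the result is stable under re-pruning.
// [[Rcpp::export]]
LogicalMatrix cpp_prune(LogicalMatrix skel, int minlen) {
  int H = skel.nrow(), W = skel.ncol();
  LogicalMatrix m = clone(skel);
  bool changed = true;
  while (changed) {
    changed = false;
    // small-component removal (8-connected BFS)
    IntegerMatrix lab(H, W);
    int next = 0;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        if (!m(i, j) || lab(i, j) != 0) continue;
        ++next;
        std::vector<std::pair<int, int> > comp;
        std::queue<std::pair<int, int> > q;
        q.push(std::make_pair(i, j));
        lab(i, j) = next;
        while (!q.empty()) {
          std::pair<int, int> p = q.front();
          q.pop();
          comp.push_back(p);
          for (int a = -1; a <= 1; ++a)
            for (int b = -1; b <= 1; ++b) {
              int r = p.first + a, c = p.second + b;
              if (r < 0 || r >= H || c < 0 || c >= W) continue;
              if (m(r, c) && lab(r, c) == 0) {
                lab(r, c) = next;
                q.push(std::make_pair(r, c));
              }
            }
        }
        if ((int)comp.size() < minlen) {
          for (size_t t = 0; t < comp.size(); ++t)
            m(comp[t].first, comp[t].second) = false;
          changed = true;
        }
      }
    // spur removal from endpoints
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        if (!m(i, j) || degree8(m, i, j) != 1) continue;
        std::vector<std::pair<int, int> > path;
        int ci = i, cj = j, pi = -1, pj = -1;
        bool hit_branch = false;
        while ((int)path.size() < minlen) {
          path.push_back(std::make_pair(ci, cj));
          int ni = -1, nj = -1, nn = 0;
          for (int a = -1; a <= 1; ++a)
            for (int b = -1; b <= 1; ++b) {
              if (a == 0 && b == 0) continue;
              int r = ci + a, c = cj + b;
              if (r == pi && c == pj) continue;
              if (at(m, r, c)) {
                ++nn;
                ni = r;
                nj = c;
              }
            }
          if (nn == 0) break;           // isolated open end (component rule applies)
          if (nn > 1) { hit_branch = true; break; }
          if (degree8(m, ni, nj) > 2) { hit_branch = true; break; }
          pi = ci; pj = cj; ci = ni; cj = nj;
        }
        if (hit_branch && (int)path.size() < minlen) {
          for (size_t t = 0; t < path.size(); ++t)
            m(path[t].first, path[t].second) = false;
          changed = true;
        }
      }
  }
  return m;
}

// For each pixel: labels and distances of the nearest and second-nearest seed
// point under an optionally anisotropic metric (columns divided by `elong`).
// Used to build Voronoi tessellations and their border bands.
// [[Rcpp::export]]
List cpp_nearest_two(NumericVector seed_r, NumericVector seed_c,
                     int H, int W, double elong) {
  int n = seed_r.size();
  IntegerMatrix l1(H, W), l2(H, W);
  NumericMatrix d1(H, W), d2(H, W);
  std::fill(d1.begin(), d1.end(), R_PosInf);
  std::fill(d2.begin(), d2.end(), R_PosInf);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double b1 = R_PosInf, b2 = R_PosInf;
      int i1 = 0, i2 = 0;
      for (int s = 0; s < n; ++s) {
        double dr = (i + 1) - seed_r[s];
        double dc = ((j + 1) - seed_c[s]) / elong;
        double d = dr * dr + dc * dc;
        if (d < b1) {
          b2 = b1; i2 = i1;
          b1 = d; i1 = s + 1;
        } else if (d < b2) {
          b2 = d; i2 = s + 1;
        }
      }
      d1(i, j) = std::sqrt(b1);
      d2(i, j) = std::sqrt(b2);
      l1(i, j) = i1;
      l2(i, j) = i2;
    }
  return List::create(_["label1"] = l1, _["label2"] = l2,
                      _["dist1"] = d1, _["dist2"] = d2);
}
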