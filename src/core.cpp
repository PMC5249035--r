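#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Pixel coordinates throughout: x = column, y = row, both 0-based, matching
// the package's documented convention. Matrices are indexed (row, col).

static inline int reflect_idx(int i, int n) {
  // reflect-101-style padding without repeating the border pixel twice
  // would change the window median; plain reflection (border repeated) is
  // the documented contract.
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int radius) {
  int H = x.nrow(), W = x.ncol();
  if (radius <= 0) return clone(x);
  NumericMatrix out(H, W);
  int side = 2 * radius + 1;
  std::vector<double> win(side * side);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int t = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = reflect_idx(j + dj, W);
        for (int di = -radius; di <= radius; ++di) {
          int ii = reflect_idx(i + di, H);
          win[t++] = x(ii, jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + t / 2, win.begin() + t);
      out(i, j) = win[t / 2];
    }
  }
  return out;
}

// Maximum of p over the Bresenham raster of the segment (x0,y0)-(x1,y1),
// endpoints included.  The run direction is canonicalized by lexicographic
// ordering of the endpoints so the result is symmetric in (i, j).
static double line_max_impl(const NumericMatrix &p, int x0, int y0,
                            int x1, int y1) {
  if (x1 < x0 || (x1 == x0 && y1 < y0)) {
    std::swap(x0, x1);
    std::swap(y0, y1);
  }
  int dx = std::abs(x1 - x0), sx = x0 < x1 ? 1 : -1;
  int dy = -std::abs(y1 - y0), sy = y0 < y1 ? 1 : -1;
  int err = dx + dy;
  double best = p(y0, x0);
  while (!(x0 == x1 && y0 == y1)) {
    int e2 = 2 * err;
    if (e2 >= dy) { err += dy; x0 += sx; }
    if (e2 <= dx) { err += dx; y0 += sy; }
    double v = p(y0, x0);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
double cpp_line_max(NumericMatrix p, int x0, int y0, int x1, int y1) {
  if (x0 < 0 || y0 < 0 || x1 < 0 || y1 < 0 ||
      x0 >= p.ncol() || x1 >= p.ncol() || y0 >= p.nrow() || y1 >= p.nrow())
    stop("pixel outside the image");
  return line_max_impl(p, x0, y0, x1, y1);
}

// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polyline(IntegerMatrix pts, int H, int W) {
  // pts: n x 2 (x, y) 0-based; returns all raster pixels visited, in order.
  int n = pts.nrow();
  std::vector<int> xs, ys;
  for (int s = 0; s + 1 < n || (n == 1 && s == 0); ++s) {
    int x0 = pts(s, 0), y0 = pts(s, 1);
    int x1 = (n == 1) ? x0 : pts(s + 1, 0);
    int y1 = (n == 1) ? y0 : pts(s + 1, 1);
    if (x0 < 0 || x0 >= W || y0 < 0 || y0 >= H ||
        x1 < 0 || x1 >= W || y1 < 0 || y1 >= H)
      stop("path pixel outside the image");
    int dx = std::abs(x1 - x0), sx = x0 < x1 ? 1 : -1;
    int dy = -std::abs(y1 - y0), sy = y0 < y1 ? 1 : -1;
    int err = dx + dy;
    int x = x0, y = y0;
    if (xs.empty() || xs.back() != x || ys.back() != y) {
      xs.push_back(x); ys.push_back(y);
    }
    while (!(x == x1 && y == y1)) {
      int e2 = 2 * err;
      if (e2 >= dy) { err += dy; x += sx; }
      if (e2 <= dx) { err += dx; y += sy; }
      xs.push_back(x); ys.push_back(y);
    }
    if (n == 1) break;
  }
  IntegerMatrix out(xs.size(), 2);
  for (size_t k = 0; k < xs.size(); ++k) {
    out(k, 0) = xs[k];
    out(k, 1) = ys[k];
  }
  return out;
}

// ---------------------------------------------------------------------------
// SLIC-MMED core loop.
//
// Feature vector per pixel: [c, y, r, x, y]; distance
//   D'^2 = (d'_c / m)^2 + (d_s / S)^2 + alpha * d_e^2
// with d_e the maximum edge probability along the Bresenham segment from the
// pixel to the centroid's rounded position.  Comparing squared distances is
// order-equivalent to comparing D'.  With use_edge = FALSE the alpha term is
// skipped entirely (plain SLIC); with an all-zero edge map the added term is
// exactly 0.0, so both code paths produce bit-identical label maps.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_slic(NumericMatrix cc, NumericMatrix yy, NumericMatrix rr,
              NumericMatrix p, NumericMatrix cent0, double S, double m,
              double alpha, int iterations, bool use_edge) {
  int H = cc.nrow(), W = cc.ncol();
  int K = cent0.nrow();
  NumericMatrix cent = clone(cent0);  // cols: c, y, r, x, y
  IntegerMatrix labels(H, W);         // 0 = unassigned
  NumericMatrix dist(H, W);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  int half = (int)std::ceil(S);
  double m2 = m * m, S2 = S * S;
  std::vector<bool> frozen(K, false);

  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < K; ++k) {
      double ck = cent(k, 0), yk = cent(k, 1), rk = cent(k, 2);
      double cx = cent(k, 3), cy = cent(k, 4);
      int cxr = (int)std::lround(cx), cyr = (int)std::lround(cy);
      if (cxr < 0) cxr = 0; if (cxr > W - 1) cxr = W - 1;
      if (cyr < 0) cyr = 0; if (cyr > H - 1) cyr = H - 1;
      int x0 = std::max(0, cxr - half), x1 = std::min(W - 1, cxr + half);
      int y0 = std::max(0, cyr - half), y1 = std::min(H - 1, cyr + half);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          double dc2 = (cc(y, x) - ck) * (cc(y, x) - ck) +
                       (yy(y, x) - yk) * (yy(y, x) - yk) +
                       (rr(y, x) - rk) * (rr(y, x) - rk);
          double ds2 = (x - cx) * (x - cx) + (y - cy) * (y - cy);
          double d2 = dc2 / m2 + ds2 / S2;
          if (use_edge) {
            double de = line_max_impl(p, x, y, cxr, cyr);
            d2 += alpha * de * de;
          }
          if (d2 < dist(y, x)) {  // strict: ties keep the incumbent
            dist(y, x) = d2;
            labels(y, x) = k + 1;
          }
        }
      }
    }
    // centroid update: mean feature vector of members; empty clusters freeze
    std::vector<double> sc(K, 0), sy(K, 0), sr(K, 0), sx(K, 0), syy(K, 0);
    std::vector<int> cnt(K, 0);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int k = labels(y, x) - 1;
        if (k < 0) continue;
        sc[k] += cc(y, x); sy[k] += yy(y, x); sr[k] += rr(y, x);
        sx[k] += x; syy[k] += y; cnt[k]++;
      }
    for (int k = 0; k < K; ++k) {
      if (cnt[k] == 0) { frozen[k] = true; continue; }
      cent(k, 0) = sc[k] / cnt[k];
      cent(k, 1) = sy[k] / cnt[k];
      cent(k, 2) = sr[k] / cnt[k];
      cent(k, 3) = sx[k] / cnt[k];
      cent(k, 4) = syy[k] / cnt[k];
    }
  }
  return List::create(_["labels"] = labels, _["centroids"] = cent);
}

// ---------------------------------------------------------------------------
// Connectivity enforcement: connected-component relabeling of the raw SLIC
// assignment.  Components smaller than min_size (and any unassigned pixels)
// are merged into the neighboring component sharing the largest border;
// larger detached components become labels of their own.  Output labels are
// compacted to 1..L in column-major first-occurrence order.
// ---------------------------------------------------------------------------

static void label_components(const IntegerMatrix &labels, IntegerMatrix &comp,
                             std::vector<int> &comp_size,
                             std::vector<int> &comp_lab) {
  int H = labels.nrow(), W = labels.ncol();
  std::fill(comp.begin(), comp.end(), 0);
  comp_size.clear();
  comp_lab.clear();
  std::vector<std::pair<int, int>> stack;
  int nc = 0;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (comp(y, x) != 0) continue;
      int lab = labels(y, x);
      ++nc;
      int sz = 0;
      stack.clear();
      stack.push_back({x, y});
      comp(y, x) = nc;
      while (!stack.empty()) {
        auto [px, py] = stack.back();
        stack.pop_back();
        ++sz;
        const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
        for (int d = 0; d < 4; ++d) {
          int qx = px + dx[d], qy = py + dy[d];
          if (qx < 0 || qx >= W || qy < 0 || qy >= H) continue;
          if (comp(qy, qx) == 0 && labels(qy, qx) == lab) {
            comp(qy, qx) = nc;
            stack.push_back({qx, qy});
          }
        }
      }
      comp_size.push_back(sz);
      comp_lab.push_back(lab);
    }
}

// [[Rcpp::export]]
IntegerMatrix cpp_enforce_connectivity(IntegerMatrix labels, int min_size) {
  int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix cur = clone(labels);
  IntegerMatrix comp(H, W);
  std::vector<int> comp_size, comp_lab;
  for (int pass = 0; pass < 100; ++pass) {
    label_components(cur, comp, comp_size, comp_lab);
    int nc = comp_size.size();
    if (nc <= 1) break;
    std::vector<int> small_ids;
    for (int c = 0; c < nc; ++c)
      if (comp_lab[c] == 0 || comp_size[c] < min_size)
        small_ids.push_back(c + 1);
    if (small_ids.empty()) break;
    // shared-border counts between small components and their neighbors
    std::map<std::pair<int, int>, int> border;
    std::vector<bool> is_small(nc + 1, false);
    for (int id : small_ids) is_small[id] = true;
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int a = comp(y, x);
        if (x + 1 < W) {
          int b = comp(y, x + 1);
          if (a != b) {
            if (is_small[a]) border[{a, b}]++;
            if (is_small[b]) border[{b, a}]++;
          }
        }
        if (y + 1 < H) {
          int b = comp(y + 1, x);
          if (a != b) {
            if (is_small[a]) border[{a, b}]++;
            if (is_small[b]) border[{b, a}]++;
          }
        }
      }
    // union-find over components; merge each small one into its
    // largest-border neighbor (ties: lowest component id)
    std::vector<int> parent(nc + 1);
    for (int c = 0; c <= nc; ++c) parent[c] = c;
    std::function<int(int)> find = [&](int a) {
      while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
      return a;
    };
    for (int id : small_ids) {
      int best = -1, best_cnt = -1;
      auto it = border.lower_bound({id, 0});
      for (; it != border.end() && it->first.first == id; ++it) {
        if (it->second > best_cnt) {
          best_cnt = it->second;
          best = it->first.second;
        }
      }
      if (best < 0) continue;  // isolated (single-component image)
      int ra = find(id), rb = find(best);
      if (ra != rb) parent[ra] = rb;
    }
    // rewrite: pixels take the label of their root component
    bool changed = false;
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int r = find(comp(y, x));
        int lab = comp_lab[r - 1];
        if (cur(y, x) != lab) { cur(y, x) = lab; changed = true; }
      }
    if (!changed) break;
  }
  // compact to 1..L, detached large components become new labels
  label_components(cur, comp, comp_size, comp_lab);
  IntegerMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) out(y, x) = comp(y, x);
  return out;
}

// ---------------------------------------------------------------------------
// Region statistics for the merging stage: sizes, per-channel intensity
// histograms (counts over `bins` equal bins spanning [0, 255]), mean colour
// intensity, and the directed adjacency structure.  For a directed pair
// (i, j), n is the number of border pixels of i facing j (pixels of i with
// at least one 4-neighbor in j, each counted once) and psum the sum of the
// edge probability over those pixels, so E_ij = psum / n.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_region_stats(IntegerMatrix labels, NumericMatrix cc,
                      NumericMatrix yy, NumericMatrix rr, NumericMatrix p,
                      int bins) {
  int H = labels.nrow(), W = labels.ncol();
  int L = 0;
  for (int i = 0; i < H * W; ++i) L = std::max(L, labels[i]);
  IntegerVector sizes(L);
  NumericVector isum(L);
  NumericMatrix hist(L, 3 * bins);
  std::map<std::pair<int, int>, std::pair<int, double>> adj;
  const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int lab = labels(y, x);
      if (lab < 1) stop("label map contains unassigned pixels");
      int li = lab - 1;
      sizes[li]++;
      double cv = cc(y, x), yv = yy(y, x), rv = rr(y, x);
      isum[li] += (cv + yv + rv) / 3.0;
      int bc = std::min(bins - 1, std::max(0, (int)(cv / 256.0 * bins)));
      int by = std::min(bins - 1, std::max(0, (int)(yv / 256.0 * bins)));
      int br = std::min(bins - 1, std::max(0, (int)(rv / 256.0 * bins)));
      hist(li, bc)++;
      hist(li, bins + by)++;
      hist(li, 2 * bins + br)++;
      int seen[4];
      int nseen = 0;
      for (int d = 0; d < 4; ++d) {
        int qx = x + dx[d], qy = y + dy[d];
        if (qx < 0 || qx >= W || qy < 0 || qy >= H) continue;
        int nl = labels(qy, qx);
        if (nl == lab) continue;
        bool dup = false;
        for (int s = 0; s < nseen; ++s)
          if (seen[s] == nl) { dup = true; break; }
        if (dup) continue;
        seen[nseen++] = nl;
        auto &e = adj[{lab, nl}];
        e.first += 1;
        e.second += p(y, x);
      }
    }
  int ne = adj.size();
  IntegerVector ei(ne), ej(ne), en(ne);
  NumericVector ep(ne);
  int t = 0;
  for (auto &kv : adj) {
    ei[t] = kv.first.first;
    ej[t] = kv.first.second;
    en[t] = kv.second.first;
    ep[t] = kv.second.second;
    ++t;
  }
  return List::create(_["sizes"] = sizes, _["intensity_sum"] = isum,
                      _["hist"] = hist, _["edge_i"] = ei, _["edge_j"] = ej,
                      _["edge_n"] = en, _["edge_psum"] = ep);
}

// [[Rcpp::export]]
LogicalMatrix cpp_boundary_mask(IntegerMatrix labels) {
  int H = labels.nrow(), W = labels.ncol();
  LogicalMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int lab = labels(y, x);
      bool b = (x + 1 < W && labels(y, x + 1) != lab) ||
               (x > 0 && labels(y, x - 1) != lab) ||
               (y + 1 < H && labels(y + 1, x) != lab) ||
               (y > 0 && labels(y - 1, x) != lab);
      out(y, x) = b;
    }
  return out;
}
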