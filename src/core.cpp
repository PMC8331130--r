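#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighborhood offsets, raster order (row-major, top-left to bottom-right)
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Connected-component labeling by breadth-first search, 8-connectivity.
// Components are numbered 1..n in raster order of their first-encountered
// pixel (row-major scan). Background (mask == 0) stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_bfs(const IntegerMatrix& mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> qr(h * (size_t)w), qc(h * (size_t)w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      size_t head = 0, tail = 0;
      qr[tail] = i; qc[tail] = j; ++tail;
      lab(i, j) = next;
      while (head < tail) {
        int r = qr[head], c = qc[head]; ++head;
        for (int k = 0; k < 8; ++k) {
          int nr = r + DR[k], nc = c + DC[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            qr[tail] = nr; qc[tail] = nc; ++tail;
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Flag foreground pixels having at least one background 8-neighbor;
// pixels outside the image count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_boundary(const IntegerMatrix& mask) {
  int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix out(h, w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (mask(i, j) == 0) { out(i, j) = false; continue; }
      bool b = false;
      for (int k = 0; k < 8 && !b; ++k) {
        int nr = i + DR[k], nc = j + DC[k];
        if (nr < 0 || nr >= h || nc < 0 || nc >= w || mask(nr, nc) == 0) b = true;
      }
      out(i, j) = b;
    }
  }
  return out;
}

// Assign each pixel of `grow` (value 1) to the geodesically nearest label in
// `labels` by multi-source BFS (8-connectivity) through grow + labeled
// pixels. Sources are enqueued in raster order, so first-arrival ties are
// broken deterministically in favor of the raster-earlier wavefront.
// [[Rcpp::export]]
IntegerMatrix cpp_assign_nearest(const IntegerMatrix& labels,
                                 const IntegerMatrix& grow) {
  int h = labels.nrow(), w = labels.ncol();
  IntegerMatrix out(h, w);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      out(i, j) = labels(i, j);
      if (labels(i, j) != 0) q.push(std::make_pair(i, j));
    }
  while (!q.empty()) {
    int r = q.front().first, c = q.front().second; q.pop();
    int lb = out(r, c);
    for (int k = 0; k < 8; ++k) {
      int nr = r + DR[k], nc = c + DC[k];
      if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
      if (grow(nr, nc) != 0 && out(nr, nc) == 0) {
        out(nr, nc) = lb;
        q.push(std::make_pair(nr, nc));
      }
    }
  }
  return out;
}

// Local maxima of `x` over a centered square window of half-width `radius`,
// restricted to pixels with x > 0. A pixel is a maximum when no pixel in its
// window (inside the image) exceeds it.
// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(const NumericMatrix& x, int radius) {
  int h = x.nrow(), w = x.ncol();
  LogicalMatrix out(h, w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      double v = x(i, j);
      if (v <= 0) { out(i, j) = false; continue; }
      bool ismax = true;
      int r0 = std::max(0, i - radius), r1 = std::min(h - 1, i + radius);
      int c0 = std::max(0, j - radius), c1 = std::min(w - 1, j + radius);
      for (int r = r0; r <= r1 && ismax; ++r)
        for (int c = c0; c <= c1; ++c)
          if (x(r, c) > v) { ismax = false; break; }
      out(i, j) = ismax;
    }
  }
  return out;
}

// Promote windowed local maxima to markers with regional-maximum
// semantics: each connected component of flagged pixels is extended through
// all equal-valued 8-neighbors (within the positive-distance support); the
// plateau becomes one marker — at the pixel nearest its centroid — unless
// some pixel bordering the plateau is strictly greater, which marks a
// ridge artifact rather than a true peak. Markers are numbered in raster
// order of the plateau's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_plateau_markers(const NumericMatrix& dist,
                                  const LogicalMatrix& flags) {
  int h = dist.nrow(), w = dist.ncol();
  IntegerMatrix markers(h, w);
  LogicalMatrix visited(h, w);
  int next = 0;
  std::vector<int> pr, pc;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!flags(i, j) || visited(i, j)) continue;
      double v = dist(i, j);
      bool dominated = false;
      pr.clear(); pc.clear();
      pr.push_back(i); pc.push_back(j);
      visited(i, j) = true;
      for (size_t head = 0; head < pr.size(); ++head) {
        int r = pr[head], c = pc[head];
        for (int k = 0; k < 8; ++k) {
          int nr = r + DR[k], nc = c + DC[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          double nv = dist(nr, nc);
          if (nv > v) { dominated = true; continue; }
          if (nv == v && !visited(nr, nc)) {
            visited(nr, nc) = true;
            pr.push_back(nr); pc.push_back(nc);
          }
        }
      }
      if (dominated) continue;
      double mr = 0, mc = 0;
      for (size_t t = 0; t < pr.size(); ++t) { mr += pr[t]; mc += pc[t]; }
      mr /= pr.size(); mc /= pc.size();
      int bi = 0;
      double bd = R_PosInf;
      for (size_t t = 0; t < pr.size(); ++t) {
        double d2 = (pr[t] - mr) * (pr[t] - mr) + (pc[t] - mc) * (pc[t] - mc);
        if (d2 < bd - 1e-12) { bd = d2; bi = (int)t; }
      }
      markers(pr[bi], pc[bi]) = ++next;
    }
  }
  markers.attr("n") = next;
  return markers;
}

// Saddle heights between adjacent watershed basins: entry (a, b) is the
// highest min(dist_p, dist_q) over 8-adjacent pixel pairs p in basin a+1,
// q in basin b+1, or -1 when the basins do not touch. Used to measure the
// prominence (dynamics) of candidate markers.
// [[Rcpp::export]]
NumericMatrix cpp_basin_saddles(const IntegerMatrix& labels,
                                const NumericMatrix& dist, int n) {
  NumericMatrix out(n, n);
  std::fill(out.begin(), out.end(), -1.0);
  int h = labels.nrow(), w = labels.ncol();
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      int a = labels(i, j);
      if (a <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int nr = i + DR[k], nc = j + DC[k];
        if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
        int b = labels(nr, nc);
        if (b <= 0 || b == a) continue;
        double s = std::min(dist(i, j), dist(nr, nc));
        if (s > out(a - 1, b - 1)) {
          out(a - 1, b - 1) = s;
          out(b - 1, a - 1) = s;
        }
      }
    }
  return out;
}

struct FloodNode {
  double prio;   // negated distance: lower floods first
  long long ord; // insertion order, FIFO tie-break for determinism
  int r, c, lab;
};
struct FloodCmp {
  bool operator()(const FloodNode& a, const FloodNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.ord > b.ord;
  }
};

// Marker-controlled watershed by priority flooding of the negated distance
// map: basins grow from markers, deepest (largest distance) pixels first.
// `markers` holds positive basin labels; `mask` limits flooding to the
// segment. Returns the basin label of every mask pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& dist,
                            const IntegerMatrix& markers,
                            const IntegerMatrix& mask) {
  int h = dist.nrow(), w = dist.ncol();
  IntegerMatrix out(h, w);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  long long ord = 0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      if (markers(i, j) > 0 && mask(i, j) != 0) {
        FloodNode n = { -dist(i, j), ord++, i, j, markers(i, j) };
        pq.push(n);
      }
  while (!pq.empty()) {
    FloodNode n = pq.top(); pq.pop();
    if (out(n.r, n.c) != 0) continue;
    out(n.r, n.c) = n.lab;
    for (int k = 0; k < 8; ++k) {
      int nr = n.r + DR[k], nc = n.c + DC[k];
      if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
      if (mask(nr, nc) != 0 && out(nr, nc) == 0) {
        FloodNode m = { -dist(nr, nc), ord++, nr, nc, n.lab };
        pq.push(m);
      }
    }
  }
  return out;
}

// Count 8-adjacencies between pixels labeled `id` and every other positive
// label; entry L of the result is the number of ordered neighbor pairs
// (p in id, q in L).
// [[Rcpp::export]]
IntegerVector cpp_border_counts(const IntegerMatrix& labels, int id, int nmax) {
  int h = labels.nrow(), w = labels.ncol();
  IntegerVector counts(nmax);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      if (labels(i, j) != id) continue;
      for (int k = 0; k < 8; ++k) {
        int nr = i + DR[k], nc = j + DC[k];
        if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
        int lb = labels(nr, nc);
        if (lb > 0 && lb != id && lb <= nmax) counts[lb - 1]++;
      }
    }
  return counts;
}

// Per-label pixel count and tight bounding box (1-based rows/cols) for
// labels 1..n. Columns: area, rmin, cmin, rmax, cmax.
// [[Rcpp::export]]
IntegerMatrix cpp_label_stats(const IntegerMatrix& labels, int n) {
  IntegerMatrix st(n, 5);
  int h = labels.nrow(), w = labels.ncol();
  for (int s = 0; s < n; ++s) {
    st(s, 1) = h + 1; st(s, 2) = w + 1; st(s, 3) = 0; st(s, 4) = 0;
  }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int lb = labels(i, j);
      if (lb <= 0 || lb > n) continue;
      int s = lb - 1;
      st(s, 0)++;
      if (i + 1 < st(s, 1)) st(s, 1) = i + 1;
      if (j + 1 < st(s, 2)) st(s, 2) = j + 1;
      if (i + 1 > st(s, 3)) st(s, 3) = i + 1;
      if (j + 1 > st(s, 4)) st(s, 4) = j + 1;
    }
  return st;
}
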