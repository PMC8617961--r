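// Raster operations for the counting workflow and polygon ground truth.
// Masks are integer matrices (0 background, nonzero foreground), indexed
// (row, col); polygon coordinates are 0-based pixel-centre (x = col,
// y = row).
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// 8- or 4-connectivity component labelling; labels assigned in
// column-major scan order (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask,
                                   int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int nn = (connectivity == 8) ? 8 : 4;
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int* dr = (connectivity == 8) ? DR8 : dr4;
  const int* dc = (connectivity == 8) ? DC8 : dc4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + H * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          const int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + H * c2);
          }
        }
      }
    }
  }
  return lab;
}

// Erosion with a binary structuring element; out-of-image samples are
// ignored (treated as foreground), so blobs touching the border are not
// eroded from outside. Anchor follows the OpenCV convention
// (floor(size/2)).
// [[Rcpp::export]]
IntegerMatrix cpp_erode(const IntegerMatrix& mask,
                        const IntegerMatrix& kernel, int ar, int ac) {
  const int H = mask.nrow(), W = mask.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      bool keep = true;
      for (int kj = 0; kj < kw && keep; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          if (kernel(ki, kj) == 0) continue;
          const int r2 = r + ki - ar, c2 = c + kj - ac;
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) == 0) { keep = false; break; }
        }
      }
      out(r, c) = keep ? 1 : 0;
    }
  }
  return out;
}

// Dilation with the kernel reflected about the anchor, so that
// dilate(erode(x)) is the standard morphological opening.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate(const IntegerMatrix& mask,
                         const IntegerMatrix& kernel, int ar, int ac) {
  const int H = mask.nrow(), W = mask.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      bool hit = false;
      for (int kj = 0; kj < kw && !hit; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          if (kernel(ki, kj) == 0) continue;
          const int r2 = r - (ki - ar), c2 = c - (kj - ac);
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0) { hit = true; break; }
        }
      }
      out(r, c) = hit ? 1 : 0;
    }
  }
  return out;
}

// Regional maxima of a distance map, plateau-merged, with greedy
// non-maximum suppression at Euclidean separation < min_distance.
// Suppression applies only between peaks of the same 8-connected
// foreground component: peaks in disjoint blobs are distinct organisms
// regardless of their distance, and every foreground component keeps at
// least one seed. Returns a marker label map (one pixel per accepted
// peak, labelled in acceptance order).
// [[Rcpp::export]]
IntegerMatrix cpp_peak_markers(const NumericMatrix& dist,
                               double min_distance) {
  const int H = dist.nrow(), W = dist.ncol();
  // 8-connected components of the strictly positive support
  IntegerMatrix comp(H, W);
  {
    int ncomp = 0;
    std::vector<int> st;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (dist(r, c) <= 0 || comp(r, c) != 0) continue;
        ++ncomp;
        st.clear();
        st.push_back(r + H * c);
        comp(r, c) = ncomp;
        while (!st.empty()) {
          const int idx = st.back();
          st.pop_back();
          const int rr = idx % H, cc = idx / H;
          for (int k = 0; k < 8; ++k) {
            const int r2 = rr + DR8[k], c2 = cc + DC8[k];
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            if (dist(r2, c2) > 0 && comp(r2, c2) == 0) {
              comp(r2, c2) = ncomp;
              st.push_back(r2 + H * c2);
            }
          }
        }
      }
    }
  }
  IntegerMatrix plateau(H, W);
  int nplat = 0;
  std::vector<int> stack;
  // label equal-valued 8-connected plateaus among strictly positive pixels
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (dist(r, c) <= 0 || plateau(r, c) != 0) continue;
      const double v = dist(r, c);
      ++nplat;
      stack.clear();
      stack.push_back(r + H * c);
      plateau(r, c) = nplat;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int rr = idx % H, cc = idx / H;
        for (int k = 0; k < 8; ++k) {
          const int r2 = rr + DR8[k], c2 = cc + DC8[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (plateau(r2, c2) == 0 && dist(r2, c2) == v) {
            plateau(r2, c2) = nplat;
            stack.push_back(r2 + H * c2);
          }
        }
      }
    }
  }
  std::vector<char> is_max(nplat + 1, 1);
  std::vector<double> val(nplat + 1, 0.0);
  std::vector<double> sum_r(nplat + 1, 0.0), sum_c(nplat + 1, 0.0);
  std::vector<int> cnt(nplat + 1, 0);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int p = plateau(r, c);
      if (p == 0) continue;
      val[p] = dist(r, c);
      sum_r[p] += r; sum_c[p] += c; cnt[p] += 1;
      for (int k = 0; k < 8; ++k) {
        const int r2 = r + DR8[k], c2 = c + DC8[k];
        if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
        if (dist(r2, c2) > dist(r, c)) { is_max[p] = 0; break; }
      }
    }
  }
  // representative pixel: plateau member closest to plateau centroid
  std::vector<int> rep_r(nplat + 1, -1), rep_c(nplat + 1, -1);
  std::vector<double> rep_d(nplat + 1, 1e300);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int p = plateau(r, c);
      if (p == 0 || !is_max[p]) continue;
      const double mr = sum_r[p] / cnt[p], mc = sum_c[p] / cnt[p];
      const double d = (r - mr) * (r - mr) + (c - mc) * (c - mc);
      if (d < rep_d[p] - 1e-12) {
        rep_d[p] = d; rep_r[p] = r; rep_c[p] = c;
      }
    }
  }
  std::vector<int> order;
  for (int p = 1; p <= nplat; ++p) if (is_max[p]) order.push_back(p);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (val[a] != val[b]) return val[a] > val[b];
    if (rep_r[a] != rep_r[b]) return rep_r[a] < rep_r[b];
    return rep_c[a] < rep_c[b];
  });
  IntegerMatrix markers(H, W);
  std::vector<int> acc_r, acc_c, acc_comp;
  int next = 0;
  const double d2min = min_distance * min_distance;
  for (int p : order) {
    const int pc = comp(rep_r[p], rep_c[p]);
    bool ok = true;
    for (size_t i = 0; i < acc_r.size(); ++i) {
      if (acc_comp[i] != pc) continue;
      const double dr = rep_r[p] - acc_r[i], dc = rep_c[p] - acc_c[i];
      if (dr * dr + dc * dc < d2min) { ok = false; break; }
    }
    if (!ok) continue;
    acc_r.push_back(rep_r[p]);
    acc_c.push_back(rep_c[p]);
    acc_comp.push_back(pc);
    markers(rep_r[p], rep_c[p]) = ++next;
  }
  return markers;
}

struct WsEntry {
  double elev;
  long long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.order > b.order;                     // FIFO among ties
  }
};

// Marker-seeded watershed by priority flooding of the elevation map
// restricted to the mask.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const IntegerMatrix& mask,
                            const IntegerMatrix& markers,
                            const NumericMatrix& elev, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int nn = (connectivity == 8) ? 8 : 4;
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int* dr = (connectivity == 8) ? DR8 : dr4;
  const int* dc = (connectivity == 8) ? DC8 : dc4;
  IntegerMatrix lab(H, W);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long order = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (markers(r, c) != 0)
        pq.push({elev(r, c), order++, r + H * c, markers(r, c)});
  while (!pq.empty()) {
    const WsEntry e = pq.top();
    pq.pop();
    const int r = e.idx % H, c = e.idx / H;
    if (lab(r, c) != 0) continue;
    lab(r, c) = e.label;
    for (int k = 0; k < nn; ++k) {
      const int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
      if (mask(r2, c2) != 0 && lab(r2, c2) == 0)
        pq.push({elev(r2, c2), order++, r2 + H * c2, e.label});
    }
  }
  return lab;
}

// Nonzero-winding polygon fill at pixel centres, boundary included: a
// pixel is foreground if its centre lies strictly inside (winding != 0)
// or exactly on a polygon edge.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polygons(const List& polys, int H, int W) {
  IntegerMatrix mask(H, W);
  const double eps = 1e-9;
  for (int pi = 0; pi < polys.size(); ++pi) {
    NumericMatrix P = polys[pi];
    const int n = P.nrow();
    if (n < 3) stop("polygon %d has fewer than 3 vertices", pi + 1);
    // per-row winding crossings
    double ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      ymin = std::min(ymin, P(i, 1));
      ymax = std::max(ymax, P(i, 1));
    }
    const int y0 = std::max(0, (int)std::ceil(ymin - eps));
    const int y1 = std::min(H - 1, (int)std::floor(ymax + eps));
    for (int y = y0; y <= y1; ++y) {
      std::vector<std::pair<double, int> > cross;
      for (int i = 0; i < n; ++i) {
        const double x1 = P(i, 0), yy1 = P(i, 1);
        const double x2 = P((i + 1) % n, 0), yy2 = P((i + 1) % n, 1);
        if (yy1 == yy2) continue;
        int dir = 0;
        if (yy1 <= y && y < yy2) dir = 1;
        else if (yy2 <= y && y < yy1) dir = -1;
        if (dir == 0) continue;
        const double xx = x1 + (y - yy1) * (x2 - x1) / (yy2 - yy1);
        cross.push_back(std::make_pair(xx, dir));
      }
      if (cross.empty()) continue;
      std::sort(cross.begin(), cross.end());
      int w = 0;
      size_t k = 0;
      for (int x = 0; x < W; ++x) {
        while (k < cross.size() && cross[k].first <= x + eps) {
          w += cross[k].second;
          ++k;
        }
        if (w != 0) mask(y, x) = 1;
      }
    }
    // boundary pass: mark pixel centres lying exactly on an edge
    for (int i = 0; i < n; ++i) {
      const double x1 = P(i, 0), yy1 = P(i, 1);
      const double x2 = P((i + 1) % n, 0), yy2 = P((i + 1) % n, 1);
      if (std::fabs(yy1 - yy2) < eps) {
        const double y = yy1;
        const double yr = std::floor(y + 0.5);
        if (std::fabs(y - yr) < eps && yr >= 0 && yr < H) {
          const int xa = std::max(0, (int)std::ceil(std::min(x1, x2) - eps));
          const int xb = std::min(W - 1, (int)std::floor(std::max(x1, x2) + eps));
          for (int x = xa; x <= xb; ++x) mask((int)yr, x) = 1;
        }
      } else {
        const int ya = std::max(0, (int)std::ceil(std::min(yy1, yy2) - eps));
        const int yb = std::min(H - 1, (int)std::floor(std::max(yy1, yy2) + eps));
        for (int y = ya; y <= yb; ++y) {
          const double t = (y - yy1) / (yy2 - yy1);
          if (t < -eps || t > 1 + eps) continue;
          const double xx = x1 + t * (x2 - x1);
          const double xr = std::floor(xx + 0.5);
          if (std::fabs(xx - xr) < eps && xr >= 0 && xr < W)
            mask(y, (int)xr) = 1;
        }
      }
    }
  }
  return mask;
}

// Outer boundary of the 4-connected foreground component containing the
// topmost-then-leftmost foreground pixel, walked along pixel cracks with
// the region kept on the right; vertices are pixel-corner coordinates
// (half-integers in pixel-centre space). Direction-change corners only.
// [[Rcpp::export]]
NumericMatrix cpp_trace_outer_boundary(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c) != 0) { sr = r; sc = c; break; }
  if (sr < 0) return NumericMatrix(0, 2);
  // directions: 0 = +x, 1 = +y, 2 = -x, 3 = -y
  static const double DX[4] = {1, 0, -1, 0};
  static const double DY[4] = {0, 1, 0, -1};
  auto fg = [&](double px, double py) -> bool {
    // pixel whose centre is (px, py)
    const int x = (int)std::lround(px), y = (int)std::lround(py);
    if (x < 0 || x >= W || y < 0 || y >= H) return false;
    return mask(y, x) != 0;
  };
  // start at the top-left corner of (sr, sc), moving +x along its top crack
  double x = sc - 0.5, y = sr - 0.5;
  int dir = 0;
  const double x0 = x, y0 = y;
  const int dir0 = dir;
  std::vector<double> vx, vy;
  vx.push_back(x);
  vy.push_back(y);
  int guard = 0, maxsteps = 8 * (H + 2) * (W + 2);
  do {
    // advance one crack
    x += DX[dir];
    y += DY[dir];
    // choose next direction at the corner (region on the right)
    const int right = (dir + 1) % 4, left = (dir + 3) % 4;
    const double arx = x + 0.5 * (DX[dir] + DX[right]);
    const double ary = y + 0.5 * (DY[dir] + DY[right]);
    const double alx = x + 0.5 * (DX[dir] + DX[left]);
    const double aly = y + 0.5 * (DY[dir] + DY[left]);
    int ndir;
    if (!fg(arx, ary)) ndir = right;       // convex corner / saddle: turn right
    else if (fg(alx, aly)) ndir = left;    // concave corner
    else ndir = dir;                       // straight edge
    if (ndir != dir) {
      vx.push_back(x);
      vy.push_back(y);
      dir = ndir;
    }
    if (++guard > maxsteps) stop("boundary trace failed to close");
  } while (!(x == x0 && y == y0 && dir == dir0));
  // last stored vertex duplicates the start; drop it if so
  int m = vx.size();
  if (m > 1 && vx[m - 1] == vx[0] && vy[m - 1] == vy[0]) m -= 1;
  NumericMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = vx[i]; out(i, 1) = vy[i]; }
  return out;
}
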