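// Compiled primitives for the generative worm tracker.
//
// Image coordinate convention (used everywhere): x right, y down, origin at
// the top-left pixel center; matrix element [i, j] (1-based in R) is the
// pixel with center (x = j-1, y = i-1). Angles are measured from +x toward
// +y.
//
// The per-posture search objective is evaluated hundreds of thousands of
// times per frame, so the core routines run on plain buffers; the exported
// functions are thin wrappers over the same code.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

namespace coil {

struct View {
  const int* data;  // column-major, as an R logical matrix
  int H, W;
  inline int at(int y, int x) const { return data[x * H + y]; }
};

// reusable scratch buffers (single-threaded R)
struct Scratch {
  std::vector<int> mask;
  std::vector<double> px, py, bx, by, s, gx, gy, ds, cs, qx, qy, psi;
  std::vector<long> cA, cB;
  std::vector<double> rev;
};
static Scratch S;

// ---- backbone -------------------------------------------------------------

static void backbone_points(const double* theta, int n, double arcLen,
                            std::vector<double>& px,
                            std::vector<double>& py) {
  const double seg = arcLen / (n - 1);
  px.resize(n);
  py.resize(n);
  px[0] = 0.0;
  py[0] = 0.0;
  for (int k = 1; k < n; ++k) {
    // segment k uses the mean of its endpoint angles (reversal-exact rule)
    const double a = 0.5 * (theta[k - 1] + theta[k]);
    px[k] = px[k - 1] + seg * std::cos(a);
    py[k] = py[k - 1] + seg * std::sin(a);
  }
}

// ---- rendering ------------------------------------------------------------

template <class Img>
static void stamp_discs(Img& set, int H, int W, const std::vector<double>& px,
                        const std::vector<double>& py, const double* radii,
                        int n) {
  for (int k = 0; k < n; ++k) {
    const double r = radii[k], r2 = r * r;
    const int x0 = std::max(0, (int)std::ceil(px[k] - r));
    const int x1 = std::min(W - 1, (int)std::floor(px[k] + r));
    const int y0 = std::max(0, (int)std::ceil(py[k] - r));
    const int y1 = std::min(H - 1, (int)std::floor(py[k] + r));
    for (int x = x0; x <= x1; ++x) {
      const double dx = x - px[k];
      for (int y = y0; y <= y1; ++y) {
        const double dy = y - py[k];
        if (dx * dx + dy * dy <= r2) set(y, x);
      }
    }
  }
}

// center the backbone on the canvas; returns false if the shape overflows
static bool place_backbone(std::vector<double>& px, std::vector<double>& py,
                           const double* radii, int n, int H, int W,
                           bool center, double ax, double ay) {
  if (center) {
    double mx = 0.0, my = 0.0;
    for (int k = 0; k < n; ++k) { mx += px[k]; my += py[k]; }
    mx /= n;
    my /= n;
    const double dx = (W - 1) / 2.0 - mx, dy = (H - 1) / 2.0 - my;
    for (int k = 0; k < n; ++k) { px[k] += dx; py[k] += dy; }
  } else {
    for (int k = 0; k < n; ++k) { px[k] += ax; py[k] += ay; }
  }
  for (int k = 0; k < n; ++k) {
    if (px[k] - radii[k] < -0.5 || px[k] + radii[k] > W - 0.5 ||
        py[k] - radii[k] < -0.5 || py[k] + radii[k] > H - 0.5)
      return false;
  }
  return true;
}

// ---- boundary tracing and the outline signature ---------------------------

// Moore-neighbour tracing of the outer boundary from the topmost-leftmost
// foreground pixel; returns false when there is no foreground
template <class At>
static bool trace_boundary(At img, int H, int W, std::vector<double>& bx,
                           std::vector<double>& by) {
  int sy = -1, sx = -1;
  for (int y = 0; y < H && sy < 0; ++y)
    for (int x = 0; x < W; ++x)
      if (img(y, x)) { sy = y; sx = x; break; }
  if (sy < 0) return false;

  const int nx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int ny[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  auto fg = [&](int y, int x) {
    return x >= 0 && x < W && y >= 0 && y < H && img(y, x);
  };
  bx.clear();
  by.clear();
  int cy = sy, cx = sx;
  int backtrack = 0;  // entered from the west (background by construction)
  const long maxSteps = 8L * (long)H * W;
  long steps = 0;
  int firstDir = -1;
  while (true) {
    bx.push_back((double)cx);
    by.push_back((double)cy);
    int d = backtrack, found = -1;
    for (int t = 0; t < 8; ++t) {
      d = (d + 1) % 8;
      if (fg(cy + ny[d], cx + nx[d])) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    if ((int)bx.size() == 1) firstDir = found;
    const int prev = (found + 7) % 8;             // last background checked
    const int bx2 = cx + nx[prev], by2 = cy + ny[prev];
    cx += nx[found];
    cy += ny[found];
    backtrack = (found + 4) % 8;
    for (int t = 0; t < 8; ++t)
      if (cx + nx[t] == bx2 && cy + ny[t] == by2) { backtrack = t; break; }
    if (cx == sx && cy == sy) {
      int d2 = backtrack, nextDir = -1;
      for (int t = 0; t < 8; ++t) {
        d2 = (d2 + 1) % 8;
        if (fg(cy + ny[d2], cx + nx[d2])) { nextDir = d2; break; }
      }
      if (nextDir == firstDir || nextDir < 0) break;
    }
    if (++steps > maxSteps) break;
  }
  return true;
}

// equal-arc outline signature; returns the number of boundary pixels, or -1
// on failure. psi receives nseg cyclic turning angles; qx/qy the resampled
// points; perim the smoothed perimeter.
template <class At>
static int outline_signature(At img, int H, int W, int nseg, double sigma,
                             std::vector<double>& psi, double& perim,
                             std::vector<double>& qx,
                             std::vector<double>& qy) {
  if (!trace_boundary(img, H, W, S.bx, S.by)) return -1;
  const int nb = (int)S.bx.size();
  if (nb < 8) return nb;

  std::vector<double>& s = S.s;
  s.resize(nb + 1);
  s[0] = 0.0;
  for (int i = 1; i <= nb; ++i) {
    const double dx = S.bx[i % nb] - S.bx[i - 1];
    const double dy = S.by[i % nb] - S.by[i - 1];
    s[i] = s[i - 1] + std::sqrt(dx * dx + dy * dy);
  }
  const double Stot = s[nb];

  // periodic Gaussian smoothing in arc length; each point carries its local
  // arc-length measure so uneven pixel spacing does not bias the kernel
  std::vector<double>& gx = S.gx;
  std::vector<double>& gy = S.gy;
  std::vector<double>& ds = S.ds;
  gx.resize(nb);
  gy.resize(nb);
  ds.resize(nb);
  for (int j = 0; j < nb; ++j) {
    const double prev = s[j] - s[(j - 1 + nb) % nb] + (j == 0 ? Stot : 0.0);
    ds[j] = 0.5 * (prev + (s[j + 1] - s[j]));
  }
  const int halfw = std::min(nb / 2, (int)std::ceil(3.0 * sigma) + 2);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int i = 0; i < nb; ++i) {
    double wsum = 0.0, xs = 0.0, ys = 0.0;
    for (int o = -halfw; o <= halfw; ++o) {
      const int j = ((i + o) % nb + nb) % nb;
      double d = s[j] - s[i];
      if (d > Stot / 2) d -= Stot;
      if (d < -Stot / 2) d += Stot;
      const double w = ds[j] * std::exp(-d * d * inv2s2);
      wsum += w;
      xs += w * S.bx[j];
      ys += w * S.by[j];
    }
    gx[i] = xs / wsum;
    gy[i] = ys / wsum;
  }

  std::vector<double>& cs = S.cs;
  cs.resize(nb + 1);
  cs[0] = 0.0;
  for (int i = 1; i <= nb; ++i) {
    const double dx = gx[i % nb] - gx[i - 1], dy = gy[i % nb] - gy[i - 1];
    cs[i] = cs[i - 1] + std::sqrt(dx * dx + dy * dy);
  }
  perim = cs[nb];
  if (perim <= 0) return -1;

  // equal-arc resampling into nseg segments of the closed curve
  std::vector<double>& rx = S.qx;
  std::vector<double>& ry = S.qy;
  rx.resize(nseg);
  ry.resize(nseg);
  int seg = 0;
  for (int k = 0; k < nseg; ++k) {
    const double target = perim * k / nseg;
    while (seg < nb && cs[seg + 1] < target) ++seg;
    const double den = cs[seg + 1] - cs[seg];
    const double t = den > 0 ? (target - cs[seg]) / den : 0.0;
    rx[k] = gx[seg] + t * (gx[(seg + 1) % nb] - gx[seg]);
    ry[k] = gy[seg] + t * (gy[(seg + 1) % nb] - gy[seg]);
  }

  // distribute the residual per-vertex turning: short periodic Gaussian on
  // the (uniformly spaced) resampled points
  qx.resize(nseg);
  qy.resize(nseg);
  {
    const int hw = 6;
    static double kern[2 * 6 + 1];
    static bool init = false;
    if (!init) {
      for (int o = -hw; o <= hw; ++o)
        kern[o + hw] = std::exp(-(double)(o * o) / 8.0);
      init = true;
    }
    for (int k = 0; k < nseg; ++k) {
      double wsum = 0.0, xs = 0.0, ys = 0.0;
      for (int o = -hw; o <= hw; ++o) {
        const int j = ((k + o) % nseg + nseg) % nseg;
        const double w = kern[o + hw];
        wsum += w;
        xs += w * rx[j];
        ys += w * ry[j];
      }
      qx[k] = xs / wsum;
      qy[k] = ys / wsum;
    }
  }

  psi.resize(nseg);
  for (int k = 0; k < nseg; ++k) {
    const int km = (k - 1 + nseg) % nseg, kp = (k + 1) % nseg;
    const double v1x = qx[k] - qx[km], v1y = qy[k] - qy[km];
    const double v2x = qx[kp] - qx[k], v2y = qy[kp] - qy[k];
    psi[k] = std::atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y);
  }
  return nb;
}

// min over cyclic offsets and both directions of the summed squared angle
// difference
static double f_outline_core(const double* p1, const double* p2, int n,
                             double len1, double len2, double C0,
                             double C1) {
  double best = std::numeric_limits<double>::infinity();
  std::vector<double>& b = S.rev;
  b.resize(n);
  for (int dir = 0; dir < 2; ++dir) {
    if (dir == 0) {
      std::memcpy(b.data(), p2, n * sizeof(double));
    } else {
      for (int k = 0; k < n; ++k) b[k] = -p2[(n - k) % n];
    }
    for (int o = 0; o < n; ++o) {
      double ss = 0.0;
      int j = o;
      for (int k = 0; k < n; ++k) {
        const double d = p1[k] - b[j];
        ss += d * d;
        if (++j == n) j = 0;
      }
      if (ss < best) best = ss;
    }
  }
  const double dl = len1 - len2;
  return C0 * best + C1 * dl * dl;
}

// block-density error between two images given as accessors, with img2
// shifted by integer (dx, dy)
template <class A1, class A2>
static double f_pixel_core(A1 im1, int H1, int W1, A2 im2, int H2, int W2,
                           double c1x, double c1y, double c2x, double c2y,
                           int block) {
  const int dx = (int)std::round(c1x - c2x);
  const int dy = (int)std::round(c1y - c2y);
  int x0 = INT_MAX, x1 = INT_MIN, y0 = INT_MAX, y1 = INT_MIN;
  for (int x = 0; x < W1; ++x)
    for (int y = 0; y < H1; ++y)
      if (im1(y, x)) {
        if (x < x0) x0 = x;
        if (x > x1) x1 = x;
        if (y < y0) y0 = y;
        if (y > y1) y1 = y;
      }
  for (int x = 0; x < W2; ++x)
    for (int y = 0; y < H2; ++y)
      if (im2(y, x)) {
        if (x + dx < x0) x0 = x + dx;
        if (x + dx > x1) x1 = x + dx;
        if (y + dy < y0) y0 = y + dy;
        if (y + dy > y1) y1 = y + dy;
      }
  const int nbx = (x1 - x0) / block + 1;
  const int nby = (y1 - y0) / block + 1;
  S.cA.assign(nbx * nby, 0);
  S.cB.assign(nbx * nby, 0);
  for (int x = 0; x < W1; ++x)
    for (int y = 0; y < H1; ++y)
      if (im1(y, x)) ++S.cA[((y - y0) / block) * nbx + (x - x0) / block];
  for (int x = 0; x < W2; ++x)
    for (int y = 0; y < H2; ++y)
      if (im2(y, x))
        ++S.cB[((y + dy - y0) / block) * nbx + (x + dx - x0) / block];
  const double area = (double)block * block;
  double ss = 0.0;
  for (size_t i = 0; i < S.cA.size(); ++i) {
    const double d = (S.cA[i] - S.cB[i]) / area;
    ss += d * d;
  }
  return ss / (nbx * nby);
}

template <class At>
static void centroid_core(At img, int H, int W, double& cx, double& cy,
                          long& cnt) {
  cx = cy = 0.0;
  cnt = 0;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (img(y, x)) { cx += x; cy += y; ++cnt; }
  if (cnt) { cx /= cnt; cy /= cnt; }
}

}  // namespace coil

// ---------------------------------------------------------------------------
// Exported wrappers
// ---------------------------------------------------------------------------

// Render a worm given the full tangent-angle vector (orientation included).
// center = true translates the backbone centroid to the canvas center;
// otherwise backbone point 1 goes to (ax, ay).
// [[Rcpp::export]]
List cpp_render(NumericVector theta, double arcLen, NumericVector radii,
                int H, int W, bool center, double ax, double ay,
                bool errorOnOverflow = true) {
  const int n = theta.size();
  std::vector<double> px, py;
  coil::backbone_points(&theta[0], n, arcLen, px, py);
  if (!coil::place_backbone(px, py, &radii[0], n, H, W, center, ax, ay)) {
    if (errorOnOverflow) {
      double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf,
             ymax = R_NegInf;
      for (int k = 0; k < n; ++k) {
        xmin = std::min(xmin, px[k] - radii[k]);
        xmax = std::max(xmax, px[k] + radii[k]);
        ymin = std::min(ymin, py[k] - radii[k]);
        ymax = std::max(ymax, py[k] + radii[k]);
      }
      stop("rendered shape does not fit the canvas: need at least %d x %d "
           "(rows x cols), have %d x %d",
           (int)std::ceil(ymax - ymin) + 2, (int)std::ceil(xmax - xmin) + 2,
           H, W);
    }
    return List::create(_["mask"] = R_NilValue, _["points"] = R_NilValue);
  }
  LogicalMatrix img(H, W);
  int* data = LOGICAL(img);
  auto set = [&](int y, int x) { data[x * H + y] = 1; };
  coil::stamp_discs(set, H, W, px, py, &radii[0], n);
  NumericMatrix pts(n, 2);
  for (int k = 0; k < n; ++k) {
    pts(k, 0) = px[k];
    pts(k, 1) = py[k];
  }
  return List::create(_["mask"] = img, _["points"] = pts);
}

// Equal-arc outline signature: nseg cyclic turning angles + perimeter.
// [[Rcpp::export]]
List cpp_outline_signature(LogicalMatrix img, int nseg, double sigma) {
  coil::View v{LOGICAL(img), (int)img.nrow(), (int)img.ncol()};
  auto at = [&](int y, int x) { return v.at(y, x) != 0; };
  std::vector<double> psi, qx, qy;
  double perim = 0.0;
  const int nb =
      coil::outline_signature(at, v.H, v.W, nseg, sigma, psi, perim, qx, qy);
  if (nb < 0) stop("image has no foreground pixels");
  if (nb < 8) stop("degenerate shape: fewer than 8 boundary pixels");
  NumericMatrix q(nseg, 2);
  for (int k = 0; k < nseg; ++k) {
    q(k, 0) = qx[k];
    q(k, 1) = qy[k];
  }
  return List::create(_["psi"] = wrap(psi), _["perimeter"] = perim,
                      _["points"] = q, _["n_boundary"] = nb);
}

// [[Rcpp::export]]
double cpp_f_outline(NumericVector psi1, double len1, NumericVector psi2,
                     double len2, double C0, double C1) {
  const int n = psi1.size();
  if (psi2.size() != n) stop("signature lengths differ");
  return coil::f_outline_core(&psi1[0], &psi2[0], n, len1, len2, C0, C1);
}

// [[Rcpp::export]]
double cpp_f_pixel(LogicalMatrix img1, LogicalMatrix img2, int block) {
  coil::View v1{LOGICAL(img1), (int)img1.nrow(), (int)img1.ncol()};
  coil::View v2{LOGICAL(img2), (int)img2.nrow(), (int)img2.ncol()};
  auto a1 = [&](int y, int x) { return v1.at(y, x) != 0; };
  auto a2 = [&](int y, int x) { return v2.at(y, x) != 0; };
  double c1x, c1y, c2x, c2y;
  long n1, n2;
  coil::centroid_core(a1, v1.H, v1.W, c1x, c1y, n1);
  coil::centroid_core(a2, v2.H, v2.W, c2x, c2y, n2);
  if (n1 == 0 || n2 == 0) stop("empty image in f_pixel");
  return coil::f_pixel_core(a1, v1.H, v1.W, a2, v2.H, v2.W, c1x, c1y, c2x,
                            c2y, block);
}

// Full per-posture objective for the inverse search: f_err between the
// target frame and the render of p = (a1..a5, theta_mean); +Inf for
// curvature-infeasible or canvas-overflowing postures. basis is K x 100.
// [[Rcpp::export]]
double cpp_frame_objective(NumericVector p, NumericMatrix basis,
                           double arcLen, NumericVector radii, int H, int W,
                           NumericVector targetPsi, double targetLen,
                           LogicalMatrix targetImg, double C0, double C1,
                           int block, int nseg, double smoothSigma,
                           double curvLimit, int curvSep) {
  const int K = basis.nrow(), npts = basis.ncol();
  static std::vector<double> theta;
  theta.resize(npts);
  for (int j = 0; j < npts; ++j) {
    double v = p[K];
    for (int i = 0; i < K; ++i) v += p[i] * basis(i, j);
    theta[j] = v;
  }
  for (int j = 0; j + curvSep < npts; ++j)
    if (std::fabs(theta[j + curvSep] - theta[j]) > curvLimit)
      return R_PosInf;

  coil::backbone_points(theta.data(), npts, arcLen, coil::S.px, coil::S.py);
  if (!coil::place_backbone(coil::S.px, coil::S.py, &radii[0], npts, H, W,
                            true, 0, 0))
    return R_PosInf;

  // render into a reusable buffer; track the touched bounding box so only
  // that region is cleared next time
  static std::vector<int> mask;
  static int mH = 0, mW = 0;
  if (mH != H || mW != W) {
    mask.assign((size_t)H * W, 0);
    mH = H;
    mW = W;
  } else {
    std::fill(mask.begin(), mask.end(), 0);
  }
  auto set = [&](int y, int x) { mask[(size_t)x * H + y] = 1; };
  coil::stamp_discs(set, H, W, coil::S.px, coil::S.py, &radii[0], npts);
  auto at = [&](int y, int x) { return mask[(size_t)x * H + y] != 0; };

  static std::vector<double> psi, qx, qy;
  double perim = 0.0;
  const int nb =
      coil::outline_signature(at, H, W, nseg, smoothSigma, psi, perim, qx, qy);
  if (nb < 8) return R_PosInf;
  const double fo = coil::f_outline_core(&targetPsi[0], psi.data(), nseg,
                                         targetLen, perim, C0, C1);

  coil::View vt{LOGICAL(targetImg), (int)targetImg.nrow(),
                (int)targetImg.ncol()};
  auto att = [&](int y, int x) { return vt.at(y, x) != 0; };
  double c1x, c1y, c2x, c2y;
  long n1, n2;
  coil::centroid_core(att, vt.H, vt.W, c1x, c1y, n1);
  coil::centroid_core(at, H, W, c2x, c2y, n2);
  if (n1 == 0 || n2 == 0) return R_PosInf;
  const double fp = coil::f_pixel_core(att, vt.H, vt.W, at, H, W, c1x, c1y,
                                       c2x, c2y, block);
  return fo * fp;
}

// Count foreground components under 8-connectivity (rendered worms may
// touch only diagonally at the thin tapered tips).
// [[Rcpp::export]]
int cpp_component_count(LogicalMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<char> seen((size_t)H * W, 0);
  const int nx[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int ny[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int comps = 0;
  std::vector<int> stack;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (!img(y, x) || seen[(size_t)x * H + y]) continue;
      ++comps;
      stack.clear();
      stack.push_back(x * H + y);
      seen[(size_t)x * H + y] = 1;
      while (!stack.empty()) {
        const int id = stack.back();
        stack.pop_back();
        const int cx = id / H, cy = id % H;
        for (int t = 0; t < 8; ++t) {
          const int qx = cx + nx[t], qy = cy + ny[t];
          if (qx < 0 || qy < 0 || qx >= W || qy >= H) continue;
          if (img(qy, qx) && !seen[(size_t)qx * H + qy]) {
            seen[(size_t)qx * H + qy] = 1;
            stack.push_back(qx * H + qy);
          }
        }
      }
    }
  return comps;
}

// ---------------------------------------------------------------------------
// Skeletonization (Zhang-Suen) and skeleton utilities
// ---------------------------------------------------------------------------

static inline int nbval(const LogicalMatrix& m, int y, int x) {
  if (y < 0 || x < 0 || y >= m.nrow() || x >= m.ncol()) return 0;
  return m(y, x) ? 1 : 0;
}

// [[Rcpp::export]]
LogicalMatrix cpp_skeletonize(LogicalMatrix input) {
  LogicalMatrix img = clone(input);
  const int H = img.nrow(), W = img.ncol();
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int y = 0; y < H; ++y) {
        for (int x = 0; x < W; ++x) {
          if (!img(y, x)) continue;
          const int p2 = nbval(img, y - 1, x), p3 = nbval(img, y - 1, x + 1);
          const int p4 = nbval(img, y, x + 1), p5 = nbval(img, y + 1, x + 1);
          const int p6 = nbval(img, y + 1, x), p7 = nbval(img, y + 1, x - 1);
          const int p8 = nbval(img, y, x - 1), p9 = nbval(img, y - 1, x - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int t = 0; t < 8; ++t)
            if (seq[t] == 0 && seq[t + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({y, x});
        }
      }
      for (auto& k : kill) img(k.first, k.second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}

// number of distinct skeleton arms meeting at a pixel (crossing number)
static int arm_count(const LogicalMatrix& m, int y, int x) {
  const int nx[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int ny[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int a = 0;
  for (int t = 0; t < 8; ++t) {
    const int v0 = nbval(m, y + ny[t], x + nx[t]);
    const int v1 = nbval(m, y + ny[(t + 1) % 8], x + nx[(t + 1) % 8]);
    if (v0 == 0 && v1 == 1) ++a;
  }
  return a;
}

// Remove endpoint spurs shorter than minLen pixels; repeat until stable.
// [[Rcpp::export]]
LogicalMatrix cpp_prune_spurs(LogicalMatrix input, int minLen) {
  LogicalMatrix img = clone(input);
  const int H = img.nrow(), W = img.ncol();
  const int nx[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int ny[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        if (!img(y, x) || arm_count(img, y, x) != 1) continue;
        std::vector<std::pair<int, int>> chain;
        int cy = y, cx = x, py = -1, px = -1;
        bool hitBranch = false;
        while ((int)chain.size() <= minLen) {
          chain.push_back({cy, cx});
          if (arm_count(img, cy, cx) >= 3) { hitBranch = true; break; }
          int ty = -1, tx = -1, nnb = 0;
          for (int t = 0; t < 8; ++t) {
            const int qy = cy + ny[t], qx = cx + nx[t];
            if (qy == py && qx == px) continue;
            if (nbval(img, qy, qx)) { ty = qy; tx = qx; ++nnb; }
          }
          if (nnb != 1) break;
          py = cy; px = cx; cy = ty; cx = tx;
        }
        if (hitBranch && (int)chain.size() - 1 < minLen) {
          for (size_t i = 0; i + 1 < chain.size(); ++i)
            img(chain[i].first, chain[i].second) = false;
          changed = true;
        }
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
List cpp_skeleton_info(LogicalMatrix skel) {
  std::vector<int> ex, ey, bxv, byv;
  for (int y = 0; y < skel.nrow(); ++y)
    for (int x = 0; x < skel.ncol(); ++x) {
      if (!skel(y, x)) continue;
      const int a = arm_count(skel, y, x);
      if (a == 1) { ex.push_back(x); ey.push_back(y); }
      if (a >= 3) { bxv.push_back(x); byv.push_back(y); }
    }
  return List::create(_["endpoints_x"] = wrap(ex), _["endpoints_y"] = wrap(ey),
                      _["branch_x"] = wrap(bxv), _["branch_y"] = wrap(byv));
}

// Longest geodesic endpoint-to-endpoint path on a skeleton; ordered (x, y)
// pixel coordinates, or an empty matrix for degenerate skeletons.
// [[Rcpp::export]]
NumericMatrix cpp_longest_path(LogicalMatrix skel) {
  const int H = skel.nrow(), W = skel.ncol();
  const int nx[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int ny[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> ex, ey;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (skel(y, x) && arm_count(skel, y, x) == 1) {
        ex.push_back(x);
        ey.push_back(y);
      }
  if (ex.size() < 2) return NumericMatrix(0, 2);

  auto dijkstra = [&](int sx, int sy, std::vector<double>& dist,
                      std::vector<int>& prev) {
    dist.assign((size_t)H * W, std::numeric_limits<double>::infinity());
    prev.assign((size_t)H * W, -1);
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> q;
    dist[sy * W + sx] = 0.0;
    q.push({0.0, sy * W + sx});
    while (!q.empty()) {
      const QE top = q.top();
      q.pop();
      const int id = top.second;
      if (top.first > dist[id]) continue;
      const int cy = id / W, cx = id % W;
      for (int t = 0; t < 8; ++t) {
        const int qy = cy + ny[t], qx = cx + nx[t];
        if (qy < 0 || qx < 0 || qy >= H || qx >= W || !skel(qy, qx)) continue;
        const double w = (nx[t] == 0 || ny[t] == 0) ? 1.0 : M_SQRT2;
        if (dist[id] + w < dist[qy * W + qx]) {
          dist[qy * W + qx] = dist[id] + w;
          prev[qy * W + qx] = id;
          q.push({dist[qy * W + qx], qy * W + qx});
        }
      }
    }
  };

  double best = -1.0;
  int bi = 0, bj = 0;
  std::vector<double> dist;
  std::vector<int> prev;
  for (size_t i = 0; i < ex.size(); ++i) {
    dijkstra(ex[i], ey[i], dist, prev);
    for (size_t j = 0; j < ex.size(); ++j) {
      const double d = dist[ey[j] * W + ex[j]];
      if (std::isfinite(d) && d > best) {
        best = d;
        bi = i;
        bj = j;
      }
    }
  }
  if (best <= 0) return NumericMatrix(0, 2);
  dijkstra(ex[bi], ey[bi], dist, prev);
  std::vector<int> path;
  for (int id = ey[bj] * W + ex[bj]; id >= 0; id = prev[id])
    path.push_back(id);
  NumericMatrix out(path.size(), 2);
  for (size_t k = 0; k < path.size(); ++k) {
    const int id = path[path.size() - 1 - k];
    out(k, 0) = id % W;
    out(k, 1) = id / W;
  }
  return out;
}
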