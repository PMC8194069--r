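// Dense optical flow (Farneback polynomial expansion), bilinear warping and
// separable Gaussian smoothing. Matrices are H x W (row = y, col = x);
// displacement fields (u, v) are in pixels along x (columns) and y (rows),
// mapping a target-frame pixel p to the corresponding source location p + d.
// Loops are ordered for column-major storage.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// quadratic-expansion coefficients of f ~ x'Ax + b'x + c under a Gaussian
// applicability of half-width nh
struct PolyExp {
  mat bx, by, axx, ayy, axy;
};

static PolyExp poly_expansion(const mat& img, int n, double sigma) {
  const int H = img.n_rows, W = img.n_cols;
  const int nh = n / 2;
  std::vector<double> w(2 * nh + 1);
  double a0 = 0, a2 = 0, a4 = 0;
  for (int i = -nh; i <= nh; ++i) {
    double g = std::exp(-(double)(i * i) / (2.0 * sigma * sigma));
    w[i + nh] = g;
    a0 += g; a2 += i * i * g; a4 += (double)i * i * i * i * g;
  }
  const double s0 = a0 * a0, s2 = a2 * a0, s4 = a4 * a0, s22 = a2 * a2;
  arma::mat33 G = {{s0, s2, s2}, {s2, s4, s22}, {s2, s22, s4}};
  arma::mat33 Gi = arma::inv(G);

  // pass 1: correlate along x with {w, i*w, i^2*w} (whole-column updates)
  mat t0(H, W, arma::fill::zeros), t1(H, W, arma::fill::zeros),
      t2(H, W, arma::fill::zeros);
  for (int x = 0; x < W; ++x) {
    for (int i = -nh; i <= nh; ++i) {
      const vec& c = img.col(clampi(x + i, 0, W - 1));
      double g = w[i + nh];
      t0.col(x) += g * c;
      t1.col(x) += (g * i) * c;
      t2.col(x) += (g * i * i) * c;
    }
  }
  // pass 2: correlate along y inside each column (contiguous memory)
  PolyExp pe;
  pe.bx.set_size(H, W); pe.by.set_size(H, W);
  pe.axx.set_size(H, W); pe.ayy.set_size(H, W); pe.axy.set_size(H, W);
  for (int x = 0; x < W; ++x) {
    const double* p0 = t0.colptr(x);
    const double* p1 = t1.colptr(x);
    const double* p2 = t2.colptr(x);
    double* obx = pe.bx.colptr(x);
    double* oby = pe.by.colptr(x);
    double* oxx = pe.axx.colptr(x);
    double* oyy = pe.ayy.colptr(x);
    double* oxy = pe.axy.colptr(x);
    for (int y = 0; y < H; ++y) {
      double m00 = 0, m01 = 0, m02 = 0, m10 = 0, m11 = 0, m20 = 0;
      for (int j = -nh; j <= nh; ++j) {
        int yy = clampi(y + j, 0, H - 1);
        double g = w[j + nh];
        m00 += g * p0[yy];
        m01 += g * j * p0[yy];
        m02 += g * j * j * p0[yy];
        m10 += g * p1[yy];
        m11 += g * j * p1[yy];
        m20 += g * p2[yy];
      }
      obx[y] = m10 / s2;
      oby[y] = m01 / s2;
      oxy[y] = 0.5 * m11 / s22;
      oxx[y] = Gi(1, 0) * m00 + Gi(1, 1) * m20 + Gi(1, 2) * m02;
      oyy[y] = Gi(2, 0) * m00 + Gi(2, 1) * m20 + Gi(2, 2) * m02;
    }
  }
  return pe;
}

// normalized box filter (windowed mean, clamped edges); separable with a
// running column-vector sum along x and a running scalar sum along y
static void box_blur(const mat& m, mat& out, mat& tmp, int radius) {
  const int H = m.n_rows, W = m.n_cols;
  if (radius <= 0) { out = m; return; }
  tmp.set_size(H, W); out.set_size(H, W);
  vec run(H, arma::fill::zeros);
  int cnt = 0;
  for (int x = 0; x <= std::min(radius, W - 1); ++x) { run += m.col(x); ++cnt; }
  tmp.col(0) = run / cnt;
  for (int x = 1; x < W; ++x) {
    int add = x + radius, rem = x - radius - 1;
    if (add < W) { run += m.col(add); ++cnt; }
    if (rem >= 0) { run -= m.col(rem); --cnt; }
    tmp.col(x) = run / cnt;
  }
  for (int x = 0; x < W; ++x) {
    const double* src = tmp.colptr(x);
    double* dst = out.colptr(x);
    double s = 0; int c = 0;
    for (int y = 0; y <= std::min(radius, H - 1); ++y) { s += src[y]; ++c; }
    dst[0] = s / c;
    for (int y = 1; y < H; ++y) {
      int add = y + radius, rem = y - radius - 1;
      if (add < H) { s += src[add]; ++c; }
      if (rem >= 0) { s -= src[rem]; --c; }
      dst[y] = s / c;
    }
  }
}

static void sep_gauss(const mat& m, mat& out, double sigma) {
  if (sigma <= 0) { out = m; return; }
  const int H = m.n_rows, W = m.n_cols;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-i * i / (2.0 * sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  mat tmp(H, W, arma::fill::zeros);
  for (int x = 0; x < W; ++x)
    for (int i = -r; i <= r; ++i)
      tmp.col(x) += k[i + r] * m.col(clampi(x + i, 0, W - 1));
  out.set_size(H, W);
  for (int x = 0; x < W; ++x) {
    const double* src = tmp.colptr(x);
    double* dst = out.colptr(x);
    for (int y = 0; y < H; ++y) {
      double a = 0;
      for (int i = -r; i <= r; ++i) a += k[i + r] * src[clampi(y + i, 0, H - 1)];
      dst[y] = a;
    }
  }
}

// center-aligned bilinear resize with replicate borders
static mat resize_bilinear(const mat& m, int H2, int W2) {
  const int H = m.n_rows, W = m.n_cols;
  mat out(H2, W2);
  std::vector<int> ry0(H2), ry1(H2);
  std::vector<double> rwy(H2);
  for (int y = 0; y < H2; ++y) {
    double fy = (y + 0.5) * (double)H / H2 - 0.5;
    int y0 = (int)std::floor(fy);
    rwy[y] = fy - y0;
    ry0[y] = clampi(y0, 0, H - 1);
    ry1[y] = clampi(y0 + 1, 0, H - 1);
  }
  for (int x = 0; x < W2; ++x) {
    double fx = (x + 0.5) * (double)W / W2 - 0.5;
    int x0 = (int)std::floor(fx);
    double wx = fx - x0;
    int x0c = clampi(x0, 0, W - 1), x1c = clampi(x0 + 1, 0, W - 1);
    const double* c0 = m.colptr(x0c);
    const double* c1 = m.colptr(x1c);
    double* dst = out.colptr(x);
    for (int y = 0; y < H2; ++y) {
      double top = (1 - wx) * c0[ry0[y]] + wx * c1[ry0[y]];
      double bot = (1 - wx) * c0[ry1[y]] + wx * c1[ry1[y]];
      dst[y] = (1 - rwy[y]) * top + rwy[y] * bot;
    }
  }
  return out;
}

// one displacement update: averaged expansion coefficients around the
// current estimate, windowed normal equations, per-pixel 2x2 solve
static void flow_update(const PolyExp& p1, const PolyExp& p2,
                        mat& u, mat& v, int win_radius, mat* ws) {
  const int H = u.n_rows, W = u.n_cols;
  mat& g11 = ws[0]; mat& g12 = ws[1]; mat& g22 = ws[2];
  mat& h1 = ws[3]; mat& h2 = ws[4];
  g11.set_size(H, W); g12.set_size(H, W); g22.set_size(H, W);
  h1.set_size(H, W); h2.set_size(H, W);
  for (int x = 0; x < W; ++x) {
    const double* uc = u.colptr(x);
    const double* vc = v.colptr(x);
    for (int y = 0; y < H; ++y) {
      int x2 = clampi((int)std::lround(x + uc[y]), 0, W - 1);
      int y2 = clampi((int)std::lround(y + vc[y]), 0, H - 1);
      double dx = x2 - x, dy = y2 - y;
      double a11 = 0.5 * (p1.axx(y, x) + p2.axx(y2, x2));
      double a22 = 0.5 * (p1.ayy(y, x) + p2.ayy(y2, x2));
      double a12 = 0.5 * (p1.axy(y, x) + p2.axy(y2, x2));
      double db1 = -0.5 * (p2.bx(y2, x2) - p1.bx(y, x)) + a11 * dx + a12 * dy;
      double db2 = -0.5 * (p2.by(y2, x2) - p1.by(y, x)) + a12 * dx + a22 * dy;
      g11(y, x) = a11 * a11 + a12 * a12;
      g12(y, x) = a12 * (a11 + a22);
      g22(y, x) = a12 * a12 + a22 * a22;
      h1(y, x) = a11 * db1 + a12 * db2;
      h2(y, x) = a12 * db1 + a22 * db2;
    }
  }
  mat& tmp = ws[5]; mat& blur = ws[6];
  box_blur(g11, blur, tmp, win_radius); g11 = blur;
  box_blur(g12, blur, tmp, win_radius); g12 = blur;
  box_blur(g22, blur, tmp, win_radius); g22 = blur;
  box_blur(h1, blur, tmp, win_radius); h1 = blur;
  box_blur(h2, blur, tmp, win_radius); h2 = blur;
  const double diag = std::sqrt((double)H * H + (double)W * W);
  for (int x = 0; x < W; ++x) {
    double* uc = u.colptr(x);
    double* vc = v.colptr(x);
    const double* a = g11.colptr(x); const double* b = g12.colptr(x);
    const double* c = g22.colptr(x);
    const double* r1 = h1.colptr(x); const double* r2 = h2.colptr(x);
    for (int y = 0; y < H; ++y) {
      double det = a[y] * c[y] - b[y] * b[y];
      double uu, vv;
      if (std::abs(det) < 1e-12) { uu = uc[y]; vv = vc[y]; }
      else {
        uu = (c[y] * r1[y] - b[y] * r2[y]) / det;
        vv = (a[y] * r2[y] - b[y] * r1[y]) / det;
      }
      if (!std::isfinite(uu)) uu = 0;
      if (!std::isfinite(vv)) vv = 0;
      uc[y] = (uu > diag ? diag : (uu < -diag ? -diag : uu));
      vc[y] = (vv > diag ? diag : (vv < -diag ? -diag : vv));
    }
  }
}

struct Pyramid {
  std::vector<mat> img;
  std::vector<PolyExp> pe;
  std::vector<int> hs, ws;
};

static Pyramid build_pyramid(const mat& frame, double pyr_scale, int levels,
                             int poly_n, double poly_sigma) {
  Pyramid P;
  P.hs.push_back(frame.n_rows); P.ws.push_back(frame.n_cols);
  P.img.push_back(frame);
  const double smooth_sigma = 0.5 / pyr_scale;
  for (int l = 1; l < levels; ++l) {
    int h2 = (int)std::lround(P.hs.back() * pyr_scale);
    int w2 = (int)std::lround(P.ws.back() * pyr_scale);
    if (std::min(h2, w2) < poly_n + 2) break;
    mat sm;
    sep_gauss(P.img.back(), sm, smooth_sigma);
    P.img.push_back(resize_bilinear(sm, h2, w2));
    P.hs.push_back(h2); P.ws.push_back(w2);
  }
  for (size_t l = 0; l < P.img.size(); ++l)
    P.pe.push_back(poly_expansion(P.img[l], poly_n, poly_sigma));
  return P;
}

static void flow_from_pyramids(const Pyramid& P1, const Pyramid& P2,
                               mat& u, mat& v, int winsize, int iterations) {
  const int L = P1.img.size();
  const int win_radius = std::max(1, winsize / 2);
  mat ws[7];
  for (int l = L - 1; l >= 0; --l) {
    if (l == L - 1) {
      u.zeros(P1.hs[l], P1.ws[l]); v.zeros(P1.hs[l], P1.ws[l]);
    } else {
      double rw = (double)P1.ws[l] / P1.ws[l + 1];
      double rh = (double)P1.hs[l] / P1.hs[l + 1];
      u = resize_bilinear(u, P1.hs[l], P1.ws[l]) * rw;
      v = resize_bilinear(v, P1.hs[l], P1.ws[l]) * rh;
    }
    for (int it = 0; it < iterations; ++it)
      flow_update(P1.pe[l], P2.pe[l], u, v, win_radius, ws);
  }
}

// [[Rcpp::export(name = ".fb_flow")]]
List fb_flow(const arma::mat& ref, const arma::mat& src,
             int winsize, double pyr_scale, int levels, int iterations,
             int poly_n, double poly_sigma) {
  if (ref.n_rows != src.n_rows || ref.n_cols != src.n_cols)
    stop("reference and source frames must share dimensions");
  Pyramid P1 = build_pyramid(ref, pyr_scale, levels, poly_n, poly_sigma);
  Pyramid P2 = build_pyramid(src, pyr_scale, levels, poly_n, poly_sigma);
  mat u, v;
  flow_from_pyramids(P1, P2, u, v, winsize, iterations);
  return List::create(Named("u") = u, Named("v") = v);
}

// flows from one reference frame to several source frames; the reference
// pyramid and its polynomial expansions are computed once
// [[Rcpp::export(name = ".fb_flow_batch")]]
List fb_flow_batch(const arma::mat& ref, const List& srcs,
                   int winsize, double pyr_scale, int levels, int iterations,
                   int poly_n, double poly_sigma) {
  Pyramid P1 = build_pyramid(ref, pyr_scale, levels, poly_n, poly_sigma);
  List out(srcs.size());
  for (int i = 0; i < srcs.size(); ++i) {
    mat src = as<mat>(srcs[i]);
    if (src.n_rows != ref.n_rows || src.n_cols != ref.n_cols)
      stop("reference and source frames must share dimensions");
    Pyramid P2 = build_pyramid(src, pyr_scale, levels, poly_n, poly_sigma);
    mat u, v;
    flow_from_pyramids(P1, P2, u, v, winsize, iterations);
    out[i] = List::create(Named("u") = u, Named("v") = v);
  }
  return out;
}

// backward warp: out(p) = h(p + d(p)), bilinear, out-of-grid taps contribute 0
// [[Rcpp::export(name = ".warp_cube")]]
arma::cube warp_cube(const arma::cube& h, const arma::mat& u, const arma::mat& v) {
  const int H = h.n_rows, W = h.n_cols, P = h.n_slices;
  if ((int)u.n_rows != H || (int)u.n_cols != W ||
      (int)v.n_rows != H || (int)v.n_cols != W)
    stop("flow field dimensions must match the heatmap grids");
  cube out(H, W, P, arma::fill::zeros);
  for (int x = 0; x < W; ++x) {
    const double* uc = u.colptr(x);
    const double* vc = v.colptr(x);
    for (int y = 0; y < H; ++y) {
      double fx = x + uc[y], fy = y + vc[y];
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
      double wx = fx - x0, wy = fy - y0;
      if (x0 < -1 || x0 >= W || y0 < -1 || y0 >= H) continue;
      bool in00 = x0 >= 0 && y0 >= 0;
      bool in01 = x0 + 1 < W && y0 >= 0;
      bool in10 = x0 >= 0 && y0 + 1 < H;
      bool in11 = x0 + 1 < W && y0 + 1 < H;
      double w00 = (1 - wx) * (1 - wy), w01 = wx * (1 - wy);
      double w10 = (1 - wx) * wy, w11 = wx * wy;
      for (int p = 0; p < P; ++p) {
        double a = 0;
        if (in00) a += w00 * h(y0, x0, p);
        if (in01) a += w01 * h(y0, x0 + 1, p);
        if (in10) a += w10 * h(y0 + 1, x0, p);
        if (in11) a += w11 * h(y0 + 1, x0 + 1, p);
        out(y, x, p) = a;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".gauss_smooth")]]
arma::mat gauss_smooth(const arma::mat& m, double sigma) {
  mat out;
  sep_gauss(m, out, sigma);
  return out;
}

// [[Rcpp::export(name = ".resize_bilinear")]]
arma::mat resize_bilinear_r(const arma::mat& m, int out_h, int out_w) {
  return resize_bilinear(m, out_h, out_w);
}
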