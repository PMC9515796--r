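// Low-level numerical kernels: 3D convolution (im2col + GEMM), separable
// box filtering for local-window SSIM, and surface-distance extraction for
// the 95th-percentile Hausdorff metric.
//
// Array layout convention (matches R column-major arrays):
//   volumes  (D, H, W)        index d + D*(h + H*w)
//   features (D, H, W, C)     index d + D*(h + H*(w + W*c))
//   weights  (kd, kh, kw, Cin, Cout)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix: rows index output voxels (d fastest), columns
// index (kd, kh, kw, cin) in the same order the weight array is laid out.
static arma::mat im2col3(const double* x, int D, int H, int W, int C,
                         int kd, int kh, int kw, int stride, int pad,
                         int Do, int Ho, int Wo) {
  const arma::uword M = (arma::uword)Do * Ho * Wo;
  arma::mat col(M, (arma::uword)kd * kh * kw * C, arma::fill::zeros);
  arma::uword k = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)D * H * W * c;
    for (int kwi = 0; kwi < kw; ++kwi)
      for (int khi = 0; khi < kh; ++khi)
        for (int kdi = 0; kdi < kd; ++kdi, ++k) {
          double* dst = col.colptr(k);
          for (int wo = 0; wo < Wo; ++wo) {
            int w = wo * stride - pad + kwi;
            if (w < 0 || w >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int h = ho * stride - pad + khi;
              if (h < 0 || h >= H) continue;
              const double* src = xc + (size_t)D * (h + (size_t)H * w);
              double* d0 = dst + (size_t)Do * (ho + (size_t)Ho * wo);
              for (int dmo = 0; dmo < Do; ++dmo) {
                int d = dmo * stride - pad + kdi;
                if (d < 0 || d >= D) continue;
                d0[dmo] = src[d];
              }
            }
          }
        }
  }
  return col;
}

// Scatter-add of an im2col-shaped gradient back onto the input grid.
static void col2im3(const arma::mat& col, double* dx, int D, int H, int W,
                    int C, int kd, int kh, int kw, int stride, int pad,
                    int Do, int Ho, int Wo) {
  arma::uword k = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)D * H * W * c;
    for (int kwi = 0; kwi < kw; ++kwi)
      for (int khi = 0; khi < kh; ++khi)
        for (int kdi = 0; kdi < kd; ++kdi, ++k) {
          const double* src0 = col.colptr(k);
          for (int wo = 0; wo < Wo; ++wo) {
            int w = wo * stride - pad + kwi;
            if (w < 0 || w >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int h = ho * stride - pad + khi;
              if (h < 0 || h >= H) continue;
              double* dstc = xc + (size_t)D * (h + (size_t)H * w);
              const double* s0 = src0 + (size_t)Do * (ho + (size_t)Ho * wo);
              for (int dmo = 0; dmo < Do; ++dmo) {
                int d = dmo * stride - pad + kdi;
                if (d < 0 || d >= D) continue;
                dstc[d] += s0[dmo];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, int stride, int pad) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int kd = wdim[0], kh = wdim[1], kw = wdim[2], Ci = wdim[3], Co = wdim[4];
  if (Ci != C) stop("conv3d: input channel mismatch");
  int Do = out_extent(D, kd, stride, pad);
  int Ho = out_extent(H, kh, stride, pad);
  int Wo = out_extent(W, kw, stride, pad);
  if (Do <= 0 || Ho <= 0 || Wo <= 0) stop("conv3d: kernel larger than input");
  arma::mat col = im2col3(x.begin(), D, H, W, C, kd, kh, kw, stride, pad,
                          Do, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()),
               (arma::uword)kd * kh * kw * Ci, Co, false, true);
  arma::mat Y = col * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Co, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector dy, int stride, int pad, bool need_dx) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int kd = wdim[0], kh = wdim[1], kw = wdim[2], Ci = wdim[3], Co = wdim[4];
  int Do = out_extent(D, kd, stride, pad);
  int Ho = out_extent(H, kh, stride, pad);
  int Wo = out_extent(W, kw, stride, pad);
  const arma::uword M = (arma::uword)Do * Ho * Wo;
  arma::mat dY(const_cast<double*>(dy.begin()), M, Co, false, true);
  arma::mat col = im2col3(x.begin(), D, H, W, C, kd, kh, kw, stride, pad,
                          Do, Ho, Wo);
  arma::mat dW = col.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wdim;
  NumericVector dbv(db.begin(), db.end());
  NumericVector dxv;
  if (need_dx) {
    arma::mat Wm(const_cast<double*>(w.begin()),
                 (arma::uword)kd * kh * kw * Ci, Co, false, true);
    arma::mat dcol = dY * Wm.t();
    dxv = NumericVector((size_t)D * H * W * C);
    col2im3(dcol, dxv.begin(), D, H, W, C, kd, kh, kw, stride, pad,
            Do, Ho, Wo);
    dxv.attr("dim") = xdim;
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// ---- separable sliding-window sums (valid positions) --------------------

// valid sliding sum along the first axis of a (N, rest) column-major block
static void slide_sum_axis0(const double* x, double* y, int N, size_t rest,
                            int win) {
  int No = N - win + 1;
  for (size_t r = 0; r < rest; ++r) {
    const double* xi = x + (size_t)N * r;
    double* yo = y + (size_t)No * r;
    double s = 0.0;
    for (int i = 0; i < win; ++i) s += xi[i];
    yo[0] = s;
    for (int i = 1; i < No; ++i) {
      s += xi[i + win - 1] - xi[i - 1];
      yo[i] = s;
    }
  }
}

// adjoint: scatter sliding sums back (length No -> N)
static void slide_sum_axis0_adj(const double* g, double* y, int N, size_t rest,
                                int win) {
  int No = N - win + 1;
  for (size_t r = 0; r < rest; ++r) {
    const double* gi = g + (size_t)No * r;
    double* yo = y + (size_t)N * r;
    // y[d] = sum of g[k] over k in [d-win+1, d] ∩ [0, No)
    double s = 0.0;
    for (int d = 0; d < N; ++d) {
      if (d < No) s += gi[d];
      if (d - win >= 0 && d - win < No) s -= gi[d - win];
      yo[d] = s;
    }
  }
}

// permute (A,B,C) -> (B,C,A): moves the leading axis to the back
static void rot_axes(const double* x, double* y, int A, int B, int C) {
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b) {
      const double* xi = x + (size_t)A * (b + (size_t)B * c);
      double* yo = y + (size_t)b + (size_t)B * c;
      size_t strideBC = (size_t)B * C;
      for (int a = 0; a < A; ++a) yo[(size_t)a * strideBC] = xi[a];
    }
}

// [[Rcpp::export]]
NumericVector cpp_boxfilter_valid(NumericVector x, IntegerVector xdim,
                                  int win) {
  int D = xdim[0], H = xdim[1], W = xdim[2];
  int Do = D - win + 1, Ho = H - win + 1, Wo = W - win + 1;
  if (Do <= 0 || Ho <= 0 || Wo <= 0) stop("box filter window larger than volume");
  std::vector<double> a((size_t)Do * H * W), b((size_t)H * W * Do),
      c((size_t)Ho * W * Do), d((size_t)W * Do * Ho), e((size_t)Wo * Do * Ho);
  slide_sum_axis0(x.begin(), a.data(), D, (size_t)H * W, win);
  rot_axes(a.data(), b.data(), Do, H, W);
  slide_sum_axis0(b.data(), c.data(), H, (size_t)W * Do, win);
  rot_axes(c.data(), d.data(), Ho, W, Do);
  slide_sum_axis0(d.data(), e.data(), W, (size_t)Do * Ho, win);
  NumericVector out((size_t)Do * Ho * Wo);
  rot_axes(e.data(), out.begin(), Wo, Do, Ho);
  double norm = 1.0 / ((double)win * win * win);
  for (auto& v : out) v *= norm;
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_boxfilter_adjoint(NumericVector g, IntegerVector xdim,
                                    int win) {
  int D = xdim[0], H = xdim[1], W = xdim[2];
  int Do = D - win + 1, Ho = H - win + 1, Wo = W - win + 1;
  if (Do <= 0 || Ho <= 0 || Wo <= 0) stop("box filter window larger than volume");
  // adjoint of (sumD -> sumH -> sumW) applied in reverse order
  std::vector<double> a((size_t)W * Do * Ho), b((size_t)Do * Ho * W),
      c((size_t)H * W * Do), d((size_t)Do * H * W);
  // g laid out (Do,Ho,Wo): bring Wo to front
  std::vector<double> gperm((size_t)Wo * Do * Ho);
  // inverse of rot_axes(e, out, Wo, Do, Ho): out (Do,Ho,Wo) -> e (Wo,Do,Ho)
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int dmo = 0; dmo < Do; ++dmo)
        gperm[(size_t)wo + (size_t)Wo * (dmo + (size_t)Do * ho)] =
            g[(size_t)dmo + (size_t)Do * (ho + (size_t)Ho * wo)];
  slide_sum_axis0_adj(gperm.data(), a.data(), W, (size_t)Do * Ho, win);
  // a is (W,Do,Ho); undo rot: want (Ho?,...) chain back to (Do,H?,...)
  // forward chain: d (W,Do,Ho) from rot of c2 (Ho,W,Do); adjoint permute back
  for (int ho = 0; ho < Ho; ++ho)
    for (int dmo = 0; dmo < Do; ++dmo)
      for (int w = 0; w < W; ++w)
        b[(size_t)ho + (size_t)Ho * (w + (size_t)W * dmo)] =
            a[(size_t)w + (size_t)W * (dmo + (size_t)Do * ho)];
  slide_sum_axis0_adj(b.data(), c.data(), H, (size_t)W * Do, win);
  // c is (H,W,Do) -> permute to (Do,H,W)
  for (int dmo = 0; dmo < Do; ++dmo)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        d[(size_t)dmo + (size_t)Do * (h + (size_t)H * w)] =
            c[(size_t)h + (size_t)H * (w + (size_t)W * dmo)];
  NumericVector out((size_t)D * H * W);
  slide_sum_axis0_adj(d.data(), out.begin(), D, (size_t)H * W, win);
  double norm = 1.0 / ((double)win * win * win);
  for (auto& v : out) v *= norm;
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}

// ---- surface distances for HD95 ----------------------------------------

static void surface_voxels(const int* m, int D, int H, int W,
                           std::vector<std::array<int, 3>>& out) {
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        size_t i = (size_t)d + (size_t)D * (h + (size_t)H * w);
        if (!m[i]) continue;
        bool surf = d == 0 || d == D - 1 || h == 0 || h == H - 1 || w == 0 ||
                    w == W - 1;
        if (!surf) {
          surf = !m[i - 1] || !m[i + 1] || !m[i - D] || !m[i + D] ||
                 !m[i - (size_t)D * H] || !m[i + (size_t)D * H];
        }
        if (surf) out.push_back({d, h, w});
      }
}

static std::vector<double> directed_dists(
    const std::vector<std::array<int, 3>>& A,
    const std::vector<std::array<int, 3>>& B, const double* sp) {
  std::vector<double> out(A.size());
  for (size_t i = 0; i < A.size(); ++i) {
    double best = R_PosInf;
    for (size_t j = 0; j < B.size(); ++j) {
      double dd = (A[i][0] - B[j][0]) * sp[0];
      double dh = (A[i][1] - B[j][1]) * sp[1];
      double dw = (A[i][2] - B[j][2]) * sp[2];
      double v = dd * dd + dh * dh + dw * dw;
      if (v < best) best = v;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_surface_dists(IntegerVector a, IntegerVector b, IntegerVector dims,
                       NumericVector spacing) {
  int D = dims[0], H = dims[1], W = dims[2];
  std::vector<std::array<int, 3>> sa, sb;
  surface_voxels(a.begin(), D, H, W, sa);
  surface_voxels(b.begin(), D, H, W, sb);
  std::vector<double> dab = directed_dists(sa, sb, spacing.begin());
  std::vector<double> dba = directed_dists(sb, sa, spacing.begin());
  return List::create(_["ab"] = NumericVector(dab.begin(), dab.end()),
                      _["ba"] = NumericVector(dba.begin(), dba.end()));
}
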