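// Training kernels for the reference encoder-decoder: 3x3 same-padding
// convolution (im2col + GEMM, batched across the mini-batch), 2x2 max-pooling,
// nearest-neighbour 2x upsampling and leaky ReLU, with analytic backward
// passes. Arrays follow the package layout (H, W, C, N), column-major as
// stored by R. Weights are (3, 3, Cin, Cout); row index of the im2col matrix
// is kh + 3*kw + 9*c, matching R's column-major flattening of the weights.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static NumericVector make4d(int H, int W, int C, int N) {
  NumericVector v((size_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

// convolution arithmetic runs in single precision (the standard working
// precision for this kind of training); inputs/outputs stay double on the R
// side, so all R-level logic remains double.

// fill rows [n*H*W, (n+1)*H*W) of col, one sample's zero-padded patches
static void im2col3(const float* x, int H, int W, int C, int n, arma::fmat& col) {
  size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const arma::fmat Xc(const_cast<float*>(x) + HW * c, H, W, false, true);
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        int q = (kh + 1) + 3 * (kw + 1) + 9 * c;
        arma::fmat Cq(col.colptr(q) + n * HW, H, W, false, true);
        int r0 = std::max(0, -kh), r1 = std::min(H, H - kh) - 1;
        int c0 = std::max(0, -kw), c1 = std::min(W, W - kw) - 1;
        Cq.zeros();
        if (r0 > r1 || c0 > c1) continue;
        Cq.submat(r0, c0, r1, c1) = Xc.submat(r0 + kh, c0 + kw, r1 + kh, c1 + kw);
      }
    }
  }
}

static arma::fvec to_f(const double* p, size_t n) {
  arma::fvec v(n);
  for (size_t i = 0; i < n; ++i) v[i] = (float)p[i];
  return v;
}

static void from_f(const arma::fmat& src, double* dst) {
  const float* s = src.memptr();
  for (size_t i = 0; i < src.n_elem; ++i) dst[i] = (double)s[i];
}

// [[Rcpp::export]]
NumericVector conv3x3_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Cout = dw[3];
  if (dw[2] != C) stop("conv3x3_fw: input has %d channels, weights expect %d", C, dw[2]);
  size_t HW = (size_t)H * W;
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fvec wf = to_f(w.begin(), w.size());
  arma::fmat Wm(wf.memptr(), 9 * C, Cout, false, true);
  arma::fvec bv = to_f(b.begin(), Cout);
  NumericVector y = make4d(H, W, Cout, N);
  arma::fmat col(HW * N, 9 * C);
  for (int n = 0; n < N; ++n) im2col3(xf.memptr() + HW * C * n, H, W, C, n, col);
  arma::fmat Y = col * Wm;
  Y.each_row() += bv.t();
  for (int n = 0; n < N; ++n) {
    arma::fmat Yn = Y.rows(n * HW, (n + 1) * HW - 1);
    from_f(Yn, y.begin() + HW * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Cout = dw[3];
  size_t HW = (size_t)H * W;
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fvec wf = to_f(w.begin(), w.size());
  arma::fmat Wm(wf.memptr(), 9 * C, Cout, false, true);

  NumericVector gx = make4d(H, W, C, N);
  NumericVector gw((size_t)9 * C * Cout);
  gw.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  NumericVector gb(Cout);

  arma::fmat col(HW * N, 9 * C);
  arma::fmat GY(HW * N, Cout);
  arma::fvec gyf = to_f(gy.begin(), gy.size());
  for (int n = 0; n < N; ++n) {
    im2col3(xf.memptr() + HW * C * n, H, W, C, n, col);
    GY.rows(n * HW, (n + 1) * HW - 1) =
      arma::fmat(gyf.memptr() + HW * Cout * n, HW, Cout, false, true);
  }
  arma::fmat GW = col.t() * GY;
  from_f(GW, gw.begin());
  arma::fvec GB = arma::sum(GY, 0).t();
  for (int i = 0; i < Cout; ++i) gb[i] = (double)GB[i];
  arma::fmat gcol = GY * Wm.t();

  arma::fmat gxf(HW * C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    float* gxn = gxf.colptr(n);
    for (int c = 0; c < C; ++c) {
      arma::fmat GXc(gxn + HW * c, H, W, false, true);
      for (int kw = -1; kw <= 1; ++kw) {
        for (int kh = -1; kh <= 1; ++kh) {
          int q = (kh + 1) + 3 * (kw + 1) + 9 * c;
          arma::fmat Gq(gcol.colptr(q) + n * HW, H, W, false, true);
          int r0 = std::max(0, -kh), r1 = std::min(H, H - kh) - 1;
          int c0 = std::max(0, -kw), c1 = std::min(W, W - kw) - 1;
          if (r0 > r1 || c0 > c1) continue;
          GXc.submat(r0 + kh, c0 + kw, r1 + kh, c1 + kw) += Gq.submat(r0, c0, r1, c1);
        }
      }
    }
  }
  from_f(gxf, gx.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector lrelu_fw(NumericVector x, double slope) {
  NumericVector y = clone(x);
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    if (p[i] < 0) p[i] *= slope;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector lrelu_bw_cpp(NumericVector x_pre, NumericVector g, double slope) {
  NumericVector out = clone(g);
  const double* xp = x_pre.begin();
  double* p = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    if (xp[i] < 0) p[i] *= slope;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector maxpool2_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4d(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* xs = xp + pl * H * W;
    double* ys = yp + pl * (size_t)Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double* c0 = xs + 2 * i + (size_t)(2 * j) * H;
        const double* c1 = c0 + H;
        double m = c0[0];
        if (c0[1] > m) m = c0[1];
        if (c1[0] > m) m = c1[0];
        if (c1[1] > m) m = c1[1];
        ys[i + (size_t)j * Ho] = m;
      }
    }
  }
  return y;
}

// route gradient to the first maximum in scan order (deterministic tie-break)
// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector x, NumericVector g) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector gx = make4d(H, W, C, N);
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* xs = xp + pl * H * W;
    const double* gs = gp + pl * (size_t)Ho * Wo;
    double* os = op + pl * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        size_t o0 = 2 * i + (size_t)(2 * j) * H;
        size_t o1 = o0 + H;
        double v0 = xs[o0], v1 = xs[o0 + 1], v2 = xs[o1], v3 = xs[o1 + 1];
        double m = v0;
        int am = 0;
        if (v1 > m) { m = v1; am = 1; }
        if (v2 > m) { m = v2; am = 2; }
        if (v3 > m) { m = v3; am = 3; }
        size_t dst = (am == 0) ? o0 : (am == 1) ? o0 + 1 : (am == 2) ? o1 : o1 + 1;
        os[dst] += gs[i + (size_t)j * Ho];
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4d(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* xs = xp + pl * (size_t)H * W;
    double* ys = yp + pl * (size_t)Ho * Wo;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double v = xs[i + (size_t)j * H];
        size_t o = 2 * i + (size_t)(2 * j) * Ho;
        ys[o] = v;
        ys[o + 1] = v;
        ys[o + Ho] = v;
        ys[o + Ho + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw_cpp(NumericVector g) {
  IntegerVector d = g.attr("dim");
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx = make4d(H, W, C, N);
  const double* gp = g.begin();
  double* op = gx.begin();
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* gs = gp + pl * (size_t)Ho * Wo;
    double* os = op + pl * (size_t)H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        size_t o = 2 * i + (size_t)(2 * j) * Ho;
        os[i + (size_t)j * H] = gs[o] + gs[o + 1] + gs[o + Ho] + gs[o + Ho + 1];
      }
    }
  }
  return gx;
}

// forward that also returns the im2col matrix for reuse in the backward pass
// [[Rcpp::export]]
List conv3x3_fw_cache(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Cout = dw[3];
  if (dw[2] != C) stop("conv3x3_fw_cache: input has %d channels, weights expect %d", C, dw[2]);
  size_t HW = (size_t)H * W;
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fvec wf = to_f(w.begin(), w.size());
  arma::fmat Wm(wf.memptr(), 9 * C, Cout, false, true);
  arma::fvec bv = to_f(b.begin(), Cout);
  XPtr<arma::fmat> colP(new arma::fmat(HW * N, 9 * C), true);
  arma::fmat& col = *colP;
  for (int n = 0; n < N; ++n) im2col3(xf.memptr() + HW * C * n, H, W, C, n, col);
  NumericVector y = make4d(H, W, Cout, N);
  arma::fmat Y = col * Wm;
  Y.each_row() += bv.t();
  for (int n = 0; n < N; ++n) {
    arma::fmat Yn = Y.rows(n * HW, (n + 1) * HW - 1);
    from_f(Yn, y.begin() + HW * Cout * n);
  }
  return List::create(_["y"] = y, _["col"] = colP);
}

// backward from a cached im2col matrix; gx computed only when requested
// [[Rcpp::export]]
List conv3x3_bw_col(SEXP colS, NumericVector w, NumericVector gy,
                    bool need_gx) {
  XPtr<arma::fmat> colP(colS);
  arma::fmat& col = *colP;
  IntegerVector dg = gy.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dg[0], W = dg[1], Cout = dg[2], N = dg[3];
  int C = dw[2];
  size_t HW = (size_t)H * W;
  arma::fvec wf = to_f(w.begin(), w.size());
  arma::fmat Wm(wf.memptr(), 9 * C, Cout, false, true);
  arma::fvec gyf = to_f(gy.begin(), gy.size());
  arma::fmat GY(HW * N, Cout);
  for (int n = 0; n < N; ++n) {
    GY.rows(n * HW, (n + 1) * HW - 1) =
      arma::fmat(gyf.memptr() + HW * Cout * n, HW, Cout, false, true);
  }
  NumericVector gw((size_t)9 * C * Cout);
  gw.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  NumericVector gb(Cout);
  arma::fmat GW = col.t() * GY;
  from_f(GW, gw.begin());
  arma::fvec GB = arma::sum(GY, 0).t();
  for (int i = 0; i < Cout; ++i) gb[i] = (double)GB[i];
  if (!need_gx) {
    return List::create(_["gw"] = gw, _["gb"] = gb);
  }
  NumericVector gx = make4d(H, W, C, N);
  arma::fmat gcol = GY * Wm.t();
  arma::fmat gxf(HW * C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    float* gxn = gxf.colptr(n);
    for (int c = 0; c < C; ++c) {
      arma::fmat GXc(gxn + HW * c, H, W, false, true);
      for (int kw = -1; kw <= 1; ++kw) {
        for (int kh = -1; kh <= 1; ++kh) {
          int q = (kh + 1) + 3 * (kw + 1) + 9 * c;
          arma::fmat Gq(gcol.colptr(q) + n * HW, H, W, false, true);
          int r0 = std::max(0, -kh), r1 = std::min(H, H - kh) - 1;
          int c0 = std::max(0, -kw), c1 = std::min(W, W - kw) - 1;
          if (r0 > r1 || c0 > c1) continue;
          GXc.submat(r0 + kh, c0 + kw, r1 + kh, c1 + kw) += Gq.submat(r0, c0, r1, c1);
        }
      }
    }
  }
  from_f(gxf, gx.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
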