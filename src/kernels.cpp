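// Low-level network kernels: 3x3 same-padding convolution, 1x1 convolution,
// 2x2 stride-2 transposed convolution and 2x2 stride-2 max-pooling, each with
// the backward pass used by the R-side backpropagation. Arrays are column-major
// (H, W, C, B); weights are (kh, kw, Cin, Cout). im2col + BLAS matmul.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dim4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// build im2col matrix (H*W x 9*Ci) for one image held in Xm (H*W x Ci)
static void im2col3(const arma::mat& Xm, int H, int W, arma::mat& col) {
  const int Ci = Xm.n_cols;
  col.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    const arma::mat img(const_cast<double*>(Xm.colptr(ci)), H, W, false, true);
    for (int kx = 0; kx < 3; ++kx) {
      int dx = kx - 1;
      int w0 = std::max(0, -dx), w1 = W - 1 - std::max(0, dx);
      for (int ky = 0; ky < 3; ++ky) {
        int dy = ky - 1;
        int h0 = std::max(0, -dy), h1 = H - 1 - std::max(0, dy);
        if (w0 > w1 || h0 > h1) continue;
        arma::mat dst(col.colptr(ky + 3 * kx + 9 * ci), H, W, false, true);
        dst.submat(h0, w0, h1, w1) = img.submat(h0 + dy, w0 + dx, h1 + dy, w1 + dx);
      }
    }
  }
}

// scatter-add of a column-matrix gradient back onto the input image
static void col2im3(const arma::mat& gcol, int H, int W, arma::mat& Gm) {
  const int Ci = Gm.n_cols;
  for (int ci = 0; ci < Ci; ++ci) {
    arma::mat gimg(Gm.colptr(ci), H, W, false, true);
    for (int kx = 0; kx < 3; ++kx) {
      int dx = kx - 1;
      int w0 = std::max(0, -dx), w1 = W - 1 - std::max(0, dx);
      for (int ky = 0; ky < 3; ++ky) {
        int dy = ky - 1;
        int h0 = std::max(0, -dy), h1 = H - 1 - std::max(0, dy);
        if (w0 > w1 || h0 > h1) continue;
        const arma::mat src(const_cast<double*>(gcol.colptr(ky + 3 * kx + 9 * ci)),
                            H, W, false, true);
        gimg.submat(h0 + dy, w0 + dx, h1 + dy, w1 + dx) += src.submat(h0, w0, h1, w1);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3], Co = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != Ci) stop("weight shape mismatch");
  NumericVector y(static_cast<R_xlen_t>(H) * W * Co * B);
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  const arma::mat Wm(const_cast<double*>(w.begin()), 9 * Ci, Co, false, true);
  const arma::vec bv(const_cast<double*>(b.begin()), Co, false, true);
  arma::mat col(H * W, 9 * Ci);
  for (int ib = 0; ib < B; ++ib) {
    const arma::mat Xm(const_cast<double*>(x.begin()) + (R_xlen_t)ib * H * W * Ci,
                       H * W, Ci, false, true);
    arma::mat Ym(y.begin() + (R_xlen_t)ib * H * W * Co, H * W, Co, false, true);
    im2col3(Xm, H, W, col);
    Ym = col * Wm;
    Ym.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3], Co = dw[3];
  NumericVector gx(x.size()), gw(w.size());
  NumericVector gb(Co);
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  const arma::mat Wm(const_cast<double*>(w.begin()), 9 * Ci, Co, false, true);
  arma::mat GW(gw.begin(), 9 * Ci, Co, false, true);
  arma::vec GB(gb.begin(), Co, false, true);
  arma::mat col(H * W, 9 * Ci);
  for (int ib = 0; ib < B; ++ib) {
    const arma::mat Xm(const_cast<double*>(x.begin()) + (R_xlen_t)ib * H * W * Ci,
                       H * W, Ci, false, true);
    const arma::mat Gy(const_cast<double*>(gy.begin()) + (R_xlen_t)ib * H * W * Co,
                       H * W, Co, false, true);
    arma::mat Gx(gx.begin() + (R_xlen_t)ib * H * W * Ci, H * W, Ci, false, true);
    im2col3(Xm, H, W, col);
    GW += col.t() * Gy;
    GB += arma::sum(Gy, 0).t();
    arma::mat gcol = Gy * Wm.t();
    col2im3(gcol, H, W, Gx);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_conv1x1_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector dx = dim4(x);
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3], Co = w.ncol();
  if (w.nrow() != Ci) stop("weight shape mismatch");
  NumericVector y(static_cast<R_xlen_t>(H) * W * Co * B);
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  const arma::mat Wm(const_cast<double*>(w.begin()), Ci, Co, false, true);
  const arma::vec bv(const_cast<double*>(b.begin()), Co, false, true);
  for (int ib = 0; ib < B; ++ib) {
    const arma::mat Xm(const_cast<double*>(x.begin()) + (R_xlen_t)ib * H * W * Ci,
                       H * W, Ci, false, true);
    arma::mat Ym(y.begin() + (R_xlen_t)ib * H * W * Co, H * W, Co, false, true);
    Ym = Xm * Wm;
    Ym.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv1x1_bwd(NumericVector x, NumericMatrix w, NumericVector gy) {
  IntegerVector dx = dim4(x);
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3], Co = w.ncol();
  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  NumericMatrix gw(Ci, Co);
  NumericVector gb(Co);
  const arma::mat Wm(const_cast<double*>(w.begin()), Ci, Co, false, true);
  arma::mat GW(gw.begin(), Ci, Co, false, true);
  arma::vec GB(gb.begin(), Co, false, true);
  for (int ib = 0; ib < B; ++ib) {
    const arma::mat Xm(const_cast<double*>(x.begin()) + (R_xlen_t)ib * H * W * Ci,
                       H * W, Ci, false, true);
    const arma::mat Gy(const_cast<double*>(gy.begin()) + (R_xlen_t)ib * H * W * Co,
                       H * W, Co, false, true);
    arma::mat Gx(gx.begin() + (R_xlen_t)ib * H * W * Ci, H * W, Ci, false, true);
    GW += Xm.t() * Gy;
    GB += arma::sum(Gy, 0).t();
    Gx = Gy * Wm.t();
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// transposed 2x2 stride-2 convolution: (H,W,Ci) -> (2H,2W,Co)
// y(2h+a, 2w+c, co) = sum_ci x(h,w,ci) * w(a,c,ci,co) + b(co)
// [[Rcpp::export]]
NumericVector cpp_convT2x2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3], Co = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != Ci) stop("weight shape mismatch");
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(H2) * W2 * Co * B);
  y.attr("dim") = IntegerVector::create(H2, W2, Co, B);
  // reorder weights to (Ci x 4*Co), column a + 2*c + 4*co
  arma::mat Wre(Ci, 4 * Co);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int c = 0; c < 2; ++c)
        for (int a = 0; a < 2; ++a)
          Wre(ci, a + 2 * c + 4 * co) = w[a + 2 * (c + 2 * (ci + (R_xlen_t)Ci * co))];
  for (int ib = 0; ib < B; ++ib) {
    const arma::mat Xm(const_cast<double*>(x.begin()) + (R_xlen_t)ib * H * W * Ci,
                       H * W, Ci, false, true);
    arma::mat T = Xm * Wre;  // (H*W) x (4*Co)
    double* yb = y.begin() + (R_xlen_t)ib * H2 * W2 * Co;
    for (int co = 0; co < Co; ++co) {
      double* ych = yb + (R_xlen_t)co * H2 * W2;
      for (int c = 0; c < 2; ++c)
        for (int a = 0; a < 2; ++a) {
          const double* tc = T.colptr(a + 2 * c + 4 * co);
          for (int iw = 0; iw < W; ++iw) {
            double* dst = ych + (R_xlen_t)(2 * iw + c) * H2 + a;
            const double* src = tc + (R_xlen_t)iw * H;
            for (int ih = 0; ih < H; ++ih) dst[2 * ih] = src[ih] + b[co];
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convT2x2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3], Co = dw[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  arma::mat Wre(Ci, 4 * Co);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int c = 0; c < 2; ++c)
        for (int a = 0; a < 2; ++a)
          Wre(ci, a + 2 * c + 4 * co) = w[a + 2 * (c + 2 * (ci + (R_xlen_t)Ci * co))];
  arma::mat GWre(Ci, 4 * Co, arma::fill::zeros);
  arma::mat GT(H * W, 4 * Co);
  for (int ib = 0; ib < B; ++ib) {
    const arma::mat Xm(const_cast<double*>(x.begin()) + (R_xlen_t)ib * H * W * Ci,
                       H * W, Ci, false, true);
    arma::mat Gx(gx.begin() + (R_xlen_t)ib * H * W * Ci, H * W, Ci, false, true);
    const double* gyb = gy.begin() + (R_xlen_t)ib * H2 * W2 * Co;
    for (int co = 0; co < Co; ++co) {
      const double* gch = gyb + (R_xlen_t)co * H2 * W2;
      double s = 0.0;
      for (R_xlen_t k = 0; k < (R_xlen_t)H2 * W2; ++k) s += gch[k];
      gb[co] += s;
      for (int c = 0; c < 2; ++c)
        for (int a = 0; a < 2; ++a) {
          double* tc = GT.colptr(a + 2 * c + 4 * co);
          for (int iw = 0; iw < W; ++iw) {
            const double* src = gch + (R_xlen_t)(2 * iw + c) * H2 + a;
            double* dst = tc + (R_xlen_t)iw * H;
            for (int ih = 0; ih < H; ++ih) dst[ih] = src[2 * ih];
          }
        }
    }
    Gx = GT * Wre.t();
    GWre += Xm.t() * GT;
  }
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int c = 0; c < 2; ++c)
        for (int a = 0; a < 2; ++a)
          gw[a + 2 * (c + 2 * (ci + (R_xlen_t)Ci * co))] = GWre(ci, a + 2 * c + 4 * co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector dx = dim4(x);
  const int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  if (H % 2 || W % 2) stop("max-pooling needs even spatial dims");
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y(static_cast<R_xlen_t>(H2) * W2 * C * B);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(H2, W2, C, B);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, B);
  R_xlen_t o = 0;
  for (int cb = 0; cb < C * B; ++cb) {
    const double* ch = x.begin() + (R_xlen_t)cb * H * W;
    for (int iw = 0; iw < W2; ++iw)
      for (int ih = 0; ih < H2; ++ih, ++o) {
        const double* p = ch + (R_xlen_t)(2 * iw) * H + 2 * ih;
        double v = p[0];
        int k = 0;
        if (p[1] > v) { v = p[1]; k = 1; }
        if (p[H] > v) { v = p[H]; k = 2; }
        if (p[H + 1] > v) { v = p[H + 1]; k = 3; }
        y[o] = v;
        idx[o] = k;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy, int H, int W) {
  IntegerVector dy = dim4(gy);
  const int H2 = dy[0], W2 = dy[1], C = dy[2], B = dy[3];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * B);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  R_xlen_t o = 0;
  for (int cb = 0; cb < C * B; ++cb) {
    double* ch = gx.begin() + (R_xlen_t)cb * H * W;
    for (int iw = 0; iw < W2; ++iw)
      for (int ih = 0; ih < H2; ++ih, ++o) {
        int k = idx[o];
        double* p = ch + (R_xlen_t)(2 * iw + (k >> 1)) * H + 2 * ih + (k & 1);
        *p += gy[o];
      }
  }
  return gx;
}

// batch normalisation over (H,W,B) per channel; returns y plus the
// quantities the backward pass needs
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector g, NumericVector b,
                NumericVector mean_in, NumericVector var_in,
                bool use_batch_stats, double eps) {
  IntegerVector d = dim4(x);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = d;
  xhat.attr("dim") = d;
  NumericVector mu(C), vv(C), istd(C);
  if (use_batch_stats) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int ib = 0; ib < B; ++ib) {
        const double* p = x.begin() + HW * (c + (R_xlen_t)C * ib);
        for (R_xlen_t k = 0; k < HW; ++k) { s += p[k]; s2 += p[k] * p[k]; }
      }
      double n = (double)HW * B;
      mu[c] = s / n;
      vv[c] = s2 / n - mu[c] * mu[c];
      if (vv[c] < 0) vv[c] = 0;
    }
  } else {
    mu = clone(mean_in);
    vv = clone(var_in);
  }
  for (int c = 0; c < C; ++c) istd[c] = 1.0 / std::sqrt(vv[c] + eps);
  for (int ib = 0; ib < B; ++ib)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (R_xlen_t)C * ib);
      double* ph = xhat.begin() + HW * (c + (R_xlen_t)C * ib);
      double* py = y.begin() + HW * (c + (R_xlen_t)C * ib);
      const double m = mu[c], is = istd[c], gg = g[c], bb = b[c];
      for (R_xlen_t k = 0; k < HW; ++k) {
        ph[k] = (p[k] - m) * is;
        py[k] = gg * ph[k] + bb;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["mean"] = mu, _["var"] = vv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector gy, NumericVector xhat, NumericVector g,
                NumericVector istd, bool batch_stats) {
  IntegerVector d = dim4(gy);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  const double n = (double)HW * B;
  NumericVector gx(gy.size()), gg(C), gb(C);
  gx.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int ib = 0; ib < B; ++ib) {
      const double* pg = gy.begin() + HW * (c + (R_xlen_t)C * ib);
      const double* ph = xhat.begin() + HW * (c + (R_xlen_t)C * ib);
      for (R_xlen_t k = 0; k < HW; ++k) {
        s1 += pg[k];
        s2 += pg[k] * ph[k];
      }
    }
    gb[c] = s1;
    gg[c] = s2;
    const double gc = g[c], is = istd[c];
    const double m1 = s1 / n, m2 = s2 / n;
    for (int ib = 0; ib < B; ++ib) {
      const double* pg = gy.begin() + HW * (c + (R_xlen_t)C * ib);
      const double* ph = xhat.begin() + HW * (c + (R_xlen_t)C * ib);
      double* px = gx.begin() + HW * (c + (R_xlen_t)C * ib);
      if (batch_stats)
        for (R_xlen_t k = 0; k < HW; ++k)
          px[k] = gc * is * (pg[k] - m1 - ph[k] * m2);
      else
        for (R_xlen_t k = 0; k < HW; ++k)
          px[k] = gc * is * pg[k];
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t k = 0; k < x.size(); ++k)
    y[k] = x[k] >= 0 ? x[k] : slope * x[k];
  return y;
}

// backward using the forward output (sign-preserving for slope > 0)
// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector gy, NumericVector y, double slope) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  for (R_xlen_t k = 0; k < gy.size(); ++k)
    gx[k] = y[k] >= 0 ? gy[k] : slope * gy[k];
  return gx;
}
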