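// Convolution and pooling kernels used by the backbone networks.
// Arrays follow R's column-major layout: images are (H, W, C, N),
// kernels are (kh, kw, Cin, Cout). im2col + GEMM via Armadillo.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int Cin,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat& col) {
  // col is (kh*kw*Cin) x (Ho*Wo); column index = oi + Ho*oj
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const int cidx = oi + Ho * oj;
      double* dst = col.colptr(cidx);
      for (int c = 0; c < Cin; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = oj * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = oi * stride - pad + ki;
            const int r = ki + kh * (kj + kw * c);
            if (hi >= 0 && hi < H && wj >= 0 && wj < W)
              dst[r] = x[hi + H * (wj + W * c)];
            else
              dst[r] = 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im_add(const arma::mat& col, int H, int W, int Cin,
                              int kh, int kw, int stride, int pad,
                              int Ho, int Wo, double* gx) {
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const int cidx = oi + Ho * oj;
      const double* src = col.colptr(cidx);
      for (int c = 0; c < Cin; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = oj * stride - pad + kj;
          if (wj < 0 || wj >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = oi * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const int r = ki + kh * (kj + kw * c);
            gx[hi + H * (wj + W * c)] += src[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int krows = kh * kw * Cin;

  arma::mat Wmat(const_cast<double*>(w.begin()), krows, Cout, false, true);
  NumericVector out(Ho * (R_xlen_t)Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat col(krows, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * H * W * Cin, H, W, Cin,
           kh, kw, stride, pad, Ho, Wo, col);
    arma::mat o = col.t() * Wmat;  // (Ho*Wo) x Cout
    double* op = out.begin() + (R_xlen_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      const double* oc = o.colptr(co);
      double* dst = op + (R_xlen_t)co * Ho * Wo;
      for (int i = 0; i < Ho * Wo; ++i) dst[i] = oc[i] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int krows = kh * kw * Cin;

  arma::mat Wmat(const_cast<double*>(w.begin()), krows, Cout, false, true);
  arma::mat gW(krows, Cout, arma::fill::zeros);
  arma::vec gB(Cout, arma::fill::zeros);

  NumericVector gx(x.size());
  gx.attr("dim") = xd;

  arma::mat col(krows, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (R_xlen_t)n * H * W * Cin;
    im2col(xp, H, W, Cin, kh, kw, stride, pad, Ho, Wo, col);
    // gout sample as (Ho*Wo) x Cout
    arma::mat G(Ho * Wo, Cout);
    const double* gp = gout.begin() + (R_xlen_t)n * Ho * Wo * Cout;
    std::copy(gp, gp + (R_xlen_t)Ho * Wo * Cout, G.memptr());
    gW += col * G;
    gB += arma::sum(G, 0).t();
    arma::mat colg = Wmat * G.t();  // krows x (Ho*Wo)
    col2im_add(colg, H, W, Cin, kh, kw, stride, pad, Ho, Wo,
               gx.begin() + (R_xlen_t)n * H * W * Cin);
  }

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gw.begin());
  NumericVector gb(Cout);
  std::copy(gB.memptr(), gB.memptr() + Cout, gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int size, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H - size) / stride + 1;
  const int Wo = (W - size) / stride + 1;
  NumericVector out(Ho * (R_xlen_t)Wo * C * N);
  IntegerVector idx(out.size());  // 0-based linear index hi + H*wj
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (R_xlen_t)(n * C + c) * H * W;
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = R_NegInf; int bidx = 0;
          for (int kj = 0; kj < size; ++kj) {
            const int wj = oj * stride + kj;
            for (int ki = 0; ki < size; ++ki) {
              const int hi = oi * stride + ki;
              const double v = xp[hi + H * wj];
              if (v > best) { best = v; bidx = hi + H * wj; }
            }
          }
          // column-major over (oi, oj) within the (c, n) plane
          out[o + oi + (R_xlen_t)Ho * oj] = best;
          idx[o + oi + (R_xlen_t)Ho * oj] = bidx;
        }
      }
      o += (R_xlen_t)Ho * Wo;
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector gout, IntegerVector idx,
                              int H, int W) {
  IntegerVector od = gout.attr("dim");
  const int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  R_xlen_t o = 0, plane = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* gp = gx.begin() + (R_xlen_t)(n * C + c) * plane;
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i)
        gp[idx[o + i]] += gout[o + i];
      o += (R_xlen_t)Ho * Wo;
    }
  }
  return gx;
}
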