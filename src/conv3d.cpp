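// 3D cross-correlation via im2col + GEMM, with the exact adjoint used for
// backpropagation. Tensors follow R's column-major array layout (D,H,W,C).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Gather patches: rows index output voxels (column-major over Do,Ho,Wo),
// columns index kernel taps (kd fastest, then kh, kw, then input channel).
static arma::mat im2col3(const double* x, int D, int H, int W, int C,
                         int k, int s, int p, int Do, int Ho, int Wo) {
  const arma::uword nrow = (arma::uword)Do * Ho * Wo;
  arma::mat M(nrow, (arma::uword)k * k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const arma::uword col =
              (arma::uword)kd + k * ((arma::uword)kh + k * ((arma::uword)kw + k * (arma::uword)ci));
          double* Mcol = M.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * s - p + kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + kh;
              if (hi < 0 || hi >= H) continue;
              const size_t xoff = (size_t)D * (hi + (size_t)H * wi);
              const arma::uword moff = (arma::uword)Do * (ho + (arma::uword)Ho * wo);
              for (int dd = 0; dd < Do; ++dd) {
                const int di = dd * s - p + kd;
                if (di < 0 || di >= D) continue;
                Mcol[dd + moff] = xc[di + xoff];
              }
            }
          }
        }
  }
  return M;
}

// Scatter-add adjoint of im2col3.
static void col2im3(const arma::mat& M, double* gx, int D, int H, int W, int C,
                    int k, int s, int p, int Do, int Ho, int Wo) {
  for (int ci = 0; ci < C; ++ci) {
    double* gc = gx + (size_t)ci * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const arma::uword col =
              (arma::uword)kd + k * ((arma::uword)kh + k * ((arma::uword)kw + k * (arma::uword)ci));
          const double* Mcol = M.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * s - p + kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + kh;
              if (hi < 0 || hi >= H) continue;
              const size_t xoff = (size_t)D * (hi + (size_t)H * wi);
              const arma::uword moff = (arma::uword)Do * (ho + (arma::uword)Ho * wo);
              for (int dd = 0; dd < Do; ++dd) {
                const int di = dd * s - p + kd;
                if (di < 0 || di >= D) continue;
                gc[di + xoff] += Mcol[dd + moff];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector dimx, NumericVector w,
                            IntegerVector dimw, NumericVector b, int stride, int pad) {
  const int D = dimx[0], H = dimx[1], W = dimx[2], C = dimx[3];
  const int k = dimw[0], Cin = dimw[3], Cout = dimw[4];
  if (Cin != C) stop("conv3d: channel mismatch");
  const int Do = out_extent(D, k, stride, pad);
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("conv3d: kernel larger than padded input");
  arma::mat M = im2col3(x.begin(), D, H, W, C, k, stride, pad, Do, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)k * k * k * Cin, Cout, false, true);
  arma::mat Y = M * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector dimx, NumericVector w,
                   IntegerVector dimw, NumericVector gy, int stride, int pad,
                   bool need_gx) {
  const int D = dimx[0], H = dimx[1], W = dimx[2], C = dimx[3];
  const int k = dimw[0], Cin = dimw[3], Cout = dimw[4];
  const int Do = out_extent(D, k, stride, pad);
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  arma::mat M = im2col3(x.begin(), D, H, W, C, k, stride, pad, Do, Ho, Wo);
  arma::mat GY(const_cast<double*>(gy.begin()), (arma::uword)Do * Ho * Wo, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)k * k * k * Cin, Cout, false, true);
  arma::mat GW = M.t() * GY;
  arma::rowvec GB = arma::sum(GY, 0);
  NumericVector gx;
  if (need_gx) {
    arma::mat GM = GY * Wm.t();
    gx = NumericVector((R_xlen_t)D * H * W * C);
    col2im3(GM, gx.begin(), D, H, W, C, k, stride, pad, Do, Ho, Wo);
    gx.attr("dim") = dimx;
  }
  NumericVector gwv(GW.begin(), GW.end());
  gwv.attr("dim") = dimw;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}
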