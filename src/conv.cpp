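#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensor layout (column-major, matching R arrays):
//   activations x : H x W x C x N
//   weights     w : K x K x Cin x Cout
// im2col is materialised transposed, (Ho*Wo*N) x (K*K*Cin), so the inner
// ho-loop is contiguous (memcpy for stride 1) and the GEMM against the
// (K*K*Cin) x Cout weight matrix yields the output directly.  Boundary
// handling is hoisted out of the inner loops: the valid ho/wo ranges are
// computed per kernel offset.

static inline int out_side(int in, int K, int stride, int pad) {
  return (in + 2 * pad - K) / stride + 1;
}

// valid output range [lo, hi] such that 0 <= o*stride + k - pad < in
static inline void valid_range(int in, int n_out, int k, int stride, int pad,
                               int& lo, int& hi) {
  int off = k - pad;
  lo = (off < 0) ? ((-off + stride - 1) / stride) : 0;
  hi = (in - 1 - off) / stride;
  if (hi > n_out - 1) hi = n_out - 1;
}

static void im2col_t(const double* x, int H, int W, int C, int N,
                     int K, int stride, int pad, int Ho, int Wo,
                     arma::mat& colT) {
  const size_t nrow = (size_t)Ho * Wo * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < K; ++kw) {
      int wo_lo, wo_hi;
      valid_range(W, Wo, kw, stride, pad, wo_lo, wo_hi);
      for (int kh = 0; kh < K; ++kh) {
        int ho_lo, ho_hi;
        valid_range(H, Ho, kh, stride, pad, ho_lo, ho_hi);
        const int r = kh + K * (kw + K * ci);
        double* dst0 = colT.memptr() + (size_t)r * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xc = x + ((size_t)n * C + ci) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            double* drow = dst0 + ((size_t)Wo * n + wo) * Ho;
            if (wo < wo_lo || wo > wo_hi) {
              std::fill(drow, drow + Ho, 0.0);
              continue;
            }
            const double* src = xc + (size_t)(wo * stride + kw - pad) * H;
            if (ho_lo > 0) std::fill(drow, drow + ho_lo, 0.0);
            if (ho_hi < Ho - 1) std::fill(drow + ho_hi + 1, drow + Ho, 0.0);
            if (stride == 1) {
              std::memcpy(drow + ho_lo, src + ho_lo + kh - pad,
                          (size_t)(ho_hi - ho_lo + 1) * sizeof(double));
            } else {
              const double* s = src + (size_t)ho_lo * stride + kh - pad;
              for (int ho = ho_lo; ho <= ho_hi; ++ho, s += stride)
                drow[ho] = *s;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector b, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: channel mismatch (input %d, kernel %d)", C, Cin);
  const int Ho = out_side(H, K, stride, pad), Wo = out_side(W, K, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");

  const size_t nrow = (size_t)Ho * Wo * N;
  arma::mat colT(nrow, (size_t)K * K * C);
  im2col_t(x.begin(), H, W, C, N, K, stride, pad, Ho, Wo, colT);

  const arma::mat Wmat(const_cast<double*>(w.begin()),
                       (size_t)K * K * C, Cout, false, true);
  arma::mat Y = colT * Wmat;  // (Ho*Wo*N) x Cout
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];

  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  const size_t plane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::memcpy(out.begin() + plane * (co + (size_t)Cout * n),
                  Y.colptr(co) + plane * n, plane * sizeof(double));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dy, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Cout = wdim[3];
  const int Ho = out_side(H, K, stride, pad), Wo = out_side(W, K, stride, pad);
  const size_t nrow = (size_t)Ho * Wo * N;
  const size_t plane = (size_t)Ho * Wo;

  arma::mat colT(nrow, (size_t)K * K * C);
  im2col_t(x.begin(), H, W, C, N, K, stride, pad, Ho, Wo, colT);

  // reorder dy (Ho,Wo,Cout,N) into (Ho*Wo*N) x Cout
  arma::mat dY(nrow, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::memcpy(dY.colptr(co) + plane * n,
                  dy.begin() + plane * (co + (size_t)Cout * n),
                  plane * sizeof(double));

  const arma::mat Wmat(const_cast<double*>(w.begin()),
                       (size_t)K * K * C, Cout, false, true);
  arma::mat dWmat = colT.t() * dY;               // (K*K*C) x Cout
  arma::rowvec dbr = arma::sum(dY, 0);
  arma::mat dcolT = dY * Wmat.t();               // (Ho*Wo*N) x (K*K*C)

  NumericVector dx((R_xlen_t)H * W * C * N);     // zero-initialised
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < K; ++kw) {
      int wo_lo, wo_hi;
      valid_range(W, Wo, kw, stride, pad, wo_lo, wo_hi);
      for (int kh = 0; kh < K; ++kh) {
        int ho_lo, ho_hi;
        valid_range(H, Ho, kh, stride, pad, ho_lo, ho_hi);
        const int r = kh + K * (kw + K * ci);
        const double* src0 = dcolT.memptr() + (size_t)r * nrow;
        for (int n = 0; n < N; ++n) {
          double* xc = dx.begin() + ((size_t)n * C + ci) * H * W;
          for (int wo = wo_lo; wo <= wo_hi; ++wo) {
            const double* srow = src0 + ((size_t)Wo * n + wo) * Ho;
            double* dcol = xc + (size_t)(wo * stride + kw - pad) * H + kh - pad;
            if (stride == 1) {
              for (int ho = ho_lo; ho <= ho_hi; ++ho) dcol[ho] += srow[ho];
            } else {
              double* d = dcol + (size_t)ho_lo * stride;
              for (int ho = ho_lo; ho <= ho_hi; ++ho, d += stride)
                *d += srow[ho];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;

  NumericVector dw(w.length());
  std::memcpy(dw.begin(), dWmat.memptr(), (size_t)w.length() * sizeof(double));
  dw.attr("dim") = wdim;
  NumericVector db(Cout);
  std::memcpy(db.begin(), dbr.memptr(), (size_t)Cout * sizeof(double));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
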