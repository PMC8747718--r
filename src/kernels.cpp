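#include <Rcpp.h>
using namespace Rcpp;

// Activation tensors are R arrays (H, W, C, N), column-major.
// im2col row index r = ho + wo*Hout + n*Hout*Wout (0-based);
// column index k = c*kh*kw + kj*kh + ki, so a conv weight matrix of shape
// (kh*kw*Cin) x Cout multiplies from the right. Zero padding, stride >= 1.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int pad, int stride) {
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t nrow = (R_xlen_t)N * Hout * Wout;
  NumericMatrix out(nrow, kh * kw * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = c * kh * kw + kj * kh + ki;
        double* ocol = op + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xim = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            const R_xlen_t rbase = (R_xlen_t)n * Hout * Wout + (R_xlen_t)wo * Hout;
            const double* xcolp = xim + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              ocol[rbase + ho] = xcolp[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch-gradient columns back onto the
// input gradient tensor (H, W, C, N).

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int pad, int stride) {
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t nrow = (R_xlen_t)N * Hout * Wout;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double* cp = cols.begin();
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = c * kh * kw + kj * kh + ki;
        const double* ccol = cp + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          double* dim = dp + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            const R_xlen_t rbase = (R_xlen_t)n * Hout * Wout + (R_xlen_t)wo * Hout;
            double* dcolp = dim + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              dcolp[hi] += ccol[rbase + ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling over a win x win window; returns pooled tensor and the 1-based
// linear index of each selected element for the backward pass. Trailing rows
// or columns that do not fill a window are dropped.

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int H, int W, int C, int N,
                     int win, int stride) {
  const int Hout = (H - win) / stride + 1;
  const int Wout = (W - win) / stride + 1;
  const R_xlen_t len = (R_xlen_t)Hout * Wout * C * N;
  NumericVector out(len);
  IntegerVector idx(len);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wout; ++wo) {
        const int w0 = wo * stride;
        for (int ho = 0; ho < Hout; ++ho) {
          const int h0 = ho * stride;
          double best = xp[base + (R_xlen_t)w0 * H + h0];
          R_xlen_t besti = base + (R_xlen_t)w0 * H + h0;
          for (int dw = 0; dw < win; ++dw) {
            const R_xlen_t coloff = base + (R_xlen_t)(w0 + dw) * H;
            for (int dh = 0; dh < win; ++dh) {
              const double v = xp[coloff + h0 + dh];
              if (v > best) { best = v; besti = coloff + h0 + dh; }
            }
          }
          // output layout (Hout, Wout, C, N), column-major
          const R_xlen_t oi = ((R_xlen_t)n * C + c) * Hout * Wout +
                              (R_xlen_t)wo * Hout + ho;
          op[oi] = best;
          ip[oi] = (int)(besti + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector idx,
                              R_xlen_t len_x) {
  NumericVector dx(len_x);
  const double* dp = dout.begin();
  const int* ip = idx.begin();
  double* xp = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[ip[i] - 1] += dp[i];
  return dx;
}
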