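#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Patch extraction for convolution-as-matrix-multiply. Input is an (H,W,C)
// array; the result has k*k*C rows (kr fastest, then kc, then channel — the
// same order R uses to flatten a (k,k,C) weight block) and OH*OW columns
// (output rows fastest). Zero padding.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, OH * OW);
  for (int oc = 0; oc < OW; ++oc) {
    for (int orow = 0; orow < OH; ++orow) {
      int col = orow + oc * OH;
      int r0 = orow * stride - pad, c0 = oc * stride - pad;
      double *dst = &out(0, col);
      for (int ch = 0; ch < C; ++ch)
        for (int kc = 0; kc < k; ++kc) {
          int cc = c0 + kc;
          for (int kr = 0; kr < k; ++kr) {
            int rr = r0 + kr;
            double v = 0.0;
            if (rr >= 0 && rr < H && cc >= 0 && cc < W)
              v = x[rr + cc * H + ch * H * W];
            dst[kr + kc * k + ch * k * k] = v;
          }
        }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch gradients back onto the input.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericVector x(H * W * C);
  for (int oc = 0; oc < OW; ++oc) {
    for (int orow = 0; orow < OH; ++orow) {
      int col = orow + oc * OH;
      int r0 = orow * stride - pad, c0 = oc * stride - pad;
      double *src = &cols(0, col);
      for (int ch = 0; ch < C; ++ch)
        for (int kc = 0; kc < k; ++kc) {
          int cc = c0 + kc;
          if (cc < 0 || cc >= W) continue;
          for (int kr = 0; kr < k; ++kr) {
            int rr = r0 + kr;
            if (rr < 0 || rr >= H) continue;
            x[rr + cc * H + ch * H * W] += src[kr + kc * k + ch * k * k];
          }
        }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Max pooling over k×k windows with the given stride (valid windows only).
// Returns the pooled map and the 0-based linear argmax index of each window,
// for use by the backward pass.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int k, int stride) {
  int OH = (H - k) / stride + 1;
  int OW = (W - k) / stride + 1;
  NumericVector out(OH * OW * C);
  IntegerVector arg(OH * OW * C);
  for (int ch = 0; ch < C; ++ch)
    for (int oc = 0; oc < OW; ++oc)
      for (int orow = 0; orow < OH; ++orow) {
        int r0 = orow * stride, c0 = oc * stride;
        double best = R_NegInf;
        int bestIdx = -1;
        for (int kc = 0; kc < k; ++kc)
          for (int kr = 0; kr < k; ++kr) {
            int idx = (r0 + kr) + (c0 + kc) * H + ch * H * W;
            if (x[idx] > best) { best = x[idx]; bestIdx = idx; }
          }
        int o = orow + oc * OH + ch * OH * OW;
        out[o] = best;
        arg[o] = bestIdx;
      }
  out.attr("dim") = IntegerVector::create(OH, OW, C);
  arg.attr("dim") = IntegerVector::create(OH, OW, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector grad, IntegerVector argmax,
                              int H, int W, int C) {
  NumericVector gx(H * W * C);
  for (R_xlen_t i = 0; i < grad.size(); ++i) gx[argmax[i]] += grad[i];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}
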