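#include <Rcpp.h>
using namespace Rcpp;

// Strided valid convolution (cross-correlation convention, as in feedforward
// nets): input (H, W, C), weights (fh, fw, C, J), bias (J).
// out[p,q,j] = b[j] + sum_{u,v,c} W[u,v,c,j] * in[p*s+u, q*s+v, c]
// [[Rcpp::export]]
NumericVector cpp_conv_valid(NumericVector input, NumericVector weights,
                             NumericVector bias, int stride) {
  IntegerVector di = input.attr("dim");
  IntegerVector dw = weights.attr("dim");
  const int H = di[0], W = di[1], C = di[2];
  const int fh = dw[0], fw = dw[1], Cw = dw[2], J = dw[3];
  if (Cw != C) stop("channel mismatch between input and weights");
  if (fh > H || fw > W) stop("input smaller than one filter placement");
  const int oh = (H - fh) / stride + 1;
  const int ow = (W - fw) / stride + 1;
  NumericVector out(oh * ow * J);
  out.attr("dim") = IntegerVector::create(oh, ow, J);
  for (int j = 0; j < J; ++j) {
    for (int q = 0; q < ow; ++q) {
      for (int p = 0; p < oh; ++p) {
        double acc = bias[j];
        for (int c = 0; c < C; ++c) {
          const double *in = &input[(size_t)c * H * W];
          const double *wt = &weights[((size_t)j * C + c) * fh * fw];
          for (int v = 0; v < fw; ++v) {
            const double *incol = in + (size_t)(q * stride + v) * H + p * stride;
            const double *wcol = wt + (size_t)v * fh;
            for (int u = 0; u < fh; ++u) acc += wcol[u] * incol[u];
          }
        }
        out[((size_t)j * ow + q) * oh + p] = acc;
      }
    }
  }
  return out;
}

// Strided transposed convolution: hidden (oh, ow, J), weights (fh, fw, J, C).
// out[x,y,c] = b[c] + sum_{p,q,j} W[x-p*s, y-q*s, j, c] * h[p,q,j]
// Output extent (H, W) supplied by the caller; H >= (oh-1)*s + fh is not
// required (excess contributions are dropped), but the natural size is that.
// [[Rcpp::export]]
NumericVector cpp_conv_transpose(NumericVector hidden, NumericVector weights,
                                 NumericVector bias, int stride,
                                 int H, int W) {
  IntegerVector dh = hidden.attr("dim");
  IntegerVector dw = weights.attr("dim");
  const int oh = dh[0], ow = dh[1], J = dh[2];
  const int fh = dw[0], fw = dw[1], Jw = dw[2], C = dw[3];
  if (Jw != J) stop("feature mismatch between hidden block and weights");
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c) {
    double *o = &out[(size_t)c * H * W];
    for (size_t i = 0; i < (size_t)H * W; ++i) o[i] = bias[c];
    for (int j = 0; j < J; ++j) {
      const double *wt = &weights[((size_t)c * J + j) * fh * fw];
      const double *h = &hidden[(size_t)j * oh * ow];
      for (int q = 0; q < ow; ++q) {
        for (int p = 0; p < oh; ++p) {
          const double hv = h[(size_t)q * oh + p];
          if (hv == 0.0) continue;
          for (int v = 0; v < fw; ++v) {
            const int y = q * stride + v;
            if (y >= W) break;
            double *ocol = o + (size_t)y * H + p * stride;
            const double *wcol = wt + (size_t)v * fh;
            const int umax = std::min(fh, H - p * stride);
            for (int u = 0; u < umax; ++u) ocol[u] += wcol[u] * hv;
          }
        }
      }
    }
  }
  return out;
}

// Gradient of a strided valid convolution with respect to its weights:
// dW[u,v,c,j] = sum_{p,q} delta[p,q,j] * in[p*s+u, q*s+v, c]
// [[Rcpp::export]]
NumericVector cpp_conv_weight_grad(NumericVector input, NumericVector delta,
                                   int fh, int fw, int stride) {
  IntegerVector di = input.attr("dim");
  IntegerVector dd = delta.attr("dim");
  const int H = di[0], C = di[2];
  const int oh = dd[0], ow = dd[1], J = dd[2];
  NumericVector out((size_t)fh * fw * C * J);
  out.attr("dim") = IntegerVector::create(fh, fw, C, J);
  for (int j = 0; j < J; ++j) {
    const double *dl = &delta[(size_t)j * oh * ow];
    for (int c = 0; c < C; ++c) {
      const double *in = &input[(size_t)c * H * (size_t)di[1]];
      double *o = &out[((size_t)j * C + c) * fh * fw];
      for (int q = 0; q < ow; ++q) {
        for (int p = 0; p < oh; ++p) {
          const double dv = dl[(size_t)q * oh + p];
          if (dv == 0.0) continue;
          for (int v = 0; v < fw; ++v) {
            const double *incol = in + (size_t)(q * stride + v) * H + p * stride;
            double *ocol = o + (size_t)v * fh;
            for (int u = 0; u < fh; ++u) ocol[u] += dv * incol[u];
          }
        }
      }
    }
  }
  return out;
}
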