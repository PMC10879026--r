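#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are numeric arrays [H, W, C] in R's column-major layout;
// convolution weights are [kh, kw, Cin, Cout]. Stride is always 1 and the
// output has the same spatial size as the input ("same" padding supplied by
// the caller as `pad`). Out-of-bounds taps contribute nothing.

static inline int idx3(int i, int j, int c, int H, int W) {
  return i + H * (j + W * c);
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  NumericVector out(H * W * Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double acc = b[co];
        for (int ci = 0; ci < C; ++ci) {
          for (int dj = 0; dj < kw; ++dj) {
            int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            for (int di = 0; di < kh; ++di) {
              int ii = i + di - pad;
              if (ii < 0 || ii >= H) continue;
              acc += x[idx3(ii, jj, ci, H, W)] *
                     w[di + kh * (dj + kw * (ci + Cin * co))];
            }
          }
        }
        out[idx3(i, j, co, H, W)] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gout,
                   int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  NumericVector gin(H * W * C), gw(kh * kw * Cin * Cout), gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double g = gout[idx3(i, j, co, H, W)];
        if (g == 0.0) continue;
        gb[co] += g;
        for (int ci = 0; ci < C; ++ci) {
          for (int dj = 0; dj < kw; ++dj) {
            int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            for (int di = 0; di < kh; ++di) {
              int ii = i + di - pad;
              if (ii < 0 || ii >= H) continue;
              int wi = di + kh * (dj + kw * (ci + Cin * co));
              gin[idx3(ii, jj, ci, H, W)] += g * w[wi];
              gw[wi] += g * x[idx3(ii, jj, ci, H, W)];
            }
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(H, W, C);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2; H and W must be even. Returns the pooled
// map and the flat argmax index into the input for the backward pass.

// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  if (H % 2 != 0 || W % 2 != 0) stop("maxpool2 requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector amax(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int best = idx3(2 * i, 2 * j, c, H, W);
        double bv = x[best];
        const int cand[3] = {idx3(2 * i + 1, 2 * j, c, H, W),
                             idx3(2 * i, 2 * j + 1, c, H, W),
                             idx3(2 * i + 1, 2 * j + 1, c, H, W)};
        for (int k = 0; k < 3; ++k) {
          if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
        }
        int o = idx3(i, j, c, Ho, Wo);
        out[o] = bv;
        amax[o] = best;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector gout, IntegerVector amax,
                              IntegerVector in_dim) {
  NumericVector gin(in_dim[0] * in_dim[1] * in_dim[2]);
  for (int k = 0; k < gout.size(); ++k) gin[amax[k]] += gout[k];
  gin.attr("dim") = in_dim;
  return gin;
}
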