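// Minimal batched 2-D convolution / pooling kernels used by the clip
// classifier and the fully convolutional segmenter.  Arrays are column-major
// with layout (H, W, C, N); weights are (k, k, Cin, Cout).  Convolutions are
// stride-1 with "same" zero padding (k odd).
#include <Rcpp.h>
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int K = dw[0], Cout = dw[3];
  if (dw[1] != K || dw[2] != Cin) stop("weight dims do not match input");
  const int P = (K - 1) / 2;
  NumericVector out(R_xlen_t(H) * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();
  const R_xlen_t sxc = R_xlen_t(H) * W, sxn = sxc * Cin;
  const R_xlen_t soc = R_xlen_t(H) * W, son = soc * Cout;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      double *o = po + n * son + co * soc;
      const double bias = pb[co];
      for (R_xlen_t i = 0; i < soc; ++i) o[i] = bias;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xin = px + n * sxn + ci * sxc;
        for (int kw = 0; kw < K; ++kw) {
          const int w0 = std::max(0, P - kw), w1 = std::min(W - 1, W - 1 - kw + P);
          for (int kh = 0; kh < K; ++kh) {
            const double wv = pw[kh + K * (kw + K * (ci + Cin * co))];
            if (wv == 0.0) continue;
            const int h0 = std::max(0, P - kh), h1 = std::min(H - 1, H - 1 - kh + P);
            for (int wo = w0; wo <= w1; ++wo) {
              const double *xc = xin + R_xlen_t(wo + kw - P) * H + (kh - P);
              double *oc = o + R_xlen_t(wo) * H;
              for (int ho = h0; ho <= h1; ++ho) oc[ho] += wv * xc[ho];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx); get_dims4(w, dw); get_dims4(gout, dg);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int K = dw[0], Cout = dw[3];
  if (dg[0] != H || dg[1] != W || dg[2] != Cout || dg[3] != N)
    stop("gradient dims do not match");
  const int P = (K - 1) / 2;
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  const double *px = x.begin(), *pw = w.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  const R_xlen_t sxc = R_xlen_t(H) * W, sxn = sxc * Cin;
  const R_xlen_t soc = R_xlen_t(H) * W, son = soc * Cout;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *g = pg + n * son + co * soc;
      double acc = 0.0;
      for (R_xlen_t i = 0; i < soc; ++i) acc += g[i];
      pgb[co] += acc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xin = px + n * sxn + ci * sxc;
        double *gxin = pgx + n * sxn + ci * sxc;
        for (int kw = 0; kw < K; ++kw) {
          const int w0 = std::max(0, P - kw), w1 = std::min(W - 1, W - 1 - kw + P);
          for (int kh = 0; kh < K; ++kh) {
            const R_xlen_t wi = kh + K * (kw + K * (R_xlen_t(ci) + Cin * co));
            const double wv = pw[wi];
            const int h0 = std::max(0, P - kh), h1 = std::min(H - 1, H - 1 - kh + P);
            double gwacc = 0.0;
            for (int wo = w0; wo <= w1; ++wo) {
              const double *xc = xin + R_xlen_t(wo + kw - P) * H + (kh - P);
              double *gxc = gxin + R_xlen_t(wo + kw - P) * H + (kh - P);
              const double *gc = g + R_xlen_t(wo) * H;
              for (int ho = h0; ho <= h1; ++ho) {
                gwacc += xc[ho] * gc[ho];
                gxc[ho] += wv * gc[ho];
              }
            }
            pgw[wi] += gwacc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the 0-based linear
// index of each argmax into the input array (for the backward pass).
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int dx[4]; get_dims4(x, dx);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("pooling needs even height and width");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());  // double to hold large indices safely
  idx.attr("dim") = y.attr("dim");
  const double *px = x.begin();
  double *py = y.begin(), *pi = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t(n) * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          R_xlen_t i00 = base + R_xlen_t(2 * wo) * H + 2 * ho;
          R_xlen_t best = i00; double bv = px[i00];
          const R_xlen_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
          py[o] = bv; pi[o] = double(best); ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector idx, NumericVector gy, IntegerVector in_dim) {
  R_xlen_t sz = R_xlen_t(in_dim[0]) * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(sz);
  gx.attr("dim") = in_dim;
  const double *pi = idx.begin(), *pg = gy.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[R_xlen_t(pi[i])] += pg[i];
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  int dx[4]; get_dims4(x, dx);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector y(R_xlen_t(H) * 2 * W * 2 * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double *px = x.begin(); double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t bi = (R_xlen_t(n) * C + c) * H * W;
      const R_xlen_t bo = (R_xlen_t(n) * C + c) * 4 * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = px[bi + R_xlen_t(w) * H + h];
          R_xlen_t o = bo + R_xlen_t(2 * w) * 2 * H + 2 * h;
          py[o] = v; py[o + 1] = v;
          py[o + 2 * H] = v; py[o + 2 * H + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector gy) {
  int dg[4]; get_dims4(gy, dg);
  const int H2 = dg[0], W2 = dg[1], C = dg[2], N = dg[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pg = gy.begin(); double *px = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t bi = (R_xlen_t(n) * C + c) * H * W;
      const R_xlen_t bo = (R_xlen_t(n) * C + c) * H2 * W2;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          R_xlen_t o = bo + R_xlen_t(2 * w) * H2 + 2 * h;
          px[bi + R_xlen_t(w) * H + h] =
            pg[o] + pg[o + 1] + pg[o + H2] + pg[o + H2 + 1];
        }
    }
  return gx;
}
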