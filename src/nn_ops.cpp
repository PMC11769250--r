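// Batched 2-D convolution and pooling primitives for the branch networks.
// Convolution is stride-1 with "same" zero padding (odd kernels), computed
// as direct shift-and-accumulate passes over the (small) channel planes —
// cheaper than im2col for 3x3 kernels on few channels. All tensors are
// column-major R arrays: inputs (H, W, C, N), kernels (kh, kw, Cin, Cout).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector k,
                            NumericVector bias, bool tanh_act = false) {
  int dx[4], dk[4];
  get_dims4(x, dx); get_dims4(k, dk);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dk[0], kw = dk[1], Cout = dk[3];
  if (dk[2] != C) stop("kernel input channels do not match input");
  if (bias.size() != Cout) stop("bias length must equal output channels");
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const long HW = (long)H * W;
  NumericVector out(HW * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const double *kp = k.begin();
  for (long n = 0; n < N; ++n) {
    const double *xn = x.begin() + n * HW * C;
    double *on = out.begin() + n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      double *op = on + (long)co * HW;
      const double b = bias[co];
      for (long p = 0; p < HW; ++p) op[p] = b;
      for (int c = 0; c < C; ++c) {
        const double *xp = xn + (long)c * HW;
        for (int kj = 0; kj < kw; ++kj) {
          const int dj = kj - pw;
          const int jlo = dj < 0 ? -dj : 0, jhi = dj > 0 ? W - dj : W;
          for (int ki = 0; ki < kh; ++ki) {
            const double w = kp[ki + kh * (kj + kw * ((long)c + C * co))];
            if (w == 0.0) continue;
            const int di = ki - ph;
            const int ilo = di < 0 ? -di : 0, ihi = di > 0 ? H - di : H;
            for (int j = jlo; j < jhi; ++j) {
              const double *xcol = xp + (long)(j + dj) * H + di;
              double *ocol = op + (long)j * H;
              for (int i = ilo; i < ihi; ++i) ocol[i] += w * xcol[i];
            }
          }
        }
      }
      if (tanh_act)
        for (long p = 0; p < HW; ++p) op[p] = std::tanh(op[p]);
    }
  }
  return out;
}

// gradient w.r.t. input, kernel and bias given dz (pre-activation gradient)
// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector k, NumericVector dout) {
  int dx4[4], dk4[4], do4[4];
  get_dims4(x, dx4); get_dims4(k, dk4); get_dims4(dout, do4);
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int kh = dk4[0], kw = dk4[1], Cout = dk4[3];
  if (do4[0] != H || do4[1] != W || do4[2] != Cout || do4[3] != N)
    stop("dout shape mismatch");
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const long HW = (long)H * W;
  NumericVector dxv(x.size());
  dxv.attr("dim") = x.attr("dim");
  NumericVector dkv(k.size());
  dkv.attr("dim") = k.attr("dim");
  NumericVector dbv(Cout);
  const double *kp = k.begin();
  double *dkp = dkv.begin();
  for (long n = 0; n < N; ++n) {
    const double *xn = x.begin() + n * HW * C;
    double *dxn = dxv.begin() + n * HW * C;
    const double *don = dout.begin() + n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double *dop = don + (long)co * HW;
      double acc = 0;
      for (long p = 0; p < HW; ++p) acc += dop[p];
      dbv[co] += acc;
      for (int c = 0; c < C; ++c) {
        const double *xp = xn + (long)c * HW;
        double *dxp = dxn + (long)c * HW;
        for (int kj = 0; kj < kw; ++kj) {
          const int dj = kj - pw;
          const int jlo = dj < 0 ? -dj : 0, jhi = dj > 0 ? W - dj : W;
          for (int ki = 0; ki < kh; ++ki) {
            const long kidx = ki + kh * (kj + kw * ((long)c + C * co));
            const double w = kp[kidx];
            const int di = ki - ph;
            const int ilo = di < 0 ? -di : 0, ihi = di > 0 ? H - di : H;
            double s = 0;
            for (int j = jlo; j < jhi; ++j) {
              const double *xcol = xp + (long)(j + dj) * H + di;
              double *dxcol = dxp + (long)(j + dj) * H + di;
              const double *dcol = dop + (long)j * H;
              for (int i = ilo; i < ihi; ++i) {
                s += xcol[i] * dcol[i];
                dxcol[i] += w * dcol[i];
              }
            }
            dkp[kidx] += s;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dk"] = dkv, _["db"] = dbv);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x, int ph, int pw) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / ph, Wo = W / pw;
  if (Ho < 1 || Wo < 1) stop("pooling window larger than input");
  const long HWo = (long)Ho * Wo, HW = (long)H * W;
  NumericVector out(HWo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(HWo * C * N);   // 1-based linear index into the H*W plane
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (long nc = 0; nc < (long)C * N; ++nc) {
    const double *xp = x.begin() + nc * HW;
    double *op = out.begin() + nc * HWo;
    int *ip = idx.begin() + nc * HWo;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = -1e300; long barg = 0;
        for (int dj = 0; dj < pw; ++dj) {
          for (int di = 0; di < ph; ++di) {
            const long p = (long)(jo * pw + dj) * H + (io * ph + di);
            // NaN-propagating: !(x <= best) is true for NaN inputs
            if (!(xp[p] <= best)) { best = xp[p]; barg = p; }
          }
        }
        op[(long)jo * Ho + io] = best;
        ip[(long)jo * Ho + io] = (int)(barg + 1);
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector dout, IntegerVector idx,
                             int H, int W) {
  int d[4]; get_dims4(dout, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const long HWo = (long)Ho * Wo, HW = (long)H * W;
  NumericVector dx(HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (long nc = 0; nc < (long)C * N; ++nc) {
    const double *dp = dout.begin() + nc * HWo;
    const int *ip = idx.begin() + nc * HWo;
    double *xp = dx.begin() + nc * HW;
    for (long p = 0; p < HWo; ++p) xp[ip[p] - 1] += dp[p];
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_avgpool_fwd(NumericVector x, int ph, int pw) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / ph, Wo = W / pw;
  if (Ho < 1 || Wo < 1) stop("pooling window larger than input");
  const long HWo = (long)Ho * Wo, HW = (long)H * W;
  const double inv = 1.0 / (ph * pw);
  NumericVector out(HWo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (long nc = 0; nc < (long)C * N; ++nc) {
    const double *xp = x.begin() + nc * HW;
    double *op = out.begin() + nc * HWo;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        double s = 0;
        for (int dj = 0; dj < pw; ++dj)
          for (int di = 0; di < ph; ++di)
            s += xp[(long)(jo * pw + dj) * H + (io * ph + di)];
        op[(long)jo * Ho + io] = s * inv;
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nn_avgpool_bwd(NumericVector dout, int H, int W,
                             int ph, int pw) {
  int d[4]; get_dims4(dout, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const long HWo = (long)Ho * Wo, HW = (long)H * W;
  const double inv = 1.0 / (ph * pw);
  NumericVector dx(HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (long nc = 0; nc < (long)C * N; ++nc) {
    const double *dp = dout.begin() + nc * HWo;
    double *xp = dx.begin() + nc * HW;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        const double g = dp[(long)jo * Ho + io] * inv;
        for (int dj = 0; dj < pw; ++dj)
          for (int di = 0; di < ph; ++di)
            xp[(long)(jo * pw + dj) * H + (io * ph + di)] += g;
      }
  }
  return dx;
}

// tanh on a whole array in one pass (used by the dense layers)
// [[Rcpp::export]]
NumericVector nn_tanh(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (long i = 0; i < (long)x.size(); ++i) out[i] = std::tanh(x[i]);
  return out;
}
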