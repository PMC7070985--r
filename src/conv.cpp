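// Computational kernels: 3D convolution (im2col + GEMM) forward/backward,
// temporal max pooling, and batch normalization over 5D activations.
//
// Activation tensors use the layout (l, h, w, channels, batch), column-major
// as handed over from R arrays. Kernels use (d, kh, kw, c_in, c_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims5(const NumericVector &x, int d[5]) {
  IntegerVector dim = x.attr("dim");
  for (int i = 0; i < 5; ++i) d[i] = dim[i];
}

// Fill the im2col matrix (d*kh*kw*ci rows, lo*ho*wo cols) for sample s.
static void im2col(const double *x, int l, int h, int w, int ci,
                   int d, int kh, int kw, int pt, int ph, int pw,
                   int lo, int ho, int wo, arma::mat &col) {
  const long chan_stride = (long)l * h * w;
  int rr = 0;
  for (int c = 0; c < ci; ++c) {
    const double *xc = x + c * chan_stride;
    for (int dr = 0; dr < kw; ++dr)
      for (int dq = 0; dq < kh; ++dq)
        for (int dp = 0; dp < d; ++dp) {
          // row index consistent with kernel array layout (dp fastest)
          int row = dp + d * (dq + kh * (dr + kw * c));
          double *dst = col.memptr() + row; // stride = col.n_rows
          long p = 0;
          for (int ko = 0; ko < wo; ++ko) {
            int cc = ko - pw + dr;
            for (int jo = 0; jo < ho; ++jo) {
              int rrow = jo - ph + dq;
              for (int io = 0; io < lo; ++io, ++p) {
                int tt = io - pt + dp;
                double v = 0.0;
                if (tt >= 0 && tt < l && rrow >= 0 && rrow < h &&
                    cc >= 0 && cc < w)
                  v = xc[tt + (long)l * (rrow + (long)h * cc)];
                dst[p * col.n_rows] = v;
              }
            }
          }
          (void)rr;
        }
  }
}

// Scatter-add of a column matrix back into the (padded) input gradient.
static void col2im_add(double *gx, int l, int h, int w, int ci,
                       int d, int kh, int kw, int pt, int ph, int pw,
                       int lo, int ho, int wo, const arma::mat &col) {
  const long chan_stride = (long)l * h * w;
  for (int c = 0; c < ci; ++c) {
    double *gc = gx + c * chan_stride;
    for (int dr = 0; dr < kw; ++dr)
      for (int dq = 0; dq < kh; ++dq)
        for (int dp = 0; dp < d; ++dp) {
          int row = dp + d * (dq + kh * (dr + kw * c));
          const double *src = col.memptr() + row;
          long p = 0;
          for (int ko = 0; ko < wo; ++ko) {
            int cc = ko - pw + dr;
            for (int jo = 0; jo < ho; ++jo) {
              int rrow = jo - ph + dq;
              for (int io = 0; io < lo; ++io, ++p) {
                int tt = io - pt + dp;
                if (tt >= 0 && tt < l && rrow >= 0 && rrow < h &&
                    cc >= 0 && cc < w)
                  gc[tt + (long)l * (rrow + (long)h * cc)] += src[p * col.n_rows];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericVector wt,
                                 NumericVector bias, IntegerVector pad) {
  int dx[5]; get_dims5(x, dx);
  int l = dx[0], h = dx[1], w = dx[2], ci = dx[3], n = dx[4];
  IntegerVector dw = wt.attr("dim");
  int d = dw[0], kh = dw[1], kw = dw[2], co = dw[4];
  if (dw[3] != ci) stop("kernel input-channel mismatch");
  int pt = pad[0], ph = pad[1], pw = pad[2];
  int lo = l + 2 * pt - d + 1, ho = h + 2 * ph - kh + 1, wo = w + 2 * pw - kw + 1;
  if (lo < 1 || ho < 1 || wo < 1) stop("kernel larger than padded input");
  long rows = (long)d * kh * kw * ci, P = (long)lo * ho * wo;
  arma::mat Wm(const_cast<double *>(wt.begin()), rows, co, false, true);
  arma::mat col(rows, P);
  NumericVector y((R_xlen_t)lo * ho * wo * co * n);
  y.attr("dim") = IntegerVector::create(lo, ho, wo, co, n);
  const long in_s = (long)l * h * w * ci, out_s = (long)lo * ho * wo * co;
  arma::colvec bv(const_cast<double *>(bias.begin()), co, false, true);
  for (int s = 0; s < n; ++s) {
    im2col(x.begin() + s * in_s, l, h, w, ci, d, kh, kw, pt, ph, pw,
           lo, ho, wo, col);
    arma::mat ys = Wm.t() * col;           // co x P
    ys.each_col() += bv;
    // write transposed into (lo,ho,wo,co) layout
    double *dst = y.begin() + s * out_s;
    for (long p = 0; p < P; ++p)
      for (int o = 0; o < co; ++o)
        dst[p + o * P] = ys(o, p);
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericVector wt,
                         NumericVector gy, IntegerVector pad) {
  int dx[5]; get_dims5(x, dx);
  int l = dx[0], h = dx[1], w = dx[2], ci = dx[3], n = dx[4];
  IntegerVector dw = wt.attr("dim");
  int d = dw[0], kh = dw[1], kw = dw[2], co = dw[4];
  int pt = pad[0], ph = pad[1], pw = pad[2];
  int lo = l + 2 * pt - d + 1, ho = h + 2 * ph - kh + 1, wo = w + 2 * pw - kw + 1;
  long rows = (long)d * kh * kw * ci, P = (long)lo * ho * wo;
  arma::mat Wm(const_cast<double *>(wt.begin()), rows, co, false, true);
  arma::mat col(rows, P), Gy(co, P);
  NumericVector gx((R_xlen_t)l * h * w * ci * n);
  gx.attr("dim") = IntegerVector::create(l, h, w, ci, n);
  NumericVector gw((R_xlen_t)d * kh * kw * ci * co);
  gw.attr("dim") = IntegerVector::create(d, kh, kw, ci, co);
  NumericVector gb(co);
  arma::mat gW(gw.begin(), rows, co, false, true);
  arma::colvec gB(gb.begin(), co, false, true);
  const long in_s = (long)l * h * w * ci, out_s = (long)lo * ho * wo * co;
  for (int s = 0; s < n; ++s) {
    const double *gsrc = gy.begin() + s * out_s;
    for (long p = 0; p < P; ++p)
      for (int o = 0; o < co; ++o)
        Gy(o, p) = gsrc[p + o * P];
    im2col(x.begin() + s * in_s, l, h, w, ci, d, kh, kw, pt, ph, pw,
           lo, ho, wo, col);
    gW += col * Gy.t();
    gB += arma::sum(Gy, 1);
    arma::mat gcol = Wm * Gy;              // rows x P
    col2im_add(gx.begin() + s * in_s, l, h, w, ci, d, kh, kw, pt, ph, pw,
               lo, ho, wo, gcol);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Temporal max pooling with window s, stride s, and a boundary-truncated
// final window (output length ceil(l / s)).
// [[Rcpp::export]]
List pool_t_forward_cpp(NumericVector x, int s) {
  int dx[5]; get_dims5(x, dx);
  int l = dx[0], h = dx[1], w = dx[2], c = dx[3], n = dx[4];
  int lo = (l + s - 1) / s;
  NumericVector y((R_xlen_t)lo * h * w * c * n);
  y.attr("dim") = IntegerVector::create(lo, h, w, c, n);
  IntegerVector idx((R_xlen_t)lo * h * w * c * n);
  idx.attr("dim") = IntegerVector::create(lo, h, w, c, n);
  long ncols = (long)h * w * c * n;
  for (long col = 0; col < ncols; ++col) {
    const double *xc = x.begin() + col * l;
    double *yc = y.begin() + col * lo;
    int *ic = idx.begin() + col * lo;
    for (int io = 0; io < lo; ++io) {
      int t0 = io * s, t1 = std::min(l, t0 + s);
      double best = xc[t0]; int bi = t0;
      for (int t = t0 + 1; t < t1; ++t)
        if (xc[t] > best) { best = xc[t]; bi = t; }
      yc[io] = best; ic[io] = bi;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_t_backward_cpp(IntegerVector idx, NumericVector gy, int l_in) {
  IntegerVector dim = idx.attr("dim");
  int lo = dim[0], h = dim[1], w = dim[2], c = dim[3], n = dim[4];
  NumericVector gx((R_xlen_t)l_in * h * w * c * n);
  gx.attr("dim") = IntegerVector::create(l_in, h, w, c, n);
  long ncols = (long)h * w * c * n;
  for (long col = 0; col < ncols; ++col) {
    const double *gyc = gy.begin() + col * lo;
    const int *ic = idx.begin() + col * lo;
    double *gxc = gx.begin() + col * l_in;
    for (int io = 0; io < lo; ++io) gxc[ic[io]] += gyc[io];
  }
  return gx;
}

// Batch normalization over the channel axis of a (l, h, w, c, n) tensor.
// Returns the normalized output plus the caches backward needs.
// [[Rcpp::export]]
List bn5d_forward_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector run_mean, NumericVector run_var,
                      bool training, double momentum, double eps) {
  int dx[5]; get_dims5(x, dx);
  long spat = (long)dx[0] * dx[1] * dx[2];
  int c = dx[3], n = dx[4];
  long per_ch = spat * n;
  std::vector<double> mu(c), var(c);
  if (training) {
    for (int ch = 0; ch < c; ++ch) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < n; ++b) {
        const double *p = x.begin() + ((long)b * c + ch) * spat;
        for (long i = 0; i < spat; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu[ch] = s / per_ch;
      var[ch] = s2 / per_ch - mu[ch] * mu[ch];
      if (var[ch] < 0) var[ch] = 0;
    }
  } else {
    for (int ch = 0; ch < c; ++ch) { mu[ch] = run_mean[ch]; var[ch] = run_var[ch]; }
  }
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  NumericVector ivar(c), nm(c), nv(c);
  for (int ch = 0; ch < c; ++ch) {
    ivar[ch] = 1.0 / std::sqrt(var[ch] + eps);
    nm[ch] = training ? momentum * run_mean[ch] + (1 - momentum) * mu[ch] : run_mean[ch];
    nv[ch] = training ? momentum * run_var[ch] + (1 - momentum) * var[ch] : run_var[ch];
  }
  for (int b = 0; b < n; ++b)
    for (int ch = 0; ch < c; ++ch) {
      const double *p = x.begin() + ((long)b * c + ch) * spat;
      double *ph = xhat.begin() + ((long)b * c + ch) * spat;
      double *py = y.begin() + ((long)b * c + ch) * spat;
      double m = mu[ch], iv = ivar[ch], g = gamma[ch], bt = beta[ch];
      for (long i = 0; i < spat; ++i) {
        ph[i] = (p[i] - m) * iv;
        py[i] = g * ph[i] + bt;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["ivar"] = ivar,
                      _["run_mean"] = nm, _["run_var"] = nv);
}

// [[Rcpp::export]]
List bn5d_backward_cpp(NumericVector gy, NumericVector xhat, NumericVector ivar,
                       NumericVector gamma) {
  int dx[5]; get_dims5(gy, dx);
  long spat = (long)dx[0] * dx[1] * dx[2];
  int c = dx[3], n = dx[4];
  long m = spat * n;
  NumericVector ggamma(c), gbeta(c);
  for (int b = 0; b < n; ++b)
    for (int ch = 0; ch < c; ++ch) {
      const double *pg = gy.begin() + ((long)b * c + ch) * spat;
      const double *ph = xhat.begin() + ((long)b * c + ch) * spat;
      double sg = 0.0, sgx = 0.0;
      for (long i = 0; i < spat; ++i) { sg += pg[i]; sgx += pg[i] * ph[i]; }
      gbeta[ch] += sg; ggamma[ch] += sgx;
    }
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  for (int b = 0; b < n; ++b)
    for (int ch = 0; ch < c; ++ch) {
      const double *pg = gy.begin() + ((long)b * c + ch) * spat;
      const double *ph = xhat.begin() + ((long)b * c + ch) * spat;
      double *px = gx.begin() + ((long)b * c + ch) * spat;
      double g = gamma[ch], iv = ivar[ch];
      double sg = gbeta[ch], sgx = ggamma[ch];
      for (long i = 0; i < spat; ++i)
        px[i] = (iv * g / m) * (m * pg[i] - sg - ph[i] * sgx);
    }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
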