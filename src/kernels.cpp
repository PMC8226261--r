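// Dense CNN primitives for the vessel network. All tensors are R arrays in
// column-major (H, W, C, N) layout; convolution weights are (k, k, Cin, Cout).
// Stride is always 1 with "same" zero padding; pooling/upsampling are fixed 2x.
#include <RcppArmadillo.h>
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Forward convolution. 1x1 kernels reduce to a GEMM on the channel
// dimension; larger (3x3) kernels use direct shifted-accumulate loops,
// which beat im2col at the small channel counts this network uses.
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("square kernels only");
  if (Cin != C) stop("channel mismatch in conv2d");
  const int pad = k / 2;
  const size_t HW = (size_t)H * W;
  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  if (k == 1) {
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * HW * C,
                   HW, C, false, true);
      arma::mat ym(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
      ym = xm * Wm;
      ym.each_row() += bv;
    }
    return y;
  }
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    double* yn = y.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* yp = yn + (size_t)co * HW;
      const double bc = b[co];
      for (size_t t = 0; t < HW; ++t) yp[t] = bc;
      for (int ci = 0; ci < C; ++ci) {
        const double* xp = xn + (size_t)ci * HW;
        for (int kj = 0; kj < k; ++kj) {
          const int dj = kj - pad;
          for (int ki = 0; ki < k; ++ki) {
            const int di = ki - pad;
            const double wv = w[ki + k * (kj + k * (ci + (size_t)C * co))];
            if (wv == 0.0) continue;
            const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
            const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            for (int j = j0; j < j1; ++j) {
              double* yc = yp + (size_t)H * j;
              const double* xc = xp + (size_t)H * (j + dj) + di;
              for (int i = i0; i < i1; ++i) yc[i] += wv * xc[i];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    bool need_gx) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  const int pad = k / 2;
  const size_t HW = (size_t)H * W;
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  NumericVector gx;
  if (need_gx) { gx = NumericVector(x.size()); gx.attr("dim") = x.attr("dim"); }
  if (k == 1) {
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    arma::mat gWm(gw.begin(), C, Cout, false, true);
    arma::rowvec gbv(gb.begin(), Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * HW * C,
                   HW, C, false, true);
      arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)n * HW * Cout,
                    HW, Cout, false, true);
      gWm += xm.t() * gym;
      gbv += arma::sum(gym, 0);
      if (need_gx) {
        arma::mat gxm(gx.begin() + (size_t)n * HW * C, HW, C, false, true);
        gxm = gym * Wm.t();
      }
    }
    return List::create(_["gx"] = need_gx ? (RObject)gx : (RObject)R_NilValue,
                        _["gw"] = gw, _["gb"] = gb);
  }
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    const double* gyn = gy.begin() + (size_t)n * HW * Cout;
    double* gxn = need_gx ? gx.begin() + (size_t)n * HW * C : nullptr;
    for (int co = 0; co < Cout; ++co) {
      const double* gp = gyn + (size_t)co * HW;
      double s = 0;
      for (size_t t = 0; t < HW; ++t) s += gp[t];
      gb[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double* xp = xn + (size_t)ci * HW;
        double* gxp = need_gx ? gxn + (size_t)ci * HW : nullptr;
        for (int kj = 0; kj < k; ++kj) {
          const int dj = kj - pad;
          for (int ki = 0; ki < k; ++ki) {
            const int di = ki - pad;
            const size_t widx = ki + k * (kj + k * (ci + (size_t)C * co));
            const double wv = w[widx];
            const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
            const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            double acc = 0;
            for (int j = j0; j < j1; ++j) {
              const double* __restrict gc = gp + (size_t)H * j;
              const double* __restrict xc = xp + (size_t)H * (j + dj) + di;
              for (int i = i0; i < i1; ++i) acc += gc[i] * xc[i];
              if (need_gx) {
                double* __restrict gxc = gxp + (size_t)H * (j + dj) + di;
                for (int i = i0; i < i1; ++i) gxc[i] += wv * gc[i];
              }
            }
            gw[widx] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = need_gx ? (RObject)gx : (RObject)R_NilValue,
                      _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t t = 0; t < x.size(); ++t) y[t] = x[t] > 0 ? x[t] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector gy, NumericVector x) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[t] = x[t] > 0 ? gy[t] : 0.0;
  return gx;
}

// y += a (in-place gradient accumulation without an R-level copy)
// [[Rcpp::export]]
NumericVector add_into_cpp(NumericVector y, NumericVector a) {
  if (y.size() != a.size()) stop("size mismatch in add_into");
  for (R_xlen_t t = 0; t < y.size(); ++t) y[t] += a[t];
  return y;
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector y(HWo * C * N);
  IntegerVector idx(HWo * C * N);  // absolute linear index into x of the max
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = ((size_t)n * C + c) * HW;
      const size_t yoff = ((size_t)n * C + c) * HWo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t best = xoff + (size_t)(2 * j) * H + 2 * i;
          double bv = x[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int q = 0; q < 3; ++q)
            if (x[cand[q]] > bv) { bv = x[cand[q]]; best = cand[q]; }
          y[yoff + (size_t)j * Ho + i] = bv;
          idx[yoff + (size_t)j * Ho + i] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[idx[t]] += gy[t];
  return gx;
}

// Per-axis source indices/weights for the fixed 2x bilinear upsample
// (half-pixel-centre convention: src = (i + 0.5)/2 - 0.5).
static void up2_axis(int Hin, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& t, bool nearest) {
  const int Ho = 2 * Hin;
  i0.resize(Ho); i1.resize(Ho); t.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    if (nearest) { i0[i] = i / 2; i1[i] = i / 2; t[i] = 0.0; continue; }
    double s = (i + 0.5) * 0.5 - 0.5;
    int f = (int)std::floor(s);
    double tt = s - f;
    if (f < 0) { f = 0; tt = 0.0; }
    if (f >= Hin - 1) { f = Hin - 1; tt = 0.0; }
    i0[i] = f; i1[i] = std::min(f + 1, Hin - 1); t[i] = tt;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, std::string mode) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const bool nearest = (mode == "nearest");
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_axis(H, r0, r1, tr, nearest);
  up2_axis(W, c0, c1, tc, nearest);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * HW;
      double* ys = y.begin() + ((size_t)n * C + c) * HWo;
      for (int j = 0; j < Wo; ++j) {
        const double* xa = xs + (size_t)H * c0[j];
        const double* xb = xs + (size_t)H * c1[j];
        const double wj = tc[j];
        double* yj = ys + (size_t)Ho * j;
        for (int i = 0; i < Ho; ++i) {
          const double wi = tr[i];
          const double va = xa[r0[i]] * (1 - wi) + xa[r1[i]] * wi;
          const double vb = xb[r0[i]] * (1 - wi) + xb[r1[i]] * wi;
          yj[i] = va * (1 - wj) + vb * wj;
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector gy, IntegerVector xdim,
                                std::string mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const bool nearest = (mode == "nearest");
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_axis(H, r0, r1, tr, nearest);
  up2_axis(W, c0, c1, tc, nearest);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gs = gx.begin() + ((size_t)n * C + c) * HW;
      const double* gys = gy.begin() + ((size_t)n * C + c) * HWo;
      for (int j = 0; j < Wo; ++j) {
        double* ga = gs + (size_t)H * c0[j];
        double* gb = gs + (size_t)H * c1[j];
        const double wj = tc[j];
        const double* gj = gys + (size_t)Ho * j;
        for (int i = 0; i < Ho; ++i) {
          const double wi = tr[i], g = gj[i];
          ga[r0[i]] += g * (1 - wi) * (1 - wj);
          ga[r1[i]] += g * wi * (1 - wj);
          gb[r0[i]] += g * (1 - wi) * wj;
          gb[r1[i]] += g * wi * wj;
        }
      }
    }
  return gx;
}

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool train,
                double momentum, double eps, bool relu = false) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  NumericVector xhat, invstd(C), nmean(clone(rmean)), nvar(clone(rvar));
  if (train) { xhat = NumericVector(x.size()); xhat.attr("dim") = x.attr("dim"); }
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (train) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xs = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t t = 0; t < HW; ++t) { s += xs[t]; s2 += xs[t] * xs[t]; }
      }
      mu = s / M;
      var = std::max(0.0, s2 / M - mu * mu);
      nmean[c] = (1 - momentum) * nmean[c] + momentum * mu;
      nvar[c] = (1 - momentum) * nvar[c] + momentum * var;
    } else {
      mu = rmean[c]; var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* xs = x.begin() + off;
      double* ys = y.begin() + off;
      if (train) {
        double* hs = xhat.begin() + off;
        for (size_t t = 0; t < HW; ++t) {
          hs[t] = (xs[t] - mu) * is;
          const double v = g * hs[t] + b;
          ys[t] = (relu && v < 0) ? 0.0 : v;
        }
      } else {
        for (size_t t = 0; t < HW; ++t) {
          const double v = g * (xs[t] - mu) * is + b;
          ys[t] = (relu && v < 0) ? 0.0 : v;
        }
      }
    }
  }
  return List::create(_["y"] = y,
                      _["xhat"] = train ? (RObject)xhat : (RObject)R_NilValue,
                      _["invstd"] = invstd, _["rmean"] = nmean,
                      _["rvar"] = nvar);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector gy, NumericVector xhat, NumericVector invstd,
                NumericVector gamma, Nullable<NumericVector> y_post = R_NilValue,
                bool relu = false) {
  int H, W, C, N; get_dims4(gy, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector gx(gy.size()); gx.attr("dim") = gy.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  NumericVector yv;
  if (relu) {
    if (y_post.isNull()) stop("relu backward needs the activation output");
    yv = y_post.get();
  }
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* gs = gy.begin() + off;
      const double* hs = xhat.begin() + off;
      const double* ys = relu ? yv.begin() + off : nullptr;
      for (size_t t = 0; t < HW; ++t) {
        const double g = (relu && ys[t] <= 0) ? 0.0 : gs[t];
        sg += g; sgx += g * hs[t];
      }
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double a = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* gs = gy.begin() + off;
      const double* hs = xhat.begin() + off;
      const double* ys = relu ? yv.begin() + off : nullptr;
      double* gxs = gx.begin() + off;
      for (size_t t = 0; t < HW; ++t) {
        const double g = (relu && ys[t] <= 0) ? 0.0 : gs[t];
        gxs[t] = a * (g - sg / M - hs[t] * sgx / M);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
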