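// Dense network primitives for the patch segmentation model.
// Tensors are R arrays dim (H, W, C, N), column-major; viewed here as
// cubes with C*N slices (slice index = c + C*n). Convolution weights are
// matrices (Cout x kh*kw*Cin) with row index ki + kh*(kj + kw*c); the
// layout is internal and only needs to be consistent between forward
// and backward passes. im2col is batched over the whole mini-batch
// (row index ho + Ho*(wo + Wo*n)) so each layer runs as one GEMM.
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Large im2col buffers are allocated and freed once per layer call;
// with glibc's default mmap threshold every call pays the kernel
// page-fault cost again. Raising the thresholds keeps the arenas warm.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

static void im2col_all(const arma::cube& x, int C, int N, int kh, int kw,
                       int stride, int pad, int Ho, int Wo, arma::mat& M) {
  const int H = x.n_rows, W = x.n_cols;
  const size_t HoWo = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int rr = ki + kh * (kj + kw * c);
        double* dst = M.colptr(rr);
        for (int n = 0; n < N; ++n) {
          const arma::mat& ch = x.slice(n * C + c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            double* d = dst + (size_t)Ho * wo + HoWo * n;
            if (wi < 0 || wi >= W) {
              std::fill(d, d + Ho, 0.0);
              continue;
            }
            const double* src = ch.colptr(wi);
            const int hi0 = -pad + ki; // hi = ho*stride + hi0
            if (stride == 1 && hi0 >= 0 && hi0 + Ho <= H) {
              std::copy(src + hi0, src + hi0 + Ho, d);
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride + hi0;
                d[ho] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

static void col2im_all(arma::cube& dx, int C, int N, int kh, int kw,
                       int stride, int pad, int Ho, int Wo,
                       const arma::mat& dM) {
  const int H = dx.n_rows, W = dx.n_cols;
  const size_t HoWo = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int rr = ki + kh * (kj + kw * c);
        const double* srcc = dM.colptr(rr);
        for (int n = 0; n < N; ++n) {
          arma::mat& ch = dx.slice(n * C + c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            const double* s = srcc + (size_t)Ho * wo + HoWo * n;
            double* dcol = ch.colptr(wi);
            const int hi0 = -pad + ki;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + hi0;
              if (hi >= 0 && hi < H) dcol[hi] += s[ho];
            }
          }
        }
      }
    }
  }
}

// grow-only workspaces shared across calls (R is single-threaded); they
// avoid repeated large allocations and their first-touch page faults
static std::vector<double> g_ws_m, g_ws_dy, g_ws_dm;

static arma::mat workspace(std::vector<double>& buf, size_t rows,
                           size_t cols) {
  if (buf.size() < rows * cols) buf.resize(rows * cols);
  return arma::mat(buf.data(), rows, cols, false, true);
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector xv, int H, int W, int C, int N,
                           const arma::mat& Wm, const arma::vec& b,
                           int kh, int kw, int stride, int pad,
                           bool relu = false) {
  arma::cube x(xv.begin(), H, W, C * N, false, true);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = Wm.n_rows;
  const size_t HoWo = (size_t)Ho * Wo;
  arma::mat M = workspace(g_ws_m, (size_t)N * HoWo, kh * kw * C);
  im2col_all(x, C, N, kh, kw, stride, pad, Ho, Wo, M);
  arma::mat Y = workspace(g_ws_dy, (size_t)N * HoWo, Cout);
  Y = M * Wm.t(); // (N*Ho*Wo) x Cout
  NumericVector yv(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  arma::cube y(yv.begin(), Ho, Wo, Cout * N, false, true);
  for (int co = 0; co < Cout; ++co) {
    const double* src = Y.colptr(co);
    const double bias = b(co);
    for (int n = 0; n < N; ++n) {
      double* dst = y.slice(n * Cout + co).memptr();
      const double* s = src + HoWo * n;
      if (relu)
        for (size_t i = 0; i < HoWo; ++i) {
          const double v = s[i] + bias;
          dst[i] = v > 0 ? v : 0;
        }
      else
        for (size_t i = 0; i < HoWo; ++i) dst[i] = s[i] + bias;
    }
  }
  yv.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return yv;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector xv, int H, int W, int C, int N,
                  const arma::mat& Wm, int kh, int kw, int stride, int pad,
                  NumericVector dyv, bool want_dx = true) {
  arma::cube x(xv.begin(), H, W, C * N, false, true);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = Wm.n_rows;
  const size_t HoWo = (size_t)Ho * Wo;
  arma::cube dy(dyv.begin(), Ho, Wo, Cout * N, false, true);
  arma::mat M = workspace(g_ws_m, (size_t)N * HoWo, kh * kw * C);
  im2col_all(x, C, N, kh, kw, stride, pad, Ho, Wo, M);
  arma::mat dY = workspace(g_ws_dy, (size_t)N * HoWo, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* dst = dY.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* src = dy.slice(n * Cout + co).memptr();
      std::copy(src, src + HoWo, dst + HoWo * n);
    }
  }
  arma::mat dW = dY.t() * M;                   // Cout x K
  arma::vec db = arma::sum(dY, 0).t();         // Cout
  if (!want_dx)
    return List::create(_["dx"] = R_NilValue, _["dW"] = dW, _["db"] = db);
  arma::mat dM = workspace(g_ws_dm, (size_t)N * HoWo, kh * kw * C);
  dM = dY * Wm;                                // (N*Ho*Wo) x K
  NumericVector dxv(static_cast<R_xlen_t>(H) * W * C * N);
  arma::cube dx(dxv.begin(), H, W, C * N, false, true);
  col2im_all(dx, C, N, kh, kw, stride, pad, Ho, Wo, dM);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dxv, _["dW"] = dW, _["db"] = db);
}

// Adaptive average pooling to bins x bins (half-open integer bins).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector xv, int H, int W, int C, int N,
                              int bins) {
  arma::cube x(xv.begin(), H, W, C * N, false, true);
  NumericVector yv(static_cast<R_xlen_t>(bins) * bins * C * N);
  arma::cube y(yv.begin(), bins, bins, C * N, false, true);
  for (int s = 0; s < C * N; ++s) {
    for (int bj = 0; bj < bins; ++bj) {
      const int c0 = (bj * W) / bins, c1 = ((bj + 1) * W) / bins;
      for (int bi = 0; bi < bins; ++bi) {
        const int r0 = (bi * H) / bins, r1 = ((bi + 1) * H) / bins;
        y.slice(s)(bi, bj) =
          arma::accu(x.slice(s).submat(r0, c0, r1 - 1, c1 - 1)) /
          ((r1 - r0) * (c1 - c0));
      }
    }
  }
  yv.attr("dim") = IntegerVector::create(bins, bins, C, N);
  return yv;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dyv, int bins, int C, int N,
                              int H, int W) {
  arma::cube dy(dyv.begin(), bins, bins, C * N, false, true);
  NumericVector dxv(static_cast<R_xlen_t>(H) * W * C * N);
  arma::cube dx(dxv.begin(), H, W, C * N, false, true);
  for (int s = 0; s < C * N; ++s) {
    for (int bj = 0; bj < bins; ++bj) {
      const int c0 = (bj * W) / bins, c1 = ((bj + 1) * W) / bins;
      for (int bi = 0; bi < bins; ++bi) {
        const int r0 = (bi * H) / bins, r1 = ((bi + 1) * H) / bins;
        const double g = dy.slice(s)(bi, bj) / ((r1 - r0) * (c1 - c0));
        dx.slice(s).submat(r0, c0, r1 - 1, c1 - 1) += g;
      }
    }
  }
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  return dxv;
}

struct LinIdx { int i0, i1; double w0, w1; };

static std::vector<LinIdx> bilinear_axis(int in, int out) {
  // half-pixel-centre sampling (align_corners = false convention)
  std::vector<LinIdx> v(out);
  const double scale = static_cast<double>(in) / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    const int i0 = static_cast<int>(std::floor(src));
    const int i1 = std::min(i0 + 1, in - 1);
    const double w1 = src - i0;
    v[o] = {i0, i1, 1.0 - w1, w1};
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector xv, int H, int W, int C, int N,
                               int Ho, int Wo) {
  arma::cube x(xv.begin(), H, W, C * N, false, true);
  NumericVector yv(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  arma::cube y(yv.begin(), Ho, Wo, C * N, false, true);
  const std::vector<LinIdx> ri = bilinear_axis(H, Ho);
  const std::vector<LinIdx> ci = bilinear_axis(W, Wo);
  for (int s = 0; s < C * N; ++s) {
    const arma::mat& xs = x.slice(s);
    arma::mat& ys = y.slice(s);
    for (int c = 0; c < Wo; ++c) {
      const LinIdx& cj = ci[c];
      const double* x0 = xs.colptr(cj.i0);
      const double* x1 = xs.colptr(cj.i1);
      double* yc = ys.colptr(c);
      for (int r = 0; r < Ho; ++r) {
        const LinIdx& rj = ri[r];
        yc[r] = rj.w0 * (cj.w0 * x0[rj.i0] + cj.w1 * x1[rj.i0]) +
                rj.w1 * (cj.w0 * x0[rj.i1] + cj.w1 * x1[rj.i1]);
      }
    }
  }
  yv.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return yv;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector dyv, int Ho, int Wo, int C, int N,
                               int H, int W) {
  arma::cube dy(dyv.begin(), Ho, Wo, C * N, false, true);
  NumericVector dxv(static_cast<R_xlen_t>(H) * W * C * N);
  arma::cube dx(dxv.begin(), H, W, C * N, false, true);
  const std::vector<LinIdx> ri = bilinear_axis(H, Ho);
  const std::vector<LinIdx> ci = bilinear_axis(W, Wo);
  for (int s = 0; s < C * N; ++s) {
    arma::mat& dxs = dx.slice(s);
    const arma::mat& dys = dy.slice(s);
    for (int c = 0; c < Wo; ++c) {
      const LinIdx& cj = ci[c];
      double* d0 = dxs.colptr(cj.i0);
      double* d1 = dxs.colptr(cj.i1);
      const double* g = dys.colptr(c);
      for (int r = 0; r < Ho; ++r) {
        const LinIdx& rj = ri[r];
        d0[rj.i0] += rj.w0 * cj.w0 * g[r];
        d1[rj.i0] += rj.w0 * cj.w1 * g[r];
        d0[rj.i1] += rj.w1 * cj.w0 * g[r];
        d1[rj.i1] += rj.w1 * cj.w1 * g[r];
      }
    }
  }
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  return dxv;
}

// sigmoid + loss gradients computed natively to keep the training loop
// lean: given upsampled logits, truth, and loss parameters, returns the
// probability map, the loss components, and dL/dlogit.
// Jaccard is per-sample-averaged; focal is a mean over all pixels.
// [[Rcpp::export]]
List cpp_sigmoid_loss(NumericVector upv, NumericVector truthv, int npix,
                      int N, double w_j, double w_f, double smooth,
                      double gamma, double alpha) {
  const double eps = 1e-7;
  const R_xlen_t total = upv.size();
  NumericVector probv(total);
  NumericVector gradv(total); // dL/d(logit)
  const double* up = upv.begin();
  const double* tr = truthv.begin();
  double* pr = probv.begin();
  double* gd = gradv.begin();
  double loss_j = 0, loss_f = 0;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t off = (R_xlen_t)npix * n;
    for (R_xlen_t i = 0; i < npix; ++i)
      pr[off + i] = 1.0 / (1.0 + std::exp(-up[off + i]));
    if (w_j > 0) {
      double inter = 0, sp = 0, st = 0;
      for (R_xlen_t i = 0; i < npix; ++i) {
        inter += pr[off + i] * tr[off + i];
        sp += pr[off + i];
        st += tr[off + i];
      }
      const double u = sp + st - inter;
      loss_j += (1.0 - (inter + smooth) / (u + smooth)) / N;
      const double denom = (u + smooth) * (u + smooth);
      for (R_xlen_t i = 0; i < npix; ++i) {
        const double t = tr[off + i];
        const double dj = -(t * (u + smooth) - (inter + smooth) * (1.0 - t)) /
          denom / N;
        gd[off + i] += w_j * dj;
      }
    }
  }
  if (w_f > 0) {
    const double inv_total = 1.0 / (double)total;
    const bool g2 = (gamma == 2.0), g1 = (gamma == 1.0), g0 = (gamma == 0.0);
    for (R_xlen_t i = 0; i < total; ++i) {
      double p = pr[i];
      if (p < eps) p = eps;
      if (p > 1 - eps) p = 1 - eps;
      const double t = tr[i];
      const double pt = t > 0 ? p : 1.0 - p;
      const double om = 1.0 - pt;
      const double lg = std::log(pt);
      const double omg = g2 ? om * om : (g1 ? om : (g0 ? 1.0 :
        std::pow(om, gamma)));
      loss_f += -alpha * omg * lg * inv_total;
      double dpt;
      if (g0) dpt = -alpha / pt;
      else {
        const double omg1 = g2 ? om : (g1 ? 1.0 : std::pow(om, gamma - 1.0));
        dpt = alpha * gamma * omg1 * lg - alpha * omg / pt;
      }
      const double sgn = t > 0 ? 1.0 : -1.0;
      gd[i] += w_f * dpt * sgn * inv_total;
    }
  }
  // chain through the sigmoid
  for (R_xlen_t i = 0; i < total; ++i) gd[i] *= pr[i] * (1.0 - pr[i]);
  probv.attr("dim") = upv.attr("dim");
  gradv.attr("dim") = upv.attr("dim");
  return List::create(_["prob"] = probv, _["grad_logit"] = gradv,
                      _["loss"] = w_j * loss_j + w_f * loss_f,
                      _["jaccard"] = loss_j, _["focal"] = loss_f);
}
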