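// Minimal CNN layer kernels for desk-scale training on one CPU core.
// Convolution is stride-1 zero-padded, computed in single precision via a
// batched im2col + GEMM (all instances of a bag share one column matrix);
// max pooling caches argmax indices; adaptive average pooling bins like the
// usual adaptive-pool convention. Batch layout is column-major (H, W, C, N),
// matching R arrays. Parameters and activations cross the R boundary as
// doubles; float is an internal speed choice.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

#include <malloc.h>
#include <dlfcn.h>
#include <vector>

// Keep large scratch blocks heap-resident between calls instead of paying
// mmap/page-fault cost on every layer call.
// [[Rcpp::export]]
void tune_allocator() {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
}

// Run BLAS single-threaded: the layer GEMMs are too small to gain from
// threading, and a fixed thread count keeps reduction order -- and hence
// training trajectories -- bit-reproducible across machines.
// [[Rcpp::export]]
void limit_blas_threads() {
  typedef void (*setfn)(int);
  void* self = dlopen(NULL, RTLD_NOW | RTLD_GLOBAL);
  if (!self) return;
  const char* names[] = {"openblas_set_num_threads", "goto_set_num_threads",
                         "blas_set_num_threads"};
  for (const char* nm : names) {
    if (setfn f = reinterpret_cast<setfn>(dlsym(self, nm))) {
      f(1);
      break;
    }
  }
  dlclose(self);
}

static float* scratch(int slot, size_t n) {
  static std::vector<float> bufs[4];
  if (bufs[slot].size() < n) bufs[slot].resize(n);
  return bufs[slot].data();
}

// im2col for the whole batch: rows are sample-major blocks of Ho*Wo. The
// inner loops are branch-free over the valid range so they vectorise.
static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int pad, int Ho, int Wo, float* Mbuf) {
  const size_t R = (size_t)Ho * Wo;
  const size_t RN = R * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = ki + (size_t)kh * (kj + (size_t)kw * c);
        float* mcol = Mbuf + RN * col;
        const int ho0 = std::max(0, pad - ki);
        const int ho1 = std::min(Ho, H + pad - ki);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          float* m = mcol + R * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo - pad + kj;
            float* mrow = m + (size_t)Ho * wo;
            if (w < 0 || w >= W) {
              std::fill(mrow, mrow + Ho, 0.0f);
              continue;
            }
            const double* src = xc + (size_t)H * w + (ho0 - pad + ki);
            for (int ho = 0; ho < ho0; ++ho) mrow[ho] = 0.0f;
            for (int ho = ho0; ho < ho1; ++ho) mrow[ho] = (float)src[ho - ho0];
            for (int ho = ho1; ho < Ho; ++ho) mrow[ho] = 0.0f;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector X, NumericVector Wt, NumericVector b,
                        int pad, bool relu = false) {
  IntegerVector dx = X.attr("dim"), dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], F = dw[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const size_t R = (size_t)Ho * Wo, RN = R * N, K = (size_t)kh * kw * C;
  float* Mbuf = scratch(0, RN * K);
  im2col_batch(X.begin(), H, W, C, N, kh, kw, pad, Ho, Wo, Mbuf);
  arma::fmat M(Mbuf, RN, K, false, true);
  const arma::mat Wd(const_cast<double*>(Wt.begin()), K, F, false, true);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat Y(scratch(1, RN * F), RN, F, false, true);
  Y = M * Wf;
  NumericVector out((R_xlen_t)R * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  for (int n = 0; n < N; ++n) {
    double* on = out.begin() + R * F * n;
    for (int f = 0; f < F; ++f) {
      const float* yc = Y.colptr(f) + R * n;
      const double bf = b[f];
      double* oc = on + R * f;
      if (relu) {
        for (size_t r = 0; r < R; ++r) {
          const double v = (double)yc[r] + bf;
          oc[r] = v > 0.0 ? v : 0.0;
        }
      } else {
        for (size_t r = 0; r < R; ++r) oc[r] = (double)yc[r] + bf;
      }
    }
  }
  return out;
}

// Backward for conv2d_fw. If the forward was fused with ReLU, pass the
// forward output Y and the incoming gradient is masked where Y == 0.
// [[Rcpp::export]]
List conv2d_bw(NumericVector X, NumericVector Wt, NumericVector dY, int pad,
               Nullable<NumericVector> Yrelu = R_NilValue, bool need_dx = true) {
  IntegerVector dx = X.attr("dim"), dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], F = dw[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const size_t R = (size_t)Ho * Wo, RN = R * N, K = (size_t)kh * kw * C;
  float* Mbuf = scratch(0, RN * K);
  im2col_batch(X.begin(), H, W, C, N, kh, kw, pad, Ho, Wo, Mbuf);
  arma::fmat M(Mbuf, RN, K, false, true);
  const arma::mat Wd(const_cast<double*>(Wt.begin()), K, F, false, true);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wd);
  // gather dY into sample-major row blocks (masked by the fused ReLU if any)
  arma::fmat dYf(scratch(1, RN * F), RN, F, false, true);
  const double* yr = Yrelu.isNotNull() ? NumericVector(Yrelu).begin() : nullptr;
  for (int n = 0; n < N; ++n) {
    const double* dn = dY.begin() + R * F * n;
    const double* yn = yr ? yr + R * F * n : nullptr;
    for (int f = 0; f < F; ++f) {
      float* dc = dYf.colptr(f) + R * n;
      const double* sc = dn + R * f;
      if (yn) {
        const double* yc = yn + R * f;
        for (size_t r = 0; r < R; ++r) dc[r] = yc[r] > 0.0 ? (float)sc[r] : 0.0f;
      } else {
        for (size_t r = 0; r < R; ++r) dc[r] = (float)sc[r];
      }
    }
  }
  arma::fmat dWf = M.t() * dYf;
  arma::frowvec dbf = arma::sum(dYf, 0);
  NumericVector dW((R_xlen_t)K * F);
  dW.attr("dim") = dw;
  std::copy(dWf.begin(), dWf.end(), dW.begin());
  NumericVector db(F);
  std::copy(dbf.begin(), dbf.end(), db.begin());
  if (!need_dx) {
    return List::create(_["dX"] = R_NilValue, _["dW"] = dW, _["db"] = db);
  }
  arma::fmat dM(scratch(2, RN * K), RN, K, false, true);
  dM = dYf * Wf.t();
  NumericVector dX((R_xlen_t)H * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = ki + (size_t)kh * (kj + (size_t)kw * c);
        const float* mcol = dM.colptr(col);
        const int ho0 = std::max(0, pad - ki);
        const int ho1 = std::min(Ho, H + pad - ki);
        for (int n = 0; n < N; ++n) {
          double* dxc = dX.begin() + (size_t)H * W * (c + (size_t)C * n);
          const float* m = mcol + R * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo - pad + kj;
            if (w < 0 || w >= W) continue;
            double* dst = dxc + (size_t)H * w + (ho0 - pad + ki);
            const float* mrow = m + (size_t)Ho * wo;
            for (int ho = ho0; ho < ho1; ++ho) dst[ho - ho0] += (double)mrow[ho];
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector X, int q) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = H / q, Wo = W / q;
  const R_xlen_t M = (R_xlen_t)Ho * Wo * C * N;
  NumericVector Y(M);
  IntegerVector idx(M); // 0-based linear index into X of each max
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* x = X.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; size_t bi = 0;
          for (int dj = 0; dj < q; ++dj) {
            const size_t colb = base + (size_t)H * (wo * q + dj) + ho * q;
            for (int di = 0; di < q; ++di)
              if (x[colb + di] > best) { best = x[colb + di]; bi = colb + di; }
          }
          Y[o] = best; idx[o] = (int)bi; ++o;
        }
    }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(IntegerVector idx, IntegerVector xdim, NumericVector dY) {
  NumericVector dX((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dX.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dY.size(); ++i) dX[idx[i]] += dY[i];
  return dX;
}

// [[Rcpp::export]]
NumericVector adaptpool_fw(NumericVector X, int oh, int ow) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector Y((R_xlen_t)oh * ow * C * N);
  Y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  const double* x = X.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        const int w0 = (j * W) / ow, w1 = ((j + 1) * W + ow - 1) / ow;
        for (int i = 0; i < oh; ++i) {
          const int h0 = (i * H) / oh, h1 = ((i + 1) * H + oh - 1) / oh;
          double s = 0.0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) s += x[base + (size_t)H * w + h];
          Y[o++] = s / ((h1 - h0) * (w1 - w0));
        }
      }
    }
  return Y;
}

// [[Rcpp::export]]
NumericVector adaptpool_bw(IntegerVector xdim, int oh, int ow, NumericVector dY) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dX((R_xlen_t)H * W * C * N);
  dX.attr("dim") = xdim;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        const int w0 = (j * W) / ow, w1 = ((j + 1) * W + ow - 1) / ow;
        for (int i = 0; i < oh; ++i) {
          const int h0 = (i * H) / oh, h1 = ((i + 1) * H + oh - 1) / oh;
          const double g = dY[o++] / ((h1 - h0) * (w1 - w0));
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) dX[base + (size_t)H * w + h] += g;
        }
      }
    }
  return dX;
}

// Fused in-place Adam step. params, m and v are updated by reference; the
// caller owns them exclusively during training (checkpoints are deep-copied).
// idx maps each grads element to its (1-based) position in params/m/v;
// integer indexing avoids Rcpp's slow by-name list access in the hot loop.
// [[Rcpp::export]]
void adam_step_inplace(List params, List grads, List m, List v,
                       IntegerVector idx, int t,
                       double lr, double beta1, double beta2, double eps) {
  const double c1 = 1.0 - std::pow(beta1, (double)t);
  const double c2 = 1.0 - std::pow(beta2, (double)t);
  for (int i = 0; i < idx.size(); ++i) {
    const int k = idx[i] - 1;
    double* g = REAL(VECTOR_ELT(grads, i));
    double* p = REAL(VECTOR_ELT(params, k));
    double* mi = REAL(VECTOR_ELT(m, k));
    double* vi = REAL(VECTOR_ELT(v, k));
    const R_xlen_t len = Rf_xlength(VECTOR_ELT(grads, i));
    for (R_xlen_t j = 0; j < len; ++j) {
      mi[j] = beta1 * mi[j] + (1.0 - beta1) * g[j];
      vi[j] = beta2 * vi[j] + (1.0 - beta2) * g[j] * g[j];
      p[j] -= lr * (mi[j] / c1) / (std::sqrt(vi[j] / c2) + eps);
    }
  }
}
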