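#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Layout convention for all 4-D tensors: column-major (H, W, C, N),
// i.e. x[h + H*(w + W*(c + C*n))].  1-D signals use H = 1.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims,
                         int kh, int kw, int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const size_t rows = (size_t)OH * OW * N;
  const int cols = kh * kw * C;
  NumericMatrix out((int)rows, cols);
  const double* xp = x.begin();
  double* op0 = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * (size_t)H * W;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int col = ki + kh * (kj + kw * c);
          double* op = op0 + (size_t)col * rows;
          for (int j = 0; j < OW; ++j) {
            const int win = j * stride - pad + kj;
            const bool wok = (win >= 0 && win < W);
            const size_t rbase = (size_t)OH * (j + (size_t)OW * n);
            if (!wok) continue;  // column pre-zeroed
            const size_t cbase = base + (size_t)win * H;
            for (int i = 0; i < OH; ++i) {
              const int hin = i * stride - pad + ki;
              if (hin >= 0 && hin < H)
                op[rbase + i] = xp[cbase + hin];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix colmat, IntegerVector dims,
                         int kh, int kw, int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const size_t rows = (size_t)OH * OW * N;
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp0 = colmat.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * (size_t)H * W;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int col = ki + kh * (kj + kw * c);
          const double* cp = cp0 + (size_t)col * rows;
          for (int j = 0; j < OW; ++j) {
            const int win = j * stride - pad + kj;
            if (win < 0 || win >= W) continue;
            const size_t rbase = (size_t)OH * (j + (size_t)OW * n);
            const size_t cbase = base + (size_t)win * H;
            for (int i = 0; i < OH; ++i) {
              const int hin = i * stride - pad + ki;
              if (hin >= 0 && hin < H)
                xp[cbase + hin] += cp[rbase + i];
            }
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, IntegerVector dims,
                 int kh, int kw, int stride) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int OH = (H - kh) / stride + 1;
  const int OW = (W - kw) / stride + 1;
  const size_t olen = (size_t)OH * OW * C * N;
  NumericVector out(olen);
  IntegerVector arg(olen);
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * (size_t)H * W;
      for (int j = 0; j < OW; ++j) {
        const int w0 = j * stride;
        for (int i = 0; i < OH; ++i) {
          const int h0 = i * stride;
          double best = R_NegInf;
          size_t bidx = 0;
          for (int kj = 0; kj < kw; ++kj) {
            const size_t cb = base + (size_t)(w0 + kj) * H;
            for (int ki = 0; ki < kh; ++ki) {
              const double v = xp[cb + h0 + ki];
              if (v > best) { best = v; bidx = cb + h0 + ki; }
            }
          }
          // output layout (OH, OW, C, N): o = i + OH*(j + OW*(c + C*n))
          const size_t oo = (size_t)i +
            (size_t)OH * (j + (size_t)OW * (c + (size_t)C * n));
          out[oo] = best;
          arg[oo] = (int)(bidx + 1);  // 1-based into x
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["odims"] = IntegerVector::create(OH, OW, C, N));
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector argmax, NumericVector dout,
                                   double len) {
  NumericVector dx((size_t)len);
  const size_t n = dout.size();
  for (size_t i = 0; i < n; ++i)
    dx[(size_t)argmax[i] - 1] += dout[i];
  return dx;
}

// Direct-form II transposed IIR filter, a[0]-normalized.
// [[Rcpp::export]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  const int nz = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0)
      z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}

// Single-precision GEMM through the BLAS R links against; the engine's
// heavy convolution products do not need double precision and sgemm is
// ~2x dgemm on one core.
extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

// [[Rcpp::export]]
NumericMatrix cpp_gemm32(NumericMatrix A, NumericMatrix B,
                         bool ta, bool tb) {
  const int m = ta ? A.ncol() : A.nrow();
  const int k = ta ? A.nrow() : A.ncol();
  const int kb = tb ? B.ncol() : B.nrow();
  const int n = tb ? B.nrow() : B.ncol();
  if (k != kb) stop("gemm dimension mismatch");
  std::vector<float> fa(A.begin(), A.end());
  std::vector<float> fb(B.begin(), B.end());
  std::vector<float> fc((size_t)m * n);
  const float alpha = 1.0f, beta = 0.0f;
  const int lda = A.nrow(), ldb = B.nrow();
  sgemm_(ta ? "T" : "N", tb ? "T" : "N", &m, &n, &k, &alpha,
         fa.data(), &lda, fb.data(), &ldb, &beta, fc.data(), &m);
  NumericMatrix C(m, n);
  std::copy(fc.begin(), fc.end(), C.begin());
  return C;
}

// ---- fused single-precision convolution layers ----
// Building the im2col tiles per sample in float and calling sgemm on
// them avoids ever materializing (and converting) the full column
// matrix in double precision, which dominates the cost of the naive
// path on one core.

static void im2col_tile(const float* xs, int H, int W, int C,
                        int kh, int kw, int stride, int pad,
                        int OH, int OW, float* col) {
  // col: (OH*OW) x (kh*kw*C), column-major
  const size_t rows = (size_t)OH * OW;
  for (int c = 0; c < C; ++c) {
    const float* xc = xs + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        float* cp = col + ((size_t)(ki + kh * (kj + kw * c))) * rows;
        for (int j = 0; j < OW; ++j) {
          const int win = j * stride - pad + kj;
          float* cpj = cp + (size_t)OH * j;
          if (win < 0 || win >= W) {
            std::fill(cpj, cpj + OH, 0.0f);
            continue;
          }
          const float* xcw = xc + (size_t)win * H;
          for (int i = 0; i < OH; ++i) {
            const int hin = i * stride - pad + ki;
            cpj[i] = (hin >= 0 && hin < H) ? xcw[hin] : 0.0f;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_forward32(NumericVector x, IntegerVector dims,
                                 NumericMatrix W, NumericVector b,
                                 int kh, int kw, int stride, int pad) {
  const int H = dims[0], Wd = dims[1], C = dims[2], N = dims[3];
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (Wd + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, F = W.ncol();
  const size_t tile = (size_t)OH * OW;
  std::vector<float> xf(x.begin(), x.end());
  std::vector<float> Wf(W.begin(), W.end());
  std::vector<float> bf(b.begin(), b.end());
  std::vector<float> col(tile * K), outf(tile * F);
  NumericMatrix out((int)(tile * N), F);
  const float one = 1.0f, zero = 0.0f;
  const int m = (int)tile;
  for (int n = 0; n < N; ++n) {
    im2col_tile(xf.data() + (size_t)n * H * Wd * C, H, Wd, C,
                kh, kw, stride, pad, OH, OW, col.data());
    sgemm_("N", "N", &m, &F, &K, &one, col.data(), &m, Wf.data(), &K,
           &zero, outf.data(), &m);
    for (int f = 0; f < F; ++f) {
      double* op = &out((int)((size_t)n * tile), f);
      const float* sp = outf.data() + (size_t)f * tile;
      const float bias = bf[f];
      for (size_t i = 0; i < tile; ++i) op[i] = sp[i] + bias;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_backward32(NumericVector x, IntegerVector dims,
                         NumericMatrix W, NumericMatrix gmat,
                         int kh, int kw, int stride, int pad) {
  const int H = dims[0], Wd = dims[1], C = dims[2], N = dims[3];
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (Wd + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, F = W.ncol();
  const size_t tile = (size_t)OH * OW;
  std::vector<float> xf(x.begin(), x.end());
  std::vector<float> Wf(W.begin(), W.end());
  std::vector<float> gf(gmat.begin(), gmat.end());  // (tile*N) x F
  std::vector<float> col(tile * K), gtile(tile * F), dcol(tile * K);
  std::vector<float> dWf((size_t)K * F, 0.0f), dxf((size_t)H * Wd * C * N,
                                                   0.0f);
  std::vector<double> db(F, 0.0);
  const float one = 1.0f, zero = 0.0f;
  const int m = (int)tile;
  const size_t grows = tile * N;
  for (int n = 0; n < N; ++n) {
    im2col_tile(xf.data() + (size_t)n * H * Wd * C, H, Wd, C,
                kh, kw, stride, pad, OH, OW, col.data());
    for (int f = 0; f < F; ++f) {
      const float* gp = gf.data() + (size_t)f * grows + (size_t)n * tile;
      float* tp = gtile.data() + (size_t)f * tile;
      double acc = 0.0;
      for (size_t i = 0; i < tile; ++i) { tp[i] = gp[i]; acc += gp[i]; }
      db[f] += acc;
    }
    // dW += col' * gtile
    sgemm_("T", "N", &K, &F, &m, &one, col.data(), &m, gtile.data(), &m,
           &one, dWf.data(), &K);
    // dcol = gtile * W'
    sgemm_("N", "T", &m, &K, &F, &one, gtile.data(), &m, Wf.data(), &K,
           &zero, dcol.data(), &m);
    // col2im accumulate into dxf
    float* dxs = dxf.data() + (size_t)n * H * Wd * C;
    for (int c = 0; c < C; ++c) {
      float* dxc = dxs + (size_t)c * H * Wd;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const float* cp = dcol.data() +
            ((size_t)(ki + kh * (kj + kw * c))) * tile;
          for (int j = 0; j < OW; ++j) {
            const int win = j * stride - pad + kj;
            if (win < 0 || win >= Wd) continue;
            const float* cpj = cp + (size_t)OH * j;
            float* dxw = dxc + (size_t)win * H;
            for (int i = 0; i < OH; ++i) {
              const int hin = i * stride - pad + ki;
              if (hin >= 0 && hin < H) dxw[hin] += cpj[i];
            }
          }
        }
      }
    }
  }
  NumericMatrix dW(K, F);
  std::copy(dWf.begin(), dWf.end(), dW.begin());
  NumericVector dx((size_t)H * Wd * C * N);
  std::copy(dxf.begin(), dxf.end(), dx.begin());
  return List::create(_["dW"] = dW, _["db"] = NumericVector(db.begin(),
                                                            db.end()),
                      _["dx"] = dx);
}
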