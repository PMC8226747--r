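// Numeric kernels for the segmentation network and instance labeling.
// Tensors are R arrays in H x W x C x N layout (column-major), double precision.
// Convolutions are 3x3, stride 1, zero padding 1 ("same"); implemented as
// im2col + BLAS gemm via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col in single precision: the conv gemms run in fp32 (the standard
// precision for CNN training); everything around them stays double.
// rows: H*W pixels (h + H*w); cols: kh + 3*kw + 9*c (matches column-major
// flattening of a 3x3xCxO weight array)
static inline arma::fmat im2col3(const double* x, int H, int W, int C) {
  arma::fmat A(static_cast<arma::uword>(H) * W, 9 * static_cast<arma::uword>(C));
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(H) * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        float* col = A.colptr(kh + 3 * kw + 9 * c);
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          float* dst = col + static_cast<size_t>(H) * w;
          if (sw < 0 || sw >= W) {
            std::fill(dst, dst + H, 0.0f);
            continue;
          }
          const double* src = xc + static_cast<size_t>(H) * sw;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0f);
          if (h1 < H) std::fill(dst + h1, dst + H, 0.0f);
          for (int h = h0; h < h1; ++h) dst[h] = static_cast<float>(src[h + dh]);
        }
      }
    }
  }
  return A;
}

// cast a double slab to a float matrix (no patch expansion)
static inline arma::fmat im2col_identity(const double* x, size_t HW, int C) {
  arma::fmat A(HW, C);
  float* p = A.memptr();
  for (size_t i = 0; i < HW * C; ++i) p[i] = static_cast<float>(x[i]);
  return A;
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Cout = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C) stop("weight/input channel mismatch");
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(w.begin()), 9 * C, Cout, false, true));
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::fmat A = im2col3(x.begin() + static_cast<size_t>(H) * W * C * n, H, W, C);
    arma::fmat Y = A * Wm;
    double* py = y.begin() + static_cast<size_t>(H) * W * Cout * n;
    size_t HW = static_cast<size_t>(H) * W;
    for (int co = 0; co < Cout; ++co) {
      const float* pc = Y.colptr(co);
      double bb = b[co];
      for (size_t i = 0; i < HW; ++i) py[HW * co + i] = pc[i] + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Cout = dw[3];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = dx;
  NumericVector gw(static_cast<R_xlen_t>(9) * C * Cout);
  gw.attr("dim") = dw;
  NumericVector gb(Cout);
  // dx is the "full" correlation of dy with spatially flipped weights whose
  // in/out channels are swapped; that reuses the same im2col + gemm path.
  arma::fmat Wflip(9 * Cout, C);
  const double* wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      for (int kw = 0; kw < 3; ++kw)
        for (int kh = 0; kh < 3; ++kh)
          Wflip((2 - kh) + 3 * (2 - kw) + 9 * co, c) =
            static_cast<float>(wp[kh + 3 * kw + 9 * c + 9 * C * co]);
  arma::fmat GW(9 * C, Cout, arma::fill::zeros);
  arma::frowvec GB(Cout, arma::fill::zeros);
  size_t HW = static_cast<size_t>(H) * W;
  for (int n = 0; n < N; ++n) {
    arma::fmat A = im2col3(x.begin() + HW * C * n, H, W, C);
    arma::fmat DY = im2col_identity(dy.begin() + HW * Cout * n, HW, Cout);
    GW += A.t() * DY;
    GB += arma::sum(DY, 0);
    arma::fmat Ady = im2col3(dy.begin() + HW * Cout * n, H, W, Cout);
    arma::fmat DX = Ady * Wflip;
    double* pg = gx.begin() + HW * C * n;
    const float* pf = DX.memptr();
    for (size_t i = 0; i < HW * C; ++i) pg[i] = pf[i];
  }
  for (int i = 0; i < 9 * C * Cout; ++i) gw[i] = GW.memptr()[i];
  for (int i = 0; i < Cout; ++i) gb[i] = GB[i];
  return List::create(_["dx"] = gx, _["dw"] = gw, _["db"] = gb);
}

// Batch normalization over (H, W, N) per channel; optionally fused ReLU.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps, bool training,
                NumericVector run_mean, NumericVector run_var,
                bool relu = false) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  size_t HW = static_cast<size_t>(H) * W, CH = HW * C;
  NumericVector y(x.size());
  y.attr("dim") = dx;
  NumericVector mean(C), var(C);
  double m = static_cast<double>(HW) * N;
  for (int c = 0; c < C; ++c) {
    double mu, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + CH * n + HW * c;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu = s / m;
      v = s2 / m - mu * mu;
      if (v < 0) v = 0;
    } else {
      mu = run_mean[c];
      v = run_var[c];
    }
    mean[c] = mu; var[c] = v;
    double inv = gamma[c] / std::sqrt(v + eps), sh = beta[c] - mu * inv;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + CH * n + HW * c;
      double* q = y.begin() + CH * n + HW * c;
      if (relu) {
        for (size_t i = 0; i < HW; ++i) {
          double v = p[i] * inv + sh;
          q[i] = v > 0 ? v : 0;
        }
      } else {
        for (size_t i = 0; i < HW; ++i) q[i] = p[i] * inv + sh;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// Backward of (BN, optional fused ReLU). When `relu`, `y` is the post-ReLU
// output and the incoming gradient is gated by y > 0 on the fly.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
                NumericVector var, NumericVector dy, double eps,
                Nullable<NumericVector> y = R_NilValue, bool relu = false) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  size_t HW = static_cast<size_t>(H) * W, CH = HW * C;
  double m = static_cast<double>(HW) * N;
  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  NumericVector dgamma(C), dbeta(C);
  const double* py = nullptr;
  NumericVector yy;
  if (relu) {
    if (y.isNull()) stop("relu backward requires y");
    yy = y.get();
    py = yy.begin();
  }
  for (int c = 0; c < C; ++c) {
    double istd = 1.0 / std::sqrt(var[c] + eps), mu = mean[c];
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = CH * n + HW * c;
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      const double* pyy = relu ? py + off : nullptr;
      for (size_t i = 0; i < HW; ++i) {
        double d = relu ? (pyy[i] > 0 ? pd[i] : 0.0) : pd[i];
        sdy += d;
        sdyx += d * (px[i] - mu) * istd;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    double k = gamma[c] * istd;
    for (int n = 0; n < N; ++n) {
      size_t off = CH * n + HW * c;
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      const double* pyy = relu ? py + off : nullptr;
      double* pg = gx.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        double d = relu ? (pyy[i] > 0 ? pd[i] : 0.0) : pd[i];
        double xh = (px[i] - mu) * istd;
        pg[i] = k * (d - sdy / m - xh * sdyx / m);
      }
    }
  }
  return List::create(_["dx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2 max pool, stride 2, floor on odd sizes; records argmax linear index
// (0-based within each H x W slab) for the paired unpool.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Ho = H / 2, Wo = W / 2;
  size_t HW = static_cast<size_t>(H) * W, HWo = static_cast<size_t>(Ho) * Wo;
  NumericVector y(HWo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(HWo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + static_cast<size_t>(C) * n);
      double* q = y.begin() + HWo * (c + static_cast<size_t>(C) * n);
      int* qi = idx.begin() + HWo * (c + static_cast<size_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h = 2 * ho, w = 2 * wo;
          size_t i00 = h + static_cast<size_t>(H) * w;
          size_t cand[4] = {i00, i00 + 1, i00 + static_cast<size_t>(H), i00 + static_cast<size_t>(H) + 1};
          size_t best = cand[0];
          for (int k = 1; k < 4; ++k) if (p[cand[k]] > p[best]) best = cand[k];
          q[ho + static_cast<size_t>(Ho) * wo] = p[best];
          qi[ho + static_cast<size_t>(Ho) * wo] = static_cast<int>(best);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector dd = dy.attr("dim");
  int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  size_t HW = static_cast<size_t>(H) * W, HWo = static_cast<size_t>(Ho) * Wo;
  NumericVector gx(HW * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t s = 0; s < static_cast<size_t>(C) * N; ++s) {
    const double* pd = dy.begin() + HWo * s;
    const int* pi = idx.begin() + HWo * s;
    double* pg = gx.begin() + HW * s;
    for (size_t i = 0; i < HWo; ++i) pg[pi[i]] += pd[i];
  }
  return gx;
}

// Max unpool: scatter values to recorded argmax positions of the paired pool.
// [[Rcpp::export]]
NumericVector cpp_maxunpool_fwd(NumericVector x, IntegerVector idx, int H, int W) {
  IntegerVector dx = x.attr("dim");
  int Ho = dx[0], Wo = dx[1], C = dx[2], N = dx[3];
  size_t HW = static_cast<size_t>(H) * W, HWo = static_cast<size_t>(Ho) * Wo;
  NumericVector y(HW * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t s = 0; s < static_cast<size_t>(C) * N; ++s) {
    const double* px = x.begin() + HWo * s;
    const int* pi = idx.begin() + HWo * s;
    double* py = y.begin() + HW * s;
    for (size_t i = 0; i < HWo; ++i) py[pi[i]] = px[i];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_maxunpool_bwd(NumericVector dy, IntegerVector idx, int Ho, int Wo) {
  IntegerVector dd = dy.attr("dim");
  int H = dd[0], W = dd[1], C = dd[2], N = dd[3];
  size_t HW = static_cast<size_t>(H) * W, HWo = static_cast<size_t>(Ho) * Wo;
  NumericVector gx(HWo * C * N);
  gx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t s = 0; s < static_cast<size_t>(C) * N; ++s) {
    const double* pd = dy.begin() + HW * s;
    const int* pi = idx.begin() + HWo * s;
    double* pg = gx.begin() + HWo * s;
    for (size_t i = 0; i < HWo; ++i) pg[i] = pd[pi[i]];
  }
  return gx;
}

// 8-connected component labeling; labels assigned 1..K in raster order
// (row-major scan) of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<int> lab(static_cast<size_t>(H) * W, 0);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  // pass 1 (row-major scan)
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) {
      if (!mask(h, w)) continue;
      size_t me = static_cast<size_t>(h) * W + w;  // row-major index for lab
      int neigh[4][2] = {{h, w - 1}, {h - 1, w - 1}, {h - 1, w}, {h - 1, w + 1}};
      int cur = 0;
      for (auto& nb : neigh) {
        int nh = nb[0], nw = nb[1];
        if (nh < 0 || nw < 0 || nw >= W || !mask(nh, nw)) continue;
        int nl = lab[static_cast<size_t>(nh) * W + nw];
        if (!cur) cur = nl; else unite(cur, nl);
      }
      if (!cur) {
        cur = ++next;
        parent.push_back(cur);
      }
      lab[me] = cur;
    }
  }
  // pass 2: resolve + relabel by first raster occurrence
  IntegerMatrix out(H, W);
  std::vector<int> remap(next + 1, 0);
  int k = 0;
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) {
      int l = lab[static_cast<size_t>(h) * W + w];
      if (!l) continue;
      int r = find(l);
      if (!remap[r]) remap[r] = ++k;
      out(h, w) = remap[r];
    }
  }
  return out;
}

// Separable bilinear resize of an H x W x C array (edge-clamped, pixel
// centers aligned as in standard image resampling: src = (i+0.5)*scale-0.5).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1];
  int C = dx.size() >= 3 ? dx[2] : 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  if (dx.size() >= 3) y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  else y.attr("dim") = IntegerVector::create(Ho, Wo);
  double sh = static_cast<double>(H) / Ho, sw = static_cast<double>(W) / Wo;
  std::vector<int> r0(Ho), r1(Ho); std::vector<double> rf(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    r0[i] = static_cast<int>(std::floor(s));
    r1[i] = std::min(r0[i] + 1, H - 1);
    rf[i] = s - r0[i];
  }
  std::vector<int> c0(Wo), c1(Wo); std::vector<double> cf(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    c0[j] = static_cast<int>(std::floor(s));
    c1[j] = std::min(c0[j] + 1, W - 1);
    cf[j] = s - c0[j];
  }
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + static_cast<size_t>(H) * W * c;
    double* q = y.begin() + static_cast<size_t>(Ho) * Wo * c;
    for (int j = 0; j < Wo; ++j) {
      const double* colA = p + static_cast<size_t>(H) * c0[j];
      const double* colB = p + static_cast<size_t>(H) * c1[j];
      double fj = cf[j];
      for (int i = 0; i < Ho; ++i) {
        double a = colA[r0[i]] * (1 - rf[i]) + colA[r1[i]] * rf[i];
        double b = colB[r0[i]] * (1 - rf[i]) + colB[r1[i]] * rf[i];
        q[i + static_cast<size_t>(Ho) * j] = a * (1 - fj) + b * fj;
      }
    }
  }
  return y;
}

// Nearest-neighbor resize (labels preserved exactly).
// [[Rcpp::export]]
IntegerVector cpp_resize_nearest(IntegerVector x, int Ho, int Wo) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1];
  IntegerVector y(static_cast<R_xlen_t>(Ho) * Wo);
  y.attr("dim") = IntegerVector::create(Ho, Wo);
  double sh = static_cast<double>(H) / Ho, sw = static_cast<double>(W) / Wo;
  std::vector<int> ri(Ho);
  for (int i = 0; i < Ho; ++i) {
    int s = static_cast<int>(std::floor((i + 0.5) * sh));
    ri[i] = std::min(std::max(s, 0), H - 1);
  }
  for (int j = 0; j < Wo; ++j) {
    int s = static_cast<int>(std::floor((j + 0.5) * sw));
    int cj = std::min(std::max(s, 0), W - 1);
    const int* p = x.begin() + static_cast<size_t>(H) * cj;
    int* q = y.begin() + static_cast<size_t>(Ho) * j;
    for (int i = 0; i < Ho; ++i) q[i] = p[ri[i]];
  }
  return y;
}
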