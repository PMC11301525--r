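// U-net kernels: im2col/gemm convolutions, 2x2 max pooling, 2x2 stride-2
// transposed convolutions, per-pixel two-class softmax cross-entropy.
// Feature maps are arma::fcube (H, W, C); pixels are flattened column-major
// (p = r + c*H) so a cube slice and a matrix column share memory layout.
// Single precision: training on one CPU is gemm-bound and sgemm is ~2x dgemm.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>

using namespace arma;
using Rcpp::List;

static fmat as_fmat(SEXP x) {
  Rcpp::NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  const double* src = m.begin();
  float* dst = out.memptr();
  for (uword i = 0; i < out.n_elem; ++i) dst[i] = (float)src[i];
  return out;
}

static fvec as_fvec(SEXP x) {
  Rcpp::NumericVector v(x);
  fvec out(v.size());
  for (uword i = 0; i < out.n_elem; ++i) out[i] = (float)v[i];
  return out;
}

static Rcpp::NumericMatrix to_rmat(const fmat& x) {
  Rcpp::NumericMatrix m(x.n_rows, x.n_cols);
  const float* src = x.memptr();
  for (uword i = 0; i < x.n_elem; ++i) m[i] = (double)src[i];
  return m;
}

static Rcpp::NumericVector to_rvec(const fvec& x) {
  Rcpp::NumericVector v(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) v[i] = (double)x[i];
  return v;
}

// im2col for a 3x3 window, same zero padding.
// Column index: off*C + ch with off = (dr+1)*3 + (dc+1).
static fmat im2col3(const fcube& in) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  fmat X((uword)H * W, 9 * (uword)C, fill::zeros);
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int off = (dr + 1) * 3 + (dc + 1);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      if (r1 <= r0 || c1 <= c0) continue;
      for (int ch = 0; ch < C; ++ch) {
        const float* src = in.slice_memptr(ch);
        float* dst = X.colptr((uword)off * C + ch);
        for (int c = c0; c < c1; ++c) {
          std::memcpy(dst + (size_t)c * H + r0,
                      src + (size_t)(c + dc) * H + (r0 + dr),
                      (size_t)(r1 - r0) * sizeof(float));
        }
      }
    }
  }
  return X;
}

// Adjoint of im2col3: accumulate (HW x 9C) gradients back onto an H x W x C cube.
static void col2im3_add(const fmat& Xg, int H, int W, int C, fcube& out) {
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int off = (dr + 1) * 3 + (dc + 1);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      if (r1 <= r0 || c1 <= c0) continue;
      for (int ch = 0; ch < C; ++ch) {
        const float* src = Xg.colptr((uword)off * C + ch);
        float* dst = out.slice_memptr(ch);
        for (int c = c0; c < c1; ++c) {
          const float* s = src + (size_t)c * H + r0;
          float* d = dst + (size_t)(c + dc) * H + (r0 + dr);
          for (int r = 0; r < r1 - r0; ++r) d[r] += s[r];
        }
      }
    }
  }
}

struct ConvCache {
  fmat X;  // im2col of the input
  fmat Z;  // pre-activation (HW x Cout)
  int Hin, Win, Cin;
};

static fcube conv3x3_fwd(const fcube& in, const fmat& W, const fvec& b,
                         bool relu, ConvCache* cc) {
  const int H = in.n_rows, Wd = in.n_cols;
  fmat X = im2col3(in);
  fmat Z = X * W;
  Z.each_row() += b.t();
  fcube out(H, Wd, W.n_cols);
  std::memcpy(out.memptr(), Z.memptr(), Z.n_elem * sizeof(float));
  if (relu) out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (cc) {
    cc->Hin = H; cc->Win = Wd; cc->Cin = in.n_slices;
    cc->X = std::move(X);
    cc->Z = std::move(Z);
  }
  return out;
}

static fcube conv3x3_bwd(const fcube& gout, const ConvCache& cc, const fmat& W,
                         bool relu, fmat& dW, fvec& db) {
  const uword HW = gout.n_rows * gout.n_cols, Cout = gout.n_slices;
  fmat G(HW, Cout);
  std::memcpy(G.memptr(), gout.memptr(), G.n_elem * sizeof(float));
  if (relu) {
    const float* z = cc.Z.memptr();
    float* g = G.memptr();
    for (uword i = 0; i < G.n_elem; ++i) if (z[i] <= 0.0f) g[i] = 0.0f;
  }
  dW = cc.X.t() * G;
  db = conv_to<fvec>::from(sum(G, 0));
  fmat Gi = G * W.t();
  fcube gin(cc.Hin, cc.Win, cc.Cin, fill::zeros);
  col2im3_add(Gi, cc.Hin, cc.Win, cc.Cin, gin);
  return gin;
}

static fcube maxpool2_fwd(const fcube& in, umat& arg) {
  const uword H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const uword H2 = H / 2, W2 = W / 2;
  fcube out(H2, W2, C);
  arg.set_size(H2 * W2, C);
  for (uword ch = 0; ch < C; ++ch) {
    const float* src = in.slice_memptr(ch);
    float* dst = out.slice_memptr(ch);
    for (uword c = 0; c < W2; ++c) {
      for (uword r = 0; r < H2; ++r) {
        const uword i00 = 2 * r + 2 * c * H;
        uword best = i00;
        float bv = src[i00];
        const uword cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
        for (int k = 0; k < 3; ++k)
          if (src[cand[k]] > bv) { bv = src[cand[k]]; best = cand[k]; }
        dst[r + c * H2] = bv;
        arg(r + c * H2, ch) = best;
      }
    }
  }
  return out;
}

static fcube maxpool2_bwd(const fcube& gout, const umat& arg, uword H, uword W) {
  const uword C = gout.n_slices;
  fcube gin(H, W, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    const float* g = gout.slice_memptr(ch);
    float* d = gin.slice_memptr(ch);
    for (uword p = 0; p < gout.n_rows * gout.n_cols; ++p) d[arg(p, ch)] += g[p];
  }
  return gin;
}

// 2x2 stride-2 transposed convolution; weight rows blocked by quadrant
// q = dr*2 + dc (dr, dc in {0,1}), each block Cin x Cout.
static fcube upconv2_fwd(const fcube& in, const fmat& W, const fvec& b, fmat* Acache) {
  const uword H = in.n_rows, Wd = in.n_cols, Cin = in.n_slices, Cout = W.n_cols;
  fmat A(H * Wd, Cin);
  std::memcpy(A.memptr(), in.memptr(), A.n_elem * sizeof(float));
  fcube out(2 * H, 2 * Wd, Cout);
  for (int dr = 0; dr <= 1; ++dr) {
    for (int dc = 0; dc <= 1; ++dc) {
      const uword q = (uword)(dr * 2 + dc);
      fmat Oq = A * W.rows(q * Cin, (q + 1) * Cin - 1);
      Oq.each_row() += b.t();
      for (uword k = 0; k < Cout; ++k) {
        const float* src = Oq.colptr(k);
        float* dst = out.slice_memptr(k);
        for (uword c = 0; c < Wd; ++c) {
          const float* s = src + c * H;
          float* d = dst + (size_t)(2 * c + dc) * (2 * H) + dr;
          for (uword r = 0; r < H; ++r) d[2 * r] = s[r];
        }
      }
    }
  }
  if (Acache) *Acache = std::move(A);
  return out;
}

static fcube upconv2_bwd(const fcube& gout, const fmat& A, const fmat& W,
                         uword H, uword Wd, fmat& dW, fvec& db) {
  const uword Cin = W.n_rows / 4, Cout = W.n_cols;
  dW.set_size(4 * Cin, Cout);
  db.zeros(Cout);
  fmat Gin(H * Wd, Cin, fill::zeros);
  for (int dr = 0; dr <= 1; ++dr) {
    for (int dc = 0; dc <= 1; ++dc) {
      const uword q = (uword)(dr * 2 + dc);
      fmat Gq(H * Wd, Cout);
      for (uword k = 0; k < Cout; ++k) {
        const float* src = gout.slice_memptr(k);
        float* dst = Gq.colptr(k);
        for (uword c = 0; c < Wd; ++c) {
          const float* s = src + (size_t)(2 * c + dc) * (2 * H) + dr;
          float* d = dst + c * H;
          for (uword r = 0; r < H; ++r) d[r] = s[2 * r];
        }
      }
      dW.rows(q * Cin, (q + 1) * Cin - 1) = A.t() * Gq;
      db += conv_to<fvec>::from(sum(Gq, 0));
      Gin += Gq * W.rows(q * Cin, (q + 1) * Cin - 1).t();
    }
  }
  fcube gin(H, Wd, Cin);
  std::memcpy(gin.memptr(), Gin.memptr(), Gin.n_elem * sizeof(float));
  return gin;
}

struct UNetW {
  int depth;
  std::vector<fmat> encWa, encWb, upW, decWa, decWb;
  std::vector<fvec> encba, encbb, upb, decba, decbb;
  fmat botWa, botWb, finW;
  fvec botba, botbb, finb;
};

// Weight list order (matches build_unet() on the R side):
// for l in 0..depth-1: encWa, encba, encWb, encbb
// botWa, botba, botWb, botbb
// for l in depth-1..0: upW, upb, decWa, decba, decWb, decbb
// finW, finb
static UNetW parse_weights(List weights, int depth) {
  UNetW w;
  w.depth = depth;
  int i = 0;
  for (int l = 0; l < depth; ++l) {
    w.encWa.push_back(as_fmat(weights[i++]));
    w.encba.push_back(as_fvec(weights[i++]));
    w.encWb.push_back(as_fmat(weights[i++]));
    w.encbb.push_back(as_fvec(weights[i++]));
  }
  w.botWa = as_fmat(weights[i++]); w.botba = as_fvec(weights[i++]);
  w.botWb = as_fmat(weights[i++]); w.botbb = as_fvec(weights[i++]);
  for (int l = depth - 1; l >= 0; --l) {
    w.upW.push_back(as_fmat(weights[i++]));
    w.upb.push_back(as_fvec(weights[i++]));
    w.decWa.push_back(as_fmat(weights[i++]));
    w.decba.push_back(as_fvec(weights[i++]));
    w.decWb.push_back(as_fmat(weights[i++]));
    w.decbb.push_back(as_fvec(weights[i++]));
  }
  w.finW = as_fmat(weights[i++]);
  w.finb = as_fvec(weights[i++]);
  return w;
}

struct FwdCache {
  std::vector<ConvCache> ecA, ecB, dcA, dcB;
  ConvCache bcA, bcB;
  std::vector<fcube> skip;     // encoder outputs pre-pool
  std::vector<umat> poolArg;
  std::vector<fmat> upA;       // flattened inputs to each upconv
  std::vector<uword> upH, upW; // input dims of each upconv
  fmat A0;                     // flattened input to the final 1x1 conv
  fmat P;                      // softmax probabilities (HW x 2)
};

// Forward pass; returns softmax probabilities (HW x 2).
static fmat unet_forward(const fmat& image, const UNetW& w, FwdCache* fc) {
  const int depth = w.depth;
  fcube x(image.n_rows, image.n_cols, 1);
  x.slice(0) = image;
  if (fc) {
    fc->ecA.resize(depth); fc->ecB.resize(depth);
    fc->dcA.resize(depth); fc->dcB.resize(depth);
    fc->skip.resize(depth); fc->poolArg.resize(depth);
    fc->upA.resize(depth); fc->upH.resize(depth); fc->upW.resize(depth);
  }
  std::vector<fcube> skip_local(depth);
  for (int l = 0; l < depth; ++l) {
    x = conv3x3_fwd(x, w.encWa[l], w.encba[l], true, fc ? &fc->ecA[l] : nullptr);
    x = conv3x3_fwd(x, w.encWb[l], w.encbb[l], true, fc ? &fc->ecB[l] : nullptr);
    if (fc) fc->skip[l] = x; else skip_local[l] = x;
    umat arg;
    x = maxpool2_fwd(x, arg);
    if (fc) fc->poolArg[l] = std::move(arg);
  }
  x = conv3x3_fwd(x, w.botWa, w.botba, true, fc ? &fc->bcA : nullptr);
  x = conv3x3_fwd(x, w.botWb, w.botbb, true, fc ? &fc->bcB : nullptr);
  for (int j = 0; j < depth; ++j) {  // j = 0 handles level depth-1
    const int l = depth - 1 - j;
    if (fc) { fc->upH[j] = x.n_rows; fc->upW[j] = x.n_cols; }
    fcube up = upconv2_fwd(x, w.upW[j], w.upb[j], fc ? &fc->upA[j] : nullptr);
    const fcube& sk = fc ? fc->skip[l] : skip_local[l];
    fcube cat = join_slices(up, sk);
    x = conv3x3_fwd(cat, w.decWa[j], w.decba[j], true, fc ? &fc->dcA[j] : nullptr);
    x = conv3x3_fwd(x, w.decWb[j], w.decbb[j], true, fc ? &fc->dcB[j] : nullptr);
  }
  const uword HW = x.n_rows * x.n_cols;
  fmat A0(HW, x.n_slices);
  std::memcpy(A0.memptr(), x.memptr(), A0.n_elem * sizeof(float));
  fmat Lg = A0 * w.finW;
  Lg.each_row() += w.finb.t();
  // stable two-class softmax
  fmat P(HW, 2);
  for (uword p = 0; p < HW; ++p) {
    const float m = std::max(Lg(p, 0), Lg(p, 1));
    const float e0 = std::exp(Lg(p, 0) - m), e1 = std::exp(Lg(p, 1) - m);
    const float s = e0 + e1;
    P(p, 0) = e0 / s;
    P(p, 1) = e1 / s;
  }
  if (fc) { fc->A0 = std::move(A0); fc->P = P; }
  return P;
}

// Backward pass from softmax cross-entropy; appends gradients in the
// canonical weight order to `grads`. Returns the mean pixel loss.
static double unet_backward(const Rcpp::IntegerMatrix& target, const UNetW& w,
                            FwdCache& fc, std::vector<fmat>& gW,
                            std::vector<fvec>& gb) {
  const int depth = w.depth;
  const uword HW = fc.P.n_rows;
  double loss = 0.0;
  fmat dL = fc.P;
  const int* y = target.begin();
  for (uword p = 0; p < HW; ++p) {
    const int t = y[p] ? 1 : 0;
    loss -= std::log((double)fc.P(p, t) + 1e-12);
    dL(p, t) -= 1.0f;
  }
  loss /= (double)HW;
  dL /= (float)HW;

  // gradients are collected in reverse and reordered at the end
  std::vector<fmat> rW; std::vector<fvec> rb;
  fmat dFinW = fc.A0.t() * dL;
  fvec dFinb = conv_to<fvec>::from(sum(dL, 0));
  fmat dA0 = dL * w.finW.t();
  rW.push_back(dFinW); rb.push_back(dFinb);

  const uword C0 = fc.A0.n_cols;
  const uword H0 = (uword)std::sqrt((double)HW);  // inputs are square
  fcube g(H0, HW / H0, C0);
  std::memcpy(g.memptr(), dA0.memptr(), dA0.n_elem * sizeof(float));

  for (int j = depth - 1; j >= 0; --j) {
    const int l = depth - 1 - j;
    fmat dWb, dWa, dWu; fvec dbb, dba, dbu;
    g = conv3x3_bwd(g, fc.dcB[j], w.decWb[j], true, dWb, dbb);
    fcube gcat = conv3x3_bwd(g, fc.dcA[j], w.decWa[j], true, dWa, dba);
    const uword Fup = w.upW[j].n_cols;
    fcube gup = gcat.slices(0, Fup - 1);
    fcube gskip = gcat.slices(Fup, gcat.n_slices - 1);
    fcube gx = upconv2_bwd(gup, fc.upA[j], w.upW[j], fc.upH[j], fc.upW[j], dWu, dbu);
    rW.push_back(dWb); rb.push_back(dbb);
    rW.push_back(dWa); rb.push_back(dba);
    rW.push_back(dWu); rb.push_back(dbu);
    g = std::move(gx);
    // the forward activation is no longer needed: reuse the slot to carry
    // the skip-connection gradient down to the matching encoder level
    fc.skip[l] = std::move(gskip);
  }

  // bottleneck
  {
    fmat dWb, dWa; fvec dbb, dba;
    g = conv3x3_bwd(g, fc.bcB, w.botWb, true, dWb, dbb);
    g = conv3x3_bwd(g, fc.bcA, w.botWa, true, dWa, dba);
    rW.push_back(dWb); rb.push_back(dbb);
    rW.push_back(dWa); rb.push_back(dba);
  }

  for (int l = depth - 1; l >= 0; --l) {
    const uword H = fc.ecB[l].Hin, W_ = fc.ecB[l].Win;
    fcube gpool = maxpool2_bwd(g, fc.poolArg[l], H, W_);
    gpool += fc.skip[l];  // add the skip-connection gradient
    fmat dWb, dWa; fvec dbb, dba;
    g = conv3x3_bwd(gpool, fc.ecB[l], w.encWb[l], true, dWb, dbb);
    g = conv3x3_bwd(g, fc.ecA[l], w.encWa[l], true, dWa, dba);
    rW.push_back(dWb); rb.push_back(dbb);
    rW.push_back(dWa); rb.push_back(dba);
  }

  // reverse into canonical order
  gW.assign(rW.rbegin(), rW.rend());
  gb.assign(rb.rbegin(), rb.rend());
  return loss;
}

// [[Rcpp::export]]
Rcpp::List unet_batch_grad_cpp(Rcpp::List images, Rcpp::List targets,
                               Rcpp::List weights, int depth, int base) {
  (void)base;
  UNetW w = parse_weights(weights, depth);
  const int B = images.size();
  std::vector<fmat> accW; std::vector<fvec> accb;
  double loss = 0.0;
  for (int i = 0; i < B; ++i) {
    fmat img = as_fmat(images[i]);
    Rcpp::IntegerMatrix tgt(targets[i]);
    FwdCache fc;
    unet_forward(img, w, &fc);
    std::vector<fmat> gW; std::vector<fvec> gb;
    loss += unet_backward(tgt, w, fc, gW, gb);
    if (i == 0) { accW = std::move(gW); accb = std::move(gb); }
    else {
      for (size_t k = 0; k < accW.size(); ++k) { accW[k] += gW[k]; accb[k] += gb[k]; }
    }
  }
  const float inv = 1.0f / (float)B;
  Rcpp::List grads(2 * accW.size());
  for (size_t k = 0; k < accW.size(); ++k) {
    grads[2 * k] = to_rmat(accW[k] * inv);
    grads[2 * k + 1] = to_rvec(accb[k] * inv);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss / B,
                            Rcpp::Named("grads") = grads);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix unet_predict_cpp(Rcpp::NumericMatrix image,
                                     Rcpp::List weights, int depth, int base) {
  (void)base;
  UNetW w = parse_weights(weights, depth);
  fmat img = as_fmat(image);
  fmat P = unet_forward(img, w, nullptr);
  const uword H = img.n_rows, W_ = img.n_cols;
  Rcpp::NumericMatrix out(H, W_);
  for (uword i = 0; i < H * W_; ++i) out[i] = (double)P(i, 1);
  return out;
}
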