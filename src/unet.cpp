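// Compact U-Net (encoder-decoder with skip connections) for binary
// segmentation, trained with Dice loss and Adam. Feature maps are stored
// as (channels x H*W) single-precision matrices with column-major spatial
// indexing (pixel (r, c) at index c*H + r, matching R matrices), so 3x3
// convolutions reduce to nine shifted GEMMs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using arma::fmat;
using arma::fvec;
using arma::uword;

// gather input shifted by (dr, dc) into Xs (zero outside)
static void shift_gather(const fmat& X, int H, int W, int dr, int dc,
                         fmat& Xs) {
  Xs.zeros(X.n_rows, X.n_cols);
  int rs = std::max(0, -dr), re = H - std::max(0, dr);
  if (re <= rs) return;
  for (int cc = 0; cc < W; ++cc) {
    int ic = cc + dc;
    if (ic < 0 || ic >= W) continue;
    Xs.cols(cc * H + rs, cc * H + re - 1) =
        X.cols(ic * H + rs + dr, ic * H + re - 1 + dr);
  }
}

// reverse of shift_gather: dX(:, source) += dXs(:, output)
static void shift_scatter_add(fmat& dX, const fmat& dXs, int H, int W,
                              int dr, int dc) {
  int rs = std::max(0, -dr), re = H - std::max(0, dr);
  if (re <= rs) return;
  for (int cc = 0; cc < W; ++cc) {
    int ic = cc + dc;
    if (ic < 0 || ic >= W) continue;
    dX.cols(ic * H + rs + dr, ic * H + re - 1 + dr) +=
        dXs.cols(cc * H + rs, cc * H + re - 1);
  }
}

struct AdamState {
  fmat mW, vW;
  fvec mb, vb;
};

struct Conv3 {
  int Cin = 0, Cout = 0;
  fmat W;   // Cout x Cin*9, tap-major blocks
  fvec b;
  fmat gW;
  fvec gb;
  AdamState adam;
  fmat Xin;  // cached input for backward
  int H = 0, Wd = 0;

  void init(int cin, int cout, std::mt19937& rng) {
    Cin = cin; Cout = cout;
    std::normal_distribution<float> nd(0.f, std::sqrt(2.f / (cin * 9)));
    W.set_size(cout, cin * 9);
    for (auto& w : W) w = nd(rng);
    b.zeros(cout);
    gW.zeros(cout, cin * 9);
    gb.zeros(cout);
    adam.mW.zeros(cout, cin * 9); adam.vW.zeros(cout, cin * 9);
    adam.mb.zeros(cout); adam.vb.zeros(cout);
  }

  fmat forward(const fmat& X, int h, int w) {
    Xin = X; H = h; Wd = w;
    fmat Y(Cout, X.n_cols);
    Y.each_col() = b;
    fmat Xs;
    for (int t = 0; t < 9; ++t) {
      shift_gather(X, H, Wd, t / 3 - 1, t % 3 - 1, Xs);
      Y += W.cols(t * Cin, t * Cin + Cin - 1) * Xs;
    }
    return Y;
  }

  fmat backward(const fmat& dY, float scale) {
    gb += scale * arma::sum(dY, 1);
    fmat dX(Cin, Xin.n_cols, arma::fill::zeros);
    fmat Xs;
    for (int t = 0; t < 9; ++t) {
      int dr = t / 3 - 1, dc = t % 3 - 1;
      shift_gather(Xin, H, Wd, dr, dc, Xs);
      gW.cols(t * Cin, t * Cin + Cin - 1) += scale * (dY * Xs.t());
      fmat dXs = W.cols(t * Cin, t * Cin + Cin - 1).t() * dY;
      shift_scatter_add(dX, dXs, H, Wd, dr, dc);
    }
    return dX;
  }
};

// 1x1 output convolution
struct Conv1 {
  int Cin = 0, Cout = 1;
  fmat W;
  fvec b;
  fmat gW;
  fvec gb;
  AdamState adam;
  fmat Xin;

  void init(int cin, std::mt19937& rng) {
    Cin = cin;
    std::normal_distribution<float> nd(0.f, std::sqrt(2.f / cin));
    W.set_size(1, cin);
    for (auto& w : W) w = nd(rng);
    b.zeros(1);
    gW.zeros(1, cin); gb.zeros(1);
    adam.mW.zeros(1, cin); adam.vW.zeros(1, cin);
    adam.mb.zeros(1); adam.vb.zeros(1);
  }
  fmat forward(const fmat& X) {
    Xin = X;
    fmat Y = W * X;
    Y.each_col() += b;
    return Y;
  }
  fmat backward(const fmat& dY, float scale) {
    gb += scale * arma::sum(dY, 1);
    gW += scale * (dY * Xin.t());
    return W.t() * dY;
  }
};

// leaky ReLU (slope 0.01) so sparse-input feature maps cannot die
struct Relu {
  arma::umat mask;
  fmat forward(fmat X) {
    mask = X > 0.f;
    X.elem(arma::find(mask == 0)) *= 0.01f;
    return X;
  }
  fmat backward(fmat dY) {
    dY.elem(arma::find(mask == 0)) *= 0.01f;
    return dY;
  }
};

// per-channel instance normalization with affine parameters
struct InstNorm {
  int C = 0;
  fvec g, b;        // scale, shift
  fvec gg, gb;
  AdamState adam;   // mW/vW used for g, mb/vb for b
  fmat xhat;
  fvec invstd;

  void init(int c) {
    C = c;
    g.ones(c); b.zeros(c);
    gg.zeros(c); gb.zeros(c);
    adam.mW.zeros(c, 1); adam.vW.zeros(c, 1);
    adam.mb.zeros(c); adam.vb.zeros(c);
  }
  fmat forward(const fmat& X) {
    const float eps = 1e-5f;
    fvec mu = arma::mean(X, 1);
    fvec va = arma::var(X, 1, 1);  // population variance per channel
    invstd = 1.f / arma::sqrt(va + eps);
    xhat = X;
    xhat.each_col() -= mu;
    xhat.each_col() %= invstd;
    fmat Y = xhat;
    Y.each_col() %= g;
    Y.each_col() += b;
    return Y;
  }
  fmat backward(const fmat& dY, float scale) {
    gb += scale * arma::sum(dY, 1);
    gg += scale * arma::sum(dY % xhat, 1);
    float N = (float)dY.n_cols;
    fvec m1 = arma::sum(dY, 1) / N;
    fvec m2 = arma::sum(dY % xhat, 1) / N;
    fmat dX = dY;
    dX.each_col() -= m1;
    dX -= xhat.each_col() % m2;
    dX.each_col() %= (g % invstd);
    return dX;
  }
};

struct MaxPool2 {
  arma::umat idx;  // source pixel per output element (per channel row)
  int H = 0, Wd = 0;
  fmat forward(const fmat& X, int h, int w) {
    H = h; Wd = w;
    int Ho = h / 2, Wo = w / 2;
    fmat Y(X.n_rows, Ho * Wo);
    idx.set_size(X.n_rows, Ho * Wo);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        uword p[4] = {(uword)((2 * co) * h + 2 * ro),
                      (uword)((2 * co) * h + 2 * ro + 1),
                      (uword)((2 * co + 1) * h + 2 * ro),
                      (uword)((2 * co + 1) * h + 2 * ro + 1)};
        uword o = co * Ho + ro;
        for (uword ch = 0; ch < X.n_rows; ++ch) {
          float best = X(ch, p[0]); uword bi = p[0];
          for (int t = 1; t < 4; ++t)
            if (X(ch, p[t]) > best) { best = X(ch, p[t]); bi = p[t]; }
          Y(ch, o) = best; idx(ch, o) = bi;
        }
      }
    }
    return Y;
  }
  fmat backward(const fmat& dY) {
    fmat dX(dY.n_rows, H * Wd, arma::fill::zeros);
    for (uword o = 0; o < dY.n_cols; ++o)
      for (uword ch = 0; ch < dY.n_rows; ++ch)
        dX(ch, idx(ch, o)) += dY(ch, o);
    return dX;
  }
};

// nearest-neighbour 2x upsampling
static fmat upsample2(const fmat& X, int H, int W) {
  fmat Y(X.n_rows, 4 * H * W);
  for (int c = 0; c < 2 * W; ++c)
    for (int r = 0; r < 2 * H; ++r)
      Y.col(c * 2 * H + r) = X.col((c / 2) * H + r / 2);
  return Y;
}
static fmat upsample2_backward(const fmat& dY, int H, int W) {
  fmat dX(dY.n_rows, H * W, arma::fill::zeros);
  for (int c = 0; c < 2 * W; ++c)
    for (int r = 0; r < 2 * H; ++r)
      dX.col((c / 2) * H + r / 2) += dY.col(c * 2 * H + r);
  return dX;
}

struct Block {       // two (conv -> instance norm -> leaky relu) pairs
  Conv3 c1, c2;
  InstNorm n1, n2;
  Relu r1, r2;
  fmat forward(const fmat& X, int H, int W) {
    fmat a = r1.forward(n1.forward(c1.forward(X, H, W)));
    return r2.forward(n2.forward(c2.forward(a, H, W)));
  }
  fmat backward(const fmat& dY, float s) {
    fmat d = c2.backward(n2.backward(r2.backward(dY), s), s);
    return c1.backward(n1.backward(r1.backward(d), s), s);
  }
};

struct UNet {
  int in_ch, base, levels;
  long step_count = 0;
  std::vector<Block> enc;       // levels blocks (last = bottleneck)
  std::vector<MaxPool2> pools;  // levels-1
  std::vector<Block> dec;       // levels-1 blocks, deepest first
  Conv1 out_conv;
  std::vector<Conv1> aux_heads; // deep supervision at coarse decoder scales
  std::vector<fmat> skips, dec_out;
  std::vector<int> Hs, Ws;

  UNet(int in_ch_, int base_, int levels_, int seed) {
    in_ch = in_ch_; base = base_; levels = levels_;
    std::mt19937 rng(seed);
    enc.resize(levels); pools.resize(levels - 1); dec.resize(levels - 1);
    for (int l = 0; l < levels; ++l) {
      int cin = l == 0 ? in_ch : base << (l - 1);
      int cout = base << l;
      enc[l].c1.init(cin, cout, rng);
      enc[l].c2.init(cout, cout, rng);
      enc[l].n1.init(cout);
      enc[l].n2.init(cout);
    }
    for (int i = 0; i < levels - 1; ++i) {
      int l = levels - 2 - i;           // decoder level resolution index
      int cskip = base << l, cup = base << (l + 1);
      dec[i].c1.init(cskip + cup, cskip, rng);
      dec[i].c2.init(cskip, cskip, rng);
      dec[i].n1.init(cskip);
      dec[i].n2.init(cskip);
    }
    aux_heads.resize(levels >= 3 ? levels - 2 : 0);
    for (int i = 0; i < (int)aux_heads.size(); ++i)
      aux_heads[i].init(base << (levels - 2 - i), rng);
    out_conv.init(base, rng);
  }

  // logits over H0*W0 pixels
  fmat forward(const fmat& x0, int H0, int W0) {
    int div = 1 << (levels - 1);
    if (H0 % div || W0 % div)
      Rcpp::stop("image side must be divisible by %d", div);
    skips.assign(levels, fmat());
    Hs.assign(levels, 0); Ws.assign(levels, 0);
    fmat x = x0;
    int H = H0, W = W0;
    for (int l = 0; l < levels; ++l) {
      x = enc[l].forward(x, H, W);
      skips[l] = x; Hs[l] = H; Ws[l] = W;
      if (l < levels - 1) {
        x = pools[l].forward(x, H, W);
        H /= 2; W /= 2;
      }
    }
    dec_out.assign(levels - 1, fmat());
    for (int i = 0; i < levels - 1; ++i) {
      int l = levels - 2 - i;
      fmat up = upsample2(x, Hs[l + 1], Ws[l + 1]);
      fmat cat = arma::join_cols(skips[l], up);
      x = dec[i].forward(cat, Hs[l], Ws[l]);
      dec_out[i] = x;
    }
    return out_conv.forward(x);
  }

  // aux_dlogits[i] (may be empty) is the gradient of the deep-supervision
  // loss at decoder stage i, already weighted
  void backward(const fmat& dlogits, float scale,
                const std::vector<fmat>* aux_dlogits = nullptr) {
    fmat d = out_conv.backward(dlogits, scale);
    for (int i = levels - 2; i >= 0; --i) {
      int l = levels - 2 - i;
      if (aux_dlogits && i < (int)aux_dlogits->size() &&
          !(*aux_dlogits)[i].is_empty())
        d += aux_heads[i].backward((*aux_dlogits)[i], scale);
      fmat dcat = dec[i].backward(d, scale);
      int cskip = base << l;
      fmat dskip = dcat.rows(0, cskip - 1);
      fmat dup = dcat.rows(cskip, dcat.n_rows - 1);
      d = upsample2_backward(dup, Hs[l + 1], Ws[l + 1]);
      // add skip gradient after passing through the pooling chain below
      pending_skip.push_back(dskip);
      pending_level.push_back(l);
    }
    // walk back up the encoder
    for (int l = levels - 1; l >= 0; --l) {
      // merge any skip gradient entering at this level
      for (size_t k = 0; k < pending_level.size(); ++k)
        if (pending_level[k] == l) d += pending_skip[k];
      d = enc[l].backward(d, scale);
      if (l > 0) d = pools[l - 1].backward(d);
    }
    pending_skip.clear();
    pending_level.clear();
  }

  std::vector<fmat> pending_skip;
  std::vector<int> pending_level;

  void zero_grads() {
    for (auto& b : enc) { b.c1.gW.zeros(); b.c1.gb.zeros();
                          b.c2.gW.zeros(); b.c2.gb.zeros();
                          b.n1.gg.zeros(); b.n1.gb.zeros();
                          b.n2.gg.zeros(); b.n2.gb.zeros(); }
    for (auto& b : dec) { b.c1.gW.zeros(); b.c1.gb.zeros();
                          b.c2.gW.zeros(); b.c2.gb.zeros();
                          b.n1.gg.zeros(); b.n1.gb.zeros();
                          b.n2.gg.zeros(); b.n2.gb.zeros(); }
    for (auto& h : aux_heads) { h.gW.zeros(); h.gb.zeros(); }
    out_conv.gW.zeros(); out_conv.gb.zeros();
  }

  template <class F>
  void for_each_param(F f) {
    for (auto& b : enc) {
      f(b.c1.W, b.c1.gW, b.c1.adam.mW, b.c1.adam.vW);
      f(b.c2.W, b.c2.gW, b.c2.adam.mW, b.c2.adam.vW);
    }
    for (auto& b : dec) {
      f(b.c1.W, b.c1.gW, b.c1.adam.mW, b.c1.adam.vW);
      f(b.c2.W, b.c2.gW, b.c2.adam.mW, b.c2.adam.vW);
    }
    for (auto& h : aux_heads)
      f(h.W, h.gW, h.adam.mW, h.adam.vW);
    f(out_conv.W, out_conv.gW, out_conv.adam.mW, out_conv.adam.vW);
    // biases and normalization parameters
    for (auto& b : enc) {
      fb(b.c1.b, b.c1.gb, b.c1.adam.mb, b.c1.adam.vb, f);
      fb(b.c2.b, b.c2.gb, b.c2.adam.mb, b.c2.adam.vb, f);
      fn(b.n1, f); fn(b.n2, f);
    }
    for (auto& b : dec) {
      fb(b.c1.b, b.c1.gb, b.c1.adam.mb, b.c1.adam.vb, f);
      fb(b.c2.b, b.c2.gb, b.c2.adam.mb, b.c2.adam.vb, f);
      fn(b.n1, f); fn(b.n2, f);
    }
    for (auto& h : aux_heads)
      fb(h.b, h.gb, h.adam.mb, h.adam.vb, f);
    fb(out_conv.b, out_conv.gb, out_conv.adam.mb, out_conv.adam.vb, f);
  }
  template <class F>
  static void fn(InstNorm& n, F f) {
    fmat gm(n.g.memptr(), n.C, 1, false, true);
    fmat ggm(n.gg.memptr(), n.C, 1, false, true);
    f(gm, ggm, n.adam.mW, n.adam.vW);
    fb(n.b, n.gb, n.adam.mb, n.adam.vb, f);
  }
  template <class F>
  static void fb(fvec& w, fvec& g, fvec& m, fvec& v, F f) {
    fmat wm(w.memptr(), w.n_elem, 1, false, true);
    fmat gm(g.memptr(), g.n_elem, 1, false, true);
    fmat mm(m.memptr(), m.n_elem, 1, false, true);
    fmat vm(v.memptr(), v.n_elem, 1, false, true);
    f(wm, gm, mm, vm);
  }

  void adam_step(float lr) {
    ++step_count;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    float c1 = 1.f - std::pow(b1, (float)step_count);
    float c2 = 1.f - std::pow(b2, (float)step_count);
    for_each_param([&](fmat& w, fmat& g, fmat& m, fmat& v) {
      m = b1 * m + (1.f - b1) * g;
      v = b2 * v + (1.f - b2) * (g % g);
      w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
    });
  }
};

// soft Dice with squared denominator terms (better-conditioned gradients
// on heavily imbalanced masks)
static float dice_loss_and_grad(const fmat& logits, const fmat& y,
                                fmat& dlogits) {
  fmat p = 1.f / (1.f + arma::exp(-logits));
  const float eps = 1.f;
  float S = arma::accu(p % p) + arma::accu(y % y) + eps;
  float num = 2.f * arma::accu(p % y) + eps;
  float loss = 1.f - num / S;
  fmat dp = (2.f * num / (S * S)) * p - 2.f * y / S;
  dlogits = dp % p % (1.f - p);
  return loss;
}

// 2x nearest-neighbour downsampling of a 1 x (H*W) map
static fmat down2(const fmat& y, int H, int W) {
  fmat out(1, (H / 2) * (W / 2));
  for (int c = 0; c < W / 2; ++c)
    for (int r = 0; r < H / 2; ++r)
      out(0, c * (H / 2) + r) = y(0, (2 * c) * H + 2 * r);
  return out;
}

// forward + (optionally) backward with deep supervision; returns the
// weighted loss. Auxiliary heads at coarser decoder scales get weights
// 0.5, 0.25, ... of the full-resolution loss (normalized).
static float supervised_pass(UNet* u, const fmat& xi, const fmat& yi,
                             int H, int W, bool do_backward, float scale) {
  fmat logits = u->forward(xi, H, W);
  int n_aux = (int)u->aux_heads.size();
  std::vector<float> wts(1 + n_aux);
  wts[0] = 1.f;
  float wsum = 1.f;
  for (int i = 0; i < n_aux; ++i) {
    // aux stage i lives at resolution level (levels-2-i)
    wts[1 + i] = std::pow(0.5f, (float)(u->levels - 2 - i));
    wsum += wts[1 + i];
  }
  fmat dmain;
  float loss = wts[0] * dice_loss_and_grad(logits, yi, dmain);
  std::vector<fmat> aux_d(n_aux);
  for (int i = 0; i < n_aux; ++i) {
    int l = u->levels - 2 - i;          // resolution level of stage i
    int f = 1 << l;                      // total downsampling factor
    fmat yd = yi;
    int h = H, w = W;
    for (int k = 0; k < l; ++k) { yd = down2(yd, h, w); h /= 2; w /= 2; }
    fmat li = u->aux_heads[i].forward(u->dec_out[i]);
    fmat di;
    loss += wts[1 + i] * dice_loss_and_grad(li, yd, di);
    aux_d[i] = wts[1 + i] / wsum * di;
    (void)f;
  }
  loss /= wsum;
  if (do_backward) {
    dmain *= wts[0] / wsum;
    u->backward(dmain, scale, &aux_d);
  }
  return loss;
}

static UNet* get_net(SEXP ptr) {
  Rcpp::XPtr<UNet> xp(ptr);
  return xp.get();
}

static fmat slice_to_fmat(const arma::cube& x, int i) {
  arma::mat m = x.slice(i);
  fmat out(1, m.n_elem);
  for (uword k = 0; k < m.n_elem; ++k) out(0, k) = (float)m(k);
  return out;
}

// [[Rcpp::export]]
SEXP unet_create(int in_ch, int base, int levels, int seed) {
  if (levels < 2 || levels > 6) Rcpp::stop("levels must be in 2..6");
  Rcpp::XPtr<UNet> ptr(new UNet(in_ch, base, levels, seed), true);
  return ptr;
}

// [[Rcpp::export]]
double unet_train_batch(SEXP net, arma::cube x, arma::cube y, double lr) {
  UNet* u = get_net(net);
  int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  u->zero_grads();
  double total = 0;
  for (int i = 0; i < B; ++i) {
    fmat xi = slice_to_fmat(x, i);
    fmat yi = slice_to_fmat(y, i);
    total += supervised_pass(u, xi, yi, H, W, true, 1.f / B);
  }
  u->adam_step((float)lr);
  return total / B;
}

// [[Rcpp::export]]
double unet_batch_loss(SEXP net, arma::cube x, arma::cube y) {
  UNet* u = get_net(net);
  int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  double total = 0;
  for (int i = 0; i < B; ++i) {
    fmat xi = slice_to_fmat(x, i);
    fmat yi = slice_to_fmat(y, i);
    total += supervised_pass(u, xi, yi, H, W, false, 0.f);
  }
  return total / B;
}

// [[Rcpp::export]]
Rcpp::List unet_batch_grads(SEXP net, arma::cube x, arma::cube y) {
  UNet* u = get_net(net);
  int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  u->zero_grads();
  for (int i = 0; i < B; ++i) {
    fmat xi = slice_to_fmat(x, i);
    fmat yi = slice_to_fmat(y, i);
    supervised_pass(u, xi, yi, H, W, true, 1.f / B);
  }
  Rcpp::List out;
  int k = 0;
  u->for_each_param([&](fmat& w, fmat& g, fmat&, fmat&) {
    out.push_back(Rcpp::wrap(arma::conv_to<arma::mat>::from(g)));
    (void)w; ++k;
  });
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_predict_cpp(SEXP net, arma::cube x) {
  UNet* u = get_net(net);
  int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  arma::cube out(H, W, B);
  for (int i = 0; i < B; ++i) {
    fmat xi = slice_to_fmat(x, i);
    fmat logits = u->forward(xi, H, W);
    fmat p = 1.f / (1.f + arma::exp(-logits));
    for (uword k = 0; k < p.n_elem; ++k) out.slice(i)(k) = p(0, k);
  }
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
Rcpp::List unet_get_weights(SEXP net) {
  UNet* u = get_net(net);
  Rcpp::List out;
  u->for_each_param([&](fmat& w, fmat&, fmat&, fmat&) {
    out.push_back(Rcpp::wrap(arma::conv_to<arma::mat>::from(w)));
  });
  return out;
}

// [[Rcpp::export]]
void unet_set_weights(SEXP net, Rcpp::List weights) {
  UNet* u = get_net(net);
  int k = 0;
  u->for_each_param([&](fmat& w, fmat&, fmat&, fmat&) {
    arma::mat m = Rcpp::as<arma::mat>(weights[k]);
    if (m.n_elem != w.n_elem) Rcpp::stop("weight %d shape mismatch", k);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = (float)m(i);
    ++k;
  });
}

// [[Rcpp::export]]
Rcpp::IntegerVector unet_config(SEXP net) {
  UNet* u = get_net(net);
  return Rcpp::IntegerVector::create(
      Rcpp::Named("in_ch") = u->in_ch, Rcpp::Named("base") = u->base,
      Rcpp::Named("levels") = u->levels);
}
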