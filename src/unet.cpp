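// Compact CPU U-Net: forward pass, composite loss (weighted cross-entropy +
// MAE + soft-Dice) and full backpropagation. The layer channel table is
// computed on the R side from the encoder spec (the "dynamic" decoder
// sizing); this file consumes it. Parameters travel as one flat vector so
// the optimizer (Adam, R side) stays architecture-agnostic.
//
// Activations are stored as (S*S x C) matrices in column-major order, so a
// channel is one contiguous column; im2col is built transposed (S*S x 9C)
// to keep every copy contiguous and let the convolution run as one GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// transposed im2col for 3x3 same-padding convolution on (S*S x C) input
static mat im2col3t(const mat &A, uword S) {
  const uword C = A.n_cols, N = S * S;
  mat K(N, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double *src = A.colptr(c);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        double *dst = K.colptr(c * 9 + (dr + 1) * 3 + (dc + 1));
        uword j0 = dc < 0 ? 1 : 0, j1 = dc > 0 ? S - 1 : S;
        uword r0 = dr < 0 ? 1 : 0, rlen = S - std::abs(dr);
        for (uword j = j0; j < j1; ++j) {
          // dest column j rows r0..r0+rlen-1 <- source column j+dc shifted dr
          std::memcpy(dst + j * S + r0, src + (j + dc) * S + r0 + dr,
                      rlen * sizeof(double));
        }
      }
    }
  }
  return K;
}

// transpose of im2col3t: scatter-add (S*S x 9C) back to (S*S x C)
static mat col2im3t(const mat &dK, uword S, uword C) {
  mat dA(S * S, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double *dst = dA.colptr(c);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const double *src = dK.colptr(c * 9 + (dr + 1) * 3 + (dc + 1));
        uword j0 = dc < 0 ? 1 : 0, j1 = dc > 0 ? S - 1 : S;
        uword r0 = dr < 0 ? 1 : 0, rlen = S - std::abs(dr);
        for (uword j = j0; j < j1; ++j) {
          double *d = dst + (j + dc) * S + r0 + dr;
          const double *s = src + j * S + r0;
          for (uword r = 0; r < rlen; ++r) d[r] += s[r];
        }
      }
    }
  }
  return dA;
}

struct ConvLayer {
  uword cin, cout, k; // k in {1,3}
  uword off_w, off_b; // offsets into the flat parameter vector
};

struct Net {
  std::vector<ConvLayer> layers;
  uword depth, n_classes, n_par;
};

static Net build_net(const Rcpp::IntegerMatrix &table, int depth, int n_classes) {
  Net net;
  net.depth = depth;
  net.n_classes = n_classes;
  uword off = 0;
  for (int i = 0; i < table.nrow(); ++i) {
    ConvLayer L;
    L.cin = table(i, 0);
    L.cout = table(i, 1);
    L.k = table(i, 2);
    L.off_w = off;
    off += L.cout * L.cin * L.k * L.k;
    L.off_b = off;
    off += L.cout;
    net.layers.push_back(L);
  }
  net.n_par = off;
  return net;
}

// weight as (cin*k*k x cout) so conv is Y = K * W
static mat Wof(const vec &par, const ConvLayer &L) {
  return reshape(par.subvec(L.off_w, L.off_w + L.cout * L.cin * L.k * L.k - 1),
                 L.cin * L.k * L.k, L.cout);
}
static rowvec bof(const vec &par, const ConvLayer &L) {
  return par.subvec(L.off_b, L.off_b + L.cout - 1).t();
}

static mat conv_fwd(const vec &par, const ConvLayer &L, const mat &A, uword S,
                    bool relu, mat &Kcache) {
  mat Y;
  if (L.k == 3) {
    Kcache = im2col3t(A, S);
    Y = Kcache * Wof(par, L);
  } else {
    Y = A * Wof(par, L);
  }
  Y.each_row() += bof(par, L);
  if (relu) Y.for_each([](double &v) { if (v < 0) v = 0; });
  return Y;
}

// dY is the gradient w.r.t. this layer's (post-ReLU) output
static mat conv_bwd(const vec &par, const ConvLayer &L, const mat &out,
                    const mat &in, uword S, const mat &Kcache, mat &dY,
                    bool relu, vec &grad) {
  if (relu) dY %= conv_to<mat>::from(out > 0);
  grad.subvec(L.off_b, L.off_b + L.cout - 1) += sum(dY, 0).t();
  if (L.k == 3) {
    mat dW = Kcache.t() * dY; // (9cin x N)(N x cout)
    grad.subvec(L.off_w, L.off_w + dW.n_elem - 1) += vectorise(dW);
    mat dK = dY * Wof(par, L).t(); // (N x 9cin)
    return col2im3t(dK, S, L.cin);
  } else {
    mat dW = in.t() * dY;
    grad.subvec(L.off_w, L.off_w + dW.n_elem - 1) += vectorise(dW);
    return dY * Wof(par, L).t();
  }
}

// 2x2 max pooling on (S*S x C); argmax offsets recorded for backprop
static mat maxpool2(const mat &A, uword S, umat &amax) {
  const uword T = S / 2, C = A.n_cols;
  mat Y(T * T, C);
  amax.set_size(T * T, C);
  for (uword c = 0; c < C; ++c) {
    const double *src = A.colptr(c);
    double *dst = Y.colptr(c);
    uword *am = amax.colptr(c);
    for (uword j = 0; j < T; ++j)
      for (uword i = 0; i < T; ++i) {
        uword base = (2 * j) * S + 2 * i;
        uword offs[4] = {base, base + 1, base + S, base + S + 1};
        double m = src[offs[0]];
        uword a = offs[0];
        for (int q = 1; q < 4; ++q)
          if (src[offs[q]] > m) { m = src[offs[q]]; a = offs[q]; }
        dst[j * T + i] = m;
        am[j * T + i] = a;
      }
  }
  return Y;
}

static mat maxpool2_bwd(const mat &dY, const umat &amax, uword S) {
  const uword C = dY.n_cols;
  mat dA(S * S, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double *dst = dA.colptr(c);
    const double *src = dY.colptr(c);
    const uword *am = amax.colptr(c);
    for (uword i = 0; i < dY.n_rows; ++i) dst[am[i]] += src[i];
  }
  return dA;
}

static mat upsample2(const mat &A, uword T) { // (T*T x C) -> (4T*T x C)
  const uword S = 2 * T, C = A.n_cols;
  mat Y(S * S, C);
  for (uword c = 0; c < C; ++c) {
    const double *src = A.colptr(c);
    double *dst = Y.colptr(c);
    for (uword j = 0; j < T; ++j)
      for (uword i = 0; i < T; ++i) {
        double v = src[j * T + i];
        uword base = (2 * j) * S + 2 * i;
        dst[base] = v;
        dst[base + 1] = v;
        dst[base + S] = v;
        dst[base + S + 1] = v;
      }
  }
  return Y;
}

static mat upsample2_bwd(const mat &dY, uword S) {
  const uword T = S / 2, C = dY.n_cols;
  mat dA(T * T, C);
  for (uword c = 0; c < C; ++c) {
    const double *src = dY.colptr(c);
    double *dst = dA.colptr(c);
    for (uword j = 0; j < T; ++j)
      for (uword i = 0; i < T; ++i) {
        uword base = (2 * j) * S + 2 * i;
        dst[j * T + i] = src[base] + src[base + 1] + src[base + S] + src[base + S + 1];
      }
  }
  return dA;
}

struct FwdState {
  std::vector<mat> enc_out;  // post second conv per level (pre-pool)
  std::vector<mat> ins;      // input of each conv layer, layer order
  std::vector<mat> Kc;       // im2col caches, layer order
  std::vector<mat> outs;     // post-activation outputs, layer order
  std::vector<umat> amax;    // pooling argmax per level
  std::vector<uword> sz;     // spatial side per layer
  mat drop_mask;
  mat logits;                // (S*S x n_classes)
};

static FwdState forward_net(const Net &net, const vec &par, const mat &x,
                            uword S0, double dropout) {
  FwdState st;
  const uword nl = net.layers.size();
  st.ins.resize(nl); st.Kc.resize(nl); st.outs.resize(nl); st.sz.resize(nl);
  uword li = 0, S = S0;
  mat cur = x;
  for (uword d = 0; d < net.depth; ++d) {
    st.ins[li] = cur; st.sz[li] = S;
    cur = conv_fwd(par, net.layers[li], cur, S, true, st.Kc[li]);
    st.outs[li] = cur; ++li;
    st.ins[li] = cur; st.sz[li] = S;
    cur = conv_fwd(par, net.layers[li], cur, S, true, st.Kc[li]);
    st.outs[li] = cur;
    st.enc_out.push_back(cur); ++li;
    umat am;
    cur = maxpool2(cur, S, am);
    st.amax.push_back(am);
    S /= 2;
  }
  st.ins[li] = cur; st.sz[li] = S;
  cur = conv_fwd(par, net.layers[li], cur, S, true, st.Kc[li]);
  st.outs[li] = cur; ++li;
  if (dropout > 0) {
    double keep = 1.0 - dropout;
    st.drop_mask.set_size(cur.n_rows, cur.n_cols);
    for (uword i = 0; i < st.drop_mask.n_elem; ++i)
      st.drop_mask(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    cur %= st.drop_mask;
  }
  for (uword lev = net.depth; lev-- > 0;) {
    mat up = upsample2(cur, S);
    S *= 2;
    mat cat = join_rows(up, st.enc_out[lev]);
    st.ins[li] = cat; st.sz[li] = S;
    cur = conv_fwd(par, net.layers[li], cat, S, true, st.Kc[li]);
    st.outs[li] = cur; ++li;
  }
  st.ins[li] = cur; st.sz[li] = S;
  st.logits = conv_fwd(par, net.layers[li], cur, S, false, st.Kc[li]);
  st.outs[li] = st.logits;
  return st;
}

static mat softmax_rows(const mat &z) {
  mat p = z;
  p.each_col() -= max(p, 1);
  p = exp(p);
  p.each_col() /= sum(p, 1);
  return p;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_unet_forward(Rcpp::NumericVector par_,
                                     Rcpp::NumericVector img_,
                                     Rcpp::IntegerMatrix layer_table,
                                     int depth, int n_classes) {
  Rcpp::IntegerVector dm = img_.attr("dim");
  uword S = dm[0];
  mat x(img_.begin(), S * S, dm[2]);
  vec par(par_.begin(), par_.size());
  Net net = build_net(layer_table, depth, n_classes);
  if ((uword)par.n_elem != net.n_par)
    Rcpp::stop("parameter vector length %d does not match architecture (%d)",
               (int)par.n_elem, (int)net.n_par);
  FwdState st = forward_net(net, par, x, S, 0.0);
  mat p = softmax_rows(st.logits);
  Rcpp::NumericVector out(p.memptr(), p.memptr() + p.n_elem);
  out.attr("dim") = Rcpp::IntegerVector::create(S, S, n_classes);
  return out;
}

// composite loss on probabilities (N x C) vs integer labels; fills dz
static double loss_and_dlogits(const mat &p, const ivec &y, const vec &cls_w,
                               const vec &comp_w, mat &dz, double *parts) {
  const uword N = p.n_rows, C = p.n_cols;
  vec w_px(N);
  for (uword i = 0; i < N; ++i) w_px(i) = cls_w(y(i));
  const double wsum = accu(w_px);
  // one-hot columns handled implicitly per class
  double ce = 0, mae = 0;
  vec sp(C), sy(C, fill::zeros), si(C, fill::zeros);
  for (uword c = 0; c < C; ++c) sp(c) = accu(p.col(c));
  for (uword i = 0; i < N; ++i) {
    uword yc = y(i);
    sy(yc) += 1.0;
    si(yc) += p(i, yc);
    ce += -w_px(i) * std::log(std::max(p(i, yc), 1e-12));
  }
  ce /= wsum;
  for (uword c = 0; c < C; ++c) mae += accu(abs(p.col(c)));
  // |p - y| = p for y=0 and 1-p for y=1: correct the positive entries
  for (uword i = 0; i < N; ++i) {
    uword yc = y(i);
    mae += (1.0 - p(i, yc)) - p(i, yc);
  }
  mae /= (double)(N * C);
  const double eps = 1e-7;
  double dice_mean = 0;
  vec denom(C);
  for (uword c = 0; c < C; ++c) {
    denom(c) = sp(c) + sy(c) + eps;
    dice_mean += 2.0 * si(c) / denom(c);
  }
  dice_mean /= C;
  // dL/dp (MAE + Dice), then chain through softmax; CE added on logits
  mat g(N, C);
  const double mae_n = 1.0 / (double)(N * C);
  for (uword c = 0; c < C; ++c) {
    const double d2 = denom(c) * denom(c);
    const double g_dice_neg = 2.0 * si(c) / d2 / C; // y = 0 entries
    const double g_dice_pos = -(2.0 * denom(c) - 2.0 * si(c)) / d2 / C;
    double *gc = g.colptr(c);
    const double *pc = p.colptr(c);
    for (uword i = 0; i < N; ++i) {
      bool pos = ((uword)y(i) == c);
      double g_mae = (pos ? (pc[i] > 1.0 ? 1.0 : -1.0) : (pc[i] > 0 ? 1.0 : 0.0)) * mae_n;
      gc[i] = comp_w(1) * g_mae + comp_w(2) * (pos ? g_dice_pos : g_dice_neg);
    }
  }
  vec dot = sum(g % p, 1);
  g.each_col() -= dot;
  dz = p % g;
  // weighted CE gradient on logits: w_y (p - onehot) / wsum
  mat pw = p;
  pw.each_col() %= w_px;
  dz += (comp_w(0) / wsum) * pw;
  for (uword i = 0; i < N; ++i)
    dz(i, y(i)) -= comp_w(0) * w_px(i) / wsum;
  parts[0] = ce;
  parts[1] = mae;
  parts[2] = 1.0 - dice_mean;
  return comp_w(0) * ce + comp_w(1) * mae + comp_w(2) * (1.0 - dice_mean);
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_lossgrad(Rcpp::NumericVector par_,
                             Rcpp::NumericVector img_,
                             Rcpp::IntegerMatrix mask,
                             Rcpp::NumericVector class_w_,
                             Rcpp::NumericVector comp_w_,
                             Rcpp::IntegerMatrix layer_table, int depth,
                             int n_classes, double dropout) {
  Rcpp::IntegerVector dm = img_.attr("dim");
  uword S = dm[0];
  mat x(img_.begin(), S * S, dm[2]);
  vec par(par_.begin(), par_.size());
  vec cls_w(class_w_.begin(), class_w_.size());
  vec comp_w(comp_w_.begin(), comp_w_.size());
  ivec y(S * S);
  for (uword i = 0; i < S * S; ++i) y(i) = mask[i];
  Net net = build_net(layer_table, depth, n_classes);
  if ((uword)par.n_elem != net.n_par)
    Rcpp::stop("parameter vector length %d does not match architecture (%d)",
               (int)par.n_elem, (int)net.n_par);
  Rcpp::RNGScope rng; // dropout uses R's RNG -> reproducible under set.seed
  FwdState st = forward_net(net, par, x, S, dropout);
  mat p = softmax_rows(st.logits);
  mat dz;
  double parts[3];
  double loss = loss_and_dlogits(p, y, cls_w, comp_w, dz, parts);
  vec grad(net.n_par, fill::zeros);
  std::vector<mat> skip_grad(net.depth);
  uword li = net.layers.size() - 1;
  mat d = conv_bwd(par, net.layers[li], st.outs[li], st.ins[li], st.sz[li],
                   st.Kc[li], dz, false, grad);
  --li;
  // decoder layers sit deep-to-shallow in layer order; walk them shallow-to-
  // deep (lev = encoder level of the skip connection)
  for (uword lev = 0; lev < net.depth; ++lev) {
    mat dcat = conv_bwd(par, net.layers[li], st.outs[li], st.ins[li],
                        st.sz[li], st.Kc[li], d, true, grad);
    --li;
    uword skip_ch = st.enc_out[lev].n_cols;
    uword upc = dcat.n_cols - skip_ch;
    skip_grad[lev] = dcat.cols(upc, dcat.n_cols - 1);
    mat dup = dcat.cols(0, upc - 1);
    d = upsample2_bwd(dup, (uword)std::sqrt((double)dup.n_rows));
  }
  if (st.drop_mask.n_elem > 0) d %= st.drop_mask;
  d = conv_bwd(par, net.layers[li], st.outs[li], st.ins[li], st.sz[li],
               st.Kc[li], d, true, grad);
  for (uword level = net.depth; level-- > 0;) {
    --li;
    uword S_lev = 2 * (uword)std::sqrt((double)d.n_rows);
    mat dpre = maxpool2_bwd(d, st.amax[level], S_lev);
    dpre += skip_grad[level];
    mat dmid = conv_bwd(par, net.layers[li], st.outs[li], st.ins[li],
                        st.sz[li], st.Kc[li], dpre, true, grad);
    --li;
    d = conv_bwd(par, net.layers[li], st.outs[li], st.ins[li], st.sz[li],
                 st.Kc[li], dmid, true, grad);
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("grad") = grad,
      Rcpp::Named("ce") = parts[0], Rcpp::Named("mae") = parts[1],
      Rcpp::Named("dice") = parts[2]);
}

// [[Rcpp::export]]
int cpp_unet_npar(Rcpp::IntegerMatrix layer_table, int depth, int n_classes) {
  return (int)build_net(layer_table, depth, n_classes).n_par;
}
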