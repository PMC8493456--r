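// Three-slice-input encoder-decoder segmentation networks (3intoUNet and an
// inception-style variant): forward pass, backpropagation and Adam updates.
// Dense linear algebra goes through Armadillo/BLAS (im2col + GEMM convolutions).
//
// Conventions:
//  - a feature map is an arma::cube (H x W x channels), column-major;
//  - the three input patches (previous/main/next slice) enter three encoder
//    branches with independent weights; skip features and bottleneck features
//    are summed element-wise across branches; the decoder is single-stream;
//  - patches of side `in_size` are zero-padded to P, the smallest multiple of
//    2^depth >= in_size, so max-pooling always halves exactly; the loss and
//    the returned probability maps are restricted to the central in_size^2.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct ConvDesc {
  int type;          // 0 = same-padding conv, 1 = 2x2 stride-2 transposed conv
  int k, cin, cout;
  uword woff, boff;  // offsets into the flat parameter vector
};

struct NetDesc {
  int variant, depth, base, K, in_size, P, pad0;
  std::vector<ConvDesc> convs;
  std::vector<int> ch;   // channels per encoder level, ch[depth] = bottleneck
  uword nparam;
};

static NetDesc build_desc(int variant, int depth, int base, int K, int in_size) {
  if (depth < 1) Rcpp::stop("encoder depth must be >= 1");
  if (K < 2) Rcpp::stop("need at least 2 classes");
  if (variant == 1 && base % 4 != 0)
    Rcpp::stop("inception variant needs base_channels divisible by 4");
  NetDesc D;
  D.variant = variant; D.depth = depth; D.base = base; D.K = K; D.in_size = in_size;
  int m = 1 << depth;
  D.P = ((in_size + m - 1) / m) * m;
  D.pad0 = (D.P - in_size) / 2;
  D.ch.resize(depth + 1);
  for (int l = 0; l <= depth; ++l) D.ch[l] = base << l;
  uword off = 0;
  auto add = [&](int type, int k, int cin, int cout) {
    ConvDesc c; c.type = type; c.k = k; c.cin = cin; c.cout = cout;
    uword wn = (type == 0 ? (uword)k * k * cin : (uword)4 * cin) * cout;
    c.woff = off; off += wn;
    c.boff = off; off += cout;
    D.convs.push_back(c);
  };
  for (int b = 0; b < 3; ++b) {
    int cin = 1;
    for (int l = 0; l < depth; ++l) {
      int c = D.ch[l];
      if (variant == 0) {            // plain U-Net double-conv block
        add(0, 3, cin, c); add(0, 3, c, c);
      } else {                       // inception-style block: 1x1 | 3x3 | 3x3+3x3
        add(0, 1, cin, c / 2);
        add(0, 3, cin, c / 4);
        add(0, 3, cin, c / 4); add(0, 3, c / 4, c / 4);
      }
      cin = c;
    }
  }
  add(0, 3, D.ch[depth - 1], D.ch[depth]);   // bottleneck double conv
  add(0, 3, D.ch[depth],     D.ch[depth]);
  for (int l = depth - 1; l >= 0; --l) {
    add(1, 2, D.ch[l + 1], D.ch[l]);         // up-conv
    add(0, 3, 2 * D.ch[l], D.ch[l]);         // after concat with summed skip
    add(0, 3, D.ch[l],     D.ch[l]);
  }
  add(0, 1, D.ch[0], K);                     // logits
  D.nparam = off;
  return D;
}

// ---- im2col / col2im --------------------------------------------------------

static mat im2col(const cube& in, int k) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices, pad = k / 2;
  mat cols((uword)H * W, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& s = in.slice(c);
    for (int dy = 0; dy < k; ++dy) for (int dx = 0; dx < k; ++dx) {
      const int ci = (dy * k + dx) * C + c;
      const int sy = dy - pad, sx = dx - pad;
      const int y0 = std::max(0, -sy), y1 = std::min(H, H - sy);
      const int x0 = std::max(0, -sx), x1 = std::min(W, W - sx);
      if (y1 <= y0 || x1 <= x0) continue;
      double* dst = cols.colptr(ci);
      for (int x = x0; x < x1; ++x)
        std::memcpy(dst + (uword)x * H + y0,
                    s.colptr(x + sx) + (y0 + sy),
                    (size_t)(y1 - y0) * sizeof(double));
    }
  }
  return cols;
}

static cube col2im(const mat& gcols, int H, int W, int C, int k) {
  const int pad = k / 2;
  cube gin(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& s = gin.slice(c);
    for (int dy = 0; dy < k; ++dy) for (int dx = 0; dx < k; ++dx) {
      const int ci = (dy * k + dx) * C + c;
      const int sy = dy - pad, sx = dx - pad;
      const int y0 = std::max(0, -sy), y1 = std::min(H, H - sy);
      const int x0 = std::max(0, -sx), x1 = std::min(W, W - sx);
      if (y1 <= y0 || x1 <= x0) continue;
      const double* src = gcols.colptr(ci);
      for (int x = x0; x < x1; ++x) {
        double* dp = s.colptr(x + sx) + (y0 + sy);
        const double* sp = src + (uword)x * H + y0;
        for (int y = 0; y < y1 - y0; ++y) dp[y] += sp[y];
      }
    }
  }
  return gin;
}

// ---- layer forward/backward -------------------------------------------------

struct CCache {           // per-conv cache for backprop
  int di = -1;
  mat cols;               // im2col matrix (type 0) or flattened input (type 1)
  cube out;               // post-activation output (ReLU mask source)
  bool relu = false;
  int inH = 0, inW = 0;
};

static cube conv_fwd(const vec& w, const NetDesc& D, int di, const cube& in,
                     bool relu, CCache& C) {
  const ConvDesc& d = D.convs[di];
  C.di = di; C.relu = relu; C.inH = in.n_rows; C.inW = in.n_cols;
  cube out;
  if (d.type == 0) {
    const mat W(const_cast<double*>(w.memptr()) + d.woff,
                (uword)d.k * d.k * d.cin, d.cout, false, true);
    C.cols = im2col(in, d.k);
    mat o = C.cols * W;
    for (int co = 0; co < d.cout; ++co) o.col(co) += w(d.boff + co);
    out = cube(in.n_rows, in.n_cols, d.cout);
    std::memcpy(out.memptr(), o.memptr(), o.n_elem * sizeof(double));
  } else {
    const int h = in.n_rows, wd = in.n_cols;
    const mat W(const_cast<double*>(w.memptr()) + d.woff,
                (uword)4 * d.cin, d.cout, false, true);
    C.cols = mat(in.memptr(), (uword)h * wd, d.cin);
    out.zeros(2 * h, 2 * wd, d.cout);
    for (int off = 0; off < 4; ++off) {
      const int dy = off % 2, dx = off / 2;
      mat O = C.cols * W.rows((uword)off * d.cin, (uword)(off + 1) * d.cin - 1);
      for (int co = 0; co < d.cout; ++co) {
        mat& os = out.slice(co);
        const double* op = O.colptr(co);
        for (int x = 0; x < wd; ++x)
          for (int y = 0; y < h; ++y)
            os(2 * y + dy, 2 * x + dx) = op[(uword)x * h + y];
      }
    }
    for (int co = 0; co < d.cout; ++co) out.slice(co) += w(d.boff + co);
  }
  if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  C.out = out;
  return out;
}

static cube conv_bwd(const vec& w, vec& g, const NetDesc& D, const CCache& C,
                     cube gout) {
  const ConvDesc& d = D.convs[C.di];
  if (C.relu)
    for (uword i = 0; i < gout.n_elem; ++i)
      if (C.out(i) <= 0) gout(i) = 0.0;
  if (d.type == 0) {
    const mat W(const_cast<double*>(w.memptr()) + d.woff,
                (uword)d.k * d.k * d.cin, d.cout, false, true);
    const mat gom(gout.memptr(), (uword)C.inH * C.inW, d.cout, false, true);
    mat gW = C.cols.t() * gom;
    g.subvec(d.woff, d.woff + gW.n_elem - 1) += vectorise(gW);
    g.subvec(d.boff, d.boff + d.cout - 1) += sum(gom, 0).t();
    mat gcols = gom * W.t();
    return col2im(gcols, C.inH, C.inW, d.cin, d.k);
  }
  const int h = C.inH, wd = C.inW;
  const mat W(const_cast<double*>(w.memptr()) + d.woff,
              (uword)4 * d.cin, d.cout, false, true);
  cube gin(h, wd, d.cin, fill::zeros);
  mat ginm(gin.memptr(), (uword)h * wd, d.cin, false, true);
  mat gWfull((uword)4 * d.cin, d.cout, fill::zeros);
  rowvec gb(d.cout, fill::zeros);
  for (int off = 0; off < 4; ++off) {
    const int dy = off % 2, dx = off / 2;
    mat Goff((uword)h * wd, d.cout);
    for (int co = 0; co < d.cout; ++co) {
      double* gp = Goff.colptr(co);
      const mat& gs = gout.slice(co);
      for (int x = 0; x < wd; ++x)
        for (int y = 0; y < h; ++y)
          gp[(uword)x * h + y] = gs(2 * y + dy, 2 * x + dx);
    }
    gWfull.rows((uword)off * d.cin, (uword)(off + 1) * d.cin - 1) = C.cols.t() * Goff;
    ginm += Goff * W.rows((uword)off * d.cin, (uword)(off + 1) * d.cin - 1).t();
    gb += sum(Goff, 0);
  }
  g.subvec(d.woff, d.woff + gWfull.n_elem - 1) += vectorise(gWfull);
  g.subvec(d.boff, d.boff + d.cout - 1) += gb.t();
  return gin;
}

static cube pool_fwd(const cube& in, Cube<uword>& idx) {
  const int H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  cube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    const mat& s = in.slice(c);
    for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y) {
      double best = s(2 * y, 2 * x); uword bi = 0; double v;
      v = s(2 * y + 1, 2 * x);     if (v > best) { best = v; bi = 1; }
      v = s(2 * y,     2 * x + 1); if (v > best) { best = v; bi = 2; }
      v = s(2 * y + 1, 2 * x + 1); if (v > best) { best = v; bi = 3; }
      out(y, x, c) = best; idx(y, x, c) = bi;
    }
  }
  return out;
}

static cube pool_bwd(const cube& gr, const Cube<uword>& idx) {
  const int H = gr.n_rows, W = gr.n_cols, C = gr.n_slices;
  cube gin(2 * H, 2 * W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x) for (int y = 0; y < H; ++y) {
      const uword bi = idx(y, x, c);
      gin(2 * y + (bi & 1u), 2 * x + (bi >> 1), c) = gr(y, x, c);
    }
  return gin;
}

// ---- whole-network forward (+cache) and backward ----------------------------

struct FCache {
  std::vector<std::vector<std::vector<CCache>>> bconv; // [branch][level][conv]
  std::vector<std::vector<Cube<uword>>> pidx;          // [branch][level]
  std::vector<cube> skipsum;                           // [level]
  CCache bn1, bn2;
  cube drop_mask; bool dropped = false;
  std::vector<CCache> dup, dc1, dc2;                   // [level]
  CCache fin;
};

static cube net_forward(const vec& w, const NetDesc& D, const cube& x,
                        FCache& F, bool train, double dropout,
                        std::mt19937& rng) {
  int ci = 0;
  F.bconv.assign(3, {}); F.pidx.assign(3, {});
  F.skipsum.assign(D.depth, cube());
  std::vector<cube> pooled(3);
  for (int b = 0; b < 3; ++b) {
    cube cur(D.P, D.P, 1, fill::zeros);
    cur.slice(0).submat(D.pad0, D.pad0,
                        D.pad0 + D.in_size - 1, D.pad0 + D.in_size - 1) = x.slice(b);
    F.bconv[b].resize(D.depth); F.pidx[b].resize(D.depth);
    for (int l = 0; l < D.depth; ++l) {
      cube skip;
      if (D.variant == 0) {
        F.bconv[b][l].resize(2);
        cube a = conv_fwd(w, D, ci, cur, true, F.bconv[b][l][0]); ++ci;
        skip   = conv_fwd(w, D, ci, a,   true, F.bconv[b][l][1]); ++ci;
      } else {
        F.bconv[b][l].resize(4);
        cube p1  = conv_fwd(w, D, ci, cur, true, F.bconv[b][l][0]); ++ci;
        cube p2  = conv_fwd(w, D, ci, cur, true, F.bconv[b][l][1]); ++ci;
        cube p3a = conv_fwd(w, D, ci, cur, true, F.bconv[b][l][2]); ++ci;
        cube p3b = conv_fwd(w, D, ci, p3a, true, F.bconv[b][l][3]); ++ci;
        skip = join_slices(join_slices(p1, p2), p3b);
      }
      if (b == 0) F.skipsum[l] = skip; else F.skipsum[l] += skip;
      cur = pool_fwd(skip, F.pidx[b][l]);
    }
    pooled[b] = cur;
  }
  cube t = pooled[0] + pooled[1] + pooled[2];
  t = conv_fwd(w, D, ci, t, true, F.bn1); ++ci;
  t = conv_fwd(w, D, ci, t, true, F.bn2); ++ci;
  F.dropped = false;
  if (train && dropout > 0) {
    std::uniform_real_distribution<double> ud(0.0, 1.0);
    F.drop_mask.set_size(size(t));
    const double keep = 1.0 - dropout;
    for (uword i = 0; i < t.n_elem; ++i)
      F.drop_mask(i) = (ud(rng) < keep) ? 1.0 / keep : 0.0;
    t %= F.drop_mask;
    F.dropped = true;
  }
  F.dup.resize(D.depth); F.dc1.resize(D.depth); F.dc2.resize(D.depth);
  for (int l = D.depth - 1; l >= 0; --l) {
    cube u = conv_fwd(w, D, ci, t, false, F.dup[l]); ++ci;
    cube cat = join_slices(u, F.skipsum[l]);
    cube a = conv_fwd(w, D, ci, cat, true, F.dc1[l]); ++ci;
    t      = conv_fwd(w, D, ci, a,   true, F.dc2[l]); ++ci;
  }
  return conv_fwd(w, D, ci, t, false, F.fin);  // logits, P x P x K
}

// softmax + (optionally class-weighted) cross-entropy on labelled pixels;
// labels(y,x) in {0..K-1}, or -1 for ignore (the padding ring).
static double net_backward(const vec& w, vec& g, const NetDesc& D, FCache& F,
                           const cube& logits, const Mat<int>& labels,
                           const vec& cw) {
  const int H = D.P;
  cube glog(H, H, D.K, fill::zeros);
  double loss = 0.0, wsum = 0.0;
  std::vector<double> e(D.K);
  for (int x = 0; x < H; ++x) for (int y = 0; y < H; ++y) {
    const int lab = labels(y, x);
    if (lab < 0) continue;
    double mx = logits(y, x, 0);
    for (int k = 1; k < D.K; ++k) mx = std::max(mx, logits(y, x, k));
    double s = 0.0;
    for (int k = 0; k < D.K; ++k) { e[k] = std::exp(logits(y, x, k) - mx); s += e[k]; }
    const double wt = cw(lab);
    loss += -wt * std::log(std::max(e[lab] / s, 1e-300));
    wsum += wt;
    for (int k = 0; k < D.K; ++k)
      glog(y, x, k) = wt * (e[k] / s - (k == lab ? 1.0 : 0.0));
  }
  if (wsum <= 0) Rcpp::stop("no labelled pixels in sample");
  loss /= wsum; glog /= wsum;

  cube gt = conv_bwd(w, g, D, F.fin, glog);
  std::vector<cube> gskip(D.depth);
  for (int l = 0; l < D.depth; ++l) {
    gt = conv_bwd(w, g, D, F.dc2[l], gt);
    cube gcat = conv_bwd(w, g, D, F.dc1[l], gt);
    const int c = D.ch[l];
    cube gu = gcat.slices(0, c - 1);
    gskip[l] = gcat.slices(c, 2 * c - 1);
    gt = conv_bwd(w, g, D, F.dup[l], gu);
  }
  if (F.dropped) gt %= F.drop_mask;
  gt = conv_bwd(w, g, D, F.bn2, gt);
  cube gxb = conv_bwd(w, g, D, F.bn1, gt);
  for (int b = 0; b < 3; ++b) {
    cube gcur = gxb;
    for (int l = D.depth - 1; l >= 0; --l) {
      cube gs = pool_bwd(gcur, F.pidx[b][l]);
      gs += gskip[l];
      if (D.variant == 0) {
        gs   = conv_bwd(w, g, D, F.bconv[b][l][1], gs);
        gcur = conv_bwd(w, g, D, F.bconv[b][l][0], gs);
      } else {
        const int c = D.ch[l];
        cube g1 = gs.slices(0, c / 2 - 1);
        cube g2 = gs.slices(c / 2, c / 2 + c / 4 - 1);
        cube g3 = gs.slices(c / 2 + c / 4, c - 1);
        cube gi  = conv_bwd(w, g, D, F.bconv[b][l][0], g1);
        gi      += conv_bwd(w, g, D, F.bconv[b][l][1], g2);
        cube g3a = conv_bwd(w, g, D, F.bconv[b][l][3], g3);
        gi      += conv_bwd(w, g, D, F.bconv[b][l][2], g3a);
        gcur = gi;
      }
    }
  }
  return loss;
}

// ---- R interface ------------------------------------------------------------

static cube as_input(const Rcpp::NumericVector& x, int in_size) {
  Rcpp::IntegerVector dm = x.attr("dim");
  if (dm.size() != 3 || dm[0] != in_size || dm[1] != in_size || dm[2] != 3)
    Rcpp::stop("input must be an in_size x in_size x 3 array");
  cube c(in_size, in_size, 3);
  std::memcpy(c.memptr(), x.begin(), x.size() * sizeof(double));
  return c;
}

// [[Rcpp::export]]
double cnet_param_count(int variant, int depth, int base, int nclasses, int in_size) {
  return (double)build_desc(variant, depth, base, nclasses, in_size).nparam;
}

// [[Rcpp::export]]
Rcpp::NumericVector cnet_init_weights(int variant, int depth, int base,
                                      int nclasses, int in_size, int seed) {
  NetDesc D = build_desc(variant, depth, base, nclasses, in_size);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  Rcpp::NumericVector w(D.nparam);
  for (const ConvDesc& d : D.convs) {
    const uword fan = (d.type == 0 ? (uword)d.k * d.k * d.cin : (uword)4 * d.cin);
    const uword wn = fan * d.cout;
    const double sd = std::sqrt(2.0 / (double)fan);
    for (uword i = 0; i < wn; ++i) w[d.woff + i] = nd(rng) * sd;
    for (int i = 0; i < d.cout; ++i) w[d.boff + i] = 0.0;
  }
  return w;
}

// [[Rcpp::export]]
Rcpp::NumericVector cnet_predict(Rcpp::NumericVector weights, int variant, int depth,
                                 int base, int nclasses, int in_size,
                                 Rcpp::NumericVector x) {
  NetDesc D = build_desc(variant, depth, base, nclasses, in_size);
  if ((uword)weights.size() != D.nparam) Rcpp::stop("weight vector has wrong length");
  vec w(weights.begin(), weights.size());
  cube xi = as_input(x, in_size);
  FCache F;
  std::mt19937 rng(0);
  cube logits = net_forward(w, D, xi, F, false, 0.0, rng);
  Rcpp::NumericVector out(Rcpp::Dimension(in_size, in_size, nclasses));
  cube probs(out.begin(), in_size, in_size, nclasses, false, true);
  const int o = D.pad0;
  for (int x2 = 0; x2 < in_size; ++x2) for (int y = 0; y < in_size; ++y) {
    double mx = logits(o + y, o + x2, 0);
    for (int k = 1; k < nclasses; ++k) mx = std::max(mx, logits(o + y, o + x2, k));
    double s = 0.0;
    for (int k = 0; k < nclasses; ++k) {
      const double e = std::exp(logits(o + y, o + x2, k) - mx);
      probs(y, x2, k) = e; s += e;
    }
    for (int k = 0; k < nclasses; ++k) probs(y, x2, k) /= s;
  }
  return out;
}

// Runs the given samples (in order) in mini-batches, one Adam step per batch.
// X: list of in_size x in_size x 3 arrays; Y: list of in_size x in_size integer
// label matrices (0-based classes). Returns updated parameters, Adam state and
// the per-batch mean loss.
// [[Rcpp::export]]
Rcpp::List cnet_train_batches(Rcpp::NumericVector weights, Rcpp::NumericVector m_,
                              Rcpp::NumericVector v_, int t, int variant, int depth,
                              int base, int nclasses, int in_size,
                              Rcpp::List X, Rcpp::List Y, double lr,
                              Rcpp::NumericVector class_weights, double dropout,
                              int seed, int batch_size) {
  NetDesc D = build_desc(variant, depth, base, nclasses, in_size);
  if ((uword)weights.size() != D.nparam) Rcpp::stop("weight vector has wrong length");
  if ((uword)m_.size() != D.nparam || (uword)v_.size() != D.nparam)
    Rcpp::stop("Adam state has wrong length");
  if (class_weights.size() != nclasses) Rcpp::stop("need one class weight per class");
  if (X.size() != Y.size()) Rcpp::stop("X and Y lengths differ");
  if (batch_size < 1) Rcpp::stop("batch_size must be >= 1");
  const int n = X.size();
  vec w(weights.begin(), weights.size());
  vec m(m_.begin(), m_.size());
  vec v(v_.begin(), v_.size());
  vec cw(class_weights.begin(), class_weights.size());
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  std::mt19937 rng((unsigned)seed);
  std::vector<double> losses;
  int i = 0;
  while (i < n) {
    const int bend = std::min(n, i + batch_size);
    const int bs = bend - i;
    vec g(D.nparam, fill::zeros);
    double bloss = 0.0;
    for (int j = i; j < bend; ++j) {
      cube xi = as_input(X[j], in_size);
      Rcpp::IntegerMatrix yj = Y[j];
      if (yj.nrow() != in_size || yj.ncol() != in_size)
        Rcpp::stop("label matrix has wrong shape");
      Mat<int> lab(D.P, D.P);
      lab.fill(-1);
      for (int xx = 0; xx < in_size; ++xx)
        for (int yy = 0; yy < in_size; ++yy)
          lab(D.pad0 + yy, D.pad0 + xx) = yj(yy, xx);
      FCache F;
      cube logits = net_forward(w, D, xi, F, true, dropout, rng);
      bloss += net_backward(w, g, D, F, logits, lab, cw);
      Rcpp::checkUserInterrupt();
    }
    g /= (double)bs;
    bloss /= (double)bs;
    ++t;
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * square(g);
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
    losses.push_back(bloss);
    i = bend;
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = Rcpp::NumericVector(w.begin(), w.end()),
    Rcpp::Named("m") = Rcpp::NumericVector(m.begin(), m.end()),
    Rcpp::Named("v") = Rcpp::NumericVector(v.begin(), v.end()),
    Rcpp::Named("t") = t,
    Rcpp::Named("losses") = Rcpp::NumericVector(losses.begin(), losses.end()));
}
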