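// ConvNeXt forward/backward kernels.
//
// The network is a patchify stem (4x4 stride-4 conv + channelwise LayerNorm),
// four stages of residual blocks (7x7 depthwise conv -> LayerNorm -> 1x1
// expansion -> GELU -> 1x1 projection -> residual add) separated by
// LayerNorm + 2x2 stride-2 downsampling convs, then global average pooling,
// LayerNorm and a linear head. Activations are (H, W, C) cubes; pointwise
// convolutions run as (H*W x C) matrix products. Parameters arrive as a
// named R list; gradients are returned as a list with matching names/shapes.
//
// LayerNorm follows mu = mean(a), sigma = sqrt(mean((a-mu)^2)) and
// normalizes as (a - mu) / (sigma + eps) (note: eps added to sigma, not to
// the variance), with learnable per-unit scale/shift.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double SQRT1_2 = 0.70710678118654752440;
static const double INV_SQRT_2PI = 0.39894228040143267794;
static const double SQRT_2_PI = 0.79788456080286535588; // sqrt(2/pi)

// ---------------------------------------------------------------- basics --

static inline double gelu_exact(double z) {
  return 0.5 * z * (1.0 + std::erf(z * SQRT1_2));
}
static inline double gelu_exact_d(double z) {
  double Phi = 0.5 * (1.0 + std::erf(z * SQRT1_2));
  double phi = INV_SQRT_2PI * std::exp(-0.5 * z * z);
  return Phi + z * phi;
}
static inline double gelu_tanh(double z) {
  double u = SQRT_2_PI * (z + 0.044715 * z * z * z);
  return 0.5 * z * (1.0 + std::tanh(u));
}
static inline double gelu_tanh_d(double z) {
  double u = SQRT_2_PI * (z + 0.044715 * z * z * z);
  double t = std::tanh(u);
  double sech2 = 1.0 - t * t;
  double du = SQRT_2_PI * (1.0 + 3.0 * 0.044715 * z * z);
  return 0.5 * (1.0 + t) + 0.5 * z * sech2 * du;
}

// erf with ~1.5e-7 absolute accuracy (Abramowitz & Stegun 7.1.26); much
// faster than libm erf and well inside the network's numerical needs.
static inline double erf_fast(double x) {
  double ax = std::fabs(x);
  double t = 1.0 / (1.0 + 0.3275911 * ax);
  double y = 1.0 -
             (((((1.061405429 * t - 1.453152027) * t) + 1.421413741) * t -
               0.284496736) * t + 0.254829592) * t * std::exp(-ax * ax);
  return x < 0 ? -y : y;
}

static mat gelu_fwd_mat(const mat& z, bool tanh_mode) {
  mat y(z.n_rows, z.n_cols);
  const double* zp = z.memptr();
  double* yp = y.memptr();
  size_t n = z.n_elem;
  if (tanh_mode) {
    for (size_t i = 0; i < n; ++i) yp[i] = gelu_tanh(zp[i]);
  } else {
    for (size_t i = 0; i < n; ++i) {
      yp[i] = 0.5 * zp[i] * (1.0 + erf_fast(zp[i] * SQRT1_2));
    }
  }
  return y;
}

// One-pass GELU: value and derivative together (shares the erf/exp work);
// used in the training path so the backward pass needs no re-evaluation.
static void gelu_fwd_grad_mat(const mat& z, bool tanh_mode, mat& y, mat& g) {
  y.set_size(z.n_rows, z.n_cols);
  g.set_size(z.n_rows, z.n_cols);
  const double* zp = z.memptr();
  double* yp = y.memptr();
  double* gp = g.memptr();
  size_t n = z.n_elem;
  if (tanh_mode) {
    for (size_t i = 0; i < n; ++i) {
      yp[i] = gelu_tanh(zp[i]);
      gp[i] = gelu_tanh_d(zp[i]);
    }
  } else {
    for (size_t i = 0; i < n; ++i) {
      double zi = zp[i];
      double Phi = 0.5 * (1.0 + erf_fast(zi * SQRT1_2));
      double phi = INV_SQRT_2PI * std::exp(-0.5 * zi * zi);
      yp[i] = zi * Phi;
      gp[i] = Phi + zi * phi;
    }
  }
}

// LayerNorm over rows of X (each row is one position's channel vector).
static void ln_fwd(const mat& X, const vec& g, const vec& b, double eps,
                   mat& out, mat& xhat, vec& sd) {
  vec mu = arma::mean(X, 1);
  mat D = X.each_col() - mu;
  sd = arma::sqrt(arma::mean(D % D, 1));
  vec d = sd + eps;
  xhat = D.each_col() / d;
  out = xhat.each_row() % g.t();
  out.each_row() += b.t();
}

// Backward of ln_fwd. Accumulates parameter grads into gg/gb, writes input
// grad into GA.
static void ln_bwd(const mat& Gout, const mat& xhat, const vec& sd,
                   double eps, const vec& g, mat& GA, vec& gg, vec& gb) {
  gg += arma::sum(Gout % xhat, 0).t();
  gb += arma::sum(Gout, 0).t();
  mat Gx = Gout.each_row() % g.t();
  vec d = sd + eps;
  vec mg = arma::mean(Gx, 1);
  vec mgx = arma::mean(Gx % xhat, 1);
  GA = Gx.each_col() - mg;
  GA.each_col() /= d;
  // sigma-path term; vanishes when sd == 0 (xhat is zero there too)
  vec t(sd.n_elem);
  for (arma::uword i = 0; i < sd.n_elem; ++i) {
    t(i) = sd(i) > 0 ? mgx(i) / sd(i) : 0.0;
  }
  GA -= xhat.each_col() % t;
}

// im2col for a valid strided convolution: rows = output positions
// (column-major over the Ho x Wo grid, matching the activation layout),
// cols = (ki, kj, ci) patch entries, matching the (k, k, cin, cout) weight
// layout flattened to (k*k*cin, cout).
static mat conv_im2col(const cube& x, int k, int st, int Ho, int Wo) {
  int cin = x.n_slices;
  int H = x.n_rows;
  mat X(Ho * Wo, (size_t)k * k * cin);
  for (int ci = 0; ci < cin; ++ci) {
    const double* xs = x.memptr() + (size_t)ci * H * x.n_cols;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = X.colptr(ki + k * (kj + k * ci));
        for (int j = 0; j < Wo; ++j) {
          const double* src = xs + (size_t)(j * st + kj) * H + ki;
          double* dst = col + (size_t)j * Ho;
          for (int i = 0; i < Ho; ++i) dst[i] = src[(size_t)i * st];
        }
      }
    }
  }
  return X;
}

// Standard (valid, strided) convolution; w laid out (k, k, cin, cout)
// column-major. GEMM over the im2col matrix.
static void conv2d_fwd(const cube& x, const double* w, const vec& b, int k,
                       int st, int cout, cube& out) {
  int cin = x.n_slices;
  int Ho = (x.n_rows - k) / st + 1;
  int Wo = (x.n_cols - k) / st + 1;
  out.set_size(Ho, Wo, cout);
  mat X = conv_im2col(x, k, st, Ho, Wo);
  const mat W(const_cast<double*>(w), (size_t)k * k * cin, cout, false);
  mat O(out.memptr(), Ho * Wo, cout, false);
  O = X * W;
  O.each_row() += b.t();
}

static void conv2d_bwd(const cube& x, const double* w, int k, int st,
                       const cube& gy, cube& gx, double* gw, vec& gb) {
  int cin = x.n_slices, cout = gy.n_slices;
  int Ho = gy.n_rows, Wo = gy.n_cols;
  int H = x.n_rows;
  const mat G(const_cast<double*>(gy.memptr()), Ho * Wo, cout, false);
  mat X = conv_im2col(x, k, st, Ho, Wo);
  const mat W(const_cast<double*>(w), (size_t)k * k * cin, cout, false);
  mat GW(gw, (size_t)k * k * cin, cout, false);
  GW += X.t() * G;
  gb += arma::sum(G, 0).t();
  // col2im scatter of G * W^T
  mat GX = G * W.t();
  gx.zeros(x.n_rows, x.n_cols, cin);
  for (int ci = 0; ci < cin; ++ci) {
    double* xs = gx.memptr() + (size_t)ci * H * gx.n_cols;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = GX.colptr(ki + k * (kj + k * ci));
        for (int j = 0; j < Wo; ++j) {
          double* dst = xs + (size_t)(j * st + kj) * H + ki;
          const double* src = col + (size_t)j * Ho;
          for (int i = 0; i < Ho; ++i) dst[(size_t)i * st] += src[i];
        }
      }
    }
  }
}

// Depthwise same-padded (zero) convolution, odd kernel, w is (k, k, C).
// Implemented as k*k shifted submatrix AXPYs, which vectorize well.
static void dwconv_fwd(const cube& x, const cube& w, const vec& b, cube& out) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int k = w.n_rows, P = (k - 1) / 2;
  out.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.memptr() + (size_t)c * H * W;
    const double* ws = w.memptr() + (size_t)c * k * k;
    double* os = out.memptr() + (size_t)c * H * W;
    double bc = b(c);
    for (size_t t = 0; t < (size_t)H * W; ++t) os[t] = bc;
    for (int kj = 0; kj < k; ++kj) {
      int dj = kj - P;
      int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
      if (j1 < j0) continue;
      for (int ki = 0; ki < k; ++ki) {
        int di = ki - P;
        int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        if (i1 < i0) continue;
        double wv = ws[ki + k * kj];
        int len = i1 - i0 + 1;
        for (int j = j0; j <= j1; ++j) {
          double* op = os + (size_t)j * H + i0;
          const double* ip = xs + (size_t)(j + dj) * H + i0 + di;
          for (int i = 0; i < len; ++i) op[i] += wv * ip[i];
        }
      }
    }
  }
}

static void dwconv_bwd(const cube& x, const cube& w, const cube& gy,
                       cube& gx, cube& gw, vec& gb) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int k = w.n_rows, P = (k - 1) / 2;
  gx.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.memptr() + (size_t)c * H * W;
    const double* ws = w.memptr() + (size_t)c * k * k;
    const double* gs = gy.memptr() + (size_t)c * H * W;
    double* gxs = gx.memptr() + (size_t)c * H * W;
    double* gws = gw.memptr() + (size_t)c * k * k;
    double acc = 0;
    for (size_t t = 0; t < (size_t)H * W; ++t) acc += gs[t];
    gb(c) += acc;
    for (int kj = 0; kj < k; ++kj) {
      int dj = kj - P;
      int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
      if (j1 < j0) continue;
      for (int ki = 0; ki < k; ++ki) {
        int di = ki - P;
        int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        if (i1 < i0) continue;
        double wv = ws[ki + k * kj];
        double wg = 0;
        int len = i1 - i0 + 1;
        for (int j = j0; j <= j1; ++j) {
          const double* gp = gs + (size_t)j * H + i0;
          const double* ip = xs + (size_t)(j + dj) * H + i0 + di;
          double* gxp = gxs + (size_t)(j + dj) * H + i0 + di;
          for (int i = 0; i < len; ++i) {
            wg += gp[i] * ip[i];
            gxp[i] += wv * gp[i];
          }
        }
        gws[ki + k * kj] += wg;
      }
    }
  }
}

// --------------------------------------------------------- param plumbing --

struct Cfg {
  arma::ivec depths, widths;
  int patch, patch_stride, dwk, expand, K, input;
  double eps;
  bool tanh_mode;
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.depths = as<arma::ivec>(cfg["stage_depths"]);
  c.widths = as<arma::ivec>(cfg["stage_widths"]);
  c.patch = as<int>(cfg["patch_size"]);
  c.patch_stride = as<int>(cfg["patch_stride"]);
  c.dwk = as<int>(cfg["dw_kernel"]);
  c.expand = as<int>(cfg["expansion_ratio"]);
  c.K = as<int>(cfg["num_classes"]);
  c.eps = as<double>(cfg["norm_epsilon"]);
  std::string gm = as<std::string>(cfg["gelu_mode"]);
  c.tanh_mode = (gm == "tanh");
  c.input = as<int>(cfg["input_size"]);
  return c;
}

static NumericVector getp(const List& p, const std::string& name) {
  if (!p.containsElementNamed(name.c_str())) {
    stop("missing parameter '%s'", name);
  }
  return p[name];
}
static vec as_view(NumericVector v) { return vec(v.begin(), v.size(), false); }

struct BlockP {
  cube dww; vec dwb, lng, lnb;
  mat w1; vec b1; mat w2; vec b2;
};
struct NetP {
  NumericVector stem_w; vec stem_b, stem_lng, stem_lnb;
  std::vector<std::vector<BlockP> > blk;
  vec ds_lng[3], ds_lnb[3], ds_b[3];
  NumericVector ds_w[3];
  vec head_lng, head_lnb, head_b;
  mat head_w;
};

static std::string bname(int s, int k, const char* part) {
  char buf[64];
  std::snprintf(buf, sizeof(buf), "s%d.b%d.%s", s + 1, k + 1, part);
  return std::string(buf);
}
static std::string dname(int i, const char* part) {
  char buf[64];
  std::snprintf(buf, sizeof(buf), "ds%d.%s", i + 1, part);
  return std::string(buf);
}

static NetP parse_params(const List& p, const Cfg& c) {
  NetP n;
  n.stem_w = getp(p, "stem.w");
  n.stem_b = as_view(getp(p, "stem.b"));
  n.stem_lng = as_view(getp(p, "stem.ln.g"));
  n.stem_lnb = as_view(getp(p, "stem.ln.b"));
  n.blk.resize(4);
  for (int s = 0; s < 4; ++s) {
    int C = c.widths(s);
    for (int k = 0; k < c.depths(s); ++k) {
      BlockP bp;
      NumericVector dww = getp(p, bname(s, k, "dw.w"));
      bp.dww = cube(dww.begin(), c.dwk, c.dwk, C, false);
      bp.dwb = as_view(getp(p, bname(s, k, "dw.b")));
      bp.lng = as_view(getp(p, bname(s, k, "ln.g")));
      bp.lnb = as_view(getp(p, bname(s, k, "ln.b")));
      NumericVector w1 = getp(p, bname(s, k, "pw1.w"));
      bp.w1 = mat(w1.begin(), C, c.expand * C, false);
      bp.b1 = as_view(getp(p, bname(s, k, "pw1.b")));
      NumericVector w2 = getp(p, bname(s, k, "pw2.w"));
      bp.w2 = mat(w2.begin(), c.expand * C, C, false);
      bp.b2 = as_view(getp(p, bname(s, k, "pw2.b")));
      n.blk[s].push_back(bp);
    }
  }
  for (int i = 0; i < 3; ++i) {
    n.ds_lng[i] = as_view(getp(p, dname(i, "ln.g")));
    n.ds_lnb[i] = as_view(getp(p, dname(i, "ln.b")));
    n.ds_w[i] = getp(p, dname(i, "w"));
    n.ds_b[i] = as_view(getp(p, dname(i, "b")));
  }
  n.head_lng = as_view(getp(p, "head.ln.g"));
  n.head_lnb = as_view(getp(p, "head.ln.b"));
  NumericVector hw = getp(p, "head.w");
  n.head_w = mat(hw.begin(), c.widths(3), c.K, false);
  n.head_b = as_view(getp(p, "head.b"));
  return n;
}

// Gradient buffers, flat per parameter name (same layout as params).
struct NetG {
  std::vector<std::string> names;
  std::vector<vec> bufs;
  std::map<std::string, int> idx;

  void add(const std::string& name, size_t n) {
    idx[name] = names.size();
    names.push_back(name);
    bufs.push_back(vec(n, arma::fill::zeros));
  }
  vec& operator[](const std::string& name) { return bufs[idx.at(name)]; }

  List to_list(const List& params) {
    List out(names.size());
    CharacterVector nm(names.size());
    for (size_t i = 0; i < names.size(); ++i) {
      NumericVector v(bufs[i].begin(), bufs[i].end());
      NumericVector ref = getp(params, names[i]);
      if (!Rf_isNull(ref.attr("dim"))) v.attr("dim") = ref.attr("dim");
      out[i] = v;
      nm[i] = names[i];
    }
    out.attr("names") = nm;
    return out;
  }
};

static NetG make_grads(const Cfg& c) {
  NetG g;
  g.add("stem.w", (size_t)c.patch * c.patch * c.widths(0));
  g.add("stem.b", c.widths(0));
  g.add("stem.ln.g", c.widths(0));
  g.add("stem.ln.b", c.widths(0));
  for (int s = 0; s < 4; ++s) {
    int C = c.widths(s);
    for (int k = 0; k < c.depths(s); ++k) {
      g.add(bname(s, k, "dw.w"), (size_t)c.dwk * c.dwk * C);
      g.add(bname(s, k, "dw.b"), C);
      g.add(bname(s, k, "ln.g"), C);
      g.add(bname(s, k, "ln.b"), C);
      g.add(bname(s, k, "pw1.w"), (size_t)C * c.expand * C);
      g.add(bname(s, k, "pw1.b"), c.expand * C);
      g.add(bname(s, k, "pw2.w"), (size_t)c.expand * C * C);
      g.add(bname(s, k, "pw2.b"), C);
    }
  }
  for (int i = 0; i < 3; ++i) {
    g.add(dname(i, "ln.g"), c.widths(i));
    g.add(dname(i, "ln.b"), c.widths(i));
    g.add(dname(i, "w"), (size_t)4 * c.widths(i) * c.widths(i + 1));
    g.add(dname(i, "b"), c.widths(i + 1));
  }
  g.add("head.ln.g", c.widths(3));
  g.add("head.ln.b", c.widths(3));
  g.add("head.w", (size_t)c.widths(3) * c.K);
  g.add("head.b", c.K);
  return g;
}

// ------------------------------------------------------------ net forward --

struct BlockC {
  cube xin, y1;
  mat xhat; vec sd;
  mat m1grad, m1act;
};
struct NetC {
  cube stem_conv;           // conv output, LN input
  mat stem_xhat; vec stem_sd;
  std::vector<std::vector<BlockC> > bc;
  cube ds_in[3], ds_ln[3];
  mat ds_xhat[3]; vec ds_sd[3];
  cube s4out;
  rowvec gap;
  mat head_xhat; vec head_sd;
  vec head_ln_out;
  vec logits;
};

static mat cube_as_mat(const cube& x) {
  return mat(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols, x.n_slices,
             false);
}

static cube block_fwd(const cube& x, const BlockP& p, double eps,
                      bool tanh_mode, BlockC* cc) {
  cube y1;
  dwconv_fwd(x, p.dww, p.dwb, y1);
  mat Y1 = cube_as_mat(y1);
  mat L, xhat; vec sd;
  ln_fwd(Y1, p.lng, p.lnb, eps, L, xhat, sd);
  mat m1pre = L * p.w1;
  m1pre.each_row() += p.b1.t();
  mat m1act, m1grad;
  if (cc) {
    gelu_fwd_grad_mat(m1pre, tanh_mode, m1act, m1grad);
  } else {
    m1act = gelu_fwd_mat(m1pre, tanh_mode);
  }
  mat m2 = m1act * p.w2;
  m2.each_row() += p.b2.t();
  cube out = x;
  mat O = cube_as_mat(out);
  O += m2;
  if (cc) {
    cc->xin = x; cc->y1 = y1; cc->xhat = xhat; cc->sd = sd;
    cc->m1grad = m1grad; cc->m1act = m1act;
  }
  return out;
}

static cube block_bwd(const cube& gout, const BlockP& p, const BlockC& c,
                      double eps, bool tanh_mode, NetG& g, int s, int k) {
  int C = c.xin.n_slices;
  int E = p.w1.n_cols / C;
  mat Gm2 = cube_as_mat(gout);
  // pw2
  mat L = c.xhat.each_row() % p.lng.t();
  L.each_row() += p.lnb.t();
  vec& gw2 = g[bname(s, k, "pw2.w")];
  mat GW2(gw2.memptr(), E * C, C, false);
  GW2 += c.m1act.t() * Gm2;
  g[bname(s, k, "pw2.b")] += arma::sum(Gm2, 0).t();
  mat Gm1act = Gm2 * p.w2.t();
  mat Gm1pre = Gm1act % c.m1grad;
  vec& gw1 = g[bname(s, k, "pw1.w")];
  mat GW1(gw1.memptr(), C, E * C, false);
  GW1 += L.t() * Gm1pre;
  g[bname(s, k, "pw1.b")] += arma::sum(Gm1pre, 0).t();
  mat GL = Gm1pre * p.w1.t();
  mat GY1;
  ln_bwd(GL, c.xhat, c.sd, eps, p.lng, GY1,
         g[bname(s, k, "ln.g")], g[bname(s, k, "ln.b")]);
  cube gy1(GY1.memptr(), c.xin.n_rows, c.xin.n_cols, C, false);
  cube gxb;
  vec& gdww = g[bname(s, k, "dw.w")];
  cube GDW(gdww.memptr(), p.dww.n_rows, p.dww.n_cols, C, false);
  dwconv_bwd(c.xin, p.dww, gy1, gxb, GDW, g[bname(s, k, "dw.b")]);
  gxb += gout; // residual path
  return gxb;
}

// Full forward for one sample (H x W x 1). Fills cache when cc != NULL.
static vec net_fwd(const cube& x, const NetP& p, const Cfg& c, NetC* cc) {
  cube a;
  conv2d_fwd(x, p.stem_w.begin(), p.stem_b, c.patch, c.patch_stride,
             c.widths(0), a);
  mat A = cube_as_mat(a);
  mat ln_out, xhat; vec sd;
  ln_fwd(A, p.stem_lng, p.stem_lnb, c.eps, ln_out, xhat, sd);
  cube cur(a.n_rows, a.n_cols, a.n_slices);
  cube_as_mat(cur) = ln_out;
  if (cc) { cc->stem_conv = a; cc->stem_xhat = xhat; cc->stem_sd = sd;
            cc->bc.resize(4); }
  for (int s = 0; s < 4; ++s) {
    for (int k = 0; k < c.depths(s); ++k) {
      if (cc) {
        BlockC bc;
        cur = block_fwd(cur, p.blk[s][k], c.eps, c.tanh_mode, &bc);
        cc->bc[s].push_back(bc);
      } else {
        cur = block_fwd(cur, p.blk[s][k], c.eps, c.tanh_mode, NULL);
      }
    }
    if (s < 3) {
      mat X = cube_as_mat(cur);
      mat lo, xh; vec sdv;
      ln_fwd(X, p.ds_lng[s], p.ds_lnb[s], c.eps, lo, xh, sdv);
      cube lncube(cur.n_rows, cur.n_cols, cur.n_slices);
      cube_as_mat(lncube) = lo;
      cube nxt;
      conv2d_fwd(lncube, p.ds_w[s].begin(), p.ds_b[s], 2, 2, c.widths(s + 1),
                 nxt);
      if (cc) { cc->ds_in[s] = cur; cc->ds_xhat[s] = xh; cc->ds_sd[s] = sdv;
                cc->ds_ln[s] = lncube; }
      cur = nxt;
    }
  }
  if (cc) cc->s4out = cur;
  mat S4 = cube_as_mat(cur);
  rowvec gap = arma::mean(S4, 0);
  mat hx(1, gap.n_elem);
  hx.row(0) = gap;
  mat hout, hxhat; vec hsd;
  ln_fwd(hx, p.head_lng, p.head_lnb, c.eps, hout, hxhat, hsd);
  vec hl = hout.row(0).t();
  vec logits = p.head_w.t() * hl + p.head_b;
  if (cc) { cc->gap = gap; cc->head_xhat = hxhat; cc->head_sd = hsd;
            cc->head_ln_out = hl; cc->logits = logits; }
  return logits;
}

// Full backward including stem conv; x is the original input sample.
static void net_bwd_full(const cube& x, const vec& glogits, const NetP& p,
                         const Cfg& c, const NetC& cc, NetG& g) {
  vec& ghw = g["head.w"];
  mat GHW(ghw.memptr(), c.widths(3), c.K, false);
  GHW += cc.head_ln_out * glogits.t();
  g["head.b"] += glogits;
  vec ghl = p.head_w * glogits;
  mat Ghl = ghl.t();
  mat Ggap;
  ln_bwd(Ghl, cc.head_xhat, cc.head_sd, c.eps, p.head_lng, Ggap,
         g["head.ln.g"], g["head.ln.b"]);
  const cube& s4 = cc.s4out;
  size_t HW = s4.n_rows * s4.n_cols;
  cube gcur(s4.n_rows, s4.n_cols, s4.n_slices);
  {
    mat Gc = cube_as_mat(gcur);
    Gc.zeros();
    Gc.each_row() += Ggap.row(0) / (double)HW;
  }
  for (int s = 3; s >= 0; --s) {
    if (s < 3) {
      cube gln;
      vec& gdw = g[dname(s, "w")];
      conv2d_bwd(cc.ds_ln[s], p.ds_w[s].begin(), 2, 2, gcur, gln,
                 gdw.memptr(), g[dname(s, "b")]);
      mat Gln = cube_as_mat(gln);
      mat Gin;
      ln_bwd(Gln, cc.ds_xhat[s], cc.ds_sd[s], c.eps, p.ds_lng[s], Gin,
             g[dname(s, "ln.g")], g[dname(s, "ln.b")]);
      gcur.set_size(cc.ds_in[s].n_rows, cc.ds_in[s].n_cols,
                    cc.ds_in[s].n_slices);
      cube_as_mat(gcur) = Gin;
    }
    for (int k = c.depths(s) - 1; k >= 0; --k) {
      gcur = block_bwd(gcur, p.blk[s][k], cc.bc[s][k], c.eps, c.tanh_mode, g,
                       s, k);
    }
  }
  mat Gln = cube_as_mat(gcur);
  mat Gconv;
  ln_bwd(Gln, cc.stem_xhat, cc.stem_sd, c.eps, p.stem_lng, Gconv,
         g["stem.ln.g"], g["stem.ln.b"]);
  cube gconv(Gconv.memptr(), cc.stem_conv.n_rows, cc.stem_conv.n_cols,
             cc.stem_conv.n_slices, false);
  cube gx_unused;
  vec& gsw = g["stem.w"];
  conv2d_bwd(x, p.stem_w.begin(), c.patch, c.patch_stride, gconv, gx_unused,
             gsw.memptr(), g["stem.b"]);
}

static cube slice_to_cube(const arma::cube& xall, arma::uword b) {
  cube x(xall.n_rows, xall.n_cols, 1);
  x.slice(0) = xall.slice(b);
  return x;
}

// ------------------------------------------------------------- interfaces --

// Logits for a batch of grayscale frames stacked as an (H, W, N) array.
// [[Rcpp::export]]
NumericMatrix cn_logits(const arma::cube& x, List params, List cfg) {
  Cfg c = parse_cfg(cfg);
  NetP p = parse_params(params, c);
  NumericMatrix out(x.n_slices, c.K);
  for (arma::uword b = 0; b < x.n_slices; ++b) {
    cube xb = slice_to_cube(x, b);
    vec lg = net_fwd(xb, p, c, NULL);
    for (int k = 0; k < c.K; ++k) out(b, k) = lg(k);
  }
  return out;
}

// Mean cross-entropy loss and parameter gradients for a minibatch.
// y holds 0-based class indices.
// [[Rcpp::export]]
List cn_loss_grad(const arma::cube& x, IntegerVector y, List params,
                  List cfg) {
  Cfg c = parse_cfg(cfg);
  NetP p = parse_params(params, c);
  NetG g = make_grads(c);
  int B = x.n_slices;
  if (y.size() != B) stop("labels do not match batch size");
  double loss = 0.0;
  NumericMatrix logits_out(B, c.K);
  for (int b = 0; b < B; ++b) {
    cube xb = slice_to_cube(x, b);
    NetC cc;
    vec lg = net_fwd(xb, p, c, &cc);
    vec z = lg - lg.max();
    vec ez = arma::exp(z);
    vec prob = ez / arma::accu(ez);
    int yi = y[b];
    if (yi < 0 || yi >= c.K) stop("label out of range");
    double pi = std::max(prob(yi), 1e-12);
    loss += -std::log(pi);
    vec gl = prob;
    gl(yi) -= 1.0;
    gl /= (double)B;
    net_bwd_full(xb, gl, p, c, cc, g);
    for (int k = 0; k < c.K; ++k) logits_out(b, k) = lg(k);
  }
  loss /= (double)B;
  return List::create(_["loss"] = loss, _["logits"] = logits_out,
                      _["grads"] = g.to_list(params));
}

// Stage-4 activations and d(logit_target)/d(activations) for Grad-CAM.
// x is a single (H, W) frame.
// [[Rcpp::export]]
List cn_stage4_grad(const arma::mat& x, List params, List cfg, int target) {
  Cfg c = parse_cfg(cfg);
  NetP p = parse_params(params, c);
  if (target < 0 || target >= c.K) stop("target class out of range");
  cube xb(x.n_rows, x.n_cols, 1);
  xb.slice(0) = x;
  NetC cc;
  vec lg = net_fwd(xb, p, c, &cc);
  // backward of logit (pre-softmax) wrt stage-4 output, through the head
  NetG g = make_grads(c);
  vec gl(c.K, arma::fill::zeros);
  gl(target) = 1.0;
  vec ghl = p.head_w * gl;
  mat Ghl = ghl.t();
  mat Ggap;
  ln_bwd(Ghl, cc.head_xhat, cc.head_sd, c.eps, p.head_lng, Ggap,
         g["head.ln.g"], g["head.ln.b"]);
  size_t HW = cc.s4out.n_rows * cc.s4out.n_cols;
  cube grad(cc.s4out.n_rows, cc.s4out.n_cols, cc.s4out.n_slices);
  mat Gc = cube_as_mat(grad);
  Gc.zeros();
  Gc.each_row() += Ggap.row(0) / (double)HW;
  return List::create(_["logits"] = NumericVector(lg.begin(), lg.end()),
                      _["activations"] = cc.s4out, _["gradients"] = grad);
}

// Single ConvNeXt block forward (testing hook). x is (H, W, C).
// [[Rcpp::export]]
arma::cube cn_block_forward(const arma::cube& x, const arma::cube& dw_w,
                            const arma::vec& dw_b, const arma::vec& ln_g,
                            const arma::vec& ln_b, const arma::mat& pw1_w,
                            const arma::vec& pw1_b, const arma::mat& pw2_w,
                            const arma::vec& pw2_b, double eps,
                            bool tanh_mode) {
  if ((int)dw_w.n_slices != (int)x.n_slices) stop("channel mismatch");
  BlockP p;
  p.dww = dw_w; p.dwb = dw_b; p.lng = ln_g; p.lnb = ln_b;
  p.w1 = pw1_w; p.b1 = pw1_b; p.w2 = pw2_w; p.b2 = pw2_b;
  return block_fwd(x, p, eps, tanh_mode, NULL);
}

// Valid strided convolution (testing hook). w is (k, k, cin, cout).
// [[Rcpp::export]]
arma::cube cn_conv2d(const arma::cube& x, NumericVector w, const arma::vec& b,
                     int k, int stride, int cout) {
  cube out;
  conv2d_fwd(x, w.begin(), b, k, stride, cout, out);
  return out;
}

// Depthwise same-padded convolution (testing hook). w is (k, k, C).
// [[Rcpp::export]]
arma::cube cn_dwconv2d(const arma::cube& x, const arma::cube& w,
                       const arma::vec& b) {
  if (w.n_slices != x.n_slices) stop("channel mismatch");
  cube out;
  dwconv_fwd(x, w, b, out);
  return out;
}

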