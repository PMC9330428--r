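// Compact 3D U-Net / Res U-Net in single-precision Armadillo.
//
// No deep-learning framework exists in this environment, so the two
// reference backbones are implemented directly: 3x3x3 "same" convolutions
// via vol2col + sgemm, batch normalization (per-cube statistics during
// training, running statistics in eval mode), ReLU, 2x max pooling,
// nearest-neighbor upsampling with skip concatenation, and a combined
// soft-Dice + cross-entropy loss with analytic gradients.  Feature maps are
// stored as (V x C) float matrices with voxel linear index
// v = z + Z*(y + Y*x), matching the package's (z, y, x) array convention.
//
// All randomness (init, shuffling, augmentation) lives on the R side; these
// routines are deterministic.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <string>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;

struct Shp {
  int Z, Y, X;
  long V() const { return (long)Z * Y * X; }
};

static inline long vid(int z, int y, int x, const Shp& s) {
  return (long)z + (long)s.Z * (y + (long)s.Y * x);
}

// "Same"-padded 3x3x3 convolution as 27 shifted GEMMs over a zero-padded
// copy of the volume: on the padded frame a kernel offset is a single
// linear index shift, so each tap is one contiguous-row GEMM instead of
// hundreds of thousands of short strided copies.  Weight layout matches an
// im2col formulation: W row (t*Cin + c) holds tap t (dx-major, then dy,
// then dz) of input channel c.

static inline Shp padded(const Shp& s) { return Shp{s.Z + 2, s.Y + 2, s.X + 2}; }

// copy (V x C) into the center of a zeroed (Vp x C) padded frame
static fmat embed_pad(const fmat& in, const Shp& s) {
  Shp sp = padded(s);
  fmat out(sp.V(), in.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < in.n_cols; ++c) {
    const float* src0 = in.colptr(c);
    float* dst0 = out.colptr(c);
    for (int x = 0; x < s.X; ++x)
      for (int y = 0; y < s.Y; ++y)
        std::memcpy(dst0 + vid(0, y + 1, x + 1, sp) + 1,
                    src0 + vid(0, y, x, s), s.Z * sizeof(float));
  }
  return out;
}

static fmat extract_center(const fmat& inp, const Shp& s) {
  Shp sp = padded(s);
  fmat out(s.V(), inp.n_cols);
  for (arma::uword c = 0; c < inp.n_cols; ++c) {
    const float* src0 = inp.colptr(c);
    float* dst0 = out.colptr(c);
    for (int x = 0; x < s.X; ++x)
      for (int y = 0; y < s.Y; ++y)
        std::memcpy(dst0 + vid(0, y, x, s),
                    src0 + vid(0, y + 1, x + 1, sp) + 1, s.Z * sizeof(float));
  }
  return out;
}

// Implicit-GEMM convolution: on the padded frame each kernel tap is a
// single linear shift, so a tap contributes one strided GEMM.  Work is
// chunked over rows so the shifted input region stays cache-resident
// across all 27 taps — no im2col matrix is ever materialized.

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

static const long CONV_CHUNK = 8192;

// out(q, co) = sum_t sum_c Xp(q + o_t, c) * W(t*C + c, co)
static fmat conv3_forward(const fmat& X, const Shp& s, const fmat& W) {
  const int C = X.n_cols, Cout = W.n_cols;
  Shp sp = padded(s);
  const long Vp = sp.V();
  fmat Xp = embed_pad(X, s);
  fmat outp(Vp, Cout);
  fmat acc(CONV_CHUNK, Cout);
  for (long r0 = 0; r0 < Vp; r0 += CONV_CHUNK) {
    const long r1 = std::min(r0 + CONV_CHUNK, Vp) - 1;
    const long nr = r1 - r0 + 1;
    acc.zeros(nr, Cout);
    int t = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz, ++t) {
          const long o = (long)dz + (long)sp.Z * (dy + (long)sp.Y * dx);
          const long qa = std::max(r0, -o), qb = std::min(r1, Vp - 1 - o);
          if (qa > qb) continue;
          sgemm('N', 'N', (int)(qb - qa + 1), Cout, C, 1.0f,
                Xp.memptr() + qa + o, (int)Vp,
                W.memptr() + (long)t * C, 27 * C,
                1.0f, acc.memptr() + (qa - r0), (int)nr);
        }
    for (int co = 0; co < Cout; ++co)
      std::memcpy(outp.colptr(co) + r0, acc.colptr(co), nr * sizeof(float));
  }
  return extract_center(outp, s);
}

// gradients of conv3_forward: dW (27*Cin x Cout) and dX (V x Cin);
// dX(q) = sum_t dpre(q - o_t) W_t^T is computed in the same chunked sweep
// that accumulates dW, sharing the cached chunk of both operands.
static void conv3_backward(const fmat& Xin, const Shp& s, const fmat& W,
                           const fmat& dpre, fmat& dW, fmat& dX) {
  const int C = Xin.n_cols, Cout = W.n_cols;
  Shp sp = padded(s);
  const long Vp = sp.V();
  fmat Xp = embed_pad(Xin, s);
  fmat dpp = embed_pad(dpre, s);
  dW.zeros(27L * C, Cout);
  fmat dXp(Vp, C);
  fmat acc(CONV_CHUNK, C);
  for (long r0 = 0; r0 < Vp; r0 += CONV_CHUNK) {
    const long r1 = std::min(r0 + CONV_CHUNK, Vp) - 1;
    const long nr = r1 - r0 + 1;
    acc.zeros(nr, C);
    int t = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz, ++t) {
          const long o = (long)dz + (long)sp.Z * (dy + (long)sp.Y * dx);
          // dW_t += Xp.rows(q + o)^T dpp.rows(q) over q in chunk
          long qa = std::max(r0, -o), qb = std::min(r1, Vp - 1 - o);
          if (qa <= qb)
            sgemm('T', 'N', C, Cout, (int)(qb - qa + 1), 1.0f,
                  Xp.memptr() + qa + o, (int)Vp,
                  dpp.memptr() + qa, (int)Vp,
                  1.0f, dW.memptr() + (long)t * C, 27 * C);
          // dXp.rows(q) += dpp.rows(q + o_rev) * W_t'^T with o_rev = -o_t
          // handled by iterating taps: contribution of tap t to dX is
          // dpp(q - o_t) * W_t^T; q - o_t in [0, Vp) bounds the q range.
          qa = std::max(r0, o); qb = std::min(r1, Vp - 1 + o);
          if (qa <= qb)
            sgemm('N', 'T', (int)(qb - qa + 1), C, Cout, 1.0f,
                  dpp.memptr() + qa - o, (int)Vp,
                  W.memptr() + (long)t * C, 27 * C,
                  1.0f, acc.memptr() + (qa - r0), (int)nr);
        }
    for (int c = 0; c < C; ++c)
      std::memcpy(dXp.colptr(c) + r0, acc.colptr(c), nr * sizeof(float));
  }
  dX = extract_center(dXp, s);
}

static inline void relu_(fmat& x) {
  x.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// one conv(3x3x3) + BN (+ optional ReLU) unit
struct Unit {
  fmat W;          // (27*Cin) x Cout
  fvec g, b;       // BN scale/shift
  fvec rm, rv;     // running mean/var (updated in training mode)
  bool relu = true;
  // caches for backward
  fmat Xin, xhat, out;
  fvec invstd;
  // grads
  fmat dW; fvec dg, db;
};

static fmat unit_forward(Unit& u, const fmat& X, const Shp& s,
                         bool training, bool cache) {
  fmat pre = conv3_forward(X, s, u.W);
  frowvec mu, var;
  if (training) {
    mu = arma::mean(pre, 0);
    var = arma::mean(arma::square(pre), 0) - arma::square(mu);
    var.transform([](float v) { return v < 0.0f ? 0.0f : v; });
    u.rm = 0.9f * u.rm + 0.1f * mu.t();
    u.rv = 0.9f * u.rv + 0.1f * var.t();
  } else {
    mu = u.rm.t();
    var = u.rv.t();
  }
  frowvec inv = 1.0f / arma::sqrt(var + 1e-5f);
  pre.each_row() -= mu;
  pre.each_row() %= inv;          // pre is now xhat
  fmat out = pre;
  out.each_row() %= u.g.t();
  out.each_row() += u.b.t();
  if (u.relu) relu_(out);
  if (cache) {
    u.Xin = X;
    u.xhat = std::move(pre);
    u.out = out;
    u.invstd = inv.t();
  }
  return out;
}

static fmat unit_backward(Unit& u, fmat dOut, const Shp& s) {
  if (u.relu) dOut.elem(arma::find(u.out <= 0.0f)).zeros();
  u.dg = arma::sum(dOut % u.xhat, 0).t();
  u.db = arma::sum(dOut, 0).t();
  fmat dxhat = dOut;
  dxhat.each_row() %= u.g.t();
  frowvec m1 = arma::mean(dxhat, 0);
  frowvec m2 = arma::mean(dxhat % u.xhat, 0);
  fmat dpre = dxhat;
  dpre.each_row() -= m1;
  {
    fmat t = u.xhat;
    t.each_row() %= m2;
    dpre -= t;
  }
  dpre.each_row() %= u.invstd.t();
  fmat dX;
  conv3_backward(u.Xin, s, u.W, dpre, u.dW, dX);
  return dX;
}

// conv block: two units; residual variant adds a (projected) shortcut
// before the final ReLU.
struct Block {
  Unit u1, u2;
  bool residual = false;
  bool has_proj = false;
  fmat Wp;                 // Cin x Cout shortcut projection
  fmat Xin, out;           // residual caches
  fmat dWp;
};

static fmat block_forward(Block& bl, const fmat& X, const Shp& s,
                          bool training, bool cache) {
  if (!bl.residual) {
    fmat h = unit_forward(bl.u1, X, s, training, cache);
    return unit_forward(bl.u2, h, s, training, cache);
  }
  fmat h = unit_forward(bl.u1, X, s, training, cache);
  fmat pre2 = unit_forward(bl.u2, h, s, training, cache);  // u2.relu == false
  fmat sum = bl.has_proj ? fmat(pre2 + X * bl.Wp) : fmat(pre2 + X);
  relu_(sum);
  if (cache) { bl.Xin = X; bl.out = sum; }
  return sum;
}

static fmat block_backward(Block& bl, fmat dOut, const Shp& s) {
  if (!bl.residual) {
    fmat dh = unit_backward(bl.u2, std::move(dOut), s);
    return unit_backward(bl.u1, std::move(dh), s);
  }
  dOut.elem(arma::find(bl.out <= 0.0f)).zeros();
  fmat dh = unit_backward(bl.u2, dOut, s);
  fmat dX = unit_backward(bl.u1, std::move(dh), s);
  if (bl.has_proj) {
    bl.dWp = bl.Xin.t() * dOut;
    dX += dOut * bl.Wp.t();
  } else {
    dX += dOut;
  }
  return dX;
}

static fmat pool_forward(const fmat& X, const Shp& si, const Shp& so,
                         arma::umat& argm) {
  const int C = X.n_cols;
  fmat out(so.V(), C);
  argm.set_size(so.V(), C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    float* dst = out.colptr(c);
    arma::uword* am = argm.colptr(c);
    for (int x = 0; x < so.X; ++x)
      for (int y = 0; y < so.Y; ++y)
        for (int z = 0; z < so.Z; ++z) {
          float bv = -std::numeric_limits<float>::infinity();
          long bi = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz) {
                long id = vid(2 * z + dz, 2 * y + dy, 2 * x + dx, si);
                if (src[id] > bv) { bv = src[id]; bi = id; }
              }
          long o = vid(z, y, x, so);
          dst[o] = bv;
          am[o] = (arma::uword)bi;
        }
  }
  return out;
}

static fmat pool_backward(const fmat& dOut, const arma::umat& argm,
                          const Shp& si) {
  const int C = dOut.n_cols;
  fmat dIn(si.V(), C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dIn.colptr(c);
    const float* src = dOut.colptr(c);
    const arma::uword* am = argm.colptr(c);
    const long n = dOut.n_rows;
    for (long o = 0; o < n; ++o) dst[am[o]] += src[o];
  }
  return dIn;
}

static fmat up_forward(const fmat& X, const Shp& si, const Shp& so) {
  const int C = X.n_cols;
  fmat out(so.V(), C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    float* dst = out.colptr(c);
    for (int x = 0; x < so.X; ++x)
      for (int y = 0; y < so.Y; ++y)
        for (int z = 0; z < so.Z; ++z)
          dst[vid(z, y, x, so)] = src[vid(z / 2, y / 2, x / 2, si)];
  }
  return out;
}

static fmat up_backward(const fmat& dOut, const Shp& si, const Shp& so) {
  const int C = dOut.n_cols;
  fmat dIn(si.V(), C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dIn.colptr(c);
    const float* src = dOut.colptr(c);
    for (int x = 0; x < so.X; ++x)
      for (int y = 0; y < so.Y; ++y)
        for (int z = 0; z < so.Z; ++z)
          dst[vid(z / 2, y / 2, x / 2, si)] += src[vid(z, y, x, so)];
  }
  return dIn;
}

// ---------- parameter marshalling ----------

static fmat get_fmat(const List& L, const std::string& nm) {
  NumericMatrix m = as<NumericMatrix>(L[nm]);
  fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static fvec get_fvec(const List& L, const std::string& nm) {
  NumericVector v = as<NumericVector>(L[nm]);
  fvec out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}
static NumericMatrix put_mat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static NumericVector put_vec(const fvec& v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

static void load_unit(Unit& u, const List& params, const List& state,
                      const std::string& pre, bool relu) {
  u.W = get_fmat(params, pre + ".W");
  u.g = get_fvec(params, pre + ".g");
  u.b = get_fvec(params, pre + ".b");
  u.rm = get_fvec(state, pre + ".rm");
  u.rv = get_fvec(state, pre + ".rv");
  u.relu = relu;
}

static void load_block(Block& bl, const List& params, const List& state,
                       const std::string& pre, bool residual) {
  bl.residual = residual;
  load_unit(bl.u1, params, state, pre + ".c1", true);
  load_unit(bl.u2, params, state, pre + ".c2", !residual);
  bl.has_proj = residual && params.containsElementNamed((pre + ".proj.W").c_str());
  if (bl.has_proj) bl.Wp = get_fmat(params, pre + ".proj.W");
}

struct Net {
  int depth, K;
  bool residual;
  std::vector<Block> enc, dec;
  fmat headW; fvec headb;
};

static Net load_net(const List& params, const List& state, const List& cfg) {
  Net net;
  net.depth = as<int>(cfg["depth"]);
  net.K = as<int>(cfg["out_classes"]);
  net.residual = as<bool>(cfg["residual"]);
  net.enc.resize(net.depth);
  net.dec.resize(net.depth - 1);
  for (int i = 0; i < net.depth; ++i)
    load_block(net.enc[i], params, state, "enc" + std::to_string(i), net.residual);
  for (int i = 0; i < net.depth - 1; ++i)
    load_block(net.dec[i], params, state, "dec" + std::to_string(i), net.residual);
  net.headW = get_fmat(params, "head.W");
  net.headb = get_fvec(params, "head.b");
  return net;
}

struct FwdCache {
  std::vector<Shp> shapes;
  std::vector<fmat> skips;       // encoder outputs per level (levels 0..depth-2)
  std::vector<arma::umat> poolarg;
  fmat last;                     // input to the head
};

static fmat net_forward(Net& net, const fmat& x0, const Shp& s0,
                        bool training, bool cache, FwdCache& fc) {
  fc.shapes.resize(net.depth);
  fc.skips.resize(net.depth);
  fc.poolarg.resize(net.depth);
  fc.shapes[0] = s0;
  for (int i = 1; i < net.depth; ++i)
    fc.shapes[i] = Shp{fc.shapes[i - 1].Z / 2, fc.shapes[i - 1].Y / 2,
                       fc.shapes[i - 1].X / 2};
  fmat x = x0;
  for (int i = 0; i < net.depth; ++i) {
    if (i > 0) x = pool_forward(x, fc.shapes[i - 1], fc.shapes[i], fc.poolarg[i]);
    x = block_forward(net.enc[i], x, fc.shapes[i], training, cache);
    if (i < net.depth - 1) fc.skips[i] = x;
  }
  for (int i = net.depth - 2; i >= 0; --i) {
    fmat up = up_forward(x, fc.shapes[i + 1], fc.shapes[i]);
    x = arma::join_rows(up, fc.skips[i]);
    x = block_forward(net.dec[i], x, fc.shapes[i], training, cache);
  }
  if (cache) fc.last = x;
  fmat scores = x * net.headW;
  scores.each_row() += net.headb.t();
  return scores;
}

// ---------- loss ----------

struct LossOut {
  double ce, dice_loss;
  fmat dZ;
};

static LossOut softmax_dice_ce(const fmat& scores, const IntegerVector& target,
                               int K, bool want_grad) {
  const long V = scores.n_rows;
  fmat p = scores;
  fvec mx = arma::max(p, 1);
  p.each_col() -= mx;
  p = arma::exp(p);
  fvec ssum = arma::sum(p, 1);
  p.each_col() /= ssum;

  double ce = 0.0;
  for (long v = 0; v < V; ++v) {
    float pv = p(v, target[v]);
    ce -= std::log(std::max(pv, 1e-12f));
  }
  ce /= (double)V;

  std::vector<double> S(K, 0.0), Psum(K, 0.0), Tsum(K, 0.0);
  for (int c = 0; c < K; ++c) Psum[c] = arma::accu(p.col(c));
  for (long v = 0; v < V; ++v) {
    S[target[v]] += p(v, target[v]);
    Tsum[target[v]] += 1.0;
  }
  double dice_mean = 0.0;
  std::vector<double> num(K), den(K);
  for (int c = 0; c < K; ++c) {
    num[c] = 2.0 * S[c] + 1.0;
    den[c] = Psum[c] + Tsum[c] + 1.0;
    dice_mean += num[c] / den[c];
  }
  dice_mean /= K;

  LossOut out;
  out.ce = ce;
  out.dice_loss = 1.0 - dice_mean;
  if (want_grad) {
    // d(diceloss)/dp_c(v) = -(1/K) * (2*T - num/den) / den
    fmat g(V, K);
    for (int c = 0; c < K; ++c) {
      const double dn = den[c];
      const double base = -(1.0 / K) * (-num[c] / (dn * dn));  // T = 0 part
      const double tpart = -(1.0 / K) * (2.0 / dn - num[c] / (dn * dn));
      g.col(c).fill((float)base);
      // overwrite rows where target == c
      for (long v = 0; v < V; ++v)
        if (target[v] == c) g(v, c) = (float)tpart;
    }
    // chain through softmax: dz = p % (g - rowsum(g % p))
    fvec inner = arma::sum(g % p, 1);
    fmat dz = g;
    dz.each_col() -= inner;
    dz %= p;
    // cross-entropy: (p - T)/V
    dz += p / (float)V;
    for (long v = 0; v < V; ++v) dz(v, target[v]) -= 1.0f / (float)V;
    out.dZ = std::move(dz);
  }
  return out;
}

// ---------- exported entry points ----------

static Shp shape_of(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("cube must be a 3D array");
  return Shp{d[0], d[1], d[2]};
}

static List dump_state(const Net& net) {
  List st;
  for (int i = 0; i < net.depth; ++i) {
    std::string pre = "enc" + std::to_string(i);
    st[pre + ".c1.rm"] = put_vec(net.enc[i].u1.rm);
    st[pre + ".c1.rv"] = put_vec(net.enc[i].u1.rv);
    st[pre + ".c2.rm"] = put_vec(net.enc[i].u2.rm);
    st[pre + ".c2.rv"] = put_vec(net.enc[i].u2.rv);
  }
  for (int i = 0; i < net.depth - 1; ++i) {
    std::string pre = "dec" + std::to_string(i);
    st[pre + ".c1.rm"] = put_vec(net.dec[i].u1.rm);
    st[pre + ".c1.rv"] = put_vec(net.dec[i].u1.rv);
    st[pre + ".c2.rm"] = put_vec(net.dec[i].u2.rm);
    st[pre + ".c2.rv"] = put_vec(net.dec[i].u2.rv);
  }
  return st;
}

// Predict raw class scores (logits) for one cube: returns (V x K) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_net_predict(NumericVector x, List params, List state, List cfg) {
  Shp s = shape_of(x);
  fmat x0(s.V(), 1);
  std::copy(x.begin(), x.end(), x0.begin());
  Net net = load_net(params, state, cfg);
  FwdCache fc;
  fmat scores = net_forward(net, x0, s, false, false, fc);
  return put_mat(scores);
}

// One training forward+backward on a cube.  Returns loss components,
// parameter gradients, and updated BN running statistics.
// [[Rcpp::export]]
List cpp_net_grad(NumericVector x, IntegerVector target, List params,
                  List state, List cfg) {
  Shp s = shape_of(x);
  if ((long)target.size() != s.V()) stop("target length must equal cube voxels");
  fmat x0(s.V(), 1);
  std::copy(x.begin(), x.end(), x0.begin());
  Net net = load_net(params, state, cfg);

  FwdCache fc;
  fmat scores = net_forward(net, x0, s, true, true, fc);
  LossOut lo = softmax_dice_ce(scores, target, net.K, true);

  // ----- backward -----
  fmat dHeadW = fc.last.t() * lo.dZ;
  fvec dHeadb = arma::sum(lo.dZ, 0).t();
  fmat dx = lo.dZ * net.headW.t();

  // decoder levels were applied in order i = depth-2 .. 0; reverse for grad
  std::vector<fmat> dskip(net.depth);
  for (int i = 0; i <= net.depth - 2; ++i) {
    dx = block_backward(net.dec[i], std::move(dx), fc.shapes[i]);
    int cTot = dx.n_cols;
    int cSkip = fc.skips[i].n_cols;
    int cUp = cTot - cSkip;
    dskip[i] = dx.cols(cUp, cTot - 1);
    fmat dUp = dx.cols(0, cUp - 1);
    dx = up_backward(dUp, fc.shapes[i + 1], fc.shapes[i]);
  }
  // dx now holds the gradient at the bottom encoder output; walk encoders up
  for (int i = net.depth - 1; i >= 0; --i) {
    if (i < net.depth - 1) dx += dskip[i];
    dx = block_backward(net.enc[i], std::move(dx), fc.shapes[i]);
    if (i > 0) dx = pool_backward(dx, fc.poolarg[i], fc.shapes[i - 1]);
  }

  List grads;
  auto dump_block = [&](Block& bl, const std::string& pre) {
    grads[pre + ".c1.W"] = put_mat(bl.u1.dW);
    grads[pre + ".c1.g"] = put_vec(bl.u1.dg);
    grads[pre + ".c1.b"] = put_vec(bl.u1.db);
    grads[pre + ".c2.W"] = put_mat(bl.u2.dW);
    grads[pre + ".c2.g"] = put_vec(bl.u2.dg);
    grads[pre + ".c2.b"] = put_vec(bl.u2.db);
    if (bl.has_proj) grads[pre + ".proj.W"] = put_mat(bl.dWp);
  };
  for (int i = 0; i < net.depth; ++i)
    dump_block(net.enc[i], "enc" + std::to_string(i));
  for (int i = 0; i < net.depth - 1; ++i)
    dump_block(net.dec[i], "dec" + std::to_string(i));
  grads["head.W"] = put_mat(dHeadW);
  grads["head.b"] = put_vec(dHeadb);

  return List::create(_["loss"] = lo.ce + lo.dice_loss,
                      _["ce"] = lo.ce,
                      _["dice_loss"] = lo.dice_loss,
                      _["grads"] = grads,
                      _["state"] = dump_state(net));
}

// Loss only (training-mode BN forward, no gradient): used for validation.
// [[Rcpp::export]]
List cpp_net_loss(NumericVector x, IntegerVector target, List params,
                  List state, List cfg) {
  Shp s = shape_of(x);
  fmat x0(s.V(), 1);
  std::copy(x.begin(), x.end(), x0.begin());
  Net net = load_net(params, state, cfg);
  FwdCache fc;
  fmat scores = net_forward(net, x0, s, false, false, fc);
  LossOut lo = softmax_dice_ce(scores, target, net.K, false);
  return List::create(_["loss"] = lo.ce + lo.dice_loss,
                      _["ce"] = lo.ce, _["dice_loss"] = lo.dice_loss);
}
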