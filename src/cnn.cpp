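// CNN14-style convolutional network: forward, loss and analytic gradients.
//
// Layout: activations are per-sample arma::cube (frames x mel-bins x channels),
// batches are std::vector<cube>. Each of the 6 blocks is two (3x3 conv ->
// batch-norm -> ReLU) layers; 2x2 max-pooling follows blocks 1-5; block 6
// feeds global (mean + max) pooling, an FC embedding layer with ReLU, and
// either a 2-unit sigmoid head (supervised) or a projection head whose
// L2-normalized outputs enter the InfoNCE loss (contrastive pre-training).
// Convolution is im2col + GEMM; column matrices are recomputed in the backward
// pass instead of cached to bound memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct NetCfg {
  ivec ch;                    // channels of the 6 conv blocks
  int embed, nout;
  bool proj;
  int ph, po;                 // projection head dims
  double eps, mom;            // batch-norm epsilon / running-stat momentum
  double in_off, in_scale;    // input affine: (x - in_off) / in_scale
  int npool;                  // number of leading blocks followed by 2x2 pool
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  IntegerVector chv = cfg["channels"];
  if (chv.size() != 6) stop("cfg$channels must have 6 entries");
  c.ch.set_size(6);
  for (int i = 0; i < 6; i++) c.ch[i] = chv[i];
  c.embed = as<int>(cfg["embed_dim"]);
  c.nout = as<int>(cfg["n_outputs"]);
  c.proj = as<bool>(cfg["projection_head"]);
  c.ph = as<int>(cfg["proj_hidden"]);
  c.po = as<int>(cfg["proj_out"]);
  c.eps = as<double>(cfg["bn_eps"]);
  c.mom = as<double>(cfg["bn_momentum"]);
  c.in_off = as<double>(cfg["input_offset"]);
  c.in_scale = as<double>(cfg["input_scale"]);
  c.npool = as<int>(cfg["n_pool_blocks"]);
  return c;
}

// transposed im2col for a 3x3 pad-1 convolution: (H*W) x (9*C), column
// r = c*9 + di*3 + dj. The transposed layout keeps every write contiguous and
// lets both GEMMs below run without explicit operand copies.
static mat im2colT(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube Xp(H + 2, W + 2, C, fill::zeros);
  Xp.subcube(1, 1, 0, H, W, C - 1) = X;
  mat colT(H * W, 9 * C);
  for (int c = 0; c < C; c++)
    for (int di = 0; di < 3; di++)
      for (int dj = 0; dj < 3; dj++)
        colT.col(c * 9 + di * 3 + dj) =
          vectorise(Xp.slice(c).submat(di, dj, di + H - 1, dj + W - 1));
  return colT;
}

static cube col2imT(const mat& dcolT, int H, int W, int C) {
  cube dXp(H + 2, W + 2, C, fill::zeros);
  for (int c = 0; c < C; c++)
    for (int di = 0; di < 3; di++)
      for (int dj = 0; dj < 3; dj++)
        dXp.slice(c).submat(di, dj, di + H - 1, dj + W - 1) +=
          reshape(dcolT.col(c * 9 + di * 3 + dj), H, W);
  return dXp.subcube(1, 1, 0, H, W, C - 1);
}

// a cube's (H, W, C) memory is exactly the (H*W) x C matrix with slices as
// columns; alias it so conv output lands in place with no per-slice reshape
static cube conv_fwd(const cube& X, const mat& W, const vec& b) {
  const int H = X.n_rows, Wd = X.n_cols;
  cube Y(H, Wd, W.n_rows);
  mat alias(Y.memptr(), H * Wd, W.n_rows, false, true);
  alias = im2colT(X) * W.t();
  alias.each_row() += b.t();
  return Y;
}

struct ConvLayerCache {
  std::vector<cube> z;        // conv output, pre-BN
  std::vector<cube> a;        // post-ReLU activation
  vec mu, istd;
};

struct PoolCache {
  std::vector<umat> idx;      // per sample: (Hout*Wout) x C argmax linear index
  int Hin, Win;
};

struct FwdCache {
  std::vector<std::vector<cube>> block_in;   // input batch of each block
  std::vector<ConvLayerCache> layers;        // 12 conv layers
  std::vector<PoolCache> pools;
  std::vector<uvec> gmax_idx;                // global-pool argmax per sample
  mat pooled;                                // C_last x B
  mat e_pre, e;                              // embedding pre/post ReLU
  mat logits, probs;                         // supervised head
  mat h_pre, h, q, Z;                        // contrastive head
  vec qnorm;
};

// batch-norm + ReLU over a batch of cubes, channel-wise
static void bn_relu_fwd(std::vector<cube>& z, ConvLayerCache& L,
                        const vec& g, const vec& be, vec& rm, vec& rv,
                        bool training, bool update_running, double eps,
                        double mom) {
  const int B = z.size();
  const int C = z[0].n_slices;
  const double M = (double)B * z[0].n_rows * z[0].n_cols;
  vec mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; c++) {
      double s = 0, s2 = 0;
      for (int i = 0; i < B; i++) {
        s += accu(z[i].slice(c));
        s2 += accu(square(z[i].slice(c)));
      }
      mu[c] = s / M;
      var[c] = s2 / M - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
    }
    if (update_running) {
      rm = (1 - mom) * rm + mom * mu;
      rv = (1 - mom) * rv + mom * var;
    }
  } else {
    mu = rm; var = rv;
  }
  L.mu = mu;
  L.istd = 1.0 / sqrt(var + eps);
  L.z = z;
  L.a.resize(B);
  for (int i = 0; i < B; i++) {
    cube a = z[i];
    for (int c = 0; c < C; c++)
      a.slice(c) = clamp((a.slice(c) - mu[c]) * L.istd[c] * g[c] + be[c],
                         0.0, datum::inf);
    L.a[i] = std::move(a);
  }
}

static std::vector<cube> maxpool_fwd(const std::vector<cube>& x, PoolCache& P) {
  const int B = x.size();
  const int H = x[0].n_rows, W = x[0].n_cols, C = x[0].n_slices;
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small for 2x2 pooling stage");
  P.Hin = H; P.Win = W;
  P.idx.resize(B);
  std::vector<cube> y(B);
  for (int i = 0; i < B; i++) {
    cube out(Ho, Wo, C);
    umat idx(Ho * Wo, C);
    for (int c = 0; c < C; c++) {
      const mat& s = x[i].slice(c);
      for (int jo = 0; jo < Wo; jo++)
        for (int io = 0; io < Ho; io++) {
          int i0 = 2 * io, j0 = 2 * jo;
          double best = s(i0, j0); uword bi = i0, bj = j0;
          if (s(i0 + 1, j0) > best) { best = s(i0 + 1, j0); bi = i0 + 1; }
          if (s(i0, j0 + 1) > best) { best = s(i0, j0 + 1); bi = i0; bj = j0 + 1; }
          if (s(i0 + 1, j0 + 1) > best) { best = s(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
          out(io, jo, c) = best;
          idx(jo * Ho + io, c) = bj * H + bi;
        }
    }
    y[i] = std::move(out);
    P.idx[i] = std::move(idx);
  }
  return y;
}

static mat get_mat(const List& p, const std::string& nm) {
  return as<mat>(p[nm]);
}
static vec get_vec(const List& p, const std::string& nm) {
  return as<vec>(p[nm]);
}

static std::string lname(const char* base, int b, int l, const char* suf) {
  char buf[32];
  snprintf(buf, sizeof(buf), "%s%d_%d_%s", base, b + 1, l + 1, suf);
  return std::string(buf);
}

// full forward pass; running stats (rm/rv) are copied out so the caller can
// merge updates back into the parameter list
static void net_forward(std::vector<cube> input, const List& params,
                        const NetCfg& cfg, bool training, bool update_running,
                        const char* head, FwdCache& F, List& new_running) {
  const int B = input.size();
  F.block_in.resize(6);
  F.layers.resize(12);
  F.pools.resize(cfg.npool);
  std::vector<cube> cur = std::move(input);
  for (int b = 0; b < 6; b++) {
    F.block_in[b] = std::move(cur);
    for (int l = 0; l < 2; l++) {
      const int li = 2 * b + l;
      mat W = get_mat(params, lname("c", b, l, "W"));
      vec bias = get_vec(params, lname("c", b, l, "b"));
      std::vector<cube> z(B);
      const std::vector<cube>& src = (l == 0) ? F.block_in[b] : F.layers[li - 1].a;
      for (int i = 0; i < B; i++) z[i] = conv_fwd(src[i], W, bias);
      vec g = get_vec(params, lname("bn", b, l, "g"));
      vec be = get_vec(params, lname("bn", b, l, "b"));
      vec rm = get_vec(params, lname("bn", b, l, "rm"));
      vec rv = get_vec(params, lname("bn", b, l, "rv"));
      bn_relu_fwd(z, F.layers[li], g, be, rm, rv, training, update_running,
                  cfg.eps, cfg.mom);
      if (training && update_running) {
        new_running[lname("bn", b, l, "rm")] = NumericVector(rm.begin(), rm.end());
        new_running[lname("bn", b, l, "rv")] = NumericVector(rv.begin(), rv.end());
      }
    }
    if (b < cfg.npool)
      cur = maxpool_fwd(F.layers[2 * b + 1].a, F.pools[b]);
  }
  // global pooling: mean + max over the remaining time-frequency extent
  const std::vector<cube>& top = F.layers[11].a;
  const int C = top[0].n_slices;
  F.pooled.set_size(C, B);
  F.gmax_idx.resize(B);
  for (int i = 0; i < B; i++) {
    uvec gi(C);
    for (int c = 0; c < C; c++) {
      const mat& s = top[i].slice(c);
      uword im = s.index_max();
      gi[c] = im;
      F.pooled(c, i) = accu(s) / s.n_elem + s(im);
    }
    F.gmax_idx[i] = gi;
  }
  mat fc1W = get_mat(params, "fc1_W");
  vec fc1b = get_vec(params, "fc1_b");
  F.e_pre = fc1W * F.pooled;
  F.e_pre.each_col() += fc1b;
  F.e = clamp(F.e_pre, 0.0, datum::inf);
  if (std::string(head) != "nce") {
    mat fc2W = get_mat(params, "fc2_W");
    vec fc2b = get_vec(params, "fc2_b");
    F.logits = fc2W * F.e;
    F.logits.each_col() += fc2b;
    F.probs = 1.0 / (1.0 + exp(-F.logits));
  }
  if (std::string(head) != "bce") {
    if (cfg.proj) {
      mat p1W = get_mat(params, "p1_W");
      vec p1b = get_vec(params, "p1_b");
      mat p2W = get_mat(params, "p2_W");
      vec p2b = get_vec(params, "p2_b");
      F.h_pre = p1W * F.e;
      F.h_pre.each_col() += p1b;
      F.h = clamp(F.h_pre, 0.0, datum::inf);
      F.q = p2W * F.h;
      F.q.each_col() += p2b;
    } else {
      F.q = F.e;
    }
    F.qnorm = sqrt(sum(square(F.q), 0)).t() + 1e-12;
    F.Z = F.q.each_row() / F.qnorm.t();
  }
}

// [[Rcpp::export]]
List cnn_forward_cpp(List inputs, List params, List cfg_list,
                     bool training = false) {
  NetCfg cfg = parse_cfg(cfg_list);
  const int B = inputs.size();
  std::vector<cube> input(B);
  for (int i = 0; i < B; i++) {
    mat x = as<mat>(inputs[i]);
    if ((int)x.n_cols != 64) stop("input must have 64 mel bins");
    cube c0(x.n_rows, x.n_cols, 1);
    c0.slice(0) = (x - cfg.in_off) / cfg.in_scale;
    input[i] = std::move(c0);
  }
  FwdCache F;
  List dummy;
  net_forward(input, params, cfg, training, false, "both", F, dummy);
  return List::create(_["embed"] = wrap(trans(F.e)),
                      _["logits"] = wrap(trans(F.logits)),
                      _["probs"] = wrap(trans(F.probs)),
                      _["z"] = wrap(trans(F.Z)));
}

// InfoNCE over columns of Z (L2-normalized, po x 2N, pair-ordered);
// returns loss and fills dZ
static double infonce_loss_grad(const mat& Z, double tau, mat& dZ) {
  const int n2 = Z.n_cols;
  mat S = (Z.t() * Z) / tau;
  S.diag().fill(-datum::inf);
  mat G(n2, n2, fill::zeros);
  double loss = 0;
  for (int i = 0; i < n2; i++) {
    int p = (i % 2 == 0) ? i + 1 : i - 1;
    rowvec si = S.row(i);
    double m = si.max();
    rowvec ex = exp(si - m);
    ex[i] = 0;
    double denom = accu(ex);
    loss += (m + std::log(denom)) - S(i, p);
    rowvec P = ex / denom;
    G.row(i) = P / n2;
    G(i, p) -= 1.0 / n2;
  }
  loss /= n2;
  dZ = Z * (G + G.t()) / tau;
  return loss;
}

// [[Rcpp::export]]
List cnn_lossgrad_cpp(List inputs, List params, List cfg_list,
                      std::string objective,
                      Nullable<NumericMatrix> targets = R_NilValue,
                      double tau = 0.5, bool training = true,
                      bool update_running = true) {
  NetCfg cfg = parse_cfg(cfg_list);
  const int B = inputs.size();
  if (B < 1) stop("empty batch");
  std::vector<cube> input(B);
  for (int i = 0; i < B; i++) {
    mat x = as<mat>(inputs[i]);
    if ((int)x.n_cols != 64) stop("input must have 64 mel bins");
    cube c0(x.n_rows, x.n_cols, 1);
    c0.slice(0) = (x - cfg.in_off) / cfg.in_scale;
    input[i] = std::move(c0);
  }
  FwdCache F;
  List new_running;
  const char* head = (objective == "nce") ? "nce" : "bce";
  net_forward(input, params, cfg, training, update_running, head, F, new_running);

  double loss = 0;
  mat de;                                    // gradient wrt embedding e (E x B)
  List grads;

  if (objective == "bce") {
    if (targets.isNull()) stop("bce objective needs targets");
    mat Y = trans(as<mat>(targets.get()));   // nout x B
    mat P = clamp(F.probs, 1e-12, 1 - 1e-12);
    loss = -accu(Y % log(P) + (1 - Y) % log(1 - P)) / B;
    mat dlogits = (F.probs - Y) / B;
    grads["fc2_W"] = wrap(dlogits * F.e.t());
    grads["fc2_b"] = wrap(sum(dlogits, 1));
    de = get_mat(params, "fc2_W").t() * dlogits;
  } else if (objective == "nce") {
    if (B % 2 != 0) stop("nce objective needs an even batch (crop pairs)");
    mat dZ;
    loss = infonce_loss_grad(F.Z, tau, dZ);
    // back through column-wise L2 normalization
    mat dq(F.q.n_rows, B);
    for (int i = 0; i < B; i++) {
      vec z = F.Z.col(i);
      vec dz = dZ.col(i);
      dq.col(i) = (dz - z * dot(z, dz)) / F.qnorm[i];
    }
    if (cfg.proj) {
      grads["p2_W"] = wrap(dq * F.h.t());
      grads["p2_b"] = wrap(sum(dq, 1));
      mat dh = get_mat(params, "p2_W").t() * dq;
      dh %= conv_to<mat>::from(F.h_pre > 0);
      grads["p1_W"] = wrap(dh * F.e.t());
      grads["p1_b"] = wrap(sum(dh, 1));
      de = get_mat(params, "p1_W").t() * dh;
    } else {
      de = dq;
    }
  } else {
    stop("unknown objective: " + objective);
  }

  de %= conv_to<mat>::from(F.e_pre > 0);
  grads["fc1_W"] = wrap(de * F.pooled.t());
  grads["fc1_b"] = wrap(sum(de, 1));
  mat dpooled = get_mat(params, "fc1_W").t() * de;   // C_last x B

  // global pooling backward
  const int C5 = cfg.ch[5];
  const std::vector<cube>& top = F.layers[11].a;
  std::vector<cube> dcur(B);
  for (int i = 0; i < B; i++) {
    const double ne = top[i].slice(0).n_elem;
    cube d(top[i].n_rows, top[i].n_cols, C5, fill::zeros);
    for (int c = 0; c < C5; c++) {
      d.slice(c).fill(dpooled(c, i) / ne);
      d.slice(c)(F.gmax_idx[i][c]) += dpooled(c, i);
    }
    dcur[i] = std::move(d);
  }

  // blocks in reverse
  for (int b = 5; b >= 0; b--) {
    if (b < cfg.npool) {
      // dcur currently matches the pooled output of block b: un-pool
      const PoolCache& P = F.pools[b];
      std::vector<cube> dup(B);
      for (int i = 0; i < B; i++) {
        const int C = dcur[i].n_slices, Ho = dcur[i].n_rows, Wo = dcur[i].n_cols;
        cube d(P.Hin, P.Win, C, fill::zeros);
        for (int c = 0; c < C; c++) {
          const mat& ds = dcur[i].slice(c);
          for (int jo = 0; jo < Wo; jo++)
            for (int io = 0; io < Ho; io++)
              d.slice(c)(P.idx[i](jo * Ho + io, c)) += ds(io, jo);
        }
        dup[i] = std::move(d);
      }
      dcur = std::move(dup);
    }
    for (int l = 1; l >= 0; l--) {
      const int li = 2 * b + l;
      ConvLayerCache& L = F.layers[li];
      const int C = L.z[0].n_slices;
      const double M = (double)B * L.z[0].n_rows * L.z[0].n_cols;
      vec g = get_vec(params, lname("bn", b, l, "g"));
      // ReLU backward
      for (int i = 0; i < B; i++)
        dcur[i] %= conv_to<cube>::from(L.a[i] > 0);
      // BN backward, temporary-free: dgamma_c = (sum dy*z - mu sum dy) istd
      vec sd(C, fill::zeros), sdz(C, fill::zeros);
      for (int i = 0; i < B; i++)
        for (int c = 0; c < C; c++) {
          sd[c] += accu(dcur[i].slice(c));
          sdz[c] += accu(dcur[i].slice(c) % L.z[i].slice(c));
        }
      vec dgamma = (sdz - L.mu % sd) % L.istd;
      vec dbeta = sd;
      for (int i = 0; i < B; i++)
        for (int c = 0; c < C; c++) {
          const double a1 = g[c] * L.istd[c];
          const double a3 = L.istd[c] * L.istd[c] * g[c] * dgamma[c] / M;
          const double a0 = a1 * sd[c] / M - a3 * L.mu[c];
          dcur[i].slice(c) = a1 * dcur[i].slice(c) - a3 * L.z[i].slice(c) - a0;
        }
      grads[lname("bn", b, l, "g")] = NumericVector(dgamma.begin(), dgamma.end());
      grads[lname("bn", b, l, "b")] = NumericVector(dbeta.begin(), dbeta.end());
      // conv backward; the upstream-gradient cube's memory already is the
      // (H*W) x Cout matrix needed, so both GEMMs use it without copying
      mat W = get_mat(params, lname("c", b, l, "W"));
      mat dW(W.n_rows, W.n_cols, fill::zeros);
      vec db(W.n_rows, fill::zeros);
      const std::vector<cube>& src = (l == 0) ? F.block_in[b] : F.layers[li - 1].a;
      std::vector<cube> dsrc(B);
      for (int i = 0; i < B; i++) {
        const int H = dcur[i].n_rows, Wd = dcur[i].n_cols;
        const mat doutT(dcur[i].memptr(), H * Wd, W.n_rows, false, true);
        mat colT = im2colT(src[i]);
        dW += doutT.t() * colT;
        db += sum(doutT, 0).t();
        dsrc[i] = col2imT(doutT * W, H, Wd, src[i].n_slices);
      }
      grads[lname("c", b, l, "W")] = wrap(dW);
      grads[lname("c", b, l, "b")] = wrap(db);
      dcur = std::move(dsrc);
    }
  }

  List out = List::create(_["loss"] = loss, _["grads"] = grads,
                          _["running"] = new_running);
  if (objective == "bce") out["probs"] = wrap(trans(F.probs));
  return out;
}
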