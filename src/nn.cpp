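// Neural sequence feature descriptor: six parallel 1-D convolution branches
// over one-hot DNA input, two bidirectional GRU stacks of different depth,
// a dot-product attention pool and a dense sigmoid head. Implemented with
// explicit forward/backward passes so that training is single-threaded and
// bit-reproducible from one integer seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct Arch {
  std::vector<int> kernels, filters;
  double dropout;
  int pool_stride, gruA, gruB, attn_dim, dense_units, window;
  bool use_attention, use_gru;
  std::string feature_layer;
  int channels() const {
    int c = 0; for (int f : filters) c += f; return c;
  }
  // width of the per-position representation fed to the pooling stage
  int hdim() const { return use_gru ? 2 * gruA + 2 * gruB : channels(); }
  int feature_dim() const {
    return feature_layer == "penultimate_dense" ? dense_units : hdim();
  }
};

Arch parse_arch(const List& a) {
  Arch ar;
  IntegerVector ks = a["kernels"], fs = a["filters"];
  ar.kernels = std::vector<int>(ks.begin(), ks.end());
  ar.filters = std::vector<int>(fs.begin(), fs.end());
  ar.dropout = as<double>(a["dropout"]);
  ar.pool_stride = as<int>(a["pool_stride"]);
  ar.gruA = as<int>(a["gru_units_a"]);
  ar.gruB = as<int>(a["gru_units_b"]);
  ar.attn_dim = as<int>(a["attention_dim"]);
  ar.dense_units = as<int>(a["dense_units"]);
  ar.window = as<int>(a["window_length"]);
  ar.use_attention = as<bool>(a["use_attention"]);
  ar.use_gru = as<bool>(a["use_gru"]);
  ar.feature_layer = as<std::string>(a["feature_layer"]);
  return ar;
}

struct RNG {
  std::mt19937_64 eng;
  explicit RNG(uint64_t seed) : eng(seed) {}
  double unif() {
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  double gauss() {  // Box-Muller, self-contained for reproducibility
    double u1 = std::max(unif(), 1e-300), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int integer(int n) { return (int)(eng() % (uint64_t)n); }
};

struct Net {
  Arch ar;
  std::vector<std::string> names;
  std::vector<mat> W;
  std::map<std::string, int> idx;

  void add(const std::string& nm, int r, int c) {
    names.push_back(nm);
    idx[nm] = (int)W.size();
    W.push_back(mat(r, c, arma::fill::zeros));
  }
  mat& get(const std::string& nm) { return W[idx.at(nm)]; }

  void build() {
    for (size_t i = 0; i < ar.kernels.size(); ++i) {
      add("conv_W_" + std::to_string(i), ar.filters[i], 4 * ar.kernels[i]);
      add("conv_b_" + std::to_string(i), ar.filters[i], 1);
    }
    int C = ar.channels();
    if (ar.use_gru) {
      struct G { std::string nm; int h, in; };
      std::vector<G> units = {
        {"gruA_l1", ar.gruA, C}, {"gruB_l1", ar.gruB, C},
        {"gruB_l2", ar.gruB, 2 * ar.gruB}};
      for (auto& u : units)
        for (std::string d : {"f", "b"}) {
          add("gru_" + u.nm + "_" + d + "_W", 3 * u.h, u.in);
          add("gru_" + u.nm + "_" + d + "_U", 3 * u.h, u.h);
          add("gru_" + u.nm + "_" + d + "_b", 3 * u.h, 1);
        }
    }
    int H = ar.hdim();
    if (ar.use_attention) {
      add("attn_Wk", ar.attn_dim, H);
      add("attn_bk", ar.attn_dim, 1);
      add("attn_q", ar.attn_dim, 1);
    }
    add("dense_W", ar.dense_units, H);
    add("dense_b", ar.dense_units, 1);
    add("out_W", ar.dense_units, 1);
    add("out_b", 1, 1);
  }

  void init(RNG& rng) {
    for (size_t i = 0; i < W.size(); ++i) {
      bool bias = W[i].n_cols == 1 && names[i] != "attn_q" &&
                  names[i] != "out_W";
      if (bias) continue;  // biases stay zero
      double fan = std::sqrt(2.0 / (W[i].n_rows + W[i].n_cols));
      for (arma::uword j = 0; j < W[i].n_elem; ++j)
        W[i](j) = fan * rng.gauss();
    }
  }
};

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// per-sequence forward cache
struct Cache {
  std::vector<mat> convZ, convMask;      // per branch: F x L (pre-relu), mask
  mat pooled_in;                         // C x T
  struct GruDir { mat z, r, n, h, x; };  // each h x T (x: in x T)
  std::map<std::string, GruDir> gru;
  mat H;                                 // hdim x T
  vec alpha, scores, pooled, u_pre_tanh_unused;
  mat U;                                 // attn_dim x T (tanh outputs)
  vec dvec_pre, dvec;                    // dense pre-relu / post-dropout
  vec dense_mask;
  double out = 0.0;
};

// one GRU direction over input X (in x T); reverse = run right-to-left.
// The input projection W*X + b is one GEMM for the whole sequence; only the
// recurrent terms run step by step.
void gru_forward(const mat& Wm, const mat& Um, const vec& b, const mat& X,
                 bool reverse, Cache::GruDir& cd) {
  int h = Wm.n_rows / 3, T = X.n_cols;
  cd.z.set_size(h, T); cd.r.set_size(h, T); cd.n.set_size(h, T);
  cd.h.set_size(h, T); cd.x = X;
  mat G = Wm * X;
  G.each_col() += b;
  vec hp(h, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    vec uh = Um.rows(0, 2 * h - 1) * hp;
    vec z = sigmoid(G.submat(0, t, h - 1, t) + uh.rows(0, h - 1));
    vec r = sigmoid(G.submat(h, t, 2 * h - 1, t) + uh.rows(h, 2 * h - 1));
    vec n = arma::tanh(G.submat(2 * h, t, 3 * h - 1, t) +
                       Um.rows(2 * h, 3 * h - 1) * (r % hp));
    vec hn = (1.0 - z) % n + z % hp;
    cd.z.col(t) = z; cd.r.col(t) = r; cd.n.col(t) = n; cd.h.col(t) = hn;
    hp = hn;
  }
}

// backward through one GRU direction; dH: grad wrt outputs (h x T).
// Accumulates dW/dU/db, returns grad wrt inputs (in x T).
mat gru_backward(const mat& Wm, const mat& Um, const Cache::GruDir& cd,
                 const mat& dH, bool reverse,
                 mat& dW, mat& dU, mat& db) {
  int h = Wm.n_rows / 3, T = cd.h.n_cols;
  vec carry(h, arma::fill::zeros);
  mat Uz = Um.rows(0, h - 1), Ur = Um.rows(h, 2 * h - 1),
      Un = Um.rows(2 * h, 3 * h - 1);
  mat Gstack(3 * h, T);        // per-step pre-activation grads
  mat HP(h, T), RHP(h, T);     // h_{t-1} and r_t % h_{t-1} per step
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? T - 1 - s : s;
    int tp = reverse ? t + 1 : t - 1;
    vec hp = (s > 0) ? vec(cd.h.col(tp)) : vec(h, arma::fill::zeros);
    vec z = cd.z.col(t), r = cd.r.col(t), n = cd.n.col(t);
    vec dh = dH.col(t) + carry;
    vec dz = dh % (hp - n);
    vec dn = dh % (1.0 - z);
    vec dhp = dh % z;
    vec dn_pre = dn % (1.0 - n % n);
    vec un_t_dn = Un.t() * dn_pre;
    vec dr = un_t_dn % hp;
    dhp += un_t_dn % r;
    vec dz_pre = dz % z % (1.0 - z);
    vec dr_pre = dr % r % (1.0 - r);
    Gstack.submat(0, t, h - 1, t) = dz_pre;
    Gstack.submat(h, t, 2 * h - 1, t) = dr_pre;
    Gstack.submat(2 * h, t, 3 * h - 1, t) = dn_pre;
    HP.col(t) = hp;
    RHP.col(t) = r % hp;
    dhp += Uz.t() * dz_pre + Ur.t() * dr_pre;
    carry = dhp;
  }
  dW += Gstack * cd.x.t();
  dU.rows(0, h - 1) += Gstack.rows(0, h - 1) * HP.t();
  dU.rows(h, 2 * h - 1) += Gstack.rows(h, 2 * h - 1) * HP.t();
  dU.rows(2 * h, 3 * h - 1) += Gstack.rows(2 * h, 3 * h - 1) * RHP.t();
  db += arma::sum(Gstack, 1);
  return Wm.t() * Gstack;
}

void bigru_forward(Net& net, const std::string& unit, const mat& X,
                   Cache& c, mat& out) {
  const mat& Wf = net.get("gru_" + unit + "_f_W");
  const mat& Uf = net.get("gru_" + unit + "_f_U");
  const mat& Wb = net.get("gru_" + unit + "_b_W");
  const mat& Ub = net.get("gru_" + unit + "_b_U");
  Cache::GruDir &cf = c.gru[unit + "_f"], &cb = c.gru[unit + "_b"];
  gru_forward(Wf, Uf, net.get("gru_" + unit + "_f_b").col(0), X, false, cf);
  gru_forward(Wb, Ub, net.get("gru_" + unit + "_b_b").col(0), X, true, cb);
  out = arma::join_cols(cf.h, cb.h);
}

mat bigru_backward(Net& net, const std::string& unit, Cache& c,
                   const mat& dOut, std::vector<mat>& G) {
  int h = c.gru[unit + "_f"].h.n_rows;
  mat dXf = gru_backward(net.get("gru_" + unit + "_f_W"),
                         net.get("gru_" + unit + "_f_U"),
                         c.gru[unit + "_f"], dOut.rows(0, h - 1), false,
                         G[net.idx["gru_" + unit + "_f_W"]],
                         G[net.idx["gru_" + unit + "_f_U"]],
                         G[net.idx["gru_" + unit + "_f_b"]]);
  mat dXb = gru_backward(net.get("gru_" + unit + "_b_W"),
                         net.get("gru_" + unit + "_b_U"),
                         c.gru[unit + "_b"], dOut.rows(h, 2 * h - 1), true,
                         G[net.idx["gru_" + unit + "_b_W"]],
                         G[net.idx["gru_" + unit + "_b_U"]],
                         G[net.idx["gru_" + unit + "_b_b"]]);
  return dXf + dXb;
}

// forward one sequence; codes are 0..3, length = window
double forward_seq(Net& net, const arma::ivec& codes, bool training,
                   RNG* rng, Cache& c) {
  const Arch& ar = net.ar;
  int L = codes.n_elem;
  int nb = ar.kernels.size();
  int C = ar.channels();
  mat A(C, L);
  c.convZ.resize(nb); c.convMask.resize(nb);
  int row0 = 0;
  double keep = 1.0 - ar.dropout;
  for (int b = 0; b < nb; ++b) {
    int k = ar.kernels[b], F = ar.filters[b], pad = (k - 1) / 2;
    const mat& Wc = net.get("conv_W_" + std::to_string(b));
    vec bc = net.get("conv_b_" + std::to_string(b)).col(0);
    mat Z(F, L);
    Z.each_col() = bc;
    for (int j = 0; j < k; ++j) {
      int t0 = std::max(0, pad - j), t1 = std::min(L - 1, L - 1 + pad - j);
      if (t0 > t1) continue;
      arma::uvec idx(t1 - t0 + 1);
      for (int t = t0; t <= t1; ++t)
        idx[t - t0] = (arma::uword)(j * 4 + codes[t + j - pad]);
      Z.cols(t0, t1) += Wc.cols(idx);
    }
    c.convZ[b] = Z;
    mat Ab = arma::clamp(Z, 0.0, arma::datum::inf);
    if (training && ar.dropout > 0) {
      mat m(F, L);
      for (arma::uword i = 0; i < m.n_elem; ++i)
        m(i) = (rng->unif() < keep) ? 1.0 / keep : 0.0;
      c.convMask[b] = m;
      Ab %= m;
    } else c.convMask[b] = mat();
    A.rows(row0, row0 + F - 1) = Ab;
    row0 += F;
  }
  int s = ar.pool_stride, T = L / s;
  mat P(C, T);
  for (int t = 0; t < T; ++t)
    P.col(t) = arma::mean(A.cols(t * s, t * s + s - 1), 1);
  c.pooled_in = P;

  if (ar.use_gru) {
    mat OA, OB1, OB2;
    bigru_forward(net, "gruA_l1", P, c, OA);
    bigru_forward(net, "gruB_l1", P, c, OB1);
    bigru_forward(net, "gruB_l2", OB1, c, OB2);
    c.H = arma::join_cols(OA, OB2);
  } else c.H = P;

  if (ar.use_attention) {
    const mat& Wk = net.get("attn_Wk");
    vec bk = net.get("attn_bk").col(0), q = net.get("attn_q").col(0);
    c.U = arma::tanh(Wk * c.H + arma::repmat(bk, 1, T));
    c.scores = c.U.t() * q;
    vec e = arma::exp(c.scores - c.scores.max());
    c.alpha = e / arma::accu(e);
  } else c.alpha = vec(T, arma::fill::value(1.0 / T));
  c.pooled = c.H * c.alpha;

  c.dvec_pre = net.get("dense_W") * c.pooled + net.get("dense_b").col(0);
  vec dv = arma::clamp(c.dvec_pre, 0.0, arma::datum::inf);
  if (training && ar.dropout > 0) {
    c.dense_mask.set_size(dv.n_elem);
    for (arma::uword i = 0; i < dv.n_elem; ++i)
      c.dense_mask(i) = (rng->unif() < keep) ? 1.0 / keep : 0.0;
    dv %= c.dense_mask;
  } else c.dense_mask.reset();
  c.dvec = dv;
  double z = arma::dot(net.get("out_W").col(0), dv) + net.get("out_b")(0, 0);
  c.out = 1.0 / (1.0 + std::exp(-z));
  return c.out;
}

// backward for one sequence given dL/dz (z = pre-sigmoid logit)
void backward_seq(Net& net, const arma::ivec& codes, Cache& c,
                  double dlogit, std::vector<mat>& G) {
  const Arch& ar = net.ar;
  int L = codes.n_elem, s = ar.pool_stride, T = L / s;
  G[net.idx["out_W"]] += dlogit * c.dvec;
  G[net.idx["out_b"]](0, 0) += dlogit;
  vec ddv = dlogit * net.get("out_W").col(0);
  if (c.dense_mask.n_elem) ddv %= c.dense_mask;
  ddv %= arma::conv_to<vec>::from(c.dvec_pre > 0);
  G[net.idx["dense_W"]] += ddv * c.pooled.t();
  G[net.idx["dense_b"]] += ddv;
  vec dpooled = net.get("dense_W").t() * ddv;

  // pooling stage
  mat dH = dpooled * c.alpha.t();
  if (ar.use_attention) {
    vec dalpha = c.H.t() * dpooled;
    vec dscore = c.alpha % (dalpha - arma::dot(c.alpha, dalpha));
    vec q = net.get("attn_q").col(0);
    G[net.idx["attn_q"]] += c.U * dscore;
    mat dpre = (q * dscore.t()) % (1.0 - c.U % c.U);  // attn_dim x T
    G[net.idx["attn_Wk"]] += dpre * c.H.t();
    G[net.idx["attn_bk"]] += arma::sum(dpre, 1);
    dH += net.get("attn_Wk").t() * dpre;
  }

  mat dP;
  if (ar.use_gru) {
    int hA2 = 2 * ar.gruA;
    mat dOA = dH.rows(0, hA2 - 1);
    mat dOB2 = dH.rows(hA2, dH.n_rows - 1);
    dP = bigru_backward(net, "gruA_l1", c, dOA, G);
    mat dOB1 = bigru_backward(net, "gruB_l2", c, dOB2, G);
    dP += bigru_backward(net, "gruB_l1", c, dOB1, G);
  } else dP = dH;

  // pool backward -> conv concat grads
  int C = ar.channels();
  mat dA(C, L, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < s; ++j) dA.col(t * s + j) = dP.col(t) / s;

  int row0 = 0;
  for (size_t b = 0; b < ar.kernels.size(); ++b) {
    int k = ar.kernels[b], F = ar.filters[b], pad = (k - 1) / 2;
    mat dZ = dA.rows(row0, row0 + F - 1);
    if (c.convMask[b].n_elem) dZ %= c.convMask[b];
    dZ %= arma::conv_to<mat>::from(c.convZ[b] > 0);
    mat& dWc = G[net.idx["conv_W_" + std::to_string(b)]];
    G[net.idx["conv_b_" + std::to_string(b)]] += arma::sum(dZ, 1);
    for (int j = 0; j < k; ++j) {
      int t0 = std::max(0, pad - j), t1 = std::min(L - 1, L - 1 + pad - j);
      for (int base = 0; base < 4; ++base) {
        std::vector<arma::uword> ts;
        for (int t = t0; t <= t1; ++t)
          if (codes[t + j - pad] == base) ts.push_back((arma::uword)t);
        if (!ts.empty())
          dWc.col(j * 4 + base) += arma::sum(dZ.cols(arma::uvec(ts)), 1);
      }
    }
    row0 += F;
  }
}

Net net_from_r(const List& arch, const List& weights) {
  Net net;
  net.ar = parse_arch(arch);
  net.build();
  for (size_t i = 0; i < net.names.size(); ++i) {
    NumericMatrix m = weights[net.names[i]];
    mat a(m.begin(), m.nrow(), m.ncol());
    if (a.n_rows != net.W[i].n_rows || a.n_cols != net.W[i].n_cols)
      stop("weight '%s' has wrong shape", net.names[i].c_str());
    net.W[i] = a;
  }
  return net;
}

List net_to_r(const Net& net) {
  List out(net.W.size());
  CharacterVector nm(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    out[i] = wrap(net.W[i]);
    nm[i] = net.names[i];
  }
  out.attr("names") = nm;
  return out;
}

arma::ivec row_codes(const IntegerMatrix& codes, int i) {
  arma::ivec v(codes.ncol());
  for (int j = 0; j < codes.ncol(); ++j) v[j] = codes(i, j) - 1;
  return v;
}

double bce(double p, int y) {
  p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
  return -(y * std::log(p) + (1 - y) * std::log(1.0 - p));
}

}  // namespace

// [[Rcpp::export]]
List nn_init_cpp(List arch, int seed) {
  Net net;
  net.ar = parse_arch(arch);
  net.build();
  RNG rng((uint64_t)seed);
  net.init(rng);
  return net_to_r(net);
}

// [[Rcpp::export]]
List nn_forward_cpp(List arch, List weights, IntegerMatrix codes,
                    std::string feature_layer) {
  Net net = net_from_r(arch, weights);
  int n = codes.nrow();
  int fd = feature_layer == "penultimate_dense" ? net.ar.dense_units
                                                : net.ar.hdim();
  NumericVector prob(n);
  NumericMatrix feat(n, fd);
  Cache c;
  for (int i = 0; i < n; ++i) {
    arma::ivec cv = row_codes(codes, i);
    prob[i] = forward_seq(net, cv, false, nullptr, c);
    vec f = feature_layer == "penultimate_dense" ? c.dvec : c.pooled;
    for (int j = 0; j < fd; ++j) feat(i, j) = f[j];
  }
  return List::create(_["prob"] = prob, _["features"] = feat);
}

// [[Rcpp::export]]
List nn_loss_grad_cpp(List arch, List weights, IntegerMatrix codes,
                      IntegerVector y) {
  Net net = net_from_r(arch, weights);
  int n = codes.nrow();
  std::vector<mat> G(net.W.size());
  for (size_t i = 0; i < G.size(); ++i)
    G[i] = mat(net.W[i].n_rows, net.W[i].n_cols, arma::fill::zeros);
  double loss = 0;
  Cache c;
  for (int i = 0; i < n; ++i) {
    arma::ivec cv = row_codes(codes, i);
    double p = forward_seq(net, cv, false, nullptr, c);
    loss += bce(p, y[i]) / n;
    backward_seq(net, cv, c, (p - y[i]) / n, G);
  }
  List gl(G.size());
  CharacterVector nm(G.size());
  for (size_t i = 0; i < G.size(); ++i) {
    gl[i] = wrap(G[i]);
    nm[i] = net.names[i];
  }
  gl.attr("names") = nm;
  return List::create(_["loss"] = loss, _["grads"] = gl);
}

// [[Rcpp::export]]
List nn_train_cpp(List arch, List weights, IntegerMatrix codes,
                  IntegerVector y, List cfg) {
  Net net = net_from_r(arch, weights);
  int n = codes.nrow();
  int epochs = as<int>(cfg["epochs"]);
  int batch = as<int>(cfg["batch_size"]);
  double lr = as<double>(cfg["learning_rate"]);
  double vfrac = as<double>(cfg["validation_fraction"]);
  int patience = as<int>(cfg["early_stop_patience"]);
  RNG rng((uint64_t)as<int>(cfg["seed"]));

  // stratified validation split
  std::vector<int> pos, neg;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? pos : neg).push_back(i);
  auto shuffle_vec = [&](std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i)
      std::swap(v[i], v[rng.integer(i + 1)]);
  };
  shuffle_vec(pos); shuffle_vec(neg);
  std::vector<int> val, train;
  int nvp = std::max(1, (int)std::floor(vfrac * pos.size()));
  int nvn = std::max(1, (int)std::floor(vfrac * neg.size()));
  for (size_t i = 0; i < pos.size(); ++i)
    ((int)i < nvp ? val : train).push_back(pos[i]);
  for (size_t i = 0; i < neg.size(); ++i)
    ((int)i < nvn ? val : train).push_back(neg[i]);

  // Adam state
  std::vector<mat> G(net.W.size()), M(net.W.size()), V(net.W.size());
  for (size_t i = 0; i < G.size(); ++i) {
    M[i] = mat(net.W[i].n_rows, net.W[i].n_cols, arma::fill::zeros);
    V[i] = M[i];
    G[i] = M[i];
  }
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<double> hist_train, hist_val;
  std::vector<mat> best_W = net.W;
  double best_val = arma::datum::inf;
  int best_epoch = 0, since_best = 0;
  Cache c;

  for (int ep = 1; ep <= epochs; ++ep) {
    shuffle_vec(train);
    double tr_loss = 0;
    int nb = 0;
    for (size_t start = 0; start < train.size(); start += batch) {
      size_t end = std::min(train.size(), start + batch);
      int bs = (int)(end - start);
      for (auto& g : G) g.zeros();
      double bl = 0;
      for (size_t ii = start; ii < end; ++ii) {
        arma::ivec cv = row_codes(codes, train[ii]);
        double p = forward_seq(net, cv, true, &rng, c);
        bl += bce(p, y[train[ii]]) / bs;
        backward_seq(net, cv, c, (p - y[train[ii]]) / bs, G);
      }
      ++step;
      double corr = std::sqrt(1.0 - std::pow(b2, step)) /
                    (1.0 - std::pow(b1, step));
      for (size_t i = 0; i < net.W.size(); ++i) {
        M[i] = b1 * M[i] + (1 - b1) * G[i];
        V[i] = b2 * V[i] + (1 - b2) * (G[i] % G[i]);
        net.W[i] -= lr * corr * M[i] / (arma::sqrt(V[i]) + eps);
      }
      tr_loss += bl;
      ++nb;
    }
    tr_loss /= std::max(1, nb);
    double vl = 0;
    for (int i : val) {
      arma::ivec cv = row_codes(codes, i);
      vl += bce(forward_seq(net, cv, false, nullptr, c), y[i]) / val.size();
    }
    hist_train.push_back(tr_loss);
    hist_val.push_back(vl);
    if (vl < best_val - 1e-9) {
      best_val = vl;
      best_W = net.W;
      best_epoch = ep;
      since_best = 0;
    } else if (++since_best >= patience) break;
  }
  net.W = best_W;
  int ne = hist_train.size();
  return List::create(
      _["weights"] = net_to_r(net),
      _["history"] = DataFrame::create(
          _["epoch"] = seq_len(ne),
          _["train_loss"] = NumericVector(hist_train.begin(),
                                          hist_train.end()),
          _["val_loss"] = NumericVector(hist_val.begin(), hist_val.end())),
      _["best_epoch"] = best_epoch);
}
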