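// Dual-branch sequence regression network: shared 1-D convolution over a
// one-hot 4xN input feeding (A) a stack of further convolutions + max-pool +
// dense and (B) a bidirectional GRU + dense; branches concatenate into a
// dense head with a single linear output. Trained by Adam on MSE with
// optional per-layer freezing (gradients flow through frozen layers but
// their parameters are never updated). Everything is double precision and
// deterministic given the seed (single RNG stream: init, shuffling, dropout).

#include <RcppArmadillo.h>
#include <random>
#include <map>
#include <set>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::map<std::string, mat> ParamMap;

struct NetSpec {
  int N;                 // input length
  int k0, F0;            // shared conv kernel / filters
  int kA;                // branch-A kernel
  std::vector<int> cA;   // branch-A filter counts
  int pool;              // max-pool width (= stride)
  int DA;                // branch-A dense units
  int U;                 // GRU units per direction
  int DB;                // branch-B dense units
  std::vector<int> M;    // merge dense sizes
  double dropout;
};

static NetSpec parse_spec(const Rcpp::List& s) {
  NetSpec sp;
  sp.N  = Rcpp::as<int>(s["input_len"]);
  sp.k0 = Rcpp::as<int>(s["conv_kernel"]);
  sp.F0 = Rcpp::as<int>(s["conv_filters"]);
  sp.kA = Rcpp::as<int>(s["branch_kernel"]);
  sp.cA = Rcpp::as<std::vector<int> >(s["branch_filters"]);
  sp.pool = Rcpp::as<int>(s["pool"]);
  sp.DA = Rcpp::as<int>(s["dense_a"]);
  sp.U  = Rcpp::as<int>(s["gru_units"]);
  sp.DB = Rcpp::as<int>(s["dense_b"]);
  sp.M  = Rcpp::as<std::vector<int> >(s["merge_dense"]);
  sp.dropout = Rcpp::as<double>(s["dropout"]);
  return sp;
}

// canonical parameter order (stable across init / train / serialization)
static std::vector<std::string> param_names(const NetSpec& sp) {
  std::vector<std::string> nm;
  nm.push_back("conv_shared_W"); nm.push_back("conv_shared_b");
  for (size_t i = 0; i < sp.cA.size(); ++i) {
    std::string base = "conv_a" + std::to_string(i + 1);
    nm.push_back(base + "_W"); nm.push_back(base + "_b");
  }
  nm.push_back("dense_a_W"); nm.push_back("dense_a_b");
  const char* dirs[2] = {"f", "b"};
  const char* gates[3] = {"z", "r", "c"};
  for (int d = 0; d < 2; ++d)
    for (int g = 0; g < 3; ++g) {
      std::string base = std::string("bigru_") + dirs[d] + "_";
      nm.push_back(base + "W" + gates[g]);
      nm.push_back(base + "U" + gates[g]);
      nm.push_back(base + "b" + gates[g]);
    }
  nm.push_back("dense_b_W"); nm.push_back("dense_b_b");
  for (size_t i = 0; i < sp.M.size(); ++i) {
    std::string base = "dense_merge" + std::to_string(i + 1);
    nm.push_back(base + "_W"); nm.push_back(base + "_b");
  }
  nm.push_back("output_W"); nm.push_back("output_b");
  return nm;
}

// expand layer names (user-facing freeze granularity) to parameter keys
static std::vector<std::string> layer_params(const NetSpec& sp,
                                             const std::string& layer) {
  std::vector<std::string> out;
  const char* gates[3] = {"z", "r", "c"};
  if (layer == "bigru") {
    const char* dirs[2] = {"f", "b"};
    for (int d = 0; d < 2; ++d)
      for (int g = 0; g < 3; ++g) {
        std::string base = std::string("bigru_") + dirs[d] + "_";
        out.push_back(base + "W" + gates[g]);
        out.push_back(base + "U" + gates[g]);
        out.push_back(base + "b" + gates[g]);
      }
  } else {
    out.push_back(layer + "_W");
    out.push_back(layer + "_b");
  }
  return out;
}

static ParamMap weights_from_list(const Rcpp::List& w) {
  ParamMap p;
  Rcpp::CharacterVector nm = w.names();
  for (int i = 0; i < w.size(); ++i)
    p[Rcpp::as<std::string>(nm[i])] = Rcpp::as<mat>(w[i]);
  return p;
}

static Rcpp::List weights_to_list(const ParamMap& p,
                                  const std::vector<std::string>& order) {
  Rcpp::List out(order.size());
  Rcpp::CharacterVector nm(order.size());
  for (size_t i = 0; i < order.size(); ++i) {
    nm[i] = order[i];
    out[i] = Rcpp::wrap(p.at(order[i]));
  }
  out.names() = nm;
  return out;
}

static double urand(std::mt19937& rng) {
  return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
}

static mat glorot(int rows, int cols, std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (rows + cols));
  mat m(rows, cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (2.0 * urand(rng) - 1.0) * lim;
  return m;
}

// ---------------------------------------------------------------- forward ---

struct Cache {
  cube Y0;                       // shared conv output (B, F0, L0), post-ReLU
  std::vector<cube> A;           // branch-A conv outputs, post-ReLU
  cube Pmask;                    // max-pool argmax mask (1 where left wins)
  cube Pout;                     // pooled (B, C, Lp)
  mat FA;                        // flattened (B, C*Lp)
  mat A1, A1d, mA;               // dense_a post-act, post-dropout, mask
  cube Zf, Rf, Cf, Hf;           // forward GRU gates/states (B, U, T)
  cube Zb, Rb, Cb, Hb;           // backward GRU
  mat hcat;                      // (B, 2U)
  mat B1, B1d, mB;               // dense_b
  std::vector<mat> Mi, Mid, mM;  // merge denses
  vec yhat;
};

static mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }
static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static mat conv_window(const cube& X, int p, int k) {
  // horizontal concat of slices p..p+k-1 -> (B, C*k)
  int B = X.n_rows, C = X.n_cols;
  mat M(B, C * k);
  for (int j = 0; j < k; ++j)
    M.cols(j * C, (j + 1) * C - 1) = X.slice(p + j);
  return M;
}

static cube conv_forward(const cube& X, const mat& W, const mat& b, int k) {
  int B = X.n_rows, L = X.n_slices, F = W.n_cols;
  int Lout = L - k + 1;
  cube Y(B, F, Lout);
  for (int p = 0; p < Lout; ++p)
    Y.slice(p) = relu(conv_window(X, p, k) * W + repmat(b, B, 1));
  return Y;
}

static void conv_backward(const cube& X, const cube& Y, const cube& dY,
                          const mat& W, int k,
                          mat& dW, mat& db, cube& dX) {
  int B = X.n_rows, C = X.n_cols, Lout = Y.n_slices;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(1, W.n_cols);
  dX.zeros(B, C, X.n_slices);
  for (int p = 0; p < Lout; ++p) {
    mat dpre = dY.slice(p) % conv_to<mat>::from(Y.slice(p) > 0);
    mat win = conv_window(X, p, k);
    dW += win.t() * dpre;
    db += sum(dpre, 0);
    mat dwin = dpre * W.t();
    for (int j = 0; j < k; ++j)
      dX.slice(p + j) += dwin.cols(j * C, (j + 1) * C - 1);
  }
}

static void gru_forward(const cube& X, const ParamMap& P,
                        const std::string& pre, bool reverse,
                        cube& Z, cube& R, cube& Cc, cube& H) {
  int B = X.n_rows, T = X.n_slices;
  const mat &Wz = P.at(pre + "Wz"), &Uz = P.at(pre + "Uz"), &bz = P.at(pre + "bz");
  const mat &Wr = P.at(pre + "Wr"), &Ur = P.at(pre + "Ur"), &br = P.at(pre + "br");
  const mat &Wc = P.at(pre + "Wc"), &Uc = P.at(pre + "Uc"), &bc = P.at(pre + "bc");
  int U_ = Wz.n_cols;
  Z.set_size(B, U_, T); R.set_size(B, U_, T);
  Cc.set_size(B, U_, T); H.set_size(B, U_, T);
  mat h(B, U_, fill::zeros);
  for (int s = 0; s < T; ++s) {
    mat x = X.slice(reverse ? (T - 1 - s) : s);
    mat z = sigmoid(x * Wz + h * Uz + repmat(bz, B, 1));
    mat r = sigmoid(x * Wr + h * Ur + repmat(br, B, 1));
    mat c = tanh(x * Wc + (r % h) * Uc + repmat(bc, B, 1));
    h = (1.0 - z) % h + z % c;
    Z.slice(s) = z; R.slice(s) = r; Cc.slice(s) = c; H.slice(s) = h;
  }
}

static void gru_backward(const cube& X, const ParamMap& P,
                         const std::string& pre, bool reverse,
                         const cube& Z, const cube& R, const cube& Cc,
                         const cube& H, const mat& dh_final,
                         ParamMap& G, cube& dX) {
  int B = X.n_rows, T = X.n_slices;
  const mat &Wz = P.at(pre + "Wz"), &Uz = P.at(pre + "Uz");
  const mat &Wr = P.at(pre + "Wr"), &Ur = P.at(pre + "Ur");
  const mat &Wc = P.at(pre + "Wc"), &Uc = P.at(pre + "Uc");
  int U_ = Wz.n_cols, I = Wz.n_rows;
  mat dWz(I, U_, fill::zeros), dUz(U_, U_, fill::zeros), dbz(1, U_, fill::zeros);
  mat dWr(I, U_, fill::zeros), dUr(U_, U_, fill::zeros), dbr(1, U_, fill::zeros);
  mat dWc(I, U_, fill::zeros), dUc(U_, U_, fill::zeros), dbc(1, U_, fill::zeros);
  mat dh = dh_final;
  for (int s = T - 1; s >= 0; --s) {
    mat x = X.slice(reverse ? (T - 1 - s) : s);
    mat h_prev = (s > 0) ? H.slice(s - 1) : mat(B, U_, fill::zeros);
    const mat &z = Z.slice(s), &r = R.slice(s), &c = Cc.slice(s);
    mat dz = dh % (c - h_prev);
    mat dc = dh % z;
    mat da_c = dc % (1.0 - c % c);
    mat drh = da_c * Uc.t();
    mat dr = drh % h_prev;
    mat da_r = dr % r % (1.0 - r);
    mat da_z = dz % z % (1.0 - z);
    mat dh_prev = dh % (1.0 - z) + drh % r + da_r * Ur.t() + da_z * Uz.t();
    dWz += x.t() * da_z; dUz += h_prev.t() * da_z; dbz += sum(da_z, 0);
    dWr += x.t() * da_r; dUr += h_prev.t() * da_r; dbr += sum(da_r, 0);
    dWc += x.t() * da_c; dUc += (r % h_prev).t() * da_c; dbc += sum(da_c, 0);
    dX.slice(reverse ? (T - 1 - s) : s) +=
      da_z * Wz.t() + da_r * Wr.t() + da_c * Wc.t();
    dh = dh_prev;
  }
  G[pre + "Wz"] = dWz; G[pre + "Uz"] = dUz; G[pre + "bz"] = dbz;
  G[pre + "Wr"] = dWr; G[pre + "Ur"] = dUr; G[pre + "br"] = dbr;
  G[pre + "Wc"] = dWc; G[pre + "Uc"] = dUc; G[pre + "bc"] = dbc;
}

static mat dropout_mask(int B, int n, double p, std::mt19937& rng) {
  mat m(B, n);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (urand(rng) >= p) ? 1.0 / (1.0 - p) : 0.0;
  return m;
}

static Cache net_forward(const ParamMap& P, const NetSpec& sp, const cube& X,
                         bool training, std::mt19937* rng) {
  Cache C;
  int B = X.n_rows;
  bool drop = training && sp.dropout > 0.0;

  C.Y0 = conv_forward(X, P.at("conv_shared_W"), P.at("conv_shared_b"), sp.k0);

  // branch A
  cube cur = C.Y0;
  for (size_t i = 0; i < sp.cA.size(); ++i) {
    std::string base = "conv_a" + std::to_string(i + 1);
    cur = conv_forward(cur, P.at(base + "_W"), P.at(base + "_b"), sp.kA);
    C.A.push_back(cur);
  }
  int Lp = cur.n_slices / sp.pool;
  int Cch = cur.n_cols;
  C.Pout.set_size(B, Cch, Lp);
  C.Pmask.set_size(B, Cch, Lp);
  for (int q = 0; q < Lp; ++q) {
    // pool width is fixed at 2 in practice; generalized elementwise max
    mat best = cur.slice(q * sp.pool);
    mat mask(B, Cch, fill::ones);
    for (int j = 1; j < sp.pool; ++j) {
      mat cand = cur.slice(q * sp.pool + j);
      umat gt = cand > best;
      best = max(best, cand);
      mask = mask % (1.0 - conv_to<mat>::from(gt));
    }
    C.Pout.slice(q) = best;
    C.Pmask.slice(q) = mask;  // 1 iff the first element of the window won
  }
  C.FA.set_size(B, Cch * Lp);
  for (int q = 0; q < Lp; ++q)
    C.FA.cols(q * Cch, (q + 1) * Cch - 1) = C.Pout.slice(q);
  C.A1 = relu(C.FA * P.at("dense_a_W") + repmat(P.at("dense_a_b"), B, 1));
  C.mA = drop ? dropout_mask(B, sp.DA, sp.dropout, *rng) : mat(B, sp.DA, fill::ones);
  C.A1d = C.A1 % C.mA;

  // branch B
  gru_forward(C.Y0, P, "bigru_f_", false, C.Zf, C.Rf, C.Cf, C.Hf);
  gru_forward(C.Y0, P, "bigru_b_", true,  C.Zb, C.Rb, C.Cb, C.Hb);
  int T = C.Y0.n_slices;
  C.hcat = join_rows(C.Hf.slice(T - 1), C.Hb.slice(T - 1));
  C.B1 = relu(C.hcat * P.at("dense_b_W") + repmat(P.at("dense_b_b"), B, 1));
  C.mB = drop ? dropout_mask(B, sp.DB, sp.dropout, *rng) : mat(B, sp.DB, fill::ones);
  C.B1d = C.B1 % C.mB;

  // merge head
  mat h = join_rows(C.A1d, C.B1d);
  for (size_t i = 0; i < sp.M.size(); ++i) {
    std::string base = "dense_merge" + std::to_string(i + 1);
    mat a = relu(h * P.at(base + "_W") + repmat(P.at(base + "_b"), B, 1));
    mat m = drop ? dropout_mask(B, sp.M[i], sp.dropout, *rng)
                 : mat(B, sp.M[i], fill::ones);
    C.Mi.push_back(a); C.mM.push_back(m); C.Mid.push_back(a % m);
    h = C.Mid.back();
  }
  C.yhat = vec(h * P.at("output_W") + repmat(P.at("output_b"), B, 1));
  return C;
}

static ParamMap net_backward(const ParamMap& P, const NetSpec& sp,
                             const cube& X, const Cache& C, const vec& y) {
  ParamMap G;
  int B = X.n_rows;
  vec dy = 2.0 * (C.yhat - y) / (double)B;

  mat head_in = sp.M.empty() ? join_rows(C.A1d, C.B1d) : C.Mid.back();
  G["output_W"] = head_in.t() * dy;
  G["output_b"] = mat(1, 1).fill(accu(dy));
  mat dh = dy * P.at("output_W").t();

  for (int i = (int)sp.M.size() - 1; i >= 0; --i) {
    std::string base = "dense_merge" + std::to_string(i + 1);
    mat dpost = dh % C.mM[i];
    mat dpre = dpost % conv_to<mat>::from(C.Mi[i] > 0);
    mat in = (i == 0) ? join_rows(C.A1d, C.B1d) : C.Mid[i - 1];
    G[base + "_W"] = in.t() * dpre;
    G[base + "_b"] = sum(dpre, 0);
    dh = dpre * P.at(base + "_W").t();
  }
  mat dA1d = dh.cols(0, sp.DA - 1);
  mat dB1d = dh.cols(sp.DA, sp.DA + sp.DB - 1);

  // branch B dense
  mat dB1 = dB1d % C.mB % conv_to<mat>::from(C.B1 > 0);
  G["dense_b_W"] = C.hcat.t() * dB1;
  G["dense_b_b"] = sum(dB1, 0);
  mat dhcat = dB1 * P.at("dense_b_W").t();
  int U_ = sp.U;
  cube dY0_gru(B, sp.F0, C.Y0.n_slices, fill::zeros);
  gru_backward(C.Y0, P, "bigru_f_", false, C.Zf, C.Rf, C.Cf, C.Hf,
               dhcat.cols(0, U_ - 1), G, dY0_gru);
  gru_backward(C.Y0, P, "bigru_b_", true, C.Zb, C.Rb, C.Cb, C.Hb,
               dhcat.cols(U_, 2 * U_ - 1), G, dY0_gru);

  // branch A dense + pool + convs
  mat dA1 = dA1d % C.mA % conv_to<mat>::from(C.A1 > 0);
  G["dense_a_W"] = C.FA.t() * dA1;
  G["dense_a_b"] = sum(dA1, 0);
  mat dFA = dA1 * P.at("dense_a_W").t();
  const cube& lastA = C.A.back();
  int Cch = lastA.n_cols, Lp = C.Pout.n_slices;
  cube dLast(B, Cch, lastA.n_slices, fill::zeros);
  for (int q = 0; q < Lp; ++q) {
    mat dout = dFA.cols(q * Cch, (q + 1) * Cch - 1);
    // route to argmax: first element if mask==1, else recompute winner
    if (sp.pool == 2) {
      dLast.slice(q * 2)     += dout % C.Pmask.slice(q);
      dLast.slice(q * 2 + 1) += dout % (1.0 - C.Pmask.slice(q));
    } else {
      for (int j = 0; j < sp.pool; ++j) {
        mat is_max = conv_to<mat>::from(lastA.slice(q * sp.pool + j) ==
                                        C.Pout.slice(q));
        dLast.slice(q * sp.pool + j) += dout % is_max;
      }
    }
  }
  cube dcur = dLast;
  for (int i = (int)sp.cA.size() - 1; i >= 0; --i) {
    std::string base = "conv_a" + std::to_string(i + 1);
    const cube& in = (i == 0) ? C.Y0 : C.A[i - 1];
    mat dW, db; cube dX_;
    conv_backward(in, C.A[i], dcur, P.at(base + "_W"), sp.kA, dW, db, dX_);
    G[base + "_W"] = dW; G[base + "_b"] = db;
    dcur = dX_;
  }

  // shared conv: gradients from branch A and the GRU
  cube dY0 = dcur + dY0_gru;
  mat dW0, db0; cube dXin;
  conv_backward(X, C.Y0, dY0, P.at("conv_shared_W"), sp.k0, dW0, db0, dXin);
  G["conv_shared_W"] = dW0; G["conv_shared_b"] = db0;
  return G;
}

// ------------------------------------------------------------------ exports --

// [[Rcpp::export]]
Rcpp::List nn_init_cpp(Rcpp::List spec, int seed) {
  NetSpec sp = parse_spec(spec);
  std::mt19937 rng(seed);
  ParamMap P;
  P["conv_shared_W"] = glorot(4 * sp.k0, sp.F0, rng);
  P["conv_shared_b"] = mat(1, sp.F0, fill::zeros);
  int prev = sp.F0;
  int L = sp.N - sp.k0 + 1;
  for (size_t i = 0; i < sp.cA.size(); ++i) {
    std::string base = "conv_a" + std::to_string(i + 1);
    P[base + "_W"] = glorot(prev * sp.kA, sp.cA[i], rng);
    P[base + "_b"] = mat(1, sp.cA[i], fill::zeros);
    prev = sp.cA[i];
    L = L - sp.kA + 1;
    if (L < 1) Rcpp::stop("branch-A convolution output length underflows; shorten the stack or the kernels");
  }
  int flat = prev * (L / sp.pool);
  if (L / sp.pool < 1) Rcpp::stop("max-pool output empty");
  P["dense_a_W"] = glorot(flat, sp.DA, rng);
  P["dense_a_b"] = mat(1, sp.DA, fill::zeros);
  const char* dirs[2] = {"f", "b"};
  const char* gates[3] = {"z", "r", "c"};
  for (int d = 0; d < 2; ++d)
    for (int g = 0; g < 3; ++g) {
      std::string base = std::string("bigru_") + dirs[d] + "_";
      P[base + "W" + gates[g]] = glorot(sp.F0, sp.U, rng);
      P[base + "U" + gates[g]] = glorot(sp.U, sp.U, rng);
      P[base + "b" + gates[g]] = mat(1, sp.U, fill::zeros);
    }
  P["dense_b_W"] = glorot(2 * sp.U, sp.DB, rng);
  P["dense_b_b"] = mat(1, sp.DB, fill::zeros);
  prev = sp.DA + sp.DB;
  for (size_t i = 0; i < sp.M.size(); ++i) {
    std::string base = "dense_merge" + std::to_string(i + 1);
    P[base + "_W"] = glorot(prev, sp.M[i], rng);
    P[base + "_b"] = mat(1, sp.M[i], fill::zeros);
    prev = sp.M[i];
  }
  P["output_W"] = glorot(prev, 1, rng);
  P["output_b"] = mat(1, 1, fill::zeros);
  return weights_to_list(P, param_names(sp));
}

// [[Rcpp::export]]
arma::vec nn_forward_cpp(Rcpp::List weights, Rcpp::List spec, arma::cube X) {
  NetSpec sp = parse_spec(spec);
  if ((int)X.n_slices != sp.N)
    Rcpp::stop("input length %d does not match model input_len %d",
               (int)X.n_slices, sp.N);
  ParamMap P = weights_from_list(weights);
  Cache C = net_forward(P, sp, X, false, nullptr);
  return C.yhat;
}

// [[Rcpp::export]]
Rcpp::List nn_grad_cpp(Rcpp::List weights, Rcpp::List spec,
                       arma::cube X, arma::vec y) {
  NetSpec sp = parse_spec(spec);
  ParamMap P = weights_from_list(weights);
  Cache C = net_forward(P, sp, X, false, nullptr);
  ParamMap G = net_backward(P, sp, X, C, y);
  double loss = accu(square(C.yhat - y)) / (double)X.n_rows;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = weights_to_list(G, param_names(sp)));
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List weights, Rcpp::List spec,
                        arma::cube X, arma::vec y,
                        int epochs, int batch_size, double lr, int seed,
                        Rcpp::CharacterVector trainable_layers,
                        bool use_dropout) {
  NetSpec sp = parse_spec(spec);
  if ((int)X.n_slices != sp.N)
    Rcpp::stop("input length %d does not match model input_len %d",
               (int)X.n_slices, sp.N);
  if (!use_dropout) sp.dropout = 0.0;
  ParamMap P = weights_from_list(weights);
  std::vector<std::string> order = param_names(sp);

  std::set<std::string> upd;
  for (int i = 0; i < trainable_layers.size(); ++i) {
    std::vector<std::string> ps =
      layer_params(sp, Rcpp::as<std::string>(trainable_layers[i]));
    for (size_t j = 0; j < ps.size(); ++j) {
      if (P.find(ps[j]) == P.end())
        Rcpp::stop("freeze plan references unknown layer: %s",
                   Rcpp::as<std::string>(trainable_layers[i]).c_str());
      upd.insert(ps[j]);
    }
  }

  ParamMap Ms, Vs;  // Adam state
  for (std::set<std::string>::iterator it = upd.begin(); it != upd.end(); ++it) {
    Ms[*it] = mat(P[*it].n_rows, P[*it].n_cols, fill::zeros);
    Vs[*it] = mat(P[*it].n_rows, P[*it].n_cols, fill::zeros);
  }
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;

  std::mt19937 rng(seed);
  int n = X.n_rows;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> history;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double esum = 0.0; int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      int B = end - start;
      cube Xb(B, X.n_cols, X.n_slices);
      vec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.row(i) = X.row(idx[start + i]);
        yb(i) = y(idx[start + i]);
      }
      Cache C = net_forward(P, sp, Xb, true, &rng);
      double loss = accu(square(C.yhat - yb)) / (double)B;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d; lower the learning rate", e + 1);
      ParamMap G = net_backward(P, sp, Xb, C, yb);
      ++tstep;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)tstep)) /
                    (1.0 - std::pow(b1, (double)tstep));
      for (std::set<std::string>::iterator it = upd.begin(); it != upd.end(); ++it) {
        mat& g = G[*it];
        Ms[*it] = b1 * Ms[*it] + (1.0 - b1) * g;
        Vs[*it] = b2 * Vs[*it] + (1.0 - b2) * (g % g);
        P[*it] -= corr * Ms[*it] / (sqrt(Vs[*it]) + eps);
      }
      esum += loss; ++nb;
    }
    history.push_back(esum / nb);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_to_list(P, order),
    Rcpp::Named("history") = history);
}
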