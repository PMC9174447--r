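// Stacked-LSTM next-token model: teacher-forced training with Adam,
// held-out scoring, batched ancestral sampling. Gate order everywhere is
// [input, forget, candidate, output]. All token codes are 0-based; the
// caller supplies pad/bos/eos indices. All randomness (init, shuffling,
// dropout, sampling) draws from R's RNG so R-side set.seed() governs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat get_mat(const List& p, const char* name) {
  return as<mat>(p[name]);
}

static List clone_params(const List& p) {
  return clone(p);
}

// [[Rcpp::export]]
List cpp_lstm_new(int vocab_size, int n_layers, int hidden, int emb_dim) {
  RNGScope scope;
  double r = 0.08;
  List W(n_layers), U(n_layers), b(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    int in_dim = (l == 0) ? emb_dim : hidden;
    mat w(4 * hidden, in_dim), u(4 * hidden, hidden);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = R::runif(-r, r);
    for (uword i = 0; i < u.n_elem; ++i) u(i) = R::runif(-r, r);
    vec bb(4 * hidden, fill::zeros);
    // forget-gate bias starts at 1 (standard stabilization)
    bb.subvec(hidden, 2 * hidden - 1).fill(1.0);
    W[l] = w; U[l] = u; b[l] = bb;
  }
  mat emb(emb_dim, vocab_size), Wy(vocab_size, hidden);
  for (uword i = 0; i < emb.n_elem; ++i) emb(i) = R::runif(-r, r);
  for (uword i = 0; i < Wy.n_elem; ++i) Wy(i) = R::runif(-r, r);
  vec by(vocab_size, fill::zeros);
  return List::create(_["emb"] = emb, _["W"] = W, _["U"] = U, _["b"] = b,
                      _["Wy"] = Wy, _["by"] = by,
                      _["n_layers"] = n_layers, _["hidden"] = hidden,
                      _["emb_dim"] = emb_dim, _["vocab_size"] = vocab_size);
}

struct Cache {
  std::vector<mat> x, i, f, g, o, c, tc, h;
};

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// forward one layer over one time step
static void lstm_cell(const mat& W, const mat& U, const vec& b,
                      const mat& x, const mat& h_prev, const mat& c_prev,
                      mat& i, mat& f, mat& g, mat& o, mat& c, mat& tc, mat& h) {
  int H = h_prev.n_rows;
  mat z = W * x + U * h_prev;
  z.each_col() += b;
  i = sigmoid(z.rows(0, H - 1));
  f = sigmoid(z.rows(H, 2 * H - 1));
  g = tanh(z.rows(2 * H, 3 * H - 1));
  o = sigmoid(z.rows(3 * H, 4 * H - 1));
  c = f % c_prev + i % g;
  tc = tanh(c);
  h = o % tc;
}

// One optimization epoch over `seqs` (list of 0-based integer vectors,
// each beginning with BOS and ending with EOS). Returns updated params,
// Adam state and the epoch's mean per-token NLL.
// [[Rcpp::export]]
List cpp_lstm_epoch(List params, List opt, List seqs, int batch_size,
                    double lr, double dropout, int pad, double clip) {
  RNGScope scope;
  int L = as<int>(params["n_layers"]);
  int H = as<int>(params["hidden"]);
  int V = as<int>(params["vocab_size"]);
  mat emb = get_mat(params, "emb");
  mat Wy = get_mat(params, "Wy");
  vec by = as<vec>(params["by"]);
  std::vector<mat> W(L), U(L);
  std::vector<vec> b(L);
  List Wl = params["W"], Ul = params["U"], bl = params["b"];
  for (int l = 0; l < L; ++l) {
    W[l] = as<mat>(Wl[l]); U[l] = as<mat>(Ul[l]); b[l] = as<vec>(bl[l]);
  }

  // Adam state: one moment pair per tensor, flattened order
  int n_tensors = 2 + 3 * L + 1; // emb, Wy, (W,U,b)*L, by
  std::vector<mat> m1(n_tensors), m2(n_tensors);
  int t_adam = 0;
  if (opt.size() == 0) {
    int k = 0;
    auto zero_like = [&](const mat& x) { m1[k] = zeros(size(x)); m2[k] = zeros(size(x)); ++k; };
    zero_like(emb); zero_like(Wy); m1[k] = zeros(V, 1); m2[k] = zeros(V, 1); ++k;
    for (int l = 0; l < L; ++l) {
      zero_like(W[l]); zero_like(U[l]);
      m1[k] = zeros(4 * H, 1); m2[k] = zeros(4 * H, 1); ++k;
    }
  } else {
    List M1 = opt["m1"], M2 = opt["m2"];
    t_adam = as<int>(opt["t"]);
    for (int k = 0; k < n_tensors; ++k) { m1[k] = as<mat>(M1[k]); m2[k] = as<mat>(M2[k]); }
  }

  int n_seq = seqs.size();
  IntegerVector ord(n_seq);
  for (int i = 0; i < n_seq; ++i) ord[i] = i;
  // Fisher-Yates with R RNG, then stable sort by length: batches are
  // length-homogeneous (little padding waste) but random within a length,
  // and the batch visit order is itself shuffled below.
  for (int i = n_seq - 1; i > 0; --i) {
    int j = (int) floor(R::unif_rand() * (i + 1));
    std::swap(ord[i], ord[j]);
  }
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return as<IntegerVector>(seqs[a]).size() < as<IntegerVector>(seqs[b]).size();
  });
  int n_batches = (n_seq + batch_size - 1) / batch_size;
  std::vector<int> batch_order(n_batches);
  for (int i = 0; i < n_batches; ++i) batch_order[i] = i;
  for (int i = n_batches - 1; i > 0; --i) {
    int j = (int) floor(R::unif_rand() * (i + 1));
    std::swap(batch_order[i], batch_order[j]);
  }

  double total_loss = 0.0;
  double total_tokens = 0.0;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  for (int bidx = 0; bidx < n_batches; ++bidx) {
    int start = batch_order[bidx] * batch_size;
    int B = std::min(batch_size, n_seq - start);
    int T = 0;
    std::vector<IntegerVector> batch(B);
    for (int bi = 0; bi < B; ++bi) {
      batch[bi] = as<IntegerVector>(seqs[ord[start + bi]]);
      T = std::max(T, (int) batch[bi].size());
    }
    if (T < 2) continue;
    imat codes(B, T);
    codes.fill(pad);
    for (int bi = 0; bi < B; ++bi)
      for (int t = 0; t < batch[bi].size(); ++t) codes(bi, t) = batch[bi][t];

    int S = T - 1; // prediction steps
    Cache cache;
    cache.x.resize(S * L); cache.i.resize(S * L); cache.f.resize(S * L);
    cache.g.resize(S * L); cache.o.resize(S * L); cache.c.resize(S * L);
    cache.tc.resize(S * L); cache.h.resize(S * L);
    std::vector<mat> drop_mask(S);
    std::vector<mat> probs(S);
    std::vector<mat> h_prev(L, zeros(H, B)), c_prev(L, zeros(H, B));

    // gradients
    mat demb = zeros(size(emb)), dWy = zeros(size(Wy));
    vec dby = zeros(V);
    std::vector<mat> dW(L), dU(L);
    std::vector<vec> db(L);
    for (int l = 0; l < L; ++l) {
      dW[l] = zeros(size(W[l])); dU[l] = zeros(size(U[l])); db[l] = zeros(4 * H);
    }

    double batch_loss = 0.0;
    double n_tok = 0.0;
    // ---- forward
    for (int s = 0; s < S; ++s) {
      mat x(emb.n_rows, B);
      for (int bi = 0; bi < B; ++bi) x.col(bi) = emb.col(codes(bi, s));
      mat input = x;
      for (int l = 0; l < L; ++l) {
        int idx = s * L + l;
        lstm_cell(W[l], U[l], b[l], input, h_prev[l], c_prev[l],
                  cache.i[idx], cache.f[idx], cache.g[idx], cache.o[idx],
                  cache.c[idx], cache.tc[idx], cache.h[idx]);
        cache.x[idx] = input;
        c_prev[l] = cache.c[idx];
        h_prev[l] = cache.h[idx];
        input = cache.h[idx];
      }
      // inverted dropout on the last layer's output
      mat mask(H, B, fill::ones);
      if (dropout > 0) {
        for (uword ii = 0; ii < mask.n_elem; ++ii)
          mask(ii) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      }
      drop_mask[s] = mask;
      mat hd = input % mask;
      mat logits = Wy * hd;
      logits.each_col() += by;
      logits.each_row() -= max(logits, 0);
      mat ex = exp(logits);
      mat p = ex.each_row() / sum(ex, 0);
      probs[s] = p;
      for (int bi = 0; bi < B; ++bi) {
        int target = codes(bi, s + 1);
        if (target != pad) {
          batch_loss += -std::log(std::max(p(target, bi), 1e-12));
          n_tok += 1.0;
        }
      }
    }
    if (n_tok == 0) continue;

    // ---- backward
    std::vector<mat> dh_next(L, zeros(H, B)), dc_next(L, zeros(H, B));
    for (int s = S - 1; s >= 0; --s) {
      mat dlogits = probs[s];
      for (int bi = 0; bi < B; ++bi) {
        int target = codes(bi, s + 1);
        if (target == pad) {
          dlogits.col(bi).zeros();
        } else {
          dlogits(target, bi) -= 1.0;
        }
      }
      dlogits /= n_tok;
      int top = s * L + (L - 1);
      mat hd = cache.h[top] % drop_mask[s];
      dWy += dlogits * hd.t();
      dby += sum(dlogits, 1);
      mat dh_top = (Wy.t() * dlogits) % drop_mask[s];
      mat dh_carry; // same-step gradient from the layer above
      for (int l = L - 1; l >= 0; --l) {
        int idx = s * L + l;
        mat dh = dh_next[l];
        if (l == L - 1) dh += dh_top; else dh += dh_carry;
        mat& i = cache.i[idx]; mat& f = cache.f[idx]; mat& g = cache.g[idx];
        mat& o = cache.o[idx]; mat& tc = cache.tc[idx];
        mat c_prev_t = (s == 0) ? zeros(H, B) : cache.c[(s - 1) * L + l];
        mat h_prev_t = (s == 0) ? zeros(H, B) : cache.h[(s - 1) * L + l];
        mat ddo = dh % tc;
        mat dct = dh % o % (1.0 - tc % tc) + dc_next[l];
        mat di = dct % g;
        mat dg = dct % i;
        mat df = dct % c_prev_t;
        dc_next[l] = dct % f;
        mat dz(4 * H, B);
        dz.rows(0, H - 1) = di % i % (1.0 - i);
        dz.rows(H, 2 * H - 1) = df % f % (1.0 - f);
        dz.rows(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
        dz.rows(3 * H, 4 * H - 1) = ddo % o % (1.0 - o);
        dW[l] += dz * cache.x[idx].t();
        dU[l] += dz * h_prev_t.t();
        db[l] += sum(dz, 1);
        dh_next[l] = U[l].t() * dz;
        mat dx = W[l].t() * dz;
        if (l > 0) {
          dh_carry = dx;
        } else {
          for (int bi = 0; bi < B; ++bi) demb.col(codes(bi, s)) += dx.col(bi);
        }
      }
    }

    // ---- gradient clip (global norm) and Adam step
    std::vector<mat*> tensors; std::vector<mat*> grads;
    mat dby_m = conv_to<mat>::from(dby);
    std::vector<mat> db_m(L);
    for (int l = 0; l < L; ++l) db_m[l] = conv_to<mat>::from(db[l]);
    mat by_m = conv_to<mat>::from(by);
    std::vector<mat> b_m(L);
    for (int l = 0; l < L; ++l) b_m[l] = conv_to<mat>::from(b[l]);

    double sq = accu(demb % demb) + accu(dWy % dWy) + accu(dby_m % dby_m);
    for (int l = 0; l < L; ++l)
      sq += accu(dW[l] % dW[l]) + accu(dU[l] % dU[l]) + accu(db_m[l] % db_m[l]);
    double norm = std::sqrt(sq);
    double scale = (clip > 0 && norm > clip) ? clip / norm : 1.0;

    ++t_adam;
    double corr1 = 1.0 - std::pow(b1, t_adam);
    double corr2 = 1.0 - std::pow(b2, t_adam);
    int k = 0;
    auto adam_step = [&](mat& x, mat gmat) {
      gmat *= scale;
      m1[k] = b1 * m1[k] + (1 - b1) * gmat;
      m2[k] = b2 * m2[k] + (1 - b2) * (gmat % gmat);
      x -= lr * (m1[k] / corr1) / (sqrt(m2[k] / corr2) + eps);
      ++k;
    };
    adam_step(emb, demb);
    adam_step(Wy, dWy);
    adam_step(by_m, dby_m);
    for (int l = 0; l < L; ++l) {
      adam_step(W[l], dW[l]);
      adam_step(U[l], dU[l]);
      adam_step(b_m[l], db_m[l]);
    }
    by = by_m.col(0);
    for (int l = 0; l < L; ++l) b[l] = b_m[l].col(0);

    total_loss += batch_loss;
    total_tokens += n_tok;
  }

  List Wo(L), Uo(L), bo(L);
  for (int l = 0; l < L; ++l) { Wo[l] = W[l]; Uo[l] = U[l]; bo[l] = b[l]; }
  List new_params = List::create(
    _["emb"] = emb, _["W"] = Wo, _["U"] = Uo, _["b"] = bo,
    _["Wy"] = Wy, _["by"] = by, _["n_layers"] = L, _["hidden"] = H,
    _["emb_dim"] = (int) emb.n_rows, _["vocab_size"] = V);
  List M1(n_tensors), M2(n_tensors);
  for (int k2 = 0; k2 < n_tensors; ++k2) { M1[k2] = m1[k2]; M2[k2] = m2[k2]; }
  List new_opt = List::create(_["m1"] = M1, _["m2"] = M2, _["t"] = t_adam);
  double mean_nll = (total_tokens > 0) ? total_loss / total_tokens : NA_REAL;
  return List::create(_["params"] = new_params, _["opt"] = new_opt,
                      _["nll"] = mean_nll);
}

// Mean per-token NLL of `seqs` under the model (no dropout).
// [[Rcpp::export]]
double cpp_lstm_nll(List params, List seqs, int pad) {
  int L = as<int>(params["n_layers"]);
  int H = as<int>(params["hidden"]);
  mat emb = get_mat(params, "emb");
  mat Wy = get_mat(params, "Wy");
  vec by = as<vec>(params["by"]);
  List Wl = params["W"], Ul = params["U"], bl = params["b"];
  std::vector<mat> W(L), U(L); std::vector<vec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<mat>(Wl[l]); U[l] = as<mat>(Ul[l]); b[l] = as<vec>(bl[l]);
  }
  int n_seq = seqs.size();
  double total = 0, n_tok = 0;
  int batch_size = 256;
  for (int start = 0; start < n_seq; start += batch_size) {
    int B = std::min(batch_size, n_seq - start);
    int T = 0;
    std::vector<IntegerVector> batch(B);
    for (int bi = 0; bi < B; ++bi) {
      batch[bi] = as<IntegerVector>(seqs[start + bi]);
      T = std::max(T, (int) batch[bi].size());
    }
    if (T < 2) continue;
    imat codes(B, T); codes.fill(pad);
    for (int bi = 0; bi < B; ++bi)
      for (int t = 0; t < batch[bi].size(); ++t) codes(bi, t) = batch[bi][t];
    std::vector<mat> h(L, zeros(H, B)), c(L, zeros(H, B));
    for (int s = 0; s < T - 1; ++s) {
      mat x(emb.n_rows, B);
      for (int bi = 0; bi < B; ++bi) x.col(bi) = emb.col(codes(bi, s));
      mat input = x;
      for (int l = 0; l < L; ++l) {
        mat i, f, g, o, cc, tc, hh;
        lstm_cell(W[l], U[l], b[l], input, h[l], c[l], i, f, g, o, cc, tc, hh);
        c[l] = cc; h[l] = hh; input = hh;
      }
      mat logits = Wy * input;
      logits.each_col() += by;
      logits.each_row() -= max(logits, 0);
      mat ex = exp(logits);
      mat p = ex.each_row() / sum(ex, 0);
      for (int bi = 0; bi < B; ++bi) {
        int target = codes(bi, s + 1);
        if (target != pad) {
          total += -std::log(std::max(p(target, bi), 1e-12));
          n_tok += 1.0;
        }
      }
    }
  }
  return (n_tok > 0) ? total / n_tok : NA_REAL;
}

// Next-token distributions along a single teacher-forced sequence;
// returns V x (len) matrix, column s = p(token | codes[0..s]).
// [[Rcpp::export]]
NumericMatrix cpp_lstm_probs(List params, IntegerVector codes) {
  int L = as<int>(params["n_layers"]);
  int H = as<int>(params["hidden"]);
  int V = as<int>(params["vocab_size"]);
  mat emb = get_mat(params, "emb");
  mat Wy = get_mat(params, "Wy");
  vec by = as<vec>(params["by"]);
  List Wl = params["W"], Ul = params["U"], bl = params["b"];
  std::vector<mat> W(L), U(L); std::vector<vec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<mat>(Wl[l]); U[l] = as<mat>(Ul[l]); b[l] = as<vec>(bl[l]);
  }
  int T = codes.size();
  mat out(V, T);
  std::vector<mat> h(L, zeros(H, 1)), c(L, zeros(H, 1));
  for (int s = 0; s < T; ++s) {
    mat x = emb.col(codes[s]);
    mat input = x;
    for (int l = 0; l < L; ++l) {
      mat i, f, g, o, cc, tc, hh;
      lstm_cell(W[l], U[l], b[l], input, h[l], c[l], i, f, g, o, cc, tc, hh);
      c[l] = cc; h[l] = hh; input = hh;
    }
    vec logits = Wy * input + by;
    logits -= logits.max();
    vec ex = exp(logits);
    out.col(s) = ex / accu(ex);
  }
  return wrap(out);
}

// Batched ancestral sampling. Returns an n x max_len integer matrix of
// token codes (pad-filled after EOS); EOS itself is not included.
// [[Rcpp::export]]
IntegerMatrix cpp_lstm_sample(List params, int n, int max_len,
                              int bos, int eos, int pad, bool mask_first_eos) {
  RNGScope scope;
  int L = as<int>(params["n_layers"]);
  int H = as<int>(params["hidden"]);
  int V = as<int>(params["vocab_size"]);
  mat emb = get_mat(params, "emb");
  mat Wy = get_mat(params, "Wy");
  vec by = as<vec>(params["by"]);
  List Wl = params["W"], Ul = params["U"], bl = params["b"];
  std::vector<mat> W(L), U(L); std::vector<vec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<mat>(Wl[l]); U[l] = as<mat>(Ul[l]); b[l] = as<vec>(bl[l]);
  }
  IntegerMatrix out(n, max_len);
  std::fill(out.begin(), out.end(), pad);
  std::vector<mat> h(L, zeros(H, n)), c(L, zeros(H, n));
  ivec cur(n); cur.fill(bos);
  std::vector<bool> done(n, false);
  int n_done = 0;
  for (int s = 0; s < max_len && n_done < n; ++s) {
    mat x(emb.n_rows, n);
    for (int bi = 0; bi < n; ++bi) x.col(bi) = emb.col(cur(bi));
    mat input = x;
    for (int l = 0; l < L; ++l) {
      mat i, f, g, o, cc, tc, hh;
      lstm_cell(W[l], U[l], b[l], input, h[l], c[l], i, f, g, o, cc, tc, hh);
      c[l] = cc; h[l] = hh; input = hh;
    }
    mat logits = Wy * input;
    logits.each_col() += by;
    // BOS and PAD are never legal emissions; EOS is masked at the first step
    logits.row(bos).fill(-1e30);
    logits.row(pad).fill(-1e30);
    if (s == 0 && mask_first_eos) logits.row(eos).fill(-1e30);
    logits.each_row() -= max(logits, 0);
    mat ex = exp(logits);
    mat p = ex.each_row() / sum(ex, 0);
    for (int bi = 0; bi < n; ++bi) {
      if (done[bi]) continue;
      double u = R::unif_rand();
      double acc = 0.0;
      int pick = V - 1;
      for (int v = 0; v < V; ++v) {
        acc += p(v, bi);
        if (u <= acc) { pick = v; break; }
      }
      if (pick == eos) {
        done[bi] = true;
        ++n_done;
        cur(bi) = eos;
      } else {
        out(bi, s) = pick;
        cur(bi) = pick;
      }
    }
  }
  return out;
}
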