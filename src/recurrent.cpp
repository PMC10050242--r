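// Recurrent-network core: stacked LSTM and tap-delay RNN, sequence-to-label,
// trained with Adam on softmax cross-entropy. Gate layout in each LSTM
// weight matrix is [forget; input; candidate; output], each block acting on
// the concatenation [h_{t-1}, x_t].

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec sigmoidv(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

static inline vec softmax2(const vec& a) {
  vec s = exp(a - a.max());
  return s / accu(s);
}

struct LayerCache {
  mat Z, F, I, G, O, C, TC; // per-time-step gate values
};

// Forward one sequence (X: D x T) through stacked LSTM layers.
// Returns final hidden state of the top layer; fills caches/hseq if given.
static vec lstm_forward_seq(const std::vector<mat>& W,
                            const std::vector<vec>& b,
                            const mat& X,
                            std::vector<LayerCache>* caches,
                            std::vector<mat>* hseq) {
  mat input = X;
  vec h;
  for (size_t l = 0; l < W.size(); ++l) {
    const int H = b[l].n_elem / 4;
    const int D = W[l].n_cols - H;
    const int T = input.n_cols;
    vec hprev(H, fill::zeros), c(H, fill::zeros);
    mat Hout(H, T);
    LayerCache cc;
    if (caches) {
      cc.Z.set_size(H + D, T); cc.F.set_size(H, T); cc.I.set_size(H, T);
      cc.G.set_size(H, T); cc.O.set_size(H, T); cc.C.set_size(H, T);
      cc.TC.set_size(H, T);
    }
    for (int t = 0; t < T; ++t) {
      vec z(H + D);
      z.head(H) = hprev;
      z.tail(D) = input.col(t);
      vec a = W[l] * z + b[l];
      vec f = sigmoidv(a.subvec(0, H - 1));
      vec i = sigmoidv(a.subvec(H, 2 * H - 1));
      vec g = tanh(a.subvec(2 * H, 3 * H - 1));
      vec o = sigmoidv(a.subvec(3 * H, 4 * H - 1));
      c = f % c + i % g;
      vec tc = tanh(c);
      hprev = o % tc;
      Hout.col(t) = hprev;
      if (caches) {
        cc.Z.col(t) = z; cc.F.col(t) = f; cc.I.col(t) = i; cc.G.col(t) = g;
        cc.O.col(t) = o; cc.C.col(t) = c; cc.TC.col(t) = tc;
      }
    }
    if (caches) caches->push_back(cc);
    if (hseq) hseq->push_back(Hout);
    input = Hout;
    h = hprev;
  }
  return h;
}

// BPTT through one LSTM layer. dHout: gradient w.r.t. the layer's outputs.
// Returns gradient w.r.t. the layer's inputs (D x T).
static mat lstm_backward_layer(const mat& W, const LayerCache& cc,
                               const mat& dHout, mat& dW, vec& db) {
  const int H = dHout.n_rows;
  const int T = dHout.n_cols;
  const int D = W.n_cols - H;
  mat dX(D, T, fill::zeros);
  vec dh(H, fill::zeros), dc(H, fill::zeros);
  vec da(4 * H);
  for (int t = T - 1; t >= 0; --t) {
    dh += dHout.col(t);
    vec o = cc.O.col(t), tc = cc.TC.col(t), f = cc.F.col(t);
    vec i = cc.I.col(t), g = cc.G.col(t);
    vec cprev = (t > 0) ? vec(cc.C.col(t - 1)) : vec(H, fill::zeros);
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec df = dc % cprev;
    vec di = dc % g;
    vec dg = dc % i;
    da.subvec(0, H - 1) = df % f % (1.0 - f);
    da.subvec(H, 2 * H - 1) = di % i % (1.0 - i);
    da.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dW += da * cc.Z.col(t).t();
    db += da;
    vec dz = W.t() * da;
    dh = dz.head(H);
    dX.col(t) = dz.tail(D);
    dc = dc % f;
  }
  return dX;
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<mat>& Ws, const std::vector<vec>& bs) {
    for (const auto& w : Ws) { mW.push_back(zeros(size(w)));
                               vW.push_back(zeros(size(w))); }
    for (const auto& b : bs) { mb.push_back(zeros(size(b)));
                               vb.push_back(zeros(size(b))); }
  }
  void step(std::vector<mat>& Ws, std::vector<vec>& bs,
            const std::vector<mat>& gW, const std::vector<vec>& gb,
            double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < Ws.size(); ++k) {
      mW[k] = b1 * mW[k] + (1 - b1) * gW[k];
      vW[k] = b2 * vW[k] + (1 - b2) * (gW[k] % gW[k]);
      Ws[k] -= lr * (mW[k] / c1) / (sqrt(vW[k] / c2) + eps);
    }
    for (size_t k = 0; k < bs.size(); ++k) {
      mb[k] = b1 * mb[k] + (1 - b1) * gb[k];
      vb[k] = b2 * vb[k] + (1 - b2) * (gb[k] % gb[k]);
      bs[k] -= lr * (mb[k] / c1) / (sqrt(vb[k] / c2) + eps);
    }
  }
};

static std::vector<mat> as_mat_list(Rcpp::List L) {
  std::vector<mat> out;
  for (int i = 0; i < L.size(); ++i) out.push_back(Rcpp::as<mat>(L[i]));
  return out;
}
static std::vector<vec> as_vec_list(Rcpp::List L) {
  std::vector<vec> out;
  for (int i = 0; i < L.size(); ++i) out.push_back(Rcpp::as<vec>(L[i]));
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_lstm_predict(Rcpp::List X, Rcpp::List Wl, Rcpp::List bl,
                           arma::mat Wd, arma::vec bd) {
  std::vector<mat> W = as_mat_list(Wl);
  std::vector<vec> b = as_vec_list(bl);
  mat probs(X.size(), 2);
  for (int n = 0; n < X.size(); ++n) {
    mat x = Rcpp::as<mat>(X[n]); // D x T
    vec h = lstm_forward_seq(W, b, x, nullptr, nullptr);
    probs.row(n) = softmax2(Wd * h + bd).t();
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(Rcpp::List X, Rcpp::IntegerVector y,
                          Rcpp::List W0, Rcpp::List b0,
                          arma::mat Wd, arma::vec bd,
                          int epochs, double lr, int batch, int seed) {
  std::vector<mat> W = as_mat_list(W0);
  std::vector<vec> b = as_vec_list(b0);
  const int N = X.size();
  const size_t L = W.size();
  std::vector<mat> seqs(N);
  for (int n = 0; n < N; ++n) seqs[n] = Rcpp::as<mat>(X[n]);

  // Adam over the layer parameters plus the dense head (appended last).
  std::vector<mat> allW = W; allW.push_back(Wd);
  std::vector<vec> allb = b; allb.push_back(bd);
  Adam opt;
  opt.init(allW, allb);

  std::mt19937 rng(seed);
  std::vector<int> idx(N);
  for (int n = 0; n < N; ++n) idx[n] = n;
  vec loss_hist(epochs, fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      int stop = std::min(start + batch, N);
      int bs = stop - start;
      std::vector<mat> gW(L + 1);
      std::vector<vec> gb(L + 1);
      for (size_t l = 0; l < L; ++l) {
        gW[l] = zeros(size(allW[l]));
        gb[l] = zeros(size(allb[l]));
      }
      gW[L] = zeros(size(allW[L]));
      gb[L] = zeros(size(allb[L]));
      for (int k = start; k < stop; ++k) {
        const mat& x = seqs[idx[k]];
        const int yk = y[idx[k]];
        std::vector<LayerCache> caches;
        std::vector<mat> hseq;
        vec h = lstm_forward_seq(W, b, x, &caches, &hseq);
        vec p = softmax2(allW[L] * h + allb[L]);
        ep_loss += -std::log(std::max(p(yk), 1e-12));
        vec dlog = p;
        dlog(yk) -= 1.0;
        gW[L] += dlog * h.t();
        gb[L] += dlog;
        // gradient on the top layer's output sequence: only the final step
        mat dH = zeros(h.n_elem, x.n_cols);
        dH.col(x.n_cols - 1) = allW[L].t() * dlog;
        for (int l = (int)L - 1; l >= 0; --l) {
          mat dX = lstm_backward_layer(W[l], caches[l], dH, gW[l], gb[l]);
          if (l > 0) dH = dX;
        }
      }
      for (size_t l = 0; l <= L; ++l) {
        gW[l] /= bs;
        gb[l] /= bs;
      }
      std::vector<mat> params(W);
      params.push_back(allW[L]);
      std::vector<vec> paramsb(b);
      paramsb.push_back(allb[L]);
      opt.step(params, paramsb, gW, gb, lr);
      for (size_t l = 0; l < L; ++l) { W[l] = params[l]; b[l] = paramsb[l]; }
      allW[L] = params[L];
      allb[L] = paramsb[L];
    }
    loss_hist(ep) = ep_loss / N;
  }
  Rcpp::List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("Wd") = allW[L],
                            Rcpp::Named("bd") = allb[L],
                            Rcpp::Named("loss") = loss_hist);
}

// ---- tap-delay RNN ----------------------------------------------------------

// h_t = tanh(Wx x_t + Wh h_{t-d} + b); h with non-positive index is zero.
static vec rnn_forward_seq(const mat& Wx, const mat& Wh, const vec& b,
                           const mat& X, int delay, mat* Hout) {
  const int H = b.n_elem;
  const int T = X.n_cols;
  mat Hs(H, T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = Wx * X.col(t) + b;
    if (t - delay >= 0) a += Wh * Hs.col(t - delay);
    Hs.col(t) = tanh(a);
  }
  if (Hout) *Hout = Hs;
  return Hs.col(T - 1);
}

// [[Rcpp::export]]
arma::mat cpp_rnn_predict(Rcpp::List X, arma::mat Wx, arma::mat Wh,
                          arma::vec b, arma::mat Wd, arma::vec bd,
                          int delay) {
  mat probs(X.size(), 2);
  for (int n = 0; n < X.size(); ++n) {
    mat x = Rcpp::as<mat>(X[n]);
    vec h = rnn_forward_seq(Wx, Wh, b, x, delay, nullptr);
    probs.row(n) = softmax2(Wd * h + bd).t();
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::List cpp_rnn_train(Rcpp::List X, Rcpp::IntegerVector y,
                         arma::mat Wx, arma::mat Wh, arma::vec b,
                         arma::mat Wd, arma::vec bd, int delay,
                         int epochs, double lr, int batch, int seed) {
  const int N = X.size();
  const int H = b.n_elem;
  std::vector<mat> seqs(N);
  for (int n = 0; n < N; ++n) seqs[n] = Rcpp::as<mat>(X[n]);

  std::vector<mat> Ws = {Wx, Wh, Wd};
  std::vector<vec> bs = {b, bd};
  Adam opt;
  opt.init(Ws, bs);

  std::mt19937 rng(seed);
  std::vector<int> idx(N);
  for (int n = 0; n < N; ++n) idx[n] = n;
  vec loss_hist(epochs, fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      int stop = std::min(start + batch, N);
      int bsz = stop - start;
      mat gWx = zeros(size(Ws[0])), gWh = zeros(size(Ws[1])),
          gWd = zeros(size(Ws[2]));
      vec gb = zeros(H), gbd = zeros(size(bs[1]));
      for (int k = start; k < stop; ++k) {
        const mat& x = seqs[idx[k]];
        const int yk = y[idx[k]];
        const int T = x.n_cols;
        mat Hs;
        vec h = rnn_forward_seq(Ws[0], Ws[1], bs[0], x, delay, &Hs);
        vec p = softmax2(Ws[2] * h + bs[1]);
        ep_loss += -std::log(std::max(p(yk), 1e-12));
        vec dlog = p;
        dlog(yk) -= 1.0;
        gWd += dlog * h.t();
        gbd += dlog;
        mat dH = zeros(H, T);
        dH.col(T - 1) = Ws[2].t() * dlog;
        for (int t = T - 1; t >= 0; --t) {
          vec ht = Hs.col(t);
          vec da = dH.col(t) % (1.0 - ht % ht);
          gWx += da * x.col(t).t();
          gb += da;
          if (t - delay >= 0) {
            gWh += da * Hs.col(t - delay).t();
            dH.col(t - delay) += Ws[1].t() * da;
          }
        }
      }
      gWx /= bsz; gWh /= bsz; gWd /= bsz; gb /= bsz; gbd /= bsz;
      std::vector<mat> gW = {gWx, gWh, gWd};
      std::vector<vec> gvb = {gb, gbd};
      opt.step(Ws, bs, gW, gvb, lr);
    }
    loss_hist(ep) = ep_loss / N;
  }
  return Rcpp::List::create(Rcpp::Named("Wx") = Ws[0],
                            Rcpp::Named("Wh") = Ws[1],
                            Rcpp::Named("b") = bs[0],
                            Rcpp::Named("Wd") = Ws[2],
                            Rcpp::Named("bd") = bs[1],
                            Rcpp::Named("loss") = loss_hist);
}
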