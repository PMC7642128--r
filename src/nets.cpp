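// Compact CNN and LSTM trainers for channel x time epochs.
//
// Both nets are small enough that a dependency-free implementation is
// practical: plain Armadillo matrix algebra, full backpropagation, Adam, and
// early stopping on a validation split. All stochastic choices (weight
// initialisation, minibatch order, validation split) are made in R from R's
// RNG and passed in, so a fixed seed gives bit-identical training runs.
//
// Layout conventions:
//   X: cube (channels x time x trials), already z-scored and decimated in R.
//   CNN: temporal conv (kernel k, F1 filters, linear) -> spatial conv across
//        all channels x temporal filters (F2 filters, linear) -> square ->
//        non-overlapping average pool (factor p) -> log -> dense softmax(2).
//   LSTM: single layer, H hidden units, channels as per-timestep features,
//        mean of hidden states over time -> dense softmax(2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double kLogEps = 1e-6;

// ---------------------------------------------------------------- Adam ----

struct Adam {
  std::vector<mat> m, v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const std::vector<mat*>& ws, double lr_) : lr(lr_) {
    for (auto w : ws) {
      m.emplace_back(size(*w), fill::zeros);
      v.emplace_back(size(*w), fill::zeros);
    }
  }
  void step(std::vector<mat*>& ws, const std::vector<mat>& gs) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < ws.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * gs[i];
      v[i] = b2 * v[i] + (1 - b2) * square(gs[i]);
      *ws[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

static inline vec softmax2(const vec& z) {
  vec s = z - z.max();
  vec e = exp(s);
  return e / accu(e);
}

// ----------------------------------------------------------------- CNN ----

struct CnnPars {
  mat W1;  // k x F1 temporal kernels
  vec b1;  // F1
  mat W2;  // F2 x (F1*C) spatial mixing
  vec b2;  // F2
  mat W3;  // 2 x (F2*T2) dense
  vec b3;  // 2
  int pool;
};

// temporal conv + stack: returns U ((F1*C) x T1), rows grouped filter-major.
static mat cnn_layer1(const mat& X, const CnnPars& p) {
  const int C = X.n_rows, T = X.n_cols, k = p.W1.n_rows, F1 = p.W1.n_cols;
  const int T1 = T - k + 1;
  mat U(F1 * C, T1);
  for (int f = 0; f < F1; ++f) {
    mat O(C, T1, fill::zeros);
    for (int j = 0; j < k; ++j)
      O += p.W1(j, f) * X.cols(j, j + T1 - 1);
    O += p.b1(f);
    U.rows(f * C, (f + 1) * C - 1) = O;
  }
  return U;
}

struct CnnFwd {
  mat U, O2, P, feat;  // feat = log(P + eps), flattened later
  vec prob;
};

static CnnFwd cnn_forward(const mat& X, const CnnPars& p) {
  CnnFwd f;
  f.U = cnn_layer1(X, p);
  f.O2 = p.W2 * f.U;
  f.O2.each_col() += p.b2;
  mat S = square(f.O2);
  const int T1 = S.n_cols, T2 = T1 / p.pool;
  f.P.set_size(S.n_rows, T2);
  for (int t = 0; t < T2; ++t)
    f.P.col(t) = mean(S.cols(t * p.pool, (t + 1) * p.pool - 1), 1);
  f.feat = log(f.P + kLogEps);
  vec z = p.W3 * vectorise(f.feat) + p.b3;
  f.prob = softmax2(z);
  return f;
}

struct CnnGrads {
  mat W1, W2, W3;
  vec b1, b2, b3;
  void zero(const CnnPars& p) {
    W1.zeros(size(p.W1)); W2.zeros(size(p.W2)); W3.zeros(size(p.W3));
    b1.zeros(size(p.b1)); b2.zeros(size(p.b2)); b3.zeros(size(p.b3));
  }
};

static double cnn_backward(const mat& X, int y, const CnnPars& p,
                           CnnGrads& g) {
  CnnFwd f = cnn_forward(X, p);
  double loss = -std::log(std::max(f.prob(y), 1e-12));
  vec dz = f.prob;
  dz(y) -= 1.0;
  g.W3 += dz * vectorise(f.feat).t();
  g.b3 += dz;
  mat dfeat(p.W3.t() * dz);
  dfeat.reshape(f.P.n_rows, f.P.n_cols);
  mat dP = dfeat / (f.P + kLogEps);
  const int T1 = f.O2.n_cols, T2 = f.P.n_cols;
  mat dS(f.P.n_rows, T1, fill::zeros);
  for (int t = 0; t < T2; ++t)
    dS.cols(t * p.pool, (t + 1) * p.pool - 1) =
        repmat(dP.col(t) / p.pool, 1, p.pool);
  mat dO2 = 2.0 * f.O2 % dS;
  g.W2 += dO2 * f.U.t();
  g.b2 += sum(dO2, 1);
  mat dU = p.W2.t() * dO2;
  const int C = X.n_rows, k = p.W1.n_rows, F1 = p.W1.n_cols;
  for (int fi = 0; fi < F1; ++fi) {
    mat dO1 = dU.rows(fi * C, (fi + 1) * C - 1);
    for (int j = 0; j < k; ++j)
      g.W1(j, fi) += accu(X.cols(j, j + T1 - 1) % dO1);
    g.b1(fi) += accu(dO1);
  }
  return loss;
}

static double cnn_mean_loss(const cube& X, const ivec& y, const CnnPars& p) {
  double s = 0;
  for (uword i = 0; i < X.n_slices; ++i)
    s += -std::log(std::max(cnn_forward(X.slice(i), p).prob(y(i)), 1e-12));
  return s / X.n_slices;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::cube& X, const arma::ivec& y,
                         const arma::cube& Xval, const arma::ivec& yval,
                         arma::mat W1, arma::vec b1, arma::mat W2,
                         arma::vec b2, arma::mat W3, arma::vec b3, int pool,
                         const arma::imat& batch_order, int batch_size,
                         double lr, int patience, int min_epochs) {
  CnnPars p{W1, b1, W2, b2, W3, b3, pool};
  // Adam treats biases as 1-column matrices
  mat B1(p.b1), B2(p.b2), B3(p.b3);
  std::vector<mat*> params{&p.W1, &p.W2, &p.W3, &B1, &B2, &B3};
  Adam opt(params, lr);
  const int max_epochs = batch_order.n_rows;
  const int n = X.n_slices;
  CnnPars best = p;
  double best_val = datum::inf;
  int best_epoch = 0, bad = 0, ran = 0;
  std::vector<double> tr_hist, val_hist;
  CnnGrads g;
  for (int ep = 0; ep < max_epochs; ++ep) {
    ++ran;
    double ep_loss = 0;
    int n_seen = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(s + batch_size, n);
      g.zero(p);
      double bl = 0;
      for (int i = s; i < e; ++i) {
        int idx = batch_order(ep, i);
        bl += cnn_backward(X.slice(idx), y(idx), p, g);
      }
      double bs = e - s;
      std::vector<mat> gs{g.W1 / bs, g.W2 / bs, g.W3 / bs,
                          mat(g.b1 / bs), mat(g.b2 / bs), mat(g.b3 / bs)};
      opt.step(params, gs);
      p.b1 = B1.col(0); p.b2 = B2.col(0); p.b3 = B3.col(0);
      ep_loss += bl;
      n_seen += e - s;
    }
    tr_hist.push_back(ep_loss / n_seen);
    double vl = cnn_mean_loss(Xval, yval, p);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-6) {
      best_val = vl;
      best = p;
      best_epoch = ep + 1;
      bad = 0;
    } else if (ep + 1 >= min_epochs && ++bad >= patience) {
      break;  // early stopping only arms after min_epochs
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("W1") = best.W1, Rcpp::Named("b1") = best.b1,
      Rcpp::Named("W2") = best.W2, Rcpp::Named("b2") = best.b2,
      Rcpp::Named("W3") = best.W3, Rcpp::Named("b3") = best.b3,
      Rcpp::Named("train_loss") = tr_hist, Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = ran);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::cube& X, const arma::mat& W1,
                          const arma::vec& b1, const arma::mat& W2,
                          const arma::vec& b2, const arma::mat& W3,
                          const arma::vec& b3, int pool) {
  CnnPars p{W1, b1, W2, b2, W3, b3, pool};
  mat out(X.n_slices, 2);
  for (uword i = 0; i < X.n_slices; ++i)
    out.row(i) = cnn_forward(X.slice(i), p).prob.t();
  return out;
}

// ---------------------------------------------------------------- LSTM ----

struct LstmPars {
  mat Wx;  // 4H x C
  mat Wh;  // 4H x H
  vec b;   // 4H   (gate order: i, f, g, o)
  mat Wo;  // 2 x H
  vec bo;  // 2
};

// forward over a batch; optionally keeps per-timestep state for BPTT.
struct LstmFwd {
  std::vector<mat> I, F, G, O, Cc, Tc, Hprev;  // each H x B, per timestep
  mat hmean;                                   // H x B
  mat prob;                                    // 2 x B
};

static LstmFwd lstm_forward(const cube& X, const uvec& idx,
                            const LstmPars& p, bool keep) {
  const int C = X.n_rows, T = X.n_cols, B = idx.n_elem;
  const int H = p.Wh.n_cols;
  LstmFwd f;
  if (keep) {
    f.I.resize(T); f.F.resize(T); f.G.resize(T); f.O.resize(T);
    f.Cc.resize(T); f.Tc.resize(T); f.Hprev.resize(T);
  }
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  mat hsum(H, B, fill::zeros);
  mat Xt(C, B);
  for (int t = 0; t < T; ++t) {
    for (int b = 0; b < B; ++b) Xt.col(b) = X.slice(idx(b)).col(t);
    mat A = p.Wx * Xt + p.Wh * h;
    A.each_col() += p.b;
    mat i = 1.0 / (1.0 + exp(-A.rows(0, H - 1)));
    mat fg = 1.0 / (1.0 + exp(-A.rows(H, 2 * H - 1)));
    mat g = tanh(A.rows(2 * H, 3 * H - 1));
    mat o = 1.0 / (1.0 + exp(-A.rows(3 * H, 4 * H - 1)));
    if (keep) f.Hprev[t] = h;
    c = fg % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    hsum += h;
    if (keep) {
      f.I[t] = i; f.F[t] = fg; f.G[t] = g; f.O[t] = o;
      f.Cc[t] = c; f.Tc[t] = tc;
    }
  }
  f.hmean = hsum / T;
  mat Z = p.Wo * f.hmean;
  Z.each_col() += p.bo;
  f.prob.set_size(2, B);
  for (int b = 0; b < B; ++b) f.prob.col(b) = softmax2(Z.col(b));
  return f;
}

static double lstm_mean_loss(const cube& X, const ivec& y,
                             const LstmPars& p) {
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  LstmFwd f = lstm_forward(X, idx, p, false);
  double s = 0;
  for (uword b = 0; b < idx.n_elem; ++b)
    s += -std::log(std::max(f.prob(y(b), b), 1e-12));
  return s / idx.n_elem;
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::cube& X, const arma::ivec& y,
                          const arma::cube& Xval, const arma::ivec& yval,
                          arma::mat Wx, arma::mat Wh, arma::vec b,
                          arma::mat Wo, arma::vec bo,
                          const arma::imat& batch_order, int batch_size,
                          double lr, int patience, int min_epochs) {
  LstmPars p{Wx, Wh, b, Wo, bo};
  mat Bg(p.b), Bo(p.bo);
  std::vector<mat*> params{&p.Wx, &p.Wh, &p.Wo, &Bg, &Bo};
  Adam opt(params, lr);
  const int max_epochs = batch_order.n_rows;
  const int n = X.n_slices, T = X.n_cols, H = p.Wh.n_cols, C = X.n_rows;
  LstmPars best = p;
  double best_val = datum::inf;
  int best_epoch = 0, bad = 0, ran = 0;
  std::vector<double> tr_hist, val_hist;
  for (int ep = 0; ep < max_epochs; ++ep) {
    ++ran;
    double ep_loss = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(s + batch_size, n);
      int B = e - s;
      uvec idx(B);
      ivec yb(B);
      for (int i = 0; i < B; ++i) {
        idx(i) = batch_order(ep, s + i);
        yb(i) = y(idx(i));
      }
      LstmFwd f = lstm_forward(X, idx, p, true);
      mat dZ = f.prob;
      for (int bix = 0; bix < B; ++bix) {
        ep_loss += -std::log(std::max(f.prob(yb(bix), bix), 1e-12));
        dZ(yb(bix), bix) -= 1.0;
      }
      dZ /= B;
      mat gWo = dZ * f.hmean.t();
      vec gbo = sum(dZ, 1);
      mat dhmean = p.Wo.t() * dZ;  // H x B
      mat gWx(size(p.Wx), fill::zeros), gWh(size(p.Wh), fill::zeros);
      vec gb(4 * H, fill::zeros);
      mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
      mat Xt(C, B);
      for (int t = T - 1; t >= 0; --t) {
        mat dh = dhmean / T + dh_next;
        mat dtc = dh % f.O[t];
        mat dc = dtc % (1.0 - square(f.Tc[t])) + dc_next;
        mat c_prev = (t == 0) ? mat(H, B, fill::zeros) : f.Cc[t - 1];
        mat di = dc % f.G[t] % f.I[t] % (1.0 - f.I[t]);
        mat df = dc % c_prev % f.F[t] % (1.0 - f.F[t]);
        mat dg = dc % f.I[t] % (1.0 - square(f.G[t]));
        mat do_ = dh % f.Tc[t] % f.O[t] % (1.0 - f.O[t]);
        mat dA = join_cols(di, df, dg, do_);  // 4H x B
        for (int bix = 0; bix < B; ++bix)
          Xt.col(bix) = X.slice(idx(bix)).col(t);
        gWx += dA * Xt.t();
        gWh += dA * f.Hprev[t].t();
        gb += sum(dA, 1);
        dh_next = p.Wh.t() * dA;
        dc_next = dc % f.F[t];
      }
      std::vector<mat> gs{gWx, gWh, gWo, mat(gb), mat(gbo)};
      opt.step(params, gs);
      p.b = Bg.col(0);
      p.bo = Bo.col(0);
    }
    tr_hist.push_back(ep_loss / n);
    double vl = lstm_mean_loss(Xval, yval, p);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-6) {
      best_val = vl;
      best = p;
      best_epoch = ep + 1;
      bad = 0;
    } else if (ep + 1 >= min_epochs && ++bad >= patience) {
      break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("Wx") = best.Wx, Rcpp::Named("Wh") = best.Wh,
      Rcpp::Named("b") = best.b, Rcpp::Named("Wo") = best.Wo,
      Rcpp::Named("bo") = best.bo,
      Rcpp::Named("train_loss") = tr_hist, Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = ran);
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(const arma::cube& X, const arma::mat& Wx,
                           const arma::mat& Wh, const arma::vec& b,
                           const arma::mat& Wo, const arma::vec& bo) {
  LstmPars p{Wx, Wh, b, Wo, bo};
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  LstmFwd f = lstm_forward(X, idx, p, false);
  return f.prob.t();
}
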