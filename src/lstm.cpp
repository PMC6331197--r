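// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Single-layer LSTM sequence classifier: one recurrent layer, dropout on its
// last-step output, a dense softmax head. Trained with Adam, global-norm
// gradient clipping and cross-entropy loss. All randomness (initialization,
// shuffling, dropout masks) is drawn from R's RNG so runs are reproducible
// under set.seed().
//
// Weight list layout: Wx (C x 4H), Wh (H x 4H), b (4H), Wy (H x K), by (K).
// Gate column blocks, in order: input, forget, cell candidate, output.

static arma::mat sigmoid(const arma::mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

struct Weights {
  arma::mat Wx, Wh, Wy;
  arma::rowvec b, by;
};

static Weights unpack(List W) {
  Weights w;
  w.Wx = as<arma::mat>(W["Wx"]);
  w.Wh = as<arma::mat>(W["Wh"]);
  w.b  = as<arma::rowvec>(W["b"]);
  w.Wy = as<arma::mat>(W["Wy"]);
  w.by = as<arma::rowvec>(W["by"]);
  return w;
}

static List pack(const Weights& w) {
  return List::create(_["Wx"] = w.Wx, _["Wh"] = w.Wh, _["b"] = w.b,
                      _["Wy"] = w.Wy, _["by"] = w.by);
}

static arma::mat glorot(int nr, int nc) {
  const double lim = std::sqrt(6.0 / (nr + nc));
  arma::mat m(nr, nc);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (2.0 * unif_rand() - 1.0) * lim;
  return m;
}

// random orthogonal H x H block via QR of a Gaussian matrix, sign-fixed for
// determinism
static arma::mat orthogonal(int n) {
  arma::mat A(n, n);
  for (arma::uword j = 0; j < A.n_cols; ++j)
    for (arma::uword i = 0; i < A.n_rows; ++i)
      A(i, j) = norm_rand();
  arma::mat Q, R;
  arma::qr_econ(Q, R, A);
  for (int j = 0; j < n; ++j)
    if (R(j, j) < 0) Q.col(j) *= -1.0;
  return Q;
}

// [[Rcpp::export(name = ".cpp_lstm_init")]]
List cpp_lstm_init(int input_dim, int hidden, int n_classes) {
  Weights w;
  w.Wx = glorot(input_dim, 4 * hidden);
  // orthogonal recurrent blocks, one per gate (standard recurrent init)
  w.Wh.set_size(hidden, 4 * hidden);
  for (int g = 0; g < 4; ++g)
    w.Wh.cols(g * hidden, (g + 1) * hidden - 1) = orthogonal(hidden);
  w.b  = arma::rowvec(4 * hidden, arma::fill::zeros);
  w.b.subvec(hidden, 2 * hidden - 1).fill(1.0);  // forget-gate bias
  w.Wy = glorot(hidden, n_classes);
  w.by = arma::rowvec(n_classes, arma::fill::zeros);
  return pack(w);
}

// Forward pass over a row subset; returns last hidden state (B x H).
// X has dimensions (n, T, C).
static arma::mat lstm_last_hidden(const Weights& w, const arma::cube& X,
                                  const arma::uvec& rows,
                                  arma::cube* gates, arma::cube* cs, arma::cube* hs) {
  const int B = rows.n_elem;
  const int T = X.n_cols;
  const int C = X.n_slices;
  const int H = w.Wh.n_rows;

  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  arma::mat Xt(B, C);
  for (int t = 0; t < T; ++t) {
    for (int ch = 0; ch < C; ++ch)
      for (int bi = 0; bi < B; ++bi)
        Xt(bi, ch) = X(rows[bi], t, ch);
    arma::mat Z = Xt * w.Wx + h * w.Wh;
    Z.each_row() += w.b;
    arma::mat gi = sigmoid(Z.cols(0, H - 1));
    arma::mat gf = sigmoid(Z.cols(H, 2 * H - 1));
    arma::mat gg = arma::tanh(Z.cols(2 * H, 3 * H - 1));
    arma::mat go = sigmoid(Z.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % arma::tanh(c);
    if (gates) {
      gates->slice(t).cols(0, H - 1) = gi;
      gates->slice(t).cols(H, 2 * H - 1) = gf;
      gates->slice(t).cols(2 * H, 3 * H - 1) = gg;
      gates->slice(t).cols(3 * H, 4 * H - 1) = go;
      cs->slice(t) = c;
      hs->slice(t) = h;
    }
  }
  return h;
}

static arma::mat softmax_rows(arma::mat logits) {
  logits.each_col() -= arma::max(logits, 1);
  arma::mat e = arma::exp(logits);
  e.each_col() /= arma::sum(e, 1);
  return e;
}

// [[Rcpp::export(name = ".cpp_lstm_forward")]]
arma::mat cpp_lstm_forward(List W, arma::cube X, int chunk = 512) {
  Weights w = unpack(W);
  const int n = X.n_rows;
  const int K = w.Wy.n_cols;
  arma::mat probs(n, K);
  for (int lo = 0; lo < n; lo += chunk) {
    const int hi = std::min(n, lo + chunk) - 1;
    arma::uvec rows = arma::regspace<arma::uvec>(lo, hi);
    arma::mat h = lstm_last_hidden(w, X, rows, nullptr, nullptr, nullptr);
    arma::mat logits = h * w.Wy;
    logits.each_row() += w.by;
    probs.rows(lo, hi) = softmax_rows(logits);
  }
  return probs;
}

struct Adam {
  arma::mat mWx, vWx, mWh, vWh, mWy, vWy;
  arma::rowvec mb, vb, mby, vby;
  long t = 0;
  void init(const Weights& w) {
    mWx.zeros(arma::size(w.Wx)); vWx.zeros(arma::size(w.Wx));
    mWh.zeros(arma::size(w.Wh)); vWh.zeros(arma::size(w.Wh));
    mWy.zeros(arma::size(w.Wy)); vWy.zeros(arma::size(w.Wy));
    mb.zeros(w.b.n_elem);  vb.zeros(w.b.n_elem);
    mby.zeros(w.by.n_elem); vby.zeros(w.by.n_elem);
  }
  template <typename M>
  void upd(M& p, const M& g, M& m, M& v, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double corr = lr * std::sqrt(1 - std::pow(b2, (double)t)) / (1 - std::pow(b1, (double)t));
    p -= corr * m / (arma::sqrt(v) + eps);
  }
};

// Training with BPTT. y is 0-based. Returns weights, per-epoch log and a
// status string ("ok", "diverged").
// [[Rcpp::export(name = ".cpp_lstm_train")]]
List cpp_lstm_train(arma::cube X, arma::ivec y, arma::cube Xval, arma::ivec yval,
                    arma::vec mids, arma::vec yval_pa, List W0,
                    double lr, int batch_size, int max_epochs, int patience,
                    int warmup, double clip_norm, double dropout_p) {
  Weights w = unpack(W0);
  const int n = X.n_rows;
  const int T = X.n_cols;
  const int C = X.n_slices;
  const int H = w.Wh.n_rows;
  const double keep = 1.0 - dropout_p;

  Adam opt;
  opt.init(w);

  std::vector<double> log_train, log_val, log_acc, log_mape;
  std::vector<double> log_gnorm, log_clipfrac;
  double best_val = R_PosInf;
  int since_best = 0;
  std::string status = "ok";
  int epoch = 0;

  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // shuffle by R-RNG keys
    arma::vec keys(n);
    for (int i = 0; i < n; ++i) keys[i] = unif_rand();
    arma::uvec perm = arma::sort_index(keys);

    double epoch_loss = 0.0;
    double epoch_gnorm = 0.0;
    int n_clipped = 0;
    int n_batches = 0;
    bool bad = false;

    for (int lo = 0; lo < n; lo += batch_size) {
      const int hi = std::min(n, lo + batch_size) - 1;
      arma::uvec rows = perm.subvec(lo, hi);
      const int B = rows.n_elem;

      arma::cube gates(B, 4 * H, T), cs(B, H, T), hs(B, H, T);
      arma::mat hT = lstm_last_hidden(w, X, rows, &gates, &cs, &hs);

      // inverted dropout on the recurrent output
      arma::mat mask(B, H);
      if (dropout_p > 0.0) {
        for (arma::uword j = 0; j < mask.n_cols; ++j)
          for (arma::uword i = 0; i < mask.n_rows; ++i)
            mask(i, j) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
      } else mask.ones();
      arma::mat hdrop = hT % mask;

      arma::mat logits = hdrop * w.Wy;
      logits.each_row() += w.by;
      arma::mat probs = softmax_rows(logits);

      double loss = 0.0;
      arma::mat dlogits = probs;
      for (int bi = 0; bi < B; ++bi) {
        const int cls = y[rows[bi]];
        loss -= std::log(std::max(probs(bi, cls), 1e-300));
        dlogits(bi, cls) -= 1.0;
      }
      loss /= B;
      dlogits /= B;
      if (!std::isfinite(loss)) { bad = true; break; }
      epoch_loss += loss;
      ++n_batches;

      // backward
      arma::mat dWy = hdrop.t() * dlogits;
      arma::rowvec dby = arma::sum(dlogits, 0);
      arma::mat dh = (dlogits * w.Wy.t()) % mask;
      arma::mat dc(B, H, arma::fill::zeros);
      arma::mat dWx(arma::size(w.Wx), arma::fill::zeros);
      arma::mat dWh(arma::size(w.Wh), arma::fill::zeros);
      arma::rowvec db(4 * H, arma::fill::zeros);
      arma::mat Xt(B, C);

      for (int t = T - 1; t >= 0; --t) {
        arma::mat gi = gates.slice(t).cols(0, H - 1);
        arma::mat gf = gates.slice(t).cols(H, 2 * H - 1);
        arma::mat gg = gates.slice(t).cols(2 * H, 3 * H - 1);
        arma::mat go = gates.slice(t).cols(3 * H, 4 * H - 1);
        arma::mat tc = arma::tanh(cs.slice(t));

        arma::mat do_ = dh % tc;
        dc += dh % go % (1.0 - tc % tc);
        arma::mat c_prev = (t > 0) ? cs.slice(t - 1) : arma::mat(B, H, arma::fill::zeros);
        arma::mat di = dc % gg;
        arma::mat df = dc % c_prev;
        arma::mat dg = dc % gi;

        arma::mat dZ(B, 4 * H);
        dZ.cols(0, H - 1)          = di % gi % (1.0 - gi);
        dZ.cols(H, 2 * H - 1)      = df % gf % (1.0 - gf);
        dZ.cols(2 * H, 3 * H - 1)  = dg % (1.0 - gg % gg);
        dZ.cols(3 * H, 4 * H - 1)  = do_ % go % (1.0 - go);

        for (int ch = 0; ch < C; ++ch)
          for (int bi = 0; bi < B; ++bi)
            Xt(bi, ch) = X(rows[bi], t, ch);
        arma::mat h_prev = (t > 0) ? hs.slice(t - 1) : arma::mat(B, H, arma::fill::zeros);

        dWx += Xt.t() * dZ;
        dWh += h_prev.t() * dZ;
        db  += arma::sum(dZ, 0);
        dh = dZ * w.Wh.t();
        dc = dc % gf;
      }

      // global-norm gradient clipping
      double sq = arma::accu(dWx % dWx) + arma::accu(dWh % dWh) +
                  arma::accu(dWy % dWy) + arma::dot(db, db) + arma::dot(dby, dby);
      double gn = std::sqrt(sq);
      epoch_gnorm += gn;
      if (clip_norm > 0.0 && gn > clip_norm) {
        ++n_clipped;
        const double sc = clip_norm / gn;
        dWx *= sc; dWh *= sc; dWy *= sc; db *= sc; dby *= sc;
      }

      ++opt.t;
      opt.upd(w.Wx, dWx, opt.mWx, opt.vWx, lr);
      opt.upd(w.Wh, dWh, opt.mWh, opt.vWh, lr);
      opt.upd(w.Wy, dWy, opt.mWy, opt.vWy, lr);
      opt.upd(w.b, db, opt.mb, opt.vb, lr);
      opt.upd(w.by, dby, opt.mby, opt.vby, lr);
    }

    if (bad) { status = "diverged"; break; }
    epoch_loss /= std::max(n_batches, 1);

    // validation pass (dropout off)
    arma::mat vp = cpp_lstm_forward(pack(w), Xval, 512);
    double vloss = 0.0, vacc = 0.0, vmape = 0.0;
    const int nv = Xval.n_rows;
    for (int i = 0; i < nv; ++i) {
      vloss -= std::log(std::max(vp(i, yval[i]), 1e-300));
      arma::uword am = arma::index_max(vp.row(i));
      if ((int)am == yval[i]) vacc += 1.0;
      vmape += std::fabs(mids[am] - yval_pa[i]) / yval_pa[i];
    }
    vloss /= nv; vacc /= nv; vmape = 100.0 * vmape / nv;

    log_train.push_back(epoch_loss);
    log_val.push_back(vloss);
    log_acc.push_back(vacc);
    log_mape.push_back(vmape);
    log_gnorm.push_back(epoch_gnorm / std::max(n_batches, 1));
    log_clipfrac.push_back((double)n_clipped / std::max(n_batches, 1));

    if (vloss < best_val) { best_val = vloss; since_best = 0; }
    else ++since_best;
    if (epoch + 1 > warmup && since_best >= patience) { ++epoch; break; }

    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["weights"] = pack(w),
    _["train_loss"] = wrap(log_train),
    _["val_loss"] = wrap(log_val),
    _["val_acc"] = wrap(log_acc),
    _["val_mape"] = wrap(log_mape),
    _["grad_norm"] = wrap(log_gnorm),
    _["clip_frac"] = wrap(log_clipfrac),
    _["epochs_run"] = (int)log_train.size(),
    _["status"] = status);
}
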