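// Bidirectional LSTM sequence labeler: forward pass, cross-entropy loss and
// backprop-through-time gradients. The network maps a univariate normalized
// signal (one value per 1-Hz sample) through a biLSTM (H cells per
// direction), a per-sample fully connected layer to 3 class scores and a
// softmax. Gate layout in the stacked weight matrices is [input; forget;
// cell-candidate; output], each block of H rows.
//
// Shapes: X is T x B (T samples per window, B windows per batch);
// Wx* are 4H x 1, Wh* are 4H x H, b* length 4H; Wy is 3 x 2H (forward
// hidden states first), by length 3. Targets Y are T x B integers in
// {1 = start, 2 = measurement, 3 = na}; 0 marks padded samples excluded
// from the loss.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat sigmoid_mat(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache {
  cube i, f, g, o, c, tc, h; // each H x B x T, indexed by time t
};

static void lstm_forward(const mat& X, const mat& Wx, const mat& Wh,
                         const vec& b, bool reverse, DirCache& cache) {
  const int T = X.n_rows, B = X.n_cols;
  const int H = Wh.n_cols;
  cache.i.set_size(H, B, T); cache.f.set_size(H, B, T);
  cache.g.set_size(H, B, T); cache.o.set_size(H, B, T);
  cache.c.set_size(H, B, T); cache.tc.set_size(H, B, T);
  cache.h.set_size(H, B, T);
  mat hprev(H, B, fill::zeros), cprev(H, B, fill::zeros);
  for (int step = 0; step < T; ++step) {
    const int t = reverse ? (T - 1 - step) : step;
    mat a = Wx * X.row(t) + Wh * hprev; // 4H x B
    a.each_col() += b;
    mat ig = sigmoid_mat(a.rows(0, H - 1));
    mat fg = sigmoid_mat(a.rows(H, 2 * H - 1));
    mat gg = tanh(a.rows(2 * H, 3 * H - 1));
    mat og = sigmoid_mat(a.rows(3 * H, 4 * H - 1));
    mat cc = fg % cprev + ig % gg;
    mat tc = tanh(cc);
    mat hh = og % tc;
    cache.i.slice(t) = ig; cache.f.slice(t) = fg; cache.g.slice(t) = gg;
    cache.o.slice(t) = og; cache.c.slice(t) = cc; cache.tc.slice(t) = tc;
    cache.h.slice(t) = hh;
    hprev = hh; cprev = cc;
  }
}

static void lstm_backward(const mat& X, const mat& Wh, bool reverse,
                          const DirCache& cache, const cube& dH,
                          mat& dWx, mat& dWh, vec& db) {
  const int T = X.n_rows, B = X.n_cols;
  const int H = Wh.n_cols;
  dWx.zeros(4 * H, 1); dWh.zeros(4 * H, H); db.zeros(4 * H);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    const int t = reverse ? (T - 1 - step) : step;
    mat hprev(H, B, fill::zeros), cprev(H, B, fill::zeros);
    if (step > 0) {
      const int tprev = reverse ? t + 1 : t - 1;
      hprev = cache.h.slice(tprev);
      cprev = cache.c.slice(tprev);
    }
    mat dh = dH.slice(t) + dh_next;
    const mat& ig = cache.i.slice(t);
    const mat& fg = cache.f.slice(t);
    const mat& gg = cache.g.slice(t);
    const mat& og = cache.o.slice(t);
    const mat& tc = cache.tc.slice(t);
    mat do_ = dh % tc;
    mat dc = dh % og % (1.0 - tc % tc) + dc_next;
    mat di = dc % gg;
    mat dg = dc % ig;
    mat df = dc % cprev;
    dc_next = dc % fg;
    mat da(4 * H, B);
    da.rows(0, H - 1)         = di % ig % (1.0 - ig);
    da.rows(H, 2 * H - 1)     = df % fg % (1.0 - fg);
    da.rows(2 * H, 3 * H - 1) = dg % (1.0 - gg % gg);
    da.rows(3 * H, 4 * H - 1) = do_ % og % (1.0 - og);
    dWx += da * X.row(t).t();
    dWh += da * hprev.t();
    db += sum(da, 1);
    dh_next = Wh.t() * da;
  }
}

// [[Rcpp::export(name = ".bilstm_loss_grad")]]
List bilstm_loss_grad(List params, const arma::mat& X, const arma::imat& Y) {
  mat Wxf = params["Wxf"], Whf = params["Whf"];
  vec bf = params["bf"];
  mat Wxb = params["Wxb"], Whb = params["Whb"];
  vec bb = params["bb"];
  mat Wy = params["Wy"];
  vec by = params["by"];
  const int T = X.n_rows, B = X.n_cols;
  const int H = Whf.n_cols;

  DirCache cf, cb;
  lstm_forward(X, Wxf, Whf, bf, false, cf);
  lstm_forward(X, Wxb, Whb, bb, true, cb);

  mat Wyf = Wy.cols(0, H - 1), Wyb = Wy.cols(H, 2 * H - 1);
  int n_obs = 0;
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < B; ++k)
      if (Y(t, k) > 0) ++n_obs;
  const double scale = n_obs > 0 ? 1.0 / n_obs : 0.0;

  double loss = 0.0;
  cube dHf(H, B, T, fill::zeros), dHb(H, B, T, fill::zeros);
  mat dWy(3, 2 * H, fill::zeros);
  vec dby(3, fill::zeros);

  for (int t = 0; t < T; ++t) {
    mat logits = Wyf * cf.h.slice(t) + Wyb * cb.h.slice(t); // 3 x B
    logits.each_col() += by;
    logits.each_row() -= max(logits, 0);
    mat P = exp(logits);
    P.each_row() /= sum(P, 0);
    mat dlog(3, B, fill::zeros);
    for (int k = 0; k < B; ++k) {
      const int y = Y(t, k);
      if (y > 0) {
        loss -= std::log(std::max(P(y - 1, k), 1e-300)) * scale;
        dlog.col(k) = P.col(k) * scale;
        dlog(y - 1, k) -= scale;
      }
    }
    dWy.cols(0, H - 1)     += dlog * cf.h.slice(t).t();
    dWy.cols(H, 2 * H - 1) += dlog * cb.h.slice(t).t();
    dby += sum(dlog, 1);
    dHf.slice(t) = Wyf.t() * dlog;
    dHb.slice(t) = Wyb.t() * dlog;
  }

  mat dWxf, dWhf; vec dbf;
  lstm_backward(X, Whf, false, cf, dHf, dWxf, dWhf, dbf);
  mat dWxb, dWhb; vec dbb;
  lstm_backward(X, Whb, true, cb, dHb, dWxb, dWhb, dbb);

  return List::create(
    _["loss"] = loss,
    _["grads"] = List::create(
      _["Wxf"] = dWxf, _["Whf"] = dWhf, _["bf"] = dbf,
      _["Wxb"] = dWxb, _["Whb"] = dWhb, _["bb"] = dbb,
      _["Wy"] = dWy, _["by"] = dby));
}

// [[Rcpp::export(name = ".bilstm_probs")]]
arma::cube bilstm_probs(List params, const arma::mat& X) {
  mat Wxf = params["Wxf"], Whf = params["Whf"];
  vec bf = params["bf"];
  mat Wxb = params["Wxb"], Whb = params["Whb"];
  vec bb = params["bb"];
  mat Wy = params["Wy"];
  vec by = params["by"];
  const int T = X.n_rows, B = X.n_cols;
  const int H = Whf.n_cols;

  DirCache cf, cb;
  lstm_forward(X, Wxf, Whf, bf, false, cf);
  lstm_forward(X, Wxb, Whb, bb, true, cb);
  mat Wyf = Wy.cols(0, H - 1), Wyb = Wy.cols(H, 2 * H - 1);

  cube P(3, B, T);
  for (int t = 0; t < T; ++t) {
    mat logits = Wyf * cf.h.slice(t) + Wyb * cb.h.slice(t);
    logits.each_col() += by;
    logits.each_row() -= max(logits, 0);
    mat e = exp(logits);
    e.each_row() /= sum(e, 0);
    P.slice(t) = e;
  }
  return P;
}
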