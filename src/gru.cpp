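// Batched fused GRU forward / backward passes.
//
// The cell: reset and update gates and a
// candidate state (motion feedback as an extra input column at history
// steps), with the hidden-state update
//   h = u % h_prev + htilde - u % htilde + b_h
// where the trailing bias is dropped when standard_gru is set.  Windows
// are processed as rows of the batch; the initial hidden state is zero.
// Forward caches stay on the C++ side behind an external pointer, so the
// backward pass never marshals intermediates through R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat get_mat(const List& w, const char* nm) {
  return as<arma::mat>(w[nm]);
}
static arma::vec get_vec(const List& w, const char* nm) {
  return as<arma::vec>(w[nm]);
}

struct Fused {
  arma::mat Wh;      // 3H x H
  arma::mat Wxq;     // 3H x (n_in + 1)
  arma::vec bias;    // 3H
  arma::vec b_h;     // H
  arma::rowvec W_hq; // 1 x H
  double b_q;
  bool std_gru;
  arma::uword H, n_in;
};

static Fused fuse(const List& w, bool std_gru) {
  Fused f;
  arma::mat W_hr = get_mat(w, "W_hr");
  f.H = W_hr.n_rows;
  f.Wh = arma::join_cols(W_hr, get_mat(w, "W_hu"), get_mat(w, "W_hht"));
  arma::mat Wx = arma::join_cols(get_mat(w, "W_xr"), get_mat(w, "W_xu"),
                                 get_mat(w, "W_xht"));
  arma::mat Wq = arma::join_cols(get_mat(w, "W_qr"), get_mat(w, "W_qu"),
                                 get_mat(w, "W_qht"));
  f.n_in = Wx.n_cols;
  f.Wxq = arma::join_rows(Wx, Wq);
  f.bias = arma::join_cols(get_vec(w, "b_r"), get_vec(w, "b_u"),
                           get_vec(w, "b_ht"));
  f.b_h = get_vec(w, "b_h");
  f.W_hq = as<arma::rowvec>(w["W_hq"]);
  f.b_q = as<double>(w["b_q"]);
  f.std_gru = std_gru;
  return f;
}

struct GruCache {
  std::vector<arma::mat> Hp, XQ, r, u, k, ht;
  std::vector<bool> hist;
  arma::mat h_last;
};

// [[Rcpp::export(name = ".gru_seq_forward_cpp")]]
List gru_seq_forward_cpp(List Xs, List Qs, List w, bool standard_gru) {
  const int m = Qs.size();
  Fused f = fuse(w, standard_gru);
  const arma::uword H = f.H;
  XPtr<GruCache> cache(new GruCache(), true);

  arma::mat Hp;
  for (int s = 0; s <= m; ++s) {
    bool hist = s < m;
    arma::mat XQ = as<arma::mat>(Xs[s]);
    if (hist) XQ = arma::join_rows(XQ, as<arma::mat>(Qs[s]));
    const arma::uword N = XQ.n_rows;
    arma::mat W = hist ? f.Wxq : arma::mat(f.Wxq.cols(0, f.n_in - 1));
    arma::mat S = XQ * W.t();
    S.each_row() += f.bias.t();
    arma::mat r, u, k, ht, h;
    if (s == 0) {
      r = 1.0 / (1.0 + arma::exp(-S.cols(0, H - 1)));
      u = 1.0 / (1.0 + arma::exp(-S.cols(H, 2 * H - 1)));
      k.zeros(N, H);
      ht = arma::tanh(S.cols(2 * H, 3 * H - 1));
      h = ht - u % ht;
    } else {
      arma::mat Fh = Hp * f.Wh.t();
      r = 1.0 / (1.0 + arma::exp(-(Fh.cols(0, H - 1) + S.cols(0, H - 1))));
      u = 1.0 / (1.0 + arma::exp(-(Fh.cols(H, 2 * H - 1) +
                                   S.cols(H, 2 * H - 1))));
      k = Fh.cols(2 * H, 3 * H - 1);
      ht = arma::tanh(r % k + S.cols(2 * H, 3 * H - 1));
      h = u % Hp + ht - u % ht;
    }
    if (!f.std_gru) h.each_row() += f.b_h.t();
    cache->Hp.push_back(Hp);
    cache->XQ.push_back(std::move(XQ));
    cache->r.push_back(std::move(r));
    cache->u.push_back(std::move(u));
    cache->k.push_back(std::move(k));
    cache->ht.push_back(std::move(ht));
    cache->hist.push_back(hist);
    Hp = std::move(h);
  }
  cache->h_last = Hp;
  arma::vec qhat = Hp * f.W_hq.t() + f.b_q;
  return List::create(_["qhat"] = NumericVector(qhat.begin(), qhat.end()),
                      _["h"] = Hp, _["handle"] = cache);
}

// shared reverse pass: accumulates into the caller's gradient buffers
static void backward_accum(const arma::vec& dqhat, GruCache* cache,
                           const Fused& f, arma::mat& gWh, arma::mat& gWxq,
                           arma::vec& gbias, arma::vec& gb_h,
                           arma::rowvec& gW_hq, double& gb_q) {
  const arma::uword n_in = f.n_in;
  gW_hq += dqhat.t() * cache->h_last;
  gb_q += arma::accu(dqhat);
  arma::mat dh = dqhat * f.W_hq;   // N x H
  for (int s = (int)cache->r.size() - 1; s >= 0; --s) {
    const arma::mat& r = cache->r[s];
    const arma::mat& u = cache->u[s];
    const arma::mat& k = cache->k[s];
    const arma::mat& ht = cache->ht[s];
    const arma::mat& Hp = cache->Hp[s];
    const arma::mat& XQ = cache->XQ[s];
    if (!f.std_gru) gb_h += arma::sum(dh, 0).t();
    bool zeroH = (s == 0);
    arma::mat du = zeroH ? arma::mat(dh % (-ht)) : arma::mat(dh % (Hp - ht));
    arma::mat dpre_c = (dh % (1.0 - u)) % (1.0 - ht % ht);
    arma::mat dk = dpre_c % r;
    arma::mat dpre_r = (dpre_c % k) % (r % (1.0 - r));
    arma::mat dpre_u = du % (u % (1.0 - u));
    arma::mat dS = arma::join_rows(dpre_r, dpre_u, dpre_c);
    if (cache->hist[s]) {
      gWxq += dS.t() * XQ;
    } else {
      gWxq.cols(0, n_in - 1) += dS.t() * XQ;
    }
    gbias += arma::sum(dS, 0).t();
    if (zeroH) break;
    arma::mat dFh = arma::join_rows(dpre_r, dpre_u, dk);
    gWh += dFh.t() * Hp;
    dh = dh % u + dFh * f.Wh;
  }
}

// [[Rcpp::export(name = ".gru_seq_backward_cpp")]]
List gru_seq_backward_cpp(arma::vec dqhat, SEXP handle, List w,
                          bool standard_gru) {
  Fused f = fuse(w, standard_gru);
  const arma::uword H = f.H, n_in = f.n_in;
  XPtr<GruCache> cache(handle);

  arma::mat gWh(3 * H, H, arma::fill::zeros);
  arma::mat gWxq(3 * H, n_in + 1, arma::fill::zeros);
  arma::vec gbias(3 * H, arma::fill::zeros);
  arma::vec gb_h(H, arma::fill::zeros);
  arma::rowvec gW_hq(H, arma::fill::zeros);
  double gb_q = 0.0;
  backward_accum(dqhat, cache.get(), f, gWh, gWxq, gbias, gb_h,
                 gW_hq, gb_q);

  return List::create(
    _["W_hr"] = gWh.rows(0, H - 1), _["W_hu"] = gWh.rows(H, 2 * H - 1),
    _["W_hht"] = gWh.rows(2 * H, 3 * H - 1),
    _["W_xr"] = gWxq.submat(0, 0, H - 1, n_in - 1),
    _["W_xu"] = gWxq.submat(H, 0, 2 * H - 1, n_in - 1),
    _["W_xht"] = gWxq.submat(2 * H, 0, 3 * H - 1, n_in - 1),
    _["W_qr"] = gWxq.submat(0, n_in, H - 1, n_in),
    _["W_qu"] = gWxq.submat(H, n_in, 2 * H - 1, n_in),
    _["W_qht"] = gWxq.submat(2 * H, n_in, 3 * H - 1, n_in),
    _["W_hq"] = gW_hq,
    _["b_r"] = NumericVector(gbias.begin(), gbias.begin() + H),
    _["b_u"] = NumericVector(gbias.begin() + H, gbias.begin() + 2 * H),
    _["b_ht"] = NumericVector(gbias.begin() + 2 * H, gbias.begin() + 3 * H),
    _["b_h"] = NumericVector(gb_h.begin(), gb_h.end()), _["b_q"] = gb_q);
}

// two teacher-forcing passes (noise-augmented data pass and clean
// residual pass) backpropagated in one call with summed gradients
// [[Rcpp::export(name = ".gru_seq_backward2_cpp")]]
List gru_seq_backward2_cpp(arma::vec dq_a, SEXP handle_a,
                           arma::vec dq_b, SEXP handle_b,
                           List w, bool standard_gru) {
  Fused f = fuse(w, standard_gru);
  const arma::uword H = f.H, n_in = f.n_in;
  XPtr<GruCache> ca(handle_a), cb(handle_b);

  arma::mat gWh(3 * H, H, arma::fill::zeros);
  arma::mat gWxq(3 * H, n_in + 1, arma::fill::zeros);
  arma::vec gbias(3 * H, arma::fill::zeros);
  arma::vec gb_h(H, arma::fill::zeros);
  arma::rowvec gW_hq(H, arma::fill::zeros);
  double gb_q = 0.0;
  backward_accum(dq_a, ca.get(), f, gWh, gWxq, gbias, gb_h, gW_hq, gb_q);
  backward_accum(dq_b, cb.get(), f, gWh, gWxq, gbias, gb_h, gW_hq, gb_q);

  return List::create(
    _["W_hr"] = gWh.rows(0, H - 1), _["W_hu"] = gWh.rows(H, 2 * H - 1),
    _["W_hht"] = gWh.rows(2 * H, 3 * H - 1),
    _["W_xr"] = gWxq.submat(0, 0, H - 1, n_in - 1),
    _["W_xu"] = gWxq.submat(H, 0, 2 * H - 1, n_in - 1),
    _["W_xht"] = gWxq.submat(2 * H, 0, 3 * H - 1, n_in - 1),
    _["W_qr"] = gWxq.submat(0, n_in, H - 1, n_in),
    _["W_qu"] = gWxq.submat(H, n_in, 2 * H - 1, n_in),
    _["W_qht"] = gWxq.submat(2 * H, n_in, 3 * H - 1, n_in),
    _["W_hq"] = gW_hq,
    _["b_r"] = NumericVector(gbias.begin(), gbias.begin() + H),
    _["b_u"] = NumericVector(gbias.begin() + H, gbias.begin() + 2 * H),
    _["b_ht"] = NumericVector(gbias.begin() + 2 * H, gbias.begin() + 3 * H),
    _["b_h"] = NumericVector(gb_h.begin(), gb_h.end()), _["b_q"] = gb_q);
}

// final-step gate values, needed by the closed-form time-derivative path
// [[Rcpp::export(name = ".gru_last_cache_cpp")]]
List gru_last_cache_cpp(SEXP handle) {
  XPtr<GruCache> cache(handle);
  size_t s = cache->r.size() - 1;
  return List::create(_["Hp"] = cache->Hp[s], _["r"] = cache->r[s],
                      _["u"] = cache->u[s], _["k"] = cache->k[s],
                      _["ht"] = cache->ht[s]);
}

// ---- current-step time-jet: first/second derivatives of the output with
// respect to the (standardized) current-step time input, plus the full
// reverse pass of (qhat, qhat_t, qhat_tt) through the jet and the history
// steps.  Jet intermediates are recomputed in the backward pass from the
// cached primal gate values.

static void jet_values(const Fused& f, const GruCache* cache,
                       arma::mat& h1, arma::mat& h2) {
  size_t s = cache->r.size() - 1;
  const arma::mat& Hp = cache->Hp[s];
  const arma::mat& r = cache->r[s];
  const arma::mat& u = cache->u[s];
  const arma::mat& k = cache->k[s];
  const arma::mat& ht = cache->ht[s];
  arma::rowvec er = f.Wxq.submat(0, 0, f.H - 1, 0).t();
  arma::rowvec eu = f.Wxq.submat(f.H, 0, 2 * f.H - 1, 0).t();
  arma::rowvec ec = f.Wxq.submat(2 * f.H, 0, 3 * f.H - 1, 0).t();
  arma::mat sr = r % (1.0 - r), su = u % (1.0 - u);
  arma::mat r1 = sr;  r1.each_row() %= er;
  arma::mat r2 = sr % (1.0 - 2.0 * r); r2.each_row() %= (er % er);
  arma::mat u1 = su;  u1.each_row() %= eu;
  arma::mat u2 = su % (1.0 - 2.0 * u); u2.each_row() %= (eu % eu);
  arma::mat pc1 = r1 % k; pc1.each_row() += ec;
  arma::mat pc2 = r2 % k;
  arma::mat one = 1.0 - ht % ht;
  arma::mat ht1 = one % pc1;
  arma::mat ht2 = -2.0 * ht % one % (pc1 % pc1) + one % pc2;
  h1 = u1 % (Hp - ht) + (1.0 - u) % ht1;
  h2 = u2 % (Hp - ht) - 2.0 * u1 % ht1 + (1.0 - u) % ht2;
}

// [[Rcpp::export(name = ".gru_jet_cpp")]]
List gru_jet_cpp(SEXP handle, List w, bool standard_gru) {
  Fused f = fuse(w, standard_gru);
  XPtr<GruCache> cache(handle);
  arma::mat h1, h2;
  jet_values(f, cache.get(), h1, h2);
  arma::vec q1 = h1 * f.W_hq.t();
  arma::vec q2 = h2 * f.W_hq.t();
  return List::create(_["d1"] = NumericVector(q1.begin(), q1.end()),
                      _["d2"] = NumericVector(q2.begin(), q2.end()));
}

// [[Rcpp::export(name = ".gru_seq_backward_jet_cpp")]]
List gru_seq_backward_jet_cpp(arma::vec dq, arma::vec dq1, arma::vec dq2,
                              SEXP handle, List w, bool standard_gru) {
  Fused f = fuse(w, standard_gru);
  const arma::uword H = f.H, n_in = f.n_in;
  XPtr<GruCache> cache(handle);
  size_t last = cache->r.size() - 1;

  arma::mat gWh(3 * H, H, arma::fill::zeros);
  arma::mat gWxq(3 * H, n_in + 1, arma::fill::zeros);
  arma::vec gbias(3 * H, arma::fill::zeros);
  arma::vec gb_h(H, arma::fill::zeros);

  // ---- current step with jet ----
  const arma::mat& Hp = cache->Hp[last];
  const arma::mat& XQ = cache->XQ[last];   // X only (no motion column)
  const arma::mat& r = cache->r[last];
  const arma::mat& u = cache->u[last];
  const arma::mat& k = cache->k[last];
  const arma::mat& ht = cache->ht[last];
  arma::rowvec er = f.Wxq.submat(0, 0, H - 1, 0).t();
  arma::rowvec eu = f.Wxq.submat(H, 0, 2 * H - 1, 0).t();
  arma::rowvec ec = f.Wxq.submat(2 * H, 0, 3 * H - 1, 0).t();
  arma::mat sr = r % (1.0 - r), su = u % (1.0 - u);
  arma::mat r1 = sr;  r1.each_row() %= er;
  arma::mat fr2 = sr % (1.0 - 2.0 * r);         // f2(r)
  arma::mat r2 = fr2; r2.each_row() %= (er % er);
  arma::mat u1 = su;  u1.each_row() %= eu;
  arma::mat fu2 = su % (1.0 - 2.0 * u);
  arma::mat u2 = fu2; u2.each_row() %= (eu % eu);
  arma::mat pc1 = r1 % k; pc1.each_row() += ec;
  arma::mat pc2 = r2 % k;
  arma::mat one = 1.0 - ht % ht;
  arma::mat ht1 = one % pc1;
  arma::mat ht2 = -2.0 * ht % one % (pc1 % pc1) + one % pc2;
  arma::mat h1 = u1 % (Hp - ht) + (1.0 - u) % ht1;
  arma::mat h2 = u2 % (Hp - ht) - 2.0 * u1 % ht1 + (1.0 - u) % ht2;

  arma::rowvec gW_hq = dq.t() * cache->h_last + dq1.t() * h1 + dq2.t() * h2;
  double gb_q = arma::accu(dq);
  arma::mat gh = dq * f.W_hq;
  arma::mat gh1 = dq1 * f.W_hq;
  arma::mat gh2 = dq2 * f.W_hq;

  arma::mat aHp(Hp.n_rows, H, arma::fill::zeros);
  arma::mat aht(Hp.n_rows, H, arma::fill::zeros);
  arma::mat au(Hp.n_rows, H, arma::fill::zeros);
  arma::mat aht1(Hp.n_rows, H, arma::fill::zeros);
  arma::mat aht2, apc1(Hp.n_rows, H, arma::fill::zeros), apc2;
  arma::mat au1(Hp.n_rows, H, arma::fill::zeros), au2;
  arma::mat HpMht = Hp - ht;

  // h2
  au2 = gh2 % HpMht;
  aHp += gh2 % u2;
  aht -= gh2 % u2;
  au1 -= 2.0 * gh2 % ht1;
  aht1 -= 2.0 * gh2 % u1;
  au -= gh2 % ht2;
  aht2 = gh2 % (1.0 - u);
  // h1
  au1 += gh1 % HpMht;
  aHp += gh1 % u1;
  aht -= gh1 % u1;
  au -= gh1 % ht1;
  aht1 += gh1 % (1.0 - u);
  // h
  au += gh % HpMht;
  aHp += gh % u;
  aht += gh % (1.0 - u);
  if (!f.std_gru) gb_h += arma::sum(gh, 0).t();
  // ht2 = -2 T one P^2 + one pc2
  aht += aht2 % ((-2.0 + 6.0 * ht % ht) % (pc1 % pc1) - 2.0 * ht % pc2);
  apc1 += aht2 % (-4.0 * ht % one % pc1);
  apc2 = aht2 % one;
  // ht1 = one pc1
  aht += aht1 % (-2.0 * ht % pc1);
  apc1 += aht1 % one;
  // ht = tanh(pc)
  arma::mat apc = aht % one;
  // pc = r k + S3 ; pc2 = r2 k ; pc1 = r1 k + ec
  arma::mat ar = apc % k;
  arma::mat ak = apc % r + apc2 % r2 + apc1 % r1;
  arma::mat aS3 = apc;
  arma::mat ar2 = apc2 % k;
  arma::mat ar1 = apc1 % k;
  arma::rowvec g_ec = arma::sum(apc1, 0);
  // r2 = f2(r) er^2 ; r1 = sr er
  arma::mat t2 = ar2 % (1.0 - 6.0 * r + 6.0 * r % r);
  t2.each_row() %= (er % er);
  ar += t2;
  arma::mat t1 = ar1 % (1.0 - 2.0 * r);
  t1.each_row() %= er;
  ar += t1;
  arma::rowvec g_er = arma::sum(ar2 % fr2, 0) % (2.0 * er) +
    arma::sum(ar1 % sr, 0);
  // u2, u1
  arma::mat s2 = au2 % (1.0 - 6.0 * u + 6.0 * u % u);
  s2.each_row() %= (eu % eu);
  au += s2;
  arma::mat s1 = au1 % (1.0 - 2.0 * u);
  s1.each_row() %= eu;
  au += s1;
  arma::rowvec g_eu = arma::sum(au2 % fu2, 0) % (2.0 * eu) +
    arma::sum(au1 % su, 0);
  // gates
  arma::mat apre_r = ar % sr;
  arma::mat apre_u = au % su;
  // k = Hp W_hht^T
  gWh.rows(2 * H, 3 * H - 1) += ak.t() * Hp;
  aHp += ak * f.Wh.rows(2 * H, 3 * H - 1);
  // pre_r, pre_u, S3
  gWh.rows(0, H - 1) += apre_r.t() * Hp;
  gWh.rows(H, 2 * H - 1) += apre_u.t() * Hp;
  aHp += apre_r * f.Wh.rows(0, H - 1) + apre_u * f.Wh.rows(H, 2 * H - 1);
  arma::mat dS = arma::join_rows(apre_r, apre_u, aS3);
  gWxq.cols(0, n_in - 1) += dS.t() * XQ;
  gbias += arma::sum(dS, 0).t();
  // direct first-column (time-input) weight usage inside the jet
  gWxq(arma::span(0, H - 1), arma::span(0, 0)) += g_er.t();
  gWxq(arma::span(H, 2 * H - 1), arma::span(0, 0)) += g_eu.t();
  gWxq(arma::span(2 * H, 3 * H - 1), arma::span(0, 0)) += g_ec.t();

  // ---- history steps (standard backward) ----
  arma::mat dh = aHp;
  for (int s = (int)last - 1; s >= 0; --s) {
    const arma::mat& rs = cache->r[s];
    const arma::mat& us = cache->u[s];
    const arma::mat& ks = cache->k[s];
    const arma::mat& hts = cache->ht[s];
    const arma::mat& Hps = cache->Hp[s];
    const arma::mat& XQs = cache->XQ[s];
    if (!f.std_gru) gb_h += arma::sum(dh, 0).t();
    bool zeroH = (s == 0);
    arma::mat du = zeroH ? arma::mat(dh % (-hts))
                         : arma::mat(dh % (Hps - hts));
    arma::mat dpre_c = (dh % (1.0 - us)) % (1.0 - hts % hts);
    arma::mat dk = dpre_c % rs;
    arma::mat dpre_r = (dpre_c % ks) % (rs % (1.0 - rs));
    arma::mat dpre_u = du % (us % (1.0 - us));
    arma::mat dSs = arma::join_rows(dpre_r, dpre_u, dpre_c);
    gWxq += dSs.t() * XQs;
    gbias += arma::sum(dSs, 0).t();
    if (zeroH) break;
    arma::mat dFh = arma::join_rows(dpre_r, dpre_u, dk);
    gWh += dFh.t() * Hps;
    dh = dh % us + dFh * f.Wh;
  }

  return List::create(
    _["W_hr"] = gWh.rows(0, H - 1), _["W_hu"] = gWh.rows(H, 2 * H - 1),
    _["W_hht"] = gWh.rows(2 * H, 3 * H - 1),
    _["W_xr"] = gWxq.submat(0, 0, H - 1, n_in - 1),
    _["W_xu"] = gWxq.submat(H, 0, 2 * H - 1, n_in - 1),
    _["W_xht"] = gWxq.submat(2 * H, 0, 3 * H - 1, n_in - 1),
    _["W_qr"] = gWxq.submat(0, n_in, H - 1, n_in),
    _["W_qu"] = gWxq.submat(H, n_in, 2 * H - 1, n_in),
    _["W_qht"] = gWxq.submat(2 * H, n_in, 3 * H - 1, n_in),
    _["W_hq"] = gW_hq,
    _["b_r"] = NumericVector(gbias.begin(), gbias.begin() + H),
    _["b_u"] = NumericVector(gbias.begin() + H, gbias.begin() + 2 * H),
    _["b_ht"] = NumericVector(gbias.begin() + 2 * H, gbias.begin() + 3 * H),
    _["b_h"] = NumericVector(gb_h.begin(), gb_h.end()), _["b_q"] = gb_q);
}

// One fused Adam update over a named list of numeric arrays (weights),
// with first/second-moment lists of the same shapes.
// [[Rcpp::export(name = ".adam_step_cpp")]]
List adam_step_cpp(List w, List g, List m, List v, int t, double lr,
                   double b1, double b2, double eps) {
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  // deep copies: the caller's objects (including any best-weights
  // snapshots referencing them) must remain untouched
  List wo = clone(w), mo = clone(m), vo = clone(v);
  for (int i = 0; i < wo.size(); ++i) {
    NumericVector wi = wo[i];
    NumericVector gi = as<NumericVector>(g[i]);
    NumericVector mi = mo[i];
    NumericVector vi = vo[i];
    const R_xlen_t n = wi.size();
    for (R_xlen_t j = 0; j < n; ++j) {
      mi[j] = b1 * mi[j] + (1.0 - b1) * gi[j];
      vi[j] = b2 * vi[j] + (1.0 - b2) * gi[j] * gi[j];
      wi[j] -= lr * (mi[j] / c1) / (std::sqrt(vi[j] / c2) + eps);
    }
  }
  return List::create(_["w"] = wo, _["m"] = mo, _["v"] = vo);
}
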