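// Core computation for the BiGRU encoder-decoder with additive attention.
//
// The network maps a padded symbol sequence (one-hot over `A` channels) to a
// single scalar. Layout:
//   encoder : one bidirectional GRU layer (u units per direction); state at
//             position p is the concatenation [h_fwd(p), h_bwd(p)] (2u).
//   attention: additive (alignment a(s, h_j) = va' tanh(Was' s + Uah' h_j + ba)),
//             softmax-normalised over positions; context c = sum_j alpha_j h_j.
//   decoder : a single BiGRU step on [c ; one-hot(start)] initialised from the
//             encoder final state, then a dense layer with one unit.
// Gradients are exact backprop-through-time; training uses Adam on MSE.
//
// The implementation is templated on the element type: training and bulk
// prediction run in single precision (the standard choice for this kind of
// model, and about twice as fast on BLAS), while the exported loss/gradient
// entry points run in double precision so that analytic gradients can be
// verified against central finite differences.
//
// Sequences are passed as 0-based integer index matrices (B x T); the one-hot
// product X * W is realised as a row gather W.rows(idx), and its gradient as a
// row scatter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

template <typename T> struct Net {
  int A;     // encoder input channels (alphabet incl. pad if used)
  int u;     // GRU units per direction
  int Ad;    // decoder one-hot vocabulary (alphabet + start symbol)
  Mat<T> Wf, Uf, Wb, Ub;   // encoder input/recurrent weights (fwd, bwd)
  Row<T> bf, bb;           // encoder biases (1 x 3u, blocks z|r|h)
  Mat<T> Was, Uah;         // attention projections (2u x u)
  Row<T> ba;               // attention bias (1 x u)
  Col<T> va;               // attention score vector (u)
  Mat<T> Vf, Qf, Vb, Qb;   // decoder cell input/recurrent weights
  Row<T> cf, cb;           // decoder biases
  Col<T> wd;               // dense head weights (2u)
  T bd;                    // dense head bias
};

template <typename T> Net<T> unpack(const Rcpp::List& par) {
  Net<T> n;
  n.Wf = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Wf"]));
  n.Uf = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Uf"]));
  n.bf = conv_to<Row<T>>::from(Rcpp::as<rowvec>(par["bf"]));
  n.Wb = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Wb"]));
  n.Ub = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Ub"]));
  n.bb = conv_to<Row<T>>::from(Rcpp::as<rowvec>(par["bb"]));
  n.Was = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Was"]));
  n.Uah = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Uah"]));
  n.ba = conv_to<Row<T>>::from(Rcpp::as<rowvec>(par["ba"]));
  n.va = conv_to<Col<T>>::from(Rcpp::as<vec>(par["va"]));
  n.Vf = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Vf"]));
  n.Qf = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Qf"]));
  n.cf = conv_to<Row<T>>::from(Rcpp::as<rowvec>(par["cf"]));
  n.Vb = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Vb"]));
  n.Qb = conv_to<Mat<T>>::from(Rcpp::as<mat>(par["Qb"]));
  n.cb = conv_to<Row<T>>::from(Rcpp::as<rowvec>(par["cb"]));
  n.wd = conv_to<Col<T>>::from(Rcpp::as<vec>(par["wd"]));
  n.bd = (T)Rcpp::as<Rcpp::NumericVector>(par["bd"])[0];
  n.A  = n.Wf.n_rows;
  n.u  = n.Uf.n_rows;
  n.Ad = n.Vf.n_rows - 2 * n.u;
  return n;
}

template <typename T> Rcpp::List pack(const Net<T>& n) {
  return Rcpp::List::create(
    Rcpp::Named("Wf") = conv_to<mat>::from(n.Wf),
    Rcpp::Named("Uf") = conv_to<mat>::from(n.Uf),
    Rcpp::Named("bf") = conv_to<rowvec>::from(n.bf),
    Rcpp::Named("Wb") = conv_to<mat>::from(n.Wb),
    Rcpp::Named("Ub") = conv_to<mat>::from(n.Ub),
    Rcpp::Named("bb") = conv_to<rowvec>::from(n.bb),
    Rcpp::Named("Was") = conv_to<mat>::from(n.Was),
    Rcpp::Named("Uah") = conv_to<mat>::from(n.Uah),
    Rcpp::Named("ba") = conv_to<rowvec>::from(n.ba),
    Rcpp::Named("va") = conv_to<vec>::from(n.va),
    Rcpp::Named("Vf") = conv_to<mat>::from(n.Vf),
    Rcpp::Named("Qf") = conv_to<mat>::from(n.Qf),
    Rcpp::Named("cf") = conv_to<rowvec>::from(n.cf),
    Rcpp::Named("Vb") = conv_to<mat>::from(n.Vb),
    Rcpp::Named("Qb") = conv_to<mat>::from(n.Qb),
    Rcpp::Named("cb") = conv_to<rowvec>::from(n.cb),
    Rcpp::Named("wd") = conv_to<vec>::from(n.wd),
    Rcpp::Named("bd") = (double)n.bd);
}

template <typename M> M sigmoid(M x) { return 1.0 / (1.0 + exp(-x)); }

// One GRU step.  P = X * W (B x 3u) precomputed by the caller.
template <typename T>
Mat<T> gru_step(const Mat<T>& P, const Mat<T>& Hprev, const Mat<T>& U,
                const Row<T>& b, int u, Mat<T>& Z, Mat<T>& R, Mat<T>& HH) {
  Mat<T> RZ = Hprev * U.cols(0, 2 * u - 1);
  Mat<T> Az = P.cols(0, u - 1) + RZ.cols(0, u - 1);
  Az.each_row() += b.cols(0, u - 1);
  Mat<T> Ar = P.cols(u, 2 * u - 1) + RZ.cols(u, 2 * u - 1);
  Ar.each_row() += b.cols(u, 2 * u - 1);
  Z = sigmoid(std::move(Az));
  R = sigmoid(std::move(Ar));
  Mat<T> Ah = P.cols(2 * u, 3 * u - 1) +
    (R % Hprev) * U.cols(2 * u, 3 * u - 1);
  Ah.each_row() += b.cols(2 * u, 3 * u - 1);
  HH = tanh(std::move(Ah));
  return (1.0 - Z) % Hprev + Z % HH;
}

// Backward through one GRU step.  Accumulates dU, db; returns dHprev and
// fills dP (gradient w.r.t. the input pre-product X * W).
template <typename T>
Mat<T> gru_step_back(const Mat<T>& dH, const Mat<T>& Hprev, const Mat<T>& Z,
                     const Mat<T>& R, const Mat<T>& HH, const Mat<T>& U,
                     int u, Mat<T>& dU, Row<T>& db, Mat<T>& dP) {
  Mat<T> dZ = dH % (HH - Hprev);
  Mat<T> dHH = dH % Z;
  Mat<T> dHprev = dH % (1.0 - Z);
  Mat<T> dAh = dHH % (1.0 - HH % HH);
  Mat<T> dRH = dAh * U.cols(2 * u, 3 * u - 1).t();
  dU.cols(2 * u, 3 * u - 1) += (R % Hprev).t() * dAh;
  Mat<T> dR = dRH % Hprev;
  dHprev += dRH % R;
  Mat<T> dAz = dZ % Z % (1.0 - Z);
  Mat<T> dAr = dR % R % (1.0 - R);
  dU.cols(0, u - 1) += Hprev.t() * dAz;
  dU.cols(u, 2 * u - 1) += Hprev.t() * dAr;
  dHprev += dAz * U.cols(0, u - 1).t() + dAr * U.cols(u, 2 * u - 1).t();
  db.cols(0, u - 1) += sum(dAz, 0);
  db.cols(u, 2 * u - 1) += sum(dAr, 0);
  db.cols(2 * u, 3 * u - 1) += sum(dAh, 0);
  dP = join_rows(dAz, dAr, dAh);
  return dHprev;
}

template <typename T> struct Cache {
  Cube<T> Zf, Rf, HHf, Hf;   // forward-direction encoder caches (B x u x T)
  Cube<T> Zb, Rb, HHb, Hb;   // backward direction, slices in scan order
  Mat<T> S;                  // encoder final state (B x 2u)
  Mat<T> Hall;               // stacked per-position states ((T*B) x 2u)
  Mat<T> Aall;               // attention tanh activations ((T*B) x u)
  Mat<T> e, alpha;           // scores and weights (B x T)
  Mat<T> C;                  // context (B x 2u)
  Mat<T> Xd;                 // decoder input (B x (2u+Ad))
  Mat<T> Zdf, Rdf, HHdf, Df; // decoder fwd cell
  Mat<T> Zdb, Rdb, HHdb, Db; // decoder bwd cell
  Col<T> yhat;
};

// Full forward pass for a batch of index sequences (0-based, B x T).
template <typename T>
void forward(const Net<T>& n, const umat& seq, int pad_idx, bool mask_pad,
             Cache<T>& c) {
  const int B = seq.n_rows, Tn = seq.n_cols, u = n.u;
  c.Zf.set_size(B, u, Tn); c.Rf.set_size(B, u, Tn);
  c.HHf.set_size(B, u, Tn); c.Hf.set_size(B, u, Tn);
  c.Zb.set_size(B, u, Tn); c.Rb.set_size(B, u, Tn);
  c.HHb.set_size(B, u, Tn); c.Hb.set_size(B, u, Tn);

  Mat<T> H = zeros<Mat<T>>(B, u);
  for (int s = 0; s < Tn; ++s) {
    uvec idx = conv_to<uvec>::from(seq.col(s));
    Mat<T> Z, R, HH;
    H = gru_step<T>(n.Wf.rows(idx), H, n.Uf, n.bf, u, Z, R, HH);
    c.Zf.slice(s) = Z; c.Rf.slice(s) = R; c.HHf.slice(s) = HH;
    c.Hf.slice(s) = H;
  }
  H.zeros();
  for (int s = 0; s < Tn; ++s) {            // scan position p = Tn-1-s
    uvec idx = conv_to<uvec>::from(seq.col(Tn - 1 - s));
    Mat<T> Z, R, HH;
    H = gru_step<T>(n.Wb.rows(idx), H, n.Ub, n.bb, u, Z, R, HH);
    c.Zb.slice(s) = Z; c.Rb.slice(s) = R; c.HHb.slice(s) = HH;
    c.Hb.slice(s) = H;
  }
  c.S = join_rows(c.Hf.slice(Tn - 1), c.Hb.slice(Tn - 1));

  // Stack concatenated states by position for batched attention GEMMs.
  c.Hall.set_size(Tn * B, 2 * u);
  for (int p = 0; p < Tn; ++p)
    c.Hall.rows(p * B, p * B + B - 1) =
      join_rows(c.Hf.slice(p), c.Hb.slice(Tn - 1 - p));

  Mat<T> SW = c.S * n.Was;
  SW.each_row() += n.ba;
  Mat<T> Pre = c.Hall * n.Uah;
  for (int p = 0; p < Tn; ++p) Pre.rows(p * B, p * B + B - 1) += SW;
  c.Aall = tanh(std::move(Pre));
  Col<T> evec = c.Aall * n.va;
  c.e.set_size(B, Tn);
  for (int p = 0; p < Tn; ++p) c.e.col(p) = evec.subvec(p * B, p * B + B - 1);
  if (mask_pad && pad_idx >= 0) {
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < Tn; ++p)
        if ((int)seq(b, p) == pad_idx)
          c.e(b, p) = -std::numeric_limits<T>::infinity();
  }
  Mat<T> esh = c.e;
  esh.each_col() -= max(c.e, 1);
  c.alpha = exp(esh);
  c.alpha.each_col() /= sum(c.alpha, 1);

  c.C = zeros<Mat<T>>(B, 2 * u);
  for (int p = 0; p < Tn; ++p) {
    Mat<T> Hp = c.Hall.rows(p * B, p * B + B - 1);
    Hp.each_col() %= c.alpha.col(p);
    c.C += Hp;
  }

  c.Xd = zeros<Mat<T>>(B, 2 * u + n.Ad);
  c.Xd.cols(0, 2 * u - 1) = c.C;
  c.Xd.col(2 * u + n.Ad - 1).ones();       // one-hot start symbol
  c.Df = gru_step<T>(c.Xd * n.Vf, c.Hf.slice(Tn - 1), n.Qf, n.cf, u,
                     c.Zdf, c.Rdf, c.HHdf);
  c.Db = gru_step<T>(c.Xd * n.Vb, c.Hb.slice(Tn - 1), n.Qb, n.cb, u,
                     c.Zdb, c.Rdb, c.HHdb);
  c.yhat = join_rows(c.Df, c.Db) * n.wd + n.bd;
}

// Backward pass: gradient of mean((yhat - y)^2) over the batch.
template <typename T>
void backward(const Net<T>& n, const umat& seq, const Col<T>& y,
              const Cache<T>& c, Net<T>& g) {
  const int B = seq.n_rows, Tn = seq.n_cols, u = n.u;
  Col<T> dy = 2.0 * (c.yhat - y) / (T)B;

  Mat<T> D = join_rows(c.Df, c.Db);
  g.wd += D.t() * dy;
  g.bd += accu(dy);
  Mat<T> dD = dy * n.wd.t();

  Mat<T> dPf, dPb;
  Mat<T> dHfin_f = gru_step_back<T>(dD.cols(0, u - 1), c.Hf.slice(Tn - 1),
                                    c.Zdf, c.Rdf, c.HHdf, n.Qf, u,
                                    g.Qf, g.cf, dPf);
  Mat<T> dHfin_b = gru_step_back<T>(dD.cols(u, 2 * u - 1),
                                    c.Hb.slice(Tn - 1), c.Zdb, c.Rdb,
                                    c.HHdb, n.Qb, u, g.Qb, g.cb, dPb);
  g.Vf += c.Xd.t() * dPf;
  g.Vb += c.Xd.t() * dPb;
  Mat<T> dXd = dPf * n.Vf.t() + dPb * n.Vb.t();
  Mat<T> dC = dXd.cols(0, 2 * u - 1);

  // Attention backward.
  Mat<T> dalpha(B, Tn);
  Mat<T> dHall = zeros<Mat<T>>(Tn * B, 2 * u);
  for (int p = 0; p < Tn; ++p) {
    Mat<T> Hp = c.Hall.rows(p * B, p * B + B - 1);
    dalpha.col(p) = sum(dC % Hp, 1);
    Mat<T> dCp = dC;
    dCp.each_col() %= c.alpha.col(p);
    dHall.rows(p * B, p * B + B - 1) = dCp;
  }
  Col<T> rs = sum(c.alpha % dalpha, 1);
  Mat<T> dalpha_c = dalpha;
  dalpha_c.each_col() -= rs;
  Mat<T> de = c.alpha % dalpha_c;
  Col<T> devec(Tn * B);
  for (int p = 0; p < Tn; ++p)
    devec.subvec(p * B, p * B + B - 1) = de.col(p);
  g.va += c.Aall.t() * devec;
  Mat<T> dPre = (devec * n.va.t()) % (1.0 - c.Aall % c.Aall);
  g.Uah += c.Hall.t() * dPre;
  dHall += dPre * n.Uah.t();
  Mat<T> dSW = zeros<Mat<T>>(B, u);
  for (int p = 0; p < Tn; ++p) dSW += dPre.rows(p * B, p * B + B - 1);
  g.Was += c.S.t() * dSW;
  g.ba += sum(dSW, 0);
  Mat<T> dS = dSW * n.Was.t();

  // Encoder BPTT, forward direction (slices in scan order = position).
  Mat<T> dH = zeros<Mat<T>>(B, u), dP;
  for (int s = Tn - 1; s >= 0; --s) {
    dH += dHall.rows(s * B, s * B + B - 1).cols(0, u - 1);
    if (s == Tn - 1) dH += dS.cols(0, u - 1) + dHfin_f;
    Mat<T> Hprev = (s > 0) ? c.Hf.slice(s - 1) : zeros<Mat<T>>(B, u);
    dH = gru_step_back<T>(dH, Hprev, c.Zf.slice(s), c.Rf.slice(s),
                          c.HHf.slice(s), n.Uf, u, g.Uf, g.bf, dP);
    for (int b = 0; b < B; ++b) g.Wf.row(seq(b, s)) += dP.row(b);
  }
  // Backward direction: slice s holds scan step s (position Tn-1-s).
  dH.zeros();
  for (int s = Tn - 1; s >= 0; --s) {
    int p = Tn - 1 - s;
    dH += dHall.rows(p * B, p * B + B - 1).cols(u, 2 * u - 1);
    if (s == Tn - 1) dH += dS.cols(u, 2 * u - 1) + dHfin_b;
    Mat<T> Hprev = (s > 0) ? c.Hb.slice(s - 1) : zeros<Mat<T>>(B, u);
    dH = gru_step_back<T>(dH, Hprev, c.Zb.slice(s), c.Rb.slice(s),
                          c.HHb.slice(s), n.Ub, u, g.Ub, g.bb, dP);
    for (int b = 0; b < B; ++b) g.Wb.row(seq(b, p)) += dP.row(b);
  }
}

template <typename T> Net<T> zeros_like(const Net<T>& n) {
  Net<T> g = n;
  g.Wf.zeros(); g.Uf.zeros(); g.bf.zeros();
  g.Wb.zeros(); g.Ub.zeros(); g.bb.zeros();
  g.Was.zeros(); g.Uah.zeros(); g.ba.zeros(); g.va.zeros();
  g.Vf.zeros(); g.Qf.zeros(); g.cf.zeros();
  g.Vb.zeros(); g.Qb.zeros(); g.cb.zeros();
  g.wd.zeros(); g.bd = 0.0;
  return g;
}

umat as_seq(const Rcpp::IntegerMatrix& m) {
  umat s(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) {
      int v = m(i, j);
      if (v < 1) Rcpp::stop("sequence indices must be 1-based positive");
      s(i, j) = (uword)(v - 1);
    }
  return s;
}

// Adam with the classic bias correction: alpha_t = lr sqrt(1-b2^t)/(1-b1^t).
template <typename T> struct Adam {
  Net<T> m, v;
  T b1, b2, eps, lr;
  long t = 0;
  Adam(const Net<T>& n, double lr_, double b1_, double b2_, double eps_)
    : m(zeros_like(n)), v(zeros_like(n)),
      b1((T)b1_), b2((T)b2_), eps((T)eps_), lr((T)lr_) {}
  template <typename M>
  void upd(M& p, M& gm, M& gv, const M& g, T a, T ec) {
    gm = b1 * gm + (1 - b1) * g;
    gv = b2 * gv + (1 - b2) * (g % g);
    p -= a * gm / (sqrt(gv) + eps * ec);
  }
  void step(Net<T>& n, const Net<T>& g) {
    ++t;
    T ec = std::sqrt(1 - std::pow((double)b2, (double)t));
    T a = lr * ec / (1 - std::pow((double)b1, (double)t));
    upd(n.Wf, m.Wf, v.Wf, g.Wf, a, ec);   upd(n.Uf, m.Uf, v.Uf, g.Uf, a, ec);
    upd(n.bf, m.bf, v.bf, g.bf, a, ec);
    upd(n.Wb, m.Wb, v.Wb, g.Wb, a, ec);   upd(n.Ub, m.Ub, v.Ub, g.Ub, a, ec);
    upd(n.bb, m.bb, v.bb, g.bb, a, ec);
    upd(n.Was, m.Was, v.Was, g.Was, a, ec);
    upd(n.Uah, m.Uah, v.Uah, g.Uah, a, ec);
    upd(n.ba, m.ba, v.ba, g.ba, a, ec);   upd(n.va, m.va, v.va, g.va, a, ec);
    upd(n.Vf, m.Vf, v.Vf, g.Vf, a, ec);   upd(n.Qf, m.Qf, v.Qf, g.Qf, a, ec);
    upd(n.cf, m.cf, v.cf, g.cf, a, ec);
    upd(n.Vb, m.Vb, v.Vb, g.Vb, a, ec);   upd(n.Qb, m.Qb, v.Qb, g.Qb, a, ec);
    upd(n.cb, m.cb, v.cb, g.cb, a, ec);
    upd(n.wd, m.wd, v.wd, g.wd, a, ec);
    m.bd = b1 * m.bd + (1 - b1) * g.bd;
    v.bd = b2 * v.bd + (1 - b2) * g.bd * g.bd;
    n.bd -= a * m.bd / (std::sqrt(v.bd) + eps * ec);
  }
};

template <typename T>
Col<T> predict_chunked(const Net<T>& n, const umat& seq, int pad_idx,
                       bool mask_pad, int chunk, Mat<T>* alpha_out) {
  const int B = seq.n_rows;
  Col<T> yhat(B);
  if (alpha_out) alpha_out->set_size(B, seq.n_cols);
  for (int lo = 0; lo < B; lo += chunk) {
    int hi = std::min(lo + chunk, B) - 1;
    Cache<T> c;
    forward<T>(n, seq.rows(lo, hi), pad_idx, mask_pad, c);
    yhat.subvec(lo, hi) = c.yhat;
    if (alpha_out) alpha_out->rows(lo, hi) = c.alpha;
  }
  return yhat;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List params, Rcpp::IntegerMatrix seq,
                       int pad_idx = -1, bool mask_pad = false,
                       bool details = false) {
  Net<double> n = unpack<double>(params);
  umat s = as_seq(seq);
  if ((int)s.max() >= n.A) Rcpp::stop("sequence index exceeds alphabet size");
  Cache<double> c;
  forward<double>(n, s, pad_idx - 1, mask_pad, c);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("yhat") = c.yhat, Rcpp::Named("alpha") = c.alpha);
  if (details) {
    const int Tn = s.n_cols, B = s.n_rows;
    cube states(B, 2 * n.u, Tn);
    for (int p = 0; p < Tn; ++p)
      states.slice(p) = c.Hall.rows(p * B, p * B + B - 1);
    out["states"] = states;
    out["final_state"] = c.S;
    out["scores"] = c.e;
    out["context"] = c.C;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_predict(Rcpp::List params, Rcpp::IntegerMatrix seq,
                       int pad_idx = -1, bool mask_pad = false,
                       int chunk = 512, bool single = true) {
  umat s = as_seq(seq);
  if (single) {
    Net<float> n = unpack<float>(params);
    Mat<float> alpha;
    Col<float> yhat = predict_chunked<float>(n, s, pad_idx - 1, mask_pad,
                                             chunk, &alpha);
    return Rcpp::List::create(
      Rcpp::Named("yhat") = conv_to<vec>::from(yhat),
      Rcpp::Named("alpha") = conv_to<mat>::from(alpha));
  }
  Net<double> n = unpack<double>(params);
  mat alpha;
  vec yhat = predict_chunked<double>(n, s, pad_idx - 1, mask_pad, chunk,
                                     &alpha);
  return Rcpp::List::create(Rcpp::Named("yhat") = yhat,
                            Rcpp::Named("alpha") = alpha);
}

// [[Rcpp::export]]
double cpp_loss(Rcpp::List params, Rcpp::IntegerMatrix seq,
                Rcpp::NumericVector y, int pad_idx = -1,
                bool mask_pad = false) {
  Net<double> n = unpack<double>(params);
  umat s = as_seq(seq);
  Cache<double> c;
  forward<double>(n, s, pad_idx - 1, mask_pad, c);
  vec yy = Rcpp::as<vec>(y);
  return accu(square(c.yhat - yy)) / yy.n_elem;
}

// [[Rcpp::export]]
Rcpp::List cpp_grad(Rcpp::List params, Rcpp::IntegerMatrix seq,
                    Rcpp::NumericVector y, int pad_idx = -1,
                    bool mask_pad = false) {
  Net<double> n = unpack<double>(params);
  umat s = as_seq(seq);
  Cache<double> c;
  forward<double>(n, s, pad_idx - 1, mask_pad, c);
  Net<double> g = zeros_like(n);
  backward<double>(n, s, Rcpp::as<vec>(y), c, g);
  return pack(g);
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List params, Rcpp::IntegerMatrix seq,
                     Rcpp::NumericVector y, Rcpp::IntegerMatrix seq_val,
                     Rcpp::NumericVector y_val, int epochs = 30,
                     int batch_size = 256, double lr = 0.001,
                     double beta1 = 0.9, double beta2 = 0.999,
                     double eps = 1e-8, int patience = 0,
                     double min_delta = 0.0, int seed = 1,
                     int pad_idx = -1, bool mask_pad = false,
                     bool verbose = false) {
  typedef float T;
  Net<T> n = unpack<T>(params);
  umat s = as_seq(seq);
  umat sv = as_seq(seq_val);
  Col<T> yy = conv_to<Col<T>>::from(Rcpp::as<vec>(y));
  Col<T> yv = conv_to<Col<T>>::from(Rcpp::as<vec>(y_val));
  const int N = s.n_rows;
  if (N == 0) Rcpp::stop("empty training set");
  if (batch_size > N) batch_size = N;
  Adam<T> opt(n, lr, beta1, beta2, eps);
  std::mt19937 rng((unsigned)seed);
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;

  std::vector<double> tr_mse, tr_mae, va_mae;
  double best_val = datum::inf;
  int best_epoch = -1, wait = 0;
  Net<T> best = n;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(ord.begin(), ord.end(), rng);
    double se = 0.0, ae = 0.0;
    long cnt = 0;
    for (int lo = 0; lo < N; lo += batch_size) {
      int hi = std::min(lo + batch_size, N) - 1;
      uvec idx(hi - lo + 1);
      for (int i = lo; i <= hi; ++i) idx(i - lo) = (uword)ord[i];
      umat sb = s.rows(idx);
      Col<T> yb = yy(idx);
      Cache<T> c;
      forward<T>(n, sb, pad_idx - 1, mask_pad, c);
      if (!c.yhat.is_finite())
        Rcpp::stop("non-finite predictions at epoch %d; training aborted "
                   "(check target scaling and learning rate)", ep + 1);
      Net<T> g = zeros_like(n);
      backward<T>(n, sb, yb, c, g);
      opt.step(n, g);
      se += accu(square(conv_to<vec>::from(c.yhat - yb)));
      ae += accu(abs(conv_to<vec>::from(c.yhat - yb)));
      cnt += yb.n_elem;
    }
    tr_mse.push_back(se / cnt);
    tr_mae.push_back(ae / cnt);
    double vmae = datum::nan;
    if (sv.n_rows > 0) {
      Col<T> yhv = predict_chunked<T>(n, sv, pad_idx - 1, mask_pad, 1024,
                                      nullptr);
      vmae = accu(abs(conv_to<vec>::from(yhv - yv))) / yv.n_elem;
    }
    va_mae.push_back(vmae);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " train_mse=" << tr_mse.back()
                  << " val_mae=" << vmae << std::endl;
    if (sv.n_rows > 0 && patience > 0) {
      if (vmae < best_val - min_delta) {
        best_val = vmae; best = n; best_epoch = ep; wait = 0;
      } else if (++wait >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch >= 0) n = best;
  return Rcpp::List::create(
    Rcpp::Named("params") = pack(n),
    Rcpp::Named("train_mse") = tr_mse,
    Rcpp::Named("train_mae") = tr_mae,
    Rcpp::Named("val_mae") = va_mae,
    Rcpp::Named("best_epoch") = best_epoch + 1);
}
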