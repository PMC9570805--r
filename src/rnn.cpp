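// Batched per-timestep sequence classifier: GRU -> biLSTM -> dense -> softmax,
// with full backpropagation through time. Sequences are padded to a common
// length and masked; masked timesteps contribute nothing to states, loss or
// gradients (states are zeroed at masked steps so the reverse LSTM direction
// enters real samples with a clean state).
//
// Layouts: X is a D x B x T cube (channels x sequences x timesteps),
// mask and y are B x T, probabilities come back as C x B x T.
// Gate orders: GRU [r; z; n], LSTM [i; f; g; o].
//
// Templated on the element type: float for training throughput, double for
// finite-difference gradient verification.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

template <typename eT>
static inline Mat<eT> sigm(const Mat<eT>& x) {
  return eT(1) / (eT(1) + exp(-x));
}

template <typename eT>
struct Net {
  Mat<eT> Wg, Ug; Col<eT> bg;   // GRU        3*H1 x D,  3*H1 x H1
  Mat<eT> Wf, Uf; Col<eT> bf;   // LSTM fwd   4*H2 x H1, 4*H2 x H2
  Mat<eT> Wb, Ub; Col<eT> bb;   // LSTM bwd
  Mat<eT> Wo; Col<eT> bo;       // dense      C x 2*H2
  uword D, H1, H2, C;
};

template <typename eT>
static Net<eT> net_from_list(const List& p) {
  Net<eT> n;
  n.Wg = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p["gru_W"]));
  n.Ug = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p["gru_U"]));
  n.bg = conv_to<Col<eT>>::from(Rcpp::as<vec>(p["gru_b"]));
  n.Wf = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p["lstm_fw_W"]));
  n.Uf = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p["lstm_fw_U"]));
  n.bf = conv_to<Col<eT>>::from(Rcpp::as<vec>(p["lstm_fw_b"]));
  n.Wb = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p["lstm_bw_W"]));
  n.Ub = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p["lstm_bw_U"]));
  n.bb = conv_to<Col<eT>>::from(Rcpp::as<vec>(p["lstm_bw_b"]));
  n.Wo = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p["fc_W"]));
  n.bo = conv_to<Col<eT>>::from(Rcpp::as<vec>(p["fc_b"]));
  n.D  = n.Wg.n_cols;
  n.H1 = n.Ug.n_cols;
  n.H2 = n.Uf.n_cols;
  n.C  = n.Wo.n_rows;
  return n;
}

// ---- GRU -------------------------------------------------------------------
// r = sig(Wr x + Ur h + br); z = sig(Wz x + Uz h + bz)
// n = tanh(Wn x + Un (r.h) + bn); h' = m . ((1-z).n + z.h)
template <typename eT>
static void gru_forward(const Net<eT>& net, const Mat<eT>& Xmat,
                        const Mat<eT>& mask, uword B, uword T,
                        Cube<eT>& G, Cube<eT>& RH, Cube<eT>& Hprev,
                        Cube<eT>& H) {
  const uword H1 = net.H1;
  Mat<eT> inG = net.Wg * Xmat;           // 3H1 x (B*T)
  inG.each_col() += net.bg;
  const Mat<eT> Ur = net.Ug.rows(0, H1 - 1);
  const Mat<eT> Uz = net.Ug.rows(H1, 2 * H1 - 1);
  const Mat<eT> Un = net.Ug.rows(2 * H1, 3 * H1 - 1);
  Mat<eT> h(H1, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const Mat<eT> a = inG.cols(t * B, t * B + B - 1);
    Hprev.slice(t) = h;
    Mat<eT> r = sigm<eT>(a.rows(0, H1 - 1) + Ur * h);
    Mat<eT> z = sigm<eT>(a.rows(H1, 2 * H1 - 1) + Uz * h);
    Mat<eT> rh = r % h;
    Mat<eT> n = tanh(a.rows(2 * H1, 3 * H1 - 1) + Un * rh);
    Mat<eT> hn = (eT(1) - z) % n + z % h;
    hn.each_row() %= mask.col(t).t();
    G.slice(t).rows(0, H1 - 1)          = r;
    G.slice(t).rows(H1, 2 * H1 - 1)     = z;
    G.slice(t).rows(2 * H1, 3 * H1 - 1) = n;
    RH.slice(t) = rh;
    H.slice(t)  = hn;
    h = hn;
  }
}

template <typename eT>
static void gru_backward(const Net<eT>& net, const Mat<eT>& Xmat,
                         const Mat<eT>& mask, uword B, uword T,
                         const Cube<eT>& G, const Cube<eT>& RH,
                         const Cube<eT>& Hprev, const Mat<eT>& dHmat,
                         Mat<eT>& dWg, Mat<eT>& dUg, Col<eT>& dbg) {
  const uword H1 = net.H1;
  const Mat<eT> Ur = net.Ug.rows(0, H1 - 1);
  const Mat<eT> Uz = net.Ug.rows(H1, 2 * H1 - 1);
  const Mat<eT> Un = net.Ug.rows(2 * H1, 3 * H1 - 1);
  Cube<eT> dG(3 * H1, B, T);
  Mat<eT> carry(H1, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    Mat<eT> dh = dHmat.cols(t * B, t * B + B - 1) + carry;
    dh.each_row() %= mask.col(t).t();        // through the state mask
    const Mat<eT> r = G.slice(t).rows(0, H1 - 1);
    const Mat<eT> z = G.slice(t).rows(H1, 2 * H1 - 1);
    const Mat<eT> n = G.slice(t).rows(2 * H1, 3 * H1 - 1);
    const Mat<eT>& hp = Hprev.slice(t);
    Mat<eT> dz = dh % (hp - n);
    Mat<eT> dn = dh % (eT(1) - z);
    Mat<eT> dhp = dh % z;
    Mat<eT> dnp = dn % (eT(1) - n % n);
    Mat<eT> drh = Un.t() * dnp;
    Mat<eT> dr  = drh % hp;
    dhp += drh % r;
    Mat<eT> drp = dr % r % (eT(1) - r);
    Mat<eT> dzp = dz % z % (eT(1) - z);
    dhp += Ur.t() * drp + Uz.t() * dzp;
    dG.slice(t).rows(0, H1 - 1)          = drp;
    dG.slice(t).rows(H1, 2 * H1 - 1)     = dzp;
    dG.slice(t).rows(2 * H1, 3 * H1 - 1) = dnp;
    carry = dhp;
  }
  const Mat<eT> dGmat(const_cast<eT*>(dG.memptr()), 3 * H1, B * T, false);
  const Mat<eT> Hpm(const_cast<eT*>(Hprev.memptr()), H1, B * T, false);
  const Mat<eT> RHm(const_cast<eT*>(RH.memptr()), H1, B * T, false);
  dWg = dGmat * Xmat.t();
  dbg = sum(dGmat, 1);
  dUg.set_size(3 * H1, H1);
  dUg.rows(0, H1 - 1)          = dGmat.rows(0, H1 - 1) * Hpm.t();
  dUg.rows(H1, 2 * H1 - 1)     = dGmat.rows(H1, 2 * H1 - 1) * Hpm.t();
  dUg.rows(2 * H1, 3 * H1 - 1) = dGmat.rows(2 * H1, 3 * H1 - 1) * RHm.t();
}

// ---- LSTM (one direction) --------------------------------------------------
// i,f,o = sig(.), g = tanh(.); c' = m.(f.c + i.g); h' = m.(o.tanh(c'))
template <typename eT>
static void lstm_forward(const Mat<eT>& W, const Mat<eT>& U, const Col<eT>& b,
                         const Mat<eT>& Xin, const Mat<eT>& mask,
                         uword B, uword T, bool reverse,
                         Cube<eT>& G, Cube<eT>& Cc, Cube<eT>& TC,
                         Cube<eT>& Hprev, Cube<eT>& Cprev, Cube<eT>& H) {
  const uword H2 = U.n_cols;
  Mat<eT> inG = W * Xin;                 // 4H2 x (B*T)
  inG.each_col() += b;
  Mat<eT> h(H2, B, fill::zeros), c(H2, B, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    const uword t = reverse ? (T - 1 - s) : s;
    const Mat<eT> a = inG.cols(t * B, t * B + B - 1);
    Hprev.slice(t) = h;
    Cprev.slice(t) = c;
    Mat<eT> pre = a + U * h;
    Mat<eT> i = sigm<eT>(pre.rows(0, H2 - 1));
    Mat<eT> f = sigm<eT>(pre.rows(H2, 2 * H2 - 1));
    Mat<eT> g = tanh(pre.rows(2 * H2, 3 * H2 - 1));
    Mat<eT> o = sigm<eT>(pre.rows(3 * H2, 4 * H2 - 1));
    Mat<eT> cn = f % c + i % g;
    cn.each_row() %= mask.col(t).t();
    Mat<eT> tc = tanh(cn);
    Mat<eT> hn = o % tc;
    hn.each_row() %= mask.col(t).t();
    G.slice(t).rows(0, H2 - 1)          = i;
    G.slice(t).rows(H2, 2 * H2 - 1)     = f;
    G.slice(t).rows(2 * H2, 3 * H2 - 1) = g;
    G.slice(t).rows(3 * H2, 4 * H2 - 1) = o;
    Cc.slice(t) = cn;
    TC.slice(t) = tc;
    H.slice(t)  = hn;
    h = hn;
    c = cn;
  }
}

template <typename eT>
static void lstm_backward(const Mat<eT>& W, const Mat<eT>& U,
                          const Mat<eT>& Xin, const Mat<eT>& mask,
                          uword B, uword T, bool reverse,
                          const Cube<eT>& G, const Cube<eT>& Cc,
                          const Cube<eT>& TC, const Cube<eT>& Hprev,
                          const Cube<eT>& Cprev, const Mat<eT>& dHmat,
                          Mat<eT>& dW, Mat<eT>& dU, Col<eT>& db,
                          Mat<eT>& dXin) {
  const uword H2 = U.n_cols;
  Cube<eT> dG(4 * H2, B, T);
  Mat<eT> hcarry(H2, B, fill::zeros), ccarry(H2, B, fill::zeros);
  for (uword s = T; s-- > 0;) {
    // walk opposite to the forward recursion of this direction
    const uword t = reverse ? (T - 1 - s) : s;
    Mat<eT> dh = dHmat.cols(t * B, t * B + B - 1) + hcarry;
    dh.each_row() %= mask.col(t).t();
    const Mat<eT> i = G.slice(t).rows(0, H2 - 1);
    const Mat<eT> f = G.slice(t).rows(H2, 2 * H2 - 1);
    const Mat<eT> g = G.slice(t).rows(2 * H2, 3 * H2 - 1);
    const Mat<eT> o = G.slice(t).rows(3 * H2, 4 * H2 - 1);
    const Mat<eT>& tc = TC.slice(t);
    Mat<eT> dc = dh % o % (eT(1) - tc % tc) + ccarry;
    dc.each_row() %= mask.col(t).t();
    Mat<eT> dip = dh % tc % o % (eT(1) - o);            // d pre(o)
    Mat<eT> di  = dc % g % i % (eT(1) - i);             // d pre(i)
    Mat<eT> df  = dc % Cprev.slice(t) % f % (eT(1) - f);
    Mat<eT> dg  = dc % i % (eT(1) - g % g);
    dG.slice(t).rows(0, H2 - 1)          = di;
    dG.slice(t).rows(H2, 2 * H2 - 1)     = df;
    dG.slice(t).rows(2 * H2, 3 * H2 - 1) = dg;
    dG.slice(t).rows(3 * H2, 4 * H2 - 1) = dip;
    hcarry = U.t() * dG.slice(t);
    ccarry = dc % f;
  }
  const Mat<eT> dGmat(const_cast<eT*>(dG.memptr()), 4 * H2, B * T, false);
  const Mat<eT> Hpm(const_cast<eT*>(Hprev.memptr()), H2, B * T, false);
  dW = dGmat * Xin.t();
  dU = dGmat * Hpm.t();
  db = sum(dGmat, 1);
  dXin = W.t() * dGmat;
}

// ---- full network ----------------------------------------------------------

template <typename eT>
static cube forward_impl(const Net<eT>& net, const cube& Xd, const mat& maskd) {
  const uword B = Xd.n_cols, T = Xd.n_slices;
  const Cube<eT> X = conv_to<Cube<eT>>::from(Xd);
  const Mat<eT> mask = conv_to<Mat<eT>>::from(maskd);
  const Mat<eT> Xmat(const_cast<eT*>(X.memptr()), net.D, B * T, false);

  Cube<eT> G(3 * net.H1, B, T), RH(net.H1, B, T), Hp(net.H1, B, T),
           Hg(net.H1, B, T);
  gru_forward(net, Xmat, mask, B, T, G, RH, Hp, Hg);
  const Mat<eT> Hgmat(const_cast<eT*>(Hg.memptr()), net.H1, B * T, false);

  Cube<eT> Gf(4 * net.H2, B, T), Cf(net.H2, B, T), TCf(net.H2, B, T),
           Hpf(net.H2, B, T), Cpf(net.H2, B, T), Hf(net.H2, B, T);
  lstm_forward(net.Wf, net.Uf, net.bf, Hgmat, mask, B, T, false,
               Gf, Cf, TCf, Hpf, Cpf, Hf);
  Cube<eT> Gb(4 * net.H2, B, T), Cb(net.H2, B, T), TCb(net.H2, B, T),
           Hpb(net.H2, B, T), Cpb(net.H2, B, T), Hb(net.H2, B, T);
  lstm_forward(net.Wb, net.Ub, net.bb, Hgmat, mask, B, T, true,
               Gb, Cb, TCb, Hpb, Cpb, Hb);

  const Mat<eT> Hfm(const_cast<eT*>(Hf.memptr()), net.H2, B * T, false);
  const Mat<eT> Hbm(const_cast<eT*>(Hb.memptr()), net.H2, B * T, false);
  Mat<eT> logits = net.Wo * join_cols(Hfm, Hbm);
  logits.each_col() += net.bo;
  logits.each_row() -= max(logits, 0);
  Mat<eT> P = exp(logits);
  P.each_row() /= sum(P, 0);

  cube out(net.C, B, T);
  mat Pd = conv_to<mat>::from(P);
  std::memcpy(out.memptr(), Pd.memptr(), sizeof(double) * Pd.n_elem);
  return out;
}

template <typename eT>
static List grad_impl(const Net<eT>& net, const cube& Xd, const imat& y,
                      const mat& maskd) {
  const uword B = Xd.n_cols, T = Xd.n_slices, C = net.C;
  const Cube<eT> X = conv_to<Cube<eT>>::from(Xd);
  const Mat<eT> mask = conv_to<Mat<eT>>::from(maskd);
  const Mat<eT> Xmat(const_cast<eT*>(X.memptr()), net.D, B * T, false);

  // forward with caches
  Cube<eT> G(3 * net.H1, B, T), RH(net.H1, B, T), Hp(net.H1, B, T),
           Hg(net.H1, B, T);
  gru_forward(net, Xmat, mask, B, T, G, RH, Hp, Hg);
  const Mat<eT> Hgmat(const_cast<eT*>(Hg.memptr()), net.H1, B * T, false);

  Cube<eT> Gf(4 * net.H2, B, T), Cf(net.H2, B, T), TCf(net.H2, B, T),
           Hpf(net.H2, B, T), Cpf(net.H2, B, T), Hf(net.H2, B, T);
  lstm_forward(net.Wf, net.Uf, net.bf, Hgmat, mask, B, T, false,
               Gf, Cf, TCf, Hpf, Cpf, Hf);
  Cube<eT> Gb(4 * net.H2, B, T), Cb(net.H2, B, T), TCb(net.H2, B, T),
           Hpb(net.H2, B, T), Cpb(net.H2, B, T), Hb(net.H2, B, T);
  lstm_forward(net.Wb, net.Ub, net.bb, Hgmat, mask, B, T, true,
               Gb, Cb, TCb, Hpb, Cpb, Hb);

  const Mat<eT> Hfm(const_cast<eT*>(Hf.memptr()), net.H2, B * T, false);
  const Mat<eT> Hbm(const_cast<eT*>(Hb.memptr()), net.H2, B * T, false);
  Mat<eT> Hcat = join_cols(Hfm, Hbm);          // 2H2 x BT
  Mat<eT> logits = net.Wo * Hcat;
  logits.each_col() += net.bo;
  logits.each_row() -= max(logits, 0);
  Mat<eT> P = exp(logits);
  P.each_row() /= sum(P, 0);

  // masked mean cross-entropy + argmax accuracy
  double nvalid = 0.0, lsum = 0.0;
  uword ncorrect = 0;
  Mat<eT> dlogits = P;
  for (uword t = 0; t < T; ++t) {
    for (uword b = 0; b < B; ++b) {
      const uword col = t * B + b;
      if (maskd(b, t) > 0.5) {
        const sword lab = y(b, t);
        nvalid += 1.0;
        lsum -= std::log(std::max((double)P(lab, col), 1e-12));
        dlogits(lab, col) -= eT(1);
        uword amax = 0;
        P.col(col).max(amax);
        if ((sword)amax == lab) ++ncorrect;
      } else {
        dlogits.col(col).zeros();
      }
    }
  }
  dlogits *= eT(1.0 / std::max(nvalid, 1.0));

  Mat<eT> dWo = dlogits * Hcat.t();
  Col<eT> dbo = sum(dlogits, 1);
  Mat<eT> dHcat = net.Wo.t() * dlogits;

  Mat<eT> dWf, dUf, dXf, dWb, dUb, dXb;
  Col<eT> dbf, dbb;
  lstm_backward(net.Wf, net.Uf, Hgmat, mask, B, T, false, Gf, Cf, TCf,
                Hpf, Cpf, Mat<eT>(dHcat.rows(0, net.H2 - 1)),
                dWf, dUf, dbf, dXf);
  lstm_backward(net.Wb, net.Ub, Hgmat, mask, B, T, true, Gb, Cb, TCb,
                Hpb, Cpb, Mat<eT>(dHcat.rows(net.H2, 2 * net.H2 - 1)),
                dWb, dUb, dbb, dXb);

  Mat<eT> dHg = dXf + dXb;
  Mat<eT> dWg, dUg;
  Col<eT> dbg;
  gru_backward(net, Xmat, mask, B, T, G, RH, Hp, dHg, dWg, dUg, dbg);

  List grads = List::create(
    Named("gru_W") = conv_to<mat>::from(dWg),
    Named("gru_U") = conv_to<mat>::from(dUg),
    Named("gru_b") = conv_to<vec>::from(dbg),
    Named("lstm_fw_W") = conv_to<mat>::from(dWf),
    Named("lstm_fw_U") = conv_to<mat>::from(dUf),
    Named("lstm_fw_b") = conv_to<vec>::from(dbf),
    Named("lstm_bw_W") = conv_to<mat>::from(dWb),
    Named("lstm_bw_U") = conv_to<mat>::from(dUb),
    Named("lstm_bw_b") = conv_to<vec>::from(dbb),
    Named("fc_W") = conv_to<mat>::from(dWo),
    Named("fc_b") = conv_to<vec>::from(dbo));

  return List::create(
    Named("loss") = lsum / std::max(nvalid, 1.0),
    Named("accuracy") = (double)ncorrect / std::max(nvalid, 1.0),
    Named("n_valid") = nvalid,
    Named("grads") = grads);
}

// [[Rcpp::export]]
arma::cube rnn_forward_cpp(Rcpp::List params, arma::cube X, arma::mat mask,
                           bool use_double = false) {
  if (use_double) {
    Net<double> net = net_from_list<double>(params);
    return forward_impl<double>(net, X, mask);
  }
  Net<float> net = net_from_list<float>(params);
  return forward_impl<float>(net, X, mask);
}

// [[Rcpp::export]]
Rcpp::List rnn_grad_cpp(Rcpp::List params, arma::cube X, arma::imat y,
                        arma::mat mask, bool use_double = false) {
  if (use_double) {
    Net<double> net = net_from_list<double>(params);
    return grad_impl<double>(net, X, y, mask);
  }
  Net<float> net = net_from_list<float>(params);
  return grad_impl<float>(net, X, y, mask);
}
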