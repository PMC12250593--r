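// Batched GRU forward / backward (BPTT) over a stack of layers, with an
// optional clinical-feature block concatenated to the final hidden state
// before the linear softmax head.
//
// Gate equations per layer and time step (sigma = logistic):
//   z_t = sigma(W_z x_t + U_z h_{t-1} + b_z)
//   r_t = sigma(W_r x_t + U_r h_{t-1} + b_r)
//   c_t = tanh(W_h x_t + U_h (r_t . h_{t-1}) + b_h)
//   h_t = (1 - z_t) . h_{t-1} + z_t . c_t
//
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigm(const mat& a) { return 1.0 / (1.0 + exp(-a)); }

// x:    cube, input_size x batch x time
// feat: matrix, n_features x batch (0 rows when fusion is off)
// layers: list of per-layer parameter lists (W_z,U_z,b_z,W_r,U_r,b_r,W_h,U_h,b_h)
// headW: n_classes x (hidden + n_features), headb: n_classes
// y: 1-based class indices (length 0 => no loss)
// [[Rcpp::export]]
Rcpp::List gru_batch_cpp(const arma::cube& x, const arma::mat& feat,
                         const Rcpp::List& layers, const arma::mat& headW,
                         const arma::vec& headb, const Rcpp::IntegerVector& y,
                         double smoothing, bool want_grad) {
  const uword T = x.n_slices, B = x.n_cols;
  const uword L = layers.size();
  const uword K = headW.n_rows;

  std::vector<mat> Wz(L), Uz(L), Wr(L), Ur(L), Wh(L), Uh(L);
  std::vector<vec> bz(L), br(L), bh(L);
  for (uword l = 0; l < L; ++l) {
    Rcpp::List p = layers[l];
    Wz[l] = Rcpp::as<mat>(p["W_z"]); Uz[l] = Rcpp::as<mat>(p["U_z"]);
    bz[l] = Rcpp::as<vec>(p["b_z"]);
    Wr[l] = Rcpp::as<mat>(p["W_r"]); Ur[l] = Rcpp::as<mat>(p["U_r"]);
    br[l] = Rcpp::as<vec>(p["b_r"]);
    Wh[l] = Rcpp::as<mat>(p["W_h"]); Uh[l] = Rcpp::as<mat>(p["U_h"]);
    bh[l] = Rcpp::as<vec>(p["b_h"]);
  }
  const uword H = Wz[0].n_rows;

  std::vector<cube> Hs(L), Zs(L), Rs(L), Cs(L);
  for (uword l = 0; l < L; ++l) {
    Hs[l] = cube(H, B, T + 1, fill::zeros);
    if (want_grad) {
      Zs[l] = cube(H, B, T);
      Rs[l] = cube(H, B, T);
      Cs[l] = cube(H, B, T);
    }
  }

  // forward
  for (uword t = 0; t < T; ++t) {
    mat inp = x.slice(t);
    for (uword l = 0; l < L; ++l) {
      const mat& hp = Hs[l].slice(t);
      mat az = Wz[l] * inp + Uz[l] * hp; az.each_col() += bz[l];
      mat z = sigm(az);
      mat ar = Wr[l] * inp + Ur[l] * hp; ar.each_col() += br[l];
      mat r = sigm(ar);
      mat ah = Wh[l] * inp + Uh[l] * (r % hp); ah.each_col() += bh[l];
      mat c = tanh(ah);
      mat h = (1.0 - z) % hp + z % c;
      Hs[l].slice(t + 1) = h;
      if (want_grad) {
        Zs[l].slice(t) = z; Rs[l].slice(t) = r; Cs[l].slice(t) = c;
      }
      inp = h;
    }
  }

  mat hT = Hs[L - 1].slice(T);
  mat rep = (feat.n_rows > 0) ? join_cols(hT, feat) : hT;
  mat logits = headW * rep; logits.each_col() += headb;

  rowvec mx = max(logits, 0);
  mat el = exp(logits.each_row() - mx);
  rowvec sm = sum(el, 0);
  mat P = el.each_row() / sm;

  double loss = NA_REAL;
  mat Q;
  if (y.size() > 0) {
    Q.set_size(K, B);
    Q.fill(smoothing / K);
    for (uword b = 0; b < B; ++b) Q(y[b] - 1, b) += 1.0 - smoothing;
    mat lp = log(clamp(P, 1e-12, 1.0));
    loss = -accu(Q % lp) / B;
  }

  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("probs") = P,
                              Rcpp::Named("loss") = loss);
  }

  // backward
  mat dlogits = (P - Q) / (double)B;
  mat gheadW = dlogits * rep.t();
  vec gheadb = sum(dlogits, 1);
  mat drep = headW.t() * dlogits;

  std::vector<mat> gWz(L), gUz(L), gWr(L), gUr(L), gWh(L), gUh(L);
  std::vector<vec> gbz(L), gbr(L), gbh(L);
  for (uword l = 0; l < L; ++l) {
    gWz[l].zeros(size(Wz[l])); gUz[l].zeros(size(Uz[l])); gbz[l].zeros(size(bz[l]));
    gWr[l].zeros(size(Wr[l])); gUr[l].zeros(size(Ur[l])); gbr[l].zeros(size(br[l]));
    gWh[l].zeros(size(Wh[l])); gUh[l].zeros(size(Uh[l])); gbh[l].zeros(size(bh[l]));
  }

  cube dX; // gradient w.r.t. the hidden outputs of the layer below
  for (int l = L - 1; l >= 0; --l) {
    cube dXbelow;
    if (l > 0) dXbelow.zeros(H, B, T);
    mat dh_next(H, B, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat dh = dh_next;
      if (l == (int)L - 1) {
        if (t == (int)T - 1) dh += drep.rows(0, H - 1);
      } else {
        dh += dX.slice(t);
      }
      const mat& z = Zs[l].slice(t);
      const mat& r = Rs[l].slice(t);
      const mat& c = Cs[l].slice(t);
      const mat& hp = Hs[l].slice(t);
      mat inp = (l == 0) ? x.slice(t) : Hs[l - 1].slice(t + 1);

      mat dc = dh % z;
      mat dz = dh % (c - hp);
      mat dhp = dh % (1.0 - z);

      mat dac = dc % (1.0 - c % c);
      gWh[l] += dac * inp.t();
      gUh[l] += dac * (r % hp).t();
      gbh[l] += sum(dac, 1);
      mat drh = Uh[l].t() * dac;
      mat dr = drh % hp;
      dhp += drh % r;

      mat daz = dz % (z % (1.0 - z));
      gWz[l] += daz * inp.t();
      gUz[l] += daz * hp.t();
      gbz[l] += sum(daz, 1);
      dhp += Uz[l].t() * daz;

      mat dar = dr % (r % (1.0 - r));
      gWr[l] += dar * inp.t();
      gUr[l] += dar * hp.t();
      gbr[l] += sum(dar, 1);
      dhp += Ur[l].t() * dar;

      if (l > 0) {
        dXbelow.slice(t) = Wz[l].t() * daz + Wr[l].t() * dar + Wh[l].t() * dac;
      }
      dh_next = dhp;
    }
    if (l > 0) dX = dXbelow;
  }

  Rcpp::List glayers(L);
  for (uword l = 0; l < L; ++l) {
    glayers[l] = Rcpp::List::create(
      Rcpp::Named("W_z") = gWz[l], Rcpp::Named("U_z") = gUz[l],
      Rcpp::Named("b_z") = gbz[l],
      Rcpp::Named("W_r") = gWr[l], Rcpp::Named("U_r") = gUr[l],
      Rcpp::Named("b_r") = gbr[l],
      Rcpp::Named("W_h") = gWh[l], Rcpp::Named("U_h") = gUh[l],
      Rcpp::Named("b_h") = gbh[l]);
  }
  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("layers") = glayers,
    Rcpp::Named("head") = Rcpp::List::create(
      Rcpp::Named("W") = gheadW, Rcpp::Named("b") = gheadb));

  return Rcpp::List::create(
    Rcpp::Named("probs") = P,
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = grads);
}
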