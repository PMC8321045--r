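// Recurrent encoder core: stacked (optionally bidirectional) LSTM forward
// pass, backpropagation through time, softmax classification head, and the
// two training objectives (weighted cross-entropy; margin triplet hinge).
//
// Parameters live in one flat vector so the optimizer can treat the model as
// a single point in R^P. Layout, for layer l = 0..L-1 and direction
// d = 0..ndir-1 (0 = forward in time, 1 = reverse):
//   W_{l,d} : in_l x 4H   (input -> gates; in_0 = B, in_l = H*ndir for l>0)
//   U_{l,d} : H    x 4H   (hidden -> gates)
//   b_{l,d} : 4H
// followed by the fully connected head W_fc : E x n, b_fc : n, with
// E = H*ndir. Gate column blocks are ordered [input | forget | cell | output].
//
// Time series enter as cubes of shape N x B x T (samples x bands x steps).
// The embedding f(x) is the concatenation of the last-step hidden states of
// the two directions of the top layer (the reverse direction's last processed
// step sits at original time 0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double LOG_EPS = 1e-12; // clamp for log() on confident wrong predictions

struct Dims {
  int B, H, L, n, ndir, E;
};

Dims make_dims(int B, int H, int L, bool bidir, int n) {
  Dims d;
  d.B = B;
  d.H = H;
  d.L = L;
  d.n = n;
  d.ndir = bidir ? 2 : 1;
  d.E = H * d.ndir;
  return d;
}

int unit_in(const Dims& d, int l) { return l == 0 ? d.B : d.H * d.ndir; }

int unit_size(const Dims& d, int l) {
  return unit_in(d, l) * 4 * d.H + d.H * 4 * d.H + 4 * d.H;
}

// offset of the (l, dir) parameter block; (L, 0) addresses the FC head
int unit_offset(const Dims& d, int l, int dir) {
  int off = 0;
  for (int ll = 0; ll < d.L; ++ll)
    for (int dd = 0; dd < d.ndir; ++dd) {
      if (ll == l && dd == dir) return off;
      off += unit_size(d, ll);
    }
  return off;
}

int total_params(const Dims& d) {
  return unit_offset(d, d.L, 0) + d.E * d.n + d.n;
}

// non-owning matrix view into a parameter (or gradient) vector
mat view(const vec& v, int off, int r, int c) {
  return mat(const_cast<double*>(v.memptr()) + off, r, c, false, true);
}

mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache {
  cube I, F, G, O, TC, C; // gate activations, tanh(c), cell state; N x H x T
};

struct Forward {
  mat emb;                      // N x E
  std::vector<cube> layer_out;  // per layer: N x (H*ndir) x T
  std::vector<DirCache> caches; // indexed l * ndir + d
};

void check_dims(const cube& X, const Dims& dm, const vec& params) {
  if ((int)X.n_cols != dm.B)
    Rcpp::stop("input has %d bands but the encoder expects %d",
               (int)X.n_cols, dm.B);
  if ((int)params.n_elem != total_params(dm))
    Rcpp::stop("parameter vector has length %d, expected %d",
               (int)params.n_elem, total_params(dm));
}

Forward encoder_forward(const cube& X, const vec& params, const Dims& dm,
                        bool need_cache) {
  const int N = X.n_rows, T = X.n_slices, H = dm.H;
  Forward fr;
  fr.emb.set_size(N, dm.E);
  fr.layer_out.resize(dm.L);
  if (need_cache) fr.caches.resize(dm.L * dm.ndir);

  for (int l = 0; l < dm.L; ++l) {
    const cube& LI = (l == 0) ? X : fr.layer_out[l - 1];
    fr.layer_out[l].set_size(N, dm.E, T);
    for (int d = 0; d < dm.ndir; ++d) {
      const int off = unit_offset(dm, l, d);
      const int in = unit_in(dm, l);
      mat W = view(params, off, in, 4 * H);
      mat U = view(params, off + in * 4 * H, H, 4 * H);
      rowvec b(const_cast<double*>(params.memptr()) + off + (in + H) * 4 * H,
               4 * H, false, true);

      DirCache* cc = need_cache ? &fr.caches[l * dm.ndir + d] : nullptr;
      if (cc) {
        cc->I.set_size(N, H, T); cc->F.set_size(N, H, T);
        cc->G.set_size(N, H, T); cc->O.set_size(N, H, T);
        cc->TC.set_size(N, H, T); cc->C.set_size(N, H, T);
      }

      mat h(N, H, fill::zeros), c(N, H, fill::zeros);
      for (int s = 0; s < T; ++s) {
        const int t = (d == 0) ? s : T - 1 - s;
        mat Gt = LI.slice(t) * W + h * U;
        Gt.each_row() += b;
        mat Ig = sigmoid(Gt.cols(0, H - 1));
        mat Fg = sigmoid(Gt.cols(H, 2 * H - 1));
        mat Gg = tanh(Gt.cols(2 * H, 3 * H - 1));
        mat Og = sigmoid(Gt.cols(3 * H, 4 * H - 1));
        c = Fg % c + Ig % Gg;
        mat tc = tanh(c);
        h = Og % tc;
        fr.layer_out[l].slice(t).cols(d * H, d * H + H - 1) = h;
        if (cc) {
          cc->I.slice(t) = Ig; cc->F.slice(t) = Fg;
          cc->G.slice(t) = Gg; cc->O.slice(t) = Og;
          cc->TC.slice(t) = tc; cc->C.slice(t) = c;
        }
      }
      if (l == dm.L - 1) fr.emb.cols(d * H, d * H + H - 1) = h;
    }
  }
  return fr;
}

// Backpropagate dEmb (N x E) through the encoder; gate/FC gradients are
// accumulated into `grad` (same layout and length as the parameter vector).
void encoder_backward(const cube& X, const vec& params, const Dims& dm,
                      const Forward& fr, const mat& dEmb, vec& grad) {
  const int N = X.n_rows, T = X.n_slices, H = dm.H;

  // gradient w.r.t. the top layer's output sequence: only the final processed
  // step of each direction feeds the embedding
  cube dLO(N, dm.E, T, fill::zeros);
  for (int d = 0; d < dm.ndir; ++d) {
    const int tf = (d == 0) ? T - 1 : 0;
    dLO.slice(tf).cols(d * H, d * H + H - 1) += dEmb.cols(d * H, d * H + H - 1);
  }

  for (int l = dm.L - 1; l >= 0; --l) {
    const cube& LI = (l == 0) ? X : fr.layer_out[l - 1];
    const int in = unit_in(dm, l);
    cube dLI;
    if (l > 0) dLI.zeros(N, in, T);

    for (int d = 0; d < dm.ndir; ++d) {
      const int off = unit_offset(dm, l, d);
      mat W = view(params, off, in, 4 * H);
      mat U = view(params, off + in * 4 * H, H, 4 * H);
      mat gW = view(grad, off, in, 4 * H);
      mat gU = view(grad, off + in * 4 * H, H, 4 * H);
      rowvec gb(grad.memptr() + off + (in + H) * 4 * H, 4 * H, false, true);
      const DirCache& cc = fr.caches[l * dm.ndir + d];

      mat dh_carry(N, H, fill::zeros), dc_carry(N, H, fill::zeros);
      mat dGates(N, 4 * H);
      for (int s = T - 1; s >= 0; --s) {
        const int t = (d == 0) ? s : T - 1 - s;
        const int tprev = (d == 0) ? t - 1 : t + 1; // previous processed step
        const bool first = (s == 0);

        mat dh = dh_carry + dLO.slice(t).cols(d * H, d * H + H - 1);
        const mat& tc = cc.TC.slice(t);
        const mat& Og = cc.O.slice(t);
        mat dc = dc_carry + dh % Og % (1.0 - tc % tc);

        const mat& Ig = cc.I.slice(t);
        const mat& Fg = cc.F.slice(t);
        const mat& Gg = cc.G.slice(t);
        dGates.cols(0, H - 1)         = (dc % Gg) % Ig % (1.0 - Ig);
        if (first)
          dGates.cols(H, 2 * H - 1).zeros(); // c_{-1} = 0: forget gate idle
        else
          dGates.cols(H, 2 * H - 1)   = (dc % cc.C.slice(tprev)) % Fg % (1.0 - Fg);
        dGates.cols(2 * H, 3 * H - 1) = (dc % Ig) % (1.0 - Gg % Gg);
        dGates.cols(3 * H, 4 * H - 1) = (dh % tc) % Og % (1.0 - Og);

        gW += LI.slice(t).t() * dGates;
        if (!first) {
          const mat hprev =
              fr.layer_out[l].slice(tprev).cols(d * H, d * H + H - 1);
          gU += hprev.t() * dGates;
        }
        gb += sum(dGates, 0);
        if (l > 0) dLI.slice(t) += dGates * W.t();

        dh_carry = dGates * U.t();
        dc_carry = dc % Fg;
      }
    }
    if (l > 0) dLO = dLI;
  }
}

mat softmax_probs(const mat& emb, const vec& params, const Dims& dm) {
  const int off = unit_offset(dm, dm.L, 0);
  mat Wfc = view(params, off, dm.E, dm.n);
  rowvec bfc(const_cast<double*>(params.memptr()) + off + dm.E * dm.n,
             dm.n, false, true);
  mat Z = emb * Wfc;
  Z.each_row() += bfc;
  Z.each_col() -= max(Z, 1);
  mat P = exp(Z);
  P.each_col() /= sum(P, 1);
  return P;
}

// Mean weighted cross-entropy over the batch plus its gradients.
// dEmb_out is accumulated (+=); FC gradients go into `grad`.
// `mask` (possibly empty) is an inverted-dropout mask on the head input.
double ce_forward_backward(const mat& emb, const Rcpp::IntegerVector& y,
                           const vec& w, const vec& params, const Dims& dm,
                           const mat& mask, mat& dEmb_out, vec& grad) {
  const int N = emb.n_rows;
  const int off = unit_offset(dm, dm.L, 0);
  mat Wfc = view(params, off, dm.E, dm.n);
  mat gWfc = view(grad, off, dm.E, dm.n);
  rowvec gbfc(grad.memptr() + off + dm.E * dm.n, dm.n, false, true);

  const bool drop = mask.n_elem > 0;
  mat ein = drop ? mat(emb % mask) : emb;
  mat P = softmax_probs(ein, params, dm);

  double loss = 0.0;
  mat dZ = P;
  for (int i = 0; i < N; ++i) {
    const int k = y[i];
    if (k < 0 || k >= dm.n) Rcpp::stop("label %d outside [0, %d)", k, dm.n);
    loss += -w[k] * std::log(std::max(P(i, k), LOG_EPS));
    dZ(i, k) -= 1.0;
    dZ.row(i) *= w[k] / N;
  }
  gWfc += ein.t() * dZ;
  gbfc += sum(dZ, 0);
  mat de = dZ * Wfc.t();
  if (drop) de %= mask;
  dEmb_out += de;
  return loss / N;
}

cube as_cube(const Rcpp::NumericVector& a) {
  Rcpp::IntegerVector d = a.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array (samples x bands x steps)");
  return cube(const_cast<double*>(a.begin()), d[0], d[1], d[2], false, true);
}

} // namespace

// [[Rcpp::export]]
int cpp_n_params(int B, int H, int L, bool bidir, int n_classes) {
  return total_params(make_dims(B, H, L, bidir, n_classes));
}

// [[Rcpp::export]]
arma::mat cpp_encode(Rcpp::NumericVector X, const arma::vec& params,
                     int B, int H, int L, bool bidir, int n_classes) {
  const Dims dm = make_dims(B, H, L, bidir, n_classes);
  cube Xc = as_cube(X);
  check_dims(Xc, dm, params);
  return encoder_forward(Xc, params, dm, false).emb;
}

// [[Rcpp::export]]
arma::mat cpp_classify(const arma::mat& emb, const arma::vec& params,
                       int B, int H, int L, bool bidir, int n_classes) {
  const Dims dm = make_dims(B, H, L, bidir, n_classes);
  if ((int)emb.n_cols != dm.E)
    Rcpp::stop("embedding has dimension %d but the model expects %d",
               (int)emb.n_cols, dm.E);
  if ((int)params.n_elem != total_params(dm))
    Rcpp::stop("parameter vector has length %d, expected %d",
               (int)params.n_elem, total_params(dm));
  return softmax_probs(emb, params, dm);
}

// Single-branch step: mean weighted cross-entropy over the batch.
// [[Rcpp::export]]
Rcpp::List cpp_ce_step(Rcpp::NumericVector X, Rcpp::IntegerVector y,
                       const arma::vec& params, const arma::vec& w,
                       int B, int H, int L, bool bidir, int n_classes,
                       Rcpp::Nullable<Rcpp::NumericMatrix> dropout_mask =
                           R_NilValue) {
  const Dims dm = make_dims(B, H, L, bidir, n_classes);
  cube Xc = as_cube(X);
  check_dims(Xc, dm, params);

  Forward fr = encoder_forward(Xc, params, dm, true);
  vec grad(total_params(dm), fill::zeros);
  mat dEmb(Xc.n_rows, dm.E, fill::zeros);
  mat mask;
  if (dropout_mask.isNotNull()) mask = Rcpp::as<mat>(dropout_mask.get());
  const double loss =
      ce_forward_backward(fr.emb, y, w, params, dm, mask, dEmb, grad);
  encoder_backward(Xc, params, dm, fr, dEmb, grad);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// Triplet step. Batch objective (mean over the N triplets of the batch):
//   L = mean CE(positive) + mean CE(anchor) + mean CE(negative)
//       + lambda * mean max(0, D(a,p) - D(a,n) + margin)
// with D the (non-squared) Euclidean distance between embeddings. The three
// branch roles are evaluated with the one shared parameter vector.
// [[Rcpp::export]]
Rcpp::List cpp_triplet_step(Rcpp::NumericVector Xa, Rcpp::NumericVector Xp,
                            Rcpp::NumericVector Xn, Rcpp::IntegerVector ya,
                            Rcpp::IntegerVector yp, Rcpp::IntegerVector yn,
                            const arma::vec& params, const arma::vec& w,
                            double lambda, double margin,
                            int B, int H, int L, bool bidir, int n_classes,
                            Rcpp::Nullable<Rcpp::List> dropout_masks =
                                R_NilValue) {
  const Dims dm = make_dims(B, H, L, bidir, n_classes);
  cube Ca = as_cube(Xa), Cp = as_cube(Xp), Cn = as_cube(Xn);
  check_dims(Ca, dm, params);
  if (Cp.n_rows != Ca.n_rows || Cn.n_rows != Ca.n_rows)
    Rcpp::stop("anchor, positive and negative batches must have equal size");
  const int N = Ca.n_rows;

  Forward fa = encoder_forward(Ca, params, dm, true);
  Forward fp = encoder_forward(Cp, params, dm, true);
  Forward fn = encoder_forward(Cn, params, dm, true);

  mat ma, mp, mn;
  if (dropout_masks.isNotNull()) {
    Rcpp::List dl(dropout_masks.get());
    ma = Rcpp::as<mat>(dl["anchor"]);
    mp = Rcpp::as<mat>(dl["positive"]);
    mn = Rcpp::as<mat>(dl["negative"]);
  }

  vec grad(total_params(dm), fill::zeros);
  mat dEa(N, dm.E, fill::zeros), dEp(N, dm.E, fill::zeros),
      dEn(N, dm.E, fill::zeros);
  const double ce_a =
      ce_forward_backward(fa.emb, ya, w, params, dm, ma, dEa, grad);
  const double ce_p =
      ce_forward_backward(fp.emb, yp, w, params, dm, mp, dEp, grad);
  const double ce_n =
      ce_forward_backward(fn.emb, yn, w, params, dm, mn, dEn, grad);

  // margin hinge on embedding distances; subgradient 0 at D == 0 and at the
  // hinge kink
  mat diff_ap = fa.emb - fp.emb;
  mat diff_an = fa.emb - fn.emb;
  vec d_ap = sqrt(sum(square(diff_ap), 1));
  vec d_an = sqrt(sum(square(diff_an), 1));
  vec hinge = d_ap - d_an + margin;
  double margin_loss = 0.0;
  vec s_ap(N, fill::zeros), s_an(N, fill::zeros);
  for (int i = 0; i < N; ++i) {
    if (hinge[i] > 0) {
      margin_loss += hinge[i];
      if (d_ap[i] > 0) s_ap[i] = lambda / (N * d_ap[i]);
      if (d_an[i] > 0) s_an[i] = lambda / (N * d_an[i]);
    }
  }
  margin_loss /= N;
  mat g_ap = diff_ap.each_col() % s_ap;
  mat g_an = diff_an.each_col() % s_an;
  dEa += g_ap - g_an;
  dEp -= g_ap;
  dEn += g_an;

  encoder_backward(Ca, params, dm, fa, dEa, grad);
  encoder_backward(Cp, params, dm, fp, dEp, grad);
  encoder_backward(Cn, params, dm, fn, dEn, grad);

  const double ce_sum = ce_a + ce_p + ce_n;
  return Rcpp::List::create(
      Rcpp::Named("grad") = grad,
      Rcpp::Named("ce_sum") = ce_sum,
      Rcpp::Named("margin_loss") = margin_loss,
      Rcpp::Named("total") = ce_sum + lambda * margin_loss);
}
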