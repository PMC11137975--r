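// Gated recurrent unit (GRU) feature extractor: forward pass, max-pooling
// over the hidden axis, sigmoid classification head, and full
// backpropagation through time.  One batch per call; the optimiser and
// epoch loop live on the R side so that all randomness flows through R's
// RNG and results are reproducible from a single seed.
//
// Cell equations (update gate u, reset gate r, candidate state hc):
//   u_t  = sigmoid(Wu_h h_{t-1} + Wu_x x_t + bu)
//   r_t  = sigmoid(Wr_h h_{t-1} + Wr_x x_t + br)
//   hc_t = tanh(Wc_h (r_t . h_{t-1}) + Wc_x x_t + bc)
//   h_t  = u_t . hc_t + (1 - u_t) . h_{t-1}
// "." is the Hadamard product.  Tokens are integers 0..5 (0 = pad,
// 1..4 = A,C,G,T, 5 = N); padding participates (no masking).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GruDirParams {
  arma::mat Wu_h, Wu_x, Wr_h, Wr_x, Wc_h, Wc_x;
  arma::vec bu, br, bc;
};

GruDirParams dir_params(const List& p, const std::string& suffix) {
  GruDirParams g;
  g.Wu_h = as<arma::mat>(p["Wu_h" + suffix]);
  g.Wu_x = as<arma::mat>(p["Wu_x" + suffix]);
  g.Wr_h = as<arma::mat>(p["Wr_h" + suffix]);
  g.Wr_x = as<arma::mat>(p["Wr_x" + suffix]);
  g.Wc_h = as<arma::mat>(p["Wc_h" + suffix]);
  g.Wc_x = as<arma::mat>(p["Wc_x" + suffix]);
  g.bu = as<arma::vec>(p["bu" + suffix]);
  g.br = as<arma::vec>(p["br" + suffix]);
  g.bc = as<arma::vec>(p["bc" + suffix]);
  return g;
}

struct DirCache {
  arma::cube u, r, hc, h;  // H x B x L, h(.,.,t) is the state after step t
};

// Run one direction over the token matrix.  `reverse` walks the sequence
// 3'->5' (the backward half of a Bi-GRU); its hidden state stored at slice
// t always corresponds to sequence position t so pooling can align the
// two directions position-wise.
DirCache run_direction(const GruDirParams& g, const arma::mat& E,
                       const arma::imat& X, bool reverse) {
  const arma::uword L = X.n_rows, B = X.n_cols, H = g.bu.n_elem;
  DirCache c;
  c.u.set_size(H, B, L);
  c.r.set_size(H, B, L);
  c.hc.set_size(H, B, L);
  c.h.set_size(H, B, L);
  arma::mat h_prev(H, B, arma::fill::zeros);
  for (arma::uword s = 0; s < L; ++s) {
    arma::uword t = reverse ? (L - 1 - s) : s;
    arma::mat x(E.n_rows, B);
    for (arma::uword b = 0; b < B; ++b) x.col(b) = E.col(X(t, b));
    arma::mat u = 1.0 / (1.0 + arma::exp(-(g.Wu_h * h_prev + g.Wu_x * x +
                                           arma::repmat(g.bu, 1, B))));
    arma::mat r = 1.0 / (1.0 + arma::exp(-(g.Wr_h * h_prev + g.Wr_x * x +
                                           arma::repmat(g.br, 1, B))));
    arma::mat hc = arma::tanh(g.Wc_h * (r % h_prev) + g.Wc_x * x +
                              arma::repmat(g.bc, 1, B));
    arma::mat h = u % hc + (1.0 - u) % h_prev;
    c.u.slice(t) = u;
    c.r.slice(t) = r;
    c.hc.slice(t) = hc;
    c.h.slice(t) = h;
    h_prev = h;
  }
  return c;
}

struct DirGrads {
  arma::mat Wu_h, Wu_x, Wr_h, Wr_x, Wc_h, Wc_x;
  arma::vec bu, br, bc;
  arma::mat E;  // d_emb x 6, shared accumulator handled by caller via +=
};

// Backprop one direction given dh injected at every position from the
// pooling layer (dh_inj: H x B x L, aligned to sequence positions).
DirGrads backprop_direction(const GruDirParams& g, const arma::mat& E,
                            const arma::imat& X, const DirCache& c,
                            const arma::cube& dh_inj, bool reverse) {
  const arma::uword L = X.n_rows, B = X.n_cols, H = g.bu.n_elem,
                    D = E.n_rows;
  DirGrads gr;
  gr.Wu_h.zeros(H, H); gr.Wu_x.zeros(H, D);
  gr.Wr_h.zeros(H, H); gr.Wr_x.zeros(H, D);
  gr.Wc_h.zeros(H, H); gr.Wc_x.zeros(H, D);
  gr.bu.zeros(H); gr.br.zeros(H); gr.bc.zeros(H);
  gr.E.zeros(D, E.n_cols);
  arma::mat dh_next(H, B, arma::fill::zeros);
  for (arma::uword s = 0; s < L; ++s) {
    // walk processing order in reverse
    arma::uword t = reverse ? s : (L - 1 - s);
    // processing-order predecessor position
    arma::mat h_prev;
    bool first = (s == L - 1);
    if (first) {
      h_prev.zeros(H, B);
    } else {
      arma::uword tp = reverse ? (t + 1) : (t - 1);
      h_prev = c.h.slice(tp);
    }
    const arma::mat& u = c.u.slice(t);
    const arma::mat& r = c.r.slice(t);
    const arma::mat& hc = c.hc.slice(t);
    arma::mat x(D, B);
    for (arma::uword b = 0; b < B; ++b) x.col(b) = E.col(X(t, b));

    arma::mat dh = dh_inj.slice(t) + dh_next;
    arma::mat da_u = dh % (hc - h_prev) % u % (1.0 - u);
    arma::mat da_c = (dh % u) % (1.0 - hc % hc);
    arma::mat drh = g.Wc_h.t() * da_c;
    arma::mat da_r = (drh % h_prev) % r % (1.0 - r);

    gr.Wu_h += da_u * h_prev.t();
    gr.Wu_x += da_u * x.t();
    gr.bu += arma::sum(da_u, 1);
    gr.Wr_h += da_r * h_prev.t();
    gr.Wr_x += da_r * x.t();
    gr.br += arma::sum(da_r, 1);
    gr.Wc_h += da_c * (r % h_prev).t();
    gr.Wc_x += da_c * x.t();
    gr.bc += arma::sum(da_c, 1);

    arma::mat dx = g.Wu_x.t() * da_u + g.Wr_x.t() * da_r + g.Wc_x.t() * da_c;
    for (arma::uword b = 0; b < B; ++b) gr.E.col(X(t, b)) += dx.col(b);

    dh_next = dh % (1.0 - u) + drh % r + g.Wu_h.t() * da_u +
              g.Wr_h.t() * da_r;
  }
  return gr;
}

}  // namespace

// Forward (and optionally backward) pass for one minibatch.
//
// params: named list with E (d_emb x 6), per-direction gate weights
//   (suffix "" forward, "_b" backward when bidirectional), head_w (L),
//   head_b (scalar).
// X: L x B integer token matrix.  y: length-B 0/1 labels (may be empty
//   when compute_grad = false).
//
// The two staged max-pools over the hidden axis followed by the final
// collapse compose to a single max over all hidden channels per position,
// which is how they are evaluated here; gradients route to the argmax.
// [[Rcpp::export]]
List gru_batch_cpp(const List& params, const arma::imat& X,
                   const arma::vec& y, bool bidirectional,
                   bool compute_grad) {
  const arma::uword L = X.n_rows, B = X.n_cols;
  arma::mat E = as<arma::mat>(params["E"]);
  GruDirParams gf = dir_params(params, "");
  DirCache cf = run_direction(gf, E, X, false);
  GruDirParams gb;
  DirCache cb;
  if (bidirectional) {
    gb = dir_params(params, "_b");
    cb = run_direction(gb, E, X, true);
  }
  const arma::uword H = gf.bu.n_elem;
  const arma::uword C = bidirectional ? 2 * H : H;  // channels per position

  // Pooled features: one value per sequence position.
  arma::mat F(L, B);
  arma::umat amax(L, B);  // winning channel in [0, C)
  for (arma::uword t = 0; t < L; ++t) {
    for (arma::uword b = 0; b < B; ++b) {
      arma::vec chan(C);
      chan.subvec(0, H - 1) = cf.h.slice(t).col(b);
      if (bidirectional) chan.subvec(H, 2 * H - 1) = cb.h.slice(t).col(b);
      arma::uword j = chan.index_max();
      amax(t, b) = j;
      F(t, b) = chan(j);
    }
  }

  arma::vec head_w = as<arma::vec>(params["head_w"]);
  double head_b = as<double>(params["head_b"]);
  arma::vec z = F.t() * head_w + head_b;
  arma::vec p = 1.0 / (1.0 + arma::exp(-z));

  double loss = NA_REAL;
  if (y.n_elem == B) {
    const double eps = 1e-12;
    loss = -arma::mean(y % arma::log(p + eps) +
                       (1.0 - y) % arma::log(1.0 - p + eps));
  }

  List out = List::create(Named("features") = F, Named("prob") = p,
                          Named("loss") = loss);
  if (!compute_grad) return out;
  if (y.n_elem != B) stop("labels required when compute_grad = TRUE");

  arma::vec dz = (p - y) / static_cast<double>(B);
  arma::vec g_head_w = F * dz;
  double g_head_b = arma::sum(dz);

  // Route pooled-feature gradients back to the winning hidden channel.
  arma::cube dhf(H, B, L, arma::fill::zeros);
  arma::cube dhb;
  if (bidirectional) dhb.zeros(H, B, L);
  for (arma::uword t = 0; t < L; ++t) {
    for (arma::uword b = 0; b < B; ++b) {
      double dF = head_w(t) * dz(b);
      arma::uword j = amax(t, b);
      if (j < H) dhf(j, b, t) += dF;
      else dhb(j - H, b, t) += dF;
    }
  }

  DirGrads grf = backprop_direction(gf, E, X, cf, dhf, false);
  arma::mat gE = grf.E;
  List grads = List::create(
      Named("Wu_h") = grf.Wu_h, Named("Wu_x") = grf.Wu_x,
      Named("Wr_h") = grf.Wr_h, Named("Wr_x") = grf.Wr_x,
      Named("Wc_h") = grf.Wc_h, Named("Wc_x") = grf.Wc_x,
      Named("bu") = grf.bu, Named("br") = grf.br, Named("bc") = grf.bc);
  if (bidirectional) {
    DirGrads grb = backprop_direction(gb, E, X, cb, dhb, true);
    gE += grb.E;
    grads["Wu_h_b"] = grb.Wu_h; grads["Wu_x_b"] = grb.Wu_x;
    grads["Wr_h_b"] = grb.Wr_h; grads["Wr_x_b"] = grb.Wr_x;
    grads["Wc_h_b"] = grb.Wc_h; grads["Wc_x_b"] = grb.Wc_x;
    grads["bu_b"] = grb.bu; grads["br_b"] = grb.br; grads["bc_b"] = grb.bc;
  }
  grads["E"] = gE;
  grads["head_w"] = g_head_w;
  grads["head_b"] = g_head_b;
  out["grads"] = grads;
  return out;
}
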