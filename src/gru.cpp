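// Stacked 1-directional GRU: forward pass and backpropagation through time.
//
// Gate layout follows the common convention: the 3h-row weight matrices
// stack the reset (r), update (z) and candidate (n) blocks, and the
// candidate uses the reset gate on the recurrent contribution:
//   r_t = sigmoid(Wx_r x_t + bx_r + Wh_r h_{t-1} + bh_r)
//   z_t = sigmoid(Wx_z x_t + bx_z + Wh_z h_{t-1} + bh_z)
//   g_t = Wh_n h_{t-1} + bh_n
//   n_t = tanh(Wx_n x_t + bx_n + r_t % g_t)
//   h_t = (1 - z_t) % n_t + z_t % h_{t-1}
// Sequences are processed at their native length (T x d input matrix,
// rows = frames); the initial hidden state is zero. The input-side affine
// maps are hoisted out of the time loop as single matrix products; only
// the recurrent contribution is computed stepwise.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward pass through all layers.
// layers: list of list(Wx [3h x d], Wh [3h x h], bx [3h], bh [3h])
// Returns per-layer hidden states H (T x h) and gate caches R, Z, N, G
// needed by the backward pass.
// [[Rcpp::export(name = ".gru_forward_cpp")]]
List gru_forward_cpp(const arma::mat& X, const List& layers) {
  const arma::uword T = X.n_rows;
  const int L = layers.size();
  List Hs(L), Rs(L), Zs(L), Ns(L), Gs(L);
  arma::mat input_t = X.t();  // d x T, columns are frames
  for (int l = 0; l < L; ++l) {
    List lay = layers[l];
    arma::mat Wx = lay["Wx"], Wh = lay["Wh"];
    arma::vec bx = lay["bx"], bh = lay["bh"];
    const arma::uword h = Wh.n_cols;
    // input-side pre-activations for all frames at once
    arma::mat A = Wx * input_t;        // 3h x T
    A.each_col() += bx;
    arma::mat H(h, T), R(h, T), Z(h, T), N(h, T), G(h, T);
    arma::vec hprev(h, arma::fill::zeros);
    for (arma::uword t = 0; t < T; ++t) {
      arma::vec ah = Wh * hprev + bh;
      arma::vec r = 1.0 / (1.0 + arma::exp(-(A.col(t).subvec(0, h - 1) +
                                             ah.subvec(0, h - 1))));
      arma::vec z = 1.0 / (1.0 + arma::exp(-(A.col(t).subvec(h, 2 * h - 1) +
                                             ah.subvec(h, 2 * h - 1))));
      arma::vec g = ah.subvec(2 * h, 3 * h - 1);
      arma::vec n = arma::tanh(A.col(t).subvec(2 * h, 3 * h - 1) + r % g);
      hprev = (1.0 - z) % n + z % hprev;
      R.col(t) = r; Z.col(t) = z; N.col(t) = n; G.col(t) = g;
      H.col(t) = hprev;
    }
    Hs[l] = arma::mat(H.t()); Rs[l] = arma::mat(R.t()); Zs[l] = arma::mat(Z.t());
    Ns[l] = arma::mat(N.t()); Gs[l] = arma::mat(G.t());
    input_t = H;  // feed next layer (h x T)
  }
  return List::create(_["H"] = Hs, _["R"] = Rs, _["Z"] = Zs,
                      _["N"] = Ns, _["G"] = Gs);
}

// Backward pass. dHtop is the T x h gradient of the loss with respect to
// the top layer's hidden state at every frame. Returns per-layer parameter
// gradients and the gradient with respect to the input sequence.
// [[Rcpp::export(name = ".gru_backward_cpp")]]
List gru_backward_cpp(const arma::mat& X, const List& layers,
                      const List& cache, const arma::mat& dHtop) {
  const arma::uword T = X.n_rows;
  const int L = layers.size();
  List Hs = cache["H"], Rs = cache["R"], Zs = cache["Z"],
       Ns = cache["N"], Gs = cache["G"];
  List grads(L);
  arma::mat dH_ext = dHtop.t();  // h x T, external gradient into layer l
  for (int l = L - 1; l >= 0; --l) {
    List lay = layers[l];
    arma::mat Wx = lay["Wx"], Wh = lay["Wh"];
    arma::mat H = as<arma::mat>(Hs[l]).t();   // h x T
    arma::mat R = as<arma::mat>(Rs[l]).t(), Z = as<arma::mat>(Zs[l]).t(),
              N = as<arma::mat>(Ns[l]).t(), G = as<arma::mat>(Gs[l]).t();
    const arma::uword h = Wh.n_cols;
    arma::mat input_t = (l == 0) ? arma::mat(X.t())
                                 : arma::mat(as<arma::mat>(Hs[l - 1]).t());

    // per-frame pre-activation gradients, filled in the reverse loop
    arma::mat DA(3 * h, T);   // rows: [da_r; da_z; da_n] -> dWx, dbx
    arma::mat DB(3 * h, T);   // rows: [da_r; da_z; dg]   -> dWh, dbh
    arma::vec dh_future(h, arma::fill::zeros);
    const arma::mat Whr_t = Wh.rows(0, h - 1).t();
    const arma::mat Whz_t = Wh.rows(h, 2 * h - 1).t();
    const arma::mat Whn_t = Wh.rows(2 * h, 3 * h - 1).t();
    for (arma::uword t = T; t-- > 0;) {
      arma::vec dht = dH_ext.col(t) + dh_future;
      arma::vec hprev = (t > 0) ? arma::vec(H.col(t - 1))
                                : arma::vec(h, arma::fill::zeros);
      arma::vec r = R.col(t), z = Z.col(t), n = N.col(t), g = G.col(t);
      arma::vec dn = dht % (1.0 - z);
      arma::vec dz = dht % (hprev - n);
      arma::vec da_n = dn % (1.0 - n % n);   // pre-tanh
      arma::vec dr = da_n % g;
      arma::vec dg = da_n % r;               // grad of Wh_n hprev + bh_n
      arma::vec da_z = dz % z % (1.0 - z);
      arma::vec da_r = dr % r % (1.0 - r);
      DA.col(t).subvec(0, h - 1) = da_r;
      DA.col(t).subvec(h, 2 * h - 1) = da_z;
      DA.col(t).subvec(2 * h, 3 * h - 1) = da_n;
      DB.col(t).subvec(0, h - 1) = da_r;
      DB.col(t).subvec(h, 2 * h - 1) = da_z;
      DB.col(t).subvec(2 * h, 3 * h - 1) = dg;
      dh_future = dht % z + Whr_t * da_r + Whz_t * da_z + Whn_t * dg;
    }
    // batched parameter and input gradients
    arma::mat Hprev(h, T, arma::fill::zeros);        // h_{t-1} columns
    if (T > 1) Hprev.cols(1, T - 1) = H.cols(0, T - 2);
    arma::mat dWx = DA * input_t.t();
    arma::mat dWh = DB * Hprev.t();
    arma::vec dbx = arma::sum(DA, 1);
    arma::vec dbh = arma::sum(DB, 1);
    arma::mat dInput = Wx.t() * DA;                  // d x T
    grads[l] = List::create(_["Wx"] = dWx, _["Wh"] = dWh,
                            _["bx"] = dbx, _["bh"] = dbh);
    dH_ext = dInput;
  }
  return List::create(_["layers"] = grads, _["dX"] = arma::mat(dH_ext.t()));
}
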