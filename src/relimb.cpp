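// Numerical core: IIR filtering (direct form II transposed) and a 3-layer
// LSTM sequence-to-sequence regressor trained with Adam. The C++ side is
// RNG-free: weight initialization and batch shuffling happen in R, so results
// are a pure function of the supplied weights and batch order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector cpp_iir_filter(Rcpp::NumericVector b_, Rcpp::NumericVector a_,
                                   Rcpp::NumericVector x_, Rcpp::NumericVector zi_) {
  vec b = Rcpp::as<vec>(b_), a = Rcpp::as<vec>(a_), x = Rcpp::as<vec>(x_);
  const arma::uword n = std::max(a.n_elem, b.n_elem);
  b.resize(n); a.resize(n);
  b /= a(0); a /= a(0);
  vec z(n - 1, fill::zeros);
  if (zi_.size() > 0) z = Rcpp::as<vec>(zi_);
  vec y(x.n_elem);
  for (arma::uword t = 0; t < x.n_elem; ++t) {
    const double xt = x(t);
    const double yt = b(0) * xt + z(0);
    for (arma::uword k = 0; k + 1 < n - 1; ++k)
      z(k) = b(k + 1) * xt + z(k + 1) - a(k + 1) * yt;
    z(n - 2) = b(n - 1) * xt - a(n - 1) * yt;
    y(t) = yt;
  }
  return Rcpp::wrap(y);
}

// ---------------------------------------------------------------------------
// LSTM
//
// Gate layout within the 4H rows of W/U/b: [input i | forget f | cell g |
// output o], each block of H rows. Per layer l and time t:
//   A = X_t W' + H_{t-1} U' + 1 b'       (B x 4H)
//   i = sigmoid(Ai), f = sigmoid(Af), g = tanh(Ag), o = sigmoid(Ao)
//   c_t = f % c_{t-1} + i % g,  h_t = o % tanh(c_t)
// Output head: Y_t = h_t V' + 1 d'  (time-distributed linear projection).

static inline fmat sigm(const fmat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmParams {
  std::vector<fmat> W, U;   // per layer: (4H x in), (4H x H)
  std::vector<fvec> b;      // per layer: 4H
  fmat V;                   // (C_out x H)
  fvec d;                   // C_out
};

static LstmParams unpack(const Rcpp::List& wl) {
  LstmParams p;
  Rcpp::List layers = wl["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    Rcpp::List ly = layers[l];
    p.W.push_back(Rcpp::as<fmat>(ly["W"]));
    p.U.push_back(Rcpp::as<fmat>(ly["U"]));
    p.b.push_back(Rcpp::as<fvec>(ly["b"]));
  }
  p.V = Rcpp::as<fmat>(wl["V"]);
  p.d = Rcpp::as<fvec>(wl["d"]);
  return p;
}

static Rcpp::List pack(const LstmParams& p) {
  Rcpp::List layers(p.W.size());
  for (size_t l = 0; l < p.W.size(); ++l) {
    layers[l] = Rcpp::List::create(Rcpp::Named("W") = p.W[l],
                                   Rcpp::Named("U") = p.U[l],
                                   Rcpp::Named("b") = p.b[l]);
  }
  return Rcpp::List::create(Rcpp::Named("layers") = layers,
                            Rcpp::Named("V") = p.V,
                            Rcpp::Named("d") = p.d);
}

// Forward pass over a batch. X: fcube (B, C_in, T). Returns Y (B, C_out, T);
// optionally fills caches for backprop.
struct LayerCache {
  fcube i, f, g, o, c, tc, h;  // each (B, H, T)
};

static fcube lstm_forward(const fcube& X, const LstmParams& p,
                         std::vector<LayerCache>* caches,
                         std::vector<fcube>* inputs) {
  const arma::uword B = X.n_rows, T = X.n_slices;
  const arma::uword L = p.W.size();
  const arma::uword H = p.U[0].n_cols;
  fcube in = X;
  for (arma::uword l = 0; l < L; ++l) {
    if (inputs) (*inputs)[l] = in;
    fcube hs(B, H, T);
    LayerCache cc;
    if (caches) {
      cc.i.set_size(B, H, T); cc.f.set_size(B, H, T); cc.g.set_size(B, H, T);
      cc.o.set_size(B, H, T); cc.c.set_size(B, H, T); cc.tc.set_size(B, H, T);
    }
    fmat hprev(B, H, fill::zeros), cprev(B, H, fill::zeros);
    const fmat Wt = p.W[l].t(), Ut = p.U[l].t();
    const frowvec br = p.b[l].t();
    // input-side contributions for all time steps in one GEMM
    const arma::uword Cl = in.n_cols;
    fmat P;
    {
      fmat in_flat(B * T, Cl);
      for (arma::uword t = 0; t < T; ++t)
        in_flat.rows(t * B, t * B + B - 1) = in.slice(t);
      P = in_flat * Wt;
      P.each_row() += br;
    }
    fmat A(B, 4 * H);
    for (arma::uword t = 0; t < T; ++t) {
      A = P.rows(t * B, t * B + B - 1);
      A += hprev * Ut;
      fmat gi = sigm(A.cols(0, H - 1));
      fmat gf = sigm(A.cols(H, 2 * H - 1));
      fmat gg = tanh(A.cols(2 * H, 3 * H - 1));
      fmat go = sigm(A.cols(3 * H, 4 * H - 1));
      fmat c = gf % cprev + gi % gg;
      fmat tc = tanh(c);
      fmat h = go % tc;
      if (caches) {
        cc.i.slice(t) = gi; cc.f.slice(t) = gf; cc.g.slice(t) = gg;
        cc.o.slice(t) = go; cc.c.slice(t) = c; cc.tc.slice(t) = tc;
      }
      hs.slice(t) = h;
      hprev = h; cprev = c;
    }
    if (caches) { cc.h = hs; (*caches)[l] = cc; }
    in = hs;
  }
  const arma::uword Cout = p.V.n_rows;
  fcube Y(B, Cout, T);
  const fmat Vt = p.V.t();
  const frowvec dr = p.d.t();
  for (arma::uword t = 0; t < T; ++t) {
    fmat y = in.slice(t) * Vt;
    y.each_row() += dr;
    Y.slice(t) = y;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_lstm_predict(Rcpp::NumericVector X_, Rcpp::List weights) {
  Rcpp::IntegerVector dims = X_.attr("dim");
  const cube Xd(X_.begin(), dims[0], dims[1], dims[2], false, true);
  const fcube X = conv_to<fcube>::from(Xd);
  LstmParams p = unpack(weights);
  fcube Y = lstm_forward(X, p, nullptr, nullptr);
  Rcpp::NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = Rcpp::IntegerVector::create(Y.n_rows, Y.n_cols, Y.n_slices);
  return out;
}

struct AdamState {
  std::vector<fmat> m, v;
  double b1, b2, eps;
  long step = 0;
  void init(const std::vector<fmat*>& params, double b1_, double b2_, double e_) {
    b1 = b1_; b2 = b2_; eps = e_;
    for (auto* p : params) {
      m.push_back(zeros<fmat>(p->n_rows, p->n_cols));
      v.push_back(zeros<fmat>(p->n_rows, p->n_cols));
    }
  }
  void update(std::vector<fmat*>& params, const std::vector<fmat>& grads,
              double lr) {
    ++step;
    const double bc1 = 1.0 - std::pow(b1, (double)step);
    const double bc2 = 1.0 - std::pow(b2, (double)step);
    for (size_t k = 0; k < params.size(); ++k) {
      m[k] = b1 * m[k] + (1.0 - b1) * grads[k];
      v[k] = b2 * v[k] + (1.0 - b2) * square(grads[k]);
      *params[k] -= lr * (m[k] / bc1) / (sqrt(v[k] / bc2) + eps);
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(Rcpp::NumericVector X_, Rcpp::NumericVector Y_,
                          Rcpp::List weights, int epochs, int batch_size,
                          double lr, Rcpp::IntegerMatrix order,
                          double beta1 = 0.9, double beta2 = 0.999,
                          double adam_eps = 1e-8, double clip_norm = 1.0) {
  Rcpp::IntegerVector dx = X_.attr("dim"), dy = Y_.attr("dim");
  const arma::uword N = dx[0], Cin = dx[1], T = dx[2];
  const arma::uword Cout = dy[1];
  const cube Xd(X_.begin(), N, Cin, T, false, true);
  const cube Yd(Y_.begin(), N, Cout, T, false, true);
  const fcube X = conv_to<fcube>::from(Xd);
  const fcube Y = conv_to<fcube>::from(Yd);
  LstmParams p = unpack(weights);
  const arma::uword L = p.W.size();
  const arma::uword H = p.U[0].n_cols;

  std::vector<fmat> bmat(L);  // biases as 1-col mats for uniform Adam handling
  for (arma::uword l = 0; l < L; ++l) bmat[l] = fmat(p.b[l]);
  fmat dmat(p.d);
  std::vector<fmat*> params;
  for (arma::uword l = 0; l < L; ++l) {
    params.push_back(&p.W[l]); params.push_back(&p.U[l]);
    params.push_back(&bmat[l]);
  }
  params.push_back(&p.V); params.push_back(&dmat);
  AdamState adam;
  adam.init(params, beta1, beta2, adam_eps);

  fvec epoch_loss(epochs, fill::zeros);
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long loss_n = 0;
    for (arma::uword start = 0; start < N; start += batch_size) {
      const arma::uword stop = std::min<arma::uword>(start + batch_size, N) - 1;
      const arma::uword B = stop - start + 1;
      uvec idx(B);
      for (arma::uword k = 0; k < B; ++k)
        idx(k) = (arma::uword)order(ep, start + k) - 1;
      fcube Xb(B, Cin, T), Yb(B, Cout, T);
      for (arma::uword t = 0; t < T; ++t) {
        Xb.slice(t) = X.slice(t).rows(idx);
        Yb.slice(t) = Y.slice(t).rows(idx);
      }
      for (arma::uword l = 0; l < L; ++l) p.b[l] = bmat[l].col(0);
      p.d = dmat.col(0);

      std::vector<LayerCache> caches(L);
      std::vector<fcube> inputs(L);
      fcube pred = lstm_forward(Xb, p, &caches, &inputs);
      fcube diff = pred - Yb;
      const double denom = (double)(B * Cout * T);
      loss_sum += accu(square(diff)) / denom * B;
      loss_n += B;
      if (!diff.is_finite())
        Rcpp::stop("training diverged (non-finite loss); reduce the learning rate");

      // gradients
      std::vector<fmat> gW(L), gU(L), gb(L);
      for (arma::uword l = 0; l < L; ++l) {
        gW[l] = zeros<fmat>(p.W[l].n_rows, p.W[l].n_cols);
        gU[l] = zeros<fmat>(p.U[l].n_rows, p.U[l].n_cols);
        gb[l] = zeros<fmat>(4 * H, 1);
      }
      fmat gV = zeros<fmat>(p.V.n_rows, p.V.n_cols);
      fmat gd = zeros<fmat>(Cout, 1);

      // output head: dY -> dh(top layer, per t)
      fcube dtop(B, H, T);
      const fcube& htop = caches[L - 1].h;
      for (arma::uword t = 0; t < T; ++t) {
        fmat dy = (2.0 / denom) * diff.slice(t);      // B x Cout
        gV += dy.t() * htop.slice(t);
        gd += sum(dy, 0).t();
        dtop.slice(t) = dy * p.V;                    // B x H
      }

      // BPTT, top layer down. Only the recurrent carry needs the time loop;
      // weight/input gradients are batched over all steps afterwards.
      fcube dabove = dtop;
      for (int l = (int)L - 1; l >= 0; --l) {
        const LayerCache& cc = caches[l];
        const fcube& in = inputs[l];
        const arma::uword Cl = in.n_cols;
        fmat dA_flat(B * T, 4 * H);
        fmat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros);
        for (int t = (int)T - 1; t >= 0; --t) {
          fmat dh = dabove.slice(t) + dh_carry;
          fmat dc = dc_carry + dh % cc.o.slice(t) % (1.0 - square(cc.tc.slice(t)));
          fmat dA(B, 4 * H);
          dA.cols(3 * H, 4 * H - 1) =
            (dh % cc.tc.slice(t)) % cc.o.slice(t) % (1.0 - cc.o.slice(t));
          dA.cols(0, H - 1) =
            (dc % cc.g.slice(t)) % cc.i.slice(t) % (1.0 - cc.i.slice(t));
          dA.cols(2 * H, 3 * H - 1) =
            (dc % cc.i.slice(t)) % (1.0 - square(cc.g.slice(t)));
          if (t == 0) {
            dA.cols(H, 2 * H - 1).zeros();   // c_{-1} = 0
          } else {
            dA.cols(H, 2 * H - 1) =
              (dc % cc.c.slice(t - 1)) % cc.f.slice(t) % (1.0 - cc.f.slice(t));
          }
          dA_flat.rows(t * B, t * B + B - 1) = dA;
          dh_carry = dA * p.U[l];
          dc_carry = dc % cc.f.slice(t);
        }
        fmat in_flat(B * T, Cl);
        for (arma::uword t = 0; t < T; ++t)
          in_flat.rows(t * B, t * B + B - 1) = in.slice(t);
        gW[l] = dA_flat.t() * in_flat;
        gb[l] = sum(dA_flat, 0).t();
        // gU: sum_t dA_t' h_{t-1}; h_{-1} = 0, so drop step 0
        if (T > 1) {
          fmat h_flat(B * (T - 1), H);
          for (arma::uword t = 0; t + 1 < T; ++t)
            h_flat.rows(t * B, t * B + B - 1) = cc.h.slice(t);
          gU[l] = dA_flat.rows(B, B * T - 1).t() * h_flat;
        }
        fmat din_flat = dA_flat * p.W[l];
        fcube dinput(B, Cl, T);
        for (arma::uword t = 0; t < T; ++t)
          dinput.slice(t) = din_flat.rows(t * B, t * B + B - 1);
        dabove = dinput;   // becomes dh of the layer below
      }

      std::vector<fmat> grads;
      for (arma::uword l = 0; l < L; ++l) {
        grads.push_back(gW[l]); grads.push_back(gU[l]); grads.push_back(gb[l]);
      }
      grads.push_back(gV); grads.push_back(gd);
      if (clip_norm > 0) {
        double sq = 0;
        for (const fmat& g : grads) sq += accu(square(g));
        const double nrm = std::sqrt(sq);
        if (nrm > clip_norm) {
          const float s = (float)(clip_norm / nrm);
          for (fmat& g : grads) g *= s;
        }
      }
      adam.update(params, grads, lr);
    }
    epoch_loss(ep) = loss_sum / (double)loss_n;
    if (ep % 20 == 0) Rcpp::checkUserInterrupt();
  }
  for (arma::uword l = 0; l < L; ++l) p.b[l] = bmat[l].col(0);
  p.d = dmat.col(0);
  return Rcpp::List::create(Rcpp::Named("weights") = pack(p),
                            Rcpp::Named("loss") = epoch_loss);
}
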