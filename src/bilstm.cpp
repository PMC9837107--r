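// Stacked bidirectional LSTM sequence regressor with an MSE head,
// trained by backpropagation through time with Adam updates per sequence
// chunk. No randomness lives here: weight initialisation and data order
// are fixed by the caller, so training is bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cell {
  mat W, U;  // (4H x Din), (4H x H)
  vec b;     // 4H
};

struct Layer { Cell fw, bw; };

struct Net {
  std::vector<Layer> layers;
  vec w_out; double b_out;
  int hidden;
};

static Net parse_net(const Rcpp::List& weights) {
  Net net;
  Rcpp::List layers = weights["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    Rcpp::List ly = layers[l];
    Layer L;
    L.fw.W = Rcpp::as<mat>(ly["Wf"]); L.fw.U = Rcpp::as<mat>(ly["Uf"]);
    L.fw.b = Rcpp::as<vec>(ly["bf"]);
    L.bw.W = Rcpp::as<mat>(ly["Wb"]); L.bw.U = Rcpp::as<mat>(ly["Ub"]);
    L.bw.b = Rcpp::as<vec>(ly["bb"]);
    net.layers.push_back(L);
  }
  net.w_out = Rcpp::as<vec>(weights["w_out"]);
  net.b_out = Rcpp::as<double>(weights["b_out"]);
  net.hidden = net.layers[0].fw.U.n_cols;
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List layers(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    layers[l] = Rcpp::List::create(
      Rcpp::Named("Wf") = net.layers[l].fw.W, Rcpp::Named("Uf") = net.layers[l].fw.U,
      Rcpp::Named("bf") = net.layers[l].fw.b,
      Rcpp::Named("Wb") = net.layers[l].bw.W, Rcpp::Named("Ub") = net.layers[l].bw.U,
      Rcpp::Named("bb") = net.layers[l].bw.b);
  }
  return Rcpp::List::create(Rcpp::Named("layers") = layers,
                            Rcpp::Named("w_out") = net.w_out,
                            Rcpp::Named("b_out") = net.b_out);
}

// cached activations of one direction over one sequence
struct Trace {
  mat i, f, g, o, c, tc, h;  // each H x T
};

// run one LSTM direction; X is Din x T, reverse = process right-to-left
static void run_cell(const Cell& cell, const mat& X, bool reverse, int H, Trace& tr) {
  const int T = X.n_cols;
  tr.i.set_size(H, T); tr.f.set_size(H, T); tr.g.set_size(H, T);
  tr.o.set_size(H, T); tr.c.set_size(H, T); tr.tc.set_size(H, T); tr.h.set_size(H, T);
  vec h = zeros<vec>(H), c = zeros<vec>(H);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    vec z = cell.W * X.col(t) + cell.U * h + cell.b;
    vec iz = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec fz = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec gz = tanh(z.subvec(2 * H, 3 * H - 1));
    vec oz = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    c = fz % c + iz % gz;
    vec tc = tanh(c);
    h = oz % tc;
    tr.i.col(t) = iz; tr.f.col(t) = fz; tr.g.col(t) = gz; tr.o.col(t) = oz;
    tr.c.col(t) = c; tr.tc.col(t) = tc; tr.h.col(t) = h;
  }
}

// backward pass of one direction; dH is the gradient on this direction's
// hidden outputs. Returns grads and accumulates input gradient into dX.
static void back_cell(const Cell& cell, const mat& X, const Trace& tr,
                      const mat& dH, bool reverse, int H,
                      mat& dW, mat& dU, vec& db, mat& dX) {
  const int T = X.n_cols;
  dW.zeros(cell.W.n_rows, cell.W.n_cols);
  dU.zeros(cell.U.n_rows, cell.U.n_cols);
  db.zeros(cell.b.n_elem);
  vec dh_next = zeros<vec>(H), dc_next = zeros<vec>(H);
  for (int s = T - 1; s >= 0; --s) {
    // walk the processing order backwards
    int t = reverse ? T - 1 - s : s;
    vec dh = dH.col(t) + dh_next;
    vec c_prev, h_prev;
    int tprev = reverse ? t + 1 : t - 1;
    bool has_prev = reverse ? (t + 1 <= T - 1) : (t - 1 >= 0);
    if (has_prev) { c_prev = tr.c.col(tprev); h_prev = tr.h.col(tprev); }
    else { c_prev = zeros<vec>(H); h_prev = zeros<vec>(H); }

    vec do_ = dh % tr.tc.col(t);
    vec dc = dh % tr.o.col(t) % (1.0 - square(tr.tc.col(t))) + dc_next;
    vec di = dc % tr.g.col(t);
    vec df = dc % c_prev;
    vec dg = dc % tr.i.col(t);
    vec dzi = di % tr.i.col(t) % (1.0 - tr.i.col(t));
    vec dzf = df % tr.f.col(t) % (1.0 - tr.f.col(t));
    vec dzg = dg % (1.0 - square(tr.g.col(t)));
    vec dzo = do_ % tr.o.col(t) % (1.0 - tr.o.col(t));
    vec dz = join_cols(join_cols(dzi, dzf), join_cols(dzg, dzo));

    dW += dz * X.col(t).t();
    dU += dz * h_prev.t();
    db += dz;
    dX.col(t) += cell.W.t() * dz;
    dh_next = cell.U.t() * dz;
    dc_next = dc % tr.f.col(t);
  }
}

// full forward over all layers; returns per-layer traces and layer inputs
static vec forward_net(const Net& net, const mat& X,
                       std::vector<mat>& inputs,
                       std::vector<Trace>& trf, std::vector<Trace>& trb) {
  const int L = net.layers.size(), H = net.hidden;
  inputs.resize(L); trf.resize(L); trb.resize(L);
  mat cur = X;
  for (int l = 0; l < L; ++l) {
    inputs[l] = cur;
    run_cell(net.layers[l].fw, cur, false, H, trf[l]);
    run_cell(net.layers[l].bw, cur, true, H, trb[l]);
    cur = join_cols(trf[l].h, trb[l].h);
  }
  vec yhat(cur.n_cols);
  for (unsigned t = 0; t < cur.n_cols; ++t)
    yhat(t) = dot(net.w_out, cur.col(t)) + net.b_out;
  return yhat;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_bilstm_forward(Rcpp::List weights, arma::mat X) {
  Net net = parse_net(weights);
  std::vector<mat> inputs; std::vector<Trace> trf, trb;
  vec yhat = forward_net(net, X, inputs, trf, trb);
  return Rcpp::wrap(yhat);
}

struct Adam {
  std::vector<mat> m, v;
  long t = 0;
  void init(const std::vector<mat*>& params) {
    for (auto p : params) { m.push_back(zeros<mat>(size(*p)));
                            v.push_back(zeros<mat>(size(*p))); }
  }
  void step(std::vector<mat*>& params, std::vector<mat*>& grads,
            double lr, double clip) {
    double nrm2 = 0;
    for (auto g : grads) nrm2 += accu(square(*g));
    double scale = 1.0;
    if (clip > 0 && std::sqrt(nrm2) > clip) scale = clip / std::sqrt(nrm2);
    ++t;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    for (size_t k = 0; k < params.size(); ++k) {
      mat g = (*grads[k]) * scale;
      m[k] = b1 * m[k] + (1 - b1) * g;
      v[k] = b2 * v[k] + (1 - b2) * square(g);
      mat mhat = m[k] / (1 - std::pow(b1, (double)t));
      mat vhat = v[k] / (1 - std::pow(b2, (double)t));
      *params[k] -= lr * mhat / (sqrt(vhat) + eps);
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_train(Rcpp::List weights, Rcpp::List Xs, Rcpp::List ys,
                            int epochs, double lr, double clip) {
  Net net = parse_net(weights);
  const int L = net.layers.size(), H = net.hidden;
  const int nseq = Xs.size();

  // parameter/gradient registry
  std::vector<mat> gW(L * 6 + 1);  // per layer: Wf Uf bf Wb Ub bb ; + w_out
  mat w_out_m(net.w_out);          // column view as mat
  mat b_out_m(1, 1); b_out_m(0, 0) = net.b_out;
  std::vector<mat> bf_m(L), bb_m(L);
  std::vector<mat*> params;
  for (int l = 0; l < L; ++l) {
    params.push_back(&net.layers[l].fw.W);
    params.push_back(&net.layers[l].fw.U);
    bf_m[l] = mat(net.layers[l].fw.b); params.push_back(&bf_m[l]);
    params.push_back(&net.layers[l].bw.W);
    params.push_back(&net.layers[l].bw.U);
    bb_m[l] = mat(net.layers[l].bw.b); params.push_back(&bb_m[l]);
  }
  params.push_back(&w_out_m);
  params.push_back(&b_out_m);
  Adam adam; adam.init(params);

  std::vector<vec> losses;
  vec loss_curve(epochs, fill::zeros);
  bool diverged = false;

  std::vector<mat> Xmats(nseq); std::vector<vec> yvecs(nseq);
  for (int s = 0; s < nseq; ++s) {
    Xmats[s] = Rcpp::as<mat>(Xs[s]);
    yvecs[s] = Rcpp::as<vec>(ys[s]);
  }

  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    double ep_loss = 0;
    for (int s = 0; s < nseq; ++s) {
      // sync bias vectors from their matrix views
      for (int l = 0; l < L; ++l) {
        net.layers[l].fw.b = bf_m[l].col(0);
        net.layers[l].bw.b = bb_m[l].col(0);
      }
      net.w_out = w_out_m.col(0);
      net.b_out = b_out_m(0, 0);

      const mat& X = Xmats[s];
      const vec& y = yvecs[s];
      const int T = X.n_cols;
      std::vector<mat> inputs; std::vector<Trace> trf, trb;
      vec yhat = forward_net(net, X, inputs, trf, trb);
      vec err = yhat - y;
      double loss = mean(square(err));
      if (!std::isfinite(loss)) { diverged = true; loss_curve(ep) = NA_REAL; break; }
      ep_loss += loss;

      vec dyhat = 2.0 * err / (double)T;
      mat Z = join_cols(trf[L - 1].h, trb[L - 1].h);
      mat g_wout = Z * dyhat;                    // 2H x 1
      mat g_bout(1, 1); g_bout(0, 0) = accu(dyhat);
      mat dZ = net.w_out * dyhat.t();            // 2H x T

      std::vector<mat> gWf(L), gUf(L), gWb(L), gUb(L);
      std::vector<vec> gbf(L), gbb(L);
      mat dcur = dZ;
      for (int l = L - 1; l >= 0; --l) {
        mat dHf = dcur.rows(0, H - 1);
        mat dHb = dcur.rows(H, 2 * H - 1);
        mat dX(inputs[l].n_rows, T, fill::zeros);
        back_cell(net.layers[l].fw, inputs[l], trf[l], dHf, false, H,
                  gWf[l], gUf[l], gbf[l], dX);
        back_cell(net.layers[l].bw, inputs[l], trb[l], dHb, true, H,
                  gWb[l], gUb[l], gbb[l], dX);
        dcur = dX;
      }
      std::vector<mat> gbf_m(L), gbb_m(L);
      std::vector<mat*> grads;
      for (int l = 0; l < L; ++l) {
        grads.push_back(&gWf[l]); grads.push_back(&gUf[l]);
        gbf_m[l] = mat(gbf[l]); grads.push_back(&gbf_m[l]);
        grads.push_back(&gWb[l]); grads.push_back(&gUb[l]);
        gbb_m[l] = mat(gbb[l]); grads.push_back(&gbb_m[l]);
      }
      grads.push_back(&g_wout);
      grads.push_back(&g_bout);
      adam.step(params, grads, lr, clip);
    }
    if (!diverged) loss_curve(ep) = ep_loss / nseq;
  }
  // final sync
  for (int l = 0; l < L; ++l) {
    net.layers[l].fw.b = bf_m[l].col(0);
    net.layers[l].bw.b = bb_m[l].col(0);
  }
  net.w_out = w_out_m.col(0);
  net.b_out = b_out_m(0, 0);

  return Rcpp::List::create(Rcpp::Named("weights") = net_to_list(net),
                            Rcpp::Named("loss_curve") = loss_curve,
                            Rcpp::Named("diverged") = diverged);
}
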