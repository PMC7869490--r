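// Forward and backward passes for the contact-graph solubility model:
// stacked row-stochastic graph convolutions (ReLU + layer normalization),
// multi-head self-attention pooling, and a sigmoid MLP head.  Gradients are
// derived by hand and checked against finite differences in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct Params {
  std::vector<arma::mat> gcn_W;
  std::vector<arma::vec> gcn_gamma, gcn_beta;
  arma::mat W1, W2;
  std::vector<arma::mat> head_W;
  std::vector<arma::vec> head_b;
};

static Params unpack(const List& p) {
  Params out;
  List gw = p["gcn_W"], gg = p["gcn_gamma"], gb = p["gcn_beta"];
  for (int l = 0; l < gw.size(); ++l) {
    out.gcn_W.push_back(as<arma::mat>(gw[l]));
    out.gcn_gamma.push_back(as<arma::vec>(gg[l]));
    out.gcn_beta.push_back(as<arma::vec>(gb[l]));
  }
  out.W1 = as<arma::mat>(p["W1"]);
  out.W2 = as<arma::mat>(p["W2"]);
  List hw = p["head_W"], hb = p["head_b"];
  for (int l = 0; l < hw.size(); ++l) {
    out.head_W.push_back(as<arma::mat>(hw[l]));
    out.head_b.push_back(as<arma::vec>(hb[l]));
  }
  return out;
}

// row-wise layer normalization; caches mu, s (=sqrt(var+eps)), xhat
static arma::mat layer_norm(const arma::mat& R, const arma::vec& gamma,
                            const arma::vec& beta, arma::vec& mu,
                            arma::vec& s, arma::mat& xhat) {
  const arma::uword p = R.n_cols;
  mu = arma::mean(R, 1);
  arma::mat centered = R.each_col() - mu;
  arma::vec v = arma::sum(arma::square(centered), 1) / double(p);
  s = arma::sqrt(v + LN_EPS);
  xhat = centered.each_col() / s;
  arma::mat out = xhat.each_row() % gamma.t();
  out.each_row() += beta.t();
  return out;
}

struct Cache {
  std::vector<arma::mat> G;           // layer inputs, G[0] = X
  std::vector<arma::mat> AG;          // Ahat * G
  std::vector<arma::mat> Z, Rl, xhat; // pre-activation, relu out, LN xhat
  std::vector<arma::vec> mu, sdev;
  arma::mat M, U, Tn, Tmat;           // embeddings, W1*M', tanh, softmax
  arma::mat Pmat;                     // T * M
  arma::vec H;
  std::vector<arma::vec> h;           // head activations, h[0] = H
  std::vector<arma::vec> hz;          // head pre-activations
  double o, S;
};

static void forward_pass(const arma::mat& X, const arma::mat& Ahat,
                         const Params& P, bool use_ln, Cache& C) {
  const int nlay = P.gcn_W.size();
  C.G.resize(nlay + 1); C.AG.resize(nlay); C.Z.resize(nlay);
  C.Rl.resize(nlay); C.xhat.resize(nlay); C.mu.resize(nlay);
  C.sdev.resize(nlay);
  C.G[0] = X;
  for (int l = 0; l < nlay; ++l) {
    C.AG[l] = Ahat * C.G[l];
    C.Z[l] = C.AG[l] * P.gcn_W[l];
    C.Rl[l] = arma::clamp(C.Z[l], 0.0, arma::datum::inf);
    if (use_ln) {
      C.G[l + 1] = layer_norm(C.Rl[l], P.gcn_gamma[l], P.gcn_beta[l],
                              C.mu[l], C.sdev[l], C.xhat[l]);
    } else {
      C.G[l + 1] = C.Rl[l];
    }
  }
  C.M = C.G[nlay];                          // L x p
  C.U = P.W1 * C.M.t();                     // q x L
  C.Tn = arma::tanh(C.U);
  arma::mat Sc = P.W2 * C.Tn;               // r x L
  // row-wise softmax over residues
  arma::vec mx = arma::max(Sc, 1);
  arma::mat E = arma::exp(Sc.each_col() - mx);
  C.Tmat = E.each_col() / arma::sum(E, 1);
  C.Pmat = C.Tmat * C.M;                    // r x p
  C.H = arma::mean(C.Pmat, 0).t();          // p
  const int nh = P.head_W.size();
  C.h.assign(nh + 1, arma::vec());
  C.hz.assign(nh, arma::vec());
  C.h[0] = C.H;
  for (int l = 0; l < nh; ++l) {
    C.hz[l] = P.head_W[l] * C.h[l] + P.head_b[l];
    if (l < nh - 1) {
      C.h[l + 1] = arma::clamp(C.hz[l], 0.0, arma::datum::inf);
    } else {
      C.h[l + 1] = C.hz[l];
    }
  }
  C.o = C.h[nh](0);
  C.S = 1.0 / (1.0 + std::exp(-C.o));
}

// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(const arma::mat& X, const arma::mat& Ahat, const List& params,
                 bool layer_norm = true, bool return_hidden = false) {
  Params P = unpack(params);
  Cache C;
  forward_pass(X, Ahat, P, layer_norm, C);
  if (!return_hidden) return List::create(_["S"] = C.S);
  return List::create(_["S"] = C.S, _["M"] = C.M, _["T"] = C.Tmat,
                      _["H"] = C.H);
}

// [[Rcpp::export(name = ".cpp_loss_grad")]]
List cpp_loss_grad(const arma::mat& X, const arma::mat& Ahat,
                   const List& params, double y, bool layer_norm = true) {
  Params P = unpack(params);
  Cache C;
  forward_pass(X, Ahat, P, layer_norm, C);
  const int nlay = P.gcn_W.size();
  const int nh = P.head_W.size();
  const arma::uword r = C.Tmat.n_rows;

  double loss = (C.S - y) * (C.S - y);
  double dS = 2.0 * (C.S - y);
  double dout = dS * C.S * (1.0 - C.S); // d loss / d o

  // head backward
  std::vector<arma::mat> d_head_W(nh);
  std::vector<arma::vec> d_head_b(nh);
  arma::vec dh = arma::vec(1);
  dh(0) = dout;
  for (int l = nh - 1; l >= 0; --l) {
    arma::vec dz = dh;
    if (l < nh - 1) dz = dh % arma::conv_to<arma::vec>::from(C.hz[l] > 0);
    d_head_W[l] = dz * C.h[l].t();
    d_head_b[l] = dz;
    dh = P.head_W[l].t() * dz;
  }
  arma::vec dH = dh; // p

  // pooling backward: H = mean over rows of Pmat
  arma::mat dP(r, dH.n_elem);
  dP.each_row() = dH.t() / double(r);
  arma::mat dT = dP * C.M.t();              // r x L
  arma::mat dM = C.Tmat.t() * dP;           // L x p

  // softmax rows backward
  arma::mat dSc(arma::size(dT));
  for (arma::uword k = 0; k < r; ++k) {
    arma::rowvec tk = C.Tmat.row(k);
    arma::rowvec dtk = dT.row(k);
    dSc.row(k) = tk % (dtk - arma::dot(dtk, tk));
  }
  arma::mat dW2 = dSc * C.Tn.t();           // r x q
  arma::mat dTn = P.W2.t() * dSc;           // q x L
  arma::mat dU = dTn % (1.0 - arma::square(C.Tn));
  arma::mat dW1 = dU * C.M;                 // q x p
  dM += (P.W1.t() * dU).t();                // L x p

  // GCN layers backward
  std::vector<arma::mat> d_gcn_W(nlay);
  std::vector<arma::vec> d_gamma(nlay), d_beta(nlay);
  arma::mat dG = dM;
  for (int l = nlay - 1; l >= 0; --l) {
    arma::mat dR;
    if (layer_norm) {
      d_gamma[l] = arma::sum(dG % C.xhat[l], 0).t();
      d_beta[l] = arma::sum(dG, 0).t();
      arma::mat dxhat = dG.each_row() % P.gcn_gamma[l].t();
      arma::vec m1 = arma::mean(dxhat, 1);
      arma::vec m2 = arma::mean(dxhat % C.xhat[l], 1);
      dR = dxhat.each_col() - m1;
      dR -= (C.xhat[l].each_col() % m2);
      dR.each_col() /= C.sdev[l];
    } else {
      d_gamma[l] = arma::zeros<arma::vec>(C.Rl[l].n_cols);
      d_beta[l] = arma::zeros<arma::vec>(C.Rl[l].n_cols);
      dR = dG;
    }
    arma::mat dZ = dR % arma::conv_to<arma::mat>::from(C.Z[l] > 0);
    d_gcn_W[l] = C.AG[l].t() * dZ;
    dG = Ahat.t() * (dZ * P.gcn_W[l].t());
  }

  List gW(nlay), gGam(nlay), gBet(nlay), hW(nh), hB(nh);
  for (int l = 0; l < nlay; ++l) {
    gW[l] = d_gcn_W[l]; gGam[l] = d_gamma[l]; gBet[l] = d_beta[l];
  }
  for (int l = 0; l < nh; ++l) { hW[l] = d_head_W[l]; hB[l] = d_head_b[l]; }
  List grads = List::create(
    _["gcn_W"] = gW, _["gcn_gamma"] = gGam, _["gcn_beta"] = gBet,
    _["W1"] = dW1, _["W2"] = dW2, _["head_W"] = hW, _["head_b"] = hB);
  return List::create(_["loss"] = loss, _["S"] = C.S, _["grads"] = grads);
}
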