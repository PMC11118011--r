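// LSTM step loops (forward and BPTT backward) for one direction.
// Gate order along the 4H axis: input, forget, cell, output.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::rowvec sigm(const arma::rowvec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// X: (T, D); Wx: (D, 4H); Wh: (H, 4H); b: 4H.
// [[Rcpp::export]]
List lstm_fw_cpp(const arma::mat& X, const arma::mat& Wx, const arma::mat& Wh,
                 const arma::vec& b) {
  const int T = X.n_rows, H = Wh.n_rows;
  arma::mat Z = X * Wx;
  Z.each_row() += b.t();
  arma::mat out(T, H), I(T, H), F(T, H), G(T, H), O(T, H),
      Tc(T, H), Cprev(T, H), Hprev(T, H);
  arma::rowvec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::rowvec z = Z.row(t) + h * Wh;
    arma::rowvec i = sigm(z.cols(0, H - 1));
    arma::rowvec f = sigm(z.cols(H, 2 * H - 1));
    arma::rowvec g = arma::tanh(z.cols(2 * H, 3 * H - 1));
    arma::rowvec o = sigm(z.cols(3 * H, 4 * H - 1));
    Cprev.row(t) = c;
    Hprev.row(t) = h;
    c = f % c + i % g;
    arma::rowvec tc = arma::tanh(c);
    h = o % tc;
    I.row(t) = i; F.row(t) = f; G.row(t) = g; O.row(t) = o;
    Tc.row(t) = tc;
    out.row(t) = h;
  }
  return List::create(_["out"] = out, _["I"] = I, _["F"] = F, _["G"] = G,
                      _["O"] = O, _["Tc"] = Tc, _["Cprev"] = Cprev,
                      _["Hprev"] = Hprev);
}

// [[Rcpp::export]]
List lstm_bw_cpp(const arma::mat& X, const arma::mat& Wx, const arma::mat& Wh,
                 const arma::mat& I, const arma::mat& F, const arma::mat& G,
                 const arma::mat& O, const arma::mat& Tc,
                 const arma::mat& Cprev, const arma::mat& Hprev,
                 const arma::mat& dH) {
  const int T = X.n_rows, H = Wh.n_rows;
  arma::mat dZ(T, 4 * H);
  arma::rowvec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::rowvec dh = dH.row(t) + dh_next;
    arma::rowvec o = O.row(t), tc = Tc.row(t), i = I.row(t), f = F.row(t),
        g = G.row(t);
    arma::rowvec do_ = dh % tc;
    arma::rowvec dc = dc_next + dh % o % (1.0 - tc % tc);
    arma::rowvec di = dc % g;
    arma::rowvec dg = dc % i;
    arma::rowvec df = dc % Cprev.row(t);
    dc_next = dc % f;
    arma::rowvec dz(4 * H);
    dz.cols(0, H - 1) = di % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = df % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dZ.row(t) = dz;
    dh_next = dz * Wh.t();
  }
  return List::create(_["dX"] = dZ * Wx.t(), _["dWx"] = X.t() * dZ,
                      _["dWh"] = Hprev.t() * dZ,
                      _["db"] = arma::sum(dZ, 0).t());
}
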