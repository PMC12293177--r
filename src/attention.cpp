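// Batched block-diagonal scaled dot-product attention.
//
// Q, K, V hold B stacked length-T sequences as (B*T) x d matrices; the
// attention is computed independently per block. This is the innermost hot
// loop of every encoder forward/backward pass, hence compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List attention_forward_cpp(const arma::mat& Q, const arma::mat& K,
                           const arma::mat& V, int B, int T, double scale) {
  arma::mat out(B * T, V.n_cols);
  arma::cube att(T, T, B);
  for (int b = 0; b < B; b++) {
    arma::span r(b * T, b * T + T - 1);
    arma::mat S = Q.rows(r) * K.rows(r).t() * scale;
    arma::vec m = arma::max(S, 1);
    S.each_col() -= m;
    arma::mat E = arma::exp(S);
    arma::vec s = arma::sum(E, 1);
    E.each_col() /= s;
    att.slice(b) = E;
    out.rows(r) = E * V.rows(r);
  }
  return List::create(_["out"] = out, _["att"] = att);
}

// [[Rcpp::export]]
List attention_backward_cpp(const arma::mat& G, const arma::cube& att,
                            const arma::mat& Q, const arma::mat& K,
                            const arma::mat& V, int B, int T, double scale) {
  arma::mat gq(arma::size(Q), arma::fill::zeros);
  arma::mat gk(arma::size(K), arma::fill::zeros);
  arma::mat gv(arma::size(V), arma::fill::zeros);
  for (int b = 0; b < B; b++) {
    arma::span r(b * T, b * T + T - 1);
    const arma::mat& A = att.slice(b);
    arma::mat Gb = G.rows(r);
    gv.rows(r) = A.t() * Gb;
    arma::mat gA = Gb * V.rows(r).t();
    arma::vec rs = arma::sum(gA % A, 1);
    gA.each_col() -= rs;
    arma::mat gS = A % gA;
    gq.rows(r) = scale * gS * K.rows(r);
    gk.rows(r) = scale * gS.t() * Q.rows(r);
  }
  return List::create(_["gq"] = gq, _["gk"] = gk, _["gv"] = gv);
}
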