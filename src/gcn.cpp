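#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fused forward + backward pass for one local structure.
//
// Forward: H0 = X P; for each layer l: Z_l = H_{l-1} + (A H_{l-1}) W_l,
// H_l = relu(Z_l); g = column means of H_L; score = sigmoid(w . g);
// loss contribution = (score - y)^2.
//
// Backward returns exact gradients of (score - y)^2 w.r.t. P, each W_l and w.
// A is the (symmetric, 0/1, no self-loops) adjacency of the local structure
// with the target edge absent.
// [[Rcpp::export(name = ".cpp_gcn_grad")]]
List cpp_gcn_grad(const arma::mat& X, const arma::mat& A,
                  const arma::mat& P, const List& Ws,
                  const arma::vec& w, double y) {
  int L = Ws.size();
  int N = X.n_rows;
  std::vector<arma::mat> Wl(L), H(L + 1), M(L), Z(L);
  for (int l = 0; l < L; ++l) Wl[l] = as<arma::mat>(Ws[l]);

  H[0] = X * P;
  for (int l = 0; l < L; ++l) {
    M[l] = A * H[l];
    Z[l] = H[l] + M[l] * Wl[l];
    H[l + 1] = arma::clamp(Z[l], 0.0, arma::datum::inf);
  }
  arma::rowvec g = arma::mean(H[L], 0);
  double z = arma::dot(g.t(), w);
  double score = 1.0 / (1.0 + std::exp(-z));
  double dz = 2.0 * (score - y) * score * (1.0 - score);

  arma::vec gw = dz * g.t();
  arma::mat dH = (dz / N) * arma::ones<arma::vec>(N) * w.t();

  List gWs(L);
  for (int l = L - 1; l >= 0; --l) {
    arma::mat G = dH % arma::conv_to<arma::mat>::from(Z[l] > 0);
    gWs[l] = arma::mat(M[l].t() * G);
    dH = G + A * (G * Wl[l].t());
  }
  arma::mat gP = X.t() * dH;

  return List::create(_["score"] = score, _["gP"] = gP,
                      _["gW"] = gWs, _["gw"] = gw);
}

// Forward-only scoring (same computation, no gradients).
// [[Rcpp::export(name = ".cpp_gcn_score")]]
double cpp_gcn_score(const arma::mat& X, const arma::mat& A,
                     const arma::mat& P, const List& Ws, const arma::vec& w) {
  int L = Ws.size();
  arma::mat H = X * P;
  for (int l = 0; l < L; ++l) {
    arma::mat Wl = as<arma::mat>(Ws[l]);
    H = arma::clamp(H + (A * H) * Wl, 0.0, arma::datum::inf);
  }
  arma::rowvec g = arma::mean(H, 0);
  double z = arma::dot(g.t(), w);
  return 1.0 / (1.0 + std::exp(-z));
}
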