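// Disentangled-attention inner loops. The encoder keeps its structure in R;
// only the per-example, per-head score/softmax/context computations and
// their adjoints live here. D is the L x L matrix of 1-based relative-
// position bucket indices (offset j - i clipped to [-k, k]).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, const arma::mat& Qr,
                      const arma::mat& Kr, const arma::imat& D,
                      const arma::imat& real, int B, int L, int H,
                      double scale) {
  const int d = Q.n_cols;
  const int dh = d / H;
  mat O(B * L, d, fill::zeros);
  cube A(L, L, (uword)B * H);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * L;
    const uword r1 = r0 + L - 1;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dh;
      const uword c1 = c0 + dh - 1;
      mat Qh = Q.submat(r0, c0, r1, c1);
      mat Kh = K.submat(r0, c0, r1, c1);
      mat S = Qh * Kh.t();
      mat C2P = Qh * Kr.cols(c0, c1).t();   // L x nb
      mat P2C = Kh * Qr.cols(c0, c1).t();   // L x nb
      for (int j = 0; j < L; ++j) {
        double* scol = S.colptr(j);
        for (int i = 0; i < L; ++i)
          scol[i] += C2P(i, D(i, j) - 1) + P2C(j, D(j, i) - 1);
      }
      S /= scale;
      for (int j = 0; j < L; ++j)
        if (!real(b, j)) S.col(j) -= 1e30;
      vec mx = max(S, 1);
      S.each_col() -= mx;
      S = exp(S);
      vec rs = sum(S, 1);
      S.each_col() /= rs;
      A.slice((uword)b * H + h) = S;
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(Named("O") = O, Named("A") = A);
}

// [[Rcpp::export]]
List attn_backward_cpp(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::mat& Qr,
                       const arma::mat& Kr, const arma::imat& D,
                       const Rcpp::NumericVector& Av, const arma::mat& dO,
                       int B, int L, int H, double scale) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const int nb = Kr.n_rows;
  // view onto the cached attention cube, no copy
  const cube A(const_cast<double*>(Av.begin()), L, L, (uword)B * H,
               false, true);
  mat dQ(B * L, d, fill::zeros), dK(B * L, d, fill::zeros),
      dV(B * L, d, fill::zeros);
  mat dQr(nb, d, fill::zeros), dKr(nb, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * L;
    const uword r1 = r0 + L - 1;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dh;
      const uword c1 = c0 + dh - 1;
      mat Qh = Q.submat(r0, c0, r1, c1);
      mat Kh = K.submat(r0, c0, r1, c1);
      mat Vh = V.submat(r0, c0, r1, c1);
      mat Krh = Kr.cols(c0, c1);
      mat Qrh = Qr.cols(c0, c1);
      const mat& Ah = A.slice((uword)b * H + h);
      mat dOh = dO.submat(r0, c0, r1, c1);
      mat dA = dOh * Vh.t();
      dV.submat(r0, c0, r1, c1) += Ah.t() * dOh;
      // softmax adjoint, then the shared 1/scale factor
      vec rs = sum(dA % Ah, 1);
      mat dS = Ah % (dA.each_col() - rs);
      dS /= scale;
      dQ.submat(r0, c0, r1, c1) += dS * Kh;
      dK.submat(r0, c0, r1, c1) += dS.t() * Qh;
      mat dC2P(L, nb, fill::zeros), dP2C(L, nb, fill::zeros);
      for (int j = 0; j < L; ++j) {
        const double* gcol = dS.colptr(j);
        for (int i = 0; i < L; ++i) {
          dC2P(i, D(i, j) - 1) += gcol[i];
          dP2C(j, D(j, i) - 1) += gcol[i];
        }
      }
      dQ.submat(r0, c0, r1, c1) += dC2P * Krh;
      dKr.cols(c0, c1) += dC2P.t() * Qh;
      dK.submat(r0, c0, r1, c1) += dP2C * Qrh;
      dQr.cols(c0, c1) += dP2C.t() * Kh;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK,
                      Named("dV") = dV, Named("dQr") = dQr,
                      Named("dKr") = dKr);
}

// exact GELU (erf form) and its derivative, vectorized

// [[Rcpp::export]]
arma::mat gelu_cpp(const arma::mat& x) {
  arma::mat out(x.n_rows, x.n_cols);
  const double* xi = x.memptr();
  double* oi = out.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    oi[i] = 0.5 * xi[i] * (1.0 + std::erf(xi[i] * M_SQRT1_2));
  return out;
}

// [[Rcpp::export]]
arma::mat dgelu_cpp(const arma::mat& x) {
  arma::mat out(x.n_rows, x.n_cols);
  const double* xi = x.memptr();
  double* oi = out.memptr();
  const double inv_sqrt2pi = 0.3989422804014327;
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    double phi = 0.5 * (1.0 + std::erf(xi[i] * M_SQRT1_2));
    oi[i] = phi + xi[i] * inv_sqrt2pi * std::exp(-0.5 * xi[i] * xi[i]);
  }
  return out;
}
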