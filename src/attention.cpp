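// Multi-head self-attention forward/backward. Hidden states arrive as
// (B*L, h) sample-major matrices; heads partition the hidden columns.
// Kept in C++ because the per-(sample, head) loop dominates training time
// when done in interpreted code. The backward pass recomputes the softmax
// probabilities from Q and K rather than caching them: one extra small
// GEMM per (sample, head) in exchange for not shuttling an L x L x B*heads
// probability cube through the R heap every batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void softmax_rows(mat &S) {
  for (uword i = 0; i < S.n_rows; ++i) {
    rowvec r = S.row(i);
    r -= r.max();
    r = exp(r);
    S.row(i) = r / accu(r);
  }
}

// [[Rcpp::export(name = ".attn_fwd_cpp")]]
arma::mat attn_fwd_cpp(const arma::mat &Q, const arma::mat &K,
                       const arma::mat &V, int B, int L, int heads) {
  const uword h = Q.n_cols;
  const uword dh = h / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat O(Q.n_rows, h);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * L;
    for (int hd = 0; hd < heads; ++hd) {
      const uword c0 = (uword)hd * dh;
      mat S = Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1) *
              K.submat(r0, c0, r0 + L - 1, c0 + dh - 1).t() * scale;
      softmax_rows(S);
      O.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        S * V.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
    }
  }
  return O;
}

// [[Rcpp::export(name = ".attn_bwd_cpp")]]
Rcpp::List attn_bwd_cpp(const arma::mat &dO, const arma::mat &Q,
                        const arma::mat &K, const arma::mat &V,
                        int B, int L, int heads) {
  const uword h = Q.n_cols;
  const uword dh = h / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dQ(Q.n_rows, h), dK(Q.n_rows, h), dV(Q.n_rows, h);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * L;
    for (int hd = 0; hd < heads; ++hd) {
      const uword c0 = (uword)hd * dh;
      mat Qb = Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat Kb = K.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      mat P = Qb * Kb.t() * scale;
      softmax_rows(P);
      mat dOb = dO.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      dV.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        P.t() * dOb;
      mat dP = dOb * V.submat(r0, c0, r0 + L - 1, c0 + dh - 1).t();
      mat dS = (dP - repmat(sum(dP % P, 1), 1, L)) % P * scale;
      dQ.submat(r0, c0, r0 + L - 1, c0 + dh - 1) = dS * Kb;
      dK.submat(r0, c0, r0 + L - 1, c0 + dh - 1) = dS.t() * Qb;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
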