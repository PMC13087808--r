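// Batched matrix multiply over 3D arrays (slices along the 3rd dimension).
// The one compiled kernel behind the transformer's attention layers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// softmax over the 2nd dimension of a (Tq, Tk, S) cube with optional
// masking: causal (key position > query position) and key padding.
// padmask is a (Tk x B) 0/1 matrix (1 = padded key) or 0x0 for none;
// slices map to batch items via b = k / H.
// [[Rcpp::export]]
arma::cube softmax_dim2(const arma::cube& s, bool causal,
                        const arma::mat& padmask, int H) {
  arma::cube out = s;
  const double NEG = -1e30;
  for (arma::uword k = 0; k < out.n_slices; ++k) {
    arma::mat& M = out.slice(k);
    if (causal)
      for (arma::uword i = 0; i < M.n_rows; ++i)
        for (arma::uword j = i + 1; j < M.n_cols; ++j) M(i, j) = NEG;
    if (padmask.n_elem > 0) {
      const arma::uword b = k / H;
      for (arma::uword j = 0; j < M.n_cols; ++j)
        if (padmask(j, b) > 0.5) M.col(j).fill(NEG);
    }
    arma::vec mx = arma::max(M, 1);
    M.each_col() -= mx;
    M = arma::exp(M);
    arma::vec z = arma::sum(M, 1);
    M.each_col() /= z;
  }
  return out;
}

// backward of softmax_dim2: ds = P % (dP - rowsum(dP % P)) / scale
// [[Rcpp::export]]
arma::cube softmax_dim2_bwd(const arma::cube& P, const arma::cube& dP,
                            double scale) {
  arma::cube out(arma::size(P));
  for (arma::uword k = 0; k < P.n_slices; ++k) {
    arma::vec inner = arma::sum(dP.slice(k) % P.slice(k), 1);
    arma::mat d = dP.slice(k);
    d.each_col() -= inner;
    out.slice(k) = (P.slice(k) % d) / scale;
  }
  return out;
}

// (B*T) x D matrix with row (b-1)*T + t  ->  (T, dh, H*B) cube,
// slice (b-1)*H + h
// [[Rcpp::export]]
arma::cube heads_split(const arma::mat& X, int B, int T, int H) {
  const int D = X.n_cols, dh = D / H;
  arma::cube out(T, dh, (arma::uword)H * B);
  for (int b = 0; b < B; ++b)
    for (int h = 0; h < H; ++h)
      out.slice((arma::uword)b * H + h) =
        X.submat(b * T, h * dh, b * T + T - 1, h * dh + dh - 1);
  return out;
}

// inverse of heads_split
// [[Rcpp::export]]
arma::mat heads_merge(const arma::cube& Y, int B, int T, int H) {
  const int dh = Y.n_cols, D = dh * H;
  arma::mat out((arma::uword)B * T, D);
  for (int b = 0; b < B; ++b)
    for (int h = 0; h < H; ++h)
      out.submat(b * T, h * dh, b * T + T - 1, h * dh + dh - 1) =
        Y.slice((arma::uword)b * H + h);
  return out;
}

// one nucleus-sampling step over a batch: for each row of `probs`, find the
// smallest probability-sorted prefix whose cumulative probability strictly
// exceeds p, renormalize within it, and draw with uniform variate u[row].
// Returns 1-based token indices.
// [[Rcpp::export]]
Rcpp::IntegerVector nucleus_step_cpp(const arma::mat& probs, double p,
                                     const arma::vec& u) {
  const arma::uword B = probs.n_rows, V = probs.n_cols;
  Rcpp::IntegerVector out(B);
  for (arma::uword b = 0; b < B; ++b) {
    arma::rowvec pr = probs.row(b);
    arma::uvec o = arma::sort_index(pr, "descend");
    double cum = 0.0;
    arma::uword k = 0;
    for (; k < V; ++k) {
      cum += pr(o(k));
      if (cum > p) { ++k; break; }
    }
    if (k == 0) k = V;
    const double target = u(b) * cum;
    double acc = 0.0;
    arma::uword pick = o(k - 1);
    for (arma::uword j = 0; j < k; ++j) {
      acc += pr(o(j));
      if (acc >= target) { pick = o(j); break; }
    }
    out[b] = (int)pick + 1;
  }
  return out;
}

// [[Rcpp::export]]
arma::cube bmm(const arma::cube& A, const arma::cube& B,
               bool transA = false, bool transB = false) {
  const arma::uword K = A.n_slices;
  if (B.n_slices != K) Rcpp::stop("bmm: slice counts differ");
  const arma::uword n = transA ? A.n_cols : A.n_rows;
  const arma::uword p = transB ? B.n_rows : B.n_cols;
  arma::cube C(n, p, K);
  for (arma::uword k = 0; k < K; ++k) {
    if (!transA && !transB)      C.slice(k) = A.slice(k) * B.slice(k);
    else if (transA && !transB)  C.slice(k) = A.slice(k).t() * B.slice(k);
    else if (!transA && transB)  C.slice(k) = A.slice(k) * B.slice(k).t();
    else                         C.slice(k) = A.slice(k).t() * B.slice(k).t();
  }
  return C;
}
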