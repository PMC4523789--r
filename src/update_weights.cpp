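#include <Rcpp.h>
using namespace Rcpp;

// In-place Bayesian update of a batch of posterior weight columns:
//   W[, k] <- W[, k] * L[, col[k]] * inv_norm[k]
// W is node x replication; L is the likelihood cache (node x condition*response).
// Mutating W in place keeps the replicated-session driver free of
// node-by-replication temporaries, whose repeated allocation dominates the
// runtime otherwise.
// [[Rcpp::export]]
void update_weights_inplace(NumericMatrix W, NumericMatrix L,
                            IntegerVector col, NumericVector inv_norm) {
  const int N = W.nrow(), K = W.ncol();
  if (col.size() != K || inv_norm.size() != K)
    stop("col and inv_norm must have one entry per replication column");
  for (int k = 0; k < K; ++k) {
    const int c = col[k] - 1;
    if (c < 0 || c >= L.ncol()) stop("likelihood column index out of range");
    double *w = &W(0, k);
    const double *l = &L(0, c);
    const double s = inv_norm[k];
    for (int i = 0; i < N; ++i) w[i] *= l[i] * s;
  }
}
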