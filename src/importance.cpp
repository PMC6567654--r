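// Permutation-importance inner loop over flatten neurons.
// Permuting one flatten column changes the dense pre-activations by a
// rank-one update, so each (neuron, repeat) costs one n x denseUnits
// update + ReLU + margin instead of a full forward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Mann-Whitney AUC with midrank tie handling (the 1/2 convention).
static double rankAuc(const vec& s, const uvec& y) {
  const uword n = s.n_elem;
  uvec ord = sort_index(s);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && s(ord(j + 1)) == s(ord(i))) ++j;
    const double avg = 0.5 * ((double)(i + 1) + (double)(j + 1));
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = avg;
    i = j + 1;
  }
  double rPos = 0.0; uword nPos = 0;
  for (uword k = 0; k < n; ++k)
    if (y(k) == 1) { rPos += ranks(k); ++nPos; }
  const uword nNeg = n - nPos;
  return (rPos - (double) nPos * (nPos + 1) / 2.0) /
         ((double) nPos * (double) nNeg);
}

// [[Rcpp::export(name = ".cppPermImportance")]]
Rcpp::List cppPermImportance(const arma::mat& F,     // n x fs flatten acts
                             const arma::mat& Z1,    // n x d dense pre-acts
                             const arma::mat& W1,    // fs x d
                             const arma::vec& wDiff, // d (W2[,2]-W2[,1])
                             const arma::uvec& y,    // 0/1
                             const arma::umat& perms)// n x R, 1-based
{
  const uword n = F.n_rows, fs = F.n_cols, d = Z1.n_cols,
              R = perms.n_cols;
  mat H0 = Z1 % conv_to<mat>::from(Z1 > 0.0);
  const double baseline = rankAuc(H0 * wDiff, y);
  vec scores(fs, fill::zeros);
  vec delta(n), sPerm(n);
  for (uword i = 0; i < fs; ++i) {
    // a constant activation column is unchanged by permutation
    const double* fi = F.colptr(i);
    double fmin = fi[0], fmax = fi[0];
    for (uword k = 1; k < n; ++k) {
      if (fi[k] < fmin) fmin = fi[k];
      if (fi[k] > fmax) fmax = fi[k];
    }
    if (fmin == fmax) { scores(i) = 0.0; continue; }
    double drop = 0.0;
    for (uword r = 0; r < R; ++r) {
      for (uword k = 0; k < n; ++k)
        delta(k) = fi[perms(k, r) - 1] - fi[k];
      sPerm.zeros();
      for (uword j = 0; j < d; ++j) {
        const double w1ij = W1(i, j), wd = wDiff(j);
        const double* z1c = Z1.colptr(j);
        double* sp = sPerm.memptr();
        const double* dl = delta.memptr();
        for (uword k = 0; k < n; ++k) {
          const double v = z1c[k] + dl[k] * w1ij;
          if (v > 0.0) sp[k] += v * wd;
        }
      }
      drop += baseline - rankAuc(sPerm, y);
    }
    scores(i) = drop / (double) R;
  }
  return Rcpp::List::create(Rcpp::Named("scores") = scores,
                            Rcpp::Named("baseline") = baseline);
}
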