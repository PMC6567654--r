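// Mini-batch SGD training core for the convolutional classifiers.
// Mirrors the R reference implementation in trainClassifier() exactly
// (same batch algebra, same update order); epoch shuffles are drawn in R
// and passed in, so both paths are deterministic and interchangeable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cppTrain")]]
Rcpp::List cppTrain(const arma::mat& Xmat,        // n x (rows*cols)
                    const arma::ivec& y,          // 0/1
                    arma::mat convW,              // kk x nf
                    arma::rowvec convB,           // nf
                    arma::mat W1, arma::rowvec b1,
                    arma::mat W2, arma::rowvec b2,
                    const arma::umat& idx,        // npos x kk, 1-based
                    const arma::umat& poolMembers,// ppp x (ph*pw), 1-based
                    const arma::uvec& flattenPerm,// fs, 1-based
                    double lr, double mom, int batchSize,
                    const arma::umat& orders)     // n x epochs, 1-based
{
  const uword n = Xmat.n_rows;
  const uword npos = idx.n_rows, kk = idx.n_cols;
  const uword nf = convW.n_cols;
  const uword ppp = poolMembers.n_rows, nmem = poolMembers.n_cols;
  const uword fs = flattenPerm.n_elem;
  const uword epochs = orders.n_cols;

  // im2col once: row p + i*npos holds window p of sample i
  mat Pfull(n * npos, kk);
  for (uword q = 0; q < kk; ++q)
    for (uword i = 0; i < n; ++i)
      for (uword p = 0; p < npos; ++p)
        Pfull(p + i * npos, q) = Xmat(i, idx(p, q) - 1);

  mat vConvW(size(convW), fill::zeros), vW1(size(W1), fill::zeros),
      vW2(size(W2), fill::zeros);
  rowvec vConvB(nf, fill::zeros), vb1(b1.n_elem, fill::zeros),
      vb2(2, fill::zeros);

  vec history(epochs, fill::zeros);

  for (uword ep = 0; ep < epochs; ++ep) {
    double eploss = 0.0;
    for (uword s = 0; s < n; s += batchSize) {
      const uword nb = std::min<uword>(batchSize, n - s);
      // gather batch windows
      mat P(nb * npos, kk);
      uvec yb(nb);
      for (uword i = 0; i < nb; ++i) {
        const uword g = orders(s + i, ep) - 1;
        yb(i) = (uword) y(g);
        P.rows(i * npos, (i + 1) * npos - 1) =
          Pfull.rows(g * npos, (g + 1) * npos - 1);
      }
      // conv + bias + ReLU
      mat convPre = P * convW;
      convPre.each_row() += convB;
      mat mask = conv_to<mat>::from(convPre > 0.0);
      mat conv = convPre % mask;
      // sum pooling, rows (q + i*ppp)
      mat pooled(nb * ppp, nf, fill::zeros);
      for (uword i = 0; i < nb; ++i)
        for (uword t = 0; t < nmem; ++t)
          for (uword q = 0; q < ppp; ++q)
            pooled.row(q + i * ppp) +=
              conv.row(poolMembers(q, t) - 1 + i * npos);
      // flatten in public neuron order
      mat F(nb, fs);
      for (uword j = 0; j < fs; ++j) {
        const uword internal = flattenPerm(j) - 1;
        const uword pos = internal % ppp, map = internal / ppp;
        for (uword i = 0; i < nb; ++i)
          F(i, j) = pooled(pos + i * ppp, map);
      }
      // dense head
      mat Z1 = F * W1; Z1.each_row() += b1;
      mat H = Z1 % conv_to<mat>::from(Z1 > 0.0);
      mat Z2 = H * W2; Z2.each_row() += b2;
      vec mx = max(Z2, 1);
      mat E = exp(Z2.each_col() - mx);
      vec Zs = sum(E, 1);
      mat prob = E.each_col() / Zs;
      for (uword i = 0; i < nb; ++i)
        eploss -= std::log(std::max(prob(i, yb(i)), 1e-300));
      // backward
      mat dZ2 = prob;
      for (uword i = 0; i < nb; ++i) dZ2(i, yb(i)) -= 1.0;
      dZ2 /= (double) nb;
      mat gW2 = H.t() * dZ2;
      rowvec gb2 = sum(dZ2, 0);
      mat dH = dZ2 * W2.t();
      mat dZ1 = dH % conv_to<mat>::from(Z1 > 0.0);
      mat gW1 = F.t() * dZ1;
      rowvec gb1 = sum(dZ1, 0);
      mat dF = dZ1 * W1.t();
      // un-flatten and un-pool (gradient of a sum copies to every member)
      mat dConv(nb * npos, nf, fill::zeros);
      {
        mat dPl(nb * ppp, nf, fill::zeros);
        for (uword j = 0; j < fs; ++j) {
          const uword internal = flattenPerm(j) - 1;
          const uword pos = internal % ppp, map = internal / ppp;
          for (uword i = 0; i < nb; ++i)
            dPl(pos + i * ppp, map) = dF(i, j);
        }
        for (uword i = 0; i < nb; ++i)
          for (uword t = 0; t < nmem; ++t)
            for (uword q = 0; q < ppp; ++q)
              dConv.row(poolMembers(q, t) - 1 + i * npos) +=
                dPl.row(q + i * ppp);
      }
      dConv %= mask;
      mat gConvW = P.t() * dConv;
      rowvec gConvB = sum(dConv, 0);
      // momentum updates
      vConvW = mom * vConvW - lr * gConvW;  convW += vConvW;
      vConvB = mom * vConvB - lr * gConvB;  convB += vConvB;
      vW1 = mom * vW1 - lr * gW1;           W1 += vW1;
      vb1 = mom * vb1 - lr * gb1;           b1 += vb1;
      vW2 = mom * vW2 - lr * gW2;           W2 += vW2;
      vb2 = mom * vb2 - lr * gb2;           b2 += vb2;
    }
    history(ep) = eploss / (double) n;
  }

  return Rcpp::List::create(
    Rcpp::Named("convW") = convW, Rcpp::Named("convB") = convB,
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2,
    Rcpp::Named("history") = history);
}
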