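// Layer-wise Hebbian training loop.
//
// Reproduces exactly the composition of the exported R operations
// (activation -> lateral inhibition -> percentile threshold -> sigmoid ->
// Hebbian update with synaptic scaling), specialised for the inner training
// loop where a single layer's weights are updated over many epochs while its
// afferent inputs are fixed per image.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// type-7 (linear interpolation) quantile, matching stats::quantile
static double quantile7(const vec& x, double p) {
  vec s = sort(x);
  const uword n = s.n_elem;
  double h = (double)(n - 1) * p;
  uword lo = (uword)std::floor(h);
  if (lo >= n - 1) return s(n - 1);
  double frac = h - (double)lo;
  return s(lo) + frac * (s(lo + 1) - s(lo));
}

// same-size zero-padded 2-D convolution of field (g x g) with kernel
// ((2hw+1) square): r(i,j) = sum_{a,b} K(a+hw, b+hw) * field(i-a, j-b)
static mat conv_same(const mat& field, const mat& K) {
  const int g1 = field.n_rows, g2 = field.n_cols;
  const int hw1 = ((int)K.n_rows - 1) / 2, hw2 = ((int)K.n_cols - 1) / 2;
  mat r(g1, g2, fill::zeros);
  for (int a = -hw1; a <= hw1; ++a) {
    for (int b = -hw2; b <= hw2; ++b) {
      const double k = K(a + hw1, b + hw2);
      if (k == 0.0) continue;
      const int i0 = std::max(0, a), i1 = std::min(g1 - 1, g1 - 1 + a);
      const int j0 = std::max(0, b), j1 = std::min(g2 - 1, g2 - 1 + b);
      if (i0 > i1 || j0 > j1) continue;
      r.submat(i0, j0, i1, j1) += k * field.submat(i0 - a, j0 - b, i1 - a, j1 - b);
    }
  }
  return r;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix train_layer_cpp(Rcpp::List G, Rcpp::NumericMatrix W0,
                                    Rcpp::NumericMatrix K0, int grid,
                                    double percentile, double beta,
                                    double rate, int epochs) {
  const int n_img = G.size();
  mat W(W0.begin(), W0.nrow(), W0.ncol()); // copy
  const mat K(K0.begin(), K0.nrow(), K0.ncol(), false);

  // afferent inputs, no copy (R guarantees the list outlives this call)
  std::vector<mat> gs;
  gs.reserve(n_img);
  for (int i = 0; i < n_img; ++i) {
    Rcpp::NumericMatrix gi = G[i];
    gs.emplace_back(gi.begin(), gi.nrow(), gi.ncol(), false);
  }

  const double p = percentile / 100.0;
  for (int e = 0; e < epochs; ++e) {
    for (int i = 0; i < n_img; ++i) {
      const mat& g = gs[i];
      vec h = sum(W % g, 1);
      mat hf(h.memptr(), grid, grid, false);
      mat r = conv_same(hf, K);
      double alpha = quantile7(vectorise(r), p);
      vec y = 1.0 / (1.0 + exp(-2.0 * beta * (vectorise(r) - alpha)));
      if (rate == 0.0 || y.max() <= 0.0) continue;
      W += rate * (g.each_col() % y);
      vec norms = sqrt(sum(W % W, 1));
      W.each_col() /= norms;
    }
  }
  return Rcpp::wrap(W);
}
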