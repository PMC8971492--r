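#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training on a rectangular grid with a Gaussian neighborhood.
// Presentation order and initial codebook are produced in R under the
// caller's seed, so training is fully deterministic given its arguments.
// Learning rate and neighborhood radius both decay linearly over the
// total number of presentation steps.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& X, NumericMatrix codes,
                            const IntegerVector& order, int grid_x,
                            int grid_y, double alpha_start, double alpha_end,
                            double radius_start, double radius_end) {
  const int m = X.ncol();
  const int k = codes.nrow();
  const R_xlen_t steps = order.size();
  std::vector<int> gx(k), gy(k);
  for (int j = 0; j < k; ++j) {  // node j sits at column j%gx, row j/gx
    gx[j] = j % grid_x;
    gy[j] = j / grid_x;
  }
  for (R_xlen_t t = 0; t < steps; ++t) {
    double frac = steps > 1 ? (double)t / (double)(steps - 1) : 0.0;
    double alpha = alpha_start + (alpha_end - alpha_start) * frac;
    double radius = radius_start + (radius_end - radius_start) * frac;
    if (radius < 1e-8) radius = 1e-8;
    int i = order[t];
    // best-matching unit, ties to the lowest node index
    int bmu = 0;
    double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = X(i, c) - codes(j, c);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; bmu = j; }
    }
    double denom = 2.0 * radius * radius;
    for (int j = 0; j < k; ++j) {
      double dxg = gx[j] - gx[bmu];
      double dyg = gy[j] - gy[bmu];
      double h = std::exp(-(dxg * dxg + dyg * dyg) / denom);
      if (h < 1e-4) continue;
      double ah = alpha * h;
      for (int c = 0; c < m; ++c) {
        codes(j, c) += ah * (X(i, c) - codes(j, c));
      }
    }
  }
  return codes;
}

// Nearest codebook row per observation (squared Euclidean), ties broken
// by the lowest node index; returns 1-based labels.
// [[Rcpp::export]]
IntegerVector som_map_cpp(const NumericMatrix& X,
                          const NumericMatrix& codes) {
  const int n = X.nrow(), m = X.ncol(), k = codes.nrow();
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = X(i, c) - codes(j, c);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; bmu = j; }
    }
    labels[i] = bmu + 1;
  }
  return labels;
}
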