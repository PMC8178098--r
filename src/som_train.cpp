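#include <Rcpp.h>
using namespace Rcpp;

// Competitive-learning training loop for a rectangular SOM.
//
// data: n x d inputs (row per sample); W: nodes x d initial weights
// (modified copy returned); grid: nodes x 2 (row, col) coordinates.
// Schedules: gamma(i) = gamma0 * (gammaT/gamma0)^(i/T) (or linear),
// sigma(i) = sigma0 * (sigmaT/sigma0)^(i/T). Neighborhood: gaussian
// exp(-d2/(2 sigma^2)) or bubble (d2 <= sigma^2). Stops at T steps or when
// the max absolute weight change over one epoch (n steps) < tol.
// Uses R's RNG (caller seeds it), so runs are reproducible.
// [[Rcpp::export(name = ".som_train_cpp")]]
List som_train_cpp(NumericMatrix data, NumericMatrix W_in,
                   IntegerMatrix grid, double T_steps,
                   double gamma0, double gammaT, bool gamma_linear,
                   double sigma0, double sigmaT, bool gaussian,
                   double tol) {
  int n = data.nrow(), d = data.ncol(), m = W_in.nrow();
  NumericMatrix W = clone(W_in);
  std::vector<double> epoch_qe;
  std::vector<int> order(n);
  for (int k = 0; k < n; ++k) order[k] = k;
  double i = 0.0;
  long steps = 0;
  RNGScope scope;
  while (i < T_steps) {
    double max_change = 0.0;
    int epoch_len = (int)std::min((double)n, T_steps - i);
    // one cycle visits every input once, in fresh random order
    for (int k = n - 1; k > 0; --k) {
      int j = (int)std::floor(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(order[k], order[j]);
    }
    for (int s = 0; s < epoch_len; ++s) {
      int q = order[s];
      // BMU: exhaustive Euclidean argmin
      int bmu = 0;
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double acc = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = W(k, j) - data(q, j);
          acc += diff * diff;
        }
        if (acc < best) { best = acc; bmu = k; }
      }
      double frac = i / T_steps;
      double gamma = gamma_linear ? gamma0 * (1.0 - frac)
                                  : gamma0 * std::pow(gammaT / gamma0, frac);
      double sigma = sigma0 * std::pow(sigmaT / sigma0, frac);
      for (int k = 0; k < m; ++k) {
        double dr = grid(k, 0) - grid(bmu, 0);
        double dc = grid(k, 1) - grid(bmu, 1);
        double d2 = dr * dr + dc * dc;
        double u = gaussian ? std::exp(-d2 / (2.0 * sigma * sigma))
                            : (d2 <= sigma * sigma ? 1.0 : 0.0);
        double coef = u * gamma;
        if (coef <= 1e-12) continue;
        for (int j = 0; j < d; ++j) {
          double delta = coef * (data(q, j) - W(k, j));
          W(k, j) += delta;
          double a = std::fabs(delta);
          if (a > max_change) max_change = a;
        }
      }
      i += 1.0;
      ++steps;
    }
    // quantization error after this epoch
    double qe = 0.0;
    for (int r = 0; r < n; ++r) {
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double acc = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = W(k, j) - data(r, j);
          acc += diff * diff;
        }
        if (acc < best) best = acc;
      }
      qe += std::sqrt(best);
    }
    epoch_qe.push_back(qe / n);
    if (max_change < tol) break;
  }
  return List::create(_["weights"] = W,
                      _["steps"] = (double)steps,
                      _["epoch_qe"] = NumericVector(epoch_qe.begin(),
                                                    epoch_qe.end()));
}
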