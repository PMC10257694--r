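#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64 -> xorshift) so that
// shuffling and validation splits reproduce bit-identically from a seed,
// independent of R's RNG state.
namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

void shuffle(std::vector<int>& idx, Rng& rng) {
  for (int i = static_cast<int>(idx.size()) - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(idx[i], idx[j]);
  }
}

} // namespace

// Linear classifier fitted by stochastic gradient descent on standardized
// features. loss: 0 = hinge (L2-regularized linear SVM), 1 = logistic.
// Learning-rate schedule is "adaptive": eta stays at eta0 until the
// validation (or training) objective stops improving for n_iter_no_change
// consecutive epochs, then eta /= 5; fitting stops once eta < 1e-6 or
// max_epochs is reached. Class weight cw applies to the positive class.
// [[Rcpp::export(name = ".sgd_fit")]]
List sgd_fit(NumericMatrix X, IntegerVector y, int loss, double alpha,
             double pos_weight, int max_epochs, double eta0,
             bool early_stopping, double validation_fraction,
             int n_iter_no_change, double tol, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0);
  double b = 0.0;

  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  shuffle(order, rng);

  int n_val = 0;
  if (early_stopping) {
    n_val = static_cast<int>(std::floor(validation_fraction * n));
    if (n_val < 1) n_val = 1;
    if (n_val >= n) n_val = n - 1;
  }
  const int n_train = n - n_val;
  std::vector<int> val(order.begin() + n_train, order.end());
  std::vector<int> train(order.begin(), order.begin() + n_train);

  auto objective = [&](const std::vector<int>& rows) {
    // monitored objective: mean weighted loss on `rows`
    double tot = 0.0, wsum = 0.0;
    for (int i : rows) {
      double z = b;
      for (int j = 0; j < p; ++j) z += w[j] * X(i, j);
      double cw = (y[i] == 1) ? pos_weight : 1.0;
      if (loss == 0) {
        double ys = (y[i] == 1) ? 1.0 : -1.0;
        double h = 1.0 - ys * z;
        tot += cw * (h > 0 ? h : 0.0);
      } else {
        // numerically stable log-loss
        double t = (y[i] == 1) ? 1.0 : 0.0;
        double ll = (z > 0) ? (std::log1p(std::exp(-z)) + (1.0 - t) * z)
                            : (std::log1p(std::exp(z)) - t * z);
        tot += cw * ll;
      }
      wsum += cw;
    }
    return wsum > 0 ? tot / wsum : 0.0;
  };

  const std::vector<int>& monitor = early_stopping ? val : train;
  double best = R_PosInf, eta = eta0;
  int stall = 0, epochs_run = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    shuffle(train, rng);
    for (int i : train) {
      double z = b;
      for (int j = 0; j < p; ++j) z += w[j] * X(i, j);
      double cw = (y[i] == 1) ? pos_weight : 1.0;
      if (loss == 0) {
        double ys = (y[i] == 1) ? 1.0 : -1.0;
        bool active = ys * z < 1.0;
        for (int j = 0; j < p; ++j) {
          double g = alpha * w[j];
          if (active) g -= cw * ys * X(i, j);
          w[j] -= eta * g;
        }
        if (active) b += eta * cw * ys;
      } else {
        double pr = 1.0 / (1.0 + std::exp(-z));
        double t = (y[i] == 1) ? 1.0 : 0.0;
        double g0 = cw * (pr - t);
        for (int j = 0; j < p; ++j) w[j] -= eta * (alpha * w[j] + g0 * X(i, j));
        b -= eta * g0;
      }
    }
    epochs_run = epoch + 1;
    double obj = objective(monitor);
    if (obj < best - tol) {
      best = obj;
      stall = 0;
    } else if (++stall >= n_iter_no_change) {
      eta /= 5.0;
      stall = 0;
      if (eta < 1e-6) break;
    }
  }

  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["bias"] = b,
    _["epochs"] = epochs_run
  );
}

// Decision margins X %*% w + b for a fitted linear model.
// [[Rcpp::export(name = ".linear_margin")]]
NumericVector linear_margin(NumericMatrix X, NumericVector w, double b) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double z = b;
    for (int j = 0; j < p; ++j) z += w[j] * X(i, j);
    out[i] = z;
  }
  return out;
}
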