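// Feed-forward network core: SELU hidden layers, softmax output, binary
// cross-entropy, per-sample AdaGrad SGD with alpha-dropout, and the
// input-perturbation sensitivity sweep. All randomness is drawn from R's RNG
// stream (norm_rand/unif_rand) so set.seed() on the R side makes every entry
// point deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat selu_mat(const arma::mat& z, double lambda, double alpha) {
  arma::mat out = z;
  arma::uvec neg = arma::find(z <= 0);
  out *= lambda;
  out.elem(neg) = lambda * alpha * (arma::exp(z.elem(neg)) - 1.0);
  return out;
}

static inline arma::mat selu_deriv(const arma::mat& z, double lambda, double alpha) {
  arma::mat d(z.n_rows, z.n_cols);
  d.fill(lambda);
  arma::uvec neg = arma::find(z <= 0);
  d.elem(neg) = lambda * alpha * arma::exp(z.elem(neg));
  return d;
}

static inline arma::mat softmax_rows(const arma::mat& z) {
  arma::vec m = arma::max(z, 1);
  arma::mat e = arma::exp(z.each_col() - m);
  arma::vec s = arma::sum(e, 1);
  return e.each_col() / s;
}

// Fisher-Yates permutation of 0..n-1 using R's RNG.
static arma::uvec shuffle_r(unsigned int n) {
  arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
  for (unsigned int i = n - 1; i > 0; --i) {
    unsigned int j = (unsigned int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// [[Rcpp::export]]
List cpp_init_fnn(int input_size, int width, int depth) {
  // weight SD = 1 / fan_in of the layer, biases zero
  List W(depth + 1), B(depth + 1);
  int fan_in = input_size;
  for (int l = 0; l <= depth; ++l) {
    int fan_out = (l == depth) ? 2 : width;
    arma::mat w(fan_in, fan_out);
    double sd = 1.0 / fan_in;
    for (arma::uword k = 0; k < w.n_elem; ++k) w[k] = norm_rand() * sd;
    W[l] = w;
    B[l] = arma::rowvec(fan_out, arma::fill::zeros);
    fan_in = fan_out;
  }
  return List::create(_["weights"] = W, _["biases"] = B);
}

struct AlphaDropout {
  double q, ap, a, b;
  AlphaDropout(double keep, double lambda, double alpha) : q(keep) {
    ap = -lambda * alpha;
    a = 1.0 / std::sqrt(q + ap * ap * q * (1.0 - q));
    b = -a * (1.0 - q) * ap;
  }
};

// [[Rcpp::export]]
arma::mat cpp_forward(List W, List B, const arma::mat& X,
                      double lambda, double alpha,
                      bool training = false, double keep = 1.0) {
  int depth = W.size() - 1;
  arma::mat A = X;
  bool drop = training && keep < 1.0;
  AlphaDropout ad(keep, lambda, alpha);
  for (int l = 0; l < depth; ++l) {
    arma::mat Wl = W[l];
    arma::rowvec bl = B[l];
    arma::mat Z = A * Wl;
    Z.each_row() += bl;
    arma::mat H = selu_mat(Z, lambda, alpha);
    if (drop) {
      for (arma::uword k = 0; k < H.n_elem; ++k) {
        double h = (unif_rand() < ad.q) ? H[k] : ad.ap;
        H[k] = ad.a * h + ad.b;
      }
    }
    A = H;
  }
  arma::mat Wo = W[depth];
  arma::rowvec bo = B[depth];
  arma::mat Z = A * Wo;
  Z.each_row() += bo;
  return softmax_rows(Z);
}

static inline double bce(double p_mal, int y) {
  double eps = 1e-12;
  double p = std::min(std::max(p_mal, eps), 1.0 - eps);
  return -(y * std::log(p) + (1 - y) * std::log(1.0 - p));
}

// Gradients for one sample (no dropout); used by the training loop with
// dropout folded in separately, and exported for finite-difference checks.
// [[Rcpp::export]]
List cpp_grad_single(List W, List B, const arma::rowvec& x, int y,
                     double lambda, double alpha) {
  int depth = W.size() - 1;
  std::vector<arma::mat> Zs(depth);
  std::vector<arma::rowvec> As(depth + 1);
  arma::rowvec A = x;
  As[0] = A;
  for (int l = 0; l < depth; ++l) {
    arma::mat Wl = W[l];
    arma::rowvec bl = B[l];
    arma::rowvec Z = A * Wl + bl;
    Zs[l] = Z;
    A = arma::conv_to<arma::rowvec>::from(selu_mat(Z, lambda, alpha));
    As[l + 1] = A;
  }
  arma::mat Wo = W[depth];
  arma::rowvec bo = B[depth];
  arma::rowvec Z = A * Wo + bo;
  arma::rowvec P = arma::conv_to<arma::rowvec>::from(softmax_rows(Z));
  double loss = bce(P[1], y);
  arma::rowvec ideal = {1.0 - (double)y, (double)y};
  arma::rowvec dZ = P - ideal;
  List gW(depth + 1), gB(depth + 1);
  gW[depth] = arma::mat(As[depth].t() * dZ);
  gB[depth] = dZ;
  arma::rowvec dA = dZ * Wo.t();
  for (int l = depth - 1; l >= 0; --l) {
    arma::rowvec dZl = dA % arma::conv_to<arma::rowvec>::from(
        selu_deriv(Zs[l], lambda, alpha));
    gW[l] = arma::mat(As[l].t() * dZl);
    gB[l] = dZl;
    if (l > 0) {
      arma::mat Wl = W[l];
      dA = dZl * Wl.t();
    }
  }
  return List::create(_["gw"] = gW, _["gb"] = gB, _["loss"] = loss);
}

// [[Rcpp::export]]
List cpp_train_fnn(List W0, List B0, List Gw0, List Gb0,
                   const arma::mat& X, const arma::ivec& y,
                   const arma::mat& Xval, const arma::ivec& yval,
                   bool has_val,
                   int epochs, double lr, double keep,
                   double lambda, double alpha, double eps = 1e-8) {
  int depth = W0.size() - 1;
  int n = X.n_rows;
  std::vector<arma::mat> W(depth + 1), Gw(depth + 1);
  std::vector<arma::rowvec> B(depth + 1), Gb(depth + 1);
  for (int l = 0; l <= depth; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    B[l] = as<arma::rowvec>(B0[l]);
    Gw[l] = as<arma::mat>(Gw0[l]);
    Gb[l] = as<arma::rowvec>(Gb0[l]);
  }
  bool drop = keep < 1.0;
  AlphaDropout ad(keep, lambda, alpha);
  arma::vec hist_loss(epochs, arma::fill::zeros);
  arma::vec hist_val(epochs); hist_val.fill(NA_REAL);

  std::vector<arma::rowvec> Zs(depth), As(depth + 1), masks(depth);

  for (int e = 0; e < epochs; ++e) {
    arma::uvec ord = shuffle_r(n);
    double tot = 0.0;
    for (int s = 0; s < n; ++s) {
      int i = ord[s];
      arma::rowvec A = X.row(i);
      As[0] = A;
      for (int l = 0; l < depth; ++l) {
        arma::rowvec Z = A * W[l] + B[l];
        Zs[l] = Z;
        arma::rowvec H = arma::conv_to<arma::rowvec>::from(
            selu_mat(Z, lambda, alpha));
        if (drop) {
          arma::rowvec m(H.n_elem);
          for (arma::uword k = 0; k < H.n_elem; ++k) {
            m[k] = (unif_rand() < ad.q) ? 1.0 : 0.0;
            double h = m[k] > 0.5 ? H[k] : ad.ap;
            H[k] = ad.a * h + ad.b;
          }
          masks[l] = m;
        }
        A = H;
        As[l + 1] = A;
      }
      arma::rowvec Z = A * W[depth] + B[depth];
      arma::rowvec P = arma::conv_to<arma::rowvec>::from(softmax_rows(Z));
      int yi = y[i];
      tot += bce(P[1], yi);
      arma::rowvec ideal = {1.0 - (double)yi, (double)yi};
      arma::rowvec dZ = P - ideal;
      if (!dZ.is_finite()) stop("non-finite gradient during training");
      // output layer
      arma::rowvec dA = dZ * W[depth].t();
      {
        arma::mat g = As[depth].t() * dZ;
        Gw[depth] += arma::square(g);
        W[depth] -= lr * g / (arma::sqrt(Gw[depth]) + eps);
        Gb[depth] += arma::square(dZ);
        B[depth] -= lr * dZ / (arma::sqrt(Gb[depth]) + eps);
      }
      for (int l = depth - 1; l >= 0; --l) {
        arma::rowvec dH = dA;
        arma::rowvec dZl = dH % arma::conv_to<arma::rowvec>::from(
            selu_deriv(Zs[l], lambda, alpha));
        if (drop) dZl = ad.a * (dZl % masks[l]);
        if (l > 0) dA = dZl * W[l].t();
        arma::mat g = As[l].t() * dZl;
        Gw[l] += arma::square(g);
        W[l] -= lr * g / (arma::sqrt(Gw[l]) + eps);
        Gb[l] += arma::square(dZl);
        B[l] -= lr * dZl / (arma::sqrt(Gb[l]) + eps);
      }
    }
    hist_loss[e] = tot / n;
    if (has_val) {
      List Wl(depth + 1), Bl(depth + 1);
      for (int l = 0; l <= depth; ++l) { Wl[l] = W[l]; Bl[l] = B[l]; }
      arma::mat P = cpp_forward(Wl, Bl, Xval, lambda, alpha, false, 1.0);
      int ok = 0;
      for (arma::uword i = 0; i < Xval.n_rows; ++i) {
        ok += ((P(i, 1) > 0.5) == (yval[i] == 1));
      }
      hist_val[e] = (double)ok / Xval.n_rows;
    }
  }
  List Wout(depth + 1), Bout(depth + 1), Gwout(depth + 1), Gbout(depth + 1);
  for (int l = 0; l <= depth; ++l) {
    Wout[l] = W[l]; Bout[l] = B[l]; Gwout[l] = Gw[l]; Gbout[l] = Gb[l];
  }
  return List::create(
    _["weights"] = Wout, _["biases"] = Bout,
    _["gw"] = Gwout, _["gb"] = Gbout,
    _["loss"] = hist_loss, _["val_accuracy"] = hist_val);
}

// Per-channel perturbation sweep. For each channel j and each fraction k the
// perturbation frac_k * mean(X[, j]) is added to channel j of every sample
// and the mean squared output error against the ideal one-hot targets is
// recorded. Only the first-layer pre-activations change by a rank-1 update,
// which keeps the sweep O(L * K * N * width) instead of re-doing the full
// first-layer product.
// [[Rcpp::export]]
arma::mat cpp_sensitivity_sweep(List W, List B, const arma::mat& X,
                                const arma::mat& ideal,
                                const arma::vec& fractions,
                                double lambda, double alpha,
                                bool literal = false) {
  int depth = W.size() - 1;
  int n = X.n_rows, L = X.n_cols, K = fractions.n_elem;
  arma::mat W1 = W[0];
  arma::rowvec b1 = B[0];
  arma::mat Z1 = X * W1;
  Z1.each_row() += b1;
  arma::rowvec means = arma::mean(X, 0);
  arma::mat out(L, K);
  for (int j = 0; j < L; ++j) {
    arma::rowvec w1j = W1.row(j);
    for (int k = 0; k < K; ++k) {
      double delta = fractions[k] * means[j];
      arma::mat A = selu_mat(Z1 + arma::ones(n) * (delta * w1j), lambda, alpha);
      for (int l = 1; l < depth; ++l) {
        arma::mat Wl = W[l];
        arma::rowvec bl = B[l];
        arma::mat Z = A * Wl;
        Z.each_row() += bl;
        A = selu_mat(Z, lambda, alpha);
      }
      arma::mat Wo = W[depth];
      arma::rowvec bo = B[depth];
      arma::mat Z = A * Wo;
      Z.each_row() += bo;
      arma::mat P = softmax_rows(Z);
      if (literal) {
        out(j, k) = arma::accu(arma::square(P) - arma::square(ideal)) / 2.0;
      } else {
        out(j, k) = arma::accu(arma::square(P - ideal)) / (2.0 * n);
      }
    }
  }
  return out;
}
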