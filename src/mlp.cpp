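// Multilayer perceptron for tabular kinematic features.
// Architecture: FC-BN-LeakyReLU (x3) -> FC -> sigmoid, binary cross-entropy,
// ADAM, with a permanent learning-rate drop once training accuracy reaches a
// threshold. All randomness (initial weights, shuffle orders) is supplied
// from R so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uvec;

struct Net {
  std::vector<mat> W;       // 4 weight matrices
  std::vector<rowvec> b;    // 4 biases
  std::vector<rowvec> gamma, beta, rmean, rvar;  // 3 batch norms
};

static Net net_from_list(const List& p) {
  Net n;
  for (int l = 0; l < 4; ++l) {
    n.W.push_back(as<mat>(p["W" + std::to_string(l + 1)]));
    n.b.push_back(as<rowvec>(p["b" + std::to_string(l + 1)]));
  }
  for (int l = 0; l < 3; ++l) {
    n.gamma.push_back(as<rowvec>(p["gamma" + std::to_string(l + 1)]));
    n.beta.push_back(as<rowvec>(p["beta" + std::to_string(l + 1)]));
    n.rmean.push_back(as<rowvec>(p["rmean" + std::to_string(l + 1)]));
    n.rvar.push_back(as<rowvec>(p["rvar" + std::to_string(l + 1)]));
  }
  return n;
}

static List net_to_list(const Net& n) {
  List p;
  for (int l = 0; l < 4; ++l) {
    p["W" + std::to_string(l + 1)] = n.W[l];
    p["b" + std::to_string(l + 1)] = n.b[l];
  }
  for (int l = 0; l < 3; ++l) {
    p["gamma" + std::to_string(l + 1)] = n.gamma[l];
    p["beta" + std::to_string(l + 1)] = n.beta[l];
    p["rmean" + std::to_string(l + 1)] = n.rmean[l];
    p["rvar" + std::to_string(l + 1)] = n.rvar[l];
  }
  return p;
}

static mat leaky(const mat& x, double s) {
  return arma::max(x, arma::zeros<mat>(x.n_rows, x.n_cols)) +
         s * arma::min(x, arma::zeros<mat>(x.n_rows, x.n_cols));
}

static vec sigmoid(const vec& z) { return 1.0 / (1.0 + arma::exp(-z)); }

static double bce(const vec& p, const vec& y) {
  vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

// Evaluation-mode forward pass (running batch-norm statistics).
static vec eval_forward(const Net& n, const mat& X, double slope,
                        double bn_eps) {
  mat A = X;
  for (int l = 0; l < 3; ++l) {
    mat Z = A * n.W[l];
    Z.each_row() += n.b[l];
    mat Zh = Z;
    Zh.each_row() -= n.rmean[l];
    Zh.each_row() /= arma::sqrt(n.rvar[l] + bn_eps);
    Zh.each_row() %= n.gamma[l];
    Zh.each_row() += n.beta[l];
    A = leaky(Zh, slope);
  }
  vec z4 = A * n.W[3].col(0) + n.b[3](0);
  return sigmoid(z4);
}

struct Cache {
  std::vector<mat> A;      // inputs to each FC layer (4)
  std::vector<mat> Zhat;   // normalised pre-activations (3)
  std::vector<mat> Y;      // BN outputs pre-activation (3)
  std::vector<rowvec> istd;  // 1/sqrt(var+eps) (3)
  vec p;
};

// Training-mode forward pass; updates running statistics when momentum > 0.
static Cache train_forward(Net& n, const mat& Xb, double slope, double bn_eps,
                           double momentum) {
  Cache c;
  mat A = Xb;
  for (int l = 0; l < 3; ++l) {
    c.A.push_back(A);
    mat Z = A * n.W[l];
    Z.each_row() += n.b[l];
    rowvec mu = arma::mean(Z, 0);
    mat Zc = Z;
    Zc.each_row() -= mu;
    rowvec var = arma::mean(arma::square(Zc), 0);  // biased
    if (momentum > 0) {
      n.rmean[l] = (1.0 - momentum) * n.rmean[l] + momentum * mu;
      n.rvar[l] = (1.0 - momentum) * n.rvar[l] + momentum * var;
    }
    rowvec istd = 1.0 / arma::sqrt(var + bn_eps);
    mat Zhat = Zc;
    Zhat.each_row() %= istd;
    mat Y = Zhat;
    Y.each_row() %= n.gamma[l];
    Y.each_row() += n.beta[l];
    c.Zhat.push_back(Zhat);
    c.Y.push_back(Y);
    c.istd.push_back(istd);
    A = leaky(Y, slope);
  }
  c.A.push_back(A);
  vec z4 = A * n.W[3].col(0) + n.b[3](0);
  c.p = sigmoid(z4);
  return c;
}

struct Grads {
  std::vector<mat> W;
  std::vector<rowvec> b, gamma, beta;
};

static Grads backward(const Net& n, const Cache& c, const vec& y,
                      double slope) {
  int B = y.n_elem;
  Grads g;
  g.W.resize(4);
  g.b.resize(4);
  g.gamma.resize(3);
  g.beta.resize(3);
  vec dz4 = (c.p - y) / double(B);
  g.W[3] = c.A[3].t() * dz4;
  g.b[3] = rowvec(1);
  g.b[3](0) = arma::accu(dz4);
  mat dA = dz4 * n.W[3].col(0).t();
  for (int l = 2; l >= 0; --l) {
    mat mask = arma::conv_to<mat>::from(c.Y[l] > 0);
    mat dY = dA % (mask + slope * (1.0 - mask));
    g.gamma[l] = arma::sum(dY % c.Zhat[l], 0);
    g.beta[l] = arma::sum(dY, 0);
    mat dZhat = dY;
    dZhat.each_row() %= n.gamma[l];
    rowvec m1 = arma::mean(dZhat, 0);
    rowvec m2 = arma::mean(dZhat % c.Zhat[l], 0);
    mat dZ = dZhat;
    dZ.each_row() -= m1;
    dZ -= c.Zhat[l].each_row() % m2;
    dZ.each_row() %= c.istd[l];
    g.W[l] = c.A[l].t() * dZ;
    g.b[l] = arma::sum(dZ, 0);
    dA = dZ * n.W[l].t();
  }
  return g;
}

struct AdamState {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb, mg, vg, mbe, vbe;
  long t = 0;
};

static void adam_update_mat(mat& p, const mat& g, mat& m, mat& v, double lr,
                            double b1, double b2, double eps, long t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  mat mh = m / (1.0 - std::pow(b1, double(t)));
  mat vh = v / (1.0 - std::pow(b2, double(t)));
  p -= lr * mh / (arma::sqrt(vh) + eps);
}

static void adam_update_row(rowvec& p, const rowvec& g, rowvec& m, rowvec& v,
                            double lr, double b1, double b2, double eps,
                            long t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  rowvec mh = m / (1.0 - std::pow(b1, double(t)));
  rowvec vh = v / (1.0 - std::pow(b2, double(t)));
  p -= lr * mh / (arma::sqrt(vh) + eps);
}

// [[Rcpp::export]]
List mlp_train_cpp(List params0, const arma::mat& X, const arma::vec& y,
                   const arma::mat& Xval, const arma::vec& yval,
                   const arma::umat& order, List cfg) {
  Net n = net_from_list(params0);
  double slope = as<double>(cfg["leaky_slope"]);
  int epochs = as<int>(cfg["epochs"]);
  double lr = as<double>(cfg["lr_initial"]);
  double lr_reduced = as<double>(cfg["lr_reduced"]);
  double lr_switch = as<double>(cfg["lr_switch_train_acc"]);
  double b1 = as<double>(cfg["adam_beta1"]);
  double b2 = as<double>(cfg["adam_beta2"]);
  double adam_eps = as<double>(cfg["adam_eps"]);
  double bn_eps = as<double>(cfg["bn_eps"]);
  double momentum = as<double>(cfg["bn_momentum"]);
  int batch_size = as<int>(cfg["batch_size"]);
  int nobs = X.n_rows;
  if (batch_size <= 0 || batch_size > nobs) batch_size = nobs;

  AdamState ad;
  for (int l = 0; l < 4; ++l) {
    ad.mW.push_back(arma::zeros<mat>(n.W[l].n_rows, n.W[l].n_cols));
    ad.vW.push_back(arma::zeros<mat>(n.W[l].n_rows, n.W[l].n_cols));
    ad.mb.push_back(arma::zeros<rowvec>(n.b[l].n_elem));
    ad.vb.push_back(arma::zeros<rowvec>(n.b[l].n_elem));
  }
  for (int l = 0; l < 3; ++l) {
    ad.mg.push_back(arma::zeros<rowvec>(n.gamma[l].n_elem));
    ad.vg.push_back(arma::zeros<rowvec>(n.gamma[l].n_elem));
    ad.mbe.push_back(arma::zeros<rowvec>(n.beta[l].n_elem));
    ad.vbe.push_back(arma::zeros<rowvec>(n.beta[l].n_elem));
  }

  bool switched = false;
  double best_val = arma::datum::inf;
  int best_epoch = -1;
  Net best = n;
  vec hist_train_acc(epochs), hist_val_loss(epochs), hist_lr(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    uvec idx = order.row(ep).t() - 1;  // 1-based from R
    int start = 0;
    while (start < nobs) {
      int stop = std::min(start + batch_size, nobs);
      // avoid singleton batches: batch statistics would be degenerate
      if (nobs - stop == 1) stop = nobs;
      uvec bidx = idx.subvec(start, stop - 1);
      mat Xb = X.rows(bidx);
      vec yb = y.elem(bidx);
      Cache c = train_forward(n, Xb, slope, bn_eps, momentum);
      Grads g = backward(n, c, yb, slope);
      ad.t += 1;
      for (int l = 0; l < 4; ++l) {
        adam_update_mat(n.W[l], g.W[l], ad.mW[l], ad.vW[l], lr, b1, b2,
                        adam_eps, ad.t);
        adam_update_row(n.b[l], g.b[l], ad.mb[l], ad.vb[l], lr, b1, b2,
                        adam_eps, ad.t);
      }
      for (int l = 0; l < 3; ++l) {
        adam_update_row(n.gamma[l], g.gamma[l], ad.mg[l], ad.vg[l], lr, b1,
                        b2, adam_eps, ad.t);
        adam_update_row(n.beta[l], g.beta[l], ad.mbe[l], ad.vbe[l], lr, b1,
                        b2, adam_eps, ad.t);
      }
      start = stop;
    }
    vec ptr = eval_forward(n, X, slope, bn_eps);
    double train_acc =
        arma::mean(arma::conv_to<vec>::from((ptr > 0.5) == (y > 0.5)));
    vec pv = eval_forward(n, Xval, slope, bn_eps);
    double val_loss = bce(pv, yval);
    hist_train_acc(ep) = train_acc;
    hist_val_loss(ep) = val_loss;
    hist_lr(ep) = lr;
    if (val_loss < best_val) {
      best_val = val_loss;
      best_epoch = ep + 1;
      best = n;
    }
    if (!switched && train_acc >= lr_switch) {
      lr = lr_reduced;
      switched = true;
    }
  }

  return List::create(
      _["final"] = net_to_list(n), _["best"] = net_to_list(best),
      _["best_epoch"] = best_epoch, _["best_val_loss"] = best_val,
      _["lr_switched"] = switched,
      _["history"] = List::create(_["train_acc"] = hist_train_acc,
                                  _["val_loss"] = hist_val_loss,
                                  _["lr"] = hist_lr));
}

// [[Rcpp::export]]
arma::vec mlp_eval_cpp(List params, const arma::mat& X, double leaky_slope,
                       double bn_eps) {
  Net n = net_from_list(params);
  return eval_forward(n, X, leaky_slope, bn_eps);
}

// Training-mode loss and gradients for one batch; exposed for
// finite-difference gradient checking from R.
// [[Rcpp::export]]
List mlp_grad_cpp(List params, const arma::mat& X, const arma::vec& y,
                  double leaky_slope, double bn_eps) {
  Net n = net_from_list(params);
  Cache c = train_forward(n, X, leaky_slope, bn_eps, 0.0);
  Grads g = backward(n, c, y, leaky_slope);
  List gl;
  for (int l = 0; l < 4; ++l) {
    gl["W" + std::to_string(l + 1)] = g.W[l];
    gl["b" + std::to_string(l + 1)] = g.b[l];
  }
  for (int l = 0; l < 3; ++l) {
    gl["gamma" + std::to_string(l + 1)] = g.gamma[l];
    gl["beta" + std::to_string(l + 1)] = g.beta[l];
  }
  return List::create(_["loss"] = bce(c.p, y), _["grads"] = gl);
}

// Training-mode loss only (batch statistics from X itself).
// [[Rcpp::export]]
double mlp_train_loss_cpp(List params, const arma::mat& X, const arma::vec& y,
                          double leaky_slope, double bn_eps) {
  Net n = net_from_list(params);
  Cache c = train_forward(n, X, leaky_slope, bn_eps, 0.0);
  return bce(c.p, y);
}
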