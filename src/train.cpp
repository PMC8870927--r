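// Whole-training-loop driver for the 1-D convolutional regressor: runs
// all epochs of mini-batch SGD (MSE loss, step-decayed learning rate,
// momentum) in one call, so the R side pays no per-batch interface cost.
// Layer parameters arrive as the R-side state lists and are returned in
// the same layout, together with the per-epoch losses and the checkpoint
// registry.  Batch order is supplied by R (pre-drawn permutations), which
// keeps training deterministic under R's seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

enum LType { CONV = 0, BN = 1, RELU = 2, SIGMOID = 3, MAXPOOL = 4,
             AVGPOOL = 5, FLATTEN = 6, DENSE = 7 };

struct Lay {
  int type = 0;
  mat W, vW, gW;
  vec b, vb, gb;
  int k = 0, s = 0, p = 0, cin = 0, cout = 0;
  vec gamma, beta, vgamma, vbeta, ggamma, gbeta, rmean, rvar;
  double eps = 1e-5, mom = 0.1;
  int C = 0;
  // caches
  mat Xcol, bn_xhat, act_out, in_cache;
  vec bn_sdv;
  Mat<int> mp_arg;
  int len_in = 0, len_out = 0, Bcur = 0;
};

int type_code(const std::string& t) {
  if (t == "conv1d") return CONV;
  if (t == "batchnorm") return BN;
  if (t == "relu") return RELU;
  if (t == "sigmoid") return SIGMOID;
  if (t == "maxpool") return MAXPOOL;
  if (t == "avgpool") return AVGPOOL;
  if (t == "flatten") return FLATTEN;
  if (t == "dense") return DENSE;
  stop("unknown layer type: " + t);
}

std::vector<Lay> parse_layers(const List& spec) {
  std::vector<Lay> L(spec.size());
  for (int i = 0; i < spec.size(); ++i) {
    List li = spec[i];
    Lay& l = L[i];
    l.type = type_code(as<std::string>(li["type"]));
    if (l.type == CONV) {
      l.W = as<mat>(li["W"]); l.vW = as<mat>(li["vW"]);
      l.k = as<int>(li["kernel"]); l.s = as<int>(li["stride"]);
      l.p = as<int>(li["padding"]);
      l.cin = as<int>(li["c_in"]); l.cout = as<int>(li["c_out"]);
    } else if (l.type == BN) {
      l.gamma = as<vec>(li["gamma"]); l.beta = as<vec>(li["beta"]);
      l.vgamma = as<vec>(li["vgamma"]); l.vbeta = as<vec>(li["vbeta"]);
      l.rmean = as<vec>(li["running_mean"]);
      l.rvar = as<vec>(li["running_var"]);
      l.eps = as<double>(li["eps"]); l.mom = as<double>(li["momentum"]);
      l.C = as<int>(li["channels"]);
    } else if (l.type == MAXPOOL || l.type == AVGPOOL) {
      l.k = as<int>(li["kernel"]); l.s = as<int>(li["stride"]);
    } else if (l.type == DENSE) {
      l.W = as<mat>(li["W"]); l.vW = as<mat>(li["vW"]);
      l.b = as<vec>(li["b"]); l.vb = as<vec>(li["vb"]);
    }
  }
  return L;
}

// Forward one batch; X is (channels, len*B), column blocks per sample.
mat forward(std::vector<Lay>& L, mat X, int len, int B) {
  for (Lay& l : L) {
    switch (l.type) {
    case CONV: {
      const int lpad = len + 2 * l.p;
      const int lout = (lpad - l.k) / l.s + 1;
      mat Xp;
      if (l.p > 0) {
        Xp.zeros(l.cin, lpad * B);
        for (int b = 0; b < B; ++b)
          Xp.cols(b * lpad + l.p, b * lpad + l.p + len - 1) =
            X.cols(b * len, b * len + len - 1);
      } else Xp = X;
      l.Xcol.set_size(l.cin * l.k, lout * B);
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < lout; ++j)
          l.Xcol.col(b * lout + j) = vectorise(
            Xp.cols(b * lpad + j * l.s, b * lpad + j * l.s + l.k - 1));
      X = l.W * l.Xcol;
      l.len_in = len; l.len_out = lout; l.Bcur = B;
      len = lout;
      break;
    }
    case BN: {
      const double n = X.n_cols;
      vec mu = mean(X, 1);
      l.bn_xhat = X.each_col() - mu;
      vec v = mean(l.bn_xhat % l.bn_xhat, 1);
      l.bn_sdv = sqrt(v + l.eps);
      l.bn_xhat.each_col() /= l.bn_sdv;
      l.rmean = (1 - l.mom) * l.rmean + l.mom * mu;
      l.rvar = (1 - l.mom) * l.rvar + l.mom * v * n / std::max(n - 1, 1.0);
      X = l.bn_xhat.each_col() % l.gamma;
      X.each_col() += l.beta;
      break;
    }
    case RELU: {
      X.transform([](double v) { return v > 0 ? v : 0.0; });
      l.act_out = X;
      break;
    }
    case SIGMOID: {
      X.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
      l.act_out = X;
      break;
    }
    case MAXPOOL: {
      const int C = X.n_rows;
      const int lout = (len - l.k) / l.s + 1;
      mat Y(C, lout * B);
      l.mp_arg.set_size(C, lout * B);
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < lout; ++j)
          for (int c = 0; c < C; ++c) {
            double best = X(c, b * len + j * l.s);
            int bk = 0;
            for (int kk = 1; kk < l.k; ++kk) {
              const double v = X(c, b * len + j * l.s + kk);
              if (v > best) { best = v; bk = kk; }
            }
            Y(c, b * lout + j) = best;
            l.mp_arg(c, b * lout + j) = bk;
          }
      X = std::move(Y);
      l.len_in = len; l.len_out = lout; l.Bcur = B;
      len = lout;
      break;
    }
    case AVGPOOL: {
      const int C = X.n_rows;
      const int lout = (len - l.k) / l.s + 1;
      mat Y(C, lout * B, fill::zeros);
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < lout; ++j) {
          for (int kk = 0; kk < l.k; ++kk)
            Y.col(b * lout + j) += X.col(b * len + j * l.s + kk);
          Y.col(b * lout + j) /= l.k;
        }
      X = std::move(Y);
      l.len_in = len; l.len_out = lout; l.Bcur = B;
      len = lout;
      break;
    }
    case FLATTEN: {
      // column blocks per sample are contiguous, so flattening is a
      // plain reshape of the same memory
      X.reshape(X.n_rows * len, B);
      l.len_in = len;
      len = 1;
      break;
    }
    case DENSE: {
      l.in_cache = X;
      X = l.W * X;
      X.each_col() += l.b;
      break;
    }
    }
  }
  return X;
}

mat backward(std::vector<Lay>& L, mat dY) {
  for (int i = (int) L.size() - 1; i >= 0; --i) {
    Lay& l = L[i];
    switch (l.type) {
    case CONV: {
      const int lpad = l.len_in + 2 * l.p;
      l.gW = dY * l.Xcol.t();
      mat dXcol = l.W.t() * dY;
      mat dXp(l.cin, lpad * l.Bcur, fill::zeros);
      for (int b = 0; b < l.Bcur; ++b)
        for (int j = 0; j < l.len_out; ++j)
          dXp.cols(b * lpad + j * l.s, b * lpad + j * l.s + l.k - 1) +=
            reshape(dXcol.col(b * l.len_out + j), l.cin, l.k);
      if (l.p > 0) {
        mat dX(l.cin, l.len_in * l.Bcur);
        for (int b = 0; b < l.Bcur; ++b)
          dX.cols(b * l.len_in, (b + 1) * l.len_in - 1) =
            dXp.cols(b * lpad + l.p, b * lpad + l.p + l.len_in - 1);
        dY = std::move(dX);
      } else dY = std::move(dXp);
      break;
    }
    case BN: {
      l.ggamma = sum(dY % l.bn_xhat, 1);
      l.gbeta = sum(dY, 1);
      mat dxhat = dY.each_col() % l.gamma;
      vec m1 = mean(dxhat, 1);
      vec m2 = mean(dxhat % l.bn_xhat, 1);
      dY = dxhat.each_col() - m1;
      dY -= l.bn_xhat.each_col() % m2;
      dY.each_col() /= l.bn_sdv;
      break;
    }
    case RELU: {
      const mat& Y = l.act_out;
      for (uword j = 0; j < dY.n_elem; ++j)
        if (Y[j] <= 0) dY[j] = 0;
      break;
    }
    case SIGMOID: {
      dY %= l.act_out % (1 - l.act_out);
      break;
    }
    case MAXPOOL: {
      const int C = dY.n_rows;
      mat dX(C, l.len_in * l.Bcur, fill::zeros);
      for (int b = 0; b < l.Bcur; ++b)
        for (int j = 0; j < l.len_out; ++j)
          for (int c = 0; c < C; ++c)
            dX(c, b * l.len_in + j * l.s + l.mp_arg(c, b * l.len_out + j))
              += dY(c, b * l.len_out + j);
      dY = std::move(dX);
      break;
    }
    case AVGPOOL: {
      const int C = dY.n_rows;
      mat dX(C, l.len_in * l.Bcur, fill::zeros);
      for (int b = 0; b < l.Bcur; ++b)
        for (int j = 0; j < l.len_out; ++j)
          for (int kk = 0; kk < l.k; ++kk)
            dX.col(b * l.len_in + j * l.s + kk) +=
              dY.col(b * l.len_out + j) / l.k;
      dY = std::move(dX);
      break;
    }
    case FLATTEN: {
      dY.reshape(dY.n_rows / l.len_in, l.len_in * dY.n_cols);
      break;
    }
    case DENSE: {
      l.gW = dY * l.in_cache.t();
      l.gb = sum(dY, 1);
      dY = l.W.t() * dY;
      break;
    }
    }
  }
  return dY;
}

void sgd_step(std::vector<Lay>& L, double lr, double momentum) {
  for (Lay& l : L) {
    if (l.type == CONV) {
      l.vW = momentum * l.vW - lr * l.gW;
      l.W += l.vW;
    } else if (l.type == DENSE) {
      l.vW = momentum * l.vW - lr * l.gW;
      l.W += l.vW;
      l.vb = momentum * l.vb - lr * l.gb;
      l.b += l.vb;
    } else if (l.type == BN) {
      l.vgamma = momentum * l.vgamma - lr * l.ggamma;
      l.gamma += l.vgamma;
      l.vbeta = momentum * l.vbeta - lr * l.gbeta;
      l.beta += l.vbeta;
    }
  }
}

// State in the same per-layer named-list layout the R side uses.
List export_state(const std::vector<Lay>& L, bool with_momentum) {
  List out(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    const Lay& l = L[i];
    if (l.type == CONV) {
      if (with_momentum)
        out[i] = List::create(_["W"] = l.W, _["vW"] = l.vW);
      else out[i] = List::create(_["W"] = l.W);
    } else if (l.type == DENSE) {
      if (with_momentum)
        out[i] = List::create(_["W"] = l.W, _["b"] = l.b,
                              _["vW"] = l.vW, _["vb"] = l.vb);
      else out[i] = List::create(_["W"] = l.W, _["b"] = l.b);
    } else if (l.type == BN) {
      if (with_momentum)
        out[i] = List::create(_["gamma"] = l.gamma, _["beta"] = l.beta,
                              _["running_mean"] = l.rmean,
                              _["running_var"] = l.rvar,
                              _["vgamma"] = l.vgamma,
                              _["vbeta"] = l.vbeta);
      else out[i] = List::create(_["gamma"] = l.gamma, _["beta"] = l.beta,
                                 _["running_mean"] = l.rmean,
                                 _["running_var"] = l.rvar);
    } else {
      out[i] = List::create();
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_train_sgd(const List& layer_spec, const arma::cube& X,
                   const arma::vec& y, const arma::imat& perms,
                   int batch_size, double lr0, int lr_step,
                   double lr_gamma, double momentum, int ckpt_every) {
  std::vector<Lay> L = parse_layers(layer_spec);
  const int C = X.n_rows, len = X.n_cols, N = X.n_slices;
  const int n_epochs = perms.n_cols;
  if ((int) perms.n_rows != N) stop("permutation size mismatch");
  // (C, len*N) view of the input cube
  const mat Xall(const_cast<double*>(X.memptr()), C, len * N, false, true);
  vec loss(n_epochs);
  List ckpts;
  CharacterVector ckpt_names;
  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double lr = lr0 * std::pow(lr_gamma, (epoch - 1) / lr_step);
    double tot = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int bn = std::min(batch_size, N - start);
      mat Xb(C, len * bn);
      vec yb(bn);
      for (int bi = 0; bi < bn; ++bi) {
        const int i = perms(start + bi, epoch - 1) - 1;  // R is 1-based
        Xb.cols(bi * len, (bi + 1) * len - 1) =
          Xall.cols(i * len, (i + 1) * len - 1);
        yb[bi] = y[i];
      }
      mat out = forward(L, std::move(Xb), len, bn);
      rowvec err = out.row(0) - yb.t();
      tot += accu(err % err);
      mat dY = (2.0 / bn) * err;
      backward(L, std::move(dY));
      sgd_step(L, lr, momentum);
    }
    loss[epoch - 1] = tot / N;
    if (!std::isfinite(loss[epoch - 1]))
      stop("training diverged (non-finite loss) at epoch %d", epoch);
    if (epoch % ckpt_every == 0 || epoch == n_epochs) {
      ckpts.push_back(export_state(L, false));
      ckpt_names.push_back(std::to_string(epoch));
    }
  }
  ckpts.attr("names") = ckpt_names;
  return List::create(_["loss"] = NumericVector(loss.begin(), loss.end()),
                      _["checkpoints"] = ckpts,
                      _["final"] = export_state(L, true));
}
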