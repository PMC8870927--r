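// Hot paths of the 1-D network layers: im2col convolution, batch
// normalization, max pooling and ReLU, forward and backward.  Data layout
// matches the R side: cubes are (channels, length, batch), column-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat im2col(const cube& Xp, int K, int s, int Lout) {
  const int Cin = Xp.n_rows, B = Xp.n_slices;
  mat out(Cin * K, Lout * B);
  for (int b = 0; b < B; ++b) {
    const mat& sl = Xp.slice(b);
    for (int j = 0; j < Lout; ++j) {
      out.col(b * Lout + j) = vectorise(sl.cols(j * s, j * s + K - 1));
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_fwd(const arma::cube& X, const arma::mat& W,
                  int K, int s, int p) {
  const int Cin = X.n_rows, Lin = X.n_cols, B = X.n_slices;
  const int Lpad = Lin + 2 * p;
  const int Lout = (Lpad - K) / s + 1;
  mat Xcol;
  if (p > 0) {
    cube Xp = zeros<cube>(Cin, Lpad, B);
    Xp.cols(p, p + Lin - 1) = X;
    Xcol = im2col(Xp, K, s, Lout);
  } else {
    Xcol = im2col(X, K, s, Lout);
  }
  mat Ym = W * Xcol;
  cube Y(Ym.memptr(), W.n_rows, Lout, B);
  return List::create(_["Y"] = Y, _["Xcol"] = Xcol);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& dY, const arma::mat& Xcol,
                  const arma::mat& W, int Cin, int Lin, int B,
                  int K, int s, int p) {
  const int Lpad = Lin + 2 * p;
  const int Lout = (Lpad - K) / s + 1;
  mat gW = dY * Xcol.t();
  mat dXcol = W.t() * dY;  // (Cin*K, Lout*B)
  cube dXp = zeros<cube>(Cin, Lpad, B);
  for (int b = 0; b < B; ++b) {
    mat& sl = dXp.slice(b);
    for (int j = 0; j < Lout; ++j) {
      sl.cols(j * s, j * s + K - 1) +=
        reshape(dXcol.col(b * Lout + j), Cin, K);
    }
  }
  cube dX = (p > 0) ? cube(dXp.cols(p, p + Lin - 1)) : dXp;
  return List::create(_["gW"] = gW, _["dX"] = dX);
}

// [[Rcpp::export]]
List cpp_bn_fwd(const arma::vec& X, const arma::vec& gamma,
                const arma::vec& beta, int C, double eps) {
  const int n = X.n_elem / C;
  const mat Xm(const_cast<double*>(X.memptr()), C, n, false, true);
  vec mu = mean(Xm, 1);
  mat xhat = Xm.each_col() - mu;
  vec v = mean(xhat % xhat, 1);
  vec sdv = sqrt(v + eps);
  xhat.each_col() /= sdv;
  mat Y = xhat.each_col() % gamma;
  Y.each_col() += beta;
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["sdv"] = sdv,
                      _["mu"] = mu, _["v"] = v);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::vec& dY, const arma::mat& xhat,
                const arma::vec& sdv, const arma::vec& gamma, int C) {
  const int n = dY.n_elem / C;
  const mat dYm(const_cast<double*>(dY.memptr()), C, n, false, true);
  vec ggamma = sum(dYm % xhat, 1);
  vec gbeta = sum(dYm, 1);
  mat dxhat = dYm.each_col() % gamma;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() /= sdv;
  return List::create(_["ggamma"] = ggamma, _["gbeta"] = gbeta,
                      _["dX"] = dX);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& X, int K, int s) {
  const int C = X.n_rows, Lin = X.n_cols, B = X.n_slices;
  const int Lout = (Lin - K) / s + 1;
  cube Y(C, Lout, B);
  cube arg(C, Lout, B);  // tap index stored as double: safe R round-trip
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < Lout; ++j) {
      for (int c = 0; c < C; ++c) {
        double best = X(c, j * s, b);
        int bk = 0;
        for (int k = 1; k < K; ++k) {
          const double v = X(c, j * s + k, b);
          if (v > best) { best = v; bk = k; }
        }
        Y(c, j, b) = best;
        arg(c, j, b) = bk;
      }
    }
  }
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& dY, const arma::cube& arg,
                           int Lin, int K, int s) {
  const int C = dY.n_rows, Lout = dY.n_cols, B = dY.n_slices;
  cube dX = zeros<cube>(C, Lin, B);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < Lout; ++j) {
      for (int c = 0; c < C; ++c) {
        dX(c, j * s + (int) arg(c, j, b), b) += dY(c, j, b);
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
arma::vec cpp_relu_fwd(const arma::vec& X) {
  vec Y = X;
  Y.transform([](double v) { return v > 0 ? v : 0.0; });
  return Y;
}

// [[Rcpp::export]]
arma::vec cpp_relu_bwd(const arma::vec& dY, const arma::vec& Y) {
  vec dX = dY;
  for (uword i = 0; i < dX.n_elem; ++i) if (Y[i] <= 0) dX[i] = 0;
  return dX;
}
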