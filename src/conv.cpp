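// Valid stride-1 2-D convolution over a (C, H, W, B) array, lowered to
// matrix multiplication (im2col + GEMM). Patch-matrix layout matches the
// R side: row r = c + C*(dy + k*dx), column j = y + Ho*(x + Wo*b).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const vec& x, int C, int H, int W, int B, int k) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  mat M(C * k * k, (size_t)Ho * Wo * B);
  const double* xp = x.memptr();
  for (int b = 0; b < B; ++b) {
    const size_t xoff = (size_t)b * C * H * W;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t col = (size_t)b * Ho * Wo + (size_t)xo * Ho + yo;
        double* dst = M.colptr(col);
        for (int dx = 0; dx < k; ++dx) {
          for (int dy = 0; dy < k; ++dy) {
            const double* src =
                xp + xoff + (size_t)(xo + dx) * C * H + (size_t)(yo + dy) * C;
            std::memcpy(dst + (size_t)C * (dy + k * dx), src,
                        C * sizeof(double));
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::mat cpp_conv_forward(const arma::vec& x, Rcpp::IntegerVector dims,
                           const arma::mat& Wm, const arma::vec& b, int k) {
  mat M = im2col(x, dims[0], dims[1], dims[2], dims[3], k);
  mat Z = Wm * M;
  Z.each_col() += b;
  return Z;
}


static void col2im_add(const mat& dM, int C, int H, int W, int B, int k,
                       double* xp) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  for (int b2 = 0; b2 < B; ++b2) {
    const size_t xoff = (size_t)b2 * C * H * W;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t col = (size_t)b2 * Ho * Wo + (size_t)xo * Ho + yo;
        const double* src = dM.colptr(col);
        for (int dx2 = 0; dx2 < k; ++dx2) {
          for (int dy = 0; dy < k; ++dy) {
            double* dst = xp + xoff + (size_t)(xo + dx2) * C * H +
                          (size_t)(yo + dy) * C;
            const double* s = src + (size_t)C * (dy + k * dx2);
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
        }
      }
    }
  }
}

// Fused conv + ReLU forward for the training loop: keeps the patch matrix
// alive between forward and backward via an external pointer so it is
// gathered only once per batch.
// [[Rcpp::export]]
Rcpp::List cpp_conv_relu_forward(const Rcpp::NumericVector& x,
                                 Rcpp::IntegerVector dims,
                                 const Rcpp::NumericMatrix& Wm,
                                 const Rcpp::NumericVector& b, int k) {
  const vec xv(const_cast<double*>(x.begin()), x.size(), false, true);
  const mat W(const_cast<double*>(Wm.begin()), Wm.nrow(), Wm.ncol(), false,
              true);
  const vec bv(const_cast<double*>(b.begin()), b.size(), false, true);
  mat* M = new mat(im2col(xv, dims[0], dims[1], dims[2], dims[3], k));
  mat A = W * (*M);
  A.each_col() += bv;
  A.transform([](double v) { return v > 0 ? v : 0.0; });
  Rcpp::XPtr<mat> pM(M, true);
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("M") = pM);
}

// Backward for the fused layer: the ReLU mask is recovered from the
// activations (A > 0 iff the pre-activation was > 0).
// [[Rcpp::export]]
Rcpp::List cpp_conv_relu_backward(SEXP Mptr, const Rcpp::NumericMatrix& Wm,
                                  const Rcpp::NumericMatrix& A,
                                  const Rcpp::NumericMatrix& dA,
                                  Rcpp::IntegerVector dims, int k,
                                  bool need_dx) {
  Rcpp::XPtr<mat> pM(Mptr);
  const mat W(const_cast<double*>(Wm.begin()), Wm.nrow(), Wm.ncol(), false,
              true);
  const mat Am(const_cast<double*>(A.begin()), A.nrow(), A.ncol(), false,
               true);
  const mat dAm(const_cast<double*>(dA.begin()), dA.nrow(), dA.ncol(), false,
                true);
  mat dZ = dAm % (Am > 0);
  mat dW = dZ * pM->t();
  vec db = sum(dZ, 1);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) {
    const int C = dims[0], H = dims[1], W2 = dims[2], B = dims[3];
    mat dM = W.t() * dZ;
    vec dx((size_t)C * H * W2 * B, fill::zeros);
    col2im_add(dM, C, H, W2, B, k, dx.memptr());
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::vec& x, Rcpp::IntegerVector dims,
                             const arma::mat& Wm, int k, const arma::mat& dZ,
                             bool need_dx) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  mat M = im2col(x, C, H, W, B, k);
  mat dW = dZ * M.t();
  vec db = sum(dZ, 1);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) {
    mat dM = Wm.t() * dZ;
    vec dx((size_t)C * H * W * B, fill::zeros);
    col2im_add(dM, C, H, W, B, k, dx.memptr());
    out["dx"] = dx;
  }
  return out;
}
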