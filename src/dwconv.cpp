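#include <Rcpp.h>
using namespace Rcpp;

// Depthwise spatial convolution over a batched activation matrix.
//
// Activations are stored as a (V * B) x C matrix: row (b-1)*V + v holds the
// value of spatial voxel v (column-major linear index) of sample b; columns
// are channels. `idx` is a Vout x K integer map: idx(o, k) is the 1-based
// input voxel gathered by kernel tap k at output voxel o, or 0 when the tap
// falls into the zero padding. `W` is K x C (one 3^d kernel per channel).

// [[Rcpp::export]]
NumericMatrix dw_forward(const NumericMatrix& X, const IntegerMatrix& idx,
                         const NumericMatrix& W, const int B) {
  const int K = idx.ncol(), Vout = idx.nrow(), C = X.ncol();
  const int Vin = X.nrow() / B;
  NumericMatrix out(Vout * B, C);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const int xoff = b * Vin, ooff = b * Vout;
      for (int o = 0; o < Vout; ++o) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) {
          const int i = idx(o, k);
          if (i > 0) acc += X(xoff + i - 1, c) * W(k, c);
        }
        out(ooff + o, c) = acc;
      }
    }
  }
  return out;
}

// Gradients of dw_forward with respect to the input activations and the
// kernel weights. Within one kernel tap the gather map is injective
// (stride 2 > dilation 1), so the scatter-add below has no races.

// [[Rcpp::export]]
List dw_backward(const NumericMatrix& dOut, const NumericMatrix& X,
                 const IntegerMatrix& idx, const NumericMatrix& W,
                 const int B, const bool need_dx = true) {
  const int K = idx.ncol(), Vout = idx.nrow(), C = X.ncol();
  const int Vin = X.nrow() / B;
  NumericMatrix dX(need_dx ? Vin * B : 1, need_dx ? C : 1);
  NumericMatrix dW(K, C);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const int xoff = b * Vin, ooff = b * Vout;
      for (int o = 0; o < Vout; ++o) {
        const double g = dOut(ooff + o, c);
        if (g == 0.0) continue;
        for (int k = 0; k < K; ++k) {
          const int i = idx(o, k);
          if (i > 0) {
            if (need_dx) dX(xoff + i - 1, c) += g * W(k, c);
            dW(k, c) += g * X(xoff + i - 1, c);
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW);
}

// Fused batch-norm (given per-channel mean and inverse SD) + affine + ReLU:
// returns the normalised activations xhat and the block output A.

// [[Rcpp::export]]
List bn_relu_forward(const NumericMatrix& Xp, const NumericVector& mu,
                     const NumericVector& invstd, const NumericVector& gamma,
                     const NumericVector& beta) {
  const int n = Xp.nrow(), C = Xp.ncol();
  NumericMatrix xhat(n, C), A(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = invstd[c], g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double xh = (Xp(i, c) - m) * s;
      xhat(i, c) = xh;
      const double y = g * xh + b;
      A(i, c) = y > 0.0 ? y : 0.0;
    }
  }
  return List::create(_["xhat"] = xhat, _["A"] = A);
}

// Fused backward through ReLU + batch norm. `A` is the block output (its
// positivity encodes the ReLU mask). In training mode the batch-statistic
// terms are included; in evaluation mode mean/var are constants.

// [[Rcpp::export]]
List bn_relu_backward(const NumericMatrix& dA, const NumericMatrix& A,
                      const NumericMatrix& xhat, const NumericVector& gamma,
                      const NumericVector& invstd, const bool training) {
  const int n = dA.nrow(), C = dA.ncol();
  NumericMatrix dXp(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], s = invstd[c];
    double sum_dx = 0.0, sum_dx_xh = 0.0, dg = 0.0, db = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dy = A(i, c) > 0.0 ? dA(i, c) : 0.0;
      dg += dy * xhat(i, c);
      db += dy;
      const double dxh = dy * g;
      sum_dx += dxh;
      sum_dx_xh += dxh * xhat(i, c);
      dXp(i, c) = dxh;
    }
    dgamma[c] = dg; dbeta[c] = db;
    if (training) {
      const double m1 = sum_dx / n, m2 = sum_dx_xh / n;
      for (int i = 0; i < n; ++i) {
        const double dy = A(i, c) > 0.0 ? dA(i, c) : 0.0;
        dXp(i, c) = (dy * g - m1 - xhat(i, c) * m2) * s;
      }
    } else {
      for (int i = 0; i < n; ++i) dXp(i, c) *= s;
    }
  }
  return List::create(_["dXp"] = dXp, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
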