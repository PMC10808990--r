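// Minimal dense CNN kernels: im2col convolution (forward/backward) and
// bilinear upsampling (forward/backward). Tensors are R arrays in
// column-major (H, W, C) layout; weights are (k, k, Cin, Cout).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Build the im2col matrix: rows index output pixels (io + Hout*jo),
// columns index (di + k*dj + k*k*c). Zero padding outside the input.
// Valid output range [lo, hi] such that o*stride + d - pad stays in
// [0, n-1].
inline void validRange(int n, int nOut, int stride, int d, int pad,
                       int& lo, int& hi) {
  int num = pad - d;
  lo = num <= 0 ? 0 : (num + stride - 1) / stride;
  hi = std::min(nOut - 1, (n - 1 + pad - d) / stride);
}

arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                 int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(static_cast<size_t>(Hout) * Wout,
              static_cast<size_t>(k) * k * C, arma::fill::zeros);
  const double* xp = x.memptr();
  double* Mp = M.memptr();
  const size_t colStride = static_cast<size_t>(Hout) * Wout;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + static_cast<size_t>(H) * W * c;
    for (int dj = 0; dj < k; ++dj) {
      int jlo, jhi;
      validRange(W, Wout, stride, dj, pad, jlo, jhi);
      for (int di = 0; di < k; ++di) {
        int ilo, ihi;
        validRange(H, Hout, stride, di, pad, ilo, ihi);
        double* Mcol =
            Mp + (di + k * dj + static_cast<size_t>(k) * k * c) *
                     colStride;
        for (int jo = jlo; jo <= jhi; ++jo) {
          const int j = jo * stride + dj - pad;
          const double* src = xc + static_cast<size_t>(H) * j;
          double* dst = Mcol + static_cast<size_t>(Hout) * jo;
          if (stride == 1) {
            std::memcpy(dst + ilo, src + ilo + di - pad,
                        (ihi - ilo + 1) * sizeof(double));
          } else {
            for (int io = ilo; io <= ihi; ++io)
              dst[io] = src[io * stride + di - pad];
          }
        }
      }
    }
  }
  return M;
}

void col2im_add(arma::cube& dx, const arma::mat& Mg, int k, int stride,
                int pad, int Hout, int Wout) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  double* xp = dx.memptr();
  const double* Mp = Mg.memptr();
  const size_t colStride = static_cast<size_t>(Hout) * Wout;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + static_cast<size_t>(H) * W * c;
    for (int dj = 0; dj < k; ++dj) {
      int jlo, jhi;
      validRange(W, Wout, stride, dj, pad, jlo, jhi);
      for (int di = 0; di < k; ++di) {
        int ilo, ihi;
        validRange(H, Hout, stride, di, pad, ilo, ihi);
        const double* Mcol =
            Mp + (di + k * dj + static_cast<size_t>(k) * k * c) *
                     colStride;
        for (int jo = jlo; jo <= jhi; ++jo) {
          const int j = jo * stride + dj - pad;
          double* dst = xc + static_cast<size_t>(H) * j + di - pad;
          const double* src = Mcol + static_cast<size_t>(Hout) * jo;
          if (stride == 1) {
            for (int io = ilo; io <= ihi; ++io) dst[io] += src[io];
          } else {
            for (int io = ilo; io <= ihi; ++io)
              dst[io * stride] += src[io];
          }
        }
      }
    }
  }
}

arma::cube as_cube(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H, W, C)");
  return arma::cube(const_cast<double*>(a.begin()), d[0], d[1], d[2],
                    false, true);
}

NumericVector wrap_cube(const arma::cube& y) {
  NumericVector out(y.begin(), y.end());
  out.attr("dim") =
      IntegerVector::create(y.n_rows, y.n_cols, y.n_slices);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".convForward")]]
NumericVector conv_forward(NumericVector x, NumericVector w,
                           NumericVector b, int stride, int pad) {
  arma::cube xc = as_cube(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (k, k, Cin, Cout)");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("only square kernels are supported");
  if (Cin != static_cast<int>(xc.n_slices))
    stop("input channels do not match weights");
  const int Hout = (static_cast<int>(xc.n_rows) + 2 * pad - k) / stride + 1;
  const int Wout = (static_cast<int>(xc.n_cols) + 2 * pad - k) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()),
               static_cast<size_t>(k) * k * Cin, Cout, false, true);
  arma::mat M = im2col(xc, k, stride, pad, Hout, Wout);
  arma::mat Y = M * Wm;
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  arma::cube yc(Y.memptr(), Hout, Wout, Cout);
  return wrap_cube(yc);
}

// [[Rcpp::export(name = ".convBackward")]]
List conv_backward(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  arma::cube xc = as_cube(x);
  arma::cube dyc = as_cube(dy);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Hout = dyc.n_rows, Wout = dyc.n_cols;
  arma::mat Wm(const_cast<double*>(w.begin()),
               static_cast<size_t>(k) * k * Cin, Cout, false, true);
  arma::mat dYm(dyc.memptr(), static_cast<size_t>(Hout) * Wout, Cout,
                false, true);
  arma::mat M = im2col(xc, k, stride, pad, Hout, Wout);
  arma::mat dW = M.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dM = dYm * Wm.t();
  arma::cube dx(xc.n_rows, xc.n_cols, Cin, arma::fill::zeros);
  col2im_add(dx, dM, k, stride, pad, Hout, Wout);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["dx"] = wrap_cube(dx), _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Bilinear upsampling by an integer factor, half-pixel-center convention
// (align_corners = FALSE): output pixel i samples input at
// (i + 0.5)/f - 0.5, neighbours clamped at the border.
// [[Rcpp::export(name = ".upsampleForward")]]
NumericVector upsample_forward(NumericVector x, int factor) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = H * factor, Wo = W * factor;
  arma::cube y(Ho, Wo, C);
  std::vector<int> i0(Ho), i1(Ho), j0(Wo), j1(Wo);
  std::vector<double> wi(Ho), wj(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / factor - 0.5;
    int f = static_cast<int>(std::floor(s));
    wi[i] = s - f;
    i0[i] = std::min(std::max(f, 0), H - 1);
    i1[i] = std::min(std::max(f + 1, 0), H - 1);
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / factor - 0.5;
    int f = static_cast<int>(std::floor(s));
    wj[j] = s - f;
    j0[j] = std::min(std::max(f, 0), W - 1);
    j1[j] = std::min(std::max(f + 1, 0), W - 1);
  }
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double a = xc(i0[i], j0[j], c) * (1 - wi[i]) +
                   xc(i1[i], j0[j], c) * wi[i];
        double b = xc(i0[i], j1[j], c) * (1 - wi[i]) +
                   xc(i1[i], j1[j], c) * wi[i];
        y(i, j, c) = a * (1 - wj[j]) + b * wj[j];
      }
  return wrap_cube(y);
}

// [[Rcpp::export(name = ".upsampleBackward")]]
NumericVector upsample_backward(NumericVector dy, int H, int W,
                                int factor) {
  arma::cube dyc = as_cube(dy);
  const int Ho = dyc.n_rows, Wo = dyc.n_cols, C = dyc.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      double s = (j + 0.5) / factor - 0.5;
      int f = static_cast<int>(std::floor(s));
      double wjj = s - f;
      int jj0 = std::min(std::max(f, 0), W - 1);
      int jj1 = std::min(std::max(f + 1, 0), W - 1);
      for (int i = 0; i < Ho; ++i) {
        double si = (i + 0.5) / factor - 0.5;
        int fi = static_cast<int>(std::floor(si));
        double wii = si - fi;
        int ii0 = std::min(std::max(fi, 0), H - 1);
        int ii1 = std::min(std::max(fi + 1, 0), H - 1);
        double g = dyc(i, j, c);
        dx(ii0, jj0, c) += g * (1 - wii) * (1 - wjj);
        dx(ii1, jj0, c) += g * wii * (1 - wjj);
        dx(ii0, jj1, c) += g * (1 - wii) * wjj;
        dx(ii1, jj1, c) += g * wii * wjj;
      }
    }
  return wrap_cube(dx);
}
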