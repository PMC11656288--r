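// GEMM-backed 3D convolution (stride 1, zero "same" padding) used by the
// V-Net layers. Volumes are column-major R arrays with dim (X, Y, Z, C);
// weights are stored as a (k^3 * Cin) x Cout matrix whose row index is
// kx + k*(ky + k*(kz + k*cin)), matching the im2col layout below.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void build_col(const double* x, double* colmem,
                      int X, int Y, int Z, int Cin, int k) {
  const int d = (k - 1) / 2;
  const long N = (long)X * Y * Z;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (long)c * N;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const long jcol = kx + (long)k * (ky + (long)k * (kz + (long)k * c));
          double* dst = colmem + jcol * N;
          const int ox = kx - d, oy = ky - d, oz = kz - d;
          for (int z = 0; z < Z; ++z) {
            const int sz = z + oz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + oy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
              const long dbase = (long)z * X * Y + (long)y * X;
              const long sbase = (long)sz * X * Y + (long)sy * X + ox;
              for (int xx = x0; xx < x1; ++xx)
                dst[dbase + xx] = xc[sbase + xx];
            }
          }
        }
      }
    }
  }
}

// scatter-add adjoint of build_col
static void col2im_add(const arma::mat& gcol, double* gx,
                       int X, int Y, int Z, int Cin, int k) {
  const int d = (k - 1) / 2;
  const long N = (long)X * Y * Z;
  for (int c = 0; c < Cin; ++c) {
    double* gc = gx + (long)c * N;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const long jcol = kx + (long)k * (ky + (long)k * (kz + (long)k * c));
          const double* src = gcol.colptr(jcol);
          const int ox = kx - d, oy = ky - d, oz = kz - d;
          for (int z = 0; z < Z; ++z) {
            const int sz = z + oz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + oy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
              const long sbase = (long)z * X * Y + (long)y * X;
              const long dbase = (long)sz * X * Y + (long)sy * X + ox;
              for (int xx = x0; xx < x1; ++xx)
                gc[dbase + xx] += src[sbase + xx];
            }
          }
        }
      }
    }
  }
}

// forward pass; also returns the im2col matrix so the backward pass can
// reuse it instead of rebuilding
// [[Rcpp::export]]
List conv3d_fw_cpp(NumericVector x, NumericMatrix W, NumericVector b,
                   int X, int Y, int Z, int Cin, int k) {
  const long N = (long)X * Y * Z;
  const int Cout = W.ncol();
  NumericMatrix colr(N, (long)k * k * k * Cin);   // zero-initialized
  build_col(x.begin(), colr.begin(), X, Y, Z, Cin, k);
  const arma::mat col(colr.begin(), N, colr.ncol(), false);
  const arma::mat Wm(W.begin(), W.nrow(), Cout, false);
  NumericVector res(N * Cout);
  arma::mat out(res.begin(), N, Cout, false);
  out = col * Wm;
  for (int c = 0; c < Cout; ++c) out.col(c) += b[c];
  res.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return List::create(Named("out") = res, Named("col") = colr);
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericMatrix colr, NumericMatrix W, NumericVector gout,
                   int X, int Y, int Z, int Cin, int k, bool need_xgrad) {
  const long N = (long)X * Y * Z;
  const int Cout = W.ncol();
  const arma::mat col(colr.begin(), colr.nrow(), colr.ncol(), false);
  const arma::mat G(gout.begin(), N, Cout, false);
  arma::mat gW = col.t() * G;
  arma::vec gb = arma::sum(G, 0).t();

  NumericMatrix gWr(W.nrow(), Cout);
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gWr.begin());
  NumericVector gbr(Cout);
  std::copy(gb.memptr(), gb.memptr() + Cout, gbr.begin());

  List res = List::create(Named("gW") = gWr, Named("gb") = gbr);
  if (need_xgrad) {
    arma::mat Wm(W.begin(), W.nrow(), Cout, false);
    arma::mat gcol = G * Wm.t();
    NumericVector gx(N * Cin);  // zero-initialized
    col2im_add(gcol, gx.begin(), X, Y, Z, Cin, k);
    gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
    res["gx"] = gx;
  }
  return res;
}
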