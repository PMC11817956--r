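// Low-level numeric kernels for the 3D segmentation networks.
// Volumes are column-major R arrays with dim (X, Y, Z, C); convolution
// weights have dim (k, k, k, IC, OC) so that reshaping to a (k^3*IC x OC)
// matrix is a plain memory reinterpretation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (X, Y, Z, C)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill an im2col block for output z-slab [z0, z1).  col has k3*IC rows and
// (Xo*Yo*(z1-z0)) columns.
static void im2col_slab(const double *x, const int xd[4], int k, int stride,
                        int pad, int Xo, int Yo, int z0, int z1,
                        arma::mat &col) {
  const int X = xd[0], Y = xd[1], Z = xd[2], IC = xd[3];
  const int k3 = k * k * k;
  col.zeros();
  for (int oz = z0; oz < z1; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::uword cidx =
            (arma::uword)(ox + Xo * (oy + (arma::uword)Yo * (oz - z0)));
        double *cptr = col.colptr(cidx);
        const int bx = ox * stride - pad;
        const int by = oy * stride - pad;
        const int bz = oz * stride - pad;
        for (int ic = 0; ic < IC; ++ic) {
          const double *xc = x + (size_t)ic * X * Y * Z;
          for (int dz = 0; dz < k; ++dz) {
            const int iz = bz + dz;
            for (int dy = 0; dy < k; ++dy) {
              const int iy = by + dy;
              for (int dx = 0; dx < k; ++dx) {
                const int ix = bx + dx;
                const int row = dx + k * (dy + k * (dz + k * ic));
                if (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 &&
                    iz < Z) {
                  cptr[row] = xc[ix + (size_t)X * (iy + (size_t)Y * iz)];
                }
              }
            }
          }
        }
        (void)k3;
      }
    }
  }
}

static int pick_zchunk(int rows, int Xo, int Yo, int Zo) {
  // keep the im2col buffer under ~256 MB
  double budget = 32e6; // doubles
  int zc = (int)std::max(1.0, std::floor(budget / ((double)rows * Xo * Yo)));
  if (zc > Zo) zc = Zo;
  return zc;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  int xd[4];
  get_dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weight must have dim (k,k,k,IC,OC)");
  const int k = wd[0], IC = wd[3], OC = wd[4];
  if (wd[1] != k || wd[2] != k) stop("kernel must be cubic");
  if (xd[3] != IC) stop("input channels mismatch");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = (X + 2 * pad - k) / stride + 1;
  const int Yo = (Y + 2 * pad - k) / stride + 1;
  const int Zo = (Z + 2 * pad - k) / stride + 1;
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("output would be empty");
  const int rows = k * k * k * IC;
  arma::mat Wm(const_cast<double *>(w.begin()), rows, OC, false, true);

  NumericVector y((R_xlen_t)Xo * Yo * Zo * OC);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, OC);
  double *yp = y.begin();

  const int zc = pick_zchunk(rows, Xo, Yo, Zo);
  arma::mat col(rows, (arma::uword)Xo * Yo * zc);
  for (int z0 = 0; z0 < Zo; z0 += zc) {
    const int z1 = std::min(Zo, z0 + zc);
    arma::mat colv = col.cols(0, (arma::uword)Xo * Yo * (z1 - z0) - 1);
    im2col_slab(x.begin(), xd, k, stride, pad, Xo, Yo, z0, z1, colv);
    arma::mat out = Wm.t() * colv; // OC x n
    const arma::uword n = colv.n_cols;
    for (int oc = 0; oc < OC; ++oc) {
      double *dst =
          yp + (size_t)oc * Xo * Yo * Zo + (size_t)z0 * Xo * Yo;
      const double bb = b[oc];
      for (arma::uword j = 0; j < n; ++j) dst[j] = out(oc, j) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  int xd[4];
  get_dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], IC = wd[3], OC = wd[4];
  int yd[4];
  get_dims4(dy, yd);
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2];
  if (yd[3] != OC) stop("dy channels mismatch");
  const int rows = k * k * k * IC;
  arma::mat Wm(const_cast<double *>(w.begin()), rows, OC, false, true);

  NumericVector dxv((R_xlen_t)X * Y * Z * IC);
  dxv.attr("dim") = IntegerVector::create(X, Y, Z, IC);
  NumericVector dwv((R_xlen_t)rows * OC);
  dwv.attr("dim") = wd;
  NumericVector dbv(OC);
  arma::mat dWm(dwv.begin(), rows, OC, false, true);
  double *dx = dxv.begin();
  const double *dyp = dy.begin();

  const int zc = pick_zchunk(rows, Xo, Yo, Zo);
  arma::mat col(rows, (arma::uword)Xo * Yo * zc);
  for (int z0 = 0; z0 < Zo; z0 += zc) {
    const int z1 = std::min(Zo, z0 + zc);
    const arma::uword n = (arma::uword)Xo * Yo * (z1 - z0);
    arma::mat colv = col.cols(0, n - 1);
    im2col_slab(x.begin(), xd, k, stride, pad, Xo, Yo, z0, z1, colv);
    arma::mat G(OC, n);
    for (int oc = 0; oc < OC; ++oc) {
      const double *src =
          dyp + (size_t)oc * Xo * Yo * Zo + (size_t)z0 * Xo * Yo;
      double acc = 0.0;
      for (arma::uword j = 0; j < n; ++j) {
        G(oc, j) = src[j];
        acc += src[j];
      }
      dbv[oc] += acc;
    }
    dWm += colv * G.t();
    arma::mat dcol = Wm * G; // rows x n
    // col2im scatter-add
    for (int oz = z0; oz < z1; ++oz) {
      for (int oy = 0; oy < Yo; ++oy) {
        for (int ox = 0; ox < Xo; ++ox) {
          const arma::uword cidx =
              (arma::uword)(ox + Xo * (oy + (arma::uword)Yo * (oz - z0)));
          const double *cptr = dcol.colptr(cidx);
          const int bx = ox * stride - pad;
          const int by = oy * stride - pad;
          const int bz = oz * stride - pad;
          for (int ic = 0; ic < IC; ++ic) {
            double *xc = dx + (size_t)ic * X * Y * Z;
            for (int dz = 0; dz < k; ++dz) {
              const int iz = bz + dz;
              if (iz < 0 || iz >= Z) continue;
              for (int dyk = 0; dyk < k; ++dyk) {
                const int iy = by + dyk;
                if (iy < 0 || iy >= Y) continue;
                for (int dxk = 0; dxk < k; ++dxk) {
                  const int ix = bx + dxk;
                  if (ix < 0 || ix >= X) continue;
                  const int row = dxk + k * (dyk + k * (dz + k * ic));
                  xc[ix + (size_t)X * (iy + (size_t)Y * iz)] += cptr[row];
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
// [[Rcpp::export]]
NumericVector cpp_tconv3d_fwd(NumericVector x, NumericVector w,
                              NumericVector b) {
  int xd[4];
  get_dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5 || wd[0] != 2 || wd[1] != 2 || wd[2] != 2)
    stop("transposed conv expects a (2,2,2,IC,OC) kernel");
  const int IC = wd[3], OC = wd[4];
  if (xd[3] != IC) stop("input channels mismatch");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * OC);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, OC);
  double *yp = y.begin();
  const double *xp = x.begin();
  const double *wp = w.begin();
  for (int oc = 0; oc < OC; ++oc) {
    double *ych = yp + (size_t)oc * Xo * Yo * Zo;
    const double bb = b[oc];
    for (size_t i = 0; i < (size_t)Xo * Yo * Zo; ++i) ych[i] = bb;
  }
  for (int oc = 0; oc < OC; ++oc) {
    double *ych = yp + (size_t)oc * Xo * Yo * Zo;
    for (int ic = 0; ic < IC; ++ic) {
      const double *xc = xp + (size_t)ic * X * Y * Z;
      const double *wk = wp + (size_t)8 * (ic + (size_t)IC * oc);
      for (int kz = 0; kz < Z; ++kz)
        for (int jy = 0; jy < Y; ++jy)
          for (int ix = 0; ix < X; ++ix) {
            const double v = xc[ix + (size_t)X * (jy + (size_t)Y * kz)];
            if (v == 0.0) continue;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  ych[(2 * ix + dx) +
                      (size_t)Xo * ((2 * jy + dy) +
                                    (size_t)Yo * (2 * kz + dz))] +=
                      v * wk[dx + 2 * (dy + 2 * dz)];
                }
          }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv3d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int xd[4];
  get_dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int IC = wd[3], OC = wd[4];
  int yd[4];
  get_dims4(dy, yd);
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2];
  if (Xo != 2 * X || Yo != 2 * Y || Zo != 2 * Z || yd[3] != OC)
    stop("dy shape mismatch");
  NumericVector dxv((R_xlen_t)X * Y * Z * IC);
  dxv.attr("dim") = IntegerVector::create(X, Y, Z, IC);
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  NumericVector dbv(OC);
  double *dxp = dxv.begin();
  double *dwp = dwv.begin();
  const double *xp = x.begin();
  const double *wp = w.begin();
  const double *dyp = dy.begin();
  for (int oc = 0; oc < OC; ++oc) {
    const double *ych = dyp + (size_t)oc * Xo * Yo * Zo;
    double acc = 0.0;
    for (size_t i = 0; i < (size_t)Xo * Yo * Zo; ++i) acc += ych[i];
    dbv[oc] = acc;
    for (int ic = 0; ic < IC; ++ic) {
      const double *xc = xp + (size_t)ic * X * Y * Z;
      double *dxc = dxp + (size_t)ic * X * Y * Z;
      const double *wk = wp + (size_t)8 * (ic + (size_t)IC * oc);
      double *dwk = dwp + (size_t)8 * (ic + (size_t)IC * oc);
      for (int kz = 0; kz < Z; ++kz)
        for (int jy = 0; jy < Y; ++jy)
          for (int ix = 0; ix < X; ++ix) {
            const size_t xi = ix + (size_t)X * (jy + (size_t)Y * kz);
            const double xv = xc[xi];
            double g = 0.0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy2 = 0; dy2 < 2; ++dy2)
                for (int dx2 = 0; dx2 < 2; ++dx2) {
                  const double gy =
                      ych[(2 * ix + dx2) +
                          (size_t)Xo * ((2 * jy + dy2) +
                                        (size_t)Yo * (2 * kz + dz))];
                  g += gy * wk[dx2 + 2 * (dy2 + 2 * dz)];
                  dwk[dx2 + 2 * (dy2 + 2 * dz)] += gy * xv;
                }
            dxc[xi] += g;
          }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 26-connectivity component labeling of a binary 3D mask.
// [[Rcpp::export]]
List cpp_label_components(IntegerVector mask) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3-d array");
  const int X = dm[0], Y = dm[1], Z = dm[2];
  IntegerVector lab((R_xlen_t)X * Y * Z);
  lab.attr("dim") = dm;
  const int *m = mask.begin();
  int *L = lab.begin();
  int next = 0;
  std::vector<size_t> stack;
  std::vector<int> sizes;
  for (size_t s = 0; s < (size_t)X * Y * Z; ++s) {
    if (m[s] == 0 || L[s] != 0) continue;
    ++next;
    int count = 0;
    stack.push_back(s);
    L[s] = next;
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      ++count;
      const int cx = cur % X;
      const int cy = (cur / X) % Y;
      const int cz = cur / ((size_t)X * Y);
      for (int dz = -1; dz <= 1; ++dz) {
        const int nz = cz + dz;
        if (nz < 0 || nz >= Z) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int ny = cy + dy;
          if (ny < 0 || ny >= Y) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int nx = cx + dx;
            if (nx < 0 || nx >= X) continue;
            const size_t ni = nx + (size_t)X * (ny + (size_t)Y * nz);
            if (m[ni] != 0 && L[ni] == 0) {
              L[ni] = next;
              stack.push_back(ni);
            }
          }
        }
      }
    }
    sizes.push_back(count);
  }
  return List::create(_["labels"] = lab, _["n"] = next,
                      _["sizes"] = wrap(sizes));
}
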