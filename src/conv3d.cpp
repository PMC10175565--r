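// Direct 3D convolution (cross-correlation) kernels for the voxel
// segmentation network. Tensor layout is R column-major [x, y, z, channel];
// weights are [kx, ky, kz, cin, cout]. "Same" zero padding: odd kernels pad
// (k-1)/2 on both sides, even kernels pad k/2-1 left and k/2 right.

#include <Rcpp.h>
using namespace Rcpp;

static inline int pad_left(int k) { return (k % 2 == 1) ? (k - 1) / 2 : k / 2 - 1; }

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector input, IntegerVector nxyz, int cin,
                         NumericVector w, int k, int cout, NumericVector bias) {
  const int nx = nxyz[0], ny = nxyz[1], nz = nxyz[2];
  const int pl = pad_left(k);
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out((R_xlen_t)nvox * cout);
  const double *in = input.begin();
  const double *W = w.begin();
  double *O = out.begin();

  for (int oc = 0; oc < cout; ++oc) {
    const double b = bias[oc];
    for (int oz = 0; oz < nz; ++oz) {
      int kz0 = std::max(0, pl - oz), kz1 = std::min(k, nz + pl - oz);
      for (int oy = 0; oy < ny; ++oy) {
        int ky0 = std::max(0, pl - oy), ky1 = std::min(k, ny + pl - oy);
        for (int ox = 0; ox < nx; ++ox) {
          int kx0 = std::max(0, pl - ox), kx1 = std::min(k, nx + pl - ox);
          double acc = b;
          for (int ci = 0; ci < cin; ++ci) {
            const double *inc = in + (R_xlen_t)ci * nvox;
            const double *Wc = W + ((R_xlen_t)oc * cin + ci) * k * k * k;
            for (int kz = kz0; kz < kz1; ++kz) {
              int iz = oz + kz - pl;
              for (int ky = ky0; ky < ky1; ++ky) {
                int iy = oy + ky - pl;
                const double *inrow = inc + ((R_xlen_t)iz * ny + iy) * nx + (ox - pl);
                const double *Wrow = Wc + ((R_xlen_t)kz * k + ky) * k;
                for (int kx = kx0; kx < kx1; ++kx)
                  acc += inrow[kx] * Wrow[kx];
              }
            }
          }
          O[(R_xlen_t)oc * nvox + ((R_xlen_t)oz * ny + oy) * nx + ox] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
NumericVector conv3d_bwd_input(NumericVector gout, IntegerVector nxyz, int cout,
                               NumericVector w, int k, int cin) {
  const int nx = nxyz[0], ny = nxyz[1], nz = nxyz[2];
  const int pl = pad_left(k);
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gin((R_xlen_t)nvox * cin);
  const double *G = gout.begin();
  const double *W = w.begin();
  double *GI = gin.begin();

  // gin[i, ci] = sum_{oc, kk} gout[i - kk + pl, oc] * w[kk, ci, oc]
  for (int ci = 0; ci < cin; ++ci) {
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        for (int ix = 0; ix < nx; ++ix) {
          double acc = 0.0;
          for (int oc = 0; oc < cout; ++oc) {
            const double *Gc = G + (R_xlen_t)oc * nvox;
            const double *Wc = W + ((R_xlen_t)oc * cin + ci) * k * k * k;
            for (int kz = 0; kz < k; ++kz) {
              int oz = iz - kz + pl;
              if (oz < 0 || oz >= nz) continue;
              for (int ky = 0; ky < k; ++ky) {
                int oy = iy - ky + pl;
                if (oy < 0 || oy >= ny) continue;
                const double *Grow = Gc + ((R_xlen_t)oz * ny + oy) * nx;
                const double *Wrow = Wc + ((R_xlen_t)kz * k + ky) * k;
                for (int kx = 0; kx < k; ++kx) {
                  int ox = ix - kx + pl;
                  if (ox < 0 || ox >= nx) continue;
                  acc += Grow[ox] * Wrow[kx];
                }
              }
            }
          }
          GI[(R_xlen_t)ci * nvox + ((R_xlen_t)iz * ny + iy) * nx + ix] = acc;
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return gin;
}

// [[Rcpp::export]]
List conv3d_bwd_weights(NumericVector input, IntegerVector nxyz, int cin,
                        NumericVector gout, int cout, int k) {
  const int nx = nxyz[0], ny = nxyz[1], nz = nxyz[2];
  const int pl = pad_left(k);
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gw((R_xlen_t)k * k * k * cin * cout);
  NumericVector gb(cout);
  const double *in = input.begin();
  const double *G = gout.begin();
  double *GW = gw.begin();

  for (int oc = 0; oc < cout; ++oc) {
    const double *Gc = G + (R_xlen_t)oc * nvox;
    double bacc = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) bacc += Gc[i];
    gb[oc] = bacc;
    for (int ci = 0; ci < cin; ++ci) {
      const double *inc = in + (R_xlen_t)ci * nvox;
      double *Wc = GW + ((R_xlen_t)oc * cin + ci) * k * k * k;
      for (int kz = 0; kz < k; ++kz) {
        for (int ky = 0; ky < k; ++ky) {
          for (int kx = 0; kx < k; ++kx) {
            double acc = 0.0;
            int oz0 = std::max(0, pl - kz), oz1 = std::min(nz, nz + pl - kz);
            int oy0 = std::max(0, pl - ky), oy1 = std::min(ny, ny + pl - ky);
            int ox0 = std::max(0, pl - kx), ox1 = std::min(nx, nx + pl - kx);
            for (int oz = oz0; oz < oz1; ++oz) {
              int iz = oz + kz - pl;
              for (int oy = oy0; oy < oy1; ++oy) {
                int iy = oy + ky - pl;
                const double *Grow = Gc + ((R_xlen_t)oz * ny + oy) * nx;
                const double *inrow = inc + ((R_xlen_t)iz * ny + iy) * nx + (kx - pl);
                for (int ox = ox0; ox < ox1; ++ox)
                  acc += Grow[ox] * inrow[ox];
              }
            }
            Wc[((R_xlen_t)kz * k + ky) * k + kx] = acc;
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
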