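// Finite-difference Poisson solver: face-dielectric setup and SOR sweeps,
// plus the grid morphology helper used for the molecular-surface mask.
#include <Rcpp.h>
using namespace Rcpp;

// Face dielectric constants between neighbouring nodes.  Faces crossing the
// solute/solvent boundary use a harmonic mean weighted by the sub-grid
// boundary position, estimated from the signed distance to the nearest atom
// sphere (exact on convex parts of the molecular surface); if the signed
// distance does not change sign across the edge (reentrant surface), the
// boundary is taken at the edge midpoint.
// [[Rcpp::export]]
List pb_setup_faces(LogicalVector solute, NumericVector fdist,
                    IntegerVector dims, double eps_in, double eps_out) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  NumericVector ex(n, eps_out), ey(n, eps_out), ez(n, eps_out);
  NumericVector *faces[3] = {&ex, &ey, &ez};
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        int here[3] = {i, j, k};
        int lim[3] = {nx, ny, nz};
        for (int ax = 0; ax < 3; ++ax) {
          if (here[ax] + 1 >= lim[ax]) continue;
          R_xlen_t nb = id + stride[ax];
          bool sa = solute[id], sb = solute[nb];
          double e;
          if (sa && sb) {
            e = eps_in;
          } else if (!sa && !sb) {
            e = eps_out;
          } else {
            double fa = fdist[id], fb = fdist[nb];
            double fin = 0.5;  // fraction of the edge on the solute side
            if ((fa < 0) != (fb < 0)) {
              double t = fa / (fa - fb);  // F = 0 crossing along the edge
              fin = sa ? t : 1.0 - t;
            }
            e = 1.0 / (fin / eps_in + (1.0 - fin) / eps_out);
          }
          (*faces[ax])[id] = e;
        }
      }
    }
  }
  return List::create(_["ex"] = ex, _["ey"] = ey, _["ez"] = ez);
}

// Successive over-relaxation sweeps for div(eps grad phi) = -4 pi rho with
// precomputed face dielectrics.  phi is updated in place; boundary nodes
// (fixed == TRUE) hold Dirichlet values.  src holds 4*pi*q/h per node.
// Returns the maximum absolute update at every `check_every`-th sweep.
// [[Rcpp::export]]
NumericVector sor_poisson(NumericVector phi, NumericVector ex,
                          NumericVector ey, NumericVector ez,
                          NumericVector src, LogicalVector fixed,
                          IntegerVector dims, double omega, int iters,
                          int check_every) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // inverse diagonal, constant across sweeps
  std::vector<double> invden(n, 0.0);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        R_xlen_t id = i + sy * j + sz * k;
        double den = ex[id - sx] + ex[id] + ey[id - sy] + ey[id] +
                     ez[id - sz] + ez[id];
        invden[id] = 1.0 / den;
      }
  const double *px = REAL(ex), *py = REAL(ey), *pz = REAL(ez);
  const double *ps = REAL(src);
  const int *pf = LOGICAL(fixed);
  double *pp = REAL(phi);
  std::vector<double> res_hist;
  for (int it = 0; it < iters; ++it) {
    double maxupd = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t base = sy * j + sz * k;
        for (int i = 1; i < nx - 1; ++i) {
          R_xlen_t id = base + i;
          if (pf[id]) continue;
          double num = px[id - sx] * pp[id - sx] + px[id] * pp[id + sx] +
                       py[id - sy] * pp[id - sy] + py[id] * pp[id + sy] +
                       pz[id - sz] * pp[id - sz] + pz[id] * pp[id + sz] +
                       ps[id];
          double upd = omega * (num * invden[id] - pp[id]);
          pp[id] += upd;
          double a = std::fabs(upd);
          if (a > maxupd) maxupd = a;
        }
      }
    }
    if ((it + 1) % check_every == 0 || it == iters - 1)
      res_hist.push_back(maxupd);
  }
  return wrap(res_hist);
}

// Logical dilation of a 3D mask by a set of voxel offsets (the spherical
// structuring element of the probe).  Out-of-grid neighbours count as FALSE.
// [[Rcpp::export]]
LogicalVector dilate_mask(LogicalVector mask, IntegerVector dims,
                          IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int no = offsets.nrow();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        bool hit = false;
        for (int o = 0; o < no && !hit; ++o) {
          int ii = i + offsets(o, 0);
          int jj = j + offsets(o, 1);
          int kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          if (mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) hit = true;
        }
        out[id] = hit;
      }
    }
  }
  return out;
}
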