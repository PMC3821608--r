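#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-centered finite-volume operator on a uniform voxel grid:
//   A C = -div(D grad C) + diag_add * C
// with harmonic-mean face diffusivities, a ghost-cell Dirichlet value c_top
// on the z = 0 face (face diffusivity = adjacent voxel's value, half-cell
// distance), and zero-flux on every other boundary face.  Voxels whose row
// would be identically zero (zero conductance and zero diag_add, e.g.
// impermeable strut interiors) are pinned to c_top by an identity row; they
// are decoupled from the rest of the system.
//
// The linear system is solved by Jacobi-preconditioned conjugate gradients,
// matrix-free; the operator is symmetric positive definite whenever any
// voxel touches the Dirichlet face or carries a sink.

struct FvOp {
  int nx, ny, nz;
  R_xlen_t n, sx, sy, sz;
  std::vector<double> wx, wy, wz;  // face weights toward +x/+y/+z neighbour
  std::vector<double> dg;          // diagonal
  std::vector<char> pinned;
  // vertical-line preconditioner: per-column tridiagonal (dg, -wz) factors
  std::vector<double> td_inv;      // 1 / pivot from Thomas elimination

  FvOp(const NumericVector& dvox, int nx_, int ny_, int nz_, double h,
       const NumericVector& diag_add)
      : nx(nx_), ny(ny_), nz(nz_) {
    n = (R_xlen_t)nx * ny * nz;
    sx = 1; sy = nx; sz = (R_xlen_t)nx * ny;
    wx.assign(n, 0.0); wy.assign(n, 0.0); wz.assign(n, 0.0);
    dg.assign(n, 0.0); pinned.assign(n, 0);
    const double ih2 = 1.0 / (h * h);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t p = i + sy * j + sz * k;
          double dp = dvox[p];
          if (i + 1 < nx) {
            double dq = dvox[p + sx], s = dp + dq;
            wx[p] = s > 0 ? 2.0 * dp * dq / s * ih2 : 0.0;
          }
          if (j + 1 < ny) {
            double dq = dvox[p + sy], s = dp + dq;
            wy[p] = s > 0 ? 2.0 * dp * dq / s * ih2 : 0.0;
          }
          if (k + 1 < nz) {
            double dq = dvox[p + sz], s = dp + dq;
            wz[p] = s > 0 ? 2.0 * dp * dq / s * ih2 : 0.0;
          }
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t p = i + sy * j + sz * k;
          double d = diag_add[p];
          if (i > 0) d += wx[p - sx];
          if (i + 1 < nx) d += wx[p];
          if (j > 0) d += wy[p - sy];
          if (j + 1 < ny) d += wy[p];
          if (k > 0) d += wz[p - sz];
          if (k + 1 < nz) d += wz[p];
          if (k == 0) d += 2.0 * dvox[p] * ih2;  // Dirichlet ghost at top
          if (d <= 0.0) { d = 1.0; pinned[p] = 1; }
          dg[p] = d;
        }
    // Incomplete Cholesky (zero fill) pivots for the 7-point SPD matrix
    // under natural ordering; exists for M-matrices like this one.
    td_inv.assign(n, 0.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t p = i + sy * j + sz * k;
          double d = dg[p];
          if (i > 0) { double w = wx[p - sx]; d -= w * w * td_inv[p - sx]; }
          if (j > 0) { double w = wy[p - sy]; d -= w * w * td_inv[p - sy]; }
          if (k > 0) { double w = wz[p - sz]; d -= w * w * td_inv[p - sz]; }
          if (d <= 0.0) d = dg[p];  // safeguard; cannot occur for M-matrices
          td_inv[p] = 1.0 / d;
        }
  }

  // z = M^-1 r with M = (D + L) D^-1 (D + L^T), D the IC(0) pivots and L
  // the strictly lower original off-diagonals
  void prec(const double* r, double* z) const {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t row = sy * j + sz * k;
        for (int i = 0; i < nx; ++i) {
          R_xlen_t p = row + i;
          double v = r[p];
          if (i > 0) v += wx[p - sx] * z[p - sx];
          if (j > 0) v += wy[p - sy] * z[p - sy];
          if (k > 0) v += wz[p - sz] * z[p - sz];
          z[p] = v * td_inv[p];  // forward sweep: t = (D+L)^-1 r
        }
      }
    for (int k = nz - 1; k >= 0; --k)
      for (int j = ny - 1; j >= 0; --j) {
        R_xlen_t row = sy * j + sz * k;
        for (int i = nx - 1; i >= 0; --i) {
          R_xlen_t p = row + i;
          double acc = 0.0;
          if (i + 1 < nx) acc += wx[p] * z[p + sx];
          if (j + 1 < ny) acc += wy[p] * z[p + sy];
          if (k + 1 < nz) acc += wz[p] * z[p + sz];
          z[p] += acc * td_inv[p];
        }
      }
  }

  void apply(const double* x, double* y) const {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t p = i + sy * j + sz * k;
          double v = dg[p] * x[p];
          if (i > 0) v -= wx[p - sx] * x[p - sx];
          if (i + 1 < nx) v -= wx[p] * x[p + sx];
          if (j > 0) v -= wy[p - sy] * x[p - sy];
          if (j + 1 < ny) v -= wy[p] * x[p + sy];
          if (k > 0) v -= wz[p - sz] * x[p - sz];
          if (k + 1 < nz) v -= wz[p] * x[p + sz];
          y[p] = v;
        }
  }
};

// [[Rcpp::export(name = ".fv_solve_cpp")]]
List fv_solve_cpp(NumericVector dvox, IntegerVector dims, double h,
                  NumericVector diag_add, NumericVector rhs_add,
                  double c_top, NumericVector x0,
                  double tol = 1e-10, int maxit = 5000) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (dvox.size() != n || diag_add.size() != n || rhs_add.size() != n ||
      x0.size() != n)
    stop("field length does not match grid dimensions");
  FvOp A(dvox, nx, ny, nz, h, diag_add);

  const double ih2 = 1.0 / (h * h);
  std::vector<double> b(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    if (A.pinned[p]) { b[p] = c_top; continue; }
    b[p] = rhs_add[p];
    if (p < A.sz) b[p] += 2.0 * dvox[p] * ih2 * c_top;  // top slab
  }

  NumericVector x(clone(x0));
  std::vector<double> r(n), z(n), pv(n), Ap(n);
  A.apply(REAL(x), Ap.data());
  double bnorm = 0.0;
  for (R_xlen_t p = 0; p < n; ++p) {
    r[p] = b[p] - Ap[p];
    bnorm += b[p] * b[p];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  A.prec(r.data(), z.data());
  double rz = 0.0;
  for (R_xlen_t p = 0; p < n; ++p) {
    pv[p] = z[p];
    rz += r[p] * z[p];
  }
  double relres = 0.0;
  int it = 0;
  for (; it < maxit; ++it) {
    double rn = 0.0;
    for (R_xlen_t p = 0; p < n; ++p) rn += r[p] * r[p];
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) break;
    A.apply(pv.data(), Ap.data());
    double pAp = 0.0;
    for (R_xlen_t p = 0; p < n; ++p) pAp += pv[p] * Ap[p];
    if (pAp <= 0.0) break;  // numerical breakdown; return best iterate
    double alpha = rz / pAp;
    for (R_xlen_t p = 0; p < n; ++p) {
      x[p] += alpha * pv[p];
      r[p] -= alpha * Ap[p];
    }
    A.prec(r.data(), z.data());
    double rz_new = 0.0;
    for (R_xlen_t p = 0; p < n; ++p) rz_new += r[p] * z[p];
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t p = 0; p < n; ++p) pv[p] = z[p] + beta * pv[p];
  }
  return List::create(_["x"] = x, _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = relres <= tol);
}
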