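#include <Rcpp.h>
#include <R_ext/Applic.h>
using namespace Rcpp;

// 3D connected-component labeling, 6- or 26-connectivity, flood fill.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector fg, IntegerVector dims,
                          int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back(dx + nx * (dy + ny * dz));
      }
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!fg[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.clear(); stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int px = p % nx, py = (p / nx) % ny, pz = p / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        R_xlen_t q = p + offs[k];
        if (q < 0 || q >= n) continue;
        // reject neighbours that wrapped across an array edge
        int qx = q % nx, qy = (q / nx) % ny, qz = q / ((R_xlen_t)nx * ny);
        if (std::abs(qx - px) > 1 || std::abs(qy - py) > 1 || std::abs(qz - pz) > 1)
          continue;
        if (fg[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// Direct non-uniform DFT of a cubic complex volume at normalized k-space
// locations (cycles/voxel in [-0.5, 0.5]); image indices centred on N/2.
// [[Rcpp::export]]
ComplexVector nudft3_forward(ComplexVector img, NumericMatrix traj) {
  IntegerVector dims = img.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int M = traj.ncol();
  ComplexVector out(M);
  const double cx = nx / 2.0, cy = ny / 2.0, cz = nz / 2.0;
  for (int m = 0; m < M; ++m) {
    const double kx = traj(0, m), ky = traj(1, m), kz = traj(2, m);
    double sr = 0.0, si = 0.0;
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++idx) {
          Rcomplex v = img[idx];
          if (v.r == 0.0 && v.i == 0.0) continue;
          double ph = -2.0 * M_PI *
            (kx * (x - cx) + ky * (y - cy) + kz * (z - cz));
          double c = cos(ph), s = sin(ph);
          sr += v.r * c - v.i * s;
          si += v.r * s + v.i * c;
        }
    out[m].r = sr; out[m].i = si;
  }
  return out;
}

// Kaiser-Bessel gridding kernel, tabulated kernel on |t| in [0, 1], linear interpolation
struct KBTable {
  std::vector<double> v;
  double hw;
  KBTable(double halfwidth, double beta, int nt = 4096) : v(nt + 1), hw(halfwidth) {
    for (int i = 0; i <= nt; ++i) {
      double t = (double)i / nt;
      v[i] = R::bessel_i(beta * sqrt(1.0 - t * t), 0.0, 1.0);
    }
  }
  inline double operator()(double d) const {
    double t = std::fabs(d) / hw;
    if (t >= 1.0) return 0.0;
    double x = t * (v.size() - 1);
    int i = (int)x;
    double f = x - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
};

// Spread weighted k-space samples onto an oversampled cubic grid with a
// Kaiser-Bessel kernel. traj normalized cycles/voxel of the *target* image;
// grid of size ng maps k = -0.5..0.5 (times osf) onto 0..ng-1.
// [[Rcpp::export]]
ComplexVector kb_grid(ComplexVector samples, NumericMatrix traj,
                      NumericVector weights, int ng, double width = 4.0,
                      double beta = 0.0) {
  if (beta <= 0) beta = M_PI * sqrt((width * width) / 4.0 * 2.25 - 0.8);
  const int M = traj.ncol();
  const double hw = width / 2.0;
  ComplexVector grid((R_xlen_t)ng * ng * ng);
  IntegerVector dims = IntegerVector::create(ng, ng, ng);
  KBTable tab(hw, beta);
  double wx[8], wy[8], wz[8];
  for (int m = 0; m < M; ++m) {
    double gx = (traj(0, m) + 0.5) * ng, gy = (traj(1, m) + 0.5) * ng,
           gz = (traj(2, m) + 0.5) * ng;
    double wr = samples[m].r * weights[m], wi = samples[m].i * weights[m];
    int x0 = std::max((int)ceil(gx - hw), 0), x1 = std::min((int)floor(gx + hw), ng - 1);
    int y0 = std::max((int)ceil(gy - hw), 0), y1 = std::min((int)floor(gy + hw), ng - 1);
    int z0 = std::max((int)ceil(gz - hw), 0), z1 = std::min((int)floor(gz + hw), ng - 1);
    for (int x = x0; x <= x1; ++x) wx[x - x0] = tab(x - gx);
    for (int y = y0; y <= y1; ++y) wy[y - y0] = tab(y - gy);
    for (int z = z0; z <= z1; ++z) wz[z - z0] = tab(z - gz);
    for (int z = z0; z <= z1; ++z) {
      double kz = wz[z - z0];
      for (int y = y0; y <= y1; ++y) {
        double kyz = kz * wy[y - y0];
        R_xlen_t base = (R_xlen_t)ng * (y + (R_xlen_t)ng * z);
        for (int x = x0; x <= x1; ++x) {
          double k = kyz * wx[x - x0];
          grid[base + x].r += wr * k;
          grid[base + x].i += wi * k;
        }
      }
    }
  }
  grid.attr("dim") = dims;
  return grid;
}

// Interpolate an oversampled cubic grid back at sample locations (adjoint of
// kb_grid spreading); used by Pipe-style density-compensation iterations.
// [[Rcpp::export]]
ComplexVector kb_sample(ComplexVector grid, NumericMatrix traj,
                        double width = 4.0, double beta = 0.0) {
  if (beta <= 0) beta = M_PI * sqrt((width * width) / 4.0 * 2.25 - 0.8);
  IntegerVector dims = grid.attr("dim");
  const int ng = dims[0];
  const int M = traj.ncol();
  const double hw = width / 2.0;
  ComplexVector out(M);
  KBTable tab(hw, beta);
  double wx[8], wy[8], wz[8];
  for (int m = 0; m < M; ++m) {
    double gx = (traj(0, m) + 0.5) * ng, gy = (traj(1, m) + 0.5) * ng,
           gz = (traj(2, m) + 0.5) * ng;
    int x0 = std::max((int)ceil(gx - hw), 0), x1 = std::min((int)floor(gx + hw), ng - 1);
    int y0 = std::max((int)ceil(gy - hw), 0), y1 = std::min((int)floor(gy + hw), ng - 1);
    int z0 = std::max((int)ceil(gz - hw), 0), z1 = std::min((int)floor(gz + hw), ng - 1);
    for (int x = x0; x <= x1; ++x) wx[x - x0] = tab(x - gx);
    for (int y = y0; y <= y1; ++y) wy[y - y0] = tab(y - gy);
    for (int z = z0; z <= z1; ++z) wz[z - z0] = tab(z - gz);
    double sr = 0.0, si = 0.0;
    for (int z = z0; z <= z1; ++z) {
      double kz = wz[z - z0];
      for (int y = y0; y <= y1; ++y) {
        double kyz = kz * wy[y - y0];
        R_xlen_t base = (R_xlen_t)ng * (y + (R_xlen_t)ng * z);
        for (int x = x0; x <= x1; ++x) {
          sr += grid[base + x].r * kyz * wx[x - x0];
          si += grid[base + x].i * kyz * wx[x - x0];
        }
      }
    }
    out[m].r = sr; out[m].i = si;
  }
  return out;
}

// Per-defect-voxel neighbourhood fraction for the defect distribution index:
// for each defect voxel, 100 * (#defect within Chebyshev radius r, in lung) /
// (#lung within radius r). mode2d restricts the neighbourhood to the slice.
// [[Rcpp::export]]
NumericVector ddi_fractions(LogicalVector defect, LogicalVector lung,
                            IntegerVector dims, int radius, bool mode2d) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!defect[i]) continue;
    int px = i % nx, py = (i / nx) % ny, pz = i / ((R_xlen_t)nx * ny);
    int z0 = mode2d ? pz : std::max(pz - radius, 0);
    int z1 = mode2d ? pz : std::min(pz + radius, nz - 1);
    int nd = 0, nl = 0;
    for (int z = z0; z <= z1; ++z)
      for (int y = std::max(py - radius, 0); y <= std::min(py + radius, ny - 1); ++y)
        for (int x = std::max(px - radius, 0); x <= std::min(px + radius, nx - 1); ++x) {
          R_xlen_t q = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (lung[q]) { ++nl; if (defect[q]) ++nd; }
        }
    out[i] = nl ? 100.0 * nd / nl : 0.0;
  }
  return out;
}
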