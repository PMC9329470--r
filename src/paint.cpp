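#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Rasterise banded elliptical shapes into a labelled voxel array.
// `shapes` has one row per (slice, shape): z (1-based slice index), cx, cy,
// a, b (mm, semi-axes), then three radial bands (t1,l1,t2,l2,t3,l3): a voxel
// at normalised elliptical radius rho gets label l1 if rho<=t1, l2 if
// rho<=t2, l3 if rho<=t3. Negative labels leave the voxel untouched.
// Array layout is column-major with dims (nz, ny, nx); voxel centres sit at
// (i + 0.5) * spacing along each axis.
// [[Rcpp::export(name = ".paint_shapes")]]
IntegerVector paint_shapes(IntegerVector dims, NumericMatrix shapes,
                           NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector lab(static_cast<R_xlen_t>(nz) * ny * nx, 0);
  lab.attr("dim") = dims;
  const double dy = spacing[1], dx = spacing[2];
  for (int r = 0; r < shapes.nrow(); ++r) {
    const int z = static_cast<int>(shapes(r, 0)) - 1;
    if (z < 0 || z >= nz) continue;
    const double cx = shapes(r, 1), cy = shapes(r, 2);
    const double a = shapes(r, 3), b = shapes(r, 4);
    if (a <= 0 || b <= 0) continue;
    const double t1 = shapes(r, 5), t2 = shapes(r, 7), t3 = shapes(r, 9);
    const int l1 = static_cast<int>(shapes(r, 6));
    const int l2 = static_cast<int>(shapes(r, 8));
    const int l3 = static_cast<int>(shapes(r, 10));
    const double tmax = std::max(t1, std::max(t2, t3));
    int x0 = std::max(0, static_cast<int>(std::floor((cx - a * tmax) / dx)) - 1);
    int x1 = std::min(nx - 1, static_cast<int>(std::ceil((cx + a * tmax) / dx)) + 1);
    int y0 = std::max(0, static_cast<int>(std::floor((cy - b * tmax) / dy)) - 1);
    int y1 = std::min(ny - 1, static_cast<int>(std::ceil((cy + b * tmax) / dy)) + 1);
    for (int ix = x0; ix <= x1; ++ix) {
      const double u = ((ix + 0.5) * dx - cx) / a;
      for (int iy = y0; iy <= y1; ++iy) {
        const double v = ((iy + 0.5) * dy - cy) / b;
        const double rho = std::sqrt(u * u + v * v);
        int l = -1;
        if (rho <= t1) l = l1;
        else if (rho <= t2) l = l2;
        else if (rho <= t3) l = l3;
        if (l >= 0)
          lab[z + static_cast<R_xlen_t>(nz) * (iy + static_cast<R_xlen_t>(ny) * ix)] = l;
      }
    }
  }
  return lab;
}

// Number of 26-connected components of a 3-D logical mask (dims nz, ny, nx).
// [[Rcpp::export(name = ".count_components_3d")]]
int count_components_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nz) * ny * nx;
  std::vector<char> seen(n, 0);
  int ncomp = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || seen[s]) continue;
    ++ncomp;
    seen[s] = 1;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int z = cur % nz;
      const int y = (cur / nz) % ny;
      const int x = cur / (static_cast<R_xlen_t>(nz) * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dyy = -1; dyy <= 1; ++dyy)
          for (int dxx = -1; dxx <= 1; ++dxx) {
            if (!dz && !dyy && !dxx) continue;
            const int z2 = z + dz, y2 = y + dyy, x2 = x + dxx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
              continue;
            const R_xlen_t idx = z2 + static_cast<R_xlen_t>(nz) *
              (y2 + static_cast<R_xlen_t>(ny) * x2);
            if (mask[idx] && !seen[idx]) { seen[idx] = 1; q.push(idx); }
          }
    }
  }
  return ncomp;
}

// 4-connected component labelling of a 2-D logical matrix.
// [[Rcpp::export(name = ".label_components_2d")]]
IntegerMatrix label_components_2d(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(i + nr * j);
      while (!q.empty()) {
        const int cur = q.front(); q.pop();
        const int ci = cur % nr, cj = cur / nr;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int i2 = ci + di[k], j2 = cj + dj[k];
          if (i2 < 0 || i2 >= nr || j2 < 0 || j2 >= nc) continue;
          if (mask(i2, j2) && !lab(i2, j2)) {
            lab(i2, j2) = next;
            q.push(i2 + nr * j2);
          }
        }
      }
    }
  return lab;
}

// One-pass summary of a label volume: per-label voxel counts (labels 0..5)
// and per-slice body voxel counts.
// [[Rcpp::export(name = ".label_summary")]]
List label_summary(IntegerVector lab, IntegerVector dims) {
  const int nz = dims[0];
  const R_xlen_t n = lab.size();
  std::vector<double> counts(6, 0.0);
  NumericVector slice(nz);
  const int* p = INTEGER(lab);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int v = p[i];
    if (v >= 0 && v < 6) counts[v] += 1.0;
    if (v > 0) slice[i % nz] += 1.0;
  }
  return List::create(_["label_counts"] = wrap(counts),
                      _["slice_counts"] = slice);
}

// Coronal ([z, x], OR over y) and sagittal ([z, y], OR over x) shadow
// projections of the body mask (labels > 0) in one pass.
// [[Rcpp::export(name = ".project_mask")]]
List project_mask(IntegerVector lab, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerMatrix cor(nz, nx), sag(nz, ny);
  const int* p = INTEGER(lab);
  R_xlen_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i)
        if (p[i] > 0) { cor(z, x) = 1; sag(z, y) = 1; }
  return List::create(_["coronal"] = cor, _["sagittal"] = sag);
}
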