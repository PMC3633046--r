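#include <Rcpp.h>
#include <array>
#include <vector>
using namespace Rcpp;

// Flood-fill labelling of {voxels >= th} with an explicit stack, so that
// 512 x 512 x 35 stacks never hit recursion limits.  Voxel order is
// column-major (z fastest), matching R arrays of dim c(nz, ny, nx).
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector vox, IntegerVector dims,
                                   double th, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3 (nz, ny, nx)");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vox.size() != n) stop("voxel vector does not match dims");

  IntegerVector labels(n);

  std::vector<std::array<int, 3> > nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        const int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({{dz, dy, dx}});
      }

  std::vector<R_xlen_t> stack;
  int lab = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] != 0 || vox[i] < th) continue;
    ++lab;
    labels[i] = lab;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = (int)(cur % nz);
      const R_xlen_t rest = cur / nz;
      const int y = (int)(rest % ny);
      const int x = (int)(rest / ny);
      for (size_t k = 0; k < nb.size(); ++k) {
        const int zz = z + nb[k][0];
        const int yy = y + nb[k][1];
        const int xx = x + nb[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        const R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (labels[j] == 0 && vox[j] >= th) {
          labels[j] = lab;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Two-pass city-block distance to the nearest pixel outside the mask.
// Pixels outside the mask get 0; interior pixels >= 1.  Used to build
// feathering weights for mosaic blending.
// [[Rcpp::export]]
NumericMatrix chamfer_interior_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix d(nr, nc);
  const double big = 1e9;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? big : 0.0;
  // forward
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0) v = std::min(v, d(i - 1, j) + 1.0);
      else v = std::min(v, 1.0);  // image border counts as outside
      if (j > 0) v = std::min(v, d(i, j - 1) + 1.0);
      else v = std::min(v, 1.0);
      d(i, j) = v;
    }
  // backward
  for (int j = nc - 1; j >= 0; --j)
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < nr - 1) v = std::min(v, d(i + 1, j) + 1.0);
      else v = std::min(v, 1.0);
      if (j < nc - 1) v = std::min(v, d(i, j + 1) + 1.0);
      else v = std::min(v, 1.0);
      d(i, j) = v;
    }
  return d;
}
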