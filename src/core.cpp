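// Numerical cores: batch symmetric 3x3 eigendecomposition and deterministic
// streamline propagation along the interpolated principal eigenvector.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void eig3(const double c[6], arma::vec &val, arma::mat &vec) {
  // component order: Dxx, Dxy, Dxz, Dyy, Dyz, Dzz
  arma::mat33 D = {{c[0], c[1], c[2]},
                   {c[1], c[3], c[4]},
                   {c[2], c[4], c[5]}};
  arma::eig_sym(val, vec, D);   // ascending
}

// comp: N x 6 matrix (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
// Returns eigenvalues sorted descending (N x 3) and eigenvectors
// (N x 9, columns e1x e1y e1z e2x ... e3z) matching that order.
// [[Rcpp::export]]
List eig3_batch(const NumericMatrix comp) {
  const int n = comp.nrow();
  NumericMatrix values(n, 3), vectors(n, 9);
  arma::vec val;
  arma::mat vec;
  double c[6];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 6; ++k) c[k] = comp(i, k);
    eig3(c, val, vec);
    for (int j = 0; j < 3; ++j) {          // flip to descending
      values(i, j) = val(2 - j);
      for (int a = 0; a < 3; ++a) vectors(i, 3 * j + a) = vec(a, 2 - j);
    }
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}

struct Grid {
  const double *comp;  // nx*ny*nz*6
  const int *mask;
  const double *fa;    // may be null
  int nx, ny, nz;
  long nvox() const { return (long)nx * ny * nz; }
  inline long vidx(int i, int j, int k) const {
    return (long)i + (long)nx * (j + (long)ny * k);
  }
  bool in_grid(const arma::vec3 &p) const {
    return p(0) > -0.5 && p(0) < nx - 0.5 && p(1) > -0.5 && p(1) < ny - 0.5 &&
           p(2) > -0.5 && p(2) < nz - 0.5;
  }
  bool in_mask(const arma::vec3 &p) const {
    int i = (int)std::lround(p(0)), j = (int)std::lround(p(1)),
        k = (int)std::lround(p(2));
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[vidx(i, j, k)] != 0;
  }
  // trilinear interpolation of one scalar channel (offset in voxels units)
  double interp1(const double *vol, const arma::vec3 &p) const {
    double x = std::min(std::max(p(0), 0.0), nx - 1.0);
    double y = std::min(std::max(p(1), 0.0), ny - 1.0);
    double z = std::min(std::max(p(2), 0.0), nz - 1.0);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c00 = vol[vidx(i0, j0, k0)] * (1 - fx) + vol[vidx(i1, j0, k0)] * fx;
    double c10 = vol[vidx(i0, j1, k0)] * (1 - fx) + vol[vidx(i1, j1, k0)] * fx;
    double c01 = vol[vidx(i0, j0, k1)] * (1 - fx) + vol[vidx(i1, j0, k1)] * fx;
    double c11 = vol[vidx(i0, j1, k1)] * (1 - fx) + vol[vidx(i1, j1, k1)] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }
  // principal eigenvector of the trilinearly interpolated tensor at p;
  // returns false if the interpolated tensor is (numerically) zero.
  bool e1_at(const arma::vec3 &p, arma::vec3 &e1) const {
    double c[6];
    long n = nvox();
    for (int k = 0; k < 6; ++k) c[k] = interp1(comp + (long)k * n, p);
    double tr = std::fabs(c[0]) + std::fabs(c[3]) + std::fabs(c[5]);
    if (tr < 1e-15) return false;
    arma::vec val;
    arma::mat vec;
    eig3(c, val, vec);
    e1 = vec.col(2);   // largest eigenvalue last (ascending order)
    return true;
  }
};

// Propagate one direction from seed; appends points (excluding the seed) to
// out. Returns when a stopping rule fires.
static void propagate(const Grid &g, arma::vec3 seed, arma::vec3 dir0,
                      double step, double cos_thresh, double fa_thresh,
                      int max_steps, std::vector<arma::vec3> &out) {
  arma::vec3 p = seed, dir = dir0;
  for (int s = 0; s < max_steps; ++s) {
    arma::vec3 pn = p + step * dir;
    if (!g.in_grid(pn) || !g.in_mask(pn)) return;            // exits mask
    if (g.fa && g.interp1(g.fa, pn) < fa_thresh) return;     // low FA
    arma::vec3 e1;
    if (!g.e1_at(pn, e1)) return;
    if (arma::dot(e1, dir) < 0) e1 = -e1;                    // sign continuity
    if (arma::dot(e1, dir) < cos_thresh) return;             // turning angle
    out.push_back(pn);
    p = pn;
    dir = e1;
  }
}

// Deterministic bidirectional tracking.  All coordinates are continuous
// 0-based voxel indices; step is in voxel units.  Returns a list of
// n_points x 3 matrices (seed-centred, both halves concatenated).
// [[Rcpp::export]]
List track_core(const NumericVector comp, const IntegerVector mask,
                const NumericVector fa, const IntegerVector dims,
                const NumericMatrix seeds, const double step,
                const double angle_threshold_deg, const double fa_threshold,
                const int max_steps, const int min_points) {
  Grid g;
  g.comp = comp.begin();
  g.mask = mask.begin();
  g.fa = (fa.size() > 1) ? fa.begin() : nullptr;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  const double cos_thresh = std::cos(angle_threshold_deg * M_PI / 180.0);
  List out;
  std::vector<int> seed_index;
  for (int s = 0; s < seeds.nrow(); ++s) {
    arma::vec3 seed = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    if (!g.in_grid(seed) || !g.in_mask(seed)) continue;
    if (g.fa && g.interp1(g.fa, seed) < fa_threshold) continue;
    arma::vec3 e1;
    if (!g.e1_at(seed, e1)) continue;
    std::vector<arma::vec3> fwd, bwd;
    propagate(g, seed, e1, step, cos_thresh, fa_threshold, max_steps, fwd);
    propagate(g, seed, -e1, step, cos_thresh, fa_threshold, max_steps, bwd);
    const int np = (int)(fwd.size() + bwd.size()) + 1;
    if (np < min_points) continue;
    NumericMatrix sl(np, 3);
    int r = 0;
    for (int i = (int)bwd.size() - 1; i >= 0; --i, ++r)
      for (int a = 0; a < 3; ++a) sl(r, a) = bwd[i](a);
    for (int a = 0; a < 3; ++a) sl(r, a) = seed(a);
    ++r;
    for (size_t i = 0; i < fwd.size(); ++i, ++r)
      for (int a = 0; a < 3; ++a) sl(r, a) = fwd[i](a);
    out.push_back(sl);
    seed_index.push_back(s + 1);   // 1-based for R
  }
  return List::create(_["streamlines"] = out,
                      _["seed_index"] = wrap(seed_index));
}
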