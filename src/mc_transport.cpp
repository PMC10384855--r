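#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simplified voxel Monte Carlo photon transport.
//
// For each source voxel with decay rate above `threshold`, `n_decays` decays
// are simulated.  Each photon line is emitted with its yield from a uniform
// position in the voxel in an isotropic direction; the free path is sampled
// against the optical depth accumulated along the ray (water mass attenuation
// scaled by local density, Amanatides-Woo voxel traversal); the full line
// energy is deposited in the voxel of first interaction, or scored as escaped
// when the ray leaves the grid.  Tallies are scaled by (true decay rate /
// simulated decays), so results are exactly linear in the activity field for
// a fixed RNG stream.  var_j_h accumulates the sum of squared deposition
// weights, the analog-estimator variance of each voxel tally.
//
// Uses R's RNG (unif_rand) so set.seed() in R governs reproducibility.

// [[Rcpp::export]]
List mc_photon_transport(NumericVector decays_h, NumericVector density,
                         IntegerVector dim, NumericVector spacing_cm,
                         NumericVector line_e_j, NumericVector line_yield,
                         NumericVector line_mu_rho, int n_decays,
                         double threshold) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int nlines = line_e_j.size();
  NumericVector photon(nvox), var(nvox);
  double escaped = 0.0, emitted = 0.0;
  const double sx = spacing_cm[0], sy = spacing_cm[1], sz = spacing_cm[2];

  RNGScope rng;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    const double rate = decays_h[v];
    if (rate <= threshold || rate <= 0.0) continue;
    const double w0 = rate / n_decays;  // decays/h represented per history
    const int vx = (int)(v % nx);
    const int vy = (int)((v / nx) % ny);
    const int vz = (int)(v / ((R_xlen_t)nx * ny));
    for (int d = 0; d < n_decays; ++d) {
      for (int l = 0; l < nlines; ++l) {
        if (unif_rand() >= line_yield[l]) continue;
        const double e_w = line_e_j[l] * w0;  // J/h carried by this photon
        emitted += e_w;
        // uniform position inside the source voxel (cm)
        double px = (vx + unif_rand()) * sx;
        double py = (vy + unif_rand()) * sy;
        double pz = (vz + unif_rand()) * sz;
        // isotropic direction
        const double ct = 2.0 * unif_rand() - 1.0;
        const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        const double phi = 2.0 * M_PI * unif_rand();
        double dx = st * std::cos(phi), dy = st * std::sin(phi), dz = ct;
        const double eps = 1e-12;
        if (std::fabs(dx) < eps) dx = eps;
        if (std::fabs(dy) < eps) dy = eps;
        if (std::fabs(dz) < eps) dz = eps;
        const double tau_target = -std::log(unif_rand());
        // Amanatides-Woo traversal
        int ix = vx, iy = vy, iz = vz;
        const int stepx = dx > 0 ? 1 : -1, stepy = dy > 0 ? 1 : -1,
                  stepz = dz > 0 ? 1 : -1;
        double tMaxX = ((ix + (stepx > 0 ? 1 : 0)) * sx - px) / dx;
        double tMaxY = ((iy + (stepy > 0 ? 1 : 0)) * sy - py) / dy;
        double tMaxZ = ((iz + (stepz > 0 ? 1 : 0)) * sz - pz) / dz;
        const double tDx = sx / std::fabs(dx), tDy = sy / std::fabs(dy),
                     tDz = sz / std::fabs(dz);
        double t_prev = 0.0, tau = 0.0;
        bool done = false;
        while (!done) {
          const double t_exit = std::min(tMaxX, std::min(tMaxY, tMaxZ));
          const R_xlen_t cur = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
          const double mu = line_mu_rho[l] * density[cur];  // 1/cm
          const double seg_tau = mu * (t_exit - t_prev);
          if (tau + seg_tau >= tau_target) {
            photon[cur] += e_w;
            var[cur] += e_w * e_w;
            done = true;
            break;
          }
          tau += seg_tau;
          t_prev = t_exit;
          if (tMaxX <= tMaxY && tMaxX <= tMaxZ) {
            ix += stepx; tMaxX += tDx;
            if (ix < 0 || ix >= nx) { escaped += e_w; break; }
          } else if (tMaxY <= tMaxZ) {
            iy += stepy; tMaxY += tDy;
            if (iy < 0 || iy >= ny) { escaped += e_w; break; }
          } else {
            iz += stepz; tMaxZ += tDz;
            if (iz < 0 || iz >= nz) { escaped += e_w; break; }
          }
        }
      }
    }
  }
  return List::create(_["photon_j_h"] = photon, _["var_j_h"] = var,
                      _["escaped_j_h"] = escaped, _["emitted_j_h"] = emitted);
}
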