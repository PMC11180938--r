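#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
using namespace Rcpp;

// Probabilistic streamline tracker. Each seed voxel owns an RNG substream
// derived from (master seed, voxel linear index), so counts are reproducible
// and independent of seed-mask composition or execution order.

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::mt19937_64 gen;
  bool has_cache = false;
  double cache = 0.0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {  // uniform in [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Box-Muller, cached pair
    if (has_cache) { has_cache = false; return cache; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cache = r * std::sin(2.0 * M_PI * u2);
    has_cache = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

static inline void ortho_basis(const double d[3], double t1[3], double t2[3]) {
  // pick the axis least aligned with d to start the Gram-Schmidt
  double ax = std::fabs(d[0]), ay = std::fabs(d[1]), az = std::fabs(d[2]);
  double a[3] = {0.0, 0.0, 0.0};
  if (ax <= ay && ax <= az) a[0] = 1.0;
  else if (ay <= az) a[1] = 1.0;
  else a[2] = 1.0;
  double dot = a[0] * d[0] + a[1] * d[1] + a[2] * d[2];
  for (int i = 0; i < 3; ++i) t1[i] = a[i] - dot * d[i];
  double n = std::sqrt(t1[0] * t1[0] + t1[1] * t1[1] + t1[2] * t1[2]);
  for (int i = 0; i < 3; ++i) t1[i] /= n;
  t2[0] = d[1] * t1[2] - d[2] * t1[1];
  t2[1] = d[2] * t1[0] - d[0] * t1[2];
  t2[2] = d[0] * t1[1] - d[1] * t1[0];
}

// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(IntegerVector seed_vox,       // 0-based linear voxel indices
               NumericVector field,          // dim c(nx,ny,nz,3)
               NumericVector dispersion_deg, // per-voxel, same grid
               LogicalVector field_defined,
               LogicalVector boundary,
               LogicalVector brain,
               IntegerVector dim,
               NumericVector spacing,
               int samples_per_voxel,
               double step_mm,
               int max_steps,
               double curv_threshold_deg,
               double master_seed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double cos_curv = std::cos(curv_threshold_deg * M_PI / 180.0);
  IntegerVector counts(nvox);
  double n_success = 0.0, n_fail = 0.0;

  for (R_xlen_t s = 0; s < seed_vox.size(); ++s) {
    const R_xlen_t v0 = seed_vox[s];
    uint64_t state = (uint64_t)master_seed * 0x9E3779B97F4A7C15ULL + (uint64_t)v0 + 1ULL;
    Rng rng(splitmix64(state));
    const int i0 = (int)(v0 % nx);
    const int j0 = (int)((v0 / nx) % ny);
    const int k0 = (int)(v0 / ((R_xlen_t)nx * ny));

    for (int rep = 0; rep < samples_per_voxel; ++rep) {
      // jittered start inside the seed voxel (voxel center at index*spacing)
      double px = (i0 + rng.unif() - 0.5) * sx;
      double py = (j0 + rng.unif() - 0.5) * sy;
      double pz = (k0 + rng.unif() - 0.5) * sz;
      // initial direction: field orientation at the seed voxel, stored sign
      double prev[3] = {field[v0], field[v0 + nvox], field[v0 + 2 * nvox]};
      bool success = false;
      for (int st = 0; st < max_steps; ++st) {
        int i = (int)std::lround(px / sx);
        int j = (int)std::lround(py / sy);
        int k = (int)std::lround(pz / sz);
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) break;
        R_xlen_t v = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        if (boundary[v]) { counts[v] += 1; success = true; break; }
        if (!brain[v]) break;
        if (!field_defined[v]) break;
        double d[3] = {field[v], field[v + nvox], field[v + 2 * nvox]};
        double dt = d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2];
        if (dt < 0.0) { d[0] = -d[0]; d[1] = -d[1]; d[2] = -d[2]; }
        double sig = dispersion_deg[v] * M_PI / 180.0;
        double nd[3];
        if (sig > 0.0) {
          double t1[3], t2[3];
          ortho_basis(d, t1, t2);
          double g1 = sig * rng.norm(), g2 = sig * rng.norm();
          for (int c = 0; c < 3; ++c) nd[c] = d[c] + g1 * t1[c] + g2 * t2[c];
          double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
          for (int c = 0; c < 3; ++c) nd[c] /= nn;
        } else {
          nd[0] = d[0]; nd[1] = d[1]; nd[2] = d[2];
        }
        double ca = nd[0] * prev[0] + nd[1] * prev[1] + nd[2] * prev[2];
        if (ca < cos_curv) break;       // excessive turn -> discard
        px += step_mm * nd[0];
        py += step_mm * nd[1];
        pz += step_mm * nd[2];
        prev[0] = nd[0]; prev[1] = nd[1]; prev[2] = nd[2];
      }
      if (success) n_success += 1.0; else n_fail += 1.0;
    }
  }

  return List::create(_["counts"] = counts,
                      _["n_success"] = n_success,
                      _["n_failure"] = n_fail);
}
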