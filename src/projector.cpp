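// Line-integral projectors and single-scatter kernels for a miniature
// cylindrical PET scanner. Sinograms are parameterised per plane as
// (radial, angle); oblique segments tilt axially between ring planes.
// Volumes are column-major (nx, ny, nz), physical origin at the FOV centre,
// transverse pitch px (x = y) and axial pitch pz.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tri_gather(const double *v, int nx, int ny, int nz,
                                double px, double pz,
                                double x, double y, double z) {
  double fx = x / px + 0.5 * (nx - 1);
  double fy = y / px + 0.5 * (ny - 1);
  double fz = z / pz + 0.5 * (nz - 1);
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
      iz = (int)std::floor(fz);
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int kz = iz + dz;
    if (kz < 0 || kz >= nz) continue;
    double wzz = dz ? wz : 1.0 - wz;
    for (int dy = 0; dy <= 1; ++dy) {
      int ky = iy + dy;
      if (ky < 0 || ky >= ny) continue;
      double wyy = dy ? wy : 1.0 - wy;
      for (int dx = 0; dx <= 1; ++dx) {
        int kx = ix + dx;
        if (kx < 0 || kx >= nx) continue;
        double wxx = dx ? wx : 1.0 - wx;
        acc += wzz * wyy * wxx * v[kx + (size_t)nx * (ky + (size_t)ny * kz)];
      }
    }
  }
  return acc;
}

static inline void tri_scatter(double *v, int nx, int ny, int nz,
                               double px, double pz,
                               double x, double y, double z, double val) {
  double fx = x / px + 0.5 * (nx - 1);
  double fy = y / px + 0.5 * (ny - 1);
  double fz = z / pz + 0.5 * (nz - 1);
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
      iz = (int)std::floor(fz);
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  for (int dz = 0; dz <= 1; ++dz) {
    int kz = iz + dz;
    if (kz < 0 || kz >= nz) continue;
    double wzz = dz ? wz : 1.0 - wz;
    for (int dy = 0; dy <= 1; ++dy) {
      int ky = iy + dy;
      if (ky < 0 || ky >= ny) continue;
      double wyy = dy ? wy : 1.0 - wy;
      for (int dx = 0; dx <= 1; ++dx) {
        int kx = ix + dx;
        if (kx < 0 || kx >= nx) continue;
        double wxx = dx ? wx : 1.0 - wx;
        v[kx + (size_t)nx * (ky + (size_t)ny * kz)] += wzz * wyy * wxx * val;
      }
    }
  }
}

// Forward (gather) or back (scatter) projection over the full bin grid.
// angles: projection angles (rad); radials: signed radial offsets (mm);
// za, zb: per-plane axial endpoint positions (mm); det_radius: radius of
// the detector circle on which LOR endpoints sit. step: sampling step (mm).
// If forward, returns sinogram of length nr*na*np; else backprojects
// sino_in into a volume of length nx*ny*nz. Forward and back use identical
// sample positions and trilinear weights, so they are exact adjoints.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector dim3,
                          double px, double pz,
                          NumericVector angles, NumericVector radials,
                          NumericVector za, NumericVector zb,
                          double det_radius, double step,
                          bool forward, NumericVector sino_in) {
  const int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  const int na = angles.size(), nr = radials.size(), np = za.size();
  NumericVector out(forward ? (R_xlen_t)nr * na * np
                            : (R_xlen_t)nx * ny * nz);
  const double *vp = vol.begin();
  double *op = out.begin();
  const double *sp = sino_in.begin();
  for (int p = 0; p < np; ++p) {
    const double z1 = za[p], z2 = zb[p];
    for (int a = 0; a < na; ++a) {
      const double c = std::cos(angles[a]), sn = std::sin(angles[a]);
      for (int r = 0; r < nr; ++r) {
        const double s = radials[r];
        const size_t idx = (size_t)r + (size_t)nr * (a + (size_t)na * p);
        if (std::fabs(s) >= det_radius) continue;
        const double tmax = std::sqrt(det_radius * det_radius - s * s);
        // endpoints A (t = -tmax, ring a) and B (t = +tmax, ring b)
        const double ax = -sn * s - tmax * c, ay = c * s - tmax * sn;
        const double bx = -sn * s + tmax * c, by = c * s + tmax * sn;
        const double dx = bx - ax, dy = by - ay, dz = z2 - z1;
        const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
        const int n = std::max(2, (int)std::ceil(L / step));
        const double w = L / n;
        if (forward) {
          double acc = 0.0;
          for (int m = 0; m < n; ++m) {
            const double t = (m + 0.5) / n;
            acc += tri_gather(vp, nx, ny, nz, px, pz,
                              ax + t * dx, ay + t * dy, z1 + t * dz);
          }
          op[idx] = acc * w;
        } else {
          const double val = sp[idx] * w;
          if (val == 0.0) continue;
          for (int m = 0; m < n; ++m) {
            const double t = (m + 0.5) / n;
            tri_scatter(op, nx, ny, nz, px, pz,
                        ax + t * dx, ay + t * dy, z1 + t * dz, val);
          }
        }
      }
    }
  }
  return out;
}

// Line integrals of two volumes (activity, mu) from each endpoint to each
// scatter point, plus the endpoint-to-point distance. Endpoints and scatter
// points are (n x 3) matrices of physical mm coordinates.
// [[Rcpp::export]]
List cpp_ray_integrals(NumericVector act, NumericVector mu, IntegerVector dim3,
                       double px, double pz,
                       NumericMatrix ep, NumericMatrix sp, double step) {
  const int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  const int ne = ep.nrow(), ns = sp.nrow();
  NumericMatrix ia(ne, ns), im(ne, ns);
  const double *ap = act.begin(), *mp = mu.begin();
  for (int k = 0; k < ns; ++k) {
    const double sx = sp(k, 0), sy = sp(k, 1), sz = sp(k, 2);
    for (int e = 0; e < ne; ++e) {
      const double ex = ep(e, 0), ey = ep(e, 1), ez = ep(e, 2);
      const double dx = sx - ex, dy = sy - ey, dz = sz - ez;
      const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
      const int n = std::max(2, (int)std::ceil(L / step));
      const double w = L / n;
      double sa = 0.0, sm = 0.0;
      for (int m = 0; m < n; ++m) {
        const double t = (m + 0.5) / n;
        const double x = ex + t * dx, y = ey + t * dy, z = ez + t * dz;
        sa += tri_gather(ap, nx, ny, nz, px, pz, x, y, z);
        sm += tri_gather(mp, nx, ny, nz, px, pz, x, y, z);
      }
      ia(e, k) = sa * w;
      im(e, k) = sm * w;
    }
  }
  return List::create(_["act"] = ia, _["mu"] = im);
}

// Klein-Nishina total cross-section (per electron, units of r_e^2) as a
// function of eps = E / 511 keV; used for the energy scaling of mu.
static inline double kn_total_eps(double eps) {
  const double l = std::log(1.0 + 2.0 * eps);
  return 2.0 * M_PI *
         ((1.0 + eps) / (eps * eps) *
              (2.0 * (1.0 + eps) / (1.0 + 2.0 * eps) - l / eps) +
          l / (2.0 * eps) -
          (1.0 + 3.0 * eps) / ((1.0 + 2.0 * eps) * (1.0 + 2.0 * eps)));
}

// [[Rcpp::export]]
double cpp_kn_total(double eps) { return kn_total_eps(eps); }

// Single-scatter assembly. For each LOR (rows of ia_idx/ib_idx, 1-based
// indices into the endpoint table used for cpp_ray_integrals) sums over
// scatter points the standard SSS term: emission integral on one leg,
// 511-keV attenuation on the unscattered leg, energy-scaled attenuation on
// the scattered leg, Klein-Nishina weight, inverse-square distances, and a
// Gaussian-smoothed lower-level-discriminator acceptance.
// [[Rcpp::export]]
NumericVector cpp_sss_assemble(NumericMatrix ep, NumericMatrix sp,
                               NumericVector mu_s,
                               NumericMatrix int_act, NumericMatrix int_mu,
                               IntegerVector ia_idx, IntegerVector ib_idx,
                               double lld_keV, double eres_fwhm,
                               double vol_elem, double min_dist) {
  const int nl = ia_idx.size(), ns = sp.nrow();
  const double kn511 = kn_total_eps(1.0);
  NumericVector out(nl);
  for (int l = 0; l < nl; ++l) {
    const int ea = ia_idx[l] - 1, eb = ib_idx[l] - 1;
    if (ea < 0 || eb < 0) continue;
    const double axp = ep(ea, 0), ayp = ep(ea, 1), azp = ep(ea, 2);
    const double bxp = ep(eb, 0), byp = ep(eb, 1), bzp = ep(eb, 2);
    double acc = 0.0;
    for (int k = 0; k < ns; ++k) {
      const double sx = sp(k, 0), sy = sp(k, 1), sz = sp(k, 2);
      const double vax = sx - axp, vay = sy - ayp, vaz = sz - azp;
      const double vbx = bxp - sx, vby = byp - sy, vbz = bzp - sz;
      const double ra = std::sqrt(vax * vax + vay * vay + vaz * vaz);
      const double rb = std::sqrt(vbx * vbx + vby * vby + vbz * vbz);
      if (ra < min_dist || rb < min_dist) continue;
      double ct = (vax * vbx + vay * vby + vaz * vbz) / (ra * rb);
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      // scattered photon energy and Klein-Nishina differential weight
      const double P = 1.0 / (2.0 - ct);       // E'/511
      const double Ekev = 511.0 * P;
      const double s2 = 1.0 - ct * ct;
      const double kn = 0.5 * P * P * (P + 1.0 / P - s2);
      // energy acceptance: Gaussian-smoothed step at the LLD
      const double sig = eres_fwhm * Ekev / 2.354820045;
      const double accp = 0.5 * std::erfc(-(Ekev - lld_keV) / (sig * M_SQRT2));
      if (accp < 1e-6) continue;
      const double fmu = kn_total_eps(P) / kn511;  // mu(E')/mu(511)
      const double Ia = int_act(ea, k), Ib = int_act(eb, k);
      const double Ma = int_mu(ea, k), Mb = int_mu(eb, k);
      const double em =
          Ia * std::exp(-Ma - fmu * Mb) + Ib * std::exp(-Mb - fmu * Ma);
      if (em <= 0.0) continue;
      acc += mu_s[k] * kn * accp * em / (ra * ra * rb * rb);
    }
    out[l] = acc * vol_elem;
  }
  return out;
}

// Trilinearly interpolated rigid translation: out(x) = vol(x - d), i.e. the
// content moves by +d (mm). Voxels sampling outside the grid become 0.
// [[Rcpp::export]]
NumericVector cpp_shift_volume(NumericVector vol, IntegerVector dim3,
                               double px, double pz,
                               double dx, double dy, double dz) {
  const int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *vp = vol.begin();
  double *op = out.begin();
  for (int k = 0; k < nz; ++k) {
    const double z = (k - 0.5 * (nz - 1)) * pz - dz;
    for (int j = 0; j < ny; ++j) {
      const double y = (j - 0.5 * (ny - 1)) * px - dy;
      for (int i = 0; i < nx; ++i) {
        const double x = (i - 0.5 * (nx - 1)) * px - dx;
        op[i + (size_t)nx * (j + (size_t)ny * k)] =
            tri_gather(vp, nx, ny, nz, px, pz, x, y, z);
      }
    }
  }
  return out;
}
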