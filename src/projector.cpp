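// Rotation-based parallel-beam SPECT projector pair.
//
// Forward model per angle:
//   1. rotate activity and attenuation volumes about the z axis into the
//      detector frame (bilinear gather in the transaxial plane; rays run
//      along +y, detector u axis along rotated x, v axis along z);
//   2. weight each voxel by exp(-integral of mu from voxel to detector),
//      using half the voxel's own mu for the first step;
//   3. blur each constant-depth plane with an isotropic Gaussian whose
//      sigma grows with distance to the collimator face,
//      sigma(d) = sqrt(sigma0^2 + (slope * d)^2);
//   4. sum over depth and scale by sensitivity * voxel volume (mL), so a
//      concentration volume in MBq/mL maps to counts/s per detector pixel.
//
// The back projector is the exact matrix transpose: the bilinear gather is
// mirrored by a bilinear scatter with identical weights, the symmetric
// zero-padded convolutions are self-adjoint, and the attenuation weights
// are diagonal.  Adjointness holds to machine precision, which OS-EM and
// the dense-matrix tests rely on.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Geometry {
  int nx, ny, nz;
  double voxel;  // mm, isotropic
  double orbit;  // mm, rotation centre to collimator face
  double sigma0; // mm, intrinsic resolution sigma
  double slope;  // mm blur-sigma per mm distance
  double sens;   // counts/s per MBq
};

// Bilinear interpolation stencil of the in-plane rotation, shared by all z
// slices of one angle.  Precomputed once per angle.
struct RotStencil {
  std::vector<int> i00;       // lab-frame base index x0 + nx*y0, -1 if out
  std::vector<double> w00, w10, w01, w11;
};

void build_stencil(RotStencil &st, double angle_deg, int nx, int ny) {
  const double th = angle_deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const int n = nx * ny;
  st.i00.assign(n, -1);
  st.w00.assign(n, 0.0); st.w10.assign(n, 0.0);
  st.w01.assign(n, 0.0); st.w11.assign(n, 0.0);
  for (int yd = 0; yd < ny; ++yd) {
    for (int xd = 0; xd < nx; ++xd) {
      // detector-frame point mapped back into the lab frame
      const double dx = xd - cx, dy = yd - cy;
      const double xl = cx + c * dx - s * dy;
      const double yl = cy + s * dx + c * dy;
      const int x0 = (int)std::floor(xl), y0 = (int)std::floor(yl);
      if (x0 < 0 || y0 < 0 || x0 + 1 >= nx || y0 + 1 >= ny) continue;
      const double fx = xl - x0, fy = yl - y0;
      const int k = xd + nx * yd;
      st.i00[k] = x0 + nx * y0;
      st.w00[k] = (1 - fx) * (1 - fy);
      st.w10[k] = fx * (1 - fy);
      st.w01[k] = (1 - fx) * fy;
      st.w11[k] = fx * fy;
    }
  }
}

// out(xd, yd, z) = interpolated vol at rotated position; zero outside.
void rotate_gather(const double *vol, double *out, const RotStencil &st,
                   int nx, int ny, int nz) {
  const int plane = nx * ny;
  for (int z = 0; z < nz; ++z) {
    const double *src = vol + (size_t)plane * z;
    double *dst = out + (size_t)plane * z;
    for (int k = 0; k < plane; ++k) {
      const int i = st.i00[k];
      if (i < 0) { dst[k] = 0.0; continue; }
      dst[k] = st.w00[k] * src[i] + st.w10[k] * src[i + 1] +
               st.w01[k] * src[i + nx] + st.w11[k] * src[i + nx + 1];
    }
  }
}

// Exact transpose of rotate_gather: scatter detector-frame values into the
// lab frame with the same four weights.
void rotate_scatter(const double *det, double *acc, const RotStencil &st,
                    int nx, int ny, int nz) {
  const int plane = nx * ny;
  for (int z = 0; z < nz; ++z) {
    const double *src = det + (size_t)plane * z;
    double *dst = acc + (size_t)plane * z;
    for (int k = 0; k < plane; ++k) {
      const int i = st.i00[k];
      if (i < 0) continue;
      const double v = src[k];
      if (v == 0.0) continue;
      dst[i] += st.w00[k] * v;
      dst[i + 1] += st.w10[k] * v;
      dst[i + nx] += st.w01[k] * v;
      dst[i + nx + 1] += st.w11[k] * v;
    }
  }
}

// Survival fraction towards the detector (+y side of the rotated frame).
void attenuation_factors(const double *mu_rot, double *att, int nx, int ny,
                         int nz, double voxel_mm) {
  const double step_cm = voxel_mm / 10.0;
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      double cum = 0.0;
      for (int y = ny - 1; y >= 0; --y) {
        const size_t i = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
        const double m = mu_rot[i];
        att[i] = std::exp(-step_cm * (cum + 0.5 * m));
        cum += m;
      }
    }
  }
}

// Normalized symmetric 1-D Gaussian kernels, one per depth plane.
void build_kernels(std::vector<std::vector<double>> &kernels,
                   const Geometry &g) {
  kernels.assign(g.ny, std::vector<double>());
  const double cy = 0.5 * (g.ny - 1);
  for (int y = 0; y < g.ny; ++y) {
    double d = g.orbit - (y - cy) * g.voxel; // mm to collimator face
    if (d < 0) d = 0;
    const double sig_mm = std::sqrt(g.sigma0 * g.sigma0 +
                                    g.slope * g.slope * d * d);
    const double sig = sig_mm / g.voxel; // pixels
    int r = (sig < 1e-6) ? 0 : (int)std::ceil(3.5 * sig);
    const int rmax = std::max(g.nx, g.nz);
    if (r > rmax) r = rmax;
    std::vector<double> k(2 * r + 1, 0.0);
    if (r == 0) {
      k[0] = 1.0;
    } else {
      double sum = 0.0;
      for (int j = -r; j <= r; ++j) {
        const double v = std::exp(-0.5 * (j / sig) * (j / sig));
        k[j + r] = v;
        sum += v;
      }
      for (double &v : k) v /= sum;
    }
    kernels[y] = std::move(k);
  }
}

// Separable symmetric convolution of an nx-by-nz plane (zero padded), with
// the same 1-D kernel along both axes.  Self-adjoint by symmetry.
void conv2_sym(const double *in, double *out, double *tmp, int nx, int nz,
               const std::vector<double> &k) {
  const int r = ((int)k.size() - 1) / 2;
  if (r == 0) {
    std::copy(in, in + (size_t)nx * nz, out);
    return;
  }
  // along x
  for (int z = 0; z < nz; ++z) {
    const double *row = in + (size_t)nx * z;
    double *trow = tmp + (size_t)nx * z;
    for (int x = 0; x < nx; ++x) {
      const int j0 = std::max(-r, -x), j1 = std::min(r, nx - 1 - x);
      double acc = 0.0;
      for (int j = j0; j <= j1; ++j) acc += k[j + r] * row[x + j];
      trow[x] = acc;
    }
  }
  // along z
  for (int z = 0; z < nz; ++z) {
    const int j0 = std::max(-r, -z), j1 = std::min(r, nz - 1 - z);
    double *orow = out + (size_t)nx * z;
    for (int x = 0; x < nx; ++x) {
      double acc = 0.0;
      for (int j = j0; j <= j1; ++j) acc += k[j + r] * tmp[x + (size_t)nx * (z + j)];
      orow[x] = acc;
    }
  }
}

Geometry make_geom(const IntegerVector &dim, double voxel_mm, double orbit_mm,
                   double sigma0_mm, double slope, double sensitivity) {
  Geometry g;
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.voxel = voxel_mm; g.orbit = orbit_mm;
  g.sigma0 = sigma0_mm; g.slope = slope; g.sens = sensitivity;
  return g;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector f, NumericVector mu,
                                  NumericVector angles_deg, double voxel_mm,
                                  double orbit_mm, double sigma0_mm,
                                  double slope, double sensitivity) {
  IntegerVector dim = f.attr("dim");
  if (dim.size() != 3) stop("activity volume must be a 3-D array");
  const Geometry g = make_geom(dim, voxel_mm, orbit_mm, sigma0_mm, slope,
                               sensitivity);
  if (mu.size() != f.size()) stop("activity and attenuation grids differ");
  const int na = angles_deg.size();
  const size_t nvox = (size_t)g.nx * g.ny * g.nz;
  const size_t npix = (size_t)g.nx * g.nz;

  std::vector<std::vector<double>> kernels;
  build_kernels(kernels, g);
  const double scale = g.sens * std::pow(g.voxel / 10.0, 3); // mL per voxel

  NumericVector proj(npix * na);
  proj.attr("dim") = IntegerVector::create(g.nx, g.nz, na);

  std::vector<double> rotf(nvox), rotmu(nvox), att(nvox);
  std::vector<double> plane(npix), blurred(npix), tmp(npix);
  RotStencil st;

  for (int a = 0; a < na; ++a) {
    build_stencil(st, angles_deg[a], g.nx, g.ny);
    rotate_gather(f.begin(), rotf.data(), st, g.nx, g.ny, g.nz);
    rotate_gather(mu.begin(), rotmu.data(), st, g.nx, g.ny, g.nz);
    attenuation_factors(rotmu.data(), att.data(), g.nx, g.ny, g.nz, g.voxel);
    double *out = proj.begin() + npix * a;
    for (int y = 0; y < g.ny; ++y) {
      // gather the depth plane (x fast, z slow), attenuation applied
      bool any = false;
      for (int z = 0; z < g.nz; ++z) {
        const size_t base = (size_t)g.nx * (y + (size_t)g.ny * z);
        for (int x = 0; x < g.nx; ++x) {
          const size_t i = base + x;
          const double v = rotf[i] * att[i];
          plane[x + (size_t)g.nx * z] = v;
          any = any || (v != 0.0);
        }
      }
      if (!any) continue; // empty depth plane contributes nothing
      conv2_sym(plane.data(), blurred.data(), tmp.data(), g.nx, g.nz,
                kernels[y]);
      for (size_t k = 0; k < npix; ++k) out[k] += blurred[k];
    }
    for (size_t k = 0; k < npix; ++k) out[k] *= scale;
  }
  return proj;
}

// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector p, NumericVector mu,
                               NumericVector angles_deg, double voxel_mm,
                               double orbit_mm, double sigma0_mm, double slope,
                               double sensitivity) {
  IntegerVector mdim = mu.attr("dim");
  if (mdim.size() != 3) stop("attenuation volume must be a 3-D array");
  const Geometry g = make_geom(mdim, voxel_mm, orbit_mm, sigma0_mm, slope,
                               sensitivity);
  IntegerVector pdim = p.attr("dim");
  if (pdim.size() != 3 || pdim[0] != g.nx || pdim[1] != g.nz ||
      pdim[2] != angles_deg.size())
    stop("projection array does not match grid/angles");
  const size_t nvox = (size_t)g.nx * g.ny * g.nz;
  const size_t npix = (size_t)g.nx * g.nz;

  std::vector<std::vector<double>> kernels;
  build_kernels(kernels, g);
  const double scale = g.sens * std::pow(g.voxel / 10.0, 3);

  NumericVector vol(nvox);
  vol.attr("dim") = mdim;

  std::vector<double> rotmu(nvox), att(nvox), w(nvox);
  std::vector<double> q(npix), blurred(npix), tmp(npix);
  RotStencil st;

  for (int a = 0; a < angles_deg.size(); ++a) {
    build_stencil(st, angles_deg[a], g.nx, g.ny);
    rotate_gather(mu.begin(), rotmu.data(), st, g.nx, g.ny, g.nz);
    attenuation_factors(rotmu.data(), att.data(), g.nx, g.ny, g.nz, g.voxel);
    const double *src = p.begin() + npix * a;
    for (size_t k = 0; k < npix; ++k) q[k] = src[k] * scale;
    for (int y = 0; y < g.ny; ++y) {
      conv2_sym(q.data(), blurred.data(), tmp.data(), g.nx, g.nz, kernels[y]);
      for (int z = 0; z < g.nz; ++z) {
        const size_t base = (size_t)g.nx * (y + (size_t)g.ny * z);
        for (int x = 0; x < g.nx; ++x) {
          const size_t i = base + x;
          w[i] = blurred[x + (size_t)g.nx * z] * att[i];
        }
      }
    }
    rotate_scatter(w.data(), vol.begin(), st, g.nx, g.ny, g.nz);
  }
  return vol;
}
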