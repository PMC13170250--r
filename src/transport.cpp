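// Monte Carlo photon-packet transport in a cylindrical (r,z) phantom.
//
// Conventions: lengths in mm, optical coefficients in mm^-1. The beam enters
// the top face (z = 0) travelling in +z; depth increases downward. Tallies are
// accumulated on an (n_r x n_z) cylindrical-shell grid. Fluence uses a
// track-length estimator with sub-steps capped at ds_max so that every
// deposit lands in the voxel containing the sub-segment midpoint. Absorption
// is deposited at collisions (implicit capture: w <- w * mu_s/mu_t), which
// makes the energy budget close to machine precision apart from Russian
// roulette noise. Uses R's RNG, so results are bit-reproducible under
// set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

inline double fresnel_unpolarized(double n1, double n2, double ci) {
  if (std::abs(n1 - n2) < 1e-12) return 0.0;
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 * si / n2;
  if (st >= 1.0) return 1.0;           // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine from a uniform deviate.
inline double hg_cos(double g, double u) {
  if (std::abs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and azimuth psi.
inline void spin(double &ux, double &uy, double &uz, double ct, double psi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(psi), sp = std::sin(psi);
  if (std::abs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0) ? ct : -ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

struct Domain {
  double radius, height, dr, dz;
  int n_r, n_z;
  inline int ivox(double x, double y, double z) const {
    double r = std::sqrt(x * x + y * y);
    int ir = (int)(r / dr); if (ir >= n_r) ir = n_r - 1;
    int iz = (int)(z / dz); if (iz >= n_z) iz = n_z - 1; if (iz < 0) iz = 0;
    return ir + n_r * iz;
  }
};

// Distance along (ux,uy,uz) from (x,y,z) to the cylinder boundary.
// face: 0 top (z=0), 1 bottom (z=height), 2 side (r=radius).
inline double boundary_distance(const Domain &D, double x, double y, double z,
                                double ux, double uy, double uz, int &face) {
  double s = INF; face = -1;
  if (uz > 0.0) { double t = (D.height - z) / uz; if (t < s) { s = t; face = 1; } }
  else if (uz < 0.0) { double t = -z / uz; if (t < s) { s = t; face = 0; } }
  double a = ux * ux + uy * uy;
  if (a > 1e-20) {
    double b = x * ux + y * uy;
    double c = x * x + y * y - D.radius * D.radius;
    double disc = b * b - a * c;
    if (disc > 0.0) {
      double t = (-b + std::sqrt(disc)) / a;
      if (t >= 0.0 && t < s) { s = t; face = 2; }
    }
  }
  if (s < 0.0) s = 0.0;
  return s;
}

}  // namespace

//' @keywords internal
// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(NumericMatrix mu_a, NumericMatrix mu_s, NumericMatrix g,
                      double n_medium, double n_outside,
                      double radius, double height,
                      int n_photons, double beam_radius, int beam_profile,
                      double w_min, double p_survive,
                      double ds_max, int n_batches) {
  const int n_r = mu_a.nrow(), n_z = mu_a.ncol();
  Domain D{radius, height, radius / n_r, height / n_z, n_r, n_z};
  const int nv = n_r * n_z;

  // Batch accumulators for per-voxel standard errors.
  std::vector<double> phi_sum(nv, 0.0), phi_sq(nv, 0.0);
  std::vector<double> abs_sum(nv, 0.0), abs_sq(nv, 0.0);
  std::vector<double> phi_b(nv, 0.0), abs_b(nv, 0.0);

  double w_refl = 0.0, w_trans = 0.0, w_side = 0.0, w_abs = 0.0;
  double w_roulette = 0.0;  // net weight destroyed (+) / created (-) by roulette
  double path_total = 0.0;
  double scat_total = 0.0;

  if (n_batches < 2) n_batches = 2;
  if (n_batches > n_photons) n_batches = n_photons;
  const int batch_size = n_photons / n_batches;
  int batch_left = batch_size, batches_done = 0;
  int n_used = batch_size * n_batches;  // drop remainder so batches are equal

  // Specular reflection of the collimated beam at the entry face.
  const double r_sp = fresnel_unpolarized(n_outside, n_medium, 1.0);

  for (int ip = 0; ip < n_used; ip++) {
    // Launch: radial position from the beam profile, azimuth uniform.
    double rr;
    if (beam_profile == 0) {
      rr = beam_radius * std::sqrt(unif_rand());
    } else {  // gaussian, beam_radius = 1/e^2 intensity radius, truncated at domain
      do {
        rr = 0.5 * beam_radius * std::sqrt(-2.0 * std::log(unif_rand()));
      } while (rr >= radius);
    }
    double phi0 = 2.0 * M_PI * unif_rand();
    double x = rr * std::cos(phi0), y = rr * std::sin(phi0), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - r_sp;
    w_refl += r_sp;

    double tau = -std::log(unif_rand());
    bool alive = true;
    int guard = 0;

    while (alive && ++guard < 2000000) {
      int v = D.ivox(x, y, z);
      double ma = mu_a[v], ms = mu_s[v], mt = ma + ms;
      double s_coll = (mt > 0.0) ? tau / mt : INF;
      int face;
      double s_bound = boundary_distance(D, x, y, z, ux, uy, uz, face);

      int event;  // 0 = plain sub-step, 1 = collision, 2 = boundary
      double ds;
      if (s_bound <= s_coll && s_bound <= ds_max) { ds = s_bound; event = 2; }
      else if (s_coll <= ds_max)                  { ds = s_coll; event = 1; }
      else                                        { ds = ds_max; event = 0; }

      // Track-length fluence deposit in the voxel of the sub-segment midpoint.
      int vm = D.ivox(x + 0.5 * ds * ux, y + 0.5 * ds * uy, z + 0.5 * ds * uz);
      phi_b[vm] += w * ds;

      x += ds * ux; y += ds * uy; z += ds * uz;
      tau -= mt * ds;
      path_total += ds;

      if (event == 1) {  // collision: implicit capture, then scatter
        int vc = D.ivox(x, y, z);
        double mac = mu_a[vc], msc = mu_s[vc], mtc = mac + msc;
        double dw = (mtc > 0.0) ? w * mac / mtc : 0.0;
        abs_b[vc] += dw;
        w_abs += dw;
        w -= dw;
        if (w <= 0.0 || msc <= 0.0) { alive = false; }
        else {
          double ct = hg_cos(g[vc], unif_rand());
          spin(ux, uy, uz, ct, 2.0 * M_PI * unif_rand());
          scat_total += 1.0;
        }
        tau = -std::log(unif_rand());
      } else if (event == 2) {  // boundary: Fresnel reflect or escape
        double nxn, nyn, nzn;  // outward normal
        if (face == 0)      { nxn = 0.0; nyn = 0.0; nzn = -1.0; }
        else if (face == 1) { nxn = 0.0; nyn = 0.0; nzn = 1.0; }
        else {
          double rb = std::sqrt(x * x + y * y);
          nxn = x / rb; nyn = y / rb; nzn = 0.0;
        }
        double ci = ux * nxn + uy * nyn + uz * nzn;  // > 0 heading out
        if (ci < 0.0) ci = 0.0;
        double R = fresnel_unpolarized(n_medium, n_outside, ci);
        if (unif_rand() < R) {
          ux -= 2.0 * ci * nxn; uy -= 2.0 * ci * nyn; uz -= 2.0 * ci * nzn;
          // nudge inward off the boundary
          x -= 1e-9 * nxn; y -= 1e-9 * nyn; z -= 1e-9 * nzn;
        } else {
          if (face == 0) w_refl += w;
          else if (face == 1) w_trans += w;
          else w_side += w;
          alive = false;
        }
      }

      if (alive && w < w_min) {  // Russian roulette
        if (unif_rand() < p_survive) {
          w_roulette -= w * (1.0 / p_survive - 1.0);
          w /= p_survive;
        } else {
          w_roulette += w;
          alive = false;
        }
      }
    }

    if (--batch_left == 0) {
      for (int k = 0; k < nv; k++) {
        double mphi = phi_b[k] / batch_size, mabs = abs_b[k] / batch_size;
        phi_sum[k] += mphi; phi_sq[k] += mphi * mphi;
        abs_sum[k] += mabs; abs_sq[k] += mabs * mabs;
        phi_b[k] = 0.0; abs_b[k] = 0.0;
      }
      batch_left = batch_size;
      batches_done++;
    }
  }

  const int nb = batches_done;
  NumericMatrix phi(n_r, n_z), phi_se(n_r, n_z), am(n_r, n_z), am_se(n_r, n_z);
  NumericVector vol(n_r);
  for (int i = 0; i < n_r; i++) {
    double r0 = i * D.dr, r1 = (i + 1) * D.dr;
    vol[i] = M_PI * (r1 * r1 - r0 * r0) * D.dz;  // mm^3
  }
  for (int j = 0; j < n_z; j++) {
    for (int i = 0; i < n_r; i++) {
      int k = i + n_r * j;
      double m = phi_sum[k] / nb;
      double var = (phi_sq[k] / nb - m * m) / std::max(1, nb - 1);
      phi(i, j) = m / vol[i];
      phi_se(i, j) = std::sqrt(std::max(0.0, var)) / vol[i];
      double ma2 = abs_sum[k] / nb;
      double va2 = (abs_sq[k] / nb - ma2 * ma2) / std::max(1, nb - 1);
      am(i, j) = ma2 / vol[i];
      am_se(i, j) = std::sqrt(std::max(0.0, va2)) / vol[i];
    }
  }

  double N = (double)n_used;
  return List::create(
    _["phi"] = phi, _["phi_se"] = phi_se,
    _["a_total"] = am, _["a_se"] = am_se,
    _["budget"] = NumericVector::create(
      _["reflected"] = w_refl / N, _["transmitted"] = w_trans / N,
      _["side_escaped"] = w_side / N, _["absorbed"] = w_abs / N,
      _["roulette_residual"] = w_roulette / N),
    _["mean_pathlength"] = path_total / N,
    _["mean_scatter_events"] = scat_total / N,
    _["n_photons"] = n_used,
    _["specular"] = r_sp);
}

//' @keywords internal
// [[Rcpp::export(name = ".hg_sample_cpp")]]
NumericVector hg_sample_cpp(double g, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = hg_cos(g, u[i]);
  return out;
}

//' @keywords internal
// [[Rcpp::export(name = ".fresnel_cpp")]]
NumericVector fresnel_cpp(NumericVector n1, NumericVector n2, NumericVector ci) {
  int n = std::max(n1.size(), std::max(n2.size(), ci.size()));
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = fresnel_unpolarized(n1[i % n1.size()], n2[i % n2.size()],
                                 ci[i % ci.size()]);
  return out;
}
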