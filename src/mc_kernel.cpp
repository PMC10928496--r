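// Layered-slab Monte Carlo photon-packet transport.
//
// Geometry: layers stacked along z, z = 0 at the tracheal lumen surface,
// z = total thickness at the outer skin surface.  The source sits on the
// lumen surface and fires inward (+z).  Lengths in mm; interaction
// coefficients arrive already converted to 1/mm.
//
// Transport follows the classic MCML scheme: exponential optical-depth
// sampling against mu_t with the residual depth carried across layer
// boundaries, partial absorption (w * mu_a/mu_t) at each interaction,
// Henyey-Greenstein scattering, unpolarized Fresnel reflection/refraction
// at every index step, and Russian roulette for low-weight packets.
// All randomness comes from R's RNG so set.seed() fixes a run exactly.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double WMIN = 1e-4;   // roulette trigger weight
static const double PSURV = 0.1;   // roulette survival probability
static const long MAX_EVENTS = 40000000L; // per-packet safeguard, never hit in practice

struct Layer {
  double z0, z1;      // boundaries (mm)
  double mua, mus, mut; // 1/mm
  double g, n;
};

// Unpolarized Fresnel reflectance for |cos(theta_i)| = ci; sets the
// transmitted |cos(theta_t)|.  Returns 1 beyond the critical angle.
static inline double fresnelR(double n1, double n2, double ci, double& ct) {
  if (n1 == n2) { ct = ci; return 0.0; }
  if (ci > 1.0) ci = 1.0;
  double si2 = 1.0 - ci * ci;
  double r = n1 / n2;
  double st2 = r * r * si2;
  if (st2 >= 1.0) { ct = 0.0; return 1.0; }
  ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// 3D Henyey-Greenstein inverse-CDF sample of cos(theta).
static inline double hg_cos3d(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Planar (2D) Henyey-Greenstein deflection angle, closed-form inverse CDF
// of p(theta) = (1 - g^2) / (2*pi*(1 + g^2 - 2 g cos(theta))).
static inline double hg_angle2d(double g, double u) {
  if (std::fabs(g) < 1e-12) return M_PI * (2.0 * u - 1.0);
  return 2.0 * std::atan(((1.0 - g) / (1.0 + g)) * std::tan(M_PI * (u - 0.5)));
}

static std::vector<Layer> build_layers(const NumericMatrix& lay) {
  // columns: thickness_mm, mua_per_cm, mus_per_cm, g, n
  int nl = lay.nrow();
  std::vector<Layer> L(nl);
  double z = 0.0;
  for (int i = 0; i < nl; ++i) {
    L[i].z0 = z;
    z += lay(i, 0);
    L[i].z1 = z;
    L[i].mua = lay(i, 1) * 0.1;  // 1/cm -> 1/mm
    L[i].mus = lay(i, 2) * 0.1;
    L[i].mut = L[i].mua + L[i].mus;
    L[i].g = lay(i, 3);
    L[i].n = lay(i, 4);
  }
  return L;
}

// [[Rcpp::export(name = ".mc_run_2d")]]
List mc_run_2d(NumericMatrix layers, double n_packets, double x0,
               int angular_model, double tilt_rad,
               double bin_width, double domain_halfwidth,
               double n_out_lumen, double n_out_skin) {
  std::vector<Layer> L = build_layers(layers);
  const int nl = (int)L.size();
  const double Lx = domain_halfwidth;
  const int nb = (int)std::ceil(2.0 * Lx / bin_width);
  NumericVector bins(nb);
  double absorbed = 0.0, skin = 0.0, lumen = 0.0, lateral = 0.0;
  const long np = (long)n_packets;

  RNGScope scope;
  for (long ip = 0; ip < np; ++ip) {
    double x = x0, z = 0.0, w = 1.0;
    int li = 0;
    double psi; // launch angle from +z within the plane
    if (angular_model == 0) {          // Lambertian (cosine) lobe
      psi = std::asin(2.0 * unif_rand() - 1.0) + tilt_rad;
    } else {                           // pencil
      psi = tilt_rad;
    }
    double ux = std::sin(psi), uz = std::cos(psi);
    if (uz <= 0.0) { lumen += w; continue; }
    double srem = -std::log(unif_rand());
    long ev = 0;
    while (true) {
      if (++ev > MAX_EVENTS) { absorbed += w; break; }
      Layer& ly = L[li];
      double db; // distance to the layer boundary along the flight path
      if (uz > 0.0)      db = (ly.z1 - z) / uz;
      else if (uz < 0.0) db = (ly.z0 - z) / uz; // uz < 0 => db > 0
      else               db = R_PosInf;
      double dbmut = (ly.mut > 0.0) ? db * ly.mut : 0.0;
      if (dbmut <= srem) {
        // reach the boundary without interacting
        x += ux * db;
        z = (uz > 0.0) ? ly.z1 : ly.z0;
        srem -= dbmut;
        if (std::fabs(x) > Lx) { lateral += w; break; }
        bool up = (uz > 0.0);
        int lj = up ? li + 1 : li - 1;
        double n1 = ly.n;
        double n2 = up ? ((lj < nl) ? L[lj].n : n_out_skin)
                       : ((lj >= 0) ? L[lj].n : n_out_lumen);
        double ci = std::fabs(uz), ct;
        double R = fresnelR(n1, n2, ci, ct);
        if (R >= 1.0 || unif_rand() < R) {
          uz = -uz; // specular reflection, stay in layer
        } else {
          double nux = ux * (n1 / n2);
          double nuz = (up ? 1.0 : -1.0) * ct;
          double nrm = std::sqrt(nux * nux + nuz * nuz);
          ux = nux / nrm; uz = nuz / nrm;
          if (up && lj == nl) {
            skin += w;
            int ib = (int)std::floor((x + Lx) / bin_width);
            if (ib < 0) ib = 0;
            if (ib >= nb) ib = nb - 1;
            bins[ib] += w;
            break;
          }
          if (!up && lj < 0) { lumen += w; break; }
          li = lj;
        }
      } else {
        // interaction inside the layer
        double s = srem / ly.mut;
        x += ux * s; z += uz * s;
        if (std::fabs(x) > Lx) { lateral += w; break; }
        double dep = w * (ly.mua / ly.mut);
        absorbed += dep; w -= dep;
        if (w <= 0.0) break;
        double th = hg_angle2d(ly.g, unif_rand());
        double c = std::cos(th), sn = std::sin(th);
        double nux = ux * c - uz * sn;
        double nuz = ux * sn + uz * c;
        ux = nux; uz = nuz;
        if (w < WMIN) {
          if (unif_rand() < PSURV) w /= PSURV;
          else break; // roulette kill (unbiased)
        }
        srem = -std::log(unif_rand());
      }
    }
  }

  return List::create(_["bins"] = bins,
                      _["absorbed"] = absorbed,
                      _["skin"] = skin,
                      _["lumen"] = lumen,
                      _["lateral"] = lateral,
                      _["launched"] = (double)np);
}

// [[Rcpp::export(name = ".mc_run_3d")]]
List mc_run_3d(NumericMatrix layers, double n_packets, double x0,
               int angular_model, double tilt_rad,
               double bin_width, double domain_halfwidth, double y_halfwidth,
               double n_out_lumen, double n_out_skin) {
  std::vector<Layer> L = build_layers(layers);
  const int nl = (int)L.size();
  const double Lx = domain_halfwidth;
  const double Ly = y_halfwidth;
  const int nbx = (int)std::ceil(2.0 * Lx / bin_width);
  const int nby = (int)std::ceil(2.0 * Ly / bin_width);
  NumericMatrix bins(nbx, nby);
  double absorbed = 0.0, skin = 0.0, lumen = 0.0, lateral = 0.0;
  const long np = (long)n_packets;

  // lobe axis tilted by tilt_rad within the y-z plane (tube rotation moves
  // the side-firing direction perpendicular to the sensor axis x)
  const double ay = std::sin(tilt_rad), az = std::cos(tilt_rad);
  // orthonormal frame around the axis: t1 = x-hat, t2 = a x x-hat
  const double t2y = az, t2z = -ay;

  RNGScope scope;
  for (long ip = 0; ip < np; ++ip) {
    double x = x0, y = 0.0, z = 0.0, w = 1.0;
    int li = 0;
    double ux, uy, uz;
    if (angular_model == 0) {
      double cw = std::sqrt(unif_rand()); // Lambertian about the axis
      double sw = std::sqrt(1.0 - cw * cw);
      double ph = 2.0 * M_PI * unif_rand();
      double cp = std::cos(ph), sp = std::sin(ph);
      ux = sw * cp;
      uy = cw * ay + sw * sp * t2y;
      uz = cw * az + sw * sp * t2z;
    } else {
      ux = 0.0; uy = ay; uz = az;
    }
    if (uz <= 0.0) { lumen += w; continue; }
    double srem = -std::log(unif_rand());
    long ev = 0;
    while (true) {
      if (++ev > MAX_EVENTS) { absorbed += w; break; }
      Layer& ly = L[li];
      double db;
      if (uz > 0.0)      db = (ly.z1 - z) / uz;
      else if (uz < 0.0) db = (ly.z0 - z) / uz;
      else               db = R_PosInf;
      double dbmut = (ly.mut > 0.0) ? db * ly.mut : 0.0;
      if (dbmut <= srem) {
        x += ux * db; y += uy * db;
        z = (uz > 0.0) ? ly.z1 : ly.z0;
        srem -= dbmut;
        if (std::fabs(x) > Lx || std::fabs(y) > Lx) { lateral += w; break; }
        bool up = (uz > 0.0);
        int lj = up ? li + 1 : li - 1;
        double n1 = ly.n;
        double n2 = up ? ((lj < nl) ? L[lj].n : n_out_skin)
                       : ((lj >= 0) ? L[lj].n : n_out_lumen);
        double ci = std::fabs(uz), ct;
        double R = fresnelR(n1, n2, ci, ct);
        if (R >= 1.0 || unif_rand() < R) {
          uz = -uz;
        } else {
          double sc = n1 / n2;
          double nux = ux * sc, nuy = uy * sc;
          double nuz = (up ? 1.0 : -1.0) * ct;
          double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
          if (up && lj == nl) {
            skin += w;
            if (std::fabs(y) <= Ly) {
              int ib = (int)std::floor((x + Lx) / bin_width);
              int jb = (int)std::floor((y + Ly) / bin_width);
              if (ib < 0) ib = 0;
              if (ib >= nbx) ib = nbx - 1;
              if (jb < 0) jb = 0;
              if (jb >= nby) jb = nby - 1;
              bins(ib, jb) += w;
            }
            break;
          }
          if (!up && lj < 0) { lumen += w; break; }
          li = lj;
        }
      } else {
        double s = srem / ly.mut;
        x += ux * s; y += uy * s; z += uz * s;
        if (std::fabs(x) > Lx || std::fabs(y) > Lx) { lateral += w; break; }
        double dep = w * (ly.mua / ly.mut);
        absorbed += dep; w -= dep;
        if (w <= 0.0) break;
        double c = hg_cos3d(ly.g, unif_rand());
        double sn = std::sqrt(1.0 - c * c);
        double ph = 2.0 * M_PI * unif_rand();
        double cp = std::cos(ph), sp = std::sin(ph);
        if (std::fabs(uz) > 0.99999) {
          ux = sn * cp; uy = sn * sp; uz = (uz >= 0.0 ? c : -c);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double nux = sn * (ux * uz * cp - uy * sp) / den + ux * c;
          double nuy = sn * (uy * uz * cp + ux * sp) / den + uy * c;
          double nuz = -sn * cp * den + uz * c;
          ux = nux; uy = nuy; uz = nuz;
        }
        if (w < WMIN) {
          if (unif_rand() < PSURV) w /= PSURV;
          else break;
        }
        srem = -std::log(unif_rand());
      }
    }
  }

  return List::create(_["bins"] = bins,
                      _["absorbed"] = absorbed,
                      _["skin"] = skin,
                      _["lumen"] = lumen,
                      _["lateral"] = lateral,
                      _["launched"] = (double)np);
}
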