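// Analog Monte Carlo photon transport through a soil cylinder containing a
// root cylinder, with Woodcock (delta) tracking. Interactions: photoelectric
// (full local absorption), incoherent (Klein-Nishina, recoil electron energy
// deposited locally, photon continues), coherent (direction resampled
// against a screened atomic form factor, no deposition). Secondary electrons
// are not transported (kerma approximation); surrounding air is vacuum.
// Uses R's RNG so set.seed() gives reproducible tallies.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double ME_KEV = 510.99895;

// linear interpolation into the uniform energy grid, clamped at the ends
static inline double lin(const double* tab, int n, double e0, double de,
                         double E) {
  double f = (E - e0) / de;
  if (f <= 0.0) return tab[0];
  if (f >= n - 1) return tab[n - 1];
  int i = (int)f;
  double w = f - i;
  return tab[i] * (1.0 - w) + tab[i + 1] * w;
}

// Kahn's rejection method for the Klein-Nishina ratio x = E/E'
static inline double kahn_x(double alpha) {
  double t = 1.0 + 2.0 * alpha;
  for (;;) {
    double r1 = unif_rand(), r2 = unif_rand(), r3 = unif_rand();
    if (r1 <= t / (t + 8.0)) {
      double x = 1.0 + 2.0 * alpha * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return x;
    } else {
      double x = t / (1.0 + 2.0 * alpha * r2);
      double mu = 1.0 - (x - 1.0) / alpha;
      if (r3 <= 0.5 * (mu * mu + 1.0 / x)) return x;
    }
  }
}

// rotate direction u by polar angle with cosine mu and uniform azimuth
static inline void rotate_dir(double* u, double mu) {
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double ux = u[0], uy = u[1], uz = u[2];
  double a = std::sqrt(std::max(0.0, 1.0 - uz * uz));
  if (a > 1e-10) {
    u[0] = mu * ux + s * (std::cos(phi) * ux * uz - std::sin(phi) * uy) / a;
    u[1] = mu * uy + s * (std::cos(phi) * uy * uz + std::sin(phi) * ux) / a;
    u[2] = mu * uz - s * std::cos(phi) * a;
  } else {
    u[0] = s * std::cos(phi);
    u[1] = s * std::sin(phi);
    u[2] = mu * (uz > 0 ? 1.0 : -1.0);
  }
  double norm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= norm; u[1] /= norm; u[2] /= norm;
}

// distance along u from p to the entry of the finite cylinder (axis z,
// radius r, |z| <= hz); returns -1 when the ray misses
static inline double cyl_entry(const double* p, const double* u,
                               double cx, double cy, double r, double hz) {
  double ox = p[0] - cx, oy = p[1] - cy;
  double a = u[0] * u[0] + u[1] * u[1];
  double t1, t2;
  if (a < 1e-300) {
    if (ox * ox + oy * oy >= r * r) return -1.0;
    t1 = -1e300; t2 = 1e300;
  } else {
    double b = 2.0 * (ox * u[0] + oy * u[1]);
    double c = ox * ox + oy * oy - r * r;
    double disc = b * b - 4.0 * a * c;
    if (disc <= 0.0) return -1.0;
    double sq = std::sqrt(disc);
    t1 = (-b - sq) / (2.0 * a);
    t2 = (-b + sq) / (2.0 * a);
  }
  double z1, z2;
  if (std::fabs(u[2]) < 1e-300) {
    if (p[2] <= -hz || p[2] >= hz) return -1.0;
    z1 = -1e300; z2 = 1e300;
  } else {
    z1 = (-hz - p[2]) / u[2];
    z2 = (hz - p[2]) / u[2];
    if (z1 > z2) std::swap(z1, z2);
  }
  double lo = std::max(t1, z1), hi = std::min(t2, z2);
  if (lo >= hi || hi <= 0.0) return -1.0;
  return std::max(lo, 0.0);
}

// [[Rcpp::export]]
List mc_transport_cpp(
    double e0, double de,
    NumericMatrix mu_pe, NumericMatrix mu_inc, NumericMatrix mu_coh,
    NumericVector src_cdf, NumericVector src_lo, NumericVector src_hi,
    double soil_r, double soil_hz,
    double root_x, double root_y, double root_r, double root_hz,
    double cross_y, double cross_z, double cross_half,
    double seg_y, double seg_z, double seg_half,
    NumericVector shell_edges, NumericVector scr,
    NumericVector men_water, int n_azimuth,
    double cutoff, int n_primaries, int n_batches) {
  const int ne = mu_pe.nrow();
  const int nmat = mu_pe.ncol();   // 0 = soil, 1 = root
  if (nmat != 2) stop("expected two materials (soil, root)");
  std::vector<double> pe(ne * 2), inc(ne * 2), coh(ne * 2), tot(ne * 2),
      maj(ne);
  for (int i = 0; i < ne; ++i) {
    for (int m = 0; m < 2; ++m) {
      pe[m * ne + i] = mu_pe(i, m);
      inc[m * ne + i] = mu_inc(i, m);
      coh[m * ne + i] = mu_coh(i, m);
      tot[m * ne + i] = mu_pe(i, m) + mu_inc(i, m) + mu_coh(i, m);
    }
    maj[i] = std::max(tot[i], tot[ne + i]);
  }
  const int nb = src_cdf.size();
  const int nshell = shell_edges.size() - 1;
  const int npb = std::max(1, n_primaries / n_batches);
  NumericMatrix out(n_batches, 11);
  // collision-estimator tally of the water-kerma track density per soil
  // shell and azimuth bin: each Woodcock candidate collision contributes
  // E * (mu_en/rho)_water(E) / mu_majorant(E)
  NumericMatrix klen(nshell * n_azimuth, n_batches);
  const double x_start = -(soil_r + 1.0);

  RNGScope scope;
  for (int b = 0; b < n_batches; ++b) {
    double t_seg = 0, t_seg_sc = 0, t_root = 0, t_root_sc = 0, t_dep = 0,
        t_esc = 0, t_emit = 0;
    std::vector<double> t_shell(nshell, 0.0);
    for (int ip = 0; ip < npb; ++ip) {
      // sample source energy: bin from the CDF, uniform within the bin
      double u = unif_rand();
      int lo = 0, hi = nb - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (src_cdf[mid] < u) lo = mid + 1; else hi = mid;
      }
      double E = src_lo[lo] + unif_rand() * (src_hi[lo] - src_lo[lo]);
      t_emit += E;
      double p[3] = {x_start,
                     cross_y + (unif_rand() - 0.5) * 2.0 * cross_half,
                     cross_z + (unif_rand() - 0.5) * 2.0 * cross_half};
      double dir[3] = {1.0, 0.0, 0.0};
      bool scattered = false, alive = true;
      while (alive) {
        // advance to the soil cylinder if outside it
        double r2 = p[0] * p[0] + p[1] * p[1];
        bool inside = (r2 < soil_r * soil_r) && (std::fabs(p[2]) < soil_hz);
        if (!inside) {
          double t = cyl_entry(p, dir, 0.0, 0.0, soil_r, soil_hz);
          if (t < 0.0) { t_esc += E; break; }
          p[0] += dir[0] * (t + 1e-9);
          p[1] += dir[1] * (t + 1e-9);
          p[2] += dir[2] * (t + 1e-9);
          continue;
        }
        double mu_maj = lin(maj.data(), ne, e0, de, E);
        double s = -std::log(unif_rand()) / mu_maj;
        p[0] += dir[0] * s; p[1] += dir[1] * s; p[2] += dir[2] * s;
        r2 = p[0] * p[0] + p[1] * p[1];
        if (r2 >= soil_r * soil_r || std::fabs(p[2]) >= soil_hz) {
          // left the (convex) sample; straight rays cannot re-enter
          t_esc += E;
          break;
        }
        if (n_azimuth > 0 && std::fabs(p[2] - seg_z) <= seg_half) {
          double rr0 = std::sqrt(r2);
          for (int k = 0; k < nshell; ++k) {
            if (rr0 >= shell_edges[k] && rr0 < shell_edges[k + 1]) {
              // azimuth relative to the beam: 0 faces the incoming beam
              double phi = std::atan2(p[1], -p[0]);
              if (phi < 0.0) phi += 2.0 * M_PI;
              int ia = (int)(phi / (2.0 * M_PI) * n_azimuth);
              if (ia >= n_azimuth) ia = n_azimuth - 1;
              klen(k * n_azimuth + ia, b) +=
                  E * lin(&men_water[0], ne, e0, de, E) / (10.0 * mu_maj);
              break;
            }
          }
        }
        double dx = p[0] - root_x, dyy = p[1] - root_y;
        bool in_root = (dx * dx + dyy * dyy < root_r * root_r) &&
            (std::fabs(p[2]) < root_hz);
        int m = in_root ? 1 : 0;
        double mt = lin(&tot[m * ne], ne, e0, de, E);
        if (unif_rand() * mu_maj > mt) continue;   // virtual collision
        double mpe = lin(&pe[m * ne], ne, e0, de, E);
        double minc = lin(&inc[m * ne], ne, e0, de, E);
        double v = unif_rand() * mt;
        double edep = 0.0;
        // a deposit counts as "scattered" only when the photon scattered
        // at least once BEFORE this interaction (the first Compton recoil
        // is primary-beam energy transfer, which the kerma engine models)
        bool dep_scattered = scattered;
        if (v < mpe) {                // photoelectric: full absorption
          edep = E;
          alive = false;
        } else if (v < mpe + minc) {  // incoherent
          double x = kahn_x(E / ME_KEV);
          double mu = 1.0 - (x - 1.0) * ME_KEV / E;
          double Ep = E / x;
          edep = E - Ep;
          E = Ep;
          rotate_dir(dir, mu);
          scattered = true;
          if (E < cutoff) { edep += E; alive = false; }
        } else {                      // coherent: redirect only
          double mu;
          for (;;) {
            mu = 2.0 * unif_rand() - 1.0;
            double q = E * std::sqrt((1.0 - mu) / 2.0) * scr[m];
            double ff = 1.0 / ((1.0 + q * q) * (1.0 + q * q));
            if (unif_rand() <= 0.5 * (1.0 + mu * mu) * ff * ff) break;
          }
          rotate_dir(dir, mu);
          scattered = true;
        }
        if (edep > 0.0) {
          t_dep += edep;
          if (in_root) {
            t_root += edep;
            if (dep_scattered) t_root_sc += edep;
            if (std::fabs(p[1] - seg_y) <= seg_half &&
                std::fabs(p[2] - seg_z) <= seg_half) {
              t_seg += edep;
              if (dep_scattered) t_seg_sc += edep;
            }
          } else {
            double rr = std::sqrt(r2);
            for (int k = 0; k < nshell; ++k) {
              if (rr >= shell_edges[k] && rr < shell_edges[k + 1] &&
                  std::fabs(p[2] - seg_z) <= seg_half) {
                t_shell[k] += edep;
                break;
              }
            }
          }
        }
      }
    }
    out(b, 0) = t_seg; out(b, 1) = t_seg_sc; out(b, 2) = t_root;
    out(b, 3) = t_root_sc;
    for (int k = 0; k < nshell && k < 4; ++k) out(b, 4 + k) = t_shell[k];
    out(b, 8) = t_dep; out(b, 9) = t_esc; out(b, 10) = t_emit;
  }
  return List::create(Named("tallies") = out,
                      Named("kerma_water") = klen);
}
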