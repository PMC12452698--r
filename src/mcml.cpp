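#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Layered-tissue Monte Carlo photon transport (MCML-style random walk):
// exponential step sampling, implicit-capture weight deposition
// W * mu_a / mu_t at each interaction, Henyey-Greenstein scattering,
// Fresnel reflection/refraction at refractive-index mismatches, Russian
// roulette below a weight threshold.  The incident pencil beam enters
// the top surface at the origin, tilted by tilt_deg in the x-z plane.
//
// Bookkeeping: roulette survival multiplies the weight by 1/p; the net
// weight created (or destroyed on death) is charged to the absorbed
// tally, so reflected + transmitted + absorbed equals the launched
// weight exactly (up to floating-point summation error) on every run.
//
// Uses R's RNG (unif_rand) so a set.seed() in R makes runs reproducible.

static inline double fresnel_R(double n1, double n2, double ci,
                               double *ct_out) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) { *ct_out = 0.0; return 1.0; }  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  *ct_out = ct;
  if (ci > 0.999999) {
    double r0 = (n1 - n2) / (n1 + n2);
    return r0 * r0;
  }
  double thi = std::asin(si), tht = std::asin(st);
  double sm = std::sin(thi - tht), sp = std::sin(thi + tht);
  double tm = std::tan(thi - tht), tp = std::tan(thi + tht);
  return 0.5 * (sm * sm / (sp * sp) + tm * tm / (tp * tp));
}

// [[Rcpp::export(name = "mcml_run")]]
List mcml_run(NumericVector mu_a, NumericVector mu_s, NumericVector g,
              NumericVector n_idx, NumericVector thickness,
              double n_above, double n_below, double tilt_deg,
              int n_photons, double rr_threshold, double rr_survival,
              int n_bins, double r_max) {
  const int L = mu_a.size();
  std::vector<double> z_top(L), z_bot(L);
  double z_acc = 0.0;
  for (int i = 0; i < L; ++i) {
    z_top[i] = z_acc;
    z_acc += thickness[i];
    z_bot[i] = z_acc;
  }

  NumericVector bin_w(n_bins);
  const double bin_dr = r_max / n_bins;
  double refl = 0.0, trans = 0.0, absorbed = 0.0;
  double sum_x = 0.0, sum_y = 0.0, sum_r2 = 0.0;
  double un_w = 0.0, un_sum_x = 0.0;

  // specular reflection and refraction at the ambient / first-layer
  // interface (deterministic split, as in the standard layered model)
  const double alpha = tilt_deg * M_PI / 180.0;
  double ct_in;
  double rsp = fresnel_R(n_above, n_idx[0], std::cos(alpha), &ct_in);
  double ux0, uz0;
  if (rsp >= 1.0) {
    ux0 = 0.0; uz0 = 1.0;  // nothing enters; loop below tallies reflection
  } else {
    ux0 = n_above / n_idx[0] * std::sin(alpha);
    uz0 = ct_in;
  }

  for (int ph = 0; ph < n_photons; ++ph) {
    refl += rsp;
    if (rsp >= 1.0) continue;
    double W = 1.0 - rsp;
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = ux0, uy = 0.0, uz = uz0;
    int l = 0;
    long nscat = 0, nbounce = 0;
    bool alive = true;

    while (alive) {
      double mt = mu_a[l] + mu_s[l];
      double s = -std::log(unif_rand());  // dimensionless step
      while (s > 0.0 && alive) {
        double geom = (mt > 0.0) ? s / mt : DBL_MAX;
        double db;
        int toward;  // +1 toward bottom, -1 toward top
        if (uz > 0.0) { db = (z_bot[l] - z) / uz; toward = 1; }
        else if (uz < 0.0) { db = (z_top[l] - z) / uz; toward = -1; }
        else { db = DBL_MAX; toward = 0; }

        if (toward != 0 && db <= geom) {
          // hop to the boundary, bank the unused step
          x += ux * db; y += uy * db;
          z = (toward == 1) ? z_bot[l] : z_top[l];
          s -= db * mt;
          double n1 = n_idx[l];
          double n2 = (toward == 1)
            ? (l == L - 1 ? n_below : n_idx[l + 1])
            : (l == 0 ? n_above : n_idx[l - 1]);
          double ct;
          double R = fresnel_R(n1, n2, std::fabs(uz), &ct);
          if (unif_rand() > R) {
            if (toward == 1 && l == L - 1) {
              trans += W;
              double r = std::sqrt(x * x + y * y);
              int b = (int)(r / bin_dr);
              if (b >= n_bins) b = n_bins - 1;  // last bin open
              bin_w[b] += W;
              sum_x += W * x; sum_y += W * y; sum_r2 += W * r * r;
              if (nscat == 0) { un_w += W; un_sum_x += W * x; }
              alive = false;
            } else if (toward == -1 && l == 0) {
              refl += W;
              alive = false;
            } else {
              double ratio = n1 / n2;
              ux *= ratio; uy *= ratio;
              uz = (toward == 1) ? ct : -ct;
              l += toward;
              mt = mu_a[l] + mu_s[l];
            }
          } else {
            uz = -uz;
          }
          // guard against a lossless total-internal-reflection trap in
          // non-interacting layers
          if (++nbounce > 1000000L) {
            absorbed += W;
            alive = false;
          }
        } else {
          if (mt <= 0.0) {
            // non-interacting layer with horizontal direction: photon
            // can never leave; retire its weight
            absorbed += W;
            alive = false;
            break;
          }
          x += ux * geom; y += uy * geom; z += uz * geom;
          s = 0.0;
          double dw = W * mu_a[l] / mt;
          absorbed += dw;
          W -= dw;
          // Henyey-Greenstein deflection
          double gg = g[l], cth;
          double xi = unif_rand();
          if (std::fabs(gg) < 1e-12) {
            cth = 2.0 * xi - 1.0;
          } else {
            double t = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * xi);
            cth = (1.0 + gg * gg - t * t) / (2.0 * gg);
          }
          if (cth > 1.0) cth = 1.0;
          if (cth < -1.0) cth = -1.0;
          double sth = std::sqrt(1.0 - cth * cth);
          double phi = 2.0 * M_PI * unif_rand();
          double cp = std::cos(phi), sp = std::sin(phi);
          if (std::fabs(uz) > 0.999999) {
            ux = sth * cp;
            uy = sth * sp;
            uz = (uz >= 0.0) ? cth : -cth;
          } else {
            double den = std::sqrt(1.0 - uz * uz);
            double nux = sth * (ux * uz * cp - uy * sp) / den + ux * cth;
            double nuy = sth * (uy * uz * cp + ux * sp) / den + uy * cth;
            double nuz = -sth * cp * den + uz * cth;
            ux = nux; uy = nuy; uz = nuz;
          }
          ++nscat;
          if (W < rr_threshold) {
            if (unif_rand() < rr_survival) {
              double w_old = W;
              W /= rr_survival;
              absorbed += w_old - W;  // net weight created, charged here
            } else {
              absorbed += W;
              alive = false;
            }
          }
        }
      }
    }
  }

  return List::create(
    _["bin_weight"] = bin_w,
    _["reflected"] = refl,
    _["transmitted"] = trans,
    _["absorbed"] = absorbed,
    _["sum_x"] = sum_x, _["sum_y"] = sum_y, _["sum_r2"] = sum_r2,
    _["unscattered_weight"] = un_w,
    _["unscattered_sum_x"] = un_sum_x,
    _["n_photons"] = n_photons
  );
}
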