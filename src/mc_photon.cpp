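// Monte-Carlo photon transport in a layered slab: the independent oracle for
// the adding-doubling solver. Classic weighted-photon random walk with
// Henyey-Greenstein scattering, Fresnel boundary handling (internal
// reflection, refraction between layers), absorption by weight decay and
// Russian roulette. Collimated normal incidence; the specular reflection at
// the entry interface is excluded (the photon enters with weight 1 - r_sp),
// matching the solver's cross-polarized detection convention.

#include <Rcpp.h>
#include <random>
#include <cmath>

static double fresnel(double n1, double n2, double mu) {
  // unpolarized reflectance crossing from index n1 into n2 at |cos| = mu
  if (std::abs(n1 - n2) < 1e-12) return 0.0;
  const double s1 = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  const double s2 = n1 / n2 * s1;
  if (s2 >= 1.0) return 1.0;
  const double c1 = mu;
  const double c2 = std::sqrt(1.0 - s2 * s2);
  const double rs = (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2);
  const double rp = (n1 * c2 - n2 * c1) / (n1 * c2 + n2 * c1);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
Rcpp::List cpp_mc_slab(const Rcpp::NumericVector& mua,
                       const Rcpp::NumericVector& mus,
                       const Rcpp::NumericVector& g,
                       const Rcpp::NumericVector& n,
                       const Rcpp::NumericVector& thickness,
                       double n_outside, int n_photons, int seed,
                       int n_batches = 10) {
  const int nlay = mua.size();
  std::vector<double> zb(nlay + 1, 0.0);
  for (int l = 0; l < nlay; ++l) zb[l + 1] = zb[l] + thickness[l];
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  auto runif_pos = [&]() { double u; do { u = U(rng); } while (u <= 0.0); return u; };

  const double r_sp = fresnel(n_outside, n[0], 1.0);
  std::vector<double> Rd_b(n_batches, 0.0), Td_b(n_batches, 0.0),
      A_b(n_batches, 0.0);
  const int per_batch = n_photons / n_batches;

  for (int b = 0; b < n_batches; ++b) {
    double Rd = 0.0, Td = 0.0, Ab = 0.0;
    for (int p = 0; p < per_batch; ++p) {
      int lay = 0;
      double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
      double wgt = 1.0 - r_sp;
      bool alive = true;
      int nsteps = 0;
      while (alive && ++nsteps < 1000000) {
        const double mut = mua[lay] + mus[lay];
        double s = (mut > 0.0) ? -std::log(runif_pos()) / mut : 1e9;
        // propagate, handling boundary crossings
        while (alive) {
          double zstop = (uz > 0.0) ? zb[lay + 1] : zb[lay];
          double dz = zstop - z;
          double sb = (std::abs(uz) > 1e-12) ? dz / uz : 1e30;
          if (sb >= s || std::abs(uz) <= 1e-12) {
            z += s * uz;
            break;  // interaction inside the layer
          }
          // hit a boundary; decide reflect/transmit
          z = zstop;
          s -= sb;
          const double mu_in = std::abs(uz);
          const bool down = uz > 0.0;
          const int next = down ? lay + 1 : lay - 1;
          const double n1 = n[lay];
          const double n2 = (next < 0 || next >= nlay) ? n_outside : n[next];
          const double r = fresnel(n1, n2, mu_in);
          if (U(rng) < r) {
            uz = -uz;  // reflected
          } else {
            if (next < 0) { Rd += wgt; alive = false; break; }
            if (next >= nlay) { Td += wgt; alive = false; break; }
            // refract into the next layer
            const double ratio = n1 / n2;
            const double s1 = std::sqrt(std::max(0.0, 1.0 - mu_in * mu_in));
            const double s2 = ratio * s1;
            const double c2 = std::sqrt(std::max(0.0, 1.0 - s2 * s2));
            if (s1 > 1e-12) {
              ux *= ratio; uy *= ratio;
            }
            uz = down ? c2 : -c2;
            // rescale optical path for the new layer
            const double mut2 = mua[next] + mus[next];
            if (mut > 0.0 && mut2 > 0.0) s *= mut / mut2;
            else if (mut2 <= 0.0) s = 1e9;
            lay = next;
          }
        }
        if (!alive) break;
        // absorb and scatter (lay may have changed during propagation)
        const double mut_cur = mua[lay] + mus[lay];
        if (mut_cur <= 0.0) continue;
        const double da = wgt * mua[lay] / mut_cur;
        Ab += da;
        wgt -= da;
        if (wgt < 1e-4) {  // Russian roulette
          if (U(rng) < 0.1) wgt *= 10.0;
          else { alive = false; break; }
        }
        // Henyey-Greenstein polar angle
        const double gg = g[lay];
        double ct;
        if (std::abs(gg) < 1e-6) {
          ct = 2.0 * U(rng) - 1.0;
        } else {
          const double tmp = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * U(rng));
          ct = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
          ct = std::min(1.0, std::max(-1.0, ct));
        }
        const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        const double phi = 2.0 * M_PI * U(rng);
        const double cp = std::cos(phi), sp = std::sin(phi);
        if (std::abs(uz) > 0.99999) {
          ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
        } else {
          const double den = std::sqrt(1.0 - uz * uz);
          const double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          const double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          const double nz = -st * cp * den + uz * ct;
          ux = nx; uy = ny; uz = nz;
          const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
        }
      }
    }
    const double launched = per_batch * (1.0 - r_sp);
    Rd_b[b] = Rd / per_batch;
    Td_b[b] = Td / per_batch;
    A_b[b] = Ab / per_batch;
    (void)launched;
  }
  auto mean_se = [&](const std::vector<double>& v) {
    double m = 0.0;
    for (double x : v) m += x;
    m /= v.size();
    double s2 = 0.0;
    for (double x : v) s2 += (x - m) * (x - m);
    const double se = std::sqrt(s2 / (v.size() - 1.0) / v.size());
    return std::make_pair(m, se);
  };
  auto r = mean_se(Rd_b);
  auto t = mean_se(Td_b);
  auto a = mean_se(A_b);
  return Rcpp::List::create(
      Rcpp::Named("R") = r.first, Rcpp::Named("R_se") = r.second,
      Rcpp::Named("T") = t.first, Rcpp::Named("T_se") = t.second,
      Rcpp::Named("A") = a.first, Rcpp::Named("A_se") = a.second,
      Rcpp::Named("r_specular") = r_sp,
      Rcpp::Named("n_photons") = per_batch * n_batches);
}
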