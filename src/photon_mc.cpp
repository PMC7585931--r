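#include <Rcpp.h>
using namespace Rcpp;

// Photon random walk in a semi-infinite homogeneous slab, pencil beam at
// normal incidence, implicit-capture weighting with Russian roulette.
// Only the depth coordinate matters for remittance detection, so lateral
// position is not tracked; the full geometric path is.
//
// RNG protocol (must stay in lock-step with the pure-R reference walker in
// R/montecarlo.R): per step draw u_step; if the photon does not exit, draw
// u_cos, u_phi for the Henyey-Greenstein deflection, and u_roulette only
// when the weight has fallen below the roulette threshold.

// [[Rcpp::export]]
List photon_walk_engine(double mua, double mus, double g,
                        int n_photons, double w_min, double p_survive,
                        int max_steps) {
  RNGScope scope;  // uses R's global RNG stream
  const double mut = mua + mus;
  const double albedo = mus / mut;
  std::vector<double> paths, weights;
  paths.reserve(n_photons);
  weights.reserve(n_photons);

  for (int i = 0; i < n_photons; ++i) {
    double z = 0.0, uz = 1.0, w = 1.0, path = 0.0;
    for (int step = 0; step < max_steps; ++step) {
      double u1 = unif_rand();
      double s = -std::log(u1) / mut;
      double znew = z + uz * s;
      if (uz < 0.0 && znew <= 0.0) {
        path += (-z / uz);          // partial step to the surface
        paths.push_back(path);
        weights.push_back(w);
        break;
      }
      z = znew;
      path += s;
      w *= albedo;
      double u2 = unif_rand();
      double u3 = unif_rand();
      double ct;
      if (g != 0.0) {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u2);
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      } else {
        ct = 2.0 * u2 - 1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * u3;
      // direction update tracks uz only (azimuthal symmetry about launch
      // axis is broken per-photon, but lateral position is irrelevant);
      // the full 3D update of uz needs the in-plane component, carried
      // implicitly as sqrt(1 - uz^2) with azimuth phi.
      double sz = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      double uz_new;
      if (std::fabs(uz) > 0.99999) {
        uz_new = (uz >= 0.0 ? ct : -ct);
      } else {
        uz_new = -sz * st * std::cos(phi) + uz * ct;
      }
      uz = uz_new;
      if (w < w_min) {
        double u4 = unif_rand();
        if (u4 <= p_survive) {
          w /= p_survive;
        } else {
          break;                    // terminated, not detected
        }
      }
    }
  }
  return List::create(_["paths"] = wrap(paths),
                      _["weights"] = wrap(weights));
}
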