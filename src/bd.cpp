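#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

// Euler-Maruyama Brownian-dynamics reference for the reversible geminate
// problem.  Radial SDE in generalized dimensionality d with the Coulomb
// drift of V(r) = -RD/r (kBT units):
//
//   dr = [ (d-1) D / r - D RD / r^2 ] dt + sqrt(2 D) dW
//
// Bound walkers dissociate with rate kPT (exact exponential sampling) and
// are released at contact.  A free walker stepping below the contact
// radius is reflected and rebinds with the Erban-Chapman radiation-
// boundary probability ka * sqrt(pi dt / D).  Uses its own mt19937_64
// stream so results depend only on the seed argument.
// [[Rcpp::export]]
NumericMatrix bd_geminate_cpp(double a, double RD, double D, double d,
                              double kPT, double ka, int n_particles,
                              NumericVector out_times, double dt,
                              double r0, bool start_bound, int seed) {
  const int n_out = out_times.size();
  const double p_react = ka * std::sqrt(M_PI * dt / D);
  if (p_react > 0.01)
    stop("per-step reaction probability %.3g exceeds 1%%; reduce dt", p_react);

  std::mt19937_64 rng((uint64_t) seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const double sq = std::sqrt(2.0 * D * dt);
  std::vector<long> bound_count(n_out, 0);

  for (int p = 0; p < n_particles; ++p) {
    bool bound = start_bound;
    double r = start_bound ? a : r0;
    double t = 0.0;
    int k = 0;  // next output index
    while (k < n_out) {
      if (bound) {
        // exact dissociation time; kPT == 0 means bound forever
        double t_diss = (kPT > 0.0)
          ? t - std::log(1.0 - unif(rng)) / kPT
          : R_PosInf;
        while (k < n_out && out_times[k] <= t_diss) {
          ++bound_count[k];
          ++k;
        }
        if (k >= n_out) break;
        t = t_diss;
        r = a;
        bound = false;
      } else {
        while (k < n_out && out_times[k] <= t) ++k;  // record as free
        if (k >= n_out) break;
        const double drift = (d - 1.0) * D / r - D * RD / (r * r);
        double rn = r + drift * dt + sq * gauss(rng);
        if (rn < a) {
          rn = 2.0 * a - rn;
          if (unif(rng) < p_react) {
            bound = true;
            r = a;
            t += dt;
            continue;
          }
        }
        r = rn;
        t += dt;
      }
    }
  }

  NumericMatrix out(n_out, 3);
  for (int k = 0; k < n_out; ++k) {
    const double phat = (double) bound_count[k] / n_particles;
    out(k, 0) = out_times[k];
    out(k, 1) = phat;
    out(k, 2) = std::sqrt(std::max(phat * (1.0 - phat), 1e-12) / n_particles);
  }
  colnames(out) = CharacterVector::create("time", "p_bound", "se");
  return out;
}
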