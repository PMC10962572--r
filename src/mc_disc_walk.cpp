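#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo random walk in an impermeable disc of radius r (um), with
// intrinsic diffusivity d (um^2/ms). Walkers accumulate gradient phase
// under a pulsed-gradient pair (lobe 1 on [0, delta), lobe 2 negated on
// [Delta, Delta + delta)), with unit effective gamma*g. Returns the
// variance of the accumulated phase over walkers; under the Gaussian
// phase approximation -ln S = Var(phi) / 2, so the apparent perpendicular
// diffusivity is Var(phi) / (2 delta^2 (Delta - delta/3)).
//
// Boundary handling: radial specular reflection (a step ending at radius
// rho > r is mirrored to 2r - rho along the same ray), adequate for step
// lengths well below r. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
double mc_disc_phase_var(double r, double d, double Delta, double delta,
                         int n_walkers, double dt) {
  if (r <= 0.0 || d <= 0.0) stop("r and d must be positive");
  if (Delta <= delta / 3.0) stop("Delta must exceed delta/3");
  const int n_steps = (int)std::ceil((Delta + delta) / dt - 1e-9);
  const double step_sd = std::sqrt(2.0 * d * dt);

  std::vector<double> x(n_walkers), y(n_walkers), phase(n_walkers, 0.0);
  RNGScope scope;
  for (int i = 0; i < n_walkers; ++i) {  // uniform start inside the disc
    double xi, yi;
    do {
      xi = r * (2.0 * unif_rand() - 1.0);
      yi = r * (2.0 * unif_rand() - 1.0);
    } while (xi * xi + yi * yi > r * r);
    x[i] = xi; y[i] = yi;
  }

  for (int s = 0; s < n_steps; ++s) {
    const double tm = (s + 0.5) * dt;  // midpoint of the step
    double f = 0.0;
    if (tm < delta) f = 1.0;
    else if (tm >= Delta && tm < Delta + delta) f = -1.0;
    for (int i = 0; i < n_walkers; ++i) {
      double xi = x[i] + step_sd * norm_rand();
      double yi = y[i] + step_sd * norm_rand();
      double rho2 = xi * xi + yi * yi;
      if (rho2 > r * r) {
        double rho = std::sqrt(rho2);
        double scale = (2.0 * r - rho) / rho;
        if (scale < 0.0) scale = 0.0;  // pathological long step: clamp to centre
        xi *= scale; yi *= scale;
      }
      x[i] = xi; y[i] = yi;
      if (f != 0.0) phase[i] += f * x[i] * dt;
    }
  }

  double mean = 0.0;
  for (int i = 0; i < n_walkers; ++i) mean += phase[i];
  mean /= n_walkers;
  double var = 0.0;
  for (int i = 0; i < n_walkers; ++i) {
    const double e = phase[i] - mean;
    var += e * e;
  }
  return var / (n_walkers - 1);
}
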