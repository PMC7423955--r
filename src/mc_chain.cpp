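#include <Rcpp.h>
using namespace Rcpp;

// Toy lambda-coupled potentials evaluated inline for speed.
// kind 0: 1-D harmonic with spring constant and center interpolated
//         linearly in lambda; params = {k0, k1, c0, c1}.
// kind 1: soft-core LJ pair energy of a particle at distance r from a
//         fixed site, lambda-scaled (Beutler-style, shift on r^6 only);
//         params = {epsilon, sigma, alpha, box_length}.
static inline double toy_energy(int kind, const double *p, double lambda,
                                double x) {
  if (kind == 0) {
    double k = (1.0 - lambda) * p[0] + lambda * p[1];
    double c = (1.0 - lambda) * p[2] + lambda * p[3];
    double d = x - c;
    return 0.5 * k * d * d;
  }
  // soft-core LJ
  if (lambda == 0.0) return 0.0;
  double sig6 = std::pow(p[1], 6.0);
  double s = sig6 / (p[2] * (1.0 - lambda) * sig6 + std::pow(x, 6.0));
  return 4.0 * p[0] * lambda * (s * s - s);
}

// Metropolis chain at lambda_sim recording, at every step, the energy
// difference dU = U(lambda_other, x) - U(lambda_sim, x). Uses R's RNG
// so results are reproducible under set.seed(). Harmonic coordinates
// are unbounded; soft-core coordinates are reflected into (0, L].
// [[Rcpp::export(name = ".mc_chain_dU")]]
List mc_chain_dU(int kind, NumericVector params, double lambda_sim,
                 double lambda_other, double x0, int n_steps,
                 double step_size, double kT) {
  if (n_steps <= 0) stop("n_steps must be > 0");
  if (kT <= 0) stop("kT must be > 0");
  const double *p = params.begin();
  double L = (kind == 1) ? p[3] : 0.0;
  NumericVector dU(n_steps);
  double x = x0;
  double u_cur = toy_energy(kind, p, lambda_sim, x);
  int n_accept = 0;
  RNGScope scope;
  for (int i = 0; i < n_steps; ++i) {
    double xp = x + (unif_rand() * 2.0 - 1.0) * step_size;
    if (kind == 1) {
      // reflective walls at 0 and L keep the proposal symmetric
      if (xp < 0.0) xp = -xp;
      if (xp > L) xp = 2.0 * L - xp;
      if (xp < 0.0) xp = 0.0; // pathological step sizes
    }
    double u_prop = toy_energy(kind, p, lambda_sim, xp);
    if (!std::isfinite(u_prop)) stop("non-finite trial energy in MC chain");
    double dE = u_prop - u_cur;
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) {
      x = xp;
      u_cur = u_prop;
      ++n_accept;
    }
    double d = toy_energy(kind, p, lambda_other, x) - u_cur;
    if (!std::isfinite(d)) stop("non-finite energy difference in MC chain");
    dU[i] = d;
  }
  return List::create(_["dU"] = dU,
                      _["acceptance_rate"] = double(n_accept) / n_steps,
                      _["x_final"] = x);
}
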