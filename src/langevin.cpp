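#include <Rcpp.h>
using namespace Rcpp;

// Model potentials, mirrored by the R-side evaluators in sampler.R.
// kind codes: 0 flat, 1 adsorption_well, 2 hydration_oscillatory,
//             3 extraction_plateau
// params layout (fixed-length 10):
//  [0] well_depth  [1] well_position [2] well_width
//  [3] wall_position [4] wall_steepness [5] wall_height
//  [6] osc_amplitude [7] osc_period
//  [8] plateau_height (extraction_plateau reuses [1] as ramp_start and
//      [2] as ramp_width)

static inline double pot_U(int kind, const double* p, double x) {
  switch (kind) {
  case 0:
    return 0.0;
  case 1: {
    double g = (x - p[1]) / p[2];
    return p[0] * std::exp(-0.5 * g * g) +
           p[5] * std::exp(-(x - p[3]) * p[4]);
  }
  case 2: {
    double g = (x - p[1]) / p[2];
    double env = (x - p[1]) / (3.0 * p[2]);
    return p[0] * std::exp(-0.5 * g * g) +
           p[5] * std::exp(-(x - p[3]) * p[4]) +
           p[6] * std::cos(2.0 * M_PI * (x - p[1]) / p[7]) *
             std::exp(-0.5 * env * env);
  }
  case 3: {
    double t = (x - p[1]) / p[2];
    if (t <= 0.0) return 0.0;
    if (t >= 1.0) return p[8];
    return p[8] * t * t * (3.0 - 2.0 * t);
  }
  default:
    return 0.0;
  }
}

static inline double pot_dU(int kind, const double* p, double x) {
  switch (kind) {
  case 0:
    return 0.0;
  case 1: {
    double g = (x - p[1]) / p[2];
    return -p[0] * g / p[2] * std::exp(-0.5 * g * g) -
           p[4] * p[5] * std::exp(-(x - p[3]) * p[4]);
  }
  case 2: {
    double g = (x - p[1]) / p[2];
    double env = (x - p[1]) / (3.0 * p[2]);
    double e = std::exp(-0.5 * env * env);
    double w = 2.0 * M_PI / p[7];
    return -p[0] * g / p[2] * std::exp(-0.5 * g * g) -
           p[4] * p[5] * std::exp(-(x - p[3]) * p[4]) +
           p[6] * e * (-w * std::sin(w * (x - p[1])) -
                       std::cos(w * (x - p[1])) * env / (3.0 * p[2]));
  }
  case 3: {
    double t = (x - p[1]) / p[2];
    if (t <= 0.0 || t >= 1.0) return 0.0;
    return p[8] * 6.0 * t * (1.0 - t) / p[2];
  }
  default:
    return 0.0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_potential(int kind, NumericVector params, NumericVector x,
                            bool deriv) {
  NumericVector out(x.size());
  const double* p = params.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = deriv ? pot_dU(kind, p, x[i]) : pot_U(kind, p, x[i]);
  }
  return out;
}

// Overdamped Langevin dynamics of a particle in U(x) dragged by a harmonic
// trap moving at constant velocity:
//   dx = [-U'(x) - k (x - lambda)] / gamma * dt + sqrt(2 kT dt / gamma) eta
// External work accumulates as dW = k (lambda - x) dlambda.
// Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate_pull(int kind, NumericVector params, double spring_k,
                       double gamma, double kT, double dt, double lambda0,
                       double lambda1, int n_steps, int n_out, int burn_in) {
  const double* p = params.begin();
  double noise = std::sqrt(2.0 * kT * dt / gamma);
  double dlam = (lambda1 - lambda0) / n_steps;

  RNGScope scope;
  double x = lambda0;
  // burn-in at the stationary trap to start from an equilibrated state
  for (int i = 0; i < burn_in; ++i) {
    double f = -pot_dU(kind, p, x) - spring_k * (x - lambda0);
    x += f / gamma * dt + noise * norm_rand();
  }

  NumericVector lam_out(n_out), work_out(n_out), x_out(n_out), force_out(n_out);
  // save indices: n_out points uniform over [0, n_steps]. The recorded
  // spring force is the block average since the previous save point:
  // instantaneous samples fluctuate with sd sqrt(kT * k) and would be
  // useless for reconstructing the work by quadrature.
  double save_every = (double)n_steps / (n_out - 1);
  int next_save = 0;
  double W = 0.0, lambda = lambda0;
  double f_acc = 0.0;
  long n_acc = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (next_save < n_out &&
        step >= (int)std::floor(next_save * save_every + 0.5)) {
      lam_out[next_save] = lambda;
      work_out[next_save] = W;
      x_out[next_save] = x;
      force_out[next_save] =
        n_acc > 0 ? f_acc / n_acc : spring_k * (lambda - x);
      f_acc = 0.0;
      n_acc = 0;
      ++next_save;
    }
    if (step == n_steps) break;
    double f = -pot_dU(kind, p, x) - spring_k * (x - lambda);
    x += f / gamma * dt + noise * norm_rand();
    W += spring_k * (lambda - x) * dlam;
    f_acc += spring_k * (lambda - x);
    ++n_acc;
    lambda += dlam;
  }
  return List::create(_["lambda"] = lam_out, _["work"] = work_out,
                      _["x"] = x_out, _["force"] = force_out);
}

// Equilibrium sampling at a fixed trap position (velocity zero); returns
// thinned particle positions after burn-in.
// [[Rcpp::export]]
NumericVector cpp_sample_fixed(int kind, NumericVector params, double spring_k,
                               double gamma, double kT, double dt,
                               double lambda, int n_samples, int thin,
                               int burn_in) {
  const double* p = params.begin();
  double noise = std::sqrt(2.0 * kT * dt / gamma);
  RNGScope scope;
  double x = lambda;
  for (int i = 0; i < burn_in; ++i) {
    double f = -pot_dU(kind, p, x) - spring_k * (x - lambda);
    x += f / gamma * dt + noise * norm_rand();
  }
  NumericVector out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < thin; ++i) {
      double f = -pot_dU(kind, p, x) - spring_k * (x - lambda);
      x += f / gamma * dt + noise * norm_rand();
    }
    out[s] = x;
  }
  return out;
}
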