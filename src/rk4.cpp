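#include <Rcpp.h>
using namespace Rcpp;

// Healthy-liver reference proportions; model constants mirrored from R/.
static const double H0 = 0.8, K0 = 0.06, M0 = 0.06, E0 = 0.08;

struct State { double H, K, M, E; };

static inline State deriv(const State& s, const double* k, double t) {
  if (s.H <= 0.0 || s.K <= 0.0 || s.M <= 0.0 || s.E <= 0.0) {
    stop("integration left the valid region (non-positive compartment) near t = %f days",
         t);
  }
  const double kh = k[0], kEH = k[1], kHK = k[2], kHM = k[3], kHE = k[4],
               kME = k[5];
  const double total = s.H + s.K + s.M + s.E;
  State d;
  d.H = kh * (1.0 - s.H / H0) + kEH * (H0 / E0 - s.H / s.E);
  d.K = kh * (1.0 - s.K / K0) + kHK * (H0 - s.H);
  d.M = kh * (1.0 - s.M / M0) + kHM * (H0 - s.H);
  d.E = kh * (1.0 - s.E / E0) + kHE * (H0 - s.H) + kME * (s.M / total - M0);
  return d;
}

// Classical fixed-step fourth-order Runge-Kutta over nsteps steps of
// size `step` (days). Returns an (nsteps + 1) x 4 matrix of states
// including the initial state; columns H, K, M, E.
// [[Rcpp::export(name = ".rk4_kernel")]]
NumericMatrix rk4_kernel(NumericVector y0, NumericVector params,
                         double step, int nsteps) {
  if (y0.size() != 4) stop("y0 must have four elements");
  if (params.size() != 6) stop("params must have six elements");
  if (step <= 0.0 || nsteps < 0) stop("invalid step or step count");

  double k[6];
  for (int i = 0; i < 6; ++i) k[i] = params[i];

  NumericMatrix out(nsteps + 1, 4);
  State y = {y0[0], y0[1], y0[2], y0[3]};
  out(0, 0) = y.H; out(0, 1) = y.K; out(0, 2) = y.M; out(0, 3) = y.E;

  for (int i = 0; i < nsteps; ++i) {
    const double t = i * step;
    State k1 = deriv(y, k, t);
    State y2 = {y.H + 0.5 * step * k1.H, y.K + 0.5 * step * k1.K,
                y.M + 0.5 * step * k1.M, y.E + 0.5 * step * k1.E};
    State k2 = deriv(y2, k, t + 0.5 * step);
    State y3 = {y.H + 0.5 * step * k2.H, y.K + 0.5 * step * k2.K,
                y.M + 0.5 * step * k2.M, y.E + 0.5 * step * k2.E};
    State k3 = deriv(y3, k, t + 0.5 * step);
    State y4 = {y.H + step * k3.H, y.K + step * k3.K,
                y.M + step * k3.M, y.E + step * k3.E};
    State k4 = deriv(y4, k, t + step);
    y.H += step / 6.0 * (k1.H + 2.0 * k2.H + 2.0 * k3.H + k4.H);
    y.K += step / 6.0 * (k1.K + 2.0 * k2.K + 2.0 * k3.K + k4.K);
    y.M += step / 6.0 * (k1.M + 2.0 * k2.M + 2.0 * k3.M + k4.M);
    y.E += step / 6.0 * (k1.E + 2.0 * k2.E + 2.0 * k3.E + k4.E);
    if (y.H <= 0.0 || y.K <= 0.0 || y.M <= 0.0 || y.E <= 0.0) {
      stop("integration left the valid region (non-positive compartment) near t = %f days",
           (i + 1) * step);
    }
    out(i + 1, 0) = y.H; out(i + 1, 1) = y.K;
    out(i + 1, 2) = y.M; out(i + 1, 3) = y.E;
  }
  return out;
}
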