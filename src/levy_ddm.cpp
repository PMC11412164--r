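#include <Rcpp.h>
using namespace Rcpp;

// Chambers-Mallows-Stuck draw from the standard symmetric alpha-stable law
// S(alpha, beta = 0, scale = 1, loc = 0), valid for alpha in (0, 2], alpha != 1.
// At alpha = 2 this equals sqrt(2) * N(0,1); callers rescale by 1/sqrt(2) so
// that alpha = 2 yields a unit-variance Gaussian increment.
static inline double cms_stable(double alpha) {
  double u = M_PI * (unif_rand() - 0.5);   // Uniform(-pi/2, pi/2)
  double w = exp_rand();                   // Exp(1)
  double s = std::sin(alpha * u) / std::pow(std::cos(u), 1.0 / alpha);
  double t = std::pow(std::cos(u - alpha * u) / w, (1.0 - alpha) / alpha);
  return s * t;
}

// [[Rcpp::export]]
NumericVector cpp_rstable(int n, double alpha) {
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = M_SQRT1_2 * cms_stable(alpha);
  return out;
}

// First-passage Euler simulation of the Levy-flight diffusion between
// absorbing boundaries at 0 and a.  x starts at z*a; per step of size dt,
// x <- x + v*dt + dt^(1/alpha) * xi with xi standard symmetric stable
// scaled so alpha = 2 is a unit-diffusion Wiener process.
// v is per-trial (length n or recycled scalar).  Trials that do not absorb
// within max_t seconds of decision time are flagged censored (choice NA).
// [[Rcpp::export]]
List cpp_simulate_levy(NumericVector v, double a, double z, double t0,
                       double alpha, double dt, double max_t) {
  int n = v.size();
  IntegerVector choice(n);
  NumericVector rt(n);
  LogicalVector censored(n);
  long max_steps = (long)std::ceil(max_t / dt);
  bool gaussian = (alpha == 2.0);
  // CMS output is sqrt(2) * N(0,1) at alpha = 2; norm_rand() is used
  // directly in the Gaussian case, so the 1/sqrt(2) factor applies only
  // to the stable branch.
  double noise_scale = (gaussian ? 1.0 : M_SQRT1_2) *
    std::pow(dt, 1.0 / alpha);

  for (int i = 0; i < n; i++) {
    double x = z * a;
    double vdt = v[i] * dt;
    long step = 0;
    int ch = NA_INTEGER;
    bool cen = false;
    for (;;) {
      step++;
      double x_old = x;
      x += vdt + noise_scale * (gaussian ? norm_rand() : cms_stable(alpha));
      if (x >= a) { ch = 1; break; }
      if (x <= 0.0) { ch = 0; break; }
      if (gaussian) {
        // Brownian-bridge crossing correction: the continuous path may
        // have touched a boundary inside the step even though both
        // endpoints lie inside; removes the O(sqrt(dt)) Euler bias.
        double p_up = std::exp(-2.0 * (a - x_old) * (a - x) / dt);
        double p_lo = std::exp(-2.0 * x_old * x / dt);
        double u = unif_rand();
        if (u < p_up) { ch = 1; break; }
        if (u < p_up + p_lo) { ch = 0; break; }
      }
      if (step >= max_steps) { cen = true; break; }
    }
    choice[i] = ch;
    rt[i] = t0 + step * dt;
    censored[i] = cen;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt,
                      _["censored"] = censored);
}
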