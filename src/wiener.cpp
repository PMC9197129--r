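#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Series factor f1(tau, w): first-passage-time density at the lower boundary
// of a zero-drift, unit-separation Wiener process started at relative
// position w, at scaled time tau = (t - t0) / a^2.  Two classical expansions
// are available; the number of terms needed to push the truncation error
// below `eps` is computed for both and the cheaper series is used.
double fpt_series(double tau, double w, double eps) {
  if (tau <= 0.0) return 0.0;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau *
                         std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    double lo = std::sqrt(tau) + 1.0;
    if (ks < lo) ks = lo;
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    double lo = 1.0 / (M_PI * std::sqrt(tau));
    if (kl < lo) kl = lo;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f = 0.0;
  if (ks < kl) {
    // small-time representation: sum of image charges
    int K = (int)std::ceil(ks);
    for (int k = -K; k <= K; ++k) {
      double u = w + 2.0 * k;
      f += u * std::exp(-u * u / (2.0 * tau));
    }
    f /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    // large-time representation: sine eigenfunction expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
           std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Defective density of absorption at the lower boundary at total time t,
// boundary separation a, mean drift v, relative start w, non-decision time
// t0, across-trial drift SD sv (Gaussian-marginalised analytically).
double wiener_lower(double t, double a, double v, double w, double t0,
                    double sv, double eps) {
  if (!(t > t0)) return 0.0;
  double tt = t - t0;
  double f1 = fpt_series(tt / (a * a), w, eps);
  if (f1 <= 0.0) return 0.0;
  double g;
  if (sv > 0.0) {
    double m = 1.0 + sv * sv * tt;
    g = std::exp((a * a * w * w * sv * sv - 2.0 * v * a * w - v * v * tt) /
                 (2.0 * m)) /
        std::sqrt(m);
  } else {
    g = std::exp(-v * a * w - v * v * tt / 2.0);
  }
  double out = f1 / (a * a) * g;
  return R_FINITE(out) && out > 0.0 ? out : 0.0;
}

} // namespace

// Vectorised defective first-passage density.  `v` has length 1 or
// length(t); `lower = false` evaluates the upper boundary via reflection.
// [[Rcpp::export]]
NumericVector wiener_pdf_cpp(NumericVector t, double a, double z, double t0,
                             NumericVector v, double sv, bool lower,
                             double eps) {
  R_xlen_t n = t.size();
  bool vec = v.size() == n;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double vi = vec ? v[i] : v[0];
    double vv = lower ? vi : -vi;
    double ww = lower ? z : 1.0 - z;
    out[i] = wiener_lower(t[i], a, vv, ww, t0, sv, eps);
  }
  return out;
}

// Negative log-likelihood contribution for one homogeneous block of trials
// (shared a, z, t0, sv; per-trial or shared drift; per-trial boundary).
// Densities are floored so the optimizer sees a large finite penalty instead
// of -Inf in invalid regions.
// [[Rcpp::export]]
double wiener_negll_cpp(NumericVector t, LogicalVector is_lower, double a,
                        double z, double t0, NumericVector v, double sv,
                        double eps, double floor_dens) {
  R_xlen_t n = t.size();
  bool vec = v.size() == n;
  double nll = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double vi = vec ? v[i] : v[0];
    double vv = is_lower[i] ? vi : -vi;
    double ww = is_lower[i] ? z : 1.0 - z;
    double d = wiener_lower(t[i], a, vv, ww, t0, sv, eps);
    if (!(d > floor_dens)) d = floor_dens;
    nll -= std::log(d);
  }
  return nll;
}

// Euler-Maruyama simulation of the two-boundary process.  Uses R's RNG so
// that set.seed() governs reproducibility.  boundary: 0 = lower, 1 = upper,
// NA = censored at max_t.
// [[Rcpp::export]]
List wiener_sim_cpp(int n, double a, double z, double t0, NumericVector v,
                    double sv, double dt, double max_t) {
  bool vec = v.size() == (R_xlen_t)n;
  NumericVector rt(n);
  IntegerVector boundary(n);
  LogicalVector censored(n);
  double sqdt = std::sqrt(dt);
  double tmax_dec = max_t - t0;
  for (int i = 0; i < n; ++i) {
    double vi = vec ? v[i] : v[0];
    if (sv > 0.0) vi += sv * norm_rand();
    double x = z * a;
    double tdec = 0.0;
    int b = NA_INTEGER;
    while (true) {
      tdec += dt;
      if (tdec > tmax_dec) {
        b = NA_INTEGER;
        break;
      }
      x += vi * dt + sqdt * norm_rand();
      if (x <= 0.0) { b = 0; break; }
      if (x >= a)  { b = 1; break; }
    }
    if (b == NA_INTEGER) {
      boundary[i] = NA_INTEGER;
      rt[i] = max_t;
      censored[i] = true;
    } else {
      boundary[i] = b;
      rt[i] = t0 + tdec;
      censored[i] = false;
    }
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt,
                      _["censored"] = censored);
}
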