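#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage-time machinery for a Wiener accumulator between two
// absorbing boundaries (diffusion scale s = 1).  Parameterisation:
//   a  boundary separation, absorbing boundaries at 0 and a
//   v  drift rate (signed; positive drives towards the upper boundary)
//   w  RELATIVE starting point in (0,1); absolute start = w * a
// Decision time td is measured after removing non-decision time.
//
// The defective density at the LOWER boundary is evaluated through the
// standard dual-series representation in normalised time u = td / a^2:
// the small-time (image/reflection) expansion and the large-time
// (spectral/sine) expansion agree everywhere; whichever needs fewer terms
// at truncation tolerance eps is used.

static double fnorm_lower(double u, double w, double eps) {
  // zero-drift, unit-boundary density in normalised time u
  if (u <= 0.0) return 0.0;

  // required term counts (small-time ks, large-time kl)
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f = 0.0;
  if (ks < kl) {
    int half = (int)std::ceil(ks / 2.0);
    for (int k = -half; k <= half; ++k) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// lower-boundary defective density at decision time td, with optional
// closed-form marginalisation over v ~ Normal(v, sv^2)
static double dens_lower(double td, double a, double v, double w,
                         double sv, double eps) {
  if (td <= 0.0) return 0.0;
  double u = td / (a * a);
  double base = fnorm_lower(u, w, eps) / (a * a);
  if (base <= 0.0) return 0.0;
  double mult;
  if (sv <= 0.0) {
    mult = std::exp(-v * a * w - v * v * td / 2.0);
  } else {
    double s2t = sv * sv * td;
    mult = std::exp((sv * sv * a * a * w * w - 2.0 * a * v * w - v * v * td) /
                    (2.0 * (1.0 + s2t))) / std::sqrt(1.0 + s2t);
  }
  return base * mult;
}

// density at the requested boundary (upper via reflection v -> -v, w -> 1-w)
static double dens_boundary(double td, double a, double v, double w,
                            int upper, double sv, double eps) {
  if (upper) return dens_lower(td, a, -v, 1.0 - w, sv, eps);
  return dens_lower(td, a, v, w, sv, eps);
}

static double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// marginal density at observed rt: closed form over sv, Gauss-Legendre
// over t0 ~ U(t0 +/- st/2) and z ~ U(z +/- sz/2); qx/qw are nodes and
// weights on [-1, 1]
static double marg_dens_one(double rt, double a, double v, double z,
                            double t0, int upper, double sv, double st,
                            double sz, const NumericVector &qx,
                            const NumericVector &qw,
                            const NumericVector &zqx,
                            const NumericVector &zqw, double eps) {
  int nq = qx.size();
  int nz = zqx.size();
  if (st <= 0.0 && sz <= 0.0) {
    return dens_boundary(rt - t0, a, v, z, upper, sv, eps);
  }
  double f = 0.0;
  if (st > 0.0) {
    // Integrate t0 over the part of [t0 - st/2, t0 + st/2] that is both
    // physical (t0' >= 0) and compatible with the observation
    // (t0' < rt).  Restricting the Gauss-Legendre nodes to that
    // sub-interval removes the kink at td = 0 from the integrand, which
    // keeps low node counts accurate; the uniform density contributes
    // the factor (width of sub-interval) / st.
    double lo = t0 - 0.5 * st;
    if (lo < 0.0) lo = 0.0;
    double hi = t0 + 0.5 * st;
    if (hi > rt) hi = rt;
    if (hi <= lo) return 0.0;
    double half = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
    double wfac = (hi - lo) / st;
    for (int i = 0; i < nq; ++i) {
      double td = rt - (mid + half * qx[i]);
      if (td <= 0.0) continue;
      double inner = 0.0;
      if (sz > 0.0) {
        for (int j = 0; j < nz; ++j) {
          double zj = clampd(z + 0.5 * sz * zqx[j], 1e-3, 1.0 - 1e-3);
          inner += 0.5 * zqw[j] * dens_boundary(td, a, v, zj, upper, sv, eps);
        }
      } else {
        inner = dens_boundary(td, a, v, z, upper, sv, eps);
      }
      f += 0.5 * qw[i] * wfac * inner;
    }
  } else {
    double td = rt - t0;
    if (td <= 0.0) return 0.0;
    for (int j = 0; j < nz; ++j) {
      double zj = clampd(z + 0.5 * sz * zqx[j], 1e-3, 1.0 - 1e-3);
      f += 0.5 * zqw[j] * dens_boundary(td, a, v, zj, upper, sv, eps);
    }
  }
  return f;
}

// [[Rcpp::export]]
NumericVector wiener_fpt_cpp(NumericVector td, double a, double v, double z,
                             int upper, double eps) {
  int n = td.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = dens_boundary(td[i], a, v, z, upper, 0.0, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector wiener_marg_cpp(NumericVector rt, IntegerVector upper,
                              NumericVector a, NumericVector v,
                              NumericVector z, NumericVector t0, double sv,
                              double st, double sz, NumericVector qx,
                              NumericVector qw, NumericVector zqx,
                              NumericVector zqw, double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = marg_dens_one(rt[i], a[i], v[i], z[i], t0[i], upper[i], sv, st,
                           sz, qx, qw, zqx, zqw, eps);
  }
  return out;
}

// [[Rcpp::export]]
double wiener_logdens_sum_cpp(NumericVector rt, IntegerVector upper,
                              NumericVector a, NumericVector v,
                              NumericVector z, NumericVector t0, double sv,
                              double st, double sz, NumericVector qx,
                              NumericVector qw, NumericVector zqx,
                              NumericVector zqw, double eps,
                              double log_floor) {
  int n = rt.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = marg_dens_one(rt[i], a[i], v[i], z[i], t0[i], upper[i], sv,
                             st, sz, qx, qw, zqx, zqw, eps);
    double ld = d > 0.0 ? std::log(d) : R_NegInf;
    if (ld < log_floor) ld = log_floor;
    s += ld;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector wiener_logdens_cpp(NumericVector rt, IntegerVector upper,
                                 NumericVector a, NumericVector v,
                                 NumericVector z, NumericVector t0,
                                 double sv, double st, double sz,
                                 NumericVector qx, NumericVector qw,
                                 NumericVector zqx, NumericVector zqw,
                                 double eps, double log_floor) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d = marg_dens_one(rt[i], a[i], v[i], z[i], t0[i], upper[i], sv,
                             st, sz, qx, qw, zqx, zqw, eps);
    double ld = d > 0.0 ? std::log(d) : R_NegInf;
    if (ld < log_floor) ld = log_floor;
    out[i] = ld;
  }
  return out;
}

// Euler-Maruyama path simulator with linear boundary-crossing
// interpolation.  Inter-trial variabilities drawn per trial:
// v ~ Normal(v, sv), z ~ Uniform(z +/- sz/2), t0 ~ Uniform(t0 +/- st/2).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List simulate_ddm_cpp(NumericVector a, NumericVector v, NumericVector z,
                      NumericVector t0, double sv, double st, double sz,
                      double dt, double t_max) {
  int n = a.size();
  NumericVector rt(n);
  IntegerVector upper(n);
  double sqdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double vi = v[i] + (sv > 0.0 ? sv * norm_rand() : 0.0);
    double zi = z[i] + (sz > 0.0 ? sz * (unif_rand() - 0.5) : 0.0);
    double t0i = t0[i] + (st > 0.0 ? st * (unif_rand() - 0.5) : 0.0);
    zi = clampd(zi, 1e-3, 1.0 - 1e-3);
    double ai = a[i];
    double x = zi * ai;
    double t = 0.0;
    int up = -1;
    while (t < t_max) {
      double xprev = x;
      x += vi * dt + sqdt * norm_rand();
      t += dt;
      if (x >= ai) {
        double frac = (ai - xprev) / (x - xprev);
        t += (frac - 1.0) * dt;
        up = 1;
        break;
      }
      if (x <= 0.0) {
        double frac = (0.0 - xprev) / (x - xprev);
        t += (frac - 1.0) * dt;
        up = 0;
        break;
      }
      // Brownian-bridge correction: the path may have touched a boundary
      // within the step even though both endpoints are interior
      double p_up = std::exp(-2.0 * (ai - xprev) * (ai - x) / dt);
      if (unif_rand() < p_up) {
        t -= unif_rand() * dt;  // crossing occurred somewhere inside the step
        up = 1;
        break;
      }
      double p_lo = std::exp(-2.0 * xprev * x / dt);
      if (unif_rand() < p_lo) {
        t -= unif_rand() * dt;
        up = 0;
        break;
      }
    }
    if (up < 0) up = (x >= ai / 2.0) ? 1 : 0;  // pathological non-absorption
    rt[i] = t0i + t;
    upper[i] = up;
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}
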