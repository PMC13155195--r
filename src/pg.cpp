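#include <Rcpp.h>
using namespace Rcpp;

// Exact Devroye-type sampler for the Polya-Gamma distribution PG(b, c).
// PG(1, c) is drawn by rejection from a mixture of a truncated inverse
// Gaussian and a truncated exponential, with the alternating-series
// accept/reject step of the Jacobi theta representation. Integer b up to
// `max_exact` is drawn as a sum of b exact PG(1, c) variates; beyond that a
// moment-matched Gaussian is used (the b-fold convolution is asymptotically
// normal; relative error is negligible at the count magnitudes involved).

static const double PG_TRUNC = 0.64;

static double pg_a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > PG_TRUNC) {
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  }
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// Probability of proposing from the exponential tail (x > PG_TRUNC).
static double pg_mass_texpon(double z) {
  double t = PG_TRUNC;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse Gaussian IG(1/z, 1) truncated to (0, PG_TRUNC).
static double pg_rtigauss(double z) {
  z = std::fabs(z);
  double t = PG_TRUNC;
  double x = t + 1.0;
  if (z < 1.0 / t) {  // mu = 1/z > t: rejection from scaled chi-square tail
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double mu_y = mu * y;
      x = mu + 0.5 * mu * mu_y - 0.5 * mu * std::sqrt(4.0 * mu_y + mu_y * mu_y);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double pg_draw1(double c) {
  double z = std::fabs(c) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  for (;;) {
    double x;
    if (R::unif_rand() < pg_mass_texpon(z)) {
      x = PG_TRUNC + R::exp_rand() / fz;
    } else {
      x = pg_rtigauss(z);
    }
    double s = pg_a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

static double pg_mean(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-6) return b / 4.0 - b * ac * ac / 24.0;
  return b / (2.0 * ac) * std::tanh(ac / 2.0);
}

static double pg_var(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-3) return b / 24.0;
  double ch = std::cosh(ac / 2.0);
  return b * (std::sinh(ac) - ac) / (4.0 * ac * ac * ac * ch * ch);
}

static double pg_draw(double b, double c, int max_exact) {
  if (b == 0.0) return 0.0;
  double bi;
  if (std::fabs(b - std::round(b)) > 1e-8)
    stop("PG(b, c): non-integer b is not supported");
  bi = std::round(b);
  if (bi < 0) stop("PG(b, c): b must be non-negative");
  if (bi <= max_exact) {
    double s = 0.0;
    for (int k = 0; k < (int)bi; ++k) s += pg_draw1(c);
    return s;
  }
  // moment-matched gamma for large integer b: matches the exact mean and
  // variance and, unlike a Gaussian, preserves positivity and right skew
  double m = pg_mean(bi, c), v = pg_var(bi, c);
  double shape = m * m / v;
  return R::rgamma(shape, v / m);
}

//' @noRd
// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(NumericVector b, NumericVector c, int max_exact = 30) {
  R_xlen_t n = b.size();
  if (c.size() != n) stop("b and c must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = pg_draw(b[i], c[i], max_exact);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".rpg_mat")]]
NumericMatrix rpg_mat(NumericMatrix b, NumericMatrix c, int max_exact = 30) {
  if (b.nrow() != c.nrow() || b.ncol() != c.ncol())
    stop("b and c must have equal dimensions");
  NumericMatrix out(b.nrow(), b.ncol());
  R_xlen_t n = b.size();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = pg_draw(b[i], c[i], max_exact);
  return out;
}
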