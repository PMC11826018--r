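#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density with diffusion coefficient 1.
//
// The standardized density (boundary separation 1, drift 0) at the lower
// boundary is evaluated through the two complementary series expansions
// (small-time and large-time), picking whichever needs fewer terms for a
// requested truncation error, per evaluation.

static const double WFPT_EPS = 1e-10;  // truncation error per evaluation

// standardized lower-boundary density at normalized time u, start fraction w
static double fpt_std(double u, double w) {
  double ks, kl;
  // number of terms needed by the small-time expansion
  if (2.0 * std::sqrt(2.0 * M_PI * u) * WFPT_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * std::sqrt(2.0 * M_PI * u) * WFPT_EPS));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  // number of terms needed by the large-time expansion
  if (M_PI * u * WFPT_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * WFPT_EPS) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double p = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; k++) {
      double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * u));
    }
    p /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      p += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// log density of absorption at the *lower* boundary after decision time
// u_raw (seconds), boundary separation a, start fraction w (from lower),
// drift v
static double dwiener_lower_log(double u_raw, double a, double w, double v) {
  if (u_raw <= 0.0) return R_NegInf;
  double p = fpt_std(u_raw / (a * a), w);
  if (p <= 0.0) return R_NegInf;
  return std::log(p) - v * a * w - v * v * u_raw / 2.0 - 2.0 * std::log(a);
}

// signed-rt convention: rt > 0 is an upper-boundary (male) response,
// rt < 0 a lower-boundary (female) response; b is the start fraction
// toward the upper boundary
static double wfpt_log1(double rt_signed, double a, double t0, double b, double v) {
  double u = std::fabs(rt_signed) - t0;
  if (rt_signed > 0.0) {
    return dwiener_lower_log(u, a, 1.0 - b, -v);  // reflection to the upper boundary
  }
  return dwiener_lower_log(u, a, b, v);
}

// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector rt_signed, double a, double t0,
                               NumericVector b, NumericVector v) {
  int n = rt_signed.size();
  bool b1 = b.size() == 1, v1 = v.size() == 1;
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    out[i] = wfpt_log1(rt_signed[i], a, t0, b1 ? b[0] : b[i], v1 ? v[0] : v[i]);
  }
  return out;
}

// Per-(subject, cell) summed log likelihood over a set of trials.
// subj and cell are 0-based indices; a_s, t_s are per-subject, b_t and v_t
// per-trial. lik = 0 selects the wfpt likelihood, lik = 1 a unit-variance
// gaussian on the signed rt centered at the trial's drift (test hook for
// conjugate checks).
// [[Rcpp::export]]
NumericMatrix cell_loglik_cpp(NumericVector rt_signed, IntegerVector subj,
                              IntegerVector cell, int n_subj, int n_cell,
                              NumericVector a_s, NumericVector t_s,
                              NumericVector b_t, NumericVector v_t, int lik) {
  NumericMatrix out(n_subj, n_cell);
  int n = rt_signed.size();
  for (int i = 0; i < n; i++) {
    int s = subj[i], c = cell[i];
    double ll;
    if (lik == 0) {
      ll = wfpt_log1(rt_signed[i], a_s[s], t_s[s], b_t[i], v_t[i]);
    } else {
      double z = rt_signed[i] - v_t[i];
      ll = -0.5 * z * z - 0.5 * std::log(2.0 * M_PI);
    }
    out(s, c) += ll;
  }
  return out;
}

// Euler-Maruyama simulation of the diffusion path; uses R's RNG so results
// are reproducible through set.seed(). Returns columns (upper, rt_seconds).
// [[Rcpp::export]]
NumericMatrix sim_ddm_euler_cpp(int n, double a, double t0, double b, double v,
                                double dt, double tmax) {
  NumericMatrix out(n, 2);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; i++) {
    double x = b * a;
    double u = 0.0;
    int upper;
    for (;;) {
      x += v * dt + sdt * norm_rand();
      u += dt;
      if (x >= a) { upper = 1; break; }
      if (x <= 0.0) { upper = 0; break; }
      if (u >= tmax) { upper = (x >= b * a) ? 1 : 0; break; }
    }
    out(i, 0) = upper;
    out(i, 1) = t0 + u;
  }
  return out;
}
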