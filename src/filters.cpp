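#include <Rcpp.h>
using namespace Rcpp;

// Time-variant harmonic IIR notch cascade, direct form 2.
// Section j (j = 1..P) at sample n has coefficients
//   a1 = (1 + r_j) cos(j theta[n]),  a2 = -r_j,
//   b1 = -2 cos(j theta[n]),         k  = (1 + r_j) / 2,
// i.e. H_j(z) = k (1 + b1 z^-1 + z^-2) / (1 - a1 z^-1 - a2 z^-2).
// Coefficients are recomputed every sample from theta[n]; per-section
// state is carried through the recursion (zero-initialised).
// [[Rcpp::export]]
NumericVector tv_notch_cpp(NumericVector u, NumericVector theta,
                           NumericVector r) {
  const int n = u.size();
  const int P = r.size();
  if (theta.size() != n)
    stop("`theta` must have the same length as the input signal");
  std::vector<double> s1(P, 0.0), s2(P, 0.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = u[i];
    const double th = theta[i];
    for (int j = 0; j < P; ++j) {
      const double c = std::cos((j + 1) * th);
      const double rj = r[j];
      const double a1 = (1.0 + rj) * c;
      const double b1 = -2.0 * c;
      const double k = (1.0 + rj) / 2.0;
      // direct form 2: t = x + a1 s1 + a2 s2 with a2 = -rj
      const double t = x + a1 * s1[j] - rj * s2[j];
      x = k * (t + b1 * s1[j] + s2[j]);
      s2[j] = s1[j];
      s1[j] = t;
    }
    out[i] = x;
  }
  return out;
}

// Adaptive lattice-style notch frequency tracker.
// Constrained second-order IIR notch with transfer function
//   (1 - 2c z^-1 + z^-2) / (1 - 2 c rho z^-1 + rho^2 z^-2),
// where c = cos(theta) is the single adapted parameter. The squared
// notch output is minimised by a normalised stochastic-gradient step;
// the regressor is the all-pole state w[n-1] and the step is divided by
// a running estimate of its power, making the update scale-free.
// `state` = (w1, w2, pw, c); input must already be normalised.
// [[Rcpp::export]]
List alnf_cpp(NumericVector u, double mu, double rho,
              double cmin, double cmax, NumericVector state) {
  const int n = u.size();
  double w1 = state[0], w2 = state[1], pw = state[2], c = state[3];
  const double rho2 = rho * rho;
  NumericVector theta(n);
  for (int i = 0; i < n; ++i) {
    const double w = u[i] + 2.0 * c * rho * w1 - rho2 * w2;
    const double e = w - 2.0 * c * w1 + w2;
    pw = 0.99 * pw + 0.01 * w1 * w1;
    c += mu * e * w1 / (pw + 1e-12);
    if (c > cmax) c = cmax;
    if (c < cmin) c = cmin;
    w2 = w1;
    w1 = w;
    theta[i] = std::acos(c);
  }
  return List::create(_["theta"] = theta,
                      _["state"] = NumericVector::create(w1, w2, pw, c));
}
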