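#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli log-likelihood of candidate angular placements.
//
// For a node with radial coordinate r_i and each candidate angle cand[c],
// accumulates sum_j [ A_ij log p_ij + (1 - A_ij) log(1 - p_ij) ] over the
// already-placed nodes j, with p_ij the Fermi probability of the hyperbolic
// distance at the current coordinates.  Stable via the softplus form:
// log p = -softplus(x), log(1-p) = -softplus(-x), x = (beta*zeta/2)*(d - R).
//
// [[Rcpp::export]]
NumericVector placement_loglik(NumericVector cand, double r_i,
                               NumericVector theta_p, NumericVector r_p,
                               IntegerVector adj, double beta, double zeta,
                               double R) {
  const int P = theta_p.size();
  const int C = cand.size();
  if (r_p.size() != P || adj.size() != P)
    stop("placed-node vectors must have equal length");

  std::vector<double> ch(P), sh(P);
  const double chi = std::cosh(zeta * r_i);
  const double shi = std::sinh(zeta * r_i);
  for (int j = 0; j < P; ++j) {
    ch[j] = std::cosh(zeta * r_p[j]);
    sh[j] = std::sinh(zeta * r_p[j]);
  }

  const double half = beta * zeta / 2.0;
  // non-adjacent pairs farther than R + 3 contribute -softplus(-x) with
  // x >= 1.5*beta*zeta, below ~3e-7 at the default beta = 10: skip the
  // transcendental tail for them
  const double arg_far = std::cosh(zeta * (R + 3.0));
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    const double th = cand[c];
    double ll = 0.0;
    for (int j = 0; j < P; ++j) {
      double dth = std::fabs(th - theta_p[j]);
      if (dth > M_PI) dth = 2.0 * M_PI - dth;
      double arg = chi * ch[j] - shi * sh[j] * std::cos(dth);
      if (!adj[j] && arg > arg_far) continue;
      if (arg < 1.0) arg = 1.0;
      const double d = std::acosh(arg) / zeta;
      const double x = half * (d - R);
      // softplus(x) = log(1 + e^x), computed without overflow
      const double sp = x > 0 ? x + std::log1p(std::exp(-x))
                              : std::log1p(std::exp(x));
      ll += adj[j] ? -sp : (x - sp);
    }
    out[c] = ll;
  }
  return out;
}
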