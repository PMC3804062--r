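#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of the reduced critical birth-death process:
// each progenitor duplicates or is lost at equal rates, total per-cell
// event rate 2*r*lambda. Started from a single progenitor.
// Returns the progenitor count of each replicate at `duration`.
// [[Rcpp::export]]
IntegerVector cpp_simulate_reduced(double rlambda, double duration, int n_rep) {
  IntegerVector out(n_rep);
  const double rate2 = 2.0 * rlambda;
  for (int i = 0; i < n_rep; ++i) {
    int k = 1;
    double t = 0.0;
    while (k > 0 && rate2 > 0.0) {
      t += R::rexp(1.0 / (rate2 * k));
      if (t > duration) break;
      if (R::unif_rand() < 0.5) ++k; else --k;
    }
    out[i] = k;
  }
  return out;
}

// Exact Gillespie simulation of the two-compartment fate process:
// a progenitor S divides at rate lambda with outcomes S+S (prob r),
// S+D (prob 1-2r), D+D (prob r); a differentiated cell D is shed at
// rate gamma. Each clone starts as a single progenitor and is evolved
// for its own duration. Returns a matrix with columns (k_S, k_D).
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_clones(double lambda, double r, double gamma,
                                  NumericVector durations) {
  const int n = durations.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int kS = 1, kD = 0;
    double t = 0.0;
    const double T = durations[i];
    while (kS > 0 || kD > 0) {
      const double rdiv = lambda * kS;
      const double rloss = gamma * kD;
      const double total = rdiv + rloss;
      if (total <= 0.0) break;
      t += R::rexp(1.0 / total);
      if (t > T) break;
      if (R::unif_rand() * total < rdiv) {
        const double u = R::unif_rand();
        if (u < r) {
          ++kS;                       // S -> S + S
        } else if (u < 2.0 * r) {
          --kS; kD += 2;              // S -> D + D
        } else {
          ++kD;                       // S -> S + D
        }
      } else {
        --kD;                         // D -> shed
      }
    }
    out(i, 0) = kS;
    out(i, 1) = kD;
  }
  return out;
}
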