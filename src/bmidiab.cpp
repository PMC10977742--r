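// Numerical core: matrix exponentials for interval transition probabilities,
// row-vector propagation of the panel likelihood, exact (Gillespie) simulation
// of piecewise-constant-rate trajectories, and annual cohort stepping with an
// absorbing death state.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat& M) {
  return arma::expmat(M);
}

// Interval transition probabilities for a set of observation "keys" (unique
// sex x birth-year x survey-year combinations). All keys share a pool of
// (generator slice, duration) pairs whose exponentials are computed once.
// Returns, per key, the start-state row of the product of segment matrices.
// [[Rcpp::export]]
NumericMatrix key_state_probs_cpp(const arma::cube& Q,
                                  const IntegerVector& pair_q,
                                  const NumericVector& pair_dt,
                                  const List& key_pairs,
                                  const int start_state) {
  const int npair = pair_q.size();
  const int ns = Q.n_rows;
  std::vector<arma::mat> P(npair);
  for (int i = 0; i < npair; ++i) {
    P[i] = arma::expmat(Q.slice(pair_q[i] - 1) * pair_dt[i]);
  }
  const int nkey = key_pairs.size();
  NumericMatrix out(nkey, ns);
  arma::rowvec v(ns);
  for (int k = 0; k < nkey; ++k) {
    IntegerVector ids = key_pairs[k];
    v.zeros();
    v(start_state - 1) = 1.0;
    for (int j = 0; j < ids.size(); ++j) v = v * P[ids[j] - 1];
    for (int s = 0; s < ns; ++s) out(k, s) = v(s);
  }
  return out;
}

// Exact simulation of end-of-interval states. Individuals are grouped by key;
// each key carries an ordered segment table (generator slice index, duration)
// over which competing exponential clocks are run. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector sim_endpoints_cpp(const arma::cube& Q,
                                const List& key_segs,
                                const IntegerVector& n_per_key,
                                const int start_state) {
  const int ns = Q.n_rows;
  int total = 0;
  for (int k = 0; k < n_per_key.size(); ++k) total += n_per_key[k];
  IntegerVector out(total);
  int pos = 0;
  for (int k = 0; k < key_segs.size(); ++k) {
    NumericMatrix segs = key_segs[k];
    const int nseg = segs.nrow();
    for (int ind = 0; ind < n_per_key[k]; ++ind) {
      int s = start_state - 1;
      for (int g = 0; g < nseg; ++g) {
        const arma::mat& Qs = Q.slice(static_cast<int>(segs(g, 0)) - 1);
        double remain = segs(g, 1);
        for (;;) {
          const double lam = -Qs(s, s);
          if (lam <= 0.0) break;
          const double w = R::rexp(1.0 / lam);
          if (w >= remain) break;
          remain -= w;
          double u = R::runif(0.0, 1.0) * lam;
          double acc = 0.0;
          int dest = s;
          for (int j = 0; j < ns; ++j) {
            if (j == s) continue;
            acc += Qs(s, j);
            if (u <= acc) { dest = j; break; }
          }
          s = dest;
        }
      }
      out[pos++] = s + 1;
    }
  }
  return out;
}

// Annual stepping of one birth cohort through the living states plus an
// absorbing death state. Qsteps holds the living-state generator for each
// year; h the baseline death intensity -log(1 - qx); hr the per-state
// mortality hazard ratios. Row t of the result is the distribution after t
// years (columns: living states, then dead).
// [[Rcpp::export]]
NumericMatrix project_cohort_cpp(const arma::cube& Qsteps,
                                 const arma::vec& h,
                                 const arma::vec& hr) {
  const int T = Qsteps.n_slices;
  const int ns = Qsteps.n_rows;
  NumericMatrix out(T + 1, ns + 1);
  arma::rowvec v(ns + 1, arma::fill::zeros);
  v(0) = 1.0;
  out(0, 0) = 1.0;
  arma::mat Qa(ns + 1, ns + 1);
  for (int t = 0; t < T; ++t) {
    Qa.zeros();
    Qa.submat(0, 0, ns - 1, ns - 1) = Qsteps.slice(t);
    for (int i = 0; i < ns; ++i) {
      const double mu = h(t) * hr(i);
      Qa(i, ns) += mu;
      Qa(i, i) -= mu;
    }
    v = v * arma::expmat(Qa);
    for (int j = 0; j <= ns; ++j) out(t + 1, j) = v(j);
  }
  return out;
}
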