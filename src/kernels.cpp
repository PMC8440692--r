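#include <Rcpp.h>
using namespace Rcpp;

// Probability correct / incorrect for one RT over the expanded parameter grid.
// q is computed as (1 - chance - lam) + lam * e rather than 1 - pc: at extreme
// grid corners pc rounds to 1.0 in double precision while q stays ~1e-17 > 0.
static inline void pc_q(double x, double lam, double gam, double del,
                        double chance, double &pc, double &q) {
  if (x > del) {
    double e = std::exp(-gam * (x - del));
    pc = chance + lam * (1.0 - e);
    q  = (1.0 - chance - lam) + lam * e;
  } else {
    pc = chance;
    q  = 1.0 - chance;
  }
}

// Sequential Bayes update of grid weights over a run of trials, renormalizing
// after every trial. Returns the new (normalized) weight vector.
// [[Rcpp::export]]
NumericVector grid_update_cpp(NumericVector w0, NumericVector lam,
                              NumericVector gam, NumericVector del,
                              double chance, NumericVector rt,
                              IntegerVector correct) {
  int m = w0.size(), T = rt.size();
  if (lam.size() != m || gam.size() != m || del.size() != m)
    stop("parameter vectors must match grid size");
  if (correct.size() != T)
    stop("rt and correct must have equal length");
  NumericVector w = clone(w0);
  for (int t = 0; t < T; ++t) {
    double x = rt[t];
    int c = correct[t];
    double s = 0.0;
    for (int i = 0; i < m; ++i) {
      double pc, q;
      pc_q(x, lam[i], gam[i], del[i], chance, pc, q);
      w[i] *= c ? pc : q;
      // flush vanishing mass to exact zero: subnormal weights are
      // numerically irrelevant (< 1e-300 of the posterior) but make the
      // selection kernel pay the hardware's denormal penalty
      if (w[i] < 1e-300) w[i] = 0.0;
      s += w[i];
    }
    if (!(s > 0.0)) stop("posterior normalizer vanished (impossible data)");
    for (int i = 0; i < m; ++i) w[i] /= s;
  }
  return w;
}

// Per-grid-point likelihood of one (rt, correct) observation.
// [[Rcpp::export]]
NumericVector grid_likelihood_cpp(NumericVector lam, NumericVector gam,
                                  NumericVector del, double chance,
                                  double rt, int correct) {
  int m = lam.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double pc, q;
    pc_q(rt, lam[i], gam[i], del[i], chance, pc, q);
    out[i] = correct ? pc : q;
  }
  return out;
}

// Expected information gain (nats) of an n-trial block for each candidate SOA.
//
// PC:  m x S matrix, probability correct at each SOA's expected RT per grid
//      point; Hc: m x S conditional outcome entropies H(R|theta) per grid
//      point; Tm: (n+1) x (n+1) upper-triangular map from raw moments of pc to
//      the binomial pmf over k = 0..n (mixture predictive = mapped mixture
//      moments). Tiny negative pmf values from the alternating sum (~1e-13)
//      are treated as zero mass.
// [[Rcpp::export]]
NumericVector block_gain_cpp(NumericVector w, NumericMatrix PC,
                             NumericMatrix Hc, int n, NumericMatrix Tm) {
  int m = PC.nrow(), S = PC.ncol(), K = n + 1;
  if (w.size() != m || Hc.nrow() != m || Hc.ncol() != S)
    stop("dimension mismatch");
  if (Tm.nrow() != K || Tm.ncol() != K)
    stop("moment transform must be (n+1) x (n+1)");
  NumericVector gain(S);
  std::vector<double> mom(K);
  for (int s = 0; s < S; ++s) {
    std::fill(mom.begin(), mom.end(), 0.0);
    double hcond = 0.0;
    const double *pc = &PC(0, s), *h = &Hc(0, s);
    for (int i = 0; i < m; ++i) {
      double wi = w[i];
      if (wi < 1e-30) continue;  // negligible mass, avoids denormal math
      double p = pc[i], pw = wi;
      hcond += wi * h[i];
      mom[0] += pw;
      for (int k = 1; k < K; ++k) {
        pw *= p;
        mom[k] += pw;
      }
    }
    double hmarg = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = k; j < K; ++j) v += Tm(k, j) * mom[j];
      if (v > 0.0) hmarg -= v * std::log(v);
    }
    gain[s] = hmarg - hcond;
  }
  return gain;
}
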