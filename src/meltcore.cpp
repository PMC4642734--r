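#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Poland-Scheraga forward/backward partition-function recursions with the
// Fixman-Freire sum-of-exponentials loop weight.
//
// Configuration space: each base is closed (paired) or open. Weights:
//   - exp(-(dH - T dS)/RT) per adjacent closed pair (step weights w[i]),
//   - sigma * g(L) per internal open run of length L, with
//     g(L) = sum_k a_k exp(-b_k L),
//   - unit weight for terminal open runs (free ends),
//   - one association weight beta per molecule with >= 1 closed base
//     (log_beta); the fully open/dissociated state has weight 1.
//
// p_closed(i) = beta * F(i) * B(i) / (1 + beta * Z), where F(i)/B(i) are the
// left/right partial partition sums with base i closed and
// Z = sum_i F(i) with i read as the last closed base.
//
// Running rescaling keeps the recursions in double range; per-position log
// scale factors are carried alongside and recombined in log space.

static const double RESCALE_AT = 1e120;
static const double R_GAS = 1.987; // cal/(mol K)

static void ps_forward(const std::vector<double>& w, double sigma,
                       const std::vector<double>& a, const std::vector<double>& eb,
                       std::vector<double>& F, std::vector<double>& Lf) {
  const int n = (int)w.size() + 1;
  const int K = (int)a.size();
  std::vector<double> C(K, 0.0);
  double logscale = 0.0, one = 1.0, Fm1 = 0.0, Fm2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i >= 2) {
      for (int k = 0; k < K; ++k) C[k] = eb[k] * (C[k] + Fm2);
    }
    double loop = 0.0;
    for (int k = 0; k < K; ++k) loop += a[k] * C[k];
    double Fi = one + (i >= 1 ? w[i - 1] * Fm1 : 0.0) + sigma * loop;
    F[i] = Fi;
    Lf[i] = logscale;
    Fm2 = Fm1;
    Fm1 = Fi;
    if (Fi > RESCALE_AT) {
      double s = Fi;
      logscale += std::log(s);
      one /= s;
      Fm1 /= s;
      Fm2 /= s;
      for (int k = 0; k < K; ++k) C[k] /= s;
    }
  }
}

static void ps_closed_one(const std::vector<double>& w, double sigma,
                          const std::vector<double>& a, const std::vector<double>& eb,
                          double log_beta, double* p) {
  const int n = (int)w.size() + 1;
  std::vector<double> F(n), Lf(n);
  ps_forward(w, sigma, a, eb, F, Lf);
  // backward recursion == forward recursion on the reversed step weights
  std::vector<double> wr(w.rbegin(), w.rend());
  std::vector<double> Br(n), Lbr(n);
  ps_forward(wr, sigma, a, eb, Br, Lbr);

  // log Z = logsumexp_i (log F[i] + Lf[i])
  std::vector<double> lf(n);
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) {
    lf[i] = (F[i] > 0.0) ? std::log(F[i]) + Lf[i] : R_NegInf;
    if (lf[i] > m) m = lf[i];
  }
  double logZ;
  if (!R_FINITE(m)) {
    logZ = R_NegInf;
  } else {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      if (R_FINITE(lf[i])) s += std::exp(lf[i] - m);
    logZ = m + std::log(s);
  }

  double x = log_beta + logZ; // log of the associated partition mass
  double log_denom = (x > 35.0) ? x : std::log1p(std::exp(x));

  for (int i = 0; i < n; ++i) {
    double lb = (Br[n - 1 - i] > 0.0)
      ? std::log(Br[n - 1 - i]) + Lbr[n - 1 - i] : R_NegInf;
    double num = log_beta + lf[i] + lb;
    double pi = R_FINITE(num) ? std::exp(num - log_denom) : 0.0;
    p[i] = (pi > 1.0) ? 1.0 : pi;
  }
}

// closing probabilities for one sequence (step enthalpies/entropies in
// cal/mol and cal/mol/K) over a vector of temperatures (Kelvin);
// returns an n x length(tK) matrix
// [[Rcpp::export]]
NumericMatrix ps_closed_cpp(NumericVector dH, NumericVector dS,
                            NumericVector tK, double sigma,
                            NumericVector ffa, NumericVector ffb,
                            double init_dH, double init_dS, double log_ct4) {
  const int n = dH.size() + 1;
  const int m = tK.size();
  const int K = ffa.size();
  if (n < 2) stop("sequence must have at least 2 bases");
  std::vector<double> a(ffa.begin(), ffa.end());
  std::vector<double> eb(K);
  for (int k = 0; k < K; ++k) eb[k] = std::exp(-ffb[k]);
  NumericMatrix P(n, m);
  std::vector<double> w(n - 1);
  for (int t = 0; t < m; ++t) {
    const double T = tK[t];
    for (int i = 0; i < n - 1; ++i)
      w[i] = std::exp(-(dH[i] - T * dS[i]) / (R_GAS * T));
    const double log_beta = -(init_dH - T * init_dS) / (R_GAS * T) + log_ct4;
    ps_closed_one(w, sigma, a, eb, log_beta, &P(0, t));
  }
  return P;
}
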