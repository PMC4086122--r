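// Block-HMM window scoring.
//
// A window of length L is modelled as generated left-to-right: with
// probability 1-p emit one background letter, with probability p emit a
// motif block of width W whose emission is the half/half mixture of the
// motif on the forward and reverse-complement strand.  The reported score
// is log2 of the likelihood ratio against the pure-background model
// (p = 0), with p maximised over [0, 0.5].
//
// The DP runs in odds space: R(i) = F(i) / prod_{j<=i} b_j stays O(1)
// unless the window carries strong sites, in which case it grows like the
// likelihood ratio itself.  Overflow (ratio beyond ~1e200) switches to a
// log-space evaluation with golden-section search over p.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double P_MAX = 0.5;
static const double OVERFLOW_GUARD = 1e200;

// Per-position background probability b[i] for encoded window x (0..3, 4=N).
// tables[m] holds order-m conditionals, length 4^m * 4.  The first k
// positions (and positions whose context contains N) drop to the longest
// usable lower-order context.
static void background_probs(const int* x, int L, int k,
                             const std::vector<const double*>& tables,
                             std::vector<double>& b) {
  for (int i = 0; i < L; ++i) {
    if (x[i] == 4) { b[i] = 1.0; continue; }
    int m = i < k ? i : k;
    // shrink context until N-free
    while (m > 0) {
      bool ok = true;
      for (int j = i - m; j < i; ++j) if (x[j] == 4) { ok = false; break; }
      if (ok) break;
      --m;
    }
    int ctx = 0;
    for (int j = i - m; j < i; ++j) ctx = ctx * 4 + x[j];
    b[i] = tables[m][ctx * 4 + x[i]];
  }
}

// Odds of a motif block ending at 0-based position i (covering i-W+1..i):
// 0.5*(forward + revcomp emission) / product of background probs.
// Any N inside the block gives odds 0.
static void block_odds(const int* x, int L, const NumericMatrix& theta,
                       const std::vector<double>& b, std::vector<double>& odds) {
  int W = theta.nrow();
  for (int i = 0; i < L; ++i) odds[i] = 0.0;
  for (int i = W - 1; i < L; ++i) {
    int s = i - W + 1;
    double fwd = 1.0, rev = 1.0, denom = 1.0;
    bool hasN = false;
    for (int t = 0; t < W; ++t) {
      int base = x[s + t];
      if (base == 4) { hasN = true; break; }
      fwd *= theta(t, base);
      rev *= theta(W - 1 - t, 3 - base);
      denom *= b[s + t];
    }
    if (!hasN) odds[i] = 0.5 * (fwd + rev) / denom;
  }
}

// Forward odds recursion; returns R(L) (likelihood ratio at this p).
static double forward_odds(int L, int W, double p,
                           const std::vector<double>& odds,
                           std::vector<double>& Rf) {
  Rf[0] = 1.0;
  double q = 1.0 - p;
  for (int i = 1; i <= L; ++i) {
    double v = q * Rf[i - 1];
    if (i >= W) v += p * odds[i - 1] * Rf[i - W];
    Rf[i] = v;
  }
  return Rf[L];
}

static double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(-std::fabs(a - b)));
}

// log of the likelihood ratio at p, computed fully in log space.
static double log_forward(int L, int W, double p,
                          const std::vector<double>& logodds) {
  if (p <= 0.0) return 0.0;
  std::vector<double> lf(L + 1);
  lf[0] = 0.0;
  double lq = std::log1p(-p), lp = std::log(p);
  for (int i = 1; i <= L; ++i) {
    double v = lq + lf[i - 1];
    if (i >= W && logodds[i - 1] != R_NegInf)
      v = logsumexp2(v, lp + logodds[i - 1] + lf[i - W]);
    lf[i] = v;
  }
  return lf[L];
}

// Golden-section maximisation of log LR over p in [0, P_MAX].
static double golden_log_lr(int L, int W, const std::vector<double>& odds) {
  std::vector<double> logodds(L);
  for (int i = 0; i < L; ++i)
    logodds[i] = odds[i] > 0.0 ? std::log(odds[i]) : R_NegInf;
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = 0.0, bnd = P_MAX;
  double c = bnd - gr * (bnd - a), d = a + gr * (bnd - a);
  double fc = log_forward(L, W, c, logodds), fd = log_forward(L, W, d, logodds);
  for (int it = 0; it < 80 && (bnd - a) > 1e-7; ++it) {
    if (fc > fd) {
      bnd = d; d = c; fd = fc;
      c = bnd - gr * (bnd - a);
      fc = log_forward(L, W, c, logodds);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (bnd - a);
      fd = log_forward(L, W, d, logodds);
    }
  }
  double best = fc > fd ? fc : fd;
  if (best < 0.0) best = 0.0;  // p = 0 is always feasible
  return best;
}

// EM for p: expected block count from forward/backward odds.  Returns log
// LR at the fitted p, or falls back to golden-section on overflow or a
// decreasing likelihood.
static double em_log_lr(int L, int W, const std::vector<double>& odds,
                        double tol, int maxit) {
  // Screening: the likelihood-ratio derivative at p = 0 is sum(odds) - L.
  // When it is non-positive the optimum EM converges to from its small
  // starting point is p = 0, i.e. score 0 — the case for the vast majority
  // of genomic windows.
  double sum_odds = 0.0;
  for (int i = W - 1; i < L; ++i) sum_odds += odds[i];
  if (sum_odds <= (double)L) return 0.0;
  std::vector<double> Rf(L + 1), Rb(L + 1);
  double p = 0.01;
  double prev_ll = R_NegInf;
  for (int it = 0; it < maxit; ++it) {
    double lr = forward_odds(L, W, p, odds, Rf);
    if (!std::isfinite(lr) || lr > OVERFLOW_GUARD)
      return golden_log_lr(L, W, odds);
    double ll = std::log(lr);
    if (ll < prev_ll - 1e-10)
      return golden_log_lr(L, W, odds);
    prev_ll = ll;
    // backward odds
    Rb[L] = 1.0;
    double q = 1.0 - p;
    for (int i = L - 1; i >= 0; --i) {
      double v = q * Rb[i + 1];
      if (i + W <= L) v += p * odds[i + W - 1] * Rb[i + W];
      Rb[i] = v;
      if (!std::isfinite(v) || v > OVERFLOW_GUARD)
        return golden_log_lr(L, W, odds);
    }
    double nb = 0.0;  // expected motif block count
    for (int i = W; i <= L; ++i)
      nb += Rf[i - W] * p * odds[i - 1] * Rb[i];
    nb /= lr;
    double nl = (double)L - (double)W * nb;  // expected background letters
    double pnew = nb / (nb + nl);
    if (!std::isfinite(pnew) || pnew < 0.0) pnew = 0.0;
    if (pnew > P_MAX) pnew = P_MAX;
    if (std::fabs(pnew - p) < tol) { p = pnew; break; }
    p = pnew;
  }
  double lr = forward_odds(L, W, p, odds, Rf);
  if (!std::isfinite(lr) || lr > OVERFLOW_GUARD)
    return golden_log_lr(L, W, odds);
  double ll = std::log(lr);
  return ll > 0.0 ? ll : 0.0;
}

// log LR (nats) of one encoded window, p fixed (>= 0) or optimized (< 0)
static double window_log_lr(const int* x, int L, const NumericMatrix& theta,
                            const std::vector<const double*>& tables,
                            int bg_order, double fixed_p, double tol,
                            int maxit, std::vector<double>& b,
                            std::vector<double>& odds, std::vector<double>& Rf) {
  int W = theta.nrow();
  background_probs(x, L, bg_order, tables, b);
  block_odds(x, L, theta, b, odds);
  if (fixed_p >= 0.0) {
    double lr = forward_odds(L, W, fixed_p, odds, Rf);
    if (!std::isfinite(lr) || lr > OVERFLOW_GUARD) {
      std::vector<double> logodds(L);
      for (int i = 0; i < L; ++i)
        logodds[i] = odds[i] > 0.0 ? std::log(odds[i]) : R_NegInf;
      return log_forward(L, W, fixed_p, logodds);
    }
    return std::log(lr);
  }
  return em_log_lr(L, W, odds, tol, maxit);
}

static std::vector<const double*> table_ptrs(const List& bg_tables) {
  std::vector<const double*> tables(bg_tables.size());
  for (int j = 0; j < bg_tables.size(); ++j) {
    NumericVector t = bg_tables[j];
    tables[j] = REAL(t);
  }
  return tables;
}

// [[Rcpp::export]]
NumericVector cpp_score_windows(IntegerVector seq, IntegerVector starts,
                                IntegerVector ends, NumericMatrix theta,
                                List bg_tables, int bg_order,
                                double fixed_p, double tol, int maxit) {
  int n = starts.size();
  int W = theta.nrow();
  NumericVector scores(n);
  std::vector<const double*> tables = table_ptrs(bg_tables);
  const int* sptr = INTEGER(seq);
  int maxL = 0;
  for (int w = 0; w < n; ++w) {
    int L = ends[w] - starts[w];
    if (L > maxL) maxL = L;
  }
  std::vector<double> b(maxL), odds(maxL), Rf(maxL + 1);
  std::vector<int> rc(maxL);
  for (int w = 0; w < n; ++w) {
    int L = ends[w] - starts[w];
    const int* x = sptr + starts[w];
    if (L < W) { scores[w] = 0.0; continue; }
    bool allN = true;
    for (int i = 0; i < L; ++i) if (x[i] != 4) { allN = false; break; }
    if (allN) { scores[w] = 0.0; continue; }
    // strand-symmetrized score: mean of the window's and its reverse
    // complement's log likelihood ratio (a Markov background of order >= 1
    // is not reverse-complement invariant, so symmetry is imposed here)
    for (int i = 0; i < L; ++i) {
      int base = x[L - 1 - i];
      rc[i] = base == 4 ? 4 : 3 - base;
    }
    double ll_f = window_log_lr(x, L, theta, tables, bg_order, fixed_p,
                                tol, maxit, b, odds, Rf);
    double ll_r = window_log_lr(rc.data(), L, theta, tables, bg_order, fixed_p,
                                tol, maxit, b, odds, Rf);
    scores[w] = 0.5 * (ll_f + ll_r) / std::log(2.0);
    if (fixed_p < 0.0 && scores[w] < 0.0) scores[w] = 0.0;
  }
  return scores;
}

// Plain (linear-space) parse likelihood of a short sequence at fixed p,
// for cross-checking the DP against brute-force parse enumeration.
// [[Rcpp::export]]
double cpp_parse_likelihood(IntegerVector seq, NumericMatrix theta,
                            List bg_tables, int bg_order, double p) {
  int L = seq.size();
  int W = theta.nrow();
  std::vector<const double*> tables = table_ptrs(bg_tables);
  std::vector<double> b(L > 0 ? L : 1), odds(L > 0 ? L : 1), Rf(L + 1);
  const int* x = INTEGER(seq);
  if (L == 0) return 1.0;
  background_probs(x, L, bg_order, tables, b);
  block_odds(x, L, theta, b, odds);
  double lr = forward_odds(L, W, p, odds, Rf);
  double bgl = 1.0;
  for (int i = 0; i < L; ++i) bgl *= b[i];
  return lr * bgl;
}
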