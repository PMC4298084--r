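// Assembly-prior internals.
//
// Generative process behind the contig length prior ("bag of contigs"):
//   1. a parent transcript length m ~ NB(size, prob), truncated at max_len;
//   2. at each of the n = m - L + 1 valid start positions, Poisson(lambda)
//      reads start independently, so a position is occupied with
//      q = 1 - exp(-lambda);
//   3. contigs are maximal chains of occupied positions whose successive
//      reads overlap by >= w bases, i.e. successive occupied positions at
//      most G = L - w apart; a chain spanning d positions yields a contig
//      of length d + L.
// P(ell | lambda) is the expected frequency of contig length ell in the bag.
//
// Key quantity: g(d) = P(interior occupancy pattern bridges two occupied
// positions d apart with all successive gaps <= G). Recurrence (first
// occupied interior position at offset j):
//   g(0) = 1;  g(d) = [d <= G] u^{d-1} (1-q... see below) summed form:
//   g(d) = q * W(d) + [d <= G] u^d,   W(d) = sum_{j=1}^{min(G,d)} u^{j-1} g(d-j)
// with u = 1 - q, maintained in O(1) per step:
//   W(d+1) = g(d) + u W(d) - [d >= G] u^G g(d-G).
//
// Expected number of maximal chains spanning d in an array of K = n - d
// candidate anchor positions:
//   E_d(n) = c(d) * S(K),  c(0) = q, c(d) = q^2 g(d),
//   S(K) = sum_{a=0}^{K-1} v_a v_{K-1-a},  v_a = u^{min(G,a)}
// (v terms are the no-occupied-position-within-G boundary clearances).
// S(K) is computed directly for K <= 2G and via the closed form
//   S(K) = 2 u^G (1-u^G)/(1-u) + (K-2G) u^{2G}   for K > 2G,
// which makes the NB marginalisation over transcript lengths O(G) per
// contig span using suffix sums of the NB weights.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// g(d) for d = 0..dmax, optionally with running rescaling to avoid
// underflow; logscale[d] holds the log of the factor taken out of g[d].
static void chain_bridge_probs(double q, int G, int dmax,
                               std::vector<double>& g,
                               std::vector<double>& logscale) {
  const double u = 1.0 - q;
  g.assign(dmax + 1, 0.0);
  logscale.assign(dmax + 1, 0.0);
  g[0] = 1.0;
  if (dmax == 0) return;
  double W = 0.0;          // W(d) on the current scale
  double Wscale = 0.0;     // log factor taken out of W
  double u_pow_d = 1.0;    // u^d (no rescale needed: only used for d <= G)
  double uG = std::pow(u, G);
  for (int d = 1; d <= dmax; ++d) {
    // W(d) = g(d-1) + u W(d-1) - [d-1 >= G] u^G g(d-1-G)
    // all g's must be brought onto W's scale
    if (d == 1) {
      W = g[0]; Wscale = logscale[0];
    } else {
      double add = g[d - 1] * std::exp(logscale[d - 1] - Wscale);
      double sub = (d - 1 >= G)
        ? uG * g[d - 1 - G] * std::exp(logscale[d - 1 - G] - Wscale) : 0.0;
      W = add + u * W - sub;
      if (W < 0) W = 0;  // numerical guard
    }
    if (d <= G) u_pow_d *= u;
    double val = q * W;
    double vscale = Wscale;
    if (d <= G) {
      // add u^d on scale 0
      val += u_pow_d * std::exp(-Wscale);
    }
    g[d] = val;
    logscale[d] = vscale;
    // renormalise W and g[d] jointly when they get small
    if (g[d] > 0 && g[d] < 1e-200) {
      double f = std::log(g[d]);
      logscale[d] += f;
      g[d] = 1.0;
      // W keeps its own scale; nothing else to do
    }
    if (W > 0 && W < 1e-200) {
      Wscale += std::log(W);
      W = 1.0;
    }
    if (W > 1e200) {
      Wscale += std::log(W);
      W = 1.0;
    }
  }
}

// log P(a contig of length ell is fully covered by reads with successive
// overlaps >= w), under Poisson(lambda) starts at each of the
// n = ell - L + 1 valid positions: requires position 1 and position n
// occupied and all gaps <= G, i.e. q^2 g(n-1) (or q when n = 1).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_coverage_logprob(NumericVector ell, NumericVector lambda,
                                         int L, int w) {
  const int G = L - w;
  if (G < 1) stop("coverage: w must be < L");
  const int n_out = ell.size();
  NumericVector out(n_out);
  for (int i = 0; i < n_out; ++i) {
    const int len = (int)ell[i];
    const double lam = lambda[i];
    if (len < L) { out[i] = R_NegInf; continue; }
    if (lam <= 0) { out[i] = R_NegInf; continue; }
    const double q = -std::expm1(-lam);
    const int n = len - L + 1;
    if (n == 1) { out[i] = std::log(q); continue; }
    std::vector<double> g, ls;
    chain_bridge_probs(q, G, n - 1, g, ls);
    if (g[n - 1] <= 0) { out[i] = R_NegInf; continue; }
    out[i] = 2.0 * std::log(q) + std::log(g[n - 1]) + ls[n - 1];
  }
  return out;
}

// Full bag-of-contigs length distribution for one lambda.
// Returns log P(ell | lambda) for ell = L .. L + n_max - 1 (n_max =
// max_len - L + 1), normalised over that support.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_length_prior_dist(double lambda, int L, int w,
                                          double nb_size, double nb_prob,
                                          int max_len) {
  const int G = L - w;
  if (G < 1) stop("length prior: w must be < L");
  if (lambda <= 0) stop("length prior: lambda must be > 0");
  const int n_max = max_len - L + 1;
  if (n_max < 1) stop("length prior: max_len must be >= L");
  const double q = -std::expm1(-lambda);
  const double u = 1.0 - q;

  // NB weights for array size n (transcript length m = n + L - 1) and
  // suffix sums sum_n nbw, sum_n n*nbw
  std::vector<double> nbw(n_max + 1, 0.0);
  for (int n = 1; n <= n_max; ++n)
    nbw[n] = R::dnbinom((double)(n + L - 1), nb_size, nb_prob, 0);
  std::vector<double> C0(n_max + 2, 0.0), C1(n_max + 2, 0.0);
  for (int n = n_max; n >= 1; --n) {
    C0[n] = C0[n + 1] + nbw[n];
    C1[n] = C1[n + 1] + (double)n * nbw[n];
  }

  // boundary-clearance autocorrelation S(K), exact for K <= 2G
  const double uG = std::pow(u, G);
  const int Kdir = std::min(2 * G, n_max);
  std::vector<double> v(std::min(n_max, 2 * G) + 1, 1.0);
  for (int a = 1; a < (int)v.size(); ++a)
    v[a] = (a <= G) ? v[a - 1] * u : uG;
  std::vector<double> Sdir(Kdir + 1, 0.0);
  for (int K = 1; K <= Kdir; ++K) {
    double s = 0.0;
    for (int a = 0; a < K; ++a) {
      const int b = K - 1 - a;
      const double va = (a >= G) ? uG : v[a];
      const double vb = (b >= G) ? uG : v[b];
      s += va * vb;
    }
    Sdir[K] = s;
  }
  // S(K) = alpha + beta*K for K > 2G
  const double beta = uG * uG;
  const double alpha = (u < 1.0)
    ? 2.0 * uG * (1.0 - uG) / (1.0 - u) - 2.0 * G * beta
    : 0.0;  // u == 1 means q == 0: no contigs at all (handled below)

  std::vector<double> g, ls;
  chain_bridge_probs(q, G, n_max - 1, g, ls);

  std::vector<double> logmass(n_max, R_NegInf);
  double mx = R_NegInf;
  for (int d = 0; d <= n_max - 1; ++d) {
    // T(d) = sum_{K=1}^{n_max-d} nbw(d+K) S(K)
    double T = 0.0;
    const int Kup = std::min(2 * G, n_max - d);
    for (int K = 1; K <= Kup; ++K) T += nbw[d + K] * Sdir[K];
    if (n_max - d > 2 * G) {
      const int from = d + 2 * G + 1;
      T += alpha * C0[from] + beta * (C1[from] - (double)d * C0[from]);
    }
    if (T <= 0) continue;
    double lc = (d == 0) ? std::log(q)
      : 2.0 * std::log(q) + std::log(g[d]) + ls[d];
    if (!R_FINITE(lc)) continue;
    logmass[d] = lc + std::log(T);
    if (logmass[d] > mx) mx = logmass[d];
  }
  if (!R_FINITE(mx)) stop("length prior: distribution has no mass");
  double Z = 0.0;
  for (int d = 0; d < n_max; ++d)
    if (R_FINITE(logmass[d])) Z += std::exp(logmass[d] - mx);
  const double logZ = mx + std::log(Z);
  NumericVector out(n_max);
  for (int d = 0; d < n_max; ++d) out[d] = logmass[d] - logZ;
  return out;
}

// log P(ell_i | lambda_i) for many contigs (each its own lambda).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_length_prior(NumericVector ell, NumericVector lambda,
                                     int L, int w, double nb_size,
                                     double nb_prob, int max_len) {
  const int n = ell.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (lambda[i] <= 0) stop("length prior: lambda must be > 0");
    const int len = (int)ell[i];
    if (len < L || len > max_len) { out[i] = R_NegInf; continue; }
    NumericVector dist = cpp_length_prior_dist(lambda[i], L, w, nb_size,
                                               nb_prob, max_len);
    out[i] = dist[len - L];
  }
  return out;
}

// ---- Monte-Carlo oracles (independent simulations of the stated
// generative processes; used by the test-suite to certify the DPs) ----

// Draw occupied positions on 1..n via geometric gaps; append spans of the
// maximal chains (gap <= G) to 'spans'.
static void sim_chains(int n, double q, int G, std::vector<int>& spans) {
  if (q <= 0.0) return;
  int pos = 1 + (int)R::rgeom(q);      // first occupied position
  if (pos > n) return;
  int first = pos, last = pos;
  while (true) {
    int nxt = pos + 1 + (int)R::rgeom(q);
    if (nxt > n) { spans.push_back(last - first); break; }
    if (nxt - last > G) {
      spans.push_back(last - first);
      first = nxt;
    }
    last = nxt;
    pos = nxt;
  }
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_mc_bag_lengths(int reps, double lambda, int L, int w,
                                       double nb_size, double nb_prob,
                                       int max_len) {
  const int G = L - w;
  const double q = -std::expm1(-lambda);
  std::vector<int> spans;
  spans.reserve(reps);
  for (int i = 0; i < reps; ++i) {
    int m = (int)R::rnbinom(nb_size, nb_prob);
    if (m > max_len) m = max_len;   // mirror the DP truncation
    const int n = m - L + 1;
    if (n < 1) continue;            // transcript too short to host a read
    sim_chains(n, q, G, spans);
  }
  IntegerVector out(spans.size());
  for (size_t i = 0; i < spans.size(); ++i) out[i] = spans[i] + L;
  return out;
}

// Fraction of simulations in which a contig of length ell is fully covered
// with successive overlaps >= w. Read starts are raw Poisson counts per
// position (not Bernoulli occupancy), keeping the oracle independent of
// the DP's occupancy reduction.
// [[Rcpp::export]]
double cpp_mc_coverage(int reps, int ell, int L, double lambda, int w) {
  const int G = L - w;
  const int n = ell - L + 1;
  if (n < 1) return 0.0;
  int ok = 0;
  for (int i = 0; i < reps; ++i) {
    int last = 0;
    bool fail = false;
    for (int pos = 1; pos <= n; ++pos) {
      if (R::rpois(lambda) > 0) {
        if (pos == 1) last = 1;
        else if (last == 0 || pos - last > G) { fail = true; break; }
        else last = pos;
      }
    }
    if (!fail && last == n) ++ok;
  }
  return (double)ok / (double)reps;
}
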