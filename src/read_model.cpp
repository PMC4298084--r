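// Read-model internals: exhaustive seeded ungapped alignment of fixed-length
// reads against contigs, noise-model log-likelihoods, and the EM fit of the
// mixture weights theta over {noise, contig_1..contig_M}.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

struct Hit {
  int contig;   // 1-based
  int start;    // 0-based on contig
  int strand;   // 0 = '+', 1 = '-'
  int mm;
  bool operator<(const Hit& o) const {
    if (contig != o.contig) return contig < o.contig;
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
  bool operator==(const Hit& o) const {
    return contig == o.contig && start == o.start && strand == o.strand;
  }
};

// count mismatches of read (length L) against contig window at 'start';
// contig 'N' counts as a mismatch; early exit beyond max_mm.
static inline int window_mm(const std::string& contig, int start,
                            const std::string& read, int max_mm) {
  int mm = 0;
  const int L = (int)read.size();
  for (int j = 0; j < L; ++j) {
    if (contig[start + j] != read[j]) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector contigs, CharacterVector reads,
                     int L, int max_mm, bool both_strands, int seed_len) {
  const int M = contigs.size();
  std::vector<std::string> ctg(M);
  for (int i = 0; i < M; ++i) ctg[i] = as<std::string>(contigs[i]);

  const int n_seeds = max_mm + 1;
  bool exhaustive = seed_len < 4 || (int64_t)seed_len * n_seeds > L;

  // seed index: packed seed -> positions (contig, offset)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  if (!exhaustive) {
    size_t total = 0;
    for (int i = 0; i < M; ++i)
      if ((int)ctg[i].size() >= seed_len) total += ctg[i].size();
    index.reserve(total * 2);
    for (int i = 0; i < M; ++i) {
      const std::string& s = ctg[i];
      const int n = (int)s.size();
      if (n < L) continue;  // cannot host any read
      uint64_t key = 0; int valid = 0;
      const uint64_t mask = (seed_len >= 32) ? ~0ULL
        : ((1ULL << (2 * seed_len)) - 1);
      for (int p = 0; p < n; ++p) {
        int c = base2code(s[p]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid >= seed_len)
          index[key].push_back({i, p - seed_len + 1});
      }
    }
  }

  std::vector<int> out_read, out_contig, out_start, out_strand, out_mm;
  int n_skipped = 0;
  const int NR = reads.size();
  std::vector<Hit> hits;
  hits.reserve(16);

  for (int r = 0; r < NR; ++r) {
    std::string rd = as<std::string>(reads[r]);
    if ((int)rd.size() != L)
      stop("align_reads: read %d has length %d, expected L = %d",
           r + 1, (int)rd.size(), L);
    bool hasN = false;
    for (char c : rd) if (base2code(c) < 0) { hasN = true; break; }
    if (hasN) { ++n_skipped; continue; }

    hits.clear();
    const int n_strands = both_strands ? 2 : 1;
    for (int st = 0; st < n_strands; ++st) {
      std::string q = (st == 0) ? rd : revcomp_str(rd);
      if (exhaustive) {
        for (int i = 0; i < M; ++i) {
          const int n = (int)ctg[i].size();
          for (int p = 0; p + L <= n; ++p) {
            int mm = window_mm(ctg[i], p, q, max_mm);
            if (mm <= max_mm) hits.push_back({i + 1, p, st, mm});
          }
        }
      } else {
        for (int k = 0; k < n_seeds; ++k) {
          const int off = k * seed_len;
          uint64_t key = 0;
          for (int j = 0; j < seed_len; ++j)
            key = (key << 2) | (uint64_t)base2code(q[off + j]);
          auto it = index.find(key);
          if (it == index.end()) continue;
          for (auto& cp : it->second) {
            const int i = cp.first;
            const int start = cp.second - off;
            if (start < 0 || start + L > (int)ctg[i].size()) continue;
            Hit h{i + 1, start, st, 0};
            bool dup = false;
            for (auto& e : hits)
              if (e == h) { dup = true; break; }
            if (dup) continue;
            int mm = window_mm(ctg[i], start, q, max_mm);
            if (mm <= max_mm) hits.push_back({i + 1, start, st, mm});
          }
        }
      }
    }
    std::sort(hits.begin(), hits.end());
    hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
    for (auto& h : hits) {
      out_read.push_back(r + 1);
      out_contig.push_back(h.contig);
      out_start.push_back(h.start);
      out_strand.push_back(h.strand);
      out_mm.push_back(h.mm);
    }
  }

  return List::create(_["read"] = wrap(out_read),
                      _["contig"] = wrap(out_contig),
                      _["start"] = wrap(out_start),
                      _["strand"] = wrap(out_strand),
                      _["mm"] = wrap(out_mm),
                      _["n_skipped"] = n_skipped);
}

// [[Rcpp::export]]
NumericVector cpp_noise_loglik(CharacterVector reads, NumericVector bg) {
  const int NR = reads.size();
  NumericVector out(NR);
  double lbg[4];
  for (int i = 0; i < 4; ++i) lbg[i] = std::log(bg[i]);
  const double lN = std::log(0.25);  // unknown base: uniform
  for (int r = 0; r < NR; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    double ll = 0.0;
    for (; *s; ++s) {
      int c = base2code(*s);
      ll += (c >= 0) ? lbg[c] : lN;
    }
    out[r] = ll;
  }
  return out;
}

// EM over mixture weights. Rows must be sorted by read; every read in
// 1..n_reads must have at least one row (the noise pseudo-alignment
// guarantees this). comp is in 0..M (0 = noise).
// [[Rcpp::export]]
List cpp_em(IntegerVector read, IntegerVector comp, NumericVector logp,
            int n_reads, int M, double tol, int max_iter) {
  const int A = read.size();
  if (A == 0) stop("em: no alignments");
  // per-read row ranges and scaling constants
  std::vector<int> row_start(n_reads + 1, -1);
  std::vector<double> maxlog(n_reads, R_NegInf);
  for (int a = 0; a < A; ++a) {
    int r = read[a] - 1;
    if (r < 0 || r >= n_reads) stop("em: read index out of range");
    if (row_start[r] < 0) row_start[r] = a;
    if (a > 0 && read[a] < read[a - 1]) stop("em: rows must be sorted by read");
    if (logp[a] > maxlog[r]) maxlog[r] = logp[a];
  }
  row_start[n_reads] = A;
  for (int r = n_reads - 1; r >= 0; --r)
    if (row_start[r] < 0)
      stop("em: read %d has no alignments (not even noise)", r + 1);

  std::vector<double> p(A);
  for (int a = 0; a < A; ++a)
    p[a] = std::exp(logp[a] - maxlog[read[a] - 1]);

  std::vector<double> theta(M + 1, 1.0 / (M + 1)), cnt(M + 1);
  std::vector<double> trace;
  double ll = R_NegInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double new_ll = 0.0;
    for (int r = 0; r < n_reads; ++r) {
      double denom = 0.0;
      for (int a = row_start[r]; a < row_start[r + 1]; ++a)
        denom += theta[comp[a]] * p[a];
      if (denom <= 0.0)
        stop("em: read %d has zero total probability", r + 1);
      for (int a = row_start[r]; a < row_start[r + 1]; ++a)
        cnt[comp[a]] += theta[comp[a]] * p[a] / denom;
      new_ll += std::log(denom) + maxlog[r];
    }
    trace.push_back(new_ll);
    for (int i = 0; i <= M; ++i) theta[i] = cnt[i] / n_reads;
    bool done = (it > 0) &&
      (std::fabs(new_ll - ll) <= tol * std::fabs(new_ll));
    ll = new_ll;
    if (done) break;
  }

  // final log-likelihood and posteriors under the returned theta
  NumericVector gamma(A);
  double final_ll = 0.0;
  for (int r = 0; r < n_reads; ++r) {
    double denom = 0.0;
    for (int a = row_start[r]; a < row_start[r + 1]; ++a)
      denom += theta[comp[a]] * p[a];
    if (denom <= 0.0) stop("em: read %d has zero total probability", r + 1);
    for (int a = row_start[r]; a < row_start[r + 1]; ++a)
      gamma[a] = theta[comp[a]] * p[a] / denom;
    final_ll += std::log(denom) + maxlog[r];
  }
  trace.push_back(final_ll);

  return List::create(_["theta"] = wrap(theta), _["loglik"] = final_ll,
                      _["iterations"] = it + 1, _["trace"] = wrap(trace),
                      _["gamma"] = gamma);
}

// Posterior alignment probabilities under fixed theta.
// [[Rcpp::export]]
NumericVector cpp_posteriors(IntegerVector read, IntegerVector comp,
                             NumericVector logp, NumericVector theta,
                             int n_reads) {
  const int A = read.size();
  NumericVector out(A);
  int a = 0;
  while (a < A) {
    int r = read[a];
    int b = a;
    double mx = R_NegInf;
    while (b < A && read[b] == r) { mx = std::max(mx, logp[b]); ++b; }
    double denom = 0.0;
    for (int j = a; j < b; ++j)
      denom += theta[comp[j]] * std::exp(logp[j] - mx);
    if (denom <= 0.0) stop("posteriors: read %d has zero probability", r);
    for (int j = a; j < b; ++j)
      out[j] = theta[comp[j]] * std::exp(logp[j] - mx) / denom;
    a = b;
  }
  return out;
}

// Per-read log of the full mixture likelihood sum_j theta_j P(read|aln_j),
// under fixed theta. Rows must be sorted by read.
// [[Rcpp::export]]
NumericVector cpp_read_logdenom(IntegerVector read, IntegerVector comp,
                                NumericVector logp, NumericVector theta,
                                int n_reads) {
  const int A = read.size();
  NumericVector out(n_reads, R_NegInf);
  int a = 0;
  while (a < A) {
    int r = read[a];
    int b = a;
    double mx = R_NegInf;
    while (b < A && read[b] == r) { mx = std::max(mx, logp[b]); ++b; }
    double denom = 0.0;
    for (int j = a; j < b; ++j)
      denom += theta[comp[j]] * std::exp(logp[j] - mx);
    out[r - 1] = std::log(denom) + mx;
    a = b;
  }
  return out;
}
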