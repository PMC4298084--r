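// Reference-based measure internals: a seed-and-extend local aligner
// (exact k-mer seeds, collinear chaining with small-gap stitching, X-drop
// ungapped end extension) and the abundance-weighted k-mer recall.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int b2c(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}
static inline char cb(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
  case 'T': return 'A'; default: return 'N';
  }
}
static std::string rc(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = cb(c);
  return r;
}

struct Run { int q, t, len; };       // exact-match run (0-based starts)
struct Chain {
  std::vector<Run> runs;
  int qend, tend;                    // half-open ends of last run
};

struct Aln {
  int q_id, t_id, strand;            // strand 0='+',1='-'
  int q_start, q_end, t_start, t_end; // on the aligned (possibly RC) query
  int matches, mismatches, indel;
  std::vector<int> t_match, q_match; // 0-based matched-identical positions
};

// stitch chains into alignments, counting matches per position
static void finalize_chain(const std::string& q, const std::string& t,
                           Chain& ch, int xdrop, Aln& out) {
  out.matches = 0; out.mismatches = 0; out.indel = 0;
  out.t_match.clear(); out.q_match.clear();
  std::vector<Run>& rs = ch.runs;
  // inter-run gap fill (left-aligned comparison of the shorter gap side)
  for (size_t i = 0; i + 1 < rs.size(); ++i) {
    int dq = rs[i + 1].q - (rs[i].q + rs[i].len);
    int dt = rs[i + 1].t - (rs[i].t + rs[i].len);
    int m = std::min(dq, dt);
    out.indel += std::abs(dq - dt);
    for (int j = 0; j < m; ++j) {
      char a = q[rs[i].q + rs[i].len + j], b = t[rs[i].t + rs[i].len + j];
      if (a == b && b2c(a) >= 0) {
        ++out.matches;
        out.q_match.push_back(rs[i].q + rs[i].len + j);
        out.t_match.push_back(rs[i].t + rs[i].len + j);
      } else ++out.mismatches;
    }
  }
  for (auto& r : rs) {
    out.matches += r.len;
    for (int j = 0; j < r.len; ++j) {
      out.q_match.push_back(r.q + j);
      out.t_match.push_back(r.t + j);
    }
  }
  // X-drop ungapped extension, +1 match / -3 mismatch
  int qs = rs.front().q, ts = rs.front().t;
  {
    int score = 0, best = 0, bq = qs;
    std::vector<std::pair<int,int>> picked, bestpick;
    int i = 1;
    while (qs - i >= 0 && ts - i >= 0) {
      char a = q[qs - i], b = t[ts - i];
      if (a == b && b2c(a) >= 0) { score += 1; picked.push_back({qs-i, ts-i}); }
      else score -= 3;
      if (score > best) { best = score; bq = qs - i; bestpick = picked; }
      if (score < best - xdrop) break;
      ++i;
    }
    for (auto& pr : bestpick) {
      ++out.matches; out.q_match.push_back(pr.first);
      out.t_match.push_back(pr.second);
    }
    out.mismatches += (qs - bq) - (int)bestpick.size();
    qs = bq; ts -= (rs.front().q - qs);
  }
  int qe = ch.qend, te = ch.tend;
  {
    int score = 0, best = 0, bq = qe;
    std::vector<std::pair<int,int>> picked, bestpick;
    int i = 0;
    while (qe + i < (int)q.size() && te + i < (int)t.size()) {
      char a = q[qe + i], b = t[te + i];
      if (a == b && b2c(a) >= 0) { score += 1; picked.push_back({qe+i, te+i}); }
      else score -= 3;
      if (score > best) { best = score; bq = qe + i + 1; bestpick = picked; }
      if (score < best - xdrop) break;
      ++i;
    }
    for (auto& pr : bestpick) {
      ++out.matches; out.q_match.push_back(pr.first);
      out.t_match.push_back(pr.second);
    }
    out.mismatches += (bq - qe) - (int)bestpick.size();
    qe = bq; te += (qe - ch.qend);
  }
  out.q_start = qs; out.q_end = qe; out.t_start = ts; out.t_end = te;
}

// [[Rcpp::export]]
List cpp_local_align(CharacterVector qseqs, CharacterVector tseqs,
                     int seed_k, int max_gap, int band, int xdrop,
                     int min_matches, bool both_strands) {
  const int NQ = qseqs.size(), NT = tseqs.size();
  std::vector<std::string> T(NT);
  for (int i = 0; i < NT; ++i) T[i] = as<std::string>(tseqs[i]);

  // index target k-mers
  const uint64_t mask = (seed_k >= 32) ? ~0ULL : ((1ULL << (2 * seed_k)) - 1);
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> idx;
  for (int t = 0; t < NT; ++t) {
    const std::string& s = T[t];
    uint64_t key = 0; int valid = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int c = b2c(s[p]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= seed_k) idx[key].push_back({t, p - seed_k + 1});
    }
  }

  std::vector<Aln> alns;
  for (int qi = 0; qi < NQ; ++qi) {
    std::string fwd = as<std::string>(qseqs[qi]);
    for (int st = 0; st < (both_strands ? 2 : 1); ++st) {
      std::string qs = (st == 0) ? fwd : rc(fwd);
      // hits per target: (diag, qpos, tpos)
      std::unordered_map<int, std::vector<std::array<long long,3>>> per_t;
      uint64_t key = 0; int valid = 0;
      for (int p = 0; p < (int)qs.size(); ++p) {
        int c = b2c(qs[p]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid >= seed_k) {
          auto it = idx.find(key);
          if (it == idx.end()) continue;
          int qpos = p - seed_k + 1;
          for (auto& tp : it->second)
            per_t[tp.first].push_back(
              {(long long)qpos - tp.second, qpos, tp.second});
        }
      }
      for (auto& kv : per_t) {
        auto& hits = kv.second;
        std::sort(hits.begin(), hits.end());
        // merge same-diagonal overlapping seeds into exact runs
        std::vector<Run> runs;
        for (size_t i = 0; i < hits.size(); ) {
          long long diag = hits[i][0];
          int q0 = (int)hits[i][1], t0 = (int)hits[i][2];
          int qe = q0 + seed_k;
          size_t j = i + 1;
          while (j < hits.size() && hits[j][0] == diag &&
                 (int)hits[j][1] <= qe) {
            qe = std::max(qe, (int)hits[j][1] + seed_k);
            ++j;
          }
          runs.push_back({q0, t0, qe - q0});
          i = j;
        }
        std::sort(runs.begin(), runs.end(),
                  [](const Run& a, const Run& b) {
                    return a.q != b.q ? a.q < b.q : a.t < b.t; });
        // greedy collinear chaining
        std::vector<Chain> chains;
        for (auto r : runs) {
          int bestc = -1; long long bestgap = -1;
          for (int c = (int)chains.size() - 1; c >= 0; --c) {
            Chain& ch = chains[c];
            int dq = r.q - ch.qend, dt = r.t - ch.tend;
            long long d0 = (long long)(ch.qend - ch.tend);
            long long dd = std::llabs(((long long)r.q - r.t) - d0);
            if (dd > band) continue;
            int trim = std::max(0, -std::min(dq, dt));
            if (trim >= r.len) continue;
            if (dq + trim < 0 || dt + trim < 0) continue;
            if (dq > max_gap || dt > max_gap) continue;
            long long gap = std::max(dq, 0) + std::max(dt, 0);
            if (bestc < 0 || gap < bestgap) { bestc = c; bestgap = gap; }
          }
          if (bestc < 0) {
            Chain ch; ch.runs.push_back(r);
            ch.qend = r.q + r.len; ch.tend = r.t + r.len;
            chains.push_back(ch);
          } else {
            Chain& ch = chains[bestc];
            int trim = std::max(0, -std::min(r.q - ch.qend, r.t - ch.tend));
            r.q += trim; r.t += trim; r.len -= trim;
            ch.runs.push_back(r);
            ch.qend = r.q + r.len; ch.tend = r.t + r.len;
          }
        }
        for (auto& ch : chains) {
          Aln a; a.q_id = qi + 1; a.t_id = kv.first + 1; a.strand = st;
          finalize_chain(qs, T[kv.first], ch, xdrop, a);
          if (a.matches >= min_matches) alns.push_back(std::move(a));
        }
      }
    }
  }

  const int NA = (int)alns.size();
  IntegerVector q_id(NA), t_id(NA), q_start(NA), q_end(NA), t_start(NA),
    t_end(NA), matches(NA), mismatches(NA), indel(NA);
  CharacterVector strand(NA);
  List t_match(NA), q_match(NA);
  for (int i = 0; i < NA; ++i) {
    Aln& a = alns[i];
    q_id[i] = a.q_id; t_id[i] = a.t_id;
    strand[i] = (a.strand == 0) ? "+" : "-";
    const int qlen = (int)std::string(as<std::string>(qseqs[a.q_id - 1])).size();
    if (a.strand == 0) {
      q_start[i] = a.q_start; q_end[i] = a.q_end;
      IntegerVector qm(a.q_match.size());
      for (size_t j = 0; j < a.q_match.size(); ++j) qm[j] = a.q_match[j];
      q_match[i] = qm;
    } else {  // convert RC coords to forward-query coords
      q_start[i] = qlen - a.q_end; q_end[i] = qlen - a.q_start;
      IntegerVector qm(a.q_match.size());
      for (size_t j = 0; j < a.q_match.size(); ++j)
        qm[j] = qlen - 1 - a.q_match[j];
      q_match[i] = qm;
    }
    t_start[i] = a.t_start; t_end[i] = a.t_end;
    matches[i] = a.matches; mismatches[i] = a.mismatches; indel[i] = a.indel;
    IntegerVector tm(a.t_match.size());
    for (size_t j = 0; j < a.t_match.size(); ++j) tm[j] = a.t_match[j];
    t_match[i] = tm;
  }
  return List::create(
    _["q_id"] = q_id, _["t_id"] = t_id, _["strand"] = strand,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["t_start"] = t_start, _["t_end"] = t_end,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["indel_bases"] = indel,
    _["t_match_pos"] = t_match, _["q_match_pos"] = q_match);
}

// Abundance-weighted k-mer recall:
//   p(r) = sum_b n(r,b) tau(b) / sum_b n(b) tau(b)
//   WKR  = sum over the distinct k-mers r present in the assembly of p(r).
// [[Rcpp::export]]
List cpp_wkr(CharacterVector ref, NumericVector tau, CharacterVector asm_,
             int k, bool canonical) {
  std::unordered_map<std::string, double> p;
  double denom = 0.0;
  for (int b = 0; b < ref.size(); ++b) {
    const std::string s = as<std::string>(ref[b]);
    const double w = tau[b];
    if ((int)s.size() < k) continue;
    for (int i = 0; i + k <= (int)s.size(); ++i) {
      std::string km = s.substr(i, k);
      if (km.find_first_not_of("ACGT") != std::string::npos) continue;
      if (canonical) { std::string r2 = rc(km); if (r2 < km) km = r2; }
      p[km] += w;
      denom += w;
    }
  }
  if (denom <= 0.0) stop("kc: no reference k-mers (is k too large?)");
  std::unordered_set<std::string> seen;
  double wkr = 0.0;
  long long n_asm = 0;
  for (int a = 0; a < asm_.size(); ++a) {
    const std::string s = as<std::string>(asm_[a]);
    if ((int)s.size() < k) continue;
    for (int i = 0; i + k <= (int)s.size(); ++i) {
      std::string km = s.substr(i, k);
      if (km.find_first_not_of("ACGT") != std::string::npos) continue;
      if (canonical) { std::string r2 = rc(km); if (r2 < km) km = r2; }
      if (seen.insert(km).second) {
        ++n_asm;
        auto it = p.find(km);
        if (it != p.end()) wkr += it->second / denom;
      }
    }
  }
  return List::create(_["wkr"] = wkr, _["n_assembly_kmers"] = (double)n_asm);
}
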