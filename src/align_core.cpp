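// Seed-and-extend local alignment (HSP discovery) and 3' adapter trimming.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>
#include <set>

using namespace Rcpp;

static inline int b2b(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// 3' adapter trim: lowest-error occurrence of an adapter prefix at the read's
// 3' end (substitution errors only). Returns the kept read length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(CharacterVector seqs, std::string adapter,
                               int min_overlap, double max_err) {
  const int alen = (int)adapter.size();
  IntegerVector out(seqs.size());
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int n = (int)s.size();
    int best_off = -1;          // 0-based start of the adapter occurrence
    double best_frac = 1e9;
    for (int off = 0; off < n; ++off) {
      int m = std::min(n - off, alen);   // compared columns
      if (m < min_overlap) break;        // shorter suffixes only get shorter
      int err = 0;
      for (int i = 0; i < m; ++i)
        if (s[off + i] != adapter[i] &&
            toupper(s[off + i]) != toupper(adapter[i])) ++err;
      double frac = (double)err / m;
      if (frac <= max_err && frac < best_frac - 1e-12) {
        best_frac = frac;
        best_off = off;  // ties keep the earlier (longer) match
      }
    }
    out[r] = (best_off >= 0) ? best_off : n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// HSP discovery: exact seed matches on both strands, ungapped X-drop
// extension into diagonal cores, then banded gapped local alignment around
// each core group. Scoring: match/mismatch/gap are integer parameters
// (defaults +1/-2/-2), no E-values.
// ---------------------------------------------------------------------------

struct Core { long diag; int qs, qe; int score; };

struct RawHsp {
  int q_start, q_end, s_start, s_end;  // 0-based inclusive, strand-local query
  int score, matches, alen;
  int strand;                          // 0 = '+', 1 = '-'
};

// Ungapped X-drop extension of an exact seed [qs,qe] on diagonal d.
static Core ungapped_extend(const std::string& q, const std::string& s,
                            long d, int qs, int qe, int match, int mismatch,
                            int xdrop) {
  const int nq = (int)q.size(), ns = (int)s.size();
  int score = (qe - qs + 1) * match;
  int best = score, bl = qs, br = qe;
  // right
  int cur = score;
  for (int i = qe + 1; i < nq; ++i) {
    long j = d + i;
    if (j < 0 || j >= ns) break;
    cur += (q[i] == s[j]) ? match : -mismatch;
    if (cur > best) { best = cur; br = i; bl = bl; }
    if (best - cur > xdrop) break;
  }
  // left
  int base = best;
  cur = base;
  for (int i = qs - 1; i >= 0; --i) {
    long j = d + i;
    if (j < 0 || j >= ns) break;
    cur += (q[i] == s[j]) ? match : -mismatch;
    if (cur > best) { best = cur; bl = i; }
    if (best - cur > xdrop) break;
  }
  return Core{d, bl, br, best};
}

// Banded local alignment restricted to query rows [qlo,qhi] and the diagonal
// band d0 +/- band. Returns best local alignment by traceback.
static bool banded_local(const std::string& q, const std::string& s, long d0,
                         int band, int qlo, int qhi, int match, int mismatch,
                         int gap, RawHsp& out) {
  const int ns = (int)s.size();
  const int W = 2 * band + 1;
  const int R = qhi - qlo + 2;  // +1 rows, row 0 empty
  std::vector<int> dp((size_t)R * W, 0);
  std::vector<uint8_t> dir((size_t)R * W, 0);
  int best = 0, bi = 0, bo = 0;
  for (int r = 1; r < R; ++r) {
    int i = qlo + r - 1;  // 0-based query index consumed at this row
    for (int o = 0; o < W; ++o) {
      long j = d0 + i + (o - band);  // 0-based subject index consumed
      int v = 0; uint8_t d = 0;
      if (j >= 0 && j < ns) {
        int mm = (q[i] == s[j]) ? match : -mismatch;
        int fd = dp[(size_t)(r - 1) * W + o] + mm;
        if (fd > v) { v = fd; d = 1; }
        if (o + 1 < W) {
          int up = dp[(size_t)(r - 1) * W + (o + 1)] - gap;
          if (up > v) { v = up; d = 2; }
        }
        if (o > 0) {
          int lf = dp[(size_t)r * W + (o - 1)] - gap;
          if (lf > v) { v = lf; d = 3; }
        }
      }
      dp[(size_t)r * W + o] = v;
      dir[(size_t)r * W + o] = (v > 0) ? d : 0;
      if (v > best) { best = v; bi = r; bo = o; }
    }
  }
  if (best <= 0) return false;
  int r = bi, o = bo;
  int q_end = qlo + bi - 1, q_start = q_end;
  long s_end = d0 + q_end + (bo - band), s_start = s_end;
  int matches = 0, alen = 0;
  while (r > 0) {
    uint8_t d = dir[(size_t)r * W + o];
    if (d == 0) break;
    int i = qlo + r - 1;
    long j = d0 + i + (o - band);
    if (d == 1) {
      ++alen;
      if (q[i] == s[j]) ++matches;
      q_start = i; s_start = j;
      --r;
    } else if (d == 2) {
      ++alen; q_start = i; --r; ++o;
    } else {
      ++alen; s_start = j; --o;
    }
  }
  out.q_start = q_start; out.q_end = q_end;
  out.s_start = (int)s_start; out.s_end = (int)s_end;
  out.score = best; out.matches = matches; out.alen = alen;
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<int>> SeedIndex;

static void build_seed_index(const std::string& s, int seed_len,
                             SeedIndex& sidx) {
  const int ns = (int)s.size();
  uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  uint64_t val = 0; int run = 0;
  for (int j = 0; j < ns; ++j) {
    int b = b2b(s[j]);
    if (b < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)b) & mask;
    if (++run >= seed_len) sidx[val].push_back(j - seed_len + 1);
  }
}

static void find_strand_hsps(const std::string& q, const std::string& s,
                             const SeedIndex& sidx, int strand, int seed_len,
                             int match, int mismatch, int gap, int xdrop,
                             int band, std::vector<RawHsp>& out) {
  const int nq = (int)q.size(), ns = (int)s.size();
  if (nq < seed_len || ns < seed_len) return;
  uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  // seed hits grouped per diagonal
  std::vector<std::pair<long, int>> hits;  // (diag, qpos)
  {
    uint64_t val = 0; int run = 0;
    for (int i = 0; i < nq; ++i) {
      int b = b2b(q[i]);
      if (b < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)b) & mask;
      if (run++ >= seed_len - 1) {
        int qp = i - seed_len + 1;
        auto it = sidx.find(val);
        if (it != sidx.end())
          for (int sp : it->second) hits.push_back({(long)sp - qp, qp});
      }
    }
  }
  if (hits.empty()) return;
  std::sort(hits.begin(), hits.end());
  // ungapped cores per diagonal
  std::vector<Core> cores;
  size_t h = 0;
  while (h < hits.size()) {
    long d = hits[h].first;
    int cover_end = -1;
    while (h < hits.size() && hits[h].first == d) {
      int qp = hits[h].second;
      if (qp > cover_end) {
        Core c = ungapped_extend(q, s, d, qp, qp + seed_len - 1, match,
                                 mismatch, xdrop);
        cores.push_back(c);
        cover_end = c.qe;
      }
      ++h;
    }
  }
  // gapped extension per core group, strongest first
  std::vector<int> ord(cores.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (cores[a].score != cores[b].score) return cores[a].score > cores[b].score;
    if (cores[a].diag != cores[b].diag) return cores[a].diag < cores[b].diag;
    return cores[a].qs < cores[b].qs;
  });
  std::vector<char> used(cores.size(), 0);
  // wide enough to pick up unseeded short match islands beyond the cores
  const int margin = 2 * xdrop + band;
  for (int oi : ord) {
    if (used[oi]) continue;
    const Core& c0 = cores[oi];
    // group: cores within the band of c0's diagonal, chained by query range
    int wlo = c0.qs, whi = c0.qe;
    bool grew = true;
    std::vector<int> group{oi};
    std::vector<char> ingrp(cores.size(), 0);
    ingrp[oi] = 1;
    while (grew) {
      grew = false;
      for (size_t ci = 0; ci < cores.size(); ++ci) {
        if (ingrp[ci] || used[ci]) continue;
        if (std::labs(cores[ci].diag - c0.diag) > band) continue;
        if (cores[ci].qs > whi + 2 * xdrop || cores[ci].qe < wlo - 2 * xdrop)
          continue;
        ingrp[ci] = 1; group.push_back((int)ci);
        wlo = std::min(wlo, cores[ci].qs);
        whi = std::max(whi, cores[ci].qe);
        grew = true;
      }
    }
    int qlo = std::max(0, wlo - margin);
    int qhi = std::min(nq - 1, whi + margin);
    RawHsp hsp;
    if (banded_local(q, s, c0.diag, band, qlo, qhi, match, mismatch, gap,
                     hsp)) {
      hsp.strand = strand;
      out.push_back(hsp);
      // consume cores explained by this alignment
      for (size_t ci = 0; ci < cores.size(); ++ci) {
        if (used[ci]) continue;
        if (std::labs(cores[ci].diag - c0.diag) <= band &&
            cores[ci].qs >= hsp.q_start && cores[ci].qe <= hsp.q_end)
          used[ci] = 1;
      }
    }
    for (int gi : group) used[gi] = 1;
  }
}

static List hsps_for_query(const std::string& query,
                           const std::string& subject, const SeedIndex& sidx,
                           int seed_len, int match, int mismatch, int gap,
                           int xdrop, int min_len, double min_identity,
                           int band) {
  std::vector<RawHsp> raw;
  find_strand_hsps(query, subject, sidx, 0, seed_len, match, mismatch, gap,
                   xdrop, band, raw);
  std::string qrc = rc_str(query);
  find_strand_hsps(qrc, subject, sidx, 1, seed_len, match, mismatch, gap,
                   xdrop, band, raw);
  const int nq = (int)query.size();
  // filter, convert to 1-based query coordinates on the original strand
  struct Fin { int qs, qe, ss, se, score, alen; double ident; int strand; };
  std::vector<Fin> fin;
  std::set<std::tuple<int,int,int,int,int>> seen;
  for (const RawHsp& h : raw) {
    if (h.alen < min_len) continue;
    double ident = h.alen > 0 ? (double)h.matches / h.alen : 0.0;
    if (ident < min_identity) continue;
    int qs, qe;
    if (h.strand == 0) { qs = h.q_start + 1; qe = h.q_end + 1; }
    else { qs = nq - h.q_end; qe = nq - h.q_start; }
    auto key = std::make_tuple(qs, qe, h.s_start, h.s_end, h.strand);
    if (seen.count(key)) continue;
    seen.insert(key);
    fin.push_back({qs, qe, h.s_start + 1, h.s_end + 1, h.score, h.alen, ident,
                   h.strand});
  }
  std::sort(fin.begin(), fin.end(), [](const Fin& a, const Fin& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.qs < b.qs;
  });
  const int n = (int)fin.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), score(n), alen(n);
  NumericVector ident(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = fin[i].qs; qe[i] = fin[i].qe;
    ss[i] = fin[i].ss; se[i] = fin[i].se;
    score[i] = fin[i].score; alen[i] = fin[i].alen;
    ident[i] = fin[i].ident;
    strand[i] = fin[i].strand == 0 ? "+" : "-";
  }
  return List::create(_["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss,
                      _["s_end"] = se, _["strand"] = strand, _["score"] = score,
                      _["length"] = alen, _["identity"] = ident);
}

// [[Rcpp::export]]
List cpp_find_hsps(std::string query, std::string subject, int seed_len,
                   int match, int mismatch, int gap, int xdrop, int min_len,
                   double min_identity, int band) {
  SeedIndex sidx;
  build_seed_index(subject, seed_len, sidx);
  return hsps_for_query(query, subject, sidx, seed_len, match, mismatch, gap,
                        xdrop, min_len, min_identity, band);
}

// Batch variant: the subject seed index is built once for all queries.
// [[Rcpp::export]]
List cpp_find_hsps_multi(CharacterVector queries, std::string subject,
                         int seed_len, int match, int mismatch, int gap,
                         int xdrop, int min_len, double min_identity,
                         int band) {
  SeedIndex sidx;
  build_seed_index(subject, seed_len, sidx);
  List out(queries.size());
  for (int i = 0; i < queries.size(); ++i)
    out[i] = hsps_for_query(as<std::string>(queries[i]), subject, sidx,
                            seed_len, match, mismatch, gap, xdrop, min_len,
                            min_identity, band);
  return out;
}
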