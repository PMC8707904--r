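// Core k-mer machinery: 2-bit encoding, canonical k-mer index, seed-and-verify
// read mapping, cassette k-mer screening, solid-k-mer counting and unitig
// assembly. k is capped at 31 so a k-mer fits one 64-bit word.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (x & 3));
    x >>= 2;
  }
  return r;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break;
    }
  }
  return r;
}

// Enumerate (position, forward k-mer value) pairs of a sequence, skipping
// k-mers containing non-ACGT characters. Positions are 0-based.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F fun) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t val = 0;
  int run = 0;  // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)b) & mask;
    if (++run >= k) fun(i - k + 1, val);
  }
}

// ---------------------------------------------------------------------------
// Canonical k-mer index of a genome
// ---------------------------------------------------------------------------

struct KIndex {
  // canonical k-mer -> packed entries: (pos << 1) | orient
  // orient = 0 when the forward genome k-mer equals the canonical form.
  std::unordered_map<uint64_t, std::vector<uint32_t>> map;
  int k;
  int L;          // genome length (wrap k-mers use positions > L - k)
  bool circular;
};

static void build_index(KIndex& idx, const std::string& genome, int k,
                        bool circular) {
  idx.k = k;
  idx.L = (int)genome.size();
  idx.circular = circular;
  std::string s = genome;
  if (circular && idx.L > k) s += genome.substr(0, (size_t)(k - 1));
  for_each_kmer(s, k, [&](int pos, uint64_t fwd) {
    if (pos >= idx.L) return;  // wrap copies of the start
    uint64_t rc = revcomp_kmer(fwd, k);
    uint64_t canon = std::min(fwd, rc);
    uint32_t orient = (fwd == canon) ? 0u : 1u;
    idx.map[canon].push_back(((uint32_t)pos << 1) | orient);
  });
}

// [[Rcpp::export]]
List cpp_index_query(std::string genome, int k, bool circular,
                     CharacterVector kmers) {
  KIndex idx;
  build_index(idx, genome, k, circular);
  List out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string q = as<std::string>(kmers[i]);
    std::vector<int> pos;
    if ((int)q.size() == k) {
      uint64_t val = 0; bool ok = true;
      for (char c : q) {
        int b = base2bit(c);
        if (b < 0) { ok = false; break; }
        val = (val << 2) | (uint64_t)b;
      }
      if (ok) {
        uint64_t canon = std::min(val, revcomp_kmer(val, k));
        auto it = idx.map.find(canon);
        if (it != idx.map.end())
          for (uint32_t e : it->second) pos.push_back((int)(e >> 1) + 1);
      }
    }
    std::sort(pos.begin(), pos.end());
    out[i] = wrap(pos);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded local alignment (match +1, mismatch -1, gap -1, floor 0) used to
// verify a candidate diagonal. Returns identity over aligned columns and the
// fraction of the read covered by the optimal local alignment.
// ---------------------------------------------------------------------------

struct VerifyResult {
  bool ok;
  double identity, coverage;
  int s_start;  // 0-based subject coordinate of alignment start
};

static inline char subject_at(const std::string& g, long j, bool circular) {
  long L = (long)g.size();
  if (j >= 0 && j < L) return g[j];
  if (circular) {
    long m = j % L; if (m < 0) m += L;
    return g[m];
  }
  return '\0';  // out of range on a linear genome
}

static VerifyResult banded_verify(const std::string& read,
                                  const std::string& genome, long diag,
                                  int band, bool circular) {
  const int n = (int)read.size();
  const int W = 2 * band + 1;
  // dp[i][o] = best local score of alignment ending at read i (1-based rows)
  // and subject j = diag + (i-1) + (o-band) consumed last.
  std::vector<int16_t> dp((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> dir((size_t)(n + 1) * W, 0);  // 0 stop,1 diag,2 up,3 left
  int best = 0, bi = 0, bo = 0;
  for (int i = 1; i <= n; ++i) {
    for (int o = 0; o < W; ++o) {
      long j = diag + (i - 1) + (o - band);  // subject index consumed (0-based)
      char sc = subject_at(genome, j, circular);
      int v = 0; uint8_t d = 0;
      if (sc != '\0') {
        int mm = (sc == read[i - 1]) ? 1 : -1;
        // cell (i,o) holds subject index j; (i-1,o) holds j-1 (diagonal move)
        int fromdiag = dp[(size_t)(i - 1) * W + o] + mm;
        if (fromdiag > v) { v = fromdiag; d = 1; }
        if (o + 1 < W) {  // gap in subject: consume read base, j unchanged
          int up = dp[(size_t)(i - 1) * W + (o + 1)] - 1;
          if (up > v) { v = up; d = 2; }
        }
        if (o > 0) {  // gap in read: consume subject base only
          int left = dp[(size_t)i * W + (o - 1)] - 1;
          if (left > v) { v = left; d = 3; }
        }
      }
      dp[(size_t)i * W + o] = (int16_t)v;
      dir[(size_t)i * W + o] = (v > 0) ? d : 0;
      if (v > best) { best = v; bi = i; bo = o; }
    }
  }
  VerifyResult res{false, 0.0, 0.0, 0};
  if (best <= 0) return res;
  // traceback
  int i = bi, o = bo;
  int matches = 0, alen = 0;
  int q_end = bi, q_start = bi;
  long s_end = diag + (bi - 1) + (bo - band), s_start = s_end;
  while (i > 0) {
    uint8_t d = dir[(size_t)i * W + o];
    if (d == 0) break;
    long j = diag + (i - 1) + (o - band);
    if (d == 1) {
      ++alen;
      if (subject_at(genome, j, circular) == read[i - 1]) ++matches;
      q_start = i; s_start = j;
      --i;
    } else if (d == 2) {          // gap in subject: step back in read only
      ++alen; q_start = i; --i; ++o;
    } else {                      // gap in read: step back in subject only
      ++alen; s_start = j; --o;
    }
  }
  res.ok = true;
  res.identity = alen > 0 ? (double)matches / alen : 0.0;
  res.coverage = (double)(q_end - q_start + 1) / n;
  long L = (long)genome.size();
  long ss = s_start;
  if (circular) { ss %= L; if (ss < 0) ss += L; }
  res.s_start = (int)ss;
  return res;
}

// ---------------------------------------------------------------------------
// Read mapping: vote on (strand, diagonal) with canonical seed hits, verify
// the best diagonal by banded local alignment.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string genome, int k,
                   bool circular, double min_identity, double min_cov,
                   int band, int max_hits_per_kmer = 100) {
  KIndex idx;
  build_index(idx, genome, k, circular);
  const int nr = reads.size();
  IntegerVector status(nr), pos(nr);
  CharacterVector strand(nr);
  NumericVector identity(nr);

  std::vector<std::pair<long, int>> votes;  // (diag, strand 0/1)
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int n = (int)rd.size();
    votes.clear();
    if (n >= k) {
      for_each_kmer(rd, k, [&](int i, uint64_t fwd) {
        uint64_t rc = revcomp_kmer(fwd, k);
        uint64_t canon = std::min(fwd, rc);
        int orient_r = (fwd == canon) ? 0 : 1;
        auto it = idx.map.find(canon);
        if (it == idx.map.end()) return;
        if ((int)it->second.size() > max_hits_per_kmer) return;
        for (uint32_t e : it->second) {
          int p = (int)(e >> 1);
          int orient_g = (int)(e & 1);
          int str = orient_g ^ orient_r;  // 0 = forward, 1 = reverse
          long diag = (str == 0) ? (long)p - i : (long)p - (n - k - i);
          votes.push_back({diag * 2 + str, 0});
        }
      });
    }
    bool mapped = false;
    if (!votes.empty()) {
      std::sort(votes.begin(), votes.end());
      // best-supported (diagonal, strand); ties to the leftmost diagonal,
      // forward strand first (encoded ordering gives exactly that)
      long bestkey = votes[0].first; int bestcnt = 1;
      long curkey = votes[0].first; int curcnt = 1;
      for (size_t i = 1; i < votes.size(); ++i) {
        if (votes[i].first == curkey) ++curcnt;
        else { curkey = votes[i].first; curcnt = 1; }
        if (curcnt > bestcnt) { bestcnt = curcnt; bestkey = curkey; }
      }
      int str = (int)(((bestkey % 2) + 2) % 2);
      long diag = (bestkey - str) / 2;
      std::string q = (str == 0) ? rd : revcomp_str(rd);
      // fast path: a gapless scan of the voted diagonal; if identity over
      // the whole read already clears the threshold the banded alignment
      // can only agree (it may trim mismatched ends, never lower identity)
      {
        int mm = 0; bool inrange = true;
        for (int i = 0; i < n; ++i) {
          char sc = subject_at(genome, diag + i, circular);
          if (sc == '\0') { inrange = false; break; }
          if (sc != q[i]) ++mm;
        }
        if (inrange && (double)(n - mm) / n >= min_identity) {
          mapped = true;
          status[r] = 1;
          long L = (long)genome.size();
          long ss = diag;
          if (circular) { ss %= L; if (ss < 0) ss += L; }
          pos[r] = (int)ss + 1;
          strand[r] = (str == 0) ? "+" : "-";
          identity[r] = (double)(n - mm) / n;
        }
      }
      if (!mapped) {
        VerifyResult v = banded_verify(q, genome, diag, band, circular);
        if (v.ok && v.identity >= min_identity && v.coverage >= min_cov) {
          mapped = true;
          status[r] = 1;
          pos[r] = v.s_start + 1;
          strand[r] = (str == 0) ? "+" : "-";
          identity[r] = v.identity;
        }
      }
    }
    if (!mapped) {
      status[r] = 0; pos[r] = NA_INTEGER;
      strand[r] = NA_STRING; identity[r] = NA_REAL;
    }
  }
  return List::create(_["mapped"] = status, _["ref_pos"] = pos,
                      _["strand"] = strand, _["identity"] = identity);
}

// ---------------------------------------------------------------------------
// Cassette k-mer screen: number of read k-mer positions whose canonical
// k-mer occurs in the cassette.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_screen_counts(CharacterVector reads, std::string cassette,
                                int k) {
  std::unordered_set<uint64_t> cas;
  for_each_kmer(cassette, k, [&](int, uint64_t fwd) {
    cas.insert(std::min(fwd, revcomp_kmer(fwd, k)));
  });
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int cnt = 0;
    for_each_kmer(rd, k, [&](int, uint64_t fwd) {
      if (cas.count(std::min(fwd, revcomp_kmer(fwd, k)))) ++cnt;
    });
    out[r] = cnt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Solid-k-mer counting for k selection
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_solid_counts(CharacterVector reads, IntegerVector ks,
                               int min_abund) {
  IntegerVector out(ks.size());
  for (int ki = 0; ki < ks.size(); ++ki) {
    int k = ks[ki];
    std::unordered_map<uint64_t, int> counts;
    for (int r = 0; r < reads.size(); ++r) {
      std::string rd = as<std::string>(reads[r]);
      for_each_kmer(rd, k, [&](int, uint64_t fwd) {
        ++counts[std::min(fwd, revcomp_kmer(fwd, k))];
      });
    }
    int solid = 0;
    for (auto& kv : counts) if (kv.second >= min_abund) ++solid;
    out[ki] = solid;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Unitig assembly on the bidirected De Bruijn graph of solid canonical k-mers
// ---------------------------------------------------------------------------

struct DBG {
  int k;
  uint64_t mask;
  std::vector<uint64_t> kmers;   // sorted canonical solid k-mers
  std::vector<int> abund;
  std::unordered_map<uint64_t, int> id;

  int find(uint64_t canon) const {
    auto it = id.find(canon);
    return it == id.end() ? -1 : it->second;
  }
  // successors of oriented k-mer f; returns out-degree, stores one successor
  int succ(uint64_t f, uint64_t& out) const {
    int deg = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t nf = ((f << 2) | b) & mask;
      uint64_t canon = std::min(nf, revcomp_kmer(nf, k));
      if (find(canon) >= 0) { ++deg; out = nf; }
    }
    return deg;
  }
  int pred(uint64_t f, uint64_t& out) const {
    int deg = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t pf = (f >> 2) | (b << (2 * (k - 1)));
      uint64_t canon = std::min(pf, revcomp_kmer(pf, k));
      if (find(canon) >= 0) { ++deg; out = pf; }
    }
    return deg;
  }
};

static std::string spell(const DBG& g, const std::vector<uint64_t>& nodes) {
  std::string s;
  uint64_t first = nodes[0];
  for (int i = g.k - 1; i >= 0; --i)
    s.push_back(BITS2BASE[(first >> (2 * i)) & 3]);
  for (size_t i = 1; i < nodes.size(); ++i)
    s.push_back(BITS2BASE[nodes[i] & 3]);
  return s;
}

// [[Rcpp::export]]
List cpp_build_unitigs(CharacterVector reads, int k, int min_abund) {
  DBG g;
  g.k = k;
  g.mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  {
    std::unordered_map<uint64_t, int> counts;
    for (int r = 0; r < reads.size(); ++r) {
      std::string rd = as<std::string>(reads[r]);
      for_each_kmer(rd, k, [&](int, uint64_t fwd) {
        ++counts[std::min(fwd, revcomp_kmer(fwd, k))];
      });
    }
    for (auto& kv : counts)
      if (kv.second >= min_abund) g.kmers.push_back(kv.first);
    std::sort(g.kmers.begin(), g.kmers.end());
    g.abund.resize(g.kmers.size());
    for (size_t i = 0; i < g.kmers.size(); ++i) {
      g.id[g.kmers[i]] = (int)i;
      g.abund[i] = counts[g.kmers[i]];
    }
  }
  const size_t N = g.kmers.size();
  std::vector<char> visited(N, 0);
  std::vector<std::string> seqs;
  std::vector<double> mabund;
  std::vector<int> nkmer;

  for (size_t s0 = 0; s0 < N; ++s0) {
    if (visited[s0]) continue;
    uint64_t f0 = g.kmers[s0];
    // walk left to the unitig start
    uint64_t cur = f0;
    size_t steps = 0;
    while (steps++ <= N) {
      uint64_t p, tmp;
      if (g.pred(cur, p) != 1) break;
      if (g.succ(p, tmp) != 1) break;
      uint64_t pc = std::min(p, revcomp_kmer(p, k));
      if (pc == std::min(f0, revcomp_kmer(f0, k))) break;  // cycle
      int pid = g.find(pc);
      if (pid < 0 || visited[pid]) break;
      cur = p;
    }
    // walk right collecting nodes
    std::vector<uint64_t> nodes;
    double ab = 0;
    uint64_t node = cur;
    while (true) {
      uint64_t canon = std::min(node, revcomp_kmer(node, k));
      int idn = g.find(canon);
      if (idn < 0 || visited[idn]) break;
      visited[idn] = 1;
      nodes.push_back(node);
      ab += g.abund[idn];
      uint64_t s, tmp;
      if (g.succ(node, s) != 1) break;
      if (g.pred(s, tmp) != 1) break;
      node = s;
    }
    if (nodes.empty()) continue;
    if ((int)nodes.size() + k - 1 < k + 10) continue;  // length filter
    std::string seq = spell(g, nodes);
    std::string rc = revcomp_str(seq);
    if (rc < seq) seq = rc;
    seqs.push_back(seq);
    mabund.push_back(ab / nodes.size());
    nkmer.push_back((int)nodes.size());
  }
  // deterministic order
  std::vector<int> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return seqs[a] < seqs[b]; });
  CharacterVector oseq(ord.size());
  NumericVector oab(ord.size());
  IntegerVector onk(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    oseq[i] = seqs[ord[i]];
    oab[i] = mabund[ord[i]];
    onk[i] = nkmer[ord[i]];
  }
  return List::create(_["seq"] = oseq, _["mean_abund"] = oab,
                      _["n_kmers"] = onk);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector s) {
  CharacterVector out(s.size());
  for (int i = 0; i < s.size(); ++i)
    out[i] = revcomp_str(as<std::string>(s[i]));
  return out;
}

// Count, per contig, the reads sharing at least one canonical k-mer with
// it. Unitigs have pairwise-disjoint k-mer sets, so a k-mer maps to a
// single contig.
// [[Rcpp::export]]
IntegerVector cpp_assign_reads(CharacterVector reads, CharacterVector contigs,
                               int k) {
  std::unordered_map<uint64_t, int> owner;
  for (int c = 0; c < contigs.size(); ++c) {
    std::string s = as<std::string>(contigs[c]);
    for_each_kmer(s, k, [&](int, uint64_t fwd) {
      uint64_t canon = std::min(fwd, revcomp_kmer(fwd, k));
      owner.emplace(canon, c);
    });
  }
  IntegerVector out(contigs.size());
  std::vector<int> seen;
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    seen.clear();
    for_each_kmer(rd, k, [&](int, uint64_t fwd) {
      uint64_t canon = std::min(fwd, revcomp_kmer(fwd, k));
      auto it = owner.find(canon);
      if (it != owner.end()) seen.push_back(it->second);
    });
    std::sort(seen.begin(), seen.end());
    seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
    for (int c : seen) ++out[c];
  }
  return out;
}
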