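#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// ---- shared helpers ---------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// ---- Smith-Waterman local alignment with traceback --------------------------
// Linear gap penalty. Returns 0-based half-open intervals and a CIGAR over
// {M, I, D} (I consumes query, D consumes target). Empty alignment: score 0.

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  double match, double mismatch, double gap) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0, _["qstart"] = 0, _["qend"] = 0,
                        _["tstart"] = 0, _["tend"] = 0, _["cigar"] = "");
  }
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0); // 0 stop, 1 diag, 2 up(I), 3 left(D)
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H[(size_t)(i - 1) * (m + 1) + (j - 1)] +
        (query[i - 1] == target[j - 1] ? match : mismatch);
      double up = H[(size_t)(i - 1) * (m + 1) + j] + gap;
      double left = H[(size_t)i * (m + 1) + (j - 1)] + gap;
      double v = 0.0; uint8_t t = 0;
      if (diag > v) { v = diag; t = 1; }
      if (up > v)   { v = up;   t = 2; }
      if (left > v) { v = left; t = 3; }
      H[(size_t)i * (m + 1) + j] = v;
      tb[(size_t)i * (m + 1) + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<std::pair<char,int>> ops;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && tb[(size_t)i * (m + 1) + j] != 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    char op = (t == 1) ? 'M' : (t == 2) ? 'I' : 'D';
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back({op, 1});
    if (t == 1) { --i; --j; } else if (t == 2) { --i; } else { --j; }
  }
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (auto& p : ops) cig += std::to_string(p.second) + p.first;
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = bi,
                      _["tstart"] = j, _["tend"] = bj, _["cigar"] = cig);
}

// ---- k-mer index + gapless seed-and-extend mapper ---------------------------
// Seeds are voted per (reference, strand, diagonal); each candidate diagonal is
// scored gaplessly: per-base +match for a match, -mismatch_pen for a mismatch,
// and the maximal-scoring contiguous segment (Kadane) becomes the M block, the
// remainders terminal soft clips. All co-optimal placements are reported with
// n_opt, so ambiguity (e.g. construct/genome shared sequence) is detectable.

struct RefIndex {
  int k;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t>> map; // kmer -> (ref<<40)|pos
};

static void index_add(RefIndex& idx, int ref_i, const std::string& s) {
  const int k = idx.k;
  const int L = (int)s.size();
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int pos = i - k + 1;
      idx.map[kmer].push_back(((uint64_t)ref_i << 40) | (uint64_t)pos);
    }
  }
}

struct Hit {
  int ref, pos, strand;     // pos 0-based leftmost; strand 0 = '+', 1 = '-'
  int clip_left, mlen, nm;
  double score;
};

static void eval_diag(const std::string& read, const std::string& ref,
                      long diag, double match, double mism, Hit& out) {
  const int n = (int)read.size(), L = (int)ref.size();
  // Kadane over read positions; out-of-reference bases are unalignable
  double bestsum = 0, cur = 0;
  int bs = 0, be = -1, cs = 0;
  for (int i = 0; i < n; ++i) {
    long rp = diag + i;
    double sc;
    if (rp < 0 || rp >= L) sc = -1e18;
    else sc = (read[i] == ref[rp]) ? match : -mism;
    if (cur <= 0) { cur = sc; cs = i; } else cur += sc;
    if (cur > bestsum) { bestsum = cur; bs = cs; be = i; }
  }
  if (be < 0) { out.score = -1; return; }
  int nm = 0;
  for (int i = bs; i <= be; ++i) if (read[i] != ref[diag + i]) ++nm;
  out.pos = (int)(diag + bs);
  out.clip_left = bs;
  out.mlen = be - bs + 1;
  out.nm = nm;
  out.score = bestsum;
}

// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector ref_seqs,
                        int k, double match, double mismatch_pen,
                        int max_report) {
  RefIndex idx; idx.k = k;
  idx.seqs.reserve(ref_seqs.size());
  for (int r = 0; r < ref_seqs.size(); ++r) {
    idx.seqs.push_back(as<std::string>(ref_seqs[r]));
    index_add(idx, r, idx.seqs.back());
  }

  std::vector<int> o_read, o_ref, o_pos, o_strand, o_nm, o_nopt;
  std::vector<double> o_score;
  std::vector<std::string> o_cigar;

  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::unordered_map<uint64_t, int> votes;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    const int n = (int)fwd.size();
    if (n < k) continue;
    std::string rev = revcomp(fwd);
    votes.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = (strand == 0) ? fwd : rev;
      uint64_t kmer = 0; int run = 0;
      for (int i = 0; i < n; ++i) {
        int b = base2bit(rd[i]);
        if (b < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        if (++run < k) continue;
        auto it = idx.map.find(kmer);
        if (it == idx.map.end()) continue;
        if (it->second.size() > 64) continue; // highly repetitive seed, skip
        int off = i - k + 1;
        for (uint64_t h : it->second) {
          int ref = (int)(h >> 40);
          long rp = (long)(h & ((1ULL << 40) - 1));
          long diag = rp - off;
          uint64_t key = ((uint64_t)ref << 34) | ((uint64_t)strand << 33) |
            (uint64_t)(diag + (1L << 31));
          votes[key]++;
        }
      }
    }
    if (votes.empty()) continue;
    // evaluate candidate diagonals (cap at the 64 best-voted)
    std::vector<std::pair<int, uint64_t>> cand;
    cand.reserve(votes.size());
    for (auto& kv : votes) cand.push_back({kv.second, kv.first});
    std::sort(cand.begin(), cand.end(),
              [](const std::pair<int, uint64_t>& a, const std::pair<int, uint64_t>& b) {
                return a.first > b.first || (a.first == b.first && a.second < b.second);
              });
    if (cand.size() > 64) cand.resize(64);

    std::vector<Hit> hits;
    for (auto& c : cand) {
      int ref = (int)(c.second >> 34);
      int strand = (int)((c.second >> 33) & 1);
      long diag = (long)(c.second & ((1ULL << 33) - 1)) - (1L << 31);
      Hit h; h.ref = ref; h.strand = strand;
      eval_diag(strand == 0 ? fwd : rev, idx.seqs[ref], diag, match, mismatch_pen, h);
      if (h.score > 0) hits.push_back(h);
    }
    if (hits.empty()) continue;
    double best = -1;
    for (auto& h : hits) best = std::max(best, h.score);
    std::vector<Hit> top;
    for (auto& h : hits) if (h.score == best) top.push_back(h);
    // dedupe identical placements (same ref/pos/strand reachable from two diagonals)
    std::sort(top.begin(), top.end(), [](const Hit& a, const Hit& b) {
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.strand < b.strand;
    });
    top.erase(std::unique(top.begin(), top.end(), [](const Hit& a, const Hit& b) {
      return a.ref == b.ref && a.pos == b.pos && a.strand == b.strand;
    }), top.end());
    int nopt = (int)top.size();
    int nrep = std::min(nopt, max_report);
    for (int t = 0; t < nrep; ++t) {
      const Hit& h = top[t];
      std::string cig;
      if (h.clip_left > 0) cig += std::to_string(h.clip_left) + "S";
      cig += std::to_string(h.mlen) + "M";
      int cr = n - h.clip_left - h.mlen;
      if (cr > 0) cig += std::to_string(cr) + "S";
      o_read.push_back(ri + 1);
      o_ref.push_back(h.ref + 1);
      o_pos.push_back(h.pos);
      o_strand.push_back(h.strand);
      o_cigar.push_back(cig);
      o_score.push_back(h.score);
      o_nm.push_back(h.nm);
      o_nopt.push_back(nopt);
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["ref"] = o_ref, _["pos"] = o_pos,
    _["strand"] = o_strand, _["cigar"] = o_cigar, _["score"] = o_score,
    _["nm"] = o_nm, _["n_opt"] = o_nopt, _["stringsAsFactors"] = false);
}

// Exact k-mer anchor hits of a long query against a reference set, for
// diagonal-chained placement of assembled contigs.
// [[Rcpp::export]]
DataFrame anchor_hits_cpp(std::string query, CharacterVector ref_seqs, int k) {
  RefIndex idx; idx.k = k;
  for (int r = 0; r < ref_seqs.size(); ++r) {
    idx.seqs.push_back(as<std::string>(ref_seqs[r]));
    index_add(idx, r, idx.seqs.back());
  }
  std::vector<int> o_ref, o_strand, o_qpos, o_rpos;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int strand = 0; strand < 2; ++strand) {
    std::string q = (strand == 0) ? query : revcomp(query);
    uint64_t kmer = 0; int run = 0;
    const int n = (int)q.size();
    for (int i = 0; i < n; ++i) {
      int b = base2bit(q[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      auto it = idx.map.find(kmer);
      if (it == idx.map.end()) continue;
      if (it->second.size() > 64) continue;
      int off = i - k + 1;
      for (uint64_t h : it->second) {
        o_ref.push_back((int)(h >> 40) + 1);
        o_strand.push_back(strand);
        o_qpos.push_back(off);
        o_rpos.push_back((int)(h & ((1ULL << 40) - 1)));
      }
    }
  }
  return DataFrame::create(_["ref"] = o_ref, _["strand"] = o_strand,
                           _["qpos"] = o_qpos, _["rpos"] = o_rpos);
}

// ---- greedy overlap-layout-consensus assembler ------------------------------
// Repeatedly merges the pair with the longest exact suffix-prefix overlap
// >= min_overlap, trying the second sequence in both orientations. Contained
// sequences (substring of another, either orientation) are absorbed first.
// Deterministic tie-breaking: longer overlap, then smaller i, smaller j,
// forward orientation before reverse.

static int suffix_prefix_overlap(const std::string& a, const std::string& b) {
  // longest k <= min(|a|,|b|): suffix of a == prefix of b (Z-algorithm on b#a)
  const int la = (int)a.size(), lb = (int)b.size();
  std::string s = b + '\x01' + a;
  const int n = (int)s.size();
  std::vector<int> z(n, 0);
  int l = 0, r = 0, best = 0;
  for (int i = 1; i < n; ++i) {
    if (i < r) z[i] = std::min(r - i, z[i - l]);
    while (i + z[i] < n && s[z[i]] == s[i + z[i]]) z[i]++;
    if (i + z[i] > r) { l = i; r = i + z[i]; }
  }
  for (int i = lb + 1; i < n; ++i) {
    if (i + z[i] == n) { // suffix of a starting here matches prefix of b
      int k = n - i;
      if (k <= lb && k > best) best = k;
    }
  }
  return best;
}

// [[Rcpp::export]]
CharacterVector assemble_greedy_cpp(CharacterVector seqs, int min_overlap) {
  std::vector<std::string> s;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string x = as<std::string>(seqs[i]);
    if (!x.empty()) s.push_back(x);
  }
  if (s.empty()) return CharacterVector(0);
  // drop exact / reverse-complement duplicates
  {
    std::vector<std::string> uniq;
    std::unordered_map<std::string, bool> seen;
    for (auto& x : s) {
      std::string rc = revcomp(x);
      std::string key = std::min(x, rc);
      if (!seen.count(key)) { seen[key] = true; uniq.push_back(x); }
    }
    s.swap(uniq);
  }
  // absorb contained sequences (longest-first scan)
  {
    std::vector<int> ord(s.size());
    for (size_t i = 0; i < s.size(); ++i) ord[i] = (int)i;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return s[a].size() > s[b].size() || (s[a].size() == s[b].size() && s[a] < s[b]);
    });
    std::vector<bool> dead(s.size(), false);
    for (size_t ii = 0; ii < ord.size(); ++ii) {
      int i = ord[ii];
      if (dead[i]) continue;
      for (size_t jj = ii + 1; jj < ord.size(); ++jj) {
        int j = ord[jj];
        if (dead[j] || s[j].size() > s[i].size()) continue;
        if (s[i].find(s[j]) != std::string::npos ||
            s[i].find(revcomp(s[j])) != std::string::npos)
          dead[j] = true;
      }
    }
    std::vector<std::string> keep;
    for (int i : ord) if (!dead[i]) keep.push_back(s[i]);
    s.swap(keep);
  }

  const int n0 = (int)s.size();
  std::vector<bool> alive(n0, true);
  // ov[i][j]: best suffix(i)-prefix(j or rc j) overlap; flip flag in fl[i][j]
  std::vector<std::vector<int>> ov(n0, std::vector<int>(n0, 0));
  std::vector<std::vector<uint8_t>> fl(n0, std::vector<uint8_t>(n0, 0));
  auto compute = [&](int i, int j) {
    int o1 = suffix_prefix_overlap(s[i], s[j]);
    int o2 = suffix_prefix_overlap(s[i], revcomp(s[j]));
    if (o1 >= o2) { ov[i][j] = o1; fl[i][j] = 0; }
    else { ov[i][j] = o2; fl[i][j] = 1; }
  };
  for (int i = 0; i < n0; ++i)
    for (int j = 0; j < n0; ++j)
      if (i != j) compute(i, j);

  while (true) {
    int bi = -1, bj = -1, bo = min_overlap - 1;
    for (int i = 0; i < n0; ++i) {
      if (!alive[i]) continue;
      for (int j = 0; j < n0; ++j) {
        if (i == j || !alive[j]) continue;
        if (ov[i][j] > bo) { bo = ov[i][j]; bi = i; bj = j; }
      }
    }
    if (bi < 0) break;
    std::string b = fl[bi][bj] ? revcomp(s[bj]) : s[bj];
    s[bi] = s[bi] + b.substr(bo);
    alive[bj] = false;
    for (int x = 0; x < n0; ++x) {
      if (!alive[x] || x == bi) continue;
      compute(bi, x);
      compute(x, bi);
    }
  }
  std::vector<std::string> out;
  for (int i = 0; i < n0; ++i) if (alive[i]) out.push_back(s[i]);
  std::stable_sort(out.begin(), out.end(), [](const std::string& a, const std::string& b) {
    return a.size() > b.size() || (a.size() == b.size() && a < b);
  });
  return wrap(out);
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) { return revcomp(s); }
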