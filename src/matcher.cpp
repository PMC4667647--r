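#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Ungapped end-to-end read matching against a set of target sequences,
// with at most `max_mm` mismatches. Seed-and-verify: a read is checked only
// at offsets suggested by (max_mm + 1) disjoint k-mer seeds; by pigeonhole,
// any end-to-end placement with <= max_mm mismatches leaves at least one
// seed exact, so no qualifying placement is missed. Reads too short to carry
// (max_mm + 1) disjoint seeds are verified by a full scan instead, so the
// guarantee holds at every read length >= 1.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else: never part of an indexed k-mer
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  // packed (target << 32) | position
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;

  void build(const CharacterVector& targets, int k_) {
    k = k_;
    seqs.reserve(targets.size());
    for (R_xlen_t t = 0; t < targets.size(); ++t)
      seqs.push_back(as<std::string>(targets[t]));
    for (size_t t = 0; t < seqs.size(); ++t) {
      const std::string& s = seqs[t];
      if ((int)s.size() < k) continue;
      uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
      int valid = 0; // run length of ACGT-only bases ending here
      for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid >= k) {
          uint64_t pos = i + 1 - k;
          table[key].push_back(((uint64_t)t << 32) | pos);
        }
      }
    }
  }
};

static inline int hamming_leq(const std::string& a, const std::string& b,
                              size_t off, int limit) {
  // mismatches of a against b[off .. off+|a|), or limit+1 if exceeded
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[off + i] && ++mm > limit) return limit + 1;
  }
  return mm;
}

struct Hit {
  int target;
  long offset;
  int mm;
  char strand;
};

static void scan_one(const std::string& read, const KmerIndex& idx,
                     int max_mm, char strand, bool first_only,
                     std::vector<Hit>& out,
                     std::unordered_set<uint64_t>& seen) {
  const int k = idx.k;
  const long L = (long)read.size();
  if (L < 1) return;

  if (L < (long)(max_mm + 1) * k) {
    // full scan fallback (short reads)
    for (size_t t = 0; t < idx.seqs.size(); ++t) {
      const std::string& s = idx.seqs[t];
      if ((long)s.size() < L) continue;
      for (size_t o = 0; o + read.size() <= s.size(); ++o) {
        int mm = hamming_leq(read, s, o, max_mm);
        if (mm <= max_mm) {
          out.push_back(Hit{(int)t, (long)o, mm, strand});
          if (first_only) return;
        }
      }
    }
    return;
  }

  // (max_mm + 1) disjoint seeds spread over the read
  int nseed = max_mm + 1;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int si = 0; si < nseed; ++si) {
    long start = (long)((double)si * (L - k) / (nseed > 1 ? nseed - 1 : 1));
    if (nseed > 1 && si > 0) {
      // keep seeds disjoint: never overlap the previous seed
      long min_start = (long)si * k;
      if (start < min_start) start = min_start;
    }
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int c = base_code(read[start + i]);
      if (c < 0) { ok = false; break; }
      key = ((key << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
      idx.table.find(key);
    if (it == idx.table.end()) continue;
    for (size_t j = 0; j < it->second.size(); ++j) {
      uint64_t packed = it->second[j];
      int t = (int)(packed >> 32);
      long pos = (long)(packed & 0xffffffffULL);
      long o = pos - start;
      if (o < 0 || o + L > (long)idx.seqs[t].size()) continue;
      uint64_t ckey = ((uint64_t)t << 40) ^ (uint64_t)(o + 1) ^
                      ((uint64_t)(strand == '-') << 63);
      if (seen.count(ckey)) continue;
      seen.insert(ckey);
      int mm = hamming_leq(read, idx.seqs[t], (size_t)o, max_mm);
      if (mm <= max_mm) {
        out.push_back(Hit{t, o, mm, strand});
        if (first_only) return;
      }
    }
  }
}

// [[Rcpp::export(name = ".tc_match_any")]]
LogicalVector tc_match_any(CharacterVector reads, CharacterVector targets,
                           int k, int max_mm, bool both_strands) {
  KmerIndex idx;
  idx.build(targets, k);
  LogicalVector res(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    std::vector<Hit> hits;
    std::unordered_set<uint64_t> seen;
    scan_one(r, idx, max_mm, '+', true, hits, seen);
    if (hits.empty() && both_strands) {
      seen.clear();
      scan_one(revcomp(r), idx, max_mm, '-', true, hits, seen);
    }
    res[i] = !hits.empty();
  }
  return res;
}

// [[Rcpp::export(name = ".tc_match_hits")]]
DataFrame tc_match_hits(CharacterVector reads, CharacterVector targets,
                        int k, int max_mm, bool both_strands) {
  KmerIndex idx;
  idx.build(targets, k);
  std::vector<int> rr, tt, mm_;
  std::vector<double> oo;
  std::vector<std::string> ss;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    std::vector<Hit> hits;
    std::unordered_set<uint64_t> seen;
    scan_one(r, idx, max_mm, '+', false, hits, seen);
    if (both_strands) {
      std::unordered_set<uint64_t> seen2;
      scan_one(revcomp(r), idx, max_mm, '-', false, hits, seen2);
    }
    for (size_t h = 0; h < hits.size(); ++h) {
      rr.push_back((int)i + 1);
      tt.push_back(hits[h].target + 1);
      oo.push_back((double)hits[h].offset);
      mm_.push_back(hits[h].mm);
      ss.push_back(std::string(1, hits[h].strand));
    }
  }
  return DataFrame::create(_["read"] = rr, _["target"] = tt,
                           _["offset"] = oo, _["mismatches"] = mm_,
                           _["strand"] = ss,
                           _["stringsAsFactors"] = false);
}

// Per-read quality control: (1) reject unless >= min_frac of bases have
// Q >= min_q (evaluated on the untrimmed read); (2) trim contiguous
// low-quality runs from both ends; (3) reject if the trimmed read is shorter
// than min_len or carries more than max_n 'N' bases.
// Returns an n x 3 integer matrix: status (0 pass, 1 low-quality fraction,
// 2 too short after trimming, 3 too many N), trim start, trim end (1-based).
// [[Rcpp::export(name = ".tc_qc")]]
IntegerMatrix tc_qc(CharacterVector seqs, CharacterVector quals,
                    int min_q, double min_frac, int max_n, int min_len) {
  IntegerMatrix res(seqs.size(), 3);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int L = (int)s.size();
    if ((int)q.size() != L) stop("sequence/quality length mismatch at record %d", (int)i + 1);
    int hq = 0;
    for (int j = 0; j < L; ++j) if ((int)q[j] - 33 >= min_q) ++hq;
    if ((double)hq + 1e-9 < min_frac * (double)L) {
      res(i, 0) = 1; res(i, 1) = 0; res(i, 2) = -1;
      continue;
    }
    int a = 0, b = L - 1;
    while (a < L && (int)q[a] - 33 < min_q) ++a;
    while (b >= a && (int)q[b] - 33 < min_q) --b;
    int len2 = b - a + 1;
    if (len2 < min_len || len2 <= 0) {
      res(i, 0) = 2; res(i, 1) = a + 1; res(i, 2) = b + 1;
      continue;
    }
    int nn = 0;
    for (int j = a; j <= b; ++j) if (s[j] == 'N') ++nn;
    res(i, 0) = (nn > max_n) ? 3 : 0;
    res(i, 1) = a + 1;
    res(i, 2) = b + 1;
  }
  return res;
}
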