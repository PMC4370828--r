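// Alignment kernels for ighclone.
//
// Three contracts, mirroring the roles the pipeline needs:
//   * ungapped_scan   - end-to-end placement of whole mates on reference
//                       contigs with a mismatch cap, best-stratum reporting
//                       and a suppression marker for over-multimapped mates.
//   * local_align     - ungapped local alignment of a mate against short
//                       germline segments with identity and length floors;
//                       best placement per (mate, segment).
//   * seeded_align    - local alignment on D segments gated by an exact
//                       common substring (seed); at most one reported hit
//                       per mate.
//
// All three are exact (equivalent to exhaustive position scans).  Speed
// comes from a k-mer candidate index: a valid placement is guaranteed to
// contain an exact run of length >= k (runs-between-mismatches bound), so
// only diagonals carrying a shared k-mer need to be scanned.  Callers pass
// k; k < 4 disables the index and forces the exhaustive path.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N'; break;
    }
  }
  return r;
}

// k-mer -> packed (seq_index << 32 | position) postings
typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerMap;

static void index_kmers(const std::vector<std::string> &seqs, int k,
                        KmerMap &map) {
  const uint64_t mask =
      (k >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
  for (size_t s = 0; s < seqs.size(); ++s) {
    const std::string &q = seqs[s];
    if ((int)q.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;
    for (size_t i = 0; i < q.size(); ++i) {
      int b = base2(q[i]);
      if (b < 0) {
        valid = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | (uint64_t)b) & mask;
      ++valid;
      if (valid >= k)
        map[key].push_back(((uint64_t)s << 32) | (uint64_t)(i - k + 1));
    }
  }
}

// roll k-mers of `q`, appending (kmer, pos) pairs for valid windows
static void roll_kmers(const std::string &q, int k,
                       std::vector<std::pair<uint64_t, int> > &out) {
  const uint64_t mask =
      (k >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
  if ((int)q.size() < k) return;
  uint64_t key = 0;
  int valid = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    int b = base2(q[i]);
    if (b < 0) {
      valid = 0;
      key = 0;
      continue;
    }
    key = ((key << 2) | (uint64_t)b) & mask;
    ++valid;
    if (valid >= k) out.push_back(std::make_pair(key, (int)(i - k + 1)));
  }
}

// ---------------------------------------------------------------------------
// ungapped end-to-end scan
// ---------------------------------------------------------------------------

struct UHit {
  int ref, start, strand, mm;  // strand: +1 / -1
};

static bool uhit_less(const UHit &a, const UHit &b) {
  if (a.ref != b.ref) return a.ref < b.ref;
  if (a.start != b.start) return a.start < b.start;
  return a.strand > b.strand;  // '+' before '-'
}

// [[Rcpp::export]]
List cpp_ungapped_scan(CharacterVector mates, CharacterVector refs,
                       int max_mm, int max_report, int kmer) {
  int n_mates = mates.size(), n_refs = refs.size();
  std::vector<std::string> R(n_refs);
  for (int i = 0; i < n_refs; ++i) R[i] = as<std::string>(refs[i]);

  bool use_index = kmer >= 4;
  KmerMap idx;
  if (use_index) index_kmers(R, kmer, idx);

  IntegerVector status(n_mates);  // 0 none, 1 hits, 2 suppressed
  std::vector<int> o_mate, o_ref, o_start, o_strand, o_mm;

  for (int m = 0; m < n_mates; ++m) {
    std::string fwd = as<std::string>(mates[m]);
    int Lm = (int)fwd.size();
    std::string rev = revcomp(fwd);
    std::vector<UHit> hits;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = strand == 0 ? fwd : rev;
      std::unordered_set<uint64_t> seen;  // dedupe (ref, start)
      if (use_index && Lm >= kmer) {
        std::vector<std::pair<uint64_t, int> > km;
        roll_kmers(q, kmer, km);
        for (size_t t = 0; t < km.size(); ++t) {
          KmerMap::const_iterator it = idx.find(km[t].first);
          if (it == idx.end()) continue;
          const std::vector<uint64_t> &post = it->second;
          for (size_t p = 0; p < post.size(); ++p) {
            int r = (int)(post[p] >> 32);
            int pos = (int)(post[p] & 0xffffffffu);
            int start = pos - km[t].second;
            if (start < 0) continue;
            if ((int)R[r].size() < Lm) continue;  // contig shorter than mate
            if (start + Lm > (int)R[r].size()) continue;
            uint64_t key = ((uint64_t)r << 32) | (uint64_t)start;
            if (!seen.insert(key).second) continue;
            int mm = 0;
            const std::string &rf = R[r];
            for (int i = 0; i < Lm; ++i) {
              char a = q[i], b = rf[start + i];
              if (a != b || base2(a) < 0) {
                if (++mm > max_mm) break;
              }
            }
            if (mm <= max_mm) {
              UHit h;
              h.ref = r;
              h.start = start;
              h.strand = strand == 0 ? 1 : -1;
              h.mm = mm;
              hits.push_back(h);
            }
          }
        }
      } else {
        for (int r = 0; r < n_refs; ++r) {
          const std::string &rf = R[r];
          if ((int)rf.size() < Lm) continue;
          for (int start = 0; start + Lm <= (int)rf.size(); ++start) {
            int mm = 0;
            for (int i = 0; i < Lm; ++i) {
              char a = q[i], b = rf[start + i];
              if (a != b || base2(a) < 0) {
                if (++mm > max_mm) break;
              }
            }
            if (mm <= max_mm) {
              UHit h;
              h.ref = r;
              h.start = start;
              h.strand = strand == 0 ? 1 : -1;
              h.mm = mm;
              hits.push_back(h);
            }
          }
        }
      }
    }

    if (hits.empty()) {
      status[m] = 0;
      continue;
    }
    int best = max_mm + 1;
    for (size_t i = 0; i < hits.size(); ++i)
      if (hits[i].mm < best) best = hits[i].mm;
    std::vector<UHit> strat;
    for (size_t i = 0; i < hits.size(); ++i)
      if (hits[i].mm == best) strat.push_back(hits[i]);
    if ((int)strat.size() > max_report) {
      status[m] = 2;  // suppressed: too many placements in best stratum
      continue;
    }
    status[m] = 1;
    std::sort(strat.begin(), strat.end(), uhit_less);
    for (size_t i = 0; i < strat.size(); ++i) {
      o_mate.push_back(m + 1);
      o_ref.push_back(strat[i].ref + 1);
      o_start.push_back(strat[i].start);
      o_strand.push_back(strat[i].strand);
      o_mm.push_back(strat[i].mm);
    }
  }

  return List::create(
      _["status"] = status,
      _["hits"] = DataFrame::create(
          _["mate"] = wrap(o_mate), _["ref"] = wrap(o_ref),
          _["start"] = wrap(o_start), _["strand"] = wrap(o_strand),
          _["mismatches"] = wrap(o_mm)));
}

// ---------------------------------------------------------------------------
// local alignment (ungapped, identity/length floors)
// ---------------------------------------------------------------------------

struct LHit {
  bool set;
  int strand;  // +1/-1
  int rs, re, ss, se, matches, len, score;
  LHit() : set(false) {}
};

// better-than comparison with deterministic tie-break: score desc, then
// shorter window (= higher identity at equal score, so alignments do not
// creep across junction breakpoints), '+' strand first, smaller seg_start
static bool lhit_better(const LHit &a, const LHit &b) {
  if (!b.set) return true;
  if (a.score != b.score) return a.score > b.score;
  if (a.len != b.len) return a.len < b.len;
  if (a.strand != b.strand) return a.strand > b.strand;
  return a.ss < b.ss;
}

// scan one diagonal of q (oriented mate) vs segment t; diag = seg_pos - q_pos
static void scan_diag(const std::string &q, const std::string &t, int diag,
                      double min_id, int min_len, int strand, LHit &best) {
  int Lq = (int)q.size(), Lt = (int)t.size();
  int lo = std::max(0, -diag);
  int hi = std::min(Lq, Lt - diag);
  int K = hi - lo;
  if (K < min_len) return;
  // prefix sums of matches over positions lo..hi-1
  std::vector<int> P(K + 1, 0);
  for (int j = 0; j < K; ++j) {
    char a = q[lo + j], b = t[lo + j + diag];
    P[j + 1] = P[j] + ((a == b && base2(a) >= 0) ? 1 : 0);
  }
  for (int i1 = 0; i1 + min_len <= K; ++i1) {
    for (int i2 = i1 + min_len; i2 <= K; ++i2) {
      int len = i2 - i1;
      int mt = P[i2] - P[i1];
      if ((double)mt + 1e-9 < min_id * (double)len) continue;
      int score = 2 * mt - len;
      LHit h;
      h.set = true;
      h.strand = strand;
      h.rs = lo + i1;  // oriented coords; caller converts for '-'
      h.re = lo + i2;
      h.ss = lo + i1 + diag;
      h.se = lo + i2 + diag;
      h.matches = mt;
      h.len = len;
      h.score = score;
      if (lhit_better(h, best)) best = h;
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_local_align(CharacterVector mates, CharacterVector segs,
                          double min_id, int min_len, int kmer) {
  int n_mates = mates.size(), n_segs = segs.size();
  std::vector<std::string> S(n_segs);
  for (int i = 0; i < n_segs; ++i) S[i] = as<std::string>(segs[i]);

  bool use_index = kmer >= 4;
  KmerMap idx;
  if (use_index) index_kmers(S, kmer, idx);

  std::vector<int> o_mate, o_seg, o_strand, o_rs, o_re, o_ss, o_se, o_mt,
      o_len, o_score;

  for (int m = 0; m < n_mates; ++m) {
    std::string fwd = as<std::string>(mates[m]);
    int Lm = (int)fwd.size();
    std::string rev = revcomp(fwd);
    std::vector<LHit> best(n_segs);

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = strand == 0 ? fwd : rev;
      int sgn = strand == 0 ? 1 : -1;
      if (use_index) {
        std::unordered_set<uint64_t> seen;  // (seg, diag) pairs
        std::vector<std::pair<uint64_t, int> > km;
        roll_kmers(q, kmer, km);
        for (size_t t = 0; t < km.size(); ++t) {
          KmerMap::const_iterator it = idx.find(km[t].first);
          if (it == idx.end()) continue;
          const std::vector<uint64_t> &post = it->second;
          for (size_t p = 0; p < post.size(); ++p) {
            int s = (int)(post[p] >> 32);
            int pos = (int)(post[p] & 0xffffffffu);
            int diag = pos - km[t].second;
            uint64_t key =
                ((uint64_t)s << 32) | (uint64_t)(uint32_t)(diag + Lm);
            if (!seen.insert(key).second) continue;
            scan_diag(q, S[s], diag, min_id, min_len, sgn, best[s]);
          }
        }
      } else {
        for (int s = 0; s < n_segs; ++s) {
          int Ls = (int)S[s].size();
          for (int diag = -(Lm - 1); diag < Ls; ++diag)
            scan_diag(q, S[s], diag, min_id, min_len, sgn, best[s]);
        }
      }
    }

    for (int s = 0; s < n_segs; ++s) {
      if (!best[s].set) continue;
      const LHit &h = best[s];
      int rs = h.rs, re = h.re;
      if (h.strand < 0) {  // convert to original mate coordinates
        rs = Lm - h.re;
        re = Lm - h.rs;
      }
      o_mate.push_back(m + 1);
      o_seg.push_back(s + 1);
      o_strand.push_back(h.strand);
      o_rs.push_back(rs);
      o_re.push_back(re);
      o_ss.push_back(h.ss);
      o_se.push_back(h.se);
      o_mt.push_back(h.matches);
      o_len.push_back(h.len);
      o_score.push_back(h.score);
    }
  }

  return DataFrame::create(
      _["mate"] = wrap(o_mate), _["seg"] = wrap(o_seg),
      _["strand"] = wrap(o_strand), _["read_start"] = wrap(o_rs),
      _["read_end"] = wrap(o_re), _["seg_start"] = wrap(o_ss),
      _["seg_end"] = wrap(o_se), _["matches"] = wrap(o_mt),
      _["length"] = wrap(o_len), _["score"] = wrap(o_score));
}

// ---------------------------------------------------------------------------
// seeded alignment on D segments (exact seed >= min_seed, one hit per mate)
// ---------------------------------------------------------------------------

struct SHit {
  bool set;
  int seg, strand, rs, re, ss, se, matches, len, score;
  SHit() : set(false) {}
};

// score desc, then lexicographically smaller segment (callers pass segs
// sorted by formatted name, so the index order is the name order),
// '+' strand first, smaller seg_start
static bool shit_better(const SHit &a, const SHit &b) {
  if (!b.set) return true;
  if (a.score != b.score) return a.score > b.score;
  if (a.seg != b.seg) return a.seg < b.seg;
  if (a.strand != b.strand) return a.strand > b.strand;
  return a.ss < b.ss;
}

// [[Rcpp::export]]
DataFrame cpp_seeded_align(CharacterVector mates, CharacterVector segs,
                           int min_seed) {
  int n_mates = mates.size(), n_segs = segs.size();
  std::vector<std::string> S(n_segs);
  for (int i = 0; i < n_segs; ++i) S[i] = as<std::string>(segs[i]);

  std::vector<int> o_mate, o_seg, o_strand, o_rs, o_re, o_ss, o_se, o_mt,
      o_len, o_score, o_tie;

  for (int m = 0; m < n_mates; ++m) {
    std::string fwd = as<std::string>(mates[m]);
    int Lm = (int)fwd.size();
    std::string rev = revcomp(fwd);
    SHit best;
    int tie = 0;
    std::vector<char> mv(Lm);

    for (int s = 0; s < n_segs; ++s) {
      const std::string &t = S[s];
      int Lt = (int)t.size();
      for (int strand = 0; strand < 2; ++strand) {
        const std::string &q = strand == 0 ? fwd : rev;
        int sgn = strand == 0 ? 1 : -1;
        for (int diag = -(Lm - 1); diag < Lt; ++diag) {
          int lo = std::max(0, -diag);
          int hi = std::min(Lm, Lt - diag);
          int K = hi - lo;
          if (K < min_seed) continue;
          // match vector along the diagonal (buffer reused across diags)
          for (int j = 0; j < K; ++j) {
            char a = q[lo + j], b = t[lo + j + diag];
            mv[j] = (a == b && base2(a) >= 0) ? 1 : 0;
          }
          // maximal exact runs
          int j = 0;
          while (j < K) {
            if (!mv[j]) {
              ++j;
              continue;
            }
            int r0 = j;
            while (j < K && mv[j]) ++j;
            int r1 = j;  // run [r0, r1)
            if (r1 - r0 < min_seed) continue;
            // best extension containing the run: max suffix-sum to the
            // left of r0 and max prefix-sum to the right of r1 (+1/-1)
            int bestL = 0, curL = 0, argL = 0, cur = 0;
            for (int x = r0 - 1; x >= 0; --x) {
              cur += mv[x] ? 1 : -1;
              if (cur > curL) {
                curL = cur;
                argL = r0 - x;
              }
            }
            bestL = curL;
            int bestR = 0, argR = 0;
            cur = 0;
            for (int x = r1; x < K; ++x) {
              cur += mv[x] ? 1 : -1;
              if (cur > bestR) {
                bestR = cur;
                argR = x - r1 + 1;
              }
            }
            SHit h;
            h.set = true;
            h.seg = s;
            h.strand = sgn;
            int w0 = r0 - argL, w1 = r1 + argR;
            h.rs = lo + w0;
            h.re = lo + w1;
            h.ss = lo + w0 + diag;
            h.se = lo + w1 + diag;
            int mt = 0;
            for (int x = w0; x < w1; ++x) mt += mv[x] ? 1 : 0;
            h.matches = mt;
            h.len = w1 - w0;
            h.score = 2 * mt - h.len;
            if (best.set && h.score == best.score && h.seg != best.seg)
              tie = 1;
            if (shit_better(h, best)) {
              if (best.set && h.score > best.score) tie = 0;
              best = h;
            }
          }
        }
      }
    }

    if (!best.set) continue;
    int rs = best.rs, re = best.re;
    if (best.strand < 0) {
      rs = Lm - best.re;
      re = Lm - best.rs;
    }
    o_mate.push_back(m + 1);
    o_seg.push_back(best.seg + 1);
    o_strand.push_back(best.strand);
    o_rs.push_back(rs);
    o_re.push_back(re);
    o_ss.push_back(best.ss);
    o_se.push_back(best.se);
    o_mt.push_back(best.matches);
    o_len.push_back(best.len);
    o_score.push_back(best.score);
    o_tie.push_back(tie);
  }

  return DataFrame::create(
      _["mate"] = wrap(o_mate), _["seg"] = wrap(o_seg),
      _["strand"] = wrap(o_strand), _["read_start"] = wrap(o_rs),
      _["read_end"] = wrap(o_re), _["seg_start"] = wrap(o_ss),
      _["seg_end"] = wrap(o_se), _["matches"] = wrap(o_mt),
      _["length"] = wrap(o_len), _["score"] = wrap(o_score),
      _["tie"] = wrap(o_tie));
}
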