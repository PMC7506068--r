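// k-mer machinery shared by the mapper, assembler, anchorer, clusterer and
// polisher. All k-mers are 2-bit packed (k <= 31); canonical = min(fwd, rc).
// Windows containing non-ACGT characters are skipped everywhere.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t rc_kmer(uint64_t x, int k) {
  // complement then reverse 2-bit groups
  x = ~x;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
  x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
  x = (x << 32) | (x >> 32);
  return x >> (64 - 2 * k);
}

static std::string kmer_string(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = CODE_BASE[x & 3]; x >>= 2; }
  return s;
}

// Extract (position, canonical kmer, is_rc) over one sequence.
// is_rc is true when the canonical form is the reverse complement of the
// forward k-mer at that position.
struct KmerHit { int pos; uint64_t canon; bool rc; };

static void extract_kmers(const std::string& s, int k, std::vector<KmerHit>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      uint64_t rc = rc_kmer(fwd, k);
      bool isrc = rc < fwd;
      out.push_back({i - k + 1, isrc ? rc : fwd, isrc});
    }
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    default: c = 'N';
    }
  }
  return r;
}

// ---------------------------------------------------------------- index ----

struct KmerIndex {
  int k;
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
  // canonical kmer -> packed occurrences: (contig << 32) | (pos << 1) | rc
  std::unordered_map<uint64_t, std::vector<uint64_t>> occ;
  size_t n_positions = 0;
};

// [[Rcpp::export]]
SEXP dm_index_build(CharacterVector seqs, CharacterVector ids, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  std::vector<KmerHit> hits;
  for (int ci = 0; ci < seqs.size(); ++ci) {
    std::string s = as<std::string>(seqs[ci]);
    idx->ids.push_back(as<std::string>(ids[ci]));
    idx->seqs.push_back(s);
    extract_kmers(s, k, hits);
    for (const auto& h : hits) {
      idx->occ[h.canon].push_back(((uint64_t)ci << 32) |
                                  ((uint64_t)h.pos << 1) | (h.rc ? 1 : 0));
      ++idx->n_positions;
    }
  }
  XPtr<KmerIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
List dm_index_info(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  IntegerVector lens(xp->seqs.size());
  for (size_t i = 0; i < xp->seqs.size(); ++i) lens[i] = (int)xp->seqs[i].size();
  return List::create(_["k"] = xp->k,
                      _["n_positions"] = (double)xp->n_positions,
                      _["n_kmers"] = (double)xp->occ.size(),
                      _["contig_ids"] = wrap(xp->ids),
                      _["contig_lengths"] = lens);
}

// Test introspection: dump all indexed positions (small indexes only).
// [[Rcpp::export]]
DataFrame dm_index_dump(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  if (xp->n_positions > 100000) stop("index too large to dump");
  std::vector<std::string> km, id;
  std::vector<int> pos; std::vector<bool> rc;
  for (const auto& kv : xp->occ) {
    for (uint64_t p : kv.second) {
      km.push_back(kmer_string(kv.first, xp->k));
      id.push_back(xp->ids[p >> 32]);
      pos.push_back((int)((p >> 1) & 0x7FFFFFFF));
      rc.push_back(p & 1);
    }
  }
  return DataFrame::create(_["kmer"] = km, _["contig_id"] = id,
                           _["pos"] = pos, _["rc"] = rc,
                           _["stringsAsFactors"] = false);
}

// --------------------------------------------------------------- mapper ----

struct Cand { int contig; int offset; bool minus; int votes; };

static int count_mismatch_range(const std::string& a, int ai,
                                const std::string& b, int bi, int len,
                                int stop_after) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (a[ai + i] != b[bi + i]) { if (++mm > stop_after) return mm; }
  }
  return mm;
}

// Best ungapped placement per read by seed voting; ties by
// (contig id lexicographic, offset, strand + first). Reads may overhang
// contig ends (end-clipping): the placement is scored over the overlap,
// which must reach min_overlap_frac of the read length (and k); the winner
// is verified at max_mm_frac of the overlap. `offset` is the unclipped
// 0-based position of the (oriented) read start on the contig; start/end
// are clipped to the contig.
// [[Rcpp::export]]
DataFrame dm_map_short(SEXP xp_, CharacterVector reads, double max_mm_frac,
                       double min_overlap_frac = 0.5) {
  XPtr<KmerIndex> xp(xp_);
  int k = xp->k;
  int n = reads.size();
  IntegerVector contig(n, NA_INTEGER), start(n, NA_INTEGER), end(n, NA_INTEGER),
    score(n, NA_INTEGER), nmm(n, NA_INTEGER), offset(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);
  std::vector<KmerHit> hits;
  std::unordered_map<uint64_t, int> votes; // (contig<<34 | (off+2^30)<<1 | minus)
  const long OSHIFT = 1L << 30;
  for (int ri = 0; ri < n; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    int len = (int)rd.size();
    if (len < k) continue;
    extract_kmers(rd, k, hits);
    votes.clear();
    for (const auto& h : hits) {
      auto it = xp->occ.find(h.canon);
      if (it == xp->occ.end()) continue;
      if (it->second.size() > 200) continue; // ultra-repetitive seed
      for (uint64_t p : it->second) {
        int ci = (int)(p >> 32);
        int cpos = (int)((p >> 1) & 0x7FFFFFFF);
        bool erc = p & 1;
        bool minus = (erc != h.rc);
        long off = minus ? (long)cpos - (long)(len - k - h.pos)
                         : (long)cpos - (long)h.pos;
        uint64_t key = ((uint64_t)ci << 34) |
          ((uint64_t)(off + OSHIFT) << 1) | (minus ? 1 : 0);
        votes[key]++;
      }
    }
    if (votes.empty()) continue;
    // winner: max votes, tie by (id, offset, strand)
    bool have = false; uint64_t bk = 0; int bv = -1;
    for (const auto& kv : votes) {
      if (kv.second > bv) { bv = kv.second; bk = kv.first; have = true; }
      else if (kv.second == bv) {
        int ci1 = (int)(kv.first >> 34), ci2 = (int)(bk >> 34);
        const std::string& id1 = xp->ids[ci1];
        const std::string& id2 = xp->ids[ci2];
        long off1 = (long)((kv.first >> 1) & 0x1FFFFFFFF) - OSHIFT;
        long off2 = (long)((bk >> 1) & 0x1FFFFFFFF) - OSHIFT;
        bool m1 = kv.first & 1, m2 = bk & 1;
        if (std::tie(id1, off1, m1) < std::tie(id2, off2, m2)) bk = kv.first;
      }
    }
    if (!have) continue;
    int ci = (int)(bk >> 34);
    long off = (long)((bk >> 1) & 0x1FFFFFFFF) - OSHIFT;
    bool minus = bk & 1;
    int clen = (int)xp->seqs[ci].size();
    long qs = std::max(0L, -off);          // read start within overlap
    long cs = std::max(0L, off);           // contig start of overlap
    long ov = std::min((long)len - qs, (long)clen - cs);
    int min_ov = std::max(k, (int)std::ceil(min_overlap_frac * len));
    if (ov < min_ov) continue;
    std::string q = minus ? revcomp_str(rd) : rd;
    int max_mm = (int)std::floor(max_mm_frac * ov);
    int mm = count_mismatch_range(q, (int)qs, xp->seqs[ci], (int)cs, (int)ov,
                                  max_mm);
    if (mm > max_mm) continue;
    contig[ri] = ci + 1;
    start[ri] = (int)cs;
    end[ri] = (int)(cs + ov);
    offset[ri] = (int)off;
    strand[ri] = minus ? "-" : "+";
    score[ri] = (int)ov - mm;
    nmm[ri] = mm;
  }
  return DataFrame::create(_["contig"] = contig, _["start"] = start,
                           _["end"] = end, _["strand"] = strand,
                           _["score"] = score, _["nmm"] = nmm,
                           _["offset"] = offset,
                           _["stringsAsFactors"] = false);
}

// All near-exact ungapped placements of each query (marker census, identity
// checks): every seed-supported offset with full containment and
// mismatches <= max_mm_frac * length.
// [[Rcpp::export]]
DataFrame dm_map_occurrences(SEXP xp_, CharacterVector queries, double max_mm_frac) {
  XPtr<KmerIndex> xp(xp_);
  int k = xp->k;
  std::vector<int> q_out, c_out, s_out, mm_out;
  std::vector<std::string> strand_out;
  std::vector<KmerHit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string rd = as<std::string>(queries[qi]);
    int len = (int)rd.size();
    if (len < k) continue;
    extract_kmers(rd, k, hits);
    std::unordered_set<uint64_t> cands;
    for (const auto& h : hits) {
      auto it = xp->occ.find(h.canon);
      if (it == xp->occ.end()) continue;
      for (uint64_t p : it->second) {
        int ci = (int)(p >> 32);
        int cpos = (int)((p >> 1) & 0x7FFFFFFF);
        bool erc = p & 1;
        bool minus = (erc != h.rc);
        int off = minus ? cpos - (len - k - h.pos) : cpos - h.pos;
        if (off < 0 || off + len > (int)xp->seqs[ci].size()) continue;
        cands.insert(((uint64_t)ci << 33) | ((uint64_t)off << 1) | (minus ? 1 : 0));
      }
    }
    std::string rdrc = revcomp_str(rd);
    int max_mm = (int)std::floor(max_mm_frac * len);
    for (uint64_t key : cands) {
      int ci = (int)(key >> 33);
      int off = (int)((key >> 1) & 0xFFFFFFFF);
      bool minus = key & 1;
      const std::string& q = minus ? rdrc : rd;
      int mm = count_mismatch_range(q, 0, xp->seqs[ci], off, len, max_mm);
      if (mm > max_mm) continue;
      q_out.push_back(qi + 1); c_out.push_back(ci + 1); s_out.push_back(off);
      strand_out.push_back(minus ? "-" : "+"); mm_out.push_back(mm);
    }
  }
  return DataFrame::create(_["query"] = q_out, _["contig"] = c_out,
                           _["start"] = s_out, _["strand"] = strand_out,
                           _["nmm"] = mm_out, _["stringsAsFactors"] = false);
}

// Long-read mapper: seeds binned by (contig, strand, diagonal band of
// band_frac * read length); best adjacent-band window wins if it holds
// >= min_chain_seeds seeds. Interval spans first-to-last seed.
// [[Rcpp::export]]
DataFrame dm_map_long(SEXP xp_, CharacterVector reads, int min_chain_seeds,
                      double band_frac) {
  XPtr<KmerIndex> xp(xp_);
  int k = xp->k;
  int n = reads.size();
  IntegerVector contig(n, NA_INTEGER), start(n, NA_INTEGER), end(n, NA_INTEGER),
    nseed(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);
  std::vector<KmerHit> hits;
  for (int ri = 0; ri < n; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    int len = (int)rd.size();
    if (len < k) continue;
    extract_kmers(rd, k, hits);
    int band = std::max(1, (int)(band_frac * len));
    // key: contig, strand, bucket -> seed contig positions
    std::unordered_map<uint64_t, int> cnt;
    std::vector<std::pair<uint64_t, int>> seedpos; // key -> contig pos
    for (const auto& h : hits) {
      auto it = xp->occ.find(h.canon);
      if (it == xp->occ.end()) continue;
      if (it->second.size() > 200) continue;
      for (uint64_t p : it->second) {
        int ci = (int)(p >> 32);
        int cpos = (int)((p >> 1) & 0x7FFFFFFF);
        bool erc = p & 1;
        bool minus = (erc != h.rc);
        long diag = minus ? (long)cpos - (long)(len - k - h.pos)
                          : (long)cpos - (long)h.pos;
        long bucket = (diag + 2000000000L) / band; // shift to keep positive
        uint64_t key = ((uint64_t)ci << 33) | ((uint64_t)bucket << 1) | (minus ? 1 : 0);
        cnt[key]++;
        seedpos.push_back({key, cpos});
      }
    }
    if (cnt.empty()) continue;
    // window = bucket b + bucket b+1
    bool have = false; uint64_t bk = 0; int bv = -1;
    for (const auto& kv : cnt) {
      uint64_t next = kv.first + 2; // same contig/strand, bucket+1
      int tot = kv.second;
      auto it2 = cnt.find(next);
      if (it2 != cnt.end()) tot += it2->second;
      if (tot > bv) { bv = tot; bk = kv.first; have = true; }
      else if (tot == bv) {
        int ci1 = (int)(kv.first >> 33), ci2 = (int)(bk >> 33);
        const std::string& id1 = xp->ids[ci1];
        const std::string& id2 = xp->ids[ci2];
        uint64_t b1 = (kv.first >> 1) & 0xFFFFFFFF, b2 = (bk >> 1) & 0xFFFFFFFF;
        bool m1 = kv.first & 1, m2 = bk & 1;
        if (std::tie(id1, b1, m1) < std::tie(id2, b2, m2)) bk = kv.first;
      }
    }
    if (!have || bv < min_chain_seeds) continue;
    int ci = (int)(bk >> 33);
    int mn = INT32_MAX, mx = -1;
    for (const auto& sp : seedpos) {
      if (sp.first == bk || sp.first == bk + 2) {
        mn = std::min(mn, sp.second); mx = std::max(mx, sp.second);
      }
    }
    contig[ri] = ci + 1;
    start[ri] = mn;
    end[ri] = std::min((int)xp->seqs[ci].size(), mx + k);
    strand[ri] = (bk & 1) ? "-" : "+";
    nseed[ri] = bv;
  }
  return DataFrame::create(_["contig"] = contig, _["start"] = start,
                           _["end"] = end, _["strand"] = strand,
                           _["score"] = nseed, _["stringsAsFactors"] = false);
}

// ------------------------------------------------------------ assembler ----

// De Bruijn unitig assembly over canonical k-mers with an abundance floor.
// Unitigs are emitted in the lexicographically smaller orientation, sorted by
// (length desc, sequence asc).
// [[Rcpp::export]]
CharacterVector dm_assemble(CharacterVector reads, int k, int min_count) {
  if (k % 2 == 0 || k < 3 || k > 31) stop("k must be odd, 3 <= k <= 31");
  std::unordered_map<uint64_t, uint32_t> cnt;
  std::vector<KmerHit> hits;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    extract_kmers(rd, k, hits);
    for (const auto& h : hits) cnt[h.canon]++;
  }
  // node set: both orientations of kept canonical kmers
  std::unordered_set<uint64_t> S;
  S.reserve(cnt.size() * 2);
  for (const auto& kv : cnt) {
    if ((int)kv.second >= min_count) {
      S.insert(kv.first);
      S.insert(rc_kmer(kv.first, k));
    }
  }
  cnt.clear();
  if (S.empty()) return CharacterVector(0);
  uint64_t mask = (1ULL << (2 * k)) - 1;
  auto out_neighbors = [&](uint64_t x, uint64_t* nb) {
    int m = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = ((x << 2) | b) & mask;
      if (S.count(y)) nb[m++] = y;
    }
    return m;
  };
  auto in_degree = [&](uint64_t x) {
    int m = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = (x >> 2) | (b << (2 * (k - 1)));
      if (S.count(y)) ++m;
    }
    return m;
  };
  // unique extension: outdeg(x)==1 and indeg(succ)==1
  auto unique_next = [&](uint64_t x, uint64_t& y) {
    uint64_t nb[4];
    if (out_neighbors(x, nb) != 1) return false;
    if (in_degree(nb[0]) != 1) return false;
    y = nb[0];
    return true;
  };
  auto unique_prev = [&](uint64_t x, uint64_t& y) {
    uint64_t pb[4]; int m = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t p = (x >> 2) | (b << (2 * (k - 1)));
      if (S.count(p)) pb[m++] = p;
    }
    if (m != 1) return false;
    uint64_t nb[4];
    if (out_neighbors(pb[0], nb) != 1) return false;
    y = pb[0];
    return true;
  };
  std::unordered_set<uint64_t> visited;
  visited.reserve(S.size());
  std::unordered_set<std::string> emitted;
  std::vector<std::string> unitigs;
  auto walk_from = [&](uint64_t u) {
    std::string seq = kmer_string(u, k);
    visited.insert(u);
    uint64_t x = u, y;
    while (unique_next(x, y)) {
      if (visited.count(y)) break; // guard cycles
      seq.push_back(CODE_BASE[y & 3]);
      visited.insert(y);
      x = y;
    }
    std::string rc = revcomp_str(seq);
    const std::string& canon = (seq <= rc) ? seq : rc;
    // the twin walk is discovered independently; dedupe on canonical sequence
    if (emitted.insert(canon).second) unitigs.push_back(canon);
  };
  // pass 1: path starts (no unique predecessor)
  std::vector<uint64_t> nodes(S.begin(), S.end());
  std::sort(nodes.begin(), nodes.end()); // deterministic iteration
  uint64_t dummy;
  for (uint64_t u : nodes) {
    if (visited.count(u)) continue;
    if (!unique_prev(u, dummy)) walk_from(u);
  }
  // pass 2: leftovers are perfect cycles
  for (uint64_t u : nodes) {
    if (!visited.count(u)) walk_from(u);
  }
  std::sort(unitigs.begin(), unitigs.end(), [](const std::string& a, const std::string& b) {
    if (a.size() != b.size()) return a.size() > b.size();
    return a < b;
  });
  return wrap(unitigs);
}

// canonical k-mer counts >= floor_count (abundance histogram support)
// [[Rcpp::export]]
IntegerVector dm_kmer_counts(CharacterVector reads, int k, int floor_count) {
  std::unordered_map<uint64_t, uint32_t> cnt;
  std::vector<KmerHit> hits;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    extract_kmers(rd, k, hits);
    for (const auto& h : hits) cnt[h.canon]++;
  }
  std::vector<int> out;
  for (const auto& kv : cnt)
    if ((int)kv.second >= floor_count) out.push_back((int)kv.second);
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// -------------------------------------------------------------- anchors ----

// Locate contigs on long reads via k-mers unique within the contig set;
// per (read, contig, orientation, diagonal band) clusters with
// >= min_anchor_kmers hits become anchors; anchors are chained left-to-right
// per read, discarding read-interval overlaps by keeping the higher count.
// [[Rcpp::export]]
DataFrame dm_anchor(CharacterVector contigs, CharacterVector reads, int k,
                    int min_anchor_kmers, double band_frac) {
  // unique-kmer map: canonical -> (contig, pos, rc); multi-occurring dropped
  std::unordered_map<uint64_t, uint64_t> uniq;
  std::unordered_set<uint64_t> banned;
  std::vector<KmerHit> hits;
  std::vector<int> clen(contigs.size());
  for (int ci = 0; ci < contigs.size(); ++ci) {
    std::string s = as<std::string>(contigs[ci]);
    clen[ci] = (int)s.size();
    extract_kmers(s, k, hits);
    for (const auto& h : hits) {
      if (banned.count(h.canon)) continue;
      auto it = uniq.find(h.canon);
      if (it != uniq.end()) { uniq.erase(it); banned.insert(h.canon); continue; }
      uniq[h.canon] = ((uint64_t)ci << 32) | ((uint64_t)h.pos << 1) | (h.rc ? 1 : 0);
    }
  }
  std::vector<int> r_out, c_out, rs_out, re_out, cs_out, ce_out, nk_out;
  std::vector<int> or_out;
  struct Anc { int contig; int orient; int rs, re, cs, ce, nk; };
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    int len = (int)rd.size();
    if (len < k) continue;
    extract_kmers(rd, k, hits);
    int band = std::max(1, (int)(band_frac * len));
    // bucketed hits: key (contig, orient, bucket)
    struct HitRec { int rpos, cpos; };
    std::unordered_map<uint64_t, std::vector<HitRec>> clusters;
    for (const auto& h : hits) {
      auto it = uniq.find(h.canon);
      if (it == uniq.end()) continue;
      uint64_t p = it->second;
      int ci = (int)(p >> 32);
      int cpos = (int)((p >> 1) & 0x7FFFFFFF);
      bool erc = p & 1;
      bool minus = (erc != h.rc);
      long diag = minus ? (long)cpos + (long)h.pos : (long)cpos - (long)h.pos;
      long bucket = (diag + 2000000000L) / band;
      uint64_t key = ((uint64_t)ci << 33) | ((uint64_t)bucket << 1) | (minus ? 1 : 0);
      clusters[key].push_back({h.pos, cpos});
    }
    // merge adjacent buckets: a cluster owns bucket b if bucket b-1 absent;
    // it absorbs bucket b+1 (chains split across a boundary re-join)
    std::vector<Anc> ancs;
    for (const auto& kv : clusters) {
      uint64_t prev = kv.first - 2;
      if (clusters.count(prev)) continue; // absorbed by the previous bucket
      std::vector<HitRec> all = kv.second;
      auto nx = clusters.find(kv.first + 2);
      if (nx != clusters.end())
        all.insert(all.end(), nx->second.begin(), nx->second.end());
      if ((int)all.size() < min_anchor_kmers) continue;
      int ci = (int)(kv.first >> 33);
      bool minus = kv.first & 1;
      int rs = INT32_MAX, re = -1, cs = INT32_MAX, ce = -1;
      for (const auto& h : all) {
        rs = std::min(rs, h.rpos); re = std::max(re, h.rpos + k);
        cs = std::min(cs, h.cpos); ce = std::max(ce, h.cpos + k);
      }
      ancs.push_back({ci, minus ? -1 : 1, rs, re, cs, ce, (int)all.size()});
    }
    // chain: sort by kmer count desc, keep non-overlapping on the read
    std::sort(ancs.begin(), ancs.end(), [](const Anc& a, const Anc& b) {
      if (a.nk != b.nk) return a.nk > b.nk;
      if (a.rs != b.rs) return a.rs < b.rs;
      return a.contig < b.contig;
    });
    std::vector<Anc> kept;
    for (const auto& a : ancs) {
      bool clash = false;
      for (const auto& b : kept) {
        int ov = std::min(a.re, b.re) - std::max(a.rs, b.rs);
        if (ov > (int)(0.25 * std::min(a.re - a.rs, b.re - b.rs))) { clash = true; break; }
      }
      if (!clash) kept.push_back(a);
    }
    std::sort(kept.begin(), kept.end(), [](const Anc& a, const Anc& b) {
      return a.rs < b.rs;
    });
    for (const auto& a : kept) {
      r_out.push_back(ri + 1); c_out.push_back(a.contig + 1);
      or_out.push_back(a.orient);
      rs_out.push_back(a.rs); re_out.push_back(a.re);
      cs_out.push_back(a.cs); ce_out.push_back(a.ce);
      nk_out.push_back(a.nk);
    }
  }
  return DataFrame::create(_["read"] = r_out, _["contig"] = c_out,
                           _["orient"] = or_out,
                           _["read_start"] = rs_out, _["read_end"] = re_out,
                           _["contig_start"] = cs_out, _["contig_end"] = ce_out,
                           _["n_kmers"] = nk_out, _["stringsAsFactors"] = false);
}

// -------------------------------------------------- containment cluster ----

// Greedy incremental containment clustering (CD-HIT flavored): sequences must
// arrive sorted (length desc, sequence asc). Each sequence joins the first
// founded cluster whose representative aligns ungapped (best seed-voted
// offset, better strand) at >= min_id over >= min_cov of the shorter
// sequence, else founds a cluster. Returns 1-based representative index per
// sequence plus the realized identity/coverage.
// [[Rcpp::export]]
DataFrame dm_greedy_cluster(CharacterVector seqs, int k, double min_id,
                            double min_cov) {
  int n = seqs.size();
  IntegerVector rep(n);
  NumericVector identity(n), coverage(n);
  std::unordered_map<uint64_t, std::vector<uint64_t>> occ; // canon -> (rep<<33|pos<<1|rc)
  std::vector<std::string> reps_seq;
  std::vector<int> reps_orig;
  std::vector<KmerHit> hits;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = (int)s.size();
    extract_kmers(s, k, hits);
    // vote per (rep, strand, offset)
    std::unordered_map<uint64_t, int> votes;
    for (const auto& h : hits) {
      auto it = occ.find(h.canon);
      if (it == occ.end()) continue;
      for (uint64_t p : it->second) {
        int rj = (int)(p >> 33);
        int rpos = (int)((p >> 1) & 0xFFFFFFFF);
        bool erc = p & 1;
        bool minus = (erc != h.rc);
        long off = minus ? (long)rpos - (long)(len - k - h.pos)
                         : (long)rpos - (long)h.pos;
        uint64_t key = ((uint64_t)rj << 34) | ((uint64_t)(off + 1000000000L) << 1) |
          (minus ? 1 : 0);
        votes[key]++;
      }
    }
    // per-rep best offset, reps tried in founding order
    std::unordered_map<int, std::pair<int, uint64_t>> best_per_rep;
    for (const auto& kv : votes) {
      int rj = (int)(kv.first >> 34);
      auto it = best_per_rep.find(rj);
      if (it == best_per_rep.end() || kv.second > it->second.first ||
          (kv.second == it->second.first && kv.first < it->second.second))
        best_per_rep[rj] = {kv.second, kv.first};
    }
    std::vector<int> cand;
    for (const auto& kv : best_per_rep) cand.push_back(kv.first);
    std::sort(cand.begin(), cand.end());
    int joined = -1; double jid = 0, jcov = 0;
    std::string srev = revcomp_str(s);
    for (int rj : cand) {
      uint64_t key = best_per_rep[rj].second;
      long off = (long)((key >> 1) & 0x1FFFFFFFF) - 1000000000L;
      bool minus = key & 1;
      const std::string& rs = reps_seq[rj];
      const std::string& q = minus ? srev : s;
      // overlap on rep coordinates
      long qs = std::max(0L, -off);              // query start
      long rs0 = std::max(0L, off);              // rep start
      long ov = std::min((long)q.size() - qs, (long)rs.size() - rs0);
      if (ov <= 0) continue;
      int shorter = std::min((int)q.size(), (int)rs.size());
      double cov = (double)ov / shorter;
      if (cov < min_cov) continue;
      int mm = count_mismatch_range(q, (int)qs, rs, (int)rs0, (int)ov, (int)ov);
      double id = (double)(ov - mm) / ov;
      if (id < min_id) continue;
      joined = rj; jid = id; jcov = cov;
      break;
    }
    if (joined >= 0) {
      rep[i] = reps_orig[joined] + 1;
      identity[i] = jid; coverage[i] = jcov;
    } else {
      int rj = (int)reps_seq.size();
      reps_seq.push_back(s);
      reps_orig.push_back(i);
      rep[i] = i + 1; identity[i] = 1.0; coverage[i] = 1.0;
      extract_kmers(s, k, hits);
      for (const auto& h : hits)
        occ[h.canon].push_back(((uint64_t)rj << 33) | ((uint64_t)h.pos << 1) |
                               (h.rc ? 1 : 0));
    }
  }
  return DataFrame::create(_["rep"] = rep, _["identity"] = identity,
                           _["coverage"] = coverage,
                           _["stringsAsFactors"] = false);
}

// Single ungapped pair alignment at the best seed-voted offset (both strands).
// Returns identity over the overlap and coverage of the shorter sequence.
// [[Rcpp::export]]
List dm_pair_align(std::string a, std::string b, int k) {
  std::vector<KmerHit> ha, hb;
  extract_kmers(a, k, ha);
  std::unordered_map<uint64_t, std::vector<std::pair<int,bool>>> amap;
  for (const auto& h : ha) amap[h.canon].push_back({h.pos, h.rc});
  extract_kmers(b, k, hb);
  int blen = (int)b.size();
  std::unordered_map<long long, int> votes; // (strand, offset on a)
  for (const auto& h : hb) {
    auto it = amap.find(h.canon);
    if (it == amap.end()) continue;
    for (const auto& ap : it->second) {
      bool minus = (ap.second != h.rc);
      long off = minus ? (long)ap.first - (long)(blen - k - h.pos)
                       : (long)ap.first - (long)h.pos;
      votes[((long long)(off + 1000000000L) << 1) | (minus ? 1 : 0)]++;
    }
  }
  if (votes.empty())
    return List::create(_["identity"] = 0.0, _["coverage"] = 0.0,
                        _["overlap"] = 0, _["offset"] = NA_INTEGER,
                        _["strand"] = NA_STRING);
  long long bk = 0; int bv = -1;
  for (const auto& kv : votes)
    if (kv.second > bv || (kv.second == bv && kv.first < bk)) { bv = kv.second; bk = kv.first; }
  long off = (long)(bk >> 1) - 1000000000L;
  bool minus = bk & 1;
  std::string q = minus ? revcomp_str(b) : b;
  long qs = std::max(0L, -off), as0 = std::max(0L, off);
  long ov = std::min((long)q.size() - qs, (long)a.size() - as0);
  if (ov <= 0)
    return List::create(_["identity"] = 0.0, _["coverage"] = 0.0,
                        _["overlap"] = 0, _["offset"] = (int)off,
                        _["strand"] = minus ? "-" : "+");
  int mm = count_mismatch_range(q, (int)qs, a, (int)as0, (int)ov, (int)ov);
  int shorter = std::min((int)a.size(), (int)b.size());
  return List::create(_["identity"] = (double)(ov - mm) / ov,
                      _["coverage"] = (double)ov / shorter,
                      _["overlap"] = (int)ov, _["offset"] = (int)off,
                      _["strand"] = minus ? "-" : "+");
}

// -------------------------------------------------------------- polish ----

// Majority-vote substitution polishing from ungapped short-read placements.
// aln_*: 1-based contig index, 0-based start, strand "-" means the read maps
// reverse complemented.
// [[Rcpp::export]]
List dm_polish(CharacterVector contigs, IntegerVector aln_contig,
               IntegerVector aln_start, CharacterVector aln_strand,
               CharacterVector read_seqs, int min_depth, double min_frac) {
  int nc = contigs.size();
  std::vector<std::string> seqs(nc);
  std::vector<std::vector<std::array<uint32_t, 4>>> counts(nc);
  for (int i = 0; i < nc; ++i) {
    seqs[i] = as<std::string>(contigs[i]);
    counts[i].assign(seqs[i].size(), {0, 0, 0, 0});
  }
  int na = aln_contig.size();
  for (int a = 0; a < na; ++a) {
    if (aln_contig[a] == NA_INTEGER) continue;
    int ci = aln_contig[a] - 1;
    int st = aln_start[a];
    std::string rd = as<std::string>(read_seqs[a]);
    if (as<std::string>(aln_strand[a]) == "-") rd = revcomp_str(rd);
    int len = (int)rd.size();
    int clen = (int)seqs[ci].size();
    for (int i = std::max(0, -st); i < len && st + i < clen; ++i) {
      int c = base_code(rd[i]);
      if (c >= 0) counts[ci][st + i][c]++;
    }
  }
  CharacterVector out(nc);
  IntegerVector ncorr(nc);
  for (int ci = 0; ci < nc; ++ci) {
    int corr = 0;
    std::string s = seqs[ci];
    for (size_t i = 0; i < s.size(); ++i) {
      uint32_t tot = 0, best = 0; int bb = -1;
      for (int b = 0; b < 4; ++b) {
        tot += counts[ci][i][b];
        if (counts[ci][i][b] > best) { best = counts[ci][i][b]; bb = b; }
      }
      if ((int)tot >= min_depth && bb >= 0 &&
          (double)best / tot >= min_frac && s[i] != CODE_BASE[bb]) {
        s[i] = CODE_BASE[bb];
        ++corr;
      }
    }
    out[ci] = s;
    ncorr[ci] = corr;
  }
  return List::create(_["seq"] = out, _["n_corrections"] = ncorr);
}

// ------------------------------------------------------------ utilities ----

// [[Rcpp::export]]
int dm_edit_distance(std::string a, std::string b) {
  size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  if ((double)n * (double)m > 6e8) stop("sequences too long for full DP");
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min({sub, prev[j] + 1, cur[j - 1] + 1});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
CharacterVector dm_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// Canonical tetranucleotide frequency matrix (136 classes, rows sum to 1).
// [[Rcpp::export]]
NumericMatrix dm_tnf(CharacterVector seqs) {
  // canonical class mapping over 256 4-mers
  std::vector<int> cls(256, -1);
  int nclass = 0;
  for (int x = 0; x < 256; ++x) {
    int r = (int)rc_kmer((uint64_t)x, 4);
    int c = std::min(x, r);
    if (cls[c] < 0) cls[c] = nclass++;
    cls[x] = cls[c];
  }
  NumericMatrix out(seqs.size(), nclass);
  std::vector<KmerHit> hits;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    extract_kmers(s, 4, hits);
    double tot = 0;
    for (const auto& h : hits) {
      // canonical kmer value < 256; class by canonical value
      out(i, cls[(int)h.canon]) += 1.0;
      tot += 1.0;
    }
    if (tot > 0)
      for (int j = 0; j < nclass; ++j) out(i, j) /= tot;
  }
  return out;
}

// Apply planted substitutions: at (read[i], pos[i]) replace the base by
// (base + off[i]) mod 4, off in 1..3 (never the identity). 1-based indices.
// [[Rcpp::export]]
CharacterVector dm_apply_subs(CharacterVector seqs, IntegerVector read,
                              IntegerVector pos, IntegerVector off) {
  std::vector<std::string> s(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < read.size(); ++i) {
    int r = read[i] - 1, p = pos[i] - 1;
    if (r < 0 || r >= (int)s.size() || p < 0 || p >= (int)s[r].size()) continue;
    int c = base_code(s[r][p]);
    if (c < 0) continue;
    s[r][p] = CODE_BASE[(c + off[i]) & 3];
  }
  return wrap(s);
}

// Hamming distance between equal-length strings (vectorized over pairs).
// [[Rcpp::export]]
IntegerVector dm_hamming(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    if (x.size() != y.size()) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (size_t j = 0; j < x.size(); ++j) if (x[j] != y[j]) ++mm;
    out[i] = mm;
  }
  return out;
}
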