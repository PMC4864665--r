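// Alignment and sequence kernels for the amplicon pipeline.
//
// Identity here is always "matching columns / total alignment columns" of an
// optimal semi-global alignment: the shorter sequence is aligned end to end
// and terminal gaps are free only on the longer one, under match +1,
// mismatch -1 and gap -2 (gaps heavier than mismatches, as in the standard
// identity-clustering tools), with
// terminal gaps free (semi-global), so reads shortened by quality trimming are
// not penalised against longer centroids.  Among equal-score alignments the
// one with more matches (then fewer columns) is taken, which makes the
// reported identity deterministic without a traceback.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

namespace {

struct Cell {
  int s;  // score (possibly scaled by 2 for half-integer penalties)
  int m;  // matching columns on the best path
  int c;  // total columns on the best path
};

inline bool cell_less(const Cell& a, const Cell& b) {
  if (a.s != b.s) return a.s < b.s;
  if (a.m != b.m) return a.m < b.m;
  return a.c > b.c;  // prefer fewer columns
}

inline Cell cell_max(const Cell& a, const Cell& b) {
  return cell_less(a, b) ? b : a;
}

inline int base_code(char x) {
  switch (x) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: never matches
  }
}

// ---- semi-global identity ------------------------------------------------

// Optimal end-free alignment of a vs b under unit costs.  band < 0 means full
// dynamic programming; otherwise only cells within `band` of the main
// diagonal (widened by the length difference) are filled.
// Packed-cell DP: (score, matches, -columns) packed lexicographically into
// one int64 so the per-cell max is a single integer comparison.
// layout: score+BIAS in bits 44.., matches in bits 24..43, (CMAX - cols) in
// bits 0..23.  Field widths leave ample headroom for reads up to ~2 kb.
static const int64_t PK_BIAS = 4096;
static const int64_t PK_CMAX = (1 << 23) - 1;
inline int64_t pk(int s, int m, int c) {
  return ((int64_t)(s + PK_BIAS) << 44) | ((int64_t)m << 24) |
         (int64_t)(PK_CMAX - c);
}
inline int pk_m(int64_t v) { return (int)((v >> 24) & 0xFFFFF); }
inline int pk_c(int64_t v) { return (int)(PK_CMAX - (v & 0xFFFFFF)); }
inline int pk_s(int64_t v, int bias = 0) { return (int)((v >> 44) - PK_BIAS); }
// step deltas: diagonal match +1/+1/+1, mismatch -1/0/+1, gap -2/0/+1
static const int64_t D_MATCH = (1LL << 44) + (1LL << 24) - 1;
static const int64_t D_MISM  = -(1LL << 44) - 1;
static const int64_t D_GAP   = -(2LL << 44) - 1;
static const int64_t PK_NEG  = INT64_MIN / 4;

Cell sg_align_best(const char* a0, int la0, const char* b0, int lb0, int band) {
  if (la0 == 0 || lb0 == 0) return Cell{ 0, 0, 0 };
  // the shorter sequence is aligned end to end; terminal gaps are free only
  // on the longer one (otherwise unrelated sequences could score a perfect
  // micro-overlap and report identity 1)
  const char* a = a0; const char* b = b0; int la = la0, lb = lb0;
  if (la > lb) { a = b0; b = a0; la = lb0; lb = la0; }
  int widen = lb - la;
  int lo_off, hi_off;  // allowed j - i range
  if (band < 0) {
    lo_off = -la; hi_off = lb;
  } else {
    lo_off = -band;
    hi_off = band + widen;
  }
  int width = hi_off - lo_off + 1;
  std::vector<int64_t> prev(width + 2, PK_NEG), cur(width + 2, PK_NEG);
  auto idx = [&](int i, int j) { return j - i - lo_off + 1; };

  // row 0: skipping b's prefix is free
  for (int j = 0; j <= lb; ++j) {
    if (j < lo_off || j > hi_off) continue;
    prev[idx(0, j)] = pk(0, 0, 0);
  }
  int64_t best = PK_NEG;
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), PK_NEG);
    int jmin = std::max(0, i + lo_off);
    int jmax = std::min(lb, i + hi_off);
    if (jmin > jmax) break;
    const char ai = a[i - 1];
    int64_t* prow = prev.data() - (i - 1) - lo_off + 1;
    int64_t* crow = cur.data() - i - lo_off + 1;
    for (int j = jmin; j <= jmax; ++j) {
      int64_t v = PK_NEG;
      if (j == 0) {
        // gap columns before b starts are paid (a must align end to end)
        v = pk(-2 * i, 0, i);
      } else {
        int ca = base_code(ai), cb = base_code(b[j - 1]);
        int64_t d = prow[j - 1] + ((ca >= 0 && ca == cb) ? D_MATCH : D_MISM);
        int64_t u = prow[j] + D_GAP;
        int64_t l = crow[j - 1] + D_GAP;
        v = std::max(d, std::max(u, l));
      }
      crow[j] = v;
      if (i == la) best = std::max(best, v);  // skipping b's tail is free
    }
    std::swap(prev, cur);
  }
  if (best <= PK_NEG / 2) return Cell{ 0, 0, 0 };
  return Cell{ pk_s(best), pk_m(best), pk_c(best) };
}

// Identity in [0,1]; sequences with no positively scoring overlap get 0.
double sg_identity_one(const char* a, int la, const char* b, int lb, int band) {
  if (la == 0 || lb == 0) return NA_REAL;
  Cell best = sg_align_best(a, la, b, lb, band);
  if (best.c <= 0) return 0.0;
  return (double)best.m / (double)best.c;
}

// Identity of a query against a centroid; when both carry a junction (> 0,
// concatenated amplicons with possibly different junction geometry) the two
// halves are aligned separately and pooled, so junction-length differences
// between the quality-trimming passes are not charged as internal gaps.
double query_identity(const char* q, int lq, int qj,
                      const char* c, int lc, int cj, int band) {
  if (qj > 0 && cj > 0 && qj < lq && cj < lc) {
    Cell f = sg_align_best(q, qj, c, cj, band);
    Cell r = sg_align_best(q + qj, lq - qj, c + cj, lc - cj, band);
    int m = f.m + r.m, cols = f.c + r.c;
    return cols > 0 ? (double)m / (double)cols : 0.0;
  }
  return sg_identity_one(q, lq, c, lc, band);
}

// ---- k-mer screening -----------------------------------------------------

// Collect the 2-bit-encoded k-mers of a sequence (windows containing N are
// skipped).
void collect_kmers(const char* s, int n, int k, std::vector<uint32_t>& out) {
  out.clear();
  if (n < k) return;
  uint32_t kmer = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)c) & mask;
    if (++valid >= k) out.push_back(kmer);
  }
}

// Posting-list index from k-mer to centroid ids.
struct KmerIndex {
  int k;
  std::unordered_map<uint32_t, std::vector<int>> post;
  explicit KmerIndex(int k_) : k(k_) {}
  void add(const char* s, int n, int id, std::vector<uint32_t>& scratch) {
    collect_kmers(s, n, k, scratch);
    for (uint32_t km : scratch) post[km].push_back(id);
  }
};

// Max mismatches compatible with `threshold` on a query of length lq, padded
// for indel/terminal slack.
inline int allowed_mismatches(int lq, double threshold) {
  return (int)std::floor((1.0 - threshold) * lq + 1e-9) + 3;
}

}  // namespace

// [[Rcpp::export(name = ".sg_identity_cpp")]]
NumericVector sg_identity_cpp(CharacterVector a, CharacterVector b, int band) {
  int n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, i));
    const char* sb = CHAR(STRING_ELT(b, i));
    out[i] = sg_identity_one(sa, (int)std::strlen(sa), sb, (int)std::strlen(sb), band);
  }
  return out;
}

// Greedy first-fit clustering: sequences are scanned in the given order; each
// joins the FIRST existing centroid (in founding = abundance order) with
// identity >= threshold, else founds a new centroid.  Returns the 1-based
// centroid index per input sequence; new centroids are identified by the
// sequence's own index appearing for the first time.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold,
                                 int band, int kmer_k, int screen_from) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<const char*> cent;
  std::vector<int> cent_len;
  KmerIndex index(kmer_k);
  std::vector<uint32_t> scratch, qkmers;
  std::vector<int> shared;         // per-centroid shared k-mer counts
  std::vector<int> touched;

  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(seqs, i));
    int lq = (int)std::strlen(q);
    int nc = (int)cent.size();
    int hit = -1;
    bool use_screen = nc >= screen_from && lq >= 4 * kmer_k;
    if (!use_screen) {
      for (int c = 0; c < nc; ++c) {
        double id = sg_identity_one(q, lq, cent[c], cent_len[c], band);
        if (id >= threshold) { hit = c; break; }
      }
    } else {
      collect_kmers(q, lq, kmer_k, qkmers);
      if ((int)shared.size() < nc) shared.resize(nc, 0);
      touched.clear();
      for (uint32_t km : qkmers) {
        auto it = index.post.find(km);
        if (it == index.post.end()) continue;
        for (int c : it->second) {
          if (shared[c] == 0) touched.push_back(c);
          shared[c]++;
        }
      }
      int m_allow = allowed_mismatches(lq, threshold);
      int min_shared = std::max(1, (lq - kmer_k + 1) - kmer_k * m_allow - 2 * kmer_k);
      std::sort(touched.begin(), touched.end());  // first-fit order
      for (int c : touched) {
        if (shared[c] < min_shared) continue;
        double id = sg_identity_one(q, lq, cent[c], cent_len[c], band);
        if (id >= threshold) { hit = c; break; }
      }
      for (int c : touched) shared[c] = 0;
    }
    if (hit < 0) {
      cent.push_back(q);
      cent_len.push_back(lq);
      index.add(q, lq, (int)cent.size() - 1, scratch);
      assign[i] = (int)cent.size();  // centroid id in founding order
    } else {
      assign[i] = hit + 1;
    }
  }
  return assign;
}

// Best-fit mapping of query sequences to fixed centroids.  Each query is
// assigned to the centroid of maximal identity if that identity >= threshold
// (ties toward the earlier centroid), else 0.  A k-mer prescreen limits which
// centroids are aligned once there are >= screen_from of them.  qjunc/cjunc
// give concatenation junctions (0 = merged read, identity on the full
// sequence; > 0 = identity pooled over the two halves).
// [[Rcpp::export(name = ".map_to_centroids_cpp")]]
List map_to_centroids_cpp(CharacterVector seqs, IntegerVector qjunc,
                          CharacterVector centroids, IntegerVector cjunc,
                          double threshold, int band, int kmer_k,
                          int screen_from) {
  int n = seqs.size(), nc = centroids.size();
  if (qjunc.size() != n || cjunc.size() != nc)
    stop("junction vectors must match sequence vectors");
  std::vector<const char*> cent(nc);
  std::vector<int> cent_len(nc);
  KmerIndex index(kmer_k);
  std::vector<uint32_t> scratch;
  for (int c = 0; c < nc; ++c) {
    cent[c] = CHAR(STRING_ELT(centroids, c));
    cent_len[c] = (int)std::strlen(cent[c]);
    index.add(cent[c], cent_len[c], c, scratch);
  }
  IntegerVector best_idx(n);
  NumericVector best_id(n);
  std::vector<int> shared(nc, 0), touched;
  std::vector<uint32_t> qkmers;

  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(seqs, i));
    int lq = (int)std::strlen(q);
    int qj = qjunc[i];
    double bid = -1.0; int bc = -1;
    bool use_screen = nc >= screen_from && lq >= 4 * kmer_k;
    if (!use_screen) {
      for (int c = 0; c < nc; ++c) {
        double id = query_identity(q, lq, qj, cent[c], cent_len[c], cjunc[c], band);
        if (id > bid) { bid = id; bc = c; }
      }
    } else {
      collect_kmers(q, lq, kmer_k, qkmers);
      touched.clear();
      for (uint32_t km : qkmers) {
        auto it = index.post.find(km);
        if (it == index.post.end()) continue;
        for (int c : it->second) {
          if (shared[c] == 0) touched.push_back(c);
          shared[c]++;
        }
      }
      int m_allow = allowed_mismatches(lq, threshold);
      int min_shared = std::max(1, (lq - kmer_k + 1) - kmer_k * m_allow - 2 * kmer_k);
      std::sort(touched.begin(), touched.end());
      for (int c : touched) {
        if (shared[c] < min_shared) continue;
        double id = query_identity(q, lq, qj, cent[c], cent_len[c], cjunc[c], band);
        if (id > bid) { bid = id; bc = c; }
      }
      for (int c : touched) shared[c] = 0;
    }
    if (bc >= 0 && bid >= threshold) {
      best_idx[i] = bc + 1;
      best_id[i] = bid;
    } else {
      best_idx[i] = 0;
      best_id[i] = (bc >= 0) ? bid : NA_REAL;
    }
  }
  return List::create(_["centroid"] = best_idx, _["identity"] = best_id);
}

// ---- local (Smith-Waterman) alignment ------------------------------------

namespace {

// Banded local alignment of q vs r restricted to diagonals (j - i) in
// [d0 - w, d0 + w]; w < 0 means full matrix.  Packed-cell DP as above;
// cells restart (Smith-Waterman) whenever the running score drops to 0.
Cell sw_one(const char* q, int lq, const char* r, int lr,
            int match, int mismatch, int gap, int d0, int w) {
  int lo_off, hi_off;
  if (w < 0) { lo_off = -lq; hi_off = lr; }
  else { lo_off = d0 - w; hi_off = d0 + w; }
  int width = hi_off - lo_off + 1;
  if (width <= 0) return Cell{ 0, 0, 0 };
  const int64_t ZERO = pk(0, 0, 0);
  const int64_t dm = ((int64_t)match << 44) + (1LL << 24) - 1;
  const int64_t dx = ((int64_t)mismatch << 44) - 1;
  const int64_t dg = ((int64_t)gap << 44) - 1;
  std::vector<int64_t> prev(width + 2, PK_NEG), cur(width + 2, PK_NEG);
  int64_t best = ZERO;
  for (int j = 0; j <= lr; ++j)
    if (j >= lo_off && j <= hi_off) prev[j - lo_off + 1] = ZERO;
  for (int i = 1; i <= lq; ++i) {
    std::fill(cur.begin(), cur.end(), PK_NEG);
    int jmin = std::max(0, i + lo_off);
    int jmax = std::min(lr, i + hi_off);
    if (jmin > jmax) break;
    const char qi = q[i - 1];
    int64_t* prow = prev.data() - (i - 1) - lo_off + 1;
    int64_t* crow = cur.data() - i - lo_off + 1;
    for (int j = jmin; j <= jmax; ++j) {
      int64_t v;
      if (j == 0) {
        v = ZERO;
      } else {
        int cq = base_code(qi), cr = base_code(r[j - 1]);
        int64_t d = prow[j - 1] + ((cq >= 0 && cq == cr) ? dm : dx);
        int64_t u = prow[j] + dg;
        int64_t l = crow[j - 1] + dg;
        v = std::max(d, std::max(u, l));
        if ((v >> 44) <= PK_BIAS) v = ZERO;  // local restart at score <= 0
      }
      crow[j] = v;
      best = std::max(best, v);
    }
    std::swap(prev, cur);
  }
  return Cell{ pk_s(best), pk_m(best), pk_c(best) };
}

void revcomp_str(const char* s, int n, std::string& out) {
  out.resize(n);
  for (int i = 0; i < n; ++i) {
    char c = s[n - 1 - i], r;
    switch (c) {
      case 'A': r = 'T'; break; case 'C': r = 'G'; break;
      case 'G': r = 'C'; break; case 'T': r = 'A'; break;
      case 'a': r = 't'; break; case 'c': r = 'g'; break;
      case 'g': r = 'c'; break; case 't': r = 'a'; break;
      default: r = 'N';
    }
    out[i] = r;
  }
}

// Modal diagonal (j - i) of shared k-mers between query and an indexed
// reference; returns false when no k-mer is shared.
bool modal_diagonal(const std::vector<uint32_t>& qk,
                    const std::unordered_map<uint32_t, std::vector<int>>& rk,
                    int& d0, int& support) {
  std::unordered_map<int, int> diag;
  for (int qi = 0; qi < (int)qk.size(); ++qi) {
    auto it = rk.find(qk[qi]);
    if (it == rk.end()) continue;
    for (int rj : it->second) diag[rj - qi]++;
  }
  if (diag.empty()) return false;
  d0 = 0; support = 0;
  for (auto& kv : diag)
    if (kv.second > support || (kv.second == support && kv.first < d0)) {
      support = kv.second; d0 = kv.first;
    }
  return true;
}

}  // namespace

// All-vs-all local alignment of queries against references, both strands.
// Scores use integer match/mismatch/gap already scaled by `scale`; returned
// `score` is divided back by scale.  band_w < 0 disables banding and the
// k-mer strand screen (both strands are then aligned in full).  Returns a
// data-frame-shaped list of hits: query (1-based), ref (1-based), score,
// matches, aln_len, strand (+1/-1).  Only the best alignment per
// query/ref/strand is kept; per query/ref the better strand wins.
// [[Rcpp::export(name = ".sw_hits_cpp")]]
List sw_hits_cpp(CharacterVector queries, CharacterVector refs,
                 int match, int mismatch, int gap, int scale,
                 int band_w, int kmer_k) {
  int nq = queries.size(), nr = refs.size();
  // per-reference k-mer position index
  std::vector<std::unordered_map<uint32_t, std::vector<int>>> ridx(nr);
  std::vector<const char*> rs(nr);
  std::vector<int> rl(nr);
  std::vector<uint32_t> kms;
  for (int r = 0; r < nr; ++r) {
    rs[r] = CHAR(STRING_ELT(refs, r));
    rl[r] = (int)std::strlen(rs[r]);
    collect_kmers(rs[r], rl[r], kmer_k, kms);
    for (int p = 0; p < (int)kms.size(); ++p) ridx[r][kms[p]].push_back(p);
  }
  std::vector<int> out_q, out_r, out_m, out_c, out_s;
  std::vector<double> out_sc;
  std::string qrc;
  std::vector<uint32_t> qk_f, qk_r;
  for (int qi = 0; qi < nq; ++qi) {
    const char* q = CHAR(STRING_ELT(queries, qi));
    int lq = (int)std::strlen(q);
    revcomp_str(q, lq, qrc);
    collect_kmers(q, lq, kmer_k, qk_f);
    collect_kmers(qrc.c_str(), lq, kmer_k, qk_r);
    for (int r = 0; r < nr; ++r) {
      Cell best = { 0, 0, 0 };
      int best_strand = 0;
      if (band_w < 0) {
        Cell f = sw_one(q, lq, rs[r], rl[r], match, mismatch, gap, 0, -1);
        Cell rv = sw_one(qrc.c_str(), lq, rs[r], rl[r], match, mismatch, gap, 0, -1);
        if (!cell_less(f, rv)) { best = f; best_strand = 1; }
        else { best = rv; best_strand = -1; }
      } else {
        int d0f = 0, supf = 0, d0r = 0, supr = 0;
        bool okf = modal_diagonal(qk_f, ridx[r], d0f, supf);
        bool okr = modal_diagonal(qk_r, ridx[r], d0r, supr);
        if (okf && (!okr || supf >= supr)) {
          best = sw_one(q, lq, rs[r], rl[r], match, mismatch, gap, d0f, band_w);
          best_strand = 1;
        } else if (okr) {
          best = sw_one(qrc.c_str(), lq, rs[r], rl[r], match, mismatch, gap, d0r, band_w);
          best_strand = -1;
        }
      }
      if (best.c > 0 && best.s > 0) {
        out_q.push_back(qi + 1);
        out_r.push_back(r + 1);
        out_sc.push_back((double)best.s / (double)scale);
        out_m.push_back(best.m);
        out_c.push_back(best.c);
        out_s.push_back(best_strand);
      }
    }
  }
  return List::create(_["query"] = wrap(out_q), _["ref"] = wrap(out_r),
                      _["score"] = wrap(out_sc), _["matches"] = wrap(out_m),
                      _["aln_len"] = wrap(out_c), _["strand"] = wrap(out_s));
}

// ---- paired-read merging -------------------------------------------------

namespace {

// 2-bit packing with an N mask for bit-parallel mismatch counting.
struct Packed {
  std::vector<uint64_t> bits;   // 2 bits per base, 32 bases per word
  std::vector<uint64_t> nmask;  // 1 bit per base pair-slot (2 bits set for N)
  int n;
  void pack(const char* s, int len) {
    n = len;
    int nw = (len + 31) / 32;
    bits.assign(nw + 1, 0);
    nmask.assign(nw + 1, 0);
    for (int i = 0; i < len; ++i) {
      int c = base_code(s[i]);
      uint64_t v = (c < 0) ? 0 : (uint64_t)c;
      bits[i / 32] |= v << (2 * (i % 32));
      if (c < 0) nmask[i / 32] |= 3ull << (2 * (i % 32));
    }
  }
  // 64-bit word starting at base offset `off` (2*off bits)
  inline uint64_t word_at(const std::vector<uint64_t>& v, int off) const {
    int w = off / 32, r = 2 * (off % 32);
    uint64_t x = v[w] >> r;
    if (r) x |= v[w + 1] << (64 - r);
    return x;
  }
};

// Mismatches between a[aoff .. aoff+len) and b[0 .. len).
int count_mismatches(const Packed& a, int aoff, const Packed& b, int len) {
  int mm = 0;
  for (int p = 0; p < len; p += 32) {
    int chunk = std::min(32, len - p);
    uint64_t xa = a.word_at(a.bits, aoff + p);
    uint64_t xb = b.word_at(b.bits, p);
    uint64_t nm = a.word_at(a.nmask, aoff + p) | b.word_at(b.nmask, p);
    uint64_t x = (xa ^ xb) | nm;
    // collapse 2-bit slots: slot differs if either bit set
    uint64_t d = (x | (x >> 1)) & 0x5555555555555555ull;
    if (chunk < 32) d &= (1ull << (2 * chunk)) - 1;
    mm += __builtin_popcountll(d);
  }
  return mm;
}

}  // namespace

// Merge forward reads with reverse-complemented mates.  For each pair, every
// overlap offset is scored exactly (bit-parallel); the offset maximising
// matching bases is chosen, then the three rejection rules are applied:
// best overlap < min_overlap ("overlap"), > max_mismatches in the overlap
// ("mismatches"), merged length < min_len ("length").  In the overlap the
// base with the higher Phred score wins; merged quality is the max of the
// two.  Returns merged seq/qual and a status code (0 = merged, 1..3 the
// rejection reasons above).
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector rev_rc,
                     CharacterVector fq, CharacterVector rq,
                     int min_overlap, int max_mismatches, int min_len) {
  int n = fwd.size();
  CharacterVector out_seq(n), out_qual(n);
  IntegerVector status(n), out_overlap(n), out_mm(n);
  Packed pa, pb;
  std::string seq, qual;
  for (int i = 0; i < n; ++i) {
    const char* a = CHAR(STRING_ELT(fwd, i));
    const char* b = CHAR(STRING_ELT(rev_rc, i));
    const char* qa = CHAR(STRING_ELT(fq, i));
    const char* qb = CHAR(STRING_ELT(rq, i));
    int la = (int)std::strlen(a), lb = (int)std::strlen(b);
    pa.pack(a, la);
    pb.pack(b, lb);
    int best_matches = -1, best_o = -1, best_ov = 0, best_mm = 0;
    // offset o: position of b's start within a's coordinates (o >= 0)
    for (int o = 0; o < la; ++o) {
      int ov = std::min(la - o, lb);
      if (ov < 1 || ov <= best_matches) {
        if (ov <= best_matches) break;  // overlaps only shrink from here
        continue;
      }
      int mm = count_mismatches(pa, o, pb, ov);
      int matches = ov - mm;
      if (matches > best_matches) {
        best_matches = matches; best_o = o; best_ov = ov; best_mm = mm;
      }
    }
    if (best_o < 0) { status[i] = 1; continue; }
    out_overlap[i] = best_ov;
    out_mm[i] = best_mm;
    if (best_ov < min_overlap) { status[i] = 1; continue; }
    if (best_mm > max_mismatches) { status[i] = 2; continue; }
    int mlen = std::max(la, best_o + lb);
    if (mlen < min_len) { status[i] = 3; continue; }
    seq.assign(mlen, 'N');
    qual.assign(mlen, '!');
    for (int p = 0; p < la; ++p) { seq[p] = a[p]; qual[p] = qa[p]; }
    for (int p = 0; p < lb; ++p) {
      int t = best_o + p;
      if (t >= mlen) break;
      if (t < la) {
        // overlap: higher-quality base wins (tie keeps forward); merged
        // quality is the max of the two
        if (qb[p] > qa[t]) seq[t] = b[p];
        qual[t] = std::max(qa[t], qb[p]);
      } else {
        seq[t] = b[p]; qual[t] = qb[p];
      }
    }
    out_seq[i] = seq;
    out_qual[i] = qual;
    status[i] = 0;
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["status"] = status, _["overlap"] = out_overlap,
                      _["mismatches"] = out_mm);
}

// ---- small utilities -----------------------------------------------------

// [[Rcpp::export(name = ".rev_str_cpp")]]
CharacterVector rev_str_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(STRING_ELT(x, i));
    int len = (int)std::strlen(s);
    buf.assign(s, len);
    std::reverse(buf.begin(), buf.end());
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(STRING_ELT(x, i));
    revcomp_str(s, (int)std::strlen(s), buf);
    out[i] = buf;
  }
  return out;
}

// 1-based index of the first base whose Phred score (offset 33) is below
// qmin; 0 when all bases pass.
// [[Rcpp::export(name = ".first_below_q_cpp")]]
IntegerVector first_below_q_cpp(CharacterVector qual, int qmin) {
  int n = qual.size();
  IntegerVector out(n);
  char cut = (char)(33 + qmin);
  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(qual, i));
    int len = (int)std::strlen(q), pos = 0;
    for (int p = 0; p < len; ++p)
      if (q[p] < cut) { pos = p + 1; break; }
    out[i] = pos;
  }
  return out;
}

// Per-base substitutions at position-dependent rates (rate vector recycled at
// its last value beyond its length).  Uses the R RNG so set.seed() governs it.
// [[Rcpp::export(name = ".mutate_seqs_cpp")]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, NumericVector rate) {
  static const char BASES[4] = { 'A', 'C', 'G', 'T' };
  int n = seqs.size(), nr = rate.size();
  if (nr == 0) stop("empty rate vector");
  CharacterVector out(n);
  std::string buf;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int)std::strlen(s);
    buf.assign(s, len);
    for (int p = 0; p < len; ++p) {
      double rp = rate[p < nr ? p : nr - 1];
      if (rp <= 0) continue;
      if (unif_rand() < rp) {
        int c = base_code(buf[p]);
        if (c < 0) continue;
        int alt = (int)(unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        buf[p] = BASES[(c + 1 + alt) % 4];
      }
    }
    out[i] = buf;
  }
  return out;
}

// Monte-Carlo engine of the label-shuffling test: labels are shuffled over
// the population of correlated 18S OTUs; each shuffle, the labels landing on
// the chloroplast pairs' partner OTUs are compared to the 16S classes.
// Returns the number of shuffles with >= threshold_k matches.  partner gives,
// per chloroplast pair, the 0-based index of its partner in the population;
// pairs sharing a partner share one drawn label.
// [[Rcpp::export(name = ".shuffle_match_count_cpp")]]
double shuffle_match_count_cpp(IntegerVector pop_labels, IntegerVector partner,
                               IntegerVector class16, int threshold_k,
                               double n_shuffles) {
  int np = pop_labels.size(), m = partner.size();
  std::vector<int> labels(pop_labels.begin(), pop_labels.end());
  RNGScope scope;
  double hits = 0;
  // Fisher-Yates over the full population each shuffle keeps the multiset
  // intact by construction.
  for (double s = 0; s < n_shuffles; ++s) {
    for (int i = np - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(labels[i], labels[j]);
    }
    int k = 0;
    for (int p = 0; p < m; ++p)
      if (labels[partner[p]] == class16[p]) ++k;
    if (k >= threshold_k) hits += 1;
  }
  return hits;
}
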