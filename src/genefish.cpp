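#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <deque>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hashing (shard assignment + content fingerprints)
// ---------------------------------------------------------------------------

static inline uint64_t fnv1a64(const char *s, size_t n, uint64_t h = 1469598103934665603ULL) {
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

// murmur3 finalizer: avalanches low bits so `%% n_shards` stays unbiased even
// for near-sequential read names
static inline uint64_t mix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

// [[Rcpp::export(rng = false)]]
IntegerVector cpp_shard_of(CharacterVector ids, int n_shards, std::string salt) {
  if (n_shards < 1) stop("n_shards must be >= 1");
  R_xlen_t n = ids.size();
  IntegerVector out(n);
  uint64_t hsalt = fnv1a64(salt.c_str(), salt.size());
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(ids, i));
    uint64_t h = mix64(fnv1a64(s, std::strlen(s), hsalt));
    out[i] = (int)(h % (uint64_t)n_shards);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
std::string cpp_fingerprint(CharacterVector parts) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < parts.size(); ++i) {
    const char *s = CHAR(STRING_ELT(parts, i));
    h = fnv1a64(s, std::strlen(s), h);
    h = fnv1a64("\n", 1, h);
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// ---------------------------------------------------------------------------
// Scoring scheme
// ---------------------------------------------------------------------------

struct Scorer {
  int tab[128][128];
  int gap_first;  // cost of the first base of a gap (open + extend), positive
  int gap_ext;    // cost of each further gapped base, positive
  bool protein;
};

static const int MASK_SCORE = -100000;
static const int NEG_INF = -1000000000;

static Scorer build_scorer(const List &sc) {
  Scorer s;
  s.protein = as<bool>(sc["protein"]);
  int go = as<int>(sc["gap_open"]);   // positive costs
  int ge = as<int>(sc["gap_extend"]);
  s.gap_first = go + ge;
  s.gap_ext = ge;
  int mism = as<int>(sc["mismatch"]); // negative
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) s.tab[i][j] = mism;
  if (s.protein) {
    std::string alpha = as<std::string>(sc["alphabet"]);
    IntegerMatrix m = sc["submat"];
    for (size_t i = 0; i < alpha.size(); ++i)
      for (size_t j = 0; j < alpha.size(); ++j)
        s.tab[(int)alpha[i]][(int)alpha[j]] = m(i, j);
  } else {
    int match = as<int>(sc["match"]);
    const char *b = "ACGT";
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j)
        s.tab[(int)b[i]][(int)b[j]] = (i == j) ? match : mism;
  }
  // '\1' is the HSP masking sentinel: nothing may align across it
  for (int i = 0; i < 128; ++i) { s.tab[1][i] = MASK_SCORE; s.tab[i][1] = MASK_SCORE; }
  return s;
}

// ---------------------------------------------------------------------------
// Affine-gap local alignment (Smith-Waterman), linear memory; the alignment
// start is recovered by re-aligning the reversed prefixes.
// ---------------------------------------------------------------------------

struct SWHit {
  int score;
  int a0, a1, b0, b1;  // 0-based half-open
};

// forward pass: best score and END coordinates (first maximum in row-major order)
static void sw_forward(const char *a, int n, const char *b, int m,
                       const Scorer &sc, int &best, int &bi, int &bj) {
  std::vector<int> H(m + 1, 0), E(m + 1, NEG_INF);
  best = 0; bi = 0; bj = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0;       // H[i-1][j-1]
    int F = NEG_INF;    // gap consuming b (horizontal)
    const int *row = sc.tab[(int)(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - sc.gap_first, E[j] - sc.gap_ext);
      F = std::max(H[j - 1] - sc.gap_first, F - sc.gap_ext);
      int h = diag + row[(int)(unsigned char)b[j - 1]];
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
}

static SWHit sw_align(const char *a, int n, const char *b, int m, const Scorer &sc) {
  SWHit hit; hit.score = 0; hit.a0 = hit.a1 = hit.b0 = hit.b1 = 0;
  int best, bi, bj;
  sw_forward(a, n, b, m, sc, best, bi, bj);
  if (best <= 0) return hit;
  std::string ar(a, a + bi), br(b, b + bj);
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());
  int rbest, ri, rj;
  sw_forward(ar.c_str(), bi, br.c_str(), bj, sc, rbest, ri, rj);
  hit.score = best;
  hit.a0 = bi - ri; hit.a1 = bi;
  hit.b0 = bj - rj; hit.b1 = bj;
  return hit;
}

// [[Rcpp::export(rng = false)]]
List cpp_sw_pair(std::string a, std::string b, List scheme) {
  Scorer sc = build_scorer(scheme);
  SWHit h = sw_align(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(), sc);
  return List::create(_["score"] = h.score, _["q0"] = h.a0, _["q1"] = h.a1,
                      _["s0"] = h.b0, _["s1"] = h.b1);
}

// ---------------------------------------------------------------------------
// Seeded search: exact shared words of `seed_len` select candidate subjects;
// extension is exact affine local DP on a query window spanning the seed
// diagonals (the subject, a short read, is included in full).
// ---------------------------------------------------------------------------

static inline int dna2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(rng = false)]]
DataFrame cpp_search(std::string query, CharacterVector subjects, List scheme,
                     int seed_len, int min_score) {
  Scorer sc = build_scorer(scheme);
  int qn = (int)query.size();
  if (seed_len < 1 || seed_len > (sc.protein ? 12 : 31)) stop("unsupported seed length");
  int aidx[128];
  if (sc.protein) {
    std::string alpha = as<std::string>(scheme["alphabet"]);
    for (int i = 0; i < 128; ++i) aidx[i] = -1;
    for (size_t i = 0; i < alpha.size(); ++i) aidx[(int)alpha[i]] = (int)i;
  }
  const int shift = sc.protein ? 5 : 2;
  const uint64_t mask = (shift * seed_len >= 64) ? ~0ULL : ((1ULL << (shift * seed_len)) - 1);
  // each seed word -> min/max query offset where it occurs (enough for windowing)
  std::unordered_map<uint64_t, std::pair<int, int> > seeds;
  {
    uint64_t w = 0; int run = 0;
    for (int i = 0; i < qn; ++i) {
      int code = sc.protein ? aidx[(int)(unsigned char)query[i]] : dna2bit(query[i]);
      if (code < 0) { run = 0; w = 0; continue; }
      w = ((w << shift) | (uint64_t)code) & mask;
      if (++run >= seed_len) {
        int pos = i - seed_len + 1;
        auto it = seeds.find(w);
        if (it == seeds.end()) seeds.emplace(w, std::make_pair(pos, pos));
        else { if (pos < it->second.first) it->second.first = pos;
               if (pos > it->second.second) it->second.second = pos; }
      }
    }
  }
  std::vector<int> r_idx, r_score, r_q0, r_q1, r_s0, r_s1;
  R_xlen_t ns = subjects.size();
  for (R_xlen_t si = 0; si < ns; ++si) {
    const char *s = CHAR(STRING_ELT(subjects, si));
    int sn = (int)std::strlen(s);
    if (sn < seed_len) continue;
    int minq = qn, maxq = -1;
    uint64_t w = 0; int run = 0;
    for (int i = 0; i < sn; ++i) {
      int code = sc.protein ? aidx[(int)(unsigned char)s[i]] : dna2bit(s[i]);
      if (code < 0) { run = 0; w = 0; continue; }
      w = ((w << shift) | (uint64_t)code) & mask;
      if (++run >= seed_len) {
        auto it = seeds.find(w);
        if (it != seeds.end()) {
          if (it->second.first < minq) minq = it->second.first;
          if (it->second.second > maxq) maxq = it->second.second;
        }
      }
    }
    if (maxq < 0) continue;  // no shared word: no hit
    int lo = std::max(0, minq - sn - 20);
    int hi = std::min(qn, maxq + seed_len + sn + 20);
    SWHit h = sw_align(query.c_str() + lo, hi - lo, s, sn, sc);
    if (h.score >= min_score && h.a1 > h.a0) {
      r_idx.push_back((int)si + 1);
      r_score.push_back(h.score);
      r_q0.push_back(h.a0 + lo); r_q1.push_back(h.a1 + lo);
      r_s0.push_back(h.b0); r_s1.push_back(h.b1);
    }
  }
  return DataFrame::create(_["idx"] = r_idx, _["score"] = r_score,
                           _["q0"] = r_q0, _["q1"] = r_q1,
                           _["s0"] = r_s0, _["s1"] = r_s1);
}

// All distinct local alignments (HSPs) of query vs subject: repeated optimal
// local alignment with masking of the matched subject interval.
// [[Rcpp::export(rng = false)]]
DataFrame cpp_hsps(std::string query, std::string subject, List scheme,
                   int min_score, int max_hsps) {
  Scorer sc = build_scorer(scheme);
  std::vector<int> r_score, r_q0, r_q1, r_s0, r_s1;
  std::string sub = subject;
  for (int round = 0; round < max_hsps; ++round) {
    SWHit h = sw_align(query.c_str(), (int)query.size(), sub.c_str(), (int)sub.size(), sc);
    if (h.score < min_score || h.a1 <= h.a0) break;
    r_score.push_back(h.score);
    r_q0.push_back(h.a0); r_q1.push_back(h.a1);
    r_s0.push_back(h.b0); r_s1.push_back(h.b1);
    for (int i = h.b0; i < h.b1; ++i) sub[i] = '\1';
  }
  return DataFrame::create(_["score"] = r_score, _["q0"] = r_q0, _["q1"] = r_q1,
                           _["s0"] = r_s0, _["s1"] = r_s1);
}

// ---------------------------------------------------------------------------
// Overlap (semi-global) alignment with affine gaps and full traceback.
// End gaps on both sequences are free; unaligned overhangs are emitted as
// gap-padded columns. Traceback tie-break: diagonal > gap-in-a > gap-in-b.
// ---------------------------------------------------------------------------

// dir byte layout: bits 0-1 = source state of M (0=M, 1=Ix, 2=Iy),
// bit 2 = Ix extends (vs opens), bit 3 = Iy extends (vs opens)
// states: 0 = M (diagonal), 1 = Ix (gap in b, consumes a), 2 = Iy (gap in a, consumes b)

// [[Rcpp::export(rng = false)]]
List cpp_overlap_align(std::string a, std::string b, List scheme) {
  Scorer sc = build_scorer(scheme);
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("cannot align an empty sequence");
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("sequences too long for exact overlap alignment");
  std::vector<uint8_t> dir((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> M(m + 1), Ix(m + 1), Iy(m + 1), pM(m + 1), pIx(m + 1), pIy(m + 1);
  std::vector<int> colM(n + 1, NEG_INF), colIx(n + 1, NEG_INF), colIy(n + 1, NEG_INF);
  for (int j = 0; j <= m; ++j) { M[j] = 0; Ix[j] = NEG_INF; Iy[j] = NEG_INF; }
  colM[0] = 0;
  std::vector<int> lastM(M), lastIx(Ix), lastIy(Iy);
  for (int i = 1; i <= n; ++i) {
    std::swap(pM, M); std::swap(pIx, Ix); std::swap(pIy, Iy);
    M[0] = 0; Ix[0] = NEG_INF; Iy[0] = NEG_INF;  // free leading gap in b
    const int *row = sc.tab[(int)(unsigned char)a[i - 1]];
    uint8_t *drow = &dir[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      uint8_t d = 0;
      // M from (i-1, j-1); tie preference: M > Iy (gap-in-a) > Ix (gap-in-b)
      int best = pM[j - 1]; int src = 0;
      if (pIy[j - 1] > best) { best = pIy[j - 1]; src = 2; }
      if (pIx[j - 1] > best) { best = pIx[j - 1]; src = 1; }
      M[j] = (best <= NEG_INF / 2) ? NEG_INF : best + row[(int)(unsigned char)b[j - 1]];
      d |= (uint8_t)src;
      // Ix from (i-1, j): open from M or extend
      int open = pM[j] - sc.gap_first, ext = pIx[j] - sc.gap_ext;
      if (ext > open) { Ix[j] = ext; d |= 4; } else Ix[j] = open;
      // Iy from (i, j-1)
      open = M[j - 1] - sc.gap_first; ext = Iy[j - 1] - sc.gap_ext;
      if (ext > open) { Iy[j] = ext; d |= 8; } else Iy[j] = open;
      drow[j] = d;
    }
    colM[i] = M[m]; colIx[i] = Ix[m]; colIy[i] = Iy[m];
    if (i == n) { lastM = M; lastIx = Ix; lastIy = Iy; }
  }
  // pick the best end on the last row or last column; prefer M > Iy > Ix
  int bi = n, bj = m, bstate = 0, bscore = NEG_INF;
  auto consider = [&](int i, int j, int st, int sc_) {
    if (sc_ > bscore) { bscore = sc_; bi = i; bj = j; bstate = st; }
  };
  for (int j = m; j >= 0; --j) {
    consider(n, j, 0, lastM[j]); consider(n, j, 2, lastIy[j]); consider(n, j, 1, lastIx[j]);
  }
  for (int i = n; i >= 0; --i) {
    consider(i, m, 0, colM[i]); consider(i, m, 2, colIy[i]); consider(i, m, 1, colIx[i]);
  }
  // traceback
  std::string aa, bb;
  int i = bi, j = bj, st = bstate;
  // trailing overhangs (free end gaps) rendered as gap-padded columns
  std::string tail_a, tail_b;
  for (int t = n; t > bi; --t) { tail_a += a[t - 1]; tail_b += '-'; }
  for (int t = m; t > bj; --t) { tail_a += '-'; tail_b += b[t - 1]; }
  while (i > 0 && j > 0) {
    uint8_t d = dir[(size_t)i * (m + 1) + j];
    if (st == 0) {
      aa += a[i - 1]; bb += b[j - 1];
      st = d & 3; --i; --j;
    } else if (st == 1) {
      aa += a[i - 1]; bb += '-';
      st = (d & 4) ? 1 : 0; --i;
    } else {
      aa += '-'; bb += b[j - 1];
      st = (d & 8) ? 2 : 0; --j;
    }
  }
  // leading overhangs
  while (i > 0) { aa += a[i - 1]; bb += '-'; --i; }
  while (j > 0) { aa += '-'; bb += b[j - 1]; --j; }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  std::reverse(tail_a.begin(), tail_a.end());
  std::reverse(tail_b.begin(), tail_b.end());
  aa += tail_a; bb += tail_b;
  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = bscore);
}

// ---------------------------------------------------------------------------
// DNA utilities
// ---------------------------------------------------------------------------

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    case 'U': return 'A';
    case 'R': return 'Y'; case 'Y': return 'R'; case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K'; case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D'; case 'N': return 'N'; case '-': return '-';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_char(c);
  return r;
}

// [[Rcpp::export(rng = false)]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// lexicographically smaller of sequence and reverse complement (byte order)
// [[Rcpp::export(rng = false)]]
CharacterVector cpp_canonical(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r = revcomp_str(s);
    out[i] = (r < s) ? r : s;
  }
  return out;
}

// six-frame translation, standard genetic code, '*' for stops, 'X' for
// ambiguous codons, trailing partial codons dropped
static inline int tcag(char c) {
  switch (c) {
    case 'T': return 0; case 'C': return 1; case 'A': return 2; case 'G': return 3;
    default: return -1;
  }
}

static const char *CODE_TCAG =
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static std::string translate_frame(const std::string &s, int offset) {
  std::string out;
  int n = (int)s.size();
  out.reserve((n - offset) / 3 + 1);
  for (int i = offset; i + 2 < n; i += 3) {
    int x = tcag(s[i]), y = tcag(s[i + 1]), z = tcag(s[i + 2]);
    out += (x < 0 || y < 0 || z < 0) ? 'X' : CODE_TCAG[16 * x + 4 * y + z];
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_translate6(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  List frames(6);
  std::vector<CharacterVector> fr;
  for (int f = 0; f < 6; ++f) fr.push_back(CharacterVector(n));
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string rc = revcomp_str(s);
    for (int f = 0; f < 3; ++f) {
      fr[f][i] = translate_frame(s, f);
      fr[f + 3][i] = translate_frame(rc, f);
    }
  }
  for (int f = 0; f < 6; ++f) frames[f] = fr[f];
  return frames;
}

// i.i.d. per-base substitution to a uniformly chosen *different* base;
// non-ACGT symbols are left untouched. Uses the R RNG (set.seed-reproducible).
// [[Rcpp::export]]
CharacterVector cpp_mutate(CharacterVector seqs, double rate) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  const char *bases = "ACGT";
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (auto &c : s) {
      int code = dna2bit(c);
      if (code < 0) continue;
      if (unif_rand() < rate) {
        int off = 1 + (int)(unif_rand() * 3.0);
        if (off > 3) off = 3;
        c = bases[(code + off) & 3];
      }
    }
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// De Bruijn graph: canonical k-mer counting and unitig extraction
// ---------------------------------------------------------------------------

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

static inline uint64_t canon_kmer(uint64_t x, int k) {
  uint64_t r = rc_kmer(x, k);
  return r < x ? r : x;
}

static std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  const char *bases = "ACGT";
  for (int i = k - 1; i >= 0; --i) { s[i] = bases[x & 3]; x >>= 2; }
  return s;
}

static uint64_t encode_kmer(const char *s, int k) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) x = (x << 2) | (uint64_t)dna2bit(s[i]);
  return x;
}

// [[Rcpp::export(rng = false)]]
List cpp_kmer_count(CharacterVector reads, int k, int min_count) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  R_xlen_t n = reads.size();
  for (R_xlen_t r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = (int)std::strlen(s);
    uint64_t w = 0; int run = 0;
    for (int i = 0; i < len; ++i) {
      int code = dna2bit(s[i]);
      if (code < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)code) & mask;
      if (++run >= k) counts[canon_kmer(w, k)]++;
    }
  }
  std::vector<uint64_t> keep;
  keep.reserve(counts.size());
  for (auto &kv : counts)
    if ((int)kv.second >= min_count) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());  // deterministic order
  R_xlen_t nk = (R_xlen_t)keep.size();
  CharacterVector kmers(nk);
  IntegerVector cnt(nk);
  for (R_xlen_t i = 0; i < nk; ++i) {
    kmers[i] = decode_kmer(keep[i], k);
    cnt[i] = (int)counts[keep[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// maximal non-branching paths (unitigs) of the bidirected canonical k-mer graph
// [[Rcpp::export(rng = false)]]
List cpp_unitigs(CharacterVector kmers, IntegerVector counts, int k, int min_len) {
  std::unordered_map<uint64_t, uint32_t> cnt;
  cnt.reserve(kmers.size() * 2);
  std::vector<uint64_t> order;
  order.reserve(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t x = canon_kmer(encode_kmer(CHAR(STRING_ELT(kmers, i)), k), k);
    if (cnt.emplace(x, (uint32_t)counts[i]).second) order.push_back(x);
  }
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  auto present = [&](uint64_t x) { return cnt.count(canon_kmer(x, k)) > 0; };
  auto successors = [&](uint64_t x, std::vector<uint64_t> &out) {
    out.clear();
    uint64_t base = (x << 2) & mask;
    for (uint64_t b = 0; b < 4; ++b) if (present(base | b)) out.push_back(base | b);
  };
  auto predecessors = [&](uint64_t x, std::vector<uint64_t> &out) {
    out.clear();
    uint64_t suf = x >> 2;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = suf | (b << (2 * (k - 1)));
      if (present(y)) out.push_back(y);
    }
  };
  std::unordered_set<uint64_t> visited;
  visited.reserve(cnt.size() * 2);
  std::vector<std::string> seqs;
  std::vector<double> covs;
  std::vector<uint64_t> nb, pb;
  for (uint64_t c : order) {
    if (visited.count(c)) continue;
    visited.insert(c);
    std::deque<uint64_t> path;
    path.push_back(c);
    // extend right
    uint64_t x = c;
    while (true) {
      successors(x, nb);
      if (nb.size() != 1) break;
      uint64_t y = nb[0];
      predecessors(y, pb);
      if (pb.size() != 1) break;
      uint64_t cy = canon_kmer(y, k);
      if (visited.count(cy)) break;
      path.push_back(y);
      visited.insert(cy);
      x = y;
    }
    // extend left
    x = c;
    while (true) {
      predecessors(x, pb);
      if (pb.size() != 1) break;
      uint64_t y = pb[0];
      successors(y, nb);
      if (nb.size() != 1) break;
      uint64_t cy = canon_kmer(y, k);
      if (visited.count(cy)) break;
      path.push_front(y);
      visited.insert(cy);
      x = y;
    }
    int len = (int)path.size() + k - 1;
    if (len < min_len) continue;
    std::string s = decode_kmer(path.front(), k);
    const char *bases = "ACGT";
    for (size_t i = 1; i < path.size(); ++i) s += bases[path[i] & 3];
    std::string rc = revcomp_str(s);
    if (rc < s) s = rc;
    double tot = 0;
    for (uint64_t node : path) tot += (double)cnt[canon_kmer(node, k)];
    seqs.push_back(s);
    covs.push_back(tot / (double)path.size());
  }
  return List::create(_["seq"] = wrap(seqs), _["mean_cov"] = wrap(covs));
}
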