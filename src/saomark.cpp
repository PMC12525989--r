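// Core scanning and alignment kernels.
//
// Conventions shared with the R side:
//   * all positions exchanged with R are 0-based unless a column is
//     explicitly named *1 / pos (VCF-style 1-based);
//   * base codes A=0, C=1, G=2, T=3, anything else = 4 (N);
//   * only {A,C,G,T,N} ever reach these kernels (seqio normalises).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}

static inline char comp_char(char c) {
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
  for (auto& c : r) c = comp_char(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// ---------------------------------------------------------------------------
// canonical k-mer index
// ---------------------------------------------------------------------------

typedef std::unordered_map<uint64_t, int> KmerMap;

// Rolling canonical (min of strand codes) k-mer enumeration; windows
// containing N are skipped.  Callback receives the canonical code.
template <typename F>
static void for_each_canonical_kmer(const std::string& s, int k, F fun) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  const int shift_rc = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c >= 4) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
    if (++run >= k) fun(i + 1 - (size_t)k, std::min(fwd, rc));
  }
}

// [[Rcpp::export]]
SEXP cpp_kmer_build(CharacterVector seqs, int k) {
  XPtr<KmerMap> ptr(new KmerMap(), true);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_each_canonical_kmer(s, k, [&](size_t, uint64_t code) {
      ++(*ptr)[code];
    });
  }
  return ptr;
}

// [[Rcpp::export]]
double cpp_kmer_n_distinct(SEXP ptr_) {
  XPtr<KmerMap> ptr(ptr_);
  return (double)ptr->size();
}

// Per-position counts of the canonical k-mers of one sequence.
// Positions whose window contains N get NA.
// [[Rcpp::export]]
IntegerVector cpp_kmer_query(SEXP ptr_, std::string seq, int k) {
  XPtr<KmerMap> ptr(ptr_);
  int n = (int)seq.size() - k + 1;
  if (n < 1) return IntegerVector(0);
  IntegerVector out(n, NA_INTEGER);
  for_each_canonical_kmer(seq, k, [&](size_t pos, uint64_t code) {
    auto it = ptr->find(code);
    out[pos] = (it == ptr->end()) ? 0 : it->second;
  });
  return out;
}

// Batch (mean, max, n_valid) k-mer-count summaries for many oligos.
// [[Rcpp::export]]
NumericMatrix cpp_kmer_stats(SEXP ptr_, CharacterVector oligos, int k) {
  XPtr<KmerMap> ptr(ptr_);
  NumericMatrix out(oligos.size(), 3);
  colnames(out) = CharacterVector::create("mean", "max", "n_valid");
  for (R_xlen_t i = 0; i < oligos.size(); ++i) {
    std::string s = as<std::string>(oligos[i]);
    double tot = 0; int mx = 0, nv = 0;
    for_each_canonical_kmer(s, k, [&](size_t, uint64_t code) {
      auto it = ptr->find(code);
      int c = (it == ptr->end()) ? 0 : it->second;
      tot += c; if (c > mx) mx = c; ++nv;
    });
    out(i, 0) = nv ? tot / nv : NA_REAL;
    out(i, 1) = nv ? (double)mx : NA_REAL;
    out(i, 2) = nv;
  }
  return out;
}

// ---------------------------------------------------------------------------
// gap-free homology scan (bit-parallel primary implementation)
// ---------------------------------------------------------------------------

struct Packed {
  std::vector<uint64_t> words;  // 2-bit codes, N packed as 0 (A)
  std::vector<uint8_t> codes;   // 0..4, 4 = N
  size_t len;
};

static Packed pack_seq(const std::string& s) {
  Packed p;
  p.len = s.size();
  p.codes.resize(p.len);
  p.words.assign(p.len / 32 + 3, 0ULL);
  for (size_t i = 0; i < p.len; ++i) {
    int c = base_code(s[i]);
    p.codes[i] = (uint8_t)c;
    uint64_t b = (c >= 4) ? 0ULL : (uint64_t)c;
    p.words[i >> 5] |= b << ((i & 31) << 1);
  }
  return p;
}

static inline uint64_t extract_word(const std::vector<uint64_t>& w, size_t pos) {
  size_t idx = pos >> 5;
  int sh = (int)((pos & 31) << 1);
  uint64_t a = w[idx] >> sh;
  if (sh) a |= w[idx + 1] << (64 - sh);
  return a;
}

// Exact scan of one query over one packed chromosome.  The 2-bit XOR/popcount
// pre-check never over-rejects (N is packed as A, which can only turn true
// mismatches into pre-check matches); survivors are verified byte-wise with
// N counted as a mismatch.
static void scan_query(const Packed& chrom, const std::vector<uint8_t>& qc,
                       int maxmm, std::vector<int>& pos, std::vector<int>& mm_out) {
  size_t qlen = qc.size();
  if (chrom.len < qlen) return;
  int qw = (int)std::min<size_t>(32, qlen);
  uint64_t qword = 0;
  for (int i = 0; i < qw; ++i) qword |= ((uint64_t)qc[i]) << (2 * i);
  const uint64_t mask = (qw == 32) ? ~0ULL : ((1ULL << (2 * qw)) - 1);
  const uint64_t m55 = 0x5555555555555555ULL;
  for (size_t p = 0; p + qlen <= chrom.len; ++p) {
    uint64_t x = (extract_word(chrom.words, p) ^ qword) & mask;
    int mm = __builtin_popcountll((x | (x >> 1)) & m55);
    if (mm > maxmm) continue;
    int m2 = 0;
    for (size_t i = 0; i < qlen; ++i) {
      uint8_t cc = chrom.codes[p + i];
      if (cc >= 4 || cc != qc[i]) { if (++m2 > maxmm) break; }
    }
    if (m2 <= maxmm) { pos.push_back((int)p); mm_out.push_back(m2); }
  }
}

static std::vector<uint8_t> code_query(const std::string& q, bool* has_n) {
  std::vector<uint8_t> qc(q.size());
  *has_n = false;
  for (size_t i = 0; i < q.size(); ++i) {
    qc[i] = (uint8_t)base_code(q[i]);
    if (qc[i] >= 4) *has_n = true;
  }
  return qc;
}

static inline int max_mismatches(size_t qlen, double min_identity) {
  // identity = matches/len >= min_identity, boundary inclusive
  int min_match = (int)std::ceil(min_identity * (double)qlen - 1e-9);
  return (int)qlen - min_match;
}

// [[Rcpp::export]]
DataFrame cpp_homology_scan(CharacterVector seqs, std::string oligo,
                            double min_identity) {
  std::vector<int> chrom, start, mm;
  std::vector<std::string> strand;
  bool has_n = false;
  std::vector<uint8_t> qf = code_query(oligo, &has_n);
  std::string rc = revcomp(oligo);
  std::vector<uint8_t> qr = code_query(rc, &has_n);
  int maxmm = max_mismatches(oligo.size(), min_identity);
  if (!has_n) {
    for (R_xlen_t ci = 0; ci < seqs.size(); ++ci) {
      Packed p = pack_seq(as<std::string>(seqs[ci]));
      std::vector<int> pos, m;
      scan_query(p, qf, maxmm, pos, m);
      for (size_t i = 0; i < pos.size(); ++i) {
        chrom.push_back((int)ci + 1); start.push_back(pos[i]);
        strand.push_back("+"); mm.push_back(m[i]);
      }
      pos.clear(); m.clear();
      scan_query(p, qr, maxmm, pos, m);
      for (size_t i = 0; i < pos.size(); ++i) {
        chrom.push_back((int)ci + 1); start.push_back(pos[i]);
        strand.push_back("-"); mm.push_back(m[i]);
      }
    }
  }
  NumericVector ident(mm.size());
  for (size_t i = 0; i < mm.size(); ++i)
    ident[i] = 1.0 - (double)mm[i] / (double)oligo.size();
  return DataFrame::create(_["chrom_idx"] = wrap(chrom),
                           _["start"] = wrap(start),
                           _["strand"] = wrap(strand),
                           _["identity"] = ident,
                           _["stringsAsFactors"] = false);
}

// Batch hit counts for many oligos over one genome (packed once).
// [[Rcpp::export]]
IntegerVector cpp_homology_nhits(CharacterVector seqs, CharacterVector oligos,
                                 double min_identity) {
  std::vector<Packed> packed;
  for (R_xlen_t ci = 0; ci < seqs.size(); ++ci)
    packed.push_back(pack_seq(as<std::string>(seqs[ci])));
  IntegerVector out(oligos.size());
  for (R_xlen_t oi = 0; oi < oligos.size(); ++oi) {
    std::string q = as<std::string>(oligos[oi]);
    bool has_n = false;
    std::vector<uint8_t> qf = code_query(q, &has_n);
    std::string rc = revcomp(q);
    std::vector<uint8_t> qr = code_query(rc, &has_n);
    if (has_n) { out[oi] = NA_INTEGER; continue; }
    int maxmm = max_mismatches(q.size(), min_identity);
    int n = 0;
    std::vector<int> pos, m;
    for (auto& p : packed) {
      pos.clear(); m.clear(); scan_query(p, qf, maxmm, pos, m); n += (int)pos.size();
      pos.clear(); m.clear(); scan_query(p, qr, maxmm, pos, m); n += (int)pos.size();
    }
    out[oi] = n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// independent exhaustive scan (reference oracle; deliberately naive)
// ---------------------------------------------------------------------------

// Branch-free full-length character comparison at every position of both
// strands; no packing, no pre-check.  Kept structurally independent of the
// bit-parallel scanner above.
static void naive_scan_one(const std::string& chrom, const std::string& q,
                           int maxmm, std::vector<int>& pos,
                           std::vector<int>& mm_out) {
  size_t qlen = q.size(), n = chrom.size();
  if (n < qlen) return;
  const char* cp = chrom.data();
  const char* qp = q.data();
  for (size_t p = 0; p + qlen <= n; ++p) {
    int mm = 0;
    const char* c = cp + p;
    for (size_t i = 0; i < qlen; ++i) mm += (c[i] != qp[i]);
    if (mm <= maxmm) { pos.push_back((int)p); mm_out.push_back(mm); }
  }
}

static std::string mask_n_lower(std::string s) {
  for (auto& c : s) if (c != 'A' && c != 'C' && c != 'G' && c != 'T') c = 'n';
  return s;  // 'n' never equals an uppercase query base
}

// [[Rcpp::export]]
DataFrame cpp_homology_scan_naive(CharacterVector seqs, std::string oligo,
                                  double min_identity) {
  std::vector<int> chrom, start, mm;
  std::vector<std::string> strand;
  bool bad = oligo.find_first_not_of("ACGT") != std::string::npos;
  int maxmm = max_mismatches(oligo.size(), min_identity);
  std::string rc = revcomp(oligo);
  if (!bad) {
    for (R_xlen_t ci = 0; ci < seqs.size(); ++ci) {
      std::string s = mask_n_lower(as<std::string>(seqs[ci]));
      std::vector<int> pos, m;
      naive_scan_one(s, oligo, maxmm, pos, m);
      for (size_t i = 0; i < pos.size(); ++i) {
        chrom.push_back((int)ci + 1); start.push_back(pos[i]);
        strand.push_back("+"); mm.push_back(m[i]);
      }
      pos.clear(); m.clear();
      naive_scan_one(s, rc, maxmm, pos, m);
      for (size_t i = 0; i < pos.size(); ++i) {
        chrom.push_back((int)ci + 1); start.push_back(pos[i]);
        strand.push_back("-"); mm.push_back(m[i]);
      }
    }
  }
  NumericVector ident(mm.size());
  for (size_t i = 0; i < mm.size(); ++i)
    ident[i] = 1.0 - (double)mm[i] / (double)oligo.size();
  return DataFrame::create(_["chrom_idx"] = wrap(chrom),
                           _["start"] = wrap(start),
                           _["strand"] = wrap(strand),
                           _["identity"] = ident,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_homology_nhits_naive(CharacterVector seqs,
                                       CharacterVector oligos,
                                       double min_identity) {
  std::vector<std::string> chroms;
  for (R_xlen_t ci = 0; ci < seqs.size(); ++ci)
    chroms.push_back(mask_n_lower(as<std::string>(seqs[ci])));
  IntegerVector out(oligos.size());
  for (R_xlen_t oi = 0; oi < oligos.size(); ++oi) {
    std::string q = as<std::string>(oligos[oi]);
    if (q.find_first_not_of("ACGT") != std::string::npos) {
      out[oi] = NA_INTEGER; continue;
    }
    int maxmm = max_mismatches(q.size(), min_identity);
    std::string rc = revcomp(q);
    int n = 0;
    std::vector<int> pos, m;
    for (auto& s : chroms) {
      pos.clear(); m.clear(); naive_scan_one(s, q, maxmm, pos, m); n += (int)pos.size();
      pos.clear(); m.clear(); naive_scan_one(s, rc, maxmm, pos, m); n += (int)pos.size();
    }
    out[oi] = n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// nearest-neighbor thermodynamics (unified duplex parameter set)
// ---------------------------------------------------------------------------

// dH kcal/mol, dS cal/(mol K); index 4*first + second, A=0 C=1 G=2 T=3.
static const double NNH[16] = {
  -7.9, -8.4, -7.8, -7.2,   // AA AC AG AT
  -8.5, -8.0, -10.6, -7.8,  // CA CC CG CT
  -8.2, -9.8, -8.0, -8.4,   // GA GC GG GT
  -7.2, -8.2, -8.5, -7.9    // TA TC TG TT
};
static const double NNS[16] = {
  -22.2, -22.4, -21.0, -20.4,
  -22.7, -19.9, -27.2, -21.0,
  -22.2, -24.4, -19.9, -22.4,
  -21.3, -22.2, -22.7, -22.2
};

static double tm_core(const uint8_t* c, size_t n, double Na_M, double conc_M) {
  double dH = 0, dS = 0;
  for (size_t i = 0; i + 1 < n; ++i) {
    int idx = c[i] * 4 + c[i + 1];
    dH += NNH[idx]; dS += NNS[idx];
  }
  // terminal initiation: G/C end vs A/T end
  size_t ends[2] = { 0, n - 1 };
  for (int e = 0; e < 2; ++e) {
    uint8_t b = c[ends[e]];
    if (b == 1 || b == 2) { dH += 0.1; dS += -2.8; }
    else                  { dH += 2.3; dS += 4.1; }
  }
  dS += 0.368 * (double)(n - 1) * std::log(Na_M);
  double denom = dS + 1.987 * std::log(conc_M / 4.0);
  return 1000.0 * dH / denom - 273.15;
}

// [[Rcpp::export]]
NumericVector cpp_tm(CharacterVector seqs, double Na_mM, double conc_nM) {
  NumericVector out(seqs.size());
  double Na_M = Na_mM / 1000.0, conc_M = conc_nM * 1e-9;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    bool has_n = false;
    std::vector<uint8_t> c = code_query(s, &has_n);
    out[i] = (has_n || s.size() < 2) ? NA_REAL
                                     : tm_core(c.data(), c.size(), Na_M, conc_M);
  }
  return out;
}

static inline bool pairs_wc(uint8_t a, uint8_t b) {
  return a < 4 && b < 4 && (int)a + (int)b == 3;
}

// Maximal-stem hairpin approximation: enumerate every closing pair (a, b),
// extend the gap-free stem inward while the loop stays >= min_loop, and score
// qualifying stems as a perfect duplex of the stem arm.  Floor at 0 C.
// [[Rcpp::export]]
NumericVector cpp_hairpin_tm(CharacterVector seqs, int min_loop, int min_stem,
                             double Na_mM, double conc_nM) {
  NumericVector out(seqs.size());
  double Na_M = Na_mM / 1000.0, conc_M = conc_nM * 1e-9;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    bool has_n = false;
    std::vector<uint8_t> c = code_query(s, &has_n);
    int n = (int)c.size();
    double best = 0.0;
    for (int a = 0; a < n; ++a) {
      for (int b = n - 1; b > a + min_loop; --b) {
        int l = 0;
        while (a + l < b - l && pairs_wc(c[a + l], c[b - l]) &&
               (b - l) - (a + l) - 1 >= min_loop)
          ++l;
        if (l >= min_stem) {
          double tm = tm_core(c.data() + a, (size_t)l, Na_M, conc_M);
          if (tm > best) best = tm;
        }
      }
    }
    out[si] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// affine-gap alignment (glocal and global) with deterministic traceback
// ---------------------------------------------------------------------------

struct AlnResult {
  double score;
  std::string cigar;
  int ref_start, ref_end;
  bool ok;
};

// read-vs-ref affine alignment.  free_ref_ends = true: global in read, local
// in ref (no penalty for unaligned ref flanks).  Optional diagonal band
// |j - i - d0| <= band when use_band.  Tie preference in traceback:
// M(diagonal) > I(read gap-open/extend via M) > D.
static AlnResult align_engine(const std::string& read, const std::string& ref,
                              bool free_ref_ends, bool use_band, int d0, int band,
                              double match, double mismatch,
                              double gap_open, double gap_extend) {
  const double NEG = -1e18;
  int m = (int)read.size(), n = (int)ref.size();
  AlnResult res; res.ok = false; res.score = NEG; res.ref_start = 0; res.ref_end = 0;
  if (m == 0) return res;
  size_t W = (size_t)(n + 1);
  std::vector<double> M((size_t)(m + 1) * W, NEG), IX(M), IY(M);
  std::vector<uint8_t> pM((size_t)(m + 1) * W, 255), pX(pM), pY(pM);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  if (free_ref_ends) {
    for (int j = 0; j <= n; ++j) M[at(0, j)] = 0.0;
  } else {
    M[at(0, 0)] = 0.0;
    for (int j = 1; j <= n; ++j) {
      IY[at(0, j)] = gap_open + gap_extend * j;
      pY[at(0, j)] = (j == 1) ? 0 : 2;  // from M then extend
    }
  }
  for (int i = 1; i <= m; ++i) {
    int jlo = 0, jhi = n;
    if (use_band) {
      jlo = std::max(0, i + d0 - band);
      jhi = std::min(n, i + d0 + band);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      // IX: consume read[i-1], gap in ref
      double vM = M[at(i - 1, j)] + gap_open + gap_extend;
      double vX = IX[at(i - 1, j)] + gap_extend;
      if (vM >= vX) { IX[at(i, j)] = vM; pX[at(i, j)] = 0; }
      else          { IX[at(i, j)] = vX; pX[at(i, j)] = 1; }
      if (j > 0) {
        // IY: consume ref[j-1], gap in read
        double wM = M[at(i, j - 1)] + gap_open + gap_extend;
        double wY = IY[at(i, j - 1)] + gap_extend;
        if (wM >= wY) { IY[at(i, j)] = wM; pY[at(i, j)] = 0; }
        else          { IY[at(i, j)] = wY; pY[at(i, j)] = 2; }
        // M: align read[i-1] with ref[j-1]
        char a = read[(size_t)i - 1], b = ref[(size_t)j - 1];
        double s = (a == b && a != 'N') ? match : mismatch;
        double dM = M[at(i - 1, j - 1)], dX = IX[at(i - 1, j - 1)],
               dY = IY[at(i - 1, j - 1)];
        double bestd = dM; uint8_t pd = 0;
        if (dX > bestd) { bestd = dX; pd = 1; }
        if (dY > bestd) { bestd = dY; pd = 2; }
        if (bestd > NEG / 2) { M[at(i, j)] = bestd + s; pM[at(i, j)] = pd; }
      }
    }
  }
  // terminus
  int bj = -1; uint8_t bstate = 0; double bscore = NEG;
  if (free_ref_ends) {
    for (int j = 0; j <= n; ++j) {
      if (M[at(m, j)] > bscore) { bscore = M[at(m, j)]; bj = j; bstate = 0; }
      if (IX[at(m, j)] > bscore) { bscore = IX[at(m, j)]; bj = j; bstate = 1; }
    }
  } else {
    bj = n;
    bscore = M[at(m, n)]; bstate = 0;
    if (IX[at(m, n)] > bscore) { bscore = IX[at(m, n)]; bstate = 1; }
    if (IY[at(m, n)] > bscore) { bscore = IY[at(m, n)]; bstate = 2; }
  }
  if (bj < 0 || bscore < NEG / 2) return res;

  // traceback
  std::string ops;
  int i = m, j = bj; uint8_t st = bstate;
  while (i > 0 || (!free_ref_ends && j > 0)) {
    if (st == 0) {
      if (i == 0) break;  // free-start marker row
      uint8_t pd = pM[at(i, j)];
      ops.push_back('M'); --i; --j; st = pd;
    } else if (st == 1) {
      uint8_t pd = pX[at(i, j)];
      ops.push_back('I'); --i; st = pd;
    } else {
      uint8_t pd = pY[at(i, j)];
      ops.push_back('D'); --j; st = pd;
    }
    if (free_ref_ends && i == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p); cig.push_back(ops[p]);
    p = q;
  }
  res.score = bscore; res.cigar = cig; res.ref_start = j; res.ref_end = bj;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_banded_align(std::string read, std::string ref, int band, int d0,
                      bool use_band, double match, double mismatch,
                      double gap_open, double gap_extend) {
  AlnResult r = align_engine(read, ref, true, use_band, d0, band,
                             match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["cigar"] = r.cigar,
                      _["ref_start"] = r.ref_start, _["ref_end"] = r.ref_end,
                      _["ok"] = r.ok);
}

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, double match,
                      double mismatch, double gap_open, double gap_extend) {
  AlnResult r = align_engine(a, b, false, false, 0, 0,
                             match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["cigar"] = r.cigar,
                      _["ref_start"] = r.ref_start, _["ref_end"] = r.ref_end,
                      _["ok"] = r.ok);
}

// ---------------------------------------------------------------------------
// read-to-window assignment (seed + banded align, unique best window)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector window_seqs, IntegerVector window_rank,
                      CharacterVector reads, int seed_len, int band,
                      double match, double mismatch, double gap_open,
                      double gap_extend, double min_score_frac) {
  int nw = (int)window_seqs.size();
  std::vector<std::string> wseqs(nw);
  for (int i = 0; i < nw; ++i) wseqs[i] = as<std::string>(window_seqs[i]);

  // seed index: k-mer -> (window, position)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  {
    const uint64_t mask = (seed_len == 32) ? ~0ULL
                                           : ((1ULL << (2 * seed_len)) - 1);
    for (int w = 0; w < nw; ++w) {
      uint64_t h = 0; int run = 0;
      const std::string& s = wseqs[w];
      for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[i]);
        if (c >= 4) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= seed_len)
          index[h].push_back({w, (int)(i + 1 - (size_t)seed_len)});
      }
    }
  }

  std::vector<int> out_read, out_win, out_refstart;
  std::vector<double> out_score;
  std::vector<std::string> out_strand, out_cigar, out_seq;
  int n_unassigned = 0;

  const uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    if ((int)fwd.size() < seed_len) { ++n_unassigned; continue; }
    std::string rcs = revcomp(fwd);
    double min_score = min_score_frac * match * (double)fwd.size();

    double best_score = -1e18;
    int best_win = -1, best_rank = INT_MAX, best_refstart = 0, best_orient = 0;
    std::string best_cigar;

    for (int orient = 0; orient < 2; ++orient) {
      const std::string& seq = orient ? rcs : fwd;
      // vote on (window, diagonal)
      std::unordered_map<uint64_t, int> votes;
      uint64_t h = 0; int run = 0;
      for (size_t i = 0; i < seq.size(); ++i) {
        int c = base_code(seq[i]);
        if (c >= 4) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= seed_len) {
          auto it = index.find(h);
          if (it == index.end()) continue;
          int rpos = (int)(i + 1 - (size_t)seed_len);
          for (auto& e : it->second) {
            int diag = e.second - rpos;  // expected ref_start of read
            uint64_t key = ((uint64_t)e.first << 24) ^
                           (uint64_t)(uint32_t)(diag + 4096);
            ++votes[key];
          }
        }
      }
      if (votes.empty()) continue;
      // per window keep best-voted diagonal (deterministic: sort)
      std::vector<std::pair<uint64_t, int>> vv(votes.begin(), votes.end());
      std::sort(vv.begin(), vv.end());
      std::unordered_map<int, std::pair<int, int>> best_diag;  // win -> (votes, diag)
      for (auto& kv : vv) {
        int w = (int)(kv.first >> 24);
        int diag = (int)(kv.first & 0xFFFFFF) - 4096;
        auto it = best_diag.find(w);
        if (it == best_diag.end() || kv.second > it->second.first)
          best_diag[w] = {kv.second, diag};
      }
      std::vector<std::pair<int, std::pair<int, int>>> cands(best_diag.begin(),
                                                             best_diag.end());
      std::sort(cands.begin(), cands.end());
      for (auto& cd : cands) {
        int w = cd.first, diag = cd.second.second;
        AlnResult r = align_engine(seq, wseqs[w], true, true, diag, band,
                                   match, mismatch, gap_open, gap_extend);
        if (!r.ok) continue;
        int rk = window_rank[w];
        bool better = r.score > best_score ||
          (r.score == best_score && rk < best_rank) ||
          (r.score == best_score && rk == best_rank && orient < best_orient);
        if (better) {
          best_score = r.score; best_win = w; best_rank = rk;
          best_refstart = r.ref_start; best_cigar = r.cigar;
          best_orient = orient;
        }
      }
    }
    if (best_win < 0 || best_score < min_score) { ++n_unassigned; continue; }
    out_read.push_back((int)ri + 1);
    out_win.push_back(best_win + 1);
    out_strand.push_back(best_orient ? "-" : "+");
    out_score.push_back(best_score);
    out_refstart.push_back(best_refstart);
    out_cigar.push_back(best_cigar);
    out_seq.push_back(best_orient ? rcs : fwd);
  }
  DataFrame df = DataFrame::create(
      _["read"] = wrap(out_read), _["window"] = wrap(out_win),
      _["strand"] = wrap(out_strand), _["score"] = wrap(out_score),
      _["ref_start"] = wrap(out_refstart), _["cigar"] = wrap(out_cigar),
      _["aln_seq"] = wrap(out_seq), _["stringsAsFactors"] = false);
  return List::create(_["assignments"] = df,
                      _["n_unassigned"] = n_unassigned);
}

// ---------------------------------------------------------------------------
// pileup over one window
// ---------------------------------------------------------------------------

// counts: 5 x L matrix (A,C,G,T,DEL); jcov[j]: reads contiguously spanning
// the junction between columns j and j+1 (0-based); insertions keyed by the
// column index they precede.
// [[Rcpp::export]]
List cpp_pileup(int window_len, IntegerVector ref_starts, CharacterVector cigars,
                CharacterVector seqs) {
  IntegerMatrix counts(5, window_len);
  IntegerVector jcov(std::max(0, window_len - 1));
  std::map<std::pair<int, std::string>, int> ins;
  for (R_xlen_t r = 0; r < cigars.size(); ++r) {
    std::string cig = as<std::string>(cigars[r]);
    std::string seq = as<std::string>(seqs[r]);
    int pos = ref_starts[r], rpos = 0;
    size_t ci = 0;
    int span_start = pos;
    while (ci < cig.size()) {
      int len = 0;
      while (ci < cig.size() && isdigit(cig[ci])) len = len * 10 + (cig[ci++] - '0');
      char op = cig[ci++];
      if (op == 'M') {
        for (int t = 0; t < len; ++t, ++pos, ++rpos) {
          if (pos < 0 || pos >= window_len) continue;
          int c = base_code(seq[rpos]);
          if (c < 4) ++counts(c, pos);
        }
      } else if (op == 'I') {
        if (pos > 0 && pos < window_len)
          ++ins[{pos, seq.substr((size_t)rpos, (size_t)len)}];
        rpos += len;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t, ++pos)
          if (pos >= 0 && pos < window_len) ++counts(4, pos);
      }
    }
    for (int j = std::max(0, span_start); j < std::min(window_len - 1, pos - 1); ++j)
      ++jcov[j];
  }
  std::vector<int> ins_pos, ins_count;
  std::vector<std::string> ins_seq;
  for (auto& kv : ins) {
    ins_pos.push_back(kv.first.first);
    ins_seq.push_back(kv.first.second);
    ins_count.push_back(kv.second);
  }
  DataFrame insdf = DataFrame::create(
      _["before_col"] = wrap(ins_pos), _["seq"] = wrap(ins_seq),
      _["count"] = wrap(ins_count), _["stringsAsFactors"] = false);
  return List::create(_["counts"] = counts, _["jcov"] = jcov,
                      _["insertions"] = insdf);
}

// ---------------------------------------------------------------------------
// primer binding-site scan (in-silico PCR support)
// ---------------------------------------------------------------------------

// Sites where `primer` matches seqs with <= max_mm total mismatches and
// <= max_tp_mm mismatches inside the 3'-terminal window (right end when
// tp_right, else left end).  N never matches.
// [[Rcpp::export]]
DataFrame cpp_primer_sites(CharacterVector seqs, std::string primer,
                           int max_mm, int tp_window, int max_tp_mm,
                           bool tp_right) {
  std::vector<int> out_chrom, out_start;
  size_t plen = primer.size();
  int tpw = std::min<int>((int)plen, tp_window);
  size_t tp_off = tp_right ? plen - (size_t)tpw : 0;
  for (R_xlen_t ci = 0; ci < seqs.size(); ++ci) {
    std::string s = mask_n_lower(as<std::string>(seqs[ci]));
    if (s.size() < plen) continue;
    for (size_t p = 0; p + plen <= s.size(); ++p) {
      const char* c = s.data() + p;
      int tpmm = 0;
      for (int i = 0; i < tpw; ++i)
        tpmm += (c[tp_off + (size_t)i] != primer[tp_off + (size_t)i]);
      if (tpmm > max_tp_mm) continue;
      int mm = 0;
      for (size_t i = 0; i < plen && mm <= max_mm; ++i)
        mm += (c[i] != primer[i]);
      if (mm <= max_mm) { out_chrom.push_back((int)ci + 1); out_start.push_back((int)p); }
    }
  }
  return DataFrame::create(_["chrom_idx"] = wrap(out_chrom),
                           _["start"] = wrap(out_start),
                           _["stringsAsFactors"] = false);
}
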