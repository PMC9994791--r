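// Core kernels: IUPAC alphabet ops, canonical k-mer scanning, splitter
// selection, LZSS parsing against a reference segment, division-point search,
// radix symbol packing and LEB128 varints.  Everything here is deterministic:
// no global state, no randomness, fixed tie-breaks.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------- alphabet --

// 16-letter IUPAC alphabet; complement per the DNA code table (U pairs with A,
// hence complement is not an involution on U -- callers never flip U-bearing
// sequences).
static inline const unsigned char* comp_table() {
  static unsigned char tab[256];
  static bool init = false;
  if (!init) {
    std::memset(tab, 0, sizeof(tab));
    const char* from = "ACGTURYSWKMBDHVN";
    const char* to   = "TGCAAYRSWMKVHDBN";
    for (int i = 0; from[i]; ++i) tab[(unsigned char)from[i]] = (unsigned char)to[i];
    init = true;
  }
  return tab;
}

static inline const signed char* code2_table() {
  // 2-bit codes for ACGT, -1 otherwise
  static signed char tab[256];
  static bool init = false;
  if (!init) {
    std::memset(tab, -1, sizeof(tab));
    tab[(unsigned char)'A'] = 0; tab[(unsigned char)'C'] = 1;
    tab[(unsigned char)'G'] = 2; tab[(unsigned char)'T'] = 3;
    init = true;
  }
  return tab;
}

static inline bool is_iupac(unsigned char c) { return comp_table()[c] != 0; }

static void check_iupac(const std::string& s, const char* what) {
  for (size_t i = 0; i < s.size(); ++i)
    if (!is_iupac((unsigned char)s[i]))
      stop("%s contains non-IUPAC symbol '%c' at position %d",
           what, s[i], (int)(i + 1));
}

static std::string revcomp1(const std::string& s) {
  const unsigned char* tab = comp_table();
  std::string out(s.size(), 'N');
  size_t n = s.size();
  for (size_t i = 0; i < n; ++i) {
    unsigned char c = tab[(unsigned char)s[i]];
    if (!c) stop("sequence contains non-IUPAC symbol '%c'", s[i]);
    out[n - 1 - i] = (char)c;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_ingest(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    for (size_t i = 0; i < s.size(); ++i) {
      unsigned char c = (unsigned char)s[i];
      if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
      if (!is_iupac(c))
        stop("sequence %d contains non-IUPAC symbol '%c' at position %d",
             (int)(j + 1), s[i], (int)(i + 1));
      s[i] = (char)c;
    }
    out[j] = s;
  }
  if (seqs.hasAttribute("names")) out.names() = seqs.names();
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t j = 0; j < seqs.size(); ++j)
    out[j] = revcomp1(as<std::string>(seqs[j]));
  if (seqs.hasAttribute("names")) out.names() = seqs.names();
  return out;
}

// [[Rcpp::export]]
bool cpp_lex_lt(std::string a, std::string b) { return a < b; }

// ------------------------------------------------------------ k-mer coding --

static inline uint64_t kmer_mask(int k) {
  return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static bool encode_kmer(const std::string& s, uint64_t& out) {
  const signed char* code = code2_table();
  uint64_t v = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = code[(unsigned char)s[i]];
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static std::string decode_kmer(uint64_t v, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int i = 0; i < k; ++i) s[i] = B[(v >> (2 * (k - 1 - i))) & 3ULL];
  return s;
}

// Calls f(pos, canonical_value) for every window of k ACGT symbols; windows
// containing any other symbol are skipped.
template <typename F>
static void scan_canonical(const std::string& s, int k, F f) {
  const signed char* code = code2_table();
  if ((int)s.size() < k) return;
  uint64_t mask = kmer_mask(k);
  int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = code[(unsigned char)s[i]];
    if (c < 0) { run = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) f(i - (size_t)k + 1, std::min(fwd, rev));
  }
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    std::string s = as<std::string>(kmers[j]);
    uint64_t v;
    if (s.empty() || !encode_kmer(s, v))
      stop("invalid k-mer: '%s' contains a non-ACGT symbol", s.c_str());
    std::string rc = revcomp1(s);
    out[j] = (rc < s) ? rc : s;
  }
  return out;
}

// Canonical k-mers occurring exactly once across all contigs, sorted.
// [[Rcpp::export]]
CharacterVector cpp_find_candidates(CharacterVector contigs, int k) {
  std::unordered_map<uint64_t, uint32_t> counts;
  for (R_xlen_t j = 0; j < contigs.size(); ++j) {
    std::string s = as<std::string>(contigs[j]);
    scan_canonical(s, k, [&](size_t, uint64_t v) {
      auto it = counts.find(v);
      if (it == counts.end()) counts.emplace(v, 1u); else it->second = 2u;
    });
  }
  std::vector<uint64_t> uniq;
  for (auto& kv : counts) if (kv.second == 1u) uniq.push_back(kv.first);
  std::sort(uniq.begin(), uniq.end());
  CharacterVector out(uniq.size());
  for (size_t i = 0; i < uniq.size(); ++i) out[i] = decode_kmer(uniq[i], k);
  return out;
}

static std::unordered_set<uint64_t>
encode_kmer_set(CharacterVector kmers, int k) {
  std::unordered_set<uint64_t> set;
  set.reserve(kmers.size() * 2 + 8);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) stop("k-mer of wrong length: '%s'", s.c_str());
    uint64_t v;
    if (!encode_kmer(s, v)) stop("invalid k-mer: '%s'", s.c_str());
    set.insert(v);
  }
  return set;
}

// Spaced left-to-right walk over each contig: first candidate occurrence is a
// splitter, then resume k bases.. at position + segment_size; the last
// candidate occurrence of a contig is also a splitter.  Returned in insertion
// order (= id order), deduplicated by canonical form.
// [[Rcpp::export]]
CharacterVector cpp_determine_splitters(CharacterVector contigs,
                                        CharacterVector candidates,
                                        int k, double segment_size) {
  std::unordered_set<uint64_t> cand = encode_kmer_set(candidates, k);
  std::unordered_set<uint64_t> seen;
  std::vector<uint64_t> order;
  for (R_xlen_t j = 0; j < contigs.size(); ++j) {
    std::string s = as<std::string>(contigs[j]);
    double resume = 0;
    bool have_last = false;
    uint64_t last = 0;
    scan_canonical(s, k, [&](size_t pos, uint64_t v) {
      if (!cand.count(v)) return;
      have_last = true; last = v;
      if ((double)pos >= resume) {
        if (seen.insert(v).second) order.push_back(v);
        resume = (double)pos + segment_size;
      }
    });
    if (have_last && seen.insert(last).second) order.push_back(last);
  }
  CharacterVector out(order.size());
  for (size_t i = 0; i < order.size(); ++i) out[i] = decode_kmer(order[i], k);
  return out;
}

// Positions (0-based) in `contig` whose canonical k-mer is a splitter, plus
// the 1-based index of the matched splitter.
// [[Rcpp::export]]
List cpp_split_positions(std::string contig, CharacterVector splitters, int k) {
  std::unordered_map<uint64_t, int> ids;
  ids.reserve(splitters.size() * 2 + 8);
  for (R_xlen_t i = 0; i < splitters.size(); ++i) {
    std::string s = as<std::string>(splitters[i]);
    uint64_t v;
    if (!encode_kmer(s, v)) stop("invalid splitter k-mer: '%s'", s.c_str());
    ids.emplace(v, (int)i + 1);
  }
  std::vector<int> pos, id;
  scan_canonical(contig, k, [&](size_t p, uint64_t v) {
    auto it = ids.find(v);
    if (it != ids.end()) { pos.push_back((int)p); id.push_back(it->second); }
  });
  return List::create(_["pos"] = wrap(pos), _["id"] = wrap(id));
}

// Sample-candidate k-mers for adaptive mode: canonical k-mers unique within
// the buffered contigs, minus every k-mer present in the reference (any
// count), minus the existing splitters.  Sorted.
// [[Rcpp::export]]
CharacterVector cpp_adaptive_candidates(CharacterVector buffer,
                                        CharacterVector reference,
                                        CharacterVector existing, int k) {
  std::unordered_map<uint64_t, uint32_t> counts;
  for (R_xlen_t j = 0; j < buffer.size(); ++j) {
    std::string s = as<std::string>(buffer[j]);
    scan_canonical(s, k, [&](size_t, uint64_t v) {
      auto it = counts.find(v);
      if (it == counts.end()) counts.emplace(v, 1u); else it->second = 2u;
    });
  }
  std::unordered_set<uint64_t> refset;
  for (R_xlen_t j = 0; j < reference.size(); ++j) {
    std::string s = as<std::string>(reference[j]);
    scan_canonical(s, k, [&](size_t, uint64_t v) { refset.insert(v); });
  }
  std::unordered_set<uint64_t> excl = encode_kmer_set(existing, k);
  std::vector<uint64_t> uniq;
  for (auto& kv : counts)
    if (kv.second == 1u && !refset.count(kv.first) && !excl.count(kv.first))
      uniq.push_back(kv.first);
  std::sort(uniq.begin(), uniq.end());
  CharacterVector out(uniq.size());
  for (size_t i = 0; i < uniq.size(); ++i) out[i] = decode_kmer(uniq[i], k);
  return out;
}

// 2-bit packed splitter k-mers for the archive header (8 bytes each, LE).
// [[Rcpp::export]]
RawVector cpp_kmers_pack(CharacterVector kmers, int k) {
  RawVector out(kmers.size() * 8);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t v;
    if (!encode_kmer(as<std::string>(kmers[i]), v))
      stop("invalid k-mer at %d", (int)i + 1);
    for (int b = 0; b < 8; ++b) out[i * 8 + b] = (Rbyte)((v >> (8 * b)) & 0xFF);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_kmers_unpack(RawVector packed, int k) {
  if (packed.size() % 8 != 0) stop("corrupt packed k-mer section");
  R_xlen_t n = packed.size() / 8;
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = 0;
    for (int b = 0; b < 8; ++b) v |= ((uint64_t)(unsigned char)packed[i * 8 + b]) << (8 * b);
    out[i] = decode_kmer(v, k);
  }
  return out;
}

// ----------------------------------------------------------- spt-0 buckets --

// FNV-1a 64 over the lexicographically smaller orientation, mod 16, so a
// segment and its reverse complement land in the same bucket.
// [[Rcpp::export]]
IntegerVector cpp_spt0_bucket(CharacterVector seqs) {
  IntegerVector out(seqs.size());
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    std::string rc = revcomp1(s);
    const std::string& t = (rc < s) ? rc : s;
    uint64_t h = 14695981039346656037ULL;
    for (size_t i = 0; i < t.size(); ++i) {
      h ^= (uint64_t)(unsigned char)t[i];
      h *= 1099511628211ULL;
    }
    out[j] = (int)(h & 15ULL);
  }
  return out;
}

// ------------------------------------------------------------ LEB128 varints --

static inline void put_varint(std::vector<uint8_t>& out, uint64_t v) {
  while (v >= 0x80) { out.push_back((uint8_t)(v & 0x7F) | 0x80); v >>= 7; }
  out.push_back((uint8_t)v);
}

static inline int varint_len(uint64_t v) {
  int n = 1;
  while (v >= 0x80) { v >>= 7; ++n; }
  return n;
}

static uint64_t get_varint(const uint8_t* buf, size_t n, size_t& cur) {
  uint64_t v = 0;
  int shift = 0;
  for (;;) {
    if (cur >= n) stop("corrupt stream: truncated varint");
    uint8_t b = buf[cur++];
    v |= (uint64_t)(b & 0x7F) << shift;
    if (!(b & 0x80)) return v;
    shift += 7;
    if (shift > 63) stop("corrupt stream: varint overflow");
  }
}

// [[Rcpp::export]]
RawVector cpp_leb128_encode(NumericVector values) {
  std::vector<uint8_t> out;
  out.reserve(values.size() * 2);
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    double d = values[i];
    if (d < 0 || d != d || d > 9.007199254740992e15)
      stop("varint value out of range: %f", d);
    put_varint(out, (uint64_t)d);
  }
  return RawVector(out.begin(), out.end());
}

// Decode n varints starting at 0-based byte offset `at`; returns values and
// the offset just past the last one.
// [[Rcpp::export]]
List cpp_leb128_decode(RawVector raw, double at, int n) {
  const uint8_t* buf = (const uint8_t*)RAW(raw);
  size_t cur = (size_t)at;
  NumericVector vals(n);
  for (int i = 0; i < n; ++i)
    vals[i] = (double)get_varint(buf, (size_t)raw.size(), cur);
  return List::create(_["values"] = vals, _["at"] = (double)cur);
}

// ---------------------------------------------------------- symbol packing --

// Radix packing tiers by distinct-symbol count sigma of the sequence itself:
// sigma<=4 -> 4 symbols/byte (radix 4), <=6 -> 3/byte (radix 6),
// <=16 -> 2/byte (radix 16), else 1/byte.
static void pack_tier(int sigma, int& per_byte, int& radix) {
  if (sigma <= 4)      { per_byte = 4; radix = 4; }
  else if (sigma <= 6) { per_byte = 3; radix = 6; }
  else if (sigma <= 16){ per_byte = 2; radix = 16; }
  else                 { per_byte = 1; radix = 256; }
}

// [[Rcpp::export]]
List cpp_pack_seq(std::string s) {
  check_iupac(s, "sequence");
  if (s.empty()) stop("cannot pack an empty sequence");
  bool present[256] = {false};
  for (size_t i = 0; i < s.size(); ++i) present[(unsigned char)s[i]] = true;
  std::string symbols;
  for (int c = 0; c < 256; ++c) if (present[c]) symbols.push_back((char)c);
  int code[256];
  for (size_t i = 0; i < symbols.size(); ++i) code[(unsigned char)symbols[i]] = (int)i;
  int per_byte, radix;
  pack_tier((int)symbols.size(), per_byte, radix);
  size_t nbytes = (s.size() + per_byte - 1) / per_byte;
  RawVector out(nbytes);
  for (size_t b = 0; b < nbytes; ++b) {
    int v = 0, mult = 1;
    for (int j = 0; j < per_byte; ++j) {
      size_t i = b * per_byte + j;
      if (i < s.size()) v += code[(unsigned char)s[i]] * mult;
      mult *= radix;
    }
    out[b] = (Rbyte)v;
  }
  return List::create(_["bytes"] = out, _["symbols"] = symbols,
                      _["per_byte"] = per_byte);
}

// [[Rcpp::export]]
std::string cpp_unpack_seq(RawVector bytes, std::string symbols, double n) {
  int per_byte, radix;
  pack_tier((int)symbols.size(), per_byte, radix);
  size_t len = (size_t)n;
  if ((size_t)bytes.size() * per_byte < len)
    stop("corrupt packed sequence: too few bytes");
  std::string s(len, 'N');
  for (size_t i = 0; i < len; ++i) {
    int v = (unsigned char)bytes[i / per_byte];
    int j = (int)(i % per_byte);
    for (int q = 0; q < j; ++q) v /= radix;
    int c = v % radix;
    if (c >= (int)symbols.size()) stop("corrupt packed sequence: bad code");
    s[i] = symbols[(size_t)c];
  }
  return s;
}

// [[Rcpp::export]]
int cpp_nsym(std::string s) {
  bool present[256] = {false};
  int n = 0;
  for (size_t i = 0; i < s.size(); ++i)
    if (!present[(unsigned char)s[i]]) { present[(unsigned char)s[i]] = true; ++n; }
  return n;
}

// ------------------------------------------------------------------- LZSS --

// Token serialization (pinned; recorded in the archive header via
// min_match/mmer): 0x00 terminator; 0x01 varint(runlen) <runlen raw symbol
// bytes>; 0x02 varint(zigzag(offset - expected)) varint(length - min_match).
// `expected` is an implicit reference cursor: 0 initially, off+len after a
// match, advanced by the run length after a literal run.  Descriptions of
// SNP-like differences thus reduce to near-constant byte patterns (delta 0),
// which keeps streams short and highly compressible across samples in a
// block.  Matches refer to the forward orientation of the reference only.

static inline uint64_t zigzag(int64_t d) {
  return ((uint64_t)d << 1) ^ (uint64_t)(d >> 63);
}
static inline int64_t unzigzag(uint64_t z) {
  return (int64_t)(z >> 1) ^ -(int64_t)(z & 1);
}

static const int MAX_CHAIN = 128;   // candidate positions examined per m-mer

struct Finder {
  const std::string& ref;
  int m;
  std::unordered_map<uint64_t, std::vector<int>> tab;

  Finder(const std::string& r, int m_) : ref(r), m(m_) {
    if ((int)ref.size() >= m) {
      tab.reserve(ref.size() * 2);
      for (size_t p = 0; p + (size_t)m <= ref.size(); ++p)
        tab[hash_at(ref, p)].push_back((int)p);
    }
  }

  uint64_t hash_at(const std::string& s, size_t p) const {
    uint64_t h = 14695981039346656037ULL;
    for (int i = 0; i < m; ++i) {
      h ^= (uint64_t)(unsigned char)s[p + i];
      h *= 1099511628211ULL;
    }
    return h;
  }

  // Longest match of s[p..] (bounded by maxlen) in ref; leftmost on tie.
  // Returns length (0 if below min threshold handled by caller) and offset.
  void longest(const std::string& s, size_t p, int maxlen,
               int& len, int& off) const {
    len = 0; off = -1;
    if ((int)(s.size() - p) < m || maxlen < m) return;
    auto it = tab.find(hash_at(s, p));
    if (it == tab.end()) return;
    const std::vector<int>& chain = it->second;
    int nc = std::min((int)chain.size(), MAX_CHAIN);
    for (int idx = 0; idx < nc; ++idx) {
      int rp = chain[idx];
      int lim = std::min(maxlen, std::min((int)(s.size() - p),
                                          (int)(ref.size() - rp)));
      if (lim <= len) continue;
      int e = 0;
      const char* a = s.data() + p;
      const char* b = ref.data() + rp;
      while (e < lim && a[e] == b[e]) ++e;
      if (e > len) { len = e; off = rp; }
      if (len == maxlen) break;
    }
  }

  // All candidates at p with their (unbounded) extension lengths, chain order.
  void candidates(const std::string& s, size_t p,
                  std::vector<int>& rps, std::vector<int>& exts) const {
    rps.clear(); exts.clear();
    if ((int)(s.size() - p) < m) return;
    auto it = tab.find(hash_at(s, p));
    if (it == tab.end()) return;
    const std::vector<int>& chain = it->second;
    int nc = std::min((int)chain.size(), MAX_CHAIN);
    for (int idx = 0; idx < nc; ++idx) {
      int rp = chain[idx];
      int lim = std::min((int)(s.size() - p), (int)(ref.size() - rp));
      int e = 0;
      const char* a = s.data() + p;
      const char* b = ref.data() + rp;
      while (e < lim && a[e] == b[e]) ++e;
      rps.push_back(rp); exts.push_back(e);
    }
  }
};

struct Token { uint8_t type; int pos; int len; int off; };  // type 1 lit-run, 2 match

static void greedy_parse(const std::string& s, const Finder& f, int mm,
                         std::vector<Token>& toks) {
  toks.clear();
  size_t n = s.size(), p = 0;
  int run_start = -1;
  while (p < n) {
    int len, off;
    f.longest(s, p, (int)(n - p), len, off);
    if (len >= mm) {
      if (run_start >= 0) {
        toks.push_back({1, run_start, (int)p - run_start, 0});
        run_start = -1;
      }
      toks.push_back({2, (int)p, len, off});
      p += (size_t)len;
    } else {
      if (run_start < 0) run_start = (int)p;
      ++p;
    }
  }
  if (run_start >= 0) toks.push_back({1, run_start, (int)n - run_start, 0});
}

static void serialize_tokens(const std::string& s, const std::vector<Token>& toks,
                             int mm, std::vector<uint8_t>& out) {
  int64_t expected = 0;
  for (const Token& t : toks) {
    if (t.type == 1) {
      out.push_back(0x01);
      put_varint(out, (uint64_t)t.len);
      out.insert(out.end(), s.begin() + t.pos, s.begin() + t.pos + t.len);
      expected += t.len;
    } else {
      out.push_back(0x02);
      put_varint(out, zigzag((int64_t)t.off - expected));
      put_varint(out, (uint64_t)(t.len - mm));
      expected = (int64_t)t.off + t.len;
    }
  }
  out.push_back(0x00);
}

// [[Rcpp::export]]
RawVector cpp_lzss_parse(std::string s, std::string ref, int min_match, int mmer) {
  Finder f(ref, mmer);
  std::vector<Token> toks;
  greedy_parse(s, f, min_match, toks);
  std::vector<uint8_t> out;
  out.reserve(s.size() / 8 + 16);
  serialize_tokens(s, toks, min_match, out);
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
double cpp_lzss_cost(std::string s, std::string ref, int min_match, int mmer) {
  Finder f(ref, mmer);
  std::vector<Token> toks;
  greedy_parse(s, f, min_match, toks);
  double cost = 1;  // terminator
  int64_t expected = 0;
  for (const Token& t : toks) {
    if (t.type == 1) {
      cost += 1 + varint_len((uint64_t)t.len) + t.len;
      expected += t.len;
    } else {
      cost += 1 + varint_len(zigzag((int64_t)t.off - expected)) +
              varint_len((uint64_t)(t.len - min_match));
      expected = (int64_t)t.off + t.len;
    }
  }
  return cost;
}

// [[Rcpp::export]]
std::string cpp_lzss_decode(RawVector tokens, std::string ref, int min_match) {
  const uint8_t* buf = (const uint8_t*)RAW(tokens);
  size_t n = tokens.size(), cur = 0;
  std::string out;
  int64_t expected = 0;
  for (;;) {
    if (cur >= n) stop("corrupt stream: missing terminator");
    uint8_t flag = buf[cur++];
    if (flag == 0x00) break;
    if (flag == 0x01) {
      uint64_t len = get_varint(buf, n, cur);
      if (cur + len > n) stop("corrupt stream: literal run past end");
      out.append((const char*)buf + cur, (size_t)len);
      cur += (size_t)len;
      expected += (int64_t)len;
    } else if (flag == 0x02) {
      int64_t off = expected + unzigzag(get_varint(buf, n, cur));
      uint64_t len = get_varint(buf, n, cur) + (uint64_t)min_match;
      if (off < 0 || (uint64_t)off + len > ref.size())
        stop("corrupt stream: match window outside reference");
      out.append(ref, (size_t)off, (size_t)len);
      expected = off + (int64_t)len;
    } else {
      stop("corrupt stream: unknown token flag %d", (int)flag);
    }
  }
  return out;
}

// Division point for a segment spanning a missing splitter: the index i
// minimizing cost(parse(s[0:i], refA)) + cost(parse(s[i:], refB)), prefix
// costs from one forward pass, suffix costs from one backward DP, ties to the
// smallest i.  Exactly consistent with exhaustively re-parsing every cut.
// [[Rcpp::export]]
List cpp_find_division(std::string s, std::string refA, std::string refB,
                       int min_match, int mmer, int imin, int imax) {
  int n = (int)s.size();
  if (imin < 0) imin = 0;
  if (imax > n) imax = n;
  if (imin > imax) stop("empty division range");
  const int mm = min_match;

  // ---- suffix costs vs refB: suf0[i] = cost of parse(s[i:]) standalone ----
  // With delta-coded match offsets, tails of different suffix parses share
  // all token costs once their boundaries merge, except the first match
  // token, whose delta depends on the incoming reference cursor; firstO/D
  // record that first match so composition can correct exactly.
  Finder fb(refB, mmer);
  std::vector<int> Lb(n, 0), Ob(n, 0);
  for (int i = 0; i < n; ++i) {
    int len, off;
    fb.longest(s, (size_t)i, n - i, len, off);
    if (len >= mm) { Lb[i] = len; Ob[i] = off; }
  }
  std::vector<int> nextm(n + 1);
  nextm[n] = n;
  for (int i = n - 1; i >= 0; --i) nextm[i] = (Lb[i] >= mm) ? i : nextm[i + 1];
  std::vector<double> suf(n + 1);
  std::vector<int64_t> firstO(n + 1, -1);
  std::vector<int64_t> Dlit(n + 1, 0);
  suf[n] = 1;
  auto adj = [&](int q, int64_t pe) -> double {
    if (q >= n || firstO[q] < 0) return 0;
    int64_t d0 = firstO[q] - Dlit[q];
    return (double)varint_len(zigzag(d0 - pe)) - (double)varint_len(zigzag(d0));
  };
  for (int i = n - 1; i >= 0; --i) {
    if (Lb[i] >= mm) {
      int nx = i + Lb[i];
      suf[i] = 1 + varint_len(zigzag((int64_t)Ob[i])) +
               varint_len((uint64_t)(Lb[i] - mm)) +
               suf[nx] + adj(nx, (int64_t)Ob[i] + Lb[i]);
      firstO[i] = Ob[i];
      Dlit[i] = 0;
    } else {
      int j = nextm[i];  // == nextm[i + 1] since there is no match at i
      int r = j - i;
      suf[i] = 1 + varint_len((uint64_t)r) + r + suf[j] + adj(j, (int64_t)r);
      firstO[i] = (j < n) ? (int64_t)Ob[j] : -1;
      Dlit[i] = (j < n) ? (int64_t)r : 0;
    }
  }

  // ---- prefix costs vs refA: pref[i] = cost of parse(s[0:i]) ----
  // One forward parse; tokens before the cut are identical to the full
  // parse (same reference cursor), so only the crossing token is reworked.
  Finder fa(refA, mmer);
  std::vector<Token> toks;
  greedy_parse(s, fa, mm, toks);
  std::vector<double> pref(n + 1, 0);
  pref[0] = 1;
  double cost_before = 0;        // serialized bytes of tokens fully before p
  double cost_before_run = 0;    // cost_before at the start of the preceding literal run
  int prev_run = 0;              // length of literal run immediately preceding p
  int64_t expected = 0;          // reference cursor before the current token
  std::vector<int> rps, exts, idx;
  for (const Token& t : toks) {
    if (t.type == 1) {
      for (int q = 1; q <= t.len; ++q)
        pref[t.pos + q] = cost_before + 1 + varint_len((uint64_t)q) + q + 1;
      cost_before_run = cost_before;
      cost_before += 1 + varint_len((uint64_t)t.len) + t.len;
      prev_run = t.len;
      expected += t.len;
    } else {
      // cuts inside the match shorter than min_match become literals that
      // merge with any immediately preceding literal run
      int tmax_lit = std::min(mm - 1, t.len);
      for (int q = 1; q <= tmax_lit; ++q) {
        int r = prev_run + q;
        pref[t.pos + q] = cost_before_run + 1 + varint_len((uint64_t)r) + r + 1;
      }
      if (t.len >= mm) {
        // truncated matches: leftmost reference occurrence of s[pos:pos+q]
        fa.candidates(s, (size_t)t.pos, rps, exts);
        idx.resize(rps.size());
        for (size_t z = 0; z < idx.size(); ++z) idx[z] = (int)z;
        std::sort(idx.begin(), idx.end(),
                  [&](int a, int b) { return exts[a] > exts[b]; });
        size_t ptr = 0;
        int curmin = INT_MAX;
        for (int q = t.len; q >= mm; --q) {
          while (ptr < idx.size() && exts[idx[ptr]] >= q) {
            curmin = std::min(curmin, rps[idx[ptr]]);
            ++ptr;
          }
          pref[t.pos + q] = cost_before + 1 +
                            varint_len(zigzag((int64_t)curmin - expected)) +
                            varint_len((uint64_t)(q - mm)) + 1;
        }
      }
      cost_before += 1 + varint_len(zigzag((int64_t)t.off - expected)) +
                     varint_len((uint64_t)(t.len - mm));
      cost_before_run = cost_before;
      prev_run = 0;
      expected = (int64_t)t.off + t.len;
    }
  }

  int best_i = imin;
  double best = pref[imin] + suf[imin];
  for (int i = imin + 1; i <= imax; ++i) {
    double tot = pref[i] + suf[i];
    if (tot < best) { best = tot; best_i = i; }
  }
  return List::create(_["i"] = best_i, _["cost"] = best);
}
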