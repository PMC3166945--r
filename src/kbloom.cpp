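// Packed k-mer codec, Bloom / counting Bloom filters, and the two-pass
// counting engine. k-mers are stored as big-endian, right-aligned 2-bit
// packed byte arrays (A=00, C=01, G=10, T=11, first base most significant),
// so memcmp order on the bytes equals lexicographic order on the sequence.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

namespace {

const uint64_t SEED_MIX = 0x9E3779B97F4A7C15ULL;
const int MAX_D = 64;

inline int nbytes_for(int k) { return (2 * k + 7) / 8; }

inline int code_for(char ch) {
  switch (ch) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// pad = number of always-zero leading bits in byte 0 (2k mod 8 is even, so
// codes never straddle a byte boundary awkwardly: shift is one of 0,2,4,6).
inline void put_code(unsigned char* out, int pad, int i, int code) {
  int bit = pad + 2 * i;
  out[bit >> 3] |= (unsigned char)(code << (6 - (bit & 7)));
}
inline int get_code(const unsigned char* in, int pad, int i) {
  int bit = pad + 2 * i;
  return (in[bit >> 3] >> (6 - (bit & 7))) & 3;
}

// MurmurHash64A (public-domain construction), seeded.
uint64_t mmh64(const unsigned char* data, int len, uint64_t seed) {
  const uint64_t m = 0xc6a4a7935bd1e995ULL;
  const int r = 47;
  uint64_t h = seed ^ ((uint64_t)len * m);
  const unsigned char* end = data + (len & ~7);
  while (data != end) {
    uint64_t k;
    std::memcpy(&k, data, 8);
    data += 8;
    k *= m; k ^= k >> r; k *= m;
    h ^= k; h *= m;
  }
  int rem = len & 7;
  if (rem) {
    uint64_t k = 0;
    std::memcpy(&k, data, rem);
    h ^= k; h *= m;
  }
  h ^= h >> r; h *= m; h ^= h >> r;
  return h;
}

// Double hashing: two seeded 64-bit hashes u, v (v forced odd),
// index_i = (u + i*v) mod m.
inline void dh_indices(const unsigned char* key, int nb, int d, uint64_t m,
                       uint64_t seed, uint64_t* ix) {
  uint64_t u = mmh64(key, nb, seed);
  uint64_t v = mmh64(key, nb, seed ^ SEED_MIX) | 1ULL;
  for (int i = 0; i < d; ++i) ix[i] = (u + (uint64_t)i * v) % m;
}

struct Bloom {
  uint64_t m;
  int d;
  uint64_t seed;
  std::vector<uint64_t> w;
  Bloom(uint64_t m_, int d_, uint64_t s)
      : m(m_), d(d_), seed(s), w((m_ + 63) / 64, 0) {}
  void insert(const unsigned char* key, int nb) {
    uint64_t ix[MAX_D];
    dh_indices(key, nb, d, m, seed, ix);
    for (int i = 0; i < d; ++i) w[ix[i] >> 6] |= 1ULL << (ix[i] & 63);
  }
  bool contains(const unsigned char* key, int nb) const {
    uint64_t ix[MAX_D];
    dh_indices(key, nb, d, m, seed, ix);
    for (int i = 0; i < d; ++i)
      if (!((w[ix[i] >> 6] >> (ix[i] & 63)) & 1ULL)) return false;
    return true;
  }
  double n_set() const {
    double s = 0;
    for (uint64_t x : w) s += __builtin_popcountll(x);
    return s;
  }
};

// m counters of b = ceil(log2 c) bits, saturating at c - 1, bit-packed.
struct CBF {
  uint64_t m;
  int d, c, b;
  uint64_t seed;
  std::vector<uint64_t> w;
  CBF(uint64_t m_, int c_, int d_, uint64_t s)
      : m(m_), d(d_), c(c_), seed(s) {
    b = 1;
    while ((1ULL << b) < (uint64_t)c) ++b;
    w.assign((m * (uint64_t)b + 63) / 64, 0);
  }
  uint32_t get(uint64_t i) const {
    uint64_t bit = i * (uint64_t)b;
    uint64_t wi = bit >> 6;
    int off = (int)(bit & 63);
    uint64_t val = w[wi] >> off;
    if (off + b > 64) val |= w[wi + 1] << (64 - off);
    return (uint32_t)(val & ((1ULL << b) - 1));
  }
  void set(uint64_t i, uint32_t v) {
    uint64_t bit = i * (uint64_t)b;
    uint64_t wi = bit >> 6;
    int off = (int)(bit & 63);
    uint64_t mask = (1ULL << b) - 1;
    w[wi] = (w[wi] & ~(mask << off)) | ((uint64_t)v << off);
    if (off + b > 64) {
      uint64_t himask = (1ULL << (off + b - 64)) - 1;
      w[wi + 1] = (w[wi + 1] & ~himask) | ((uint64_t)v >> (64 - off));
    }
  }
  void insert(const unsigned char* key, int nb) {
    uint64_t ix[MAX_D];
    dh_indices(key, nb, d, m, seed, ix);
    for (int i = 0; i < d; ++i) {
      uint32_t v = get(ix[i]);
      if (v < (uint32_t)(c - 1)) set(ix[i], v + 1);
    }
  }
  bool at_cutoff(const unsigned char* key, int nb) const {
    uint64_t ix[MAX_D];
    dh_indices(key, nb, d, m, seed, ix);
    for (int i = 0; i < d; ++i)
      if (get(ix[i]) != (uint32_t)(c - 1)) return false;
    return true;
  }
  uint32_t min_count(const unsigned char* key, int nb) const {
    uint64_t ix[MAX_D];
    dh_indices(key, nb, d, m, seed, ix);
    uint32_t mn = get(ix[0]);
    for (int i = 1; i < d; ++i) {
      uint32_t v = get(ix[i]);
      if (v < mn) mn = v;
    }
    return mn;
  }
};

uint64_t as_u64(double x, const char* what) {
  if (!R_finite(x) || x < 0 || x > 9007199254740992.0)
    stop("%s must be a non-negative finite number below 2^53", what);
  return (uint64_t)x;
}

// Visit the canonical form of every ACGT-only window of length k.
template <typename F>
void stream_canonical(const char* s, int L, int k, F&& f) {
  if (L < k || k < 1) return;
  int nb = nbytes_for(k), pad = 8 * nb - 2 * k;
  std::vector<unsigned char> fwd(nb), rc(nb);
  int scanned = 0, last_bad = -1;
  for (int pos = 0; pos + k <= L; ++pos) {
    int end = pos + k;
    while (scanned < end) {
      if (code_for(s[scanned]) < 0) last_bad = scanned;
      ++scanned;
    }
    if (last_bad >= pos) continue;
    std::fill(fwd.begin(), fwd.end(), 0);
    std::fill(rc.begin(), rc.end(), 0);
    for (int i = 0; i < k; ++i) {
      int c = code_for(s[pos + i]);
      put_code(fwd.data(), pad, i, c);
      put_code(rc.data(), pad, k - 1 - i, 3 - c);
    }
    const unsigned char* key =
        (std::memcmp(fwd.data(), rc.data(), nb) <= 0) ? fwd.data() : rc.data();
    f(key, nb);
  }
}

void check_keys(const RawMatrix& keys, int k) {
  if (keys.nrow() != nbytes_for(k))
    stop("packed k-mer byte width (%d) does not match k = %d", keys.nrow(), k);
}

}  // namespace

// [[Rcpp::export]]
RawMatrix cpp_encode(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  if (n == 0) stop("no sequences to encode");
  int k = (int)LENGTH(STRING_ELT(seqs, 0));
  if (k < 1) stop("k-mer length must be at least 1");
  int nb = nbytes_for(k), pad = 8 * nb - 2 * k;
  RawMatrix out(nb, n);
  for (R_xlen_t j = 0; j < n; ++j) {
    SEXP el = STRING_ELT(seqs, j);
    if (el == NA_STRING) stop("sequence %ld is NA", (long)(j + 1));
    if ((int)LENGTH(el) != k)
      stop("all sequences must have the same length (sequence %ld has %d bases, expected %d)",
           (long)(j + 1), (int)LENGTH(el), k);
    const char* s = CHAR(el);
    unsigned char* col = (unsigned char*)&out(0, j);
    for (int i = 0; i < k; ++i) {
      int c = code_for(s[i]);
      if (c < 0)
        stop("invalid character '%c' at position %d of sequence %ld (only A, C, G, T allowed)",
             s[i], i + 1, (long)(j + 1));
      put_code(col, pad, i, c);
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(RawMatrix keys, int k) {
  check_keys(keys, k);
  int nb = keys.nrow(), pad = 8 * nb - 2 * k;
  unsigned char padmask = pad ? (unsigned char)(((1u << pad) - 1u) << (8 - pad)) : 0;
  R_xlen_t n = keys.ncol();
  CharacterVector out(n);
  std::string buf(k, 'A');
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (R_xlen_t j = 0; j < n; ++j) {
    const unsigned char* col = (const unsigned char*)&keys(0, j);
    if (padmask && (col[0] & padmask))
      stop("corrupt packed k-mer %ld: value is not below 4^k", (long)(j + 1));
    for (int i = 0; i < k; ++i) buf[i] = bases[get_code(col, pad, i)];
    out[j] = buf;
  }
  return out;
}

// [[Rcpp::export]]
RawMatrix cpp_revcomp(RawMatrix keys, int k) {
  check_keys(keys, k);
  int nb = keys.nrow(), pad = 8 * nb - 2 * k;
  R_xlen_t n = keys.ncol();
  RawMatrix out(nb, n);
  for (R_xlen_t j = 0; j < n; ++j) {
    const unsigned char* in = (const unsigned char*)&keys(0, j);
    unsigned char* o = (unsigned char*)&out(0, j);
    for (int i = 0; i < k; ++i)
      put_code(o, pad, i, 3 - get_code(in, pad, k - 1 - i));
  }
  return out;
}

// [[Rcpp::export]]
RawMatrix cpp_canonical(RawMatrix keys, int k) {
  check_keys(keys, k);
  int nb = keys.nrow(), pad = 8 * nb - 2 * k;
  R_xlen_t n = keys.ncol();
  RawMatrix out(nb, n);
  std::vector<unsigned char> rc(nb);
  for (R_xlen_t j = 0; j < n; ++j) {
    const unsigned char* in = (const unsigned char*)&keys(0, j);
    std::fill(rc.begin(), rc.end(), 0);
    for (int i = 0; i < k; ++i)
      put_code(rc.data(), pad, i, 3 - get_code(in, pad, k - 1 - i));
    const unsigned char* key =
        (std::memcmp(in, rc.data(), nb) <= 0) ? in : rc.data();
    std::memcpy(&out(0, j), key, nb);
  }
  return out;
}

// [[Rcpp::export]]
RawMatrix cpp_extract(std::string seq, int k) {
  if (k < 1) stop("k must be at least 1");
  std::vector<unsigned char> flat;
  int nb = nbytes_for(k);
  stream_canonical(seq.c_str(), (int)seq.size(), k,
                   [&](const unsigned char* key, int nbk) {
                     flat.insert(flat.end(), key, key + nbk);
                   });
  R_xlen_t n = (R_xlen_t)(flat.size() / nb);
  RawMatrix out(nb, n);
  if (n > 0) std::memcpy(&out(0, 0), flat.data(), flat.size());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_make_hashes(RawVector key, int d, double m, double seed) {
  if (d < 1 || d > MAX_D) stop("d must be between 1 and %d", MAX_D);
  uint64_t mm = as_u64(m, "m");
  if (mm < 1) stop("m must be at least 1");
  uint64_t ix[MAX_D];
  dh_indices((const unsigned char*)RAW(key), (int)key.size(), d, mm,
             as_u64(seed, "seed"), ix);
  NumericVector out(d);
  for (int i = 0; i < d; ++i) out[i] = (double)ix[i];
  return out;
}

// [[Rcpp::export]]
SEXP cpp_bloom_new(double m, int d, double seed) {
  uint64_t mm = as_u64(m, "m");
  if (mm < 1) stop("m must be at least 1");
  if (d < 1 || d > MAX_D) stop("d must be between 1 and %d", MAX_D);
  return XPtr<Bloom>(new Bloom(mm, d, as_u64(seed, "seed")), true);
}

// [[Rcpp::export]]
void cpp_bloom_insert(SEXP ptr, RawMatrix keys) {
  XPtr<Bloom> bf(ptr);
  int nb = keys.nrow();
  for (R_xlen_t j = 0; j < keys.ncol(); ++j)
    bf->insert((const unsigned char*)&keys(0, j), nb);
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_contains(SEXP ptr, RawMatrix keys) {
  XPtr<Bloom> bf(ptr);
  int nb = keys.nrow();
  LogicalVector out(keys.ncol());
  for (R_xlen_t j = 0; j < keys.ncol(); ++j)
    out[j] = bf->contains((const unsigned char*)&keys(0, j), nb);
  return out;
}

// [[Rcpp::export]]
double cpp_bloom_n_set(SEXP ptr) {
  XPtr<Bloom> bf(ptr);
  return bf->n_set();
}

// [[Rcpp::export]]
SEXP cpp_cbf_new(double m, int c, int d, double seed) {
  uint64_t mm = as_u64(m, "m");
  if (mm < 1) stop("m must be at least 1");
  if (c < 2) stop("cutoff c must be at least 2");
  if (c > 256) stop("cutoff c above 256 is not supported");
  if (d < 1 || d > MAX_D) stop("d must be between 1 and %d", MAX_D);
  return XPtr<CBF>(new CBF(mm, c, d, as_u64(seed, "seed")), true);
}

// [[Rcpp::export]]
void cpp_cbf_insert(SEXP ptr, RawMatrix keys) {
  XPtr<CBF> cf(ptr);
  int nb = keys.nrow();
  for (R_xlen_t j = 0; j < keys.ncol(); ++j)
    cf->insert((const unsigned char*)&keys(0, j), nb);
}

// [[Rcpp::export]]
LogicalVector cpp_cbf_at_cutoff(SEXP ptr, RawMatrix keys) {
  XPtr<CBF> cf(ptr);
  int nb = keys.nrow();
  LogicalVector out(keys.ncol());
  for (R_xlen_t j = 0; j < keys.ncol(); ++j)
    out[j] = cf->at_cutoff((const unsigned char*)&keys(0, j), nb);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_cbf_min_count(SEXP ptr, RawMatrix keys) {
  XPtr<CBF> cf(ptr);
  int nb = keys.nrow();
  IntegerVector out(keys.ncol());
  for (R_xlen_t j = 0; j < keys.ncol(); ++j)
    out[j] = (int)cf->min_count((const unsigned char*)&keys(0, j), nb);
  return out;
}

// First pass: stage k-mers in the filter; table (count placeholder 0) every
// k-mer the filter already reports at the cutoff.
// [[Rcpp::export]]
List cpp_pass1(CharacterVector reads, int k, SEXP filter, bool counting, int c) {
  Bloom* bf = nullptr;
  CBF* cf = nullptr;
  if (counting) cf = XPtr<CBF>(filter).get();
  else bf = XPtr<Bloom>(filter).get();
  if (counting && cf->c != c) stop("filter cutoff does not match c");
  std::unordered_set<std::string> tabled;
  std::vector<std::string> order;
  double n_occ = 0, n_filter_inserts = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    if (el == NA_STRING) continue;
    stream_canonical(CHAR(el), (int)LENGTH(el), k,
                     [&](const unsigned char* key, int nb) {
                       ++n_occ;
                       bool at = counting ? cf->at_cutoff(key, nb)
                                          : bf->contains(key, nb);
                       if (at) {
                         std::string ks((const char*)key, nb);
                         if (tabled.insert(ks).second) order.push_back(ks);
                       } else {
                         if (counting) cf->insert(key, nb);
                         else bf->insert(key, nb);
                         ++n_filter_inserts;
                       }
                     });
  }
  int nb = nbytes_for(k);
  RawMatrix keys(nb, (R_xlen_t)order.size());
  for (size_t j = 0; j < order.size(); ++j)
    std::memcpy(&keys(0, (R_xlen_t)j), order[j].data(), nb);
  return List::create(_["keys"] = keys, _["n_occurrences"] = n_occ,
                      _["n_filter_inserts"] = n_filter_inserts);
}

// Second pass: exact recount of the tabled keys, then prune counts < c.
// [[Rcpp::export]]
List cpp_pass2(CharacterVector reads, int k, RawMatrix keys, int c, int cap) {
  check_keys(keys, k);
  if (cap < 1) stop("max_count must be at least 1");
  int nb = keys.nrow();
  R_xlen_t N = keys.ncol();
  std::unordered_map<std::string, int> tab;
  std::vector<std::string> order((size_t)N);
  tab.reserve((size_t)N * 2);
  for (R_xlen_t j = 0; j < N; ++j) {
    order[(size_t)j].assign((const char*)&keys(0, j), nb);
    tab[order[(size_t)j]] = 0;
  }
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    if (el == NA_STRING) continue;
    stream_canonical(CHAR(el), (int)LENGTH(el), k,
                     [&](const unsigned char* key, int nbk) {
                       auto it = tab.find(std::string((const char*)key, nbk));
                       if (it != tab.end() && it->second < cap) ++(it->second);
                     });
  }
  std::vector<R_xlen_t> keep;
  for (R_xlen_t j = 0; j < N; ++j)
    if (tab[order[(size_t)j]] >= c) keep.push_back(j);
  RawMatrix okeys(nb, (R_xlen_t)keep.size());
  IntegerVector counts((R_xlen_t)keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    std::memcpy(&okeys(0, (R_xlen_t)i), order[(size_t)keep[i]].data(), nb);
    counts[(R_xlen_t)i] = tab[order[(size_t)keep[i]]];
  }
  return List::create(_["keys"] = okeys, _["counts"] = counts,
                      _["n_removed"] = (double)(N - (R_xlen_t)keep.size()));
}

// One-pass approximate mode (c = 2): table a k-mer with count 2 the first
// time the filter claims to have seen it, then increment.
// [[Rcpp::export]]
List cpp_count_approx(CharacterVector reads, int k, SEXP filter, int cap) {
  XPtr<Bloom> bf(filter);
  if (cap < 2) stop("max_count must be at least 2");
  std::unordered_map<std::string, int> tab;
  std::vector<std::string> order;
  double n_occ = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    if (el == NA_STRING) continue;
    stream_canonical(CHAR(el), (int)LENGTH(el), k,
                     [&](const unsigned char* key, int nb) {
                       ++n_occ;
                       std::string ks((const char*)key, nb);
                       auto it = tab.find(ks);
                       if (it != tab.end()) {
                         if (it->second < cap) ++(it->second);
                       } else if (bf->contains(key, nb)) {
                         tab.emplace(ks, 2);
                         order.push_back(ks);
                       } else {
                         bf->insert(key, nb);
                       }
                     });
  }
  int nb = nbytes_for(k);
  RawMatrix keys(nb, (R_xlen_t)order.size());
  IntegerVector counts((R_xlen_t)order.size());
  for (size_t j = 0; j < order.size(); ++j) {
    std::memcpy(&keys(0, (R_xlen_t)j), order[j].data(), nb);
    counts[(R_xlen_t)j] = tab[order[j]];
  }
  return List::create(_["keys"] = keys, _["counts"] = counts,
                      _["n_occurrences"] = n_occ);
}
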