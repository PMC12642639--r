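// MurmurHash3 x64_128 (Austin Appleby, public domain), low 64 bits, plus
// FracMinHash k-mer sketching. Hashes cross the C++/R boundary as fixed-width
// 16-char lowercase hex strings because R has no 64-bit unsigned integer type;
// the retention threshold h < 2^64/scaled is applied here on native uint64.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static inline uint64_t getblock64(const uint8_t* p, size_t i) {
  uint64_t k;
  std::memcpy(&k, p + i * 8, 8);  // little-endian assumed (all target platforms)
  return k;
}

// Low 64 bits (h1) of MurmurHash3_x64_128.
static uint64_t murmur3_low64(const char* key, size_t len, uint32_t seed) {
  const uint8_t* data = reinterpret_cast<const uint8_t*>(key);
  const size_t nblocks = len / 16;

  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (size_t i = 0; i < nblocks; i++) {
    uint64_t k1 = getblock64(data, i * 2 + 0);
    uint64_t k2 = getblock64(data, i * 2 + 1);

    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t* tail = data + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;

  switch (len & 15) {
    case 15: k2 ^= ((uint64_t)tail[14]) << 48; // fallthrough
    case 14: k2 ^= ((uint64_t)tail[13]) << 40; // fallthrough
    case 13: k2 ^= ((uint64_t)tail[12]) << 32; // fallthrough
    case 12: k2 ^= ((uint64_t)tail[11]) << 24; // fallthrough
    case 11: k2 ^= ((uint64_t)tail[10]) << 16; // fallthrough
    case 10: k2 ^= ((uint64_t)tail[9])  << 8;  // fallthrough
    case  9: k2 ^= ((uint64_t)tail[8])  << 0;
             k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
             // fallthrough
    case  8: k1 ^= ((uint64_t)tail[7]) << 56;  // fallthrough
    case  7: k1 ^= ((uint64_t)tail[6]) << 48;  // fallthrough
    case  6: k1 ^= ((uint64_t)tail[5]) << 40;  // fallthrough
    case  5: k1 ^= ((uint64_t)tail[4]) << 32;  // fallthrough
    case  4: k1 ^= ((uint64_t)tail[3]) << 24;  // fallthrough
    case  3: k1 ^= ((uint64_t)tail[2]) << 16;  // fallthrough
    case  2: k1 ^= ((uint64_t)tail[1]) << 8;   // fallthrough
    case  1: k1 ^= ((uint64_t)tail[0]) << 0;
             k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= (uint64_t)len; h2 ^= (uint64_t)len;
  h1 += h2;
  h2 += h1;
  h1 = fmix64(h1);
  h2 = fmix64(h2);
  h1 += h2;
  return h1;
}

static const uint32_t HASH_SEED = 42;

static inline std::string to_hex(uint64_t v) {
  static const char* digits = "0123456789abcdef";
  std::string s(16, '0');
  for (int i = 15; i >= 0; --i) { s[i] = digits[v & 0xf]; v >>= 4; }
  return s;
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline bool valid_dna(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline bool valid_aa(char c) {
  static const std::string aas = "ACDEFGHIKLMNPQRSTVWY";
  return aas.find(c) != std::string::npos;
}

// Retention threshold H/scaled with H = 2^64; scaled = 1 keeps everything.
static inline uint64_t max_hash_for_scaled(double scaled) {
  if (scaled <= 1.0) return std::numeric_limits<uint64_t>::max();
  long double h = 18446744073709551616.0L; // 2^64
  return (uint64_t)(h / (long double)scaled);
}

// [[Rcpp::export(name = ".hash_kmer_cpp")]]
CharacterVector hash_kmer_cpp(CharacterVector kmers, bool canonical) {
  size_t n = kmers.size();
  CharacterVector out(n);
  for (size_t i = 0; i < n; ++i) {
    std::string km = as<std::string>(kmers[i]);
    if (canonical) {
      std::string rc(km.rbegin(), km.rend());
      for (auto& c : rc) c = complement(c);
      if (rc < km) km = rc;
    }
    out[i] = to_hex(murmur3_low64(km.data(), km.size(), HASH_SEED));
  }
  return out;
}

// All retained k-mer hashes of one sequence, in order of occurrence
// (duplicates included; the caller deduplicates). Invalid-character k-mers
// are skipped. attr "n_kmers" carries the count of valid k-mers seen.
// [[Rcpp::export(name = ".sketch_hashes_cpp")]]
CharacterVector sketch_hashes_cpp(std::string seq, int k, double scaled,
                                  bool dna) {
  std::vector<std::string> kept;
  long n_valid = 0;
  uint64_t max_hash = max_hash_for_scaled(scaled);
  long n = (long)seq.size();
  if (n >= k) {
    std::string rc;
    if (dna) {
      rc.assign(seq.rbegin(), seq.rend());
      for (auto& c : rc) c = complement(c);
    }
    for (long i = 0; i + k <= n; ++i) {
      bool ok = true;
      for (long j = i; j < i + k; ++j) {
        char c = seq[(size_t)j];
        if (dna ? !valid_dna(c) : !valid_aa(c)) { ok = false; break; }
      }
      if (!ok) continue;
      ++n_valid;
      uint64_t h;
      if (dna) {
        // canonical: lexicographic min of k-mer and its reverse complement
        const char* fwd = seq.data() + i;
        const char* rev = rc.data() + (n - i - k);
        if (std::memcmp(rev, fwd, (size_t)k) < 0)
          h = murmur3_low64(rev, (size_t)k, HASH_SEED);
        else
          h = murmur3_low64(fwd, (size_t)k, HASH_SEED);
      } else {
        h = murmur3_low64(seq.data() + i, (size_t)k, HASH_SEED);
      }
      if (scaled <= 1.0 || h < max_hash) kept.push_back(to_hex(h));
    }
  }
  CharacterVector out(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) out[i] = kept[i];
  out.attr("n_kmers") = (double)n_valid;
  return out;
}
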