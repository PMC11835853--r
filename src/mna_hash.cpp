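// Iterative computation of canonical MNA descriptor identities.
//
// The level-k MNA descriptor of an atom is its element label plus the
// canonically sorted level-(k-1) descriptors of its bonded neighbours
// (hydrogens included as neighbours).  The literal canonical string
// enumerates all backtracking walks of length <= k and grows exponentially
// with the level, so descriptor identity is carried instead by a 128-bit
// Merkle-style fingerprint: two independent 64-bit FNV-1a lanes over
// (element label, neighbour fingerprints sorted by their 128-bit value).
// Equal fingerprints <=> equal canonical strings (up to hash collision,
// ~2^-128); the fingerprint is a pure function of the descriptor, hence
// stable across graphs, sessions and platforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdio>

using namespace Rcpp;

static const uint64_t FNV_BASIS = 14695981039346656037ULL;
static const uint64_t FNV_PRIME = 1099511628211ULL;
static const uint64_t LANE_SEED[2] = {0ULL, 0x9e3779b97f4a7c15ULL};

struct H128 {
  uint64_t a, b;
  bool operator<(const H128& o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

static inline void absorb(uint64_t& h, const void* data, size_t n) {
  const unsigned char* p = static_cast<const unsigned char*>(data);
  for (size_t i = 0; i < n; ++i) { h ^= p[i]; h *= FNV_PRIME; }
}

static std::string hex128(const H128& h) {
  char buf[33];
  std::snprintf(buf, sizeof buf, "%016llx%016llx",
                (unsigned long long)h.a, (unsigned long long)h.b);
  return std::string(buf);
}

// elements: element symbol per atom; bonds: 2-column 1-based atom indices.
// Returns a list with one character vector per level 0..max_level holding
// every atom's fingerprint at that level.
// [[Rcpp::export(name = ".mna_hash_levels")]]
List mna_hash_levels_cpp(CharacterVector elements, IntegerMatrix bonds,
                         int max_level) {
  const int n = elements.size();
  if (max_level < 0) stop("level must be >= 0");

  std::vector<std::vector<int>> adj(n);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int u = bonds(k, 0) - 1, v = bonds(k, 1) - 1;
    if (u < 0 || u >= n || v < 0 || v >= n) stop("bond index out of range");
    adj[u].push_back(v);
    adj[v].push_back(u);
  }

  std::vector<H128> cur(n), nxt(n);
  for (int i = 0; i < n; ++i) {
    const char* lab = CHAR(STRING_ELT(elements, i));
    for (int s = 0; s < 2; ++s) {
      uint64_t h = FNV_BASIS ^ LANE_SEED[s];
      absorb(h, lab, std::char_traits<char>::length(lab));
      (s == 0 ? cur[i].a : cur[i].b) = h;
    }
  }

  List out(max_level + 1);
  CharacterVector lv0(n);
  for (int i = 0; i < n; ++i) lv0[i] = hex128(cur[i]);
  out[0] = lv0;

  std::vector<H128> kids;
  for (int level = 1; level <= max_level; ++level) {
    for (int i = 0; i < n; ++i) {
      kids.clear();
      for (int v : adj[i]) kids.push_back(cur[v]);
      std::sort(kids.begin(), kids.end());
      const char* lab = CHAR(STRING_ELT(elements, i));
      for (int s = 0; s < 2; ++s) {
        uint64_t h = FNV_BASIS ^ LANE_SEED[s];
        absorb(h, lab, std::char_traits<char>::length(lab));
        const unsigned char open = '(';
        absorb(h, &open, 1);
        for (const H128& c : kids) {
          absorb(h, &c.a, 8);
          absorb(h, &c.b, 8);
        }
        (s == 0 ? nxt[i].a : nxt[i].b) = h;
      }
    }
    std::swap(cur, nxt);
    CharacterVector lv(n);
    for (int i = 0; i < n; ++i) lv[i] = hex128(cur[i]);
    out[level] = lv;
  }
  return out;
}
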