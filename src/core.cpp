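#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <random>

using namespace Rcpp;

// 2-bit encoding with A=0, C=1, G=2, T=3 so that integer order on codes of
// equal k equals lexicographic order on the strings; the most significant
// pair encodes the first base. k in [1,32] fits one uint64_t.

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t kmask(int k) {
  return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

// returns false on non-ACGT input
static bool encode_kmer(const char *s, int k, uint64_t &code) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2code(s[i]);
    if (b < 0) return false;
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL)); // complement of least sig. base
    code >>= 2;
  }
  return rc;
}

static inline uint64_t canon_code(uint64_t code, int k, bool canonical) {
  if (!canonical) return code;
  uint64_t rc = revcomp_code(code, k);
  return code < rc ? code : rc;
}

static void check_k(int k) {
  if (k < 1 || k > 32)
    stop("k must be in [1, 32] (one 64-bit code per k-mer); got %d", k);
}

// [[Rcpp::export]]
CharacterVector cpp_roundtrip(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    int k = (int)s.size();
    check_k(k);
    uint64_t code;
    if (!encode_kmer(s.c_str(), k, code))
      stop("non-ACGT character in k-mer '%s'", s.c_str());
    out[i] = decode_kmer(code, k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'A');
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base2code(s[s.size() - 1 - j]);
      if (b < 0)
        stop("non-ACGT character '%c' in sequence %d", s[s.size() - 1 - j],
             i + 1);
      r[j] = CODE2BASE[3 - b];
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'A');
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base2code(s[s.size() - 1 - j]);
      if (b < 0)
        stop("non-ACGT character '%c' in sequence %d", s[s.size() - 1 - j],
             i + 1);
      r[j] = CODE2BASE[3 - b];
    }
    out[i] = (s <= r) ? s : r;
  }
  return out;
}

// Extract the distinct (canonical) k-mers of a set of sequences. Sequences
// are folded to upper case; any non-ACGT character splits the sequence, so
// no k-mer ever spans an ambiguous position. Result is sorted by packed
// code, i.e. lexicographically.
// [[Rcpp::export]]
CharacterVector cpp_build_kmer_set(CharacterVector seqs, int k,
                                   bool canonical) {
  check_k(k);
  std::unordered_set<uint64_t> members;
  uint64_t mask = kmask(k);
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    uint64_t code = 0;
    int run = 0; // valid bases accumulated since last split
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base2code((char)std::toupper((unsigned char)s[j]));
      if (b < 0) {
        run = 0;
        code = 0;
        continue;
      }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) members.insert(canon_code(code, k, canonical));
    }
  }
  std::vector<uint64_t> v(members.begin(), members.end());
  std::sort(v.begin(), v.end());
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = decode_kmer(v[i], k);
  return out;
}

// ---- greedy simplitigs --------------------------------------------------

// Greedy maximal-simplitig construction: seed with the next unused k-mer,
// extend forwards base by base while some candidate k-mer (tested in the
// policy's nucleotide order) is still in the working set, then extend
// backwards the same way; every matched k-mer is removed from the working
// set the moment it is appended, the seed included.
// [[Rcpp::export]]
CharacterVector cpp_compute_simplitigs(CharacterVector kmers, int k,
                                       bool canonical,
                                       std::string seed_order, int seed,
                                       std::string nuc_order) {
  check_k(k);
  if (nuc_order.size() != 4)
    stop("nucleotide order must be a permutation of ACGT");
  int trial[4];
  {
    bool seen[4] = {false, false, false, false};
    for (int i = 0; i < 4; ++i) {
      int b = base2code(nuc_order[i]);
      if (b < 0 || seen[b])
        stop("nucleotide order must be a permutation of ACGT");
      seen[b] = true;
      trial[i] = b;
    }
  }

  int n = kmers.size();
  std::vector<uint64_t> seeds(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k)
      stop("k-mer %d has length %d, expected %d", i + 1, (int)s.size(), k);
    uint64_t code;
    if (!encode_kmer(s.c_str(), k, code))
      stop("non-ACGT character in k-mer '%s'", s.c_str());
    seeds[i] = canon_code(code, k, canonical);
  }
  if (seed_order == "sorted-code") {
    std::sort(seeds.begin(), seeds.end());
  } else if (seed_order == "random") {
    std::mt19937 rng((uint32_t)seed);
    std::shuffle(seeds.begin(), seeds.end(), rng);
  } else if (seed_order != "insertion") {
    stop("unknown seed order '%s'", seed_order.c_str());
  }

  std::unordered_set<uint64_t> work(seeds.begin(), seeds.end());
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  std::vector<std::string> out;

  for (int i = 0; i < n; ++i) {
    uint64_t s0 = seeds[i];
    auto it = work.find(s0);
    if (it == work.end()) continue; // already consumed
    work.erase(it);
    std::string simplitig = decode_kmer(s0, k);

    // forward: candidate = (k-1)-suffix of the last k-mer + trial base
    uint64_t last = s0;
    for (;;) {
      bool extended = false;
      for (int t = 0; t < 4; ++t) {
        uint64_t cand = ((last << 2) | (uint64_t)trial[t]) & mask;
        auto hit = work.find(canon_code(cand, k, canonical));
        if (hit != work.end()) {
          work.erase(hit);
          simplitig.push_back(CODE2BASE[trial[t]]);
          last = cand;
          extended = true;
          break;
        }
      }
      if (!extended) break;
    }

    // backward: candidate = trial base + (k-1)-prefix of the first k-mer
    uint64_t first = s0;
    for (;;) {
      bool extended = false;
      for (int t = 0; t < 4; ++t) {
        uint64_t cand = ((uint64_t)trial[t] << shift) | (first >> 2);
        auto hit = work.find(canon_code(cand, k, canonical));
        if (hit != work.end()) {
          work.erase(hit);
          simplitig.insert(simplitig.begin(), CODE2BASE[trial[t]]);
          first = cand;
          extended = true;
          break;
        }
      }
      if (!extended) break;
    }

    out.push_back(simplitig);
    if (work.empty()) break;
  }
  return wrap(out);
}

// ---- maximal unitigs ----------------------------------------------------

namespace {

struct UnitigCtx {
  const std::unordered_set<uint64_t> *members;
  int k;
  bool canonical;
  uint64_t mask;
  int shift;

  bool has(uint64_t code) const {
    return members->count(canon_code(code, k, canonical)) > 0;
  }
  // number of admissible one-base forward continuations of an oriented k-mer
  int outdeg(uint64_t code, uint64_t &only) const {
    int d = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t cand = ((code << 2) | b) & mask;
      if (has(cand)) { ++d; only = cand; }
    }
    return d;
  }
  int indeg(uint64_t code, uint64_t &only) const {
    int d = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t cand = (b << shift) | (code >> 2);
      if (has(cand)) { ++d; only = cand; }
    }
    return d;
  }
};

} // namespace

// Maximal unitigs of the node-centric graph. A node is compacted into its
// predecessor's unitig only when the connecting edge is the unique
// continuation on both sides (out-degree 1 at the tail, in-degree 1 at the
// head), degrees taken per traversal orientation in the bi-directed model.
// Isolated cycles left after the sweep are broken at the smallest packed
// code. Every (canonical) k-mer is emitted exactly once.
// [[Rcpp::export]]
CharacterVector cpp_compute_unitigs(CharacterVector kmers, int k,
                                    bool canonical) {
  check_k(k);
  int n = kmers.size();
  std::vector<uint64_t> nodes(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k)
      stop("k-mer %d has length %d, expected %d", i + 1, (int)s.size(), k);
    uint64_t code;
    if (!encode_kmer(s.c_str(), k, code))
      stop("non-ACGT character in k-mer '%s'", s.c_str());
    nodes[i] = canon_code(code, k, canonical);
  }
  std::sort(nodes.begin(), nodes.end());
  nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());
  std::unordered_set<uint64_t> members(nodes.begin(), nodes.end());

  UnitigCtx ctx{&members, k, canonical, kmask(k), 2 * (k - 1)};
  std::unordered_set<uint64_t> visited;
  std::vector<std::string> out;

  // walk forward from an oriented start k-mer, consuming canonical nodes
  auto walk = [&](uint64_t start) {
    std::string u = decode_kmer(start, k);
    visited.insert(canon_code(start, k, canonical));
    uint64_t cur = start;
    for (;;) {
      uint64_t nxt = 0, tmp = 0;
      if (ctx.outdeg(cur, nxt) != 1) break;
      if (visited.count(canon_code(nxt, k, canonical))) break;
      if (ctx.indeg(nxt, tmp) != 1) break;
      u.push_back(CODE2BASE[nxt & 3ULL]);
      visited.insert(canon_code(nxt, k, canonical));
      cur = nxt;
    }
    out.push_back(u);
  };

  // an oriented k-mer starts a unitig unless it is the unique continuation
  // of a unique predecessor
  auto is_start = [&](uint64_t code) {
    uint64_t pred = 0, tmp = 0;
    if (ctx.indeg(code, pred) != 1) return true;
    return ctx.outdeg(pred, tmp) != 1;
  };

  for (uint64_t node : nodes) {
    if (visited.count(node)) continue;
    if (is_start(node)) { walk(node); continue; }
    if (canonical) {
      uint64_t rc = revcomp_code(node, k);
      if (rc != node && is_start(rc)) walk(rc);
    }
  }
  // leftover nodes sit on isolated cycles; break each at its smallest code
  for (uint64_t node : nodes)
    if (!visited.count(node)) walk(node);

  return wrap(out);
}
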