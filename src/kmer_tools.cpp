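#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding; -1 for anything that is not A/C/G/T.
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// splitmix64 finaliser: deterministic, well-mixed 64-bit hash of the packed
// canonical k-mer code. The value returned to R is truncated to the top 53
// bits so it is exactly representable in a double.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double hash53(uint64_t code) {
  return static_cast<double>(mix64(code) >> 11);
}

// Enumerate canonical k-mer hash values along a sequence. Positions whose
// window contains a non-ACGT base are skipped. Returns one value per valid
// window (with duplicates).
static std::vector<double> kmer_hashes(const std::string& s, int k) {
  std::vector<double> out;
  const size_t n = s.size();
  if (n < static_cast<size_t>(k)) return out;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(b)) & mask;
    rev = (rev >> 2) | (static_cast<uint64_t>(3 - b) << shift);
    if (++valid >= k) {
      uint64_t canon = std::min(fwd, rev);
      out.push_back(hash53(canon));
    }
  }
  return out;
}

//' @title Canonical k-mer hash values of a sequence
//' @description Internal helper: hash every canonical k-mer window of a
//'   DNA string with a deterministic 53-bit hash. Windows containing
//'   non-ACGT characters are skipped.
//' @param seq single DNA string
//' @param k k-mer size
//' @return numeric vector of hash values, one per valid window
//' @keywords internal
// [[Rcpp::export]]
NumericVector kmer_hash_values(std::string seq, int k) {
  std::vector<double> h = kmer_hashes(seq, k);
  return NumericVector(h.begin(), h.end());
}

// [[Rcpp::export]]
NumericVector minhash_sketch_cpp(std::vector<std::string> seqs, int k,
                                 int sketch_size) {
  std::unordered_set<uint64_t> seen;
  std::vector<double> all;
  for (const std::string& s : seqs) {
    std::vector<double> h = kmer_hashes(s, k);
    for (double v : h) {
      uint64_t key = static_cast<uint64_t>(v);
      if (seen.insert(key).second) all.push_back(v);
    }
  }
  if (static_cast<int>(all.size()) > sketch_size) {
    std::nth_element(all.begin(), all.begin() + sketch_size, all.end());
    all.resize(sketch_size);
  }
  std::sort(all.begin(), all.end());
  return NumericVector(all.begin(), all.end());
}

// Exact k-mer anchor matches between a set of query sequences and one
// target sequence. For the minus strand the reverse complement of each
// query is scanned, and reported query offsets are in reverse-complement
// coordinates (chaining stays diagonal-collinear that way). k-mers
// occurring more than max_occ times in the target are treated as repeats
// and skipped.
// [[Rcpp::export]]
DataFrame kmer_anchor_hits(std::vector<std::string> queries,
                           std::string target, int k, int max_occ) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // index target k-mers (forward orientation only)
  std::unordered_map<uint64_t, std::vector<int> > idx;
  {
    uint64_t fwd = 0; int valid = 0;
    for (size_t i = 0; i < target.size(); ++i) {
      int b = base2bit(target[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | static_cast<uint64_t>(b)) & mask;
      if (++valid >= k) {
        std::vector<int>& v = idx[fwd];
        if (static_cast<int>(v.size()) <= max_occ)
          v.push_back(static_cast<int>(i) - k + 1);
      }
    }
  }

  std::vector<int> out_q, out_qpos, out_tpos;
  std::vector<int> out_strand; // 1 = '+', -1 = '-'

  for (size_t qi = 0; qi < queries.size(); ++qi) {
    for (int pass = 0; pass < 2; ++pass) {
      std::string s = queries[qi];
      if (pass == 1) { // reverse complement
        std::string rc(s.rbegin(), s.rend());
        for (char& c : rc) {
          switch (c) {
          case 'A': case 'a': c = 'T'; break;
          case 'C': case 'c': c = 'G'; break;
          case 'G': case 'g': c = 'C'; break;
          case 'T': case 't': c = 'A'; break;
          default: c = 'N';
          }
        }
        s = rc;
      }
      uint64_t fwd = 0; int valid = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { valid = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | static_cast<uint64_t>(b)) & mask;
        if (++valid >= k) {
          std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            idx.find(fwd);
          if (it == idx.end()) continue;
          if (static_cast<int>(it->second.size()) > max_occ) continue;
          int qpos = static_cast<int>(i) - k + 1;
          for (int tpos : it->second) {
            out_q.push_back(static_cast<int>(qi) + 1);
            out_qpos.push_back(qpos);
            out_tpos.push_back(tpos);
            out_strand.push_back(pass == 0 ? 1 : -1);
          }
        }
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["qpos"] = out_qpos,
                           _["tpos"] = out_tpos, _["strand"] = out_strand);
}
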