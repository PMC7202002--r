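#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
using namespace Rcpp;

// Canonical k-mer machinery shared by the spectrum, branch-frequency and
// scaffold-coverage code. Windows containing any non-ACGT character are
// skipped everywhere.

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

static inline std::string canonical(const std::string& s) {
  std::string rc = revcomp(s);
  return (rc < s) ? rc : s;
}

typedef std::unordered_map<std::string, int> kmap;

static void count_seq(const std::string& seq, int k, kmap& counts,
                      long long& windows) {
  int n = (int)seq.size();
  if (n < k) return;
  // rightmost index (0-based) of a non-ACGT char seen so far, -1 if none
  int last_bad = -1;
  for (int i = 0; i < k - 1; ++i) if (!is_acgt(seq[i])) last_bad = i;
  for (int i = 0; i + k <= n; ++i) {
    int j = i + k - 1;
    if (!is_acgt(seq[j])) last_bad = j;
    if (last_bad >= i) continue;  // window contains a non-ACGT base
    ++windows;
    ++counts[canonical(seq.substr(i, k))];
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  kmap counts;
  long long windows = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    count_seq(seq, k, counts, windows);
  }
  CharacterVector km(counts.size());
  IntegerVector ct(counts.size());
  R_xlen_t i = 0;
  for (auto& kv : counts) {
    km[i] = kv.first;
    ct[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = km, _["count"] = ct,
                      _["windows"] = (double)windows);
}

// Branch classification over (k-1)-mer vertices of the de Bruijn graph of
// solid k-mers. A side (left or right extensions of the vertex) with >= 2
// solid extensions is a repeat branch when the top two counts sum to more
// than c_rep * coverage_mode, and a variant branch when the minor/major
// ratio of the top two is >= r_min. Repeat classification takes precedence
// at the vertex level.
// [[Rcpp::export]]
List cpp_branch_stats(CharacterVector kmers, IntegerVector counts, int k,
                      double coverage_mode, double r_min, double c_rep) {
  kmap solid;
  solid.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    solid[as<std::string>(kmers[i])] = counts[i];

  std::unordered_set<std::string> vertices;
  vertices.reserve(solid.size() * 2);
  for (auto& kv : solid) {
    vertices.insert(canonical(kv.first.substr(0, k - 1)));
    vertices.insert(canonical(kv.first.substr(1, k - 1)));
  }

  const char bases[4] = {'A', 'C', 'G', 'T'};
  long long n_variant = 0, n_repeat = 0;
  for (const auto& v : vertices) {
    bool variant = false, repeat = false;
    for (int side = 0; side < 2; ++side) {
      int top1 = 0, top2 = 0, n_ext = 0;
      for (int b = 0; b < 4; ++b) {
        std::string km = side == 0 ? v + bases[b] : bases[b] + v;
        auto it = solid.find(canonical(km));
        if (it == solid.end()) continue;
        ++n_ext;
        int c = it->second;
        if (c >= top1) { top2 = top1; top1 = c; }
        else if (c > top2) top2 = c;
      }
      if (n_ext < 2) continue;
      double combined = (double)top1 + (double)top2;
      if (combined > c_rep * coverage_mode) repeat = true;
      else if ((double)top2 / (double)top1 >= r_min) variant = true;
    }
    if (repeat) ++n_repeat;
    else if (variant) ++n_variant;
  }
  return List::create(_["n_vertices"] = (double)vertices.size(),
                      _["n_variant"] = (double)n_variant,
                      _["n_repeat"] = (double)n_repeat);
}

// Mean read-spectrum multiplicity over each scaffold's canonical k-mers.
// K-mers absent from the read spectrum contribute multiplicity 0.
// [[Rcpp::export]]
NumericVector cpp_scaffold_kmer_coverage(CharacterVector seqs,
                                         CharacterVector kmers,
                                         IntegerVector counts, int k) {
  kmap tab;
  tab.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    tab[as<std::string>(kmers[i])] = counts[i];

  NumericVector out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int n = (int)seq.size();
    long long total = 0, nwin = 0;
    int last_bad = -1;
    for (int i = 0; i < k - 1 && i < n; ++i)
      if (!is_acgt(seq[i])) last_bad = i;
    for (int i = 0; i + k <= n; ++i) {
      int j = i + k - 1;
      if (!is_acgt(seq[j])) last_bad = j;
      if (last_bad >= i) continue;
      ++nwin;
      auto it = tab.find(canonical(seq.substr(i, k)));
      if (it != tab.end()) total += it->second;
    }
    out[s] = nwin > 0 ? (double)total / (double)nwin : NA_REAL;
  }
  return out;
}

// Does any length-k window of `read` (either strand) lie within Hamming
// distance <= hdist of any length-k window of any contaminant sequence?
// Non-ACGT characters mismatch everything, including themselves.
static inline bool hamming_le(const char* a, const char* b, int k, int hdist) {
  int d = 0;
  for (int i = 0; i < k; ++i) {
    if (!(is_acgt(a[i]) && a[i] == b[i])) {
      if (++d > hdist) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_kmer_contaminant_match(CharacterVector reads,
                                         CharacterVector contams,
                                         int k, int hdist) {
  std::vector<std::string> cwin;
  for (R_xlen_t c = 0; c < contams.size(); ++c) {
    std::string s = as<std::string>(contams[c]);
    for (int i = 0; i + k <= (int)s.size(); ++i)
      cwin.push_back(s.substr(i, k));
  }
  LogicalVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    bool hit = false;
    for (int strand = 0; strand < 2 && !hit; ++strand) {
      const std::string& s = strand == 0 ? fwd : rev;
      for (int i = 0; i + k <= (int)s.size() && !hit; ++i)
        for (size_t w = 0; w < cwin.size() && !hit; ++w)
          if (hamming_le(s.c_str() + i, cwin[w].c_str(), k, hdist))
            hit = true;
    }
    out[r] = hit;
  }
  return out;
}
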