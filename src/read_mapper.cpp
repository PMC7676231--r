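#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding; -1 for non-ACGT
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char rc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > KmerIndex;

// index all k-mers of refs: hash -> (ref index, 0-based position)
static void build_index(const std::vector<std::string>& refs, int k, KmerIndex& idx) {
  for (size_t g = 0; g < refs.size(); ++g) {
    const std::string& s = refs[g];
    if ((int)s.size() < k) continue;
    uint64_t h = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= k)
        idx[h].emplace_back((int)g, (int)(i - k + 1));
    }
  }
}

// hash of the k-mer starting at off; false if it contains non-ACGT
static inline bool kmer_at(const std::string& s, int off, int k, uint64_t& h) {
  h = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[off + i]);
    if (b < 0) return false;
    h = (h << 2) | (uint64_t)b;
  }
  return true;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = rc_base(s[i]);
  return r;
}

// Candidate ungapped alignment of a read against one reference at a fixed
// diagonal; returns matches over the overlapping span.
static inline void extend(const std::string& read, const std::string& ref,
                          int diag, int& matches, int& ov_len) {
  int rl = (int)read.size(), gl = (int)ref.size();
  int gs = diag < 0 ? 0 : diag;              // overlap start on ref
  int ge = diag + rl - 1; if (ge > gl - 1) ge = gl - 1;
  ov_len = ge - gs + 1;
  matches = 0;
  if (ov_len <= 0) { ov_len = 0; return; }
  const char* rp = read.data() + (gs - diag);
  const char* gp = ref.data() + gs;
  for (int i = 0; i < ov_len; ++i)
    if (rp[i] == gp[i] && base2bit(rp[i]) >= 0) ++matches;
}

struct MapIndex {
  std::vector<std::string> refs;
  int k;
  KmerIndex idx;
};

// Build a reusable k-mer index over reference sequences.
// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector genes, int k) {
  MapIndex* mi = new MapIndex();
  mi->refs.resize(genes.size());
  for (int i = 0; i < genes.size(); ++i)
    mi->refs[i] = as<std::string>(genes[i]);
  mi->k = k;
  build_index(mi->refs, k, mi->idx);
  XPtr<MapIndex> ptr(mi, true);
  return ptr;
}

static List map_reads_core(const std::vector<std::string>& refs,
                           const KmerIndex& idx, int k,
                           CharacterVector reads, double min_identity,
                           bool both_strands) {
  List out(reads.size());
  std::vector<std::pair<int,int> > cands;   // (gene, diag)
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int rl = (int)rd.size();
    int best_score = -1;
    std::vector<int> best_genes;
    int n_strands = both_strands ? 2 : 1;
    for (int strand = 0; strand < n_strands; ++strand) {
      // a full-length perfect forward hit cannot be beaten on the
      // reverse strand; skip the second scan
      if (strand == 1 && best_score == rl) break;
      std::string seq = (strand == 0) ? rd : revcomp(rd);
      if (rl < k) continue;
      cands.clear();
      // disjoint seeds plus the final k-mer
      for (int off = 0; off <= rl - k; off += k) {
        uint64_t h;
        if (!kmer_at(seq, off, k, h)) continue;
        KmerIndex::const_iterator it = idx.find(h);
        if (it == idx.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j)
          cands.emplace_back(it->second[j].first, it->second[j].second - off);
      }
      {
        int off = rl - k;
        if (off > 0 && off % k != 0) {
          uint64_t h;
          if (kmer_at(seq, off, k, h)) {
            KmerIndex::const_iterator it = idx.find(h);
            if (it != idx.end())
              for (size_t j = 0; j < it->second.size(); ++j)
                cands.emplace_back(it->second[j].first, it->second[j].second - off);
          }
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (size_t c = 0; c < cands.size(); ++c) {
        int matches, ov_len;
        extend(seq, refs[cands[c].first], cands[c].second, matches, ov_len);
        if (ov_len <= 0) continue;
        double ident = (double)matches / (double)ov_len;
        if (ident < min_identity) continue;
        if (matches > best_score) {
          best_score = matches;
          best_genes.assign(1, cands[c].first + 1);
        } else if (matches == best_score) {
          best_genes.push_back(cands[c].first + 1);
        }
      }
    }
    std::sort(best_genes.begin(), best_genes.end());
    best_genes.erase(std::unique(best_genes.begin(), best_genes.end()),
                     best_genes.end());
    out[r] = IntegerVector(best_genes.begin(), best_genes.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector genes,
                   int k, double min_identity, bool both_strands) {
  std::vector<std::string> refs(genes.size());
  for (int i = 0; i < genes.size(); ++i) refs[i] = as<std::string>(genes[i]);
  KmerIndex idx;
  build_index(refs, k, idx);
  return map_reads_core(refs, idx, k, reads, min_identity, both_strands);
}

// [[Rcpp::export]]
List cpp_map_reads_indexed(SEXP index, CharacterVector reads,
                           double min_identity, bool both_strands) {
  XPtr<MapIndex> mi(index);
  return map_reads_core(mi->refs, mi->idx, mi->k, reads, min_identity,
                        both_strands);
}

// Exact-overlap matching of reads against excised marker windows: a read
// counts toward a window iff the overlapping segment matches with zero
// mismatches over at least min_overlap nt (either strand).
// [[Rcpp::export]]
List cpp_match_windows(CharacterVector reads, CharacterVector windows,
                       int min_overlap, int k) {
  std::vector<std::string> wins(windows.size());
  for (int i = 0; i < windows.size(); ++i) wins[i] = as<std::string>(windows[i]);
  KmerIndex idx;
  build_index(wins, k, idx);

  IntegerVector counts(windows.size());
  LogicalVector read_hit(reads.size());
  std::vector<std::pair<int,int> > cands;
  std::vector<int> matched;
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int rl = (int)rd.size();
    matched.clear();
    for (int strand = 0; strand < 2; ++strand) {
      std::string seq = (strand == 0) ? rd : revcomp(rd);
      if (rl < k) continue;
      cands.clear();
      int step = k / 2; if (step < 1) step = 1;
      for (int off = 0; off <= rl - k; off += step) {
        uint64_t h;
        if (!kmer_at(seq, off, k, h)) continue;
        KmerIndex::const_iterator it = idx.find(h);
        if (it == idx.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j)
          cands.emplace_back(it->second[j].first, it->second[j].second - off);
      }
      {
        int off = rl - k;
        uint64_t h;
        if (off >= 0 && kmer_at(seq, off, k, h)) {
          KmerIndex::const_iterator it = idx.find(h);
          if (it != idx.end())
            for (size_t j = 0; j < it->second.size(); ++j)
              cands.emplace_back(it->second[j].first, it->second[j].second - off);
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (size_t c = 0; c < cands.size(); ++c) {
        int matches, ov_len;
        extend(seq, wins[cands[c].first], cands[c].second, matches, ov_len);
        if (ov_len < min_overlap) continue;
        if (matches == ov_len)                 // zero mismatches, no gaps
          matched.push_back(cands[c].first);
      }
    }
    std::sort(matched.begin(), matched.end());
    matched.erase(std::unique(matched.begin(), matched.end()), matched.end());
    for (size_t m = 0; m < matched.size(); ++m) counts[matched[m]]++;
    read_hit[r] = !matched.empty();
  }
  return List::create(_["window_counts"] = counts, _["read_matched"] = read_hit);
}
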