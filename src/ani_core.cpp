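#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Fragment-based ANI: the query is cut into non-overlapping fragments, each
// fragment is anchored to the reference by shared k-mers (both strands),
// placed on its best-supported diagonal, and scored as ungapped percent
// identity over the part of the fragment that projects inside one reference
// contig. Fragments below the seed-identity or minimum-overlap thresholds
// are unmapped; ANI is the mean identity over mapped fragments.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

struct RefIndex {
  std::string seq;                    // concatenated contigs
  std::vector<long> cstart, cend;     // contig bounds in seq (half-open)
  // sorted (k-mer hash, ref position) pairs; lookups by binary search
  std::vector<std::pair<uint64_t, long> > kmers;
  int k;
};

// matches per query k-mer are capped to guard against low-complexity blowup
static const size_t KMER_HIT_CAP = 256;

static void index_reference(const CharacterVector& contigs, int k, RefIndex& idx) {
  idx.k = k;
  long total = 0;
  for (int i = 0; i < contigs.size(); ++i) total += LENGTH(STRING_ELT(contigs, i));
  idx.seq.reserve(total);
  for (int i = 0; i < contigs.size(); ++i) {
    std::string c = as<std::string>(contigs[i]);
    idx.cstart.push_back((long) idx.seq.size());
    idx.seq += c;
    idx.cend.push_back((long) idx.seq.size());
  }
  idx.kmers.reserve(idx.seq.size());
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0;
  int run = 0;  // consecutive unambiguous bases ending here
  for (size_t ci = 0; ci < idx.cstart.size(); ++ci) {
    h = 0; run = 0;
    for (long p = idx.cstart[ci]; p < idx.cend[ci]; ++p) {
      int b = base_code(idx.seq[p]);
      if (b < 0) { h = 0; run = 0; continue; }
      h = ((h << 2) | (uint64_t) b) & mask;
      if (++run >= k) idx.kmers.push_back(std::make_pair(h, p - k + 1));
    }
  }
  std::sort(idx.kmers.begin(), idx.kmers.end());
}

// Identity of `frag` placed at diagonal d against the reference, clipped to
// the contig holding the anchor. Returns overlap length via out param.
static double diag_identity(const std::string& frag, const RefIndex& idx,
                            long diag, long anchor_ref_pos, long& overlap_out) {
  // locate contig containing the anchor
  size_t lo = std::upper_bound(idx.cstart.begin(), idx.cstart.end(),
                               anchor_ref_pos) - idx.cstart.begin();
  size_t ci = lo == 0 ? 0 : lo - 1;
  long fl = (long) frag.size();
  long qlo = std::max(0L, idx.cstart[ci] - diag);
  long qhi = std::min(fl, idx.cend[ci] - diag);
  overlap_out = qhi - qlo;
  if (overlap_out <= 0) return -1.0;
  long matches = 0;
  for (long q = qlo; q < qhi; ++q) {
    char a = frag[q], b = idx.seq[diag + q];
    if (a == b && base_code(a) >= 0) ++matches;
  }
  return 100.0 * (double) matches / (double) overlap_out;
}

// best identity of a fragment (one strand) against the indexed reference
static double map_fragment_strand(const std::string& frag, const RefIndex& idx,
                                  long min_overlap) {
  const int k = idx.k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<long, int> diag_count;
  std::unordered_map<long, long> diag_anchor;  // one ref anchor per diagonal
  uint64_t h = 0; int run = 0;
  for (long i = 0; i < (long) frag.size(); ++i) {
    int b = base_code(frag[i]);
    if (b < 0) { h = 0; run = 0; continue; }
    h = ((h << 2) | (uint64_t) b) & mask;
    if (++run >= k) {
      std::vector<std::pair<uint64_t, long> >::const_iterator it =
        std::lower_bound(idx.kmers.begin(), idx.kmers.end(),
                         std::make_pair(h, (long) -1));
      long qpos = i - k + 1;
      size_t hits = 0;
      for (; it != idx.kmers.end() && it->first == h && hits < KMER_HIT_CAP;
           ++it, ++hits) {
        long rpos = it->second;
        long d = rpos - qpos;
        diag_count[d]++;
        if (diag_anchor.find(d) == diag_anchor.end()) diag_anchor[d] = rpos;
      }
    }
  }
  if (diag_count.empty()) return -1.0;
  // evaluate the best-supported diagonals (up to 8)
  std::vector<std::pair<int, long> > diags;
  diags.reserve(diag_count.size());
  for (std::unordered_map<long, int>::iterator it = diag_count.begin();
       it != diag_count.end(); ++it)
    diags.push_back(std::make_pair(-it->second, it->first));
  size_t ntop = std::min((size_t) 8, diags.size());
  std::partial_sort(diags.begin(), diags.begin() + ntop, diags.end());
  double best = -1.0;
  for (size_t t = 0; t < ntop; ++t) {
    long d = diags[t].second;
    long overlap = 0;
    double ident = diag_identity(frag, idx, d, diag_anchor[d], overlap);
    if (overlap >= min_overlap && ident > best) best = ident;
  }
  return best;
}

// [[Rcpp::export]]
List cpp_fragment_ani(CharacterVector query_contigs, CharacterVector ref_contigs,
                      int fragment_len, int k, double min_identity_seed,
                      int min_overlap) {
  if (k < 4 || k > 32) stop("k must be between 4 and 32");
  RefIndex idx;
  index_reference(ref_contigs, k, idx);
  int total = 0, mapped = 0;
  std::vector<double> idents;
  for (int ci = 0; ci < query_contigs.size(); ++ci) {
    std::string contig = as<std::string>(query_contigs[ci]);
    int nfrag = (int) (contig.size() / (size_t) fragment_len);
    for (int f = 0; f < nfrag; ++f) {
      ++total;
      std::string frag = contig.substr((size_t) f * fragment_len, fragment_len);
      // forward strand first; ties broken toward forward by strict '>'
      double best = map_fragment_strand(frag, idx, min_overlap);
      double rc = map_fragment_strand(revcomp_str(frag), idx, min_overlap);
      if (rc > best) best = rc;
      if (best >= min_identity_seed) {
        ++mapped;
        idents.push_back(best);
      }
    }
  }
  double ani = NA_REAL;
  if (mapped > 0) {
    double s = 0.0;
    for (size_t i = 0; i < idents.size(); ++i) s += idents[i];
    ani = s / (double) mapped;
  }
  return List::create(_["ani"] = ani,
                      _["fragments_mapped"] = mapped,
                      _["fragments_total"] = total,
                      _["fragment_identities"] = wrap(idents));
}

// Substitute bases at a fixed per-base rate, each error drawn uniformly from
// the three alternative bases. Uses the R RNG so set.seed() applies.
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)");
  static const char* bases = "ACGT";
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (rate > 0) {
      for (size_t j = 0; j < s.size(); ++j) {
        int b = base_code(s[j]);
        if (b < 0) continue;
        if (R::unif_rand() < rate) {
          int shift = 1 + (int) (R::unif_rand() * 3.0);
          if (shift > 3) shift = 3;
          s[j] = bases[(b + shift) % 4];
        }
      }
    }
    out[i] = s;
  }
  return out;
}
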