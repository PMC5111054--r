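// Hot loops of the read-processing pipeline: 2-bit k-mer machinery for the
// seed-and-extend transcriptome mapper and the ribosomal screen, the
// BWA-style 3' quality trimmer, Hamming-distance barcode matching, and
// substitution-error injection for the simulator (driven by R's RNG so that
// set.seed() governs reproducibility).

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::iterator it = r.begin(); it != r.end(); ++it)
    *it = comp_base(*it);
  return r;
}

// All valid (ACGT-only) k-mers of s as (2-bit code, 0-based start).
static void kmers_of(const std::string &s, int k,
                     std::vector<std::pair<uint64_t, int> > &out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k || k < 1 || k > 31) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t code = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid >= k) out.push_back(std::make_pair(code, i - k + 1));
  }
}

// kmer -> list of (ref index, ref position)
typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > RefIndex;

static RefIndex build_index(const std::vector<std::string> &refs, int k) {
  RefIndex idx;
  std::vector<std::pair<uint64_t, int> > km;
  for (size_t r = 0; r < refs.size(); ++r) {
    kmers_of(refs[r], k, km);
    for (size_t i = 0; i < km.size(); ++i)
      idx[km[i].first].push_back(std::make_pair((int)r, km[i].second));
  }
  return idx;
}

// Diagonal offset keys: diag = ref_pos - read_pos can be negative.
static const int DIAG_OFFSET = 1 << 24;

// Seed-and-extend one strand of a read; keeps, per gene, the best ungapped
// match count over the gene's most-seeded diagonal.
static void map_strand(const std::string &read, const RefIndex &idx,
                       const std::vector<std::string> &refs, int k,
                       int min_seed, std::unordered_map<int, int> &best_by_gene) {
  std::vector<std::pair<uint64_t, int> > km;
  kmers_of(read, k, km);
  std::unordered_map<int, int> seeds;
  std::unordered_map<int64_t, int> diag_seeds;
  for (size_t i = 0; i < km.size(); ++i) {
    RefIndex::const_iterator it = idx.find(km[i].first);
    if (it == idx.end()) continue;
    const std::vector<std::pair<int, int> > &hits = it->second;
    for (size_t h = 0; h < hits.size(); ++h) {
      seeds[hits[h].first] += 1;
      int64_t key = ((int64_t)hits[h].first << 32) |
        (uint32_t)(hits[h].second - km[i].second + DIAG_OFFSET);
      diag_seeds[key] += 1;
    }
  }
  for (std::unordered_map<int, int>::const_iterator g = seeds.begin();
       g != seeds.end(); ++g) {
    if (g->second < min_seed) continue;
    int best_diag = 0, best_n = -1;
    for (std::unordered_map<int64_t, int>::const_iterator d = diag_seeds.begin();
         d != diag_seeds.end(); ++d) {
      if ((int)(d->first >> 32) != g->first) continue;
      int diag = (int)(uint32_t)(d->first & 0xffffffffLL) - DIAG_OFFSET;
      if (d->second > best_n || (d->second == best_n && diag < best_diag)) {
        best_n = d->second;
        best_diag = diag;
      }
    }
    const std::string &ref = refs[g->first];
    int score = 0;
    for (int i = 0; i < (int)read.size(); ++i) {
      int j = i + best_diag;
      if (j < 0 || j >= (int)ref.size()) continue;
      int a = base_code(read[i]);
      if (a >= 0 && a == base_code(ref[j])) ++score;
    }
    std::unordered_map<int, int>::iterator it = best_by_gene.find(g->first);
    if (it == best_by_gene.end() || score > it->second)
      best_by_gene[g->first] = score;
  }
}

struct Cand { int gene; int score; };
static bool cand_lt(const Cand &a, const Cand &b) {
  if (a.score != b.score) return a.score > b.score;
  return a.gene < b.gene;
}

static std::vector<Cand> map_one(const std::string &read, const RefIndex &idx,
                                 const std::vector<std::string> &refs,
                                 int k, int min_seed, bool both_strands) {
  std::unordered_map<int, int> best;
  map_strand(read, idx, refs, k, min_seed, best);
  if (both_strands) map_strand(revcomp(read), idx, refs, k, min_seed, best);
  std::vector<Cand> out;
  for (std::unordered_map<int, int>::const_iterator b = best.begin();
       b != best.end(); ++b) {
    Cand c; c.gene = b->first; c.score = b->second;
    out.push_back(c);
  }
  std::sort(out.begin(), out.end(), cand_lt);
  return out;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs, int k,
                   int min_seed, bool both_strands) {
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);
  RefIndex idx = build_index(R, k);
  const int n = reads.size();
  IntegerVector gene(n, NA_INTEGER), score(n, NA_INTEGER), n_top(n, 0);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<Cand> cands = map_one(rd, idx, R, k, min_seed, both_strands);
    if (cands.empty()) continue;
    gene[i] = cands[0].gene + 1;
    score[i] = cands[0].score;
    int t = 0;
    for (size_t c = 0; c < cands.size(); ++c)
      if (cands[c].score == cands[0].score) ++t;
    n_top[i] = t;
  }
  return List::create(_["gene"] = gene, _["score"] = score, _["n_top"] = n_top);
}

// Full candidate list for a single read (the map_read() API).
// [[Rcpp::export]]
List cpp_map_candidates(std::string read, CharacterVector refs, int k,
                        int min_seed, bool both_strands) {
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);
  RefIndex idx = build_index(R, k);
  std::vector<Cand> cands = map_one(read, idx, R, k, min_seed, both_strands);
  IntegerVector gene(cands.size()), score(cands.size());
  for (size_t i = 0; i < cands.size(); ++i) {
    gene[i] = cands[i].gene + 1;
    score[i] = cands[i].score;
  }
  return List::create(_["gene"] = gene, _["score"] = score);
}

// Maximum number of distinct read k-mers shared with any single reference
// sequence, checking the read and its reverse complement.
// [[Rcpp::export]]
IntegerVector cpp_max_shared_kmers(CharacterVector reads, CharacterVector refs,
                                   int k) {
  const int nref = refs.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  std::vector<std::pair<uint64_t, int> > km;
  for (int r = 0; r < nref; ++r) {
    std::string s = as<std::string>(refs[r]);
    kmers_of(s, k, km);
    std::unordered_set<uint64_t> seen;
    for (size_t i = 0; i < km.size(); ++i)
      if (seen.insert(km[i].first).second) idx[km[i].first].push_back(r);
  }
  const int n = reads.size();
  IntegerVector out(n, 0);
  std::vector<int> counts(nref);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int best = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = (strand == 0) ? rd : revcomp(rd);
      kmers_of(s, k, km);
      std::unordered_set<uint64_t> uniq;
      for (size_t j = 0; j < km.size(); ++j) uniq.insert(km[j].first);
      std::fill(counts.begin(), counts.end(), 0);
      for (std::unordered_set<uint64_t>::const_iterator u = uniq.begin();
           u != uniq.end(); ++u) {
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          idx.find(*u);
        if (it == idx.end()) continue;
        for (size_t r = 0; r < it->second.size(); ++r)
          counts[it->second[r]] += 1;
      }
      for (int r = 0; r < nref; ++r) if (counts[r] > best) best = counts[r];
    }
    out[i] = best;
  }
  return out;
}

// BWA -q rule on Phred+33 quality strings: cut at the 0-based position c
// maximizing sum_{i>=c} (q_threshold - q_i); retain [0, c). If the maximum is
// <= 0 the read is untouched. Ties keep the largest c (least trimming).
// Returns the retained length per read.
// [[Rcpp::export]]
IntegerVector cpp_trim_bwa(CharacterVector quals, int q_threshold) {
  const int n = quals.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    const int len = (int)q.size();
    long best = 0, sum = 0;
    int cut = len;
    for (int j = len - 1; j >= 0; --j) {
      sum += q_threshold - ((int)q[j] - 33);
      if (sum > best) { best = sum; cut = j; }
    }
    out[i] = cut;
  }
  return out;
}

// Hamming-distance barcode matching against a design whitelist.
// Returns per query: 1-based design index; 0 = no barcode within
// max_mismatch; -1 = ambiguous (>= 2 candidates tied at the minimum
// distance); -2 = query length differs from the design barcode length.
// [[Rcpp::export]]
IntegerVector cpp_match_barcode(CharacterVector queries,
                                CharacterVector barcodes, int max_mismatch) {
  const int nb = barcodes.size();
  std::vector<std::string> bc(nb);
  std::unordered_map<std::string, int> exact;
  int bc_len = -1;
  for (int i = 0; i < nb; ++i) {
    bc[i] = as<std::string>(barcodes[i]);
    if (bc_len < 0) bc_len = (int)bc[i].size();
    exact[bc[i]] = i;
  }
  const int n = queries.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(queries[i]);
    if ((int)q.size() != bc_len) { out[i] = -2; continue; }
    std::unordered_map<std::string, int>::const_iterator hit = exact.find(q);
    if (hit != exact.end()) { out[i] = hit->second + 1; continue; }
    if (max_mismatch < 1) { out[i] = 0; continue; }
    int best = max_mismatch + 1, best_idx = -1, n_best = 0;
    for (int b = 0; b < nb; ++b) {
      int d = 0;
      const std::string &s = bc[b];
      for (int p = 0; p < bc_len; ++p) {
        if (q[p] != s[p] && ++d > best) break;
      }
      if (d < best) { best = d; best_idx = b; n_best = 1; }
      else if (d == best && d <= max_mismatch) ++n_best;
    }
    if (best > max_mismatch) out[i] = 0;
    else if (n_best > 1) out[i] = -1;
    else out[i] = best_idx + 1;
  }
  return out;
}

// Per-base substitution errors at the given rate; substitutes with one of the
// three other bases. Uses R's RNG (reproducible under set.seed).
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  if (rate <= 0) return clone(seqs);
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (R::unif_rand() < rate) {
        int cur = base_code(s[j]);
        if (cur < 0) {
          s[j] = bases[(int)(R::unif_rand() * 4) & 3];
        } else {
          int sub = (int)(R::unif_rand() * 3);
          if (sub > 2) sub = 2;
          if (sub >= cur) ++sub;
          s[j] = bases[sub];
        }
      }
    }
    out[i] = s;
  }
  return out;
}
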