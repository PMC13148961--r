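// Bit-level core: 5-bit k-mer encoding, seeded 64-bit hashing, the
// interleaved Bloom filter bit matrix, forward-strand minimizers and
// branch-and-bound substitution-variant enumeration. Everything that must
// stay in exact uint64 arithmetic lives here; R sees sequences, counts and
// (for k <= 10, where doubles are exact) numeric k-mer codes.
#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// canonical 20-letter alphabet in the fixed alphabetical ordinal order
static const char ALPHABET[20] = {'A','C','D','E','F','G','H','I','K','L',
                                  'M','N','P','Q','R','S','T','V','W','Y'};

static inline int residue_ord(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19;
    default:  return -1;
  }
}

static inline char collapse(char c, bool collapse_il) {
  return (collapse_il && c == 'L') ? 'I' : c;
}

// encode a canonical k-mer; returns false if any residue is non-canonical
static bool encode_str(const std::string& km, bool collapse_il, uint64_t& out) {
  uint64_t code = 0;
  for (size_t i = 0; i < km.size(); ++i) {
    int o = residue_ord(collapse(km[i], collapse_il));
    if (o < 0) return false;
    code = (code << 5) | (uint64_t)o;
  }
  out = code;
  return true;
}

static std::string decode_code(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = ALPHABET[code & 31u];
    code >>= 5;
  }
  return s;
}

// --- hashing ---------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_code(uint64_t code, uint64_t seed) {
  return splitmix64(code ^ splitmix64(seed));
}

static std::vector<uint64_t> seeds_from_r(const NumericVector& seeds) {
  std::vector<uint64_t> out(seeds.size());
  for (int i = 0; i < seeds.size(); ++i) out[i] = (uint64_t)seeds[i];
  return out;
}

// --- bit matrix helpers (position-major: bit index = pos * b + bin) --------

static inline void set_bit(Rbyte* bits, uint64_t idx) {
  bits[idx >> 3] |= (Rbyte)(1u << (idx & 7u));
}

static inline bool get_bit(const Rbyte* bits, uint64_t idx) {
  return (bits[idx >> 3] >> (idx & 7u)) & 1u;
}

// --- k-mer stream of one sequence ------------------------------------------

// valid (all-canonical) k-mers of one sequence, in order; 0-based start
// positions; number of windows dropped for non-canonical residues
struct KmerStream {
  std::vector<uint64_t> codes;
  std::vector<int> pos;
  int dropped;
};

static KmerStream kmer_stream(const std::string& seq, int k, bool collapse_il) {
  KmerStream st;
  st.dropped = 0;
  int n = (int)seq.size();
  if (n < k) return st;
  // next_bad[i]: does window starting at i contain a non-canonical residue?
  // incremental rolling encode with reset at bad residues
  for (int i = 0; i + k <= n; ++i) {
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int o = residue_ord(collapse(seq[i + j], collapse_il));
      if (o < 0) { ok = false; break; }
      code = (code << 5) | (uint64_t)o;
    }
    if (ok) {
      st.codes.push_back(code);
      st.pos.push_back(i);
    } else {
      st.dropped++;
    }
  }
  return st;
}

// indices into `codes` selected as window minimizers (windows of `window`
// consecutive k-mers; fewer than `window` k-mers -> global minimum)
static std::vector<int> minimizer_indices(const std::vector<uint64_t>& codes,
                                          int window) {
  std::vector<int> sel;
  int n = (int)codes.size();
  if (n == 0) return sel;
  std::vector<bool> picked(n, false);
  if (n < window) {
    int best = 0;
    for (int i = 1; i < n; ++i) if (codes[i] < codes[best]) best = i;
    picked[best] = true;
  } else {
    for (int s = 0; s + window <= n; ++s) {
      int best = s;
      for (int i = s + 1; i < s + window; ++i)
        if (codes[i] < codes[best]) best = i;
      picked[best] = true;
    }
  }
  for (int i = 0; i < n; ++i) if (picked[i]) sel.push_back(i);
  return sel;
}

// --- substitution-variant enumeration (branch and bound) -------------------

struct SubstModel {
  int scores[20][20];
  int cand[20][20];  // cand[a][j]: j-th candidate for residue a, descending score
};

static SubstModel model_from_r(const IntegerMatrix& scores) {
  SubstModel m;
  for (int a = 0; a < 20; ++a)
    for (int b = 0; b < 20; ++b) m.scores[a][b] = scores(a, b);
  for (int a = 0; a < 20; ++a) {
    std::vector<int> idx(20);
    for (int b = 0; b < 20; ++b) idx[b] = b;
    // descending score; stable keeps alphabetical order for ties
    std::stable_sort(idx.begin(), idx.end(), [&](int x, int y) {
      return m.scores[a][x] > m.scores[a][y];
    });
    for (int j = 0; j < 20; ++j) m.cand[a][j] = idx[j];
  }
  return m;
}

struct VariantSink {
  std::vector<std::string>* strings;   // optional
  std::set<uint64_t>* codes;           // optional
  long nodes;
};

static void variants_dfs(const std::vector<int>& ords, int depth, int score,
                         const std::vector<int>& suffix_max, int threshold,
                         const SubstModel& m, std::string& buf,
                         VariantSink& sink) {
  sink.nodes++;
  int k = (int)ords.size();
  if (depth == k) {
    if (score >= threshold) {
      if (sink.strings) sink.strings->push_back(buf);
      if (sink.codes) {
        uint64_t code;
        encode_str(buf, false, code);
        sink.codes->insert(code);
      }
    }
    return;
  }
  // bound: best completion of the remaining positions
  if (score + suffix_max[depth] < threshold) return;
  int a = ords[depth];
  for (int j = 0; j < 20; ++j) {
    int b = m.cand[a][j];
    int s2 = score + m.scores[a][b];
    // candidates are sorted descending: once one cannot reach the
    // threshold even with the best completion, none of the rest can
    if (s2 + suffix_max[depth + 1] < threshold) break;
    buf[depth] = ALPHABET[b];
    variants_dfs(ords, depth + 1, s2, suffix_max, threshold, m, buf, sink);
  }
}

// enumerate { v : sum_i S(kmer_i, v_i) >= threshold }; original k-mer is
// appended afterwards by the callers (always represented)
static void enumerate_variants(const std::string& kmer, const SubstModel& m,
                               int threshold, VariantSink& sink) {
  int k = (int)kmer.size();
  std::vector<int> ords(k);
  for (int i = 0; i < k; ++i) {
    int o = residue_ord(kmer[i]);
    if (o < 0) stop("non-canonical residue '%s' at position %d in k-mer '%s'",
                    std::string(1, kmer[i]).c_str(), i + 1, kmer.c_str());
    ords[i] = o;
  }
  std::vector<int> suffix_max(k + 1, 0);
  for (int i = k - 1; i >= 0; --i) {
    int mx = m.scores[ords[i]][0];
    for (int b = 1; b < 20; ++b) mx = std::max(mx, m.scores[ords[i]][b]);
    suffix_max[i] = suffix_max[i + 1] + mx;
  }
  std::string buf(k, 'A');
  variants_dfs(ords, 0, 0, suffix_max, threshold, m, buf, sink);
}

// --- distinct k-mer set of a bin (the build-side pipeline) -----------------

// kmerize -> (minimizer-select) -> (mutation-expand) -> distinct encoded set
static std::set<uint64_t> bin_code_set(const CharacterVector& sequences, int k,
                                       bool collapse_il, int window,
                                       bool mutate, const SubstModel* model,
                                       int threshold) {
  std::set<uint64_t> out;
  for (int s = 0; s < sequences.size(); ++s) {
    std::string seq = as<std::string>(sequences[s]);
    KmerStream st = kmer_stream(seq, k, collapse_il);
    std::vector<int> sel;
    if (window > 0) {
      sel = minimizer_indices(st.codes, window);
    } else {
      sel.resize(st.codes.size());
      for (size_t i = 0; i < st.codes.size(); ++i) sel[i] = (int)i;
    }
    for (int idx : sel) {
      if (mutate) {
        std::string km = seq.substr(st.pos[idx], k);
        if (collapse_il)
          for (auto& c : km) c = collapse(c, true);
        VariantSink sink{nullptr, &out, 0};
        enumerate_variants(km, *model, threshold, sink);
      }
      out.insert(st.codes[idx]);  // original always represented
    }
  }
  return out;
}

// ===========================================================================
// exported entry points
// ===========================================================================

// [[Rcpp::export]]
List cpp_kmerize(std::string sequence, int k, bool collapse_il) {
  KmerStream st = kmer_stream(sequence, k, collapse_il);
  CharacterVector kmers(st.codes.size());
  IntegerVector pos(st.codes.size());
  for (size_t i = 0; i < st.codes.size(); ++i) {
    std::string km = sequence.substr(st.pos[i], k);
    if (collapse_il)
      for (auto& c : km) c = collapse(c, true);
    kmers[i] = km;
    pos[i] = st.pos[i];
  }
  return List::create(_["position"] = pos, _["kmer"] = kmers,
                      _["dropped"] = st.dropped);
}

// [[Rcpp::export]]
NumericVector cpp_encode(CharacterVector kmers, bool collapse_il) {
  NumericVector out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    for (size_t j = 0; j < km.size(); ++j) {
      if (residue_ord(collapse(km[j], collapse_il)) < 0)
        stop("non-canonical residue '%s' at position %d of k-mer '%s'",
             std::string(1, km[j]).c_str(), (int)j + 1, km.c_str());
    }
    uint64_t code;
    encode_str(km, collapse_il, code);
    out[i] = (double)code;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector codes, int k) {
  CharacterVector out(codes.size());
  for (int i = 0; i < codes.size(); ++i)
    out[i] = decode_code((uint64_t)codes[i], k);
  return out;
}

// encode+decode entirely in uint64; exercises the full 5-bit x k <= 12 range
// without passing codes through doubles
// [[Rcpp::export]]
CharacterVector cpp_roundtrip(CharacterVector kmers, bool collapse_il) {
  CharacterVector out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    uint64_t code;
    if (!encode_str(km, collapse_il, code))
      stop("non-canonical residue in '%s'", km.c_str());
    out[i] = decode_code(code, (int)km.size());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_minimizers(NumericVector codes, int window) {
  std::vector<uint64_t> v(codes.size());
  for (int i = 0; i < codes.size(); ++i) v[i] = (uint64_t)codes[i];
  std::vector<int> sel = minimizer_indices(v, window);
  std::set<uint64_t> uniq;
  for (int idx : sel) uniq.insert(v[idx]);
  NumericVector out(uniq.size());
  int i = 0;
  for (uint64_t c : uniq) out[i++] = (double)c;
  return out;
}

// probe positions for each (code, seed) pair; the scalar-Bloom oracle in the
// tests reuses these so implementation and oracle share the hash scheme
// [[Rcpp::export]]
IntegerMatrix cpp_hash_positions(NumericVector codes, NumericVector seeds,
                                 double n) {
  std::vector<uint64_t> sd = seeds_from_r(seeds);
  uint64_t nn = (uint64_t)n;
  IntegerMatrix out(codes.size(), sd.size());
  for (int i = 0; i < codes.size(); ++i)
    for (size_t h = 0; h < sd.size(); ++h)
      out(i, h) = (int)(hash_code((uint64_t)codes[i], sd[h]) % nn);
  return out;
}

// [[Rcpp::export]]
RawVector cpp_insert_codes(RawVector bits, double n, int b, int bin,
                           NumericVector codes, NumericVector seeds) {
  RawVector out = clone(bits);
  std::vector<uint64_t> sd = seeds_from_r(seeds);
  uint64_t nn = (uint64_t)n;
  for (int i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (uint64_t s : sd) {
      uint64_t pos = hash_code(code, s) % nn;
      set_bit(RAW(out), pos * (uint64_t)b + (uint64_t)bin);
    }
  }
  return out;
}

static void count_codes(const Rbyte* bits, uint64_t n, int b,
                        const std::vector<uint64_t>& codes,
                        const std::vector<uint64_t>& seeds, int* counts) {
  for (uint64_t code : codes) {
    std::vector<uint64_t> pos(seeds.size());
    for (size_t h = 0; h < seeds.size(); ++h)
      pos[h] = hash_code(code, seeds[h]) % n;
    for (int j = 0; j < b; ++j) {
      bool all = true;
      for (size_t h = 0; h < seeds.size(); ++h) {
        if (!get_bit(bits, pos[h] * (uint64_t)b + (uint64_t)j)) {
          all = false;
          break;
        }
      }
      if (all) counts[j]++;
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_query_counts(RawVector bits, double n, int b,
                               NumericVector codes, NumericVector seeds) {
  std::vector<uint64_t> sd = seeds_from_r(seeds);
  std::set<uint64_t> uniq;
  for (int i = 0; i < codes.size(); ++i) uniq.insert((uint64_t)codes[i]);
  std::vector<uint64_t> cs(uniq.begin(), uniq.end());
  IntegerVector counts(b);
  count_codes(RAW(bits), (uint64_t)n, b, cs, sd, INTEGER(counts));
  return counts;
}

// [[Rcpp::export]]
double cpp_bin_distinct_count(CharacterVector sequences, int k,
                              bool collapse_il, int window, bool mutate,
                              Nullable<IntegerMatrix> scores, int threshold) {
  SubstModel m;
  if (mutate) {
    if (scores.isNull()) stop("mutation enabled but no substitution matrix");
    m = model_from_r(IntegerMatrix(scores));
  }
  std::set<uint64_t> s = bin_code_set(sequences, k, collapse_il, window,
                                      mutate, mutate ? &m : nullptr, threshold);
  return (double)s.size();
}

// [[Rcpp::export]]
RawVector cpp_insert_bin(RawVector bits, double n, int b, int bin,
                         CharacterVector sequences, int k, bool collapse_il,
                         int window, NumericVector seeds, bool mutate,
                         Nullable<IntegerMatrix> scores, int threshold) {
  SubstModel m;
  if (mutate) {
    if (scores.isNull()) stop("mutation enabled but no substitution matrix");
    m = model_from_r(IntegerMatrix(scores));
  }
  std::set<uint64_t> s = bin_code_set(sequences, k, collapse_il, window,
                                      mutate, mutate ? &m : nullptr, threshold);
  RawVector out = clone(bits);
  std::vector<uint64_t> sd = seeds_from_r(seeds);
  uint64_t nn = (uint64_t)n;
  for (uint64_t code : s) {
    for (uint64_t sdv : sd) {
      uint64_t pos = hash_code(code, sdv) % nn;
      set_bit(RAW(out), pos * (uint64_t)b + (uint64_t)bin);
    }
  }
  return out;
}

// query-side pipeline: per peptide, distinct (optionally minimized) k-mer
// codes counted against every bin of one IBF
// [[Rcpp::export]]
List cpp_query_peptides(RawVector bits, double n, int b,
                        CharacterVector peptides, int k, bool collapse_il,
                        int window, NumericVector seeds) {
  std::vector<uint64_t> sd = seeds_from_r(seeds);
  int u = peptides.size();
  IntegerMatrix counts(u, b);
  IntegerVector y(u);
  for (int i = 0; i < u; ++i) {
    std::string pep = as<std::string>(peptides[i]);
    KmerStream st = kmer_stream(pep, k, collapse_il);
    std::set<uint64_t> uniq;
    if (window > 0) {
      for (int idx : minimizer_indices(st.codes, window))
        uniq.insert(st.codes[idx]);
    } else {
      uniq.insert(st.codes.begin(), st.codes.end());
    }
    y[i] = (int)uniq.size();
    std::vector<uint64_t> cs(uniq.begin(), uniq.end());
    std::vector<int> row(b, 0);
    count_codes(RAW(bits), (uint64_t)n, b, cs, sd, row.data());
    for (int j = 0; j < b; ++j) counts(i, j) = row[j];
  }
  return List::create(_["counts"] = counts, _["y"] = y);
}

// per-peptide distinct query k-mer counts only (for configs with no index)
// [[Rcpp::export]]
IntegerVector cpp_peptide_y(CharacterVector peptides, int k, bool collapse_il,
                            int window) {
  IntegerVector y(peptides.size());
  for (int i = 0; i < peptides.size(); ++i) {
    std::string pep = as<std::string>(peptides[i]);
    KmerStream st = kmer_stream(pep, k, collapse_il);
    std::set<uint64_t> uniq;
    if (window > 0) {
      for (int idx : minimizer_indices(st.codes, window))
        uniq.insert(st.codes[idx]);
    } else {
      uniq.insert(st.codes.begin(), st.codes.end());
    }
    y[i] = (int)uniq.size();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_generate_variants(std::string kmer, IntegerMatrix scores,
                           int threshold) {
  SubstModel m = model_from_r(scores);
  std::vector<std::string> vars;
  VariantSink sink{&vars, nullptr, 0};
  enumerate_variants(kmer, m, threshold, sink);
  std::set<std::string> uniq(vars.begin(), vars.end());
  uniq.insert(kmer);  // original always represented
  CharacterVector out(uniq.size());
  int i = 0;
  for (const std::string& v : uniq) out[i++] = v;
  return List::create(_["variants"] = out, _["nodes"] = (double)sink.nodes);
}

// [[Rcpp::export]]
IntegerMatrix cpp_sorted_candidates(IntegerMatrix scores) {
  SubstModel m = model_from_r(scores);
  IntegerMatrix out(20, 20);
  for (int a = 0; a < 20; ++a)
    for (int j = 0; j < 20; ++j) out(a, j) = m.cand[a][j] + 1;  // 1-based
  return out;
}
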