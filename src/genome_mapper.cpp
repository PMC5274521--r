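// End-to-end placement of trimmed flanks / full reads / supporting reads on
// the reference genome, allowing substitutions only.  For each fragment all
// placements (either strand) with <= max_mismatch substitutions are found;
// the best placement is reported with mapq 60 when it is unique at the
// minimal mismatch count and mapq 0 when >= 2 co-optimal placements exist.
// Completeness: pigeonhole seeding (3 exact segments for a <=2-mismatch
// budget) via 10-mer and 7-mer genome indexes; fragments too short to carry
// three seeds are scanned exhaustively.
#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <algorithm>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}
static inline char basecomp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

struct GenomeIdx {
  std::string concat;           // chromosomes joined by 'N' sentinels
  std::vector<long> offset;     // start of each chromosome in concat
  std::vector<long> clen;
  // k-mer indexes for the pigeonhole seed ladder
  static const int NK = 5;
  int kvals[NK] = {3, 4, 5, 7, 10};
  std::vector<int> idx[NK], pos[NK];
  void build_kmer(int k, std::vector<int>& idx, std::vector<int>& pos) {
    int nkey = 1 << (2 * k);
    std::vector<int> cnt(nkey + 1, 0);
    std::vector<std::pair<int,int>> keys;
    int key = 0, run = 0;
    for (size_t i = 0; i < concat.size(); ++i) {
      int b = base2bit(concat[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | b) & (nkey - 1);
      if (++run >= k) keys.push_back(std::make_pair(key, (int)i - k + 1));
    }
    for (size_t i = 0; i < keys.size(); ++i) cnt[keys[i].first + 1]++;
    for (int i = 0; i < nkey; ++i) cnt[i + 1] += cnt[i];
    idx = cnt;
    pos.resize(keys.size());
    std::vector<int> fill(idx.begin(), idx.end());
    for (size_t i = 0; i < keys.size(); ++i) pos[fill[keys[i].first]++] = keys[i].second;
  }
};

struct Placement { long g; char strand; int mm; };

static inline bool place_less(const Placement& a, const Placement& b) {
  if (a.strand != b.strand) return a.strand < b.strand; // '+' before '-'
  return a.g < b.g;
}

// verify fragment f (oriented) at global start g; returns mismatches or INT_MAX
static inline int verify(const std::string& G, long g, const char* f, int L, int maxmm) {
  if (g < 0 || g + L > (long)G.size()) return INT_MAX;
  int mm = 0;
  const char* s = G.data() + g;
  for (int i = 0; i < L; ++i) {
    if (s[i] != f[i]) { if (++mm > maxmm) return INT_MAX; }
  }
  return mm;
}

static void seed_candidates(const GenomeIdx& GI, const char* f, int L, int k,
                            const std::vector<int>& idx, const std::vector<int>& pos,
                            std::vector<long>& cand) {
  // three segment anchors at 0, L/3, 2L/3 (each segment >= k)
  int a = L / 3, b = (2 * L) / 3;
  int offs[3] = { 0, a, b };
  int nkeymask = (1 << (2 * k)) - 1;
  for (int s = 0; s < 3; ++s) {
    int o = offs[s];
    int key = 0; bool ok = true;
    for (int i = 0; i < k; ++i) {
      int bb = base2bit(f[o + i]);
      if (bb < 0) { ok = false; break; }
      key = ((key << 2) | bb) & nkeymask;
    }
    if (!ok) continue;
    for (int p = idx[key]; p < idx[key + 1]; ++p)
      cand.push_back((long)pos[p] - o);
  }
}

// [[Rcpp::export]]
DataFrame cpp_align_end_to_end(CharacterVector frags, CharacterVector chrom_seqs,
                               int max_mismatch) {
  if (chrom_seqs.size() == 0) stop("empty reference");
  GenomeIdx GI;
  for (int i = 0; i < chrom_seqs.size(); ++i) {
    GI.offset.push_back((long)GI.concat.size());
    const char* s = CHAR(STRING_ELT(chrom_seqs, i));
    long l = (long)strlen(s);
    GI.clen.push_back(l);
    GI.concat.append(s);
    GI.concat.push_back('N');
  }
  for (int i = 0; i < GenomeIdx::NK; ++i)
    GI.build_kmer(GI.kvals[i], GI.idx[i], GI.pos[i]);
  int n = frags.size();
  // chromosome lookup for a global start; -1 when the span crosses a sentinel
  #define CHROM_OF(g, L, ci, local) do {                                        \
    ci = (int)(std::upper_bound(GI.offset.begin(), GI.offset.end(), (long)(g)) -\
               GI.offset.begin()) - 1;                                          \
    local = (g) - GI.offset[ci];                                                \
    if (local + (L) > GI.clen[ci]) ci = -1;                                     \
  } while (0)
  std::vector<int> o_frag, o_chrom, o_start, o_end, o_mm, o_mapq, o_nbest;
  std::vector<char> o_strand;
  std::string rcbuf;
  std::vector<long> cand;
  for (int fi = 0; fi < n; ++fi) {
    const char* f = CHAR(STRING_ELT(frags, fi));
    int L = (int)strlen(f);
    rcbuf.resize(L);
    for (int i = 0; i < L; ++i) rcbuf[i] = basecomp(f[L - 1 - i]);
    std::vector<Placement> found;
    const char* oriented[2] = { f, rcbuf.data() };
    char strands[2] = { '+', '-' };
    // largest seed length usable for three non-overlapping exact segments
    int ki = -1;
    for (int i = GenomeIdx::NK - 1; i >= 0; --i)
      if (L / 3 >= GI.kvals[i]) { ki = i; break; }
    for (int s = 0; s < 2; ++s) {
      const char* q = oriented[s];
      if (ki >= 0) {
        cand.clear();
        seed_candidates(GI, q, L, GI.kvals[ki], GI.idx[ki], GI.pos[ki], cand);
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        for (size_t c = 0; c < cand.size(); ++c) {
          int ci; long local; CHROM_OF(cand[c], L, ci, local);
          if (ci < 0) continue;
          int mm = verify(GI.concat, cand[c], q, L, max_mismatch);
          if (mm <= max_mismatch) found.push_back(Placement{cand[c], strands[s], mm});
        }
      } else {
        // exhaustive scan for fragments too short to carry three seeds
        long gmax = (long)GI.concat.size() - L;
        for (long g = 0; g <= gmax; ++g) {
          int mm = verify(GI.concat, g, q, L, max_mismatch);
          if (mm <= max_mismatch) {
            int ci; long local; CHROM_OF(g, L, ci, local);
            if (ci >= 0) found.push_back(Placement{g, strands[s], mm});
          }
        }
      }
    }
    if (found.empty()) continue;
    int best_mm = INT_MAX;
    for (size_t i = 0; i < found.size(); ++i) best_mm = std::min(best_mm, found[i].mm);
    int n_best = 0; int bi = -1;
    for (size_t i = 0; i < found.size(); ++i) {
      if (found[i].mm != best_mm) continue;
      ++n_best;
      if (bi < 0 || place_less(found[i], found[bi])) bi = (int)i;
    }
    const Placement& P = found[bi];
    int ci; long local; CHROM_OF(P.g, L, ci, local);
    o_frag.push_back(fi + 1); o_chrom.push_back(ci + 1);
    o_start.push_back((int)local); o_end.push_back((int)(local + L));
    o_strand.push_back(P.strand); o_mm.push_back(best_mm);
    o_mapq.push_back(n_best == 1 ? 60 : 0); o_nbest.push_back(n_best);
  }
  CharacterVector strand(o_strand.size());
  for (size_t i = 0; i < o_strand.size(); ++i)
    strand[i] = (o_strand[i] == '+') ? "+" : "-";
  return DataFrame::create(
    _["fragment"] = o_frag, _["chrom_id"] = o_chrom,
    _["start0"] = o_start, _["end0"] = o_end, _["strand"] = strand,
    _["mapq"] = o_mapq, _["mismatches"] = o_mm, _["n_best"] = o_nbest,
    _["stringsAsFactors"] = false);
}
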