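// Seed-and-extend ungapped matcher between short reads and a TE consensus
// library, plus bulk read-pair classification (junction / full-TE /
// supporting).  Contract: a hit is any maximal ungapped local alignment with
// aligned length >= len_cut_match and mismatches <= max_mismatch that
// contains an exact seed_len-mer; overlapping hits to the same family are
// reduced to the highest-scoring one (score = matches - mismatches).
#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
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

struct Win {
  int te;        // 0-based family index
  int rs, re;    // read interval, 0-based half-open, forward-read coords
  int ts, tee;   // consensus interval, 0-based half-open
  int mm;
  char strand;   // '+': read matches consensus; '-': read matches revcomp
  int score() const { return (re - rs) - 2 * mm; }
};

struct TELib {
  std::string concat;            // all consensi, '\0'-free, concatenated
  std::vector<int> offset;       // start of each TE in concat
  std::vector<int> len;
  std::vector<int> kidx;         // counting-sort k-mer index: bucket starts
  std::vector<int> kpos;         // global positions sorted by k-mer
  int k;
};

static TELib build_lib(const CharacterVector& te_seqs, int k) {
  TELib L; L.k = k;
  int n = te_seqs.size();
  L.offset.resize(n); L.len.resize(n);
  size_t tot = 0;
  for (int i = 0; i < n; ++i) tot += LENGTH(STRING_ELT(te_seqs, i));
  L.concat.reserve(tot);
  for (int i = 0; i < n; ++i) {
    L.offset[i] = (int)L.concat.size();
    const char* s = CHAR(STRING_ELT(te_seqs, i));
    L.len[i] = (int)strlen(s);
    L.concat.append(s);
  }
  int nkey = 1 << (2 * k);
  std::vector<int> cnt(nkey + 1, 0);
  // enumerate valid k-mers fully inside a single TE
  std::vector<std::pair<int,int>> keys; // (key, global pos)
  for (int t = 0; t < n; ++t) {
    const char* s = L.concat.data() + L.offset[t];
    int key = 0, run = 0;
    for (int i = 0; i < L.len[t]; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | b) & (nkey - 1);
      if (++run >= k) keys.push_back(std::make_pair(key, L.offset[t] + i - k + 1));
    }
  }
  for (size_t i = 0; i < keys.size(); ++i) cnt[keys[i].first + 1]++;
  for (int i = 0; i < nkey; ++i) cnt[i + 1] += cnt[i];
  L.kidx = cnt;
  L.kpos.resize(keys.size());
  std::vector<int> fill(L.kidx.begin(), L.kidx.end());
  for (size_t i = 0; i < keys.size(); ++i) L.kpos[fill[keys[i].first]++] = keys[i].second;
  return L;
}

static inline int te_of_pos(const TELib& L, int gpos) {
  // binary search: largest offset <= gpos
  int lo = 0, hi = (int)L.offset.size() - 1;
  while (lo < hi) { int mid = (lo + hi + 1) / 2; if (L.offset[mid] <= gpos) lo = mid; else hi = mid - 1; }
  return lo;
}

// Enumerate all maximal <=max_mismatch windows (length >= len_cut_match)
// containing an exact seed, for one oriented read against the library.
// Windows are appended in forward-read coordinates.
static void collect_windows(const char* r, int rlen, bool is_rc, int fwd_len,
                            const TELib& L, int len_cut_match, int max_mismatch,
                            std::vector<Win>& out,
                            std::unordered_set<uint64_t>& seen) {
  const int k = L.k;
  if (rlen < k) return;
  const int nkeymask = (1 << (2 * k)) - 1;
  int key = 0, run = 0;
  int lmm[8], rmm[8];
  for (int i = 0; i < rlen; ++i) {
    int b = base2bit(r[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | b) & nkeymask;
    if (++run < k) continue;
    int i0 = i - k + 1;              // seed start on oriented read
    for (int p = L.kidx[key]; p < L.kidx[key + 1]; ++p) {
      int g = L.kpos[p];
      int te = te_of_pos(L, g);
      int jt = g - L.offset[te];     // seed start on consensus
      const char* t = L.concat.data() + L.offset[te];
      int tlen = L.len[te];
      // scan left collecting up to max_mismatch+1 mismatch offsets (rel to seed start)
      int nl = 0; int minRel = -std::min(i0, jt);
      int rel = -1;
      for (; rel >= minRel && nl <= max_mismatch; --rel)
        if (r[i0 + rel] != t[jt + rel]) lmm[nl++] = rel;
      // scan right from seed end
      int nr = 0; int maxRel = std::min(rlen - i0, tlen - jt) - 1; // last valid rel
      int rr = k;
      for (; rr <= maxRel && nr <= max_mismatch; ++rr)
        if (r[i0 + rr] != t[jt + rr]) rmm[nr++] = rr;
      // widest reachable window spans the full scanned extent; skip early
      // when even that cannot reach len_cut_match
      int loRel = (nl > max_mismatch) ? lmm[max_mismatch] + 1 : minRel;
      int hiRel = (nr > max_mismatch) ? rmm[max_mismatch] : maxRel + 1;
      if (hiRel - loRel < len_cut_match) continue;
      for (int kl = 0; kl <= max_mismatch; ++kl) {
        int kr = max_mismatch - kl;
        int s  = (nl > kl) ? lmm[kl] + 1 : minRel;
        int e  = (nr > kr) ? rmm[kr]     : maxRel + 1;  // exclusive
        int len = e - s;
        if (len < len_cut_match) continue;
        int mm = std::min(kl, nl) + std::min(kr, nr);
        int rs_o = i0 + s, re_o = i0 + e;        // oriented read coords
        int ts = jt + s, tee = jt + e;
        int rs = is_rc ? fwd_len - re_o : rs_o;  // forward-read coords
        int re = is_rc ? fwd_len - rs_o : re_o;
        uint64_t kkey = ((uint64_t)(L.offset[te] + ts) << 24) ^
                        ((uint64_t)rs << 4) ^ (is_rc ? 1u : 0u);
        if (!seen.insert(kkey).second) continue;
        Win w; w.te = te; w.rs = rs; w.re = re; w.ts = ts; w.tee = tee;
        w.mm = mm; w.strand = is_rc ? '-' : '+';
        out.push_back(w);
      }
    }
  }
}

// order used for assign_family ties and overlap merging
struct WinOrder {
  const std::vector<int>* rank; // lexicographic rank of family names (may be null)
  bool operator()(const Win& a, const Win& b) const {
    int sa = a.score(), sb = b.score();
    if (sa != sb) return sa > sb;
    if (a.mm != b.mm) return a.mm < b.mm;
    if (rank) {
      int ra = (*rank)[a.te], rb = (*rank)[b.te];
      if (ra != rb) return ra < rb;
    }
    if (a.rs != b.rs) return a.rs < b.rs;
    if (a.ts != b.ts) return a.ts < b.ts;
    return a.strand < b.strand; // '+' (43) < '-' (45)
  }
};

// keep, per family, only the top-scoring hit among mutually overlapping
// read intervals (greedy by descending score)
static void merge_overlaps(std::vector<Win>& wins, const std::vector<int>* rank) {
  WinOrder ord; ord.rank = rank;
  std::stable_sort(wins.begin(), wins.end(), ord);
  std::vector<Win> kept;
  for (size_t i = 0; i < wins.size(); ++i) {
    bool drop = false;
    for (size_t j = 0; j < kept.size(); ++j) {
      if (kept[j].te == wins[i].te &&
          wins[i].rs < kept[j].re && kept[j].rs < wins[i].re) { drop = true; break; }
    }
    if (!drop) kept.push_back(wins[i]);
  }
  wins.swap(kept);
}

static void all_windows_for_read(const char* s, int len, const TELib& L,
                                 int len_cut_match, int max_mismatch,
                                 std::vector<Win>& wins, std::string& rcbuf,
                                 std::unordered_set<uint64_t>& seen) {
  wins.clear(); seen.clear();
  collect_windows(s, len, false, len, L, len_cut_match, max_mismatch, wins, seen);
  rcbuf.resize(len);
  for (int i = 0; i < len; ++i) rcbuf[i] = basecomp(s[len - 1 - i]);
  seen.clear();
  collect_windows(rcbuf.data(), len, true, len, L, len_cut_match, max_mismatch, wins, seen);
}

// [[Rcpp::export]]
DataFrame cpp_find_repeat_hits(CharacterVector reads, CharacterVector te_seqs,
                               int len_cut_match, int max_mismatch,
                               int seed_len) {
  TELib L = build_lib(te_seqs, seed_len);
  std::vector<int> o_read, o_te, o_rs, o_re, o_ts, o_tee, o_mm, o_score;
  std::vector<char> o_strand;
  std::vector<Win> wins; std::string rcbuf;
  std::unordered_set<uint64_t> seen;
  for (int ri = 0; ri < reads.size(); ++ri) {
    const char* s = CHAR(STRING_ELT(reads, ri));
    int len = (int)strlen(s);
    all_windows_for_read(s, len, L, len_cut_match, max_mismatch, wins, rcbuf, seen);
    merge_overlaps(wins, NULL);
    for (size_t i = 0; i < wins.size(); ++i) {
      const Win& w = wins[i];
      o_read.push_back(ri + 1); o_te.push_back(w.te + 1);
      o_rs.push_back(w.rs); o_re.push_back(w.re);
      o_ts.push_back(w.ts); o_tee.push_back(w.tee);
      o_mm.push_back(w.mm); o_score.push_back(w.score());
      o_strand.push_back(w.strand);
    }
  }
  CharacterVector strand(o_strand.size());
  for (size_t i = 0; i < o_strand.size(); ++i)
    strand[i] = (o_strand[i] == '+') ? "+" : "-";
  return DataFrame::create(
    _["read"] = o_read, _["te"] = o_te,
    _["read_start0"] = o_rs, _["read_end0"] = o_re,
    _["te_start0"] = o_ts, _["te_end0"] = o_tee,
    _["strand"] = strand, _["mismatches"] = o_mm, _["score"] = o_score,
    _["stringsAsFactors"] = false);
}

// categories: 1 JUNCTION, 2 FULL_TE, 3 SUPPORTING, 4 UNINFORMATIVE
struct MateClass {
  int category = 4;
  int family = NA_INTEGER;     // 1-based
  bool has_internal = false;   // blocks SUPPORTING promotion
  bool has_any = false;
  // up to two junction fragments
  int nfrag = 0;
  int fs[2], fe[2];            // flank interval on forward read
  int ps[2], pe[2];            // trimmed (TE-side) portion adjacent to flank
  char side5[2];               // '5' or '3': consensus terminus the flank abuts
  char te_at[2];               // 'L'/'R': side of the flank the TE sits on (read coords)
};

static MateClass classify_mate(const char* s, int len, const TELib& L,
                               const std::vector<int>& rank,
                               int len_cut_match, int len_cut_trim,
                               int max_mismatch, int terminus_tol, int control_len,
                               int block_score,
                               std::vector<Win>& wins, std::string& rcbuf,
                               std::unordered_set<uint64_t>& seen) {
  MateClass mc;
  all_windows_for_read(s, len, L, len_cut_match, max_mismatch, wins, rcbuf, seen);
  if (wins.empty()) return mc;
  mc.has_any = true;
  // classification operates on the merged hit set (same view a caller of
  // find_repeat_hits sees), so blocking/promotion semantics match exactly
  merge_overlaps(wins, &rank);
  for (size_t i = 0; i < wins.size(); ++i) {
    int tlen = L.len[wins[i].te];
    bool rS = wins[i].ts <= terminus_tol;
    bool rE = tlen - wins[i].tee <= terminus_tol;
    if (!rS && !rE && wins[i].score() >= block_score) mc.has_internal = true;
  }
  int fam = wins[0].te;  // merged hits are sorted best-first; winner = hits[0]
  mc.family = fam + 1;
  std::vector<Win> fw;
  for (size_t i = 0; i < wins.size(); ++i) if (wins[i].te == fam) fw.push_back(wins[i]);
  int tlen = L.len[fam];
  // FULL_TE: a hit covering essentially the whole read
  for (size_t i = 0; i < fw.size(); ++i) {
    if (fw[i].rs < len_cut_trim && (len - fw[i].re) < len_cut_trim) {
      mc.category = 2;
      return mc;
    }
  }
  // JUNCTION: best hit reaching a consensus terminus with a long-enough flank
  for (size_t i = 0; i < fw.size(); ++i) {  // fw sorted best-first by merge_overlaps
    const Win& w = fw[i];
    bool rS = w.ts <= terminus_tol;
    bool rE = tlen - w.tee <= terminus_tol;
    // terminus adjacent to each read-side flank depends on hit strand
    bool leftAdjReached  = (w.strand == '+') ? rS : rE;
    bool rightAdjReached = (w.strand == '+') ? rE : rS;
    // project the trim point to the consensus terminus: a hit may stop
    // g <= terminus_tol bases short of the terminus (sequencing error at
    // the extreme junction base); those bases are TE sequence and are
    // trimmed along with the match
    int gL = (w.strand == '+') ? w.ts : (tlen - w.tee);
    int gR = (w.strand == '+') ? (tlen - w.tee) : w.ts;
    int lf = leftAdjReached ? (w.rs - gL) : w.rs;
    int rf = rightAdjReached ? (len - w.re - gR) : (len - w.re);
    bool qualL = leftAdjReached && lf >= len_cut_trim;
    bool qualR = rightAdjReached && rf >= len_cut_trim;
    bool emitL = qualL && (rf < len_cut_trim || qualR);
    bool emitR = qualR && (lf < len_cut_trim || qualL);
    if (!emitL && !emitR) continue;
    mc.category = 1;
    if (emitL) {
      int f = mc.nfrag++;
      int fe = w.rs - gL;
      mc.fs[f] = 0; mc.fe[f] = fe;
      mc.ps[f] = fe; mc.pe[f] = std::min(len, fe + control_len);
      mc.side5[f] = (w.strand == '+') ? '5' : '3';
      mc.te_at[f] = 'R';
    }
    if (emitR) {
      int f = mc.nfrag++;
      int fs = w.re + gR;
      mc.fs[f] = fs; mc.fe[f] = len;
      mc.ps[f] = std::max(0, fs - control_len); mc.pe[f] = fs;
      mc.side5[f] = (w.strand == '+') ? '3' : '5';
      mc.te_at[f] = 'L';
    }
    return mc;
  }
  return mc;  // UNINFORMATIVE (internal or short-flank hits only)
}

// [[Rcpp::export]]
List cpp_classify_pairs(CharacterVector mate1, CharacterVector mate2,
                        CharacterVector te_seqs, IntegerVector name_rank,
                        int len_cut_match, int len_cut_trim, int max_mismatch,
                        int seed_len, int terminus_tol, int control_len,
                        int block_score) {
  TELib L = build_lib(te_seqs, seed_len);
  std::vector<int> rank(name_rank.begin(), name_rank.end());
  int n = mate1.size();
  IntegerVector cat1(n), cat2(n), fam1(n), fam2(n);
  std::vector<int> f_pair, f_mate, f_fs, f_fe, f_ps, f_pe, f_fam;
  std::vector<char> f_side, f_teat;
  std::vector<Win> wins; std::string rcbuf;
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < n; ++i) {
    const char* s1 = CHAR(STRING_ELT(mate1, i));
    const char* s2 = CHAR(STRING_ELT(mate2, i));
    MateClass c1 = classify_mate(s1, (int)strlen(s1), L, rank, len_cut_match,
                                 len_cut_trim, max_mismatch, terminus_tol,
                                 control_len, block_score, wins, rcbuf, seen);
    MateClass c2 = classify_mate(s2, (int)strlen(s2), L, rank, len_cut_match,
                                 len_cut_trim, max_mismatch, terminus_tol,
                                 control_len, block_score, wins, rcbuf, seen);
    // SUPPORTING promotion: no hit at all (or terminus-only hits), partner informative
    if (c1.category == 4 && !c1.has_internal && (c2.category == 1 || c2.category == 2)) {
      c1.category = 3; c1.family = c2.family;
    }
    if (c2.category == 4 && !c2.has_internal && (c1.category == 1 || c1.category == 2)) {
      c2.category = 3; c2.family = c1.family;
    }
    cat1[i] = c1.category; cat2[i] = c2.category;
    fam1[i] = c1.family;  fam2[i] = c2.family;
    const MateClass* cs[2] = { &c1, &c2 };
    for (int m = 0; m < 2; ++m) {
      const MateClass& c = *cs[m];
      if (c.category != 1) continue;
      for (int f = 0; f < c.nfrag; ++f) {
        f_pair.push_back(i + 1); f_mate.push_back(m + 1);
        f_fs.push_back(c.fs[f]); f_fe.push_back(c.fe[f]);
        f_ps.push_back(c.ps[f]); f_pe.push_back(c.pe[f]);
        f_fam.push_back(c.family);
        f_side.push_back(c.side5[f]); f_teat.push_back(c.te_at[f]);
      }
    }
  }
  CharacterVector side(f_side.size()), teat(f_teat.size());
  for (size_t i = 0; i < f_side.size(); ++i) {
    side[i] = (f_side[i] == '5') ? "TE_5PRIME" : "TE_3PRIME";
    teat[i] = (f_teat[i] == 'L') ? "L" : "R";
  }
  DataFrame frags = DataFrame::create(
    _["pair"] = f_pair, _["mate"] = f_mate, _["family_id"] = f_fam,
    _["flank_start0"] = f_fs, _["flank_end0"] = f_fe,
    _["portion_start0"] = f_ps, _["portion_end0"] = f_pe,
    _["te_side"] = side, _["te_at"] = teat, _["stringsAsFactors"] = false);
  return List::create(_["category1"] = cat1, _["category2"] = cat2,
                      _["family1"] = fam1, _["family2"] = fam2,
                      _["fragments"] = frags);
}
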