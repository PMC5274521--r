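---
title: "Methods: junction-read discovery of TE insertions and its simulation benchmark"
author: "junctionTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-read discovery of TE insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A transposable element (TE) insertion that is present in a sequenced
individual but absent from the reference assembly leaves a characteristic
signature in paired-end short reads. Reads sequenced across the boundary
between genomic flank and TE sequence (*junction reads*) contain a partial
TE match at one end; once the TE portion is trimmed away, the remaining
flank maps to the reference at the insertion point. Reads lying entirely
inside the element (*full-TE reads*) are positionally uninformative, but
their mates (*supporting reads*) localize the insertion to within the
library insert size. Because TE integration proceeds through staggered
cuts, a short direct repeat of host sequence — the target site duplication
(TSD), typically 2–9 bp — flanks the element; junction reads from the two
genomic sides overlap by exactly the TSD, which pins the insertion to
single-base resolution.

The caller composes six stages:

1. **Repeat matching.** Every read is compared against all TE consensi at
   once with a seed-and-extend ungapped matcher (7-mer seeds; a hit needs
   an aligned length of at least `len_cut_match = 10` with at most
   `mismatch = 2` substitutions). Per family, overlapping hits collapse
   to the highest scorer (score = matches − mismatches).
2. **Classification and trimming.** A hit covering essentially the whole
   mate (unmatched overhang < `len_cut_trim` on both ends) marks it
   FULL_TE. A hit reaching a consensus terminus (within
   `terminus_tol = 3` bp) with a flank of ≥ `len_cut_trim = 10` bp on
   exactly one side marks it JUNCTION; the flank is kept and the TE
   portion discarded. Mates without TE similarity whose partner is
   informative become SUPPORTING.
3. **Mapping.** Flanks, full reads and supporting reads are placed
   end-to-end on the reference (substitutions only). A placement unique
   at the minimal mismatch count gets `mapq = 60`; repeat-ambiguous
   placements get `mapq = 0`, so the downstream `mapq < 29` filter
   separates the two regimes cleanly.
4. **False-junction control.** The trimmed-off portion of every mapped
   junction read is compared with the reference immediately adjacent to
   its flank alignment. If it continues the reference (mismatch fraction
   < `junction_control_frac = 0.4`), the read is ordinary genomic
   sequence whose tail matched a TE terminus by chance, and it is
   discarded (its mate also loses SUPPORTING status). True junction reads
   carry TE sequence there, which diverges from the adjacent reference at
   ~75% of positions and passes easily.
5. **Clustering and TSD calling.** Sorted alignments chain into clusters
   (start-to-start gaps ≤ `window_bp = 2000`); clusters without junction
   evidence are dropped. Within a cluster, junction breakpoints of one
   family within `tsd_slack = 25` bp form a subcluster. A left junction's
   breakpoint is its rightmost aligned base, a right junction's its
   leftmost; when both sides are present and the right breakpoint does
   not pass the left one, the overlap **is** the TSD and its sequence is
   read from the reference (never from reads, which carry errors).
6. **Cleaning and confidence.** Rule (i) drops candidates whose best
   junction mapq is below `mapq_min = 29`; rule (iii) drops
   junction-only candidates within `annot_proximity_bp = 10` of an
   annotated reference TE; rule (ii) then drops candidates with fewer
   than `min_cluster_junctions = 3` junction reads (left + right summed)
   when another candidate in the same cluster survived (i) and (iii).
   A call is CONFIDENT when a junction read covers one side and a
   junction or supporting read covers the other; everything else stays
   in the raw output only.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `len_cut_match` | 10 | bp | minimum read–consensus aligned length |
| `len_cut_trim` | 10 | bp | minimum flank retained after trimming |
| `mismatch` | 2 | count | substitution budget for matching and mapping |
| `window_bp` | 2000 | bp | cluster chaining distance |
| `mapq_min` | 29 | — | cleaning rule (i) threshold |
| `min_cluster_junctions` | 3 | reads | cleaning rule (ii) threshold |
| `annot_proximity_bp` | 10 | bp | cleaning rule (iii) distance |
| `terminus_tol` | 3 | bp | slack for a hit to count as reaching a consensus end |
| `tsd_slack` | 25 | bp | breakpoint grouping slack (exceeds the longest expected TSD, separates nearby independent insertions) |
| `junction_control_frac` | 0.4 | fraction | mismatch fraction below which a trimmed portion is judged reference-contiguous |
| `supporting_block_score` | 20 | score | internal-hit score that bars SUPPORTING promotion |

Three of these deserve their design story.

**Terminus projection.** A sequencing error at the extreme junction base
makes the best repeat hit stop 1–3 bp short of the consensus terminus;
the unmatched TE bases would otherwise stay attached to the flank and
shift the breakpoint, corrupting the TSD. The classifier therefore
projects the trim point to the terminus: the flank is shortened by the
unmatched terminal gap (at most `terminus_tol` bases). Without this
projection, every insertion with at least one junction read carrying an
error at its extreme junction base would report a TSD interval extended
past the true duplication.

**False-junction control.** With a multi-family library totalling tens of
kilobases, a random 100 bp read has an appreciable chance of a ≥10 bp,
≤2-mismatch match ending exactly at some consensus terminus — the exact
signature of a junction read. Left unchecked, these chance junctions pair
with their (genuinely genomic) mates into confident-looking calls and
destroy specificity. The control exploits an asymmetry: for a chance
junction the "TE portion" of the read is ordinary genomic sequence and
continues the reference beyond the flank alignment almost perfectly,
while for a true junction it is TE sequence and matches the adjacent
reference only at background (~25%) identity. The 0.4 threshold sits far
from both modes, so the decision is insensitive to sequencing errors on
either side.

**Supporting-promotion blocking.** The same chance-match phenomenon means
almost every genomic mate carries some low-score internal TE hit. Barring
all of them from SUPPORTING status would eliminate the supporting-read
evidence channel entirely (and with it, most low-coverage sensitivity).
Promotion is therefore blocked only by internal hits with score ≥
`supporting_block_score = 20` — genuine partial TE content — which chance
matches essentially never reach.

## The simulator and what it does (not) emulate

`plant_insertions()` draws insertion sites uniformly (per chromosome,
proportional to length) with a minimum pairwise distance of
2 × `window_bp`, duplicates the `tsd_len` reference bases following each
site, and splices the family consensus (random strand) between the two
motif copies. `simulate_reads()` draws
`N = ceiling(coverage × genome_length / (2 × read_len))` fragments with
lengths from Normal(500, 100) truncated to `[read_len, 1000]`, reads
100 bp from each fragment end (mate 2 reverse-complemented), and applies
uniform per-base substitution errors (default 1%) with constant Q30
qualities. Everything is driven by a single integer seed and is
byte-reproducible.

The generator emulates the features the caller actually exploits —
junction structure, TSDs, insert-size geometry, substitution noise — but
not several properties of real data: indel sequencing errors, quality-
dependent error profiles, GC or coverage bias, nested or truncated
elements, and pre-existing reference TE copies (the synthetic reference
is repeat-free, so the repeat-ambiguity and annotation-proximity filters
are exercised only lightly). Passing the benchmark therefore demonstrates
the correctness of the junction logic and its robustness to substitution
noise, not performance on heterochromatic, repeat-dense sequence.

The bundled 14-family library uses the family names commonly profiled in
rice resequencing, but its consensi are seeded random sequences (lengths
300–8000 bp; TSD lengths 2–9 bp by family class), since real consensi
are not redistributable here. Random consensi are, if anything, adversarial
for nothing: they lack terminal inverted repeats and internal repetition,
which makes family assignment slightly easier than with real MITEs. The
benchmark's difficulty lives in the coverage, error and evidence-count
regime, which is preserved.

## Benchmark problem sizes

The packaged benchmark plants 200 insertions into a 2 Mb random genome
and scores three replicates at 3, 10 and 20-fold coverage (1% errors),
matching calls to truth within 100 bp (call position = TSD-interval
midpoint; each true-positive call is compared to its nearest truth record
for TSD identity). A 2 Mb chromosome holds 200 sites at the required
4 kb spacing comfortably while keeping a full sweep within minutes on one
CPU; sensitivity/specificity at this scale are governed by per-site read
counts (binomial in coverage), not genome size, so the scale-down leaves
the operating characteristics intact.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; files (GFF3) are 1-based
  inclusive; conversion happens only at I/O boundaries.
* Ties everywhere resolve deterministically: family assignment by score,
  then mismatches, then lexicographic name; co-optimal placements by
  strand (`+` first) then coordinate; stable sorts throughout. Identical
  input and configuration give byte-identical GFF3 output.
* A subcluster with junctions on both sides but non-overlapping flanks
  (no TSD, e.g. a blunt insertion or a trimming artefact) reports the
  single base at the left breakpoint and `tsd_seq = NA`.
* Insertion strand is reported only when junction reads abut both TE
  termini and agree; otherwise it is unknown (`.` in GFF3).
* Empty inputs (no reads, no candidates) produce header-only GFF3 files;
  an empty TE library or reference is an error, not an empty result.
* The matcher's contract is seed-limited by design: a hit must contain an
  exact 7-mer. Marginal alignments whose longest exact stretch is shorter
  (possible at length 10 with 2 mismatches) are invisible to tile-based
  search engines and are excluded from the contract — the test-suite
  oracle applies the same criterion.

## Known limitations

Substitution-only alignment (no indels) in both the matcher and the
mapper; detection of TE absences, nested insertions and insertion
frequency estimation are out of scope. On repeat-dense references the
mapq filter will suppress calls whose flanks are not unique, and the
annotation-proximity rule requires a reference TE annotation to be
supplied. The SAM adapter (`read_sam_alignments()`) allows an external
aligner to stand in for the internal mapper; its MAPQ values are used
only relative to `mapq_min`.
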