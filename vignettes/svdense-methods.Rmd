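---
title: "svdense: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svdense: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

svdense discovers structural variants (SVs) — insertions, deletions, tandem
duplications, inversions and translocations of roughly 50 bp and larger —
from long-read alignments. This vignette explains the model behind each
stage, the tunable parameters and their defaults, the design decisions that
were genuinely open, and what the bundled simulator does and does not
emulate.

## Raw SV signals

Every aligned read contributes *raw SV signals*, per-read observations of a
putative SV:

* **Intra-alignment signals.** A CIGAR insertion (`I`) or deletion (`D`/`N`)
  operation of at least `min_signal_size` (default 30 bp) becomes one
  INS/DEL signal at its reference coordinate. Aligners fragment single
  events in noisy reads, so two same-type operations are merged when the
  gap between them (read gap for `I`, reference gap for `D`) is at most
  `max(100, 0.5 x summed size)` bp. The default signal floor (30 bp) sits
  below the reported-SV floor (`min_sv_size`, 45 bp) deliberately:
  sub-threshold fragments can merge into reportable events.
* **Split-read signals.** A read aligned as several segments (primary +
  supplementary records) is scanned pairwise along its read coordinates.
  Classification priority is: different chromosomes → TRA; different
  strands → INV; otherwise the read-side gap *g* and reference-side gap *r*
  decide — DEL when `r − g >= min_signal_size`, INS when
  `g − r >= min_signal_size`, DUP when the segments overlap on the
  reference (`r < 0`). Chromosome and orientation changes are unambiguous,
  which is why they take priority over gap arithmetic; gap arithmetic is
  only meaningful for same-chromosome, same-strand pairs. Segment pairs
  with MAPQ 0 on both sides are suppressed at the source: ambiguous
  placements generate correlated noise.
* **Clip signals.** Alignments with at least 200 bp of soft/hard-clipped
  sequence on a side are recorded as clipped ends; these feed the
  large-insertion module only. A clip whose read interval is already
  covered (>= 50%) by another segment of the same read is explained by that
  supplementary alignment and suppressed.

While scanning, the caller also records the total aligned read length per
chromosome. The genome-average depth sets the minimum supporting-read count

    N_supp = floor(depth / 10) + 2

(the floor makes the threshold a conservative integer; minimum 2). At 50x
this gives N_supp = 7.

## Density-based clustering

Signals of one type on one chromosome are sorted and their *density* is
computed sparsely: `density(p)` is the number of signals within
bandwidth/2 of `p`, evaluated at signal positions. Clustering scans for
density peaks:

1. find the highest remaining peak with summit density >= `N_supp`;
2. extend the window on both sides until the density drops below 10% of
   the summit height (or the next signal is farther away than one
   bandwidth, i.e. the density provably passes through zero);
3. consume the member signals and repeat.

Processing peaks from highest to lowest with consumption makes the
assignment deterministic and one-to-one (each signal joins at most one
cluster), and raising `N_supp` can only remove clusters, never add them.

The bandwidth adapts to event size, in two passes: a provisional pass at
100 bp, then a final pass in which each provisionally clustered signal
carries `clamp(0.5 x median member size, 100, 1000)` bp. Longer SVs
scatter their raw signals more (especially around repeats), so they get
wider windows; the clamp keeps windows bounded.

Translocation breakpoints are clustered with fixed windows instead: both
breakpoints must co-locate, with a 400 bp window for groups whose
breakpoint spread is small (sd <= 200 bp) and 800 bp otherwise. The 200 bp
cutoff is the midpoint of the two window radii.

**Multi-allele separation.** For INS/DEL/DUP clusters the first and third
quartiles (Q1, Q3; inclusive linear-interpolation definition, R type 7) of
member sizes decide: if `Q3 < 2 x Q1` the cluster is a single allele and
size outliers outside `[Q1/2, 2 x Q3]` are dropped (the outlier band is
deliberately symmetric with the multi-allele trigger); otherwise the sizes
are split into two alleles with a one-dimensional 2-means. The 1-D optimum
is always a threshold split of the sorted sizes, so the implementation
scores all n−1 splits with prefix sums and returns the exact optimum — no
random initialization, no seeds. Inversions are never split: their size
signal comes from junction geometry and is essentially noise-free, and a
bimodal inversion cluster is more plausibly two events than two alleles.

## Breakpoint refinement

Raw signal coordinates are imprecise on noisy reads. Each INS/DEL/DUP
cluster (per allele) is refined:

1. **Read windows.** From each supporting read, the subsequence spanning
   the provisional breakpoint +/- a 500 bp flank is extracted via a CIGAR
   walk (for deletions the window also spans the deleted interval; only
   fully spanning reads are used). 500 bp gives enough anchor to realign a
   consensus at 15% read error. At most 20 reads enter (12 for insertions
   over 3 kbp, where windows are long); support counting is unaffected.
2. **POA consensus.** The windows are combined by partial order alignment:
   reads are added to a growing DAG in a fixed order (descending length,
   then read id — pinned for determinism), each aligned with affine gaps
   (match +2, mismatch −4, gap open −4, extend −2) inside a band around
   the graph's expected-position coordinate. The consensus is the heaviest
   path by edge support, with a per-step penalty of a quarter of the
   maximum edge weight — the penalty is what keeps low-support insertion
   detours out of the path (a plain summed-weight path would *gain* weight
   by visiting them). On gap-free equal-length reads the consensus reduces
   to the column-wise majority vote. Fewer than 2 usable reads, or a
   consensus shorter than half the expected window, is a failure.
3. **Local realignment.** The consensus is realigned to the reference
   window `breakpoint +/- (size + flank)`. Rather than one giant banded
   DP, detection uses a single-long-gap model: forward and backward local
   DP row maxima joined across one unconstrained reference-side jump
   (forward jump = deletion, backward jump = tandem-duplication junction),
   and a three-state DP with a long query-side gap state for insertions.
   This finds arbitrarily large events in O(nm) time and O(n) memory. The
   consensus counts as properly aligned when the score reaches the
   aligned consensus length (at +2/−4 scoring this corresponds to roughly
   70–80% identity over the aligned bases), and the split must beat the
   best single local alignment by a margin (20, i.e. ten matched bases) —
   without that margin an SV-free consensus would fabricate a junction,
   since every split of a perfect alignment ties.
4. **Normalization.** Detected events are left-normalized (shifted left
   while the flanking base equals the last event base), the standard VCF
   convention, so breakpoints are comparable at single-base resolution.

On success the breakpoint is consensus-derived (`PRECISE`); on any failure
the cluster keeps the rounded mean (half-up — a pinned convention) of its
raw signal positions and sizes (`IMPRECISE`). Inversion and translocation
clusters always use means of their junction coordinates: split-read
junction coordinates are reference-exact up to alignment ambiguity, and
the one-gap realignment model does not describe a strand flip.

## Large insertions (longer than the reads)

An insertion longer than the read length is never spanned, so it produces
no `I` operation — only clipped alignments at the breakpoint. The module:

1. groups >= 200 bp clips within 1 kbp windows and keeps candidates with at
   least `N_supp` left-clips *and* `N_supp` right-clips (cluster position =
   median clip coordinate; clips scatter more than CIGAR signals, hence
   the 1 kbp window);
2. assembles the clipped reads per side. Because the clip coordinate pins
   each read's offset relative to the breakpoint, the layout is
   clip-anchored: the longest read becomes the backbone, every other read
   is banded-aligned at its known offset and accepted when it aligns over
   at least half its length at >= 55% identity (two 15%-error reads agree
   at only ~72%, which is why a raw-read threshold near 80% would reject
   every true overlap), and the backbone is polished by per-column
   majority voting over bases, deletions and inserted strings. Reads that
   fail to join are retried as their own layouts; single-read leftovers
   are dropped as fragments. The right-clip consensus (left flank +
   insertion prefix) and left-clip consensus (insertion suffix + right
   flank) are then merged across a k-mer-seeded overlap verified at >= 80%
   identity over >= 200 bp — polished sequences are accurate enough for
   the stricter threshold;
3. realigns the single resulting contig to the local reference (+/- 5 kbp;
   the long-query-gap DP again) and reports the insertion only when
   exactly one contig was assembled, the detected insertion lies within
   1 kbp of the candidate breakpoint on the same chromosome, and its size
   is >= 1 kbp. An insertion already called by the CIGAR/split path within
   1 kbp and 0.5–2x size is merged (the assembly size wins — it is derived
   from more sequence).

Heterozygous loci are handled implicitly: only clipped reads enter the
assembly, so reference-allele reads never contaminate the layout. The
reachable insertion size is bounded by roughly twice the read length
(each side contributes at most one read length of insertion sequence); no
explicit cap is imposed.

## Filtering, genotyping, duplication rescue

Candidates below `N_supp` supporting reads are flagged `low_support`;
candidates whose supporting segments' mean MAPQ is below `mapq_min`
(default 20, the conventional uniqueness threshold) are `low_mapq`.
Multi-allele loci are filtered per allele; exactly one passing allele
demotes the locus to a single-allele call, two passing alleles are
reported as one record with genotype 1/2.

Genotypes come from the support ratio r = supporting reads / local depth,
with local depth measured as mean aligned coverage over breakpoint
+/- 500 bp. r >= 0.75 calls a homozygote; under random sampling
heterozygotes concentrate near 0.5 and homozygotes near 1.0, and 0.75 is
biased slightly toward the homozygous side of the midpoint to keep
high-support heterozygotes from flipping.

Tandem duplications shorter than the read length usually surface as
insertions. For each INS call the supporting reads' inserted sequences are
locally realigned to the +/- 1 kbp reference flank; a sequence "aligns
back" when >= 50% of its bases sit in an alignment with >= 80% identity
(tolerant of 10–15% read error), and a strict majority (> 50%) of aligning
sequences flips the call to DUP. Calls longer than 2 kbp skip the test:
more than half of a > 2 kbp insertion cannot fit a 2 kbp window, so the
outcome is forced. At most 12 sequences are tested, with an early exit
once the majority is decided.

Output is VCF 4.2: POS is the 1-based first affected base, deletions carry
negative SVLEN, translocations become paired BND records with MATEID, and
multi-allele loci are one record with two ALT alleles and GT 1/2.

## The simulator

The simulator exists so that every stage — including the benchmark
experiments — runs without downloads or external aligners.

* **Truth sets.** Exact per-type counts (defaults: 10,000 DEL, 10,000 INS,
  1,000 DUP, 1,000 INV, 200 TRA = 22,200, placed by default on the GRCh38
  chr1–22+X chromosome lengths). Sizes follow a mixture of a
  geometric-decay background (weight 0.6, mean ~300 bp above the 50 bp
  floor) and Gaussian peaks at 350 +/- 30 bp and 6,000 +/- 500 bp (weights
  0.3/0.1) — the Alu and LINE peaks of real human genomes, with explicit
  parameters since only the peak locations are established. Zygosity is
  deterministic: round(2n/3) heterozygotes per type (an exact, testable
  2:1 ratio rather than Bernoulli draws), heterozygous events assigned to
  a random haplotype. Placement is uniform with a 2 x max(size, 1 kbp)
  exclusion zone between events (the larger radius of any pair governs)
  and a 20 kbp margin from chromosome ends, a telomere-like buffer that
  also keeps coverage near breakpoints representative. Truth coordinates
  are left-normalized at sampling time, exactly as the caller normalizes —
  otherwise ~25% of random events would carry an irreducible 1+ bp
  ambiguity and "exact breakpoint" would be ill-defined.
* **Haplotypes and liftover.** Each haplotype chromosome is a block list
  mapping haplotype intervals to reference intervals (collinear, inverted,
  or inserted content); translocations swap block-list tails between the
  haplotype chromosomes that currently carry the breakpoints. A
  translocation whose two cut points have been displaced into the same
  derived chromosome by an earlier swap cannot be applied and is removed
  from the truth.
* **Reads.** Lengths are gamma (shape 4, CV 0.5 — the spread of CLR-like
  length distributions) with configurable mean; starts uniform; strands
  Bernoulli. Error presets: `pacbio-clr` 15% total (40/30/30
  substitution/insertion/deletion), `nanopore` 12% (25/35/40), `hifi` 1%.
  Reads are drawn until the per-haplotype depth target is met (achieved
  depth within one read length, i.e. well within 2%).
* **Oracle alignments.** Each read's alignment is *computed* from its
  known placement: error edits are injected into the liftover-derived
  CIGAR, junction-crossing reads become primary + supplementary records
  with correct SA tags, segments with < 50 bp of aligned reference are
  clipped away, reads entirely inside inserted sequence are unmapped, and
  MAPQ is 60 throughout. This isolates the caller from aligner behavior
  and makes parameter-recovery tests exact.

What the simulator does **not** emulate: aligner-specific artifacts
(breakpoint slop, mapping ambiguity, MAPQ distributions), chimeric/junk
reads, base-quality strings, repeat-induced multi-mapping, and
low-complexity sequence (the synthetic genome is uniform random, so there
are no Alu/LINE homologies for signals to slide along). Passing the
simulation benchmarks therefore demonstrates correctness of the SV
machinery under the stated error model, not performance on real repeats —
the component real data stresses hardest is the clustering bandwidth
adaptation, which is exercised here only through error-induced scatter.

## Bundled benchmark experiments

`bench_run()` reproduces the whole-genome simulation protocol at desk
scale: a 5 Mbp synthetic genome in 4 chromosomes with 400 SVs in the
standard proportions (180/180/18/18/4), 2:1 het:hom, 25x per haplotype and
15 kbp mean reads — the full protocol divided by 55.5, chosen so a
complete run (simulation, calling with refinement and assembly, scoring)
takes a few minutes on one core. `bench_large_ins_run()` implants 20
homozygous 20–30 kbp insertions in 2 Mbp at 50x with 15 kbp reads, so
every event exceeds the mean read length and detection must come from the
local-assembly module. Calls are scored with the standard true-positive
rules: matching type, breakpoints within 1 kbp (both breakpoints for
TRA), size within 0.5–2x of truth, greedy one-to-one matching by
coordinate distance, both sets floored at 45 bp.

## Known limitations

* Diploid assumption throughout: k = 2 in the allele split, genotypes in
  {0/1, 1/1, 1/2}. Polyploid genomes are out of scope.
* The one-long-gap realignment model assumes at most one SV per
  refinement window; nested or clustered events fall back to imprecise
  means.
* Inversion and translocation breakpoints are not POA-refined; on real
  aligners their precision is limited by the aligner's junction placement.
* CRAM input and unsorted name-grouped streams are not supported.
* The duplication-rescue window (±1 kbp) bounds rescuable duplications at
  2 kbp; larger tandem duplications must be caught by split-read overlap
  signals.
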