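---
title: "Re-joining metagenome-assembled contigs: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-joining metagenome-assembled contigs: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

De Bruijn graph assemblers emit a contig for every unbranched path of the
assembly graph. Where the graph branches — at a repeat, at a region shared
by two genomes, or at a within-population variant — the path is cut, and the
two contigs that abut at the cut both carry the branching node's sequence at
their facing ends. That sequence has a fixed, assembler-determined length:

* `L = maxK` for metaSPAdes and MEGAHIT,
* `L = maxK - 1` for IDBA_UD,

with `maxK` the largest k-mer size used in the assembly. A join between two
contigs is therefore *certified* at the sequence level by an exact,
L-length end match (possibly through the reverse complement). But an end
match alone is weak evidence — a shared repeat produces the same signature —
so a candidate join must also pass two orthogonal filters before it is made:

1. **Coverage compatibility.** Fragments of one genome were sequenced at one
   depth; the candidate's mean depth must lie within a ratio window of the
   *query's* depth (default `[0.5, 2]`, inclusive). Reads from sequencing
   error or from a minor strain variant create spurious branches whose
   coverage is far from the query's; this filter removes them.
2. **Spanning read pairs.** At least `min_spanning_pairs` (default 1) read
   pairs must have one mate mapped to each of the two contigs, each mate
   with at most `mm_max` (default 2) mismatches, read from the NM tag of
   primary alignments. A real adjacency in the underlying genome is
   physically covered by inserts; a coincidental k-mer match is not.

### End classification

All contig ends are indexed by their L-mer and its reverse complement. Two
ends are *partners* when one contig can be glued after the other across an
exact L-overlap: opposite ends (right/left) with equal L-mers, or same-side
ends (right/right, left/left) with reverse-complementary L-mers. Each end is
classified:

* `no_match` — no partner;
* `one_path_end` — exactly one partner;
* `two_paths_end` — partners B and C, where B and C are each partnered
  exclusively with this end (the shape produced by a two-copy repeat or a
  two-genome shared region);
* `multi_path_end` — anything more tangled, including two partners without
  the exclusivity property.

### Walking joins

Each query is extended depth-first from both ends, one contig at a time. At
a `one_path_end` the unique partner is accepted iff it passes both filters;
at a `two_paths_end` the *single* candidate that passes both filters is
accepted, and if zero or both pass the extension fails there. `no_match` and
`multi_path_end` stop the walk. A contig is never used twice in one walk;
revisiting a walk member stops that direction, except that reaching the
query's own opposite end closes the walk into a circle (`extended_circular`).
Sequences are merged by dropping one copy of each internal L-overlap, so a
linear join has length `sum(member lengths) - (n-1)*L` and a circular join
`sum - n*L`.

After all queries are walked, path uniqueness is enforced globally:

* if a contig is claimed by the accepted walks of two or more *distinct*
  final sequences (distinct member sets), every query involved is demoted to
  `extended_failed` — the two seemingly unique paths cannot both be real;
* if the two directional extensions of one query pulled in distinct contigs
  whose sequences are near-duplicates, the query is demoted — its two ends
  converged into closely related (strain-variant) sequence and the true
  layout is ambiguous.

### Self-circularity

A single contig is a circular genome in linear clothing when its two ends
certify the wrap-around:

* **case 1** — the L-length prefix equals the L-length suffix and the two
  ends match nothing else (the shape an assembler emits for a clean circular
  traversal);
* **case 2** — neither end has any partner, and the contig carries an exact
  terminal repeat of length `d >= minK`. No upper cap is placed on `d` other
  than not being the case-1 shape: direct terminal repeats of circular viral
  genomes are commonly 100-200 bp and routinely *exceed* L, in which case
  the first and last L-mers differ (they start at different offsets inside
  the repeat) and only the full-repeat comparison reveals the circle. The
  repeat must be exact; a single mismatch disqualifies. One repeat copy is
  trimmed from the output.

`minK` (default 21 in the command-line tool, the smallest assembler k-mer)
bounds how short a terminal repeat can be before it is indistinguishable
from chance: a random match of length 21 occurs with probability ~4^-21 per
contig, negligible even genome-wide.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `maxK` | — | bp | from the assembly command line |
| `minK` | 21 | bp | smallest assembler k-mer; lower bound for case-2 terminal repeats |
| `cov_ratio_window` | (0.5, 2) | ratio | a symmetric two-fold window; fragments of one genome rarely differ more in depth within one sample, while strain variants and repeats usually do. Inclusive at the boundaries so exact 2:1 repeats are not silently split |
| `min_spanning_pairs` | 1 | pairs | the weakest faithful reading of "spanned by paired reads"; raise for noisy libraries |
| `mm_max` | 2 | mismatches/read | tolerates one sequencing error plus one minor variant per 126-150 bp read without admitting cross-variant mappings |
| conflict `k`, `T` | 31, 0.9 | — | canonical k-mer containment between left- and right-walk contigs; k = 31 is long enough that shared words imply near-identity, T = 0.9 catches strain-variant convergence while ignoring chance repeats |

Two deliberate tie-break rules: when both `two_paths_end` candidates pass
all checks the join *fails* (conservative — picking the higher-coverage one
would silently gamble on the wrong strain), and queries are processed in
descending length then id, which is deterministic and favors long seeds.

## Coordinates and conventions

All interval coordinates are 0-based, half-open. Sequences are uppercased on
load; `N` is allowed, but an end L-mer containing `N` never matches any
partner — an ambiguous base cannot certify an exact overlap. Palindromic
L-mers (their own reverse complement) are matched once, not double-counted.
Circular outputs are compared in tests via the lexicographically smallest
rotation of the smaller of sequence and reverse complement (computed by a
linear-time least-rotation algorithm); written FASTA keeps the natural
rotation. Coverage is taken from the two-column input table and never
recomputed from the BAM; insert-size and mate-orientation consistency are
deliberately not enforced (contig-level linkage only), and spanning pairs
are counted between the two joined contigs anywhere, not only across the
junction base itself.

## The synthetic community generator

`simulate_community()` emulates the composite-benchmark design: circular
genomes with direct terminal repeats of 100-200 bp, pairs of an original
genome plus a variant mutated at 1%, 3% or 5% of bases (positions drawn
without replacement, substitutions uniform over the three alternatives), and
original + 3% + 5% triplets. Defaults are the benchmark's category sizes
(500/500/500/500/300, totalling 4,400 genomes), per-genome depths uniform in
10-100x, and genome lengths of 5-50 kb (the typical phage range). Tests and
the acceptance script shrink genome lengths and counts — the *structure*
(categories, rates, depth law) is what matters to the engine, not the base
count.

`fragment_at_repeats()` cuts each genome so that adjacent fragments share
exactly the L-length end sequence. Three fragmentation sources are
supported: random breakpoints at unique positions (recoverable chains — the
surrogate for breaks whose other graph parties are outside the community),
within-genome planted duplications (flank/repeat/flank contigs whose repeat
contig is needed twice by the true walk, so full recovery is impossible, as
in real assemblies), and cross-genome shared regions (the shared contig is
emitted once, as an assembler would collapse identical unitigs; the truth
table attributes it to the first genome and the placements table carries
both placements).

`simulate_reads()` draws 126 bp pairs uniformly per genome at its depth
(insert 300 +/- 30 bp, clamped to at least two read lengths) and writes the
SAM directly from the known coordinates, with exact NM tags — no aligner is
involved, which makes the mismatch filter exactly testable. A read crossing
a fragment junction beyond the shared end sequence fits no single contig
and is simply left unmapped (its mate keeps the mate-unmapped flag), mildly
deflating edge coverage, as real clipped alignments would.

What the generator does *not* emulate: sequencing error models and quality
strings (an optional uniform substitution rate stands in), chimeric
assembly artifacts, uneven within-genome coverage, and real assembler
breakpoints (ours are planted idealizations). Passing tests therefore show
the engine's logic is correct under the stated breakage model — not that
any particular real assembly will be resolved.

## Problem sizes used by the test suite

The round-trip property runs communities of 20 circular genomes of 5-20 kb
at 20-50x depth over three seeds and requires at least 90% of
multi-fragment genomes to be recovered exactly (rotation-equivalent); the
full 4,400-genome design is exercised at 500-800 bp genome length, where
only the category arithmetic is at stake. These sizes were chosen as the
smallest at which every code path (wrap-around fragments, junction-spanning
pairs, coverage windows) is genuinely exercised.

## Known limitations

* Queries at very low depth rarely extend: few spanning pairs exist, and
  their breakpoints often come from coverage gaps with no overlap partner at
  all (`orphan_end`).
* A repeat contig can be traversed only once per walk, so genomes with
  multi-copy internal repeats cannot be fully rebuilt from a single sample.
* Input contigs are trusted as-is: chimeras introduced by the assembler are
  neither detected nor repaired.
* Reads from only one sample are used; joins below the validation thresholds
  in that sample are not rescued by other samples.
* The coverage window is a heuristic on mean depths; highly uneven coverage
  (amplification bias, prophage induction) can push true joins outside it.
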