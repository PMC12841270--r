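---
title: "Methods: 8-mer spectrum decomposition for alignment-free phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 8-mer spectrum decomposition for alignment-free phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`kmerphylo` treats a genome as a bag of overlapping 8-mers. A window of
8 bp slides along every sequence record with step 1 bp; windows containing
any character outside `{A, C, G, T}` are skipped, records are counted
independently (no windows span record boundaries), only the given strand
is counted, and lowercase (soft-masked) residues are upper-cased and
counted. The result is a count vector $N_1, \dots, N_{4^8}$ over the
65,536 possible 8-mers, indexed by the base-4 encoding $A=0, C=1, G=2,
T=3$ (equivalently, lexicographic order).

Two derived quantities describe the spectrum: the **relative motif
number** $RMN(i) = (\#\{8\text{-mers with count } i\}) / 4^8$, and the
**random center** $\bar N = \sum_i N_i / 4^8$, the count every 8-mer would
have under uniform usage. The $RMN$ denominator is fixed at $4^8$ even
when the histogram is restricted to a subset, so subset histograms sum to
(subset size)$/4^8$ rather than 1 — this keeps subset histograms directly
superimposable on the total spectrum.

### Motif classes

For a dinucleotide $XY$, every 8-mer belongs to class $XY0$, $XY1$ or
$XY2$: zero, exactly one, or two-or-more occurrences of $XY$, **with
overlaps allowed** (the 8-mer `AAAAAAAA` contains seven `AA`). Overlap
counting is not optional: it is the convention under which the class
cardinalities take their combinatorial values — 40,545 / 21,468 / 3,523
for any $X \neq Y$ and 44,631 / 14,931 / 5,974 for $X = Y$ — which the
package asserts for all 16 dinucleotides, and likewise for all 64
trinucleotide partitions of the 262,144 9-mers (three symmetry classes:
$X{=}Y{=}Z$, $X{=}Z{\neq}Y$, and the rest, distinguished by the motif's
self-overlap periods). Every cardinality is verified by a second,
independent route: a dynamic program over the motif's KMP failure
automaton with occurrence counts capped at 2 — a transfer-matrix linear
recurrence that never touches individual k-mers. For non-self-overlapping
motifs it collapses to classical avoid-word recurrences such as
$f(n) = 4f(n-1) - f(n-2)$ for `CG`.

### Class-level features

Vertebrate genomes deplete CpG, so the `CG1`/`CG2` subsets sit far below
the random center and are unusually narrow. Two log-ratios quantify this
per subset $i$:

* separability $\delta_i = \log_2(\bar x / \bar x_i)$, where $\bar x$ is
  the random center and $\bar x_i$ the subset's mean count — positive when
  the subset is depleted;
* conservatism $\beta_i = \log_2(SD / SD_i)$, where $SD$ is the standard
  deviation of all 65,536 counts and $SD_i$ that of the subset — positive
  when the subset spectrum is narrower than the total.

The canonical feature set has 93 subsets: `CG0, CG1, CG2`, then for each
of the 15 non-CG dinucleotides (lexicographic: `AA, AC, ..., TT`,
including `GC` — the arithmetic $3 + 15 \times 2 \times 3 = 93$ forces its
inclusion) the six second-level subsets $XYi\_CGj$ with $i \in \{0, 1\}$
($XY1$ and $XY2$ merged into "present") and $j \in \{0, 1, 2\}$. The
93 δ plus 93 β values form the 186-entry class-level feature vector, in a
fixed order shared by all species; the class-level distance pairs features
by position, so a consistent order is all that matters and this one is the
package's choice.

### Order-level features

Each 8-mer's count is replaced by its rank: 1 for the most frequent,
65,536 for the least. Ranks are a strict permutation; ties are broken by
ascending 8-mer index. A deterministic tie rule is mandatory for
reproducibility; ordinal ranking with index tie-break was chosen over
average ranks because the distance below assumes integer ranks forming a
permutation. Ranking deliberately discards genome-size scale (multiplying
all counts by a constant leaves ranks unchanged) and tames the spectrum's
heavy right tail without filtering high-frequency outliers — the rank
transform itself is the remedy, so no mean + 3 SD truncation is applied.

### Distances and trees

* Class-level: $D_{nm} = \sum_{k=1}^{93}
  \sqrt{(\delta_{nk}-\delta_{mk})^2 + (\beta_{nk}-\beta_{mk})^2}$ — the
  square root is **inside** the sum: each subset contributes its own
  planar displacement, so no single feature's square dominates. The
  plausible alternative, a single root over all 186 squared differences,
  is available as `class_distance(..., pooled = TRUE)` for sensitivity
  analysis but is not the default and not used by the pipeline.
* Order-level: $W_{nm} = \sqrt{\sum_{k=1}^{65536} (R_{nk}-R_{mk})^2}$ —
  plain Euclidean distance on rank vectors, hence a true metric (the test
  suite checks symmetry, identity and the triangle inequality; $D$ is
  symmetric and non-negative but, as a sum of roots, is not asserted to be
  Euclidean).

Trees are built by a native Saitou–Nei neighbor-joining implementation:
join the pair minimising $Q(i,j) = (r-2)d(i,j) - R_i - R_j$, estimate
pendant branches by the two-point formulas, reduce, and finish with the
three-point equations. Two numerical policies make the output
deterministic and well-formed: Q-ties are broken by the lowest (row,
column) pair in label order, and negative branch-length estimates are
clamped to zero with the deficit moved to the sister branch (preserving
their sum). Distance matrices pass through uncorrected. No bootstrap is
computed. On additive matrices NJ is consistent: the test suite checks
exact topology and branch-length recovery (to $10^{-9}$) on 200 random
trees with 4–12 leaves.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | window width (nt); the feature pipeline requires 8, the trinucleotide analysis 9. 8 is where eukaryotic spectra stabilise and matches typical transcription-factor site length |
| CpG multiplier | 0.2 in fixtures | factor on the C→G transition probability of the simulator; 0.2 emulates the roughly five-fold CpG depletion typical of vertebrates |
| genome length | $10^6$ nt | simulator default for tests: large enough that the random center ($\approx 15$ counts per 8-mer) gives non-degenerate subset statistics, small enough for seconds-scale generation |
| `n_per_clade` | 3 | genomes per clade in the two-clade fixture |
| seed scheme | master + ordinal | per-genome seeds are `seed + i`, so fixtures are stable across platforms |

## What the simulator does and does not emulate

`generate_genome()` samples a first-order Markov chain whose transition
matrix is `base_frequencies[y] * bias[xy]`, row-renormalised, with the
initial base drawn from the chain's stationary distribution. This
reproduces exactly the dinucleotide-level structure the features read out:
lowering the CpG multiplier depresses the `CG1`/`CG2` subset means below
the random center, and $\delta_{CG1}, \delta_{CG2}$ respond monotonically
(checked at multipliers 1.0, 0.5, 0.2, 0.05). It does **not** emulate
isochores, repeats, higher-order composition, chromosome structure, or
evolution along a tree (no substitution model) — so a passing two-clade
recovery shows that the pipeline converts a dinucleotide-bias contrast
into the correct bipartition, not that it resolves real taxonomies;
resolution claims on real genomes are outside what the tests can show.

## Numerical choices and degenerate inputs

* **SD interpretation.** "Standard deviation of the spectrum" is read as
  the population SD of the per-8-mer counts (divisor $n$), over the full
  set for $SD$ and the subset for $SD_i$: it measures the narrowness of
  the count distribution, which is what conservatism describes. The
  sample/population difference is negligible at the smallest subset size
  used (3,523).
* **δ at the random center.** A subset distributed like the random center
  has $\bar x_i = \bar x$, hence $\delta_i = 0$; the formula is
  implemented exactly as the log-ratio.
* **Degenerate genomes.** Empty subsets cannot occur for the 93 canonical
  subsets; a genome too small (or too uniform) for a subset to have a
  positive mean or SD raises an error naming the subset rather than
  emitting NaN features. A perfectly flat count table has $SD = 0$ and
  errors likewise.
* **Windows and masking.** Any window containing a non-ACGT character is
  skipped entirely; lowercase is counted after upper-casing; reverse
  complements are never merged (the motif classes, e.g. `CG1` vs `GC1`,
  are strand-specific by construction).
* **Problem sizes in the test suite.** Module tests run on $2 \times 10^5$
  nt genomes and reduced-n permutations; the end-to-end acceptance checks
  use the fixture defaults (3+3 genomes of $10^6$ nt, multipliers 0.2 vs
  1.0) and 200 random additive matrices. These sizes are the package's
  documented study conditions.

## Known limitations

* The class-level distance $D$ is a sum of per-feature Euclidean
  distances; it is symmetric, non-negative and zero on feature-wise equal
  inputs, but no triangle-inequality guarantee is claimed or tested.
* `count_kmers()` accepts `k` up to 15, but memory is $O(4^k)$; the
  partition machinery is capped at $k \le 12$.
* The CLI is single-process; genomes are streamed one at a time.
* Real-genome preprocessing (chromosome selection, assembly masking
  policy) is left to the user; the package counts whatever FASTA it is
  given.
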