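---
title: "Binning amplicon reads with locality-sensitive hashing: models and methods"
author: "lshOTU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning amplicon reads with locality-sensitive hashing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lshOTU)
```

## The problem

Targeted (16S rRNA) metagenome surveys produce large collections of reads
from a single marker gene, and the first analysis step is almost always the
same: group reads into Operational Taxonomic Units (OTUs), clusters of
sequences close enough to stand in for species. Classical OTU pickers
build an all-pairs distance matrix — \(O(N^2)\) Needleman–Wunsch
alignments or k-mer profiles — before clustering, which is the step that
exhausts memory and CPU first as samples grow.

`lshOTU` replaces the all-pairs matrix with a randomized filter. A
*locality-sensitive hash* maps each read to a short signature whose
collision probability grows with sequence similarity; greedy seed-based
clustering then only needs signature comparisons, which cost \(O(k)\) per
pair instead of \(O(n^2)\) dynamic programming, and no pairwise structure
is ever materialized.

## The hash and its filter

For reads of effective length \(n\) (the shortest read of the sample), one
iteration draws \(k\) distinct window centers \(i_1 < \dots < i_k\)
uniformly without replacement from the positions where a full window fits.
The signature of read \(s\) is the tuple of \(w\)-mers centered at the
sampled positions,

\[ h(s) = (s[i_1 - \tfrac{w-1}{2} .. i_1 + \tfrac{w-1}{2}], \dots), \]

with \(w\) odd so windows are symmetric. Two signatures *collide* when at
most \(\lfloor p k \rfloor\) of the \(k\) symbols differ; a symbol either
matches exactly or mismatches — there is no partial credit inside a
\(w\)-mer, so widening \(w\) at fixed centers is strictly more stringent.
With \(k = 64\) and \(p = 10\%\), for instance, up to 6 of the 64 sampled
symbols may differ.

For single-nucleotide windows, two reads differing at no more than \(m\)
positions collide (at \(p = 0\)) with probability at least
\((1 - m/n)^k\) under independent index draws
(`collisionProbabilityBound()`). Because the implementation samples
centers *without* replacement, its exact collision probability for a pair
at exactly \(m\) mismatches is hypergeometric,
\(\binom{n-m}{k}/\binom{n}{k}\), which is slightly *below* the classical
bound (a distinct-index draw cannot re-test a position already known to
match); `collisionProbabilityExact()` exposes this value, and the test
suite verifies both against Monte-Carlo frequencies under their respective
sampling models.

## Greedy assignment and the union over iterations

Within one iteration, the pool of unassigned reads is scanned (in an order
shuffled by the iteration's RNG stream by default): the first read seeds a
new OTU, every pool member whose signature collides with the seed's joins
and leaves the pool, and the scan repeats until the pool is empty. A
single hash can split truly similar reads — a false negative — whenever
the sampled centers happen to hit their differences, so the procedure is
repeated for \(l\) iterations with fresh hash functions and the partitions
are merged by *union*: two reads share a final OTU iff they were
co-clustered in at least one iteration, directly or through a chain of
intermediates. We implement the union as transitive closure with a
disjoint-set structure; it is the only well-defined reading of a union of
partitions, and it makes the merged OTU count non-increasing in \(l\)
(edges only accumulate). Larger \(l\) therefore trades false negatives
for false positives.

Two properties worth knowing:

* The greedy covering is order-dependent by construction; with the default
  random seeding the full run is still exactly reproducible from the
  master seed, because iteration \(t\) uses a deterministic stream derived
  from (seed, \(t\)). A deterministic `input_order` mode exists for
  debugging.
* Raising \(p\) enlarges every seed's accept set but is **not** guaranteed
  to reduce the OTU count: similarity is not transitive, and a more
  permissive seed can "steal" the read that would otherwise have seeded a
  large cluster, leaving its former neighbours stranded. On
  species-structured reads (well-separated groups) the count does decrease
  with \(p\), and the suite tests exactly that; the adversarial
  counterexample needs three reads at carefully tuned distances and does
  not arise in the simulated regimes.

## Mapping a distance cutoff to the mismatch fraction

Practitioners state OTU radii as *nucleotide* divergence — "a 4% cutoff"
means reads inside an OTU are at most 4% apart. The filter, however,
counts whole \(w\)-mer symbols. A pair of reads at divergence \(d\)
corrupts a randomly placed \(w\)-window with probability
\(q = 1 - (1-d)^w\) (any of the \(w\) covered positions may differ), and
the \(k\) sampled windows observe roughly \(\mathrm{Bin}(k, q)\) corrupted
symbols. Setting \(p = q\) alone would reject half of the pairs sitting
at the nominal divergence in any one iteration, so the package maps

\[ p(d) = q + \sqrt{q (1 - q) / k}, \qquad q = 1 - (1-d)^w, \]

the expected corrupted fraction plus one binomial standard error
(`cutoffToMismatch()`). For \(w = 1\) and large \(k\) this reduces to
\(\approx d\). The naive identification \(p = d\) is wrong for
\(w > 1\) — at \(k = 30, w = 3, d = 0.04\) it allows only one corrupted
symbol and over-splits species into several-fold too many OTUs — whereas
the calibrated mapping recovers a 43-species ground truth exactly at the
4% cutoff with 3%-error reads, and overestimates (as it should) when the
reads carry 5% errors. `clusterOTUs()` accepts either the raw fraction
`p` or `distanceCutoff`, which applies this mapping.

## Post-hoc cutoff validation

Because the filter only approximates a distance criterion, compliance is
*measured*, never assumed: `validateCutoff()` computes all within-OTU
pairwise distances under an exact metric and reports each OTU's maximum
and the global maximum against the cutoff.

Two exact metrics are provided. The alignment distance is a unit-cost
global Needleman–Wunsch (match 0, mismatch 1, gap 1, no end-gap
discount), normalized by alignment length so it lives on the same
\([0,1]\) scale as the cutoff. Co-optimal alignments can differ in
*length* (a mismatch trades against two gap columns at equal cost), so
each pair is aligned in a canonical lexicographic order to keep the
distance well-defined and symmetric; the alignment engine is
`Biostrings::pairwiseAlignment`, cross-checked in the tests against an
independent Levenshtein DP. The k-mer distance is
\(1 - \sum_v \min(c_a(v), c_b(v)) / (\min(L_a, L_b) - k + 1)\) over k-mer
multisets (default \(k = 6\)); this is our reconstruction of the standard
k-mer screening distance, exposed mainly to contrast k-mer-defined with
alignment-defined cutoffs. An ambiguous base `N` mismatches everything,
including another `N`: ambiguity must never manufacture a collision or a
zero distance. Large OTUs can cap the quadratic pair count via
`maxPairs`; the report is then flagged as a sampled lower bound.

## Richness and diversity estimators

From the OTU size histogram \(n_i\) (number of OTUs with exactly \(i\)
reads, \(S_{obs}\) OTUs, \(N\) reads in total):

* **Chao1** (bias-corrected): \(S_{obs} + n_1 (n_1 - 1) / (2 (n_2 + 1))\),
  finite even without doubletons.
* **Shannon** \(H' = -\sum (n_i/N) \ln (n_i/N)\), in nats by default.
* **ACE** with rare/abundant threshold `abund` (default 10):
  \(N_{rare} = \sum_{i \le abund} i n_i\),
  \(C = 1 - n_1 / N_{rare}\),
  \(\gamma^2 = \max\bigl(\frac{S_{rare}}{C}
  \frac{\sum i(i-1) n_i}{N_{rare}(N_{rare}-1)} - 1,\, 0\bigr)\),
  \(S_{ACE} = S_{abund} + S_{rare}/C + (n_1/C)\,\gamma^2\).

The \(\gamma^2\) parenthesization above is the standard
coefficient-of-variation form; every intermediate is exposed in
`AceComponents` so an alternative reading can be swapped in one place.
Edge cases are explicit: no rare OTUs gives \(S_{ACE} = S_{abund}\); all
rare OTUs singletons gives zero estimated coverage and an error (the
estimator's known singularity); \(N_{rare} \le 1\) forces
\(\gamma^2 = 0\). The estimators are validated against hand-evaluated
values and against `vegan::estimateR`/`vegan::diversity` as independent
implementations.

## Comparing samples

After a *joint* clustering of several samples, each sample reduces to the
set of OTU labels its reads populate; samples are compared by the Jaccard
index \(|A \cap B| / |A \cup B|\) (presence/absence only — no abundance
weighting) and grouped by agglomeration on the distance \(1 - J\).
Average linkage is the default — the usual choice for Jaccard-based
beta-diversity dendrograms — and is configurable; trees serialize to
Newick via `ape`.

## The read simulator

`generateReferences()` draws uniform-random reference sequences under a
pairwise Hamming-divergence floor (rejection sampling), and
`simulateReads()` emits full-length reads whose substitution count is
uniform on \(0 .. \lfloor e L \rfloor\) — "up to \(e\)" errors as a
per-read budget, not a per-base rate — at uniform positions, always to a
different base. Defaults mirror the benchmark conditions used throughout:
43 species, 200 bp, divergence floor 0.20, 20 reads per species, up to 3%
errors. `recoveryScore()` reports the OTU count against the known species
count and the majority-label purity (over-splitting is pure; spurious
merges lose purity).

What the simulation does *not* emulate: indels and homopolymer noise
(the filter is position-based; indel-dominated platforms would shift every
downstream window and need an anchoring step first), chimeras, abundance
skew, and length variation. Passing the recovery benchmark therefore
shows the hashing pipeline is correct and calibrated for
substitution-noise regimes, not that real 454/Illumina samples will
cluster at the same accuracy.

## Numerical and design choices

* Window convention: \(w\) is the *total* window width, centered on the
  sampled index, \(w\) odd. This keeps one symbol per index and makes the
  \(k=64 \to 6\) allowance example coherent.
* Variable-length reads: centers are sampled over the shortest read's
  length, so every read supports every window; reads shorter than the
  effective length are rejected at key extraction.
* Allowance is \(\lfloor p k \rfloor\) over symbols (floor reproduces the
  printed \(64 \times 10\% \to 6\) example).
* OTU labels are `OTU_<integer>` in creation order; merged labels in
  first-appearance order along input order — stable, diff-friendly output.
* Per-iteration seeds derive from the master seed by a fixed affine map
  modulo \(2^{31}-2\), so iteration sets are nested: runs with \(l\) and
  \(l+1\) iterations share their first \(l\) hash functions.
* Agglomeration ties follow `stats::hclust`'s deterministic ordering.

## Problem sizes

The recovery benchmark in the tests and the acceptance script runs 10
replicates of 860 reads (43 species × 20 reads, 200 bp) with
\(k = 30, w = 3, l = 4\) — a desk-scale surrogate chosen so the full
suite runs in minutes; the clustering itself scales linearly in reads per
iteration and has handled the same settings at much larger read counts.
Cutoff validation is quadratic per OTU (here \(43 \times \binom{20}{2}\)
alignments) and is the slowest step of the suite.

## Limitations

* The cutoff-to-\(p\) mapping is a calibration, not an exact guarantee;
  compliance with a nominal cutoff should always be checked with
  `validateCutoff()` on the data at hand.
* Greedy seeding is order-dependent; different seeds give slightly
  different partitions (the union over iterations damps, but does not
  remove, this variance).
* No preprocessing is included: dereplication, chimera removal, quality
  trimming and paired-end merging are upstream concerns.
* Presence/absence Jaccard ignores abundance; deeply sequenced samples
  sharing rare OTUs can look more similar than ecologically warranted.
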