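---
title: "Methods: quantifying intraspecific genome divergence with intradiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying intraspecific genome divergence with intradiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intradiv)
```

# Scope

`intradiv` measures how far genome assemblies of isolates of one species
have diverged, in sequence and in structure, and dissects the gene-level
processes behind structural divergence.  It was designed for microalgal
genomes (dinoflagellates in particular), where assemblies of multiple
isolates per species are increasingly available, but nothing in the
methods is taxon-specific.  Every stage has a matching synthetic
generator, so all claims the package makes about itself are checked on
inputs with known ground truth.

# Sequence divergence

## Alignment-based: Q and ID

Two assemblies are compared with a light-weight whole-genome aligner:

1. **Anchoring.** Seed words of the minimum anchor length (capped at 26
   nt for exact 2-bit packing) that occur exactly once in each genome
   (both query strands) are matched, merged along diagonals, and runs
   separated by identical sequence are joined.  This reconstructs
   maximal exact matches that contain at least one globally unique
   seed — a practical approximation of strict maximal-unique-match
   semantics that is exact on the synthetic genomes the package targets.
2. **Chaining.** Within each (reference scaffold, query scaffold,
   strand) group the highest-scoring strictly collinear chain (score =
   total anchor length; sweep plus Fenwick prefix-maximum, so groups
   with tens of thousands of anchors chain in seconds) is extracted,
   its anchors removed, and chaining repeated, so several rearranged
   segments (e.g. multiple inversions) on one strand are all recovered.
3. **Gap closing.** Inter-anchor gaps of at most `max_diag_gap` (90 bp
   by default) on both genomes are closed: equal-length gaps by direct
   base comparison, unequal gaps by exact global alignment (match +1,
   mismatch −1, gap −2) via Biostrings.  Larger gaps split the chain
   into separate blocks.  Blocks shorter than `min_report_len` columns
   (100, 1000 or 10000 in the standard configuration) are discarded.

From the reported blocks, **Q** is the percentage of query positions
covered by at least one block (positions counted once) and **ID** is
the column-length-weighted mean of block identities.  For genomes
beyond desk scale the same statistics can be computed on imported
coordinate tables from an external aligner (`read_coords_table()`);
ID is then the many-to-many length-weighted average, which differs
from a one-to-one variant when alignments overlap.

## Alignment-free: D2S distance d and core k-mers

k-mers (default k = 23, strand-collapsed canonical counting) are packed
2 bits per base into doubles; any k ≤ 26 is exact.  Counts are centred
by their expectation under each genome's own zero-order background:
for word *w*, \(\tilde X_w = X_w - n\,p_w\) with \(p_w\) the product of
the genome's nucleotide frequencies over the letters of *w* and *n* the
number of valid (N-free) windows.  The similarity is

\[
D2S = \sum_{w} \frac{\tilde X_w \tilde Y_w}
                    {\sqrt{\tilde X_w^2 + \tilde Y_w^2}},
\]

summed over the union of words observed in either genome; words
observed in neither contribute nothing, and zero-denominator terms are
skipped.  The distance is the self-normalised log transform

\[
d = -\ln\!\left(\frac{D2S(X,Y)}{\sqrt{D2S(X,X)\,D2S(Y,Y)}}\right),
\]

which is 0 for identical genomes, symmetric, and unbounded for
unrelated ones (a non-positive normalised similarity is reported as
+Inf with a warning).  The triangle inequality is not asserted.  A
zero-order background was chosen as the simplest model consistent with
the statistic's standard definition; higher-order Markov backgrounds
are out of scope.  Canonical counting is the default because genomes
are double-stranded; it is exposed as a flag since either convention
is defensible.

**Core k-mers** are the intersection of the distinct k-mer sets of all
isolates of a species; per isolate, *x* is the percentage of its
distinct k-mers that are core.  Occurrences of core k-mers can be
mapped back to BED intervals and intersected with feature annotations
(half-open coordinates; `bedtools`-style pairwise intersection via
GenomicRanges).

# Structural divergence

## Collinear blocks and duplication classes

Gene positions are reduced to per-scaffold ranks (order of gene start,
ties broken by gene id).  Filtered homology hits (e-value < 1e-5, query
*or* subject coverage > 50 %, top five hits per query, self hits
removed) become dots in rank space; collinear blocks are maximal
strictly monotone chains with inter-anchor rank gaps ≤ 25 on both axes,
extracted greedily (largest chain first, ties to the smaller total rank
gap), in both orientations, and reported at ≥ 5 anchors.  In
within-genome comparisons, dots closer than `max_gap` ranks to the
self-comparison diagonal are excluded, so tandem and proximal arrays
cannot masquerade as segmental duplications — the same practical
convention reference collinearity tools adopt by masking local
duplicates.  Block significance testing is deliberately out of scope:
acceptance is purely by anchor count.

Every gene receives exactly one of five labels, with precedence
`wgd > tandem > proximal > dispersed` over `singleton` (no surviving
hit): `wgd` anchors a within-genome collinear block; `tandem` has a
rank-adjacent homolog on the same scaffold; `proximal` a same-scaffold
homolog with 1–10 intervening genes; `dispersed` anything farther or on
another scaffold.  A homolog with exactly 10 intervening genes is
classified proximal; the boundary is a parameter (`proximal_max`)
because the defining inequalities ("< 10" vs "> 10") leave the boundary
case open.

When a gene anchors several partners (typical after whole-genome
duplication), `dedup_wgd_pairs()` keeps only its lowest-Ka+Ks pairing
and re-filters blocks to ≥ 5 anchors; anchors without a Ka+Ks value
score +Inf and lose ties.

## Tandem-duplication blocks and selection

A TD block is a maximal run of two or more genes at consecutive ranks
on one scaffold in which each adjacent pair is homologous under the
same hit filters (no extra identity threshold — homology output defines
membership).  For each block, Ka and Ks are computed for **all** gene
pairs in the block: coding sequences are translated, globally aligned
as proteins (BLOSUM62, gap open 11, extend 1), back-translated, and
gap-free codon columns scored with the Nei–Gojobori (1986) method:

* synonymous site counts per codon are the per-position fractions of
  the three possible changes that are synonymous, averaged between the
  two sequences; changes that create a stop codon count as
  nonsynonymous sites;
* differences per codon average all minimal substitution pathways with
  equal weight, excluding pathways through stop codons (if every
  pathway is blocked, all are used);
* proportions are Jukes–Cantor corrected,
  \(d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\), undefined for
  \(p \ge 3/4\).

Conventions for ω = Ka/Ks: 0/0 is undefined (NaN) and excluded from
means; Ka > 0 with Ks = 0 is +Inf and likewise excluded from block
means (the infinity-ignoring rule); block classes are `purifying`
(mean ω < 1), `neutral` (= 1), `positive` (> 1), `undefined` (no finite
ω).  NG86 was chosen as the single supported counting method; maximum-
likelihood codon models are out of scope.

## Orthogroups across inflation parameters

Proteins from all isolates form an undirected graph weighted by the
maximum bitscore over hit directions.  Plain Markov clustering is run
at inflation parameters 1.5–10: self loops at each node's maximum
incident weight, column normalisation, then alternating expansion
(matrix square) and inflation (elementwise power, renormalise) with
pruning at 1e-5 until the largest entry change falls below 1e-8;
clusters are the connected components of the converged support.  The
statistic of interest is the percentage of proteins in isolate-specific
clusters (all members from one isolate; singletons count by default,
exposed as a flag because conventions differ on unassigned proteins).
This is deliberately MCL on the raw bitscore graph — no length
normalisation, reciprocal-best-hit phase or gene trees — because the
granularity-versus-inflation behaviour, which the statistic depends on,
is a property of the clustering alone.

## Introner-element signatures

Introns are extracted in transcription order (minus-strand introns
reverse-complemented).  The de novo scan looks for arm pairs with the
5′ arm starting within `end_window` (30 nt) of the intron start and the
3′ arm ending within `end_window` of the intron end, equal to the
reverse complement of the 5′ arm (inverted) or to the arm itself
(direct) under a Hamming budget (`max_mismatch`, default 0; no indels).
Arms are extended maximally and the longest arm per intron is reported.
Defaults (minimum arm 6 nt inverted / 4 nt direct, window 30 nt) are
package choices exposed in the configuration; a user-supplied motif
FASTA can additionally be matched per intron
(`repeat_type = "reference_motif"`).

# Synthetic data: what it emulates and what it does not

* `make_genome_pair()` draws an i.i.d. ancestor at a chosen GC content
  and applies Bernoulli substitutions (uniform alternatives), optional
  segment inversions (1–5 % of genome length each), then
  geometric-length indels; every event is logged.  It emulates neutral
  sequence drift, not repeat landscapes, GC isochores or chromosome-
  scale rearrangement processes — so alignment statistics on real
  repeat-rich assemblies will be harder than the tests imply.
* `plant_gene_landscape()` builds scaffolds of spacer-separated genes
  (random in-frame CDS of 100–300 codons, 2–3 exons unless allocated
  single-exon; exactly `round(fraction × n)` single-exon genes) and
  plants tandem, proximal and dispersed duplicate pairs plus an
  optional whole-scaffold duplication with 10 % gene loss.  The
  homology table is emitted directly with perfect hits so synteny tests
  do not depend on a search tool.  All genes are on the plus strand;
  strand handling is exercised separately by the intron tests.
* `evolve_codon_pair()` evolves a stop-free CDS by proposal/acceptance:
  synonymous proposals accepted with probability 1 and nonsynonymous
  with probability ω (roles inverted and scaled by 1/ω for ω > 1),
  stopping when realised synonymous substitutions per synonymous site
  reach the Ks target.  This gives exact control of the realised ω at
  desk scale without rate-matrix exponentials.  It is approximate for
  ω > 1: stop-codon rejection and multiple hits at the same site bias
  the recovered ω slightly downward (about 1.6 recovered at a true 2.0
  under the standard settings), within the ±25 % recovery band the
  package tests.
* `insert_introner()` plants arm–spacer–arm elements at an intron's 5′
  end.  For the default 30 nt scan window to see both arms, the host
  intron should be shorter than the window (or the scan run with a
  wider window); the tests scan with the window set to the intron
  length.
* `simulate_similarity_graph()` builds two-isolate graphs from
  four-protein families whose cross-isolate edges are weaker than
  within-isolate edges by a family-specific factor, so families split
  into isolate-specific halves at family-specific inflation values —
  the regime in which the isolate-specific fraction grows with
  inflation.

All generators are bit-reproducible from their parameters and seed.

# Numerical and design choices

* k-mers are packed into IEEE doubles (exact to 2^53), so k ≤ 26;
  the default k = 23 needs 2^46 of that range.  Counting is exact —
  no probabilistic sketches.
* The D2S sum runs over observed words only.  This is what makes k = 23
  tractable, and it is also the defining convention: never-observed
  words are assigned zero centred counts, so adding them changes
  nothing.  The brute-force oracle in the test suite loops over all
  4^k words under the same convention.
* Chaining forbids coordinate overlap between consecutive anchors;
  ties in chain score resolve to the chain found first in reference
  order.  Gap closing uses exact dynamic programming (via Biostrings)
  rather than a banded approximation; at the ≤ 90 bp gaps involved the
  difference is only speed, and equal-length gaps — the vast majority
  under substitution-dominated divergence — bypass the aligner
  entirely.
* MCL is deterministic for a fixed node order; nodes are sorted
  lexicographically on construction.
* Degenerate inputs: empty k-mer profiles (k longer than every
  scaffold) warn and propagate as empty; zero-length introns are
  skipped with a warning; an empty homology table yields all-singleton
  labels, no TD blocks and an edgeless graph; non-positive normalised
  similarity gives d = +Inf with a warning.
* Pipeline outputs are plain TSVs stamped with a hash of the
  configuration (paths reduced to basenames) and written
  write-then-rename, so a rerun with the same seed is byte-identical
  and an interrupted run leaves no truncated tables.

# Problem sizes in the test suite

The package's own checks run the aligner and k-mer statistics on
500 kb genome pairs, the duplication classifier on landscapes of about
590 genes over six scaffolds, ω recovery on 100 replicate codon pairs
of 300 codons per ω value, and Markov clustering on graphs of about a
hundred proteins.  These sizes keep the full suite within a few minutes
on one CPU while leaving every statistic in a regime where its expected
value is known analytically or by construction.

# Known limitations

* The aligner targets desk-scale genomes (up to a few Mb); real
  multi-Gbp assemblies should be aligned externally and imported as
  coordinate tables.
* MUM uniqueness is approximated at the seed level; in highly repetitive
  regions anchors may be missed where every seed of an exact match
  repeats elsewhere.
* The published distance scale of the statistic depends on the exact
  normalisation of the reference implementation; before comparing d
  values against externally published numbers, verify the
  normalisation and canonical-counting conventions match.
* ω recovery for ω > 1 is modestly biased downward (see above).
* Orthogroup inference is plain MCL, documented as an approximation of
  full orthology pipelines; absolute isolate-specific percentages are
  not comparable to theirs, though the inflation trend is.
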