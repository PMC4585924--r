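---
title: "Comparing reduced plastid genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing reduced plastid genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidcomp)
```

## The scientific problem

Loss of photosynthesis has evolved repeatedly in plants and algae, yet
almost all non-photosynthetic lineages retain a plastid with a reduced
genome. Pairs of closely related photosynthetic and heterotrophic algae are
natural experiments for studying this transition: their plastomes can be
compared gene by gene to ask what was lost, how the deletions happened,
and how recently the lineages diverged. `plastidcomp` implements the full
comparative toolkit for such a pair of circular, AT-rich, highly compact
plastomes:

1. **Compactness statistics** — genome size, A+T/G+C content, the fraction
   of positions covered by no annotated gene, the mean length of maximal
   intergenic gaps on the circle, gene counts by type, and detection of a
   large inverted repeat (IR).
2. **Gene content** — set algebra on normalized gene names, with losses
   resolved by functional category.
3. **Gene order (synteny)** — signed circular permutations of shared genes,
   conserved adjacencies, collinear blocks and breakpoint distance.
4. **Deletion breakpoints** — maximal runs of reference genes missing from
   the reduced genome, and the AT content and tRNA adjacency of the fused
   junctions.
5. **Molecular evolution** — protein-guided codon alignment, Nei–Gojobori
   (1986) counting of synonymous/non-synonymous substitutions with
   Jukes–Cantor correction, and a generation-time molecular clock.
6. **A simulator** that evolves genome pairs with *known* divergence,
   deletions and inversions, so that every stage above is testable without
   downloading anything.

## Representation and conventions

Genomes are `annotated_genome` objects: a nucleotide string plus a feature
table. Coordinates are 0-based half-open on the circle; a feature whose end
does not exceed its start wraps through the origin and carries a `wrap`
flag, and `feature_seq()` is the single place that linearizes it. GenBank's
1-based inclusive locations (including origin-spanning `join(a..L,1..b)`)
are converted at the file boundary.

Gene identity across genomes is the *normalized name*: symbols are
case-folded to the organelle convention (`atpI`, `rpl12`, `rpoC1`), a
curated synonym table maps verbose products (e.g. "16S ribosomal RNA" to
`rrs`), and tRNAs are rendered as one-letter amino-acid code plus anticodon
in the RNA alphabet — `trnL(GAG)` and `trnL(UAG)` are different genes, which
matters because isoacceptor losses are part of the biology of plastome
reduction. All protein work uses translation table 11 (bacterial/plastid).

Nine functional categories (photosynthesis, ATP synthase, cytochrome,
ribosomal protein, RNA polymerase, rRNA, tRNA, other conserved,
ORF/unknown) are assigned from the name prefix, mirroring the color groups
conventionally used on plastome maps.

## Compactness statistics

Non-coding percentage uses the **union** of all annotated gene features:
overlapping genes are counted once. Published tables rarely state their
overlap rule; the union is the conservative reading and keeps the invariant
that adding a feature can never increase the non-coding fraction. Mean
intergenic distance is defined here as total uncovered length divided by
the number of *maximal* uncovered runs on the circle. Published values of
this quantity depend on an unstated gap-count convention (e.g. whether
zero-length gaps between abutting genes count), so the package reports the
metric under its own stated definition rather than attempting to reproduce
any particular table cell; the identity
`mean_intergenic_bp * n_gaps = uncovered length` is asserted exactly in the
tests.

IR detection is exact-seed (k = 25) and extension: any reverse-complement
repeat pair with arms of at least `min_len` (default 1000 bp, the scale of
the canonical plastid IR) contains a full seed, so the scan cannot miss
one; self-overlapping palindromic hits are excluded. Only the longest arm
pair is reported, matching how genome tables quote a single IR size.

## Synteny statistics

Shared genes (protein-coding and rRNA by default; tRNAs can be included
but are conventionally excluded from gene-order comparisons) are read
around each circle as a signed permutation. A **conserved adjacency** is a
pair of genes adjacent on both circles; the count is orientation-blind,
which makes it invariant under rotation and reflection of either genome by
construction and gives the clean null expectation below. Orientation is
not discarded: the reported `orientation_agreement` is the fraction of
shared genes transcribed in the same relative direction under the better
of the two readings of the second genome, and collinear blocks are maximal
chains of conserved adjacencies. On a circle, blocks and breakpoints
alternate, so `n_blocks` equals the breakpoint distance
(`n_shared - conserved_adjacencies`) whenever the circles differ.

For a uniformly random signed circular permutation of *n* genes, a given
pair is adjacent with probability 2/(n−1), so the null expectation of the
adjacency fraction is 2/(n−1); the test suite checks the Monte-Carlo mean
against this closed form. Genome-rearrangement edit distances (DCJ,
inversion distance) are out of scope: the adjacency/breakpoint statistics
are descriptive.

## Deletion breakpoints

Walking the reference circle (tRNAs included here, because lost tRNAs
participate in deletion runs), maximal runs of genes absent from the
reduced genome become breakpoint regions. Abutting runs merge by
construction — a "flank" that is itself missing simply extends the run.
Each region records its retained flanks, the reference span from the end
of the left flank to the start of the right flank (which therefore bounds
the summed length of the missing genes from above), and the junction: the
intergenic interval between the two flanks in the reduced genome, extended
symmetrically into the flanks to a minimum window of 100 bp when the gap
is shorter. The 100 bp default matches the windowing used for identity
profiles; it is a parameter, not a finding. tRNA adjacency is scored if
*either* flank is a tRNA — the weakest reading of "adjacent to a tRNA
gene". Junction similarity is screened with global alignment identity
(threshold 0.70 over at least 30 bp); local alignment was deliberately
avoided because AT-rich windows produce high-identity local matches by
chance, which would make the "no shared sequence" null untestable.

## Ks/Ka estimation

Each shared protein gene is aligned via its translation (BLOSUM62, gap
open 11 / extend 1) and the protein alignment is back-translated, so gaps
only occur in whole-codon units; genes with internal stops are rejected.
The estimator is the Nei–Gojobori (1986) counting method: per codon
position, the three single-nucleotide neighbours are enumerated and the
synonymous fraction taken over non-stop neighbours, so each position
contributes exactly one site and `S + N = 3 × codons`; differences between
codons are averaged over all minimal substitution pathways, excluding
pathways through stops (under table 11 no sense-codon pair loses *all* of
its pathways, but if that were to occur the implementation falls back to
averaging over all pathways). The proportions are corrected with
Jukes–Cantor, `d = -3/4 ln(1 - 4p/3)`; at `p >= 3/4` the distance is
undefined and the gene is flagged saturated. A flag is also set when a
defined Ks reaches 1 — the conventional caution threshold — but such genes
still enter `mean_ks()`, which excludes only genes whose correction is
undefined. The default average is the unweighted per-gene mean; a
synonymous-site-weighted mean is available.

The choice of a counting estimator (rather than a
transition/transversion- and codon-usage-corrected one such as the
Yang–Nielsen 2000 method, or a maximum-likelihood codon model) is
deliberate: the counting method is fully specifiable and can be verified
against an exhaustive enumeration oracle on all 61 × 61 sense-codon pairs,
which the test suite does exactly. Estimates from different counting
corrections typically differ by several percent at these divergences, and
that spread should be kept in mind when comparing against values computed
with other software.

## The generation clock

`divergence_time()` converts a mean synonymous distance into generations,
`n = Ks / mu`, and into years via lifestyle-specific generation times. The
defaults are the measured per-generation nuclear substitution rate of a
unicellular green alga, `mu = 3.23e-10` (applied to the plastid on the
common observation that green-algal plastid and nuclear rates are
similar), and generation times of 24 h (0.00274 y, heterotrophic growth)
and 72 h (0.008219 y, photoautotrophic growth). The convention divides by
`mu`, not `2 mu`: the quantity is the number of generations separating the
two genomes along the whole path through their common ancestor. Whether
that total should be split across the two descendant lineages is an
interpretive choice, surfaced as the `per_lineage` flag (default off,
matching the convention above). With Ks = 0.816 these inputs give
2.53 × 10⁹ generations and a window of about 6.9–20.8 million years:

```{r clock}
divergence_time(0.816)
```

## The simulator

`generate_ancestor()` assembles a circular gene–spacer alternation from
configured per-category gene counts. Defaults emulate a compact reduced
plastome: 98 genes across the nine categories, protein genes of 100–500
codons drawn as stop-free AT-biased codon strings, rRNAs of realistic
lengths (1480/2890/120 bp), tRNAs of 72–90 bp, spacers of 60–300 bp at AT
fraction 0.85, and a plus-strand bias of 0.8 (reduced plastomes show
strongly asymmetric transcription). The resulting genomes fall at 60–75%
AT overall, the range typical of these genomes.

`evolve()` drives each protein gene toward a target divergence by
proposing random single-nucleotide codon changes (stop-creating proposals
rejected, start codon frozen) and tracking the *realized* NG86-counted
divergence incrementally from precomputed codon tables; proposals of a
class whose target is already met are rejected, and the gene stops at the
first crossing, so the realized value overshoots the target by at most one
substitution. `simulate_pair()` places half the divergence on branch A and
then evolves branch B until its realized divergence *against A* reaches
the configured value, so the pairwise Ks of the emitted pair sits at the
target rather than drifting with multiple-hit effects across branches.
Structural RNAs and spacers evolve by per-site substitution at rates
scaled from the target (defaults 0.1× for tRNA/rRNA, 1.5× for spacers),
reproducing the empirical conservation ranking: structural RNAs most
conserved, then proteins, then intergenic/upstream sequence.

Deletions remove configured runs of consecutive genes plus their internal
spacers and fuse the flanks with a freshly drawn junction spacer of
120–200 bp at AT fraction 0.9 — the designed analog of the very AT-rich
junctions (>85%) observed at real deletion breakpoints, and the basis for
the junction-AT expectation in the acceptance checks. Inversions
reverse-complement a run in place. The recorded truth (per-gene realized
Ks/Ka, deletion runs with junction coordinates, inversion boundaries) is
an exact recomputation on the true column correspondence, not the target,
so estimator tests measure estimation error only, never the proposal
loop's targeting error.

What the simulator deliberately does **not** model: indels within genes
(so protein-guided alignments are exactly recoverable — alignment
robustness to coding indels is untested), rate heterogeneity among sites
and genes beyond the class-level scaling, codon-usage selection,
recombination, and realistic rRNA/tRNA secondary structure. Passing tests
on simulated data therefore validate the *counting and bookkeeping* of the
estimators, not their robustness to every feature of real sequence data.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the scale the
analyses are designed for: the study fixture is a 39-gene reference
(~30 kb) with 12 photosynthesis genes deleted in 6 runs at pairwise
Ks ≈ 0.8; parameter recovery uses 50 replicate pairs of 30 genes of
300–400 codons at realized Ks 0.1/0.4/0.8; breakpoint recovery uses
fixtures with 5, 9 and 17 planted runs; the synteny null uses 1000 random
signed circular permutations of 50 genes. Floating-point output in TSV
files is fixed at 4 significant digits (full precision in JSON) so reruns
are byte-identical. All randomness flows from a single integer seed per
simulation; the generator state is R's default integer-state RNG, so
results are reproducible across platforms.

## Known limitations

* Orthology is by normalized gene name only; paralog confusion and
  annotation disagreements between genomes are not detected.
* The %ncDNA and mean-intergenic definitions may differ from any given
  published table's unstated conventions; comparisons across publications
  should re-derive both from the annotations with one shared rule.
* The NG86 estimator ignores transition/transversion bias and codon usage;
  at Ks near 1 this can bias distances by several percent relative to
  richer estimators.
* Divergence times inherit the full uncertainty of the per-generation rate
  and of the generation times themselves; the reported low/high window
  spans only the generation-time range, not rate uncertainty.
* Multi-exon (`join`) features that are not origin-spanning are collapsed
  to their outer span; the target genomes are intron-free, so this only
  matters if the package is pointed at intron-containing plastomes.
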