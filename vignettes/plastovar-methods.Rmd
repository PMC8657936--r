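---
title: "Comparative plastome variant analysis with plastovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome variant analysis with plastovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastovar)
```

## The problem

Chloroplast genomes (plastomes) are small circular molecules — roughly
130–160 kb in grasses — inherited uniparentally, which makes them the
marker of choice for maternal-lineage genealogy in crops. Within a
species, plastomes from different accessions are nearly identical
(~99.9%), so the analytically interesting object is not the alignment
itself but the short list of differences it exposes: SNPs, small indels
dominated by mononucleotide (homopolymer) run-length changes, tandem
duplications, and a class of small inversions mediated by hairpin
(stem-loop) structures. Hexaploid wheat is the motivating system: twenty
accessions compared against the Chinese Spring plastome, with the SNP
table partitioning the cohort into a major free-threshing-like lineage
and a minor spelta-like lineage, complemented by in-silico PCR
haplotyping of the nuclear *Wknox1* loci, where presence or absence of
MITE-sized insertions shifts gel band sizes.

`plastovar` implements that entire analysis as testable code: a
deterministic synthetic-plastome generator with truth tables, an
anchor-based pairwise aligner for near-identical genomes, a variant
classifier with locus and amino-acid annotation, multi-sample haplotype
matrices with distance-based grouping and neighbor-joining trees, and an
amplicon predictor for primer pairs. The packaged transcription of the
published 34-site × 20-sample wheat SNP table and the printed marker
sequences make the published quantities reproducible without any
download.

## Alignment model

Two near-identical sequences are aligned in three steps.

1. **Anchoring.** All k-mers (default k = 21) occurring exactly once in
   both sequences are matched, merged along diagonals, and extended
   outward to maximal exact matches. Uniqueness on both sides suppresses
   seeds inside repeats.
2. **Chaining.** A maximum-weight strictly co-linear chain (weight =
   anchor length) is selected by dynamic programming with a
   deterministic tie-break (earliest reference start). Overlaps between
   neighbouring chained anchors — a by-product of maximal extension over,
   e.g., a shared homopolymer run — are trimmed from the head of the later
   anchor, which preserves exactness.
3. **Interstices.** The short segments between consecutive anchors are
   aligned globally with affine gap scores (match +1, mismatch −2, gap
   open −4, gap extend −1; a gap of length L costs −4 − L). Ties prefer a
   diagonal step over a gap and a gap in the query over a gap in the
   reference, so output is reproducible bit for bit.

The result is a tiling of both sequences into `match` and `divergent`
blocks, where divergent blocks are maximal runs of non-match columns.
The scores only matter inside interstices of a few dozen bases; the
defaults were chosen once for that regime and are exposed through
`align_params()` for other uses. Interstices are capped (default 20 kb)
with an error advising a larger k, since a cap-sized dynamic program
signals mis-anchoring rather than a real use case.

Circularity is handled by rotation normalization: the query is rotated so
that its longest exact match to the leading reference k-mer lands at the
corresponding reference coordinate (`rotate_circular()`), after which the
alignment is linear. This matches the convention of reporting positions
on a fixed linearization of the reference, and avoids doubled-genome
alignment.

## Variant classification

Each divergent block yields exactly one call, with precedence
inversion → duplication → homopolymer → insertion/deletion → SNP:

* **Inversions.** A flipped stem-loop differs from the reference only
  where the loop differs from its own reverse complement; the stems,
  being reverse complements of each other, realign perfectly. The
  observable signal is therefore a short divergent patch (possibly
  several patches, or even cancelling insertion/deletion pairs when the
  gapped alignment outscores a mismatch run). `detect_inversion()`
  extends a length-balanced cluster of divergent blocks symmetrically to
  the *maximal* window W with query(W) = revcomp(reference(W)), bounded
  by neighbouring indels and a window cap (default 200 bp, comfortably
  above the 25–58 bp published cases). Maximal extension is what
  reproduces the published stem-to-stem extents. A window must cover at
  least two mismatching columns: an isolated transversion SNP is a 1-bp
  reverse-complement-consistent window and must not be promoted.
  `characterize_hairpin()` then reports the decomposition; the stem is
  the longest prefix equal to the reverse complement of the suffix, so
  2·stem + loop = window length by construction.
* **Homopolymer run changes.** Indels are first left-normalized
  (`left_normalize_indel()`) to their leftmost equivalent placement. A
  pure indel of one repeated base lying wholly within a reference run of
  that base of length ≥ 5 is reported in run notation ("15T" → "18T") at
  the run start. The published runs are all ≥ 8; 5 is a deliberately
  conservative cutoff below which an indel is reported plainly.
* **Tandem duplications.** A pure insertion whose left-normalized payload
  equals the immediately adjacent reference segment on either side is a
  duplication. Mononucleotide payloads are excluded from this rule —
  formally a +3T run change *is* a duplication of TTT, but run notation
  is the established reporting convention for that class, and the
  precedence order would otherwise never let the homopolymer caller
  fire.
* **Complex blocks.** A block that both substitutes and changes length is
  decomposed into paired deletion + insertion records flagged
  `complex`; the wheat data contain no such case.

Annotation places each call as "Gene X" (inside a CDS), "Intron X"
(inside a gene, between its CDS parts), or "Intergenic A-B" (nearest
flanking genes, wrapping around circular genomes). Coding SNPs are
translated on the coding strand — concatenating CDS parts in
transcription order and reverse-complementing for minus-strand genes —
with the standard genetic code, which is also the bacterial/plastid code
for all codons that matter here; the label is "Syn" or the one-letter
pair such as "Q-K". A CDS whose length is not a multiple of three is an
error, not a silent skip.

## Haplotype matrix, grouping and trees

`build_matrix()` joins per-sample calls on reference coordinates; samples
lacking a call at a site carry the reference state, and conflicting
reference alleles across samples are an error. `tally_by_context()`
counts sites (not sample occurrences) by locus class; on the packaged
wheat table it returns 22 intergenic, 2 intronic and 10 genic sites of
which 7 are synonymous. Distances are Hamming counts over SNP sites by
default (indel and inversion sites can be included by flag, but the
published grouping statements rest on the SNP table). Grouping uses
complete-linkage hierarchical clustering — preferred over single linkage
because chaining could dissolve the small 4-sample lineage — applied to
samples in lexicographic order so that the result is invariant under
input permutation.

Trees are built by a hand-implemented canonical neighbor joining, since
the grouping claim is about an unrooted bipartition and NJ is consistent
on additive matrices. Tie-breaks (smallest Q, then lexicographically
smallest name pair) and the negative-branch policy (clamp to zero,
moving the deficit to the sibling so cherry path lengths are preserved)
are fixed for reproducibility. UPGMA is available behind a flag for
comparison. The published figure names no method; only the 16/4
bipartition is treated as reproducible, and group membership is asserted
by allele pattern, not by sample name.

## In-silico PCR

`find_sites()` scans both orientations for primer matches with a
configurable mismatch budget and a 3'-clamp that must match exactly
(defaults: 0 mismatches, 3-base clamp — no thermodynamic model is
implied). Every forward site paired with a downstream reverse site
within 3 kb yields a product whose length includes both primer
footprints. `band_table()` collapses product lengths within ±2 bp, a
coarse model of agarose-gel resolution. Real *Wknox1* genomic sequences
are not reconstructed: fixtures are synthetic templates sized so that
the band arithmetic is exercised, and the printed 42-bp insertion is the
single quantitative anchor (published band sizes for the MITE alleles
are not internally consistent, so they are not asserted).

## The synthetic-data generator

`make_reference()` emulates the features of a plastome that this
pipeline is sensitive to: an AT-rich (62%) random sequence carrying
non-overlapping protein-coding genes on both strands (one intron-bearing),
mononucleotide runs of length 8–15 with distinct flanking bases, and
stem-loop windows with perfect stems of 8–14 bp and loops of 3–14 bp.
Embedded windows are constructed to be *detectable and exact*: the loop
differs from its own reverse complement at two or more positions, the
stem does not extend into the loop, and the bases just outside the
window do not extend it — so the planted window is precisely the maximal
window the classifier should report. `sample_variant_specs()` plants
variants with ≥ 50 bp spacing and rejection-samples placements whose
canonical (left-normalized) call would differ from the planted
coordinates, or which would be legitimately re-classified (mononucleotide
insertion next to a run, duplication beside a pre-existing tandem copy).

These constraints define what the recovery tests do and do not show.
They show that alignment, normalization and classification are exact on
isolated, well-separated variants of every class in realistic sequence
composition, at the published density (~30 variants per 30 kb is an
order of magnitude above the real inter-accession distances). They do
not exercise overlapping variants, heteroplasmy, inverted-repeat
expansion, sequencing error, or assembly artefacts — real-data phenomena
that are upstream of this package's scope. The default study conditions
(30 kb genomes; 20 SNPs, 2 insertions, 1 deletion, 2 homopolymer
changes, 1 duplication, 2 inversions; 10 seeds) keep the full recovery
suite under a minute on one CPU; genome length only changes anchor
bookkeeping, not the per-variant logic.

## Numerical and degenerate-input choices

* All coordinates are 1-based and inclusive on the reference; insertions
  are anchored to the base they follow, matching tables that give a
  single position per insertion. Whether such a position means "base
  before" or "first inserted base" is not stated in the source tables;
  the former is this package's convention.
* The generator alphabet is uppercase ACGT with no ambiguity codes, so
  reverse-complement identities in tests are exact.
* Empty inputs are defined: an empty spec list is the identity, identical
  genomes classify to a zero-row table, an empty matrix tallies to
  zeros.
* Determinism everywhere: one seed drives each simulation; alignment,
  clustering and NJ tie-breaks are fixed; repeated runs are
  byte-identical.

## Worked example

```{r, eval = FALSE}
g <- make_reference(30000, n_genes = 10, homopolymer_runs = 5,
                    palindromes = 3, seed = 1)
specs <- sample_variant_specs(g, seed = 2)
qry <- apply_variants(g, specs)$query
map <- whole_genome_align(g$seq, qry)
calls <- classify_all(map, g, sample_name = "sim1")
table(calls$kind)

m <- paper_table4_matrix()
tally_by_context(m)          # 22 / 2 / 10, 7 synonymous
partition_samples(m, 2)      # 16 samples + 4 samples
tree <- build_tree(m)
has_bipartition(tree, c("Splt1", "Splt2", "Splt3", "Vav2"))
```

## Known limitations

Beyond the generator caveats above: the aligner assumes co-linearity and
will not represent large rearrangements or inverted-repeat
expansion/contraction; multi-sample analysis is strictly per-query
against one reference joined on reference coordinates; bootstrap or
model-based phylogenetics are out of scope; and the PCR model is purely
combinatorial (no melting temperatures, efficiencies or multiplex
artefacts).
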