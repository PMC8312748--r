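---
title: "Designing and optimizing target-enrichment probe sets in duplicated genomes"
author: "probeforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and optimizing target-enrichment probe sets in duplicated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeforge)
```

## The problem

Hybrid-capture phylogenomics in a clade with a shared whole-genome
duplication (WGD) has to contend with paralogy at every locus. A custom
probe set for such a group targets two kinds of loci: apparently
single-copy genes (often hidden paralogs after reciprocal one-duplicate
loss) and genes duplicated exactly once, where the pair is divergent
enough to be disentangled during assembly. The design regime this package
implements is built around three empirical anchors for an apple-tribe-like
system: orthologs between closely related genera differ by about 3.65% on
average, orthologs to the outgroup tribe by about 9.4%, and paralogs from
the most recent WGD by roughly 8%. A 6% floor on paralog divergence
separates the two distributions; a 15% ceiling on cross-genome ortholog
divergence keeps capture feasible.

## The locus-discovery cascade

`design_probe_set()` orchestrates the per-genome cascade
(`run_design_cascade()`) and the two-genome validation
(`cross_genome_validate()`). The stages, with their boundary semantics:

1. **Similarity search.** Query transcripts against the genome, E &le;
   1e-5. Hits may come from any BLAST outfmt-6 table
   (`read_hit_table()`) or from the built-in engine (below).
2. **Initial hit filter** — keep hits whose alignment length *exceeds*
   70 bp (strict) and *exceeds* 10% of the query length (strict), at
   percent identity &ge; 80 (inclusive). Hits wholly contained in a longer
   hit of the same pair are dropped.
3. **Clustering** — per (query, subject, strand), sorted by subject
   position, a new locus starts when the inter-hit gap exceeds 10,000 bp
   (a gap of exactly 10,000 joins). Queries with more than 6 loci are
   discarded.
4. **Refined filter** — per locus: merged query coverage &ge; 90%,
   alignment-length-weighted identity &ge; 90, every hit &ge; 100 bp (the
   bait length), every inter-hit subject gap &le; 1200 bp. Queries with
   more than 2 surviving loci are discarded. We apply the locus-count rule
   to the loci that survive the refined criteria (the alternative —
   counting before filtering — differs only for queries carrying spurious
   extra clusters, which the thresholds above make vanishingly rare).
5. **Inter-locus divergence** — two-locus queries are kept only when the
   exon concatenations of the two loci diverge by &ge; 6%. Divergence is
   measured on exon concatenations, not full loci: the cross-genome
   criterion is explicitly exonic, and the intra-genome criterion is read
   the same way.
6. **Cross-genome validation** — a query must survive the full cascade in
   both genomes with identical locus counts; single-copy loci must have
   exon divergence &le; 15% between the genomes (paralog pairs are paired
   across genomes by minimal divergence). Exons shorter than 80 bp are
   excluded from the targets; a locus survives only if an exon remains.
   We drop the exon rather than the whole locus because the alternative
   would discard otherwise qualifying multi-exon loci for one marginal
   exon; the audit table records the exclusion either way.
7. **Target emission** — full loci (exons + introns) are extracted,
   minus-strand loci reverse-complemented; introns &ge; 80 bp become
   intron targets; extracted sequences are collapsed greedily at &ge; 95%
   identity (longest first, identity computed over the shorter sequence).
   The collapse runs within each genome, not across genomes: orthologs of
   closely related genomes typically exceed 95% identity, and collapsing
   across genomes would defeat the purpose of carrying one representative
   per genome.

Every elimination is logged as (query, stage, verdict, criterion) in an
audit table, so the provenance of the final set is inspectable. Because
several criteria overlap (a 79-bp single-exon locus violates both the
100-bp hit rule and the 80-bp exon rule, and a 20%-diverged ortholog
usually dies at the second genome's 90% identity rule before the 15%
rule), the audit records the stage that actually eliminated a candidate.

## The alignment engine

The engine (`local_search()`) performs repeated exact Smith-Waterman
alignment with affine gaps — match +2, mismatch -3, a gap of length k
costs 5 + 2k (BLASTN-like) — masking each reported subject interval
before the next pass, until the best remaining score falls below the
threshold implied by the E-value cutoff (Karlin-Altschul with K = 0.41,
lambda = 0.625; the constants are approximate and raw-score thresholds
are preferred in all exact work). Minus-strand hits are reported with
descending subject coordinates, as in BLAST tabular output.

Determinism requires pinned tie-breaks, which the package declares and
tests: the best cell is the first maximum in a row-major scan; traceback
prefers a diagonal step, then the query-consuming gap state, then the
subject-consuming one; closing a gap beats extending it on ties. The test
suite re-implements the same conventions in an independent plain-R
dynamic program and requires identical hit sets, coordinates and scores.

For genome-scale subjects, exhaustive DP is wasteful; windows around
shared 11-mers whose ungapped diagonal extension reaches a minimum score
restrict the DP, and below two million cells the engine always scans
exhaustively, so every small instance is exact. E-values are monotone in
construction: raising the threshold only truncates the masking loop, so
lowering `e_value_max` never adds hits.

## Reference optimization

`build_optimized_references()` reduces a multi-representative universal
probe set to one sequence per locus, optimized toward one or more focal
annotated genomes. Exons are extracted and concatenated into transcripts
(`extract_exon_transcripts()`) including protein-coding genes, long
non-coding RNAs and pseudogenes (transcribed ones included) but excluding
all other RNA classes and organellar sequences; annotations without
transcript children are treated as one implicit transcript per gene, and
genes with several transcripts yield several models. Representatives are
searched against the transcripts and, per locus, the *longest* hit (ties:
higher bit score, then lexicographic id) selects both the winning
representative and the best matching transcript — across genomes, the
globally longest hit wins. The chosen transcript is split into exons, the
exons searched back against the winning representative, only the top hit
per exon kept, and both sides trimmed to the hit bounds and concatenated
co-directionally (minus-orientation exon segments are
reverse-complemented). Trimmed segments are concatenated without
separators. The "bestHit" side (trimmed representative) is a fixpoint
under re-optimization against an unchanged genome, which the tests
assert.

## Recovery and alignment statistics

`threshold_summary()` counts, for each pair of a target-length threshold
L in {0.25, 0.50, 0.75} and an accessions-presence threshold P in
{0.50, 0.75}, the loci for which the proportion of samples recovering at
least L of the target length is at least P. Presence is evaluated
*jointly* at the same L — the only reading under which the six grid cells
differ in both axes; the any-data reading is available via
`joint = FALSE`. Per-locus target lengths of multi-representative loci
are the arithmetic mean of the representative lengths. Recovered
fractions are capped at 1 (assembled contigs can exceed the reference).
The grid is monotone non-increasing in both axes, asserted in the tests
against a brute-force double loop.

`trim_alignment()` removes rows (taxa) with more than 30% missing data
(on the original columns), then columns with more than 30% missing data
with respect to the retained rows — exactly one pass each, deliberately
order-dependent and *not* iterated to a fixpoint: after column removal a
retained row can again exceed 30%, and the test suite contains a
constructed witness of the order dependence. Missing symbols are `-`,
`?`, `N`; other IUPAC ambiguities count as data for the missing-fraction
computation but are ignored in site classification (a conservative,
AMAS-compatible choice). A column is parsimony-informative when at least
two states each occur in at least two sequences; constant, singleton and
informative columns partition the alignment length. Proportions are kept
at full precision internally and rounded only in reports.

## The synthetic-data generator

`simulate_genome_pair()` emulates the inputs of the design study: an
annotated genome with planted loci, an ortholog genome derived from it,
and exon-concatenation queries. Choices that matter:

* **Structure.** Loci have 2-4 exons of 150-300 bp and introns of
  350-800 bp, separated by 400-1200 bp of neutral intergenic DNA on four
  chromosomes; copies of the same query are placed on distinct
  (chromosome, strand) slots so that hits of different copies can never
  fall within one clustering gap. The intron floor is *validated* to
  exceed the exon ceiling: an affine gap across the shortest intron
  (5 + 2 x 350 = 705) must cost more than the longest exon can score
  (2 x 300 = 600), otherwise an exact local aligner would merge adjacent
  exon hits across short introns into one low-identity hit — an artifact
  a heuristic X-drop aligner never produces, and one that would break the
  generator's own one-hit-per-exon invariant.
* **Substitutions.** Planted divergences are realized as an exact count
  of substituted sites per exon/intron segment (round(d x length), each
  to a different base, no indels), so the truth table's verdicts at the
  6% and 15% thresholds are mechanically crisp; binomial scatter would
  otherwise blur the planted side of a boundary. The uniform-rate
  `evolve_ortholog_genome()` operation keeps per-site Bernoulli
  substitutions for uses where crispness is irrelevant.
* **Rate heterogeneity.** The mean ortholog divergence is 3.65%, but the
  per-locus rates are heterogeneous: paralog-pair loci evolve at 1.5%,
  single-copy loci at 5.1% (mean across the default 12 + 4 x 2 loci:
  3.66%). This is not cosmetic: with the refined filter demanding &ge; 90%
  identity in the second genome, a paralog pair at &ge; 6% divergence has
  an identity budget of barely 10% - 6% = 4% for its ortholog divergence;
  at a uniform 3.65% no pair could robustly survive, while heterogeneous
  rates — a real feature of genomes — let pairs with slowly evolving
  orthologs pass, exactly the loci a designer would recover. Paralog
  pairs are planted at 6.8-7.8% divergence, comfortably above the 6%
  floor yet leaving identity margin in the ortholog genome.
* **Decoys.** One planted locus per design criterion violates exactly
  that criterion: all-short exons (70-bp rule), many short exons on a
  long query (10% rule), a query mutated to 75% identity, a 10.5-kb
  intron (cluster gap), seven copies (initial count), a query with an
  extra unmatched tail (coverage), an 85-bp exon (100-bp hit rule), a
  1.5-kb intron, three copies (refined count), a 3% paralog pair
  (divergence floor), a 20% ortholog (cross-genome ceiling), and a 79-bp
  single exon; plus a four-copy multigene family. The truth table states
  each decoy's expected verdict and planted violation.

What passing tests on this generator do and do not show: the cascade's
thresholds, orderings and boundary conditions are exercised exactly, on
both strands, across annotation dialects — but the sequences are
composition-uniform, indel-free and repeat-free, so the tests say nothing
about repeat masking, assembly artifacts, alignment around indels, or
BLAST's heuristic deviations from exact alignment on real genomes.
Divergence estimates on real data would also sit slightly below the
planted substitution load because local alignments trim diverged ends.

## Numerical choices and problem sizes

All coordinates are 1-based inclusive (GFF3 convention). The engine uses
integer scores throughout; identity percentages are exact rationals
(matches / columns) kept in double precision. The test suite runs the
full cascade on ten generator seeds (about 30 queries against two
~120-kb genomes each), compares the engine against the brute-force DP
oracle on 200 random pairs up to 1 kb, the recovery grid against an
exhaustive double loop on fifty 20 x 50 matrices, the trimming and site
classification against exhaustive oracles on 100 alignments and 1000
columns, and verifies byte-exact reference reconstruction on a
five-locus universal set with three representatives each — sizes chosen
so the whole suite completes in a few minutes on one core while still
crossing every threshold from both sides.

## Known limitations

* The engine is exact, not a BLAST re-implementation: bit scores and
  E-values use fixed Karlin-Altschul constants, word seeding is used only
  as a window pre-filter, and no X-drop heuristics apply. External BLAST
  tables are consumed but never produced.
* Locus pairing across genomes uses minimal exon divergence; for pairs
  whose paralogs are more similar across genomes than within (unusual but
  possible after gene conversion) the pairing may differ from the true
  orthology.
* The 95% collapse is greedy in descending length order; like all greedy
  clusterings it is order-dependent, and membership (not the
  representative choice) is what the post-hoc identity test guarantees.
* Physical bait tiling, repeat masking, read mapping and assembly are out
  of scope; recovery statistics consume externally produced seq_lengths
  and read-count tables.
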