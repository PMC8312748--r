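# probeforge

Probe-set design and optimization for target enrichment in lineages shaped
by a whole-genome duplication (WGD).

Target enrichment (hybrid capture) pulls a chosen set of loci out of a
genomic library with biotinylated baits. Designing a *custom* probe set for
a plant group that went through a recent WGD — such as the apple subtribe
(Malinae, Rosaceae, x = 17) — means walking a narrow corridor: loci must be
either single-copy (possibly hidden paralogs after one-duplicate loss) or
duplicated exactly once, with the paralog pair divergent enough
(&ge; 6%) to separate during assembly, yet orthologs across related genera
(Malus/Pyrus-level divergence, ~3.65%) similar enough to capture. Universal
probe sets such as Angiosperms353 avoid the design work, but their
representatives can sit far from the focal clade; replacing them with the
best-matching orthologs from a close genome ("2ex"-style optimization)
improves locus recovery from the same raw reads.

`probeforge` implements both workflows and their downstream accounting as
one tested R package:

* **Locus-discovery cascade** (`design_probe_set()` and per-stage
  functions): BLAST-style hits of mRNA queries against a genome are
  filtered (hits must exceed 70 bp and 10% of the query length at &ge; 80%
  identity), clustered into loci (inter-hit gaps &le; 10 kb), screened
  (&le; 6 loci initially, summed coverage and identity &ge; 90%, single hits
  &ge; 100 bp, introns &le; 1200 bp, &le; 2 loci per query, inter-locus
  divergence &ge; 6%), validated against a second genome (equal locus
  counts, ortholog exon divergence &le; 15%, exons &ge; 80 bp), and emitted
  as exon/intron bait targets collapsed at &ge; 95% identity, with a full
  audit trail.
* **Built-in exact local aligner** (`local_search()`): repeated
  Smith-Waterman with affine gaps (match +2, mismatch -3, gap 5 + 2k) and
  masking of reported subject regions, word-seeded for genome-scale
  subjects, exact below a cell-count cutoff — so the whole pipeline runs
  without external binaries and is testable against a brute-force oracle.
* **Universal-reference optimization** (`build_optimized_references()`):
  per locus, the longest hit picks the best universal representative and
  its best matching annotated transcript; the transcript's exons are hit
  back against the representative, both sides trimmed to the hit bounds and
  concatenated — yielding a "bestHit" reference (trimmed original
  representative) and a "group-optimized" reference (focal-genome
  orthologs), one record per locus.
* **Recovery statistics** (`load_seq_lengths()`, `threshold_summary()`):
  HybPiper-style seq_lengths tables become sample x locus recovered-length
  fractions; the grid of locus counts at target-length thresholds
  {25, 50, 75}% and accessions-presence thresholds {50, 75}% summarizes
  data completeness, plus zero-data loci, enrichment efficiency and heatmap
  export.
* **Alignment statistics** (`trim_alignment()`, `batch_summary()`): the
  row-then-column 30% missing-data trim, the &lt; 4-sequence discard, and
  variable / parsimony-informative site counts with min/avg/max batch
  reports.
* **Synthetic data with truth tables** (`simulate_genome_pair()` and
  friends): annotated genome pairs with planted single-copy loci, paralog
  pairs at controlled divergence, one decoy per design criterion, decoy
  multigene families, plus recovery tables and alignment batches whose
  expected outcomes are computed mechanically — every module is testable
  offline.

## Worked example

```r
library(probeforge)

sim <- simulate_genome_pair(sim_config(seed = 42))
pts <- design_probe_set(sim$genome, sim$genome_b, sim$queries)
pts
#> probe_target_set: 40 loci from 16 queries; 24008 exonic bp

# the cascade retained exactly the planted truth set
setdiff(retained_queries(pts),
        sim$truth$query_id[sim$truth$expected_verdict == "retain"])
#> character(0)

# why was each decoy eliminated?
subset(pts$audit, query_id == "D_long_intron")
#>         query_id                stage       verdict              failing_criterion
#> 11 D_long_intron refined_locus_filter locus_dropped                 max_intron_len
#> 12 D_long_intron refined_locus_filter       dropped no_locus_passed_refined_filter
#> 13 D_long_intron refined_locus_filter locus_dropped                 max_intron_len
#> 14 D_long_intron refined_locus_filter       dropped no_locus_passed_refined_filter
```

(The decoy is evaluated — and eliminated — in each of the two genomes,
hence the two pairs of audit rows.)

The 16 retained queries are the 12 planted single-copy loci and 4 paralog
pairs (20 loci; 40 records across the two genomes); every decoy —
short hits, low identity, a 10.5-kb intron gap, seven-copy and three-copy
families, sub-6% paralog divergence, a 20%-diverged ortholog, a 79-bp
exon, and the rest — is eliminated at the stage its planted violation
predicts, which the audit table documents.

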