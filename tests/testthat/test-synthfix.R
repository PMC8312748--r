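small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_single_copy = 3L, n_paralog_pairs = 2L,
             decoys = c("short_hits", "low_paralog_divergence"),
             decoy_multigene_copies = 0L, ...)
}

test_that("the generator is byte-identical for the same seed", {
  a <- simulate_annotated_genome(small_cfg(7))
  b <- simulate_annotated_genome(small_cfg(7))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$features, b$features)
  expect_identical(as.character(a$queries), as.character(b$queries))
  expect_identical(a$truth, b$truth)

  c2 <- simulate_annotated_genome(small_cfg(8))
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))
})

test_that("truth table covers every planted query with a verdict", {
  sim <- simulate_annotated_genome(small_cfg(3))
  expect_setequal(sim$truth$query_id, names(sim$queries))
  expect_true(all(sim$truth$expected_verdict %in% c("retain", "drop")))
  expect_true(all(sim$truth$failing_criterion[sim$truth$expected_verdict ==
                                                "drop"] != ""))
  # without paralog pairs every qualifying locus is single copy
  cfg0 <- sim_config(seed = 4, n_single_copy = 4L, n_paralog_pairs = 0L,
                     decoys = character(), decoy_multigene_copies = 0L)
  sim0 <- simulate_annotated_genome(cfg0)
  expect_true(all(sim0$truth$expected_verdict == "retain"))
  expect_true(all(sim0$truth$copy_number == 1))
})

test_that("planted copies sit at their recorded coordinates", {
  sim <- simulate_annotated_genome(small_cfg(5))
  g <- as.character(sim$genome)
  # exon features of each copy substring back to the planted exon sequences
  ex <- sim$features[sim$features$feature_type == "exon", ]
  for (r in sample(nrow(ex), 5)) {
    seg <- substring(g[[ex$seq_id[r]]], ex$start[r], ex$end[r])
    expect_equal(nchar(seg), ex$end[r] - ex$start[r] + 1L)
    expect_false(grepl("[^ACGT]", seg))
  }
  # queries of unperturbed single-copy loci match the genome exon concat
  tx <- extract_exon_transcripts(sim$genome, sim$features)
  s1 <- tx$seq[tx$transcript_id == "mRNA:S01.c1"]
  expect_equal(s1, as.character(sim$queries[["S01"]]))
})

test_that("realized paralog divergence matches the alignment oracle", {
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, n_single_copy = 0L, n_paralog_pairs = 2L,
                      decoys = character(), decoy_multigene_copies = 0L)
    sim <- simulate_annotated_genome(cfg)
    tx <- extract_exon_transcripts(sim$genome, sim$features)
    for (q in sim$truth$query_id) {
      concats <- tx$seq[tx$transcript_id %in%
                          sprintf("mRNA:%s.c%d", q, 1:2)]
      d <- as.numeric(percent_divergence(concats[1], concats[2]))
      planted <- sim$truth$realized_divergence_pct[sim$truth$query_id == q]
      expect_lt(abs(d - planted), 0.8)
      expect_gte(planted, 100 * cfg$paralog_divergence_range[1] - 0.1)
    }
  }
})

test_that("ortholog evolution at rate zero is the identity", {
  sim <- simulate_annotated_genome(small_cfg(6))
  out <- evolve_ortholog_genome(sim$genome, sim$features, 0, seed = 1)
  expect_identical(as.character(out$genome), as.character(sim$genome))
  expect_identical(out$features, sim$features)
})

test_that("ortholog evolution hits the requested exon divergence", {
  sim <- simulate_annotated_genome(small_cfg(9))
  out <- evolve_ortholog_genome(sim$genome, sim$features, 0.0365, seed = 2)
  tx_a <- extract_exon_transcripts(sim$genome, sim$features)
  tx_b <- extract_exon_transcripts(out$genome, out$features)
  stopifnot(identical(tx_a$transcript_id, tx_b$transcript_id))
  total <- sum(nchar(tx_a$seq))
  diffs <- sum(vapply(seq_len(nrow(tx_a)), function(i) {
    sum(strsplit(tx_a$seq[i], "")[[1]] != strsplit(tx_b$seq[i], "")[[1]])
  }, numeric(1)))
  # binomial sampling error around 3.65% at ~10 kb of exon sequence
  expect_lt(abs(diffs / total * 100 - 3.65), 0.8)
})

test_that("the genome pair preserves layout and plants ortholog divergence", {
  sim <- simulate_genome_pair(small_cfg(11))
  expect_identical(names(sim$genome_b), names(sim$genome))
  expect_identical(Biostrings::width(sim$genome_b),
                   Biostrings::width(sim$genome))
  tx_a <- extract_exon_transcripts(sim$genome, sim$features)
  tx_b <- extract_exon_transcripts(sim$genome_b, sim$features_b)
  # single-copy loci diverge at the per-locus single rate
  i <- match("mRNA:S01.c1", tx_a$transcript_id)
  d <- sum(strsplit(tx_a$seq[i], "")[[1]] != strsplit(tx_b$seq[i], "")[[1]]) /
    nchar(tx_a$seq[i]) * 100
  cfg <- small_cfg(11)
  expect_lt(abs(d - 100 * cfg$ortholog_divergence_singles), 0.7)
})

test_that("simulated recovery tables carry an exhaustive truth grid", {
  target <- setNames(sample(200:2000, 30), paste0("loc", 1:30))
  # full dropout: everything is a zero-data locus
  r1 <- simulate_recovery_table(6, target, dropout_rate = 1, seed = 2)
  expect_true(all(r1$matrix$recovered == 0))
  expect_true(all(r1$truth_grid$n_loci == 0))

  # no dropout and Beta mass near 1: the grid saturates
  r2 <- simulate_recovery_table(6, target, dropout_rate = 0,
                                length_beta_params = c(400, 1), seed = 3)
  expect_true(all(r2$truth_grid$n_loci == 30))

  # random table: package summary equals the generator-side truth
  r3 <- simulate_recovery_table(12, target, dropout_rate = 0.2,
                                length_beta_params = c(3, 2), seed = 4)
  got <- threshold_summary(r3$matrix)$grid
  expect_equal(got$n_loci, r3$truth_grid$n_loci)
  expect_equal(got$pct_loci, r3$truth_grid$pct_loci)

  # round trip through the seq_lengths dialect
  f <- withr::local_tempfile(fileext = ".tsv")
  r4 <- simulate_recovery_table(5, target, seed = 5, path = f)
  back <- load_seq_lengths(f)
  expect_equal(back$recovered, r4$matrix$recovered)
})

test_that("simulated alignment batches match their truth statistics", {
  # without missing data the planted column types are recovered exactly
  b0 <- simulate_alignment_batch(4, taxa = 8, length = 120,
                                 missing_rate = 0, pi_fraction = 0.2,
                                 singleton_fraction = 0.1, seed = 6)
  for (id in names(b0$alignments)) {
    s <- alignment_summary(b0$alignments[[id]])
    tr <- b0$truth[b0$truth$alignment == id, ]
    expect_equal(s$n_variable, tr$n_variable)
    expect_equal(s$n_parsimony_informative, tr$n_parsimony_informative)
  }

  # heavy missing data: survivors still match the recomputed truth, and
  # trimming plus the taxa filter behave as configured
  b1 <- simulate_alignment_batch(4, taxa = c(4, 10), length = c(60, 150),
                                 missing_rate = 0.5, pi_fraction = 0.2,
                                 singleton_fraction = 0.1, seed = 7)
  for (id in names(b1$alignments)) {
    s <- alignment_summary(b1$alignments[[id]])
    tr <- b1$truth[b1$truth$alignment == id, ]
    expect_equal(s$n_parsimony_informative, tr$n_parsimony_informative)
  }
  trimmed <- lapply(b1$alignments, trim_alignment)
  kept <- discard_small(trimmed)
  expect_true(all(vapply(kept, nrow, integer(1)) >= 4))

  a3 <- simulate_alignment_batch(1, taxa = 3, length = 50,
                                 missing_rate = 0, pi_fraction = 0.1,
                                 singleton_fraction = 0.1, seed = 8)
  expect_length(discard_small(a3$alignments), 0)
})
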