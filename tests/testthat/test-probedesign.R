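mk_hit <- function(query_id = "q", subject_id = "s", pident = 95,
                   len = 200L, q_start = 1L, q_end = q_start + len - 1L,
                   s_start = 1000L, s_end = s_start + len - 1L,
                   bit = len * 1.8) {
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = pident, align_length = as.integer(len),
             mismatches = 0L, gap_opens = 0L,
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             e_value = 1e-30, bit_score = bit, stringsAsFactors = FALSE)
}

test_that("initial hit filter applies strict length/fraction and >=80% identity", {
  qlen <- c(q = 500L, big = 2000L)
  cfg <- design_config()
  # exactly 70 bp must be rejected (thresholds are 'exceeding')
  expect_equal(nrow(initial_hit_filter(mk_hit(len = 70), qlen, cfg)), 0)
  # 71 bp at exactly 80% identity on a 500-bp query is retained
  expect_equal(nrow(initial_hit_filter(mk_hit(len = 71, pident = 80), qlen, cfg)), 1)
  # 150 bp <= 10% of a 2000-bp query is rejected despite high identity
  expect_equal(nrow(initial_hit_filter(
    mk_hit(query_id = "big", len = 150, pident = 95), qlen, cfg)), 0)
  # identity below 80 rejected
  expect_equal(nrow(initial_hit_filter(mk_hit(pident = 79.9), qlen, cfg)), 0)
  expect_error(initial_hit_filter(mk_hit(query_id = "nope"), qlen, cfg),
               "unknown")
})

test_that("clustering splits loci only when the gap exceeds 10 kb", {
  cfg <- design_config()
  two <- function(gap) rbind(
    mk_hit(s_start = 1000L, s_end = 1199L, len = 200),
    mk_hit(s_start = 1200L + gap, s_end = 1399L + gap, len = 200,
           q_start = 201L))
  expect_length(cluster_hits_to_loci(two(10000L), cfg), 1)
  expect_length(cluster_hits_to_loci(two(10001L), cfg), 2)
  h <- rbind(mk_hit(subject_id = "s1"), mk_hit(subject_id = "s2"))
  expect_length(cluster_hits_to_loci(h, cfg), 2)
})

test_that("queries with too many loci are removed at each stage", {
  cfg <- design_config()
  mk_clusters <- function(n) {
    hits <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_hit(subject_id = sprintf("s%d", i))))
    cluster_hits_to_loci(hits, cfg)
  }
  expect_length(drop_promiscuous_queries(mk_clusters(6), cfg, "initial"), 6)
  expect_length(drop_promiscuous_queries(mk_clusters(7), cfg, "initial"), 0)
  expect_length(drop_promiscuous_queries(mk_clusters(2), cfg, "refined"), 2)
  expect_length(drop_promiscuous_queries(mk_clusters(3), cfg, "refined"), 0)
})

test_that("refined filter checks coverage, identity, hit length and introns", {
  cfg <- design_config()
  base <- rbind(
    mk_hit(len = 150, pident = 93, q_start = 1L, s_start = 1000L),
    mk_hit(len = 200, pident = 91, q_start = 151L, s_start = 1950L))
  cl <- cluster_hits_to_loci(base, cfg)[[1]]
  r <- refined_locus_filter(cl, 368L, cfg)  # coverage 350/368 = 95%
  expect_true(r$pass)

  # one 99-bp hit fails only the single-hit length criterion
  h99 <- rbind(mk_hit(len = 150, q_start = 1L, s_start = 1000L),
               mk_hit(len = 99, q_start = 151L, s_start = 1950L))
  r <- refined_locus_filter(cluster_hits_to_loci(h99, cfg)[[1]], 260L, cfg)
  expect_false(r$pass)
  expect_equal(names(which(r$flags)), "min_single_hit_len")

  # inter-hit subject gap of 1201 fails the intron criterion
  gap <- rbind(mk_hit(len = 150, q_start = 1L, s_start = 1000L),
               mk_hit(len = 150, q_start = 151L, s_start = 1149L + 1202L))
  r <- refined_locus_filter(cluster_hits_to_loci(gap, cfg)[[1]], 320L, cfg)
  expect_false(r$pass)
  expect_equal(names(which(r$flags)), "max_intron_len")
  # gap of exactly 1200 passes it
  gap2 <- rbind(mk_hit(len = 150, q_start = 1L, s_start = 1000L),
                mk_hit(len = 150, q_start = 151L, s_start = 1149L + 1201L))
  r2 <- refined_locus_filter(cluster_hits_to_loci(gap2, cfg)[[1]], 320L, cfg)
  expect_false(r2$flags[["max_intron_len"]])

  # overlapping query intervals are merged before computing coverage
  ov <- rbind(mk_hit(len = 200, q_start = 1L, s_start = 1000L),
              mk_hit(len = 200, q_start = 101L, s_start = 2000L))
  r <- refined_locus_filter(cluster_hits_to_loci(ov, cfg)[[1]], 300L, cfg)
  expect_equal(r$metrics$sum_coverage_frac, 1.0)
})

test_that("exon/intron boundaries partition the cluster span", {
  cfg <- design_config()
  h <- rbind(mk_hit(len = 100, q_start = 1L, s_start = 1L, s_end = 100L),
             mk_hit(len = 100, q_start = 101L, s_start = 301L, s_end = 400L))
  b <- infer_exon_intron_boundaries(cluster_hits_to_loci(h, cfg)[[1]])
  expect_equal(b$exon_intervals, data.frame(start = c(1L, 301L),
                                            end = c(100L, 400L)))
  expect_equal(b$intron_intervals, data.frame(start = 101L, end = 300L))

  single <- cluster_hits_to_loci(mk_hit(), cfg)[[1]]
  b1 <- infer_exon_intron_boundaries(single)
  expect_equal(nrow(b1$exon_intervals), 1)
  expect_equal(nrow(b1$intron_intervals), 0)

  # three-hit cluster: intervals cover the span exactly once
  h3 <- rbind(mk_hit(len = 120, q_start = 1L, s_start = 500L),
              mk_hit(len = 150, q_start = 121L, s_start = 900L),
              mk_hit(len = 130, q_start = 271L, s_start = 1400L))
  cl <- cluster_hits_to_loci(h3, cfg)[[1]]
  b3 <- infer_exon_intron_boundaries(cl)
  iv <- rbind(b3$exon_intervals, b3$intron_intervals)
  iv <- iv[order(iv$start), ]
  expect_equal(iv$start[1], cl$s_min)
  expect_equal(iv$end[nrow(iv)], cl$s_max)
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1L))
})

test_that("locus extraction handles both strands", {
  set.seed(14)
  chr <- random_seq(3000)
  h <- rbind(mk_hit(len = 100, q_start = 1L, s_start = 1000L, s_end = 1099L),
             mk_hit(len = 100, q_start = 101L, s_start = 1300L, s_end = 1399L))
  cl <- cluster_hits_to_loci(h, design_config())[[1]]
  ext <- extract_locus_sequence(c(s = chr), cl)
  expect_equal(ext$seq, substring(chr, 1000, 1399))
  expect_equal(ext$exon_seqs, c(substring(chr, 1000, 1099),
                                substring(chr, 1300, 1399)))

  hm <- rbind(mk_hit(len = 100, q_start = 1L, s_start = 1399L, s_end = 1300L),
              mk_hit(len = 100, q_start = 101L, s_start = 1099L, s_end = 1000L))
  clm <- cluster_hits_to_loci(hm, design_config())[[1]]
  expect_equal(clm$strand, "-")
  extm <- extract_locus_sequence(c(s = chr), clm)
  expect_equal(extm$seq, oracle_revcomp(substring(chr, 1000, 1399)))
  # exon order reversed and reverse-complemented
  expect_equal(extm$exon_seqs,
               c(oracle_revcomp(substring(chr, 1300, 1399)),
                 oracle_revcomp(substring(chr, 1000, 1099))))

  one <- cluster_hits_to_loci(mk_hit(s_start = 2000L, s_end = 2199L, len = 200),
                              design_config())[[1]]
  expect_equal(extract_locus_sequence(c(s = chr), one)$seq,
               substring(chr, 2000, 2199))
})

test_that("inter-locus divergence keeps paralog pairs at >= 6% apart", {
  set.seed(15)
  base <- random_seq(1000)
  mutate_inner <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(6:995, k)
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  cfg <- design_config()
  expect_true(interlocus_divergence_filter(base, cfg)$pass)
  lo <- interlocus_divergence_filter(c(base, mutate_inner(base, 59)), cfg)
  expect_false(lo$pass)   # 5.9% < 6%
  hi <- interlocus_divergence_filter(c(base, mutate_inner(base, 80)), cfg)
  expect_true(hi$pass)    # 8%
  expect_gt(hi$divergence, 6)
})

fake_report <- function(queries) {
  # queries: named list of character vectors (exon concatenations per locus)
  out <- list()
  for (q in names(queries)) {
    loci <- lapply(queries[[q]], function(s) {
      list(exon_concat = s,
           extraction = list(exon_seqs = s,
                             exon_intervals = data.frame(start = 1L,
                                                         end = nchar(s)),
                             intron_seqs = character(),
                             intron_intervals = data.frame(start = integer(),
                                                           end = integer())))
    })
    out[[q]] <- list(loci = loci, divergence = NA_real_)
  }
  out
}

test_that("cross-genome validation enforces counts, divergence and exon length", {
  set.seed(16)
  cfg <- design_config()
  a <- random_seq(600)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(6:(nchar(s) - 5), k)
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  # count mismatch: 2 loci in A, 1 in B
  cv <- cross_genome_validate(fake_report(list(q = c(a, mut(a, 60)))),
                              fake_report(list(q = a)), cfg)
  expect_length(cv$queries, 0)
  expect_equal(cv$audit$failing_criterion, "locus_count_mismatch")

  # exactly 15.0% exon divergence is retained (<= 15)
  b15 <- mut(a, 90L)  # 90 of 600 sites, confined to the inner 590 bp
  d <- percent_divergence(a, b15)
  expect_lte(abs(d - 15.0), 0.05)
  cv2 <- cross_genome_validate(fake_report(list(q = a)),
                               fake_report(list(q = b15)), cfg)
  if (d <= 15) expect_length(cv2$queries, 1) else expect_length(cv2$queries, 0)

  # > 15% divergence is dropped
  cv3 <- cross_genome_validate(fake_report(list(q = a)),
                               fake_report(list(q = mut(a, 120))), cfg)
  expect_length(cv3$queries, 0)

  # a locus whose only exon is 79 bp is dropped
  short <- random_seq(79)
  cv4 <- cross_genome_validate(fake_report(list(q = short)),
                               fake_report(list(q = short)), cfg)
  expect_length(cv4$queries, 0)
  expect_equal(cv4$audit$failing_criterion, "min_exon_len")
})

test_that("intron target selection keeps only introns >= 80 bp", {
  loci <- list(list(intron_seqs = c(random_seq(80), random_seq(79))),
               list(intron_seqs = character()))
  out <- select_intron_targets(loci, design_config())
  expect_equal(nchar(out[[1]]$intron_seqs), 80)
  expect_length(out[[2]]$intron_seqs, 0)
})

test_that("greedy collapse joins only sequences >= 95% identical", {
  set.seed(17)
  a <- random_seq(300)
  out <- collapse_sequences(c(x = a, y = a))
  expect_length(out$representatives, 1)
  expect_equal(unname(out$membership[c("x", "y")]),
               rep(names(out$representatives), 2))

  # ~94% identity pair stays apart, ends pinned so the alignment is full
  v <- strsplit(a, "")[[1]]
  pos <- sample(8:292, 18)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  b <- paste(v, collapse = "")
  out2 <- collapse_sequences(c(x = a, y = b))
  expect_length(out2$representatives, 2)

  # post-hoc: every member is >= 95% identical to its representative
  pool <- c(
    setNames(lapply(1:6, function(i) random_seq(sample(150:250, 1))),
             paste0("u", 1:6)),
    setNames(lapply(1:6, function(i) mutate_seq(a, sample(0:6, 1))),
             paste0("v", 1:6)))
  pool <- vapply(pool, identity, character(1))
  res <- collapse_sequences(pool)
  for (id in names(res$membership)) {
    rep_id <- res$membership[[id]]
    if (id == rep_id) next
    d <- percent_divergence(pool[[id]], pool[[rep_id]])
    expect_lte(as.numeric(d), 5.5)
  }
})

test_that("identical inputs produce byte-identical design outputs", {
  cfg <- sim_config(seed = 12, n_single_copy = 3L, n_paralog_pairs = 1L,
                    decoys = "long_intron", decoy_multigene_copies = 0L)
  sim <- simulate_genome_pair(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    pts <- design_probe_set(sim$genome, sim$genome_b, sim$queries)
    write_probe_target_set(pts, d)
  }
  for (f in c("targets_exons.fasta", "audit.tsv", "provenance.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # headers follow the documented naming scheme
  heads <- grep("^>", readLines(file.path(d1, "targets_exons.fasta")),
                value = TRUE)
  expect_true(all(grepl("^>[^|]+\\|[^|]+\\|[AB]\\|L[12]\\|exon\\d+$", heads)))
})

test_that("empty query set gives an empty probe set without error", {
  g <- c(chr = random_seq(400))
  pts <- design_probe_set(g, g, Biostrings::DNAStringSet())
  expect_s3_class(pts, "probe_target_set")
  expect_length(pts$loci, 0)
  expect_equal(pts$total_exon_bp, 0)
})
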