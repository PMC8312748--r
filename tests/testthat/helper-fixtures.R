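# Hand-constructed toy universal probe set + annotated genome for the
# reference-optimization tests. Everything needed to predict the outputs
# byte-exactly is kept in the returned truth list, assembled independently
# of the package's extraction code.
make_refopt_toy <- function(n_loci = 5, reps_per_locus = 3, seed = 99) {
  set.seed(seed)
  pad <- 40L
  loci <- sprintf("%04d", 5000 + seq_len(n_loci))
  chrom <- character()
  feats <- list()
  universal <- character()
  truth <- list()
  pos <- 0L
  for (i in seq_len(n_loci)) {
    strand <- if (i == n_loci) "-" else "+"     # one minus-strand locus
    n_ex <- sample(2:3, 1)
    exon_seqs <- vapply(seq_len(n_ex), function(e)
      random_seq(sample(120:220, 1)), character(1))
    intron_seqs <- vapply(seq_len(n_ex - 1), function(e)
      random_seq(sample(80:150, 1)), character(1))
    locus_seq <- exon_seqs[1]
    offsets <- c(0L)
    for (e in seq_len(n_ex - 1)) {
      locus_seq <- paste0(locus_seq, intron_seqs[e], exon_seqs[e + 1])
      offsets <- c(offsets, nchar(locus_seq) - nchar(exon_seqs[e + 1]))
    }
    spacer <- random_seq(150)
    chrom <- paste0(paste(chrom, collapse = ""), spacer)
    gstart <- nchar(chrom) + 1L
    genomic <- if (strand == "+") locus_seq else oracle_revcomp(locus_seq)
    chrom <- paste0(chrom, genomic)
    gend <- nchar(chrom)
    L <- nchar(locus_seq)
    # locus-relative exon intervals -> genomic
    rel <- data.frame(start = offsets + 1L,
                      end = offsets + nchar(exon_seqs))
    ge <- if (strand == "+") {
      data.frame(start = gstart + rel$start - 1L, end = gstart + rel$end - 1L)
    } else {
      out <- data.frame(start = gstart + (L - rel$end),
                        end = gstart + (L - rel$start))
      out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
    gid <- sprintf("gene%02d", i); tid <- sprintf("t%02d", i)
    feats[[i]] <- data.frame(
      seq_id = "chr1",
      feature_type = c("gene", "mRNA", rep("exon", n_ex)),
      start = c(gstart, gstart, ge$start), end = c(gend, gend, ge$end),
      strand = strand,
      id = c(gid, tid, sprintf("%s.e%d", tid, seq_len(n_ex))),
      parent_id = c(NA, gid, rep(tid, n_ex)),
      biotype = c("protein_coding", rep(NA, 1 + n_ex)),
      stringsAsFactors = FALSE)
    concat <- paste(exon_seqs, collapse = "")
    # representative 1: exact exon concatenation with random padding (wins
    # by hit length); 2: truncated; 3: mutated
    reps <- c(paste0(random_seq(pad), concat, random_seq(pad)),
              substring(concat, 1, floor(nchar(concat) * 0.6)),
              mutate_seq(concat, round(nchar(concat) * 0.1)))
    reps <- reps[seq_len(reps_per_locus)]
    names(reps) <- sprintf("Taxon%d-%s", seq_along(reps), loci[i])
    universal <- c(universal, reps)
    truth[[loci[i]]] <- list(exon_concat = concat, winner = names(reps)[1],
                             strand = strand, transcript = tid)
  }
  chrom <- paste0(chrom, random_seq(150))
  list(genome = c(chr1 = chrom),
       gff = do.call(rbind, feats),
       universal = universal,
       truth = truth)
}
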