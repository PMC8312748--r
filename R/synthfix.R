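# Synthetic annotated genomes with planted single-copy loci, once-duplicated
# paralog pairs at controlled divergence, decoy loci violating individual
# design criteria, and machine-readable truth tables.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

DNA_BASES <- c("A", "C", "G", "T")

# Substitute the bases at `pos` of character vector `v`, each to a
# uniformly chosen different base.
substitute_positions <- function(v, pos) {
  if (!length(pos)) return(v)
  code <- match(v[pos], DNA_BASES)
  v[pos] <- DNA_BASES[((code - 1L + sample.int(3L, length(pos),
                                               replace = TRUE)) %% 4L) + 1L]
  v
}

# Substitute exactly round(d * length) distinct positions of a DNA string,
# each to a different base, so the realized divergence is crisp.
mutate_exact <- function(seq, d) {
  n <- nchar(seq)
  k <- round(d * n)
  if (k == 0) return(seq)
  v <- substitute_positions(strsplit(seq, "")[[1]], sample.int(n, k))
  paste(v, collapse = "")
}

# Mutate each exon/intron segment of a locus sequence independently at rate
# d, so exon-restricted divergence equals d as closely as rounding allows.
mutate_segments <- function(seq, bounds, d) {
  segs <- substring(seq, bounds$start, bounds$end)
  segs <- vapply(segs, mutate_exact, character(1), d = d, USE.NAMES = FALSE)
  paste(segs, collapse = "")
}

#' Configuration of the synthetic-genome generator
#'
#' Defaults plant 12 single-copy loci and 4 once-duplicated paralog pairs
#' (20 qualifying loci) plus one decoy per design criterion and one
#' multigene family. Paralog pairs sit just above the 6% divergence design
#' threshold; per-locus ortholog divergences are heterogeneous (pairs low,
#' singles higher) with a genome-wide mean matching the 3.65% Malus/Pyrus
#' ortholog divergence the design regime assumes.
#'
#' @param seed Integer seed; all generator functions are reproducible from
#'   it.
#' @param n_single_copy,n_paralog_pairs Planted qualifying loci.
#' @param paralog_divergence_range Substitutions/site between paralog
#'   copies.
#' @param ortholog_divergence Genome-wide mean ortholog divergence (also
#'   the intergenic rate).
#' @param ortholog_divergence_pairs,ortholog_divergence_singles Per-locus
#'   ortholog divergences for paralog-pair and single-copy loci.
#' @param exons_per_locus_range,exon_len_range,intron_len_range,intergenic_len_range
#'   Structural ranges (bp).
#' @param base_composition Named probabilities over A, C, G, T.
#' @param decoys Character vector of decoy classes to plant (see
#'   [simulate_annotated_genome()]).
#' @param decoy_multigene_copies Copy number of the decoy multigene family
#'   (> 2; 0 disables it).
#' @param n_chromosomes Number of chromosome sequences.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_single_copy = 12L,
                       n_paralog_pairs = 4L,
                       paralog_divergence_range = c(0.068, 0.078),
                       ortholog_divergence = 0.0365,
                       ortholog_divergence_pairs = 0.015,
                       ortholog_divergence_singles = 0.051,
                       exons_per_locus_range = c(2L, 4L),
                       exon_len_range = c(150L, 300L),
                       intron_len_range = c(350L, 800L),
                       intergenic_len_range = c(400L, 1200L),
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       decoys = c("short_hits", "query_fraction",
                                  "low_identity", "cluster_gap",
                                  "too_many_loci_initial", "low_coverage",
                                  "short_single_hit", "long_intron",
                                  "too_many_loci_refined",
                                  "low_paralog_divergence",
                                  "high_ortholog_divergence", "short_exon"),
                       decoy_multigene_copies = 4L,
                       n_chromosomes = 4L) {
  stopifnot(diff(paralog_divergence_range) >= 0,
            all(c(paralog_divergence_range, ortholog_divergence,
                  ortholog_divergence_pairs,
                  ortholog_divergence_singles) < 0.75),
            exon_len_range[1] >= 10, intron_len_range[1] >= 1,
            abs(sum(base_composition) - 1) < 1e-8)
  if (intron_len_range[2] > 10000) {
    stop("intron_len_range exceeds the clustering gap budget")
  }
  # an affine gap across the shortest intron must cost more than aligning
  # the longest exon can gain, so every exon yields its own local hit
  # (gap cost 5 + 2L vs at most 2 bp-score per exon base)
  if (intron_len_range[1] <= exon_len_range[2]) {
    stop("intron_len_range[1] must exceed exon_len_range[2]: shorter introns ",
         "could be gap-bridged by the aligner, merging adjacent exon hits")
  }
  structure(as.list(environment()), class = "sim_config")
}

# One locus structure: exon lengths, intron lengths, the plus-oriented
# sequence of the founder copy and its locus-relative segment bounds.
new_locus_structure <- function(cfg, exon_lens = NULL, intron_lens = NULL) {
  if (is.null(exon_lens)) {
    k <- sample(seq(cfg$exons_per_locus_range[1],
                    cfg$exons_per_locus_range[2]), 1)
    exon_lens <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]),
                        k, replace = TRUE)
  }
  k <- length(exon_lens)
  if (is.null(intron_lens)) {
    intron_lens <- if (k > 1) {
      sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]),
             k - 1, replace = TRUE)
    } else integer()
  }
  lens <- integer(0); types <- character(0)
  for (i in seq_len(k)) {
    lens <- c(lens, exon_lens[i]); types <- c(types, "exon")
    if (i < k) { lens <- c(lens, intron_lens[i]); types <- c(types, "intron") }
  }
  ends <- cumsum(lens)
  bounds <- data.frame(start = ends - lens + 1L, end = ends, type = types)
  seq <- random_dna(sum(lens), cfg$base_composition)
  list(seq = seq, bounds = bounds,
       exon_bounds = bounds[bounds$type == "exon", c("start", "end")])
}

exon_concat_of <- function(st) {
  paste(substring(st$seq, st$exon_bounds$start, st$exon_bounds$end),
        collapse = "")
}

# Internal: full plan of planted loci. Each item: query_id, class,
# expected verdict, copies (list of list(seq, bounds)), query_seq,
# ortholog divergence for the second genome.
build_plan <- function(cfg) {
  plan <- list()
  add <- function(query_id, class, verdict, criterion, copies, query_seq,
                  ortho_div, realized_div = NA_real_) {
    plan[[length(plan) + 1L]] <<- list(
      query_id = query_id, class = class, expected_verdict = verdict,
      failing_criterion = criterion, copies = copies, query_seq = query_seq,
      ortholog_divergence = ortho_div, realized_divergence = realized_div)
  }
  derive <- function(st, d) {
    list(seq = mutate_segments(st$seq, st$bounds, d), bounds = st$bounds,
         exon_bounds = st$exon_bounds)
  }

  for (i in seq_len(cfg$n_single_copy)) {
    st <- new_locus_structure(cfg)
    add(sprintf("S%02d", i), "single_copy", "retain", "", list(st),
        exon_concat_of(st), cfg$ortholog_divergence_singles)
  }
  for (i in seq_len(cfg$n_paralog_pairs)) {
    st <- new_locus_structure(cfg)
    d <- runif(1, cfg$paralog_divergence_range[1],
               cfg$paralog_divergence_range[2])
    copy2 <- derive(st, d)
    ex_len <- sum(st$exon_bounds$end - st$exon_bounds$start + 1L)
    realized <- sum(round(d * (st$exon_bounds$end - st$exon_bounds$start + 1L))) /
      ex_len * 100
    add(sprintf("P%02d", i), "paralog_pair", "retain", "",
        list(st, copy2), exon_concat_of(st),
        cfg$ortholog_divergence_pairs, realized)
  }

  for (cls in cfg$decoys) {
    switch(cls,
      short_hits = {
        st <- new_locus_structure(cfg, exon_lens = rep(60L, 5))
        add("D_short_hits", cls, "drop", "min_hit_len", list(st),
            exon_concat_of(st), cfg$ortholog_divergence)
      },
      query_fraction = {
        st <- new_locus_structure(cfg, exon_lens = rep(160L, 11),
                                  intron_lens = rep(400L, 10))
        add("D_query_fraction", cls, "drop", "min_hit_query_frac", list(st),
            exon_concat_of(st), cfg$ortholog_divergence)
      },
      low_identity = {
        st <- new_locus_structure(cfg)
        q <- mutate_exact(exon_concat_of(st), 0.25)
        add("D_low_identity", cls, "drop", "min_hit_identity", list(st), q,
            cfg$ortholog_divergence)
      },
      cluster_gap = {
        st <- new_locus_structure(cfg, exon_lens = rep(250L, 4),
                                  intron_lens = c(400L, 10500L, 400L))
        add("D_cluster_gap", cls, "drop", "max_cluster_gap", list(st),
            exon_concat_of(st), cfg$ortholog_divergence)
      },
      too_many_loci_initial = {
        st <- new_locus_structure(cfg, exon_lens = c(250L, 250L),
                                  intron_lens = 400L)
        copies <- c(list(st), lapply(1:6, function(i) derive(st, 0.02)))
        add("D_seven_loci", cls, "drop", "max_loci_per_query_initial",
            copies, exon_concat_of(st), cfg$ortholog_divergence)
      },
      low_coverage = {
        st <- new_locus_structure(cfg, exon_lens = c(200L, 200L),
                                  intron_lens = 400L)
        q <- paste0(exon_concat_of(st), random_dna(100, cfg$base_composition))
        add("D_low_coverage", cls, "drop", "min_sum_coverage", list(st), q,
            cfg$ortholog_divergence)
      },
      short_single_hit = {
        st <- new_locus_structure(cfg, exon_lens = c(85L, 250L, 250L),
                                  intron_lens = c(400L, 400L))
        add("D_short_single_hit", cls, "drop", "min_single_hit_len",
            list(st), exon_concat_of(st), cfg$ortholog_divergence)
      },
      long_intron = {
        st <- new_locus_structure(cfg, exon_lens = c(250L, 250L),
                                  intron_lens = 1500L)
        add("D_long_intron", cls, "drop", "max_intron_len", list(st),
            exon_concat_of(st), cfg$ortholog_divergence)
      },
      too_many_loci_refined = {
        st <- new_locus_structure(cfg, exon_lens = c(250L, 250L),
                                  intron_lens = 400L)
        copies <- c(list(st), lapply(1:2, function(i) derive(st, 0.03)))
        add("D_three_loci", cls, "drop", "max_loci_per_query", copies,
            exon_concat_of(st), cfg$ortholog_divergence)
      },
      low_paralog_divergence = {
        st <- new_locus_structure(cfg)
        add("D_low_divergence", cls, "drop", "min_interlocus_divergence",
            list(st, derive(st, 0.03)), exon_concat_of(st),
            cfg$ortholog_divergence_pairs)
      },
      high_ortholog_divergence = {
        st <- new_locus_structure(cfg)
        add("D_far_ortholog", cls, "drop", "max_ortholog_divergence",
            list(st), exon_concat_of(st), 0.20)
      },
      short_exon = {
        st <- new_locus_structure(cfg, exon_lens = 79L)
        add("D_short_exon", cls, "drop", "min_exon_len", list(st),
            exon_concat_of(st), cfg$ortholog_divergence)
      },
      stop("unknown decoy class: ", cls)
    )
  }
  if (cfg$decoy_multigene_copies > 2) {
    st <- new_locus_structure(cfg, exon_lens = c(250L, 250L),
                              intron_lens = 400L)
    copies <- c(list(st), lapply(seq_len(cfg$decoy_multigene_copies - 1L),
                                 function(i) derive(st, 0.03)))
    add("D_multigene", "multigene_family", "drop", "max_loci_per_query",
        copies, exon_concat_of(st), cfg$ortholog_divergence)
  }
  plan
}

# Place all copies of a plan on chromosomes; returns genome, features and
# per-copy coordinates. Copies of the same query are assigned to distinct
# (chromosome, strand) slots so that the hits of different copies can never
# fall within one clustering gap of each other.
place_plan <- function(plan, cfg) {
  n_slots <- 2L * cfg$n_chromosomes
  slots <- data.frame(chr = rep(seq_len(cfg$n_chromosomes), 2),
                      strand = rep(c("+", "-"), each = cfg$n_chromosomes))
  copies <- list()
  for (p in plan) {
    if (length(p$copies) > n_slots) {
      stop("query ", p$query_id, " has more copies (", length(p$copies),
           ") than available chromosome/strand slots (", n_slots, ")")
    }
    sl <- sample.int(n_slots, length(p$copies))
    for (ci in seq_along(p$copies)) {
      copies[[length(copies) + 1L]] <- list(
        query_id = p$query_id, copy = ci, st = p$copies[[ci]],
        chr = slots$chr[sl[ci]], strand = slots$strand[sl[ci]])
    }
  }
  copies <- copies[sample.int(length(copies))]

  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  feats <- list(); coords <- list()
  pos <- integer(cfg$n_chromosomes)
  parts <- lapply(seq_len(cfg$n_chromosomes), function(i) character())
  for (k in seq_along(copies)) {
    cp <- copies[[k]]
    chr <- cp$chr
    spacer <- random_dna(sample(seq(cfg$intergenic_len_range[1],
                                    cfg$intergenic_len_range[2]), 1),
                         cfg$base_composition)
    parts[[chr]] <- c(parts[[chr]], spacer)
    pos[chr] <- pos[chr] + nchar(spacer)
    gstart <- pos[chr] + 1L
    gseq <- if (cp$strand == "+") cp$st$seq else revcomp(cp$st$seq)
    parts[[chr]] <- c(parts[[chr]], gseq)
    pos[chr] <- pos[chr] + nchar(gseq)
    gend <- pos[chr]
    L <- nchar(gseq)
    # locus-relative -> genomic exon intervals
    eb <- cp$st$exon_bounds
    if (cp$strand == "+") {
      ge <- data.frame(start = gstart + eb$start - 1L,
                       end = gstart + eb$end - 1L)
    } else {
      ge <- data.frame(start = gstart + (L - eb$end),
                       end = gstart + (L - eb$start))
      ge <- ge[rev(seq_len(nrow(ge))), , drop = FALSE]
    }
    gid <- sprintf("gene:%s.c%d", cp$query_id, cp$copy)
    tid <- sprintf("mRNA:%s.c%d", cp$query_id, cp$copy)
    chr_id <- chrom_names[chr]
    feats[[length(feats) + 1L]] <- data.frame(
      seq_id = chr_id,
      feature_type = c("gene", "mRNA", rep("exon", nrow(ge))),
      start = c(gstart, gstart, ge$start), end = c(gend, gend, ge$end),
      strand = cp$strand,
      id = c(gid, tid, sprintf("%s.exon%d", tid, seq_len(nrow(ge)))),
      parent_id = c(NA, gid, rep(tid, nrow(ge))),
      biotype = c("protein_coding", rep(NA, 1 + nrow(ge))),
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- data.frame(
      query_id = cp$query_id, copy = cp$copy, seq_id = chr_id,
      start = gstart, end = gend, strand = cp$strand,
      stringsAsFactors = FALSE)
  }
  # terminal spacers
  for (chr in seq_len(cfg$n_chromosomes)) {
    parts[[chr]] <- c(parts[[chr]],
                      random_dna(mean(cfg$intergenic_len_range),
                                 cfg$base_composition))
  }
  genome <- Biostrings::DNAStringSet(
    vapply(parts, paste, character(1), collapse = ""))
  names(genome) <- chrom_names
  list(genome = genome,
       features = do.call(rbind, feats),
       coords = do.call(rbind, coords))
}

plan_truth <- function(plan) {
  do.call(rbind, lapply(plan, function(p) data.frame(
    query_id = p$query_id, class = p$class,
    copy_number = length(p$copies),
    realized_divergence_pct = p$realized_divergence,
    ortholog_divergence = p$ortholog_divergence,
    expected_verdict = p$expected_verdict,
    failing_criterion = p$failing_criterion,
    stringsAsFactors = FALSE)))
}

plan_queries <- function(plan) {
  Biostrings::DNAStringSet(stats::setNames(
    vapply(plan, `[[`, character(1), "query_seq"),
    vapply(plan, `[[`, character(1), "query_id")))
}

#' Simulate one annotated genome with planted loci and a truth table
#'
#' The genome contains single-copy loci, once-duplicated paralog pairs at
#' controlled divergence, decoy loci each violating one design criterion
#' (classes: `short_hits`, `query_fraction`, `low_identity`, `cluster_gap`,
#' `too_many_loci_initial`, `low_coverage`, `short_single_hit`,
#' `long_intron`, `too_many_loci_refined`, `low_paralog_divergence`,
#' `high_ortholog_divergence`, `short_exon`), a multigene decoy family with
#' more than two copies, and neutral intergenic spacers. Queries are the
#' exon concatenations of one copy per locus (decoy classes may perturb
#' them, e.g. `low_identity` mutates the query itself). Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` (DNAStringSet), `features` (GFF-style data
#'   frame), `queries` (DNAStringSet), `truth` (per planted query: class,
#'   copy number, realized divergence, expected verdict and violated
#'   criterion) and `copies` (genomic coordinates of every planted copy).
#' @export
simulate_annotated_genome <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    plan <- build_plan(cfg)
    placed <- place_plan(plan, cfg)
    list(genome = placed$genome, features = placed$features,
         queries = plan_queries(plan), truth = plan_truth(plan),
         copies = placed$coords, plan = plan)
  })
}

#' Simulate a genome pair (focal genome plus evolved ortholog genome)
#'
#' Genome A is produced as in [simulate_annotated_genome()]; genome B keeps
#' the same layout and annotation but every planted copy is mutated at its
#' locus-specific ortholog divergence (segment-wise, exact substitution
#' counts) and intergenic DNA at the genome-wide rate.
#'
#' @param cfg A [sim_config()].
#' @return The list from [simulate_annotated_genome()] plus `genome_b` and
#'   `features_b`.
#' @export
simulate_genome_pair <- function(cfg = sim_config()) {
  sim <- simulate_annotated_genome(cfg)
  with_seed(cfg$seed + 104729L, {
    ortho <- stats::setNames(
      vapply(sim$plan, `[[`, numeric(1), "ortholog_divergence"),
      vapply(sim$plan, `[[`, character(1), "query_id"))
    chroms <- as.character(sim$genome)
    exons <- sim$features[sim$features$feature_type == "exon", , drop = FALSE]
    for (chr in names(chroms)) {
      v <- strsplit(chroms[[chr]], "")[[1]]
      cc <- sim$copies[sim$copies$seq_id == chr, , drop = FALSE]
      in_copy <- rep(FALSE, length(v))
      for (r in seq_len(nrow(cc))) {
        d <- ortho[[cc$query_id[r]]]
        tid <- sprintf("mRNA:%s.c%d", cc$query_id[r], cc$copy[r])
        ex <- exons[exons$parent_id == tid, , drop = FALSE]
        segs <- rbind(ex[, c("start", "end")],
                      interval_complement(ex, cc$start[r], cc$end[r]))
        for (s in seq_len(nrow(segs))) {
          idx <- segs$start[s]:segs$end[s]
          k <- round(d * length(idx))
          if (k > 0) v <- substitute_positions(v, sample(idx, k))
        }
        in_copy[cc$start[r]:cc$end[r]] <- TRUE
      }
      inter <- which(!in_copy)
      k <- round(cfg$ortholog_divergence * length(inter))
      if (k > 0) v <- substitute_positions(v, sample(inter, k))
      chroms[[chr]] <- paste(v, collapse = "")
    }
    sim$genome_b <- Biostrings::DNAStringSet(chroms)
    sim$features_b <- sim$features
    sim
  })
}

# Intervals of [lo, hi] not covered by the rows of df (start/end columns).
interval_complement <- function(df, lo, hi) {
  ir <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
  g <- IRanges::gaps(ir, start = lo, end = hi)
  data.frame(start = IRanges::start(g), end = IRanges::end(g))
}

#' Evolve an ortholog genome at a uniform per-site substitution rate
#'
#' Site-independent substitutions (Jukes-Cantor style): every position is
#' substituted with probability `divergence`, to a uniformly chosen
#' different base. Indel-free, so annotation coordinates are preserved.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or character vector).
#' @param gff Feature data frame (returned unchanged).
#' @param divergence Per-site substitution probability.
#' @param seed Integer seed.
#' @return A list with `genome` (mutated DNAStringSet) and `features`.
#' @export
evolve_ortholog_genome <- function(genome, gff, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.75)
  genome <- as_dna(genome)
  with_seed(seed, {
    chroms <- as.character(genome)
    for (i in seq_along(chroms)) {
      v <- strsplit(chroms[[i]], "")[[1]]
      v <- substitute_positions(v, which(runif(length(v)) < divergence))
      chroms[[i]] <- paste(v, collapse = "")
    }
    out <- Biostrings::DNAStringSet(chroms)
    names(out) <- names(genome)
    list(genome = out, features = gff)
  })
}

#' Simulate a HybPiper-style recovery table with its truth grid
#'
#' Per-cell recovered length = target length x a Beta draw, zeroed with the
#' dropout probability. The truth grid is computed exhaustively
#' (double loop) from the emitted table, independently of
#' [threshold_summary()].
#'
#' @param n_samples Number of samples.
#' @param reference Named numeric vector of target lengths, or a
#'   DNAStringSet whose widths are used.
#' @param dropout_rate Probability that a cell has zero data.
#' @param length_beta_params Shape1/shape2 of the Beta recovered-length
#'   fraction.
#' @param seed Integer seed.
#' @param path Optional path; when given the table is written in the
#'   seq_lengths dialect.
#' @param length_thresholds,presence_thresholds Grid axes for the truth.
#' @return A list with `matrix` (a [recovery_matrix()]), `truth_grid` (data
#'   frame) and `path`.
#' @export
simulate_recovery_table <- function(n_samples, reference,
                                    dropout_rate = 0.05,
                                    length_beta_params = c(6, 1.5),
                                    seed = 1L, path = NULL,
                                    length_thresholds = c(0.25, 0.50, 0.75),
                                    presence_thresholds = c(0.50, 0.75)) {
  target <- if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(Biostrings::width(reference), names(reference))
  } else reference
  stopifnot(!is.null(names(target)), all(target > 0))
  with_seed(seed, {
    nl <- length(target)
    frac <- matrix(stats::rbeta(n_samples * nl, length_beta_params[1],
                                length_beta_params[2]),
                   nrow = n_samples)
    drop <- matrix(stats::runif(n_samples * nl) < dropout_rate,
                   nrow = n_samples)
    frac[drop] <- 0
    rec <- round(sweep(frac, 2, target, "*"))
    dimnames(rec) <- list(sprintf("sample%02d", seq_len(n_samples)),
                          names(target))
    # exhaustive truth computation, cell by cell
    truth <- expand.grid(length_threshold = length_thresholds,
                         presence_threshold = presence_thresholds,
                         KEEP.OUT.ATTRS = FALSE)
    truth <- truth[order(truth$length_threshold, truth$presence_threshold), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    n <- integer(nrow(truth))
    for (r in seq_len(nrow(truth))) {
      cnt <- 0L
      for (l in seq_len(nl)) {
        hits <- 0L
        for (s in seq_len(n_samples)) {
          f <- min(rec[s, l] / target[[l]], 1)
          if (f >= truth$length_threshold[r]) hits <- hits + 1L
        }
        if (hits / n_samples >= truth$presence_threshold[r]) cnt <- cnt + 1L
      }
      n[r] <- cnt
    }
    truth$n_loci <- n
    truth$pct_loci <- n / nl * 100
    if (!is.null(path)) {
      lines <- c(paste(c("Species", names(target)), collapse = "\t"),
                 paste(c("MeanLength", target), collapse = "\t"),
                 vapply(seq_len(n_samples), function(s)
                   paste(c(rownames(rec)[s], rec[s, ]), collapse = "\t"),
                   character(1)))
      writeLines(lines, path)
    }
    list(matrix = recovery_matrix(rec, target), truth_grid = truth,
         path = path)
  })
}

#' Simulate a batch of alignments with known site-class truth
#'
#' Columns are drawn as constant / singleton / parsimony-informative per the
#' requested fractions, then missing data is injected cell-wise; the truth
#' statistics are recomputed after injection by exhaustive per-column state
#' counting.
#'
#' @param n_aln Number of alignments.
#' @param taxa Taxa per alignment (single value or range).
#' @param length Columns per alignment (single value or range).
#' @param missing_rate Per-cell probability of replacement by `-`.
#' @param pi_fraction Fraction of parsimony-informative columns drawn.
#' @param singleton_fraction Fraction of singleton-variable columns drawn.
#' @param seed Integer seed.
#' @return A list with `alignments` (named list of matrices) and `truth`
#'   (per-alignment data frame with post-injection variable/PI counts).
#' @export
simulate_alignment_batch <- function(n_aln, taxa, length, missing_rate = 0,
                                     pi_fraction = 0.1,
                                     singleton_fraction = 0.1, seed = 1L) {
  stopifnot(pi_fraction + singleton_fraction <= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    alns <- list(); truth <- list()
    for (a in seq_len(n_aln)) {
      nt <- if (base::length(taxa) > 1) sample(seq(taxa[1], taxa[2]), 1) else taxa
      nc <- if (base::length(length) > 1) sample(seq(length[1], length[2]), 1) else length
      m <- matrix("", nrow = nt, ncol = nc)
      type <- sample(c("pi", "singleton", "constant"), nc, replace = TRUE,
                     prob = c(pi_fraction, singleton_fraction,
                              1 - pi_fraction - singleton_fraction))
      for (j in seq_len(nc)) {
        b <- sample(bases, 2)
        col <- rep(b[1], nt)
        if (type[j] == "singleton") {
          col[sample.int(nt, 1)] <- b[2]
        } else if (type[j] == "pi" && nt >= 4) {
          k <- sample(2:(nt - 2), 1)
          col[sample.int(nt, k)] <- b[2]
        }
        m[, j] <- col
      }
      if (missing_rate > 0) {
        m[matrix(stats::runif(nt * nc) < missing_rate, nt, nc)] <- "-"
      }
      rownames(m) <- sprintf("t%02d", seq_len(nt))
      # exhaustive post-injection truth: tally states per column
      n_pi <- 0L; n_var <- 0L
      for (j in seq_len(nc)) {
        tab <- table(m[m[, j] %in% bases, j])
        if (base::length(tab) >= 2) {
          n_var <- n_var + 1L
          if (sum(tab >= 2) >= 2) n_pi <- n_pi + 1L
        }
      }
      id <- sprintf("aln%03d", a)
      alns[[id]] <- m
      truth[[id]] <- data.frame(
        alignment = id, n_taxa = nt, length_bp = nc,
        n_variable = n_var, n_parsimony_informative = n_pi,
        stringsAsFactors = FALSE)
    }
    list(alignments = alns, truth = do.call(rbind, truth))
  })
}
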