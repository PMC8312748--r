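#' Initial hit filter of the design cascade
#'
#' Retains only the hits exceeding the minimal length (strict >), exceeding
#' the minimal fraction of their query's length (strict >), and with percent
#' identity at or above the identity threshold.
#'
#' @param hits Hit data frame.
#' @param query_lengths Named integer vector of query lengths.
#' @param cfg A [design_config()].
#' @return The retained hits.
#' @export
initial_hit_filter <- function(hits, query_lengths, cfg = design_config()) {
  if (!nrow(hits)) return(hits)
  unknown <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(unknown)) {
    stop("hits reference queries of unknown length: ",
         paste(unknown, collapse = ", "))
  }
  qlen <- query_lengths[hits$query_id]
  keep <- hits$align_length > cfg$min_hit_len &
    hits$align_length > cfg$min_hit_query_frac * qlen &
    hits$percent_identity >= cfg$min_hit_identity
  hits[keep, , drop = FALSE]
}

hit_strand <- function(hits) ifelse(hits$s_start <= hits$s_end, "+", "-")

#' Cluster filtered hits into candidate loci
#'
#' Hits are grouped by (query, subject, strand) and sorted by subject start;
#' a new cluster (candidate locus) starts whenever the number of bases
#' between consecutive hits exceeds `cfg$max_cluster_gap` (a gap of exactly
#' the threshold still joins).
#'
#' @param hits Filtered hit data frame.
#' @param cfg A [design_config()].
#' @return A list of `locus_cluster` objects, each with fields `query_id`,
#'   `subject_id`, `strand`, `hits`, `s_min`, `s_max`.
#' @export
cluster_hits_to_loci <- function(hits, cfg = design_config()) {
  if (!nrow(hits)) return(list())
  strand <- hit_strand(hits)
  smin <- pmin(hits$s_start, hits$s_end)
  smax <- pmax(hits$s_start, hits$s_end)
  key <- paste(hits$query_id, hits$subject_id, strand, sep = "\r")
  clusters <- list()
  for (idx in split(seq_len(nrow(hits)), key)) {
    idx <- idx[order(smin[idx], smax[idx])]
    gap <- smin[idx][-1] - smax[idx][-length(idx)] - 1L
    grp <- cumsum(c(0L, as.integer(gap > cfg$max_cluster_gap)))
    for (g in split(idx, grp)) {
      h <- hits[g, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- structure(
        list(query_id = h$query_id[1], subject_id = h$subject_id[1],
             strand = hit_strand(h)[1], hits = h,
             s_min = min(pmin(h$s_start, h$s_end)),
             s_max = max(pmax(h$s_start, h$s_end))),
        class = "locus_cluster")
    }
  }
  ord <- order(vapply(clusters, `[[`, character(1), "query_id"),
               vapply(clusters, `[[`, character(1), "subject_id"),
               vapply(clusters, `[[`, numeric(1), "s_min"))
  clusters[ord]
}

#' Drop queries hitting too many loci
#'
#' @param clusters List of clusters from [cluster_hits_to_loci()].
#' @param cfg A [design_config()].
#' @param stage `"initial"` (more than `max_loci_per_query_initial` loci
#'   removes the query) or `"refined"` (more than `max_loci_per_query`).
#' @return The clusters of surviving queries.
#' @export
drop_promiscuous_queries <- function(clusters, cfg = design_config(),
                                     stage = c("initial", "refined")) {
  stage <- match.arg(stage)
  limit <- if (stage == "initial") cfg$max_loci_per_query_initial else
    cfg$max_loci_per_query
  qids <- vapply(clusters, `[[`, character(1), "query_id")
  counts <- table(qids)
  keep <- qids %in% names(counts)[counts <= limit]
  clusters[keep]
}

# Merged query intervals, weighted identity and subject exon/intron
# structure of a cluster.
cluster_metrics <- function(cluster, query_length) {
  h <- cluster$hits
  qr <- IRanges::reduce(IRanges::IRanges(h$q_start, h$q_end))
  bounds <- infer_exon_intron_boundaries(cluster)
  list(
    sum_coverage_frac = sum(IRanges::width(qr)) / query_length,
    weighted_identity = sum(h$percent_identity * h$align_length) /
      sum(h$align_length),
    exon_intervals = bounds$exon_intervals,
    intron_intervals = bounds$intron_intervals
  )
}

#' Refined per-locus filter
#'
#' A locus passes when (i) the union of the query intervals of its hits
#' covers at least `min_sum_coverage` of the query (overlaps merged before
#' summing), (ii) the alignment-length-weighted mean identity of its hits is
#' at least `min_sum_identity`, (iii) every hit is at least
#' `min_single_hit_len` long, and (iv) every inter-hit subject gap is at most
#' `max_intron_len`.
#'
#' @param cluster A `locus_cluster`.
#' @param query_length Length of the cluster's query.
#' @param cfg A [design_config()].
#' @return A list with `pass` (logical) and `flags`, a named logical vector
#'   marking each violated criterion.
#' @export
refined_locus_filter <- function(cluster, query_length, cfg = design_config()) {
  m <- cluster_metrics(cluster, query_length)
  intron_len <- if (nrow(m$intron_intervals)) {
    m$intron_intervals$end - m$intron_intervals$start + 1L
  } else integer()
  flags <- c(
    min_sum_coverage = m$sum_coverage_frac < cfg$min_sum_coverage,
    min_sum_identity = m$weighted_identity < cfg$min_sum_identity,
    min_single_hit_len = any(cluster$hits$align_length < cfg$min_single_hit_len),
    max_intron_len = any(intron_len > cfg$max_intron_len)
  )
  list(pass = !any(flags), flags = flags, metrics = m)
}

#' Infer exon/intron boundaries of a cluster
#'
#' Exons are the merged subject intervals of the hits; introns are the
#' complementary gaps between consecutive exons within the cluster span.
#' Together they partition `[s_min, s_max]` without overlap.
#'
#' @param cluster A `locus_cluster`.
#' @return A list with data frames `exon_intervals` and `intron_intervals`
#'   (columns `start`, `end`, genomic coordinates).
#' @export
infer_exon_intron_boundaries <- function(cluster) {
  h <- cluster$hits
  sr <- IRanges::reduce(IRanges::IRanges(pmin(h$s_start, h$s_end),
                                         pmax(h$s_start, h$s_end)))
  gaps <- IRanges::gaps(sr, start = min(IRanges::start(sr)),
                        end = max(IRanges::end(sr)))
  list(
    exon_intervals = data.frame(start = IRanges::start(sr),
                                end = IRanges::end(sr)),
    intron_intervals = data.frame(start = IRanges::start(gaps),
                                  end = IRanges::end(gaps))
  )
}

#' Extract the full locus sequence (exons and introns) of a cluster
#'
#' Returns the genomic substring spanning the cluster; minus-strand loci are
#' reverse-complemented and their exon/intron intervals remapped so that all
#' coordinates are 1-based on the returned (transcription-oriented) sequence.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or character vector).
#' @param cluster A `locus_cluster`.
#' @return A list with `seq`, `exon_intervals`, `intron_intervals` (locus
#'   coordinates, transcription order) and `exon_seqs`, `intron_seqs`.
#' @export
extract_locus_sequence <- function(genome, cluster) {
  genome <- as_dna(genome)
  if (!cluster$subject_id %in% names(genome)) {
    stop("cluster subject '", cluster$subject_id, "' absent from genome")
  }
  full <- as.character(genome[[cluster$subject_id]])
  b <- infer_exon_intron_boundaries(cluster)
  s0 <- cluster$s_min
  seq <- substring(full, cluster$s_min, cluster$s_max)
  remap <- function(iv) {
    if (!nrow(iv)) return(data.frame(start = integer(), end = integer()))
    if (cluster$strand == "+") {
      data.frame(start = iv$start - s0 + 1L, end = iv$end - s0 + 1L)
    } else {
      L <- nchar(seq)
      out <- data.frame(start = L - (iv$end - s0 + 1L) + 1L,
                        end = L - (iv$start - s0 + 1L) + 1L)
      out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
  }
  if (cluster$strand == "-") seq <- revcomp(seq)
  ex <- remap(b$exon_intervals)
  rownames(ex) <- NULL
  intr <- remap(b$intron_intervals)
  rownames(intr) <- NULL
  list(seq = seq,
       exon_intervals = ex, intron_intervals = intr,
       exon_seqs = if (nrow(ex)) substring(seq, ex$start, ex$end) else character(),
       intron_seqs = if (nrow(intr)) substring(seq, intr$start, intr$end) else character())
}

#' Divergence filter between the loci of one query
#'
#' Single-locus queries pass. Two-locus queries pass only when the percent
#' divergence between the exon concatenations of the two loci is at least
#' `cfg$min_interlocus_divergence`.
#'
#' @param exon_concats Character vector of 1 or 2 exon concatenations.
#' @param cfg A [design_config()].
#' @param params [search_params()] used for the divergence alignment.
#' @return A list with `pass` and `divergence` (NA for single loci).
#' @export
interlocus_divergence_filter <- function(exon_concats, cfg = design_config(),
                                         params = search_params()) {
  if (length(exon_concats) == 1) return(list(pass = TRUE, divergence = NA_real_))
  if (length(exon_concats) != 2) {
    stop("divergence filter applies to queries with 1 or 2 loci")
  }
  d <- percent_divergence(exon_concats[[1]], exon_concats[[2]], params)
  list(pass = d >= cfg$min_interlocus_divergence, divergence = as.numeric(d))
}

#' Select intron targets
#'
#' Removes introns shorter than `cfg$min_intron_target_len` from each locus;
#' exons are untouched.
#'
#' @param loci List of probe loci (each with an `intron_seqs` field).
#' @param cfg A [design_config()].
#' @return The loci with filtered `intron_seqs`.
#' @export
select_intron_targets <- function(loci, cfg = design_config()) {
  lapply(loci, function(l) {
    l$intron_seqs <- l$intron_seqs[nchar(l$intron_seqs) >= cfg$min_intron_target_len]
    l
  })
}

#' Greedy collapse of near-identical sequences
#'
#' Sequences are processed in descending length order (ties broken by id); a
#' sequence joins the first existing cluster whose representative aligns to
#' it at or above `identity` percent identity computed over the shorter of
#' the two sequences, otherwise it founds a new cluster.
#'
#' @param seqs Named character vector (or DNAStringSet) of sequences.
#' @param identity Collapse threshold in percent (default 95).
#' @param params [search_params()] used for the alignments.
#' @return A list with `representatives` (named character vector in founding
#'   order) and `membership` (named character vector mapping every input id
#'   to its representative id).
#' @export
collapse_sequences <- function(seqs, identity = 95, params = search_params()) {
  seqs <- as.character(as_dna(seqs))
  if (!length(seqs)) stop("no sequences to collapse")
  if (is.null(names(seqs))) stop("sequences must be named")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  # shared-word prefilter: two sequences >= 95% identical over the shorter
  # one necessarily share an exact word, so pairs without one are skipped
  k <- min(params$word_size, min(nchar(seqs)))
  kmers <- lapply(seqs, function(s)
    unique(substring(s, seq_len(nchar(s) - k + 1),
                     seq_len(nchar(s) - k + 1) + k - 1)))
  reps <- character()
  membership <- character()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    assigned <- NA_character_
    for (rid in reps) {
      if (!any(kmers[[id]] %in% kmers[[rid]])) next
      r <- seqs[[rid]]
      df <- .cpp_search_pair(s, r, params$match, params$mismatch,
                             params$gap_open, params$gap_extend,
                             1L, 1L, params$word_size, Inf, FALSE)
      if (!nrow(df)) next
      pct <- df$matches[1] / min(nchar(s), nchar(r)) * 100
      if (pct >= identity) { assigned <- rid; break }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      assigned <- id
    }
    membership[[id]] <- assigned
  }
  list(representatives = seqs[reps], membership = membership)
}
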