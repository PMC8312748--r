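#' Parse locus ids from universal-probe representative names
#'
#' Universal probe sets such as Angiosperms353 name each representative
#' `taxon-locus`; the locus tag is the substring after the last hyphen by
#' default.
#'
#' @param ids Character vector of representative ids.
#' @param locus_regex Regex with one capture group extracting the locus tag.
#' @return Character vector of locus ids.
#' @export
parse_locus_ids <- function(ids, locus_regex = "-([^-]+)$") {
  m <- regmatches(ids, regexec(locus_regex, ids))
  tags <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
                 character(1))
  if (anyNA(tags)) {
    stop("representative id(s) without a parsable locus tag: ",
         paste(ids[is.na(tags)], collapse = ", "))
  }
  tags
}

# Longest hit wins; ties by higher bit score, then lexicographic ids.
order_hits_for_top <- function(hits) {
  order(-hits$align_length, -hits$bit_score, hits$query_id, hits$subject_id)
}

#' Best representative (and best matching transcript) per universal locus
#'
#' The hit table (probe representatives vs concatenated exon transcripts) is
#' sorted by hit length; per locus the longest hit selects both the winning
#' representative and the best matching genome transcript. Ties are broken
#' by higher bit score, then lexicographically.
#'
#' @param hits Hit data frame with representative ids as `query_id` and
#'   transcript ids as `subject_id`.
#' @param locus_regex Passed to [parse_locus_ids()].
#' @return A data frame with one row per locus that has hits: `locus_id`,
#'   `rep_id`, `transcript_id`, plus the chosen hit's columns.
#' @export
best_representative_per_locus <- function(hits, locus_regex = "-([^-]+)$") {
  if (!nrow(hits)) {
    return(data.frame(locus_id = character(), rep_id = character(),
                      transcript_id = character(), stringsAsFactors = FALSE))
  }
  hits$locus_id <- parse_locus_ids(hits$query_id, locus_regex)
  hits <- hits[order_hits_for_top(hits), , drop = FALSE]
  top <- hits[!duplicated(hits$locus_id), , drop = FALSE]
  out <- cbind(data.frame(locus_id = top$locus_id, rep_id = top$query_id,
                          transcript_id = top$subject_id,
                          stringsAsFactors = FALSE),
               top[, c("percent_identity", "align_length", "bit_score",
                       "q_start", "q_end", "s_start", "s_end")])
  rownames(out) <- NULL
  out[order(out$locus_id), , drop = FALSE]
}

#' Split a transcript model into per-exon sequence records
#'
#' @param transcript One row of the data frame returned by
#'   [extract_exon_transcripts()].
#' @return Named character vector of exon sequences, ids
#'   `{transcript_id}.exon{n}`, in transcription order; their concatenation
#'   equals the transcript sequence.
#' @export
split_transcript_to_exons <- function(transcript) {
  starts <- as.integer(strsplit(transcript$exon_starts, ",")[[1]])
  ends <- as.integer(strsplit(transcript$exon_ends, ",")[[1]])
  lens <- abs(ends - starts) + 1L
  offs <- cumsum(c(0L, lens[-length(lens)]))
  segs <- substring(transcript$seq, offs + 1L, offs + lens)
  stats::setNames(segs, sprintf("%s.exon%d", transcript$transcript_id,
                                seq_along(segs)))
}

#' Top hit per exon
#'
#' Per exon (query side of the hit table) the longest hit is kept, ties
#' broken by bit score then lexicographic ids; exons without hits are
#' absent from the result.
#'
#' @param hits Hit data frame with exon ids as `query_id`.
#' @return The hit data frame reduced to one row per exon.
#' @export
top_hit_per_exon <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order_hits_for_top(hits), , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Trim exons and representative to their top hit bounds and concatenate
#'
#' For each exon in transcription order, the exon is cut to the exon-side
#' interval of its top hit and the representative to the representative-side
#' interval (the hits come from searching exons as queries against the
#' representative as subject). Minus-orientation hits reverse-complement the
#' exon segment so both concatenations are co-directional. Exons without a
#' hit contribute nothing.
#'
#' @param rep_seq The chosen representative sequence (character).
#' @param exon_seqs Named character vector from
#'   [split_transcript_to_exons()].
#' @param per_exon_hits Hit data frame from [top_hit_per_exon()].
#' @return A list with `trimmed_probe_seq` (concatenated representative
#'   segments) and `trimmed_genome_seq` (concatenated exon segments).
#' @export
trim_and_concatenate <- function(rep_seq, exon_seqs, per_exon_hits) {
  probe_parts <- character()
  genome_parts <- character()
  for (ex_id in names(exon_seqs)) {
    row <- per_exon_hits[per_exon_hits$query_id == ex_id, , drop = FALSE]
    if (!nrow(row)) next
    row <- row[1, ]
    ex <- exon_seqs[[ex_id]]
    if (row$q_end > nchar(ex) || row$q_start < 1) {
      stop("hit coordinates out of bounds for exon ", ex_id)
    }
    lo <- min(row$s_start, row$s_end); hi <- max(row$s_start, row$s_end)
    if (hi > nchar(rep_seq)) {
      stop("hit coordinates out of bounds on the representative for exon ", ex_id)
    }
    ex_seg <- substring(ex, row$q_start, row$q_end)
    if (row$s_start > row$s_end) ex_seg <- revcomp(ex_seg)
    probe_parts <- c(probe_parts, substring(rep_seq, lo, hi))
    genome_parts <- c(genome_parts, ex_seg)
  }
  list(trimmed_probe_seq = paste(probe_parts, collapse = ""),
       trimmed_genome_seq = paste(genome_parts, collapse = ""))
}

#' Build optimized references from a universal probe set and genome(s)
#'
#' Implements the two-step optimization: (1) exon transcripts are extracted
#' from every supplied annotated genome and the universal representatives
#' are searched against them; per locus the longest hit selects the best
#' representative and the best matching transcript (across genomes). (2) The
#' chosen transcript is split into exons, the exons are searched back
#' against the chosen representative, only the top hit per exon is kept, and
#' both sides are trimmed to the hit bounds and concatenated. The result is
#' two references with exactly one record per retained locus: the trimmed
#' best representative ("bestHit-modified") and the trimmed genome
#' concatenation ("group-optimized"). Loci without hits are excluded and
#' reported.
#'
#' @param universal Named [Biostrings::DNAStringSet] of probe
#'   representatives (`taxon-locus` naming).
#' @param genomes List of named [Biostrings::DNAStringSet]s.
#' @param gffs List of feature data frames (one per genome).
#' @param params A [search_params()].
#' @param policy A [biotype_policy()] for the exon extraction.
#' @param locus_regex Passed to [parse_locus_ids()].
#' @param genome_labels Labels prefixed to transcript ids so ids stay unique
#'   across genomes.
#' @return A list with `bestHit_reference` and `group_optimized_reference`
#'   (named character vectors, one entry per locus), `report` (data frame:
#'   locus, chosen rep, transcript, exons kept, total bp per side) and
#'   `missing_loci`.
#' @export
build_optimized_references <- function(universal, genomes, gffs,
                                       params = search_params(),
                                       policy = biotype_policy(),
                                       locus_regex = "-([^-]+)$",
                                       genome_labels = NULL) {
  universal <- as_dna(universal)
  if (is.null(genome_labels)) genome_labels <- paste0("g", seq_along(genomes))
  stopifnot(length(genomes) == length(gffs),
            length(genomes) == length(genome_labels))
  tx_all <- list()
  for (i in seq_along(genomes)) {
    tx <- extract_exon_transcripts(genomes[[i]], gffs[[i]], policy)
    if (!nrow(tx)) next
    tx$transcript_id <- paste0(genome_labels[i], ":", tx$transcript_id)
    tx_all[[i]] <- tx
  }
  tx_all <- do.call(rbind, tx_all)
  if (is.null(tx_all) || !nrow(tx_all)) stop("no transcripts extracted from the genomes")
  tx_seqs <- stats::setNames(tx_all$seq, tx_all$transcript_id)

  hits <- local_search(universal, tx_seqs, params)
  best <- best_representative_per_locus(hits, locus_regex)
  all_loci <- sort(unique(parse_locus_ids(names(universal), locus_regex)))
  missing <- setdiff(all_loci, best$locus_id)

  best_ref <- character(); group_ref <- character()
  report <- list()
  for (r in seq_len(nrow(best))) {
    locus <- best$locus_id[r]
    rep_seq <- as.character(universal[[best$rep_id[r]]])
    tx_row <- tx_all[tx_all$transcript_id == best$transcript_id[r], , drop = FALSE][1, ]
    exons <- split_transcript_to_exons(tx_row)
    ex_hits <- local_search(exons, stats::setNames(rep_seq, best$rep_id[r]),
                            params)
    top <- top_hit_per_exon(ex_hits)
    tc <- trim_and_concatenate(rep_seq, exons, top)
    if (!nzchar(tc$trimmed_probe_seq)) next
    best_ref[[locus]] <- tc$trimmed_probe_seq
    group_ref[[locus]] <- tc$trimmed_genome_seq
    report[[locus]] <- data.frame(
      locus_id = locus, rep_id = best$rep_id[r],
      transcript_id = best$transcript_id[r],
      n_exons_kept = nrow(top), n_exons_total = length(exons),
      probe_bp = nchar(tc$trimmed_probe_seq),
      genome_bp = nchar(tc$trimmed_genome_seq),
      stringsAsFactors = FALSE)
  }
  list(bestHit_reference = best_ref,
       group_optimized_reference = group_ref,
       report = if (length(report)) do.call(rbind, report) else NULL,
       missing_loci = sort(union(missing, setdiff(best$locus_id, names(best_ref)))))
}
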