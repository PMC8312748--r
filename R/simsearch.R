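#' Search parameters for the built-in local-alignment engine
#'
#' Scoring defaults are BLASTN-like: match +2, mismatch -3, gap open 5,
#' gap extend 2 (a gap of length k costs open + k * extend). E-values use a
#' Karlin-Altschul approximation with K = 0.41, lambda = 0.625; they are
#' approximate and score thresholds should be preferred for exact work.
#'
#' @param e_value_max Maximum reported E-value (default 1e-5, the lowered
#'   threshold used for genome-scale locus discovery).
#' @param min_raw_score Optional raw-score floor; when given it overrides the
#'   score threshold derived from `e_value_max`.
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open,gap_extend Positive gap costs.
#' @param word_size Seed word size for large subjects (default 11).
#' @param max_hits_per_pair Cap on reported hits per query/subject/strand.
#' @param full_dp_limit Below this many DP cells the subject is scanned
#'   exhaustively without seeding.
#' @param both_strands Search the minus strand as well (default TRUE).
#' @return A `search_params` list.
#' @export
search_params <- function(e_value_max = 1e-5, min_raw_score = NULL,
                          match = 2L, mismatch = -3L,
                          gap_open = 5L, gap_extend = 2L,
                          word_size = 11L, max_hits_per_pair = 100L,
                          full_dp_limit = 2e6, both_strands = TRUE) {
  stopifnot(e_value_max > 0, match > 0, mismatch < 0,
            gap_open >= 0, gap_extend > 0, word_size >= 4)
  structure(list(e_value_max = e_value_max, min_raw_score = min_raw_score,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 max_hits_per_pair = as.integer(max_hits_per_pair),
                 full_dp_limit = full_dp_limit,
                 both_strands = isTRUE(both_strands),
                 K = 0.41, lambda = 0.625),
            class = "search_params")
}

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity", "align_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "e_value", "bit_score")

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), align_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             e_value = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the 12 standard columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Minus-strand hits are
#' encoded, as in BLAST, by `s_start > s_end`.
#'
#' @param path Path to a tab-separated hit table (may be empty).
#' @return A hit data frame.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("expected 12 tab-separated columns, found ", nf[nf != 12L][1],
         " at line ", which(nf != 12L)[1], " of '", path, "'")
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    align_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(hits$percent_identity) | is.na(hits$align_length) |
                 is.na(hits$q_start) | is.na(hits$q_end))
  if (length(bad)) stop("non-numeric field at line ", bad[1], " of '", path, "'")
  if (any(hits$q_start > hits$q_end)) {
    stop("q_start > q_end at line ", which(hits$q_start > hits$q_end)[1],
         " of '", path, "'")
  }
  hits
}

#' Write a hit table in BLAST tabular (outfmt 6) format
#'
#' @param hits A hit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                   hits$query_id, hits$subject_id, hits$percent_identity,
                   hits$align_length, hits$mismatches, hits$gap_opens,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   hits$e_value, hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}

# Raw score -> (bit score, E-value) under the Karlin-Altschul approximation.
score_to_bits <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

min_score_for_evalue <- function(params, m, n_total) {
  if (!is.null(params$min_raw_score)) return(as.integer(params$min_raw_score))
  # smallest integer S with E = m * n * 2^-bits(S) <= e_value_max
  s <- (log(params$K * m * n_total) - log(params$e_value_max)) / params$lambda
  max(1L, as.integer(ceiling(s)))
}

#' Exact local search of queries against subjects
#'
#' The engine performs repeated Smith-Waterman alignment with affine gaps,
#' masking each reported subject region before the next pass, until the best
#' remaining score falls below the threshold implied by
#' `params$e_value_max` (or `params$min_raw_score`). For subjects large
#' enough that exhaustive DP is wasteful, shared `word_size`-mers seed the
#' DP windows; small instances are always scanned exhaustively. Both strands
#' are searched; minus-strand hits have `s_start > s_end`. Results are
#' deterministic and sorted by query id, then descending bit score.
#'
#' @param queries,subjects Named [Biostrings::DNAStringSet]s or named
#'   character vectors.
#' @param params A [search_params()] object.
#' @return A hit data frame (BLAST outfmt 6 columns).
#' @export
local_search <- function(queries, subjects, params = search_params()) {
  qs <- as.character(as_dna(queries))
  ss <- as.character(as_dna(subjects))
  if (!length(qs) || !length(ss)) stop("non-empty query and subject sets required")
  if (is.null(names(qs)) || is.null(names(ss))) stop("sequences must be named")
  n_total <- sum(nchar(ss))
  out <- vector("list", length(qs) * length(ss))
  k <- 0L
  for (qi in seq_along(qs)) {
    q <- qs[[qi]]
    if (!grepl("[ACGT]", q)) {
      warning("query '", names(qs)[qi], "' has no unambiguous bases; skipped")
      next
    }
    min_s <- min_score_for_evalue(params, nchar(q), n_total)
    for (si in seq_along(ss)) {
      df <- .cpp_search_pair(q, ss[[si]], params$match, params$mismatch,
                             params$gap_open, params$gap_extend,
                             min_s, params$max_hits_per_pair,
                             params$word_size, params$full_dp_limit,
                             params$both_strands)
      if (!nrow(df)) next
      bits <- score_to_bits(df$raw_score, params)
      k <- k + 1L
      out[[k]] <- data.frame(
        query_id = names(qs)[qi], subject_id = names(ss)[si],
        percent_identity = df$matches / df$align_length * 100,
        align_length = df$align_length, mismatches = df$mismatches,
        gap_opens = df$gap_opens,
        q_start = df$q_start, q_end = df$q_end,
        s_start = df$s_start, s_end = df$s_end,
        e_value = nchar(q) * n_total * 2^(-bits),
        bit_score = bits, stringsAsFactors = FALSE
      )
    }
  }
  if (!k) return(empty_hits())
  hits <- do.call(rbind, out[seq_len(k)])
  hits <- hits[hits$e_value <= params$e_value_max, , drop = FALSE]
  hits <- hits[order(hits$query_id, -hits$bit_score,
                     hits$subject_id, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Percent divergence between two sequences
#'
#' Defined as 100 minus the percent identity (matches / alignment columns x
#' 100) of the highest-scoring local alignment between the two sequences.
#' Symmetric by construction: both orders are aligned and the higher-scoring
#' (on ties, the lower-divergence) alignment is used.
#'
#' @param a,b DNA strings.
#' @param params A [search_params()]; only the scoring fields are used.
#' @param min_score Minimal raw alignment score; if no alignment reaches it
#'   the function returns 100 with attribute `no_alignment = TRUE`.
#' @return Percent divergence in `[0, 100]`.
#' @export
percent_divergence <- function(a, b, params = search_params(), min_score = 20L) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("both sequences must be non-empty")
  one <- function(q, s) {
    df <- .cpp_search_pair(q, s, params$match, params$mismatch,
                           params$gap_open, params$gap_extend,
                           as.integer(min_score), 1L, params$word_size,
                           Inf, FALSE)
    if (!nrow(df)) return(NULL)
    list(score = df$raw_score[1],
         div = 100 - df$matches[1] / df$align_length[1] * 100)
  }
  ab <- one(a, b); ba <- one(b, a)
  cand <- Filter(Negate(is.null), list(ab, ba))
  if (!length(cand)) {
    return(structure(100, no_alignment = TRUE))
  }
  scores <- vapply(cand, `[[`, numeric(1), "score")
  divs <- vapply(cand, `[[`, numeric(1), "div")
  best <- which(scores == max(scores))
  min(divs[best])
}

#' Drop hits wholly contained in a longer hit of the same pair
#'
#' A hit is dropped when another hit with the same query and subject id (and
#' strand) covers both its query and subject intervals entirely and has
#' greater or equal alignment length. Overlapping partial hits are kept.
#'
#' @param hits A hit data frame.
#' @return The filtered hit data frame.
#' @export
dedupe_contained_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  strand <- ifelse(hits$s_start <= hits$s_end, "+", "-")
  smin <- pmin(hits$s_start, hits$s_end)
  smax <- pmax(hits$s_start, hits$s_end)
  keep <- rep(TRUE, nrow(hits))
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$query_id, hits$subject_id, strand, sep = "\r"))
  for (idx in groups) {
    if (length(idx) < 2) next
    for (i in idx) {
      for (j in idx) {
        if (i == j || !keep[i]) next
        contained <- hits$q_start[i] >= hits$q_start[j] &&
          hits$q_end[i] <= hits$q_end[j] &&
          smin[i] >= smin[j] && smax[i] <= smax[j] &&
          (hits$align_length[i] < hits$align_length[j] ||
             (hits$align_length[i] == hits$align_length[j] && i > j))
        if (contained) keep[i] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}
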