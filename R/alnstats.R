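#' Read a multi-FASTA alignment into a character matrix
#'
#' @param path Path to an aligned FASTA file (gaps `-`, missing `?`/`N`
#'   allowed).
#' @return Character matrix, taxa in rows (rownames = ids), columns =
#'   aligned positions, upper case.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("empty alignment file: ", path)
  alignment_matrix(stats::setNames(toupper(as.character(x)),
                                   sub("\\s.*$", "", names(x))))
}

#' Build an alignment matrix from aligned strings
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Character matrix (taxa x columns).
#' @export
alignment_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) {
    stop("alignment rows have unequal lengths")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Write an alignment matrix as FASTA
#'
#' @param aln Character matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

MISSING_CHARS <- c("-", "?", "N")

#' Trim rows then columns with excess missing data
#'
#' Single pass: first every row (taxon) with a missing-data fraction above
#' `max_missing` (strict >; exactly the threshold is kept) is removed,
#' computed on the original columns; then every column with a missing
#' fraction above the threshold with respect to the *retained* rows is
#' removed. The procedure is deliberately order-dependent (row first, then
#' column) and is not iterated to a fixpoint.
#'
#' @param aln Character matrix from [read_alignment()].
#' @param max_missing Maximum tolerated missing fraction (default 0.30).
#' @param missing_chars Symbols counted as missing (default `-`, `?`, `N`).
#' @return The trimmed matrix; attribute `empty` is TRUE when everything
#'   was removed.
#' @export
trim_alignment <- function(aln, max_missing = 0.30,
                           missing_chars = MISSING_CHARS) {
  miss <- matrix(aln %in% missing_chars, nrow = nrow(aln))
  keep_rows <- rowMeans(miss) <= max_missing
  aln2 <- aln[keep_rows, , drop = FALSE]
  if (nrow(aln2) == 0) {
    out <- aln2[, integer(), drop = FALSE]
    attr(out, "empty") <- TRUE
    return(out)
  }
  miss2 <- matrix(aln2 %in% missing_chars, nrow = nrow(aln2))
  keep_cols <- colMeans(miss2) <= max_missing
  out <- aln2[, keep_cols, drop = FALSE]
  attr(out, "empty") <- nrow(out) == 0 || ncol(out) == 0
  out
}

#' Discard alignments with too few sequences
#'
#' @param alignments List of alignment matrices.
#' @param min_taxa Minimum number of rows to keep (default 4; exactly 4 is
#'   kept).
#' @return The surviving alignments.
#' @export
discard_small <- function(alignments, min_taxa = 4L) {
  Filter(function(a) nrow(a) >= min_taxa, alignments)
}

#' Classify one alignment column
#'
#' Missing symbols and partial IUPAC ambiguities (anything but A, C, G, T)
#' are ignored. A column is `constant` with at most one distinct state,
#' `parsimony_informative` when at least two states each occur in at least
#' two sequences, and `variable_singleton` otherwise.
#'
#' @param column Character vector of states.
#' @return One of `"constant"`, `"variable_singleton"`,
#'   `"parsimony_informative"`.
#' @export
site_classification <- function(column) {
  states <- column[column %in% c("A", "C", "G", "T")]
  tab <- table(states)
  if (length(tab) <= 1) return("constant")
  if (sum(tab >= 2) >= 2) return("parsimony_informative")
  "variable_singleton"
}

#' Summary statistics of one alignment
#'
#' Variable sites are columns with at least two distinct unambiguous states
#' (singletons plus parsimony-informative); proportions are percentages of
#' the alignment length, kept at full precision (round only at report
#' time).
#'
#' @param aln Character matrix.
#' @return A one-row data frame: `n_taxa`, `length_bp`, `n_variable`,
#'   `prop_variable`, `n_parsimony_informative`,
#'   `prop_parsimony_informative`.
#' @export
alignment_summary <- function(aln) {
  L <- ncol(aln)
  cls <- if (L) apply(aln, 2, site_classification) else character()
  n_pi <- sum(cls == "parsimony_informative")
  n_var <- n_pi + sum(cls == "variable_singleton")
  data.frame(
    n_taxa = nrow(aln), length_bp = L,
    n_variable = n_var,
    prop_variable = if (L) n_var / L * 100 else 0,
    n_parsimony_informative = n_pi,
    prop_parsimony_informative = if (L) n_pi / L * 100 else 0
  )
}

#' Batch alignment summary
#'
#' Per-alignment statistics plus min/avg/max rows and totals, the row shape
#' used to report alignment characteristics per probe set.
#'
#' @param alignments Named list of alignment matrices.
#' @return A list with `per_alignment` (data frame, one row each),
#'   `summary` (data frame with `min`, `avg`, `max` rows over taxa, length,
#'   variable and PI proportions) and `totals` (`n_alignments`,
#'   `total_length_bp`, `total_parsimony_informative`).
#' @export
batch_summary <- function(alignments) {
  if (!length(alignments)) stop("no alignments to summarize")
  per <- do.call(rbind, lapply(alignments, alignment_summary))
  per <- cbind(data.frame(alignment = names(alignments) %||%
                            as.character(seq_along(alignments)),
                          stringsAsFactors = FALSE), per)
  rownames(per) <- NULL
  stat_cols <- c("n_taxa", "length_bp", "n_variable", "prop_variable",
                 "n_parsimony_informative", "prop_parsimony_informative")
  summ <- rbind(min = vapply(per[stat_cols], min, numeric(1)),
                avg = vapply(per[stat_cols], mean, numeric(1)),
                max = vapply(per[stat_cols], max, numeric(1)))
  list(per_alignment = per,
       summary = as.data.frame(summ),
       totals = data.frame(
         n_alignments = nrow(per),
         total_length_bp = sum(per$length_bp),
         total_variable = sum(per$n_variable),
         total_parsimony_informative = sum(per$n_parsimony_informative)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
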