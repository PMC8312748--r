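#' Construct a recovery matrix
#'
#' @param recovered Numeric matrix of recovered lengths (bp), samples in
#'   rows, loci in columns, dimnames set.
#' @param target_len Named numeric vector of per-locus target lengths (bp);
#'   for loci with multiple representatives of differing lengths this is
#'   their mean (see [mean_target_length()]).
#' @return A `recovery_matrix`: list with `samples`, `loci`, `recovered`,
#'   `target_len` and `fraction` (recovered / target, capped at 1).
#' @export
recovery_matrix <- function(recovered, target_len) {
  stopifnot(is.matrix(recovered), !is.null(rownames(recovered)),
            !is.null(colnames(recovered)))
  target_len <- target_len[colnames(recovered)]
  if (anyNA(target_len)) stop("target length missing for some loci")
  if (any(target_len <= 0)) stop("target lengths must be positive")
  if (any(recovered < 0)) stop("recovered lengths must be non-negative")
  fraction <- sweep(recovered, 2, target_len, "/")
  if (any(fraction > 1)) {
    warning(sum(fraction > 1),
            " cell(s) with recovered length above the target; fraction capped at 1")
    fraction[fraction > 1] <- 1
  }
  structure(list(samples = rownames(recovered), loci = colnames(recovered),
                 recovered = recovered, target_len = target_len,
                 fraction = fraction),
            class = "recovery_matrix")
}

#' Load a HybPiper-style seq_lengths table
#'
#' Dialect: row 1 holds locus ids (first cell a label such as `Species`),
#' row 2 the reference target lengths (`MeanLength`), and each further row
#' one sample's recovered lengths.
#'
#' @param path Path to the tab-separated table.
#' @return A [recovery_matrix()].
#' @export
load_seq_lengths <- function(path) {
  if (!file.exists(path)) stop("seq_lengths table not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) < 3) stop("seq_lengths table needs locus, reference and sample rows")
  loci <- as.character(raw[1, -1])
  parse_num <- function(row, what) {
    v <- suppressWarnings(as.numeric(raw[row, -1]))
    if (anyNA(v)) {
      stop("non-numeric cell at row ", row, ", column ",
           which(is.na(v))[1] + 1, " (", what, ")")
    }
    v
  }
  target <- stats::setNames(parse_num(2, "reference length"), loci)
  samples <- as.character(raw[-(1:2), 1])
  rec <- t(vapply(seq_len(nrow(raw) - 2) + 2,
                  function(r) parse_num(r, "recovered length"),
                  numeric(length(loci))))
  dimnames(rec) <- list(samples, loci)
  recovery_matrix(rec, target)
}

#' Mean target length of a multi-representative locus
#'
#' @param representative_lengths Numeric vector of representative lengths.
#' @return Their arithmetic mean.
#' @export
mean_target_length <- function(representative_lengths) {
  stopifnot(length(representative_lengths) >= 1)
  mean(representative_lengths)
}

#' Enrichment efficiency
#'
#' Percentage of reads mapping to the targeted loci.
#'
#' @param mapped_reads,total_reads Read counts (vectors recycle).
#' @return `mapped / total * 100`.
#' @export
enrichment_efficiency <- function(mapped_reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(mapped_reads > total_reads)) stop("mapped_reads exceed total_reads")
  if (any(mapped_reads < 0)) stop("mapped_reads must be non-negative")
  mapped_reads / total_reads * 100
}

#' Loci with zero data across all samples
#'
#' @param mat A [recovery_matrix()].
#' @return A list with `count`, `pct` and `loci` (ids).
#' @export
zero_data_loci <- function(mat) {
  zero <- colSums(mat$recovered > 0) == 0
  list(count = sum(zero), pct = mean(zero) * 100,
       loci = mat$loci[zero])
}

#' Threshold grid over target length and accessions presence
#'
#' A locus counts at grid cell (L, P) when the proportion of samples whose
#' recovered fraction of that locus is at least L is itself at least P: the
#' "accessions presence" is evaluated jointly at the same length level L
#' (set `joint = FALSE` for the any-data reading, where presence means a
#' recovered length > 0).
#'
#' @param mat A [recovery_matrix()].
#' @param length_thresholds Fractions of the target length.
#' @param presence_thresholds Fractions of samples.
#' @param joint Evaluate presence at the length threshold (default) or as
#'   any data.
#' @return A `threshold_summary`: list with `grid` (data frame
#'   `length_threshold`, `presence_threshold`, `n_loci`, `pct_loci`),
#'   `n_zero_data`, `pct_zero_data`, `n_loci_total`.
#' @export
threshold_summary <- function(mat,
                              length_thresholds = c(0.25, 0.50, 0.75),
                              presence_thresholds = c(0.50, 0.75),
                              joint = TRUE) {
  nl <- length(mat$loci)
  grid <- expand.grid(length_threshold = length_thresholds,
                      presence_threshold = presence_thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$length_threshold, grid$presence_threshold), ,
               drop = FALSE]
  rownames(grid) <- NULL
  n <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    L <- grid$length_threshold[r]; P <- grid$presence_threshold[r]
    ok <- if (joint) mat$fraction >= L else mat$recovered > 0
    presence <- colMeans(ok)
    n[r] <- sum(presence >= P)
  }
  grid$n_loci <- n
  grid$pct_loci <- n / nl * 100
  zd <- zero_data_loci(mat)
  structure(list(grid = grid, n_zero_data = zd$count,
                 pct_zero_data = zd$pct, n_loci_total = nl),
            class = "threshold_summary")
}

#' Export a recovery heatmap table
#'
#' Writes the fraction matrix (samples as rows, loci as columns, reference
#' column order preserved) as TSV; optionally draws a heatmap.
#'
#' @param mat A [recovery_matrix()].
#' @param path Output TSV path.
#' @param plot Draw a heatmap via the pheatmap package (if installed).
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(mat, path, plot = FALSE) {
  df <- data.frame(sample = mat$samples, mat$fraction, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (plot && requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(mat$fraction, cluster_rows = FALSE,
                       cluster_cols = FALSE)
  }
  invisible(path)
}

#' Re-import an exported heatmap table
#'
#' @param path TSV written by [export_heatmap()].
#' @return A numeric fraction matrix.
#' @export
read_heatmap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
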