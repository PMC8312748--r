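#' Configuration of the probe-design filter cascade
#'
#' Numeric thresholds of the locus-discovery cascade. Boundary semantics are
#' exactly as used throughout the cascade and stated per field below
#' ("exceeding" thresholds are strict, ">=" / "<=" thresholds are inclusive):
#'
#' \describe{
#'   \item{min_hit_len}{hits must *exceed* this length (strict >; 70 bp).}
#'   \item{min_hit_query_frac}{hits must *exceed* this fraction of the query
#'     length (strict >; 0.10).}
#'   \item{min_hit_identity}{hit percent identity must be >= this (80).}
#'   \item{max_cluster_gap}{consecutive hits separated by more than this many
#'     bases start a new locus (inclusive; 10000 bp).}
#'   \item{max_loci_per_query_initial}{queries with more loci than this after
#'     clustering are discarded (6).}
#'   \item{min_sum_coverage}{merged query coverage of all hits of a locus
#'     must be >= this fraction (0.90).}
#'   \item{min_sum_identity}{alignment-length-weighted mean identity of the
#'     hits of a locus must be >= this (90).}
#'   \item{min_single_hit_len}{every hit must be >= this long (100 bp, in
#'     accordance with a 100-bp bait length).}
#'   \item{max_intron_len}{every inter-hit subject gap within a locus must be
#'     <= this (1200 bp).}
#'   \item{max_loci_per_query}{queries with more surviving loci than this are
#'     discarded at the refined stage (2).}
#'   \item{min_interlocus_divergence}{two-locus queries are kept only if the
#'     exon-concatenation divergence between the loci is >= this percent (6).}
#'   \item{max_ortholog_divergence}{single-copy loci are kept only if the
#'     exon divergence between the two genomes is <= this percent (15).}
#'   \item{min_exon_len}{exons shorter than this are excluded from targets
#'     (>= 80 bp kept).}
#'   \item{collapse_identity}{greedy collapse threshold, percent identity
#'     over the shorter sequence (>= 95 collapses).}
#'   \item{min_intron_target_len}{introns >= this long are selected as
#'     intron targets (80 bp).}
#' }
#'
#' @param min_hit_len,min_hit_query_frac,min_hit_identity,max_cluster_gap,max_loci_per_query_initial,min_sum_coverage,min_sum_identity,min_single_hit_len,max_intron_len,max_loci_per_query,min_interlocus_divergence,max_ortholog_divergence,min_exon_len,collapse_identity,min_intron_target_len
#'   See Details.
#' @return A `design_config` list.
#' @export
design_config <- function(min_hit_len = 70L,
                          min_hit_query_frac = 0.10,
                          min_hit_identity = 80,
                          max_cluster_gap = 10000L,
                          max_loci_per_query_initial = 6L,
                          min_sum_coverage = 0.90,
                          min_sum_identity = 90,
                          min_single_hit_len = 100L,
                          max_intron_len = 1200L,
                          max_loci_per_query = 2L,
                          min_interlocus_divergence = 6,
                          max_ortholog_divergence = 15,
                          min_exon_len = 80L,
                          collapse_identity = 95,
                          min_intron_target_len = 80L) {
  cfg <- list(min_hit_len = min_hit_len,
              min_hit_query_frac = min_hit_query_frac,
              min_hit_identity = min_hit_identity,
              max_cluster_gap = max_cluster_gap,
              max_loci_per_query_initial = max_loci_per_query_initial,
              min_sum_coverage = min_sum_coverage,
              min_sum_identity = min_sum_identity,
              min_single_hit_len = min_single_hit_len,
              max_intron_len = max_intron_len,
              max_loci_per_query = max_loci_per_query,
              min_interlocus_divergence = min_interlocus_divergence,
              max_ortholog_divergence = max_ortholog_divergence,
              min_exon_len = min_exon_len,
              collapse_identity = collapse_identity,
              min_intron_target_len = min_intron_target_len)
  num <- unlist(cfg)
  if (any(num < 0)) stop("all design thresholds must be non-negative")
  if (min_sum_coverage > 1) stop("min_sum_coverage is a fraction in [0, 1]")
  if (min_sum_identity > 100 || collapse_identity > 100 ||
      min_hit_identity > 100) {
    stop("identity thresholds are percentages in [0, 100]")
  }
  structure(cfg, class = "design_config")
}
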