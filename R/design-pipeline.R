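#' Run the per-genome locus-discovery cascade
#'
#' Orchestrates, for one genome: local search (or a supplied precomputed hit
#' table), the initial hit filter, containment dedup, clustering, the
#' initial locus-count filter, the refined per-locus filter, the refined
#' locus-count filter, and the inter-locus divergence filter. Every
#' elimination is recorded in an audit table.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or character vector).
#' @param queries Named [Biostrings::DNAStringSet] (or character vector).
#' @param cfg A [design_config()].
#' @param params A [search_params()].
#' @param hits Optional precomputed hit data frame (BLAST outfmt 6 columns);
#'   when `NULL` the built-in engine is used.
#' @return A list with `report` (per retained query: a list of loci, each
#'   carrying its cluster, extracted sequence and exon concatenation),
#'   `audit` (data frame `query_id`, `stage`, `verdict`,
#'   `failing_criterion`) and `hits` (the raw hit table used).
#' @export
run_design_cascade <- function(genome, queries, cfg = design_config(),
                               params = search_params(), hits = NULL) {
  genome <- as_dna(genome)
  queries <- as_dna(queries)
  qlen <- stats::setNames(Biostrings::width(queries), names(queries))
  if (is.null(hits)) hits <- local_search(queries, genome, params)
  audit <- list()
  note <- function(query, stage, verdict, crit = "") {
    audit[[length(audit) + 1L]] <<- data.frame(
      query_id = query, stage = stage, verdict = verdict,
      failing_criterion = crit, stringsAsFactors = FALSE)
  }

  all_q <- names(queries)
  f1 <- initial_hit_filter(hits, qlen, cfg)
  f1 <- dedupe_contained_hits(f1)
  lost <- setdiff(all_q, unique(f1$query_id))
  for (q in lost) {
    note(q, "initial_hit_filter", "dropped",
         if (q %in% hits$query_id) "no_hit_passed_initial_filter" else "no_hits")
  }

  clusters <- cluster_hits_to_loci(f1, cfg)
  qids <- vapply(clusters, `[[`, character(1), "query_id")
  kept1 <- drop_promiscuous_queries(clusters, cfg, "initial")
  for (q in setdiff(unique(qids),
                    unique(vapply(kept1, `[[`, character(1), "query_id")))) {
    note(q, "locus_count_initial", "dropped", "max_loci_per_query_initial")
  }

  refined <- list()
  for (cl in kept1) {
    r <- refined_locus_filter(cl, qlen[[cl$query_id]], cfg)
    if (r$pass) {
      cl$metrics <- r$metrics
      refined[[length(refined) + 1L]] <- cl
    } else {
      note(cl$query_id, "refined_locus_filter", "locus_dropped",
           paste(names(r$flags)[r$flags], collapse = "+"))
    }
  }
  rq <- vapply(refined, `[[`, character(1), "query_id")
  for (q in setdiff(unique(vapply(kept1, `[[`, character(1), "query_id")),
                    unique(rq))) {
    note(q, "refined_locus_filter", "dropped", "no_locus_passed_refined_filter")
  }
  kept2 <- drop_promiscuous_queries(refined, cfg, "refined")
  rq2 <- vapply(kept2, `[[`, character(1), "query_id")
  for (q in setdiff(unique(rq), unique(rq2))) {
    note(q, "locus_count_refined", "dropped", "max_loci_per_query")
  }

  report <- list()
  for (q in unique(rq2)) {
    loci <- kept2[rq2 == q]
    loci <- lapply(loci, function(cl) {
      ext <- extract_locus_sequence(genome, cl)
      list(cluster = cl, extraction = ext,
           exon_concat = paste(ext$exon_seqs, collapse = ""))
    })
    dv <- interlocus_divergence_filter(
      vapply(loci, `[[`, character(1), "exon_concat"), cfg, params)
    if (!dv$pass) {
      note(q, "interlocus_divergence", "dropped", "min_interlocus_divergence")
      next
    }
    note(q, "per_genome_cascade", "retained",
         if (length(loci) == 2) sprintf("paralog_pair_divergence=%.2f", dv$divergence)
         else "")
    report[[q]] <- list(loci = loci, divergence = dv$divergence)
  }
  list(report = report,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(query_id = character(), stage = character(),
                    verdict = character(), failing_criterion = character()),
       hits = hits)
}

#' Validate per-query locus sets across two genomes
#'
#' A query is retained only when it survives the per-genome cascade in both
#' genomes with identical locus counts and, for single-copy queries, an exon
#' divergence between the two genomes' loci of at most
#' `cfg$max_ortholog_divergence` percent. Exons shorter than
#' `cfg$min_exon_len` are excluded from the targets; a locus survives that
#' exclusion only if at least one exon remains, and a query is dropped if
#' the exclusion breaks the equality of locus counts.
#'
#' @param report_a,report_b `report` elements from [run_design_cascade()]
#'   run on the two genomes with the same queries.
#' @param cfg A [design_config()].
#' @param params A [search_params()].
#' @return A list with `queries` (per retained query: loci of both genomes,
#'   ortholog divergence) and `audit` rows for dropped queries.
#' @export
cross_genome_validate <- function(report_a, report_b, cfg = design_config(),
                                  params = search_params()) {
  audit <- list()
  note <- function(query, verdict, crit) {
    audit[[length(audit) + 1L]] <<- data.frame(
      query_id = query, stage = "cross_genome", verdict = verdict,
      failing_criterion = crit, stringsAsFactors = FALSE)
  }
  out <- list()
  for (q in union(names(report_a), names(report_b))) {
    a <- report_a[[q]]; b <- report_b[[q]]
    if (is.null(a) || is.null(b)) {
      note(q, "dropped", "absent_in_one_genome")
      next
    }
    na <- length(a$loci); nb <- length(b$loci)
    if (na != nb) {
      note(q, "dropped", "locus_count_mismatch")
      next
    }
    orth_div <- NA_real_
    if (na == 1L) {
      orth_div <- as.numeric(percent_divergence(a$loci[[1]]$exon_concat,
                                                b$loci[[1]]$exon_concat, params))
      if (orth_div > cfg$max_ortholog_divergence) {
        note(q, "dropped", "max_ortholog_divergence")
        next
      }
      pairing <- c(1L)
    } else {
      # pair paralogous loci across genomes by minimal total divergence
      d <- matrix(NA_real_, na, na)
      for (i in seq_len(na)) for (j in seq_len(na)) {
        d[i, j] <- as.numeric(percent_divergence(a$loci[[i]]$exon_concat,
                                                 b$loci[[j]]$exon_concat, params))
      }
      if (d[1, 1] + d[2, 2] <= d[1, 2] + d[2, 1]) pairing <- c(1L, 2L)
      else pairing <- c(2L, 1L)
    }
    drop_short <- function(locus) {
      keep <- nchar(locus$extraction$exon_seqs) >= cfg$min_exon_len
      locus$extraction$exon_seqs <- locus$extraction$exon_seqs[keep]
      locus$extraction$exon_intervals <-
        locus$extraction$exon_intervals[keep, , drop = FALSE]
      locus
    }
    a$loci <- lapply(a$loci, drop_short)
    b$loci <- lapply(b$loci, drop_short)
    ok_a <- vapply(a$loci, function(l) length(l$extraction$exon_seqs) > 0, logical(1))
    ok_b <- vapply(b$loci, function(l) length(l$extraction$exon_seqs) > 0, logical(1))
    if (!all(ok_a) || !all(ok_b)) {
      if (sum(ok_a) != sum(ok_b) || sum(ok_a) == 0) {
        note(q, "dropped", "min_exon_len")
        next
      }
      a$loci <- a$loci[ok_a]; b$loci <- b$loci[ok_b]
    }
    note(q, "retained", if (na == 1)
      sprintf("ortholog_divergence=%.2f", orth_div) else "paralog_pair")
    out[[q]] <- list(loci_a = a$loci, loci_b = b$loci, pairing = pairing,
                     copy_number = length(a$loci), ortholog_divergence = orth_div)
  }
  list(queries = out,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(query_id = character(), stage = character(),
                    verdict = character(), failing_criterion = character()))
}

#' Design a probe target set from two genomes and a query set
#'
#' Runs the full cascade on both genomes, validates across genomes, selects
#' intron targets, collapses near-identical extracted sequences within each
#' genome, and assembles the final probe target set with a per-query audit
#' trail and provenance. The result is deterministic for identical inputs
#' and configuration.
#'
#' @param genome_a,genome_b Named [Biostrings::DNAStringSet]s.
#' @param queries Named [Biostrings::DNAStringSet] of query transcripts; an
#'   empty set yields an empty target set.
#' @param cfg A [design_config()].
#' @param params A [search_params()].
#' @param hits_a,hits_b Optional precomputed hit tables.
#' @param labels Genome labels used in locus ids.
#' @return A `probe_target_set`: list with `loci` (each a `probe_locus` with
#'   `locus_id`, `paralog_group_id`, `source_query_id`, `genome_label`,
#'   `exon_seqs`, `intron_seqs`, `copy_number`), `audit`, `provenance`,
#'   `total_exon_bp`.
#' @export
design_probe_set <- function(genome_a, genome_b, queries,
                             cfg = design_config(), params = search_params(),
                             hits_a = NULL, hits_b = NULL,
                             labels = c("A", "B")) {
  queries <- as_dna(queries)
  provenance <- list(
    config = unclass(cfg),
    labels = labels,
    n_queries = length(queries),
    genome_bp = c(sum(Biostrings::width(as_dna(genome_a))),
                  sum(Biostrings::width(as_dna(genome_b))))
  )
  if (!length(queries)) {
    return(structure(list(loci = list(),
                          audit = data.frame(query_id = character(),
                                             stage = character(),
                                             verdict = character(),
                                             failing_criterion = character()),
                          provenance = provenance, total_exon_bp = 0L),
                     class = "probe_target_set"))
  }
  run_a <- run_design_cascade(genome_a, queries, cfg, params, hits_a)
  run_b <- run_design_cascade(genome_b, queries, cfg, params, hits_b)
  cv <- cross_genome_validate(run_a$report, run_b$report, cfg, params)

  loci <- list()
  for (q in names(cv$queries)) {
    entry <- cv$queries[[q]]
    cn <- entry$copy_number
    for (side in c("a", "b")) {
      gl <- labels[if (side == "a") 1 else 2]
      ll <- entry[[paste0("loci_", side)]]
      for (i in seq_along(ll)) {
        ext <- ll[[i]]$extraction
        loci[[length(loci) + 1L]] <- structure(
          list(locus_id = sprintf("%s|%s|L%d", q, gl, i),
               paralog_group_id = q, source_query_id = q, genome_label = gl,
               exon_seqs = ext$exon_seqs, intron_seqs = ext$intron_seqs,
               copy_number = cn),
          class = "probe_locus")
      }
    }
  }
  loci <- select_intron_targets(loci, cfg)

  # within-genome collapse of the extracted exon sequences
  if (length(loci)) {
    for (gl in labels) {
      sel <- vapply(loci, function(l) l$genome_label == gl, logical(1))
      if (!any(sel)) next
      seqs <- unlist(lapply(which(sel), function(i) {
        s <- loci[[i]]$exon_seqs
        stats::setNames(s, sprintf("%s|exon%d", loci[[i]]$locus_id,
                                   seq_along(s)))
      }))
      if (!length(seqs)) next
      coll <- collapse_sequences(seqs, cfg$collapse_identity, params)
      reps <- names(coll$representatives)
      for (i in which(sel)) {
        ids <- sprintf("%s|exon%d", loci[[i]]$locus_id,
                       seq_along(loci[[i]]$exon_seqs))
        loci[[i]]$exon_seqs <- loci[[i]]$exon_seqs[ids %in% reps]
      }
    }
    loci <- Filter(function(l) length(l$exon_seqs) > 0, loci)
  }

  audit <- rbind(run_a$audit, run_b$audit, cv$audit)
  audit <- audit[order(audit$query_id, audit$stage), , drop = FALSE]
  rownames(audit) <- NULL
  structure(list(
    loci = loci, audit = audit, provenance = provenance,
    total_exon_bp = sum(vapply(loci, function(l)
      sum(nchar(l$exon_seqs)), numeric(1)))
  ), class = "probe_target_set")
}

#' @export
print.probe_target_set <- function(x, ...) {
  qs <- unique(vapply(x$loci, `[[`, character(1), "paralog_group_id"))
  cat("probe_target_set:", length(x$loci), "loci from", length(qs),
      "queries;", x$total_exon_bp, "exonic bp\n")
  invisible(x)
}

#' Queries retained in a probe target set
#'
#' @param x A `probe_target_set`.
#' @return Sorted character vector of retained query (paralog group) ids.
#' @export
retained_queries <- function(x) {
  sort(unique(vapply(x$loci, `[[`, character(1), "paralog_group_id")))
}

#' Write a probe target set to disk
#'
#' Emits `targets_exons.fasta`, `targets_introns.fasta` (headers
#' `>{paralog_group_id}|{locus_id}|exon{n}` / `intron{n}`), `audit.tsv` and
#' `provenance.json` into `dir`.
#'
#' @param x A `probe_target_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_probe_target_set <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gather <- function(field, tag) {
    out <- character()
    for (l in x$loci) {
      s <- l[[field]]
      if (!length(s)) next
      names(s) <- sprintf("%s|%s|%s%d", l$paralog_group_id, l$locus_id,
                          tag, seq_along(s))
      out <- c(out, s)
    }
    out
  }
  ex <- gather("exon_seqs", "exon")
  intr <- gather("intron_seqs", "intron")
  if (length(ex)) write_fasta(ex, file.path(dir, "targets_exons.fasta"))
  if (length(intr)) write_fasta(intr, file.path(dir, "targets_introns.fasta"))
  utils::write.table(x$audit, file.path(dir, "audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(x$provenance, list(total_exon_bp = x$total_exon_bp)),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
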