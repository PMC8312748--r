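#' Read a FASTA file into a DNAStringSet
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' the remainder is kept as the `description` metadata column. Sequences are
#' upper-cased on read.
#'
#' @param path Path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return A [Biostrings::DNAStringSet] named by sequence id, with a
#'   `description` column in its `mcols`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop("FASTA record with empty id in '", path, "' (record ",
         which(ids == "")[1], ")")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(x) && any(Biostrings::width(x) == 0)) {
    stop("empty sequence for record '", ids[Biostrings::width(x) == 0][1],
         "' in '", path, "'")
  }
  names(x) <- ids
  S4Vectors::mcols(x)$description <- desc
  x
}

#' Write sequences to a FASTA file
#'
#' Round-trips [read_fasta()]: descriptions stored in `mcols` are appended to
#' the headers.
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  seqs <- as_dna(seqs)
  nm <- names(seqs)
  if (is.null(nm)) stop("sequences must be named")
  desc <- S4Vectors::mcols(seqs)$description
  if (!is.null(desc) && any(nzchar(desc))) {
    names(seqs) <- ifelse(nzchar(desc), paste(nm, desc), nm)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

# Coerce character vectors to DNAStringSet, preserving names.
as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(toupper(x))
}

#' Parse a GFF3 annotation file
#'
#' Wraps [rtracklayer::import()] and flattens the result to a data frame of
#' features with 1-based inclusive coordinates. `ID` and `Parent` attributes
#' are resolved into `id` / `parent_id` columns; a feature naming an unknown
#' parent is kept (orphaned) with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns `seq_id`, `feature_type`, `start`,
#'   `end`, `strand`, `id`, `parent_id` (NA if none), `biotype`.
#' @export
parse_gff <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  md <- S4Vectors::mcols(gr)
  n <- length(gr)
  get_col <- function(col) {
    if (col %in% colnames(md)) as.character(md[[col]]) else rep(NA_character_, n)
  }
  parent <- if ("Parent" %in% colnames(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, n)
  biotype <- get_col("biotype")
  if (all(is.na(biotype))) biotype <- get_col("gene_biotype")
  feats <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    feature_type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = get_col("ID"),
    parent_id = parent,
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  if (any(feats$end < feats$start)) {
    bad <- which(feats$end < feats$start)[1]
    stop("GFF3 feature with end < start at record ", bad, " in '", path, "'")
  }
  known <- feats$id[!is.na(feats$id)]
  orphan <- !is.na(feats$parent_id) & !(feats$parent_id %in% known)
  if (any(orphan)) {
    warning(sum(orphan), " feature(s) reference an unknown parent; kept orphaned")
  }
  feats
}

# Write a feature data frame as GFF3 (plain 9-column formatting).
write_gff3 <- function(feats, path, source = "probeforge") {
  attrs <- ifelse(
    is.na(feats$parent_id) | feats$parent_id == "",
    paste0("ID=", feats$id),
    paste0("ID=", feats$id, ";Parent=", feats$parent_id)
  )
  bt <- !is.na(feats$biotype) & nzchar(feats$biotype)
  attrs[bt] <- paste0(attrs[bt], ";biotype=", feats$biotype[bt])
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   feats$seq_id, source, feats$feature_type,
                   as.integer(feats$start), as.integer(feats$end),
                   feats$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Biotype inclusion policy for exon-transcript extraction
#'
#' Defaults follow the extraction rule used for annotated apple genomes:
#' protein-coding genes, long non-coding RNAs and pseudogenes (including
#' transcribed ones) are included; rRNA, tRNA, miRNA, snoRNA and all other
#' RNA classes are excluded, as are sequences whose seq id matches a
#' plastid/mitochondrial pattern. Matching is case-insensitive and an alias
#' table maps annotation-dialect variants onto canonical terms.
#'
#' @param include Character vector of included biotypes.
#' @param exclude Character vector of excluded biotypes.
#' @param aliases Named character vector mapping biotype spellings to
#'   canonical terms.
#' @param organelle_patterns Regexes applied to sequence ids; matching
#'   sequences are excluded wholesale.
#' @return A `biotype_policy` list.
#' @export
biotype_policy <- function(include = c("protein_coding", "lnc_rna", "pseudogene"),
                           exclude = c("rrna", "trna", "mirna", "snorna",
                                       "snrna", "other_rna", "ncrna"),
                           aliases = c(lncrna = "lnc_rna",
                                       lnc_RNA = "lnc_rna",
                                       pseudogenic_transcript = "pseudogene",
                                       transcribed_pseudogene = "pseudogene"),
                           organelle_patterns = c("^chlo", "^mito", "^Pltd", "^MT$")) {
  include <- tolower(include)
  exclude <- tolower(exclude)
  if (length(intersect(include, exclude))) {
    stop("biotype policy include and exclude sets overlap")
  }
  structure(list(include = include, exclude = exclude,
                 aliases = stats::setNames(tolower(aliases), tolower(names(aliases))),
                 organelle_patterns = organelle_patterns),
            class = "biotype_policy")
}

canonical_biotype <- function(x, policy) {
  x <- tolower(x)
  hit <- match(x, names(policy$aliases))
  x[!is.na(hit)] <- policy$aliases[hit[!is.na(hit)]]
  x
}

#' Extract and concatenate annotated exons into transcript sequences
#'
#' For every transcript (mRNA or other transcript-level feature) whose parent
#' gene's biotype passes the policy, exons are sorted 5'->3' in transcription
#' order, extracted from the genome, and concatenated; minus-strand models
#' are reverse-complemented. Genes that carry exons directly (flat
#' annotations without transcript children) yield one implicit transcript.
#' Genes with multiple transcript children yield multiple models.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param features Feature data frame from [parse_gff()].
#' @param policy A [biotype_policy()].
#' @return A data frame with columns `transcript_id`, `gene_id`, `seq_id`,
#'   `strand`, `n_exons`, `exon_starts`, `exon_ends` (comma-separated,
#'   transcription order) and a `seq` column of concatenated sequences.
#' @export
extract_exon_transcripts <- function(genome, features, policy = biotype_policy()) {
  genome <- as_dna(genome)
  exons <- features[features$feature_type == "exon", , drop = FALSE]
  if (nrow(exons) == 0) return(empty_transcripts())
  missing_seq <- setdiff(unique(exons$seq_id), names(genome))
  if (length(missing_seq)) {
    stop("annotation references sequences absent from the genome: ",
         paste(missing_seq, collapse = ", "))
  }
  genes <- features[features$feature_type %in%
                      c("gene", "pseudogene"), , drop = FALSE]
  gene_bt <- stats::setNames(canonical_biotype(
    ifelse(is.na(genes$biotype) & genes$feature_type == "pseudogene",
           "pseudogene", genes$biotype), policy), genes$id)
  # map every feature id to its gene ancestor (one level of nesting suffices
  # for gene -> transcript -> exon; flat gene -> exon also supported)
  parent_of <- stats::setNames(features$parent_id, features$id)
  gene_ids <- genes$id
  resolve_gene <- function(pid) {
    if (is.na(pid)) return(NA_character_)
    if (pid %in% gene_ids) return(pid)
    gp <- parent_of[[pid]]
    if (!is.null(gp) && !is.na(gp) && gp %in% gene_ids) return(gp)
    NA_character_
  }
  out <- list()
  widths <- stats::setNames(Biostrings::width(genome), names(genome))
  split_parent <- split(seq_len(nrow(exons)), exons$parent_id)
  for (pid in names(split_parent)) {
    ex <- exons[split_parent[[pid]], , drop = FALSE]
    gid <- resolve_gene(pid)
    if (is.na(gid)) next
    bt <- gene_bt[[gid]]
    if (is.null(bt) || is.na(bt)) bt <- "protein_coding"
    if (!(bt %in% policy$include) || bt %in% policy$exclude) next
    if (any(vapply(policy$organelle_patterns, grepl, logical(1),
                   x = ex$seq_id[1]))) next
    if (any(ex$end > widths[[ex$seq_id[1]]] | ex$start < 1)) {
      bad <- ex[which(ex$end > widths[[ex$seq_id[1]]] | ex$start < 1)[1], ]
      stop("exon ", bad$id, " of transcript ", pid,
           " exceeds the bounds of sequence ", bad$seq_id)
    }
    strand <- ex$strand[1]
    ex <- ex[order(ex$start), , drop = FALSE]
    segs <- substring(as.character(genome[[ex$seq_id[1]]]), ex$start, ex$end)
    if (strand == "-") {
      segs <- rev(segs)                     # transcription order
      ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
      segs <- vapply(segs, revcomp, character(1), USE.NAMES = FALSE)
    }
    out[[pid]] <- data.frame(
      transcript_id = pid, gene_id = gid, seq_id = ex$seq_id[1],
      strand = strand, n_exons = nrow(ex),
      exon_starts = paste(ex$start, collapse = ","),
      exon_ends = paste(ex$end, collapse = ","),
      seq = paste(segs, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty_transcripts())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_transcripts <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             seq_id = character(), strand = character(),
             n_exons = integer(), exon_starts = character(),
             exon_ends = character(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string
#'
#' @param x A single DNA string.
#' @return The reverse complement (via [Biostrings::reverseComplement()]).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
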