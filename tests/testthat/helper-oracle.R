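# Independent plain-R oracles used to cross-check the package.
#
# The alignment oracle is a from-scratch Gotoh local-alignment DP with the
# same declared conventions as the engine (first maximum in row-major scan;
# traceback prefers diagonal, then the query-consuming gap state, then the
# subject-consuming one; gap close beats extend on ties; a gap of length k
# costs open + k*extend; non-ACGT letters mismatch; masked subject columns
# score -100000). It shares no code with the compiled engine.

oracle_encode <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  match(v, c("A", "C", "G", "T"))   # NA for non-ACGT
}

oracle_revcomp <- function(s) {
  v <- rev(strsplit(toupper(s), "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- comp[v]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

# One full DP pass; returns NULL or a hit list.
oracle_sw_once <- function(qc, sc, mask, match, mismatch, gap_open, gap_ext,
                           min_score) {
  m <- length(qc); n <- length(sc)
  open1 <- -(gap_open + gap_ext); ext <- -gap_ext
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0; bi <- -1; bj <- -1
  for (i in 1:m) {
    qi <- qc[i]
    for (j in 1:n) {
      sub <- if (mask[j]) -100000
        else if (!is.na(qi) && !is.na(sc[j]) && qi == sc[j]) match else mismatch
      e <- max(H[i, j + 1] + open1, E[i, j + 1] + ext)
      f <- max(H[i + 1, j] + open1, F[i + 1, j] + ext)
      h <- max(0, H[i, j] + sub, e, f)
      E[i + 1, j + 1] <- e
      F[i + 1, j + 1] <- f
      H[i + 1, j + 1] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best < min_score || best <= 0) return(NULL)
  # traceback
  i <- bi; j <- bj
  matches <- 0L; mism <- 0L; gapo <- 0L; len <- 0L
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    h <- H[i + 1, j + 1]
    sub <- if (mask[j]) -100000
      else if (!is.na(qc[i]) && !is.na(sc[j]) && qc[i] == sc[j]) match else mismatch
    if (h == H[i, j] + sub) {
      if (sub == match) matches <- matches + 1L else mism <- mism + 1L
      len <- len + 1L; i <- i - 1L; j <- j - 1L
    } else if (h == E[i + 1, j + 1]) {
      gapo <- gapo + 1L
      repeat {
        len <- len + 1L
        close <- E[i + 1, j + 1] == H[i, j + 1] + open1
        i <- i - 1L
        if (close) break
      }
    } else {
      gapo <- gapo + 1L
      repeat {
        len <- len + 1L
        close <- F[i + 1, j + 1] == H[i + 1, j] + open1
        j <- j - 1L
        if (close) break
      }
    }
  }
  list(q_start = i + 1L, q_end = bi, s_start = j + 1L, s_end = bj,
       score = best, matches = matches, mismatches = mism,
       gap_opens = gapo, align_length = len)
}

# Repeated masked search of one strand.
oracle_sw_strand <- function(q, s, match, mismatch, gap_open, gap_ext,
                             min_score, max_hits) {
  qc <- oracle_encode(q); sc <- oracle_encode(s)
  mask <- rep(FALSE, length(sc))
  hits <- list()
  while (length(hits) < max_hits) {
    h <- oracle_sw_once(qc, sc, mask, match, mismatch, gap_open, gap_ext,
                        min_score)
    if (is.null(h)) break
    hits[[length(hits) + 1L]] <- h
    mask[h$s_start:h$s_end] <- TRUE
  }
  hits
}

# Engine-comparable hit table (raw coordinates and scores) for one pair.
oracle_search_pair <- function(q, s, match = 2, mismatch = -3, gap_open = 5,
                               gap_ext = 2, min_score = 40, max_hits = 100,
                               both_strands = FALSE) {
  plus <- oracle_sw_strand(q, s, match, mismatch, gap_open, gap_ext,
                           min_score, max_hits)
  rows <- lapply(plus, as.data.frame)
  if (both_strands) {
    m <- nchar(q)
    minus <- oracle_sw_strand(oracle_revcomp(q), s, match, mismatch,
                              gap_open, gap_ext, min_score, max_hits)
    rows <- c(rows, lapply(minus, function(h) {
      data.frame(q_start = m - h$q_end + 1L, q_end = m - h$q_start + 1L,
                 s_start = h$s_end, s_end = h$s_start, score = h$score,
                 matches = h$matches, mismatches = h$mismatches,
                 gap_opens = h$gap_opens, align_length = h$align_length)
    }))
  }
  if (!length(rows)) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      score = integer(), matches = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      align_length = integer()))
  }
  do.call(rbind, rows)
}

oracle_divergence <- function(a, b, min_score = 20) {
  one <- function(q, s) {
    h <- oracle_sw_strand(q, s, 2, -3, 5, 2, min_score, 1)
    if (!length(h)) return(NULL)
    list(score = h[[1]]$score,
         div = 100 - h[[1]]$matches / h[[1]]$align_length * 100)
  }
  cand <- Filter(Negate(is.null), list(one(a, b), one(b, a)))
  if (!length(cand)) return(100)
  sc <- vapply(cand, `[[`, numeric(1), "score")
  dv <- vapply(cand, `[[`, numeric(1), "div")
  min(dv[sc == max(sc)])
}

# ---- alignment-statistics oracles -----------------------------------------

oracle_trim <- function(aln, max_missing = 0.30) {
  missing <- c("-", "?", "N")
  is_missing <- function(x) x %in% missing
  keep_r <- logical(nrow(aln))
  for (r in seq_len(nrow(aln))) {
    keep_r[r] <- sum(is_missing(aln[r, ])) / ncol(aln) <= max_missing
  }
  out <- aln[keep_r, , drop = FALSE]
  if (nrow(out) == 0) return(out[, integer(), drop = FALSE])
  keep_c <- logical(ncol(out))
  for (cc in seq_len(ncol(out))) {
    keep_c[cc] <- sum(is_missing(out[, cc])) / nrow(out) <= max_missing
  }
  out[, keep_c, drop = FALSE]
}

oracle_classify <- function(column) {
  counts <- integer(4)
  names(counts) <- c("A", "C", "G", "T")
  for (x in column) if (x %in% names(counts)) counts[x] <- counts[x] + 1L
  present <- counts[counts > 0]
  if (length(present) <= 1) return("constant")
  if (sum(present >= 2) >= 2) return("parsimony_informative")
  "variable_singleton"
}

# ---- recovery-grid oracle --------------------------------------------------

oracle_grid <- function(fraction, Ls, Ps) {
  out <- NULL
  for (L in Ls) for (P in Ps) {
    cnt <- 0L
    for (l in seq_len(ncol(fraction))) {
      n_ok <- 0L
      for (s in seq_len(nrow(fraction))) {
        if (fraction[s, l] >= L) n_ok <- n_ok + 1L
      }
      if (n_ok / nrow(fraction) >= P) cnt <- cnt + 1L
    }
    out <- rbind(out, data.frame(length_threshold = L, presence_threshold = P,
                                 n_loci = cnt))
  }
  out[order(out$length_threshold, out$presence_threshold), , drop = FALSE]
}

# ---- misc helpers ----------------------------------------------------------

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, n_subs) {
  v <- strsplit(s, "")[[1]]
  pos <- sample.int(length(v), n_subs)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
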