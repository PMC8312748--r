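test_that("hit tables parse the 12 standard columns and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t83.50\t250\t40\t2\t1\t250\t1000\t1249\t1e-50\t180.3", f)
  h <- read_hit_table(f)
  expect_equal(h$percent_identity, 83.5)
  expect_equal(h$align_length, 250L)
  expect_equal(h$s_start, 1000L)

  writeLines(character(), f)
  expect_equal(nrow(read_hit_table(f)), 0)

  writeLines("q1\ts1\t90\t100", f)
  expect_error(read_hit_table(f), "12")

  # 20-row round trip
  set.seed(3)
  subj <- random_seq(3000)
  qs <- setNames(lapply(1:10, function(i) {
    p <- sample(1:2700, 1); mutate_seq(substring(subj, p, p + 199), 5)
  }), sprintf("q%02d", 1:10))
  qs <- unlist(qs)
  hits <- local_search(c(qs, setNames(vapply(qs, oracle_revcomp,
                                             character(1)),
                                      sprintf("r%02d", 1:10))),
                       c(s1 = subj))
  expect_gte(nrow(hits), 20)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, f2)
  back <- read_hit_table(f2)
  num <- c("align_length", "mismatches", "gap_opens", "q_start", "q_end",
           "s_start", "s_end")
  expect_equal(back[num], hits[num])
  expect_equal(back$percent_identity, round(hits$percent_identity, 3))
})

test_that("an exact substring query yields one full-identity hit", {
  set.seed(4)
  subj <- random_seq(1500)
  q <- substring(subj, 301, 400)
  h <- local_search(c(q = q), c(s = subj))
  plus <- h[h$s_start <= h$s_end, ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$percent_identity, 100)
  expect_equal(plus$align_length, 100L)
  expect_equal(c(plus$q_start, plus$q_end, plus$s_start, plus$s_end),
               c(1L, 100L, 301L, 400L))
})

test_that("no shared word and a high score threshold yields zero hits", {
  q <- paste(rep("ACT", 40), collapse = "")
  s <- paste(rep("GGA", 400), collapse = "")
  p <- search_params(min_raw_score = 60L, both_strands = FALSE,
                     full_dp_limit = 0)
  expect_equal(nrow(local_search(c(q = q), c(s = s), p)), 0)
})

test_that("a query of only N characters warns and yields zero hits", {
  s <- random_seq(500)
  expect_warning(h <- local_search(c(q = strrep("N", 80)), c(s = s)),
                 "unambiguous")
  expect_equal(nrow(h), 0)
})

test_that("engine agrees with the exhaustive DP oracle on random pairs", {
  set.seed(21)
  for (i in 1:25) {
    m <- sample(50:140, 1); n <- sample(60:220, 1)
    q <- random_seq(m); s <- random_seq(n)
    if (i %% 2 == 0) {  # plant a diverged homologous segment
      seg <- mutate_seq(substring(q, 5, 5 + sample(30:70, 1)), sample(0:5, 1))
      p0 <- sample(seq_len(n - nchar(seg) - 1), 1)
      s <- paste0(substring(s, 1, p0), seg, substring(s, p0 + nchar(seg) + 1, n))
    }
    eng <- probeforge:::.cpp_search_pair(q, s, 2L, -3L, 5L, 2L, 25L, 100L,
                                         11L, Inf, TRUE)
    ora <- oracle_search_pair(q, s, min_score = 25, both_strands = TRUE)
    eng <- eng[order(eng$s_start, eng$q_start), ]
    ora <- ora[order(ora$s_start, ora$q_start), ]
    expect_equal(eng$raw_score, ora$score)
    expect_equal(eng[c("q_start", "q_end", "s_start", "s_end", "matches",
                       "align_length", "gap_opens")],
                 ora[c("q_start", "q_end", "s_start", "s_end", "matches",
                       "align_length", "gap_opens")],
                 ignore_attr = TRUE)
  }
})

test_that("seeded window path agrees with exhaustive DP on planted cases", {
  set.seed(31)
  for (i in 1:8) {
    subj <- random_seq(8000)
    q <- mutate_seq(substring(subj, 3001, 3400), 20)
    seeded <- probeforge:::.cpp_search_pair(q, subj, 2L, -3L, 5L, 2L, 45L,
                                            100L, 11L, 0, TRUE)
    full <- probeforge:::.cpp_search_pair(q, subj, 2L, -3L, 5L, 2L, 45L,
                                          100L, 11L, Inf, TRUE)
    seeded <- seeded[order(seeded$s_start, seeded$q_start), ]
    full <- full[order(full$s_start, full$q_start), ]
    rownames(seeded) <- rownames(full) <- NULL
    expect_equal(seeded, full)
  }
})

test_that("lowering e_value_max never adds hits", {
  set.seed(8)
  subj <- random_seq(4000)
  qs <- setNames(vapply(1:4, function(i) {
    p <- sample(1:3500, 1)
    mutate_seq(substring(subj, p, p + 250), 30)
  }, character(1)), paste0("q", 1:4))
  loose <- local_search(qs, c(s = subj), search_params(e_value_max = 1e-3))
  strict <- local_search(qs, c(s = subj), search_params(e_value_max = 1e-8))
  key <- function(h) paste(h$query_id, h$q_start, h$q_end, h$s_start, h$s_end)
  expect_true(all(key(strict) %in% key(loose)))
  expect_lte(nrow(strict), nrow(loose))
})

test_that("searching the reverse complement of the subject swaps s coordinates", {
  set.seed(9)
  subj <- random_seq(2000)
  q <- mutate_seq(substring(subj, 501, 800), 15)
  fwd <- local_search(c(q = q), c(s = subj))
  rev <- local_search(c(q = q), setNames(oracle_revcomp(subj), "s"))
  n <- nchar(subj)
  expect_equal(nrow(fwd), nrow(rev))
  fwd <- fwd[order(fwd$bit_score, pmin(fwd$s_start, fwd$s_end)), ]
  map <- data.frame(s_start = n - rev$s_start + 1L, s_end = n - rev$s_end + 1L,
                    bit_score = rev$bit_score)
  map <- map[order(map$bit_score, pmin(map$s_start, map$s_end)), ]
  expect_equal(fwd$s_start, map$s_start)
  expect_equal(fwd$s_end, map$s_end)
  expect_equal(fwd$bit_score, map$bit_score)
})

test_that("percent divergence matches its definition and the DP oracle", {
  set.seed(12)
  a <- random_seq(200)
  expect_equal(percent_divergence(a, a), 0)

  b <- random_seq(100)
  b2 <- b
  substr(b2, 50, 50) <- setdiff(c("A", "C", "G", "T"), substring(b, 50, 50))[1]
  expect_equal(percent_divergence(b, b2), 1.0)

  for (i in 1:10) {
    x <- random_seq(150)
    y <- mutate_seq(x, sample(3:25, 1))
    expect_equal(percent_divergence(x, y), oracle_divergence(x, y))
    expect_equal(percent_divergence(x, y), percent_divergence(y, x))
  }

  far <- percent_divergence(strrep("AC", 60), strrep("GT", 60),
                            min_score = 60)
  expect_equal(as.numeric(far), 100)
  expect_true(attr(far, "no_alignment"))
})

test_that("contained hits are dropped, partial overlaps kept", {
  h <- data.frame(
    query_id = "q", subject_id = "s",
    percent_identity = c(95, 99, 90), align_length = c(300L, 100L, 200L),
    mismatches = 0L, gap_opens = 0L,
    q_start = c(1L, 50L, 250L), q_end = c(300L, 149L, 449L),
    s_start = c(1001L, 1050L, 1240L), s_end = c(1300L, 1149L, 1439L),
    e_value = 0, bit_score = c(300, 120, 200))
  out <- dedupe_contained_hits(h)
  # the 100-bp hit is inside the 300-bp one on both axes; the third overlaps
  expect_equal(out$align_length, c(300L, 200L))
})
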