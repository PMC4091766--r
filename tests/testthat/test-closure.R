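mk_hit <- function(qid, sid, q0, q1, s0, s1, orientation, score, qlen,
                   slen) {
  data.frame(
    query_id = qid, subject_id = sid, q_start = q0, q_end = q1,
    s_start = s0, s_end = s1, orientation = orientation, score = score,
    evalue = 1e-20, identity = 100, aln_length = q1 - q0,
    n_ident = q1 - q0, q_len = qlen, s_len = slen,
    stringsAsFactors = FALSE
  )
}

exact_overlap_case <- function(seed = 1L, g_len = 30L) {
  set.seed(seed)
  L <- rand_dna(50L)
  R <- rand_dna(50L)
  G <- rand_dna(g_len)
  subj <- paste0(L, G, R)
  flanks <- list(left_seq = L, right_seq = R, gap_start = 500L,
                 gap_end = 510L, trim = 0L)
  list(L = L, R = R, G = G, subj = subj, flanks = flanks)
}

test_that("an exactly spanning subject yields the one expected candidate", {
  cs <- exact_overlap_case()
  slen <- nchar(cs$subj)
  lh <- mk_hit("L", "s1", 0L, 50L, 0L, 50L, "forward", 90, 50L, slen)
  rh <- mk_hit("R", "s1", 0L, 50L, 80L, 130L, "forward", 88, 50L, slen)
  cands <- enumerate_candidates(lh, rh, cs$flanks, c(s1 = cs$subj))
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$insert_len, 30L)
  expect_identical(cands$insert_seq, cs$G)
  expect_equal(cands$removed_left, 0L)
  expect_equal(cands$removed_right, 0L)
  expect_equal(cands$combined_score, 178)
})

test_that("reverse-complemented subjects give the same fill after re-complementing", {
  cs <- exact_overlap_case(seed = 2L)
  slen <- nchar(cs$subj)
  # On the reverse-complemented subject, oriented [a,b) maps to
  # forward-strand [slen-b, slen-a).
  lh <- mk_hit("L", "s1", 0L, 50L, 80L, 130L, "reverse", 90, 50L, slen)
  rh <- mk_hit("R", "s1", 0L, 50L, 0L, 50L, "reverse", 88, 50L, slen)
  cands <- enumerate_candidates(lh, rh, cs$flanks,
                                c(s1 = revcomp(cs$subj)))
  expect_equal(nrow(cands), 1L)
  expect_identical(cands$orientation, "reverse")
  expect_equal(cands$insert_len, 30L)
  expect_identical(cands$insert_seq, cs$G)
})

test_that("insertion/removal limits and gap-sign options are enforced", {
  cs <- exact_overlap_case(seed = 3L, g_len = 120L)
  slen <- nchar(cs$subj)
  lh <- mk_hit("L", "s1", 0L, 50L, 0L, 50L, "forward", 90, 50L, slen)
  rh <- mk_hit("R", "s1", 0L, 50L, 170L, 220L, "forward", 88, 50L, slen)
  flanks <- cs$flanks
  subjects <- c(s1 = cs$subj)

  expect_equal(nrow(enumerate_candidates(
    lh, rh, flanks, subjects, closure_limits(max_insert = 119))), 0L)
  expect_equal(nrow(enumerate_candidates(
    lh, rh, flanks, subjects, closure_limits(max_insert = 120))), 1L)

  # Overlapping flanks on the subject: a negative gap.
  rh_neg <- mk_hit("R", "s1", 0L, 50L, 38L, 88L, "forward", 88, 50L, slen)
  expect_equal(nrow(enumerate_candidates(
    lh, rh_neg, flanks, subjects, closure_limits())), 0L)
  neg <- enumerate_candidates(lh, rh_neg, flanks, subjects,
                              closure_limits(allow_negative = TRUE))
  expect_equal(neg$insert_len, -12L)
  expect_equal(neg$removed_right, 12L)
  expect_identical(neg$insert_seq, "")
  expect_equal(nrow(enumerate_candidates(
    lh, rh_neg, flanks, subjects,
    closure_limits(allow_negative = TRUE, max_remove = 11))), 0L)

  # Abutting flanks: a zero gap, controlled by allow_zero.
  rh_zero <- mk_hit("R", "s1", 0L, 50L, 50L, 100L, "forward", 88, 50L,
                    slen)
  expect_equal(enumerate_candidates(lh, rh_zero, flanks, subjects,
                                    closure_limits())$insert_len, 0L)
  expect_equal(nrow(enumerate_candidates(
    lh, rh_zero, flanks, subjects, closure_limits(allow_zero = FALSE))),
    0L)
})

test_that("unaligned gap-adjacent tails count as removals and shift the cut", {
  cs <- exact_overlap_case(seed = 4L)
  slen <- nchar(cs$subj)
  # Left hit misses its last 6 flank bases, right hit its first 4.
  lh <- mk_hit("L", "s1", 0L, 44L, 0L, 44L, "forward", 80, 50L, slen)
  rh <- mk_hit("R", "s1", 4L, 50L, 84L, 130L, "forward", 78, 50L, slen)
  cands <- enumerate_candidates(lh, rh, cs$flanks, c(s1 = cs$subj))
  expect_equal(cands$removed_left, 6L)
  expect_equal(cands$removed_right, 4L)
  expect_equal(cands$insert_len, 40L)
  # The fill carries the dataset's version of the skipped tail bases.
  expect_identical(cands$insert_seq, substr(cs$subj, 45L, 84L))
  edit <- make_edit(cands, cs$flanks, 2000L)
  expect_equal(edit$cut_start, 494L)
  expect_equal(edit$cut_end, 514L)
  expect_equal(edit$delta, 40L - 20L)
})

test_that("candidate enumeration equals brute force on random instances", {
  set.seed(404)
  n_checked <- 0L
  for (i in 1:200) {
    subjects <- vapply(seq_len(sample(1:3, 1L)),
                       function(k) rand_dna(sample(200:1000, 1L)),
                       character(1))
    names(subjects) <- paste0("s", seq_along(subjects))
    nl <- sample(30:200, 1L)
    nr <- sample(30:200, 1L)
    flanks <- list(left_seq = rand_dna(nl), right_seq = rand_dna(nr),
                   gap_start = 1000L, gap_end = 1040L,
                   trim = sample(0:5, 1L))
    limits <- closure_limits(
      max_insert = sample(50:500, 1L), max_remove = sample(20:300, 1L),
      allow_negative = sample(c(TRUE, FALSE), 1L),
      allow_zero = sample(c(TRUE, FALSE), 1L),
      min_query_cov = runif(1L, 0.1, 0.6)
    )
    lh <- rand_hits(sample(0:8, 1L), nl, subjects, "L")
    rh <- rand_hits(sample(0:8, 1L), nr, subjects, "R")
    got <- enumerate_candidates(lh, rh, flanks, subjects, limits)
    want <- bf_enumerate(lh, rh, flanks, subjects, limits)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
      next
    }
    n_checked <- n_checked + 1L
    key <- function(d) do.call(order, d[c("subject_id", "orientation",
                                          "left_s_start", "right_s_start",
                                          "left_q_start", "right_q_start")])
    got_s <- got[key(got), names(want), drop = FALSE]
    want_s <- want[key(want), , drop = FALSE]
    rownames(got_s) <- rownames(want_s) <- NULL
    expect_equal(got_s, want_s, info = paste("instance", i))
    # Selection agrees with the literal pairwise-comparison oracle.
    bsel <- bf_select(got)
    gsel <- select_best(got)
    expect_equal(gsel$combined_score, bsel$combined_score)
    expect_identical(gsel$subject_id, bsel$subject_id)
    expect_equal(gsel$insert_len, bsel$insert_len)
  }
  expect_gte(n_checked, 40L)
})

test_that("select_best maximizes combined score and ignores input order", {
  cands <- data.frame(
    subject_id = c("b", "a"), orientation = "forward",
    left_score = c(40, 50), right_score = c(40, 45),
    left_s_start = c(5L, 9L), insert_len = c(10L, 40L),
    combined_score = c(80, 95), stringsAsFactors = FALSE
  )
  expect_identical(select_best(cands)$subject_id, "a")
  expect_null(select_best(cands[0, ]))
  expect_null(select_best(NULL))
  set.seed(8)
  for (i in 1:10) {
    perm <- cands[sample(nrow(cands)), ]
    expect_identical(select_best(perm), select_best(cands))
  }
})

test_that("ties fall through min-score, insert length and subject id", {
  base <- data.frame(
    orientation = "forward", left_s_start = 0L,
    combined_score = 100, stringsAsFactors = FALSE
  )
  a <- cbind(base, subject_id = "x", left_score = 50, right_score = 50,
             insert_len = 30L)
  b <- cbind(base, subject_id = "y", left_score = 60, right_score = 40,
             insert_len = 10L)
  expect_identical(select_best(rbind(b, a))$subject_id, "x")  # min score
  c2 <- cbind(base, subject_id = "z", left_score = 50, right_score = 50,
              insert_len = -10L)
  expect_identical(select_best(rbind(a, c2))$subject_id, "z")  # |insert|
  d <- a; d$subject_id <- "w"
  expect_identical(select_best(rbind(a, d))$subject_id, "w")  # lexical
})

test_that("apply_edit splices replacements and preserves the rest", {
  edit <- list(cut_start = 3L, cut_end = 6L, replacement = "GGG",
               delta = 0L)
  expect_identical(apply_edit("AAANNNCCC", edit), "AAAGGGCCC")
  edit$replacement <- ""
  expect_identical(apply_edit("AAANNNCCC", edit), "AAACCC")
  edit$cut_end <- 99L
  expect_error(apply_edit("AAANNNCCC", edit), "out of bounds")
})

test_that("zero and negative edits delete the N-run and the overlap", {
  flanks <- list(gap_start = 100L, gap_end = 105L, trim = 0L)
  neg <- data.frame(insert_len = -12L, removed_left = 0L,
                    removed_right = 12L, insert_seq = "",
                    stringsAsFactors = FALSE)
  edit <- make_edit(neg, flanks, 1000L)
  expect_equal(edit$cut_start, 100L)
  expect_equal(edit$cut_end, 117L)
  expect_equal(edit$delta, -17L)

  flanks0 <- list(gap_start = 100L, gap_end = 107L, trim = 0L)
  zero <- data.frame(insert_len = 0L, removed_left = 0L,
                     removed_right = 0L, insert_seq = "",
                     stringsAsFactors = FALSE)
  edit <- make_edit(zero, flanks0, 1000L)
  expect_equal(edit$delta, -7L)
  expect_error(make_edit(neg, list(gap_start = 5L, gap_end = 998L,
                                   trim = 0L), 1000L),
               "escapes scaffold bounds")
})
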