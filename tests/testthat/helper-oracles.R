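# Independent oracles used to cross-check the implementation. These are
# deliberately written from scratch against the definitions, not by calling
# the package's own code paths.

rand_dna <- function(n, chars = c("A", "C", "G", "T")) {
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

# Reverse complement written independently of the package (ACGTN only).
rc_simple <- function(x) {
  chartr_rev <- chartr("ACGTN", "TGCAN", x)
  vapply(chartr_rev, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force affine-gap local alignment score (Gotoh recurrences, score
# only). A gap of length L costs open + L * extend; alignments end in a
# match/mismatch state.
bf_local_score <- function(q, s, match = 1, mismatch = -3, open = 5,
                           extend = 2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(qc); m <- length(sc)
  if (n == 0L || m == 0L) return(0)
  NEG <- -1e18
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
      sub <- if (qc[i - 1L] == sc[j - 1L]) match else mismatch
      M[i, j] <- max(0, sub + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                                  Y[i - 1L, j - 1L]))
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Maximal N-run scanner based on run-length encoding (independent of the
# package's regex scan).
rle_gaps <- function(seq, min_run = 1L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  r <- rle(chars == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

# Literal brute-force candidate enumeration: loop over all hit pairs and
# apply every constraint explicitly.
bf_enumerate <- function(left_hits, right_hits, flanks, subjects, limits) {
  nl <- nchar(flanks$left_seq)
  nr <- nchar(flanks$right_seq)
  rows <- list()
  for (i in seq_len(nrow(left_hits))) {
    for (j in seq_len(nrow(right_hits))) {
      lh <- left_hits[i, ]
      rh <- right_hits[j, ]
      if (lh$subject_id != rh$subject_id) next
      if (lh$orientation != rh$orientation) next
      slen <- lh$s_len
      if (lh$orientation == "forward") {
        l_os <- c(lh$s_start, lh$s_end)
        r_os <- c(rh$s_start, rh$s_end)
      } else {
        l_os <- c(slen - lh$s_end, slen - lh$s_start)
        r_os <- c(slen - rh$s_end, slen - rh$s_start)
      }
      if (!(l_os[1L] < r_os[1L] && l_os[2L] < r_os[2L])) next
      if ((lh$q_end - lh$q_start) < limits$min_query_cov * nl) next
      if ((rh$q_end - rh$q_start) < limits$min_query_cov * nr) next
      insert_len <- r_os[1L] - l_os[2L]
      if (insert_len > limits$max_insert) next
      if (insert_len < -limits$max_remove) next
      if (insert_len < 0L && !limits$allow_negative) next
      if (insert_len == 0L && !limits$allow_zero) next
      removed_left <- (nl - lh$q_end) + flanks$trim
      removed_right <- rh$q_start + flanks$trim + max(-insert_len, 0L)
      if (removed_left > limits$max_remove) next
      if (removed_right > limits$max_remove) next
      ins <- ""
      if (insert_len > 0L) {
        s <- subjects[[lh$subject_id]]
        if (lh$orientation == "forward") {
          ins <- substr(s, l_os[2L] + 1L, r_os[1L])
        } else {
          ins <- rc_simple(substr(s, slen - r_os[1L] + 1L, slen - l_os[2L]))
        }
        n_frac <- lengths(regmatches(ins, gregexpr("N", ins))) / insert_len
        if (n_frac > limits$max_n_frac) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = lh$subject_id, orientation = lh$orientation,
        left_score = lh$score, right_score = rh$score,
        left_q_start = lh$q_start, left_q_end = lh$q_end,
        left_s_start = lh$s_start, left_s_end = lh$s_end,
        right_q_start = rh$q_start, right_q_end = rh$q_end,
        right_s_start = rh$s_start, right_s_end = rh$s_end,
        insert_len = insert_len, removed_left = removed_left,
        removed_right = removed_right, insert_seq = ins,
        combined_score = lh$score + rh$score,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Literal best-candidate selection by explicit pairwise comparison.
bf_select <- function(cands) {
  if (is.null(cands) || nrow(cands) == 0L) return(NULL)
  better <- function(a, b) {
    if (a$combined_score != b$combined_score)
      return(a$combined_score > b$combined_score)
    ma <- min(a$left_score, a$right_score)
    mb <- min(b$left_score, b$right_score)
    if (ma != mb) return(ma > mb)
    if (abs(a$insert_len) != abs(b$insert_len))
      return(abs(a$insert_len) < abs(b$insert_len))
    if (a$subject_id != b$subject_id) return(a$subject_id < b$subject_id)
    a$left_s_start < b$left_s_start
  }
  best <- cands[1L, ]
  for (i in seq_len(nrow(cands))[-1L]) {
    if (better(cands[i, ], best)) best <- cands[i, ]
  }
  best
}

# Random synthetic hit table for a flank of length qlen over the given
# subjects (plain coordinates; not produced by any aligner). Query
# intervals are biased toward high coverage so that pairing constraints
# are exercised rather than trivially failed.
rand_hits <- function(n, qlen, subjects, query_id = "q") {
  if (n == 0L) return(gapweld:::empty_hits())
  sid <- sample(names(subjects), n, replace = TRUE)
  slen <- nchar(subjects)[sid]
  head_room <- max(1L, qlen %/% 4L)
  q_a <- vapply(seq_len(n), function(i) sample.int(head_room, 1L) - 1L, 0L)
  q_b <- vapply(seq_len(n), function(i) {
    max(q_a[i] + 1L, qlen - sample.int(head_room, 1L) + 1L)
  }, 0L)
  alen <- q_b - q_a
  s_a <- vapply(seq_len(n), function(i) {
    sample.int(max(1L, slen[i] - alen[i]), 1L) - 1L
  }, 0L)
  data.frame(
    query_id = query_id, subject_id = sid,
    q_start = q_a, q_end = q_b,
    s_start = s_a, s_end = s_a + alen,
    orientation = sample(c("forward", "reverse"), n, replace = TRUE),
    score = round(runif(n, 20, 120), 1), evalue = 10^-runif(n, 8, 30),
    identity = round(runif(n, 70, 100), 2), aln_length = alen,
    n_ident = alen, q_len = qlen, s_len = unname(slen),
    stringsAsFactors = FALSE
  )
}
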