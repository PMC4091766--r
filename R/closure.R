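# Closure geometry: pair left/right flank hits on a shared subject into
# fill candidates, select the best, and construct/apply the scaffold edit.
#
# Geometry (all 0-based half-open; "oriented subject" = subject as seen by
# the flank queries, i.e. reverse-complemented for reverse-orientation
# hits):
#   tail_left  = unaligned gap-adjacent bases of the left flank query
#   tail_right = unaligned gap-adjacent bases of the right flank query
#   insert_len = right_hit oriented start - left_hit oriented end
#                (negative = the true flanks overlap on the subject)
#   removed_left  = tail_left + trim
#   removed_right = tail_right + trim + max(-insert_len, 0)
#   cut = [gap_start - removed_left, gap_end + removed_right)
#   replacement = oriented subject bases between the two aligned intervals
#                 (includes the dataset's version of trimmed/unaligned flank
#                 edges; empty when insert_len <= 0)

#' Limits and options controlling gap closure
#'
#' @param max_insert Maximum bases inserted into a gap.
#' @param max_remove Maximum bases removed per side (flank tails, trimmed
#'   edges and negative-gap overlap all count against this cap).
#' @param allow_negative Allow negative gaps (overlapping contig ends;
#'   closing removes bases). Default `FALSE`.
#' @param allow_zero Allow zero-length fills (flanks abut exactly; the
#'   N-run is deleted). Default `TRUE`.
#' @param min_query_cov Minimum fraction of each flank that its hit must
#'   align (default 0.40).
#' @param max_n_frac Maximum fraction of `N` tolerated in a replacement
#'   sequence (default 0: fills must not reintroduce unknown bases).
#' @return An object of class `closure_limits`.
#' @export
closure_limits <- function(max_insert = 500, max_remove = 500,
                           allow_negative = FALSE, allow_zero = TRUE,
                           min_query_cov = 0.4, max_n_frac = 0) {
  stopifnot(max_insert >= 0, max_remove >= 0,
            min_query_cov > 0, min_query_cov <= 1,
            max_n_frac >= 0, max_n_frac <= 1)
  structure(
    list(max_insert = max_insert, max_remove = max_remove,
         allow_negative = isTRUE(allow_negative),
         allow_zero = isTRUE(allow_zero),
         min_query_cov = min_query_cov, max_n_frac = max_n_frac),
    class = "closure_limits"
  )
}

empty_candidates <- function() {
  data.frame(
    subject_id = character(0), orientation = character(0),
    left_score = numeric(0), left_evalue = numeric(0),
    left_identity = numeric(0), left_q_start = integer(0),
    left_q_end = integer(0), left_s_start = integer(0),
    left_s_end = integer(0),
    right_score = numeric(0), right_evalue = numeric(0),
    right_identity = numeric(0), right_q_start = integer(0),
    right_q_end = integer(0), right_s_start = integer(0),
    right_s_end = integer(0),
    insert_len = integer(0), removed_left = integer(0),
    removed_right = integer(0), insert_seq = character(0),
    combined_score = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Enumerate geometric fill candidates for one gap
#'
#' Forms every (left-hit, right-hit) pair that shares a subject and an
#' orientation, has the left-flank hit preceding the right-flank hit in
#' flank order on the subject, satisfies the per-hit query-coverage
#' minimum, and stays within the insertion/removal limits. The fill
#' sequence is extracted from the subject forward strand and
#' reverse-complemented for reverse-orientation pairs.
#'
#' @param left_hits,right_hits Hit data.frames for the left and right flank
#'   queries (already threshold-filtered).
#' @param flanks Flank pair from [extract_flanks()].
#' @param subjects Named character vector holding the subject sequences.
#' @param limits A [closure_limits()] object.
#' @return Candidate data.frame (possibly empty), one row per admissible
#'   pair, with both hits' statistics, `insert_len` (signed), per-side
#'   removals, `insert_seq` and `combined_score` (sum of the two bit
#'   scores).
#' @export
enumerate_candidates <- function(left_hits, right_hits, flanks, subjects,
                                 limits = closure_limits()) {
  if (nrow(left_hits) == 0L || nrow(right_hits) == 0L) {
    return(empty_candidates())
  }
  nl <- nchar(flanks$left_seq)
  nr <- nchar(flanks$right_seq)
  trim <- flanks$trim

  lh <- left_hits
  rh <- right_hits
  names(lh) <- paste0("left_", names(lh))
  names(rh) <- paste0("right_", names(rh))
  pairs <- merge(lh, rh,
                 by.x = c("left_subject_id", "left_orientation"),
                 by.y = c("right_subject_id", "right_orientation"))
  if (nrow(pairs) == 0L) return(empty_candidates())
  names(pairs)[1:2] <- c("subject_id", "orientation")

  slen <- pairs$left_s_len
  fwd <- pairs$orientation == "forward"
  # Oriented-subject coordinates of each hit interval.
  l_os_start <- ifelse(fwd, pairs$left_s_start, slen - pairs$left_s_end)
  l_os_end <- ifelse(fwd, pairs$left_s_end, slen - pairs$left_s_start)
  r_os_start <- ifelse(fwd, pairs$right_s_start, slen - pairs$right_s_end)
  r_os_end <- ifelse(fwd, pairs$right_s_end, slen - pairs$right_s_start)

  tail_left <- nl - pairs$left_q_end
  tail_right <- pairs$right_q_start
  insert_len <- r_os_start - l_os_end
  removed_left <- tail_left + trim
  removed_right <- tail_right + trim + pmax(-insert_len, 0L)

  ok <- (pairs$left_q_end - pairs$left_q_start) >= limits$min_query_cov * nl &
    (pairs$right_q_end - pairs$right_q_start) >= limits$min_query_cov * nr &
    l_os_start < r_os_start & l_os_end < r_os_end &
    insert_len <= limits$max_insert &
    insert_len >= -limits$max_remove &
    removed_left <= limits$max_remove &
    removed_right <= limits$max_remove
  if (!limits$allow_negative) ok <- ok & insert_len >= 0L
  if (!limits$allow_zero) ok <- ok & insert_len != 0L

  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_candidates())
  l_os_end <- l_os_end[ok]
  r_os_start <- r_os_start[ok]
  insert_len <- insert_len[ok]
  removed_left <- removed_left[ok]
  removed_right <- removed_right[ok]
  slen <- slen[ok]
  fwd <- fwd[ok]

  insert_seq <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (insert_len[i] <= 0L) next
    s <- subjects[[pairs$subject_id[i]]]
    if (fwd[i]) {
      insert_seq[i] <- substr(s, l_os_end[i] + 1L, r_os_start[i])
    } else {
      # Oriented [a, b) maps to forward [slen - b, slen - a).
      frag <- substr(s, slen[i] - r_os_start[i] + 1L, slen[i] - l_os_end[i])
      insert_seq[i] <- revcomp(frag)
    }
  }
  n_frac <- ifelse(insert_len > 0L,
                   nchar(gsub("[^N]", "", insert_seq)) / pmax(insert_len, 1L),
                   0)
  keep <- n_frac <= limits$max_n_frac
  out <- data.frame(
    subject_id = pairs$subject_id,
    orientation = pairs$orientation,
    left_score = pairs$left_score, left_evalue = pairs$left_evalue,
    left_identity = pairs$left_identity,
    left_q_start = pairs$left_q_start, left_q_end = pairs$left_q_end,
    left_s_start = pairs$left_s_start, left_s_end = pairs$left_s_end,
    right_score = pairs$right_score, right_evalue = pairs$right_evalue,
    right_identity = pairs$right_identity,
    right_q_start = pairs$right_q_start, right_q_end = pairs$right_q_end,
    right_s_start = pairs$right_s_start, right_s_end = pairs$right_s_end,
    insert_len = as.integer(insert_len),
    removed_left = as.integer(removed_left),
    removed_right = as.integer(removed_right),
    insert_seq = insert_seq,
    combined_score = pairs$left_score + pairs$right_score,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the best fill candidate
#'
#' Highest combined bit score wins. Deterministic tie-break: (1) greater
#' minimum of the two hit scores, (2) smaller `|insert_len|`, (3)
#' lexicographically smallest subject id, (4) smallest left-hit subject
#' start. Order-independent.
#'
#' @param candidates Candidate data.frame from [enumerate_candidates()].
#' @return One-row data.frame, or `NULL` for an empty input.
#' @export
select_best <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  ord <- order(
    -candidates$combined_score,
    -pmin(candidates$left_score, candidates$right_score),
    abs(candidates$insert_len),
    candidates$subject_id,
    candidates$left_s_start
  )
  out <- candidates[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct the scaffold edit for a selected candidate
#'
#' The cut interval contains the whole N-run plus the per-side removals
#' (unaligned flank tails, trimmed edges, and for negative gaps the overlap
#' resolved on the right side under a local-collinearity assumption). The
#' replacement is the candidate's fill sequence (empty for zero/negative
#' gaps).
#'
#' @param candidate One-row candidate (from [select_best()]).
#' @param flanks Flank pair from [extract_flanks()] for the same gap.
#' @param scaffold_len Length of the scaffold being edited.
#' @return List with `cut_start`, `cut_end`, `replacement`, `delta`.
#' @export
make_edit <- function(candidate, flanks, scaffold_len) {
  cut_start <- flanks$gap_start - candidate$removed_left
  cut_end <- flanks$gap_end + candidate$removed_right
  if (cut_start < 0L || cut_end > scaffold_len || cut_start > cut_end) {
    stop("edit interval [", cut_start, ",", cut_end,
         ") escapes scaffold bounds (geometry bug)", call. = FALSE)
  }
  replacement <- if (candidate$insert_len > 0L) candidate$insert_seq else ""
  list(
    cut_start = as.integer(cut_start),
    cut_end = as.integer(cut_end),
    replacement = replacement,
    delta = nchar(replacement) - (cut_end - cut_start)
  )
}

#' Apply an edit to a scaffold sequence
#'
#' @param seq Scaffold sequence.
#' @param edit Edit from [make_edit()].
#' @return The edited sequence; length changes by `edit$delta` and no
#'   position outside the cut interval is altered.
#' @export
apply_edit <- function(seq, edit) {
  n <- nchar(seq)
  if (edit$cut_start < 0L || edit$cut_end > n) {
    stop("edit interval [", edit$cut_start, ",", edit$cut_end,
         ") out of bounds for sequence of length ", n, call. = FALSE)
  }
  paste0(
    substr(seq, 1L, edit$cut_start),
    edit$replacement,
    substr(seq, edit$cut_end + 1L, n)
  )
}
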