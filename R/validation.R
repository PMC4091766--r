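# Three-criterion validation of closed gaps against a reference genome:
#   1) each flank aligns over at least min_flank_coverage of its length;
#   2) flank and insert identities reach min_identity;
#   3) the closed region agrees with the reference better than the joined
#      flanks did without the insertion.
#
# "Identity" of a region is identical bases divided by (alignment columns +
# unaligned query bases), in percent: gap columns and unaligned tails both
# count against it, so a region that only half-aligns cannot score 100.
# Flank/region alignments use the same engine as closing; insert identity
# uses the package's exact local aligner inside the reference window
# located by the flank hits (short inserts are below blastn's word size),
# falling back to the engine when the window exceeds the exact aligner's
# size guard.

#' Thresholds for closure validation
#'
#' @param min_flank_coverage Minimum aligned fraction of each flank
#'   (default 0.40).
#' @param min_identity Minimum percent identity for flanks and inserts
#'   (default 70, matching [alignment_params()]).
#' @return An object of class `validation_thresholds`.
#' @export
validation_thresholds <- function(min_flank_coverage = 0.4,
                                  min_identity = 70) {
  stopifnot(min_flank_coverage > 0, min_flank_coverage <= 1,
            min_identity > 0, min_identity <= 100)
  structure(list(min_flank_coverage = min_flank_coverage,
                 min_identity = min_identity),
            class = "validation_thresholds")
}

# Permissive engine settings used to *measure* identities; the criteria
# apply the thresholds themselves.
measurement_params <- function(params) {
  alignment_params(
    min_score = 0, max_evalue = 1e-3, min_identity = 0,
    match = params$match, mismatch = params$mismatch,
    open_gap = params$open_gap, extend_gap = params$extend_gap,
    word_size = params$word_size, max_alignments = 5
  )
}

region_identity <- function(hit) {
  if (is.null(hit) || nrow(hit) == 0L) return(0)
  h <- hit[1L, ]
  100 * h$n_ident / (h$aln_length + (h$q_len - (h$q_end - h$q_start)))
}

best_hit <- function(hits, qid) {
  h <- hits[hits$query_id == qid, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h[order(-h$score, h$evalue, h$subject_id, h$s_start)[1L], , drop = FALSE]
}

empty_verdict <- function(reason) {
  data.frame(
    criterion1 = FALSE, criterion2 = FALSE, criterion3 = FALSE,
    overall = FALSE, flank_cov_left = 0, flank_cov_right = 0,
    identity_left = 0, identity_right = 0, identity_insert = NA_real_,
    identity_before = 0, identity_after = 0, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Validate one closed gap against a reference
#'
#' @param left_flank,right_flank The N-free flank sequences adjacent to the
#'   closure in the edited assembly.
#' @param insert_seq The inserted sequence (may be empty for zero/negative
#'   gaps).
#' @param reference Named character vector of reference sequences (or a
#'   single string), ignored when `ref_index` is given.
#' @param thresholds A [validation_thresholds()] object.
#' @param params [alignment_params()] supplying scoring for the validation
#'   alignments.
#' @param ref_index Optional prebuilt [build_blast_index()] handle for the
#'   reference (reused by [validate_all()]).
#' @return One-row data.frame: `criterion1`..`criterion3`, `overall`,
#'   per-flank coverages and identities, `identity_insert`,
#'   `identity_before`, `identity_after`, `reason`.
#' @export
validate_closure <- function(left_flank, insert_seq, right_flank,
                             reference = NULL,
                             thresholds = validation_thresholds(),
                             params = alignment_params(),
                             ref_index = NULL) {
  if (is.null(ref_index)) {
    if (is.null(reference)) stop("a reference is required", call. = FALSE)
    if (is.null(names(reference))) names(reference) <- "reference"
    ref_index <- build_blast_index(reference, label = "reference")
  }
  if (!nzchar(left_flank) || !nzchar(right_flank)) {
    return(empty_verdict("empty flank"))
  }
  mp <- measurement_params(params)
  queries <- c(LF = left_flank, RF = right_flank,
               AFTER = paste0(left_flank, insert_seq, right_flank),
               BEFORE = paste0(left_flank, right_flank))
  hits <- align_queries(queries, ref_index, mp)
  hl <- best_hit(hits, "LF")
  hr <- best_hit(hits, "RF")
  if (is.null(hl) || is.null(hr)) {
    return(empty_verdict("a flank has no reference alignment"))
  }

  cov_l <- (hl$q_end - hl$q_start) / hl$q_len
  cov_r <- (hr$q_end - hr$q_start) / hr$q_len
  id_l <- region_identity(hl)
  id_r <- region_identity(hr)
  id_before <- region_identity(best_hit(hits, "BEFORE"))
  id_after <- region_identity(best_hit(hits, "AFTER"))

  id_ins <- NA_real_
  if (nzchar(insert_seq)) {
    id_ins <- insert_identity(insert_seq, hl, hr, ref_index, params)
  }

  c1 <- cov_l >= thresholds$min_flank_coverage &&
    cov_r >= thresholds$min_flank_coverage
  c2 <- id_l >= thresholds$min_identity &&
    id_r >= thresholds$min_identity &&
    (is.na(id_ins) || id_ins >= thresholds$min_identity)
  c3 <- if (nzchar(insert_seq)) {
    id_after > id_before + 1e-9
  } else {
    id_after >= id_before - 1e-9
  }
  data.frame(
    criterion1 = c1, criterion2 = c2, criterion3 = c3,
    overall = c1 && c2 && c3,
    flank_cov_left = cov_l, flank_cov_right = cov_r,
    identity_left = id_l, identity_right = id_r,
    identity_insert = id_ins,
    identity_before = id_before, identity_after = id_after,
    reason = "", stringsAsFactors = FALSE
  )
}

# Identity of the insert measured inside the reference window bracketed by
# the two flank hits (margin 50 bp each side). Exact aligner when the
# window fits its guard; engine fallback otherwise.
insert_identity <- function(insert_seq, hl, hr, ref_index, params) {
  same_subject <- identical(hl$subject_id, hr$subject_id)
  win_len <- 0
  if (same_subject) {
    a <- max(0L, min(hl$s_start, hr$s_start) - 50L)
    b <- min(hl$s_len, max(hl$s_end, hr$s_end) + 50L)
    win_len <- b - a
  }
  if (same_subject &&
      as.double(nchar(insert_seq)) * win_len <= 1e6 && win_len > 0) {
    window <- substr(ref_index$seqs[[hl$subject_id]], a + 1L, b)
    q <- if (identical(hl$orientation, "reverse")) revcomp(insert_seq)
         else insert_seq
    al <- oracle_align(q, window, params$match, params$mismatch,
                       params$open_gap, params$extend_gap)
    if (al$score <= 0) return(0)
    unaligned <- nchar(insert_seq) - (al$q_end - al$q_start)
    return(100 * al$n_matches / (al$aln_length + unaligned))
  }
  mp <- measurement_params(params)
  h <- best_hit(align_queries(c(INS = insert_seq), ref_index, mp), "INS")
  region_identity(h)
}

#' Validate all closed gaps of a run
#'
#' @param records Closure records (from [close_gaps()] or
#'   [read_closure_log()]); rows with status `closed` are validated using
#'   their logged post-edit flank contexts and replacement sequence.
#' @param reference Named character vector of reference sequences.
#' @param thresholds A [validation_thresholds()] object.
#' @param params [alignment_params()] for the validation alignments.
#' @return List with `verdicts` (one row per closed gap: scaffold, gap
#'   coordinates, the per-criterion booleans and identities) and `totals`
#'   (`n_closed`, `n_validated`, `fraction`).
#' @export
validate_all <- function(records, reference,
                         thresholds = validation_thresholds(),
                         params = alignment_params()) {
  closed <- records[records$status == "closed", , drop = FALSE]
  if (nrow(closed) == 0L) {
    verdicts <- cbind(
      data.frame(scaffold_id = character(0), gap_index = integer(0),
                 gap_start = integer(0), gap_end = integer(0),
                 round = integer(0), stringsAsFactors = FALSE),
      empty_verdict("")[0, ]
    )
    return(list(verdicts = verdicts,
                totals = list(n_closed = 0L, n_validated = 0L,
                              fraction = NA_real_)))
  }
  if (is.null(names(reference))) names(reference) <- "reference"
  ref_index <- build_blast_index(reference, label = "reference")
  rows <- lapply(seq_len(nrow(closed)), function(i) {
    r <- closed[i, ]
    v <- validate_closure(r$left_context, r$replacement, r$right_context,
                          thresholds = thresholds, params = params,
                          ref_index = ref_index)
    cbind(data.frame(scaffold_id = r$scaffold_id, gap_index = r$gap_index,
                     gap_start = r$gap_start, gap_end = r$gap_end,
                     round = r$round, stringsAsFactors = FALSE),
          v)
  })
  verdicts <- do.call(rbind, rows)
  rownames(verdicts) <- NULL
  list(
    verdicts = verdicts,
    totals = list(
      n_closed = nrow(closed),
      n_validated = sum(verdicts$overall),
      fraction = sum(verdicts$overall) / nrow(closed)
    )
  )
}
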