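# Gap discovery, flank extraction and coordinate bookkeeping.
# Coordinates are 0-based, half-open: a gap [start, end) covers the N bases
# at string positions start+1 .. end in R's 1-based substr() terms.

#' Locate N-run gaps in an assembly
#'
#' Finds maximal runs of `N` of at least `min_gap_run` bases in every
#' scaffold. Runs touching either end of a scaffold have no flank on that
#' side and are reported with `fillable = FALSE`; they are never edited.
#'
#' @param seqs Named character vector of scaffold sequences (as returned by
#'   [read_fasta()]), or a single unnamed sequence.
#' @param min_gap_run Minimum N-run length to report (default 1: any `N` is
#'   an unknown base).
#' @return data.frame with columns `scaffold_id`, `gap_index` (1-based
#'   ordinal within the scaffold), `start`, `end` (0-based half-open),
#'   `length`, `fillable`, sorted by scaffold (input order) then `start`.
#' @export
find_gaps <- function(seqs, min_gap_run = 1L) {
  stopifnot(min_gap_run >= 1L)
  if (is.null(names(seqs))) {
    if (length(seqs) != 1L) stop("unnamed input must be a single sequence")
    names(seqs) <- "seq"
  }
  out <- lapply(seq_along(seqs), function(k) {
    s <- seqs[[k]]
    m <- gregexpr("N+", s)[[1L]]
    if (m[1L] == -1L) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_gap_run
    if (!any(keep)) return(NULL)
    start <- as.integer(m[keep]) - 1L
    len <- as.integer(len[keep])
    end <- start + len
    data.frame(
      scaffold_id = names(seqs)[k],
      gap_index = seq_along(start),
      start = start,
      end = end,
      length = len,
      fillable = start > 0L & end < nchar(s),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(
      scaffold_id = character(0), gap_index = integer(0),
      start = integer(0), end = integer(0), length = integer(0),
      fillable = logical(0), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Extract the flanking sequences of a gap
#'
#' Copies up to `end_length` bases from each side of the gap, with the
#' window shifted away from the gap by `trim` bases so that the `trim`
#' bases immediately adjacent to the gap are ignored (contig edges are
#' frequently low quality). Flanks are truncated at the scaffold bounds and
#' at any interior `N`, so a flank never bridges into a neighbouring gap
#' and never contains an unknown base.
#'
#' @param seq Scaffold sequence (single string).
#' @param gap One-row data.frame (or list) with `start` and `end` as
#'   produced by [find_gaps()]; must be fillable.
#' @param end_length Maximum flank window per side, in bases.
#' @param trim Bases ignored at each gap-adjacent edge (default 0).
#' @return List with `left_seq`, `right_seq`, `left_span`, `right_span`
#'   (integer `c(start, end)`, 0-based half-open scaffold coordinates the
#'   flanks were copied from), `gap_start`, `gap_end`, `trim`.
#' @export
extract_flanks <- function(seq, gap, end_length, trim = 0L) {
  stopifnot(end_length > trim, trim >= 0L)
  gs <- as.integer(gap$start)
  ge <- as.integer(gap$end)
  n <- nchar(seq)
  want <- as.integer(end_length)

  # Left flank: window ends at gs - trim.
  le <- gs - as.integer(trim)
  ls <- max(0L, le - want)
  left <- if (le > ls) substr(seq, ls + 1L, le) else ""
  # Truncate at the last interior N (keep only the N-free suffix).
  nn <- gregexpr("N", left)[[1L]]
  if (nn[1L] != -1L) {
    cut <- max(nn)
    ls <- ls + cut
    left <- substr(left, cut + 1L, nchar(left))
  }

  # Right flank: window starts at ge + trim.
  rs <- ge + as.integer(trim)
  re <- min(n, rs + want)
  right <- if (re > rs) substr(seq, rs + 1L, re) else ""
  nn <- gregexpr("N", right)[[1L]]
  if (nn[1L] != -1L) {
    cut <- min(nn)
    re <- rs + cut - 1L
    right <- substr(right, 1L, cut - 1L)
  }

  list(
    left_seq = left, right_seq = right,
    left_span = c(ls, le), right_span = c(rs, re),
    gap_start = gs, gap_end = ge, trim = as.integer(trim)
  )
}

#' Shift gap coordinates downstream of an edit
#'
#' After replacing an interval of a scaffold, gaps at or beyond the edit
#' position move by the edit's length change.
#'
#' @param gaps data.frame from [find_gaps()] (one scaffold), sorted by
#'   `start`.
#' @param edit_at Scaffold offset of the edit; no gap may span it.
#' @param delta Signed length change of the edit.
#' @return `gaps` with `start`/`end` of downstream gaps shifted by `delta`.
#' @export
shift_downstream <- function(gaps, edit_at, delta) {
  if (nrow(gaps) == 0L) return(gaps)
  spans <- gaps$start < edit_at & gaps$end > edit_at
  if (any(spans)) {
    stop("gap [", gaps$start[spans][1L], ",", gaps$end[spans][1L],
         ") spans edit position ", edit_at, call. = FALSE)
  }
  move <- gaps$start >= edit_at
  gaps$start[move] <- gaps$start[move] + as.integer(delta)
  gaps$end[move] <- gaps$end[move] + as.integer(delta)
  if (any(gaps$start < 0L)) {
    stop("coordinate shift produced a negative gap start (bookkeeping bug)",
         call. = FALSE)
  }
  gaps
}
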