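# Exact local alignment used as an engine-independent oracle in tests and
# for short-insert validation.

#' Exact affine-gap local alignment
#'
#' Optimal Smith-Waterman local alignment with affine gap costs: a gap of
#' length L costs `open_gap + L * extend_gap`. Tie-breaking among
#' equal-score optima is deterministic: smallest query start, then smallest
#' subject start. Intended as an exact oracle on small inputs; guarded to
#' `|query| * |subject| <= 1e6`.
#'
#' @param query,subject Nucleotide strings.
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param open_gap,extend_gap Gap open / extend penalties (positive).
#' @return List with `score` and, when `score > 0`: `q_start`, `q_end`,
#'   `s_start`, `s_end` (0-based half-open), `n_matches`, `aln_length`
#'   (alignment columns including gaps) and `identity` (percent matches
#'   over columns). `score = 0` means no positive-scoring local alignment
#'   exists.
#' @export
oracle_align <- function(query, subject, match = 1, mismatch = -3,
                         open_gap = 5, extend_gap = 2) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1L, length(subject) == 1L,
            match > 0, mismatch < 0, open_gap >= 0, extend_gap > 0)
  if (as.double(nchar(query)) * nchar(subject) > 1e6) {
    stop("oracle_align guard exceeded: |query| * |subject| > 1e6",
         call. = FALSE)
  }
  .sw_align_cpp(query, subject, match, mismatch, open_gap, extend_gap)
}
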