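# Per-round logs: a human-readable text log (1-based inclusive coordinates,
# matching BLAST convention) and a machine-parseable TSV companion that
# keeps the package's internal 0-based half-open coordinates.

fmt1 <- function(start0, end0) sprintf("%d..%d", start0 + 1L, end0)

#' Write closure records to a human-readable log and a TSV companion
#'
#' The text log has one labelled block per gap; the TSV holds every record
#' column and round-trips through [read_closure_log()].
#'
#' @param records Closure records from [run_round()] / [close_gaps()].
#' @param path Text log path.
#' @param tsv_path TSV companion path (default: `path` with a `.tsv`
#'   extension).
#' @return Invisibly, `c(path, tsv_path)`.
#' @export
write_log <- function(records, path, tsv_path = NULL) {
  if (is.null(tsv_path)) {
    tsv_path <- paste0(tools::file_path_sans_ext(path), ".tsv")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open log file '", path, "' for writing", call. = FALSE)
  })
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# gapweld closure log (coordinates 1-based inclusive)")
  w("# %d gap record(s)", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    w("")
    w("gap %s:%d [%s] len=%d round=%d status=%s",
      r$scaffold_id, r$gap_index, fmt1(r$gap_start, r$gap_end),
      r$gap_length, r$round, r$status)
    if (identical(r$status, "closed")) {
      w("  subject=%s orientation=%s combined_score=%.1f",
        r$subject_id, r$orientation, r$combined_score)
      w("  left  hit: score=%.1f evalue=%.2g identity=%.2f q=%s s=%s",
        r$left_score, r$left_evalue, r$left_identity,
        fmt1(r$left_q_start, r$left_q_end),
        fmt1(r$left_s_start, r$left_s_end))
      w("  right hit: score=%.1f evalue=%.2g identity=%.2f q=%s s=%s",
        r$right_score, r$right_evalue, r$right_identity,
        fmt1(r$right_q_start, r$right_q_end),
        fmt1(r$right_s_start, r$right_s_end))
      w("  insert_len=%d removed_left=%d removed_right=%d delta=%d",
        r$insert_len, r$removed_left, r$removed_right, r$delta)
      w("  cut=%s", fmt1(r$cut_start, r$cut_end))
      w("  inserted=%s",
        if (nchar(r$replacement) > 0L) r$replacement else "(none)")
    }
    if (!is.na(r$note) && nzchar(r$note)) w("  note: %s", r$note)
  }
  utils::write.table(records, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(path, tsv_path))
}

#' Read a closure-record TSV back into a data.frame
#'
#' @param tsv_path Path written by [write_log()] (one or several; rows are
#'   concatenated).
#' @return Closure records with the same columns and types as produced by
#'   [run_round()].
#' @export
read_closure_log <- function(tsv_path) {
  template <- empty_records()
  classes <- vapply(template, function(x) class(x)[1L], character(1))
  parts <- lapply(tsv_path, function(p) {
    df <- utils::read.delim(p, sep = "\t", quote = "", na.strings = "NA",
                            colClasses = unname(classes),
                            stringsAsFactors = FALSE)
    # Empty strings survive as NA through colClasses="character"; restore.
    for (cn in names(classes)[classes == "character"]) {
      if (cn %in% c("replacement", "left_context", "right_context",
                    "note")) {
        df[[cn]][is.na(df[[cn]]) & df$status == "closed"] <- ""
      }
    }
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
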