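# External alignment engine: nucleotide BLAST+ (makeblastdb + blastn),
# driven over flank queries and parsed from tabular output into a canonical
# hit table. All hit coordinates are normalized to 0-based half-open
# intervals on the subject FORWARD strand plus an orientation flag.

BLAST_COLUMNS <- c("qseqid", "sseqid", "qstart", "qend", "sstart", "send",
                   "sstrand", "bitscore", "evalue", "pident", "length",
                   "nident", "qlen", "slen")

#' Alignment engine parameters
#'
#' Thresholds and scoring used both to configure blastn and to filter the
#' returned hits. `min_score` is a bit-score threshold. Defaults are
#' conventional blastn scoring (match 1, mismatch -3, gap open 5, gap
#' extend 2, word size 11) with conservative hit thresholds; all are
#' user-overridable.
#'
#' @param min_score Minimum bit score for a hit to be kept.
#' @param max_evalue Maximum e-value.
#' @param min_identity Minimum percent identity, in `[0, 100]`.
#' @param match,mismatch Match reward and mismatch penalty (mismatch
#'   negative).
#' @param open_gap,extend_gap Gap open / extend penalties (positive).
#' @param word_size blastn word size (>= 4).
#' @param max_alignments Maximum hits retained per query, by descending bit
#'   score.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(min_score = 25, max_evalue = 1e-7,
                             min_identity = 70, match = 1, mismatch = -3,
                             open_gap = 5, extend_gap = 2, word_size = 11,
                             max_alignments = 50) {
  stopifnot(
    min_identity >= 0, min_identity <= 100,
    max_evalue > 0, word_size >= 4, max_alignments >= 1,
    match > 0, mismatch < 0, open_gap >= 0, extend_gap > 0
  )
  structure(
    list(
      min_score = min_score, max_evalue = max_evalue,
      min_identity = min_identity, match = match, mismatch = mismatch,
      open_gap = open_gap, extend_gap = extend_gap,
      word_size = as.integer(word_size),
      max_alignments = as.integer(max_alignments)
    ),
    class = "alignment_params"
  )
}

blast_binary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    stop("BLAST+ binary '", name, "' not found on PATH", call. = FALSE)
  }
  path
}

#' Build a BLAST nucleotide index over a dataset
#'
#' Writes the dataset to `workdir` and runs `makeblastdb`. The handle keeps
#' the dataset sequences in memory (they are needed to extract fill
#' sequences) and is reusable across rounds.
#'
#' @param dataset Named character vector of dataset sequences.
#' @param workdir Directory for index files (created if missing; default a
#'   fresh temporary directory).
#' @param label Short label used in file names and logs.
#' @return An object of class `blast_index`.
#' @export
build_blast_index <- function(dataset, workdir = tempfile("gwdb"),
                              label = "dataset") {
  if (length(dataset) == 0L) {
    stop("cannot index an empty dataset", call. = FALSE)
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(workdir, paste0(label, ".fa"))
  write_fasta(dataset, fasta)
  db <- file.path(workdir, label)
  out <- suppressWarnings(system2(
    blast_binary("makeblastdb"),
    c("-in", shQuote(fasta), "-dbtype", "nucl", "-out", shQuote(db)),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("makeblastdb failed (exit ", status, "):\n",
         paste(out, collapse = "\n"), call. = FALSE)
  }
  structure(
    list(db = db, fasta = fasta, label = label, seqs = dataset,
         n = length(dataset)),
    class = "blast_index"
  )
}

empty_hits <- function() {
  data.frame(
    query_id = character(0), subject_id = character(0),
    q_start = integer(0), q_end = integer(0),
    s_start = integer(0), s_end = integer(0),
    orientation = character(0), score = numeric(0), evalue = numeric(0),
    identity = numeric(0), aln_length = integer(0), n_ident = integer(0),
    q_len = integer(0), s_len = integer(0),
    stringsAsFactors = FALSE
  )
}

parse_blast_tabular <- function(lines) {
  if (length(lines) == 0L) return(empty_hits())
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- tryCatch(
    utils::read.table(con, sep = "\t", quote = "", comment.char = "",
                      col.names = BLAST_COLUMNS, stringsAsFactors = FALSE),
    error = function(e) {
      stop("unparseable blastn tabular output: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  reverse <- tab$sstrand == "minus"
  data.frame(
    query_id = as.character(tab$qseqid),
    subject_id = as.character(tab$sseqid),
    q_start = tab$qstart - 1L,
    q_end = tab$qend,
    s_start = ifelse(reverse, tab$send, tab$sstart) - 1L,
    s_end = ifelse(reverse, tab$sstart, tab$send),
    orientation = ifelse(reverse, "reverse", "forward"),
    score = tab$bitscore,
    evalue = tab$evalue,
    identity = tab$pident,
    aln_length = tab$length,
    n_ident = tab$nident,
    q_len = tab$qlen,
    s_len = tab$slen,
    stringsAsFactors = FALSE
  )
}

#' Align query sequences against an indexed dataset
#'
#' Runs blastn (`-task blastn`, dust masking off for determinism) and
#' returns hits with 0-based half-open forward-strand subject coordinates
#' and an `orientation` flag (`reverse` means the query matched the reverse
#' complement of the subject interval). Hits are threshold-filtered and at
#' most `params$max_alignments` hits per query are kept, by descending bit
#' score with deterministic tie-breaking.
#'
#' @param queries Named character vector of N-free query sequences.
#' @param index A `blast_index` from [build_blast_index()].
#' @param params An [alignment_params()] object.
#' @param threads blastn threads (default 1).
#' @return Hit data.frame (see [filter_hits()] for the columns).
#' @export
align_queries <- function(queries, index, params = alignment_params(),
                          threads = 1L) {
  stopifnot(inherits(index, "blast_index"),
            inherits(params, "alignment_params"))
  if (length(queries) == 0L) return(empty_hits())
  if (any(grepl("N", queries, fixed = TRUE))) {
    stop("query sequences must be N-free", call. = FALSE)
  }
  qfile <- tempfile("gwq", fileext = ".fa")
  on.exit(unlink(qfile), add = TRUE)
  write_fasta(queries, qfile)

  args <- c(
    "-task", "blastn",
    "-query", shQuote(qfile),
    "-db", shQuote(index$db),
    "-word_size", params$word_size,
    "-reward", params$match,
    "-penalty", params$mismatch,
    "-gapopen", params$open_gap,
    "-gapextend", params$extend_gap,
    "-evalue", format(params$max_evalue, scientific = TRUE),
    "-perc_identity", params$min_identity,
    "-dust", "no", "-soft_masking", "false",
    "-num_threads", max(1L, as.integer(threads)),
    "-max_target_seqs", max(500L, params$max_alignments),
    "-outfmt", shQuote(paste(c(6, BLAST_COLUMNS), collapse = " "))
  )
  out <- suppressWarnings(system2(blast_binary("blastn"), args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("blastn failed (exit ", status, "):\n",
         paste(out, collapse = "\n"), call. = FALSE)
  }
  hits <- parse_blast_tabular(out)
  hits <- filter_hits(hits, params)
  cap_hits_per_query(hits, params$max_alignments)
}

# Keep at most k hits per query by descending score; ties broken by
# ascending e-value, subject id, subject start, orientation.
cap_hits_per_query <- function(hits, k) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, -hits$score, hits$evalue, hits$subject_id,
               hits$s_start, hits$orientation)
  hits <- hits[ord, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                     FUN = seq_along) <= k
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter alignment hits by score, e-value and identity thresholds
#'
#' Applied defensively even though [align_queries()] already passes the
#' thresholds to the engine. Order is preserved; the operation is
#' idempotent.
#'
#' @param hits Hit data.frame.
#' @param params An [alignment_params()] object.
#' @return The rows of `hits` passing all three thresholds.
#' @export
filter_hits <- function(hits, params = alignment_params()) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$score >= params$min_score &
    hits$evalue <= params$max_evalue &
    hits$identity >= params$min_identity
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
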