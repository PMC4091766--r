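# FASTA I/O and sequence primitives. An assembly is represented throughout
# the package as a named character vector: names are record ids, values are
# uppercase nucleotide strings. All internal coordinates are 0-based,
# half-open.

IUPAC_CHARS <- "ACGTNRYSWKMBDHV"

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and headers are tokenized at the first
#' whitespace to obtain the record id. Records are returned in file order.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, one element per
#'   record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a scaffold", "acgt", "NNAC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no sequences found in FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("empty sequence id in FASTA file: ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[duplicated(ids)][1L],
         "' in FASTA file: ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  bad <- regexpr(sprintf("[^%s]", IUPAC_CHARS), seqs)
  if (any(bad > 0L)) {
    k <- which(bad > 0L)[1L]
    stop("non-IUPAC character '", substr(seqs[k], bad[k], bad[k]),
         "' at position ", bad[k], " of record '", ids[k], "'",
         call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' Round-trips with [read_fasta()]: ids and sequences are reproduced
#' exactly.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Bases per output line (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), width >= 1L)
  if (length(seqs) == 0L) {
    stop("refusing to write an empty FASTA file", call. = FALSE)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  ok <- tryCatch({
    Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write FASTA file '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' Handles the full IUPAC ambiguity alphabet including `N`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))
  )
  names(out) <- names(x)
  out
}
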