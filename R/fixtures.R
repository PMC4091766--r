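# Synthetic reference/draft/dataset triples with known ground truth, so
# every stage and the end-to-end pipeline are testable without downloads.
# The draft is derived from the reference by punching three kinds of gap:
#   positive     - fill_len reference bases replaced by an N-run;
#   zero         - an N-run inserted between abutting contigs;
#   negative(k)  - k reference bases duplicated on both sides of an
#                  inserted N-run, emulating overlapping contig ends.
# Dataset fragments span every gap region plus flanks, optionally carry
# substitution errors and reverse-complemented orientation; decoy fragments
# are drawn from an unrelated random sequence so threshold filters are
# exercised.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Default mixed gap table for fixtures
#'
#' Evenly spaced gaps cycling through positive fills (10-400 bp), zero
#' gaps, and negative gaps (overlapping contig ends, 8-60 bp overlap), with
#' varying N-run lengths.
#'
#' @param n Number of gaps (default 20).
#' @return data.frame with columns `pos_frac`, `kind`, `n_run`,
#'   `fill_len`, `overlap`.
#' @export
default_gap_table <- function(n = 20L) {
  pos_frac <- seq(0.05, 0.95, length.out = n)
  kind <- rep(c("positive", "positive", "positive", "zero", "negative"),
              length.out = n)
  n_pos <- sum(kind == "positive")
  fill <- integer(n)
  fill[kind == "positive"] <- as.integer(round(
    seq(10, 400, length.out = max(n_pos, 2L))))[seq_len(n_pos)]
  overlap <- integer(n)
  n_neg <- sum(kind == "negative")
  overlap[kind == "negative"] <- as.integer(round(
    seq(8, 60, length.out = max(n_neg, 2L))))[seq_len(n_neg)]
  data.frame(
    pos_frac = pos_frac, kind = kind,
    n_run = rep(c(10L, 1L, 45L, 80L, 25L), length.out = n),
    fill_len = fill, overlap = overlap,
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic fixture
#'
#' Defaults describe the package's standard test scenario: a 100 kb random
#' genome with 20 mixed gaps, two error-free spanning fragments per gap and
#' ten decoys.
#'
#' @param genome_length Reference length in bases.
#' @param gc_content Target GC fraction.
#' @param seed Integer seed; all three artifacts are fully deterministic
#'   given the spec.
#' @param gaps Gap table as from [default_gap_table()].
#' @param end_length Flank span each fragment must cover beyond its gap
#'   region (match the closing run's `end_length`).
#' @param fragment_mean,fragment_sd Dataset fragment length distribution.
#' @param frags_per_gap Spanning fragments generated per gap (coverage).
#' @param substitution_rate Per-base substitution probability in fragments,
#'   in `[0, 0.2]`.
#' @param reverse_complement_fraction Fraction of fragments emitted as
#'   reverse complements.
#' @param decoys Number of unrelated decoy fragments.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(genome_length = 100000L, gc_content = 0.5,
                         seed = 1L, gaps = default_gap_table(20L),
                         end_length = 300L,
                         fragment_mean = 4000L, fragment_sd = 300L,
                         frags_per_gap = 2L, substitution_rate = 0,
                         reverse_complement_fraction = 0,
                         decoys = 10L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.2,
            reverse_complement_fraction >= 0,
            reverse_complement_fraction <= 1,
            gc_content > 0, gc_content < 1, frags_per_gap >= 1L)
  gaps <- gaps[order(gaps$pos_frac), , drop = FALSE]
  anchors <- round(gaps$pos_frac * genome_length)
  if (any(anchors < end_length) ||
      any(anchors + gaps$fill_len > genome_length - end_length)) {
    stop("gap positions must leave at least end_length flank on each side",
         call. = FALSE)
  }
  structure(
    list(genome_length = as.integer(genome_length),
         gc_content = gc_content, seed = as.integer(seed), gaps = gaps,
         end_length = as.integer(end_length),
         fragment_mean = as.integer(fragment_mean),
         fragment_sd = as.integer(fragment_sd),
         frags_per_gap = as.integer(frags_per_gap),
         substitution_rate = substitution_rate,
         reverse_complement_fraction = reverse_complement_fraction,
         decoys = as.integer(decoys)),
    class = "fixture_spec"
  )
}

#' Generate the fixture reference genome
#'
#' @param spec A [fixture_spec()].
#' @return Named character vector with one record, `genome`.
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  seq <- with_seed(spec$seed,
                   random_dna(spec$genome_length, spec$gc_content))
  c(genome = seq)
}

#' Derive a gapped draft from the reference
#'
#' @param reference Named character vector from [make_reference()].
#' @param spec A [fixture_spec()].
#' @return List with `draft` (named character vector; the record keeps the
#'   reference id) and `truth` (data.frame: `gap_id`, `kind`, `ref_pos`,
#'   `n_run`, `fill_len`, `overlap`, `draft_start`, `draft_end` (0-based
#'   half-open N-run coordinates in the draft), `true_fill`).
#' @export
make_gapped_draft <- function(reference, spec) {
  ref <- reference[[1L]]
  L <- nchar(ref)
  gaps <- spec$gaps
  anchors <- as.integer(round(gaps$pos_frac * L))

  parts <- character(0)
  draft_len <- 0L
  cursor <- 0L  # next reference base to emit
  truth <- list()
  for (j in seq_len(nrow(gaps))) {
    g <- gaps[j, ]
    p <- anchors[j]
    k <- if (g$kind == "negative") g$overlap else 0L
    if (p - k <= cursor) {
      stop("overlapping gap specs at reference position ", p,
           call. = FALSE)
    }
    seg <- substr(ref, cursor + 1L, p)
    parts <- c(parts, seg, strrep("N", g$n_run))
    draft_start <- draft_len + nchar(seg)
    draft_end <- draft_start + g$n_run
    draft_len <- draft_end
    cursor <- switch(g$kind,
      positive = p + g$fill_len,
      zero = p,
      negative = p - k
    )
    truth[[j]] <- data.frame(
      gap_id = j, kind = g$kind, ref_pos = p, n_run = g$n_run,
      fill_len = if (g$kind == "positive") g$fill_len else 0L,
      overlap = k, draft_start = draft_start, draft_end = draft_end,
      true_fill = if (g$kind == "positive")
        substr(ref, p + 1L, p + g$fill_len) else "",
      stringsAsFactors = FALSE
    )
  }
  parts <- c(parts, substr(ref, cursor + 1L, L))
  draft <- paste(parts, collapse = "")
  names(draft) <- names(reference)[1L]
  list(draft = draft, truth = do.call(rbind, truth))
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate the dataset fragments for a fixture
#'
#' For every gap, `frags_per_gap` fragments fully spanning the gap's true
#' reference region plus `end_length` flanks, mutated at
#' `substitution_rate`, a `reverse_complement_fraction` of them flipped;
#' plus `decoys` unrelated fragments drawn from a different seed's random
#' sequence, length- and GC-matched.
#'
#' @param reference Named character vector from [make_reference()].
#' @param spec A [fixture_spec()].
#' @return Named character vector of fragments.
#' @export
make_dataset <- function(reference, spec) {
  ref <- reference[[1L]]
  L <- nchar(ref)
  gaps <- spec$gaps
  anchors <- as.integer(round(gaps$pos_frac * L))
  margin <- spec$end_length + 50L

  with_seed(spec$seed + 1L, {
    frags <- character(0)
    for (j in seq_len(nrow(gaps))) {
      g <- gaps[j, ]
      p <- anchors[j]
      region <- switch(g$kind,
        positive = c(p, p + g$fill_len),
        zero = c(p, p),
        negative = c(p - g$overlap, p)
      )
      need <- (region[2L] - region[1L]) + 2L * margin
      for (f in seq_len(spec$frags_per_gap)) {
        flen <- max(need, as.integer(round(
          stats::rnorm(1L, spec$fragment_mean, spec$fragment_sd))))
        if (flen > L) {
          stop("fragment longer than the reference", call. = FALSE)
        }
        centre <- (region[1L] + region[2L]) %/% 2L
        lo <- max(0L, region[2L] + margin - flen)
        hi <- min(L - flen, region[1L] - margin)
        if (lo > hi) {
          stop("cannot place a spanning fragment for gap ", j, call. = FALSE)
        }
        a <- min(max(centre - flen %/% 2L, lo), hi)
        frag <- substr(ref, a + 1L, a + flen)
        if (spec$substitution_rate > 0) {
          frag <- mutate_seq(frag, spec$substitution_rate)
        }
        if (stats::runif(1L) < spec$reverse_complement_fraction) {
          frag <- revcomp(frag)
        }
        frags[sprintf("frag_g%02d_%d", j, f)] <- frag
      }
    }
    if (spec$decoys > 0L) {
      pool <- random_dna(spec$decoys * spec$fragment_mean +
                           spec$fragment_mean, spec$gc_content)
      for (d in seq_len(spec$decoys)) {
        a <- (d - 1L) * spec$fragment_mean
        frags[sprintf("decoy_%02d", d)] <-
          substr(pool, a + 1L, a + spec$fragment_mean)
      }
    }
    frags
  })
}

#' Write a complete fixture to a directory
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return List with paths `reference`, `draft`, `dataset`, `truth` and the
#'   in-memory objects.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- make_reference(spec)
  gd <- make_gapped_draft(reference, spec)
  dataset <- make_dataset(reference, spec)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    draft = file.path(dir, "draft.fa"),
    dataset = file.path(dir, "dataset.fa"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(reference, paths$reference)
  write_fasta(gd$draft, paths$draft)
  write_fasta(dataset, paths$dataset)
  utils::write.table(gd$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(reference_seq = reference, draft_seq = gd$draft,
                truth_table = gd$truth, dataset_seqs = dataset))
}
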