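# Shared fixture builders for driver/validation tests. Everything is
# generated in code; nothing is read from disk except what the test itself
# writes.

# A reference with two equal-length gaps punched `dist` bases apart plus a
# single spanning dataset fragment. Closing both restores the reference.
make_pair_gap_fixture <- function(dir, dist = 100L, n_run = 50L,
                                  seed = 11L) {
  set.seed(seed)
  r <- rand_dna(8000L)
  ref <- c(chrA = r)
  g1 <- c(3000L, 3000L + n_run)             # replaces ref[3000, 3050)
  g2s <- g1[2L] + dist                      # second gap starts dist later
  draft <- paste0(
    substr(r, 1, g1[1L]), strrep("N", n_run),
    substr(r, g1[2L] + 1L, g2s), strrep("N", n_run),
    substr(r, g2s + n_run + 1L, nchar(r))
  )
  names(draft) <- "chrA"
  dataset <- c(span = substr(r, 2200L + 1L, 4200L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    draft = file.path(dir, "draft.fa"),
    dataset = file.path(dir, "dataset.fa")
  )
  write_fasta(ref, paths$reference)
  write_fasta(draft, paths$draft)
  write_fasta(dataset, paths$dataset)
  c(paths, list(reference_seq = ref, draft_seq = draft,
                gap_starts = c(g1[1L], g2s)))
}

# Small standard fixture (quick to close) for driver-level tests.
small_fixture <- function(dir, n_gaps = 6L, genome = 30000L, seed = 7L,
                          ...) {
  spec <- fixture_spec(genome_length = genome,
                       gaps = default_gap_table(n_gaps), seed = seed, ...)
  write_fixture(spec, dir)
}
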