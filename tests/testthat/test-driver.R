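test_that("an assembly without gaps passes through unchanged", {
  set.seed(61)
  asm <- c(chr = rand_dna(2000L))
  ix <- build_blast_index(c(d = rand_dna(1000L)))
  cfg <- run_config(draft = "unused", datasets = "unused",
                    out_prefix = "unused")
  res <- run_round(asm, list(ix), cfg)
  expect_identical(res$assembly, asm)
  expect_equal(nrow(res$records), 0L)
})

test_that("well-separated gaps all close in round one and restore the reference", {
  dir <- withr::local_tempdir()
  fx <- small_fixture(file.path(dir, "fx"))
  cfg <- run_config(draft = fx$draft, datasets = fx$dataset,
                    out_prefix = file.path(dir, "out"),
                    limits = closure_limits(allow_negative = TRUE))
  res <- close_gaps(cfg, quiet = TRUE)
  r1 <- res$records[res$records$round == 1L, ]
  expect_true(all(r1$status == "closed"))
  expect_identical(res$assembly[["genome"]], fx$reference_seq[["genome"]])
})

test_that("adjacent gaps are deferred in round one and closed in round two", {
  dir <- withr::local_tempdir()
  fx <- make_pair_gap_fixture(file.path(dir, "fx"), dist = 100L)
  cfg <- run_config(draft = fx$draft, datasets = fx$dataset,
                    out_prefix = file.path(dir, "out"))
  res <- close_gaps(cfg, quiet = TRUE)
  rec <- res$records
  expect_identical(
    rec$status[rec$round == 1L][order(rec$gap_start[rec$round == 1L])],
    c("closed", "deferred_conflict"))
  expect_identical(rec$status[rec$round == 2L], "closed")
  expect_identical(res$assembly[["chrA"]], fx$reference_seq[["chrA"]])

  # With a single round the deferred gap stays open.
  cfg1 <- run_config(draft = fx$draft, datasets = fx$dataset,
                     out_prefix = file.path(dir, "out1"), max_rounds = 1L)
  res1 <- close_gaps(cfg1, quiet = TRUE)
  expect_equal(sum(res1$records$status == "closed"), 1L)
  expect_equal(nrow(find_gaps(res1$assembly)), 1L)
})

test_that("a dataset with no homology changes nothing and exits cleanly", {
  dir <- withr::local_tempdir()
  fx <- small_fixture(file.path(dir, "fx"), n_gaps = 3L, genome = 15000L)
  set.seed(88)
  noise <- c(junk1 = rand_dna(3000L), junk2 = rand_dna(3000L))
  write_fasta(noise, file.path(dir, "noise.fa"))
  cfg <- run_config(draft = fx$draft,
                    datasets = file.path(dir, "noise.fa"),
                    out_prefix = file.path(dir, "out"))
  res <- close_gaps(cfg, quiet = TRUE)
  expect_equal(sum(res$records$status == "closed"), 0L)
  expect_identical(res$assembly[["genome"]], fx$draft_seq[["genome"]])
  st <- res$stats
  expect_true(all(st$gaps_closed == 0L))
  expect_true(all(st$bases_inserted == 0L))
})

test_that("per-round outputs are written and stats add up", {
  dir <- withr::local_tempdir()
  fx <- small_fixture(file.path(dir, "fx"))
  cfg <- run_config(draft = fx$draft, datasets = fx$dataset,
                    out_prefix = file.path(dir, "out"),
                    limits = closure_limits(allow_negative = TRUE))
  res <- close_gaps(cfg, quiet = TRUE)
  expect_true(all(file.exists(res$files)))
  st <- res$stats
  expect_true(all(st$gaps_before - st$gaps_closed == st$gaps_remaining))
  total <- st[st$round == "total", ]
  len_change <- nchar(res$assembly[["genome"]]) -
    nchar(fx$draft_seq[["genome"]])
  expect_equal(total$bases_inserted - total$bases_removed, len_change)
  # Re-scanning the final FASTA finds exactly the gaps logged unclosed.
  final_fa <- res$files[grep("round2\\.fasta$",
                             res$files)[1L]]
  expect_equal(nrow(find_gaps(read_fasta(final_fa))), 0L)
})

test_that("the closure log TSV round-trips through its parser", {
  dir <- withr::local_tempdir()
  fx <- small_fixture(file.path(dir, "fx"))
  cfg <- run_config(draft = fx$draft, datasets = fx$dataset,
                    out_prefix = file.path(dir, "out"),
                    limits = closure_limits(allow_negative = TRUE))
  res <- close_gaps(cfg, quiet = TRUE)
  tsvs <- res$files[grepl("\\.tsv$", res$files) &
                      grepl("round", res$files)]
  back <- read_closure_log(tsvs)
  expect_equal(back, res$records)
  # The text log names every closed gap's subject and both hit scores.
  log1 <- readLines(res$files[grepl("round1\\.log$", res$files)])
  closed1 <- res$records[res$records$round == 1L &
                           res$records$status == "closed", ]
  for (sid in closed1$subject_id) {
    expect_true(any(grepl(sid, log1, fixed = TRUE)))
  }
  expect_true(any(grepl("left  hit: score=", log1, fixed = TRUE)))
})

test_that("identical runs produce byte-identical outputs", {
  dir <- withr::local_tempdir()
  fx <- small_fixture(file.path(dir, "fx"), n_gaps = 4L, genome = 20000L)
  run_once <- function(tag) {
    cfg <- run_config(draft = fx$draft, datasets = fx$dataset,
                      out_prefix = file.path(dir, tag),
                      limits = closure_limits(allow_negative = TRUE))
    close_gaps(cfg, quiet = TRUE)$files
  }
  f1 <- run_once("a")
  f2 <- run_once("b")
  expect_equal(length(f1), length(f2))
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[k]), readLines(f2[k]),
                     info = basename(f1[k]))
  }
})

test_that("YAML configuration merges with overrides", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("draft: d.fa", "datasets: x.fa", "out_prefix: pre",
               "end_length: 250", "min_identity: 80",
               "allow_negative: yes"), yml)
  cfg <- run_config_from_yaml(yml, overrides = list(end_length = 400L))
  expect_equal(cfg$end_length, 400L)
  expect_equal(cfg$params$min_identity, 80)
  expect_true(cfg$limits$allow_negative)
  expect_identical(cfg$draft, "d.fa")
})
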