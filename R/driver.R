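# Multi-round, conflict-safe orchestration over all scaffolds and datasets.
#
# A round pre-extracts the flanks of every fillable gap, aligns them in one
# engine call per dataset, then walks each scaffold left to right applying
# the best edit per gap. A gap is eligible only if neither of its flank
# windows (end_length bases per side) intersects an interval already edited
# this round on the same scaffold; otherwise it is deferred to the next
# round, which prevents a closure from rewriting the query sequence of a
# neighbouring gap. Rounds repeat until one closes nothing or max_rounds is
# reached; the FASTA written by round k is the input of round k+1.

#' Configuration for a gap-closing run
#'
#' @param draft Path to the draft assembly FASTA.
#' @param datasets Character vector of dataset FASTA paths (alternative
#'   assemblies, long reads, contigs), consulted as one pooled candidate
#'   set.
#' @param out_prefix Output prefix; the run writes
#'   `<prefix>.round<k>.fasta`, `<prefix>.round<k>.log`,
#'   `<prefix>.round<k>.tsv` and `<prefix>.stats.tsv`.
#' @param end_length Flank window per gap side, bases (default 300).
#' @param trim Bases ignored at each gap-adjacent contig edge (default 0).
#' @param params [alignment_params()].
#' @param limits [closure_limits()].
#' @param max_rounds Maximum rounds (default 3).
#' @param min_flank Minimum usable flank length; shorter flanks make a gap
#'   unalignable for the round (default 20).
#' @param min_gap_run Minimum N-run length treated as a gap (default 1).
#' @param fasta_width Output FASTA line width (default 70).
#' @param threads Threads for the alignment engine (default 1).
#' @return An object of class `run_config`.
#' @export
run_config <- function(draft, datasets, out_prefix,
                       end_length = 300L, trim = 0L,
                       params = alignment_params(),
                       limits = closure_limits(),
                       max_rounds = 3L, min_flank = 20L,
                       min_gap_run = 1L, fasta_width = 70L,
                       threads = 1L) {
  stopifnot(max_rounds >= 1L, end_length > trim, min_flank >= 1L,
            inherits(params, "alignment_params"),
            inherits(limits, "closure_limits"))
  structure(
    list(draft = draft, datasets = datasets, out_prefix = out_prefix,
         end_length = as.integer(end_length), trim = as.integer(trim),
         params = params, limits = limits,
         max_rounds = as.integer(max_rounds),
         min_flank = as.integer(min_flank),
         min_gap_run = as.integer(min_gap_run),
         fasta_width = as.integer(fasta_width),
         threads = as.integer(threads)),
    class = "run_config"
  )
}

#' Build a run configuration from a YAML file plus overrides
#'
#' Every [run_config()] argument (and every field of the nested alignment
#' parameters and closure limits, given flat) may appear as a YAML key;
#' entries in `overrides` win over the file.
#'
#' @param path YAML file path (or `NULL` for overrides only).
#' @param overrides Named list of settings taking precedence.
#' @return A `run_config` object.
#' @export
run_config_from_yaml <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  pnames <- names(formals(alignment_params))
  lnames <- names(formals(closure_limits))
  params <- do.call(alignment_params, vals[intersect(names(vals), pnames)])
  limits <- do.call(closure_limits, vals[intersect(names(vals), lnames)])
  rest <- vals[setdiff(names(vals), c(pnames, lnames))]
  do.call(run_config, c(rest, list(params = params, limits = limits)))
}

empty_records <- function() {
  num <- numeric(0); int <- integer(0); chr <- character(0)
  data.frame(
    round = int, scaffold_id = chr, gap_index = int,
    gap_start = int, gap_end = int, gap_length = int, status = chr,
    subject_id = chr, orientation = chr, combined_score = num,
    left_score = num, left_evalue = num, left_identity = num,
    left_q_start = int, left_q_end = int, left_s_start = int,
    left_s_end = int,
    right_score = num, right_evalue = num, right_identity = num,
    right_q_start = int, right_q_end = int, right_s_start = int,
    right_s_end = int,
    insert_len = int, removed_left = int, removed_right = int,
    cut_start = int, cut_end = int, delta = int,
    replacement = chr, left_context = chr, right_context = chr,
    note = chr, stringsAsFactors = FALSE
  )
}

record_row <- function(round, scaffold_id, gap, status, note = "") {
  r <- empty_records()[NA_integer_, , drop = FALSE][1, , drop = FALSE]
  r <- utils::modifyList(as.list(r), list(
    round = as.integer(round), scaffold_id = scaffold_id,
    gap_index = gap$gap_index, gap_start = gap$start, gap_end = gap$end,
    gap_length = gap$length, status = status, note = note
  ))
  as.data.frame(r, stringsAsFactors = FALSE)
}

# N-free context of up to end_length bases ending at (side = "left") or
# starting at (side = "right") position pos of seq.
edge_context <- function(seq, pos, end_length, side) {
  n <- nchar(seq)
  if (side == "left") {
    a <- max(0L, pos - end_length)
    ctx <- substr(seq, a + 1L, pos)
    nn <- gregexpr("N", ctx)[[1L]]
    if (nn[1L] != -1L) ctx <- substr(ctx, max(nn) + 1L, nchar(ctx))
  } else {
    b <- min(n, pos + end_length)
    ctx <- substr(seq, pos + 1L, b)
    nn <- gregexpr("N", ctx)[[1L]]
    if (nn[1L] != -1L) ctx <- substr(ctx, 1L, min(nn) - 1L)
  }
  ctx
}

#' Run one closing round over an assembly
#'
#' @param assembly Named character vector of scaffolds.
#' @param indices List of `blast_index` handles (one per dataset).
#' @param config A [run_config()] object.
#' @param round_no Round number (>= 1), recorded in the log.
#' @return List with `assembly` (edited) and `records` (one row per gap
#'   seen this round; statuses `closed`, `no_candidate`,
#'   `deferred_conflict`, `unalignable`).
#' @export
run_round <- function(assembly, indices, config, round_no = 1L) {
  gaps_all <- find_gaps(assembly, config$min_gap_run)
  if (nrow(gaps_all) == 0L) {
    return(list(assembly = assembly, records = empty_records()))
  }

  # Pre-extract flanks for fillable gaps and pool one query set.
  gaps_all$qkey <- paste0("g", seq_len(nrow(gaps_all)))
  flank_of <- vector("list", nrow(gaps_all))
  queries <- character(0)
  for (i in seq_len(nrow(gaps_all))) {
    g <- gaps_all[i, ]
    if (!g$fillable) next
    fl <- extract_flanks(assembly[[g$scaffold_id]], g,
                         config$end_length, config$trim)
    flank_of[[i]] <- fl
    if (nchar(fl$left_seq) >= config$min_flank &&
        nchar(fl$right_seq) >= config$min_flank) {
      qs <- c(fl$left_seq, fl$right_seq)
      names(qs) <- paste0(g$qkey, c("L", "R"))
      queries <- c(queries, qs)
    }
  }

  hits <- empty_hits()
  subjects <- character(0)
  if (length(queries) > 0L) {
    hits <- do.call(rbind, lapply(indices, function(ix) {
      align_queries(queries, ix, config$params, config$threads)
    }))
    subjects <- do.call(c, unname(lapply(indices, function(ix) ix$seqs)))
  }

  records <- list()
  for (sid in names(assembly)) {
    gaps <- gaps_all[gaps_all$scaffold_id == sid, , drop = FALSE]
    if (nrow(gaps) == 0L) next
    seq_now <- assembly[[sid]]
    cum_delta <- 0L
    edited <- list()  # closed intervals in round-start coordinates

    for (i in seq_len(nrow(gaps))) {
      g <- gaps[i, ]
      idx <- as.integer(sub("^g", "", g$qkey))
      fl <- flank_of[[idx]]
      if (!g$fillable) {
        records[[length(records) + 1L]] <- record_row(
          round_no, sid, g, "unalignable", "boundary N-run: no flank")
        next
      }
      if (nchar(fl$left_seq) < config$min_flank ||
          nchar(fl$right_seq) < config$min_flank) {
        records[[length(records) + 1L]] <- record_row(
          round_no, sid, g, "unalignable",
          sprintf("flank below min_flank (%d/%d bp)",
                  nchar(fl$left_seq), nchar(fl$right_seq)))
        next
      }
      win_a <- g$start - config$end_length
      win_b <- g$end + config$end_length
      conflict <- Filter(function(iv) win_a < iv[2L] && iv[1L] < win_b,
                         edited)
      if (length(conflict) > 0L) {
        iv <- conflict[[1L]]
        records[[length(records) + 1L]] <- record_row(
          round_no, sid, g, "deferred_conflict",
          sprintf("flank window intersects edit [%d,%d)", iv[1L], iv[2L]))
        next
      }
      lhits <- hits[hits$query_id == paste0(g$qkey, "L"), , drop = FALSE]
      rhits <- hits[hits$query_id == paste0(g$qkey, "R"), , drop = FALSE]
      cands <- enumerate_candidates(lhits, rhits, fl, subjects,
                                    config$limits)
      best <- select_best(cands)
      if (is.null(best)) {
        records[[length(records) + 1L]] <- record_row(
          round_no, sid, g, "no_candidate",
          sprintf("%d left / %d right hits, %d pairs admissible",
                  nrow(lhits), nrow(rhits), nrow(cands)))
        next
      }
      edit <- make_edit(best, fl, nchar(assembly[[sid]]))
      # Apply at coordinates shifted by edits already made upstream.
      sh <- list(cut_start = edit$cut_start + cum_delta,
                 cut_end = edit$cut_end + cum_delta,
                 replacement = edit$replacement, delta = edit$delta)
      seq_now <- apply_edit(seq_now, sh)
      left_ctx <- edge_context(seq_now, sh$cut_start, config$end_length,
                               "left")
      right_ctx <- edge_context(seq_now,
                                sh$cut_start + nchar(sh$replacement),
                                config$end_length, "right")
      rec <- record_row(round_no, sid, g, "closed",
                        if (best$insert_len < 0L)
                          "negative gap: overlap removed on right side"
                        else "")
      rec[names(best)] <- as.list(best[1L, ])
      rec$insert_seq <- NULL
      rec$cut_start <- edit$cut_start
      rec$cut_end <- edit$cut_end
      rec$delta <- as.integer(edit$delta)
      rec$replacement <- edit$replacement
      rec$left_context <- left_ctx
      rec$right_context <- right_ctx
      records[[length(records) + 1L]] <- rec[names(empty_records())]
      edited[[length(edited) + 1L]] <- c(edit$cut_start, edit$cut_end)
      cum_delta <- cum_delta + as.integer(edit$delta)
    }
    assembly[[sid]] <- seq_now
  }

  records <- if (length(records)) do.call(rbind, records) else
    empty_records()
  rownames(records) <- NULL
  list(assembly = assembly, records = records)
}

round_stats <- function(records, round_no) {
  closed <- records[records$status == "closed", , drop = FALSE]
  data.frame(
    round = as.character(round_no),
    gaps_before = nrow(records),
    gaps_closed = nrow(closed),
    gaps_remaining = nrow(records) - nrow(closed),
    bases_inserted = sum(nchar(closed$replacement)),
    bases_removed = sum(closed$cut_end - closed$cut_start),
    negative_gaps_closed = sum(closed$insert_len < 0L),
    stringsAsFactors = FALSE
  )
}

#' Close the gaps of a draft assembly
#'
#' Full multi-round pipeline: reads the draft and datasets, indexes each
#' dataset once, runs closing rounds until one closes nothing or
#' `max_rounds` is reached, and writes per-round FASTA and logs plus a
#' final statistics table. Changes are incremental: round k's FASTA is the
#' input of round k+1. The pipeline is deterministic; identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param config A [run_config()] object.
#' @param quiet Suppress per-round progress messages on stderr.
#' @return Invisibly, a list with `assembly` (final sequences), `records`
#'   (all rounds' closure records), `stats` (per-round rows plus a totals
#'   row), and `files` (paths written).
#' @export
close_gaps <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  assembly <- read_fasta(config$draft)
  indices <- lapply(seq_along(config$datasets), function(k) {
    ds <- read_fasta(config$datasets[[k]])
    build_blast_index(ds, label = sprintf("dataset%d", k))
  })
  all_ids <- unlist(lapply(indices, function(ix) names(ix$seqs)))
  if (anyDuplicated(all_ids)) {
    stop("duplicate sequence id across datasets: ",
         all_ids[duplicated(all_ids)][1L], call. = FALSE)
  }

  files <- character(0)
  all_records <- empty_records()
  stats <- list()
  for (k in seq_len(config$max_rounds)) {
    round_files <- paste0(config$out_prefix,
                          c(sprintf(".round%d.fasta", k),
                            sprintf(".round%d.log", k),
                            sprintf(".round%d.tsv", k)))
    res <- tryCatch(
      run_round(assembly, indices, config, k),
      error = function(e) {
        unlink(round_files)
        stop("round ", k, " failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    assembly <- res$assembly
    write_fasta(assembly, round_files[1L], config$fasta_width)
    write_log(res$records, round_files[2L], tsv_path = round_files[3L])
    files <- c(files, round_files)
    all_records <- rbind(all_records, res$records)
    st <- round_stats(res$records, k)
    stats[[k]] <- st
    if (!quiet) {
      message(sprintf("[gapweld] round %d: %d/%d gaps closed (%+d bp)",
                      k, st$gaps_closed, st$gaps_before,
                      st$bases_inserted - st$bases_removed))
    }
    if (st$gaps_closed == 0L) break
  }

  stats <- do.call(rbind, stats)
  total <- stats[1L, , drop = FALSE]
  total$round <- "total"
  for (cn in setdiff(names(stats), "round")) total[[cn]] <- sum(stats[[cn]])
  stats <- rbind(stats, total)
  rownames(stats) <- NULL
  stats_path <- paste0(config$out_prefix, ".stats.tsv")
  utils::write.table(stats, stats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, stats_path)
  invisible(list(assembly = assembly, records = all_records,
                 stats = stats, files = files))
}
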