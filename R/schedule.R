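#' Timing specifications for the miniblock runs
#'
#' \code{timing_main()} returns the main-run timing: blocks of 12 stimuli,
#' each shown 150 ms followed by 200 ms fixation (4.2 s per block), jittered
#' inter-block fixations of 3.8/5.8/7.8 s (mean 5.8 s), 7 additional
#' fixation-only blocks of 8/10/12 s summing to 68 s, 16 s lead-in, 14 s
#' lead-out, TR 2 s. \code{timing_localizer()} returns the localizer timing:
#' blocks of 20 stimuli at 100 + 200 ms (6 s per block), jittered fixations
#' of 4/6/8 s (mean 6 s), 6 s lead-in and lead-out.
#'
#' All durations are kept on a 50 ms grid (integer milliseconds internally)
#' so that run lengths tile exactly.
#'
#' @return a list of class \code{timing_spec}.
#' @export
timing_main <- function() {
  structure(list(
    stim_dur = 0.150, isi = 0.200, items_per_block = 12L,
    iti_values = c(3.8, 5.8, 7.8), iti_mean = 5.8,
    n_fixation_blocks = 7L,
    fixation_durations = c(8, 8, 10, 10, 10, 10, 12),
    lead_in = 16, lead_out = 14, tr = 2),
    class = "timing_spec")
}

#' @rdname timing_main
#' @export
timing_localizer <- function() {
  structure(list(
    stim_dur = 0.100, isi = 0.200, items_per_block = 20L,
    iti_values = c(4, 6, 8), iti_mean = 6,
    n_fixation_blocks = 0L, fixation_durations = numeric(0),
    lead_in = 6, lead_out = 6, tr = 2),
    class = "timing_spec")
}

ms <- function(s) as.integer(round(s * 1000))

# jitter multiset of n values averaging exactly the middle value:
# floor(n/3) of each value, remainder 1 -> one extra middle value,
# remainder 2 -> one extra low and one extra high.
balanced_jitter <- function(n, values) {
  values <- sort(values)
  stopifnot(length(values) == 3L,
            abs(mean(values[c(1L, 3L)]) - values[2L]) < 1e-9)
  k <- n %/% 3L
  out <- rep(values, k)
  out <- switch(as.character(n %% 3L),
                `0` = out,
                `1` = c(out, values[2L]),
                `2` = c(out, values[1L], values[3L]))
  out
}

#' Order the items of one block to avoid repeated letter positions
#'
#' Finds, by randomized backtracking, an ordering of the block's strings in
#' which no two consecutive strings share a letter at the same position (so
#' rapid serial presentation never shows the same letter twice in a row at
#' one location).
#'
#' @param items character vector of equal-length strings.
#' @param seed integer seed; the ordering is deterministic given it.
#' @return the reordered items.
#' @export
order_block_items <- function(items, seed = 1L) {
  n <- length(items)
  if (n <= 1L) return(items)
  L <- unique(nchar(items))
  if (length(L) != 1L) stop("all items must have equal length")
  chars <- do.call(rbind, strsplit(items, ""))
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    conflict[i, j] <- conflict[j, i] <- any(chars[i, ] == chars[j, ])
  }
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  perm <- integer(n)
  used <- logical(n)
  solve <- function(depth, prev) {
    if (depth > n) return(TRUE)
    cands <- which(!used)
    if (prev > 0L) cands <- cands[!conflict[prev, cands]]
    if (!length(cands)) return(FALSE)
    for (j in cands[sample.int(length(cands))]) {
      perm[depth] <<- j
      used[j] <<- TRUE
      if (solve(depth + 1L, j)) return(TRUE)
      used[j] <<- FALSE
    }
    FALSE
  }
  if (!solve(1L, 0L))
    stop("no ordering satisfies the letter-position constraint")
  items[perm]
}

# order every block of one condition; when a block admits no valid
# ordering (single-letter-variant items can make one infeasible), the
# condition's items are re-dealt across its blocks and ordering retried
order_condition_blocks <- function(mat, seed0, max_redeals = 20L) {
  for (attempt in seq_len(max_redeals)) {
    ok <- TRUE
    res <- vector("list", nrow(mat))
    for (r in seq_len(nrow(mat))) {
      o <- tryCatch(order_block_items(mat[r, ],
                                      seed = seed0 + 100L * attempt + r),
                    error = function(e) NULL)
      if (is.null(o)) { ok <- FALSE; break }
      res[[r]] <- o
    }
    if (ok) return(res)
    mat <- matrix(sample(as.vector(mat)), nrow(mat))
  }
  stop("no ordering satisfies the letter-position constraint ",
       "for a condition's blocks")
}

# condition order with no immediate repetition; seeded caller RNG
no_repeat_order <- function(counts, max_restart = 2000L) {
  labs <- names(counts)
  total <- sum(counts)
  for (r in seq_len(max_restart)) {
    cnt <- counts
    prev <- ""
    out <- character(total)
    ok <- TRUE
    for (i in seq_len(total)) {
      avail <- labs[cnt > 0L & labs != prev]
      if (!length(avail)) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = cnt[avail])
      out[i] <- pick
      cnt[pick] <- cnt[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("could not construct a block order without immediate repetition")
}

new_schedule <- function(events, items, timing, run_type, meta) {
  structure(list(events = events, items = items, timing = timing,
                 run_type = run_type, meta = meta),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  ev <- x$events
  cat("<schedule>", x$run_type, ":",
      sum(ev$kind == "stimulus"), "stimulus blocks,",
      sprintf("%.1f s,", sum(ev$duration)),
      ceiling(sum(ev$duration) / x$timing$tr), "volumes\n")
  invisible(x)
}

# shared assembly: interleave stimulus blocks (+ following ITI) with
# fixation-only blocks, bracketed by lead-in/out; onsets tile exactly.
assemble_events <- function(conds, itis, fix_durs, fix_slots, timing) {
  block_ms <- timing$items_per_block * ms(timing$stim_dur + timing$isi)
  n_stim <- length(conds)
  n_slots <- n_stim + length(fix_durs)
  rows <- list()
  t <- 0L
  add <- function(kind, dur_ms, condition = NA_character_,
                  block_id = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      onset = t / 1000, duration = dur_ms / 1000, kind = kind,
      condition = condition, block_id = block_id,
      stringsAsFactors = FALSE)
    t <<- t + dur_ms
  }
  add("lead", ms(timing$lead_in))
  si <- 0L; fi <- 0L
  for (slot in seq_len(n_slots)) {
    if (slot %in% fix_slots) {
      fi <- fi + 1L
      add("fixation", ms(fix_durs[fi]))
    } else {
      si <- si + 1L
      add("stimulus", block_ms, condition = conds[si], block_id = si)
      add("iti", ms(itis[si]))
    }
  }
  add("lead", ms(timing$lead_out))
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  ev
}

#' Build one main-experiment miniblock run
#'
#' Schedules \code{reps_per_condition} blocks of each of the 14 conditions
#' (70 blocks by default), in randomized order without immediate condition
#' repetition, interleaved with 7 fixation-only blocks, with jittered
#' inter-block fixations balanced to their declared mean, lead-in and
#' lead-out. In \code{catch_per_condition} blocks per condition a catch
#' target ("######") replaces one stimulus at a random position after the
#' fifth. Block items are ordered so consecutive strings never share a
#' letter position.
#'
#' @param stimuli stimulus data.frame (columns \code{string},
#'   \code{category}) from \code{\link{build_design}}, or any set providing
#'   enough strings per condition.
#' @param reps_per_condition blocks per condition in this run (study: 5).
#' @param catch_per_condition catch blocks per condition (study: 2).
#' @param timing a \code{\link{timing_main}} spec.
#' @param seed integer seed.
#' @param items optional pre-allocated items: named list (one element per
#'   condition) of character matrices with \code{reps_per_condition} rows
#'   and \code{items_per_block} columns; used by
#'   \code{\link{build_main_session}} to counterbalance items across runs.
#' @return object of class \code{schedule}: \code{events} (onset, duration,
#'   kind, condition, block_id), \code{items} (per-block ordered strings,
#'   catch already substituted), \code{meta} (jitter sequence, catch
#'   positions, seed).
#' @export
build_main_run <- function(stimuli, reps_per_condition = 5L,
                           catch_per_condition = 2L,
                           timing = timing_main(), seed = 1L,
                           items = NULL) {
  labels <- condition_labels("enfr")
  if (catch_per_condition > reps_per_condition)
    stop("catch_per_condition cannot exceed reps_per_condition")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  ipb <- timing$items_per_block
  if (is.null(items)) {
    items <- lapply(labels, function(lab) {
      pool <- stimuli$string[stimuli$category == lab]
      need <- reps_per_condition * ipb
      if (length(pool) < need)
        stop("condition ", lab, " has ", length(pool),
             " strings but needs ", need)
      matrix(sample(pool, need), nrow = reps_per_condition)
    })
    names(items) <- labels
  }
  if (!all(labels %in% names(items)))
    stop("items must cover all 14 conditions")
  n_blocks <- length(labels) * reps_per_condition
  conds <- no_repeat_order(stats::setNames(rep(reps_per_condition,
                                               length(labels)), labels))
  itis <- sample(balanced_jitter(n_blocks, timing$iti_values))
  fix_durs <- sample(timing$fixation_durations)
  fix_slots <- sort(sample.int(n_blocks + timing$n_fixation_blocks,
                               timing$n_fixation_blocks))
  ev <- assemble_events(conds, itis, fix_durs, fix_slots, timing)
  # per-condition rep index for each block, catch assignment
  rep_idx <- stats::ave(seq_along(conds), conds, FUN = seq_along)
  catch_rep <- lapply(labels, function(lab)
    sample.int(reps_per_condition, catch_per_condition))
  names(catch_rep) <- labels
  ordered_by_cond <- lapply(seq_along(labels), function(i)
    order_condition_blocks(items[[labels[i]]], seed + 1000L * i))
  names(ordered_by_cond) <- labels
  block_items <- vector("list", n_blocks)
  catch_pos <- rep(NA_integer_, n_blocks)
  for (b in seq_len(n_blocks)) {
    lab <- conds[b]
    ordered <- ordered_by_cond[[lab]][[rep_idx[b]]]
    if (rep_idx[b] %in% catch_rep[[lab]]) {
      pos <- sample(6:ipb, 1L)
      ordered[pos] <- "######"
      catch_pos[b] <- pos
    }
    block_items[[b]] <- ordered
  }
  meta <- list(seed = as.integer(seed), conditions = conds,
               iti_s = itis, fixation_durations_s = fix_durs,
               fixation_slots = fix_slots, catch_pos = catch_pos,
               catch_target = "######")
  new_schedule(ev, block_items, timing, "main", meta)
}

#' Build the full three-run main session
#'
#' Partitions each condition's \code{3 * reps_per_condition *
#' items_per_block} stimuli into three runs so that every string is
#' presented exactly once in the session, then builds each run with
#' \code{\link{build_main_run}}.
#'
#' @inheritParams build_main_run
#' @param n_runs number of runs (study: 3).
#' @return list of \code{schedule} objects.
#' @export
build_main_session <- function(stimuli, n_runs = 3L,
                               reps_per_condition = 5L,
                               catch_per_condition = 2L,
                               timing = timing_main(), seed = 1L) {
  labels <- condition_labels("enfr")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  ipb <- timing$items_per_block
  per_run <- reps_per_condition * ipb
  alloc <- lapply(labels, function(lab) {
    pool <- stimuli$string[stimuli$category == lab]
    need <- n_runs * per_run
    if (length(pool) < need)
      stop("condition ", lab, " has ", length(pool),
           " strings but the session needs ", need)
    pool <- sample(pool, need)
    lapply(seq_len(n_runs), function(r)
      matrix(pool[seq((r - 1L) * per_run + 1L, r * per_run)],
             nrow = reps_per_condition))
  })
  names(alloc) <- labels
  run_seeds <- sample.int(1e6, n_runs)
  lapply(seq_len(n_runs), function(r) {
    items <- lapply(alloc, `[[`, r)
    build_main_run(stimuli = NULL,
                   reps_per_condition = reps_per_condition,
                   catch_per_condition = catch_per_condition,
                   timing = timing, seed = run_seeds[r], items = items)
  })
}

#' Build a localizer run
#'
#' Nine visual categories, \code{blocks_per_category} blocks each (45 blocks
#' of 6 s by default), jittered inter-block fixations balanced to their
#' declared mean, 6 s lead-in and lead-out. Two blocks per category carry a
#' star catch target at a random position after the fifth stimulus; the
#' checkerboard condition is exempt.
#'
#' @param categories character vector of category labels.
#' @param blocks_per_category blocks per category (study: 5).
#' @param catch_per_category catch blocks per category (study: 2).
#' @param catch_exempt categories without catch trials.
#' @param timing a \code{\link{timing_localizer}} spec.
#' @param seed integer seed.
#' @return a \code{schedule}; items are synthetic ids
#'   \code{<category>_<k>}, each used once in the run.
#' @export
build_localizer_run <- function(categories = c("words_en", "words_fr",
                                               "numbers", "false_fonts",
                                               "faces", "bodies", "houses",
                                               "tools", "checkerboard"),
                                blocks_per_category = 5L,
                                catch_per_category = 2L,
                                catch_exempt = "checkerboard",
                                timing = timing_localizer(), seed = 1L) {
  if (catch_per_category > blocks_per_category)
    stop("catch_per_category cannot exceed blocks_per_category")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  ipb <- timing$items_per_block
  n_blocks <- length(categories) * blocks_per_category
  conds <- no_repeat_order(stats::setNames(rep(blocks_per_category,
                                               length(categories)),
                                           categories))
  itis <- sample(balanced_jitter(n_blocks, timing$iti_values))
  ev <- assemble_events(conds, itis, numeric(0), integer(0), timing)
  rep_idx <- stats::ave(seq_along(conds), conds, FUN = seq_along)
  catch_rep <- lapply(categories, function(cat)
    if (cat %in% catch_exempt) integer(0) else
      sample.int(blocks_per_category, catch_per_category))
  names(catch_rep) <- categories
  block_items <- vector("list", n_blocks)
  catch_pos <- rep(NA_integer_, n_blocks)
  for (b in seq_len(n_blocks)) {
    cat_b <- conds[b]
    k0 <- (rep_idx[b] - 1L) * ipb
    ids <- sprintf("%s_%03d", cat_b, k0 + seq_len(ipb))
    ids <- sample(ids)
    if (rep_idx[b] %in% catch_rep[[cat_b]]) {
      pos <- sample(6:ipb, 1L)
      ids[pos] <- "*"
      catch_pos[b] <- pos
    }
    block_items[[b]] <- ids
  }
  meta <- list(seed = as.integer(seed), conditions = conds, iti_s = itis,
               catch_pos = catch_pos, catch_target = "*",
               catch_exempt = catch_exempt)
  new_schedule(ev, block_items, timing, "localizer", meta)
}

#' Summarize one or more run schedules
#'
#' @param schedules a \code{schedule} or a list of them.
#' @return list with \code{per_run} (data.frame: run, run_type, n_blocks,
#'   duration_s, n_volumes, catch_pct), \code{pooled} (same quantities over
#'   all runs) and \code{condition_counts} (condition x run matrix of block
#'   counts).
#' @export
schedule_summary <- function(schedules) {
  if (inherits(schedules, "schedule")) schedules <- list(schedules)
  if (!length(schedules)) stop("no schedules supplied")
  if (!all(vapply(schedules, inherits, TRUE, "schedule")))
    stop("all elements must be schedule objects")
  per <- do.call(rbind, lapply(seq_along(schedules), function(i) {
    s <- schedules[[i]]
    dur <- sum(s$events$duration)
    nb <- sum(s$events$kind == "stimulus")
    data.frame(run = i, run_type = s$run_type, n_blocks = nb,
               duration_s = dur,
               n_volumes = as.integer(ceiling(dur / s$timing$tr)),
               catch_pct = 100 * sum(!is.na(s$meta$catch_pos)) / nb)
  }))
  conds <- sort(unique(unlist(lapply(schedules,
                                     function(s) s$meta$conditions))))
  cc <- vapply(schedules, function(s)
    as.integer(table(factor(s$meta$conditions, levels = conds))),
    integer(length(conds)))
  cc <- matrix(cc, nrow = length(conds),
               dimnames = list(conds, paste0("run", seq_along(schedules))))
  pooled <- list(
    n_blocks = sum(per$n_blocks),
    duration_s = sum(per$duration_s),
    n_volumes = sum(per$n_volumes),
    catch_pct = 100 * sum(per$catch_pct / 100 * per$n_blocks) /
      sum(per$n_blocks))
  list(per_run = per, pooled = pooled, condition_counts = cc)
}

#' Write a schedule as a BIDS-style events table
#'
#' Columns: \code{onset}, \code{duration}, \code{trial_type},
#' \code{stim_file} (comma-joined ordered items with the catch target
#' substituted), \code{catch} (0/1).
#'
#' @param schedule a \code{schedule}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "schedule"))
  ev <- schedule$events
  stim_file <- rep(NA_character_, nrow(ev))
  is_stim <- ev$kind == "stimulus"
  stim_file[is_stim] <- vapply(ev$block_id[is_stim], function(b)
    paste(schedule$items[[b]], collapse = ","), "")
  catch <- integer(nrow(ev))
  catch[is_stim] <- as.integer(!is.na(schedule$meta$catch_pos[
    ev$block_id[is_stim]]))
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ifelse(is.na(ev$condition), ev$kind,
                                        ev$condition),
                    stim_file = stim_file, catch = catch)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Write a session manifest (seeds and jitter sequences) as JSON
#'
#' @param schedules list of \code{schedule} objects.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_session_manifest <- function(schedules, path) {
  if (inherits(schedules, "schedule")) schedules <- list(schedules)
  manifest <- lapply(schedules, function(s)
    list(run_type = s$run_type, seed = s$meta$seed,
         conditions = s$meta$conditions, iti_s = s$meta$iti_s,
         fixation_durations_s = s$meta$fixation_durations_s,
         catch_pos = s$meta$catch_pos))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
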